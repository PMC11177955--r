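#' Build the integer edge-edit program for a target coloring
#'
#' Constructs the exact integer program that edits a connectome with the
#' fewest weighted arc removals (`r_ij`) and additions (`a_ij`) so that a
#' target coloring becomes a balanced coloring of the edited graph. The
#' program carries, per arc, a binary removal variable; per non-edge, a binary
#' addition variable (all fixed to zero when additions are disallowed); and,
#' per ordered cross-colour node pair and colour `R`, a binary imbalance
#' indicator `s_pq^R` whose big-M constraints (M = n) force at least one
#' colour to distinguish every pair of differently coloured nodes -- a
#' necessary (not sufficient) condition for the target to be the *minimal*
#' balanced coloring, completed by [verify_and_repair_minimality()].
#'
#' @param g a `connectome`
#' @param target a `roi_coloring` partitioning `g`'s nodes
#' @param alpha,beta positive weights of removals and additions in the
#'   objective `alpha * sum(r) + beta * sum(a)`
#' @param allow_additions if `FALSE` (the removals-only hypothesis test), all
#'   addition variables are fixed to zero
#' @return an object of class `edit_program`
#' @export
build_edit_program <- function(g, target, alpha = 1, beta = 1,
                               allow_additions = FALSE) {
  stopifnot_connectome(g)
  bind_coloring(target, g)
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive", call. = FALSE)
  removal_vars <- dplyr::mutate(g$arcs,
                                var = paste0("r_", .data$from, "_", .data$to))
  ne <- non_edges(g)
  addition_vars <- dplyr::mutate(ne,
                                 var = paste0("a_", .data$from, "_", .data$to),
                                 fixed_zero = !allow_additions)
  memb <- membership(target)
  cls <- names(target$classes)
  pairs <- list()
  for (S in cls) for (T in cls) {
    if (S == T) next
    for (p in target$classes[[S]]) for (q in target$classes[[T]]) {
      pairs[[length(pairs) + 1L]] <- tibble::tibble(p = p, q = q, R = cls)
    }
  }
  imbalance_vars <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(p = character(), q = character(), R = character())
  imbalance_vars$var <- paste0("s_", imbalance_vars$p, "_", imbalance_vars$q,
                               "_", imbalance_vars$R)
  structure(list(graph = g, target = target, alpha = alpha, beta = beta,
                 allow_additions = allow_additions,
                 removal_vars = removal_vars, addition_vars = addition_vars,
                 imbalance_vars = imbalance_vars, big_m = n_nodes(g)),
            class = "edit_program")
}

#' @export
print.edit_program <- function(x, ...) {
  cat(sprintf(paste0("<edit_program> %d removal, %d addition (%s), %d imbalance",
                     " vars; alpha = %g, beta = %g\n"),
              nrow(x$removal_vars), nrow(x$addition_vars),
              if (x$allow_additions) "free" else "fixed 0",
              nrow(x$imbalance_vars), x$alpha, x$beta))
  invisible(x)
}

# ---- internal: profile-space representation -------------------------------
#
# The balance equalities force, for every target class T and source class S, a
# common retained+added in-count k[T, S] shared by all members of T. Costs
# separate per node (remove down to k or add up to k), the in-degree
# constraint becomes rowSums(k) >= 1, and the s-variable system is satisfiable
# exactly when the rows of k are pairwise distinct. Solving over these integer
# profiles is therefore *equivalent* to the arc-level integer program, at a
# tiny fraction of the search space; arc-level solutions are recovered by a
# deterministic lexicographic materialization.

edit_problem_data <- function(program) {
  g <- program$graph
  target <- program$target
  memb <- membership(target)
  cls <- names(target$classes)
  d <- in_count_table(g, memb, cls)
  avail_add <- matrix(0L, n_nodes(g), length(cls),
                      dimnames = dimnames(d))
  for (S in cls) {
    avail_add[, S] <- length(target$classes[[S]]) -
      (g$nodes %in% target$classes[[S]]) - d[, S]
  }
  list(g = g, cls = cls, classes = target$classes, d = d,
       avail_add = avail_add, memb = memb)
}

# per-class sorted profile tables: list of (cost, k-vector)
class_profiles <- function(pd, Tname, alpha, beta, allow_additions, cap = 2e5) {
  members <- pd$classes[[Tname]]
  kmax <- vapply(pd$cls, function(S) {
    lim <- pd$d[members, S, drop = TRUE]
    if (allow_additions) lim <- lim + pd$avail_add[members, S, drop = TRUE]
    min(lim)
  }, 0L)
  if (prod(kmax + 1) > cap) {
    stop("edit program too large for profile enumeration (", prod(kmax + 1),
         " profiles for one class)", call. = FALSE)
  }
  grid <- as.matrix(expand.grid(lapply(kmax, function(k) 0:k)))
  colnames(grid) <- pd$cls
  grid <- grid[rowSums(grid) >= 1L, , drop = FALSE]
  cost <- apply(grid, 1L, function(k) {
    sum(vapply(members, function(v) {
      dd <- pd$d[v, ]
      sum(alpha * pmax(0, dd - k) + beta * pmax(0, k - dd))
    }, 0))
  })
  ord <- order(cost)
  list(cost = cost[ord], k = grid[ord, , drop = FALSE])
}

# lazy enumeration of profile assignments in increasing total cost via a
# best-first search over index vectors into the per-class sorted profiles
assignment_stream <- function(profs, max_pop = 2e5) {
  K <- length(profs)
  heap <- list(list(cost = sum(vapply(profs, function(p) p$cost[1L], 0)),
                    idx = rep(1L, K)))
  seen <- new.env(parent = emptyenv())
  assign(paste(rep(1L, K), collapse = ","), TRUE, envir = seen)
  pops <- 0L
  nxt <- function() {
    while (length(heap)) {
      costs <- vapply(heap, `[[`, 0, "cost")
      i <- which.min(costs)
      node <- heap[[i]]
      heap[[i]] <<- NULL
      pops <<- pops + 1L
      if (pops > max_pop) stop("edit-program search cap exceeded", call. = FALSE)
      for (j in seq_len(K)) {
        idx2 <- node$idx
        idx2[j] <- idx2[j] + 1L
        if (idx2[j] > length(profs[[j]]$cost)) next
        key <- paste(idx2, collapse = ",")
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          heap[[length(heap) + 1L]] <<- list(
            cost = sum(vapply(seq_len(K),
                              function(t) profs[[t]]$cost[idx2[t]], 0)),
            idx = idx2)
        }
      }
      kmat <- do.call(rbind, lapply(seq_len(K),
                                    function(t) profs[[t]]$k[node$idx[t], ]))
      # distinct-profile (necessary minimality) filter
      if (anyDuplicated(apply(kmat, 1L, paste, collapse = ","))) next
      return(list(cost = node$cost, kmat = kmat))
    }
    NULL
  }
  nxt
}

# enumerate arc materializations of one profile assignment in a fixed
# deterministic order (slots by target node then source class; kept-source
# combinations in lexicographic order); returns up to `cap` of them
materializations <- function(pd, kmat, cap = 200L) {
  slots <- list()
  for (Tname in rownames(kmat)) {
    for (v in pd$classes[[Tname]]) {
      for (S in pd$cls) {
        k <- kmat[Tname, S]
        srcs <- pd$g$arcs$from[pd$g$arcs$to == v &
                                 pd$g$arcs$from %in% pd$classes[[S]]]
        srcs <- srcs[order(match(srcs, pd$g$nodes))]
        dd <- length(srcs)
        if (k <= dd) {
          if (k == dd) {
            choices <- list(list(keep = srcs, add = character(0)))
          } else {
            cmb <- utils::combn(srcs, k, simplify = FALSE)
            choices <- lapply(cmb, function(s) list(keep = s, add = character(0)))
          }
        } else {
          pool <- setdiff(pd$classes[[S]], c(v, srcs))
          pool <- pool[order(match(pool, pd$g$nodes))]
          cmb <- utils::combn(pool, k - dd, simplify = FALSE)
          choices <- lapply(cmb, function(s) list(keep = srcs, add = s))
        }
        slots[[length(slots) + 1L]] <- list(v = v, choices = choices)
      }
    }
  }
  n_choices <- vapply(slots, function(s) length(s$choices), 0L)
  total <- prod(n_choices)
  out <- list()
  idx <- rep(1L, length(slots))
  repeat {
    keep <- list(); add <- list()
    for (si in seq_along(slots)) {
      ch <- slots[[si]]$choices[[idx[si]]]
      v <- slots[[si]]$v
      if (length(ch$keep)) keep[[length(keep) + 1L]] <-
          tibble::tibble(from = ch$keep, to = v)
      if (length(ch$add)) add[[length(add) + 1L]] <-
          tibble::tibble(from = ch$add, to = v)
    }
    out[[length(out) + 1L]] <- list(
      kept = if (length(keep)) dplyr::bind_rows(keep) else
        tibble::tibble(from = character(), to = character()),
      added = if (length(add)) dplyr::bind_rows(add) else
        tibble::tibble(from = character(), to = character()))
    if (length(out) >= cap) break
    # odometer increment, last slot fastest
    si <- length(slots)
    repeat {
      if (si == 0L) break
      idx[si] <- idx[si] + 1L
      if (idx[si] <= n_choices[si]) break
      idx[si] <- 1L
      si <- si - 1L
    }
    if (si == 0L) break
  }
  out
}

arc_key <- function(df) paste(paste(df$from, df$to, sep = ">"), collapse = ";")

edit_signature <- function(removals, additions) {
  paste(arc_key(removals[order(removals$from, removals$to), , drop = FALSE]),
        arc_key(additions[order(additions$from, additions$to), , drop = FALSE]),
        sep = "|")
}

#' Solve an edge-edit program exactly
#'
#' Finds a minimum-objective edit (or reports infeasibility) by exact
#' branch-and-bound over per-class in-count profiles, which is equivalent to
#' the arc-level integer program (see [build_edit_program()]). Among optimal
#' edits, the returned solution is selected deterministically by a
#' lexicographic secondary criterion over the canonical removal-variable
#' order.
#'
#' @param program an `edit_program`
#' @param config optional list: `exclude` (edit-set signatures barred by
#'   no-good cuts), `max_assignments`, `max_materializations`
#' @return an object of class `edit_solution` with `status`
#'   (`"optimal"`/`"infeasible"`), `objective`, `removals`, `additions`,
#'   `edited_graph`, and `verified = FALSE`
#' @export
solve_edit_program <- function(program, config = list()) {
  if (!inherits(program, "edit_program")) stop("expected an `edit_program`", call. = FALSE)
  exclude <- config$exclude %||% character(0)
  max_mat <- config$max_materializations %||% 200L
  pd <- edit_problem_data(program)
  profs <- lapply(pd$cls, function(Tname)
    class_profiles(pd, Tname, program$alpha, program$beta,
                   program$allow_additions))
  names(profs) <- pd$cls
  if (any(vapply(profs, function(p) length(p$cost) == 0L, TRUE))) {
    return(infeasible_solution(program))
  }
  stream <- assignment_stream(profs, max_pop = config$max_assignments %||% 2e5)
  arcs_key <- paste(program$graph$arcs$from, program$graph$arcs$to)
  collect <- function(a) {
    rownames(a$kmat) <- pd$cls
    out <- list()
    for (mt in materializations(pd, a$kmat, cap = max_mat)) {
      removals <- program$graph$arcs[
        !arcs_key %in% paste(mt$kept$from, mt$kept$to), ]
      sig <- edit_signature(removals, mt$added)
      if (sig %in% exclude) next
      out[[length(out) + 1L]] <-
        list(cost = a$cost, removals = removals, additions = mt$added, sig = sig)
    }
    out
  }
  # walk assignments in increasing cost; stop at the first cost level that
  # yields at least one non-excluded arc materialization
  level_cost <- NULL
  candidates <- list()
  repeat {
    a <- stream()
    if (is.null(a)) break
    if (!is.null(level_cost) && a$cost > level_cost + 1e-9) {
      if (length(candidates)) break
      level_cost <- a$cost
    }
    if (is.null(level_cost)) level_cost <- a$cost
    candidates <- c(candidates, collect(a))
  }
  if (!length(candidates)) return(infeasible_solution(program))
  # lexicographic secondary objective over the canonical removal-variable
  # order (then additions)
  all_arcs <- paste(program$graph$arcs$from, program$graph$arcs$to)
  lex_key <- vapply(candidates, function(cd) {
    r <- as.integer(all_arcs %in% paste(cd$removals$from, cd$removals$to))
    paste(paste(r, collapse = ""), arc_key(cd$additions), sep = "|")
  }, "")
  best <- candidates[[order(lex_key)[1L]]]
  edited <- edit_arcs(program$graph, remove = best$removals, add = best$additions)
  structure(list(status = "optimal",
                 objective = program$alpha * nrow(best$removals) +
                   program$beta * nrow(best$additions),
                 removals = tibble::as_tibble(best$removals),
                 additions = tibble::as_tibble(best$additions),
                 edited_graph = edited,
                 verified = FALSE,
                 program = program,
                 signature = best$sig),
            class = "edit_solution")
}

infeasible_solution <- function(program) {
  structure(list(status = "infeasible", objective = NA_real_,
                 removals = NULL, additions = NULL, edited_graph = NULL,
                 verified = FALSE, program = program, signature = NA_character_),
            class = "edit_solution")
}

#' @export
print.edit_solution <- function(x, ...) {
  cat(sprintf("<edit_solution> status = %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective = %g (%d removals, %d additions), verified = %s",
                x$objective, nrow(x$removals), nrow(x$additions), x$verified))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.edit_solution <- function(x, ...) {
  if (x$status != "optimal") return(tibble::tibble(edit = character(),
                                                   from = character(),
                                                   to = character()))
  dplyr::bind_rows(
    dplyr::mutate(x$removals, edit = "remove"),
    dplyr::mutate(x$additions, edit = "add"))[, c("edit", "from", "to")]
}

#' @export
glance.edit_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective = x$objective,
                 n_removals = if (is.null(x$removals)) NA_integer_ else nrow(x$removals),
                 n_additions = if (is.null(x$additions)) NA_integer_ else nrow(x$additions),
                 verified = x$verified)
}

#' Verify that a solution's target is the minimal balanced coloring, repairing
#' by no-good cuts if not
#'
#' The imbalance constraints of the edit program are necessary but not
#' sufficient for minimality: two colour classes with identical profiles of
#' retained in-counts and no distinguishing colour can still merge under
#' refinement. This post-solve loop recomputes the minimal balanced coloring
#' of the edited graph; when it is coarser than the target, the current edit
#' set is excluded by a no-good cut and the program re-solved, up to
#' `max_iter` times.
#'
#' @param sol an optimal `edit_solution`
#' @param target the target `roi_coloring`
#' @param max_iter iteration cap
#' @return the solution with `verified = TRUE` and a `minimal_coloring` field
#' @export
verify_and_repair_minimality <- function(sol, target, max_iter = 25L) {
  if (sol$status != "optimal") stop("solution is not optimal", call. = FALSE)
  exclude <- character(0)
  for (i in seq_len(max_iter)) {
    mc <- minimal_balanced_coloring(sol$edited_graph)
    if (same_partition(mc, target)) {
      sol$verified <- TRUE
      sol$minimal_coloring <- mc
      return(sol)
    }
    exclude <- c(exclude, sol$signature)
    sol <- solve_edit_program(sol$program, config = list(exclude = exclude))
    if (sol$status != "optimal") {
      stop("no verifiable solution: all remaining optima are excluded and ",
           "the program is exhausted", call. = FALSE)
    }
  }
  mc <- minimal_balanced_coloring(sol$edited_graph)
  stop("minimality repair cap exhausted; coarsest balanced coloring found has ",
       n_classes(mc), " classes vs ", n_classes(target), " in the target",
       call. = FALSE)
}

#' Infer the structural network sustaining a synchronization coloring
#'
#' End-to-end build / solve / verify: edits the baseline connectome with
#' minimum cost so that the target coloring is the minimal balanced coloring
#' of the edited graph. In `removals_only` mode (the one-to-many
#' structure-function hypothesis) infeasibility is reported as status
#' `"hypothesis_falsified"` rather than an error.
#'
#' @param baseline a `connectome`
#' @param target a `roi_coloring` partitioning the baseline nodes
#' @param mode `"removals_only"` or `"joint"` (removals and additions)
#' @param alpha,beta objective weights
#' @param max_iter cap for the minimality repair loop
#' @return a verified `edit_solution` (fields `edited_graph`, `removals`,
#'   `additions`, `objective`), or an unverified one with status
#'   `"hypothesis_falsified"`
#' @export
infer_structural_network <- function(baseline, target,
                                     mode = c("removals_only", "joint"),
                                     alpha = 1, beta = 1, max_iter = 25L) {
  mode <- match.arg(mode)
  program <- build_edit_program(baseline, target, alpha = alpha, beta = beta,
                                allow_additions = mode == "joint")
  sol <- solve_edit_program(program)
  if (sol$status == "infeasible") {
    if (mode == "removals_only") {
      sol$status <- "hypothesis_falsified"
      return(sol)
    }
    stop("edit program infeasible even with additions", call. = FALSE)
  }
  verify_and_repair_minimality(sol, target, max_iter = max_iter)
}

#' Export an edit program in LP file format
#'
#' Writes the full arc-level integer program (objective, balance equalities,
#' in-degree constraints, big-M imbalance constraints, binary declarations) in
#' CPLEX LP format for use with external solvers.
#'
#' @param program an `edit_program`
#' @param path output path
#' @export
write_lp <- function(program, path) {
  g <- program$graph
  target <- program$target
  memb <- membership(target)
  n <- n_nodes(g)
  rv <- function(from, to) paste0("r_", from, "_", to)
  av <- function(from, to) paste0("a_", from, "_", to)
  in_terms <- function(p, S) {
    srcs <- g$arcs$from[g$arcs$to == p & memb[g$arcs$from] == S]
    adds <- if (program$allow_additions) {
      setdiff(target$classes[[S]], c(p, srcs))
    } else character(0)
    list(d = length(srcs), r = rv(srcs, rep(p, length(srcs))),
         a = av(adds, rep(p, length(adds))))
  }
  lines <- c("Minimize",
             paste(" obj:",
                   paste(c(paste(program$alpha, program$removal_vars$var, sep = " "),
                           if (program$allow_additions)
                             paste(program$beta, program$addition_vars$var, sep = " ")),
                         collapse = " + ")),
             "Subject To")
  cname <- 0L
  add_con <- function(txt) {
    cname <<- cname + 1L
    lines <<- c(lines, paste0(" c", cname, ": ", txt))
  }
  lincomb <- function(tp, tq) {
    terms <- c(paste0("- ", tp$r), paste0("+ ", tp$a),
               paste0("+ ", tq$r), paste0("- ", tq$a))
    if (!length(terms)) "0 r_dummy" else paste(terms, collapse = " ")
  }
  for (S in names(target$classes)) {
    mem <- target$classes[[S]]
    for (Tn in names(target$classes)) {
      tgt <- target$classes[[Tn]]
      if (length(tgt) < 2L) next
      p <- tgt[1L]
      for (q in tgt[-1L]) {
        tp <- in_terms(p, S); tq <- in_terms(q, S)
        add_con(paste(lincomb(tp, tq), "=", tq$d - tp$d))
      }
    }
  }
  for (p in g$nodes) {
    srcs <- g$arcs$from[g$arcs$to == p]
    adds <- if (program$allow_additions) setdiff(g$nodes, c(p, srcs)) else character(0)
    terms <- c(paste0("- ", rv(srcs, rep(p, length(srcs)))),
               paste0("+ ", av(adds, rep(p, length(adds)))))
    add_con(paste(paste(terms, collapse = " "), ">=", 1L - length(srcs)))
  }
  iv <- program$imbalance_vars
  done_pairs <- character(0)
  for (i in seq_len(nrow(iv))) {
    p <- iv$p[i]; q <- iv$q[i]; R <- iv$R[i]
    tp <- in_terms(p, R); tq <- in_terms(q, R)
    spq <- iv$var[i]
    sqp <- paste0("s_", q, "_", p, "_", R)
    add_con(paste(lincomb(tq, tp), "-", spq, "+", n, sqp, ">=", tq$d - tp$d))
    pr_key <- paste(sort(c(p, q)), collapse = "|")
    if (!paste(pr_key, R) %in% done_pairs) {
      add_con(paste(spq, "+", sqp, "<=", 1))
      done_pairs <- c(done_pairs, paste(pr_key, R))
    }
    if (R == iv$R[i] && i == min(which(iv$p == p & iv$q == q))) {
      all_s <- c(paste0("s_", p, "_", q, "_", unique(iv$R)),
                 paste0("s_", q, "_", p, "_", unique(iv$R)))
      add_con(paste(paste(all_s, collapse = " + "), ">=", 1))
    }
  }
  bins <- c(program$removal_vars$var,
            if (program$allow_additions) program$addition_vars$var,
            unique(c(iv$var, paste0("s_", iv$q, "_", iv$p, "_", iv$R))))
  lines <- c(lines, "Binary", paste(" ", bins), "End")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
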