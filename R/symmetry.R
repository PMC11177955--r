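#' Is a coloring balanced (equitable) on a connectome?
#'
#' A coloring is balanced when nodes of one colour receive identical colour
#' count vectors from their in-neighbours: for every class and every pair of
#' its members, the number of in-arcs arriving from each colour is the same.
#' Balanced colorings are exactly the fiber partitions of graph fibrations,
#' and their classes synchronize under any admissible dynamics.
#'
#' @param g a `connectome`
#' @param c a `roi_coloring` partitioning `g`'s nodes
#' @return a list with `balanced` (logical) and `violations`, a tibble of
#'   `(node_a, node_b, color)` triples where two same-coloured nodes receive
#'   different in-counts from `color`.
#' @export
is_balanced <- function(g, c) {
  stopifnot_connectome(g)
  bind_coloring(c, g)
  memb <- membership(c)
  counts <- in_count_table(g, memb, names(c$classes))
  viol <- list()
  for (cl in names(c$classes)) {
    members <- c$classes[[cl]]
    if (length(members) < 2L) next
    ref <- counts[members[1L], , drop = FALSE]
    for (v in members[-1L]) {
      diff_cols <- colnames(counts)[which(counts[v, , drop = FALSE] != ref)]
      for (r in diff_cols) {
        viol[[length(viol) + 1L]] <- tibble::tibble(
          node_a = members[1L], node_b = v, color = r)
      }
    }
  }
  viol <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(node_a = character(), node_b = character(), color = character())
  list(balanced = nrow(viol) == 0L, violations = viol)
}

# node x class matrix of in-arc counts per source colour
in_count_table <- function(g, memb, class_names) {
  counts <- matrix(0L, n_nodes(g), length(class_names),
                   dimnames = list(g$nodes, class_names))
  if (nrow(g$arcs)) {
    tab <- table(factor(g$arcs$to, levels = g$nodes),
                 factor(memb[g$arcs$from], levels = class_names))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Minimal balanced coloring (fiber partition) of a connectome
#'
#' Computes the coarsest balanced coloring by iterated refinement: start with
#' all nodes in one class and repeatedly split classes by the multiset of
#' in-neighbour colours until a fixed point. The result is the fiber partition
#' of the symmetry fibration; two nodes share a class exactly when their input
#' trees are isomorphic.
#'
#' Class names `f1, f2, ...` are assigned in canonical order (size descending,
#' then smallest member label), so the output is deterministic.
#'
#' @param g a non-empty `connectome`
#' @return a `roi_coloring`
#' @export
minimal_balanced_coloring <- function(g) {
  stopifnot_connectome(g)
  if (n_nodes(g) == 0L) stop("empty graph", call. = FALSE)
  inn <- in_neighbours(g)
  col <- stats::setNames(rep(1L, n_nodes(g)), g$nodes)
  repeat {
    sig <- vapply(g$nodes, function(v) {
      paste(col[v], paste(sort(col[inn[[v]]]), collapse = ","), sep = "|")
    }, "")
    new <- as.integer(factor(sig, levels = unique(sig)))
    names(new) <- g$nodes
    if (length(unique(new)) == length(unique(col))) break
    col <- new
  }
  cl <- roi_coloring(split(g$nodes, col))
  names(cl$classes) <- paste0("f", seq_along(cl$classes))
  cl
}

#' Input tree of a node, truncated at a given depth
#'
#' The input tree of node v is the rooted tree whose root has one child per
#' in-neighbour of v, each child carrying (recursively) the input tree of that
#' in-neighbour. It encodes the history of all directed walks terminating at
#' v. Depth n-1 suffices to decide fiber equivalence on an n-node graph, so
#' trees are truncated here rather than infinite.
#'
#' @param g a `connectome`
#' @param v a node label
#' @param depth non-negative truncation depth; a depth-0 tree is a bare root
#' @return a nested list with fields `node`, `depth`, `children`
#' @export
input_tree <- function(g, v, depth) {
  stopifnot_connectome(g)
  if (!v %in% g$nodes) stop("unknown node: ", v, call. = FALSE)
  if (depth < 0) stop("depth must be non-negative", call. = FALSE)
  inn <- in_neighbours(g)
  # memoize on (node, depth): subtrees repeat heavily, so the nested
  # structure shares sub-objects and the canonical form is computed once
  memo <- new.env(parent = emptyenv())
  build <- function(u, d) {
    key <- paste0(u, "\r", d)
    if (!is.null(memo[[key]])) return(memo[[key]])
    kids <- if (d == 0L) list() else lapply(inn[[u]], build, d = d - 1L)
    canon <- paste0("(", paste(sort(vapply(kids, attr, "", "canon")),
                               collapse = ""), ")")
    t <- structure(list(node = u, depth = d, children = kids),
                   class = "input_tree", canon = canon)
    memo[[key]] <- t
    t
  }
  build(v, as.integer(depth))
}

#' @export
print.input_tree <- function(x, ...) {
  cat(sprintf("<input_tree> root %s, depth %d, %d children\n",
              x$node, x$depth, length(x$children)))
  invisible(x)
}

# AHU-style canonical form: children are unordered, so sort child canons;
# trees built by input_tree() carry the form precomputed
tree_canon <- function(t) {
  pre <- attr(t, "canon")
  if (!is.null(pre)) return(pre)
  if (!length(t$children)) return("()")
  paste0("(", paste(sort(vapply(t$children, tree_canon, "")), collapse = ""), ")")
}

#' Are two input trees isomorphic (as unordered rooted trees)?
#'
#' @param t1,t2 `input_tree` objects of equal truncation depth
#' @return logical verdict
#' @export
input_trees_isomorphic <- function(t1, t2) {
  if (t1$depth != t2$depth) stop("input trees have different depths", call. = FALSE)
  identical(tree_canon(t1), tree_canon(t2))
}

#' Enumerate the automorphism group of a connectome
#'
#' An automorphism is a node permutation that preserves both adjacency and
#' non-adjacency; equivalently its permutation matrix P commutes with the
#' adjacency matrix A (PA = AP). The search backtracks over nodes, pruning
#' candidate images to nodes in the same fiber with matching in/out degrees
#' (orbits always refine fibers, so this loses nothing), which keeps exact
#' enumeration fast for the small graphs this package targets.
#'
#' @param g a `connectome` with at most `max_nodes` nodes
#' @param max_nodes enumeration size cap (default 16)
#' @return an object of class `automorphism_group`: list with `elements`
#'   (list of named permutation vectors, identity first), `generators` (a
#'   greedily minimized generating subset), and `n` (group order).
#' @export
enumerate_automorphisms <- function(g, max_nodes = 16L) {
  stopifnot_connectome(g)
  n <- n_nodes(g)
  if (n > max_nodes) {
    stop("graph has ", n, " nodes; exact enumeration is capped at ", max_nodes,
         " (raise `max_nodes` to force a longer pruned search)", call. = FALSE)
  }
  A <- adjacency_matrix(g)
  fib <- membership(minimal_balanced_coloring(g))[g$nodes]
  indeg <- colSums(A); outdeg <- rowSums(A)
  fsize <- table(fib)
  cands <- lapply(g$nodes, function(v) {
    g$nodes[fsize[fib] == fsize[[fib[v]]] & indeg == indeg[[v]] & outdeg == outdeg[[v]]]
  })
  names(cands) <- g$nodes
  elements <- list()
  perm <- character(0)
  bt <- function(i, used) {
    if (i > n) {
      p <- perm; names(p) <- g$nodes
      elements[[length(elements) + 1L]] <<- p
      return(invisible(NULL))
    }
    v <- g$nodes[i]
    for (u in cands[[v]]) {
      if (u %in% used) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        w <- g$nodes[j]; pw <- perm[j]
        if (A[v, w] != A[u, pw] || A[w, v] != A[pw, u]) { ok <- FALSE; break }
      }
      if (ok) {
        perm[i] <<- u
        bt(i + 1L, c(used, u))
        perm <<- perm[seq_len(i - 1L)]
      }
    }
  }
  bt(1L, character(0))
  # identity first, then lexicographic on image sequence
  ord <- order(vapply(elements, function(p) paste(p, collapse = "\r"), ""))
  elements <- elements[ord]
  id_at <- which(vapply(elements, function(p) all(p == g$nodes), TRUE))
  elements <- c(elements[id_at], elements[-id_at])
  structure(list(elements = elements,
                 generators = find_generators(elements, g$nodes),
                 n = length(elements)),
            class = "automorphism_group")
}

#' @export
print.automorphism_group <- function(x, ...) {
  cat(sprintf("<automorphism_group> order %d, %d generator(s)\n", x$n,
              length(x$generators)))
  for (p in x$generators) cat(" ", cycle_notation(p), "\n")
  invisible(x)
}

compose_perm <- function(p, q) {
  out <- p[q]
  names(out) <- names(q)
  out
}

# grow a subgroup closure (hash-set of element keys) after adding `new_gen`
grow_closure <- function(closure, gens, new_gen, nodes) {
  pkey <- function(p) paste(p, collapse = "\r")
  if (exists(pkey(new_gen), envir = closure$keys)) return(closure)
  gens <- c(gens, list(new_gen))
  frontier <- list(new_gen)
  assign(pkey(new_gen), TRUE, envir = closure$keys)
  closure$elems[[length(closure$elems) + 1L]] <- new_gen
  while (length(frontier)) {
    nxt <- list()
    for (f in frontier) {
      for (e in closure$elems) {
        for (z in list(compose_perm(f, e), compose_perm(e, f))) {
          k <- pkey(z)
          if (!exists(k, envir = closure$keys)) {
            assign(k, TRUE, envir = closure$keys)
            closure$elems[[length(closure$elems) + 1L]] <- z
            nxt[[length(nxt) + 1L]] <- z
          }
        }
      }
    }
    frontier <- nxt
  }
  closure
}

# greedily minimized generating subset; skipped (empty) for groups larger
# than `max_order`, where listing generators has no reporting value and the
# closure bookkeeping would dominate the enumeration itself
find_generators <- function(elements, nodes, max_order = 1024L) {
  if (length(elements) <= 1L || length(elements) > max_order) return(list())
  id <- stats::setNames(nodes, nodes)
  closure <- list(elems = list(id), keys = new.env(parent = emptyenv()))
  assign(paste(id, collapse = "\r"), TRUE, envir = closure$keys)
  gens <- list()
  for (p in elements) {
    if (all(p == nodes)) next
    if (exists(paste(p, collapse = "\r"), envir = closure$keys)) next
    closure <- grow_closure(closure, gens, p, nodes)
    gens[[length(gens) + 1L]] <- p
    if (length(closure$elems) == length(elements)) break
  }
  gens
}

#' Cycle notation for a node permutation
#' @param p named character vector mapping node -> image
#' @return a string such as `"(WA_L SMG_L)(WA_R SMG_R)"`; the identity is `"Id"`
#' @export
cycle_notation <- function(p) {
  nodes <- names(p)
  seen <- character(0)
  cycles <- character(0)
  for (v in nodes) {
    if (v %in% seen || p[[v]] == v) { seen <- c(seen, v); next }
    cyc <- v; u <- p[[v]]
    while (u != v) { cyc <- c(cyc, u); u <- p[[u]] }
    seen <- c(seen, cyc)
    cycles <- c(cycles, paste0("(", paste(cyc, collapse = " "), ")"))
  }
  if (!length(cycles)) "Id" else paste(cycles, collapse = "")
}

#' Orbit partition induced by an automorphism group
#'
#' The orbit of node i is the set of nodes that some group element maps i to.
#' Orbits are disjoint, cover the node set, and always refine the fiber
#' partition.
#'
#' @param group an `automorphism_group` enumerated for `g`
#' @param g the `connectome` the group acts on
#' @return a `roi_coloring` whose classes are the orbits
#' @export
orbit_partition <- function(group, g) {
  stopifnot_connectome(g)
  parent <- stats::setNames(seq_along(g$nodes), g$nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (p in group$elements) {
    for (v in g$nodes) {
      a <- find(match(v, g$nodes)); b <- find(match(p[[v]], g$nodes))
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(g$nodes), find, 1L)
  cl <- roi_coloring(split(g$nodes, roots))
  names(cl$classes) <- paste0("S", seq_along(cl$classes))
  cl
}

#' Minimal base of the symmetry fibration
#'
#' Collapses each fiber of a balanced coloring to a single base node. Because
#' the coloring is balanced, every member of a fiber receives the same number
#' of in-arcs from each source fiber; that common count is the lift
#' multiplicity annotated on each base arc, and the lifting property holds by
#' construction.
#'
#' @param g a `connectome`
#' @param fibers a balanced `roi_coloring` of `g`
#' @return a list with `base` (a `connectome` over fiber names; base
#'   self-arcs, which arise when a fiber feeds itself, live only in the
#'   multiplicity table because connectomes are simple digraphs) and
#'   `multiplicities` (tibble `from_fiber`, `to_fiber`, `multiplicity`,
#'   including self-arcs).
#' @export
minimal_base <- function(g, fibers) {
  chk <- is_balanced(g, fibers)
  if (!chk$balanced) {
    stop("coloring is not balanced; cannot form a base (",
         nrow(chk$violations), " violation(s))", call. = FALSE)
  }
  memb <- membership(fibers)
  counts <- in_count_table(g, memb, names(fibers$classes))
  reps <- vapply(fibers$classes, `[`, "", 1L)
  mult <- dplyr::bind_rows(lapply(names(fibers$classes), function(to) {
    tibble::tibble(from_fiber = names(fibers$classes), to_fiber = to,
                   multiplicity = as.integer(counts[reps[[to]], ]))
  }))
  mult <- mult[mult$multiplicity > 0L, ]
  proper <- mult[mult$from_fiber != mult$to_fiber, ]
  base <- connectome(data.frame(from = proper$from_fiber, to = proper$to_fiber),
                     nodes = names(fibers$classes), directed = TRUE)
  list(base = base, multiplicities = mult)
}
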