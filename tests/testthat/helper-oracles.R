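# Independent oracles used to cross-check the package implementations.
# Everything here is deliberately brute-force and shares no code path with R/.

random_digraph <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  connectome(pairs[keep, , drop = FALSE], nodes = nodes, directed = TRUE)
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# full-enumeration automorphism oracle (n <= 6)
brute_automorphisms <- function(g) {
  A <- adjacency_matrix(g)
  n <- n_nodes(g)
  perms <- all_permutations(seq_len(n))
  keep <- Filter(function(p) identical(A[p, p], unname(A)) ||
                   all(A[p, p] == A), perms)
  lapply(keep, function(p) stats::setNames(g$nodes[p], g$nodes))
}

# independent balance check from in-count tables
oracle_balanced <- function(arcs, classes) {
  memb <- rep(names(classes), lengths(classes))
  names(memb) <- unlist(classes)
  for (cl in classes) {
    if (length(cl) < 2L) next
    cnt <- lapply(cl, function(v) {
      srcs <- arcs$from[arcs$to == v]
      table(factor(memb[srcs], levels = names(classes)))
    })
    for (k in seq_along(cnt)[-1L]) {
      if (!all(cnt[[k]] == cnt[[1L]])) return(FALSE)
    }
  }
  TRUE
}

# exhaustive removal-subset oracle for the removals-only edit program:
# minimum number of removals such that the target is balanced, every node
# keeps in-degree >= 1, and class in-profiles are pairwise distinct
brute_min_removals <- function(g, target) {
  arcs <- g$arcs
  m <- nrow(arcs)
  classes <- target$classes
  memb <- rep(names(classes), lengths(classes))
  names(memb) <- unlist(classes)
  best <- Inf
  for (mask in 0:(2^m - 1)) {
    removed <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    k <- sum(removed)
    if (k >= best) next
    kept <- arcs[!removed, , drop = FALSE]
    if (!all(g$nodes %in% kept$to)) next
    if (!oracle_balanced(kept, classes)) next
    prof <- vapply(names(classes), function(Tn) {
      v <- classes[[Tn]][1L]
      srcs <- kept$from[kept$to == v]
      paste(table(factor(memb[srcs], levels = names(classes))), collapse = ",")
    }, "")
    if (anyDuplicated(prof)) next
    best <- k
  }
  best
}

random_plv_matrix <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- sample(seq(0.05, 0.95, length.out = n * (n - 1) / 2))
  m <- m + t(m)
  diag(m) <- 1
  plv_matrix_obj(m, LETTERS[seq_len(n)])
}

# exhaustive-subset replay oracle for cluster-synchronization detection:
# enumerate every proper subset (size >= 2), keep those that are maximal
# cliques of the graph thresholded at their weakest internal link and satisfy
# the clique condition, then replay them in formation order with the
# freeze/growth rule and the coverage stop
cs_oracle <- function(m) {
  labs <- m$roi_labels
  n <- length(labs)
  vals <- m$values
  cands <- list()
  for (mask in 1:(2^n - 1)) {
    members <- labs[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))]
    if (length(members) < 2L || length(members) >= n) next
    sub <- vals[members, members]
    intra <- sub[upper.tri(sub)]
    wform <- min(intra)
    outside <- setdiff(labs, members)
    if (any(vapply(outside, function(v) all(vals[v, members] >= wform), TRUE))) next
    if (mean(intra) < max(vals[members, outside]) - 1e-12) next
    cands[[length(cands) + 1L]] <-
      list(members = sort(members), plv = mean(intra), wform = wform)
  }
  ord <- order(-vapply(cands, `[[`, 0, "wform"),
               -vapply(cands, `[[`, 0, "plv"),
               -lengths(lapply(cands, `[[`, "members")),
               vapply(cands, function(x) x$members[1L], ""))
  cands <- cands[ord]
  pool <- list()
  batches <- unique(vapply(cands, `[[`, 0, "wform"))
  for (w in batches) {
    for (cd in cands[vapply(cands, `[[`, 0, "wform") == w]) {
      overlapping <- which(vapply(pool, function(p) any(p$members %in% cd$members), TRUE))
      if (length(overlapping) &&
          !all(vapply(pool[overlapping], function(p)
            all(p$members %in% cd$members), TRUE))) next
      if (length(overlapping)) pool <- pool[-overlapping]
      pool[[length(pool) + 1L]] <- cd
    }
    if (all(labs %in% unlist(lapply(pool, `[[`, "members")))) break
  }
  ord <- order(-vapply(pool, `[[`, 0, "plv"),
               -lengths(lapply(pool, `[[`, "members")),
               vapply(pool, function(x) x$members[1L], ""))
  lapply(pool[ord], function(x) x[c("members", "plv")])
}

# direct grid-inversion sampler of the von Mises distribution (independent of
# the package's rejection sampler)
grid_vonmises <- function(n, kappa, grid = 4096L) {
  th <- seq(-pi, pi, length.out = grid)
  sample(th, n, replace = TRUE, prob = exp(kappa * cos(th)))
}

random_coloring <- function(nodes, k, seed = 1) {
  set.seed(seed)
  repeat {
    assign <- sample.int(k, length(nodes), replace = TRUE)
    if (length(unique(assign)) == k) break
  }
  roi_coloring(split(nodes, assign))
}
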