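path_abc <- function() connectome(data.frame(from = c("A", "B"), to = c("B", "C")))

test_that("balance verdicts match hand-computed in-sets", {
  g <- path_abc()
  bad <- is_balanced(g, roi_coloring(list(c("A", "C"), "B")))
  expect_false(bad$balanced)
  expect_true(all(c("A", "C") %in% c(bad$violations$node_a, bad$violations$node_b)))

  singletons <- roi_coloring(as.list(c("A", "B", "C")))
  expect_true(is_balanced(g, singletons)$balanced)

  base <- baseline_connectome()
  printed <- roi_coloring(list(
    c("PreMA_L", "PreMA_R"), c("BA_L", "BA_R"), c("AG_L", "AG_R"),
    c("WA_L", "WA_R", "SMG_L", "SMG_R"), "SMA"))
  expect_true(is_balanced(base, printed)$balanced)
})

test_that("refinement finds the coarsest balanced coloring on canonical cases", {
  edgeless <- connectome(data.frame(from = character(), to = character()),
                         nodes = c("A", "B", "C"))
  expect_equal(n_classes(minimal_balanced_coloring(edgeless)), 1L)

  cyc <- connectome(data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")))
  expect_equal(n_classes(minimal_balanced_coloring(cyc)), 1L)

  fib <- minimal_balanced_coloring(baseline_connectome())
  expect_equal(n_classes(fib), 5L)
  expect_true("SMA" %in% unlist(fib$classes[lengths(fib$classes) == 1L]))
})

test_that("merging any two classes of the minimal coloring breaks balance", {
  for (seed in 1:8) {
    g <- random_digraph(sample(4:7, 1), seed = seed)
    mc <- minimal_balanced_coloring(g)
    expect_true(is_balanced(g, mc)$balanced)
    if (n_classes(mc) < 2L) next
    for (i in seq_len(n_classes(mc) - 1L)) {
      merged <- mc$classes
      merged[[i]] <- c(merged[[i]], merged[[i + 1L]])
      merged[[i + 1L]] <- NULL
      expect_false(is_balanced(g, roi_coloring(merged))$balanced)
    }
  }
})

test_that("input trees truncate correctly and decide fiber equivalence", {
  g <- path_abc()
  t0 <- input_tree(g, "A", 5)
  expect_equal(length(t0$children), 0L)   # in-degree 0 -> bare root

  two <- connectome(data.frame(from = c("A", "B"), to = c("B", "A")))
  t3 <- input_tree(two, "A", 3)
  expect_equal(length(t3$children), 1L)
  expect_equal(length(t3$children[[1L]]$children), 1L)

  expect_error(input_tree(g, "Z", 1), "unknown")
  expect_error(input_trees_isomorphic(input_tree(g, "A", 1),
                                      input_tree(g, "A", 2)), "depth")

  base <- baseline_connectome()
  fib <- minimal_balanced_coloring(base)
  d <- n_nodes(base) - 1L
  trees <- lapply(stats::setNames(base$nodes, base$nodes),
                  function(v) input_tree(base, v, 10))
  expect_true(input_trees_isomorphic(trees[["WA_L"]], trees[["SMG_L"]]))
  for (cl in fib$classes) {
    for (v in cl[-1L]) {
      expect_true(input_trees_isomorphic(trees[[cl[1L]]], trees[[v]]))
    }
  }
  reps <- vapply(fib$classes, `[`, "", 1L)
  for (i in seq_along(reps)) for (j in seq_along(reps)) {
    if (i < j) expect_false(input_trees_isomorphic(trees[[reps[i]]],
                                                   trees[[reps[j]]]))
  }
})

test_that("refinement equals the input-tree isomorphism partition at depth n-1", {
  for (seed in 1:15) {
    g <- random_digraph(sample(3:7, 1), seed = 100 + seed)
    canon <- vapply(g$nodes, function(v)
      fibrasym:::tree_canon(input_tree(g, v, n_nodes(g) - 1L)), "")
    tree_part <- roi_coloring(split(g$nodes, canon))
    expect_true(same_partition(minimal_balanced_coloring(g), tree_part))
  }
})

test_that("automorphism enumeration is exact on canonical groups", {
  k3 <- connectome(expand.grid(from = c("A", "B", "C"), to = c("A", "B", "C"),
                               stringsAsFactors = FALSE) |>
                     dplyr::filter(from != to))
  expect_equal(enumerate_automorphisms(k3)$n, 6L)

  base <- baseline_connectome()
  grp <- enumerate_automorphisms(base)
  keys <- vapply(grp$elements, function(p) paste(p[base$nodes], collapse = " "), "")
  pi1 <- mirror_permutation(); pi2 <- wa_smg_swap()
  expect_true(paste(pi1[base$nodes], collapse = " ") %in% keys)
  expect_true(paste(pi2[base$nodes], collapse = " ") %in% keys)

  big <- random_digraph(17, seed = 1)
  expect_error(enumerate_automorphisms(big), "capped")
})

test_that("every enumerated element commutes with the adjacency matrix and the group is closed", {
  g <- baseline_connectome()
  A <- adjacency_matrix(g)
  grp <- enumerate_automorphisms(g)
  for (p in grp$elements) {
    P <- matrix(0L, n_nodes(g), n_nodes(g), dimnames = dimnames(A))
    P[cbind(p[g$nodes], g$nodes)] <- 1L
    expect_true(all(P %*% A == A %*% P))
  }
  keys <- vapply(grp$elements, function(p) paste(p[g$nodes], collapse = " "), "")
  for (p in grp$elements) for (q in grp$elements) {
    pq <- fibrasym:::compose_perm(p, q)
    expect_true(paste(pq[g$nodes], collapse = " ") %in% keys)
  }
})

test_that("backtracking enumeration matches full-permutation oracle on small digraphs", {
  for (seed in 1:10) {
    g <- random_digraph(sample(3:5, 1), seed = 200 + seed)
    fast <- enumerate_automorphisms(g)
    slow <- brute_automorphisms(g)
    expect_equal(fast$n, length(slow))
  }
})

test_that("orbit partitions follow the group action", {
  base <- baseline_connectome()
  orb <- orbit_partition(enumerate_automorphisms(base), base)
  expect_equal(n_classes(orb), 5L)
  expect_true(any(vapply(orb$classes, function(cl)
    setequal(cl, c("WA_L", "WA_R", "SMG_L", "SMG_R")), TRUE)))

  pair <- connectome(data.frame(from = character(), to = character()),
                     nodes = c("A", "B"))
  orb2 <- orbit_partition(enumerate_automorphisms(pair), pair)
  expect_equal(n_classes(orb2), 1L)
})

test_that("orbits refine fibers and fiber count <= orbit count on random digraphs", {
  for (seed in 1:25) {
    g <- random_digraph(sample(3:8, 1), p = stats::runif(1, 0.25, 0.6),
                        seed = 300 + seed)
    fib <- minimal_balanced_coloring(g)
    orb <- orbit_partition(enumerate_automorphisms(g), g)
    expect_lte(n_classes(fib), n_classes(orb))
    fmemb <- membership(fib)
    for (cl in orb$classes) {
      expect_equal(length(unique(fmemb[cl])), 1L)
    }
  }
})

test_that("minimal base collapses fibers with well-defined lift multiplicities", {
  base <- baseline_connectome()
  fib <- minimal_balanced_coloring(base)
  mb <- minimal_base(base, fib)
  expect_equal(n_nodes(mb$base), 5L)

  cyc <- connectome(data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")))
  one <- minimal_base(cyc, roi_coloring(list(c("A", "B", "C"))))
  expect_equal(n_nodes(one$base), 1L)
  expect_equal(one$multiplicities$multiplicity, 1L)

  singl <- roi_coloring(as.list(cyc$nodes))
  iso <- minimal_base(cyc, singl)
  expect_equal(n_nodes(iso$base), 3L)
  expect_equal(n_arcs(iso$base), 3L)

  expect_error(minimal_base(path_abc(), roi_coloring(list(c("A", "C"), "B"))),
               "not balanced")
})
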