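test_that("program construction exposes the expected variable sets", {
  g <- baseline_connectome()
  rs <- load_coloring(system.file("extdata", "rs_coloring.json",
                                  package = "fibrasym"))
  p <- build_edit_program(g, rs, allow_additions = FALSE)
  expect_equal(nrow(p$removal_vars), n_arcs(g))
  expect_true(all(p$addition_vars$fixed_zero))
  expect_equal(nrow(p$addition_vars), 11 * 10 - n_arcs(g))
  expect_equal(p$big_m, 11L)
  expect_error(build_edit_program(g, rs, alpha = 0), "positive")
  expect_error(build_edit_program(g, roi_coloring(list(c("A", "B")))), "unknown")
})

test_that("an already-minimal coloring costs zero edits", {
  g <- baseline_connectome()
  fib <- minimal_balanced_coloring(g)
  sol <- solve_edit_program(build_edit_program(g, fib))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
  expect_equal(nrow(sol$removals), 0L)
  v <- verify_and_repair_minimality(sol, fib)
  expect_true(v$verified)
})

test_that("removals-only infeasibility surfaces as hypothesis_falsified", {
  # one arc, two singleton colours: A has no in-arc, so in-degree >= 1 fails
  g <- connectome(data.frame(from = "A", to = "B"))
  target <- roi_coloring(list("A", "B"))
  sol <- infer_structural_network(g, target, mode = "removals_only")
  expect_equal(sol$status, "hypothesis_falsified")
  # with additions allowed the program becomes feasible (balance + in-degree),
  # though on two nodes no digraph has two singleton fibers, so the
  # minimality verification correctly reports failure
  sol2 <- solve_edit_program(build_edit_program(g, target, allow_additions = TRUE))
  expect_equal(sol2$status, "optimal")
  expect_gte(nrow(sol2$additions), 1L)
  expect_true(is_balanced(sol2$edited_graph, target)$balanced)
  expect_error(infer_structural_network(g, target, mode = "joint"), "exhausted")
})

test_that("optimum matches the exhaustive removal-subset oracle on 4-node digraphs", {
  tried <- 0L
  for (seed in 1:40) {
    g <- random_digraph(4, p = 0.5, seed = 500 + seed)
    if (n_arcs(g) == 0L || n_arcs(g) > 12L) next
    target <- random_coloring(g$nodes, sample(2:3, 1), seed = 500 + seed)
    sol <- solve_edit_program(build_edit_program(g, target))
    want <- brute_min_removals(g, target)
    if (is.infinite(want)) {
      expect_equal(sol$status, "infeasible", info = paste("seed", seed))
    } else {
      expect_equal(sol$objective, want, info = paste("seed", seed))
      expect_true(is_balanced(sol$edited_graph, target)$balanced)
    }
    tried <- tried + 1L
  }
  expect_gte(tried, 20L)
})

test_that("solutions satisfy balance, in-degree and objective accounting post hoc", {
  g <- baseline_connectome()
  for (f in c("rs_coloring.json", "task_coloring.json")) {
    target <- load_coloring(system.file("extdata", f, package = "fibrasym"))
    sol <- solve_edit_program(build_edit_program(g, target))
    expect_equal(sol$status, "optimal")
    expect_true(is_balanced(sol$edited_graph, target)$balanced)
    indeg <- table(factor(sol$edited_graph$arcs$to, levels = g$nodes))
    expect_true(all(indeg >= 1L))
    expect_equal(sol$objective, nrow(sol$removals) + nrow(sol$additions))
  }
})

test_that("removals-only optimum is never below the joint optimum", {
  for (seed in 1:6) {
    g <- random_digraph(5, p = 0.45, seed = 600 + seed)
    if (!all(g$nodes %in% g$arcs$to)) next
    target <- random_coloring(g$nodes, 2, seed = seed)
    ro <- solve_edit_program(build_edit_program(g, target))
    jo <- solve_edit_program(build_edit_program(g, target, allow_additions = TRUE))
    if (ro$status == "optimal" && jo$status == "optimal") {
      expect_gte(ro$objective, jo$objective)
    }
  }
})

test_that("objective is invariant under node relabeling", {
  g <- random_digraph(5, p = 0.5, seed = 777)
  target <- random_coloring(g$nodes, 2, seed = 777)
  sol <- solve_edit_program(build_edit_program(g, target))
  relab <- stats::setNames(paste0("N", seq_along(g$nodes)), rev(g$nodes))
  g2 <- connectome(data.frame(from = relab[g$arcs$from], to = relab[g$arcs$to]),
                   nodes = unname(relab[rev(g$nodes)]))
  target2 <- roi_coloring(lapply(target$classes, function(cl) unname(relab[cl])))
  sol2 <- solve_edit_program(build_edit_program(g2, target2))
  expect_equal(sol2$status, sol$status)
  if (sol$status == "optimal") expect_equal(sol2$objective, sol$objective)
})

test_that("the repair loop rejects colorings that refinement merges", {
  # two colour classes with identical connectivity and no cross edges: the
  # necessary imbalance constraints pass but the minimal coloring is coarser
  g <- connectome(data.frame(from = c("A", "B", "C", "D"),
                             to   = c("B", "A", "D", "C")))
  target <- roi_coloring(list(c("A", "B"), c("C", "D")))
  sol <- solve_edit_program(build_edit_program(g, target))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
  expect_false(same_partition(minimal_balanced_coloring(sol$edited_graph), target))
  expect_error(verify_and_repair_minimality(sol, target, max_iter = 5),
               "exhausted|coarsest")
})

test_that("resting-state inference reproduces the reported symmetry breaking", {
  g <- baseline_connectome()
  rs <- load_coloring(system.file("extdata", "rs_coloring.json",
                                  package = "fibrasym"))
  sol <- infer_structural_network(g, rs, mode = "removals_only")
  expect_equal(sol$status, "optimal")
  expect_true(sol$verified)
  expect_equal(nrow(sol$additions), 0L)
  rep <- run_symmetry_report(sol$edited_graph, "rest")
  expect_equal(rep$n_fibers, 4L)
  expect_equal(rep$n_orbits, 11L)
  expect_equal(rep$automorphism_count, 1L)
})

test_that("task inference splits Broca and keeps eleven orbits", {
  g <- baseline_connectome()
  tk <- load_coloring(system.file("extdata", "task_coloring.json",
                                  package = "fibrasym"))
  sol <- infer_structural_network(g, tk, mode = "removals_only")
  expect_true(sol$verified)
  rep <- run_symmetry_report(sol$edited_graph, "task")
  expect_equal(rep$n_fibers, 5L)
  expect_equal(rep$n_orbits, 11L)
  fib <- rep$fibers$classes
  expect_true(any(vapply(fib, function(cl) setequal(cl, c("SMA", "BA_L")), TRUE)))
  expect_true(any(vapply(fib, function(cl)
    setequal(cl, c("BA_R", "WA_L", "WA_R")), TRUE)))
})

test_that("LP export writes a syntactically complete program", {
  g <- connectome(data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")))
  target <- roi_coloring(list(c("A", "B"), "C"))
  p <- build_edit_program(g, target)
  tmp <- withr::local_tempfile(fileext = ".lp")
  write_lp(p, tmp)
  txt <- readLines(tmp)
  expect_equal(txt[1L], "Minimize")
  expect_true(any(txt == "Subject To"))
  expect_true(any(txt == "Binary"))
  expect_equal(txt[length(txt)], "End")
  expect_true(any(grepl("r_A_B", txt)))
})
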