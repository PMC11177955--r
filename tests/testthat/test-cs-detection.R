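test_that("cluster_plv is the mean pairwise entry, matching reported values", {
  rest <- build_printed_plv_fixture("rest")
  expect_equal(cluster_plv(rest, c("SMG_L", "SMG_R")), 0.762)
  expect_equal(cluster_plv(rest, c("PreMA_L", "PreMA_R", "SMA", "WA_L", "WA_R")),
               0.712)

  m <- plv_matrix_obj(matrix(c(1, 0.2, 0.4, 0.2, 1, 0.6, 0.4, 0.6, 1), 3),
                      c("A", "B", "C"))
  expect_equal(cluster_plv(m, c("A", "B", "C")), 0.4)
  expect_error(cluster_plv(m, c("A", "Z")), "unknown")
  expect_error(cluster_plv(m, "A"), "at least 2")
})

test_that("the resting-state fixture yields the reported clique hierarchy", {
  r <- detect_cs(build_printed_plv_fixture("rest"))
  expect_length(r$cliques, 4L)
  expect_equal(lapply(r$cliques, `[[`, "members"),
               list(c("SMG_L", "SMG_R"),
                    c("PreMA_L", "PreMA_R", "SMA", "WA_L", "WA_R"),
                    c("AG_L", "AG_R"), c("BA_L", "BA_R")))
  expect_equal(vapply(r$cliques, `[[`, 0, "cluster_plv"),
               c(0.762, 0.712, 0.689, 0.689))
  expect_length(r$unassigned, 0L)
  top3 <- r$interclique_links[1:3, ]
  expect_equal(top3$plv, c(0.682, 0.662, 0.639))
  expect_setequal(paste(top3$node_a, top3$node_b),
                  c("WA_R AG_R", "SMA BA_L", "SMG_R PreMA_L"))
})

test_that("both task fixtures yield five cliques with the reported ranks", {
  v <- detect_cs(build_printed_plv_fixture("verb"))
  expect_equal(vapply(v$cliques, `[[`, 0, "cluster_plv"),
               c(0.764, 0.625, 0.624, 0.560, 0.538))
  expect_setequal(v$cliques[[1L]]$members, c("SMA", "BA_L"))
  p <- detect_cs(build_printed_plv_fixture("phonemic"))
  expect_equal(vapply(p$cliques, `[[`, 0, "cluster_plv"),
               c(0.725, 0.699, 0.595, 0.570, 0.550))
  expect_setequal(p$cliques[[2L]]$members, c("AG_L", "AG_R"))
  # same coloring, different rank order
  expect_true(same_partition(cs_to_coloring(v, language_rois()),
                             cs_to_coloring(p, language_rois())))
})

test_that("an isolated strong pair is the sole clique", {
  m <- matrix(0.1, 4, 4); diag(m) <- 1
  m[1, 2] <- m[2, 1] <- 0.9
  r <- detect_cs(plv_matrix_obj(m, c("A", "B", "C", "D")))
  expect_length(r$cliques, 1L)
  expect_equal(r$cliques[[1L]]$members, c("A", "B"))
  expect_equal(r$cliques[[1L]]$cluster_plv, 0.9)
})

test_that("an accepted pair grows into its true triangle", {
  m <- matrix(0.1, 5, 5); diag(m) <- 1
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.85
  m[2, 3] <- m[3, 2] <- 0.8
  r <- detect_cs(plv_matrix_obj(m, LETTERS[1:5]))
  expect_equal(r$cliques[[1L]]$members, c("A", "B", "C"))
})

test_that("every finalized clique satisfies the clique condition post hoc and is disjoint", {
  for (cond in c("rest", "verb", "phonemic")) {
    m <- build_printed_plv_fixture(cond)
    r <- detect_cs(m)
    members <- lapply(r$cliques, `[[`, "members")
    expect_equal(anyDuplicated(unlist(members)), 0L)
    plvs <- vapply(r$cliques, `[[`, 0, "cluster_plv")
    expect_true(all(diff(plvs) <= 1e-12))   # non-increasing hierarchy
    for (cl in r$cliques) {
      outside <- setdiff(m$roi_labels, cl$members)
      expect_gte(cl$cluster_plv + 1e-12, max(m$values[cl$members, outside]))
    }
  }
})

test_that("detection matches the exhaustive-subset oracle on random matrices", {
  for (seed in 1:25) {
    n <- sample(4:6, 1)
    m <- random_plv_matrix(n, seed = 400 + seed)
    got <- detect_cs(m)
    want <- cs_oracle(m)
    expect_equal(lapply(got$cliques, `[[`, "members"),
                 lapply(want, `[[`, "members"),
                 info = paste("seed", seed))
    expect_equal(vapply(got$cliques, `[[`, 0, "cluster_plv"),
                 vapply(want, `[[`, 0, "plv"), tolerance = 1e-12)
  }
})

test_that("cs_to_coloring maps cliques to classes and leftovers to singletons", {
  r <- detect_cs(build_printed_plv_fixture("rest"))
  col <- cs_to_coloring(r, language_rois())
  expect_equal(n_classes(col), 4L)
  rs <- load_coloring(system.file("extdata", "rs_coloring.json",
                                  package = "fibrasym"))
  expect_true(same_partition(col, rs))

  empty <- structure(list(cliques = list(), interclique_links = NULL,
                          unassigned = c("A", "B", "C"),
                          roi_labels = c("A", "B", "C")), class = "cs_result")
  expect_equal(n_classes(cs_to_coloring(empty, c("A", "B", "C"))), 3L)

  two <- structure(list(cliques = list(list(members = c("A", "B"), cluster_plv = 1),
                                       list(members = c("C", "D"), cluster_plv = 1)),
                        interclique_links = NULL, unassigned = "E",
                        roi_labels = LETTERS[1:5]), class = "cs_result")
  expect_equal(n_classes(cs_to_coloring(two, LETTERS[1:5])), 3L)
})

test_that("cs results serialize to JSON and tidy to tibbles", {
  r <- detect_cs(build_printed_plv_fixture("rest"))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_cs_result(r, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$cliques$cluster_plv, c(0.762, 0.712, 0.689, 0.689))
  td <- tidy(r)
  expect_equal(nrow(td), 11L)
  expect_equal(glance(r)$n_cliques, 4L)
})
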