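sweep_fixture <- function() {
  fx <- kp_generate_fixture(kp_fixture_spec(n_nodes = 15, n_edges = 22, n_cases = 20,
                                            module_size = 5, background_active_prob = 0.1,
                                            planted_active_prob = 0.95, seed = 12))
  fx$profile_l <- function(l) kp_activity_profile(fx$network, fx$matrices, list(M1 = l))
  fx
}

test_that("a degenerate 1x1 grid reproduces a direct solver run", {
  fx <- sweep_fixture()
  grid <- kp_sweep_grid(1L, list(M1 = list(kp_l("25%"))))
  sw <- kp_run_sweep(fx$network, fx$matrices, NULL, grid, algorithm = "exact")
  direct <- kp_enumerate_pathways(fx$network, fx$profile_l("25%"), kp_params(1))
  expect_identical(pathway_node_sets(sw$cells[[1]]$pathways),
                   pathway_node_sets(direct))
  expect_identical(sw$cells[[1]]$l, c(M1 = 5L))
})

test_that("max pathway size per cell is non-decreasing in K", {
  fx <- sweep_fixture()
  grid <- kp_sweep_grid(0:2, list(M1 = list(kp_l("25%"))))
  sw <- kp_run_sweep(fx$network, fx$matrices, NULL, grid, algorithm = "exact")
  sizes <- vapply(sw$cells, function(cell) {
    if (length(cell$pathways)) cell$pathways[[1]]$size else 0L
  }, 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("node scores reflect number and size of containing pathways, max-normalized", {
  cells <- list(list(pathways = list(kp_pathway(c("A", "B", "C")))))
  sc <- kp_node_scores(cells, c("A", "B", "C", "D"))
  expect_identical(sc, c(A = 1, B = 1, C = 1, D = 0))

  # v in two size-3 pathways vs w in one: raw 6 vs 3 -> scores 1.0 vs 0.5
  cells2 <- list(list(pathways = list(kp_pathway(c("v", "a", "b")),
                                      kp_pathway(c("v", "c", "d")))),
                 list(pathways = list(kp_pathway(c("w", "e", "f")))))
  sc2 <- kp_node_scores(cells2)
  expect_identical(sc2[["v"]], 1)
  expect_identical(sc2[["w"]], 0.5)

  expect_identical(unname(kp_node_scores(list(), c("A", "B"))), c(0, 0))
})

test_that("every cell is valid under its own parameters and scores peak at exactly 1", {
  fx <- sweep_fixture()
  grid <- kp_sweep_grid(0:1, list(M1 = list(kp_l("10%"), kp_l("25%"))))
  sw <- kp_run_sweep(fx$network, fx$matrices, NULL, grid, algorithm = "greedy")
  expect_length(sw$cells, 4L)
  for (cell in sw$cells) {
    profile <- fx$profile_l(cell$l[["M1"]])
    for (p in cell$pathways) {
      expect_true(kp_is_valid_pathway(p$nodes, fx$network, profile,
                                      kp_params(cell$k)))
    }
  }
  expect_true(all(sw$node_scores >= 0 & sw$node_scores <= 1))
  if (any(vapply(sw$cells, function(c) length(c$pathways) > 0, TRUE))) {
    expect_identical(max(sw$node_scores), 1)
  }
})

test_that("extending the grid to larger K never shrinks the positive-score node set", {
  fx <- sweep_fixture()
  small <- kp_run_sweep(fx$network, fx$matrices, NULL,
                        kp_sweep_grid(0:1, list(M1 = list(kp_l("25%")))),
                        algorithm = "exact")
  big <- kp_run_sweep(fx$network, fx$matrices, NULL,
                      kp_sweep_grid(0:3, list(M1 = list(kp_l("25%")))),
                      algorithm = "exact")
  covered_small <- names(small$node_scores)[small$node_scores > 0]
  covered_big <- names(big$node_scores)[big$node_scores > 0]
  expect_true(all(covered_small %in% covered_big))
})

test_that("heuristic sweeps are reproducible and write deterministic files", {
  fx <- sweep_fixture()
  grid <- kp_sweep_grid(0:1, list(M1 = list(kp_l("25%"))))
  s1 <- kp_run_sweep(fx$network, fx$matrices, NULL, grid, algorithm = "aco",
                     seed = 5, aco = kp_aco_config(n_ants = 5, n_iterations = 10))
  s2 <- kp_run_sweep(fx$network, fx$matrices, NULL, grid, algorithm = "aco",
                     seed = 5, aco = kp_aco_config(n_ants = 5, n_iterations = 10))
  expect_identical(s1, s2)

  d1 <- tempfile()
  d2 <- tempfile()
  kp_write_sweep(s1, fx$network, d1)
  kp_write_sweep(s2, fx$network, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
  expect_true("node_scores.tsv" %in% list.files(d1))
})
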