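test_that("percent thresholds resolve by ceiling and clamp absolute counts", {
  expect_identical(kp_resolve_l(kp_l("25%"), 155), 39L)
  expect_identical(kp_resolve_l(kp_l("25%"), 291), 73L)
  expect_identical(kp_resolve_l(kp_l("0%"), 7), 0L)
  expect_identical(kp_resolve_l(kp_l("100%"), 7), 7L)
  expect_identical(kp_resolve_l(kp_l("10%"), 50), 5L)   # exact fraction stays exact
  expect_warning(L <- kp_resolve_l(kp_l(5), 3), "clamped")
  expect_identical(L, 3L)
  expect_error(kp_l("150%"), "\\[0, 100\\]")
  expect_error(kp_l(-1), "non-negative")
  expect_error(kp_l(2.5), "integer")
})

test_that("percent resolution is non-decreasing in both percentage and case count", {
  for (n in c(1L, 10L, 155L, 291L)) {
    ls <- vapply(seq(0, 100, by = 5),
                 function(p) kp_resolve_l(kp_l(paste0(p, "%")), n), 0L)
    expect_true(all(diff(ls) >= 0))
  }
  for (p in c("10%", "25%", "33%")) {
    ls <- vapply(1:60, function(n) kp_resolve_l(kp_l(p), n), 0L)
    expect_true(all(diff(ls) >= 0))
  }
})

test_that("inactive-case counts and per-matrix activity follow the row contract", {
  vals <- rbind(g1 = c(1L, 0L, 1L, 0L), g2 = c(1L, 1L, 1L, 1L))
  m <- kp_indicator_matrix(vals, "M1")
  expect_identical(kp_count_inactive(m, c("g1", "g2")), c(g1 = 2L, g2 = 0L))
  expect_identical(kp_count_inactive(m, "absent"), c(absent = 4L))

  m2 <- kp_indicator_matrix(rbind(g1 = c(1L, 0L, 1L), g2 = c(0L, 0L, 1L)), "M2")
  expect_identical(kp_matrix_activity(m2, 1L, c("g1", "g2")),
                   c(g1 = TRUE, g2 = FALSE))
  # vacuous threshold L = n_cases, and strict L = 0
  expect_true(all(kp_matrix_activity(m2, 3L, c("g1", "g2", "zz"))))
  expect_identical(unname(kp_matrix_activity(m, 0L, c("g1", "g2"))), c(FALSE, TRUE))
})

test_that("activity under a fixed matrix is monotone in L", {
  set.seed(5)
  vals <- matrix(rbinom(200, 1, 0.5), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  m <- kp_indicator_matrix(vals, "M1")
  genes <- rownames(vals)
  prev <- rep(FALSE, 20)
  for (L in 0:10) {
    cur <- kp_matrix_activity(m, L, genes)
    expect_true(all(prev <= cur))
    prev <- cur
  }
})

test_that("formula parsing is left-associative with parentheses and named errors", {
  f <- kp_parse_formula("M1 AND M2 OR M3", c("M1", "M2", "M3"))
  expect_identical(format(f), "((M1 AND M2) OR M3)")
  f2 <- kp_parse_formula("(M1 AND M2) OR (M3 AND M4)", paste0("M", 1:4))
  expect_identical(format(f2), "((M1 AND M2) OR (M3 AND M4))")
  expect_identical(format(kp_parse_formula("m1 and M2", c("m1", "M2"))),
                   "(m1 AND M2)")
  expect_error(kp_parse_formula("(M1"), "unbalanced parentheses")
  expect_error(kp_parse_formula("M1 )"), "unbalanced|unexpected")
  expect_error(kp_parse_formula("M1 & M2"), "position 4")
  expect_error(kp_parse_formula("M1 AND MX", c("M1", "M2")), "unknown matrix")
  expect_error(kp_parse_formula("M1", c("M1", "M2")), "absent from formula")
})

test_that("formula evaluation applies the AND/OR/XOR truth tables gene-wise", {
  lits <- list(M1 = c(p = TRUE), M2 = c(p = FALSE))
  expect_false(kp_evaluate_formula("M1 AND M2", lits)[["p"]])
  expect_true(kp_evaluate_formula("M1 OR M2", lits)[["p"]])
  expect_true(kp_evaluate_formula("M1 XOR M2", lits)[["p"]])

  lits4 <- list(M1 = c(p = TRUE), M2 = c(p = TRUE),
                M3 = c(p = FALSE), M4 = c(p = FALSE))
  expect_true(kp_evaluate_formula("(M1 AND M2) OR (M3 AND M4)", lits4)[["p"]])

  # left fold of an XOR chain: (T xor T) xor T = T
  lits3 <- list(M1 = c(p = TRUE), M2 = c(p = TRUE))
  expect_true(kp_evaluate_formula("M1 XOR M2 XOR M1", lits3)[["p"]])

  # single-leaf formula is the per-matrix activity itself
  m <- kp_indicator_matrix(rbind(g1 = c(1L, 0L), g2 = c(1L, 1L)), "M1")
  g <- path_graph(c("g1", "g2"))
  expect_identical(kp_activity_profile(g, m, list(M1 = 0L)),
                   kp_matrix_activity(m, 0L, c("g1", "g2")))
})

test_that("raising L never deactivates a gene under AND/OR but can under XOR", {
  g <- path_graph(c("p", "q"))
  m1 <- kp_indicator_matrix(rbind(p = c(1L, 0L), q = c(1L, 1L)), "M1")
  m2 <- kp_indicator_matrix(rbind(p = c(1L, 1L), q = c(0L, 0L)), "M2")
  for (op in c("AND", "OR")) {
    fml <- paste("M1", op, "M2")
    for (l2 in 0:2) {
      act <- sapply(0:2, function(l1) {
        kp_activity_profile(g, list(m1, m2), list(M1 = l1, M2 = l2), fml)
      })
      expect_true(all(act[, 1] <= act[, 2]) && all(act[, 2] <= act[, 3]))
    }
  }
  # XOR: p is (M1 inactive, M2 active) at L1=0 -> TRUE; raising L1 activates
  # the M1 literal and flips the XOR to FALSE
  a0 <- kp_activity_profile(g, list(m1, m2), list(M1 = 0L, M2 = 0L), "M1 XOR M2")
  a1 <- kp_activity_profile(g, list(m1, m2), list(M1 = 1L, M2 = 0L), "M1 XOR M2")
  expect_true(a0[["p"]])
  expect_false(a1[["p"]])
})

test_that("cell-wise combination matches its truth table and the L=0 formula route", {
  m1 <- kp_indicator_matrix(rbind(g = c(1L, 0L)), "M1")
  m2 <- kp_indicator_matrix(rbind(g = c(0L, 0L)), "M2")
  expect_identical(unname(kp_cellwise_combine(m1, m2, "OR")$values["g", ]), c(1L, 0L))

  set.seed(9)
  vals <- matrix(rbinom(40, 1, 0.5), 8, 5, dimnames = list(letters[1:8], NULL))
  m <- kp_indicator_matrix(vals, "M1")
  expect_identical(kp_cellwise_combine(m, m, "AND")$values, m$values)
  expect_true(all(kp_cellwise_combine(m, m, "XOR")$values == 0L))

  m3 <- kp_indicator_matrix(matrix(1L, 1, 3, dimnames = list("g", NULL)), "M3")
  expect_error(kp_cellwise_combine(m1, m3, "OR"), "case lists differ")

  # under L = 0 the AND routes coincide exactly; the OR routes agree only in
  # one direction (a formula-active gene is always cell-wise active, because
  # an all-ones row in either matrix makes the OR-combined row all ones)
  mm2 <- kp_indicator_matrix(matrix(rbinom(40, 1, 0.5), 8, 5,
                                    dimnames = list(letters[1:8], NULL)), "M2")
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(letters[1:8])
  and_formula <- kp_activity_profile(g, list(m, mm2), list(M1 = 0L, M2 = 0L), "M1 AND M2")
  and_cells <- kp_matrix_activity(kp_cellwise_combine(m, mm2, "AND"), 0L, letters[1:8])
  expect_identical(and_formula, and_cells)
  or_formula <- kp_activity_profile(g, list(m, mm2), list(M1 = 0L, M2 = 0L), "M1 OR M2")
  or_cells <- kp_matrix_activity(kp_cellwise_combine(m, mm2, "OR"), 0L, letters[1:8])
  expect_true(all(!or_formula | or_cells))
})
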