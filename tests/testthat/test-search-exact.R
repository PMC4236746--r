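test_that("effective state honours positive and negative lists", {
  profile <- c(a = TRUE, b = FALSE, c = TRUE)
  params <- kp_params(0, positive = "b", negative = "c")
  st <- kp_effective_state(c("a", "b", "c"), profile, params)
  expect_identical(unname(st), c("active", "active", "exception"))
  # unlisted nodes mirror the profile
  st0 <- kp_effective_state(c("a", "b"), profile, kp_params(0))
  expect_identical(unname(st0), c("active", "exception"))
  expect_error(kp_effective_state("zz", profile), "missing from activity profile")
})

test_that("pathway validity requires connectivity and the exception budget", {
  g <- path_graph(c("A", "B", "C"))
  profile <- make_profile(c("A", "B", "C"), c("A", "C"))
  expect_true(kp_is_valid_pathway(c("A", "B", "C"), g, profile, kp_params(1)))
  expect_false(kp_is_valid_pathway(c("A", "B", "C"), g, profile, kp_params(0)))
  expect_false(kp_is_valid_pathway(c("A", "C"), g, profile, kp_params(3)))
  expect_false(kp_is_valid_pathway(character(0), g, profile, kp_params(3)))
})

test_that("exact enumeration reproduces hand-checked path and star instances", {
  g <- path_graph(c("A", "B", "C", "D"))
  profile <- make_profile(c("A", "B", "C", "D"), c("A", "B", "D"))
  r1 <- kp_enumerate_pathways(g, profile, kp_params(1))
  expect_identical(pathway_node_sets(r1), list(c("A", "B", "C", "D")))
  expect_identical(r1[[1]]$exceptions, "C")
  r0 <- kp_enumerate_pathways(g, profile, kp_params(0))
  expect_identical(pathway_node_sets(r0), list(c("A", "B"), "D"))

  s <- star_graph("X", c("a", "b", "c"))
  sprof <- make_profile(c("X", "a", "b", "c"), c("a", "b", "c"))
  expect_identical(pathway_node_sets(kp_enumerate_pathways(s, sprof, kp_params(0))),
                   list("a", "b", "c"))
  expect_identical(pathway_node_sets(kp_enumerate_pathways(s, sprof, kp_params(1))),
                   list(c("X", "a", "b", "c")))
})

test_that("enumeration refuses oversized instances unless forced", {
  g <- kp_generate_network(kp_fixture_spec(n_nodes = 30, n_edges = 40, seed = 2))
  profile <- make_profile(igraph::V(g)$name, igraph::V(g)$name[1:5])
  expect_error(kp_enumerate_pathways(g, profile, kp_params(0)), "max_exact_nodes")
  expect_silent(kp_enumerate_pathways(g, profile, kp_params(0), max_exact_nodes = 30))
})

test_that("every enumerated pathway is valid and single-node maximal", {
  for (seed in 1:15) {
    inst <- random_instance(seed)
    res <- kp_enumerate_pathways(inst$network, inst$profile, inst$params)
    for (p in res) {
      expect_true(kp_is_valid_pathway(p$nodes, inst$network, inst$profile, inst$params))
      nb <- setdiff(unique(unlist(igraph::adjacent_vertices(
        inst$network, p$nodes) |> lapply(function(v) v$name))), p$nodes)
      for (u in nb) {
        expect_false(kp_is_valid_pathway(c(p$nodes, u), inst$network,
                                         inst$profile, inst$params))
      }
    }
  }
})

test_that("single-node maximality coincides with set-inclusion maximality", {
  for (seed in 101:110) {
    inst <- random_instance(seed, n_max = 9L)
    a <- sort(pathway_keys(kp_enumerate_pathways(inst$network, inst$profile, inst$params)))
    b <- sort(pathway_keys(oracle_inclusion_maximal(inst$network, inst$profile, inst$params)))
    expect_identical(a, b)
  }
})

test_that("optimum size is monotone in K and responds to knowledge lists as expected", {
  best_size <- function(res) if (length(res)) res[[1]]$size else 0L
  for (seed in 21:30) {
    inst <- random_instance(seed)
    sizes <- vapply(0:3, function(k) {
      best_size(kp_enumerate_pathways(inst$network, inst$profile,
                                      kp_params(k, inst$params$positive, inst$params$negative)))
    }, 0L)
    expect_true(all(diff(sizes) >= 0))

    vn <- igraph::V(inst$network)$name
    free <- setdiff(vn, c(inst$params$positive, inst$params$negative))
    if (length(free)) {
      pick <- free[1]
      base <- best_size(kp_enumerate_pathways(inst$network, inst$profile,
                                              kp_params(1)))
      plus <- best_size(kp_enumerate_pathways(inst$network, inst$profile,
                                              kp_params(1, positive = pick)))
      minus <- best_size(kp_enumerate_pathways(inst$network, inst$profile,
                                               kp_params(1, negative = pick)))
      expect_gte(plus, base)
      expect_lte(minus, base)
    }
  }
})
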