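# Small graph/profile builders shared across tests.

path_graph <- function(ids) {
  igraph::graph_from_data_frame(
    data.frame(from = ids[-length(ids)], to = ids[-1L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
}

star_graph <- function(center, leaves) {
  igraph::graph_from_data_frame(
    data.frame(from = center, to = leaves, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = c(center, leaves), stringsAsFactors = FALSE))
}

# Named logical profile over `all` nodes, TRUE for those in `active`.
make_profile <- function(all, active) {
  stats::setNames(all %in% active, all)
}

pathway_node_sets <- function(pathways) lapply(pathways, function(p) p$nodes)

# Random connected-ish instance for oracle comparisons: an Erdos-Renyi
# G(n, m) graph (possibly disconnected), a Bernoulli activity profile, a
# small K, and occasionally positive/negative lists.
random_instance <- function(seed, n_max = 12L) {
  set.seed(seed)
  n <- sample(4:n_max, 1L)
  m <- sample(seq(n - 1L, min(n * (n - 1L) / 2L, 2L * n)), 1L)
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  vn <- igraph::V(g)$name
  profile <- stats::setNames(stats::runif(n) < 0.5, vn)
  k <- sample(0:2, 1L)
  positive <- character(0)
  negative <- character(0)
  if (stats::runif(1) < 0.3) positive <- sample(vn, 1L)
  if (stats::runif(1) < 0.3) negative <- sample(setdiff(vn, positive), 1L)
  list(network = g, profile = profile,
       params = kp_params(k, positive, negative))
}

# Canonical string keys of a pathway list, order-sensitive.
pathway_keys <- function(pathways) {
  vapply(pathways, function(p) paste(p$nodes, collapse = "|"), "")
}
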