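#' Synthetic fixture specification
#'
#' Describes a random connected network with a planted active module:
#' a connected set of genes whose indicator-matrix rows are mostly 1
#' (probability `planted_active_prob` per cell) against a mostly-0 background
#' (`background_active_prob`). The defaults mirror a sparse interaction
#' network (mean degree 4) carrying a strong, coherent disease module over a
#' moderately sized patient cohort.
#'
#' @param n_nodes Number of network nodes (default 100).
#' @param n_edges Number of edges (default 200); must be feasible, i.e. at
#'   least `n_nodes - 1` and at most `choose(n_nodes, 2)`.
#' @param n_cases Cases per matrix; a vector gives one matrix per entry
#'   (default one matrix with 50 cases).
#' @param module_size Planted module size (default 15).
#' @param background_active_prob Per-cell activity probability of background
#'   genes (default 0.05).
#' @param planted_active_prob Per-cell activity probability of planted genes
#'   (default 0.9); must exceed the background probability.
#' @param seed RNG seed.
#' @return An object of class `kp_fixture_spec`.
#' @export
kp_fixture_spec <- function(n_nodes = 100L, n_edges = 200L, n_cases = 50L,
                            module_size = min(15L, n_nodes), background_active_prob = 0.05,
                            planted_active_prob = 0.9, seed = 1L) {
  stopifnot(n_nodes >= 1L, module_size >= 1L, module_size <= n_nodes,
            all(n_cases >= 1L), planted_active_prob > background_active_prob,
            background_active_prob >= 0, planted_active_prob <= 1)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < n_nodes - 1L || n_edges > max_edges) {
    stop("infeasible edge count: need ", n_nodes - 1L, " <= n_edges <= ", max_edges,
         call. = FALSE)
  }
  structure(list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 n_cases = as.integer(n_cases), module_size = as.integer(module_size),
                 background_active_prob = background_active_prob,
                 planted_active_prob = planted_active_prob, seed = as.integer(seed)),
            class = "kp_fixture_spec")
}

#' Generate a random connected network
#'
#' Builds a uniform random spanning tree backbone (each new node attaches to
#' a uniformly chosen earlier node of a random permutation) and adds extra
#' distinct random edges up to `n_edges`, so the result is connected by
#' construction and deterministic per seed. Node IDs are zero-padded
#' (`g001`, `g002`, ...) so lexicographic and numeric orders agree.
#'
#' @param spec A [kp_fixture_spec()] (or `n_nodes`/`n_edges`/`seed` via `...`).
#' @param ... Passed to `kp_fixture_spec()` when `spec` is missing.
#' @return An undirected igraph graph.
#' @export
kp_generate_network <- function(spec = kp_fixture_spec(...), ...) {
  n <- spec$n_nodes
  m <- spec$n_edges
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  kp_with_seed(spec$seed, function() {
    if (n == 1L) {
      return(igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids))
    }
    perm <- sample.int(n)
    from <- integer(n - 1L)
    to <- integer(n - 1L)
    for (i in 2:n) {
      from[i - 1L] <- perm[sample.int(i - 1L, 1L)]
      to[i - 1L] <- perm[i]
    }
    a <- pmin(from, to)
    b <- pmax(from, to)
    have <- new.env(parent = emptyenv())
    for (j in seq_along(a)) have[[paste(a[j], b[j])]] <- TRUE
    extra <- m - (n - 1L)
    max_edges <- n * (n - 1) / 2
    if (extra > 0L && m > 0.5 * max_edges) {
      # dense request: enumerate the complement and sample without rejection
      allp <- utils::combn(n, 2L)
      keys <- paste(allp[1L, ], allp[2L, ])
      free <- which(vapply(keys, function(k) is.null(have[[k]]), TRUE))
      pick <- free[sample.int(length(free), extra)]
      a <- c(a, allp[1L, pick])
      b <- c(b, allp[2L, pick])
    } else if (extra > 0L) {
      got <- 0L
      while (got < extra) {
        u <- sample.int(n, 1L)
        v <- sample.int(n, 1L)
        if (u == v) next
        lo <- min(u, v); hi <- max(u, v)
        key <- paste(lo, hi)
        if (!is.null(have[[key]])) next
        have[[key]] <- TRUE
        a <- c(a, lo)
        b <- c(b, hi)
        got <- got + 1L
      }
    }
    igraph::graph_from_data_frame(
      data.frame(from = ids[a], to = ids[b], stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  })
}

#' Plant a connected active module and draw indicator matrices
#'
#' Selects a connected node set of `module_size` nodes by seeded
#' breadth-first growth from a random root (connected by construction — no
#' rejection sampling), then fills one indicator matrix per entry of
#' `n_cases` with independent Bernoulli cells: planted genes are active with
#' `planted_active_prob`, all others with `background_active_prob`.
#'
#' @param network A connected igraph network (e.g. [kp_generate_network()]).
#' @param spec A [kp_fixture_spec()]; matrix layout and probabilities are
#'   taken from it, and its `seed` (offset so the module differs from the
#'   network draw) drives the randomness.
#' @return List with `module` (character vector of planted node IDs) and
#'   `matrices` (list of [kp_indicator_matrix()], named `M1`, `M2`, ...).
#' @export
kp_plant_module <- function(network, spec) {
  vn <- igraph::V(network)$name
  stopifnot(spec$module_size <= length(vn))
  kp_with_seed(spec$seed + 1L, function() {
    adj <- lapply(igraph::as_adj_list(network, mode = "all"), as.integer)
    root <- sample.int(length(vn), 1L)
    picked <- root
    frontier <- setdiff(adj[[root]], picked)
    while (length(picked) < spec$module_size) {
      if (!length(frontier)) stop("network component smaller than module_size", call. = FALSE)
      nxt <- frontier[sample.int(length(frontier), 1L)]
      picked <- c(picked, nxt)
      frontier <- setdiff(unique(c(frontier, adj[[nxt]])), picked)
    }
    module <- sort(vn[picked], method = "radix")
    matrices <- lapply(seq_along(spec$n_cases), function(mi) {
      nc <- spec$n_cases[mi]
      prob <- ifelse(vn %in% module, spec$planted_active_prob,
                     spec$background_active_prob)
      vals <- matrix(stats::rbinom(length(vn) * nc, 1L, rep(prob, times = nc)),
                     nrow = length(vn), ncol = nc,
                     dimnames = list(vn, paste0("case_", seq_len(nc))))
      kp_indicator_matrix(vals, paste0("M", mi))
    })
    list(module = module, matrices = matrices)
  })
}

#' Generate a complete fixture and optionally write it to disk
#'
#' Convenience wrapper producing the network, the planted module and the
#' matrices in one call; with `out_dir` set it also writes the network
#' (SIF), the matrices (TSV) and a ground-truth JSON naming the planted
#' nodes.
#'
#' @param spec A [kp_fixture_spec()].
#' @param out_dir Optional output directory.
#' @return List with `network`, `module`, `matrices` (and `files` when
#'   written).
#' @export
kp_generate_fixture <- function(spec = kp_fixture_spec(), out_dir = NULL) {
  network <- kp_generate_network(spec)
  planted <- kp_plant_module(network, spec)
  res <- list(network = network, module = planted$module, matrices = planted$matrices)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    nf <- file.path(out_dir, "network.sif")
    kp_write_network(network, nf, format = "sif")
    mfs <- vapply(planted$matrices, function(m) {
      f <- file.path(out_dir, paste0(m$name, ".tsv"))
      kp_write_indicator_matrix(m, f)
      f
    }, "")
    tf <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(list(planted_module = as.list(planted$module),
                              seed = spec$seed),
                         tf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$files <- c(nf, mfs, tf)
  }
  res
}
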