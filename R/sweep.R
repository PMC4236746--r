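#' Parameter grid for a (K, L) sweep
#'
#' Grid cells are the Cartesian product of the node-exception values and the
#' per-matrix case-exception lists.
#'
#' @param k_values Ordered vector of non-negative integers.
#' @param l_specs Named list: matrix name -> list of [kp_l()] specifications
#'   (or values coercible by `kp_l()`).
#' @return An object of class `kp_sweep_grid`.
#' @export
kp_sweep_grid <- function(k_values, l_specs) {
  k_values <- as.integer(k_values)
  stopifnot(length(k_values) >= 1L, all(k_values >= 0L),
            is.list(l_specs), length(l_specs) >= 1L, !is.null(names(l_specs)))
  l_specs <- lapply(l_specs, function(ls) {
    if (inherits(ls, "kp_l") || !is.list(ls)) ls <- as.list(ls)
    stopifnot(length(ls) >= 1L)
    lapply(ls, kp_l)
  })
  structure(list(k_values = k_values, l_specs = l_specs), class = "kp_sweep_grid")
}

# Derive an independent, reproducible seed for one grid cell.
kp_cell_seed <- function(base_seed, cell_index) {
  as.integer((as.numeric(base_seed) * 1103515245 + as.numeric(cell_index) * 12345 + 7) %%
               2147483647)
}

#' Sweep the (K, L) parameter space and score node appearances
#'
#' For each grid cell the activity profile is recomputed (L changes
#' activity) and the chosen solver is run; cells are independent — heuristic
#' cells derive their own seeds from `seed` and the cell index, so no state
#' leaks between cells. Per-node appearance scores aggregated over all cells
#' (see [kp_node_scores()]) drive color-intensity visualization: the darker
#' a node, the more / the larger the key pathways containing it.
#'
#' @inheritParams kp_activity_profile
#' @param grid A [kp_sweep_grid()].
#' @param algorithm `"exact"`, `"greedy"` or `"aco"`.
#' @param params A [kp_params()]; its `k` is overridden per cell.
#' @param seed Base seed for heuristic cells.
#' @param top_n Pathways kept per cell (heuristic solvers).
#' @param aco ACO settings ([kp_aco_config()]); its seed is overridden per
#'   cell.
#' @param max_exact_nodes Size cap for the exact solver.
#' @return An object of class `kp_sweep`: `cells` (named list of cell
#'   results, each with `k`, resolved `l`, and `pathways`) and `node_scores`
#'   (named numeric in `[0, 1]` over the network's nodes).
#' @export
kp_run_sweep <- function(network, matrices, formula = NULL, grid,
                         algorithm = c("exact", "greedy", "aco"),
                         params = kp_params(), seed = 42L, top_n = 20L,
                         aco = kp_aco_config(), max_exact_nodes = 25L) {
  algorithm <- match.arg(algorithm)
  if (inherits(matrices, "kp_matrix")) matrices <- list(matrices)
  names(matrices) <- vapply(matrices, function(m) m$name, "")
  mat_names <- names(grid$l_specs)
  if (!setequal(mat_names, names(matrices))) {
    stop("sweep grid matrices (", paste(mat_names, collapse = ", "),
         ") do not match supplied matrices (", paste(names(matrices), collapse = ", "), ")",
         call. = FALSE)
  }
  combo <- expand.grid(c(list(k = seq_along(grid$k_values)),
                         lapply(grid$l_specs, seq_along)),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- vector("list", nrow(combo))
  labels <- character(nrow(combo))
  for (ci in seq_len(nrow(combo))) {
    k <- grid$k_values[combo$k[ci]]
    l <- lapply(mat_names, function(nm) grid$l_specs[[nm]][[combo[[nm]][ci]]])
    names(l) <- mat_names
    l_resolved <- vapply(mat_names, function(nm) {
      kp_resolve_l(l[[nm]], kp_n_cases(matrices[[nm]]))
    }, 0L)
    label <- paste0("K=", k, ",", paste0(mat_names, "=", l_resolved, collapse = ","))
    cell_params <- kp_params(k, params$positive, params$negative)
    profile <- kp_activity_profile(network, matrices, l, formula)
    pathways <- tryCatch(
      switch(algorithm,
        exact = kp_enumerate_pathways(network, profile, cell_params,
                                      max_exact_nodes = max_exact_nodes),
        greedy = kp_greedy_search(network, profile, cell_params, top_n = top_n),
        aco = {
          cfg <- aco
          cfg$seed <- kp_cell_seed(seed, ci)
          kp_aco_search(network, profile, cell_params, config = cfg, top_n = top_n)
        }),
      error = function(e) stop("sweep cell ", label, ": ", conditionMessage(e), call. = FALSE))
    attr(pathways, "best_size_history") <- NULL
    cells[[ci]] <- list(k = k, l = l_resolved, pathways = pathways)
    labels[ci] <- label
  }
  names(cells) <- labels
  structure(list(cells = cells,
                 node_scores = kp_node_scores(cells, igraph::V(network)$name)),
            class = "kp_sweep")
}

#' Aggregate per-node appearance scores over sweep cells
#'
#' A node's raw score is the sum, over every pathway in every cell that
#' contains it, of that pathway's size — so the score grows with both the
#' number and the size of containing pathways. Scores are normalized by the
#' maximum raw score, so the top node scores exactly 1 whenever any pathway
#' exists; nodes in no pathway score 0.
#'
#' @param cells Named list of cell results (each with a `pathways` list), as
#'   in [kp_run_sweep()]'s output, or a bare list of pathway lists.
#' @param nodes Optional character vector fixing the score universe.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
kp_node_scores <- function(cells, nodes = NULL) {
  raw <- new.env(parent = emptyenv())
  for (cell in cells) {
    pws <- if (!is.null(cell$pathways)) cell$pathways else cell
    for (p in pws) {
      for (v in p$nodes) {
        raw[[v]] <- (if (is.null(raw[[v]])) 0 else raw[[v]]) + p$size
      }
    }
  }
  ids <- ls(raw)
  vals <- vapply(ids, function(v) raw[[v]], 0)
  if (is.null(nodes)) nodes <- ids
  scores <- stats::setNames(numeric(length(nodes)), nodes)
  hit <- intersect(ids, nodes)
  scores[hit] <- vals[hit]
  m <- if (length(vals)) max(vals) else 0
  if (m > 0) scores <- scores / m
  scores
}

#' Write sweep results: per-cell JSON plus node-score tables
#'
#' Emits one JSON solution file and one node-score TSV per cell, plus the
#' global aggregate `node_scores.tsv` over all cells.
#'
#' @param sweep A [kp_run_sweep()] result.
#' @param network The network the sweep ran on.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
kp_write_sweep <- function(sweep, network, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  nodes <- igraph::V(network)$name
  files <- character(0)
  for (label in names(sweep$cells)) {
    cell <- sweep$cells[[label]]
    slug <- gsub("[^A-Za-z0-9=_-]", "_", label)
    jf <- file.path(out_dir, paste0("cell_", slug, ".json"))
    jsonlite::write_json(
      list(k = cell$k, l = as.list(cell$l),
           pathways = lapply(cell$pathways, function(p) {
             list(size = p$size, nodes = as.list(p$nodes),
                  exceptions = as.list(p$exceptions))
           })),
      jf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    sf <- file.path(out_dir, paste0("cell_", slug, "_scores.tsv"))
    kp_write_node_scores(kp_node_scores(list(cell), nodes), sf)
    files <- c(files, jf, sf)
  }
  gf <- file.path(out_dir, "node_scores.tsv")
  kp_write_node_scores(sweep$node_scores, gf)
  invisible(c(files, gf))
}
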