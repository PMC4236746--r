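# End-to-end runner and input validator behind the command-line front-end
# (inst/cli/keypathways.R). A run config is a plain named list, loadable
# from YAML; results go to files, log lines to stderr via message().

#' Load a run configuration from a YAML file
#'
#' The YAML schema mirrors the [kp_run()] config: `network`,
#' `network_format`, `matrices` (list of `{name, path, l, header}`),
#' `formula`, `k`, `positive`, `negative`, `algorithm`, `top_n`, `seed`,
#' `out_dir`, `aco` (ACO settings), `max_exact_nodes`.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
kp_read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

kp_config_default <- function(config, field, default) {
  if (is.null(config[[field]])) default else config[[field]]
}

# Read every input named by a config; shared by kp_run and kp_validate.
kp_load_inputs <- function(config) {
  if (is.null(config$network)) stop("config: 'network' path is required", call. = FALSE)
  network <- kp_read_network(config$network,
                             kp_config_default(config, "network_format", "auto"))
  if (is.null(config$matrices) || !length(config$matrices)) {
    stop("config: at least one matrix is required", call. = FALSE)
  }
  matrices <- lapply(config$matrices, function(ms) {
    if (is.null(ms$name) || is.null(ms$path)) {
      stop("config: each matrix needs 'name' and 'path'", call. = FALSE)
    }
    kp_read_indicator_matrix(ms$path, ms$name,
                             header = isTRUE(ms$header),
                             missing_token = ms$missing_token)
  })
  names(matrices) <- vapply(matrices, function(m) m$name, "")
  if (anyDuplicated(names(matrices))) stop("config: duplicate matrix names", call. = FALSE)
  l <- lapply(config$matrices, function(ms) {
    if (is.null(ms$l)) stop("config: matrix '", ms$name, "' needs an 'l' threshold", call. = FALSE)
    kp_l(ms$l)
  })
  names(l) <- names(matrices)
  positive <- if (!is.null(config$positive)) kp_read_node_list(config$positive) else character(0)
  negative <- if (!is.null(config$negative)) kp_read_node_list(config$negative) else character(0)
  params <- kp_params(kp_config_default(config, "k", 0L), positive, negative)
  list(network = network, matrices = matrices, l = l,
       formula = config$formula, params = params)
}

kp_aco_from_config <- function(config, seed) {
  aco <- kp_config_default(config, "aco", list())
  do.call(kp_aco_config, c(aco[setdiff(names(aco), "seed")], list(seed = seed)))
}

#' Run one key-pathway extraction from a configuration
#'
#' Reads all inputs, logs an input summary (node/edge counts, per-matrix case
#' counts, resolved L values, the fraction of network nodes active under the
#' formula), runs the chosen solver, and writes the pathways (GraphML + JSON
#' summary, see [kp_write_pathways()]) to `out_dir`. Finding zero pathways is
#' a successful run, reported in the summary.
#'
#' @param config Named list (see [kp_read_config()] for the schema).
#' @return Invisibly, a list with `pathways`, `profile`, `resolved_l`,
#'   `files`.
#' @export
kp_run <- function(config) {
  inputs <- kp_load_inputs(config)
  network <- inputs$network
  matrices <- inputs$matrices
  message("network: ", igraph::vcount(network), " nodes, ",
          igraph::ecount(network), " edges")
  resolved_l <- vapply(names(matrices), function(nm) {
    L <- kp_resolve_l(inputs$l[[nm]], kp_n_cases(matrices[[nm]]))
    message("matrix ", nm, ": ", nrow(matrices[[nm]]$values), " genes, ",
            kp_n_cases(matrices[[nm]]), " cases, resolved L=", L)
    L
  }, 0L)
  profile <- kp_activity_profile(network, matrices, inputs$l, inputs$formula)
  message(sprintf("active nodes under formula: %d/%d (%.1f%%)",
                  sum(profile), length(profile), 100 * mean(profile)))
  algorithm <- kp_config_default(config, "algorithm", "greedy")
  top_n <- kp_config_default(config, "top_n", 20L)
  seed <- kp_config_default(config, "seed", 42L)
  pathways <- switch(algorithm,
    exact = kp_enumerate_pathways(network, profile, inputs$params,
                                  max_exact_nodes = kp_config_default(config, "max_exact_nodes", 25L)),
    greedy = kp_greedy_search(network, profile, inputs$params, top_n = top_n),
    aco = kp_aco_search(network, profile, inputs$params,
                        config = kp_aco_from_config(config, seed), top_n = top_n),
    stop("unknown algorithm: ", algorithm, call. = FALSE))
  attr(pathways, "best_size_history") <- NULL
  message("found ", length(pathways), " pathway(s)",
          if (length(pathways)) paste0("; largest has ", pathways[[1L]]$size, " nodes"))
  files <- NULL
  if (!is.null(config$out_dir)) {
    files <- kp_write_pathways(pathways, network, config$out_dir)
  }
  invisible(list(pathways = pathways, profile = profile,
                 resolved_l = resolved_l, files = files))
}

#' Run a (K, L) parameter sweep from a configuration
#'
#' Like [kp_run()] but over a grid given in `config$sweep`:
#' `k_values` (vector) and `l_values` (named list: matrix name -> vector of
#' thresholds). Writes per-cell JSON + score tables and the aggregate
#' node-score TSV via [kp_write_sweep()].
#'
#' @param config Named list.
#' @return Invisibly, the [kp_run_sweep()] result.
#' @export
kp_run_sweep_config <- function(config) {
  inputs <- kp_load_inputs(config)
  sw <- config$sweep
  if (is.null(sw$k_values) || is.null(sw$l_values)) {
    stop("config: sweep needs 'k_values' and 'l_values'", call. = FALSE)
  }
  grid <- kp_sweep_grid(sw$k_values, sw$l_values)
  seed <- kp_config_default(config, "seed", 42L)
  sweep <- kp_run_sweep(inputs$network, inputs$matrices, inputs$formula, grid,
                        algorithm = kp_config_default(config, "algorithm", "greedy"),
                        params = inputs$params, seed = seed,
                        top_n = kp_config_default(config, "top_n", 20L),
                        aco = kp_aco_from_config(config, seed),
                        max_exact_nodes = kp_config_default(config, "max_exact_nodes", 25L))
  message("sweep: ", length(sweep$cells), " cells")
  if (!is.null(config$out_dir)) kp_write_sweep(sweep, inputs$network, config$out_dir)
  invisible(sweep)
}

#' Validate inputs and report ID-overlap statistics
#'
#' Side-effect free: reads the configured inputs and reports, per matrix, how
#' many network nodes it covers, the resolved L value, overlaps between the
#' positive/negative lists and the network, and any structural problems —
#' without modifying any file.
#'
#' @param config Named list (see [kp_read_config()]).
#' @return A list with `lines` (report text) and `n_problems`, invisibly;
#'   the report is also printed with `message()`.
#' @export
kp_validate <- function(config) {
  lines <- character(0)
  problems <- 0L
  note <- function(txt) lines <<- c(lines, txt)
  inputs <- tryCatch(kp_load_inputs(config), error = function(e) e)
  if (inherits(inputs, "error")) {
    note(paste0("ERROR: ", conditionMessage(inputs)))
    problems <- problems + 1L
    report <- list(lines = lines, n_problems = problems)
    for (ln in lines) message(ln)
    return(invisible(report))
  }
  vn <- igraph::V(inputs$network)$name
  note(paste0("network: ", length(vn), " nodes, ", igraph::ecount(inputs$network), " edges"))
  for (nm in names(inputs$matrices)) {
    m <- inputs$matrices[[nm]]
    covered <- sum(vn %in% rownames(m$values))
    absent <- length(vn) - covered
    L <- kp_resolve_l(inputs$l[[nm]], kp_n_cases(m))
    note(paste0("matrix ", nm, ": ", kp_n_cases(m), " cases, resolved L=", L, "; ",
                covered, " network nodes covered, ", absent, " absent"))
    if (covered == 0L) {
      note(paste0("PROBLEM: matrix ", nm, " covers no network node"))
      problems <- problems + 1L
    }
  }
  for (kind in c("positive", "negative")) {
    ids <- inputs$params[[kind]]
    if (length(ids)) {
      unknown <- setdiff(ids, vn)
      note(paste0(kind, " list: ", length(ids), " IDs, ", length(unknown),
                  " not in network"))
      if (length(unknown)) {
        note(paste0("WARNING: ", kind, " list IDs ignored (absent from network): ",
                    paste(utils::head(unknown, 5L), collapse = ", ")))
      }
    }
  }
  if (!is.null(inputs$formula)) {
    ok <- tryCatch({
      kp_parse_formula(inputs$formula, names(inputs$matrices))
      TRUE
    }, error = function(e) {
      note(paste0("PROBLEM: ", conditionMessage(e)))
      FALSE
    })
    if (!ok) problems <- problems + 1L
  }
  note(paste0(problems, " problems"))
  for (ln in lines) message(ln)
  invisible(list(lines = lines, n_problems = problems))
}
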