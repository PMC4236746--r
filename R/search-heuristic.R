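# Heuristic solvers: multi-start greedy expansion and ant colony
# optimization. Both grow connected sets one frontier node at a time under
# the exception budget, so every emitted pathway is valid and single-node
# maximal by construction.

# Deterministic greedy growth from a start index. Frontier preference:
# active-state over exception-state, then more active-state neighbours
# outside the set, then lexicographically smaller node ID.
kp_greedy_expand_idx <- function(inst, start) {
  adj <- inst$adj
  exc <- inst$exc
  in_set <- logical(inst$n)
  in_set[start] <- TRUE
  in_frontier <- logical(inst$n)
  in_frontier[adj[[start]]] <- TRUE
  exc_used <- as.integer(exc[start])
  repeat {
    cand <- which(in_frontier)
    if (exc_used >= inst$k) cand <- cand[!exc[cand]]
    if (!length(cand)) break
    act <- !exc[cand]
    pool <- if (any(act)) cand[act] else cand
    gain <- vapply(pool, function(u) {
      nb <- adj[[u]]
      sum(!exc[nb] & !in_set[nb])
    }, 0L)
    pool <- pool[gain == max(gain)]
    u <- if (length(pool) > 1L) pool[order(inst$names[pool], method = "radix")[1L]] else pool[1L]
    in_set[u] <- TRUE
    in_frontier[u] <- FALSE
    exc_used <- exc_used + as.integer(exc[u])
    nb <- adj[[u]]
    in_frontier[nb[!in_set[nb]]] <- TRUE
  }
  which(in_set)
}

#' Grow a key pathway greedily from a start node
#'
#' Deterministic baseline heuristic: starting from an active-state node, the
#' set is grown by repeatedly adding the best frontier node — active-state
#' nodes are preferred over exception-state ones, then nodes with more
#' active-state neighbours outside the set, then the lexicographically
#' smallest ID — until no addition keeps the exception count within `k`. The
#' result is a valid, single-node-maximal pathway.
#'
#' @param start Node ID to grow from; must have effective state active (or be
#'   on the positive list).
#' @inheritParams kp_is_valid_pathway
#' @return A [kp_pathway] object.
#' @export
kp_greedy_expand <- function(start, network, profile, params = kp_params()) {
  inst <- kp_instance(network, profile, params)
  i0 <- match(start, inst$names)
  if (is.na(i0)) stop("start node not in network: ", start, call. = FALSE)
  if (inst$exc[i0]) {
    stop("start node '", start, "' has effective state exception; ",
         "greedy expansion starts from active-state nodes", call. = FALSE)
  }
  kp_pathway_from_idx(inst, kp_greedy_expand_idx(inst, i0))
}

#' Multi-start greedy key-pathway search
#'
#' Runs [kp_greedy_expand()] from every active-state node, deduplicates
#' identical node sets, and returns the `top_n` largest pathways (ties broken
#' lexicographically by sorted node IDs). Deterministic.
#'
#' @inheritParams kp_is_valid_pathway
#' @param top_n Maximum number of pathways to return.
#' @return List of [kp_pathway] objects.
#' @export
kp_greedy_search <- function(network, profile, params = kp_params(), top_n = 20L) {
  inst <- kp_instance(network, profile, params)
  starts <- which(!inst$exc)
  seen <- new.env(parent = emptyenv())
  res <- list()
  for (s in starts) {
    idx <- kp_greedy_expand_idx(inst, s)
    p <- kp_pathway_from_idx(inst, idx)
    key <- kp_pathway_key(p)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      res[[length(res) + 1L]] <- p
    }
  }
  utils::head(kp_sort_pathways(res), top_n)
}

#' Ant-colony-optimization configuration
#'
#' Vertex pheromones start at `tau_max`; each iteration every ant builds one
#' pathway, then pheromones evaporate (`tau <- (1 - rho) * tau`) and the
#' iteration-best solution deposits `|S_best| / |V|` on its member nodes,
#' clamped to `[tau_min, tau_max]`. Ants pick a start among active-state
#' nodes with probability proportional to `tau^alpha` and grow the set by
#' choosing frontier node `u` with probability proportional to
#' `tau_u^alpha * eta_u^beta`, where `eta_u` is 1 for active-state nodes and
#' `epsilon_inactive` for exception-state nodes, subject to the budget.
#'
#' @param n_ants Ants per iteration (default 20).
#' @param n_iterations Iterations (default 100).
#' @param alpha Pheromone exponent (default 1).
#' @param beta Desirability exponent (default 2).
#' @param rho Evaporation rate in (0, 1) (default 0.1).
#' @param tau_min,tau_max Pheromone bounds (defaults 0.01 and 1).
#' @param epsilon_inactive Desirability of exception-state nodes in (0, 1)
#'   (default 0.1).
#' @param seed RNG seed; one stream drives start selection and growth.
#' @return An object of class `kp_aco_config`.
#' @export
kp_aco_config <- function(n_ants = 20L, n_iterations = 100L, alpha = 1,
                          beta = 2, rho = 0.1, tau_min = 0.01, tau_max = 1,
                          epsilon_inactive = 0.1, seed = 42L) {
  stopifnot(n_ants >= 1L, n_iterations >= 1L, rho > 0, rho < 1,
            tau_min > 0, tau_min <= tau_max,
            epsilon_inactive > 0, epsilon_inactive < 1)
  structure(list(n_ants = as.integer(n_ants),
                 n_iterations = as.integer(n_iterations),
                 alpha = alpha, beta = beta, rho = rho,
                 tau_min = tau_min, tau_max = tau_max,
                 epsilon_inactive = epsilon_inactive,
                 seed = as.integer(seed)),
            class = "kp_aco_config")
}

# Run body with a private RNG stream, restoring the caller's stream after.
kp_with_seed <- function(seed, body) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  body()
}

# One probabilistic ant walk; returns member indices of a maximal valid set.
kp_ant_walk <- function(inst, start, tau_a, eta_b) {
  adj <- inst$adj
  exc <- inst$exc
  in_set <- logical(inst$n)
  in_set[start] <- TRUE
  in_frontier <- logical(inst$n)
  in_frontier[adj[[start]]] <- TRUE
  exc_used <- as.integer(exc[start])
  repeat {
    cand <- which(in_frontier)
    if (exc_used >= inst$k) cand <- cand[!exc[cand]]
    if (!length(cand)) break
    w <- tau_a[cand] * eta_b[cand]
    u <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L, prob = w)]
    in_set[u] <- TRUE
    in_frontier[u] <- FALSE
    exc_used <- exc_used + as.integer(exc[u])
    nb <- adj[[u]]
    in_frontier[nb[!in_set[nb]]] <- TRUE
  }
  which(in_set)
}

#' Ant-colony-optimization key-pathway search
#'
#' Population heuristic for instances too large for exact enumeration.
#' Reproducible: a fixed seed yields identical output. The best solution
#' found so far never shrinks across iterations (elitist bookkeeping); the
#' per-iteration best sizes are attached as attribute `best_size_history`.
#'
#' @inheritParams kp_greedy_search
#' @param config A [kp_aco_config()].
#' @return List of the `top_n` distinct best [kp_pathway] objects found
#'   across all iterations, sorted by descending size.
#' @export
kp_aco_search <- function(network, profile, params = kp_params(),
                          config = kp_aco_config(), top_n = 20L) {
  inst <- kp_instance(network, profile, params)
  active_idx <- which(!inst$exc)
  if (!length(active_idx)) return(list())
  n <- inst$n
  eta_b <- ifelse(inst$exc, config$epsilon_inactive, 1)^config$beta
  tau <- rep(config$tau_max, n)
  sols <- new.env(parent = emptyenv())
  history <- integer(config$n_iterations)
  best_so_far <- 0L
  kp_with_seed(config$seed, function() {
    for (iter in seq_len(config$n_iterations)) {
      tau_a <- tau^config$alpha
      iter_best <- NULL
      iter_best_key <- ""
      for (ant in seq_len(config$n_ants)) {
        ws <- tau_a[active_idx]
        start <- if (length(active_idx) == 1L) active_idx else {
          active_idx[sample.int(length(active_idx), 1L, prob = ws)]
        }
        idx <- kp_ant_walk(inst, start, tau_a, eta_b)
        key <- paste(idx, collapse = ",")
        if (is.null(sols[[key]])) sols[[key]] <- idx
        if (is.null(iter_best) || length(idx) > length(iter_best) ||
            (length(idx) == length(iter_best) && key < iter_best_key)) {
          iter_best <- idx
          iter_best_key <- key
        }
      }
      tau <<- tau * (1 - config$rho)
      tau[iter_best] <<- tau[iter_best] + length(iter_best) / n
      tau <<- pmin(config$tau_max, pmax(config$tau_min, tau))
      best_so_far <<- max(best_so_far, length(iter_best))
      history[iter] <<- best_so_far
    }
  })
  res <- lapply(sort(ls(sols, sorted = FALSE), method = "radix"),
                function(key) kp_pathway_from_idx(inst, sols[[key]]))
  res <- utils::head(kp_sort_pathways(res), top_n)
  attr(res, "best_size_history") <- history
  res
}
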