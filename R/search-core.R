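#' Search parameters: node-exception budget and prior-knowledge lists
#'
#' `k` is the number of exception nodes a key pathway may contain (the INES
#' strategy: each exception node counts once against the budget, regardless
#' of how many cases it fails in). The positive list forces nodes to behave
#' as non-exception nodes — they bypass the activity constraints and never
#' consume budget — while the negative list forces nodes to always count as
#' exceptions. Negative-list nodes are not forbidden: they may still enter a
#' pathway, but only by consuming budget.
#'
#' @param k Non-negative integer node-exception budget.
#' @param positive,negative Character vectors of node IDs; must be disjoint.
#' @return An object of class `kp_params`.
#' @export
kp_params <- function(k = 0L, positive = character(0), negative = character(0)) {
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("k must be a non-negative integer", call. = FALSE)
  overlap <- intersect(positive, negative)
  if (length(overlap)) {
    stop("positive and negative lists overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  structure(list(k = k, positive = unique(positive), negative = unique(negative)),
            class = "kp_params")
}

#' Effective state of nodes under prior-knowledge lists
#'
#' Positive-list nodes are always `"active"` (they bypass the activity
#' constraints); negative-list nodes are always `"exception"`; all other
#' nodes mirror the activity profile.
#'
#' @param nodes Character vector of node IDs.
#' @param profile Named logical activity vector (see [kp_activity_profile()]).
#' @param params A [kp_params()] object.
#' @return Character vector of `"active"` / `"exception"` states.
#' @export
kp_effective_state <- function(nodes, profile, params = kp_params()) {
  if (anyNA(match(nodes, names(profile)))) {
    stop("node(s) missing from activity profile: ",
         paste(setdiff(nodes, names(profile)), collapse = ", "), call. = FALSE)
  }
  state <- ifelse(profile[nodes], "active", "exception")
  state[nodes %in% params$positive] <- "active"
  state[nodes %in% params$negative] <- "exception"
  stats::setNames(state, nodes)
}

# Compiled search instance: integer adjacency lists plus per-node exception
# flags, shared by the exact and heuristic solvers.
kp_instance <- function(network, profile, params) {
  vn <- igraph::V(network)$name
  state <- kp_effective_state(vn, profile, params)
  adj <- lapply(igraph::as_adj_list(network, mode = "all"), as.integer)
  list(names = vn, adj = adj, exc = unname(state == "exception"), n = length(vn),
       k = params$k)
}

# Connectivity of a set of vertex indices via BFS on the instance adjacency.
kp_idx_connected <- function(inst, idx) {
  if (length(idx) <= 1L) return(length(idx) == 1L)
  in_set <- logical(inst$n)
  in_set[idx] <- TRUE
  seen <- logical(inst$n)
  queue <- idx[1L]
  seen[queue] <- TRUE
  found <- 1L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- inst$adj[[v]]
    nb <- nb[in_set[nb] & !seen[nb]]
    if (length(nb)) {
      seen[nb] <- TRUE
      found <- found + length(nb)
      queue <- c(queue, nb)
    }
  }
  found == length(idx)
}

#' A key pathway: a connected node set with its exception nodes
#'
#' @param nodes Character vector of member node IDs.
#' @param exceptions Subset of `nodes` in effective state exception.
#' @return An object of class `kp_pathway` with sorted `nodes`, sorted
#'   `exceptions` and `size`.
#' @export
kp_pathway <- function(nodes, exceptions = character(0)) {
  stopifnot(all(exceptions %in% nodes))
  structure(list(nodes = sort(nodes, method = "radix"),
                 exceptions = sort(exceptions, method = "radix"),
                 size = length(nodes)),
            class = "kp_pathway")
}

#' @export
print.kp_pathway <- function(x, ...) {
  cat("<key pathway: ", x$size, " nodes, ", length(x$exceptions),
      " exception(s)>\n", sep = "")
  invisible(x)
}

kp_pathway_key <- function(p) paste(p$nodes, collapse = "|")

# Sort pathways by descending size, ties lexicographically by sorted node IDs.
kp_sort_pathways <- function(pathways) {
  if (!length(pathways)) return(pathways)
  sizes <- vapply(pathways, function(p) p$size, 0L)
  keys <- vapply(pathways, kp_pathway_key, "")
  pathways[order(-sizes, keys, method = "radix")]
}

kp_pathway_from_idx <- function(inst, idx) {
  kp_pathway(inst$names[idx], inst$names[idx[inst$exc[idx]]])
}

#' Is a node set a valid key pathway?
#'
#' Valid means: non-empty, the induced subgraph is connected, and the number
#' of effective-exception nodes in the set is at most `k`.
#'
#' @param nodes Character vector of node IDs (subset of the network's nodes).
#' @inheritParams kp_effective_state
#' @param network Undirected igraph graph with named vertices.
#' @return `TRUE` or `FALSE`.
#' @export
kp_is_valid_pathway <- function(nodes, network, profile, params = kp_params()) {
  if (!length(nodes)) return(FALSE)
  vn <- igraph::V(network)$name
  if (!all(nodes %in% vn)) stop("node(s) not in network", call. = FALSE)
  state <- kp_effective_state(nodes, profile, params)
  if (sum(state == "exception") > params$k) return(FALSE)
  igraph::is_connected(igraph::induced_subgraph(network, nodes))
}

#' Enumerate all maximal key pathways (exact solver)
#'
#' Enumerates every connected induced subgraph whose exception count stays
#' within the budget `k` (branches exceeding the budget are pruned eagerly:
#' every superset of an over-budget set is also over budget) and reports the
#' maximal ones — sets to which no further node can be added while keeping
#' connectivity and the budget. Each set is visited exactly once via
#' anchor-based enumeration with exclusive extension sets. Pathways must
#' contain at least one active-state node; all-exception sets carry no signal
#' and are never reported.
#'
#' Exhaustive enumeration is exponential in the worst case and is intended
#' for small instances and as a correctness oracle for the heuristics; above
#' `max_exact_nodes` nodes an error advises the heuristic solvers unless
#' `force = TRUE`.
#'
#' @inheritParams kp_is_valid_pathway
#' @param max_exact_nodes Refuse larger networks unless forced (default 25).
#' @param force Override the size cap.
#' @return List of [kp_pathway] objects, sorted by descending size with ties
#'   broken lexicographically by sorted node IDs.
#' @export
kp_enumerate_pathways <- function(network, profile, params = kp_params(),
                                  max_exact_nodes = 25L, force = FALSE) {
  n <- igraph::vcount(network)
  if (n > max_exact_nodes && !force) {
    stop("network has ", n, " nodes (> max_exact_nodes = ", max_exact_nodes,
         "); use the greedy or ACO solver, or set force = TRUE", call. = FALSE)
  }
  inst <- kp_instance(network, profile, params)
  K <- inst$k
  exc <- inst$exc
  adj <- inst$adj
  out <- new.env(parent = emptyenv())
  out$res <- list()

  record_if_maximal <- function(members, exc_used) {
    idx <- which(members)
    if (all(exc[idx])) return(invisible())        # needs >= 1 active node
    # frontier = neighbours of the set outside the set
    fr <- unique(unlist(adj[idx], use.names = FALSE))
    fr <- fr[!members[fr]]
    if (length(fr)) {
      if (any(!exc[fr])) return(invisible())      # an active node could join
      if (exc_used < K) return(invisible())       # budget left for an exception
    }
    out$res[[length(out$res) + 1L]] <- kp_pathway_from_idx(inst, idx)
    invisible()
  }

  # Anchor-based enumeration: for anchor v, enumerate every connected set
  # whose minimum index is v. `ext` holds extendable candidates; `banned`
  # marks vertices already owned by an earlier extension branch (exclusive
  # neighbours), guaranteeing each set is generated once.
  extend <- function(members, exc_used, ext, seen, anchor) {
    record_if_maximal(members, exc_used)
    while (length(ext)) {
      u <- ext[[1L]]
      ext <- ext[-1L]
      cost <- exc_used + as.integer(exc[u])
      if (cost > K) next
      nb <- adj[[u]]
      nb <- nb[nb > anchor & !seen[nb]]
      seen2 <- seen
      if (length(nb)) seen2[nb] <- TRUE
      members2 <- members
      members2[u] <- TRUE
      extend(members2, cost, c(ext, nb), seen2, anchor)
    }
  }

  for (v in seq_len(n)) {
    if (exc[v] && K == 0L) next
    members <- logical(n)
    members[v] <- TRUE
    nb <- adj[[v]]
    nb <- nb[nb > v]
    seen <- logical(n)
    seen[v] <- TRUE
    if (length(nb)) seen[nb] <- TRUE
    extend(members, as.integer(exc[v]), nb, seen, v)
  }
  kp_sort_pathways(out$res)
}
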