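# Exhaustive oracle: iterate ALL vertex subsets as bitmasks, keep the valid
# ones (connected induced subgraph, exception count within budget, at least
# one active-state node), and report those with no valid single-node
# extension. Independent of the package's anchor-based enumerator.

oracle_maximal_pathways <- function(network, profile, params) {
  vn <- igraph::V(network)$name
  n <- length(vn)
  stopifnot(n <= 14L)
  full <- bitwShiftL(1L, n) - 1L
  bit <- bitwShiftL(1L, seq_len(n) - 1L)

  amask <- integer(n)
  el <- igraph::as_edgelist(network, names = FALSE)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      i <- el[r, 1L]
      j <- el[r, 2L]
      amask[i] <- bitwOr(amask[i], bit[j])
      amask[j] <- bitwOr(amask[j], bit[i])
    }
  }
  state <- kp_effective_state(vn, profile, params)
  excmask <- 0L
  for (i in which(state == "exception")) excmask <- bitwOr(excmask, bit[i])
  actmask <- bitwXor(full, excmask)

  popcount <- integer(full + 1L)
  for (m in seq_len(full)) {
    popcount[m + 1L] <- popcount[bitwShiftR(m, 1L) + 1L] + bitwAnd(m, 1L)
  }

  is_connected_mask <- function(m) {
    first <- which(bitwAnd(m, bit) != 0L)[1L]
    reach <- bit[first]
    repeat {
      members <- which(bitwAnd(reach, bit) != 0L)
      grown <- reach
      for (i in members) grown <- bitwOr(grown, amask[i])
      grown <- bitwAnd(grown, m)
      if (grown == reach) break
      reach <- grown
    }
    reach == m
  }

  valid <- logical(full + 1L)
  for (m in seq_len(full)) {
    if (popcount[bitwAnd(m, excmask) + 1L] > params$k) next
    if (is_connected_mask(m)) valid[m + 1L] <- TRUE
  }

  res <- list()
  for (m in seq_len(full)) {
    if (!valid[m + 1L]) next
    if (bitwAnd(m, actmask) == 0L) next
    extendable <- FALSE
    for (j in seq_len(n)) {
      if (bitwAnd(m, bit[j]) == 0L && valid[bitwOr(m, bit[j]) + 1L]) {
        extendable <- TRUE
        break
      }
    }
    if (extendable) next
    members <- which(bitwAnd(m, bit) != 0L)
    res[[length(res) + 1L]] <- kp_pathway(vn[members],
                                          vn[members[state[members] == "exception"]])
  }
  res
}

# Size of the best valid pathway according to the oracle (0 when none).
oracle_optimum_size <- function(network, profile, params) {
  res <- oracle_maximal_pathways(network, profile, params)
  if (!length(res)) 0L else max(vapply(res, function(p) p$size, 0L))
}

# Set-inclusion maximality, computed directly over the family of valid masks
# (used to verify that single-node maximality and inclusion maximality agree
# on small instances rather than assuming it).
oracle_inclusion_maximal <- function(network, profile, params) {
  vn <- igraph::V(network)$name
  n <- length(vn)
  stopifnot(n <= 12L)
  full <- bitwShiftL(1L, n) - 1L
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  state <- kp_effective_state(vn, profile, params)
  valid_masks <- integer(0)
  for (m in seq_len(full)) {
    members <- which(bitwAnd(m, bit) != 0L)
    nodes <- vn[members]
    if (sum(state[nodes] == "exception") > params$k) next
    if (!all(state[nodes] == "exception") &&
        kp_is_valid_pathway(nodes, network, profile, params)) {
      valid_masks <- c(valid_masks, m)
    }
  }
  res <- list()
  for (m in valid_masks) {
    sup <- valid_masks[bitwAnd(valid_masks, m) == m & valid_masks != m]
    if (length(sup)) next
    members <- which(bitwAnd(m, bit) != 0L)
    res[[length(res) + 1L]] <- kp_pathway(vn[members],
                                          vn[members[state[members] == "exception"]])
  }
  res
}
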