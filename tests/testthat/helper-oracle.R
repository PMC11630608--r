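# Independent oracle: a naive, matrix-based transcription of the update
# rules, written separately from the package implementation (dense strength
# matrix, explicit per-node loops, no shared code). Used to cross-check the
# engine on small networks.
#
# strength_mat: n x n integer matrix, [parent, child], NA = no edge.
# priors: integer vector of length n (0 = no knowledge).
oracle_predict <- function(strength_mat, priors, iterations = 4) {
  n <- nrow(strength_mat)
  p <- 0.5 + priors / 10
  pinned <- which(priors != 0)
  pin_p <- p[pinned]
  for (iter in seq_len(iterations)) {
    q <- p
    for (x in seq_len(n)) {
      conds <- numeric(0)
      for (y in seq_len(n)) {
        if (!is.na(strength_mat[y, x]) && abs(p[y] - 0.5) > 1e-9) {
          e <- 0.5 + strength_mat[y, x] / 10
          conds <- c(conds, e * p[y] + (1 - e) * (1 - p[y]))
        }
      }
      if (length(conds) == 0) next
      with_prior <- p[x] + (1 - p[x]) * sum(p[x] * (conds - 0.5)) / length(conds)
      with_prior <- min(0.9, max(0.1, with_prior))
      from_inter <- min(0.9, max(0.1, sum(conds) / length(conds)))
      # most-certain selection; ties (within 1e-9) keep the prior-bearing value
      q[x] <- if (abs(from_inter - 0.5) - abs(with_prior - 0.5) > 1e-9) {
        from_inter
      } else {
        with_prior
      }
    }
    for (k in seq_along(pinned)) {
      if (abs(q[pinned[k]] - 0.5) < abs(pin_p[k] - 0.5)) {
        q[pinned[k]] <- pin_p[k]
      }
    }
    p <- q
  }
  10 * (p - 0.5)
}

# build a bbn_network from the oracle's dense strength matrix
network_from_matrix <- function(strength_mat, nodes) {
  idx <- which(!is.na(strength_mat), arr.ind = TRUE)
  edges <- data.frame(parent = nodes[idx[, 1]], child = nodes[idx[, 2]],
                      strength = strength_mat[idx])
  bbn_network(nodes, edges)
}
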