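# Independent oracles used across tests. These deliberately avoid the
# package's covariance/likelihood code paths: trait processes are simulated
# by walking tree edges with explicit transition draws, and parsimony
# scores are recomputed with a Sankoff dynamic program.

# n independent BM draws at the tips, evolved edge by edge
sim_tips_bm_oracle <- function(tree, n, sigma2 = 1, root = 0) {
  nn <- ape::Ntip(tree) + tree$Nnode
  states <- matrix(NA_real_, n, nn)
  root_node <- ape::Ntip(tree) + 1L
  states[, root_node] <- root
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 1L]])
  for (e in ord) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    states[, ch] <- states[, par] +
      stats::rnorm(n, 0, sqrt(sigma2 * tree$edge.length[e]))
  }
  out <- states[, seq_len(ape::Ntip(tree)), drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

# n independent stationary-OU draws at the tips (exact edge transitions)
sim_tips_ou_oracle <- function(tree, n, alpha, sigma2 = 1, theta = 0) {
  nn <- ape::Ntip(tree) + tree$Nnode
  vst <- sigma2 / (2 * alpha)
  states <- matrix(NA_real_, n, nn)
  root_node <- ape::Ntip(tree) + 1L
  states[, root_node] <- stats::rnorm(n, theta, sqrt(vst))
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 1L]])
  for (e in ord) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    states[, ch] <- theta + (states[, par] - theta) * exp(-alpha * t) +
      stats::rnorm(n, 0, sqrt(vst * (1 - exp(-2 * alpha * t))))
  }
  out <- states[, seq_len(ape::Ntip(tree)), drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

# minimum number of binary state changes on a rooted tree (Sankoff DP);
# independent of the package's reconstruction enumeration
sankoff_min_changes <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  cost <- matrix(Inf, nn, 2)
  s <- tip_states[tree$tip.label]
  for (i in seq_len(ntip)) cost[i, s[i] + 1L] <- 0
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 1L]],
               decreasing = TRUE)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  done <- rep(FALSE, nn); done[seq_len(ntip)] <- TRUE
  repeat {
    progressed <- FALSE
    for (node in as.integer(names(children))) {
      if (done[node]) next
      ch <- children[[as.character(node)]]
      if (!all(done[ch])) next
      for (st in 0:1) {
        cost[node, st + 1L] <- sum(vapply(ch, function(c2)
          min(cost[c2, st + 1L], cost[c2, 2L - st] + 1), numeric(1)))
      }
      done[node] <- TRUE; progressed <- TRUE
    }
    if (all(done)) break
    if (!progressed) stop("oracle DP failed to progress")
  }
  min(cost[ntip + 1L, ])
}

# small fixed traits matrix around the example tree, for fit smoke paths
toy_traits <- function(tree, means, n_rep = 3, sd_rep = 0.1, seed = 1) {
  set.seed(seed)
  m <- sapply(seq_len(n_rep), function(r)
    means + stats::rnorm(length(means), 0, sd_rep))
  rownames(m) <- tree$tip.label
  m
}
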