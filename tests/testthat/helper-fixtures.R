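# shared fixtures, built in code at load time

fixture_tree <- function(n = 20, seed = 42) simulate_tree(n, seed = seed)

# brute-force shared-path-length covariance via MRCA node depths
brute_covariance <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  mrca <- ape::mrca(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- if (i == j) depth[i] else depth[mrca[i, j]]
  }
  C
}

# direct GLS solve for fixed covariance: beta = (X' V^-1 X)^-1 X' V^-1 y
brute_gls <- function(y, X, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# enumeration likelihood for a binary Mk model: sum over all internal-state
# assignments of prior(root) * prod over edges of P[parent, child](t)
brute_mk_loglik <- function(tree, states01, q12, q21, prior = c(0.5, 0.5)) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  root <- n_tip + 1L
  P_edge <- lapply(seq_len(nrow(tree$edge)), function(i)
    asrpath:::mk_prob(q12, q21, tree$edge.length[i]))
  total <- 0
  grid <- expand.grid(rep(list(1:2), n_int))
  for (g in seq_len(nrow(grid))) {
    st <- c(states01[tree$tip.label] + 1L, as.integer(grid[g, ]))
    lik <- prior[st[root]]
    for (i in seq_len(nrow(tree$edge)))
      lik <- lik * P_edge[[i]][st[tree$edge[i, 1]], st[tree$edge[i, 2]]]
    total <- total + lik
  }
  log(total)
}

states_to_01 <- function(states) {
  lev <- sort(unique(as.character(states)))
  stats::setNames(match(as.character(states), lev) - 1L, names(states))
}
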