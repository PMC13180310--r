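# Shared test fixtures and independent oracle implementations.
# Everything here is deliberately written from first principles (no calls into
# the package's own internals) so tests compare two independent derivations.

# a fixed 3-tip ultrametric tree used throughout
tree3 <- function() read_newick("((A:1,B:1):1,C:2);")

# random ultrametric tree (coalescent), deterministic by seed
rand_tree <- function(n, seed, height = NULL) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  if (!is.null(height)) {
    tr$edge.length <- tr$edge.length * height / max(ape::node.depth.edgelength(tr))
  }
  tr
}

# random non-ultrametric tree
rand_tree_nonultra <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}

# closed-form GLS estimate for covariance V: beta = (X'V^-1 X)^-1 X'V^-1 y
gls_oracle <- function(X, y, V) {
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# log-density of y ~ N(mu, C), from scratch
mvn_logdens <- function(y, mu, C) {
  L <- chol(C)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# 2x2 matrix exponential of Q*t by eigendecomposition (independent of the
# package's closed-form transition matrix)
expm2 <- function(Q, t) {
  e <- eigen(Q * t)
  Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
}

# brute-force binary-Mk likelihood by enumerating all internal-node states
mk_enum_loglik <- function(tree, tip_idx, q12, q21, pi_root) {
  Q <- matrix(c(-q12, q21, q12, -q21), 2, 2)
  P <- lapply(tree$edge.length, function(t) expm2(Q, t))
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  total <- 0
  for (code in 0:(2^m - 1)) {
    node_state <- integer(n + m)
    node_state[seq_len(n)] <- tip_idx
    node_state[n + seq_len(m)] <- bitwAnd(code %/% 2^(seq_len(m) - 1), 1L) + 1L
    pr <- pi_root[node_state[n + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][node_state[tree$edge[e, 1]], node_state[tree$edge[e, 2]]]
    }
    total <- total + pr
  }
  log(total)
}

# brute-force marginal ancestral probabilities by the same enumeration
mk_enum_marginals <- function(tree, tip_idx, q12, q21, pi_root) {
  Q <- matrix(c(-q12, q21, q12, -q21), 2, 2)
  P <- lapply(tree$edge.length, function(t) expm2(Q, t))
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  marg <- matrix(0, m, 2)
  for (code in 0:(2^m - 1)) {
    node_state <- integer(n + m)
    node_state[seq_len(n)] <- tip_idx
    node_state[n + seq_len(m)] <- bitwAnd(code %/% 2^(seq_len(m) - 1), 1L) + 1L
    pr <- pi_root[node_state[n + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][node_state[tree$edge[e, 1]], node_state[tree$edge[e, 2]]]
    }
    for (j in seq_len(m)) marg[j, node_state[n + j]] <- marg[j, node_state[n + j]] + pr
  }
  marg / rowSums(marg)
}

# expected tip values of a multi-regime OU by recursing the transition mean
# down every painting segment (independent of the package's weight matrix)
ou_mean_oracle <- function(tree, painting, alpha, thetas, root_mean) {
  n <- ape::Ntip(tree)
  mu <- numeric(n + tree$Nnode)
  mu[n + 1L] <- root_mean
  pre <- ape::reorder.phylo(tree, "cladewise")
  eord <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nrow(pre$edge))) {
    e <- eord[k]
    rows <- painting[painting$edge == e, , drop = FALSE]
    m <- mu[tree$edge[e, 1]]
    for (j in seq_len(nrow(rows))) {
      dt <- rows$end[j] - rows$start[j]
      th <- thetas[[rows$regime[j]]]
      m <- th + (m - th) * exp(-alpha * dt)
    }
    mu[tree$edge[e, 2]] <- m
  }
  mu[seq_len(n)]
}

# OU tip covariance from textbook formulas (stationary or fixed root)
ou_cov_oracle <- function(tree, alpha, sigma2, root = "stationary") {
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  td <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  R <- if (root == "stationary") exp(-alpha * D) else
    exp(-alpha * D) - exp(-alpha * outer(td, td, `+`))
  sigma2 / (2 * alpha) * R
}
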