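# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, for the tree oracle, ape's vcv): brute-force
# enumeration and dense textbook algebra only.

# Monte-Carlo sampling variance of the percent change: draw the two group
# means from their implied normal sampling distributions and take the
# empirical variance of 100 * (c - a) / c.
mc_percent_change_variance <- function(control_mean, control_sd, control_n,
                                       alt_mean, alt_sd, alt_n,
                                       nsim = 1e6, seed = 1) {
  set.seed(seed)
  cm <- rnorm(nsim, control_mean, control_sd / sqrt(control_n))
  am <- rnorm(nsim, alt_mean, alt_sd / sqrt(alt_n))
  var(100 * (cm - am) / cm)
}

# Brute-force Brownian-motion correlation: walk the edge matrix from each tip
# to the root, collect the edges on the path, and sum the lengths of the
# edges two tips share. Independent of ape::vcv.
bm_correlation_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  edge_len_to <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_len_to[tree$edge[, 2]] <- tree$edge.length
  path_edges <- lapply(seq_len(n), function(tip) {
    nodes <- integer(0)
    cur <- tip
    while (cur != root) {
      nodes <- c(nodes, cur)  # identify an edge by its child node
      cur <- parent_of[cur]
    }
    nodes
  })
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(path_edges[[i]], path_edges[[j]])
      C[i, j] <- sum(edge_len_to[shared])
    }
  }
  d <- diag(C)
  R <- C / sqrt(outer(d, d))
  dimnames(R) <- list(tree$tip.label, tree$tip.label)
  R
}

# Brute-force pairwise tip distances by summing path edge lengths.
tip_distances_bruteforce <- function(tree) {
  R_env <- bm_correlation_bruteforce(tree)  # reuse the path walk
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  edge_len_to <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_len_to[tree$edge[, 2]] <- tree$edge.length
  depth <- function(tip) {
    s <- 0; cur <- tip
    while (cur != root) { s <- s + edge_len_to[cur]; cur <- parent_of[cur] }
    s
  }
  dep <- vapply(seq_len(n), depth, numeric(1))
  C <- R_env * sqrt(outer(dep, dep))  # back to shared-path covariance
  D <- outer(dep, dep, `+`) - 2 * C
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# Textbook dense-algebra REML log-likelihood via det() and solve() only.
reml_loglik_dense <- function(vc, spec) {
  M <- marginal_covariance(vc, spec)
  X <- spec$X; y <- spec$y
  n <- length(y); p <- ncol(X)
  Mi <- solve(M)
  XtMiX <- t(X) %*% Mi %*% X
  P <- Mi - Mi %*% X %*% solve(XtMiX) %*% t(X) %*% Mi
  as.numeric(
    -0.5 * (determinant(M)$modulus + determinant(XtMiX)$modulus +
              drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
  )
}

# Brute-force weighted least squares (fixed-effect limit) and its
# leave-one-out Cook's distances.
wls_beta <- function(X, y, v) {
  W <- diag(1 / v, length(y))
  solve(t(X) %*% W %*% X) %*% t(X) %*% W %*% y
}

wls_cooks <- function(X, y, v) {
  n <- length(y)
  beta <- wls_beta(X, y, v)
  covb <- solve(t(X) %*% diag(1 / v, n) %*% X)
  vapply(seq_len(n), function(i) {
    bi <- wls_beta(X[-i, , drop = FALSE], y[-i], v[-i])
    drop(t(bi - beta) %*% solve(covb) %*% (bi - beta))
  }, numeric(1))
}

# Random fixture tree (generation is not the oracle; ape is fine here).
random_fixture_tree <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n)
  tree$tip.label <- paste0("t", seq_len(n))
  tree
}

# Small toy effect-size table spanning the three analyses.
toy_records <- function() {
  data.frame(
    study_id = paste0("s", c(1, 1, 2, 2, 3, 3)),
    effect_id = paste0("e", 1:6),
    host_species = paste0("h", c(1, 1, 2, 2, 3, 3)),
    symbiont_species = paste0("sym", c(1, 2, 1, 2, 3, 3)),
    analysis = rep(c("host_association", "environment", "time"), each = 2),
    symbiont_location = c("intracellular", "extracellular", "intracellular",
                          "both", "extracellular", "intracellular"),
    y = c(0.5, -0.2, 1.1, 0.3, -0.8, 0.1),
    v = c(0.4, 0.5, 0.3, 0.6, 0.5, 0.4),
    percent_change = c(0.5, -0.2, 1.1, 0.3, -0.8, 0.1)^3,
    variance = c(0.4, 0.5, 0.3, 0.6, 0.5, 0.4)^3,
    stringsAsFactors = FALSE
  )
}
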