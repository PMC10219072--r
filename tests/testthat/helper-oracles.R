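# shared builders and independent oracles used across test files

# tightly wound, slightly jittered helical chain: at a cutoff of 8 A each
# site contacts both sequence neighbours and the adjacent turn, so the
# spring network is connected and generically rigid (exactly 6 zero modes)
helix_model <- function(n, domain_ranges = list()) {
  t <- seq_len(n)
  co <- cbind(4 * cos(t * 0.7), 4 * sin(t * 0.7), 0.8 * t) +
    0.3 * cbind(sin(1.7 * t + 0.3), sin(2.3 * t + 1.1), sin(2.9 * t + 2.2))
  site_model(label = t, role = rep("CA", n), coords = co,
             domain_ranges = domain_ranges)
}

# uniform-ish random proper rotation (QR of a Gaussian matrix, det +1)
rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# axis-angle (Rodrigues) rotation used by the numeric superposition oracle
rotmat_aa <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# minimum RMSD over rotations by direct numeric minimization (multi-start
# BFGS over the axis-angle parameterization), independent of the SVD route
min_rmsd_numeric <- function(A, B, n_starts = 6L) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  obj <- function(w) mean(rowSums((A0 %*% t(rotmat_aa(w)) - B0)^2))
  starts <- c(list(c(0, 0, 0)),
              lapply(seq_len(n_starts), function(i) rnorm(3, sd = 2)))
  vals <- vapply(starts, function(w0)
    stats::optim(w0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-15))$value, 0)
  sqrt(min(vals))
}

# exhaustive shortest-path betweenness oracle: Floyd--Warshall distances,
# then pairwise path counting sigma[s, t] by dynamic programming over
# increasing distance, then BC(v) = sum_{s<t} sigma_sv sigma_vt / sigma_st
bc_pair_counting_oracle <- function(n, edges, w, normalized = TRUE) {
  W <- matrix(Inf, n, n); diag(W) <- 0
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    W[a, b] <- W[b, a] <- min(W[a, b], w[k])
  }
  D <- W
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(D[s, ])) {
      if (t == s) next
      pred <- which(is.finite(W[, t]) & abs(D[s, ] + W[, t] - D[s, t]) < 1e-9)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) for (v in seq_len(n)) {
    if (v == s || v == t) next
    if (abs(D[s, v] + D[v, t] - D[s, t]) < 1e-9)
      bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  if (normalized && n > 2) bc / ((n - 1) * (n - 2) / 2) else bc
}

# residue_network over an explicit edge list with exact (integer) weights:
# correlations exp(-w) reproduce the weights only approximately, so the
# graph weights are overwritten with the exact values afterwards
network_with_weights <- function(n, edges, w) {
  r <- matrix(0, n, n)
  r[edges] <- exp(-w)
  r <- r + t(r); diag(r) <- 1
  sm <- site_model(label = seq_len(n), role = rep("CA", n),
                   coords = matrix(seq_len(3 * n), n, 3),
                   domain_ranges = list())
  net <- build_network(r, contacts = data.frame(a = edges[, 1], b = edges[, 2]),
                       site_model = sm)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  exact <- w[match(paste(net$edges$a, net$edges$b), key)]
  igraph::E(net$graph)$weight <- exact
  net$edges$weight <- exact
  net
}

# random connected undirected graph: random spanning tree plus extra edges
rand_connected_graph <- function(n, extra = n) {
  perm <- sample(n)
  tree <- cbind(perm[2:n],
                vapply(2:n, function(i) perm[sample(i - 1, 1)], 0L))
  more <- cbind(sample(n, extra, replace = TRUE),
                sample(n, extra, replace = TRUE))
  e <- rbind(tree, more)
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}
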