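#' Linear mutual information between site fluctuations
#'
#' Treats each site's 3D fluctuation vector as jointly Gaussian and computes
#' the mutual information between site pairs from the 3x3 marginal and 6x6
#' joint covariance blocks,
#' `I(i,j) = (ln det C_ii + ln det C_jj - ln det C_ij) / 2` (nats),
#' mapped to a generalized correlation coefficient in `[0, 1]` by
#' `r = sqrt(1 - exp(-2 I / 3))`. Unlike the Pearson-type cross-correlation,
#' this captures coupled motions even when their directions are orthogonal.
#'
#' @param cov a `covariance_model` (see [covariance()] / [anm_covariance()])
#' @return object of class `lmi_result`: `mutual_information` (n x n, nats,
#'   `Inf` on the diagonal), `generalized_correlation` (n x n in `[0, 1]`,
#'   unit diagonal), `site_model`
#' @export
lmi_matrix <- function(cov) {
  stopifnot(inherits(cov, "covariance_model"))
  g <- cov$gamma
  n <- nrow(cov$site_model)
  blk <- function(i, j) g[(3L * i - 2L):(3L * i), (3L * j - 2L):(3L * j)]
  logdet <- function(m) {
    ch <- tryCatch(chol(m), error = function(e) NULL)
    if (is.null(ch)) NA_real_ else 2 * sum(log(diag(ch)))
  }
  ld <- vapply(seq_len(n), function(i) logdet(blk(i, i)), 0)
  if (anyNA(ld)) {
    bad <- cov$site_model$label[which(is.na(ld))]
    stop("singular marginal covariance block at site(s): ",
         paste(bad, collapse = ", "))
  }
  I <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    J <- rbind(cbind(blk(i, i), blk(i, j)), cbind(blk(j, i), blk(j, j)))
    ldj <- logdet((J + t(J)) / 2)
    # a singular joint block means deterministic dependence: maximal MI
    Iij <- if (is.na(ldj)) Inf else max(0, (ld[i] + ld[j] - ldj) / 2)
    I[i, j] <- I[j, i] <- Iij
  }
  diag(I) <- Inf
  r <- sqrt(1 - exp(-2 * I / 3))
  diag(r) <- 1
  lbl <- paste0(cov$site_model$role, ":", cov$site_model$label)
  dimnames(I) <- dimnames(r) <- list(lbl, lbl)
  structure(list(mutual_information = I, generalized_correlation = r,
                 site_model = cov$site_model),
            class = "lmi_result")
}

#' Build a correlation-weighted residue network
#'
#' Nodes are sites; edges connect the supplied contact pairs with weight
#' `-ln r(i, j)`, so strong coupling means a short path and shortest paths
#' trace the most correlated communication routes. Edges with `r = 0` carry
#' infinite weight and are dropped with a warning; `r = 1` gives weight 0.
#'
#' @param correlation an `lmi_result`, a `correlation_map`, or a plain
#'   symmetric matrix of correlations in `[0, 1]` (absolute value is taken)
#' @param contacts a `contact_set` restricting the edges (default: dense,
#'   every pair)
#' @param site_model required when `correlation` is a plain matrix
#' @return object of class `residue_network`: `graph` (igraph, weighted),
#'   `site_model`, `edges` (data frame `a`, `b`, `r`, `weight`),
#'   `connected`
#' @export
build_network <- function(correlation, contacts = NULL, site_model = NULL) {
  if (inherits(correlation, "lmi_result")) {
    r <- correlation$generalized_correlation
    site_model <- correlation$site_model
  } else if (inherits(correlation, "correlation_map")) {
    r <- abs(correlation$matrix)
    site_model <- correlation$site_model
  } else {
    r <- abs(as.matrix(correlation))
    if (is.null(site_model)) stop("site_model required with a plain matrix")
  }
  n <- nrow(r)
  if (is.null(contacts)) {
    pairs <- which(upper.tri(r), arr.ind = TRUE)
    contacts <- data.frame(a = pairs[, 1], b = pairs[, 2])
  }
  contacts <- as_contact_set(contacts)
  rv <- r[cbind(contacts$a, contacts$b)]
  if (any(rv > 1 + 1e-9)) stop("correlations must lie in [0, 1]")
  rv <- pmin(rv, 1)
  zero <- rv <= 0
  if (any(zero)) {
    warning(sum(zero), " edge(s) with zero correlation dropped")
    contacts <- contacts[!zero, , drop = FALSE]
    rv <- rv[!zero]
  }
  edges <- data.frame(a = contacts$a, b = contacts$b, r = rv,
                      weight = -log(rv))
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::E(g)$weight <- edges$weight
  structure(list(graph = g, site_model = site_model, edges = edges,
                 connected = igraph::is_connected(g)),
            class = "residue_network")
}

#' @export
print.residue_network <- function(x, ...) {
  cat("residue_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges",
      if (!x$connected) "(disconnected)" else "", "\n")
  invisible(x)
}

#' Betweenness centrality of a residue network
#'
#' `BC(i) = sum over node pairs (a, b) of n_ab(i) / g_ab`, where `g_ab`
#' counts shortest paths from a to b and `n_ab(i)` those passing through i:
#' Brandes' algorithm on the weighted graph, with degenerate shortest paths
#' counted fractionally and endpoints excluded. Normalization divides by the
#' number of pairs `(n - 1)(n - 2) / 2`.
#'
#' @param network a `residue_network`
#' @param normalized report BC in `[0, 1]` (default TRUE)
#' @return data frame: `site`, `label`, `role`, `domain`, `bc`
#' @export
betweenness_centrality <- function(network, normalized = TRUE) {
  stopifnot(inherits(network, "residue_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0L) stop("empty graph")
  # zero-weight edges are legal here (r = 1); igraph requires positive
  # weights, so shift by the smallest representable epsilon-free transform:
  # add a constant much smaller than the smallest nonzero weight
  w <- igraph::E(g)$weight
  if (any(w <= 0)) {
    eps <- if (any(w > 0)) min(w[w > 0]) * 1e-9 else 1e-12
    w <- w + eps
  }
  bc <- igraph::betweenness(g, directed = FALSE, weights = w, normalized = FALSE)
  n <- igraph::vcount(g)
  if (normalized && n > 2L) bc <- bc / ((n - 1) * (n - 2) / 2)
  sm <- network$site_model
  data.frame(site = seq_len(nrow(sm)), label = sm$label, role = sm$role,
             domain = sm$domain, bc = as.numeric(bc))
}

#' Betweenness-centrality difference between two networks
#'
#' Per-node `BC_a - BC_b` on normalized centralities (the perturbed system
#' is conventionally `network_a`, so positive values are importance gained
#' under the perturbation). Nodes with `|delta| > flag_threshold` are
#' flagged.
#' @param network_a,network_b `residue_network`s over identical node sets
#' @param flag_threshold magnitude above which a site is flagged
#'   (default 0.1)
#' @return data frame: `site`, `label`, `role`, `domain`, `bc_a`, `bc_b`,
#'   `delta_bc`, `flagged`
#' @export
bc_difference <- function(network_a, network_b, flag_threshold = 0.1) {
  bca <- betweenness_centrality(network_a, normalized = TRUE)
  bcb <- betweenness_centrality(network_b, normalized = TRUE)
  if (!identical(bca[, c("label", "role")], bcb[, c("label", "role")]))
    stop("networks cover different node sets")
  out <- bca[, c("site", "label", "role", "domain")]
  out$bc_a <- bca$bc
  out$bc_b <- bcb$bc
  out$delta_bc <- bca$bc - bcb$bc
  out$flagged <- abs(out$delta_bc) > flag_threshold
  out
}
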