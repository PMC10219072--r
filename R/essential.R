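#' Cartesian fluctuation covariance of an ensemble
#'
#' Builds the 3N x 3N covariance of positional fluctuations about the mean
#' structure, the input to essential-dynamics PCA, cross-correlation maps and
#' linear-mutual-information networks. Frames are by default superposed onto
#' the iteratively refined ensemble mean first, so rigid-body motion does not
#' contaminate the internal fluctuations.
#'
#' @param e an [ensemble()]
#' @param selection sites included (default all)
#' @param align superpose frames onto the refined mean before estimating
#'   (default TRUE; set FALSE if `e` is already aligned)
#' @param estimator `"ml"` (divisor n, default) or `"unbiased"` (n - 1)
#' @return object of class `covariance_model`: `mean` (n x 3), `gamma`
#'   (3N x 3N), `evalues` (descending), `evectors` (orthonormal columns),
#'   `site_model`, `n_frames`
#' @export
covariance <- function(e, selection = "all", align = TRUE,
                       estimator = c("ml", "unbiased")) {
  estimator <- match.arg(estimator)
  if (n_frames(e) < 2L) stop("covariance needs at least 2 frames")
  es <- subset_ensemble(e, select_sites(e$site_model, selection))
  if (align) es <- align_ensemble(es)
  xyz <- ensemble_xyz(es)
  mu <- colMeans(xyz)
  xc <- sweep(xyz, 2, mu)
  div <- if (estimator == "ml") nrow(xyz) else nrow(xyz) - 1L
  gamma <- crossprod(xc) / div
  gamma <- (gamma + t(gamma)) / 2
  covariance_model(gamma, matrix(mu, ncol = 3L, byrow = TRUE),
                   es$site_model, n_frames = nrow(xyz))
}

#' Assemble a covariance model from an explicit matrix
#'
#' Used both by [covariance()] and to wrap an analytic covariance (e.g.
#' `kT * pseudoinverse(H)` of an elastic network) in the same container, so
#' every downstream stage runs identically on sampled and analytic input.
#' @param gamma 3N x 3N symmetric positive-semidefinite matrix
#' @param mean_coords n x 3 mean structure
#' @param site_model the [site_model()]
#' @param n_frames number of frames used (NA for analytic)
#' @export
covariance_model <- function(gamma, mean_coords, site_model, n_frames = NA) {
  n3 <- nrow(site_model) * 3L
  stopifnot(identical(dim(gamma), c(n3, n3)))
  if (max(abs(gamma - t(gamma))) > 1e-8 * max(1, max(abs(gamma))))
    stop("gamma must be symmetric")
  eg <- eigen((gamma + t(gamma)) / 2, symmetric = TRUE)
  structure(list(gamma = gamma, mean = as.matrix(mean_coords),
                 evalues = eg$values, evectors = eg$vectors,
                 site_model = site_model, n_frames = n_frames),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("covariance_model:", nrow(x$site_model), "sites, trace",
      format(sum(diag(x$gamma)), digits = 4), "\n")
  invisible(x)
}

# per-site-pair block traces of a 3N x 3N matrix -> n x n matrix
block_trace <- function(gamma) {
  n <- nrow(gamma) / 3L
  i1 <- seq(1L, by = 3L, length.out = n)
  gamma[i1, i1] + gamma[i1 + 1L, i1 + 1L] + gamma[i1 + 2L, i1 + 2L]
}

#' Dynamic cross-correlation map
#'
#' `C(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`: +1 for perfectly
#' correlated motion, -1 for anti-correlated, 0 for uncorrelated or
#' orthogonal displacements.
#' @param cov a `covariance_model`
#' @return object of class `correlation_map` (kind `"DCCM"`): symmetric
#'   n x n matrix, unit diagonal, labelled by site
#' @export
dccm <- function(cov) {
  stopifnot(inherits(cov, "covariance_model"))
  bt <- block_trace(cov$gamma)
  v <- diag(bt)
  if (any(v <= 0)) {
    bad <- cov$site_model$label[which(v <= 0)]
    stop("site(s) with zero fluctuation: ", paste(bad, collapse = ", "))
  }
  C <- bt / sqrt(outer(v, v))
  diag(C) <- 1
  correlation_map(C, "DCCM", cov$site_model)
}

correlation_map <- function(m, kind, site_model) {
  lbl <- paste0(site_model$role, ":", site_model$label)
  dimnames(m) <- list(lbl, lbl)
  structure(list(matrix = m, kind = kind, site_model = site_model),
            class = "correlation_map")
}

#' Elementwise difference of two maps or matrices
#'
#' Used to contrast perturbed vs wild-type correlation (or PRS) structure;
#' `map_difference(A, B)` is `A - B`, so positive entries are couplings
#' gained in `A`.
#' @param map_a,map_b `correlation_map`s or plain matrices of equal shape
#'   and site ordering
#' @return matrix of differences
#' @export
map_difference <- function(map_a, map_b) {
  ma <- if (inherits(map_a, "correlation_map")) map_a$matrix else as.matrix(map_a)
  mb <- if (inherits(map_b, "correlation_map")) map_b$matrix else as.matrix(map_b)
  if (!identical(dim(ma), dim(mb))) stop("maps differ in shape")
  if (!is.null(dimnames(ma)) && !is.null(dimnames(mb)) &&
      !identical(dimnames(ma), dimnames(mb)))
    stop("maps differ in site ordering")
  ma - mb
}

#' Essential-dynamics principal components
#'
#' The eigendecomposition of the fluctuation covariance, reported mode by
#' mode with variance fractions: eigenvalues give the amplitude of each
#' collective motion, eigenvectors its direction.
#' @param cov a `covariance_model`
#' @param n_components number of leading modes to report
#' @return data frame with columns `component`, `eigenvalue`,
#'   `variance_fraction`, `cumulative_fraction`; attribute `vectors` holds
#'   the corresponding 3N x k eigenvector matrix
#' @export
pca <- function(cov, n_components = 20L) {
  stopifnot(inherits(cov, "covariance_model"))
  n3 <- length(cov$evalues)
  if (n_components > n3) stop("n_components exceeds 3N = ", n3)
  ev <- pmax(cov$evalues, 0)
  tot <- sum(ev)
  frac <- if (tot > 0) ev / tot else rep(0, n3)
  out <- data.frame(component = seq_len(n_components),
                    eigenvalue = cov$evalues[seq_len(n_components)],
                    variance_fraction = frac[seq_len(n_components)],
                    cumulative_fraction = cumsum(frac)[seq_len(n_components)])
  attr(out, "vectors") <- cov$evectors[, seq_len(n_components), drop = FALSE]
  out
}

#' Project an ensemble onto a principal component
#'
#' Frames are superposed onto the covariance model's mean structure (unless
#' already aligned), centred on it, and dotted with the chosen eigenvector.
#' @param e an [ensemble()] over the same sites as `cov`
#' @param cov a `covariance_model`
#' @param component mode index (1 = largest eigenvalue)
#' @param align superpose frames onto `cov$mean` first (default TRUE)
#' @return list of class `pc_projection`: `component`, `values` (per frame),
#'   `variance`, `variance_fraction`, `cosine_content`
#' @export
project <- function(e, cov, component = 1L, align = TRUE) {
  stopifnot(inherits(cov, "covariance_model"))
  n3 <- length(cov$evalues)
  if (component < 1L || component > n3) stop("component out of range")
  if (nrow(e$site_model) != nrow(cov$site_model))
    stop("ensemble and covariance model cover different sites")
  co <- e$coords
  if (align)
    for (i in seq_len(dim(co)[3]))
      co[, , i] <- superpose(co[, , i, drop = TRUE], cov$mean)$coords
  xyz <- t(matrix(aperm(co, c(2, 1, 3)), nrow = n3))
  xc <- sweep(xyz, 2, as.vector(t(cov$mean)))
  vals <- as.vector(xc %*% cov$evectors[, component])
  tot <- sum(pmax(cov$evalues, 0))
  structure(list(component = component, values = vals,
                 variance = mean(vals^2) - mean(vals)^2,
                 variance_fraction = if (tot > 0) cov$evalues[component] / tot else 0,
                 cosine_content = cosine_content(vals)),
            class = "pc_projection")
}

#' Cosine content of a projection
#'
#' The overlap of a time series with a half-period cosine,
#' `c_k = (2/T) (int cos(k pi t / T) p(t) dt)^2 / int p(t)^2 dt`,
#' evaluated by midpoint quadrature on the frame index. Values near 1
#' indicate random-diffusion-like sampling; well-converged collective modes
#' score low (<= 0.1 is the usual benchmark).
#' @param p numeric series (a PC projection) or a `pc_projection`
#' @param k harmonic index (default 1)
#' @return value in `[0, 1]`
#' @export
cosine_content <- function(p, k = 1L) {
  if (inherits(p, "pc_projection")) p <- p$values
  n <- length(p)
  if (n < 2L) stop("cosine content needs at least 2 frames")
  if (stats::var(p) == 0)
    stop("zero-variance projection; cosine content undefined")
  t <- (seq_len(n) - 0.5) / n
  # midpoint quadrature of c_k = 2 (int cos(k pi t) p dt)^2 / int p^2 dt
  num <- 2 * (sum(cos(k * pi * t) * p) / n)^2
  den <- sum(p^2) / n
  num / den
}

#' Free-energy landscape over two reaction coordinates
#'
#' Bins the joint samples of two collective coordinates (PC1/PC2, or
#' RMSD/Rg) and converts occupancy to free energy,
#' `F = -kT ln(count / max_count)`, so the most populated bin sits at 0 and
#' empty bins are masked.
#' @param x,y equal-length coordinate series
#' @param n_bins bins per axis (default 50)
#' @param kT energy scale of the output (default 1, i.e. units of kT)
#' @return object of class `free_energy_surface`: `x_edges`, `y_edges`,
#'   `free_energy` (matrix, `NA` on masked bins), `mask`, `kT`, `counts`
#' @export
free_energy_landscape <- function(x, y, n_bins = 50L, kT = 1) {
  stopifnot(length(x) == length(y), n_bins >= 2L)
  xe <- seq(min(x), max(x), length.out = n_bins + 1L)
  ye <- seq(min(y), max(y), length.out = n_bins + 1L)
  # degenerate axes (all samples identical) collapse to one occupied column
  if (xe[1] == xe[n_bins + 1L]) xe <- xe + seq(-0.5, 0.5, length.out = n_bins + 1L)
  if (ye[1] == ye[n_bins + 1L]) ye <- ye + seq(-0.5, 0.5, length.out = n_bins + 1L)
  ix <- pmin(findInterval(x, xe, all.inside = TRUE), n_bins)
  iy <- pmin(findInterval(y, ye, all.inside = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  fe <- matrix(NA_real_, n_bins, n_bins)
  occ <- counts > 0L
  fe[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(x_edges = xe, y_edges = ye, free_energy = fe,
                 mask = !occ, kT = kT, counts = counts),
            class = "free_energy_surface")
}

#' Detect basins on a free-energy surface
#'
#' Watershed assignment on the occupied bins: bins are processed in order of
#' increasing free energy (ties broken by x-then-y index); a bin with no
#' assigned 8-connected neighbour founds a new basin provided its free
#' energy is below `depth_threshold`, otherwise it joins the neighbouring
#' basin with the lowest minimum. When a bin bridges several basins, any
#' basin whose depth relative to the bridging bin is less than
#' `merge_barrier` is absorbed into the deepest one — with the default
#' `merge_barrier = 0` every local minimum keeps its own basin, while a
#' positive value suppresses sampling-noise ripples shallower than the
#' barrier. Basins are numbered by increasing free energy at their minimum.
#'
#' @param surface a `free_energy_surface`
#' @param depth_threshold only minima with `F` below this found basins
#'   (default `Inf`); if nothing qualifies the global minimum still does
#' @param merge_barrier persistence threshold in the surface's energy units
#'   (default 0, no merging)
#' @return data frame with one row per basin: `basin`, `x_bin`, `y_bin`,
#'   `x`, `y` (bin centres), `min_free_energy`, `n_bins`; attribute
#'   `assignment` holds the per-bin basin-label matrix, attribute
#'   `degenerate` flags an all-flat surface
#' @export
detect_basins <- function(surface, depth_threshold = Inf, merge_barrier = 0) {
  fe <- surface$free_energy
  if (all(is.na(fe))) stop("surface has no occupied bins")
  nb <- dim(fe)
  nbr <- function(i, j) {
    di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
    keep <- !(di == 0 & dj == 0)
    ii <- i + di[keep]; jj <- j + dj[keep]
    ok <- ii >= 1 & ii <= nb[1] & jj >= 1 & jj <= nb[2]
    cbind(ii[ok], jj[ok])
  }
  occ <- which(!is.na(fe), arr.ind = TRUE)
  ord <- order(fe[occ], occ[, 1], occ[, 2])
  occ <- occ[ord, , drop = FALSE]
  assignment <- matrix(NA_integer_, nb[1], nb[2])
  parent <- integer(0)           # union-find over basin labels
  minF <- numeric(0)
  seed_x <- integer(0); seed_y <- integer(0)
  find <- function(k) { while (parent[k] != k) k <- parent[k]; k }
  for (r in seq_len(nrow(occ))) {
    i <- occ[r, 1]; j <- occ[r, 2]; f <- fe[i, j]
    labs <- assignment[nbr(i, j)]
    labs <- unique(vapply(labs[!is.na(labs)], find, 1L))
    if (!length(labs)) {
      if (f < depth_threshold || length(parent) == 0L) {
        parent <- c(parent, length(parent) + 1L)
        minF <- c(minF, f)
        seed_x <- c(seed_x, i); seed_y <- c(seed_y, j)
        assignment[i, j] <- length(parent)
      }
      # above-threshold isolated regions stay unassigned
      next
    }
    deepest <- labs[order(minF[labs], seed_x[labs], seed_y[labs])][1]
    assignment[i, j] <- deepest
    for (b in setdiff(labs, deepest))
      if (f - minF[b] < merge_barrier) parent[b] <- deepest
  }
  lab_occ <- assignment[occ]
  keep <- !is.na(lab_occ)
  lab_occ[keep] <- vapply(lab_occ[keep], find, 1L)
  assignment[occ] <- lab_occ
  roots <- sort(unique(lab_occ[keep]))
  ord2 <- roots[order(minF[roots], seed_x[roots], seed_y[roots])]
  relabel <- integer(length(parent)); relabel[ord2] <- seq_along(ord2)
  assignment[occ[keep, , drop = FALSE]] <- relabel[lab_occ[keep]]
  xc <- (surface$x_edges[-1] + surface$x_edges[-length(surface$x_edges)]) / 2
  yc <- (surface$y_edges[-1] + surface$y_edges[-length(surface$y_edges)]) / 2
  out <- data.frame(basin = seq_along(ord2),
                    x_bin = seed_x[ord2], y_bin = seed_y[ord2],
                    x = xc[seed_x[ord2]], y = yc[seed_y[ord2]],
                    min_free_energy = minF[ord2],
                    n_bins = as.vector(table(factor(assignment[occ],
                                                    seq_along(ord2)))))
  attr(out, "assignment") <- assignment
  attr(out, "degenerate") <- nrow(out) == 1L &&
    length(unique(fe[occ])) == 1L && nrow(occ) > 1L
  out
}

#' Porcupine arrows for a principal component
#'
#' One 3-vector per site: the site's segment of the chosen eigenvector,
#' scaled, anchored at the mean structure. Arrows shorter than `min_length`
#' are suppressed, the usual de-cluttering step before rendering.
#' @param cov a `covariance_model`
#' @param component mode index
#' @param scale multiplier applied to the eigenvector segments
#' @param min_length suppress arrows shorter than this (Angstrom, default 0)
#' @return data frame: `site`, `label`, `role`, `domain`, anchor `x,y,z`,
#'   arrow `dx,dy,dz`, `length`; suppressed arrows are omitted
#' @export
porcupine_vectors <- function(cov, component = 1L, scale = 1, min_length = 0) {
  stopifnot(inherits(cov, "covariance_model"))
  if (component < 1L || component > length(cov$evalues))
    stop("component out of range")
  v <- matrix(cov$evectors[, component], ncol = 3L, byrow = TRUE) * scale
  len <- sqrt(rowSums(v^2))
  keep <- len >= min_length & len > 0
  sm <- cov$site_model
  data.frame(site = which(keep), label = sm$label[keep], role = sm$role[keep],
             domain = sm$domain[keep],
             x = cov$mean[keep, 1], y = cov$mean[keep, 2], z = cov$mean[keep, 3],
             dx = v[keep, 1], dy = v[keep, 2], dz = v[keep, 3],
             length = len[keep])
}

#' Write porcupine arrows as a two-model PDB
#'
#' Model 1 holds arrow tails (the mean structure), model 2 the tips, for
#' rendering in any molecular viewer.
#' @param arrows output of [porcupine_vectors()]
#' @param path file path
#' @export
write_porcupine_pdb <- function(arrows, path) {
  fmt <- function(serial, resno, x, y, z)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, resno, x, y, z)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("MODEL     1", con)
  for (i in seq_len(nrow(arrows)))
    writeLines(fmt(i, arrows$label[i], arrows$x[i], arrows$y[i], arrows$z[i]), con)
  writeLines(c("ENDMDL", "MODEL     2"), con)
  for (i in seq_len(nrow(arrows)))
    writeLines(fmt(i, arrows$label[i], arrows$x[i] + arrows$dx[i],
                   arrows$y[i] + arrows$dy[i], arrows$z[i] + arrows$dz[i]), con)
  writeLines(c("ENDMDL", "END"), con)
  invisible(path)
}
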