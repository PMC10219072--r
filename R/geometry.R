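#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' coordinate sets over the fitted sites, via SVD of the cross-covariance with
#' the usual sign correction so the rotation determinant is +1 (no
#' reflection).
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstrom)
#' @param fit_idx indices of the sites used for the fit (default all);
#'   at least 3 non-collinear sites are required for a unique rotation
#' @return list with `coords` (the rotated+translated mobile set, all sites),
#'   `rmsd` (over the fitted sites, Angstrom), `rotation` (3x3, det +1) and
#'   `translation`
#' @export
superpose <- function(mobile, reference, fit_idx = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, identical(dim(mobile), dim(reference)))
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(mobile))
  if (length(fit_idx) < 3L) stop("superposition needs at least 3 fitted sites")
  A <- mobile[fit_idx, , drop = FALSE]
  B <- reference[fit_idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinear fit sets leave a free rotation about the common axis
  if (qr(A0)$rank < 2L || qr(B0)$rank < 2L)
    stop("fitted sites are collinear; rotation is not unique")
  s <- svd(crossprod(A0, B0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(sweep(mobile, 2, ca) %*% R, 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((fitted[fit_idx, , drop = FALSE] - B)^2)))
  list(coords = fitted, rmsd = rmsd, rotation = R,
       translation = cb - as.vector(ca %*% R))
}

#' Per-frame RMSD series
#'
#' Each frame is rigidly superposed onto the reference over the selected
#' sites (fit set = measure set) and the residual RMSD recorded, the standard
#' trajectory RMSD-vs-time descriptor.
#'
#' @param e an [ensemble()]
#' @param selection selection resolved against the ensemble's site model
#' @param reference `"initial"` (frame 1), a frame index, or an `n x 3`
#'   coordinate matrix
#' @return data frame of class `descriptor_series` with columns `frame`,
#'   `time`, `value` (Angstrom); `name` attribute `"RMSD"`
#' @export
rmsd_series <- function(e, selection = "all", reference = "initial") {
  idx <- select_sites(e$site_model, selection)
  ref <- resolve_reference(e, reference)
  vals <- vapply(seq_len(n_frames(e)), function(i)
    superpose(frame_coords(e, i), ref, fit_idx = idx)$rmsd, 0)
  descriptor_series("RMSD", e, vals)
}

resolve_reference <- function(e, reference) {
  if (is.character(reference) && identical(reference, "initial"))
    frame_coords(e, 1L)
  else if (is.numeric(reference) && length(reference) == 1L)
    frame_coords(e, as.integer(reference))
  else as.matrix(reference)
}

descriptor_series <- function(name, e, values) {
  out <- data.frame(frame = seq_len(n_frames(e)), time = e$times,
                    value = values)
  attr(out, "name") <- name
  class(out) <- c("descriptor_series", "data.frame")
  out
}

#' Radius of gyration of one frame
#'
#' `sqrt(sum m_i |r_i - r_cm|^2 / sum m_i)`; with the default equal coarse
#' masses this is the purely geometric radius of gyration.
#'
#' @param coords `n x 3` matrix (Angstrom)
#' @param mass per-site masses; default equal
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(coords, mass = NULL) {
  coords <- as.matrix(coords)
  if (is.null(mass)) mass <- rep(1, nrow(coords))
  if (sum(mass) <= 0) stop("total mass must be positive")
  cm <- colSums(coords * mass) / sum(mass)
  sqrt(sum(mass * rowSums(sweep(coords, 2, cm)^2)) / sum(mass))
}

#' Per-frame radius-of-gyration series
#' @inheritParams rmsd_series
#' @param mass_weighted use the site-model masses (default: equal masses)
#' @export
rg_series <- function(e, selection = "all", mass_weighted = FALSE) {
  idx <- select_sites(e$site_model, selection)
  mass <- if (mass_weighted) e$site_model$mass[idx] else NULL
  vals <- vapply(seq_len(n_frames(e)), function(i)
    radius_of_gyration(frame_coords(e, i)[idx, , drop = FALSE], mass), 0)
  descriptor_series("RG", e, vals)
}

#' Root-mean-square fluctuation per site
#'
#' RMSF_i = sqrt(< |r_i(t) - <r_i>|^2 >). With `align_first` every frame is
#' first superposed onto the ensemble mean (two refinement passes) so that
#' rigid-body tumbling does not inflate the fluctuations.
#'
#' @param e an [ensemble()]
#' @param selection sites to report (alignment uses the same set)
#' @param align_first superpose frames before measuring (default TRUE)
#' @return data frame with columns `site`, `label`, `role`, `domain`, `rmsf`
#' @export
rmsf <- function(e, selection = "all", align_first = TRUE) {
  if (n_frames(e) < 2L) stop("RMSF needs at least 2 frames")
  idx <- select_sites(e$site_model, selection)
  es <- subset_ensemble(e, idx)
  if (align_first) es <- align_ensemble(es)
  xyz <- ensemble_xyz(es)
  dev2 <- sweep(xyz, 2, colMeans(xyz))^2
  persite <- matrix(colMeans(dev2), nrow = 3L)  # 3 x n_sites
  data.frame(site = idx, label = es$site_model$label,
             role = es$site_model$role, domain = es$site_model$domain,
             rmsf = sqrt(colSums(persite)))
}

#' Superpose every frame of an ensemble onto its mean structure
#'
#' Iterative mean-structure alignment (frames fitted to the running mean,
#' mean recomputed; `n_iter` passes), the standard preprocessing before
#' covariance analysis.
#' @param e an [ensemble()]
#' @param fit_selection sites used for the fit (default all)
#' @param n_iter refinement passes (default 2)
#' @return an aligned [ensemble()]
#' @export
align_ensemble <- function(e, fit_selection = "all", n_iter = 2L) {
  idx <- select_sites(e$site_model, fit_selection)
  co <- e$coords
  ref <- co[, , 1L, drop = TRUE]
  if (n_frames(e) == 1L) ref <- matrix(ref, ncol = 3L)
  for (it in seq_len(n_iter)) {
    for (i in seq_len(dim(co)[3]))
      co[, , i] <- superpose(co[, , i, drop = TRUE], ref, fit_idx = idx)$coords
    ref <- apply(co, c(1, 2), mean)
  }
  ensemble(co, e$site_model, times = e$times, aligned = TRUE)
}

#' Hydrogen-bond geometric criterion
#'
#' A donor-hydrogen-acceptor triple is bonded when the donor--acceptor
#' distance is at most `d_max` and the hydrogen deviates from the
#' donor-acceptor axis (angle hydrogen-donor-acceptor) by at most
#' `angle_max`.
#' @param d_max donor-acceptor cutoff, Angstrom (default 3.5)
#' @param angle_max hydrogen-donor-acceptor deviation cutoff, degrees
#'   (default 30)
#' @return list of class `hbond_criterion`
#' @export
hbond_criterion <- function(d_max = 3.5, angle_max = 30) {
  stopifnot(d_max > 0, angle_max > 0, angle_max < 180)
  structure(list(d_max = d_max, angle_max = angle_max),
            class = "hbond_criterion")
}

#' Evaluate the H-bond criterion on one geometry
#' @param donor,hydrogen,acceptor 3-vectors (Angstrom)
#' @param criterion an [hbond_criterion()]
#' @return logical
#' @export
detect_hbond <- function(donor, hydrogen, acceptor,
                         criterion = hbond_criterion()) {
  dh <- hydrogen - donor
  da <- acceptor - donor
  if (sqrt(sum(dh^2)) < 1e-9) stop("donor and hydrogen coincide; angle undefined")
  d <- sqrt(sum(da^2))
  cosang <- sum(dh * da) / (sqrt(sum(dh^2)) * d)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  d <= criterion$d_max && ang <= criterion$angle_max
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' Occupancy is the fraction of frames in which the donor-hydrogen-acceptor
#' triple satisfies the geometric criterion.
#' @param e an [ensemble()] whose site model contains the three pseudo-sites
#' @param donor,hydrogen,acceptor site labels (CA role by default; use
#'   `c(label, role)` semantics of [site_index()] via the `roles` argument)
#' @param roles character(3), roles of the three sites (default all `"CA"`)
#' @param criterion an [hbond_criterion()]
#' @return list of class `contact_record` with `per_frame` (logical),
#'   `occupancy`, `distance` (donor-acceptor series, Angstrom)
#' @export
hbond_occupancy <- function(e, donor, hydrogen, acceptor,
                            roles = c("CA", "CA", "CA"),
                            criterion = hbond_criterion()) {
  id <- site_index(e$site_model, donor, roles[1])
  ih <- site_index(e$site_model, hydrogen, roles[2])
  ia <- site_index(e$site_model, acceptor, roles[3])
  nf <- n_frames(e)
  per <- logical(nf); dist <- numeric(nf)
  for (i in seq_len(nf)) {
    fc <- frame_coords(e, i)
    per[i] <- detect_hbond(fc[id, ], fc[ih, ], fc[ia, ], criterion)
    dist[i] <- sqrt(sum((fc[ia, ] - fc[id, ])^2))
  }
  contact_record(donor, acceptor, "HBOND", per, dist)
}

contact_record <- function(site_a, site_b, kind, per_frame, distance) {
  structure(list(site_a = site_a, site_b = site_b, kind = kind,
                 per_frame = per_frame, occupancy = mean(per_frame),
                 distance = distance),
            class = "contact_record")
}

#' @export
print.contact_record <- function(x, ...) {
  cat(sprintf("%s %s-%s occupancy %.3f mean distance %.2f A\n",
              x$kind, x$site_a, x$site_b, x$occupancy, mean(x$distance)))
  invisible(x)
}

#' Salt-bridge scan over basic/acidic site pairs
#'
#' For every (basic, acidic) pair the per-frame distance between the sites is
#' compared to `d_max` (the coarse proxy for the basic-N to acidic-O contact
#' distance); pairs within the cutoff in at least `occupancy_min` of frames
#' are reported with their occupancy and mean distance.
#'
#' @param e an [ensemble()]
#' @param basic_labels,acidic_labels site labels (CA sites)
#' @param d_max contact cutoff, Angstrom (default 4.0)
#' @param occupancy_min minimum occupancy to report a pair (default 0.5)
#' @return list of `contact_record`s (kind `"SALT_BRIDGE"`) for reported
#'   pairs, plus attribute `all_pairs`: data frame of every scanned pair with
#'   occupancy and mean distance
#' @export
salt_bridge_scan <- function(e, basic_labels, acidic_labels, d_max = 4.0,
                             occupancy_min = 0.5) {
  if (!length(basic_labels) || !length(acidic_labels))
    stop("basic and acidic site sets must be non-empty")
  stopifnot(d_max > 0)
  bi <- vapply(basic_labels, site_index, 1L, sm = e$site_model)
  ai <- vapply(acidic_labels, site_index, 1L, sm = e$site_model)
  recs <- list(); rows <- list()
  for (b in seq_along(bi)) for (a in seq_along(ai)) {
    d <- sqrt(colSums((e$coords[bi[b], , ] - e$coords[ai[a], , ])^2))
    per <- d <= d_max
    rows[[length(rows) + 1L]] <- data.frame(
      basic = basic_labels[b], acidic = acidic_labels[a],
      occupancy = mean(per), mean_distance = mean(d))
    if (mean(per) >= occupancy_min)
      recs[[length(recs) + 1L]] <- contact_record(
        basic_labels[b], acidic_labels[a], "SALT_BRIDGE", per, d)
  }
  attr(recs, "all_pairs") <- do.call(rbind, rows)
  recs
}

#' Inter-selection distance series
#'
#' Per-frame distance between two site selections, either centroid-centroid
#' (`mode = "centroid"`, e.g. domain--subdomain separation) or the minimum
#' over all cross pairs (`mode = "min"`, e.g. closest approach of a residue
#' to DNA).
#' @param e an [ensemble()]
#' @param selection_a,selection_b selections (see [select_sites()])
#' @param mode `"centroid"` or `"min"`
#' @return a `descriptor_series` (name `"DISTANCE"`)
#' @export
distance_series <- function(e, selection_a, selection_b,
                            mode = c("centroid", "min")) {
  mode <- match.arg(mode)
  ia <- select_sites(e$site_model, selection_a)
  ib <- select_sites(e$site_model, selection_b)
  vals <- vapply(seq_len(n_frames(e)), function(i) {
    fc <- frame_coords(e, i)
    A <- fc[ia, , drop = FALSE]; B <- fc[ib, , drop = FALSE]
    if (mode == "centroid") {
      sqrt(sum((colMeans(A) - colMeans(B))^2))
    } else {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      sqrt(max(0, min(d2)))
    }
  }, 0)
  descriptor_series("DISTANCE", e, vals)
}

#' Centred moving average
#'
#' Window mean with centred windows that shrink symmetrically at the series
#' edges, so the output has the same length as the input.
#' @param x numeric series
#' @param bin_size window width (frames)
#' @return numeric vector, `length(x)`
#' @export
moving_average <- function(x, bin_size) {
  n <- length(x)
  stopifnot(bin_size >= 1)
  if (bin_size > n) stop("bin_size exceeds series length")
  half <- (bin_size - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, ceiling(i - half)); hi <- min(n, floor(i + half))
    mean(x[lo:hi])
  }, 0)
}
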