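#' Contact set of a structure
#'
#' Pairs of sites within `cutoff` of one another, the spring topology of the
#' anisotropic network model. Returned as a data frame of internal site
#' indices `a < b` with a per-contact `scale` multiplier on the spring
#' constant (1 by default).
#' @param coords n x 3 coordinates (Angstrom)
#' @param cutoff contact distance threshold, Angstrom (default 12)
#' @return data frame of class `contact_set`: columns `a`, `b`, `scale`
#' @export
contacts_from_coords <- function(coords, cutoff = 12) {
  coords <- as.matrix(coords)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") - 2 * tcrossprod(coords)
  hit <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
  out <- data.frame(a = hit[, 1], b = hit[, 2], scale = 1)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_set", "data.frame")
  out
}

as_contact_set <- function(df) {
  stopifnot(all(c("a", "b") %in% names(df)))
  if (is.null(df$scale)) df$scale <- 1
  swap <- df$a > df$b
  tmp <- df$a[swap]; df$a[swap] <- df$b[swap]; df$b[swap] <- tmp
  if (any(df$a == df$b)) stop("self-contacts are not allowed")
  df <- df[order(df$a, df$b), c("a", "b", "scale"), drop = FALSE]
  if (anyDuplicated(df[, c("a", "b")])) stop("duplicate contacts")
  rownames(df) <- NULL
  class(df) <- c("contact_set", "data.frame")
  df
}

#' Anisotropic network model
#'
#' Builds the 3N x 3N ANM Hessian over the given sites: each contact (i, j)
#' contributes the rank-1 block `-(gamma_ij / d^2) (d x d)` off the diagonal
#' (d the inter-site vector) and its negative to both diagonal blocks, so
#' every row-block sums to zero (translation invariance). The
#' eigendecomposition is attached; a connected contact graph has exactly six
#' zero modes (rigid translations and rotations).
#'
#' @param site_model the [site_model()]
#' @param coords n x 3 coordinates the springs are anchored at (default the
#'   site model's reference coordinates; pass an ensemble mean to build from
#'   a trajectory)
#' @param cutoff spring distance threshold, Angstrom (default 12); ignored
#'   when `contacts` is supplied
#' @param gamma uniform spring constant (default 1)
#' @param contacts optional explicit `contact_set` (e.g. a perturbed
#'   topology); per-contact `scale` multiplies `gamma`
#' @return object of class `anm_model`: `hessian`, `evalues` (ascending),
#'   `evectors`, `n_zero_modes`, `contacts`, `coords`, `site_model`,
#'   `cutoff`, `gamma`
#' @export
build_anm <- function(site_model, coords = NULL, cutoff = 12, gamma = 1,
                      contacts = NULL) {
  stopifnot(inherits(site_model, "site_model"))
  if (is.null(coords)) coords <- ref_coords(site_model)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("ANM needs at least 2 sites")
  if (is.null(contacts)) contacts <- contacts_from_coords(coords, cutoff)
  contacts <- as_contact_set(contacts)
  g <- igraph::graph_from_data_frame(contacts[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("contact graph is disconnected (", comp$no, " components); ",
         "component sizes: ", paste(comp$csize, collapse = ", "))
  H <- matrix(0, 3L * n, 3L * n)
  for (k in seq_len(nrow(contacts))) {
    i <- contacts$a[k]; j <- contacts$b[k]
    d <- coords[i, ] - coords[j, ]
    d2 <- sum(d^2)
    if (d2 < 1e-12) stop("contact sites ", i, " and ", j, " coincide")
    blk <- (gamma * contacts$scale[k] / d2) * tcrossprod(d)
    ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ev <- rev(eg$values); U <- eg$vectors[, rev(seq_len(3L * n)), drop = FALSE]
  nz <- sum(ev < 1e-8 * max(ev))
  structure(list(hessian = H, evalues = ev, evectors = U, n_zero_modes = nz,
                 contacts = contacts, coords = coords, site_model = site_model,
                 cutoff = cutoff, gamma = gamma),
            class = "anm_model")
}

#' @export
print.anm_model <- function(x, ...) {
  cat("anm_model:", nrow(x$coords), "sites,", nrow(x$contacts), "springs,",
      x$n_zero_modes, "zero modes\n")
  invisible(x)
}

#' Mode-restricted pseudo-inverse of the ANM Hessian
#'
#' `sum_k u_k u_k' / lambda_k` over the `n_modes` slowest non-zero modes
#' (ascending eigenvalue). With all non-zero modes included this is the
#' Moore--Penrose pseudo-inverse of H.
#' @param anm an `anm_model`
#' @param n_modes number of non-zero modes (default: all)
#' @return 3N x 3N matrix
#' @export
mode_restricted_inverse <- function(anm, n_modes = NULL) {
  stopifnot(inherits(anm, "anm_model"))
  nz <- anm$n_zero_modes
  avail <- length(anm$evalues) - nz
  if (is.null(n_modes)) n_modes <- avail
  if (n_modes < 1L) stop("n_modes must be at least 1")
  if (n_modes > avail) stop("only ", avail, " non-zero modes available")
  idx <- (nz + 1L):(nz + n_modes)
  U <- anm$evectors[, idx, drop = FALSE]
  U %*% (t(U) / anm$evalues[idx])
}

#' Analytic fluctuation covariance of an ANM
#'
#' `kT * pseudoinverse(H)` wrapped as a [covariance_model()], so DCCM, PCA
#' and LMI run on the analytic model exactly as on a sampled ensemble.
#' @param anm an `anm_model`
#' @param kT thermal energy scale (default 1)
#' @param n_modes modes retained (default all non-zero)
#' @export
anm_covariance <- function(anm, kT = 1, n_modes = NULL) {
  covariance_model(kT * mode_restricted_inverse(anm, n_modes),
                   anm$coords, anm$site_model)
}

#' Perturbation response scanning
#'
#' Site `i` is subjected in turn to the three Cartesian unit forces; the
#' linear response of site `j` is read off the mode-restricted inverse of the
#' Hessian (`dR = H^+ F`). Entry (i, j) of the map is the summed squared
#' displacement of `j` over the three forces, i.e. the squared Frobenius norm
#' of the (j, i) 3x3 block of `H^+`. With `normalize = TRUE` (default) each
#' row is divided by its self-response `S_ii`, making profiles comparable
#' across systems.
#'
#' @param anm an `anm_model`
#' @param n_modes non-zero modes used (default 20, capped at available)
#' @param normalize divide rows by the diagonal self-response
#' @return object of class `prs_map`: `matrix` (rows = perturbed site,
#'   columns = responding site), `effectiveness` (row means), `sensitivity`
#'   (column means), `n_modes`, `normalized`, `site_model`
#' @export
prs_scan <- function(anm, n_modes = 20L, normalize = TRUE) {
  stopifnot(inherits(anm, "anm_model"))
  avail <- length(anm$evalues) - anm$n_zero_modes
  n_modes <- min(n_modes, avail)
  Hinv <- mode_restricted_inverse(anm, n_modes)
  n <- nrow(anm$coords)
  G <- Hinv^2
  K <- kronecker(diag(n), rep(1, 3))      # 3N x N block indicator
  M <- crossprod(K, G) %*% K              # M[j, i] = Frobenius^2 of block (j, i)
  S <- t(M)                               # row = perturbed site i
  if (normalize) {
    if (any(diag(S) <= 0)) stop("zero self-response; cannot normalize")
    S <- S / diag(S)
  }
  lbl <- paste0(anm$site_model$role, ":", anm$site_model$label)
  dimnames(S) <- list(lbl, lbl)
  structure(list(matrix = S,
                 effectiveness = rowMeans(S), sensitivity = colMeans(S),
                 n_modes = n_modes, normalized = normalize,
                 site_model = anm$site_model),
            class = "prs_map")
}

#' @export
print.prs_map <- function(x, ...) {
  cat("prs_map:", nrow(x$matrix), "sites,", x$n_modes, "modes",
      if (x$normalized) "(row-normalized)" else "", "\n")
  invisible(x)
}

#' Effector / sensor profiles of a PRS map
#'
#' Effectiveness of site i = mean of row i (how strongly perturbing i moves
#' the rest of the structure); sensitivity of site j = mean of column j (how
#' strongly j responds to perturbations elsewhere).
#' @param prs a `prs_map`
#' @return data frame: `site`, `label`, `role`, `domain`, `effectiveness`,
#'   `sensitivity`
#' @export
effector_sensor_profiles <- function(prs) {
  stopifnot(inherits(prs, "prs_map"))
  sm <- prs$site_model
  data.frame(site = seq_len(nrow(sm)), label = sm$label, role = sm$role,
             domain = sm$domain,
             effectiveness = rowMeans(prs$matrix),
             sensitivity = colMeans(prs$matrix))
}

#' Difference of two PRS maps
#'
#' `map_a - map_b` elementwise, plus per-site effectiveness and sensitivity
#' deltas ranked by magnitude — the comparison that localises where a
#' perturbation rewires the response landscape.
#' @param map_a,map_b `prs_map`s over the same sites
#' @return list: `matrix` (difference), `profile_changes` (data frame with
#'   `label`, `role`, `domain`, `d_effectiveness`, `d_sensitivity`, ordered
#'   by decreasing `max(|d_eff|, |d_sens|)`)
#' @export
prs_difference <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "prs_map"), inherits(map_b, "prs_map"))
  if (!identical(dim(map_a$matrix), dim(map_b$matrix)))
    stop("PRS maps differ in shape")
  d <- map_a$matrix - map_b$matrix
  sm <- map_a$site_model
  pc <- data.frame(label = sm$label, role = sm$role, domain = sm$domain,
                   d_effectiveness = rowMeans(map_a$matrix) - rowMeans(map_b$matrix),
                   d_sensitivity = colMeans(map_a$matrix) - colMeans(map_b$matrix))
  pc <- pc[order(-pmax(abs(pc$d_effectiveness), abs(pc$d_sensitivity))), ]
  rownames(pc) <- NULL
  list(matrix = d, profile_changes = pc)
}
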