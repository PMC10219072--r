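#' Conformational ensemble over a site model
#'
#' Frames are stored as an `n_sites x 3 x n_frames` array of Angstrom
#' coordinates whose site ordering matches the `site_model` exactly.
#'
#' @param coords `n_sites x 3 x n_frames` array, or a list of `n_sites x 3`
#'   matrices (one per frame).
#' @param site_model the shared [site_model()]
#' @param times optional per-frame times (ps); default `0, 1, 2, ...`
#' @param aligned logical, whether frames have been superposed already
#' @return object of class `ensemble`
#' @export
ensemble <- function(coords, site_model, times = NULL, aligned = FALSE) {
  stopifnot(inherits(site_model, "site_model"))
  if (is.list(coords)) {
    n <- length(coords)
    if (n < 1L) stop("an ensemble needs at least one frame")
    coords <- array(unlist(lapply(coords, function(m) {
      m <- as.matrix(m)
      if (!identical(dim(m), c(nrow(site_model), 3L)))
        stop("frame dimensions do not match the site model")
      m
    })), dim = c(nrow(site_model), 3L, n))
  }
  d <- dim(coords)
  if (length(d) != 3L || d[1] != nrow(site_model) || d[2] != 3L)
    stop("coords must be n_sites x 3 x n_frames with n_sites matching the site model")
  if (d[3] < 1L) stop("an ensemble needs at least one frame")
  if (is.null(times)) times <- seq_len(d[3]) - 1
  stopifnot(length(times) == d[3])
  structure(list(coords = coords, times = as.numeric(times),
                 site_model = site_model, aligned = isTRUE(aligned)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", n_frames(x), "frames x", nrow(x$site_model), "sites",
      if (x$aligned) "(aligned)" else "(unaligned)", "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param e an `ensemble`
#' @export
n_frames <- function(e) dim(e$coords)[3]

#' Coordinates of one frame
#' @param e an `ensemble`
#' @param i frame index
#' @return `n_sites x 3` matrix
#' @export
frame_coords <- function(e, i) {
  if (i < 1L || i > n_frames(e)) stop("frame index out of range")
  e$coords[, , i, drop = TRUE]
}

# frames as an n_frames x 3N matrix (x1 y1 z1 x2 ...), the layout shared by
# the covariance, PCA and ANM stages
ensemble_xyz <- function(e, sel = NULL) {
  co <- e$coords
  if (!is.null(sel)) co <- co[sel, , , drop = FALSE]
  d <- dim(co)
  m <- matrix(aperm(co, c(2, 1, 3)), nrow = d[1] * 3L, ncol = d[3])
  t(m)
}

xyz_to_frames <- function(xyz) {
  # inverse of ensemble_xyz: n_frames x 3N -> n_sites x 3 x n_frames
  nf <- nrow(xyz); ns <- ncol(xyz) / 3L
  aperm(array(t(xyz), dim = c(3L, ns, nf)), c(2, 1, 3))
}

#' Restrict an ensemble to a selection of sites
#' @param e an `ensemble`
#' @param sel selection (see [select_sites()])
#' @export
subset_ensemble <- function(e, sel) {
  idx <- select_sites(e$site_model, sel)
  sm <- e$site_model[idx, , drop = FALSE]
  rownames(sm) <- NULL
  class(sm) <- c("site_model", "data.frame")
  ensemble(e$coords[idx, , , drop = FALSE], sm, times = e$times,
           aligned = e$aligned)
}
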