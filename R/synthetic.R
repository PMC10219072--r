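#' Specification of a synthetic coarse complex
#'
#' Defaults emulate the architecture of the DNA polymerase beta / gapped-DNA
#' coarse model: 326 protein C-alpha sites labelled 10..335 in four spatially
#' clustered domains (lyase 10-87, DNA-binding D 90-150, catalytic C 151-260,
#' nascent-pair-binding N 261-335; the two residues 88-89 link lyase to D),
#' plus a 28-site DNA phosphate chain at the D/C interface — 354 sites in
#' all. Closed-state geometry places the lyase site 44 near the N-subdomain
#' terminus (the locking-contact region) .
#'
#' @param n_protein_sites number of C-alpha sites (default 326)
#' @param n_dna_sites number of phosphate sites (default 28)
#' @param first_label label of the first protein residue (default 10)
#' @param domain_ranges protein domain ranges (default the polymerase-beta
#'   partition)
#' @param ca_bond,p_bond pseudo-chain bond lengths, Angstrom (defaults 3.8
#'   and 6.5)
#' @param kT thermal energy scale for ensemble sampling (default 1)
#' @param seed integer RNG seed
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_protein_sites = 326L, n_dna_sites = 28L,
                           first_label = 10L,
                           domain_ranges = default_domain_ranges(),
                           ca_bond = 3.8, p_bond = 6.5, kT = 1, seed = 1L) {
  stopifnot(n_protein_sites >= 1L, n_dna_sites >= 0L, ca_bond > 0, p_bond > 0,
            kT >= 0)
  validate_domain_ranges(domain_ranges)
  structure(list(n_protein_sites = as.integer(n_protein_sites),
                 n_dna_sites = as.integer(n_dna_sites),
                 first_label = as.integer(first_label),
                 domain_ranges = domain_ranges,
                 ca_bond = ca_bond, p_bond = p_bond, kT = kT,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# domain centroid targets (Angstrom): catalytic core central, D and N on
# opposite sides, lyase leaning towards the N-subdomain (closed state), DNA
# along the D/C interface
synthetic_domain_centers <- function() {
  list(LYASE = c(-16, 22, 2), D = c(24, 0, 0), C = c(0, 0, 0),
       N = c(-24, 0, 0), LINKER = c(6, 14, 1), DNA = c(14, -12, 8))
}

#' Generate a synthetic coarse reference structure
#'
#' Builds a seeded self-avoiding pseudo-chain: each C-alpha follows its
#' predecessor at the configured bond length, with steps biased towards the
#' centre of the domain the residue belongs to, so the four protein domains
#' form spatially clustered blobs with the closed-state arrangement described
#' in [synthetic_spec()]. The DNA phosphate chain runs along the D/C
#' interface and is held within contact range (10 A) of the protein surface,
#' as a bound ligand in the binding groove. Self-avoidance (minimum 3.0 A
#' between non-bonded sites) is enforced with bounded retries.
#'
#' @param spec a [synthetic_spec()]
#' @return a [site_model()] with 326 + 28 sites under the default spec
#' @export
make_reference <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  labels <- spec$first_label + seq_len(spec$n_protein_sites) - 1L
  centers <- synthetic_domain_centers()
  dom <- rep("LINKER", spec$n_protein_sites)
  for (dn in names(spec$domain_ranges)) {
    rg <- spec$domain_ranges[[dn]]
    dom[labels >= rg[1] & labels <= rg[2]] <- dn
  }
  ca <- grow_chain(spec$n_protein_sites, bond = spec$ca_bond,
                   targets = t(vapply(dom, function(d)
                     centers[[d]] %||% centers$LINKER, numeric(3))),
                   start = centers[[dom[1]]] %||% centers$LINKER,
                   existing = NULL, rng = rng)
  coords <- ca; role <- rep("CA", spec$n_protein_sites)
  lab <- labels
  if (spec$n_dna_sites > 0L) {
    dna_targets <- matrix(rep(centers$DNA, spec$n_dna_sites), ncol = 3,
                          byrow = TRUE)
    # drift the chain axis so the DNA is elongated, not a blob
    dna_targets[, 2] <- dna_targets[, 2] +
      seq(-spec$p_bond, spec$p_bond, length.out = spec$n_dna_sites) * 2
    # the DNA lies in the binding groove along the D/C interface: start the
    # chain just outside the closest protein site and keep every phosphate
    # within contact range (10 A) of the protein surface, so the bound
    # ligand is fully constrained by the complex rather than dangling free
    d2_center <- rowSums(sweep(ca, 2, centers$DNA)^2)
    ca_near <- ca[which.min(d2_center), ]
    away <- ca_near - colMeans(ca)
    away <- away / max(sqrt(sum(away^2)), 1e-9)
    p <- grow_chain(spec$n_dna_sites, bond = spec$p_bond,
                    targets = dna_targets, start = ca_near + 6 * away,
                    existing = ca, rng = rng,
                    surface = ca, max_surface_dist = 10)
    coords <- rbind(coords, p)
    role <- c(role, rep("P", spec$n_dna_sites))
    lab <- c(lab, seq_len(spec$n_dna_sites))
  }
  site_model(label = lab, role = role, coords = coords,
             domain_ranges = spec$domain_ranges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# biased self-avoiding random walk; error after bounded retries
grow_chain <- function(n, bond, targets, start, existing, rng,
                       min_sep = 3.0, max_retry = 200L,
                       surface = NULL, max_surface_dist = Inf) {
  near_surface <- function(cand)
    is.null(surface) ||
      min(rowSums(sweep(surface, 2, cand)^2)) <= max_surface_dist^2
  pts <- matrix(NA_real_, n, 3L)
  for (try in seq_len(max_retry)) {
    cand <- start + rng$rnorm(3) * 0.5
    if ((is.null(existing) ||
         min(rowSums(sweep(existing, 2, cand)^2)) >= min_sep^2) &&
        near_surface(cand)) {
      pts[1, ] <- cand
      break
    }
  }
  if (anyNA(pts[1, ]))
    stop("could not place site 1 after ", max_retry,
         " retries; geometry infeasible")
  all_prev <- function(k) rbind(existing, pts[seq_len(k - 1L), , drop = FALSE])
  for (k in seq(2L, length.out = n - 1L)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      to_center <- targets[k, ] - pts[k - 1L, ]
      nc <- sqrt(sum(to_center^2))
      dirv <- (if (nc > 1e-9) to_center / nc else c(0, 0, 0)) * 0.45 + rng$rnorm(3)
      dirv <- dirv / sqrt(sum(dirv^2))
      cand <- pts[k - 1L, ] + bond * dirv
      prev <- all_prev(k)
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      # the last previous point is the bonded predecessor; all other placed
      # sites must keep min_sep
      d2_nonbond <- d2[-length(d2)]
      if ((!length(d2_nonbond) || min(d2_nonbond) >= min_sep^2) &&
          near_surface(cand)) {
        pts[k, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place site ", k, " after ", max_retry,
           " retries; geometry infeasible")
  }
  pts
}

# seeded RNG that does not disturb the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    st
  }
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = function(n, ...) draw(stats::rnorm, n, ...),
       runif = function(n, ...) draw(stats::runif, n, ...),
       sample = function(x, ...) draw(base::sample, x, ...))
}

#' Perturbation of a contact topology
#'
#' Describes a local rewiring of the spring/contact network, e.g. a
#' phosphorylation that breaks the closed-state locking contact between the
#' lyase residue 44 and the N-subdomain terminus 335 and forms a new salt
#' bridge to residue 149 at the D/C linker (the default).
#' @param removed_contacts list of `c(label_a, label_b)` protein-residue
#'   pairs to delete
#' @param added_contacts list of pairs to insert
#' @param spring_scale spring-constant multiplier on added contacts
#'   (default 1)
#' @return list of class `perturbation_spec`
#' @export
perturbation_spec <- function(removed_contacts = list(c(44, 335)),
                              added_contacts = list(c(44, 149)),
                              spring_scale = 1) {
  stopifnot(spring_scale > 0)
  structure(list(removed_contacts = removed_contacts,
                 added_contacts = added_contacts,
                 spring_scale = spring_scale),
            class = "perturbation_spec")
}

#' Apply a perturbation to a contact set
#'
#' Returns a contact set differing from the input exactly by the listed
#' edits. Removing a contact that is not present is an error; adding one
#' that already exists only updates its spring scale.
#' @param contacts a `contact_set` (see [contacts_from_coords()])
#' @param pspec a [perturbation_spec()]
#' @param site_model the [site_model()] resolving residue labels to sites
#' @return the edited `contact_set`
#' @export
apply_perturbation <- function(contacts, pspec, site_model) {
  stopifnot(inherits(pspec, "perturbation_spec"))
  contacts <- as_contact_set(contacts)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(contacts$a, contacts$b)
  for (pr in pspec$removed_contacts) {
    i <- site_index(site_model, pr[1]); j <- site_index(site_model, pr[2])
    hit <- have == key(i, j)
    if (!any(hit))
      stop("cannot remove contact ", pr[1], "-", pr[2], ": not present")
    contacts <- contacts[!hit, , drop = FALSE]
    have <- have[!hit]
  }
  for (pr in pspec$added_contacts) {
    i <- site_index(site_model, pr[1]); j <- site_index(site_model, pr[2])
    hit <- have == key(i, j)
    if (any(hit)) {
      contacts$scale[hit] <- pspec$spring_scale
    } else {
      contacts <- rbind(contacts,
                        data.frame(a = min(i, j), b = max(i, j),
                                   scale = pspec$spring_scale))
      have <- c(have, key(i, j))
    }
  }
  as_contact_set(contacts)
}

#' Sample a Gaussian ensemble from an elastic network
#'
#' Frames are drawn i.i.d. from the zero-mean Gaussian over fluctuations
#' with covariance `kT * pseudoinverse(H)` (all non-zero modes), added to
#' the network's anchor coordinates — the equilibrium ensemble the ANM
#' implies. Sampling is done in mode space, so cost scales with the number
#' of modes retained.
#'
#' @param anm an `anm_model` (see [build_anm()])
#' @param n_frames frames to draw (>= 1)
#' @param kT thermal energy scale (default 1; 0 gives the rigid reference)
#' @param seed integer RNG seed
#' @param n_modes non-zero modes sampled (default all)
#' @return an [ensemble()], `aligned = TRUE` (frames share the anchor frame)
#' @export
sample_anm_ensemble <- function(anm, n_frames, kT = 1, seed = 1L,
                                n_modes = NULL) {
  stopifnot(inherits(anm, "anm_model"))
  if (n_frames < 1L) stop("n_frames must be at least 1")
  nz <- anm$n_zero_modes
  avail <- length(anm$evalues) - nz
  if (avail < 1L) stop("ANM has no non-zero modes")
  if (is.null(n_modes)) n_modes <- avail
  n_modes <- min(n_modes, avail)
  idx <- (nz + 1L):(nz + n_modes)
  rng <- local_rng(seed)
  ref <- as.vector(t(anm$coords))
  if (kT == 0) {
    xyz <- matrix(ref, nrow = n_frames, ncol = length(ref), byrow = TRUE)
  } else {
    Z <- matrix(rng$rnorm(n_frames * n_modes), n_frames, n_modes)
    amp <- sqrt(kT / anm$evalues[idx])
    xyz <- sweep(Z %*% t(anm$evectors[, idx, drop = FALSE] *
                           rep(amp, each = nrow(anm$evectors))), 2, ref, "+")
  }
  ensemble(xyz_to_frames(xyz), anm$site_model, aligned = TRUE)
}

#' Open-state reference by rigid hinge rotation
#'
#' Produces a second conformational basin from a closed reference by
#' swinging one domain (default the lyase) rigidly about a hinge (default
#' the lyase--D linker residues) so that its centroid rotates towards
#' (positive angle) or away from a target selection's centroid (default the
#' catalytic subdomain) — the twist-towards-the-catalytic-subdomain motion
#' of the closed-to-open transition.
#' @param sm closed-state [site_model()]
#' @param rotate_selection sites that move (default `"LYASE"`)
#' @param hinge_selection sites whose centroid is the pivot (default the
#'   linker residues `"88-90"`)
#' @param toward_selection sites whose centroid defines the swing target
#'   (default `"C"`)
#' @param angle_deg rotation magnitude in degrees (default 25)
#' @return n x 3 coordinate matrix of the open-state reference
#' @export
open_state_coords <- function(sm, rotate_selection = "LYASE",
                              hinge_selection = "88-90",
                              toward_selection = "C", angle_deg = 25) {
  co <- ref_coords(sm)
  mv <- select_sites(sm, rotate_selection)
  tg <- select_sites(sm, toward_selection)
  pivot <- colMeans(co[select_sites(sm, hinge_selection), , drop = FALSE])
  v1 <- colMeans(co[mv, , drop = FALSE]) - pivot
  v2 <- colMeans(co[tg, , drop = FALSE]) - pivot
  ax <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  na <- sqrt(sum(ax^2))
  if (na < 1e-9) stop("hinge, moving and target centroids are collinear")
  ax <- ax / na
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  co[mv, ] <- sweep(sweep(co[mv, , drop = FALSE], 2, pivot) %*% t(R), 2,
                    pivot, "+")
  co
}

#' Sample a two-basin mixture ensemble
#'
#' Each frame is drawn from basin k with probability `weights[k]`, then
#' isotropic Gaussian jitter of standard deviation `jitter` is added per
#' coordinate — the simplest ensemble with a closed/open two-state marginal
#' structure. Ground-truth basin assignments are recorded.
#'
#' @param references list of n x 3 coordinate matrices (one per basin),
#'   sharing the site model's dimensions
#' @param site_model the shared [site_model()]
#' @param weights positive basin probabilities, summing to 1
#' @param jitter per-coordinate Gaussian s.d., Angstrom
#' @param n_frames frames to draw
#' @param seed integer RNG seed
#' @return an [ensemble()] with attribute `basin` (integer ground truth per
#'   frame)
#' @export
sample_two_state <- function(references, site_model, weights = c(0.8, 0.2),
                             jitter = 0.3, n_frames = 1000L, seed = 1L) {
  stopifnot(length(references) == length(weights), all(weights > 0),
            abs(sum(weights) - 1) < 1e-9, jitter >= 0, n_frames >= 1L)
  refs <- lapply(references, function(r) {
    r <- as.matrix(r)
    if (!identical(dim(r), c(nrow(site_model), 3L)))
      stop("basin reference dimensions do not match the site model")
    r
  })
  rng <- local_rng(seed)
  basin <- rng$sample(seq_along(refs), size = n_frames, replace = TRUE,
                      prob = weights)
  n <- nrow(site_model)
  co <- array(0, dim = c(n, 3L, n_frames))
  for (i in seq_len(n_frames)) {
    noise <- if (jitter > 0) matrix(rng$rnorm(3L * n, sd = jitter), n, 3L) else 0
    co[, , i] <- refs[[basin[i]]] + noise
  }
  e <- ensemble(co, site_model, aligned = TRUE)
  attr(e, "basin") <- basin
  e
}

#' Sample a two-basin mixture with elastic-network fluctuations
#'
#' Like [sample_two_state()], but within-basin fluctuations are drawn from
#' the Gaussian implied by an ANM (`kT * pseudoinverse(H)`) instead of
#' isotropic jitter: each frame picks basin k with probability `weights[k]`
#' and adds an elastic-network fluctuation about that basin's reference.
#' This is the generative model of an unlocked system exchanging between a
#' closed and an open conformation while retaining its internal collective
#' dynamics.
#' @param anm an `anm_model` supplying the within-basin covariance
#' @param references list of n x 3 basin reference coordinate matrices
#' @param weights positive basin probabilities, summing to 1
#' @param n_frames frames to draw
#' @param kT thermal energy scale
#' @param seed integer RNG seed
#' @return an [ensemble()] with attribute `basin`
#' @export
sample_two_state_anm <- function(anm, references, weights = c(0.5, 0.5),
                                 n_frames = 1000L, kT = 1, seed = 1L) {
  stopifnot(inherits(anm, "anm_model"),
            length(references) == length(weights), all(weights > 0),
            abs(sum(weights) - 1) < 1e-9, n_frames >= 1L)
  fl <- sample_anm_ensemble(anm, n_frames, kT = kT, seed = seed)
  rng <- local_rng(seed + 1L)
  basin <- rng$sample(seq_along(references), size = n_frames, replace = TRUE,
                      prob = weights)
  co <- fl$coords
  anchor <- anm$coords
  for (i in seq_len(n_frames))
    co[, , i] <- co[, , i] - anchor + as.matrix(references[[basin[i]]])
  e <- ensemble(co, anm$site_model, aligned = TRUE)
  attr(e, "basin") <- basin
  e
}

#' Scripted hydrogen-bond trace
#'
#' A three-site (donor, hydrogen, acceptor) ensemble in which exactly
#' `round(occupancy * n_frames)` frames adopt a bonded geometry and the rest
#' a broken one, in seeded random order — ground truth for occupancy
#' estimators.
#' @param n_frames total frames
#' @param occupancy target bonded fraction in `[0, 1]`
#' @param geometry_in,geometry_out 3 x 3 matrices (rows donor, hydrogen,
#'   acceptor) that must satisfy / violate `criterion` respectively
#' @param seed integer RNG seed
#' @param criterion an [hbond_criterion()]
#' @return an [ensemble()] over pseudo-sites labelled 1 (donor), 2
#'   (hydrogen), 3 (acceptor), with attribute `bonded` (logical ground
#'   truth)
#' @export
script_hbond_trace <- function(n_frames, occupancy,
                               geometry_in = rbind(c(0, 0, 0), c(1, 0, 0),
                                                   c(3.2, 0.4, 0)),
                               geometry_out = rbind(c(0, 0, 0), c(1, 0, 0),
                                                    c(4.5, 0, 0)),
                               seed = 1L, criterion = hbond_criterion()) {
  stopifnot(n_frames >= 1L, occupancy >= 0, occupancy <= 1)
  gin <- as.matrix(geometry_in); gout <- as.matrix(geometry_out)
  if (!detect_hbond(gin[1, ], gin[2, ], gin[3, ], criterion))
    stop("geometry_in does not satisfy the H-bond criterion")
  if (detect_hbond(gout[1, ], gout[2, ], gout[3, ], criterion))
    stop("geometry_out satisfies the H-bond criterion")
  n_on <- round(occupancy * n_frames)
  rng <- local_rng(seed)
  bonded <- rep(FALSE, n_frames)
  if (n_on > 0) bonded[rng$sample(n_frames, size = n_on)] <- TRUE
  sm <- site_model(label = 1:3, role = rep("CA", 3), coords = gin,
                   domain_ranges = list())
  co <- array(0, dim = c(3L, 3L, n_frames))
  for (i in seq_len(n_frames)) co[, , i] <- if (bonded[i]) gin else gout
  e <- ensemble(co, sm, aligned = TRUE)
  attr(e, "bonded") <- bonded
  e
}
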