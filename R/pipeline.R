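#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the standard
#' analysis conventions used throughout the package: 3.5 A / 30 degree
#' H-bond criterion, 12 A ANM spring cutoff, 20 PRS modes, 30 x 30
#' free-energy bins, 15 A porcupine arrow cutoff, +-0.1 betweenness-change
#' flag, 500-frame moving-average bin. Round-trips through
#' [write_config()] / [read_config()].
#'
#' @param seed master RNG seed; every stochastic stage derives its seed
#'   from it
#' @param n_frames frames sampled per system
#' @param kT thermal energy scale of the synthetic ensembles; the default
#'   0.05 puts per-site RMSF in the 1-2 Angstrom range typical of folded
#'   complexes, so conformational transitions dominate thermal jitter
#' @param fel_depth_threshold,fel_merge_barrier basin detection on the
#'   PC1/PC2 free-energy landscape (kT units): minima deeper than the
#'   threshold found basins, ripples shallower than the barrier are merged
#' @param anm_cutoff spring distance threshold, Angstrom
#' @param n_modes PRS modes
#' @param hbond_d_max,hbond_angle_max H-bond criterion
#' @param salt_bridge_d_max,salt_bridge_occupancy_min salt-bridge scan
#' @param fel_bins free-energy-landscape bins per axis
#' @param porcupine_min_length arrow suppression cutoff, Angstrom
#' @param dbc_flag_threshold betweenness-change flag magnitude
#' @param moving_average_bin bin size for smoothed distance traces
#' @param open_angle_deg lyase rotation of the synthetic open state, degrees
#' @param open_weight population of the open basin in the perturbed system
#'   (the wild type stays locked in the closed basin)
#' @return named list of class `run_config`
#' @export
run_config <- function(seed = 1L, n_frames = 2000L, kT = 0.05,
                       anm_cutoff = 12, n_modes = 20L,
                       hbond_d_max = 3.5, hbond_angle_max = 30,
                       salt_bridge_d_max = 4.0, salt_bridge_occupancy_min = 0.5,
                       fel_bins = 30L, fel_depth_threshold = 2,
                       fel_merge_barrier = 1, porcupine_min_length = 15,
                       dbc_flag_threshold = 0.1, moving_average_bin = 500L,
                       open_angle_deg = 25, open_weight = 0.4) {
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 kT = kT, anm_cutoff = anm_cutoff,
                 n_modes = as.integer(n_modes),
                 hbond_d_max = hbond_d_max, hbond_angle_max = hbond_angle_max,
                 salt_bridge_d_max = salt_bridge_d_max,
                 salt_bridge_occupancy_min = salt_bridge_occupancy_min,
                 fel_bins = as.integer(fel_bins),
                 fel_depth_threshold = fel_depth_threshold,
                 fel_merge_barrier = fel_merge_barrier,
                 porcupine_min_length = porcupine_min_length,
                 dbc_flag_threshold = dbc_flag_threshold,
                 moving_average_bin = as.integer(moving_average_bin),
                 open_angle_deg = open_angle_deg,
                 open_weight = open_weight),
            class = c("run_config", "list"))
}

#' Mean and standard deviation of a descriptor series
#'
#' Population (divisor n) standard deviation, formatted `"mean (sd)"`.
#' @param x numeric series or a `descriptor_series`
#' @param digits digits in the formatted string (default 2)
#' @return list: `mean`, `sd`, `formatted`
#' @export
summarize_series <- function(x, digits = 2) {
  if (inherits(x, "descriptor_series")) x <- x$value
  if (!length(x)) stop("empty series")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  list(mean = m, sd = s,
       formatted = sprintf(paste0("%.", digits, "f (%.", digits, "f)"), m, s))
}

# derived per-stage seeds, kept well inside 32-bit integer range
stage_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

#' Run the full wild-type vs perturbed comparison pipeline
#'
#' Builds the synthetic coarse complex, derives the closed-state (wild-type)
#' and perturbed spring topologies (the default perturbation removes the
#' lyase--N locking contact 44-335 and adds the 44-149 salt-bridge contact),
#' samples an elastic-network ensemble for each system, and runs every
#' analysis stage: structural descriptors, cross-correlation maps and their
#' difference, essential-dynamics PCA with cosine content and PC1/PC2
#' free-energy landscapes, perturbation response scanning, and LMI residue
#' networks with betweenness-centrality differencing. All artifacts are
#' written as TSV under `out_dir` together with a manifest; every stage is
#' seeded from `config$seed`, so a rerun is bit-identical.
#'
#' @param config a [run_config()]
#' @param spec a [synthetic_spec()] describing the complex (its `seed` is
#'   overridden by `config$seed`)
#' @param pspec the [perturbation_spec()] applied to the perturbed system
#' @param out_dir output directory (created); `NULL` skips file output
#' @return a `comparison_report` list (see Details) with components
#'   `summaries`, `rmsf`, `dccm_difference`, `pca`, `fel_basins`,
#'   `prs_difference`, `bc`, `flagged_sites`, `site_model`, `config`,
#'   `manifest`
#' @export
run_pipeline <- function(config = run_config(), spec = synthetic_spec(),
                         pspec = perturbation_spec(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  spec$seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list()
  emit_matrix <- function(m, file) {
    if (!is.null(out_dir)) {
      write_matrix(m, file.path(out_dir, file))
      manifest[[length(manifest) + 1L]] <<- file
    }
  }
  emit_table <- function(d, file) {
    if (!is.null(out_dir)) {
      write_table(d, file.path(out_dir, file))
      manifest[[length(manifest) + 1L]] <<- file
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## -- synthetic systems -------------------------------------------------
  sm <- stage("reference", make_reference(spec))
  ref <- ref_coords(sm)
  contacts_geo <- stage("contacts", contacts_from_coords(ref, config$anm_cutoff))
  # the closed state is defined by the locking contact between the lyase
  # residue 44 and the N-terminus residue 335; assert it into the wild-type
  # topology, then let the perturbation rewire it
  lock <- perturbation_spec(removed_contacts = list(),
                            added_contacts = list(c(44, 335)))
  contacts_wt <- stage("contacts", apply_perturbation(contacts_geo, lock, sm))
  contacts_ph <- stage("contacts", apply_perturbation(contacts_wt, pspec, sm))

  anm_wt <- stage("anm", build_anm(sm, ref, contacts = contacts_wt,
                                   gamma = 1, cutoff = config$anm_cutoff))
  anm_ph <- stage("anm", build_anm(sm, ref, contacts = contacts_ph,
                                   gamma = 1, cutoff = config$anm_cutoff))
  # the wild type stays locked in the closed basin; losing the lock lets the
  # perturbed system exchange between the closed and open (lyase rotated
  # towards the catalytic subdomain) conformations
  ens_wt <- stage("sampling", sample_anm_ensemble(
    anm_wt, config$n_frames, kT = config$kT, seed = stage_seed(config$seed, 1L)))
  open_ref <- stage("sampling", open_state_coords(
    sm, angle_deg = config$open_angle_deg))
  ens_ph <- stage("sampling", sample_two_state_anm(
    anm_ph, list(ref, open_ref),
    weights = c(1 - config$open_weight, config$open_weight),
    n_frames = config$n_frames, kT = config$kT,
    seed = stage_seed(config$seed, 2L)))

  ## -- structural descriptors -------------------------------------------
  systems <- list(wt = ens_wt, phos = ens_ph)
  summaries <- list()
  rmsf_tabs <- list()
  for (nm in names(systems)) {
    e <- systems[[nm]]
    rs <- stage("descriptors", rmsd_series(e, "CA", reference = ref))
    rg <- stage("descriptors", rg_series(e, "CA"))
    dist_lc <- stage("descriptors",
                     distance_series(e, "LYASE", "C", mode = "centroid"))
    smooth <- moving_average(dist_lc$value,
                             min(config$moving_average_bin, n_frames(e)))
    # residue-pair traces of the rewired contacts (locking bond vs new bridge)
    d_44_335 <- stage("descriptors", distance_series(e, "44", "335"))
    d_44_149 <- stage("descriptors", distance_series(e, "44", "149"))
    rmsf_tabs[[nm]] <- stage("descriptors", rmsf(e, "all", align_first = FALSE))
    summaries[[nm]] <- list(rmsd = summarize_series(rs),
                            rg = summarize_series(rg),
                            lyase_c_distance = summarize_series(dist_lc))
    emit_table(data.frame(frame = rs$frame, rmsd = rs$value, rg = rg$value,
                          lyase_c_distance = dist_lc$value,
                          lyase_c_distance_smooth = smooth,
                          d_44_335 = d_44_335$value, d_44_149 = d_44_149$value),
               paste0("series_", nm, ".tsv"))
    emit_table(rmsf_tabs[[nm]], paste0("rmsf_", nm, ".tsv"))
  }

  ## -- essential dynamics ------------------------------------------------
  cov_wt <- stage("covariance", covariance(ens_wt, align = FALSE))
  cov_ph <- stage("covariance", covariance(ens_ph, align = FALSE))
  dccm_wt <- stage("dccm", dccm(cov_wt))
  dccm_ph <- stage("dccm", dccm(cov_ph))
  ddccm <- stage("dccm", map_difference(dccm_ph, dccm_wt))
  emit_matrix(dccm_wt$matrix, "dccm_wt.tsv")
  emit_matrix(dccm_ph$matrix, "dccm_phos.tsv")
  emit_matrix(ddccm, "dccm_difference.tsv")

  pca_tabs <- list(wt = pca(cov_wt, config$n_modes),
                   phos = pca(cov_ph, config$n_modes))
  fel_basins <- list(); proj_info <- list()
  for (nm in names(systems)) {
    cv <- if (nm == "wt") cov_wt else cov_ph
    p1 <- stage("pca", project(systems[[nm]], cv, 1L, align = FALSE))
    p2 <- stage("pca", project(systems[[nm]], cv, 2L, align = FALSE))
    fel <- stage("fel", free_energy_landscape(p1$values, p2$values,
                                              n_bins = config$fel_bins,
                                              kT = 1))
    fel_basins[[nm]] <- stage("fel", detect_basins(
      fel, depth_threshold = config$fel_depth_threshold,
      merge_barrier = config$fel_merge_barrier))
    proj_info[[nm]] <- list(pc1_cosine = p1$cosine_content,
                            pc2_cosine = p2$cosine_content,
                            pc1_fraction = p1$variance_fraction,
                            pc2_fraction = p2$variance_fraction)
    emit_matrix(fel$free_energy, paste0("fel_", nm, ".tsv"))
    emit_table(pca_tabs[[nm]], paste0("pca_", nm, ".tsv"))
    arrows <- porcupine_vectors(cv, 1L,
                                scale = 30 / max(sqrt(rowSums(matrix(
                                  cv$evectors[, 1], ncol = 3, byrow = TRUE)^2))),
                                min_length = config$porcupine_min_length)
    emit_table(arrows, paste0("porcupine_", nm, ".tsv"))
  }

  ## -- perturbation response scanning -------------------------------------
  prs_wt <- stage("prs", prs_scan(anm_wt, n_modes = config$n_modes))
  prs_ph <- stage("prs", prs_scan(anm_ph, n_modes = config$n_modes))
  dprs <- stage("prs", prs_difference(prs_ph, prs_wt))
  emit_matrix(prs_wt$matrix, "prs_wt.tsv")
  emit_matrix(prs_ph$matrix, "prs_phos.tsv")
  emit_table(dprs$profile_changes, "prs_profile_changes.tsv")

  ## -- residue networks ----------------------------------------------------
  lmi_wt <- stage("lmi", lmi_matrix(cov_wt))
  lmi_ph <- stage("lmi", lmi_matrix(cov_ph))
  net_wt <- stage("network", build_network(lmi_wt, contacts = contacts_wt))
  net_ph <- stage("network", build_network(lmi_ph, contacts = contacts_ph))
  bc <- stage("network", bc_difference(net_ph, net_wt,
                                       flag_threshold = config$dbc_flag_threshold))
  emit_table(bc, "bc_difference.tsv")

  report <- structure(list(
    summaries = summaries,
    rmsf = rmsf_tabs,
    dccm_difference = ddccm,
    pca = pca_tabs,
    projections = proj_info,
    fel_basins = fel_basins,
    prs_difference = dprs,
    bc = bc,
    flagged_sites = bc[bc$flagged, , drop = FALSE],
    site_model = sm,
    config = config,
    manifest = unlist(manifest)), class = "comparison_report")
  if (!is.null(out_dir)) {
    write_config(config, file.path(out_dir, "config.txt"))
    writeLines(c("file", report$manifest), file.path(out_dir, "manifest.txt"))
  }
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (wild-type vs perturbed)\n")
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-5s RMSD %s A  Rg %s A  lyase-C distance %s A\n", nm,
                s$rmsd$formatted, s$rg$formatted,
                s$lyase_c_distance$formatted))
  }
  cat(sprintf("  PC1 variance fraction: wt %.3f, perturbed %.3f\n",
              x$projections$wt$pc1_fraction, x$projections$phos$pc1_fraction))
  cat(sprintf("  FEL basins: wt %d, perturbed %d\n",
              nrow(x$fel_basins$wt), nrow(x$fel_basins$phos)))
  cat(sprintf("  betweenness-change flags (|delta| > %.2f): %d site(s)\n",
              x$config$dbc_flag_threshold, nrow(x$flagged_sites)))
  if (nrow(x$flagged_sites))
    cat("   ", paste(sprintf("%s:%d (%s)", x$flagged_sites$role,
                             x$flagged_sites$label, x$flagged_sites$domain),
                     collapse = ", "), "\n")
  invisible(x)
}
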