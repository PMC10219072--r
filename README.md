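# allodyn

Allosteric dynamics analysis of coarse-grained conformational ensembles.

## The scientific problem

A single post-translational modification — one phosphate on one residue —
can inactivate a multi-domain enzyme without changing its fold. A common
mechanistic explanation is allosteric: the modification breaks a specific
inter-domain contact, which unlocks a hinge motion of one domain, shifts
the population balance between closed and open conformations, and reroutes
the pathways of correlated motion through different residues.

`allodyn` implements the full ensemble-comparison toolchain needed to test
that hypothesis on coarse-grained (one site per residue / nucleotide)
conformational ensembles:

- **Structural descriptors** — Kabsch superposition and RMSD, radius of
  gyration, inter-domain distances, per-site RMSF, geometric hydrogen-bond
  and salt-bridge occupancy (`superpose`, `rmsd_series`, `rmsf`,
  `hbond_occupancy`, `salt_bridge_scan`).
- **Correlated motions** — dynamic cross-correlation maps and their
  between-condition differences (`dccm`, `map_difference`).
- **Essential dynamics** — PCA of aligned fluctuations, cosine-content
  convergence diagnostics, porcupine models of the dominant mode, and
  free-energy landscapes over (PC1, PC2) with watershed basin detection
  (`pca`, `project`, `cosine_content`, `free_energy_landscape`,
  `detect_basins`, `porcupine_vectors`).
- **Elastic-network mechanics** — anisotropic network models from contact
  topology, mode-restricted covariances, and perturbation response
  scanning (`build_anm`, `mode_restricted_inverse`, `prs_scan`,
  `prs_difference`).
- **Communication networks** — linear-mutual-information generalized
  correlations, weighted residue graphs, and betweenness-centrality
  differencing that flags rerouted sites (`lmi_matrix`, `build_network`,
  `betweenness_centrality`, `bc_difference`).
- **Synthetic ensembles with recorded ground truth** — a seeded generator
  for a 354-site protein–DNA complex (326 C-alpha + 28 phosphate), ANM
  Gaussian samples, two-basin closed/open mixtures, and scripted
  hydrogen-bond traces whose true states are stored as attributes
  (`make_reference`, `sample_anm_ensemble`, `sample_two_state_anm`,
  `script_hbond_trace`).
- **A pipeline** that runs the paired wild-type vs perturbed comparison
  end to end and writes all tables to disk (`run_pipeline`, plus a thin
  command-line interface in `inst/cli/allodyn.R`).

The methods vignette (`vignettes/ensemble-comparison-methods.Rmd`)
documents the model, every default parameter with units, and the
numerical choices.

## Worked example

The default study system is a synthetic polymerase-like complex. The
wild type carries a long-range 44–335 "lock" contact between the lyase
and C-terminal domains; the perturbed condition removes that lock and
adds a 44–149 contact instead, and its ensemble mixes a closed and an
open (lyase hinge swung 25°) basin.

```r
library(allodyn)

sm <- make_reference(synthetic_spec(seed = 1))
sm
#> site_model: 354 sites ( 326 CA, 28 P )
#> domains: C=110 D=61 DNA=28 LINKER=2 LYASE=78 N=75

report <- run_pipeline(run_config(seed = 1, n_frames = 2000),
                       out_dir = "run1")
report
#> comparison_report (wild-type vs perturbed)
#>   wt    RMSD 1.05 (0.54) A  Rg 23.28 (0.35) A  lyase-C distance 32.40 (2.17) A
#>   phos  RMSD 1.72 (1.25) A  Rg 22.86 (0.52) A  lyase-C distance 29.83 (3.23) A
#>   PC1 variance fraction: wt 0.787, perturbed 0.885
#>   FEL basins: wt 1, perturbed 2
#>   betweenness-change flags (|delta| > 0.10): 2 site(s)
#>     CA:44 (LYASE), CA:149 (D)

report$flagged_sites
#>     site label role domain      bc_a         bc_b  delta_bc flagged
#> 35    35    44   CA  LYASE 0.1279777 0.0006277363 0.1273500    TRUE
#> 140  140   149   CA      D 0.1271890 0.0004023951 0.1267866    TRUE
```

The pipeline recovers the designed mechanism: the perturbation doubles
the mobility of the lyase domain, pulls it ~2.5 Å closer to the
catalytic core, splits the free-energy landscape into two basins, and
reroutes network communication exactly through the two endpoints of the
rewired contact (C-alpha 44 and 149). All per-frame series, matrices,
PCA/FEL tables, PRS maps and the betweenness difference are written as
TSV files under `out_dir` (see `manifest.txt` there).

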