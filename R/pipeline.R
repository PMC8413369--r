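# End-to-end phantom experiment: simulate tractograms and two-run task BOLD,
# build voxel-wise priors, then run both analysis arms per subject and run —
# the functionnectome arm (projection, no smoothing) and the classical arm
# (Gaussian smoothing of the raw BOLD) — each through the same first-level
# OLS and group one-sample t.  This is the scaled-down analogue of a
# whole-cohort task-fMRI study and the basis of the package's headline
# checks: circuit detection, the coincidence penalty, and run-to-run
# reproducibility.

#' Run the two-arm phantom experiment
#'
#' @param cfg a [sim_config()]; its amplitudes, noise and seed define the
#'   experiment.
#' @param onsets block paradigm, default [default_onsets()].
#' @param smooth_fwhm smoothing applied to the classical arm only (mm);
#'   the functionnectome arm is never smoothed.
#' @param runs which runs to analyse (`1`, `2` or `c(1, 2)`).
#' @param keep_first_level return the per-subject stat maps too.
#' @return list with the phantom (`phantom`), the priors store (`priors`),
#'   and per arm/run group `stat_map`s in `group`, a nested list
#'   `group[[arm]][[run]]` with arms `"fn"` (functionnectome) and `"classic"`.
#' @export
run_phantom_experiment <- function(cfg = sim_config(),
                                   onsets = default_onsets(cfg$n_frames,
                                                           cfg$tr),
                                   smooth_fwhm = 4,
                                   runs = c(1, 2),
                                   keep_first_level = FALSE) {
  ph <- make_phantom(cfg)
  sl <- simulate_streamlines(ph, cfg)
  priors <- build_priors(sl, ph$gm_mask)
  design <- make_design(onsets, cfg$n_frames, cfg$tr)
  full_mask <- brain_mask(ph$grid, array(TRUE, ph$grid$shape))
  firsts <- list(fn = list(), classic = list())
  for (r in runs) firsts$fn[[r]] <- firsts$classic[[r]] <- vector("list",
                                                                  cfg$n_subjects)
  for (sub in seq_len(cfg$n_subjects)) {
    for (r in runs) {
      bold <- simulate_bold_run(ph, cfg, onsets, sub, as.integer(r))
      proj <- project_voxelwise(bold, ph$gm_mask, priors)
      firsts$fn[[r]][[sub]] <- fit_first_level(proj$volume, design, full_mask)
      smoothed <- smooth_volume(bold, smooth_fwhm)
      firsts$classic[[r]][[sub]] <- fit_first_level(smoothed, design,
                                                    full_mask)
    }
  }
  group <- lapply(firsts, function(arm) {
    out <- list()
    for (r in runs) out[[r]] <- fit_group(arm[[r]])
    out
  })
  res <- list(phantom = ph, priors = priors, design = design, group = group)
  if (keep_first_level) res$first_level <- firsts
  res
}

#' Summarise tract-level evidence of a group z-map
#'
#' Compares the z statistics on the phantom tract with those of the
#' remaining white-matter voxels: the tract mean and median z, and the 95th
#' percentile of z over non-tract white matter (the null reference used by
#' the circuit-detection check).
#'
#' @param zmap a group `stat_map`.
#' @param ph the phantom the experiment ran on.
#' @return list with `tract_mean_z`, `tract_median_z`, `wm_q95_z` and the
#'   voxel counts.
#' @export
tract_summary <- function(zmap, ph) {
  stopifnot(inherits(zmap, "stat_map"), inherits(ph, "phantom"))
  stop_unless_same_grid(zmap, ph$wm_mask, "z-map and phantom")
  tract_lin <- ijk_to_linear(ph$tract, ph$grid$shape)
  wm_lin <- setdiff(which(ph$wm_mask$data), tract_lin)
  z_tract <- zmap$z[tract_lin]
  z_wm <- zmap$z[wm_lin]
  list(tract_mean_z = mean(z_tract),
       tract_median_z = median(z_tract),
       wm_q95_z = unname(quantile(z_wm, 0.95)),
       n_tract = length(tract_lin), n_wm = length(wm_lin))
}
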