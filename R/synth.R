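# Synthetic phantom: a toy brain on a small isotropic grid with two
# grey-matter endpoint regions (A, B) joined by a white-matter tract, a
# control region (C) attached to a distractor bundle, jittered polyline
# streamlines per pseudo-subject, and block-design BOLD (boxcar * HRF plus
# white Gaussian noise) with known activation amplitudes.  Every module of
# the pipeline is testable against this ground truth without any download.

#' Simulation configuration for the synthetic phantom
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: a 20x20x20 grid of 2 mm voxels, 10 pseudo-subjects, 200
#' frames at TR 1 s, 1% signal change in both endpoint regions over a
#' baseline of 100, 1% Gaussian noise, and 1 mm streamline jitter (half a
#' voxel).
#'
#' @param n_subjects number of pseudo-subjects (>= 1).
#' @param n_frames frames per run.
#' @param tr repetition time (s).
#' @param amp_A,amp_B,amp_C activation amplitude of each region in baseline
#'   units (baseline 100, so 1 equals a 1% signal change).
#' @param noise_sd additive Gaussian noise standard deviation, baseline
#'   units.
#' @param streamline_jitter positional jitter of streamline points (mm, sd).
#' @param seed base random seed; every stochastic step derives its own
#'   stream from it.
#' @param n_streamlines bundle streamlines per subject (A to B).
#' @param n_distractors distractor streamlines per subject (avoiding the
#'   tract; half attach to region C).
#' @param grid_shape,voxel_size phantom grid geometry.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10, n_frames = 200, tr = 1,
                       amp_A = 1, amp_B = 1, amp_C = 0,
                       noise_sd = 1, streamline_jitter = 1, seed = 42,
                       n_streamlines = 20, n_distractors = 10,
                       grid_shape = c(20, 20, 20), voxel_size = 2) {
  stopifnot(n_subjects >= 1, n_frames >= 1, tr > 0, noise_sd >= 0,
            streamline_jitter >= 0, n_streamlines >= 1,
            all(grid_shape >= 16), voxel_size > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d subjects, %d frames @ TR %.3g s, ",
                     "amp A/B/C %.3g/%.3g/%.3g, noise sd %.3g, ",
                     "jitter %.3g mm, seed %d\n"),
              x$n_subjects, x$n_frames, x$tr, x$amp_A, x$amp_B, x$amp_C,
              x$noise_sd, x$streamline_jitter, x$seed))
  invisible(x)
}

block_of <- function(center, half, shape) {
  rng <- lapply(1:3, function(a)
    max(0L, center[a] - half):min(shape[a] - 1L, center[a] + half))
  as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
}

#' Build the deterministic phantom geometry
#'
#' Region centers are placed at fixed fractions of the grid extent, so
#' region and tract voxel counts scale with the configured shape.  Regions A
#' and B sit on the mid-axial line and are joined by a straight
#' single-voxel-wide tract; region C sits off-axis and anchors the
#' distractor bundle.  The white-matter mask is a slab containing the tract
#' (and distractor paths) but no grey matter.
#'
#' @param cfg a [sim_config()].
#' @return object of class `phantom`: fields `grid`, `gm_regions` (named
#'   0-based index matrices A/B/C), `tract` (ordered voxel path), `wm_mask`,
#'   `gm_mask`, `parc` (labels A=1, B=2, C=3) and `anchors` (the region
#'   voxels adjacent to the bundle paths).
#' @export
make_phantom <- function(cfg = sim_config()) {
  s <- cfg$grid_shape
  aff <- diag(c(rep(cfg$voxel_size, 3), 1))
  grid <- voxel_grid(s, aff)
  half <- max(1L, round(min(s) / 20))
  cx <- round(0.5 * (s[1] - 1)); cy <- round(0.5 * (s[2] - 1))
  cz <- round(0.5 * (s[3] - 1))
  ax <- round(0.2 * (s[1] - 1)); bx <- round(0.8 * (s[1] - 1))
  jc <- round(0.2 * (s[2] - 1))
  A <- block_of(c(ax, cy, cz), half, s)
  B <- block_of(c(bx, cy, cz), half, s)
  C <- block_of(c(cx, jc, cz), half, s)
  tract <- cbind(i = (ax + half + 1L):(bx - half - 1L), j = cy, k = cz)
  wm_rng <- list((ax - 2L):(bx + 2L), (jc + 1L):(cy + 4L),
                 (cz - 2L):(cz + 2L))
  wm <- as.matrix(expand.grid(i = wm_rng[[1]], j = wm_rng[[2]],
                              k = wm_rng[[3]]))
  gm <- rbind(A, B, C)
  gm_lin <- ijk_to_linear(gm, s)
  wm <- wm[!(ijk_to_linear(wm, s) %in% gm_lin), , drop = FALSE]
  labels <- array(0L, s)
  labels[ijk_to_linear(A, s)] <- 1L
  labels[ijk_to_linear(B, s)] <- 2L
  labels[ijk_to_linear(C, s)] <- 3L
  structure(list(
    grid = grid,
    gm_regions = list(A = A, B = B, C = C),
    tract = tract,
    wm_mask = brain_mask(grid, wm),
    gm_mask = brain_mask(grid, gm),
    parc = parcellation(grid, labels),
    anchors = list(A = c(ax + half, cy, cz), B = c(bx - half, cy, cz),
                   C = c(cx, jc + half, cz))), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(paste0("<phantom> %s grid; regions A/B/C of %d/%d/%d voxels; ",
                     "tract %d voxels; wm mask %d voxels\n"),
              paste(x$grid$shape, collapse = "x"),
              nrow(x$gm_regions$A), nrow(x$gm_regions$B),
              nrow(x$gm_regions$C), nrow(x$tract), sum(x$wm_mask$data)))
  invisible(x)
}

#' Simulate per-subject streamline sets on the phantom
#'
#' For each subject, `n_streamlines` bundle polylines run from a voxel of A
#' through the tract centerline to a voxel of B (start/end voxels cycle
#' through the regions), plus `n_distractors` streamlines avoiding the
#' tract: half follow the C-region distractor path, half a free-floating
#' line parallel to the tract.  Every polyline point receives isotropic
#' Gaussian jitter with sd `streamline_jitter` mm; with zero jitter each
#' bundle polyline rasterises exactly to its start voxel, the
#' anchor-tract-anchor spine and its end voxel.  The first `n_streamlines`
#' polylines of each set are always the bundle.
#'
#' Deterministic per `(seed, subject)`.
#'
#' @param ph a [make_phantom()] phantom.
#' @param cfg a [sim_config()].
#' @return list of [streamline_set()], one per subject.
#' @export
simulate_streamlines <- function(ph, cfg = sim_config()) {
  g <- ph$grid
  path_world <- function(ijk) voxel_to_world(g, ijk)
  spine <- rbind(ph$anchors$A, ph$tract, ph$anchors$B)
  A <- ph$gm_regions$A; B <- ph$gm_regions$B; C <- ph$gm_regions$C
  cz <- ph$anchors$A[3]
  # free distractor: parallel to the tract, offset in j and k
  free_line <- cbind(ph$tract[, 1], ph$tract[, 2] - 3L, cz - 1L)
  c_path <- cbind(ph$anchors$C[1],
                  (ph$anchors$C[2] + 1L):(ph$anchors$A[2] - 2L), cz)
  lapply(seq_len(cfg$n_subjects), function(sub) {
    set.seed(cfg$seed + 7919L * sub)
    lines <- vector("list", cfg$n_streamlines + cfg$n_distractors)
    for (q in seq_len(cfg$n_streamlines)) {
      a_vox <- A[((q - 1L) %% nrow(A)) + 1L, ]
      b_vox <- B[((q - 1L) %% nrow(B)) + 1L, ]
      pts <- path_world(rbind(a_vox, spine, b_vox))
      lines[[q]] <- jitter_points(pts, cfg$streamline_jitter)
    }
    for (q in seq_len(cfg$n_distractors)) {
      base <- if (q %% 2L == 1L) {
        c_vox <- C[((q - 1L) %% nrow(C)) + 1L, ]
        path_world(rbind(c_vox, ph$anchors$C, c_path))
      } else {
        path_world(free_line)
      }
      lines[[cfg$n_streamlines + q]] <- jitter_points(base,
                                                      cfg$streamline_jitter)
    }
    streamline_set(lines, subject_id = sprintf("sub-%02d", sub))
  })
}

jitter_points <- function(pts, sd) {
  if (sd <= 0) return(pts)
  pts + matrix(rnorm(length(pts), 0, sd), nrow(pts), 3)
}

#' Default block paradigm for the phantom runs
#'
#' 15 s task blocks separated by 25 s rest, first onset at 20 s, for as many
#' blocks as fit the run.
#'
#' @param n_frames frames per run.
#' @param tr repetition time (s).
#' @return `(start, duration)` matrix in seconds.
#' @export
default_onsets <- function(n_frames = 200, tr = 1) {
  dur <- n_frames * tr
  if (dur < 35) stop("run too short for the default block paradigm (>= 35 s)")
  starts <- seq(20, dur - 15, by = 40)
  cbind(start = starts, duration = 15)
}

#' Simulate two-run task BOLD on the phantom
#'
#' Baseline 100 everywhere; voxels of regions A/B/C gain their configured
#' amplitude times the HRF-convolved, unit-peak block regressor; i.i.d.
#' Gaussian noise of sd `noise_sd` is added to every voxel and frame.  The
#' two runs of a subject share the signal and differ only in the noise
#' stream, emulating a test-retest acquisition pair.  Deterministic per
#' `(seed, subject, run)`.
#'
#' @param ph a phantom.
#' @param cfg a [sim_config()].
#' @param onsets block onsets, default [default_onsets()].
#' @param ar1 optional lag-1 autocorrelation of the noise (default 0,
#'   i.i.d.).
#' @return list per subject of `list(run1 = , run2 = )`
#'   [functional_volume()] pairs.
#' @export
simulate_bold <- function(ph, cfg = sim_config(),
                          onsets = default_onsets(cfg$n_frames, cfg$tr),
                          ar1 = 0) {
  lapply(seq_len(cfg$n_subjects), function(sub)
    list(run1 = simulate_bold_run(ph, cfg, onsets, sub, 1L, ar1),
         run2 = simulate_bold_run(ph, cfg, onsets, sub, 2L, ar1)))
}

simulate_bold_run <- function(ph, cfg, onsets, subject, run, ar1 = 0) {
  g <- ph$grid
  nt <- cfg$n_frames
  reg <- task_regressor(onsets, nt, cfg$tr)
  nv <- prod(g$shape)
  dat <- matrix(100, nv, nt)
  amps <- c(A = cfg$amp_A, B = cfg$amp_B, C = cfg$amp_C)
  for (nm in names(amps)) {
    if (amps[[nm]] == 0) next
    lin <- ijk_to_linear(ph$gm_regions[[nm]], g$shape)
    dat[lin, ] <- dat[lin, ] + rep(amps[[nm]] * reg, each = length(lin))
  }
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed + 104729L * subject + 13L * run)
    eps <- matrix(rnorm(nv * nt, 0, cfg$noise_sd), nv, nt)
    if (ar1 != 0) {
      for (tt in 2:nt) eps[, tt] <- ar1 * eps[, tt - 1] +
          sqrt(1 - ar1^2) * eps[, tt]
    }
    dat <- dat + eps
  }
  functional_volume(g, array(dat, c(g$shape, nt)), tr = cfg$tr)
}

#' Write a phantom dataset to disk in standard formats
#'
#' Emits NIfTI masks (`gm.nii.gz`, `wm.nii.gz`, `tract.nii.gz`,
#' `parcellation.nii.gz`), one TRK tractogram per subject, two BOLD runs per
#' subject and a BIDS-style `events.tsv` — exactly the formats the pipeline
#' consumes.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [sim_config()].
#' @param onsets block onsets, default [default_onsets()].
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dir, cfg = sim_config(),
                                  onsets = default_onsets(cfg$n_frames,
                                                          cfg$tr)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- make_phantom(cfg)
  write_volume(ph$gm_mask, file.path(dir, "gm.nii.gz"))
  write_volume(ph$wm_mask, file.path(dir, "wm.nii.gz"))
  write_volume(brain_mask(ph$grid, ph$tract), file.path(dir, "tract.nii.gz"))
  write_volume(ph$parc, file.path(dir, "parcellation.nii.gz"))
  sl <- simulate_streamlines(ph, cfg)
  for (s in seq_along(sl))
    write_streamlines(sl[[s]], file.path(dir, sprintf("sub-%02d.trk", s)),
                      grid = ph$grid)
  bold <- simulate_bold(ph, cfg, onsets)
  for (s in seq_along(bold)) {
    write_volume(bold[[s]]$run1,
                 file.path(dir, sprintf("sub-%02d_run-1_bold.nii.gz", s)))
    write_volume(bold[[s]]$run2,
                 file.path(dir, sprintf("sub-%02d_run-2_bold.nii.gz", s)))
  }
  ev <- data.frame(onset = onsets[, 1], duration = onsets[, 2])
  write_tsv_report(ev, file.path(dir, "events.tsv"))
  invisible(dir)
}
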