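# Simplified activation statistics: double-gamma HRF design, per-voxel OLS
# first level (optional AR(1) prewhitening), one-sample-t group level, and
# Gaussian smoothing for the classical arm.  The z transform maps t through
# the exact Student tail in log space, capped at +/- 38 (the double-precision
# limit of the normal quantile).

Z_CAP <- 38

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional difference of two gamma densities: response peak around
#' `peak` seconds, undershoot around `undershoot` seconds, peak-to-undershoot
#' ratio `ratio` (SPM/FSL defaults 6 / 16 / 6).
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot shape parameters (s) of the two gamma components
#'   (rate 1).
#' @param ratio undershoot attenuation.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- dgamma(t, shape = peak, rate = 1) -
    dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Task regressor: boxcar convolved with the HRF
#'
#' Sampled on a fine micro-time grid, convolved, then read out at frame
#' acquisition times and scaled to unit peak, so first-level betas are in
#' units of peak signal change.
#'
#' @param onsets two-column matrix / data.frame / list of `(start, duration)`
#'   pairs in seconds.
#' @param n_frames number of frames.
#' @param tr repetition time (s).
#' @param dt micro-time resolution (s).
#' @return numeric vector of length `n_frames` (unit peak, not centred).
#' @export
task_regressor <- function(onsets, n_frames, tr, dt = 0.1) {
  onsets <- as_onsets(onsets)
  dur_total <- n_frames * tr
  if (nrow(onsets)) {
    if (any(onsets[, 2] < 0)) stop("negative event duration")
    if (any(onsets[, 1] < 0) || any(rowSums(onsets) > dur_total + 1e-9))
      stop("event outside scan duration")
  }
  tg <- seq(0, dur_total + 32, by = dt)
  box <- numeric(length(tg))
  for (r in seq_len(nrow(onsets)))
    box[tg >= onsets[r, 1] & tg < onsets[r, 1] + onsets[r, 2]] <- 1
  h <- hrf_double_gamma(tg)
  conv <- convolve(box, rev(h), type = "open")[seq_along(tg)] * dt
  frame_t <- (seq_len(n_frames) - 1) * tr
  reg <- conv[pmin(length(tg), round(frame_t / dt) + 1)]
  pk <- max(abs(reg))
  if (pk > 0) reg <- reg / pk
  reg
}

as_onsets <- function(onsets) {
  if (is.null(onsets) || (is.list(onsets) && !length(onsets)) ||
      (is.data.frame(onsets) && !nrow(onsets)))
    return(matrix(numeric(0), 0, 2))
  if (is.data.frame(onsets)) onsets <- as.matrix(onsets[, 1:2])
  if (is.list(onsets)) onsets <- do.call(rbind, onsets)
  if (is.null(dim(onsets))) onsets <- matrix(onsets, ncol = 2, byrow = TRUE)
  storage.mode(onsets) <- "double"
  onsets[, 1:2, drop = FALSE]
}

#' Build a first-level design matrix
#'
#' One HRF-convolved, unit-peak, mean-centred task regressor plus an
#' intercept.  With no events the design degenerates to the intercept alone
#' and carries no testable contrast; a task regressor that is constant over
#' the run (e.g. a block covering the whole acquisition) is flagged
#' collinear and rejected at fit time.
#'
#' @param onsets `(start, duration)` pairs in seconds; may be empty.
#' @param n_frames number of frames.
#' @param tr repetition time (s).
#' @param dt micro-time resolution for the convolution (s).
#' @return object of class `design_matrix` with fields `regressors`
#'   (`n_frames` x K), `names`, `tr`, `contrast` (`NULL` when no task
#'   regressor exists) and `collinear`.
#' @export
make_design <- function(onsets, n_frames, tr, dt = 0.1) {
  stopifnot(n_frames >= 1, tr > 0)
  onsets <- as_onsets(onsets)
  if (!nrow(onsets)) {
    X <- matrix(1, n_frames, 1)
    return(structure(list(regressors = X, names = "intercept", tr = tr,
                          contrast = NULL, collinear = FALSE),
                     class = "design_matrix"))
  }
  reg <- task_regressor(onsets, n_frames, tr, dt)
  centred <- reg - mean(reg)
  collinear <- sd(centred) < 1e-10
  if (collinear) {
    warning("task regressor is constant over the run; design is collinear")
    centred <- centred * 0
  }
  X <- cbind(task = centred, intercept = 1)
  structure(list(regressors = X, names = colnames(X), tr = tr,
                 contrast = c(1, 0), collinear = collinear),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d frames x %d regressors (%s), TR %.3g s\n",
              nrow(x$regressors), ncol(x$regressors),
              paste(x$names, collapse = ", "), x$tr))
  invisible(x)
}

# exact Student tail -> standard normal, symmetric, capped
t_to_z <- function(t, dof, cap = Z_CAP) {
  logp <- pt(-abs(t), df = dof, log.p = TRUE)
  za <- -qnorm(logp, log.p = TRUE)
  sign(t) * pmin(za, cap)
}

#' First-level GLM: per-voxel OLS of a 4D volume on a design
#'
#' Ordinary least squares at every mask voxel; the contrast effect, its t
#' statistic (residual dof `T - K`) and the z-transformed t.  Standard
#' errors are floored at 1e-12 so exact fits produce capped, finite
#' statistics.  Optional AR(1) prewhitening (Cochrane-Orcutt, per voxel)
#' for autocorrelated noise.
#'
#' @param f a `functional_volume`.
#' @param design a `design_matrix` with a valid contrast.
#' @param mask `brain_mask` of voxels to fit.
#' @param prewhiten estimate a per-voxel lag-1 residual autocorrelation and
#'   refit on quasi-differenced data (default `FALSE`).
#' @return a [stat_map()] (beta = contrast effect).
#' @export
fit_first_level <- function(f, design, mask, prewhiten = FALSE) {
  stopifnot(inherits(f, "functional_volume"),
            inherits(design, "design_matrix"),
            inherits(mask, "brain_mask"))
  stop_unless_same_grid(f, mask, "BOLD and mask")
  X <- design$regressors
  if (nrow(X) != dim(f$data)[4]) stop("design frames do not match volume")
  if (is.null(design$contrast)) stop("design has no testable contrast")
  if (design$collinear || qr(X)$rank < ncol(X)) stop("rank-deficient design")
  lin <- which(mask$data)
  if (!length(lin)) stop("empty mask")
  Y <- t(series_matrix(f, lin))               # T x V
  fit <- ols_contrast(X, Y, design$contrast)
  if (prewhiten) {
    res <- Y - X %*% fit$beta_full
    num <- colSums(res[-1, , drop = FALSE] * res[-nrow(res), , drop = FALSE])
    den <- colSums(res^2)
    rho <- ifelse(den > 0, num / den, 0)
    rho <- pmin(pmax(rho, -0.99), 0.99)
    n <- nrow(Y)
    Yw <- Y[-1, , drop = FALSE] - Y[-n, , drop = FALSE] *
      matrix(rho, n - 1, ncol(Y), byrow = TRUE)
    # X must be whitened per voxel; loop only over distinct rho bins
    eff <- se <- numeric(ncol(Y))
    for (v in seq_len(ncol(Y))) {
      Xw <- X[-1, , drop = FALSE] - rho[v] * X[-n, , drop = FALSE]
      fv <- ols_contrast(Xw, Yw[, v, drop = FALSE], design$contrast)
      eff[v] <- fv$eff; se[v] <- fv$se
    }
    dof <- n - 1 - ncol(X)
    fit <- list(eff = eff, se = se)
  } else {
    dof <- nrow(X) - ncol(X)
  }
  tval <- fit$eff / pmax(fit$se, 1e-12)
  zval <- t_to_z(tval, dof)
  pack_stat_map(f$grid, mask, lin, fit$eff, tval, zval, dof)
}

ols_contrast <- function(X, Y, contrast) {
  XtX <- crossprod(X)
  bet <- solve(XtX, crossprod(X, Y))          # K x V
  res <- Y - X %*% bet
  dof <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / dof
  cXc <- drop(t(contrast) %*% solve(XtX, contrast))
  list(eff = drop(crossprod(contrast, bet)),
       se = sqrt(pmax(s2 * cXc, 0)),
       beta_full = bet)
}

pack_stat_map <- function(grid, mask, lin, eff, tval, zval, dof) {
  mk <- function(v) { a <- array(0, grid$shape); a[lin] <- v; a }
  stat_map(grid, mk(eff), mk(tval), mk(zval), dof, mask)
}

#' Group-level one-sample t on first-level effects
#'
#' Per voxel, a one-sample t-test of the subjects' contrast effects against
#' zero (dof `n - 1`), z-transformed.  The sampling variance is floored at
#' 1e-12 so identical nonzero effects yield the capped z rather than an
#' infinity.
#'
#' @param maps list of >= 3 first-level `stat_map`s on one grid.
#' @return a [stat_map()] (`beta` = group mean effect) on the intersection
#'   of the input masks.
#' @export
fit_group <- function(maps) {
  if (length(maps) < 3) stop("group analysis needs at least 3 subjects")
  stopifnot(all(vapply(maps, inherits, logical(1), "stat_map")))
  g <- maps[[1]]$grid
  for (m in maps[-1]) stop_unless_same_grid(g, m, "group input maps")
  mask_arr <- Reduce(`&`, lapply(maps, function(m) m$mask$data))
  mask <- brain_mask(g, array(mask_arr, g$shape))
  lin <- which(mask_arr)
  if (!length(lin)) stop("empty group mask")
  B <- vapply(maps, function(m) m$beta[lin], numeric(length(lin)))
  n <- length(maps)
  mu <- rowMeans(B)
  v <- pmax(rowSums((B - mu)^2) / (n - 1), 1e-12)
  tval <- mu / sqrt(v / n)
  zval <- t_to_z(tval, n - 1)
  pack_stat_map(g, mask, lin, mu, tval, zval, n - 1)
}

#' Gaussian spatial smoothing of a 4D volume
#'
#' Separable per-axis Gaussian with `sigma = fwhm / (2 sqrt(2 log 2))` in mm,
#' converted to voxels per axis (anisotropic grids smooth correctly per
#' axis).  Kernels are renormalised at the boundaries, so constants are
#' preserved exactly (unit DC gain); `fwhm = 0` is the identity.
#'
#' @param f a `functional_volume`.
#' @param fwhm full width at half maximum in mm, >= 0.
#' @return a smoothed `functional_volume`.
#' @export
smooth_volume <- function(f, fwhm) {
  stopifnot(inherits(f, "functional_volume"), fwhm >= 0)
  if (fwhm == 0) return(f)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  arr <- f$data
  for (ax in 1:3) {
    sig <- sigma_mm / f$grid$voxel_size[ax]
    if (sig < 1e-8) next
    arr <- filter_axis(arr, gaussian_matrix(dim(arr)[ax], sig), ax)
  }
  functional_volume(f$grid, arr, tr = f$tr)
}

# n x n convolution matrix for a 1D Gaussian, rows renormalised to sum 1
gaussian_matrix <- function(n, sigma) {
  r <- ceiling(4 * sigma)
  idx <- matrix(seq_len(n), n, n)
  d <- idx - t(idx)
  C <- exp(-d^2 / (2 * sigma^2))
  C[abs(d) > r] <- 0
  C / rowSums(C)
}

filter_axis <- function(arr, C, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  dp <- dim(a)
  dim(a) <- c(dp[1], prod(dp[-1]))
  a <- C %*% a
  dim(a) <- dp
  aperm(a, order(perm))
}
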