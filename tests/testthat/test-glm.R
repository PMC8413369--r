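test_that("design construction handles empty, degenerate and block paradigms", {
  d0 <- make_design(NULL, 50, 1)
  expect_equal(d0$names, "intercept")
  expect_null(d0$contrast)
  g <- unit_grid(c(4, 4, 4))
  expect_error(fit_first_level(random_volume(g, nt = 50), d0, full_mask(g)),
               "contrast")

  # a block covering the whole run still varies through the HRF ramp-in,
  # so it stays estimable; a zero-duration event is the degenerate design
  dfull <- make_design(rbind(c(0, 100)), 100, 1)
  expect_false(dfull$collinear)
  expect_warning(dnull <- make_design(rbind(c(10, 0)), 100, 1), "collinear")
  expect_true(dnull$collinear)
  expect_true(all(dnull$regressors[, "task"] == 0))
  expect_error(fit_first_level(random_volume(g, nt = 100), dnull,
                               full_mask(g)), "rank-deficient")

  expect_error(make_design(rbind(c(10, -5)), 100, 1), "negative")
  expect_error(make_design(rbind(c(95, 10)), 100, 1), "outside scan")
})

test_that("the convolved regressor peak follows the HRF lag of a 15 s block", {
  # independent oracle: direct O(n^2) discrete convolution on a fine grid
  dt <- 0.01
  tg <- seq(0, 120, by = dt)
  box <- as.numeric(tg >= 20 & tg < 35)
  h <- hrf_double_gamma(tg)
  conv <- numeric(length(tg))
  for (i in seq_along(tg)) {
    idx <- seq_len(i)
    conv[i] <- sum(box[idx] * h[i - idx + 1]) * dt
  }
  oracle_peak <- tg[which.max(conv)]
  reg <- task_regressor(rbind(c(20, 15)), 120, 1)
  expect_lte(abs(which.max(reg) - 1 - oracle_peak), 1)
  # for a sustained block the response peaks near block end + HRF delay
  expect_gt(oracle_peak - 20, 4)
  expect_lt(oracle_peak - 20, 16)
  expect_equal(max(reg), 1)
  # the frame-sampled regressor agrees with the oracle along the whole run
  oracle_frames <- conv[0:119 * 100 + 1]
  expect_equal(reg, oracle_frames / max(abs(oracle_frames)),
               tolerance = 0.02)
})

test_that("first-level OLS recovers exact fits and nulls orthogonal data", {
  g <- unit_grid(c(4, 4, 4))
  d <- make_design(rbind(c(5, 10), c(30, 10)), 60, 1)
  reg <- d$regressors[, "task"]
  nv <- prod(g$shape)
  arr <- array(rep(5 + 2 * reg, each = nv), c(g$shape, 60))
  f <- functional_volume(g, arr, 1)
  fit <- fit_first_level(f, d, full_mask(g))
  expect_equal(fit$beta[1, 1, 1], 2, tolerance = 1e-10)
  expect_equal(fit$z[2, 3, 4], fnkit:::Z_CAP)         # zero residual: capped
  expect_equal(fit$dof, 58)

  orth <- array(rep(1 + 0 * reg, each = nv), c(g$shape, 60))
  orth[1, 1, 1, ] <- orth[1, 1, 1, ] + (seq_len(60) %% 2) * 0  # stay constant
  fit0 <- fit_first_level(functional_volume(g, orth, 1), d, full_mask(g))
  expect_equal(fit0$beta[2, 2, 2], 0, tolerance = 1e-10)
  expect_equal(fit0$z[2, 2, 2], 0, tolerance = 1e-4)
})

test_that("z transform is odd, monotone in t, and capped symmetrically", {
  t2z <- fnkit:::t_to_z
  tt <- c(-50, -5, -1, 0, 1, 5, 50, 1e6)
  z <- t2z(tt, 20)
  expect_equal(z, -rev(t2z(-rev(tt), 20)))
  expect_true(all(diff(z) >= 0))
  expect_lte(max(abs(z)), fnkit:::Z_CAP)
  # exact small case against base R distributions
  expect_equal(t2z(2, 10), qnorm(pt(2, 10)), tolerance = 1e-10)
})

test_that("group one-sample t matches base R and handles zero variance", {
  g <- unit_grid(c(4, 4, 4))
  m <- full_mask(g)
  mk <- function(vals) {
    arr <- array(vals, g$shape)
    stat_map(g, arr, arr, arr, 50, m)
  }
  zero <- fit_group(lapply(1:5, function(i) mk(0)))
  expect_true(all(zero$z == 0))
  # zero sampling variance hits the 1e-12 floor: a huge but finite t whose
  # exact Student transform at dof 4 is large, finite and reproducible
  same <- fit_group(lapply(1:5, function(i) mk(1)))
  expect_equal(same$z[1, 1, 1],
               fnkit:::t_to_z(1 / sqrt(1e-12 / 5), 4))
  expect_gt(same$z[1, 1, 1], 10)
  expect_true(is.finite(same$z[1, 1, 1]))

  set.seed(71)
  betas <- rnorm(20, 0.5, 1)
  maps <- lapply(betas, mk)
  grp <- fit_group(maps)
  oracle <- t.test(betas)                               # independent route
  expect_equal(grp$t[2, 2, 2], unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(grp$dof, 19)
  expect_error(fit_group(maps[1:2]), "at least 3")
})

test_that("under pure noise the first-level z rate at 1.96 is calibrated", {
  g <- voxel_grid(c(10, 10, 10), diag(c(2, 2, 2, 1)))
  set.seed(4242)
  nt <- 120
  f <- functional_volume(g, array(rnorm(1000 * nt), c(g$shape, nt)), 1)
  d <- make_design(default_onsets(nt, 1), nt, 1)
  fit <- fit_first_level(f, d, full_mask(g))
  rate <- mean(abs(fit$z) > 1.96)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})

test_that("AR(1) prewhitening runs and stays close to OLS on white noise", {
  g <- unit_grid(c(4, 4, 4))
  f <- random_volume(g, nt = 80, seed = 81)
  d <- make_design(rbind(c(10, 15), c(45, 15)), 80, 1)
  ols <- fit_first_level(f, d, full_mask(g))
  pw <- fit_first_level(f, d, full_mask(g), prewhiten = TRUE)
  expect_true(all(is.finite(pw$z)))
  expect_gt(cor(as.numeric(ols$t), as.numeric(pw$t)), 0.95)
})

test_that("Gaussian smoothing preserves constants and matches the analytic kernel", {
  g <- voxel_grid(c(15, 15, 15), diag(c(2, 2, 2, 1)))
  f <- random_volume(g, nt = 2, seed = 91)
  expect_identical(smooth_volume(f, 0)$data, f$data)

  const <- functional_volume(g, array(3.5, c(g$shape, 2)), 1)
  expect_equal(smooth_volume(const, 6)$data, const$data, tolerance = 1e-12)

  imp <- array(0, c(g$shape, 1)); imp[8, 8, 8, 1] <- 1
  sm <- smooth_volume(functional_volume(g, imp, 1), 4)
  sigma_vox <- 4 / (2 * sqrt(2 * log(2))) / 2
  prof <- sm$data[, 8, 8, 1]
  expected <- exp(-((1:15 - 8)^2) / (2 * sigma_vox^2))
  expected <- expected / sum(expected)
  ratio <- prof[6:10] / sum(prof)
  expect_equal(ratio / sum(ratio), expected[6:10] / sum(expected[6:10]),
               tolerance = 1e-6)
  # mass preserved away from boundaries (DC gain 1)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
})

test_that("anisotropic grids smooth with per-axis sigma", {
  g <- voxel_grid(c(15, 15, 15), diag(c(1, 2, 4, 1)))
  imp <- array(0, c(g$shape, 1)); imp[8, 8, 8, 1] <- 1
  sm <- smooth_volume(functional_volume(g, imp, 1), 8)$data[, , , 1]
  # spread (voxel units) must shrink as voxel size grows
  sx <- sqrt(sum(sm[, 8, 8] / sum(sm[, 8, 8]) * (1:15 - 8)^2))
  sz <- sqrt(sum(sm[8, 8, ] / sum(sm[8, 8, ]) * (1:15 - 8)^2))
  expect_gt(sx, 2 * sz)
})
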