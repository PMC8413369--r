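# Shared fixtures: tiny grids, random volumes and hand-rolled oracle
# implementations kept deliberately naive and independent of the package's
# optimised code paths.

unit_grid <- function(shape = c(4, 4, 4), voxel = 1, shift = c(0, 0, 0)) {
  aff <- diag(c(rep(voxel, 3), 1))
  aff[1:3, 4] <- shift
  voxel_grid(shape, aff)
}

random_volume <- function(grid, nt = 6, seed = 1, baseline = 0) {
  set.seed(seed)
  functional_volume(grid,
                    array(baseline + rnorm(prod(grid$shape) * nt),
                          c(grid$shape, nt)),
                    tr = 1)
}

full_mask <- function(grid) brain_mask(grid, array(TRUE, grid$shape))

# priors store where each seed's map is the indicator of the seed itself
delta_priors <- function(grid, mask) {
  lin <- which(mask$data)
  keys <- apply(fnkit:::linear_to_ijk(lin, grid$shape), 1, paste,
                collapse = "_")
  W <- Matrix::sparseMatrix(i = lin, j = seq_along(lin), x = 1,
                            dims = c(prod(grid$shape), length(lin)))
  priors_store(grid, "voxel", W, keys)
}

# random sparse voxel-wise priors over the given seed voxels
random_priors <- function(grid, seed_lin, density = 0.2, seed = 7) {
  set.seed(seed)
  nv <- prod(grid$shape)
  cols <- lapply(seq_along(seed_lin), function(q) {
    nz <- which(runif(nv) < density)
    list(i = nz, x = runif(length(nz)))
  })
  W <- Matrix::sparseMatrix(
    i = unlist(lapply(cols, `[[`, "i")),
    j = rep(seq_along(cols), vapply(cols, function(c) length(c$i),
                                    integer(1))),
    x = unlist(lapply(cols, `[[`, "x")),
    dims = c(nv, length(seed_lin)))
  keys <- apply(fnkit:::linear_to_ijk(seed_lin, grid$shape), 1, paste,
                collapse = "_")
  priors_store(grid, "voxel", W, keys)
}

# ---- independent oracles -----------------------------------------------------

# voxels traversed by a polyline: dense sampling at a very fine step
oracle_rasterize <- function(line, grid, step = min(grid$voxel_size) / 100) {
  pts <- list()
  for (s in seq_len(max(1, nrow(line) - 1))) {
    p0 <- line[s, ]; p1 <- line[min(s + 1, nrow(line)), ]
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(1, ceiling(len / step))
    tt <- seq(0, 1, length.out = n + 1)
    pts[[s]] <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                      p0[2] + tt * (p1[2] - p0[2]),
                      p0[3] + tt * (p1[3] - p0[3]))
  }
  pts <- do.call(rbind, pts)
  vox <- round(fnkit::world_to_voxel(grid, pts))
  keep <- vox[, 1] >= 0 & vox[, 1] < grid$shape[1] &
          vox[, 2] >= 0 & vox[, 2] < grid$shape[2] &
          vox[, 3] >= 0 & vox[, 3] < grid$shape[3]
  vox <- vox[keep, , drop = FALSE]
  sort(unique(1 + vox[, 1] + grid$shape[1] *
                (vox[, 2] + grid$shape[2] * vox[, 3])))
}

# number of dense sample points of a polyline landing inside one voxel
oracle_points_in_voxel <- function(line, grid, vox_lin, step) {
  pts <- list()
  for (s in seq_len(max(1, nrow(line) - 1))) {
    p0 <- line[s, ]; p1 <- line[min(s + 1, nrow(line)), ]
    n <- max(1, ceiling(sqrt(sum((p1 - p0)^2)) / step))
    tt <- seq(0, 1, length.out = n + 1)
    pts[[s]] <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                      p0[2] + tt * (p1[2] - p0[2]),
                      p0[3] + tt * (p1[3] - p0[3]))
  }
  vox <- round(fnkit::world_to_voxel(grid, do.call(rbind, pts)))
  lin <- 1 + vox[, 1] + grid$shape[1] * (vox[, 2] + grid$shape[2] * vox[, 3])
  lin == vox_lin
}

# visitation map by testing every streamline independently; uses the package
# rasteriser per streamline so that what is checked is the subset-selection
# and union logic, not the rasterisation step size
oracle_visitation <- function(sl, seed_lin, grid) {
  arr <- array(0, grid$shape)
  for (s in sl$streamlines) {
    ijk <- fnkit::rasterize_streamline(s, grid)
    vox <- 1 + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
    if (any(vox %in% seed_lin)) arr[vox] <- 1
  }
  arr
}

# quadruple-loop projection oracle (voxels x time x mask seeds)
oracle_project <- function(f, mask_lin, priors) {
  shape <- f$grid$shape
  nt <- dim(f$data)[4]
  nv <- prod(shape)
  Fm <- matrix(f$data, nv, nt)
  keys <- apply(fnkit:::linear_to_ijk(mask_lin, shape), 1, paste,
                collapse = "_")
  P <- vapply(keys, function(k) {
    pm <- priors_entry(priors, k)
    as.numeric(pm$data)
  }, numeric(nv))
  out <- matrix(0, nv, nt)
  for (v in seq_len(nv)) {
    den <- 0
    for (m in seq_along(mask_lin)) den <- den + P[v, m]
    if (den == 0) next
    for (tt in seq_len(nt)) {
      num <- 0
      for (m in seq_along(mask_lin)) num <- num + P[v, m] * Fm[mask_lin[m], tt]
      out[v, tt] <- num / den
    }
  }
  array(out, c(shape, nt))
}

# region-wise projection oracle: loop regions, then voxels
oracle_project_region <- function(f, parc, priors) {
  shape <- f$grid$shape
  nt <- dim(f$data)[4]
  nv <- prod(shape)
  Fm <- matrix(f$data, nv, nt)
  labs <- setdiff(sort(unique(as.vector(parc$labels))), 0L)
  P <- vapply(as.character(labs), function(k)
    as.numeric(priors_entry(priors, k)$data), numeric(nv))
  series <- t(vapply(labs, function(l) {
    lin <- which(parc$labels == l)
    colMeans(Fm[lin, , drop = FALSE])
  }, numeric(nt)))
  out <- matrix(0, nv, nt)
  for (v in seq_len(nv)) {
    den <- sum(P[v, ])
    if (den == 0) next
    for (tt in seq_len(nt))
      out[v, tt] <- sum(P[v, ] * series[, tt]) / den
  }
  array(out, c(shape, nt))
}
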