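test_that("delta priors make projection the identity on the mask", {
  g <- unit_grid(c(4, 4, 4))
  f <- random_volume(g, nt = 6, seed = 2)
  m <- full_mask(g)
  res <- project_voxelwise(f, m, delta_priors(g, m))
  expect_identical(res$volume$data, f$data)
  expect_equal(sum(res$uncovered$data), 0)

  # partial mask: identity on the mask, complement uncovered
  m2 <- brain_mask(g, rbind(c(0, 0, 0), c(1, 2, 3), c(3, 3, 3)))
  res2 <- project_voxelwise(f, m2, delta_priors(g, m2))
  lin <- which(m2$data)
  nt <- dim(f$data)[4]
  for (tt in seq_len(nt))
    expect_identical(res2$volume$data[, , , tt][lin], f$data[, , , tt][lin])
  expect_equal(which(res2$uncovered$data), setdiff(seq_len(64), lin))
})

test_that("equal weights average the contributing time-series", {
  g <- unit_grid(c(4, 4, 4))
  arr <- array(0, c(g$shape, 3))
  arr[1, 1, 1, ] <- c(1, 2, 3)
  arr[2, 1, 1, ] <- c(3, 2, 1)
  f <- functional_volume(g, arr, 1)
  m <- brain_mask(g, rbind(c(0, 0, 0), c(1, 0, 0)))
  target <- fnkit:::ijk_to_linear(c(3, 3, 3), g$shape)
  W <- Matrix::sparseMatrix(i = c(target, target), j = c(1, 2), x = 0.5,
                            dims = c(64, 2))
  pr <- priors_store(g, "voxel", W, c("0_0_0", "1_0_0"))
  res <- project_voxelwise(f, m, pr)
  expect_equal(res$volume$data[4, 4, 4, ], c(2, 2, 2))
})

test_that("voxel-wise projection matches the quadruple-loop oracle", {
  g <- unit_grid(c(4, 4, 4))
  f <- random_volume(g, nt = 6, seed = 14)
  set.seed(15)
  mask_lin <- sort(sample(64, 10))
  m <- brain_mask(g, fnkit:::linear_to_ijk(mask_lin, g$shape))
  pr <- random_priors(g, mask_lin, density = 0.3, seed = 16)
  res <- project_voxelwise(f, m, pr)
  expect_lt(max(abs(res$volume$data - oracle_project(f, mask_lin, pr))),
            1e-10)
})

test_that("region-wise projection matches its loop oracle and the singleton case", {
  g <- unit_grid(c(4, 4, 4))
  f <- random_volume(g, nt = 5, seed = 24)
  labels <- array(0L, g$shape)
  labels[1:2, 1, 1] <- 1L; labels[3:4, 2, 2] <- 2L; labels[1, 4, 4] <- 3L
  parc <- parcellation(g, labels)
  set.seed(25)
  W <- Matrix::Matrix(matrix(runif(64 * 3) * (runif(64 * 3) < 0.4), 64, 3),
                      sparse = TRUE)
  pr <- priors_store(g, "region", W, c("1", "2", "3"))
  res <- project_regionwise(f, parc, pr)
  expect_lt(max(abs(res$volume$data - oracle_project_region(f, parc, pr))),
            1e-10)

  # regions that are single voxels with identical priors reduce to voxel-wise
  labs1 <- array(0L, g$shape)
  vox <- rbind(c(0, 0, 0), c(2, 1, 3))
  lin <- fnkit:::ijk_to_linear(vox, g$shape)
  labs1[lin] <- c(1L, 2L)
  pr_vox <- random_priors(g, lin, density = 0.3, seed = 26)
  pr_reg <- priors_store(g, "region", pr_vox$W, c("1", "2"))
  res_v <- project_voxelwise(f, brain_mask(g, vox), pr_vox)
  res_r <- project_regionwise(f, parcellation(g, labs1), pr_reg)
  expect_equal(res_r$volume$data, res_v$volume$data)
})

test_that("covered outputs are convex combinations of contributing inputs", {
  g <- unit_grid(c(4, 4, 4))
  set.seed(33)
  for (rep in 1:100) {
    f <- random_volume(g, nt = 3, seed = 100 + rep)
    mask_lin <- sort(sample(64, sample(3:12, 1)))
    m <- brain_mask(g, fnkit:::linear_to_ijk(mask_lin, g$shape))
    pr <- random_priors(g, mask_lin, density = runif(1, 0.05, 0.5),
                        seed = 200 + rep)
    res <- project_voxelwise(f, m, pr)
    Fm <- matrix(f$data, 64, 3)[mask_lin, , drop = FALSE]
    P <- as.matrix(pr$W)
    for (v in which(res$coverage > 0)) {
      contrib <- P[v, ] > 0
      lo <- apply(Fm[contrib, , drop = FALSE], 2, min)
      hi <- apply(Fm[contrib, , drop = FALSE], 2, max)
      out <- matrix(res$volume$data, 64, 3)[v, ]
      expect_true(all(out >= lo - 1e-10 & out <= hi + 1e-10))
    }
  }
})

test_that("projection is linear and invariant to seed order", {
  g <- unit_grid(c(4, 4, 4))
  f1 <- random_volume(g, nt = 4, seed = 41)
  f2 <- random_volume(g, nt = 4, seed = 42)
  mask_lin <- c(3, 17, 33, 60)
  m <- brain_mask(g, fnkit:::linear_to_ijk(mask_lin, g$shape))
  pr <- random_priors(g, mask_lin, seed = 43)
  a <- 0.7; b <- -2.1
  mix <- functional_volume(g, a * f1$data + b * f2$data, 1)
  lhs <- project_voxelwise(mix, m, pr)$volume$data
  rhs <- a * project_voxelwise(f1, m, pr)$volume$data +
         b * project_voxelwise(f2, m, pr)$volume$data
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  perm <- c(3, 1, 4, 2)
  pr_perm <- priors_store(g, "voxel", pr$W[, perm], pr$keys[perm])
  expect_equal(project_voxelwise(f1, m, pr_perm)$volume$data,
               project_voxelwise(f1, m, pr)$volume$data)
})

test_that("chunked execution is bit-compatible and coverage partitions the grid", {
  g <- unit_grid(c(4, 4, 4))
  f <- random_volume(g, nt = 7, seed = 51)
  mask_lin <- c(1, 22, 40)
  m <- brain_mask(g, fnkit:::linear_to_ijk(mask_lin, g$shape))
  pr <- random_priors(g, mask_lin, seed = 52)
  full <- project_voxelwise(f, m, pr)
  for (chunk in c(1, 2, 3, 5)) {
    res <- project_voxelwise(f, m, pr, frames_per_chunk = chunk)
    expect_identical(res$volume$data, full$volume$data)
  }
  expect_setequal(c(which(full$uncovered$data), which(full$coverage > 0)),
                  seq_len(64))
})

test_that("projection rejects bad masks and reports missing priors entries", {
  g <- unit_grid(c(4, 4, 4))
  f <- random_volume(g, nt = 3)
  m_empty <- brain_mask(g, array(FALSE, g$shape))
  pr <- delta_priors(g, full_mask(g))
  expect_error(project_voxelwise(f, m_empty, pr), "empty")
  pr_small <- delta_priors(g, brain_mask(g, rbind(c(0, 0, 0))))
  m2 <- brain_mask(g, rbind(c(0, 0, 0), c(2, 2, 2)))
  expect_error(project_voxelwise(f, m2, pr_small), "2_2_2")
  pr_region <- priors_store(g, "region", pr$W[, 1:2], c("1", "2"))
  expect_error(project_voxelwise(f, m2, pr_region), "not voxel-wise")
})

test_that("white-matter masking zeroes outside and only outside the mask", {
  g <- unit_grid(c(4, 4, 4))
  f <- random_volume(g, nt = 3, seed = 61)
  expect_equal(mask_to_white_matter(f, full_mask(g))$data, f$data)
  empty <- brain_mask(g, array(FALSE, g$shape))
  expect_true(all(mask_to_white_matter(f, empty)$data == 0))
  wm <- brain_mask(g, rbind(c(1, 1, 1), c(2, 2, 2)))
  masked <- mask_to_white_matter(f, wm)
  nz <- which(apply(masked$data != 0, 1:3, any))
  expect_true(all(nz %in% which(wm$data)))
})
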