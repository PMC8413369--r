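# Anatomical connectivity priors from streamline tractograms.
#
# For each seed (a voxel, or a parcellation region) and each subject, the
# streamlines intersecting the seed are rasterised and binarised into a
# visitation map; averaging those binary maps across subjects gives the
# population probability of a streamline linking the seed to every voxel.

#' Voxels traversed by a streamline
#'
#' The default backend resamples every segment at a step no larger than a
#' quarter of the smallest voxel edge and collects the containing voxels
#' (NIfTI center convention: the containing voxel of a world point is the
#' rounded continuous voxel coordinate).  `method = "exact"` walks the voxel
#' boundaries analytically (Amanatides-Woo traversal) instead and visits
#' every voxel whose box the polyline crosses.
#'
#' @param line numeric n x 3 matrix, a polyline in world mm (n >= 2, or a
#'   degenerate repeated point).
#' @param grid a `voxel_grid`.
#' @param method `"resample"` (default) or `"exact"`.
#' @param step resampling step in mm; default `min(voxel_size)/4`.
#' @return integer m x 3 matrix of unique 0-based voxel indices, ordered by
#'   linear array index; points outside the grid are dropped.
#' @export
rasterize_streamline <- function(line, grid,
                                 method = c("resample", "exact"),
                                 step = NULL) {
  method <- match.arg(method)
  line <- rbind_points(line)
  if (nrow(line) < 1) stop("empty polyline")
  lin <- if (method == "resample")
    rasterize_resample(line, grid, step %||% (min(grid$voxel_size) / 4))
  else
    rasterize_exact(line, grid)
  linear_to_ijk(sort(unique(lin)), grid$shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rasterize_resample <- function(line, grid, step) {
  pts <- resample_polyline(line, step)
  vox <- round(world_to_voxel(grid, pts))
  keep <- in_grid(vox, grid$shape)
  if (!any(keep)) return(integer(0))
  ijk_to_linear(vox[keep, , drop = FALSE], grid$shape)
}

resample_polyline <- function(line, step) {
  if (nrow(line) == 1) return(line)
  out <- vector("list", nrow(line) - 1L)
  for (s in seq_len(nrow(line) - 1L)) {
    p0 <- line[s, ]; p1 <- line[s + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(1L, ceiling(len / step))
    tt <- seq(0, 1, length.out = n + 1L)
    out[[s]] <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                      p0[2] + tt * (p1[2] - p0[2]),
                      p0[3] + tt * (p1[3] - p0[3]))
  }
  do.call(rbind, out)
}

# Exact voxel traversal: march each segment through the voxel boundary planes
# at half-integer continuous voxel coordinates.
rasterize_exact <- function(line, grid) {
  vox <- world_to_voxel(grid, line)   # continuous voxel coords
  lin <- integer(0)
  for (s in seq_len(max(1L, nrow(vox) - 1L))) {
    p0 <- vox[s, ]
    p1 <- vox[min(s + 1L, nrow(vox)), ]
    d <- p1 - p0
    # crossing parameters of the planes x_a = m + 0.5 for each axis
    tcross <- numeric(0)
    for (a in 1:3) {
      if (abs(d[a]) < 1e-12) next
      lo <- min(p0[a], p1[a]); hi <- max(p0[a], p1[a])
      planes <- seq(floor(lo - 0.5) + 0.5, ceiling(hi + 0.5) - 0.5, by = 1)
      planes <- planes[planes > lo & planes < hi]
      if (length(planes)) tcross <- c(tcross, (planes - p0[a]) / d[a])
    }
    tcross <- sort(unique(c(0, tcross[tcross > 0 & tcross < 1], 1)))
    # midpoint of each sub-interval lies strictly inside one voxel
    tmid <- (head(tcross, -1) + tcross[-1]) / 2
    if (!length(tmid)) tmid <- 0.5
    pm <- cbind(p0[1] + tmid * d[1], p0[2] + tmid * d[2], p0[3] + tmid * d[3])
    v <- round(pm)
    keep <- in_grid(v, grid$shape)
    if (any(keep)) lin <- c(lin, ijk_to_linear(v[keep, , drop = FALSE],
                                               grid$shape))
  }
  lin
}

#' Binary visitation map of the streamlines passing through a seed
#'
#' Selects the streamlines whose rasterisation intersects the seed voxel (or
#' any voxel of the seed region) and marks every voxel those selected
#' streamlines traverse.  A seed crossed by no streamline yields an all-zero
#' map, not an error.
#'
#' @param streamlines a `streamline_set`.
#' @param seed a length-3 0-based voxel index, or a region label paired with
#'   `parc`.
#' @param grid a `voxel_grid`.
#' @param parc a `parcellation` when `seed` is a region label.
#' @param method,step passed to [rasterize_streamline()].
#' @return a binary [probability_map()].
#' @export
visitation_map <- function(streamlines, seed, grid, parc = NULL,
                           method = "resample", step = NULL) {
  stopifnot(inherits(streamlines, "streamline_set"))
  seed_lin <- seed_linear(seed, grid, parc)
  rast <- lapply(streamlines$streamlines, function(s)
    ijk_to_linear(rasterize_streamline(s, grid, method = method, step = step),
                  grid$shape))
  hit <- vapply(rast, function(v) any(v %in% seed_lin), logical(1))
  arr <- array(0, grid$shape)
  if (any(hit)) arr[unique(unlist(rast[hit]))] <- 1
  probability_map(grid, arr)
}

seed_linear <- function(seed, grid, parc) {
  if (!is.null(parc)) {
    stopifnot(inherits(parc, "parcellation"))
    stop_unless_same_grid(grid, parc, "grid and parcellation")
    lin <- which(parc$labels == as.integer(seed))
    if (!length(lin)) stop("region ", seed, " has no voxels")
    return(lin)
  }
  seed <- as.integer(seed)
  stopifnot(length(seed) == 3)
  if (!all(in_grid(matrix(seed, 1), grid$shape))) stop("seed outside grid")
  ijk_to_linear(seed, grid$shape)
}

#' Build an anatomical priors store from per-subject tractograms
#'
#' For every seed the subject-level visitation maps (binary streamline
#' rasterisations) are averaged, so each stored probability equals k/n with
#' k the number of subjects in which the seed-to-voxel link exists.  Seeds
#' that no streamline crosses keep an all-zero entry so that projection can
#' report uncovered voxels explicitly; no thresholding is applied.
#'
#' @param subjects list of `streamline_set`, one per subject (>= 1).
#' @param seeds a `brain_mask` (voxel-wise priors, one entry per mask voxel)
#'   or a `parcellation` (region-wise priors, one entry per nonzero label).
#' @param grid a `voxel_grid`; defaults to the grid of `seeds`.
#' @param method,step passed to [rasterize_streamline()].
#' @return a `priors_store` with `mode` `"voxel"` or `"region"`.
#' @export
build_priors <- function(subjects, seeds, grid = NULL,
                         method = "resample", step = NULL) {
  if (!length(subjects)) stop("need at least one subject")
  stopifnot(all(vapply(subjects, inherits, logical(1), "streamline_set")))
  grid <- grid %||% grid_of(seeds)
  stop_unless_same_grid(grid, seeds, "grid and seeds")
  if (inherits(seeds, "brain_mask")) {
    mode <- "voxel"
    lin <- which(seeds$data)
    if (!length(lin)) stop("empty seed mask")
    seed_sets <- as.list(lin)
    keys <- apply(linear_to_ijk(lin, grid$shape), 1, paste, collapse = "_")
  } else if (inherits(seeds, "parcellation")) {
    mode <- "region"
    labs <- setdiff(sort(unique(as.vector(seeds$labels))), 0L)
    if (!length(labs)) stop("parcellation has no regions")
    seed_sets <- lapply(labs, function(l) which(seeds$labels == l))
    keys <- as.character(labs)
  } else stop("seeds must be a brain_mask or a parcellation")

  n_sub <- length(subjects)
  nvox <- prod(grid$shape)
  trip_i <- list(); trip_j <- list()
  for (sub in subjects) {
    rast <- lapply(sub$streamlines, function(s)
      ijk_to_linear(rasterize_streamline(s, grid, method = method,
                                         step = step), grid$shape))
    # inverted index voxel -> streamline ids
    vox_all <- unlist(rast)
    sl_id <- rep.int(seq_along(rast), vapply(rast, length, integer(1)))
    for (q in seq_along(seed_sets)) {
      hits <- unique(sl_id[vox_all %in% seed_sets[[q]]])
      if (!length(hits)) next
      vis <- unique(unlist(rast[hits]))
      trip_i[[length(trip_i) + 1L]] <- vis
      trip_j[[length(trip_j) + 1L]] <- rep.int(q, length(vis))
    }
  }
  W <- Matrix::sparseMatrix(i = unlist(trip_i) %||% integer(0),
                            j = unlist(trip_j) %||% integer(0),
                            x = 1 / n_sub,
                            dims = c(nvox, length(seed_sets)))
  priors_store(grid, mode, W, keys)
}

# ---- priors store container --------------------------------------------------

#' Keyed container of probability maps sharing one grid
#'
#' Entries are held column-wise in one sparse matrix (`prod(shape)` rows, one
#' column per seed), which is both the in-memory layout and what the
#' projection consumes.  Voxel-wise keys are `"i_j_k"` strings of 0-based
#' indices; region-wise keys are the label numbers as strings.
#'
#' @param grid a `voxel_grid`.
#' @param mode `"voxel"` or `"region"`.
#' @param W sparse (or dense) matrix, `prod(grid$shape)` x `length(keys)`,
#'   values in `[0,1]`.
#' @param keys unique character keys, one per column.
#' @return object of class `priors_store`.
#' @export
priors_store <- function(grid, mode = c("voxel", "region"), W, keys) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "voxel_grid"))
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  if (nrow(W) != prod(grid$shape)) stop("W rows must equal prod(shape)")
  if (ncol(W) != length(keys)) stop("one key per column required")
  if (anyDuplicated(keys)) stop("duplicate seed keys")
  rng <- range(0, W@x)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) stop("priors values outside [0,1]")
  colnames(W) <- keys
  structure(list(grid = grid, mode = mode, W = W,
                 keys = as.character(keys)),
            class = "priors_store")
}

#' @export
print.priors_store <- function(x, ...) {
  cat(sprintf("<priors_store> %s-wise, %d seeds on %s grid, %.2f%% nonzero\n",
              x$mode, length(x$keys), paste(x$grid$shape, collapse = "x"),
              100 * length(x$W@x) / prod(dim(x$W))))
  invisible(x)
}

#' @rdname priors_store
#' @param store a `priors_store`.
#' @export
priors_keys <- function(store) store$keys

#' Fetch one entry of a priors store as a probability map
#'
#' @param store a `priors_store`.
#' @param key a seed key: `"i_j_k"` string or length-3 0-based voxel index
#'   (voxel mode); label number or string (region mode).
#' @return a [probability_map()].
#' @export
priors_entry <- function(store, key) {
  key <- normalize_key(store, key)
  j <- match(key, store$keys)
  if (is.na(j)) stop("no priors entry for seed ", key)
  arr <- array(0, store$grid$shape)
  col <- store$W[, j]
  arr[seq_along(arr)] <- as.numeric(col)
  probability_map(store$grid, arr)
}

normalize_key <- function(store, key) {
  if (is.numeric(key) && length(key) == 3 && store$mode == "voxel")
    return(paste(as.integer(key), collapse = "_"))
  as.character(key)
}

#' Key string for a voxel seed
#' @param ijk length-3 0-based voxel index.
#' @return the `"i_j_k"` key used by voxel-wise priors stores.
#' @export
voxel_key <- function(ijk) paste(as.integer(ijk), collapse = "_")

# ---- persistence -------------------------------------------------------------

#' Save / load a priors store
#'
#' One archive file per store: a version-tagged RDS container holding the
#' grid attributes (mode, shape, affine) and a sparse record of nonzero
#' voxels per seed, mirroring the group-per-seed layout of HDF5-style priors
#' archives.
#'
#' @param store a `priors_store`.
#' @param path archive path (conventionally `.rds`).
#' @return `write_priors` returns `path` invisibly; `read_priors` the store.
#' @export
write_priors <- function(store, path) {
  stopifnot(inherits(store, "priors_store"))
  payload <- list(format = "fnkit-priors", version = 1L,
                  mode = store$mode, shape = store$grid$shape,
                  affine = store$grid$affine, keys = store$keys,
                  i = store$W@i, p = store$W@p, x = store$W@x)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "fnkit-priors"))
    stop("not a priors archive: ", path)
  grid <- voxel_grid(payload$shape, payload$affine)
  W <- Matrix::sparseMatrix(i = payload$i + 1L, p = payload$p,
                            x = payload$x,
                            dims = c(prod(payload$shape),
                                     length(payload$keys)))
  priors_store(grid, payload$mode, W, payload$keys)
}
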