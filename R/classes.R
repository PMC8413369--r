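#' @importFrom methods is
#' @importFrom stats convolve cor dgamma median pnorm pt qnorm quantile rnorm sd
#' @importFrom utils head read.delim write.table
NULL

# ---- voxel grid --------------------------------------------------------------

#' Voxel grid: shape, affine and voxel size
#'
#' A `voxel_grid` ties a 3D array shape to world (scanner) space through a
#' 4x4 voxel-to-world affine in mm, following the NIfTI convention: voxel
#' indices are 0-based and the world position of the *center* of voxel
#' `(i,j,k)` is `affine %*% c(i,j,k,1)`.  Voxel `(i,j,k)` therefore occupies
#' the half-open box `[i-0.5, i+0.5) x [j-0.5, j+0.5) x [k-0.5, k+0.5)` in
#' continuous voxel coordinates.
#'
#' @param shape integer vector of length 3, all positive.
#' @param affine 4x4 numeric voxel-to-world matrix (mm); must be invertible
#'   with last row `c(0,0,0,1)`.
#' @return An object of class `voxel_grid` with fields `shape`, `affine` and
#'   `voxel_size` (the Euclidean norms of the first three affine columns).
#' @examples
#' g <- voxel_grid(c(20, 20, 20), diag(c(2, 2, 2, 1)))
#' g$voxel_size
#' @export
voxel_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine is singular")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last affine row must be (0,0,0,1)")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(shape = shape, affine = affine, voxel_size = vs),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s, voxel size %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Extract the voxel grid of a grid-bearing object
#'
#' @param x a `voxel_grid` or any fnkit container carrying one
#'   (`functional_volume`, `brain_mask`, `probability_map`, `parcellation`,
#'   `priors_store`, `stat_map`, `projection_result`).
#' @return the underlying `voxel_grid`.
#' @export
grid_of <- function(x) {
  if (inherits(x, "voxel_grid")) return(x)
  if (!is.null(x$grid) && inherits(x$grid, "voxel_grid")) return(x$grid)
  if (inherits(x, "projection_result")) return(x$volume$grid)
  stop("object does not carry a voxel grid")
}

#' Test whether two objects live on the same voxel grid
#'
#' Grids match when the shapes are identical and the affines agree entry-wise
#' within an absolute tolerance (default 1e-4 mm).  A pure predicate: callers
#' decide whether a mismatch is an error.
#'
#' @param a,b grid-bearing objects (see [grid_of()]).
#' @param tol absolute tolerance on affine entries, in mm.
#' @return `TRUE` or `FALSE`.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  ga <- grid_of(a); gb <- grid_of(b)
  identical(ga$shape, gb$shape) && max(abs(ga$affine - gb$affine)) <= tol
}

stop_unless_same_grid <- function(a, b, what = "inputs") {
  if (!check_same_grid(a, b))
    stop(sprintf("grid mismatch between %s", what))
  invisible(TRUE)
}

# ---- coordinate transforms ---------------------------------------------------

#' Convert world coordinates (mm) to continuous 0-based voxel coordinates
#'
#' @param grid a `voxel_grid`.
#' @param xyz numeric n x 3 matrix (or length-3 vector) of world points in mm.
#' @return n x 3 matrix of continuous voxel coordinates; the containing voxel
#'   of a point is `round()` of its row (NIfTI center convention).
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind_points(xyz)
  inv <- solve(grid$affine)
  v <- cbind(xyz, 1) %*% t(inv)
  v[, 1:3, drop = FALSE]
}

#' Convert 0-based voxel coordinates to world coordinates (mm)
#'
#' @param grid a `voxel_grid`.
#' @param ijk numeric n x 3 matrix (or length-3 vector) of voxel coordinates
#'   (may be fractional).
#' @return n x 3 matrix of world points (mm), voxel centers for integer input.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind_points(ijk)
  w <- cbind(ijk, 1) %*% t(grid$affine)
  w[, 1:3, drop = FALSE]
}

rbind_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  x
}

# 0-based ijk matrix <-> 1-based linear index into an array of dim `shape`
ijk_to_linear <- function(ijk, shape) {
  ijk <- rbind_points(ijk)
  as.integer(1 + ijk[, 1] + shape[1] * (ijk[, 2] + shape[2] * ijk[, 3]))
}

linear_to_ijk <- function(lin, shape) {
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% shape[1]
  j <- (lin0 %/% shape[1]) %% shape[2]
  k <- lin0 %/% (shape[1] * shape[2])
  cbind(i = i, j = j, k = k)
}

in_grid <- function(ijk, shape) {
  ijk[, 1] >= 0 & ijk[, 1] < shape[1] &
  ijk[, 2] >= 0 & ijk[, 2] < shape[2] &
  ijk[, 3] >= 0 & ijk[, 3] < shape[3]
}

# ---- containers --------------------------------------------------------------

#' 4D functional volume (BOLD or functionnectome)
#'
#' @param grid a `voxel_grid`.
#' @param data 4D numeric array `(x, y, z, t)`; all values finite; at least
#'   one frame.
#' @param tr repetition time in seconds.
#' @return object of class `functional_volume`.
#' @export
functional_volume <- function(grid, data, tr) {
  stopifnot(inherits(grid, "voxel_grid"))
  data <- as_array(data, 4L)
  if (!identical(dim(data)[1:3], grid$shape))
    stop("data shape does not match grid")
  if (dim(data)[4] < 1L) stop("need at least one frame")
  if (!all(is.finite(data))) stop("non-finite values in functional data")
  stopifnot(is.numeric(tr), tr > 0)
  structure(list(grid = grid, data = data, tr = as.numeric(tr)),
            class = "functional_volume")
}

#' @export
print.functional_volume <- function(x, ...) {
  cat(sprintf("<functional_volume> %s frames x %s, TR %.3g s\n",
              dim(x$data)[4], paste(x$grid$shape, collapse = "x"), x$tr))
  invisible(x)
}

#' Binary voxel mask
#'
#' @param grid a `voxel_grid`.
#' @param data logical (or coercible) 3D array matching the grid shape, or an
#'   n x 3 matrix of 0-based voxel indices to set.
#' @return object of class `brain_mask` with a logical 3D `data` field.
#' @export
brain_mask <- function(grid, data) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.matrix(data) && ncol(data) == 3L && length(dim(data)) == 2L) {
    arr <- array(FALSE, grid$shape)
    if (nrow(data)) {
      if (!all(in_grid(data, grid$shape))) stop("mask voxel outside grid")
      arr[ijk_to_linear(data, grid$shape)] <- TRUE
    }
    data <- arr
  } else {
    data <- as_array(data, 3L)
    if (!identical(dim(data), grid$shape)) stop("mask shape does not match grid")
    data <- array(data > 0, grid$shape)
  }
  structure(list(grid = grid, data = data), class = "brain_mask")
}

#' 0-based voxel indices of a mask
#'
#' @param mask a `brain_mask`.
#' @return integer n x 3 matrix of 0-based `(i,j,k)` indices, ordered by
#'   linear (column-major) array index.
#' @export
mask_voxels <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  linear_to_ijk(which(mask$data), mask$grid$shape)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d of %d voxels set\n",
              sum(x$data), prod(x$grid$shape)))
  invisible(x)
}

#' 3D probability-of-connection map
#'
#' Values must lie in `[0, 1]`; a tiny numerical overshoot (<= 1e-9) is
#' clamped.
#'
#' @param grid a `voxel_grid`.
#' @param data 3D numeric array in `[0,1]`.
#' @return object of class `probability_map`.
#' @export
probability_map <- function(grid, data) {
  stopifnot(inherits(grid, "voxel_grid"))
  data <- as_array(data, 3L)
  if (!identical(dim(data), grid$shape)) stop("data shape does not match grid")
  if (any(!is.finite(data))) stop("non-finite probability values")
  if (min(data) < -1e-9 || max(data) > 1 + 1e-9)
    stop("probability values outside [0, 1]")
  data[data < 0] <- 0; data[data > 1] <- 1
  structure(list(grid = grid, data = data), class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s, %d nonzero voxels\n",
              paste(x$grid$shape, collapse = "x"), sum(x$data > 0)))
  invisible(x)
}

#' Integer-labelled parcellation (0 = background)
#'
#' @param grid a `voxel_grid`.
#' @param labels 3D array of non-negative integers.
#' @return object of class `parcellation`.
#' @export
parcellation <- function(grid, labels) {
  stopifnot(inherits(grid, "voxel_grid"))
  labels <- as_array(labels, 3L)
  if (!identical(dim(labels), grid$shape)) stop("labels shape does not match grid")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(grid = grid, labels = labels), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("<parcellation> %s, %d regions\n",
              paste(x$grid$shape, collapse = "x"), length(labs)))
  invisible(x)
}

#' Per-subject set of streamlines in world coordinates
#'
#' @param streamlines list of numeric n x 3 matrices (n >= 2 unless the
#'   streamline is a degenerate single repeated point), world mm.
#' @param subject_id identifier string.
#' @return object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, subject_id = "subject") {
  stopifnot(is.list(streamlines))
  streamlines <- lapply(streamlines, function(s) {
    s <- rbind_points(s)
    if (nrow(s) < 2) stop("streamline needs >= 2 points")
    if (!all(is.finite(s))) stop("non-finite streamline point")
    s
  })
  structure(list(streamlines = streamlines,
                 subject_id = as.character(subject_id)),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<streamline_set> '%s': %d streamlines, %d points total\n",
              x$subject_id, length(np), sum(np)))
  invisible(x)
}

#' Voxel-wise statistic map (beta / t / z) with its analysis mask
#'
#' @param grid a `voxel_grid`.
#' @param beta,t,z 3D arrays; finite on the mask, 0 elsewhere.
#' @param dof residual (or group) degrees of freedom, >= 1.
#' @param mask the `brain_mask` the statistics were computed on.
#' @return object of class `stat_map`.
#' @export
stat_map <- function(grid, beta, t, z, dof, mask) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "brain_mask"))
  stop_unless_same_grid(grid, mask, "stat map and mask")
  beta <- as_array(beta, 3L); t <- as_array(t, 3L); z <- as_array(z, 3L)
  for (a in list(beta, t, z)) {
    if (!identical(dim(a), grid$shape)) stop("stat array shape mismatch")
    if (!all(is.finite(a[mask$data]))) stop("non-finite statistic on mask")
  }
  stopifnot(dof >= 1)
  structure(list(grid = grid, beta = beta, t = t, z = z,
                 dof = as.integer(dof), mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  zm <- x$z[x$mask$data]
  cat(sprintf("<stat_map> dof %d, %d mask voxels, z range [%.3g, %.3g]\n",
              x$dof, sum(x$mask$data), min(zm), max(zm)))
  invisible(x)
}

as_array <- function(x, ndim) {
  x <- unclass(x)
  attributes(x) <- attributes(x)["dim"]
  if (is.null(dim(x))) stop(sprintf("expected a %dD array", ndim))
  if (length(dim(x)) == ndim + 1L && dim(x)[ndim + 1L] == 1L)
    dim(x) <- dim(x)[seq_len(ndim)]
  if (length(dim(x)) != ndim) stop(sprintf("expected a %dD array, got %dD",
                                           ndim, length(dim(x))))
  storage.mode(x) <- "double"
  x
}
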