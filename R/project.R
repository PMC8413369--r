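# The functionnectome transform: replace each voxel's signal with the
# connectivity-weighted average of grey-matter BOLD from the voxels
# structurally connected to it,
#
#   out(v,t) = sum_{m in M} P_m(v) F(m,t)  /  sum_{m in M} P_m(v),
#
# where M is the analysis mask and P_m the anatomical prior of seed m.  The
# division keeps every covered voxel in the range of the contributing BOLD
# values; voxels whose denominator is zero carry no projected signal and are
# returned as an explicit "uncovered" mask (their output is 0 at all times).

#' Result of a functionnectome projection
#'
#' @param volume the projected `functional_volume`.
#' @param coverage 3D array of the per-voxel denominator, the summed
#'   connection probabilities over the mask seeds.
#' @param uncovered `brain_mask` of voxels with zero denominator.
#' @return object of class `projection_result`.
#' @export
projection_result <- function(volume, coverage, uncovered) {
  stopifnot(inherits(volume, "functional_volume"),
            inherits(uncovered, "brain_mask"))
  coverage <- as_array(coverage, 3L)
  stop_unless_same_grid(volume, uncovered, "volume and coverage")
  if (!identical(which(coverage == 0), which(uncovered$data)))
    stop("uncovered mask must be exactly the zero-coverage voxels")
  structure(list(volume = volume, coverage = coverage, uncovered = uncovered),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %d frames, %d covered / %d uncovered voxels\n",
              dim(x$volume$data)[4], sum(x$coverage > 0), sum(x$uncovered$data)))
  invisible(x)
}

#' Project BOLD onto white matter with voxel-wise priors
#'
#' Every voxel of the analysis mask `m` contributes its full time-series,
#' weighted at each target voxel `v` by the prior probability `P_m(v)` that a
#' streamline links `m` to `v`; the weighted sum is divided by the summed
#' probabilities so covered voxels stay in the range of the input BOLD.
#'
#' @param f a `functional_volume` (grey-matter BOLD).
#' @param m a `brain_mask` selecting the seed voxels whose signal is
#'   projected; every mask voxel must have a priors entry.
#' @param priors a voxel-wise `priors_store` on the same grid.
#' @param frames_per_chunk optional time-chunk size; the chunked path is
#'   bit-identical to the all-in-memory path and only bounds peak memory.
#' @return a [projection_result()] defined on the full grid.
#' @export
project_voxelwise <- function(f, m, priors, frames_per_chunk = Inf) {
  stopifnot(inherits(f, "functional_volume"), inherits(m, "brain_mask"),
            inherits(priors, "priors_store"))
  if (priors$mode != "voxel") stop("priors store is not voxel-wise")
  stop_unless_same_grid(f, m, "BOLD and mask")
  stop_unless_same_grid(f, priors, "BOLD and priors")
  lin <- which(m$data)
  if (!length(lin)) stop("empty analysis mask")
  keys <- apply(linear_to_ijk(lin, f$grid$shape), 1, paste, collapse = "_")
  j <- match(keys, priors$keys)
  if (anyNA(j))
    stop("mask voxels missing from priors: ",
         paste(head(keys[is.na(j)], 10), collapse = ", "),
         if (sum(is.na(j)) > 10) " ...")
  series <- series_matrix(f, lin)             # n_mask x T
  project_core(f, priors$W[, j, drop = FALSE], series, frames_per_chunk)
}

#' Project BOLD onto white matter with region-wise ("simplified") priors
#'
#' Same contract as [project_voxelwise()], but each parcellation region
#' contributes the mean time-series of its voxels, weighted by the region's
#' prior map.  With singleton regions and matching priors this reduces
#' exactly to the voxel-wise projection.
#'
#' @param f a `functional_volume`.
#' @param parc a `parcellation`; every nonzero label must have a priors
#'   entry and at least one voxel.
#' @param priors a region-wise `priors_store` on the same grid.
#' @param frames_per_chunk as in [project_voxelwise()].
#' @return a [projection_result()].
#' @export
project_regionwise <- function(f, parc, priors, frames_per_chunk = Inf) {
  stopifnot(inherits(f, "functional_volume"), inherits(parc, "parcellation"),
            inherits(priors, "priors_store"))
  if (priors$mode != "region") stop("priors store is not region-wise")
  stop_unless_same_grid(f, parc, "BOLD and parcellation")
  stop_unless_same_grid(f, priors, "BOLD and priors")
  labs <- setdiff(sort(unique(as.vector(parc$labels))), 0L)
  if (!length(labs)) stop("parcellation has no regions")
  j <- match(as.character(labs), priors$keys)
  if (anyNA(j))
    stop("regions missing from priors: ",
         paste(labs[is.na(j)], collapse = ", "))
  nt <- dim(f$data)[4]
  series <- matrix(0, length(labs), nt)       # region-mean time-series
  for (q in seq_along(labs)) {
    lin <- which(parc$labels == labs[q])
    if (!length(lin)) stop("region ", labs[q], " has no voxels")
    series[q, ] <- colMeans(series_matrix(f, lin))
  }
  project_core(f, priors$W[, j, drop = FALSE], series, frames_per_chunk)
}

series_matrix <- function(f, lin) {
  nt <- dim(f$data)[4]
  nv <- prod(f$grid$shape)
  dim(f$data) <- c(nv, nt)
  out <- f$data[lin, , drop = FALSE]
  out
}

project_core <- function(f, W, series, frames_per_chunk) {
  nt <- ncol(series)
  denom <- Matrix::rowSums(W)
  covered <- denom > 0
  out <- matrix(0, nrow(W), nt)
  chunk <- if (is.finite(frames_per_chunk))
    max(1L, as.integer(frames_per_chunk)) else nt
  for (s in seq(1L, nt, by = chunk)) {
    idx <- s:min(s + chunk - 1L, nt)
    num <- as.matrix(W %*% series[, idx, drop = FALSE])
    out[covered, idx] <- num[covered, , drop = FALSE] / denom[covered]
  }
  vol <- functional_volume(f$grid, array(out, c(f$grid$shape, nt)), tr = f$tr)
  cov_arr <- array(denom, f$grid$shape)
  projection_result(vol, cov_arr,
                    brain_mask(f$grid, array(!covered, f$grid$shape)))
}

#' Restrict a map or projection to a white-matter mask (display helper)
#'
#' Zeroes every value outside `wm`.  Intended for reporting and
#' visualisation only — statistics are always computed on unmasked maps.
#'
#' @param x a `projection_result`, `stat_map`, `functional_volume` or
#'   `probability_map`.
#' @param wm a `brain_mask` on the same grid.
#' @return an object of the same class as `x`.
#' @export
mask_to_white_matter <- function(x, wm) {
  stopifnot(inherits(wm, "brain_mask"))
  stop_unless_same_grid(x, wm, "input and white-matter mask")
  keep <- wm$data
  if (inherits(x, "projection_result")) {
    v <- x$volume
    v$data <- v$data * as.numeric(rep(keep, dim(v$data)[4]))
    cov <- x$coverage; cov[!keep] <- 0
    unc <- brain_mask(v$grid, array(cov == 0, v$grid$shape))
    return(projection_result(v, cov, unc))
  }
  if (inherits(x, "stat_map")) {
    x$beta[!keep] <- 0; x$t[!keep] <- 0; x$z[!keep] <- 0
    x$mask <- brain_mask(x$grid, x$mask$data & keep)
    return(x)
  }
  if (inherits(x, "functional_volume")) {
    x$data <- x$data * as.numeric(rep(keep, dim(x$data)[4]))
    return(x)
  }
  if (inherits(x, "probability_map")) {
    x$data[!keep] <- 0
    return(x)
  }
  stop("unsupported type for mask_to_white_matter")
}
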