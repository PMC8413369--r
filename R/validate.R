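# Spatial map-comparison statistics: Pearson correlation between maps inside
# a brain mask (reproducibility of z-maps across runs) and cross-correlation
# matrices between two sets of spatial maps with best-match assignment.

map_values <- function(x, lin) {
  if (inherits(x, "stat_map")) return(x$z[lin])
  if (inherits(x, "probability_map")) return(x$data[lin])
  if (is.array(x) && length(dim(x)) == 3) return(x[lin])
  stop("expected a stat_map, probability_map or 3D array")
}

#' Spatial Pearson correlation between two maps
#'
#' Standard Pearson r over the voxels of `mask` (operationalising "excluding
#' voxels outside the brain" as a caller-supplied mask).  Errors when fewer
#' than 3 mask voxels are available or either map is constant on the mask.
#'
#' @param a,b `stat_map` (its z array is used), `probability_map` or bare 3D
#'   array, on a shared grid.
#' @param mask a `brain_mask`; default is the union of nonzero voxels of the
#'   two maps.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_spatial <- function(a, b, mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "brain_mask"))
    if (!is.array(a)) stop_unless_same_grid(a, mask, "map and mask")
    if (!is.array(b)) stop_unless_same_grid(b, mask, "map and mask")
    lin <- which(mask$data)
  } else {
    ga <- if (is.array(a)) NULL else grid_of(a)
    if (!is.array(a) && !is.array(b)) stop_unless_same_grid(a, b, "maps")
    va <- map_values(a, seq_len(length_of_map(a)))
    vb <- map_values(b, seq_len(length_of_map(b)))
    lin <- which(va != 0 | vb != 0)
  }
  if (length(lin) < 3) stop("need at least 3 voxels to correlate")
  va <- map_values(a, lin); vb <- map_values(b, lin)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("zero variance inside the mask; correlation undefined")
  cor(va, vb)
}

length_of_map <- function(x) {
  if (is.array(x)) length(x) else prod(grid_of(x)$shape)
}

#' Cross-correlation matrix between two sets of spatial maps
#'
#' Entry `(i, j)` is the spatial Pearson correlation of `set_a[[i]]` with
#' `set_b[[j]]` over `mask`.  By default the negative part of every map is
#' zeroed before correlating (the usual convention when matching component
#' maps), and the best match of each row is returned alongside.
#'
#' @param set_a,set_b lists of maps (see [pearson_spatial()]).
#' @param mask a `brain_mask`; default is the union of nonzero voxels over
#'   all maps.
#' @param zero_negative zero negative values first (default `TRUE`).
#' @return list with `r` (`|A| x |B|` matrix) and `best_match` (per-row
#'   argmax column index).
#' @export
crosscorr_matrix <- function(set_a, set_b, mask = NULL, zero_negative = TRUE) {
  stopifnot(length(set_a) >= 1, length(set_b) >= 1)
  vals <- function(x) {
    v <- map_values(x, seq_len(length_of_map(x)))
    if (zero_negative) v[v < 0] <- 0
    v
  }
  A <- vapply(set_a, vals, numeric(length_of_map(set_a[[1]])))
  B <- vapply(set_b, vals, numeric(length_of_map(set_b[[1]])))
  if (nrow(A) != nrow(B)) stop("map sets live on different grids")
  lin <- if (!is.null(mask)) which(mask$data)
         else which(rowSums(abs(A)) + rowSums(abs(B)) > 0)
  if (length(lin) < 3) stop("need at least 3 voxels to correlate")
  A <- A[lin, , drop = FALSE]; B <- B[lin, , drop = FALSE]
  if (any(apply(A, 2, sd) == 0) || any(apply(B, 2, sd) == 0))
    stop("a map has zero variance inside the mask")
  r <- cor(A, B)
  dimnames(r) <- list(names(set_a), names(set_b))
  list(r = r, best_match = apply(r, 1, which.max))
}

#' Run-to-run reproducibility of z-maps
#'
#' Pearson correlation between the run-1 and run-2 group z-map of each task,
#' one row per task, plus the mean and standard deviation across tasks — the
#' summary used to compare analysis arms (e.g. functionnectome
#' vs. classical).
#'
#' @param zmaps_run1,zmaps_run2 named lists of `stat_map` (or 3D arrays),
#'   paired by name/position; names are the task labels.
#' @param mask a `brain_mask` passed to [pearson_spatial()].
#' @return data.frame with columns `task` and `r`; attributes `mean_r` and
#'   `sd_r` carry the across-task summary.
#' @export
reproducibility_report <- function(zmaps_run1, zmaps_run2, mask = NULL) {
  if (length(zmaps_run1) != length(zmaps_run2))
    stop("unpaired inputs: run lists differ in length")
  tasks <- names(zmaps_run1) %||% paste0("task", seq_along(zmaps_run1))
  if (!is.null(names(zmaps_run2)) &&
      !identical(sort(tasks), sort(names(zmaps_run2))))
    stop("unpaired inputs: task names differ between runs")
  if (!is.null(names(zmaps_run2))) zmaps_run2 <- zmaps_run2[tasks]
  r <- vapply(seq_along(tasks), function(i)
    pearson_spatial(zmaps_run1[[i]], zmaps_run2[[i]], mask), numeric(1))
  out <- data.frame(task = tasks, r = r, row.names = NULL)
  attr(out, "mean_r") <- mean(r)
  attr(out, "sd_r") <- if (length(r) > 1) sd(r) else 0
  out
}

#' Write a reproducibility table (or any data.frame) as TSV
#'
#' @param x data.frame, e.g. from [reproducibility_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
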