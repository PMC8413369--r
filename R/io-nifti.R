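# NIfTI I/O via RNifti; on-disk volumes are float32, internal arithmetic is
# double.

grid_from_nifti <- function(im) {
  aff <- structure(RNifti::xform(im), imagedim = NULL, code = NULL)
  attributes(aff) <- attributes(aff)["dim"]
  voxel_grid(dim(im)[1:3], aff)
}

#' Read a NIfTI file as one of the fnkit containers
#'
#' A single reader dispatches on the role the caller wants the file to play:
#' 4D files become [functional_volume()] objects, 3D files become probability
#' maps, masks (binarised at `> 0`) or parcellations.  `role = "auto"` picks
#' `"functional"` for 4D data and `"probability"` for 3D data whose values
#' lie in `[0,1]`, otherwise `"mask"`.
#'
#' @param path NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param role one of `"auto"`, `"functional"`, `"probability"`, `"mask"`,
#'   `"parcellation"`.
#' @param tr repetition time override in seconds; default taken from the
#'   header's 4th `pixdim` entry.
#' @return a `functional_volume`, `probability_map`, `brain_mask` or
#'   `parcellation`.
#' @export
read_volume <- function(path,
                        role = c("auto", "functional", "probability",
                                 "mask", "parcellation"),
                        tr = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  nd <- length(dim(im))
  if (nd < 3 || nd > 4) stop("expected a 3D or 4D NIfTI, got ", nd, "D")
  grid <- grid_from_nifti(im)
  arr <- as.array(im)
  if (role == "auto")
    role <- if (nd == 4) "functional"
            else if (min(arr) >= 0 && max(arr) <= 1) "probability" else "mask"
  switch(role,
    functional = {
      if (nd == 3) dim(arr) <- c(dim(arr), 1L)
      if (is.null(tr)) {
        pd <- RNifti::pixdim(im)
        tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
      }
      functional_volume(grid, arr, tr = tr)
    },
    probability = {
      if (nd != 3) stop("probability map must be 3D")
      probability_map(grid, arr)
    },
    mask = {
      if (nd != 3) stop("mask must be 3D")
      brain_mask(grid, arr > 0)
    },
    parcellation = {
      if (nd != 3) stop("parcellation must be 3D")
      parcellation(grid, round(arr))
    })
}

#' Write an fnkit container to a NIfTI file
#'
#' Volumes are stored as float32; masks and parcellations as integers.  The
#' grid affine goes into both qform and sform (code 2), and a functional
#' volume's TR into the 4th `pixdim` slot.
#'
#' @param x a `functional_volume`, `probability_map`, `brain_mask`,
#'   `parcellation`, `stat_map` (its z array is written) or a bare 3D/4D
#'   array paired with `grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid required only when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  tr <- NULL
  if (inherits(x, "functional_volume")) {
    arr <- x$data; grid <- x$grid; tr <- x$tr; dt <- "float"
  } else if (inherits(x, "probability_map")) {
    arr <- x$data; grid <- x$grid; dt <- "float"
  } else if (inherits(x, "brain_mask")) {
    arr <- array(as.integer(x$data), x$grid$shape); grid <- x$grid; dt <- "uint8"
  } else if (inherits(x, "parcellation")) {
    arr <- x$labels; grid <- x$grid; dt <- "int16"
  } else if (inherits(x, "stat_map")) {
    arr <- x$z; grid <- x$grid; dt <- "float"
  } else if (is.array(x)) {
    if (is.null(grid)) stop("grid required to write a bare array")
    arr <- x; dt <- "float"
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  im <- RNifti::asNifti(arr)
  aff <- structure(grid$affine, code = 2L)
  RNifti::qform(im) <- aff
  RNifti::sform(im) <- aff
  # pixdim must be set explicitly or writeNifti discards the stored xform
  RNifti::pixdim(im) <- if (is.null(tr)) grid$voxel_size
                        else c(grid$voxel_size, tr)
  RNifti::writeNifti(im, path, datatype = dt)
  invisible(path)
}
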