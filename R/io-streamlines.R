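# TRK / TCK streamline file I/O.
#
# Both formats are read into world-mm (RAS) polylines regardless of the
# on-disk convention: TCK already stores world mm; TRK stores "voxmm" points
# (continuous voxel coordinate + half voxel, scaled by voxel size) plus a
# voxel-to-RAS affine in its version-2 header.

#' Read a TRK or TCK streamline file
#'
#' @param path file ending in `.trk` or `.tck` (format also detected from the
#'   magic bytes when the extension is unusual).
#' @param subject_id identifier stored on the returned set; defaults to the
#'   file name without extension.
#' @return a [streamline_set()] with polylines in world mm.  A well-formed
#'   file containing zero streamlines yields an empty set with a warning.
#' @export
read_streamlines <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.(trk|tck)$", "", basename(path), ignore.case = TRUE)
  magic <- readBin(path, "raw", n = 6)
  fmt <- if (identical(rawToChar(magic[1:5]), "TRACK")) "trk"
         else if (grepl("^mrtrix", rawToChar(magic), useBytes = TRUE)) "tck"
         else if (grepl("\\.trk$", path, ignore.case = TRUE)) "trk"
         else if (grepl("\\.tck$", path, ignore.case = TRUE)) "tck"
         else stop("unrecognised streamline format: ", path)
  lines <- if (fmt == "trk") read_trk_lines(path) else read_tck_lines(path)
  if (length(lines) == 0) {
    warning("no streamlines in ", path)
    return(structure(list(streamlines = list(), subject_id = subject_id),
                     class = "streamline_set"))
  }
  streamline_set(lines, subject_id = subject_id)
}

#' Write a streamline set to a TRK or TCK file
#'
#' @param x a `streamline_set` (world mm polylines).
#' @param path output path; format chosen by extension (`.trk` or `.tck`).
#' @param grid a `voxel_grid`; required for TRK (whose header carries the
#'   grid), ignored for TCK.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(x, path, grid = NULL) {
  stopifnot(inherits(x, "streamline_set"))
  if (grepl("\\.tck$", path, ignore.case = TRUE)) {
    write_tck(x, path)
  } else if (grepl("\\.trk$", path, ignore.case = TRUE)) {
    if (is.null(grid)) stop("writing TRK requires a voxel_grid")
    write_trk(x, path, grid)
  } else stop("unknown streamline extension: ", path)
  invisible(path)
}

# ---- TCK (MRtrix tracks) -----------------------------------------------------

read_tck_lines <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  first <- readLines(con, n = 1, warn = FALSE)
  if (!grepl("^mrtrix tracks", first)) stop("not a TCK file: ", path)
  datatype <- "Float32LE"; offset <- NA_real_
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    if (length(ln) == 0) stop("TCK header missing END")
    if (ln == "END") break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "datatype") datatype <- val
      if (key == "file") offset <- as.numeric(sub("^\\.\\s+", "", val))
    }
  }
  if (is.na(offset)) stop("TCK header missing file offset")
  endian <- if (grepl("BE$", datatype)) "big" else "little"
  if (!grepl("^Float32", datatype)) stop("unsupported TCK datatype: ", datatype)
  seek(con, offset)
  vals <- readBin(con, "numeric", size = 4, endian = endian,
                  n = (file.size(path) - offset) / 4)
  if (length(vals) %% 3 != 0) vals <- vals[seq_len(length(vals) %/% 3 * 3)]
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  split_tracks(pts)
}

# tracks are NaN-triplet separated and Inf-triplet terminated
split_tracks <- function(pts) {
  bad <- !is.finite(pts[, 1])
  ends <- which(bad)
  lines <- list(); start <- 1L
  for (e in c(ends, nrow(pts) + 1L)) {
    if (e > start) lines[[length(lines) + 1L]] <- pts[start:(e - 1L), , drop = FALSE]
    start <- e + 1L
    if (e <= nrow(pts) && any(is.infinite(pts[e, ]))) break
  }
  lines
}

write_tck <- function(x, path) {
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(x$streamlines)))
  # reserve room for the self-referential offset line
  body_off <- sum(nchar(hdr) + 1L) + nchar("file: . ") + 8L + 1L + nchar("END") + 1L
  hdr <- c(hdr, sprintf("file: . %08d", body_off), "END")
  writeLines(hdr, con, sep = "\n")
  for (s in x$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
}

# ---- TRK (TrackVis) ----------------------------------------------------------

read_trk_header <- function(con, endian) {
  id <- rawToChar(readBin(con, "raw", 6)[1:5])
  dim <- readBin(con, "integer", 3, size = 2, endian = endian)
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = endian)
  origin <- readBin(con, "numeric", 3, size = 4, endian = endian)
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = endian)
  invisible(readBin(con, "raw", 200))
  n_properties <- readBin(con, "integer", 1, size = 2, endian = endian)
  invisible(readBin(con, "raw", 200))
  vox_to_ras <- matrix(readBin(con, "numeric", 16, size = 4, endian = endian),
                       4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6))
  n_count <- readBin(con, "integer", 1, size = 4, endian = endian)
  version <- readBin(con, "integer", 1, size = 4, endian = endian)
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
  list(id = id, dim = dim, voxel_size = voxel_size, origin = origin,
       n_scalars = n_scalars, n_properties = n_properties,
       vox_to_ras = vox_to_ras, n_count = n_count, version = version,
       hdr_size = hdr_size)
}

read_trk_lines <- function(path) {
  endian <- "little"
  con <- file(path, "rb")
  h <- read_trk_header(con, endian)
  if (!identical(h$hdr_size, 1000L)) {     # byte-swapped file
    close(con)
    endian <- "big"
    con <- file(path, "rb")
    h <- read_trk_header(con, endian)
  }
  on.exit(close(con))
  if (h$id != "TRACK" || !identical(h$hdr_size, 1000L))
    stop("malformed TRK header: ", path)
  A <- h$vox_to_ras
  if (h$version < 2 || abs(A[4, 4]) < .Machine$double.eps) {
    warning("TRK file lacks a voxel-to-RAS affine; assuming identity orientation")
    A <- diag(c(h$voxel_size, 1))
    vs <- h$voxel_size
  } else {
    vs <- h$voxel_size
  }
  lines <- list()
  repeat {
    n <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (length(n) == 0) break
    if (n < 0) stop("corrupt TRK track length")
    vals <- readBin(con, "numeric", n * (3 + h$n_scalars), size = 4,
                    endian = endian)
    if (h$n_properties > 0)
      invisible(readBin(con, "numeric", h$n_properties, size = 4,
                        endian = endian))
    if (length(vals) < n * (3 + h$n_scalars)) stop("truncated TRK track data")
    m <- matrix(vals, ncol = 3 + h$n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm -> continuous voxel (corner origin, hence the half-voxel shift)
    vox <- sweep(m, 2, vs, "/") - 0.5
    w <- cbind(vox, 1) %*% t(A)
    lines[[length(lines) + 1L]] <- w[, 1:3, drop = FALSE]
    if (h$n_count > 0 && length(lines) >= h$n_count) break
  }
  lines
}

write_trk <- function(x, path, grid) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(raw(1), con)
  writeBin(as.integer(grid$shape), con, size = 2, endian = "little")
  writeBin(as.numeric(grid$voxel_size), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")  # origin
  writeBin(0L, con, size = 2, endian = "little")                      # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")                      # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(grid$affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeBin(c(charToRaw("RAS"), raw(1)), con)                          # voxel_order
  writeBin(raw(4), con)
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(raw(2 + 6), con)
  writeBin(length(x$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")                      # version
  writeBin(1000L, con, size = 4, endian = "little")                   # hdr_size
  inv <- solve(grid$affine)
  for (s in x$streamlines) {
    vox <- cbind(s, 1) %*% t(inv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, grid$voxel_size, "*")
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
}
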