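# Minimal single-file NIfTI-1 I/O.
#
# The pre-installed R stack has no NIfTI package, so the package carries a
# small reader/writer for the subset it needs: single-file (.nii / .nii.gz),
# 2-D or 3-D, datatypes uint8 / int16 / int32 / float32 / float64, no
# extensions, native endianness declared through sizeof_hdr. This is not a
# general NIfTI implementation.

nifti_datatypes <- c(uint8 = 2L, int16 = 4L, int32 = 8L,
                     float32 = 16L, float64 = 64L)
nifti_bytes <- c(uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)

#' Write a matrix or array as a NIfTI-1 image
#'
#' @param img numeric matrix (rows x cols) or 3-D array; matrix rows map to
#'   the second NIfTI dimension (j), columns to the first (i), so that the
#'   in-plane spacing order matches `spacing`
#' @param path output path; a ".gz" suffix triggers gzip compression
#' @param spacing pixel spacing in mm, length 2 or 3
#' @param datatype one of "uint8", "int16", "int32", "float32", "float64"
#' @return invisibly, `path`
#' @export
write_nifti <- function(img, path, spacing = c(1, 1),
                        datatype = "float32") {
  stopifnot(datatype %in% names(nifti_datatypes))
  dm <- dim(img)
  if (length(dm) == 2L) {
    dims <- c(dm[2L], dm[1L], 1L)       # i = col, j = row
    dat <- as.vector(t(img))            # i fastest
    sp <- c(spacing[1], spacing[2], 1)
  } else if (length(dm) == 3L) {
    dims <- c(dm[2L], dm[1L], dm[3L])
    dat <- as.vector(aperm(img, c(2L, 1L, 3L)))
    sp <- if (length(spacing) >= 3) spacing[1:3] else c(spacing, 1)
  } else stop("only 2-D or 3-D images are supported")

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4)
  wi(348L, 4)                            # sizeof_hdr
  writeBin(raw(36), con)                 # unused header fields
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)     # dim[8]
  wf(c(0, 0, 0))                         # intent_p1..p3
  wi(0L, 2)                              # intent_code
  wi(nifti_datatypes[[datatype]], 2)     # datatype
  wi(8L * nifti_bytes[[datatype]], 2)    # bitpix
  wi(0L, 2)                              # slice_start
  wf(c(1, sp, 1, 1, 1, 1))               # pixdim[8]
  wf(352)                                # vox_offset
  wf(c(1, 0))                            # scl_slope, scl_inter
  wi(0L, 2); wi(0L, 1); wi(0L, 1)        # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                      # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4)                       # glmax, glmin (unused)
  writeBin(raw(80 + 24), con)            # descrip, aux_file
  wi(c(0L, 0L), 2)                       # qform_code, sform_code
  wf(rep(0, 18))                         # quatern/qoffset + srow
  writeBin(raw(16), con)                 # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)                  # extension flag
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(dat), con, size = nifti_bytes[[datatype]])
  } else {
    writeBin(as.integer(dat), con, size = nifti_bytes[[datatype]])
  }
  invisible(path)
}

#' Read a NIfTI-1 image written by this package (or compatible)
#'
#' @param path `.nii` or `.nii.gz` file
#' @return list with `data` (matrix for single-slice images, otherwise a
#'   3-D array \[row, col, slice\]) and `spacing` (mm per in-plane pixel,
#'   plus slice spacing for volumes)
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size)
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4)
  }
  if (ri(0, 4) != 348L) stop("not a NIfTI-1 file (or non-native endianness): ", path)
  dim8 <- ri(40, 2, 8)
  ndim <- dim8[1]
  dims <- dim8[2:(1 + max(ndim, 1))]
  datatype <- ri(70, 2)
  dtname <- names(nifti_datatypes)[match(datatype, nifti_datatypes)]
  if (is.na(dtname)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic: ", magic)
  if (vox_offset > 352) readBin(con, "raw", vox_offset - 352)
  n <- prod(dims)
  what <- if (dtname %in% c("float32", "float64")) "numeric" else "integer"
  signed <- dtname != "uint8"
  dat <- readBin(con, what, n = n, size = nifti_bytes[[dtname]],
                 signed = signed)
  if (length(dims) < 3) dims <- c(dims, rep(1L, 3 - length(dims)))
  arr <- array(dat, dim = dims[1:3])
  arr <- aperm(arr, c(2L, 1L, 3L))       # back to [row, col, slice]
  sp <- pixdim[2:4]
  if (dim(arr)[3] == 1L) {
    list(data = arr[, , 1L], spacing = sp[1:2])
  } else {
    list(data = arr, spacing = sp)
  }
}

#' Write a matrix as a plain-text PGM (P2) preview
#'
#' Intensities are linearly scaled to 0..255 over `range`.
#' @param img numeric matrix
#' @param path output path
#' @param range intensity range mapped to 0..255
#' @export
write_pgm <- function(img, path, range = c(0, 1)) {
  v <- round(255 * (pmin(pmax(img, range[1]), range[2]) - range[1]) /
               (range[2] - range[1]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply(v, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
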