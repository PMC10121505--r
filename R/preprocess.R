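# Slice selection and standardization.
#
# The working canvas of the whole pipeline is the "standard slice": one
# mid-sagittal raster of exactly 448 x 320 pixels at 0.6 x 0.6 mm, unit
# intensity range. Raw 12-bit intensities are divided by 2500 and clipped
# to 1.0 — during development of the original system the informative T2
# range for separating vertebral body from anulus fibrosus lay below 2500.

STANDARD_ROWS <- 448L
STANDARD_COLS <- 320L
STANDARD_SPACING <- 0.6
INTENSITY_DIVISOR <- 2500

#' Select the eligible sagittal T2-weighted series of a study
#'
#' Eligibility: sagittal orientation, echo time >= 80 ms, repetition time
#' >= 3000 ms, slice thickness 2–4 mm, in-plane spacing <= 0.8 mm. If
#' several series qualify, the one with the smallest in-plane spacing wins
#' (first such series on an exact tie).
#'
#' @param series data frame with one row per series and columns
#'   `series_id`, `plane` ("sagittal"/...), `te_ms`, `tr_ms`,
#'   `slice_thickness_mm`, `pixel_spacing_mm`
#' @return the selected row (single-row data frame)
#' @export
select_sequence <- function(series) {
  stopifnot(is.data.frame(series), nrow(series) >= 1)
  need <- c("plane", "te_ms", "tr_ms", "slice_thickness_mm",
            "pixel_spacing_mm")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols) > 0) {
    stop("series table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ok <- tolower(series$plane) == "sagittal" &
    series$te_ms >= 80 & series$tr_ms >= 3000 &
    series$slice_thickness_mm >= 2 & series$slice_thickness_mm <= 4 &
    series$pixel_spacing_mm <= 0.8
  if (!any(ok)) {
    stop("no eligible sequence: need a sagittal T2 series with TE >= 80 ms, ",
         "TR >= 3000 ms, thickness 2-4 mm, spacing <= 0.8 mm")
  }
  cand <- series[ok, , drop = FALSE]
  cand[which.min(cand$pixel_spacing_mm), , drop = FALSE]
}

#' Index of the central slice of a sagittal stack
#'
#' For `n` slices the 0-based index is `floor((n - 1) / 2)`: the unique
#' centre for odd `n`, the centre-left slice for even `n`. All other
#' slices are discarded by the pipeline.
#'
#' @param n_slices slice count (or a 3-D array, whose third dimension is
#'   used)
#' @return 0-based slice index
#' @export
select_center_slice <- function(n_slices) {
  if (is.array(n_slices)) n_slices <- dim(n_slices)[3]
  n_slices <- as.integer(n_slices)
  stopifnot(n_slices >= 1)
  (n_slices - 1L) %/% 2L
}

#' Standardize a raw sagittal slice
#'
#' Resamples to 0.6 x 0.6 mm (bilinear for intensities, nearest-neighbour
#' for label masks), centre-places onto (or centre-crops to) a 448 x 320
#' canvas, and maps each 12-bit intensity v to min(v / 2500, 1). Inputs
#' already in the unit range (e.g. phantom renders) are first rescaled by
#' 2500 so the clip step is the identity on them — re-standardizing a
#' standard slice is a no-op up to interpolation round-off.
#'
#' @param slice numeric matrix; intensities on the 12-bit scale (0–4096)
#'   or already in \[0, 1\]
#' @param spacing_mm in-plane spacing, scalar or length 2 (row, col), mm
#' @param label_mask logical; use nearest-neighbour resampling and skip the
#'   intensity mapping (mask values are preserved verbatim)
#' @return `standard_slice`: 448 x 320 matrix in \[0, 1\] with attributes
#'   `spacing_mm` and `orientation`
#' @export
standardize_slice <- function(slice, spacing_mm, label_mask = FALSE) {
  stopifnot(is.matrix(slice))
  spacing_mm <- rep_len(spacing_mm, 2L)
  if (any(spacing_mm <= 0)) stop("pixel spacing must be strictly positive")
  orientation <- attr(slice, "orientation")
  if (is.null(orientation)) orientation <- c(anterior = "left", cranial = "top")

  out_nr <- max(1L, as.integer(round(nrow(slice) * spacing_mm[1] / STANDARD_SPACING)))
  out_nc <- max(1L, as.integer(round(ncol(slice) * spacing_mm[2] / STANDARD_SPACING)))
  resampled <- if (label_mask) {
    nearest_resize(slice, out_nr, out_nc)
  } else {
    bilinear_resize(slice, out_nr, out_nc)
  }

  canvas <- matrix(0, STANDARD_ROWS, STANDARD_COLS)
  # symmetric centre crop/pad (paper is silent on canvas fitting)
  src_r <- crop_range(out_nr, STANDARD_ROWS)
  src_c <- crop_range(out_nc, STANDARD_COLS)
  dst_r <- pad_range(out_nr, STANDARD_ROWS)
  dst_c <- pad_range(out_nc, STANDARD_COLS)
  canvas[dst_r, dst_c] <- resampled[src_r, src_c]

  if (!label_mask) {
    mx <- max(canvas)
    if (mx <= 1 + 1e-9) canvas <- canvas * INTENSITY_DIVISOR
    canvas <- pmin(canvas / INTENSITY_DIVISOR, 1)
    canvas <- pmax(canvas, 0)
  }
  attr(canvas, "spacing_mm") <- STANDARD_SPACING
  attr(canvas, "orientation") <- orientation
  class(canvas) <- c("standard_slice", class(canvas))
  canvas
}

crop_range <- function(n_src, n_dst) {
  if (n_src <= n_dst) return(seq_len(n_src))
  off <- (n_src - n_dst) %/% 2L
  (off + 1L):(off + n_dst)
}

pad_range <- function(n_src, n_dst) {
  if (n_src >= n_dst) return(seq_len(n_dst))
  off <- (n_dst - n_src) %/% 2L
  (off + 1L):(off + n_src)
}

#' @export
print.standard_slice <- function(x, ...) {
  cat("Standard slice:", nrow(x), "x", ncol(x), "px @",
      attr(x, "spacing_mm"), "mm, intensity [",
      signif(min(x), 3), ",", signif(max(x), 3), "]\n")
  invisible(x)
}
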