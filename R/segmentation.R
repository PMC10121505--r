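# Vertebral-body segmentation stage.
#
# Segmentation is a pluggable contract: the pipeline only requires a binary
# mask on the standard-slice grid. Two backends exist:
#   * "oracle" — binarizes a known label mask (phantom ground truth),
#     optionally corrupted with holes, satellite blobs and boundary jitter
#     under a seeded model, to exercise the post-processing stage;
#   * "model"  — a trained U-net (see unet_spec()/build_unet()); requested
#     without weights it errors, never silently falls back.

#' Seeded corruption model for oracle masks
#'
#' Defines how a perfect mask is degraded to emulate the defects a trained
#' segmenter produces: interior holes, small satellite clusters away from
#' the spine, and boundary jitter. All sizes are in pixels of the standard
#' grid.
#'
#' @param n_holes number of circular holes punched into the foreground
#' @param hole_radius_px radius range (min, max) of holes
#' @param n_satellites number of spurious foreground blobs
#' @param satellite_radius_px radius range of satellites
#' @param satellite_offset_px distance range from the mask's bounding box
#' @param boundary_flip_prob probability that a boundary-adjacent pixel is
#'   flipped
#' @return object of class `mask_corruption`
#' @export
mask_corruption <- function(n_holes = 3, hole_radius_px = c(1, 3),
                            n_satellites = 3, satellite_radius_px = c(1, 3),
                            satellite_offset_px = c(15, 60),
                            boundary_flip_prob = 0.2) {
  structure(
    list(n_holes = n_holes, hole_radius_px = hole_radius_px,
         n_satellites = n_satellites,
         satellite_radius_px = satellite_radius_px,
         satellite_offset_px = satellite_offset_px,
         boundary_flip_prob = boundary_flip_prob),
    class = "mask_corruption"
  )
}

disk_indices <- function(nr, nc, r0, c0, radius) {
  rr <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

apply_corruption <- function(mask, corruption, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(m)

  for (i in seq_len(corruption$n_holes)) {
    p <- fg[sample.int(nrow(fg), 1L), ]
    rad <- stats::runif(1, corruption$hole_radius_px[1],
                        corruption$hole_radius_px[2])
    m[disk_indices(nr, nc, p[1], p[2], rad)] <- FALSE
  }
  bb <- c(range(fg[, 1]), range(fg[, 2]))
  for (i in seq_len(corruption$n_satellites)) {
    off <- stats::runif(1, corruption$satellite_offset_px[1],
                        corruption$satellite_offset_px[2])
    ang <- stats::runif(1, 0, 2 * pi)
    r0 <- mean(bb[1:2]) + (diff(bb[1:2]) / 2 + off) * sin(ang)
    c0 <- mean(bb[3:4]) + (diff(bb[3:4]) / 2 + off) * cos(ang)
    if (r0 < 1 || c0 < 1 || r0 > nr || c0 > nc) next
    rad <- stats::runif(1, corruption$satellite_radius_px[1],
                        corruption$satellite_radius_px[2])
    m[disk_indices(nr, nc, r0, c0, rad)] <- TRUE
  }
  if (corruption$boundary_flip_prob > 0) {
    dil <- m | shift_mask(m, 1, 0) | shift_mask(m, -1, 0) |
      shift_mask(m, 0, 1) | shift_mask(m, 0, -1)
    ero <- m & shift_mask(m, 1, 0) & shift_mask(m, -1, 0) &
      shift_mask(m, 0, 1) & shift_mask(m, 0, -1)
    band <- which(dil & !ero)
    flip <- band[stats::runif(length(band)) < corruption$boundary_flip_prob]
    m[flip] <- !m[flip]
  }
  m
}

#' Segment the vertebral bodies of a standard slice
#'
#' @param slice a `standard_slice`
#' @param backend "oracle" (binarize a supplied label mask, optionally
#'   corrupted) or "model" (forward pass of a trained U-net)
#' @param labels labeled or binary ground-truth mask on the same grid
#'   (oracle backend)
#' @param corruption optional [mask_corruption()] (oracle backend)
#' @param seed corruption seed
#' @param model a trained model from [build_unet()] (model backend); an
#'   explicit error is raised if absent — there is no silent fallback
#' @param threshold probability cut for the model backend
#' @return binary matrix (0/1) with attributes `spacing_mm` and
#'   `provenance` ("oracle" or "model")
#' @export
segment_slice <- function(slice, backend = c("oracle", "model"),
                          labels = NULL, corruption = NULL, seed = 0L,
                          model = NULL, threshold = 0.5) {
  backend <- match.arg(backend)
  if (backend == "oracle") {
    if (is.null(labels)) stop("oracle backend requires a ground-truth label mask")
    stopifnot(all(dim(labels) == dim(slice)))
    m <- labels > 0
    if (!is.null(corruption)) m <- apply_corruption(m, corruption, seed)
  } else {
    if (is.null(model)) {
      stop("model backend requested but no trained model/weights supplied")
    }
    prob <- unet_predict(model, slice)
    m <- prob >= threshold
  }
  out <- matrix(as.integer(m), nrow(slice), ncol(slice))
  attr(out, "spacing_mm") <- attr(slice, "spacing_mm")
  attr(out, "provenance") <- backend
  out
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b binary matrices of equal shape
#' @return coefficient in \[0, 1\]
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

#' U-net architecture description
#'
#' The reference architecture: five encoder blocks, each two stacks of
#' (3 x 3 convolution, batch normalization, ReLU) followed by 2 x 2 max
#' pooling, filter counts doubling 32, 64, 128, 256, 512; the first four
#' encoder blocks are concatenated to their mirrored decoder blocks (four
#' skip connections); Dice-coefficient loss, Adam optimizer at learning
#' rate 0.05, batch size 16, 100 epochs. A 448 x 320 input reaches a
#' 14 x 10 bottleneck after the five poolings.
#'
#' @param input_shape (rows, cols) of the single-channel input
#' @param base_filters filters of the first block (doubles per block)
#' @param depth number of encoder blocks
#' @param learning_rate,batch_size,epochs training hyper-parameters
#' @return object of class `unet_spec`
#' @export
unet_spec <- function(input_shape = c(448L, 320L), base_filters = 32L,
                      depth = 5L, learning_rate = 0.05, batch_size = 16L,
                      epochs = 100L) {
  input_shape <- as.integer(input_shape)
  if (any(input_shape %% (2L^depth) != 0L)) {
    stop("input shape ", paste(input_shape, collapse = "x"),
         " is not divisible by 2^", depth, " for ", depth, " pooling stages")
  }
  filters <- as.integer(base_filters * 2L^(seq_len(depth) - 1L))
  structure(
    list(input_shape = input_shape, filters = filters, depth = as.integer(depth),
         skip_connections = as.integer(depth - 1L),
         convs_per_block = 2L, kernel = c(3L, 3L), pool = c(2L, 2L),
         loss = "dice", optimizer = "adam",
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs)),
    class = "unet_spec"
  )
}

#' @export
print.unet_spec <- function(x, ...) {
  bneck <- x$input_shape %/% (2L^x$depth)
  cat("U-net:", x$depth, "encoder blocks, filters",
      paste(x$filters, collapse = "/"), "\n")
  cat("  input", paste(x$input_shape, collapse = "x"),
      "-> bottleneck", paste(bneck, collapse = "x"), "\n")
  cat("  loss", x$loss, "| optimizer", x$optimizer, "lr", x$learning_rate,
      "| batch", x$batch_size, "| epochs", x$epochs, "\n")
  invisible(x)
}

#' Feature-map shapes of every U-net stage
#'
#' @param spec a [unet_spec()]
#' @return data frame: stage, rows, cols, filters
#' @export
unet_shapes <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  rows <- spec$input_shape[1]; cols <- spec$input_shape[2]
  out <- list()
  r <- rows; c <- cols
  for (i in seq_len(spec$depth)) {
    out[[length(out) + 1L]] <- data.frame(
      stage = paste0("enc", i), rows = r, cols = c, filters = spec$filters[i])
    r <- r %/% 2L; c <- c %/% 2L
  }
  out[[length(out) + 1L]] <- data.frame(
    stage = "bottleneck", rows = r, cols = c,
    filters = spec$filters[spec$depth])
  # decoder mirrors the encoder; the deepest decoder block has no skip
  # (only the first four encoder blocks are concatenated across)
  for (i in rev(seq_len(spec$depth))) {
    r <- r * 2L; c <- c * 2L
    out[[length(out) + 1L]] <- data.frame(
      stage = paste0("dec", i), rows = r, cols = c, filters = spec$filters[i])
  }
  do.call(rbind, out)
}
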