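# Low-level raster and polygon helpers shared by the phantom generator,
# mask post-processing and corner detection.
#
# Conventions (package-wide):
#   * images are R matrices indexed [row, col]; row 1 is the cranial-most
#     (top) image row, col 1 the anterior-most (left) column
#   * pixel (r, c) has 0-based indices (r-1, c-1) and millimetre centre
#     x = (c-1) * spacing, y = (r-1) * spacing
#   * polygons are n x 2 matrices of (x, y) millimetre coordinates

#' Convert 0-based pixel indices to millimetre coordinates
#' @param rc two-column matrix of (row, col) 1-based matrix indices
#' @param spacing pixel spacing in mm
#' @return two-column matrix of (x, y) mm coordinates
#' @keywords internal
px_to_mm <- function(rc, spacing) {
  cbind(x = (rc[, 2] - 1) * spacing, y = (rc[, 1] - 1) * spacing)
}

#' @keywords internal
mm_to_px <- function(xy, spacing) {
  cbind(row = xy[, 2] / spacing + 1, col = xy[, 1] / spacing + 1)
}

#' Vectorised even-odd point-in-polygon test
#'
#' Ray casting with the even-odd rule; points exactly on an edge may fall on
#' either side (half-open rule along y), which is adequate for pixel-centre
#' membership tests.
#'
#' @param px,py point coordinates
#' @param poly n x 2 polygon vertex matrix (closed implicitly)
#' @return logical vector
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Rasterise a polygon onto a pixel grid by pixel-centre membership
#' @param poly polygon in mm
#' @param nrow,ncol grid dimensions
#' @param spacing pixel spacing mm
#' @return logical matrix
#' @keywords internal
rasterize_polygon <- function(poly, nrow, ncol, spacing) {
  out <- matrix(FALSE, nrow, ncol)
  # restrict the test to the polygon bounding box
  r0 <- max(1L, floor(min(poly[, 2]) / spacing) + 1L)
  r1 <- min(nrow, ceiling(max(poly[, 2]) / spacing) + 1L)
  c0 <- max(1L, floor(min(poly[, 1]) / spacing) + 1L)
  c1 <- min(ncol, ceiling(max(poly[, 1]) / spacing) + 1L)
  if (r0 > r1 || c0 > c1) return(out)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  hit <- point_in_polygon((cc - 1) * spacing, (rr - 1) * spacing, poly)
  out[cbind(rr[hit], cc[hit])] <- TRUE
  out
}

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs + dr; cdst <- cs + dc
  keep_r <- rdst >= 1 & rdst <= nr
  keep_c <- cdst >= 1 & cdst <= nc
  out[rdst[keep_r], cdst[keep_c]] <- m[rs[keep_r], cs[keep_c]]
  out
}

#' Label 4-connected components of a binary mask
#'
#' Iterative frontier propagation; adequate for the few hundred iterations a
#' spine mask needs and free of recursion limits.
#'
#' @param mask logical matrix
#' @return integer matrix, 0 = background, components numbered 1..k in
#'   raster-scan order of their first pixel
#' @keywords internal
label_components <- function(mask) {
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  remaining <- mask & lab == 0L
  while (any(remaining)) {
    k <- k + 1L
    seed <- which(remaining)[1L]
    comp <- matrix(FALSE, nrow(mask), ncol(mask))
    comp[seed] <- TRUE
    repeat {
      grown <- comp |
        shift_mask(comp, 1L, 0L) | shift_mask(comp, -1L, 0L) |
        shift_mask(comp, 0L, 1L) | shift_mask(comp, 0L, -1L)
      grown <- grown & mask
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- k
    remaining <- mask & lab == 0L
  }
  lab
}

#' Fill interior holes of a binary mask
#'
#' Background connected (4-connectivity) to the image border is kept;
#' all other background pixels are holes and become foreground.
#' @keywords internal
fill_holes <- function(mask) {
  mask <- mask > 0
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- bg[1, ]; reach[nrow(bg), ] <- bg[nrow(bg), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(bg)] <- bg[, ncol(bg)]
  repeat {
    grown <- reach |
      shift_mask(reach, 1L, 0L) | shift_mask(reach, -1L, 0L) |
      shift_mask(reach, 0L, 1L) | shift_mask(reach, 0L, -1L)
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

#' Trace the outer boundary of a single connected component
#'
#' Moore-neighbour tracing with Jacob's stopping criterion. The component
#' must be 4-connected; the result is the closed 8-connected contour as
#' 1-based (row, col) matrix indices in clockwise order (image coordinates,
#' y down).
#'
#' @param mask logical matrix containing exactly one component
#' @return two-column integer matrix (row, col); first pixel not repeated
#' @keywords internal
trace_boundary <- function(mask) {
  mask <- mask > 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no boundary")
  if (nrow(idx) == 1L) return(idx)
  # start at the uppermost, then leftmost foreground pixel
  start <- idx[order(idx[, 1], idx[, 2])[1L], ]
  # clockwise Moore neighbourhood beginning west (y grows downward)
  dirs <- rbind(
    c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)
  )
  inside <- function(r, c) r >= 1L && c >= 1L && r <= nrow(mask) && c <= ncol(mask)
  fg <- function(r, c) inside(r, c) && mask[r, c]
  contour <- matrix(0L, nrow = 8L * nrow(idx) + 8L, ncol = 2L)
  n_out <- 1L
  contour[1L, ] <- start
  cur <- start
  dir_from <- 1L   # entered "from the west": search starts one past west
  first_move <- NULL
  max_steps <- 8L * nrow(idx) + 8L
  for (step in seq_len(max_steps)) {
    found <- FALSE
    for (k in 0:7) {
      d <- ((dir_from - 1L + k) %% 8L) + 1L
      r <- cur[1L] + dirs[d, 1L]; c <- cur[2L] + dirs[d, 2L]
      if (fg(r, c)) {
        # re-entering the start pixel with the same first move closes the loop
        if (r == start[1L] && c == start[2L] && !is.null(first_move)) {
          nxt_from <- ((d - 1L + 5L) %% 8L) + 1L
          probe <- nxt_from
          for (k2 in 0:7) {
            d2 <- ((probe - 1L + k2) %% 8L) + 1L
            r2 <- r + dirs[d2, 1L]; c2 <- c + dirs[d2, 2L]
            if (fg(r2, c2)) {
              if (r2 == first_move[1L] && c2 == first_move[2L]) {
                return(contour[seq_len(n_out), , drop = FALSE])
              }
              break
            }
          }
        }
        n_out <- n_out + 1L
        contour[n_out, ] <- c(r, c)
        if (is.null(first_move)) first_move <- c(r, c)
        cur <- c(r, c)
        # next search starts from the neighbour "behind" the move direction
        dir_from <- ((d - 1L + 5L) %% 8L) + 1L
        found <- TRUE
        break
      }
    }
    if (!found) return(contour[seq_len(n_out), , drop = FALSE]) # isolated pixel
  }
  contour[seq_len(n_out), , drop = FALSE]
}

#' Minimum-area enclosing rectangle of a 2-D point set
#'
#' Rotating-calipers over the convex hull: the optimal rectangle has a side
#' collinear with a hull edge.
#'
#' @param pts n x 2 matrix (x, y)
#' @return 4 x 2 matrix of rectangle corners in cyclic order
#' @keywords internal
min_area_rect <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3L) {
    # degenerate: fall back to the axis-aligned bbox
    return(cbind(
      x = c(min(pts[, 1]), max(pts[, 1]), max(pts[, 1]), min(pts[, 1])),
      y = c(min(pts[, 2]), min(pts[, 2]), max(pts[, 2]), max(pts[, 2]))
    ))
  }
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  nh <- nrow(hull)
  best <- NULL
  best_area <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) next
    u <- e / len                 # edge direction
    v <- c(-u[2], u[1])          # normal
    pu <- hull %*% u
    pv <- hull %*% v
    area <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (area < best_area) {
      best_area <- area
      corners_uv <- rbind(
        c(min(pu), min(pv)), c(max(pu), min(pv)),
        c(max(pu), max(pv)), c(min(pu), max(pv))
      )
      best <- corners_uv %*% rbind(u, v)
    }
  }
  colnames(best) <- c("x", "y")
  best
}

#' Area-sampled polygon rasterisation
#'
#' A pixel is foreground when at least half of a `ss` x `ss` subsample grid
#' of its area falls inside the polygon — a partial-volume-like criterion
#' that preserves thin corner tips which pixel-centre sampling drops.
#' @keywords internal
rasterize_polygon_area <- function(poly, nrow, ncol, spacing, ss = 3L) {
  r0 <- max(1L, floor(min(poly[, 2]) / spacing))
  r1 <- min(nrow, ceiling(max(poly[, 2]) / spacing) + 1L)
  c0 <- max(1L, floor(min(poly[, 1]) / spacing))
  c1 <- min(ncol, ceiling(max(poly[, 1]) / spacing) + 1L)
  out <- matrix(FALSE, nrow, ncol)
  if (r0 > r1 || c0 > c1) return(out)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  votes <- integer(length(rr))
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss * spacing
  for (dx in offs) for (dy in offs) {
    votes <- votes + point_in_polygon((cc - 1) * spacing + dx,
                                      (rr - 1) * spacing + dy, poly)
  }
  hit <- votes * 2L >= ss * ss
  out[cbind(rr[hit], cc[hit])] <- TRUE
  out
}

#' Minimum distance from each point to a closed polygon's edges
#' @param pts n x 2 points
#' @param poly m x 2 polygon vertices (closed implicitly)
#' @return numeric vector of distances
#' @keywords internal
dist_to_polygon <- function(pts, poly) {
  m <- nrow(poly)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 < 1e-12) rep(0, nrow(pts)) else
      pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    best <- pmin(best, sqrt(dx^2 + dy^2))
  }
  best
}

#' Intersection-over-union between a mask and a polygon
#'
#' The polygon is rasterised on the mask's grid by pixel-centre membership
#' (the same convention used everywhere in the package), then IoU is computed
#' pixel-wise.
#' @keywords internal
polygon_mask_iou <- function(poly, mask, spacing) {
  pm <- rasterize_polygon(poly, nrow(mask), ncol(mask), spacing)
  m <- mask > 0
  u <- sum(pm | m)
  if (u == 0L) return(0)
  sum(pm & m) / u
}

#' Bilinear image resize
#'
#' Pixel-centre aligned: output centre k (0-based) maps to input coordinate
#' (k + 0.5) * scale - 0.5. Out-of-range samples clamp to the edge.
#'
#' @param img numeric matrix
#' @param out_nrow,out_ncol target dimensions
#' @return resized matrix
#' @keywords internal
bilinear_resize <- function(img, out_nrow, out_ncol) {
  nr <- nrow(img); nc <- ncol(img)
  if (out_nrow == nr && out_ncol == nc) return(img)
  rf <- ((seq_len(out_nrow) - 0.5) * nr / out_nrow) - 0.5
  cf <- ((seq_len(out_ncol) - 0.5) * nc / out_ncol) - 0.5
  rf <- pmin(pmax(rf, 0), nr - 1)
  cf <- pmin(pmax(cf, 0), nc - 1)
  r0 <- pmin(floor(rf), nr - 1); r1 <- pmin(r0 + 1, nr - 1)
  c0 <- pmin(floor(cf), nc - 1); c1 <- pmin(c0 + 1, nc - 1)
  wr <- rf - r0; wc <- cf - c0
  a00 <- img[cbind(rep(r0 + 1, length(c0)), rep(c0 + 1, each = length(r0)))]
  a10 <- img[cbind(rep(r1 + 1, length(c0)), rep(c0 + 1, each = length(r0)))]
  a01 <- img[cbind(rep(r0 + 1, length(c1)), rep(c1 + 1, each = length(r0)))]
  a11 <- img[cbind(rep(r1 + 1, length(c1)), rep(c1 + 1, each = length(r0)))]
  wrm <- rep(wr, length(cf)); wcm <- rep(wc, each = length(rf))
  out <- (1 - wrm) * (1 - wcm) * a00 + wrm * (1 - wcm) * a10 +
    (1 - wrm) * wcm * a01 + wrm * wcm * a11
  matrix(out, out_nrow, out_ncol)
}

#' Nearest-neighbour resize (for label masks)
#' @keywords internal
nearest_resize <- function(img, out_nrow, out_ncol) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(round(((seq_len(out_nrow) - 0.5) * nr / out_nrow) + 0.5), 1), nr)
  ci <- pmin(pmax(round(((seq_len(out_ncol) - 0.5) * nc / out_ncol) + 0.5), 1), nc)
  img[ri, ci, drop = FALSE]
}
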