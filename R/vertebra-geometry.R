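# Mask post-processing, vertebra splitting/labelling, and corner-landmark
# detection.
#
# Three corner strategies are implemented, mirroring the deployed system:
#   1. basin-hopping refinement of the minimum-area bounding rectangle,
#      maximizing the IoU between the mask and the corner quadrilateral;
#   2. curvature maxima (k-cosine) along the traced mask border;
#   3. robust straight-line fits to the four border sides, corners at the
#      line intersections snapped to the border.
# The selector keeps the quad with the highest polygon-mask IoU.

#' Post-process a binary segmentation mask
#'
#' Fills interior holes, removes isolated clusters smaller than
#' `min_area_mm2`, and removes clusters whose centroid lies farther than
#' `max_dist_mm` from the straight line fitted (total least squares)
#' through the centroids of all large components — clusters "too far from
#' the majority of segmented vertebrae". Idempotent; an empty mask passes
#' through unchanged.
#'
#' @param mask binary matrix
#' @param spacing_mm pixel spacing (default: `spacing_mm` attribute)
#' @param min_area_mm2 minimum component area kept (default 50)
#' @param max_dist_mm maximum centroid distance from the spine axis
#'   (default 40)
#' @return cleaned binary (integer 0/1) matrix, attributes preserved
#' @export
clean_mask <- function(mask, spacing_mm = attr(mask, "spacing_mm"),
                       min_area_mm2 = 50, max_dist_mm = 40) {
  if (is.null(spacing_mm)) stop("spacing_mm required (attribute or argument)")
  m <- mask > 0
  if (!any(m)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attributes(out) <- attributes(mask)
    return(out)
  }
  m <- fill_holes(m)
  lab <- label_components(m)
  k <- max(lab)
  px_area <- spacing_mm^2
  areas <- tabulate(lab[lab > 0L], nbins = k) * px_area
  keep <- areas >= min_area_mm2
  m[!matrix(keep[pmax(lab, 1L)], nrow(lab), ncol(lab)) | lab == 0L] <- FALSE

  # spine-axis filter on the surviving components
  lab <- label_components(m)
  k <- max(lab)
  if (k >= 3L) {
    cents <- t(vapply(seq_len(k), function(i) {
      idx <- which(lab == i, arr.ind = TRUE)
      colMeans(px_to_mm(idx, spacing_mm))
    }, numeric(2)))
    ctr <- colMeans(cents)
    sv <- svd(sweep(cents, 2, ctr))
    axis_dir <- sv$v[, 1]
    nrm <- c(-axis_dir[2], axis_dir[1])
    dist <- abs((cents[, 1] - ctr[1]) * nrm[1] + (cents[, 2] - ctr[2]) * nrm[2])
    drop <- which(dist > max_dist_mm)
    for (i in drop) m[lab == i] <- FALSE
  }
  out <- matrix(as.integer(m), nrow(mask), ncol(mask))
  attr(out, "spacing_mm") <- spacing_mm
  attr(out, "orientation") <- attr(mask, "orientation")
  out
}

#' Split a cleaned mask into labelled vertebra components
#'
#' Components are ordered cranial to caudal by centroid row (ties broken by
#' the anterior column), and labels assigned from the supplied vector. With
#' `sacrum_present = TRUE` and no labels, the most caudal component is S1
#' and the rest are named upward L5, L4, ... T12, T11.
#'
#' @param mask cleaned binary mask
#' @param labels character vector, cranial to caudal; must match the
#'   component count when given
#' @param sacrum_present used only when `labels` is NULL
#' @param spacing_mm pixel spacing
#' @return list of `vertebra_component` objects: `mask` (full-grid binary
#'   matrix), `label`, `centroid_mm`, `angle_deg` (principal-axis
#'   rotation), `area_mm2`
#' @export
split_and_label <- function(mask, labels = NULL, sacrum_present = TRUE,
                            spacing_mm = attr(mask, "spacing_mm")) {
  if (is.null(spacing_mm)) stop("spacing_mm required")
  lab <- label_components(mask > 0)
  k <- max(lab)
  if (k == 0L) return(list())
  info <- lapply(seq_len(k), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    mm <- px_to_mm(idx, spacing_mm)
    ctr <- colMeans(mm)
    sv <- svd(sweep(mm, 2, ctr))
    ang <- atan2(sv$v[2, 1], sv$v[1, 1]) * 180 / pi
    # principal axis reported as the rotation of the long axis from
    # horizontal, wrapped to (-90, 90]
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
    list(idx = idx, centroid = ctr, angle = ang,
         area = nrow(idx) * spacing_mm^2)
  })
  ord <- order(vapply(info, function(x) x$centroid[2], numeric(1)),
               vapply(info, function(x) x$centroid[1], numeric(1)))
  info <- info[ord]
  if (is.null(labels)) {
    full <- c("T10", "T11", "T12", "L1", "L2", "L3", "L4", "L5", "S1")
    labels <- if (sacrum_present) {
      utils::tail(full, k)
    } else {
      utils::tail(full[-length(full)], k)
    }
    if (k > length(full)) labels <- sprintf("V%02d", seq_len(k))
  }
  if (length(labels) != k) {
    stop("label count (", length(labels), ") does not match component count (",
         k, ")")
  }
  lapply(seq_len(k), function(i) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    m[info[[i]]$idx] <- TRUE
    structure(
      list(mask = m, label = labels[i], centroid_mm = info[[i]]$centroid,
           angle_deg = info[[i]]$angle, area_mm2 = info[[i]]$area,
           spacing_mm = spacing_mm),
      class = "vertebra_component"
    )
  })
}

#' @export
print.vertebra_component <- function(x, ...) {
  cat(sprintf("Vertebra %s: area %.0f mm2, centroid (%.1f, %.1f) mm, axis %.1f deg\n",
              x$label, x$area_mm2, x$centroid_mm[1], x$centroid_mm[2],
              x$angle_deg))
  invisible(x)
}

# Sub-pixel landmark sharpening: on stair-stepped (tilted) borders every
# overlap objective is near-flat over the last 1-2 boundary pixels of a
# corner tip, so strategies may stop one pixel short. Each corner may move
# to a boundary point within a +/- `radius` contour neighbourhood if that
# enlarges the quadrilateral's area (the anatomical corner is the
# outermost consistent landmark); two refinement passes.
sharpen_corners <- function(corners, comp, radius = 2L) {
  bnd_mm <- px_to_mm(trace_boundary(comp$mask > 0), comp$spacing_mm)
  nb <- nrow(bnd_mm)
  if (nb < 4L * (2L * radius + 1L)) return(corners)
  quad_area <- function(q) {
    abs(sum(q[, 1] * (q[c(2:4, 1), 2] - q[c(4, 1:3), 2])) / 2)
  }
  q <- corners
  for (pass in 1:2) {
    for (i in 1:4) {
      i0 <- which.min((bnd_mm[, 1] - q[i, 1])^2 + (bnd_mm[, 2] - q[i, 2])^2)
      win <- ((i0 - radius):(i0 + radius) - 1L) %% nb + 1L
      areas <- vapply(win, function(j) {
        q2 <- q; q2[i, ] <- bnd_mm[j, ]; quad_area(q2)
      }, numeric(1))
      q[i, ] <- bnd_mm[win[which.max(areas)], ]
    }
  }
  # pixel-extent correction: a border pixel's centre underestimates the
  # physical corner by half a pixel per axis; shift each landmark to the
  # outer corner of its pixel (half-pixel outward along the image
  # diagonal). On an axis-aligned rectangle this makes the landmarks the
  # rectangle's true geometric corners.
  ctr <- colMeans(q)
  half <- comp$spacing_mm / 2
  q + half * cbind(sign(q[, 1] - ctr[1]), sign(q[, 2] - ctr[2]))
}

new_corner_quad <- function(corners, strategy, comp, overlap = NA_real_) {
  corners <- sharpen_corners(corners, comp)
  rownames(corners) <- c("as", "ps", "pi", "ai")
  colnames(corners) <- c("x", "y")
  if (is.na(overlap)) {
    overlap <- polygon_mask_iou(corners, comp$mask, comp$spacing_mm)
  }
  structure(
    list(corners = corners, strategy = strategy, overlap = overlap,
         label = comp$label, spacing_mm = comp$spacing_mm),
    class = "corner_quad"
  )
}

#' @export
print.corner_quad <- function(x, ...) {
  cat(sprintf("Corner quad (%s, IoU %.3f)%s:\n", x$strategy, x$overlap,
              if (is.null(x$label) || is.na(x$label)) "" else paste0(" ", x$label)))
  print(round(x$corners, 2))
  invisible(x)
}

# assign anatomical roles to 4 points: quadrants relative to the centroid
# after rotating the principal axis to horizontal (anterior = left image
# border, cranial = top). Errors if the 4 points do not occupy distinct
# quadrants cleanly; callers pass points that do.
assign_roles <- function(pts, comp) {
  ctr <- comp$centroid_mm
  rot <- rotation_matrix(-comp$angle_deg)
  rel <- sweep(pts, 2, ctr) %*% t(rot)
  role <- character(4)
  role[rel[, 1] < 0 & rel[, 2] < 0] <- "as"
  role[rel[, 1] >= 0 & rel[, 2] < 0] <- "ps"
  role[rel[, 1] >= 0 & rel[, 2] >= 0] <- "pi"
  role[rel[, 1] < 0 & rel[, 2] >= 0] <- "ai"
  if (anyDuplicated(role) || any(role == "")) {
    # fall back: order by angle around the centroid, starting cranial-left
    ang <- atan2(rel[, 2], rel[, 1])
    ord <- order(ang)  # -pi..pi: as (-3pi/4), ps (-pi/4), pi (pi/4), ai (3pi/4)
    out <- pts[ord, , drop = FALSE]
    rownames(out) <- c("as", "ps", "pi", "ai")
    return(out)
  }
  out <- pts[match(c("as", "ps", "pi", "ai"), role), , drop = FALSE]
  rownames(out) <- c("as", "ps", "pi", "ai")
  out
}

comp_check <- function(comp) {
  stopifnot(inherits(comp, "vertebra_component"))
  idx <- which(comp$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty component")
  if (diff(range(idx[, 1])) < 2L || diff(range(idx[, 2])) < 2L) {
    stop("degenerate component: width or height below 3 px")
  }
  idx
}

#' Corner detection by basin-hopping refinement
#'
#' Starts from the corners of the component's minimum-area bounding
#' rectangle (each snapped to the nearest border pixel — corner landmarks
#' live on the vertebra border) and maximizes the overlap of the
#' quadrilateral spanned by the four points with the component. The
#' objective is the covered mask fraction `|mask ∩ quad| / |mask|`; with
#' corners constrained to the border this equals the IoU on convex bodies
#' while keeping the corners anatomical on concave endplates (a pure IoU
#' objective would pull the superior corners into deep endplate
#' depressions and bias every height measurement). The search is
#' parameterized over positions along the traced border polyline: each
#' basin-hopping iteration perturbs the four border positions with
#' Gaussian arc-length steps and refines them by cyclic coordinate
#' descent; a move is kept only if the objective improves
#' (zero-temperature acceptance). Deterministic for a fixed seed.
#'
#' @param comp a `vertebra_component`
#' @param seed integer seed
#' @param iterations basin-hopping iterations (default 50)
#' @param step_mm Gaussian perturbation SD in mm of arc length
#' @return a `corner_quad` (strategy "basin-hopping")
#' @export
corners_basinhopping <- function(comp, seed = 0L, iterations = 50L,
                                 step_mm = 3) {
  idx <- comp_check(comp)
  sp <- comp$spacing_mm
  bnd_mm <- px_to_mm(trace_boundary(comp$mask), sp)
  nb <- nrow(bnd_mm)
  rect <- min_area_rect(bnd_mm)

  # evaluate the IoU on a cropped window around the component; corners sit
  # on the border, so the polygon never leaves the window
  mar <- 3L
  r0 <- max(1L, min(idx[, 1]) - mar); r1 <- min(nrow(comp$mask), max(idx[, 1]) + mar)
  c0 <- max(1L, min(idx[, 2]) - mar); c1 <- min(ncol(comp$mask), max(idx[, 2]) + mar)
  subm <- comp$mask[r0:r1, c0:c1] > 0
  wr <- rep(seq(r0, r1), times = c1 - c0 + 1L)
  wc <- rep(seq(c0, c1), each = r1 - r0 + 1L)
  wx <- (wc - 1) * sp; wy <- (wr - 1) * sp
  mvec <- as.vector(subm)
  n_mask <- sum(mvec)
  # covered mask fraction, with a sub-pixel polygon-area tie-break: when a
  # candidate move changes no pixel membership (thin slivers), prefer the
  # larger quad, i.e. the outermost (anatomical) corner
  area_norm <- n_mask * sp^2
  obj <- function(ix) {
    poly <- bnd_mm[ix, , drop = FALSE]
    inside <- point_in_polygon(wx, wy, poly)
    a <- abs(sum(poly[, 1] * (poly[c(2:4, 1), 2] - poly[c(4, 1:3), 2])) / 2)
    sum(inside & mvec) / n_mask + 3e-5 * a / area_norm
  }
  snap <- function(p) {
    which.min((bnd_mm[, 1] - p[1])^2 + (bnd_mm[, 2] - p[2])^2)
  }
  wrap <- function(i) (i - 1L) %% nb + 1L

  refine <- function(ix, v) {
    steps <- unique(pmax(1L, round(c(8, 4, 2, 1) * step_mm / (4 * sp))))
    repeat {
      improved <- FALSE
      for (ci in 1:4) for (s in c(steps, -steps)) {
        ix2 <- ix
        ix2[ci] <- wrap(ix2[ci] + s)
        if (anyDuplicated(ix2)) next
        v2 <- obj(ix2)
        if (v2 > v) { ix <- ix2; v <- v2; improved <- TRUE }
      }
      if (!improved) break
    }
    list(ix = ix, v = v)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ix0 <- vapply(seq_len(4), function(i) snap(rect[i, ]), integer(1))
  if (anyDuplicated(ix0)) ix0 <- wrap(round(seq(1, nb, length.out = 5)[1:4]))
  res <- refine(ix0, obj(ix0))
  best <- res$ix; best_v <- res$v
  cur <- best; cur_v <- best_v
  sigma <- max(1, step_mm / sp)
  for (it in seq_len(iterations)) {
    cand <- wrap(cur + as.integer(round(stats::rnorm(4, 0, sigma))))
    if (anyDuplicated(cand)) next
    res <- refine(cand, obj(cand))
    if (res$v > best_v) { best <- res$ix; best_v <- res$v }
    if (res$v > cur_v) { cur <- res$ix; cur_v <- res$v }
  }
  # the quad's reported overlap score is the selector's IoU, not the
  # internal coverage objective; never return a quad the initialization
  # beats on that score
  out <- new_corner_quad(assign_roles(bnd_mm[best, , drop = FALSE], comp),
                         "basin-hopping", comp)
  init <- new_corner_quad(assign_roles(bnd_mm[ix0, , drop = FALSE], comp),
                          "basin-hopping", comp)
  if (init$overlap > out$overlap) init else out
}

# k-cosine discrete curvature along a closed polyline (n x 2): the angle at
# vertex i between the chords to the vertices k steps behind and ahead.
# Returns values in [0, pi]: straight = 0 (cos = -1 mapped accordingly).
k_cosine_curvature <- function(path, k) {
  n <- nrow(path)
  ahead <- path[(seq_len(n) + k - 1L) %% n + 1L, , drop = FALSE]
  behind <- path[(seq_len(n) - k - 1L) %% n + 1L, , drop = FALSE]
  a <- ahead - path
  b <- behind - path
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  cosang <- rowSums(a * b) / pmax(na * nb, 1e-12)
  cosang <- pmin(pmax(cosang, -1), 1)
  # sharp corner -> vectors nearly parallel -> cos near +1
  cosang
}

#' Corner detection by boundary curvature
#'
#' The traced mask border serves as the concave hull of the segmentation
#' boundary; `hull_alpha` sets the resampling step of the border polyline
#' (the hull's scale parameter). Discrete curvature is estimated with the
#' k-cosine measure over `window` polyline vertices, and the four curvature
#' maxima separated by at least one eighth of the perimeter are returned,
#' roles assigned by quadrant relative to the centroid.
#'
#' @param comp a `vertebra_component`
#' @param hull_alpha border resampling step in mm (default 3 x spacing)
#' @param window k-cosine half-window in polyline vertices (default 7)
#' @return a `corner_quad` (strategy "curvature")
#' @export
corners_curvature <- function(comp, hull_alpha = 3 * comp$spacing_mm,
                              window = 7L) {
  comp_check(comp)
  sp <- comp$spacing_mm
  bnd_mm <- px_to_mm(trace_boundary(comp$mask), sp)
  path <- resample_polyline(bnd_mm, hull_alpha)
  n <- nrow(path)
  if (n < 4L * window) {
    stop("boundary too short (", n, " vertices) for curvature window ", window)
  }
  curv <- k_cosine_curvature(path, window)
  min_sep <- n / 8  # one quarter of half the perimeter
  ord <- order(curv, decreasing = TRUE)
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) == 4L) break
    gaps <- vapply(picked, function(j) {
      d <- abs(i - j); min(d, n - d)
    }, numeric(1))
    if (all(gaps >= min_sep)) picked <- c(picked, i)
  }
  if (length(picked) < 4L) {
    stop("no four separated curvature maxima on the boundary ",
         "(near-circular component?)")
  }
  pts <- path[sort(picked), , drop = FALSE]
  # sub-alpha refinement: around each coarse peak, re-maximize a short-span
  # k-cosine on the full-resolution border
  nb <- nrow(bnd_mm)
  if (nb >= 24L) {
    k_fine <- 5L
    curv_fine <- k_cosine_curvature(bnd_mm, k_fine)
    radius <- ceiling(hull_alpha / sp) + 2L
    pts <- t(apply(pts, 1, function(p) {
      i0 <- which.min((bnd_mm[, 1] - p[1])^2 + (bnd_mm[, 2] - p[2])^2)
      win <- ((i0 - radius):(i0 + radius) - 1L) %% nb + 1L
      bnd_mm[win[which.max(curv_fine[win])], ]
    }))
  }
  new_corner_quad(assign_roles(pts, comp), "curvature", comp)
}

# resample a closed polyline at (approximately) equal arc steps
resample_polyline <- function(path, step) {
  closed <- rbind(path, path[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n_out <- max(8L, ceiling(total / step))
  targets <- seq(0, total, length.out = n_out + 1L)[-(n_out + 1L)]
  i <- findInterval(targets, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(closed) - 1L)
  frac <- (targets - cum[i]) / pmax(seg[i], 1e-12)
  closed[i, , drop = FALSE] + frac * (closed[i + 1L, , drop = FALSE] -
                                        closed[i, , drop = FALSE])
}

#' Corner detection by side line fitting
#'
#' Boundary pixels are partitioned into the four sides of the body by
#' angular sector around the centroid (sectors aligned to the principal
#' axes). Only border points on (or within one pixel of) the component's
#' convex hull enter the fits, so a concave endplate contributes its
#' support line — the line a reader would draw across the depression —
#' rather than a mid-depth chord. A robust line is fitted to each side
#' (total least squares with one residual-trimming pass), and the corners
#' are the pairwise intersections of adjacent side lines, each snapped to
#' the nearest boundary point.
#'
#' @param comp a `vertebra_component`
#' @param trim fraction of worst-residual points dropped in the second fit
#'   pass
#' @return a `corner_quad` (strategy "line-fit")
#' @export
corners_linefit <- function(comp, trim = 0.2) {
  comp_check(comp)
  sp <- comp$spacing_mm
  bnd_all <- px_to_mm(trace_boundary(comp$mask), sp)
  ctr <- comp$centroid_mm
  hull <- bnd_all[grDevices::chull(bnd_all), , drop = FALSE]
  hd <- dist_to_polygon(bnd_all, hull)
  bnd_mm <- bnd_all[hd <= 0.55 * sp, , drop = FALSE]
  if (nrow(bnd_mm) < 12L) bnd_mm <- bnd_all[hd <= 1.01 * sp, , drop = FALSE]
  if (nrow(bnd_mm) < 12L) bnd_mm <- bnd_all
  # partition by the nearest side of the minimum-area bounding rectangle:
  # adapts to aspect ratio, tilt and wedge asymmetry, where fixed diagonal
  # sectors can leave a short side without pixels
  rect <- min_area_rect(bnd_all)
  edge_dist <- vapply(1:4, function(i) {
    j <- i %% 4L + 1L
    dist_to_polygon(bnd_mm, rbind(rect[i, ], rect[j, ], rect[j, ]))
  }, numeric(nrow(bnd_mm)))
  side_of <- max.col(-edge_dist, ties.method = "first")
  sides <- lapply(1:4, function(s) bnd_mm[side_of == s, , drop = FALSE])
  fit_line <- function(pts) {
    if (nrow(pts) < 3L) stop("side with fewer than 3 boundary pixels")
    tls <- function(p) {
      c0 <- colMeans(p)
      sv <- svd(sweep(p, 2, c0))
      list(p0 = c0, dir = sv$v[, 1])
    }
    f <- tls(pts)
    if (nrow(pts) >= 5L) {
      nrm <- c(-f$dir[2], f$dir[1])
      res <- abs((pts[, 1] - f$p0[1]) * nrm[1] + (pts[, 2] - f$p0[2]) * nrm[2])
      keep <- res <= stats::quantile(res, 1 - trim)
      if (sum(keep) >= 3L) f <- tls(pts[keep, , drop = FALSE])
    }
    f
  }
  lines <- lapply(sides, fit_line)
  meet <- function(l1, l2) {
    # p0 + t d crossing
    A <- cbind(l1$dir, -l2$dir)
    if (abs(det(A)) < 1e-9) stop("parallel side lines cannot intersect")
    t <- solve(A, l2$p0 - l1$p0)
    l1$p0 + t[1] * l1$dir
  }
  # adjacent sectors meet at the rectangle-corner directions; roles are
  # assigned afterwards from the geometry
  raw <- rbind(
    meet(lines[[1]], lines[[2]]),
    meet(lines[[2]], lines[[3]]),
    meet(lines[[3]], lines[[4]]),
    meet(lines[[4]], lines[[1]])
  )
  # "next to the intersections": snap each to the nearest boundary point
  snap <- t(apply(raw, 1, function(p) {
    bnd_mm[which.min((bnd_mm[, 1] - p[1])^2 + (bnd_mm[, 2] - p[2])^2), ]
  }))
  new_corner_quad(assign_roles(snap, comp), "line-fit", comp)
}

#' Run all three corner strategies and keep the best quad
#'
#' The quad maximizing the IoU between the component mask and the polygon
#' spanned by the four corners wins; exact ties fall to the fixed strategy
#' order basin-hopping > curvature > line-fit. Individual strategy failures
#' are tolerated; if all fail, an error lists every per-strategy reason.
#'
#' @param comp a `vertebra_component`
#' @param seed seed for the basin-hopping strategy
#' @param iterations basin-hopping iteration cap
#' @return the winning `corner_quad`
#' @export
detect_corners <- function(comp, seed = 0L, iterations = 50L) {
  quads <- list(
    `basin-hopping` = try(corners_basinhopping(comp, seed = seed,
                                               iterations = iterations),
                          silent = TRUE),
    curvature = try(corners_curvature(comp), silent = TRUE),
    `line-fit` = try(corners_linefit(comp), silent = TRUE)
  )
  select_corners(comp, quads)
}

#' @rdname detect_corners
#' @param quads named list of `corner_quad`s (or `try-error`s) in strategy
#'   order
#' @export
select_corners <- function(comp, quads) {
  ok <- !vapply(quads, inherits, logical(1), "try-error")
  if (!any(ok)) {
    reasons <- vapply(quads, function(e) conditionMessage(attr(e, "condition")),
                      character(1))
    stop("all corner strategies failed: ",
         paste(names(quads), reasons, sep = ": ", collapse = "; "))
  }
  quads <- quads[ok]
  scores <- vapply(quads, function(q) q$overlap, numeric(1))
  # which.max keeps the first maximum: list order = strategy precedence
  quads[[which.max(scores)]]
}
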