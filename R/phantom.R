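# Synthetic mid-sagittal lumbar spine phantom.
#
# The phantom renders a stack of vertebral bodies on a T2-like canvas:
# each body is a quadrilateral whose superior and inferior edges are
# replaced by circular arcs curving into the body (endplate concavity).
# Geometry is defined analytically in millimetres, so ground-truth corner
# landmarks and morphometry come from the generating shape, never from the
# rendered raster. Orientation: anterior = left image border, cranial = top.

#' Phantom configuration
#'
#' Describes a stack of vertebral bodies to simulate. Defaults emulate a
#' healthy adult lumbar column (T12 analog down to S1): body height 27 mm,
#' width 33 mm, 9 mm disc gaps, 1 mm baseline endplate concavity, rendered
#' at 0.6 x 0.6 mm like a standardized sagittal T2 slice.
#'
#' @param n_vertebrae number of bodies (default 7, a T12..S1 analog)
#' @param vertebra_height_mm healthy posterior height in mm
#' @param vertebra_width_mm anteroposterior width in mm
#' @param disc_gap_mm intervertebral gap in mm
#' @param endplate_concavity_mm healthy baseline depression depth in mm
#' @param deformities list of per-vertebra entries
#'   `list(type = "none"|"wedge"|"concave"|"crush", severity = s)` with
#'   `s` in \[0, 1\]; recycled `"none"` entries fill the remainder
#' @param pixel_spacing_mm in-plane spacing of the rendered raster
#' @param noise_sd additive Gaussian noise SD on the unit intensity scale
#' @param tilt_deg per-vertebra rotation in degrees, each in \[-15, 15\]
#'   (positive = clockwise in image coordinates); scalar recycled
#' @param canvas_px integer (rows, cols) of the rendered raster; the default
#'   448 x 320 matches the pipeline's standard slice
#' @param bone_intensity,background_intensity,disc_intensity unit-scale
#'   rendering intensities; bone must exceed background and disc
#' @param max_anterior_loss maximum fractional height loss at severity 1 for
#'   wedge/crush deformities (default 0.6: severity 1 keeps 40% of height)
#' @param max_concavity_mm depression depth at concave severity 1 (default 6)
#' @param labels optional character vector of anatomical names,
#'   cranial to caudal; default picks the caudal-most `n_vertebrae` of
#'   c("T11","T12","L1","L2","L3","L4","L5","S1")
#' @param seed integer seed for the noise generator
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(n_vertebrae = 7,
                           vertebra_height_mm = 27,
                           vertebra_width_mm = 33,
                           disc_gap_mm = 9,
                           endplate_concavity_mm = 1,
                           deformities = list(),
                           pixel_spacing_mm = 0.6,
                           noise_sd = 0.02,
                           tilt_deg = 0,
                           canvas_px = c(448L, 320L),
                           bone_intensity = 0.8,
                           background_intensity = 0.35,
                           disc_intensity = 0.15,
                           max_anterior_loss = 0.6,
                           max_concavity_mm = 6,
                           labels = NULL,
                           seed = 0L) {
  stopifnot(
    n_vertebrae >= 1,
    vertebra_height_mm > 0, vertebra_width_mm > 0, disc_gap_mm > 0,
    endplate_concavity_mm >= 0, pixel_spacing_mm > 0, noise_sd >= 0,
    max_anterior_loss > 0, max_anterior_loss < 1,
    max_concavity_mm > endplate_concavity_mm,
    bone_intensity > background_intensity,
    bone_intensity > disc_intensity
  )
  n_vertebrae <- as.integer(n_vertebrae)
  tilt_deg <- rep_len(tilt_deg, n_vertebrae)
  if (any(abs(tilt_deg) > 15)) {
    stop("tilt_deg must lie in [-15, 15] degrees")
  }
  defs <- vector("list", n_vertebrae)
  for (i in seq_len(n_vertebrae)) {
    d <- if (i <= length(deformities) && !is.null(deformities[[i]])) {
      deformities[[i]]
    } else {
      list(type = "none", severity = 0)
    }
    if (is.null(d$severity)) d$severity <- 0
    if (!d$type %in% c("none", "wedge", "concave", "crush")) {
      stop("unknown deformity type: ", d$type)
    }
    if (d$severity < 0 || d$severity > 1) stop("severity must lie in [0, 1]")
    # severity 0 is geometrically identical to 'none'
    if (d$severity == 0) d$type <- "none"
    defs[[i]] <- d
  }
  if (is.null(labels)) {
    full <- c("T11", "T12", "L1", "L2", "L3", "L4", "L5", "S1")
    if (n_vertebrae > length(full)) {
      labels <- sprintf("V%02d", seq_len(n_vertebrae))
    } else {
      labels <- utils::tail(full, n_vertebrae)
    }
  }
  stopifnot(length(labels) == n_vertebrae)
  structure(
    list(
      n_vertebrae = n_vertebrae,
      vertebra_height_mm = vertebra_height_mm,
      vertebra_width_mm = vertebra_width_mm,
      disc_gap_mm = disc_gap_mm,
      endplate_concavity_mm = endplate_concavity_mm,
      deformities = defs,
      pixel_spacing_mm = pixel_spacing_mm,
      noise_sd = noise_sd,
      tilt_deg = tilt_deg,
      canvas_px = as.integer(canvas_px),
      bone_intensity = bone_intensity,
      background_intensity = background_intensity,
      disc_intensity = disc_intensity,
      max_anterior_loss = max_anterior_loss,
      max_concavity_mm = max_concavity_mm,
      labels = labels,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

# Analytic vertebra shape: corners in role order plus endplate arc depths.
# Corner roles (orientation anterior = left, cranial = top, y grows caudally):
#   as = anterosuperior, ps = posterosuperior,
#   pi = posteroinferior, ai = anteroinferior
vertebra_shape <- function(height, width, concavity) {
  list(
    corners = rbind(
      as = c(0, 0),
      ps = c(width, 0),
      pi = c(width, height),
      ai = c(0, height)
    ),
    sup_depth = concavity,
    inf_depth = concavity
  )
}

#' Apply a Genant-style deformity to an analytic vertebra shape
#'
#' * `wedge`: the anterosuperior corner moves caudally so the anterior height
#'   becomes `(1 - severity * max_loss)` of baseline; the posterior edge is
#'   untouched.
#' * `concave`: the superior depression deepens linearly from its baseline to
#'   `max_depth_mm` at severity 1; corners are untouched.
#' * `crush`: both superior corners move caudally by the same factor, a
#'   global height loss.
#' * `none`: identity.
#'
#' @param shape list with `corners` (4 x 2, roles as/ps/pi/ai) and
#'   `sup_depth`, `inf_depth` arc depths, as built by the generator
#' @param type one of "none", "wedge", "concave", "crush"
#' @param severity fraction in \[0, 1\]
#' @param max_loss fractional height loss at severity 1 (wedge/crush)
#' @param max_depth_mm depression depth at concave severity 1
#' @return deformed shape (same structure)
#' @export
apply_deformity <- function(shape, type, severity,
                            max_loss = 0.6, max_depth_mm = 6) {
  stopifnot(severity >= 0, severity <= 1)
  type <- match.arg(type, c("none", "wedge", "concave", "crush"))
  if (type == "none" || severity == 0) return(shape)
  corners <- shape$corners
  h_ant <- corners["ai", 2] - corners["as", 2]
  h_post <- corners["pi", 2] - corners["ps", 2]
  if (type == "wedge") {
    loss <- severity * max_loss * h_ant
    corners["as", 2] <- corners["as", 2] + loss
  } else if (type == "crush") {
    corners["as", 2] <- corners["as", 2] + severity * max_loss * h_ant
    corners["ps", 2] <- corners["ps", 2] + severity * max_loss * h_post
  } else if (type == "concave") {
    # both endplate depressions deepen; a biconcave ("fish") vertebra
    shape$sup_depth <- shape$sup_depth +
      severity * (max_depth_mm - shape$sup_depth)
    shape$inf_depth <- shape$inf_depth +
      severity * (max_depth_mm - shape$inf_depth)
  }
  shape$corners <- corners
  shape
}

# Endplate depression edge from p0 to p1: flat shoulders at both ends and a
# circular arc over the central `span` fraction of the chord, dipping by
# `depth` toward unit normal `nrm`. Real concave deformities depress the
# central endplate while the cortical rim at the corners stays close to
# perpendicular; full-width arcs would instead create acute corner tips
# that no imaging grid (or reader) could localize.
endplate_edge <- function(p0, p1, depth, nrm, n = 24, span = 0.8) {
  if (depth <= 0) return(NULL)
  s0 <- p0 + (1 - span) / 2 * (p1 - p0)
  s1 <- p0 + (1 + span) / 2 * (p1 - p0)
  rbind(s0, arc_points(s0, s1, depth, nrm, n), s1)
}

# Sample a circular arc from p0 to p1 bulging by `depth` toward the side of
# unit normal `nrm` (depth measured perpendicular to the chord at midpoint).
# Returns interior points only (excludes endpoints), ordered p0 -> p1.
arc_points <- function(p0, p1, depth, nrm, n = 24) {
  if (depth <= 0) return(NULL)
  chord <- p1 - p0
  L <- sqrt(sum(chord^2))
  # circle through p0, p1 with sagitta = depth
  R <- (L^2 / 4 + depth^2) / (2 * depth)
  mid <- (p0 + p1) / 2
  centre <- mid + (depth - R) * nrm
  a0 <- atan2(p0[2] - centre[2], p0[1] - centre[1])
  a1 <- atan2(p1[2] - centre[2], p1[1] - centre[1])
  # walk the minor arc from a0 to a1 (the one bulging toward nrm)
  da <- a1 - a0
  while (da > pi) da <- da - 2 * pi
  while (da < -pi) da <- da + 2 * pi
  tt <- seq(0, 1, length.out = n + 2)[-c(1, n + 2)]
  ang <- a0 + tt * da
  cbind(centre[1] + R * cos(ang), centre[2] + R * sin(ang))
}

# Closed polygon (mm) of a deformed, tilted, translated vertebra shape.
# Endplate arcs bulge INTO the body: superior arc caudally, inferior arc
# cranially, perpendicular to the respective corner chord.
vertebra_polygon <- function(shape, tilt_deg = 0, offset = c(0, 0),
                             n_arc = 24) {
  co <- shape$corners
  # inward normals (pre-tilt, y down): superior chord normal points caudally
  sup_dir <- co["ps", ] - co["as", ]
  sup_n <- c(-sup_dir[2], sup_dir[1]) / sqrt(sum(sup_dir^2))
  if (sup_n[2] < 0) sup_n <- -sup_n
  inf_dir <- co["ai", ] - co["pi", ]
  inf_n <- c(-inf_dir[2], inf_dir[1]) / sqrt(sum(inf_dir^2))
  if (inf_n[2] > 0) inf_n <- -inf_n
  poly <- rbind(
    co["as", , drop = FALSE],
    endplate_edge(co["as", ], co["ps", ], shape$sup_depth, sup_n, n_arc),
    co["ps", , drop = FALSE],
    co["pi", , drop = FALSE],
    endplate_edge(co["pi", ], co["ai", ], shape$inf_depth, inf_n, n_arc),
    co["ai", , drop = FALSE]
  )
  rot <- rotation_matrix(tilt_deg)
  ctr <- colMeans(co)
  poly <- sweep(poly, 2, ctr) %*% t(rot)
  poly <- sweep(poly, 2, ctr + offset, "+")
  corners <- sweep(co, 2, ctr) %*% t(rot)
  corners <- sweep(corners, 2, ctr + offset, "+")
  rownames(corners) <- rownames(co)
  list(polygon = poly, corners = corners)
}

rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Analytic morphometry of a (deformed, tilted) shape. All quantities are
# invariant to the tilt/offset, so they are evaluated on the pre-tilt
# shape. The central height uses the same perpendicular-line construction
# as the measurement module, applied to the exact generating polygon, so
# truth and measurement share one definition.
shape_truth_morphometry <- function(shape) {
  co <- shape$corners
  ah <- sqrt(sum((co["as", ] - co["ai", ])^2))
  ph <- sqrt(sum((co["ps", ] - co["pi", ])^2))
  u_s <- (co["ps", ] - co["as", ]); u_s <- u_s / sqrt(sum(u_s^2))
  u_i <- (co["pi", ] - co["ai", ]); u_i <- u_i / sqrt(sum(u_i^2))
  va <- atan2(u_s[1] * u_i[2] - u_s[2] * u_i[1], sum(u_s * u_i)) * 180 / pi
  sup_n <- c(-u_s[2], u_s[1]); if (sup_n[2] < 0) sup_n <- -sup_n
  inf_n <- c(-u_i[2], u_i[1]); if (inf_n[2] > 0) inf_n <- -inf_n
  sup_path <- rbind(co["as", , drop = FALSE],
                    endplate_edge(co["as", ], co["ps", ], shape$sup_depth,
                                  sup_n, n = 200),
                    co["ps", , drop = FALSE])
  inf_path <- rbind(co["pi", , drop = FALSE],
                    endplate_edge(co["pi", ], co["ai", ], shape$inf_depth,
                                  inf_n, n = 200),
                    co["ai", , drop = FALSE])
  ch <- central_height(co, sup_path, inf_path, central_fraction = 0.5)
  c(AH = ah, PH = ph, CH = ch, SC = shape$sup_depth, IC = shape$inf_depth,
    VA = va)
}

#' Generate a synthetic mid-sagittal lumbar spine phantom
#'
#' Renders the configured stack of vertebral bodies as a T2-like intensity
#' image plus a labelled mask, and returns analytic ground truth (corner
#' landmarks, morphometry, fracture status) computed from the generating
#' geometry — never measured from the raster. Equal (config, seed) give
#' bit-identical output.
#'
#' Truth fracture status is obtained by running the package's Genant
#' classifier ([classify_vertebra()]) on the analytic morphometry with the
#' shipped default reference norms, so truth and generating thresholds are
#' consistent by construction.
#'
#' @param config a [phantom_config()]
#' @return list of class `phantom` with elements
#'   \describe{
#'     \item{image}{numeric matrix, unit intensity range, standard-slice
#'       compatible (attributes `spacing_mm`, `orientation`)}
#'     \item{labels}{integer matrix, 0 background, vertebra i = i
#'       (cranial to caudal)}
#'     \item{truth}{data frame: label, four corner coordinates (mm),
#'       AH/PH/CH/SC/IC/VA, deformity, severity, fractured}
#'     \item{corners}{list of 4 x 2 corner matrices (mm), roles
#'       as/ps/pi/ai, per vertebra}
#'     \item{config}{the input configuration}
#'   }
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(n_vertebrae = 5, noise_sd = 0))
#' ph$truth[, c("label", "AH", "PH", "VA", "fractured")]
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  sp <- config$pixel_spacing_mm
  nr <- config$canvas_px[1]; nc <- config$canvas_px[2]
  n <- config$n_vertebrae
  h <- config$vertebra_height_mm
  w <- config$vertebra_width_mm
  gap <- config$disc_gap_mm

  stack_h <- n * h + (n - 1) * gap
  canvas_h <- (nr - 1) * sp
  canvas_w <- (nc - 1) * sp
  if (stack_h > canvas_h - 2 * gap) {
    stop("geometry infeasible: vertebral stack (", round(stack_h, 1),
         " mm) does not fit the canvas (", round(canvas_h, 1), " mm)")
  }
  # half-pixel offset keeps polygon edges off the pixel-centre lattice,
  # avoiding borderline membership ties in the rasterizer
  x0 <- round((canvas_w - w) / 2 / sp) * sp + sp / 2
  y0 <- round((canvas_h - stack_h) / 2 / sp) * sp + sp / 2

  shapes <- vector("list", n)
  polys <- vector("list", n)
  corners <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- config$deformities[[i]]
    sh <- vertebra_shape(h, w, config$endplate_concavity_mm)
    sh <- apply_deformity(sh, d$type, d$severity,
                          max_loss = config$max_anterior_loss,
                          max_depth_mm = config$max_concavity_mm)
    # deformities remove height from the superior side; keep the inferior
    # endplate on its healthy line so disc gaps are preserved
    off <- c(x0, y0 + (i - 1) * (h + gap))
    vp <- vertebra_polygon(sh, config$tilt_deg[i], off)
    shapes[[i]] <- sh
    polys[[i]] <- vp$polygon
    corners[[i]] <- vp$corners
    tm <- shape_truth_morphometry(sh)
    truth_rows[[i]] <- data.frame(
      label = config$labels[i],
      as_x = vp$corners["as", 1], as_y = vp$corners["as", 2],
      ps_x = vp$corners["ps", 1], ps_y = vp$corners["ps", 2],
      pi_x = vp$corners["pi", 1], pi_y = vp$corners["pi", 2],
      ai_x = vp$corners["ai", 1], ai_y = vp$corners["ai", 2],
      AH = tm["AH"], PH = tm["PH"], CH = tm["CH"],
      SC = tm["SC"], IC = tm["IC"], VA = tm["VA"],
      deformity = d$type, severity = d$severity,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  labels <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    # area-sampled rendering (partial-volume-like): keeps the thin tips at
    # acute corners that pixel-centre sampling would drop
    m <- rasterize_polygon_area(polys[[i]], nr, nc, sp)
    if (any(labels[m] != 0L)) {
      stop("geometry infeasible: vertebra ", i,
           " overlaps a neighbour after deformity/tilt")
    }
    labels[m] <- i
  }

  img <- matrix(config$background_intensity, nr, nc)
  # disc band: the corridor between consecutive inferior/superior endplates
  for (i in seq_len(n - 1)) {
    ytop <- max(polys[[i]][, 2])
    ybot <- min(polys[[i + 1]][, 2])
    r0 <- max(1L, floor(ytop / sp) + 1L)
    r1 <- min(nr, ceiling(ybot / sp) + 1L)
    c0 <- max(1L, floor(x0 / sp) + 1L)
    c1 <- min(nc, ceiling((x0 + w) / sp) + 1L)
    if (r0 <= r1 && c0 <= c1) {
      block <- img[r0:r1, c0:c1]
      block[labels[r0:r1, c0:c1] == 0L] <- config$disc_intensity
      img[r0:r1, c0:c1] <- block
    }
  }
  img[labels > 0L] <- config$bone_intensity
  if (config$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(config$seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    img <- pmin(pmax(img, 0), 1)
  }
  attr(img, "spacing_mm") <- sp
  attr(img, "orientation") <- c(anterior = "left", cranial = "top")
  attr(labels, "spacing_mm") <- sp
  attr(labels, "orientation") <- c(anterior = "left", cranial = "top")

  # truth fracture status from the analytic morphometry under default norms
  norms <- default_reference_norms()
  calls <- character(n); fractured <- logical(n)
  for (i in seq_len(n)) {
    mi <- as.list(truth[i, c("AH", "PH", "CH", "SC", "IC", "VA")])
    nb <- lapply(setdiff(c(i - 1, i + 1), c(0, n + 1)), function(j) {
      as.list(truth[j, c("AH", "PH", "CH", "SC", "IC", "VA")])
    })
    fc <- classify_vertebra(mi, neighbors = nb, norms = norms,
                            label = truth$label[i])
    calls[i] <- fc$deformity
    fractured[i] <- fc$fractured
  }
  truth$fractured <- fractured
  truth$truth_call <- calls

  structure(
    list(image = img, labels = labels, truth = truth,
         corners = corners, polygons = polys, config = config),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("Synthetic spine phantom:", x$config$n_vertebrae, "vertebrae,",
      nrow(x$image), "x", ncol(x$image), "px @",
      x$config$pixel_spacing_mm, "mm\n")
  cat("Deformities:",
      paste(sprintf("%s=%s(%.2g)", x$truth$label, x$truth$deformity,
                    x$truth$severity), collapse = ", "), "\n")
  invisible(x)
}

#' Write phantom outputs to disk
#'
#' Writes the image and label mask as NIfTI (pixel spacing in the header),
#' the truth table as CSV, and optionally plain-text PGM previews.
#'
#' @param phantom a [generate_phantom()] result
#' @param dir output directory (created if needed)
#' @param pgm also write P2 PGM previews
#' @return invisibly, the written file paths
#' @export
write_phantom <- function(phantom, dir, pgm = FALSE) {
  stopifnot(inherits(phantom, "phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- phantom$config$pixel_spacing_mm
  paths <- c(
    image = file.path(dir, "phantom.nii"),
    labels = file.path(dir, "phantom_labels.nii"),
    truth = file.path(dir, "phantom_truth.csv")
  )
  write_nifti(phantom$image, paths["image"], spacing = c(sp, sp))
  write_nifti(phantom$labels, paths["labels"], spacing = c(sp, sp),
              datatype = "int16")
  tr <- phantom$truth
  utils::write.csv(
    tr[, c("label", "AH", "PH", "CH", "SC", "IC", "VA",
           "deformity", "fractured")],
    paths["truth"], row.names = FALSE)
  if (pgm) {
    paths <- c(paths, preview = file.path(dir, "phantom.pgm"))
    write_pgm(phantom$image, paths["preview"])
  }
  invisible(paths)
}
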