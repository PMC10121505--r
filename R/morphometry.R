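# Vertebral morphometry and Genant-rule deformity classification.
#
# Measurement definitions (mid-sagittal, orientation anterior = left,
# cranial = top):
#   AH  anterior height  = |anterosuperior - anteroinferior|
#   PH  posterior height = |posterosuperior - posteroinferior|
#   SC  superior endplate concavity: maximum perpendicular depression of the
#       superior boundary below the anterosuperior->posterosuperior chord
#   IC  inferior analog (depression above the inferior chord)
#   VA  signed angle between the superior and inferior chords; positive when
#       they converge anteriorly
#   CH  central height: boundary-to-boundary distance along the perpendicular
#       of the mean chord direction through the mid-chord point

#' Healthy-population reference norms for the Genant ratios
#'
#' Mean and SD of the anterior ratio (AH/PH), middle ratio (CH/PH) and
#' neighbor height ratio (overall height relative to adjacent vertebrae)
#' in a healthy population. The classifier flags a deformity when a ratio
#' falls more than three SDs below its mean.
#'
#' The shipped defaults are plausible placeholders in the spirit of
#' published vertebral morphometry tables; they are NOT clinically
#' validated. Supply population-specific norms for any real use.
#'
#' @param anterior_ratio,middle_ratio,neighbor_height_ratio numeric
#'   `c(mean, sd)` pairs, all entries positive
#' @return object of class `reference_norms`
#' @export
reference_norms <- function(anterior_ratio, middle_ratio,
                            neighbor_height_ratio) {
  check <- function(x, nm) {
    if (length(x) != 2 || any(!is.finite(x)) || x[2] <= 0 || x[1] <= 0) {
      stop("norm '", nm, "' must be c(mean, sd) with mean > 0 and sd > 0")
    }
    stats::setNames(as.numeric(x), c("mean", "sd"))
  }
  structure(
    list(
      anterior_ratio = check(anterior_ratio, "anterior_ratio"),
      middle_ratio = check(middle_ratio, "middle_ratio"),
      neighbor_height_ratio = check(neighbor_height_ratio,
                                    "neighbor_height_ratio")
    ),
    class = "reference_norms"
  )
}

#' @rdname reference_norms
#' @export
default_reference_norms <- function() {
  reference_norms(
    anterior_ratio = c(0.96, 0.04),
    middle_ratio = c(0.91, 0.045),
    neighbor_height_ratio = c(1.00, 0.05)
  )
}

#' Read/write reference norms as a small CSV config
#'
#' Columns: ratio, mean, sd — one row per ratio.
#' @param path file path
#' @param norms a [reference_norms()] object
#' @return `read_reference_norms` returns a `reference_norms` object
#' @export
read_reference_norms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("anterior_ratio", "middle_ratio", "neighbor_height_ratio")
  if (!all(need %in% df$ratio)) {
    stop("norms file must contain rows: ", paste(need, collapse = ", "))
  }
  g <- function(nm) unlist(df[df$ratio == nm, c("mean", "sd")][1, ])
  reference_norms(g(need[1]), g(need[2]), g(need[3]))
}

#' @rdname read_reference_norms
#' @export
write_reference_norms <- function(norms, path) {
  stopifnot(inherits(norms, "reference_norms"))
  df <- data.frame(
    ratio = names(norms),
    mean = vapply(norms, `[[`, numeric(1), "mean"),
    sd = vapply(norms, `[[`, numeric(1), "sd")
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# signed perpendicular distance of points from the line p0 -> p1;
# positive on the side of unit normal `nrm`
signed_dist <- function(pts, p0, nrm) {
  (pts[, 1] - p0[1]) * nrm[1] + (pts[, 2] - p0[2]) * nrm[2]
}

# boundary path (mm polyline) between the boundary vertices nearest to two
# corner points, taking the arc that does NOT contain `avoid`
boundary_path_between <- function(bnd_mm, from, to, avoid) {
  d2 <- function(p) (bnd_mm[, 1] - p[1])^2 + (bnd_mm[, 2] - p[2])^2
  i0 <- which.min(d2(from)); i1 <- which.min(d2(to))
  ia <- which.min(d2(avoid))
  n <- nrow(bnd_mm)
  seq_wrap <- function(a, b) if (a <= b) a:b else c(a:n, 1:b)
  path1 <- seq_wrap(i0, i1)
  path2 <- seq_wrap(i1, i0)
  if (ia %in% path1 && !(ia %in% path2)) path1 <- rev(path2)
  bnd_mm[path1, , drop = FALSE]
}

# first intersection of segment chain `path` with the infinite line through
# `p` along direction `d`; returns all intersection points
polyline_line_intersections <- function(path, p, d) {
  n <- nrow(path)
  if (n < 2) return(NULL)
  a <- path[-n, , drop = FALSE]
  b <- path[-1, , drop = FALSE]
  # solve a + t (b - a) = p + s d  via cross products
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  denom <- ex * d[2] - ey * d[1]
  ok <- abs(denom) > 1e-12
  t <- rep(NA_real_, n - 1)
  t[ok] <- ((p[1] - a[ok, 1]) * d[2] - (p[2] - a[ok, 2]) * d[1]) / denom[ok]
  hit <- ok & t >= 0 & t <= 1
  if (!any(hit)) return(NULL)
  cbind(a[hit, 1] + t[hit] * ex[hit], a[hit, 2] + t[hit] * ey[hit])
}

#' Measure vertebral morphometry from a mask and its corner landmarks
#'
#' @param mask binary matrix of one vertebral body (the component the quad
#'   was detected on)
#' @param quad a `corner_quad` (see [detect_corners()]) or a 4 x 2 matrix of
#'   mm coordinates with rownames as/ps/pi/ai
#' @param spacing_mm pixel spacing (taken from the quad if absent)
#' @param central_fraction chord fraction at which the central height is
#'   read (default 0.5, the mid-body)
#' @return object of class `morphometry`: list with AH, PH, CH, SC, IC
#'   (mm) and VA (degrees, positive = anteriorly converging)
#' @export
measure_vertebra <- function(mask, quad, spacing_mm = NULL,
                             central_fraction = 0.5) {
  co <- if (inherits(quad, "corner_quad")) quad$corners else quad
  if (is.null(spacing_mm)) {
    spacing_mm <- if (inherits(quad, "corner_quad")) quad$spacing_mm else
      stop("spacing_mm required")
  }
  stopifnot(all(c("as", "ps", "pi", "ai") %in% rownames(co)))
  ah <- sqrt(sum((co["as", ] - co["ai", ])^2))
  ph <- sqrt(sum((co["ps", ] - co["pi", ])^2))
  sup <- co["ps", ] - co["as", ]
  inf <- co["pi", ] - co["ai", ]
  ls <- sqrt(sum(sup^2)); li <- sqrt(sum(inf^2))
  if (ls < .Machine$double.eps || li < .Machine$double.eps) {
    stop("degenerate corner quad: zero-length endplate chord")
  }
  u_s <- sup / ls; u_i <- inf / li
  va <- atan2(u_s[1] * u_i[2] - u_s[2] * u_i[1], sum(u_s * u_i)) * 180 / pi

  bnd <- trace_boundary(mask > 0)
  bnd_mm <- px_to_mm(bnd, spacing_mm)

  # concavities: max perpendicular depression of each endplate path into the
  # body, measured from the corner chord (tilt-invariant by construction)
  sup_n <- c(-u_s[2], u_s[1]); if (sup_n[2] < 0) sup_n <- -sup_n  # caudal
  inf_n <- c(-u_i[2], u_i[1]); if (inf_n[2] > 0) inf_n <- -inf_n  # cranial
  sup_path <- boundary_path_between(bnd_mm, co["as", ], co["ps", ], ctr_opposite(co, "sup"))
  inf_path <- boundary_path_between(bnd_mm, co["pi", ], co["ai", ], ctr_opposite(co, "inf"))
  sc <- max(0, signed_dist(sup_path, co["as", ], sup_n))
  ic <- max(0, signed_dist(inf_path, co["pi", ], inf_n))

  ch <- central_height(co, sup_path, inf_path, central_fraction)

  structure(
    list(AH = ah, PH = ph, CH = ch, SC = sc, IC = ic, VA = va,
         spacing_mm = spacing_mm, central_fraction = central_fraction),
    class = "morphometry"
  )
}

# Central height: cast a line along the perpendicular of the mean chord
# direction through the point midway between the two chords at
# `central_fraction`, and take the distance between the body-interior
# crossings of the superior and inferior endplate paths (the crossing
# nearest the mid-body point on each side). Shared by the measurement
# module and the phantom's analytic truth.
central_height <- function(co, sup_path, inf_path, central_fraction = 0.5) {
  u_s <- co["ps", ] - co["as", ]; u_s <- u_s / sqrt(sum(u_s^2))
  u_i <- co["pi", ] - co["ai", ]; u_i <- u_i / sqrt(sum(u_i^2))
  u_mean <- u_s + u_i
  u_mean <- u_mean / sqrt(sum(u_mean^2))
  nrm <- c(-u_mean[2], u_mean[1])
  m_s <- co["as", ] + central_fraction * (co["ps", ] - co["as", ])
  m_i <- co["ai", ] + central_fraction * (co["pi", ] - co["ai", ])
  pmid <- (m_s + m_i) / 2
  hit_s <- polyline_line_intersections(sup_path, pmid, nrm)
  hit_i <- polyline_line_intersections(inf_path, pmid, nrm)
  if (!is.null(hit_s) && !is.null(hit_i)) {
    near <- function(h) h[which.min((h[, 1] - pmid[1])^2 + (h[, 2] - pmid[2])^2), ]
    sqrt(sum((near(hit_s) - near(hit_i))^2))
  } else {
    sqrt(sum((m_s - m_i)^2))   # degenerate fall-back: corner-chord midspan
  }
}

# point diametrically opposite an endplate, used to pick the correct
# boundary arc (the path from as->ps must not pass the inferior side)
ctr_opposite <- function(co, side) {
  if (side == "sup") (co["ai", ] + co["pi", ]) / 2
  else (co["as", ] + co["ps", ]) / 2
}

#' @export
print.morphometry <- function(x, ...) {
  cat(sprintf(
    "Morphometry: AH %.1f  PH %.1f  CH %.1f  SC %.1f  IC %.1f mm;  VA %.1f deg\n",
    x$AH, x$PH, x$CH, x$SC, x$IC, x$VA))
  invisible(x)
}

#' Classify a vertebra as intact or fractured by the Genant rules
#'
#' A wedge deformity is called when the anterior ratio AH/PH falls more than
#' three SDs below the healthy-population mean; a concave deformity when the
#' middle ratio CH/PH does; a crush deformity when the overall height
#' relative to the mean of the available adjacent vertebrae does. All
#' comparisons use strict inequality at mean - 3 SD. When several rules
#' fire, the reported deformity follows the precedence
#' crush > wedge > concave; `fractured` is TRUE if any rule fired.
#'
#' "Overall height" defaults to mean(AH, CH, PH) (configurable via
#' `overall_height`).
#'
#' @param m a [measure_vertebra()] result, or a list with AH, PH, CH
#' @param neighbors list of morphometry objects for adjacent vertebrae; may
#'   be empty, in which case the crush rule is skipped (recorded in audit)
#' @param norms a [reference_norms()] object (required, no silent defaults)
#' @param label optional vertebra name carried into the result
#' @param overall_height function reducing a morphometry to one height
#' @return object of class `fracture_call`: label, fractured, deformity,
#'   and an `audit` data frame with each rule's ratio and threshold
#' @export
classify_vertebra <- function(m, neighbors = list(), norms, label = NA_character_,
                              overall_height = function(x) mean(c(x$AH, x$CH, x$PH))) {
  if (missing(norms) || !inherits(norms, "reference_norms")) {
    stop("reference norms are required (see reference_norms()); no defaults are assumed")
  }
  thr <- function(nm) norms[[nm]]["mean"] - 3 * norms[[nm]]["sd"]

  anterior <- m$AH / m$PH
  middle <- m$CH / m$PH
  wedge <- anterior < thr("anterior_ratio")
  concave <- middle < thr("middle_ratio")

  crush <- FALSE
  crush_ratio <- NA_real_
  if (length(neighbors) > 0) {
    own <- overall_height(m)
    nb <- mean(vapply(neighbors, overall_height, numeric(1)))
    crush_ratio <- own / nb
    crush <- crush_ratio < thr("neighbor_height_ratio")
  }

  deformity <- if (crush) "crush" else if (wedge) "wedge" else
    if (concave) "concave" else "none"
  audit <- data.frame(
    rule = c("wedge", "concave", "crush"),
    ratio = c(anterior, middle, crush_ratio),
    threshold = c(thr("anterior_ratio"), thr("middle_ratio"),
                  thr("neighbor_height_ratio")),
    fired = c(wedge, concave, crush),
    evaluated = c(TRUE, TRUE, length(neighbors) > 0)
  )
  structure(
    list(label = label, fractured = deformity != "none",
         deformity = deformity, audit = audit),
    class = "fracture_call"
  )
}

#' @export
print.fracture_call <- function(x, ...) {
  cat(sprintf("%s: %s (%s)\n",
              ifelse(is.na(x$label), "vertebra", x$label),
              if (x$fractured) "FRACTURED" else "intact", x$deformity))
  invisible(x)
}
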