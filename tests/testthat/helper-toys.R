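# Shared fixtures: toy masks built in code, a component constructor, and
# the exhaustive boundary-subset corner-search oracle.

# wrap a binary matrix as the single vertebra_component it contains
make_component <- function(mask, spacing = 1) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  attr(m, "spacing_mm") <- spacing
  comps <- split_and_label(m, labels = "V1", spacing_mm = spacing)
  stopifnot(length(comps) == 1L)
  comps[[1]]
}

# polygon-rasterized toy mask on an nr x nc grid (polygon in mm)
poly_mask <- function(poly, nr, nc, spacing = 1) {
  vertmorph:::rasterize_polygon(poly, nr, nc, spacing)
}

# axis-aligned or rotated rectangle polygon, optionally with rounded
# corners (radius in mm), centred on the grid
rect_poly <- function(w, h, nr, nc, spacing = 1, angle = 0, round_r = 0) {
  cx <- (nc - 1) * spacing / 2
  cy <- (nr - 1) * spacing / 2
  if (round_r > 0) {
    # quarter arcs at each corner, traversed in consistent cyclic order
    arc <- function(cx, cy, from) {
      a <- seq(from, from + pi / 2, length.out = 8)
      cbind(cx + round_r * cos(a), cy + round_r * sin(a))
    }
    poly <- rbind(
      arc(w / 2 - round_r, -h / 2 + round_r, -pi / 2),  # top-right
      arc(w / 2 - round_r, h / 2 - round_r, 0),         # bottom-right
      arc(-w / 2 + round_r, h / 2 - round_r, pi / 2),   # bottom-left
      arc(-w / 2 + round_r, -h / 2 + round_r, pi)       # top-left
    )
  } else {
    poly <- rbind(c(-w / 2, -h / 2), c(w / 2, -h / 2),
                  c(w / 2, h / 2), c(-w / 2, h / 2))
  }
  if (angle != 0) {
    th <- angle * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    poly <- poly %*% t(rot)
  }
  sweep(poly, 2, c(cx, cy), "+")
}

trapezoid_poly <- function(w, h_ant, h_post, nr, nc, spacing = 1) {
  cx <- (nc - 1) * spacing / 2
  cy <- (nr - 1) * spacing / 2
  poly <- rbind(
    c(-w / 2, -h_ant / 2), c(w / 2, -h_post / 2),
    c(w / 2, h_post / 2), c(-w / 2, h_ant / 2)
  )
  sweep(poly, 2, c(cx, cy), "+")
}

# Exhaustive search over all boundary-pixel 4-subsets (vertices taken in
# boundary cyclic order) maximizing the polygon-mask IoU. Each vertex is
# given the same half-pixel outward extent correction the package applies
# to its landmarks, so oracle and pipeline search the same quad family.
# Vectorized in chunks; intended for toy masks with <= ~50 boundary pixels.
oracle_corner_search <- function(comp, chunk = 2000L) {
  sp <- comp$spacing_mm
  idx <- which(comp$mask > 0, arr.ind = TRUE)
  bnd <- vertmorph:::trace_boundary(comp$mask > 0)
  bnd_mm <- vertmorph:::px_to_mm(bnd, sp)
  n <- nrow(bnd_mm)
  subsets <- utils::combn(n, 4L)
  r0 <- min(idx[, 1]) - 1L; r1 <- max(idx[, 1]) + 1L
  c0 <- min(idx[, 2]) - 1L; c1 <- max(idx[, 2]) + 1L
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  px <- (cc - 1) * sp; py <- (rr - 1) * sp
  inb <- rr >= 1 & rr <= nrow(comp$mask) & cc >= 1 & cc <= ncol(comp$mask)
  mvec <- logical(length(rr))
  mvec[inb] <- comp$mask[cbind(rr[inb], cc[inb])] > 0
  P <- length(px)
  nsub <- ncol(subsets)
  iou <- numeric(nsub)
  for (start in seq(1L, nsub, by = chunk)) {
    cols <- start:min(start + chunk - 1L, nsub)
    sub <- subsets[, cols, drop = FALSE]
    C <- ncol(sub)
    xs <- matrix(bnd_mm[sub, 1], 4L, C)
    ys <- matrix(bnd_mm[sub, 2], 4L, C)
    # half-pixel extent correction, as applied by the package's landmarks
    xs <- xs + sp / 2 * sign(sweep(xs, 2, colMeans(xs)))
    ys <- ys + sp / 2 * sign(sweep(ys, 2, colMeans(ys)))
    inside <- matrix(FALSE, P, C)
    for (m in 1:4) {
      m2 <- m %% 4L + 1L
      yi <- ys[m, ]; yj <- ys[m2, ]; xi <- xs[m, ]; xj <- xs[m2, ]
      t1 <- outer(py, yi, "<")
      t2 <- outer(py, yj, "<")
      crosses <- t1 != t2
      slope <- (xj - xi) / (yj - yi)
      xint <- matrix(xi, P, C, byrow = TRUE) +
        outer(py, yi, "-") * matrix(slope, P, C, byrow = TRUE)
      flip <- crosses & (px < xint)
      inside <- xor(inside, flip)
    }
    inter <- colSums(inside & mvec)
    un <- colSums(inside | mvec)
    iou[cols] <- ifelse(un == 0, 0, inter / un)
  }
  best <- max(iou)
  opt <- which(iou >= best - 1e-9)
  correct <- function(q) {
    ctr <- colMeans(q)
    q + sp / 2 * cbind(sign(q[, 1] - ctr[1]), sign(q[, 2] - ctr[2]))
  }
  list(best_iou = best,
       optima = lapply(opt, function(j) {
         correct(bnd_mm[subsets[, j], , drop = FALSE])
       }))
}

# smallest max corner-to-corner distance between a 4x2 quad and any of the
# oracle's optimal subsets (over all 1-1 matchings)
quad_oracle_distance <- function(corners, optima) {
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1)
  )
  best <- Inf
  for (opt in optima) {
    for (p in seq_len(nrow(perms))) {
      d <- sqrt(rowSums((corners - opt[perms[p, ], , drop = FALSE])^2))
      best <- min(best, max(d))
    }
  }
  best
}

# small sagittal-phantom config used across tests (fast to render);
# callers may override any field, including the defaults set here
test_phantom_config <- function(...) {
  args <- utils::modifyList(list(n_vertebrae = 5, noise_sd = 0), list(...))
  do.call(phantom_config, args)
}
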