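test_that("clean_mask fills holes, drops small and far clusters, idempotently", {
  m <- matrix(0L, 60, 60)
  m[10:30, 10:30] <- 1L
  m[18, 18] <- 0L                       # interior hole
  m[40, 40] <- 1L                       # 1-px satellite (0.36 mm2 < 50)
  attr(m, "spacing_mm") <- 0.6
  out <- clean_mask(m)
  expect_equal(out[18, 18], 1L)
  expect_equal(out[40, 40], 0L)
  expect_equal(sum(out), 21L * 21L)
  # idempotence
  expect_identical(clean_mask(out), out)
  # empty in, empty out
  e <- matrix(0L, 10, 10); attr(e, "spacing_mm") <- 0.6
  expect_true(all(clean_mask(e) == 0))
})

test_that("clean_mask drops clusters far from the spine axis", {
  # five large bodies on a vertical line plus one large blob ~80 mm off it;
  # the axis is fitted through ALL large-component centroids, so the
  # aligned bodies must dominate the fit
  m <- matrix(0L, 260, 200)
  for (r0 in c(20, 65, 110, 155, 200)) m[r0:(r0 + 30), 80:120] <- 1L
  m[30:55, 175:195] <- 1L
  attr(m, "spacing_mm") <- 1
  out <- clean_mask(m, max_dist_mm = 40)
  expect_true(all(out[30:55, 175:195] == 0))
  expect_equal(sum(out), 5L * 31L * 41L)
  # with a generous threshold the blob survives
  out2 <- clean_mask(m, max_dist_mm = 300)
  expect_gt(sum(out2), 5L * 31L * 41L)
})

test_that("split_and_label orders components cranial to caudal", {
  ph <- generate_phantom(phantom_config(n_vertebrae = 7, noise_sd = 0))
  comps <- split_and_label(ph$labels,
                           labels = c("T12", "L1", "L2", "L3", "L4", "L5", "S1"))
  expect_length(comps, 7)
  expect_identical(vapply(comps, `[[`, character(1), "label"),
                   c("T12", "L1", "L2", "L3", "L4", "L5", "S1"))
  rows <- vapply(comps, function(c) c$centroid_mm[2], numeric(1))
  expect_true(all(diff(rows) > 0))
  # default labelling ends at S1 when a sacrum is declared
  d <- split_and_label(ph$labels)
  expect_identical(d[[7]]$label, "S1")
  expect_identical(split_and_label(ph$labels, sacrum_present = FALSE)[[7]]$label, "L5")
  # error lists counts on mismatch
  expect_error(split_and_label(ph$labels, labels = c("L1", "L2")), "7")
  # empty mask -> empty list
  e <- matrix(0L, 8, 8); attr(e, "spacing_mm") <- 0.6
  expect_identical(split_and_label(e), list())
})

test_that("equal-row centroids break ties by anterior column", {
  m <- matrix(0L, 20, 40)
  m[5:10, 3:10] <- 1L
  m[5:10, 25:32] <- 1L
  attr(m, "spacing_mm") <- 1
  comps <- split_and_label(m, labels = c("A", "B"))
  expect_lt(comps[[1]]$centroid_mm[1], comps[[2]]$centroid_mm[1])
  expect_identical(comps[[1]]$label, "A")
})

test_that("all strategies recover the corners of an axis-aligned rectangle", {
  truth <- rect_poly(12, 8, 20, 24)           # the rectangle's true corners
  comp <- make_component(poly_mask(truth, 20, 24))
  strategies <- list(
    corners_basinhopping,
    function(c) corners_curvature(c, hull_alpha = 1, window = 5),
    corners_linefit
  )
  for (f in strategies) {
    q <- f(comp)
    err <- apply(q$corners, 1, function(p) sqrt(min(colSums((t(truth) - p)^2))))
    expect_lt(max(err), 0.51)
  }
})

test_that("a rotated rectangle's corners rotate with it", {
  comp0 <- make_component(poly_mask(rect_poly(14, 9, 28, 28), 28, 28))
  q0 <- detect_corners(comp0)
  comp10 <- make_component(poly_mask(rect_poly(14, 9, 28, 28, angle = 10), 28, 28))
  q10 <- detect_corners(comp10)
  th <- 10 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(13.5, 13.5)
  expected <- sweep(sweep(q0$corners, 2, ctr) %*% t(rot), 2, ctr, "+")
  expect_lt(max(sqrt(rowSums((q10$corners - expected)^2))), 1.01)
})

test_that("line fitting recovers trapezoid vertices and snaps rounded corners", {
  comp <- make_component(poly_mask(trapezoid_poly(18, 9, 15, 24, 28), 24, 28))
  q <- corners_linefit(comp)
  expect_lt(abs(sqrt(sum((q$corners["as", ] - q$corners["ai", ])^2)) - 9), 1.01)
  expect_lt(abs(sqrt(sum((q$corners["ps", ] - q$corners["pi", ])^2)) - 15), 1.01)
  # rounded corners: intersections fall outside the mask, snap stays within
  # the rounding radius of the ideal corner
  compr <- make_component(poly_mask(rect_poly(14, 10, 24, 24, round_r = 2), 24, 24))
  qr <- corners_linefit(compr)
  ideal <- rbind(c(-7, -5), c(7, -5), c(7, 5), c(-7, 5)) + 11.5
  err <- sqrt(rowSums((qr$corners[c("as", "ps", "pi", "ai"), ] - ideal)^2))
  expect_lt(max(err), 2.9)
  # on the boundary up to the half-pixel extent correction
  bnd <- vertmorph:::px_to_mm(vertmorph:::trace_boundary(compr$mask), 1)
  for (i in 1:4) {
    expect_lt(min(sqrt((bnd[, 1] - qr$corners[i, 1])^2 +
                         (bnd[, 2] - qr$corners[i, 2])^2)), 0.72)
  }
})

test_that("basin-hopping is deterministic and degenerate input errors", {
  comp <- make_component(poly_mask(rect_poly(12, 8, 20, 24, angle = 7), 20, 24))
  q1 <- corners_basinhopping(comp, seed = 5)
  q2 <- corners_basinhopping(comp, seed = 5)
  expect_identical(q1$corners, q2$corners)
  thin <- matrix(0L, 10, 10); thin[3:8, 5] <- 1L
  attr(thin, "spacing_mm") <- 1
  expect_error(corners_basinhopping(make_component(thin)), "degenerate")
})

test_that("a circle yields no four distinct curvature corners", {
  th <- seq(0, 2 * pi, length.out = 72)[-72]
  circ <- cbind(10 + 8 * cos(th), 10 + 8 * sin(th))
  comp <- make_component(poly_mask(circ, 21, 21))
  res <- try(corners_curvature(comp), silent = TRUE)
  if (inherits(res, "try-error")) {
    succeed("circle rejected as having no distinct maxima")
  } else {
    # four points at >= 1/8 perimeter spacing with a poor-fit overlap score
    expect_lt(res$overlap, 0.95)
  }
})

test_that("select_corners picks the best overlap with fixed tie order", {
  comp <- make_component(poly_mask(rect_poly(12, 8, 20, 24), 20, 24))
  qb <- corners_basinhopping(comp)
  fake <- function(strategy, overlap) {
    q <- qb; q$strategy <- strategy; q$overlap <- overlap; q
  }
  picked <- select_corners(comp, list(fake("basin-hopping", 0.91),
                                      fake("curvature", 0.95),
                                      fake("line-fit", 0.88)))
  expect_identical(picked$strategy, "curvature")
  # exact tie: earlier strategy wins
  picked2 <- select_corners(comp, list(fake("basin-hopping", 0.9),
                                       fake("curvature", 0.9)))
  expect_identical(picked2$strategy, "basin-hopping")
  # all failed: error aggregates reasons
  err <- simpleError("boom")
  tryb <- try(stop("no quad"), silent = TRUE)
  expect_error(select_corners(comp, list(a = tryb, b = tryb)),
               "all corner strategies failed")
})

test_that("detected quads never undercut the bounding-rectangle baseline", {
  ph <- generate_phantom(test_phantom_config(
    tilt_deg = c(-8, 0, 8, -4, 4),
    deformities = list(NULL, list(type = "wedge", severity = 0.5), NULL,
                       list(type = "concave", severity = 0.7), NULL)))
  comps <- split_and_label(ph$labels, labels = ph$config$labels)
  for (comp in comps) {
    bnd <- vertmorph:::px_to_mm(vertmorph:::trace_boundary(comp$mask), 0.6)
    rect <- vertmorph:::min_area_rect(bnd)
    snap <- t(apply(rect, 1, function(p) {
      bnd[which.min((bnd[, 1] - p[1])^2 + (bnd[, 2] - p[2])^2), ]
    }))
    # the initialization as the strategies realize it (incl. the half-pixel
    # extent correction applied to every returned quad)
    snap <- vertmorph:::sharpen_corners(snap, comp)
    baseline <- vertmorph:::polygon_mask_iou(snap, comp$mask, 0.6)
    q <- detect_corners(comp, iterations = 10)
    expect_gte(q$overlap, baseline - 1e-9)
  }
})
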