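test_that("rectangle geometry measures trivially", {
  # a 12 mm tall, 18 mm wide axis-aligned body
  truth <- rect_poly(18, 12, 30, 40, spacing = 0.6)
  mask <- poly_mask(truth, 30, 40, spacing = 0.6)
  quad <- truth[c(1, 2, 3, 4), ]
  rownames(quad) <- c("as", "ps", "pi", "ai")
  m <- measure_vertebra(mask, quad, spacing_mm = 0.6)
  expect_equal(m$AH, 12)
  expect_equal(m$PH, 12)
  expect_lt(abs(m$CH - 12), 0.7)   # boundary-to-boundary on the raster
  expect_lt(m$SC, 0.65)
  expect_lt(m$IC, 0.65)
  expect_equal(m$VA, 0)
})

test_that("trapezoid yields the analytic wedge angle", {
  # anterior 9 mm, posterior 15 mm, width 18 mm, all loss superiorly:
  # VA = atan(6 / 18) = 18.43 degrees, anteriorly converging (positive)
  quad <- rbind(as = c(3, 9), ps = c(21, 3), pi = c(21, 18), ai = c(3, 18))
  mask <- poly_mask(quad, 40, 45, spacing = 0.6)
  m <- measure_vertebra(mask, quad, spacing_mm = 0.6)
  expect_equal(m$AH, 9)
  expect_equal(m$PH, 15)
  expect_equal(m$VA, atan(6 / 18) * 180 / pi, tolerance = 1e-6)
  # posteriorly converging wedge flips the sign
  quad2 <- rbind(as = c(3, 3), ps = c(21, 9), pi = c(21, 18), ai = c(3, 18))
  mask2 <- poly_mask(quad2, 40, 45, spacing = 0.6)
  expect_equal(measure_vertebra(mask2, quad2, spacing_mm = 0.6)$VA,
               -atan(6 / 18) * 180 / pi, tolerance = 1e-6)
})

test_that("endplate depression depth is read from the chord", {
  # depression of depth 3 mm (5 px at 0.6 mm) in the superior endplate
  w <- 19.8; h <- 13.8
  corners <- rbind(as = c(3, 3), ps = c(3 + w, 3), pi = c(3 + w, 3 + h),
                   ai = c(3, 3 + h))
  edge <- vertmorph:::endplate_edge(corners["as", ], corners["ps", ], 3,
                                    c(0, 1), n = 60)
  poly <- rbind(corners["as", , drop = FALSE], edge,
                corners["ps", , drop = FALSE], corners["pi", , drop = FALSE],
                corners["ai", , drop = FALSE])
  mask <- poly_mask(poly, 40, 45, spacing = 0.6)
  m <- measure_vertebra(mask, corners, spacing_mm = 0.6)
  expect_lt(abs(m$SC - 3), 0.61)                 # within one pixel
  expect_lt(m$IC, 0.65)
  expect_equal(m$AH, h)                          # heights from the corners
  expect_equal(m$PH, h)
  expect_lt(abs(m$CH - (h - 3)), 0.75)
  expect_error(measure_vertebra(mask, rbind(as = c(1, 1), ps = c(1, 1),
                                            pi = c(2, 2), ai = c(1, 2)),
                                spacing_mm = 0.6), "degenerate")
})

test_that("morphometry is scale-equivariant", {
  truth <- rect_poly(18, 12, 30, 40, spacing = 0.6)
  mask <- poly_mask(truth, 30, 40, spacing = 0.6)
  quad <- truth; rownames(quad) <- c("as", "ps", "pi", "ai")
  m1 <- measure_vertebra(mask, quad, spacing_mm = 0.6)
  # joint scaling of grid and spacing leaves everything invariant
  mask2 <- poly_mask(truth * 2, 60, 80, spacing = 1.2)
  m2 <- measure_vertebra(mask2, quad * 2, spacing_mm = 1.2)
  expect_equal(m2$AH / m1$AH, 2)
  expect_equal(m2$PH / m1$PH, 2)
  expect_equal(m2$VA, m1$VA)
  expect_equal((m2$AH / m2$PH), (m1$AH / m1$PH))
})

test_that("Genant rules fire at strict 3-SD thresholds", {
  norms <- reference_norms(anterior_ratio = c(1.00, 0.04),
                           middle_ratio = c(0.91, 0.045),
                           neighbor_height_ratio = c(1.00, 0.05))
  mk <- function(ah, ph, ch) list(AH = ah, PH = ph, CH = ch)
  # 0.87 < 1.00 - 0.12 = 0.88 -> wedge
  expect_identical(classify_vertebra(mk(8.7, 10, 9.5), norms = norms)$deformity,
                   "wedge")
  # boundary value is NOT a fracture (strict inequality)
  r <- classify_vertebra(mk(8.8, 10, 9.5), norms = norms)
  expect_identical(r$deformity, "none")
  expect_false(r$fractured)
  # concave: CH/PH below mean - 3 SD = 0.775
  expect_identical(classify_vertebra(mk(10, 10, 7.7), norms = norms)$deformity,
                   "concave")
  # crush beats wedge by precedence when both fire
  healthy <- mk(27, 27, 25)
  res <- classify_vertebra(mk(10, 12, 10), neighbors = list(healthy, healthy),
                           norms = norms)
  expect_identical(res$deformity, "crush")
  expect_true(all(c("crush", "wedge") %in% res$audit$rule[res$audit$fired]))
  # empty neighbors: crush rule skipped but recorded
  res2 <- classify_vertebra(mk(10, 12, 10), neighbors = list(), norms = norms)
  expect_false(res2$audit$evaluated[res2$audit$rule == "crush"])
  expect_identical(res2$deformity, "wedge")
  # norms are mandatory
  expect_error(classify_vertebra(mk(1, 1, 1)), "norms")
})

test_that("phantom crush severity 1 among healthy neighbors is a crush call", {
  ph <- generate_phantom(test_phantom_config(
    deformities = list(NULL, NULL, list(type = "crush", severity = 1))))
  expect_identical(ph$truth$truth_call[3], "crush")
  expect_true(ph$truth$fractured[3])
  expect_false(any(ph$truth$fractured[-3]))
})

test_that("wedge call is monotone in decreasing anterior height", {
  norms <- default_reference_norms()
  ph <- 20
  fired <- vapply(seq(20, 8, by = -0.5), function(ah) {
    classify_vertebra(list(AH = ah, PH = ph, CH = 18.5), norms = norms)$fractured
  }, logical(1))
  # once fractured, lowering AH further never un-fires the call
  expect_true(all(diff(fired) >= 0))
})

test_that("norms round-trip through CSV and are validated", {
  n <- default_reference_norms()
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_norms(n, path)
  back <- read_reference_norms(path)
  expect_equal(back, n)
  expect_error(reference_norms(c(1, 0), c(0.9, 0.04), c(1, 0.05)), "sd")
  expect_error(reference_norms(c(-1, 0.1), c(0.9, 0.04), c(1, 0.05)))
})
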