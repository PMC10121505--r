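test_that("healthy phantom truth matches the generating geometry", {
  ph <- generate_phantom(test_phantom_config())
  expect_equal(ph$truth$AH, rep(27, 5))
  expect_equal(ph$truth$PH, rep(27, 5))
  expect_equal(ph$truth$VA, rep(0, 5))
  expect_equal(ph$truth$SC, rep(1, 5))
  expect_false(any(ph$truth$fractured))
  # labels unique per vertebra, shared grid and spacing
  expect_equal(sort(unique(as.vector(ph$labels))), 0:5)
  expect_identical(dim(ph$image), dim(ph$labels))
  expect_equal(attr(ph$image, "spacing_mm"), attr(ph$labels, "spacing_mm"))
})

test_that("identical config and seed give bit-identical phantoms", {
  cfg <- test_phantom_config(noise_sd = 0.05, seed = 42L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(test_phantom_config(noise_sd = 0.05, seed = 43L))
  expect_false(identical(a$image, c$image))
})

test_that("wedge severity 0.5 yields the stated anterior height loss", {
  # anterior height scaled by 1 - severity * max_loss, max_loss = 0.6
  ph <- generate_phantom(test_phantom_config(
    deformities = list(NULL, NULL, list(type = "wedge", severity = 0.5))))
  expect_equal(ph$truth$AH[3], 27 * 0.70)
  expect_equal(ph$truth$PH[3], 27)
  expect_equal(ph$truth$VA[3], atan2(27 * 0.3, 33) * 180 / pi)
})

test_that("apply_deformity honors its contracts", {
  base <- vertmorph:::vertebra_shape(27, 33, 1)
  # identity for none at any severity
  expect_identical(apply_deformity(base, "none", 0.7), base)
  # severity 0 of any type is geometrically 'none'
  expect_identical(apply_deformity(base, "wedge", 0), base)
  # crush severity 1 with max_loss 0.6 keeps 40% of both heights
  cr <- apply_deformity(base, "crush", 1)
  tm <- vertmorph:::shape_truth_morphometry(cr)
  expect_equal(unname(tm["AH"]), 27 * 0.4)
  expect_equal(unname(tm["PH"]), 27 * 0.4)
  # concave severity 0.5 with max depth 6: depth 1 + 0.5*(6-1) = 3.5,
  # biconcave (both endplates deepen)
  cc <- apply_deformity(base, "concave", 0.5)
  expect_equal(cc$sup_depth, 3.5)
  expect_equal(cc$inf_depth, 3.5)
  expect_error(apply_deformity(base, "collapse", 0.5))
  expect_error(apply_deformity(base, "wedge", 1.5))
})

test_that("severity responses are strictly monotone in truth", {
  sev <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  ratios <- numeric(length(sev))
  scs <- numeric(length(sev))
  for (i in seq_along(sev)) {
    w <- apply_deformity(vertmorph:::vertebra_shape(27, 33, 1), "wedge", sev[i])
    tw <- vertmorph:::shape_truth_morphometry(w)
    ratios[i] <- tw["AH"] / tw["PH"]
    cc <- apply_deformity(vertmorph:::vertebra_shape(27, 33, 1), "concave", sev[i])
    scs[i] <- vertmorph:::shape_truth_morphometry(cc)["SC"]
  }
  expect_true(all(diff(ratios) < 0))
  expect_true(all(diff(scs) > 0))
})

test_that("measuring the generating polygon reproduces analytic truth", {
  # consistency invariant: the morphometry module's chord/height
  # definitions, applied to the noise-free generating polygon (rasterized
  # finely enough that quantization is negligible) with the true corner
  # landmarks, agree with truth within one 0.6 mm pixel and one degree
  ph <- generate_phantom(test_phantom_config(
    tilt_deg = 5,
    deformities = list(NULL, list(type = "wedge", severity = 0.6), NULL,
                       list(type = "concave", severity = 0.8))))
  fine <- 0.2
  for (i in seq_len(5)) {
    tr <- ph$truth[i, ]
    poly <- ph$polygons[[i]]
    nr <- ceiling(max(poly[, 2]) / fine) + 3L
    nc <- ceiling(max(poly[, 1]) / fine) + 3L
    comp_mask <- vertmorph:::rasterize_polygon_area(poly, nr, nc, fine)
    quad <- rbind(as = c(tr$as_x, tr$as_y), ps = c(tr$ps_x, tr$ps_y),
                  pi = c(tr$pi_x, tr$pi_y), ai = c(tr$ai_x, tr$ai_y))
    m <- measure_vertebra(comp_mask, quad, spacing_mm = fine)
    expect_lt(abs(m$AH - tr$AH), 0.6)
    expect_lt(abs(m$PH - tr$PH), 0.6)
    expect_lt(abs(m$CH - tr$CH), 0.6)
    expect_lt(abs(m$SC - tr$SC), 0.6)
    expect_lt(abs(m$VA - tr$VA), 1)
  }
})

test_that("infeasible geometry is rejected", {
  # stack taller than the canvas
  expect_error(generate_phantom(phantom_config(n_vertebrae = 7, noise_sd = 0,
                                               canvas_px = c(128L, 128L))),
               "infeasible")
  # tilt out of the supported range
  expect_error(phantom_config(tilt_deg = 20), "tilt")
  # invalid severity and unknown type are rejected at config time
  expect_error(phantom_config(deformities = list(list(type = "wedge",
                                                      severity = 1.2))))
  expect_error(phantom_config(deformities = list(list(type = "melt",
                                                      severity = 0.2))))
})

test_that("phantom round-trips through NIfTI and CSV", {
  ph <- generate_phantom(test_phantom_config(noise_sd = 0.03, seed = 7L))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir, pgm = TRUE)
  expect_true(all(file.exists(paths)))
  img <- read_nifti(paths[["image"]])
  expect_equal(img$spacing[1:2], c(0.6, 0.6), tolerance = 1e-6)
  expect_equal(img$data, unclass(ph$image), ignore_attr = TRUE,
               tolerance = 1e-6)
  lab <- read_nifti(paths[["labels"]])
  expect_identical(max(lab$data), 5L)
  truth <- read.csv(paths[["truth"]])
  expect_equal(truth$AH, ph$truth$AH)
  # PGM preview is plain text
  expect_identical(readLines(paths[["preview"]], n = 1L), "P2")
})
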