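test_that("oracle backend returns the binarized labels, deterministically corrupted", {
  ph <- generate_phantom(test_phantom_config())
  std <- standardize_slice(ph$image, 0.6)
  lab <- standardize_slice(ph$labels, 0.6, label_mask = TRUE)
  m <- segment_slice(std, "oracle", labels = lab)
  expect_identical(unclass(m), matrix(as.integer(lab > 0), 448, 320),
                   ignore_attr = TRUE)
  expect_identical(attr(m, "provenance"), "oracle")

  corr <- mask_corruption()
  c1 <- segment_slice(std, "oracle", labels = lab, corruption = corr, seed = 9L)
  c2 <- segment_slice(std, "oracle", labels = lab, corruption = corr, seed = 9L)
  expect_identical(c1, c2)
  c3 <- segment_slice(std, "oracle", labels = lab, corruption = corr, seed = 10L)
  expect_false(identical(c1, c3))
  expect_false(identical(unclass(c1), unclass(m)))

  # empty image -> empty mask
  zero <- standardize_slice(matrix(0, 448, 320), 0.6)
  expect_true(all(segment_slice(zero, "oracle",
                                labels = matrix(0L, 448, 320)) == 0))
  # model backend without weights must fail loudly
  expect_error(segment_slice(std, "model"), "no trained model")
})

test_that("Dice coefficient satisfies its definition and properties", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L
  b <- matrix(0L, 6, 6); b[3:4, 2:3] <- 1L   # |a|=|b|=4, overlap 2
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a, matrix(0L, 6, 6)), 0)
  expect_equal(dice_coefficient(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(0L, 5, 5)), "shapes")
  # symmetry and monotone growth of overlap at fixed mask sizes
  x <- matrix(0L, 8, 8); x[1:2, 1:2] <- 1L        # |x| = 4
  far <- which(matrix(seq_len(64), 8, 8) > 48)     # disjoint from x
  prev <- -1
  for (ov in 1:4) {
    y <- matrix(0L, 8, 8)
    y[which(x == 1L)[seq_len(ov)]] <- 1L           # ov shared pixels
    if (ov < 4) y[far[seq_len(4 - ov)]] <- 1L      # |y| = 4 always
    d <- dice_coefficient(x, y)
    expect_equal(d, dice_coefficient(y, x))
    expect_gt(d, prev)
    prev <- d
  }
})

test_that("U-net spec encodes the reference architecture", {
  spec <- unet_spec()
  expect_identical(spec$filters, c(32L, 64L, 128L, 256L, 512L))
  expect_identical(spec$depth, 5L)
  expect_identical(spec$skip_connections, 4L)
  expect_identical(spec$loss, "dice")
  expect_identical(spec$optimizer, "adam")
  expect_equal(spec$learning_rate, 0.05)
  expect_identical(spec$batch_size, 16L)
  expect_identical(spec$epochs, 100L)
  sh <- unet_shapes(spec)
  bn <- sh[sh$stage == "bottleneck", ]
  expect_equal(c(bn$rows, bn$cols, bn$filters), c(14, 10, 512))
  expect_equal(sh[sh$stage == "dec1", c("rows", "cols")],
               data.frame(rows = 448, cols = 320), ignore_attr = TRUE)
  # shape not divisible for 5 pooling stages fails at construction
  expect_error(unet_spec(input_shape = c(450, 320)), "divisible")
})

test_that("an untrained U-net maps zeros to finite probabilities in [0,1]", {
  spec <- unet_spec(input_shape = c(64, 32), base_filters = 2)
  model <- build_unet(spec, seed = 3)
  p <- unet_predict(model, matrix(0, 64, 32))
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(dim(p), c(64L, 32L))
  expect_error(unet_predict(model, matrix(0, 32, 64)), "shape")
})

test_that("backpropagation matches finite differences", {
  spec <- unet_spec(input_shape = c(32, 32), base_filters = 2)
  m <- build_unet(spec, seed = 1)
  set.seed(2)
  x <- matrix(runif(32 * 32), 32, 32)
  tgt <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  fw <- vertmorph:::unet_forward(m, x)
  lg <- vertmorph:::dice_loss_grad(fw$prob, tgt)
  g <- vertmorph:::unet_backward(m, fw$cache, lg$dlogit)
  loss_of <- function(model) {
    f <- vertmorph:::unet_forward(model, x)
    vertmorph:::dice_loss_grad(f$prob, tgt)$loss
  }
  eps <- 1e-5
  probes <- list(
    list(get = function(m) m$enc[[1]]$conv1$W[3, 1],
         set = function(m, v) { m$enc[[1]]$conv1$W[3, 1] <- v; m },
         grad = g$enc[[1]]$conv1$W[3, 1]),
    list(get = function(m) m$enc[[3]]$bn2$gamma[1],
         set = function(m, v) { m$enc[[3]]$bn2$gamma[1] <- v; m },
         grad = g$enc[[3]]$bn2$gamma[1]),
    list(get = function(m) m$dec[[2]]$conv2$W[5, 2],
         set = function(m, v) { m$dec[[2]]$conv2$W[5, 2] <- v; m },
         grad = g$dec[[2]]$conv2$W[5, 2]),
    list(get = function(m) m$final$W[1, 1],
         set = function(m, v) { m$final$W[1, 1] <- v; m },
         grad = g$final$W[1, 1])
  )
  for (p in probes) {
    num <- (loss_of(p$set(m, p$get(m) + eps)) -
              loss_of(p$set(m, p$get(m) - eps))) / (2 * eps)
    expect_equal(p$grad, num, tolerance = 1e-4)
  }
})

test_that("desk-scale training reaches Dice > 0.8 on held-out phantoms", {
  # width-reduced architecture (filters from 8) on coarse 96x64 phantom
  # rasters (3 mm spacing) to fit the CPU budget; the 0.8 bar is unchanged
  set.seed(100)
  mk <- function(seed) {
    types <- c("none", "wedge", "concave", "crush")
    d <- lapply(1:5, function(i) list(type = sample(types, 1),
                                      severity = runif(1, 0.3, 1)))
    ph <- generate_phantom(phantom_config(
      n_vertebrae = 5, pixel_spacing_mm = 3, canvas_px = c(96L, 64L),
      noise_sd = 0.05, tilt_deg = runif(5, -10, 10), deformities = d,
      seed = seed))
    list(img = unclass(ph$image), mask = (ph$labels > 0) * 1L)
  }
  data <- lapply(1:38, mk)
  spec <- unet_spec(input_shape = c(96, 64), base_filters = 8, depth = 5,
                    batch_size = 4, epochs = 4)
  model <- build_unet(spec, seed = 0)
  model <- train_unet(model,
                      lapply(data[1:32], `[[`, "img"),
                      lapply(data[1:32], `[[`, "mask"),
                      seed = 1)
  dices <- vapply(data[33:38], function(d) {
    dice_coefficient(unet_predict(model, d$img) >= 0.5, d$mask)
  }, numeric(1))
  expect_gt(min(dices), 0.8)
  # loss history decreased
  expect_lt(tail(attr(model, "history"), 1), attr(model, "history")[1])
})
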