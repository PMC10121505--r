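# Executable U-net: a compact conv-net implementation in base R.
#
# No tensor framework is pre-installed for R, so the trainable segmenter is
# implemented directly: 3x3 same-padding convolutions via im2col + BLAS
# matrix products, per-channel normalization, ReLU, 2x2 max pooling,
# nearest-neighbour upsampling, channel concatenation, a 1x1 output
# convolution with sigmoid, Dice-coefficient loss and the Adam optimizer.
# Normalization uses the spatial statistics of the current instance (batch
# normalization with batch-of-one semantics), which keeps inference
# deterministic without running averages.
#
# Arrays are [H, W, C]. All functions are pure; the model object carries
# the parameters.

conv_offsets <- expand.grid(dr = -1:1, dc = -1:1)  # column-major kernel order

im2col3 <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; ch <- d[3]
  xp <- array(0, c(h + 2L, w + 2L, ch))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, h * w, 9L * ch)
  for (m in seq_len(9L)) {
    dr <- conv_offsets$dr[m]; dc <- conv_offsets$dc[m]
    blk <- xp[(1:h) + dr + 1L, (1:w) + dc + 1L, , drop = FALSE]
    cols[, ((m - 1L) * ch + 1L):(m * ch)] <- blk
  }
  cols
}

col2im3 <- function(dcols, h, w, ch) {
  dxp <- array(0, c(h + 2L, w + 2L, ch))
  for (m in seq_len(9L)) {
    dr <- conv_offsets$dr[m]; dc <- conv_offsets$dc[m]
    blk <- array(dcols[, ((m - 1L) * ch + 1L):(m * ch)], c(h, w, ch))
    dxp[(1:h) + dr + 1L, (1:w) + dc + 1L, ] <-
      dxp[(1:h) + dr + 1L, (1:w) + dc + 1L, , drop = FALSE] + blk
  }
  dxp[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

conv3_forward <- function(x, p) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% p$W
  y <- sweep(y, 2, p$b, "+")
  list(y = array(y, c(d[1], d[2], ncol(p$W))),
       cache = list(cols = cols, dim = d))
}

conv3_backward <- function(dy, p, cache) {
  d <- cache$dim
  dym <- matrix(dy, d[1] * d[2], length(p$b))
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dcols <- dym %*% t(p$W)
  dx <- col2im3(dcols, d[1], d[2], d[3])
  list(dx = dx, grads = list(W = dW, b = db))
}

norm_forward <- function(x, p, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_std, "*")
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(y = array(y, d), cache = list(xhat = xhat, inv_std = inv_std, dim = d))
}

norm_backward <- function(dy, p, cache) {
  d <- cache$dim; n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, p$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat, 2, s1 / n) - sweep(xhat, 2, s2 / n, "*")
  dx <- sweep(dx, 2, cache$inv_std, "*")
  list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

maxpool_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; ch <- d[3]
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  n <- h2 * w2 * ch
  cand <- matrix(0, n, 4L)
  m <- 0L
  for (dc in 0:1) for (dr in 0:1) {
    m <- m + 1L
    cand[, m] <- x[seq(1L, h, 2L) + dr, seq(1L, w, 2L) + dc, , drop = FALSE]
  }
  idx <- max.col(cand, ties.method = "first")
  y <- cand[cbind(seq_len(n), idx)]
  list(y = array(y, c(h2, w2, ch)),
       cache = list(idx = idx, dim = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dim; h <- d[1]; w <- d[2]; ch <- d[3]
  h2 <- h %/% 2L; w2 <- w %/% 2L
  n <- h2 * w2 * ch
  pos <- seq_len(n) - 1L
  r2 <- pos %% h2
  c2 <- (pos %/% h2) %% w2
  cc <- pos %/% (h2 * w2)
  m <- cache$idx - 1L
  dr <- m %% 2L
  dc <- m %/% 2L
  sr <- 2L * r2 + dr
  sc <- 2L * c2 + dc
  lin <- cc * (h * w) + sc * h + sr + 1L
  dx <- numeric(h * w * ch)
  dx[lin] <- as.vector(dy)
  array(dx, d)
}

upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample_backward <- function(dy) {
  d <- dim(dy); h <- d[1]; w <- d[2]
  ro <- seq(1L, h, 2L); re <- seq(2L, h, 2L)
  co <- seq(1L, w, 2L); ce <- seq(2L, w, 2L)
  dy[ro, co, , drop = FALSE] + dy[re, co, , drop = FALSE] +
    dy[ro, ce, , drop = FALSE] + dy[re, ce, , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# one encoder/decoder block: (conv3, norm, relu) x 2
block_forward <- function(x, p) {
  c1 <- conv3_forward(x, p$conv1)
  n1 <- norm_forward(c1$y, p$bn1)
  r1 <- relu_forward(n1$y)
  c2 <- conv3_forward(r1$y, p$conv2)
  n2 <- norm_forward(c2$y, p$bn2)
  r2 <- relu_forward(n2$y)
  list(y = r2$y, cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                              c2 = c2$cache, n2 = n2$cache, r2 = r2$cache))
}

block_backward <- function(dy, p, cache) {
  dy <- relu_backward(dy, cache$r2)
  nb2 <- norm_backward(dy, p$bn2, cache$n2)
  cb2 <- conv3_backward(nb2$dx, p$conv2, cache$c2)
  dy <- relu_backward(cb2$dx, cache$r1)
  nb1 <- norm_backward(dy, p$bn1, cache$n1)
  cb1 <- conv3_backward(nb1$dx, p$conv1, cache$c1)
  # grads listed in the same order as the parameter block: the optimizer
  # pairs parameter and gradient trees positionally
  list(dx = cb1$dx,
       grads = list(conv1 = cb1$grads, bn1 = nb1$grads,
                    conv2 = cb2$grads, bn2 = nb2$grads))
}

init_block <- function(c_in, c_out, rng) {
  mk_conv <- function(ci, co) list(
    W = matrix(rng(9L * ci * co) * sqrt(2 / (9 * ci)), 9L * ci, co),
    b = numeric(co)
  )
  mk_norm <- function(co) list(gamma = rep(1, co), beta = numeric(co))
  list(conv1 = mk_conv(c_in, c_out), bn1 = mk_norm(c_out),
       conv2 = mk_conv(c_out, c_out), bn2 = mk_norm(c_out))
}

#' Build a U-net model from an architecture description
#'
#' Instantiates randomly initialized weights (He initialization, seeded)
#' for the layer graph described by the spec. The returned model maps a
#' single-channel input of the spec's shape to a same-size probability map
#' in \[0, 1\]; [segment_slice()] thresholds it at 0.5 by default.
#'
#' @param spec a [unet_spec()]
#' @param seed weight-initialization seed
#' @return object of class `unet_model`
#' @export
build_unet <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "unet_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  d <- spec$depth
  f <- spec$filters
  enc <- vector("list", d)
  c_in <- 1L
  for (i in seq_len(d)) {
    enc[[i]] <- init_block(c_in, f[i], function(n) stats::rnorm(n))
    c_in <- f[i]
  }
  dec <- vector("list", d)
  c_prev <- f[d]
  for (i in rev(seq_len(d))) {
    c_in_dec <- if (i < d) c_prev + f[i] else c_prev
    dec[[i]] <- init_block(c_in_dec, f[i], function(n) stats::rnorm(n))
    c_prev <- f[i]
  }
  final <- list(W = matrix(stats::rnorm(f[1]) * sqrt(2 / f[1]), f[1], 1L),
                b = 0)
  structure(list(spec = spec, enc = enc, dec = dec, final = final),
            class = "unet_model")
}

unet_forward <- function(model, x) {
  d <- model$spec$depth
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  cache <- list(enc = vector("list", d), pool = vector("list", d),
                dec = vector("list", d), concat_ch = integer(d))
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    bf <- block_forward(x, model$enc[[i]])
    skips[[i]] <- bf$y
    cache$enc[[i]] <- bf$cache
    pf <- maxpool_forward(bf$y)
    cache$pool[[i]] <- pf$cache
    x <- pf$y
  }
  for (i in rev(seq_len(d))) {
    x <- upsample_forward(x)
    if (i < d) {
      cache$concat_ch[i] <- dim(x)[3]
      x <- concat_channels(x, skips[[i]])
    }
    bf <- block_forward(x, model$dec[[i]])
    cache$dec[[i]] <- bf$cache
    x <- bf$y
  }
  dd <- dim(x)
  xm <- matrix(x, dd[1] * dd[2], dd[3])
  logits <- xm %*% model$final$W + model$final$b
  prob <- 1 / (1 + exp(-logits))
  cache$final_in <- xm
  cache$out_dim <- dd
  list(prob = matrix(prob, dd[1], dd[2]), cache = cache)
}

unet_backward <- function(model, cache, dprob) {
  d <- model$spec$depth
  dd <- cache$out_dim
  prob_grad <- as.vector(dprob)
  # through sigmoid happens in the loss-side caller (dprob is dL/dlogit here)
  dlogit <- matrix(prob_grad, dd[1] * dd[2], 1L)
  # same tree order as the parameter list (enc, dec, final): see train_unet
  g <- list(enc = vector("list", d), dec = vector("list", d),
            final = list(W = crossprod(cache$final_in, dlogit),
                         b = sum(dlogit)))
  dx <- array(dlogit %*% t(model$final$W), dd)
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    bb <- block_backward(dx, model$dec[[i]], cache$dec[[i]])
    g$dec[[i]] <- bb$grads
    dx <- bb$dx
    if (i < d) {
      nup <- cache$concat_ch[i]
      dskips[[i]] <- dx[, , (nup + 1L):dim(dx)[3], drop = FALSE]
      dx <- dx[, , seq_len(nup), drop = FALSE]
    }
    dx <- upsample_backward(dx)
  }
  for (i in rev(seq_len(d))) {
    dx <- maxpool_backward(dx, cache$pool[[i]])
    if (!is.null(dskips[[i]])) dx <- dx + dskips[[i]]
    bb <- block_backward(dx, model$enc[[i]], cache$enc[[i]])
    g$enc[[i]] <- bb$grads
    dx <- bb$dx
  }
  g
}

# Dice loss and its gradient w.r.t. the logits (through the sigmoid)
dice_loss_grad <- function(prob, target, eps = 1) {
  p <- as.vector(prob); t <- as.vector(target)
  inter <- sum(p * t)
  denom <- sum(p) + sum(t) + eps
  dice <- (2 * inter + eps) / denom
  dldp <- -(2 * t * denom - (2 * inter + eps)) / denom^2
  dldlogit <- dldp * p * (1 - p)
  list(loss = 1 - dice, dlogit = matrix(dldlogit, nrow(prob), ncol(prob)))
}

#' Forward pass of a (trained or untrained) U-net
#'
#' @param model a [build_unet()] model
#' @param slice numeric matrix matching the model's input shape
#' @return probability matrix in \[0, 1\]
#' @export
unet_predict <- function(model, slice) {
  stopifnot(inherits(model, "unet_model"))
  if (!all(dim(slice) == model$spec$input_shape)) {
    stop("input shape ", paste(dim(slice), collapse = "x"),
         " does not match the model's ",
         paste(model$spec$input_shape, collapse = "x"))
  }
  unet_forward(model, as.matrix(slice))$prob
}

map_params <- function(p, f) {
  if (is.list(p)) lapply(p, map_params, f = f) else f(p)
}
map2_params <- function(a, b, f) {
  if (is.list(a)) Map(function(x, y) map2_params(x, y, f), a, b) else f(a, b)
}

#' Train a U-net on image/mask pairs with Adam and Dice loss
#'
#' Hyper-parameters default to the spec's fields (Adam, learning rate,
#' batch size, epochs). Gradients are averaged over each mini-batch.
#'
#' @param model a [build_unet()] model
#' @param images list of input matrices (model input shape)
#' @param masks list of binary target matrices
#' @param epochs,batch_size,learning_rate overrides of the spec fields
#' @param seed shuffling seed
#' @param verbose print per-epoch mean loss
#' @return the trained model, with a `history` attribute (mean Dice loss
#'   per epoch)
#' @export
train_unet <- function(model, images, masks,
                       epochs = model$spec$epochs,
                       batch_size = model$spec$batch_size,
                       learning_rate = model$spec$learning_rate,
                       seed = 0L, verbose = FALSE) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  params <- list(enc = model$enc, dec = model$dec, final = model$final)
  mstate <- map_params(params, function(x) x * 0)
  vstate <- map_params(params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  tstep <- 0
  history <- numeric(epochs)
  n <- length(images)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      gsum <- NULL
      for (k in batch) {
        model$enc <- params$enc; model$dec <- params$dec
        model$final <- params$final
        fw <- unet_forward(model, images[[k]])
        lg <- dice_loss_grad(fw$prob, masks[[k]] > 0)
        losses <- c(losses, lg$loss)
        g <- unet_backward(model, fw$cache, lg$dlogit)
        gsum <- if (is.null(gsum)) g else map2_params(gsum, g, `+`)
      }
      gmean <- map_params(gsum, function(x) x / length(batch))
      tstep <- tstep + 1
      mstate <- map2_params(mstate, gmean, function(m, g) beta1 * m + (1 - beta1) * g)
      vstate <- map2_params(vstate, gmean, function(v, g) beta2 * v + (1 - beta2) * g^2)
      bc1 <- 1 - beta1^tstep; bc2 <- 1 - beta2^tstep
      upd <- map2_params(mstate, vstate, function(m, v) {
        learning_rate * (m / bc1) / (sqrt(v / bc2) + adam_eps)
      })
      params <- map2_params(params, upd, `-`)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: mean Dice loss %.4f", ep, history[ep]))
  }
  model$enc <- params$enc; model$dec <- params$dec; model$final <- params$final
  attr(model, "history") <- history
  model
}
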