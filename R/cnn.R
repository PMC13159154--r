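# Internal encoder-decoder (U-net style) engine used by the
# bright-field-to-fluorescence translation models. Pure parameter lists +
# hand-written backprop on top of the compiled conv/pool kernels, trained
# with Adam on an MSE loss. Supported topology: `depth` resolution levels,
# two 3x3 conv + ReLU per level, 2x2 mean pooling on the way down, nearest
# upsampling + skip concatenation on the way up, linear 1x1 output conv.

unet_channel_plan <- function(base, depth) {
  enc <- base * 2^(seq_len(depth) - 1L)   # last entry = bottleneck width
  list(enc = enc)
}

# He-initialized parameter list. Conv weights are (9*Cin x F) matrices.
unet_init <- function(in_ch = 1L, base = 16L, depth = 4L, seed = 1L) {
  plan <- unet_channel_plan(base, depth)$enc
  he <- function(fan_in, n) matrix(stats::rnorm(fan_in * n, 0, sqrt(2 / fan_in)),
                                   fan_in, n)
  with_seed(seed, {
    p <- list(depth = depth, base = base, in_ch = in_ch, conv = list())
    cin <- in_ch
    for (l in seq_len(depth)) {            # encoder incl. bottleneck
      f <- plan[l]
      p$conv[[paste0("enc", l, "a")]] <- list(W = he(9 * cin, f), b = rep(0, f))
      p$conv[[paste0("enc", l, "b")]] <- list(W = he(9 * f, f), b = rep(0, f))
      cin <- f
    }
    for (l in rev(seq_len(depth - 1L))) {  # decoder
      cat_ch <- plan[l] + plan[l + 1L]
      f <- plan[l]
      p$conv[[paste0("dec", l, "a")]] <- list(W = he(9 * cat_ch, f), b = rep(0, f))
      p$conv[[paste0("dec", l, "b")]] <- list(W = he(9 * f, f), b = rep(0, f))
      cin <- f
    }
    p$conv[["out"]] <- list(W = he(plan[1], 1L), b = 0)   # 1x1 linear
    p
  })
}

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

conv_block <- function(x, par, keep) {
  r <- conv3_forward(as_cube(x), par$W, par$b, keep)
  z <- r$y
  a <- z * (z > 0)
  list(a = a, mask = z > 0, xcol = if (keep) r$xcol else NULL)
}

# Forward pass. Returns prediction matrix and (optionally) the tape needed
# by unet_backward. Input dims must be divisible by 2^(depth-1).
unet_forward <- function(p, x, keep = FALSE) {
  x <- as_cube(x)
  d <- p$depth
  tape <- list(input = if (keep) x else NULL, enc = vector("list", d),
               dec = vector("list", max(d - 1L, 0L)))
  skips <- vector("list", d)
  cur <- x
  for (l in seq_len(d)) {
    b1 <- conv_block(cur, p$conv[[paste0("enc", l, "a")]], keep)
    b2 <- conv_block(b1$a, p$conv[[paste0("enc", l, "b")]], keep)
    if (keep) tape$enc[[l]] <- list(b1 = b1[c("mask", "xcol")], b2 = b2[c("mask", "xcol")])
    skips[[l]] <- b2$a
    if (l < d) cur <- meanpool2(b2$a) else cur <- b2$a
  }
  for (l in rev(seq_len(d - 1L))) {
    up <- upsample2(cur)
    cat_in <- array(c(skips[[l]], up),
                    dim = c(dim(up)[1], dim(up)[2], dim(skips[[l]])[3] + dim(up)[3]))
    b1 <- conv_block(cat_in, p$conv[[paste0("dec", l, "a")]], keep)
    b2 <- conv_block(b1$a, p$conv[[paste0("dec", l, "b")]], keep)
    if (keep) tape$dec[[l]] <- list(b1 = b1[c("mask", "xcol")], b2 = b2[c("mask", "xcol")],
                                    skip_ch = dim(skips[[l]])[3])
    cur <- b2$a
  }
  # 1x1 linear output
  H <- dim(cur)[1]; W <- dim(cur)[2]; C <- dim(cur)[3]
  flat <- matrix(cur, H * W, C)
  y <- matrix(flat %*% p$conv$out$W + p$conv$out$b, H, W)
  if (keep) tape$pre_out <- cur
  list(y = y, tape = tape)
}

conv_block_bwd <- function(da, block, par, cin) {
  dz <- da * block$mask
  conv3_backward(as_cube(dz), block$xcol, par$W, cin)
}

# Backprop of dL/dy through the network; returns gradients in the same
# shape as p$conv.
unet_backward <- function(p, tape, dy) {
  d <- p$depth
  plan <- unet_channel_plan(p$base, d)$enc
  g <- list()
  H <- nrow(dy); W <- ncol(dy)
  pre <- tape$pre_out
  C <- dim(pre)[3]
  flat <- matrix(pre, H * W, C)
  dym <- matrix(dy, H * W, 1)
  g$out <- list(dW = crossprod(flat, dym), db = sum(dym))
  dcur <- array(dym %*% t(p$conv$out$W), dim = c(H, W, C))
  for (l in seq_len(d - 1L)) {            # decoder, shallow to deep
    tp <- tape$dec[[l]]
    cat_ch <- plan[l] + plan[l + 1L]
    r2 <- conv_block_bwd(dcur, tp$b2, p$conv[[paste0("dec", l, "b")]], plan[l])
    g[[paste0("dec", l, "b")]] <- r2[c("dW", "db")]
    r1 <- conv_block_bwd(r2$dX, tp$b1, p$conv[[paste0("dec", l, "a")]], cat_ch)
    g[[paste0("dec", l, "a")]] <- r1[c("dW", "db")]
    sc <- tp$skip_ch
    dskip <- r1$dX[, , seq_len(sc), drop = FALSE]
    dup <- r1$dX[, , sc + seq_len(dim(r1$dX)[3] - sc), drop = FALSE]
    dcur_deeper <- upsample2_backward(as_cube(dup))
    # stash for the encoder pass
    tape$enc[[l]]$dskip <- dskip
    dcur <- dcur_deeper
  }
  # encoder, deep to shallow; dcur currently holds gradient into bottleneck
  for (l in rev(seq_len(d))) {
    tp <- tape$enc[[l]]
    dinto <- if (l == d) {
      dcur
    } else {
      dpool <- meanpool2_backward(as_cube(dcur))
      dpool + tp$dskip
    }
    cin_b <- plan[l]
    cin_a <- if (l == 1L) p$in_ch else plan[l - 1L]
    r2 <- conv_block_bwd(dinto, tp$b2, p$conv[[paste0("enc", l, "b")]], cin_b)
    g[[paste0("enc", l, "b")]] <- r2[c("dW", "db")]
    r1 <- conv_block_bwd(r2$dX, tp$b1, p$conv[[paste0("enc", l, "a")]], cin_a)
    g[[paste0("enc", l, "a")]] <- r1[c("dW", "db")]
    dcur <- r1$dX
  }
  g
}

adam_init <- function(p) {
  lapply(p$conv, function(cv) list(mW = cv$W * 0, vW = cv$W * 0,
                                   mb = cv$b * 0, vb = cv$b * 0))
}

adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(p$conv)) {
    gi <- g[[nm]]
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * gi$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * gi$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * as.numeric(gi$db)
    st$vb <- beta2 * st$vb + (1 - beta2) * as.numeric(gi$db)^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    p$conv[[nm]]$W <- p$conv[[nm]]$W - lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
    p$conv[[nm]]$b <- p$conv[[nm]]$b - lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[nm]] <- st
  }
  list(p = p, state = state)
}

# One Adam update on a batch of (input, target) matrices; gradients are
# averaged across the batch. Returns updated params/state and the batch MSE.
unet_train_batch <- function(p, state, xs, ys, lr, t) {
  n <- length(xs)
  gacc <- NULL
  loss <- 0
  for (i in seq_len(n)) {
    fw <- unet_forward(p, xs[[i]], keep = TRUE)
    resid <- fw$y - ys[[i]]
    loss <- loss + mean(resid^2)
    dy <- 2 * resid / length(resid) / n
    g <- unet_backward(p, fw$tape, dy)
    if (is.null(gacc)) {
      gacc <- g
    } else {
      for (nm in names(g)) {
        gacc[[nm]]$dW <- gacc[[nm]]$dW + g[[nm]]$dW
        gacc[[nm]]$db <- gacc[[nm]]$db + g[[nm]]$db
      }
    }
  }
  upd <- adam_step(p, gacc, state, lr, t)
  list(p = upd$p, state = upd$state, mse = loss / n)
}

unet_mse <- function(p, xs, ys) {
  tot <- 0; npx <- 0
  for (i in seq_along(xs)) {
    fw <- unet_forward(p, xs[[i]], keep = FALSE)
    tot <- tot + sum((fw$y - ys[[i]])^2)
    npx <- npx + length(ys[[i]])
  }
  tot / npx
}
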