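# Bright-field-to-fluorescence translation ("in silico staining"):
# patch handling, per-channel model training and inference, and pixel-wise
# (SSIM/PSNR) plus feature-level (Pearson across chips) evaluation.

#' Patch specification
#'
#' Chips are cropped into square patches with overlapping regions for
#' training and inference; edge patches are anchored to the image border
#' so the union of patches covers every pixel.
#'
#' @param patch_size_px Patch side in pixels (default 224).
#' @param stride_px Grid stride; `stride_px < patch_size_px` gives overlap.
#' @param blend Overlap blending at reassembly: `"average"` or
#'   `"linear_ramp"` (weights taper towards patch edges).
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(patch_size_px = 224L, stride_px = 112L,
                       blend = c("average", "linear_ramp")) {
  blend <- match.arg(blend)
  if (stride_px <= 0L || stride_px > patch_size_px)
    stopf("require 0 < stride_px <= patch_size_px")
  list(patch_size_px = as.integer(patch_size_px),
       stride_px = as.integer(stride_px), blend = blend)
}

# Border-anchored grid origins (1-based) covering an axis of length n.
grid_origins <- function(n, patch, stride) {
  if (n <= patch) return(1L)
  o <- seq.int(1L, n - patch + 1L, by = stride)
  if (o[length(o)] != n - patch + 1L) o <- c(o, n - patch + 1L)
  o
}

#' Extract overlapping patches
#'
#' @param img A [chip_image()] or matrix.
#' @param spec A [patch_spec()].
#' @return List of `list(patch, x0, y0)` with 1-based origins; the patch
#'   grid covers the full image. Images smaller than the patch size yield
#'   a single full-image patch.
#' @export
extract_patches <- function(img, spec = patch_spec()) {
  px <- as_pixels(img)
  p <- spec$patch_size_px
  ph <- min(p, nrow(px)); pw <- min(p, ncol(px))
  ys <- grid_origins(nrow(px), ph, spec$stride_px)
  xs <- grid_origins(ncol(px), pw, spec$stride_px)
  out <- vector("list", length(ys) * length(xs))
  k <- 1L
  for (y0 in ys) for (x0 in xs) {
    out[[k]] <- list(patch = px[y0 + seq_len(ph) - 1L, x0 + seq_len(pw) - 1L,
                                drop = FALSE],
                     x0 = x0, y0 = y0)
    k <- k + 1L
  }
  out
}

#' Reassemble patches into a full image
#'
#' Overlapping contributions are blended according to the patch spec:
#' plain averaging, or a linear ramp that down-weights pixels near patch
#' edges. Reassembling unmodified patches reproduces the source image
#' exactly under both modes.
#'
#' @param patches List as returned by [extract_patches()] (patch values
#'   may have been replaced by model predictions).
#' @param height,width Output dimensions.
#' @param spec The [patch_spec()] used for extraction.
#' @return Numeric matrix `height x width`.
#' @export
reassemble_patches <- function(patches, height, width, spec = patch_spec()) {
  acc <- matrix(0, height, width)
  wsum <- matrix(0, height, width)
  for (pt in patches) {
    ph <- nrow(pt$patch); pw <- ncol(pt$patch)
    wt <- if (spec$blend == "average") {
      matrix(1, ph, pw)
    } else {
      ramp <- function(n) pmin(seq_len(n), rev(seq_len(n)), (n + 1) / 2) /
        ((n + 1) / 2)
      outer(ramp(ph), ramp(pw))
    }
    rows <- pt$y0 + seq_len(ph) - 1L
    cols <- pt$x0 + seq_len(pw) - 1L
    acc[rows, cols] <- acc[rows, cols] + pt$patch * wt
    wsum[rows, cols] <- wsum[rows, cols] + wt
  }
  acc / wsum
}

#' Training hyperparameters for translation models
#'
#' Defaults are the desk-scale settings: short Adam/MSE training on
#' random crops with a raised learning rate to compensate for the reduced
#' update count. Fidelity mode (the published protocol: learning rate
#' 1e-4, 150 epochs, batch 8, patch 224) is available by overriding
#' `lr`, `epochs` and `crop_px`.
#'
#' @param epochs Training epochs.
#' @param batch_size Patches per Adam update.
#' @param lr Adam learning rate.
#' @param crop_px Side of random training crops (multiple of
#'   `2^(depth-1)`).
#' @param patches_per_epoch Random crops sampled per epoch.
#' @param base_filters First-level filter count (doubled per level).
#' @param depth Resolution levels of the encoder-decoder.
#' @param schedule Learning-rate schedule: `"step"` (x0.3 at 60% and 85%
#'   of the epoch budget) or `"onecycle"` (linear warmup over the first
#'   10%, cosine decay to ~0 after).
#' @param patience Early-stopping patience in epochs (ignored when
#'   `fixed_epochs`).
#' @param fixed_epochs If `TRUE`, always run all epochs (fidelity mode);
#'   best-validation weights are still the ones retained.
#' @param seed RNG seed for init and data order.
#' @return Hyperparameter list.
#' @export
train_hyper <- function(epochs = 18L, batch_size = 8L, lr = 1e-3,
                        crop_px = 96L, patches_per_epoch = 64L,
                        base_filters = 16L, depth = 4L,
                        schedule = c("step", "onecycle"), patience = 15L,
                        fixed_epochs = FALSE, seed = 1L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, crop_px = as.integer(crop_px),
       patches_per_epoch = as.integer(patches_per_epoch),
       base_filters = as.integer(base_filters), depth = as.integer(depth),
       schedule = match.arg(schedule),
       patience = as.integer(patience), fixed_epochs = fixed_epochs,
       seed = as.integer(seed))
}

pair_pixels <- function(pair) {
  list(bf = as_pixels(pair[[1]]), fl = as_pixels(pair[[2]]))
}

# Deterministic validation crops: centered grid, up to `max_n` per pair.
val_crops <- function(pairs, crop, max_n = 16L) {
  xs <- list(); ys <- list()
  for (pp in pairs) {
    p <- pair_pixels(pp)
    h <- nrow(p$bf); w <- ncol(p$bf)
    oy <- grid_origins(h, min(crop, h), crop)
    ox <- grid_origins(w, min(crop, w), crop)
    for (y0 in oy) for (x0 in ox) {
      xs[[length(xs) + 1L]] <- p$bf[y0 + seq_len(min(crop, h)) - 1L,
                                    x0 + seq_len(min(crop, w)) - 1L, drop = FALSE]
      ys[[length(ys) + 1L]] <- p$fl[y0 + seq_len(min(crop, h)) - 1L,
                                    x0 + seq_len(min(crop, w)) - 1L, drop = FALSE]
    }
  }
  if (length(xs) > max_n) {
    keep <- round(seq(1, length(xs), length.out = max_n))
    xs <- xs[keep]; ys <- ys[keep]
  }
  list(xs = xs, ys = ys)
}

#' Train a bright-field to fluorescence translation model
#'
#' Trains one encoder-decoder model for a single fluorescence channel on
#' spatially registered (bright-field, fluorescence) image pairs using an
#' MSE loss and the Adam optimizer. Bright-field inputs are z-scored with
#' statistics estimated on the training set; fluorescence targets stay on
#' the normalized `[0, 1]` intensity scale. Each epoch samples random
#' crops from the training pairs; the weights with the best validation MSE
#' are retained. Training is fully seeded (init and data order).
#'
#' @param train_pairs,val_pairs Lists of `list(bf, fluorescence)` image
#'   pairs ([chip_image()]s or matrices); pairs must be registered and
#'   share shapes.
#' @param channel `"DAPI"` or `"TRITC"`; stored on the model. One model
#'   serves exactly one fluorescence channel.
#' @param hyper A [train_hyper()] list.
#' @param spec [patch_spec()] used later at inference.
#' @param verbose Print per-epoch validation loss.
#' @return A `translation_model`: parameters, normalization stats,
#'   architecture and patch spec, and the training log.
#' @export
train_translation <- function(train_pairs, val_pairs, channel = "DAPI",
                              hyper = train_hyper(), spec = patch_spec(),
                              verbose = FALSE) {
  if (!length(train_pairs)) stopf("empty training set")
  tp <- lapply(train_pairs, pair_pixels)
  for (p in tp) if (!identical(dim(p$bf), dim(p$fl)))
    stopf("mismatched pair shapes")
  crop <- hyper$crop_px
  if (crop %% 2^(hyper$depth - 1L) != 0L)
    stopf("`crop_px` must be a multiple of 2^(depth-1)")
  bf_all <- unlist(lapply(tp, function(p) as.numeric(p$bf)))
  bf_mean <- mean(bf_all); bf_sd <- max(stats::sd(bf_all), 1e-6)
  norm_x <- function(m) (m - bf_mean) / bf_sd

  p <- unet_init(1L, hyper$base_filters, hyper$depth,
                 seed = derive_seed(hyper$seed, "init", channel))
  st <- adam_init(p)
  vc <- val_crops(lapply(if (length(val_pairs)) val_pairs else train_pairs,
                         identity), crop)
  vxs <- lapply(vc$xs, norm_x)
  log <- data.frame(epoch = integer(), train_mse = numeric(),
                    val_mse = numeric())
  best <- list(p = p, val = Inf, epoch = 0L)
  t <- 0L
  for (ep in seq_len(hyper$epochs)) {
    lr_ep <- if ((hyper$schedule %||% "step") == "onecycle") {
      frac <- ep / hyper$epochs
      if (frac <= 0.1) hyper$lr * frac / 0.1
      else hyper$lr * (0.5 * (1 + cos(pi * (frac - 0.1) / 0.9)))
    } else {
      # step decay: x0.3 at 60% and 85% of the epoch budget
      hyper$lr * 0.3^((ep > 0.6 * hyper$epochs) + (ep > 0.85 * hyper$epochs))
    }
    idx <- with_seed(derive_seed(hyper$seed, "order", channel, ep), {
      n <- hyper$patches_per_epoch
      list(img = sample.int(length(tp), n, replace = TRUE),
           u = stats::runif(n), v = stats::runif(n))
    })
    ep_mse <- 0; nb <- 0L
    for (b0 in seq(1L, hyper$patches_per_epoch, by = hyper$batch_size)) {
      bi <- b0:min(b0 + hyper$batch_size - 1L, hyper$patches_per_epoch)
      xs <- vector("list", length(bi)); ys <- xs
      for (k in seq_along(bi)) {
        pp <- tp[[idx$img[bi[k]]]]
        h <- nrow(pp$bf); w <- ncol(pp$bf)
        ch <- min(crop, h - h %% 2^(hyper$depth - 1L))
        cw <- min(crop, w - w %% 2^(hyper$depth - 1L))
        y0 <- 1L + floor(idx$u[bi[k]] * (h - ch + 1L) * 0.99999)
        x0 <- 1L + floor(idx$v[bi[k]] * (w - cw + 1L) * 0.99999)
        xs[[k]] <- norm_x(pp$bf[y0 + seq_len(ch) - 1L, x0 + seq_len(cw) - 1L])
        ys[[k]] <- pp$fl[y0 + seq_len(ch) - 1L, x0 + seq_len(cw) - 1L]
      }
      t <- t + 1L
      upd <- unet_train_batch(p, st, xs, ys, lr_ep, t)
      p <- upd$p; st <- upd$state
      ep_mse <- ep_mse + upd$mse; nb <- nb + 1L
    }
    vmse <- unet_mse(p, vxs, vc$ys)
    log <- rbind(log, data.frame(epoch = ep, train_mse = ep_mse / nb,
                                 val_mse = vmse))
    if (vmse < best$val) best <- list(p = p, val = vmse, epoch = ep)
    if (verbose)
      message(sprintf("[%s] epoch %d: train %.3e val %.3e (best %.3e @%d)",
                      channel, ep, ep_mse / nb, vmse, best$val, best$epoch))
    if (!hyper$fixed_epochs && ep - best$epoch >= hyper$patience) break
  }
  structure(list(channel = channel, params = best$p,
                 norm = list(bf_mean = bf_mean, bf_sd = bf_sd),
                 patch_spec = spec, hyper = hyper, log = log,
                 best_val_mse = best$val),
            class = "translation_model")
}

#' @export
print.translation_model <- function(x, ...) {
  cat(sprintf("<translation_model> BF -> %s | depth %d, base %d | best val MSE %.3e (%d epochs run)\n",
              x$channel, x$params$depth, x$params$base, x$best_val_mse,
              nrow(x$log)))
  invisible(x)
}

# Reflect-pad a matrix so both dims are multiples of `m`; returns padded
# matrix plus the original dims for cropping back.
pad_to_multiple <- function(px, m) {
  h <- nrow(px); w <- ncol(px)
  ph <- (m - h %% m) %% m
  pw <- (m - w %% m) %% m
  if (ph > 0) px <- rbind(px, px[h:(h - ph + 1L), , drop = FALSE])
  if (pw > 0) px <- cbind(px, px[, w:(w - pw + 1L), drop = FALSE])
  list(px = px, h = h, w = w)
}

#' Predict a fluorescence image from bright-field
#'
#' Patch-wise inference with the model's patch spec, reassembled with
#' overlap blending; output matches the input size, with intensities
#' clipped to the valid `[0, 1]` range. Inference is deterministic.
#'
#' @param model A [train_translation()] model.
#' @param bf Bright-field [chip_image()] or matrix.
#' @return A [chip_image()] of the model's fluorescence channel (or a
#'   matrix when `bf` is a matrix).
#' @export
predict_fluorescence <- function(model, bf) {
  stopifnot(inherits(model, "translation_model"))
  px <- as_pixels(bf)
  xn <- (px - model$norm$bf_mean) / model$norm$bf_sd
  m <- 2L^(model$params$depth - 1L)
  patches <- extract_patches(xn, model$patch_spec)
  for (k in seq_along(patches)) {
    pd <- pad_to_multiple(patches[[k]]$patch, m)
    y <- unet_forward(model$params, pd$px, keep = FALSE)$y
    patches[[k]]$patch <- y[seq_len(pd$h), seq_len(pd$w), drop = FALSE]
  }
  out <- clamp01(reassemble_patches(patches, nrow(px), ncol(px),
                                    model$patch_spec))
  if (inherits(bf, "chip_image")) rewrap(out, bf, channel = model$channel)
  else out
}

#' Save / load a translation model
#'
#' The weights go to an RDS blob and the metadata (architecture,
#' normalization stats, patch spec, training log) to a JSON sidecar.
#'
#' @param model A `translation_model`.
#' @param path Base path; `.rds` and `.json` are appended.
#' @return `path` (invisibly) / the model.
#' @export
save_translation_model <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  meta <- list(channel = model$channel, depth = model$params$depth,
               base_filters = model$params$base, norm = model$norm,
               patch_spec = model$patch_spec, best_val_mse = model$best_val_mse,
               log = model$log)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_translation_model
#' @export
load_translation_model <- function(path) readRDS(paste0(path, ".rds"))

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5) and constants
#' `K1 = 0.01`, `K2 = 0.03`, computed with reflective boundary handling
#' and averaged over the image.
#'
#' @param x,y Images on a common intensity scale.
#' @param max_val Dynamic range (1 for the package's normalized scale).
#' @return Mean SSIM in `[-1, 1]`.
#' @export
eval_ssim <- function(x, y, max_val = 1) {
  x <- as_pixels(x); y <- as_pixels(y)
  if (!identical(dim(x), dim(y))) stopf("images must share shape")
  k <- exp(-(seq(-5, 5))^2 / (2 * 1.5^2)); k <- k / sum(k)
  # true 2D reflective padding before separable filtering, so corner
  # handling follows the windowed definition exactly
  h <- nrow(x); w <- ncol(x)
  ri <- c(rev(seq_len(min(5, h))), seq_len(h), h + 1L - seq_len(min(5, h)))
  ci <- c(rev(seq_len(min(5, w))), seq_len(w), w + 1L - seq_len(min(5, w)))
  f <- function(m) convolve_sep(m[ri, ci, drop = FALSE], k)[5L + seq_len(h),
                                                           5L + seq_len(w),
                                                           drop = FALSE]
  c1 <- (0.01 * max_val)^2; c2 <- (0.03 * max_val)^2
  mx <- f(x); my <- f(y)
  vx <- f(x * x) - mx^2; vy <- f(y * y) - my^2
  cxy <- f(x * y) - mx * my
  ssim_map <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(ssim_map)
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' `10 * log10(MAX^2 / MSE)` with `MAX` the declared dynamic range.
#' Identical images (MSE 0) are reported as the capped sentinel 99 dB.
#'
#' @inheritParams eval_ssim
#' @param cap Sentinel value returned for exact equality.
#' @return PSNR in dB.
#' @export
eval_psnr <- function(x, y, max_val = 1, cap = 99) {
  x <- as_pixels(x); y <- as_pixels(y)
  if (!identical(dim(x), dim(y))) stopf("images must share shape")
  mse <- mean((x - y)^2)
  if (mse == 0) return(cap)
  min(10 * log10(max_val^2 / mse), cap)
}

#' Pixel-wise evaluation of a prediction
#'
#' @param pred,truth Predicted and ground-truth images on the normalized
#'   `[0, 1]` scale. PSNR at `max_val = 1` equals PSNR computed on integer
#'   intensities at the declared bit depth with `MAX = 2^bits - 1`.
#' @return List with `ssim` and `psnr`.
#' @export
evaluate_pixelwise <- function(pred, truth) {
  list(ssim = eval_ssim(pred, truth), psnr = eval_psnr(pred, truth))
}

#' Feature-level evaluation across test chips
#'
#' For each test chip, extracts the chip-level sum intensity and sum area
#' (via the standard post-processing: smoothing, artifact removal, Otsu
#' masking) from both the predicted and the ground-truth fluorescence
#' image, then correlates predicted against true values across chips
#' (Pearson), per feature.
#'
#' @param pred_set,truth_set Lists of predicted / ground-truth images in
#'   matching chip order.
#' @param channel `"DAPI"` or `"TRITC"` (selects the Otsu variant).
#' @param params [segment_params()] for post-processing.
#' @return List: `pearson_sum_intensity`, `pearson_sum_area`,
#'   `n_test_chips`, and the per-chip feature table.
#' @export
evaluate_featurewise <- function(pred_set, truth_set, channel = "DAPI",
                                 params = segment_params()) {
  if (length(pred_set) != length(truth_set)) stopf("set lengths differ")
  feat <- function(img) {
    pp <- postprocess_channel(img, channel, params)
    c(area = pp$sum_area, intensity = pp$sum_intensity)
  }
  fp <- t(vapply(pred_set, feat, numeric(2)))
  ft <- t(vapply(truth_set, feat, numeric(2)))
  tab <- data.frame(chip = seq_len(nrow(fp)),
                    pred_sum_area = fp[, "area"], true_sum_area = ft[, "area"],
                    pred_sum_intensity = fp[, "intensity"],
                    true_sum_intensity = ft[, "intensity"])
  list(pearson_sum_intensity = correlate_readouts(tab$pred_sum_intensity,
                                                  tab$true_sum_intensity)$pearson_r,
       pearson_sum_area = correlate_readouts(tab$pred_sum_area,
                                             tab$true_sum_area)$pearson_r,
       n_test_chips = nrow(tab), features = tab)
}
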