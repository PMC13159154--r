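# Shared fixtures and independent oracles, all built in code at test time.

# Small simulation configuration used across tests (kept tiny for speed).
tiny_config <- function(...) {
  defaults <- list(channel_width_px = 160L, channel_height_px = 128L,
                   seeding_density = 30L, noise_sd = 0.01,
                   stain_unevenness_amplitude = 0.15, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Brute-force flood-fill component count (8-connectivity) -- independent
# oracle for the label machinery.
flood_fill_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      q <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- q[1] + di; jj <- q[2] + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

# Exhaustive double-loop three-class Otsu oracle over an already binned
# histogram (counts per bin, bin midpoints).
otsu3_bruteforce <- function(counts, mids) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf; best_pair <- c(NA, NA)
  mu_T <- sum(p * mids)
  for (t1 in 1:(n - 2)) for (t2 in (t1 + 1):(n - 1)) {
    w0 <- sum(p[1:t1]); w1 <- sum(p[(t1 + 1):t2]); w2 <- sum(p[(t2 + 1):n])
    if (w0 == 0 || w1 == 0 || w2 == 0) next
    m0 <- sum(p[1:t1] * mids[1:t1]) / w0
    m1 <- sum(p[(t1 + 1):t2] * mids[(t1 + 1):t2]) / w1
    m2 <- sum(p[(t2 + 1):n] * mids[(t2 + 1):n]) / w2
    sb <- w0 * (m0 - mu_T)^2 + w1 * (m1 - mu_T)^2 + w2 * (m2 - mu_T)^2
    if (sb > best) { best <- sb; best_pair <- c(t1, t2) }
  }
  best_pair
}

# Direct windowed SSIM oracle: explicit per-pixel window extraction with
# reflective padding, straight from the definition.
ssim_naive <- function(x, y, max_val = 1) {
  k1d <- exp(-(seq(-5, 5))^2 / (2 * 1.5^2)); k1d <- k1d / sum(k1d)
  w <- outer(k1d, k1d)
  c1 <- (0.01 * max_val)^2; c2 <- (0.03 * max_val)^2
  H <- nrow(x); W <- ncol(x)
  reflect <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  s <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ri <- reflect(i + (-5:5), H); rj <- reflect(j + (-5:5), W)
    wx <- x[ri, rj]; wy <- y[ri, rj]
    mx <- sum(w * wx); my <- sum(w * wy)
    vx <- sum(w * wx^2) - mx^2; vy <- sum(w * wy^2) - my^2
    cxy <- sum(w * wx * wy) - mx * my
    s[i, j] <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  mean(s)
}

# Rebuild a chip_image from new pixels, copying metadata from a template.
rewrap_test <- function(px, template) {
  chip_image(px, template$channel, template$chip_id, template$day,
             template$pixel_size_um, template$bit_depth)
}

# Disk mask helper used to build synthetic segmentation inputs.
disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  ys <- matrix(seq_len(H) - 1, H, W)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}
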