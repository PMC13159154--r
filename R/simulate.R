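# Synthetic paired bright-field / fluorescence chip images with known
# ground truth. Cells are rendered in a single 2D Z-projection:
# sharp-edged nuclei in the fluorescence channels, Gaussian shading and
# rims in bright-field; dead cells carry a distinct bright-field
# appearance (condensed body, dark granular interior) so that the TRITC
# channel is predictable from bright-field, mirroring how dying cells look
# under transmitted light.

#' Simulation configuration
#'
#' Defines one study condition for the synthetic chip generator. Defaults
#' emulate a full-size gel-channel region of interest (1024 x 320 px at
#' ~3 um/px, i.e. the 500-um-wide channel), 300 seeded single cells, daily
#' growth, a 4PL dose-viability law and mild staining/detection artifacts.
#'
#' @param channel_width_px,channel_height_px Image width/height in pixels.
#' @param seeding_density Cells per chip at day 0 (> 0).
#' @param seeding_cv Chip-to-chip coefficient of variation of the realized
#'   cell count (lognormal); 0 gives exactly `seeding_density` cells.
#' @param base_radius_px,radius_sd_px Day-0 cell radius distribution (px).
#' @param growth_rate Per-day multiplicative radius factor (>= 1 typical).
#' @param aggregate_fraction_per_day Fraction of cells newly recruited into
#'   multi-cell aggregates per day of culture.
#' @param aggregate_mean_size Mean number of cells per aggregate.
#' @param baseline_death_rate Per-day probability of spontaneous cell death
#'   (culture attrition); cells only ever flip live to dead.
#' @param drug_bottom,drug_top,drug_ic50,drug_hill 4PL viability-vs-dose
#'   parameters: viability fraction in `[0, 1]`, IC50 in uM, Hill slope > 0.
#' @param stain_unevenness_amplitude Amplitude in `[0, 1]` of the smooth
#'   low-frequency multiplicative field applied to fluorescence (not BF).
#' @param noise_sd Gaussian detector noise SD as a fraction of full scale.
#' @param bit_depth 8 or 16.
#' @param pixel_size_um Physical pixel size.
#' @param seed Base RNG seed; fixed seed implies byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(channel_width_px = 1024L, channel_height_px = 320L,
                       seeding_density = 300L, seeding_cv = 0,
                       base_radius_px = 6, radius_sd_px = 0.8,
                       growth_rate = 1.10, aggregate_fraction_per_day = 0.06,
                       aggregate_mean_size = 4, baseline_death_rate = 0.01,
                       drug_bottom = 0.05, drug_top = 1, drug_ic50 = 1,
                       drug_hill = 1, stain_unevenness_amplitude = 0.15,
                       noise_sd = 0.01, bit_depth = 16L, pixel_size_um = 3,
                       seed = 1L) {
  cfg <- list(channel_width_px = as.integer(channel_width_px),
              channel_height_px = as.integer(channel_height_px),
              seeding_density = as.integer(seeding_density),
              seeding_cv = seeding_cv,
              base_radius_px = base_radius_px, radius_sd_px = radius_sd_px,
              growth_rate = growth_rate,
              aggregate_fraction_per_day = aggregate_fraction_per_day,
              aggregate_mean_size = aggregate_mean_size,
              baseline_death_rate = baseline_death_rate,
              drug_bottom = drug_bottom, drug_top = drug_top,
              drug_ic50 = drug_ic50, drug_hill = drug_hill,
              stain_unevenness_amplitude = stain_unevenness_amplitude,
              noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
              pixel_size_um = pixel_size_um, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$channel_width_px < 8L || cfg$channel_height_px < 8L)
    stopf("image dimensions too small")
  if (cfg$seeding_density <= 0L)
    stopf("configuration error: `seeding_density` must be positive")
  if (cfg$drug_bottom < 0 || cfg$drug_top > 1 || cfg$drug_bottom > cfg$drug_top)
    stopf("4PL parameters must satisfy 0 <= bottom <= top <= 1")
  if (cfg$drug_ic50 <= 0) stopf("`drug_ic50` must be positive")
  if (cfg$drug_hill <= 0) stopf("`drug_hill` must be positive")
  if (cfg$stain_unevenness_amplitude < 0 || cfg$stain_unevenness_amplitude > 1)
    stopf("`stain_unevenness_amplitude` must be in [0, 1]")
  if (cfg$noise_sd < 0) stopf("`noise_sd` must be non-negative")
  if (cfg$baseline_death_rate < 0 || cfg$baseline_death_rate >= 1)
    stopf("`baseline_death_rate` must be in [0, 1)")
  if (!cfg$bit_depth %in% c(8L, 16L)) stopf("`bit_depth` must be 8 or 16")
  invisible(cfg)
}

#' 4PL viability function
#'
#' Expected viable fraction at a given dose under the simulator's
#' four-parameter logistic law
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`.
#'
#' @param dose Dose(s) in uM, >= 0 (0 gives `top`).
#' @param config A [sim_config()], or individual parameters.
#' @param bottom,top,ic50,hill Used when `config` is missing.
#' @return Viability fraction(s) in `[bottom, top]`.
#' @export
viability_4pl <- function(dose, config = NULL, bottom = 0, top = 1,
                          ic50 = 1, hill = 1) {
  if (!is.null(config)) {
    bottom <- config$drug_bottom; top <- config$drug_top
    ic50 <- config$drug_ic50; hill <- config$drug_hill
  }
  if (any(dose < 0)) stopf("`dose` must be non-negative")
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Generate a ground-truth cell population
#'
#' Draws a day-0 single-cell layout for one chip (uniform positions inside
#' the channel, Gaussian radii), then applies the deterministic day
#' transform: radii grow as `growth_rate^day` and a growing fraction of
#' cells is recruited into spatially merged aggregates. The same chip id
#' yields the same underlying cells at every day, so the only change across
#' days is growth/aggregation (and drug-induced death via [apply_drug()]).
#'
#' @param config A [sim_config()].
#' @param day Integer day >= 0.
#' @param chip_id Chip identifier; part of the per-chip random stream.
#' @return A `cell_population`: data.frame with columns `cell_id`, `x`, `y`
#'   (px, 0-based centers), `radius` (px), `state` (`"live"`/`"dead"`) and
#'   `aggregate_id` (NA for unclustered cells), plus `chip_id`, `day` and
#'   `config` attributes.
#' @export
generate_population <- function(config, day = 0L, chip_id = "chip01") {
  stopifnot(inherits(config, "sim_config"))
  if (day < 0) stopf("`day` must be >= 0")
  day <- as.integer(day)
  W <- config$channel_width_px; H <- config$channel_height_px
  seed <- derive_seed(config$seed, "pop", chip_id)
  pop <- with_seed(seed, {
    n <- config$seeding_density
    if (config$seeding_cv > 0) {
      sdlog <- sqrt(log(1 + config$seeding_cv^2))
      n <- max(1L, as.integer(round(n * stats::rlnorm(1, -sdlog^2 / 2, sdlog))))
    }
    margin <- 3 * config$base_radius_px
    x <- stats::runif(n, margin, W - 1 - margin)
    y <- stats::runif(n, margin, H - 1 - margin)
    r0 <- pmax(1.5, stats::rnorm(n, config$base_radius_px, config$radius_sd_px))
    perm <- sample.int(n)   # fixed recruitment order into aggregates
    u_death <- stats::runif(n)  # nested spontaneous-death draws across days
    list(n = n, x = x, y = y, r0 = r0, perm = perm, u_death = u_death)
  })
  n <- pop$n
  radius <- pop$r0 * config$growth_rate^day
  x <- pop$x; y <- pop$y
  aggregate_id <- rep(NA_integer_, n)
  k <- round(min(0.9, config$aggregate_fraction_per_day * day) * n)
  if (k >= 2) {
    members <- pop$perm[seq_len(k)]
    gsize <- max(2L, as.integer(round(config$aggregate_mean_size)))
    grp <- ((seq_len(k) - 1L) %/% gsize) + 1L
    for (g in unique(grp)) {
      idx <- members[grp == g]
      if (length(idx) < 2L) next
      seed_cell <- idx[1]
      ang <- 2 * pi * (seq_along(idx) - 1) / length(idx)
      off <- 1.1 * radius[seed_cell]
      x[idx] <- pmin(pmax(x[seed_cell] + off * cos(ang) * (seq_along(idx) > 1), 1), W - 2)
      y[idx] <- pmin(pmax(y[seed_cell] + off * sin(ang) * (seq_along(idx) > 1), 1), H - 2)
      aggregate_id[idx] <- g
    }
  }
  # spontaneous culture attrition, nested so state only flips live -> dead
  state <- ifelse(pop$u_death < 1 - (1 - config$baseline_death_rate)^day,
                  "dead", "live")
  structure(
    data.frame(cell_id = seq_len(n), x = x, y = y, radius = radius,
               state = state, aggregate_id = aggregate_id,
               stringsAsFactors = FALSE),
    chip_id = as.character(chip_id), day = day, class = c("cell_population", "data.frame"))
}

#' Apply a drug dose to a population
#'
#' Each live cell independently flips to dead with probability
#' `1 - v(dose)` where `v` is the 4PL viability law of the configuration,
#' so the expected live fraction equals `v(dose)`. Dead cells never revive.
#'
#' @param pop A `cell_population`.
#' @param dose Dose in uM (>= 0).
#' @param config The [sim_config()] holding the 4PL parameters.
#' @param seed RNG seed for the death draws.
#' @return The population with updated `state`.
#' @export
apply_drug <- function(pop, dose, config, seed = config$seed) {
  stopifnot(inherits(pop, "cell_population"))
  if (!is_scalar_number(dose) || dose < 0) stopf("`dose` must be >= 0")
  v <- viability_4pl(dose, config)
  live <- which(pop$state == "live")
  if (length(live)) {
    dies <- with_seed(derive_seed(seed, "drug", attr(pop, "chip_id"), format(dose)),
                      stats::runif(length(live)) > v)
    pop$state[live[dies]] <- "dead"
  }
  pop
}

# Deterministic per-cell texture phase from the rounded cell center, so the
# bright-field render is a pure function of the layout.
cell_phase <- function(x, y) {
  h <- (round(x) * 73856093 + round(y) * 19349663) %% 6283
  h / 1000
}

# Add a radially symmetric Gaussian blob (optionally textured) to a canvas.
add_blob <- function(canvas, cx, cy, sigma, amp, texture_freq = 0,
                     texture_amp = 0, phase = 0) {
  H <- nrow(canvas); W <- ncol(canvas)
  r <- ceiling(3 * sigma)
  xs <- max(0, floor(cx) - r):min(W - 1, ceiling(cx) + r)
  ys <- max(0, floor(cy) - r):min(H - 1, ceiling(cy) + r)
  if (!length(xs) || !length(ys)) return(canvas)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  g <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
  val <- amp * g
  if (texture_amp > 0) {
    val <- val + texture_amp * g * sin(texture_freq * dx + phase) *
      sin(texture_freq * dy + 1.7 * phase)
  }
  canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] + val
  canvas
}

# Sharp-edged nucleus profile: logistic falloff around radius R (edge width
# ~10% of R), so mask area is insensitive to the exact threshold — nuclei
# at ~3 um/px have near-binary boundaries.
add_nucleus <- function(canvas, cx, cy, R, amp) {
  H <- nrow(canvas); W <- ncol(canvas)
  r <- ceiling(R + 6 * max(0.3, 0.05 * R))
  xs <- max(0, floor(cx) - r):min(W - 1, ceiling(cx) + r)
  ys <- max(0, floor(cy) - r):min(H - 1, ceiling(cy) + r)
  if (!length(xs) || !length(ys)) return(canvas)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  d <- sqrt(dx^2 + dy^2)
  w <- max(0.3, 0.05 * R)
  canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] + amp / (1 + exp((d - R) / w))
  canvas
}

# Ring-shaped (annulus) profile used for the bright-field cell rim.
add_ring <- function(canvas, cx, cy, radius, width, amp) {
  H <- nrow(canvas); W <- ncol(canvas)
  r <- ceiling(radius + 3 * width)
  xs <- max(0, floor(cx) - r):min(W - 1, ceiling(cx) + r)
  ys <- max(0, floor(cy) - r):min(H - 1, ceiling(cy) + r)
  if (!length(xs) || !length(ys)) return(canvas)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  d <- sqrt(dx^2 + dy^2)
  canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] +
    amp * exp(-(d - radius)^2 / (2 * width^2))
  canvas
}

# Smooth low-frequency multiplicative field: 1 + amplitude * normalized sum
# of 3 random 2D cosines. Mimics uneven staining across the gel channel.
unevenness_field <- function(H, W, amplitude, seed) {
  if (amplitude <= 0) return(matrix(1, H, W))
  with_seed(seed, {
    s <- matrix(0, H, W)
    xg <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
    yg <- matrix(seq_len(H) / H, H, W)
    for (k in 1:3) {
      fx <- stats::runif(1, 0.3, 1.6); fy <- stats::runif(1, 0.3, 1.6)
      ph <- stats::runif(1, 0, 2 * pi)
      s <- s + stats::runif(1, 0.5, 1) * cos(2 * pi * (fx * xg + fy * yg) + ph)
    }
    1 + amplitude * s / max(abs(s))
  })
}

#' Render paired bright-field and fluorescence channels
#'
#' Renders one population as co-registered BF, DAPI and TRITC images.
#' DAPI (Hoechst) signal appears at every cell nucleus; TRITC (EthD-2)
#' only at dead cells. The bright-field image is a deterministic function
#' of the cell layout: a bright background with a dark membrane rim per
#' cell, a bright center for live cells and a darker granular interior for
#' dead cells, so the BF-to-fluorescence mapping is learnable. The uneven
#' staining field multiplies the fluorescence channels only; detector noise
#' is added last, then intensities are clipped and quantized to the
#' configured bit depth.
#'
#' @param pop A `cell_population`.
#' @param config A [sim_config()].
#' @param tiles If > 1, the chip is returned as this many overlapping
#'   fields of view along x (per channel).
#' @param tile_overlap Overlap fraction between neighbouring tiles.
#' @param noise Set `FALSE` to disable detector noise (ground-truth mode).
#' @param unevenness Set `FALSE` to disable the uneven staining field.
#' @return A list with elements `bf`, `dapi`, `tritc` ([chip_image()]s, or
#'   lists of tile images when `tiles > 1`).
#' @export
render_channels <- function(pop, config, tiles = 1L, tile_overlap = 0.1,
                            noise = TRUE, unevenness = TRUE) {
  stopifnot(inherits(pop, "cell_population"), inherits(config, "sim_config"))
  W <- config$channel_width_px; H <- config$channel_height_px
  if (nrow(pop) && (any(pop$x < 0 | pop$x > W - 1) || any(pop$y < 0 | pop$y > H - 1)))
    stopf("population lies outside the image bounds")
  chip_id <- attr(pop, "chip_id"); day <- attr(pop, "day")

  bf <- matrix(0.72, H, W)
  dapi <- matrix(0, H, W)
  tritc <- matrix(0, H, W)
  for (i in seq_len(nrow(pop))) {
    cx <- pop$x[i]; cy <- pop$y[i]; r <- pop$radius[i]
    dead <- pop$state[i] == "dead"
    ph <- cell_phase(cx, cy)
    if (dead) {
      # dying cells condense: smaller, brighter (pyknotic) nucleus, shrunken
      # body with a dark granular interior under transmitted light
      dapi <- add_nucleus(dapi, cx, cy, 0.55 * r, 0.85)
      # bright nuclear core over a faint cytoplasmic haze: the dead-cell
      # stain also enters the cytoplasm weakly, which is what the middle
      # class of the three-class Otsu split absorbs
      tritc <- add_nucleus(tritc, cx, cy, 0.55 * r, 0.68)
      tritc <- add_nucleus(tritc, cx, cy, 0.90 * r, 0.22)
      bf <- add_ring(bf, cx, cy, 0.85 * r, 0.30 * r, -0.33)
      bf <- add_blob(bf, cx, cy, 0.50 * r, -0.20,
                     texture_freq = 2.4 / sqrt(r), texture_amp = 0.18, phase = ph)
    } else {
      dapi <- add_nucleus(dapi, cx, cy, 0.65 * r, 0.75)
      bf <- add_ring(bf, cx, cy, r, 0.30 * r, -0.33)
      bf <- add_blob(bf, cx, cy, 0.50 * r, +0.10,
                     texture_freq = 1.1 / sqrt(r), texture_amp = 0.04, phase = ph)
    }
  }
  if (unevenness && config$stain_unevenness_amplitude > 0) {
    amp <- config$stain_unevenness_amplitude
    dapi <- dapi * unevenness_field(H, W, amp, derive_seed(config$seed, "uf-dapi", chip_id, day))
    # uneven staining is markedly less severe for the dead-cell stain
    tritc <- tritc * unevenness_field(H, W, 0.4 * amp,
                                      derive_seed(config$seed, "uf-tritc", chip_id, day))
  }
  chans <- list(BF = bf, DAPI = dapi, TRITC = tritc)
  if (noise && config$noise_sd > 0) {
    for (ch in names(chans)) {
      nz <- with_seed(derive_seed(config$seed, "noise", ch, chip_id, day),
                      stats::rnorm(H * W, 0, config$noise_sd))
      chans[[ch]] <- chans[[ch]] + matrix(nz, H, W)
    }
  }
  wrap <- function(px, ch) chip_image(quantize(px, config$bit_depth), ch,
                                      chip_id, day, config$pixel_size_um,
                                      config$bit_depth)
  out <- list(bf = wrap(chans$BF, "BF"), dapi = wrap(chans$DAPI, "DAPI"),
              tritc = wrap(chans$TRITC, "TRITC"))
  if (tiles > 1L) out <- lapply(out, cut_into_tiles, tiles = tiles,
                                overlap_fraction = tile_overlap)
  out
}

# Emulate acquisition as overlapping fields of view: crop `tiles` windows
# whose union covers the chip, each sharing `overlap_fraction` of its width
# with its neighbour.
cut_into_tiles <- function(img, tiles, overlap_fraction = 0.1) {
  px <- as_pixels(img)
  W <- ncol(px)
  w <- ceiling(W / (tiles - (tiles - 1) * overlap_fraction))
  ov <- round(overlap_fraction * w)
  step <- w - ov
  lapply(seq_len(tiles), function(i) {
    x0 <- min((i - 1L) * step, W - w)
    rewrap(px[, x0 + seq_len(w), drop = FALSE], img)
  })
}

#' Simulate a Z-stack for one channel
#'
#' Produces axially shifted, blurred and attenuated copies of the in-focus
#' render so that maximum-intensity projection approximately recovers it.
#'
#' @param img In-focus [chip_image()].
#' @param n_slices Number of slices (default 19).
#' @param step_um Axial step (default 14).
#' @param blur_per_um Defocus blur sigma growth per um from focus.
#' @return A [z_stack()].
#' @export
simulate_zstack <- function(img, n_slices = 19L, step_um = 14,
                            blur_per_um = 0.02) {
  px <- as_pixels(img)
  focus <- (n_slices + 1) / 2
  slices <- lapply(seq_len(n_slices), function(i) {
    dz <- abs(i - focus) * step_um
    s <- if (dz == 0) px else convolve_sep(px, gaussian_kernel_1d(1e-6 + blur_per_um * dz))
    s / (1 + 0.01 * dz)
  })
  z_stack(slices, step_um = step_um,
          channel = if (inherits(img, "chip_image")) img$channel else "BF")
}

#' Ground-truth areas for a population
#'
#' Rasterizes the noiseless, evenly stained fluorescence render and
#' thresholds it at roughly half the nucleus amplitude — on the sharp-edged
#' nucleus profile this recovers the geometric disk area — to define the
#' true DAPI and TRITC masks; the true viable area is the DAPI mask minus
#' the TRITC mask within it.
#'
#' @param pop A `cell_population`.
#' @param config A [sim_config()].
#' @param threshold Mask threshold on the noiseless render.
#' @return List with `dapi_area`, `tritc_area`, `live_area` (px) and the
#'   logical masks.
#' @export
truth_areas <- function(pop, config, threshold = 0.4) {
  ch <- render_channels(pop, config, noise = FALSE, unevenness = FALSE)
  dmask <- ch$dapi$pixels > threshold
  tmask <- ch$tritc$pixels > threshold
  list(dapi_area = sum(dmask), tritc_area = sum(dmask & tmask),
       live_area = sum(dmask) - sum(dmask & tmask),
       dapi_mask = dmask, tritc_mask = tmask)
}

#' Generate a full synthetic dataset on disk
#'
#' Writes per-chip/day/channel TIFF images, a CSV manifest and a
#' ground-truth CSV (true areas plus a simulated ATP luminescence readout
#' proportional to true live area). Chips cycle through the dose list;
#' drug-induced death is applied only at days after `treat_day`, emulating
#' treatment at `treat_day` followed by imaging 48 h later. An optional
#' 7:2:1 train/validation/test split is assigned at chip level.
#'
#' @param config A [sim_config()].
#' @param n_chips Number of chips.
#' @param days Integer vector of imaging days.
#' @param doses Dose list in uM (0 = vehicle) recycled across chips.
#' @param out_dir Output directory (created).
#' @param split If `TRUE`, assign chips to train/val/test at 7:2:1.
#' @param treat_day Day at which drug treatment starts (death appears on
#'   later imaging days).
#' @param atp_cv CV of the simulated ATP (CellTiter-Glo-like) readout.
#' @return The manifest data.frame (invisibly); files under `out_dir`.
#' @export
generate_dataset <- function(config, n_chips, days = c(0L, 2L, 4L, 6L, 8L),
                             doses = c(0, 0.01, 0.1, 1, 10, 100),
                             out_dir = tempfile("chips"), split = TRUE,
                             treat_day = 6L, atp_cv = 0.08) {
  stopifnot(inherits(config, "sim_config"))
  if (n_chips < 1L) stopf("`n_chips` must be positive")
  if (split && n_chips < 10L)
    stopf("`n_chips` < 10 with a 7:2:1 split would leave an empty set")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  chip_ids <- sprintf("chip%03d", seq_len(n_chips))
  chip_dose <- rep_len(doses, n_chips)
  split_of <- rep(NA_character_, n_chips)
  if (split) {
    n_test <- max(1L, round(0.1 * n_chips))
    n_val <- max(1L, round(0.2 * n_chips))
    ord <- with_seed(derive_seed(config$seed, "split"), sample.int(n_chips))
    split_of[ord[seq_len(n_test)]] <- "test"
    split_of[ord[n_test + seq_len(n_val)]] <- "val"
    split_of[is.na(split_of)] <- "train"
  }
  rows <- list(); truth_rows <- list()
  for (i in seq_len(n_chips)) {
    cid <- chip_ids[i]
    for (d in days) {
      pop <- generate_population(config, day = d, chip_id = cid)
      if (d > treat_day && chip_dose[i] > 0)
        pop <- apply_drug(pop, chip_dose[i], config)
      ch <- render_channels(pop, config)
      paths <- vapply(c("bf", "dapi", "tritc"), function(nm) {
        p <- file.path(out_dir, "images",
                       sprintf("%s_d%02d_%s.tif", cid, d, toupper(nm)))
        write_chip_tiff(ch[[nm]], p)
        p
      }, character(1))
      ta <- truth_areas(pop, config)
      atp <- ta$live_area *
        with_seed(derive_seed(config$seed, "atp", cid, d),
                  stats::rlnorm(1, -log(1 + atp_cv^2) / 2, sqrt(log(1 + atp_cv^2))))
      rows[[length(rows) + 1L]] <- data.frame(
        chip_id = cid, day = d, dose = chip_dose[i],
        replicate = ((i - 1L) %/% length(doses)) + 1L, split = split_of[i],
        bf_path = paths[1], dapi_path = paths[2], tritc_path = paths[3],
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        chip_id = cid, day = d, dose = chip_dose[i],
        true_dapi_area = ta$dapi_area, true_tritc_area = ta$tritc_area,
        true_live_area = ta$live_area, atp_signal = atp,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
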