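test_that("two-class Otsu separates well-separated modes and scales with intensity", {
  set.seed(2)
  px <- matrix(c(rep(10, 500), rep(200, 500)) + rnorm(1000, 0, 0.5), 40, 25)
  t2 <- otsu_threshold(px, 2L)
  expect_gt(t2, 11)
  expect_lt(t2, 199)
  # doubling intensities doubles the threshold within one bin width
  t2x <- otsu_threshold(px * 2, 2L)
  bin <- diff(range(px * 2)) / 256
  expect_lt(abs(t2x - 2 * t2), 2 * bin)
  expect_error(otsu_threshold(matrix(1, 5, 5), 2L), "degenerate")
})

test_that("three-class Otsu equals the exhaustive brute-force search", {
  set.seed(4)
  for (rep in 1:3) {
    px <- matrix(c(rnorm(400, 0.1, 0.02), rnorm(300, 0.45, 0.03),
                   rnorm(300, 0.85, 0.02)), 50, 20)
    thr <- otsu_threshold(px, 3L)
    expect_length(thr, 2)
    expect_lt(thr[1], thr[2])
    # reproduce the binning, then brute force over all (t1 < t2) pairs
    lo <- min(px); hi <- max(px); n_bins <- 256
    counts <- tabulate(pmin(pmax(floor((px - lo) / (hi - lo) * n_bins) + 1, 1),
                            n_bins), n_bins)
    mids <- lo + (hi - lo) * ((seq_len(n_bins) - 0.5) / n_bins)
    bf <- otsu3_bruteforce(counts, mids)
    edges <- lo + (hi - lo) * (seq_len(n_bins) / n_bins)
    expect_equal(thr, edges[bf])
  }
})

test_that("8-connected labeling matches a brute-force flood fill", {
  set.seed(11)
  for (rep in 1:5) {
    mask <- matrix(runif(64 * 64) < 0.25, 64, 64)
    lab <- label_components(mask)
    expect_equal(max(lab), flood_fill_count(mask))
    expect_identical(lab > 0, mask)
    expect_setequal(unique(as.integer(lab[lab > 0])), seq_len(max(lab)))
  }
  # diagonal touch is one object under 8-connectivity
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m)), 1L)
})

test_that("object segmentation finds disks, filters small components", {
  blank <- matrix(0, 40, 40)
  expect_equal(nrow(segment_objects(blank, 0.5)$objects), 0)

  img <- matrix(0, 64, 64)
  img[disk_mask(64, 64, 15, 15, 5)] <- 1
  img[disk_mask(64, 64, 45, 45, 5)] <- 1
  seg <- segment_objects(img, 0.5, min_area_px = 10L)
  expect_equal(nrow(seg$objects), 2)
  expect_equal(seg$objects$area_px, rep(pi * 25, 2), tolerance = 0.10)
  expect_equal(seg$objects$eccentricity, c(0, 0), tolerance = 0.1)
  # a disk below min_area is removed
  img2 <- matrix(0, 32, 32); img2[disk_mask(32, 32, 16, 16, 2)] <- 1
  expect_equal(nrow(segment_objects(img2, 0.5, min_area_px = 50L)$objects), 0)
})

test_that("aggregate classification uses the area cutoff with >= ties", {
  obj <- data.frame(object_id = 1:10, area_px = c(rep(50, 7), 300, 400, 500))
  cl <- classify_objects(obj, 200L)
  expect_equal(cl$pct_aggregates, 30)
  expect_equal(sum(cl$objects$class == "aggregate"), 3)
  allsmall <- classify_objects(data.frame(area_px = c(10, 20)), 200L)
  expect_equal(allsmall$pct_aggregates, 0)
  tie <- classify_objects(data.frame(area_px = 200), 200L)
  expect_equal(tie$objects$class, "aggregate")
  # invariant to ordering
  perm <- classify_objects(obj[sample(10), , drop = FALSE], 200L)
  expect_equal(perm$pct_aggregates, 30)
})

test_that("viability arithmetic is exact set arithmetic", {
  h <- matrix(FALSE, 20, 20); h[1:10, 1:10] <- TRUE   # 100 px
  e <- matrix(FALSE, 20, 20); e[1:10, 1:3] <- TRUE    # 30 px inside
  v <- compute_viability(h, e)
  expect_equal(v$viable_area, 70)
  expect_equal(v$viability_pct, 70)
  expect_equal(v$viable_area + v$dead_area, sum(h))   # conservation

  expect_equal(compute_viability(h, h | e)$viability_pct, 0)
  disjoint <- matrix(FALSE, 20, 20); disjoint[15:20, 15:20] <- TRUE
  expect_equal(compute_viability(h, disjoint)$viability_pct, 100)

  none <- matrix(FALSE, 20, 20)
  flagged <- compute_viability(none, e)
  expect_equal(flagged$qc_flag, "empty_hoechst")
  expect_true(is.na(flagged$viability_pct))
  expect_error(compute_viability(h, matrix(FALSE, 5, 5)), "shape")
})

test_that("chip features recover simulator ground truth and are reproducible", {
  cfg <- tiny_config(noise_sd = 0, stain_unevenness_amplitude = 0,
                     seeding_density = 25L)
  pop <- apply_drug(generate_population(cfg, 2), 1, cfg)
  ch <- render_channels(pop, cfg)
  ta <- truth_areas(pop, cfg)
  f <- chip_features(ch$bf, ch$dapi, ch$tritc)
  expect_lt(abs(f$viable_area - ta$live_area) / ta$live_area, 0.10)
  f2 <- chip_features(ch$bf, ch$dapi, ch$tritc)
  expect_identical(f, f2)
})

test_that("higher simulated dose lowers measured viability across replicates", {
  cfg <- tiny_config(seeding_density = 40L)
  viab_at <- function(dose) {
    mean(vapply(1:8, function(r) {
      cid <- sprintf("rep%d_%g", r, dose)
      pop <- apply_drug(generate_population(cfg, 2, cid), dose, cfg,
                        seed = cfg$seed + r)
      ch <- render_channels(pop, cfg)
      chip_features(NULL, ch$dapi, ch$tritc)$viability_pct
    }, numeric(1)))
  }
  v <- c(viab_at(0), viab_at(1), viab_at(100))
  expect_true(all(diff(v) < 0))
  expect_gt(v[1], 90)
  expect_lt(v[3], 40)
})
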