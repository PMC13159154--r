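test_that("day-0 population has the seeded count, all live, base radii", {
  cfg <- sim_config(seeding_density = 50L, seed = 1L,
                    channel_width_px = 256L, channel_height_px = 128L)
  pop <- generate_population(cfg, day = 0)
  expect_equal(nrow(pop), 50L)
  expect_true(all(pop$state == "live"))
  expect_equal(mean(pop$radius), cfg$base_radius_px, tolerance = 0.15)
  expect_true(all(pop$radius > 0))
  expect_true(all(pop$x >= 0 & pop$x <= cfg$channel_width_px - 1))
  expect_error(sim_config(seeding_density = 0), "positive")
})

test_that("radius growth follows the multiplicative law exactly", {
  cfg <- tiny_config()
  p0 <- generate_population(cfg, 0)
  p3 <- generate_population(cfg, 3)
  expect_equal(mean(p3$radius) / mean(p0$radius), cfg$growth_rate^3,
               tolerance = 1e-10)
  cfg1 <- tiny_config(growth_rate = 1.0, aggregate_fraction_per_day = 0)
  expect_equal(generate_population(cfg1, 5)$radius,
               generate_population(cfg1, 0)$radius)
})

test_that("populations are deterministic given the seed", {
  cfg <- tiny_config()
  a <- generate_population(cfg, 4, "chipA")
  b <- generate_population(cfg, 4, "chipA")
  expect_identical(a, b)
  c <- generate_population(cfg, 4, "chipB")
  expect_false(identical(a$x, c$x))
})

test_that("drug deaths follow the 4PL law", {
  cfg <- sim_config(seeding_density = 10000L, drug_bottom = 0, drug_top = 1,
                    drug_ic50 = 1, drug_hill = 1, seed = 5L,
                    channel_width_px = 2048L, channel_height_px = 2048L)
  pop <- generate_population(cfg, 0)
  # zero dose with top = 1: nobody dies
  expect_true(all(apply_drug(pop, 0, cfg)$state == "live"))
  # at the IC50 the expected live fraction is (bottom + top) / 2
  lf <- mean(apply_drug(pop, 1, cfg)$state == "live")
  expect_lt(abs(lf - 0.5), 3 * sqrt(0.25 / 10000))
  # saturating dose approaches bottom
  lf_hi <- mean(apply_drug(pop, 1e6, cfg)$state == "live")
  expect_lt(lf_hi, 0.01)
  expect_error(apply_drug(pop, -1, cfg), ">= 0")
})

test_that("expected live fraction is non-increasing in dose", {
  cfg <- tiny_config()
  doses <- c(0, 0.01, 0.1, 1, 10, 100)
  v <- viability_4pl(doses, cfg)
  expect_true(all(diff(v) <= 0))
  expect_equal(v[1], cfg$drug_top)
})

test_that("rendering places DAPI at all cells and TRITC only at dead cells", {
  cfg <- tiny_config(noise_sd = 0, stain_unevenness_amplitude = 0)
  empty <- generate_population(cfg, 0)[0, ]
  attr(empty, "chip_id") <- "e"; attr(empty, "day") <- 0L
  class(empty) <- c("cell_population", "data.frame")
  ch0 <- render_channels(empty, cfg)
  expect_equal(sum(ch0$dapi$pixels > 0.05), 0)

  one <- generate_population(tiny_config(seeding_density = 1L), 0)
  ch1 <- render_channels(one, tiny_config(seeding_density = 1L), noise = FALSE)
  expect_gt(max(ch1$dapi$pixels), 0.5)
  expect_equal(max(ch1$tritc$pixels), 0)   # live cell carries no TRITC

  dead <- one; dead$state <- "dead"
  chd <- render_channels(dead, tiny_config(seeding_density = 1L), noise = FALSE)
  expect_gt(max(chd$tritc$pixels), 0.5)
})

test_that("uneven staining modulates fluorescence but never bright-field", {
  cfg0 <- tiny_config(stain_unevenness_amplitude = 0, noise_sd = 0)
  cfg5 <- tiny_config(stain_unevenness_amplitude = 0.5, noise_sd = 0)
  pop <- generate_population(cfg0, 2)
  ch0 <- render_channels(pop, cfg0)
  ch5 <- render_channels(pop, cfg5)
  expect_identical(ch0$bf$pixels, ch5$bf$pixels)
  expect_false(identical(ch0$dapi$pixels, ch5$dapi$pixels))
  # per-tile mean DAPI intensity varies spatially under unevenness
  tile_means <- function(px) c(mean(px[, 1:40]), mean(px[, 41:80]),
                               mean(px[, 81:120]), mean(px[, 121:160]))
  ratio5 <- tile_means(ch5$dapi$pixels) / tile_means(ch0$dapi$pixels)
  expect_gt(diff(range(ratio5)), 0.05)
})

test_that("rendering is byte-identical under a fixed seed", {
  cfg <- tiny_config()
  pop <- generate_population(cfg, 3)
  pop <- apply_drug(pop, 1, cfg)
  a <- render_channels(pop, cfg)
  b <- render_channels(pop, cfg)
  expect_identical(a$bf$pixels, b$bf$pixels)
  expect_identical(a$dapi$pixels, b$dapi$pixels)
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  write_chip_tiff(a$tritc, f1); write_chip_tiff(b$tritc, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("ground-truth viable area matches the rendered DAPI-minus-TRITC area", {
  cfg <- tiny_config(noise_sd = 0, stain_unevenness_amplitude = 0)
  pop <- apply_drug(generate_population(cfg, 2), 1, cfg)
  ta <- truth_areas(pop, cfg)
  rendered <- render_channels(pop, cfg)
  dmask <- rendered$dapi$pixels > 0.4
  tmask <- rendered$tritc$pixels > 0.4
  live_rendered <- sum(dmask) - sum(dmask & tmask)
  expect_lt(abs(live_rendered - ta$live_area) / ta$live_area, 0.05)
  expect_equal(ta$dapi_area, ta$live_area + ta$tritc_area)
})

test_that("dataset generation writes a consistent manifest with a 7:2:1 split", {
  cfg <- tiny_config(seeding_density = 10L)
  out <- tempfile("ds")
  man <- generate_dataset(cfg, n_chips = 10L, days = c(0L, 8L),
                          doses = c(0, 1), out_dir = out)
  expect_equal(nrow(man), 10L * 2L)
  spl <- unique(man[, c("chip_id", "split")])
  expect_equal(sort(as.integer(table(spl$split))), c(1L, 2L, 7L))
  expect_equal(length(unique(spl$chip_id)), 10L)       # disjoint by construction
  expect_true(all(file.exists(man$bf_path)))
  truth <- read.csv(file.path(out, "truth.csv"))
  expect_equal(nrow(truth), 20L)
  expect_true(all(truth$true_live_area <= truth$true_dapi_area))
  expect_error(generate_dataset(cfg, n_chips = 5L, out_dir = tempfile()),
               "empty set")
})

test_that("simulated z-stacks max-project back to the in-focus image", {
  cfg <- tiny_config(noise_sd = 0)
  img <- render_channels(generate_population(cfg, 1), cfg, noise = FALSE)$dapi
  zs <- simulate_zstack(img, n_slices = 5L)
  proj <- max_project(zs, chip_id = img$chip_id)
  expect_equal(proj$pixels, img$pixels, tolerance = 0.02)
})
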