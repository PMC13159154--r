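# Post-processing of (predicted) fluorescence into chip-level features,
# baseline-subtracted longitudinal drug response, and the comparison of
# endpoint vs baseline-change dose-response readouts.

#' Post-process one fluorescence image into chip-level features
#'
#' Applies the standard feature-extraction chain: Gaussian smoothing,
#' Otsu thresholding (two-class for DAPI; three-class for TRITC, where
#' the positive mask is the top/brightest class and the middle class is
#' treated as background haze), then artifact removal (sub-minimum-area
#' 8-connected components dropped). Sum area is the mask pixel count; sum
#' intensity is the intensity integral of the input image within the mask.
#' A degenerate (near-constant) image does not error out of a batch: it
#' yields a zero-feature record flagged in `qc_flag`.
#'
#' @param img A [chip_image()] or matrix.
#' @param channel `"DAPI"` or `"TRITC"`.
#' @param params A [segment_params()] list.
#' @return List: `mask` (logical), `sum_area`, `sum_intensity`, `qc_flag`
#'   (`NA` when clean, `"degenerate_histogram"` otherwise).
#' @export
postprocess_channel <- function(img, channel = c("DAPI", "TRITC"),
                                params = segment_params()) {
  channel <- match.arg(channel)
  px <- as_pixels(img)
  sm <- gaussian_smooth(px, params$smooth_sigma_px)
  thr <- tryCatch({
    if (diff(range(sm)) < (params$min_dynamic_range %||% 0))
      stopf("degenerate histogram: dynamic range below floor")
    if (channel == "DAPI") otsu_threshold(sm, 2L) else otsu_threshold(sm, 3L)[2]
  }, error = function(e) NULL)
  if (is.null(thr)) {
    return(list(mask = matrix(FALSE, nrow(px), ncol(px)), sum_area = 0,
                sum_intensity = 0, qc_flag = "degenerate_histogram"))
  }
  mask <- remove_small_components(label_components(sm > thr),
                                  params$min_area_px) > 0L
  list(mask = mask, sum_area = sum(mask), sum_intensity = sum(px[mask]),
       qc_flag = NA_character_)
}

#' Live-cell features from paired DAPI/TRITC images
#'
#' The live mask is the DAPI mask minus the TRITC-positive area within it;
#' live area is its pixel count and live intensity the DAPI intensity
#' integral over it. Exact set arithmetic guarantees
#' `live_area + tritc_within_dapi_area = dapi_area`.
#'
#' @param dapi_img,tritc_img Co-registered images.
#' @param params [segment_params()].
#' @return List: `live_area`, `live_intensity`, `dapi_area`,
#'   `dapi_intensity`, `tritc_within_area`, `tritc_area`,
#'   `tritc_intensity`, `qc_flag`.
#' @export
live_features <- function(dapi_img, tritc_img, params = segment_params()) {
  d <- postprocess_channel(dapi_img, "DAPI", params)
  t <- postprocess_channel(tritc_img, "TRITC", params)
  live_mask <- d$mask & !t$mask
  dpx <- as_pixels(dapi_img)
  list(live_area = sum(live_mask), live_intensity = sum(dpx[live_mask]),
       dapi_area = d$sum_area, dapi_intensity = d$sum_intensity,
       tritc_within_area = sum(d$mask & t$mask),
       tritc_area = t$sum_area, tritc_intensity = t$sum_intensity,
       qc_flag = if (!is.na(d$qc_flag)) d$qc_flag else t$qc_flag)
}

#' Build a longitudinal feature table
#'
#' One row per chip and day with DAPI/TRITC sum area and intensity and the
#' live-cell features.
#'
#' @param images Nested list: `images[[chip_id]][[as.character(day)]]` is
#'   `list(dapi = , tritc = )`.
#' @param doses Named numeric vector: dose per chip_id.
#' @param params [segment_params()].
#' @return Data.frame of `longitudinal_record` rows.
#' @export
longitudinal_records <- function(images, doses, params = segment_params()) {
  rows <- list()
  for (cid in names(images)) {
    for (dstr in names(images[[cid]])) {
      lf <- live_features(images[[cid]][[dstr]]$dapi,
                          images[[cid]][[dstr]]$tritc, params)
      rows[[length(rows) + 1L]] <- data.frame(
        chip_id = cid, dose = unname(doses[cid]), day = as.integer(dstr),
        dapi_sum_area = lf$dapi_area, dapi_sum_intensity = lf$dapi_intensity,
        tritc_sum_area = lf$tritc_area, tritc_sum_intensity = lf$tritc_intensity,
        live_area = lf$live_area, live_intensity = lf$live_intensity,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Baseline-subtracted change of a feature
#'
#' Day-8 measurements minus day-6 (baseline) measurements per chip;
#' negative values mean net death or shrinkage after treatment. Baseline
#' subtraction cancels additive per-chip offsets (seeding variation).
#'
#' @param records Data.frame from [longitudinal_records()].
#' @param feature Feature column name (e.g. `"live_area"`).
#' @param day_end,day_base End and baseline days (defaults 8 and 6).
#' @return Data.frame `(chip_id, dose, delta)`.
#' @export
baseline_change <- function(records, feature, day_end = 8L, day_base = 6L) {
  if (!feature %in% names(records)) stopf("unknown feature `%s`", feature)
  e <- records[records$day == day_end, c("chip_id", "dose", feature)]
  b <- records[records$day == day_base, c("chip_id", feature)]
  m <- merge(e, b, by = "chip_id", suffixes = c("_end", "_base"))
  missing <- setdiff(e$chip_id, b$chip_id)
  if (length(missing))
    stopf("baseline unavailable for chip(s): %s",
          paste(missing, collapse = ", "))
  data.frame(chip_id = m$chip_id, dose = m$dose,
             delta = m[[paste0(feature, "_end")]] - m[[paste0(feature, "_base")]],
             stringsAsFactors = FALSE)
}

approach_values <- function(records, approach) {
  switch(approach,
    endpoint_day8 = {
      e <- records[records$day == 8L, ]
      data.frame(chip_id = e$chip_id, dose = e$dose, value = e$live_area)
    },
    delta_dapi = {
      d <- baseline_change(records, "dapi_sum_area")
      data.frame(chip_id = d$chip_id, dose = d$dose, value = d$delta)
    },
    delta_live = {
      d <- baseline_change(records, "live_area")
      data.frame(chip_id = d$chip_id, dose = d$dose, value = d$delta)
    },
    stopf("unknown approach `%s`", approach))
}

#' Compare endpoint and baseline-change dose-response approaches
#'
#' Computes, from the same chips, three dose-response readouts: endpoint
#' live area at day 8, baseline-subtracted DAPI sum area (day 8 - day 6)
#' and baseline-subtracted live area. Each is normalized to the vehicle
#' chips, fitted with the 4PL model, and summarized by a sensitivity
#' statistic: the dynamic range between vehicle and top dose in units of
#' the vehicle SD (on the normalized scale). Approaches are returned
#' ranked by sensitivity.
#'
#' @param records Data.frame from [longitudinal_records()] covering days 6
#'   and 8 and a vehicle (dose 0) group.
#' @return List with per-approach `fit` (a `dose_response`), `sensitivity`,
#'   `normalized` value tables, and `ranking`.
#' @export
compare_approaches <- function(records) {
  approaches <- c("endpoint_day8", "delta_dapi", "delta_live")
  out <- list()
  for (ap in approaches) {
    av <- approach_values(records, ap)
    veh <- av$value[av$dose == 0]
    if (length(veh) < 2L) stopf("need >= 2 vehicle chips")
    if (mean(veh) == 0) stopf("vehicle mean is zero for `%s`", ap)
    av$norm <- normalize_to_vehicle(av$value, veh)
    pos <- av[av$dose > 0, ]
    fit <- tryCatch(fit_dose_response(pos$dose, pos$norm),
                    error = function(e) NULL)
    veh_norm <- av$norm[av$dose == 0]
    top_norm <- av$norm[av$dose == max(av$dose)]
    sens <- (mean(veh_norm) - mean(top_norm)) /
      max(stats::sd(veh_norm), .Machine$double.eps)
    out[[ap]] <- list(values = av, fit = fit, sensitivity = sens,
                      dynamic_range_pct = mean(veh_norm) - mean(top_norm),
                      vehicle_sd_pct = stats::sd(veh_norm))
  }
  sv <- vapply(out, function(o) o$sensitivity, numeric(1))
  out$ranking <- data.frame(approach = names(sv)[order(-sv)],
                            sensitivity = sv[order(-sv)], row.names = NULL)
  out
}

#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: simulation
#' (one [sim_config()]), experiment layout (chips, days, doses, treatment
#' day), training hyperparameters and post-processing parameters. A YAML
#' file with the same nesting can be loaded via `load_pipeline_config()`.
#'
#' @param sim [sim_config()] arguments as a list.
#' @param n_chips,days,doses,treat_day Experiment layout.
#' @param hyper [train_hyper()] arguments as a list.
#' @param segment [segment_params()] arguments as a list.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(sim = list(), n_chips = 24L,
                            days = c(0L, 2L, 4L, 6L, 8L),
                            doses = c(0, 0.01, 0.1, 1, 10, 100),
                            treat_day = 6L, hyper = list(),
                            segment = list()) {
  list(sim = do.call(sim_config, sim), n_chips = as.integer(n_chips),
       days = as.integer(days), doses = doses,
       treat_day = as.integer(treat_day),
       hyper = do.call(train_hyper, hyper),
       segment = do.call(segment_params, segment))
}

#' @rdname pipeline_config
#' @param path YAML file with sections `sim`, `experiment`, `hyper`,
#'   `segment`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(sim = y$sim %||% list(),
                  n_chips = y$experiment$n_chips %||% 24L,
                  days = y$experiment$days %||% c(0L, 2L, 4L, 6L, 8L),
                  doses = y$experiment$doses %||% c(0, 0.01, 0.1, 1, 10, 100),
                  treat_day = y$experiment$treat_day %||% 6L,
                  hyper = y$hyper %||% list(),
                  segment = y$segment %||% list())
}

#' Run the full label-free drug-response pipeline
#'
#' Orchestrates: simulate paired chips over the culture days -> train
#' per-channel BF-to-fluorescence models on the day-8 endpoint pairs of
#' the training chips -> predict fluorescence for every chip and day from
#' bright-field alone -> post-process into longitudinal features ->
#' normalize, fit dose-response curves and compare the endpoint and
#' baseline-change approaches. Writes a JSON report, the longitudinal CSV
#' and a stage-timing log under `out_dir`. Fully seeded: the same
#' configuration and seed reproduce identical outputs.
#'
#' @param config A [pipeline_config()] (or path to its YAML file).
#' @param out_dir Output directory.
#' @param seed Overrides the simulation seed when given.
#' @param verbose Print stage progress.
#' @return List with `records`, `comparison`, `models` and `report_path`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pipeline"), seed = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- load_pipeline_config(config)
  cfg <- config$sim
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    validate_sim_config(cfg)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list(); tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))

  t0 <- tic()
  n <- config$n_chips
  chip_ids <- sprintf("chip%03d", seq_len(n))
  chip_dose <- stats::setNames(rep_len(config$doses, n), chip_ids)
  n_test <- max(1L, round(0.1 * n)); n_val <- max(1L, round(0.2 * n))
  ord <- with_seed(derive_seed(cfg$seed, "split"), sample.int(n))
  split_of <- rep("train", n)
  split_of[ord[seq_len(n_test)]] <- "test"
  split_of[ord[n_test + seq_len(n_val)]] <- "val"
  names(split_of) <- chip_ids

  images <- list()
  for (cid in chip_ids) {
    images[[cid]] <- list()
    for (d in config$days) {
      pop <- generate_population(cfg, day = d, chip_id = cid)
      if (d > config$treat_day && chip_dose[cid] > 0)
        pop <- apply_drug(pop, chip_dose[cid], cfg)
      images[[cid]][[as.character(d)]] <- render_channels(pop, cfg)
    }
  }
  timings$simulate <- tic() - t0; say("simulated %d chips (%.1fs)", n, timings$simulate)

  t0 <- tic()
  endpoint <- as.character(max(config$days))
  mk_pairs <- function(ids, ch)
    lapply(ids, function(cid) list(images[[cid]][[endpoint]]$bf,
                                   images[[cid]][[endpoint]][[ch]]))
  train_ids <- chip_ids[split_of == "train"]
  val_ids <- chip_ids[split_of == "val"]
  models <- list(
    DAPI = train_translation(mk_pairs(train_ids, "dapi"),
                             mk_pairs(val_ids, "dapi"), "DAPI",
                             config$hyper, verbose = verbose),
    TRITC = train_translation(mk_pairs(train_ids, "tritc"),
                              mk_pairs(val_ids, "tritc"), "TRITC",
                              config$hyper, verbose = verbose))
  timings$train <- tic() - t0; say("trained both channels (%.1fs)", timings$train)

  t0 <- tic()
  pred <- list()
  for (cid in chip_ids) {
    pred[[cid]] <- lapply(images[[cid]], function(day_imgs) list(
      dapi = predict_fluorescence(models$DAPI, day_imgs$bf),
      tritc = predict_fluorescence(models$TRITC, day_imgs$bf)))
  }
  timings$predict <- tic() - t0; say("predicted all chips/days (%.1fs)", timings$predict)

  t0 <- tic()
  records <- longitudinal_records(pred, chip_dose, config$segment)
  comparison <- compare_approaches(records)
  timings$analyze <- tic() - t0

  records_path <- file.path(out_dir, "longitudinal_records.csv")
  utils::write.csv(records, records_path, row.names = FALSE)
  fits <- lapply(comparison[setdiff(names(comparison), "ranking")], function(o)
    list(ic50 = o$fit$ic50 %||% NA, hill = o$fit$hill %||% NA,
         bottom = o$fit$bottom %||% NA, top = o$fit$top %||% NA,
         auc = o$fit$auc %||% NA, converged = isTRUE(o$fit$converged),
         sensitivity = o$sensitivity,
         dynamic_range_pct = o$dynamic_range_pct))
  report <- list(seed = cfg$seed, n_chips = n, days = config$days,
                 doses = config$doses, split = as.list(table(split_of)),
                 best_val_mse = list(DAPI = models$DAPI$best_val_mse,
                                     TRITC = models$TRITC$best_val_mse),
                 approaches = fits,
                 ranking = comparison$ranking,
                 timings_s = lapply(timings, round, 2))
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(records = records, comparison = comparison, models = models,
                 report_path = report_path, records_path = records_path,
                 report = report))
}
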