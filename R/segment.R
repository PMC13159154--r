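# Object segmentation, single-cell/aggregate classification and viability
# metrics. The segmentation backbone is: Otsu thresholding on the intensity
# histogram, 8-connected component labeling, removal of sub-minimum-area
# components (artifact removal), then per-object measurement.

#' Otsu thresholding (two- or three-class)
#'
#' Computes the threshold(s) that maximize the between-class variance of
#' the 256-bin intensity histogram. The two-class variant returns one
#' threshold; the three-class variant returns two ordered thresholds found
#' by exhaustive search over all cut pairs (vectorized over the second
#' cut). Thresholds are returned on the intensity scale of the input, at
#' bin boundaries, so scaling the image scales the thresholds within one
#' bin width.
#'
#' For TRITC-like images the convention used downstream is that the
#' "positive" class of the three-class split is the top (brightest) class;
#' the middle class is treated as background haze.
#'
#' @param img A [chip_image()] or numeric matrix.
#' @param n_classes 2 or 3.
#' @param n_bins Histogram resolution (default 256).
#' @return Numeric vector of 1 (`n_classes = 2`) or 2 ordered thresholds.
#' @export
otsu_threshold <- function(img, n_classes = 2L, n_bins = 256L) {
  if (!n_classes %in% c(2L, 3L)) stopf("`n_classes` must be 2 or 3")
  px <- as.numeric(as_pixels(img))
  lo <- min(px); hi <- max(px)
  if (length(unique(px)) < n_classes || hi <= lo)
    stopf("degenerate histogram: image has fewer than %d distinct gray levels",
          n_classes)
  h <- tabulate(pmin(pmax(floor((px - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  edges <- lo + (hi - lo) * (seq_len(n_bins) / n_bins)  # upper bin edges
  mids <- lo + (hi - lo) * ((seq_len(n_bins) - 0.5) / n_bins)
  cw <- cumsum(p)                       # class weight up to bin t
  cm <- cumsum(p * mids)                # class first moment up to bin t
  total_mean <- cm[n_bins]
  if (n_classes == 2L) {
    w0 <- cw; w1 <- 1 - cw
    m0 <- cm / pmax(w0, .Machine$double.eps)
    m1 <- (total_mean - cm) / pmax(w1, .Machine$double.eps)
    sb <- w0 * w1 * (m0 - m1)^2
    sb[w0 == 0 | w1 == 0] <- -Inf
    t <- which.max(sb[-n_bins])
    return(edges[t])
  }
  # three classes: maximize over cut pairs (t1 < t2)
  best <- -Inf; best_t <- c(NA_integer_, NA_integer_)
  for (t1 in seq_len(n_bins - 2L)) {
    w0 <- cw[t1]
    if (w0 == 0) next
    m0 <- cm[t1] / w0
    t2 <- (t1 + 1L):(n_bins - 1L)
    w1 <- cw[t2] - w0
    w2 <- 1 - cw[t2]
    m1 <- (cm[t2] - cm[t1]) / pmax(w1, .Machine$double.eps)
    m2 <- (total_mean - cm[t2]) / pmax(w2, .Machine$double.eps)
    sb <- w0 * (m0 - total_mean)^2 + w1 * (m1 - total_mean)^2 +
      w2 * (m2 - total_mean)^2
    sb[w1 == 0 | w2 == 0] <- -Inf
    j <- which.max(sb)
    if (sb[j] > best) { best <- sb[j]; best_t <- c(t1, t2[j]) }
  }
  edges[best_t]
}

#' 8-connected component labeling
#'
#' Labels connected foreground regions of a logical mask using
#' 8-connectivity; labels are dense `1..N` in raster order of each
#' component's first pixel.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (!length(idx)) return(lab)
  id_of <- integer(H * W)
  id_of[idx] <- seq_along(idx)
  edge_pairs <- function(di, dj) {
    i <- ((idx - 1L) %% H) + 1L
    j <- ((idx - 1L) %/% H) + 1L
    ok <- i + di >= 1L & i + di <= H & j + dj >= 1L & j + dj <= W
    nb <- idx[ok] + di + dj * H
    keep <- mask[nb]
    cbind(id_of[idx[ok][keep]], id_of[nb[keep]])
  }
  edges <- rbind(edge_pairs(1L, 0L), edge_pairs(0L, 1L),
                 edge_pairs(1L, 1L), edge_pairs(-1L, 1L))
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  first <- tapply(seq_along(idx), comp, min)
  dense <- match(comp, comp[sort(first)])
  lab[idx] <- dense
  lab
}

# Remove components smaller than min_area; relabel densely.
remove_small_components <- function(lab, min_area_px) {
  if (min_area_px <= 1L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_area_px)
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    keep <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
  }
  lab
}

# Per-object shape measurements from a label matrix. Centroids are 0-based
# (x, y); eccentricity from central second moments; solidity via convex
# hull area; perimeter as the count of foreground pixels with a
# 4-neighbour outside the object.
object_shape_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(object_id = integer(), area_px = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      eccentricity = numeric(), solidity = numeric(),
                      perimeter_px = numeric()))
  }
  H <- nrow(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  x <- ((idx - 1L) %/% H)      # 0-based
  y <- ((idx - 1L) %% H)
  area <- tabulate(l, n)
  sx <- rowsum(x, l)[, 1]; sy <- rowsum(y, l)[, 1]
  cx <- sx / area; cy <- sy / area
  dx <- x - cx[l]; dy <- y - cy[l]
  mxx <- rowsum(dx^2, l)[, 1] / area + 1 / 12
  myy <- rowsum(dy^2, l)[, 1] / area + 1 / 12
  mxy <- rowsum(dx * dy, l)[, 1] / area
  tr <- mxx + myy
  det2 <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + det2) / 2; l2 <- (tr - det2) / 2
  ecc <- sqrt(pmax(1 - l2 / pmax(l1, .Machine$double.eps), 0))
  # perimeter: foreground pixels adjacent (4-conn) to background/other label
  padded <- matrix(0L, H + 2L, ncol(lab) + 2L)
  padded[2:(H + 1L), 2:(ncol(lab) + 1L)] <- lab
  core <- padded[2:(H + 1L), 2:(ncol(lab) + 1L)]
  boundary <- core > 0L & (padded[1:H, 2:(ncol(lab) + 1L)] != core |
                           padded[3:(H + 2L), 2:(ncol(lab) + 1L)] != core |
                           padded[2:(H + 1L), 1:ncol(lab)] != core |
                           padded[2:(H + 1L), 3:(ncol(lab) + 2L)] != core)
  per <- tabulate(core[boundary], n)
  sol <- vapply(seq_len(n), function(k) {
    sel <- l == k
    if (sum(sel) < 3L) return(1)
    pts <- cbind(x[sel], y[sel])
    hull <- grDevices::chull(pts)
    hp <- pts[hull, , drop = FALSE]
    a <- abs(sum(hp[, 1] * hp[c(2:nrow(hp), 1), 2] -
                 hp[c(2:nrow(hp), 1), 1] * hp[, 2])) / 2
    min(1, sum(sel) / max(a + sum(sel) / 2, 1))  # pixelated hull area guard
  }, numeric(1))
  data.frame(object_id = seq_len(n), area_px = area, centroid_x = cx,
             centroid_y = cy, eccentricity = ecc, solidity = sol,
             perimeter_px = per)
}

#' Segment objects above a threshold
#'
#' Thresholds the image, labels 8-connected components, removes components
#' below the minimum area ("artifact removal") and measures each remaining
#' object: area, centroid, eccentricity, solidity, perimeter, and sum/mean
#' intensity on the segmented image plus any extra registered channels.
#'
#' @param img A [chip_image()] or matrix used both for thresholding and as
#'   the primary intensity channel.
#' @param threshold Numeric threshold; pixels strictly above are
#'   foreground. Use [otsu_threshold()] to derive it.
#' @param min_area_px Minimum object area kept (default 10 px).
#' @param channels Optional named list of co-registered images measured
#'   per object (e.g. `list(tritc = ...)`).
#' @return List with `labels` (integer matrix) and `objects` (data.frame,
#'   one row per object).
#' @export
segment_objects <- function(img, threshold, min_area_px = 20L,
                            channels = list()) {
  px <- as_pixels(img)
  lab <- remove_small_components(label_components(px > threshold), min_area_px)
  obj <- object_shape_stats(lab)
  n <- max(lab)
  meas <- c(list(intensity = px), lapply(channels, as_pixels))
  for (nm in names(meas)) {
    if (n > 0L) {
      m <- meas[[nm]]
      if (!identical(dim(m), dim(px))) stopf("channel `%s` shape mismatch", nm)
      s <- rowsum(m[lab > 0L], lab[lab > 0L])[, 1]
      obj[[paste0("sum_", nm)]] <- s
      obj[[paste0("mean_", nm)]] <- s / obj$area_px
    } else {
      obj[[paste0("sum_", nm)]] <- numeric(0)
      obj[[paste0("mean_", nm)]] <- numeric(0)
    }
  }
  list(labels = lab, objects = obj)
}

#' Classify objects into single cells and aggregates
#'
#' Class is determined solely by area: objects with
#' `area_px >= aggregate_area_cutoff_px` are aggregates (ties count as
#' aggregates).
#'
#' @param objects Object table from [segment_objects()].
#' @param aggregate_area_cutoff_px Area cutoff in pixels (default 200).
#' @return List with `objects` (a `class` column added) and
#'   `pct_aggregates` (percent of objects classified aggregate; `NA` when
#'   there are no objects).
#' @export
classify_objects <- function(objects, aggregate_area_cutoff_px = 200L) {
  cls <- ifelse(objects$area_px >= aggregate_area_cutoff_px,
                "aggregate", "single_cell")
  objects$class <- cls
  pct <- if (nrow(objects)) 100 * mean(cls == "aggregate") else NA_real_
  list(objects = objects, pct_aggregates = pct)
}

#' Viability metrics from Hoechst and EthD-2 masks
#'
#' The dead area is the EthD-2-positive area within the Hoechst (object)
#' mask; the viable area is the Hoechst mask area minus the dead area.
#' `viability_pct` normalizes the viable area to the Hoechst mask area;
#' `viable_to_total_ratio` normalizes to `total_area` (the sum area of all
#' segmented objects, defaulting to the Hoechst area). An empty Hoechst
#' mask yields `NA` metrics with `qc_flag = "empty_hoechst"` rather than
#' silent NaNs.
#'
#' @param hoechst_mask,ethd2_mask Logical matrices of identical shape.
#' @param total_area Optional denominator for `viable_to_total_ratio`.
#' @return List: `viable_area`, `dead_area`, `viability_pct`,
#'   `viable_to_total_ratio`, `qc_flag` (`NA` when clean).
#' @export
compute_viability <- function(hoechst_mask, ethd2_mask, total_area = NULL) {
  stopifnot(is.matrix(hoechst_mask), is.matrix(ethd2_mask))
  if (!identical(dim(hoechst_mask), dim(ethd2_mask)))
    stopf("masks must share shape")
  h_area <- sum(hoechst_mask)
  if (h_area == 0) {
    return(list(viable_area = NA_real_, dead_area = NA_real_,
                viability_pct = NA_real_, viable_to_total_ratio = NA_real_,
                qc_flag = "empty_hoechst"))
  }
  dead <- sum(hoechst_mask & ethd2_mask)
  viable <- h_area - dead
  total <- total_area %||% h_area
  list(viable_area = viable, dead_area = dead,
       viability_pct = 100 * viable / h_area,
       viable_to_total_ratio = 100 * viable / total, qc_flag = NA_character_)
}

#' Default segmentation parameters
#'
#' @param min_area_px Minimum object area kept after labeling.
#' @param aggregate_area_cutoff_px Single-cell vs aggregate cutoff.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma.
#' @param hoechst_threshold Fixed Hoechst threshold; `NULL` (default) uses
#'   two-class Otsu.
#' @param min_dynamic_range Minimum intensity range (fraction of full
#'   scale) an image must span for Otsu masking to be meaningful; images
#'   below it (e.g. a stain channel with no labeled cells, just detector
#'   noise) are treated as signal-free rather than thresholded.
#' @return Parameter list consumed by [chip_features()] and
#'   [postprocess_channel()].
#' @export
segment_params <- function(min_area_px = 10L, aggregate_area_cutoff_px = 200L,
                           smooth_sigma_px = 0.5, hoechst_threshold = NULL,
                           min_dynamic_range = 0.05) {
  list(min_area_px = as.integer(min_area_px),
       aggregate_area_cutoff_px = as.integer(aggregate_area_cutoff_px),
       smooth_sigma_px = smooth_sigma_px,
       hoechst_threshold = hoechst_threshold,
       min_dynamic_range = min_dynamic_range)
}

#' Per-chip feature record
#'
#' Assembles the full per-chip measurement record from co-registered
#' bright-field, DAPI (Hoechst) and TRITC (EthD-2) images: object counts
#' and classes from the Hoechst mask, sum/mean object areas and
#' intensities, mask areas, viable area and viability percent.
#' `normalized_viable_area` (percent of vehicle) is computed later against
#' vehicle controls via [normalize_to_vehicle()].
#'
#' @param bf,dapi,tritc [chip_image()]s (BF optional, `NULL` allowed).
#' @param params A [segment_params()] list.
#' @param atp_signal Optional simulated ATP readout carried through.
#' @return One-row data.frame of chip features, with the label matrix and
#'   masks attached as attributes.
#' @export
chip_features <- function(bf, dapi, tritc, params = segment_params(),
                          atp_signal = NA_real_) {
  dpx <- gaussian_smooth(as_pixels(dapi), params$smooth_sigma_px)
  tpx <- gaussian_smooth(as_pixels(tritc), params$smooth_sigma_px)
  thr_d <- params$hoechst_threshold %||% otsu_threshold(dpx, 2L)
  thr_t <- if (diff(range(tpx)) < (params$min_dynamic_range %||% 0)) Inf else
    tryCatch(otsu_threshold(tpx, 3L)[2], error = function(e) Inf)
  hmask_lab <- remove_small_components(label_components(dpx > thr_d),
                                       params$min_area_px)
  hmask <- hmask_lab > 0L
  tmask <- remove_small_components(label_components(tpx > thr_t),
                                   params$min_area_px) > 0L
  extra <- list(tritc = as_pixels(tritc))
  if (!is.null(bf)) extra$bf <- as_pixels(bf)
  seg <- segment_objects(as_pixels(dapi), thr_d, params$min_area_px,
                         channels = extra)
  cls <- classify_objects(seg$objects, params$aggregate_area_cutoff_px)
  viab <- compute_viability(hmask, tmask)
  meta <- if (inherits(dapi, "chip_image")) dapi else NULL
  out <- data.frame(
    chip_id = if (!is.null(meta)) meta$chip_id else NA_character_,
    day = if (!is.null(meta)) meta$day else NA_integer_,
    n_objects = nrow(cls$objects),
    pct_aggregates = cls$pct_aggregates,
    mean_object_area = if (nrow(cls$objects)) mean(cls$objects$area_px) else NA_real_,
    sum_object_area = sum(cls$objects$area_px),
    mean_eccentricity = if (nrow(cls$objects)) mean(cls$objects$eccentricity) else NA_real_,
    mean_solidity = if (nrow(cls$objects)) mean(cls$objects$solidity) else NA_real_,
    hoechst_mask_area = sum(hmask),
    ethd2_mask_area_within = viab$dead_area,
    sum_dapi_intensity = sum(as_pixels(dapi)[hmask]),
    sum_tritc_intensity = sum(as_pixels(tritc)[hmask & tmask]),
    viable_area = viab$viable_area,
    viability_pct = viab$viability_pct,
    viable_to_total_ratio = viab$viable_to_total_ratio,
    atp_signal = atp_signal,
    qc_flag = viab$qc_flag,
    stringsAsFactors = FALSE)
  attr(out, "labels") <- seg$labels
  attr(out, "hoechst_mask") <- hmask
  attr(out, "ethd2_mask") <- tmask
  out
}
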