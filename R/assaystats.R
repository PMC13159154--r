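# Assay-quality ranking (Z'-factor), vehicle normalization, 4PL
# dose-response fitting, AUC and readout correlation.

#' Control-group summary statistics
#'
#' @param pos_values,neg_values Numeric vectors of the metric for positive
#'   (maximum effect) and negative (vehicle) control chips; each needs at
#'   least 2 values.
#' @return List with `mu_pos`, `sd_pos`, `mu_neg`, `sd_neg`, `n_pos`,
#'   `n_neg` (class `control_stats`).
#' @export
control_stats <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L)
    stopf("each control group needs at least 2 values")
  structure(list(mu_pos = mean(pos_values), sd_pos = stats::sd(pos_values),
                 mu_neg = mean(neg_values), sd_neg = stats::sd(neg_values),
                 n_pos = length(pos_values), n_neg = length(neg_values)),
            class = "control_stats")
}

#' Z'-factor
#'
#' Screening-assay quality statistic
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mu_pos - mu_neg|`. Values near 1
#' indicate excellent separation of the control distributions; values at
#' or below 0 indicate an unusable assay window. The formula is symmetric
#' in the two control labels.
#'
#' @param stats A `control_stats` object, or `mu_pos` as a number.
#' @param sd_pos,mu_neg,sd_neg Used when the first argument is numeric.
#' @return The Z'-factor (may be negative; 1 is the supremum).
#' @export
z_prime <- function(stats, sd_pos = NULL, mu_neg = NULL, sd_neg = NULL) {
  if (inherits(stats, "control_stats")) {
    mu_p <- stats$mu_pos; s_p <- stats$sd_pos
    mu_n <- stats$mu_neg; s_n <- stats$sd_neg
  } else {
    mu_p <- stats; s_p <- sd_pos; mu_n <- mu_neg; s_n <- sd_neg
  }
  if (any(c(s_p, s_n) < 0)) stopf("standard deviations must be >= 0")
  if (mu_p == mu_n) stopf("zero dynamic range: control means are equal")
  1 - 3 * (s_p + s_n) / abs(mu_p - mu_n)
}

#' Rank imaging metrics by Z'-factor
#'
#' Computes a Z'-factor per numeric metric column from labeled control
#' chips and returns the metrics sorted by decreasing Z' (ties broken
#' alphabetically). Metrics whose control means coincide get `Z' = -Inf`
#' (no assay window).
#'
#' @param feature_table Data.frame with one row per control chip.
#' @param group_col Name of the column holding the control labels.
#' @param pos_label,neg_label Labels of the positive / negative controls.
#' @param metrics Metric column names; defaults to all numeric columns.
#' @return Data.frame `(metric, z_prime)` sorted by decreasing Z'.
#' @export
rank_metrics <- function(feature_table, group_col, pos_label, neg_label,
                         metrics = NULL) {
  g <- feature_table[[group_col]]
  if (is.null(g)) stopf("column `%s` not found", group_col)
  metrics <- metrics %||% names(feature_table)[vapply(feature_table, is.numeric,
                                                      logical(1))]
  metrics <- setdiff(metrics, group_col)
  zp <- vapply(metrics, function(m) {
    pos <- feature_table[[m]][g == pos_label]
    neg <- feature_table[[m]][g == neg_label]
    pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
    if (length(pos) < 2L || length(neg) < 2L) return(NA_real_)
    tryCatch(z_prime(control_stats(pos, neg)), error = function(e) -Inf)
  }, numeric(1))
  out <- data.frame(metric = metrics, z_prime = zp, stringsAsFactors = FALSE)
  out <- out[order(-out$z_prime, out$metric), ]
  rownames(out) <- NULL
  out
}

#' Normalize values to vehicle control
#'
#' Expresses values as percent of the vehicle-control mean (vehicle mean
#' maps to 100 percent); percent inhibition is `100 -` the normalized
#' value.
#'
#' @param values Numeric vector to normalize.
#' @param vehicle_values Vehicle-control measurements of the same metric.
#' @return Numeric vector, percent of vehicle.
#' @export
normalize_to_vehicle <- function(values, vehicle_values) {
  m <- mean(vehicle_values)
  if (!is.finite(m) || m == 0) stopf("vehicle mean is zero or undefined")
  100 * values / m
}

fourpl_log10 <- function(ld, bottom, top, lic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (ld - lic50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on the log10-dose axis,
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10 d - log10 IC50)))`,
#' with the Hill slope signed so that `hill > 0` means viability decreases
#' with dose. Fitting uses Levenberg-Marquardt (minpack.lm) from a grid of
#' starting values; bounds are `bottom >= 0`, `top <= 120` (percent-of-
#' vehicle scale). Vehicle (dose 0) responses should be excluded before
#' fitting; they anchor the normalization, not the log-dose curve. The fit
#' is flagged non-converged (`ic50 = NA`, printed as "n.d.") when the 4PL
#' does not beat a flat model (extra-sum-of-squares F test at p < 0.05
#' when residual degrees of freedom allow, otherwise a 10 percent residual
#' reduction), when the fitted dynamic range `top - bottom` is under 5
#' percentage points, or when the IC50 lands more than two decades outside
#' the tested dose range — flat or pure-noise responses must not produce
#' spurious IC50s.
#'
#' @param doses Positive doses in uM (>= 4 distinct values required).
#' @param responses Responses in percent of vehicle, same length.
#' @return A `dose_response` object: list with `bottom`, `top`, `ic50`,
#'   `hill`, `auc`, `converged`, `doses`, `responses`, `sse`.
#' @export
fit_dose_response <- function(doses, responses) {
  if (length(doses) != length(responses)) stopf("length mismatch")
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (any(doses <= 0)) stopf("doses must be positive on the log axis")
  if (length(unique(doses)) < 4L) stopf("need >= 4 distinct positive doses")
  ld <- log10(doses)
  dat <- data.frame(ld = ld, y = responses)
  sse_flat <- sum((responses - mean(responses))^2)
  lo <- c(bottom = 0, top = 0, lic50 = min(ld) - 2, hill = 0.05)
  up <- c(bottom = 120, top = 120, lic50 = max(ld) + 2, hill = 8)
  starts <- expand.grid(
    lic50 = stats::quantile(ld, c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(bottom = max(min(responses), 0),
               top = min(max(responses), 120),
               lic50 = starts$lic50[i], hill = starts$hill[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ fourpl_log10(ld, bottom, top, lic50, hill),
                        data = dat, start = st, lower = lo, upper = up,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  out <- list(doses = doses, responses = responses, bottom = NA_real_,
              top = NA_real_, ic50 = NA_real_, hill = NA_real_,
              auc = NA_real_, converged = FALSE, sse = NA_real_)
  class(out) <- "dose_response"
  if (is.null(best)) return(out)
  cf <- stats::coef(best$fit)
  ic50 <- 10^cf[["lic50"]]
  in_range <- ic50 >= min(doses) / 100 && ic50 <= max(doses) * 100
  n <- length(responses)
  improved <- if (sse_flat == 0) {
    FALSE                                  # perfectly flat data: no signal
  } else if (n > 5L) {
    f <- ((sse_flat - best$sse) / 3) / (best$sse / (n - 4L))
    best$sse == 0 || (f > 0 && stats::pf(f, 3, n - 4L, lower.tail = FALSE) < 0.05)
  } else {
    best$sse < 0.9 * sse_flat
  }
  out$sse <- best$sse
  out$bottom <- cf[["bottom"]]; out$top <- cf[["top"]]; out$hill <- cf[["hill"]]
  if (improved && in_range && cf[["top"]] - cf[["bottom"]] > 5) {
    out$ic50 <- ic50
    out$converged <- TRUE
    out$auc <- compute_auc(out)
  }
  out
}

#' @export
print.dose_response <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<dose_response> IC50 = %.4g uM | hill = %.2f | bottom = %.1f | top = %.1f | AUC = %.1f\n",
                x$ic50, x$hill, x$bottom, x$top, x$auc))
  } else {
    cat("<dose_response> IC50 = n.d. (fit did not converge)\n")
  }
  invisible(x)
}

#' Normalized area under the dose-response curve
#'
#' Trapezoidal integral of the normalized response over log10 dose,
#' divided by the log-dose span, so a constant 100 percent response gives
#' AUC 100 and a constant 0 gives 0, comparable across drugs with
#' different dose ranges. Accepts either a converged [fit_dose_response()]
#' object (integrates the fitted curve over the tested dose range on a
#' fine grid) or raw `(doses, responses)` points.
#'
#' @param fit_or_doses A `dose_response` object or a vector of positive
#'   doses.
#' @param responses Responses when doses are supplied directly.
#' @return AUC on the 0-100 scale of the responses.
#' @export
compute_auc <- function(fit_or_doses, responses = NULL) {
  if (inherits(fit_or_doses, "dose_response")) {
    f <- fit_or_doses
    ld <- seq(log10(min(f$doses)), log10(max(f$doses)), length.out = 101)
    y <- fourpl_log10(ld, f$bottom, f$top, log10(f$ic50 %||% NA), f$hill)
  } else {
    doses <- fit_or_doses
    if (any(doses <= 0)) stopf("doses must be positive")
    o <- order(doses)
    ld <- log10(doses[o]); y <- responses[o]
  }
  span <- max(ld) - min(ld)
  if (span == 0) return(mean(y))
  sum(diff(ld) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / span
}

#' Correlate two chip-level readouts
#'
#' Standard Pearson correlation between paired readouts (e.g. imaging
#' viable area vs ATP luminescence across chips).
#'
#' @param x,y Paired numeric vectors.
#' @return List with `pearson_r`, `n` and the t-test `p_value`.
#' @export
correlate_readouts <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: a readout has zero variance")
  ct <- stats::cor.test(x, y)
  list(pearson_r = unname(ct$estimate), n = length(x),
       p_value = ct$p.value)
}

#' Percent-inhibition matrix
#'
#' Builds the drug-by-dose percent-inhibition matrix used for heatmap
#' export: each cell is `100 - mean(normalized response)` for that (drug,
#' dose), with responses normalized to each drug's vehicle chips.
#'
#' @param feature_table Data.frame with `drug`, `dose` and the metric.
#' @param metric Metric column name.
#' @return Numeric matrix, rows = drugs, columns = sorted doses.
#' @export
inhibition_matrix <- function(feature_table, metric) {
  drugs <- unique(feature_table$drug)
  doses <- sort(unique(feature_table$dose[feature_table$dose > 0]))
  m <- matrix(NA_real_, length(drugs), length(doses),
              dimnames = list(drugs, as.character(doses)))
  for (dr in drugs) {
    sub <- feature_table[feature_table$drug == dr, ]
    veh <- sub[[metric]][sub$dose == 0]
    for (j in seq_along(doses)) {
      v <- sub[[metric]][sub$dose == doses[j]]
      if (length(v)) m[dr, j] <- 100 - mean(normalize_to_vehicle(v, veh))
    }
  }
  m
}
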