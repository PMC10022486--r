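#' Filter an NG86 table to a clean Ks sample
#'
#' Retains `status == "ok"` rows with `min <= Ks <= max`; saturated and
#' undefined estimates are excluded and counted, never silently dropped.
#'
#' @param ks_table Result of [ks_batch()].
#' @param min,max Ks retention bounds (defaults 0.01 and 5: near-zero
#'   allelic pairs and the saturated tail are removed).
#' @return A list of class `ks_sample`: `values` (retained Ks), bounds, and
#'   `dropped` (named counts per reason).
#' @export
filter_ks <- function(ks_table, min = 0.01, max = 5) {
  if (min >= max) stopf("filter bounds must satisfy min < max")
  ok <- ks_table$status == "ok" & !is.na(ks_table$Ks)
  in_bounds <- ok & ks_table$Ks >= min & ks_table$Ks <= max
  dropped <- c(
    not_ok = sum(!ok),
    below_min = sum(ok & ks_table$Ks < min),
    above_max = sum(ok & ks_table$Ks > max)
  )
  log_stage("filter_ks", min = min, max = max,
            retained = sum(in_bounds), dropped = sum(dropped))
  structure(list(values = ks_table$Ks[in_bounds],
                 filter_min = min, filter_max = max, dropped = dropped),
            class = "ks_sample")
}

#' Gaussian kernel density model of a Ks distribution
#'
#' Fits a Gaussian KDE on a uniform grid spanning the sample's filter
#' bounds, renormalized to integrate to 1 over the grid (trapezoid rule).
#' The automatic bandwidth is Silverman's rule of thumb.
#'
#' @param sample A `ks_sample` from [filter_ks()], or a numeric vector
#'   (bounds then default to its range).
#' @param bandwidth Kernel bandwidth, or `"auto"` for Silverman's rule.
#' @param n Grid size (default 512).
#' @return A list of class `ks_density`: `grid`, `density`, `bandwidth`.
#' @export
fit_density <- function(sample, bandwidth = "auto", n = 512L) {
  if (inherits(sample, "ks_sample")) {
    x <- sample$values; lo <- sample$filter_min; hi <- sample$filter_max
  } else {
    x <- as.numeric(sample); lo <- base::min(x); hi <- base::max(x)
  }
  if (length(x) < 50L)
    stopf("density fit needs >= 50 retained Ks values, got %d", length(x))
  if (n < 512L) n <- 512L
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(x) else {
    assert_scalar_num(bandwidth, "bandwidth", positive = TRUE)
    bandwidth
  }
  if (hi <= lo) { lo <- lo - 4 * bw; hi <- hi + 4 * bw }
  d <- stats::density(x, bw = bw, n = n, from = lo, to = hi, kernel = "gaussian")
  dens <- d$y
  area <- trapz(d$x, dens)
  if (area <= 0) stopf("degenerate density (zero mass on the grid)")
  log_stage("fit_density", n_values = length(x), bandwidth = bw)
  structure(list(grid = d$x, density = dens / area, bandwidth = bw),
            class = "ks_density")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Locate peaks of a Ks density model
#'
#' Finds local maxima of the density with topographic prominence at least
#' `min_prominence` (expressed as a fraction of the maximum density).
#' Prominence of a peak is its height minus the higher of the two saddle
#' minima separating it from higher terrain (the global maximum is measured
#' against the global minimum). Peaks are returned sorted by height
#' descending; exact ties break toward lower Ks.
#'
#' @param model A `ks_density` from [fit_density()].
#' @param min_prominence Prominence floor as a fraction of max density
#'   (default 0.05).
#' @return A data.frame with columns `mode`, `height`, `prominence`
#'   (possibly zero rows).
#' @export
find_peaks <- function(model, min_prominence = 0.05) {
  y <- model$density; x <- model$grid
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (n >= 2L && y[1L] > y[2L]) is_max <- c(1L, is_max)
  if (n >= 2L && y[n] > y[n - 1L]) is_max <- c(is_max, n)
  if (!length(is_max) || diff(range(y)) == 0)
    return(data.frame(mode = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    left <- if (any(y[seq_len(i - 1)] > h)) {
      j <- max(which(y[seq_len(i - 1)] > h))
      base::min(y[j:i])
    } else if (i > 1L) base::min(y[1:i]) else h
    right <- if (any(y[seq(i, n)] > h)) {
      j <- i - 1L + base::min(which(y[seq(i, n)] > h))
      base::min(y[i:j])
    } else if (i < n) base::min(y[i:n]) else h
    if (left == h && right == h) h - base::min(y)  # global max
    else h - base::max(left[left < h], right[right < h], base::min(y) * 0)
  }, numeric(1))
  keep <- prom >= min_prominence * base::max(y)
  out <- data.frame(mode = x[is_max][keep], height = y[is_max][keep],
                    prominence = prom[keep])
  out[order(-out$height, out$mode), , drop = FALSE]
}

#' Calibrate a per-year synonymous substitution rate from an ortholog peak
#'
#' Applies `r = Ks / (2 T)` at both ends of a calibration divergence-time
#' interval: `r_min = ks / (2 t_max)`, `r_max = ks / (2 t_min)`.
#'
#' @param ks_ortho_peak Ks mode of the ortholog distribution (> 0).
#' @param t_min,t_max Calibration divergence-time bounds in years,
#'   `0 < t_min < t_max`.
#' @return A list of class `rate_calibration`: `ks_ortho_peak`, `t_min`,
#'   `t_max`, `r_min`, `r_max` (substitutions per synonymous site per year).
#' @examples
#' calibrate_rate(1.4, 74.5e6, 106.9e6) # r in [6.55e-9, 9.40e-9]
#' @export
calibrate_rate <- function(ks_ortho_peak, t_min, t_max) {
  assert_scalar_num(ks_ortho_peak, "ks_ortho_peak", positive = TRUE)
  assert_scalar_num(t_min, "t_min", positive = TRUE)
  assert_scalar_num(t_max, "t_max", positive = TRUE)
  if (t_min >= t_max) stopf("t_min must be < t_max")
  structure(list(ks_ortho_peak = ks_ortho_peak, t_min = t_min, t_max = t_max,
                 r_min = ks_ortho_peak / (2 * t_max),
                 r_max = ks_ortho_peak / (2 * t_min)),
            class = "rate_calibration")
}

#' Date a whole-genome duplication from its Ks peak
#'
#' `Divergence time = Ks / (2 r)` applied at both rate bounds:
#' `age_min = ks / (2 r_max)`, `age_max = ks / (2 r_min)`. Ages are in
#' years; `age_min_my`/`age_max_my` give million-year values rounded to 2
#' decimals for display.
#'
#' @param ks_wgd_peak Ks mode of the paralog (WGD) distribution (>= 0).
#' @param cal A `rate_calibration` from [calibrate_rate()], or a list with
#'   `r_min` and `r_max`.
#' @return A list of class `wgd_age`: `ks_wgd_peak`, `age_min`, `age_max`
#'   (years), `age_min_my`, `age_max_my`.
#' @examples
#' cal <- list(r_min = 6.55e-9, r_max = 9.39e-9)
#' date_wgd(1.25, cal) # roughly 66.6 to 95.4 million years
#' @export
date_wgd <- function(ks_wgd_peak, cal) {
  assert_scalar_num(ks_wgd_peak, "ks_wgd_peak")
  if (ks_wgd_peak < 0) stopf("ks_wgd_peak must be >= 0")
  if (is.null(cal$r_min) || is.null(cal$r_max) || cal$r_min > cal$r_max)
    stopf("`cal` must carry rate bounds r_min <= r_max")
  age_min <- ks_wgd_peak / (2 * cal$r_max)
  age_max <- ks_wgd_peak / (2 * cal$r_min)
  structure(list(ks_wgd_peak = ks_wgd_peak,
                 age_min = age_min, age_max = age_max,
                 age_min_my = round(age_min / 1e6, 2),
                 age_max_my = round(age_max / 1e6, 2)),
            class = "wgd_age")
}

#' @export
print.wgd_age <- function(x, ...) {
  cat(sprintf("WGD dating: Ks peak %.4g -> %.2f-%.2f MYA\n",
              x$ks_wgd_peak, x$age_min_my, x$age_max_my))
  invisible(x)
}

#' Ks distribution to dated WGD, in one call
#'
#' Convenience wrapper: filter an NG86 table, fit the KDE, take the most
#' prominent peak, and date it against a rate calibration.
#'
#' @param ks_table Result of [ks_batch()].
#' @param cal A `rate_calibration` (or list with `r_min`, `r_max`).
#' @param config A [pipeline_config()].
#' @return A list with `sample`, `density`, `peaks`, `age`.
#' @export
wgd_date_pipeline <- function(ks_table, cal, config = pipeline_config()) {
  sample <- filter_ks(ks_table, config$ks_filter_min, config$ks_filter_max)
  dens <- fit_density(sample, n = config$kde_n)
  peaks <- find_peaks(dens, config$peak_min_prominence)
  if (nrow(peaks) == 0L) stopf("no Ks peak found above prominence threshold")
  list(sample = sample, density = dens, peaks = peaks,
       age = date_wgd(peaks$mode[1L], cal))
}
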