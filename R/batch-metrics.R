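#' Batch denitrification time series
#'
#' Container for one batch-culture experiment: concentrations of
#' nitrate-N and nitrite-N, optionally TOC, and biomass, sampled over
#' time. The first time point defines the baselines C20 (initial
#' nitrate) and C10 (initial nitrite) used by the efficiency metrics.
#'
#' @param time_h Sampling times, hours, strictly increasing, >= 2 points.
#' @param no3 Nitrate concentrations, mg NO3-N l^-1, >= 0.
#' @param no2 Nitrite concentrations, mg NO2-N l^-1, >= 0.
#' @param biomass Biomass measurements (dry cell weight mg l^-1 or OD600).
#' @param cc0 Initial (inoculation) cell concentration, mg DCW l^-1, > 0.
#' @param toc Optional TOC concentrations, mg l^-1.
#' @param biomass_unit Either `"mg_dcw_l"` or `"od600"`, recording what
#'   `biomass` measures.
#' @return A `batch_ts`: a data frame with columns `time_h`, `no3_mg_l`,
#'   `no2_mg_l`, `toc_mg_l`, `biomass`, and attributes `cc0` and
#'   `biomass_unit`.
#' @export
#' @examples
#' batch_time_series(c(0, 5, 10), c(100, 60, 10), c(0, 30, 80),
#'                   biomass = c(20, 60, 180), cc0 = 20)
batch_time_series <- function(time_h, no3, no2, biomass = NULL, cc0,
                              toc = NULL,
                              biomass_unit = c("mg_dcw_l", "od600")) {
  biomass_unit <- match.arg(biomass_unit)
  n <- length(time_h)
  if (n < 2L) stop("at least 2 time points are required", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("`time_h` must be strictly increasing", call. = FALSE)
  for (nm in c("no3", "no2")) {
    v <- get(nm)
    if (length(v) != n) stop(sprintf("`%s` must match `time_h` in length", nm),
                             call. = FALSE)
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("`%s` must be finite and non-negative", nm), call. = FALSE)
  }
  check_positive(cc0, "cc0")
  if (is.null(biomass)) biomass <- rep(NA_real_, n)
  if (length(biomass) != n)
    stop("`biomass` must match `time_h` in length", call. = FALSE)
  if (is.null(toc)) toc <- rep(NA_real_, n)
  out <- tibble::tibble(time_h = as.numeric(time_h),
                        no3_mg_l = as.numeric(no3),
                        no2_mg_l = as.numeric(no2),
                        toc_mg_l = as.numeric(toc),
                        biomass = as.numeric(biomass))
  attr(out, "cc0") <- cc0
  attr(out, "biomass_unit") <- biomass_unit
  class(out) <- c("batch_ts", class(out))
  out
}

check_index <- function(ts, i) {
  if (length(i) < 1L || any(i != as.integer(i)) ||
      any(i < 1L) || any(i > nrow(ts)))
    stop("`i` must be valid row index/indices of the time series",
         call. = FALSE)
  as.integer(i)
}

baseline_state <- function(ts, baseline) {
  b <- check_index(ts, baseline)
  if (length(b) != 1L) stop("`baseline` must be a single index", call. = FALSE)
  list(c20 = ts$no3_mg_l[b], c10 = ts$no2_mg_l[b], t0 = ts$time_h[b])
}

#' Nitrite accumulation efficiency
#'
#' Fraction (in percent) of the nitrate consumed that has appeared as
#' nitrite: `a = (C1i - C10) / (C20 - C2i) * 100`, where C10/C20 are
#' nitrite/nitrate at the baseline time point and C1i/C2i at point `i`.
#' A value near 100% is the signature of partial denitrification
#' (nitrate reduced only as far as nitrite).
#'
#' @param ts A [batch_time_series()].
#' @param i Row index (or indices) at which to evaluate.
#' @param baseline Row index defining C10 and C20 (default: first point).
#' @return Efficiency in percent. Values above 100 (nitrite rising more
#'   than nitrate fell) are returned with a warning.
#' @export
nitrite_accumulation_efficiency <- function(ts, i, baseline = 1L) {
  stopifnot(inherits(ts, "batch_ts"))
  i <- check_index(ts, i)
  b <- baseline_state(ts, baseline)
  consumed <- b$c20 - ts$no3_mg_l[i]
  if (any(consumed <= 0))
    stop("no nitrate consumed at the requested time point (C20 <= C2i); ",
         "the accumulation ratio is undefined", call. = FALSE)
  a <- (ts$no2_mg_l[i] - b$c10) / consumed * 100
  if (any(a > 100))
    warning("nitrite accumulation efficiency exceeds 100%: nitrite rose by ",
            "more than the nitrate consumed", call. = FALSE)
  a
}

#' Nitrate removal efficiency
#'
#' Percentage of the initial nitrate removed by time point `i`:
#' `b = (C20 - C2i) / C20 * 100`.
#'
#' @inheritParams nitrite_accumulation_efficiency
#' @return Efficiency in percent, in \[0, 100\] while nitrate stays below
#'   its baseline.
#' @export
nitrate_removal_efficiency <- function(ts, i, baseline = 1L) {
  stopifnot(inherits(ts, "batch_ts"))
  i <- check_index(ts, i)
  b <- baseline_state(ts, baseline)
  if (b$c20 <= 0)
    stop("baseline nitrate concentration is zero; removal efficiency ",
         "is undefined", call. = FALSE)
  (b$c20 - ts$no3_mg_l[i]) / b$c20 * 100
}

#' Specific nitrate degradation rate
#'
#' Nitrate removed per unit time, normalized by the initial cell
#' concentration: `c = (C20 - C2i) / dt / CC0`. With concentrations in
#' mg l^-1 and CC0 in mg DCW l^-1 the units reduce to
#' mg NO3-N (mg DCW)^-1 h^-1.
#'
#' @inheritParams nitrite_accumulation_efficiency
#' @return Rate(s), per hour per unit biomass.
#' @export
specific_nitrate_rate <- function(ts, i, baseline = 1L) {
  stopifnot(inherits(ts, "batch_ts"))
  i <- check_index(ts, i)
  b <- baseline_state(ts, baseline)
  dt <- ts$time_h[i] - b$t0
  if (any(dt <= 0))
    stop("time interval must be positive (i after the baseline point)",
         call. = FALSE)
  (b$c20 - ts$no3_mg_l[i]) / dt / attr(ts, "cc0")
}

#' Specific total oxidized-N reduction rate
#'
#' Like [specific_nitrate_rate()] but crediting only nitrogen reduced
#' past nitrite: `d = (C20 - C2i + C10 - C1i) / dt / CC0`. When nitrite
#' accumulates (C1i > C10) this is smaller than the nitrate rate; the
#' two are linked by the identity `d = c * (1 - a/100)`.
#'
#' @inheritParams nitrite_accumulation_efficiency
#' @return Rate(s), per hour per unit biomass.
#' @export
specific_total_n_rate <- function(ts, i, baseline = 1L) {
  stopifnot(inherits(ts, "batch_ts"))
  i <- check_index(ts, i)
  b <- baseline_state(ts, baseline)
  dt <- ts$time_h[i] - b$t0
  if (any(dt <= 0))
    stop("time interval must be positive (i after the baseline point)",
         call. = FALSE)
  (b$c20 - ts$no3_mg_l[i] + b$c10 - ts$no2_mg_l[i]) / dt / attr(ts, "cc0")
}

#' Specific growth rate between two biomass observations
#'
#' `mu = (ln X2 - ln X1) / (t2 - t1)`, the exponential-phase growth rate
#' between two time points. Invariant to rescaling the biomass unit.
#'
#' @param X1,X2 Biomass at times `t1`, `t2`; both > 0 (any common unit).
#' @param t1,t2 Times in hours, `t2 != t1`.
#' @return Specific growth rate, h^-1.
#' @export
#' @examples
#' specific_growth_rate(100, 200, 2, 4)  # log(2)/2
specific_growth_rate <- function(X1, X2, t1, t2) {
  if (any(!is.finite(c(X1, X2))) || any(c(X1, X2) <= 0))
    stop("biomass values must be positive and finite", call. = FALSE)
  if (any(t2 == t1)) stop("time interval must be non-zero", call. = FALSE)
  (log(X2) - log(X1)) / (t2 - t1)
}

#' Log-phase specific growth rate of a batch series
#'
#' Slides a window of `window` consecutive points along the series,
#' regresses `ln(biomass)` on time within each window, and returns the
#' maximum slope — an estimate of the exponential-phase (log-phase)
#' specific growth rate that ignores lag and stationary phases.
#'
#' @param ts A [batch_time_series()] with positive biomass values.
#' @param window Number of consecutive points per regression (>= 2;
#'   default 3, the shortest window giving a non-trivial least-squares
#'   slope).
#' @return A list with `mu` (h^-1), `t_start`, `t_end` (the time span of
#'   the winning window) and `window`.
#' @export
log_phase_mu <- function(ts, window = 3L) {
  stopifnot(inherits(ts, "batch_ts"))
  window <- as.integer(window)
  if (window < 2L) stop("`window` must be at least 2", call. = FALSE)
  x <- ts$biomass
  if (any(is.na(x)) || any(x <= 0))
    stop("log_phase_mu requires positive biomass at every point",
         call. = FALSE)
  n <- nrow(ts)
  if (n < window)
    stop(sprintf("need at least %d points for window = %d", window, window),
         call. = FALSE)
  lx <- log(x)
  best <- list(mu = -Inf, t_start = NA_real_, t_end = NA_real_)
  for (j in seq_len(n - window + 1L)) {
    idx <- j:(j + window - 1L)
    tt <- ts$time_h[idx]
    slope <- stats::cov(tt, lx[idx]) / stats::var(tt)
    if (slope > best$mu)
      best <- list(mu = slope, t_start = tt[1L], t_end = tt[window])
  }
  c(best, list(window = window))
}

#' Evaluate a performance metric along a batch series
#'
#' Tidy wrapper computing one of the batch metrics at every time point
#' after the baseline.
#'
#' @param ts A [batch_time_series()].
#' @param metric One of `"nitrite_accumulation"`, `"nitrate_removal"`,
#'   `"specific_nitrate_rate"`, `"specific_total_N_rate"`.
#' @param baseline Baseline row index (default first point).
#' @return A tibble with columns `time_h`, `value`, `metric_name`.
#' @export
metric_series <- function(ts,
                          metric = c("nitrite_accumulation",
                                     "nitrate_removal",
                                     "specific_nitrate_rate",
                                     "specific_total_N_rate"),
                          baseline = 1L) {
  stopifnot(inherits(ts, "batch_ts"))
  metric <- match.arg(metric)
  idx <- setdiff(seq_len(nrow(ts)), seq_len(baseline))
  fn <- switch(metric,
    nitrite_accumulation = nitrite_accumulation_efficiency,
    nitrate_removal = nitrate_removal_efficiency,
    specific_nitrate_rate = specific_nitrate_rate,
    specific_total_N_rate = specific_total_n_rate)
  vals <- vapply(idx, function(i) {
    tryCatch(fn(ts, i, baseline = baseline), error = function(e) NA_real_)
  }, numeric(1))
  tibble::tibble(time_h = ts$time_h[idx], value = vals, metric_name = metric)
}
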