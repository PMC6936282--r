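#' Growth-rate table
#'
#' Observations of specific growth rate versus one or two substrate
#' concentrations, the input to all kinetic fits. Substrate 1 is
#' nitrate-N and substrate 2 the carbon source, mg l^-1.
#'
#' @param s1 Nitrate-N concentrations, mg l^-1, > 0.
#' @param mu Observed specific growth rates, h^-1, >= 0.
#' @param s2 Optional carbon concentrations, mg l^-1, > 0.
#' @return A `growth_table`: a tibble with columns `s1_mg_l`, `s2_mg_l`
#'   (NA when absent) and `mu_per_h`.
#' @export
growth_table <- function(s1, mu, s2 = NULL) {
  if (!is.numeric(s1) || any(!is.finite(s1)) || any(s1 <= 0))
    stop("`s1` must be positive and finite", call. = FALSE)
  if (length(mu) != length(s1) || any(!is.finite(mu)) || any(mu < 0))
    stop("`mu` must be non-negative, finite, and match `s1` in length",
         call. = FALSE)
  if (!is.null(s2)) {
    if (length(s2) != length(s1) || any(!is.finite(s2)) || any(s2 <= 0))
      stop("`s2` must be positive, finite, and match `s1` in length",
           call. = FALSE)
  } else {
    s2 <- rep(NA_real_, length(s1))
  }
  out <- tibble::tibble(s1_mg_l = as.numeric(s1), s2_mg_l = as.numeric(s2),
                        mu_per_h = as.numeric(mu))
  class(out) <- c("growth_table", class(out))
  out
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares taken
#' about the mean of the observations. Equals 1 only for a perfect fit
#' and can be negative for fits worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return R^2, dimensionless in (-Inf, 1].
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("`observed` and `predicted` must have equal length >= 2",
         call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observations have zero variance; R^2 is undefined", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fitting options
#'
#' Controls for the nonlinear least-squares engine. Fits are run from a
#' deterministic multi-start grid in log-parameter space (positivity is
#' enforced by the log transform, not by clipping); the start with the
#' lowest sum of squared residuals wins, ties going to the smaller
#' parameter-vector norm.
#'
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol Relative tolerances on cost and parameters.
#' @param plausibility_factor A start is discarded when a fitted Ks or
#'   Ki exceeds this multiple of the largest substrate concentration, or
#'   mu_max exceeds this multiple of the largest observed rate —
#'   the signature of a diverged fit.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(maxiter = 200L, ftol = 1e-12, ptol = 1e-12,
                        plausibility_factor = 1e3) {
  structure(list(maxiter = as.integer(maxiter), ftol = ftol, ptol = ptol,
                 plausibility_factor = plausibility_factor),
            class = "fit_options")
}

# Deterministic start grid shared by single and double fits: three
# candidate rules per parameter group, crossed -> 27 starts.
start_grid <- function(S_list, mu) {
  mu_starts <- max(mu) * c(1, 2, 4)
  ks_rules <- c("min10", "med10", "med")
  ki_rules <- c("max", "max5", "max25")
  grid <- expand.grid(mu_max = mu_starts, ks_rule = ks_rules,
                      ki_rule = ki_rules, stringsAsFactors = FALSE)
  apply_rules <- function(S, ks_rule, ki_rule) {
    ks <- switch(ks_rule, min10 = min(S) / 10, med10 = stats::median(S) / 10,
                 med = stats::median(S))
    ki <- switch(ki_rule, max = max(S), max5 = 5 * max(S),
                 max25 = 25 * max(S))
    c(ks = ks, ki = ki)
  }
  lapply(seq_len(nrow(grid)), function(r) {
    p <- grid$mu_max[r]
    for (S in S_list)
      p <- c(p, apply_rules(S, grid$ks_rule[r], grid$ki_rule[r]))
    unname(p)
  })
}

# Run Levenberg-Marquardt from one start in log-parameter space.
# Returns NULL when the start fails (non-convergence, non-finite SSE,
# implausible parameters, or an invalid Edwards factor).
run_start <- function(start, resid_fn, opts, S_list, mu, kinds) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = log(start), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = opts$maxiter, ftol = opts$ftol,
                         ptol = opts$ptol)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:3)) return(NULL)
  p <- exp(fit$par)
  sse <- sum(fit$fvec^2)
  if (!is.finite(sse) || any(!is.finite(p))) return(NULL)
  # plausibility: diverged scale parameters mark a failed start
  pf <- opts$plausibility_factor
  if (p[1] > pf * max(mu)) return(NULL)
  k <- 2L
  for (j in seq_along(S_list)) {
    ks <- p[k]; ki <- p[k + 1L]
    if (ks > pf * max(S_list[[j]]) || ki > pf * max(S_list[[j]])) return(NULL)
    if (kinds[j] == "edwards" && ki <= ks) return(NULL)
    k <- k + 2L
  }
  list(par = p, sse = sse)
}

best_of_starts <- function(starts, resid_fn, opts, S_list, mu, kinds) {
  best <- NULL
  for (s in starts) {
    res <- run_start(s, resid_fn, opts, S_list, mu, kinds)
    if (is.null(res)) next
    if (is.null(best) || res$sse < best$sse * (1 - 1e-12) ||
        (abs(res$sse - best$sse) <= 1e-12 * max(best$sse, 1e-300) &&
         sum(res$par^2) < sum(best$par^2)))
      best <- res
  }
  best
}

new_fit_result <- function(fitting_number, model, substrate, params, mu, pred,
                           sse, converged, n_starts, collinear = FALSE) {
  r2 <- if (converged) r_squared(mu, pred) else NA_real_
  structure(list(fitting_number = fitting_number, model = model,
                 substrate = substrate, params = params,
                 r_squared = r2, sse = if (converged) sse else NA_real_,
                 converged = converged, n_starts_tried = n_starts,
                 residuals = if (converged) mu - pred else NULL,
                 fitted = if (converged) pred else NULL,
                 collinear = collinear),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  lbl <- paste(x$model, collapse = " x ")
  if (!x$converged) {
    cat(sprintf("<fit_result> %s [%s]: FAILED after %d starts\n",
                lbl, x$substrate, x$n_starts_tried))
    return(invisible(x))
  }
  cat(sprintf("<fit_result> %s [%s]: R^2 = %.4f, SSE = %.3g\n",
              lbl, x$substrate, x$r_squared, x$sse))
  print(x$params)
  if (x$collinear)
    cat("  note: collinear substrate design; only mu_max is fully",
        "identifiable\n")
  invisible(x)
}

#' Fit a single-substrate inhibition model
#'
#' Estimates (mu_max, Ks, Ki) of one inhibition growth law by
#' Levenberg-Marquardt least squares on the observed growth rates,
#' restarted from a deterministic 27-point grid in log-parameter space.
#' The objective is the unweighted sum of squared residuals on mu.
#'
#' @param table A [growth_table()] with at least 4 rows.
#' @param substrate Which concentration axis to fit against: `"s1"`
#'   (nitrate-N) or `"s2"` (carbon).
#' @param kind One of [model_kinds()].
#' @param options A [fit_options()] list.
#' @return A `fit_result` with the estimated [single_params()],
#'   `r_squared`, `sse`, `converged`, residuals and fitted values. When
#'   every start fails the result has `converged = FALSE` and no
#'   parameters, mirroring fits that diverge.
#' @export
fit_single <- function(table, substrate = c("s1", "s2"), kind,
                       options = fit_options()) {
  stopifnot(inherits(table, "growth_table"))
  substrate <- match.arg(substrate)
  kind <- match_kind(kind)
  S <- if (substrate == "s1") table$s1_mg_l else table$s2_mg_l
  if (any(is.na(S)))
    stop(sprintf("table has no `%s` column values to fit against", substrate),
         call. = FALSE)
  mu <- table$mu_per_h
  if (length(S) < 4L)
    stop("at least 4 observations are required to fit 3 parameters",
         call. = FALSE)
  resid_fn <- function(logp) {
    p <- exp(logp)
    mu - p[1] * mu_factor(S, kind, p[2], p[3])
  }
  starts <- start_grid(list(S), mu)
  best <- best_of_starts(starts, resid_fn, options, list(S), mu, kind)
  if (is.null(best))
    return(new_fit_result(NA_integer_, kind, substrate, NULL, mu, NULL,
                          NA_real_, FALSE, length(starts)))
  params <- single_params(best$par[1], best$par[2], best$par[3], kind)
  pred <- mu_single(S, params)
  new_fit_result(NA_integer_, kind, substrate, params, mu, pred, best$sse,
                 TRUE, length(starts))
}

#' Fit an interactive double-substrate inhibition model
#'
#' Estimates a shared mu_max and per-substrate (Ks, Ki) for the
#' multiplicative double-substrate model, one inhibition law per
#' substrate. When the two concentration columns are proportional
#' (e.g. a fixed C/N ratio design, S2 = 5 * S1) the design matrix is
#' rank deficient: the factors can trade off against each other and the
#' result carries `collinear = TRUE` with a warning — mu_max remains
#' identifiable but individual constants are not. A crossed grid over
#' both substrates identifies all five parameters.
#'
#' @param table A [growth_table()] with both substrate columns and at
#'   least 6 rows.
#' @param kind1,kind2 Model kind for substrate 1 (nitrate-N) and
#'   substrate 2 (carbon).
#' @param options A [fit_options()] list.
#' @return A `fit_result` holding [double_params()] on convergence.
#' @export
fit_double <- function(table, kind1, kind2, options = fit_options()) {
  stopifnot(inherits(table, "growth_table"))
  kind1 <- match_kind(kind1); kind2 <- match_kind(kind2)
  if (any(is.na(table$s2_mg_l)))
    stop("double-substrate fit requires the `s2` column", call. = FALSE)
  S1 <- table$s1_mg_l; S2 <- table$s2_mg_l; mu <- table$mu_per_h
  if (length(S1) < 6L)
    stop("at least 6 observations are required to fit 5 parameters",
         call. = FALSE)
  collinear <- qr(cbind(S1, S2))$rank < 2L
  if (collinear)
    warning("substrate columns are proportional (collinear design): ",
            "only mu_max is fully identifiable", call. = FALSE)
  kinds <- c(kind1, kind2)
  resid_fn <- function(logp) {
    p <- exp(logp)
    mu - p[1] * mu_factor(S1, kind1, p[2], p[3]) *
      mu_factor(S2, kind2, p[4], p[5])
  }
  starts <- start_grid(list(S1, S2), mu)
  best <- best_of_starts(starts, resid_fn, options, list(S1, S2), mu, kinds)
  if (is.null(best))
    return(new_fit_result(NA_integer_, kinds, "s1+s2", NULL, mu, NULL,
                          NA_real_, FALSE, length(starts)))
  params <- double_params(best$par[1], kind1, best$par[2], best$par[3],
                          kind2, best$par[4], best$par[5])
  pred <- mu_double(S1, S2, params)
  new_fit_result(NA_integer_, kinds, "s1+s2", params, mu, pred, best$sse,
                 TRUE, length(starts), collinear = collinear)
}

#' Fit every candidate model combination
#'
#' Runs all 15 fits of the standard comparison layout: the three
#' single-substrate laws against nitrate (numbers 1-3: Aiba, Edwards,
#' Andrews) and against carbon (4-6), then the nine interactive
#' double-substrate combinations (7-15, the nitrate-side law cycling
#' Aiba/Edwards/Andrews within carbon-side blocks). Failed fits are
#' retained with `converged = FALSE` rather than dropped.
#'
#' @param table A [growth_table()] with both substrate columns.
#' @param options A [fit_options()] list.
#' @return A `fit_collection`: a list of 15 `fit_result` objects in
#'   fitting-number order. See [fit_report()] for the tabular view and
#'   [rank_fits()] for the R^2 ranking.
#' @export
fit_all <- function(table, options = fit_options()) {
  stopifnot(inherits(table, "growth_table"))
  if (nrow(table) == 0L) stop("empty growth table", call. = FALSE)
  kinds <- c("aiba", "edwards", "andrews")
  fits <- vector("list", 15L)
  n <- 0L
  for (sub in c("s1", "s2")) for (k in kinds) {
    n <- n + 1L
    fits[[n]] <- tryCatch(fit_single(table, sub, k, options),
                          error = function(e) stop(e))
    fits[[n]]$fitting_number <- n
  }
  for (k2 in kinds) for (k1 in kinds) {
    n <- n + 1L
    fits[[n]] <- suppressWarnings(fit_double(table, k1, k2, options))
    fits[[n]]$fitting_number <- n
  }
  structure(fits, class = "fit_collection")
}

#' Tabular report of a fit collection
#'
#' Flattens the results of [fit_all()] into one row per fitting number,
#' with the per-substrate constants in dedicated columns (NA where a
#' model has no such constant or did not converge).
#'
#' @param fits A `fit_collection` from [fit_all()].
#' @return A tibble with columns `fitting_number`, `model_no3`,
#'   `model_toc`, `ks_n`, `ki_n`, `ks_c`, `ki_c`, `mu_max`, `r_squared`,
#'   `converged`.
#' @export
fit_report <- function(fits) {
  stopifnot(inherits(fits, "fit_collection"))
  rows <- lapply(fits, function(f) {
    out <- tibble::tibble(fitting_number = f$fitting_number,
                          model_no3 = NA_character_, model_toc = NA_character_,
                          ks_n = NA_real_, ki_n = NA_real_,
                          ks_c = NA_real_, ki_c = NA_real_,
                          mu_max = NA_real_, r_squared = f$r_squared,
                          converged = f$converged)
    if (length(f$model) == 1L) {
      if (f$substrate == "s1") out$model_no3 <- f$model
      else out$model_toc <- f$model
      if (f$converged) {
        out$mu_max <- f$params$mu_max
        if (f$substrate == "s1") {
          out$ks_n <- f$params$ks; out$ki_n <- f$params$ki
        } else {
          out$ks_c <- f$params$ks; out$ki_c <- f$params$ki
        }
      }
    } else {
      out$model_no3 <- f$model[1]; out$model_toc <- f$model[2]
      if (f$converged) {
        out$mu_max <- f$params$mu_max
        out$ks_n <- f$params$s1$ks; out$ki_n <- f$params$s1$ki
        out$ks_c <- f$params$s2$ks; out$ki_c <- f$params$s2$ki
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Rank converged fits by R-squared
#'
#' @param fits A `fit_collection` from [fit_all()].
#' @return The [fit_report()] tibble restricted to converged fits,
#'   sorted by decreasing `r_squared`.
#' @export
rank_fits <- function(fits) {
  rep <- fit_report(fits)
  rep <- rep[rep$converged, , drop = FALSE]
  rep[order(-rep$r_squared), , drop = FALSE]
}

#' @export
print.fit_collection <- function(x, ...) {
  cat("<fit_collection> of", length(x), "model fits\n")
  print(fit_report(x))
  invisible(x)
}

#' Fit the Arrhenius temperature law
#'
#' Linear regression of `ln(mu_max)` on `1/T`: the modified Arrhenius
#' law `mu_max = A * exp(-E/(R*T))` is log-linear with slope `-E/R` and
#' intercept `ln A`. Two points give the exact interpolating line
#' (R^2 = 1); three or more give a genuine regression.
#'
#' @param temperature_K Absolute temperatures, K, all > 0, >= 2 values.
#' @param mu_max Maximum specific growth rates at those temperatures,
#'   all > 0 (units of choice; `A` inherits them).
#' @return An `arrhenius_fit`: list with [arrhenius_params()] (`A` in
#'   the units of `mu_max`, `E` in kJ mol^-1), `r_squared`, and a
#'   per-temperature tibble of observed and fitted values.
#' @export
#' @examples
#' T_K <- 273.15 + c(20, 25, 30, 35, 40)
#' mu <- mu_max_at_temperature(T_K, arrhenius_params(77.48, 13.80))
#' fit_arrhenius(T_K, mu)
fit_arrhenius <- function(temperature_K, mu_max) {
  if (length(temperature_K) < 2L || length(mu_max) != length(temperature_K))
    stop("need >= 2 matched (temperature, mu_max) pairs", call. = FALSE)
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0))
    stop("temperatures must be positive (K)", call. = FALSE)
  if (any(!is.finite(mu_max)) || any(mu_max <= 0))
    stop("all mu_max values must be positive (log is taken)", call. = FALSE)
  inv_T <- 1 / temperature_K
  fit <- stats::lm(log(mu_max) ~ inv_T)
  co <- stats::coef(fit)
  A <- exp(unname(co[1]))
  E_kJ <- -unname(co[2]) * 8.314 / 1000
  if (E_kJ < 0)
    stop("fitted activation energy is negative: mu_max increases with 1/T, ",
         "which the Arrhenius law cannot represent", call. = FALSE)
  pred <- stats::fitted(fit)
  r2 <- if (stats::var(log(mu_max)) == 0) 1 else r_squared(log(mu_max), pred)
  structure(list(params = arrhenius_params(A, E_kJ), r_squared = r2,
                 values = tibble::tibble(temperature_K = temperature_K,
                                         mu_max = mu_max,
                                         fitted = exp(unname(pred)))),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> A = %.4g, E = %.4g kJ/mol, R^2 = %.4f\n",
              x$params$A, x$params$E, x$r_squared))
  invisible(x)
}
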