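#' Substrate-inhibition model kinds
#'
#' The three single-substrate inhibition growth laws supported by the
#' package: Andrews (Haldane), Aiba and Edwards.
#'
#' @return Character vector of the recognised model kind names.
#' @export
#' @examples
#' model_kinds()
model_kinds <- function() c("andrews", "aiba", "edwards")

match_kind <- function(kind) {
  if (length(kind) != 1L || !is.character(kind))
    stop("`kind` must be a single string", call. = FALSE)
  match.arg(tolower(kind), model_kinds())
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

#' Single-substrate inhibition model parameters
#'
#' Bundles the kinetic constants of one substrate-inhibition growth law:
#' the maximum specific growth rate `mu_max` (h^-1), the semi-saturation
#' (affinity) constant `ks` (mg l^-1) and the substrate-inhibition
#' constant `ki` (mg l^-1).
#'
#' For the Edwards law the rate is `mu_max * (exp(-S/ki) - exp(-S/ks))`,
#' which is negative for some S unless `ki > ks`; such parameter sets are
#' rejected because the inhibition scale must exceed the affinity scale
#' for the law to be physically meaningful.
#'
#' @param mu_max Maximum specific growth rate, h^-1. Must be > 0.
#' @param ks Semi-saturation constant, mg l^-1. Must be > 0.
#' @param ki Substrate-inhibition constant, mg l^-1. Must be > 0.
#' @param kind One of `model_kinds()`.
#' @return An object of class `single_params`.
#' @seealso [mu_single()], [optimal_substrate()]
#' @export
#' @examples
#' single_params(0.5687, 17.14, 1782.07, "andrews")
single_params <- function(mu_max, ks, ki, kind) {
  kind <- match_kind(kind)
  check_positive(mu_max, "mu_max")
  check_positive(ks, "ks")
  check_positive(ki, "ki")
  if (kind == "edwards" && ki <= ks)
    stop("Edwards model requires ki > ks (otherwise the rate is negative)",
         call. = FALSE)
  structure(list(mu_max = mu_max, ks = ks, ki = ki, kind = kind),
            class = "single_params")
}

#' @export
print.single_params <- function(x, ...) {
  cat(sprintf(
    "<single_params> %s: mu_max = %.4g h^-1, Ks = %.4g mg/l, Ki = %.4g mg/l\n",
    x$kind, x$mu_max, x$ks, x$ki))
  invisible(x)
}

#' Interactive double-substrate model parameters
#'
#' Parameters of the interactive (multiplicative) double-substrate
#' inhibition model: a single shared `mu_max` times the normalized
#' inhibition factor of each substrate. Substrate 1 is conventionally
#' nitrate-N and substrate 2 the carbon source (TOC), both in mg l^-1.
#'
#' @param mu_max Shared maximum specific growth rate, h^-1.
#' @param kind1,kind2 Model kind for substrate 1 / substrate 2.
#' @param ks1,ki1,ks2,ki2 Semi-saturation and inhibition constants per
#'   substrate, mg l^-1, all > 0.
#' @return An object of class `double_params`.
#' @seealso [mu_double()]
#' @export
#' @examples
#' double_params(0.5523, "andrews", 4.34, 8970.72, "andrews", 48.25, 14194.83)
double_params <- function(mu_max, kind1, ks1, ki1, kind2, ks2, ki2) {
  kind1 <- match_kind(kind1)
  kind2 <- match_kind(kind2)
  check_positive(mu_max, "mu_max")
  check_positive(ks1, "ks1"); check_positive(ki1, "ki1")
  check_positive(ks2, "ks2"); check_positive(ki2, "ki2")
  if (kind1 == "edwards" && ki1 <= ks1)
    stop("Edwards factor for substrate 1 requires ki1 > ks1", call. = FALSE)
  if (kind2 == "edwards" && ki2 <= ks2)
    stop("Edwards factor for substrate 2 requires ki2 > ks2", call. = FALSE)
  structure(list(mu_max = mu_max,
                 s1 = list(kind = kind1, ks = ks1, ki = ki1),
                 s2 = list(kind = kind2, ks = ks2, ki = ki2)),
            class = "double_params")
}

#' @export
print.double_params <- function(x, ...) {
  cat(sprintf("<double_params> %s x %s: mu_max = %.4g h^-1\n",
              x$s1$kind, x$s2$kind, x$mu_max))
  cat(sprintf("  S1 (nitrate-N): Ks = %.4g, Ki = %.4g mg/l\n",
              x$s1$ks, x$s1$ki))
  cat(sprintf("  S2 (carbon):    Ks = %.4g, Ki = %.4g mg/l\n",
              x$s2$ks, x$s2$ki))
  invisible(x)
}

#' Arrhenius temperature-dependence parameters
#'
#' Parameters of the modified Arrhenius law
#' `mu_max(T) = A * exp(-E / (R * T))` describing how the maximum specific
#' growth rate varies with absolute temperature. The gas constant is
#' fixed at R = 8.314 J mol^-1 K^-1; `E` is supplied in kJ mol^-1 and
#' converted internally. `mu_max` inherits the units of `A` — here
#' days^-1 by convention; see [per_day_to_per_hour()].
#'
#' @param A Pre-exponential factor, days^-1. Must be > 0.
#' @param E Activation energy, kJ mol^-1. Must be >= 0.
#' @return An object of class `arrhenius_params`.
#' @seealso [mu_max_at_temperature()], [fit_arrhenius()]
#' @export
#' @examples
#' arrhenius_params(A = 77.48, E = 13.80)
arrhenius_params <- function(A, E) {
  check_positive(A, "A")
  if (length(E) != 1L || !is.numeric(E) || !is.finite(E) || E < 0)
    stop("`E` must be a single non-negative finite number (kJ/mol)",
         call. = FALSE)
  structure(list(A = A, E = E, R = 8.314), class = "arrhenius_params")
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_params> A = %.4g d^-1, E = %.4g kJ/mol (R = %.3f J/mol/K)\n",
    x$A, x$E, x$R))
  invisible(x)
}

# Normalized inhibition factor: the single-substrate law with mu_max = 1.
# Vectorized over S; defined as its limit 0 at S = 0 for all kinds.
mu_factor <- function(S, kind, ks, ki) {
  out <- numeric(length(S))
  pos <- S > 0
  Sp <- S[pos]
  out[pos] <- switch(kind,
    andrews = 1 / (1 + ks / Sp + Sp / ki),
    aiba    = Sp * exp(-Sp / ki) / (ks + Sp),
    edwards = exp(-Sp / ki) - exp(-Sp / ks))
  out
}

#' Single-substrate specific growth rate
#'
#' Evaluates one of the three substrate-inhibition growth laws at
#' substrate concentration(s) `S`:
#' \describe{
#'   \item{Andrews}{`mu = mu_max / (1 + Ks/S + S/Ki)`}
#'   \item{Aiba}{`mu = mu_max * S * exp(-S/Ki) / (Ks + S)`}
#'   \item{Edwards}{`mu = mu_max * (exp(-S/Ki) - exp(-S/Ks))`}
#' }
#' All three are unimodal in S with `mu -> 0` as `S -> Inf`. At `S = 0`
#' the rate is 0: exactly for Aiba and Edwards, and as the continuous
#' limit for Andrews.
#'
#' @param S Substrate concentration(s), mg l^-1, all >= 0. Vectorized.
#' @param params A [single_params()] object.
#' @return Specific growth rate(s), h^-1, same length as `S`.
#' @export
#' @examples
#' p <- single_params(0.5687, 17.14, 1782.07, "andrews")
#' mu_single(100, p)
mu_single <- function(S, params) {
  stopifnot(inherits(params, "single_params"))
  if (!is.numeric(S) || any(!is.finite(S)) || any(S < 0))
    stop("`S` must be finite and non-negative", call. = FALSE)
  params$mu_max * mu_factor(S, params$kind, params$ks, params$ki)
}

#' Interactive double-substrate specific growth rate
#'
#' Evaluates the interactive multiple-substrate model
#' `mu = mu_max * f1(S1) * f2(S2)` where `f_k` is the normalized
#' (mu_max = 1) single-substrate inhibition factor of substrate k.
#' The rate is 0 whenever either substrate is absent.
#'
#' @param S1 Nitrate-N concentration(s), mg l^-1, >= 0.
#' @param S2 Carbon concentration(s), mg l^-1, >= 0. Recycled against `S1`.
#' @param params A [double_params()] object.
#' @return Specific growth rate(s), h^-1.
#' @export
#' @examples
#' p <- double_params(0.5523, "andrews", 4.34, 8970.72,
#'                    "andrews", 48.25, 14194.83)
#' mu_double(100, 500, p)
mu_double <- function(S1, S2, params) {
  stopifnot(inherits(params, "double_params"))
  if (!is.numeric(S1) || any(!is.finite(S1)) || any(S1 < 0))
    stop("`S1` must be finite and non-negative", call. = FALSE)
  if (!is.numeric(S2) || any(!is.finite(S2)) || any(S2 < 0))
    stop("`S2` must be finite and non-negative", call. = FALSE)
  params$mu_max *
    mu_factor(S1, params$s1$kind, params$s1$ks, params$s1$ki) *
    mu_factor(S2, params$s2$kind, params$s2$ks, params$s2$ki)
}

#' Maximum specific growth rate at a given temperature
#'
#' Evaluates the modified Arrhenius law `mu_max = A * exp(-E/(R*T))`.
#' The result carries the units of `A` (days^-1 by the package
#' convention); convert with [per_day_to_per_hour()] when comparing with
#' batch growth rates in h^-1.
#'
#' @param temperature_K Absolute temperature(s), K, > 0. Vectorized.
#' @param params An [arrhenius_params()] object.
#' @return mu_max value(s), in the units of `params$A`.
#' @export
#' @examples
#' mu_max_at_temperature(298.15, arrhenius_params(77.48, 13.80))
mu_max_at_temperature <- function(temperature_K, params) {
  stopifnot(inherits(params, "arrhenius_params"))
  if (!is.numeric(temperature_K) || any(!is.finite(temperature_K)) ||
      any(temperature_K <= 0))
    stop("`temperature_K` must be positive (absolute temperature in K)",
         call. = FALSE)
  # E is kJ/mol, R is J/mol/K: convert E to J/mol
  params$A * exp(-params$E * 1000 / (params$R * temperature_K))
}

#' @rdname unit-conversion
#' @export
per_day_to_per_hour <- function(x) x / 24

#' Rate unit conversions
#'
#' Convert specific growth rates between days^-1 (the Arrhenius
#' pre-exponential convention) and h^-1 (the batch-culture convention).
#'
#' @param x Rate value(s).
#' @return Converted rate value(s).
#' @name unit-conversion
#' @export
per_hour_to_per_day <- function(x) x * 24

#' Substrate concentration maximizing the growth rate
#'
#' For the Andrews law the optimum has the closed form `sqrt(Ks * Ki)`;
#' for Aiba and Edwards it is located numerically (golden-section search
#' refined over a wide bracket).
#'
#' @param params A [single_params()] object.
#' @return The concentration S* (mg l^-1) at which `mu_single` is maximal.
#' @export
#' @examples
#' optimal_substrate(single_params(0.5687, 17.14, 1782.07, "andrews"))
optimal_substrate <- function(params) {
  stopifnot(inherits(params, "single_params"))
  if (params$kind == "andrews") return(sqrt(params$ks * params$ki))
  # unimodal on (0, Inf); bracket generously around the geometric scale
  upper <- max(params$ks, params$ki) * 100
  stats::optimize(function(S) mu_single(S, params),
                  interval = c(1e-6, upper), maximum = TRUE,
                  tol = 1e-10)$maximum
}
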