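#' @keywords internal
#' Evaluate `expr` under a locally seeded Mersenne-Twister stream,
#' restoring the caller's RNG state afterwards. All generators route
#' through this so a seed fully determines their output.
with_local_seed <- function(seed, expr) {
  if (length(seed) != 1L || !is.finite(seed) || seed != as.integer(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

# The concentration gradients of the growth-rate experiments: twelve
# nitrate-N levels with the carbon source coupled at C/N = 5.
#' Default substrate gradients for growth-rate experiments
#'
#' The twelve-point nitrate-N gradient (50-2000 mg l^-1) used by the
#' kinetic experiments, with the carbon source coupled at a fixed
#' C/N mass ratio (default 5, giving 250-10000 mg l^-1).
#'
#' @param cn_ratio Carbon-to-nitrate-N mass ratio.
#' @return A list with numeric vectors `s1` (nitrate-N) and `s2`
#'   (carbon), mg l^-1.
#' @export
default_substrate_grid <- function(cn_ratio = 5) {
  s1 <- c(50, 100, 150, 200, 250, 300, 400, 500, 750, 1000, 1500, 2000)
  list(s1 = s1, s2 = cn_ratio * s1)
}

#' Generate a growth-rate table with known truth
#'
#' Evaluates a single- or double-substrate inhibition model on a
#' concentration design and adds seeded Gaussian noise to mu. Negative
#' noisy rates are clipped to 0 with a warning (growth rates cannot be
#' negative). The generating parameters, design and seed are stored as
#' attributes so recovery can be checked against truth.
#'
#' @param truth A [single_params()] or [double_params()] object.
#' @param s1 Nitrate-N design points, mg l^-1. Defaults to the
#'   twelve-level gradient of [default_substrate_grid()].
#' @param s2 Carbon design points. For double-substrate truth the
#'   default couples `s2 = 5 * s1` (C/N = 5); pass an explicit vector
#'   (e.g. a crossed grid via `expand.grid`) to break that collinearity.
#'   For single-substrate truth on the carbon axis, pass the carbon
#'   concentrations as `s1`.
#' @param mu_sd Gaussian noise standard deviation on mu, h^-1.
#' @param seed Integer seed; fully determines the output.
#' @return A [growth_table()] with attributes `truth`, `mu_sd`, `seed`.
#' @export
#' @examples
#' tab <- gen_growth_table(single_params(0.5687, 17.14, 1782.07, "andrews"))
#' tab$mu_per_h[tab$s1_mg_l == 100]  # ~0.4633
gen_growth_table <- function(truth, s1 = default_substrate_grid()$s1,
                             s2 = NULL, mu_sd = 0, seed = 1L) {
  if (mu_sd < 0) stop("`mu_sd` must be non-negative", call. = FALSE)
  if (inherits(truth, "single_params")) {
    mu <- mu_single(s1, truth)
    if (is.null(s2)) s2 <- rep(NA_real_, length(s1))
  } else if (inherits(truth, "double_params")) {
    if (is.null(s2)) s2 <- 5 * s1
    if (length(s2) != length(s1))
      stop("`s1` and `s2` must have equal length", call. = FALSE)
    mu <- mu_double(s1, s2, truth)
  } else {
    stop("`truth` must be single_params or double_params", call. = FALSE)
  }
  mu_obs <- with_local_seed(seed, mu + stats::rnorm(length(mu), 0, mu_sd))
  if (any(mu_obs < 0)) {
    warning("negative noisy growth rates clipped to 0", call. = FALSE)
    mu_obs <- pmax(mu_obs, 0)
  }
  out <- if (all(is.na(s2))) growth_table(s1, mu_obs)
         else growth_table(s1, mu_obs, s2)
  attr(out, "truth") <- truth
  attr(out, "mu_sd") <- mu_sd
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate a batch denitrification time series with known truth
#'
#' Constructs a batch curve directly from its target metrics so that
#' the analysis functions recover the generating values exactly on
#' noiseless output: nitrate stays at its initial value through the lag
#' then decays exponentially with timescale `tau_h`; nitrite equals
#' `a/100` of the nitrate consumed (a constant accumulation efficiency);
#' biomass is flat through the lag then grows exponentially at `mu`.
#' The series is constructed, not ODE-integrated: the aim is known
#' ground truth for the metric formulas, not mechanistic dynamics.
#'
#' Defaults emulate a C/N = 5 batch at 30 C: 100 mg l^-1 initial
#' nitrate-N, ~94% nitrite accumulation, a 6 h lag with most nitrate
#' metabolized by ~13 h, sampled hourly over 24 h.
#'
#' @param c20 Initial nitrate-N, mg l^-1.
#' @param a Nitrite accumulation efficiency, percent in \[0, 100\].
#' @param lag_h Lag-phase duration, h.
#' @param tau_h Exponential nitrate-removal timescale, h.
#' @param mu Log-phase specific growth rate, h^-1.
#' @param cc0 Initial cell concentration, mg DCW l^-1 (also the biomass
#'   during lag).
#' @param times Sampling times, h.
#' @param conc_sd Gaussian noise sd on concentrations, mg l^-1
#'   (clipped at 0).
#' @param seed Integer seed.
#' @return A [batch_time_series()] with attribute `truth`.
#' @export
gen_batch_series <- function(c20 = 100, a = 94.2, lag_h = 6, tau_h = 2,
                             mu = 0.25, cc0 = 25,
                             times = 0:24, conc_sd = 0, seed = 1L) {
  if (a < 0 || a > 100)
    stop("`a` must be a percentage in [0, 100]", call. = FALSE)
  check_positive(c20, "c20"); check_positive(tau_h, "tau_h")
  check_positive(cc0, "cc0")
  if (lag_h < 0) stop("`lag_h` must be non-negative", call. = FALSE)
  te <- pmax(times - lag_h, 0)
  no3 <- c20 * exp(-te / tau_h)
  no2 <- a / 100 * (c20 - no3)
  biomass <- cc0 * exp(mu * te)
  if (conc_sd > 0) {
    noise <- with_local_seed(seed,
      stats::rnorm(2 * length(times), 0, conc_sd))
    no3 <- pmax(no3 + noise[seq_along(times)], 0)
    no2 <- pmax(no2 + noise[length(times) + seq_along(times)], 0)
  }
  out <- batch_time_series(times, no3, no2, biomass = biomass, cc0 = cc0)
  attr(out, "truth") <- list(c20 = c20, a = a, lag_h = lag_h, tau_h = tau_h,
                             mu = mu, cc0 = cc0, conc_sd = conc_sd,
                             seed = as.integer(seed))
  out
}

#' Generate Arrhenius (temperature, mu_max) pairs with known truth
#'
#' Evaluates the Arrhenius law at the culturing temperatures and adds
#' seeded Gaussian noise on the log scale (multiplicative on mu_max, so
#' values stay positive).
#'
#' @param truth An [arrhenius_params()] object.
#' @param temperature_K Absolute temperatures; defaults to the
#'   20-40 C culturing series in 5 C steps.
#' @param log_sd Gaussian noise sd on ln(mu_max).
#' @param seed Integer seed.
#' @return A tibble with columns `temperature_K`, `mu_max`, and
#'   attribute `truth`.
#' @export
gen_arrhenius_series <- function(truth,
                                 temperature_K = 273.15 + seq(20, 40, by = 5),
                                 log_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "arrhenius_params"))
  if (log_sd < 0) stop("`log_sd` must be non-negative", call. = FALSE)
  mu <- mu_max_at_temperature(temperature_K, truth)
  mu <- with_local_seed(seed,
    mu * exp(stats::rnorm(length(mu), 0, log_sd)))
  out <- tibble::tibble(temperature_K = temperature_K, mu_max = mu)
  attr(out, "truth") <- truth
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Builds a replicated Ct table whose 2^-ddCt analysis returns the
#' requested fold changes: the reference gene sits at a constant
#' baseline Ct, and each target's Ct is the target baseline minus
#' log2(fold) relative to the control condition (higher expression ->
#' earlier threshold crossing -> lower Ct). Seeded Gaussian noise in
#' cycles is added per well.
#'
#' @param folds A data frame with columns `condition`, `gene`, `fold`
#'   (> 0) giving the true fold change of each target gene in each
#'   condition relative to `control`. The control condition itself is
#'   added automatically with fold 1 for every gene.
#' @param control Control condition label.
#' @param reference_gene Reference gene label (default `"16S"`).
#' @param baseline_ref,baseline_target Baseline Ct of the reference gene
#'   and of a fold-1 target.
#' @param ct_sd Gaussian noise sd on Ct, cycles.
#' @param replicates Number of replicates per condition (default 3).
#' @param seed Integer seed.
#' @return A [ct_table()] with attribute `truth` (the completed fold
#'   table).
#' @export
gen_ct_table <- function(folds, control, reference_gene = "16S",
                         baseline_ref = 18, baseline_target = 24,
                         ct_sd = 0, replicates = 3L, seed = 1L) {
  if (!is.data.frame(folds) ||
      !all(c("condition", "gene", "fold") %in% names(folds)))
    stop("`folds` needs columns condition, gene, fold", call. = FALSE)
  if (any(folds$fold <= 0)) stop("folds must be positive", call. = FALSE)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  if (ct_sd < 0) stop("`ct_sd` must be non-negative", call. = FALSE)
  genes <- unique(folds$gene)
  if (reference_gene %in% genes)
    stop("the reference gene cannot also appear as a target", call. = FALSE)
  # complete with the control condition at fold 1
  ctrl <- tibble::tibble(condition = control, gene = genes, fold = 1)
  truth <- rbind(tibble::tibble(condition = as.character(folds$condition),
                                gene = as.character(folds$gene),
                                fold = as.numeric(folds$fold)), ctrl)
  truth <- truth[!duplicated(truth[c("condition", "gene")]), ]

  conditions <- unique(truth$condition)
  rows <- list()
  for (cond in conditions) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cond, gene = reference_gene, role = "reference",
        replicate = r, ct = baseline_ref)
      sub <- truth[truth$condition == cond, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cond, gene = sub$gene, role = "target", replicate = r,
        ct = baseline_target - log2(sub$fold))
    }
  }
  tab <- do.call(rbind, rows)
  if (ct_sd > 0)
    tab$ct <- with_local_seed(seed,
      tab$ct + stats::rnorm(nrow(tab), 0, ct_sd))
  out <- ct_table(tab$condition, tab$gene, tab$role, tab$replicate, tab$ct)
  attr(out, "truth") <- truth
  attr(out, "seed") <- as.integer(seed)
  out
}
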