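# Published single- and double-substrate constants used as generating
# truth throughout the suite (mu_max in h^-1, Ks/Ki in mg/l).
table2 <- list(
  aiba_n    = list(kind = "aiba",    ks = 12.58,  ki = 2745.61,  mu_max = 0.5370),
  edwards_n = list(kind = "edwards", ks = 29.46,  ki = 3061.89,  mu_max = 0.5066),
  andrews_n = list(kind = "andrews", ks = 17.14,  ki = 1782.07,  mu_max = 0.5687),
  aiba_c    = list(kind = "aiba",    ks = 62.01,  ki = 13737.24, mu_max = 0.5367),
  edwards_c = list(kind = "edwards", ks = 144.86, ki = 15317.67, mu_max = 0.5065),
  andrews_c = list(kind = "andrews", ks = 84.11,  ki = 8940.23,  mu_max = 0.5679)
)
table2_double15 <- list(mu_max = 0.5523, ks_n = 4.34, ki_n = 8970.72,
                        ks_c = 48.25, ki_c = 14194.83)
arrhenius_truth <- list(A = 77.48, E = 13.80)

nitrate_grid <- c(50, 100, 150, 200, 250, 300, 400, 500, 750, 1000, 1500, 2000)
carbon_grid <- 5 * nitrate_grid

params_from <- function(row) single_params(row$mu_max, row$ks, row$ki, row$kind)

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Brute-force SSE oracle: dense log-spaced grid over a bounded parameter
# box, independent of the fitting path.
grid_oracle_sse <- function(S, mu, kind, n = 13L) {
  mu_box <- exp(seq(log(0.1), log(1.6), length.out = n))
  ks_box <- exp(seq(log(2), log(500), length.out = n))
  ki_box <- exp(seq(log(400), log(40000), length.out = n))
  pairs <- expand.grid(ks = ks_box, ki = ki_box)
  if (kind == "edwards") pairs <- pairs[pairs$ki > pairs$ks, ]
  Fm <- mapply(function(ks, ki) denitkin:::mu_factor(S, kind, ks, ki),
               pairs$ks, pairs$ki)  # length(S) x npairs
  best <- Inf
  for (m in mu_box) {
    sse <- colSums((mu - m * Fm)^2)
    best <- min(best, min(sse))
  }
  best
}
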