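#' qPCR Ct table
#'
#' Threshold-cycle records for relative-expression analysis. Each row is
#' one well: a condition label, a gene, that gene's role (`"target"` or
#' `"reference"`), a replicate index, and the Ct value. Every
#' (condition, replicate) pair must contain exactly one reference-gene
#' measurement, which normalizes the targets of that replicate.
#'
#' @param condition Condition labels (e.g. `"C/N=5"`).
#' @param gene Gene labels (e.g. `"napA"`, `"16S"`).
#' @param role `"target"` or `"reference"` per row.
#' @param replicate Replicate index per row (integer >= 1).
#' @param ct Threshold cycles, finite and > 0.
#' @return A `ct_table` tibble.
#' @export
ct_table <- function(condition, gene, role, replicate, ct) {
  n <- length(condition)
  if (any(lengths(list(gene, role, replicate, ct)) != n))
    stop("all columns must have equal length", call. = FALSE)
  if (!all(role %in% c("target", "reference")))
    stop("`role` must be \"target\" or \"reference\"", call. = FALSE)
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("`ct` values must be finite and positive", call. = FALSE)
  out <- tibble::tibble(condition = as.character(condition),
                        gene = as.character(gene),
                        role = as.character(role),
                        replicate = as.integer(replicate),
                        ct = as.numeric(ct))
  class(out) <- c("ct_table", class(out))
  out
}

#' Fold change by the 2^-ddCt method
#'
#' The elementary relative-expression computation:
#' `fold = 2 ^ -[(Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,control - Ct_ref,control)]`. Assumes a doubling of product
#' per cycle (amplification efficiency fixed at 2).
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in
#'   the sample condition.
#' @param ct_target_control,ct_ref_control The same in the control
#'   condition.
#' @return Fold change, dimensionless > 0. Vectorized.
#' @export
#' @examples
#' ddct_fold(22, 18, 24, 18)  # 4: target is 2 cycles "earlier" vs control
ddct_fold <- function(ct_target_sample, ct_ref_sample,
                      ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts)))
    stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Relative expression table by 2^-ddCt with replicate aggregation
#'
#' For every (condition, gene) pair: each replicate's target Ct is
#' normalized by that replicate's reference-gene Ct (delta Ct);
#' replicate delta Ct values are averaged arithmetically *before*
#' exponentiation (equivalent to a geometric mean of per-replicate
#' folds); the condition's mean delta Ct is then referenced to the
#' control condition's and converted to a fold change. Folds of the
#' control condition against itself are exactly 1 by construction.
#'
#' @param cts A [ct_table()].
#' @param control The control condition label (must be present).
#' @return A tibble with one row per (condition, gene): `condition`,
#'   `gene`, `fold`, `fold_sd` (standard deviation of per-replicate
#'   folds; NA with a single replicate) and `n_replicates`.
#' @export
fold_table <- function(cts, control) {
  stopifnot(inherits(cts, "ct_table"))
  if (!control %in% cts$condition)
    stop(sprintf("control condition \"%s\" is absent from the table",
                 control), call. = FALSE)
  refs <- cts[cts$role == "reference", ]
  targets <- cts[cts$role == "target", ]
  if (nrow(targets) == 0L)
    stop("table contains no target-gene rows", call. = FALSE)

  ref_ct <- function(cond, rep) {
    hit <- refs$ct[refs$condition == cond & refs$replicate == rep]
    if (length(hit) != 1L)
      stop(sprintf(
        "condition \"%s\" replicate %d needs exactly one reference-gene Ct (found %d)",
        cond, rep, length(hit)), call. = FALSE)
    hit
  }
  targets$dct <- mapply(function(cond, rep, ct) ct - ref_ct(cond, rep),
                        targets$condition, targets$replicate, targets$ct)

  key <- interaction(targets$condition, targets$gene, drop = TRUE)
  agg <- lapply(split(targets, key), function(g) {
    tibble::tibble(condition = g$condition[1], gene = g$gene[1],
                   mean_dct = mean(g$dct),
                   dct_values = list(g$dct),
                   n_replicates = nrow(g))
  })
  agg <- do.call(rbind, agg)

  control_dct <- stats::setNames(
    agg$mean_dct[agg$condition == control],
    agg$gene[agg$condition == control])
  missing <- setdiff(unique(agg$gene), names(control_dct))
  if (length(missing))
    stop(sprintf("gene(s) %s have no measurement in the control condition",
                 paste(missing, collapse = ", ")), call. = FALSE)

  agg$fold <- unname(2^(-(agg$mean_dct - control_dct[agg$gene])))
  agg$fold_sd <- vapply(seq_len(nrow(agg)), function(r) {
    rep_folds <- 2^(-(agg$dct_values[[r]] - control_dct[agg$gene[r]]))
    if (length(rep_folds) < 2L) NA_real_ else stats::sd(rep_folds)
  }, numeric(1))
  out <- agg[, c("condition", "gene", "fold", "fold_sd", "n_replicates")]
  rownames(out) <- NULL
  out
}
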