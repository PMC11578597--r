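RANK_CRITERIA <- c("abs_beta", "per_variant_h2", "significance",
                   "n_normalized_significance")

#' Coreness metric of each instrument
#'
#' Computes, from the exposure association statistics, the metric by which
#' instruments are ranked from putative core to putative peripheral:
#'
#' * `abs_beta` (default): the absolute per-allele effect \eqn{|\hat\beta_j|};
#' * `per_variant_h2`: the per-variant heritability, proportional to
#'   \eqn{f_j (1 - f_j) \hat\beta_j^2} with \eqn{f_j} the effect-allele
#'   frequency (symmetric in \eqn{f \leftrightarrow 1 - f}, so the minor
#'   allele convention is immaterial);
#' * `significance`: \eqn{|\hat\beta_j| / SE_j};
#' * `n_normalized_significance`: \eqn{|\hat\beta_j| / (SE_j \sqrt{N_j})},
#'   which can differ from `significance` in GWAS meta-analyses with
#'   variant-specific sample sizes.
#'
#' @param records Harmonized instrument table (see [harmonize()]).
#' @param criterion One of `"abs_beta"`, `"per_variant_h2"`,
#'   `"significance"`, `"n_normalized_significance"`.
#' @return Numeric vector of non-negative metric values, one per record.
#' @export
coreness_metric <- function(records, criterion = RANK_CRITERIA) {
  records <- as_instruments(records)
  criterion <- match.arg(criterion)
  b  <- records$beta_exposure
  se <- records$se_exposure
  switch(criterion,
    abs_beta = abs(b),
    per_variant_h2 = {
      f <- records$eaf_exposure
      if (is.null(f) || anyNA(f))
        estimation_error("per_variant_h2 requires eaf_exposure for all records (missing: %s)",
                         paste(records$variant_id[is.na(f)], collapse = ", "))
      f * (1 - f) * b^2
    },
    significance = abs(b) / se,
    n_normalized_significance = {
      n <- records$n_exposure
      if (is.null(n) || anyNA(n) || any(n <= 0))
        estimation_error("n_normalized_significance requires positive n_exposure for all records (missing: %s)",
                         paste(records$variant_id[is.na(n) | n <= 0], collapse = ", "))
      abs(b) / (se * sqrt(n))
    }
  )
}

#' Rank instruments by coreness and partition into K groups
#'
#' Instruments are sorted on the chosen metric in descending order; exact
#' metric ties are ordered by a seeded random shuffle. The ranked list is
#' then cut into `K` contiguous groups of near-equal size: the first
#' `J %% K` groups receive `ceiling(J/K)` instruments and the rest
#' `floor(J/K)`, so group 1 — the putative core group — is never the
#' smaller one. Records are first put into a canonical order by
#' `variant_id`, which makes the result (including tie-breaking) invariant
#' to the row order of the input.
#'
#' @inheritParams coreness_metric
#' @param K Number of groups, `1 <= K <= nrow(records)`.
#' @param seed Integer seed for tie-breaking.
#' @return A `ranked_instruments` data.frame: the instrument columns plus
#'   `criterion`, `metric_value`, `rank` (1 = most core) and `group`
#'   (1..K), ordered by rank.
#' @seealso [suggest_k()], [mr_core()]
#' @export
rank_and_group <- function(records, criterion = RANK_CRITERIA, K, seed = 1) {
  records <- as_instruments(records)
  criterion <- match.arg(criterion)
  J <- nrow(records)
  if (J == 0) data_error("no instruments to rank")
  if (!is.numeric(K) || length(K) != 1 || K != round(K))
    parameter_error("K must be a single integer")
  if (K < 1) parameter_error("K must be at least 1")
  if (K > J) parameter_error("K (%d) exceeds the number of instruments (%d)", K, J)

  records <- records[order(records$variant_id), , drop = FALSE]
  metric <- coreness_metric(records, criterion)
  tie_key <- with_seed(derive_seed(seed, "tie_break"), stats::runif(J))
  o <- order(-metric, tie_key)

  sizes <- c(rep(ceiling(J / K), J %% K), rep(floor(J / K), K - J %% K))
  out <- records[o, , drop = FALSE]
  out$criterion    <- criterion
  out$metric_value <- metric[o]
  out$rank         <- seq_len(J)
  out$group        <- rep.int(seq_len(K), sizes)
  rownames(out) <- NULL
  attr(out, "K") <- as.integer(K)
  attr(out, "seed") <- seed
  class(out) <- c("ranked_instruments", "data.frame")
  out
}

#' Suggest a number of instrument groups
#'
#' Returns `max(1, round(J / 7))`, which puts roughly 5-10 instruments in
#' each group — enough for the robust estimators (weighted median and mode
#' need at least 3) while keeping the putative core group small. Sensitivity
#' analyses should still be repeated over a range of `K`.
#'
#' @param J Number of instruments.
#' @return A positive integer.
#' @export
suggest_k <- function(J) {
  if (J < 1) parameter_error("J must be positive")
  max(1L, as.integer(round(J / 7)))
}
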