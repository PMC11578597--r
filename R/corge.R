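MR_METHODS <- c("ivw", "weighted_median", "weighted_mode")

estimate_one <- function(method, records, seed, n_boot, bandwidth_factor,
                         ivw_mode, min_instruments) {
  switch(method,
    ivw = mr_ivw(records, mode = ivw_mode),
    weighted_median = mr_weighted_median(records, n_boot = n_boot, seed = seed,
                                         min_instruments = min_instruments),
    weighted_mode = mr_weighted_mode(records, bandwidth_factor = bandwidth_factor,
                                     n_boot = n_boot, seed = seed,
                                     min_instruments = min_instruments),
    parameter_error("unknown method '%s'", method)
  )
}

missing_estimate_row <- function(k, scope, method, n, f, note) {
  data.frame(k = k, scope = scope, method = method, n_instruments = n,
             beta = NA_real_, se = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, pval = NA_real_, f_statistic = f,
             note = note, stringsAsFactors = FALSE)
}

#' Group-wise core-instrument sensitivity analysis
#'
#' The central analysis: instruments are ranked by putative coreness
#' ([rank_and_group()]), partitioned into `K` near-equal groups (group 1 =
#' putative core), and for every requested estimator both a group-specific
#' estimate (instruments of group `k` only) and a cumulative estimate
#' (groups 1..k pooled) are computed, together with each group's mean
#' F-statistic. The group-1 estimates are the primary result; a trajectory
#' that drifts as weaker instruments accumulate suggests bias from
#' horizontal pleiotropy among peripheral instruments.
#'
#' Every bootstrap receives a sub-seed derived from the master seed, the
#' method, the group index, and the scope via [derive_seed()], so results
#' are reproducible and independent of evaluation order; in particular the
#' cumulative estimate at `k = K` is bit-identical to a direct
#' all-instrument call with seed `derive_seed(seed, method, K,
#' "cumulative")`. At `k = 1` the group and cumulative instrument sets
#' coincide, so both rows are one computation under the cumulative-scope
#' seed (and with `K = 1` they also equal the all-instrument estimate
#' exactly). Groups smaller than an estimator's minimum instrument
#' count yield a missing estimate with a reason in the `note` column rather
#' than an error.
#'
#' @param records Harmonized instruments ([harmonize()] output or its
#'   `instruments` data.frame).
#' @param K Number of coreness groups ([suggest_k()] proposes one).
#' @param criterion Ranking metric, see [coreness_metric()].
#' @param methods Subset of `"ivw"`, `"weighted_median"`, `"weighted_mode"`.
#' @param seed Master seed for tie-breaking and bootstraps.
#' @param n_boot Bootstrap replicates for the median/mode standard errors.
#' @param bandwidth_factor Weighted-mode bandwidth multiplier.
#' @param ivw_mode `"multiplicative_random"` or `"fixed"`.
#' @param min_instruments Minimum group size for the median/mode estimators.
#' @return An object of class `mr_core_result` with elements `ranked`
#'   (the [rank_and_group()] table), `trajectory` (long-format estimates,
#'   see [trajectory_table()]), `group_f` (per-group mean F), `primary`
#'   (the group-1 rows of the trajectory) and `config`.
#' @examples
#' scen <- simulation_scenario(n_core = 5, n_peripheral = 30, theta = 0.2,
#'                             seed = 7)
#' sim <- simulate_summary_stats(scen)
#' h <- harmonize(sim$exposure, sim$outcome)
#' res <- mr_core(h, K = 5, seed = 1, n_boot = 100)
#' res$primary
#' @export
mr_core <- function(records, K, criterion = RANK_CRITERIA,
                    methods = MR_METHODS, seed = 1, n_boot = 1000,
                    bandwidth_factor = 1,
                    ivw_mode = c("multiplicative_random", "fixed"),
                    min_instruments = 3) {
  criterion <- match.arg(criterion)
  ivw_mode <- match.arg(ivw_mode)
  methods <- match.arg(methods, MR_METHODS, several.ok = TRUE)
  records <- as_instruments(records)
  if (nrow(records) == 0) data_error("no instruments supplied")

  ranked <- rank_and_group(records, criterion, K, seed = derive_seed(seed, "rank"))
  K <- attr(ranked, "K")

  group_f <- vapply(seq_len(K), function(k)
    mr_f_statistic(ranked[ranked$group == k, , drop = FALSE]), 0)

  min_needed <- function(method) if (method == "ivw") 1L else min_instruments
  rows <- list()
  for (method in methods) {
    for (k in seq_len(K)) {
      for (scope in c("group", "cumulative")) {
        sub <- if (scope == "group") ranked[ranked$group == k, , drop = FALSE]
               else ranked[ranked$group <= k, , drop = FALSE]
        f <- mr_f_statistic(sub)
        if (nrow(sub) < min_needed(method)) {
          rows[[length(rows) + 1]] <- missing_estimate_row(
            k, scope, method, nrow(sub), f,
            sprintf("fewer than %d instruments", min_needed(method)))
          next
        }
        ## At k = 1 the group and cumulative instrument sets coincide, so
        ## both rows share the cumulative-scope seed and are identical.
        seed_scope <- if (k == 1) "cumulative" else scope
        est <- estimate_one(method, sub,
                            seed = derive_seed(seed, method, k, seed_scope),
                            n_boot = n_boot,
                            bandwidth_factor = bandwidth_factor,
                            ivw_mode = ivw_mode,
                            min_instruments = min_instruments)
        rows[[length(rows) + 1]] <- data.frame(
          k = k, scope = scope, method = method,
          n_instruments = est$n_instruments, beta = est$beta, se = est$se,
          ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
          f_statistic = f, note = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  trajectory <- do.call(rbind, rows)
  rownames(trajectory) <- NULL

  structure(list(
    ranked = ranked,
    trajectory = trajectory,
    group_f = group_f,
    primary = trajectory[trajectory$k == 1 & trajectory$scope == "group", ,
                         drop = FALSE],
    config = list(K = K, criterion = criterion, methods = methods,
                  seed = seed, n_boot = n_boot,
                  bandwidth_factor = bandwidth_factor, ivw_mode = ivw_mode,
                  min_instruments = min_instruments)
  ), class = "mr_core_result")
}

#' Long-format trajectory table of a core-instrument analysis
#'
#' One row per (group `k`, scope, method): `scope` is `"group"` for the
#' estimate from group `k` alone and `"cumulative"` for groups 1..k pooled.
#' Columns `k`, `scope`, `method`, `n_instruments`, `beta`, `se`, `ci_low`,
#' `ci_high`, `pval`, `f_statistic`, `note` (reason when an estimate is
#' missing). Directly plottable with [plot_trajectory()].
#'
#' @param result An `mr_core_result` from [mr_core()].
#' @return A `data.frame`.
#' @export
trajectory_table <- function(result) {
  if (!inherits(result, "mr_core_result"))
    parameter_error("expected an mr_core_result")
  result$trajectory
}

#' @export
print.mr_core_result <- function(x, ...) {
  cat(sprintf("Core-instrument MR sensitivity analysis: J = %d instruments, K = %d groups, criterion = %s\n",
              nrow(x$ranked), x$config$K, x$config$criterion))
  cat(sprintf("Group-1 (putative core) mean F = %.1f; overall mean F = %.1f\n",
              x$group_f[1], mr_f_statistic(x$ranked)))
  cat("Primary (group-1) estimates:\n")
  print(x$primary[, c("method", "n_instruments", "beta", "se", "ci_low",
                      "ci_high", "pval")], row.names = FALSE)
  invisible(x)
}
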