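## Non-palindromic allele pairs (effect/other) used for simulated variants,
## plus the two palindromic pairs injected on request.
NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "G",  "A", "C",  "G", "A",  "C", "A",
  "T", "G",  "T", "C",  "G", "T",  "C", "T"
), ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)

#' Define a synthetic core/peripheral instrument architecture
#'
#' Describes a generative model for two-sample GWAS summary statistics that
#' instantiates the core gene hypothesis: a small set of core instruments
#' with large direct effects on the exposure and no pleiotropy, and a
#' larger set of peripheral instruments with smaller exposure effects that
#' may carry direct (pleiotropic) effects on the outcome.
#'
#' Per-allele exposure effects are drawn `b_j ~ Normal(0, scale^2)` with a
#' class-specific scale (`core_beta_scale > peripheral_beta_scale` encodes
#' the hypothesis). Direct variant-outcome effects `a_j` are 0 under
#' `pleiotropy_model = "none"`; under `"balanced"` they are
#' `Normal(0, pleiotropy_scale^2)`; under `"directional"` they are drawn
#' `Normal(pleiotropy_mean, pleiotropy_scale^2)` *in the orientation of the
#' exposure-increasing allele* (i.e. multiplied by `sign(b_j)`), since a
#' systematic direct effect is only defined relative to an allele
#' orientation — this makes directional pleiotropy shift all per-instrument
#' ratio estimates the same way, as it does in real data.
#'
#' @param n_core,n_peripheral Instrument counts (at least one in total).
#' @param theta True causal effect of the exposure on the outcome.
#' @param core_beta_scale,peripheral_beta_scale Standard deviations of the
#'   per-allele exposure effects (defaults 0.1 and 0.02 trait SD units).
#' @param pleiotropy_model `"none"`, `"balanced"`, or `"directional"`.
#' @param pleiotropy_mean Mean direct effect under the directional model
#'   (default 0.02; forced to 0 under `"balanced"`).
#' @param pleiotropy_scale SD of direct effects (default 0.01).
#' @param pleiotropy_targets `"peripheral_only"` (default) or `"all"`.
#' @param n_exposure,n_outcome GWAS sample sizes of the two non-overlapping
#'   samples (default 1e5 each).
#' @param eaf_range Bounds of the uniform allele-frequency distribution
#'   (default `c(0.05, 0.95)`).
#' @param palindrome_fraction Fraction of variants assigned a palindromic
#'   allele pair (default 0, so harmonization passes all variants).
#' @param seed Seed for [simulate_summary_stats()].
#' @return An object of class `mr_sim_scenario` (a validated list).
#' @seealso [simulate_summary_stats()], [run_benchmark()],
#'   [scenario_from_yaml()]
#' @export
simulation_scenario <- function(n_core = 10, n_peripheral = 90, theta = 0,
                                core_beta_scale = 0.1,
                                peripheral_beta_scale = 0.02,
                                pleiotropy_model = c("none", "balanced", "directional"),
                                pleiotropy_mean = 0.02,
                                pleiotropy_scale = 0.01,
                                pleiotropy_targets = c("peripheral_only", "all"),
                                n_exposure = 1e5, n_outcome = 1e5,
                                eaf_range = c(0.05, 0.95),
                                palindrome_fraction = 0, seed = 1) {
  pleiotropy_model <- match.arg(pleiotropy_model)
  pleiotropy_targets <- match.arg(pleiotropy_targets)
  if (pleiotropy_model == "balanced") pleiotropy_mean <- 0
  sc <- list(n_core = as.integer(n_core), n_peripheral = as.integer(n_peripheral),
             theta = theta, core_beta_scale = core_beta_scale,
             peripheral_beta_scale = peripheral_beta_scale,
             pleiotropy_model = pleiotropy_model,
             pleiotropy_mean = pleiotropy_mean,
             pleiotropy_scale = pleiotropy_scale,
             pleiotropy_targets = pleiotropy_targets,
             n_exposure = n_exposure, n_outcome = n_outcome,
             eaf_range = eaf_range,
             palindrome_fraction = palindrome_fraction, seed = seed)
  if (sc$n_core < 0 || sc$n_peripheral < 0)
    parameter_error("instrument counts must be non-negative")
  if (sc$n_core + sc$n_peripheral < 1)
    parameter_error("at least one instrument is required")
  if (sc$core_beta_scale < 0 || sc$peripheral_beta_scale < 0 ||
      sc$pleiotropy_scale < 0)
    parameter_error("effect scales must be non-negative")
  if (sc$n_exposure <= 0 || sc$n_outcome <= 0)
    parameter_error("sample sizes must be positive")
  if (length(eaf_range) != 2 || eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] > eaf_range[2])
    parameter_error("eaf_range must be increasing within (0, 1)")
  if (palindrome_fraction < 0 || palindrome_fraction > 1)
    parameter_error("palindrome_fraction must be in [0, 1]")
  structure(sc, class = "mr_sim_scenario")
}

#' Load a simulation scenario from a YAML file
#'
#' @param path YAML file whose keys are [simulation_scenario()] arguments.
#' @return An `mr_sim_scenario`.
#' @export
scenario_from_yaml <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  fields <- yaml::read_yaml(path)
  unknown <- setdiff(names(fields), names(formals(simulation_scenario)))
  if (length(unknown) > 0)
    format_error("unknown scenario field(s): %s", paste(unknown, collapse = ", "))
  do.call(simulation_scenario, fields)
}

#' Simulate two-sample GWAS summary statistics
#'
#' Generates one exposure and one outcome summary-statistics table plus a
#' ground-truth table under the architecture of a [simulation_scenario()].
#' For each variant `j`: the allele frequency `f_j` is uniform on
#' `eaf_range`; the true outcome effect is `theta * b_j + a_j`; observed
#' effects are the true effects plus independent sampling noise with the
#' standard GWAS approximation for a unit-variance trait,
#' `se_j = 1 / sqrt(2 f_j (1 - f_j) N)`; p-values are two-sided normal.
#' Exposure and outcome noise are independent (non-overlapping samples).
#' Alleles are non-palindromic pairs unless `palindrome_fraction > 0`.
#'
#' @param scenario An `mr_sim_scenario`.
#' @return A list with `exposure` and `outcome` (canonical summary-stat
#'   `data.frame`s: `variant_id`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) and `truth` (`variant_id`, `class`,
#'   `true_b`, `true_a`, `eaf`).
#' @export
simulate_summary_stats <- function(scenario) {
  if (!inherits(scenario, "mr_sim_scenario"))
    parameter_error("expected an mr_sim_scenario; see simulation_scenario()")
  sc <- scenario
  J <- sc$n_core + sc$n_peripheral
  with_seed(sc$seed, {
    class <- rep(c("core", "peripheral"), c(sc$n_core, sc$n_peripheral))
    scale <- ifelse(class == "core", sc$core_beta_scale, sc$peripheral_beta_scale)
    b <- stats::rnorm(J, 0, scale)

    a <- numeric(J)
    if (sc$pleiotropy_model != "none") {
      target <- if (sc$pleiotropy_targets == "all") rep(TRUE, J)
                else class == "peripheral"
      draw <- stats::rnorm(J, sc$pleiotropy_mean, sc$pleiotropy_scale)
      ## Directional effects act along the exposure-increasing allele.
      if (sc$pleiotropy_model == "directional") draw <- sign(b) * draw
      a[target] <- draw[target]
    }
    g <- sc$theta * b + a

    f <- stats::runif(J, sc$eaf_range[1], sc$eaf_range[2])
    n_pal <- round(J * sc$palindrome_fraction)
    pal <- seq_len(J) <= n_pal
    idx_pal <- sample(nrow(PALINDROMIC_PAIRS), J, replace = TRUE)
    idx_non <- sample(nrow(NONPALINDROMIC_PAIRS), J, replace = TRUE)
    ea <- ifelse(pal, PALINDROMIC_PAIRS[idx_pal, 1], NONPALINDROMIC_PAIRS[idx_non, 1])
    oa <- ifelse(pal, PALINDROMIC_PAIRS[idx_pal, 2], NONPALINDROMIC_PAIRS[idx_non, 2])

    se_e <- 1 / sqrt(2 * f * (1 - f) * sc$n_exposure)
    se_o <- 1 / sqrt(2 * f * (1 - f) * sc$n_outcome)
    beta_e <- b + stats::rnorm(J, 0, se_e)
    beta_o <- g + stats::rnorm(J, 0, se_o)

    id <- sprintf("sv%05d", seq_len(J))
    table_of <- function(beta, se, n) data.frame(
      variant_id = id, effect_allele = ea, other_allele = oa, eaf = f,
      beta = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)), n = n,
      stringsAsFactors = FALSE)
    list(
      exposure = table_of(beta_e, se_e, sc$n_exposure),
      outcome  = table_of(beta_o, se_o, sc$n_outcome),
      truth = data.frame(variant_id = id, class = class, true_b = b,
                         true_a = a, eaf = f, stringsAsFactors = FALSE)
    )
  })
}
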