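# Random harmonized instrument sets used across the estimator and
# orchestration tests. Built in code so no fixture files are needed.
make_instruments <- function(J, seed = 1, theta = 0.2) {
  set.seed(seed)
  b <- rnorm(J, 0, 0.1)
  b <- b + sign(b) * 0.02  # keep exposure effects away from zero, without ties
  se_e <- runif(J, 0.005, 0.02)
  se_o <- runif(J, 0.005, 0.02)
  eaf <- runif(J, 0.05, 0.95)
  beta_o <- theta * b + rnorm(J, 0, se_o)
  data.frame(
    variant_id = sprintf("rs%05d", sample.int(99999, J)),
    effect_allele = "A", other_allele = "G",
    eaf_exposure = eaf, beta_exposure = b, se_exposure = se_e,
    pval_exposure = 2 * pnorm(-abs(b / se_e)), n_exposure = 1e5,
    eaf_outcome = eaf, beta_outcome = beta_o, se_outcome = se_o,
    pval_outcome = 2 * pnorm(-abs(beta_o / se_o)), n_outcome = 1e5,
    stringsAsFactors = FALSE
  )
}

# Ratios and inverse-variance weights in the canonical (variant_id) order
# that the estimators use internally.
ratios_of <- function(records) {
  records <- records[order(records$variant_id), ]
  list(b = records$beta_outcome / records$beta_exposure,
       se = records$se_outcome / abs(records$beta_exposure))
}

# Minimal valid summary table for io tests.
toy_summary <- function(ids = c("rs1", "rs2", "rs3")) {
  n <- length(ids)
  data.frame(
    variant_id = ids, effect_allele = "A", other_allele = "G",
    eaf = seq(0.2, 0.4, length.out = n), beta = seq(0.05, 0.15, length.out = n),
    se = 0.01, pval = 1e-10, n = 5e4, stringsAsFactors = FALSE
  )
}
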