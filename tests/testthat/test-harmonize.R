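# Toy exposure/outcome pairs exercising every allele configuration.
two_tables <- function() {
  exposure <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "T", "C", "G"),
    other_allele  = c("G", "C", "A", "T"),
    eaf = c(0.3, 0.2, 0.25, 0.4),
    beta = c(0.10, -0.08, 0.05, 0.12),
    se = c(0.01, 0.012, 0.009, 0.02),
    pval = 1e-9, n = 5e4, stringsAsFactors = FALSE)
  outcome <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("G", "T", "G", "A"),  # swapped, direct, complement, complement-swapped
    other_allele  = c("A", "C", "T", "C"),
    eaf = c(0.7, 0.2, 0.25, 0.6),
    beta = c(0.05, -0.02, 0.01, 0.03),
    se = c(0.02, 0.02, 0.02, 0.02),
    pval = 0.01, n = 8e4, stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome)
}

test_that("allele swaps and strand flips are aligned to the exposure effect allele", {
  tt <- two_tables()
  h <- harmonize(tt$exposure, tt$outcome)
  inst <- h$instruments
  expect_equal(inst$variant_id, c("rs1", "rs2", "rs3", "rs4"))
  expect_equal(inst$effect_allele, tt$exposure$effect_allele)
  # rs1 swapped -> sign flip and eaf complement
  expect_equal(inst$beta_outcome[1], -0.05)
  expect_equal(inst$eaf_outcome[1], 0.3)
  # rs2 direct -> untouched
  expect_equal(inst$beta_outcome[2], -0.02)
  # rs3 strand complement only -> untouched values
  expect_equal(inst$beta_outcome[3], 0.01)
  # rs4 complement + swap -> sign flip
  expect_equal(inst$beta_outcome[4], -0.03)
  expect_equal(inst$eaf_outcome[4], 0.4)
})

test_that("palindromic variants follow the minor-allele-frequency rule", {
  exposure <- data.frame(
    variant_id = c("p1", "p2", "p3"),
    effect_allele = c("A", "C", "A"), other_allele = c("T", "G", "T"),
    eaf = c(0.45, 0.30, 0.30), beta = c(0.1, 0.1, 0.1), se = 0.01,
    pval = 1e-9, n = 5e4, stringsAsFactors = FALSE)
  outcome <- exposure
  outcome$beta <- 0.05
  outcome$eaf <- c(0.45, 0.30, 0.72)  # p3 frequency-discordant
  h <- harmonize(exposure, outcome, palindrome_maf_threshold = 0.42)
  # MAF 0.45 > 0.42 -> excluded as ambiguous
  expect_false("p1" %in% h$instruments$variant_id)
  expect_match(h$rejects$reason[h$rejects$variant_id == "p1"], "ambiguous")
  # MAF 0.30 <= 0.42 concordant -> retained unchanged
  expect_equal(h$instruments$beta_outcome[h$instruments$variant_id == "p2"], 0.05)
  # discordant minor allele -> flipped
  expect_equal(h$instruments$beta_outcome[h$instruments$variant_id == "p3"], -0.05)
  expect_equal(h$instruments$eaf_outcome[h$instruments$variant_id == "p3"], 0.28)
  # strict mode drops all palindromes
  hs <- harmonize(exposure, outcome, strict_palindromes = TRUE)
  expect_equal(nrow(hs$instruments), 0)
})

test_that("non-SNVs, incompatible alleles, zero exposure effects, and missing variants are rejected with reasons", {
  tt <- two_tables()
  tt$exposure <- rbind(tt$exposure, data.frame(
    variant_id = c("rs5", "rs6", "rs7", "rs8"),
    effect_allele = c("AT", "A", "A", "A"), other_allele = c("A", "G", "G", "G"),
    eaf = 0.3, beta = c(0.1, 0.1, 0, 0.1), se = 0.01, pval = 1e-9, n = 5e4))
  tt$outcome <- rbind(tt$outcome, data.frame(
    variant_id = c("rs5", "rs6", "rs7"),
    effect_allele = c("AT", "A", "A"), other_allele = c("A", "C", "G"),
    eaf = 0.3, beta = 0.02, se = 0.02, pval = 0.01, n = 8e4))
  h <- harmonize(tt$exposure, tt$outcome)
  reason_of <- function(id) h$rejects$reason[h$rejects$variant_id == id]
  expect_match(reason_of("rs5"), "SNV")
  expect_match(reason_of("rs6"), "incompatible")
  expect_match(reason_of("rs7"), "zero exposure")
  expect_match(reason_of("rs8"), "missing in outcome")
  # record conservation over the intersection
  n_harm_rejects <- sum(h$rejects$stage == "harmonization")
  expect_equal(nrow(h$instruments) + n_harm_rejects, 7)  # 7 shared ids
  expect_error(harmonize(tt$exposure[0, ], tt$outcome),
               "no shared", class = "mrcore_data_error")
})

test_that("harmonization is idempotent and invariant to whole-strand relabeling", {
  records <- make_instruments(20, seed = 11)
  exposure <- with(records, data.frame(
    variant_id = variant_id, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf_exposure, beta = beta_exposure,
    se = se_exposure, pval = pval_exposure, n = n_exposure))
  outcome <- with(records, data.frame(
    variant_id = variant_id, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf_outcome, beta = beta_outcome,
    se = se_outcome, pval = pval_outcome, n = n_outcome))

  h1 <- harmonize(exposure, outcome)
  expect_equal(h1$instruments[, names(records)], records, tolerance = 1e-15)

  # strand-complementing every (non-palindromic) outcome record changes nothing
  flipped <- outcome
  flipped$effect_allele <- chartr("ACGT", "TGCA", flipped$effect_allele)
  flipped$other_allele <- chartr("ACGT", "TGCA", flipped$other_allele)
  h2 <- harmonize(exposure, flipped)
  expect_identical(h1$instruments, h2$instruments)

  # swapping exposure alleles with negated beta and complemented eaf leaves
  # the causal ratios unchanged
  swapped <- exposure
  swapped$effect_allele <- exposure$other_allele
  swapped$other_allele <- exposure$effect_allele
  swapped$beta <- -exposure$beta
  swapped$eaf <- 1 - exposure$eaf
  h3 <- harmonize(swapped, outcome)
  expect_equal(h3$instruments$beta_outcome / h3$instruments$beta_exposure,
               h1$instruments$beta_outcome / h1$instruments$beta_exposure,
               tolerance = 1e-12)
})
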