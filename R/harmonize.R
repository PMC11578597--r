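complement_allele <- function(x) chartr("ACGT", "TGCA", x)

is_snv <- function(x) x %in% c("A", "C", "G", "T")

## A palindromic (strand-ambiguous) variant carries an allele pair that is
## its own reverse complement: {A,T} or {C,G}.
is_palindromic_pair <- function(ea, oa) ea == complement_allele(oa)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association statistics of every shared variant to the
#' exposure's effect allele. Outcome records whose alleles are swapped
#' relative to the exposure have their effect sign flipped and effect-allele
#' frequency replaced by its complement; records matching only under strand
#' complement (A<->T, C<->G) are complemented first. Palindromic variants
#' cannot be strand-resolved from alleles alone: those whose exposure minor
#' allele frequency exceeds `palindrome_maf_threshold` are excluded as
#' frequency-ambiguous, while the remainder are aligned by allele-frequency
#' concordance (the exposure and outcome minor alleles are assumed to be the
#' same allele). Variants that are not biallelic single-nucleotide variants,
#' have incompatible alleles, or have a zero exposure effect (unusable in
#' ratio estimates) are excluded with a reason. Nothing is silently dropped:
#' every excluded variant appears in the rejection report.
#'
#' @param exposure,outcome A `gwas_summary` from [read_summary_table()] or a
#'   `data.frame` with the canonical columns.
#' @param palindrome_maf_threshold Exposure minor-allele-frequency cutoff in
#'   (0, 0.5] above which palindromic variants are excluded; default 0.42.
#' @param strict_palindromes If `TRUE`, exclude all palindromic variants
#'   regardless of frequency.
#' @return An object of class `mr_harmonized`: list with `instruments` (a
#'   `data.frame` with one row per harmonized variant; columns
#'   `variant_id`, `effect_allele`, `other_allele`, then `eaf`, `beta`,
#'   `se`, `pval`, `n` suffixed by `_exposure` / `_outcome`) and `rejects`
#'   (columns `variant_id`, `stage`, `reason`).
#' @examples
#' exp <- data.frame(variant_id = "rs1", effect_allele = "A",
#'                   other_allele = "G", beta = 0.1, se = 0.01)
#' out <- data.frame(variant_id = "rs1", effect_allele = "G",
#'                   other_allele = "A", beta = 0.05, se = 0.02)
#' harmonize(exp, out)$instruments$beta_outcome  # -0.05: swapped alleles
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_threshold = 0.42,
                      strict_palindromes = FALSE) {
  if (!is.numeric(palindrome_maf_threshold) ||
      palindrome_maf_threshold <= 0 || palindrome_maf_threshold > 0.5)
    parameter_error("palindrome_maf_threshold must be in (0, 0.5]")

  take <- function(x, stage) {
    if (inherits(x, "gwas_summary")) {
      rej <- x$rejects
      rej$stage <- rep(paste0(stage, "_read"), nrow(rej))
      return(list(stats = x$stats, rejects = rej))
    }
    validate_summary(as.data.frame(x), stage = paste0(stage, "_read"))
  }
  e <- take(exposure, "exposure")
  o <- take(outcome, "outcome")
  rejects <- rbind(e$rejects, o$rejects)

  shared <- intersect(e$stats$variant_id, o$stats$variant_id)
  rejects <- rbind(
    rejects,
    reject_rows(setdiff(e$stats$variant_id, shared), "intersection",
                "missing in outcome"),
    reject_rows(setdiff(o$stats$variant_id, shared), "intersection",
                "missing in exposure")
  )
  if (length(shared) == 0) data_error("no shared instruments")

  ex <- e$stats[match(shared, e$stats$variant_id), ]
  ou <- o$stats[match(shared, o$stats$variant_id), ]

  reason <- rep(NA_character_, length(shared))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why

  snv <- is_snv(ex$effect_allele) & is_snv(ex$other_allele) &
    is_snv(ou$effect_allele) & is_snv(ou$other_allele)
  flag(!snv, "not a biallelic SNV")

  flag(snv & ex$beta == 0, "zero exposure effect")

  ## Allele-configuration classification (only meaningful for SNVs).
  direct  <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  comp    <- complement_allele(ou$effect_allele) == ex$effect_allele &
    complement_allele(ou$other_allele) == ex$other_allele
  comp_swapped <- complement_allele(ou$effect_allele) == ex$other_allele &
    complement_allele(ou$other_allele) == ex$effect_allele
  palin <- snv & is_palindromic_pair(ex$effect_allele, ex$other_allele)
  flag(snv & !(direct | swapped | comp | comp_swapped), "incompatible alleles")

  if (strict_palindromes) {
    flag(palin, "palindromic (strict mode)")
  } else {
    maf_exp <- pmin(ex$eaf, 1 - ex$eaf)
    flag(palin & is.na(ex$eaf), "palindromic, missing exposure frequency")
    flag(palin & !is.na(maf_exp) & maf_exp > palindrome_maf_threshold,
         "palindromic, ambiguous frequency")
    flag(palin & is.na(ou$eaf), "palindromic, missing outcome frequency")
  }

  ## Align outcome to the exposure's effect allele. For palindromes both the
  ## direct and complemented configurations are label-identical, so labels
  ## first (swap if needed), then allele-frequency concordance decides the
  ## strand: discordant minor-allele frequencies imply opposite coding.
  flip <- rep(FALSE, length(shared))
  flip[swapped | comp_swapped] <- TRUE
  keep_palin <- palin & is.na(reason)
  if (any(keep_palin)) {
    eaf_aligned <- ifelse(flip, 1 - ou$eaf, ou$eaf)
    discord <- keep_palin & ((ex$eaf < 0.5) != (eaf_aligned < 0.5))
    flip <- xor(flip, discord)
  }

  keep <- is.na(reason)
  rejects <- rbind(rejects,
                   reject_rows(shared[!keep], "harmonization", reason[!keep]))

  inst <- data.frame(
    variant_id    = ex$variant_id,
    effect_allele = ex$effect_allele,
    other_allele  = ex$other_allele,
    eaf_exposure  = ex$eaf,
    beta_exposure = ex$beta,
    se_exposure   = ex$se,
    pval_exposure = ex$pval,
    n_exposure    = ex$n,
    eaf_outcome   = ifelse(flip, 1 - ou$eaf, ou$eaf),
    beta_outcome  = ifelse(flip, -ou$beta, ou$beta),
    se_outcome    = ou$se,
    pval_outcome  = ou$pval,
    n_outcome     = ou$n,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(inst) <- NULL

  structure(list(instruments = inst, rejects = rejects),
            class = "mr_harmonized")
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %d retained, %d rejected\n",
              nrow(x$instruments), nrow(x$rejects)))
  if (nrow(x$rejects) > 0) {
    tab <- table(x$rejects$reason)
    for (r in names(tab)) cat(sprintf("  %-40s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

## Accept either the harmonize() result or a bare instrument data.frame.
as_instruments <- function(records) {
  if (inherits(records, "mr_harmonized")) records <- records$instruments
  if (!is.data.frame(records))
    data_error("expected a harmonized instrument data.frame")
  missing <- setdiff(c("variant_id", "beta_exposure", "se_exposure",
                       "beta_outcome", "se_outcome"), names(records))
  if (length(missing) > 0)
    data_error("instrument table lacks column(s): %s",
               paste(missing, collapse = ", "))
  records
}
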