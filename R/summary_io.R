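## Canonical per-trait summary-statistic columns. `beta` is the per-allele
## effect of the effect allele, `se` its standard error, `eaf` the effect
## allele frequency, `n` the analysis sample size.
SUMMARY_REQUIRED <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
SUMMARY_OPTIONAL <- c("eaf", "pval", "n")
SUMMARY_COLUMNS  <- c(SUMMARY_REQUIRED[1:3], "eaf", "beta", "se", "pval", "n")

INSTRUMENT_COLUMNS <- c(
  "variant_id", "effect_allele", "other_allele",
  "eaf_exposure", "beta_exposure", "se_exposure", "pval_exposure", "n_exposure",
  "eaf_outcome", "beta_outcome", "se_outcome", "pval_outcome", "n_outcome"
)

empty_rejects <- function() {
  data.frame(variant_id = character(), stage = character(),
             reason = character(), stringsAsFactors = FALSE)
}

reject_rows <- function(ids, stage, reason) {
  if (length(ids) == 0) return(empty_rejects())
  data.frame(variant_id = as.character(ids), stage = stage, reason = reason,
             stringsAsFactors = FALSE)
}

## Row-level invariant checks shared by the reader and by harmonize() when it
## is handed a bare data.frame. Returns list(stats = valid rows, rejects).
validate_summary <- function(df, stage = "read") {
  df$variant_id    <- as.character(df$variant_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele  <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df <- df[, SUMMARY_COLUMNS]

  dup <- unique(df$variant_id[duplicated(df$variant_id)])
  if (length(dup) > 0)
    data_error("duplicate variant_id: %s", paste(dup, collapse = ", "))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(df$variant_id) | df$variant_id == "", "missing variant_id")
  flag(is.na(df$effect_allele) | is.na(df$other_allele) |
         df$effect_allele == "" | df$other_allele == "", "missing allele")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(is.na(df$beta) | !is.finite(df$beta), "missing or non-finite beta")
  flag(is.na(df$se) | !is.finite(df$se) | df$se <= 0, "nonpositive se")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0, 1)")
  flag(!is.na(df$pval) & (df$pval < 0 | df$pval > 1), "pval outside [0, 1]")
  flag(!is.na(df$n) & df$n <= 0, "nonpositive sample size")

  bad <- !is.na(reason)
  list(stats = df[!bad, , drop = FALSE],
       rejects = reject_rows(df$variant_id[bad], stage, reason[bad]))
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited table of per-variant association
#' statistics (one row per variant, header row required), optionally
#' renaming foreign column headers to the canonical names, validates row
#' invariants, and collects failing rows into a rejection report instead of
#' silently dropping them.
#'
#' Canonical columns are `variant_id`, `effect_allele`, `other_allele`,
#' `beta`, `se` (required) and `eaf`, `pval`, `n` (optional; missing values
#' written as `NA`). Gzip-compressed files are read transparently.
#'
#' @param path Path to the table.
#' @param column_map Optional named character vector mapping file headers to
#'   canonical names, e.g. `c(rsid = "variant_id", ea = "effect_allele")`.
#' @param delim Field delimiter; by default sniffed from the header line.
#' @return An object of class `gwas_summary`: a list with elements `stats`
#'   (validated `data.frame`), `rejects` (rejection report with columns
#'   `variant_id`, `stage`, `reason`) and `source`.
#' @seealso [harmonize()], [write_instruments()]
#' @export
read_summary_table <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  delim <- delim %||% sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  missing <- setdiff(SUMMARY_REQUIRED, names(df))
  if (length(missing) > 0)
    format_error("missing required column(s): %s", paste(missing, collapse = ", "))
  out <- validate_summary(df)
  structure(list(stats = out$stats, rejects = out$rejects, source = path),
            class = "gwas_summary")
}

#' @export
print.gwas_summary <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d variants (%d rejected) from %s\n",
              nrow(x$stats), nrow(x$rejects), x$source %||% "<data.frame>"))
  invisible(x)
}

#' Write harmonized instruments to a TSV file
#'
#' Writes the canonical tab-delimited instrument table (missing values as
#' `NA`). The output round-trips losslessly through [read_instruments()] and
#' re-harmonization.
#'
#' @param records Harmonized instrument `data.frame` (see [harmonize()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_instruments <- function(records, path) {
  if (inherits(records, "mr_harmonized")) records <- records$instruments
  if (nrow(records) == 0) warning("writing header-only file: no instruments")
  utils::write.table(records[, INSTRUMENT_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a harmonized instrument table written by [write_instruments()]
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with the canonical instrument columns.
#' @export
read_instruments <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          comment.char = "")
  missing <- setdiff(INSTRUMENT_COLUMNS, names(df))
  if (length(missing) > 0)
    format_error("missing required column(s): %s", paste(missing, collapse = ", "))
  df$variant_id <- as.character(df$variant_id)
  df
}
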