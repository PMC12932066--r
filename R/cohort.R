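# Cohort summary statistics for mould-guided ex vivo biopsy cohorts.
# A 12-patient reference cohort from a mould-biopsy feasibility study is
# packaged in inst/extdata/cohort_table.csv; its mould-biopsy Gleason Grade
# Group column is `mould_gg` (empty = no cancer found ex vivo).

#' Read a cohort table
#'
#' Columns: `n`, `psa_ng_ml`, `psa_density`, `prostate_size_cc`, `pirads`,
#' `lesion_volumes_cc` (semicolon-separated when a patient has several
#' MRI-positive lesions), `lesion_location`, `clinical_gg` (diagnostic
#' biopsy Gleason Grade Group), `mould_gg` (ex vivo mould biopsy GG, empty
#' if no cancer was obtained), `notes`.
#'
#' @param path CSV file path.
#' @return data.frame of class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = TRUE))
  text_cols <- intersect(c("lesion_volumes_cc", "notes"), hdr)
  cc <- if (length(text_cols))
    stats::setNames(rep("character", length(text_cols)), text_cols) else NA
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cc)
  required <- c("n", "psa_ng_ml", "psa_density", "prostate_size_cc", "pirads",
                "lesion_volumes_cc", "lesion_location", "clinical_gg",
                "mould_gg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 1) stop("cohort table is empty", call. = FALSE)
  gg_ok <- function(x) all(is.na(x) | (x >= 1 & x <= 5))
  stopifnot(all(df$pirads %in% 3:5), all(df$psa_density > 0),
            gg_ok(df$clinical_gg), gg_ok(df$mould_gg))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @rdname read_cohort_table
#' @export
load_reference_cohort <- function() {
  read_cohort_table(system.file("extdata", "cohort_table.csv",
                                package = "prostamould", mustWork = TRUE))
}

# round half away from zero to `digits` decimals (the convention of the
# printed clinical summaries; e.g. a median of 0.175 reports as 0.18)
round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Lesion volumes as a numeric vector
#'
#' Flattens the semicolon-separated `lesion_volumes_cc` column.
#'
#' @param table a `cohort_table`.
#' @return numeric vector of per-lesion volumes (cc).
#' @export
cohort_lesion_volumes <- function(table) {
  as.numeric(unlist(strsplit(table$lesion_volumes_cc, ";")))
}

#' Cohort summary statistics
#'
#' Medians (midpoint of the two central order statistics for even n) and
#' ranges of PSA, PSA density and prostate size, the cancer-positivity
#' fraction of the mould biopsies, and the grade-concordance fraction.
#' Reported medians are rounded half-away-from-zero to the precision these
#' quantities are conventionally printed at (2 dp for PSA and PSA density,
#' 1 dp for prostate size); ranges and fractions are exact.
#'
#' @param table a `cohort_table`.
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(table) {
  if (nrow(table) < 1) stop("empty cohort table", call. = FALSE)
  conc <- if (all(!is.na(table$clinical_gg)) && all(!is.na(table$mould_gg)))
    cohort_concordance(table) else NA_real_
  structure(list(
    n = nrow(table),
    median_psa = round_half_away(stats::median(table$psa_ng_ml), 2),
    psa_range = range(table$psa_ng_ml),
    median_psa_density = round_half_away(stats::median(table$psa_density), 2),
    median_size_cc = round_half_away(stats::median(table$prostate_size_cc), 1),
    size_range_cc = range(table$prostate_size_cc),
    positivity_fraction = cohort_positivity(table),
    concordance_fraction = conc),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0("cohort_summary (n=%d)\n  PSA median %.2f ng/ml (%.2f-%.2f)\n",
           "  PSA density median %.2f\n  prostate size median %.1f cc\n",
           "  mould-biopsy positivity %.0f%%, GG concordance %s\n"),
    x$n, x$median_psa, x$psa_range[1], x$psa_range[2],
    x$median_psa_density, x$median_size_cc, 100 * x$positivity_fraction,
    if (is.na(x$concordance_fraction)) "NA"
    else sprintf("%.0f%%", 100 * x$concordance_fraction)))
  invisible(x)
}

#' Grade concordance and cancer positivity
#'
#' `cohort_concordance()`: fraction of patients whose mould-biopsy Gleason
#' Grade Group equals the diagnostic-biopsy grade (every row must carry
#' both grades). `cohort_positivity()`: fraction of patients whose mould
#' biopsy yielded cancer, i.e. has any grade recorded.
#'
#' @param table a `cohort_table`.
#' @return fraction in `[0, 1]`.
#' @export
cohort_concordance <- function(table) {
  bad <- which(is.na(table$clinical_gg) | is.na(table$mould_gg))
  if (length(bad))
    stop("missing Gleason grade in cohort row(s): ",
         paste(table$n[bad], collapse = ", "), call. = FALSE)
  mean(table$clinical_gg == table$mould_gg)
}

#' @rdname cohort_concordance
#' @export
cohort_positivity <- function(table) {
  mean(!is.na(table$mould_gg))
}
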