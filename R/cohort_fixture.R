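#' Load the packaged congenital-hypothyroidism twin cohort table
#'
#' A machine-readable transcription of the published clinical and molecular
#' characteristics of 23 twin pairs (10 MZ, 13 DZ; 27 congenital-
#' hypothyroidism cases and 19 unaffected co-twin controls), including the
#' per-subject hypo-methylated SEM counts. Case status follows the affected
#' (bold-row) annotation of the source tables, not the final diagnosis at
#' re-evaluation: one discordant MZ control was euthyroid at sampling and
#' diagnosed with hypothyroidism only years later, so it remains a control.
#'
#' The loader validates the transcription against frozen checksums (record
#' count, case count, total hypo-SEM count) and the structural invariants
#' (23 pairs of two, zygosity constant within pair).
#'
#' @return data.frame of class `clinical_records` with columns `pair`,
#'   `twin`, `zygosity`, `sex`, `is_case`, `bsTSH_screening`,
#'   `sTSH_diagnosis`, `FT4_diagnosis`, `morphology`, `age_at_sampling`,
#'   `final_diagnosis` (P/T/E), `mutations` (semicolon-separated
#'   "GENE variant (class)" or "WT"), `gestational_age_weeks`, `hypo_sems`.
#' @export
load_clinical_fixture <- function() {
  path <- system.file("extdata", "ch_twin_cohort.csv", package = "semscan",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bsTSH_screening = "character",
                                       sTSH_diagnosis = "character",
                                       FT4_diagnosis = "character"))
  if (nrow(df) != 46L || sum(df$is_case) != 27L || sum(df$hypo_sems) != 195094L)
    stop("clinical fixture checksum mismatch: packaging error")
  stopifnot(all(df$hypo_sems > 0L),
            all(df$morphology %in% c("GIS", "athyreosis", "hemiagenesis",
                                     "ectopy", "hypoplasia")),
            all(df$final_diagnosis %in% c("P", "T", "E")),
            all(table(df$pair) == 2L),
            all(tapply(df$zygosity, df$pair, function(z) length(unique(z))) == 1L))
  class(df) <- c("clinical_records", "data.frame")
  df
}

#' @export
print.clinical_records <- function(x, ...) {
  cat(sprintf("clinical_records: %d subjects in %d twin pairs (%d cases, %d controls)\n",
              nrow(x), length(unique(x$pair)), sum(x$is_case), sum(!x$is_case)))
  invisible(x)
}

#' Convert clinical records to a sample sheet
#'
#' @param records `clinical_records` from [load_clinical_fixture()].
#' @return A `sample_sheet` with sample ids `<pair><twin>` (e.g. "8A"),
#'   family = pair, groups case/control by `is_case`.
#' @export
clinical_to_sample_sheet <- function(records) {
  as_sample_sheet(data.frame(
    sample_id = paste0(records$pair, records$twin),
    family_id = sprintf("F%02d", records$pair),
    pair_id = sprintf("P%02d", records$pair),
    zygosity = records$zygosity,
    group = ifelse(records$is_case == 1L, "case", "control"),
    sex = records$sex, batch = "b1", stringsAsFactors = FALSE))
}

#' Cohort summary counts from the clinical fixture
#'
#' @param records `clinical_records`.
#' @return Named integer vector: cases, controls, MZ/DZ pairs, concordant
#'   pairs (both twins cases), morphology classes among cases, dysgenesis
#'   total, GIS cases, permanent and transient among cases, permanent among
#'   GIS cases, and cases carrying at least one (non-WT) variant.
#' @export
cohort_counts <- function(records) {
  cases <- records[records$is_case == 1L, , drop = FALSE]
  pair_case_n <- tapply(records$is_case, records$pair, sum)
  gis_cases <- cases[cases$morphology == "GIS", , drop = FALSE]
  c(n_cases = nrow(cases),
    n_controls = sum(records$is_case == 0L),
    n_pairs_mz = length(unique(records$pair[records$zygosity == "MZ"])),
    n_pairs_dz = length(unique(records$pair[records$zygosity == "DZ"])),
    n_concordant_pairs = sum(pair_case_n == 2L),
    athyreosis = sum(cases$morphology == "athyreosis"),
    hemiagenesis = sum(cases$morphology == "hemiagenesis"),
    ectopy = sum(cases$morphology == "ectopy"),
    hypoplasia = sum(cases$morphology == "hypoplasia"),
    dysgenesis = sum(cases$morphology != "GIS"),
    gis = nrow(gis_cases),
    permanent = sum(cases$final_diagnosis == "P"),
    transient = sum(cases$final_diagnosis == "T"),
    permanent_gis = sum(gis_cases$final_diagnosis == "P"),
    variant_carriers = sum(cases$mutations != "WT"))
}

#' Log hypo-SEM burden quantiles per group from the clinical fixture
#'
#' Builds a burden table from the fixture's hypo-SEM counts and summarises
#' the natural-log counts per group via [summarize_burden()].
#'
#' @param records `clinical_records`.
#' @param digits Rounding applied to the quantiles; default 3 (the precision
#'   the summaries are reported at). Use `NULL` for no rounding.
#' @return data.frame with one row per group: `group`, `n`, `median`, `q1`,
#'   `q3` on the ln scale.
#' @export
table_burden_stats <- function(records, digits = 3L) {
  sheet <- clinical_to_sample_sheet(records)
  burden <- data.frame(sample_id = sheet$sample_id,
                       n_hypo = records$hypo_sems,
                       n_hyper = 0L, stringsAsFactors = FALSE)
  burden$ln_hypo <- log(burden$n_hypo)
  burden$ln_hyper <- NA_real_
  out <- summarize_burden(burden, sheet, "hypo")
  if (!is.null(digits))
    out[c("median", "q1", "q3")] <- round(out[c("median", "q1", "q3")], digits)
  out[, c("group", "n", "median", "q1", "q3")]
}

#' Mixed-model group comparison of the fixture's hypo-SEM burdens
#'
#' Fits the log hypo-SEM burden mixed model (case/control fixed effect, sex
#' covariate, family random intercept) to the packaged cohort table.
#'
#' @param records `clinical_records`.
#' @return A `sem_burden_fit`.
#' @export
fixture_burden_model <- function(records = load_clinical_fixture()) {
  sheet <- clinical_to_sample_sheet(records)
  burden <- data.frame(sample_id = sheet$sample_id,
                       n_hypo = records$hypo_sems, n_hyper = 0L,
                       stringsAsFactors = FALSE)
  burden$ln_hypo <- log(burden$n_hypo)
  burden$ln_hyper <- NA_real_
  compare_burden_mixed(burden, sheet, "hypo", covariates = "sex")
}
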