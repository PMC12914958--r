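#' The concomitant cytotoxic chemotherapy panel
#'
#' The fourteen cytotoxic agents used to classify reports into the
#' concomitant-chemotherapy vs no-chemotherapy subgroups: carboplatin,
#' cisplatin, paclitaxel, docetaxel, nab-paclitaxel, pemetrexed,
#' gemcitabine, cyclophosphamide, etoposide, fluorouracil, oxaliplatin,
#' irinotecan, vinorelbine and doxorubicin.  Names are returned in
#' normalized form (see [normalize_text()]); brand names are handled via
#' [default_synonyms()].
#'
#' @return character vector of normalized panel drug names.
#' @export
chemo_panel <- function() {
  normalize_text(c(
    "carboplatin", "cisplatin", "paclitaxel", "docetaxel",
    "nab-paclitaxel", "pemetrexed", "gemcitabine", "cyclophosphamide",
    "etoposide", "fluorouracil", "oxaliplatin", "irinotecan",
    "vinorelbine", "doxorubicin"
  ))
}

#' Restrict to serious reports
#'
#' Keeps reports with at least one FDA seriousness outcome flag (death,
#' life-threatening, hospitalization, disability, congenital anomaly, or
#' other serious outcome).
#'
#' @param data a `faers_data` object.
#' @return a `faers_data`.
#' @export
filter_serious <- function(data) {
  stopifnot(inherits(data, "faers_data"))
  filter_reports(data, data$demo$caseid[data$demo$serious])
}

#' Build the primary-suspect + serious cohort for a drug
#'
#' Retains reports in which the drug appears as the Primary Suspect
#' (`role_cod == "PS"`, matched on the normalized drug name) and at least
#' one seriousness flag is set.  An absent drug yields an empty cohort
#' with a warning, not an error.
#'
#' @param data a deduplicated `faers_data`.
#' @param drug drug name (normalized internally).
#' @return a `faers_data` cohort.
#' @export
filter_primary_suspect_serious <- function(data, drug) {
  stopifnot(inherits(data, "faers_data"))
  drug_norm <- normalize_text(drug, default_synonyms())
  ps_ids <- unique(data$drug$caseid[data$drug$role_cod == "PS" &
                                      data$drug$drugname_norm == drug_norm])
  if (length(ps_ids) == 0) {
    warning(sprintf("drug '%s' never appears as primary suspect; empty cohort",
                    drug_norm), call. = FALSE)
  }
  serious_ids <- data$demo$caseid[data$demo$serious]
  filter_reports(data, intersect(ps_ids, serious_ids))
}

#' Select the cohort reporting one Preferred Term
#'
#' Event cohorts are defined per Preferred Term by exact, case-insensitive
#' string match: a report belongs to the cohort for `pt` if and only if
#' one of its reaction entries carries exactly that PT.  Because matching
#' is per-PT, "Febrile neutropenia" reports are *not* members of the
#' "Neutropenia" cohort (the two PTs code distinct event concepts), while
#' a report listing both PTs belongs to both cohorts.
#'
#' @param data a `faers_data` cohort.
#' @param pt Preferred Term string.
#' @return a `faers_data` sub-cohort.
#' @export
select_pt_cohort <- function(data, pt) {
  stopifnot(inherits(data, "faers_data"))
  if (!nzchar(pt)) stop("pt must be a non-empty string", call. = FALSE)
  ids <- unique(data$reac$caseid[toupper(data$reac$pt) == toupper(pt)])
  filter_reports(data, ids)
}

#' Classify reports by concomitant chemotherapy
#'
#' A report is in the chemotherapy group if at least one of its drug
#' entries with role concomitant (`C`) or interacting (`I`) has a
#' normalized name in the panel.  A panel drug present only as a suspect
#' drug does not count.  The classification partitions any cohort into
#' two disjoint, exhaustive groups.
#'
#' @param data a `faers_data` cohort.
#' @param panel character vector of normalized panel names; defaults to
#'   [chemo_panel()].
#' @return tibble with columns `caseid` and `chemo` (logical), one row
#'   per report in `data`.
#' @export
classify_chemo <- function(data, panel = chemo_panel()) {
  stopifnot(inherits(data, "faers_data"))
  conc <- data$drug[data$drug$role_cod %in% c("C", "I") &
                      data$drug$drugname_norm %in% panel, ]
  tibble::tibble(
    caseid = data$demo$caseid,
    chemo = data$demo$caseid %in% unique(conc$caseid)
  )
}
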