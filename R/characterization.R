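#' Percentage rounded half-up to one decimal
#'
#' Tabulated percentages are computed at full precision as
#' `100 * n / d` and then rounded *half-up* on the first decimal
#' (104/856 -> 12.1495... -> 12.1; 302/721 -> 41.886 -> 41.9).  Base R's
#' `round()` uses banker's rounding, which disagrees with conventional
#' table formatting at exact .x5 boundaries, so the half-up rule is
#' applied explicitly.
#'
#' @param n numerator count (vectorized).
#' @param d denominator count.
#' @return numeric percentage with one decimal.
#' @export
percent_round <- function(n, d) {
  if (any(d <= 0)) stop("denominator must be positive", call. = FALSE)
  p <- 100 * n / d
  floor(p * 10 + 0.5 + 1e-9) / 10
}

#' Demographic summary with available-case denominators
#'
#' Continuous variables are summarized over the reports where they are
#' observed, with the available-case `N` reported next to each statistic;
#' missing counts are reported against the full cohort.  Age is
#' normalized to years from the unit code (`YR`, `DEC` = decades,
#' `MON` = months) before summarizing; the 65-and-over flag is computed
#' from the observed ages.
#'
#' @param data a `faers_data` cohort.
#' @return list with elements `n` (cohort size), `age` (list: available,
#'   missing, median, q1, q3, n_ge65, pct_ge65) and `sex` (list:
#'   available, missing, n_female, pct_female, n_male, pct_male).
#'   Percentages use available-case denominators.
#' @export
summarize_demographics <- function(data) {
  stopifnot(inherits(data, "faers_data"))
  demo <- data$demo
  n <- nrow(demo)
  unit <- if ("age_cod" %in% names(demo)) demo$age_cod else "YR"
  unit[is.na(unit) | !nzchar(unit)] <- "YR"
  age_years <- demo$age
  age_years[unit == "DEC"] <- demo$age[unit == "DEC"] * 10
  age_years[unit == "MON"] <- demo$age[unit == "MON"] / 12
  avail_age <- sum(!is.na(age_years))
  age <- list(available = avail_age, missing = n - avail_age,
              median = NA_real_, q1 = NA_real_, q3 = NA_real_,
              n_ge65 = NA_integer_, pct_ge65 = NA_real_)
  if (avail_age > 0) {
    qs <- stats::quantile(age_years, c(0.25, 0.5, 0.75), na.rm = TRUE,
                          type = 7, names = FALSE)
    age$q1 <- qs[1]; age$median <- qs[2]; age$q3 <- qs[3]
    age$n_ge65 <- sum(age_years >= 65, na.rm = TRUE)
    age$pct_ge65 <- percent_round(age$n_ge65, avail_age)
  }
  sx <- demo$sex
  avail_sex <- sum(!is.na(sx) & sx %in% c("F", "M"))
  sex <- list(available = avail_sex, missing = n - avail_sex,
              n_female = sum(sx == "F", na.rm = TRUE),
              n_male = sum(sx == "M", na.rm = TRUE),
              pct_female = NA_real_, pct_male = NA_real_)
  if (avail_sex > 0) {
    sex$pct_female <- percent_round(sex$n_female, avail_sex)
    sex$pct_male <- percent_round(sex$n_male, avail_sex)
  }
  list(n = n, age = age, sex = sex)
}

#' Tabulate serious outcomes (non-mutually-exclusive)
#'
#' Each seriousness outcome is counted independently — a report carrying
#' several flags contributes to each of its rows — with percentages over
#' the full cohort size, so the column may sum to more than 100%.
#'
#' @param data a `faers_data` cohort.
#' @param outcomes which flags to tabulate, in display order.
#' @return tibble with `outcome`, `n`, `percent` (over cohort `N`,
#'   carried in the `cohort_n` attribute).
#' @export
tabulate_outcomes <- function(data,
                              outcomes = c("hospitalization",
                                           "life_threatening", "death")) {
  stopifnot(inherits(data, "faers_data"))
  n_cohort <- nrow(data$demo)
  counts <- vapply(outcomes, function(f) sum(data$demo[[f]]), integer(1))
  out <- tibble::tibble(outcome = outcomes, n = unname(counts),
                        percent = if (n_cohort > 0)
                          percent_round(unname(counts), n_cohort)
                        else NA_real_)
  attr(out, "cohort_n") <- n_cohort
  out
}

#' Rank the most frequent indications or concomitant medications
#'
#' Counts are per report (a report listing a drug twice counts once),
#' ranked by descending count with alphabetical tie-break, after removing
#' excluded terms; percentages are over the full cohort size.
#' Indications are attributed to the suspect drug's own entries
#' (`role_cod == "PS"`); concomitant medications are drug entries with
#' role concomitant or interacting.
#'
#' @param data a `faers_data` cohort.
#' @param field `"indication"` or `"concomitant_drug"`.
#' @param k number of top terms to return (fewer if fewer exist).
#' @param exclusions character vector of normalized terms removed before
#'   ranking (e.g. `"UNKNOWN INDICATION"`).
#' @return tibble with `rank`, `term`, `n`, `percent`.
#' @export
rank_top <- function(data, field = c("indication", "concomitant_drug"),
                     k = 10, exclusions = character(0)) {
  stopifnot(inherits(data, "faers_data"))
  field <- match.arg(field)
  n_cohort <- nrow(data$demo)
  if (field == "indication") {
    rows <- data$drug[data$drug$role_cod == "PS" &
                        !is.na(data$drug$indication_norm), ]
    terms <- rows$indication_norm
  } else {
    rows <- data$drug[data$drug$role_cod %in% c("C", "I"), ]
    terms <- rows$drugname_norm
  }
  df <- unique(data.frame(caseid = rows$caseid, term = terms,
                          stringsAsFactors = FALSE))
  df <- df[!df$term %in% normalize_text(exclusions), ]
  if (nrow(df) == 0 || n_cohort == 0) {
    return(tibble::tibble(rank = integer(0), term = character(0),
                          n = integer(0), percent = numeric(0)))
  }
  tab <- as.data.frame(table(term = df$term), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$Freq, tab$term), ]
  tab <- utils::head(tab, k)
  tibble::tibble(rank = seq_len(nrow(tab)), term = tab$term,
                 n = as.integer(tab$Freq),
                 percent = percent_round(tab$Freq, n_cohort))
}
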