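#' Construct a 2x2 disproportionality contingency table
#'
#' Cells follow the standard spontaneous-report convention: `a` = reports
#' with the target event where the drug is Primary Suspect; `b` = all
#' other events with the drug as Primary Suspect; `c` = target-event
#' reports for all other drugs (the drug not Primary Suspect); `d` = all
#' other events for all other drugs.  `a + b + c + d` equals the number
#' of deduplicated reports in scope.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return an object of class `pv_contingency`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 n = as.numeric(a + b + c + d)),
            class = "pv_contingency")
}

#' @export
print.pv_contingency <- function(x, ...) {
  cat(sprintf("<pv_contingency> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Count the 2x2 table for a drug-event pair over a report corpus
#'
#' @param data a deduplicated `faers_data` defining the analysis scope
#'   (e.g. all serious reports in the corpus).
#' @param drug drug name; Primary-Suspect status is matched on the
#'   normalized name.
#' @param pt Preferred Term (case-insensitive exact match).
#' @return a `pv_contingency`.
#' @export
build_contingency <- function(data, drug, pt) {
  stopifnot(inherits(data, "faers_data"))
  drug_norm <- normalize_text(drug, default_synonyms())
  all_ids <- data$demo$caseid
  ps_ids <- unique(data$drug$caseid[data$drug$role_cod == "PS" &
                                      data$drug$drugname_norm == drug_norm])
  if (length(ps_ids) == 0)
    stop(sprintf("drug absent: '%s' never appears as primary suspect",
                 drug_norm), call. = FALSE)
  ev_ids <- unique(data$reac$caseid[toupper(data$reac$pt) == toupper(pt)])
  is_ps <- all_ids %in% ps_ids
  is_ev <- all_ids %in% ev_ids
  contingency_table(sum(is_ps & is_ev), sum(is_ps & !is_ev),
                    sum(!is_ps & is_ev), sum(!is_ps & !is_ev))
}

#' Reporting odds ratio with log-Wald 95% confidence interval
#'
#' `ROR = (a d)/(b c)` with
#' `CI = exp(log(ROR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.  With a
#' zero cell the estimate and interval are undefined unless the Haldane
#' continuity correction (adding 0.5 to every cell) is enabled; corrected
#' results are flagged.
#'
#' @param tab a `pv_contingency`.
#' @param continuity apply the +0.5 Haldane correction to all cells.
#' @param conf confidence level (default 0.95).
#' @return list with `ror`, `lo`, `hi`, `continuity_applied`, `defined`.
#' @export
ror <- function(tab, continuity = FALSE, conf = 0.95) {
  stopifnot(inherits(tab, "pv_contingency"))
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  applied <- FALSE
  if (any(cells == 0)) {
    if (!continuity) {
      return(list(ror = NA_real_, lo = NA_real_, hi = NA_real_,
                  continuity_applied = FALSE, defined = FALSE))
    }
    cells <- cells + 0.5
    applied <- TRUE
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  est <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = est, lo = exp(log(est) - z * se), hi = exp(log(est) + z * se),
       continuity_applied = applied, defined = TRUE)
}

#' Proportional reporting ratio and chi-square statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`.  The screening chi-square is the
#' Yates-continuity-corrected Pearson statistic on the 2x2 table (the
#' conventional companion of the PRR>=2 / chi2>=4 criterion); the
#' uncorrected Pearson statistic is also returned for transparency.
#'
#' @param tab a `pv_contingency`.
#' @return list with `prr`, `chi2` (Yates-corrected), `chi2_uncorrected`,
#'   `defined` (`FALSE` when `c = 0` makes the PRR undefined).
#' @export
prr_chi2 <- function(tab) {
  stopifnot(inherits(tab, "pv_contingency"))
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  if (a + b == 0 || c + d == 0)
    stop("PRR requires non-empty drug and comparator margins", call. = FALSE)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  chi2_y <- suppressWarnings(
    unname(stats::chisq.test(m, correct = TRUE)$statistic))
  chi2_u <- suppressWarnings(
    unname(stats::chisq.test(m, correct = FALSE)$statistic))
  if (c == 0) {
    return(list(prr = NA_real_, chi2 = chi2_y, chi2_uncorrected = chi2_u,
                defined = FALSE))
  }
  prr <- (a / (a + b)) / (c / (c + d))
  list(prr = prr, chi2 = chi2_y, chi2_uncorrected = chi2_u, defined = TRUE)
}

#' Bayesian information component with gamma credibility interval
#'
#' The shrunken observed-to-expected log ratio of the BCPNN family:
#' with `E = (a+b)(a+c)/N`,
#' `IC = log2((a + 0.5) / (E + 0.5))`, and the 95% credibility bounds are
#' gamma quantiles `log2(qgamma(p; a + 0.5, rate = E + 0.5))` for
#' `p = 0.025, 0.975`.  The 0.5 shrinkage constant keeps the statistic
#' defined (and negative) at `a = 0`.
#'
#' @param tab a `pv_contingency`.
#' @return list with `ic`, `lo`, `hi`, `expected`.
#' @export
information_component <- function(tab) {
  stopifnot(inherits(tab, "pv_contingency"))
  if (tab$n <= 0) stop("empty table", call. = FALSE)
  e <- (tab$a + tab$b) * (tab$a + tab$c) / tab$n
  ic <- log2((tab$a + 0.5) / (e + 0.5))
  lo <- log2(stats::qgamma(0.025, shape = tab$a + 0.5, rate = e + 0.5))
  hi <- log2(stats::qgamma(0.975, shape = tab$a + 0.5, rate = e + 0.5))
  list(ic = ic, lo = lo, hi = hi, expected = e)
}

#' Apply the four standard signal criteria
#'
#' A signal is flagged per algorithm when: ROR lower 95% bound `> 1`
#' (strict); PRR `>= 2` with at least 3 cases and chi-square `>= 4`
#' (non-strict); IC lower 95% bound `> 0` (strict); EBGM05 (5th posterior
#' percentile) `> 2` (strict).
#'
#' @param result a `pv_signal` row as produced by [signal_stats()], or any
#'   list carrying `ror_lo95`, `prr`, `chi2`, `n_reports`, `ic_lo95`,
#'   `ebgm05`.
#' @return `result` with logical `ror_signal`, `prr_signal`, `ic_signal`,
#'   `ebgm_signal` set (`NA` statistics give `FALSE`).
#' @export
evaluate_signal <- function(result) {
  isnum <- function(x) !is.null(x) && length(x) == 1L && is.finite(x)
  result$ror_signal <- isnum(result$ror_lo95) && result$ror_lo95 > 1
  result$prr_signal <- isnum(result$prr) && isnum(result$chi2) &&
    isnum(result$n_reports) &&
    result$prr >= 2 && result$n_reports >= 3 && result$chi2 >= 4
  result$ic_signal <- isnum(result$ic_lo95) && result$ic_lo95 > 0
  result$ebgm_signal <- isnum(result$ebgm05) && result$ebgm05 > 2
  result
}

#' All four disproportionality statistics for one drug-event pair
#'
#' Convenience wrapper assembling [ror()], [prr_chi2()],
#' [information_component()] and, when a fitted [fit_mgps_prior()] prior
#' is supplied, [ebgm()], then applying [evaluate_signal()].
#'
#' @param data a `faers_data` analysis corpus.
#' @param drug,pt drug-event pair.
#' @param prior optional `mgps_prior`; without it the EBGM fields are
#'   `NA`.
#' @param continuity passed to [ror()].
#' @return a one-row tibble of class `pv_signal` mirroring the usual
#'   signal-table columns.
#' @export
signal_stats <- function(data, drug, pt, prior = NULL, continuity = FALSE) {
  tab <- build_contingency(data, drug, pt)
  r <- ror(tab, continuity = continuity)
  p <- prr_chi2(tab)
  icr <- information_component(tab)
  eb <- if (!is.null(prior)) ebgm(tab$a, icr$expected, prior) else
    list(ebgm = NA_real_, ebgm05 = NA_real_, ebgm95 = NA_real_,
         ebgm025 = NA_real_, ebgm975 = NA_real_)
  out <- tibble::tibble(
    drug = normalize_text(drug, default_synonyms()), pt = pt,
    a = tab$a, b = tab$b, c = tab$c, d = tab$d, n_reports = tab$a,
    expected = icr$expected,
    ror = r$ror, ror_lo95 = r$lo, ror_hi95 = r$hi,
    ror_continuity = r$continuity_applied,
    prr = p$prr, chi2 = p$chi2, chi2_uncorrected = p$chi2_uncorrected,
    ic = icr$ic, ic_lo95 = icr$lo, ic_hi95 = icr$hi,
    ebgm = eb$ebgm, ebgm05 = eb$ebgm05, ebgm95 = eb$ebgm95,
    ebgm025 = eb$ebgm025, ebgm975 = eb$ebgm975
  )
  out <- evaluate_signal(out)
  class(out) <- c("pv_signal", class(out))
  out
}

#' Stratified reporting odds ratios
#'
#' Recomputes the full 2x2 table within each level of a demographic
#' stratum (e.g. sex).  Reports with the stratum missing are excluded
#' from every level (available-case analysis); a level where `a = 0` is
#' reported with an undefined ROR rather than dropped.
#'
#' @param data a `faers_data` analysis corpus.
#' @param drug,pt drug-event pair.
#' @param stratum name of a `demo` column to stratify on (default
#'   `"sex"`).
#' @param continuity passed to [ror()].
#' @return tibble with one row per stratum level: level, cells, `ror`,
#'   `ror_lo95`, `ror_hi95`.
#' @export
stratified_ror <- function(data, drug, pt, stratum = "sex",
                           continuity = FALSE) {
  stopifnot(inherits(data, "faers_data"))
  if (!stratum %in% names(data$demo))
    stop("unknown stratum column: ", stratum, call. = FALSE)
  vals <- data$demo[[stratum]]
  levels <- sort(unique(vals[!is.na(vals)]))
  if (length(levels) == 0) stop("stratum entirely missing", call. = FALSE)
  rows <- lapply(levels, function(lv) {
    sub <- filter_reports(data, data$demo$caseid[!is.na(vals) & vals == lv])
    tab <- tryCatch(build_contingency(sub, drug, pt), error = function(e) NULL)
    if (is.null(tab)) {
      return(tibble::tibble(level = lv, a = 0, b = 0, c = 0, d = 0,
                            ror = NA_real_, ror_lo95 = NA_real_,
                            ror_hi95 = NA_real_))
    }
    r <- ror(tab, continuity = continuity)
    tibble::tibble(level = lv, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                   ror = r$ror, ror_lo95 = r$lo, ror_hi95 = r$hi)
  })
  dplyr::bind_rows(rows)
}

#' Observed and expected counts for every drug-event pair
#'
#' Tallies, over the supplied corpus, the number of reports `a` in which
#' each drug is Primary Suspect for each Preferred Term, together with
#' the independence expectation `E = n_drug * n_event / N` (report-level
#' margins).  This is the input to [fit_mgps_prior()].
#'
#' @param data a `faers_data` corpus.
#' @param min_count drop pairs with `a` below this (default 0 keeps all
#'   observed pairs).
#' @return tibble with columns `drug`, `pt`, `a`, `e`.
#' @export
pair_counts <- function(data, min_count = 0) {
  stopifnot(inherits(data, "faers_data"))
  n <- nrow(data$demo)
  ps <- data$drug[data$drug$role_cod == "PS",
                  c("caseid", "drugname_norm")]
  ps <- dplyr::distinct(ps)
  re <- dplyr::distinct(tibble::tibble(caseid = data$reac$caseid,
                                       pt = toupper(data$reac$pt)))
  pairs <- dplyr::inner_join(ps, re, by = "caseid",
                             relationship = "many-to-many")
  a_tab <- dplyr::count(pairs, .data$drugname_norm, .data$pt, name = "a")
  drug_m <- dplyr::count(dplyr::distinct(ps), .data$drugname_norm,
                         name = "n_drug")
  pt_m <- dplyr::count(re, .data$pt, name = "n_pt")
  out <- dplyr::left_join(a_tab, drug_m, by = "drugname_norm")
  out <- dplyr::left_join(out, pt_m, by = "pt")
  out$e <- out$n_drug * out$n_pt / n
  out <- out[out$a >= min_count, ]
  tibble::tibble(drug = out$drugname_norm, pt = out$pt, a = out$a, e = out$e)
}
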