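#' Derive time-to-onset per report via the hierarchical strategy
#'
#' For each report in the cohort, the onset time of the event `pt` under
#' the drug is derived by preference order: (1) date difference — when
#' both the suspect drug's therapy start date and the reaction onset
#' date are recorded, `tto = reaction date - start date` in days;
#' (2) duration conversion — otherwise, when a treatment duration with a
#' unit code is recorded, `tto = value * factor` with D = 1, WK = 7,
#' MON = 30, YR = 365.  Non-positive values, values above the outlier
#' cap, and unknown unit codes are excluded with a reason; reports with
#' neither source are absent from the output.
#'
#' @param data a `faers_data` cohort (e.g. the PT cohort).
#' @param drug suspect drug whose therapy dates/durations are used.
#' @param pt Preferred Term whose reaction onset date is used.
#' @param cap exclusion threshold in days for implausible onsets
#'   (default 1825, i.e. five years).
#' @return tibble with columns `caseid`, `tto_days`, `source`
#'   (`"date_diff"` or `"duration_converted"`); excluded candidates are
#'   returned in the `excluded` attribute with their `reason`.
#' @export
compute_tto <- function(data, drug, pt, cap = 1825) {
  stopifnot(inherits(data, "faers_data"))
  drug_norm <- normalize_text(drug, default_synonyms())
  unit_factor <- c(D = 1, WK = 7, MON = 30, YR = 365)

  dr <- data$drug[data$drug$drugname_norm == drug_norm, ]
  dr <- dr[order(dr$caseid, dr$role_cod != "PS", dr$drug_seq), ]
  dr <- dr[!duplicated(dr$caseid), c("caseid", "start_date", "dur", "dur_cod")]

  re <- data$reac[toupper(data$reac$pt) == toupper(pt) &
                    !is.na(data$reac$reaction_start_date), ]
  re <- re[order(re$caseid, re$reaction_start_date), ]
  re <- re[!duplicated(re$caseid), c("caseid", "reaction_start_date")]

  cand <- dplyr::left_join(dr, re, by = "caseid")
  has_dates <- !is.na(cand$start_date) & !is.na(cand$reaction_start_date)
  known_unit <- !is.na(cand$dur) & !is.na(cand$dur_cod) &
    cand$dur_cod %in% names(unit_factor)
  bad_unit <- !is.na(cand$dur) & !is.na(cand$dur_cod) &
    !cand$dur_cod %in% names(unit_factor)

  tto <- rep(NA_real_, nrow(cand))
  src <- rep(NA_character_, nrow(cand))
  tto[has_dates] <- as.numeric(cand$reaction_start_date[has_dates] -
                                 cand$start_date[has_dates])
  src[has_dates] <- "date_diff"
  use_dur <- !has_dates & known_unit
  tto[use_dur] <- cand$dur[use_dur] * unit_factor[cand$dur_cod[use_dur]]
  src[use_dur] <- "duration_converted"

  reason <- rep(NA_character_, nrow(cand))
  reason[!has_dates & !known_unit & bad_unit] <- "unknown unit"
  reason[!is.na(tto) & tto <= 0] <- "non-positive"
  reason[!is.na(tto) & tto > cap] <- "above outlier cap"

  keep <- !is.na(tto) & is.na(reason)
  out <- tibble::tibble(caseid = cand$caseid[keep],
                        tto_days = tto[keep], source = src[keep])
  excl <- !is.na(reason)
  attr(out, "excluded") <- tibble::tibble(caseid = cand$caseid[excl],
                                          reason = reason[excl])
  out
}

#' Summarize a time-to-onset distribution
#'
#' Median and quartiles by linear interpolation between closest ranks
#' (quantile type 7), cumulative onset proportions at the requested day
#' marks (`P(tto <= t)`), and histogram bin counts.
#'
#' @param tto_days numeric vector of positive onset times in days.
#' @param day_marks days at which to report cumulative proportions
#'   (default 30 and 60).
#' @param binwidth histogram bin width in days (default 15).
#' @return list with `n`, `median`, `q1`, `q3`, `cumulative` (named
#'   vector of proportions), `histogram` (data frame of bin edges and
#'   counts).
#' @export
tto_summary <- function(tto_days, day_marks = c(30, 60), binwidth = 15) {
  tto_days <- tto_days[is.finite(tto_days)]
  if (length(tto_days) == 0) stop("no evaluable onset times", call. = FALSE)
  qs <- stats::quantile(tto_days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  cum <- vapply(day_marks, function(t) mean(tto_days <= t), numeric(1))
  edges <- seq(0, max(tto_days) + binwidth, by = binwidth)
  counts <- tabulate(findInterval(tto_days, edges, left.open = TRUE),
                     nbins = length(edges) - 1)
  list(n = length(tto_days), median = qs[2], q1 = qs[1], q3 = qs[3],
       cumulative = stats::setNames(cum, paste0("day", day_marks)),
       histogram = data.frame(lower = edges[-length(edges)],
                              upper = edges[-1], count = counts))
}

#' Mann-Whitney U comparison of two onset-time groups
#'
#' `U` is reported for the first group: the number of pairs `(x, y)` with
#' `x < y` plus half the tied pairs.  The two-sided p-value uses exact
#' enumeration of group assignments when the smaller group has at most
#' `exact_max` observations (ties handled naturally by enumeration), and
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric vectors (e.g. chemotherapy and no-chemotherapy
#'   onset times); both non-empty.
#' @param method `"auto"` (exact when `min(n) <= exact_max`), `"exact"`,
#'   or `"normal"`.
#' @param exact_max size threshold for exact enumeration under `"auto"`
#'   (default 8).
#' @return list with `u` (for the first group), `p_value`, `method`,
#'   `n1`, `n2`.
#' @export
compare_groups <- function(x, y, method = c("auto", "exact", "normal"),
                           exact_max = 8) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  u_stat <- function(xx, yy) {
    r <- rank(c(xx, yy))
    sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
  }
  u <- u_stat(x, y)
  if (method == "auto") {
    method <- if (min(n1, n2) <= exact_max) "exact" else "normal"
  }
  if (method == "exact") {
    pooled <- c(x, y)
    n <- n1 + n2
    if (choose(n, n1) > 2e6)
      stop("groups too large for exact enumeration; use method = \"normal\"",
           call. = FALSE)
    combos <- utils::combn(n, n1)
    mu <- n1 * n2 / 2
    us <- apply(combos, 2, function(ix) {
      u_stat(pooled[ix], pooled[-ix])
    })
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(c(x, y))
    tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_adj)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    p <- min(1, p)
  }
  list(u = u, p_value = p, method = method, n1 = n1, n2 = n2)
}
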