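make_tto_raw <- function(reaction, start, dur = NA_real_,
                         dur_cod = NA_character_) {
  structure(list(
    demo = tibble::tibble(caseid = "T1", caseversion = 1L,
                          receiptdate = as.Date("2023-06-01"), age = 60,
                          age_cod = "YR", sex = "F"),
    drug = tibble::tibble(caseid = "T1", caseversion = 1L, drug_seq = 1L,
                          role_cod = "PS", drugname = "Pembrolizumab"),
    reac = tibble::tibble(caseid = "T1", caseversion = 1L,
                          pt = "Neutropenia",
                          reaction_start_date = as.Date(reaction)),
    outc = tibble::tibble(caseid = "T1", caseversion = 1L, outc_cod = "HO"),
    ther = tibble::tibble(caseid = "T1", caseversion = 1L,
                          dsg_drug_seq = 1L, start_date = as.Date(start),
                          dur = dur, dur_cod = dur_cod),
    indi = NULL), class = "faers_raw")
}

one_tto <- function(...) {
  compute_tto(deduplicate(make_tto_raw(...)), "PEMBROLIZUMAB", "Neutropenia")
}

test_that("onset derivation follows the date-then-duration hierarchy", {
  # both dates: plain difference in days
  obs <- one_tto("2023-01-20", "2023-01-01")
  expect_equal(obs$tto_days, 19)
  expect_equal(obs$source, "date_diff")
  # dates available win over an inconsistent duration field
  obs <- one_tto("2023-01-20", "2023-01-01", dur = 99, dur_cod = "D")
  expect_equal(obs$tto_days, 19)
  expect_equal(obs$source, "date_diff")
  # no dates: duration conversion with unit factors D/WK/MON/YR
  for (case in list(list(3, "WK", 21), list(2, "MON", 60),
                    list(1, "YR", 365), list(14, "D", 14))) {
    obs <- one_tto(NA, NA, dur = case[[1]], dur_cod = case[[2]])
    expect_equal(obs$tto_days, case[[3]])
    expect_equal(obs$source, "duration_converted")
  }
})

test_that("implausible onsets are excluded with a reason", {
  # reaction before therapy start
  obs <- one_tto("2022-12-20", "2023-01-01")
  expect_equal(nrow(obs), 0L)
  expect_equal(attr(obs, "excluded")$reason, "non-positive")
  # same-day onset counts as non-positive
  obs <- one_tto("2023-01-01", "2023-01-01")
  expect_equal(attr(obs, "excluded")$reason, "non-positive")
  # beyond the outlier cap
  obs <- one_tto("2029-01-01", "2023-01-01")
  expect_equal(attr(obs, "excluded")$reason, "above outlier cap")
  # the cap is configurable
  obs <- compute_tto(deduplicate(make_tto_raw("2029-01-01", "2023-01-01")),
                     "PEMBROLIZUMAB", "Neutropenia", cap = 5000)
  expect_equal(nrow(obs), 1L)
  # unknown duration unit
  obs <- one_tto(NA, NA, dur = 5, dur_cod = "HR")
  expect_equal(attr(obs, "excluded")$reason, "unknown unit")
  # no source at all: absent without an exclusion reason
  obs <- one_tto(NA, NA)
  expect_equal(nrow(obs), 0L)
  expect_equal(nrow(attr(obs, "excluded")), 0L)
})

test_that("summary statistics match hand counts and the sorting oracle", {
  s <- tto_summary(c(1, 2, 3, 4, 5), day_marks = c(3))
  expect_equal(s$median, 3)
  expect_equal(unname(s$cumulative), 0.6)
  # all onsets at or below the smallest mark
  s2 <- tto_summary(c(1, 2, 3), day_marks = c(30, 60))
  expect_equal(unname(s2$cumulative), c(1, 1))
  expect_error(tto_summary(numeric(0)), "no evaluable")
  # quartiles against the closest-rank interpolation oracle
  set.seed(19)
  for (i in 1:100) {
    x <- rlnorm(sample(3:40, 1), log(20), 1)
    s <- tto_summary(x)
    expect_equal(s$q1, o_quantile(x, 0.25), tolerance = 1e-12)
    expect_equal(s$median, o_quantile(x, 0.5), tolerance = 1e-12)
    expect_equal(s$q3, o_quantile(x, 0.75), tolerance = 1e-12)
  }
})

test_that("cumulative proportions are monotone and reach one", {
  set.seed(23)
  x <- rlnorm(200, log(19), 1)
  marks <- c(7, 14, 30, 60, 90, ceiling(max(x)))
  s <- tto_summary(x, day_marks = marks)
  expect_true(all(diff(s$cumulative) >= 0))
  expect_equal(unname(s$cumulative[length(marks)]), 1)
  expect_equal(sum(s$histogram$count), length(x))
})

test_that("the rank-sum statistic and p-values match the exact oracle", {
  # all four pairs favour the second group: U = 0 for the first
  r <- compare_groups(c(1, 2), c(3, 4), method = "exact")
  expect_equal(r$u, 0)
  # identical groups under exact enumeration: p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3),
                              method = "exact")$p_value, 1)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
  # implementation vs the independent pair-counting oracle, with ties
  set.seed(37)
  for (i in 1:20) {
    x <- sample(1:8, 5, replace = TRUE)
    y <- sample(1:8, 6, replace = TRUE)
    o <- o_mwu_exact(x, y)
    r <- compare_groups(x, y, method = "exact")
    expect_equal(r$u, o$u)
    expect_equal(r$p_value, o$p)
  }
})

test_that("the normal approximation tracks exact enumeration and wilcox.test", {
  set.seed(43)
  worst <- 0
  for (i in 1:50) {
    x <- rlnorm(7, log(14.5), 1)
    y <- rlnorm(7, log(39), 1)
    pe <- compare_groups(x, y, method = "exact")$p_value
    pn <- compare_groups(x, y, method = "normal")$p_value
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.02)
  # tie-corrected normal approximation agrees with stats::wilcox.test
  x <- rlnorm(30, 1, 1)
  y <- rlnorm(25, 1.4, 1)
  r <- compare_groups(x, y, method = "normal")
  w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$u, unname(w$statistic))
  expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
})
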