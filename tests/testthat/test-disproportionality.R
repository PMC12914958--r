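test_that("contingency cells follow the primary-suspect definitions", {
  data <- tiny_data()
  tab <- build_contingency(data, "PEMBROLIZUMAB", "Neutropenia")
  # corpus: C1(PS, neut), C2(not PS, neut), C3(PS, neut), C4(PS, FN only),
  # C5(PS, neut+FN), C6(not PS, rash)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(3, 1, 1, 1))
  expect_equal(tab$n, nrow(data$demo))
  expect_error(build_contingency(data, "NOSUCHDRUG", "Neutropenia"),
               "drug absent")
})

test_that("a single-report corpus gives the degenerate table", {
  data <- filter_reports(tiny_data(), "C1")
  tab <- build_contingency(data, "PEMBROLIZUMAB", "Neutropenia")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 0, 0, 0))
})

test_that("synthetic corpus cells equal an independent counting pass", {
  cfg <- small_config(n_reports = 1500L)
  data <- deduplicate(generate_reports(cfg))
  tab <- build_contingency(data, cfg$target_drug, cfg$target_event)
  ps <- unique(data$drug$caseid[data$drug$role_cod == "PS" &
    data$drug$drugname_norm == cfg$target_drug])
  ev <- unique(data$reac$caseid[toupper(data$reac$pt) ==
    toupper(cfg$target_event)])
  ids <- data$demo$caseid
  expect_equal(tab$a, sum(ids %in% ps & ids %in% ev))
  expect_equal(tab$b, sum(ids %in% ps & !ids %in% ev))
  expect_equal(tab$c, sum(!ids %in% ps & ids %in% ev))
  expect_equal(tab$d, sum(!ids %in% ps & !ids %in% ev))
})

test_that("ROR matches hand arithmetic and the log-Wald oracle", {
  r <- ror(contingency_table(10, 90, 100, 9900))
  expect_equal(r$ror, 11.0)
  o <- o_ror(10, 90, 100, 9900, z = qnorm(0.975))
  expect_equal(r$lo, o$lo, tolerance = 1e-12)
  expect_equal(r$hi, o$hi, tolerance = 1e-12)
  # proportional table: no disproportion
  expect_equal(ror(contingency_table(10, 90, 20, 180))$ror, 1.0)
  # invariance when the comparator margin is scaled
  r1 <- ror(contingency_table(7, 43, 60, 900))
  r5 <- ror(contingency_table(7, 43, 300, 4500))
  expect_equal(r1$ror, r5$ror)
})

test_that("zero cells flag the ROR undefined unless continuity is on", {
  tab <- contingency_table(5, 0, 12, 400)
  r <- ror(tab)
  expect_false(r$defined)
  expect_true(is.na(r$ror))
  rc <- ror(tab, continuity = TRUE)
  expect_true(rc$defined)
  expect_true(rc$continuity_applied)
  expect_equal(rc$ror, (5.5 * 400.5) / (0.5 * 12.5))
})

test_that("PRR matches hand arithmetic and chi-square matches the textbook formula", {
  p <- prr_chi2(contingency_table(10, 90, 100, 9900))
  expect_equal(p$prr, 10.0)
  for (cells in list(c(10, 90, 100, 9900), c(3, 17, 40, 940),
                     c(25, 5, 100, 870), c(1, 9, 10, 80))) {
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    got <- prr_chi2(t)
    expect_equal(got$chi2, o_chi2(cells[1], cells[2], cells[3], cells[4],
                                  yates = TRUE), tolerance = 1e-10)
    expect_equal(got$chi2_uncorrected,
                 o_chi2(cells[1], cells[2], cells[3], cells[4],
                        yates = FALSE), tolerance = 1e-10)
  }
  # perfectly proportional table: PRR 1 and zero uncorrected chi-square
  p0 <- prr_chi2(contingency_table(10, 90, 20, 180))
  expect_equal(p0$prr, 1.0)
  expect_equal(p0$chi2_uncorrected, 0)
  # c = 0 leaves the PRR undefined but flagged, not an error
  expect_false(prr_chi2(contingency_table(5, 95, 0, 900))$defined)
})

test_that("information component shrinks correctly at the boundaries", {
  # observed equals expected at large counts: IC near zero
  t <- contingency_table(1000, 9000, 9000, 81000)
  expect_lt(abs(information_component(t)$ic), 0.01)
  # a = 0 forces a negative component
  t0 <- contingency_table(0, 100, 50, 1000)
  expect_lt(information_component(t0)$ic, 0)
})

test_that("IC credibility bounds agree with a posterior-sampling oracle", {
  tab <- contingency_table(10, 90, 100, 9900)
  ic <- information_component(tab)
  set.seed(41)
  draws <- log2(rgamma(1e6, shape = tab$a + 0.5, rate = ic$expected + 0.5))
  mc <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(ic$lo - mc[1]), 0.02)
  expect_lt(abs(ic$hi - mc[2]), 0.02)
})

test_that("IC and log2 ROR agree on large balanced tables", {
  set.seed(53)
  for (i in 1:20) {
    # near-null tables whose margins are small fractions of N: the
    # shrunken observed/expected ratio then tracks the odds ratio
    n <- 1e6
    m1 <- sample(5000:20000, 1)
    m2 <- sample(5000:20000, 1)
    a <- rpois(1, m1 * m2 / n) + 1
    t <- contingency_table(a, m1 - a, m2 - a, n - m1 - m2 + a)
    ic <- information_component(t)$ic
    lr <- log2(ror(t)$ror)
    expect_lt(abs(ic - lr), 0.05)
  }
})

test_that("signal criteria apply strict and non-strict thresholds as stated", {
  base <- list(ror_lo95 = 1.5, prr = 3, chi2 = 10, n_reports = 20,
               ic_lo95 = 0.5, ebgm05 = 3)
  r <- evaluate_signal(base)
  expect_true(r$ror_signal && r$prr_signal && r$ic_signal && r$ebgm_signal)
  # PRR thresholds are inclusive
  r <- evaluate_signal(utils::modifyList(base, list(prr = 2.0, chi2 = 4.0,
                                                    n_reports = 3)))
  expect_true(r$prr_signal)
  r <- evaluate_signal(utils::modifyList(base, list(prr = 1.999)))
  expect_false(r$prr_signal)
  r <- evaluate_signal(utils::modifyList(base, list(n_reports = 2)))
  expect_false(r$prr_signal)
  # interval criteria are strict
  expect_false(evaluate_signal(utils::modifyList(base,
    list(ebgm05 = 2.0)))$ebgm_signal)
  expect_true(evaluate_signal(utils::modifyList(base,
    list(ebgm05 = 2.0001)))$ebgm_signal)
  expect_false(evaluate_signal(utils::modifyList(base,
    list(ror_lo95 = 0.99)))$ror_signal)
  expect_false(evaluate_signal(utils::modifyList(base,
    list(ror_lo95 = 1.0)))$ror_signal)
  expect_false(evaluate_signal(utils::modifyList(base,
    list(ic_lo95 = 0)))$ic_signal)
  # missing statistics never signal
  expect_false(evaluate_signal(utils::modifyList(base,
    list(ebgm05 = NA_real_)))$ebgm_signal)
})

test_that("stratified analysis excludes missing strata and never drops levels", {
  cfg <- small_config(n_reports = 2000L)
  data <- deduplicate(generate_reports(cfg))
  strat <- stratified_ror(data, cfg$target_drug, cfg$target_event)
  expect_setequal(strat$level, c("F", "M"))
  # partition: pooled a equals stratum a's plus missing-stratum a's
  tab <- build_contingency(data, cfg$target_drug, cfg$target_event)
  miss <- filter_reports(data, data$demo$caseid[is.na(data$demo$sex)])
  a_miss <- tryCatch(build_contingency(miss, cfg$target_drug,
                                       cfg$target_event)$a,
                     error = function(e) 0)
  expect_equal(sum(strat$a) + a_miss, tab$a)
  # single-level stratum reproduces the unstratified table
  data$demo$onegroup <- "all"
  s1 <- stratified_ror(data, cfg$target_drug, cfg$target_event,
                       stratum = "onegroup")
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$a, tab$a)
  expect_equal(s1$ror, ror(tab)$ror)
  # a level with a = 0 is reported with an undefined ROR, not dropped
  data$demo$odd <- ifelse(data$demo$caseid %in%
    data$reac$caseid[toupper(data$reac$pt) == toupper(cfg$target_event)],
    "with", "without")
  s2 <- stratified_ror(data, cfg$target_drug, cfg$target_event,
                       stratum = "odd")
  expect_true("without" %in% s2$level)
  expect_true(is.na(s2$ror[s2$level == "without"]))
})
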