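test_that("text normalization cleans, maps synonyms, and is idempotent", {
  map <- c("NONSMALL CELL LUNG CANCER" = "NSCLC")
  expect_equal(normalize_text("non-small cell lung cancer", map), "NSCLC")
  expect_equal(normalize_text("CARBOPLATIN"), "CARBOPLATIN")
  expect_equal(normalize_text("  FLUOROURACIL  5 "), "FLUOROURACIL 5")
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text("Abraxane", default_synonyms()), "NABPACLITAXEL")

  set.seed(31)
  rand <- vapply(seq_len(1000), function(i) {
    paste(sample(c(LETTERS, letters, 0:9, ".,-()/' ", " "), sample(1:30, 1),
                 replace = TRUE), collapse = "")
  }, character(1))
  once <- normalize_text(rand, default_synonyms())
  expect_identical(normalize_text(once, default_synonyms()), once)
  # without a synonym map, cleaning never lengthens a string
  expect_true(all(nchar(normalize_text(rand)) <= nchar(rand)))
})

test_that("reading keeps every row and treats bad dates as missing fields", {
  dir <- withr::local_tempdir()
  writeLines(c("caseid$caseversion$receiptdate$age$age_cod$sex",
               "A1$1$2023-01-05$64$YR$F",
               "A2$1$2023-02-30$71$YR$M",   # impossible date
               "A3$1$2023-03-01$$YR$"),
             file.path(dir, "DEMO.txt"))
  writeLines(c("caseid$caseversion$drug_seq$role_cod$drugname",
               "A1$1$1$PS$Pembrolizumab",
               "A2$1$1$PS$Pembrolizumab",
               "A3$1$1$PS$Nivolumab"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("caseid$caseversion$pt$reaction_start_date",
               "A1$1$Neutropenia$2023-01",   # partial date
               "A2$1$Rash$",
               "A3$1$Neutropenia$2023-03-10"),
             file.path(dir, "REAC.txt"))
  writeLines(c("caseid$caseversion$outc_cod", "A1$1$DE"),
             file.path(dir, "OUTC.txt"))

  expect_warning(raw <- read_faers_tables(dir), "unparseable date")
  expect_equal(nrow(raw$demo), 3L)
  expect_true(is.na(raw$demo$receiptdate[raw$demo$caseid == "A2"]))
  # partial year-month date resolves to day 1, flagged low precision
  a1 <- raw$reac[raw$reac$caseid == "A1", ]
  expect_equal(a1$reaction_start_date, as.Date("2023-01-01"))
  expect_true(a1$reaction_date_low_precision)

  # missing mandatory column is a hard error naming the column
  writeLines(c("caseid$caseversion$receiptdate$age$age_cod",
               "A1$1$2023-01-05$64$YR"),
             file.path(dir, "DEMO.txt"))
  expect_error(read_faers_tables(dir), "sex")
})

test_that("generated tables round-trip through write and read", {
  cfg <- small_config(n_reports = 300L)
  raw <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  write_faers_tables(raw, dir)
  back <- read_faers_tables(dir)
  expect_equal(nrow(back$demo), nrow(raw$demo))
  d1 <- deduplicate(raw)
  d2 <- deduplicate(back)
  expect_identical(d1$demo$caseid, d2$demo$caseid)
  expect_identical(d1$demo$sex, d2$demo$sex)
  expect_identical(d1$demo$serious, d2$demo$serious)
  expect_identical(d1$drug$drugname_norm, d2$drug$drugname_norm)
  expect_equal(d1$drug$start_date, d2$drug$start_date)
  # writing the same object twice is byte-identical
  dir2 <- withr::local_tempdir()
  write_faers_tables(raw, dir2)
  expect_identical(unname(tools::md5sum(file.path(dir, "DEMO.txt"))),
                   unname(tools::md5sum(file.path(dir2, "DEMO.txt"))))
  # csv dialect round-trips too
  dir3 <- withr::local_tempdir()
  write_faers_tables(raw, dir3, dialect = "csv")
  back3 <- read_faers_tables(dir3, dialect = "csv")
  expect_equal(nrow(back3$drug), nrow(raw$drug))
})

test_that("deduplication keeps the latest case version deterministically", {
  raw <- tiny_raw()
  data <- deduplicate(raw)
  # C1 has versions 1 and 2: version 2 (age 70) is retained
  expect_equal(nrow(data$demo), 6L)
  c1 <- data$demo[data$demo$caseid == "C1", ]
  expect_equal(c1$caseversion, 2L)
  expect_equal(c1$age, 70)
  # exactly one record per case id, and idempotent under re-application
  expect_equal(anyDuplicated(data$demo$caseid), 0L)
  again <- deduplicate(structure(list(demo = data$demo,
                                      drug = data$drug[, 1:5],
                                      reac = data$reac, outc = data$outc,
                                      ther = NULL, indi = NULL),
                                 class = "faers_raw"))
  expect_identical(again$demo$caseid, data$demo$caseid)
  expect_identical(again$demo$caseversion, data$demo$caseversion)
})

test_that("version ties resolve by receipt date then file order with warning", {
  raw <- tiny_raw()
  # same caseid, same version, later receipt date wins
  raw$demo <- tibble::add_row(raw$demo, caseid = "C9", caseversion = 1L,
                              receiptdate = as.Date("2023-05-01"), age = 40,
                              age_cod = "YR", sex = "F")
  raw$demo <- tibble::add_row(raw$demo, caseid = "C9", caseversion = 1L,
                              receiptdate = as.Date("2023-06-01"), age = 41,
                              age_cod = "YR", sex = "F")
  raw$reac <- tibble::add_row(raw$reac, caseid = "C9", caseversion = 1L,
                              pt = "Rash", reaction_start_date = as.Date(NA))
  d <- deduplicate(raw)
  expect_equal(d$demo$age[d$demo$caseid == "C9"], 41)
  # full tie on both keys: the later file-order row is kept, with warning
  raw$demo$receiptdate[nrow(raw$demo)] <- as.Date("2023-05-01")
  raw$demo$age[nrow(raw$demo)] <- 43
  expect_warning(d2 <- deduplicate(raw), "file-order")
  expect_equal(d2$demo$age[d2$demo$caseid == "C9"], 43)
})

test_that("deduplicated corpus size equals the distinct case-id count", {
  cfg <- small_config(n_reports = 1000L, duplicate_rate = 0.2)
  raw <- generate_reports(cfg)
  data <- deduplicate(raw)
  expect_equal(nrow(data$demo), length(unique(raw$demo$caseid)))
  expect_equal(nrow(data$demo), 1000L)
})
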