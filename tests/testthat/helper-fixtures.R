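# Hand-built six-case raw corpus exercising versioning, roles, PT
# variants, seriousness flags and both onset-derivation routes.
tiny_raw <- function() {
  demo <- tibble::tibble(
    caseid      = c("C1", "C1", "C2", "C3", "C4", "C5", "C6"),
    caseversion = c(1L, 2L, 1L, 1L, 1L, 1L, 1L),
    receiptdate = as.Date(c("2023-01-05", "2023-02-05", "2023-01-06",
                            "2023-01-07", "2023-01-08", "2023-01-09",
                            "2023-01-10")),
    age     = c(69, 70, 55, 61, NA, 48, 80),
    age_cod = "YR",
    sex     = c("F", "F", "M", "F", "M", NA, "M")
  )
  drug <- tibble::tibble(
    caseid = c("C1", "C1", "C2", "C2", "C2", "C3", "C4", "C4", "C5", "C6"),
    caseversion = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    drug_seq = c(1L, 1L, 1L, 2L, 3L, 1L, 1L, 2L, 1L, 1L),
    role_cod = c("PS", "PS", "PS", "C", "C", "PS", "PS", "C", "PS", "PS"),
    drugname = c("Keytruda", "Keytruda", "Nivolumab", "Pembrolizumab",
                 "Carboplatin", "PEMBROLIZUMAB", "Pembrolizumab",
                 "Abraxane", "Pembrolizumab", "Osimertinib")
  )
  reac <- tibble::tibble(
    caseid = c("C1", "C1", "C2", "C3", "C4", "C5", "C5", "C6"),
    caseversion = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L),
    pt = c("Neutropenia", "Neutropenia", "Neutropenia", "NEUTROPENIA",
           "Febrile neutropenia", "Neutropenia", "Febrile neutropenia",
           "Rash"),
    reaction_start_date = as.Date(c("2023-01-20", "2023-01-20", NA, NA, NA,
                                    "2022-12-20", NA, NA))
  )
  outc <- tibble::tibble(
    caseid = c("C1", "C1", "C2", "C4", "C5", "C6"),
    caseversion = c(1L, 2L, 1L, 1L, 1L, 1L),
    outc_cod = c("DE", "DE", "HO", "HO", "LT", "OT")
  )
  ther <- tibble::tibble(
    caseid = c("C1", "C1", "C4", "C5"),
    caseversion = c(1L, 2L, 1L, 1L),
    dsg_drug_seq = 1L,
    start_date = as.Date(c("2023-01-01", "2023-01-01", NA, "2023-01-01")),
    dur = c(NA, NA, 3, NA),
    dur_cod = c(NA, NA, "WK", NA)
  )
  indi <- tibble::tibble(
    caseid = c("C1", "C1", "C4", "C6"),
    caseversion = c(1L, 2L, 1L, 1L),
    indi_drug_seq = 1L,
    indi_pt = c("Non-small cell lung cancer", "Non-small cell lung cancer",
                "Breast cancer", "Lung adenocarcinoma")
  )
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther, indi = indi),
            class = "faers_raw")
}

tiny_data <- function() deduplicate(tiny_raw())

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_reports = 1000L, seed = 7L, duplicate_rate = 0.2),
    list(...))
  do.call(synthetic_config, args)
}
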