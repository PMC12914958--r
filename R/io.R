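#' Write FAERS-style quarterly tables
#'
#' Writes the six entity tables (`DEMO`, `DRUG`, `REAC`, `OUTC`, `THER`,
#' `INDI`) as delimited text with a header row.  The default dialect uses
#' the `$` field separator of the public FAERS ASCII distribution; a
#' comma dialect is available for generic CSV tooling.  Dates are written
#' as ISO-8601 strings and missing values as empty fields.
#'
#' @param raw a `faers_raw` object ([generate_reports()] output or the
#'   result of [read_faers_tables()]).
#' @param dir output directory (created if needed).
#' @param dialect `"faers"` (`$`-separated, `.txt`) or `"csv"`.
#' @return invisibly, the named vector of file paths written.
#' @export
write_faers_tables <- function(raw, dir, dialect = c("faers", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(is.list(raw), all(c("demo", "drug", "reac", "outc") %in% names(raw)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sep <- if (dialect == "faers") "$" else ","
  ext <- if (dialect == "faers") ".txt" else ".csv"
  paths <- character(0)
  for (nm in intersect(c("demo", "drug", "reac", "outc", "ther", "indi"),
                       names(raw))) {
    tb <- as.data.frame(raw[[nm]])
    for (j in seq_along(tb)) {
      if (inherits(tb[[j]], "Date")) tb[[j]] <- format(tb[[j]], "%Y-%m-%d")
    }
    path <- file.path(dir, paste0(toupper(nm), ext))
    utils::write.table(tb, path, sep = sep, na = "", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Parse report dates leniently
#'
#' Accepts full ISO dates (`2023-02-15`), compact 8-digit FAERS dates
#' (`20230215`) and partial year-month dates (`2023-02` / `202302`).
#' Partial dates are resolved to the first of the month and flagged
#' low-precision so downstream time-to-onset users can audit them.
#' Impossible dates (e.g. `2023-02-30`) and unrecognized strings become
#' `NA` with one summarizing warning; rows are never dropped for a bad
#' date.
#'
#' @param x character vector.
#' @return a data frame with columns `date` (`Date`) and `low_precision`
#'   (logical).
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  low <- rep(FALSE, length(x))
  blank <- is.na(x) | !nzchar(trimws(x))
  x <- trimws(x)
  full <- !blank & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[full] <- as.Date(strptime(x[full], "%Y-%m-%d", tz = "UTC"))
  compact <- !blank & grepl("^\\d{8}$", x)
  out[compact] <- as.Date(strptime(x[compact], "%Y%m%d", tz = "UTC"))
  ym <- !blank & (grepl("^\\d{4}-\\d{2}$", x) | grepl("^\\d{6}$", x))
  if (any(ym)) {
    y <- sub("-", "", x[ym])
    out[ym] <- as.Date(strptime(paste0(y, "01"), "%Y%m%d", tz = "UTC"))
    low[ym] <- !is.na(out[ym])
  }
  bad <- !blank & is.na(out)
  if (any(bad)) {
    warning(sprintf("%d unparseable date value(s) set to missing (e.g. '%s')",
                    sum(bad), x[which(bad)[1]]), call. = FALSE)
  }
  data.frame(date = out, low_precision = low)
}

.mandatory_cols <- list(
  demo = c("caseid", "caseversion", "receiptdate", "age", "age_cod", "sex"),
  drug = c("caseid", "caseversion", "drug_seq", "role_cod", "drugname"),
  reac = c("caseid", "caseversion", "pt"),
  outc = c("caseid", "caseversion", "outc_cod"),
  ther = c("caseid", "caseversion", "dsg_drug_seq"),
  indi = c("caseid", "caseversion", "indi_drug_seq", "indi_pt")
)

#' Read FAERS-style quarterly tables
#'
#' Reads the delimited entity tables written by [write_faers_tables()]
#' (or hand-prepared in the same layout) into typed tibbles.  Every input
#' row is accounted for: rows whose case identifier is blank are reported
#' with their line numbers in a warning and returned in the
#' `malformed` attribute; nothing is dropped silently.  A missing
#' mandatory column is a hard error naming the column.  Unparseable dates
#' become missing fields with a warning; the affected rows are retained.
#'
#' @param dir directory containing `DEMO`/`DRUG`/`REAC`/`OUTC` and
#'   optionally `THER`/`INDI` files.
#' @param dialect `"faers"` (`$`-separated `.txt`) or `"csv"`.
#' @return a `faers_raw` object (list of tibbles `demo`, `drug`, `reac`,
#'   `outc`, `ther`, `indi`).
#' @export
read_faers_tables <- function(dir, dialect = c("faers", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "faers") "$" else ","
  ext <- if (dialect == "faers") ".txt" else ".csv"
  read_one <- function(nm, required = TRUE) {
    path <- file.path(dir, paste0(toupper(nm), ext))
    if (!file.exists(path)) {
      if (required) stop("missing input file: ", path, call. = FALSE)
      return(NULL)
    }
    tb <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                            comment.char = "", colClasses = "character",
                            na.strings = "", fill = TRUE,
                            stringsAsFactors = FALSE)
    missing_cols <- setdiff(.mandatory_cols[[nm]], names(tb))
    if (length(missing_cols))
      stop(sprintf("table '%s' is missing mandatory column(s): %s",
                   toupper(nm), paste(missing_cols, collapse = ", ")),
           call. = FALSE)
    bad <- is.na(tb$caseid) | !nzchar(trimws(tb$caseid))
    if (any(bad)) {
      warning(sprintf(
        "table '%s': %d malformed row(s) without a case id at line(s) %s",
        toupper(nm), sum(bad),
        paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
    }
    attr(tb, "malformed") <- which(bad)
    tb
  }
  demo <- read_one("demo")
  drug <- read_one("drug")
  reac <- read_one("reac")
  outc <- read_one("outc")
  ther <- read_one("ther", required = FALSE)
  indi <- read_one("indi", required = FALSE)

  demo <- tibble::as_tibble(demo)
  demo$caseversion <- as.integer(demo$caseversion)
  demo$receiptdate <- parse_faers_date(demo$receiptdate)$date
  demo$age <- suppressWarnings(as.numeric(demo$age))

  drug <- tibble::as_tibble(drug)
  drug$caseversion <- as.integer(drug$caseversion)
  drug$drug_seq <- as.integer(drug$drug_seq)

  reac <- tibble::as_tibble(reac)
  reac$caseversion <- as.integer(reac$caseversion)
  if ("reaction_start_date" %in% names(reac)) {
    pd <- parse_faers_date(reac$reaction_start_date)
    reac$reaction_start_date <- pd$date
    reac$reaction_date_low_precision <- pd$low_precision
  } else {
    reac$reaction_start_date <- as.Date(NA)
    reac$reaction_date_low_precision <- FALSE
  }

  outc <- tibble::as_tibble(outc)
  outc$caseversion <- as.integer(outc$caseversion)

  if (is.null(ther)) {
    ther <- tibble::tibble(caseid = character(0), caseversion = integer(0),
                           dsg_drug_seq = integer(0),
                           start_date = as.Date(character(0)),
                           start_date_low_precision = logical(0),
                           dur = numeric(0), dur_cod = character(0))
  } else {
    ther <- tibble::as_tibble(ther)
    ther$caseversion <- as.integer(ther$caseversion)
    ther$dsg_drug_seq <- as.integer(ther$dsg_drug_seq)
    if ("start_date" %in% names(ther)) {
      pd <- parse_faers_date(ther$start_date)
      ther$start_date <- pd$date
      ther$start_date_low_precision <- pd$low_precision
    } else {
      ther$start_date <- as.Date(NA)
      ther$start_date_low_precision <- FALSE
    }
    ther$dur <- if ("dur" %in% names(ther))
      suppressWarnings(as.numeric(ther$dur)) else NA_real_
    if (!"dur_cod" %in% names(ther)) ther$dur_cod <- NA_character_
  }

  if (is.null(indi)) {
    indi <- tibble::tibble(caseid = character(0), caseversion = integer(0),
                           indi_drug_seq = integer(0), indi_pt = character(0))
  } else {
    indi <- tibble::as_tibble(indi)
    indi$caseversion <- as.integer(indi$caseversion)
    indi$indi_drug_seq <- as.integer(indi$indi_drug_seq)
  }

  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther, indi = indi),
            class = "faers_raw")
}

# fill in optional columns so in-memory and file-round-tripped tables
# share one schema
.ensure_optional_cols <- function(raw) {
  add <- function(tb, col, value) {
    if (!is.null(tb) && !col %in% names(tb)) tb[[col]] <- value
    tb
  }
  raw$reac <- add(raw$reac, "reaction_start_date", as.Date(NA))
  raw$reac <- add(raw$reac, "reaction_date_low_precision", FALSE)
  if (!is.null(raw$ther)) {
    raw$ther <- add(raw$ther, "start_date", as.Date(NA))
    raw$ther <- add(raw$ther, "start_date_low_precision", FALSE)
    raw$ther <- add(raw$ther, "dur", NA_real_)
    raw$ther <- add(raw$ther, "dur_cod", NA_character_)
  }
  raw$demo <- add(raw$demo, "age_cod", "YR")
  raw
}

#' Deduplicate case versions to one record per safety report
#'
#' FAERS cases are re-submitted as new versions; only the latest version
#' of each unique safety report id is analytically valid.  For every
#' `caseid`, the retained version is the maximum under the lexicographic
#' order (case version, receipt date, file order); exact ties on the
#' first two keys keep the later file-order row and emit a warning.  The
#' surviving key set is applied to every entity table, seriousness flags
#' are pivoted wide from the outcome table, therapy and indication rows
#' are joined onto their drug rows, and drug/indication text is
#' normalized via [normalize_text()].
#'
#' Deduplication is idempotent and the output has exactly one record per
#' distinct case id.
#'
#' @param raw a `faers_raw` object.
#' @param synonym_map passed to [normalize_text()]; defaults to
#'   [default_synonyms()].
#' @return a `faers_data` object: list of tibbles `demo` (one row per
#'   report, with logical columns `death`, `life_threatening`,
#'   `hospitalization`, `disability`, `congenital_anomaly`,
#'   `other_serious`, `serious`), `drug` (with `drugname_norm`,
#'   `indication`, `indication_norm`, `start_date`, `dur`, `dur_cod`),
#'   `reac`, `outc`.
#' @export
deduplicate <- function(raw, synonym_map = default_synonyms()) {
  stopifnot(inherits(raw, "faers_raw") || is.list(raw))
  raw <- .ensure_optional_cols(raw)
  demo <- tibble::as_tibble(raw$demo)
  demo$.file_order <- seq_len(nrow(demo))
  demo <- demo[!(is.na(demo$caseid) | !nzchar(trimws(demo$caseid))), ]

  ord <- order(demo$caseid,
               demo$caseversion,
               demo$receiptdate,
               demo$.file_order,
               na.last = FALSE)
  demo_sorted <- demo[ord, ]
  keep_idx <- !duplicated(demo_sorted$caseid, fromLast = TRUE)
  dup_key <- duplicated(demo_sorted[, c("caseid", "caseversion",
                                        "receiptdate")]) |
    duplicated(demo_sorted[, c("caseid", "caseversion", "receiptdate")],
               fromLast = TRUE)
  if (any(dup_key & keep_idx)) {
    warning(sprintf(
      "%d case(s) had ties on (caseversion, receiptdate); kept the later file-order row",
      sum(dup_key & keep_idx)), call. = FALSE)
  }
  winners <- demo_sorted[keep_idx, ]
  keys <- winners[, c("caseid", "caseversion")]

  pick <- function(tb) {
    if (is.null(tb)) return(tibble::tibble())
    if (nrow(tb) == 0) return(tibble::as_tibble(tb))
    dplyr::semi_join(tibble::as_tibble(tb), keys,
                     by = c("caseid", "caseversion"))
  }
  drug <- pick(raw$drug)
  reac <- pick(raw$reac)
  outc <- pick(raw$outc)
  ther <- pick(raw$ther)
  indi <- pick(raw$indi)

  flag_map <- c(DE = "death", LT = "life_threatening", HO = "hospitalization",
                DS = "disability", CA = "congenital_anomaly",
                OT = "other_serious")
  demo_out <- winners
  demo_out$.file_order <- NULL
  for (code in names(flag_map)) {
    ids <- unique(outc$caseid[outc$outc_cod == code])
    demo_out[[flag_map[[code]]]] <- demo_out$caseid %in% ids
  }
  demo_out$serious <- Reduce(`|`, lapply(unname(flag_map),
                                         function(f) demo_out[[f]]))

  drug$drugname_norm <- normalize_text(drug$drugname, synonym_map)
  if (nrow(indi)) {
    indi_j <- indi[, c("caseid", "caseversion", "indi_drug_seq", "indi_pt")]
    names(indi_j)[3:4] <- c("drug_seq", "indication")
    indi_j <- indi_j[!duplicated(indi_j[, c("caseid", "caseversion",
                                            "drug_seq")]), ]
    drug <- dplyr::left_join(drug, indi_j,
                             by = c("caseid", "caseversion", "drug_seq"))
  } else {
    drug$indication <- NA_character_
  }
  drug$indication_norm <- normalize_text(drug$indication, synonym_map)
  drug$indication_norm[is.na(drug$indication)] <- NA_character_
  if (nrow(ther)) {
    ther_j <- ther[, c("caseid", "caseversion", "dsg_drug_seq", "start_date",
                       "start_date_low_precision", "dur", "dur_cod")]
    names(ther_j)[3] <- "drug_seq"
    ther_j <- ther_j[!duplicated(ther_j[, c("caseid", "caseversion",
                                            "drug_seq")]), ]
    drug <- dplyr::left_join(drug, ther_j,
                             by = c("caseid", "caseversion", "drug_seq"))
  } else {
    drug$start_date <- as.Date(NA)
    drug$start_date_low_precision <- FALSE
    drug$dur <- NA_real_
    drug$dur_cod <- NA_character_
  }

  structure(list(demo = demo_out, drug = drug, reac = reac, outc = outc),
            class = "faers_data")
}

#' Subset a deduplicated report set to given case ids
#'
#' @param data a `faers_data` object.
#' @param caseids character vector of case ids to retain.
#' @return a `faers_data` with all tables restricted to `caseids`.
#' @export
filter_reports <- function(data, caseids) {
  stopifnot(inherits(data, "faers_data"))
  out <- lapply(data, function(tb) tb[tb$caseid %in% caseids, , drop = FALSE])
  structure(out, class = "faers_data")
}

#' Flatten a deduplicated report set to one row per report-drug-reaction
#'
#' The normalized long layout used for file export: the cartesian join of
#' a report's drug entries and reaction entries, carrying demographics
#' and seriousness flags.
#'
#' @param data a `faers_data` object.
#' @return a tibble.
#' @export
flatten_reports <- function(data) {
  stopifnot(inherits(data, "faers_data"))
  d <- dplyr::inner_join(
    data$drug[, c("caseid", "drug_seq", "role_cod", "drugname",
                  "drugname_norm", "indication_norm")],
    data$reac[, c("caseid", "pt")],
    by = "caseid", relationship = "many-to-many")
  dplyr::left_join(
    d,
    data$demo[, c("caseid", "age", "sex", "death", "life_threatening",
                  "hospitalization", "serious")],
    by = "caseid")
}

#' @export
print.faers_raw <- function(x, ...) {
  cat("<faers_raw> pre-deduplication tables\n")
  for (nm in names(x)) cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' @export
print.faers_data <- function(x, ...) {
  cat(sprintf("<faers_data> %d deduplicated reports (%d serious)\n",
              nrow(x$demo), sum(x$demo$serious)))
  invisible(x)
}
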