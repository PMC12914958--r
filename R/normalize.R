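#' Normalize free-text drug and indication strings
#'
#' Spontaneous reports carry verbatim drug and indication text
#' (`medicinalproduct`, `drugindication`) with inconsistent case,
#' punctuation and spelling.  `normalize_text()` applies the standard
#' cleaning used before counting: uppercase, strip every character outside
#' `[A-Z0-9 ]`, collapse runs of whitespace, then map known synonyms or
#' brand names to a canonical term.  The synonym lookup happens *after*
#' cleaning, so map keys must themselves be cleaned strings.
#'
#' The function is idempotent: `normalize_text(normalize_text(x))` equals
#' `normalize_text(x)` provided the synonym map's values are fixed points
#' of the map (the shipped default is).
#'
#' @param x character vector of raw strings (`NA` passes through).
#' @param synonym_map named character vector; names are cleaned keys,
#'   values the canonical replacement.  `NULL` disables mapping.
#' @return character vector of canonical strings.
#' @examples
#' normalize_text("  Carboplatin (Paraplatin)!")
#' normalize_text("Abraxane", synonym_map = default_synonyms())
#' @export
normalize_text <- function(x, synonym_map = NULL) {
  if (length(x) == 0L) return(character(0))
  out <- toupper(as.character(x))
  out <- gsub("[^A-Z0-9 ]", "", out)
  out <- gsub("[ ]+", " ", out)
  out <- trimws(out)
  if (!is.null(synonym_map) && length(synonym_map)) {
    hit <- match(out, names(synonym_map))
    out[!is.na(hit)] <- unname(synonym_map[hit[!is.na(hit)]])
  }
  out
}

#' Built-in synonym map for drug-name normalization
#'
#' Brand-to-generic entries for the fourteen cytotoxic chemotherapy agents
#' of the concomitant-chemotherapy panel (see [chemo_panel()]), plus a few
#' routine spelling variants.  Keys are already cleaned (uppercase, no
#' punctuation); values are cleaned canonical generic names, so the map is
#' idempotent under [normalize_text()].
#'
#' @return named character vector usable as `synonym_map`.
#' @export
default_synonyms <- function() {
  c(
    "PARAPLATIN"          = "CARBOPLATIN",
    "PLATINOL"            = "CISPLATIN",
    "TAXOL"               = "PACLITAXEL",
    "TAXOTERE"            = "DOCETAXEL",
    "ABRAXANE"            = "NABPACLITAXEL",
    "NAB PACLITAXEL"      = "NABPACLITAXEL",
    "PACLITAXEL PROTEIN BOUND" = "NABPACLITAXEL",
    "ALIMTA"              = "PEMETREXED",
    "GEMZAR"              = "GEMCITABINE",
    "CYTOXAN"             = "CYCLOPHOSPHAMIDE",
    "VEPESID"             = "ETOPOSIDE",
    "ETOPOPHOS"           = "ETOPOSIDE",
    "ADRUCIL"             = "FLUOROURACIL",
    "5 FU"                = "FLUOROURACIL",
    "5FU"                 = "FLUOROURACIL",
    "FLUOROURACIL 5"      = "FLUOROURACIL",
    "ELOXATIN"            = "OXALIPLATIN",
    "CAMPTOSAR"           = "IRINOTECAN",
    "NAVELBINE"           = "VINORELBINE",
    "ADRIAMYCIN"          = "DOXORUBICIN",
    "KEYTRUDA"            = "PEMBROLIZUMAB"
  )
}
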