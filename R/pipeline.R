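#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `input_dir` (a directory of FAERS-style tables) or
#' `synthetic` (a [synthetic_config()]) must be supplied.
#'
#' @param drug target drug name.
#' @param pt primary Preferred Term of interest.
#' @param input_dir directory with `DEMO`/`DRUG`/`REAC`/`OUTC`(/`THER`/
#'   `INDI`) files, or `NULL`.
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param supplementary_pt PT for the supplementary severity analysis
#'   (default `"Febrile neutropenia"`).
#' @param panel concomitant chemotherapy panel, normalized names.
#' @param day_marks cumulative-onset day marks.
#' @param cap onset outlier cap in days.
#' @param continuity apply the Haldane correction in [ror()].
#' @param indication_exclusions normalized indication terms removed
#'   before ranking.
#' @param top_k number of ranked terms to report.
#' @param dialect input table dialect, `"faers"` or `"csv"`.
#' @param out_dir output directory.
#' @param make_plots write onset histogram / cumulative-curve figures.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(drug = "PEMBROLIZUMAB", pt = "Neutropenia",
                       input_dir = NULL, synthetic = NULL,
                       supplementary_pt = "Febrile neutropenia",
                       panel = chemo_panel(), day_marks = c(30, 60),
                       cap = 1825, continuity = FALSE,
                       indication_exclusions = c("UNKNOWN INDICATION",
                                                 "PROPHYLAXIS"),
                       top_k = 10, dialect = "faers",
                       out_dir = tempfile("pvrun"), make_plots = TRUE) {
  if (is.null(input_dir) == is.null(synthetic))
    stop("exactly one of 'input_dir' and 'synthetic' must be set",
         call. = FALSE)
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (!nzchar(pt)) stop("pt must be non-empty", call. = FALSE)
  structure(list(drug = drug, pt = pt, input_dir = input_dir,
                 synthetic = synthetic, supplementary_pt = supplementary_pt,
                 panel = panel, day_marks = day_marks, cap = cap,
                 continuity = continuity,
                 indication_exclusions = indication_exclusions,
                 top_k = top_k, dialect = dialect, out_dir = out_dir,
                 make_plots = make_plots),
            class = "run_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ingestion (reading the input tables or generating
#' and round-tripping synthetic ones), deduplication, restriction to
#' serious reports, the primary-suspect cohort, disproportionality
#' statistics with signal criteria and a sex-stratified reporting odds
#' ratio, the Preferred-Term core cohort, clinical characterization
#' (demographics, outcomes, ranked indications and concomitant
#' medications), hierarchical time-to-onset analysis with the
#' chemotherapy subgroup comparison, and the supplementary
#' febrile-neutropenia severity tabulation.  Every stage logs one line
#' with its input/output row counts; any stage failure aborts with the
#' stage name and the cohort sizes reached so far.  All tables are
#' written tab-separated under `config$out_dir`, and a JSON manifest
#' records input/output file hashes, the seed, stage counts and the
#' package version.  Re-running the same configuration reproduces
#' identical tables.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) a list with the fitted objects: `data`, `corpus`
#'   (serious reports), `cohort`, `signal`, `stratified`, `pt_cohort`,
#'   `demographics`, `outcomes`, `indications`, `concomitants`, `tto`,
#'   `tto_summary`, `group_summaries`, `comparison`, `fn`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed (%s); cohort sizes so far: %s",
                   name, conditionMessage(e),
                   paste(names(counts), unlist(counts), sep = "=",
                         collapse = ", ")), call. = FALSE)
    })
  }

  # -- ingest ----------------------------------------------------------
  input_dir <- config$input_dir
  raw <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      gen <- generate_reports(config$synthetic)
      input_dir <- file.path(out_dir, "input")
      write_faers_tables(gen, input_dir, dialect = config$dialect)
    }
    read_faers_tables(input_dir, dialect = config$dialect)
  })
  counts$raw_rows <- nrow(raw$demo)
  say("ingest: %d raw demo rows", counts$raw_rows)

  # -- deduplicate -----------------------------------------------------
  data <- stage("deduplicate", deduplicate(raw))
  counts$deduplicated <- nrow(data$demo)
  say("deduplicate: %d -> %d reports", counts$raw_rows, counts$deduplicated)

  # -- serious corpus (disproportionality scope) -----------------------
  corpus <- stage("serious_filter", filter_serious(data))
  counts$serious <- nrow(corpus$demo)
  say("serious_filter: %d serious reports", counts$serious)

  # -- primary-suspect cohort ------------------------------------------
  cohort <- stage("ps_cohort",
                  filter_primary_suspect_serious(corpus, config$drug))
  counts$ps_serious <- nrow(cohort$demo)
  say("ps_cohort: %d primary-suspect serious reports", counts$ps_serious)

  # -- disproportionality ----------------------------------------------
  signal <- stage("signal", {
    prior <- tryCatch(fit_mgps_prior(pair_counts(corpus)),
                      error = function(e) {
                        say("signal: MGPS prior unavailable (%s)",
                            conditionMessage(e))
                        NULL
                      })
    signal_stats(corpus, config$drug, config$pt, prior = prior,
                 continuity = config$continuity)
  })
  stratified <- stage("stratified_ror",
                      stratified_ror(corpus, config$drug, config$pt,
                                     stratum = "sex",
                                     continuity = config$continuity))
  counts$event_reports <- as.integer(signal$a)
  say("signal: a=%g, ROR=%.2f", signal$a, signal$ror)

  # -- core PT cohort --------------------------------------------------
  pt_cohort <- stage("pt_cohort", select_pt_cohort(cohort, config$pt))
  counts$pt_cohort <- nrow(pt_cohort$demo)
  say("pt_cohort: %d reports with PT '%s'", counts$pt_cohort, config$pt)

  # -- characterization ------------------------------------------------
  demographics <- stage("characterization", summarize_demographics(pt_cohort))
  outcomes <- stage("characterization", tabulate_outcomes(pt_cohort))
  indications <- stage("characterization",
                       rank_top(pt_cohort, "indication", k = config$top_k,
                                exclusions = config$indication_exclusions))
  concomitants <- stage("characterization",
                        rank_top(pt_cohort, "concomitant_drug",
                                 k = config$top_k))

  # -- time-to-onset ---------------------------------------------------
  tto <- stage("tto", {
    obs <- compute_tto(pt_cohort, config$drug, config$pt, cap = config$cap)
    grp <- classify_chemo(pt_cohort, config$panel)
    dplyr::left_join(obs, grp, by = "caseid")
  })
  counts$tto_evaluable <- nrow(tto)
  say("tto: %d evaluable onsets", counts$tto_evaluable)
  tto_sum <- if (nrow(tto) > 0)
    stage("tto", tto_summary(tto$tto_days, day_marks = config$day_marks))
  else NULL
  group_summaries <- comparison <- NULL
  if (nrow(tto) > 0 && length(unique(tto$chemo)) == 2) {
    group_summaries <- stage("tto", lapply(
      split(tto$tto_days, ifelse(tto$chemo, "chemo", "no_chemo")),
      tto_summary, day_marks = config$day_marks))
    comparison <- stage("tto", compare_groups(tto$tto_days[tto$chemo],
                                              tto$tto_days[!tto$chemo]))
    say("tto: median chemo %.1f vs no-chemo %.1f d (U=%g, p=%.4g)",
        group_summaries$chemo$median, group_summaries$no_chemo$median,
        comparison$u, comparison$p_value)
  }

  # -- febrile-neutropenia supplement ----------------------------------
  fn <- stage("fn_supplement", {
    fn_cohort <- select_pt_cohort(cohort, config$supplementary_pt)
    cls <- classify_chemo(fn_cohort, config$panel)
    n_fn <- nrow(fn_cohort$demo)
    tibble::tibble(pt = config$supplementary_pt, n = n_fn,
                   n_chemo = sum(cls$chemo),
                   pct_chemo = if (n_fn > 0)
                     percent_round(sum(cls$chemo), n_fn) else NA_real_)
  })
  counts$fn_cohort <- fn$n
  say("fn_supplement: %d reports, %.1f%% with concomitant chemotherapy",
      fn$n, fn$pct_chemo)

  # -- outputs ---------------------------------------------------------
  files <- character(0)
  files["signal"] <- .write_tsv(signal, file.path(out_dir, "signal_table.tsv"))
  files["stratified"] <- .write_tsv(stratified,
                                    file.path(out_dir, "stratified_ror.tsv"))
  demo_tab <- tibble::tibble(
    variable = c("n", "age_available", "age_missing", "age_median", "age_q1",
                 "age_q3", "age_ge65_n", "age_ge65_pct", "sex_available",
                 "sex_missing", "female_n", "female_pct", "male_n",
                 "male_pct"),
    value = c(demographics$n, demographics$age$available,
              demographics$age$missing, demographics$age$median,
              demographics$age$q1, demographics$age$q3,
              demographics$age$n_ge65, demographics$age$pct_ge65,
              demographics$sex$available, demographics$sex$missing,
              demographics$sex$n_female, demographics$sex$pct_female,
              demographics$sex$n_male, demographics$sex$pct_male))
  files["demographics"] <- .write_tsv(demo_tab,
                                      file.path(out_dir, "demographics.tsv"))
  files["outcomes"] <- .write_tsv(outcomes, file.path(out_dir, "outcomes.tsv"))
  files["indications"] <- .write_tsv(indications,
                                     file.path(out_dir, "top_indications.tsv"))
  files["concomitants"] <- .write_tsv(
    concomitants, file.path(out_dir, "top_concomitants.tsv"))
  files["tto"] <- .write_tsv(tto, file.path(out_dir, "tto_observations.tsv"))
  if (!is.null(tto_sum)) {
    sum_tab <- tibble::tibble(
      statistic = c("n", "median", "q1", "q3",
                    paste0("cum_", names(tto_sum$cumulative))),
      value = c(tto_sum$n, tto_sum$median, tto_sum$q1, tto_sum$q3,
                unname(tto_sum$cumulative)))
    files["tto_summary"] <- .write_tsv(sum_tab,
                                       file.path(out_dir, "tto_summary.tsv"))
  }
  if (!is.null(comparison)) {
    cmp_tab <- tibble::tibble(
      statistic = c("u_chemo", "p_value", "n_chemo", "n_no_chemo",
                    "median_chemo", "median_no_chemo"),
      value = c(comparison$u, comparison$p_value, comparison$n1,
                comparison$n2, group_summaries$chemo$median,
                group_summaries$no_chemo$median))
    files["tto_comparison"] <- .write_tsv(
      cmp_tab, file.path(out_dir, "tto_comparison.tsv"))
  }
  files["fn"] <- .write_tsv(fn, file.path(out_dir, "fn_supplement.tsv"))

  plot_files <- character(0)
  if (config$make_plots && nrow(tto) > 0) {
    plot_files <- stage("plots", .tto_plots(tto, tto_sum, out_dir,
                                            config$day_marks))
  }

  input_files <- list.files(input_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pvsignal")),
    seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
    drug = config$drug, pt = config$pt,
    stage_counts = counts,
    input_hashes = as.list(tools::md5sum(input_files)),
    output_hashes = as.list(tools::md5sum(unname(files))),
    plot_files = as.list(unname(plot_files))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(data = data, corpus = corpus, cohort = cohort,
                 signal = signal, stratified = stratified,
                 pt_cohort = pt_cohort, demographics = demographics,
                 outcomes = outcomes, indications = indications,
                 concomitants = concomitants, tto = tto,
                 tto_summary = tto_sum, group_summaries = group_summaries,
                 comparison = comparison, fn = fn, manifest = manifest,
                 out_dir = out_dir))
}

# onset histogram and cumulative-proportion curve, written as PNG
.tto_plots <- function(tto, tto_sum, out_dir, day_marks) {
  md <- stats::median(tto$tto_days)
  p1 <- ggplot2::ggplot(tto, ggplot2::aes(x = .data$tto_days)) +
    ggplot2::geom_histogram(binwidth = 15, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = md, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Time to onset (days)", y = "Reports",
                  title = sprintf("Onset distribution (median %.1f d)", md)) +
    ggplot2::theme_minimal()
  df <- data.frame(t = sort(tto$tto_days))
  df$p <- seq_along(df$t) / nrow(df)
  p2 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$p)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = day_marks, linetype = "dotted") +
    ggplot2::labs(x = "Time to onset (days)",
                  y = "Cumulative proportion of events") +
    ggplot2::theme_minimal()
  f1 <- file.path(out_dir, "tto_histogram.png")
  f2 <- file.path(out_dir, "tto_cumulative.png")
  suppressMessages({
    ggplot2::ggsave(f1, p1, width = 6, height = 4, dpi = 120)
    ggplot2::ggsave(f2, p2, width = 6, height = 4, dpi = 120)
  })
  c(histogram = f1, cumulative = f2)
}
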