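#' Write a results table in the report formats
#'
#' Writes a data frame as TSV and/or JSON with deterministic column order
#' and row order (rows are written as given). The JSON mirrors the TSV
#' content row by row.
#'
#' @param results non-empty data frame.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param formats subset of `c("tsv", "json")`.
#' @return named character vector of file paths, invisibly.
#' @export
write_reports <- function(results, dir, name, formats = c("tsv", "json")) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a non-empty data frame", call. = FALSE)
  }
  bad <- setdiff(formats, c("tsv", "json"))
  if (length(bad)) {
    stop("unknown report format(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("tsv" %in% formats) {
    p <- file.path(dir, paste0(name, ".tsv"))
    con <- file(p, open = "w", encoding = "UTF-8")
    write.table(results, con, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    close(con)
    paths["tsv"] <- p
  }
  if ("json" %in% formats) {
    p <- file.path(dir, paste0(name, ".json"))
    jsonlite::write_json(results, p, dataframe = "rows", na = "null",
                         digits = NA, pretty = TRUE)
    paths["json"] <- p
  }
  invisible(paths)
}

#' Run the full alignment analysis pipeline
#'
#' Orchestrates ingestion, validation, per-speaker profiles and usage
#' summaries, dyadic turn extraction (target child vs primary caregiver),
#' per-session alignment tests against the Monte Carlo null in all three
#' directions, the attrition report, and the session-level correspondence
#' tables. All randomness derives from the single master `seed`
#' (per-session sub-seeds are drawn deterministically), so the same input
#' and seed give byte-identical tabular outputs.
#'
#' Output files (in `out_dir`): `profiles`, `usage_summary`, `turns`
#' (model-ready turn-level export), `alignment_results`, `attrition`
#' (pooled-direction accounting), `correspondence_input`,
#' `correspondence_correlations`, `correspondence_comparisons` (each in
#' the requested formats) and `manifest.json`.
#'
#' @param input a canonical table path (see [read_utterance_table()]) or a
#'   list of [session_record()] objects (e.g. from [read_eaf()] or
#'   [generate_cohort()]).
#' @param out_dir output directory.
#' @param n_iterations,dominance_threshold,min_turns,max_gap_ms alignment
#'   test settings, see [alignment_test()].
#' @param seed master integer seed.
#' @param alpha significance threshold used in the attrition report.
#' @param formats report formats, subset of `c("tsv", "json")`.
#' @param verbose emit per-stage log messages.
#' @return the run manifest (config, per-stage row counts, file list),
#'   invisibly.
#' @export
run_pipeline <- function(input, out_dir, n_iterations = 10000, seed = 1,
                         dominance_threshold = 0.80, min_turns = 30,
                         max_gap_ms = Inf, alpha = 0.05,
                         formats = c("tsv", "json"), verbose = TRUE) {
  log_msg <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  sessions <- if (is.character(input)) {
    if (!file.exists(input)) stop("unreadable input: ", input, call. = FALSE)
    read_utterance_table(input)
  } else {
    input
  }
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  log_msg("ingest", "%d session(s) read", length(sessions))

  issues <- lapply(sessions, validate_session)
  ok <- vapply(issues, nrow, integer(1L)) == 0L
  for (i in which(!ok)) {
    log_msg("validate", "session %s excluded: %s",
            sessions[[i]]$session_id,
            paste(unique(issues[[i]]$kind), collapse = ", "))
  }
  if (!any(ok)) {
    stop("zero valid sessions; issue kinds seen: ",
         paste(unique(unlist(lapply(issues, `[[`, "kind"))),
               collapse = ", "), call. = FALSE)
  }
  sessions <- sessions[ok]
  log_msg("validate", "%d valid session(s)", length(sessions))

  profiles <- do.call(rbind, lapply(sessions, speaker_profiles))
  usage <- usage_summary(sessions)
  log_msg("profiles", "%d speaker rows", nrow(profiles))

  series_per_session <- lapply(sessions, function(s) {
    lapply(c("CHILD_RESPONDS", "PARTNER_RESPONDS", "POOLED"),
           function(d) extract_turns(s, direction = d,
                                     max_gap_ms = max_gap_ms))
  })
  turn_rows <- do.call(rbind, unlist(lapply(series_per_session, function(l) {
    lapply(l[1:2], as.data.frame)   # directional rows partition the pooled
  }), recursive = FALSE))
  log_msg("turns", "%d directional turn rows", nrow(turn_rows))

  sub_seeds <- with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1L,
                      3L * length(sessions)), nrow = 3L)
  })
  results <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    meta <- data.frame(family_id = sessions[[i]]$family_id,
                       community = sessions[[i]]$community,
                       session_type = sessions[[i]]$session_type,
                       stringsAsFactors = FALSE)
    do.call(rbind, lapply(1:3, function(j) {
      at <- alignment_test(series_per_session[[i]][[j]],
                           n_iterations = n_iterations,
                           seed = sub_seeds[j, i],
                           dominance_threshold = dominance_threshold,
                           min_turns = min_turns, keep_null = FALSE)
      cbind(as.data.frame(at), meta)
    }))
  }))
  log_msg("align", "%d alignment tests (%d iterations each)",
          nrow(results), n_iterations)

  attrition <- attrition_report(
    results[results$direction == "POOLED", , drop = FALSE], alpha = alpha)
  corr_input <- family_proportion_table(sessions)
  corr <- correspondence_report(corr_input)
  log_msg("correspond", "%d correlation rows, %d comparison rows",
          nrow(corr$correlations), nrow(corr$comparisons))

  tables <- list(profiles = profiles, usage_summary = usage,
                 turns = turn_rows, alignment_results = results,
                 attrition = attrition,
                 correspondence_input = corr_input,
                 correspondence_correlations = corr$correlations,
                 correspondence_comparisons = corr$comparisons)
  files <- list()
  for (nm in names(tables)) {
    if (nrow(tables[[nm]]) == 0L) next
    # manifest records paths relative to out_dir so identical runs give
    # byte-identical manifests wherever they are written
    files[[nm]] <- as.list(basename(write_reports(tables[[nm]], out_dir,
                                                  nm, formats = formats)))
  }
  manifest <- list(
    package = "langalign",
    version = as.character(utils::packageVersion("langalign")),
    config = list(n_iterations = n_iterations, seed = seed,
                  dominance_threshold = dominance_threshold,
                  min_turns = min_turns,
                  max_gap_ms = if (is.finite(max_gap_ms)) max_gap_ms else
                    "unlimited",
                  alpha = alpha, formats = formats),
    n_sessions = length(sessions),
    row_counts = lapply(tables, nrow),
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("report", "outputs written to %s", out_dir)
  invisible(manifest)
}
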