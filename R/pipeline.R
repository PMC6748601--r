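#' Run the full matching pipeline
#'
#' Drives the stages end to end: load (or accept) a repertoire, apply the
#' productivity filter, build the index, search every query in every
#' requested mode, classify the query names, summarize with thresholds and
#' per-type strata, attribute best-match sources, and write the report in
#' both CSV and JSON plus a per-result CSV of raw matches.
#'
#' @param queries list of [numbered_chain()] query chains, or a FASTA path
#'   (numbered with `numberer`).  Heavy/light chains of one antibody share
#'   a base name with `_H`/`_L` suffixes.
#' @param repertoire list of [numbered_chain()] records, or a JSON-lines
#'   path read with [read_oas_jsonl()].
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @param modes comparison modes to run.
#' @param thresholds report thresholds.
#' @param types optional named vector query base name -> antibody type;
#'   derived from the names via [classify_inn()] otherwise.
#' @param scheme a [region_scheme()].
#' @param min_coverage productivity-filter coverage bound for file input.
#' @param numberer numberer for FASTA query input.
#' @param verbose print stage counts.
#' @return list with `report` (an `abmine_report`), `results` (all
#'   `match_result`s), `attribution` (see [source_attribution()]) and
#'   `index`.
#' @export
run_pipeline <- function(queries, repertoire, out_dir = NULL,
                         modes = MODES,
                         thresholds = c(90L, 95L, 100L), types = NULL,
                         scheme = region_scheme(), min_coverage = 0.8,
                         numberer = sequential_numberer, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(queries)) {
    q <- read_fasta_queries(queries, numberer)
    if (nrow(q$rejects)) say("queries rejected by numberer: %d", nrow(q$rejects))
    queries <- q$chains
  }
  if (is.character(repertoire)) {
    r <- read_oas_jsonl(repertoire, filter = TRUE, min_coverage = min_coverage)
    say("repertoire: %d kept, %d malformed, %d unproductive",
        length(r$chains), r$n_skipped, r$n_filtered)
    repertoire <- r$chains
  } else {
    keep <- vapply(repertoire, function(ch)
      productivity_filter(ch, min_coverage = min_coverage)$keep, TRUE)
    say("repertoire: %d of %d pass the productivity filter",
        sum(keep), length(keep))
    repertoire <- repertoire[keep]
  }
  if (length(queries) == 0L) stop("run_pipeline: no queries")
  index <- build_index(repertoire, scheme)
  say("index: %d records", index$n)

  results <- list()
  for (q in queries) {
    for (mode in modes) {
      if (mode == "cdrh3" && q$chain != "heavy") next
      results[[length(results) + 1L]] <- best_match(q, index, mode)
    }
  }
  results <- Filter(Negate(is.null), results)
  say("search: %d results over %d queries x %d mode(s)",
      length(results), length(queries), length(modes))

  if (is.null(types)) {
    base <- unique(sub("_[HL]$", "", vapply(queries, function(x)
      x$record_id, ""), ignore.case = TRUE))
    types <- stats::setNames(classify_inn(base), base)
  }
  report <- report_from_matches(results, types = types,
                                thresholds = thresholds)
  # attribution keys are full query ids
  qtypes <- stats::setNames(
    unname(types[sub("_[HL]$", "", vapply(queries, function(x)
      x$record_id, ""), ignore.case = TRUE)]),
    vapply(queries, function(x) x$record_id, ""))
  attribution <- source_attribution(results, qtypes)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "report.csv"), "csv")
    write_report(report, file.path(out_dir, "report.json"), "json")
    utils::write.csv(results_table(results),
                     file.path(out_dir, "results.csv"), row.names = FALSE)
    say("report written to %s", out_dir)
  }
  list(report = report, results = results, attribution = attribution,
       index = index)
}

#' Flatten match results to a data.frame
#'
#' @param results list of `match_result`s.
#' @return data.frame: query, mode, best_identity_raw, best_identity_pct,
#'   template_id, tie_count, study_id, species.
#' @export
results_table <- function(results) {
  results <- Filter(Negate(is.null), results)
  do.call(rbind, lapply(results, function(r) data.frame(
    query = r$query_id, mode = r$mode, best_identity_raw = r$best_value,
    best_identity_pct = percent_display(r$best_value),
    template_id = r$best_template_id, tie_count = r$tie_count,
    study_id = r$study_id, species = r$species, stringsAsFactors = FALSE)))
}
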