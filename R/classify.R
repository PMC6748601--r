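# the three CST molecules whose INN predates the modern suffix system
MOUSE_INN <- c("muromonab", "abagovomab", "racotumomab")

ANTIBODY_TYPES <- c("chimeric", "humanized", "fully_human", "mouse")

#' Classify antibody names by INN suffix
#'
#' International nonproprietary name (INN) suffix rules, applied
#' case-insensitively as substring tests: names containing `xizumab` or
#' `ximab` are chimeric; otherwise names containing `zumab` are humanized;
#' otherwise names containing `umab` are fully human.  Names on the
#' explicit mouse list override all suffix rules.  Names matching no rule
#' are reported as `"unknown"` rather than aborting a batch.
#'
#' @param names character vector of antibody names.
#' @param mouse_list names always classified as mouse.
#' @return character vector with values among `"chimeric"`, `"humanized"`,
#'   `"fully_human"`, `"mouse"`, `"unknown"`.
#' @examples
#' classify_inn(c("rituximab", "trastuzumab", "adalimumab", "muromonab"))
#' @export
classify_inn <- function(names, mouse_list = MOUSE_INN) {
  stopifnot(is.character(names), all(nzchar(names)))
  n <- tolower(names)
  out <- rep("unknown", length(n))
  out[grepl("umab", n, fixed = TRUE)] <- "fully_human"
  out[grepl("zumab", n, fixed = TRUE)] <- "humanized"
  out[grepl("ximab", n, fixed = TRUE) | grepl("xizumab", n, fixed = TRUE)] <- "chimeric"
  out[n %in% tolower(mouse_list)] <- "mouse"
  if (any(out == "unknown"))
    warning("classify_inn: ", sum(out == "unknown"),
            " name(s) matched no INN rule")
  out
}

# the five report columns, in published order
REPORT_COLUMNS <- c("heavy", "light", "heavy_cdrs", "light_cdrs", "cdrh3")

#' Build a summary report from per-query best identities
#'
#' Assembles the table-style report: one row per query with its antibody
#' type and best identity percent in each of the five comparison columns,
#' sorted by heavy-chain identity descending then name.  Threshold counts,
#' per-type strata and (when raw fractions are available) the raw values
#' are attached.
#'
#' @param identities data.frame with a `name` column and the five identity
#'   columns (integer percents 0-100; `NA` = no match found).  Columns
#'   `<col>_raw` holding the raw fractions are honoured when present.
#' @param types optional character vector of antibody types per row;
#'   computed with [classify_inn()] from `name` when missing.
#' @param thresholds integer thresholds evaluated as `>= t` per column
#'   (the top one also as `== t` when it is 100).
#' @return object of class `abmine_report`.
#' @export
summary_report <- function(identities, types = NULL,
                           thresholds = c(90L, 95L, 100L)) {
  stopifnot(is.data.frame(identities), "name" %in% names(identities))
  if (anyDuplicated(identities$name))
    stop("summary_report: duplicate query names")
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds > 100))
    stop("summary_report: thresholds must be strictly increasing in (0,100]")
  missing_cols <- setdiff(REPORT_COLUMNS, names(identities))
  for (col in missing_cols) identities[[col]] <- NA_integer_
  if (is.null(types)) types <- classify_inn(identities$name)
  rows <- data.frame(name = identities$name, type = types,
                     identities[REPORT_COLUMNS],
                     stringsAsFactors = FALSE)
  raw_cols <- paste0(REPORT_COLUMNS, "_raw")
  has_raw <- raw_cols %in% names(identities)
  raw <- if (any(has_raw)) identities[intersect(raw_cols, names(identities))]
         else NULL
  o <- order(-ifelse(is.na(rows$heavy), -1L, rows$heavy), rows$name)
  rows <- rows[o, , drop = FALSE]
  if (!is.null(raw)) raw <- raw[o, , drop = FALSE]
  rownames(rows) <- NULL
  rep <- structure(list(rows = rows, raw = raw, thresholds = thresholds),
                   class = "abmine_report")
  rep$threshold_counts <- .threshold_table(rep)
  rep$strata <- stratify_by_type(rep)
  rep
}

# predicate evaluation: on raw fractions when available (with a small
# epsilon so that exact rationals like 0.95 are not lost to representation
# error), on the displayed integer percents otherwise
.column_pass <- function(report, column, op, t) {
  raw_col <- paste0(column, "_raw")
  if (!is.null(report$raw) && raw_col %in% names(report$raw)) {
    v <- report$raw[[raw_col]]
    eps <- 1e-12
    pass <- switch(op, ">=" = v >= t / 100 - eps,
                       "==" = abs(v - t / 100) < eps)
  } else {
    v <- report$rows[[column]]
    pass <- switch(op, ">=" = v >= t, "==" = v == t)
  }
  pass & !is.na(v)  # no-match fails every predicate
}

#' Count rows passing an identity threshold predicate
#'
#' @param report an `abmine_report`.
#' @param column one of the five report columns, or a vector of columns
#'   whose predicates must all hold (e.g. `c("heavy","light")` for
#'   "both chains").
#' @param t integer threshold (percent).
#' @param op `">="` or `"=="`.
#' @return list(count, percentage) — percentage of rows, one decimal,
#'   half-up.
#' @export
threshold_count <- function(report, column, t, op = ">=") {
  stopifnot(inherits(report, "abmine_report"))
  pass <- Reduce(`&`, lapply(column, .column_pass, report = report,
                             op = op, t = t))
  count <- sum(pass)
  pct <- if (nrow(report$rows) == 0L) NA_real_
         else floor(count / nrow(report$rows) * 1000 + 0.5 + 1e-9) / 10
  list(count = count, percentage = pct)
}

.threshold_table <- function(report) {
  specs <- list()
  for (col in REPORT_COLUMNS) {
    for (t in report$thresholds) {
      op <- if (t == 100L) "==" else ">="
      specs[[length(specs) + 1L]] <- list(column = col, op = op, t = t)
    }
  }
  specs[[length(specs) + 1L]] <-
    list(column = c("heavy", "light"), op = ">=", t = 95L)
  out <- do.call(rbind, lapply(specs, function(s) {
    r <- threshold_count(report, s$column, s$t, s$op)
    data.frame(column = paste(s$column, collapse = "+"), op = s$op,
               threshold = s$t, count = r$count, percentage = r$percentage)
  }))
  out
}

#' Per-type distributions of the displayed identities
#'
#' @param report an `abmine_report`.
#' @param small_n strata with fewer rows than this are flagged
#'   `small_sample` (too few molecules for a meaningful distribution).
#' @return data.frame: type, column, n, min, q1, median, q3, max,
#'   small_sample.
#' @export
stratify_by_type <- function(report, small_n = 5L) {
  stopifnot(inherits(report, "abmine_report"))
  rows <- report$rows
  out <- list()
  for (ty in unique(rows$type)) {
    sub <- rows[rows$type == ty, , drop = FALSE]
    for (col in REPORT_COLUMNS) {
      v <- sub[[col]]
      v <- v[!is.na(v)]
      q <- if (length(v)) stats::quantile(v, c(0, .25, .5, .75, 1),
                                          names = FALSE, type = 7)
           else rep(NA_real_, 5)
      out[[length(out) + 1L]] <- data.frame(
        type = ty, column = col, n = nrow(sub),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        small_sample = nrow(sub) < small_n)
    }
  }
  do.call(rbind, out)
}

#' Attribute best-match sources by antibody type and mode
#'
#' Counts, over the retained best matches, which species the best template
#' came from, per (antibody type, comparison mode), and collects the set of
#' distinct studies contributing any best match.  When the best value was
#' tied across templates the earliest-inserted one is the retained source.
#'
#' @param results list of `match_result` objects (any modes, any queries).
#' @param types named character vector mapping query id to antibody type.
#' @return list with `counts` (data.frame type, mode, species, count,
#'   fraction within the type+mode) and `studies_hit` (character vector).
#' @export
source_attribution <- function(results, types) {
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L)
    return(list(counts = data.frame(), studies_hit = character(0)))
  df <- data.frame(
    type = unname(types[vapply(results, function(r) r$query_id, "")]),
    mode = vapply(results, function(r) r$mode, ""),
    species = vapply(results, function(r) r$species, ""),
    study = vapply(results, function(r) r$study_id, ""),
    stringsAsFactors = FALSE
  )
  tab <- as.data.frame(table(type = df$type, mode = df$mode,
                             species = df$species),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "count"
  group_tot <- stats::ave(tab$count, tab$type, tab$mode, FUN = sum)
  tab$fraction <- tab$count / group_tot
  rownames(tab) <- NULL
  list(counts = tab, studies_hit = sort(unique(df$study[!is.na(df$study)])))
}

#' Assemble a report from raw match results
#'
#' Groups `match_result`s by query (five result slots per query: heavy and
#' light full-chain, heavy and light CDR triplet, heavy CDR-H3), converting
#' raw best fractions to displayed percents.  Heavy and light chains of one
#' antibody are linked by a shared base name: query ids `name_H` / `name_L`.
#'
#' @param results list of `match_result` objects.
#' @param types optional named vector query base name -> type.
#' @param thresholds see [summary_report()].
#' @return an `abmine_report`.
#' @export
report_from_matches <- function(results, types = NULL,
                                thresholds = c(90L, 95L, 100L)) {
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L) stop("report_from_matches: no results")
  base <- function(id) sub("_[HL]$", "", id, ignore.case = TRUE)
  is_light <- function(id) grepl("_L$", id, ignore.case = TRUE)
  slot_of <- function(r) {
    light <- is_light(r$query_id)
    switch(r$mode,
           full_chain = if (light) "light" else "heavy",
           cdr_triplet = if (light) "light_cdrs" else "heavy_cdrs",
           cdrh3 = if (light) NA_character_ else "cdrh3")
  }
  names_all <- unique(vapply(results, function(r) base(r$query_id), ""))
  df <- data.frame(name = names_all, stringsAsFactors = FALSE)
  for (col in REPORT_COLUMNS) {
    df[[col]] <- NA_integer_
    df[[paste0(col, "_raw")]] <- NA_real_
  }
  for (r in results) {
    slot <- slot_of(r)
    if (is.na(slot)) next
    i <- match(base(r$query_id), df$name)
    if (!is.na(df[[slot]][i]))
      stop("report_from_matches: duplicate result for ",
           base(r$query_id), " / ", slot)
    df[[slot]][i] <- percent_display(r$best_value)
    df[[paste0(slot, "_raw")]][i] <- r$best_value
  }
  ty <- if (is.null(types)) NULL else unname(types[df$name])
  summary_report(df, types = ty, thresholds = thresholds)
}

#' @export
print.abmine_report <- function(x, ...) {
  cat(sprintf("<abmine_report: %d antibodies>\n", nrow(x$rows)))
  print(utils::head(x$rows, 5))
  if (nrow(x$rows) > 5) cat("  ...\n")
  cat("threshold counts:\n")
  print(x$threshold_counts)
  invisible(x)
}
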