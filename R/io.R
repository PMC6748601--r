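# region keys accepted in OAS-style data lines
.oas_region_keys <- c(paste0("fwh", 1:4), paste0("cdrh", 1:3),
                      paste0("fwl", 1:4), paste0("cdrl", 1:3))

#' Read an OAS-style JSON-lines repertoire
#'
#' The first line is a study-level metadata object (at least `study_id`,
#' `species` and `chain`); each subsequent line is one sequence as a JSON
#' object whose region keys (`fwh1`/`cdrh1`/... or `fwl1`/`cdrl1`/...) map
#' IMGT position labels to single residues.  Region maps are merged into one
#' ordered position map per record.  Malformed data lines (bad JSON, residues
#' outside the amino-acid alphabet, duplicate positions) are skipped and
#' counted, never fatal; sequences failing the productivity filter are
#' likewise dropped and counted.
#'
#' The file is consumed in chunks of `chunk_size` lines, so arbitrarily
#' large repertoires can be processed with a `callback` without holding all
#' records in memory.
#'
#' @param path JSON-lines file.
#' @param filter apply [productivity_filter()] on ingest (default TRUE).
#' @param min_coverage passed to the filter.
#' @param callback optional `function(chains)` invoked per chunk; when
#'   supplied the records are not accumulated.
#' @param chunk_size lines per chunk.
#' @return (invisibly when `callback` is used) a list with `chains` (list of
#'   [numbered_chain()]), `meta` (the study metadata), `n_skipped` malformed
#'   lines and `n_filtered` unproductive records with a reason table.
#' @export
read_oas_jsonl <- function(path, filter = TRUE, min_coverage = 0.8,
                           callback = NULL, chunk_size = 5000L) {
  con <- file(path, open = "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (length(header) == 0L) stop("read_oas_jsonl: empty file, no metadata line")
  meta <- tryCatch(jsonlite::fromJSON(header, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta) || is.null(meta$study_id) || is.null(meta$chain))
    stop("read_oas_jsonl: first line must be a metadata object with study_id and chain")
  if (!meta$chain %in% c("heavy", "light"))
    stop("read_oas_jsonl: unknown chain label '", meta$chain, "'")
  meta <- as.list(meta)

  chains <- list()
  n_skipped <- 0L
  reasons <- c(stop_codon = 0L, conserved_104 = 0L,
               conserved_118 = 0L, coverage = 0L)
  rec_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    batch <- vector("list", length(lines))
    nb <- 0L
    for (ln in lines) {
      rec_no <- rec_no + 1L
      ch <- .parse_oas_line(ln, meta, rec_no)
      if (is.null(ch)) { n_skipped <- n_skipped + 1L; next }
      if (filter) {
        verdict <- productivity_filter(ch, min_coverage = min_coverage)
        if (!verdict$keep) {
          reasons[verdict$reason] <- reasons[verdict$reason] + 1L
          next
        }
      }
      nb <- nb + 1L
      batch[[nb]] <- ch
    }
    batch <- batch[seq_len(nb)]
    if (is.null(callback)) chains <- c(chains, batch) else callback(batch)
  }
  if (n_skipped > 0L)
    warning("read_oas_jsonl: skipped ", n_skipped, " malformed line(s)")
  out <- list(chains = chains, meta = meta, n_skipped = n_skipped,
              n_filtered = sum(reasons), filter_reasons = reasons)
  if (is.null(callback)) out else invisible(out)
}

.parse_oas_line <- function(line, meta, rec_no) {
  obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(obj) || !is.list(obj)) return(NULL)
  keys <- intersect(names(obj), .oas_region_keys)
  if (length(keys) == 0L) return(NULL)
  pos <- character(0)
  res <- character(0)
  for (k in keys) {
    reg <- obj[[k]]
    pos <- c(pos, names(reg))
    res <- c(res, unlist(reg, use.names = FALSE))
  }
  if (!all(res %in% c(AA_ALPHABET, "*"))) return(NULL)
  id <- if (!is.null(obj$record_id)) as.character(obj$record_id)
        else paste0(meta$study_id, "_", rec_no)
  tryCatch(numbered_chain(id, meta$chain, pos, res, meta = meta),
           error = function(e) NULL)
}

#' Write numbered chains as an OAS-style JSON-lines file
#'
#' Inverse of [read_oas_jsonl()]: one metadata line, then one JSON object
#' per record with residues grouped by region.
#'
#' @param chains list of [numbered_chain()] (one chain type).
#' @param path output file.
#' @param meta study metadata list; defaults to the first chain's metadata.
#' @param scheme [region_scheme()] used to group positions into region keys.
#' @export
write_oas_jsonl <- function(chains, path, meta = NULL,
                            scheme = region_scheme()) {
  if (is.null(meta)) {
    meta <- if (length(chains)) chains[[1]]$meta else list()
  }
  if (is.null(meta$chain) && length(chains)) meta$chain <- chains[[1]]$chain
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), con)
  suffix <- if (identical(meta$chain, "light")) "l" else "h"
  for (ch in chains) {
    reg <- region_of(imgt_number(ch$positions), scheme)
    key <- paste0(sub("^(fw|cdr).*", "\\1", reg), suffix,
                  sub("^[a-z]+", "", reg))
    obj <- list(record_id = ch$record_id)
    for (k in unique(key)) {
      sel <- key == k
      obj[[k]] <- as.list(stats::setNames(ch$residues[sel], ch$positions[sel]))
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read query antibodies from FASTA, numbering them with a pluggable numberer
#'
#' Numbering (the assignment of IMGT positions to raw residues) is delegated
#' to an external component such as ANARCI; any `function(sequence, id)`
#' returning `list(chain=, positions=, residues=)` (or signalling an error /
#' returning NULL on failure) can stand in.  [sequential_numberer()] is a
#' built-in stub for pre-aligned input.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param numberer the numbering function.
#' @return list with `chains` (numbered, in file order) and `rejects`
#'   (data.frame of id + reason for records the numberer refused).
#' @export
read_fasta_queries <- function(path, numberer = sequential_numberer) {
  if (is.null(numberer)) stop("read_fasta_queries: no numberer configured")
  seqs <- .read_fasta(path)
  chains <- list()
  rejects <- data.frame(id = character(0), reason = character(0))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    num <- tryCatch(numberer(seqs[[i]], id), error = function(e) conditionMessage(e))
    if (is.character(num) || is.null(num)) {
      rejects <- rbind(rejects, data.frame(
        id = id, reason = if (is.null(num)) "numbering failed" else num))
      next
    }
    chains[[length(chains) + 1L]] <-
      numbered_chain(id, num$chain, num$positions, num$residues,
                     meta = list(query = TRUE))
  }
  list(chains = chains, rejects = rejects)
}

# FASTA reading: Biostrings when available, else a minimal fallback reader
.read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    return(stats::setNames(as.list(as.character(ss)),
                           sub("\\s.*$", "", names(ss))))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) stop("invalid FASTA: no leading header")
  idx <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  stats::setNames(as.list(unname(seqs)), ids)
}

#' Stub numberer: sequential IMGT positions from 1
#'
#' For input that is already aligned/trimmed; assigns positions 1, 2, ...
#' and infers nothing.  Chain type is taken from the record id suffix
#' (`_H`/`_L`, case-insensitive) and defaults to heavy.
#'
#' @param sequence amino-acid string.
#' @param id record id.
#' @return list(chain, positions, residues).
#' @export
sequential_numberer <- function(sequence, id = "") {
  res <- strsplit(sequence, "")[[1]]
  if (length(res) > 128L) stop("sequence longer than 128 positions")
  chain <- if (grepl("_L$", id, ignore.case = TRUE)) "light" else "heavy"
  list(chain = chain, positions = as.character(seq_along(res)), residues = res)
}

#' Read the shipped table of CST best identities
#'
#' Loads (by default) the transcription of the published table of 242
#' clinical-stage therapeutic antibodies with their best identity (integer
#' percent) to a repertoire sequence in five comparison columns.
#'
#' @param path CSV with columns name, heavy, light, heavy_cdrs, light_cdrs,
#'   cdrh3; defaults to the copy shipped with the package.
#' @param expect_rows required row count (default 242); `NULL` disables.
#' @return data.frame with the six columns, identities as integers 0-100.
#' @export
read_cst_table <- function(path = system.file("extdata",
                                              "cst_best_identities.csv",
                                              package = "abmine"),
                           expect_rows = 242L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "heavy", "light", "heavy_cdrs", "light_cdrs", "cdrh3")
  if (!all(need %in% names(df)))
    stop("read_cst_table: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  for (col in need[-1]) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != as.integer(v)))
      stop("read_cst_table: non-integer cell in column ", col)
    if (any(v < 0 | v > 100))
      stop("read_cst_table: identity outside [0,100] in column ", col)
    df[[col]] <- as.integer(v)
  }
  if (!is.null(expect_rows) && nrow(df) != expect_rows)
    stop("read_cst_table: expected ", expect_rows, " rows, found ", nrow(df))
  df
}
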