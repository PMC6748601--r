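#' Construct a numbered antibody chain
#'
#' One variable-domain chain represented as an ordered map from IMGT
#' position labels to amino-acid residues.  Positions are re-sorted into
#' IMGT sequence order on construction, so downstream code can rely on the
#' ordering regardless of input key order.
#'
#' @param record_id identifier string.
#' @param chain `"heavy"` or `"light"`.
#' @param positions character vector of IMGT position labels.
#' @param residues character vector of single residues (20 amino acids,
#'   `"X"` for unknown, or `"*"` for a stop, which the productivity filter
#'   later removes).
#' @param meta named list of study metadata (`study_id`, `species`, ...).
#' @return object of class `numbered_chain` with elements `record_id`,
#'   `chain`, `positions`, `residues`, `codes` (packed position+residue
#'   integers used by the matchers) and `meta`.
#' @examples
#' ch <- numbered_chain("q1", "heavy",
#'                      c("1", "2", "104", "105", "117", "118"),
#'                      c("E", "V", "C", "A", "W", "W"))
#' length(ch$positions)
#' @export
numbered_chain <- function(record_id, chain, positions, residues,
                           meta = list()) {
  chain <- match.arg(chain, c("heavy", "light"))
  positions <- as.character(positions)
  residues <- as.character(residues)
  if (length(positions) == 0L) stop("numbered_chain: no positions")
  if (length(positions) != length(residues))
    stop("numbered_chain: positions and residues differ in length")
  bad <- !(residues %in% c(AA_ALPHABET, "*"))
  if (any(bad))
    stop("numbered_chain: invalid residue(s): ",
         paste(unique(residues[bad]), collapse = ", "))
  r <- imgt_rank(positions)
  if (anyDuplicated(r)) stop("numbered_chain: duplicated positions")
  o <- order(r)
  positions <- positions[o]
  residues <- residues[o]
  res_code <- match(residues, c(AA_ALPHABET, "*"))
  structure(
    list(record_id = as.character(record_id), chain = chain,
         positions = positions, residues = residues,
         codes = r[o] * 32L + res_code, meta = meta),
    class = "numbered_chain"
  )
}

#' @export
print.numbered_chain <- function(x, ...) {
  cat(sprintf("<numbered_chain %s: %s, %d positions>\n",
              x$record_id, x$chain, length(x$positions)))
  cat(" ", chain_sequence(x), "\n")
  invisible(x)
}

#' @export
length.numbered_chain <- function(x) length(x$positions)

#' Linear amino-acid sequence of a chain (positions in IMGT order)
#' @param chain a [numbered_chain()].
#' @return single string.
#' @export
chain_sequence <- function(chain) paste(chain$residues, collapse = "")

#' Productivity filter
#'
#' Drops sequences that cannot encode a functional variable domain.  The
#' rules, each individually toggleable, are applied in order and the first
#' failure is reported: a stop codon anywhere; conserved position 104 not
#' cysteine; conserved position 118 not tryptophan/phenylalanine; numbered
#' coverage below `min_coverage` of the raw sequence length.
#'
#' @param chain a [numbered_chain()].
#' @param raw_sequence optional raw amino-acid string the chain was numbered
#'   from; used for the stop-codon and coverage rules.
#' @param min_coverage minimum fraction of the raw sequence that must have
#'   received a number (default 0.8); only checked when `raw_sequence` is given.
#' @param rules character vector naming the active rules.
#' @return list with `keep` (logical) and `reason` (`NA` when kept; otherwise
#'   one of `"stop_codon"`, `"conserved_104"`, `"conserved_118"`, `"coverage"`).
#' @export
productivity_filter <- function(chain, raw_sequence = NULL,
                                min_coverage = 0.8,
                                rules = c("stop_codon", "conserved_104",
                                          "conserved_118", "coverage")) {
  drop <- function(reason) list(keep = FALSE, reason = reason)
  if ("stop_codon" %in% rules) {
    if (any(chain$residues == "*") ||
        (!is.null(raw_sequence) && grepl("*", raw_sequence, fixed = TRUE)))
      return(drop("stop_codon"))
  }
  if ("conserved_104" %in% rules) {
    i <- match("104", chain$positions)
    if (is.na(i) || chain$residues[i] != "C") return(drop("conserved_104"))
  }
  if ("conserved_118" %in% rules) {
    i <- match("118", chain$positions)
    if (is.na(i) || !(chain$residues[i] %in% c("W", "F")))
      return(drop("conserved_118"))
  }
  if ("coverage" %in% rules && !is.null(raw_sequence)) {
    if (length(chain$positions) < min_coverage * nchar(raw_sequence))
      return(drop("coverage"))
  }
  list(keep = TRUE, reason = NA_character_)
}
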