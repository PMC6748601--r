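# The comparison modes recognised throughout the package
MODES <- c("full_chain", "cdr_triplet", "cdrh3")

identity_score <- function(value, m, len_query, len_template, mode) {
  structure(
    list(value = value, m = as.integer(m),
         len_query = as.integer(len_query),
         len_template = as.integer(len_template), mode = mode),
    class = "identity_score"
  )
}

#' @export
print.identity_score <- function(x, ...) {
  cat(sprintf("<identity_score %s: %.4f (m=%d, Lq=%d, Lt=%d) -> %d%%>\n",
              x$mode, x$value, x$m, x$len_query, x$len_template,
              percent_display(x)))
  invisible(x)
}

#' Symmetric positional sequence identity of two numbered chains
#'
#' A match is an IMGT position occupied in both chains with the same
#' residue.  The match count is divided by the occupied-position count of
#' each chain and the two ratios are averaged:
#' \deqn{ID = (m/L_q + m/L_t)/2.}
#' Averaging both normalisations penalises length discrepancy, so a chain
#' that is a substring of another cannot score 100%.  `"X"` never matches
#' anything, including another `"X"`.
#'
#' @param query,template [numbered_chain()] objects of the same chain type.
#' @return an `identity_score` with mode `"full_chain"`.
#' @export
positional_identity <- function(query, template) {
  stopifnot(inherits(query, "numbered_chain"),
            inherits(template, "numbered_chain"))
  if (query$chain != template$chain)
    stop("positional_identity: chain types differ (",
         query$chain, " vs ", template$chain, ")")
  lq <- length(query$positions)
  lt <- length(template$positions)
  if (lq == 0L || lt == 0L) stop("positional_identity: empty chain")
  qc <- query$codes[query$residues != "X"]
  tc <- template$codes[template$residues != "X"]
  m <- sum(qc %in% tc)
  identity_score((m / lq + m / lt) / 2, m, lq, lt, "full_chain")
}

# character-wise match count of two equal-length strings
.str_matches <- function(a, b) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  x <- utf8ToInt("X")
  sum(av == bv & av != x)
}

#' CDR-triplet identity (length-matched)
#'
#' Comparable only when all three loop lengths agree; the identity is then
#' the fraction of matching residues over the concatenated loops.  With
#' equal lengths the position-wise and character-wise counts coincide.
#'
#' @param query_cdrs,template_cdrs character vectors
#'   `c(cdr1, cdr2, cdr3)` as produced by [extract_cdrs()].
#' @return an `identity_score` with mode `"cdr_triplet"`, or `NULL` when
#'   the loop lengths differ (not comparable).
#' @export
cdr_triplet_identity <- function(query_cdrs, template_cdrs) {
  stopifnot(length(query_cdrs) == 3L, length(template_cdrs) == 3L)
  if (any(nchar(query_cdrs) != nchar(template_cdrs))) return(NULL)
  q <- paste(query_cdrs, collapse = "")
  t <- paste(template_cdrs, collapse = "")
  l <- nchar(q)
  if (l == 0L) stop("cdr_triplet_identity: all loops empty")
  m <- .str_matches(q, t)
  identity_score(m / l, m, l, l, "cdr_triplet")
}

#' CDR-H3 identity (length-matched)
#'
#' @param query_cdrh3,template_cdrh3 loop strings.
#' @return an `identity_score` with mode `"cdrh3"`, or `NULL` when the
#'   lengths differ.  A value of 1 is a perfect match.
#' @export
cdrh3_identity <- function(query_cdrh3, template_cdrh3) {
  if (nchar(query_cdrh3) != nchar(template_cdrh3)) return(NULL)
  l <- nchar(query_cdrh3)
  if (l == 0L) stop("cdrh3_identity: empty loop")
  m <- .str_matches(query_cdrh3, template_cdrh3)
  identity_score(m / l, m, l, l, "cdrh3")
}

#' Integer percent for display (half-up rounding)
#'
#' @param score an `identity_score` or a numeric fraction in [0, 1].
#' @return integer 0-100; `round(value * 100)` with ties rounded up.
#' @export
percent_display <- function(score) {
  v <- if (inherits(score, "identity_score")) score$value else score
  stopifnot(is.numeric(v), all(v >= 0 & v <= 1))
  # the 1e-9 guard keeps exact halves (e.g. 39/40) rounding up despite
  # binary representation error; scores are rationals m/L with L <= a few
  # hundred, so the guard cannot cross a rounding boundary
  as.integer(floor(v * 100 + 0.5 + 1e-9))
}
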