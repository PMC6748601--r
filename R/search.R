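#' Build a repertoire index for best-match search
#'
#' Partitions records by chain type, buckets them by the three CDR loop
#' lengths (for the length-matched triplet mode) and by CDR-H3 length, and
#' hashes exact CDR-H3 strings.  Insertion order (file order) is retained
#' and drives deterministic tie-breaking.
#'
#' @param chains list of [numbered_chain()] records (assumed to have passed
#'   the productivity filter).
#' @param scheme a [region_scheme()].
#' @return object of class `repertoire_index`.
#' @export
build_index <- function(chains, scheme = region_scheme()) {
  n <- length(chains)
  chain_type <- vapply(chains, function(x) x$chain, "")
  lens <- vapply(chains, function(x) length(x$positions), 0L)
  cdrs <- vapply(chains, function(x) extract_cdrs(x, scheme),
                 c(cdr1 = "", cdr2 = "", cdr3 = ""))
  if (n == 0L) cdrs <- matrix("", 3, 0, dimnames = list(c("cdr1","cdr2","cdr3")))
  lenkey <- paste(chain_type, nchar(cdrs["cdr1", ]), nchar(cdrs["cdr2", ]),
                  nchar(cdrs["cdr3", ]), sep = ":")
  cdr_concat <- paste0(cdrs["cdr1", ], cdrs["cdr2", ], cdrs["cdr3", ])
  h3key <- paste(chain_type, nchar(cdrs["cdr3", ]), sep = ":")
  idx <- seq_len(n)

  # flattened position+residue codes for the vectorised full-chain scan
  full <- list()
  for (ct in c("heavy", "light")) {
    sel <- idx[chain_type == ct]
    if (length(sel) == 0L) next
    codes <- lapply(chains[sel], function(x) x$codes[x$residues != "X"])
    full[[ct]] <- list(
      rec = rep.int(sel, lengths(codes)),
      codes = unlist(codes, use.names = FALSE),
      members = sel
    )
  }

  h3_exact <- new.env(hash = TRUE, parent = emptyenv())
  for (i in idx) {
    key <- paste(chain_type[i], cdrs["cdr3", i], sep = ":")
    h3_exact[[key]] <- c(h3_exact[[key]], i)
  }

  structure(list(
    chains = chains, n = n, chain_type = chain_type, lens = lens,
    cdr1 = unname(cdrs["cdr1", ]), cdr2 = unname(cdrs["cdr2", ]),
    cdr3 = unname(cdrs["cdr3", ]), cdr_concat = cdr_concat,
    buckets = split(idx, lenkey), h3_buckets = split(idx, h3key),
    h3_exact = h3_exact, scheme = scheme,
    study_id = vapply(chains, function(x)
      if (is.null(x$meta$study_id)) NA_character_ else x$meta$study_id, ""),
    species = vapply(chains, function(x)
      if (is.null(x$meta$species)) NA_character_ else x$meta$species, ""),
    full = full
  ), class = "repertoire_index")
}

#' @export
print.repertoire_index <- function(x, ...) {
  cat(sprintf("<repertoire_index: %d records (%d heavy, %d light), %d CDR-length buckets>\n",
              x$n, sum(x$chain_type == "heavy"), sum(x$chain_type == "light"),
              length(x$buckets)))
  invisible(x)
}

.match_result <- function(query, mode, values, eligible, index) {
  best <- max(values)
  ties <- eligible[values == best]
  keep <- min(ties)  # earliest insertion order
  structure(list(
    query_id = query$record_id, mode = mode, best_value = best,
    best_template_id = index$chains[[keep]]$record_id,
    template_index = keep, tie_count = length(ties),
    study_id = index$study_id[keep], species = index$species[keep]
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result %s [%s]: %.4f (%d%%) -> %s, ties=%d>\n",
              x$query_id, x$mode, x$best_value, percent_display(x$best_value),
              x$best_template_id, x$tie_count))
  invisible(x)
}

#' Best repertoire match for one query chain
#'
#' Exhaustive semantics over all eligible templates: every template of the
#' query's chain type in `full_chain` mode; templates whose three loop
#' lengths (or CDR-H3 length) equal the query's in the length-matched
#' modes, where the bucketing excludes only templates the length
#' precondition already rules out.  Ties on the best value are broken by
#' earliest insertion order and counted.
#'
#' @param query a [numbered_chain()].
#' @param index a [build_index()] result.
#' @param mode one of `"full_chain"`, `"cdr_triplet"`, `"cdrh3"`.
#' @return a `match_result`, or `NULL` when no template is eligible.
#' @export
best_match <- function(query, index, mode = MODES) {
  mode <- match.arg(mode)
  if (mode == "full_chain") {
    pool <- index$full[[query$chain]]
    if (is.null(pool)) return(NULL)
    lq <- length(query$positions)
    qc <- query$codes[query$residues != "X"]
    hits <- pool$codes %in% qc
    m <- tabulate(pool$rec[hits], nbins = index$n)[pool$members]
    lt <- index$lens[pool$members]
    values <- (m / lq + m / lt) / 2
    return(.match_result(query, mode, values, pool$members, index))
  }
  qcdrs <- extract_cdrs(query, index$scheme)
  if (mode == "cdr_triplet") {
    key <- paste(query$chain, nchar(qcdrs[["cdr1"]]), nchar(qcdrs[["cdr2"]]),
                 nchar(qcdrs[["cdr3"]]), sep = ":")
    eligible <- index$buckets[[key]]
    if (is.null(eligible)) return(NULL)
    q <- paste(qcdrs, collapse = "")
    if (nchar(q) == 0L) return(NULL)
    values <- vapply(index$cdr_concat[eligible],
                     function(t) .str_matches(q, t), 0) / nchar(q)
  } else {
    key <- paste(query$chain, nchar(qcdrs[["cdr3"]]), sep = ":")
    eligible <- index$h3_buckets[[key]]
    if (is.null(eligible)) return(NULL)
    q <- qcdrs[["cdr3"]]
    if (nchar(q) == 0L) return(NULL)
    values <- vapply(index$cdr3[eligible],
                     function(t) .str_matches(q, t), 0) / nchar(q)
  }
  .match_result(query, mode, values, eligible, index)
}

#' Exact-hash lookup of repertoire records whose CDR-H3 equals a string
#'
#' @param index a [build_index()] result.
#' @param cdrh3 loop string.
#' @param chain `"heavy"` or `"light"`.
#' @return integer vector of record indices (insertion order), possibly empty.
#' @export
cdrh3_exact_lookup <- function(index, cdrh3, chain = "heavy") {
  hits <- index$h3_exact[[paste(chain, cdrh3, sep = ":")]]
  if (is.null(hits)) integer(0) else sort(hits)
}

#' Exhaustive best-match scan (testing oracle)
#'
#' Same contract as [best_match()], implemented as a plain linear scan over
#' the repertoire list through the per-pair identity functions, with no
#' index structure.  Kept as an independent reference for equivalence
#' testing.
#'
#' @param query a [numbered_chain()].
#' @param chains list of [numbered_chain()] templates, insertion order.
#' @param mode comparison mode.
#' @param scheme a [region_scheme()].
#' @param template_cdrs optional list of precomputed [extract_cdrs()]
#'   results, one per template, to avoid re-extracting loops on every call;
#'   the per-pair comparison itself is unchanged.
#' @return a `match_result` or `NULL`.
#' @export
exhaustive_best_match <- function(query, chains, mode = MODES,
                                  scheme = region_scheme(),
                                  template_cdrs = NULL) {
  mode <- match.arg(mode)
  qcdrs <- extract_cdrs(query, scheme)
  if (mode == "cdrh3" && nchar(qcdrs[["cdr3"]]) == 0L) return(NULL)
  if (mode == "cdr_triplet" && sum(nchar(qcdrs)) == 0L) return(NULL)
  best <- -1
  keep <- 0L
  ties <- 0L
  for (i in seq_along(chains)) {
    t <- chains[[i]]
    if (t$chain != query$chain) next
    v <- switch(mode,
      full_chain = positional_identity(query, t)$value,
      cdr_triplet = {
        tc <- if (is.null(template_cdrs)) extract_cdrs(t, scheme)
              else template_cdrs[[i]]
        s <- cdr_triplet_identity(qcdrs, tc)
        if (is.null(s)) next else s$value
      },
      cdrh3 = {
        tc <- if (is.null(template_cdrs)) extract_cdrs(t, scheme)
              else template_cdrs[[i]]
        s <- cdrh3_identity(qcdrs[["cdr3"]], tc[["cdr3"]])
        if (is.null(s)) next else s$value
      })
    if (v > best) { best <- v; keep <- i; ties <- 1L }
    else if (v == best) ties <- ties + 1L
  }
  if (keep == 0L) return(NULL)
  t <- chains[[keep]]
  structure(list(
    query_id = query$record_id, mode = mode, best_value = best,
    best_template_id = t$record_id, template_index = keep,
    tie_count = ties,
    study_id = if (is.null(t$meta$study_id)) NA_character_ else t$meta$study_id,
    species = if (is.null(t$meta$species)) NA_character_ else t$meta$species
  ), class = "match_result")
}

#' Pairwise positional identities within a set of chains
#'
#' @param chains list of >= 2 [numbered_chain()] of one chain type.
#' @return symmetric matrix with unit diagonal, dimnames = record ids.
#' @export
pairwise_within_set <- function(chains) {
  n <- length(chains)
  if (n < 2L) stop("pairwise_within_set: need at least 2 chains")
  ct <- unique(vapply(chains, function(x) x$chain, ""))
  if (length(ct) > 1L) stop("pairwise_within_set: mixed chain types")
  ids <- vapply(chains, function(x) x$record_id, "")
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- positional_identity(chains[[i]], chains[[j]])$value
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Unordered pairs above an identity threshold
#'
#' @param mat matrix from [pairwise_within_set()].
#' @param threshold fraction in [0, 1); pairs with identity strictly greater
#'   are reported, each once.
#' @return data.frame(id_a, id_b, identity) sorted by identity descending.
#' @export
pairs_above <- function(mat, threshold) {
  sel <- which(upper.tri(mat) & mat > threshold, arr.ind = TRUE)
  out <- data.frame(
    id_a = rownames(mat)[sel[, 1]],
    id_b = colnames(mat)[sel[, 2]],
    identity = mat[sel]
  )
  out[order(-out$identity, out$id_a), , drop = FALSE]
}
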