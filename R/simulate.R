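# run code with a local RNG state (restores the caller's stream)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# default CDR3 length distribution: a discretised bell over 8..22 residues,
# peaked near 15 for heavy chains (light-chain loops run shorter; callers
# may override)
.default_cdr3_dist <- function(chain) {
  lens <- 8:22
  mu <- if (chain == "heavy") 15 else 10
  w <- exp(-0.5 * ((lens - mu) / 2.5)^2)
  stats::setNames(w / sum(w), lens)
}

#' Configuration for the synthetic repertoire generator
#'
#' Fully parameterizes one generated repertoire: germline sets, size,
#' CDR3 junction length distribution, somatic-hypermutation-like point
#' substitution load, per-residue sequencing-error probability, the
#' fraction of unproductive sequences to inject, and the seed.
#'
#' @param n_records number of sequences.
#' @param chain `"heavy"` or `"light"`.
#' @param cdr3_length_dist named numeric vector, length -> probability
#'   (must sum to 1); default a bell over 8-22.
#' @param shm_rate expected substitutions per sequence (Poisson mean).
#' @param error_rate per-residue substitution probability (sequencing error).
#' @param unproductive_fraction probability a record is made unproductive
#'   (stop codon, broken Cys-104 or broken Trp/Phe-118, equiprobable).
#' @param aa_freq amino-acid sampling weights for CDR3 residues
#'   (default uniform over the 20 canonical residues).
#' @param germline_v,germline_j scaffold sets; defaults ship with the
#'   package (synthetic scaffolds, 5 V and 3 J per chain).
#' @param study_id,species metadata stamped on every record.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records, chain = c("heavy", "light"),
                             cdr3_length_dist = NULL,
                             shm_rate = 4, error_rate = 0.001,
                             unproductive_fraction = 0,
                             aa_freq = NULL,
                             germline_v = NULL, germline_j = NULL,
                             study_id = "SYN1", species = "human",
                             seed = 1L) {
  chain <- match.arg(chain)
  stopifnot(n_records >= 0, shm_rate >= 0,
            error_rate >= 0, error_rate <= 1,
            unproductive_fraction >= 0, unproductive_fraction <= 1)
  if (is.null(cdr3_length_dist)) cdr3_length_dist <- .default_cdr3_dist(chain)
  if (abs(sum(cdr3_length_dist) - 1) > 1e-9)
    stop("synthetic_config: cdr3_length_dist must sum to 1")
  if (is.null(names(cdr3_length_dist)))
    stop("synthetic_config: cdr3_length_dist must be named by length")
  if (is.null(aa_freq)) aa_freq <- stats::setNames(rep(1 / 20, 20), AA20)
  if (is.null(germline_v)) germline_v <- GERMLINE_V[[chain]]
  if (is.null(germline_j)) germline_j <- GERMLINE_J[[chain]]
  structure(list(
    n_records = as.integer(n_records), chain = chain,
    cdr3_length_dist = cdr3_length_dist, shm_rate = shm_rate,
    error_rate = error_rate, unproductive_fraction = unproductive_fraction,
    aa_freq = aa_freq, germline_v = germline_v, germline_j = germline_j,
    study_id = study_id, species = species, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# substitute residues at idx with a uniformly chosen *different* residue
.substitute <- function(residues, idx) {
  for (i in idx) {
    residues[i] <- sample(setdiff(AA20, residues[i]), 1L)
  }
  residues
}

#' Generate a synthetic OAS-like repertoire
#'
#' Each record is a random V scaffold plus a sampled CDR3 junction
#' (length from the configured distribution, residues from the configured
#' amino-acid weights, numbered with the IMGT junction convention) plus a
#' random J tail; a Poisson(`shm_rate`) number of point substitutions and
#' Bernoulli(`error_rate`) per-residue errors are then applied, and a
#' configurable fraction of records is made unproductive.  Fully
#' deterministic given the config seed; a ground-truth log sufficient to
#' replay every record is returned alongside.
#'
#' @param config a [synthetic_config()].
#' @return list with `chains` (list of [numbered_chain()], possibly
#'   containing injected defects) and `truth` (data.frame: record_id, v_id,
#'   j_id, cdr3_length, cdr3_seq, mutations, errors, unproductive).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_records
  meta <- list(study_id = config$study_id, species = config$species,
               chain = config$chain)
  lens <- as.integer(names(config$cdr3_length_dist))
  with_seed(config$seed, {
    v_idx <- if (n) sample.int(length(config$germline_v), n, replace = TRUE) else integer(0)
    j_idx <- if (n) sample.int(length(config$germline_j), n, replace = TRUE) else integer(0)
    len3 <- if (n) sample(lens, n, replace = TRUE,
                          prob = config$cdr3_length_dist) else integer(0)
    nmut <- if (n) stats::rpois(n, config$shm_rate) else integer(0)
    bad <- if (n) stats::runif(n) < config$unproductive_fraction else logical(0)
    bad_mode <- rep(NA_character_, n)
    if (any(bad))
      bad_mode[bad] <- sample(c("stop", "c104", "w118"), sum(bad),
                              replace = TRUE)
    chains <- vector("list", n)
    truth <- vector("list", n)
    aa_names <- names(config$aa_freq)
    for (i in seq_len(n)) {
      v <- config$germline_v[[v_idx[i]]]
      vm <- .germline_v_map(v)
      cdr3 <- sample(aa_names, len3[i], replace = TRUE,
                     prob = config$aa_freq)
      jres <- strsplit(config$germline_j[[j_idx[i]]], "")[[1]]
      positions <- c(vm$positions, imgt_cdr3_positions(len3[i]),
                     as.character(118:128))
      residues <- c(vm$residues, cdr3, jres)
      L <- length(residues)
      # SHM and sequencing error spare the conserved 104/118 anchors: the
      # generator emulates a productive repertoire, and unproductive
      # records enter only through explicit injection below
      mutable <- which(!positions %in% c("104", "118"))
      k <- min(nmut[i], length(mutable))
      mut_idx <- if (k) sort(sample(mutable, k)) else integer(0)
      residues <- .substitute(residues, mut_idx)
      err_idx <- mutable[stats::runif(length(mutable)) < config$error_rate]
      residues <- .substitute(residues, err_idx)
      inj <- ""
      if (!is.na(bad_mode[i])) {
        p <- switch(bad_mode[i],
          stop = sample.int(L, 1L),
          c104 = match("104", positions),
          w118 = match("118", positions))
        residues[p] <- switch(bad_mode[i],
          stop = "*",
          c104 = sample(setdiff(AA20, "C"), 1L),
          w118 = sample(setdiff(AA20, c("W", "F")), 1L))
        inj <- sprintf("%s|%s:%s", bad_mode[i], positions[p], residues[p])
      }
      id <- sprintf("%s_%06d", config$study_id, i)
      chains[[i]] <- numbered_chain(id, config$chain, positions, residues,
                                    meta = meta)
      truth[[i]] <- data.frame(
        record_id = id, v_id = v$id, j_id = names(config$germline_j)[j_idx[i]],
        cdr3_length = len3[i], cdr3_seq = paste(cdr3, collapse = ""),
        mutations = paste(sprintf("%s:%s", positions[mut_idx],
                                  residues[mut_idx]), collapse = ";"),
        errors = paste(sprintf("%s:%s", positions[err_idx],
                               residues[err_idx]), collapse = ";"),
        unproductive = inj,
        stringsAsFactors = FALSE)
    }
    list(chains = chains,
         truth = if (n) do.call(rbind, truth) else
           data.frame(record_id = character(0)))
  })
}

#' Replay one record from the ground-truth log
#'
#' Reconstructs a generated chain from its truth row and the config alone
#' (germline lookup + recorded junction, substitutions and defects); used
#' to prove the log is a complete provenance record.
#'
#' @param truth_row one row of the `truth` data.frame.
#' @param config the [synthetic_config()] that produced it.
#' @return a [numbered_chain()] equal to the generated record.
#' @export
replay_record <- function(truth_row, config) {
  v <- config$germline_v[[match(truth_row$v_id,
                                vapply(config$germline_v, `[[`, "", "id"))]]
  vm <- .germline_v_map(v)
  cdr3 <- strsplit(truth_row$cdr3_seq, "")[[1]]
  jres <- strsplit(config$germline_j[[truth_row$j_id]], "")[[1]]
  positions <- c(vm$positions, imgt_cdr3_positions(truth_row$cdr3_length),
                 as.character(118:128))
  residues <- c(vm$residues, cdr3, jres)
  apply_subs <- function(residues, spec) {
    if (!nzchar(spec)) return(residues)
    for (s in strsplit(spec, ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(s, ":", fixed = TRUE)[[1]]
      residues[match(kv[1], positions)] <- kv[2]
    }
    residues
  }
  residues <- apply_subs(residues, truth_row$mutations)
  residues <- apply_subs(residues, truth_row$errors)
  if (nzchar(truth_row$unproductive))
    residues <- apply_subs(residues,
                           sub("^[a-z0-9]+\\|", "", truth_row$unproductive))
  numbered_chain(truth_row$record_id, config$chain, positions, residues,
                 meta = list(study_id = config$study_id,
                             species = config$species,
                             chain = config$chain))
}

#' Plant queries at known mutational distance from repertoire templates
#'
#' Query `i` is a copy of its template with exactly `k` substitutions at
#' distinct positions (each new residue differs from the original), so the
#' correct best match and its exact identity `(L-k)/L` are known a priori.
#'
#' @param chains repertoire records (list of [numbered_chain()]).
#' @param n_queries number of queries.
#' @param k substitutions per query (scalar or vector of length `n_queries`).
#' @param seed RNG seed.
#' @param template_idx optional explicit template indices.
#' @return list with `queries` (chains named `Q<i>`) and `key`
#'   (data.frame: query_id, template_id, template_index, k, L,
#'   expected_identity).
#' @export
plant_queries <- function(chains, n_queries, k, seed = 1L,
                          template_idx = NULL) {
  stopifnot(length(chains) >= 1L, n_queries >= 1L)
  k <- rep_len(as.integer(k), n_queries)
  with_seed(seed, {
    if (is.null(template_idx))
      template_idx <- sample.int(length(chains), n_queries, replace = TRUE)
    queries <- vector("list", n_queries)
    key <- vector("list", n_queries)
    for (i in seq_len(n_queries)) {
      tmpl <- chains[[template_idx[i]]]
      L <- length(tmpl$positions)
      if (k[i] > L) stop("plant_queries: k exceeds template length")
      residues <- tmpl$residues
      idx <- if (k[i]) sample.int(L, k[i]) else integer(0)
      residues <- .substitute(residues, idx)
      qid <- sprintf("Q%03d", i)
      queries[[i]] <- numbered_chain(qid, tmpl$chain, tmpl$positions,
                                     residues, meta = list(query = TRUE))
      key[[i]] <- data.frame(query_id = qid, template_id = tmpl$record_id,
                             template_index = template_idx[i], k = k[i],
                             L = L, expected_identity = (L - k[i]) / L,
                             stringsAsFactors = FALSE)
    }
    list(queries = queries, key = do.call(rbind, key))
  })
}

#' Make one record unproductive
#'
#' @param chain a [numbered_chain()].
#' @param mode `"stop"` (insert a stop at a CDR3 position), `"c104"`
#'   (corrupt the conserved cysteine) or `"w118"` (corrupt the conserved
#'   tryptophan/phenylalanine).
#' @return the corrupted chain.
#' @export
inject_unproductive <- function(chain, mode = c("stop", "c104", "w118")) {
  mode <- match.arg(mode)
  residues <- chain$residues
  positions <- chain$positions
  i <- switch(mode,
    stop = max(1L, match("105", positions, nomatch = 1L)),
    c104 = match("104", positions),
    w118 = match("118", positions))
  if (is.na(i)) stop("inject_unproductive: required position absent")
  residues[i] <- switch(mode, stop = "*", c104 = "G", w118 = "A")
  numbered_chain(chain$record_id, chain$chain, positions, residues,
                 meta = chain$meta)
}
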