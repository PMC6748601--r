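# compact constructors for hand-built chains in tests

chain_at <- function(positions, residues, id = "x", chain = "heavy",
                     meta = list()) {
  numbered_chain(id, chain, as.character(positions),
                 strsplit(residues, "")[[1]], meta = meta)
}

# a full-length heavy chain from the simulator, deterministic
one_synthetic_chain <- function(seed = 1, chain = "heavy") {
  cfg <- synthetic_config(1, chain, seed = seed, shm_rate = 0,
                          error_rate = 0, unproductive_fraction = 0)
  generate_repertoire(cfg)$chains[[1]]
}

random_repertoire <- function(n, seed, chain = "heavy", ...) {
  generate_repertoire(synthetic_config(n, chain, seed = seed, ...))
}

# independent brute-force identity oracle: walks both position maps as
# plain named vectors, no packed codes
naive_identity <- function(a, b) {
  ra <- stats::setNames(a$residues, a$positions)
  rb <- stats::setNames(b$residues, b$positions)
  shared <- intersect(names(ra), names(rb))
  m <- 0L
  for (p in shared) {
    if (ra[[p]] == rb[[p]] && ra[[p]] != "X") m <- m + 1L
  }
  (m / length(ra) + m / length(rb)) / 2
}
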