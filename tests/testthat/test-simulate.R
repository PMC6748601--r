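test_that("config validates its distribution and rates", {
  expect_error(synthetic_config(10, cdr3_length_dist = c("12" = 0.5)),
               "sum to 1")
  expect_error(synthetic_config(10, error_rate = 1.5))
  expect_error(synthetic_config(-1))
  cfg <- synthetic_config(10, "light")
  expect_equal(sum(cfg$cdr3_length_dist), 1)
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- synthetic_config(50, seed = 123, unproductive_fraction = 0.2)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  r1 <- generate_repertoire(cfg)
  after <- runif(1)
  expect_identical(before, after)    # RNG stream untouched
  r2 <- generate_repertoire(cfg)
  expect_identical(r1, r2)           # bit-identical rerun
  expect_false(identical(
    r1, generate_repertoire(synthetic_config(50, seed = 124,
                                             unproductive_fraction = 0.2))))
})

test_that("zero records and the no-noise limit behave exactly", {
  expect_length(generate_repertoire(synthetic_config(0))$chains, 0)
  cfg <- synthetic_config(30, shm_rate = 0, error_rate = 0,
                          unproductive_fraction = 0, seed = 6)
  out <- generate_repertoire(cfg)
  v_by_id <- stats::setNames(cfg$germline_v,
                             vapply(cfg$germline_v, `[[`, "", "id"))
  for (i in seq_along(out$chains)) {
    ch <- out$chains[[i]]
    tr <- out$truth[i, ]
    v <- v_by_id[[tr$v_id]]
    # framework + CDR1/2 exactly match the source germline scaffold
    germ <- paste0(v$fw1, v$cdr1, v$fw2, v$cdr2, v$fw3)
    expect_identical(substr(chain_sequence(ch), 1, nchar(germ)), germ)
    expect_identical(extract_cdrs(ch)[["cdr3"]], tr$cdr3_seq)
    expect_true(productivity_filter(ch)$keep)
  }
})

test_that("generated records satisfy the chain invariants pre-injection", {
  out <- random_repertoire(100, seed = 17, shm_rate = 8, error_rate = 0.01)
  for (ch in out$chains[1:20]) {
    expect_true(all(diff(imgt_rank(ch$positions)) > 0))
    expect_true(all(ch$residues %in% AA_ALPHABET))
    expect_identical(ch$residues[match("104", ch$positions)], "C")
    expect_identical(ch$residues[match("118", ch$positions)], "W")
  }
})

test_that("the truth log replays every record from scratch", {
  cfg <- synthetic_config(80, seed = 29, shm_rate = 5, error_rate = 0.01,
                          unproductive_fraction = 0.3)
  out <- generate_repertoire(cfg)
  for (i in seq_len(80)) {
    re <- replay_record(out$truth[i, ], cfg)
    expect_identical(re$positions, out$chains[[i]]$positions)
    expect_identical(re$residues, out$chains[[i]]$residues)
  }
})

test_that("CDR3 length histogram tracks the configured distribution", {
  # modest n here; the acceptance suite runs the full n = 50,000 check
  cfg <- synthetic_config(8000, seed = 37)
  out <- generate_repertoire(cfg)
  lens <- out$truth$cdr3_length
  p <- cfg$cdr3_length_dist
  n <- length(lens)
  obs <- table(factor(lens, levels = names(p)))
  for (k in names(p)) {
    se <- sqrt(n * p[[k]] * (1 - p[[k]]))
    expect_lt(abs(obs[[k]] - n * p[[k]]), 3 * se + 1e-9,
              label = paste("length", k, "count deviation"))
  }
})

test_that("planted queries mutate exactly k positions away", {
  rp <- random_repertoire(40, seed = 41)$chains
  pq <- plant_queries(rp, 6, k = c(0L, 1L, 2L, 4L, 8L, 16L), seed = 2)
  for (i in 1:6) {
    q <- pq$queries[[i]]
    tmpl <- rp[[pq$key$template_index[i]]]
    expect_identical(q$positions, tmpl$positions)
    expect_identical(sum(q$residues != tmpl$residues), pq$key$k[i])
    expect_equal(positional_identity(q, tmpl)$value,
                 pq$key$expected_identity[i])
  }
  expect_error(plant_queries(rp, 1, k = 10000L, seed = 1), "exceeds")
})

test_that("injected defects trip the filter with the matching reason", {
  ch <- one_synthetic_chain(seed = 8)
  expect_identical(productivity_filter(inject_unproductive(ch, "stop"))$reason,
                   "stop_codon")
  expect_identical(productivity_filter(inject_unproductive(ch, "c104"))$reason,
                   "conserved_104")
  expect_identical(productivity_filter(inject_unproductive(ch, "w118"))$reason,
                   "conserved_118")
})

test_that("filter pass-rate matches 1 - unproductive_fraction within 3 sigma", {
  frac <- 0.15
  out <- random_repertoire(4000, seed = 53, unproductive_fraction = frac)
  keep <- vapply(out$chains, function(ch) productivity_filter(ch)$keep, TRUE)
  n <- length(keep)
  se <- sqrt(frac * (1 - frac) / n)
  expect_lt(abs(mean(keep) - (1 - frac)), 3 * se)
  # and the injected records are exactly the flagged ones
  expect_identical(!keep, nzchar(out$truth$unproductive))
})
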