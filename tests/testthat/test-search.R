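test_that("index partitions records by chain and buckets by loop lengths", {
  h <- random_repertoire(3, seed = 1, chain = "heavy")$chains
  l <- random_repertoire(2, seed = 2, chain = "light")$chains
  idx <- build_index(c(h, l))
  expect_identical(sum(idx$chain_type == "heavy"), 3L)
  expect_identical(sum(idx$chain_type == "light"), 2L)
  # each record in exactly one length bucket
  expect_identical(sort(unlist(idx$buckets, use.names = FALSE)), 1:5)
  expect_identical(sort(unlist(idx$h3_buckets, use.names = FALSE)), 1:5)

  # exact CDR-H3 hash
  cdr3s <- vapply(c(h, l), function(x) extract_cdrs(x)[["cdr3"]], "")
  hits <- cdrh3_exact_lookup(idx, cdr3s[1], "heavy")
  expect_true(1L %in% hits)
  expect_identical(hits, which(cdr3s == cdr3s[1] & idx$chain_type == "heavy"))
  expect_identical(cdrh3_exact_lookup(idx, "ZZZZ", "heavy"), integer(0))

  # empty index: searches return no-match, never 0%
  empty <- build_index(list())
  expect_null(best_match(h[[1]], empty, "full_chain"))
  expect_null(best_match(h[[1]], empty, "cdrh3"))
})

test_that("duplicate CDR-H3 records share one hash entry", {
  ch <- one_synthetic_chain(seed = 4)
  idx <- build_index(list(ch, ch))
  key <- extract_cdrs(ch)[["cdr3"]]
  expect_identical(cdrh3_exact_lookup(idx, key, "heavy"), c(1L, 2L))
})

test_that("identical query returns value 1 at the earliest tie", {
  rp <- random_repertoire(50, seed = 31)$chains
  dup <- rp[[20]]
  rp2 <- c(rp, list(dup))  # records 20 and 51 identical
  idx <- build_index(rp2)
  q <- numbered_chain("q", dup$chain, dup$positions, dup$residues)
  r <- best_match(q, idx, "full_chain")
  expect_equal(r$best_value, 1)
  expect_identical(r$template_index, 20L)
  expect_gte(r$tie_count, 2L)
})

test_that("indexed search equals the exhaustive oracle in all modes", {
  rp <- random_repertoire(400, seed = 55, shm_rate = 6)$chains
  idx <- build_index(rp)
  pq <- plant_queries(rp, 25, k = rep(c(0L, 3L, 10L, 25L, 60L), 5), seed = 8)
  tcdrs <- lapply(rp, extract_cdrs)
  for (i in seq_along(pq$queries)) {
    q <- pq$queries[[i]]
    for (mode in c("full_chain", "cdr_triplet", "cdrh3")) {
      a <- best_match(q, idx, mode)
      b <- exhaustive_best_match(q, rp, mode, template_cdrs = tcdrs)
      expect_identical(is.null(a), is.null(b))
      if (is.null(a)) next
      expect_equal(a$best_value, b$best_value)
      expect_identical(a$best_template_id, b$best_template_id)
      expect_identical(a$tie_count, b$tie_count)
    }
  }
})

test_that("planted templates are recovered at exactly (L-k)/L", {
  rp <- random_repertoire(300, seed = 77, shm_rate = 25)$chains
  pq <- plant_queries(rp, 10, k = 4, seed = 5)
  idx <- build_index(rp)
  for (i in 1:10) {
    r <- best_match(pq$queries[[i]], idx, "full_chain")
    expect_equal(r$best_value, pq$key$expected_identity[i])
    # with heavy mutational scatter the planted template is the unique best
    expect_identical(r$best_template_id, pq$key$template_id[i])
  }
})

test_that("length bucketing excludes only length-ineligible templates", {
  rp <- random_repertoire(200, seed = 12)$chains
  idx <- build_index(rp)
  q <- plant_queries(rp, 1, 2, seed = 3)$queries[[1]]
  qcdrs <- extract_cdrs(q)
  key <- paste(q$chain, nchar(qcdrs[["cdr1"]]), nchar(qcdrs[["cdr2"]]),
               nchar(qcdrs[["cdr3"]]), sep = ":")
  in_bucket <- sort(idx$buckets[[key]])
  eligible <- which(vapply(rp, function(t)
    !is.null(cdr_triplet_identity(qcdrs, extract_cdrs(t))), TRUE))
  expect_identical(in_bucket, eligible)

  # cdrh3 mode with a loop length absent from the repertoire: no-match
  longq <- chain_at(imgt_cdr3_positions(30), strrep("A", 30))
  expect_null(best_match(longq, idx, "cdrh3"))
  expect_null(exhaustive_best_match(longq, rp, "cdrh3"))
})

test_that("exact-hash perfect-match lookup equals a linear scan", {
  rp <- random_repertoire(500, seed = 91, shm_rate = 2)$chains
  idx <- build_index(rp)
  cdr3s <- vapply(rp, function(x) extract_cdrs(x)[["cdr3"]], "")
  for (s in sample(unique(cdr3s), 20)) {
    expect_identical(cdrh3_exact_lookup(idx, s, "heavy"),
                     which(cdr3s == s))
  }
})

test_that("search results are deterministic given insertion order", {
  rp <- random_repertoire(150, seed = 13)$chains
  q <- plant_queries(rp, 1, 5, seed = 2)$queries[[1]]
  r1 <- best_match(q, build_index(rp), "full_chain")
  r2 <- best_match(q, build_index(rp), "full_chain")
  expect_identical(r1, r2)
})

test_that("pairwise identity matrix is symmetric with unit diagonal", {
  rp <- random_repertoire(20, seed = 44)$chains
  m <- pairwise_within_set(rp)
  expect_identical(dim(m), c(20L, 20L))
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 20))
  # equals nested positional_identity calls
  for (k in 1:15) {
    i <- sample(20, 1); j <- sample(20, 1)
    expect_equal(m[i, j], positional_identity(rp[[i]], rp[[j]])$value)
  }
  # two identical chains: one pair above any threshold < 1
  dup <- list(rp[[1]], numbered_chain("copy", rp[[1]]$chain,
                                      rp[[1]]$positions, rp[[1]]$residues))
  p <- pairs_above(pairwise_within_set(dup), 0.94)
  expect_identical(nrow(p), 1L)
  expect_equal(p$identity, 1)
  expect_error(pairwise_within_set(rp[1]), "at least 2")
})
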