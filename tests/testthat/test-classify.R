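test_that("INN suffix rules classify by priority with a mouse override", {
  expect_identical(classify_inn("otelixizumab"), "chimeric")
  expect_identical(classify_inn("rituximab"), "chimeric")
  expect_identical(classify_inn("trastuzumab"), "humanized")
  expect_identical(classify_inn("adalimumab"), "fully_human")
  expect_identical(classify_inn("muromonab"), "mouse")
  expect_identical(classify_inn("Racotumomab"), "mouse")   # case-insensitive
  expect_identical(classify_inn("ADALIMUMAB"), "fully_human")
  expect_warning(ty <- classify_inn("aspirin"), "no INN rule")
  expect_identical(ty, "unknown")
  expect_error(classify_inn(""))
})

test_that("the 242 CST names stratify as 100/105/34/3", {
  tab <- read_cst_table()
  ty <- classify_inn(tab$name)
  counts <- table(ty)
  expect_identical(unname(counts["fully_human"]), 100L)
  expect_identical(unname(counts["humanized"]), 105L)
  expect_identical(unname(counts["chimeric"]), 34L)
  expect_identical(unname(counts["mouse"]), 3L)
})

test_that("summary rows sort by heavy identity then name, like the source table", {
  tab <- read_cst_table()
  rep <- summary_report(tab)
  expect_identical(nrow(rep$rows), 242L)
  expect_true(all(diff(rep$rows$heavy) <= 0))
  expect_identical(rep$rows$name[1], "Enfortumab")
  expect_identical(rep$rows$name[242], "Ontuxizumab")
  # permutation invariance up to output ordering
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(summary_report(shuffled)$rows, rep$rows)
  expect_error(summary_report(rbind(tab, tab[1, ])), "duplicate")
})

test_that("threshold counts behave on raw and integer inputs", {
  tab <- read_cst_table()
  rep <- summary_report(tab)
  expect_identical(threshold_count(rep, "heavy", 95)$count, 18L)
  expect_identical(threshold_count(rep, c("heavy", "light"), 95)$count, 16L)
  # monotone in the threshold
  cts <- vapply(80:100, function(t) threshold_count(rep, "light", t)$count, 0L)
  expect_true(all(diff(cts) <= 0))

  # raw fractions: 0.95 exactly must pass >= 95 despite float representation
  df <- data.frame(name = c("aumab", "bumab"),
                   heavy = c(95L, 94L), heavy_raw = c(114 / 120, 113 / 120))
  r2 <- summary_report(df)
  expect_identical(threshold_count(r2, "heavy", 95)$count, 1L)
  expect_identical(threshold_count(r2, "heavy", 100)$count, 0L)

  # no-match (NA) fails every predicate
  df$heavy[2] <- NA; df$heavy_raw[2] <- NA
  r3 <- summary_report(df)
  expect_identical(threshold_count(r3, "heavy", 90)$count, 1L)
  # single row at 100: percentage 100.0
  one <- summary_report(data.frame(name = "xumab", heavy = 100L, light = 100L,
                                   heavy_cdrs = 100L, light_cdrs = 100L,
                                   cdrh3 = 100L))
  tc <- threshold_count(one, "heavy", 90)
  expect_identical(tc$count, 1L)
  expect_identical(tc$percentage, 100.0)
})

test_that("per-type strata partition the rows and flag small samples", {
  tab <- read_cst_table()
  rep <- summary_report(tab)
  st <- rep$strata
  heavy <- st[st$column == "heavy", ]
  expect_identical(sum(heavy$n), 242L)
  expect_true(heavy$small_sample[heavy$type == "mouse"])
  expect_false(heavy$small_sample[heavy$type == "fully_human"])
  # humanization costs identity: humanized median < fully-human median
  expect_lt(heavy$median[heavy$type == "humanized"],
            heavy$median[heavy$type == "fully_human"])

  single <- summary_report(tab[1:5, ], types = rep("fully_human", 5))
  s1 <- single$strata
  expect_identical(unique(s1$type), "fully_human")
  expect_identical(unique(s1$n), 5L)
})

test_that("source attribution counts species per type and mode", {
  mk <- function(qid, mode, species, study) {
    structure(list(query_id = qid, mode = mode, best_value = 1,
                   best_template_id = "t", template_index = 1L,
                   tie_count = 1L, study_id = study, species = species),
              class = "match_result")
  }
  types <- c(q1 = "fully_human", q2 = "fully_human", q3 = "humanized")
  res <- list(mk("q1", "full_chain", "human", "S1"),
              mk("q2", "full_chain", "mouse", "S2"),
              mk("q3", "full_chain", "human", "S1"),
              mk("q1", "cdrh3", "human", "S1"))
  at <- source_attribution(res, types)
  expect_setequal(at$studies_hit, c("S1", "S2"))
  fh <- at$counts[at$counts$type == "fully_human" &
                  at$counts$mode == "full_chain", ]
  expect_identical(sum(fh$count), 2L)
  expect_equal(sum(fh$fraction), 1)
  expect_equal(fh$count[fh$species == "human"], 1L)
  # fractions sum to 1 within every (type, mode)
  agg <- stats::aggregate(fraction ~ type + mode, at$counts, sum)
  expect_true(all(abs(agg$fraction - 1) < 1e-12))
})

test_that("reports assemble from raw match results", {
  rp <- random_repertoire(120, seed = 66)$chains
  idx <- build_index(rp)
  pq <- plant_queries(rp, 4, k = c(0L, 2L, 6L, 12L), seed = 3)
  # rename queries as antibodies with INN-style names
  nm <- c("testumab", "testozumab", "testiximab", "muromonab")
  results <- list()
  for (i in 1:4) {
    q <- pq$queries[[i]]
    q2 <- numbered_chain(paste0(nm[i], "_H"), q$chain, q$positions, q$residues)
    for (mode in c("full_chain", "cdr_triplet", "cdrh3"))
      results[[length(results) + 1L]] <- best_match(q2, idx, mode)
  }
  rep <- report_from_matches(results)
  expect_identical(nrow(rep$rows), 4L)
  expect_identical(sort(rep$rows$name), sort(nm))
  k0 <- rep$rows[rep$rows$name == "testumab", ]
  expect_identical(k0$heavy, 100L)
  expect_identical(k0$type, "fully_human")
  expect_true(all(is.na(rep$rows$light)))
  # duplicate (query, mode) is a usage error
  expect_error(report_from_matches(c(results, results[1])), "duplicate")
})
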