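test_that("relative position maps leader to 0 and tail to 1", {
  expect_equal(relative_position(1L, 10L), 0)
  expect_equal(relative_position(10L, 10L), 1)
  expect_equal(relative_position(4L, 10L), 1 / 3)
  expect_equal(relative_position(1L, 1L), 0)
  expect_error(relative_position(0L, 10L), "out of range")
  expect_error(relative_position(11L, 10L), "out of range")
})

test_that("filter 2 counts distinct regions and keeps the maximum", {
  h <- rbind(mk_hits("A", 10, 42), mk_hits("A", 100, 132),
             mk_hits("B", 10, 42))
  f2 <- filter2_region_count(h)
  expect_equal(f2$genera, "A")
  expect_equal(f2$tally$n_regions[f2$tally$genus_taxon == "A"], 2L)

  # duplicate intervals count once; equal counts tie
  h2 <- rbind(mk_hits("A", 10, 42), mk_hits("A", 10, 42),
              mk_hits("B", 50, 82))
  f22 <- filter2_region_count(h2)
  expect_setequal(f22$genera, c("A", "B"))

  # same interval on both strands counts once
  h3 <- rbind(mk_hits("A", 10, 42), mk_hits("B", 50, 82))
  h3$strand <- c("+", "-")
  h3b <- rbind(h3, mk_hits("A", 10, 42))
  h3b$strand[3] <- "-"
  expect_setequal(filter2_region_count(h3b)$genera, c("A", "B"))
})

test_that("filter 3 keeps genera closest to the leader, with exact ties", {
  h <- rbind(mk_hits("A", 10, 42, pos = 1L, loclen = 10L),
             mk_hits("B", 50, 82, pos = 5L, loclen = 10L))
  expect_equal(filter3_five_prime(h)$genera, "A")

  # both at the leader: both survive
  h2 <- rbind(mk_hits("A", 10, 42, pos = 1L, loclen = 10L),
              mk_hits("B", 50, 82, pos = 1L, loclen = 4L))
  expect_setequal(filter3_five_prime(h2)$genera, c("A", "B"))

  # 3/9 vs 2/6 are the same rational; doubles must not split the tie
  h3 <- rbind(mk_hits("A", 10, 42, pos = 4L, loclen = 10L),
              mk_hits("B", 50, 82, pos = 3L, loclen = 7L))
  expect_setequal(filter3_five_prime(h3)$genera, c("A", "B"))
  expect_equal(filter3_five_prime(h3)$best$best_rel_pos, c(1/3, 1/3))

  # minimum over all of a genus's hits decides
  h4 <- rbind(mk_hits("A", 10, 42, pos = 9L, loclen = 10L),
              mk_hits("A", 60, 92, pos = 1L, loclen = 10L),
              mk_hits("B", 50, 82, pos = 2L, loclen = 10L))
  expect_equal(filter3_five_prime(h4)$genera, "A")
})

test_that("the cascade stops at the first single-genus stage", {
  tx <- tiny_taxonomy()
  # all minimum-mismatch hits from one genus: filter 1 decides
  h1 <- rbind(mk_hits("G1", 10, 42, tm = 0L), mk_hits("G2", 50, 82, tm = 2L))
  p1 <- predict_host(h1, tx, cutoff = 2)
  expect_equal(p1$predicted_taxon, "G1")
  expect_equal(p1$deciding_filter, 1L)
  expect_equal(p1$predicted_rank, "genus")
  expect_equal(p1$candidate_genera_per_stage, list("1" = "G1"))

  # tie at filter 1, filter 2 decides
  h2 <- rbind(mk_hits("G1", 10, 42), mk_hits("G1", 100, 132),
              mk_hits("G2", 10, 42))
  p2 <- predict_host(h2, tx, cutoff = 2)
  expect_equal(p2$predicted_taxon, "G1")
  expect_equal(p2$deciding_filter, 2L)

  # ties through 2 and 3; same family: LCA fallback at family rank
  h4 <- rbind(mk_hits("G1", 10, 42, pos = 1L), mk_hits("G2", 10, 42, pos = 1L))
  p4 <- predict_host(h4, tx, cutoff = 2)
  expect_equal(p4$deciding_filter, 4L)
  expect_equal(p4$predicted_taxon, "F1")
  expect_equal(p4$predicted_rank, "family")
  expect_false(p4$low_confidence)

  # genera from different superkingdom-level branches: root LCA is flagged
  h5 <- rbind(mk_hits("G1", 10, 42, pos = 1L), mk_hits("G5", 10, 42, pos = 1L))
  p5 <- predict_host(h5, tx, cutoff = 2)
  expect_equal(p5$deciding_filter, 4L)
  expect_equal(p5$predicted_taxon, "B")
  expect_equal(p5$predicted_rank, "superkingdom")

  # no hits within cutoff: no prediction
  h0 <- mk_hits("G1", 10, 42, tm = 5L)
  p0 <- predict_host(h0, tx, cutoff = 2)
  expect_equal(p0$deciding_filter, "none")
  expect_true(is.na(p0$predicted_taxon))
})

test_that("candidate genus sets shrink monotonically to the decision", {
  run <- scenario_run("redundancy")
  for (p in run$preds) {
    sizes <- lengths(p$candidate_genera_per_stage)
    expect_true(all(diff(sizes) <= 0))
    last <- p$candidate_genera_per_stage[[length(sizes)]]
    if (p$deciding_filter %in% 1:3) {
      expect_length(last, 1L)
      expect_equal(last, p$predicted_taxon)
    } else if (identical(p$deciding_filter, 4L)) {
      expect_gte(length(last), 2L)
    }
  }
})

test_that("unresolved-genus hits are excluded before the cascade", {
  tx <- tiny_taxonomy()
  h <- rbind(mk_hits("G2", 10, 42), mk_hits(NA_character_, 5, 37))
  p <- predict_host(h, tx, cutoff = 2)
  expect_equal(p$predicted_taxon, "G2")
  expect_equal(p$n_unresolved_excluded, 1L)
})

test_that("filter order permutation changes which filter decides", {
  tx <- tiny_taxonomy()
  # region count favors A; 5' position favors B
  h <- rbind(mk_hits("G1", 10, 42, pos = 5L), mk_hits("G1", 100, 132, pos = 6L),
             mk_hits("G2", 10, 42, pos = 1L))
  p23 <- predict_host(h, tx, filter_order = c(2, 3))
  p32 <- predict_host(h, tx, filter_order = c(3, 2))
  expect_equal(p23$predicted_taxon, "G1")
  expect_equal(p23$deciding_filter, 2L)
  expect_equal(p32$predicted_taxon, "G2")
  expect_equal(p32$deciding_filter, 3L)
  expect_error(predict_host(h, tx, filter_order = c(2, 4)), "permutation")
})

test_that("batch prediction preserves order and composes per-genome results", {
  fx <- scenario_fixture("clean")
  sub <- fx$phages[1:3]
  preds <- predict_batch(sub, fx$store, cutoff = 2)
  expect_length(preds, 3L)
  expect_equal(vapply(preds, `[[`, "", "phage_id"), names(sub))

  hits <- attr(preds, "hits")
  for (i in seq_along(sub)) {
    solo <- predict_host(hits[hits$phage_id == names(sub)[i], ],
                         fx$taxonomy, phage_id = names(sub)[i], cutoff = 2)
    expect_equal(predictions_to_df(list(solo)),
                 predictions_to_df(preds[i]))
  }

  # a genome with no hits still yields a row
  none <- Biostrings::DNAStringSet(c(empty1 = random_dna(5000)))
  pn <- predict_batch(none, fx$store, cutoff = 2)
  expect_equal(predictions_to_df(pn)$deciding_filter, "none")

  dup <- fx$phages[c(1, 1)]
  expect_error(predict_batch(dup, fx$store), "duplicate")

  expect_warning(predict_batch(Biostrings::DNAStringSet(), fx$store),
                 "empty")
})

test_that("predictions are deterministic and thread-count independent", {
  fx <- scenario_fixture("clean")
  sub <- fx$phages[1:4]
  p1 <- predictions_to_df(predict_batch(sub, fx$store, cutoff = 2))
  p1b <- predictions_to_df(predict_batch(sub, fx$store, cutoff = 2))
  p2 <- predictions_to_df(predict_batch(sub, fx$store, cutoff = 2,
                                        threads = 2L))
  expect_identical(p1, p1b)
  expect_identical(p1, p2)
})

test_that("the narrative report explains each decision", {
  run <- scenario_run("redundancy")
  path <- tempfile(fileext = ".txt")
  write_prediction_report(run$preds, path, run$fx$taxonomy)
  txt <- readLines(path)
  expect_true(any(grepl("== Phage phage_001 ==", txt)))
  expect_true(any(grepl("After filter 1", txt)))
  expect_true(any(grepl("After filter 2", txt)))
  expect_true(any(grepl("deciding filter 2", txt)))
  expect_true(any(grepl("Supporting spacers", txt)))
})
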