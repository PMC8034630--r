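# build a host_prediction_set from constructed hit tables, bypassing the
# scanner: phage sequences are placeholders since hits are precomputed
preds_from_hits <- function(hits, tx, phage_ids, cutoff = 2,
                            filter_order = c(2L, 3L)) {
  phages <- stats::setNames(rep("ACGT", length(phage_ids)), phage_ids)
  store <- list(taxonomy = tx)
  predict_batch(phages, store, cutoff = cutoff, hits = hits,
                filter_order = filter_order)
}

test_that("recall and precision follow their definitions", {
  tx <- tiny_taxonomy()
  # 10 phages; 5 with a correct genus-level prediction, 5 with no hits
  hits <- do.call(rbind, lapply(1:5, function(i)
    mk_hits("G1", 10 * i, 10 * i + 29, phage = paste0("P", i))))
  truth <- stats::setNames(rep("G1", 10), paste0("P", 1:10))
  preds <- preds_from_hits(hits, tx, paste0("P", 1:10))
  ev <- evaluate_predictions(preds, truth, tx)
  expect_equal(ev$recall, 0.5)
  expect_equal(unname(ev$precision["genus"]), 1.0)
  expect_equal(ev$n_predicted, 5L)

  expect_error(evaluate_predictions(preds, truth[1:3], tx), "missing")
})

test_that("a family-level LCA prediction is right at family, wrong at genus", {
  tx <- tiny_taxonomy()
  # G1/G2 tie all the way: prediction is F1, truth G1
  hits <- rbind(mk_hits("G1", 10, 42, pos = 1L),
                mk_hits("G2", 10, 42, pos = 1L))
  preds <- preds_from_hits(hits, tx, "P1")
  ev <- evaluate_predictions(preds, c(P1 = "G1"), tx)
  expect_equal(unname(ev$precision["genus"]), 0)
  expect_equal(unname(ev$precision["family"]), 1)
  expect_equal(unname(ev$precision["order"]), 1)
  expect_equal(ev$per_phage$agreement_rank, "family")
})

test_that("precision is computed per deciding filter and per true genus", {
  run <- scenario_run("redundancy")
  pf <- run$bench$per_filter_precision
  expect_equal(pf$deciding_filter, "2")
  expect_equal(pf$precision_genus, 1)
  pg <- run$bench$per_genus
  expect_true(all(pg$recall == 1))
  expect_true(all(pg$precision_genus == 1))
})

test_that("evaluation is invariant to phage input order", {
  run <- scenario_run("clean")
  preds_rev <- rev(unclass(run$preds))
  ev_rev <- evaluate_predictions(preds_rev, run$fx$truth, run$fx$taxonomy)
  expect_equal(ev_rev$recall, run$bench$recall)
  expect_equal(ev_rev$precision, run$bench$precision)
})

test_that("null model success matches the binomial expectation", {
  tx <- tiny_taxonomy()
  # P1: every hit from the true genus -> success rate contribution 1;
  # P2: 1 true hit among 10 -> expected 0.1
  hits <- rbind(
    mk_hits(rep("G1", 3), 10, 39, phage = "P1"),
    mk_hits(c("G2", rep("G3", 9)), 10, 39, phage = "P2"))
  truth <- c(P1 = "G1", P2 = "G2")
  nm <- null_model(hits, truth, stage = "after-raw", n_sims = 1000,
                   seed = 11)
  expect_equal(nm$n_phages_used, 2L)
  # per-sim rate is (1 + Bernoulli(0.1)) / 2
  expect_true(all(nm$success_rates %in% c(0.5, 1)))
  expect_equal(mean(nm$success_rates == 1), 0.1,
               tolerance = 3 * sqrt(0.1 * 0.9 / 1000) / 0.1)

  # bit-reproducible under a fixed seed
  nm2 <- null_model(hits, truth, stage = "after-raw", n_sims = 1000,
                    seed = 11)
  expect_identical(nm$success_rates, nm2$success_rates)

  # phage with no hits at the stage is excluded and reported
  hits_p1 <- hits[hits$phage_id == "P1", ]
  nm3 <- null_model(hits_p1, truth, stage = "after-raw", n_sims = 10,
                    seed = 1)
  expect_equal(nm3$excluded_phages, "P2")
})

test_that("null model stages condition on the surviving hit sets", {
  tx <- tiny_taxonomy()
  # decoy G3 dominates raw hits but is pruned by filter 1 (2 mismatches)
  hits <- rbind(
    mk_hits(rep("G1", 2), 10, 39, tm = 0L, phage = "P1"),
    mk_hits(rep("G3", 18), 50, 79, tm = 2L, phage = "P1"))
  truth <- c(P1 = "G1")
  raw <- null_model(hits, truth, stage = "after-raw", n_sims = 400,
                    seed = 3)
  f1 <- null_model(hits, truth, stage = "after-filter1", n_sims = 400,
                   seed = 3)
  expect_lt(mean(raw$success_rates), 0.25)
  expect_equal(mean(f1$success_rates), 1)

  # after filter 2 the pool is restricted to the region-count winners
  hits2 <- rbind(
    mk_hits("G1", 10, 39, phage = "P2"), mk_hits("G1", 50, 79, phage = "P2"),
    mk_hits("G2", 90, 119, phage = "P2"))
  f2 <- null_model(hits2, c(P2 = "G1"), stage = "after-filter2",
                   n_sims = 50, seed = 5)
  expect_equal(mean(f2$success_rates), 1)
})

test_that("the smoothed empirical p-value never reaches zero", {
  nm <- list(success_rates = rep(0.2, 999), n_sims = 999L)
  expect_equal(null_model_pvalue(nm, 0.9), 1 / 1000)
  expect_equal(null_model_pvalue(nm, 0.1), 1)
})

test_that("recall grows along the mismatch grid when protospacers mutate", {
  # small dedicated fixture: 1-mutation protospacers
  fx <- scenario_fixture("clean", seed = 17, mutations = 1L,
                         n_orders = 3L, n_phages = 6L,
                         phage_len_range = c(8000L, 12000L))
  tab <- sweep_cutoffs(fx$phages, fx$store, fx$truth, cutoffs = 0:2)
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$recall) >= 0))
  # with exactly one mutation per planted spacer, cutoff 0 finds nothing
  expect_equal(tab$recall[tab$cutoff == 0], 0)
  expect_lt(tab$recall[tab$cutoff == 0], tab$recall[tab$cutoff == 2])
  # nested precision: family is never below genus
  ok <- !is.na(tab$precision_genus)
  expect_true(all(tab$precision_family[ok] >= tab$precision_genus[ok]))

  # a single-cutoff grid yields a single row
  one <- sweep_cutoffs(fx$phages, fx$store, fx$truth, cutoffs = 2)
  expect_equal(nrow(one), 1L)
})

test_that("filter-order search ranks orders by constructed informativeness", {
  tx <- tiny_taxonomy()
  # region count is informative (true genus targets 2 regions), the
  # 5'-position signal is misleading (decoy at the leader)
  hits <- do.call(rbind, lapply(1:4, function(i) {
    h <- rbind(
      mk_hits("G1", 10, 39, pos = 5L, phage = paste0("P", i)),
      mk_hits("G1", 50, 79, pos = 6L, phage = paste0("P", i)),
      mk_hits("G2", 10, 39, pos = 1L, phage = paste0("P", i)))
    h
  }))
  truth <- stats::setNames(rep("G1", 4), paste0("P", 1:4))
  phages <- stats::setNames(rep("ACGT", 4), paste0("P", 1:4))
  store <- list(taxonomy = tx)
  tab <- filter_order_search(phages, store, truth, hits = hits)
  expect_equal(nrow(tab), 2L)
  p23 <- tab$precision_genus[tab$order == "1>2>3>4"]
  p32 <- tab$precision_genus[tab$order == "1>3>2>4"]
  expect_equal(p23, 1)
  expect_equal(p32, 0)
  # deterministic: a second run gives the identical table
  expect_identical(tab, filter_order_search(phages, store, truth,
                                            hits = hits))
})

test_that("diagnostics KS statistics match a brute-force ECDF computation", {
  tx <- tiny_taxonomy()
  # 6 filter-2-decided phages: 3 accurate (high region counts), 3 wrong
  # (a decoy genus out-targets the true host)
  mk_case <- function(pid, winner, n_regions, loser) {
    rows <- lapply(seq_len(n_regions), function(r)
      mk_hits(winner, 100 * r, 100 * r + 29, phage = pid))
    rows[[length(rows) + 1L]] <- mk_hits(loser, 5, 34, phage = pid)
    do.call(rbind, rows)
  }
  hits <- rbind(
    mk_case("P1", "G1", 5L, "G2"), mk_case("P2", "G1", 4L, "G2"),
    mk_case("P3", "G1", 6L, "G2"),
    mk_case("P4", "G2", 2L, "G1"), mk_case("P5", "G2", 2L, "G1"),
    mk_case("P6", "G2", 3L, "G1"))
  truth <- stats::setNames(rep("G1", 6), paste0("P", 1:6))
  preds <- preds_from_hits(hits, tx, paste0("P", 1:6))
  ev <- evaluate_predictions(preds, truth, tx)
  dg <- diagnostics(ev, preds)

  expect_equal(sort(dg$filter2$n_regions[dg$filter2$correct]), c(4, 5, 6))
  expect_equal(sort(dg$filter2$n_regions[!dg$filter2$correct]), c(2, 2, 3))

  # brute-force two-sample KS: max |ECDF_a - ECDF_b| over the pooled grid
  a <- dg$filter2$n_regions[dg$filter2$correct]
  b <- dg$filter2$n_regions[!dg$filter2$correct]
  grid <- sort(unique(c(a, b)))
  ks_brute <- max(abs(vapply(grid, function(x)
    mean(a <= x) - mean(b <= x), numeric(1))))
  got <- dg$ks$statistic[dg$ks$filter == "2"]
  expect_equal(got, ks_brute)
  expect_equal(got, 1)  # disjoint supports

  # groups with < 2 observations yield NA with a note
  expect_true(is.na(dg$ks$statistic[dg$ks$filter == "3"]))
  expect_match(dg$ks$note[dg$ks$filter == "3"], "< 2")
})
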