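#' Evaluate predictions against known hosts
#'
#' For every phage with a prediction, computes the rank of the lowest
#' common ancestor between the true host genus and the predicted taxon;
#' "accurate at rank r" means that LCA rank is r or deeper (a prediction
#' equal to the true genus's family is accurate at family and order but
#' not at genus). Recall is the fraction of phages receiving any
#' prediction; precision at rank r is computed over predicted phages
#' only.
#'
#' @param predictions a `host_prediction_set` (or list of
#'   `host_prediction`)
#' @param truth named character vector (or two-column data.frame
#'   `phage_id`, `taxon_id`) mapping each phage to its true host genus
#'   taxon
#' @param taxonomy a `spacer_taxonomy`
#' @param ranks ranks at which to report precision
#' @return object of class `benchmark_result`: `per_phage` data.frame,
#'   `recall`, `precision` (named by rank), `per_filter_precision`
#'   (genus-level precision by deciding filter), `per_genus` (per-true-
#'   genus recall and genus-level precision), `n_phages`, `n_predicted`
#' @export
evaluate_predictions <- function(predictions, truth, taxonomy,
                                 ranks = c("genus", "family", "order")) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth[[2L]]),
                             as.character(truth[[1L]]))
  }
  df <- predictions_to_df(predictions)
  missing <- setdiff(df$phage_id, names(truth))
  if (length(missing) > 0L) {
    stop("phage(s) missing from truth map: ",
         paste(missing, collapse = ", "))
  }
  df$true_taxon <- unname(truth[df$phage_id])
  df$true_name <- unname(taxonomy$name[df$true_taxon])
  predicted <- df$deciding_filter != "none"

  df$agreement_rank <- NA_character_
  df$agreement_flagged <- NA
  for (i in which(predicted)) {
    r <- lca_rank(taxonomy, df$true_taxon[i], df$predicted_taxon[i])
    df$agreement_rank[i] <- as.character(r)
    df$agreement_flagged[i] <- isTRUE(attr(r, "from_unranked"))
  }
  df$agreement_depth <- rank_depth(df$agreement_rank, taxonomy$ranks)
  df$agreement_depth[!predicted] <- NA_integer_

  precision <- vapply(ranks, function(r) {
    if (!any(predicted)) return(NA_real_)
    mean(df$agreement_depth[predicted] >= rank_depth(r, taxonomy$ranks))
  }, numeric(1))

  gdepth <- rank_depth("genus", taxonomy$ranks)
  df$correct_genus <- predicted & !is.na(df$agreement_depth) &
    df$agreement_depth >= gdepth

  pf <- split(df$correct_genus[predicted], df$deciding_filter[predicted])
  per_filter <- data.frame(
    deciding_filter = names(pf),
    n = vapply(pf, length, integer(1)),
    precision_genus = vapply(pf, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_filter) <- NULL

  pg <- split(seq_len(nrow(df)), df$true_taxon)
  per_genus <- data.frame(
    true_taxon = names(pg),
    true_name = unname(taxonomy$name[names(pg)]),
    n_phages = vapply(pg, length, integer(1)),
    recall = vapply(pg, function(ii) mean(predicted[ii]), numeric(1)),
    precision_genus = vapply(pg, function(ii) {
      jj <- ii[predicted[ii]]
      if (length(jj) == 0L) NA_real_ else mean(df$correct_genus[jj])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_genus) <- NULL

  structure(list(
    per_phage = df,
    recall = mean(predicted),
    precision = precision,
    per_filter_precision = per_filter,
    per_genus = per_genus,
    n_phages = nrow(df),
    n_predicted = sum(predicted)
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", x$n_predicted, "/", x$n_phages,
      " phages predicted (recall ", sprintf("%.1f%%", 100 * x$recall),
      ")\n  precision: ",
      paste(sprintf("%s %.1f%%", names(x$precision), 100 * x$precision),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Random-host null model
#'
#' For each phage, a single hit is drawn uniformly at random from its hit
#' set at the requested cascade stage and the corresponding genus is taken
#' as the random prediction; a draw succeeds when that genus is the true
#' host genus. The per-simulation success rate (fraction of phages whose
#' random host is correct) is recorded over `n_sims` simulations. Phages
#' with no hits at the stage are excluded from the denominator and
#' counted in the result.
#'
#' @param hits hit table covering all phages (as from [scan_store()])
#' @param truth named vector or two-column data.frame mapping phage to
#'   true genus taxon
#' @param stage `"after-raw"` (all hits), `"after-filter1"`, or
#'   `"after-filter2"`
#' @param n_sims number of simulations (default 1000)
#' @param seed RNG seed (required; the null model is reproducible)
#' @param cutoff,criterion filter-1 settings for the filtered stages
#' @param filter_order order of filters 2-3 when `stage = "after-filter2"`
#'   applies the first of them
#' @return object of class `null_model_result`: `success_rates` (length
#'   `n_sims`), `n_sims`, `n_phages_used`, `excluded_phages`, `stage`
#' @export
null_model <- function(hits, truth, stage = c("after-raw", "after-filter1",
                                              "after-filter2"),
                       n_sims = 1000L, seed = 1L, cutoff = 2,
                       criterion = "mismatch", filter_order = c(2L, 3L)) {
  stage <- match.arg(stage)
  stopifnot(n_sims >= 1L)
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth[[2L]]),
                             as.character(truth[[1L]]))
  }
  hits <- hits[!is.na(hits$genus_taxon), , drop = FALSE]
  by_phage <- split(hits, hits$phage_id)
  genus_pools <- list()
  for (pid in names(by_phage)) {
    h <- by_phage[[pid]]
    if (stage %in% c("after-filter1", "after-filter2")) {
      h <- filter_hits(h, criterion = criterion, cutoff = cutoff)
    }
    if (stage == "after-filter2" && nrow(h) > 0L) {
      first <- as.integer(filter_order)[1L]
      surv <- if (first == 2L) filter2_region_count(h)$genera
              else filter3_five_prime(h)$genera
      h <- h[h$genus_taxon %in% surv, , drop = FALSE]
    }
    if (nrow(h) > 0L) genus_pools[[pid]] <- h$genus_taxon
  }
  used <- intersect(names(genus_pools), names(truth))
  excluded <- setdiff(names(truth), used)
  if (length(used) == 0L) stop("no phage has hits at stage ", stage)

  pools <- genus_pools[used]
  true_g <- truth[used]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rates <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    ok <- vapply(seq_along(pools), function(i) {
      pool <- pools[[i]]
      pool[sample.int(length(pool), 1L)] == true_g[[i]]
    }, logical(1))
    rates[s] <- mean(ok)
  }
  structure(list(success_rates = rates, n_sims = n_sims,
                 n_phages_used = length(used),
                 excluded_phages = excluded, stage = stage,
                 seed = seed),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat("<null_model_result> stage ", x$stage, ", ", x$n_sims,
      " simulations over ", x$n_phages_used, " phage(s): mean success ",
      sprintf("%.3f", mean(x$success_rates)), ", 95th percentile ",
      sprintf("%.3f", stats::quantile(x$success_rates, 0.95)), "\n",
      sep = "")
  invisible(x)
}

#' Empirical p-value of the cascade against the null model
#'
#' Fraction of null simulations whose success rate reaches the cascade's
#' observed genus-level precision, with +1 smoothing so the p-value is
#' never exactly zero: `(1 + #{rate >= precision}) / (n_sims + 1)`.
#'
#' @param null a `null_model_result`
#' @param precision observed genus-level precision of the cascade
#' @return numeric p-value in (0, 1]
#' @export
null_model_pvalue <- function(null, precision) {
  (1 + sum(null$success_rates >= precision)) / (null$n_sims + 1)
}

#' Sweep the filter-1 cutoff and evaluate at each value
#'
#' Hits are computed once (at the loosest mismatch cutoff of the grid for
#' mismatch mode) and the cascade plus evaluation is re-run per cutoff.
#' Recall is non-decreasing along a mismatch grid since every hit set at
#' cutoff c is contained in the set at c' > c.
#'
#' @param phages named sequences or FASTA path
#' @param store a `spacer_store`
#' @param truth truth map (see [evaluate_predictions()])
#' @param criterion `"mismatch"` or `"evalue"`
#' @param cutoffs cutoff grid (default 0:10 for mismatch mode;
#'   `10^seq(-9, -1, by = 2)` is a reasonable E-value grid)
#' @param hits optional precomputed hit table (required for E-value mode)
#' @param filter_order passed to [predict_host()]
#' @return data.frame with one row per cutoff: `cutoff`, `recall`,
#'   `precision_genus`, `precision_family`, `precision_order`
#' @export
sweep_cutoffs <- function(phages, store, truth,
                          criterion = c("mismatch", "evalue"),
                          cutoffs = 0:10, hits = NULL,
                          filter_order = c(2L, 3L)) {
  criterion <- match.arg(criterion)
  stopifnot(length(cutoffs) > 0L)
  if (is.null(hits)) {
    if (criterion == "evalue") {
      stop("E-value sweeps require precomputed hits with E-values")
    }
    if (is.character(phages) && length(phages) == 1L &&
        file.exists(phages)) {
      phages <- Biostrings::readDNAStringSet(phages)
      names(phages) <- sub("\\s.*$", "", names(phages))
    }
    hits <- scan_store(store, phages, k = max(cutoffs))
  } else if (is.character(phages) && length(phages) == 1L &&
             file.exists(phages)) {
    phages <- Biostrings::readDNAStringSet(phages)
    names(phages) <- sub("\\s.*$", "", names(phages))
  }
  rows <- lapply(cutoffs, function(cc) {
    preds <- predict_batch(phages, store, cutoff = cc,
                           criterion = criterion, hits = hits,
                           filter_order = filter_order)
    ev <- evaluate_predictions(preds, truth, store$taxonomy)
    data.frame(cutoff = cc, recall = ev$recall,
               precision_genus = unname(ev$precision["genus"]),
               precision_family = unname(ev$precision["family"]),
               precision_order = unname(ev$precision["order"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate every admissible ordering of the tie-breaking filters
#'
#' The alignment-quality filter must run first (later filters are only
#' meaningful on quality-controlled hits) and the LCA fallback is always
#' last, so the search space is the orderings of filters 2 and 3.
#'
#' @param phages named sequences or FASTA path
#' @param store a `spacer_store`
#' @param truth truth map
#' @param cutoff,criterion filter-1 settings
#' @param hits optional precomputed hit table
#' @return data.frame with one row per ordering: `order`, `recall`,
#'   `precision_genus`, `precision_family`, `precision_order`
#' @export
filter_order_search <- function(phages, store, truth, cutoff = 2,
                                criterion = "mismatch", hits = NULL) {
  orders <- list(c(2L, 3L), c(3L, 2L))
  rows <- lapply(orders, function(fo) {
    preds <- predict_batch(phages, store, cutoff = cutoff,
                           criterion = criterion, hits = hits,
                           filter_order = fo)
    ev <- evaluate_predictions(preds, truth, store$taxonomy)
    data.frame(order = paste(c(1L, fo, 4L), collapse = ">"),
               recall = ev$recall,
               precision_genus = unname(ev$precision["genus"]),
               precision_family = unname(ev$precision["family"]),
               precision_order = unname(ev$precision["order"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter diagnostics: what separated accurate from wrong decisions
#'
#' For phages decided by the region-count filter, compares the winning
#' genus's number of distinct targeted regions between accurate and wrong
#' predictions; for phages decided by the 5'-proximity filter, compares
#' the winning genus's best relative position. Each pair of distributions
#' is tested with a two-sample Kolmogorov-Smirnov statistic; groups with
#' fewer than 2 observations yield NA with a note.
#'
#' @param bench a `benchmark_result` from [evaluate_predictions()]
#' @param predictions the `host_prediction_set` that was evaluated
#' @return list with data.frames `filter2` (columns `phage_id`,
#'   `n_regions`, `correct`) and `filter3` (`phage_id`, `best_rel_pos`,
#'   `correct`), plus `ks` (data.frame `filter`, `statistic`, `p_value`,
#'   `note`)
#' @export
diagnostics <- function(bench, predictions) {
  df <- bench$per_phage
  byid <- stats::setNames(predictions, vapply(predictions, `[[`, "",
                                              "phage_id"))
  f2 <- df[df$deciding_filter == "2", , drop = FALSE]
  f3 <- df[df$deciding_filter == "3", , drop = FALSE]

  tab2 <- data.frame(phage_id = f2$phage_id,
                     n_regions = vapply(f2$phage_id, function(pid) {
                       sh <- byid[[pid]]$supporting_hits
                       length(unique(paste(sh$phage_start, sh$phage_end)))
                     }, integer(1)),
                     correct = f2$correct_genus,
                     stringsAsFactors = FALSE)
  tab3 <- data.frame(phage_id = f3$phage_id,
                     best_rel_pos = vapply(f3$phage_id, function(pid) {
                       sh <- byid[[pid]]$supporting_hits
                       min(relative_position(sh$position_in_locus,
                                             sh$locus_length))
                     }, numeric(1)),
                     correct = f3$correct_genus,
                     stringsAsFactors = FALSE)
  rownames(tab2) <- rownames(tab3) <- NULL

  ks_row <- function(vals, grp, label) {
    a <- vals[grp]; b <- vals[!grp]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(filter = label, statistic = NA_real_,
                        p_value = NA_real_,
                        note = "group with < 2 observations",
                        stringsAsFactors = FALSE))
    }
    kt <- suppressWarnings(stats::ks.test(a, b))
    data.frame(filter = label, statistic = unname(kt$statistic),
               p_value = kt$p.value, note = "",
               stringsAsFactors = FALSE)
  }
  ks <- rbind(ks_row(tab2$n_regions, tab2$correct, "2"),
              ks_row(tab3$best_rel_pos, tab3$correct, "3"))
  list(filter2 = tab2, filter3 = tab3, ks = ks)
}
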