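#' Relative position of a spacer within its CRISPR locus
#'
#' Maps the leader-relative position to `[0, 1]` so loci of different
#' lengths are comparable: `(position - 1) / (locus_length - 1)`, with 0
#' meaning 5'-most (most recently acquired). A single-spacer locus maps to
#' 0: its lone spacer is trivially the newest.
#'
#' @param position_in_locus integer in `1..locus_length` (vectorized)
#' @param locus_length integer >= 1
#' @return numeric in `[0, 1]`
#' @export
relative_position <- function(position_in_locus, locus_length) {
  if (any(locus_length < 1L)) stop("locus_length must be >= 1")
  if (any(position_in_locus < 1L | position_in_locus > locus_length)) {
    stop("position_in_locus out of range 1..locus_length")
  }
  ifelse(locus_length == 1L, 0,
         (position_in_locus - 1) / (locus_length - 1))
}

# Exact fraction machinery for filter 3 ties: relative positions are the
# rationals (p-1)/(L-1); comparing doubles could split ties like 1/3 vs
# 2/6, so comparisons go through integer cross products (exact in doubles
# for any realistic locus length).
.rel_num <- function(p, L) as.numeric(p - 1L)
.rel_den <- function(p, L) as.numeric(pmax(L - 1L, 1L))

# indices of the exact minimum of fractions num/den
.frac_min_which <- function(num, den) {
  best <- 1L
  for (i in seq_along(num)[-1L]) {
    if (num[i] * den[best] < num[best] * den[i]) best <- i
  }
  which(num * den[best] == num[best] * den)
}

#' Filter 2: number of distinct targeted regions per genus
#'
#' A genus whose spacers target many different regions of the phage
#' genome is more likely a genuine host than one hit in a single region
#' (possibly by chance or by many redundant copies of one spacer).
#' Regions are distinct `(phage_start, phage_end)` interval pairs after
#' strand normalization; strand is ignored and overlapping-but-unequal
#' intervals count separately. Genera achieving the maximum count
#' survive.
#'
#' @param hits hit table for one phage (resolved genus only)
#' @return list with `genera` (surviving genus ids) and `tally`
#'   (data.frame `genus_taxon`, `n_regions`)
#' @export
filter2_region_count <- function(hits) {
  stopifnot(nrow(hits) > 0L)
  key <- paste(hits$genus_taxon, hits$phage_start, hits$phage_end,
               sep = "\r")
  n_regions <- tapply(!duplicated(key), hits$genus_taxon, sum)
  tally <- data.frame(genus_taxon = names(n_regions),
                      n_regions = as.integer(n_regions),
                      stringsAsFactors = FALSE)
  rownames(tally) <- NULL
  list(genera = tally$genus_taxon[tally$n_regions == max(tally$n_regions)],
       tally = tally)
}

#' Filter 3: proximity to the 5' (leader) end of the CRISPR array
#'
#' New spacers are incorporated at the leader end, so leader-proximal
#' spacers witness recent phage-host encounters. Each genus is scored by
#' the minimum [relative_position()] over its hits; genera attaining the
#' global minimum survive. Positions are compared as exact fractions so
#' that ties are genuine ties.
#'
#' @param hits hit table for one phage (resolved genus only)
#' @return list with `genera` (surviving genus ids) and `best`
#'   (data.frame `genus_taxon`, `best_rel_pos`)
#' @export
filter3_five_prime <- function(hits) {
  stopifnot(nrow(hits) > 0L)
  num <- .rel_num(hits$position_in_locus, hits$locus_length)
  den <- .rel_den(hits$position_in_locus, hits$locus_length)
  genera <- unique(hits$genus_taxon)
  bn <- numeric(length(genera)); bd <- numeric(length(genera))
  for (i in seq_along(genera)) {
    sel <- hits$genus_taxon == genera[i]
    w <- .frac_min_which(num[sel], den[sel])[1L]
    bn[i] <- num[sel][w]; bd[i] <- den[sel][w]
  }
  win <- .frac_min_which(bn, bd)
  list(genera = genera[win],
       best = data.frame(genus_taxon = genera,
                         best_rel_pos = bn / bd,
                         stringsAsFactors = FALSE))
}

#' Predict the host of one phage from its spacer hits
#'
#' Applies the decision cascade to the hits of a single phage:
#'
#' 1. **Alignment quality** — [filter_hits()]: drop hits beyond the
#'    cutoff, keep only the best surviving stratum (minimum corrected
#'    mismatches, or minimum E-value in E-value mode).
#' 2. **Region count** — [filter2_region_count()].
#' 3. **5' proximity** — [filter3_five_prime()].
#' 4. **LCA fallback** — if several genera still remain, the prediction
#'    is their lowest common ancestor at its own (possibly shallower)
#'    rank.
#'
#' The cascade stops as soon as a single genus remains; hits from spacers
#' without a resolved genus are excluded up front. Filters 2 and 3 may be
#' swapped via `filter_order` to reproduce order-search experiments;
#' filter 1 always runs first and filter 4 is always the fallback.
#'
#' @param hits hit table for one phage (as from [scan_store()] or
#'   [parse_alignment_table()])
#' @param taxonomy a `spacer_taxonomy`
#' @param phage_id identifier for reporting (defaults to the hits' id)
#' @param cutoff filter-1 cutoff (default 2 mismatches)
#' @param criterion `"mismatch"` or `"evalue"`
#' @param filter_order permutation of `c(2, 3)`
#' @return object of class `host_prediction`: fields `phage_id`,
#'   `predicted_taxon`, `predicted_name`, `predicted_rank`,
#'   `deciding_filter` (1-4 or `"none"`), `low_confidence` (LCA at the
#'   unranked root), `candidate_genera_per_stage` (named list),
#'   `supporting_hits`, `n_hits_input`, `n_unresolved_excluded`
#' @export
predict_host <- function(hits, taxonomy, phage_id = NULL, cutoff = 2,
                         criterion = c("mismatch", "evalue"),
                         filter_order = c(2L, 3L)) {
  criterion <- match.arg(criterion)
  if (!identical(sort(as.integer(filter_order)), c(2L, 3L))) {
    stop("filter_order must be a permutation of c(2, 3)")
  }
  if (is.null(phage_id)) {
    phage_id <- if (nrow(hits) > 0L) hits$phage_id[1L] else NA_character_
  }
  n_input <- nrow(hits)
  unresolved <- is.na(hits$genus_taxon)
  hits <- hits[!unresolved, , drop = FALSE]

  stages <- list()
  pred <- function(taxon, rank, filter, supporting, low_conf = FALSE) {
    structure(list(
      phage_id = phage_id,
      predicted_taxon = taxon,
      predicted_name = if (is.na(taxon)) NA_character_ else
        unname(taxonomy$name[taxon]),
      predicted_rank = rank,
      deciding_filter = filter,
      low_confidence = low_conf,
      candidate_genera_per_stage = stages,
      supporting_hits = supporting,
      n_hits_input = n_input,
      n_unresolved_excluded = sum(unresolved)
    ), class = "host_prediction")
  }

  f1 <- filter_hits(hits, criterion = criterion, cutoff = cutoff)
  genera <- unique(f1$genus_taxon)
  stages[["1"]] <- genera
  if (length(genera) == 0L) {
    return(pred(NA_character_, NA_character_, "none",
                f1[0, , drop = FALSE]))
  }
  if (length(genera) == 1L) return(pred(genera, "genus", 1L, f1))

  cur <- f1
  for (f in as.integer(filter_order)) {
    surv <- if (f == 2L) filter2_region_count(cur)$genera
            else filter3_five_prime(cur)$genera
    cur <- cur[cur$genus_taxon %in% surv, , drop = FALSE]
    stages[[as.character(f)]] <- surv
    if (length(surv) == 1L) return(pred(surv, "genus", f, cur))
  }

  # filter 4: LCA of the remaining genera
  lca <- last_common_ancestor(taxonomy, unique(cur$genus_taxon))
  rk <- lca_rank(taxonomy, lca, lca)
  stages[["4"]] <- unique(cur$genus_taxon)
  pred(lca, as.character(rk), 4L, cur,
       low_conf = lca == taxonomy$root || identical(as.character(rk), "no rank"))
}

#' @export
print.host_prediction <- function(x, ...) {
  if (identical(x$deciding_filter, "none")) {
    cat("<host_prediction> ", x$phage_id, ": no prediction (no hits ",
        "passed filter 1)\n", sep = "")
  } else {
    cat("<host_prediction> ", x$phage_id, ": ", x$predicted_name, " [",
        x$predicted_rank, "] via filter ", x$deciding_filter,
        if (isTRUE(x$low_confidence)) " (low confidence)" else "",
        ", ", nrow(x$supporting_hits), " supporting hit(s)\n", sep = "")
  }
  invisible(x)
}

#' Predict hosts for a batch of phage genomes
#'
#' Scans every genome of a multi-FASTA (or named sequence set) against the
#' store's prediction spacers and runs [predict_host()] per genome,
#' preserving input order. With `threads > 1` genomes are processed in
#' parallel; results are independent of the thread count.
#'
#' @param phages path to a multi-FASTA file, or a named `DNAStringSet` /
#'   named character vector
#' @param store a `spacer_store`
#' @param cutoff,criterion,filter_order passed to [predict_host()]
#' @param hits optional precomputed hit table (e.g. from
#'   [parse_alignment_table()]); when given, no scanning is done
#' @param min_len,max_len spacer length window for scanning
#' @param threads worker count for the per-genome stage
#' @return object of class `host_prediction_set`: list of
#'   `host_prediction` in input order, with the scanned `hits` attached
#' @export
predict_batch <- function(phages, store, cutoff = 2,
                          criterion = c("mismatch", "evalue"),
                          filter_order = c(2L, 3L), hits = NULL,
                          min_len = 23L, max_len = 48L, threads = 1L) {
  criterion <- match.arg(criterion)
  if (is.character(phages) && length(phages) == 1L && file.exists(phages)) {
    phages <- Biostrings::readDNAStringSet(phages)
    names(phages) <- sub("\\s.*$", "", names(phages))
  } else if (is.character(phages)) {
    phages <- Biostrings::DNAStringSet(phages)
  }
  ids <- names(phages)
  if (length(ids) == 0L) {
    warning("empty phage input; no predictions made", call. = FALSE)
    return(structure(list(), class = "host_prediction_set",
                     hits = .empty_hit_table()))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate phage id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(hits)) {
    # scan at the requested cutoff (a wider scan only matters for sweeps)
    scan_k <- if (criterion == "mismatch") cutoff else 10L
    hits <- scan_store(store, phages, k = scan_k,
                       min_len = min_len, max_len = max_len)
  }
  one <- function(pid) {
    predict_host(hits[hits$phage_id == pid, , drop = FALSE],
                 taxonomy = store$taxonomy, phage_id = pid,
                 cutoff = cutoff, criterion = criterion,
                 filter_order = filter_order)
  }
  preds <- if (threads > 1L) {
    parallel::mclapply(ids, one, mc.cores = threads)
  } else {
    lapply(ids, one)
  }
  structure(preds, class = "host_prediction_set", hits = hits)
}

#' @export
print.host_prediction_set <- function(x, ...) {
  cat("<host_prediction_set> ", length(x), " phage(s), ",
      sum(vapply(x, function(p) !identical(p$deciding_filter, "none"),
                 logical(1))), " with a prediction\n", sep = "")
  invisible(x)
}

#' Flatten predictions to a data.frame
#'
#' @param predictions a `host_prediction_set` or list of
#'   `host_prediction`
#' @return data.frame with one row per phage: `phage_id`,
#'   `predicted_taxon`, `predicted_name`, `predicted_rank`,
#'   `deciding_filter`, `low_confidence`, `n_supporting_spacers`
#' @export
predictions_to_df <- function(predictions) {
  data.frame(
    phage_id = vapply(predictions, `[[`, "", "phage_id"),
    predicted_taxon = vapply(predictions, function(p)
      as.character(p$predicted_taxon), ""),
    predicted_name = vapply(predictions, function(p)
      as.character(p$predicted_name), ""),
    predicted_rank = vapply(predictions, function(p)
      as.character(p$predicted_rank), ""),
    deciding_filter = vapply(predictions, function(p)
      as.character(p$deciding_filter), ""),
    low_confidence = vapply(predictions, function(p)
      isTRUE(p$low_confidence), logical(1)),
    n_supporting_spacers = vapply(predictions, function(p)
      length(unique(p$supporting_hits$spacer_id)), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Write the per-phage narrative prediction report
#'
#' A plain-text report that explains each step of the cascade for every
#' phage: how many hits were found, the candidate genus sets after each
#' applied filter, which filter decided, and the supporting spacers.
#'
#' @param predictions a `host_prediction_set`
#' @param path output path
#' @param taxonomy taxonomy used to display genus names
#' @return `path`, invisibly
#' @export
write_prediction_report <- function(predictions, path, taxonomy) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  nm <- function(ids) {
    if (length(ids) == 0L) return("(none)")
    paste(sprintf("%s (%s)", unname(taxonomy$name[ids]), ids),
          collapse = ", ")
  }
  filter_desc <- c(
    "1" = "alignment quality (minimum corrected mismatches within cutoff)",
    "2" = "number of distinct targeted regions on the phage genome",
    "3" = "proximity to the 5' (leader) end of the CRISPR array",
    "4" = "lowest common ancestor of remaining genera")
  for (p in predictions) {
    writeLines(c(
      paste0("== Phage ", p$phage_id, " =="),
      paste0("Hits against spacer store: ", p$n_hits_input,
             " (", p$n_unresolved_excluded,
             " excluded: unresolved host genus)")), con)
    for (s in names(p$candidate_genera_per_stage)) {
      writeLines(paste0("After filter ", s, " [", filter_desc[[s]], "]: ",
                        nm(p$candidate_genera_per_stage[[s]])), con)
    }
    if (identical(p$deciding_filter, "none")) {
      writeLines("Decision: NO PREDICTION (no hit passed filter 1)", con)
    } else {
      writeLines(paste0(
        "Decision: ", p$predicted_name, " [rank ", p$predicted_rank,
        "], deciding filter ", p$deciding_filter,
        if (isTRUE(p$low_confidence)) " -- LOW CONFIDENCE (LCA at/near root)"
        else ""), con)
      sh <- p$supporting_hits
      writeLines(paste0("Supporting spacers (", nrow(sh), " hit(s)):"), con)
      if (nrow(sh) > 0L) {
        writeLines(sprintf(
          "  %s  region %d-%d (%s)  mismatches %d  locus pos %d/%d",
          sh$spacer_id, sh$phage_start, sh$phage_end, sh$strand,
          sh$true_mismatches, sh$position_in_locus, sh$locus_length), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}
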