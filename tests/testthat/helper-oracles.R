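# Independent oracles and shared fixture builders for the test suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# brute-force sliding-window Hamming scan over both strands; mirrors the
# scanner's contract (N never matches; palindromic spacers report plus
# strand only) but shares no code with it
brute_scan <- function(spacer, genome, k) {
  m <- nchar(spacer)
  L <- nchar(genome)
  rc <- revcomp_chr(spacer)
  strands <- if (rc == spacer) "+" else c("+", "-")
  rows <- list()
  if (m >= 1L && m <= L) {
    for (st in strands) {
      pat <- if (st == "+") spacer else rc
      pv <- strsplit(pat, "")[[1L]]
      gv <- strsplit(genome, "")[[1L]]
      for (s in seq_len(L - m + 1L)) {
        w <- gv[s:(s + m - 1L)]
        d <- sum(w != pv | w == "N" | pv == "N")
        if (d <= k) {
          rows[[length(rows) + 1L]] <- data.frame(
            phage_start = s, phage_end = s + m - 1L, strand = st,
            raw_mismatches = d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, c(list(data.frame(
    phage_start = integer(0), phage_end = integer(0),
    strand = character(0), raw_mismatches = integer(0),
    stringsAsFactors = FALSE)), rows))
  out[order(out$phage_start, out$phage_end, out$strand), , drop = FALSE]
}

# brute-force LCA: deepest element of the intersection of the two
# lineages viewed as sets
brute_lca <- function(taxonomy, a, b) {
  la <- lineage_of(taxonomy, a)
  lb <- lineage_of(taxonomy, b)
  common <- intersect(la, lb)
  common[which.max(taxonomy$depth[common])]
}

# small hand-built taxonomy: root > Bacteria > 2 orders > 3 families >
# 5 genera, with one unranked node between family F2 and genus G4
tiny_taxonomy <- function() {
  taxonomy_from_table(data.frame(
    taxon_id  = c("r", "B", "O1", "O2", "F1", "F2", "F3", "X",
                  "G1", "G2", "G3", "G4", "G5"),
    parent_id = c("r", "r", "B", "B", "O1", "O1", "O2", "F2",
                  "F1", "F1", "F2", "X", "F3"),
    rank = c("no rank", "superkingdom", "order", "order", "family",
             "family", "family", "no rank", "genus", "genus", "genus",
             "genus", "genus"),
    name = c("root", "Bacteria", "Order1", "Order2", "Family1", "Family2",
             "Family3", "clade X", "Genus1", "Genus2", "Genus3", "Genus4",
             "Genus5"),
    stringsAsFactors = FALSE))
}

# GFF builder: loci is a list of lists with fields acc, locus, strand,
# spacers (character vector in genome-coordinate order)
make_gff_text <- function(loci) {
  lines <- character(0)
  for (lc in loci) {
    cur <- 1000L
    for (i in seq_along(lc$spacers)) {
      seq <- lc$spacers[i]
      lines <- c(lines, paste(
        lc$acc, "test", "binding_site", cur, cur + nchar(seq) - 1L,
        nchar(seq), lc$strand, ".",
        sprintf("ID=%s_%d;Note=%s", lc$locus, i, seq), sep = "\t"))
      cur <- cur + nchar(seq) + 30L
    }
  }
  lines
}

write_gff <- function(lines, path = tempfile(fileext = ".gff")) {
  writeLines(lines, path)
  path
}

# minimal hit-table builder for cascade tests
mk_hits <- function(genus, start, end, pos = 1L, loclen = 10L,
                    tm = 0L, phage = "P1") {
  n <- length(genus)
  data.frame(
    spacer_id = sprintf("sp%02d", seq_len(n)),
    organism_accession = paste0("ACC_", genus),
    genus_taxon = genus,
    locus_id = "1",
    position_in_locus = rep_len(pos, n),
    locus_length = rep_len(loclen, n),
    spacer_length = 30L,
    phage_id = phage,
    phage_start = rep_len(start, n), phage_end = rep_len(end, n),
    strand = "+", aligned_length = 30L,
    raw_mismatches = rep_len(tm, n), gap_openings = 0L,
    true_mismatches = rep_len(tm, n), evalue = NA_real_,
    stringsAsFactors = FALSE
  )
}

# memoized scenario fixtures shared across test files (simulation and
# scanning are deterministic, so sharing is safe)
.fixture_cache <- new.env(parent = emptyenv())

scenario_fixture <- function(scenario, seed = 42, ...) {
  key <- paste(c(scenario, seed, unlist(list(...))), collapse = "_")
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("sx_", gsub("[^A-Za-z0-9]", "_", key)))
    sim <- simulate_dataset(sim_scenario(scenario, seed = seed, ...), dir)
    fx <- load_fixture(dir)
    fx$sim <- sim
    .fixture_cache[[key]] <- fx
  }
  .fixture_cache[[key]]
}

# predictions + evaluation for a scenario, memoized
scenario_run <- function(scenario, seed = 42, cutoff = 2) {
  key <- paste("run", scenario, seed, cutoff)
  if (is.null(.fixture_cache[[key]])) {
    fx <- scenario_fixture(scenario, seed)
    preds <- predict_batch(fx$phages, fx$store, cutoff = cutoff)
    bench <- evaluate_predictions(preds, fx$truth, fx$taxonomy)
    .fixture_cache[[key]] <- list(fx = fx, preds = preds, bench = bench)
  }
  .fixture_cache[[key]]
}
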