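test_that("the corrected mismatch count follows the formula", {
  cases <- data.frame(
    sp = c(32L, 32L, 35L, 28L, 40L, 30L),
    al = c(32L, 30L, 35L, 20L, 40L, 29L),
    mm = c(0L, 1L, 2L, 0L, 10L, 0L),
    expected = c(0L, 3L, 2L, 8L, 10L, 1L)
  )
  expect_equal(true_mismatches(cases$sp, cases$al, cases$mm),
               cases$expected)
  expect_error(true_mismatches(30, 31, 0), "exceeds")
  expect_error(true_mismatches(30, -1, 0), "non-negative")
})

test_that("hamming_nt treats N as a universal mismatch", {
  expect_equal(hamming_nt("ACGT", "ACGT"), 0L)
  expect_equal(hamming_nt("ACGT", "ACGA"), 1L)
  expect_equal(hamming_nt("ACGN", "ACGN"), 1L)
  expect_equal(hamming_nt("NNNN", "NNNN"), 4L)
  expect_error(hamming_nt("ACG", "ACGT"), "length")
})

test_that("scan_genome finds the expected placements in small cases", {
  # exact palindromic spacer: a single plus-strand hit
  h <- scan_genome("ACGT", "TTACGTTT", 0)
  expect_equal(nrow(h), 1L)
  expect_equal(h$phage_start, 3L)
  expect_equal(h$phage_end, 6L)
  expect_equal(h$strand, "+")
  expect_equal(h$true_mismatches, 0L)

  # one substitution away
  h1 <- scan_genome("ACGA", "TTACGTTT", 1)
  plus <- h1[h1$strand == "+", ]
  expect_equal(plus$phage_start, 3L)
  expect_equal(plus$true_mismatches, 1L)

  # minus-strand placement of a non-palindromic spacer
  g <- paste0("TTTT", revcomp_chr("ACCGGTAC"), "TTTT")
  hm <- scan_genome("ACCGGTAC", g, 0)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$strand, "-")
  expect_equal(c(hm$phage_start, hm$phage_end), c(5L, 12L))

  # spacer longer than genome
  expect_equal(nrow(scan_genome("ACGTACGTACGT", "ACGT", 3)), 0L)
})

test_that("scanner equals the brute-force oracle on random instances", {
  set.seed(202)
  n_checked <- 0L
  for (i in 1:110) {
    k <- sample(0:3, 1)
    glen <- sample(150:400, 1)
    g <- random_dna(glen)
    # mix planted and unplanted spacers, long (seeded path) and short
    # (direct path)
    m <- sample(c(8:12, 20:36), 1)
    if (i %% 2 == 0) {
      s0 <- sample(glen - m + 1L, 1)
      sp <- substr(g, s0, s0 + m - 1L)
      nmut <- sample(0:k, 1)
      sp <- mutate_protospacer(sp, nmut)
      if (sample(c(TRUE, FALSE), 1)) sp <- revcomp_chr(sp)
    } else {
      sp <- random_dna(m)
    }
    got <- scan_genome(sp, g, k)
    want <- brute_scan(sp, g, k)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$phage_start, want$phage_start)
    expect_equal(got$phage_end, want$phage_end)
    expect_equal(got$strand, want$strand)
    expect_equal(got$raw_mismatches, want$raw_mismatches)
    # full-length placements: corrected count is the Hamming distance
    expect_equal(got$true_mismatches, got$raw_mismatches)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("hit sets are nested in k and invariant under genome reversal", {
  set.seed(303)
  for (i in 1:20) {
    g <- random_dna(300)
    s0 <- sample(270, 1)
    sp <- mutate_protospacer(substr(g, s0, s0 + 29L), sample(0:2, 1))
    k <- sample(0:2, 1)
    h_k <- scan_genome(sp, g, k)
    h_k2 <- scan_genome(sp, g, k + 2L)
    key <- function(h) paste(h$phage_start, h$phage_end, h$strand)
    expect_true(all(key(h_k) %in% key(h_k2)))

    # reverse-complement the genome: intervals reflect, strands flip
    grc <- revcomp_chr(g)
    h_rc <- scan_genome(sp, grc, k)
    L <- nchar(g)
    mapped <- paste(L - h_rc$phage_end + 1L, L - h_rc$phage_start + 1L,
                    ifelse(h_rc$strand == "+", "-", "+"))
    expect_setequal(mapped, key(h_k))
  }
})

test_that("scan_store expands hits to every stored copy of a sequence", {
  tx <- tiny_taxonomy()
  set.seed(9)
  sp <- random_dna(30)
  rec <- parse_crispr_gff(write_gff(make_gff_text(list(
    list(acc = "A1", locus = "1", strand = "+", spacers = rep(sp, 3)),
    list(acc = "A2", locus = "1", strand = "+", spacers = sp)))))
  store <- build_store(rec, tx, data.frame(
    organism_accession = c("A1", "A2"), taxon_id = c("G1", "G2")))
  phage <- c(P1 = paste0(random_dna(100), sp, random_dna(100)))
  hits <- scan_store(store, phage, k = 0)
  # 4 stored copies, one placement each
  expect_equal(nrow(hits), 4L)
  expect_setequal(hits$organism_accession, c("A1", "A2"))
  expect_equal(unique(hits$phage_start), 101L)
  expect_true(all(is.na(hits$evalue)))
})

test_that("tabular ingestion discards gapped rows and normalizes strand", {
  fx <- scenario_fixture("clean")
  store <- fx$store
  sp <- store$spacers[1, ]
  qid <- spacer_fasta_id(sp)
  tab <- tempfile()
  writeLines(c(
    paste(qid, "phageX", "96.9", "32", "1", "0", "1", "32", "100", "131",
          "1e-8", "59.0", sep = "\t"),
    paste(qid, "phageX", "96.9", "32", "1", "1", "1", "32", "200", "231",
          "1e-8", "55.0", sep = "\t"),                       # gapped
    paste(qid, "phageX", "100.0", "30", "0", "0", "1", "30", "500", "471",
          "1e-9", "60.0", sep = "\t")), tab)                 # minus strand
  hits <- parse_alignment_table(tab, store)
  expect_equal(nrow(hits), 2L)
  expect_equal(attr(hits, "ingest_report")$n_gapped_discarded, 1L)
  minus <- hits[hits$strand == "-", ]
  expect_equal(c(minus$phage_start, minus$phage_end), c(471L, 500L))
  # corrected mismatches from the stored spacer length
  expect_equal(hits$true_mismatches,
               sp$spacer_length - hits$aligned_length + hits$raw_mismatches)
  expect_equal(hits$evalue, c(1e-8, 1e-9))
})

test_that("scanner hits survive a tabular serialization round trip", {
  fx <- scenario_fixture("clean")
  hits <- attr(scenario_run("clean")$preds, "hits")
  tab <- tempfile()
  write_alignment_table(hits, tab)
  back <- parse_alignment_table(tab, fx$store)
  cols <- c("spacer_id", "phage_id", "phage_start", "phage_end", "strand",
            "aligned_length", "raw_mismatches", "gap_openings",
            "true_mismatches")
  key <- function(df) do.call(order, df[cols])
  a <- hits[key(hits), cols]
  b <- back[key(back), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("filter 1 keeps only the best stratum within the cutoff", {
  h <- data.frame(true_mismatches = c(0L, 1L, 2L, 3L),
                  evalue = c(1e-3, 1e-9, 1e-9, 1e-2))
  expect_equal(filter_hits(h, "mismatch", 2)$true_mismatches, 0L)
  expect_equal(nrow(filter_hits(h, "mismatch", -1 + 1)), 1L)
  # all hits beyond the cutoff: nothing survives
  h2 <- data.frame(true_mismatches = c(5L, 7L), evalue = c(1, 1))
  expect_equal(nrow(filter_hits(h2, "mismatch", 2)), 0L)
  # a single hit exactly at the boundary is retained
  h3 <- data.frame(true_mismatches = 2L, evalue = 1)
  expect_equal(nrow(filter_hits(h3, "mismatch", 2)), 1L)
  # E-value mode keeps the minimum E-value stratum
  expect_equal(nrow(filter_hits(h, "evalue", 1e-2)), 2L)
  expect_equal(unique(filter_hits(h, "evalue", 1e-2)$evalue), 1e-9)
  expect_error(filter_hits(h, "evalue", -1), "positive")
  expect_error(filter_hits(h, "wat", 2))
  # NA E-values (built-in scanner) cannot be E-value-filtered
  h$evalue <- NA_real_
  expect_error(filter_hits(h, "evalue", 1e-2), "E-value")
})
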