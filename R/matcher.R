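#' Corrected mismatch count for an ungapped spacer alignment
#'
#' Local aligners may leave spacer tails unaligned; every unaligned spacer
#' base is counted as a mismatch on top of the mismatches reported inside
#' the aligned region:
#' `spacer_length - aligned_length + raw_mismatches`.
#' Gapped hits are not meaningful under this correction and must be
#' discarded upstream ([parse_alignment_table()] does so).
#'
#' @param spacer_length,aligned_length,raw_mismatches non-negative
#'   integers (vectorized); `aligned_length <= spacer_length`
#' @return integer vector of corrected mismatch counts
#' @export
true_mismatches <- function(spacer_length, aligned_length, raw_mismatches) {
  if (any(spacer_length < 0 | aligned_length < 0 | raw_mismatches < 0)) {
    stop("true_mismatches: all arguments must be non-negative")
  }
  if (any(aligned_length > spacer_length)) {
    stop("true_mismatches: aligned_length exceeds spacer_length")
  }
  as.integer(spacer_length - aligned_length + raw_mismatches)
}

#' Nucleotide Hamming distance with strict N handling
#'
#' Number of differing columns between two equal-length sequences; a
#' column containing `N` on either side always counts as a mismatch.
#'
#' @param a,b single DNA strings of equal length
#' @return integer distance
#' @export
hamming_nt <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("hamming_nt: sequences differ in length")
  }
  n <- as.raw(78L) # 'N'
  sum(ra != rb | ra == n | rb == n)
}

.empty_hits <- function() {
  data.frame(
    phage_start = integer(0), phage_end = integer(0),
    strand = character(0), aligned_length = integer(0),
    raw_mismatches = integer(0), gap_openings = integer(0),
    true_mismatches = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Scan a genome for ungapped spacer matches with at most k mismatches
#'
#' Reports every full-length ungapped placement of the spacer on either
#' strand of the genome whose Hamming distance (with `N` never matching,
#' see [hamming_nt()]) is at most `k`. Minus-strand placements are found by
#' matching the reverse complement; reported intervals always satisfy
#' `phage_start <= phage_end` in plus-strand genome coordinates. A
#' palindromic spacer (equal to its reverse complement) reports each
#' placement once, on the plus strand.
#'
#' Candidate placements are enumerated either directly with
#' `Biostrings::matchPattern()` or, when the spacer is long enough
#' relative to `k`, via a pigeonhole seed index: the spacer is split into
#' `k + 1` disjoint exact seeds, and any placement with at most `k`
#' mismatches must match one seed exactly. The accelerator cannot change
#' the reported hit set; every candidate's mismatch count is recomputed
#' under the strict N rule before reporting.
#'
#' @param spacer spacer sequence (character or DNAString)
#' @param genome genome sequence (character or DNAString)
#' @param k maximum number of mismatches (>= 0)
#' @return data.frame with columns `phage_start`, `phage_end`, `strand`,
#'   `aligned_length`, `raw_mismatches`, `gap_openings` (always 0),
#'   `true_mismatches` (= `raw_mismatches`: placements are full length)
#' @export
scan_genome <- function(spacer, genome, k) {
  hits <- scan_genome_batch(stats::setNames(as.character(spacer), "q"),
                            genome, k)
  hits$spacer <- NULL
  hits
}

# minimum seed width for which the pigeonhole index beats direct matching
.SEED_MIN_WIDTH <- 6L

#' Scan one genome with a batch of spacers
#'
#' Same contract as [scan_genome()] for every spacer of a named vector,
#' sharing one seed index across the batch. Used by [scan_store()].
#'
#' @param spacers named character vector of spacer sequences
#' @param genome genome sequence
#' @param k maximum mismatches
#' @return data.frame as [scan_genome()] plus a `spacer` column carrying
#'   the names of `spacers`
#' @export
scan_genome_batch <- function(spacers, genome, k) {
  stopifnot(k >= 0, !is.null(names(spacers)))
  spacers <- stats::setNames(toupper(as.character(spacers)), names(spacers))
  genome_str <- toupper(as.character(genome))
  glen <- nchar(genome_str)
  lens <- nchar(spacers)
  ok <- lens > 0L & lens <= glen
  res <- list(cbind(spacer = character(0), .empty_hits()))
  if (any(ok)) {
    seed_w <- min(lens[ok]) %/% (as.integer(k) + 1L)
    if (seed_w >= .SEED_MIN_WIDTH) {
      idx <- .seed_index(spacers[ok], k, seed_w)
      res <- c(res, .scan_seeded(idx, genome_str))
    } else {
      res <- c(res, .scan_direct(spacers[ok], genome_str, k))
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$spacer, names(spacers)), out$phage_start,
                   out$phage_end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.hits_df <- function(name, starts, mism, m, strand) {
  data.frame(
    spacer = name,
    phage_start = as.integer(starts), phage_end = as.integer(starts + m - 1L),
    strand = strand, aligned_length = m,
    raw_mismatches = as.integer(mism), gap_openings = 0L,
    true_mismatches = as.integer(mism),
    stringsAsFactors = FALSE
  )
}

.scan_direct <- function(spacers, genome_str, k) {
  subject <- Biostrings::DNAString(genome_str)
  res <- list()
  for (i in seq_along(spacers)) {
    m <- nchar(spacers[[i]])
    rc <- .revcomp(spacers[[i]])
    # a palindromic spacer would report every placement twice; one
    # alignment, reported on the plus strand
    strands <- if (rc == spacers[[i]]) "+" else c("+", "-")
    for (st in strands) {
      pat <- if (st == "+") spacers[[i]] else rc
      mt <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                     max.mismatch = k, with.indels = FALSE)
      if (length(mt) == 0L) next
      starts <- BiocGenerics::start(mt)
      windows <- substring(genome_str, starts, starts + m - 1L)
      mism <- vapply(windows, hamming_nt, 0L, b = pat, USE.NAMES = FALSE)
      keep <- mism <= k
      if (!any(keep)) next
      res[[length(res) + 1L]] <-
        .hits_df(names(spacers)[i], starts[keep], mism[keep], m, st)
    }
  }
  res
}

# pigeonhole seed index: k+1 disjoint width-w exact seeds per strand
# variant; a placement with <= k mismatches must contain a clean seed
# (N columns count as mismatches, so seeds containing N are unmatchable
# and dropped; a variant whose every seed holds an N cannot have <= k
# mismatches anywhere). The index is genome-independent, so batch
# scanners build it once and reuse it across genomes.
.seed_index <- function(spacers, k, seed_w) {
  k <- as.integer(k)
  n <- length(spacers)
  variant_seq <- character(2L * n)   # odd = '+', even = '-'
  palindrome <- logical(2L * n)
  for (i in seq_len(n)) {
    rc <- .revcomp(spacers[[i]])
    variant_seq[2L * i - 1L] <- spacers[[i]]
    variant_seq[2L * i] <- rc
    # skip the minus variant of palindromic spacers (duplicate placements)
    palindrome[2L * i] <- rc == spacers[[i]]
  }
  seeds <- vector("list", 2L * n * (k + 1L))
  m <- 0L
  for (v in seq_along(variant_seq)) {
    if (palindrome[v]) next
    for (j in 0:k) {
      off <- j * seed_w
      s <- substr(variant_seq[v], off + 1L, off + seed_w)
      if (grepl("N", s, fixed = TRUE)) next
      m <- m + 1L
      seeds[[m]] <- list(s, v, off)
    }
  }
  seeds <- seeds[seq_len(m)]
  idx <- list(
    names = names(spacers),
    variant_seq = variant_seq,
    k = k,
    seed_variant = vapply(seeds, function(x) x[[2L]], 0L),
    seed_offset = vapply(seeds, function(x) x[[3L]], 0L),
    pdict = if (m > 0L)
      Biostrings::PDict(Biostrings::DNAStringSet(
        vapply(seeds, function(x) x[[1L]], ""))) else NULL
  )
  idx
}

.scan_seeded <- function(idx, genome_str) {
  if (is.null(idx$pdict)) return(list())
  midx <- Biostrings::matchPDict(idx$pdict, Biostrings::DNAString(genome_str))
  starts_by_seed <- Biostrings::startIndex(midx)
  glen <- nchar(genome_str)

  # collect candidate placements per variant
  cand <- vector("list", length(idx$variant_seq))
  for (s in seq_along(starts_by_seed)) {
    st <- starts_by_seed[[s]]
    if (is.null(st) || length(st) == 0L) next
    v <- idx$seed_variant[s]
    cand[[v]] <- c(cand[[v]], st - idx$seed_offset[s])
  }
  res <- list()
  for (v in seq_along(cand)) {
    if (is.null(cand[[v]])) next
    pat <- idx$variant_seq[v]
    m <- nchar(pat)
    starts <- unique(cand[[v]])
    starts <- starts[starts >= 1L & starts + m - 1L <= glen]
    if (length(starts) == 0L) next
    starts <- sort(starts)
    windows <- substring(genome_str, starts, starts + m - 1L)
    mism <- vapply(windows, hamming_nt, 0L, b = pat, USE.NAMES = FALSE)
    keep <- mism <= idx$k
    if (!any(keep)) next
    i <- (v + 1L) %/% 2L
    strand <- if (v %% 2L == 1L) "+" else "-"
    res[[length(res) + 1L]] <-
      .hits_df(idx$names[i], starts[keep], mism[keep], m, strand)
  }
  res
}

#' Scan phage genomes with all prediction spacers of a store
#'
#' Runs [scan_genome()] for every (spacer, phage) pair, deduplicating
#' identical spacer sequences before scanning and expanding matches back
#' to every stored copy afterwards (identical sequences stored many times
#' all contribute hits, which is exactly the redundancy the prediction
#' cascade must cope with).
#'
#' @param store a `spacer_store`
#' @param phages named `DNAStringSet` (or named character vector) of phage
#'   genomes
#' @param k maximum mismatches (default 2, but scan at the largest cutoff
#'   you intend to sweep)
#' @param min_len,max_len spacer length window (default 23-48)
#' @return a hit table (data.frame) with spacer identity columns
#'   (`spacer_id`, `organism_accession`, `genus_taxon`, `locus_id`,
#'   `position_in_locus`, `locus_length`, `spacer_length`), `phage_id`,
#'   and the alignment columns of [scan_genome()]; `evalue` is NA (the
#'   scanner computes none)
#' @export
scan_store <- function(store, phages, k = 2L, min_len = 23L, max_len = 48L) {
  if (is.character(phages)) phages <- Biostrings::DNAStringSet(phages)
  stopifnot(!is.null(names(phages)), !anyNA(names(phages)))
  sp <- prediction_spacers(store, min_len = min_len, max_len = max_len)
  if (nrow(sp) == 0L || length(phages) == 0L) return(.empty_hit_table())
  useq <- unique(sp$sequence)
  names(useq) <- paste0("u", seq_along(useq))
  genome_strs <- toupper(as.character(phages))
  lens <- nchar(useq)
  seed_w <- min(lens) %/% (as.integer(k) + 1L)
  idx <- if (seed_w >= .SEED_MIN_WIDTH) .seed_index(useq, k, seed_w) else NULL
  rows <- list(.empty_hit_table())
  for (pi in seq_along(phages)) {
    pid <- names(phages)[pi]
    h_all <- if (!is.null(idx)) {
      glen <- nchar(genome_strs[pi])
      parts <- if (any(lens <= glen)) .scan_seeded(idx, genome_strs[pi])
               else list()
      out <- do.call(rbind, c(list(cbind(spacer = character(0),
                                         .empty_hits())), parts))
      # seeds can propose placements for spacers longer than the genome;
      # .scan_seeded already bounds candidates to the genome, so no
      # further length filter is needed
      out
    } else {
      scan_genome_batch(useq, genome_strs[pi], k)
    }
    if (nrow(h_all) == 0L) next
    for (s in unique(h_all$spacer)) {
      h <- h_all[h_all$spacer == s, , drop = FALSE]
      h$spacer <- NULL
      copies <- sp[sp$sequence == useq[[s]], , drop = FALSE]
      # every stored copy of the sequence yields its own hit record
      expand <- copies[rep(seq_len(nrow(copies)), each = nrow(h)), ,
                       drop = FALSE]
      hh <- h[rep(seq_len(nrow(h)), times = nrow(copies)), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        spacer_id = spacer_fasta_id(expand),
        organism_accession = expand$organism_accession,
        genus_taxon = expand$genus_taxon,
        locus_id = expand$locus_id,
        position_in_locus = expand$position_in_locus,
        locus_length = expand$locus_length,
        spacer_length = expand$spacer_length,
        phage_id = pid,
        hh,
        evalue = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_hit_table <- function() {
  data.frame(
    spacer_id = character(0), organism_accession = character(0),
    genus_taxon = character(0), locus_id = character(0),
    position_in_locus = integer(0), locus_length = integer(0),
    spacer_length = integer(0), phage_id = character(0),
    phage_start = integer(0), phage_end = integer(0),
    strand = character(0), aligned_length = integer(0),
    raw_mismatches = integer(0), gap_openings = integer(0),
    true_mismatches = integer(0), evalue = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Ingest 12-column tabular alignment output as spacer hits
#'
#' Reads the standard tab-separated 12-column alignment dialect
#' (query id, subject id, percent identity, alignment length, mismatches,
#' gap openings, query start, query end, subject start, subject end,
#' E-value, bit score). Query ids must be spacer FASTA ids
#' (`acc|locus|pos|locus_length`, as written by [export_spacer_fasta()])
#' resolvable against `store`. Per the corrected-mismatch model:
#'
#' * rows with `gap_openings > 0` are discarded (and counted);
#' * `true_mismatches` is computed with [true_mismatches()] from the
#'   stored spacer length;
#' * subject intervals with start > end are normalized to (min, max) with
#'   strand `-`;
#' * the E-value column is retained for the alternative cutoff mode.
#'
#' @param path path to the tabular file
#' @param store a `spacer_store` used to resolve spacer metadata
#' @return hit table as in [scan_store()]; attribute `ingest_report`
#'   tallies discarded gapped rows and unresolvable/unparseable rows
#' @export
parse_alignment_table <- function(path, store) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n_gapped <- 0L
  n_bad <- 0L
  sp <- store$spacers
  sp_key <- spacer_fasta_id(sp)
  rows <- list(.empty_hit_table())
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 12L) {
      warning("skipping alignment row ", ln, ": expected 12 columns, got ",
              length(f), call. = FALSE)
      n_bad <- n_bad + 1L
      next
    }
    i <- match(f[1L], sp_key)
    if (is.na(i)) {
      warning("skipping alignment row ", ln, ": query id '", f[1L],
              "' not found in store", call. = FALSE)
      n_bad <- n_bad + 1L
      next
    }
    aln_len <- as.integer(f[4L]); mism <- as.integer(f[5L])
    gapopen <- as.integer(f[6L])
    sstart <- as.integer(f[9L]); send <- as.integer(f[10L])
    if (anyNA(c(aln_len, mism, gapopen, sstart, send))) {
      warning("skipping alignment row ", ln, ": non-numeric fields",
              call. = FALSE)
      n_bad <- n_bad + 1L
      next
    }
    if (gapopen > 0L) {
      n_gapped <- n_gapped + 1L
      next
    }
    strand <- if (sstart > send) "-" else "+"
    rows[[length(rows) + 1L]] <- data.frame(
      spacer_id = f[1L],
      organism_accession = sp$organism_accession[i],
      genus_taxon = sp$genus_taxon[i],
      locus_id = sp$locus_id[i],
      position_in_locus = sp$position_in_locus[i],
      locus_length = sp$locus_length[i],
      spacer_length = sp$spacer_length[i],
      phage_id = f[2L],
      phage_start = min(sstart, send), phage_end = max(sstart, send),
      strand = strand, aligned_length = aln_len,
      raw_mismatches = mism, gap_openings = 0L,
      true_mismatches = true_mismatches(sp$spacer_length[i], aln_len, mism),
      evalue = suppressWarnings(as.numeric(f[11L])),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ingest_report") <- list(
    n_rows = length(lines), n_hits = nrow(out),
    n_gapped_discarded = n_gapped, n_skipped = n_bad
  )
  out
}

#' Serialize a hit table to the 12-column tabular dialect
#'
#' Inverse of [parse_alignment_table()] for hits produced by
#' [scan_store()] (full-length ungapped placements: query start 1, query
#' end = spacer length; minus-strand hits get subject start > end).
#' Scanner hits carry no E-value; `NA` is written in the E-value column
#' and accepted back by the parser.
#'
#' @param hits hit table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_alignment_table <- function(hits, path) {
  pident <- ifelse(hits$aligned_length > 0,
                   100 * (hits$aligned_length - hits$raw_mismatches) /
                     hits$aligned_length, 0)
  sstart <- ifelse(hits$strand == "-", hits$phage_end, hits$phage_start)
  send <- ifelse(hits$strand == "-", hits$phage_start, hits$phage_end)
  bitscore <- 2 * (hits$aligned_length - hits$raw_mismatches)
  tab <- data.frame(
    qseqid = hits$spacer_id, sseqid = hits$phage_id,
    pident = sprintf("%.2f", pident), length = hits$aligned_length,
    mismatch = hits$raw_mismatches, gapopen = hits$gap_openings,
    qstart = 1L, qend = hits$aligned_length,
    sstart = sstart, send = send,
    evalue = hits$evalue, bitscore = bitscore,
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter 1: alignment-quality cutoff, keeping only the best survivors
#'
#' Mismatch mode drops hits with `true_mismatches > cutoff` and then keeps
#' only the hits at the minimum surviving mismatch count; E-value mode
#' does the same with the E-value column (requiring hits ingested from an
#' external alignment table). Ties at the optimum all survive; the rest of
#' the cascade resolves them.
#'
#' @param hits hit table
#' @param criterion `"mismatch"` (default) or `"evalue"`
#' @param cutoff integer 0-10 for mismatch mode; positive real for
#'   E-value mode
#' @return the surviving subset of `hits`
#' @export
filter_hits <- function(hits, criterion = c("mismatch", "evalue"),
                        cutoff = 2) {
  criterion <- match.arg(criterion)
  if (nrow(hits) == 0L) return(hits)
  if (criterion == "mismatch") {
    if (cutoff < 0) stop("mismatch cutoff must be >= 0")
    keep <- hits$true_mismatches <= cutoff
    if (!any(keep)) return(hits[keep, , drop = FALSE])
    hits <- hits[keep, , drop = FALSE]
    hits[hits$true_mismatches == min(hits$true_mismatches), , drop = FALSE]
  } else {
    if (!is.finite(cutoff) || cutoff <= 0) {
      stop("evalue cutoff must be a positive real")
    }
    if (anyNA(hits$evalue)) {
      stop("E-value filtering requires hits with E-values ",
           "(ingest an external alignment table)")
    }
    keep <- hits$evalue <= cutoff
    if (!any(keep)) return(hits[keep, , drop = FALSE])
    hits <- hits[keep, , drop = FALSE]
    hits[hits$evalue == min(hits$evalue), , drop = FALSE]
  }
}
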