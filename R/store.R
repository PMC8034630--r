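#' Parse CRISPR-array annotations in GFF dialect into spacer records
#'
#' A row describes a spacer when the feature type (third column) is
#' `binding_site`; all other feature types (repeats, whole-array features)
#' are ignored. Per spacer the parser extracts: organism accession
#' (column 1), genome start/end (columns 4-5, 1-based inclusive),
#' orientation (column 7), locus number and spacer index from the `ID=`
#' attribute, and the spacer sequence from the `Note=` attribute
#' (column 9). The `ID` token is `<locus>_<index>`; more generally the last
#' two `_`-separated integer fields of the ID are taken as locus and index.
#'
#' Spacer indices in the ID run in ascending genome coordinate order. For
#' loci annotated on the reverse orientation (`-`) the leader sits at the
#' genome-distal end, so positions are re-indexed as
#' `count - index + 1`; `position_in_locus` is therefore always numbered
#' from the 5' (leader) end, position 1 being the most recently acquired
#' spacer.
#'
#' Malformed rows (wrong column count, missing/unusable `ID=` or `Note=`)
#' are skipped with a warning and tallied in the `parse_report` attribute.
#'
#' @param path path to a GFF file (or a character vector of paths, parsed
#'   and concatenated)
#' @return data.frame of spacer records with columns `organism_accession`,
#'   `locus_id`, `position_in_locus`, `locus_length`, `genome_start`,
#'   `genome_end`, `orientation`, `sequence`, plus attribute
#'   `parse_report` (list with `n_rows`, `n_spacers`, `n_skipped`,
#'   `skip_reasons`)
#' @export
parse_crispr_gff <- function(path) {
  if (length(path) > 1L) {
    parts <- lapply(path, parse_crispr_gff)
    out <- do.call(rbind, parts)
    reports <- lapply(parts, attr, "parse_report")
    attr(out, "parse_report") <- list(
      n_rows = sum(vapply(reports, `[[`, 0L, "n_rows")),
      n_spacers = sum(vapply(reports, `[[`, 0L, "n_spacers")),
      n_skipped = sum(vapply(reports, `[[`, 0L, "n_skipped")),
      skip_reasons = unlist(lapply(reports, `[[`, "skip_reasons"))
    )
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n_rows <- length(lines)
  skip_reasons <- character(0)

  acc <- character(0); start <- integer(0); end <- integer(0)
  strand <- character(0); locus <- integer(0); idx <- integer(0)
  seqs <- character(0)

  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) {
      skip_reasons <- c(skip_reasons,
                        sprintf("line %d: expected 9 columns, got %d", ln, length(f)))
      warning("skipping GFF line ", ln, ": expected 9 columns, got ",
              length(f), call. = FALSE)
      next
    }
    if (f[3L] != "binding_site") next
    attrs <- .parse_gff_attributes(f[9L])
    id <- attrs[["ID"]]
    note <- attrs[["Note"]]
    if (is.null(id) || is.null(note)) {
      missing_what <- paste(c("ID", "Note")[c(is.null(id), is.null(note))],
                            collapse = " and ")
      skip_reasons <- c(skip_reasons,
                        sprintf("line %d: missing %s attribute", ln, missing_what))
      warning("skipping spacer row at line ", ln, ": missing ",
              missing_what, " attribute", call. = FALSE)
      next
    }
    li <- .parse_locus_index(id)
    if (is.null(li)) {
      skip_reasons <- c(skip_reasons,
                        sprintf("line %d: ID '%s' lacks trailing <locus>_<index> integers",
                                ln, id))
      warning("skipping spacer row at line ", ln, ": unusable ID '", id, "'",
              call. = FALSE)
      next
    }
    seq <- toupper(gsub("\\s", "", note))
    if (!grepl("^[ACGTN]+$", seq)) {
      skip_reasons <- c(skip_reasons,
                        sprintf("line %d: Note is not a DNA sequence", ln))
      warning("skipping spacer row at line ", ln,
              ": Note attribute is not a DNA sequence", call. = FALSE)
      next
    }
    acc <- c(acc, f[1L]); start <- c(start, as.integer(f[4L]))
    end <- c(end, as.integer(f[5L]))
    strand <- c(strand, if (f[7L] %in% c("+", "-")) f[7L] else "+")
    locus <- c(locus, li[1L]); idx <- c(idx, li[2L]); seqs <- c(seqs, seq)
  }

  rec <- data.frame(
    organism_accession = acc,
    locus_id = as.character(locus),
    spacer_index = idx,
    genome_start = start,
    genome_end = end,
    orientation = strand,
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  # locus length = number of spacers in the locus; re-index '-' loci so
  # that position 1 is always the leader(5')-proximal spacer
  key <- paste(rec$organism_accession, rec$locus_id, sep = "\r")
  counts <- table(key)
  rec$locus_length <- as.integer(counts[key])
  rec$position_in_locus <- ifelse(
    rec$orientation == "-",
    rec$locus_length - rec$spacer_index + 1L,
    rec$spacer_index
  )
  rec$spacer_index <- NULL
  rec <- rec[, c("organism_accession", "locus_id", "position_in_locus",
                 "locus_length", "genome_start", "genome_end",
                 "orientation", "sequence")]
  attr(rec, "parse_report") <- list(
    n_rows = n_rows,
    n_spacers = nrow(rec),
    n_skipped = length(skip_reasons),
    skip_reasons = skip_reasons
  )
  rec
}

.parse_gff_attributes <- function(s) {
  # tolerant of 'ID = x' spacing variants seen in array-caller output
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  out <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", p))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  out
}

.parse_locus_index <- function(id) {
  toks <- strsplit(id, "_", fixed = TRUE)[[1L]]
  if (length(toks) < 2L) return(NULL)
  tail2 <- utils::tail(toks, 2L)
  if (!all(grepl("^[0-9]+$", tail2))) return(NULL)
  as.integer(tail2)
}

#' Build a queryable spacer store
#'
#' Joins spacer records to the taxonomy through an organism-to-taxon map
#' and organizes them into relational tables (spacers, loci, organisms).
#' Each spacer's host genus is resolved by walking the mapped taxon's
#' lineage to its `genus`-ranked ancestor; organisms without a mapping (or
#' whose lineage has no genus) are retained with `genus_taxon = NA` and
#' excluded from prediction queries.
#'
#' @param records spacer records from [parse_crispr_gff()]
#' @param taxonomy a `spacer_taxonomy` from [load_taxonomy()]
#' @param organism_map two-column data.frame (`organism_accession`,
#'   `taxon_id`) or path to a two-column TSV
#' @return object of class `spacer_store`
#' @export
build_store <- function(records, taxonomy, organism_map) {
  if (is.character(organism_map) && length(organism_map) == 1L) {
    organism_map <- utils::read.table(
      organism_map, sep = "\t", header = FALSE, comment.char = "#",
      col.names = c("organism_accession", "taxon_id"),
      colClasses = "character"
    )
  }
  stopifnot(ncol(organism_map) >= 2L)
  names(organism_map)[1:2] <- c("organism_accession", "taxon_id")
  organism_map$taxon_id <- as.character(organism_map$taxon_id)

  sp <- as.data.frame(records, stringsAsFactors = FALSE)
  taxon <- organism_map$taxon_id[
    match(sp$organism_accession, organism_map$organism_accession)]
  known <- !is.na(taxon) & taxon %in% names(taxonomy$parent)
  genus <- rep(NA_character_, nrow(sp))
  for (t in unique(taxon[known])) {
    genus[known & taxon == t] <- ancestor_at_rank(taxonomy, t, "genus")
  }
  sp$genus_taxon <- genus
  sp$spacer_length <- nchar(sp$sequence)

  loci <- unique(sp[, c("organism_accession", "locus_id", "locus_length",
                        "orientation")])
  rownames(loci) <- NULL
  organisms <- data.frame(
    organism_accession = unique(sp$organism_accession),
    stringsAsFactors = FALSE
  )
  organisms$taxon_id <- organism_map$taxon_id[
    match(organisms$organism_accession, organism_map$organism_accession)]
  organisms$genus_taxon <- genus[
    match(organisms$organism_accession, sp$organism_accession)]

  n_unresolved <- sum(is.na(organisms$genus_taxon))
  if (n_unresolved > 0L) {
    message(n_unresolved, " organism(s) without a resolvable genus; their ",
            "spacers are retained but excluded from prediction queries")
  }
  obj <- list(spacers = sp, loci = loci, organisms = organisms,
              taxonomy = taxonomy)
  class(obj) <- "spacer_store"
  obj
}

#' @export
print.spacer_store <- function(x, ...) {
  cat("<spacer_store> ", nrow(x$spacers), " spacers | ", nrow(x$loci),
      " loci | ", nrow(x$organisms), " organisms (",
      sum(is.na(x$organisms$genus_taxon)), " unresolved)\n", sep = "")
  invisible(x)
}

#' Spacers eligible for host prediction
#'
#' Returns stored spacers with a resolved genus and a sequence length in
#' the given window. The default window of 23-48 nt is the one used to
#' build the prediction FASTA; the narrower 28-43 nt band (which covers
#' 99.2% of observed spacers) is available as a preset via
#' `spacer_length_presets()`.
#'
#' @param store a `spacer_store`
#' @param min_len,max_len inclusive length window
#' @return data.frame subset of the spacer table
#' @export
prediction_spacers <- function(store, min_len = 23L, max_len = 48L) {
  stopifnot(min_len > 0L, min_len <= max_len)
  sp <- store$spacers
  sp[!is.na(sp$genus_taxon) &
       sp$spacer_length >= min_len & sp$spacer_length <= max_len, ,
     drop = FALSE]
}

#' Named spacer-length window presets
#'
#' `prediction` (23-48 nt) is the window used for the export FASTA;
#' `plausible` (28-43 nt) is the band that contains 99.2% of observed
#' spacer lengths, the rest likely being boundary-calling artifacts.
#'
#' @return named list of c(min, max) integer pairs
#' @export
spacer_length_presets <- function() {
  list(prediction = c(23L, 48L), plausible = c(28L, 43L))
}

#' Export stored spacers to FASTA for alignment
#'
#' Writes one entry per stored spacer whose length falls in
#' `[min_len, max_len]` (all spacers are kept in the store regardless).
#' Headers are `|`-delimited
#' `organism_accession|locus_id|position_in_locus|locus_length` so that
#' alignment hits against the exported file are self-describing.
#'
#' @param store a `spacer_store`
#' @param path output FASTA path
#' @param min_len,max_len inclusive length window (default 23-48)
#' @param resolved_only drop spacers without a resolved genus (default
#'   FALSE: the export mirrors the store)
#' @return `path`, invisibly; attribute `n_exported` gives the entry count
#' @export
export_spacer_fasta <- function(store, path, min_len = 23L, max_len = 48L,
                                resolved_only = FALSE) {
  stopifnot(min_len > 0L, min_len <= max_len)
  sp <- store$spacers
  keep <- sp$spacer_length >= min_len & sp$spacer_length <= max_len
  if (resolved_only) keep <- keep & !is.na(sp$genus_taxon)
  sp <- sp[keep, , drop = FALSE]
  if (nrow(sp) == 0L) {
    warning("no spacers in length window [", min_len, ", ", max_len,
            "]; writing empty FASTA", call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(sp$sequence)
  names(seqs) <- spacer_fasta_id(sp)
  Biostrings::writeXStringSet(seqs, filepath = path)
  structure(invisible(path), n_exported = nrow(sp))
}

#' FASTA identifier for a spacer record
#'
#' @param sp data.frame with the spacer identity columns
#' @return character vector `acc|locus|pos|locus_length`
#' @export
spacer_fasta_id <- function(sp) {
  paste(sp$organism_accession, sp$locus_id, sp$position_in_locus,
        sp$locus_length, sep = "|")
}

#' Parse a spacer FASTA produced by [export_spacer_fasta()]
#'
#' Reconstructs spacer records (identity fields + sequence) from the
#' self-describing headers. Genome coordinates are not encoded in the
#' FASTA and come back as NA.
#'
#' @param path FASTA path
#' @return data.frame of spacer records
#' @export
parse_spacer_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    return(data.frame(organism_accession = character(0),
                      locus_id = character(0),
                      position_in_locus = integer(0),
                      locus_length = integer(0),
                      sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) < 4L
  if (any(bad)) {
    stop("FASTA headers not in acc|locus|pos|locus_length form: ",
         paste(utils::head(names(seqs)[bad], 3L), collapse = ", "))
  }
  data.frame(
    organism_accession = vapply(parts, `[[`, "", 1L),
    locus_id = vapply(parts, `[[`, "", 2L),
    position_in_locus = as.integer(vapply(parts, `[[`, "", 3L)),
    locus_length = as.integer(vapply(parts, `[[`, "", 4L)),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
}

#' Per-genus spacer redundancy summary
#'
#' For each resolved genus: the total number of stored spacers, the number
#' of distinct sequences, and the unique/total ratio. Heavily resequenced
#' genera with conserved arrays show ratios far below 1 and would dominate
#' a naive random-hit host assignment, which is why the prediction cascade
#' counts distinct targeted regions rather than raw hits.
#'
#' @param store a `spacer_store`
#' @return data.frame with columns `genus_taxon`, `genus_name`, `total`,
#'   `unique`, `ratio`, sorted by decreasing total
#' @export
summarize_redundancy <- function(store) {
  sp <- store$spacers[!is.na(store$spacers$genus_taxon), , drop = FALSE]
  if (nrow(sp) == 0L) {
    return(data.frame(genus_taxon = character(0), genus_name = character(0),
                      total = integer(0), unique = integer(0),
                      ratio = numeric(0), stringsAsFactors = FALSE))
  }
  total <- tapply(sp$sequence, sp$genus_taxon, length)
  uniq <- tapply(sp$sequence, sp$genus_taxon, function(s) length(unique(s)))
  out <- data.frame(
    genus_taxon = names(total),
    genus_name = unname(store$taxonomy$name[names(total)]),
    total = as.integer(total),
    unique = as.integer(uniq[names(total)]),
    stringsAsFactors = FALSE
  )
  out$ratio <- out$unique / out$total
  out <- out[order(-out$total, out$genus_taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dump a spacer store to CSV tables
#'
#' Writes `spacers.csv`, `loci.csv`, `organisms.csv` and `taxonomy.tsv`
#' into a directory; [read_store()] reloads them.
#'
#' @param store a `spacer_store`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(store$spacers, file.path(dir, "spacers.csv"),
                   row.names = FALSE)
  utils::write.csv(store$loci, file.path(dir, "loci.csv"), row.names = FALSE)
  utils::write.csv(store$organisms, file.path(dir, "organisms.csv"),
                   row.names = FALSE)
  utils::write.table(store$taxonomy$table, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

#' Reload a spacer store dumped by [write_store()]
#'
#' @param dir directory containing the CSV dump
#' @return a `spacer_store`
#' @export
read_store <- function(dir) {
  sp <- utils::read.csv(file.path(dir, "spacers.csv"),
                        colClasses = c(
                          organism_accession = "character",
                          locus_id = "character",
                          sequence = "character",
                          genus_taxon = "character"))
  loci <- utils::read.csv(file.path(dir, "loci.csv"),
                          colClasses = c(organism_accession = "character",
                                         locus_id = "character"))
  org <- utils::read.csv(file.path(dir, "organisms.csv"),
                         colClasses = "character")
  taxonomy <- load_taxonomy(file.path(dir, "taxonomy.tsv"))
  obj <- list(spacers = sp, loci = loci, organisms = org,
              taxonomy = taxonomy)
  class(obj) <- "spacer_store"
  obj
}
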