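# Seed-scoped RNG so generation is reproducible without clobbering the
# caller's random stream.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Introduce point substitutions into a protospacer
#'
#' Exactly `n_mut` positions are changed, each to a different base, so the
#' Hamming distance between input and output is exactly `n_mut`. This
#' models the mutations a phage accumulates after a spacer was acquired
#' (the evolutionary-time premise behind the mismatch filter); the
#' matcher is ungapped, so only substitutions are generated.
#'
#' @param sequence DNA string
#' @param n_mut number of substitutions, `0 <= n_mut <= nchar(sequence)`
#' @return mutated sequence
#' @export
mutate_protospacer <- function(sequence, n_mut) {
  len <- nchar(sequence)
  if (n_mut < 0 || n_mut > len) {
    stop("n_mut must be between 0 and the sequence length")
  }
  if (n_mut == 0L) return(sequence)
  chars <- strsplit(sequence, "")[[1L]]
  pos <- sample.int(len, n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Configuration for the synthetic fixture generator
#'
#' Defines the shape of a ground-truthed benchmark: a balanced taxonomy
#' (orders > families > genera), bacterial organisms carrying CRISPR
#' arrays, and phage genomes with protospacers planted in their true
#' host's arrays. Defaults emulate a desk-scale study: 50 genera, one
#' organism each with 2 loci of 8 spacers, 20 phages of 20-60 kb, spacer
#' lengths 28-43 nt (the band covering 99.2% of real spacers), 3 planted
#' protospacers per phage-host pair, no mutations, planted spacers at the
#' leader end.
#'
#' The `decoy` argument plants a confounder mirroring failure modes seen
#' on real data:
#' * `decoy_redundancy()` — a heavily "resequenced" decoy genus holding
#'   many identical copies of one of the phage's protospacers (ties
#'   filter 1; the region-count filter must decide);
#' * `decoy_recency()` — a sibling genus matching the same number of
#'   regions but only via leader-distal spacers (ties filters 1-2; the
#'   5'-proximity filter must decide);
#' * `decoy_sibling()` — a sibling genus with an identical match profile
#'   (ties filters 1-3; the LCA fallback names the shared family).
#'
#' @param seed RNG seed; the entire fixture is a pure function of the
#'   config
#' @param n_orders,n_families_per_order,n_genera_per_family taxonomy shape
#' @param n_organisms_per_genus organisms (genomes) per genus
#' @param loci_per_organism,spacers_per_locus array shape
#' @param spacer_len_range inclusive spacer length bounds
#' @param n_phages number of phage genomes
#' @param phage_len_range inclusive phage length bounds
#' @param planted_per_pair protospacers planted per (phage, true host)
#' @param mutations substitutions applied to each planted spacer relative
#'   to its protospacer (0-10)
#' @param recency_bias place planted spacers at leader positions 1..k of
#'   locus 1 (TRUE) or at random slots (FALSE)
#' @param decoy NULL or a decoy description (see above)
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_orders = 5L, n_families_per_order = 2L,
                       n_genera_per_family = 5L,
                       n_organisms_per_genus = 1L,
                       loci_per_organism = 2L, spacers_per_locus = 8L,
                       spacer_len_range = c(28L, 43L), n_phages = 20L,
                       phage_len_range = c(20000L, 60000L),
                       planted_per_pair = 3L, mutations = 0L,
                       recency_bias = TRUE, decoy = NULL) {
  cfg <- list(seed = seed, n_orders = n_orders,
              n_families_per_order = n_families_per_order,
              n_genera_per_family = n_genera_per_family,
              n_organisms_per_genus = n_organisms_per_genus,
              loci_per_organism = loci_per_organism,
              spacers_per_locus = spacers_per_locus,
              spacer_len_range = as.integer(spacer_len_range),
              n_phages = n_phages,
              phage_len_range = as.integer(phage_len_range),
              planted_per_pair = planted_per_pair,
              mutations = mutations, recency_bias = recency_bias,
              decoy = decoy)
  counts <- unlist(cfg[c("n_orders", "n_families_per_order",
                         "n_genera_per_family", "n_organisms_per_genus",
                         "loci_per_organism", "spacers_per_locus",
                         "n_phages")])
  if (any(counts < 1L)) stop("all counts must be positive")
  if (mutations < 0L || mutations > spacer_len_range[1L]) {
    stop("mutations must be between 0 and the minimum spacer length")
  }
  capacity <- loci_per_organism * spacers_per_locus
  need <- planted_per_pair +
    if (!is.null(decoy) && decoy$mode %in% c("recency", "sibling"))
      planted_per_pair else 0L
  if (planted_per_pair > capacity) {
    stop("infeasible config: ", planted_per_pair,
         " planted spacers exceed locus capacity ", capacity)
  }
  if (need > capacity) {
    stop("infeasible config: planted + decoy copies (", need,
         ") exceed locus capacity ", capacity)
  }
  n_pairs <- n_orders * n_families_per_order *
    (n_genera_per_family %/% 2L)
  if (n_phages > n_pairs) {
    stop("infeasible config: ", n_phages, " phages need ", n_phages,
         " host/decoy genus pairs but the taxonomy provides ", n_pairs)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param duplication identical decoy copies planted per phage
#' @export
decoy_redundancy <- function(duplication = 12L) {
  list(mode = "redundancy", duplication = as.integer(duplication))
}

#' @rdname sim_config
#' @export
decoy_recency <- function() list(mode = "recency")

#' @rdname sim_config
#' @export
decoy_sibling <- function() list(mode = "sibling")

#' Named scenario presets for the synthetic benchmark
#'
#' `"clean"`: no confounders, filter 1 decides everything. The decoy
#' scenarios each make a later filter the constructed discriminator:
#' `"redundancy"` (filter 2), `"recency"` (filter 3), `"sibling"`
#' (filter 4).
#'
#' @param scenario scenario name
#' @param seed RNG seed
#' @param ... overrides passed to [sim_config()]
#' @return a `sim_config`
#' @export
sim_scenario <- function(scenario = c("clean", "redundancy", "recency",
                                      "sibling"), seed = 1L, ...) {
  scenario <- match.arg(scenario)
  args <- switch(scenario,
    clean = list(),
    redundancy = list(decoy = decoy_redundancy(), planted_per_pair = 4L),
    recency = list(decoy = decoy_recency()),
    sibling = list(decoy = decoy_sibling())
  )
  do.call(sim_config, utils::modifyList(c(list(seed = seed), args),
                                        list(...)))
}

# ---- generator internals ----------------------------------------------

.make_taxonomy_table <- function(cfg) {
  rows <- list(
    data.frame(taxon_id = "1", parent_id = "1", rank = "no rank",
               name = "root", stringsAsFactors = FALSE),
    data.frame(taxon_id = "2", parent_id = "1", rank = "superkingdom",
               name = "Bacteria", stringsAsFactors = FALSE)
  )
  nid <- 2L
  genera <- character(0)
  genus_family <- character(0)
  gi <- 0L
  for (o in seq_len(cfg$n_orders)) {
    nid <- nid + 1L; oid <- as.character(nid)
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_id = oid, parent_id = "2", rank = "order",
      name = sprintf("Order_%02d", o), stringsAsFactors = FALSE)
    for (f in seq_len(cfg$n_families_per_order)) {
      nid <- nid + 1L; fid <- as.character(nid)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = fid, parent_id = oid, rank = "family",
        name = sprintf("Family_%02d_%d", o, f), stringsAsFactors = FALSE)
      for (g in seq_len(cfg$n_genera_per_family)) {
        nid <- nid + 1L; gid <- as.character(nid)
        gi <- gi + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_id = gid, parent_id = fid, rank = "genus",
          name = sprintf("Genus_%02d", gi), stringsAsFactors = FALSE)
        genera <- c(genera, gid)
        genus_family <- c(genus_family, fid)
      }
    }
  }
  list(table = do.call(rbind, rows), genera = genera,
       genus_family = genus_family)
}

# host/decoy pairing: within each family, genera (1,2), (3,4), ... form
# (host, sibling-decoy) pairs, so a decoy genus is never itself a host
.host_decoy_pairs <- function(cfg, genera) {
  per_fam <- cfg$n_genera_per_family
  n_fam <- cfg$n_orders * cfg$n_families_per_order
  hosts <- character(0); decoys <- character(0)
  for (f in seq_len(n_fam)) {
    base <- (f - 1L) * per_fam
    for (p in seq_len(per_fam %/% 2L)) {
      hosts <- c(hosts, genera[base + 2L * p - 1L])
      decoys <- c(decoys, genera[base + 2L * p])
    }
  }
  list(hosts = hosts, decoys = decoys)
}

.sample_intervals <- function(genome_len, lens) {
  # non-overlapping random intervals; genomes are far longer than the
  # summed spacer lengths so rejection sampling terminates immediately
  placed <- matrix(integer(0), ncol = 2L)
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    for (try in 1:1000) {
      s <- sample.int(genome_len - lens[i] + 1L, 1L)
      e <- s + lens[i] - 1L
      if (nrow(placed) == 0L ||
          all(e < placed[, 1L] | s > placed[, 2L])) {
        placed <- rbind(placed, c(s, e))
        out[[i]] <- c(s, e)
        break
      }
    }
    if (is.null(out[[i]])) stop("could not place non-overlapping intervals")
  }
  out
}

#' Generate a ground-truthed synthetic fixture set
#'
#' Emits, under `dir`: `taxonomy.tsv`, `organism_map.tsv`, one GFF of
#' CRISPR-array annotations per organism under `gff/`, `phages.fasta`,
#' `truth.tsv` (phage to true host genus taxon), and `ledger.csv`
#' recording every planted spacer copy (phage, role, genus, organism,
#' locus, leader position, mutation count, protospacer interval, strand,
#' sequence). The ledger is a complete oracle: on a background of i.i.d.
#' uniform random sequence, every hit the matcher should report at the
#' configured mutation load is derivable from it.
#'
#' Generation is a pure function of the config (seed included): the same
#' config yields byte-identical files.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created; contents overwritten)
#' @return invisibly, a list with `dir`, file `paths`, the `config`, the
#'   planted-spacer `ledger`, the `truth` table, and the genus ids used
#'   as `hosts` and `decoys`
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(file.path(dir, "gff"), showWarnings = FALSE, recursive = TRUE)
  .with_seed(cfg$seed, {
    tax <- .make_taxonomy_table(cfg)
    pairs <- .host_decoy_pairs(cfg, tax$genera)

    # organisms per genus
    org <- data.frame(
      organism_accession = character(0), genus_taxon = character(0),
      stringsAsFactors = FALSE)
    for (i in seq_along(tax$genera)) {
      for (j in seq_len(cfg$n_organisms_per_genus)) {
        org <- rbind(org, data.frame(
          organism_accession = sprintf("ACC_%03d_%d", i, j),
          genus_taxon = tax$genera[i], stringsAsFactors = FALSE))
      }
    }

    # phages
    plen <- sample(cfg$phage_len_range[1L]:cfg$phage_len_range[2L],
                   cfg$n_phages, replace = TRUE)
    phage_ids <- sprintf("phage_%03d", seq_len(cfg$n_phages))
    phage_seq <- vapply(plen, .random_dna, "")
    names(phage_seq) <- phage_ids

    hosts <- pairs$hosts[seq_len(cfg$n_phages)]
    sib_decoys <- pairs$decoys[seq_len(cfg$n_phages)]

    # redundancy decoy: a dedicated non-host genus with enough organisms
    red_mode <- !is.null(cfg$decoy) && cfg$decoy$mode == "redundancy"
    sib_mode <- !is.null(cfg$decoy) &&
      cfg$decoy$mode %in% c("recency", "sibling")
    capacity <- cfg$loci_per_organism * cfg$spacers_per_locus
    if (red_mode) {
      red_genus <- setdiff(tax$genera, c(hosts, sib_decoys))[1L]
      n_red_org <- ceiling(cfg$n_phages * cfg$decoy$duplication / capacity)
      red_orgs <- sprintf("ACC_RED_%d", seq_len(n_red_org))
      org <- rbind(org, data.frame(
        organism_accession = red_orgs, genus_taxon = red_genus,
        stringsAsFactors = FALSE))
    }

    # array contents: background spacers everywhere, planted slots
    # overridden below. arrays[[acc]][[locus]] is a character vector
    # indexed by leader-relative position.
    arrays <- list()
    for (a in org$organism_accession) {
      arrays[[a]] <- lapply(seq_len(cfg$loci_per_organism), function(l) {
        lens <- sample(cfg$spacer_len_range[1L]:cfg$spacer_len_range[2L],
                       cfg$spacers_per_locus, replace = TRUE)
        vapply(lens, .random_dna, "")
      })
    }

    org_of_genus <- function(g)
      org$organism_accession[org$genus_taxon == g][1L]

    ledger <- list()
    add_ledger <- function(phage, role, genus, acc, locus, pos, mut,
                           s, e, strand, seq) {
      ledger[[length(ledger) + 1L]] <<- data.frame(
        phage_id = phage, role = role, genus_taxon = genus,
        organism_accession = acc, locus_id = as.character(locus),
        position_in_locus = pos, locus_length = cfg$spacers_per_locus,
        mutations = mut, phage_start = s, phage_end = e, strand = strand,
        sequence = seq, stringsAsFactors = FALSE)
    }

    red_slot <- 0L  # running slot index across redundancy-decoy organisms
    for (p in seq_len(cfg$n_phages)) {
      pid <- phage_ids[p]
      k <- cfg$planted_per_pair
      lens <- sample(cfg$spacer_len_range[1L]:cfg$spacer_len_range[2L],
                     k, replace = TRUE)
      ivs <- .sample_intervals(plen[p], lens)
      strands <- sample(c("+", "-"), k, replace = TRUE)
      host_acc <- org_of_genus(hosts[p])
      host_positions <- if (cfg$recency_bias) seq_len(k) else
        sort(sample.int(cfg$spacers_per_locus, k))
      spacers <- character(k)
      for (i in seq_len(k)) {
        proto <- substr(phage_seq[[pid]], ivs[[i]][1L], ivs[[i]][2L])
        if (strands[i] == "-") {
          proto <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(proto)))
        }
        spacers[i] <- mutate_protospacer(proto, cfg$mutations)
        arrays[[host_acc]][[1L]][host_positions[i]] <- spacers[i]
        add_ledger(pid, "host", hosts[p], host_acc, 1L,
                   host_positions[i], cfg$mutations,
                   ivs[[i]][1L], ivs[[i]][2L], strands[i], spacers[i])
      }
      if (red_mode) {
        # many identical copies of the first planted spacer: one region,
        # overwhelming hit count
        for (d in seq_len(cfg$decoy$duplication)) {
          oi <- red_slot %/% capacity + 1L
          within <- red_slot %% capacity
          li <- within %/% cfg$spacers_per_locus + 1L
          pos <- within %% cfg$spacers_per_locus + 1L
          red_slot <- red_slot + 1L
          acc <- sprintf("ACC_RED_%d", oi)
          arrays[[acc]][[li]][pos] <- spacers[1L]
          add_ledger(pid, "decoy", red_genus, acc, li, pos, cfg$mutations,
                     ivs[[1L]][1L], ivs[[1L]][2L], strands[1L], spacers[1L])
        }
      }
      if (sib_mode) {
        dec_acc <- org_of_genus(sib_decoys[p])
        dec_positions <- if (cfg$decoy$mode == "sibling") seq_len(k) else
          seq.int(cfg$spacers_per_locus - k + 1L, cfg$spacers_per_locus)
        for (i in seq_len(k)) {
          arrays[[dec_acc]][[1L]][dec_positions[i]] <- spacers[i]
          add_ledger(pid, "decoy", sib_decoys[p], dec_acc, 1L,
                     dec_positions[i], cfg$mutations,
                     ivs[[i]][1L], ivs[[i]][2L], strands[i], spacers[i])
        }
      }
    }

    # ---- emit files ----
    paths <- list(
      taxonomy = file.path(dir, "taxonomy.tsv"),
      organism_map = file.path(dir, "organism_map.tsv"),
      gff_dir = file.path(dir, "gff"),
      phages = file.path(dir, "phages.fasta"),
      truth = file.path(dir, "truth.tsv"),
      ledger = file.path(dir, "ledger.csv")
    )
    utils::write.table(tax$table, paths$taxonomy, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(org, paths$organism_map, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

    for (a in org$organism_accession) {
      lines <- character(0)
      offset <- 1000L
      for (l in seq_along(arrays[[a]])) {
        spc <- arrays[[a]][[l]]
        n <- length(spc)
        strand <- if (l %% 2L == 1L) "+" else "-"
        cur <- offset
        for (i in seq_len(n)) {
          # genome order index i maps to leader position: identity on
          # '+' loci, reversed on '-' loci (leader at the distal end)
          pos <- if (strand == "+") i else n - i + 1L
          seq <- spc[pos]
          e <- cur + nchar(seq) - 1L
          lines <- c(lines, paste(
            a, "crispr_sim", "binding_site", cur, e, nchar(seq), strand,
            ".", sprintf("ID=%d_%d;Note=%s", l, i, seq), sep = "\t"))
          cur <- e + 31L  # 30-nt repeat between spacers
        }
        offset <- cur + 500L
      }
      writeLines(lines, file.path(paths$gff_dir, paste0(a, ".gff")))
    }

    phage_set <- Biostrings::DNAStringSet(phage_seq)
    Biostrings::writeXStringSet(phage_set, filepath = paths$phages)

    truth <- data.frame(phage_id = phage_ids, taxon_id = hosts,
                        stringsAsFactors = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

    ledger_df <- do.call(rbind, ledger)
    utils::write.csv(ledger_df, paths$ledger, row.names = FALSE)

    invisible(list(dir = dir, paths = paths, config = cfg,
                   ledger = ledger_df, truth = truth, hosts = hosts,
                   sibling_decoys = if (sib_mode) sib_decoys else NULL,
                   redundancy_decoy = if (red_mode) red_genus else NULL))
  })
}

#' Load a simulated fixture set through the package parsers
#'
#' Convenience wrapper: parses the taxonomy, all per-organism GFF files
#' and the organism map of a [simulate_dataset()] output directory into a
#' ready-to-use spacer store, and reads the phage genomes and truth map.
#'
#' @param dir fixture directory
#' @return list with `store`, `taxonomy`, `phages` (named
#'   `DNAStringSet`), `truth` (data.frame), `ledger` (data.frame)
#' @export
load_fixture <- function(dir) {
  taxonomy <- load_taxonomy(file.path(dir, "taxonomy.tsv"))
  gffs <- sort(list.files(file.path(dir, "gff"), pattern = "\\.gff$",
                          full.names = TRUE))
  records <- parse_crispr_gff(gffs)
  store <- build_store(records, taxonomy,
                       file.path(dir, "organism_map.tsv"))
  phages <- Biostrings::readDNAStringSet(file.path(dir, "phages.fasta"))
  names(phages) <- sub("\\s.*$", "", names(phages))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             col.names = c("phage_id", "taxon_id"),
                             colClasses = "character")
  ledger <- utils::read.csv(file.path(dir, "ledger.csv"),
                            colClasses = c(phage_id = "character",
                                           genus_taxon = "character",
                                           organism_accession = "character",
                                           locus_id = "character",
                                           sequence = "character"))
  list(store = store, taxonomy = taxonomy, phages = phages, truth = truth,
       ledger = ledger)
}
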