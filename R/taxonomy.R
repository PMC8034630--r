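#' Canonical taxonomic rank order
#'
#' Ranks ordered from shallowest (closest to the root) to deepest (most
#' specific). Used to decide which of two ranks is "deeper" when computing
#' precision at a rank and when reporting the rank of a lowest common
#' ancestor. "no rank" nodes are transparent: they inherit the depth of
#' their nearest ranked ancestor.
#'
#' @return Character vector of rank labels, shallow to deep.
#' @export
canonical_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "suborder",
    "family", "genus", "species")
}

#' Numeric depth of a rank label
#'
#' Deeper (more specific) ranks get larger numbers; "no rank" and unknown
#' labels get depth 0 (shallower than every canonical rank).
#'
#' @param rank character vector of rank labels
#' @param ranks rank vocabulary, shallow to deep
#' @return integer vector of depths
#' @export
rank_depth <- function(rank, ranks = canonical_ranks()) {
  d <- match(rank, ranks)
  d[is.na(d)] <- 0L
  d
}

#' Load a taxonomy tree from a delimited file
#'
#' Reads a tab-delimited table with one row per node and columns
#' `taxon_id`, `parent_id`, `rank`, `name` (a `#`-prefixed header line is
#' tolerated, as is no header). The root is its own parent. The structure is
#' validated: every non-root parent must exist and parent chains must be
#' acyclic.
#'
#' @param path path to the tab-delimited taxonomy table
#' @param ranks rank vocabulary used for depth comparisons
#' @return an object of class `spacer_taxonomy` supporting [lineage_of()],
#'   [last_common_ancestor()] and [lca_rank()]
#' @export
load_taxonomy <- function(path, ranks = canonical_ranks()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("taxonomy file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 4L
  if (any(bad)) {
    stop("taxonomy rows with fewer than 4 tab-separated fields: lines ",
         paste(which(bad), collapse = ", "))
  }
  tab <- data.frame(
    taxon_id  = vapply(fields, `[[`, "", 1L),
    parent_id = vapply(fields, `[[`, "", 2L),
    rank      = vapply(fields, `[[`, "", 3L),
    name      = vapply(fields, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  taxonomy_from_table(tab, ranks = ranks)
}

#' Build a taxonomy object from a data frame
#'
#' Same validation as [load_taxonomy()] but taking an in-memory table with
#' columns `taxon_id`, `parent_id`, `rank`, `name`.
#'
#' @param tab data frame of taxonomy nodes
#' @param ranks rank vocabulary
#' @return a `spacer_taxonomy` object
#' @export
taxonomy_from_table <- function(tab, ranks = canonical_ranks()) {
  stopifnot(all(c("taxon_id", "parent_id", "rank", "name") %in% names(tab)))
  tab$taxon_id <- as.character(tab$taxon_id)
  tab$parent_id <- as.character(tab$parent_id)
  if (anyDuplicated(tab$taxon_id)) {
    stop("duplicate taxon_id: ",
         paste(unique(tab$taxon_id[duplicated(tab$taxon_id)]), collapse = ", "))
  }
  parent <- stats::setNames(tab$parent_id, tab$taxon_id)
  orphan <- setdiff(tab$parent_id, tab$taxon_id)
  if (length(orphan) > 0L) {
    bad_children <- tab$taxon_id[tab$parent_id %in% orphan]
    stop("parent taxon not present in table for node(s): ",
         paste(bad_children, collapse = ", "),
         " (missing parent id(s): ", paste(orphan, collapse = ", "), ")")
  }
  roots <- tab$taxon_id[tab$taxon_id == tab$parent_id]
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root (self-parent node); found ",
         length(roots))
  }
  # cycle check + depth computation by walking every parent chain
  depth <- stats::setNames(rep(NA_integer_, nrow(tab)), tab$taxon_id)
  depth[roots] <- 0L
  for (id in tab$taxon_id) {
    chain <- character(0)
    cur <- id
    while (is.na(depth[cur])) {
      if (cur %in% chain) {
        stop("cycle detected in taxonomy involving node ", cur)
      }
      chain <- c(chain, cur)
      cur <- parent[[cur]]
    }
    if (length(chain) > 0L) {
      depth[chain] <- depth[cur] + rev(seq_along(chain))
    }
  }
  obj <- list(
    table = tab,
    parent = parent,
    rank = stats::setNames(tab$rank, tab$taxon_id),
    name = stats::setNames(tab$name, tab$taxon_id),
    depth = depth,
    root = roots,
    ranks = ranks
  )
  class(obj) <- "spacer_taxonomy"
  obj
}

#' @export
print.spacer_taxonomy <- function(x, ...) {
  cat("<spacer_taxonomy> ", nrow(x$table), " nodes, root '", x$root,
      "', max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

.check_taxon <- function(taxonomy, taxon_id) {
  missing <- setdiff(as.character(taxon_id), names(taxonomy$parent))
  if (length(missing) > 0L) {
    stop("unknown taxon id(s): ", paste(missing, collapse = ", "))
  }
}

#' Root-first lineage of a taxon
#'
#' @param taxonomy a `spacer_taxonomy`
#' @param taxon_id a single taxon identifier
#' @return character vector of taxon ids ordered root first, ending at
#'   `taxon_id`
#' @export
lineage_of <- function(taxonomy, taxon_id) {
  taxon_id <- as.character(taxon_id)
  stopifnot(length(taxon_id) == 1L)
  .check_taxon(taxonomy, taxon_id)
  out <- character(taxonomy$depth[[taxon_id]] + 1L)
  cur <- taxon_id
  for (i in rev(seq_along(out))) {
    out[i] <- cur
    cur <- taxonomy$parent[[cur]]
  }
  out
}

#' Last common ancestor of a set of taxa
#'
#' The deepest node present in every taxon's root-first lineage.
#' `last_common_ancestor(t, x)` with a single taxon returns that taxon.
#'
#' @param taxonomy a `spacer_taxonomy`
#' @param taxa non-empty vector of taxon ids
#' @return the LCA taxon id (character scalar)
#' @export
last_common_ancestor <- function(taxonomy, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("last_common_ancestor needs a non-empty set of taxa")
  .check_taxon(taxonomy, taxa)
  lin <- lineage_of(taxonomy, taxa[1L])
  for (t in taxa[-1L]) {
    other <- lineage_of(taxonomy, t)
    n <- min(length(lin), length(other))
    same <- lin[seq_len(n)] == other[seq_len(n)]
    # lineages share the root, so at least position 1 matches
    lin <- lin[seq_len(max(which(same)))]
  }
  lin[length(lin)]
}

#' Rank of the last common ancestor of two taxa
#'
#' If the LCA node itself carries "no rank", the rank of its nearest ranked
#' ancestor is reported and the result is flagged via the
#' `from_unranked` attribute. Reported this way, agreement at unnamed
#' intermediate nodes resolves to the next shallower canonical rank.
#'
#' @param taxonomy a `spacer_taxonomy`
#' @param taxon_a,taxon_b taxon ids
#' @return character scalar rank label with attributes `taxon` (the LCA
#'   node id) and `from_unranked` (TRUE when the rank was lifted from an
#'   unranked LCA to its nearest ranked ancestor)
#' @export
lca_rank <- function(taxonomy, taxon_a, taxon_b) {
  lca <- last_common_ancestor(taxonomy, c(taxon_a, taxon_b))
  node <- lca
  flagged <- FALSE
  while (!(taxonomy$rank[[node]] %in% taxonomy$ranks) &&
         node != taxonomy$root) {
    node <- taxonomy$parent[[node]]
    flagged <- TRUE
  }
  rank <- taxonomy$rank[[node]]
  if (!(rank %in% taxonomy$ranks)) rank <- "no rank"  # unranked root
  structure(rank, taxon = lca, from_unranked = flagged)
}

#' Resolve the ancestor of a taxon at a given rank
#'
#' Walks the lineage and returns the ancestor (or the taxon itself) whose
#' rank label equals `rank`, or NA if the lineage has no node at that rank.
#'
#' @param taxonomy a `spacer_taxonomy`
#' @param taxon_id taxon id
#' @param rank rank label to look for
#' @return taxon id at that rank, or NA_character_
#' @export
ancestor_at_rank <- function(taxonomy, taxon_id, rank) {
  lin <- lineage_of(taxonomy, taxon_id)
  hit <- lin[taxonomy$rank[lin] == rank]
  if (length(hit) == 0L) NA_character_ else hit[[length(hit)]]
}

#' Exact-match name to taxon id lookup
#'
#' @param taxonomy a `spacer_taxonomy`
#' @param name character vector of display names
#' @return character vector of taxon ids (NA where not found)
#' @export
taxon_id_by_name <- function(taxonomy, name) {
  idx <- match(name, taxonomy$name)
  out <- names(taxonomy$name)[idx]
  out
}
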