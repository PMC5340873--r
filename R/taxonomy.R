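# Taxonomy tree, lineage operations, and rank-consensus assignment.

# Canonical rank ladder, shallow to deep. no_rank nodes may interleave
# anywhere but never terminate an assignment.
RANK_LADDER <- c("domain", "phylum", "class", "order", "family", "genus",
                 "species")
ALL_RANKS <- c("root", RANK_LADDER, "no_rank")

rank_depth <- function(rank) match(rank, RANK_LADDER)

#' Construct a taxonomy tree from a node table
#'
#' Builds the in-memory taxonomy used throughout the package: a rooted tree
#' of named nodes with canonical ranks (domain through species) plus
#' unranked (\code{no_rank}) internal nodes. Named viruses that are not yet
#' classified in the reference taxonomy carry \code{classified = FALSE};
#' consensus assignments landing on such nodes are reported with status
#' \code{unclassified_virus}.
#'
#' @param nodes data.frame with columns \code{taxid}, \code{parent},
#'   \code{rank}, \code{name} and logical (or 0/1) \code{classified}. The
#'   root node has \code{rank == "root"} and an empty/NA parent.
#' @return An object of class \code{taxonomy_tree}.
#' @examples
#' nodes <- data.frame(
#'   taxid = c("r", "A", "B"), parent = c(NA, "r", "r"),
#'   rank = c("root", "domain", "domain"),
#'   name = c("root", "Archaea", "Bacteria"), classified = TRUE)
#' tr <- taxonomy_tree(nodes)
#' @export
taxonomy_tree <- function(nodes) {
  required <- c("taxid", "parent", "rank", "name", "classified")
  missing <- setdiff(required, names(nodes))
  if (length(missing) > 0)
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "))
  nodes <- data.frame(
    taxid = as.character(nodes$taxid),
    parent = as.character(nodes$parent),
    rank = as.character(nodes$rank),
    name = as.character(nodes$name),
    classified = as.logical(nodes$classified),
    stringsAsFactors = FALSE
  )
  nodes$parent[!is.na(nodes$parent) & nodes$parent == ""] <- NA_character_
  if (anyDuplicated(nodes$taxid))
    stop("duplicate taxid(s): ",
         paste(unique(nodes$taxid[duplicated(nodes$taxid)]), collapse = ", "))
  bad_rank <- setdiff(unique(nodes$rank), ALL_RANKS)
  if (length(bad_rank) > 0)
    stop("unknown rank(s): ", paste(bad_rank, collapse = ", "))
  is_root <- nodes$rank == "root" | is.na(nodes$parent) |
    nodes$parent == nodes$taxid
  if (sum(is_root) != 1L)
    stop("tree must have exactly one root, found ", sum(is_root))
  root <- nodes$taxid[is_root]
  nodes$parent[is_root] <- NA_character_
  orphan <- !is.na(nodes$parent) & !(nodes$parent %in% nodes$taxid)
  if (any(orphan))
    stop("orphan parent(s) for taxid(s): ",
         paste(nodes$taxid[orphan], collapse = ", "))
  rownames(nodes) <- nodes$taxid
  tree <- structure(list(nodes = nodes, root = root),
                    class = "taxonomy_tree")
  # cycle + rank-order check by walking every node to the root
  for (tid in nodes$taxid) {
    seen <- character(0)
    cur <- tid
    prev_depth <- Inf
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop("cycle detected in taxonomy at taxid ", cur)
      seen <- c(seen, cur)
      rk <- nodes[cur, "rank"]
      if (rk %in% RANK_LADDER) {
        d <- rank_depth(rk)
        if (d > prev_depth)
          stop("rank order violated at taxid ", cur,
               " (", rk, " below a deeper rank)")
        prev_depth <- d
      }
      cur <- nodes[cur, "parent"]
    }
  }
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  rk <- table(factor(x$nodes$rank, levels = ALL_RANKS))
  cat("taxonomy_tree:", nrow(x$nodes), "nodes\n")
  cat("  ", paste(sprintf("%s=%d", names(rk)[rk > 0], rk[rk > 0]),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Load a taxonomy tree from a tab-delimited file
#'
#' Expects columns \code{taxid}, \code{parent}, \code{rank}, \code{name},
#' \code{classified} (0/1). Lines starting with \code{#} are comments.
#'
#' @param path path to the taxonomy TSV.
#' @return A \code{taxonomy_tree}.
#' @export
load_taxonomy <- function(path) {
  tab <- read_tsv_checked(path,
                          required = c("taxid", "parent", "rank", "name",
                                       "classified"))
  taxonomy_tree(tab)
}

has_taxid <- function(tree, taxid) taxid %in% tree$nodes$taxid

# Ancestor chain from the node up to (and including) the root, self first.
# Includes no_rank nodes; this is the set used for "lies under" tests.
ancestors_of <- function(tree, taxid) {
  if (!has_taxid(tree, taxid))
    stop("taxid not in tree: ", taxid)
  chain <- character(0)
  cur <- taxid
  while (!is.na(cur)) {
    chain <- c(chain, cur)
    cur <- tree$nodes[cur, "parent"]
  }
  chain
}

empty_lineage <- function() {
  data.frame(rank = character(0), taxid = character(0),
             name = character(0), stringsAsFactors = FALSE)
}

#' Ranked lineage of a taxon
#'
#' Returns the domain-to-leaf path for a taxon as a data.frame of
#' \code{(rank, taxid, name)} rows. Unranked (\code{no_rank}) nodes are
#' omitted from this ranked view but still count for ancestry tests.
#'
#' @param tree a \code{taxonomy_tree}.
#' @param taxid node identifier present in the tree.
#' @return data.frame with columns \code{rank}, \code{taxid}, \code{name},
#'   ordered domain first; zero rows for the root.
#' @export
lineage_of <- function(tree, taxid) {
  chain <- rev(ancestors_of(tree, taxid))  # root first
  keep <- tree$nodes[chain, "rank"] %in% RANK_LADDER
  chain <- chain[keep]
  if (length(chain) == 0) return(empty_lineage())
  data.frame(rank = tree$nodes[chain, "rank"],
             taxid = chain,
             name = tree$nodes[chain, "name"],
             stringsAsFactors = FALSE)
}

# Leading-letter style used in emitted tables: d__Archaea;p__Euryarchaeota;...
lineage_string <- function(lineage) {
  if (nrow(lineage) == 0) return("")
  paste(sprintf("%s__%s", substr(lineage$rank, 1, 1), lineage$name),
        collapse = ";")
}

lineage_domain <- function(lineage) {
  i <- which(lineage$rank == "domain")
  if (length(i) == 0) NA_character_ else lineage$name[i[1]]
}

taxon_assignment <- function(status, lineage, n_genes, n_hits) {
  structure(list(lineage = lineage, status = status,
                 support = list(n_genes_with_hits = n_genes,
                                n_hits_used = n_hits)),
            class = "taxon_assignment")
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat("taxon_assignment [", x$status, "]\n", sep = "")
  if (nrow(x$lineage) > 0)
    cat("  ", lineage_string(x$lineage), "\n", sep = "")
  cat("  genes with hits: ", x$support$n_genes_with_hits,
      "; hits used: ", x$support$n_hits_used, "\n", sep = "")
  invisible(x)
}

#' Significance filter and best-hit reduction per query gene
#'
#' Removes hits above the E-value significance threshold (default
#' \eqn{10^{-5}}) and keeps at most one hit per query gene: the lowest
#' E-value, ties broken by higher bit score and then lexicographically by
#' subject accession. This per-protein reduction is what feeds the
#' rank-consensus step, so "number of hits" equals "number of proteins with
#' a significant hit".
#'
#' @param hits data.frame of homology hits with columns \code{query_gene},
#'   \code{subject}, \code{subject_taxid}, \code{evalue}, \code{bitscore}
#'   (a \code{database} column is carried through if present).
#' @param threshold E-value significance cutoff; hits with
#'   \code{evalue > threshold} are dropped.
#' @return The retained hits ordered by ascending E-value (then descending
#'   bit score, then subject accession).
#' @export
best_hit_per_gene <- function(hits, threshold = 1e-5) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(hits)
  if (any(!is.finite(hits$evalue)) || any(hits$evalue < 0))
    stop("E-values must be finite and non-negative")
  hits <- hits[hits$evalue <= threshold, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$evalue, -hits$bitscore, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_gene), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Resolve hits against the tree. permissive: drop unresolvable subjects
# with a warning instead of erroring.
resolve_hits <- function(hits, tree, permissive = FALSE) {
  ok <- hits$subject_taxid %in% tree$nodes$taxid
  if (!all(ok)) {
    bad <- unique(hits$subject_taxid[!ok])
    if (!permissive)
      stop("subject taxid(s) not in tree: ", paste(bad, collapse = ", "))
    warning("dropping ", sum(!ok), " hit(s) with unresolvable taxid(s): ",
            paste(bad, collapse = ", "))
    hits <- hits[ok, , drop = FALSE]
  }
  hits
}

#' Rank-consensus taxonomic assignment from significant hits
#'
#' Assigns a lineage to the lowest (deepest) taxonomic rank at which there
#' is consensus among the significant hits. A candidate taxon at a rank
#' wins when (a) the two hits with the lowest E-values both lie under it
#' and (b) a strict majority (>50\%) of all hits lie under it; the
#' assignment is the lineage down to the deepest winning rank. A single
#' significant hit contributes its subject's full lineage. With no hits the
#' status is \code{unknown}.
#'
#' Status semantics: \code{classified} when the deepest winning rank is at
#' family or below and the supporting node is classified in the reference
#' taxonomy; \code{unclassified_virus} when that node is flagged as not yet
#' classified; \code{undetermined} when consensus stops above family (the
#' lineage is reported truncated at the deepest winning rank).
#'
#' @param hits significant hits, one per query gene (see
#'   \code{\link{best_hit_per_gene}}).
#' @param tree a \code{taxonomy_tree}.
#' @param truncate_rank deepest rank considered; \code{"species"} for viral
#'   taxonomy, \code{"domain"} for host-domain consensus.
#' @param permissive drop hits with unresolvable taxids (with a warning)
#'   instead of erroring.
#' @return A \code{taxon_assignment}.
#' @export
rank_consensus <- function(hits, tree, truncate_rank = "species",
                           permissive = FALSE) {
  stopifnot(truncate_rank %in% RANK_LADDER)
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (nrow(hits) > 0) hits <- resolve_hits(hits, tree, permissive)
  n <- nrow(hits)
  n_genes <- length(unique(hits$query_gene))
  if (n == 0)
    return(taxon_assignment("unknown", empty_lineage(), 0L, 0L))

  ladder <- RANK_LADDER[seq_len(rank_depth(truncate_rank))]
  truncate_lineage <- function(lin) {
    lin[lin$rank %in% ladder, , drop = FALSE]
  }

  if (n == 1) {
    lin <- truncate_lineage(lineage_of(tree, hits$subject_taxid))
    # deepest supporting node is the subject itself
    status <- single_status(tree, hits$subject_taxid, lin)
    return(taxon_assignment(status, lin, n_genes, 1L))
  }

  ord <- order(hits$evalue, -hits$bitscore, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  anc <- lapply(hits$subject_taxid, function(t) ancestors_of(tree, t))

  winner <- NULL
  for (rk in rev(ladder)) {
    # candidates: taxa at this rank ancestral to the best hit (condition (a)
    # forces any winner to contain the best hit)
    cand <- anc[[1]][tree$nodes[anc[[1]], "rank"] == rk]
    for (tx in cand) {
      under <- vapply(anc, function(a) tx %in% a, logical(1))
      if (under[1] && under[2] && sum(under) > n / 2) {
        winner <- tx
        break
      }
    }
    if (!is.null(winner)) break
  }

  if (is.null(winner))
    return(taxon_assignment("unknown", empty_lineage(), n_genes, n))

  lin <- lineage_of(tree, winner)
  win_rank <- tree$nodes[winner, "rank"]
  status <- if (rank_depth(win_rank) < rank_depth("family")) {
    "undetermined"
  } else if (isFALSE(tree$nodes[winner, "classified"])) {
    "unclassified_virus"
  } else {
    "classified"
  }
  taxon_assignment(status, lin, n_genes, n)
}

# Status for a single-hit assignment: the affiliation of the matching
# subject is used directly, so the subject node itself (even a no_rank
# leaf omitted from the ranked lineage) is the deepest support.
single_status <- function(tree, taxid, lin) {
  if (nrow(lin) == 0) return("unknown")
  if (isFALSE(tree$nodes[taxid, "classified"])) "unclassified_virus"
  else "classified"
}
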