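# Host classification of CRISPR-bearing scaffolds under eligibility
# filters, and domain-share summaries.

#' Validate CRISPR array geometry against scaffold bounds
#'
#' Checks that every annotated array lies within its scaffold and has at
#' least two repeats. Detection itself is consumed from upstream
#' annotation, never recomputed.
#'
#' @param crispr array table (see \code{\link{read_crispr}}).
#' @param scaffolds scaffold table.
#' @return invisibly TRUE; errors describe the offending array.
#' @export
validate_crispr <- function(crispr, scaffolds) {
  idx <- match(crispr$scaffold_id, scaffolds$scaffold_id)
  if (anyNA(idx))
    stop("CRISPR annotation for unknown scaffold id(s): ",
         paste(unique(crispr$scaffold_id[is.na(idx)]), collapse = ", "))
  len <- scaffolds$length[idx]
  bad <- crispr$start < 1 | crispr$end > len | crispr$end <= crispr$start
  if (any(bad))
    stop("CRISPR array out of scaffold bounds on: ",
         paste(crispr$scaffold_id[bad], collapse = ", "))
  if (any(crispr$n_repeats < 2))
    stop("CRISPR array with fewer than 2 repeats")
  invisible(TRUE)
}

#' Host classification of one CRISPR-bearing scaffold
#'
#' Bin-first: a scaffold in a labelled genome bin takes the bin lineage.
#' An unbinned scaffold is eligible for annotation-based classification
#' only when it is at least \code{min_length} bp long and carries at least
#' \code{min_genes} annotated genes; eligible scaffolds get a domain-level
#' consensus over per-gene taxonomic labels (two best-scoring labels plus
#' strict majority, via the same consensus engine used for homology hits).
#' Scaffolds failing either filter are \code{unknown}.
#'
#' @param scaffold one-row data.frame with \code{scaffold_id},
#'   \code{length}, \code{bin_id}.
#' @param crispr array table; the scaffold must carry at least one array.
#' @param bins bin table.
#' @param gene_annotations data.frame with \code{scaffold_id},
#'   \code{gene_id}, \code{taxid} (NA when the gene has no taxonomic
#'   label) and optional \code{score} (higher is better).
#' @param tree a \code{taxonomy_tree}.
#' @param min_length minimum scaffold length (bp) for annotation-based
#'   classification.
#' @param min_genes minimum number of annotated genes.
#' @param is_annotated predicate applied to the scaffold's annotation rows
#'   to count "annotated" genes; default: the gene has a taxonomic label.
#' @return A \code{host_call} (method \code{bin}, \code{consensus_nr} for
#'   the annotation path, or \code{none}).
#' @export
classify_crispr_scaffold <- function(scaffold, crispr, bins,
                                     gene_annotations, tree,
                                     min_length = 2500, min_genes = 3,
                                     is_annotated = function(ann)
                                       !is.na(ann$taxid)) {
  sid <- as.character(scaffold$scaffold_id)
  if (!sid %in% crispr$scaffold_id)
    stop("scaffold ", sid, " carries no CRISPR annotation")
  bid <- scaffold$bin_id
  if (!is.null(bid) && length(bid) == 1 && !is.na(bid)) {
    lin <- bin_lineage(bins, bid, tree)
    if (!is.null(lin) && nrow(lin) > 0) {
      dom <- lineage_domain(lin)
      dom <- if (dom %in% c("Archaea", "Bacteria")) dom else "unknown"
      return(host_call(sid, "bin", lin, dom))
    }
  }
  ann <- gene_annotations[gene_annotations$scaffold_id == sid, ,
                          drop = FALSE]
  n_annotated <- sum(is_annotated(ann))
  if (scaffold$length < min_length || n_annotated < min_genes)
    return(host_call(sid, "none", empty_lineage(), "unknown"))
  lab <- ann[!is.na(ann$taxid), , drop = FALSE]
  if (nrow(lab) == 0)
    return(host_call(sid, "none", empty_lineage(), "unknown"))
  score <- if (is.null(lab$score)) rep(50, nrow(lab)) else
    ifelse(is.na(lab$score), 50, lab$score)
  # labels enter the consensus engine as pseudo-hits ranked by score
  pseudo <- data.frame(query_gene = lab$gene_id,
                       subject = lab$gene_id,
                       subject_taxid = as.character(lab$taxid),
                       evalue = 0, bitscore = score,
                       stringsAsFactors = FALSE)
  asg <- rank_consensus(pseudo, tree, truncate_rank = "domain")
  dom <- lineage_domain(asg$lineage)
  if (!is.na(dom) && dom %in% c("Archaea", "Bacteria"))
    host_call(sid, "consensus_nr", asg$lineage, dom)
  else
    host_call(sid, "none", empty_lineage(), "unknown")
}

#' Host calls for all CRISPR-bearing scaffolds
#'
#' @param scaffolds scaffold table.
#' @inheritParams classify_crispr_scaffold
#' @return data.frame of calls (one row per distinct CRISPR-bearing
#'   scaffold).
#' @export
classify_crispr_scaffolds <- function(scaffolds, crispr, bins,
                                      gene_annotations, tree,
                                      min_length = 2500, min_genes = 3) {
  validate_crispr(crispr, scaffolds)
  ids <- unique(crispr$scaffold_id)
  calls <- lapply(ids, function(sid)
    classify_crispr_scaffold(
      scaffolds[scaffolds$scaffold_id == sid, , drop = FALSE],
      crispr, bins, gene_annotations, tree, min_length, min_genes))
  host_calls_table(calls)
}

#' Domain shares among CRISPR-bearing scaffolds
#'
#' Reports the fraction of CRISPR-bearing scaffolds that could not be
#' classified, and the archaeal and bacterial shares among the classified
#' ones (shares are computed excluding unknowns, so they sum to 100\% when
#' only the two prokaryotic domains occur). A per-taxon table counts the
#' deepest named taxon of each classified call.
#'
#' @param calls data.frame of host calls (from
#'   \code{\link{classify_crispr_scaffolds}}).
#' @return list with \code{unclassified_fraction},
#'   \code{archaeal_share_of_classified},
#'   \code{bacterial_share_of_classified} (percent; shares NA when nothing
#'   was classified) and \code{per_taxon} counts.
#' @export
crispr_domain_summary <- function(calls) {
  n <- nrow(calls)
  if (n == 0)
    return(list(unclassified_fraction = NA_real_,
                archaeal_share_of_classified = NA_real_,
                bacterial_share_of_classified = NA_real_,
                per_taxon = data.frame()))
  unknown <- calls$domain == "unknown"
  classified <- calls[!unknown & calls$domain %in% c("Archaea", "Bacteria"),
                      , drop = FALSE]
  nc <- nrow(classified)
  share <- function(d) if (nc == 0) NA_real_ else
    100 * sum(classified$domain == d) / nc
  if (nc == 0) {
    per_taxon <- data.frame(taxon = character(0),
                            n_scaffolds = integer(0),
                            stringsAsFactors = FALSE)
  } else {
    deepest <- ifelse(nzchar(classified$lineage),
                      sub(".*;.__", "", classified$lineage),
                      classified$domain)
    deepest <- sub("^.__", "", deepest)
    per_taxon <- as.data.frame(table(taxon = deepest),
                               stringsAsFactors = FALSE)
    names(per_taxon) <- c("taxon", "n_scaffolds")
  }
  list(unclassified_fraction = 100 * mean(unknown),
       archaeal_share_of_classified = share("Archaea"),
       bacterial_share_of_classified = share("Bacteria"),
       per_taxon = per_taxon)
}
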