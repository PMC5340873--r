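# Viral-scaffold classification, host inference, and depth-weighted
# community fractions.

#' Parse a VirSorter-style category table
#'
#' Consumes the detector's per-scaffold output (CSV or TSV with columns
#' \code{scaffold_id} and \code{category}). Categories 1-3 mark scaffolds
#' derived from free viruses at decreasing confidence; categories 4-6 mark
#' prophages within host scaffolds. All three confidence levels of each
#' kind are retained.
#'
#' @param path path to the category file.
#' @param sep field separator (\code{","} for the tool's native CSV).
#' @return data.frame with columns \code{scaffold_id},
#'   \code{viral_category}, \code{is_prophage}.
#' @export
parse_virsorter_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("scaffold_id", "category") %in% names(tab)))
    stop("expected columns scaffold_id and category")
  cat_num <- suppressWarnings(as.integer(tab$category))
  bad <- is.na(cat_num) | !(cat_num %in% 1:6)
  if (any(bad)) {
    # +1 for the header line
    stop("unknown category value '", tab$category[which(bad)[1]],
         "' at line ", which(bad)[1] + 1L)
  }
  data.frame(scaffold_id = as.character(tab$scaffold_id),
             viral_category = cat_num,
             is_prophage = cat_num %in% 4:6,
             stringsAsFactors = FALSE)
}

#' Viral taxonomy of a scaffold from viral-reference hits
#'
#' Applies the significance filter and per-gene best-hit reduction to the
#' scaffold's hits against the viral reference set, then assigns the
#' rank-consensus lineage. A scaffold with no significant hits is
#' \code{unknown}.
#'
#' @param scaffold_id scaffold identifier (used to subset \code{hits} when
#'   a \code{scaffold_id} column is present; otherwise all hits are taken
#'   to belong to the scaffold).
#' @param hits homology hits with \code{database == "viral_refseq"}.
#' @param tree a \code{taxonomy_tree}.
#' @param threshold E-value significance cutoff.
#' @return A \code{taxon_assignment}.
#' @export
assign_viral_taxonomy <- function(scaffold_id, hits, tree,
                                  threshold = 1e-5) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (!is.null(hits$database))
    hits <- hits[hits$database == "viral_refseq", , drop = FALSE]
  if (!is.null(hits$scaffold_id))
    hits <- hits[hits$scaffold_id == scaffold_id, , drop = FALSE]
  best <- best_hit_per_gene(hits, threshold)
  rank_consensus(best, tree)
}

host_call <- function(scaffold_id, method, lineage, domain) {
  structure(list(scaffold_id = scaffold_id, method = method,
                 lineage = lineage, domain = domain),
            class = "host_call")
}

#' @export
print.host_call <- function(x, ...) {
  cat("host_call ", x$scaffold_id, ": ", x$domain,
      " [", x$method, "]", sep = "")
  if (nrow(x$lineage) > 0) cat(" ", lineage_string(x$lineage), sep = "")
  cat("\n")
  invisible(x)
}

# Parse "d__Archaea;p__Euryarchaeota;..." into a lineage data.frame.
parse_lineage_string <- function(s, tree = NULL) {
  if (is.na(s) || !nzchar(s)) return(empty_lineage())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  rank_letter <- substr(parts, 1, 1)
  name <- sub("^.__", "", parts)
  rank <- RANK_LADDER[match(rank_letter, substr(RANK_LADDER, 1, 1))]
  keep <- !is.na(rank) & nzchar(name)
  lin <- data.frame(rank = rank[keep], taxid = NA_character_,
                    name = name[keep], stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    idx <- match(lin$name, tree$nodes$name)
    lin$taxid <- tree$nodes$taxid[idx]
  }
  lin
}

bin_lineage <- function(bins, bin_id, tree = NULL) {
  i <- match(bin_id, bins$bin_id)
  if (is.na(i)) return(NULL)
  parse_lineage_string(bins$lineage[i], tree)
}

# Replace viral subjects by their host's domain before domain-level
# consensus; non-mappable viral subjects are dropped with a warning.
substitute_virus_hosts <- function(hits, tree, virus_host_map) {
  if (nrow(hits) == 0) return(hits)
  domain_ids <- tree$nodes$taxid[tree$nodes$rank == "domain"]
  names(domain_ids) <- tree$nodes$name[tree$nodes$rank == "domain"]
  viruses_id <- domain_ids[["Viruses"]]
  is_viral <- vapply(hits$subject_taxid,
                     function(t) viruses_id %in% ancestors_of(tree, t),
                     logical(1))
  if (!any(is_viral)) return(hits)
  host_dom <- virus_host_map[hits$subject_taxid[is_viral]]
  unmapped <- is.na(host_dom) | !(host_dom %in% names(domain_ids))
  if (any(unmapped))
    warning("dropping ", sum(unmapped),
            " viral hit(s) with no host-domain mapping")
  hits$subject_taxid[is_viral] <- unname(domain_ids[host_dom])
  hits <- hits[!(seq_len(nrow(hits)) %in% which(is_viral)[unmapped]), ,
               drop = FALSE]
  hits
}

#' Infer the likely host of a viral scaffold
#'
#' Bin-first rule: a scaffold placed in a genome bin with a taxonomic label
#' takes the bin's lineage (to the lowest level the bin provides) as its
#' likely host. An unbinned scaffold (or one in an unlabelled bin) falls
#' back to domain-level consensus over its best per-gene hits against the
#' broad protein reference: a hit whose subject is itself a virus is first
#' replaced by that virus's host domain, then the two-lowest-E-value plus
#' strict-majority rule is evaluated at domain rank only. With no winning
#' domain but all hits prokaryotic the call is
#' \code{prokaryote_unresolved}; with no usable hits it is \code{unknown}.
#'
#' @param scaffold one-row data.frame (or list) with \code{scaffold_id}
#'   and \code{bin_id}.
#' @param bins bin table (see \code{\link{read_bins}}).
#' @param nr_hits hits with \code{database == "nr"}; subset by
#'   \code{scaffold_id} column when present.
#' @param virus_host_map named character vector mapping viral taxids to
#'   host domain names.
#' @param tree a \code{taxonomy_tree}.
#' @param threshold E-value significance cutoff.
#' @return A \code{host_call} with \code{method} one of \code{bin},
#'   \code{consensus_nr}, \code{none} and \code{domain} one of
#'   \code{Archaea}, \code{Bacteria}, \code{prokaryote_unresolved},
#'   \code{unknown}.
#' @export
infer_host <- function(scaffold, bins, nr_hits, virus_host_map, tree,
                       threshold = 1e-5) {
  sid <- as.character(scaffold$scaffold_id)
  bid <- scaffold$bin_id
  if (!is.null(bid) && length(bid) == 1 && !is.na(bid)) {
    lin <- bin_lineage(bins, bid, tree)
    if (!is.null(lin) && nrow(lin) > 0) {
      dom <- lineage_domain(lin)
      dom <- if (dom %in% c("Archaea", "Bacteria")) dom else "unknown"
      return(host_call(sid, "bin", lin, dom))
    }
  }
  hits <- as.data.frame(nr_hits, stringsAsFactors = FALSE)
  if (!is.null(hits$database))
    hits <- hits[hits$database == "nr", , drop = FALSE]
  if (!is.null(hits$scaffold_id))
    hits <- hits[hits$scaffold_id == sid, , drop = FALSE]
  best <- best_hit_per_gene(hits, threshold)
  best <- substitute_virus_hosts(best, tree, virus_host_map)
  if (nrow(best) == 0)
    return(host_call(sid, "none", empty_lineage(), "unknown"))
  asg <- rank_consensus(best, tree, truncate_rank = "domain")
  dom <- lineage_domain(asg$lineage)
  if (!is.na(dom) && dom %in% c("Archaea", "Bacteria"))
    return(host_call(sid, "consensus_nr", asg$lineage, dom))
  # no winning domain: prokaryote_unresolved iff every hit is prokaryotic
  doms <- vapply(best$subject_taxid, function(t)
    lineage_domain(lineage_of(tree, t)), character(1))
  if (length(doms) > 0 && all(doms %in% c("Archaea", "Bacteria")))
    host_call(sid, "consensus_nr", empty_lineage(), "prokaryote_unresolved")
  else
    host_call(sid, "none", empty_lineage(), "unknown")
}

#' Host calls for a set of scaffolds
#'
#' Vectorized wrapper around \code{\link{infer_host}}.
#'
#' @param scaffolds scaffold table (see \code{\link{read_scaffolds}}).
#' @inheritParams infer_host
#' @return data.frame with one row per scaffold: \code{scaffold_id},
#'   \code{method}, \code{domain}, \code{deepest_rank}, \code{lineage}.
#' @export
infer_hosts <- function(scaffolds, bins, nr_hits, virus_host_map, tree,
                        threshold = 1e-5) {
  calls <- lapply(seq_len(nrow(scaffolds)), function(i)
    infer_host(scaffolds[i, ], bins, nr_hits, virus_host_map, tree,
               threshold))
  host_calls_table(calls)
}

host_calls_table <- function(calls) {
  data.frame(
    scaffold_id = vapply(calls, function(x) x$scaffold_id, ""),
    method = vapply(calls, function(x) x$method, ""),
    domain = vapply(calls, function(x) x$domain, ""),
    deepest_rank = vapply(calls, function(x)
      if (nrow(x$lineage) == 0) NA_character_
      else x$lineage$rank[nrow(x$lineage)], ""),
    lineage = vapply(calls, function(x) lineage_string(x$lineage), ""),
    stringsAsFactors = FALSE
  )
}

#' Agreement between bin-based and consensus-based prophage host calls
#'
#' For prophage scaffolds whose host can be inferred both from a labelled
#' genome bin and from domain-level consensus over broad-reference hits,
#' reports the percentage of scaffolds where the two methods agree on the
#' host domain. Disagreements are resolved in favour of the bin.
#'
#' @param scaffolds scaffold table; prophages are rows with
#'   \code{is_prophage == TRUE}.
#' @inheritParams infer_host
#' @return list with \code{percent_agreement} (NA when no scaffold is
#'   eligible), \code{n}, and \code{resolved_calls} (data.frame with both
#'   calls and the final, bin-resolved domain per eligible scaffold).
#' @export
prophage_host_agreement <- function(scaffolds, bins, nr_hits,
                                    virus_host_map, tree,
                                    threshold = 1e-5) {
  pro <- scaffolds[scaffolds$is_prophage %in% TRUE, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pro))) {
    sc <- pro[i, ]
    if (is.na(sc$bin_id)) next
    blin <- bin_lineage(bins, sc$bin_id, tree)
    if (is.null(blin) || nrow(blin) == 0) next
    bin_dom <- lineage_domain(blin)
    if (!(bin_dom %in% c("Archaea", "Bacteria"))) next
    unbinned <- sc; unbinned$bin_id <- NA_character_
    blast <- infer_host(unbinned, bins, nr_hits, virus_host_map, tree,
                        threshold)
    if (!(blast$domain %in% c("Archaea", "Bacteria"))) next
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_id = sc$scaffold_id, bin_domain = bin_dom,
      blast_domain = blast$domain,
      agree = identical(bin_dom, blast$domain),
      final_domain = bin_dom,   # bin wins on disagreement
      stringsAsFactors = FALSE)
  }
  n <- length(rows)
  if (n == 0)
    return(list(percent_agreement = NA_real_, n = 0L,
                resolved_calls = data.frame()))
  tab <- do.call(rbind, rows)
  list(percent_agreement = 100 * mean(tab$agree), n = n,
       resolved_calls = tab)
}

#' Depth-weighted group fractions over scaffolds
#'
#' Shares of estimated reads per group: each scaffold is weighted by
#' \code{mean_depth * length} (an estimated-read proxy; set
#' \code{mode = "depth_only"} to weight by coverage alone) and group
#' weights are normalized over all scaffolds supplied, so fractions over
#' the full partition (including unknown/unresolved groups) sum to 1.
#'
#' @param scaffolds scaffold table with \code{scaffold_id}, \code{length},
#'   \code{mean_depth}.
#' @param calls data.frame with \code{scaffold_id} and a grouping column.
#' @param group name of the grouping column in \code{calls}.
#' @param mode weighting mode, \code{"depth_x_length"} (default) or
#'   \code{"depth_only"}.
#' @return data.frame of \code{group}, \code{weight}, \code{fraction},
#'   ordered by decreasing fraction.
#' @export
depth_weighted_fractions <- function(scaffolds, calls, group = "domain",
                                     mode = c("depth_x_length",
                                              "depth_only")) {
  mode <- match.arg(mode)
  if (any(scaffolds$length <= 0)) stop("scaffold lengths must be positive")
  idx <- match(calls$scaffold_id, scaffolds$scaffold_id)
  if (anyNA(idx))
    stop("call(s) for scaffold(s) not in table: ",
         paste(calls$scaffold_id[is.na(idx)], collapse = ", "))
  w <- switch(mode,
              depth_x_length = scaffolds$mean_depth[idx] *
                scaffolds$length[idx],
              depth_only = scaffolds$mean_depth[idx])
  g <- as.character(calls[[group]])
  agg <- tapply(w, g, sum)
  total <- sum(w)
  if (total <= 0) stop("total weight is zero")
  out <- data.frame(group = names(agg), weight = as.numeric(agg),
                    fraction = as.numeric(agg) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prevalence of prophage-containing bins per host domain
#'
#' Fraction of archaeal and of bacterial genome bins that contain at least
#' one prophage scaffold. Bins without a domain-level label are excluded
#' with a message.
#'
#' @param bins bin table with \code{bin_id}, \code{lineage},
#'   \code{member_scaffolds}.
#' @param scaffolds scaffold table with \code{is_prophage}.
#' @return list with \code{archaeal_bins_with_prophage} and
#'   \code{bacterial_bins_with_prophage} (percent; NA when the domain has
#'   no bins) and a per-bin detail table.
#' @export
prophage_bin_prevalence <- function(bins, scaffolds) {
  pro_ids <- scaffolds$scaffold_id[scaffolds$is_prophage %in% TRUE]
  dom <- vapply(bins$lineage, function(s)
    lineage_domain(parse_lineage_string(s)) %||% NA_character_,
    character(1))
  keep <- !is.na(dom) & dom %in% c("Archaea", "Bacteria")
  if (any(!keep))
    message("excluding ", sum(!keep), " bin(s) without a domain label")
  has_pro <- vapply(bins$member_scaffolds, function(m)
    any(m %in% pro_ids), logical(1))
  detail <- data.frame(bin_id = bins$bin_id, domain = dom,
                       has_prophage = has_pro,
                       stringsAsFactors = FALSE)[keep, , drop = FALSE]
  pct <- function(d) {
    sub <- detail[detail$domain == d, , drop = FALSE]
    if (nrow(sub) == 0) NA_real_ else 100 * mean(sub$has_prophage)
  }
  list(archaeal_bins_with_prophage = pct("Archaea"),
       bacterial_bins_with_prophage = pct("Bacteria"),
       bins = detail)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
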