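# Readers/writers for the tab-delimited dialects the pipeline consumes.
# UTF-8, tab-delimited, '#' comment lines, header row; missing optional
# fields as empty strings; parsing is locale-independent.

read_tsv_checked <- function(path, required, dup_key = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""),
                           colClasses = NA, check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(dup_key) && anyDuplicated(tab[[dup_key]]))
    stop("duplicate ", dup_key, " value(s) in ", path, ": ",
         paste(unique(tab[[dup_key]][duplicated(tab[[dup_key]])]),
               collapse = ", "))
  tab
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a homology-hit table
#'
#' BLAST-tabular-like file with one row per query-gene/subject match.
#' Required columns: \code{query_gene}, \code{subject},
#' \code{subject_taxid}, \code{evalue}, \code{bitscore}, \code{database}
#' (one of \code{viral_refseq}, \code{nr}). Scientific-notation E-values
#' are parsed numerically. Rows with non-numeric E-value or bit score are
#' dropped and counted in a warning.
#'
#' @param path path to the hits TSV.
#' @return data.frame of typed hits.
#' @export
read_hits <- function(path) {
  tab <- read_tsv_checked(path, required = c("query_gene", "subject",
                                             "subject_taxid", "evalue",
                                             "bitscore", "database"))
  tab$query_gene <- as.character(tab$query_gene)
  tab$subject <- as.character(tab$subject)
  tab$subject_taxid <- as.character(tab$subject_taxid)
  ev <- suppressWarnings(as.numeric(tab$evalue))
  bs <- suppressWarnings(as.numeric(tab$bitscore))
  bad <- is.na(ev) | is.na(bs)
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed hit row(s) in ", path)
    tab <- tab[!bad, , drop = FALSE]
    ev <- ev[!bad]; bs <- bs[!bad]
  }
  tab$evalue <- ev
  tab$bitscore <- bs
  bad_db <- !tab$database %in% c("viral_refseq", "nr")
  if (any(bad_db))
    stop("unknown database label(s): ",
         paste(unique(tab$database[bad_db]), collapse = ", "))
  rownames(tab) <- NULL
  tab
}

#' @rdname read_hits
#' @param hits data.frame of hits to write.
#' @export
write_hits <- function(hits, path) write_tsv(hits, path)

#' Read a scaffold metadata table
#'
#' Required columns: \code{scaffold_id}, \code{sample_id}, \code{length},
#' \code{mean_depth}; optional \code{bin_id}, \code{viral_category}.
#' Scaffold ids must be unique; lengths must be positive.
#'
#' @param path path to the scaffold TSV.
#' @return data.frame with a derived logical \code{is_prophage} column
#'   (viral categories 4-6).
#' @export
read_scaffolds <- function(path) {
  tab <- read_tsv_checked(path,
                          required = c("scaffold_id", "sample_id", "length",
                                       "mean_depth"),
                          dup_key = "scaffold_id")
  tab$scaffold_id <- as.character(tab$scaffold_id)
  tab$length <- as.numeric(tab$length)
  tab$mean_depth <- as.numeric(tab$mean_depth)
  if (any(!is.finite(tab$length) | tab$length <= 0))
    stop("scaffold lengths must be positive")
  if (any(!is.finite(tab$mean_depth) | tab$mean_depth < 0))
    stop("scaffold mean depths must be non-negative")
  if (is.null(tab$bin_id)) tab$bin_id <- NA_character_
  tab$bin_id <- as.character(tab$bin_id)
  if (is.null(tab$viral_category)) tab$viral_category <- NA_integer_
  tab$viral_category <- as.integer(tab$viral_category)
  known <- is.na(tab$viral_category) | tab$viral_category %in% 1:6
  if (!all(known))
    stop("viral_category outside 1-6 for scaffold(s): ",
         paste(tab$scaffold_id[!known], collapse = ", "))
  tab$is_prophage <- !is.na(tab$viral_category) & tab$viral_category %in% 4:6
  tab
}

#' @rdname read_scaffolds
#' @param scaffolds data.frame of scaffolds to write.
#' @export
write_scaffolds <- function(scaffolds, path) write_tsv(scaffolds, path)

#' Read a gene-coordinate table
#'
#' Required columns: \code{gene_id}, \code{scaffold_id}, \code{start},
#' \code{end}; optional \code{strand}.
#'
#' @param path path to the gene TSV.
#' @return data.frame of genes.
#' @export
read_genes <- function(path) {
  tab <- read_tsv_checked(path, required = c("gene_id", "scaffold_id",
                                             "start", "end"),
                          dup_key = "gene_id")
  tab$gene_id <- as.character(tab$gene_id)
  tab$scaffold_id <- as.character(tab$scaffold_id)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab
}

#' Read a genome-bin table
#'
#' Required columns: \code{bin_id}, \code{lineage} (a
#' \code{d__...;p__...} string, empty allowed), \code{scaffolds}
#' (comma-separated scaffold ids). Each scaffold may belong to at most one
#' bin.
#'
#' @param path path to the bin TSV.
#' @return data.frame of bins with a list-column \code{member_scaffolds}.
#' @export
read_bins <- function(path) {
  tab <- read_tsv_checked(path, required = c("bin_id", "lineage",
                                             "scaffolds"),
                          dup_key = "bin_id")
  tab$bin_id <- as.character(tab$bin_id)
  tab$lineage[is.na(tab$lineage)] <- ""
  members <- strsplit(ifelse(is.na(tab$scaffolds), "",
                             as.character(tab$scaffolds)), ",")
  members <- lapply(members, function(x) x[nzchar(x)])
  all_members <- unlist(members)
  if (anyDuplicated(all_members))
    stop("scaffold(s) in more than one bin: ",
         paste(unique(all_members[duplicated(all_members)]),
               collapse = ", "))
  tab$member_scaffolds <- members
  tab
}

#' @rdname read_bins
#' @param bins data.frame of bins to write.
#' @export
write_bins <- function(bins, path) {
  out <- bins
  if (!is.null(out$member_scaffolds)) {
    out$scaffolds <- vapply(out$member_scaffolds, paste, "", collapse = ",")
    out$member_scaffolds <- NULL
  }
  write_tsv(out, path)
}

#' Read a CRISPR-array annotation table
#'
#' Required columns: \code{scaffold_id}, \code{start}, \code{end},
#' \code{n_repeats}, \code{detector} (CRT, PILER-CR or other). Arrays must
#' have at least two repeats.
#'
#' @param path path to the CRISPR TSV.
#' @return data.frame of arrays.
#' @export
read_crispr <- function(path) {
  tab <- read_tsv_checked(path, required = c("scaffold_id", "start", "end",
                                             "n_repeats", "detector"))
  tab$scaffold_id <- as.character(tab$scaffold_id)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$n_repeats <- as.integer(tab$n_repeats)
  if (any(tab$n_repeats < 2))
    stop("CRISPR arrays must have at least 2 repeats")
  if (any(tab$start < 1 | tab$end <= tab$start))
    stop("invalid CRISPR array interval(s)")
  tab
}

#' @rdname read_crispr
#' @param crispr data.frame of arrays to write.
#' @export
write_crispr <- function(crispr, path) write_tsv(crispr, path)

#' Read a fluid-sample table
#'
#' Mirrors the published sample summary: one row per analysis/sample with
#' columns \code{analysis}, \code{sample_date}, \code{location},
#' \code{dive}, \code{collection_method}, \code{mg_lo}, \code{mg_hi}
#' (mM; equal when the measurement is a single value, NA when not
#' measured), \code{virus_conc}, \code{cell_conc} (units of 1e4 per ml),
#' and logical \code{excluded_from_cells} for filtered-only samples whose
#' cell count is not usable.
#'
#' @param path path to the fluid-sample TSV.
#' @return data.frame of samples with a derived \code{sample_id}.
#' @export
read_fluids <- function(path) {
  tab <- read_tsv_checked(path,
                          required = c("analysis", "sample_date", "location",
                                       "collection_method", "mg_lo", "mg_hi",
                                       "virus_conc", "cell_conc",
                                       "excluded_from_cells"))
  for (col in c("mg_lo", "mg_hi", "virus_conc", "cell_conc"))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  tab$excluded_from_cells <- as.logical(tab$excluded_from_cells)
  neg <- c(tab$virus_conc, tab$cell_conc)
  if (any(neg < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  tab$sample_id <- paste(tab$location, tab$sample_date,
                         tab$collection_method, sep = "_")
  tab
}

#' @rdname read_fluids
#' @param fluids data.frame of samples to write.
#' @export
write_fluids <- function(fluids, path) {
  out <- fluids
  out$sample_id <- NULL
  write_tsv(out, path)
}
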