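# Sequence statistics and interval arithmetic for complete viral genomes
# and prophage excision.

as_dna <- function(seq) {
  if (methods::is(seq, "DNAString")) return(seq)
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1) stop("expected a single sequence")
    return(seq[[1]])
  }
  if (is.character(seq) && length(seq) == 1) {
    if (!nzchar(seq)) stop("empty sequence")
    return(Biostrings::DNAString(seq))
  }
  stop("cannot interpret input as a nucleotide sequence")
}

#' G+C content of a nucleotide sequence
#'
#' Percent G+C among the unambiguous bases: ambiguity codes are excluded
#' from both numerator and denominator.
#'
#' @param seq a character string, \code{DNAString}, or single-element
#'   \code{DNAStringSet}.
#' @return percent G+C (full precision; round to one decimal for
#'   reporting).
#' @export
gc_content <- function(seq) {
  x <- as_dna(seq)
  counts <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0)
    stop("G+C content undefined: no unambiguous A/C/G/T bases")
  100 * (counts[["C"]] + counts[["G"]]) / denom
}

#' @rdname gc_content
#' @export
at_content <- function(seq) {
  x <- as_dna(seq)
  counts <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0) stop("A+T content undefined: no unambiguous bases")
  100 * (counts[["A"]] + counts[["T"]]) / denom
}

#' Extract a genomic interval (1-based, half-open)
#'
#' Coordinates follow the package's fixed convention: 1-based and
#' half-open, \code{[start, end)}, so the extracted length is
#' \code{end - start}. This is the convention under which the published
#' prophage coordinates (116,961 to 144,621) yield the published 27,660 bp
#' length. GenBank feature coordinates are 1-based \emph{inclusive}; use
#' \code{\link{gb_to_halfopen}} to convert.
#'
#' @param seq sequence (as in \code{\link{gc_content}}).
#' @param start first base of the interval (1-based).
#' @param end one past the last base; \code{end - start} bases are
#'   returned.
#' @return a \code{DNAString} of length \code{end - start}.
#' @export
extract_interval <- function(seq, start, end) {
  x <- as_dna(seq)
  L <- length(x)
  if (!(start >= 1 && start < end && end <= L + 1))
    stop("interval [", start, ", ", end, ") out of bounds for length ", L)
  Biostrings::subseq(x, start = start, end = end - 1)
}

#' @rdname extract_interval
#' @export
interval_length <- function(start, end) {
  if (any(end <= start)) stop("interval end must exceed start")
  end - start
}

#' Convert GenBank-style inclusive coordinates to half-open
#'
#' @param start,end 1-based inclusive feature coordinates.
#' @return integer vector \code{c(start, end + 1)} in the half-open
#'   convention.
#' @export
gb_to_halfopen <- function(start, end) c(start, end + 1L)

#' Summary statistics for an annotated genome
#'
#' Length, G+C content, and ORF counts. ORF calling is never performed
#' here: counts come from the supplied annotation table.
#'
#' @param seq the genome sequence.
#' @param annotations data.frame with columns \code{start}, \code{end}
#'   (1-based half-open) and optional \code{product} (empty/NA = no
#'   functional annotation). Zero-row input is allowed.
#' @return list with \code{length_nt}, \code{gc_percent}, \code{n_orfs},
#'   \code{n_annotated}.
#' @export
genome_summary <- function(seq, annotations = NULL) {
  x <- as_dna(seq)
  n_orfs <- 0L
  n_annot <- 0L
  if (!is.null(annotations) && nrow(annotations) > 0) {
    if (any(annotations$start < 1 |
            annotations$end > length(x) + 1 |
            annotations$end <= annotations$start))
      stop("annotation coordinates outside the sequence")
    n_orfs <- nrow(annotations)
    if (!is.null(annotations$product))
      n_annot <- sum(!is.na(annotations$product) &
                       nzchar(annotations$product))
  }
  list(length_nt = length(x), gc_percent = gc_content(x),
       n_orfs = n_orfs, n_annotated = n_annot)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings' wrapped-line-tolerant FASTA I/O.
#'
#' @param path FASTA file path.
#' @return \code{read_fasta}: a \code{DNAStringSet}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_fasta
#' @param seqs named character vector or \code{DNAStringSet}.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
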