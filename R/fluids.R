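# Two end-member mixing model for fluid purity and epifluorescence
# counting statistics.

#' End-member magnesium concentrations for the mixing model
#'
#' Basement fluids start as bottom seawater and lose Mg2+ through
#' water-rock reaction, so dissolved magnesium acts as a conservative
#' tracer of seawater contamination: a sample is modelled as a linear
#' mixture of a seawater end member (high Mg2+) and a crustal-fluid end
#' member (low Mg2+).
#'
#' @param mg_seawater seawater end-member Mg2+ (mM); default the measured
#'   near-bottom seawater value 53.0.
#' @param mg_crustal crustal end-member Mg2+ (mM); default 2.0, an assumed
#'   value for the altered basement fluid (configure for other sites).
#' @return list of class \code{end_members}.
#' @export
end_members <- function(mg_seawater = 53.0, mg_crustal = 2.0) {
  if (!(mg_seawater > mg_crustal && mg_crustal > 0))
    stop("end members require mg_seawater > mg_crustal > 0")
  structure(list(mg_seawater = mg_seawater, mg_crustal = mg_crustal),
            class = "end_members")
}

#' Crustal-fluid fraction of a sample from its Mg2+ concentration
#'
#' Linear two end-member mixing: \eqn{f = (Mg_{sw} - Mg_{sample}) /
#' (Mg_{sw} - Mg_{crustal})}, the fraction of the sample that is pristine
#' crustal fluid (1 = pure crustal fluid, 0 = pure seawater). Values
#' outside the end-member interval are clamped with a warning.
#'
#' @param mg_sample sample Mg2+ concentration(s), mM (vectorized).
#' @param em an \code{\link{end_members}} object.
#' @return fraction(s) in [0, 1].
#' @seealso \code{\link{crustal_percent}} for the integer-percent
#'   reporting convention.
#' @export
crustal_fraction <- function(mg_sample, em = end_members()) {
  if (em$mg_seawater == em$mg_crustal)
    stop("degenerate mixing model: identical end members")
  out_lo <- mg_sample < em$mg_crustal
  out_hi <- mg_sample > em$mg_seawater
  if (any(out_lo | out_hi, na.rm = TRUE)) {
    warning("Mg outside end-member interval; clamping ",
            sum(out_lo | out_hi, na.rm = TRUE), " value(s)")
    mg_sample <- pmin(pmax(mg_sample, em$mg_crustal), em$mg_seawater)
  }
  (em$mg_seawater - mg_sample) / (em$mg_seawater - em$mg_crustal)
}

#' @rdname crustal_fraction
#' @export
crustal_percent <- function(mg_sample, em = end_members()) {
  round(100 * crustal_fraction(mg_sample, em))
}

#' Convert per-field microscopy counts to a concentration
#'
#' Particles (virus-like or cell-like) are collected on a filter and
#' counted in a number of microscope view fields; the concentration is the
#' mean count per field scaled by the ratio of effective filter area to
#' field area and divided by the volume filtered.
#'
#' @param per_field_counts non-negative integer counts, one per view field
#'   (typically 20 fields).
#' @param field_area area of one view field (mm^2).
#' @param effective_filter_area filtration area of the filter (mm^2).
#' @param volume_filtered sample volume passed through the filter (ml).
#' @return particles per ml.
#' @export
field_counts_to_concentration <- function(per_field_counts, field_area,
                                          effective_filter_area,
                                          volume_filtered) {
  if (length(per_field_counts) < 1) stop("need at least one field count")
  if (any(per_field_counts < 0)) stop("field counts must be non-negative")
  if (field_area <= 0 || effective_filter_area <= 0 ||
      volume_filtered <= 0)
    stop("areas and volume must be positive")
  mean(per_field_counts) * (effective_filter_area / field_area) /
    volume_filtered
}

#' Summary statistics for a set of concentrations
#'
#' Mean, sample standard deviation (n-1 denominator), coefficient of
#' variation (SD as a percent of the mean), and range. The companion
#' reporting convention rounds mean and SD to one significant figure and
#' the CV to an integer percent.
#'
#' @param values numeric concentrations (NAs dropped).
#' @return list of class \code{conc_summary}: \code{n}, \code{mean},
#'   \code{sd} (NA for n < 2), \code{cv} (percent), \code{min},
#'   \code{max}.
#' @export
summarize_concentrations <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no values to summarize")
  m <- mean(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  cv <- if (!is.na(s) && m != 0) 100 * s / m else NA_real_
  structure(list(n = n, mean = m, sd = s, cv = cv,
                 min = min(values), max = max(values)),
            class = "conc_summary")
}

#' @export
print.conc_summary <- function(x, ...) {
  cat(sprintf("n=%d mean=%g sd=%g cv=%.1f%% range=[%g, %g]\n",
              x$n, x$mean, if (is.na(x$sd)) NA else x$sd,
              x$cv, x$min, x$max))
  invisible(x)
}

#' Reported (rounded) view of a concentration summary
#'
#' @param x a \code{conc_summary}.
#' @param sig significant figures for mean/SD/min/max (1 for
#'   concentrations, 2 for ratios).
#' @return list with rounded \code{mean}, \code{sd}, \code{min},
#'   \code{max} and integer \code{cv}.
#' @export
report_summary <- function(x, sig = 1) {
  list(n = x$n,
       mean = signif(x$mean, sig),
       sd = if (is.na(x$sd)) NA_real_ else signif(x$sd, sig),
       cv = if (is.na(x$cv)) NA_real_ else round(x$cv),
       min = signif(x$min, sig),
       max = signif(x$max, sig))
}

#' Virus-to-cell ratios across fluid samples
#'
#' Ratios are computed only for samples with both a virus and a usable
#' cell count (\code{excluded_from_cells == FALSE}); a zero cell count
#' skips the sample with a warning. Reporting rounds ratios to two
#' significant figures.
#'
#' @param samples fluid-sample table (see \code{\link{read_fluids}});
#'   only rows with a virus concentration are considered.
#' @return list with \code{ratios} (data.frame of sample_id, ratio) and
#'   \code{summary} (a \code{conc_summary} over the eligible ratios).
#' @export
virus_cell_ratios <- function(samples) {
  eligible <- !is.na(samples$virus_conc) & !is.na(samples$cell_conc) &
    !(samples$excluded_from_cells %in% TRUE)
  zero <- eligible & samples$cell_conc == 0
  if (any(zero)) {
    warning("skipping ", sum(zero), " sample(s) with zero cell count")
    eligible <- eligible & !zero
  }
  sub <- samples[eligible, , drop = FALSE]
  ratios <- data.frame(sample_id = sub$sample_id,
                       ratio = sub$virus_conc / sub$cell_conc,
                       stringsAsFactors = FALSE)
  list(ratios = ratios,
       summary = if (nrow(ratios) > 0)
         summarize_concentrations(ratios$ratio) else NULL)
}

#' Abundance summary of basement fluid samples
#'
#' Convenience wrapper reproducing the published abundance statistics from
#' a fluid-sample table: virus and cell concentration summaries over the
#' basement samples (near-bottom seawater rows are excluded; cell counts
#' from filtered-only samples are excluded), purity from the mixing model,
#' and virus-to-cell ratios.
#'
#' @param samples fluid-sample table.
#' @param em an \code{\link{end_members}} object.
#' @return list with \code{viruses}, \code{cells}, \code{vcr} summaries
#'   and a per-sample \code{purity} table (percent crustal fluid at both
#'   Mg endpoints).
#' @export
fluid_abundance_summary <- function(samples, em = end_members()) {
  basement <- samples[samples$location != "nbSW" &
                        samples$analysis == "EfM", , drop = FALSE]
  viruses <- summarize_concentrations(basement$virus_conc)
  cell_vals <- basement$cell_conc[!(basement$excluded_from_cells %in% TRUE)]
  cells <- summarize_concentrations(cell_vals)
  vcr <- virus_cell_ratios(basement)
  purity <- data.frame(
    sample_id = basement$sample_id,
    crustal_pct_lo = crustal_percent(basement$mg_hi, em),
    crustal_pct_hi = crustal_percent(basement$mg_lo, em),
    stringsAsFactors = FALSE)
  list(viruses = viruses, cells = cells, vcr = vcr, purity = purity)
}
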