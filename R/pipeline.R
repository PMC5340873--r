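# End-to-end orchestration: run every stage on tabular inputs and emit
# report tables mirroring the published figures.

#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for
#' \code{\link{run_all}}. All stages are optional: stages whose inputs are
#' NULL are skipped.
#'
#' @param taxonomy path to the taxonomy TSV (required).
#' @param scaffolds,genes,bins,crispr,gene_annotations,viral_refseq_hits,nr_hits,fluids
#'   input table paths (see the \code{read_*} readers); NULL skips the
#'   dependent stage.
#' @param virus_host_map named character vector mapping viral taxids to
#'   host domains.
#' @param output_dir directory for output tables (created if needed).
#' @param evalue_threshold significance cutoff for homology hits.
#' @param depth_mode weighting mode for fractions
#'   (\code{"depth_x_length"} or \code{"depth_only"}).
#' @param mg_seawater,mg_crustal end-member Mg2+ concentrations (mM).
#' @param seed integer seed recorded in the run manifest.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(taxonomy, scaffolds = NULL, genes = NULL,
                            bins = NULL, crispr = NULL,
                            gene_annotations = NULL,
                            viral_refseq_hits = NULL, nr_hits = NULL,
                            fluids = NULL, virus_host_map = NULL,
                            output_dir = tempfile("basementvirome_run"),
                            evalue_threshold = 1e-5,
                            depth_mode = "depth_x_length",
                            mg_seawater = 53.0, mg_crustal = 2.0,
                            seed = 1) {
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0")
  paths <- list(taxonomy = taxonomy, scaffolds = scaffolds, genes = genes,
                bins = bins, crispr = crispr,
                gene_annotations = gene_annotations,
                viral_refseq_hits = viral_refseq_hits, nr_hits = nr_hits,
                fluids = fluids)
  for (nm in names(paths))
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop("input path for ", nm, " does not exist: ", paths[[nm]])
  structure(c(paths,
              list(virus_host_map = virus_host_map,
                   output_dir = output_dir,
                   evalue_threshold = evalue_threshold,
                   depth_mode = depth_mode,
                   mg_seawater = mg_seawater, mg_crustal = mg_crustal,
                   seed = seed)),
            class = "pipeline_config")
}

#' Depth-weighted fraction report table
#'
#' One row per group (host domain or viral-taxonomy category) with its
#' depth-weighted fraction, in the style of the published host- and
#' viral-taxonomy fraction panels.
#'
#' @param scaffolds scaffold table.
#' @param calls per-scaffold call table with the grouping column.
#' @param group grouping column name.
#' @param mode weighting mode.
#' @param path optional output TSV path.
#' @return the fraction data.frame, invisibly written to \code{path} when
#'   given.
#' @export
report_fractions <- function(scaffolds, calls, group = "domain",
                             mode = "depth_x_length", path = NULL) {
  fr <- depth_weighted_fractions(scaffolds, calls, group = group,
                                 mode = mode)
  fr$n_scaffolds <- as.integer(table(calls[[group]])[fr$group])
  if (!is.null(path)) write_tsv(fr, path)
  fr
}

#' Run the full analysis pipeline
#'
#' Executes every stage whose inputs are configured: viral taxonomy per
#' scaffold (viral-reference consensus), host inference (bin-first with
#' domain consensus fallback), depth-weighted host and viral-taxonomy
#' fraction tables, prophage method agreement and bin prevalence, CRISPR
#' scaffold classification and domain summary, and fluid-sample purity
#' and abundance statistics. Output tables and a run manifest are written
#' under \code{config$output_dir}; any stage error aborts the run.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) a list with all stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  res <- list()
  tree <- load_taxonomy(config$taxonomy)

  scaffolds <- if (!is.null(config$scaffolds))
    read_scaffolds(config$scaffolds) else NULL
  bins <- if (!is.null(config$bins)) read_bins(config$bins) else NULL
  thr <- config$evalue_threshold

  if (!is.null(scaffolds) && !is.null(config$viral_refseq_hits)) {
    vr_hits <- read_hits(config$viral_refseq_hits)
    viral <- scaffolds[!is.na(scaffolds$viral_category), , drop = FALSE]
    asg <- lapply(viral$scaffold_id, function(sid) {
      a <- assign_viral_taxonomy(sid, vr_hits, tree, thr)
      data.frame(scaffold_id = sid, status = a$status,
                 deepest_rank = if (nrow(a$lineage) == 0) NA_character_
                 else a$lineage$rank[nrow(a$lineage)],
                 lineage = lineage_string(a$lineage),
                 stringsAsFactors = FALSE)
    })
    res$viral_taxonomy <- do.call(rbind, asg)
    write_tsv(res$viral_taxonomy, out("viral_taxonomy.tsv"))
    res$viral_taxonomy_fractions <- report_fractions(
      scaffolds, res$viral_taxonomy, group = "status",
      mode = config$depth_mode, path = out("viral_taxonomy_fractions.tsv"))
  }

  if (!is.null(scaffolds) && !is.null(config$nr_hits) &&
      !is.null(bins)) {
    nr_hits <- read_hits(config$nr_hits)
    viral <- scaffolds[!is.na(scaffolds$viral_category), , drop = FALSE]
    res$host_calls <- infer_hosts(viral, bins, nr_hits,
                                  config$virus_host_map, tree, thr)
    write_tsv(res$host_calls, out("host_calls.tsv"))
    res$host_fractions <- report_fractions(
      viral, res$host_calls, group = "domain", mode = config$depth_mode,
      path = out("host_fractions.tsv"))
    res$prophage_agreement <- prophage_host_agreement(
      scaffolds, bins, nr_hits, config$virus_host_map, tree, thr)
    res$prophage_prevalence <- prophage_bin_prevalence(bins, scaffolds)
  }

  if (!is.null(scaffolds) && !is.null(config$crispr) &&
      !is.null(config$gene_annotations) && !is.null(bins)) {
    crispr <- read_crispr(config$crispr)
    ann <- read_tsv_checked(config$gene_annotations,
                            required = c("scaffold_id", "gene_id", "taxid"))
    ann$taxid <- as.character(ann$taxid)
    res$crispr_calls <- classify_crispr_scaffolds(scaffolds, crispr, bins,
                                                  ann, tree)
    write_tsv(res$crispr_calls, out("crispr_calls.tsv"))
    res$crispr_summary <- crispr_domain_summary(res$crispr_calls)
  }

  if (!is.null(config$fluids)) {
    fluids <- read_fluids(config$fluids)
    em <- end_members(config$mg_seawater, config$mg_crustal)
    res$fluids <- fluid_abundance_summary(fluids, em)
    write_tsv(res$fluids$purity, out("fluid_purity.tsv"))
    abund <- data.frame(
      quantity = c("virus_mean", "virus_sd", "virus_cv_pct",
                   "cell_mean", "cell_sd", "cell_cv_pct",
                   "vcr_min", "vcr_max", "vcr_mean", "vcr_n"),
      value = c(res$fluids$viruses$mean, res$fluids$viruses$sd,
                res$fluids$viruses$cv, res$fluids$cells$mean,
                res$fluids$cells$sd, res$fluids$cells$cv,
                res$fluids$vcr$summary$min, res$fluids$vcr$summary$max,
                res$fluids$vcr$summary$mean, res$fluids$vcr$summary$n),
      stringsAsFactors = FALSE)
    write_tsv(abund, out("fluid_abundance.tsv"))
  }

  manifest <- c(
    paste0("package_version\t",
           as.character(utils::packageVersion("basementvirome"))),
    paste0("seed\t", config$seed),
    paste0("evalue_threshold\t", config$evalue_threshold),
    paste0("depth_mode\t", config$depth_mode),
    paste0("mg_seawater\t", config$mg_seawater),
    paste0("mg_crustal\t", config$mg_crustal),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(manifest, out("run_manifest.tsv"))
  invisible(res)
}
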