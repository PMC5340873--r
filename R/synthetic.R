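# Seeded synthetic-community generator with planted ground truth.
# Emulates the statistical structure the pipeline assumes (scaffolds with
# lengths/depths, pure bins, CRISPR arrays, noisy homology hits) so every
# stage is testable without the original metagenome assemblies.

#' Deterministic toy taxonomy for simulations and tests
#'
#' A small rooted taxonomy mirroring the lineages relevant to a
#' basement-fluid community: archaeal and bacterial phyla observed in
#' borehole fluids (Archaeoglobi, Bathyarchaeota, marine benthic group E,
#' Thermococci, Aigarchaeota/THSCG; Nitrospirae, Aminicenantes,
#' Chloroflexi, EM3, Acetothermia, Proteobacteria), tailed-virus families
#' under Caudovirales, unclassified archaeal tailed (halovirus-like) and
#' fusiform viral clades, and the proposed order Megavirales. Also returns
#' the virus-to-host-domain map used by host inference.
#'
#' @return list with \code{tree} (a \code{taxonomy_tree}),
#'   \code{virus_host_map} (named character: viral taxid -> host domain),
#'   and convenience leaf vectors \code{archaeal_leaves},
#'   \code{bacterial_leaves}, \code{virus_leaves}.
#' @export
make_toy_taxonomy <- function() {
  n <- function(taxid, parent, rank, name, classified = TRUE)
    data.frame(taxid = taxid, parent = parent, rank = rank, name = name,
               classified = classified, stringsAsFactors = FALSE)
  nodes <- rbind(
    n("root", NA, "root", "root"),
    n("d_arch", "root", "domain", "Archaea"),
    n("d_bact", "root", "domain", "Bacteria"),
    n("d_euk", "root", "domain", "Eukaryota"),
    n("d_vir", "root", "domain", "Viruses"),
    # archaeal side
    n("p_eury", "d_arch", "phylum", "Euryarchaeota"),
    n("c_archaeoglobi", "p_eury", "class", "Archaeoglobi"),
    n("g_archaeoglobus", "c_archaeoglobi", "genus", "Archaeoglobus"),
    n("c_thermococci", "p_eury", "class", "Thermococci"),
    n("g_thermococcus", "c_thermococci", "genus", "Thermococcus"),
    n("p_bathy", "d_arch", "phylum", "Bathyarchaeota"),
    n("g_bathy1", "p_bathy", "genus", "Bathyarchaeota group 1"),
    n("p_mbge", "d_arch", "phylum", "Marine benthic group E"),
    n("g_mbge1", "p_mbge", "genus", "MBG-E group 1"),
    n("p_aig", "d_arch", "phylum", "Aigarchaeota"),
    n("c_thscg", "p_aig", "class", "THSCG"),
    n("g_thscg1", "c_thscg", "genus", "THSCG group 1"),
    # bacterial side
    n("p_nitrospirae", "d_bact", "phylum", "Nitrospirae"),
    n("g_nitrospira", "p_nitrospirae", "genus", "Nitrospira"),
    n("p_aminicenantes", "d_bact", "phylum", "Aminicenantes"),
    n("g_aminicen1", "p_aminicenantes", "genus", "Aminicenantes group 1"),
    n("p_chloroflexi", "d_bact", "phylum", "Chloroflexi"),
    n("g_chloroflexus", "p_chloroflexi", "genus", "Chloroflexus"),
    n("p_em3", "d_bact", "phylum", "EM3"),
    n("g_em3_1", "p_em3", "genus", "EM3 group 1"),
    n("p_acetothermia", "d_bact", "phylum", "Acetothermia"),
    n("g_acetothermus", "p_acetothermia", "genus", "Acetothermus"),
    n("p_proteo", "d_bact", "phylum", "Proteobacteria"),
    n("g_proteo1", "p_proteo", "genus", "Proteobacteria group 1"),
    # eukaryote leaf (noise source)
    n("p_eukphy", "d_euk", "phylum", "Eukaryote phylum 1"),
    n("g_euk1", "p_eukphy", "genus", "Eukaryote group 1"),
    # viral side: tailed phages
    n("o_caudo", "d_vir", "order", "Caudovirales"),
    n("f_myo", "o_caudo", "family", "Myoviridae"),
    n("s_myo1", "f_myo", "species", "Myovirus BV1"),
    n("s_myo2", "f_myo", "species", "Myovirus BV2"),
    n("f_sipho", "o_caudo", "family", "Siphoviridae"),
    n("s_sipho1", "f_sipho", "species", "Siphovirus BV1"),
    n("f_podo", "o_caudo", "family", "Podoviridae"),
    n("s_podo1", "f_podo", "species", "Podovirus BV1"),
    # unclassified archaeal tailed viruses (haloviruses)
    n("nr_halo", "o_caudo", "no_rank", "unclassified archaeal tailed viruses",
      FALSE),
    n("s_halo1", "nr_halo", "species", "Halovirus HBV1", FALSE),
    n("s_halo2", "nr_halo", "species", "Halovirus HBV2", FALSE),
    # fusiform archaeal viruses
    n("nr_fusi", "d_vir", "no_rank", "archaeal fusiform viruses"),
    n("f_bicauda", "nr_fusi", "family", "Bicaudaviridae"),
    n("s_bicauda1", "f_bicauda", "species", "Bicaudavirus BV1"),
    n("f_fusello", "nr_fusi", "family", "Fuselloviridae"),
    n("s_fusello1", "f_fusello", "species", "Fusellovirus BV1"),
    n("s_fusi_unc1", "nr_fusi", "species", "unclassified fusiform virus 1",
      FALSE),
    # proposed giant-virus order
    n("o_mega", "d_vir", "order", "Megavirales"),
    n("s_mega1", "o_mega", "species", "Megavirus BV1")
  )
  tree <- taxonomy_tree(nodes)
  virus_host_map <- c(
    s_myo1 = "Bacteria", s_myo2 = "Bacteria", s_sipho1 = "Bacteria",
    s_podo1 = "Bacteria",
    s_halo1 = "Archaea", s_halo2 = "Archaea",
    s_bicauda1 = "Archaea", s_fusello1 = "Archaea",
    s_fusi_unc1 = "Archaea",
    s_mega1 = "Eukaryota")
  list(tree = tree, virus_host_map = virus_host_map,
       archaeal_leaves = c("g_archaeoglobus", "g_thermococcus", "g_bathy1",
                           "g_mbge1", "g_thscg1"),
       bacterial_leaves = c("g_nitrospira", "g_aminicen1", "g_chloroflexus",
                            "g_em3_1", "g_acetothermus", "g_proteo1"),
       virus_leaves = names(virus_host_map))
}

#' Write a taxonomy tree to the TSV dialect read by load_taxonomy
#'
#' @param tree a \code{taxonomy_tree}.
#' @param path output path.
#' @export
write_taxonomy <- function(tree, path) {
  out <- tree$nodes
  out$classified <- as.integer(out$classified)
  write_tsv(out, path)
}

#' Configuration for a synthetic basement-fluid community
#'
#' Defaults are the desk-scale study conditions used throughout the
#' package's tests: ~150 viral scaffolds (half of 300), planted host-domain
#' depth fractions of 80/20 Archaea/Bacteria, 19\% of viral scaffolds as
#' prophages, half of all scaffolds binned. Lengths are log-uniform and
#' depths log-normal, as generic assembly-like marginals.
#'
#' @param n_scaffolds number of scaffolds to simulate.
#' @param host_domain_depth_fractions named fractions (must sum to 1) of
#'   viral depth weight per host domain.
#' @param taxon_mix named list (per domain) of leaf-taxon sampling
#'   weights; default mirrors the dominant borehole lineages
#'   (Archaeoglobi-dominated archaea, Nitrospirae-led bacteria).
#' @param length_range log-uniform scaffold length bounds, bp.
#' @param depth_meanlog,depth_sdlog log-normal read-depth parameters.
#' @param binning_rate probability a scaffold is placed in a genome bin.
#' @param viral_rate probability a scaffold is viral.
#' @param prophage_rate probability a viral scaffold is a prophage
#'   (categories 4-6) rather than a free virus (1-3).
#' @param crispr_rate probability a cellular scaffold carries a CRISPR
#'   array.
#' @param genes_per_kb gene density.
#' @param weight_matching when TRUE, viral scaffold depths are rescaled so
#'   the depth-weighted host-domain fractions match
#'   \code{host_domain_depth_fractions} exactly (deterministic targets for
#'   recovery tests).
#' @param seed integer seed fixing all draws.
#' @return list of class \code{community_config}.
#' @export
community_config <- function(n_scaffolds = 300,
                             host_domain_depth_fractions =
                               c(Archaea = 0.80, Bacteria = 0.20),
                             taxon_mix = NULL,
                             length_range = c(2000, 50000),
                             depth_meanlog = log(10), depth_sdlog = 1,
                             binning_rate = 0.5,
                             viral_rate = 0.5,
                             prophage_rate = 0.19,
                             crispr_rate = 0.2,
                             genes_per_kb = 1,
                             weight_matching = FALSE,
                             seed = 1) {
  fr <- host_domain_depth_fractions
  if (abs(sum(fr) - 1) > 1e-9) stop("host domain fractions must sum to 1")
  if (any(fr < 0)) stop("fractions must be non-negative")
  rates <- c(binning_rate, viral_rate, prophage_rate, crispr_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (length_range[1] <= 0 || length_range[2] < length_range[1])
    stop("invalid length range")
  if (is.null(taxon_mix))
    taxon_mix <- list(
      Archaea = c(g_archaeoglobus = 0.55, g_bathy1 = 0.15, g_mbge1 = 0.15,
                  g_thermococcus = 0.10, g_thscg1 = 0.05),
      Bacteria = c(g_nitrospira = 0.40, g_aminicen1 = 0.15,
                   g_chloroflexus = 0.15, g_em3_1 = 0.15,
                   g_acetothermus = 0.15))
  structure(list(n_scaffolds = n_scaffolds,
                 host_domain_depth_fractions = fr,
                 taxon_mix = taxon_mix,
                 length_range = length_range,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 binning_rate = binning_rate, viral_rate = viral_rate,
                 prophage_rate = prophage_rate, crispr_rate = crispr_rate,
                 genes_per_kb = genes_per_kb,
                 weight_matching = weight_matching, seed = seed),
            class = "community_config")
}

#' Noise model for simulated homology hits
#'
#' @param p_correct_lineage probability the best hit of a gene points at
#'   (a taxon under) its scaffold's true lineage.
#' @param p_virus_subject probability a correct best hit is to a virus
#'   whose mapped host is the true domain (exercises the
#'   virus-substitution path of host inference).
#' @param evalue_log10_range log10 bounds for E-value draws (all below the
#'   default significance threshold).
#' @param hits_per_gene candidate hit counts per gene (sampled uniformly).
#' @param p_gene_no_hit probability a gene has no hit at all.
#' @param seed integer seed.
#' @return list of class \code{hit_noise_config}.
#' @export
hit_noise_config <- function(p_correct_lineage = 0.9,
                             p_virus_subject = 0.1,
                             evalue_log10_range = c(-30, -6),
                             hits_per_gene = 1:5,
                             p_gene_no_hit = 0.5,
                             seed = 1) {
  p <- c(p_correct_lineage, p_virus_subject, p_gene_no_hit)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(p_correct_lineage = p_correct_lineage,
                 p_virus_subject = p_virus_subject,
                 evalue_log10_range = evalue_log10_range,
                 hits_per_gene = hits_per_gene,
                 p_gene_no_hit = p_gene_no_hit, seed = seed),
            class = "hit_noise_config")
}

#' Simulate a ground-truthed scaffold community
#'
#' Every scaffold gets a true host lineage (a leaf drawn from the
#' configured per-domain taxon mix), a length, a mean read depth, and
#' viral/prophage/CRISPR flags; binned scaffolds are grouped into
#' taxonomically pure bins (one bin per leaf taxon). Viral scaffolds also
#' get a true virus taxon whose mapped host domain equals the scaffold's
#' host domain. With \code{weight_matching = TRUE} the viral depth weights
#' per host domain match the configured fractions exactly.
#'
#' @param cfg a \code{\link{community_config}}.
#' @param taxonomy result of \code{\link{make_toy_taxonomy}} (or a
#'   compatible list).
#' @return list with data.frames \code{scaffolds}, \code{genes},
#'   \code{bins}, \code{crispr}, \code{truth}, plus the \code{taxonomy}
#'   used.
#' @export
simulate_community <- function(cfg = community_config(),
                               taxonomy = make_toy_taxonomy()) {
  set.seed(cfg$seed)
  tree <- taxonomy$tree
  fr <- cfg$host_domain_depth_fractions
  domains <- names(fr)
  for (d in domains)
    if (fr[d] > 0 && (is.null(cfg$taxon_mix[[d]]) ||
                      length(cfg$taxon_mix[[d]]) == 0))
      stop("no taxon mix configured for domain ", d)
  n <- cfg$n_scaffolds
  sid <- sprintf("scf%04d", seq_len(n))
  dom <- sample(domains, n, replace = TRUE, prob = fr)
  leaf <- vapply(dom, function(d) {
    mix <- cfg$taxon_mix[[d]]
    sample(names(mix), 1, prob = mix)
  }, character(1))
  len <- round(exp(stats::runif(n, log(cfg$length_range[1]),
                                log(cfg$length_range[2]))))
  depth <- stats::rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog)
  is_viral <- stats::runif(n) < cfg$viral_rate
  if (cfg$viral_rate > 0 && !any(is_viral))
    is_viral[1] <- TRUE   # degenerate tiny-n guard
  is_pro <- is_viral & stats::runif(n) < cfg$prophage_rate
  category <- rep(NA_integer_, n)
  category[is_viral & !is_pro] <- sample(1:3, sum(is_viral & !is_pro),
                                         replace = TRUE)
  category[is_pro] <- sample(4:6, sum(is_pro), replace = TRUE)

  # viral taxon consistent with the host domain via the host map
  vh <- taxonomy$virus_host_map
  virus_taxid <- rep(NA_character_, n)
  for (d in domains) {
    pool <- names(vh)[vh == d]
    pick <- is_viral & dom == d
    if (any(pick)) {
      if (length(pool) == 0)
        stop("no virus leaves mapped to domain ", d)
      virus_taxid[pick] <- sample(pool, sum(pick), replace = TRUE)
    }
  }

  # weight matching: rescale viral depths so depth*length domain fractions
  # are exact
  if (cfg$weight_matching) {
    w <- depth * len
    total <- sum(w[is_viral])
    for (d in domains) {
      pick <- is_viral & dom == d
      if (fr[d] > 0 && !any(pick))
        stop("infeasible fractions: no viral scaffold in domain ", d)
      if (any(pick)) {
        s <- fr[d] * total / sum(w[pick])
        depth[pick] <- depth[pick] * s
      }
    }
  }

  # bins: one per leaf taxon, taxonomically pure
  binned <- stats::runif(n) < cfg$binning_rate
  bin_id <- ifelse(binned, paste0("bin_", leaf), NA_character_)
  bin_taxa <- sort(unique(unname(leaf[binned])))
  if (length(bin_taxa) == 0) {
    bins <- data.frame(bin_id = character(0), lineage = character(0),
                       stringsAsFactors = FALSE)
    bins$member_scaffolds <- list()
    bins$scaffolds <- character(0)
  } else {
    bins <- data.frame(
      bin_id = paste0("bin_", bin_taxa),
      lineage = vapply(bin_taxa, function(t)
        lineage_string(lineage_of(tree, t)), ""),
      stringsAsFactors = FALSE)
    bins$member_scaffolds <- lapply(paste0("bin_", bin_taxa), function(b)
      sid[!is.na(bin_id) & bin_id == b])
    bins$scaffolds <- vapply(bins$member_scaffolds, paste, "",
                             collapse = ",")
  }

  scaffolds <- data.frame(
    scaffold_id = sid, sample_id = "SYN1", length = len,
    mean_depth = depth, bin_id = bin_id, viral_category = category,
    is_prophage = !is.na(category) & category %in% 4:6,
    stringsAsFactors = FALSE)

  # genes laid out end to end
  genes <- do.call(rbind, lapply(seq_len(n), function(i) {
    ng <- max(1L, round(len[i] / 1000 * cfg$genes_per_kb))
    width <- len[i] %/% ng
    start <- (seq_len(ng) - 1L) * width + 1L
    end <- pmin(start + width - 1L, len[i])
    data.frame(gene_id = sprintf("%s_g%03d", sid[i], seq_len(ng)),
               scaffold_id = sid[i], start = start, end = end,
               strand = sample(c("+", "-"), ng, replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  # CRISPR arrays on a subset of cellular scaffolds
  has_crispr <- !is_viral & stats::runif(n) < cfg$crispr_rate
  ci <- which(has_crispr)
  crispr <- if (length(ci) == 0) {
    data.frame(scaffold_id = character(0), start = integer(0),
               end = integer(0), n_repeats = integer(0),
               detector = character(0), stringsAsFactors = FALSE)
  } else {
    arr_len <- pmin(len[ci] - 1L, 200L + sample(0:400, length(ci),
                                                replace = TRUE))
    start <- vapply(seq_along(ci), function(k)
      sample(seq_len(max(1L, len[ci[k]] - arr_len[k])), 1), integer(1))
    data.frame(scaffold_id = sid[ci], start = start,
               end = start + arr_len,
               n_repeats = sample(3:20, length(ci), replace = TRUE),
               detector = sample(c("CRT", "PILER-CR"), length(ci),
                                 replace = TRUE),
               stringsAsFactors = FALSE)
  }

  truth <- data.frame(
    scaffold_id = sid, host_domain = dom, host_taxid = leaf,
    is_viral = is_viral, is_prophage = scaffolds$is_prophage,
    has_crispr = has_crispr, virus_taxid = virus_taxid,
    stringsAsFactors = FALSE)

  list(scaffolds = scaffolds, genes = genes, bins = bins, crispr = crispr,
       truth = truth, taxonomy = taxonomy)
}

random_leaf <- function(pool) pool[sample.int(length(pool), 1)]

#' Simulate homology-hit tables and gene annotations for a community
#'
#' Produces (i) viral-reference hits for genes on viral scaffolds, where
#' the best hit points at the scaffold's true virus taxon with probability
#' \code{p_correct_lineage}; (ii) broad-reference ("nr") hits for the same
#' genes, where a correct best hit is the true host leaf, or, with
#' probability \code{p_virus_subject}, a virus mapped to the true host
#' domain; and (iii) per-gene taxonomic annotations for CRISPR-bearing
#' scaffolds. With \code{p_correct_lineage = 1} and
#' \code{p_gene_no_hit = 0}, every gene's best hit lies under its true
#' lineage.
#'
#' @param sim result of \code{\link{simulate_community}}.
#' @param noise a \code{\link{hit_noise_config}}.
#' @return list with data.frames \code{viral_refseq_hits},
#'   \code{nr_hits}, \code{gene_annotations}.
#' @export
simulate_hits <- function(sim, noise = hit_noise_config()) {
  set.seed(noise$seed)
  taxonomy <- sim$taxonomy
  tree <- taxonomy$tree
  vh <- taxonomy$virus_host_map
  truth <- sim$truth
  genes <- sim$genes
  lo <- noise$evalue_log10_range[1]
  hi <- noise$evalue_log10_range[2]

  cell_leaves <- list(Archaea = taxonomy$archaeal_leaves,
                      Bacteria = taxonomy$bacterial_leaves)
  other_pool <- function(d)
    c(unlist(cell_leaves[setdiff(names(cell_leaves), d)],
             use.names = FALSE), "g_euk1")

  draw_evalues <- function(k) sort(10^stats::runif(k, lo, hi))
  bitscore_for <- function(ev) round(60 - 1.5 * log10(ev))

  vr_rows <- list(); nr_rows <- list(); ann_rows <- list()
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    g <- genes[genes$scaffold_id == t$scaffold_id, , drop = FALSE]
    if (t$is_viral) {
      for (j in seq_len(nrow(g))) {
        if (stats::runif(1) < noise$p_gene_no_hit) next
        k <- noise$hits_per_gene[sample.int(length(noise$hits_per_gene), 1)]
        # viral-reference hits
        ev <- draw_evalues(k)
        subj <- character(k)
        for (m in seq_len(k)) {
          correct <- stats::runif(1) < noise$p_correct_lineage
          subj[m] <- if (m == 1 && correct) t$virus_taxid
          else if (correct) {
            pool <- names(vh)[vh == t$host_domain]
            random_leaf(pool)
          } else random_leaf(setdiff(names(vh),
                                     names(vh)[vh == t$host_domain]))
        }
        vr_rows[[length(vr_rows) + 1L]] <- data.frame(
          query_gene = g$gene_id[j], scaffold_id = t$scaffold_id,
          subject = paste0("vr|", subj), subject_taxid = subj,
          evalue = ev, bitscore = bitscore_for(ev),
          database = "viral_refseq", stringsAsFactors = FALSE)
        # nr hits
        ev <- draw_evalues(k)
        subj <- character(k)
        for (m in seq_len(k)) {
          correct <- stats::runif(1) < noise$p_correct_lineage
          subj[m] <- if (correct) {
            if (stats::runif(1) < noise$p_virus_subject) {
              pool <- names(vh)[vh == t$host_domain]
              if (length(pool) == 0) t$host_taxid else random_leaf(pool)
            } else t$host_taxid
          } else random_leaf(other_pool(t$host_domain))
        }
        nr_rows[[length(nr_rows) + 1L]] <- data.frame(
          query_gene = g$gene_id[j], scaffold_id = t$scaffold_id,
          subject = paste0("nr|", subj), subject_taxid = subj,
          evalue = ev, bitscore = bitscore_for(ev),
          database = "nr", stringsAsFactors = FALSE)
      }
    }
    if (t$has_crispr) {
      lab <- character(nrow(g))
      for (j in seq_len(nrow(g))) {
        lab[j] <- if (stats::runif(1) < noise$p_gene_no_hit) NA_character_
        else if (stats::runif(1) < noise$p_correct_lineage) t$host_taxid
        else random_leaf(other_pool(t$host_domain))
      }
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        scaffold_id = t$scaffold_id, gene_id = g$gene_id, taxid = lab,
        score = round(stats::runif(nrow(g), 40, 200)),
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(rows, template) {
    if (length(rows) == 0) template else do.call(rbind, rows)
  }
  hit_template <- data.frame(query_gene = character(0),
                             scaffold_id = character(0),
                             subject = character(0),
                             subject_taxid = character(0),
                             evalue = numeric(0), bitscore = numeric(0),
                             database = character(0),
                             stringsAsFactors = FALSE)
  ann_template <- data.frame(scaffold_id = character(0),
                             gene_id = character(0), taxid = character(0),
                             score = numeric(0), stringsAsFactors = FALSE)
  list(viral_refseq_hits = bind(vr_rows, hit_template),
       nr_hits = bind(nr_rows, hit_template),
       gene_annotations = bind(ann_rows, ann_template))
}

#' Packaged fluid-sample table fixture
#'
#' The published sample summary shipped with the package: the eight
#' basement-fluid virus counts (one of them a filtered-only sample whose
#' cell count is excluded), the seven usable cell counts, the near-bottom
#' seawater reference row, metagenome and electron-microscopy sampling
#' rows, and Mg2+ concentrations as printed.
#'
#' @return data.frame of fluid samples (see \code{\link{read_fluids}}).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1.tsv", package = "basementvirome")
  if (!nzchar(path)) stop("packaged table1.tsv not found")
  read_fluids(path)
}
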