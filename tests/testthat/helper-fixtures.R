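# Shared fixtures and independent oracles for the test suite.

toy <- make_toy_taxonomy()

make_hits <- function(taxids, evalues, genes = NULL,
                      bitscores = NULL, subjects = NULL) {
  n <- length(taxids)
  data.frame(
    query_gene = if (is.null(genes)) sprintf("g%02d", seq_len(n)) else genes,
    subject = if (is.null(subjects)) sprintf("acc%02d", seq_len(n)) else
      subjects,
    subject_taxid = taxids,
    evalue = evalues,
    bitscore = if (is.null(bitscores)) rep(50, n) else bitscores,
    stringsAsFactors = FALSE)
}

# Independent brute-force consensus oracle: test every canonical-rank node
# of the tree for (a) both lowest-E hits under it and (b) strict majority
# of all hits under it; return the deepest passing node (NULL when none).
# Deliberately independent of the ladder walk in rank_consensus.
consensus_oracle <- function(hits, tree, truncate_rank = "species") {
  ord <- order(hits$evalue, -hits$bitscore, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  n <- nrow(hits)
  under <- function(node, taxid) {
    cur <- taxid
    while (!is.na(cur)) {
      if (cur == node) return(TRUE)
      cur <- tree$nodes[cur, "parent"]
    }
    FALSE
  }
  ladder <- c("domain", "phylum", "class", "order", "family", "genus",
              "species")
  max_depth <- match(truncate_rank, ladder)
  best <- NULL
  best_depth <- 0L
  for (node in tree$nodes$taxid) {
    rk <- tree$nodes[node, "rank"]
    d <- match(rk, ladder)
    if (is.na(d) || d > max_depth) next
    flags <- vapply(hits$subject_taxid, function(t) under(node, t),
                    logical(1))
    if (flags[1] && flags[2] && sum(flags) > n / 2 && d > best_depth) {
      best <- node
      best_depth <- d
    }
  }
  best
}

# Random rooted taxonomy of <= n_nodes nodes with canonical rank order.
random_taxonomy <- function(n_nodes = 30) {
  ladder <- c("domain", "phylum", "class", "order", "family", "genus",
              "species")
  nodes <- data.frame(taxid = "root", parent = NA_character_,
                      rank = "root", name = "root", classified = TRUE,
                      stringsAsFactors = FALSE)
  depth_of <- c(root = 0L)
  for (i in seq_len(n_nodes - 1)) {
    repeat {
      parent <- sample(nodes$taxid, 1)
      pd <- depth_of[[parent]]
      if (pd < length(ladder)) break
    }
    # occasionally interleave a no_rank node
    if (runif(1) < 0.15 && pd >= 1) {
      rank <- "no_rank"
      d <- pd
    } else {
      deeper <- (pd + 1):length(ladder)
      d <- deeper[sample.int(length(deeper), 1)]
      rank <- ladder[d]
    }
    tid <- sprintf("n%03d", i)
    nodes <- rbind(nodes, data.frame(
      taxid = tid, parent = parent, rank = rank,
      name = paste0("taxon ", i), classified = runif(1) > 0.2,
      stringsAsFactors = FALSE))
    depth_of[[tid]] <- d
  }
  taxonomy_tree(nodes)
}

random_hitset <- function(tree, n_hits) {
  pool <- setdiff(tree$nodes$taxid, tree$root)
  make_hits(sample(pool, n_hits, replace = TRUE),
            10^runif(n_hits, -20, -6),
            bitscores = round(runif(n_hits, 40, 120)))
}

deepest_taxid <- function(assignment) {
  if (nrow(assignment$lineage) == 0) NULL
  else assignment$lineage$taxid[nrow(assignment$lineage)]
}

# Minimal simulated dataset written to disk for pipeline tests.
write_sim_inputs <- function(dir, cfg = community_config(
                               n_scaffolds = 80, seed = 11,
                               weight_matching = TRUE),
                             noise = hit_noise_config(
                               p_correct_lineage = 1, p_gene_no_hit = 0,
                               p_virus_subject = 0, seed = 11)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_community(cfg)
  ht <- simulate_hits(sim, noise)
  write_taxonomy(toy$tree, file.path(dir, "taxonomy.tsv"))
  write_scaffolds(sim$scaffolds, file.path(dir, "scaffolds.tsv"))
  write_tsv_like <- function(tab, f)
    utils::write.table(tab, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  write_bins(sim$bins, file.path(dir, "bins.tsv"))
  write_crispr(sim$crispr, file.path(dir, "crispr.tsv"))
  write_hits(ht$viral_refseq_hits, file.path(dir, "vr_hits.tsv"))
  write_hits(ht$nr_hits, file.path(dir, "nr_hits.tsv"))
  write_tsv_like(ht$gene_annotations, "gene_annotations.tsv")
  file.copy(system.file("extdata", "table1.tsv",
                        package = "basementvirome"),
            file.path(dir, "table1.tsv"))
  list(dir = dir, sim = sim, hits = ht)
}
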