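test_that("taxonomy loading builds valid trees and rejects broken ones", {
  minimal <- data.frame(taxid = c("r", "A", "B"),
                        parent = c(NA, "r", "r"),
                        rank = c("root", "domain", "domain"),
                        name = c("root", "Archaea", "Bacteria"),
                        classified = TRUE)
  tr <- taxonomy_tree(minimal)
  expect_equal(nrow(tr$nodes), 3)
  expect_equal(sum(tr$nodes$rank == "domain"), 2)

  # orphan parent
  bad <- minimal; bad$parent[2] <- "missing"
  expect_error(taxonomy_tree(bad), "orphan")
  # duplicate taxid
  expect_error(taxonomy_tree(rbind(minimal, minimal[2, ])), "duplicate")
  # cycle
  cyc <- data.frame(taxid = c("r", "x", "y"), parent = c(NA, "y", "x"),
                    rank = c("root", "phylum", "class"),
                    name = c("root", "x", "y"), classified = TRUE)
  expect_error(taxonomy_tree(cyc), "cycle|rank order")
  # rank inversion along a path
  inv <- data.frame(taxid = c("r", "f", "p"), parent = c(NA, "r", "f"),
                    rank = c("root", "family", "phylum"),
                    name = c("root", "fam", "phy"), classified = TRUE)
  expect_error(taxonomy_tree(inv), "rank order")

  # TSV round trip of the packaged toy taxonomy
  path <- tempfile(fileext = ".tsv")
  write_taxonomy(toy$tree, path)
  reloaded <- load_taxonomy(path)
  expect_equal(reloaded$nodes, toy$tree$nodes)
  fams <- toy$tree$nodes[toy$tree$nodes$rank == "family", "taxid"]
  under_caudo <- vapply(fams, function(f)
    "o_caudo" %in% rev(lineage_of(toy$tree, f)$taxid), logical(1))
  expect_gte(sum(under_caudo), 3)
})

test_that("lineage_of returns ranked domain-to-leaf paths", {
  lin <- lineage_of(toy$tree, "f_myo")
  expect_equal(lin$rank, c("domain", "order", "family"))
  expect_equal(lin$name, c("Viruses", "Caudovirales", "Myoviridae"))
  expect_equal(nrow(lineage_of(toy$tree, "root")), 0)
  expect_error(lineage_of(toy$tree, "nope"), "not in tree")
  # no_rank nodes omitted from the ranked view
  lin2 <- lineage_of(toy$tree, "s_halo1")
  expect_false(any(lin2$rank == "no_rank"))
  expect_true("Caudovirales" %in% lin2$name)
})

test_that("lineage_of matches a brute-force parent walk on random trees", {
  set.seed(42)
  for (rep in 1:10) {
    tr <- random_taxonomy(50)
    tid <- sample(tr$nodes$taxid, 1)
    # independent walk over the raw node table
    path <- character(0)
    cur <- tid
    while (!is.na(cur)) {
      path <- c(cur, path)
      cur <- tr$nodes[match(cur, tr$nodes$taxid), "parent"]
    }
    ranked <- path[tr$nodes[match(path, tr$nodes$taxid), "rank"] %in%
                     c("domain", "phylum", "class", "order", "family",
                       "genus", "species")]
    expect_equal(lineage_of(tr, tid)$taxid, ranked)
  }
})

test_that("best_hit_per_gene filters, deduplicates and orders correctly", {
  h <- make_hits(c("s_myo1", "s_myo1"), c(1e-3, 1e-8), genes = c("g", "g"))
  out <- best_hit_per_gene(h, 1e-5)
  expect_equal(nrow(out), 1)
  expect_equal(out$evalue, 1e-8)

  # two genes x three hits: per-gene minima enumerated by hand
  h2 <- make_hits(rep("s_myo1", 6),
                  c(1e-10, 1e-12, 1e-7, 1e-9, 1e-20, 1e-6),
                  genes = rep(c("gA", "gB"), each = 3))
  out2 <- best_hit_per_gene(h2, 1e-5)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$evalue[match(c("gA", "gB"), out2$query_gene)],
               c(1e-12, 1e-20))
  expect_equal(out2$evalue, sort(out2$evalue))  # ascending order

  # all above threshold
  expect_equal(nrow(best_hit_per_gene(make_hits("s_myo1", 1e-3))), 0)
  # empty in, empty out
  expect_equal(nrow(best_hit_per_gene(make_hits(character(0), numeric(0)))),
               0)
  # E-value tie broken by bitscore then accession
  tie <- make_hits(c("s_myo1", "s_sipho1"), c(1e-9, 1e-9),
                   genes = c("g", "g"), bitscores = c(50, 80))
  expect_equal(best_hit_per_gene(tie)$subject_taxid, "s_sipho1")
})

test_that("rank_consensus reproduces hand-checked toy cases", {
  # two lowest agree at family, 2/3 strict majority -> Myoviridae
  h <- make_hits(c("s_myo1", "s_myo2", "s_sipho1"), c(1e-20, 1e-15, 1e-8))
  a <- rank_consensus(h, toy$tree)
  expect_equal(a$status, "classified")
  expect_equal(deepest_taxid(a), "f_myo")
  expect_equal(a$support$n_hits_used, 3)

  # family fails (a); order passes both -> undetermined at Caudovirales
  h2 <- make_hits(c("s_myo1", "s_sipho1"), c(1e-20, 1e-18))
  a2 <- rank_consensus(h2, toy$tree)
  expect_equal(a2$status, "undetermined")
  expect_equal(deepest_taxid(a2), "o_caudo")
  expect_true(a2$lineage$rank[nrow(a2$lineage)] %in%
                c("domain", "phylum", "class", "order"))

  # single hit to an unclassified halovirus leaf
  a3 <- rank_consensus(make_hits("s_halo1", 1e-12), toy$tree)
  expect_equal(a3$status, "unclassified_virus")
  expect_equal(deepest_taxid(a3), "s_halo1")

  # no hits
  a4 <- rank_consensus(make_hits(character(0), numeric(0)), toy$tree)
  expect_equal(a4$status, "unknown")
  expect_equal(nrow(a4$lineage), 0)

  # consensus landing on an unclassified family-depth node
  a5 <- rank_consensus(make_hits(c("s_halo1", "s_halo1"), c(1e-12, 1e-11)),
                       toy$tree)
  expect_equal(a5$status, "unclassified_virus")

  # unresolvable taxid: error strict, dropped when permissive
  bad <- make_hits(c("s_myo1", "ghost"), c(1e-20, 1e-10))
  expect_error(rank_consensus(bad, toy$tree), "not in tree")
  expect_warning(a6 <- rank_consensus(bad, toy$tree, permissive = TRUE),
                 "dropping")
  expect_equal(deepest_taxid(a6), "s_myo1")
})

test_that("rank_consensus is permutation invariant and respects the single/identical-hit rule", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- random_taxonomy(40)
    h <- random_hitset(tr, sample(2:8, 1))
    a <- rank_consensus(h, tr)
    perm <- h[sample(nrow(h)), , drop = FALSE]
    b <- rank_consensus(perm, tr)
    expect_equal(deepest_taxid(a), deepest_taxid(b))
    expect_equal(a$status, b$status)
  }
  # single and two-identical-hit inputs return the subject's full lineage
  for (tid in c("s_myo1", "g_archaeoglobus", "s_fusi_unc1")) {
    full <- lineage_of(toy$tree, tid)
    one <- rank_consensus(make_hits(tid, 1e-10), toy$tree)
    expect_equal(one$lineage, full)
    two <- rank_consensus(make_hits(c(tid, tid), c(1e-10, 1e-9),
                                    genes = c("gX", "gY")), toy$tree)
    expect_equal(two$lineage, full)
  }
})

test_that("adding a hit under the assignment never makes it shallower", {
  set.seed(99)
  checked <- 0
  for (rep in 1:40) {
    tr <- random_taxonomy(40)
    h <- random_hitset(tr, sample(2:6, 1))
    a <- rank_consensus(h, tr)
    deep <- deepest_taxid(a)
    if (is.null(deep)) next
    # descendants of the current deepest node
    desc <- Filter(function(t) {
      cur <- t
      while (!is.na(cur)) {
        if (cur == deep) return(TRUE)
        cur <- tr$nodes[cur, "parent"]
      }
      FALSE
    }, tr$nodes$taxid)
    extra <- make_hits(sample(desc, 1), 10^runif(1, -20, -6),
                       genes = "gnew")
    b <- rank_consensus(rbind(h, extra), tr)
    old_depth <- nrow(a$lineage)
    expect_gte(nrow(b$lineage), old_depth)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})
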