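make_scaffold <- function(scaffold_id, bin_id = NA_character_,
                          length = 10000, mean_depth = 5,
                          viral_category = 1L) {
  data.frame(scaffold_id = scaffold_id, sample_id = "S", length = length,
             mean_depth = mean_depth, bin_id = bin_id,
             viral_category = viral_category,
             is_prophage = viral_category %in% 4:6,
             stringsAsFactors = FALSE)
}

toy_bins <- data.frame(
  bin_id = c("bArch", "bNitro", "bEmpty"),
  lineage = c("d__Archaea;p__Euryarchaeota;c__Archaeoglobi",
              "d__Bacteria;p__Nitrospirae", ""),
  stringsAsFactors = FALSE)
toy_bins$member_scaffolds <- list("sc1", "sc2", "sc3")

test_that("VirSorter categories map to free virus vs prophage", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("scaffold_id,category", paste0("sc", 1:6, ",", 1:6)), path)
  tab <- parse_virsorter_table(path)
  expect_equal(nrow(tab), 6)
  expect_equal(sum(!tab$is_prophage), 3)
  expect_equal(sum(tab$is_prophage), 3)
  expect_false(tab$is_prophage[tab$viral_category == 2])
  expect_true(tab$is_prophage[tab$viral_category == 5])

  writeLines(c("scaffold_id,category", "sc1,7"), path)
  expect_error(parse_virsorter_table(path), "category.*line 2")
})

test_that("viral taxonomy assignment delegates filter + consensus", {
  hits <- data.frame(query_gene = c("g1", "g2"),
                     scaffold_id = "sc1",
                     subject = c("a1", "a2"),
                     subject_taxid = c("s_myo1", "s_myo2"),
                     evalue = c(1e-20, 1e-10), bitscore = c(90, 70),
                     database = "viral_refseq", stringsAsFactors = FALSE)
  a <- assign_viral_taxonomy("sc1", hits, toy$tree)
  expect_equal(a$status, "classified")
  expect_equal(deepest_taxid(a), "f_myo")

  # only unclassified fusiform hits
  hits$subject_taxid <- c("s_fusi_unc1", "s_fusi_unc1")
  a2 <- assign_viral_taxonomy("sc1", hits, toy$tree)
  expect_equal(a2$status, "unclassified_virus")

  # zero significant hits
  hits$evalue <- c(1e-3, 1e-2)
  expect_equal(assign_viral_taxonomy("sc1", hits, toy$tree)$status,
               "unknown")
})

test_that("host inference is bin-first and domain-consensus as fallback", {
  nr <- function(taxids, evalues, sid = "sc9") {
    n <- length(taxids)
    data.frame(query_gene = sprintf("g%d", seq_len(n)),
               scaffold_id = rep(sid, n),
               subject = sprintf("a%d", seq_len(n)),
               subject_taxid = taxids, evalue = evalues,
               bitscore = rep(50, n), database = rep("nr", n),
               stringsAsFactors = FALSE)
  }

  # binned: the bin lineage wins regardless of hits
  sc <- make_scaffold("sc1", bin_id = "bArch")
  call <- infer_host(sc, toy_bins, nr("g_nitrospira", 1e-30, "sc1"),
                     toy$virus_host_map, toy$tree)
  expect_equal(call$method, "bin")
  expect_equal(call$domain, "Archaea")
  expect_equal(call$lineage$name[nrow(call$lineage)], "Archaeoglobi")

  # unbinned with a viral best hit substituted by its host domain
  sc9 <- make_scaffold("sc9")
  h <- nr(c("g_archaeoglobus", "s_halo1", "g_nitrospira"),
          c(1e-30, 1e-25, 1e-6))
  call2 <- infer_host(sc9, toy_bins, h, toy$virus_host_map, toy$tree)
  expect_equal(call2$method, "consensus_nr")
  expect_equal(call2$domain, "Archaea")
  # domain level only: never a sub-domain lineage for unbinned scaffolds
  expect_equal(nrow(call2$lineage), 1)
  expect_equal(call2$lineage$rank, "domain")

  # one archaeal + one bacterial hit: no winner, all prokaryotic
  call3 <- infer_host(sc9, toy_bins,
                      nr(c("g_archaeoglobus", "g_nitrospira"),
                         c(1e-10, 1e-10)),
                      toy$virus_host_map, toy$tree)
  expect_equal(call3$domain, "prokaryote_unresolved")

  # no hits at all
  call4 <- infer_host(sc9, toy_bins, nr(character(0), numeric(0)),
                      toy$virus_host_map, toy$tree)
  expect_equal(call4$method, "none")
  expect_equal(call4$domain, "unknown")

  # scaffold in a bin with no lineage falls back to consensus
  sc3 <- make_scaffold("sc3", bin_id = "bEmpty")
  call5 <- infer_host(sc3, toy_bins,
                      nr(c("g_archaeoglobus", "g_archaeoglobus"),
                         c(1e-20, 1e-12), "sc3"),
                      toy$virus_host_map, toy$tree)
  expect_equal(call5$method, "consensus_nr")
  expect_equal(call5$domain, "Archaea")

  # viral subject without a host mapping is dropped with a warning
  expect_warning(
    call6 <- infer_host(sc9, toy_bins,
                        nr(c("s_myo1"), 1e-10) |>
                          transform(subject_taxid = "o_caudo"),
                        toy$virus_host_map, toy$tree),
    "no host-domain mapping")
  expect_equal(call6$domain, "unknown")

  # bin-first precedence: changing hits never changes a binned call
  call7 <- infer_host(sc, toy_bins,
                      nr(c("g_nitrospira", "g_nitrospira"),
                         c(1e-40, 1e-38), "sc1"),
                      toy$virus_host_map, toy$tree)
  expect_equal(call7$domain, call$domain)
  expect_equal(call7$lineage, call$lineage)
})

test_that("prophage method agreement counts and resolves by bin", {
  scf <- rbind(make_scaffold("p1", "bArch", viral_category = 4L),
               make_scaffold("p2", "bArch", viral_category = 5L),
               make_scaffold("p3", "bArch", viral_category = 6L),
               make_scaffold("p4", "bNitro", viral_category = 4L))
  bins <- data.frame(bin_id = c("bArch", "bNitro"),
                     lineage = c("d__Archaea", "d__Bacteria"),
                     stringsAsFactors = FALSE)
  bins$member_scaffolds <- list(c("p1", "p2", "p3"), "p4")
  nr_for <- function(sid, taxid)
    data.frame(query_gene = paste0(sid, "_g1"), scaffold_id = sid,
               subject = "a", subject_taxid = taxid, evalue = 1e-20,
               bitscore = 50, database = "nr", stringsAsFactors = FALSE)
  # all four agree
  hits_all <- rbind(nr_for("p1", "g_archaeoglobus"),
                    nr_for("p2", "g_bathy1"),
                    nr_for("p3", "g_thermococcus"),
                    nr_for("p4", "g_nitrospira"))
  res <- prophage_host_agreement(scf, bins, hits_all, toy$virus_host_map,
                                 toy$tree)
  expect_equal(res$percent_agreement, 100)
  expect_equal(res$n, 4)

  # 3 agree + 1 disagree -> 75%, resolved in favour of the bin
  hits_dis <- rbind(nr_for("p1", "g_archaeoglobus"),
                    nr_for("p2", "g_bathy1"),
                    nr_for("p3", "g_thermococcus"),
                    nr_for("p4", "g_archaeoglobus"))
  res2 <- prophage_host_agreement(scf, bins, hits_dis, toy$virus_host_map,
                                  toy$tree)
  expect_equal(res2$percent_agreement, 75)
  final <- res2$resolved_calls
  expect_equal(final$final_domain[final$scaffold_id == "p4"], "Bacteria")

  # nothing eligible: NA, not zero
  res3 <- prophage_host_agreement(scf[0, ], bins, hits_all,
                                  toy$virus_host_map, toy$tree)
  expect_equal(res3$n, 0)
  expect_true(is.na(res3$percent_agreement))
})

test_that("depth-weighted fractions follow the read proxy and sum to one", {
  scf <- rbind(make_scaffold("a", length = 1000, mean_depth = 10),
               make_scaffold("b", length = 1000, mean_depth = 10))
  calls <- data.frame(scaffold_id = c("a", "b"),
                      domain = c("Archaea", "Bacteria"),
                      stringsAsFactors = FALSE)
  fr <- depth_weighted_fractions(scf, calls)
  expect_equal(sort(fr$fraction), c(0.5, 0.5))

  # 3:1 weights -> 75/25
  scf$mean_depth <- c(30, 10)
  fr2 <- depth_weighted_fractions(scf, calls)
  expect_equal(fr2$fraction[fr2$group == "Archaea"], 0.75)
  expect_equal(fr2$fraction[fr2$group == "Bacteria"], 0.25)

  # depth_only mode ignores length
  scf$length <- c(1000, 3000)
  fr3 <- depth_weighted_fractions(scf, calls, mode = "depth_only")
  expect_equal(fr3$fraction[fr3$group == "Archaea"], 0.75)

  expect_error(depth_weighted_fractions(transform(scf, length = c(-1, 10)),
                                        calls), "positive")
})

test_that("prophage bin prevalence is a per-domain bin fraction", {
  bins <- data.frame(
    bin_id = c("a1", "a2", "a3", "a4", "b1", "b2", "x"),
    lineage = c(rep("d__Archaea", 4), rep("d__Bacteria", 2), ""),
    stringsAsFactors = FALSE)
  bins$member_scaffolds <- list("s1", "s2", "s3", "s4", "s5", "s6", "s7")
  scf <- do.call(rbind, lapply(1:7, function(i)
    make_scaffold(paste0("s", i),
                  viral_category = if (i %in% c(1, 2, 3, 5)) 4L else
                    NA_integer_)))
  expect_message(res <- prophage_bin_prevalence(bins, scf), "excluding")
  expect_equal(res$archaeal_bins_with_prophage, 75)
  expect_equal(res$bacterial_bins_with_prophage, 50)

  # no prophages anywhere
  scf$is_prophage <- FALSE
  res2 <- suppressMessages(prophage_bin_prevalence(bins, scf))
  expect_equal(res2$archaeal_bins_with_prophage, 0)
  expect_equal(res2$bacterial_bins_with_prophage, 0)

  # every bin has one
  scf$is_prophage <- TRUE
  res3 <- suppressMessages(prophage_bin_prevalence(bins, scf))
  expect_equal(res3$archaeal_bins_with_prophage, 100)
  expect_equal(res3$bacterial_bins_with_prophage, 100)
})
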