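# Fixture: one gene, codons AAT | CGA | AAA for the focal species s1.
# One ancestor of s1 carries GAT at codon 1 (Asp ancestrally present).
classify_fixture <- function() {
  tr <- fixture_tree()
  aln <- fixture_alignment(list(s1 = "AATCGAAAA", s2 = "AATCGAAAA",
                                o1 = "AATCGAAAA", o2 = "AATCGAAAA"))
  s1_anc <- ancestral_node_sets(tr, "s1")$s1
  anc <- fixture_ancestry(tr, "AATCGAAAA",
                          overrides = stats::setNames(list("GATCGAAAA"),
                                                      s1_anc[1]))
  list(tree = tr, aln = aln, anc = anc)
}

test_that("potential sites are categorized by the post-editing amino acid", {
  fx <- classify_fixture()
  pot <- enumerate_potential_sites(fx$aln, fx$anc, fx$tree, species = "s1")
  # codon 1 AAT: pos 1 -> GAT (Asp, ancestral) restorative;
  #              pos 2 -> AGT (Ser, non-ancestral) diversifying
  expect_equal(pot$category[pot$position == 1], "RESTORATIVE")
  expect_equal(pot$pre_aa[pot$position == 1], "N")
  expect_equal(pot$post_aa[pot$position == 1], "D")
  expect_equal(pot$category[pot$position == 2], "DIVERSIFYING")
  # codon 2 CGA: pos 6 -> CGG, Arg -> Arg synonymous
  expect_equal(pot$category[pot$position == 6], "SYN")
  # codon 3 AAA: pos 7 -> GAA (Glu) not ancestral anywhere
  expect_equal(pot$category[pot$position == 7], "DIVERSIFYING")
})

test_that("ambiguous or stop-involving sites are EXCLUDED", {
  tr <- fixture_tree()
  # s1 codon TAT: editing position 2 gives TGT (Cys); ancestral ? -> excluded
  aln <- fixture_alignment(list(s1 = "TATAAA", s2 = "TATAAA",
                                o1 = "TATAAA", o2 = "TATAAA"))
  s1_anc <- ancestral_node_sets(tr, "s1")$s1
  anc <- fixture_ancestry(tr, "TATAAA",
                          overrides = stats::setNames(list("?ATAAA"), s1_anc[1]))
  pot <- enumerate_potential_sites(aln, anc, tr, species = "s1")
  expect_equal(pot$category[pot$codon_index == 1], rep("EXCLUDED", 1))
  # TAA after editing position 2 of codon TAT? no: TAT pos2 -> TGT fine;
  # instead check a stop-creating edit: codon TAA is itself a stop upstream
  aln2 <- fixture_alignment(list(s1 = "TCATAA", s2 = "TCATAA",
                                 o1 = "TCATAA", o2 = "TCATAA"))
  anc2 <- fixture_ancestry(tr, "TCATAA")
  pot2 <- enumerate_potential_sites(aln2, anc2, tr, species = "s1")
  # codon 2 is the stop TAA: both its A sites are excluded
  expect_true(all(pot2$category[pot2$codon_index == 2] == "EXCLUDED"))
})

test_that("the potential categories tile every genomic A exactly once", {
  sim <- simulate_dataset(sim_config(seed = 11, n_genes = 25,
                                     codons_per_gene = 40))
  anc <- reconstruct_parsimony(sim$alignments, sim$tree)
  pot <- enumerate_potential_sites(sim$alignments, anc, sim$tree)
  coleoids <- setdiff(sim$tree$tip.label, attr(sim$tree, "outgroups"))
  for (sp in coleoids) {
    n_a <- sum(vapply(strsplit(sim$alignments$sequence[sim$alignments$taxon == sp],
                               ""), function(x) sum(x == "A"), numeric(1)))
    psp <- pot[pot$species == sp, ]
    expect_equal(nrow(psp), n_a)
    expect_false(any(duplicated(psp[, c("gene_id", "position")])))
    expect_true(all(psp$category %in%
                      c("SYN", "RESTORATIVE", "DIVERSIFYING", "EXCLUDED")))
  }
})

test_that("edited sites inherit the category of their position", {
  fx <- classify_fixture()
  pot <- enumerate_potential_sites(fx$aln, fx$anc, fx$tree, species = "s1")
  sites <- tibble::tibble(species = "s1", gene_id = "g1",
                          position = c(1L, 6L, 7L), base = "A",
                          level = c(0.5, 0.1, 0.2), coverage = 500L,
                          tissue = NA_character_)
  cl <- classify_editing_sites(sites, pot)
  expect_equal(cl$category, c("RESTORATIVE", "SYN", "DIVERSIFYING"))
  expect_equal(attr(cl, "n_excluded"), 0L)
})

test_that("category frequencies and chi-square match direct computation", {
  pot <- tibble::tibble(
    species = "s1",
    gene_id = "g1",
    position = seq_len(1000 + 20000),
    category = rep(c("RESTORATIVE", "SYN"), c(1000, 20000)))
  cl <- pot[c(1:30, 1001:1200), ] # 30 restorative, 200 synonymous edited
  cl$level <- 0.1; cl$coverage <- 500L
  fr <- category_frequencies(cl, pot)
  expect_equal(fr$frequency[fr$category == "RESTORATIVE"], 30 / 1000)
  expect_equal(fr$frequency[fr$category == "SYN"], 200 / 20000)
  m <- rbind(c(30, 970), c(200, 19800))
  expect_equal(fr$chisq_stat[fr$category == "RESTORATIVE"],
               oracle_chisq_2x2(m), tolerance = 1e-10)
  expect_equal(fr$p_value[fr$category == "RESTORATIVE"],
               stats::pchisq(oracle_chisq_2x2(m), 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("a fully edited category reaches frequency 1", {
  pot <- tibble::tibble(species = "s1", gene_id = "g1", position = 1:40,
                        category = rep(c("RESTORATIVE", "SYN"), c(10, 30)))
  cl <- pot
  cl$level <- 0.1; cl$coverage <- 500L
  fr <- category_frequencies(cl, pot)
  expect_true(all(fr$frequency[fr$category != "DIVERSIFYING"] == 1))
})

test_that("level comparisons apply the 400-read coverage filter", {
  cl <- tibble::tibble(
    species = "s1", gene_id = "g1", position = 1:6,
    category = rep(c("RESTORATIVE", "SYN"), each = 3),
    level = c(0.1, 0.3, 0.9, 0.1, 0.3, 0.9),
    coverage = c(500L, 400L, 399L, 500L, 400L, 399L))
  lv <- suppressWarnings(category_levels(cl, min_coverage = 400))
  expect_equal(lv$n_sites[lv$category == "RESTORATIVE"], 2L)
  expect_equal(lv$median_level[lv$category == "RESTORATIVE"], 0.2)
  # identical retained level sets give a two-sided P of 1
  expect_equal(lv$p_value[lv$category == "RESTORATIVE"], 1, tolerance = 1e-6)
  # threshold fractions refer to the retained sites (levels 0.1 and 0.3)
  expect_equal(lv$frac_gt_5[lv$category == "SYN"], 1)
  expect_equal(lv$frac_gt_20[lv$category == "SYN"], 0.5)
})

test_that("species-specific sites are edited in exactly one species", {
  aln <- tibble::tibble(
    gene_id = "g1", taxon = c("a", "b", "c"),
    sequence = c("AAATTT", "AAATTT", "AAATTT"))
  sites <- tibble::tibble(
    species = c("a", "a", "b"), gene_id = "g1",
    position = c(1L, 2L, 2L), base = "A",
    level = 0.1, coverage = 500L, tissue = NA_character_)
  ss <- species_specific_sites(sites, aln)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$species, "a")
  expect_equal(ss$position, 1L)
  empty <- species_specific_sites(sites[0, ], aln)
  expect_equal(nrow(empty), 0)
})

test_that("shared events require all members edited with identical amino-acid states", {
  tr <- fixture_tree()
  # s1 codon AAT, s2 codon AAC: same pre (Asn) and post (Asp) at position 1
  aln <- fixture_alignment(list(s1 = "AATAAA", s2 = "AACAAA",
                                o1 = "AATAAA", o2 = "AATAAA"))
  anc <- fixture_ancestry(tr, "AATAAA")
  sites <- tibble::tibble(
    species = c("s1", "s2"), gene_id = "g1", position = c(1L, 1L),
    base = "A", level = c(0.4, 0.6), coverage = c(300L, 500L),
    tissue = NA_character_)
  sh <- shared_sites(sites, c("s1", "s2"), tr, aln, anc)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$pre_aa, "N")
  expect_equal(sh$post_aa, "D")
  expect_equal(sh$mean_level, 0.5)
  expect_equal(sh$mean_coverage, 400)
  expect_equal(sh$category, "DIVERSIFYING") # Asp absent from root ancestors
  # one member unedited -> not shared
  sh2 <- shared_sites(sites[1, ], c("s1", "s2"), tr, aln, anc)
  expect_equal(nrow(sh2), 0)
  expect_error(shared_sites(sites, "s1", tr, aln, anc), "at least 2")
})

test_that("level-range ratios use full denominators and flag empty ranges", {
  pot <- tibble::tibble(
    species = "s1", gene_id = "g1", position = 1:300,
    category = rep(c("SYN", "RESTORATIVE", "DIVERSIFYING"), each = 100))
  cl <- pot[c(1, 101, 102), ]
  cl$level <- c(0.1, 0.1, 0.1)
  cl$coverage <- 500L
  rr <- level_range_ratios(cl, pot)
  first <- rr[rr$range == "0-20%", ]
  expect_equal(first$ratio_restorative, (2 / 100) / (1 / 100)) # ratio 2.0
  # all restorative editing is in the first range
  expect_true(all(rr$f_restorative[rr$range != "0-20%"] == 0))
  # ranges with no synonymous edited sites have undefined ratios
  expect_true(all(is.na(rr$ratio_restorative[rr$range != "0-20%"])))
})

test_that("odd/even gene split ranks ascending with ties broken by id", {
  gv <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                       value = c(0.2, 0.4, 0.1, 0.3))
  sp <- split_genes_odd_even(gv)
  expect_equal(sp$gene_id[sp$bin == 1], c("g3", "g4")) # ranks 1 and 3
  expect_equal(sp$gene_id[sp$bin == 2], c("g1", "g2")) # ranks 2 and 4
  one <- split_genes_odd_even(gv[1, ])
  expect_equal(one$bin, 1L)
  tied <- split_genes_odd_even(tibble::tibble(gene_id = c("g2", "g1"),
                                              value = c(1, 1)))
  expect_equal(tied$gene_id, c("g1", "g2"))
  expect_equal(tied$bin, c(1L, 2L))
})

test_that("frequencies are invariant under row permutations", {
  sim <- simulate_dataset(sim_config(seed = 12, n_genes = 10,
                                     codons_per_gene = 30))
  anc <- reconstruct_parsimony(sim$alignments, sim$tree)
  pot <- enumerate_potential_sites(sim$alignments, anc, sim$tree)
  cl <- classify_editing_sites(sim$sites, pot)
  f1 <- category_frequencies(cl, pot)
  set.seed(1)
  f2 <- category_frequencies(cl[sample(nrow(cl)), ], pot[sample(nrow(pot)), ])
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})
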