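test_that("the worked G>A example gives the expected counts and dN/dS = 1/3", {
  parent <- "GAACGCCGG"
  child <- "AAACGCCGA"
  cnt <- count_branch_changes(parent, child, "G>A")
  expect_equal(cnt$nonsyn_sites, 3) # GAA->AAA, CGC->CAC, CGG->CAG
  expect_equal(cnt$syn_sites, 1)    # CGG->CGA
  expect_equal(cnt$nonsyn_subs, 1)  # position 1
  expect_equal(cnt$syn_subs, 1)     # position 9
  pooled <- class_dnds(dplyr::mutate(cnt, gene_id = "g1", parent = "p",
                                     child = "c", class = "G>A"))
  expect_equal(pooled$dn, 1 / 3)
  expect_equal(pooled$ds, 1)
  expect_equal(pooled$dnds, 1 / 3)
})

test_that("identical sequences give sites but no substitutions", {
  cnt <- count_branch_changes("GAACGCCGG", "GAACGCCGG", "G>A")
  expect_equal(cnt$nonsyn_sites, 3)
  expect_equal(cnt$syn_sites, 1)
  expect_equal(cnt$nonsyn_subs + cnt$syn_subs, 0)
})

test_that("codons with more than one difference are excluded entirely", {
  # parent GGG -> child AAG differs at two positions
  cnt <- count_branch_changes("GGG", "AAG", "G>A")
  expect_equal(unlist(cnt), c(nonsyn_sites = 0, syn_sites = 0,
                              nonsyn_subs = 0, syn_subs = 0))
})

test_that("counts match the per-position enumeration oracle on random pairs", {
  set.seed(99)
  classes <- list(c("G", "A"), c("CT", "A"), c("G", "CT"))
  for (i in 1:60) {
    ncod <- sample(2:10, 1)
    p <- sample(c("A", "C", "G", "T"), 3 * ncod, replace = TRUE)
    ch <- ifelse(runif(3 * ncod) < 0.2,
                 sample(c("A", "C", "G", "T"), 3 * ncod, replace = TRUE), p)
    if (i %% 5 == 0) p[sample(3 * ncod, 1)] <- "N" # exercise exclusion
    ps <- paste(p, collapse = ""); cs <- paste(ch, collapse = "")
    for (cl in classes) {
      got <- unlist(count_branch_changes(ps, cs, paste0(cl[1], ">", cl[2])))
      want <- oracle_change_counts(ps, cs, strsplit(cl[1], "")[[1]],
                                   strsplit(cl[2], "")[[1]])
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("disjoint source classes are additive and never double-count", {
  set.seed(7)
  p <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  ch <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  a <- unlist(count_branch_changes(p, ch, "G>A"))
  b <- unlist(count_branch_changes(p, ch, "CT>A"))
  both <- unlist(count_branch_changes(p, ch, list(src = c("G", "C", "T"),
                                                  tgt = "A")))
  expect_equal(a + b, both)
})

test_that("the conservation mask restricts opportunities", {
  parent <- "GAACGCCGG"
  child <- "AAACGCCGA"
  mask <- rep(FALSE, 9); mask[1] <- TRUE
  cnt <- count_branch_changes(parent, child, "G>A", mask)
  expect_equal(cnt$nonsyn_sites, 1)
  expect_equal(cnt$syn_sites, 0)
  expect_equal(cnt$nonsyn_subs, 1)
  pc <- strsplit(parent, "")[[1]]
  m <- conserved_site_mask(pc, list(pc, strsplit("GAACGCCGA", "")[[1]]))
  expect_equal(which(!m), 9L)
})

test_that("pooled dN/dS is invariant under gene duplication", {
  cnt <- dplyr::mutate(count_branch_changes("GAACGCCGG", "AAACGCCGA", "G>A"),
                       gene_id = "g1", parent = "p", child = "c",
                       class = "G>A")
  two <- dplyr::bind_rows(cnt, dplyr::mutate(cnt, gene_id = "g2"))
  expect_equal(class_dnds(cnt)$dnds, class_dnds(two)$dnds)
})

test_that("branch_counts agrees with per-branch manual counting on a simulation", {
  sim <- simulate_dataset(sim_config(seed = 21, n_genes = 6,
                                     codons_per_gene = 25))
  anc <- sim$ancestral
  counts <- branch_counts(sim$alignments, anc, sim$tree, classes = "G>A",
                          conserved = FALSE)
  br <- coleoid_branches(sim$tree)
  g <- sim$alignments$gene_id[1]
  get_seq <- function(lab) {
    hit <- anc$sequence[anc$gene_id == g & anc$node_id == lab]
    if (length(hit) == 0) {
      hit <- sim$alignments$sequence[sim$alignments$gene_id == g &
                                       sim$alignments$taxon == lab]
    }
    hit
  }
  for (b in seq_len(nrow(br))) {
    direct <- count_branch_changes(get_seq(br$parent[b]), get_seq(br$child[b]),
                                   "G>A")
    row <- counts[counts$gene_id == g & counts$parent == br$parent[b] &
                    counts$child == br$child[b], ]
    expect_equal(row$nonsyn_sites, direct$nonsyn_sites)
    expect_equal(row$syn_subs, direct$syn_subs)
  }
})

test_that("the gene bootstrap is deterministic and null for identical groups", {
  base <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    parent = "p", child = "c", class = "G>A",
    nonsyn_sites = 30L, syn_sites = 10L,
    nonsyn_subs = rep(c(2L, 3L), 10), syn_subs = rep(c(1L, 2L), 10))
  groups <- tibble::tibble(gene_id = base$gene_id,
                           group = rep(c("high_neural", "low_neural"), 10))
  b1 <- bootstrap_dnds(base, groups, B = 100, seed = 5)
  b2 <- bootstrap_dnds(base, groups, B = 100, seed = 5)
  expect_identical(glance(b1), glance(b2))
  expect_error(bootstrap_dnds(base, groups), "seed")

  # all genes identical: every resample gives the same ratio, P = 1
  flat <- dplyr::mutate(base, nonsyn_subs = 2L, syn_subs = 1L)
  bf <- bootstrap_dnds(flat, groups, B = 100, seed = 5)
  expect_equal(bf$p_two_sided, 1)
  expect_equal(bf$difference, 0)

  small <- groups
  small$group[small$gene_id != "g01"] <- "low_neural"
  expect_error(bootstrap_dnds(base, small, B = 10, seed = 1), "fewer than 2")
})
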