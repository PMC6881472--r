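test_that("ADP follows the bin-wise excess formula", {
  # 10,000 potential diversifying and 20,000 potential synonymous sites;
  # one bin with N_D = 200 (F_D = 0.02) against F_S = 0.01 gives ADP = 100
  pot <- tibble::tibble(
    species = "s1", gene_id = "g1", position = seq_len(30000),
    category = rep(c("DIVERSIFYING", "SYN"), c(10000, 20000)))
  cl <- pot[c(1:200, 10001:10200), ]
  cl$level <- rep(c(0.55, 0.55), each = 200) # all in the 50-60% bin
  cl$coverage <- 500L
  est <- adp_by_bins(cl, pot)
  b6 <- est$bins[6, ]
  expect_equal(b6$n_diversifying, 200)
  expect_equal(b6$f_diversifying, 0.02)
  expect_equal(b6$f_synonymous, 0.01)
  expect_equal(b6$adp, 100)
  expect_equal(est$total_adp, 100)
  expect_equal(est$adaptive_fraction, 0.5)
})

test_that("bins with F_D <= F_S contribute zero ADP", {
  pot <- tibble::tibble(
    species = "s1", gene_id = "g1", position = seq_len(20000),
    category = rep(c("DIVERSIFYING", "SYN"), each = 10000))
  cl <- pot[c(1:100, 10001:10200), ] # F_D = 0.01 < F_S = 0.02 in the bin
  cl$level <- 0.05
  cl$coverage <- 500L
  est <- adp_by_bins(cl, pot)
  expect_equal(est$total_adp, 0)
  expect_equal(est$adaptive_fraction, 0)
  expect_true(all(est$bins$adp >= 0 & est$bins$adp <= est$bins$n_diversifying))
})

# Shared fixture: 4 coleoids, 3 events in one gene.
ancestral_fixture <- function() {
  tr <- read_tree("(((O,B),(S,C)),N,H);", outgroups = c("N", "H"))
  # gene: codon1 AAT (editable, nonsyn N->S at pos 2), codon2 CGA (syn at
  # pos 6), codon3 AAT
  seqs <- c(O = "AATCGAAAT", B = "AATCGAAAT", S = "AATCGAAAT", C = "AATCGAAAT",
            N = "AATCGAAAT", H = "AATCGAAAT")
  aln <- fixture_alignment(as.list(seqs))
  anc <- fixture_ancestry(tr, "AATCGAAAT")
  pot <- enumerate_potential_sites(aln, anc, tr,
                                   species = c("O", "B", "S", "C"))
  list(tree = tr, aln = aln, anc = anc, pot = pot)
}

test_that("ancestral editing requires at least three of four coleoids", {
  fx <- ancestral_fixture()
  mk_sites <- function(spp, pos) {
    tibble::tibble(species = spp, gene_id = "g1", position = pos, base = "A",
                   level = 0.5, coverage = 500L, tissue = NA_character_)
  }
  sites <- dplyr::bind_rows(
    mk_sites(c("O", "B", "S"), 2L),       # 3 of 4 -> ancestral
    mk_sites(c("O", "B"), 6L),            # 2 of 4 -> not ancestral
    mk_sites(c("O", "B", "S", "C"), 7L))  # 4 of 4 -> ancestral, no candidate
  cl <- classify_editing_sites(sites, fx$pot)
  ae <- infer_ancestral_editing(cl, fx$aln, fx$tree, fx$anc)
  cols <- unique(ae$column)
  expect_setequal(cols, c(2L, 7L))
  ev2 <- ae[ae$column == 2L, ]
  expect_equal(sum(ev2$edited), 3)
  expect_equal(ev2$genomic_base[ev2$species == "C"], "A")
  ev7 <- ae[ae$column == 7L, ]
  expect_true(all(ev7$edited))
})

test_that("replacement counts a site only via unedited members with genomic G", {
  tr <- read_tree("(((O,B),(S,C)),N,H);", outgroups = c("N", "H"))
  # column 2 edited in O,B,S; C carries a genomic G there (replacement);
  # column 6 (synonymous) edited in O,B,S; C retains A;
  # column 7 edited in O,B,S; C carries T (control, not a G replacement)
  seqs <- c(O = "AATCGAAAT", B = "AATCGAAAT", S = "AATCGAAAT",
            C = "AGTCGATAT", N = "AATCGAAAT", H = "AATCGAAAT")
  aln <- fixture_alignment(as.list(seqs))
  anc <- fixture_ancestry(tr, "AATCGAAAT")
  pot <- enumerate_potential_sites(aln, anc, tr, species = c("O", "B", "S"))
  sites <- tidyr::expand_grid(species = c("O", "B", "S"),
                              position = c(2L, 6L, 7L)) |>
    dplyr::mutate(gene_id = "g1", base = "A", level = 0.5, coverage = 500L,
                  tissue = NA_character_)
  cl <- classify_editing_sites(sites, pot)
  ae <- infer_ancestral_editing(cl, aln, tr, anc)
  rt <- replacement_analysis(ae)
  expect_equal(rt$table["nonsynonymous", "replaced"], 1) # column 2 via C
  expect_equal(rt$table["synonymous", "replaced"], 0)    # column 6 retained
  expect_equal(rt$control_table["nonsynonymous", "replaced"], 1) # column 7, T
  expect_equal(sum(rt$table), 3)
  expect_error(replacement_analysis(ae[0, ]), "empty")
})

test_that("Fisher's two-tailed P matches exhaustive enumeration", {
  m <- rbind(c(3, 7), c(1, 9))
  got <- stats::fisher.test(m, alternative = "two.sided")$p.value
  expect_equal(got, oracle_fisher_two_tailed(m), tolerance = 1e-12)
  set.seed(123)
  for (i in 1:50) {
    m <- matrix(rpois(4, 5), 2)
    expect_equal(stats::fisher.test(m)$p.value, oracle_fisher_two_tailed(m),
                 tolerance = 1e-9)
  }
})

test_that("planted replacement rates are recovered with the correct ordering", {
  set.seed(77)
  n <- 1500
  r_n <- 0.3; r_s <- 0.1
  mk <- function(n, kind, rate, offset) {
    repl <- runif(n) < rate
    tibble::tibble(
      gene_id = "g1",
      column = rep(offset + seq_len(n), each = 4),
      pre_aa = if (kind == "nonsynonymous") "N" else "R",
      post_aa = if (kind == "nonsynonymous") "D" else "R",
      category = if (kind == "nonsynonymous") "DIVERSIFYING" else "SYN",
      n_edited = 3L,
      species = rep(c("O", "B", "S", "C"), n),
      edited = rep(c(TRUE, TRUE, TRUE, FALSE), n),
      genomic_base = as.vector(rbind("A", "A", "A", ifelse(repl, "G", "A"))))
  }
  ae <- dplyr::bind_rows(mk(n, "nonsynonymous", r_n, 0),
                         mk(n, "synonymous", r_s, n))
  rt <- replacement_analysis(ae)
  fr <- rt$fractions
  f_n <- fr$fraction_replaced[fr$kind == "nonsynonymous"]
  f_s <- fr$fraction_replaced[fr$kind == "synonymous"]
  expect_gt(f_n, f_s)
  expect_lt(abs(f_n - r_n), 0.05)
  expect_lt(abs(f_s - r_s), 0.05)
  expect_lt(rt$p_value, 0.001)
})
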