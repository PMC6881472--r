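test_that("sanitize_transcripts trims at the first in-frame stop and keeps the longest duplicate", {
  recs <- tibble::tibble(
    taxon = c("sq", "sq", "sq", "oc"),
    gene_id = c("g1", "g2", "g2", "g1"),
    sequence = c("ATGAAATAGGGG", # stop at codon 3
                 paste(rep("ATG", 10), collapse = ""), # 30 nt, no stop
                 paste(rep("ATG", 9), collapse = ""),  # shorter duplicate
                 "ATGAAA")                              # no stop
  )
  out <- sanitize_transcripts(recs, quiet = TRUE)
  expect_equal(out$sequence[out$taxon == "sq" & out$gene_id == "g1"], "ATGAAA")
  expect_equal(nchar(out$sequence[out$taxon == "sq" & out$gene_id == "g2"]), 30)
  expect_equal(out$sequence[out$taxon == "oc"], "ATGAAA")
  # idempotent
  expect_equal(sanitize_transcripts(out, quiet = TRUE), out)
})

test_that("sanitize_transcripts rejects invalid records with warnings", {
  recs <- tibble::tibble(taxon = c("a", "a"), gene_id = c("g1", "g2"),
                         sequence = c("ATGXXA", "TAGAAA"))
  expect_warning(expect_warning(out <- sanitize_transcripts(recs, quiet = TRUE),
                                "outside"), "empty")
  expect_equal(nrow(out), 0)
})

test_that("alignment FASTA round-trips and is validated", {
  aln <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2"),
    taxon = c("sq", "oc", "sq", "oc"),
    sequence = c("ATGAAACCC", "ATG---CCC", "AAATTT", "AAGTTT")
  )
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignments(aln, f)
  back <- read_alignments(f)
  expect_equal(dplyr::arrange(back, gene_id, taxon),
               dplyr::arrange(aln, gene_id, taxon))

  ragged <- aln
  ragged$sequence[1] <- "ATGAAACCCAAA"
  expect_error(validate_alignments(ragged), "ragged")
  off_frame <- aln
  off_frame$sequence[3:4] <- c("AAATT", "AAGTT")
  expect_error(validate_alignments(off_frame), "multiple of 3")
  bad_char <- aln
  bad_char$sequence[1] <- "ATGAAACCX"
  expect_error(validate_alignments(bad_char), "unknown character")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">noseparator", "ATGAAA"), f2)
  expect_error(read_alignments(f2), "malformed header")
})

test_that("editing sites are read 1-based, checked against the sequence, and round-trip", {
  aln <- tibble::tibble(gene_id = "g1", taxon = "squid",
                        sequence = "ATG-AAACCC") # ungapped ATGAAACCC
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tgene\tposition\tbase\tlevel\tcoverage",
               "squid\tg1\t4\tA\t0.35\t512", # ungapped pos 4 is A
               "squid\tg1\t2\tG\t0.10\t100", # base not A -> dropped
               "squid\tg1\t3\tA\t0.10\t100"),# sequence has G at 3 -> dropped
             f)
  expect_warning(sites <- read_editing_sites(f, aln), "genomic-A")
  expect_equal(nrow(sites), 1)
  expect_equal(sites$position, 4L)
  expect_equal(attr(sites, "n_dropped"), 2L)

  f_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tgene\tposition\tbase\tlevel\tcoverage",
               "squid\tg1\t4\tA\t1.2\t512"), f_bad)
  expect_error(read_editing_sites(f_bad, aln), "\\[0, 1\\]")

  f_out <- withr::local_tempfile(fileext = ".tsv")
  write_editing_sites(sites, f_out)
  back <- read_editing_sites(f_out, aln)
  expect_equal(back$position, sites$position)
  expect_equal(back$level, sites$level)
})

test_that("read_tree roots on the outgroups and gives three ancestors per coleoid", {
  tr <- read_tree("(((O,B),(S,C)),N,H);", outgroups = c("N", "H"))
  expect_true(ape::is.rooted(tr))
  anc <- ancestral_node_sets(tr)
  expect_setequal(names(anc), c("O", "B", "S", "C"))
  expect_true(all(lengths(anc) == 3))
  # the two coleoid pairs share their two deepest ancestors
  expect_length(intersect(anc$O, anc$S), 2)

  expect_error(read_tree("(A);", outgroups = "A"), "too small")
  expect_error(read_tree("(((O,B),(S,C)),N,H);", outgroups = c("N", "X")),
               "not in tree")
  aln <- tibble::tibble(gene_id = "g1", taxon = c("O", "B", "S", "C", "N"),
                        sequence = "AAA")
  expect_error(validate_taxa(tr, aln), "H")
})

test_that("mrca_ancestor_set excludes the clade MRCA itself", {
  tr <- read_tree("(((O,B),(S,C)),N,H);", outgroups = c("N", "H"))
  anc_pair <- mrca_ancestor_set(tr, c("O", "B"))
  anc_all <- mrca_ancestor_set(tr, c("O", "B", "S", "C"))
  expect_length(anc_pair, 2)
  expect_length(anc_all, 1) # only the root is above the coleoid MRCA
  expect_error(mrca_ancestor_set(tr, "O"), "at least 2")
})

test_that("gene-group tables are validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tgroup", "g1\thigh_neural", "g2\tlow_neural"), f)
  gg <- read_gene_groups(f)
  expect_equal(gg$group, c("high_neural", "low_neural"))
  writeLines(c("gene\tgroup", "g1\tneural"), f)
  expect_error(read_gene_groups(f), "unknown gene group")
  writeLines(c("gene\tgroup", "g1\thigh_neural", "g1\tlow_neural"), f)
  expect_error(read_gene_groups(f), "unique")
})
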