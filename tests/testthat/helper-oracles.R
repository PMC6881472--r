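# Independent oracles used to check the package implementations, written as
# plain enumerations so they share no code with the functions under test.

BASES_TEST <- c("A", "C", "G", "T")

# Minimum parsimony cost by exhaustive enumeration of all interior-node
# labelings. tip_states: integer states (1..4) in tree$tip.label order;
# NA-containing columns are the caller's responsibility.
brute_force_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(1:4), nn)))
  cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1] - ntip
    child <- tree$edge[e, 2]
    if (child <= ntip) {
      cost <- cost + (grid[, par] != tip_states[child])
    } else {
      cost <- cost + (grid[, par] != grid[, child - ntip])
    }
  }
  min(cost)
}

# Per-position enumeration of class-restricted sites and substitutions,
# re-translating every candidate codon with Biostrings' genetic code.
oracle_change_counts <- function(parent, child, src, tgt) {
  GC <- Biostrings::GENETIC_CODE
  p <- strsplit(parent, "")[[1]]
  ch <- strsplit(child, "")[[1]]
  out <- c(nonsyn_sites = 0, syn_sites = 0, nonsyn_subs = 0, syn_subs = 0)
  for (pos in seq_along(p)) {
    if (!(p[pos] %in% src)) next
    c0 <- ((pos - 1) %/% 3) * 3 + 1
    pcod <- paste(p[c0:(c0 + 2)], collapse = "")
    ccod <- paste(ch[c0:(c0 + 2)], collapse = "")
    if (grepl("[^ACGT]", pcod) || grepl("[^ACGT]", ccod)) next
    if (sum(p[c0:(c0 + 2)] != ch[c0:(c0 + 2)]) > 1) next
    paa <- GC[[pcod]]
    for (t in tgt) {
      if (t == p[pos]) next
      mcod <- pcod
      substr(mcod, pos - c0 + 1, pos - c0 + 1) <- t
      maa <- GC[[mcod]]
      if (paa == "*" || maa == "*") next
      is_sub <- ch[pos] == t && ch[pos] != p[pos]
      if (maa != paa) {
        out["nonsyn_sites"] <- out["nonsyn_sites"] + 1
        if (is_sub) out["nonsyn_subs"] <- out["nonsyn_subs"] + 1
      } else {
        out["syn_sites"] <- out["syn_sites"] + 1
        if (is_sub) out["syn_subs"] <- out["syn_subs"] + 1
      }
    }
  }
  out
}

# Two-tailed Fisher exact P by exhaustive hypergeometric enumeration over
# all 2x2 tables with the observed margins.
oracle_fisher_two_tailed <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  pobs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Closed-form 2x2 chi-square statistic without continuity correction.
oracle_chisq_2x2 <- function(m) {
  n <- sum(m)
  n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
}

# A random rooted binary tree with ntip tips and labeled interior nodes.
random_labeled_tree <- function(ntip) {
  tr <- ape::rtree(ntip, rooted = TRUE, br = NULL)
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  tr
}

# Small fixture: a rooted 4-taxon tree (2 ingroup, 2 outgroup) plus builders
# for one-gene alignments and hand-set ancestral states.
fixture_tree <- function() {
  read_tree("((s1,s2),(o1,o2));", outgroups = c("o1", "o2"))
}

fixture_alignment <- function(seqs, gene_id = "g1") {
  tibble::tibble(gene_id = gene_id, taxon = names(seqs),
                 sequence = unname(unlist(seqs)))
}

# Ancestral assignment that gives every interior node the same sequence,
# with optional per-node overrides.
fixture_ancestry <- function(tree, default_seq, overrides = list(),
                             gene_id = "g1") {
  seqs <- stats::setNames(rep(default_seq, tree$Nnode), tree$node.label)
  for (nd in names(overrides)) seqs[[nd]] <- overrides[[nd]]
  tibble::tibble(gene_id = gene_id, node_id = names(seqs),
                 sequence = unname(seqs), method = "sankoff", cost = NA_real_)
}
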