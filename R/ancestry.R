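#' Joint ancestral reconstruction by unit-cost parsimony
#'
#' Runs a per-column Sankoff dynamic program over the states A/C/G/T with
#' unit substitution cost and returns one minimum-cost joint assignment of
#' all interior nodes, for every gene. Ties among optimal states are broken
#' lexicographically (A < C < G < T), choosing states from the root
#' downward, so the reconstruction is deterministic. Columns in which any
#' tip carries a gap or an N are assigned `?` at every interior node and
#' contribute nothing to the parsimony cost; downstream classification
#' excludes sites touching `?` rather than guessing.
#'
#' @param alignments Alignment tibble (`gene_id`, `taxon`, `sequence`).
#' @param tree Rooted `phylo` with interior node labels (see [read_tree()]).
#' @return Tibble with columns `gene_id`, `node_id`, `sequence`, `method`
#'   (`"sankoff"`) and `cost` (the per-gene minimum number of changes,
#'   repeated across the gene's rows).
#' @export
reconstruct_parsimony <- function(alignments, tree) {
  validate_taxa(tree, alignments)
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  node_labels <- tree$node.label

  # concatenate the genes so the column-wise DP runs once, then split back
  genes <- split(alignments, alignments$gene_id)
  gene_ids <- names(genes)
  glen <- map_int(genes, function(g) {
    miss <- setdiff(tree$tip.label, g$taxon)
    if (length(miss) > 0) {
      abort(sprintf("gene %s lacks sequences for tree tip(s): %s",
                    g$gene_id[1], paste(miss, collapse = ", ")))
    }
    nchar(g$sequence[1])
  })
  offset <- cumsum(c(0L, glen))
  total <- offset[length(offset)]
  tipmat <- matrix(NA_integer_, nrow = ntip, ncol = total)
  for (i in seq_len(ntip)) {
    tp <- tree$tip.label[i]
    cat_seq <- paste(map_chr(genes, function(g) g$sequence[match(tp, g$taxon)]),
                     collapse = "")
    tipmat[i, ] <- .base_int(.chars(cat_seq))
  }
  rec <- .sankoff(tipmat, post, ntip, tree$Nnode)
  purrr::map(seq_along(gene_ids), function(k) {
    lo <- offset[k] + 1L; hi <- offset[k + 1L]
    tibble(
      gene_id = gene_ids[k],
      node_id = node_labels,
      sequence = substring(rec$sequences, lo, hi),
      method = "sankoff",
      cost = sum(rec$colcost[lo:hi])
    )
  }) |> list_rbind()
}

# Sankoff DP over a (possibly gene-concatenated) alignment. tipmat: ntip x L
# integer matrix (1..4, NA elsewhere). Returns interior-node sequences
# (character, node order ntip+1 .. ntip+nnode) and the per-column minimum
# cost (0 at columns containing a gap/N, which get "?").
.sankoff <- function(tipmat, post_edges, ntip, nnode) {
  L <- ncol(tipmat)
  # the DP only depends on the column pattern, so run it on unique patterns
  key <- colSums(tipmat * 4L^(seq_len(ntip) - 1L))
  key[is.na(key)] <- -1
  uniq <- which(!duplicated(key))
  expand <- match(key, key[uniq])
  tipmat <- tipmat[, uniq, drop = FALSE]
  L_all <- L
  L <- ncol(tipmat)

  good <- which(colSums(is.na(tipmat)) == 0L)
  Lg <- length(good)
  out <- matrix("?", nrow = nnode, ncol = L)
  if (Lg == 0) {
    return(list(sequences = rep(strrep("?", L_all), nnode),
                colcost = numeric(L_all)))
  }
  BIG <- 1e9
  nnodes_all <- ntip + nnode
  cost <- vector("list", nnodes_all)
  for (i in seq_len(ntip)) {
    m <- matrix(BIG, 4, Lg)
    m[cbind(tipmat[i, good], seq_len(Lg))] <- 0
    cost[[i]] <- m
  }
  for (k in (ntip + 1):nnodes_all) cost[[k]] <- matrix(0, 4, Lg)
  for (e in seq_len(nrow(post_edges))) {
    par <- post_edges[e, 1]; ch <- post_edges[e, 2]
    C <- cost[[ch]]
    cmin <- pmin(C[1, ], C[2, ], C[3, ], C[4, ])
    cost[[par]] <- cost[[par]] +
      rbind(pmin(C[1, ], cmin + 1), pmin(C[2, ], cmin + 1),
            pmin(C[3, ], cmin + 1), pmin(C[4, ], cmin + 1))
  }
  root <- ntip + 1L
  R <- cost[[root]]
  rmin <- pmin(R[1, ], R[2, ], R[3, ], R[4, ])
  state <- matrix(NA_integer_, nrow = nnodes_all, ncol = Lg)
  # lexicographically smallest root state achieving the minimum
  st <- rep(4L, Lg)
  for (s in c(3L, 2L, 1L)) st[R[s, ] == rmin] <- s
  state[root, ] <- st
  for (e in rev(seq_len(nrow(post_edges)))) {
    par <- post_edges[e, 1]; ch <- post_edges[e, 2]
    if (ch <= ntip) next
    C <- cost[[ch]]
    cmin <- pmin(C[1, ], C[2, ], C[3, ], C[4, ])
    stmin <- rep(4L, Lg)
    for (s in c(3L, 2L, 1L)) stmin[C[s, ] == cmin] <- s
    ps <- state[par, ]
    Cps <- C[cbind(ps, seq_len(Lg))]
    child_st <- ifelse(Cps == cmin, ps,
                       ifelse(Cps == cmin + 1 & ps < stmin, ps, stmin))
    state[ch, ] <- as.integer(child_st)
  }
  for (k in seq_len(nnode)) {
    out[k, good] <- BASES[state[ntip + k, ]]
  }
  colcost <- numeric(L)
  colcost[good] <- rmin
  # expand unique patterns back to the original columns
  out <- out[, expand, drop = FALSE]
  list(sequences = apply(out, 1, paste, collapse = ""),
       colcost = colcost[expand])
}

#' Import externally inferred ancestral sequences
#'
#' Reads a TSV with columns `gene`, `node_id`, `sequence` (for example
#' converted from a joint maximum-likelihood reconstruction) and validates
#' it against the tree and alignments: every interior node of the tree must
#' be present for every gene in the file, and sequence lengths must match
#' the gene alignment length. Sequences may contain `?` for unresolved
#' states.
#'
#' @param path TSV path.
#' @param tree Rooted `phylo` with node labels.
#' @param alignments Alignment tibble.
#' @return Tibble `gene_id`, `node_id`, `sequence`, `method`
#'   (`"imported"`), `cost` (`NA`).
#' @export
import_ancestral <- function(path, tree, alignments) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  gene_col <- intersect(c("gene_id", "gene"), names(raw))[1]
  if (is.na(gene_col) || !all(c("node_id", "sequence") %in% names(raw))) {
    abort("ancestral import needs columns 'gene', 'node_id', 'sequence'")
  }
  anc <- tibble(gene_id = as.character(raw[[gene_col]]),
                node_id = as.character(raw$node_id),
                sequence = toupper(as.character(raw$sequence)),
                method = "imported", cost = NA_real_)
  if (any(grepl("[^ACGTN?-]", anc$sequence))) {
    abort("ancestral sequences may contain only A/C/G/T/N/-/?")
  }
  gene_len <- alignments |>
    group_by(.data$gene_id) |>
    summarise(len = nchar(.data$sequence[1]), .groups = "drop")
  for (g in split(anc, anc$gene_id)) {
    missing <- setdiff(tree$node.label, g$node_id)
    if (length(missing) > 0) {
      abort(sprintf("incomplete assignment for gene %s: missing node(s) %s",
                    g$gene_id[1], paste(missing, collapse = ", ")))
    }
    len <- gene_len$len[match(g$gene_id[1], gene_len$gene_id)]
    if (is.na(len)) abort(sprintf("gene %s not present in alignments", g$gene_id[1]))
    if (any(nchar(g$sequence) != len)) {
      abort(sprintf("ancestral sequence length mismatch in gene %s", g$gene_id[1]))
    }
  }
  anc
}

#' Write ancestral sequences as TSV
#'
#' @param ancestry Ancestral assignment tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ancestral <- function(ancestry, path) {
  writeLines("# editevo ancestral sequences; '?' marks unresolved states", path)
  out <- ancestry |> transmute(gene = .data$gene_id, node_id = .data$node_id,
                               sequence = .data$sequence)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Ancestral amino-acid states at a codon
#'
#' Translates the codon at `codon_index` (1-based) at each of the given
#' interior nodes. Codons containing `?` contribute the state
#' `"AMBIGUOUS"`; stop codons contribute `"STOP"`.
#'
#' @param ancestry Ancestral assignment tibble.
#' @param gene Gene id.
#' @param codon_index 1-based codon index in alignment coordinates.
#' @param nodes Interior node labels to inspect.
#' @return Character vector of distinct amino-acid states (one-letter code,
#'   possibly including `"AMBIGUOUS"` or `"STOP"`).
#' @export
ancestral_amino_acids <- function(ancestry, gene, codon_index, nodes) {
  g <- ancestry[ancestry$gene_id == gene, , drop = FALSE]
  if (nrow(g) == 0) abort(sprintf("gene %s absent from ancestral assignment", gene))
  L <- nchar(g$sequence[1])
  if (codon_index < 1 || codon_index * 3 > L) abort("codon index out of range")
  start <- (codon_index - 1L) * 3L + 1L
  states <- map_chr(nodes, function(nd) {
    seq <- g$sequence[match(nd, g$node_id)]
    if (is.na(seq)) abort(sprintf("node %s absent for gene %s", nd, gene))
    codon <- substr(seq, start, start + 2L)
    if (grepl("[?N-]", codon)) return("AMBIGUOUS")
    aa <- translate_codons(codon)
    if (is.na(aa)) "AMBIGUOUS" else if (aa == "*") "STOP" else aa
  })
  unique(states)
}
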