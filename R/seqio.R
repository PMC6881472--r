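#' Sanitize raw coding sequences
#'
#' Prepares raw per-species coding sequences for alignment-based analyses:
#' sequences are uppercased, truncated at (and excluding) the first in-frame
#' stop codon (TAA/TAG/TGA, reading frame starting at position 1), and when a
#' gene appears more than once within a species only the longest surviving
#' sequence is retained (ties broken by input order). Records containing
#' characters other than A/C/G/T/N are rejected with a warning, as are
#' records that are empty after trimming.
#'
#' The operation is idempotent: applying it twice gives the same result.
#'
#' @param records A data frame with columns `taxon`, `gene_id`, `sequence`.
#' @param quiet Suppress per-modification log messages.
#' @return A tibble with the same columns, cleaned.
#' @export
sanitize_transcripts <- function(records, quiet = FALSE) {
  .assert_cols(records, c("taxon", "gene_id", "sequence"), "`records`")
  records <- as_tibble(records)
  say <- function(...) if (!quiet) inform(sprintf(...))

  seqs <- toupper(records$sequence)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warn(sprintf("rejected %d record(s) with characters outside A/C/G/T/N: %s",
                 sum(bad),
                 paste(head(paste(records$taxon[bad], records$gene_id[bad]), 5),
                       collapse = "; ")))
    records <- records[!bad, , drop = FALSE]
    seqs <- seqs[!bad]
  }

  trimmed <- vapply(seqs, .trim_at_stop, character(1), USE.NAMES = FALSE)
  changed <- nchar(trimmed) < nchar(seqs)
  for (i in which(changed)) {
    say("trimmed %s %s at first in-frame stop: %d -> %d nt",
        records$taxon[i], records$gene_id[i], nchar(seqs[i]), nchar(trimmed[i]))
  }
  records$sequence <- trimmed

  empty <- nchar(records$sequence) == 0
  if (any(empty)) {
    warn(sprintf("rejected %d record(s) empty after stop trimming", sum(empty)))
    records <- records[!empty, , drop = FALSE]
  }

  out <- records |>
    mutate(.ord = dplyr::row_number()) |>
    group_by(.data$taxon, .data$gene_id) |>
    arrange(dplyr::desc(nchar(.data$sequence)), .data$.ord, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")
  ndup <- nrow(records) - nrow(out)
  if (ndup > 0) say("dropped %d duplicate record(s), keeping the longest per gene", ndup)
  out
}

.trim_at_stop <- function(seq) {
  n3 <- (nchar(seq) %/% 3L) * 3L
  if (n3 == 0L) return(seq)
  codons <- substring(seq, seq.int(1L, n3, 3L), seq.int(3L, n3, 3L))
  stop_at <- which(codons %in% STOP_CODONS)
  if (length(stop_at) == 0) return(seq)
  substr(seq, 1L, (stop_at[1] - 1L) * 3L)
}

#' Read codon-aware gene alignments from aligned FASTA
#'
#' Each FASTA record header must follow the `taxon|gene_id` dialect (a
#' `header_sep` option accommodates other separators). `path` may be a single
#' multi-gene FASTA file or a directory of `.fa`/`.fasta` files. Within a
#' gene all sequences must have equal length, a multiple of 3, and use only
#' A/C/G/T/N/-.
#'
#' @param path FASTA file or directory of FASTA files.
#' @param header_sep Separator between taxon and gene id in headers.
#' @return A tibble with columns `gene_id`, `taxon`, `sequence`.
#' @export
read_alignments <- function(path, header_sep = "|") {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0) abort(sprintf("no FASTA files found at '%s'", path))
  recs <- purrr::map(files, function(f) {
    ss <- Biostrings::readBStringSet(f)
    tibble(header = names(ss), sequence = unname(toupper(as.character(ss))))
  }) |> list_rbind()

  parts <- strsplit(recs$header, header_sep, fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort(sprintf("malformed header (expected 'taxon%sgene_id'): %s",
                  header_sep, recs$header[which(lengths(parts) != 2)[1]]))
  }
  aln <- tibble(
    gene_id = map_chr(parts, 2),
    taxon = map_chr(parts, 1),
    sequence = recs$sequence
  )
  validate_alignments(aln)
  aln
}

#' Validate an alignment table
#'
#' Checks the `GeneAlignment` invariants: per gene, all sequences equal
#' length, length a multiple of 3, alphabet within A/C/G/T/N/-.
#'
#' @param alignments Tibble with columns `gene_id`, `taxon`, `sequence`.
#' @return The input, invisibly.
#' @export
validate_alignments <- function(alignments) {
  .assert_cols(alignments, c("gene_id", "taxon", "sequence"), "`alignments`")
  for (g in split(alignments, alignments$gene_id)) {
    lens <- nchar(g$sequence)
    if (length(unique(lens)) != 1) {
      abort(sprintf("ragged alignment in gene %s: lengths %s",
                    g$gene_id[1], paste(unique(lens), collapse = ", ")))
    }
    if (lens[1] %% 3L != 0L) {
      abort(sprintf("alignment length %d of gene %s is not a multiple of 3",
                    lens[1], g$gene_id[1]))
    }
    bad <- regexpr("[^ACGTN-]", g$sequence)
    if (any(bad > 0)) {
      i <- which(bad > 0)[1]
      abort(sprintf("unknown character in gene %s, taxon %s, column %d",
                    g$gene_id[1], g$taxon[i], bad[i]))
    }
    if (anyDuplicated(g$taxon)) {
      abort(sprintf("duplicated taxon in gene %s", g$gene_id[1]))
    }
  }
  invisible(alignments)
}

#' Write gene alignments to FASTA
#'
#' Headers use the `taxon|gene_id` dialect read by [read_alignments()].
#'
#' @param alignments Alignment tibble.
#' @param path Output FASTA file path.
#' @param header_sep Header separator.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path, header_sep = "|") {
  ss <- Biostrings::BStringSet(alignments$sequence)
  names(ss) <- paste0(alignments$taxon, header_sep, alignments$gene_id)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an editing-site table
#'
#' Reads a TSV with columns `species`, `gene`, `position`, `base`, `level`,
#' `coverage` and optional `tissue`. Positions are 1-based transcript
#' (ungapped) coordinates and are kept 1-based internally. Each record is
#' checked against the species' ungapped sequence in `alignments`: records
#' whose base is not A or does not match the sequence are dropped with a
#' warning (their count is stored in the `n_dropped` attribute). Editing
#' levels outside [0, 1] or non-positive positions are an error.
#'
#' @param path TSV file. Lines starting with `#` are ignored.
#' @param alignments Alignment tibble used for sequence checks.
#' @return Tibble `species`, `gene_id`, `position`, `base`, `level`,
#'   `coverage`, `tissue`, with attribute `n_dropped`.
#' @export
read_editing_sites <- function(path, alignments) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  .assert_cols(raw, c("species", "gene", "position", "base", "level", "coverage"),
               "editing-site table")
  sites <- tibble(
    species = as.character(raw$species),
    gene_id = as.character(raw$gene),
    position = as.integer(raw$position),
    base = toupper(as.character(raw$base)),
    level = as.numeric(raw$level),
    coverage = as.integer(raw$coverage),
    tissue = if ("tissue" %in% names(raw)) as.character(raw$tissue) else NA_character_
  )
  if (any(sites$level < 0 | sites$level > 1, na.rm = TRUE) || anyNA(sites$level)) {
    abort("editing levels must lie in [0, 1]")
  }
  if (any(sites$position < 1L, na.rm = TRUE)) abort("positions must be >= 1 (1-based)")
  if (any(sites$coverage < 0L, na.rm = TRUE)) abort("read coverage must be non-negative")
  validate_editing_sites(sites, alignments)
}

#' Check editing sites against the aligned sequences
#'
#' Drops (with a warning) records whose base is not A or whose stated base
#' does not match the species' ungapped transcript sequence at that
#' position; positions beyond the transcript are dropped likewise. The
#' number of dropped records is attached as attribute `n_dropped`.
#'
#' @param sites Editing-site tibble (`species`, `gene_id`, `position`,
#'   `base`, ...).
#' @param alignments Alignment tibble.
#' @return The validated tibble.
#' @export
validate_editing_sites <- function(sites, alignments) {
  ungapped <- alignments |>
    mutate(ungapped = gsub("-", "", .data$sequence, fixed = TRUE)) |>
    select("gene_id", "taxon", "ungapped")
  keyed <- sites |>
    left_join(ungapped, by = c(gene_id = "gene_id", species = "taxon"))
  at <- substr(keyed$ungapped, keyed$position, keyed$position)
  ok <- !is.na(keyed$ungapped) & keyed$base == "A" & at == "A"
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    warn(sprintf("dropped %d editing record(s) failing the genomic-A check", n_drop))
  }
  out <- sites[ok, , drop = FALSE]
  attr(out, "n_dropped") <- n_drop
  out
}

#' Write an editing-site table as TSV
#'
#' Positions are written 1-based (the same convention used internally). A
#' `#`-prefixed metadata line records the coordinate convention.
#'
#' @param sites Editing-site tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_editing_sites <- function(sites, path) {
  writeLines("# editevo editing sites; positions are 1-based transcript coordinates",
             path)
  out <- sites |>
    transmute(species = .data$species, gene = .data$gene_id,
              position = .data$position, base = .data$base,
              level = .data$level, coverage = .data$coverage,
              tissue = .data$tissue)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a gene-group table
#'
#' TSV with columns `gene` (or `gene_id`) and `group`; groups must be one of
#' `high_neural`, `low_neural`, `unassigned`, and each gene may appear once.
#'
#' @param path TSV path.
#' @return Tibble `gene_id`, `group`.
#' @export
read_gene_groups <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  gene_col <- intersect(c("gene_id", "gene"), names(raw))[1]
  if (is.na(gene_col) || !"group" %in% names(raw)) {
    abort("gene-group table needs columns 'gene' (or 'gene_id') and 'group'")
  }
  out <- tibble(gene_id = as.character(raw[[gene_col]]),
                group = as.character(raw$group))
  bad <- setdiff(unique(out$group), c("high_neural", "low_neural", "unassigned"))
  if (length(bad) > 0) {
    abort(sprintf("unknown gene group(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(out$gene_id)) abort("gene ids must be unique in the gene-group table")
  out
}

#' Read and root a species tree
#'
#' Reads a Newick tree and roots it on the branch separating the outgroup
#' taxa from the ingroup, so that the ingroup forms a clade under the root.
#' Interior nodes without labels get stable ids `n1`, `n2`, ... (root-first
#' numbering).
#'
#' @param path Newick file path, or a Newick string.
#' @param outgroups Character vector of outgroup tip labels.
#' @return A rooted `ape::phylo` with unique interior node labels and
#'   attribute `outgroups`.
#' @export
read_tree <- function(path, outgroups) {
  tree <- if (grepl("\\(", path)) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tree)) abort("could not parse Newick tree")
  if (length(tree$tip.label) < 3) abort("tree too small: need at least 3 tips")
  missing <- setdiff(outgroups, tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("outgroup taxa not in tree: %s", paste(missing, collapse = ", ")))
  }
  ingroup <- setdiff(tree$tip.label, outgroups)
  if (length(ingroup) < 2) abort("need at least 2 ingroup taxa")
  tree <- ape::unroot(tree)
  if (!ape::is.monophyletic(tree, ingroup)) {
    abort("ingroup is not monophyletic given these outgroups; cannot root")
  }
  tree <- ape::root(tree, outgroup = ingroup, resolve.root = TRUE)
  nn <- tree$Nnode
  if (is.null(tree$node.label) || any(tree$node.label == "") || anyNA(tree$node.label) ||
      anyDuplicated(tree$node.label)) {
    tree$node.label <- paste0("n", seq_len(nn))
  }
  attr(tree, "outgroups") <- outgroups
  tree
}

#' Interior nodes ancestral to each tip
#'
#' For each requested tip, the set of interior node labels on its path to
#' the root (the root included). On the six-taxon mollusk topology rooted on
#' the two outgroups this yields exactly three interior nodes per coleoid.
#'
#' @param tree Rooted `phylo` with node labels.
#' @param tips Tip labels (default: all non-outgroup tips).
#' @return Named list of character vectors of node labels.
#' @export
ancestral_node_sets <- function(tree, tips = NULL) {
  og <- attr(tree, "outgroups") %||% character(0)
  if (is.null(tips)) tips <- setdiff(tree$tip.label, og)
  ntip <- length(tree$tip.label)
  stats::setNames(lapply(tips, function(tp) {
    i <- match(tp, tree$tip.label)
    if (is.na(i)) abort(sprintf("tip '%s' not in tree", tp))
    anc <- phangorn::Ancestors(tree, i, type = "all")
    tree$node.label[anc - ntip]
  }), tips)
}

#' Interior nodes ancestral to a clade's most recent common ancestor
#'
#' @param tree Rooted `phylo` with node labels.
#' @param clade Character vector of two or more tip labels.
#' @return Character vector of interior node labels strictly ancestral to
#'   the clade MRCA (root included).
#' @export
mrca_ancestor_set <- function(tree, clade) {
  if (length(clade) < 2) abort("clade must contain at least 2 tips")
  ntip <- length(tree$tip.label)
  m <- ape::getMRCA(tree, clade)
  anc <- phangorn::Ancestors(tree, m, type = "all")
  tree$node.label[anc - ntip]
}

#' Check that tree tips match alignment taxa
#'
#' @param tree `phylo` tree.
#' @param alignments Alignment tibble.
#' @return Invisibly `TRUE`; errors listing taxa present in the tree but
#'   absent from the alignments.
#' @export
validate_taxa <- function(tree, alignments) {
  missing <- setdiff(tree$tip.label, unique(alignments$taxon))
  if (length(missing) > 0) {
    abort(sprintf("tree tips missing from alignments: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# Map ungapped transcript positions (1-based) to alignment columns for one
# aligned sequence. Returns an integer vector over transcript positions.
.transcript_to_column <- function(aligned_chars) {
  which(aligned_chars != "-")
}
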