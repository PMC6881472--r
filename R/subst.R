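# Parse a nucleotide change class like "G>A", "CT>A", "G>CT" into source and
# target base sets (or pass through a list(src=, tgt=)).
.parse_class <- function(class) {
  if (is.list(class)) {
    stopifnot(all(c("src", "tgt") %in% names(class)))
    return(list(src = toupper(class$src), tgt = toupper(class$tgt),
                label = paste0(paste(class$src, collapse = "/"), ">",
                               paste(class$tgt, collapse = "/"))))
  }
  parts <- strsplit(toupper(class), ">", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort(sprintf("cannot parse change class '%s'", class))
  list(src = strsplit(parts[1], "")[[1]], tgt = strsplit(parts[2], "")[[1]],
       label = class)
}

#' Count class-restricted substitution opportunities and events on a branch
#'
#' For a single branch, counts per-position opportunities ("sites") and
#' observed substitutions of a nucleotide change class (e.g. `"G>A"`),
#' split into synonymous and nonsynonymous according to the parent codon
#' context. At every position whose parent state is a source base of the
#' class, each class target is evaluated by substituting it into the parent
#' codon: this contributes one site of the corresponding kind, and one
#' substitution when the child carries exactly that change. Codons with more
#' than one differing position between parent and child are excluded
#' entirely (substitution-path ambiguity), as are codons containing gaps,
#' `N` or `?`, and changes involving stop codons. Positions where `mask` is
#' `FALSE` are skipped.
#'
#' @param parent,child Aligned sequences (strings or character vectors) of
#'   the parent node and child node/tip; equal length, a multiple of 3.
#' @param class Change class: `"G>A"`, `"CT>A"`, `"G>CT"`, a similar
#'   string, or `list(src=, tgt=)`.
#' @param mask Optional logical vector (length of the sequence); positions
#'   with `FALSE` are skipped (see [conserved_site_mask()]).
#' @return One-row tibble: `nonsyn_sites`, `syn_sites`, `nonsyn_subs`,
#'   `syn_subs`.
#' @export
count_branch_changes <- function(parent, child, class = "G>A", mask = NULL) {
  cl <- .parse_class(class)
  p <- if (length(parent) == 1L) .chars(parent) else parent
  ch <- if (length(child) == 1L) .chars(child) else child
  if (length(p) != length(ch)) abort("parent and child sequences differ in length")
  if (length(p) %% 3L != 0L) abort("sequence length must be a multiple of 3")
  m <- .class_change_counts(.base_int(p), .base_int(ch),
                            .base_int(cl$src), .base_int(cl$tgt), mask,
                            gene_of = NULL, n_genes = 1L)
  tibble(nonsyn_sites = m[1, 1], syn_sites = m[1, 2],
         nonsyn_subs = m[1, 3], syn_subs = m[1, 4])
}

# Shared counting core on integer-encoded sequences (possibly several genes
# concatenated; gene_of maps positions to gene indices). Returns an
# n_genes x 4 matrix: nonsyn_sites, syn_sites, nonsyn_subs, syn_subs.
.class_change_counts <- function(pi, ci, src_int, tgt_int, mask = NULL,
                                 gene_of = NULL, n_genes = 1L) {
  L <- length(pi)
  ncod <- L %/% 3L
  pm <- matrix(pi, nrow = 3)
  codon_ok <- colSums(is.na(pm)) == 0L &
    colSums(is.na(matrix(ci, nrow = 3))) == 0L
  diff <- pi != ci
  diff[is.na(diff)] <- FALSE
  ndiff <- colSums(matrix(diff, nrow = 3))
  keep_codon <- codon_ok & ndiff <= 1L
  codint <- .codon_int(pm[1, ], pm[2, ], pm[3, ])
  aa_par <- AA64[codint]

  codon_of <- rep(seq_len(ncod), each = 3L)
  k <- rep(1:3, times = ncod)
  pow <- c(16L, 4L, 1L)
  out <- matrix(0L, nrow = n_genes, ncol = 4)
  src_pos <- !is.na(pi) & pi %in% src_int & keep_codon[codon_of]
  if (!is.null(mask)) src_pos <- src_pos & mask
  for (t in tgt_int) {
    idx <- which(src_pos & pi != t)
    if (length(idx) == 0) next
    cidx <- codon_of[idx]
    mutint <- codint[cidx] + (t - pi[idx]) * pow[k[idx]]
    aa_mut <- AA64[mutint]
    ok <- aa_par[cidx] != "*" & aa_mut != "*"
    idx <- idx[ok]; cidx <- cidx[ok]; aa_mut <- aa_mut[ok]
    if (length(idx) == 0) next
    nonsyn <- aa_mut != aa_par[cidx]
    is_sub <- ci[idx] == t & pi[idx] != t
    if (is.null(gene_of)) {
      out[1, ] <- out[1, ] + c(sum(nonsyn), sum(!nonsyn),
                               sum(nonsyn & is_sub), sum(!nonsyn & is_sub))
    } else {
      gk <- gene_of[idx]
      out[, 1] <- out[, 1] + tabulate(gk[nonsyn], nbins = n_genes)
      out[, 2] <- out[, 2] + tabulate(gk[!nonsyn], nbins = n_genes)
      out[, 3] <- out[, 3] + tabulate(gk[nonsyn & is_sub], nbins = n_genes)
      out[, 4] <- out[, 4] + tabulate(gk[!nonsyn & is_sub], nbins = n_genes)
    }
  }
  out
}

# Label for a node/tip number of an ape tree.
.node_label <- function(tree, num) {
  c(tree$tip.label, tree$node.label)[num]
}

#' Branches descending from a clade's most recent common ancestor
#'
#' On the six-taxon mollusk tree with a four-coleoid ingroup this returns
#' the six coleoid branches used for the class-restricted dN/dS contrast.
#'
#' @param tree Rooted `phylo`.
#' @param clade Tip labels of the ingroup (default: all non-outgroup tips).
#' @return Tibble with columns `parent` and `child` (node/tip labels).
#' @export
coleoid_branches <- function(tree, clade = NULL) {
  og <- attr(tree, "outgroups") %||% character(0)
  if (is.null(clade)) clade <- setdiff(tree$tip.label, og)
  m <- ape::getMRCA(tree, clade)
  desc <- phangorn::Descendants(tree, m, type = "all")
  keep <- tree$edge[, 1] %in% c(m, desc) & tree$edge[, 2] %in% desc
  tibble(parent = .node_label(tree, tree$edge[keep, 1]),
         child = .node_label(tree, tree$edge[keep, 2]))
}

#' Outgroup-conservation mask for a branch
#'
#' Marks positions at which the two outgroup tips and the branch's parent
#' node share the same (unambiguous) pre-editing state. Restricting
#' substitution counts to such conserved positions focuses the dN/dS test on
#' sites where a change is likely deleterious without editing.
#'
#' @param parent_chars Parent-node aligned sequence (character vector).
#' @param outgroup_chars_list List of the outgroup tips' aligned sequences
#'   (character vectors).
#' @return Logical vector over alignment positions.
#' @export
conserved_site_mask <- function(parent_chars, outgroup_chars_list) {
  ok <- parent_chars %in% BASES
  for (oc in outgroup_chars_list) {
    ok <- ok & oc == parent_chars
  }
  ok
}

#' Per-gene, per-branch class-restricted substitution counts
#'
#' Applies [count_branch_changes()] to every gene and branch, optionally
#' restricted to positions conserved in the outgroups
#' ([conserved_site_mask()]). With `mask_scope = "nonsyn"` the conservation
#' filter applies to nonsynonymous opportunities and substitutions only,
#' while synonymous counts are taken unmasked.
#'
#' @param alignments Alignment tibble.
#' @param ancestry Ancestral assignment tibble.
#' @param tree Rooted `phylo` (with `outgroups` attribute for the
#'   conservation mask).
#' @param classes Character vector of change classes.
#' @param branches Tibble `parent`, `child` (default:
#'   [coleoid_branches()]).
#' @param conserved Apply the outgroup-conservation mask.
#' @param mask_scope `"both"` (default) or `"nonsyn"`.
#' @return Tibble `gene_id`, `parent`, `child`, `class`, `nonsyn_sites`,
#'   `syn_sites`, `nonsyn_subs`, `syn_subs`.
#' @export
branch_counts <- function(alignments, ancestry, tree, classes = "G>A",
                          branches = NULL, conserved = TRUE,
                          mask_scope = c("both", "nonsyn")) {
  mask_scope <- match.arg(mask_scope)
  if (is.null(branches)) branches <- coleoid_branches(tree)
  og <- attr(tree, "outgroups") %||% character(0)
  if (conserved && length(og) < 1) {
    abort("conserved mask requested but the tree has no outgroups attribute")
  }
  # concatenate genes and count once per branch and class, aggregating the
  # per-position contributions back to genes
  genes <- split(alignments, alignments$gene_id)
  gene_ids <- names(genes)
  n_genes <- length(gene_ids)
  glen <- map_int(genes, ~ nchar(.x$sequence[1]))
  gene_of <- rep(seq_len(n_genes), times = glen)
  anc_split <- split(ancestry, ancestry$gene_id)
  missing_anc <- setdiff(gene_ids, names(anc_split))
  if (length(missing_anc) > 0) {
    abort(sprintf("gene(s) absent from ancestral assignment: %s",
                  paste(head(missing_anc, 5), collapse = ", ")))
  }
  tip_labels <- unique(alignments$taxon)
  concat_chars <- local({
    cache <- list()
    function(label) {
      if (!is.null(cache[[label]])) return(cache[[label]])
      v <- if (label %in% tip_labels) {
        .chars(paste(map_chr(gene_ids, function(gid) {
          g <- genes[[gid]]
          s <- g$sequence[match(label, g$taxon)]
          if (is.na(s)) s <- strrep("-", nchar(g$sequence[1]))
          s
        }), collapse = ""))
      } else {
        .chars(paste(map_chr(gene_ids, function(gid) {
          a <- anc_split[[gid]]
          s <- a$sequence[match(label, a$node_id)]
          if (is.na(s)) abort(sprintf("no sequence for node/tip '%s' in gene %s",
                                      label, gid))
          s
        }), collapse = ""))
      }
      cache[[label]] <<- v
      v
    }
  })
  og_chars <- lapply(og, concat_chars)
  cls_parsed <- lapply(classes, .parse_class)

  purrr::map(seq_len(nrow(branches)), function(b) {
    pc <- concat_chars(branches$parent[b])
    cc <- concat_chars(branches$child[b])
    p_int <- .base_int(pc)
    c_int <- .base_int(cc)
    mask <- if (conserved) conserved_site_mask(pc, og_chars) else NULL
    purrr::map(cls_parsed, function(cl) {
      src <- .base_int(cl$src); tgt <- .base_int(cl$tgt)
      m <- .class_change_counts(p_int, c_int, src, tgt, mask, gene_of, n_genes)
      if (mask_scope == "nonsyn" && conserved) {
        open <- .class_change_counts(p_int, c_int, src, tgt, NULL, gene_of, n_genes)
        m[, 2] <- open[, 2]
        m[, 4] <- open[, 4]
      }
      tibble(gene_id = gene_ids, parent = branches$parent[b],
             child = branches$child[b], class = cl$label,
             nonsyn_sites = m[, 1], syn_sites = m[, 2],
             nonsyn_subs = m[, 3], syn_subs = m[, 4])
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Pooled class-restricted dN/dS
#'
#' Pools counts over genes and branches (within each change class) and
#' computes dN = total nonsynonymous substitutions / total nonsynonymous
#' sites, dS likewise, and their ratio (the total-dN over total-dS
#' convention). The ratio is `NA` when dS is undefined or zero.
#'
#' @param counts Counts tibble from [branch_counts()].
#' @return Tibble per class: pooled counts, `dn`, `ds`, `dnds`.
#' @export
class_dnds <- function(counts) {
  if (nrow(counts) == 0) abort("empty counts table")
  counts |>
    group_by(.data$class) |>
    summarise(nonsyn_subs = sum(.data$nonsyn_subs),
              nonsyn_sites = sum(.data$nonsyn_sites),
              syn_subs = sum(.data$syn_subs),
              syn_sites = sum(.data$syn_sites), .groups = "drop") |>
    mutate(dn = ifelse(.data$nonsyn_sites > 0,
                       .data$nonsyn_subs / .data$nonsyn_sites, NA_real_),
           ds = ifelse(.data$syn_sites > 0,
                       .data$syn_subs / .data$syn_sites, NA_real_),
           dnds = ifelse(!is.na(.data$ds) & .data$ds > 0,
                         .data$dn / .data$ds, NA_real_))
}

.pooled_ratio <- function(m) {
  # m: matrix with columns nonsyn_subs, nonsyn_sites, syn_subs, syn_sites
  s <- colSums(m)
  if (s[["nonsyn_sites"]] == 0 || s[["syn_sites"]] == 0 || s[["syn_subs"]] == 0) {
    return(NA_real_)
  }
  (s[["nonsyn_subs"]] / s[["nonsyn_sites"]]) / (s[["syn_subs"]] / s[["syn_sites"]])
}

#' Gene bootstrap contrast of pooled dN/dS between two gene groups
#'
#' Resamples genes with replacement within each group `B` times (default
#' 200), recomputes the pooled dN/dS per group in each replicate and reports
#' the two-sided bootstrap P value for the group contrast:
#' `P = 2 * min(frac(ratio_high <= ratio_low), frac(ratio_high >= ratio_low))`,
#' floored at `1/B` and capped at 1. A one-sided P (high > low) is reported
#' alongside. Replicates where either pooled ratio is undefined are dropped
#' (their number is recorded).
#'
#' @param counts Counts tibble from [branch_counts()] restricted to a single
#'   change class.
#' @param gene_groups Tibble `gene_id`, `group` with groups `high_neural`
#'   and `low_neural`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return An object of class `dnds_boot`; see also [tidy()] and
#'   [glance()] methods.
#' @export
bootstrap_dnds <- function(counts, gene_groups, B = 200, seed) {
  if (missing(seed)) abort("`seed` is required for bootstrap_dnds()")
  if (length(unique(counts$class)) > 1) {
    abort("counts must be restricted to a single change class")
  }
  per_gene <- counts |>
    group_by(.data$gene_id) |>
    summarise(nonsyn_subs = sum(.data$nonsyn_subs),
              nonsyn_sites = sum(.data$nonsyn_sites),
              syn_subs = sum(.data$syn_subs),
              syn_sites = sum(.data$syn_sites), .groups = "drop") |>
    inner_join(gene_groups, by = "gene_id")
  mats <- lapply(c(high = "high_neural", low = "low_neural"), function(grp) {
    m <- per_gene |> filter(.data$group == grp)
    if (nrow(m) < 2) abort(sprintf("group %s has fewer than 2 genes", grp))
    as.matrix(m[, c("nonsyn_subs", "nonsyn_sites", "syn_subs", "syn_sites")])
  })
  obs_high <- .pooled_ratio(mats$high)
  obs_low <- .pooled_ratio(mats$low)

  boot <- withr::with_seed(seed, {
    rh <- rl <- numeric(B)
    nh <- nrow(mats$high); nl <- nrow(mats$low)
    for (b in seq_len(B)) {
      rh[b] <- .pooled_ratio(mats$high[sample.int(nh, nh, replace = TRUE), , drop = FALSE])
      rl[b] <- .pooled_ratio(mats$low[sample.int(nl, nl, replace = TRUE), , drop = FALSE])
    }
    tibble(replicate = seq_len(B), ratio_high = rh, ratio_low = rl)
  })
  valid <- !is.na(boot$ratio_high) & !is.na(boot$ratio_low)
  d <- boot$ratio_high[valid] - boot$ratio_low[valid]
  if (length(d) == 0) abort("all bootstrap replicates had undefined dN/dS")
  p_low <- mean(d <= 0)
  p_high <- mean(d >= 0)
  p_two <- min(1, max(2 * min(p_low, p_high), 1 / B))
  p_one <- max(p_low, 1 / B)

  structure(list(
    observed = tibble(group = c("high_neural", "low_neural"),
                      dnds = c(obs_high, obs_low)),
    difference = obs_high - obs_low,
    boot = boot,
    p_two_sided = p_two,
    p_one_sided = p_one,
    B = B,
    seed = seed,
    n_dropped = sum(!valid),
    class_label = counts$class[1]
  ), class = "dnds_boot")
}

#' @export
print.dnds_boot <- function(x, ...) {
  cat(sprintf("Gene-bootstrap dN/dS contrast (%s), B = %d\n", x$class_label, x$B))
  cat(sprintf("  high_neural: %.4f   low_neural: %.4f   difference: %+.4f\n",
              x$observed$dnds[1], x$observed$dnds[2], x$difference))
  cat(sprintf("  P (two-sided) = %.4g   P (one-sided, high > low) = %.4g\n",
              x$p_two_sided, x$p_one_sided))
  invisible(x)
}
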