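#' Adaptive diversifying editing estimated from level-binned frequency excess
#'
#' Splits the editing-level range [0, 1] into `n_bins` equal intervals
#' (left-closed, right-open, the last closed). Within each bin the
#' diversifying and synonymous frequencies are computed with bin-restricted
#' numerators over the full potential-site denominators. For each bin with
#' F_D > F_S the number of adaptive diversifying sites is estimated as
#' `ADP = N_D * (1 - F_S / F_D)` where `N_D` is the number of diversifying
#' edited sites in the bin; bins with `F_D <= F_S` (or `F_D = 0`) contribute
#' 0. The total adaptive fraction is the summed ADP divided by the total
#' number of diversifying edited sites.
#'
#' The input tables may cover one species, a species-specific or shared
#' subset, or several species pooled; the estimate applies to whatever set
#' is passed in.
#'
#' @param classified Classified editing sites with `level` and `category`.
#' @param potential Potential-site tibble (denominators).
#' @param n_bins Number of equal editing-level bins (default 10).
#' @return An object of class `adp_estimate` with elements `bins` (tibble),
#'   `total_adp`, `n_diversifying` and `adaptive_fraction`.
#' @export
adp_by_bins <- function(classified, potential, n_bins = 10) {
  n_pot <- table(factor(potential$category,
                        levels = c("SYN", "RESTORATIVE", "DIVERSIFYING")))
  pot_d <- unname(n_pot[["DIVERSIFYING"]])
  pot_s <- unname(n_pot[["SYN"]])
  if (pot_d == 0 || pot_s == 0) {
    abort("need nonzero potential-site counts for SYN and DIVERSIFYING")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  binof <- function(x) pmin(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  div <- classified |> filter(.data$category == "DIVERSIFYING")
  syn <- classified |> filter(.data$category == "SYN")
  n_d <- tabulate(binof(div$level), nbins = n_bins)
  n_s <- tabulate(binof(syn$level), nbins = n_bins)
  f_d <- n_d / pot_d
  f_s <- n_s / pot_s
  adp <- ifelse(f_d > f_s & f_d > 0, n_d * (1 - f_s / f_d), 0)
  bins <- tibble(
    bin_lo = utils::head(breaks, -1), bin_hi = breaks[-1],
    n_diversifying = n_d, n_synonymous = n_s,
    f_diversifying = f_d, f_synonymous = f_s, adp = adp
  )
  structure(list(
    bins = bins,
    total_adp = sum(adp),
    n_diversifying = nrow(div),
    adaptive_fraction = if (nrow(div) > 0) sum(adp) / nrow(div) else NA_real_
  ), class = "adp_estimate")
}

#' @export
print.adp_estimate <- function(x, ...) {
  cat(sprintf("ADP estimate over %d level bins\n", nrow(x$bins)))
  cat(sprintf("  diversifying edited sites: %d\n", x$n_diversifying))
  cat(sprintf("  estimated adaptive sites:  %.2f (%.3f%%)\n",
              x$total_adp, 100 * x$adaptive_fraction))
  invisible(x)
}

#' Sites edited in the common ancestor of a clade
#'
#' By parsimony, an alignment column edited in at least `min_species` of the
#' clade members (default 3 of the 4 coleoids) was edited in their common
#' ancestor. Edited members are required to share identical pre- and
#' post-editing amino-acid states (`require_identity = FALSE` relaxes this).
#' The event category (SYN / RESTORATIVE / DIVERSIFYING / EXCLUDED) is
#' computed against the interior nodes ancestral to the clade MRCA. For
#' every clade member the edited status and its genomic base at the column
#' are recorded, which feeds the replacement analysis.
#'
#' @param classified Classified editing sites (with `column`, `pre_aa`,
#'   `post_aa`) covering the clade species.
#' @param alignments Alignment tibble.
#' @param tree Rooted `phylo`.
#' @param ancestry Ancestral assignment tibble.
#' @param clade Clade tip labels (default: non-outgroup tips).
#' @param min_species Minimum number of edited clade members.
#' @param require_identity Require identical pre/post amino-acid states
#'   among the edited members.
#' @return Long tibble: one row per (event, clade member) with `gene_id`,
#'   `column`, `pre_aa`, `post_aa`, `category`, `n_edited`, `species`,
#'   `edited`, `genomic_base`.
#' @export
infer_ancestral_editing <- function(classified, alignments, tree, ancestry,
                                    clade = NULL, min_species = 3,
                                    require_identity = TRUE) {
  og <- attr(tree, "outgroups") %||% character(0)
  if (is.null(clade)) clade <- setdiff(tree$tip.label, og)
  nodes <- mrca_ancestor_set(tree, clade)

  ed <- classified |>
    filter(.data$species %in% clade, !is.na(.data$pre_aa), !is.na(.data$post_aa))
  if (nrow(ed) == 0) return(tibble())
  events <- ed |>
    group_by(.data$gene_id, .data$column, .data$codon_index) |>
    summarise(n_edited = dplyr::n_distinct(.data$species),
              pre_aa = .data$pre_aa[1], post_aa = .data$post_aa[1],
              identical_states = dplyr::n_distinct(.data$pre_aa) == 1 &&
                dplyr::n_distinct(.data$post_aa) == 1,
              .groups = "drop") |>
    filter(.data$n_edited >= min_species)
  if (require_identity) events <- filter(events, .data$identical_states)
  if (nrow(events) == 0) return(tibble())

  anc_split <- split(ancestry, ancestry$gene_id)
  aln_split <- split(alignments, alignments$gene_id)
  edited_key <- paste(ed$species, ed$gene_id, ed$column, sep = "\r")

  purrr::map(split(events, events$gene_id), function(ev) {
    gid <- ev$gene_id[1]
    anc_g <- anc_split[[gid]]
    g <- aln_split[[gid]]
    if (is.null(anc_g) || is.null(g)) {
      abort(sprintf("gene %s missing from ancestry or alignments", gid))
    }
    c0 <- (ev$codon_index - 1L) * 3L + 1L
    in_anc <- rep(FALSE, nrow(ev))
    amb <- rep(FALSE, nrow(ev))
    for (nd in nodes) {
      anc <- .chars(anc_g$sequence[match(nd, anc_g$node_id)])
      acod <- paste0(anc[c0], anc[c0 + 1L], anc[c0 + 2L])
      aaa <- unname(CODON_AA[acod])
      amb <- amb | is.na(aaa) | (!is.na(aaa) & aaa == "*")
      in_anc <- in_anc | (!is.na(aaa) & aaa == ev$post_aa)
    }
    category <- ifelse(amb, "EXCLUDED",
                       ifelse(ev$pre_aa == ev$post_aa, "SYN",
                              ifelse(in_anc, "RESTORATIVE", "DIVERSIFYING")))
    tip_chars <- lapply(stats::setNames(g$sequence, g$taxon), .chars)
    purrr::map(seq_len(nrow(ev)), function(i) {
      base <- map_chr(clade, function(sp) {
        mc <- tip_chars[[sp]]
        if (is.null(mc)) NA_character_ else mc[ev$column[i]]
      })
      tibble(gene_id = gid, column = ev$column[i],
             pre_aa = ev$pre_aa[i], post_aa = ev$post_aa[i],
             category = category[i], n_edited = ev$n_edited[i],
             species = clade,
             edited = paste(clade, gid, ev$column[i], sep = "\r") %in% edited_key,
             genomic_base = base)
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Replacement of ancestral editing by genomic substitution
#'
#' For sites edited in the common ancestor of a clade (see
#' [infer_ancestral_editing()]), a site counts as replaced when at least one
#' clade member is unedited there and carries a genomic G (the edited
#' state). Members with a gap at the column are skipped. The 2x2 table
#' (nonsynonymous vs synonymous) x (replaced vs retained) is tested with a
#' two-tailed Fisher's exact test. The same computation with genomic C or T
#' in unedited members serves as a control (such replacements cannot be
#' produced by fixing the edited state).
#'
#' @param anc_edit Long tibble from [infer_ancestral_editing()].
#' @param diversifying_only Restrict the nonsynonymous row to diversifying
#'   events.
#' @return An object of class `replacement_test` with elements `table`,
#'   `p_value`, `control_table`, `control_p` and `fractions`.
#' @export
replacement_analysis <- function(anc_edit, diversifying_only = FALSE) {
  if (nrow(anc_edit) == 0) abort("empty ancestral editing set")
  ev <- anc_edit |>
    filter(!is.na(.data$genomic_base), .data$genomic_base != "-") |>
    group_by(.data$gene_id, .data$column) |>
    summarise(
      pre_aa = .data$pre_aa[1], post_aa = .data$post_aa[1],
      category = .data$category[1],
      replaced_g = any(!.data$edited & .data$genomic_base == "G"),
      replaced_ct = any(!.data$edited & .data$genomic_base %in% c("C", "T")),
      .groups = "drop"
    ) |>
    mutate(kind = ifelse(.data$pre_aa == .data$post_aa, "synonymous", "nonsynonymous"))
  if (diversifying_only) {
    ev <- filter(ev, .data$kind == "synonymous" | .data$category == "DIVERSIFYING")
  }
  mk_table <- function(flag) {
    ns <- ev$kind == "nonsynonymous"
    m <- rbind(nonsynonymous = c(sum(flag & ns), sum(!flag & ns)),
               synonymous = c(sum(flag & !ns), sum(!flag & !ns)))
    colnames(m) <- c("replaced", "retained")
    m
  }
  tab <- mk_table(ev$replaced_g)
  ctl <- mk_table(ev$replaced_ct)
  ftest <- function(m) {
    if (any(rowSums(m) == 0)) return(NA_real_)
    fisher.test(m, alternative = "two.sided")$p.value
  }
  fractions <- tibble(
    kind = rownames(tab),
    n = rowSums(tab),
    n_replaced = tab[, "replaced"],
    fraction_replaced = ifelse(rowSums(tab) > 0, tab[, "replaced"] / rowSums(tab),
                               NA_real_)
  )
  structure(list(
    table = tab, p_value = ftest(tab),
    control_table = ctl, control_p = ftest(ctl),
    fractions = fractions,
    diversifying_only = diversifying_only
  ), class = "replacement_test")
}

#' @export
print.replacement_test <- function(x, ...) {
  cat("Replacement of ancestral editing by A-to-G substitution",
      if (x$diversifying_only) "(diversifying only)" else "", "\n")
  print(x$table)
  cat(sprintf("  two-tailed Fisher P = %.4g (A-to-C/T control P = %.4g)\n",
              x$p_value, x$control_p))
  invisible(x)
}
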