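#' Enumerate potential editing sites for each species
#'
#' For every genomic A in each focal species' aligned coding sequence, the A
#' is substituted by G (that position only), the codon is retranslated, and
#' the site is assigned a potential category:
#'
#' * `SYN` — the change is synonymous;
#' * `RESTORATIVE` — nonsynonymous, and the post-editing amino acid equals
#'   the state at at least one interior node ancestral to the species;
#' * `DIVERSIFYING` — nonsynonymous, and the post-editing amino acid matches
#'   no ancestral state;
#' * `EXCLUDED` — the species codon contains a gap or N, a stop codon is
#'   involved pre- or post-editing or ancestrally, or any needed ancestral
#'   state is unresolved (`?`).
#'
#' The non-EXCLUDED categories partition all genomic A sites of the species.
#'
#' @param alignments Alignment tibble.
#' @param ancestry Ancestral assignment tibble (see
#'   [reconstruct_parsimony()] or [import_ancestral()]).
#' @param tree Rooted `phylo` with node labels.
#' @param species Focal species (default: all non-outgroup tips).
#' @return Tibble `species`, `gene_id`, `position` (1-based transcript
#'   coordinate), `column` (alignment column), `codon_index` (1-based, in
#'   alignment coordinates), `category`, `pre_aa`, `post_aa`.
#' @export
enumerate_potential_sites <- function(alignments, ancestry, tree, species = NULL) {
  og <- attr(tree, "outgroups") %||% character(0)
  if (is.null(species)) species <- setdiff(tree$tip.label, og)
  anc_sets <- ancestral_node_sets(tree, species)

  # categorize once per species on gene-concatenated sequences (every gene
  # length is a multiple of 3, so codon frames are preserved), then map the
  # global coordinates back to per-gene ones
  genes <- split(alignments, alignments$gene_id)
  gene_ids <- names(genes)
  glen <- map_int(genes, ~ nchar(.x$sequence[1]))
  offset <- cumsum(c(0L, glen))
  anc_split <- split(ancestry, ancestry$gene_id)
  missing_anc <- setdiff(gene_ids, names(anc_split))
  if (length(missing_anc) > 0) {
    abort(sprintf("gene(s) absent from ancestral assignment: %s",
                  paste(head(missing_anc, 5), collapse = ", ")))
  }
  nodes_needed <- unique(unlist(anc_sets))
  anc_concat <- lapply(stats::setNames(nodes_needed, nodes_needed), function(nd) {
    .chars(paste(map_chr(gene_ids, function(gid) {
      a <- anc_split[[gid]]
      s <- a$sequence[match(nd, a$node_id)]
      if (is.na(s)) abort(sprintf("node %s absent from ancestry of gene %s", nd, gid))
      s
    }), collapse = ""))
  })

  purrr::map(species, function(sp) {
    tip_concat <- .chars(paste(map_chr(gene_ids, function(gid) {
      g <- genes[[gid]]
      s <- g$sequence[match(sp, g$taxon)]
      if (is.na(s)) s <- strrep("-", nchar(g$sequence[1]))
      s
    }), collapse = ""))
    res <- .categorize_tip(sp, ".", tip_concat, anc_concat[anc_sets[[sp]]])
    if (is.null(res)) return(NULL)
    k <- findInterval(res$column - 0.5, offset)
    ng <- c(0L, cumsum(tip_concat != "-"))
    local_col <- res$column - offset[k]
    res$gene_id <- gene_ids[k]
    res$position <- res$position - ng[offset[k] + 1L]
    res$column <- local_col
    res$codon_index <- (local_col - 1L) %/% 3L + 1L
    res
  }) |> list_rbind()
}

# Core per-(species, gene) categorization of every genomic A.
# tip_chars: aligned sequence characters of the focal species;
# anc_chars_list: aligned character vectors of its ancestral nodes.
.categorize_tip <- function(sp, gid, tip_chars, anc_chars_list) {
  A_cols <- which(tip_chars == "A")
  if (length(A_cols) == 0) return(NULL)
  trans_pos <- cumsum(tip_chars != "-")[A_cols]
  codon_idx <- (A_cols - 1L) %/% 3L
  c0 <- codon_idx * 3L + 1L
  cod <- paste0(tip_chars[c0], tip_chars[c0 + 1L], tip_chars[c0 + 2L])
  pre_aa <- unname(CODON_AA[cod])
  pos_in <- A_cols - c0 + 1L
  post <- cod
  substr(post, pos_in, pos_in) <- "G"
  post_aa <- unname(CODON_AA[post])

  excluded <- is.na(pre_aa) | is.na(post_aa) | pre_aa == "*" | post_aa == "*"
  in_anc <- rep(FALSE, length(A_cols))
  for (anc in anc_chars_list) {
    acod <- paste0(anc[c0], anc[c0 + 1L], anc[c0 + 2L])
    aaa <- unname(CODON_AA[acod])
    excluded <- excluded | is.na(aaa) | (!is.na(aaa) & aaa == "*")
    in_anc <- in_anc | (!is.na(aaa) & !is.na(post_aa) & aaa == post_aa)
  }
  category <- ifelse(excluded, "EXCLUDED",
                     ifelse(pre_aa == post_aa, "SYN",
                            ifelse(in_anc, "RESTORATIVE", "DIVERSIFYING")))
  tibble(species = sp, gene_id = gid, position = trans_pos, column = A_cols,
         codon_index = codon_idx + 1L, category = category,
         pre_aa = pre_aa, post_aa = post_aa)
}

#' Classify observed editing sites
#'
#' Each edited site inherits the potential category of its position (each
#' site is classified assuming only that position is edited; co-edited codon
#' neighbours are ignored). Sites falling at `EXCLUDED` positions are kept
#' with category `EXCLUDED` and their count is stored in the `n_excluded`
#' attribute.
#'
#' @param sites Editing-site tibble (`species`, `gene_id`, `position`,
#'   `level`, `coverage`, ...).
#' @param potential Potential-site tibble from [enumerate_potential_sites()].
#' @return The sites tibble with added columns `column`, `codon_index`,
#'   `category`, `pre_aa`, `post_aa`.
#' @export
classify_editing_sites <- function(sites, potential) {
  out <- sites |>
    left_join(potential |>
                select("species", "gene_id", "position", "column",
                       "codon_index", "category", "pre_aa", "post_aa"),
              by = c("species", "gene_id", "position"))
  unmatched <- is.na(out$category)
  if (any(unmatched)) {
    warn(sprintf("%d editing site(s) did not map to an enumerated A site and were dropped",
                 sum(unmatched)))
    out <- out[!unmatched, , drop = FALSE]
  }
  attr(out, "n_excluded") <- sum(out$category == "EXCLUDED")
  out
}

#' Editing frequencies per category with chi-square comparisons
#'
#' Computes, per species, the fraction of potential sites that are edited in
#' each category (F_S, F_R, F_D) and compares restorative and diversifying
#' frequencies against the synonymous frequency with two-sided chi-square
#' tests on the 2x2 edited/not-edited table (no continuity correction by
#' default).
#'
#' @param classified Classified editing sites ([classify_editing_sites()]).
#' @param potential Potential-site tibble.
#' @param correct Apply Yates continuity correction.
#' @return A tibble of class `edit_freq_stats` with columns `species`,
#'   `category`, `n_potential`, `n_edited`, `frequency`, `chisq_stat`,
#'   `p_value` (`NA` for the SYN reference row and for skipped tests).
#' @export
category_frequencies <- function(classified, potential, correct = FALSE) {
  cats <- c("SYN", "RESTORATIVE", "DIVERSIFYING")
  pot <- potential |>
    filter(.data$category %in% cats) |>
    count(.data$species, .data$category, name = "n_potential")
  ed <- classified |>
    filter(.data$category %in% cats) |>
    count(.data$species, .data$category, name = "n_edited")
  grid <- tidyr::expand_grid(species = unique(potential$species), category = cats)
  stats_tbl <- grid |>
    left_join(pot, by = c("species", "category")) |>
    left_join(ed, by = c("species", "category")) |>
    mutate(n_potential = tidyr::replace_na(.data$n_potential, 0L),
           n_edited = tidyr::replace_na(.data$n_edited, 0L),
           frequency = ifelse(.data$n_potential > 0,
                              .data$n_edited / .data$n_potential, NA_real_))
  res <- stats_tbl |>
    group_by(.data$species) |>
    group_modify(function(d, key) {
      syn <- d[d$category == "SYN", ]
      d$chisq_stat <- NA_real_
      d$p_value <- NA_real_
      for (cat in c("RESTORATIVE", "DIVERSIFYING")) {
        i <- which(d$category == cat)
        if (syn$n_potential > 0 && d$n_potential[i] > 0) {
          tab <- rbind(c(d$n_edited[i], d$n_potential[i] - d$n_edited[i]),
                       c(syn$n_edited, syn$n_potential - syn$n_edited))
          if (all(rowSums(tab) > 0) && sum(tab[, 1]) + sum(tab[, 2]) > 0) {
            ct <- suppressWarnings(chisq.test(tab, correct = correct))
            d$chisq_stat[i] <- unname(ct$statistic)
            d$p_value[i] <- ct$p.value
          }
        }
      }
      d
    }) |>
    ungroup() |>
    mutate(category = factor(.data$category, levels = cats)) |>
    arrange(.data$species, .data$category)
  class(res) <- c("edit_freq_stats", class(res))
  res
}

#' Editing levels per category with Mann-Whitney comparisons
#'
#' Restricts edited sites to those covered by at least `min_coverage`
#' RNA-seq reads (default 400), then reports per species and category the
#' median editing level, the fraction of sites above configurable level
#' thresholds (defaults 5% and 20%), and two-sided Mann-Whitney U tests of
#' restorative and diversifying levels against synonymous levels (exact for
#' small samples without ties, normal approximation otherwise).
#'
#' @param classified Classified editing sites with `level` and `coverage`.
#' @param min_coverage Minimum read coverage for a site to enter the level
#'   comparison.
#' @param level_thresholds Editing-level thresholds for the reported
#'   exceedance fractions.
#' @return A tibble of class `edit_level_stats` with columns `species`,
#'   `category`, `n_sites`, `median_level`, one `frac_gt_*` column per
#'   threshold, `u_stat` and `p_value` (`NA` for SYN and skipped tests).
#' @export
category_levels <- function(classified, min_coverage = 400,
                            level_thresholds = c(0.05, 0.20)) {
  cats <- c("SYN", "RESTORATIVE", "DIVERSIFYING")
  kept <- classified |>
    filter(.data$category %in% cats, .data$coverage >= min_coverage)
  grid <- tidyr::expand_grid(species = unique(classified$species), category = cats)
  res <- grid |>
    group_by(.data$species) |>
    group_modify(function(d, key) {
      sp_levels <- lapply(stats::setNames(cats, cats), function(cat) {
        kept$level[kept$species == key$species & kept$category == cat]
      })
      syn <- sp_levels[["SYN"]]
      d$n_sites <- map_int(d$category, ~ length(sp_levels[[.x]]))
      d$median_level <- map_dbl(d$category, ~ {
        x <- sp_levels[[.x]]
        if (length(x) > 0) median(x) else NA_real_
      })
      for (thr in level_thresholds) {
        d[[sprintf("frac_gt_%g", thr * 100)]] <- map_dbl(d$category, ~ {
          x <- sp_levels[[.x]]
          if (length(x) > 0) mean(x > thr) else NA_real_
        })
      }
      d$u_stat <- NA_real_
      d$p_value <- NA_real_
      for (cat in c("RESTORATIVE", "DIVERSIFYING")) {
        x <- sp_levels[[cat]]
        if (length(x) > 0 && length(syn) > 0) {
          wt <- suppressWarnings(wilcox.test(x, syn, alternative = "two.sided"))
          i <- which(d$category == cat)
          d$u_stat[i] <- unname(wt$statistic)
          d$p_value[i] <- wt$p.value
        } else if (length(syn) == 0 || length(x) == 0) {
          warn(sprintf("empty level set for %s/%s after coverage filter; test skipped",
                       key$species, cat))
        }
      }
      d
    }) |>
    ungroup() |>
    mutate(category = factor(.data$category, levels = cats)) |>
    arrange(.data$species, .data$category)
  class(res) <- c("edit_level_stats", class(res))
  res
}

#' Map editing sites to alignment columns
#'
#' Adds the alignment `column` corresponding to each site's ungapped
#' transcript position in its species' aligned sequence.
#'
#' @param sites Editing-site tibble.
#' @param alignments Alignment tibble.
#' @return The sites tibble with a `column` column.
#' @export
site_columns <- function(sites, alignments) {
  key <- paste(alignments$taxon, alignments$gene_id, sep = "\r")
  seq_by_key <- stats::setNames(alignments$sequence, key)
  sites |>
    mutate(.key = paste(.data$species, .data$gene_id, sep = "\r")) |>
    group_by(.data$.key) |>
    group_modify(function(d, key) {
      seq <- seq_by_key[[key$.key]]
      if (is.null(seq)) abort(sprintf("no alignment for %s", gsub("\r", "/", key$.key)))
      cols <- .transcript_to_column(.chars(seq))
      d$column <- cols[d$position]
      d
    }) |>
    ungroup() |>
    select(-".key")
}

#' Editing sites specific to a single species
#'
#' A site is species-specific if its alignment column is edited in exactly
#' one of the species present in `sites`.
#'
#' @param sites Editing-site tibble (all species of interest together).
#' @param alignments Alignment tibble.
#' @return Subset of `sites` (with `column` added) edited in exactly one
#'   species.
#' @export
species_specific_sites <- function(sites, alignments) {
  if (nrow(sites) == 0) return(mutate(sites, column = integer(0)))
  sc <- site_columns(sites, alignments)
  counts <- sc |>
    distinct(.data$species, .data$gene_id, .data$column) |>
    count(.data$gene_id, .data$column, name = "n_species_edited")
  sc |>
    left_join(counts, by = c("gene_id", "column")) |>
    filter(.data$n_species_edited == 1L) |>
    select(-"n_species_edited")
}

#' Potential shared editing sites for a clade
#'
#' Enumerates alignment columns at which every clade member carries a
#' genomic A, with identical pre- and post-editing amino-acid states across
#' members, and classifies the potential A-to-G change against the interior
#' nodes ancestral to the clade's most recent common ancestor. Columns where
#' members disagree in amino-acid states, where stops are involved, or where
#' needed states are unresolved are `EXCLUDED`.
#'
#' @param alignments Alignment tibble.
#' @param ancestry Ancestral assignment tibble.
#' @param tree Rooted `phylo`.
#' @param clade Character vector of two or more tip labels.
#' @return Tibble `gene_id`, `column`, `codon_index`, `pre_aa`, `post_aa`,
#'   `category`.
#' @export
shared_potential_sites <- function(alignments, ancestry, tree, clade) {
  if (length(clade) < 2) abort("clade must contain at least 2 species")
  nodes <- mrca_ancestor_set(tree, clade)
  genes <- split(alignments, alignments$gene_id)
  anc_split <- split(ancestry, ancestry$gene_id)
  purrr::map(genes, function(g) {
    gid <- g$gene_id[1]
    rows <- match(clade, g$taxon)
    if (anyNA(rows)) return(NULL)
    member_chars <- lapply(rows, function(r) .chars(g$sequence[r]))
    L <- length(member_chars[[1]])
    allA <- rep(TRUE, L)
    for (mc in member_chars) allA <- allA & mc == "A"
    cols <- which(allA)
    if (length(cols) == 0) return(NULL)
    codon_idx <- (cols - 1L) %/% 3L
    c0 <- codon_idx * 3L + 1L
    pos_in <- cols - c0 + 1L

    pre_aa <- post_aa <- NULL
    agree <- rep(TRUE, length(cols))
    for (mc in member_chars) {
      cod <- paste0(mc[c0], mc[c0 + 1L], mc[c0 + 2L])
      pre <- unname(CODON_AA[cod])
      pst <- cod
      substr(pst, pos_in, pos_in) <- "G"
      pst <- unname(CODON_AA[pst])
      if (is.null(pre_aa)) {
        pre_aa <- pre
        post_aa <- pst
      } else {
        agree <- agree & !is.na(pre) & !is.na(pre_aa) & pre == pre_aa &
          !is.na(pst) & !is.na(post_aa) & pst == post_aa
      }
    }
    excluded <- !agree | is.na(pre_aa) | is.na(post_aa) |
      pre_aa == "*" | post_aa == "*"

    anc_g <- anc_split[[gid]]
    if (is.null(anc_g)) abort(sprintf("gene %s absent from ancestral assignment", gid))
    in_anc <- rep(FALSE, length(cols))
    for (nd in nodes) {
      anc <- .chars(anc_g$sequence[match(nd, anc_g$node_id)])
      acod <- paste0(anc[c0], anc[c0 + 1L], anc[c0 + 2L])
      aaa <- unname(CODON_AA[acod])
      excluded <- excluded | is.na(aaa) | (!is.na(aaa) & aaa == "*")
      in_anc <- in_anc | (!is.na(aaa) & !is.na(post_aa) & aaa == post_aa)
    }
    category <- ifelse(excluded, "EXCLUDED",
                       ifelse(pre_aa == post_aa, "SYN",
                              ifelse(in_anc, "RESTORATIVE", "DIVERSIFYING")))
    tibble(gene_id = gid, column = cols, codon_index = codon_idx + 1L,
           pre_aa = pre_aa, post_aa = post_aa, category = category)
  }) |> list_rbind()
}

#' Editing events shared by a clade
#'
#' An editing event is shared by a clade when every clade member is edited
#' at the same alignment column with identical pre- and post-editing
#' amino-acid states. The event's category is computed against the interior
#' nodes ancestral to the clade's most recent common ancestor, and the mean
#' editing level and mean read coverage across members represent the event
#' (the coverage filter of level analyses applies to the mean).
#'
#' @param sites Editing-site tibble covering the clade species.
#' @param clade Character vector of two or more tip labels.
#' @param tree Rooted `phylo`.
#' @param alignments Alignment tibble.
#' @param ancestry Ancestral assignment tibble.
#' @return Tibble `gene_id`, `column`, `codon_index`, `pre_aa`, `post_aa`,
#'   `category`, `n_species`, `mean_level`, `mean_coverage`.
#' @export
shared_sites <- function(sites, clade, tree, alignments, ancestry) {
  if (length(clade) < 2) abort("clade must contain at least 2 species")
  pot <- shared_potential_sites(alignments, ancestry, tree, clade)
  sc <- site_columns(filter(sites, .data$species %in% clade), alignments)
  events <- sc |>
    group_by(.data$gene_id, .data$column) |>
    summarise(n_species = dplyr::n_distinct(.data$species),
              mean_level = mean(.data$level),
              mean_coverage = mean(.data$coverage), .groups = "drop") |>
    filter(.data$n_species == length(clade))
  events |>
    inner_join(pot, by = c("gene_id", "column")) |>
    select("gene_id", "column", "codon_index", "pre_aa", "post_aa",
           "category", "n_species", "mean_level", "mean_coverage")
}

#' Frequency ratios within editing-level ranges
#'
#' Within each editing-level range (left-closed, right-open; the last range
#' closed), computes category frequencies with range-restricted numerators
#' over the full potential-site denominators, and the ratios F_R/F_S and
#' F_D/F_S. Ratios are `NA` (flagged) in ranges with no synonymous edited
#' sites.
#'
#' @param classified Classified editing sites with `level`.
#' @param potential Potential-site tibble.
#' @param breaks Range boundaries on the editing level (default five 20%
#'   ranges).
#' @return Tibble `species`, `range`, `f_syn`, `f_restorative`,
#'   `f_diversifying`, `ratio_restorative`, `ratio_diversifying`.
#' @export
level_range_ratios <- function(classified, potential,
                               breaks = seq(0, 1, by = 0.2)) {
  cats <- c("SYN", "RESTORATIVE", "DIVERSIFYING")
  pot <- potential |>
    filter(.data$category %in% cats) |>
    count(.data$species, .data$category, name = "n_potential")
  labs <- paste0(utils::head(breaks, -1) * 100, "-", breaks[-1] * 100, "%")
  ed <- classified |>
    filter(.data$category %in% cats) |>
    mutate(range = cut(.data$level, breaks = breaks, labels = labs,
                       right = FALSE, include.lowest = TRUE),
           category = factor(.data$category, levels = cats)) |>
    count(.data$species, .data$range, .data$category, name = "n_edited",
          .drop = FALSE)
  ed |>
    left_join(pot, by = c("species", "category")) |>
    mutate(f = ifelse(!is.na(.data$n_potential) & .data$n_potential > 0,
                      .data$n_edited / .data$n_potential, NA_real_)) |>
    select("species", "range", "category", "f") |>
    tidyr::pivot_wider(names_from = "category", values_from = "f") |>
    rename(f_syn = "SYN", f_restorative = "RESTORATIVE",
           f_diversifying = "DIVERSIFYING") |>
    mutate(
      ratio_restorative = ifelse(!is.na(.data$f_syn) & .data$f_syn > 0,
                                 .data$f_restorative / .data$f_syn, NA_real_),
      ratio_diversifying = ifelse(!is.na(.data$f_syn) & .data$f_syn > 0,
                                  .data$f_diversifying / .data$f_syn, NA_real_)
    )
}

#' Split genes into odd- and even-rank bins
#'
#' Genes are ranked ascending by `value` (ties broken by gene id); genes
#' with odd ranks go to bin 1 and genes with even ranks to bin 2. Used to
#' compare synonymous editing in one half of the genes against
#' nonsynonymous editing in the other half.
#'
#' @param gene_values Data frame with columns `gene_id` and `value`.
#' @return Tibble `gene_id`, `value`, `rank`, `bin`.
#' @export
split_genes_odd_even <- function(gene_values) {
  .assert_cols(gene_values, c("gene_id", "value"), "`gene_values`")
  out <- gene_values |>
    as_tibble() |>
    arrange(.data$value, .data$gene_id) |>
    mutate(rank = dplyr::row_number(),
           bin = ifelse(.data$rank %% 2L == 1L, 1L, 2L))
  out
}

#' Per-gene pairwise dN/dS between two species
#'
#' Computes Li's (1993) Ka and Ks between the aligned orthologs of two
#' species for each gene, the standard input for ranking genes by dN/dS
#' (e.g., before [split_genes_odd_even()]).
#'
#' @param alignments Alignment tibble.
#' @param taxon1,taxon2 The two species to compare.
#' @return Tibble `gene_id`, `dn`, `ds`, `dnds` (`NA` where undefined).
#' @export
pairwise_gene_dnds <- function(alignments, taxon1, taxon2) {
  genes <- split(alignments, alignments$gene_id)
  purrr::map(genes, function(g) {
    i <- match(taxon1, g$taxon); j <- match(taxon2, g$taxon)
    if (is.na(i) || is.na(j)) return(NULL)
    al <- seqinr::as.alignment(nb = 2, nam = c(taxon1, taxon2),
                               seq = tolower(c(g$sequence[i], g$sequence[j])))
    kk <- tryCatch(seqinr::kaks(al), error = function(e) NULL)
    if (is.null(kk)) return(tibble(gene_id = g$gene_id[1], dn = NA_real_,
                                   ds = NA_real_, dnds = NA_real_))
    ka <- as.numeric(kk$ka); ks <- as.numeric(kk$ks)
    ratio <- ifelse(is.finite(ka) & is.finite(ks) & ks > 0 & ka >= 0,
                    ka / ks, NA_real_)
    tibble(gene_id = g$gene_id[1], dn = ka, ds = ks, dnds = ratio)
  }) |> list_rbind()
}
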