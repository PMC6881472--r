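# Non-stop codons and their probabilities under a base composition.
.codon_pool <- function(base_comp) {
  idx <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)
  prob <- base_comp[idx$b1] * base_comp[idx$b2] * base_comp[idx$b3]
  keep <- AA64[.codon_int(idx$b1, idx$b2, idx$b3)] != "*"
  list(b1 = idx$b1[keep], b2 = idx$b2[keep], b3 = idx$b3[keep],
       prob = prob[keep] / sum(prob[keep]))
}

.rbeta_trunc <- function(n, shape, lower) {
  # draw Beta(shape) truncated to [lower, 1] by inverse-CDF
  u <- runif(n, stats::pbeta(lower, shape[1], shape[2]), 1)
  stats::qbeta(u, shape[1], shape[2])
}

#' Configuration for the harm-permitting simulator
#'
#' Builds and validates the parameter set for [simulate_dataset()]. The
#' defaults describe a six-taxon mollusk phylogeny (four coleoids plus two
#' outgroups) with shallow coleoid branches, purifying selection on
#' nonsynonymous changes, and, under the default `"harm_permitting"` regime,
#' a coupling by which half of the nonsynonymous G-to-A mutations on coleoid
#' branches are accepted only together with a high-level editing event that
#' is then constrained in all descendants. The `"null"` regime switches the
#' coupling off and makes editing density and level distributions identical
#' across categories (editing uniform over A sites); the `"adaptive"` regime
#' additionally plants a fraction of diversifying edited sites as shared,
#' highly edited events.
#'
#' @param seed Integer RNG seed (mandatory; same config gives identical
#'   output).
#' @param regime `"harm_permitting"`, `"null"` or `"adaptive"`; presets for
#'   arguments not given explicitly.
#' @param tree_newick Newick string with branch lengths in expected
#'   substitutions per site.
#' @param outgroups Outgroup tip labels.
#' @param n_genes,codons_per_gene Dataset dimensions.
#' @param base_comp Named base composition (A, C, G, T) of root sequences.
#' @param a_N Acceptance probability of an ordinary nonsynonymous mutation
#'   (purifying selection).
#' @param h Harm-permitting coupling: probability that a nonsynonymous
#'   G-to-A mutation on a coleoid branch takes the editing-coupled route.
#' @param level_threshold Minimum editing level of a coupled event.
#' @param edit_density Named per-category probabilities that an unedited A
#'   site receives background editing (SYN, RESTORATIVE, DIVERSIFYING).
#' @param level_beta Named list of Beta(shape1, shape2) parameters for
#'   background editing levels per category.
#' @param coupled_beta Beta parameters of coupled editing levels (truncated
#'   at `level_threshold`).
#' @param coverage_mean,coverage_size Negative-binomial read-coverage model.
#' @param neural_fraction Fraction of genes labelled `high_neural`.
#' @param restrict_coupling_to_neural Couple only in `high_neural` genes.
#' @param adaptive_fraction Fraction of diversifying edited sites planted as
#'   adaptive (shared, high-level).
#' @param adaptive_beta Beta parameters of planted adaptive editing levels.
#' @param replacement_prob Per-branch probability that an inherited editing
#'   event is replaced by an A-to-G substitution.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       regime = c("harm_permitting", "null", "adaptive"),
                       tree_newick = paste0(
                         "(((octopus:0.04,bimac:0.04):0.03,",
                         "(squid:0.04,cuttlefish:0.04):0.03):0.08,",
                         "(nautilus:0.10,sea_hare:0.14):0.05);"),
                       outgroups = c("nautilus", "sea_hare"),
                       n_genes = 300,
                       codons_per_gene = 200,
                       base_comp = c(A = 0.30, C = 0.20, G = 0.25, T = 0.25),
                       a_N = 0.2,
                       h = 0.5,
                       level_threshold = 0.2,
                       edit_density = c(SYN = 0.04, RESTORATIVE = 0.02,
                                        DIVERSIFYING = 0.02),
                       level_beta = list(SYN = c(0.3, 3),
                                         RESTORATIVE = c(0.3, 3),
                                         DIVERSIFYING = c(0.3, 3)),
                       coupled_beta = c(2, 2),
                       coverage_mean = 600,
                       coverage_size = 5,
                       neural_fraction = 0.5,
                       restrict_coupling_to_neural = TRUE,
                       adaptive_fraction = 0,
                       adaptive_beta = c(8, 2),
                       replacement_prob = 0.1) {
  regime <- match.arg(regime)
  if (missing(seed)) abort("`seed` is mandatory in sim_config()")
  if (regime %in% c("null", "adaptive")) {
    if (missing(h)) h <- 0
    if (missing(edit_density)) {
      edit_density <- c(SYN = 0.03, RESTORATIVE = 0.03, DIVERSIFYING = 0.03)
    }
  }
  if (regime == "adaptive" && missing(adaptive_fraction)) adaptive_fraction <- 0.05
  cfg <- list(seed = as.integer(seed), regime = regime,
              tree_newick = tree_newick, outgroups = outgroups,
              n_genes = as.integer(n_genes),
              codons_per_gene = as.integer(codons_per_gene),
              base_comp = base_comp[BASES] / sum(base_comp), a_N = a_N, h = h,
              level_threshold = level_threshold, edit_density = edit_density,
              level_beta = level_beta, coupled_beta = coupled_beta,
              coverage_mean = coverage_mean, coverage_size = coverage_size,
              neural_fraction = neural_fraction,
              restrict_coupling_to_neural = restrict_coupling_to_neural,
              adaptive_fraction = adaptive_fraction,
              adaptive_beta = adaptive_beta,
              replacement_prob = replacement_prob)
  probs <- c(cfg$a_N, cfg$h, cfg$level_threshold, cfg$edit_density,
             cfg$neural_fraction, cfg$adaptive_fraction, cfg$replacement_prob)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (anyNA(cfg$base_comp) || any(cfg$base_comp <= 0)) {
    abort("base_comp must give positive A, C, G, T weights")
  }
  if (!all(c("SYN", "RESTORATIVE", "DIVERSIFYING") %in% names(cfg$edit_density))) {
    abort("edit_density must name SYN, RESTORATIVE and DIVERSIFYING")
  }
  if (cfg$n_genes < 1 || cfg$codons_per_gene < 2) abort("dataset too small")
  structure(cfg, class = "sim_config")
}

#' Simulate a dataset under the harm-permitting model
#'
#' Generates a complete synthetic dataset: per-gene coding alignments for
#' the tree tips, the true ancestral sequences at every interior node,
#' per-coleoid editing-site tables, gene groups, and a ground-truth record
#' of every editing site and substitution. Root sequences are drawn from the
#' base composition without in-frame stops; sequences evolve branch by
#' branch under a single-nucleotide mutation process (per-position mutation
#' probability equal to the branch length) with synonymous changes accepted,
#' nonsynonymous changes accepted with probability `a_N`, and — on coleoid
#' branches — nonsynonymous G-to-A mutations taking, with probability `h`,
#' the harm-permitting route: acceptance coupled to an editing event with
#' level at least `level_threshold` that persists in all descendants unless
#' replaced by an A-to-G substitution. Background editing is then placed on
#' A sites per true category, and (if `adaptive_fraction > 0`) a fraction of
#' diversifying edited sites is planted as shared high-level events.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_dataset`: `alignments`, `tree`, `ancestral`
#'   (true interior sequences, `method = "true"`), `sites`, `gene_groups`,
#'   `truth_sites`, `truth_subs`, `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  withr::local_seed(config$seed)

  tree <- read_tree(config$tree_newick, config$outgroups)
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  edges <- post$edge
  pre_order <- rev(seq_len(nrow(edges)))
  bl <- post$edge.length
  coleoids <- setdiff(tree$tip.label, config$outgroups)
  cb <- coleoid_branches(tree, coleoids)
  edge_lab <- cbind(.node_label(tree, edges[, 1]), .node_label(tree, edges[, 2]))
  is_coleoid_edge <- paste(edge_lab[, 1], edge_lab[, 2]) %in%
    paste(cb$parent, cb$child)
  anc_sets <- ancestral_node_sets(tree, coleoids)

  L <- config$codons_per_gene * 3L
  n_genes <- config$n_genes
  pool <- .codon_pool(config$base_comp)
  pow <- c(16L, 4L, 1L)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  groups <- ifelse(runif(n_genes) < config$neural_fraction,
                   "high_neural", "low_neural")
  gene_groups <- tibble(gene_id = gene_ids, group = groups)
  nnodes <- ntip + tree$Nnode
  root <- ntip + 1L

  seq_store <- vector("list", n_genes)   # per gene: integer sequences per node
  edit_store <- vector("list", n_genes)  # per gene: coupled edits per tip
  sub_rows <- vector("list", n_genes)

  rcov <- function(n) {
    1L + stats::rnbinom(n, size = config$coverage_size,
                        mu = config$coverage_mean - 1)
  }

  for (gi in seq_len(n_genes)) {
    couple_ok <- !config$restrict_coupling_to_neural ||
      groups[gi] == "high_neural"

    ci <- sample.int(length(pool$prob), config$codons_per_gene,
                     replace = TRUE, prob = pool$prob)
    seqs <- vector("list", nnodes)
    edits <- vector("list", nnodes)
    seqs[[root]] <- as.integer(rbind(pool$b1[ci], pool$b2[ci], pool$b3[ci]))
    edits[[root]] <- numeric(0)
    v_par <- v_child <- v_from <- v_to <- character(0)
    v_pos <- integer(0)
    v_syn <- v_cpl <- v_rep <- logical(0)

    for (e in pre_order) {
      s <- seqs[[edges[e, 1]]]
      ed <- edits[[edges[e, 1]]]
      # inherited editing can be replaced by an A-to-G substitution
      if (length(ed) > 0 && config$replacement_prob > 0) {
        repl <- runif(length(ed)) < config$replacement_prob
        if (any(repl)) {
          rpos <- as.integer(names(ed)[repl])
          s[rpos] <- 3L
          n_r <- length(rpos)
          v_par <- c(v_par, rep(edge_lab[e, 1], n_r))
          v_child <- c(v_child, rep(edge_lab[e, 2], n_r))
          v_pos <- c(v_pos, rpos)
          v_from <- c(v_from, rep("A", n_r))
          v_to <- c(v_to, rep("G", n_r))
          v_syn <- c(v_syn, rep(FALSE, n_r))
          v_cpl <- c(v_cpl, rep(FALSE, n_r))
          v_rep <- c(v_rep, rep(TRUE, n_r))
          ed <- ed[!repl]
        }
      }
      pos <- which(runif(L) < bl[e])
      if (length(ed) > 0) pos <- pos[!(pos %in% as.integer(names(ed)))]
      if (length(pos) > 0) {
        tb <- sample.int(4L, length(pos), replace = TRUE)
        keep <- tb != s[pos] # a "mutation" to the same base is no event
        pos <- pos[keep]; tb <- tb[keep]
      }
      if (length(pos) > 0) {
        # proposals hitting the same codon are applied sequentially (the
        # codon context changes); all others are evaluated in one pass
        cidx <- (pos - 1L) %/% 3L
        dup <- cidx %in% cidx[duplicated(cidx)]
        for (j in which(dup)) {
          p <- pos[j]; t <- tb[j]
          cur <- s[p]
          if (cur == t) next
          c0 <- cidx[j] * 3L + 1L
          old_int <- .codon_int(s[c0], s[c0 + 1L], s[c0 + 2L])
          new_int <- old_int + (t - cur) * pow[p - c0 + 1L]
          oa <- AA64[old_int]; na_ <- AA64[new_int]
          if (na_ == "*") next
          coupled <- FALSE
          if (oa != na_) {
            if (is_coleoid_edge[e] && cur == 3L && t == 1L && couple_ok &&
                runif(1) < config$h) {
              coupled <- TRUE
              ed[as.character(p)] <-
                .rbeta_trunc(1, config$coupled_beta, config$level_threshold)
            } else if (runif(1) >= config$a_N) {
              next
            }
          }
          s[p] <- t
          v_par <- c(v_par, edge_lab[e, 1]); v_child <- c(v_child, edge_lab[e, 2])
          v_pos <- c(v_pos, p); v_from <- c(v_from, BASES[cur])
          v_to <- c(v_to, BASES[t]); v_syn <- c(v_syn, oa == na_)
          v_cpl <- c(v_cpl, coupled); v_rep <- c(v_rep, FALSE)
        }
        pos <- pos[!dup]; tb <- tb[!dup]; cidx <- cidx[!dup]
        if (length(pos) > 0) {
          cur <- s[pos]
          c0 <- cidx * 3L + 1L
          old_int <- .codon_int(s[c0], s[c0 + 1L], s[c0 + 2L])
          new_int <- old_int + (tb - cur) * pow[pos - c0 + 1L]
          oa <- AA64[old_int]; na_ <- AA64[new_int]
          viable <- na_ != "*"
          syn <- oa == na_
          eligible <- viable & !syn & is_coleoid_edge[e] & couple_ok &
            cur == 3L & tb == 1L
          coupled <- eligible & runif(length(pos)) < config$h
          accept <- viable & (syn | coupled |
                                runif(length(pos)) < config$a_N)
          acc <- which(accept)
          if (length(acc) > 0) {
            s[pos[acc]] <- tb[acc]
            cp <- which(accept & coupled)
            if (length(cp) > 0) {
              ed[as.character(pos[cp])] <-
                .rbeta_trunc(length(cp), config$coupled_beta,
                             config$level_threshold)
            }
            n_a <- length(acc)
            v_par <- c(v_par, rep(edge_lab[e, 1], n_a))
            v_child <- c(v_child, rep(edge_lab[e, 2], n_a))
            v_pos <- c(v_pos, pos[acc])
            v_from <- c(v_from, BASES[cur[acc]])
            v_to <- c(v_to, BASES[tb[acc]])
            v_syn <- c(v_syn, syn[acc])
            v_cpl <- c(v_cpl, coupled[acc])
            v_rep <- c(v_rep, rep(FALSE, n_a))
          }
        }
      }
      seqs[[edges[e, 2]]] <- s
      edits[[edges[e, 2]]] <- ed
    }
    seq_store[[gi]] <- seqs
    edit_store[[gi]] <- edits[seq_len(ntip)]
    if (length(v_pos) > 0) {
      sub_rows[[gi]] <- tibble(
        gene_id = gene_ids[gi], parent = v_par, child = v_child,
        position = v_pos, from = v_from, to = v_to, synonymous = v_syn,
        coupled = v_cpl, replacement = v_rep)
    }
  }

  alignments <- tibble(
    gene_id = rep(gene_ids, each = ntip),
    taxon = rep(tree$tip.label, times = n_genes),
    sequence = unlist(lapply(seq_store, function(seqs) {
      vapply(seq_len(ntip), function(i) paste(BASES[seqs[[i]]], collapse = ""),
             character(1))
    }))
  )
  ancestral <- tibble(
    gene_id = rep(gene_ids, each = tree$Nnode),
    node_id = rep(tree$node.label, times = n_genes),
    sequence = unlist(lapply(seq_store, function(seqs) {
      vapply(seq_len(tree$Nnode),
             function(i) paste(BASES[seqs[[ntip + i]]], collapse = ""),
             character(1))
    })),
    method = "true", cost = NA_real_
  )

  # editing tables: coupled events plus background editing per true category,
  # categorized in one concatenated pass per coleoid
  site_tbls <- list()
  cat_tabs <- list()
  for (sp in coleoids) {
    tipnum <- match(sp, tree$tip.label)
    tip_chars <- BASES[unlist(lapply(seq_store, function(seqs) seqs[[tipnum]]))]
    anc_chars <- lapply(anc_sets[[sp]], function(nd) {
      ni <- ntip + match(nd, tree$node.label)
      BASES[unlist(lapply(seq_store, function(seqs) seqs[[ni]]))]
    })
    cats <- .categorize_tip(sp, ".", tip_chars, anc_chars)
    gk <- ((cats$column - 1L) %/% L) + 1L
    local <- cats$column - (gk - 1L) * L
    cats$gene_id <- gene_ids[gk]
    cats$position <- local
    cats$column <- local
    cats$codon_index <- (local - 1L) %/% 3L + 1L
    cat_tabs[[sp]] <- cats

    ed <- edit_store |> lapply(function(e) e[[tipnum]])
    n_c <- lengths(ed)
    cpos <- as.integer(unlist(lapply(ed, names)))
    cgene <- rep(gene_ids, times = n_c)
    ckey <- paste(cgene, cpos)
    catkey <- paste(cats$gene_id, cats$position)
    coupled_tbl <- NULL
    if (length(cpos) > 0) {
      coupled_tbl <- tibble(
        species = sp, gene_id = cgene, position = cpos, base = "A",
        level = unname(unlist(ed)), coverage = rcov(length(cpos)),
        tissue = NA_character_,
        true_category = cats$category[match(ckey, catkey)],
        harm_permitting = TRUE, adaptive = FALSE)
    }
    bg <- cats[cats$category != "EXCLUDED" & !(catkey %in% ckey), ]
    hit <- runif(nrow(bg)) < config$edit_density[bg$category]
    bgh <- bg[hit, , drop = FALSE]
    lvl <- numeric(nrow(bgh))
    for (cat in c("SYN", "RESTORATIVE", "DIVERSIFYING")) {
      sel <- bgh$category == cat
      if (any(sel)) {
        sh <- config$level_beta[[cat]]
        lvl[sel] <- rbeta(sum(sel), sh[1], sh[2])
      }
    }
    bg_tbl <- tibble(
      species = sp, gene_id = bgh$gene_id, position = bgh$position, base = "A",
      level = lvl, coverage = rcov(nrow(bgh)), tissue = NA_character_,
      true_category = bgh$category, harm_permitting = FALSE, adaptive = FALSE)
    site_tbls[[sp]] <- bind_rows(coupled_tbl, bg_tbl)
  }
  sites <- list_rbind(site_tbls)
  cats_all <- list_rbind(cat_tabs)

  # plant shared adaptive diversifying editing
  if (config$adaptive_fraction > 0) {
    af <- config$adaptive_fraction
    d_bg <- sum(sites$true_category == "DIVERSIFYING", na.rm = TRUE)
    n_plant <- round(af / (1 - af) * d_bg / length(coleoids))
    if (n_plant > 0) {
      # columns diversifying in all coleoids with identical post_aa, unedited
      edited_key <- paste(sites$species, sites$gene_id, sites$position)
      cand <- cats_all |>
        filter(.data$category == "DIVERSIFYING",
               !(paste(.data$species, .data$gene_id, .data$position) %in% edited_key)) |>
        group_by(.data$gene_id, .data$position) |>
        summarise(n_sp = dplyr::n(), n_aa = dplyr::n_distinct(.data$post_aa),
                  .groups = "drop") |>
        filter(.data$n_sp == length(coleoids), .data$n_aa == 1)
      n_plant <- min(n_plant, nrow(cand))
      if (n_plant > 0) {
        pick <- cand[sample.int(nrow(cand), n_plant), ]
        planted <- tidyr::expand_grid(pick[, c("gene_id", "position")],
                                      species = coleoids) |>
          mutate(base = "A",
                 level = rbeta(dplyr::n(), config$adaptive_beta[1],
                               config$adaptive_beta[2]),
                 coverage = rcov(dplyr::n()), tissue = NA_character_,
                 true_category = "DIVERSIFYING", harm_permitting = FALSE,
                 adaptive = TRUE) |>
          select("species", "gene_id", "position", "base", "level",
                 "coverage", "tissue", "true_category", "harm_permitting",
                 "adaptive")
        sites <- bind_rows(sites, planted)
      }
    }
  }

  sites <- arrange(sites, .data$species, .data$gene_id, .data$position)
  truth_sites <- sites |>
    select("species", "gene_id", "position", "true_category",
           "harm_permitting", "adaptive")
  sites <- sites |>
    select("species", "gene_id", "position", "base", "level", "coverage",
           "tissue")
  truth_subs <- list_rbind(sub_rows[!vapply(sub_rows, is.null, logical(1))])

  structure(list(
    alignments = alignments,
    tree = tree,
    ancestral = ancestral,
    sites = sites,
    gene_groups = gene_groups,
    truth_sites = truth_sites,
    truth_subs = truth_subs,
    config = config
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset (%s regime, seed %d)\n",
              x$config$regime, x$config$seed))
  cat(sprintf("  %d genes x %d codons, %d taxa; %d editing sites, %d substitutions\n",
              x$config$n_genes, x$config$codons_per_gene,
              length(x$tree$tip.label), nrow(x$sites), nrow(x$truth_subs)))
  invisible(x)
}

#' Check that the analysis pipeline recovers the simulated pattern
#'
#' Runs the full inference pipeline (ancestral reconstruction by parsimony,
#' site classification, frequency/level statistics, class-restricted dN/dS
#' contrast, and the ADP estimator) on a simulated dataset and reports the
#' direction and magnitude of the recovered signals alongside the simulation
#' truth.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param ancestry `"parsimony"` (re-infer, the honest pipeline) or
#'   `"true"` (use the generator's ancestral states).
#' @param classes Change classes for the dN/dS contrast.
#' @param bootstrap_B Bootstrap replicates for the G>A group contrast
#'   (0 skips the bootstrap).
#' @param min_coverage Coverage filter for level comparisons.
#' @return A list of class `recovery_report`: `freq_stats`, `level_stats`,
#'   `freq_contrasts`, `dnds_contrasts`, `dnds_boot` (or `NULL`), `adp`,
#'   `coupled_restorative_recovery`, `planted_adaptive_fraction`.
#' @export
expected_pattern_check <- function(sim, ancestry = c("parsimony", "true"),
                                   classes = c("G>A", "CT>A", "G>CT"),
                                   bootstrap_B = 0, min_coverage = 400) {
  ancestry <- match.arg(ancestry)
  anc <- if (ancestry == "parsimony") {
    reconstruct_parsimony(sim$alignments, sim$tree)
  } else {
    sim$ancestral
  }
  potential <- enumerate_potential_sites(sim$alignments, anc, sim$tree)
  classified <- classify_editing_sites(sim$sites, potential)
  freq <- category_frequencies(classified, potential)
  lev <- category_levels(classified, min_coverage = min_coverage)

  wide_f <- freq |>
    select("species", "category", "frequency") |>
    tidyr::pivot_wider(names_from = "category", values_from = "frequency")
  wide_l <- lev |>
    select("species", "category", "median_level") |>
    tidyr::pivot_wider(names_from = "category", values_from = "median_level")
  freq_contrasts <- wide_f |>
    transmute(.data$species,
              f_r_minus_f_s = .data$RESTORATIVE - .data$SYN,
              f_d_minus_f_s = .data$DIVERSIFYING - .data$SYN) |>
    left_join(wide_l |>
                transmute(.data$species,
                          l_r_minus_l_s = .data$RESTORATIVE - .data$SYN,
                          l_d_minus_l_s = .data$DIVERSIFYING - .data$SYN),
              by = "species")

  counts <- branch_counts(sim$alignments, anc, sim$tree, classes = classes)
  counts_grouped <- counts |> inner_join(sim$gene_groups, by = "gene_id")
  dnds_contrasts <- counts_grouped |>
    group_by(.data$class, .data$group) |>
    summarise(nonsyn_subs = sum(.data$nonsyn_subs),
              nonsyn_sites = sum(.data$nonsyn_sites),
              syn_subs = sum(.data$syn_subs),
              syn_sites = sum(.data$syn_sites), .groups = "drop_last") |>
    mutate(dnds = (.data$nonsyn_subs / .data$nonsyn_sites) /
             (.data$syn_subs / .data$syn_sites)) |>
    select("class", "group", "dnds") |>
    tidyr::pivot_wider(names_from = "group", values_from = "dnds") |>
    ungroup() |>
    mutate(contrast = .data$high_neural - .data$low_neural)

  boot <- NULL
  if (bootstrap_B > 0) {
    boot <- bootstrap_dnds(filter(counts, .data$class == "G>A"),
                           sim$gene_groups, B = bootstrap_B,
                           seed = sim$config$seed + 1L)
  }

  adp <- adp_by_bins(classified, potential)

  hp <- sim$truth_sites |> filter(.data$harm_permitting)
  coupled_rec <- NA_real_
  if (nrow(hp) > 0) {
    key <- paste(classified$species, classified$gene_id, classified$position)
    idx <- match(paste(hp$species, hp$gene_id, hp$position), key)
    coupled_rec <- mean(classified$category[idx] == "RESTORATIVE", na.rm = TRUE)
  }

  structure(list(
    freq_stats = freq,
    level_stats = lev,
    freq_contrasts = freq_contrasts,
    dnds_contrasts = dnds_contrasts,
    dnds_boot = boot,
    adp = adp,
    coupled_restorative_recovery = coupled_rec,
    planted_adaptive_fraction = sim$config$adaptive_fraction
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Pipeline recovery report\n")
  cat("  frequency/level contrasts (per species):\n")
  print(as.data.frame(x$freq_contrasts), row.names = FALSE)
  cat("  dN/dS group contrasts (per change class):\n")
  print(as.data.frame(x$dnds_contrasts), row.names = FALSE)
  if (!is.null(x$dnds_boot)) print(x$dnds_boot)
  cat(sprintf("  ADP adaptive fraction: %.4f (planted %.4f)\n",
              x$adp$adaptive_fraction, x$planted_adaptive_fraction))
  if (!is.na(x$coupled_restorative_recovery)) {
    cat(sprintf("  harm-permitting sites recovered as restorative: %.1f%%\n",
                100 * x$coupled_restorative_recovery))
  }
  invisible(x)
}
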