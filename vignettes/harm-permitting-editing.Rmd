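---
title: "Classifying A-to-I recoding against ancestral states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying A-to-I recoding against ancestral states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editevo)
library(dplyr)
```

## The scientific question

Coleoid cephalopods (octopuses, squids, cuttlefishes) recode an
exceptionally large number of adenosines in their neural mRNAs by A-to-I
editing, which the ribosome reads as A-to-G. Because the fraction of
nonsynonymous sites under high-level editing exceeds the synonymous
fraction, this abundance has been read as evidence of widespread adaptive
recoding. There is, however, a nonadaptive alternative — the
*harm-permitting* model: once cellular editing activity is high, a
nonsynonymous G-to-A genomic mutation can fix because transcripts are edited
back to G at a sufficient level; the editing is then selectively constrained
at a high level, not because it is beneficial relative to the original
genotype but because it masks an otherwise deleterious genomic state.

Distinguishing the two hypotheses requires splitting nonsynonymous editing
by ancestral state. An editing event changing amino acid X to Y is

* **restorative** if Y is the inferred genomic amino-acid state at at least
  one interior node ancestral to the focal species — exactly the signature
  harm-permitting editing must carry, since the G state existed ancestrally;
* **diversifying** if Y matches no ancestral state — the only class in which
  an excess over synonymous editing indicates adaptation.

`editevo` implements the full inference machinery around this split:
ancestral reconstruction, per-site classification, frequency (F_S, F_R,
F_D) and level (L_S, L_R, L_D) statistics, the nucleotide-change-class
restricted dN/dS contrast between neural-expression gene groups, the
adaptive-fraction (ADP) estimator, shared-editing analyses, and a
synthetic-data generator embodying the harm-permitting model so that every
stage can be validated against ground truth.

## Coordinates and input conventions

Transcript positions are 1-based both in files and in memory (the native R
convention; every writer documents it). Alignments are codon-aware FASTA
with headers `taxon|gene_id`; gaps are `-`; `N` is tolerated on input but
any codon touching `N`, a gap, or an unresolved ancestral state is
*excluded* from classification rather than guessed. Editing sites arrive as
TSV (`species`, `gene`, `position`, `base`, `level`, `coverage`, optional
`tissue`); records that are not genomic A at the stated position are dropped
with a warning, mirroring the fact that published site lists contain only
A-to-G calls. Raw coding sequences can be cleaned with
`sanitize_transcripts()`, which truncates at the first in-frame stop codon
and keeps the longest record per gene and species.

The species tree is rooted on the branch separating the outgroups from the
ingroup. On the six-taxon mollusk topology (four coleoids, nautilus and sea
hare as outgroups) each coleoid then has exactly three interior ancestral
nodes, and the "ancestral node set" of a tip is all interior nodes on its
path to the root. For events shared by a clade, the relevant set is every
interior node ancestral to the clade's most recent common ancestor.

## Ancestral states

`reconstruct_parsimony()` assigns joint ancestral states with a per-column
Sankoff dynamic program under unit substitution cost. Ties among optimal
joint assignments are broken lexicographically (A < C < G < T) from the root
downward, making the reconstruction deterministic; columns in which any tip
carries a gap or N receive `?` at every interior node and are excluded
downstream. Parsimony was chosen over codon-model maximum likelihood
because, at the shallow divergences of interest, joint assignments agree
overwhelmingly, and because errors in ancestral inference cancel in the
frequency ratios: both the numerator (edited sites of a category) and the
denominator (potential sites of that category) depend on the same inferred
states, so misassignment only adds stochastic noise and costs power rather
than biasing F_R or F_D. Users with an external joint reconstruction (e.g.
from a likelihood method) can load it with `import_ancestral()`; everything
downstream is agnostic to the source.

## Classification and the category statistics

For every genomic A of a focal species, `enumerate_potential_sites()`
substitutes G at that position alone, retranslates the codon and assigns
SYN / RESTORATIVE / DIVERSIFYING / EXCLUDED; the non-excluded categories
partition all A sites. Sites are classified one at a time — a codon with two
edited positions is evaluated per site against the genomic codon, the only
semantics consistent with per-site frequency and level definitions. Stop
codons anywhere in the comparison (pre-editing, post-editing, or ancestral)
cause exclusion, so nonsense recoding never contaminates the missense
categories.

`category_frequencies()` computes F = edited / potential per category and
compares restorative and diversifying frequencies against synonymous with
two-sided chi-square tests on the 2x2 edited-by-category table, without
continuity correction by default (configurable). `category_levels()`
compares editing levels with two-sided Mann-Whitney U tests after discarding
sites covered by fewer than 400 reads — below that, low expression biases
level estimates upward because weak editing is undetectable; the threshold
is exposed as `min_coverage`. "Edited" means presence in the input site
table; no level threshold is applied by default.

Robustness utilities reproduce the standard checks: `species_specific_sites()`
(sites edited in exactly one coleoid, giving events of comparable age),
`level_range_ratios()` (F_R/F_S and F_D/F_S within five 20% editing-level
ranges, range-restricted numerators over full denominators),
`split_genes_odd_even()` with `pairwise_gene_dnds()` (comparing synonymous
editing in one half of the genes, ranked by ortholog dN/dS, against
nonsynonymous editing in the other half, which breaks any coupling between
neighbouring sites in the same gene), and `shared_sites()` (events present
in every member of a clade with identical pre- and post-editing amino acids,
represented by the across-member mean level and coverage).

## Class-restricted dN/dS and the gene bootstrap

The harm-permitting model predicts an acceleration specifically of
nonsynonymous G-to-A substitutions, specifically in genes expressed where
editing is high. `count_branch_changes()` counts, on one branch, the
opportunities for a single-base change of a class (e.g. G>A) in the parent
sequence — each (position, target) pair whose parent state is a source base,
classified synonymous or nonsynonymous in the parent codon context — and the
observed substitutions of each kind. Counting opportunities in the ancestral
context makes dN/dS a ratio of per-opportunity rates, cancelling base
composition differences between classes and gene groups, which is what the
group contrast needs. Codons with more than one change on a branch are
excluded entirely (the substitution path is ambiguous; such codons are rare
at these divergences). Multi-target classes (G>CT) count each target as a
separate opportunity, which keeps disjoint classes exactly additive.

`branch_counts()` applies this to the six branches descending from the
coleoid common ancestor, by default restricted to positions at which both
outgroups and the branch's parent node share the same state
(`conserved_site_mask()`): a change at a conserved position is more likely
deleterious without editing, which sharpens the test. The mask applies to
synonymous and nonsynonymous counts symmetrically by default (so the two
rates remain comparable); `mask_scope = "nonsyn"` restricts it to the
nonsynonymous side only. `class_dnds()` pools counts over genes and branches
(total dN over total dS), and `bootstrap_dnds()` contrasts two gene groups
by resampling genes with replacement within each group (default B = 200),
reporting the two-sided bootstrap P — twice the smaller tail fraction of the
replicate differences, floored at 1/B — together with the one-sided P,
since conventions differ.

## ADP and the replacement analysis

Where F_D exceeds F_S the excess cannot be explained by harm-permitting and
is attributed to adaptive editing. `adp_by_bins()` splits sites into ten
equal editing-level bins (left-closed, right-open, last closed) and
estimates, in each bin with F_D > F_S, the number of adaptive diversifying
sites as ADP = N_D (1 - F_S/F_D), with bin-restricted numerators over the
full potential-site denominators — the reading under which ADP can never
exceed N_D in a bin. The totals over bins give the adaptive fraction of
diversifying editing; the estimator applies to whatever site set is passed
in (one species, species-specific, shared, or pooled).

`infer_ancestral_editing()` collects columns edited in at least three of the
four coleoids — by parsimony such editing existed in their common ancestor —
requiring identical pre/post amino-acid states among the edited members
(relaxable via `require_identity`). `replacement_analysis()` then asks
whether the unedited species carries a genomic G, i.e. whether the editing
was replaced by the substitution it mimics; the nonsynonymous-vs-synonymous
contrast of replacement fractions is tested with a two-tailed Fisher exact
test, and A-to-C/T states in unedited species serve as a control that cannot
be produced by fixing the edited state.

## The synthetic-data generator

`simulate_dataset()` generates the complete input bundle — alignments, tree,
true ancestral sequences, editing tables, gene groups — plus a truth record
for every site and substitution. Its defaults describe the study conditions
the inference targets:

* a six-taxon mollusk tree with shallow coleoid branches (0.03–0.04
  expected substitutions per site) and deeper outgroup branches;
* 300 genes of 200 codons, root codons drawn from base composition
  A 0.30 / C 0.20 / G 0.25 / T 0.25 with stops rejected;
* a single-nucleotide mutation process (per-position, per-branch mutation
  probability equal to the branch length; no codon model — the categorical
  structure the inference consumes does not require one), synonymous changes
  accepted, nonsynonymous changes accepted with probability a_N = 0.2
  (purifying selection);
* harm-permitting coupling h = 0.5 on the six coleoid branches, restricted
  to the `high_neural` half of the genes: a coupled nonsynonymous G-to-A
  mutation fixes together with an editing event of level at least 0.2,
  drawn from Beta(2, 2) truncated to that threshold, which persists in all
  descendants unless replaced by an A-to-G substitution (probability 0.1
  per branch) — the replacement signal of the shared-editing analysis;
* background editing densities 0.04 (synonymous) and 0.02 (nonsynonymous)
  per A site with Beta(0.3, 3) levels — nonsynonymous editing held below
  synonymous to represent purifying purging of deleterious recoding, and the
  low-median, heavy-tailed Beta mimicking observed level distributions;
* negative-binomial read coverage (mean 600, size 5), so a realistic share
  of sites falls below the 400-read filter;
* optionally, a fraction of diversifying edited sites planted as adaptive:
  shared by all four coleoids at high levels (Beta(8, 2)).

The `"null"` regime (h = 0, one density 0.03 and one level distribution for
all categories) places editing uniformly over A sites, the reference for
calibration checks; the `"adaptive"` regime plants a 5% adaptive fraction by
default. Everything is driven by a single mandatory seed; identical
configurations produce byte-identical outputs.

What the generator does *not* emulate: codon-model substitution heterogeneity,
among-gene and among-site rate variation, indels and alignment error,
ascertainment of editing sites from finite RNA-seq coverage, and tissue
structure. Passing recovery tests therefore demonstrates that the inference
machinery is correct and well calibrated under the model's assumptions, not
that the biological conclusions hold for any particular real dataset.

## Numerical and design choices

* Mutation proposals are uniform over the four bases; proposals equal to the
  current base are non-events, so branch length acts as a proposal rate and
  the realized per-site substitution probability is 3/4 of it — immaterial
  for the categorical structure being generated.
* Chi-square without continuity correction, Mann-Whitney exact for small
  samples without ties (the `stats::wilcox.test` switching rule), Fisher
  two-tailed by summing tables no more probable than the observed one — the
  standard conventions of each test.
* Bootstrap replicates in which a group's pooled dS is zero are dropped and
  counted; the two-sided P is floored at 1/B and capped at 1.
* Undefined quantities are `NA` and flagged, never silently zero: dN/dS with
  dS = 0, level medians of empty sets, range ratios with F_S = 0.
* Degenerate inputs error early with named causes (ragged alignments,
  incomplete ancestral assignments, clades of size one, groups of fewer than
  two genes).

## Problem sizes used in the shipped checks

The package's own validation (test suite and `scripts/acceptance.R`) runs
the calibration experiments at 100 null replicates of 600 genes x 200
codons, directional-recovery experiments at 50 replicates of 200 genes x
150 codons, and ADP recovery at 1050 genes (above 10^4 diversifying edited
sites) — sizes at which every check has ample resolution while the whole
suite stays quick on a single CPU. Two deliberate choices: the null used
for calibration of the chi-square comparison is *neutral* (a_N = 1, editing
density 0.1), because under strong purifying selection restorative-potential
sites are so rare (about a hundred per species, a handful edited) that any
2x2 test sits in its discrete regime and rejects less often than its
nominal level, whereas the neutral null yields hundreds of potential and
tens of edited restorative sites, where the chi-square approximation — the
thing being calibrated — actually applies. Likewise, the calibration uses
600 genes (300 per expression group) because the percentile bootstrap of a
pooled-ratio contrast is a first-order asymptotic method: at 150 genes per
group its null rejection rate measures about 7% rather than 5%, while at
300 per group it is on its nominal level.

## Known limitations

* Parsimony underestimates ancestral uncertainty; sites whose true history
  involves multiple hits on one branch can be misclassified. The import
  path exists precisely so users can substitute model-based joint
  reconstructions.
* The ADP estimator inherits the positive-part bias of its definition: bins
  where sampling noise pushes F_D above F_S contribute spuriously, so very
  small datasets overestimate the adaptive fraction; the effect shrinks as
  site counts grow.
* Editing levels are taken at face value; no binomial sampling model of
  read counts is applied beyond the coverage filter.
* The pipeline analyses one tissue at a time; per-tissue runs are separate
  invocations on filtered site tables.
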