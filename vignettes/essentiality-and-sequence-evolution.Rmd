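---
title: "Essentiality and sequence evolution of testis proteins: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essentiality and sequence evolution of testis proteins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(testevol)
```

## The scientific question

Genes can be "essential" in more than one sense. A knockout that kills mice
before puberty marks a gene essential for viability; a knockout that leaves
males sub- or infertile marks a gene essential for reproduction. This
package implements an analysis pipeline asking whether these two kinds of
essentiality leave different signatures in the molecular evolution of
testis-expressed proteins. Sequence evolution is measured as pairwise
human–mouse dN/dS (the ratio of nonsynonymous to synonymous substitution
rates; values below one indicate purifying selection). Three proxies of
evolutionary constraint accompany it:

* **node degree** — the number of distinct partners in a binary
  protein–protein interaction (PPI) network; highly connected proteins tend
  to be more constrained;
* **tissue specificity τ** — an index on [0, 1], 0 for uniform expression
  across tissues and 1 for expression confined to one tissue; broadly
  expressed proteins tend to be more constrained;
* **multifunctionality** — the number of nonredundant GO-slim
  biological-process classes annotated to the protein.

Each gene is placed in one of three essentiality categories from mouse
knockout phenotype annotations: *lethality* (death before puberty at
sub-Mendelian ratios), *male sub-/infertility*, or *nonessential*.

## Classification model

Alleles enter the classification only if they are targeted null mutations
(`allele_type = "Targeted"`, attributes containing `"Null/knockout"`)
affecting a single gene, observed homozygous — or hemizygous for X-linked
genes, since male mice are hemizygous for the X.

**Lethality evidence** is any Mammalian Phenotype (MP) term inside the
subtrees of *preweaning lethality* (MP:0010770) or *lethality at weaning*
(MP:0008569). Four viability terms used as single ids — complete lethality
(MP:0011400), partial lethality (MP:0010831), decreased survivor rate
(MP:0008770), abnormal survival (MP:0010769) — count only together with the
curation flag `confirmed_prepubertal_death`, because deciding whether such
an allele actually causes prepubertal death at sub-Mendelian ratios
requires reading the underlying literature. **Sub-/infertility evidence**
is male infertility (MP:0001925) or reduced male fertility (MP:0001922);
further male-reproductive terms (configurable, default the sex-nonspecific
*infertility* MP:0001924) count only with the flag
`confirmed_male_subinfertility`. Annotations flagged as describing
female-specific phenotypes never create evidence, but do not by themselves
remove a gene.

Manual literature curation cannot be computed, only encoded: every judgment
the original curators made by reading cited articles enters this pipeline
as a `curation_flags` entry on the allele row. This is a deliberate
modelling boundary — the classifier is deterministic given those flags.

**Exclusions take precedence over classification**, in a fixed order chosen
for determinism (the order matters only for ledger attribution, not for
which genes survive):

1. `double_essentiality` — lethality evidence together with *any* male
   reproductive association (including decreased litter size, MP:0001935),
   even via different alleles;
2. `unclear_or_fertile` — curation found males fertile despite the
   annotated abnormality, or the phenotype would increase fertility;
3. `decreased_litter_size_only` — litter size as the only fertility link,
   untransferable to human reproduction;
4. `requires_extra_manipulation` — phenotypes emerging only under
   additional manipulation (e.g. diet);
5. `special_case_exclude` — individually curated removals.

Genes with phenotypic null alleles and no evidence are nonessential; genes
whose alleles are all filtered away have *no data*, which removes them from
the dataset (distinct from nonessential).

## Covariate layers

**Network degree.** The raw edge list passes an identifier-cleanup stage:
accessions deleted from the protein database are removed with their edges;
renamed accessions are replaced; products of non-protein-coding genes are
removed unless rescued by an override flag (mirroring an HGNC
"protein-coding gene" call); an unreviewed accession whose gene also maps
to a reviewed accession is merged into it, edges inherited. The graph is
then simplified (duplicate edges and self-interactions dropped) and degrees
extracted. A gene mapping to several accessions takes the one of highest
degree, ties broken to the lexicographically smallest accession — the tie
rule is this package's own, the source convention being silent.
Accessions carrying several gene ids stay in the graph (they contribute to
neighbours' degrees) but are never selectable as a gene's representative.

**Tissue specificity.** For an expression profile \(x_1,\dots,x_N\) (FPKM),

$$\tau = \frac{\sum_{i=1}^{N} (1 - x_i/x_{\max})}{N - 1}.$$

The primary analysis uses 24 tissues, excluding ovary, placenta and uterus
as female-specific; a 27-tissue mode and a `log2(FPKM+1)` option reproduce
the supplementary variants. τ is computed on raw FPKM. All-zero profiles
have undefined τ (x_max = 0) and are excluded rather than set to 0.

**Multifunctionality.** Biological-process annotations are mapped to a
GO-slim in the map2slim sense: the minimal covering slim ancestors via
is_a and part_of (regulates is not traversed, matching the classic tool's
default). The count is the size of the union of slim classes over a
protein's annotations; the root term GO:0008150 with evidence code ND marks
absence of information and is ignored. Immunity involvement is membership
of the slim class *immune system process* (GO:0002376) — a convention;
bucketing by direct annotation would be marginally stricter.

## Statistical procedures

All procedures are implemented from first principles in `R/stats.R` (the
test suite cross-checks each against an independent oracle —
`cor.test`, `kruskal.test`, `wilcox.test`, `fisher.test`, enumeration):

* Spearman correlations use average ranks and a two-tailed p from
  \(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) on \(n-2\) df.
* Partial rank correlations invert the Pearson correlation matrix of the
  ranks, \(\rho_{xy\cdot z} = -\Omega_{12}/\sqrt{\Omega_{11}\Omega_{22}}\),
  with \(n-2-k\) df.
* Kruskal–Wallis applies the tie correction
  \(H' = H / (1 - \sum (t^3-t)/(N^3-N))\); p from χ² on g−1 df.
* Mann–Whitney U uses exact enumeration when \(n_1 n_2 \le 400\) and no
  ties, otherwise the tie-corrected normal approximation with continuity
  correction (the default mode in the group comparisons, emulating the
  original analysis tool's large-sample behaviour).
* Pearson χ² carries no Yates correction; Fisher's exact test extends to
  2×3 tables by Freeman–Halton enumeration of all tables with the observed
  margins under the probability-mass rule (two-sided p = total probability
  of tables no more probable than the observed). Fisher replaces χ²
  whenever any expected count falls below 5.
* Holm's step-down adjustment accepts a family size m larger than the
  number of p-values supplied, because some families include tests run in
  analysis variants. Families: the three zero-order and three partial
  correlations involving dN/dS form one family (m = 6); the remaining
  zero-order pairs one family (m = 3); post-hoc pairwise tests m = 3 per
  variable; Kruskal–Wallis p for node degree and τ are adjusted with m = 3
  for the three network / tissue-panel variants of the full design.
* Median confidence intervals are percentile bootstrap: 100,000 resample
  medians, nearest-rank order statistics at α/2 and 1−α/2. Percentile
  rather than BCa is the minimal reading of "a bootstrap algorithm";
  both endpoints are reproducible from an explicit seed.

Randomness everywhere comes from R's default Mersenne-Twister generator
under explicit seeds; a run is bit-reproducible within R on any platform,
which is the reproducibility contract this package targets.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the *statistical
structure* of the study so that every downstream stage is exercisable
without external downloads.

* **Copula.** The four covariates (dN/dS, degree, multifunctionality, τ)
  are drawn from a Gaussian copula whose latent Pearson matrix is obtained
  from the target Spearman matrix by \(r = 2\sin(\pi \rho_s/6)\)
  (projected to the nearest positive-definite correlation matrix when
  needed, recorded). Default targets are the observed zero-order
  correlations (−0.229, −0.134, 0.088, 0.398, −0.304, −0.082).
* **Marginals** (defaults, all overridable): dN/dS ~ Beta(1.5, 8) — a
  purifying-selection-dominated distribution with every value below 1;
  degree ~ discretized lognormal(2, 1) — heavy-tailed interactome degrees,
  median ≈ 7; multifunctionality ~ 1 + Poisson(3) — every gene has at
  least one slim process, so no gene is lost to the no-GO-data filter by
  construction; τ ~ Beta(2, 2); dS ~ Gamma(8, 16) — human–mouse synonymous
  divergence around 0.5. dN is derived as (dN/dS)·dS.
* **Category shifts.** Group differences are additive shifts on the latent
  Gaussian before the marginal transform, ordering the medians as
  observed: dN/dS and τ highest in sub-/infertility and lowest in
  lethality genes; degree and multifunctionality highest in lethality
  genes; dS highest in nonessential genes. Because shifts add
  between-group covariance, the within-group correlation is compensated
  analytically from the known mixture moments
  (\(R_w = r_t\sqrt{(1+V_{b,i})(1+V_{b,j})} - \Sigma_b\)) so the sampled
  Spearman matrix still matches the targets. Multifunctionality is a small
  discrete count, so its per-category *medians* can tie at the default
  shift; the ordering there is a mean-rank property, consistent with the
  observation that only the lethality–nonessential contrast is clearly
  significant for this variable.
* **Sizes and flags.** Defaults: 965 classified genes (57 sub-/infertility,
  502 lethality, 406 nonessential) plus 102 category-excluded candidates
  (73 double essentiality, 26 unclear/litter/manipulation, 3 special
  cases), so the bookkeeping 1,067 − 102 = 965 is replayed, not assumed.
  X-linkage and immunity are drawn as exact per-category counts rounded
  from the observed proportions (27/406, 5/57, 8/502 and 130/406, 11/57,
  140/502), which at the default sizes reproduces the published
  composition tables digit for digit.
* **File emission.** Each covariate is *inverted* into its raw input form:
  the FPKM matrix uses a one-dominant-tissue profile (background
  \((1-\tau)\cdot x_{\max}\)), so recomputed τ equals ground truth to
  numerical precision; the GAF file annotates each gene with children of
  exactly its count of distinct slim classes; the PPI edge list realizes
  the degree sequence with a deterministic Havel–Hakimi construction
  (sequences are first repaired to graphical — parity fix, Erdős–Gallai
  repair — with adjustments recorded); the allele table is built so the
  classifier maps it back to the ground-truth categories exactly; rates
  and chromosome go to a TSV. Toy MP and GO/GO-slim ontologies containing
  all classification terms are bundled as code-written OBO files.

**What the generator does not emulate:** genome-scale interactome
topology (clustering, communities), realistic expression atlases, dS
saturation, correlated annotation noise, or within-category correlation
structure differing from the global copula (unreported in the source
study; the global copula is assumed within categories). Passing round-trip
tests therefore demonstrates correctness of the pipeline's bookkeeping and
statistics, not robustness to the noise structure of real HPA/Ensembl/MGI
data.

## Numerical choices and degenerate inputs

* Fisher's two-sided p uses the probability-mass rule with a relative
  tolerance of 1e−7 when comparing table probabilities, avoiding
  floating-point misclassification of ties.
* Exact Mann–Whitney enumeration with ties (forced mode) falls back to
  complete enumeration of group assignments, guarded by a size limit.
* Zero-variance rank vectors, singular rank-correlation matrices, all-zero
  expression profiles, zero contingency margins and unknown ontology roots
  are errors (or `NA` + ledger entries where the design says "excluded"),
  never silently absorbed.
* Exact conditional tests (Fisher, exact MWU) are conservative by
  construction: their finite-sample type-I error is below the nominal α,
  so calibration checks assert validity (level ≤ α) for them and the
  two-sided band only for the asymptotic tests.

## Problem sizes used in the bundled analyses

The analysis drivers and tests run at the study's native scale (1,067
candidate genes) with 10,000 bootstrap pseudo-replicates in the driver
scripts (the package default is 100,000, the analysis-wide setting);
null-calibration suites use 10,000 replicates, at which the Monte-Carlo
standard error (~0.002) is small against the calibration band. These sizes
are the package's own choices for its bundled, fully reproducible runs.

## Known limitations

* The full curated MP term list of the original design is not public;
  only the printed roots are hard defaults, the rest is configurable.
* The classifier models curation as input flags; it cannot re-derive
  judgments that required reading primary literature.
* The two alternative PPI network variants and the alternative τ source
  are out of scope; the cleanup pipeline and τ module expose the switches
  (tissue mode, log transform, Holm family sizes) needed to reproduce
  them, but no fixtures for them are bundled.
* Group comparisons default to the normal-approximation Mann–Whitney p;
  whether the original small-group contrasts used exact p is unknown, so
  both modes are selectable.
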