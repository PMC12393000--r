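---
title: "Methods: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitapath)
```

This vignette is the package's account of its science: the models it
implements, the defaults it chooses where the choice was genuinely open,
and what the synthetic validation does and does not demonstrate.

## The pathway-completeness model

The knowledge base organizes each of nine vitamins (Thi, Rib, Nia, Pan,
Pyr, Bio, Fol, Cob, Men) into one or more *routes* — alternative
biosynthetic branches such as the `thiI` and `thiO` thiazole-sulfur
branches of thiamine, `ribD1` versus the `RIB7` reductase in riboflavin,
the `NMNAT`/`NaMNAT` adenylyltransferase branches of niacin, the long
DXP-dependent pyridoxine branch (whose final oxidase `pdxH` is the
bottleneck) versus the two-gene R5P branch, four biotin precursor clades
(`FabG`, `BioI`, `BioW`, `BioZ`), the classical `Men` route versus the
futalosine (`Meq`) route of menaquinone, and the aerobic versus anaerobic
corrin-ring routes of cobalamin. A route is an ordered list of
*functional roles*; a role is the set of KEGG KOs that can perform the
same step, with an `essential` flag.

The call logic is deliberately minimal and fully Boolean:

* a role is **satisfied** when the genome carries *any* of its KOs
  (OR over KOs — isofunctional enzymes are interchangeable);
* a route is **complete** when *every essential* role is satisfied
  (AND over essential roles);
* a genome **produces** a vitamin de novo when *at least one* route is
  complete (OR over routes).

Gene copy number never affects a call: calls are presence/absence, and
copy counts are retained only for role-count heatmaps. Partial route
completeness is a diagnostic (the cobalamin stage counts), never an
upgrade to a producer call.

Two deliberate consequences: salvage and transporter roles may be present
in the file with `essential = false`, so they contribute to abundance
profiling but never to producer calls; and KOs shared between roles (the
aerobic/anaerobic cobalamin routes share most methyltransferase steps,
e.g. `CobI`/`CbiL`, `CobK`/`CbiJ`) are naturally handled, since roles are
sets and a KO may appear in several.

### The shipped catalog

The role and branch *skeleton* of the default catalog is fixed by the
biology above; the KO *fills* are curated from public KEGG pathway-map
definitions and the file (`inst/extdata/vitamin_pathways.json`, with an
equivalent flat TSV format) is meant to be edited — a group with its own
curation should replace the fills, not the code. Validation enforces the
structural invariants (known vitamin codes, non-empty routes, at least one
essential role per route, well-formed `K#####` ids, consistent definitions
when a role id recurs, legal cobalamin stage labels) and reports the
offending entity by name.

The `Meq` route ships with its two late roles filled by K10106 and
K05357. These KOs are rare in gut metagenomes, which in practice leaves
the futalosine route incomplete and routes menaquinone calls through the
classical `Men` branch; we treat this as a property of the data, not of
the catalog, so the roles stay essential rather than being dropped.

### Cobalamin stages and the CCG/SCG labels

Cobalamin roles carry one of three stage labels: `aerobic`, `anaerobic`
(the two corrin-ring routes, distinguished by the timing of cobalt
insertion — `CobNST`-mediated late chelation versus early chelation by
`CbiK`), and `post_cobyrinate` for the shared tail downstream of
cob(II)yrinate a,c-diamide. Both full routes *include* the
post-cobyrinate roles: a genome must carry the tail to be called a
cobalamin producer. We chose this stricter definition because the tail is
required to reach an actual cobamide; a user who prefers corrin-ring-only
completeness can set the tail roles to `essential: false` in the catalog
file — the relaxation is a curation decision, not a code path.

Labels: **CCG** — some full cobalamin route is complete; **SCG** — not
CCG, but at least one cobalamin role is present *and* the genome belongs
to one of the six focal genera (*Ligilactobacillus*, *Faecalibacterium*,
*Corynebacterium*, *Mediterraneibacter*, *Blautia*,
*Limosilactobacillus*); **other** — everything else, including genomes
with zero cobalamin KOs in a focal genus. The genus restriction makes the
SCG set a defined comparison cohort rather than "every genome with a
stray KO".

## Genome quality and dereplication

The inclusion rule is completeness ≥ 50, contamination **strictly** < 5,
and quality score (completeness − 5 × contamination) ≥ 50; the
near-complete gate is completeness ≥ 90 with the same strict
contamination bound. The inequality directions are centralized and
documented in `R/genome_set.R`; the rejection report lists *every* rule a
genome failed (a genome at completeness 49 fails both the completeness
and the score rule).

Dereplication is a deterministic quality-ranked greedy centroid
clustering over a user-supplied ANI matrix: rank genomes by quality score
(ties: larger genome, then lexicographic id); repeatedly promote the best
unassigned genome to representative and absorb every unassigned genome
with ANI **strictly** greater than the threshold. Thresholds 99 and 95
give strain-level dereplication and species-level genome bins. This
replaces pipeline tools that compute ANI from assemblies; computing ANI
is out of scope here, which is exactly what makes the threshold semantics
unit-testable.

One caveat we found while testing: *cluster counts are not guaranteed to
be monotone across arbitrary threshold chains* for this scheme. Lowering
the threshold can let a high-ranked representative absorb a genome that
would otherwise have become the representative of a larger cluster,
splitting that cluster's would-be members. On random matrices the
violation shows up at widely spaced thresholds; at the two thresholds the
method actually uses (99 then 95) we have not observed it, and the test
suite asserts monotonicity only there.

## Abundance profiling

TPM is the standard length-normalized unit: per sample,
`rate_g = count_g / (length_g / 1000)` and
`TPM_g = rate_g / Σ rate × 10^6`. Gene lengths come from the gene
catalog's representative sequence. All-zero samples stay all-zero with a
warning rather than erroring, since dropped samples should be a caller's
decision. Counts are taken as final per-gene integers; read-level
concerns (multi-mapping, paired-end dialects, subsampling to a common
depth) are upstream of this package, though a seeded multinomial
down-sampler is provided with the simulator.

Roll-ups are plain sums: gene → KO → functional role → vitamin pathway,
and gene → phylum/genus for taxonomy (optionally restricted to the
catalog's KO universe, i.e. "vitamin-associated" genes only). Sums
conserve mass, and features missing from a mapping are dropped with a
logged count. A KO claimed by two vitamins contributes fully to both
pathway columns — pathway abundances are *profiles*, not a partition of
reads.

## Statistics

All statistics are implemented directly in base R; the standard
distribution functions (`pnorm`, `pchisq`) are the only inherited
numerics. Established implementations (`vegan::adonis2`,
`vegan::vegdist`, `stats::wilcox.test`, `stats::p.adjust`, `cmdscale`)
appear in the test suite as independent cross-checks, never as the
implementation.

* **Alpha diversity.** Richness = number of non-zero features; Shannon
  with the natural logarithm; Simpson reported as Gini–Simpson
  (1 − Σp²), so values lie in [0, 1].
* **Bray–Curtis** = Σ|x−y| / Σ(x+y), in [0, 1] for non-negative data.
* **PCoA** is classical scaling: Gower double-centering of −d²/2,
  symmetric eigendecomposition, axes ordered by eigenvalue. Eigenvalues
  below `max|λ| × 1e-8` are treated as zero; negative eigenvalues (from
  non-Euclidean dissimilarities) contribute neither coordinates nor
  explained-variance denominator. Requesting more axes than available
  returns what exists, with a warning; an all-identical configuration
  returns zero axes.
* **PERMANOVA** uses the direct sums-of-squares partition
  (SS_total = Σ_{i<j} d²/n, SS_within per group, pseudo-F =
  (SS_B/(k−1))/(SS_W/(n−k))) and permutes group labels with a required,
  recorded seed; p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm), so the
  smallest achievable p is 1/(n_perm + 1). On univariate Euclidean data
  the pseudo-F reduces exactly to the one-way ANOVA F, which the tests
  exploit. Pairwise comparisons subset the distance matrix per group
  pair and apply Benjamini–Hochberg across pairs. The label permutation
  saves and restores the caller's RNG state.
* **Wilcoxon rank-sum** reports the Mann–Whitney U for the first sample.
  In `auto` mode the p-value is exact — computed by dynamic-programming
  enumeration of the null rank-sum distribution — whenever the smaller
  group has ≤ 8 observations and there are no ties; otherwise a normal
  approximation with tie-corrected variance and a 0.5 continuity
  correction is used. Exact mode refuses ties rather than silently
  approximating.
* **Fisher's method** (−2Σ ln p against χ² with 2k df) is exposed as a
  free function on any p-value vector: whether to combine across
  diversity indices or across group pairs is an analysis decision we
  leave to the caller. Zero p-values are clamped to a configurable floor
  with a warning.
* **Cohen's d** uses the pooled standard deviation with the n₁+n₂−2
  denominator.

## The synthetic study generator

The generator is the package's test bed: every table the analysis
consumes is emitted with recorded ground truth, as a pure function of a
seeded configuration.

What it emulates, and the defaults chosen as the standing study
conditions:

* **Designs.** Five gut regions (duodenum, jejunum, ileum, cecum,
  colorectum) × 27 samples = 135; a 5 + 5 two-group infection contrast
  (NC/ST); a 4 + 4 + 4 three-group contrast (JC/JS/JR).
* **Community.** Eleven genera across four phyla with planted per-genus
  vitamin capabilities: a broad seven-vitamin *Bacillus* producer,
  anaerobic-route cobalamin producers inside *Bacillota*, menaquinone via
  the classical route in *Campylobacter*, folate in the *Bacteroidota*
  genera, and single-vitamin genomes (*Alistipes*). Genomes are assigned
  round-robin so genus sizes are balanced.
* **Cobalamin gaps.** The focal genera are planted with the full
  cobalamin gene complement and then lose whole roles at configured
  fractions, applied to exactly `round(fraction × n)` genomes of the
  genus — deterministic planting so gap fractions are recovered exactly
  (e.g. 0.9 for the five *Blautia* knockouts; complete loss of the
  aerobic-only roles in *Mediterraneibacter*). Ground-truth producer
  calls are re-derived from each genome's final KO set by direct set
  logic, independent of the classifier under test.
* **Counts.** Gene baselines are log-normal (σ = 1); planted effects
  multiply a pathway's genes by `2^log2_fc` in the affected groups
  (defaults: riboflavin and biotin 2× in the small intestine, cobalamin
  2× in the large intestine; pantothenate 2× in ST; riboflavin 2× in
  JR); counts are negative binomial with dispersion 0.3 (metagenome-like
  overdispersion; 0 selects Poisson) around `proportion × library size`,
  library sizes uniform on [5 × 10⁵, 2 × 10⁶]. Gene lengths are uniform
  on [300, 3000] bp, with a 0.2 probability of a second copy per
  (genome, KO) and a few unannotated genes per genome.
* **ANI.** Within-genus pairs draw identities on [94, 100], cross-genus
  on [70, 80], giving both thresholds non-trivial work.

What it does **not** emulate: sequence content and read-level error, the
compositional correlation structure of real communities (taxa are
independent given the planted effects), strain mixtures within a sample,
variable genome quality–annotation coupling (completeness is drawn
independently of the KO set), and realistic rank-abundance shapes beyond
the log-normal baseline. Passing the end-to-end tests therefore shows
that the *computational chain* recovers planted truth under its own
model assumptions — it does not validate the biological annotations on
real data, which depend entirely on the curation of the catalog and the
upstream annotation pipeline.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at 110 genomes
(10 per genus, chosen so the planted fractions are exact decimals), 135
or 54 samples, and around 6,000 genes; the permutation tests use 199–1000
permutations, and the null-calibration check uses 500 simulated null
datasets. These sizes were chosen to exercise every code path at full
statistical resolution while keeping a complete run interactive.

Tolerances: ANI and distance matrices must be symmetric to 1e-9; TPM rows
sum to 10⁶ within 1e-6 relative; aggregation conserves mass to 1e-9
relative; PCoA reconstructs Euclidean geometry to 1e-8. Ties in the
greedy clustering rank are broken by genome size then id, making every
clustering bit-reproducible; all stochastic routines require an explicit
seed and record it in their result.

## Known limitations

* Producer calls inherit the catalog's curation: a missing KO in a role's
  fill set produces false negatives, and role fills drawn from general
  KEGG maps may be too permissive for specific clades.
* The greedy dereplication approximates, but is not identical to,
  score-weighted secondary clustering in assembly-based dereplication
  tools; in particular tie-breaking among equal-quality genomes is
  defined here, not inherited from any external tool.
* PERMANOVA is one-way only (no strata, no covariates), matching the
  contrasts the package targets.
* The SCG definition is genus-gated by design; communities where partial
  cobalamin pathways concentrate in other genera need the genus list
  adjusted (`scg_genera` argument).
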