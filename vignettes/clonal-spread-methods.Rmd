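---
title: "Models and methods: multi-region tumor phylogenetics and clonal deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `clonalspread`, the assumptions
they rest on, the tunable parameters that matter, and the design choices
made where the design was genuinely open. The package targets the
multi-region study design for pelvic high-grade serous (HGS) carcinoma:
per patient, three ovarian, three omental and three bowel tumor regions
profiled by RNA-seq, plus a matched normal from blood.

## 1. Consensus somatic variants and the filter cascade

Variant calling from tumor RNA is noisy, so somatic SNVs are accepted only
when at least `min_snv_callers = 3` independent callers report the same
`(chrom, pos, ref, alt)` key; INDELs require `min_indel_callers = 2`
agreement among the INDEL-capable callers. Alleles are left-normalized
before keys are compared, because callers pad and place INDELs
differently. Where callers disagree on depths at a shared key, the record
with the highest read depth wins: depth differences reflect local
realignment choices, and the maximum is stable under caller reordering.

Downstream filters, each a pure set operation with a ledger row:

* **Germline**: any key also called in the matched normal is removed.
* **Coverage**: a variant needs `min_tumor_depth = 10` reads in tumor RNA
  and `min_normal_depth = 5` reads in the normal. Two modes exist:
  `per-sample` (only the calling sample must pass) and `all-samples`
  (every tumor region of the patient must pass). The joint mode is the
  right one for heterogeneity claims: a "private" mutation at a position
  with no coverage in the other eight samples is not evidence of
  heterogeneity, merely of missing data. Positions absent from the depth
  table count as zero coverage — the conservative reading.
* **Population polymorphisms**: a variant at a known population site is
  removed **unless** the normal sample has at least 10x coverage there and
  no variant call — well-covered, variant-free normal DNA is positive
  evidence the site is somatic in this patient, so such variants are
  rescued. Without normal depth information there is no rescue.
* **RNA editing**: positions on a user-supplied editing-site list are
  removed outright, alleles and strand ignored. RNA editing would
  otherwise masquerade as recurrent somatic substitution.

The germline, population and editing filters commute (each is a key- or
position-membership test), so cascade order affects only the ledger's
attribution of removals, never the surviving set; the tests assert this.

## 2. Heterogeneity summaries

`build_mutation_matrix()` assembles per-patient presence/VAF/coverage
grids restricted to jointly covered positions. `shared_fraction()` counts,
for a sample group, the variants present in at least one member (`total`)
and in all members (`shared`); `percent = 100*shared/total` is rounded
half-up to two decimals, matching how such tables are conventionally
printed. A region's denominator is the union over that region's samples,
not the patient-wide union — that is what makes regional totals smaller
than all-region totals in the same patient.

The exported VAF matrix orders truncal variants (present in every sample)
first by descending mean VAF, then the rest by carrier count; absent calls
render as VAF 0. This is the layout used for mutation heatmaps with
catalogued-somatic (COSMIC-flagged) variants highlighted.

## 3. Sample phylogenies from concatenated SNVs

Retained SNVs are concatenated into a pseudo-alignment: each tumor sample
carries the alternate base where the variant was called in it and the
reference base otherwise; the normal taxon is all-reference. INDELs are
excluded (characters are strictly A/C/G/T). The alignment is an
*ascertained* sample: every column is variant in at least one tumor
sample. No ascertainment-bias correction is applied — branch lengths are
therefore interpretable only relatively, which is all the divergence
classification needs; this is a deliberate, known limitation.

**Models.** JC69, K80 and HKY85, each scaled to one expected substitution
per site per unit branch length. Richer models (GTR, rate heterogeneity)
are deliberately excluded: two-state-ish presence data concatenated over a
few hundred sites cannot inform them. The candidate set is configurable.
Model choice is by BIC, `-2 lnL + k ln(n columns)`, with `k` counting
branch lengths plus substitution parameters (K80: kappa; HKY85: kappa and
three free frequencies, taken empirically from the alignment), fitted on a
neighbor-joining starting topology.

**Likelihood.** Felsenstein pruning over the unrooted tree, computed in a
small C++ kernel on pattern-compressed data. Correctness is anchored two
ways in the tests: exact agreement (1e-9 log units) with exhaustive
enumeration over internal-node states on 4–5-taxon instances, and
agreement with an independent likelihood implementation on larger trees.
With at most eleven taxa no numerical rescaling is needed.

**Search.** Each of `n_starts` searches starts from an independent random
topology and alternates two local-move phases until neither improves:
nearest-neighbor interchange (each neighbor evaluated with its central,
rearranged branch re-optimized — the fixed-length surface alone is too
myopic on plateau-rich SNV alignments), and a single-taxon
subtree-prune-and-regraft sweep (each tip removed and scored on every
reattachment edge). The second move class exists because multi-region data
contain near-identical sample triplets: a whole sample misplaced by the
random start sits behind a likelihood valley that single NNI swaps cannot
cross. Branch lengths are re-optimized by per-branch Brent search; the
winning tree gets a final optimization pass at tighter tolerance.
Likelihood ties are broken by the lexicographically smallest canonical
Newick string, making results reproducible bit-for-bit under a seed.

Desk-scale defaults are 10 starts and 50 bootstrap replicates; the
full-scale settings of 100 starts and 200 replicates are available as the
`paper` preset. Bootstrap replicates resample columns with replacement and
search from a single random start each; supports are the percentage of
replicates containing each bipartition, mapped onto the best tree (and
available as a strict-majority consensus tree, built from bipartitions
occurring in more than half the replicates — these are provably mutually
compatible).

**Divergence classification.** The tree is rooted on the normal. The
classifier finds the smallest clade containing all ovarian samples and
flags each omentum/bowel sample attaching outside it as ancestral. The
patient is "peritoneal-early" when at least one peritoneal sample is
ancestral and the ovarian clade's support meets `divergence_support`
(default 50%; trees without support values count as fully supported,
which is how the bootstrap-free recovery suite runs).

## 4. Clone trees from variant allele frequencies

Mutations are clustered by k-means on their across-sample VAF vectors
(deterministic under a seed; cluster count scanned over `k_range`). Clone
trees are rooted at the normal clone A, whose single child is the founder
clone: shapes are therefore the non-isomorphic rooted trees on the
non-root nodes — 1, 1, 2, 4, 9, 20, 48, 115, 286 shapes for 1–9 nodes,
486 in total at the default `max_nodes = 9` budget, enumerated in
canonical form (tests cross-check a brute-force parent-vector generator).

Under the diploid-heterozygous assumption a cluster assigned to clone v
has predicted VAF `0.5 * p_v(s)`, where `p_v(s)` is the prevalence of v's
subtree in sample s. No copy-number correction is attempted — VAFs from
RNA with copy-number alterations are already approximate, and the package
treats the factor 0.5 as the model, not an estimate. Per-sample
frequencies solve a least-squares problem on the simplex (non-negative,
summing to one including normal A), via constrained least squares with a
projected-gradient fallback. Nodes with no assigned cluster are
contracted into their parent before fitting: an empty node's mass can
always be absorbed by its parent without changing any predicted VAF, so
nothing is lost — and this is also why scanning only shapes with exactly
k nodes per cluster count k is complete.

Shapes and assignments are scored by the **per-mutation** residual sum
plus `lambda * n_nodes * log(n_mutations * n_samples)` (default
`lambda = 0.05`). The per-mutation residual matters: cluster-center
residuals are near zero for any k-cluster/k-node fit (k observations, k
free parameters per sample), so a center-level score would always pick a
single clone. Ties go to fewer nodes, then the smaller canonical shape
string. Ancestral clones are direct children of A; a sample is flagged
when such a clone's fitted frequency reaches `ancestral_threshold`
(default 0.05 cell fraction).

## 5. The simulator: what it emulates and what it does not

`sim_config()` defaults encode the study design: 4 patients x (3 ovary +
3 omentum + 3 bowel) regions, 4 clones below the normal root, 130
mutations per patient with 40% truncal, negative-binomial coverage (mean
100x, dispersion 5 — RNA-seq-like overdispersion), binomial alt reads at
`0.5 x` clone-subtree prevalence, and per-caller false-negative (5%) and
false-positive (2% per decoy site) noise. The mutation budget of 130 was
calibrated so the pipeline's per-sample filtered SNV counts span roughly
65–110 across scenarios, matching the 60–117 range (median 98) reported
for real HGS multi-region RNA-seq cohorts.

The clone tree is role-structured rather than uniformly random: trunk B,
an ovarian-lineage clone C shared by all ovarian samples,
ovarian-sample-private subclones, and a metastasis-founding clone D. In
the **early-divergence** scenario D is a direct child of B and every
peritoneal sample carries the ancestral clone B at frequency at least 0.2
while ovarian samples exclude it. In the **late-divergence** scenario D
descends from an ovarian-sample-private subclone and peritoneal samples
carry only leaf-clone mass. The private-subclone construction is
essential: if the late metastatic clone hung off C directly, both
scenarios would yield topologically identical sample trees (peritoneal
clade sister to the ovarian clade) and no topology-based classifier could
separate them, even noiselessly. It also requires `n_clones >= 4`, the
default.

What the simulator does **not** model: real read alignment (no
FASTQ/BAM), allele-specific expression (RNA VAFs are taken as faithful up
to binomial sampling), copy-number alterations, INDELs (the INDEL
consensus path is exercised by hand-built fixtures instead), and
cross-seeding between peritoneal sites. Passing recovery tests therefore
demonstrates the pipeline's correctness under its own model assumptions,
not robustness to expression bias or copy-number distortion in real
tumors.

## 6. Numerical choices and problem sizes

* Branch lengths live in `[1e-9, 5]` expected substitutions/site;
  per-branch Brent tolerance is 1e-4 during search and 1e-6 for the final
  polish; model fitting stops when a sweep gains less than 1e-6 log units.
* k-means uses 10 restarts under the configured seed; empty clusters are
  dropped and the assignment relabeled.
* Simplex fits clip components below zero at 1e-10 and renormalize only
  when the constraint sum exceeds one.
* Test and recovery problem sizes: likelihood oracles run exhaustive
  enumeration at up to 5 taxa (4^3 internal-state combinations per
  column); topology recovery uses 10-taxon, 300-column JC69 alignments
  with branch lengths in [0.05, 0.3] — at 200 columns the maximum
  likelihood tree itself (verified by comparing optimized likelihoods)
  differs from the generating topology in roughly a tenth of draws, so
  the benchmark is run at a column count where the estimator is
  consistent and recovery reflects search correctness; scenario
  classification runs 20 single-patient cohorts at default noise without
  bootstrap (absent supports count as confident).
* Clone-tree scans at desk scale use `max_nodes <= 6`; the 9-node
  catalog (486 shapes) is enumerated in well under a second, but
  assignment search cost grows factorially in the cluster count, so
  `k_range` should stay at or below 6.

## 7. Known limitations

Ascertainment bias in the pseudo-alignment is uncorrected (shared with
the presence/absence design it reproduces); the clone model ignores copy
number and assumes every mutation is diploid-heterozygous; k-means
clustering assumes roughly spherical VAF clusters; NNI plus single-taxon
SPR is not a complete rearrangement scheme, and very flat likelihood
surfaces (near-identical samples) leave within-site resolution and its
bootstrap supports essentially arbitrary — supports on those shallow
nodes should be read as "unresolved", which is the honest answer the data
give.
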