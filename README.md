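# clonalspread

Multi-region tumor phylogenetics and clonal deconvolution from RNA-seq
variant calls, for studying how pelvic high-grade serous (HGS) carcinoma
spreads between the ovaries and the peritoneum.

HGS carcinoma usually presents as disseminated disease, and whether
peritoneal implants arise *after* the ovarian tumors (stepwise spread) or
*before/alongside* them (early peritoneal seeding) changes what early
detection can hope to achieve. Given RNA-seq variant calls from multiple
tumor regions per patient — the motivating design is nine regions each
(3 ovary, 3 omentum, 3 bowel) plus a matched normal — this package
reconstructs that history in four stages:

1. **Consensus somatic calls** (`consensus_calls()`, `apply_filter_cascade()`)
   — variants reported by ≥3 SNV callers (≥2 for INDELs), minus germline
   calls, requiring ≥10× tumor / ≥5× normal coverage, minus population
   polymorphisms (with a rescue when the normal shows ≥10× coverage and no
   variant) and known RNA-editing sites.
2. **Heterogeneity** (`build_mutation_matrix()`, `shared_fraction()`) —
   shared vs unique mutation counts per anatomical region under a joint
   coverage constraint (a variant position must be adequately covered in
   *every* sample before presence/absence is believed), plus a
   truncal-first VAF matrix for heatmaps.
3. **Sample phylogeny** (`build_pseudoalignment()`, `search_ml_tree()`,
   `bootstrap_trees()`, `majority_rule_consensus()`, `classify_divergence()`)
   — concatenated SNVs treated as an alignment; maximum-likelihood tree
   search (JC69/K80/HKY85 selected by BIC, Felsenstein pruning, NNI hill
   climbing from random starts), nonparametric bootstrap supports, and a
   classifier that asks whether peritoneal samples attach to the backbone
   below the ovarian radiation ("peritoneal-early").
4. **Clone trees from VAFs** (`enumerate_clone_trees()`, `select_best_fit()`,
   `detect_ancestral_clones()`) — every rooted clone-tree shape up to nine
   nodes (486 in total), k-means mutation clusters, and per-sample clone
   frequencies by constrained least squares under the diploid-heterozygous
   model VAF ≈ ½ × clone prevalence; ancestral clones are direct children
   of the normal root "A".

A clonal-evolution simulator (`sim_config()`, `simulate_cohort()`,
`run_recovery_suite()`) generates ground-truthed cohorts — clone mixtures
per region, negative-binomial coverage, binomial alt reads,
caller-specific false positives/negatives — so every stage is testable
without patient data.

## The model in brief

For a sample tree, the likelihood of an alignment column under a
reversible substitution model with rate matrix Q is computed by the
pruning recursion over the tree; branch lengths are in expected
substitutions per site and the search maximizes
`lnL = Σ_columns log Σ_states π · Π_edges P(t_e)`.

For clone trees, a mutation cluster assigned to clone v in sample s has
predicted allele frequency `½ · p_v(s)` where `p_v(s)` is the summed
frequency of v and its descendants; per-sample frequencies solve

```
min Σ_clusters (VAF_obs − ½ p)²   s.t.  f ≥ 0,  Σ f = 1 (including normal A)
```

and candidate shapes/cluster counts are scored by the per-mutation residual
sum plus a BIC-style penalty on the clone count.

## Worked example

```r
library(clonalspread)

cfg <- sim_config(n_patients = 1, scenario = "early_divergence", seed = 5)
dir <- tempfile(); simulate_cohort(cfg, dir)

res <- run_patient_analysis(file.path(dir, "patient1"),
                            out_dir = file.path(dir, "out"),
                            cfg = pipeline_config())
res$counts[c("median", "min", "max")]
#> $median [1] 66    $min [1] 64    $max [1] 94
res$sharing
#>     group total shared percent
#> 1   ovary   102     54   52.94
#> 2 omentum    78     48   61.54
#> 3   bowel    77     47   61.04
#> 4     all   128     14   10.94
res$divergence$ovarian_clade_support
#> [1] 92
res$divergence$peritoneal_early
#> [1] TRUE
```

Per-sample counts land in the 60–120 range typical of filtered RNA-seq
somatic calls; region-level sharing far exceeds all-region sharing
(10.9% here), the signature of strong intratumor heterogeneity; and the
bowel/omentum samples attach below the ovarian radiation (a 92%-supported
ovarian clade), so the patient is classified peritoneal-early — matching
the simulated truth. The
artifact directory contains per-sample variant TSVs and filter ledgers,
sharing tables, the Newick tree with bootstrap supports, a divergence
report, and the clone tree (JSON + Graphviz DOT).

## Layout

- `R/` — implementation; `src/` — C++ pruning kernel
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/clonal-spread-methods.Rmd` — models, assumptions, design choices
- `inst/scripts/clonal-spread` — command-line front-end (`simulate`, `run`)
- `inst/extdata/` — published cohort count/sharing tables (plain TSV)
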