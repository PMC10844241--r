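# exprevol

Phylogenetic analysis of gene expression evolution across tissues, built
for comparative RNA-seq designs: several closely related species, several
tissues, replicated samples, both sexes for some tissues. The running
example is a six-species *Drosophila* chemosensory-tissue design spanning
0.25–15 My of divergence.

The package answers, with tested and reusable code, the questions such a
study asks:

* **How fast do whole transcriptomes evolve?** Stationary
  Ornstein–Uhlenbeck (OU) distances `D = −ln ρ` on log2(TPM+1)
  species means, neighbour-joining expression trees with gene-bootstrap
  supports, and relative-rate tests
  `Z = (D(A,O) − D(B,O)) / SE` with a subsampled Wilcoxon significance
  procedure against the non-significant Z distribution.
* **Which genes changed expression, where on the tree?** Per-gene
  replicate-aware model selection among Brownian motion (neutral), OU
  with one optimum (constrained) and OU with up to three optimum shifts
  (divergent branches), scored by a combinatorially corrected BIC
  ("pBIC-lite": `−2 logL + k ln N + 2 ln C(E, s)`) over all 176 shift
  configurations on the 6-taxon tree.
* **Do multi-tissue changes happen at once?** The coincidental index
  `Σ n_obs(t) / Σ n_max(t)` over event-bearing branches: 0 = no changes,
  1/T = a single-tissue change, 1 = all T tissues changed on one branch;
  plus UpSet-style tissue-overlap tables and a permutation test of
  event counts against branch lengths.
* **How specific is expression?** τ specificity over tissues or cell
  clusters, expression calls at TPM thresholds 3/0.5, and gain/loss
  assignment to branches by Fitch parsimony with exhaustive
  most-parsimonious-reconstruction enumeration.
* **Which cell types correspond across tissues?** Marker detection
  (fraction ≥ 0.25, log2 fold change ≥ 0.25, rank-sum p < 0.001, top
  100) and a homology score = clipped profile correlation × shared-marker
  fraction, in [0, 1].
* **Which genes are sex-biased?** A self-contained negative binomial
  Wald engine (median-of-ratios size factors, method-of-moments
  dispersions, `~ tissue + sex + tissue:sex`), bias calls at ≥ 1.5-fold
  and adjusted p < 0.01, cross-species/tissue overlap and hypergeometric
  enrichment.
* **Cross-species count comparability.** The "trimmed genes" procedure:
  drop alignment regions where any species has a gap run > 150 bp, emit
  per-species trimmed GTFs from the conserved blocks.

A synthetic-data module simulates every input with planted ground truth —
expression panels evolved on the tree, count tables, toy cell atlases,
toy alignments — so each estimator is validated by recovery studies.

## Worked example

```r
library(exprevol)
tree <- example_species_tree()        # 6 species, depth 15 My

## transcriptome distances and an expression tree (2000-gene panel)
pan <- simulate_panel(sim_spec(n_genes = 2000, seed = 1))
sm  <- species_mean_tpm(pan, "antenna")
round(sou_distance(sm), 3)
#>       Dere  Dmel  Dsan  Dsec  Dsim  Dsuz
#> Dere 0.000 0.394 0.223 0.383 0.378 0.537
#> Dmel 0.394 0.000 0.405 0.113 0.107 0.563
#> Dsan 0.223 0.405 0.000 0.404 0.401 0.541
#> Dsec 0.383 0.113 0.404 0.000 0.011 0.557
#> Dsim 0.378 0.107 0.401 0.011 0.000 0.555
#> Dsuz 0.537 0.563 0.541 0.557 0.555 0.000
```

Distances grow with divergence time (sim–sec 0.011 at 0.25 My; anything
vs suzukii ≈ 0.55 at 30 My of path). Neighbour joining on that matrix
recovers the species topology with every informative node at 100%
gene-bootstrap support:

```r
nj_tree(sm, outgroup = "Dsuz", n_bootstrap = 100, seed = 1)
#> (((Dsim,Dsec)100,Dmel)100,(Dere,Dsan)100,Dsuz);   # supports as labels
```

Per-gene model selection on a panel with 30 planted optimum shifts
(4 stationary SDs, alpha = 1/My, visible branches):

```r
spec <- sim_spec(n_genes = 150, tissues = "antenna",
                 sexed_tissues = character(0),
                 params = ou_params(alpha = 1, sigma2 = 1, sigma2_e = 0.05),
                 changers = list(n = 30, delta = 4, tissues_per = 1,
                                 coincidental_fraction = 0,
                                 min_visibility = 0.5),
                 seed = 2)
pan2 <- simulate_panel(spec)
fits <- fit_gene_models(panel_traits(pan2, "antenna"), tree,
                        tissue = "antenna")
round(classify_branches(fits)$fractions, 3)
#>     neutral constrained   divergent
#>       0.247       0.711       0.042

head(change_events(fits), 3)
#>    gene  tissue edge direction
#> 1 g0006 antenna  n10        up
#> 2 g0009 antenna Dmel      down
#> 3 g0009 antenna Dsuz        up
```

Branch fractions read as in the study design: most branches constrained,
a minority neutral, divergent branches rare and concentrated in genes
with planted shifts (22 of 30 planted edges recovered exactly in this
run). Change events feed the coincidence analysis:

```r
coincidental_index(data.frame(gene = "g", tissue = "antenna",
                              edge = "Dsec"), n_tissues = 5)   # 0.2
tau(c(20, 20, 20, 20, 20))   # 0  — uniformly expressed
tau(c(0, 0, 90, 0, 0))       # 1  — single-tissue
```

`run_pipeline(config, out_dir)` chains the stages (simulation,
distances/trees, gene models, coincidence, τ, atlas homology, sex bias)
and writes TSV outputs plus a provenance manifest.

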