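---
title: "Models and methods for chemosensory transcriptome evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for chemosensory transcriptome evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprevol)
```

## The scientific setting

`exprevol` analyses how gene expression levels evolve across a clade of
closely related species sampled for several tissues, with replicates and,
for some tissues, both sexes. The package's running example is a
six-species *Drosophila* design (melanogaster, simulans, sechellia,
santomea, erecta, suzukii) spanning roughly 0.25–15 My of divergence, with
five chemosensory tissues of which three are sampled in both sexes and
three replicates per sample. All analyses operate on a rooted, calibrated
species tree; the packaged tree places the sim/sec split at 0.25 My, mel
vs (sim, sec) at 3 My, san/ere at 6 My, the subgroup crown at 10 My and
the suzukii split at 15 My — one calibration chosen within the published
range for these species and then held fixed.

Two stochastic processes carry all the modelling weight:

* **Brownian motion (BM)** — pure drift with rate $\sigma^2$
  (expression$^2$/My); the proxy for neutral expression evolution.
* **Ornstein–Uhlenbeck (OU)** — drift plus a restoring force of strength
  $\alpha$ (1/My) toward an optimum $\theta$; the proxy for stabilising
  selection. At stationarity the trait variance is $\sigma^2/(2\alpha)$
  and the correlation between two species decays as $e^{-\alpha d}$ with
  their patristic distance $d$.

Expression is modelled throughout on the $\log_2(\mathrm{TPM}+1)$ scale,
where the Gaussian process assumptions are exact for the synthetic data
and reasonable for real data. Replicates are species mean plus iid
Gaussian error with variance $\sigma^2_e$.

### Stationary versus fixed-root OU

The pipeline assumes the root state is drawn from the OU stationary
distribution. One mathematical consequence deserves a note: the
*stationary* OU likelihood does **not** converge to the BM likelihood as
$\alpha \to 0$, because the root variance $\sigma^2/(2\alpha)$ diverges;
the profiled log-likelihood drifts below BM like $\tfrac12\log\alpha$.
The classical BM limit belongs to the OU process *conditioned on the
root*. Both kernels are exposed
(`ou_covariance(..., stationary = FALSE)`, `fit_ou(..., stationary =
FALSE)`); the limit property is verified on the fixed-root form while all
pipeline fits stay stationary.

## Transcriptome distances and rate tests

The between-species transcriptome distance is $D = -\ln \rho$, with
$\rho$ the Pearson correlation of $\log_2(\mathrm{TPM}+1)$ species-mean
vectors over genes with mean TPM above 1 (the correlation is floored at
$10^{-6}$). Under a stationary OU model $\rho$ decays exponentially in
divergence time, making $D$ linear in time — the rationale for treating
it as an evolutionary distance. The gene filter reads "mean TPM across
species > 1"; the threshold is configurable.

Distance matrices feed Saitou–Nei neighbour joining, rooted on the
outgroup, with node supports from resampling genes with replacement (100
bootstraps by default). Supports are undefined for the trivial
ingroup/outgroup split and reported as blank there.

The relative-rate test asks whether ingroup lineage A diverged from the
outgroup more than ingroup lineage B:
$Z = (D_{AO} - D_{BO}) / \mathrm{SE}$, with the SE from a 200-resample
gene bootstrap (the SE construction is this package's choice; positive
$Z$ means A evolved faster). The subsampled significance procedure draws
1000 random subsets of 1000 genes per pair (both scalable), computes $Z$
on each, pools the subsample $Z$ of pairs whose full-data $|Z| \le 1.96$
into a non-significant reference distribution, and compares each pair's
$Z$ distribution against the reference maximum (right-tailed one-sample
Wilcoxon) and minimum (left-tailed) to call `elevated_A`, `elevated_B` or
`ns`. Pooling is over whichever pairs are passed in one call, so
per-tissue pooling is the natural usage and global pooling is a matter of
passing all pairs at once.

## Per-gene model selection and shift detection

For each gene and tissue the replicate-aware likelihoods of three models
are compared: BM, single-optimum OU (OU1), and multi-optimum OU (OUM)
with up to three optimum shifts — half the number of taxa — placed on any
of the ten edges of the six-taxon tree. Exhaustive enumeration replaces a
lasso search: $1 + \binom{10}{1} + \binom{10}{2} + \binom{10}{3} = 176$
configurations, exact and cheap at this tree size.

Each model is scored with a combinatorially corrected BIC ("pBIC-lite"):

$$\mathrm{pBIC} = -2\log L + k \ln N + 2 \ln \binom{E}{s}$$

with $k$ the free-parameter count (BM 3, OU1 4, OUM $s+4$), $N$ the
total observations and $E = 10$ candidate edges. The correction charges a
model for the number of ways its $s$ shifts could have been placed. The
exact determinant-based pBIC of lasso-based shift detectors is not
reproduced; pBIC-lite is this package's documented approximation.

Fitting profiles the optima and $\sigma^2$ analytically (GLS), leaving at
most a two-dimensional numerical problem in $(\log\alpha, \log\gamma)$
with $\gamma = \sigma^2_e/\sigma^2$, solved by bounded quasi-Newton from
a deterministic grid of five starts; $\alpha$ is bounded in
$[10^{-6}, 50]$/My, beyond which the surface is flat at this tree depth.
Estimation defaults to REML (mean-unbiased variance components); model
comparison always uses ML, since REML likelihoods are not comparable
across mean structures. Candidate configurations are first screened with
$(\alpha, \gamma)$ fixed at the OU1 estimates — under which richer
nested regimes can never lose likelihood, so the screen is conservative —
and the top three are re-fitted at their own ML before the final pBIC
comparison, mirroring how lasso-based detectors re-score candidate
configurations.

Selected models classify branches: BM genes contribute neutral edges,
OU1 genes constrained edges, OUM genes divergent shift edges within
otherwise constrained trees. Each shift edge yields a change event with a
direction (sign of the optimum change), the atoms of the overlap and
coincidence analyses.

### What detection can and cannot see

An optimum shift on an edge displaces a descendant tip by
$e^{-\alpha d}\,(1 - e^{-\alpha\,\mathrm{len}})$ of the optimum change,
where $d$ is the time from the edge's end to the tip. With $\alpha =
1$/My, a shift on a deep internal branch that ended 10 My before the
present displaces tips by under 0.005 of the shift — invisible to any
method. `edge_visibility()` computes this fraction per branch, and the
synthetic generator can restrict planted shifts to visible branches
(`min_visibility`), which is how the package's recovery studies are
designed. Even on fully visible branches, detection power at an optimum
shift of 4 stationary SDs is intrinsically limited: the likelihood gain
of the true configuration is of order $z^2/2 \approx 7$, barely above
the pBIC differential of $\approx 3.7$, giving per-gene power near
50–65%; shifts on the long outgroup branch are additionally confounded
with BM variance. The recovery studies report the measured rates rather
than presuming them.

## Coincidental index and overlap patterns

For one gene, events are grouped by branch: with $n_{obs}(t)$ the number
of tissues changed on branch $t$ and $T$ the number of tissues analysed,

$$\mathrm{CI} = \frac{\sum_t n_{obs}(t)}{\sum_t T}$$

summing over event-bearing branches. A gene with no events scores 0, a
single-tissue change scores $1/T$, and 1 means every event-bearing branch
changed in all $T$ tissues at once. Multiple branches each contribute
their own term. The tissue-overlap table bins changed genes by the exact
set of tissues with events (UpSet semantics), optionally restricted to
one branch. The association between coincidental changes and branch
length is a Spearman correlation of per-branch event counts against
branch lengths with a uniform-multinomial permutation null
($10^4$ permutations by default).

## Specificity, expression calls and gain/loss

τ specificity is $\sum_i (1-\hat x_i)/(n-1)$, $\hat x_i = x_i/\max x$,
computed on log1p-transformed values by default (the transform the
package adopts where only "log-transformed" is stated). It is 0 for
uniform expression and 1 for single-entity expression, and applies
unchanged to tissues or to cell clusters with $x_i$ either the cluster
mean expression or the fraction of cells expressing the gene (the two
variants give strongly correlated results). Per-tissue τ averages
replicates, sexes and species within a tissue before the formula.

Expression calls use the TPM thresholds 3 (expressed) and 0.5
(unexpressed); the interval between is an ambiguous dead zone. Gains and
losses are mapped to branches by parsimony on the fixed species topology
after pruning ambiguous species: the Fitch score gives the minimum number
of changes, all most-parsimonious reconstructions are enumerated exactly
(at most $2^5$ internal labelings), and an edge is reported as a definite
gain/loss only when every reconstruction agrees; otherwise it is
unresolved.

## Cell-type homology

Markers per cluster require in-cluster expression fraction ≥ 0.25, log2
fold change (cluster vs rest) ≥ 0.25, one-sided rank-sum p < 0.001,
positive only, ranked by fold change and capped at 100. The homology
score between clusters $i, j$ of two atlases is

$$\mathrm{score}(i,j) = \max(0, r_{ij}) \times
  \frac{|M_i \cap M_j|}{\min(|M_i|, |M_j|)}$$

with $r_{ij}$ the Pearson correlation of log1p cluster-mean expression
over the union of the two marker sets. Negative correlations are clipped
so the product stays in $[0,1]$; the marker-overlap fraction is
symmetrised with the min denominator so one matrix serves both
directions. Spearman correlation is available as an option.

## Sex-biased expression

The negative binomial engine is intentionally self-contained:
median-of-ratios size factors; an expression filter keeping genes with
normalized count ≥ 5 in ≥ 3 samples; gene-wise method-of-moments
dispersions floored at $10^{-8}$ with no empirical-Bayes shrinkage
(stricter than shrinkage-based engines for low counts); per-gene NB GLMs
with log link and size-factor offsets under
`~ tissue + sex + tissue:sex`; Wald tests on the per-tissue male-vs-female
contrast; BH adjustment across genes within each tissue. A gene is
male-biased at fold change ≥ 1.5 with adjusted p < 0.01, female-biased at
the reciprocal. The 1.5 threshold is applied on the linear scale by
default with a log2-scale option, the two readings both being in
circulation for this cutoff. Overlap across species or tissues counts
genes sharing the same bias direction, with upper-tail hypergeometric
enrichment for annotation sets among conserved-bias genes.

## The synthetic-data generators

`simulate_panel()` draws per-gene species means from the exact BM/OU
kernels on the tree (multi-optimum means by exact conditional
propagation along edges, so planted shifts have analytically known
expected tip means), adds iid replicate noise, and exponentiates to TPM.
Planted "changer" genes receive optimum shifts of `delta` stationary SDs
in randomly chosen tissues, all on one branch with probability
`coincidental_fraction` and on independent branches otherwise.
Defaults mirror the study design: 6 species, 3 replicates, five tissues,
two sexes for three tissues. Counts are NB-sampled around TPM ×
library-size means. Toy atlas pairs plant marker sets and correlated
cluster profiles with a saturating dropout model linking expression to
detection fraction; toy alignments plant exact gap runs with per-species
genomic anchors.

For transcriptome-level studies the default trait process is
$\alpha = 0.02$/My, $\sigma^2 = 0.05$: across 0.25–15 My this reproduces
the correlation scale of real cross-species transcriptomes (species-mean
correlations ≈ 0.75–0.99) — species would be essentially uncorrelated at
$\alpha \approx 1$/My, contradicting the tight phylogenetic clustering
such data show. Gene-level model-selection studies use the stronger
selection regimes stated with each study ($\alpha$ = 0.5–1/My).

What the generators do *not* emulate: read-level sampling, gene length
and GC biases, correlated expression across genes, dropout structure
beyond the saturating mean–detection curve, and annotation errors.
Passing recovery tests therefore demonstrates correctness of the
estimators under the generating model, not robustness to everything real
data contain.

## Validation design and measured behaviour

The test suite fixes every seed and runs, besides unit and property
tests, a set of recovery studies: 500 genes with single planted shifts
(4 stationary SDs, $\alpha = 1$/My, visible branches), 1000 equal-rate
panels of 500 genes for the relative-rate type-I error, 2000 BM genes
for $\sigma^2$ recovery, ten atlas pairs at planted correlation 0.9 for
homolog matching, and 100 planted 4-fold sex effects among 3000 genes
(planted in expressed genes — a 4-fold change in a gene with a handful
of counts is undetectable with three replicates at any threshold, which
is what the expression filter is for).

Two documented limits of the method at this problem size surface there.
First, per-gene shift detection at 4 stationary SDs sits near 50%
(see the power discussion above), so the shift-recovery study reports a
rate well below what larger effects or more taxa would give. Second, the
per-gene $\sigma^2$ estimate carries $n_{species}-1 = 5$ evolutionary
degrees of freedom, so its sampling distribution is $\chi^2_5$-like:
REML makes the mean unbiased (measured ≈ 1.02) while the median sits
near $q_{\chi^2_5}(0.5)/5 = 0.871$ (measured ≈ 0.89) — a skew property
of any correct estimator at six taxa, not a defect of this one.

## Worked example

```{r, eval = FALSE}
library(exprevol)
tree <- example_species_tree()

spec <- sim_spec(n_genes = 200, seed = 1,
                 params = ou_params(alpha = 1, sigma2 = 1, sigma2_e = 0.05),
                 changers = list(n = 40, delta = 4, tissues_per = 2,
                                 coincidental_fraction = 0.3,
                                 min_visibility = 0.5))
panel <- simulate_panel(spec)

## expression tree for one tissue
sm <- species_mean_tpm(panel, "antenna")
nj <- nj_tree(sm, outgroup = "Dsuz", n_bootstrap = 100, seed = 1)

## per-gene model selection -> change events -> coincidence
fits <- fit_gene_models(panel_traits(panel, "antenna"), tree,
                        tissue = "antenna")
events <- change_events(fits)
coincidental_index_all(events, n_tissues = 5)
```

The same stages, plus atlas homology and sex-bias testing, are wired
together by `run_pipeline()`; `scripts/acceptance.R` recomputes the
package's worked-example statistics into a JSON report.
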