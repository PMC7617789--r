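---
title: "Basal cell competition on a lattice and multi-site clone inference"
author: "basalClones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basal cell competition on a lattice and multi-site clone inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basalClones)
```

# Overview

`basalClones` implements two connected analyses of clonal dynamics in a
carcinogen-exposed airway epithelium:

1. a **lattice voter model** of basal-cell competition in a mosaically
   labeled epithelium, scored through the size distribution of "voids"
   (connected clusters of unlabeled cells), and
2. **multi-site somatic clone inference**: Dirichlet-process clustering of
   variant allele fractions (VAFs) across microbiopsies, followed by
   pigeonhole-principle phylogeny reconstruction and anatomical territory
   mapping.

A synthetic-data layer generates ground-truthed inputs for every stage, so
the whole pipeline is testable without imaging or sequencing data.

# The lattice model

## Neutral dynamics

The basal cell layer is a 2D lattice in which each cell carries a heritable
label bit (mosaic lineage marker) and a genotype bit (normal or fitter
mutant). Homeostasis is modeled as a voter process: in each elementary
event a uniformly chosen cell is lost (differentiation) and its site is
filled by a copy of a random neighbour (duplication). One Monte-Carlo sweep
is `nRows * nCols` elementary events under random sequential update. Time
is measured in sweeps; we make no attempt to calibrate sweeps to weeks,
because the basal division rate is a free constant that does not affect the
scaling analysis.

Design choices, where the biology does not pin them down:

* **Geometry** — rectangular lattice with 4-neighbour (von Neumann)
  connectivity by default; 8-neighbour is available. Four-connectivity is
  the canonical voter-model choice and all defaults follow it.
* **Boundaries** — periodic in both axes by default (the trachea is a
  closed tube circumferentially; periodic proximo-distal boundaries
  minimize edge effects on a finite lattice). A
  circumferential-periodic/closed-row mode approximates a half-trachea
  whole-mount, and a fully closed mode suits digitized image patches.
* **Labeling** — `seedLabels()` supports i.i.d. Bernoulli labeling, small
  contiguous seed clones (`generateLabelField()`, emulating the few-day
  post-induction pattern), and verbatim masks digitized from whole-mounts.

Two classical properties anchor the tests: the ensemble-mean labeled
fraction is a martingale, and fully labeled or unlabeled lattices are
absorbing.

## Non-neutral dynamics

Carcinogen exposure is modeled by seeding a small fraction $\rho$ of cells
(i.i.d., default configurable, 0.01 in the examples) with a *fitter*
genotype. At a contested replacement the copying neighbour is drawn with
weight 1 for normal cells and `selection` for fitter cells. The default is
`selection = Inf`: a fitter neighbour always wins the contest, fitter cells
compete neutrally *with each other*, and — so that the fitter area fraction
is non-decreasing in every realization — a loss event at a fitter site with
no fitter neighbour is a rejected no-op (normal lineages never displace
fitter cells). Finite `selection > 1` is exposed for sensitivity analysis;
there the no-op rule does not apply.

A regime worth understanding before running experiments: with
`selection = Inf` the fitter interface advances on the order of one cell
per sweep, so fitter clones seeded at density $\rho$ meet and complete a
lattice takeover after roughly $1/\sqrt{\rho}$ sweeps. After takeover the
dynamics are again neutral (among fitter cells) and the void distribution
relaxes back towards the neutral scaling form. The distinctive non-neutral
signature — an excess of large voids — therefore lives in the
*pre-takeover* window, when fitter clones are already larger than the
neutral coarsening scale but have not yet merged. The property suite tests
the excess in that window ($\rho = 0.002$, 15 sweeps on a 128-lattice,
tail probability at 200 cells); at $\rho = 0.01$ observed 500 sweeps after
seeding, takeover is long complete and we measure no excess in the
conditional tail at 50 cells.

## Void analysis

`findVoids()` labels connected components of unlabeled cells (union-find,
honouring periodic wrap), drops components below `minSize` (default 2:
only regions larger than one cell are analyzed), and returns the empirical
exceedance curve $P(S \ge s)$. `fitPowerLaw()` regresses
$\log_{10} P(S \ge s)$ on $\log_{10} s$ over a size range (default 2–100).
Under neutral competition the cumulative distribution decays with an
exponent around $-1$; the acceptance script reproduces this from a
200-replicate ensemble.

`compareToModel()` scores observed curves against an ensemble:
replicate curves are interpolated at the observed sizes (linearly in
log-log space), averaged, and summarized as
$R^2 = 1 - SS_{res}/SS_{tot}$ computed on $\log_{10}$ exceedance values.
The log-scale convention is stated openly: distributions are compared on
the scale on which they are inspected (log-log), and the published
comparison does not specify the recipe. Observed sizes covered by fewer
than half the replicate curves (configurable) are excluded and reported.
Sizes are in cells throughout; conversion to area is a user-supplied scale
factor that leaves the exponent unchanged.

# Clone inference from multi-site sequencing

## Dirichlet-process VAF clustering

`gibbsCluster()` clusters mutations whose alt/total read counts across $S$
microbiopsies follow a common per-sample VAF profile. The model is a
Dirichlet-process mixture: mutation $m$ in cluster $c$ has

$$\mathrm{alt}_{ms} \sim \mathrm{Binomial}(\mathrm{depth}_{ms},
  \theta_{cs}), \qquad \theta_{cs} \sim \mathrm{Beta}(a, b),$$

independently across samples, with DP concentration $\alpha$ (default 1)
and a flat Beta base measure (default $a=b=1$). $\theta$ is integrated out
and cluster memberships are sampled by collapsed Gibbs; the number of
clusters varies freely along the chain. The default schedule is 5,000
burn-in plus 5,000 sampling iterations — the published setting — and
reduced schedules used in tests are configuration, not a different model.

Hard assignments use the posterior similarity matrix: average-linkage
clustering on one minus the co-assignment probability, cut at 0.5. This is
label-switching-proof and standard for DP mixtures; the MAP iteration is
retained in the diagnostics as an alternative. Cluster VAFs are conjugate
posterior means over members, and mutant cell fractions follow the diploid
heterozygous mapping $CF = \min(2\theta, 1)$ (`computeCF()`). Copy-number
aware CFs are out of scope. `filterClusters()` applies the
minimum-cluster-size rule (default 50 mutations, never silently changed);
`prefilterClusters()` applies the median-VAF $\ge 0.1$ rule before
phylogeny building. Note that a clone confined to a few samples can have a
low *overall* median VAF even when it is prominent where present; analyses
of spatially confined clones may legitimately lower the threshold, and the
demo configuration does so explicitly.

## Pigeonhole phylogeny

`nestingTest()` classifies an ordered cluster pair from point CF
estimates: A is nested in B when A's CF is below B's (within `epsilon`) in
every sample where B is present and A is absent elsewhere; the evidence is
*strong* when their CFs sum to more than 100% in some shared sample (the
clones must then overlap, so the smaller is a subclone), otherwise *weak*.
Profiles that cross are independent. Samples where only the putative child
is detected count against nesting and the pair reads as independent — the
conservative choice for an unstated corner case. `epsilon` defaults to
0.05 on CF point estimates because binomial noise at ~24x depth makes
exact inequalities brittle; the presence floor defaults to CF 0.01. CFs
are capped at 1 before testing.

`buildTree()` sorts clusters by descending total CF and attaches each to
the smallest already-placed cluster that contains it (maximal nesting);
clusters contained in none become additional roots, so a forest across
anatomical compartments is a normal outcome. Mutually strong-nested pairs
(possible only for CFs equal within `epsilon`) are flagged and resolved by
total CF, never silently. Every emitted tree carries a pigeonhole audit:
for each parent and sample, the children's CFs must not exceed the
parent's beyond `|C| * epsilon`. For five or fewer clusters the tests
compare `buildTree()` against exhaustive enumeration of all
nesting-consistent forests. `mapClonesToSites()` joins the tree with a
site map and reports per-site clone composition and per-lineage
territories.

# Synthetic data

`generateTreeScenario()` draws a random rooted clone tree and a
pigeonhole-consistent CF matrix. Each clone peaks in a clone-specific
"home" sample, and draws are retried until all clone pairs are separated
by at least `minCfSeparation` (default 0.15) in some sample and all
non-ancestral pairs cross — without crossing, an unrelated small clone
whose profile sits entirely under an unrelated larger one is
*information-theoretically* indistinguishable from a subclone, and no
method could recover the truth. `generateCloneCounts()` draws depths from
a per-sample negative binomial (variance $\mu + d\mu^2$; $d = 0$ gives
fixed depth, the exact-test mode) chosen to emulate low-input whole-genome
depth variability around a median of ~24x, and alt reads as
$\mathrm{Binomial}(\mathrm{depth}, CF/2)$. There is no sequencing-error
model: variant calling is out of scope, so alt reads arise only from true
carriers. `exampleTreeSpec()` is a fixed six-clone, six-sample scenario
(a ubiquitous founder, two regionally confined lineages, three subclones)
used by the demos and the end-to-end tests.

`generateLabelField()` grows non-overlapping, non-touching label patches
by random walk, so every labeled component has at most `cloneSeedSize`
cells; patch size 1 reduces to Bernoulli labeling. Because patches must
not touch, dense fractions can be unreachable — the generator then errors
and reports the achieved fraction rather than silently under-delivering.

What the generators do *not* emulate: sequencing error and mapping
artefacts, copy-number alterations, mutational-signature composition,
anisotropic clone shapes along smooth-muscle bands, and 3D tissue
architecture. Tests passing on these synthetics demonstrate correctness of
the inference machinery under its own model assumptions, not robustness to
those real-data complications.

# Orchestration and reproducibility

`runExperiment()` runs configured stage lists
(`synth_labels -> simulate -> voids -> fit -> compare` and
`synth_clones -> cluster -> filter -> tree -> territory`) with a single
global seed; per-stage seeds are `seed + 1000 * offset` with fixed,
manifest-logged offsets, and replicate $r$ of an ensemble uses
`seed + r`. Every run writes a `manifest.json` echoing the fully resolved
configuration, so a manifest re-ingested as a configuration reproduces the
run plan; deterministic outputs are byte-identical on rerun. Unknown
configuration keys are rejected rather than ignored. A thin command-line
wrapper (`inst/scripts/clonefield.R`) exposes the same stages to shell
users; the package functions remain the primary interface.

Problem sizes used by the shipped checks are the study-scale conditions
for the headline ensemble (256 x 256 lattice, 200 replicates, 500 sweeps)
and deliberately smaller configurations elsewhere (reduced Gibbs
schedules, 96-lattice demos), chosen so the full suite runs comfortably on
a laptop; the model and defaults are unchanged by these reductions.

# Known limitations

* The voter model is strictly 2D and isotropic; luminal layers, explicit
  division/delamination mechanics and EdU-calibrated rates are out of
  scope.
* CF estimation assumes diploid heterozygous autosomes; no copy-number
  adjustment.
* The DP clustering is per-individual; clusters are not shared across
  individuals (no hierarchical coupling).
* Pigeonhole reconstruction uses CF point estimates with a single
  `epsilon`; no per-cluster uncertainty propagation.
* The maximum-likelihood tail estimators of the power-law literature are
  intentionally absent: the regression fit is the published comparison.

# A worked example

```{r example, eval = FALSE}
library(basalClones)

# lattice arm
field <- seedLabels(128, 128, labelFraction = 0.5, seed = 1)
final <- runSimulation(field, nSweeps = 100, seed = 1)[[1]]
fit <- fitPowerLaw(findVoids(final), fitRange = c(2, 100))
fit

# sequencing arm
sim <- generateCloneCounts(exampleTreeSpec(), seed = 1)
cc <- gibbsCluster(sim$counts, burnIn = 500, nSamples = 500, seed = 1)
tree <- buildTree(prefilterClusters(filterClusters(cc, 20), 0.02))
tree
```
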