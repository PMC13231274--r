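---
title: "Models and methods behind mullerx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mullerx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mullerx)
```

`mullerx` reconstructs the evolutionary history of fly sex chromosomes from
tables of reference genes mapped onto other genomes. This vignette explains
each model, its assumptions and tunable parameters, the numerical choices
made where several reasonable implementations exist, and what the
synthetic-data generators do and do not emulate.

## Gene maps and filtering

The unit of data is a **gene map**: one row per reference
(*D. melanogaster*) gene with its Muller element label (inherited from the
reference annotation, never inferred from the target) and its placement in
a target assembly. Coordinates are 0-based half-open throughout, the
convention of BLAT PSL output, and overlap length between two placements is
`max(0, min(end) - max(start))`.

Raw translated-alignment hits are reduced in two steps:

1. **Best hit per gene** (`best_hit_filter()`): the placement with the
   largest alignment score. Score ties are broken by the lexicographically
   smallest (chromosome, start) pair — an arbitrary but platform-stable
   rule chosen because any tie rule is defensible and determinism matters
   more than the choice itself.
2. **Overlap filter** (`overlap_filter()`): two retained genes on the same
   chromosome may overlap by strictly less than 20 bp; an overlap of
   exactly 20 bp violates the rule ("retention requires < 20 bp"). The
   lower-scoring member of each offending pair is dropped (ties: the
   lexicographically larger gene id), iterating until no violation
   remains. Dropping the lower score keeps the better-supported placement;
   iteration is necessary because removals can expose new closest pairs.

Genes on unplaced scaffolds stay in the table, flagged, so each downstream
stage can decide whether to use them: they are excluded from enrichment
margins (see below) and render movement calls undetermined.

## Chromosome–element homology

If a fraction $P_1$ of mapped genes lies on chromosome 1 of one species and
$P_2$ on chromosome 2 of another, then absent homology the chromosomes are
expected to share $E = P_1 P_2 N_{\mathrm{total}}$ genes, where
$N_{\mathrm{total}}$ counts genes mapped (and placed) in both species. A
pair is called homologous when

* observed / expected **strictly** exceeds 1.5 (`ratio_threshold`); the
  threshold is strict because the rule is an excess *above* 1.5-fold;
* a one-sided (greater) Fisher's exact test on the 2×2 table
  (on/off element × on/off chromosome) gives $p < \alpha$ (default 0.05);
* at least `min_observed = 2` genes support the call — a single shared gene
  cannot establish homology, however enriched.

Two open implementation choices were resolved as follows. Unplaced genes
are excluded from **both** margins of the table (rather than pooled into
the off-chromosome margin), because an unplaced gene carries no evidence
about any placed chromosome. No multiple-testing correction is applied
across chromosome pairs by default — the calls are typically so extreme
(p < 1e-100 for real homologies) that correction never changes them — but
`p_adjust = "BH"` is available.

**Karyotype classification** (`infer_karyotype()`) reduces the calls to an
event class keyed on element F, the ancestral X: F alone on the X
(`ancestral_X`); F plus other elements on the X (`X_autosome_fusion`); F
not on the X (`turnover`), subdivided by F's autosomal fate — alone on an
autosome (reverted, unfused), sharing an autosome with another element
(`turnover_with_F_fusion`), or not confidently placed (fate unresolved).
An empty X complement yields `unresolved` with a warning.

**Fusion origins** are counted by parsimony with losses allowed and absence
ancestral at the root; among all minimum-change reconstructions the one
with the fewest 0→1 transitions is reported (implemented as weighted
parsimony with gain cost $1+\varepsilon$, $\varepsilon = 10^{-6}$, which is
lexicographically exact for trees with fewer than $10^6$ tips). The split
of fusions between X-involving and autosome–autosome events is compared to
the random-pairing expectation: with $k$ of $\binom{n}{2}$ unordered
element pairs containing an X element, $m$ fusions are expected to produce
$mk/\binom{n}{2}$ X-involving events (2.67 of 8 with six elements and one
X).

**Element co-option** concentration is tested with a Monte-Carlo
max-statistic multinomial test: the p-value is the probability, under
uniform allocation of the observed events across the candidate elements,
that some element collects at least the observed maximum. A Monte-Carlo
construction was chosen because the exact form of a "binomial test" on a
maximum across categories is ambiguous (naive binomial tails ignore the
maximum's selection effect); the estimator converges to the exhaustive
enumeration value, which the tests verify at small event totals.

## Turnover-rate models on the phylogeny

The turnover character (0 = element F still the sole X, 1 = turnover
happened) evolves by a two-state continuous-time Markov chain with gain
rate $q_{01}$ and loss (reversal) rate $q_{10}$. With $s = q_{01}+q_{10}$,
the transition matrix over a branch of length $t$ is closed-form:
$P(0\!\to\!1) = \tfrac{q_{01}}{s}(1-e^{-st})$. The likelihood is computed
by Felsenstein pruning with per-node rescaling (numerically safe on long
trees), handling multifurcations natively — internal polytomies are never
arbitrarily resolved.

* **Models.** ER constrains $q_{01}=q_{10}$ within a regime; ARD frees the
  two directions. A regime map (`regime_paint()`) assigns every branch to
  a regime — e.g. a focal clade vs the background — giving 1, 2, 2 or 4
  parameters for ER/ARD × single/two-regime. The stem branch of the focal
  clade belongs to the focal regime by default (`include_stem = TRUE`): a
  rate shift is most naturally placed at the origin of the clade, and the
  choice is exposed as a flag.
* **Root prior.** Flat (1/2, 1/2) by default, the common default of the
  reference implementations of this model family; a stationary prior is
  available.
* **Optimization.** Bounded multi-start search (`nlminb`) on log rates in
  $[10^{-8}, 10^3]$ with relative tolerance $10^{-8}$ and 5 starts by
  default (one tree-length heuristic start — about one expected change per
  mean root-to-tip depth — plus seeded log-normal jitter). The
  two-parameter surfaces here are well behaved; the calibration studies
  below pass with 2–3 starts, and the number is an exposed argument.
* **Model comparison.** `lrt()` refers $2\Delta\ell$ (floored at zero) to
  $\chi^2$ with df equal to the parameter difference, and refuses
  non-nested pairs or an alternative likelihood below the null beyond
  tolerance (an optimizer-failure signal, not a statistical result).

Degenerate data (all tips in one state) drive the rate to the lower bound
with likelihood $\log \tfrac12$ under the flat prior; the fit is flagged
rather than refused.

## Brownian-motion ancestral reconstruction

The percentage of mapped genes on element F is treated as a continuous
trait under Brownian motion. With tip covariance $C$ (shared root-to-tip
path lengths), the root mean $\hat\mu$ and diffusion rate $\hat\sigma^2$
are estimated by GLS/ML, and each internal node gets its conditional
expectation
$\hat a_k = \hat\mu + v_k^\top C^{-1}(x-\hat\mu\mathbf 1)$ and variance
$\hat\sigma^2\!\left(c_k - v_k^\top C^{-1}v_k +
(1-\mathbf 1^\top C^{-1}v_k)^2/(\mathbf 1^\top C^{-1}\mathbf 1)\right)$,
where $v_k$ holds the node's shared path lengths with each tip and $c_k$
its depth. Confidence intervals are $\hat a_k \pm 1.96\sqrt{\cdot}$. Note
the ML $\hat\sigma^2$ (divisor $n$) is used throughout; reference
implementations that use a REML-flavoured rate give identical point
estimates but slightly wider intervals. Zero-length internal branches are
collapsed into multifurcations before inversion; duplicate zero-length
tip paths make $C$ singular and are refused with an explicit error.
`compare_node_sets()` contrasts reconstructed values between two disjoint
node sets with a two-sided Mann–Whitney test — the natural nonparametric
choice when no distributional claim about node estimates is warranted.

## GC content

`gc_windows()` tiles each sequence with fixed windows (default 100-kb
window and step, the standard genome-scan resolution; the trailing partial
window keeps its true length). GC fraction is $(G{+}C)/(A{+}C{+}G{+}T)$,
case-insensitive; ambiguous bases are excluded from the denominator so
that assembly gaps cannot masquerade as AT-rich sequence. Windows with
fewer than half the nominal window of unambiguous bases are flagged and
excluded from comparisons — this also removes short trailing fragments.
The X-vs-autosome contrast is a two-sided Mann–Whitney on included
windows; adjacent windows are autocorrelated in real genomes, so the
result carries a pseudoreplication caveat rather than a correction.

## Gene movement from trios

For a focal species whose X derives from a large element, with two
outgroups retaining F as the X: chromosomes are matched between each
outgroup and the focal species by the same 1.5× enrichment rule (each
source chromosome keeps its best-ratio partner; several sources may share
a target, as under fusion). A gene's ancestral location is the focal
chromosome its two outgroup placements agree on; disagreement, absence,
or unplaced scaffolds leave it undetermined. A movement is called when the
focal placement differs from the ancestral one.

Categories use the chromosome's identity **in the focal species**: a gene
that stayed on the element that was co-opted as the X has not moved
(category `none`), and "out of the X" means off the chromosome that is
the X today. The null model weights each ordered chromosome pair
$i \neq j$ by $N_i L_j f_{ij}$ — genes available to move, physical target
size, and $f_{ij} = 0.75$ for X destinations (the X's reduced population
copy number) — normalizes, bins into A→A / A→X / X→A, and compares
observed counts by Pearson's chi-square with df = bins − 1. Expected
counts below 5 warn but do not fail, and a category observed against a
zero expectation is an error. Per-chromosome loss fractions are made
comparable across species by dividing by the fraction of genes on the
other chromosomes (`normalized_loss_fraction()`).

Expression follow-up (`compare_expression()`) is a two-sided Wilcoxon of
the moved genes' per-tissue values against all mapped genes — the
background deliberately **includes** the group, matching standard
practice for "group vs all" comparisons; with group sizes a small
fraction of the background the self-overlap is negligible, which the
calibration study confirms.

## Synthetic data: what it emulates, and what it does not

The generators produce data with complete, sufficient ground truth:

* `sim_gene_maps()` — per-species placements with planted karyotype
  events; genes mismap to a uniformly chosen wrong chromosome at rate
  0.02 (a realistic translated-alignment error level) and land on
  scaffolds at rate 0.01; coordinates are laid out in non-overlapping
  slots. Element F carries 1% of genes by default — schizophoran X-linked
  F carries under 1.25% of mapped genes, and a 2.5% setting approximates
  non-schizophoran genomes.
* `sim_mk_tips()` / `sim_bm_tips()` — exact generative counterparts of
  the likelihood models (exponential waiting times; normal increments).
* `sim_fasta()` — i.i.d. bases at a controlled GC mean, optional N runs.
  Real base composition is autocorrelated (isochores, repeats); i.i.d. is
  adequate for validating rank-based window comparisons but understates
  the variance of window GC in real genomes.
* `sim_trio()` — relocations drawn from the null's own pair weights, with
  an optional multiplier on X→A weights to plant an excess; movement is
  wholesale relocation (no retained parent copies).
* `sim_expression()` — log-normal tissue values with a planted testis
  multiplier on moved genes.

Passing the recovery and calibration tests therefore shows the estimators
are correct **under their own assumptions**; it does not certify
performance under correlated mismapping, assembly-specific biases, or
duplication-mediated movement, none of which the generators model.

## Problem sizes and seeds used in the validation suite

The statistical acceptance studies use: 100 random trees of up to 6 tips
for the likelihood oracle; a fixed 150-tip coalescent tree scaled to total
length 60 (about 30 expected changes at $q=0.5$, enough signal for a
well-conditioned likelihood) with a 78-tip focal clade for the 500-replicate
LRT size study; 100 200-tip datasets for rate recovery; 50 random trees up
to 20 tips for the GLS oracle; 200 noisy species (1600 genes, 2% mismap)
for karyotype recovery; 500 multinomial draws plus 100 full trio runs
(2000 genes, 250 moves) for the movement null; 200 replicate 120-kb
genomes for the GC contrast; and 400 null resamples plus 100 planted-effect
runs for expression. All simulations are seeded and byte-reproducible.

## Known limitations

* Homology calls treat genes as exchangeable; clustered mismapping (e.g.
  segmental duplications) can inflate enrichment locally.
* The Mk machinery is strictly two-state; multi-state or hidden-rate
  turnover models are out of scope.
* The movement null conditions on present-day gene counts and chromosome
  sizes, as in the original formulation; it does not model lineage-specific
  gene loss.
* GC windows use a fixed grid, not isochore segmentation, and the X/A
  comparison inherits the pseudoreplication caveat above.
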