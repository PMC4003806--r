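---
title: "Mapping QTL from pooled segregants: the model behind bsaHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL from pooled segregants: the model behind bsaHMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaHMM)
```

## The experiment and the signal

A bulk-segregant experiment crosses a superior and an inferior parental
strain, selects haploid segregants for the phenotype, pools them, and
sequences the pool. At every polymorphic marker site we observe
`superiorCount` reads carrying the superior-parent variant out of
`totalCount` reads. Markers linked to a causal site are over-represented
for the superior allele; the over-representation decays with physical
distance at the rate at which meiotic recombination decouples loci.
Because a causal locus drags a whole linkage-disequilibrium (LD) block
with it, the informative unit is a *region* of consistently skewed
markers, not any single marker.

## The hidden Markov model

Each marker is in a hidden state: linked (P) or neutral (N). Emissions
are beta-binomial — a binomial whose success probability is itself
beta-distributed — because pooled counts are overdispersed relative to a
binomial: the pool is a finite sample of segregants, so the true allele
fraction at a site varies around its expectation from experiment to
experiment and from LD block to LD block.

* N state: `BetaBin(n, alphaN, betaN)` with `alphaN ≈ betaN`, centered
  near 1/2. Both shapes are estimated from the data (below).
* P state: `BetaBin(n, alphaP, betaP)` with `betaP = 1` fixed and
  `alphaP` free. The ratio `alphaP/betaP` is the stringency: with
  `betaP = 1` the P emission is monotonically increasing in the allele
  fraction, and larger `alphaP` concentrates it near 1, demanding a
  stronger skew before a site is interpreted as linked. Defaults:
  `alphaP = 10` (permissive); 15 is a good recovery/size trade-off and
  30 a stringent preset.

Transitions encode LD. Across an inter-marker gap of `l` bp the chain
*stays* in N with probability `exp(-rate * l)` and in P with probability
`exp(-rate * l * sExp)`; switching probabilities are the complements.
Nearby markers therefore almost surely share a state, while markers
hundreds of kilobases apart are nearly independent. Notes on this
parameterization:

* `rate` (per bp, default `3.5e-6`) plays the role of a recombination
  rate: it is the scale at which one expects state-decoupling crossovers,
  a yeast-genome-scale estimate. Overestimating it makes markers
  independent and lets isolated noisy markers form spurious calls;
  underestimating it is nearly harmless (posteriors just smooth more).
* The persistence orientation (`stay = exp(-rate*l)`) is the one
  consistent with the LD rationale: the probability of *changing* state
  grows with distance from 0 toward 1. The package exposes a sanity
  property: as `rate -> 0` the whole chromosome shares one consensus
  posterior, and when `rate * l = ln 2` (stay probability exactly 1/2)
  the transition rows are uniform and each site reduces to its single-site
  Bayes posterior. Both are pinned by tests.
* `sExp` (default 1) rescales only the P-state exponent, allowing an
  asymmetric persistence of linked stretches. It is exposed but rarely
  worth moving; the default keeps the two states symmetric.
* The initial distribution is `(piN, piP) = (0.5, 0.5)`. With hundreds
  of markers per chromosome the posterior is dominated by emissions and
  transitions, so the prior at the first marker is immaterial; it is
  configurable for completeness.

Posteriors are computed by the forward–backward algorithm with per-site
normalization (scaling) of the forward and backward variables; emissions
enter after subtracting the per-site maximum log-emission, so the
recursion never under- or overflows even at coverage in the hundreds
with extreme shape parameters. Each chromosome is decoded independently.
The decoder is checked against exhaustive enumeration over all `2^L`
state paths for chains up to 12 sites at tolerance 1e-10.

Chains are *not* broken at large inter-marker gaps (e.g. across a
centromere with no markers): the exponential decay already drives the
stay probability toward 1/2 across such gaps, which is exactly the
independence one would impose by cutting the chain.

## Two-step neutral estimation

Most of the genome is neutral, so `(alphaN, betaN)` can be estimated
from the bulk of the data by the method of moments on the per-site
fractions `p_i = superiorCount_i / totalCount_i`: with mean `mu`,
variance `v`, and mean coverage `nbar`, the intraclass correlation is

    rho = (v * nbar / (mu * (1 - mu)) - 1) / (nbar - 1)

and `alphaN + betaN = 1/rho - 1`, split in proportion `mu`. Per-site
coverages are unequal; using the mean coverage in the moment equation is
the standard beta-binomial approximation and is accurate when coverage
variation is modest (inside a 20–100 read filter window, or with fixed
simulated coverage, it is). Two numerical guards keep the pipeline
total: `rho` is clamped to `[1e-6, 1 - 1e-6]`, so underdispersed
(near-binomial or degenerate) data yield a large but finite
concentration (`1e6 - 1`) instead of an error, and the estimator refuses
only truly degenerate input (all fractions 0 or 1).

The first fit is contaminated by the linked block itself, which inflates
both the mean and the variance. Step two therefore decodes once with the
step-1 parameters, discards every site with linkage posterior above the
significance cutoff, and re-fits on the remainder; the final decoding
uses the refined parameters. If the refinement would discard everything,
the step-1 estimates are kept with a warning. On purely neutral data the
two steps agree to Monte-Carlo noise (a test pins this), so the
refinement only matters when there is signal to remove — which is
exactly when it matters most.

## Region calling and evaluation

A marker is significant when its posterior exceeds 0.95 (strictly).
Maximal runs of consecutive significant markers become regions — no gap
tolerance, so a single sub-threshold marker splits a run. Regions are
scored against a known causal position by strict containment: the
recovery indicator, the size (bp) of the containing region, and the
count of non-containing (false-positive) regions; fragments of a split
true region count as false positives. This is the conservative,
unambiguous bookkeeping; it slightly overstates false positives when a
true region fragments under an overestimated `rate`.

## The simulator

`simulateDataset()` emulates one standard experiment: a 750 kbp
chromosome with 2500 uniformly placed polymorphic sites (one causal,
chosen uniformly); haploid segregants built by recombining the parents
with Poisson crossovers at 0.37 cM/kb (intensity `3.7e-6`/bp, the
small-distance Haldane limit — the agreement of explicit breakpoints
with the odd-crossover discordance formula `(1 - exp(-2*rho*l))/2` is a
test); pool selection in which a carrier of the causal superior allele
is accepted with probability PSC and a non-carrier with 1−PSC, until
`n = 30` segregants are pooled (so the expected pooled carrier fraction
equals PSC); and sequencing at fixed per-site coverage `c = 200` with a
symmetric per-read error of 0.01. Poisson-distributed coverage is
available (`coverageMode = "poisson"`); fixed coverage is the default
because it matches the deterministic phrasing of the design and makes
test expectations sharper. Reads sample pooled segregants uniformly with
replacement; the superior count is drawn directly from its exact
marginal, `Binomial(total, f*(1-e) + (1-f)*e)` with `f` the pool's
superior-origin fraction at the site — distributionally identical to
per-read simulation and much faster. One chromosome, one causal site;
replicate seeds derive deterministically from a master seed
(`replicateSeed()`).

What the simulator does *not* emulate: alignment and variant-calling
artifacts, repetitive or copy-number-variable regions, coverage that
varies systematically along the genome, multiple or interacting QTL, and
diploid designs. Passing simulation benchmarks therefore demonstrates
the statistical behavior of the method under its own assumptions, not
robustness to upstream artifacts — on real data those are handled by the
marker filters (genotype quality ≥ 40, then coverage within [20, 100],
then a 30 bp minimum spacing that removes *both* members of any
too-close pair; that order is fixed and tested, and the spacing rule is
deliberately survivor-free so it cannot depend on processing order) and
by whatever repeat/CNV pre-filtering the upstream pipeline applies.

## False positives and the pool-size effect

Two benchmark bounds are re-computed from scratch by
`scripts/acceptance.R`: the mean number of false-positive regions per
dataset stays below one both at the standard setting (2500 markers,
`alphaP/betaP = 15`) and at the permissive high-marker corner (10000
markers, `alphaP/betaP = 5`), 100 replicates each.

An instructive subtlety: with a small pool (`n = 30`) an *unselected*
(PSC = 0.5) experiment still produces occasional called regions, because
the pooled allele fraction drifts with standard deviation
`0.5/sqrt(n) ≈ 0.09` and whole LD blocks can sit near 0.72 — a skew the
model correctly reads as real in the pool, merely not phenotype-caused.
Even then false calls average well below one per dataset. The cleaner
null statement — an unselected pool almost never yields a region —
belongs to a control-pool-sized experiment: at `n = 131` (the size of a
typical unselected control pool) the drift shrinks to ~0.044 and
essentially all replicates call nothing; the acceptance suite runs that
null at `n = 131` and the below-one bound at `n = 30`.

## Fine-mapping with individual segregants

Once a region is called, individually genotyped segregants narrow it:
at each candidate marker, `k` of `m` scored segregants carry the
superior variant, `k ~ Binomial(m, 1/2)` under no linkage. The package
uses the two-sided exact binomial p-value by tail doubling (the doubled
smaller tail, capped at 1) — chosen over the minimum-likelihood rule for
its symmetry at 1/2 and simple invertibility — and controls FDR with the
Benjamini–Yekutieli adjustment, which is valid under the arbitrary
dependence expected among markers in one LD block (delegated to
`stats::p.adjust(method = "BY")` and verified against the explicit
formula in the tests). A marker is declared linked when its adjusted
p-value falls below 0.05 (the conventional 95% confidence level).

## Problem sizes used by the test suite

Unit tests run on chains of 2–12 sites against the exhaustive-path
oracle, moment-recovery at 10^3–10^4 sites, and simulations of 150–1000
markers; the benchmark and acceptance checks use the full standard
setting (2500 or 10000 markers, 100 replicates per bound). These sizes
were chosen so the whole suite exercises every claim at the scale the
claims are made while remaining comfortable to run repeatedly during
development.

## Known limitations

* One pool at a time; no joint modeling of selected vs unselected pools
  or of replicated pools.
* `alphaP` is a user choice, not estimated; the two-step scheme
  estimates only the neutral shapes.
* The method reports LD *regions*; resolving the causal gene inside a
  region requires the individual-segregant statistics or orthogonal
  evidence.
* The moment estimator assumes one shared neutral distribution
  genome-wide; chromosome-specific neutral fits are not implemented.
* Posterior decoding (not Viterbi) is the only inference mode: the
  quantity of interest is per-marker linkage evidence, not the single
  best state path.
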