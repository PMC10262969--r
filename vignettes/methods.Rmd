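---
title: "Models and methods behind phyloconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyloconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconcord)
```

phyloconcord packages the analytical machinery for a recurring situation in
phylogenomics: four ingroup lineages (here the palaeognath groups — kiwi K,
emu+cassowary E, rheas R, tinamous+moa T) that diverged in quick succession,
studied with a near outgroup (ostrich) and a far one (chicken). This
vignette explains the models, the tunable parameters, the synthetic-data
generator, and the numerical and design decisions, in that order.

## The substitution model

All likelihood and simulation work uses a general time-reversible (GTR)
nucleotide model with discrete-gamma rate variation. `buildModel(pi, exch,
alpha, ncat, pInv)` builds the rate matrix $Q_{ij} = s_{ij}\pi_j$ and
normalizes it so the expected substitution rate at equilibrium is 1, making
branch lengths expected substitutions per site. Detailed balance
$\pi_i Q_{ij} = \pi_j Q_{ji}$ holds by construction, so the likelihood is
invariant to root placement (the pulley principle), which the tests verify.

Rate variation across sites uses `ncat` equal-probability gamma categories
(default 4). Each category's rate is the **conditional mean** of its gamma
slice — not the median — renormalized so the rates average exactly 1. The
conditional-mean convention is the dominant one in modern ML software; the
source analyses do not state which was used, so the choice is documented
here and pinned by a numerical-integration oracle in the tests. An optional
invariant-site proportion `pInv` adds a rate-0 class (used for C12-like
data, where most sites do not vary); the gamma rates are then rescaled by
$1/(1-p_{inv})$ so the overall mean rate stays 1.

Transition matrices come from the symmetric spectral decomposition of $Q$,
$P(t) = e^{Qt}$, cross-checked in the tests against scaling-and-squaring
matrix exponentials. RY-coded data are analyzed with the 2-state reduction
of the same machinery (`ryModel()`): an estimable purine frequency and a
single exchange rate, since a binary reversible model has no further free
exchangeabilities.

## Likelihood engine

`logLikelihood()` implements Felsenstein pruning over compressed site
patterns in compiled code. Ambiguity codes contribute partial likelihood 1
to every compatible state; gaps and `?` are fully missing. The trees handled
here are small (at most ~16 tips), so no per-node likelihood rescaling is
performed — per-site likelihoods stay far above double-precision underflow.
The engine is validated against an independent oracle that sums over every
internal-node state assignment explicitly.

`optimizeBranchLengths()` maximizes the likelihood one branch at a time with
bounded Brent searches, sweeping in postorder until the per-sweep relative
improvement falls below `relTol` (default 1e-8) or `maxSweeps` is reached;
branch lengths are constrained to [1e-9, 10] and non-convergence is flagged
rather than raised. For each branch the rest of the tree is condensed into
root-ward and tip-ward partial vectors, so the inner Brent evaluations cost
only one 4×4 contraction per pattern and category. The Brent x-tolerance
`brentTol` (default 1e-7) can be relaxed (1e-5) when only the topology
ranking matters; the log-likelihood is locally quadratic in each length, so
an x-error of $10^{-5}$ perturbs lnL by far less than the differences
between candidate topologies.

`exhaustiveMLSearch()` optimizes every candidate topology — all
$(2n-5)!!$ unrooted binary trees for up to 8 taxa, enumerated
deterministically by stepwise addition and sorted by canonical split keys —
and returns the maximum. Ties (within 1e-8 log units, e.g. on
zero-variation data) are broken toward the lowest canonical index and
flagged. Exhaustive evaluation replaces heuristic tree search deliberately:
for the five- and six-taxon group-level questions treated here it removes
search error entirely from the comparison.

## Concordance factors

For the three quartet hypotheses (I: KE|RT, II: KR|ET, III: KT|ER),
outgroups are excluded throughout:

* **gCF** — a gene tree is *decisive* when all four groups are present and
  each is monophyletic; its collapsed quartet then matches exactly one
  hypothesis. gCF = 100 × (decisive trees matching) / (decisive trees).
  Undecisive trees are excluded from numerator and denominator and counted
  separately; this is why the three gCFs need not sum to 100 over all input
  trees. The exact treatment of undecisive trees is not specified in the
  analyses this mirrors; exclusion from both terms is the transparent
  choice and the undecisive count is always reported.
* **sCF** — quartets are sampled uniformly with replacement from the
  Cartesian product of the four groups (5,000 by convention). A site is
  *decisive* for a sampled quartet when its four states are unambiguous
  nucleotides forming a two-state 2+2 pattern; the pairing then supports
  exactly one hypothesis (the parsimony criterion). Per quartet the support
  fraction uses decisive sites only; sCF is the mean over quartets with at
  least one decisive site, and sCF_N the mean supporting-site count over the
  same quartets. If no sampled quartet has a decisive site, sCF is NA, never
  0. Whether the reference implementation samples quartets over species or
  group-constrained combinations is unstated; group-constrained sampling is
  used because the hypotheses are group-level and outgroups are excluded.
  `scfExhaustive()` averages over every combination and serves as the
  sampler's oracle.

## Coalescent calculations

For a species-tree quartet whose internal branch spans $T$ generations in a
population of effective size $N_e$, the multispecies coalescent gives the
concordant gene-tree topology probability $1 - \tfrac{2}{3}e^{-T/N_e}$ and
each discordant topology $\tfrac{1}{3}e^{-T/N_e}$. The package implements
the exponent exactly as printed, $e^{-T/N_e}$; textbook treatments of the
diploid coalescent measure the branch in units of $2N_e$ generations, so a
`divisor` flag (1 or 2, default 1) selects the convention, and
`coalescentTime()` converts $\tau = T/N_e$ to generations ($\tau N_e$ under
the default) and years. Inverting the formula at a 40% concordant frequency
gives $\tau = -\ln 0.9 \approx 0.105$; with $N_e = 10^5$ and a 3-year
generation time that is 11,000 generations or 33,000 years. (At
$N_e = 10^4$ the same arithmetic gives 1,100 generations, so only the upper
end of the conventional $10^4$–$10^5$ range reproduces a printed range
starting at 11,000; the package follows the formula and leaves the
arithmetic to the caller.)

## Sequence simulation

`simulateAlignment()` draws root states from $\pi$, assigns each site one
gamma category (shared across branches — no heterotachy, matching standard
simulator behaviour), and evolves states down the tree. Codon structure is
modelled as fixed per-column rate-class multipliers cycling 1, 2, 3, so one
locus can carry slow first/second positions and fast third positions.

The nonstationary mode violates the stationary time-homogeneous (SH)
assumption on purpose: branches named in `branchFreqs` (tip labels or
internal node labels) substitute under a GTR generator rebuilt with that
branch's target frequencies — same exchangeabilities, renormalized — and
unlisted branches inherit the parent's effective frequencies. Because a
branch of length $t$ only moves the composition part-way toward the new
equilibrium (roughly a fraction $1-e^{-ct}$ of the gap), realized GC shifts
on short branches are much smaller than the target; diagnosing and
exploiting this is exactly what the compositional experiments below do.

## The synthetic-data generator

`generateDataset()` emulates the statistical structure of the four locus
classes on a 15-leaf fixture species tree (4 kiwi, emu+cassowary, 2 rheas,
4 tinamous + moa, ostrich, chicken). The fixture encodes the features that
matter for the analyses: two very short contested internal branches (0.004
and 0.003 substitutions/site at base scale — short enough that single loci
frequently fail to resolve them, as the real data do), rheas diverging
first, tinamous the most divergent ingroup, an ostrich path of 0.09 from
the ingroup ancestor N_CA, and a chicken path set to `outgroupRatio` times
that (default 3.5, the midpoint of the observed 2.6–4.6 range).

Class presets (`synthPreset()`) fix, per class, the reported locus counts,
length means and standard deviations (truncated normal, e.g. CNEE
376.9 ± 146.4 nt), and aggregate missing-data proportions (CNEE 0.03,
intron 0.23, UCE/CDS 0.16). Quantities the reports only constrain
qualitatively were chosen once as follows and not revisited:

* divergence multipliers 0.15 / 1.0 / 0.5 / 0.6 / 0.1 / 1.6 for CNEE /
  intron / UCE / C123 / C12 / C3, reproducing the ordering CNEE, C12 low;
  UCE intermediate; intron, C3 high;
* gamma shapes within the reported 0.2–1.93 span for most classes and the
  reported 0.02 for C12, which additionally carries `pInv = 0.5` so that
  most sites are invariant;
* GTR exchangeabilities at avian-like values with a higher
  transition/transversion ratio for coding classes;
* per-group GC targets with tinamous highest and the emu group intermediate
  in coding classes (base GC 0.50–0.52, tinamou target up to 0.60),
  reflecting the stronger GC elevation and heterogeneity of coding data.

Missing data are injected as whole-taxon dropout (half the target
proportion) plus gap runs of mean length 30, hitting the configured
proportion in expectation. In coalescent mode (`tau` set) each locus draws
its generating quartet from the concordance probabilities, so gene-tree
heterogeneity is simulated at the topology level — branch lengths within
gene trees are not coalescent-resampled, which is all the group-level
questions here require. What the generator does **not** emulate: alignment
error, indels, recombination within loci, selection, and lineage-specific
rate variation beyond the fixed tree; conclusions from passing tests
therefore speak to the statistical machinery, not to those real-data
complications.

## The simulation experiments

**Outgroup choice.** `outgroupExperiment()` simulates loci on six-taxon
model trees (one leaf per group plus both outgroups; all 15 relationship
trees are available via `modelTreeSet()`), prunes each simulated replicate
once per outgroup configuration (both / near / far), reruns the exhaustive
ML search, and reports P_C (the fraction of replicates recovering the model
topology) and the mean Robinson–Foulds distance. Prune-once sharing of
replicates across configurations removes between-configuration simulation
noise from the comparison (the alternative — independent simulations per
configuration — is unbiased but noisier). The acceptance-level check runs
five Table-anchored model trees at L ∈ {300, 1800} with 200 replicates and
asserts that the near outgroup's P_C is at least the far outgroup's in a
majority of cells; the reduced tree count keeps the default run inside a
practical compute envelope and is stated here as the package's own choice
of problem size.

**Compositional tree-II bias.** The experiment simulates four-taxon loci
(L = 2000) on the quartet obtained from the (I, R) relationship tree at
three times its base divergence — the top-divergence regime of
third-codon-position data, which is where compositional distortion is
expected to act — with GC targets of 0.75 on the tinamou branch and 0.65 on
the emu branch (third codon positions in birds show GC heterogeneity of
this magnitude), against a stationary control run from the same seeds.
Analyzed under the stationary model, the shifted data infer tree II (KR|ET)
more often than the control: the two GC-elevated lineages (T and E) are
drawn together, which is the compositional-attraction mechanism. A
tinamou-only shift has no partner lineage sharing the derived composition
and so cannot create a pairing-specific attraction, which is why the
experiment (and the coding-class presets) elevate the emu group
intermediately rather than shifting tinamous alone.

## Locus filtering, stratification and rebinning

The relative-branch rule excludes a locus when, for some species, its
branch-length path from N_CA relative to the other species' mean exceeds
five times the same ratio on the concatenated-sequence reference tree. The
wording of the rule admits several operationalizations; the package uses
this ratio-of-ratios with a **strict** inequality (a locus at exactly 5× is
kept) and records the measured value and threshold with every exclusion.
CDS mode adds the stricter screens: any path from N_CA above 1
substitution/site, or a species 5× longer than the others of its own group.
Recombination and positive-selection screens are consumed as precomputed
per-locus flags — the package never shells out to external detection tools.

`stratifyLoci()` sorts descending by divergence (ties broken by locus id,
making the partition deterministic) and returns the top ⌈k%⌉ and the
remainder. `rebinSitesByRate()` orders columns by ascending empirical-Bayes
site rate (ties keep original column order) and chunks them into
pseudo-loci of fixed length; the short final bin is kept and flagged.

## Numerical choices and degenerate inputs

* Zero-length branches: the counting threshold is inclusive (≤ 1e-6), so a
  printed sentinel of 1e-6 counts as zero.
* Brent searches are bounded to [1e-9, 10]; identical sequences drive all
  lengths to the lower bound and set the ML-search tie flag.
* RCV is computed only on sites where every scored taxon has an unambiguous
  A/C/G/T; group frequencies are means over member species of per-species
  frequencies (the alternative pooled-count convention is available behind
  `pooled = TRUE`). The printed formula sums absolute deviations of
  nucleotide counts and divides by (groups × sites), which on the
  proportion scale is the mean per-group absolute deviation.
* Matched-pair tests: Bowker's statistic drops off-diagonal pairs with zero
  total (its df is the number of contributing pairs — the handling is not
  stated in the source analyses); Stuart's marginal test uses a generalized
  inverse with df 3; the internal statistic is their difference, reported
  with NA p-value when the df difference is not positive. Identical
  sequences yield all-zero statistics reported as trivially passing.
* The empirical-Bayes site rate of a constant column is the posterior mean
  under the model, never exactly zero; constant columns always receive the
  smallest rates on a given tree.

## Problem sizes in the default test run

The shipped test suite exercises the stochastic claims at sizes chosen to
make each check statistically decisive while keeping a full run on one core
to minutes: 300,000 multinomial draws for coalescent frequencies, 200
random instances for the likelihood oracle, 100 replicates at L = 10,000
for topology recovery, 200 replicates per cell for the outgroup comparison,
and 500 paired loci for the compositional bias. All tolerances are stated
in the tests as multiples of the relevant binomial or Monte-Carlo standard
errors.

## Known limitations

* No heuristic tree search: beyond 8 taxa the exhaustive enumeration guard
  refuses, by design.
* No per-node likelihood rescaling: trees with hundreds of taxa would
  underflow; the intended domain is small group-level trees.
* The gene-tree summarizer is a plurality vote over collapsed quartets with
  locus bootstrap — a transparent stand-in for full coalescent species-tree
  estimation, sufficient for the four-group question but not a general
  species-tree method.
* Partitioned concatenated analyses use a single model across loci; per-
  partition branch-length scaling is out of scope.
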