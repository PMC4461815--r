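---
title: "Order-disorder textures and theoretical observers: models and methods"
author: "ordtex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-disorder textures and theoretical observers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A texture set is a shift-invariant pairwise Markov random field on a cyclic
H x W lattice (default 32 x 32) of three-valued amplitude indices. The set
is defined by a collection of interaction offsets (dy, dx) -- each unordered
pair of interacting sites counted exactly once -- and one 3 x 3 potential
matrix per offset. A lattice configuration $I$ has energy

$$U(I) = \sum_{p,q} \sum_{o} U_o(A_{p,q},\, A_{(p,q)+o}),$$

with cyclic wrapping, and is drawn from the Boltzmann distribution

$$P(I) = \frac{1}{Z} e^{-\beta U(I)}.$$

The single parameter $\beta$ (inverse thermodynamic temperature) controls
the amount of order: $\beta = 0$ yields i.i.d. uniform amplitudes (white
noise), large $\beta$ concentrates mass on the minimum-energy (ground
state) configurations, and intermediate values interpolate through the
order-disorder transition. Rendering maps each amplitude index to the peak
luminance of a circularly symmetric Gaussian blob (sigma 1.5 arcmin) on a
grid, so a lattice becomes a visual texture.

The package ships three canonical sets with known ground states
(`builtinSpecs()`): a ferromagnetic 3-state Potts model (uniform ground
states), an antiferromagnetic checkerboard pairing of the extreme
amplitudes, and an anisotropic horizontal-stripe set. Potentials are
configuration, not code: any set can be loaded from a YAML/JSON file
(`readTextureSet()`), so other interaction rules -- including recreations of
published ones, which are not part of the package -- plug in without
changes.

## Sampling

Equilibrium lattices are drawn by chromatic (parallel) Gibbs sampling
(`sampleTexture()`): sites are partitioned into colour groups such that no
two sites in a group interact, and each sweep resamples the groups in a
fixed order, every site from its full conditional

$$P(s) \propto \exp\Big\{-\beta \sum_o \big[U_o(s, A_{+o}) + U_o(A_{-o}, s)\big]\Big\}.$$

For nearest-neighbour (and diagonal) interactions the partition is the
classic four-group parity scheme over (even/odd row, even/odd column)
sub-grids; for longer-range offsets, where parity would put interacting
sites in one group, a greedy graph colouring of the offset-interaction
graph is used instead (`colorClasses()` verifies validity exhaustively).
The sweep kernel is compiled code driven by R's RNG, so runs are exactly
reproducible from a seed.

Defaults: burn-in 2000 sweeps, thinning 5, i.i.d.-uniform initialisation
(the exact $\beta = 0$ distribution). These are conservative for 32 x 32
lattices at the $\beta$ ranges used here (well below and around the Potts
critical coupling $\log(1+\sqrt{3}) \approx 1.005$); energy traces
equilibrate within a few hundred sweeps.

**Validation oracle.** On tiny lattices the Boltzmann distribution is
enumerated exactly (`enumerateBoltzmann()`; 3 x 3 has 19,683
configurations), and thinned Gibbs samples are compared to it by a
chi-squared goodness-of-fit test with pooling of low-expectation cells
(`gofChisq()`). For these oracle comparisons the package thins by 20
sweeps, a deliberate near-i.i.d. choice: the goodness-of-fit test assumes
independent draws, and on small lattices the chain's autocorrelation is
negligible after 20 sweeps at the couplings tested. The general-purpose
default stays at 5.

## The order parameter

Order is quantified as mean local conformance to the global symmetry of
the ground states. `groundStateOrbit()` builds all distinct minimum-energy
configurations reachable from the set's ground-state tile by cyclic
translations and by the state relabelings that leave every potential
matrix invariant; minimality is verified by exhaustive enumeration of all
same-period tilings. For each offset, the orbit induces the set of joint
states it realises anywhere on the lattice (site-independent, because the
orbit is translation-closed). The order field (`conformanceField()`) gives
each site the fraction of its interacting pairs -- both directions of every
offset -- whose joint state belongs to that allowed set, and the order
parameter (`orderParameter()`) is the field's mean.

Consequences: the order parameter is exactly 1 on (and, for the builtin
sets, only on) orbit members; it is translation-equivariant; and under
i.i.d. uniform states its expectation is analytic -- the mean over offsets
of (number of allowed joint states)/9, e.g. 1/3 for the Potts set and 2/9
for the checkerboard and stripe sets. The baseline is reported alongside
the raw value, never subtracted; the Order observer learns the statistic's
distribution anyway.

A design note: one could instead pick the single orbit member that best
matches the configuration globally and score joint states against it
alone. That variant gives a much lower disordered-phase baseline (about
1/9 on the Potts set) because a pair must then match one fixed template
rather than any symmetry-equivalent local pattern. The per-pair definition
used here is the one whose disordered baseline equals the pair-matching
probability (1/3 for Potts), makes "conformance to the symmetry" local --
as in the statistical-mechanics definition of an order field -- and keeps
the value-1-iff-ground-state property.

## Theoretical observers and the 4AFC task

A simulated trial places one target texture (sampled at $\beta$) and three
distractors in the four display quadrants. Distractors are i.i.d. uniform
lattices ("uniform" mode) or random spatial permutations of the target's
blobs ("permuted" mode; this preserves the luminance histogram exactly and
destroys geometry). An observer computes a statistic per quadrant and
chooses the quadrant maximising the likelihood ratio of target vs
distractor densities; ties break uniformly at random. Chance is 25%.

The four observers:

* **Luminance** -- the 3-vector of per-state blob counts. Blind to
  geometry; with permuted distractors its statistic is identical in all
  four quadrants, so every trial is a tie and performance is pinned to
  chance.
* **Ideal** -- the pair counts: for each offset, the 3 x 3 joint-state
  contingency over all (cyclic) site pairs, 9 entries per offset. These
  are the sufficient statistics of the Boltzmann model; the energy is the
  linear functional $U(I) = \sum_o \langle \mathrm{counts}_o, U_o\rangle$.
* **Order** -- the scalar order parameter.
* **Channel energy** -- the scalar integrated energy of a quadrature-pair
  Gabor filter output, $M = (I * G_{even})^2 + (I * G_{odd})^2$, summed
  over the quadrant's rendered image.

Densities are estimated from training samples (defaults: 1000; 100 for
the channel-energy observer, whose trials require rendering and
filtering). The scalar Order and Channel-energy statistics use a
two-moment Gaussian model -- they are averages over a thousand-odd local
terms and close to Gaussian, and the decision uses only their location and
variability. The multidimensional Luminance and Ideal statistics use a
product-Gaussian-kernel KDE (`fitDensity()`).

**KDE bandwidths.** For the Ideal observer the statistic has 9 x
(number of offsets) dimensions and 1000 training samples. MISE-optimal
rule-of-thumb bandwidths (Scott's $s_j n^{-1/(d+4)}$, the `fitDensity()`
default) estimate the *density* as well as can be hoped, but the observer
needs the *likelihood ratio*, and in this regime the ratio at a test point
is dominated by its distance to the few nearest training samples: measured
against the exact decision rule (below), the Scott-bandwidth observer
loses 10-17 percentage points at mid-slope. `trainObserver()` therefore
fits the two count-statistic densities with a shared whitening transform
(the pooled within-class covariance -- the standard multivariate KDE
recipe of transforming to unit covariance before applying the kernel) and
a deliberately oversmoothed bandwidth of 2 in whitened units. With a
shared kernel covariance the smooth-limit log ratio is the Fisher linear
discriminant, and for exponential-family sufficient statistics the true
log ratio *is* linear ($-\beta U + \mathrm{const}$), so oversmoothing
converges to the correct rule rather than away from it.

**The exact Ideal rule.** Because the target and distractor distributions
differ only through the Boltzmann factor, the log likelihood ratio of a
quadrant is $-\beta U(I) + \mathrm{const}$: for $\beta > 0$ the exact
maximum-likelihood choice is the minimum-energy quadrant
(`analyticIdealDecide()`). At $\beta = 0$ the distributions coincide and
the rule is undefined -- chance by definition. This analytic rule is the
internal oracle for the KDE implementation: `idealAgreement()` runs both
rules on identical trials (same targets, same distractors) and reports
paired accuracies; agreement is within about 1.5 percentage points at
every $\beta > 0$ at the default budgets.

**Gabor filters.** Kernels are sampled at the rendering pixel scale and
truncated at three envelope widths; the odd (sine) kernel is antisymmetric
on the symmetric support, so its DC response is exactly zero. Filtering
uses FFT convolution with zero padding. Each quadrant's map is computed on
its own texture image independently, which removes cross-border
contamination between quadrants; a `composed = TRUE` flag in
`quadrantEnergy()` switches to the composed-display variant for border
studies. `builtinGabors()` tunes orientation and frequency to each builtin
set's ordered-pattern fundamental at the default geometry. Filter
parameters in the field's conventional ranges (envelope ~0.085 deg,
frequencies of a few cycles/degree) respond selectively: a matched
grating's integrated energy exceeds an orthogonal one's by well over an
order of magnitude.

## Psychometric curves, thresholds, comparisons

`performanceCurve()` trains the observer per $\beta$ and simulates trials
(defaults 1000, matching the conventional budget; 100 for channel
energy), returning per-$\beta$ proportions correct with binomial standard
errors; per-condition seeds are derived from a master seed and a hash of
(set, observer, $\beta$, mode), so any single curve is reproducible in
isolation. Within a $\beta$ the targets are thinned states of one
equilibrium chain.

`estimateThreshold()` finds the smallest crossing of a criterion level --
default 62.5% correct, halfway between 4AFC chance and perfect -- by
linear interpolation in $\log\beta$ (the grid spans orders of magnitude);
a segment starting at $\beta = 0$ interpolates linearly in $\beta$
instead, since $\log 0$ is undefined. A curve that never reaches the level
yields NA with a reason attribute, not an error.

`chi2Compare()` sums, over the grid, the pooled two-proportion Pearson
chi-squared statistics of the per-$\beta$ 2 x 2 correct/incorrect tables.
The degrees of freedom default to the number of grid points but are a
parameter, accommodating conventions that fix them differently (e.g. 9).

## What the synthetic conditions do and do not show

The simulations here are exactly the theoretical-observer side of the
psychophysical paradigm: model observers judging model textures. Passing
checks demonstrate that the sampler draws from the intended distribution,
that the observers implement their stated decision rules, and that the
qualitative structure -- monotone psychometric curves, Ideal dominating
Order and Luminance, permuted distractors blinding the Luminance observer
while structured sets remain discriminable to the Ideal -- emerges from
those rules. They say nothing about human vision: no internal noise,
spatial inhomogeneity, display calibration, or temporal presentation is
modelled, and the builtin texture sets are canonical examples rather than
any specific published stimulus family.

## Numerical choices and problem sizes

* Oracle goodness-of-fit runs use 3 x 3 lattices (full enumeration),
  5e5 thinned samples in the test suite and 2e5 in the acceptance script,
  thinning 20, with low-expectation cells pooled to keep the chi-squared
  reference valid.
* Simulation rendering uses 80 px/degree -- the coarsest scale honouring
  the "blob sigma spans at least 2 pixels" invariant -- while the default
  `renderSpec()` stays at 120 px/degree (blob sigma = 3 px) for output
  images. Blob stamps are truncated at 4 sigma so that truncation error
  (0.03%) is negligible against the 1% tolerance on total added
  luminance; Gabor kernels are truncated at 3 sigma, a standard choice
  stated for bit-reproducibility.
* Psychometric curves in the test suite use 400-1000 trials per point and
  training budgets of 1000 (100 for channel energy); curve-level
  assertions use three pooled standard errors.
* Degenerate density dimensions (zero variance) floor the bandwidth at a
  small epsilon with a warning; undefined thresholds are values, not
  errors, and are flagged.
* The lattice/spec cache keys ground-state orbits and Gabor FFT plans by
  value, so repeated observer training does not recompute them.

## Known limitations

* KDE-based observers in high dimension are decision-calibrated, not
  density-calibrated: the oversmoothed fits are poor density estimates
  even though they make near-optimal decisions. Use the Scott default of
  `fitDensity()` when the density itself is of interest.
* The greedy colouring is not guaranteed minimal in colour count (only
  valid); for the shipped sets the parity partition applies anyway.
* `enumerateBoltzmann()` is exponential in the site count and refuses
  beyond 1e6 configurations; ground-state verification is exponential in
  the tile area and rejects periods whose tile exceeds ~11 cells.
* Heat-bath dynamics on a single chain can mix slowly deep in the ordered
  phase (large $\beta$) near phase coexistence; the shipped defaults are
  validated for the $\beta$ ranges of the builtin grids, not for critical
  slowing-down studies.
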