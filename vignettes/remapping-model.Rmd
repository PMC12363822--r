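---
title: "The remapsim model: angular latent coding, steady-state competition, and remapping statistics"
author: "remapsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The remapsim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remapsim)
```

# The coding model

remapsim simulates hippocampal place-cell remapping under a single
structural assumption: the population activity $r \in \mathbb{R}^N$ admits a
*linear decoder* of a low-dimensional latent state,
$\hat z = D r$. Inverting this constraint gives the most general encoder
consistent with it, the pseudo-linear encoder

$$ r = E z + \nu(z), \qquad E = D^+,\ D\,\nu(z) = 0 , $$

where $E$ is the right pseudo-inverse of $D$ and $\nu$ is an arbitrary
function confined to the null space of $D$. Every way a firing-rate map can
change between environments then falls into one of three channels:

* **encoder–decoder (ED)**: the map between latent and neural space changes
  (random "multi-chart" rotations, or grid-module realignment);
* **mixed-selective (MS)**: the latent trajectory itself changes, through
  environment-specific cognitive variables (space–feature coding, or
  implicit-space coding with no positional latent at all);
* **null-space (NS)**: only $\nu$ changes — e.g. through neuron-specific
  excitability (threshold) modulation — leaving the decoded latents intact.

## Angular latent coding

Environmental variables (position $p$ and cognitive variables $c$, each in
$[-1, 1]$) enter the latent space through a fixed angular code:
$\alpha = \pi (p + 1)$, $z = (\cos\alpha, \sin\alpha)$. This yields circular
(toroidal, for several variables) latent trajectories, which is what
produces localized, place-field-like tuning from linear readouts.

One printed convention deserves a note: a decoder that adds $\pi$ to the
`atan2` angle does not invert the encoder above (it shifts every decoded
position by one). `decodeAngular()` therefore uses the round-trip-consistent
rule $\alpha = \operatorname{atan2}(z_2, z_1) \bmod 2\pi$, so that
`decodeAngular(encodeAngular(p)) == p` on $[-1, 1)$; the boundary $p = 1$ is
identified with $p = -1$. Decoded outputs live in $[-1, 1)$ and all
position-error metrics use the circular distance with period 2.

Multi-module grid coding generalises this with per-module angular
frequencies $(3/2)^{f_j}$, $f_1 = 0$, so the first module is a bijection
with position and serves as the positional readout
(`decodeGridPosition()`). The lattice is square; the hexagonal
("twisted-torus") geometry is out of scope.

## Cognitive variables

Each environment draws $c(p) = k + g(p)$: a constant offset $k$
(Normal$(0, \sigma)$ for $\sigma < 1$, Uniform$[-1,1]$ at $\sigma = 1$) plus
a Gaussian-process fluctuation with squared-exponential kernel
$K(x, x') = \sigma_v^2 e^{-\|x-x'\|^2/(2v^2)}$, wrapped back into $[-1, 1)$.
A single parameter $\sigma$ plays both roles ($\sigma_v = \sigma$); this is
the simplest reading of a one-parameter family controlling both mean shifts
and fluctuations, and both uses are independently seeded. The default
lengthscale is $v = 0.3$ on the $[-1,1]$ position scale — a handful of bumps
per traversal, which is what makes cognitive variation *position-dependent*
rather than a global gain. The kernel gets a $10^{-9}$ diagonal jitter
before Cholesky factorisation; for 2-d grids the kernel distance is
Euclidean in position.

The deterministic reward profile
$c(p) = e^{-(p-\mu)^2/(2\sigma_r^2)} - 1$ is available for reward-coding
experiments (`rewardProfile()`), peaking at 0 over the reward location and
saturating at $-1$ far from it.

## Embedding maps and the input rescale

ED remapping is modelled inside an *embedding space* of dimension
$Y$ ($Z \le Y \le N$): $y^A = R^A z$, with $R^A$ column-orthonormal.
Multi-chart maps draw $R^A$ uniformly (QR of a Gaussian matrix with
sign-fixed diagonal, which makes the draw unique and seed-reproducible);
grid realignment uses block-diagonal per-module 2×2 rotations with angles
uniform on $[0, 2\pi)$. MS scenarios use the identity.

Latent columns are normalised part-wise before embedding: with both
positional and cognitive parts, each part is scaled to norm $1/\sqrt 2$ so
the full column has unit norm, matching unit-norm decoder columns. The
embedding input is then rescaled as $y \leftarrow Y\,y$
(`rescaleEmbedding()`, exponent 1). We adopted the linear rule as the
default after comparing the alternatives: with unit-norm decoder columns a
unit-norm input drives a vanishing fraction of a large population above
threshold, and the linear rescale is the choice under which the scaled-up
scenarios reproduce the qualitative remapping fingerprints that distinguish
the model classes (see below). Exponents $1/2$ (strictly $O(1)$ drive) and
$0$ (off) remain available through `rescaleExponent`.

# The network and its steady state

The network is a competitive autoencoder (the rate formulation of the
spike-coding network): decoding weights $D_y \in \mathbb{R}^{Y \times N}$
with one column per neuron, recurrent weights $-D_y^\top D_y$, and
per-neuron thresholds $T_i = \tfrac12 \|D_i\|^2$ (0.5 for unit columns).
Rather than integrating spiking dynamics, the steady-state rates at each
grid position solve the convex program

$$ r^*(p) = \arg\min_{r \ge 0} \; \|y(p) - D_y r\|^2 + 2\,T^\top r . $$

Decoder weight codes: **M** (mixed; unit columns), **C** (conjunctive; every
(cos, sin) row pair of every column at norm $\sqrt{2/Y}$, used for grid
realignment so each module drives every neuron equally), **CM** (positional
block conjunctive, cognitive block mixed, blocks at norm $1/\sqrt2$ each),
**pM** (some purely positional and purely cognitive neurons, remaining
columns mixed; zero blocks are permitted and the nonzero block is normalised
to unit column norm), and **identity** ($D = \mathrm{Id}_N$ for the
full-dimensional multi-chart case).

## Solver numerics

The QP is solved by deterministic cyclic coordinate descent from a cold
start ($r = 0$, fixed neuron order, no warm starts), with a periodic exact
active-set polish: the equality-constrained KKT system is solved on the
current support (with a Lawson–Hanson inner loop, and drop-one support
retries when the support Gram matrix is numerically singular — which
happens when two neurons carry nearly identical tuning). The internal
tolerance is $10^{-9}$ on the KKT residual
($|g_i|$ for active neurons, $\max(0, -g_i)$ for silent ones, with
$g = D^\top(Dr - y) + T$); the public contract enforced by
`steadyStateRates()`/`runRateMap()` is $10^{-7}$, and solver failure is an
error carrying diagnostics, never a silent degradation. Rates below
$10^{-12}$ are clamped to exact zero. In degenerate problems (duplicated
columns) the optimum is a manifold; the solver lands on one deterministic
point of it, and all shipped tests assert manifold invariants (rate sums,
objective, decoded output), never a particular split.

## Thresholds and the null-space protocol

Threshold suppression sets $T_{\text{suppr}} = 10$, an order of magnitude
above the working threshold, which provably silences any neuron whose drive
is bounded by $\|D_i\|\,\|y\| < 10$. The three-condition protocol
(`nullSpaceProtocol()`) solves one multi-chart environment under: a
*default* map with half the population held suppressed; *birth*, which
releases a seeded fraction of the reserve into the map; and *suppressed*,
which silences a fraction of the default-active set **while releasing an
equal fraction of the reserve**. We read the suppression condition as
replacement rather than pure removal: with pure removal, suppressing the
whole active map would silence the network, whereas the modelled phenomenon
is an alternative population compensating so the same latent trajectory is
carried by different cells — which is exactly what the replacement protocol
produces (at `spar = 1` the two maps share no active neurons while decoding
the same positions).

# Remapping statistics

Rate maps are preprocessed by zeroing entries strictly below $10^{-3}$
("less than" is read strictly, so a value exactly at the threshold
survives). A neuron is *active* if its mean preprocessed rate is nonzero;
the model itself offers no other natural activity definition.

* **Overlap** $\omega(A, B)$: cosine similarity of the two environments'
  mean population rate vectors. Its shuffle control permutes neuron
  identities in both vectors independently, averaged over 20 realizations;
  because only the relative permutation matters, the estimator switches to
  the exact mean over all $N!$ relative permutations whenever the requested
  realizations would exceed it.
* **Spatial correlation** $\rho(A, B)$: mean, over neurons active in both
  environments, of the cosine between the neuron's rate profiles. Its
  shuffle draws mismatched ordered pairs $(i, j)$, $i \ne j$, both
  co-active; the pair budget is $\min(200, \text{all ordered pairs})$ per
  realization (the pair count is otherwise unspecified, and pairs are
  ordered), collapsing to exact enumeration when the budget covers all
  pairs. Pairs of environments with no co-active neurons are flagged and
  excluded from grand means.

Pairwise values over $K$ environments (unordered pairs, $i < j$) are tested
with a one-sample t-test against the shuffle grand mean, treated as a known
constant; Bonferroni division by `nTests` is applied when a sweep performs
several tests. Zero-variance value sets are flagged degenerate and reported
as exact (in)equalities. We also report a standardized effect size,
$|\bar\omega - \bar\omega_{\text{shuff}}| / \mathrm{sd}$, with the standard
deviation taken over the pooled shuffle values (all pairs × realizations);
this is the scale-free quantity the scenario fingerprints are stated in.

## Scenario fingerprints and study sizes

The distinguishing qualitative signatures, verified by the test suite at
scaled-down sizes chosen to keep a desk run in minutes (full-scale
simulation sizes remain reachable through configuration):

| scenario | size used | overlap | spatial correlation |
|---|---|---|---|
| multichart_lowD | N=256, Y=32, 2-d position 8×8, K=8 | above shuffle | at chance |
| multichart_fullD | N=Y=256, 2-d position 8×8, K=8 | at chance | at chance |
| space_feature ($\sigma=0.2$) | N=256, 1-d position ×64, C=1, K=8 | above shuffle | above shuffle |
| grid_realignment | N=256, m=3, 2-d position 8×8, K=8 | above shuffle | effect below 1 |

Two honest caveats from our own runs. First, these are stochastic
assertions at a fixed master seed; the grid-realignment spatial-correlation
effect in particular fluctuates around its margin across seeds (it tends to
sit slightly *below* the shuffle mean — competitive exclusion makes
co-active neurons' surviving fields slightly anti-correlated — and its
standardized magnitude crosses 1 for some seeds). Second, the
low-dimensional multi-chart overlap structure strengthens as the embedding
dimension shrinks relative to $N$; at $Y = 32$ it is reliably detectable
with 28 pairs, but with 1-d position (fewer effective positions per
environment) it can drop below significance.

The null-space confinement demonstration uses $N = 48$, $Y = 3$, 100
positions on a 1-d track, and *sparse participation modulation*: four of
the ~24 spontaneously firing neurons are suppressed. Under these conditions
the decoded readout moves by less than 10% of the input norm at every
position while the population overlap drops visibly below 1. Denser
modulation (the half-map replacement of the three-condition protocol)
preserves decoded *positions* just as well — median circular decode
difference ~0.01–0.02 — but the raw readout deviation between conditions is
then dominated by each map's own threshold-induced decode bias (~0.2 of the
input norm at this scale), so the raw-readout gate is only meaningful in
the sparse regime.

# What the generator does and does not emulate

All inputs are synthetic. The generator reproduces the *structure* of the
modelled conditions — shared positional variables, environment-specific
rotations/realignments/cognitive draws, seeded and bit-reproducible — but
not the measurement process of real recordings: no spiking noise, no finite
trial counts, no behavioural sampling inhomogeneity, no cell identification
errors. Passing fingerprints therefore show that the *model classes* are
distinguishable by these statistics under clean conditions, not that any
particular experimental dataset will separate them.

# Degenerate inputs and tie-breaks

* Angular decode of the zero vector, zero-norm latent parts, and negative
  rates in the analysis layer are errors, not warnings.
* Winner-take-all preference fields break ties toward the lowest neuron
  index and emit the sentinel −1 where every rate is exactly zero;
  suppressed neurons are zeroed before the argmax.
* `spatialCorrPair()` returns a flagged `NA` (not an error) when no neuron
  is co-active; `remappingStats()` excludes such pairs from grand means.
* With a single environment pair there is no distribution to t-test; the
  summary is flagged degenerate with `NA` test fields.

# Reproducibility

Every stochastic step takes an explicit seed; per-environment and
per-shuffle seeds are derived from the master seed by a fixed congruential
scheme (`deriveSeed()`), so runs are bit-identical across sessions and
archive files are byte-identical. Run archives (`saveRun()`) are
self-describing — config snapshot, decoder, maps, thresholds, inputs,
rates, diagnostics — carry an md5 content hash verified on load, and the
analysis layer never needs the original configuration file.

# Known limitations

Steady-state rates only (no time-resolved spiking dynamics); no learning or
plasticity; square grid lattices; no morphing/interpolated environment
sequences; the embedding-rescale exponent and the GP hyperparameters are
declared defaults rather than values fitted to any dataset.
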