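---
title: "From network structure to spike-train correlations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From network structure to spike-train correlations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hawkesnet maps the wiring of a recurrent network of spiking units to the
pairwise correlations of its activity, under the multivariate Hawkes
(linearly interacting point process) model.  This vignette is the package's
account of the science: the model and its assumptions, the quantities it
computes, the parameters that matter, the design decisions taken where the
problem left room, and the limits of what the synthetic experiments can
show.

## The model

Each of $N$ units emits spikes as an inhomogeneous Poisson process whose
intensity is a constant external drive plus a linear superposition of
causal synaptic kernels triggered by presynaptic spikes:

$$u_i(t) = y_{0,i} + \sum_j \int_0^\infty g_{ij}(s)\, \mathrm{d}S_j(t-s),$$

where $S_j$ is the spike train of unit $j$ and $g_{ij}$ is the interaction
kernel of the connection $j \to i$.  Only the *integral* of the kernel
matters for every quantity this package computes; we collect the integrals
in the matrix $G$, with $G_{ij}$ the expected number of extra spikes in $i$
caused by one spike of $j$ (negative for inhibition).  Kernels here are
exponentials with time constant $\tau$ and a transmission delay; delays
shift kernels in time and leave all integrated quantities unchanged.

Two stationary quantities follow in closed form whenever no eigenvalue of
$G$ equals 1:

* equilibrium rates $y = (I - G)^{-1} y_0$;
* the integrated covariance matrix
  $C = (I - G)^{-1}\, \mathrm{diag}(y)\, (I - G^\top)^{-1}$,
  whose entries equal the large-window limit of spike-count covariances per
  unit time.  Its diagonal contains the Poisson rate term of the
  autocovariances.

The population count variance per unit bin is $v = \sum_{ij} C_{ij}$, and
the average correlation is defined with the rate term removed,
$\bar c = (\sum_{ij} C_{ij} - \sum_i y_i)/N^2$, so that
$v = \sum_i y_i + N^2 \bar c$ holds as an identity.  We deliberately work
with integrated covariances rather than correlation coefficients: the
normalisation by count variances would destroy the simple additive relation
to population fluctuations.

Assumptions worth keeping in mind: linearity (each input spike shifts the
intensity by the same amount regardless of state), stationarity, and the
neglect of rectification — the theory allows the intensity to go negative,
while real spike generation clips it at zero.  The simulator applies the
clip, which is exactly why we include it: the gap between theory and
simulation measures the rectification error.

## The motif decomposition

Expanding $(I-G)^{-1}$ as a geometric series turns $C$ into a sum over
two-branch path motifs:

$$C = \sum_{n, m \ge 0} G^{n}\,\mathrm{diag}(y)\,(G^\top)^{m}.$$

The $(n, m)$ term sums every configuration in which a source unit reaches
node $i$ along a directed path of length $n$ and node $j$ along a path of
length $m$, weighted by edge weights and the source rate.  `motif_terms()`
classifies terms as *rate* ($n = m = 0$), *chain* (one branch empty:
direct or indirect input of one unit to the other) or *common input* (both
branches non-empty), and `average_contributions()` aggregates them by total
order $k = n + m$.  The series converges iff the spectral radius of $G$ is
below one — we check this with exact eigenvalues, and use the operator
2-norm only for the truncation-error certificate
$\|C - \sum_{n+m\le K}\| \le \|Y\|\sum_{k>K}(k+1)\rho^k$
(`series_tail_bound()`), because a norm bound on the tail is valid while a
spectral-radius bound alone is not for non-normal matrices.

In inhibition-dominated networks the per-order averages alternate in sign —
each order partially cancels the previous one — which is the mechanism by
which recurrent feedback *de*correlates such networks.

## The homogeneous closed form, and when it applies

For networks with uniform connection probability $p$ the average
correlation depends on just two numbers: the average direct interaction
$\bar g = p(N_E w_E + N_I w_I)/N$ and the average common input
$\bar q = p^2(N_E w_E^2 + N_I w_I^2)$.  With $\Gamma = N\bar g$ and
homogeneous rate $y = y_0/(1-\Gamma)$,

$$A_k = y\left[2\bar g\,\Gamma^{k-1} + (k-1)\,\bar q\,\Gamma^{k-2}\right],
\qquad
\bar c = y\left[\frac{2\bar g}{1-\Gamma} + \frac{\bar q}{(1-\Gamma)^2}\right].$$

The derivation treats in- and out-degrees as fixed per type.
`make_regular_network()` realises exactly that construction (a random
biregular graph per type pair), and for it the closed form is exact to
machine precision — a useful end-to-end oracle.

For independent-Bernoulli networks the formula is an approximation, and the
package's tests document its validity boundary: realised networks contain
*repeated-edge* motifs (the two branches of a path pair sharing edges)
whose contribution the regular-graph derivation cancels exactly but a
Bernoulli ensemble does not.  The resulting upward bias of the true average
correlation relative to the closed form grows like
$B^2/(1-B^2)$, where $B$ is the bulk spectral radius below.  We therefore
validate the approximation in a regime with $B^2 \ll 1$ (balanced weights,
$w_E = 0.0025$, $w_I = -0.01$ at $N = 1000$, $p = 0.1$), and treat strong
coupling ($B \approx 0.8$) as outside the closed form's domain — there the
full-matrix machinery is the right tool.

## Spectra and stability

For a random network the eigenvalues of $G$ form a circular bulk of radius
$B = \sqrt{p(1-p)(N_E w_E^2 + N_I w_I^2)}$ — the standard deviation of a
unit's total input — plus possibly a real outlier at the mean input
$p(N_E w_E + N_I w_I)$.  Stability of the linear dynamics requires all real
parts below one, so either quantity can destabilise a network: even a
globally balanced network explodes once the *variance* of its input crosses
the line.  Two instructive scenarios with identical synaptic weights
($w_E = 0.019$, four-fold stronger inhibition, 20% inhibitory): a dense
local subnetwork ($N = 2500$, $p = 0.6$) has $B = 0.931 < 1$, while a
sparse large network ($N = 15000$, $p = 0.1$) has $B = 1.396$ — linearly
unstable.

One caveat we found and encode in the tests: the negative mean-input
outlier of strongly inhibition-dominated networks is often *not* observed
as a real eigenvalue.  A skewness correction (dominated by $w_I^3$ terms in
the column-variance profile) absorbs it into the bulk.  The outlier check
therefore runs on a mildly excitation-dominated network where the outlier
stands clear of the bulk; for inhibition-dominated networks only the bulk
radius is asserted.

## Rings: distance-dependent correlations in Fourier space

On a ring with boxcar connection-probability profiles per population, the
expected interaction between two units at signed offset $d$ is
$h(d) = f_E w_E p_E(d) + f_I w_I p_I(d)$, and the expected common input is
the circular autocorrelation
$q(d) = f_E w_E^2 (p_E \star p_E)(d) + f_I w_I^2 (p_I \star p_I)(d)$.
Matrix products become circular convolutions, so the distance-dependent
correlation $c(d)$ — the average of $C_{ij}$ over ordered pairs at offset
$d$ — has a closed form in the spatial DFT:
chains contribute $y\,\hat h^n$ (plus the conjugate branch), common-input
terms $y\,\hat q\,\hat h^{n-1}\overline{\hat h}^{m-1}$, and the total is

$$\hat c(\omega) = y\left[1 + \frac{\hat h}{1-\hat h} +
\frac{\overline{\hat h}}{1-\overline{\hat h}} +
\frac{\hat q}{|1-\hat h|^2}\right].$$

Convergence requires $|\hat h(\omega)| < 1$ at every spatial frequency; the
modes that violate it first are the large-scale oscillatory eigenmodes of
locally excitatory rings, which is why "Mexican-hat" interaction profiles
sit close to instability while locally inhibitory rings do not.  The
per-order curves explain the shape of the correlation distribution: with
local excitation all orders share one sign at short range and pile up to
extreme values; with local inhibition they alternate and cancel.  The
*average* correlation over all pairs is profile-independent at fixed
overall connectivity — only the distribution changes.

Design decisions here: signed offsets $-\lfloor N/2\rfloor \ldots \lfloor
N/2\rfloor$ mapped onto a circular length-$N$ array, with the antipodal
offset of an even ring counted once; distance 0 excluded from profiles (no
self-connections); the homogeneous rate $y = y_0/(1-\hat h(0))$ used
throughout, as appropriate for the ensemble-averaged ring.  The analytic
pipeline is a mean-field over the generator ensemble, so numeric curves
from realised networks are compared only after seed-averaging, and — for
the same repeated-edge reason as above — the quantitative agreement test
runs at weights where the quenched amplification ($\propto w^2$, measured
as a multiplicative offset of about 6% at the display weights and below 1%
at the comparison weights) is inside the seed-averaging error.

## Network generators

All generators share conventions: $G_{ij}$ is presynaptic $j$ acting on
postsynaptic $i$; no self-connections (diagonal zero); no multi-edges;
every column carries the sign of its source type.  Same seed, same
parameters — identical edge set.

* **random** — each ordered pair independently with probability $p$, or a
  fixed out-degree of `round(p (N-1))` targets sampled without replacement.
  Types get exact counts (`round(N * frac_inhib)`).
* **regular** — fixed per-type in- *and* out-degrees (stub matching with
  collision repair); the construction for which the closed form is exact.
* **ring** — boxcar profiles per source type over geodesic distance; types
  drawn independently per node, so realised counts fluctuate (and the
  metadata records them).
* **hub** — out-degrees from the geometric law $P(k) = (1-q)q^k$ with mean
  $\mu = q/(1-q)$; excitatory nodes above the threshold (default
  $\lceil\mu\rceil$, i.e. out-degree larger than the mean) are hubs; a hub
  sends a fraction $f$ of its excitatory output to other hubs.  At
  $\mu = 50$ the expected hub fraction is $(50/51)^{51} \approx 0.36$.
  Impossible demands (e.g. $f \to 1$ with few hubs) fall back to the pooled
  target set with a warning rather than failing.
* **patchy** — every source connects within one random contiguous patch of
  $s$ positions with probability $p_{patch}$; inhibitory nodes either mixed
  or confined to one contiguous block.

`weighted_assortativity()` is fixed as the Newman-style symmetric pooled
Pearson correlation, over directed edges, of the endpoints' total weighted
degrees (in- plus out-strength of absolute weights).  The pooled form is
required for a star graph to come out negative rather than undefined.
Because strengths are weight-magnitude-weighted, strongly asymmetric
weights let the inhibitory population dominate the measure; the structural
hub effect (denser hub interconnectivity raises the coefficient) is
therefore assessed at matched equal-magnitude weights.

## The simulator

`simulate_hawkes()` is a time-stepped implementation of the point process:
per step each unit fires a Bernoulli spike with probability
$\max(u_i, 0)\,\mathrm{d}t$ (rectification applied), synaptic states decay
by the exact factor $e^{-\mathrm{d}t/\tau}$, and spikes are delivered after
a global delay through a ring buffer.  One state per kernel group keeps
different excitatory/inhibitory time constants exact.  R's RNG drives the
Bernoulli draws, so identical seeds give identical spike trains bit for
bit.  Defaults: $\mathrm{d}t = 0.1$ ms (at most $\tau/10$ is enforced),
delay 1 ms, 10 s warmup discarded before any statistic.  A per-step spike
probability above 0.1 triggers a coarse-step warning; a runaway intensity
aborts with a diagnostic instead of consuming the machine.

`estimate_counts()` bins the trains (bins much wider than the kernels,
$\Delta \ge 20\tau$ recommended) and estimates rates, count covariances per
unit bin (the estimator of the integrated covariance), the population
variance (identically the sum of the covariance estimate), and per-unit
inter-spike-interval coefficients of variation.

## Study conditions

The architecture experiments run under fixed conditions chosen once, from
the constraints the problem states and from stability analysis, and used by
the tests and the acceptance script:

| condition | parameters | rationale |
|---|---|---|
| asynchronous irregular | $N=1000$, 80/20, $p=0.1$, $\tau=10$ ms, $w_E=0.035$, $w_I=-0.175$, drive 10 /s | inhibition-dominated, bulk radius $B = 0.80$; irregular near-Poisson activity |
| recovery | $N=200$, $p=0.1$, $w_E=0.016$, $w_I=-0.072$, drive 20 /s | weak intrinsic-state fluctuations ($\mathrm{sd}(u)/\bar u \approx 0.25$), so the linear prediction should hold to ~1% and the simulator can be held to it |
| balanced | $N=1000$, $p=0.1$, $w_E=0.0025$, $w_I=-0.01$ | $B^2 = 0.003$: validity regime of the homogeneous closed form |
| hub | $N=1000$, $\mu=50$, $w_E=0.0033$, $w_I=-0.0165$ | hub-subnetwork gain $0.27 f < 1$: stable across the whole $f$ sweep |
| patchy | $N=1000$, $s \in \{100,200,400\}$, $s\,p_{patch}/N=0.1$, $w_E=0.01$, $w_I=-0.05$ | overall connectivity held fixed while patch size varies |
| ring display | $N=1000$, $\sigma_E{=}100/p{=}0.5$ vs $\sigma_I{=}500/p{=}0.1$ (hat; swapped for inverted), $w_E=0.01$ | oscillatory-mode gain 0.75: strong but stable higher-order effects |
| ring comparison | same profiles, $w_E=0.004$ | mean-field vs ensemble agreement inside the validity regime |
| scaling, random | $N=1000$, $p=0.5$ fixed out-degree, $w_E=0.023$, $w_I=-0.094$ | distance-independent correlations strong enough that the quadratic term dominates from $n \approx 10$ |
| scaling, ring | $N=1000$, $\sigma=5$, $p_{box}=1$, $w_E=0.05$, $w_I=-0.25$ | correlated neighbourhood ($\pm$ tens of positions) far smaller than the population sizes 10..300, so pooled variance grows linearly |

In the asynchronous regime the intrinsic state fluctuates with standard
deviation $\mathrm{sd}(u) = B\sqrt{\bar y/((1-p)\,2\tau)}$, a multiple of
its mean — a substantial fraction of the fluctuating intensity mass sits
below zero.  Simulated rates then exceed the linear prediction and
inter-spike intervals are slightly more variable than Poisson (mean CV
$\approx 1.1$); this is intrinsic to any regime combining bulk radius near
0.8, $\tau = 10$ ms and single-digit rates, and is why the quantitative
recovery checks use the weak-fluctuation condition instead.

Problem sizes (networks of 1000 for the architecture effects, 150–500 for
the oracle comparisons, 100–500 s of simulated time) were chosen as the
smallest at which the quenched and sampling errors are comfortably below
the effects under study.

## What the synthetic experiments do and do not show

The generators emulate the *structural* features under study — degree
distributions, distance profiles, hubs, patches, type separation — under
idealised conditions: stationary drive, homogeneous weights per type pair,
exponential kernels, Poisson spike generation, no refractoriness, no
plasticity, no external correlations.  Passing tests therefore demonstrate
that the implementation realises the mapping from structure to correlations
correctly within the linear model, and that the simulator agrees with the
theory where the theory's own assumptions hold.  They do not show that
cortical data obey the model: real neurons have nonlinear transfer,
conductance effects and non-Poisson statistics, and measured correlations
include stimulus- and state-driven components the model excludes by
design.

## Numerical choices and degenerate inputs

Dense LU solves for $(I-G)^{-1}$ (the target sizes, $N \le 5000$, need no
sparse path); the covariance is symmetrised after the triple product to
remove rounding asymmetry.  Convergence decisions use exact eigenvalues;
the norm-based tail bound is only a certificate.  Negative predicted rates
warn but are kept, matching the theory-as-is treatment.  Degenerate inputs
are errors, not silent values: empty population subsets, fewer than two
counting bins, zero-variance assortativity (undefined, never 0), profile
half-widths beyond $N/2$, divergent parameter regimes (the offending
eigenvalue or spatial mode is named).  Ring offsets for even $N$ count the
antipodal offset once.  Seeds: every generator and the simulator take one;
`run_experiment()` expands a master seed by a fixed counter scheme.

## Known limitations

* Time-resolved covariance functions (correlogram shapes) are out of scope;
  only integrated quantities are computed.
* The homogeneous closed form and the ring mean-field carry a
  repeated-edge bias of relative order $B^2$ for Bernoulli ensembles; use
  the full-matrix route at strong coupling.
* The simulator's Bernoulli step allows at most one spike per unit per
  step; at intensities approaching $0.1/\mathrm{d}t$ it warns.
* `spectrum_report()` estimates $p$, $w_E$, $w_I$ from the realised network
  (max/min weight); heterogeneous-weight networks should pass their own
  parameters to `bulk_radius()` directly.
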