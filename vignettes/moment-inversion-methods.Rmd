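---
title: "Estimating tissue optical properties from spatio-temporal moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tissue optical properties from spatio-temporal moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Scattering and absorption in biological tissue are intrinsically coupled:
a single reflectance measurement cannot separate a slightly more absorbing
slab from a slightly less scattering one without a model of light
transport, and no closed-form transport solution exists for realistic
geometries. Monte Carlo simulation is the accepted forward model — given
the optical properties it produces the radiation transport — but it is far
too slow and too noisy to invert directly, point by point, during an
experiment.

`tissueoptics` takes the standard route around this: simulate the forward
problem many times across the biologically relevant parameter space,
compress each simulated response into a small, physically meaningful
feature vector, and train a small fully connected network to map features
back to parameters. Once trained, inversion of a measured response costs a
forward pass — microseconds — which is what makes dynamic, in-vivo use
conceivable at all.

The quantities recovered are the refractive index $n$, the reduced
scattering coefficient $\mu_s' = (1-g)\,\mu_s$ and the absorption
coefficient $\mu_a$. Diffusive transport depends on $g$ and $\mu_s$
essentially only through their combination $\mu_s'$, so the network is
deliberately made sensitive to $\mu_s'$ alone rather than asked to resolve
the nearly degenerate pair $(g, \mu_s)$.

## The forward model

A single homogeneous slab, 10 mm thick by default, laterally unbounded,
with air above and below. Photons launch at the origin at $t=0$, normally
into the slab. Each photon performs the classic weighted random walk:

* **Free paths** are exponential, $\rho(d) = \mu_s e^{-\mu_s d}$, sampled
  by inversion ($d = -\ln u/\mu_s$). Steps are drawn from the scattering
  coefficient alone.
* **Absorption** never terminates a photon; the weight is attenuated
  continuously, $w \mapsto w\,e^{-\mu_a d}$, along every traversed
  segment (Beer–Lambert). This pairing — $\mu_s$-sampled steps with
  continuous attenuation — is unbiased and keeps the absorbed energy
  ledger exact; it differs from the equally valid MCML convention of
  sampling against $\mu_t$ and depositing an albedo fraction per step.
* **Scattering** deflects the direction by a Henyey–Greenstein cosine,
  $\rho(\cos\theta) = \tfrac{1}{2}(1-g^2)\,[1+g^2-2g\cos\theta]^{-3/2}$,
  sampled in closed form, with uniform azimuth.
* **Boundaries** are resolved stochastically: at a face the unpolarized
  Fresnel reflectance $R = \tfrac12(R_s+R_p)$ decides between internal
  reflection and Snell-refracted exit. After an internal reflection the
  remaining step is re-sampled — statistically identical to carrying the
  residual optical depth, by memorylessness of the exponential. The
  specular reflection of the incident beam itself is deducted
  deterministically at entry, $R_{sp} = ((n_{amb}-n)/(n_{amb}+n))^2$, and
  logged as a single reflection record at $r=0$, $t=0$; it is the large
  initial spike of the time-resolved response.
* **Russian roulette**: once $w < 10^{-6}$ the photon survives with
  probability $1/m$ and is boosted by $m$ (default $m=10$, the common
  Monte Carlo convention), keeping the expectation unbiased while bounding
  run time.
* **Time** advances at the phase velocity $c/n$ with
  $c = 0.299792458$ mm/ps; dispersion is ignored. Units are mm, ps,
  mm$^{-1}$ throughout.

Every exiting photon is logged with its side, exit position, outgoing
direction, weight and arrival time. A run is reproducible bit for bit:
every photon owns an RNG substream derived from (master seed, photon
index), so results do not depend on batching or execution order, and
`propagate_photon()` can replay any single trajectory of a run.

Implementation notes that matter numerically: the photon weight is
evaluated lazily as $w = \text{mult}\cdot e^{-\mu_a\,\text{path}}$ so no
per-segment exponential is needed, the roulette trigger becomes a
precomputed path-length comparison, and the absorbed weight follows by
exact bookkeeping at termination (launched + boosts − exited − killed −
capped). With roulette disabled, energy conservation therefore holds to
floating-point accuracy, and the tests assert it at $10^{-9}$ relative.
Photons reaching the per-photon scattering-event cap (default $10^6$) are
terminated and counted as lost weight, never dropped silently; a run
warns when lost weight exceeds $10^{-3}$ of the launched weight.

## The features: spatio-temporal moments

Nothing breaks rotational symmetry, so the reflected response reduces to
$I(r, t)$. Instead of binned histograms the inversion uses the weighted
statistical moments of the exit log, computed directly from the raw
records:

$$\langle r^\alpha t^\beta \rangle =
  \frac{\sum_i w_i\,(r_i - \langle r\rangle)^\alpha
        (t_i - \langle t\rangle)^\beta}{W},$$

with $W = \sum_i w_i$ and the weighted means $\langle r\rangle$,
$\langle t\rangle$ filling the orders 0 and 1. All orders with
$\alpha + \beta \le 5$ are used, in a canonical order (total order
ascending, $\alpha$ descending within an order): 21 features. The central
form is taken for every slot with total order $\ge 2$, including the
mixed and pure second-order moments — that reading is the only one
consistent with the count of 21, and is adopted deliberately. The
specular record is included by default (every exiting photon is part of
the logged response); a switch excludes it. Summation order is pinned by
sorting on (time, radius) so the features are deterministic however the
records arrive. An empty reflection detector — possible at extreme
absorption — yields a feature vector flagged invalid, never silent zeros;
dataset generation drops and counts such runs.

## The dataset

Optical properties are drawn independently per run: $n$ uniform on
$[1.3, 1.6]$, $g$ uniform on $[0.5, 0.95]$, and $\mu_s$, $\mu_a$
log-uniform on $[0.1, 100]$ and $[0.01, 10]$ mm$^{-1}$ — the span of
values reported for biological tissues, with log spacing because the
coefficients cover several decades. The log base is immaterial to the
induced distribution; base 10 is used for readability. Each record stores
its seed, truth and features; the whole corpus regenerates bit-identically
from the master seed. A uniformly random, seed-stable test split is held
out and never touched during training.

## The inverse model

A fully connected network $[21, x, x, x, 3]$ with ReLU hidden layers and
linear output regresses the features onto the targets $n$,
$\log_{10}\mu_s'$, $\log_{10}\mu_a$, each min–max normalized to $[0,1]$
over the training split ($\tilde x = (X - \min X)/(\max X - \min X)$); the
inverse transform (affine, then $10^{(\cdot)}$) is applied on output, so
predicted coefficients are strictly positive by construction and are
never clipped to the training range. The loss is mean squared error,
optimized by Adam at learning rate $10^{-3}$ on shuffled mini-batches of
256 — the minimal standard regression setup; none of these choices are
load-bearing, and the width-insensitivity test is the evidence. Input
features are likewise min–max scaled per feature using training-split
statistics only (the high-order moments span decades); an optional
signed-log pre-transform, $\mathrm{sign}(x)\log_{10}(1+|x|)$, is provided
but off by default since the scaled features train well without it.
Training runs the full epoch budget with no early stopping, and the
per-epoch loss history is kept. The trainer owns its RNG, so a seed fixes
initialization, batch order and the entire loss history.

Models persist as self-describing JSON (architecture, scalers, weights at
17 significant digits — enough for a bit-exact double round trip), and the
forward pass is computed record by record with matrix–vector products, so
batch predictions are element-wise identical to single ones.

## Accuracy measurement

Per test record and parameter the error is the linear-scale percentage
deviation $E = 100\,|X_{truth} - X_{pred}|/X_{truth}$ — linear even for
the coefficients trained in log space. Summaries report the median, the
mean and the 95% confidence level: the error below which 95% of the test
records fall, computed as the linearly interpolated 95th percentile (the
convention is pinned because nearest-rank differs slightly at finite test
sizes).

## Problem sizes, and what the tests show

The package's test and acceptance computations run at desk scale: a
corpus of 5,000 runs of $10^4$ photons each with a 1,000-record test
split, networks of widths 50–300 trained for 500 epochs. At these
conditions (seed 1) the held-out 95% confidence levels are roughly 3% in
$n$, 87% in $\mu_s'$ and 57% in $\mu_a$, with median errors of 0.6%, 9%
and 5% — the index recovered best, as expected, since Fresnel reflections
imprint $n$ on the response strongly at all parameter values. The
qualitative impulse-response checks (monotone decay after the specular
spike, absorption suppressing late times, scattering boosting early
backscatter) use $2\times10^5$ photons averaged over three common-seed
repeats. The full-scale study — some $3\times10^5$ runs of
$2.5\times10^5$ photons and 5,000 training epochs, at which the held-out
95% levels tighten to the order of 1% in $n$, 30% in $\mu_s'$ and 15% in
$\mu_a$ — is expressible with the same configuration object and code
paths, and is a matter of compute, not of code.

The synthetic corpus emulates an idealized impulse response: a delta
illumination at a point, a noiseless detector of unbounded extent and
perfect time resolution, a single homogeneous layer. It does not emulate
detector response or laser pulse width (a convolution deliberately left
out), detector noise, finite fields of view, multi-layer or heterogeneous
tissue, or polarization. Passing tests therefore demonstrate the
soundness of the transport kernel, the featurization and the inversion
machinery — not that a network trained here transfers to any particular
instrument without retraining on data that includes these effects.

## Known limitations and edge behavior

* Accuracy degrades where the physics is uninformative: low $\mu_s'$ (the
  reflected irradiance barely depends on it) and both extremes of
  $\mu_a$ (low: little imprint; high: little light returns). These are
  limits of the inverse problem, not of a particular solver.
* Runs at the extreme corner of high $\mu_s$ and low $\mu_a$ are the
  slowest (long diffusive walks); the event cap bounds them.
* The roulette boost weight is tracked separately (`roulette_boost`) so
  the energy ledger remains exact even with roulette on; the conservation
  invariant is only asserted with roulette off, where it is deterministic.
* `g = 0` falls back to isotropic cosine sampling exactly; $|g|$ very
  near 1 loses precision in the closed-form inversion below $10^{-12}$.
* Degenerate target scalers (a constant-truth corpus) are refused rather
  than silently producing NaNs.
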