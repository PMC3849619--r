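---
title: "Matching pursuit in metric-optimal Gabor dictionaries: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching pursuit in metric-optimal Gabor dictionaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaborpursuit)
```

## The model

Matching pursuit (MP) approximates a signal by a greedy sequence of
unit-norm waveforms: at every step the element of a redundant
dictionary with the largest absolute inner product with the current
residual is selected and subtracted.  The dictionary mixes four
families: real Gabor atoms
$g(t) = K\,e^{-\pi((t-u)/s)^2}\cos(\omega(t-u)+\phi)$, pure harmonics,
Kronecker deltas and pure Gaussians, so that oscillatory transients,
steady rhythms, spikes and baseline humps all have matched
representatives.  The method assumes a uniformly sampled, finite,
real-valued epoch; all internal frequencies are in radians/sample and
conversion to Hz happens only at the I/O and filtering boundaries
($f = \omega f_s/2\pi$).

Phase is not a dictionary dimension: for every class $(u,\omega,s)$
the phase maximizing the product with the signal has a closed form, so
the dictionary is built over equivalence classes of atoms modulo
phase.

## The metric and the meaning of ε

The quantity the greedy selection "sees" is the inner product, so
dictionary density is measured by
$d_0(g_0,g_1)=\sqrt{1-\langle g_0|g_1\rangle}$ and, between phase
classes, by $d=\sqrt{1-\langle G_0|G_1\rangle_{\max}}$ with the
maximal product taken over both phases.  Orthogonal atoms sit at
distance 1; the algebraic maximum $\sqrt 2$ is reached by antipodal
atoms.  A single parameter $\varepsilon\in(0,1)$ bounds the distance
between any atom and its nearest neighbor along each of the three
parameter directions.  Because $\varepsilon^2$ is a fraction of
energy, $\varepsilon$ directly bounds the one-step energy error of the
decomposition: a structure falling midway between grid points loses at
most a controlled fraction of its energy in the first fit.  The
package default is $\varepsilon = 0.1$; values above 0.5 defeat the
construction's purpose and trigger a warning.

The closed forms behind the construction are the maximal products of
scale-, frequency- and position-adjacent classes.  They depend on
$\omega$, but near the Nyquist frequency they reduce to expressions
independent of $\omega$, and choosing the steps there is conservative
at lower frequencies (the realized distances only shrink).  This gives
the dilation factor $a(\varepsilon)$ and the per-scale steps
$\Delta\omega(s)$, $\Delta u(s)$ used by `dictionary_layout()`.

`metric_d()` computes the two-phase maximal product exactly as the
largest generalized singular value of the $2\times2$ cross-Gram of the
discrete cosine/sine components, whitened by each class's own Gram —
no iteration or phase grid is involved; tests verify it against a
brute-force phase grid with local refinement.

## Numerical choices

**Discrete normalization.**  Atoms are normalized by their discrete
sample norm, not by the continuous-time factor $K(\gamma)$; atoms
clipped by the epoch border are renormalized on the clipped support.
The analytic product formula (with continuous normalization) is
retained for screening and testing: it matches adaptive quadrature to
$10^{-8}$, and discrete dot products agree with it to $\sim10^{-10}$
in the well-sampled regime, but near the Nyquist frequency discrete
products additionally contain the alias of the sum-frequency term, so
the discrete product is authoritative throughout the engine.

**Smallest scale.**  Scales below 4 samples are dropped.  The discrete
products of narrower atoms deviate from their continuous values by
Poisson-summation (alias) terms of order $e^{-\pi s^2/2}$ — about
$2\cdot10^{-3}$ at $s=2$ — which is enough to push near-Nyquist
neighbor distances above $\varepsilon$.  At $s\ge4$ the alias terms
are below $10^{-10}$ and the metric guarantee audits cleanly for
$\varepsilon\in\{0.05,0.1,0.2\}$.

**Envelope support.**  Atom samples are generated only where the
Gaussian envelope exceeds $10^{-16}$ of its peak
($|t-u|\le s\sqrt{16\ln 10/\pi}\approx 3.42\,s$); outside, exact
zeros.  This matches the bounded-domain treatment of the product
integrals and makes distant atoms exactly orthogonal in floating
point.

**Recursive tables.**  Waveforms are synthesized by one-step
recurrences for $\sin$, $\cos$ (a complex rotation) and the Gaussian
(two coupled geometric recursions), seeded by a single transcendental
call per direction and run center-out from the sample nearest $u$, so
every recursion factor is $\le 1$ and the envelope symmetry about $u$
is exploited.  The recurrences are evaluated as cumulative products
(one multiplication per sample) and agree with direct per-sample
transcendental calls to better than $10^{-9}$ over 4096 samples.

**FFT grids.**  Per scale, products with all frequencies are obtained
from one discrete Fourier transform of the envelope-windowed residual
segment.  The transform length is the smallest *even 5-smooth* integer
$L \ge \max(2\pi/\Delta\omega_{\mathrm{nominal}},\ \text{support})$,
and the realized frequency step is $2\pi/L$.  Snapping is always
downward (denser, never coarser), so the metric bound is preserved; a
power-of-two length would over-densify the grid by up to a factor 2,
doubling memory and time for no accuracy gain.  Grid frequencies are
exact multiples of $2\pi/L$; `windowed_fft_products()` refuses
incompatible grid steps rather than silently regridding.

**Gram-corrected optimal phase.**  In discrete time the cosine and
sine components $C$ and $S$ of a class are not exactly orthogonal, so
the phase maximization is solved on the full $2\times2$ Gram system:
the maximizing direction is $G^{-1}b$ with
$G = \begin{pmatrix}cc & -cs\\ -cs & ss\end{pmatrix}$,
$b=(\langle x,C\rangle, -\langle x,S\rangle)$, and the maximal product
is $\sqrt{b^\top G^{-1}b}$.  When $cs=0$ this reduces exactly to the
textbook arctangent formula; when $G$ is numerically rank one (e.g.
$\omega=\pi$ at integer centers) the dominant single component is
used.  Amplitudes of phase-carrying atoms are reported nonnegative,
with the sign absorbed into the phase, which is stored in $[0,2\pi)$.

**Fast orthogonality and bounded products.**  The analytic product
factorizes as $X\,Y\,Z$ with $|X|<2$ and $|Y|\lesssim 2/\varepsilon^2$
for atoms of an $\varepsilon$-dictionary; when
$(2\sqrt2/\varepsilon^2)Z<\eta$ (default $\eta=10^{-16}$, the double
precision accuracy) the pair is treated as orthogonal and zero is
substituted for the cross product.  Otherwise cross products are
evaluated on a truncated interval whose half-width was re-derived from
the Gaussian tail bound:
$\Delta' = \sqrt{\big(C-\log(\tfrac{\eta\varepsilon^2}{2}\sqrt{s_0/s_1+s_1/s_0})\big)/A}$.
(The scale-ratio factor enters under a square root; the bound is
verified empirically against full-support quadrature at
$\eta=10^{-12}$.)

**Tie-breaking and determinism.**  Atom enumeration order is (family;
scale ascending; $u$ ascending; $\omega$ ascending), the first maximum
wins, and stochastic subsampling draws from a private RNG stream
seeded by the configuration, so fixed dictionary + seed + data give
bit-identical books.

## The engines

The production engine maintains, besides the explicit residual, the
tables $\langle R^n x, C\rangle$, $\langle R^n x, S\rangle$ for every
class.  After each selection the tables are advanced by the update
formula
$\langle R^{n+1}x, g_i\rangle = \langle R^n x, g_i\rangle - w\langle g_n, g_i\rangle$,
with the cross products of the selected waveform computed by windowed
FFT over only the (non-orthogonal, support-overlapping) classes.  The
weight of the selected atom is re-evaluated against the explicit
residual, which keeps energy conservation exact to machine precision
and doubles as a drift guard: the maintained table entry is compared
with the direct value at $10^{-6}$ tolerance at every selection, with
a full table rebuild on violation.

`mp_decompose_naive()` is an exhaustive reference engine: direct
per-sample transcendental synthesis and explicit dot products over
every class in every iteration, no update formula, no FFT, no
screening.  On shared instances the two engines must produce identical
atom sequences with weights agreeing to $10^{-8}$; this is checked at
$N=512$ over 20 iterations.

The stopping rule is the conjunction of defaults 50 iterations and
99% explained energy — the iteration continues only while both limits
are unmet.  Because greedy selection depends only on the residual,
earlier atoms are unaffected by extending a run (the prefix property),
except across different stochastic dictionaries.

## Multivariate variants

All variants select a single envelope class per iteration for all
signals and always compute weights against the unaveraged residua:

* **MMP1** — one common phase; the class maximizing the sum of
  absolute products.  The common-phase objective has no closed form,
  so it is scanned on a 64-point phase grid (its period is $\pi$) per
  class; the top 32 candidates per block are refined by golden-section
  search to $10^{-10}$ and the best refined value wins, ties broken in
  enumeration order.  With a single selection signal the exact closed
  form is used instead, which makes the reduction to monochannel MP
  exact.
* **MMP2** — selection is plain MP on the channel average; weights per
  channel follow by linearity.  Average-referenced data (numerically
  zero channel mean) are refused, and a near-zero mean (energy below
  $10^{-10}$ of the mean channel energy) triggers a warning; waveforms
  in exact phase opposition across channels cancel in the average and
  converge slowly, which tests exhibit by comparison with MMP1.
* **MMP3** — free phase per signal; the class maximizing the sum of
  squared maximal products (each per-signal phase from the closed
  form).  From identical residual state its objective can never fall
  below MMP1's common-phase value, which is tested stepwise.

For a channels $\times$ trials matrix the composition MMPXY applies
rule Y across trials as the inner averaging step and rule X across the
resulting signals: MMP11/33 treat every (channel, trial) pair as a
signal with common/free phase; MMP12/32 average trials within each
channel; MMP21/23 average channels within each trial.  The catalog
leaves the free phase of MMP32 ambiguous between selection and
weighting; here selection on the per-channel trial averages uses one
free phase per channel, and at weighting every (channel, trial)
residual receives its own optimal phase.  MMP13 and MMP31 are
rejected by `mmp_variant()`.  The multivariate driver recomputes the
selection tables from the current residua each iteration rather than
carrying update-formula state per signal; at the problem sizes the
package targets this costs one windowed-FFT pass per signal and
iteration and keeps the six compositions on one code path.  (The
monochannel engine, where the table state dominates the cost, does use
the update formula.)

## Postprocessing conventions

The time-frequency map sums, per atom, the squared weight times a
unit-integral Gaussian blob
$\propto\exp\!\big(-2\pi\frac{(t-u)^2}{s^2}-\frac{s^2(\omega-\omega_0)^2}{2\pi}\big)$
— the Gaussian part of the atom's Wigner distribution — with
cross-terms omitted by construction and the negative-frequency mirror
of the real cosine dropped except for pure Gaussians, whose blob is
folded at 0 Hz to preserve the energy integral.  Deltas map to time
lines (uniform in frequency), harmonics to frequency lines (uniform
over the epoch).  With these conventions the map integral reproduces
$\sum_n w_n^2$ (tested to 1%), which fixes the normalization left open
by the general Wigner definition.

Amplitudes follow the EEG convention: the reported peak-to-peak value
is twice the mathematical amplitude $|w|\max_t|g(t)|$.  Filters
combine all criteria with logical AND; the slow-wave preset is
peak-to-peak $\ge 50\,\mu V$, width $\ge 0.5$ s, 0.5–4 Hz, and the
spindle preset 11–15 Hz, 0.5–2 s, $\ge 15\,\mu V$.  Epoch occupancy is
the union (not sum) of atom supports, each one scale unit wide by
default ($[u-s/2,\,u+s/2]$, configurable), the convention used for
staging rules based on slow-wave coverage.

## The synthetic generator

All test inputs are synthesized: planted unit-norm atoms scaled to
requested peak-to-peak microvolt amplitudes (per channel/trial, signs
allowed) plus white Gaussian noise of chosen standard deviation, with
the ground truth serialized beside the signal.  The sleep-like preset
is a 4 s epoch at 64 Hz with one slow wave (1.5 Hz, 60 µV, 1.2 s) and
two spindles (0.8 s, 30 µV) at 12.5 and 13.5 Hz.  The distinct spindle
carriers reflect real sleep EEG, where separate spindles are not
phase-locked; two bursts on the *same* carrier an integer number of
periods apart form a single coherent structure that any faithful
greedy decomposition would (correctly) explain with one epoch-wide
atom, which is a different scenario from two separate transients.
`noise_sigma_for_snr()` calibrates the noise so that the expected
noise energy matches a nominal SNR in dB; the Monte-Carlo spread of
the realized SNR at these epoch lengths is a few tenths of a dB.

What the generator does *not* emulate: colored (1/f) EEG background,
artifacts, nonstationary amplitude of ongoing rhythms, inter-channel
leadfield correlations, or latency jitter beyond what phase freedom
expresses.  Passing tests therefore demonstrate correctness of the
algorithms under the stated signal model, not detection performance on
clinical recordings.

## Problem sizes and runtime posture

The test suite and the reproduction script run at desk scale by
design: epochs of 256–1024 samples, dictionaries from
$\varepsilon=0.35$ (hundreds of atoms) down to $\varepsilon=0.05$ at
$N=256$ ($3.5\times10^6$ Gabor classes, ~200 MB of tables),
oracle sweeps of $10^3$–$10^4$ random pairs, and pursuit runs of
5–50 iterations.  These sizes keep every oracle (quadrature,
brute-force grids, the exhaustive engine) computable while exercising
the same code paths as full-scale use; `build_dictionary()` reports
its memory estimate and refuses builds beyond a configurable budget.

## Known limitations

* Books store atom parameters, weights and phases, but not residual
  waveforms; re-running from provenance regenerates them exactly.
* The common-phase (MMP1-type) selection is grid-scanned before
  refinement; classes whose refined objective exceeds the winner's but
  whose 64-point grid value falls outside the top 32 of their block
  could in principle be missed.  The phase objective is smooth between
  its $\pi$-periodic break points, so this requires near-degenerate
  competitors; the reductions to closed-form cases are exact.
* Exact discrete Gabor–Gabor products via theta-function series are
  not implemented; discrete dot products on the truncated support are
  used instead, which is also what the engine equivalence checks
  validate.
* Complex (analytic) Gabor atoms, dyadic dictionaries, orthogonalized
  pursuits and alternative information-theoretic stopping criteria are
  out of scope.
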