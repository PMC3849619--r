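# gaborpursuit

Matching pursuit (MP) decomposition of single- and multi-channel,
optionally multi-trial time series — EEG/MEG epochs in particular — in
**metric-optimal Gabor dictionaries**, with multivariate variants
(MMP1/2/3 and their channel-by-trial compositions), time-frequency
energy maps, and parameter-based detection of EEG transients such as
sleep spindles and slow wave activity.

## The problem and the method

Matching pursuit represents a signal *x* as a sparse sum of waveforms
("atoms") drawn greedily from a large redundant dictionary *D*:

    R^0 x = x
    g_n  = argmax_{g in D} |<R^n x, g>|
    R^{n+1} x = R^n x - <R^n x, g_n> g_n

yielding `x ≈ Σ_n <R^n x, g_n> g_n` after *M* iterations.  For
time-frequency analysis the dictionary consists of real Gabor
functions — Gaussian-windowed cosines

    g(t) = K exp(-pi ((t-u)/s)^2) cos(omega (t-u) + phi)

parameterized by time center *u*, scale (width) *s*, frequency *omega*
and phase *phi*, plus pure harmonics, Kronecker deltas and pure
Gaussians.  Unlike spectrograms or wavelets, the result is an explicit
parameterization of each transient: its time span, frequency,
amplitude and phase, directly comparable with the criteria used in
visual EEG analysis.

The package's core contribution is the **optimal dictionary**: atoms
are distributed uniformly with respect to the inner-product metric

    d0(g0, g1) = sqrt(1 - <g0|g1>),

extended to phase-equivalence classes via the maximal scalar product
over phases.  A single user-facing parameter ε ("energy error") bounds
the metric distance between neighboring atoms in all three directions
(scale, frequency, position).  From ε the package derives the dilation
factor `a = (1 + ε sqrt((2-ε²)(ε⁴-2ε²+2)))/(1-ε²)²`, the geometric
scale set `s_j = a^j`, and per-scale steps
`Δω = sqrt(-8π log(1-ε²))/s`, `Δu = s sqrt(-(2/π) log(1-ε²))`, which
makes the maximum one-step energy error of the greedy iteration
controllable *a priori*.

The engine implements the standard numerical optimizations: recursive
sin/cos/exp table generation, windowed-FFT inner products over whole
frequency grids, the product-update formula
`<R^{n+1}x, g> = <R^n x, g> - w <g_n, g>`, fast orthogonality
screening, bounded-domain products, and a closed-form optimal phase
(Gram-corrected for discrete time).  Multivariate variants decompose
many channels/trials jointly: MMP1 (common phase, max sum of absolute
products), MMP2 (selection on the channel average), MMP3 (free phase
per channel, max sum of squared products), composed across the
channel and trial axes as MMP11/12/21/23/32/33.

## Worked example: sleep-like EEG

Simulate a 4 s epoch at 64 Hz containing one slow wave (1.5 Hz, 60 µV
peak-to-peak, 1.2 s) and two sleep spindles (12.5/13.5 Hz, 30 µV,
0.8 s) in white noise at 20 dB SNR, then decompose it in a dense Gabor
dictionary (ε = 0.05):

```r
library(gaborpursuit)

spec <- sleep_preset_spec(seed = 1)
spec$noise_sigma <- noise_sigma_for_snr(spec, 20)   # 1.136 uV
sim  <- generate_synthetic(spec)

dict <- build_dictionary(dictionary_config(epsilon = 0.05, n_samples = 256,
                                           include_families = "gabor"))
book <- mp_decompose(sim$matrix, dict)    # default stop: 99% or 50 atoms
book
#> MP decomposition (mp): 3 atoms, 1 channel(s) x 1 trial(s), N = 256, fs = 64 Hz
#>   dictionary: epsilon = 0.05 (fixed), explained energy 99.03%
#>  iteration family      u  omega     s weight
#>          1  gabor 127.30 0.1473 74.16 158.24
#>          2  gabor 192.39 1.3220 49.68  64.91
#>          3  gabor  63.47 1.2265 49.68  64.00
```

Three atoms explain 99% of the energy.  In physical units:

```r
atom_physical_params(book)[, c("family", "peak_to_peak", "frequency_hz",
                               "width_s", "center_s")]
#>   family peak_to_peak frequency_hz width_s center_s
#> 1  gabor         61.6          1.5   1.159    1.989
#> 2  gabor         30.7         13.5   0.776    3.006
#> 3  gabor         30.2         12.5   0.776    0.992
```

All three planted transients are recovered within one dictionary grid
step and within a few percent in amplitude.  The slow-wave filter
(peak-to-peak ≥ 50 µV, width ≥ 0.5 s, 0.5–4 Hz) isolates exactly the
slow wave; `epoch_occupancy` then gives the fraction of the epoch
covered by such activity, the quantity behind automatic detection of
deep-sleep stages:

```r
swa <- filter_atoms(book, filter_preset("swa"))
atom_physical_params(swa)[, c("peak_to_peak", "frequency_hz", "width_s")]
#>   peak_to_peak frequency_hz width_s
#> 1         61.6          1.5    1.16
epoch_occupancy(swa)
#> [1] 29.08402
filter_atoms(book, filter_preset("spindle"))$params$iteration
#> [1] 2 3
```

`energy_map(book)` renders the decomposition as a time-frequency
energy density (one Gaussian blob per atom, no cross-terms), and
`write_book`/`read_book` serialize the decomposition as structured
text with full provenance.  The same pipeline is available from the
shell via `inst/cli/gaborpursuit`
(`simulate`, `dict-info`, `decompose`, `filter`, `tfmap`), e.g.

```sh
gaborpursuit decompose epoch.bin --output book.txt \
    --energy-error 0.1 --variant mmp3
```

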