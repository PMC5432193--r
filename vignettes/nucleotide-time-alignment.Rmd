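---
title: "Nucleotide-time alignment for molecular recorders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleotide-time alignment for molecular recorders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntalign)
```

## The recording problem

A DNA-polymerase molecular recorder writes a time-varying analyte — here,
intracellular calcium driven by neural spiking — into the pattern of
misincorporations along a growing DNA strand. Sequencing recovers the binary
error strand $D = d_1,\dots,d_N$ but not the incorporation times
$\tau_1 < \dots < \tau_N$: the polymerase extends stochastically and pauses
unpredictably, so a record with perfectly regular DNA indexing has highly
irregular time indexing. ntalign simulates this generative process and infers
the time axis afterwards by aligning the strand to time-indexed predictions of
calcium built from hypothesized neural tunings.

## Generative model

**Kinetics.** The waiting time between incorporations is a two-component
mixture: with probability `p_pause` the polymerase pauses, with the pause
duration exponential with mean `pause_mean` (default 2000 ms); otherwise it
extends after a Gamma(`gamma_shape`, `gamma_scale`) interval (defaults 1 and
10 ms, i.e. a 100 Hz exponential extension clock). The recorder presets
(`dnap_preset()`) use `p_pause = 0.001`: an overall incorporation rate of
~83 Hz with roughly 17% of recording time spent inside pauses
(`paused_fraction()` gives the closed form). We use the same kinetics for the
parameter-evaluation recorder: at ten times that pause probability the
recorder would spend two thirds of its time paused and an overall rate of
33 Hz, which contradicts the ~100 Hz operating point the presets are meant to
represent, and — as we verified by simulation — produces records whose
inter-bin waiting times are so heavy-tailed that no setting of the alignment
recursion localizes them (see *Limits of the method* below).

**Error generation.** Each nucleotide is an error with probability
$f(C_{\tau_n})$ where
$f(C) = R_\mathrm{max} / (1 + \exp[b (C - C_0)])$.
Note that $f$ as written is *decreasing* in $C$ for $b > 0$; a recorder whose
errors increase with calcium therefore uses $b < 0$, and the presets set
$b = -1$, $R_\mathrm{max} = 0.5$, $C_0 = 0$. Because raw convolved calcium is
non-negative while $C_0 = 0$, every calcium trace and template is standardized
to zero mean and unit variance before $f$ is applied; this places the
half-maximum error rate at the trace midpoint and gives the sigmoid its full
dynamic range. The standardization convention is a package choice — the
transfer function's calcium units are only defined up to this affine map — and
all inference (e.g. `estimate_slope()`) is carried out consistently in
standardized units.

**Calcium.** Spikes are Bernoulli draws per 1 ms bin from the tuning-model
rate; calcium is the causal convolution with an exponential kernel of decay
$\tau = 200$ ms and unit peak, implemented as the exact AR(1) recursion
$c_t = e^{-\Delta t/\tau} c_{t-1} + s_t$ (no kernel truncation is needed; the
recursion *is* the infinite-support kernel). Alignment templates convolve the
*expected* rate instead of sampled spikes.

## The alignment recursion

Local evidence is the log-likelihood matrix
$A_{n,t} = \ln P(d_n \mid c^*_t)$; probabilities are floored at $10^{-12}$
before logs so that $-\infty$ is reserved for structurally infeasible cells.
Scores accumulate as

$$S_{n,t} = A_{n,t} + \max_{j \in \{1..k\}}
  \left[(1-\omega)\, S_{n-1,\,t-j} + \omega \ln P(U_\mathrm{row} = j)\right],$$

with the arg-max stored as a backpointer. Lags are strictly positive — two
strand elements can never share a template sample — and ties break toward the
smallest lag (and, in the final column selection, toward the earliest time),
so paths are deterministic. The start is uninformative ($S_{1,t} = A_{1,t}$);
an optional start-time log-prior hook exists but is off by default. Because
row $n$ depends only on row $n-1$, every cell of a row can be computed
concurrently; `accumulate()` offers a compiled kernel (default), a vectorized
R implementation that computes whole rows at once, and a plain-loop reference,
and the test suite checks cell-for-cell agreement among all three.

**Downsampled (binned) mode.** For long strands, errors are summed over bins
of `L_D` nucleotides (binomial likelihood, the final partial bin keeping its
true size) and the template is block-averaged to `L_C` ms/sample (midpoint
timestamps). The crucial modeling point is the lag prior: at bin level the
waiting time between consecutive *rows* is the sum of `L_D` single-nucleotide
intervals, so `bin_lag_log_pmf()` computes the `L_D`-fold convolution of the
kinetic mixture (by FFT on a 1 ms grid, midpoint convention, then aggregation
onto the `L_C` grid). Using the single-interval distribution at bin level
would be physically wrong — with `L_D = 100` the true inter-bin time averages
~1.2 s, beyond any plausible single-interval lag. Bin-level times are mapped
back to nucleotides by piecewise-linear interpolation anchored at bin midpoint
indices, linearly extrapolated at the ends, clamped to the template support,
and nudged to strict increase with a minimum separation of one template sample
period.

**The role of `k`.** The backward search window `k` (default 2000 ms) is not
merely a computational budget: it acts as an Itakura-style path-bounding band.
With the prior weight $\omega$ small (defaults $1/100$ for parameter
evaluation, $1/240$ for center-out work), the kinetic term contributes little
per step, and it is the band — together with the support of the convolved lag
prior, whose zero-mass lags are $-\infty$, i.e. infeasible — that keeps the
path from stretching or compressing arbitrarily. We verified both failure
modes directly: widening the band to cover extreme quantiles of the lag
distribution lets the path chase local similarity maxima anywhere in the
window, and flooring (rather than excluding) zero-mass lags lets a pause-free
record take physically impossible multi-second steps at a cost of a few nats.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `r_max` | probability | 0.5 | maximum error rate; sets evidence contrast |
| `b` | 1/(std. calcium) | −1 | sigmoid steepness; sign sets direction |
| `c0` | std. calcium | 0 | half-maximum point |
| `p_pause` | per incorporation | 0.001 | pause probability (~17% paused time) |
| `pause_mean` | ms | 2000 | mean pause duration |
| `gamma_shape`, `gamma_scale` | —, ms | 1, 10 | extension interval (100 Hz) |
| `omega` | — | 1/100 (1/240 center-out) | kinetic-prior weight in the recursion |
| `k` | ms | 2000 | backward search band |
| `calcium_downsample` (L_C) | ms/sample | 50 | template resolution |
| `dna_downsample` (L_D) | nt/bin | 100 (25 center-out) | strand binning |
| `tau` | ms | 200 | calcium indicator decay |

## What the synthetic generators emulate

`make_block_stimulus()` reproduces the parameter-evaluation stimulus: 400
blocks of 5 s with intensity Uniform(0, 1) (a 2000 s window), driving a linear
tuning of 0.05 spikes·ms⁻¹ per unit stimulus. `make_center_out_kinematics()`
is a *synthetic stand-in* for recorded reaching kinematics: minimum-jerk
out-and-back reaches to eight uniformly spaced targets with holds, speed-gated
to [0.05, 0.4] m/s before analysis, driving a speed-scaled cosine tuning with
rates between 10 and 150 spikes/s. Reach and hold durations are jittered
±25% per cycle: self-paced reaching is not metronomic, and a perfectly
periodic task makes every template match at reach-period shifts — an artifact
of the stand-in, not a property of real kinematics. The generator does not
emulate trial structure beyond this (no target-holding errors, no variable
peak speeds, no recorded-arm idiosyncrasies), so center-out results here
characterize the algorithm on an idealized task, not performance on primate
data.

Passing tests on these generators show that the recorder model, the recursion,
and the inference chain are internally consistent and that timing and tuning
are recoverable under the stated conditions. They do not show that a
biological polymerase with these properties exists, nor how the method behaves
under real calcium-indicator nonlinearities, electrode/sorting artifacts, or
neural tunings outside the hypothesis ensemble.

## Problem sizes and study conditions

The package's experiment defaults are desk-scale versions of the study
conditions: 20 trials per condition in `run_parameter_sweep()` and
`run_center_out()` (the `--full` CLI flag restores 50 and 100), records of
10,000 bp for parameter evaluation and 12,000 bp for center-out work, and the
2000 s block stimulus. Per-trial seeds derive from one master seed through a
counter scheme, so identical configurations reproduce byte-identical tables.
The acceptance script reports the paused-time percentage (closed form) and the
median timing RMSD across 20 strands at the 10,000 bp record length.

## Numerical choices

- Probability floor $10^{-12}$ on similarity entries before logs; $-\infty$
  only for structural infeasibility (out-of-band lags, zero-mass lags,
  pre-template cells).
- Lag pmf bins integrate the mixture density over $((j-1)\Delta, j\Delta]$ by
  exact CDF differencing; the convolved bin-level prior uses an FFT at 1 ms
  resolution with the midpoint index convention (the grid is sized to the
  mixture mean plus twelve standard deviations).
- Deterministic tie-breaks (smallest lag, earliest final column).
- `error_rate_inverse()` refuses rates outside $(0, R_\mathrm{max})$;
  empirical bin rates at the boundary are clipped inward by a relative
  $10^{-6}$ with a warning before inversion.
- Records truncated by the recording window return shorter strands with a
  warning rather than an error.
- Timing RMSD defaults to the conventional $\sqrt{\mathrm{mean}((\tau -
  \tau^*)^2)}$; a literal variant that divides by $N$ instead of $\sqrt N$
  (`variant = "as_printed"`) is retained for comparison with reports that
  print the formula that way.

## Design decisions on genuinely open points

- **Sign of `b` and calcium standardization.** The transfer function as
  printed decreases in calcium for positive `b` while a recorder needs errors
  that rise with activity; we keep the equation literal and use negative `b`
  in all presets, with standardized calcium making `C_0 = 0` meaningful.
- **Pause probability of the parameter-evaluation recorder.** As discussed
  above, we use 0.001 — consistent with the ~100 Hz / 2 s-pauses / ~17%-paused
  operating point — rather than the ten-fold higher figure that appears in
  some parameter listings, which is incompatible with that operating point and
  with record alignability.
- **Bin-level lag prior.** The `L_D`-fold convolution, truncated at the `k`
  band and renormalized, with zero-mass lags infeasible.
- **Error-count GLM.** The per-nucleotide error indicator is binary, so
  preferred-direction estimation uses a logistic GLM on the velocity
  components at the estimated times; the ground-truth reference is the
  standard Poisson GLM on 1 ms spike counts with McFadden pseudo-$R^2$ as the
  fit filter (thresholds: rate > 20 spikes/s, pseudo-$R^2$ > 0.05).
- **Reference slope for the ratio.** The "true" calcium-stimulus slope is the
  least-squares regression of the ground-truth standardized calcium trace on
  the stimulus trace; the estimate bins errors at estimated times into 20
  equal-count stimulus bins, inverts the sigmoid, and regresses.

## Known limitations

- At the printed center-out settings (`omega = 1/240`, `k = 2000` ms,
  `L_D = 25`), the 2 s band is wide relative to the ~300 ms bulk inter-bin
  lag, and the path freedom lets every template in the eight-direction cosine
  ensemble align nearly as well as the generating one even though, at the true
  path, the generating template dominates by a wide likelihood margin.
  Template selection on the synthetic center-out task is accordingly
  weakly concentrated, and timing errors are an order of magnitude larger than
  in the parameter-evaluation regime. The pathology — including the classical
  confusion between a tuning and its antipode on out-and-back movements, which
  patch shuffling (`shuffle_patches()`) is designed to disrupt — is inherent
  to maximum-likelihood alignment with weak kinetic regularization.
- Records much shorter than ~5,000 bp localize bimodally in the 2000 s window
  (most seeds align to within seconds; a minority land on a spurious match),
  so median — not mean — timing error is the meaningful summary, and
  population-scale conclusions need tens of strands.
- Insertions/deletions, sequence-context-dependent pausing,
  nucleotide-specific error spectra, polymerase drop-off, and multi-strand
  consensus are out of scope; errors are strictly binary per position.
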