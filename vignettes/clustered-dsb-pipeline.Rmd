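---
title: "From LET to cell killing via clustered DSBs: models and methods"
author: "fociLET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From LET to cell killing via clustered DSBs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociLET)
```

# The inference chain

`fociLET` connects three experimentally measurable quantities for
carbon-ion beams at 1 Gy — the linear energy transfer (LET), the 3D volume
of γH2AX foci, and clonogenic survival — through a small set of parametric
laws:

* the per-nucleus **maximum focus volume** $v$ at LET $L$ is Gaussian with
  mean $\mu(L) = a_\mu L + b_\mu$ and standard deviation
  $\sigma(L) = a_\sigma L + b_\sigma$;
* the **clustering probability** $p_L(v_{th})$ — the probability that a
  nucleus acquires a focus of volume $v_{th}$ or greater — is the upper
  tail of that Gaussian (boundary inclusive; for a continuous law the
  boundary carries no mass, but the empirical counterpart
  `empiricalProbability()` counts inclusively for consistency);
* the **unhit fraction** is quadratic in LET,
  $R_{unhit}(L) = (cL)^2/100$, and $R_{hit} = 1 - R_{unhit}$;
* the clonogenic **killing effect** $1 - SF$, divided by $R_{hit}$, is
  compared with $p_L(v_{th})$ over a grid of candidate thresholds; the
  minimizer of the mean absolute difference across conditions is the
  concordant lethal volume.

For mixed clinical beams the same chain applies with $L$ replaced by the
dose-averaged LET $L_{mix} = \sum_i L_i d_i / D$ of the spread-out Bragg
peak (SOBP) at its center, with component LETs capped at 100 keV/μm — the
conventional lower edge of the overkill region, beyond which the death
fate of a traversed cell is taken as fixed.

## Assumptions worth stating

* The Gaussian max-volume law is used **untruncated** when evaluating
  densities and tail probabilities, although volumes are physically
  positive. At the reference coefficients the sub-zero mass is negligible
  (&lt; 0.5% at 13 keV/μm, the worst case in the validity domain
  13–100 keV/μm).
* The quadratic unhit law is an empirical approximation, deliberately not
  a Poisson zero-class: whether one particle traversal reliably produces a
  γH2AX focus is an open biological question, so the model fits the
  observed fractions directly. The law saturates at $L = 10/c$
  (`domainMaxLET()`, ≈162 keV/μm at the reference coefficient); evaluation
  beyond it is an error rather than a clipped value, since $R_{hit}$ would
  go negative silently.
* The hit-normalization assumes survival decomposes additively into unhit
  cells (which always survive) and hit cells (which survive with their own
  probability): $SF = R_{unhit} + R_{hit}\,SF_{hit}$.
* The desk-scale SOBP reading treats each ridge-filter leg $j$ as one
  spectrum component: $L_j = L_{mono}(z + s_j)$,
  $d_j = w_j\,dose_{mono}(z+s_j)$. Full Monte Carlo LET histograms
  (nuclear fragments, straggling) are out of scope; the spectrum is
  carbon-only by construction.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `floor` (focus exclusion) | 0.01 | μm³ | smallest reliably rendered focus volume |
| `binWidth` (histogram) | 0.1 | μm³ | resolves σ at the lowest LET while keeping ≥5 populated bins at n = 30 |
| `threshold` (occupancy) | 0.01 | fraction | unhit = γH2AX occupancy strictly below 1% of the nuclear area |
| `cap` (overkill) | 100 | keV/μm | lower edge of the overkill region |
| `vthGrid` | 0.1–2.0 by 0.1 | μm³ | covers the observed max-volume range; contains 0.7 |
| LET panel | 13, 20, 40, 60, 80, 100 | keV/μm | 13 = clinical entrance LET; 100 = highest LET free of overkill |

The reference coefficients are exposed as `defaultLETLaws()`
(0.0158, 0.126, 0.00724, 0.0312) and `defaultUnhitLaw()` (0.0618); they
are the generator truths and the benchmark for recovery experiments, not
values re-estimated at load time.

# The synthetic-data generator

The generator replaces four measured inputs, at the reference study scale
(30 nuclei per LET for volumetry, 200 cells per LET for occupancy,
triplicate clonogenic wells of 2000 seeded cells, 1 Gy):

* **Focus tables** (`genFociTable`). Per nucleus, a Bernoulli unhit flag
  with probability $R_{unhit}(L)$; hit nuclei draw their maximum volume
  from Normal($\mu(L), \sigma(L)$), resampled below the exclusion floor so
  the sample size stays fixed and the fitting stage never sees sub-floor
  values. Sub-maximum foci are decoration for realism: the focus count is
  $1 + \mathrm{Poisson}(s\cdot 13/L - 1)$ with `fociCountScale` $s = 44$,
  reflecting the observed roughly inverse-in-LET focus counts and making
  the expected panel total ≈3300 foci, the scale of the reference dataset;
  their volumes are log-normal clamped to [floor, nucleus maximum]. Only
  the maxima feed the model, so the sub-max law needs plausibility, not
  fidelity.
* **Occupancy tables** (`genOccupancyTable`). Unhit cells draw occupancy
  uniformly below 1%, hit cells from $0.01 + 0.4\,\mathrm{Beta}(2, 8)$;
  nuclear areas are Normal(150, 15) μm², mimicking G0/G1-synchronized
  fibroblast monolayers.
* **Clonogenic tables** (`genClonogenicTable`). Colonies are
  Binomial($n_{seeded}$, $PE \cdot SF(L)$) with
  $SF(L) = 1 - R_{hit}(L)\,p_L(v_{th}^{true})$, $v_{th}^{true} = 0.7$ μm³,
  plating efficiency 0.7; controls are Binomial($n_{seeded}$, $PE$).
* **Depth profiles and SOBP specs** (`genMonoDepthProfile`,
  `genSOBPSpec`). A parametric Bragg-like curve on an exact 0.1 mm grid:
  dose = gentle linear ramp + Gaussian peak at the range (150 mm,
  ≈290 MeV/n in water), exponential distal falloff; LET rises
  monotonically from 13 to 180 keV/μm as $(z/R)^8$ and holds beyond the
  range, where dose is negligible. Ridge-filter weights are non-negative
  least squares against a flat unit plateau over [range − width, range] at
  2 mm shift spacing, normalized to sum 1 — a deterministic stand-in for
  proprietary ridge-filter tables. The evaluation depth is the
  dose-weighted plateau midpoint.

One master seed drives everything: each generator derives its own
substream seed, restores the caller's RNG state on exit, and is
byte-reproducible independently of call order.

**What the generator does not emulate** — and hence what green tests do
not demonstrate about real data: microscopy segmentation error and
deconvolution artefacts, cell-cycle and cell-line heterogeneity,
departures of the true max-volume distribution from Gaussianity,
correlation between focus count and focus size within a nucleus, dose-rate
effects, and fragment LET spectra in mixed beams. Passing recovery tests
show the *procedure* is unbiased and correctly implemented under the
model's own assumptions, not that the model is true.

# Numerical choices

* **Histogram fit.** Bins anchored at 0 (volumes are positive; anchor
  choice is otherwise immaterial), density-normalized (fraction per bin ÷
  bin width) so the unit-integral Gaussian density is the direct fit
  target with no floating amplitude. Levenberg–Marquardt
  (`minpack.lm::nlsLM`) initialized at the sample mean/SD, parameter and
  function tolerance $10^{-10}$, $\sigma > 0$ via box constraint;
  exhausted iterations are an error, never a silent fallback. Fewer than 5
  samples, or an all-equal sample, is an error.
* **Unhit fit.** The one-parameter quadratic is linear in $a = c^2$, so
  the non-negative least-squares solution is closed-form:
  $a = 100\sum_k R_k L_k^2 / \sum_k L_k^4$, clipped at 0. Unweighted, in
  fraction space.
* **Tail probability.** Closed form via `pnorm` (complementary error
  function); tests verify agreement with adaptive quadrature of the
  explicit density to $10^{-8}$ over the full (LET, $v_{th}$) lattice.
* **Depth interpolation.** Linear between the 0.1 mm grid points;
  extrapolation outside the grid is an error, not a clamp.
* **Concordance ties.** `optimalThreshold` breaks ties toward the smaller
  threshold, deterministically. Differences are computed on fractions;
  percent appears only at I/O edges.
* **Dispersion.** The across-condition spread of the concordance
  difference is the sample standard deviation over conditions (the
  natural reading of mean ± spread across an LET panel).
* **Empirical $p$ denominator.** `empiricalProbability` divides by the
  number of nuclei contributing a max-volume sample (hit nuclei): unhit
  handling belongs to the $R_{hit}$ normalization, and mixing unhit zeros
  into $p$ would double-count them.
* **Degenerate inputs.** Zero control colonies (plating efficiency
  undefined), empty tables, constant rank-correlation input, non-positive
  $\sigma$ at a requested LET, and LET beyond the unhit domain are all
  errors with specific messages; SF &gt; 1 or normalized killing &gt; 1 —
  possible under binomial noise near zero killing — warn and proceed.

# Problem sizes used by the test suite

Recovery experiments run at the reference scale: 500 replicates of the
full 6-LET × 30-nucleus fitting chain for the linear laws (the σ intercept
is the noisiest coefficient at n = 30, hence its wider acceptance band),
one 10⁴-cells-per-LET run for the unhit coefficient, and 100 seeded
end-to-end pipeline runs for threshold recovery (true threshold 0.7 μm³,
recovery within one 0.1 μm³ grid step). These sizes make the whole suite
run in well under a minute while leaving Monte Carlo error far inside the
acceptance bands.

# Known limitations

* The concordance thresholds reported for the reference study (and its
  headline difference percentages) depend on its undeposited measured
  data; the package reproduces the procedure and validates it on
  synthetic data, not those printed values.
* The Gaussian law was fitted at 1 Gy; focus volumes, and hence the
  lethal-volume threshold, may shift at other doses or under altered
  damage-response signalling.
* The SOBP model is a parametric stand-in: no particle transport, no
  scatterer, no fragment spectra. `composeSpectrum` is exact for the
  desk-scale ridge-filter reading, but $L_{mix}$ values should not be
  quoted against beamline Monte Carlo output.
* `fitMaxVolumeGaussian` at n = 30 with 0.1 μm³ bins is noticeably noisy
  at the lowest LET (σ ≈ 0.13 μm³ spans only a few bins); the linear-law
  regression across six LETs is what stabilizes the recovered
  coefficients.
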