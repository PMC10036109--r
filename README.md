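# fociLET

Linking LET, γH2AX focus volume and clonogenic cell killing for carbon-ion
beams.

## The problem

The cell killing effect of carbon-ion radiotherapy per unit absorbed dose
grows with linear energy transfer (LET) up to roughly 100 keV/μm.
Mechanistically this is attributed to *clustered* DNA double-strand breaks —
several breaks within a few hundred nanometres — which are prone to lethal
misrepair. High-resolution microscopy makes the clustering visible as large
γH2AX foci, so the 3D volume of the largest focus in a nucleus is a
quantitative proxy for the degree of DSB clustering. `fociLET` implements
the full inference chain that connects these quantities, for
radiobiologists and treatment-planning researchers who want to evaluate or
extend the model:

1. **Focus-volume model.** At 1 Gy, the per-nucleus maximum focus volume
   $v$ at a given LET is modelled as Gaussian,
   $f_{LET}(v) = \frac{1}{\sqrt{2\pi}\,\sigma_{LET}} \exp\!\left(-\frac{(v-\mu_{LET})^2}{2\sigma_{LET}^2}\right),$
   fitted to 0.1 μm³-binned histograms by least squares, with both
   parameters linear in LET: $\mu_{LET} = 0.0158\,\mathrm{LET} + 0.126$ and
   $\sigma_{LET} = 0.00724\,\mathrm{LET} + 0.0312$ (μm³, LET in keV/μm) for
   the reference A549 dataset. The probability of inducing a focus of at
   least a candidate lethal volume $v_{th}$ is the upper tail
   $p_{LET}(v_{th}) = \int_{v_{th}}^{\infty} f_{LET}(v)\,dv$.
2. **Unhit-cell model.** At high LET and fixed dose, fewer particles
   traverse each nucleus and a growing fraction of cells is never hit
   (γH2AX occupancy below 1% of the nuclear area). The unhit fraction is
   modelled as $R_{unhit} = (0.0618\,\mathrm{LET})^2/100$, and
   $R_{hit} = 1 - R_{unhit}$.
3. **Survival.** Clonogenic surviving fraction = (colonies / seeded) /
   plating efficiency; killing effect = 1 − SF; the *hit-normalized*
   killing effect divides by $R_{hit}$ so killing reflects only traversed
   cells.
4. **Mixed beams.** For a spread-out Bragg peak (SOBP) composed from
   ridge-filter weighted, range-shifted monoenergetic beams,
   $L_i = \sum_j w_j L_{i,mono}(z+s_j)$ and the dose-averaged LET
   $L_{mix} = \sum_i L_i d_i / D$, with components above 100 keV/μm capped
   at 100 (overkill region).
5. **Concordance.** Sweeping $v_{th}$ and comparing $p$ with the
   hit-normalized killing across conditions locates the lethal-volume
   threshold at which the two agree — 0.7 μm³ for the reference data.

Because the underlying microscopy and beamline data are not publicly
deposited, the package ships a first-class synthetic-data generator that
emulates their statistical structure (Gaussian maxima with LET-linear laws,
Bernoulli unhit cells under the quadratic law, binomial colony counts tied
to the clustering probability, parametric Bragg-like depth profiles), so
every stage is testable end to end.

## Worked example

```r
library(fociLET)

cfg <- GeneratorConfig(seed = 1)   # reference study conditions
res <- runPipeline(cfg)

res$laws
#> LETLaws
#>   mu(L)    = 0.016556 * L + 0.11396  [um^3]
#>   sigma(L) = 0.0050545 * L + 0.114  [um^3]
res$unhitLaw
#> UnhitLaw: R_unhit(L) = (0.06189 * L)^2 / 100, valid for L <= 161.6 keV/um
res$vthOpt
#> [1] 0.8
```

With 30 nuclei and 200 cells per LET — the reference sample sizes — the
laws fitted from one synthetic experiment land near the generator truths
(μ-slope 0.0166 vs 0.0158; unhit coefficient 0.0619 vs 0.0618), and the
concordance optimum (0.8 μm³) falls within one 0.1 μm³ grid step of the
true lethal threshold 0.7 μm³. Closed-form quantities:

```r
clusteringProbability(0.7, 60, defaultLETLaws())
#> [1] 0.7890891     # probability of a >= 0.7 um^3 focus at LET 60
hitFraction(100, defaultUnhitLaw())
#> [1] 0.618076      # fraction of cells traversed at LET 100
```

Mixed clinical beams, composed from a parametric monoenergetic depth
profile:

```r
mono <- genMonoDepthProfile()
for (w in c(30, 60, 120)) {
  sp <- composeSpectrum(mono, genSOBPSpec(w, mono))
  cat(sprintf("width %3d mm: L_mix = %.1f keV/um\n", w,
              doseAveragedLET(capSpectrum(sp))))
}
#> width  30 mm: L_mix = 94.7 keV/um
#> width  60 mm: L_mix = 61.7 keV/um
#> width 120 mm: L_mix = 27.5 keV/um
```

Narrow SOBPs concentrate dose near the Bragg peak and carry a high
dose-averaged LET; widening the plateau mixes in low-LET entrance
components and pulls $L_{mix}$ down — the pattern that motivates
LET-modulated treatment planning.

## Vignette

`vignettes/clustered-dsb-pipeline.Rmd` documents the model assumptions,
the generator design, numerical choices and known limitations.
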