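# hccalloc

Deterministic modelling of liver-graft allocation to patients with
hepatocellular carcinoma (HCC), for transplant-policy analysts who want to
ask: *by how much can the Milan 5 cm size cutoff be relaxed without
increasing total mortality on the waiting list?*

## The model

`N` HCC patients enter the waiting list over a short interval; `F < N`
donor livers are available. Tumor size at presentation `s` (cm) is
exponential with rate `λ` (per cm), density `p(s) = λ e^{−λs}`. Mortality
hazards (per year, constant in time at fixed size) are

- non-transplanted: `α_nt(s) = α₀ (α₁ − e^{−δ₁ s})` — concave, saturating
  at `α₀α₁`;
- transplanted: `α_t(s) = α₀ + δ₂ s` — linear.

With `α₁ = 2` the hazards coincide at `s = 0`; with `α₀ δ₁ > δ₂` they cross
once more at a positive size, below which transplantation lowers the hazard.
Survival over the horizon `T` is `e^{−α(s)T}`. Under the threshold policy
"transplant a fraction `g(s)·F/N` of patients with `s ≤ s₀`", expected total
deaths after `T` years are

```
M(s₀) = N − F∫₀^{s₀} λe^{−λs} e^{−α_t(s)T} ds
          − N∫₀^{s₀} (1 − F/N) λe^{−λs} e^{−α_nt(s)T} ds
          − N∫_{s₀}^∞ λe^{−λs} e^{−α_nt(s)T} ds .
```

`M` is stationary exactly where the two hazards cross, so the package
reports both the mortality-minimizing threshold `s*` and the *equivalent
threshold* `s_eq > s*` at which mortality climbs back to its value at the
Milan cutoff `S_M = 5` cm — the maximum criteria expansion that does not
worsen list mortality. An individual-based Monte-Carlo simulator provides an
independent stochastic check on the quadrature, and an exponential
maximum-likelihood fitter estimates `λ` from observed size samples.

## Worked example

```r
library(hccalloc)
scn <- hcc_scenario()    # N=1500, F=500, lambda=0.3, T=5, alpha0=0.048,
                         # alpha1=2, delta1=0.3, delta2=0.006, S_M=5
summary(scn)
```

```
Liver-allocation scenario (hcc_scenario)
  hazards : alpha0=0.048 /yr, alpha1=2, delta1=0.3 /cm, delta2=0.006 /yr/cm
  sizes   : exponential, lambda=0.3 /cm (mean 3.33 cm)
  cohort  : N=1500 patients, F=500 grafts, horizon T=5 yr
  policy  : threshold s0=5 cm (Milan cutoff S_M=5 cm), bias none (g=1)
  at s0=5 cm: 440.84 expected deaths, 1059.16 survivors, 388.4 grafts used
  full-utilization threshold s_F = 1.352 cm
  hazard crossing at 7.029 cm; optimal threshold s* = 7.03 cm (M = 440.13)
```

Reading: at the Milan cutoff, 440.84 of 1500 patients are expected to die
within 5 years and only 388 of the 500 grafts are used. Raising the
threshold to the hazard-crossing size 7.03 cm lowers expected deaths to
440.13 — the minimum. Beyond it mortality rises again:

```r
equivalent_threshold(scn)[c("s_eq", "M_eq", "M_ref")]
#> $s_eq  10.19    $M_eq  440.84    $M_ref 440.84
```

so the criteria can expand to about 10 cm before mortality returns to the
Milan level. The Monte-Carlo oracle agrees with the quadrature:

```r
mc <- mc_mortality(scn, s0 = 7, reps = 300, seed = 42)
#> mean 439.84, se 0.97 — quadrature gives 440.13
```

`mortality_curve(scn)` tabulates deaths/survivors/grafts over a threshold
grid (with `plot()` and `print()` methods), `milan_summary(scn)` gives the
four-way transplanted/non-transplanted split around the cutoff, and
`fit_tumor_sizes(sizes)` fits the exponential size distribution to data.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hcc-alloc.R",package="hccalloc"))')" \
    optimize --config inst/extdata/paper_scenario.yaml --out results/
```

Subcommands: `curve`, `optimize`, `milan`, `simulate`, `fit`; all outputs
echo the full parameter record.

## See also

The methods vignette (`vignettes/allocation-model.Rmd`) documents the model
assumptions, parameter conventions (including the choice of `δ₁`), numerical
tolerances, the simulator design, and known limitations.
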