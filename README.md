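# tockykinetics

Kinetic modeling and summary statistics for Fluorescent Timer
("Tocky") reporter flow cytometry in T cells.

Timer reporters are translated in a blue-fluorescent form that
converts irreversibly to a red-fluorescent form with fixed kinetics,
so Blue⁺ cells mark recent transcription, Blue⁺Red⁺ sustained
transcription, and Red⁺-only cells arrested transcription. Driven by
an immediate-early gene promoter such as *Nr4a3*, the Timer turns
flow cytometry into a clock for T-cell receptor (TCR) signaling.
`tockykinetics` is for immunologists and modelers who want to go
beyond gating percentages and ask *when* a promoter was active and
*how strongly*, from ordinary multi-timepoint flow data.

## The model

The Timer Blue signal `x(t)` follows a linear ODE driven by the
promoter activity `g(t)`:

    dx/dt = g(t) − γ·x(t)

with first-order Blue loss rate γ (degradation plus spectral
conversion). Promoter activity is parameterized as a rise-and-saturate
ratio of power laws,

    g(t) = k₁ · (t/T₁)^h₁ / (1 + (t/T₂)^h₂)

with five positive constants: amplitude `k₁`, rise timescale `T₁` and
exponent `h₁`, saturation timescale `T₂` and exponent `h₂`. When
`h₁ < h₂`, `g` rises from zero to a single interior peak and decays
back to zero. The five parameters are inferred per condition by
bounded multi-start least squares against normalized Blue median
fluorescence sampled at 5, 12, 24, 48 and 72 h post-stimulation.

Two decay presets are provided and never silently merged: `"paper"`
(γ = 0.697 h⁻¹, the value used for published inference fits) and
`"halflife"` (γ = ln 2 / 4.1 h⁻¹, from the Blue protein's reported
~4.1 h half-life). The package also ships the standard Timer flow
summary statistics (strict-threshold gating, median-of-positive MFI,
percent-of-experimental-max normalization, 48 h/24 h fold changes,
knockout/wild-type ratio curves, CFSE division-cycle summaries,
pseudo-time binning on Blue levels) and a synthetic single-cell event
generator (two-state Blue→Red maturation, division dilution,
lognormal noise) so the whole pipeline is testable end to end.

## Worked example

Simulate a wild-type vs *Itk*⁻/⁻-like experiment, summarize it, and
recover the generating promoter kinetics:

```r
library(tockykinetics)
library(dplyr)

cfg <- generator_config(
  conditions = condition_presets(c("itk_wt_N4", "itk_ko_N4")),
  n_cells = 5000, noise_cv = 0.1, seed = 42)
events <- simulate_experiment(cfg)

gate <- gate_from_control(events, "blue")   # 99th pct of t = 0 events
summaries <- summarize_events(events, gate,
                              by = c("condition", "genotype", "time_h"))
fold_change_ratio(summaries, value_cols = "mfi_positive")
#> # A tibble: 2 × 4
#>   condition genotype channel ratio_mfi_positive
#>   <chr>     <chr>    <chr>                <dbl>
#> 1 itk_ko_N4 Itk_ko   blue                0.459
#> 2 itk_wt_N4 Itk_wt   blue                0.0981
```

The 48 h/24 h Blue fold change is ~4.7× higher in the knockout-like
condition: its Blue signal persists because promoter activity declines
slowly, the hallmark of impaired signal termination. Fitting the ODE
model closes the loop:

```r
rec <- end_to_end_recovery(cfg, pairs = list(c("itk_wt_N4", "itk_ko_N4")))
rec$per_condition |> select(condition, rmse_pct_peak, t_peak_true, t_peak_fit)
#> # A tibble: 2 × 4
#>   condition rmse_pct_peak t_peak_true t_peak_fit
#>   <chr>             <dbl>       <dbl>      <dbl>
#> 1 itk_wt_N4          5.46        12.0       13.3
#> 2 itk_ko_N4          8.28        12.0       13.0
rec$pairs
#> # A tibble: 1 × 5
#>   reference alternative percent_reduction_true percent_reduction_fit
#> 1 itk_wt_N4 itk_ko_N4                     30.0                  29.4
```

Both inferred activity curves peak within ~1.3 h of the true 12 h
peak, and the knockout's true 30% peak reduction is recovered as
29.4% from 10% lognormal single-cell noise. Individual fits are
broom-friendly (`tidy()`, `glance()`) and plottable (`autoplot()`).

## Package layout

* `R/promoter.R`, `R/decay.R`, `R/simulate-blue.R` — the forward model
* `R/fit.R` — promoter-parameter inference and peak comparisons
* `R/summaries.R` — flow-cytometry summary statistics
* `R/generator.R`, `R/recovery.R` — synthetic single-cell generator
  and end-to-end self-test
* `R/io.R` — validated CSV IO, pipeline orchestration, provenance
* `vignettes/timer-kinetics.Rmd` — the methods vignette: model
  assumptions, parameter choices, generator design, limitations
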