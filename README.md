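# ddphen

Degree-day phenology analysis for multivoltine orchard pests.

Growers time insecticide and mating-disruption interventions against moths
such as the oriental fruit moth from two data streams: daily min/max
temperatures from a nearby weather station, and weekly pheromone-trap
catches. `ddphen` implements the full analysis chain connecting them:

1. **Thermal time.** Daily degree days (DD) by the *single sine* method:
   the day's temperature course is modelled as one sine wave through
   (tmin, tmax) and integrated above a lower development threshold
   (default 7.2 °C) after clipping at an upper threshold (32.2 °C,
   *horizontal cutoff* — development saturates, it is not reduced).
   Accumulation restarts every 1 January.
2. **Forecast model.** A DD-offset multivoltine forecast: first moth catch
   predicted at 126 DD after 1 January, then fixed egg-to-egg generations
   of 535 DD (plus an optional 60 DD per-generation delay for larvae
   developing on apples, 595 DD in total). Predicted generation *k* spans
   `[126 + (k−1)·G, 126 + k·G)` on the DD axis.
3. **Traps.** Weekly per-trap counts are aggregated to area means ± SE and
   re-expressed on the accumulated-DD axis.
4. **Segmentation.** Flights are separated at the minima between capture
   peaks (3-week smoothing, prominence-filtered peaks); the DD span of a
   flight is the operational adult-to-adult generation time. Ambiguous
   boundaries in one year are imputed from the same transition in the
   other years of the area.
5. **Statistics.** Stepwise factorial ANOVA of generation durations,
   Shapiro–Wilk/Bartlett checks, Tukey comparisons of flight order within
   province with compact letter display, jackknife SE of the mean.
6. **Synthetic data.** A generator with Gaussian emergence kernels on the
   DD axis and negative-binomial trap counts, with known ground-truth
   boundaries, so every stage is testable without field data.

## Worked example

Simulate a dry-continental season with five generations spaced 528 DD,
then recover them:

```r
library(ddphen)
sc  <- scenario_preset("lleida_like", seed = 7)
wx  <- generate_weather(sc$climate)             # one synthetic year
dds <- accumulate_dd(wx)                        # DD clock from 1 January
sim <- generate_catches(sc$population, dds)     # weekly catches + truth
ddc <- to_dd_axis(sim$catches, dds)             # weekly means on DD axis
segs <- segment_flights(ddc)                    # flights split at minima
segs
#> flight_order start_week   end_week  dd_start    dd_end duration_dd complete
#>            1 2019-02-11 2019-05-06  143.1518  725.9253    582.7735     TRUE
#>            2 2019-05-13 2019-06-10  725.9253 1203.8532    477.9279     TRUE
#>            3 2019-06-17 2019-07-15 1203.8532 1778.0476    574.1944     TRUE
#>            4 2019-07-22 2019-08-12 1778.0476 2245.4355    467.3880     TRUE
#>            5 2019-08-19 2019-09-16 2245.4355 2757.0324    511.5968     TRUE
round(sim$truth$boundaries_dd)                  # true flight boundaries
#> 660 1173 1708 2237
```

Five flights are recovered; the detected boundaries (726, 1204, 1778,
2245 DD) sit within one weekly check of the truth. Scoring against the
535-DD forecast windows:

```r
w <- generation_windows(phenology_params())     # 126 + k*535 windows
coverage_score(ddc, w)                          # catches inside windows
#> 1
round(boundary_offsets(segs, w)$offsets_dd)     # observed - predicted DD
#> 17 65 8 47 -21
durs <- segs$duration_dd[segs$complete]
c(mean = mean(durs), se = jackknife_se(durs))
#> mean 522.8, se 23.9 DD
```

The mean recovered generation time (522.8 ± 23.9 DD) matches the 528 DD
used to build the population; offsets fluctuate around zero with no trend,
i.e. the 535-DD model fits this population. Run the same analysis with
`scenario_preset("girona_like")` (generations spaced 626 DD) and the
offsets grow by ≈ 90 DD per generation — the accumulating forecast error
that motivates local recalibration.

The command line mirrors the stages:

```sh
Rscript -e 'ddphen::ddphen_cli()' simulate --scenario lleida_like --seed 7 \
    --out-weather w.csv --out-catches c.csv --out-truth t.json
Rscript -e 'ddphen::ddphen_cli()' dd --weather w.csv --out dd.csv
Rscript -e 'ddphen::ddphen_cli()' segment --catches c.csv --weather w.csv \
    --out flights.csv
```

## Documentation

The methods vignette (`vignettes/ddphen-methods.Rmd`) describes the model,
the segmentation and reconciliation rules, what the synthetic generator
does and does not emulate, and the package's numerical choices.
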