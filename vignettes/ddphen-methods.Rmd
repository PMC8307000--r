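---
title: "Methods: degree-day phenology analysis with ddphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degree-day phenology analysis with ddphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddphen)
```

## The model and its assumptions

Insect development is temperature-driven. Above a lower development
threshold $T_L$ each degree-hour contributes thermal time; above an upper
threshold $T_U$ development saturates. The **single sine** estimator
models one day's temperature course from its minimum and maximum as

$$T(t) = \tfrac{t_{\min}+t_{\max}}{2} + \tfrac{t_{\max}-t_{\min}}{2}\,
\sin(2\pi t), \qquad t \in [0, 1],$$

and the day's degree days are $\int_0^1 \max\{0, \min(T(t), T_U) -
T_L\}\,dt$ — the **horizontal cutoff**: the curve is clipped at $T_U$, so
development continues at its maximal rate on hot afternoons rather than
being reduced. The closed form has six cases by where the thresholds cut
the sine (fully below, spanning $T_L$ only, fully between, spanning $T_U$
only, spanning both, fully above). Correctness in this package is defined
against a numerical quadrature of the clipped sine, not against any
particular algebraic arrangement: the test suite checks agreement to
$10^{-6}$ DD over a grid spanning all six regimes.

The forecast itself is an offset model on the accumulated-DD axis:
accumulation starts 1 January (the biofix date, inclusive — 1 January's
cumulative DD equals its daily DD), the first moth catch is predicted at
`biofix_dd` (default 126 DD) and each subsequent generation occupies a
fixed `generation_dd` (535 DD egg to egg), optionally widened by a
per-generation host delay (60 DD for larvae developing on apples, 595 DD
in total). Predicted windows are **half-open** `[start, end)` so a catch
exactly on a boundary belongs unambiguously to the later generation, and
the delay is applied per generation — window *k* for apple ends exactly
$60k$ DD after the peach window — rather than as a single season shift.

Key assumptions worth keeping in mind: one sine per day fitted to that
day's extremes only (no day-to-day interpolation, no sub-daily data); a
single biofix for all areas; generation length constant within a season.

## Parameters

| parameter | unit | default | why |
|---|---|---|---|
| `lower` | °C | 7.2 | classic lower development threshold for the target moth |
| `upper` | °C | 32.2 | upper threshold; horizontal cutoff |
| `biofix_dd` | DD | 126 | predicted first catch after 1 Jan (some field series suggest ≈160; the parameter is exposed rather than resolved) |
| `generation_dd` | DD | 535 | egg-to-egg generation time |
| `host_delay_dd` | DD | 0 / 60 | peach / maximum reported apple delay, per generation |
| `n_generations` | – | 5 | generations flying in a long Mediterranean season |
| `max_gap` | days | 3 | longest weather gap filled by linear interpolation; longer gaps abort because daily DD errors compound over generations |
| `smooth_window` | weeks | 3 | centred moving average before peak/minimum detection; approximates the visual smoothing of weekly mean curves |
| `min_prominence_frac` | – | 0.15 | topographic-prominence floor (fraction of the series maximum) that keeps bimodal sub-peaks within one flight from being read as separate generations |
| `dispersion` | – | 1.5 | negative-binomial size for weekly per-trap counts; emulates trap-to-trap heterogeneity visible in field SE bands |

## Flight segmentation

Weekly mean catches, re-keyed by cumulative DD at their check date (the
end of the exposure week — the only date the protocol records), are
smoothed and local maxima are kept if their topographic prominence
reaches the floor above. Between consecutive peaks the flight boundary is
the week of the minimum smoothed catch, ties resolved to the **earliest**
week for determinism. The first flight starts at the first week with a
nonzero raw catch and the last ends at the last such week.

Two conventions needed a decision the field description leaves open:

* **Boundary ownership.** The boundary week closes the earlier flight
  (its `end_week`); the later flight's `start_week` is the next check
  date. On the DD axis, however, both flights share the boundary's
  cumulative DD: `dd_end(k) = dd_start(k+1)`. The minimum is a time
  *point* separating flights; giving each flight a full week of thermal
  time around it would systematically shorten every duration by one
  week's DD (≈ 70–90 DD in summer, a 15% bias on a ~530 DD generation)
  and durations would no longer tile the season span.
* **Truncated edge flights.** A season that opens on an already-descending
  curve caught the tail of a flight whose start was missed (traps
  deployed late). Prominence-based peak detection can never flag an edge
  maximum, so the spec rule "first flight excluded when its start is
  unobserved" would be unreachable. `split_at_minima` therefore inserts a
  pseudo-peak at the opening week when the smoothed series starts
  descending (symmetrically at the closing week when it ends rising),
  splitting the truncated flight off instead of absorbing its neighbour.
  Completeness is then purely observational: a flight is `complete` when
  a zero-catch week brackets it on the relevant side, and only complete
  flights enter the duration table.

When overlap hides a minimum in one year, the same transition in the
other years of that area is used: years whose boundary count falls short
of the area maximum get the missing boundary imputed at the **median DD**
of that boundary (matched by rank, order-preserving minimum-cost
assignment) across the fully segmented years, re-split at the week whose
cumulative DD is nearest. Imputed boundaries are flagged; if no year
resolves a boundary the area is reported unresolved.

The resulting durations are **adult-to-adult** flight spans, compared —
as the field protocol does — against the model's **egg-to-egg** 535/595
DD. The package documents this stage mismatch and does not correct it.

## Statistics

* `anova_stepwise` fits all two-way interactions among the requested
  factors, then removes the least significant term (marginal F test via
  `drop1`, interactions always eligible before their main effects) while
  $p \ge 0.05$, refitting each time. The final table reports sequential
  type-I sums of squares, the behaviour of `aov`; with unbalanced field
  designs term order matters and is the order given. Factors nested in
  one another (area within province) are partially confounded; fully
  aliased terms are dropped with a warning by default, or raise a
  diagnostic error naming them with `on_alias = "error"`.
* `tukey_by_province` uses the studentized range with Tukey–Kramer
  standard errors for unequal group sizes, so for two groups it reduces
  exactly to the pooled t-test. The compact letter display is a
  deterministic greedy insert–absorb pass over the significance matrix.
* `jackknife_se` is the textbook leave-one-out estimator; for the mean it
  equals $s/\sqrt{n}$ identically, which the tests assert to machine
  precision — the identity is the oracle, not a tolerance.

## The synthetic generator

The generator exists so every pipeline stage has ground truth. Weather is
a cosine seasonal cycle (minimum 15 January) plus independent Gaussian
noise on tmin and tmax (1.5 °C, a typical synoptic day-to-day
variability), with inverted pairs redrawn. The two presets were
calibrated **analytically, before any testing**: the diurnal range is the
difference of the published March–September mean daily maximum and
minimum for a representative humid-coastal and a dry-continental area
(12.11 and 16.68 °C), and the annual mean solves for the March–September
mean given an 8 °C annual half-amplitude chosen a priori. This yields
≈ 2 970 (girona-like) and ≈ 3 480 (lleida-like) DD per year, enough for
4 and 5 generations respectively.

Emergence kernels are Gaussians **on the DD axis** — encoding the premise
that development is temperature-driven, and making true durations exact
in DD. Expected weekly catch per trap is the kernel mass in the week's DD
interval times the generation's abundance; per-trap counts are negative
binomial. True boundaries are the minima of the mixture intensity between
consecutive centers (season edges mirrored so the outer generations also
have durations). The presets follow the field phenomenology: second
generation less abundant than the first, abundance rising from the third;
peaks under ~10 moths/trap/week in the low-density 4-generation preset
(spacing 626 DD) and up to ~50 in the 5-generation one (spacing 528 DD).

What it does **not** emulate: autocorrelated weather and heat waves,
diapause induction/termination, mortality or control interventions,
lure aging, trap placement effects, and mid-season trap entry/exit. A
green recovery test therefore establishes that the segmentation logic
recovers known structure under realistic counting noise — not that it
would segment any field season correctly.

## Numerical choices and degenerate inputs

Tiny negative round-off in the sine closed form is clamped to zero and
values capped at $T_U - T_L$. `date_at_dd` returns the *first* date
reaching the target and errors (a typed condition) when a year never
reaches it; calendar projection marks such windows `unreached` instead of
failing the whole season. All-zero catch series yield no peaks, an
`unsplit` single segment, and an NA coverage score with a warning. Minima
ties go to the earliest week; plateau peaks report their first index.
Weather gaps longer than `max_gap` abort with the offending dates rather
than guessing. All file outputs are plain text and byte-deterministic for
fixed inputs and seeds; the pipeline writes a manifest with parameters
and input checksums.

## Known limitations

The biofix/first-catch discrepancy (126 vs ≈160 DD) is exposed, not
resolved. The model's constants are not re-estimated from data — the
package evaluates the fixed offset model, it does not fit one. Flight
segmentation is a deterministic rule set, not a mixture or hidden-Markov
decomposition; heavily overlapping flights merge (by design this
degradation is monotone in kernel overlap and is itself tested).
Cross-year reconciliation assumes boundary ranks align across years,
which fails if a year genuinely has a different number of generations.
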