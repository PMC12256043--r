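---
title: "Methods and modelling choices in tpskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in tpskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpskit)
```

This vignette documents the models, default parameters, numerical choices
and known limitations behind each analysis stage, including how ambiguous
points in the source protocols were resolved.

## Thermal stability

### Model

A melt curve is modelled as a two-state unfolding transition on the
20–95 °C grid (1 °C steps, 76 points):

$$F(T) = a + b\,T + \frac{A}{1 + e^{(T_m - T)/s}} + c\,\max(T - T_m, 0)$$

with pre-transition baseline $a + bT$, transition amplitude $A$ and
steepness $s$, and a linear post-transition decay $c$ (dye dissociation
from the unfolded state). The synthetic generator (`gen_melt_curve()`) and
the Boltzmann estimator (`estimate_tm(method = "boltzmann")`) use this same
model, so noiseless round-trips are exact; defaults are amplitude 1000 AU,
baseline 500 AU, slopes +1.5 / −12 AU/°C, steepness 1.5 °C.

### Estimation

* **Derivative method**: the curve is smoothed with a Savitzky–Golay filter
  (order 2, window 5), differentiated by central differences, and the
  maximum of $dF/dT$ is taken over the rising phase only (indices up to the
  smoothed maximum), which keeps the post-transition decay from
  contaminating the estimate. Resolution is limited by the 1 °C grid.
* **Boltzmann method** (default): Levenberg–Marquardt least squares of the
  full model, initialised from the derivative estimate and a pre-transition
  line fit, with box constraints (amplitude ≥ 0, $T_m$ inside the recorded
  range, steepness in [0.1, 30]).

A transition is declared **absent** when the fitted amplitude does not
exceed `max(3 × fit RMSE, 5% of the fluorescence range)` — the absolute
floor handles noiseless flat curves where the RMSE criterion alone is
degenerate — or when the midpoint lands within 2 °C of either end of the
temperature range. Absent transitions propagate as `NA` melting
temperatures and are excluded from condition medians, with exclusion
counts reported by `rank_buffers()`.

### Screen conventions

The buffer screen is 8 buffer/pH systems (MES 5.5, Bis-Tris 6.0, HEPES
7.0/7.5, Tris 7.5/8.0/8.5, CAPS 9.0) at 200 mM crossed with one no-salt
condition plus NaCl/KCl/MgCl2 at 50/100/200 mM — 80 conditions. The
protocol text mentions a smaller condition count in passing, but the
enumerated composition implies 80; the enumeration is taken as canonical.
Thermal shifts are relative to a water control (reference $T_m$ 76.46 °C in
the reference panel; every panel row is consistent with this single
value), and "stabilising" means strictly greater than +4 °C.

## Steady-state kinetics

### Assay model

Endpoint malachite-green absorbance at 623 nm reads released phosphate.
With pyrophosphatase present, each turnover releases one PPi hydrolysed to
**two** Pi (`pi_per_turnover = 2`), so for incubation time $t$ (default
1800 s):

$$A = \beta_0 + \beta_1 \cdot \underbrace{2\,v(S)\,t}_{P_i\ (\mu M)}$$

`fit_standard_curve()` estimates $(\beta_0, \beta_1)$ from a 13-level
2-fold Pi series from 50 µM; `absorbance_to_rate()` inverts the line. The
plate's substrate-free background wells measure intercept-level signal, so
the processing step subtracts the *net* background (mean background minus
the fitted intercept) to avoid removing the intercept twice. Negative net
absorbances are floored at zero with a warning rather than producing
negative rates. Substrate series default: 13 two-fold dilutions from
100 µM.

### Fitting and reporting

`fit_michaelis_menten()` fits $v = V_{max} S/(K_m + S)$ by
Levenberg–Marquardt with tight tolerances (`ftol = ptol = 1e-12`),
initialised at $1.2\max(v)$ and the substrate level nearest half-maximal
rate, with positivity enforced by bounds. The test suite checks the
optimiser against an independent log-grid search oracle.

Two reporting conventions matter:

* **Effective enzyme concentration.** $k_{cat} = V_{max}/E_0$ with a
  default $E_0 = 10$ in $V_{max}$'s concentration unit. The assay
  protocol's nominal molar enzyme concentration does not reproduce the
  reference panel's published turnover numbers, whereas dividing the
  printed $V_{max}$ by 10 reproduces every row to the printed precision
  (one row excepted, see below); the divisor is therefore an explicit,
  configurable default rather than a hidden conversion. $V_{max}$ is
  treated as µM/s throughout.
* **Rounding.** Published-style values use half-away-from-zero rounding
  (`round_half_up()`), not R's round-half-even; e.g.
  `round_half_up(0.01895, 4)` is 0.019.

One reference-panel row (CsTPS19BL with FPP) prints a turnover number
(0.0011 s⁻¹) inconsistent with its own printed $V_{max}$ (0.0102 µM/s,
giving 0.0010 at 4 decimals under any rounding); the panel keeps the
printed value and the discrepancy is pinned in the test suite.

## Product profiles

Percent composition is computed over mono- and sesquiterpene peaks only:
the internal standard (isobutylbenzene) and non-terpene by-products
(e.g. geranyl methyl ether, pinene hydrate) are excluded from the
denominator and listed with reasons. Background correction against
boiled-enzyme controls removes a sample peak whose retention time matches
a control peak within 0.10 min when its area is at most **twice** the
control area, and otherwise subtracts the control area (floored at zero).
Compounds identified only by spectral-library match carry a `putative`
flag from the lexicon; `match_spectrum()` provides a transparent stand-in
score (1000 × squared cosine of square-root-scaled intensities).
Hedycaryol thermally degrades to elemol in the GC inlet; profiles can
report the artefact under its parent name via `alias_parent = TRUE`. One
reference profile sums to 98.66 as printed; simulation helpers renormalise
profiles to exactly 100 before generating peak tables, because the peak
generator requires a valid composition.

## Crystallisation screen design

### Parsing

Free-text conditions are split on semicolons and on commas **followed by
whitespace**, so chemical names containing commas ("PEG-3,350",
"2-methyl-2,4-pentanediol") survive. Fragments follow the grammar
`[number unit] chemical [(pH x)]` with units M, mM, % (w/v assumed when
unmarked — the mined records do not state it), case-insensitive synonym
normalisation against the lexicon, and role assignment
(buffer/salt/precipitant) from the lexicon with one override: ammonium
sulfate is a salt below 0.8 M and a precipitant at ≥ 0.8 M. Unparseable
fragments are retained with `role = "other"` and a warning; a condition
with no parseable fragment at all is an error. Empty strings are
unpublished records.

### Frequencies and selection

`frequency_stats()` uses category-specific denominators: buffer and pH
percentages are over records reporting them, salt and precipitant
percentages over records reporting at least one component of that
category, and the PEG-subtype breakdown is within PEG-containing records.
pH is binned by integer decade ("6.0–6.9").

`select_components()` encodes the published design rules: top-2 buffers by
usage; a six-step pH ladder in 0.5 increments anchored at the lower edge of
the modal pH bin, with consecutive triples assigned to the buffers in order
of their median observed pH (the published outcome — Bis-Tris 6.0/6.5/7.0,
Tris 7.5/8.0/8.5 — is also shipped verbatim as
`reference_screen_selection()`, since the exact pH levels were hand-chosen
in the source protocol); top-2 PEG subtypes; top-2 salts; concentration
ladder 5/15/25/35 % w/v. `generate_screen()` enumerates buffer-major, then
precipitant, then ascending concentration, every condition carrying 100 mM
buffer and 200 mM of both salts — 6 × 2 × 4 = 48 conditions. The source
ordering of the published screen is unknown, so specific conditions are
matched by composition, not index.

### Generator realism

`gen_condition_corpus()` samples buffer and pH-bin **jointly**: an
iterative-proportional-fitting step reconciles the two target marginals
with each buffer's plausible buffering range, so generated records never
put (say) CAPS at pH 5 and buffer-wise median pHs are realistic. Record
rendering perturbs case, synonyms and M/mM units to exercise the parser.
At corpus sizes near the reference (≈104 records) observed frequencies
deviate from targets by multinomial noise (up to ~10 percentage points);
the large-sample recovery property (n = 10,000 reproduces the reference
selection exactly) is part of the acceptance suite. The published corpus
itself is not listed in the source, so the frequency targets are
generative, not exact acceptance values.

## Determinism and problem sizes

All stochastic generators are seeded via `withr::with_seed` and record
their full parameter set plus seed in a `ground_truth` object;
`regenerate()` reproduces any dataset bit-identically, and
`derive_seeds()` expands a master seed into independent sub-seeds for
per-curve/per-plate simulation. Typical problem sizes: 76-point melt
curves × 81 screen curves; 13-level kinetics plates with 3 replicates
(~100 wells); peak tables of 5–15 peaks; corpora of 120 records
(reference) up to 10,000 (property tests), which parse in seconds thanks
to a vectorised fragment parser.

```{r example}
sim <- gen_melt_curve(tm_C = 83.18, noise_sd = 0)
estimate_tm(sim$curve)[, c("tm_C", "transition_detected")]
```
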