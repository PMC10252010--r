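---
title: "Zoometric characterization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zoometric characterization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoometry)
```

## The problem

Creole cattle of the Andean highlands survive at ~4000 m on natural
pasture and are considered at risk of absorption by exotic breeds.
Before any genetic program can target them, their phenotype has to be
characterized objectively: linear body measurements, the classical
zoometric indices derived from them, and a statement of productive
aptitude (dairy, beef, or dual purpose). This package implements that
characterization as a reusable workflow: a measurement schema and
interchange format, index computation, threshold-based aptitude
classification, descriptive and inferential statistics, and a synthetic
herd generator calibrated to a reference population of 95 animals in
three biotypes (Black 'Negro' n = 57, Colour-Sided 'Callejón' n = 20,
Brindle 'Atigrado' n = 18; 83 females, 12 males), so that every stage is
testable although the original per-animal records are not deposited.

## Measurements and indices

Seventeen traits are measured in centimetres (see
`measurement_schema()`). Nine indices are plain ratios times 100
(`compute_index()`); the anamorphosis index AI is quadratic in one
length:

$$\mathrm{AI} = \frac{\mathrm{TP}^2}{100\,\mathrm{HaW}}
             \quad(\text{lengths in cm}),$$

identically $\mathrm{TP}^2/\mathrm{HaW}$ with lengths in metres. The
historical formula is often written for centimetre inputs with a
$\times 100$ factor, which yields values near 25,000 — three orders of
magnitude away from the 2.5–3.0 dairy band the same literature quotes.
We therefore adopt the metre-consistent convention, which reproduces the
reference tables exactly (Brindle biotype:
`anamorphosis_index(177.29, 124.50)` = `r round_half_up(anamorphosis_index(177.29, 124.50), 2)`);
the literal form stays available via `literal = TRUE` for comparison
with sources that print the large convention.

Two conventions matter when reporting:

* **Mean of ratios, not ratio of means.** Population index means are
  means of per-animal indices. The two differ by a Jensen gap of order
  the squared trait CVs (here CVs are 3.6–11.3%, so gaps are a fraction
  of a percent — e.g. CEI of the mean animal is 46.41 while the
  population mean of CEI is 46.53). The gap shrinks as CVs shrink,
  which the test suite checks on simulated herds.
* **Rounding.** Reports round half away from zero to 2 decimals
  (`round_half_up()`), matching how zoometric tables are conventionally
  printed; all computation is at full precision.

A note on per-sex index tables: in the reference population the
published per-sex AI values (≈ 2.0 females / ≈ 1.45 males) cannot be
reconciled with the per-biotype AI values (≈ 2.5–2.65) under any single
unit convention, so the per-sex AI computation there is treated as
non-reproducible; the package computes per-sex summaries with the same
convention as everywhere else.

## Aptitude classification

Nine of the ten indices carry an aptitude signal; CEI is purely
descriptive (skull shape). The quantified rules from the zoometric
literature are hard defaults in `aptitude_thresholds()`:

* DTI: dairy strictly below 10, beef strictly above 11, dual between
  (both boundaries fall in the dual band — the inequalities are strict,
  so a population mean of exactly 11 is *not* beef);
* TPI and LPI: beef above 33;
* AI: dairy inside [2.5, 3.0], beef-leaning outside;
* CEI < 50 dolichocephalic; PI < 100 brachypelvic (beef-leaning: a
  longer, wider rump carries more meat).

TI, BI, DCI and LBI have no quantified cutoffs in that literature, only
comparative language ("the lower the TI, the more elliptical the
thorax", "brevilineal", "close to a rectangle"). Their defaults
(TI < 60 dairy, BI < 85 dairy, DCI ≥ 45 dairy, LBI < 90 beef-leaning
compact) were chosen once to reproduce the qualitative labels of the
reference population and are flagged `heuristic` in every report; all
are configurable.

The verdict is a majority vote. Each voter contributes its value-based
label; an index in the dual band votes with its traditional block
(dairy: TI, BI, AI, DTI, DCI; beef: LBI, PI, TPI, LPI — the block
membership is taken as given, not re-derived from values). Unanimity
gives a pure `DAIRY`/`BEEF`; any split gives a `DUAL_*_TENDENCY`; an
exact tie (impossible with nine voters, possible under reconfigured
blocks) gives `DUAL`. On the reference means the dairy block wins 5–4:
dual purpose with a dairy tendency.

```{r verdict}
ref <- c(CEI = 46.53, TI = 58.15, BI = 82.19, LBI = 85.47, AI = 2.55,
         PI = 95.85, DTI = 10.24, DCI = 46.7, TPI = 37.36, LPI = 38.99)
profile <- classify_indices(ref)
overall_verdict(profile)
```

## Inference

The reference analysis protocol fits `y = biotype + sex + biotype:sex`
per variable — nominally "one-way ANOVA" but written with two factors
and their interaction; we implement the two-factor model as written,
with a biotype-only one-way mode (`factor_b = NULL`). The design is
heavily unbalanced (57/20/18 biotypes, 83/12 sexes), which forces a
sums-of-squares choice the protocol never makes: the default is Type II
(each main effect adjusted for the other, interaction last), because it
is the most powerful correct test for main effects when the interaction
is negligible — which is the working assumption of a characterization
study; Type I and Type III (sum-to-zero contrasts) are available by
flag. The decomposition is computed by nested-model comparison on
`stats::lm` fits, and the test suite requires agreement to 1e-8 with an
independent reference implementation on random unbalanced designs.

Pairwise biotype comparisons use the Tukey–Kramer standard error
$\sqrt{\mathrm{MS}_{res}/2\,(1/n_i + 1/n_j)}$ and the studentized range
distribution (`stats::ptukey`), α = 0.05. Letters come from the
insert-and-absorb compact letter display, verified exhaustively for all
significance patterns up to k = 5: groups share a letter exactly when
not significantly different.

Pearson correlations use pairwise-complete observations and the
t-transform for p-values, without multiplicity correction by default —
the reference protocol reports per-pair significance levels with no
correction — with Holm/Bonferroni available. Assumption checks
(Shapiro–Wilk per group, Brown–Forsythe across groups) are advisory:
they are reported and logged, never gating.

## The synthetic herd generator

`default_herd_config()` *is* the study conditions: cell sizes 53/16/14
females and 4/4/4 males per biotype; per-biotype trait means and
per-trait CVs from `creole_calibration()`; a sparse correlation target
encoding the published qualitative structure (strong ≈ 0.7,
intermediate ≈ 0.5, strong negative −0.6 for HD–TD, a weak −0.3 for
ThL–IW which is reported only at p < 0.05, and an all-zero row for HW,
which showed no significant correlation with anything). Exact
correlation coefficients for the population are unpublished, so the
magnitudes are configuration, not constants.

Design choices, made once:

* **Within-biotype CV.** Only one pooled CV per trait is published; it
  is applied within biotype. This slightly overstates the pooled CV for
  traits whose biotype means separate — acceptable, and visible in the
  generated tables.
* **Sex effects default to 1.0.** Per-sex measurement means are not
  published (only per-sex indices, whose AI column is internally
  inconsistent, see above); a per-trait male multiplier exists for
  sensitivity analyses.
* **Gaussian with rejection, not log-normal.** CVs are ≤ 11.32%, so
  truncating at zero by redraw is negligible (the generator warns if
  the rejection rate exceeds 1%) and the configured means/SDs remain
  directly interpretable.
* **Tape precision.** Simulated lengths are recorded to 0.1 cm, the
  precision of a field tape measure; this also makes the CSV
  round-trip bit-exact.
* **PD repair.** The sign-pattern target need not be positive definite.
  `nearest_correlation()` implements Higham-style alternating
  projections (PSD cone with Dykstra correction ↔ unit-diagonal set),
  then floors eigenvalues at 1e-8 and rescales to unit diagonal. It is
  a fixed point on already-PD inputs and is cross-checked against an
  established PD-repair implementation in the tests. For the default
  target the repair moves entries by up to ≈ 0.3 (the verbal structure
  is mildly inconsistent); the signs of all strong pairs survive,
  which the tests assert on simulated draws.

What the generator emulates: first and second moments per biotype, the
qualitative correlation structure, the unbalanced group sizes. What it
does not: measurement error structure, age/parity covariates, any
sex dimorphism, non-Gaussian tails, and the exact correlation
coefficients. Tests passing on synthetic herds therefore validate the
*computational pipeline* under the published population structure, not
claims about real Creole cattle beyond that structure.

## Problem sizes and determinism

The test suite works at three scales, chosen as the smallest that make
each property visible: the original 95-animal structure for
structural/round-trip properties; 1,900–9,500 animals (20 replicates or
n-override 5,000) for calibration of means and correlations; and a
single 60,000-animal herd for end-to-end recovery of the ten reference
index means within 2% relative error, where the Jensen gap at the
calibration CVs is comfortably below the tolerance. All simulation is
seeded; `simulate_herd()` restores the caller's RNG state, and the same
seed yields byte-identical output files.

One calibration property deserves honesty: with the original sizes
(57/20/18) the rump-length Negro–Callejón contrast is borderline
detectable at α = 0.05 (that is what the reference tables show: it was
the significant one), and the Callejón–Atigrado contrast is not. These
relative detectabilities do not survive uniform scaling of the group
sizes — at tenfold sizes *every* nonzero contrast becomes significant
(the Callejón–Atigrado studentized range statistic reaches ≈ 8), so the
letter display collapses from a/b/ab to a/b/a. The suite checks the
pattern at the original sizes via replicate-median adjusted p-values.

## Known limitations

* Live weight is carried through the schema but neither simulated nor
  correlated (its correlation analysis in the reference work is in an
  unavailable online resource).
* The heuristic thresholds (TI, BI, DCI, LBI) are calibrated to one
  population; for other breeds they should be overridden rather than
  trusted.
* Type II SS is a default, not dogma; with a real interaction present,
  Type III with sum contrasts is the appropriate flag.
* The generator draws biotype means exactly at the calibration values;
  sampling variability of the reference study itself (its SEMs) is not
  propagated.
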