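---
title: "Classifying and quantifying supported lipid bilayer formation from QCM-D traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and quantifying supported lipid bilayer formation from QCM-D traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qslb)
library(dplyr)
```

## The measurement and the question

A quartz crystal microbalance with dissipation monitoring (QCM-D) tracks two
signals while lipid vesicles flow over a sensor crystal: the frequency shift
Δf, a proxy for mass coupled to the surface, and the dissipation shift ΔD, a
proxy for how viscoelastic that mass is. Both are measured at the odd
harmonics (3rd–11th) of the crystal's resonance. When unilamellar vesicles
meet a suitable surface, one of a small number of outcomes follows, each with
a characteristic Δf/ΔD signature:

* **Supported vesicle layer** — vesicles adsorb intact. A large frequency
  decrease (the film carries the vesicles' entrapped water), a large and
  persistent dissipation (ΔD well above 1×10⁻⁶), separated overtones, no
  recovery.
* **Two-step bilayer formation** — vesicles accumulate to a critical surface
  coverage and then rupture collectively. The frequency descends to a deep
  minimum (around −72 Hz for zwitterionic PC vesicles), then rises as water
  is released, stabilising near −26 Hz with ΔD relaxing below 1×10⁻⁶.
* **One-step bilayer formation** — vesicles rupture immediately on contact.
  Monotone approach to the bilayer plateau, no minimum, dissipation small
  throughout.
* **Incomplete bilayer** — a rigid but patchy film: the plateau is well short
  of the complete-bilayer value and the final buffer rinse removes lipid
  (frequency rises) while dissipation rises, consistent with defects opening
  up.

`qslb` turns this qualitative taxonomy into a tested decision procedure,
and carries the quantitative chain from the final frequency shift to the
molecular packing of the bilayer.

## Signature classification

`classify_signature()` works on the 3rd harmonic by default (the conventional
reporting harmonic; configurable via `signature_thresholds()`), after a
centred 5-sample moving average for noise-robust extremum detection. Its
descriptors:

* **plateaus** — means over the last minute before the rinse and the last
  minute of the record. The stabilised values these windows estimate are what
  experimentalists report; one minute of samples averages instrument noise
  without reaching back into the kinetic transient.
* **frequency minimum** — global minimum of the smoothed series, reported
  only when the subsequent recovery exceeds a prominence threshold (default
  10 Hz). This separates genuine rupture minima (recoveries of tens of Hz)
  from noise wiggles (sub-Hz).
* **initial slope** — least-squares slope of Δf from flow start to the
  minimum; steeper means faster vesicle attachment. Films with no minimum
  still get a slope: the window then ends where Δf first covers 90% of its
  final change. This surrogate endpoint is a package choice — attachment
  slopes are conventionally reported even for vesicle layers that never
  rupture, so some endpoint is required; 90% makes the window cover
  essentially the whole adsorption transient without being dominated by the
  plateau.
* **overtone spread** — max minus min of the window-averaged Δf across
  harmonics. Near zero for rigid uniform films, several Hz for hydrated
  vesicle layers.
* **rinse response** — change in plateau frequency and dissipation across the
  final buffer rinse.

The decision rules, in order: non-rigid film (ΔD_final ≥ 1×10⁻⁶) without a
prominent minimum is a vesicle layer; a prominent minimum recovering at least
10 Hz into a rigid film is a two-step bilayer; a rigid film without a minimum
whose final |Δf| falls in the 24–30 Hz bilayer band is a one-step bilayer; a
rigid film below the band whose rinse raises both frequency and dissipation
(thresholds 1 Hz and 0.1×10⁻⁶) is an incomplete bilayer; anything else is
indeterminate. When both the vesicle-layer and incomplete-bilayer patterns
could apply, the dissipation decides — above 1×10⁻⁶ means vesicle layer. The
band and thresholds are exemplar-derived defaults, not laws; all are exposed
in `signature_thresholds()`.

The rigid/viscoelastic boundary at ΔD < 1×10⁻⁶ is also the applicability
criterion of the Sauerbrey mass conversion: for strongly dissipating films
the frequency shift undercounts the coupled mass and a viscoelastic model
would be needed. This package deliberately stops at the Sauerbrey regime and
attaches a warning instead of modelling viscoelastic films (a known
limitation, see below).

```{r classify}
trace <- simulate_trace(slb_preset("PC"))
sig <- classify_signature(trace)
glance(sig)
```

## The phase-plane reading

`phase_trajectory()` encodes the ΔD-versus-Δf diagnostic: with the frequency
axis reversed, movement east is mass gain, north is increasing
viscoelasticity. Vesicle adsorption runs north-east (mass plus trapped
water); rupture runs south-west (water loss, rigidification); direct bilayer
deposition runs mainly east. Increments are computed on the smoothed series
and labelled stationary inside a dead-band (defaults 0.1 Hz, 0.02×10⁻⁶ per
step) so that plateau jitter does not masquerade as process.

```{r phase}
phase_trajectory(trace) |>
  filter(direction != "stationary") |>
  count(direction)
```

## From frequency shift to packing geometry

For a rigid film the Sauerbrey relation gives the areal mass directly,
Δm = −C·Δf with C = 17.8 ng/cm²/Hz for a 5 MHz crystal. The chain to
molecular packing, implemented in `packing_from_frequency()`:

1. Δm = −C·Δf;
2. subtract the mass of the water layer trapped between bilayer and sensor —
   102 ng/cm² as estimated for PC bilayers on silica, assumed transferable to
   anionic bilayers (an assumption inherited from the experimental
   literature, exposed via `packing_config()` so it is auditable);
3. per-molecule mass M_L = mw̄/N_A, with the mixture-average molecular weight
   mw̄ = Σ xᵢ mwᵢ over mole fractions xᵢ;
4. total lipid surface density = corrected mass / M_L (1 cm² = 10¹⁴ nm²),
   halved to the per-leaflet density N_L;
5. area per lipid a_L = 1/N_L;
6. hydrophobic thickness h_L = 2 v̄_L / a_L, with the mixture-average tail
   volume v̄_L = Σ xᵢ v_L,ᵢ.

Tail volumes are per-species constants (PG 0.96, LPG 0.46, PC 0.96
nm³/molecule, averages over the constituent C16/C18 chains) and the averaging
is simple mole-fraction weighting — this is the convention under which the
published per-mixture tail volumes (0.91, 0.86, 0.81, 0.76 nm³ for 10–40%
LPG) are all reproduced exactly. All arithmetic is done at full precision;
`format_packing_table()` rounds only for display (M_L to 3 significant
figures, the rest to 2 decimals).

```{r packing}
packing_from_frequency(-25, lipid_mixture(c(PG = 0.9, LPG = 0.1))) |>
  as_tibble() |>
  mutate(across(-M_L, ~ round(.x, 2)))
```

Sanity anchors for the geometry: a complete fluid-phase bilayer has
a_L ≈ 0.7 nm² and a hydrophobic core ≈ 2.5–2.8 nm thick. A patchy film
averages its gaps into a_L, which is why an incomplete bilayer shows
a_L ≈ 1 nm² and an implausibly thin h_L — the package flags that case rather
than hiding it.

## What the synthetic generator emulates — and what it does not

`simulate_trace()` produces the four signature shapes with saturating
exponential kinetics: the measurements motivating this package show shapes,
plateaus and time scales but no functional form, and a saturating exponential
is the simplest curve with the right asymptotics for diffusion-limited
adsorption. The two-step scenario joins two phases at the minimum; its
descent uses a fixed shape constant 2/t_min (≈86% complete at the minimum) so
the descent is visibly exponential while its least-squares slope stays within
a few percent of the secant f_min/t_min. Per-harmonic curves are scaled
proportionally so final frequencies span `overtone_spread` Hz, anchored on
the 3rd harmonic; noise is i.i.d. Gaussian per sample, fully determined by an
integer seed.

The presets pin the generator to reported outcomes: PC (two-step, minimum
−72 Hz at ~2.5 min, ΔD peak 3.5×10⁻⁶, bilayer at −26 Hz / 0.6×10⁻⁶); PG
(vesicle layer, ~40 min approach to −52 Hz, ΔD 3.8×10⁻⁶, 6 Hz overtone
spread); PG with 10/20/30% LPG (one-step bilayers at −25/−27/−28 Hz, rates
set so the initial descent matches the reported attachment slopes of
−13.6/−11.8/−8.8 Hz/min); PG with 40% LPG (incomplete: −23 Hz before the
rinse, −18 Hz after, ΔD rising to 0.8×10⁻⁶). Default markers are flow start
at 5 min, rinse at 45 min, record to 55 min, sampled at 0.05 min.

What the generator does *not* emulate: drift and temperature artefacts;
correlated (1/f) noise; partially mixed outcomes (a bilayer with a
sub-population of unruptured vesicles); overtone-dependent dissipation
spread; the mechanistic physics of vesicle deformation and rupture. Passing
the closed-loop tests therefore shows that the decision rules read the
canonical shapes correctly at realistic noise, not that they are robust to
every artefact a real instrument produces.

## DLS distributions and vesicle stability

Dynamic light scattering measures intensity-weighted size distributions; for
Nᵢ spherical particles of diameter dᵢ the three bases are related by

%I = 100·Nᵢdᵢ⁶/ΣNᵢdᵢ⁶, %V = 100·Nᵢdᵢ³/ΣNᵢdᵢ³, %N = 100·Nᵢ/ΣNᵢ.

`convert_distribution()` implements this as written — discrete binned
weights, no bin-width correction, sphericity assumed, Rayleigh d⁶ weighting
for intensity (no Mie correction). Conversion between bases is an exact
bijection on positive distributions, which the tests exercise to 10⁻⁹.

`stability_assessment()` compares a time course of distributions against the
first time point: a primary-mode diameter shift beyond 25% or a new mode
(≥5% of mass, not within tolerance of any day-0 mode) flags aggregation —
thresholds are parameters, since the behaviour they detect (vesicle
preparations growing or aggregating within days) is described qualitatively
in the literature rather than with numeric cutoffs.

```{r dls}
d <- exp(seq(log(10), log(400), length.out = 50))
day0 <- size_distribution(d, dlnorm(d, log(45), 0.25), "intensity", timestamp = 0)
day1 <- size_distribution(d, dlnorm(d, log(90), 0.25), "intensity", timestamp = 1)
stability_assessment(list(day0, day1)) |> stability_verdict()
```

## Numerical choices and degenerate inputs

* Frequency columns are taken as overtone-normalised (Δf_n/n); raw inputs are
  divided by n at read time (`read_qcmd(..., normalized = FALSE)`). This is
  the convention under which a complete bilayer sits near −26 Hz on every
  harmonic.
* Dissipation is stored in units of 1×10⁻⁶ so printed thresholds read
  literally; time is in minutes throughout.
* The rigidity comparison is strict: ΔD = 1.0×10⁻⁶ exactly is *not* rigid.
* Avogadro's number enters as 6.02214×10²³ mol⁻¹; published per-molecule
  masses (e.g. 1.25×10⁻¹² ng at 754 g/mol) confirm that convention.
* A film whose Sauerbrey mass does not exceed the water-layer correction
  aborts the packing chain ("film lighter than the assumed water layer");
  in batch mode the row is flagged and the rest of the table computes.
* A flat trace yields slope 0 with a "no adsorption" warning rather than an
  error; a trace with no prominent minimum yields an *absent* minimum, which
  is a valid result, not a failure.
* Plateau windows that contain no samples produce NA descriptors rather than
  silently extending.
* Mode detection splits peak regions at the minima between adjacent local
  maxima and reports each region's mass; ties on plateau-shaped peaks resolve
  to the left-most bin of the plateau.

## Problem sizes used in the tests

The shipped suite generates traces at 0.05–0.2 min sampling over 55 minutes
(≈280–1100 samples per harmonic, five harmonics), runs 100 noisy replicates
for classifier accuracy, 50 seeds for slope-bias estimation, 1000 random
compositions for the packing identities, and a few thousand particles per
mode for DLS sampling checks. These sizes give comfortable statistical
margins for every assertion while keeping the whole suite under a minute.

## Known limitations

* No viscoelastic (Voigt-type) mass estimation: for films with ΔD ≥ 1×10⁻⁶
  the package computes the Sauerbrey chain only under an explicit warning
  that it underestimates coupled mass.
* The 102 ng/cm² water-layer correction is a transferred estimate for PC
  bilayers on silica; its use for anionic films is an assumption, not a
  validated fact.
* Δf/ΔD are surface averages; nothing here infers spatial homogeneity,
  defect maps, or vesicle counts.
* The signature taxonomy is a hard classification with an `indeterminate`
  escape hatch; genuinely mixed films will land there rather than being
  decomposed.
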