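---
title: "Annotating metalloforms of cysteine-rich proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating metalloforms of cysteine-rich proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalloMS)
```

# Scope and model

metalloMS annotates the *metalloform* landscape of a cysteine-rich
protein: the set of species distinguished by how many Cu(I), Zn(II) or
Cd(II) ions, NEM or IAM (carbamidomethyl) cysteine labels, and
intramolecular disulfides a molecule carries, observed as intact ions in
native electrospray MS and interrogated by top-down CID. The package
does mass bookkeeping and spectral inference only: it deliberately says
nothing about disulfide connectivity, metal-cluster structure, or
binding thermodynamics.

The chemistry model is a small set of adduct deltas applied to the
protein's elemental composition:

| adduct | formula delta | H displaced | Cys consumed |
|---|---|---|---|
| Cu(I) | +Cu | 1 | ≥ 1 (configurable) |
| Zn(II), Cd(II) | +Zn / +Cd | 2 | ≥ 1 (configurable) |
| NEM | +C₆H₇NO₂ | 0 | 1 |
| IAM (CAM) | +C₂H₃NO | 0 | 1 |
| disulfide (SS) | — | 2 | 2 |
| N-terminal acetyl | +C₂H₂O | 0 | 0 |

Charging is by proton addition: m/z = (M + z·1.007276)/z. The proton
mass is kept distinct from the hydrogen atom mass because metals
displace *atoms* from thiols while electrospray adds bare protons.

A candidate composition is admitted when the cysteine budget holds:

n(NEM) + n(IAM) + 2·n(SS) + c·(n(Cu)+n(Zn)+n(Cd)) ≤ n(Cys).

The per-metal minimum c defaults to 1, not 2: four-Cu(I) species are
observed carrying up to 13 NEM on a 20-Cys protein, which is
incompatible with strict two-coordinate bookkeeping once two disulfides
are present; bridging thiolates make 1 the safe lower bound. The
disulfide range for oxidized species defaults to 1–2, since one- and
two-disulfide populations coexist. Both are configurable in the
chemistry-model YAML.

# Isotope patterns and native annotation

Theoretical isotope patterns are built by per-element convolution of a
vendored isotope table (IUPAC/NIST snapshot; no network access), using
exponentiation-by-squaring per element, pruning below 10⁻⁶ relative
abundance, and aggregating fine structure within 0.2 Da by
abundance-weighted means. Native-MS peak widths (resolving power ~10⁴ at
m/z ~1500, i.e. ~0.15 m/z FWHM) dominate isotopologue splittings of a
few mDa, so aggregated isotopologues lose nothing for fitting while
keeping pattern sizes tens of entries rather than millions.
"Monoisotopic" reporting uses each element's *most abundant* isotope by
default — for Cd the lightest isotope (¹⁰⁶Cd, 1.25%) is rare and would
be a misleading reference point; fitting always uses full patterns, so
the convention affects reported single masses only.

A theoretical profile renders each charged isotopologue as a Gaussian of
FWHM = (m/z)/R on a grid of FWHM/8 spacing. Observed envelopes are
scored by cosine similarity on resolution-matched profiles, which is
scale-invariant and needs no intensity calibration. The fit-quality
metric is a design choice of this package (the procedure it implements
specifies only "optimal fit"); cosine on matched profiles is the
standard choice and, unlike apex-mass matching, uses the whole envelope
shape. Candidates whose m/z fall within one linkage window (default
3 m/z at 5+) form an isobaric group and are deconvolved *jointly* by
non-negative least squares on the profile grid, so overlapping series —
the NEM(x)IAM(y) / NEM(x+1)IAM(y−2) / NEM(x+2)IAM(y−4) triads spaced
11.0045/z apart, or Cu₄Zn₄(ox) vs Cu₄NEM₂(ox) near 1486 m/z at 5+ — get
non-negative abundances rather than winner-takes-all assignments.
Assignments below `min_score` (default 0.7) are dropped; surviving
near-isobaric sets share a `group_id`. Equal scores break by parsimony:
fewer total adducts, then fewer metals.

# Top-down fragments, localization, reconstruction

Fragment arithmetic uses the standard conventions: the bᵢ neutral is the
sum of residues 1..i (plus the N-terminal acetyl where present); the yⱼ
neutral adds one water. Adducts partition between bᵢ and yₙ₋ᵢ subject to
both sides' cysteine budgets; metals may sit on either side — no domain
assumption is imposed, the data decide. Disulfides stay at parent level
by default because their connectivity is generally unknown, so a
complementary pair satisfies bᵢ + yₙ₋ᵢ = M(parent) + 2·n(SS)·m(H); the
reconstruction API therefore takes the disulfide count as an argument
rather than inferring it. Matching uses 20 ppm by default (a
conventional fragment tolerance for this instrument class), with an
absolute-m/z mode for poorly calibrated native top-down data; each peak
gets at most one candidate, ties broken by |error| then parsimony.

Label localization walks each ladder (b ascending; y mirrored) per label
type. Between consecutive informative fragments, a label-count increment
equal to the number of cysteines in the bracketed interval places the
labels; a smaller increment leaves those cysteines undetermined; a
decrement flags a conflict. The b and y walks are combined
conservatively: any disagreement yields "undetermined". Localization is
order-invariant in the annotation list. Residue numbering counts the
initiator Met of the supplied sequence (so the first β-domain cysteines
of MT3 are Cys6/Cys8); because the Met-exclusive convention (Cys5/Cys7)
also circulates, the output reports both numberings rather than guessing
which one a collaborator uses.

# Survival yield and spectrum comparison

Survival yield at each collision voltage is the precursor-window
intensity divided by the total detected ion intensity of that spectrum
(precursor plus fragments). The exact denominator convention varies
between laboratories; an alternative denominator (the lowest-voltage
precursor intensity) is available as a flag. Voltages convert to the
center-of-mass energy axis E_com = z·V·m_gas/(m_gas + M_ion), argon by
default, which puts ions of different mass and charge on a common scale.
The SY decline is fit with a logistic SY(E) = 1/(1+exp((E−E50)/k)) by
Levenberg–Marquardt least squares, initialized from the empirical 50%
crossing; the sigmoid form is a package choice following common SY
practice. A curve that never crosses 50% (flat, or truncated before the
decline) is refused rather than extrapolated silently; an E50 outside
the scanned range is flagged `extrapolated`.

Spectrum comparison aligns centroided peaks across spectra by
single-linkage gap clustering at `match_tol` (default 0.05 m/z) into a
union peak table; absent peaks are imputed as zero intensity (documented
behavior: this deflates correlations between spectra of very different
peak counts, which is the desired sensitivity). Pearson correlations on
that table give a symmetric, unit-diagonal matrix; the shared-ion
analysis reports per-spectrum peak counts, pairwise shared percentages
(of the pair's union), the fraction common to all spectra, and the full
membership-pattern table for UpSet-style plotting.

# The simulator and what passing tests mean

`simulate_native()` sums theoretical profiles scaled by specified
abundances and adds a baseline plus seeded Gaussian noise
(σ = max/SNR); `simulate_fragments()` emits centroid peaks at
theoretical fragment m/z with uniform ppm jitter and exponentially
decaying intensities; `simulate_sy_series()` splits a two-peak spectrum
by the logistic SY at each voltage. Defaults emulate the study
conditions: a 68-residue, 20-Cys protein at 4+/5+, resolving power
10,000, SNR 20 for single-species recovery and SNR 50 for mixture
deconvolution, 1 ppm fragment mass error, seed 1234.

The simulator reproduces isotope envelopes, noise and mass error — it
does not emulate electrospray charge-state distributions, adduction
(Na/K), detector saturation, chemical noise, or co-isolated
interferences. Recovery results on simulated data therefore demonstrate
the correctness of the inference machinery under its own forward model,
not instrument-grade performance; on real spectra the centroider's
robust noise floor (1.4826·MAD of the sub-median intensities, SNR ≥ 3)
and the `min_score` threshold carry more of the burden.

Problem sizes used by the test suite and acceptance script — 200
single-species recovery simulations, a 3-species NNLS mixture, 100 noisy
SY series — were chosen as the smallest sets that give stable (±1–2%)
statistics across seeds.

# Numerical choices and limitations

* Pattern pruning 10⁻⁶ relative abundance; fine-structure merge width
  0.2 Da; both configurable per call.
* NNLS (Lawson–Hanson via pracma) guarantees non-negative abundances;
  collinearity between candidates closer than ~0.2 m/z at 5+ inflates
  abundance variance even when scores stay high — the `group_id` is the
  signal to trust stoichiometry only after CID follow-up.
* The SY logistic fit bounds k ≥ 10⁻⁹ to keep the Jacobian finite on
  near-step curves.
* Candidate enumeration is a filtered Cartesian product in lexicographic
  order; for very wide ranges (all six adducts 0–20) the space grows
  combinatorially and should be narrowed by charge-state and m/z window
  first.
* ETD-type c/z fragments, internal fragments, ion mobility and
  intensity-based occupancy fractions are out of scope.
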