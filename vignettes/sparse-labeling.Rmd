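---
title: "Measuring sparse 15N/13C label incorporation in peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sparse 15N/13C label incorporation in peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isosparse)
```

## The measurement problem

Sparsely labeled proteins carry ¹⁵N and/or ¹³C only in selected amino
acids. The percent incorporation of each label — the fraction of the
peptide population carrying a given set of heavy atoms — determines NMR
signal intensity and must be measured per labeling state. Because the
mass shifts are small (1–6 Da) the isotope envelopes of unlabeled,
intermediately labeled and fully labeled peptides overlap, and metabolic
scrambling (α-amino ¹⁵N exchange, Ser↔Gly interconversion, ¹⁵N uptake
into off-target residues such as Ala) populates states the labeling
medium never contained. `isosparse` therefore (i) simulates the isotope
pattern of every reachable labeling state, (ii) fits a linear
combination of those patterns to the observed envelope, and (iii)
resolves isobaric states by mass defect or isotopic fine structure.

## Pattern simulation

### Pseudo-element augmentation

An enforced label is modeled by editing the elemental composition: one
¹³C label moves one atom from `C` to the single-isotope pseudo-element
`C13label` (mass 13.0033548 Da, abundance 1), and likewise `N15label`
(15.0001089 Da). Convolving with a single-isotope distribution is a pure
mass shift, so the pattern of a labeled peptide is the natural-abundance
pattern of the *remaining* atoms rigidly shifted — exactly the physics of
an enforced label, and it makes atom conservation
(`C + C13label = const`) a checkable invariant.

The bundled isotope table uses IUPAC 2013 representative masses and
abundances for C, H, N, O, S (e.g. ¹²C 12/0.9893, ¹³C 13.0033548/0.0107,
¹⁴N 14.0030740/0.99636, ¹⁵N 15.0001089/0.00364). Values are fixed in the
package so all simulations are bit-stable; swapping in another table only
moves third-decimal abundances.

### Convolution, FFT and the oracle

The reference path computes an exact multinomial distribution over
isotopologue compositions per element (heavy-isotope counts capped at a
1e-12 binomial tail) and convolves across elements with pruning. The
alternative `method = "fft"` evaluates the neutron-count generating
function on the unit circle and inverts it with an FFT — the classic
Fourier formulation of isotope pattern synthesis — together with a mass
moment transform that recovers per-peak centroid masses. Both paths
agree within 1e-6 in abundance; a third, deliberately naive per-atom
sequential convolution (`brute_force_pattern()`, guarded at 300 atoms)
serves as the independent test oracle and never backs any user-facing
computation.

Modes: `"nominal"` aggregates centroids by integer added-neutron count
and reports the abundance-weighted mean mass — matching what a centroid
algorithm reports for unresolved fine structure; `"fine"` keeps each
isotopologue composition distinct. Defaults: pruning 1e-5 (nominal) and
1e-8 (fine); abundances renormalize to 1 after pruning.

### Profile rendering

`render_profile()` places a Gaussian at each centroid's m/z
(`(mass + z·1.00727646)/z`), area proportional to abundance, width set by
`fwhm`. Grid densities of 1000 points/Da suffice at unit resolution;
fine structure needs 10000 points/Da, and the renderer warns whenever
fewer than 4 grid points span the fwhm, the regime where peaks degrade
into triangles. Rendering is linear in the pattern abundances, which the
fitter relies on.

## Labeling states

A `label_scheme` maps each residue to its label content partitioned into
*removal units* — blocks scrambling can omit independently. Val under
the VIL scheme has units `[1, 5]`: the α-amino ¹⁵N can be lost on its
own, while the five ring carbons come all-or-none as a ¹³C₅ block.
Enumeration takes every subset of unit inclusions over all labeled
residues and keeps the distinct (total ¹⁵N, total ¹³C) pairs: positional
isomers are isobaric in MS1, so totals are the only identifiable
quantity. For a peptide with 4 Val, 3 Leu and 1 Ile this yields
(8 + 1) × (4 + 1) = 45 states spanning 0–28 added labels; note that a
per-residue-assignment model would count differently (e.g. AAAVVVAAA has
14 intermediate (¹⁵N, ¹³C)-total states, not 12 as a per-residue count
might suggest). Scrambling into residues the scheme does not cover
(¹⁵N-Ala, [¹⁵N,¹³C₂]-Ser) is never inferred automatically: extra states
are explicit user configuration (`extras`), mirroring the manual review
step such data demand.

Two KGS-specific choices: Lys is supplied with α- and ε-amino ¹⁵N, but
the ε nitrogen exchanges essentially quantitatively with unlabeled
glutamate amino groups during expression, so `kgs_scheme()` defaults to
one retained ¹⁵N with `lys_n15 = 2` available; Gly's unit interval is
`[1, 2]`.

## Fitting

### Two states

`fit_two_state()` scans B over 0…100% (step 0.1%), builds
`(1-B/100)·U + (B/100)·L`, scales it to the data by least squares (the
observation's intensity units are arbitrary) and picks the B minimizing
RMSE, first occurrence winning ties.

### Many states

`fit_multi_state()` is the workhorse. Choices that the data do not pin
down, and how they were made:

* **Nearest-neighbor peak**: the observed local maximum closest in m/z to
  the state's monoisotopic position, required within
  `max(0.5·fwhm, 5 ppm)`; beyond that the state's weight is 0 and a
  diagnostic is recorded. When a window has no interior maximum the most
  intense point is used.
* **Presence of the lowest state**: an observed peak at least 3× the
  window's median absolute intensity (a cheap noise-floor estimate);
  configurable via `presence_snr`.
* **Coefficient raising**: solved analytically,
  `c_i = max(0, (I_obs − I_model)/p_i(mono_i))`, equivalent to the
  iterative raise but deterministic.
* **Fit window**: 2·fwhm below the lightest monoisotopic peak to 2·fwhm
  above the heaviest simulated centroid.
* **Isobaric ties**: `tie = "first"` (default) fits the first state at
  each neutron count and skips the rest with a diagnostic — the automated
  behavior appropriate for unit-resolution data. `tie = "all"` fits every
  state at its own exact monoisotopic m/z and is the right mode for
  fine-structure spectra, where the 6.3 mDa per ¹⁵N↔¹³C swap is resolved.
* Weights are the normalized coefficients (each pattern has unit total
  abundance, so coefficients are proportional to molar amounts); they
  always sum to 100.

On noiseless synthetic mixtures the greedy procedure is exact up to grid
discretization because each state's monoisotopic position receives no
intensity from heavier states; the residual at that position therefore
determines the coefficient uniquely. It is *not* a least-squares
estimator: with noise it reads single grid intensities, which is why the
recovery suite quotes median ~0.3 and max ~2–3 points at 1%-of-max noise
rather than the sub-0.1-point accuracy NNLS would give. The greedy
procedure is the contract here; a joint fit would silently reassign
intensity between isobaric states and hide exactly the ambiguities this
workflow is supposed to surface.

### Fine structure and mass defect

The identical fitting code serves fine-structure data: simulate with
`mode = "fine"`, render at 10000 points/Da, measure the fwhm from the
data (`measure_fwhm()`, linear-interpolated half-height width). For
unit-resolution spectra with isobaric candidates,
`mass_defect_discriminate()` refits with each candidate, takes the
centroid of the contested isotope peak in the combined model (points
above 5% of the window maximum) and compares it with the observed apex
after `calibrate_single_point()` (multiplicative single-point
recalibration). Swapping [¹⁵N₃] for [¹⁵N,¹³C₂] moves the model centroid
by ~0.0126 Da; at sub-ppm calibration the generating candidate scores the
smaller |ppm| error by an order of magnitude.

## Fragments and fingerprinting

PMF searches only the unlabeled and fully labeled monoisotopic m/z per
peptide and charge — intermediate states are the fitter's job, not the
search's. b/y chemistry follows the standard CID conventions,
`b = (Σ residues + z·p)/z`, `y = (Σ residues + H₂O + z·p)/z`, pinned by
two exact invariants tested across the whole GFP-CD16a digest:
complementarity `m(bᵢ) + m(yₙ₋ᵢ) = M + 2p`, and label conservation
`labels(bᵢ) + labels(yₙ₋ᵢ) = labels(peptide)`. ETD/ECD/UVPD series and
fitting label mixtures on fragment envelopes are out of scope.

Tryptic digestion cleaves after K/R except before Pro; the default of
one missed cleavage reflects real selective-labeling digests, where
peptides like TISFKDDGTYK (internal Lys) are routine analytes.

## The synthetic generator

No public raw spectra accompany this problem, so `generate_spectrum()`
stands in: Gaussian peaks at `fwhm = m/z / R` (R defaults: 80,000 for
unit resolution, 1,400,000 for fine structure, typical FTICR settings),
known mixing weights, additive white Gaussian noise (σ as a fraction of
the maximum), optional constant baseline, fixed seed (bit-exact,
RNG-stream neutral). What it does **not** emulate: magnitude/absorption
mode lineshapes, apodization and FT abundance distortion, multiplicative
(shot-type) noise, space-charge frequency shifts, ion-count
undersampling of the isotope distribution, and chromatographic time
structure. A green recovery test therefore establishes correctness of
the fitting machinery under the stated noise model — not robustness to
every FTICR artifact; on real spectra the dominant extra error sources
are low ion statistics and fine-structure abundance distortion.

`recovery_suite()` draws random weights over a panel of labeled tryptic
peptides (VIL and KGS) whose state sets are collision-free, at noise 0
and 1% of max: noiseless recovery is required < 0.5 percentage points
(max over 200 trials), noisy median < 1 point.

## Numerical choices

| quantity | value | note |
|---|---|---|
| proton mass | 1.00727646 Da | charge conversion |
| ¹³C shift | 1.0033548 Da | 13.0033548 − 12 |
| ¹⁵N shift | 0.9970349 Da | 15.0001089 − 14.0030740 |
| prune, nominal / fine | 1e-5 / 1e-8 | abundances renormalized after |
| points/Da, nominal / fine | 1000 / 10000 | ≥ 4 points per fwhm enforced |
| two-state grid step | 0.1% | first occurrence wins ties |
| match window | max(0.5·fwhm, 5 ppm) | nearest local maximum |
| presence threshold | 3 × median abs intensity | lowest-state detection |

## Known limitations

* The greedy fitter reads intensities at single monoisotopic positions;
  heavy spectral overlap combined with strong noise degrades it faster
  than a least-squares fit would.
* Mass-defect discrimination needs sub-ppm calibration and adequate
  resolving power; at low resolution the candidates' model centroids
  converge and the comparison becomes indeterminate.
* `tie = "first"` deliberately ignores later isobaric states; their
  weight is reported as 0 with a diagnostic, not redistributed.
* Spectra are fit as-is: no baseline subtraction beyond the optional
  constant the generator adds, no peak-shape model other than Gaussian.
* Compositions are limited to C/H/N/O/S plus the label pseudo-elements —
  glycopeptides and most PTMs need the `fixed_mods` hook and are
  untested territory.
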