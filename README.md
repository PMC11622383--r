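# isosparse

Quantifying selective (sparse) ¹⁵N/¹³C isotope enrichment in peptides by
mass spectrometry.

## The problem

Sparse isotope labeling enriches only selected amino acids of a protein
with ¹⁵N and/or ¹³C — the standard route to heteronuclear NMR of
glycoproteins that must be expressed in mammalian cells, where uniform
labeling is impractical. NMR signal scales with the enrichment level, so
the *percent incorporation* of each label must be measured, and MS of
tryptic peptides is the natural readout. Two things make this hard:

1. With only one or a few heavy atoms per peptide, the isotope envelopes
   of the unlabeled, intermediately labeled and fully labeled forms
   overlap, so monoisotopic peak ratios are useless.
2. Host-cell metabolism *scrambles* labels (loss of α-amino ¹⁵N,
   Ser↔Gly interconversion, ¹⁵N appearing in off-target residues),
   creating many partially labeled states that all contribute to the
   observed envelope.

`isosparse` addresses both: it simulates isotope patterns of selectively
labeled peptides (down to isotopic fine structure), enumerates every
intermediate labeling state a labeling scheme can reach, fits a linear
combination of the simulated patterns to the observed spectrum, and
localizes labels with label-aware peptide-mass-fingerprint and b/y
fragment matching.

## The model

A heavy label is treated as its own single-isotope *pseudo-element*: to
place one enforced ¹³C, the elemental formula vector **M** loses one C and
gains one `C13label`, and the isotope mass table **A** and abundance table
**B** gain a row with mass 13.00335 Da at 100% abundance (likewise ¹⁵N at
15.00011 Da). The isotope distribution of the edited formula is then
computed by per-element multinomial convolution (with an equivalent
FFT/generating-function path), either aggregated per added-neutron number
or resolved into fine structure.

For a peptide whose scheme allows labeling states s = 1…n with patterns
F(m)ₛ, the combined model is

    F(m)_c = A·F(m)_unlabeled + B·F(m)_1 + … + Z·F(m)_n

For a single label this reduces to the two-coefficient form
`F(m)_c = A·F(m)_unlabeled + B·F(m)_labeled`, A + B = 1, fit by RMSE over
a 0–100% grid. For many states the coefficients are assigned greedily:
the lowest-mass state present is scaled to its nearest-neighbor observed
peak, then each subsequent state's coefficient is raised until the
combined model matches the observed intensity at that state's
monoisotopic position; finally the coefficients are normalized to sum to
100 and reported as percent abundance per labeling state. States with
equal added-neutron count N are isobaric at unit resolution; they are
resolved either by the isotopic mass defect (¹⁵N adds 0.99703 Da per
label, ¹³C 1.00335 Da) or directly in fine-structure spectra.

## Worked example

Synthesize a noisy FTICR-like spectrum of the tryptic peptide EEDPIHLR
under the VIL scheme ([¹⁵N,¹³C₅]-Val, ¹⁵N-Ile, ¹⁵N-Leu) with known state
weights 40/42/18, then recover them:

```r
library(isosparse)

states <- enumerate_states("EEDPIHLR", vil_scheme())
states
#> <state_set> EEDPIHLR - 3 states
#>  n15N n13C descriptor extra neutrons
#>     0    0  unlabeled FALSE        0
#>     1    0      [15N] FALSE        1
#>     2    0     [15N2] FALSE        2

sp  <- synth_spec("EEDPIHLR", vil_scheme(), weights = c(40, 42, 18),
                  resolving_power = 80000, noise_sd = 0.01, seed = 42)
g   <- generate_spectrum(sp)
fwhm <- measure_fwhm(g$spectrum, g$truth$mono_mz)   # 0.0125 m/z at R = 80k

pats <- lapply(seq_len(nrow(states)), function(i)
  simulate_pattern(labeled_composition("EEDPIHLR", states[i, ])))
fit_multi_state(g$spectrum, states, pats, charge = 1, fwhm = fwhm)
#> <fit_result> rmse = 0.17036  fwhm = 0.0125
#>  descriptor weight coefficient
#>   unlabeled  39.66   0.3950993
#>       [15N]  41.60   0.4143348
#>      [15N2]  18.74   0.1866821
```

The weights are percent abundances of each labeling state (sum = 100):
despite the three overlapping envelopes and 1% additive noise, the true
mixture 40/42/18 is recovered to a few tenths of a point. EEDPIHLR
carries one Ile and one Leu, so the `[15N]` weight is the fraction of the
peptide population with exactly one retained ¹⁵N and `[15N2]` the
fraction with both.

A command-line interface wraps the same pipeline:

```sh
exec/isosparse enumerate --sequence GEELFTGVVPILVELDGDVNGHK --scheme vil --out states.tsv
exec/isosparse synth --sequence EEDPIHLR --scheme vil --weights 40,42,18 --seed 4 --out spec.xy
exec/isosparse fit --spectrum spec.xy --sequence EEDPIHLR --scheme vil --out fit.json
```

## Scope notes

CID b/y fragments only (no ETD/ECD/UVPD series); targeted peptide lists,
not proteome-scale search; no mzML reader (centroid `.asc` masslists and
profile `.xy` traces are the supported inputs). See the methods vignette
(`vignettes/sparse-labeling.Rmd`) for the model assumptions, tunable
parameters and known limitations.
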