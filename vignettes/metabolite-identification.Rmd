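---
title: "Fragment-shift identification of sirolimus metabolites: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-shift identification of sirolimus metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsom)
```

## The problem

Sirolimus (rapamycin, SRL; C~51~H~79~NO~13~) is a macrolide mTOR inhibitor
metabolized mainly by CYP3A4 into O-demethylated and hydroxylated products.
Because almost no metabolite standards can be purchased, their structures
must be inferred from high-resolution MS/MS fragmentation patterns: a
metabolite's precursor shifts by the net mass of its modifications, and each
of its fragments shifts only if the modified carbon lies inside the part of
the molecule the fragment retains. `metsom` turns that argument into code:
a forward model from a modification hypothesis to an expected peak set, and
an inverse solver from an observed peak list to the site(s) of metabolism
(SOM), plus the downstream kinetics and site-energetics analyses used to
corroborate the assignments.

## Mass arithmetic

All ions are handled as singly charged cations. For a neutral formula $F$
and adduct $A^+$ (Na^+^ by default; H^+^, K^+^, NH~4~^+^ supported),

$$ m/z = M(F) + M(A) - m_e $$

with monoisotopic atomic masses frozen at 7 dp (C 12, H 1.0078250,
N 14.0030740, O 15.9949146, Na 22.9897693, K 38.9637069) and the electron
mass $m_e = 0.00054858$ Da subtracted. The correction matters at the
reported precision: the sodiated molecular ion computes to 936.5444 only
with it (936.5449 without).

Metabolic and fragmentation events are additive mass shifts, frozen at 6 dp:

| event | formula change | delta (Da) |
|---|---|---|
| O-demethylation | −CH~2~ | −14.015650 |
| hydroxylation | +O | +15.994915 |
| water loss | −H~2~O | −18.010565 |
| methanol loss | −CH~4~O | −32.026215 |

Mass agreement is scored as $|m_{obs} - m_{theo}|/m_{theo} \times 10^6$ ppm;
anything below 5.0 ppm is treated as confirmatory, which is the reference
convention for this instrument class. Internal math is full precision;
display rounding is half-up (4 dp for m/z, 1 dp for ppm), matching how the
reference tables are printed (base R's `round()` is half-to-even and would
print, e.g., an intrinsic clearance of 0.075 as 0.07).

## The fragment library

The packaged library (`srl_fragment_library()`) holds the 18 sodiated
α-cleavage fragments A–R, the molecular ion, and nine
hydroxylation-diagnostic ions. Each fragment carries

* a theoretical m/z,
* a *coverage set* of IUPAC carbon positions (1–52 plus the token `"pip"`
  for the piperidine ring C3–C6), and
* a parent link; the links form a tree rooted at the molecular ion, and a
  child's coverage is validated to be a subset of its parent's.

Two data choices deserve explanation:

**Reconstructed extra decimals.** The reference table prints fragment masses
at 4 dp. Shifting those rounded values cannot reproduce all the printed
metabolite-fragment masses at 4 dp (642.3249 − 14.015650 = 628.30925 rounds
half-up to 628.3093, while 628.3092 is printed). The library therefore
stores a few extra decimals for the anchor fragments K, C, D, G and O,
chosen inside the narrow windows that are *jointly* consistent with the
printed parent masses and all their printed shifted forms (593.3813,
628.3092, 331.1880, 630.3249, 612.3144, 457.2561). Loading validates every
stored mass against the printed table at 4 dp.

**Reconstructed coverage extents.** Only a handful of coverage facts are
fixed by the main text of the source study (fragment K spans C17–C49, C51,
C52 and excludes the C16 methoxy, C11/C12/C14 and the piperidine ring;
C and D cover C39 but not C27; D covers C49 but not C45/C46; G and O cover
C23/C24; Q covers the piperidine ring; the C12 diagnostics shift under
39-demethylation and 23/24-hydroxylation). The remaining extents are
synthetic reconstructions that satisfy every such anchor plus the tree
subset invariant; the solver is agnostic to the specific sets, and the
fixture file documents which entries are anchored and which are
reconstructed. One known print inconsistency is carried as a note: the
hydroxylated fragment O appears both as 457.2561 and 457.2556, and its
printed water-loss partner 439.2449 is consistent with neither (the stored
mass computes 439.2455); none of these is asserted. Similarly, the printed
Δppm of fragment O (0.5) disagrees with its own printed mass pair, which
gives 0.2 — the package reports the recomputed value.

## Forward model

`expected_peaks(lib, mods)` shifts each fragment by the summed deltas of
the modification entries whose site intersects its coverage. Candidate
pairs ({23,24}, {45,46}) are first-class sites: a pair shifts a fragment
iff it intersects the coverage. Two neutral-loss rules reproduce the
reported satellite behaviour:

* **R1** — a fragment shifted by a methyl-carbon hydroxylation (C45/C46)
  emits a methanol-loss satellite (−32.026215 Da), the signature of a
  hydroxylated methyl group;
* **R2** — a fragment shifted by a C23/C24 hydroxylation emits a water-loss
  satellite (−18.010565 Da) that is *expected to dominate* its parent
  peak's intensity.

Diagnostic ions (e.g. 723.4806 for 11-OH, 711.4442/389.2293/357.2031 for
12-OH, 336.1050 for the hydroxy-piperidine) are appended when their site is
hydroxylated, themselves shifted by any co-occurring modification inside
their coverage — this is how the doubly modified metabolites are
recognized (711.4442 → 697.4285 under additional 39-demethylation).

## Inverse solver

`localize()` first infers the *net* modification from the precursor: the
unique combination of at most two events from {−CH~2~, +O} whose summed
delta matches the precursor-minus-parent difference within tolerance (the
six possible net deltas are separated by ≥ 12 Da except for −CH~2~+O at
+1.98 Da, far beyond any ppm window, so the solution is always unique).
The hypothesis space is then all assignments of legal sites —
demethylation ⊂ {16, 27, 39}; hydroxylation ⊂ {11, 12, 14, {23,24}, 25,
{45,46}, 49, pip} — and evidence prunes it:

1. a fragment matched *unshifted* excludes every site in its coverage;
2. a fragment matched at a *shifted* position supports sites inside its
   coverage (for two same-type modifications, the number of shift units
   identifies how many of the two sites the fragment covers);
3. a matched diagnostic ion pins its site;
4. a methanol-loss satellite on a shifted fragment restricts the
   hydroxylation to {45,46} (R1);
5. a water-loss satellite exceeding its parent's intensity (threshold
   configurable, default 1.0×) restricts it to {23,24} (R2).

Candidate sets that evidence cannot split — {23,24}, {45,46}, and the
piperidine ring, where no fragmentation signature distinguishes C3–C6 —
are reported jointly with `ambiguous = TRUE`, exactly as the underlying
assignments are reported. Contradictory evidence yields a structured
`consistent = FALSE` report listing the conflicting items, never a silent
best guess.

**Isobaric-coincidence guard.** The library contains exact isobars
(P + O = L; R − CH~2~ = F; H − CH~4~O = N; B − CH~4~O within 0.1 ppm of A;
G + O − H~2~O within 1.7 ppm of the 14-diagnostic). A probe position —
fragment shift variant, diagnostic, or neutral-loss satellite — that falls
within tolerance of a *different* ion's expected position cannot be
attributed unambiguously and is never used as evidence. This keeps the
solver sound: over the exhaustive noise-free sweep of all 67 legal
hypotheses the true sites are never excluded, and every single-modification
truth resolves uniquely. The price is a known resolution limit: three
double-modification combinations (27-desmethyl + 14-OH, 39-desmethyl +
14-OH, 39-desmethyl + 49-OH) retain two to three candidate assignments
even from perfect data, because their distinguishing variants are isobaric
with other ions. None of the reported metabolites falls in this set.

## Synthetic data: what it emulates, and what it does not

No raw spectra are deposited with the source study, so all inputs are
simulated by the package itself (`simulate_spectrum()`,
`simulate_kinetics()`, `simulate_distance_traj()`; all seed-mandatory and
bit-reproducible).

* **Spectra.** Expected peaks perturbed by Gaussian mass error expressed in
  ppm (default σ = 2 ppm, consistent with the 0.0–3.5 ppm spread of the
  reference table), plus uniform decoy peaks kept ≥ 10 ppm away from every
  expected ion. The intensity model is deliberately crude — a uniform base
  (100), half-intensity methanol satellites, and water-loss satellites at
  1.5× base for C23/C24 truths — because the solver must not rely on
  intensities except for rule R2. Real QTOF spectra add co-eluting
  interferences, isotope envelopes, detector saturation and
  retention-time structure, none of which is modelled; passing tests
  demonstrate the *inference logic*, not robustness to instrument
  artefacts.
* **Kinetics.** Velocities on the reported substrate grid (3.25, 7.5, 15,
  30, 60, 90, 120 µM; quadruplicate) with multiplicative log-normal noise
  (default CV 10%), chosen over additive noise because velocities span an
  order of magnitude across the grid.
* **Trajectories.** Positive-truncated normal distances, a stand-in for MD
  frames that preserves exactly what the analysis consumes (an occupancy
  fraction and a median).

The 21 packaged per-metabolite MGF fixtures are generated this way
(σ = 1 ppm, 5 decoys, fixed seeds) from the reported metabolite list, with
the four chromatographically distinct hydroxy-piperidine isomers kept as
separate entries and both 45- and 46-hydroxy carried with the ambiguous
{45,46} truth, as the assignments themselves are pair-level.

## Kinetics

`fit_mm()` fits $v = V_{max} S / (K_m + S)$ by bounded Levenberg–Marquardt
least squares (`minpack.lm::nlsLM`), initialized at
$V_{max}^0 = \max v$, $K_m^0 =$ the concentration nearest half-maximal
mean velocity, with positivity bounds; unweighted by default with an
optional 1/v weighting. Intrinsic clearance is $CL_{int} = V_{max}/K_m$.
Confidence intervals are percentile bootstrap (default 1000 replicates,
explicit seed), case-resampling within each concentration to preserve the
design, with a residual-resampling fallback (and a warning) when any
concentration has fewer than two replicates.

The seven reported $V_{max}/K_m$ pairs reproduce their printed clearances
at printed precision (11-hydroxy 0.65, 23/24-hydroxy 0.11, ...). Their
full-precision sum is 2.33 µL/mg protein/min; summing the *rounded*
printed entries gives 2.36, and the source prints a total of 2.35. The
package reports full precision and does not assert the printed total.

Simulation sizes used in the shipped tests: 150–200 seeded datasets for
parameter recovery (median relative error of both parameters is well
under 10% at CV 10%), and 100 seeds × 200 bootstrap replicates for the
CI-coverage check (observed coverage ≈ 95%, asserted within 90–98%).

## Site energetics

`overall_dg()` composes the thermodynamic cycle
$\Delta G_{overall} = \Delta G_{demethylation} + \Delta G_{hydrogenation}$
per candidate site and `rank_sites_by_dg()` orders sites by it
(most favorable first): C16 (−24.05) before C39 (−21.89) before C27. The
C27 row is printed as −12.71 in the source while its terms sum to −12.70;
the package computes −12.70 and does not assert the printed value.

`proximity_rank()` reduces atom-to-heme-iron distance series to the
fraction of frames within a threshold (default 5 Å, the outer edge of the
catalytically competent range; configurable) plus the median distance, and
ranks by occupancy. This is deliberately ordinal — radial-distribution
estimation is out of scope — and is used only as soft evidence to annotate
a preferred member of an MS-ambiguous pair (C46 over C45, C23 over C24);
the MS-level report keeps the pair, separating spectral from simulation
evidence.

## Numerical and design choices

* Display rounding half-up with a 10^−6^ epsilon against binary
  representation noise on exact .5 ties (which occur: 593.38125).
* Matching tie-break: smallest |ppm|, then highest intensity;
  deterministic.
* Hypothesis space capped at two simultaneous modifications
  (second-generation metabolites); configurable constant in
  `legal_hypotheses()`.
* The 25-OH diagnostic at 443.2392 reported in the source is *not*
  packaged: it lies 2.7 ppm from the methanol-loss satellite position of
  fragment I under 25-hydroxylation and would be permanently
  isobar-guarded; the packaged 447.2718/327.1922 diagnostics carry the
  same information.
* The 27-O-desmethyl precursor appears once in the source as 922.5887;
  every other demethylated ion is 922.5287 and the package computes the
  latter (treated as a typo, flagged here rather than silently corrected).

## Known limitations

* Coverage sets outside the anchored facts are reconstructions; real
  appendix-level fragment assignments could differ in the unanchored
  regions without affecting the anchored behaviour.
* Stereochemistry, rotamers (the late-eluting 39-O-desmethyl peak),
  seco-type ring-opened degradation artifacts, charge states above 1,
  negative mode and isotope patterns are out of scope.
* Intensity information is used only by rule R2; quantitative metabolite
  abundance is not inferred.
* CYP-isoform attribution is not modelled; clearances are apparent values
  for pooled microsomes.
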