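---
title: "Designing MRM assays for native peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing MRM assays for native peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativemrm)
```

## The problem

Native (endogenous, non-tryptic) peptides in serum and other body fluids
carry physiological information, but quantifying them by multiple reaction
monitoring (MRM) is harder than for tryptic peptides. A tryptic peptide
ends in Arg or Lys, so its MRM transitions can be drawn almost exclusively
from singly charged y-ions of a doubly charged precursor. A native peptide
offers no such shortcut: precursor charges 2-4, both y- and b-series, and
fragment charges 1-2 all produce usable transitions, and which of them are
intense is peptide-specific. For a 15-16-residue peptide this means
hundreds of candidate transitions per analyte. The workflow implemented
here makes the problem tractable by building a library of identified MS/MS
spectra and ranking candidate transitions by observed fragment intensity,
so that only a handful of transitions per precursor need instrument
optimization.

## Mass arithmetic

All masses are monoisotopic. A peptide's neutral mass is the sum of its
residue masses plus one water; protonated species use
$m/z = (M + z \cdot m_p)/z$ with $m_p = 1.007276$ Da. Fragments follow the
usual b/y convention with 1-based indexing (y1 is the C-terminal residue):

$$b_k = \frac{\sum_{i=1}^{k} r_i + z\,m_p}{z}, \qquad
  y_k = \frac{\sum_{i=n-k+1}^{n} r_i + m_{H_2O} + z\,m_p}{z}$$

Stable-isotope label schemes add $n_{13C} \cdot 1.003355 +
n_{15N} \cdot 0.997035$ Da per labeled residue. A rule either targets every
residue of a given letter ("one ^13^C in each glycine") or a single
position ("^13^C~6~ ^15^N~1~ on the leucine at position 15"). A label or
modification contributes to a fragment exactly when its residue lies inside
the fragment's span; this is what makes some heavy-analog fragments
coincide with their light counterparts (a diagnostic worth checking when
choosing transitions, since such transitions cannot discriminate the
channels):

```{r}
p <- triplex_peptides()
co4_light <- peptide(p$CO4$sequence)
co4_heavy <- peptide(p$CO4$sequence, label = p$CO4$label)
# Leu10 sits outside y5 but inside y6:
c(y5_light = fragment_mz(co4_light, "y", 5, 1),
  y5_heavy = fragment_mz(co4_heavy, "y", 5, 1),
  y6_light = fragment_mz(co4_light, "y", 6, 1),
  y6_heavy = fragment_mz(co4_heavy, "y", 6, 1))
```

The proton mass (not the hydrogen-atom mass) is used throughout because it
reproduces the published transition tables for these peptides to the
printed 2 decimals; display rounding is half-even at 2 decimals and all
internal arithmetic keeps full precision. Every split point obeys
$b_k(1+) + y_{n-k}(1+) = M + 2 m_p$ to $10^{-6}$ Da
(`complementary_check()`), which the test suite exercises over a thousand
random peptides — with label schemes, the labels must partition between the
complementary fragments.

## Identification filtering and multi-level FDR

Search results enter as normalized records (a pepXML subset is read and
written). The library-inclusion filters are: confidence at least 0.95;
observed precursor neutral mass within 0.2 Da of the theoretical
monoisotopic mass, allowing the observed value to sit on the isotope
cluster peak one or two ^13^C up (offsets $\{0, 1, 2\}$ only — a
monoisotopic assignment is never *below* the true mass by a ^13^C spacing);
and no modifications other than oxidation (any position) and pyroglutamate
from N-terminal Glu or Gln (position 1 only, a constraint of the
chemistry). The tolerance applies to neutral mass, not m/z, and the
minimum over the isotope offsets is taken before comparing with the
tolerance. Rejections are labeled with the first failing rule in the fixed
order confidence, mass, modification.

FDR is re-estimated after filtering at three levels: spectrum (each
peptide-spectrum match), ion (distinct sequence, charge and modification
state — the "peptide ion" in the sense used by MRM design tools), and
peptide (distinct sequence). The estimator at each level is the plain
decoy/target count ratio, capped at 1; with zero targets the estimate is
undefined and flagged rather than reported as 0. When decoy hits are
low-multiplicity (each decoy sequence supported by few spectra) while true
identifications repeat, collapsing inflates the decoy fraction, so the
ordering spectrum $\le$ ion $\le$ peptide FDR is expected — the synthetic
generator reproduces this regime and the calibration of the estimator
against the realized false-discovery proportion is part of the acceptance
suite.

## Spectral library and representative spectra

Repeat identifications of the same peptide ion are clustered and a single
representative spectrum is kept: the spectrum with the highest mean
similarity to the other members of its cluster. Similarity is the cosine
of square-root-transformed intensities aggregated on 0.05 Th m/z bins —
symmetric, bounded in [0, 1] and invariant to uniform intensity scaling.
The square root damps the dominance of the base peak; 0.05 Th matches
QTOF centroid accuracy. Exact ties are broken by the lexicographically
smallest spectrum id so builds are deterministic. No consensus averaging
is performed: the library stores a measured spectrum, not a synthetic one,
and intensities are stored as measured without renormalization.

Libraries are written either as `.blib` (the SQLite-backed BiblioSpec
convention: `LibInfo`, `RefSpectra`, `RefSpectraPeaks`, peak arrays as
zlib-compressed little-endian double/float blobs, stored raw when
compression does not help) or as NIST-style `.msp` text. Round-trips
preserve entry keys, copy counts and peaks (m/z to 1e-4, intensity to 1e-3
relative).

## Transition enumeration and ranking

Candidates are the Cartesian product of precursor charges {2, 3, 4}, ion
series {y, b}, fragment indices and fragment charges {1, 2}, filtered by a
product-ion m/z window. Two defaults deserve explanation:

* **Product window 150-2000 Th.** The library spectra are acquired from
  m/z 150, so a fragment below 150 has no library evidence to rank on;
  2000 is the upper acquisition bound.
* **Minimum fragment length 2.** Single-residue b1/y1 ions are
  non-specific (shared by every peptide ending or starting in that
  residue) and b1 ions are rarely formed at all, so they are excluded from
  candidate panels by default.

Both are switchable (`enumeration_settings(min_index = 1, mz_min = 100)`),
and the window applies to product ions only — the precursors of interest
(m/z 467-736 here) are never filtered by it, though a switch exists. No
constraint ties fragment charge to precursor charge; for native peptides
doubly charged fragments of doubly charged precursors are legitimate
candidates. Under these defaults the three reference peptides yield 459
candidates, which is the design space the library ranking collapses:

```{r}
sum(sapply(triplex_peptides(), function(p)
  nrow(enumerate_candidates(peptide(p$sequence)))))
```

Ranking scores each candidate by the most intense library peak within
0.05 Th of its product m/z (zero if unmatched) and keeps the top n,
ties broken by ascending product m/z. Zero-score candidates are excluded
unless padding is explicitly requested: a transition with no library
evidence is not a ranked transition. Taking the five most intense
transitions for each of the four usable precursors (FIBA 2+, CO3 3+, CO3
4+, CO4 3+) leaves 20 transitions to optimize on the instrument. The final
assay keeps the three best optimized transitions per precursor for FIBA
and CO4 and the two best from each CO3 charge state
(see `triplex_panel()`); heavy-analog rows are generated by recomputing
m/z under the label scheme while copying fragment identity and instrument
parameters.

Collision energies and declustering potentials come either from the
shipped fixture of empirically optimized values (keyed by precursor m/z at
2 decimals and fragment label) or from a linear per-charge model
$CE = a_z \cdot m/z + b_z$ with constant per-charge DP — generic QTRAP
starting values, intended as a pre-optimization guess, never a substitute
for empirical optimization. A fixture miss falls back to the linear model
with a warning.

## Stable-isotope-dilution quantification

Peak areas are trapezoidal integrals over a retention-time window, with an
optional linear baseline between window endpoints, floored at zero.
Concentration follows from the light/heavy area ratio times the
internal-standard spike (500 fmol/ul serum for the FIBA and CO3 peptides,
50 fmol/ul for CO4 in the reference assay). Derived assay metrics are
simple ratio readouts: recovery is the percent change of the light/heavy
ratio through sample preparation; stability time courses are ratios
normalized to baseline; carry-over is the blank-to-preceding-sample area
percentage; cross-talk the counterpart-channel percentage under
single-form injection; interference checks use per-precursor normalized
areas (each transition's share of its precursor's summed area).

Dilution series are summarized by a least-squares fit of mean response
against nominal amount on the log10-log10 scale (series span orders of
magnitude; on the linear scale the top level would dominate the fit), the
per-level CV over replicates, and the LOQ defined as the lowest level
whose CV is at most 20% with all higher levels passing as well. The 20%
criterion is the conventional bioanalytical threshold; the threshold is a
parameter because no single rule is universal. Dynamic range is
log10(top level / LOQ). Group comparisons of measured concentrations wrap
`stats::kruskal.test` with a hand-computed Dunn's post test (standard
rank-based z statistics with tie correction, Bonferroni-adjusted by
default) — a convenience, not a contribution.

## The synthetic-data generators

Three generators provide ground-truth data for validation; all are
deterministic given an integer seed.

* **Identification sets.** Each match is correct with probability
  $1 - p_{false}$; correct matches draw confidence from Beta(20, 1), false
  matches from Beta(1, 20) (the defaults place false scores far below the
  0.95 cut; calibration tests use a heavier-tailed false distribution so
  the estimator is exercised in a non-trivial regime). A false match lands
  on a decoy or a target sequence with equal probability — exactly the
  assumption that makes decoy counts estimate false-target counts.
  Observed masses get Gaussian error (sigma 0.02 Da) plus +1/+2 ^13^C
  offsets with probabilities 0.2/0.1. Records violating the mass or
  modification rules can be planted in known numbers.
* **Replicate spectra.** Peaks sit at theoretical fragment m/z with
  log-normal base intensities biased by series: `y-dominant` mimics
  Arg/Lys-C-terminal peptides, `b2-dominant` the precursors whose intense
  fragments are doubly charged b-ions. Ordinary replicates carry 35%
  intensity CV, about six spurious noise peaks and 0.003 Th m/z jitter;
  the planted representative is generated at 2% CV with proportionally
  smaller jitter — this is what "one high-SNR spectrum among noisy
  replicates" means here. Optional outlier replicates get five-fold noise.
* **MRM chromatograms.** Gaussian elution peaks with SD 0.05 min on a
  20-min axis sampled every 0.01 min (retention times 9.78 / 9.61 / 9.32
  min for the three reference peptides); heavy areas proportional to the
  spike, light areas to the planted concentration; additive Gaussian noise
  scaled by peak height over SNR. Carry-over and cross-talk percentages
  can be planted and read back.

What the generators do *not* model: physically realistic fragmentation
propensities (intensities are statistical, not mechanistic), retention
drift and peak-shape asymmetry, inter-run alignment, matrix-dependent
ionization suppression, and correlated noise between channels. Passing
tests therefore demonstrate the correctness of the arithmetic, the
filtering logic, the selection and the estimators under the stated
statistical model — not instrument-level performance on real serum.

## Numerical choices and degenerate inputs

* Exact representative ties resolve by smallest spectrum id; ranking ties
  by ascending product m/z.
* FDR with zero targets at a level is `NA` plus a flag, never 0.
* Quantification with zero heavy area returns a failure flag, not a
  number; integration never returns negative areas.
* An empty record set builds an empty, writable library; empty candidate
  lists rank to empty selections.
* Test problem sizes are chosen for desk-scale validation: 1,000 random
  peptides for the complementarity property, 200 replicates of 400-match
  identification sets for FDR calibration, 100 seeded clusters/runs for
  representative selection, ranking and end-to-end quantification
  (the latter at SNR 50 against a 5% recovery bound).

## Known limitations

* The representative-spectrum criterion (binned cosine on square-root
  intensities) is a documented choice; other library builders use related
  but not identical measures, so representative choices may differ on the
  same data.
* The blib dialect covers the tables and columns this workflow needs;
  exotic fields of other producers (retention-time tables, ion-mobility
  columns) are ignored on read and absent on write.
* The `.blib` peptide-ion FDR, library counts and transition rankings are
  only as good as the identification input; the package consumes search
  output and does not re-score it.
* The CE/DP linear model is a starting point; published optimized values
  ship as a fixture for the three reference peptides only.
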