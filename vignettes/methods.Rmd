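---
title: "Methods: morph-specific protein profiling from 2-DE and MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morph-specific protein profiling from 2-DE and MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoproteo)
```

# The question and the evidence chain

Colour morphs of a polymorphic lizard are genetically determined, and
their femoral-gland secretions — a lipid/protein mix deposited on
substrates and read by tongue-flicking conspecifics — are a candidate
chemical channel for signalling morph identity. The analysis implemented
here asks whether the *protein* fraction differs between morphs, using
three mutually reinforcing lines of evidence:

1. **Spot maps.** Per-morph consensus 2-DE spot maps ("master gels")
   built from replicate gels are compared pairwise ("high master gels",
   HMG) and jointly ("combined high master gel", CHMG) to count
   morph-shared versus morph-unique protein spots.
2. **Peptide identification.** Morph-unique spots are digested with
   trypsin and their MS/MS spectra searched against a protein database
   with target–decoy FDR control, asking whether unique spots carry
   identifiable, morph-restricted peptides.
3. **Spectral distinctness.** Independently of identification, the
   spectrum *sets* of excised spots are compared by cosine distance:
   if unique spots truly hold different proteins, each spot's
   within-spot ("self") spectral dispersion must be smaller than its
   distance to any other spot, which an exact Wilcoxon signed-rank test
   formalizes.

The package implements all three stages plus a synthetic-data generator
that provides ground truth for calibration and testing.

# Gel stage

## Spot abstraction

Raster image processing (spot detection, streak filtering, Gaussian
modelling) is out of scope; the pipeline starts from *spot lists*: a
spot is a position in (pI, log₁₀ MW kDa) with a stain intensity. This is
the natural interface after any gel-analysis package has done the image
work.

## Matching and the master-gel rule

Two spots match when they fall in a tolerance box
(|ΔpI| ≤ `tol_pI`, |Δlog₁₀MW| ≤ `tol_logmw`); candidate pairs are
accepted greedily by increasing normalized Euclidean distance
`sqrt((ΔpI/tol_pI)² + (ΔlogMW/tol_logmw)²)`. Because the globally
closest remaining pair is automatically mutual-nearest, this greedy
order realizes mutual-nearest matching with deterministic tie-breaking
(distance, then lexicographic spot ids). Defaults `tol_pI = 0.1` pH
units and `tol_logmw = 0.02` were fixed once at about five standard
deviations of the generator's positional jitter — the commercial
software's parameters behind published gel analyses are not public, so
the tolerances are calibrated on the synthetic noise model instead. On
small fixtures the greedy matcher agrees with exhaustive
maximum-cardinality, minimum-cost assignment (tested over 100 seeds).

A master gel keeps clusters supported by **at least two of the three
best replicates**, at the member-mean position. "Best three of four" is
not an objective criterion in bench practice (gels are judged visually);
the package uses a reproducibility surrogate: each replicate is scored
by its mean unmatched-spot fraction against the other three and the
worst is dropped, ties dropping the highest replicate id.

## HMG and CHMG

Pairwise comparison of master gels partitions spots into common and
morph-unique; the CHMG merges all master spots linked by any pairwise
match and labels a spot *unique to morph m* exactly when it is unmatched
in both comparisons involving *m*. Excisable spots are morph-unique
spots whose nearest CHMG neighbour lies beyond `min_separation`
(default 0.05 in raw (pI, log₁₀MW) Euclidean units) — the in-silico
counterpart of picking spots that visibly do not overlap on a gel.

## The percentage conventions

The HMG summary reports `pct_common = 100·c/((n₁+n₂)/2)` but
`pct_unique = 100·u/(n₁+n₂)`. The mixed denominators are unusual, and
they are kept **deliberately**: they are the only convention under which
the published count triples of this analysis style — e.g. 47 common
spots between master gels of 84 and 53 spots giving 68.6 % common,
27.0 % and 4.4 % unique — reproduce exactly, all nine percentages at one
decimal. `summarize_hmg()` documents this as a reporting quirk; the raw
counts always satisfy `common + unique_a = n_a` and
`common + unique_b = n_b`.

# Search stage

## Database and digestion

`build_database()` deduplicates target sequences (merging accessions),
appends contaminants (e.g. trypsin, keratins) as flagged targets, and
adds one **reversed decoy** per sequence under the `REV_` prefix;
reversal is an involution, so the decoy space mirrors target length and
composition exactly. Digestion cleaves after K/R but not before P;
semi-tryptic mode (the search default) additionally emits peptides with
exactly one non-tryptic terminus. Peptides are length-filtered to 6–35
residues with at most 2 missed cleavages, and carry monoisotopic masses
with fixed carbamidomethyl-C (+57.02146 Da). "Irregular cleavage" in
the purge rule below is interpreted as *missed cleavages*; the
alternative reading (non-tryptic termini) is subsumed by purge rule (ii)
anyway.

## Candidates and the substitute scorer

Candidates for a spectrum are peptides whose mass matches the precursor
neutral mass within 0.5 Da after allowing isotope offsets of 0–2 ×
1.00335 Da, with precursor charge in 1–6. Scoring is deliberately
simple and fully specified in-package: the **raw score** counts
theoretical b/y ions (fragment charges 1–2) matched within the fragment
tolerance (0.5 Da, mirroring the parent tolerance since only that is
published for this analysis style); the **E-value** is the Poisson
upper tail of the raw score at rate
`n_theoretical · (2·tol/span) · n_peaks`, times the candidate count;
the reported score is −log₁₀ E-value, the same scale generating-function
engines report. This scorer is a stand-in with the right semantics, not
a re-implementation of any production engine; it is isolated behind
`score_psm()` so a stricter scorer can be swapped in. Best-hit ties on
the integer raw score are broken by smallest |mass error|, then
lexicographically — a decoy-status-blind rule, so on noise-only spectra
the decoy best-hit rate stays binomial around the database composition
(a calibration property the tests check).

## Two-stage search, purge, FDR

Stage 1 searches the full database; every protein with a stage-1 best
hit (target *or* decoy) seeds stage 2. How the original analysis
"adjusted the proportion" of targets to decoys in stage 2 is not
specified; the package takes the union of surviving targets and the
targets behind surviving decoys and pairs each with its reversed decoy,
giving an exact 1:1 stage-2 ratio by construction. Before FDR, spectra
are purged when (i) their best target and best decoy raw scores tie
(exact integer comparison — a palindromic sequence, whose reversal is
itself, is the canonical case), (ii) the matched peptide has a
semi-tryptic terminus, or (iii) it has more than two missed cleavages.
Note the deliberate literalism: semi-tryptic candidates *compete* in
the search and are then purged, as the published settings imply; a
configuration flag searches fully-tryptic instead. FDR is peptide-level
`n_decoy/n_target` at each observed score, without monotonization
(q-values), because that is the printed formula; peptides at FDR ≤ 0.01
pass, and a protein needs **more than two** distinct passing peptides to
be identified.

# Distance stage

Spectra are binned into 1 Da bins over 100–2000 m/z with square-root
intensity transform (square roots summed within a bin) — standard
spectral-library practice. The cosine distance of two binned vectors is
`1 − u·v/(‖u‖‖v‖)`, with zero-norm vectors defined as distance 1 from
anything non-zero and 0 from each other.

The published description of the set-to-set comparison names external
functions without giving a formula, so the package defines a documented
surrogate: the **symmetrized mean of best matches** — for each spectrum
of A, the minimum cosine distance to B's spectra; the two directed means
averaged. The self-distance uses the same formula with the identical
spectrum index excluded (leave-one-out), which makes self-distances
strictly positive for heterogeneous sets (as in published diagonals,
0.06–0.62) while the measure still reduces to the plain cosine distance
for singleton sets. A singleton set's self-distance is undefined and
propagates as missing, dropping the spot from the paired test with a
message.

Published methods state minima were taken over spots of a *different
morph*, yet the published matrix's bolded row minima include same-morph
pairs; both modes are implemented (`different-morph`, the default, and
`any`) and the discrepancy is surfaced rather than resolved. On the
packaged reference matrix the self-versus-non-self contrast holds in
both modes.

# Inference

`wilcoxon_exact()` tests *self < non-self* one-tailed: zero differences
are dropped (classical convention; the published account is silent),
|differences| are ranked with midranks under ties, W sums the ranks of
pairs opposing the alternative, and the P-value enumerates all 2ⁿ sign
assignments (vector-doubling, n ≤ 25), which remains exact under ties.
With 15 pairs all in the alternative direction, W = 0 and
p = 2⁻¹⁵ ≈ 3.0518×10⁻⁵ — the exact value behind a printed bound of
3.052×10⁻⁵. Quartiles in the distance summaries use linear
interpolation (R's default type 7); the quartile rule behind published
IQRs is unstated, and this choice reproduces them at table precision.

# The synthetic-data generator

The generator is first-class, tested code; it emulates the *statistical
structure* the analysis assumes, not the physics of electrophoresis or
ion optics:

* **Proteomes.** Random residue strings, uniform lengths 80–400, K/R
  density ≈ 0.1 (one tryptic site per ten residues). Defaults plant
  18 shared plus 18/6/7 morph-unique proteins — master gels of roughly
  35/23/24 spots. This is the published spot-map structure scaled down
  about 2.3-fold (richness ratios W/Y ≈ 1.5 and W/R ≈ 1.45 preserved;
  the planted 31 uniques close to the published 25 CHMG-uniques), a
  size chosen so that the full pipeline and its seed sweeps run in
  seconds while keeping every count large enough to be informative.
* **Gel noise.** No quantitative gel-noise model is published, so the
  defaults are stipulated: positional jitter SD 0.02 pH / 0.005 log₁₀
  kDa (about one fifth of the matching tolerances), spot dropout 0.1
  per replicate (so ≈ 97 % of spots survive the 2-of-3 rule), and
  Poisson(2) uniform "speckle" spots per replicate so the matcher must
  reject artefacts.
* **Spectra.** Each spot's protein yields a peptide panel (≈ half the
  spectrum budget, drawn deterministically per accession so two spots
  of one protein share panels — essential for null simulations); each
  spectrum is one peptide's singly charged b/y ladder with log-normal
  intensities, fragment dropout 0.1, five uniform noise peaks, and a
  doubly charged precursor with ≤ 0.05 Da mass error. Peptides cycle
  across the 12 spectra per spot so each has a noisy replicate, making
  leave-one-out self-distances finite and small.
* **Determinism.** One root seed; every artifact draws from a derived
  stream (`derive_seed(seed, tag)`), so outputs are byte-identical
  under a fixed seed and sub-simulations are independent.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: correlated positional
distortions (gel warping), intensity-dependent detection, co-migrating
proteins in one spot, post-translational modifications beyond fixed
carbamidomethyl, chromatographic structure, and realistic fragment
intensity models. Conclusions from synthetic recovery rates transfer to
real gels only insofar as real noise resembles independent jitter and
dropout.

# Degenerate inputs and edge rules

* Fewer than 3 replicates, mixed morphs, or a common count exceeding a
  master-gel size are errors; exactly 3 replicates pass through the
  best-of-4 selection unchanged.
* Empty peak lists score raw 0 with E-value 1; spectra without
  precursor information are skipped with a warning.
* A stage-1 search with no best hits returns an empty PSM list with a
  warning; FDR thresholds with no target peptide are skipped and
  logged.
* All-zero difference vectors make the Wilcoxon test undefined (error),
  as does n beyond the enumeration guard (25).
* A null configuration (no morph-unique proteins) leaves the CHMG
  without unique spots; `run_pipeline()` then falls back to "landmark"
  spots — the same shared proteins recovered in all three masters — so
  the self/non-self comparison remains defined, and flags the report
  accordingly.

# Problem sizes

The shipped tests and simulations use: full-length pipelines at the
default scale above (seeds 1–10); FDR calibration on 20 seeds of 48
true plus 48 noise spectra against 10-protein databases; decoy-rate
checks on 5 × 500 noise spectra; oracle equivalences on 100–200 random
fixtures (digestion on ≤ 20-residue proteins, Wilcoxon at n ≤ 12 against
full 2ⁿ enumeration, 3 × 3 spectrum sets against double-loop oracles).
These sizes are the package's choice of a desk-scale benchmark; all are
configuration parameters, not limits.

# Known limitations

* The PSM scorer is a calibrated surrogate; absolute scores are not
  comparable to production engines, only their ordering semantics.
* The set-distance formula is a documented surrogate for an
  underspecified published procedure; different reasonable choices give
  different absolute distances (the self < non-self contrast is robust
  across them on the reference matrix, which is the inference that
  matters).
* Percentages use the reproduced mixed-denominator convention; anyone
  wanting conventional percentages should compute them from the counts,
  which are always reported alongside.
* The exact test is limited to n ≤ 25 pairs by design; beyond that a
  different inference procedure (not provided) is appropriate.
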