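---
title: "Methods: mass-spectrometry biotyping at unit resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-spectrometry biotyping at unit resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbiotyper)
```

`msbiotyper` turns unit-resolution ESI-MS peak lists of microbial culture
extracts into a strain-differentiation analysis: which ions two strains
share under identical culture conditions, which ions set them apart, and
which known metabolites the shared and dominant ions correspond to. This
vignette records the model behind each stage, the parameters that matter,
and the numerical and design choices a maintainer would want to know.

## Data model and assumptions

One *extract* is the crude organic extract of one strain grown on one
medium (MEA, PDA or SDA) for one incubation period (7, 15, 22 or 30 days),
measured in one electrospray polarity. Its spectrum is a list of
(m/z, relative abundance) pairs, with abundance expressed as percent of
the spectrum's most intense peak (the base peak). Three assumptions are
baked in:

- **Unit resolution.** The instrument class (triple quadrupole) reports
  nominal m/z, so all masses are integers and all mass arithmetic is
  exact integer arithmetic. Input m/z with decimals are rounded half-up
  and the rounding is reported (`as_peak_table()` messages,
  `read_msms()` for MGF precursors). There are no ppm tolerances
  anywhere.
- **Base-peak-relative abundances.** Abundances are not re-normalised on
  input; printed tables are already base-peak-relative. Whether that
  convention (rather than, say, TIC normalisation) was used upstream is
  an assumption; it only affects threshold semantics, not set operations.
- **Truncated reporting.** Printed peak lists usually omit ions below
  10% relative abundance. A truncated table therefore need not contain a
  100% peak in every extract; untruncated tables (e.g. simulator output)
  must contain exactly one.

The acquisition window is fixed at m/z 125–2000 and validated on input.

## Ion selection and common/distinctive profiling

Three rules drive the profiling stage:

- `filter_by_abundance(x, min_rel)` keeps peaks at or above a threshold.
  The working threshold for all downstream set operations is 10%,
  matching the reporting truncation of the tables.
- `select_precursors(x, min_rel = 50)` picks the (m/z, polarity) pairs
  that reach 50% anywhere on the grid — the conventional bar for
  selecting ions worth fragmenting — and reports each with its maximal
  abundance and the extract where it was attained.
- `common_ions(a, b)` intersects, per (medium, period, polarity) cell,
  the two strains' m/z sets, and then applies a recurrence rule: a
  common ion must have been *detected at least twice across the
  different extracts*.

The recurrence rule is genuinely ambiguous, and the choice is visible in
the output, so it deserves a paragraph. Counting detections **pooled**
over both strains' extracts (the default, `occurrence_scope = "pooled"`)
makes any same-cell co-occurrence satisfy the threshold of 2, so the
common-ion table equals the per-cell intersections. Counting **per
strain** (`"per_strain"`) demands each strain separately show the ion at
least twice, which prunes ions seen once in one strain. Neither reading
reproduces a manually curated reference table perfectly: on the packaged
tables, the pooled rule yields every curated row plus three extra
rule-satisfying ions (m/z 207 at MEA/22 d/+, 164 at SDA/15 d/+, 165 at
SDA/7 d/−), while the per-strain rule loses curated rows (m/z 180 at
PDA/7 d/+ and 193 at SDA/7 d/− occur only once in one of the strains).
The package defaults to the pooled reading because it is the weakest rule
consistent with every curated row, and it surfaces the differences
explicitly: `compare_common_ions()` warns per discrepancy instead of
silently conforming to the reference. The reference table itself ships as
a fixture (`reference_common_ions.csv`), not as code.

Distinctive ions are plain per-cell set differences, with no recurrence
rule: a single confident detection in one strain and absence in the
other is already informative at the profiling stage.

The strain-differentiation verdict in `biotype_report()` is deliberately
strict: the strains count as distinguishable only if **every** cell of
the grid has a non-empty symmetric difference of ion sets. Per-cell
Jaccard similarities quantify the same comparison continuously; they are
an artifact-level summary, not a statistical test (there is no
replicate-level variance model in the data).

## Adduct arithmetic and library matching

Electrospray registers intact protonated/deprotonated molecules, so at
unit resolution:

\[
 m/z_{[M+H]^+} = M + 1, \qquad m/z_{[M-H]^-} = M - 1 .
\]

`adduct_mz()` and `neutral_mass()` are exact inverses; no other adducts
(Na+, K+, dimers, multiple charges) are modelled, because none are
registered in the data the pipeline targets. The adduct set could be
extended, but each extra adduct multiplies false mass matches at 0 Da
tolerance, so extension should come with stricter downstream screening.

`match_ion()` matches the recovered neutral mass against a compound
library at an integer tolerance, default 0 Da. Matching is on nominal
mass, not monoisotopic mass, consistently with the instrument class. The
packaged library carries 13 metabolites previously reported from the
genus under study (nominal masses derived from their printed adduct
ions) and 22 decoy records at masses whose adduct ions occur nowhere in
the packaged peak tables; the decoys keep every identification test
falsifiable. Molecular formulas are present only where they could be
reconstructed with confidence (10 of 13 records) and are treated as
advisory annotations: a record without a formula skips the elemental
screen below. Known mass ambiguities (several reported compounds share
nominal mass 210; a stereoisomer pair shares 250) are carried in the
records' `note` fields and propagate into match output rather than being
resolved by fiat.

## Neutral-loss enumeration, ranking, and the consistency screen

A product ion at m/z \(p\) under precursor \(P\) is explained by any
multiset \(L\) of loss-vocabulary entries with
\(\sum_{\ell \in L} m_\ell = P - p\) exactly. `explain_loss()` enumerates
all such multisets with at most `max_depth` components by depth-first
search over non-decreasing vocabulary indices (each multiset generated
once, multiplicity caps respected). The default depth is 4, the deepest
combination needed by the printed assignments the engine was built
against; a five-component printed combination exists and is flagged in
the fixture rather than chased with a deeper default, since enumeration
breadth grows combinatorially and five-fold losses are rarely
assignable with confidence anyway.

Ranking is (fewer components, fewer radical-flagged entries, vocabulary
precedence). Radical (odd-electron) losses — CH3, OCH3, C3H7, H, ... —
are chemically special, so they are permitted but deprioritised.
Vocabulary precedence (the row order of `default_loss_vocabulary()`,
small stable neutrals first) breaks the remaining ties: at a mass
difference of 62 the engine ranks {H2O, CO2} above the isobaric
{C2H4O, H2O}, matching what an analyst would write first. Isobars are
never dropped — at Δ = 112, C6H8O2 and C8H16 are both reported — because
choosing between them takes structural reasoning the engine does not
model; `n_explanations` in the annotation output keeps the ambiguity
visible.

Two vocabulary details are deliberate:

- The mass-1 entry `H+` (hydrogen loss/transfer) is capped at one
  occurrence per combination (`max_count = 1`). Uncapped, mass-1 padding
  lets chains like {CH3, 3×H} "explain" an 18 Da difference for an
  oxygen-free molecule, which would defeat the elemental screen; one
  hydrogen transfer per pathway is the chemically defensible allowance.
- A zero mass difference is explained by the empty multiset. Product
  ions are required to sit strictly below the precursor in spectra; the
  degenerate case matters only for direct `explain_loss()` calls.

`annotate_spectrum()` reports *coverage*: the fraction of product ions
with at least one explanation (vacuously 1 for an empty product list).
`consistency_check()` then screens a candidate compound: a product ion is
*consistent* when at least one of its explanations has an elemental
composition that fits inside the candidate's molecular formula
(sub-multiset of element counts), and the verdict is positive when the
consistent fraction reaches `min_coverage` (default 0.8). Requiring the
*top-ranked* explanation to fit would be stricter but wrong in practice:
ranking cannot see the formula, so an isobaric first-ranked alternative
(e.g. a C9H20O combination where the molecule only has 16 hydrogens)
would veto a correct identification whose printed assignment is ranked
second. The any-explanation rule is exactly the logic of manual
fragmentation analysis: *some* chemically possible loss pathway must
account for the fragment. The 0.8 default is a configuration knob, not a
community standard; it is chosen so that clean reference spectra (which
reach coverage 1.0) pass with margin while element-starved decoys of
equal nominal mass fail several products at once.

## End-to-end identification

`identify_compounds()` chains the stages: filter at 10%; candidate ions =
(precursors ≥ 50%) ∪ (common ions); convert to neutral mass; match at
0 Da; for each match with an MS/MS spectrum at that (precursor, polarity),
run the consistency screen. The candidate set is a union because known
compounds arrive by both routes — some through shared ions, some through
dominant strain-specific ions. Matches without an MS/MS spectrum are
reported as `mass_match_only` and never identified: a nominal-mass match
alone, at unit resolution, is too weak a claim. The identified set is
invariant to library and spectrum order, and adding decoys cannot change
it at tolerance 0 (their masses are disjoint by construction).

## The synthetic-data generator

`simulate_strain_pair()` emulates what the fixtures look like
statistically, with known truth:

- the full 2 × 3 × 4 × 2 grid (two strains, three media, four periods,
  two polarities), every extract rescaled so its base peak is exactly
  100%;
- planted **shared ions** (default 5) present in both strains, each
  guaranteed in ≥ 2 cells per strain; **unique ions** (default 3 per
  strain); **planted compounds** (default 2, drawn from the non-decoy
  library records) whose adduct ions appear in both strains at ≥ 50%
  pre-scaling abundance — that floor is the study condition under which
  the precursor-selection rule is guaranteed to see them;
- **noise ions** (default 5 per extract) strictly below the 10%
  reporting threshold, added after base-peak scaling so they stay
  sub-threshold;
- cell-wise presence is Bernoulli with `occurrence_prob` (default 0.6),
  abundances uniform on [10, 100] (log-uniform optional);
- MS/MS spectra for planted compounds are sampled from the loss
  vocabulary (depth ≤ 3, 5 products), restricted to elementally feasible
  combinations when the compound has a formula, with the true loss
  multisets recorded.

A single seeded RNG stream drives a run, and the caller's RNG state is
restored afterwards; identical seeds give identical outputs. The
generator does **not** emulate retention time, chromatographic peak
shape, isotope envelopes, adducts beyond the two default ones, abundance
correlation across media, or m/z measurement error. Passing recovery
tests on simulated data therefore demonstrates the pipeline's logic
(set operations, matching, screening) under the stated noise model — not
robustness to instrument drift or co-elution artifacts in real data.

Degenerate configurations are handled explicitly: at least two planted
ions per strain are required (both polarities must host a base peak),
polarity assignments are rebalanced when one mode would be empty, and
m/z pools exclude all library adduct masses so decoys can never collide
with planted or noise ions.

## Problem sizes and determinism

The test suite runs the full fixture analysis (409 peaks, 48 extracts,
13 MS/MS spectra, 35 library records) plus property checks:
enumeration-vs-brute-force equivalence on vocabularies of ≤ 8 entries at
depth ≤ 3, and planted-compound recovery over 100 simulator seeds at the
default configuration. All fixture-derived quantities are deterministic;
seeded stochastic checks fix their seeds locally (`withr::local_seed`)
and never leak RNG state.

## Known limitations

- Two strains only; clustering or dendrograms over larger strain panels
  are out of scope.
- Presence/absence comparisons carry no significance model — the data
  provide no replicates to estimate one.
- Nominal-mass matching cannot distinguish isomers or isobars; the
  consistency screen narrows but does not resolve them, and the output
  says so (`note` fields, alternative explanations) rather than
  pretending otherwise.
- The loss vocabulary is finite and editable; a printed assignment using
  a species outside it (e.g. CHO) is flagged in the fixtures, not
  silently added, because vocabulary growth inflates the explanation
  space for every spectrum.
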