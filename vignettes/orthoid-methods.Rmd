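---
title: "Methods: simulating and analysing dual-orthogonal proximity labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing dual-orthogonal proximity labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoid)
```

## The measurement model

Dual-orthogonal proximity labeling places two enzymes on opposite faces of
the ER–mitochondria interface: a biotin ligase on the cytosolic face of the
outer mitochondrial membrane (OMM) biotinylates cytosol-exposed lysines
(Bt, +226.078 Da), and a peroxidase on the luminal face of the ER membrane
(ERM) tags lumen-exposed tyrosines with an adamantane-phenol (Ad,
+414.252 Da). Labeled peptides are enriched in two parallel arms —
streptavidin beads for Bt, cucurbit[7]uril beads for Ad — and identified in
MS/MS *by their mass shift on the specific residue*, not by enrichment
alone. A protein detected reliably in **both** arms has been touched by
both enzymes and is therefore a candidate resident of the
mitochondria-associated ER membrane (MAM).

`orthoid` implements this whole measurement chain as testable code:

1. **mass calculus** — one authoritative monoisotopic atomic table
   (CODATA/AME principal isotopes); every modification mass in the package
   is derived from an elemental composition, never typed in as a constant.
   Ion m/z uses bare-proton addition with electron-mass balancing for
   intrinsic cations; the convention is documented in `?ion_mz`.
2. **digestion and fragments** — tryptic cleavage after K/R, by default
   protected before proline (the common search-engine convention;
   switchable), up to two missed cleavages; b/y fragments only, charges
   1–2, as typical for HCD spectra.
3. **a synthetic-data generator** with complete ground truth.
4. **a spectrum search engine** with reverse decoys and target–decoy FDR.
5. **the decision layer**: replicate consensus, annotation filtering, arm
   intersection, topology validation, condition contrasts.

## What the generator emulates

`generate_proteome()` draws random protein sequences (human-like residue
frequencies, log-normal lengths of median ~110 aa clamped to 40–400) over
seven compartments (ER lumen, ERM, OMM, IMM, cytosol, matrix, other; the
default mixture weights cytosol most heavily). Membrane proteins receive
1–3 random 21-residue transmembrane helices with alternating sidedness
(ERM: cytosol/lumen; OMM: cytosol/IMS; IMM: matrix/IMS). Each protein gets
a log-normal abundance, an exponential distance to the ER–mito junction
(rate 1 for ERM/OMM, rate 0.25 — i.e. farther — for the rest), and, with
1% probability among matrix/cytosol proteins, endogenous biotin lysines
emulating the carboxylase background that makes streptavidin enrichment
alone unreliable.

`simulate_labeling()` models each exposed residue as an independent
Bernoulli per replicate:

* Bt on cytosol-facing K with probability `p_bt · exp(−d)` where `d` is
  the junction distance (proximity to the OMM-anchored ligase);
* Ad on lumen-facing Y with probability `p_ad` (the ERM peroxidase is
  distributed across the ER, so no distance weight);
* Ad *leakage* on cytosol-facing Y of OMM/ERM proteins within
  `junction_cutoff = 2` distance units, with probability
  `leakage_p · exp(−d)` — the radical escape observed near the translocon
  at contact sites;
* under CCCP only, Ad on IMS-facing Y with probability `cccp_ims_p`,
  emulating the reduced ER–IMM distance during mitophagy;
* endogenous biotin sites appear as Bt background in every replicate.

Defaults (`p_bt = p_ad = 0.6`, `leakage_p = cccp_ims_p = 0.5`,
`replicate_dropout = 0.1`, `capture_eff = 0.9`, `background_rate = 0.01`,
5 ppm jitter, 10% peak dropout, ~10 noise peaks, 5% Met oxidation) were
chosen once as plausible magnitudes for an efficient enzymatic labeling
experiment with good but imperfect bead capture; they are deliberately
ordinary values, not fitted to anything. The junction-distance scale is
arbitrary (the underlying biology gives no distance calibration); only the
monotone decay and the leakage cutoff matter for the decision layer, and
the generator and the topology validator share the same cutoff so that the
"leakage" exception class is well defined on both sides.

**Ground truth and detectability.** Each label event is mapped to its
tryptic peptide (fewest missed cleavages, then leftmost) and flagged
*detectable* if that peptide falls in the 6–45 residue search window with
a 2+/3+ precursor inside m/z 350–1800. A protein's ground-truth
arm-reliability counts replicates with at least one *detectable* event;
dual status requires both arms in ≥ 2 of 3 replicates. Chemistry events
whose tryptic context is invisible to the instrument are recorded but
excluded from the benchmark truth — a deliberate choice that makes the
noiseless end-to-end invariant exact ("what the instrument could in
principle see is what the pipeline must find") rather than penalising the
search engine for peptides that never enter any spectrum.

**What the generator does not model:** chromatographic elution,
co-isolation/chimeric spectra, isotope envelopes, peptides carrying two
label events at once (each event yields its own peptide instance),
protein complexes, and real topology databases (an import hook exists via
the long-format topology table, but the shipped topology is synthetic).
Passing tests therefore demonstrate the correctness of the decision logic
and the calibration of the FDR machinery under the stated noise model —
not performance on real instrument data.

## The search engine

Candidates are all tryptic peptides (6–45 aa, ≤ 2 missed cleavages) of
every target protein and its full-sequence reversal (`DECOY_` prefix),
with static carbamidomethyl-C applied everywhere and dynamic Met-ox, Ad-Y
and Bt-K enumerated in all combinations up to 3 per peptide (a hard cap of
256 forms per peptide guards pathological cases; truncations are counted).
Precursor matching is ±10 ppm on neutral mass; fragments match at
±0.02 Da.

The score is hyperscore-style:
`lfactorial(#matched b) + lfactorial(#matched y) + log1p(matched intensity)`.
It is zero when nothing matches, deterministic, and increasing in matched
evidence. Ties break toward fewer dynamic modifications, then smaller
precursor error, then lexicographic sequence — so an unmodified
explanation always beats an equally-scoring modified one.

q-values follow classic target–decoy competition: at each score cutoff,
FDR is estimated as #decoys/#targets at or above the cutoff, monotonized
from the bottom of the ranked list; decoys sort before targets at score
ties (conservative). Protein inference is greedy set-cover parsimony with
lexicographic tie-breaks and razor assignment of shared peptides; protein
q-values use picked pairing (each target competes with its own reversed
decoy, the better of the pair survives). LFQ is the arithmetic mean over a
group's razor peptides of summed matched peak intensity; groups with no
quantifiable peptide get `NA`, never zero.

These are explicit stand-ins for the closed commercial implementations of
scoring and Master-protein selection; no numerical equivalence with them
is claimed, only the same documented contracts (1% FDR at PSM and protein
level, Master-based reporting).

## The decision layer

A protein is *detected* in one (arm, replicate, condition) run iff it is a
Master protein at protein q ≤ 0.01 with at least one accepted PSM carrying
the arm's modification on the correct residue class. Reliability requires
detection in ≥ 2 of 3 replicates per arm; the dual (MAM-candidate) set is
the intersection of the two arms' reliable sets after restricting to
ER/mitochondria/both annotation classes ("other" proteins are kept in a
side table for audit, not discarded silently). Topology validation flags
any Bt site that is not a cytosol-facing K and any Ad site that is not a
lumen-facing Y, with three declared exception classes: endogenous biotin
K, junction-proximal leakage Y (OMM/ERM, within the cutoff), and IMS Y
under CCCP. Proteins absent from the topology table are "unknown", never
silently consistent.

Condition contrasts are descriptive PSM counts per (protein, residue,
modification): a site is "CCCP-gained" with ≥ 2 PSMs under CCCP and none
under NT (symmetrically "NT-only"). No multiple-testing correction is
applied — the contrast is presence/absence of identifications, not a test
statistic, and the threshold `min_psm = 2` is configurable. Reliability is
computed per condition independently; conditions are never pooled.

## Numerical and design choices

* Atomic masses: H 1.0078250319, C 12, N 14.0030740052, O 15.9949146221,
  S 31.97207069, P 30.97376151; proton 1.00727646688, electron
  0.00054857990946. Display rounding is 3 dp for mass deltas, 1–2 dp for
  the tag ions, matching the precision at which such values are reported.
* I/L are distinct letters with identical residue mass; matching therefore
  treats them as identical in mass space without any special-casing.
* The m/z jitter is uniform on ±`mass_jitter_ppm`, so a 5 ppm jitter can
  never push a precursor outside the 10 ppm search tolerance — error and
  tolerance stay decoupled by construction.
* Degenerate inputs: empty FASTA and unknown elements are errors; an empty
  peptide pool yields a valid empty MGF; spectra with charges outside
  {2,3} are skipped and counted; an empty PSM table propagates as empty
  tables, not errors.
* One master seed drives every stage through fixed per-stage sub-seeds,
  so identical configurations give byte-identical outputs.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: digestion against a
brute-force oracle on 1000 random sequences (≤ 60 aa); 100 planted
noiseless peptides for search self-consistency; 20 × 150 pure-noise
spectra for FDR calibration; an 80-protein noiseless run (both
conditions) for exact end-to-end soundness, CCCP site recovery and
topology soundness; and 20 seeds × 500-protein proteomes at default noise
(NT arm pair) for dual-call precision/recall, with the two-condition
robustness behaviour spot-checked at smaller scale. These sizes are the
package's own benchmark design: large enough for the binomial bounds used
in the assertions, small enough to run routinely.

## Known limitations

* Because ground truth is fixed at the chemistry level (label events,
  before enrichment), imperfect bead capture censors truth events that
  the pipeline never receives as data; benchmark recall therefore
  measures capture efficiency and decision logic jointly, and is bounded
  below one whenever `capture_eff < 1` for proteins whose bottleneck arm
  rests on a single peptide per replicate. Setting `capture_eff = 1`
  isolates the decision layer.
* The simulator's spectra are far cleaner than instrument data even at
  default noise; absolute precision/recall numbers on it say nothing
  about real samples, only about the decision logic.
* Site localization inherits the search engine's tie-breaking under heavy
  peak loss; no localization probability is computed.
* The leakage exception is distance-thresholded, not mechanistic; with
  real topology tables the cutoff would need calibration.
* Protein-level FDR by picked pairing is coarse at the small protein
  counts typical of simulations (few decoy masters), which makes it
  permissive rather than conservative there.
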