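---
title: "Simulated phosphopeptide spectral libraries: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated phosphopeptide spectral libraries: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphosim)
library(dplyr)
```

## The problem

Collision-induced dissociation (CID) spectra of phosphopeptides and of their
enzymatically dephosphorylated counterparts are similar in beam-type (Q-TOF /
HCD) instruments: the backbone fragmentation pattern is largely preserved,
while fragments that retain the phosphosite shift by the phosphate mass and,
for phosphoserine/phosphothreonine, additionally lose phosphoric acid. This
makes the following workflow possible: identify the *dephosphorylated*
peptides confidently by database search, then *simulate* the spectrum of
every possible singly phosphorylated form of each identified peptide, build a
spectral library from the simulated spectra, and search the phosphopeptide
spectra against that library. Because a site isoform is a separate library
entry, the library search itself localizes the phosphosite, and the margin
between the best and runner-up match quantifies localization confidence.

phosphosim implements this workflow end to end — simulation, consensus
library construction with decoys, dot-product library search, and validation
machinery (FLR curves, decoy FDR, condition sweeps, agreement analysis) —
plus a synthetic paired-experiment generator so the whole pipeline can be
exercised and benchmarked without any external data.

## The simulation model

For a template peptide-spectrum match (PSM) of a dephosphorylated peptide,
the spectrum's peaks are first annotated with theoretical a/b/y fragments
(and their ammonia/water neutral-loss variants; combined ammonia+water losses
are never generated). Simulation of a phosphosite at position $s$ then maps
each annotated peak:

* peaks whose fragment span **excludes** $s$, and unannotated peaks, are
  copied unchanged;
* an annotated peak whose span **includes** $s$ and whose loss type is
  permitted as a template (see below) spawns, for S/T sites, an *intact*
  phospho ion at $m/z + 79.966331/z$ at `r_intact_st` times the source
  intensity and a phosphoric-acid neutral-loss (NL-P) ion at
  $m/z - 18.010565/z$ at `r_nlp` times the source intensity; for Y sites only
  the intact ion is spawned, scaled by `r_intact_y`;
* site-containing source peaks themselves are removed — a singly
  phosphorylated peptide does not produce the unshifted fragment. Whether a
  removal-free variant would better match real spectra is an open question in
  the underlying method; removal matches the published spectra of simulated
  phosphopeptides, and it is what this package does.

The *NL condition* decides which neutral-loss template peaks spawn
predictions: `NL-P` uses plain a/b/y templates only, `NL-PA` adds ammonia-loss
templates, `NL-PW` water-loss templates and `NL-PAW` both. The pY prediction
is gated by the same template set as pS/pT — the alternative (always
predicting pY from all templates) is not distinguishable on the data this
package targets, so one rule is used consistently.

Shifts are applied in the mass domain and divided by fragment charge; the
nominal "+80/−18 Da" labels correspond to the exact monoisotopic masses
79.966331 (HPO~3~) and −18.010565 (H~2~O, the net of +79.966331 − 97.976896
for H~3~PO~4~ loss), which matter at the 0.05 Th matching tolerance used
throughout. Output peaks coinciding within 10^-4^ Th are merged by intensity
sum; the paper-scale tolerances make the merge rule essentially invisible,
but it keeps peak tables strictly sorted, which every downstream step
assumes.

Named intensity conditions follow the `pS/pT-intact – NL-P – pY-intact`
percentage convention: the default condition is 10–100–100 with NL-PAW
templates; the optimized conditions are 50–50–100 and 50–50–50 with NL-P.

## Library construction

Simulated entries are grouped by (sequence, site, charge) and merged into one
consensus spectrum per group: peaks are clustered across replicates by single
linkage within 0.05 Th, each cluster's m/z is the intensity-weighted mean and
its intensity the mean over replicates containing the peak, and — with at
least three replicates — clusters present in under half of them
(`consensus_min_presence = 0.5`) are dropped. This is a deliberately
simplified consensus: full production library builders apply an unpublished
cascade of quality filters, and nothing downstream here depends on those.

Each target receives one decoy (1:1) by *shuffle-and-reposition*: residues
1..L−1 are permuted with a seeded generator (the C-terminal residue stays,
preserving tryptic character), the phosphosite rides its residue through the
shuffle, and every annotated peak is moved to the corresponding fragment m/z
of the shuffled phosphopeptide, keeping its intensity. A fragment that
carried the phosphate in the target keeps it in the decoy, so every
repositioned m/z remains chemically plausible even when the shuffled site
lands outside the fragment's span. Shuffles colliding with any target
sequence are redrawn (at most 10 times) and then perturbed by an internal
swap. Decoys therefore preserve the precursor m/z, the amino-acid
composition, the peak count and the total ion current of their targets.

## Search and scoring

Query and library spectra are binned at 20 bins per m/z (0.05 Th) over the
acquisition range 100–1600 Th; each peak contributes the square root of its
intensity to its bin and the vector is scaled to unit Euclidean norm. The
similarity is the inner product (`dot` in [0, 1]), and the *dot bias*
$\sqrt{\sum_i (a_ib_i)^2} / \sum_i a_ib_i$ flags matches dominated by few
bins. Candidates are restricted to entries within 3 Th of the query
precursor; a 0.05 Th precursor filter is applied only *after* scoring, so
the runner-up structure that the deltadot scores depend on is computed on
the wide window.

Two deltadot flavours are computed per hit: **HOM1** compares each hit to the
next-ranked hit even when that is a site isoform of the same sequence;
**HOM4** skips homologous hits (identical unmodified sequence) up to three
ranks down, falling back to the last of those ranks when all are homologous.
A query with a single candidate keeps its own score as its deltadot. The
combined discriminant `fvalue` is `0.6*dot + 0.4*deltadot_hom4 − penalty`,
with a 0.12 penalty when the dot bias leaves the window [0.09, 0.57]; these
constants are configuration, not claims — every FLR/FDR statement this
package makes is self-consistent under any choice.

A second scoring route (`"v5like"`) is a documented *surrogate* for
rank-based similarity scoring: matched peaks (nearest within 0.05 Th,
one-to-one) are scored by the Spearman correlation of their intensities,
mapped to [0, 1] and weighted by the matched fraction of library peaks.
Fewer than three matches, or zero intensity variance, scores 0. It is not a
reproduction of any production scorer's internals, which are unpublished.

Ties in the ranking are broken deterministically (targets before decoys,
then sequence, then site) so repeated runs are identical.

## Validation

FLR (false localization rate) curves join rank-1 hits to ground truth by
spectrum id, order them by a chosen score (HOM1 deltadot by default), and
accumulate correct (site match) and false localizations per distinct score.
Hits whose sequence disagrees with the truth are excluded from the curve and
counted separately — the benchmark peptides have known sequences, so
sequence errors are a different failure mode — with a
`count_wrong_seq_as_false` switch providing the conservative alternative.
`cutoff_at_flr()` returns the deepest distinct-score prefix whose FLR stays
at or below the target; no interpolation is done between tied scores. The
decoy FDR is the plain counting estimator `#decoys / max(1, #targets)` above
a threshold — a deliberate methodological simplification standing in for
probabilistic PSM modelling, which is out of scope here.

`condition_sweep()` runs the full grid — four intensity conditions crossed
with four NL template sets, two scoring routes — sharing one set of template
annotations and one decoy seed across conditions, and reports the 1% FLR
cutoff and correct-localization count per cell.

## The synthetic data generator

The generator emulates the paired before/after-dephosphorylation experiment:
for each tryptic peptide a clean b/y ladder is drawn once (log-normal parent
intensities, $\sigma = 1$, scaled to a base peak of 10\,000; ammonia/water
satellites at 30% of their parents where residue-eligible), the
phosphorylated spectrum is derived from that same ladder (site-containing
fragments replaced by intact ions scaled by `phi_intact` and, for S/T, NL-P
ions scaled by `phi_nlp`; satellites of site-containing fragments are not
retained), and replicate spectra of both forms are produced by a corruption
model: uniform noise peaks, Bernoulli peak dropout, and Gaussian m/z jitter
(precursors are never jittered, and the phospho precursor always sits
exactly 79.966331/z above its dephospho partner).

Peptides are fully tryptic (C-terminal K/R, no internal K/R), 8–16 residues,
with at least one S/T/Y and at least two in 80% of peptides so localization
is non-trivial. Sequences are additionally required to have all template
fragment channels more than 0.11 Th apart; this keeps every generated peak's
fragment identity unambiguous, which the closed-loop identity below relies
on. Real peptides do produce near-isobaric fragments — this constraint is a
property of the benchmark, not of the method.

Two properties anchor the generator to the simulator:

* **Closed loop.** With corruption disabled, applying the simulator to the
  generated dephospho spectrum under the condition matching the generator's
  own parameters (`r_intact = phi_intact`, `r_nlp = phi_nlp`, NL-P) exactly
  reproduces the generated phospho spectrum, peak for peak. This is the
  module's core correctness oracle, and it is what makes the NL-P condition
  the *true* model for generated data.
* **Parameter recovery.** Data generated at `phi = (0.5, 0.5)` should be
  best served by the 50–50–\* NL-P simulation conditions in a condition
  sweep, mirroring the optimization result on real TripleTOF data.

### Choice of corruption level

The corruption defaults (30 noise peaks per spectrum, dropout probability
0.25, m/z jitter sd 0.015 Th) were calibrated once to the regime the
generator is specified to produce — *discriminative but imperfect* matching,
where the best simulation condition localizes roughly 60–90% of queries at
1% FLR. Much milder corruption saturates the benchmark (every condition
localizes everything, and condition effects vanish); much heavier corruption
degrades all conditions indiscriminately. Within this regime the intensity
dimension of the condition grid is recovered reliably; the NL dimension is a
genuinely small effect at this scale (see limitations), exactly because
spurious extra library channels cost a dot product mostly normalization,
which cancels in rankings.

What the generator does *not* model: retention time, isotope envelopes,
fragment charge states above 1 in the ladder, chimeric spectra, co-eluting
site isoform mixtures, intensity-dependent m/z error, and multiply
phosphorylated peptides. Passing tests on synthetic data therefore
demonstrate the pipeline's internal consistency and its behaviour under the
stated noise model — not instrument-level realism.

## Numerical choices

* Monoisotopic constants: proton 1.00727646677, H~2~O 18.0105646837, NH~3~
  17.02654910101, CO 27.99491461956, HPO~3~ 79.96633052075, H~3~PO~4~
  97.97689520445 Da; residue masses at the same precision.
* Fragment–peak annotation: nearest peak within 0.05 Th, one peak per
  fragment and one fragment per peak; conflicts resolved by smaller |Δm/z|,
  then higher peak intensity, then a fixed series/ordinal order, so
  annotation is deterministic.
* All randomness (decoys, peptide generation, corruption) is seeded
  explicitly, restoring the caller's RNG state afterwards; libraries record
  their decoy seed in the file header.
* Degenerate inputs: empty spectra score no hits (with a message); empty
  libraries are an error for search but valid to write/read; consensus of a
  single spectrum is the identity; an all-dropout draw keeps the base peak.

## Problem sizes used in the shipped checks

The test-suite benchmarks use 24 peptides × 3 replicates (the synthetic
design of the experiment the generator emulates) for sweeps, 100 peptides
for the closed-loop identity, 50 queries × 100 library entries for
search-oracle equivalence, and 1000 randomized hit lists for the FLR cutoff
oracle — sizes chosen so the full suite runs in minutes on one CPU while
every pipeline stage is exercised end to end.

## Known limitations

* The NL-dimension effect in the synthetic benchmark is small relative to
  seed-to-seed variance at 72 queries; sweeps on single seeds should not be
  over-interpreted. The intensity dimension separates cleanly.
* The v5-like scorer is a surrogate; conclusions about "version 4 vs
  version 5" scoring on real data do not transfer to it.
* Only single phosphorylation is simulated; multiply phosphorylated
  peptides are out of scope.
* The F-value constants approximate published discriminant scoring but are
  not fitted to any dataset.
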