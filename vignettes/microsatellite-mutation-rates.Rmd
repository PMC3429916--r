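---
title: "Methods: microsatellite composition and MA-line mutation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite composition and MA-line mutation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatma)
```

This vignette is the package's own account of the models and conventions it
implements: what each stage assumes, which tunable parameters matter, what
the synthetic-data generators do and do not emulate, and where the design
was genuinely open.

## Canonical motif taxonomy

A microsatellite is named by its repeat unit, but the unit is only defined
up to cyclic rotation (the array has no distinguished starting phase) and
reverse complementation (duplex DNA has no distinguished strand). The
package therefore works with equivalence classes: `canonical_motif()` maps
a unit to the lexicographically smallest string (A < C < G < T) among its
rotations and the rotations of its reverse complement. The choice of
*lexicographic minimum* is a convention — any fixed orbit representative
would do — but it matches the alphabetical-first labels in common use
(AC rather than GT, AAG rather than CTT) and gives an idempotent,
strand-symmetric normal form.

Class counts are defined over *primitive* units only: `"ACAC"` is not a
tetramer class, it is two copies of the dimer `AC`, and the scanner reduces
such hits before classification. `enumerate_motif_classes()` computes the
class list by exhaustive enumeration of all $4^k$ strings rather than from
a closed-form orbit count; at $k \le 6$ (4096 strings) this costs
milliseconds and the test suite cross-checks it against an independent
orbit-traversal oracle. The counts are 2, 4, 10, 33, 102 and 350 classes
for unit lengths 1–6.

A unit is called **AT-rich** when it has at most one C/G base (at least
$k-1$ of $k$ bases A or T, the `[(A/T)_{k-1}, X_1]` and stronger
categories). This is the definition under which AT-rich trimers make up
92% (123/133) of the packaged strict perfect trimer counts.

## The repeat scanner

The scanner finds tandem arrays of 2–6 bp units (homopolymers can be
requested but are excluded from default screens) with at least three
copies. Established tandem-repeat finders use a probabilistic alignment
model; reproducing one bit-exactly is not a goal here. Instead the package
defines a deterministic contract that is simple enough to reason about and
test:

1. **Seed**: any position where the $p$-mer repeats immediately at
   distance $p$.
2. **Extend**: grow the array left and right, comparing each base to the
   periodic extension of the seed unit. The running score gains
   `match_weight` per match and loses `mismatch_weight` per mismatch;
   extension stops once the score drops more than $2p \cdot
   \text{mismatch\_weight}$ (two full units of mismatches) below its
   running best, and the array is clipped at the best-scoring endpoints.
3. **Score**: over the whole clipped array, $S = w_m \cdot \#\text{match}
   - w_x \cdot \#\text{mismatch}$, so a perfect array of span $L$ scores
   exactly $w_m L$. Only arrays with $S \ge$ `min_score` and
   $\ge$ `min_copies` copies are reported.
4. **Resolve**: candidates sharing at least half of the shorter span keep
   the higher score; ties break to the smaller unit length, then the
   leftmost start. `N` runs are never crossed.

Two presets carry the conventional screening regimes: **strict**
(weights 2/3/5, minimum score 50), which demands ~25 bp of near-perfect
repeat, and **loose** (2/7/7, minimum score 20), which admits 10 bp
perfect arrays and, because of the lower threshold, long imperfect loci.
`percent_match` is the fraction of matching adjacent-copy base
comparisons (lag $p$ within the array), the same quantity genotyping
panels report.

Two deliberate simplifications:

* The extension is **gap-free**. Interrupted arrays are modelled through
  mismatches only, `percent_indels` is always 0, and the indel weight
  participates only in preset identity. Slippage-generated interruptions
  in short-unit repeats are overwhelmingly substitutions over these
  spans, and a gap-free model keeps the contract exactly testable.
* Containment between regimes (every strict locus recovered by the loose
  screen) holds for perfect and moderately imperfect loci
  ($\gtrsim 85\%$ match). A heavily interrupted locus can pass strict
  (mismatch weight 3) yet score below 20 under the loose weights
  (mismatch 7); this is a property of the stated scoring contract, and
  the test suite asserts containment on fixtures within its domain of
  validity.

Coordinates are 1-based inclusive everywhere — in the returned tibbles and
in the written tables — matching both the R/Bioconductor convention and
the output dialect of the tandem-repeat tool ecosystem.

`summarize_composition()` reports loci per megabase
(`n_loci / (genome Mb)`) and the percentage of the genome inside repeat
loci. Overlapping loci are collapsed (interval union) before summing so a
base inside two candidate arrays is counted once; published genome-fraction
figures do not always state how they treat overlap, so ours is documented
rather than assumed comparable.

## Mutation calling and the spectrum

Genotypes arrive as fragment sizes in bp, one allele per (marker, line):
the study organisms are selfing hermaphrodites propagated through
single-offspring bottlenecks from one homozygous progenitor, so every
locus is homozygous and a new mutation is fixed or lost within a couple of
generations — the package treats fixation as instantaneous. A call is the
signed difference from the progenitor in repeat units; a size difference
that is not a multiple of the unit length ("off-ladder") cannot be a clean
repeat-number change and is suppressed with a warning rather than called
(in the wet lab such alleles trigger independent re-amplification).

The spectrum statistics follow directly: single-step events
($|\Delta| = 1$, the stepwise-mutation-model signature) versus multistep;
insertion versus deletion *events* (the insertion-bias statistic is an
event count, which is the internally consistent reading of the source
tallies); per-locus net change and its trend. The mutated-line count `n`
used by the estimator is the number of distinct lines with at least one
call at the marker — not the event count — because the estimator is
defined on the zero class of lines. In the packaged panel no line mutates
twice at one marker, so the two coincide there.

`stratify_events()` operationalises "long" as repeat count strictly above
a threshold supplied by the caller; with threshold 3 the perfect-and-long
stratum captures 29 of the panel's 31 events (the exceptions being the
single imperfect-locus event and the event at a 3-copy locus).

The packaged panel itself (`fixture_ma_markers()`) records no fragment
sizes, so progenitor alleles are represented by the array length
(unit length × repeat count); calls depend only on size differences, so
this choice is immaterial downstream. Per-marker assessed-line counts were
not published either; `fixture_genotypes()` therefore treats all 82 lines
as assessed everywhere, and all rates computed from it carry `l = 82`
visibly in the output. This is also why published per-marker rates that
imply smaller `l` are not exact targets for the package: `l` is data, and
the package never assumes it silently.

## Rate estimation

For `n` mutated lines out of `l` after `t` generations,

$$\hat\mu = -\frac{\ln(1 - n/l)}{t}.$$

Assumptions: mutations arrive as a Poisson process at rate $\mu$ per
allele per generation; lines are independent; a mutated line remains
visibly mutated (homoplasy — a $+1$ followed by a $-1$ — restores the
progenitor size and biases $\hat\mu$ downward; at $\mu t \ll 1$ the bias
is $O((\mu t)^2)$ and negligible). For small mutated fractions
$\hat\mu \approx n/(lt)$; the relative gap is below 3% whenever
$n/l \le 0.05$, and the test suite asserts this Taylor bound.

Saturation ($n = l$) leaves the estimator undefined: the scalar function
raises an error, and the batch estimator records the marker with
`saturated = TRUE` and continues. Single-event markers are estimated but
flagged, mirroring the convention of reporting such rates parenthetically.

Uncertainty is a Clopper–Pearson (exact binomial) interval on $n/l$,
mapped through the estimator (monotone in $n/l$, so endpoints transform
directly). Coverage is validated by simulation in the tests: at
$\mu = 5\times10^{-4}$, $l = 82$, $t = 142$ over 1000 simulated loci, the
realised coverage of the nominal 95% interval stays within 5 percentage
points (exact binomial intervals are conservative, so realised coverage
sits at or above nominal).

The aggregate `suggested_rate` in `glance()` is the unweighted mean of
$\hat\mu$ over perfect markers with at least 30 repeat units and at least
two mutated lines. That population — long perfect loci with replicated
events — is the one with stable, usable rates; the mean is a reporting
convention for marker selection, not a statistical estimator of a global
rate.

## The synthetic-data generators

`simulate_ma_lines()` emulates the MA design the analysis assumes: `l`
surviving selfing lines (default 82) propagated `t` generations (default
142) from one homozygous progenitor, each line × locus mutating
independently with per-generation probability $\mu$. Steps are drawn from
a stepwise model: single-step with probability 26/31 and insertion with
probability 23/31 (the observed event proportions in the packaged panel);
the multistep tail magnitude is $2 + \text{Geometric}(q)$ with
$q = 0.357$, chosen once so the mean tail magnitude is $\approx 3.8$, the
mean of the five observed multistep magnitudes $\{2,2,3,3,9\}$ — no
published multistep distribution exists, so this is a labelled convention.
Repeat counts floor at 3 (a deletion that would cross the floor is
redrawn), since locus death is neither observed nor modelled. Line
attrition (e.g. 100 founded, 82 surviving) is available via `n_founding`
but off by default: rates are computed from surviving lines only, and
dropout is independent of genotype.

What the simulator does *not* emulate: PCR stutter and allele-calling
error, heterozygosity and outcrossing, selection, length- or
motif-dependent rate variation within a run (each locus has one fixed
$\mu$), and interference between loci. Passing tests therefore demonstrate
correctness of the calling/estimation machinery under the stated model,
not robustness to genotyping artifacts.

`plant_repeats()` builds scanner inputs: i.i.d. background at a given A+T
fraction (default 0.58, an AT-rich nematode-like genome) with specified
arrays inserted at non-overlapping positions. The single base flanking
each planted array on either side is forced to break the repeat period, so
the recorded truth intervals are exact rather than "exact up to chance
continuation"; recall and overlap assertions in the tests rely on this.
Imperfect arrays are substitution-corrupted at per-base rate
$(100 - \text{percent\_match})/200$ (each substitution breaks two
adjacent-copy comparisons), which lands the realised percent match near
the target without modelling indels — consistent with the gap-free
scanner.

## Numerical and testing choices

* Everything is deterministic given a seed; simulators accept an explicit
  `seed` and identical seeds give byte-identical outputs, including the
  written report files (provenance JSON carries no timestamps for this
  reason).
* Test problem sizes: orbit oracles enumerate all $4^k$ strings for
  $k \le 6$; scanner properties use 10–20 kb planted genomes; estimator
  calibration uses 500 replicate loci × 82 lines and CI coverage 1000
  simulated loci. These sizes give sub-minute suites while keeping Monte
  Carlo assertions at 3-standard-error tolerances.
* Tie-breaks are all specified (lexicographic canonical form; overlap
  resolution by score, then unit length, then position) so no result
  depends on storage order.
* Degenerate inputs: empty sequences and empty call sets propagate as
  empty tibbles / all-zero spectra; out-of-bounds loci, overlapping
  planted arrays, saturated estimators and off-ladder alleles raise or
  flag as documented rather than producing silent numbers.

## Known limitations

* The scanner is not a drop-in replacement for probabilistic
  tandem-repeat finders on real genomes; on imperfect loci its boundaries
  and scores follow the contract above, not any published tool's
  internals. Genome-scale composition figures from different detectors
  are not directly comparable.
* The zero-class estimator ignores homoplasy; at the rates and durations
  typical of MA panels this is negligible, but the simulator can generate
  regimes ($\mu t \sim 1$) where it is not.
* One recorded inconsistency in the packaged panel is preserved as data:
  the per-locus arithmetic for marker M88 yields a net decrease of 4
  units, and the package reports what the arithmetic gives.
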