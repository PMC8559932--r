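---
title: "Methods: splicing screens and branch-point calling in lariatuss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing screens and branch-point calling in lariatuss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lariatuss)
```

## Scope and model

`lariatuss` quantifies how splice-site selection shifts between two
conditions — typically a wild-type and a spliceosome mutant (e.g. an SF3B1
HEAT-repeat substitution, which alters branch-site selection by U2 snRNP) —
at three levels:

1. **Event level.** Alternative-splicing events of five types (skipped exon,
   retained intron, alternative 5'/3' splice site, mutually exclusive exons)
   are extracted from annotation by pairwise isoform comparison, quantified
   as PSI (percent spliced in) from junction counts, and screened for
   differential splicing.
2. **Site level.** Every individual donor (5'SS) and acceptor (3'SS) gets a
   usage statistic (USS) computed from read coverage in paired 40-nt
   windows flanking the exon/intron boundary, screened for differential
   usage, then related back to the event screen by an enrichment test and
   to sequence strength by a position-weight model.
3. **Nucleotide level.** Branch points (BPs) are called per sequenced
   lariat-derived clone by locating the junction where the read jumps from
   an internal intron position to the intron 5' terminus, and aggregated
   into per-strain BP usage frequencies.

A synthetic-data generator produces toy genomes, count tables and lariat
read sets with known truth, so every stage is verifiable end to end without
any external sequencing data.

## Coordinate conventions

Internally all intervals are 0-based half-open; GTF I/O converts to/from
1-based closed coordinates at the boundary of the package. A splice-site
*boundary* is the position of the first intronic base (donor) or last
intronic base (acceptor), so `-1` style offsets and window arithmetic have
a single unambiguous anchor. On the minus strand the donor sits at the
genomic right edge of the intron; all windows and sequences returned by
`fetch_window()` are reported on the transcribed strand.

Non-canonical terminal dinucleotides are recorded and flagged, never
filtered: branch-point analyses themselves report non-adenosine branch
nucleotides, and dropping non-GT/AG sites would silently bias the site-level
screens.

## PSI: quantification and screen

For an event with inclusion junction set $I$ and skipping set $S$,
$\mathrm{PSI} = \frac{\sum_{j \in I} c_j}{\sum_{j \in I} c_j + \sum_{j \in S} c_j}$
on raw junction counts, undefined (and flagged) at zero depth. This is a
junction-count estimator without effective-length normalization: the
package's inputs are junction counts, for which length weights are moot;
the divergence from length-normalized estimators matters only if counts
are derived from coverage.

Per-type conventions where a choice was required: retained-intron inclusion
evidence is a direct exon–intron boundary-support count (the simplest count
with the right monotonicity — retention up means more boundary-spanning
coverage); for alternative 5'/3' events the long-exon form (alternative
site closer to its partner across the intron) is "inclusion"; for mutually
exclusive exons the exclusive exon upstream on the transcribed strand is
"inclusion".

The differential screen pools counts within condition and tests each event
with a two-sided Fisher exact test on the 2x2 inclusion/skipping table,
followed by Benjamini–Hochberg correction over all tested events. The
significance contract is $|\Delta\mathrm{PSI}| > 0.05$, FDR $< 0.05$, and
supporting reads $\ge 5$; "supporting reads" is the minimum over samples of
inclusion+skipping, the most conservative of the per-sample/per-condition
readings, and is configurable. Pooling rather than replicate-level modeling
is deliberate: the screen's contract is its thresholds, and a hierarchical
replicate model would change the statistic without changing the interface;
the pooled exact test is exactly reproducible against enumeration oracles.

Distances between the two defining sites of significant RI/A5SS/A3SS events
(intron length, donor separation, acceptor separation respectively) are
binned in 30-nt bins anchored at 20 nt (…, 20, 50, 80, 110, …), so the
biologically salient 50–80 nt short-intron band is a single bin; bins are
configurable via `breaks`.

## USS: site usage from paired coverage windows

For a 5'SS, `a` is the read coverage in the last 40 nt of the upstream exon
and `b` the coverage in the first 40 nt of the intron (mirrored for a
3'SS). The default usage formula is the exonic share

$$\mathrm{USS} = \frac{a}{a+b},$$

which is 1 for a fully spliced intron (no intronic coverage), 0.5 at equal
coverage, bounded in [0,1], and strictly decreasing in `b`. The exact
formula used by the original tool is published separately and not restated
in the source work, so the formula here is a named, pluggable strategy
(`exonic_share`, default; `one_minus_ratio` = $1-b/a$ clipped to [0,1]) and
is recorded with the results. This is the module's largest documented
assumption.

Coverage is consumed as a per-window aggregate count; windows shorter than
40 nt (short exons or introns — common in flies, where many introns are
well under 40 nt) are truncated to the available length, tested, and
flagged `short_window` rather than dropped. Undefined sites (a+b = 0) are
excluded rather than smoothed, keeping the estimator unbiased.

The screen again pools per condition, tests the (a, b) x condition table
with the Fisher exact test, and computes **both** published flag variants —
raw p < 0.05 and FDR < 0.05, each with $|\Delta\mathrm{USS}| > 0.01$ —
because the source conventions differ between the methods text and the
figure legend; FDR is the default `significant` flag and both appear in the
output.

**Enrichment.** For each event type and site kind, sites are cross-tabled
as usage-changed vs participating in a significant differential event of
that type, tested exactly, BH-corrected across the ten strata. Strata with
an empty margin yield NA (the conditional odds ratio is undefined there).

## Splice-site strength

Strength is scored on the usual donor/acceptor windows: 9 nt for donors (3
exonic + 6 intronic) and 23 nt for acceptors (20 intronic + 3 exonic). The
native scorer is a log-odds position-weight model trained on window
sequences: per-position base frequencies with pseudocount 0.5, log2 odds
against a background defaulting to the training set's overall composition.
Published maximum-entropy score tables are external data and are not
re-derived; the PWM keeps the identical window convention, and externally
computed per-sequence score tables can be swapped in wherever scores enter
(`summarize_by_group()` takes plain numeric scores). Scores are in bits;
non-ACGT positions contribute 0 and flag the sequence. Models round-trip
bit-exactly through a TSV with `#` metadata lines.

Group comparisons (usage-decreased / unchanged / usage-increased, via
`usage_groups()`) report n, mean, median and SE per group plus pairwise
two-sided Wilcoxon rank-sum tests, BH-corrected. The rank test is this
package's documented choice; the source work names no test for its score
comparisons.

## Branch-point calling

A lariat-derived cDNA reads through the 2',5'-phosphodiester bond: the read
is an intron segment ending at the BP joined to the intron 5' terminus.
Reverse transcriptases frequently misread the branch adenosine, producing
the diagnostic A-to-T substitution at the junction base.

The caller searches both orientations (cloning orientation is arbitrary)
and every split position k and BP position p, scoring
`read[1..k]` against the intron segment ending at p and `read[k+1..]`
against the intron prefix starting **exactly** at base 1 — the bond joins
the BP to the intron's first base, so no slack is allowed there. A
mismatch at the BP is free only as the A-to-T signature; at a non-A BP the
junction base must match exactly, keeping non-adenosine branch nucleotides
(-54U, -16G style calls) reachable without special-casing. A call requires
both anchors >= `min_anchor` (default 8 nt) and non-BP mismatches <=
`max_mismatch` (default 1) — Sanger-quality defaults, both configurable.

Tie-breaking is deterministic and conservative: maximal total matches,
then the longest exact-match run of the 5'-terminus anchor, then the BP
closest to the 3' splice site; equal-scoring orientations that disagree on
the BP are reported `ambiguous` with both candidates rather than silently
chosen. Offsets are reported relative to the intron 3' end (-1 = last
base) and labels use the RNA display convention (`-25A`, `-54U`).
Frequencies aggregate over called clones only, with ambiguous/unalignable
tallies alongside — matching how subclone counts are reported in practice,
with no read-quality weighting.

The caller is implemented with match-matrix diagonal cumulative sums
(O(read x intron) per orientation); the test suite holds it to 100%
agreement with a naive exhaustive search over every orientation, split and
BP position on 1,000 random pairs.

## The synthetic generator

`make_toy_genome()` emits one chromosome per gene, each carrying exactly
one designed event encoded by an isoform pair, GT/AG consensus planted at
every intron end, strand drawn at random (so minus-strand arithmetic is
always exercised), and truth tables for event PSI, site USS and defining
coordinates. Defaults: exons 80–200 nt, introns 80–300 nt, alternative-site
shifts 6–40 nt, control PSI ~ U(0.35, 0.65), control USS ~ U(0.6, 0.95),
effect sizes zero (the null) unless planted explicitly — realistic middling
values that leave room for planted shifts in either direction.

`simulate_counts()` draws the event read total Poisson(depth), inclusion
Binomial(total, PSI), and splits counts multinomially across an event's
junction keys, so junction-set sums reproduce the event count exactly —
the documented inversion that keeps the PSI estimator's truth well-defined.
Window counts are drawn with total Poisson(2 x depth) and exonic share
Binomial(total, USS), the exact inversion of the default USS formula.

`simulate_lariat_reads()` composes each clone as
`intron[bp-L1+1..bp] ++ intron[1..L2]` with anchor lengths drawn uniformly
from `anchor_range` (default 8–16 nt, keyed to `min_anchor` — the minimum
informative anchor up to twice that, matching the short nested-PCR
amplicons of the protocol), applies the A-to-T signature with probability
`a2t_rate` (default 0.7: the misincorporation is described as frequent but
unquantified, so the rate is configurable and recorded in truth), uniform
substitution errors at `error_rate` elsewhere, and reverse-complements half
the clones by default.

What the generator does **not** emulate: positional coverage bias, PCR
duplicates, fragment-length effects, read-level quality profiles, RTs that
skip the branch base entirely (deletion rather than substitution), and
genuinely novel junctions absent from annotation. Passing tests therefore
demonstrate correctness of the statistics and the caller under clean
sampling models, not robustness to alignment artifacts in real libraries.

## Numerical choices and degenerate inputs

* All exact tests route through one Fisher-test path
  (`fisher_p_2x2()`), which the suite checks against full hypergeometric
  enumeration on every 2x2 table with margins <= 30.
* BH correction is applied within each screen's tested subset; untestable
  records keep NA p-values and are reported, never dropped silently.
* PSI/USS are NA (flagged) at zero depth; `uss = 1` exactly when `b = 0`,
  `a > 0`.
* Duplicate transcripts collapse with a warning; abutting exons (zero-length
  introns) are a validation error; windows that would leave the chromosome
  raise boundary errors instead of truncating silently.
* Event deduplication is by type + defining coordinates, so shared events
  across isoform pairs are counted once and counts are never double-assigned.

## Problem sizes used in the checks

The recovery and calibration suite (and `scripts/acceptance.R`) uses sizes
chosen to give tight Monte-Carlo bounds while staying desk-scale: 1,000
random read/intron pairs for oracle agreement; 10,000 clones for BP
frequency recovery (multinomial SE < 0.005) plus 1,000 replicate 12-clone
strains for ranking; a 9-point PSI grid x 1,000 replicates at depth 100
(binomial SE 0.005 per point); 1,000-gene null genomes (~1,000 events,
~4,000 sites) for screen calibration; 400/170 genes for screen power;
120-gene genomes for the distance analysis; 100-gene genomes for
enrichment; and n = 1,000 training draws for PWM recovery (per-cell
sampling SE <= 0.01 at the planted 0.91/0.03 composition, so the +/- 0.03
check has ~3-sigma headroom).

## Known limitations

* The USS formula is a documented stand-in for an unpublished variant; all
  conclusions drawn from USS values should treat the formula strategy as
  part of the result's metadata.
* The pooled Fisher screens do not model biological replicate dispersion;
  with few, deep replicates they will be anti-conservative relative to a
  replicate-aware model. The null-calibration test bounds the practical
  consequence under the sampling model only.
* The PWM scorer assumes position independence; maximum-entropy models with
  pairwise dependencies will rank borderline sites differently. External
  score tables can be substituted where that matters.
* The branch-point caller is designed for targeted amplicon reads; it is
  not a genome-wide lariat discovery tool.
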