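---
title: "MetaTide: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MetaTide: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaTide)
```

MetaTide analyses time-series shotgun metagenomes of seawater sampled
at fixed coastal stations. This vignette is the package's own account
of the methods: what each stage assumes, which parameters matter and
why they default as they do, what the synthetic generators emulate,
and where the design was genuinely open.

## Copies per liter

The quantification stage converts a contig's mapped-read count into an
absolute molecule count per liter:

$$
\mathrm{copies/L} \;=\; m_{\mathrm{DNA}}
\cdot \frac{n_{\mathrm{mapped}}}{n_{\mathrm{total}}}
\cdot \frac{6.02\times 10^{23}}{616 \cdot L_{\mathrm{bp}}}
\cdot \frac{1}{V}
$$

The model assumes the extracted DNA mass is partitioned across targets
in proportion to their mapped-read fraction, i.e. no mapping or
extraction bias and uniform read sampling along the genome. The
constant 616 g/mol is the average molar mass of one double-stranded
base pair, so the fraction `mass / (616 * length)` is moles of target
molecule, and Avogadro's number turns moles into molecules. Both
constants are exposed as arguments (`avogadro`, `bp_molar_mass`) for
sensitivity analyses.

Units matter: DNA mass is carried in **grams** internally
(`readSampleMeta()` converts a `total_dna_ng` column), volume in
liters, length in bp. The formula is applied at *contig* granularity
when building the abundance matrix — abundance patterns must exist
before MAGs can be formed from them — and can be re-applied at MAG
granularity (summed member length) on the summed profiles afterwards.

Only reads with identity **strictly above 0.90** count
(`filterAlignments()`); the boundary is deliberately exclusive, and a
read at exactly 90% identity is dropped. When `top_n` truncation is
requested, contigs rank by total mapped count with lexicographic ids
breaking ties, so the output is reproducible under input permutation.

## Canopy clustering into MAGs

Contigs are grouped by the shape of their appearance pattern alone —
Pearson correlation of the raw copies-per-liter vectors, no
composition features. The procedure (`canopyCluster()`) is a greedy
seeded canopy:

1. order candidate seeds by total abundance (descending, ties by id);
2. the first unassigned contig seeds a canopy, which gathers every
   unassigned contig with $r \ge 0.95$ to the canopy profile;
3. the centroid (mean member row) is recomputed and membership
   re-gathered until a fixed point (the seed always stays a member);
4. members leave the pool; repeat from 2.

At the fixed point every gathered member correlates at or above the
threshold with the final centroid, which makes the membership
condition assertable after the fact. Zero-variance (flat) profiles
have undefined correlations; they never seed and are reported
`unclustered` rather than forced into a bin. Correlation is computed
on raw values by default because the appearance pattern is the signal;
`log1p = TRUE` is available where heavy-tailed abundances dominate.
Centroid refinement can be disabled (`refine = FALSE`) to gather once
against the seed profile — the default refines, since a centroid is a
less noisy template than any single contig.

The threshold `r_threshold = 0.95` is inclusive ($\ge$). A minimum of
3 samples is required for a defined correlation to be meaningful at
all; in practice a seasonal series of 25 monthly samples is the
intended regime.

## CCP: classification by clustering with Pfam

A MAG's Pfam profile is the integer count of each domain accession
summed over member contigs. Classification correlates the query
profile against each reference genome's profile **over the union of
accessions present in either**, with absences as zeros. The union
matters: correlating only shared accessions would inflate the score of
references that share just a handful of domains with the query.
Alternatives (presence/absence via `binary = TRUE`) are exposed for
sensitivity analysis; counts are the default because domain copy
number is part of the signature.

Decision rules, all deterministic:

* best defined correlation wins;
* exact ties break by the larger number of shared accessions, then by
  lexicographic genome id;
* queries with fewer than `min_domains = 5` total domain instances are
  `unclassified` — a Pearson coefficient supported by fewer than five
  points is noise, and an honest "unknown" beats a confident guess;
* references with empty profiles are kept in the database but flagged,
  and can never win.

The reference database serializes to a single JSON archive
(`saveReferenceDb()`); reloading reproduces it bit-identically, which
the tests assert by re-serializing.

## BLAST aggregation and LCA

The BLAST route keeps hits with bit score **strictly greater than
100**, optionally restricts to hits within 10% of the best bit score
(`top_percent`), and assigns the deepest taxonomy node shared by all
participating lineages. Lineages under incompatible superkingdoms
collapse to a synthetic `root` node, still counted as assigned.
Taxonomy resolution (accession to lineage) is an upstream input — this
package consumes lineage strings and never touches taxonomy dumps.

MAG-level BLAST annotation adopts the assignment of the **longest**
member contig, including its `no_hit` status: the rule is
longest-only, never a vote, so a MAG whose longest contig is dark
stays dark even when shorter members were annotated.

Composition tables are rescaled to sum exactly to 1000 (optionally
dropping the no-hit bin) by largest-remainder rounding with
name-ordered tie-breaks, so stacked time-series panels are comparable
across sampling depths and the total is conserved exactly — a property
the tests check on a thousand random inputs.

## Tandem-repeat scanning

A repeat run is a maximal stretch of at least two tandem copies of a
primitive 2–10 bp unit; partial trailing copies count in whole bases,
`N` breaks runs, and maximality means one more base in either
direction would break the period. Primitivity (the unit is not a power
of a shorter unit) guarantees each repeat region is reported exactly
once, at its fundamental period: a $(TA)_4$ stretch is one unit-2 run,
not also a unit-4 "TATA" run.

Units are grouped by **rotation class** — TAG, AGT and GTA describe
the same tandem repeat, differing only in reading frame — and named by
the lexicographically smallest rotation (reports also carry the full
alias list, since the field labels these repeats by a conventional
representative such as TAG). Reverse-complement classes (TAG vs CTA)
are *not* merged: strand identity is informative, e.g. when designing
a hybridization probe against one strand.

A read is a repeat read when the coverage of its best class strictly
exceeds 70 bases per 100 bp of read; for reads of other lengths the
threshold scales proportionally (strict `>` at 70% of read length).
Coverage unions all runs of a class within the read, so two phases of
one rotation class combine. Reads more than half `N` are skipped but
still counted in the denominator of sample summaries.

The scanner is validated against an exhaustive brute-force oracle that
re-derives coverage by extending every start offset at every unit
length — a deliberately naive, structurally different computation —
with exact agreement required on a thousand seeded reads.

## Periodicity classes

Peaks are strict local maxima (endpoints tested one-sided) of positive
height, with a floor at 10% of the series maximum to ignore noise
bumps; both knobs (`min_height_frac`, and the recurrence parameters
below) are explicit arguments. Dates are mapped to calendar month
indices, with mid-month sampling dates rounding to the nearest month.

A peak *recurs* when another peak of at least `recurrence_frac = 0.25`
of its height appears $12 \pm 1$ months later. The series span divides
into year windows from the first sample; a window is covered when a
peak in it recurs. Two boundary decisions:

* **Missing peak**: a year window with no peak at all is a *failed*
  transition — an absent annual bloom is precisely what distinguishes
  an incomplete cycle from a complete one.
* **End censoring**: a peak whose one-year-later date falls beyond the
  observed span cannot demonstrate recurrence and is not required to;
  a window holding only such censored peaks still counts as covered.
  Without this, any series whose final annual peak sits near the end
  of the record would be demoted on grounds of missing data rather
  than missing biology.

Classes: `COMPLETE_CYCLIC` (every window covered and at least one
recurrence observed), `INCOMPLETE_CYCLIC` (some but not all),
`TRANSIENT` (exactly one peak), `IRREGULAR` (two or more peaks, no
recurrence; degenerately, a peakless series, with a warning). Scaling
a series by a positive constant never changes its class, and raising
`recurrence_frac` can only demote along COMPLETE → INCOMPLETE →
IRREGULAR — both properties are tested.

## Digital DNA chip

The DDC stage is a deliberately simple re-implementation of the
chip *view*: a probe is positive when at least `min_hits = 1` read
contains it (up to `max_mismatches = 0` Hamming mismatches, either
strand), positives vote per label category, and the chip renders as a
near-square grid (748 probes on 28 × 27 with blanks), `#`/`.` in text
or red/black in a plain-text P3 pixmap. Probe *derivation* — how
environment-associated sequences are selected in the first place — is
out of scope; probes are an input artifact, and no claim of
equivalence to any proprietary probe-selection system is made.

## Synthetic generators: what they emulate, and what they do not

All generators are deterministic given an integer seed.

* `simulateRepeatReads()` plants runs covering strictly more than 70%
  of the read in exactly `round(p * n)` reads and rejection-samples
  the background until it contains no qualifying run, so the planted
  fraction is exact by construction — the scanner closing the loop on
  `p` tests the scanner, not the generator's luck.
* `simulateCommunityTimeSeries()` defaults to the study-scale
  conditions used throughout the tests: 500 contigs in 20 MAGs over
  25 monthly samples, lognormal multiplicative noise at CV 0.1
  (positive, heavy-tailed — the standard model for coverage noise),
  contig scales lognormal. Each MAG's template is an archetype shape
  plus a MAG-specific additive exponential fingerprint, which keeps
  within-MAG profiles perfectly correlated while separating MAGs that
  happen to share an archetype and phase (pairwise template
  correlation is redrawn up to 20 times toward < 0.8).
* `simulatePatternBank()` generates the four temporal archetypes —
  annual cycle, cycle missing its final year, single pulse, two
  unrelated pulses — at 25 series per class and CV 0.1. Cyclic plants
  are anchored at phase 0–1 and the incomplete plant's missing peak is
  placed inside the window: over a 25-month record, a "missing" third
  peak dated after the record ends would be censoring, not biology,
  and carries no recoverable truth.
* `simulatePfamProfiles()` draws 50 reference genomes as sparse
  multinomials over a 100-domain vocabulary (support 30–70%,
  Dirichlet(1) concentrations, totals 300–800), then thins a source
  profile binomially at retention 0.5 with 2% uniform contamination
  per query.

What the fixtures do **not** emulate: real mapping ambiguity and
chimeric contigs; phylogenetic correlation among reference Pfam
profiles (real genera share domain architecture far more than
independent multinomials do); sequencing error inside repeat runs;
gaps and irregular spacing in the sampling calendar; and any realistic
probe-environment association. Passing the recovery tests therefore
demonstrates the algorithms implement their rules correctly and are
robust to the stated noise — not that field data of equal size would
classify as cleanly.

## Problem sizes and runtime

The test suite and the acceptance script run at the sizes quoted
above (1000-read oracle comparisons, 500 × 25 clustering, 200 CCP
queries, 100 periodicity series, 1000 normalization draws), which keep
a full run within a couple of minutes on one core while leaving each
recovery check a real test rather than a toy.

## Known limitations

* The canopy procedure is order-dependent by design (greedy,
  deterministic); a different seed order can partition borderline
  contigs differently. The by-abundance default makes the strongest
  signals seed first.
* Pearson correlation on raw counts is sensitive to a single dominant
  sample; `log1p` mitigates but changes the clustering geometry.
* The LCA implementation treats lineages as plain paths; ranks are
  positional, and no attempt is made to reconcile conflicting rank
  vocabularies between reference databases.
* Month arithmetic assumes roughly monthly sampling; series sampled
  much more finely should be aggregated to months first.
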