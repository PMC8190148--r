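# MetaTide

Tools for **long-term time-series shotgun metagenomics of seawater**:
from read-mapping summaries to absolute contig abundances, co-abundance
MAGs, Pfam-profile taxonomy, tandem-repeat content, seasonal-pattern
classes, and a digital-DNA-chip view of a sample. The package is aimed
at microbial ecologists monitoring coastal stations with regular
(e.g. monthly) sampling, where the temporal axis itself carries the
signal: contigs that rise and fall together across the series belong
together, and annual recurrence of a genome's abundance peak is an
ecological observable.

Everything runs offline: seeded synthetic-data generators produce every
input with known ground truth, so the full pipeline is testable without
any download.

## What it computes

**Absolute abundance.** Mapped reads with identity strictly above 90%
are counted per contig and sample, and converted to molecules per liter
of seawater:

```
copies/L = m_DNA * (n_mapped / n_total) * N_A / (616 * L) * 1 / V
```

with `m_DNA` the sample's extracted DNA mass (g), `N_A = 6.02e23`
molecules/mol, `616` g/mol the average molar mass of a double-stranded
base pair, `L` the target length (bp), and `V` the filtered water
volume (L).

**Co-abundance MAGs.** Contigs whose abundance patterns correlate at
Pearson r >= 0.95 are grouped into metagenome-assembled genomes by a
deterministic greedy canopy procedure with centroid refinement
(`canopyCluster()`).

**CCP taxonomy.** Classification by Clustering with Pfam: each MAG's
Pfam domain-count profile (summed over member contigs) is correlated,
over the union of accessions, against per-genome reference profiles;
the reference genome with the highest correlation supplies the
taxonomy (`ccpClassify()`). A BLAST/LCA route (`filterHits()` with bit
score > 100, `lcaAssign()`, longest-contig MAG annotation) and an
agreement report (`annotationAgreement()`) sit alongside it.

**Tandem repeats.** Reads are scanned for maximal runs of primitive
2-10 bp units grouped by rotation class; a read whose best class
covers strictly more than 70 bases per 100 bp of read is a repeat read
(`classifyReads()`, `summarizeRepeatSample()`).

**Periodicity.** Per-series peaks are detected, and a peak "recurs"
when a peak of >= 25% of its height appears 12 +/- 1 months later;
series are classified COMPLETE_CYCLIC / INCOMPLETE_CYCLIC / TRANSIENT
/ IRREGULAR (`classifyPeriodicity()`).

**Digital DNA chip.** Reads are hybridized in silico against
environment-labelled probes; positive spots vote for environmental
labels (filter fraction, station, month, ...), rendered as a
microarray-like grid (`digitalHybridize()`, `inferEnvironment()`,
`renderChip()`).

## Worked example

```r
library(MetaTide)

# one contig's absolute abundance: 50 ng DNA, 1200 of 10M reads mapped,
# 35 kb contig, 9 L of seawater
copiesPerLiter(total_dna_g = 50e-9, mapped_reads = 1200,
               total_reads = 1e7, target_length_bp = 35000,
               water_volume_L = 9)
#> [1] 18614.72

# planted community -> canopy MAGs
sim  <- simulateCommunityTimeSeries(n_contigs = 120, n_mags = 8, seed = 4)
mags <- canopyCluster(sim$abundance, contigs = sim$contigs)
mags
#> MAGSet with 8 MAGs over 120 contigs; 0 unclustered
#>   r threshold: 0.95

# seasonal-pattern classes on a small archetype bank
bank <- simulatePatternBank(n_per_class = 2, cv = 0.1, seed = 4)
classifyPeriodicity(bank$series, bank$dates)[, c("mag_id", "class")]
#>   mag_id             class
#> 1 ts_001   COMPLETE_CYCLIC
#> 2 ts_002   COMPLETE_CYCLIC
#> 3 ts_003 INCOMPLETE_CYCLIC
#> 4 ts_004 INCOMPLETE_CYCLIC
#> 5 ts_005         TRANSIENT
#> 6 ts_006         TRANSIENT
#> 7 ts_007         IRREGULAR
#> 8 ts_008         IRREGULAR

# repeat reads: 7.5% of reads planted with a (TAG)n repeat
sim2 <- simulateRepeatReads(n_reads = 1000, repeat_fraction = 0.075,
                            seed = 4)
summarizeRepeatSample(classifyReads(sim2$reads), "C5_5-20um")
#>   sample_id unit_class   rotations repeat_reads total_reads fraction rank
#> 1 C5_5-20um        AGT AGT/GTA/TAG           75        1000    0.075    1
```

The interpretation: the 35 kb contig is present at ~1.9e4 copies per
liter; the clustering recovered all eight planted genomes; each
temporal archetype was labelled correctly; and 7.5% of the sample's
reads are dominated by the TAG rotation class (reported under its
canonical rotation AGT, with the full alias list).

A command-line wrapper over the same functions is installed at
`inst/scripts/metatide-cli.R` (subcommands `quantify`, `cluster-mags`,
`ccp-build-db`, `ccp-classify`, `lca`, `scan-repeats`, `periodicity`,
`ddc`, `simulate`).

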