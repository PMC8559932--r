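# lariatuss

Splice-site selection analysis for two-condition RNA-seq designs — e.g. a
wild-type strain versus a spliceosome mutant whose SF3B1 HEAT-repeat
substitution shifts branch-site choice — plus branch-point identification
from lariat RT-PCR sequencing. It is written for researchers who have
junction counts and coverage windows (or want simulated ones) and need the
full chain from annotation to screened, enriched, strength-scored results.

## What it computes

**Event screen (PSI).** Five event types (SE, RI, A5SS, A3SS, MXE) are
extracted from annotation by isoform-pair pattern matching. For inclusion
and skipping junction sets *I*, *S* with counts *c*:

    PSI = Σ_{j∈I} c_j / (Σ_{j∈I} c_j + Σ_{j∈S} c_j)

Differential events are screened by a pooled two-sided Fisher exact test
with Benjamini–Hochberg correction and flagged at |ΔPSI| > 0.05,
FDR < 0.05, supporting reads ≥ 5 (all configurable). Distances between the
two defining sites of significant RI/A5SS/A3SS events (intron length /
donor separation / acceptor separation) are histogrammed in 30-nt bins so
short-intron enrichment bands such as 50–80 nt are directly visible.

**Site screen (USS).** Each donor and acceptor is scored from paired 40-nt
coverage windows flanking the boundary — `a` exonic, `b` intronic:

    USS = a / (a + b)        (1 = fully spliced intron, 0.5 = equal coverage)

with a Fisher exact screen at |ΔUSS| > 0.01 and both FDR- and raw-p flags.
Usage-changed sites are tested for enrichment within each differential
event type (odds ratio + exact p per type × site kind).

**Strength.** A trainable log-odds position-weight model scores the 9-nt
donor window (3 exonic + 6 intronic) and the 23-nt acceptor window (20
intronic + 3 exonic), with per-usage-group summaries and rank tests;
externally computed score tables can be substituted.

**Branch points.** For lariat-derived reads (`intron[bp-L1+1..bp] ++
intron[1..L2]`), the caller searches both orientations and all splits for
the placement maximizing matches, where a BP mismatch is tolerated only as
the A→T reverse-transcription signature of the 2′,5′-phosphodiester bond;
non-adenosine branch nucleotides are called exactly. Offsets are reported
from the intron 3′ end (−1 = last base) with RNA-style labels (`-25A`,
`-54U`), aggregated into per-strain usage frequencies.

A synthetic-data generator (`make_toy_genome`, `simulate_counts`,
`simulate_lariat_reads`) produces genomes, annotation, count tables and
read sets with known truth, so the whole pipeline is testable offline.

## Worked example

```r
library(lariatuss)

toy <- make_toy_genome(30, seed = 42, delta_psi = -0.2)   # mutant PSI down 0.2
cnt <- simulate_counts(toy$truth, n_replicates = 3, depth = 200, seed = 43)
ev  <- extract_events(toy$models)
psi <- differential_psi(ev, cnt$junctions, "control", "mutant")
head(psi[psi$significant, c("event_id","type","psi_a","psi_b","delta_psi","fdr")], 3)
#>                      event_id type     psi_a     psi_b  delta_psi          fdr
#>  A5SS:chr001:+:257:244:472:NA A5SS 0.4469565 0.2648026 -0.1821539 8.299607e-11
#>   SE:chr002:-:533:702:237:929   SE 0.4268908 0.2394881 -0.1874026 2.529759e-11
#>   SE:chr003:+:518:629:234:889   SE 0.6293823 0.4177852 -0.2115971 4.603170e-13
```

All 30 planted events are recovered with the correct negative sign; `psi_a`
/ `psi_b` are the pooled per-condition PSI estimates and `fdr` the
BH-adjusted Fisher p-value. Branch points from a 12-clone lariat set on the
first gene's intron:

```r
sites <- enumerate_splice_sites(toy$models)
iseq  <- intron_sequence(toy$genome, "chr001", toy$models[[1]]$strand,
                         sites$intron_start[1], sites$intron_end[1])
rs    <- simulate_lariat_reads(iseq, c(`-25` = 0.6, `-54` = 0.4),
                               n_clones = 12, seed = 44)
calls <- call_branchpoints(rs, iseq)
aggregate_bp(calls, intron_ref("demo", iseq), "mutant")$table
#>  bp_offset ref_base label count  frequency
#>        -54        G  -54G     1 0.08333333
#>        -25        C  -25C    11 0.91666667
```

All 12 clones are called; the 11/1 split against the 0.6/0.4 truth is
ordinary 12-clone sampling noise — exactly why per-strain frequencies are
reported with clone counts. `run_pipeline(default_config())` runs the whole
chain (simulate → PSI → USS → enrichment → strength → lariat) into an
output directory with a checksummed manifest.

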