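# concatemeR

Consensus eccDNA calling from rolling-circle-amplified (RCA) Nanopore
long reads.

Small extrachromosomal circular DNAs (eccDNAs) — apoptosis-derived circles
built from one to several chromosomal fragments — can be read out by
amplifying each circle with phi29 polymerase into one long linear molecule
containing many tandem copies ("passes") of the template, and sequencing
those concatemers on a long-read platform. Aligned back to the genome, each
read decomposes into a train of sub-reads whose cyclic pattern betrays the
circle that produced it. `concatemeR` reconstructs those circles from the
alignments, for anyone building or benchmarking an eccDNA catalog from RCA
long-read libraries.

## What it does

Given PAF alignments (minimap2 dialect, with `cs` difference strings) and
the reference FASTA, the caller works read by read:

1. **filter** — sub-reads with mapping quality < 30 are discarded;
2. **cluster** — sub-read loci are grouped greedily; two sub-reads map to
   the same locus when both start and end agree within 20 bp (same
   chromosome and strand);
3. **concordance** — the cluster labels in read order must be the periodic
   extension of one fragment cycle (any rotation: RCA phase is random);
   reads with discordant order, location or strand are discarded whole;
4. **vote** — each fragment boundary is the mode of its sub-reads' start
   (resp. end) positions, ties broken by the median of the tied values;
5. **thread** — boundaries are refined so no query gaps or overlaps remain
   between successive sub-reads: for each junction, the median unexplained
   query gap (after threading each sub-read onto the voted boundaries) is
   assigned to the upstream fragment's 3' end;
6. **pass filter** — the number of full passes is the minimum over
   fragments of concordant sub-read counts; circles with fewer than 2 full
   passes are dropped;
7. **consensus** — per-circle variants are called from the stacked passes
   (depth ≥ 4, allele frequency ≥ 0.75) and each circle's full-length
   sequence is emitted as the reference sequence with those variants
   incorporated, rotation-normalised so identical molecules from different
   reads give identical strings.

A catalog layer deduplicates calls into unique eccDNAs (canonical
rotation/orientation of the fragment cycle), counts supporting reads per
molecule (event counts), computes per-base genome coverage of unique
fragments (bedGraph), the fragment-count and event-count distributions,
inter-chromosomal pairing of two-fragment circles, per-chromosome density
(including the X/autosome ratio), and the nucleosomal size periodicity —
the ~188 bp average spacing between peaks of the circle-length histogram.

An RCA **simulator** generates ground-truthed references, circles, reads
and direct PAF records (with controlled boundary jitter, mapping-quality
mix, template variants and Nanopore-like errors on the FASTQ path), so the
entire pipeline is testable without external data.

## Worked example

```r
library(concatemeR)

params <- sim_params(seed = 42, n_circles = 50, jitter = 5,
                     pass_probs = c("3" = 0.5, "4" = 0.5))
sim   <- simulate_rca(params)          # reference + truth + direct PAF
calls <- call_circles(sim$paf)         # reconstruct circles per read
calls
#> eccDNA calls: 58 reads, 58 accepted, 0 rejected

head(as.data.frame(calls), 3)
#>      read_id n_fragments full_passes circle_length
#>  read_000001           1           2           352
#>  read_000002           1           3          1503
#>  read_000003           3           3           361
#>                                                   fragments
#>                                        chr3:287749-288101:+
#>                                            chr1:1853-3356:+
#>  chr2:96082-96208:+;chr2:94166-94287:-;chr2:294645-294759:+

st <- catalog_stats(calls, sim$reference$sizes)
#> unique eccDNAs: 57
#> single-event fraction: 0.982
#> median circle length: 1120 bp
#> X/autosome density ratio: 0.572
```

Each accepted row is one long read resolved into its fragment cycle:
`read_000003` is a non-continuous circle joining three chr2 fragments (one
on the minus strand), sequenced through 3 full passes. The 58 reads
collapse to 57 unique molecules — one circle was sampled by two reads. The
X density is about half the autosomal density because the simulated genome,
like a diploid male genome, carries one X against two copies of each
autosome.

The same workflow runs from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/concatemer.R", package = "concatemeR"))') \
    simulate --out sim --seed 42 --n-circles 50
# then: call --paf sim/alignments.paf --reference sim/reference.fa --out out
# then: stats --calls out/calls.tsv --chrom-sizes sim/chrom.sizes --out out
```

Outputs are plain text: a call TSV, BED12/BED6 circle tracks, consensus
FASTA, a variant TSV, a unique-eccDNA TSV, a coverage bedGraph and a stats
JSON.

## Scope

The package consumes PAF; running the aligner (and upstream basecalling or
trimming) is out of scope, as are short-read pipelines, signal-level
simulation, and karyotype plotting. Circles supported by a single pass are
never called — that is the point of the ≥ 2 full-pass filter.
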