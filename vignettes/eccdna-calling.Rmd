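---
title: "Calling eccDNA from rolling-circle concatemer reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling eccDNA from rolling-circle concatemer reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A small circular DNA amplified by rolling-circle amplification (RCA)
becomes one long linear molecule: tandem copies of the circle, starting at
a random phase. Aligned to the genome, such a read decomposes into
*sub-reads*, one per traversed fragment per pass. If the circle is the
cycle of fragments $(f_1, \dots, f_k)$, the sub-read loci in read order
must follow the periodic sequence
$f_{j}, f_{j+1}, \dots, f_k, f_1, \dots$ for some starting phase $j$. The
caller exploits three consequences:

* **periodicity** is a checkable structural invariant — any violation
  (wrong order, wrong strand, a locus that does not recur) marks a read
  that cannot be explained by one circle, and the read is discarded whole;
* **redundancy** — each boundary is observed once per pass, so boundaries
  can be *voted* (mode across passes) rather than trusted from any single
  noisy alignment, and per-circle sequence variants can be called from the
  stacked passes of a single molecule;
* **conservation** — every base of the circle is sequenced at least
  `full_passes` times, where `full_passes` is the minimum over fragments of
  concordant sub-read counts. Requiring `full_passes >= 2` guarantees every
  reported base and boundary was seen at least twice.

Assumptions: alignments are reported with 0-based half-open coordinates and
short-form `cs` difference strings (minimap2 dialect); sub-read order in
the read equals ascending query start; alignment boundary noise is bounded
(tens of bp), far smaller than the separation between distinct loci of one
circle.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_mapq` | 30 | phred-like | sub-reads below this are discarded before any structure is inferred |
| `max_offset` | 20 | bp | two sub-reads are the same locus when both start and end agree within this; also the partial-flank attachment tolerance and the variant boundary mask |
| `min_full_passes` | 2 | passes | minimum over fragments of concordant sub-read counts for an accepted circle |
| `max_junction_gap` | 50 | bp | largest unaligned query gap a junction may absorb during threading |
| `max_query_overlap` | 20 | bp | largest query-space overlap absorbed during threading |
| `min_depth` | 4 | sub-reads | minimum pileup depth for a variant call |
| `min_af` | 0.75 | fraction | minimum allele frequency for a variant call |
| `boundary_mask` | 20 | bp | variant calls this close to a voted boundary are suppressed |

The thresholds in the first and third blocks are the calling criteria of
the pipeline this package implements; `max_junction_gap`,
`max_query_overlap` and `boundary_mask` are engineering tolerances around
them. The boundary mask exists because junction jitter stacks artifactual
mismatches exactly where two fragments meet; suppressed calls are returned
in the `masked` attribute rather than silently dropped.

## Clustering and voting: determinism choices

Locus clustering is greedy with a *first-seen representative*: walking
sub-reads in rank order, a sub-read joins the first cluster whose
representative (the cluster's first member) matches chromosome, strand, and
both boundaries within `max_offset`; otherwise it seeds a new cluster. This
is deterministic and order-stable; it is not complete linkage, so its
guarantees hold when distinct loci are separated by well over
`2 * max_offset`, which is the regime the biology provides.

Boundary voting is the mode, computed independently for starts and ends.
Ties are broken by the median of the tied values, and for an even tie the
smaller central value — a total order, so identical inputs always give
identical boundaries.

`check_concordance` interprets the pipeline's order-verification step as a
deterministic periodicity test: the label sequence must equal the periodic
extension of its first-appearance cycle. No resampling of any kind is
performed.

## Threading: closing the junctions

After voting, successive sub-reads may leave unaligned query bases at a
junction (the aligner clipped into the junction) or claim the same query
bases twice. For each junction the caller computes, per rank-adjacent
sub-read pair, the *residual* query gap once both sub-reads are threaded
onto the voted boundaries: the raw gap `qstart_next - qend_prev` minus each
side's slack between its aligned end and its fragment's voted boundary. The
median residual is assigned entirely to the upstream fragment's 3' end (in
its strand orientation): extended for a positive gap up to
`max_junction_gap`, trimmed for an overlap up to `max_query_overlap`,
flagged (and left untouched) beyond those tolerances. An adjustment that
would invert a fragment rejects the circle.

Why the residual rather than the raw gap: with per-alignment boundary noise
the raw gap mixes the upstream clip, the downstream clip, *and* the voting
error, and its median is not bounded by the noise amplitude; the residual
is constant across pairs of a junction under per-record jitter, so after
adjustment the recomputed median gap at every junction is exactly zero and
the refined boundary error stays bounded by the voting error. When
alignments are clean (no jitter), the two definitions coincide — a uniform
7 bp query clip at a junction yields a 7 bp extension and exact recovery of
the true boundary.

Junctions are never split between the two fragments: an even split would
create half-base ambiguity, and there is no evidence to apportion the gap.

## Partial flanking sub-reads

A read that starts mid-fragment begins with a truncated copy of that
fragment (and ends with its complement). Such a flank matches an existing
cluster on exactly the boundary it fully reaches — the fragment's 3'
traversal end for a head flank, the 5' end for a tail flank. Flanks vote
only for that boundary, are excluded from the concordance sequence and the
pass counts (they are not full passes), but contribute to the variant
pileup (they are genuine coverage). One failure mode is handled explicitly:
a clipped flank that happens to be the *first* sub-read seeds a cluster and
becomes its representative, and the representative drift can split the full
copies that follow. When concordance fails, the caller retries with the
terminal sub-read(s) excluded; interior discordance — true chimerism —
still rejects the read, and no partial salvage of a discordant read is ever
attempted.

## Circle identity, consensus rotation, and dedup

A circle observed from different reads may start at any rotation and be
traversed in either orientation. Identity is therefore the
lexicographically smallest `(chrom, start, end, strand)` tuple sequence over
all rotations of the forward traversal and of the reverse traversal
(reversed order, flipped strands). The full ordered cycle is the key — two
molecules joining the same fragments in different cyclic orders are
different molecules. Consensus sequences are built in this canonical frame,
so identical molecules give identical strings and deduplication can operate
on either coordinates or sequences. Fragment-level deduplication for
coverage ignores strand and uses exact coordinates only; no fuzzy merging
of near-identical fragments is performed at dedup.

One subtlety follows from canonical orientation: a circle and its
strand-flipped mirror normalise to the *same* canonical sequence. The
reverse-complement relation between opposite traversals is therefore tested
in non-canonical mode, where it holds exactly: for a single fragment,
flipping the strand reverse-complements the consensus; for $k \ge 2$, the
true reverse traversal (order reversed and strands flipped) does.

## The size-interval statistic

Apoptotic eccDNA lengths fall on a nucleosomal ladder with ~188 bp period.
The estimator bins lengths at 1 bp over [0, 3000], smooths with a centered
11 bp moving average, keeps local maxima with topographic prominence of at
least 5% of the global maximum, merges peaks closer than 50 bp (count noise
puts small wiggles on top of each true peak), and reports the mean spacing
of successive peaks. Because the quantity is a *period*, it is reported
only when the spacings are regular (coefficient of variation at most 0.3);
an aperiodic length distribution produces irregular noise peaks and an
explicitly undefined result rather than a meaningless number. Fewer than
two peaks is likewise undefined. Histogram-peak spacing was chosen over
autocorrelation for interpretability (the peak positions themselves are
reported); the regularity gate plays the role that a dominant
autocorrelation lag would play.

## What the simulator emulates — and what it does not

The generator's defaults are the study conditions of an apoptotic mouse
embryonic stem cell eccDNA library:

* circle lengths on a 188 bp lattice with Gaussian dispersion of 15 bp;
  the multiplicity distribution over 1–8 nucleosomal units is chosen so the
  median circle is about 1 kb;
* 1–7 fragments per circle, heavily skewed to single-fragment
  (continuous) circles, default `{1: 0.8, 2: 0.15, 3: 0.05}`;
* fragments placed uniformly, chromosomes weighted by length times a copy
  number multiplier — 0.5 for the X, matching one X against two autosomal
  copies in a diploid male genome;
* reads per circle `1 + Poisson(0.117)`, making ~89% of circles
  single-read;
* per-read random phase and a configurable repetition count; boundary
  jitter as independent uniform ±J on each reported alignment end
  (default J = 5 bp); a mapping-quality mix with a small tail below 30;
  iid substitution/insertion/deletion errors (2% / 1.5% / 2%) on the
  FASTQ path.

Direct-PAF emission is the primary test path: one record per pass per
fragment, query intervals tiling the read, `cs` tags consistent with the
injected template variants and the jittered interval. It deliberately
carries *no* sequencing-error noise — it represents what a competent
aligner reports, so tests isolate the caller's own logic. Injected template
SNVs are placed at least 25 bp from fragment ends where length permits,
because junction-proximal variants are unresolvable by design (the boundary
mask suppresses them).

Features of real data the simulator does not model: homopolymer-structured
Nanopore errors (errors are iid), chimeric ligation artifacts, reference
repeats and multi-mapping ambiguity, and systematic aligner behavior at
junctions (its jitter is random per record, where a real aligner clips the
same junction the same way on every read of the same molecule). Passing
tests therefore demonstrate the decomposition, voting, threading and
catalog logic — not robustness to repeat-induced mismapping.

Two consequences of that last limitation are handled explicitly in how the
package evaluates itself. First, random per-record jitter makes two reads
of the same circle disagree by a few bp, so exact-coordinate deduplication
would count them as distinct molecules; catalog-level statistics (event
counts, single-event fraction) are therefore evaluated on noise-free
alignments, where the voted boundaries reproduce exactly, while boundary
recovery under jitter is evaluated separately. Second, simulated runs that
require every read to be confidently callable use repetition counts of at
least 3, because a random-phase read with R repetitions has only R − 1
full passes of the phase-split fragment.

## Problem sizes and numerical conventions

The test suite exercises: exhaustive concordance over all label sequences
of length ≤ 8 on ≤ 3 symbols; 1,000 random clustering and 1,000 random
voting instances against brute-force oracles; 200-circle noise-free and
200-circle jittered (J = 10 bp, 3–6 passes) recovery batches; a
5,000-circle periodicity batch (σ = 15 bp); a 10,000-fragment density
batch; and end-to-end determinism of simulate → call → stats down to byte
identity of the written files. The acceptance script uses a 200-circle
noise-free batch and a 4,000-circle catalog batch. All randomness flows
from one integer seed; each simulation stage derives its stream with a
fixed offset, so every artifact is reproducible across runs and platforms.

Conventions worth knowing when reading outputs: all in-memory and BED/
bedGraph coordinates are 0-based half-open; the variant TSV reports
positions 1-based; `cs` reference bases follow the forward target strand
regardless of alignment strand; threading medians are rounded
half-to-even to integers; insertions longer than 50 bp in a single cs
operation are treated as unaligned junction sequence and ignored for
consensus; long-form `cs` (and missing `cs`) downgrade a fragment to
reference-only consensus rather than failing the call.

## Known limitations

* Reads whose circles are supported by a single full pass are never
  called; this is the confidence filter, not a defect, but it biases the
  catalog against very long circles relative to read length.
* Exact-coordinate dedup undercollapses when upstream alignment noise
  varies between reads of the same molecule (see above); an
  offset-tolerant merge is deliberately not applied at dedup.
* The caller trusts the aligner's primary/secondary decisions; `tp:A`
  tags are preserved for upstream filtering but not interpreted.
* Variant calling is haploid-circle logic (one allele per position); it
  does not genotype heterogeneous circle populations that share a locus.
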