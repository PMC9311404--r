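---
title: "Detecting spliced-leader trans-splicing and its protein-level consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spliced-leader trans-splicing and its protein-level consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sltscan)
library(dplyr)
```

## The biology and the measurement problem

In spliced-leader trans-splicing (SLTS), a short conserved leader RNA (the
spliced leader, SL) is donated by a non-coding SL RNA onto the 5' end of a
pre-mRNA at a splice-acceptor site. In the photosynthetic amoeba
*Paulinella micropora* KR01 the SL is a 20-nt sequence
(`TGGATAATCCGGCTTTTCTG`); SL addition is not confined to transcript 5'
ends but also occurs at internal acceptor sites, producing 5'-truncated
transcript variants whose predicted proteins may lose targeting signals or
functional domains. `sltscan` implements the complete read- and
transcript-based analysis of this process: motif detection, addition-site
calling from CDS-aligned reads, gene-model misprediction screening,
truncated-variant identification with predicted consequences, a genome
survey for SL RNA loci and mRNA-recycling candidates, and an expression
comparison.

Two evidence streams are used:

* **Reads.** Locally aligned RNA-seq read pairs over predicted CDSs. A
  read carrying the conserved SL region (positions 9--20 of the leader,
  `CCGGCTTTTCTG`, matched exactly; `N` never matches) evidences an
  addition site at the CDS position of the first base after the motif --
  or, when the motif sits wholly in the 5' soft clip, at the first mapped
  base. Because gene models lack UTRs, additions upstream of the start
  codon all collapse onto CDS position 1 (`position_1` sites); this
  conflation is inherent to the design and is documented rather than
  resolved.
* **Assembled transcripts.** A transcript carries the leader if the
  conserved region matches exactly starting within its first 15 bases
  (up to 14 preceding bases tolerated, since leader 5' ends assemble
  poorly); otherwise the reverse complement is tried. The leader and any
  preceding bases are trimmed before downstream alignment.

## Site calling and its filters

Read pairs enter only if both mates are properly paired (SAM flag 0x2),
have at most 5 bp of 3' soft-clipping, and edit distance (NM) at most 5;
5' soft clips of any length are allowed because the leader itself
produces them. A position becomes a site only with **more than 10**
supporting motif reads (strict, i.e. at least 11) and no flagged
mispredicted position within 100 bp. Depth at a site counts retained
reads whose aligned span covers the position, so `support_fraction` is
supporting/covering.

Sites are classified against the gene's exon structure in CDS
coordinates (cumulative CDS-piece lengths): `position_1`, exactly at a
non-first exon start (`precise_junction`), within `near_window` of one
(`near_junction`), or `internal`. The distinction between "at a
junction" and "precisely at the splice site" has no universally fixed
window; we default `near_window = 2` bp and expose it as a parameter.
The sequence context of internal sites (±5 bp, the site base at
relative position 0) is summarised as base frequencies and information
content `2 + sum(f log2 f)` bits per column; sites lacking a full ±5
flank are excluded from the logo, which operationalises "too close to a
transcript end" as exactly the display window.

## Misprediction screening

Ab-initio gene models are often 5'-extended beyond the true transcript;
such regions attract no reads. For an anchor position (a truncation
point or addition site), the region from 100 bp upstream to 50 bp
downstream is scanned with a 20-bp window, step 1. A window fully
spanned by fewer than 10 reads (soft-clipped bases are not aligned and
do not span) flags its 5'-most base. For anchors under 200 bp, the
upstream bound is pulled in to halfway between anchor and CDS start; we
round halfway up (`ceiling(anchor/2)`; the rounding direction is a
package choice). Windows that would extend past the region or CDS end
are not scanned. Manual curation of uneven coverage is *not* automated:
the scanner reports per-region mean NM and a coverage CV as review
aids, and never drops genes on its own.

## Truncated transcripts and their consequences

SL-trimmed transcripts qualify as truncation evidence when

1. their genome alignment has average identity ≥ 95% and ≥ 90% of the
   transcript aligned (inclusive thresholds);
2. their intron chain is identical to the reference gene's (`equal`) or
   a contiguous sub-chain with terminal blocks inside the bounding
   exons (`contained`; a mono-exon transcript inside one exon counts).
   `equal` additionally requires the transcript span to lie within the
   gene's exonic span so that every `equal` case also satisfies the
   containment bounds;
3. a plus-strand transcript-vs-CDS hit starts ≤ 2 bp along the
   transcript, ends past 95% of transcript or CDS (3'-UTR tolerance),
   and starts **strictly** beyond 100 bp along the CDS -- the hit's CDS
   start is the truncation point;
4. the scan around the point is free of flagged windows.

At each point, reads covering it split into SL-evidencing (motif placing
a site exactly there) and the rest: Type 1 if SL reads are the majority,
Type 2 otherwise, with ties going to Type 2 (a tie is not a majority).

Predicted consequences use the first in-frame ATG at or after the point
(`retained_start`, frame `p == 1 (mod 3)`): **C** (translation
suppressed) when none exists or the remaining protein fraction is below
`min_remaining` (default 0.25 -- "significantly shorter" has no stated
cutoff, so it is an explicit, configurable choice); **A** when a
targeting-signal feature lies entirely 5' of the retained start;
**B** when a domain/transmembrane/coil feature starts upstream of it;
**D** when the gene has two or more addition sites. Categories co-occur.
Protein features are merged per kind (interval union, bookended
intervals merge) and converted to CDS space as aa *i* → nt
`3i-2..3i`; the within-feature rule keeps sites strictly more than
60 nt from the feature's 5' end. Nearest-feature ties resolve to the
first feature in sorted order.

## Genome survey and recycling

The survey reports, per strand, every maximal ungapped match between an
SL substring and the genome with length ≥ 8 and ≤ 1 mismatch. A
"maximal" segment starts and ends on matching bases and cannot be
extended to a longer admissible segment; this in-package scanner stands
in for a short-word nucleotide search, and externally produced outfmt-6
tables are accepted interchangeably (`sl_hits_from_blast()`). Hits
ending at SL position 20 are `full` if they start at or before the
species' full-start position (1 for KR01 and *P. ovalis*, 2 for
*P. chromatophora*, whose SL differs at base 1), else `partial` -- the
3' end is the most conserved part, so partial hits must reach it.
Partial hits are padded upstream (strand-aware) to exactly 20 nt for
cross-species comparison; windows truncated by scaffold ends are
discarded.

A gene is an mRNA-recycling candidate when a hit with query coverage
strictly above 70% sits on the gene's strand, 1--99 bp upstream of its
5' end. We additionally require hit and gene strand to agree -- a
recycled copy carries its leader in sense orientation -- and exclude
hits overlapping the gene body; neither detail is forced by the scanner
output, so both are explicit package choices. The source gene's exon
count is reported as a review aid (a true recycled copy is intron-less).

## Expression

Per replicate, `tpm = (count/length) / sum(count/length) * 1e6` from
expected counts and CDS lengths; genes with zero length are excluded
with a warning. Per-gene TPM is averaged across replicates
(arithmetic mean; averaging, not pooling, is the package's reading of
"average TPM across replicates") and compared between genes with and
without addition sites by Welch's unequal-variance t-test, implemented
in closed form (statistic, Welch--Satterthwaite df, two-tailed p) and
cross-checked against `stats::t.test` in the test suite.

## The synthetic data generator

`simulate_slts()` builds a complete dataset with a truth manifest:
multi-exon genes on a two-scaffold genome (defaults: 60 genes, CDS
600--1500 nt, 1--5 exons, ~0.3 Mb total), stranded 2×150 bp read pairs
simulated **directly as CDS alignments** (so no aligner is a test
dependency), planted addition sites at controlled support fractions
(position-1, exon-junction, and internal sites placed immediately after
a planted `AG` acceptor mimic), five construct genes carrying truncation
events with known Category labels (their in-frame ATGs are scrubbed and
re-planted so the retained start is known exactly), 5'-extended
mispredicted gene models with zero coverage over the extension, full and
decayed (3'-anchored) SL loci, recycled intron-less paralogs with a full
leader 20--80 bp upstream, and a gamma-distributed expression difference
(means 62.95 vs 22.72, CV 0.25) between site-bearing and other genes.

Choices a user should know about:

* **Background pairs tile each CDS at evenly spaced fragment starts**
  rather than Poisson sampling. Coverage is then deterministic given the
  config, which keeps window-scan margins stable; it does not emulate
  sampling noise in depth. SL support is added as extra soft-clipped
  pairs at the site, with the count floored at 12 so position-1 sites
  (where background depth is necessarily thin) remain callable -- which
  also reproduces the empirical pattern that 5'-terminal sites show
  high relative support.
* Junction and internal sites are planted at CDS position ≥ 150, away
  from the coverage edge at the CDS 5' start that UTR-less alignment
  inevitably produces (the same edge the halfway rule exists for).
* Decayed SL fragments get two mismatching genomic bases immediately
  upstream so the maximal-match scanner recovers the exact planted
  query start.
* Sequencing errors (when `error_rate > 0`) hit only aligned bases, and
  NM records exactly the planted edits; quality strings are not
  modelled. Two decoy transcripts (one below the identity threshold, one
  with a shifted donor) exercise the funnel's rejection paths.

Passing recovery tests on these data show the *rules* are implemented
exactly as stated; they do not show robustness to misalignment,
multi-mapping, or assembly artefacts, which real data add on top.

## Problem sizes and numerical notes

The test suite and the acceptance script run the default scale (60
genes, depth 50, ~24k read pairs, ~0.3 Mb genome; seeds 1--10), chosen
so the full pipeline runs in seconds per seed. All thresholds keep the
strict/inclusive senses stated above; logo frequencies tolerate ±1e-9
in their sum-to-one check; TPM normalisation is exact to 1e-6 relative.
All randomness flows from the single config seed; no stage keeps hidden
state, and re-running any stage on identical inputs is byte-identical.

## Known limitations

* Position-1 sites conflate true 5'-UTR addition with addition within
  one read length of the start; only UTR-aware models would separate
  them.
* The scanner's mismatch model is ungapped; indel-containing SL copies
  are found only via their exact sub-segments.
* The e-value semantics of a BLAST-based survey are not emulated; for
  exact toolchain fidelity, feed external outfmt-6 tables.
* Translation-level effects of 5'-UTR loss are out of scope; categories
  describe the predicted protein only.
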