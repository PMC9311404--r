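# sltscan

Detection and consequence analysis of spliced-leader trans-splicing
(SLTS) from RNA-seq data.

In SLTS, a short conserved spliced-leader (SL) RNA is donated onto the
5' end of pre-mRNAs at splice-acceptor sites. In the photosynthetic
amoeba *Paulinella micropora*, whose SL is the 20-mer
`TGGATAATCCGGCTTTTCTG`, addition also occurs at *internal* acceptor
sites, generating 5'-truncated transcript variants whose proteins may
lose targeting peptides or functional domains. `sltscan` is for anyone
who has CDS-aligned reads and/or assembled transcripts and wants to
answer: where is the SL added, how well supported is each site, which
gene models are mispredicted rather than truncated, which truncations
are real and what do they do to the protein, where do SL RNA genes live
in the genome, and do site-bearing genes differ in expression?

## The method in brief

* **Site calling.** Retained read pairs (both mates properly paired,
  3' soft clip ≤ 5 bp, NM ≤ 5; 5' clips unrestricted) are searched for
  the conserved SL region (positions 9–20, `CCGGCTTTTCTG`, exact
  match). The site is the CDS position of the first base after the
  motif, or the first mapped base when the motif lies in the 5' soft
  clip. A site needs > 10 supporting reads and no flagged mispredicted
  position within 100 bp. Sites are classed as position-1 /
  precise-junction / near-junction / internal against the exon
  structure, and internal-site context (±5 bp) is summarised as a
  sequence logo with per-column information `2 + Σ f·log₂f` bits.
* **Misprediction scan.** Around each anchor, windows of 20 bp (step 1)
  from 100 bp upstream (halfway to the CDS start for anchors < 200 bp)
  to 50 bp downstream must each be fully spanned by ≥ 10 reads; a
  failing window flags its 5'-most base.
* **Truncation funnel.** SL-trimmed transcripts with validated genome
  alignments (identity ≥ 95, aligned ≥ 90), an intron chain equal to or
  contained in the reference gene's, a CDS hit starting ≤ 2 bp along
  the transcript, ending past 95% of either sequence, and starting
  > 100 bp along the CDS, with a clean scan around that point, become
  truncation events; Type 1/2 records whether SL-evidencing reads are
  the majority at the point. Consequences: Category A (targeting signal
  removed), B (domain/TM/coil removed or truncated), C (no downstream
  in-frame ATG, or remaining fraction < 0.25), D (≥ 2 sites per gene).
* **Genome survey.** Maximal ungapped SL matches (≥ 8 bp, ≤ 1
  mismatch) per strand; hits ending at SL position 20 are full or
  partial by the species start-position rule; partial hits are padded
  upstream to 20 nt. Genes with a > 70%-coverage hit < 100 bp upstream
  on their strand are mRNA-recycling candidates.
* **Expression.** `tpm = (c/L)/Σ(c/L)·1e6` per replicate from expected
  counts and CDS lengths; genes with vs without sites compared by
  Welch's unequal-variance t-test (closed form).

A synthetic-data generator (`simulate_slts()`) plants all of the above
— sites, mispredictions, truncation constructs with known categories,
SL loci, recycled paralogs, an expression shift — with a truth
manifest, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(sltscan)
library(dplyr)

sim   <- simulate_slts(slts_sim_config(seed = 1))   # or read your own files
sites <- sl_site_pipeline(sim$reads, sim$genes)
head(sites, 4)
#>   gene_id position supporting_reads depth support_fraction relative_position_pct context_class
#> 1 g001         252               62   124            0.5                    20.9 internal
#> 2 g001         630               93   155            0.6                    52.4 internal
#> 3 g004         188               27    78            0.346                  15.6 internal
#> 4 g007         221               91   149            0.611                  17.9 precise_junction
```

Each row is a supported SL addition site: `supporting_reads` motif
reads out of `depth` covering reads, and its relative position along
the CDS. Summarising:

```r
summarize_sl_sites(sites)
#>   n_sites n_position_1 n_precise_junction n_internal mean_support_pct mean_relative_position_pct
#> 1      22            8                  4         10         65.1                15.6
```

The internal-site context shows the planted acceptor pattern — A at −2
and G at −1 with 2 bits of information, as a real acceptor-biased logo
would:

```r
logo <- sl_logo(sites, sim$genes)
round(logo$freq[, c("-2", "-1", "0")], 2)
#>   -2 -1   0
#> A  1  0 0.1
#> C  0  0 0.2
#> G  0  1 0.5
#> T  0  0 0.2
autoplot(logo)
```

Truncation events and expression:

```r
events <- find_truncations(trim_sl(find_sl(sim$transcripts)), sim$alignments,
                           sim$hits, sim$genes, filter_read_pairs(sim$reads))
tpm <- compute_tpm(sim$counts, sim$genes)
tidy(sl_expression_test(tpm, sites))
#>   estimate mean_sl mean_no_sl statistic    df  p_value
#> 1   17644.  27797.     10153.      12.4  23.0 1.09e-11
```

Genes with SL sites are ~2.7× higher expressed in this simulation (the
planted ratio), detected at p ≈ 1e-11. `recovery_report(sim)` runs every
stage and scores it against the planted truth; a command-line front-end
over the same functions is in `inst/cli/sltscan.R`
(`Rscript inst/cli/sltscan.R demo --seed 1`).

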