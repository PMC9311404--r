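# Genome scan for SL matches, full/partial classification with the
# species rule, upstream padding, and recycling candidates.

sl <- sl_definition()
full <- sl$full_sequence

test_that("planted full and partial SL copies are found with exact query coordinates", {
  set.seed(71)
  # full 20-mer flanked by guards that cannot extend a match
  left <- rand_cds(200)
  genome <- c(s1 = paste0(left, full, rand_cds(200)))
  hits <- classify_sl_hits(scan_genome_sl(genome, sl), sl)
  planted <- hits[hits$start == 201 & hits$end == 220, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$q_start, 1L)
  expect_equal(planted$q_end, 20L)
  expect_equal(planted$strand, "+")
  expect_equal(planted$classification, "full")
  expect_equal(planted$coverage_pct, 100)

  # last 10 SL bases with two mismatching guard bases upstream
  frag <- substr(full, 11, 20)
  guard <- chartr("ACGT", "TGAC", substr(full, 9, 10))
  g2 <- c(s1 = paste0(rand_cds(150), guard, frag, rand_cds(150)))
  h2 <- classify_sl_hits(scan_genome_sl(g2, sl), sl)
  p2 <- h2[h2$start == 153 & h2$end == 162, ]
  expect_equal(p2$q_start, 11L)
  expect_equal(p2$q_end, 20L)
  expect_equal(p2$classification, "partial")
})

test_that("exact 12-mer scan of random sequence yields no hits", {
  set.seed(72)
  genome <- c(rand1 = rand_cds(100000))
  hits <- scan_genome_sl(genome, sl, min_hit_len = 12L, max_mismatches = 0L)
  # expected count ~ 2 * 1e5 * (number of 12+ windows) * 4^-12 << 1
  expect_equal(nrow(hits), 0L)
})

test_that("the species start-position rule separates full from partial", {
  h <- tibble::tibble(scaffold_id = "s", start = 1L, end = 19L, strand = "+",
                      q_start = c(2L, 2L, 1L, 3L), q_end = c(20L, 20L, 19L, 20L),
                      mismatches = 0L, coverage_pct = 90)
  chrom <- sl_definition("chromatophora")
  kr01 <- sl_definition("kr01")
  expect_equal(classify_sl_hits(h[1, ], chrom)$classification, "full")
  expect_equal(classify_sl_hits(h[2, ], kr01)$classification, "partial")
  expect_equal(classify_sl_hits(h[3, ], kr01)$classification, "neither")
  expect_equal(classify_sl_hits(h[4, ], chrom)$classification, "partial")
})

test_that("padding extracts a strand-aware 20-nt window or discards", {
  set.seed(73)
  seq1 <- rand_cds(600)
  genome <- c(s1 = seq1)
  mk <- function(start, end, strand, cls = "partial") tibble::tibble(
    scaffold_id = "s1", start = start, end = end, strand = strand,
    q_start = 11L, q_end = 20L, mismatches = 0L, coverage_pct = 50,
    classification = cls)
  # plus strand: 10-bp hit at 500-509 pads to bases 490-509
  out <- pad_partial_hits(mk(500L, 509L, "+"), genome, sl)
  expect_equal(out$padded_sequence, substr(seq1, 490, 509))
  # too close to the scaffold start: discarded
  expect_true(is.na(pad_partial_hits(mk(5L, 14L, "+"), genome, sl)$padded_sequence))
  # minus strand: downstream genomic bases supply the pad, reverse-complemented
  outm <- pad_partial_hits(mk(300L, 309L, "-"), genome, sl)
  expect_equal(outm$padded_sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(seq1, 300, 319)))))
  # non-partial rows are not padded
  expect_true(is.na(pad_partial_hits(mk(500L, 509L, "+", cls = "full"),
                                     genome, sl)$padded_sequence))
})

test_that("padded partial hits end in the matched genomic bases", {
  sim <- cached_sim(1)
  hits <- classify_sl_hits(scan_genome_sl(sim$genome, sim$sl), sim$sl)
  padded <- pad_partial_hits(hits, sim$genome, sim$sl)
  part <- padded[padded$classification == "partial" &
                   !is.na(padded$padded_sequence) & padded$mismatches == 0, ]
  expect_true(nrow(part) > 0)
  expect_true(all(nchar(part$padded_sequence) == 20L))
  # the 3' tail of the padded window equals the matched SL suffix
  tail_len <- 20L - part$q_start + 1L
  expect_equal(substring(part$padded_sequence, 21L - tail_len, 20L),
               substring(sl$full_sequence, part$q_start, 20L))
})

test_that("recycling candidates need >70% coverage within 100 bp upstream", {
  gene <- make_gene("g1", rand_cds(300, seed = 74))  # exon 1001-1300, + strand
  mk <- function(cov, end) tibble::tibble(
    scaffold_id = "chrT", start = end - 15L, end = end, strand = "+",
    q_start = 1L, q_end = 16L, mismatches = 0L, coverage_pct = cov)
  expect_equal(recycling_candidates(mk(80, 950L), gene)$gene_id, "g1")  # 50 bp
  expect_equal(recycling_candidates(mk(80, 950L), gene)$distance, 50L)
  expect_equal(nrow(recycling_candidates(mk(60, 950L), gene)), 0L)
  expect_equal(nrow(recycling_candidates(mk(70, 950L), gene)), 0L)   # strict >70
  expect_equal(nrow(recycling_candidates(mk(80, 850L), gene)), 0L)   # 150 bp away
  expect_equal(nrow(recycling_candidates(mk(80, 1000L), gene)), 0L)  # distance 0
  # wrong strand: not upstream in the gene's orientation
  h <- mk(80, 950L); h$strand <- "-"
  expect_equal(nrow(recycling_candidates(h, gene)), 0L)
})

test_that("recycling detection agrees with a brute-force all-pairs oracle", {
  sim <- cached_sim(1)
  hits <- scan_genome_sl(sim$genome, sim$sl)
  cand <- recycling_candidates(hits, sim$genes)
  # brute force over every hit x gene pair
  brute <- character()
  for (i in seq_len(nrow(sim$genes))) {
    g <- sim$genes[i, ]
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(hits))) {
      h <- hits[j, ]
      if (h$coverage_pct <= 70 || h$scaffold_id != g$scaffold_id ||
            h$strand != g$strand) next
      d <- if (g$strand == "+") min(ex$start) - h$end - 1L else
        h$start - max(ex$end) - 1L
      if (d > 0 && d < 100) brute <- c(brute, paste(g$gene_id, h$start))
    }
  }
  expect_setequal(paste(cand$gene_id, cand$hit_start), brute)
  expect_setequal(unique(cand$gene_id), sim$truth$recycled_paralogs$gene_id)
})

test_that("reverse-complementing the genome swaps strands, preserving classes", {
  set.seed(75)
  genome <- c(s1 = paste0(rand_cds(400), full, rand_cds(120),
                          as.character(Biostrings::reverseComplement(
                            Biostrings::DNAString(substr(full, 9, 20)))),
                          rand_cds(400)))
  rc <- c(s1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(genome))[[1]]))
  h1 <- classify_sl_hits(scan_genome_sl(genome, sl), sl)
  h2 <- classify_sl_hits(scan_genome_sl(rc, sl), sl)
  L <- nchar(genome[[1]])
  flip <- function(h) tibble::tibble(
    start = L - h$end + 1L, end = L - h$start + 1L,
    strand = ifelse(h$strand == "+", "-", "+"),
    q_start = h$q_start, q_end = h$q_end, classification = h$classification)
  a <- dplyr::arrange(flip(h1), start, strand, q_start)
  b <- dplyr::arrange(tibble::tibble(start = h2$start, end = h2$end,
                                     strand = h2$strand, q_start = h2$q_start,
                                     q_end = h2$q_end,
                                     classification = h2$classification),
                      start, strand, q_start)
  expect_equal(as.data.frame(a), as.data.frame(b))
})
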