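# Readers/writers and coordinate conventions.

test_that("FASTA reading handles single, empty, wrapped, and malformed input", {
  f <- withr::local_tempfile()
  writeLines(c(">g1", "ACGT"), f)
  expect_equal(read_fasta(f),
               tibble::tibble(seq_id = "g1", sequence = "ACGT"))

  writeLines(character(), f)
  expect_equal(nrow(read_fasta(f)), 0L)

  # wrapped record: concatenation oracle computed from the raw lines
  lines <- c(">w1 description", "ACGTAC", "GTTTGA", "CC")
  writeLines(lines, f)
  expect_equal(read_fasta(f)$sequence, paste(lines[-1], collapse = ""))
  expect_equal(read_fasta(f)$seq_id, "w1")

  writeLines(c("ACGT", ">late"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("FASTA writer round-trips with the reader", {
  f <- withr::local_tempfile()
  tbl <- tibble::tibble(seq_id = c("a", "b"),
                        sequence = c(rand_cds(211, seed = 1), rand_cds(70)))
  write_fasta(tbl, f)
  expect_equal(read_fasta(f), tbl)
})

test_that("GFF3 gene models splice CDS from the genome, strand-aware", {
  genome <- c(chr1 = paste0(strrep("T", 10), "ATGAAA", strrep("C", 20),
                            "GGGTTT", strrep("T", 10)))
  gff <- withr::local_tempfile()
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t11\t42\t.\t+\t.\tID=gp",
    "chr1\tx\tmRNA\t11\t42\t.\t+\t.\tID=gp.t1;Parent=gp",
    # exon rows deliberately out of order
    "chr1\tx\texon\t37\t42\t.\t+\t.\tID=gp.e2;Parent=gp.t1",
    "chr1\tx\texon\t11\t16\t.\t+\t.\tID=gp.e1;Parent=gp.t1",
    "chr1\tx\tCDS\t37\t42\t.\t+\t0\tID=gp.c2;Parent=gp.t1",
    "chr1\tx\tCDS\t11\t16\t.\t+\t0\tID=gp.c1;Parent=gp.t1",
    "chr1\tx\tgene\t11\t42\t.\t-\t.\tID=gm",
    "chr1\tx\tmRNA\t11\t42\t.\t-\t.\tID=gm.t1;Parent=gm",
    "chr1\tx\texon\t11\t16\t.\t-\t.\tID=gm.e1;Parent=gm.t1",
    "chr1\tx\tCDS\t11\t16\t.\t-\t0\tID=gm.c1;Parent=gm.t1"
  ), gff)
  genes <- read_gff3_genes(gff, genome)

  gp <- genes[genes$gene_id == "gp", ]
  # manual splice oracle: exon slices concatenated
  expect_equal(gp$cds_sequence, paste0("ATGAAA", "GGGTTT"))
  expect_equal(gp$exons[[1]]$start, c(11L, 37L))  # sorted on load
  expect_equal(gp$cds_piece_starts[[1]], c(1L, 7L))

  gm <- genes[genes$gene_id == "gm", ]
  # minus-strand single exon: reverse complement of the slice
  expect_equal(gm$cds_sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ATGAAA"))))

  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t11\t99\t.\t+\t.\tID=gx",
               "chr1\tx\tmRNA\t11\t99\t.\t+\t.\tID=gx.t1;Parent=gx",
               "chr1\tx\tCDS\t11\t99\t.\t+\t0\tID=gx.c1;Parent=gx.t1"), gff)
  expect_error(read_gff3_genes(gff, genome), "scaffold bounds")
})

test_that("genomic/CDS coordinate mapping is a bijection on CDS bases", {
  sim <- cached_sim(1)
  set.seed(42)
  for (g in sample(sim$genes$gene_id, 8)) {
    pos <- cds_genomic_positions(sim$genes, g)
    L <- sim$genes$cds_length[sim$genes$gene_id == g]
    expect_equal(length(pos), L)
    expect_equal(anyDuplicated(pos), 0L)
    # map then inverse-map random CDS positions
    p <- sample.int(L, min(1000L, L), replace = TRUE)
    expect_equal(match(pos[p], pos), p)
  }
})

test_that("SAM reading parses CIGARs, flags, and NM tags", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:cds1\tLN:2000",
    sprintf("r1\t163\tcds1\t200\t60\t20S130M\t*\t0\t0\t%s\t*\tNM:i:0", strrep("A", 150)),
    sprintf("r2\t161\tcds1\t300\t60\t150M\t*\t0\t0\t%s\t*\tNM:i:3", strrep("A", 150)),
    sprintf("r3\t83\tcds1\t400\t60\t100M2D50M\t*\t0\t0\t%s\t*\tNM:i:2", strrep("A", 150))
  ), sam)
  reads <- read_sam(sam)
  expect_equal(nrow(reads), 3L)
  r1 <- reads[reads$read_id == "r1", ]
  expect_equal(r1$start, 200L)
  expect_true(r1$properly_paired)
  expect_equal(reads$properly_paired[reads$read_id == "r2"], FALSE)
  # CIGAR arithmetic oracle: 100M + 2D + 50M consumes 152 reference bases
  r3 <- reads[reads$read_id == "r3", ]
  span_end <- r3$start + 100L + 2L + 50L - 1L
  expect_equal(sltscan::spanning_read_count(reads, "cds1", 400L, span_end), 1L)
  expect_equal(sltscan::spanning_read_count(reads, "cds1", 400L, span_end + 1L), 0L)

  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:cds1\tLN:2000",
    sprintf("r4\t163\tcds1\t10\t60\t150M\t*\t0\t0\t%s\t*", strrep("A", 150))
  ), sam)
  expect_warning(r <- read_sam(sam), "NM")
  expect_true(is.na(r$edit_distance))
  expect_error(read_sam(sam, missing_nm = "error"), "NM")
})

test_that("SAM writer round-trips with the reader", {
  sim <- cached_sim(1)
  sam <- withr::local_tempfile(fileext = ".sam")
  sub <- head(sim$reads, 500)
  write_sam(sub, setNames(sim$genes$cds_length, sim$genes$gene_id), sam)
  back <- read_sam(sam)
  expect_equal(as.data.frame(dplyr::arrange(back, read_id, flag)),
               as.data.frame(dplyr::arrange(sub, read_id, flag)))
})

test_that("tabular hit parsing follows outfmt-6 column order and strand rule", {
  f <- withr::local_tempfile()
  writeLines(c(
    "t1\tg1\t98.5\t500\t5\t0\t1\t500\t101\t600\t1e-100\t900",
    "t2\tg2\t100\t200\t0\t0\t1\t200\t800\t601\t1e-50\t370"
  ), f)
  hits <- read_blast_hits(f)
  expect_equal(hits$identity_pct, c(98.5, 100))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$s_start[2], 800L)

  writeLines(c("t1\tg1\t98.5\t500", "t1\tg1\t98.5\t500"), f)
  expect_error(read_blast_hits(f), "row 1")
})

test_that("feature and count tables validate their contracts", {
  f <- withr::local_tempfile()
  readr::write_tsv(tibble::tibble(gene_id = "g1", kind = "targeting_signal",
                                  aa_start = 1L, aa_end = 30L, label = "sig"), f)
  feats <- read_feature_table(f)
  expect_equal(feats$aa_end, 30L)
  readr::write_tsv(tibble::tibble(gene_id = "g1", kind = "banana",
                                  aa_start = 1L, aa_end = 3L, label = "x"), f)
  expect_error(read_feature_table(f), "unknown feature kind")

  readr::write_tsv(tibble::tibble(gene_id = "g1", replicate_id = "r1",
                                  expected_count = -1), f)
  expect_error(read_expected_counts(f), "non-negative")
})

test_that("BED6 output is 0-based half-open", {
  f <- withr::local_tempfile()
  write_bed6(tibble::tibble(chrom = "chr1", start = 101L, end = 200L,
                            name = "x", score = 0, strand = "+"), f)
  expect_equal(readLines(f), "chr1\t100\t200\tx\t0\t+")
})
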