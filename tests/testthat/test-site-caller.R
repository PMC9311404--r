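# Read-pair filtering, site calling, junction classification, summary
# statistics, and the sequence-context logo.

test_that("pair filter keeps concordant pairs and allows any 5' clip", {
  # retained: 5' clips 20S/0S, 3' clips 0/3, NM 2/0
  p1 <- make_pair("p1", "g", 100, 300, fwd_cigar = "20S130M",
                  rev_cigar = "3S147M", fwd_nm = 2L, rev_nm = 0L)
  # dropped: one mate with 6 bp 3' soft clip (leading S on a reverse read)
  p2 <- make_pair("p2", "g", 100, 300, rev_cigar = "6S144M")
  # dropped: one mate NM = 6
  p3 <- make_pair("p3", "g", 100, 300, rev_nm = 6L)
  # dropped: not properly paired
  p4 <- make_pair("p4", "g", 100, 300, proper = FALSE)
  # dropped: orphan
  p5 <- make_read("p5", "g", 100, "150M")
  reads <- dplyr::bind_rows(p1, p2, p3, p4, p5)
  kept <- filter_read_pairs(reads)
  expect_equal(unique(kept$read_id), "p1")
  expect_equal(attr(kept, "n_dropped_pairs"), 4L)

  # reverse-strand mate: its 3' end is the leading clip
  p6 <- make_pair("p6", "g", 100, 300, rev_cigar = "8S142M")
  expect_equal(nrow(filter_read_pairs(p6)), 0L)
  p7 <- make_pair("p7", "g", 100, 300, rev_cigar = "5S145M")
  expect_equal(nrow(filter_read_pairs(p7)), 2L)
})

test_that("site calling places motif reads and applies the strict support rule", {
  cds <- rand_cds(1200, seed = 21)
  gene <- make_gene("g1", cds)
  # 15 motif pairs at 200 plus background: one site at 200 with support 15
  reads <- dplyr::bind_rows(
    sl_support_pairs(15, "g1", 200L, cds, prefix = "a"),
    bg_pairs(5, "g1", 150L, cds))
  sites <- call_sl_sites(reads, gene)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 200L)
  expect_equal(sites$supporting_reads, 15L)
  expect_equal(sites$depth, 20L)  # 15 motif + 5 background cover 200
  expect_equal(sites$support_fraction, 0.75)
  expect_equal(sites$relative_position_pct, (200 - 1) / 1200 * 100)

  # exactly 10 supporting reads: not called (> 10 is strict)
  r10 <- sl_support_pairs(10, "g1", 200L, cds)
  expect_equal(nrow(call_sl_sites(r10, gene)), 0L)
  r11 <- sl_support_pairs(11, "g1", 200L, cds)
  expect_equal(nrow(call_sl_sites(r11, gene)), 1L)
})

test_that("a motif wholly inside the 5' soft clip reports the first mapped base", {
  cds <- rand_cds(1200, seed = 22)
  gene <- make_gene("g1", cds)
  cons <- sl_definition()$conserved_region
  # 20-base 5' soft clip containing the motif; first mapped base at 350
  clip <- paste0(rand_cds(8), cons)
  reads <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_pair(sprintf("sc%02d", i), "g1", 350, 450,
              fwd_cigar = "20S130M",
              fwd_seq = paste0(clip, substr(cds, 350, 479)),
              rev_seq = substr(cds, 450, 599))
  }))
  sites <- call_sl_sites(reads, gene)
  expect_equal(sites$position, 350L)
  expect_equal(sites$supporting_reads, 12L)
})

test_that("sites near flagged mispredicted positions are suppressed", {
  cds <- rand_cds(1200, seed = 23)
  gene <- make_gene("g1", cds)
  reads <- sl_support_pairs(15, "g1", 150L, cds)
  mispred <- tibble::tibble(gene_id = "g1", position = 210L)
  expect_equal(nrow(call_sl_sites(reads, gene, mispred = mispred)), 0L)  # 60 <= 100
  far <- tibble::tibble(gene_id = "g1", position = 251L)
  expect_equal(nrow(call_sl_sites(reads, gene, mispred = far)), 1L)  # 101 > 100
})

test_that("junction classification uses cumulative CDS piece lengths", {
  cds <- rand_cds(300, seed = 24)
  gene <- make_gene("g1", cds, piece_lens = c(100L, 80L, 120L))
  sites <- tibble::tibble(gene_id = "g1", position = c(1L, 101L, 103L, 50L, 181L))
  out <- classify_junction(sites, gene, near_window = 2L)
  expect_equal(out$context_class,
               c("position_1", "precise_junction", "near_junction",
                 "internal", "precise_junction"))

  # brute-force oracle: map every genomic exon start to CDS coordinates
  # independently through the genomic-position table
  sim <- cached_sim(1)
  multi <- sim$genes[sim$genes$n_exons > 1, ]
  for (i in seq_len(min(8, nrow(multi)))) {
    g <- multi$gene_id[i]
    pos <- cds_genomic_positions(sim$genes, g)
    ex <- multi$exons[[i]]
    bound <- if (multi$strand[i] == "+") ex$start else ex$end
    cds_starts <- sort(match(bound, pos))
    expect_equal(cds_starts, multi$cds_piece_starts[[i]])
    probe <- tibble::tibble(gene_id = g, position = cds_starts[-1])
    expect_true(all(classify_junction(probe, sim$genes)$context_class ==
                      "precise_junction"))
  }
})

test_that("raising min_support never adds sites, and support <= depth", {
  sim <- cached_sim(2)
  filtered <- filter_read_pairs(sim$reads)
  s10 <- call_sl_sites(filtered, sim$genes, min_support = 10L)
  s20 <- call_sl_sites(filtered, sim$genes, min_support = 20L)
  key <- function(s) paste(s$gene_id, s$position)
  expect_true(all(key(s20) %in% key(s10)))
  expect_true(all(s10$supporting_reads <= s10$depth))
  expect_true(all(s10$depth > 0))
  expect_true(all(s10$support_fraction > 0 & s10$support_fraction <= 1))
})

test_that("site summary splits by above/below mean support", {
  sites <- tibble::tibble(
    gene_id = c("a", "b"), position = c(11L, 3L),
    supporting_reads = c(20L, 80L), depth = c(100L, 100L),
    support_fraction = c(0.2, 0.8),
    relative_position_pct = c(10, 2),
    context_class = "internal")
  s <- summarize_sl_sites(sites)
  expect_equal(s$mean_support_pct, 50)
  expect_equal(s$above_mean_relative_pct, 2)
  expect_equal(s$below_mean_relative_pct, 10)

  one <- tibble::tibble(gene_id = "a", position = 1L, supporting_reads = 12L,
                        depth = 12L, support_fraction = 1,
                        relative_position_pct = (1 - 1) / 100 * 100,
                        context_class = "position_1")
  expect_equal(summarize_sl_sites(one)$mean_relative_position_pct, 0)

  # all sites with equal support: above-mean group undefined
  eq <- dplyr::mutate(sites, support_fraction = 0.5)
  expect_true(is.na(summarize_sl_sites(eq)$above_mean_relative_pct))
})

test_that("logo matrix captures a planted acceptor pattern and excludes short flanks", {
  set.seed(31)
  n <- 40L
  cdss <- vapply(seq_len(n), function(i) {
    s <- rand_cds(400)
    # plant A at -2 and G at -1 of position 201
    paste0(substr(s, 1, 198), "AG", substr(s, 201, 400))
  }, character(1))
  genes <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_gene(sprintf("g%02d", i), cdss[i])
  }))
  sites <- tibble::tibble(gene_id = genes$gene_id, position = 201L,
                          context_class = "internal")
  logo <- sl_logo(sites, genes)
  expect_equal(logo$freq["A", "-2"], 1)
  expect_equal(logo$freq["G", "-1"], 1)
  expect_equal(logo$info[["-2"]], 2)
  expect_equal(logo$info[["-1"]], 2)
  expect_true(all(abs(colSums(logo$freq) - 1) < 1e-9))
  expect_true(all(logo$info >= 0 & logo$info <= 2))

  # a site 3 bp from the CDS start lacks a full flank and is excluded
  near_end <- dplyr::bind_rows(sites,
                               tibble::tibble(gene_id = genes$gene_id[1],
                                              position = 3L,
                                              context_class = "internal"))
  expect_equal(sl_logo(near_end, genes)$n_sites, n)

  td <- tidy(logo)
  expect_equal(nrow(td), 44L)
  expect_s3_class(autoplot(logo), "ggplot")
})

test_that("uniform random contexts carry almost no information", {
  set.seed(32)
  n <- 10000L
  big <- rand_cds(11L * n + 10L)
  gene <- make_gene("big", big)
  sites <- tibble::tibble(gene_id = "big",
                          position = as.integer(seq(6L, by = 11L, length.out = n)),
                          context_class = "internal")
  logo <- sl_logo(sites, gene)
  expect_true(all(logo$info <= 0.05))
})
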