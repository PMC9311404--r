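# Downstream starts, Categories A-D, feature merging, and site-vs-feature
# retrieval with the >60 bp rule.

# a CDS with in-frame ATGs only where requested
controlled_cds <- function(L, atg_at, seed = 1) {
  set.seed(seed)
  codons <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T")), 1, paste,
                          collapse = ""), "ATG")
  s <- paste(sample(codons, L / 3, replace = TRUE), collapse = "")
  for (p in atg_at) s <- paste0(substr(s, 1, p - 1), "ATG", substr(s, p + 3, L))
  s
}

test_that("downstream start scanning respects the reading frame", {
  expect_equal(downstream_start("ATGAAAATGCCC", 4), 7L)
  expect_equal(downstream_start("ATGAAACCCCCC", 4), NA_integer_)
  expect_equal(downstream_start("ATGAAAATGCCC", 7), 7L)  # truncation at an ATG
  # an out-of-frame ATG is not a start
  expect_equal(downstream_start("ATGAATGCCCCC", 4), NA_integer_)
  expect_equal(downstream_start(c("ATGAAAATGCCC", "ATGAAACCCCCC"), c(4, 4)),
               c(7L, NA))
})

test_that("categories A-D follow the feature and start-codon rules", {
  L <- 600L
  # A: targeting signal aa 1-30 (nt 1-90) entirely 5' of retained start 151
  cdsA <- controlled_cds(L, atg_at = c(1L, 151L), seed = 61)
  geneA <- make_gene("gA", cdsA)
  featA <- tibble::tibble(gene_id = "gA", kind = "targeting_signal",
                          aa_start = 1L, aa_end = 30L, label = "sig")
  evA <- tibble::tibble(gene_id = "gA", truncation_point = 120L)
  outA <- categorize_truncations(evA, geneA, featA)
  expect_equal(outA$retained_start, 151L)
  expect_equal(outA$categories[[1]], "A")

  # B: domain aa 10-60 (nt 28-180) starts upstream of retained start 100
  cdsB <- controlled_cds(L, atg_at = c(1L, 100L), seed = 62)
  geneB <- make_gene("gB", cdsB)
  featB <- tibble::tibble(gene_id = "gB", kind = "domain",
                          aa_start = 10L, aa_end = 60L, label = "dom")
  evB <- tibble::tibble(gene_id = "gB", truncation_point = 90L)
  outB <- categorize_truncations(evB, geneB, featB)
  expect_equal(outB$retained_start, 100L)
  expect_equal(outB$categories[[1]], "B")

  # C: no downstream in-frame ATG; fraction 0
  cdsC <- controlled_cds(L, atg_at = 1L, seed = 63)
  geneC <- make_gene("gC", cdsC)
  evC <- tibble::tibble(gene_id = "gC", truncation_point = 120L)
  outC <- categorize_truncations(evC, geneC, featB[0, ])
  expect_equal(outC$categories[[1]], "C")
  expect_equal(outC$remaining_fraction, 0)

  # C + D: second site on the gene
  sites <- tibble::tibble(gene_id = "gC", position = c(120L, 400L))
  outCD <- categorize_truncations(evC, geneC, featB[0, ], sites = sites)
  expect_equal(outCD$categories[[1]], c("C", "D"))

  # C via short remainder: a valid start too close to the 3' end
  cdsS <- controlled_cds(L, atg_at = c(1L, 571L), seed = 64)
  geneS <- make_gene("gS", cdsS)
  evS <- tibble::tibble(gene_id = "gS", truncation_point = 500L)
  outS <- categorize_truncations(evS, geneS, featB[0, ])
  expect_equal(outS$retained_start, 571L)
  expect_true("C" %in% outS$categories[[1]])
  expect_lt(outS$remaining_fraction, 0.25)

  # feature exceeding the protein errors
  bad <- tibble::tibble(gene_id = "gA", kind = "domain",
                        aa_start = 1L, aa_end = 300L, label = "x")
  expect_error(categorize_truncations(evA, geneA, bad), "exceeds protein length")

  # determinism / feature order independence
  feats2 <- dplyr::bind_rows(featA,
                             tibble::tibble(gene_id = "gA", kind = "domain",
                                            aa_start = 5L, aa_end = 20L,
                                            label = "d2"))
  o1 <- categorize_truncations(evA, geneA, feats2)
  o2 <- categorize_truncations(evA, geneA, feats2[2:1, ])
  expect_equal(o1$categories, o2$categories)
  expect_equal(o1$categories[[1]], c("A", "B"))
})

test_that("feature merging unions overlapping and bookended intervals", {
  f <- tibble::tibble(
    gene_id = "g", kind = "domain",
    aa_start = c(1L, 40L, 100L, 120L, 119L), aa_end = c(50L, 80L, 110L, 130L, 121L),
    label = c("a", "b", "c", "d", "e"))
  m <- merge_features(f)
  expect_equal(m$aa_start, c(1L, 100L, 119L))
  expect_equal(m$aa_end, c(80L, 110L, 130L))
  # minimality: no two merged intervals of one kind overlap or touch
  expect_true(all(diff(m$aa_start) > 1))
  expect_true(all(m$aa_start[-1] > m$aa_end[-nrow(m)] + 1L))

  disj <- tibble::tibble(gene_id = "g", kind = "coil",
                         aa_start = c(1L, 60L), aa_end = c(10L, 70L),
                         label = c("x", "y"))
  expect_equal(nrow(merge_features(disj)), 2L)
})

test_that("site-vs-feature retrieval applies the strict 60-bp rule", {
  cds <- rand_cds(900, seed = 65)
  gene <- make_gene("gF", cds)
  # deep uniform coverage so every interval scan is clean
  reads <- dplyr::bind_rows(lapply(1:15, function(i) {
    make_read(sprintf("c%02d", i), "gF", 1, "900M")
  }))
  feats <- tibble::tibble(
    gene_id = "gF", kind = "domain",
    aa_start = c(1L, 34L), aa_end = c(50L, 134L),  # nt 1-150 and 100-402
    label = c("f1", "f2"))
  sites <- tibble::tibble(
    gene_id = "gF", position = c(500L, 161L, 160L),
    context_class = "internal")
  out <- sites_relative_to_features(sites, feats, gene, reads)
  # 500 is downstream of the merged feature block (nt 1-402)
  expect_equal(out$feature_relation[1], "downstream_of_feature")
  expect_true(out$scan_clean[1])
  # merged feature nt 1-402 contains 161 at offset 160 > 60 and 160 at 159:
  # both within; use an unmerged second gene for the boundary case
  gene2 <- make_gene("gG", cds)
  feats2 <- tibble::tibble(gene_id = "gG", kind = "domain",
                           aa_start = 34L, aa_end = 134L, label = "f")
  reads2 <- dplyr::mutate(reads, target_id = "gG")
  sites2 <- tibble::tibble(gene_id = "gG", position = c(161L, 160L),
                           context_class = "internal")
  out2 <- sites_relative_to_features(sites2, feats2, gene2, reads2)
  expect_equal(out2$feature_relation, c("within_feature", NA))
  expect_equal(out2$offset[1], 61L)

  # brute-force check of set assignment on clean data
  brute <- function(p, fs) {
    inside <- fs$nt_start <= p & fs$nt_end >= p
    if (any(inside)) {
      off <- p - fs$nt_start[which(inside)[1]]
      if (off > 60) "within_feature" else NA_character_
    } else if (any(fs$nt_end < p)) "downstream_of_feature" else NA_character_
  }
  merged <- merge_features(feats)
  merged$nt_start <- 3L * merged$aa_start - 2L
  merged$nt_end <- 3L * merged$aa_end
  expect_equal(out$feature_relation,
               vapply(sites$position, brute, character(1), fs = merged))
})
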