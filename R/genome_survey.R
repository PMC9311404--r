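# Genome survey for SL RNA loci (full/partial hit classification with the
# species start-position rule, upstream padding of partial hits) and
# mRNA-recycling candidate detection.

# maximal admissible segments in a logical match vector: segments that
# start and end on matches, contain <= max_mm mismatches, have length >=
# min_len, and cannot be extended to a longer admissible segment
maximal_segments <- function(v, min_len, max_mm) {
  n <- length(v)
  segs <- list()
  idx <- which(v)
  if (length(idx) == 0) return(segs)
  for (s in idx) {
    for (e in idx[idx >= s]) {
      mm <- sum(!v[s:e])
      if (mm <= max_mm && (e - s + 1) >= min_len) {
        segs[[length(segs) + 1]] <- c(s = s, e = e, mm = mm)
      }
    }
  }
  if (length(segs) == 0) return(segs)
  m <- do.call(rbind, segs)
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any(m[, "s"] <= m[i, "s"] & m[, "e"] >= m[i, "e"] &
           (m[, "e"] - m[, "s"]) > (m[i, "e"] - m[i, "s"]))
  }, logical(1))
  lapply(which(keep), function(i) m[i, ])
}

# scan one scaffold strand (sequence given in the orientation to compare
# against the forward SL query); returns hits with positions on that
# oriented sequence
scan_oriented <- function(seq_chars, q_chars, min_len, max_mm) {
  L <- length(seq_chars)
  Q <- length(q_chars)
  if (L < min_len) return(NULL)
  # diagonal index j: query position q aligns to genome position j + q - Q
  D <- L + Q - 1L
  A <- matrix(FALSE, nrow = Q, ncol = D)
  for (q in seq_len(Q)) {
    A[q, (Q - q + 1L):(L + Q - q)] <- seq_chars == q_chars[q]
  }
  # candidate filter: some window of min_len rows with >= min_len - max_mm
  # matches is necessary for an admissible segment
  B <- A * 1L
  for (i in 2:Q) B[i, ] <- B[i - 1L, ] + A[i, ]
  need <- min_len - max_mm
  cand <- rep(FALSE, D)
  for (j in 0:(Q - min_len)) {
    top <- if (j == 0) B[min_len, ] else B[j + min_len, ] - B[j, ]
    cand <- cand | (top >= need)
  }
  out <- vector("list", 0)
  for (j in which(cand)) {
    qmin <- max(1L, Q - j + 1L)
    qmax <- min(Q, L + Q - j)
    if (qmax - qmin + 1L < min_len) next
    v <- A[qmin:qmax, j]
    segs <- maximal_segments(v, min_len, max_mm)
    for (sg in segs) {
      qs <- qmin + sg[["s"]] - 1L
      qe <- qmin + sg[["e"]] - 1L
      out[[length(out) + 1]] <- c(j = j, q_start = qs, q_end = qe, mm = sg[["mm"]])
    }
  }
  if (length(out) == 0) return(NULL)
  m <- do.call(rbind, out)
  tibble(q_start = as.integer(m[, "q_start"]), q_end = as.integer(m[, "q_end"]),
         o_start = as.integer(m[, "j"] + m[, "q_start"] - Q),
         o_end = as.integer(m[, "j"] + m[, "q_end"] - Q),
         mismatches = as.integer(m[, "mm"]))
}

#' Scan a genome for SL sequence matches
#'
#' Reports, per scaffold and strand, every maximal ungapped match between a
#' substring of the SL query and the genome with at least `min_hit_len`
#' bases and at most `max_mismatches` mismatches (segments begin and end on
#' matching bases). Defaults emulate a short-word nucleotide search;
#' externally produced outfmt-6 tables can be used instead via
#' [sl_hits_from_blast()].
#'
#' @param genome A `DNAStringSet`, named character vector, or
#'   `read_fasta()` tibble.
#' @param sl An [sl_definition()]; the full SL sequence is the query.
#' @param min_hit_len Minimum match length (default 8).
#' @param max_mismatches Maximum mismatches per match (default 1).
#' @return Tibble of hits: `scaffold_id`, `start`, `end` (1-based
#'   inclusive genomic, `start <= end`), `strand`, `q_start`, `q_end`
#'   (positions on the SL query), `mismatches`, `coverage_pct`.
#' @export
scan_genome_sl <- function(genome, sl = sl_definition(), min_hit_len = 8L,
                           max_mismatches = 1L) {
  genome_chr <- as_genome_chr(genome)
  q <- strsplit(sl$full_sequence, "")[[1]]
  qlen <- length(q)
  res <- purrr::imap(genome_chr, function(seq, scaf) {
    fwd_chars <- strsplit(seq, "")[[1]]
    L <- length(fwd_chars)
    plus <- scan_oriented(fwd_chars, q, min_hit_len, max_mismatches)
    minus <- scan_oriented(rev(chartr("ACGT", "TGCA", fwd_chars)), q,
                           min_hit_len, max_mismatches)
    rows <- list()
    if (!is.null(plus)) {
      rows$p <- mutate(plus, scaffold_id = scaf, strand = "+",
                       start = .data$o_start, end = .data$o_end)
    }
    if (!is.null(minus)) {
      rows$m <- mutate(minus, scaffold_id = scaf, strand = "-",
                       start = L - .data$o_end + 1L, end = L - .data$o_start + 1L)
    }
    if (length(rows) == 0) return(NULL)
    bind_rows(rows)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(scaffold_id = character(), start = integer(), end = integer(),
                  strand = character(), q_start = integer(), q_end = integer(),
                  mismatches = integer(), coverage_pct = numeric()))
  }
  out |>
    mutate(coverage_pct = (.data$q_end - .data$q_start + 1) / qlen * 100) |>
    select("scaffold_id", "start", "end", "strand", "q_start", "q_end",
           "mismatches", "coverage_pct") |>
    arrange(.data$scaffold_id, .data$start)
}

#' Convert an outfmt-6 table of SL-vs-genome hits to survey form
#'
#' For hit tables produced externally with the SL sequence as query and
#' scaffolds as subjects.
#'
#' @param hits Tibble from [read_blast_hits()].
#' @param sl An [sl_definition()].
#' @return A tibble in the [scan_genome_sl()] column layout.
#' @export
sl_hits_from_blast <- function(hits, sl = sl_definition()) {
  qlen <- nchar(sl$full_sequence)
  tibble(
    scaffold_id = hits$subject_id,
    start = pmin(hits$s_start, hits$s_end),
    end = pmax(hits$s_start, hits$s_end),
    strand = hits$strand,
    q_start = hits$q_start, q_end = hits$q_end,
    mismatches = hits$mismatches,
    coverage_pct = (hits$q_end - hits$q_start + 1) / qlen * 100
  )
}

#' Classify genome SL hits as full or partial
#'
#' A hit covers the full SL when it ends at SL position 20 and starts at
#' or before the species' full-hit start position (1 for KR01 and
#' *P. ovalis*; 2 for *P. chromatophora*, whose SL differs at its first
#' base). A hit ending at position 20 but starting later partially covers
#' the SL -- the 3' end is the most conserved part, so partial hits must
#' reach it. Anything not ending at position 20 is `neither`.
#'
#' @param hits Survey hits ([scan_genome_sl()] or [sl_hits_from_blast()]).
#' @param sl An [sl_definition()] carrying the species rule.
#' @return `hits` with a `classification` column added.
#' @export
classify_sl_hits <- function(hits, sl = sl_definition()) {
  qlen <- nchar(sl$full_sequence)
  mutate(hits, classification = dplyr::case_when(
    .data$q_end == qlen & .data$q_start <= sl$full_start_position ~ "full",
    .data$q_end == qlen ~ "partial",
    TRUE ~ "neither"
  ))
}

#' Pad partial SL hits to full query length with upstream genomic bases
#'
#' For each partial hit, extracts a strand-aware genomic window of exactly
#' the SL query length ending at the hit's 3' genomic end (upstream bases
#' supply the pad). Hits too close to a scaffold end to yield a full-length
#' window get `NA` and are to be discarded.
#'
#' @param hits Classified hits ([classify_sl_hits()]); only `partial` rows
#'   are padded.
#' @param genome Genome (`DNAStringSet`, named character, or tibble).
#' @param sl An [sl_definition()].
#' @return `hits` with a `padded_sequence` column (`NA` for non-partial
#'   rows and truncated windows).
#' @export
pad_partial_hits <- function(hits, genome, sl = sl_definition()) {
  genome_chr <- as_genome_chr(genome)
  qlen <- nchar(sl$full_sequence)
  hits$padded_sequence <- purrr::pmap_chr(
    list(hits$classification, hits$scaffold_id, hits$start, hits$end, hits$strand),
    function(cls, scaf, s, e, strand) {
      if (!identical(cls, "partial")) return(NA_character_)
      L <- nchar(genome_chr[[scaf]])
      if (strand == "+") {
        from <- e - qlen + 1L
        if (from < 1L) return(NA_character_)
        substr(genome_chr[[scaf]], from, e)
      } else {
        to <- s + qlen - 1L
        if (to > L) return(NA_character_)
        revcomp(substr(genome_chr[[scaf]], s, to))
      }
    })
  hits
}

#' Detect mRNA-recycling candidate genes
#'
#' A gene is a recycling candidate when a genome SL hit with query
#' coverage strictly above `min_coverage` percent lies on the gene's
#' strand with its 3' end between 1 and `max_distance - 1` bases upstream
#' of the gene's 5' end (hits overlapping the gene body are excluded).
#' The source gene's exon count is reported as a manual-review aid
#' (a recycled, intron-less copy should be single-exon).
#'
#' @param hits Survey hits with `coverage_pct`.
#' @param genes Gene models.
#' @param min_coverage Strict query-coverage threshold in percent
#'   (default 70: coverage 70.0 is rejected).
#' @param max_distance Strict upstream distance bound in bp (default 100).
#' @return Tibble: `gene_id`, `scaffold_id`, `strand`, `hit_start`,
#'   `hit_end`, `coverage_pct`, `distance`, `n_exons`.
#' @export
recycling_candidates <- function(hits, genes, min_coverage = 70,
                                 max_distance = 100L) {
  h <- filter(hits, .data$coverage_pct > min_coverage)
  rows <- purrr::pmap(
    list(genes$gene_id, genes$scaffold_id, genes$strand, genes$exons,
         genes$n_exons),
    function(g, scaf, strand, ex, nex) {
      cand <- h[h$scaffold_id == scaf & h$strand == strand, , drop = FALSE]
      if (nrow(cand) == 0) return(NULL)
      if (strand == "+") {
        gene5 <- min(ex$start)
        d <- gene5 - cand$end - 1L
      } else {
        gene5 <- max(ex$end)
        d <- cand$start - gene5 - 1L
      }
      keep <- d > 0L & d < max_distance
      if (!any(keep)) return(NULL)
      tibble(gene_id = g, scaffold_id = scaf, strand = strand,
             hit_start = cand$start[keep], hit_end = cand$end[keep],
             coverage_pct = cand$coverage_pct[keep],
             distance = as.integer(d[keep]), n_exons = nex)
    })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(gene_id = character(), scaffold_id = character(),
                  strand = character(), hit_start = integer(),
                  hit_end = integer(), coverage_pct = numeric(),
                  distance = integer(), n_exons = integer()))
  }
  arrange(out, .data$gene_id, .data$distance)
}
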