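# SL-truncated transcript identification: alignment validation, intron-chain
# comparison against reference gene models, truncation-point filtering of
# transcript-vs-CDS hits, and Type 1/2 assignment.

#' Validate transcript-to-genome alignments
#'
#' An alignment is valid when its average percent identity and the percent
#' of the transcript aligned both reach the thresholds (inclusive).
#'
#' @param alignments Tibble from [read_transcript_alignments()].
#' @param min_identity Minimum average percent identity (default 95).
#' @param min_aligned Minimum percent of transcript aligned (default 90).
#' @return The input with a logical `valid` column added.
#' @export
validate_alignments <- function(alignments, min_identity = 95, min_aligned = 90) {
  mutate(alignments,
         valid = .data$avg_identity_pct >= min_identity &
           .data$percent_aligned >= min_aligned)
}

# intron list (gaps between sorted blocks/exons) as a matrix of start/end
intron_list <- function(blocks) {
  if (nrow(blocks) < 2) return(cbind(start = integer(), end = integer()))
  cbind(start = blocks$end[-nrow(blocks)] + 1L, end = blocks$start[-1] - 1L)
}

# classify one transcript's chain against one gene
chain_class_one <- function(blocks, scaffold, strand, gene) {
  if (scaffold != gene$scaffold_id || strand != gene$strand) return("other")
  ex <- gene$exons[[1]]
  tx_in <- intron_list(blocks)
  g_in <- intron_list(ex)
  span_ok <- blocks$start[1] >= min(ex$start) && blocks$end[nrow(blocks)] <= max(ex$end)

  same_chain <- nrow(tx_in) == nrow(g_in) &&
    (nrow(tx_in) == 0 || all(tx_in == g_in))
  if (same_chain && span_ok) {
    if (nrow(tx_in) > 0) return("equal")
    # both mono-exon: the chains agree trivially; require the block inside
    # the gene's (single) exon
    if (nrow(g_in) == 0) return("equal")
  }

  # containment: transcript introns are a contiguous sub-list of the gene's
  if (nrow(tx_in) == 0) {
    inside <- any(blocks$start[1] >= ex$start & blocks$end[1] <= ex$end)
    return(if (nrow(blocks) == 1 && inside) "contained" else "other")
  }
  if (!span_ok || nrow(tx_in) > nrow(g_in)) return("other")
  k <- nrow(tx_in)
  for (j in seq_len(nrow(g_in) - k + 1)) {
    if (all(g_in[j:(j + k - 1), , drop = FALSE] == tx_in)) {
      prev_ok <- j == 1 || blocks$start[1] > g_in[j - 1, "end"]
      nxt <- j + k
      next_ok <- nxt > nrow(g_in) || blocks$end[nrow(blocks)] < g_in[nxt, "start"]
      if (prev_ok && next_ok) return("contained")
      return("other")
    }
  }
  "other"
}

#' Compare transcript intron chains against reference gene models
#'
#' For each (transcript, gene) pair, classifies the transcript's intron
#' chain (the gaps between its aligned blocks) against the gene's:
#' `equal` when the chains are identical (transcript span within the
#' gene's exonic span), `contained` when the transcript's introns form a
#' contiguous sub-list of the gene's introns with terminal blocks not
#' crossing the bounding reference introns (a mono-exon transcript fully
#' inside one reference exon is contained), `other` otherwise (including
#' scaffold or strand mismatches). These mirror the `=` and `c` transcript
#' classes used when matching assembled transcripts to reference
#' annotation.
#'
#' @param pairs Tibble with `transcript_id` and `gene_id` columns.
#' @param alignments Validated alignments (with `blocks` list-column).
#' @param genes Gene models from [read_gff3_genes()].
#' @return `pairs` with a `chain_class` column added.
#' @export
intron_chain_class <- function(pairs, alignments, genes) {
  aln_by_tx <- split(alignments, alignments$transcript_id)
  gene_by_id <- split(genes, genes$gene_id)
  pairs$chain_class <- purrr::map2_chr(pairs$transcript_id, pairs$gene_id,
    function(tx, g) {
      a <- aln_by_tx[[tx]]
      gn <- gene_by_id[[g]]
      if (is.null(a) || is.null(gn)) return(NA_character_)
      chain_class_one(a$blocks[[1]], a$scaffold_id[1], a$strand[1], gn)
    })
  pairs
}

#' Filter transcript-vs-CDS hits to SL-truncation points
#'
#' A plus-strand hit between an SL-trimmed transcript (query) and a
#' reference CDS (subject) defines a truncation point when it (i) starts
#' at most 2 bp along the transcript, (ii) ends beyond 95% of the
#' transcript or beyond 95% of the CDS (tolerating 3'-UTR overhang), and
#' (iii) starts strictly more than 100 bp along the CDS. The truncation
#' point is the hit's subject start.
#'
#' @param hits Tibble from [read_blast_hits()] (query = trimmed
#'   transcript, subject = gene).
#' @param transcripts Trimmed transcripts tibble (`seq_id`, `sequence`)
#'   supplying transcript lengths.
#' @param genes Gene models (CDS lengths).
#' @param max_q_start Maximum hit start along the transcript (default 2).
#' @param min_end_frac End fraction threshold (default 0.95, strict).
#' @param min_s_start Minimum CDS start, strict (default 100).
#' @return Tibble `transcript_id`, `gene_id`, `truncation_point` for
#'   retained hits.
#' @export
filter_truncation_hits <- function(hits, transcripts, genes,
                                   max_q_start = 2L, min_end_frac = 0.95,
                                   min_s_start = 100L) {
  tx_len <- setNames(nchar(transcripts$sequence), transcripts$seq_id)
  cds_len <- setNames(genes$cds_length, genes$gene_id)
  missing <- setdiff(unique(hits$subject_id), names(cds_len))
  if (length(missing)) {
    warn(paste0("hits to unknown gene(s) skipped: ", paste(missing, collapse = ", ")))
  }
  hits |>
    filter(.data$strand == "+",
           .data$query_id %in% names(tx_len),
           .data$subject_id %in% names(cds_len)) |>
    mutate(tx_len = tx_len[.data$query_id],
           cds_len = cds_len[.data$subject_id]) |>
    filter(.data$q_start <= max_q_start,
           .data$q_end > min_end_frac * .data$tx_len |
             .data$s_end > min_end_frac * .data$cds_len,
           .data$s_start > min_s_start) |>
    mutate(transcript_id = .data$query_id, gene_id = .data$subject_id,
           truncation_point = .data$s_start) |>
    select("transcript_id", "gene_id", "truncation_point")
}

#' Assign Type 1/2 to truncation events from read support
#'
#' At each truncation point, reads covering the position are split into
#' those whose SL motif places an addition site exactly there
#' (SL-evidencing) and the rest. Type 1: the SL-truncated variant is the
#' majority (`sl_reads > non_sl_reads`); Type 2 otherwise (ties are
#' Type 2).
#'
#' @param events Tibble with `gene_id` and `truncation_point` columns.
#' @param reads Filtered reads aligned to CDS coordinates.
#' @param sl An [sl_definition()].
#' @return `events` with `sl_reads`, `non_sl_reads`, `depth`, and `type`
#'   columns added.
#' @export
classify_type <- function(events, reads, sl = sl_definition()) {
  site <- sl_read_site(reads, sl)
  res <- purrr::map2(events$gene_id, events$truncation_point, function(g, p) {
    r_idx <- reads$target_id == g
    r <- reads[r_idx, , drop = FALSE]
    depth <- if (nrow(r)) sum(IRanges::overlapsAny(read_spans(r), IRanges::IRanges(p, p))) else 0L
    sl_n <- sum(site[r_idx] == p, na.rm = TRUE)
    c(sl_n = sl_n, depth = depth)
  })
  events$sl_reads <- purrr::map_int(res, ~ as.integer(.x[["sl_n"]]))
  events$depth <- purrr::map_int(res, ~ as.integer(.x[["depth"]]))
  events$non_sl_reads <- events$depth - events$sl_reads
  events$type <- ifelse(events$sl_reads > events$non_sl_reads, 1L, 2L)
  events
}

#' Identify SL-truncated transcripts end to end
#'
#' Runs the truncation funnel: keep transcripts with a valid genome
#' alignment, whose intron chain is `equal` to or `contained` in the
#' matched reference gene's, with a retained transcript-vs-CDS hit
#' defining a truncation point, and whose truncation-point neighbourhood
#' is free of flagged mispredicted positions; then assigns Type 1/2.
#' Stage counts are attached as attribute `funnel`.
#'
#' @param transcripts Trimmed SL transcripts (`seq_id`, `sequence`).
#' @param alignments Transcript-to-genome alignments.
#' @param hits Transcript-vs-CDS hits (BLAST outfmt-6 semantics).
#' @param genes Gene models.
#' @param reads Filtered reads aligned to CDS coordinates.
#' @param sl An [sl_definition()].
#' @param min_identity,min_aligned Alignment validation thresholds.
#' @param ... Passed to [scan_mispredictions()] (window sizes, spanning
#'   threshold, region extents).
#' @return Tibble of truncation events: `transcript_id`, `gene_id`,
#'   `truncation_point`, `chain_class`, `sl_reads`, `non_sl_reads`,
#'   `depth`, `type`, plus review statistics `mean_nm` and `coverage_cv`
#'   around the point.
#' @export
find_truncations <- function(transcripts, alignments, hits, genes, reads,
                             sl = sl_definition(), min_identity = 95,
                             min_aligned = 90, ...) {
  funnel <- list(input_transcripts = nrow(transcripts))

  val <- validate_alignments(alignments, min_identity, min_aligned) |>
    filter(.data$valid)
  funnel$valid_alignments <- nrow(val)

  cand <- hits |>
    filter(.data$query_id %in% val$transcript_id) |>
    distinct(transcript_id = .data$query_id, gene_id = .data$subject_id)
  cand <- intron_chain_class(cand, val, genes) |>
    filter(.data$chain_class %in% c("equal", "contained"))
  funnel$chain_matched <- nrow(cand)

  pts <- filter_truncation_hits(hits, transcripts, genes) |>
    inner_join(cand, by = c("transcript_id", "gene_id"))
  funnel$retained_hits <- nrow(pts)

  if (nrow(pts) == 0) {
    out <- tibble(transcript_id = character(), gene_id = character(),
                  truncation_point = integer(), chain_class = character(),
                  sl_reads = integer(), non_sl_reads = integer(),
                  depth = integer(), type = integer(),
                  mean_nm = numeric(), coverage_cv = numeric())
    attr(out, "funnel") <- funnel
    return(out)
  }

  scan <- scan_mispredictions(reads, genes,
                              tibble(gene_id = pts$gene_id,
                                     anchor = pts$truncation_point), ...)
  pts$mispred_clean <- scan$n_flagged == 0
  pts$mean_nm <- scan$mean_nm
  pts$coverage_cv <- scan$coverage_cv
  pts <- filter(pts, .data$mispred_clean)
  funnel$mispred_clean <- nrow(pts)

  out <- classify_type(pts, reads, sl) |>
    select("transcript_id", "gene_id", "truncation_point", "chain_class",
           "sl_reads", "non_sl_reads", "depth", "type", "mean_nm",
           "coverage_cv") |>
    arrange(.data$gene_id, .data$truncation_point)
  attr(out, "funnel") <- funnel
  out
}
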