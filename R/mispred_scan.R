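# Gene-model misprediction screening: a sliding 20-bp window (step 1) must
# be fully spanned by at least `min_spanning` aligned reads; a failing
# window flags its 5'-most base as possibly mispredicted (e.g. an
# artificially 5'-extended CDS with no read support over the extension).

#' Count reads fully spanning a window of a CDS
#'
#' A read counts only if its aligned reference span (CIGAR M/D; soft clips
#' are not aligned) covers the whole window.
#'
#' @param reads Reads tibble aligned to CDS coordinates.
#' @param gene_id Target gene.
#' @param win_start,win_end 1-based inclusive window bounds.
#' @return Integer count.
#' @export
spanning_read_count <- function(reads, gene_id, win_start, win_end) {
  r <- reads[reads$target_id == gene_id, , drop = FALSE]
  if (nrow(r) == 0) return(0L)
  spans <- read_spans(r)
  IRanges::countOverlaps(IRanges::IRanges(win_start, win_end), spans,
                         type = "within")
}

# windows [s, s+window-1] for s in [a, b-window+1], flagged where the
# spanning count drops below min_spanning
scan_windows <- function(reads, gene_id, a, b, window, min_spanning) {
  if (b - a + 1L < window) return(integer())
  starts <- seq.int(a, b - window + 1L)
  r <- reads[reads$target_id == gene_id, , drop = FALSE]
  if (nrow(r) == 0) return(starts)
  spans <- read_spans(r)
  wins <- IRanges::IRanges(starts, width = window)
  counts <- IRanges::countOverlaps(wins, spans, type = "within")
  starts[counts < min_spanning]
}

# review statistics over a region: mean NM of overlapping reads and the
# coefficient of variation of per-position depth (manual-curation aids,
# reported, never used to drop genes automatically)
region_review_stats <- function(reads, gene_id, a, b) {
  r <- reads[reads$target_id == gene_id, , drop = FALSE]
  if (nrow(r) == 0) return(c(mean_nm = NA_real_, coverage_cv = NA_real_))
  spans <- read_spans(r)
  ov <- IRanges::overlapsAny(spans, IRanges::IRanges(a, b))
  cov <- IRanges::coverage(spans, width = max(b, max(IRanges::end(spans))))
  depth <- as.numeric(cov)[a:b]
  c(mean_nm = if (any(ov)) mean(r$edit_distance[ov], na.rm = TRUE) else NA_real_,
    coverage_cv = if (mean(depth) > 0) stats::sd(depth) / mean(depth) else NA_real_)
}

#' Scan around SL anchors for mispredicted gene-model regions
#'
#' For each anchor (an SL-truncation point or addition site), the region
#' from `upstream` bp before the anchor to `downstream` bp after it is
#' scanned with a sliding window of `window` bases (step 1). If the anchor
#' lies less than 200 bp along the CDS, the upstream bound is pulled in to
#' halfway between the anchor and the CDS 5' end (`ceiling(anchor/2)`).
#' Windows truncated by the CDS 3' end are not scanned. A window spanned by
#' fewer than `min_spanning` reads flags its first (5'-most) base.
#'
#' @param reads Filtered reads aligned to CDS coordinates (the same
#'   filtered set used for site calling).
#' @param genes Gene models from [read_gff3_genes()].
#' @param anchors Tibble with `gene_id` and `anchor` (1-based CDS
#'   position) columns.
#' @param window Window size in bp (default 20).
#' @param min_spanning Minimum fully-spanning reads; a window with fewer
#'   flags (default 10, i.e. 9 spanning reads flag, 10 do not).
#' @param upstream,downstream Region extent around the anchor
#'   (defaults 100 and 50).
#' @return A tibble with one row per anchor: `gene_id`, `anchor`,
#'   `region_start`, `region_end`, `flagged_positions` (list-column of
#'   sorted flagged window-start positions), `n_flagged`, and the review
#'   statistics `mean_nm` and `coverage_cv`.
#' @export
scan_mispredictions <- function(reads, genes, anchors, window = 20L,
                                min_spanning = 10L, upstream = 100L,
                                downstream = 50L) {
  len <- setNames(genes$cds_length, genes$gene_id)
  rows <- purrr::pmap(list(anchors$gene_id, anchors$anchor), function(g, anchor) {
    L <- len[[g]]
    if (is.null(L)) abort(paste0("unknown gene_id: ", g))
    if (anchor < 1 || anchor > L) {
      abort(sprintf("anchor %d outside CDS of %s (length %d)", anchor, g, L))
    }
    a <- anchor - upstream
    if (anchor < 200L) a <- max(a, as.integer(ceiling(anchor / 2)))
    a <- max(a, 1L)
    b <- min(anchor + downstream, L)
    flagged <- sort(scan_windows(reads, g, a, b, window, min_spanning))
    stats <- region_review_stats(reads, g, a, b)
    tibble(gene_id = g, anchor = as.integer(anchor),
           region_start = as.integer(a), region_end = as.integer(b),
           flagged_positions = list(as.integer(flagged)),
           n_flagged = length(flagged),
           mean_nm = stats[["mean_nm"]], coverage_cv = stats[["coverage_cv"]])
  })
  bind_rows(rows)
}

#' Scan an arbitrary CDS interval for mispredicted regions
#'
#' Applies the same sliding-window spanning-read test to the interval
#' `[int_start, int_end]` (used, e.g., for the stretch between a feature's
#' 5' end and an SL addition site). Intervals shorter than one window have
#' no scannable windows and return an empty report.
#'
#' @inheritParams scan_mispredictions
#' @param gene_id Target gene.
#' @param int_start,int_end 1-based inclusive interval bounds within the CDS.
#' @return A one-row tibble in the [scan_mispredictions()] format (the
#'   `anchor` column holds `int_end`).
#' @export
scan_cds_interval <- function(reads, genes, gene_id, int_start, int_end,
                              window = 20L, min_spanning = 10L) {
  L <- genes$cds_length[genes$gene_id == gene_id]
  if (length(L) != 1) abort(paste0("unknown gene_id: ", gene_id))
  if (int_start > int_end) abort("int_start must be <= int_end")
  if (int_start < 1 || int_end > L) abort("interval outside CDS")
  flagged <- sort(scan_windows(reads, gene_id, int_start, int_end, window, min_spanning))
  stats <- region_review_stats(reads, gene_id, int_start, int_end)
  tibble(gene_id = gene_id, anchor = as.integer(int_end),
         region_start = as.integer(int_start), region_end = as.integer(int_end),
         flagged_positions = list(as.integer(flagged)),
         n_flagged = length(flagged),
         mean_nm = stats[["mean_nm"]], coverage_cv = stats[["coverage_cv"]])
}
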