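# SL addition-site calling on CDS alignments: concordant-pair filtering,
# motif-bearing read positioning (including the 5' soft-clip case),
# junction/context classification, and the per-site summary statistics.

# per-read 3' soft-clip length: trailing clip for forward reads, leading
# clip for reverse-strand reads (CIGAR is stored in reference orientation)
three_prime_clip <- function(reads) {
  clips <- cigar_clips(reads$cigar)
  ifelse(reads$reverse, clips$lead, clips$trail)
}

#' Filter aligned reads to concordant, well-aligned pairs
#'
#' A pair is retained only if both mates are present, both are flagged
#' properly paired (SAM 0x2), each has at most `max_clip3` bases of
#' soft-clipping at its 3' end, and each has an edit distance (NM) of at
#' most `max_edit`. Soft-clipping of any length at the 5' end is allowed,
#' because the SL leader itself produces 5' soft clips. Orphan mates and
#' reads with missing NM fail; the number of dropped pairs is attached as
#' attribute `n_dropped_pairs`.
#'
#' @param reads A reads tibble from [read_sam()].
#' @param max_clip3 Maximum 3' soft-clip length (default 5).
#' @param max_edit Maximum per-read edit distance (default 5).
#' @return The retained reads, same columns as the input.
#' @export
filter_read_pairs <- function(reads, max_clip3 = 5L, max_edit = 5L) {
  if (nrow(reads) == 0) return(reads)
  clip3 <- three_prime_clip(reads)
  ok <- reads$properly_paired &
    clip3 <= max_clip3 &
    !is.na(reads$edit_distance) & reads$edit_distance <= max_edit

  per_pair <- tibble(read_id = reads$read_id, ok = ok) |>
    group_by(.data$read_id) |>
    summarise(n = dplyr::n(), all_ok = all(.data$ok), .groups = "drop")
  keep_ids <- per_pair$read_id[per_pair$n == 2L & per_pair$all_ok]
  out <- reads[reads$read_id %in% keep_ids, , drop = FALSE]
  attr(out, "n_dropped_pairs") <- nrow(per_pair) - length(keep_ids)
  out
}

# CDS position evidenced by each motif-bearing read: the reference position
# of the first aligned base at or after the base following the motif.
# NA when the motif (or everything after it) lies beyond the aligned span.
sl_read_site <- function(reads, sl) {
  offs <- locate_sl_in_reads(reads$sequence, sl)
  idx <- which(!is.na(offs))
  site <- rep(NA_integer_, nrow(reads))
  for (i in idx) {
    site[i] <- ref_pos_at_or_after(reads$cigar[i], reads$start[i], offs[i] + 1L)
  }
  site
}

# aligned reference spans of reads, as an IRanges per target
read_spans <- function(reads) {
  IRanges::IRanges(start = reads$start,
                   width = cigar_ref_width(reads$cigar))
}

#' Call SL addition sites from filtered reads aligned to CDSs
#'
#' Each retained read is searched for the conserved SL region; the CDS
#' position of the first base after the motif is the evidenced site. When
#' the motif lies wholly within the 5' soft clip, the position of the first
#' mapped base is reported instead. Positions supported by more than
#' `min_support` motif-bearing reads are emitted, unless a flagged
#' mispredicted position on the same gene lies within
#' `exclusion_distance` bp. Depth at a site counts the retained reads whose
#' aligned span covers the position.
#'
#' @param reads Filtered reads (see [filter_read_pairs()]) aligned to CDS
#'   coordinates (`target_id` = gene id).
#' @param genes Gene models from [read_gff3_genes()].
#' @param sl An [sl_definition()].
#' @param min_support Strict support threshold: a site needs
#'   `> min_support` supporting reads (default 10, i.e. at least 11).
#' @param mispred Optional misprediction report from
#'   [scan_mispredictions()] (or a tibble with `gene_id` and `position`).
#' @param exclusion_distance Sites within this distance of a flagged
#'   position are suppressed (default 100).
#' @param near_window Window (bp) around a CDS-internal exon start within
#'   which a site counts as `near_junction` (default 2).
#' @return A tibble of sites: `gene_id`, `position`, `supporting_reads`,
#'   `depth`, `support_fraction`, `relative_position_pct`, `context_class`.
#' @export
call_sl_sites <- function(reads, genes, sl = sl_definition(),
                          min_support = 10L, mispred = NULL,
                          exclusion_distance = 100L, near_window = 2L) {
  site <- sl_read_site(reads, sl)
  ev <- tibble(gene_id = reads$target_id, position = site) |>
    filter(!is.na(.data$position)) |>
    dplyr::count(.data$gene_id, .data$position, name = "supporting_reads") |>
    filter(.data$supporting_reads > min_support)

  if (nrow(ev) == 0) {
    return(tibble(gene_id = character(), position = integer(),
                  supporting_reads = integer(), depth = integer(),
                  support_fraction = numeric(),
                  relative_position_pct = numeric(),
                  context_class = character()))
  }

  # depth: retained reads covering the site position
  ev$depth <- purrr::map2_int(ev$gene_id, ev$position, function(g, p) {
    r <- reads[reads$target_id == g, , drop = FALSE]
    sum(IRanges::overlapsAny(read_spans(r), IRanges::IRanges(p, p)))
  })
  ev$support_fraction <- ev$supporting_reads / ev$depth

  # misprediction exclusion: must be further than exclusion_distance away
  flagged <- mispred_positions(mispred)
  if (nrow(flagged) > 0) {
    ev <- ev |>
      left_join(
        flagged |> group_by(.data$gene_id) |>
          summarise(flags = list(.data$position), .groups = "drop"),
        by = "gene_id"
      ) |>
      filter(purrr::map2_lgl(.data$flags, .data$position, function(f, p) {
        is.null(f) || all(abs(f - p) > exclusion_distance)
      })) |>
      select(-"flags")
  }

  ev <- ev |>
    inner_join(select(genes, "gene_id", "cds_length"), by = "gene_id") |>
    mutate(relative_position_pct = (.data$position - 1) / .data$cds_length * 100)
  ev <- classify_junction(ev, genes, near_window = near_window)
  select(ev, "gene_id", "position", "supporting_reads", "depth",
         "support_fraction", "relative_position_pct", "context_class") |>
    arrange(.data$gene_id, .data$position)
}

# normalize a misprediction report (or long tibble) to gene_id/position
mispred_positions <- function(mispred) {
  if (is.null(mispred) || nrow(mispred) == 0) {
    return(tibble(gene_id = character(), position = integer()))
  }
  if ("flagged_positions" %in% names(mispred)) {
    return(mispred |>
             select("gene_id", "flagged_positions") |>
             tidyr::unnest_longer("flagged_positions", values_to = "position") |>
             filter(!is.na(.data$position)))
  }
  select(mispred, "gene_id", "position")
}

#' Classify SL addition sites relative to exon junctions
#'
#' Exon starts in CDS coordinates are the cumulative CDS-piece lengths of
#' the gene model. Position 1 is its own class (`position_1`: addition at
#' or upstream of the CDS start, indistinguishable from 5'-UTR addition
#' with CDS-aligned short reads). A site equal to a non-first exon start is
#' `precise_junction`; within `near_window` bp of one, `near_junction`;
#' anything else `internal`.
#'
#' @param sites Tibble with `gene_id` and `position` columns.
#' @param genes Gene models from [read_gff3_genes()].
#' @param near_window Window in bp (default 2).
#' @return `sites` with a `context_class` column added (or replaced).
#' @export
classify_junction <- function(sites, genes, near_window = 2L) {
  starts_by_gene <- setNames(genes$cds_piece_starts, genes$gene_id)
  sites$context_class <- purrr::map2_chr(sites$gene_id, sites$position, function(g, p) {
    if (p == 1L) return("position_1")
    st <- starts_by_gene[[g]]
    if (is.null(st)) abort(paste0("unknown gene_id: ", g))
    st <- st[st != 1L]  # non-first exon starts
    if (length(st) && any(st == p)) return("precise_junction")
    if (length(st) && any(abs(st - p) <= near_window)) return("near_junction")
    "internal"
  })
  sites
}

#' Summarise called SL addition sites
#'
#' Reports the unweighted mean read support and the mean relative position
#' (percent of CDS length, 5' to 3'), plus the mean relative position of
#' sites with above- versus below-average support. When all sites share
#' the same support fraction the above-mean group is empty and its mean is
#' `NA` (undefined).
#'
#' @param sites Site tibble from [call_sl_sites()].
#' @return A one-row tibble: `n_sites`, `n_genes`, `n_position_1`,
#'   `n_junction` (precise + near), `n_precise_junction`, `n_internal`,
#'   `mean_support_pct`, `mean_relative_position_pct`,
#'   `above_mean_relative_pct`, `below_mean_relative_pct`.
#' @export
summarize_sl_sites <- function(sites) {
  if (nrow(sites) == 0) abort("no sites to summarise")
  mean_frac <- mean(sites$support_fraction)
  above <- sites$support_fraction > mean_frac
  below <- sites$support_fraction < mean_frac
  tibble(
    n_sites = nrow(sites),
    n_genes = dplyr::n_distinct(sites$gene_id),
    n_position_1 = sum(sites$context_class == "position_1"),
    n_junction = sum(sites$context_class %in% c("precise_junction", "near_junction")),
    n_precise_junction = sum(sites$context_class == "precise_junction"),
    n_internal = sum(sites$context_class == "internal"),
    mean_support_pct = mean_frac * 100,
    mean_relative_position_pct = mean(sites$relative_position_pct),
    above_mean_relative_pct = if (any(above)) mean(sites$relative_position_pct[above]) else NA_real_,
    below_mean_relative_pct = if (any(below)) mean(sites$relative_position_pct[below]) else NA_real_
  )
}

#' Sequence-context matrix (logo) around internal SL addition sites
#'
#' Builds per-position base frequencies and information content for the
#' CDS context `flank` bp either side of each internal (non-junction)
#' addition site; the site base itself is relative position 0. Sites too
#' close to a CDS end to provide a full window are excluded -- these are
#' the "close to the end" sites a display-window logo cannot use.
#' Information content per column is `2 + sum(f * log2(f))` bits.
#'
#' @param sites Site tibble from [call_sl_sites()]; only rows with
#'   `context_class == "internal"` are used.
#' @param genes Gene models (for CDS sequences).
#' @param flank Bases either side of the site (default 5).
#' @return An object of class `sl_logo`: list with `freq` (4 x 2*flank+1
#'   matrix, rows A,C,G,T; columns relative positions), `info`
#'   (bits per column), `n_sites` used.
#' @export
sl_logo <- function(sites, genes, flank = 5L) {
  internal <- filter(sites, .data$context_class == "internal")
  cds <- setNames(genes$cds_sequence, genes$gene_id)
  len <- setNames(genes$cds_length, genes$gene_id)
  usable <- internal |>
    filter(.data$position - flank >= 1,
           .data$position + flank <= len[.data$gene_id])
  if (nrow(usable) == 0) abort("no usable internal sites with full flanks")
  ctx <- substr(cds[usable$gene_id], usable$position - flank, usable$position + flank)
  mat <- do.call(rbind, strsplit(ctx, ""))
  bases <- c("A", "C", "G", "T")
  freq <- apply(mat, 2, function(col) {
    col <- col[col %in% bases]
    tab <- table(factor(col, levels = bases))
    as.numeric(tab) / sum(tab)
  })
  rownames(freq) <- bases
  colnames(freq) <- as.character(seq(-flank, flank))
  info <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(freq = freq, info = info, n_sites = nrow(usable), flank = flank),
            class = "sl_logo")
}

#' @export
print.sl_logo <- function(x, ...) {
  cat(sprintf("<sl_logo> %d sites, positions %s..%s\n", x$n_sites,
              colnames(x$freq)[1], colnames(x$freq)[ncol(x$freq)]))
  print(round(x$freq, 3))
  cat("information (bits):\n")
  print(round(x$info, 3))
  invisible(x)
}

#' Tidy an SL sequence logo
#'
#' @param x An `sl_logo` object.
#' @param ... Unused.
#' @return A tibble with `position` (relative to the addition point),
#'   `base`, `freq`, and the per-position `info` in bits.
#' @export
tidy.sl_logo <- function(x, ...) {
  tibble(
    position = rep(as.integer(colnames(x$freq)), each = nrow(x$freq)),
    base = rep(rownames(x$freq), times = ncol(x$freq)),
    freq = as.numeric(x$freq),
    info = rep(x$info, each = nrow(x$freq))
  )
}

#' Plot an SL addition-site sequence logo
#'
#' Letters are stacked per position with heights proportional to
#' `freq * info` (bits), the standard information-content scaling.
#'
#' @param object An `sl_logo` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sl_logo <- function(object, ...) {
  df <- tidy(object) |>
    mutate(height = .data$freq * .data$info) |>
    filter(.data$height > 0) |>
    group_by(.data$position) |>
    arrange(.data$height, .by_group = TRUE) |>
    mutate(ymax = cumsum(.data$height), ymin = .data$ymax - .data$height,
           ymid = (.data$ymin + .data$ymax) / 2) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid,
                                   label = .data$base, colour = .data$base)) +
    ggplot2::geom_text(ggplot2::aes(size = .data$height), fontface = "bold",
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 10)) +
    ggplot2::scale_colour_manual(values = c(A = "#33A02C", C = "#1F78B4",
                                            G = "#FF7F00", T = "#E31A1C")) +
    ggplot2::scale_x_continuous(breaks = seq(-object$flank, object$flank)) +
    ggplot2::labs(x = "position relative to SL addition point",
                  y = "information (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
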