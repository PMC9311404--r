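# Predicted protein consequences of SL truncation: downstream in-frame
# start codons, removed features, Categories A-D, and site-vs-feature
# retrieval with the >60 bp within-feature rule.
#
# Categories: A = targeting signal removed (protein re-localized);
# B = upstream functional/structural feature removed or truncated;
# C = translation suppressed (no downstream in-frame AUG, or the retained
# protein is a small fraction of the full length); D = multiple SL
# addition sites on the gene. Categories can co-occur.

#' Merge overlapping protein features per gene and kind
#'
#' Overlapping or bookended intervals of the same kind on the same gene
#' are merged (interval union); labels of merged members are concatenated.
#'
#' @param features Tibble from [read_feature_table()].
#' @return Tibble with the same columns, minimal (no two intervals of one
#'   gene/kind overlap or touch).
#' @export
merge_features <- function(features) {
  if (nrow(features) == 0) return(features)
  features |>
    group_by(.data$gene_id, .data$kind) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::IRanges(df$aa_start, df$aa_end)
      red <- IRanges::reduce(ir)
      ov <- IRanges::findOverlaps(ir, red, maxgap = 1L)
      labels <- vapply(seq_along(red), function(i) {
        paste(unique(df$label[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]]),
              collapse = ",")
      }, character(1))
      tibble(aa_start = IRanges::start(red), aa_end = IRanges::end(red),
             label = labels)
    }) |>
    ungroup() |>
    select("gene_id", "kind", "aa_start", "aa_end", "label") |>
    arrange(.data$gene_id, .data$kind, .data$aa_start)
}

#' First in-frame start codon at or after a truncation point
#'
#' Returns the smallest CDS position `p >= truncation_point` with
#' `p == 1 (mod 3)` (reading frame of the annotated CDS) where the codon
#' is ATG, or `NA` when the truncated transcript has no downstream
#' in-frame start.
#'
#' @param cds_sequence Character vector of CDS sequences.
#' @param truncation_point Integer vector of 1-based CDS positions
#'   (recycled against `cds_sequence`).
#' @return Integer vector of retained start positions (`NA` = none).
#' @examples
#' downstream_start("ATGAAAATGCCC", 4)  # 7
#' @export
downstream_start <- function(cds_sequence, truncation_point) {
  unname(purrr::map2_int(cds_sequence, truncation_point, function(cds, point) {
    L <- nchar(cds)
    if (point < 1 || point > L) abort("truncation_point outside CDS")
    p <- point + ((1L - point) %% 3L)  # first in-frame codon start >= point
    while (p + 2L <= L) {
      if (substr(cds, p, p + 2L) == "ATG") return(as.integer(p))
      p <- p + 3L
    }
    NA_integer_
  }))
}

# protein aa interval -> CDS nucleotide interval
aa_to_nt <- function(features) {
  mutate(features, nt_start = 3L * .data$aa_start - 2L, nt_end = 3L * .data$aa_end)
}

#' Categorize truncation events by predicted protein consequence
#'
#' For each event, finds the retained start ([downstream_start()]) and the
#' remaining protein fraction, then assigns categories: `C` when there is
#' no downstream in-frame start or the remaining fraction is below
#' `min_remaining`; `A` when a targeting-signal feature lies entirely 5'
#' of the retained start (the signal is removed); `B` when a domain,
#' transmembrane, or coil feature has its 5' end upstream of the retained
#' start (removed or truncated); `D` when the gene carries two or more SL
#' addition sites. Categories may co-occur. Feature coordinates are
#' converted from protein to CDS space (aa i -> nt 3i-2..3i).
#'
#' @param events Truncation events (tibble with `gene_id`,
#'   `truncation_point`).
#' @param genes Gene models (CDS sequences and lengths).
#' @param features Protein features; merged internally via
#'   [merge_features()].
#' @param sites Optional site tibble used to count SL addition sites per
#'   gene for Category D; when `NULL`, distinct truncation points per gene
#'   among `events` are counted instead.
#' @param min_remaining Minimum remaining protein fraction below which an
#'   event is Category C even with a valid start (default 0.25).
#' @return `events` with `retained_start`, `remaining_fraction`,
#'   `n_sites_on_gene`, `categories` (list-column of character sets) and
#'   `categories_str` added.
#' @export
categorize_truncations <- function(events, genes, features, sites = NULL,
                                   min_remaining = 0.25) {
  cds <- setNames(genes$cds_sequence, genes$gene_id)
  len <- setNames(genes$cds_length, genes$gene_id)

  feats <- merge_features(features) |> aa_to_nt()
  over <- feats$nt_end > len[feats$gene_id]
  if (any(over, na.rm = TRUE)) {
    abort(sprintf("feature exceeds protein length on gene %s",
                  feats$gene_id[which(over)[1]]))
  }

  n_sites <- if (!is.null(sites)) {
    sites |> dplyr::count(.data$gene_id, name = "n_sites_on_gene")
  } else {
    events |> distinct(.data$gene_id, .data$truncation_point) |>
      dplyr::count(.data$gene_id, name = "n_sites_on_gene")
  }

  events$retained_start <- downstream_start(cds[events$gene_id],
                                            events$truncation_point)
  L <- unname(len[events$gene_id])
  events$remaining_fraction <- ifelse(
    is.na(events$retained_start), 0,
    (L - events$retained_start + 1) / L
  )
  events <- left_join(events, n_sites, by = "gene_id") |>
    mutate(n_sites_on_gene = dplyr::coalesce(.data$n_sites_on_gene, 0L))

  feats_by_gene <- split(feats, feats$gene_id)
  events$categories <- purrr::pmap(
    list(events$gene_id, events$retained_start, events$remaining_fraction,
         events$n_sites_on_gene),
    function(g, rs, frac, ns) {
      cats <- character()
      if (is.na(rs) || frac < min_remaining) cats <- c(cats, "C")
      f <- feats_by_gene[[g]]
      if (!is.null(f) && !is.na(rs)) {
        if (any(f$kind == "targeting_signal" & f$nt_end < rs)) cats <- c(cats, "A")
        if (any(f$kind %in% c("domain", "transmembrane", "coil") &
                  f$nt_start < rs)) cats <- c(cats, "B")
      }
      if (ns >= 2) cats <- c(cats, "D")
      sort(cats)
    })
  events$categories_str <- purrr::map_chr(events$categories, paste, collapse = "")
  events
}

#' Relate SL addition sites to protein features with misprediction checks
#'
#' Classifies each site against the gene's merged features (CDS-nucleotide
#' space): `downstream_of_feature` when the site lies strictly 3' of its
#' nearest upstream non-overlapping feature, and `within_feature` when the
#' site falls inside a feature more than `offset_min` bp from the
#' feature's 5' end. In both cases the stretch from the feature's 5' end
#' to the site is scanned for mispredicted windows ([scan_cds_interval()])
#' and the result reported as `scan_clean`. Ties for "nearest" are broken
#' by first feature in sorted order.
#'
#' @param sites Site tibble ([call_sl_sites()]).
#' @param features Protein features (merged internally).
#' @param genes Gene models.
#' @param reads Filtered reads (for the misprediction scan).
#' @param offset_min Strict minimum offset from the overlapped feature's
#'   5' end (default 60: offset 60 is excluded, 61 retained).
#' @param window,min_spanning Passed to [scan_cds_interval()].
#' @return `sites` with columns `feature_relation`
#'   (`"downstream_of_feature"`, `"within_feature"`, or `NA`),
#'   `feature_kind`, `feature_nt_start`, `feature_nt_end`, `offset`
#'   (site - feature 5' start, within-feature rows), and `scan_clean`.
#' @export
sites_relative_to_features <- function(sites, features, genes, reads,
                                       offset_min = 60L, window = 20L,
                                       min_spanning = 10L) {
  feats <- merge_features(features) |> aa_to_nt() |>
    arrange(.data$gene_id, .data$nt_start, .data$nt_end)
  feats_by_gene <- split(feats, feats$gene_id)

  res <- purrr::pmap(list(sites$gene_id, sites$position), function(g, p) {
    blank <- tibble(feature_relation = NA_character_,
                    feature_kind = NA_character_,
                    feature_nt_start = NA_integer_, feature_nt_end = NA_integer_,
                    offset = NA_integer_, scan_clean = NA)
    f <- feats_by_gene[[g]]
    if (is.null(f)) return(blank)
    inside <- which(f$nt_start <= p & f$nt_end >= p)
    if (length(inside)) {
      i <- inside[1]  # first in sorted order on ties
      off <- p - f$nt_start[i]
      if (off > offset_min) {
        scan <- scan_cds_interval(reads, genes, g, f$nt_start[i], p,
                                  window = window, min_spanning = min_spanning)
        return(tibble(feature_relation = "within_feature",
                      feature_kind = f$kind[i],
                      feature_nt_start = f$nt_start[i],
                      feature_nt_end = f$nt_end[i],
                      offset = as.integer(off),
                      scan_clean = scan$n_flagged == 0))
      }
      return(blank)
    }
    up <- which(f$nt_end < p)
    if (length(up)) {
      best_end <- max(f$nt_end[up])
      i <- up[which(f$nt_end[up] == best_end)[1]]
      scan <- scan_cds_interval(reads, genes, g, f$nt_start[i], p,
                                window = window, min_spanning = min_spanning)
      return(tibble(feature_relation = "downstream_of_feature",
                    feature_kind = f$kind[i],
                    feature_nt_start = f$nt_start[i],
                    feature_nt_end = f$nt_end[i],
                    offset = as.integer(p - f$nt_start[i]),
                    scan_clean = scan$n_flagged == 0))
    }
    blank
  })
  dplyr::bind_cols(sites, bind_rows(res))
}
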