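# End-to-end conveniences: the two-pass site pipeline (candidate sites ->
# misprediction scan around candidates -> final exclusion) and the
# recovery report comparing pipeline output against a simulation's
# planted truth.

#' Call SL addition sites with misprediction exclusion (two passes)
#'
#' First pass: filter read pairs and call candidate sites with no
#' exclusion. Second pass: scan for mispredicted windows around every
#' candidate site located more than 100 bp along the CDS (the
#' misprediction test is defined around such anchors) and re-call sites
#' excluding those within `exclusion_distance` of a flagged position.
#'
#' @param reads Raw reads from [read_sam()] (the pair filter is applied
#'   here).
#' @param genes Gene models.
#' @param sl An [sl_definition()].
#' @param min_support Strict support threshold (default 10).
#' @param exclusion_distance Exclusion radius around flagged positions
#'   (default 100).
#' @param ... Passed to [scan_mispredictions()].
#' @return A site tibble ([call_sl_sites()] format), with the
#'   misprediction report attached as attribute `mispred` and the filtered
#'   reads as attribute `filtered_reads`.
#' @export
sl_site_pipeline <- function(reads, genes, sl = sl_definition(),
                             min_support = 10L, exclusion_distance = 100L,
                             ...) {
  filtered <- filter_read_pairs(reads)
  candidates <- call_sl_sites(filtered, genes, sl, min_support = min_support)
  anchors <- candidates |>
    filter(.data$position > 100L) |>
    select("gene_id", anchor = "position")
  mispred <- if (nrow(anchors) > 0) {
    scan_mispredictions(filtered, genes, anchors, ...)
  } else NULL
  out <- call_sl_sites(filtered, genes, sl, min_support = min_support,
                       mispred = mispred,
                       exclusion_distance = exclusion_distance)
  attr(out, "mispred") <- mispred
  attr(out, "filtered_reads") <- filtered
  out
}

set_metrics <- function(truth_keys, called_keys) {
  tp <- length(intersect(truth_keys, called_keys))
  tibble(
    n_truth = length(truth_keys), n_called = length(called_keys),
    sensitivity = if (length(truth_keys)) tp / length(truth_keys) else NA_real_,
    precision = if (length(called_keys)) tp / length(called_keys) else NA_real_
  )
}

#' Run the whole pipeline on a simulation and score recovery
#'
#' Executes every stage on the simulated inputs and compares the results
#' with the planted truth: exact-coordinate site recovery, truncation
#' event recovery, Type and Category label agreement, genome-survey locus
#' recovery, recycling-candidate recovery, and the expression-group test.
#'
#' @param sim An `slts_sim` object from [simulate_slts()].
#' @return A list of class `slts_recovery`: `stages` (tibble of
#'   sensitivity/precision per stage), `sites`, `events`, `site_summary`,
#'   `expression` (the test object), and `mispred_detection`.
#' @export
recovery_report <- function(sim) {
  genes <- sim$genes
  sl <- sim$sl

  ## sites
  sites <- sl_site_pipeline(sim$reads, genes, sl)
  filtered <- attr(sites, "filtered_reads")
  truth_sites <- sim$truth$planted_sites
  key <- function(g, p) paste(g, p)
  site_m <- set_metrics(key(truth_sites$gene_id, truth_sites$position),
                        key(sites$gene_id, sites$position))

  ## context agreement for recovered sites
  joined <- inner_join(sites,
                       select(truth_sites, "gene_id", "position",
                              truth_context = "context_class"),
                       by = c("gene_id", "position"))
  context_ok <- mean(joined$context_class == joined$truth_context)

  ## truncation events
  sl_tx <- find_sl(sim$transcripts, sl)
  trimmed <- trim_sl(sl_tx)
  events <- find_truncations(trimmed, sim$alignments, sim$hits, genes,
                             filtered, sl)
  truth_ev <- sim$truth$truncation_events
  ev_m <- set_metrics(key(truth_ev$gene_id, truth_ev$truncation_point),
                      key(events$gene_id, events$truncation_point))
  ev_joined <- inner_join(events, truth_ev,
                          by = c("transcript_id", "gene_id",
                                 "truncation_point"))
  type_ok <- mean(ev_joined$type == ev_joined$planted_type)

  ## categories
  cats <- categorize_truncations(events, genes, sim$features, sites = sites)
  cat_joined <- inner_join(cats,
                           select(truth_ev, "gene_id", "truncation_point",
                                  "planted_categories"),
                           by = c("gene_id", "truncation_point"))
  cat_ok <- mean(cat_joined$categories_str == cat_joined$planted_categories)

  ## genome survey
  hits <- scan_genome_sl(sim$genome, sl) |> classify_sl_hits(sl)
  truth_loci <- sim$truth$sl_loci
  full_truth <- filter(truth_loci, .data$kind == "full")
  part_truth <- filter(truth_loci, .data$kind == "partial")
  hkey <- function(s, a, b, st) paste(s, a, b, st)
  full_called <- filter(hits, .data$classification == "full")
  part_called <- filter(hits, .data$classification == "partial")
  full_recovered <- all(hkey(full_truth$scaffold_id, full_truth$start,
                             full_truth$end, full_truth$strand) %in%
                          hkey(full_called$scaffold_id, full_called$start,
                               full_called$end, full_called$strand))
  part_key_truth <- paste(part_truth$scaffold_id, part_truth$start,
                          part_truth$end, part_truth$strand, part_truth$q_start)
  part_key_called <- paste(part_called$scaffold_id, part_called$start,
                           part_called$end, part_called$strand,
                           part_called$q_start)
  partial_recovered <- all(part_key_truth %in% part_key_called)

  ## recycling
  rec <- recycling_candidates(hits, genes)
  truth_rec <- sim$truth$recycled_paralogs
  rec_m <- set_metrics(truth_rec$gene_id, unique(rec$gene_id))

  ## misprediction detection
  mp_truth <- sim$truth$mispredicted_genes
  mp_detect <- if (nrow(mp_truth) > 0) {
    scan <- scan_mispredictions(
      filtered, genes,
      tibble(gene_id = mp_truth$gene_id,
             anchor = mp_truth$true_cds_start_offset + 100L))
    clean_genes <- setdiff(genes$gene_id,
                           c(mp_truth$gene_id, sim$truth$recycled_paralogs$gene_id))
    clean_anchor <- genes |>
      filter(.data$gene_id %in% clean_genes, .data$cds_length >= 500) |>
      slice(seq_len(min(5, dplyr::n())))
    clean_scan <- scan_mispredictions(
      filtered, genes,
      tibble(gene_id = clean_anchor$gene_id, anchor = 300L))
    tibble(
      flagged_sensitivity = mean(scan$n_flagged > 0),
      leftmost_match = mean(purrr::map2_lgl(
        scan$flagged_positions, mp_truth$true_cds_start_offset,
        function(fp, o) length(fp) > 0 && min(fp) == o)),
      clean_false_rate = mean(clean_scan$n_flagged > 0)
    )
  } else NULL

  ## expression
  tpm <- compute_tpm(sim$counts, genes)
  expr <- sl_expression_test(tpm, unique(truth_sites$gene_id))

  stages <- bind_rows(
    mutate(site_m, stage = "sl_sites"),
    mutate(ev_m, stage = "truncation_events"),
    mutate(rec_m, stage = "recycling_candidates")
  ) |>
    select("stage", "n_truth", "n_called", "sensitivity", "precision")

  structure(
    list(stages = stages, sites = sites, events = events,
         site_summary = summarize_sl_sites(sites),
         context_agreement = context_ok, type_agreement = type_ok,
         category_agreement = cat_ok,
         full_loci_recovered = full_recovered,
         partial_loci_recovered = partial_recovered,
         mispred_detection = mp_detect,
         expression = expr, categories = cats, survey_hits = hits),
    class = "slts_recovery"
  )
}

#' @export
print.slts_recovery <- function(x, ...) {
  cat("SLTS pipeline recovery report\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  cat(sprintf("context agreement: %.3f | type agreement: %.3f | category agreement: %.3f\n",
              x$context_agreement, x$type_agreement, x$category_agreement))
  cat(sprintf("SL loci recovered: full=%s partial=%s\n",
              x$full_loci_recovered, x$partial_loci_recovered))
  if (!is.null(x$mispred_detection)) {
    cat(sprintf("misprediction detection: sensitivity=%.2f leftmost-match=%.2f false-rate=%.2f\n",
                x$mispred_detection$flagged_sensitivity,
                x$mispred_detection$leftmost_match,
                x$mispred_detection$clean_false_rate))
  }
  cat(sprintf("expression: t=%.3f df=%.1f p=%.3g (SL mean %.1f vs %.1f)\n",
              x$expression$t, x$expression$df, x$expression$p_value,
              x$expression$mean_sl, x$expression$mean_no_sl))
  invisible(x)
}
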