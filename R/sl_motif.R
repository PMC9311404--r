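# SL motif detection in assembled transcripts and in raw read sequences.
# Matching is exact (0 mismatches) on the conserved region; N never matches.

# leftmost exact match position (1-based) of the conserved region in seq,
# restricted to start positions <= max_start; NA if none.
conserved_match_start <- function(seq, conserved, max_start) {
  hit <- unname(stringr::str_locate(seq, stringr::fixed(conserved))[, "start"])
  ifelse(!is.na(hit) & hit <= max_start, hit, NA_integer_)
}

#' Locate the SL conserved region at transcript 5' ends
#'
#' A transcript carries the leader if the conserved SL region matches
#' exactly (no mismatches) starting within the first
#' `max_leading_bases + 1` bases (default: start position <= 15, i.e. up
#' to 14 bases may precede the match). If the forward orientation has no
#' valid match, the reverse complement is checked; a transcript matching in
#' both orientations is reported as forward. When several valid matches
#' fall inside the allowed window the leftmost is used and the transcript
#' is flagged (`multiple_hits`).
#'
#' @param transcripts Tibble with `seq_id` and `sequence` columns
#'   (e.g. from [read_fasta()]).
#' @param sl An [sl_definition()].
#' @return The input with columns added: `orientation` (`"forward"`,
#'   `"reverse_complement"`, or `NA` when no hit), `conserved_start`
#'   (1-based match start on the oriented transcript), `trim_point`
#'   (first transcript base after the leader), `multiple_hits`, and
#'   `trimmed_sequence` (oriented sequence from `trim_point` on).
#' @examples
#' tx <- tibble::tibble(seq_id = "t1", sequence = paste0("CCGGCTTTTCTG", "ATGCCC"))
#' find_sl(tx)
#' @export
find_sl <- function(transcripts, sl = sl_definition()) {
  check_dna(transcripts$sequence, "transcript sequence")
  conserved <- sl$conserved_region
  k <- nchar(conserved)
  max_start <- sl$max_leading_bases + 1L

  fwd <- conserved_match_start(transcripts$sequence, conserved, max_start)
  rcseq <- revcomp(transcripts$sequence)
  rev <- conserved_match_start(rcseq, conserved, max_start)

  orientation <- dplyr::case_when(
    !is.na(fwd) ~ "forward",
    !is.na(rev) ~ "reverse_complement",
    TRUE ~ NA_character_
  )
  oriented <- ifelse(orientation %in% "reverse_complement", rcseq, transcripts$sequence)
  conserved_start <- ifelse(!is.na(fwd), fwd, rev)
  trim_point <- conserved_start + k

  window <- substr(oriented, 1L, max_start + k - 1L)
  multiple <- !is.na(conserved_start) &
    stringr::str_count(window, stringr::fixed(conserved)) > 1L

  trimmed <- ifelse(is.na(trim_point), NA_character_,
                    substr(oriented, trim_point, nchar(oriented)))
  mutate(transcripts,
         orientation = orientation,
         conserved_start = as.integer(conserved_start),
         trim_point = as.integer(trim_point),
         multiple_hits = multiple,
         trimmed_sequence = trimmed)
}

#' Trim the SL leader (and any preceding bases) from matched transcripts
#'
#' Keeps only transcripts with a valid SL hit and replaces their sequence
#' by the oriented remainder starting at `trim_point`, so the returned set
#' is correctly oriented and leader-free.
#'
#' @param sl_hits Output of [find_sl()].
#' @return Tibble with `seq_id` and `sequence` (trimmed), plus
#'   `orientation` and `trim_point` for provenance.
#' @export
trim_sl <- function(sl_hits) {
  out <- filter(sl_hits, !is.na(.data$orientation))
  tibble(
    seq_id = out$seq_id,
    sequence = out$trimmed_sequence,
    orientation = out$orientation,
    trim_point = out$trim_point
  )
}

#' Locate the SL conserved region within read sequences
#'
#' Reports, per read, the 0-based offset into the read of the first base
#' after the leftmost exact occurrence of the conserved region, or `NA`
#' when the read does not contain it. The offset is relative to the stored
#' (reference-orientation) sequence; no positional restriction applies.
#'
#' @param sequences Character vector of read sequences.
#' @param sl An [sl_definition()].
#' @return Integer vector of offsets (`NA` = motif absent).
#' @examples
#' locate_sl_in_reads(c("CCGGCTTTTCTGACGT", "ACGTACGT"))
#' @export
locate_sl_in_reads <- function(sequences, sl = sl_definition()) {
  hit <- unname(stringr::str_locate(sequences,
                                    stringr::fixed(sl$conserved_region))[, "start"])
  as.integer(hit - 1L + nchar(sl$conserved_region))
}

#' Strip a terminal poly-A tract from transcript sequences
#'
#' Minimal 3' poly-A trimmer: removes a trailing run of >= `min_run`
#' consecutive A bases. Provided as a convenience; it does not emulate
#' full vector/quality trimming.
#'
#' @param sequences Character vector.
#' @param min_run Minimum terminal run length to strip (default 8).
#' @return Character vector with terminal poly-A runs removed.
#' @export
strip_polya <- function(sequences, min_run = 8L) {
  pat <- sprintf("A{%d,}$", as.integer(min_run))
  stringr::str_remove(sequences, pat)
}
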