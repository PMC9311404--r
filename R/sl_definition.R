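#' Define the spliced-leader (SL) sequence and its matching rules
#'
#' The *Paulinella* SL is a 20-nt leader donated to pre-mRNAs by
#' trans-splicing. Because transcript 5' ends assemble poorly, detection
#' uses only the conserved 3' region of the leader (positions 9-20 of the
#' full sequence). Species differ in where a genomic copy of the full
#' leader may start: position 1 for *P. micropora* KR01 and *P. ovalis*,
#' position 2 for *P. chromatophora* (whose SL begins with C rather than T).
#'
#' @param species One of `"kr01"`, `"ovalis"`, `"chromatophora"`; sets
#'   `full_start_position` (1, 1, 2 respectively).
#' @param full_sequence Full SL sequence (20 nt by default).
#' @param conserved_region Conserved 3' region used for exact matching;
#'   must be a suffix of `full_sequence`.
#' @param max_leading_bases Maximum number of transcript bases allowed to
#'   precede the conserved region for a transcript match (default 14,
#'   i.e. the match must start within the first 15 bases).
#'
#' @return An object of class `sl_definition`: a list with elements
#'   `full_sequence`, `conserved_region`, `full_start_position`,
#'   `max_leading_bases`, `species`.
#' @examples
#' sl <- sl_definition()
#' sl$conserved_region
#' @export
sl_definition <- function(species = c("kr01", "ovalis", "chromatophora"),
                          full_sequence = "TGGATAATCCGGCTTTTCTG",
                          conserved_region = "CCGGCTTTTCTG",
                          max_leading_bases = 14L) {
  species <- match.arg(species)
  check_dna(full_sequence, "full_sequence")
  check_dna(conserved_region, "conserved_region")
  if (!endsWith(full_sequence, conserved_region)) {
    abort("conserved_region must be a suffix of full_sequence")
  }
  structure(
    list(
      full_sequence = full_sequence,
      conserved_region = conserved_region,
      full_start_position = if (species == "chromatophora") 2L else 1L,
      max_leading_bases = as.integer(max_leading_bases),
      species = species
    ),
    class = "sl_definition"
  )
}

#' @export
print.sl_definition <- function(x, ...) {
  cat("<sl_definition>\n")
  cat("  species:            ", x$species, "\n")
  cat("  full sequence:      ", x$full_sequence, "\n")
  cat("  conserved region:   ", x$conserved_region, "\n")
  cat("  full-hit start pos: ", x$full_start_position, "\n")
  cat("  max leading bases:  ", x$max_leading_bases, "\n")
  invisible(x)
}
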