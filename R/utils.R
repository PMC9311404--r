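# shared internal helpers

# reverse-complement a character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# coerce genome input (DNAStringSet, named character, or tibble from
# read_fasta) to a named character vector of scaffold sequences
as_genome_chr <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.data.frame(genome)) {
    return(setNames(genome$sequence, genome$seq_id))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome character vector must be named by scaffold")
    return(genome)
  }
  abort("genome must be a DNAStringSet, a named character vector, or a read_fasta() tibble")
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-DNA characters (only A,C,G,T,N allowed): %s",
                  what, x[which(bad)[1]]))
  }
  invisible(x)
}

# parse CIGAR strings (M,I,D,S ops) into a list of data.frames(op, len)
parse_cigar <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  purrr::map2(ops, lens, ~ data.frame(op = .x, len = .y))
}

# reference width consumed by an alignment (M and D ops)
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# leading / trailing soft-clip lengths (reference orientation)
cigar_clips <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead <- purrr::map2_int(ops, lens, function(o, l) {
    if (length(o) && o[1] == "S") as.integer(l[1]) else 0L
  })
  trail <- purrr::map2_int(ops, lens, function(o, l) {
    k <- length(o)
    if (k && o[k] == "S") as.integer(l[k]) else 0L
  })
  list(lead = lead, trail = trail)
}

# Map a 1-based offset into the stored read sequence to the reference
# position of the first aligned base at or after that offset.
# Returns NA if no aligned base exists at or after the offset.
ref_pos_at_or_after <- function(cigar, pos, query_offset) {
  cig <- parse_cigar(cigar)[[1]]
  q <- 0L   # query bases consumed
  r <- pos  # next reference position
  for (i in seq_len(nrow(cig))) {
    op <- cig$op[i]; len <- cig$len[i]
    if (op == "M") {
      if (query_offset <= q + len) {
        off <- max(query_offset - q, 1L)
        return(r + off - 1L)
      }
      q <- q + len; r <- r + len
    } else if (op == "I" || op == "S") {
      # offset inside a clip/insertion maps to the next aligned base,
      # handled by the max(..., 1) in the following M block
      q <- q + len
    } else if (op == "D") {
      r <- r + len
    }
  }
  NA_integer_
}

# interval membership helper: is position within any [start, end]?
pos_in_intervals <- function(pos, starts, ends) {
  any(pos >= starts & pos <= ends)
}
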