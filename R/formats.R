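# Readers/writers for external formats and the pipeline's tabular outputs.
# Coordinate conventions: FASTA/GFF3/SAM/tabular hits are 1-based inclusive;
# BED output is 0-based half-open. No science lives in this file.

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id` (header up to first whitespace)
#'   and `sequence`. An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(tibble(seq_id = character(), sequence = character()))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(sprintf("malformed FASTA record at line %d: expected '>' header", nonblank[1]))
  }
  set <- Biostrings::readBStringSet(path)
  tibble(
    seq_id = sub("\\s.*$", "", names(set)),
    sequence = unname(toupper(as.character(set)))
  )
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with `seq_id` and `sequence` columns, a named character
#'   vector, or an `XStringSet`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$seq_id)
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a genome assembly as a DNAStringSet
#'
#' @param path Path to a genome FASTA file.
#' @return A `DNAStringSet` named by scaffold (headers truncated at first
#'   whitespace).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read gene models from GFF3 and extract CDS sequences
#'
#' Expects gene/mRNA/exon/CDS rows linked by `ID`/`Parent` attributes, one
#' mRNA per gene. Exon and CDS rows are sorted by genomic start on load.
#' The CDS sequence is extracted from the genome in mRNA sense (minus-strand
#' genes are reverse-complemented), so all CDS-relative coordinates used
#' downstream are already strand-resolved.
#'
#' @param path Path to a GFF3 file.
#' @param genome A `DNAStringSet` (or `read_genome()` result), named
#'   character vector, or `read_fasta()` tibble.
#' @return A tibble with one row per gene: `gene_id`, `scaffold_id`,
#'   `strand`, `n_exons`, list-columns `exons` and `cds_intervals`
#'   (tibbles of 1-based inclusive `start`/`end`, sorted, non-overlapping),
#'   `cds_sequence`, `cds_length`, and `cds_piece_starts` (CDS coordinate at
#'   which each CDS piece begins, in mRNA sense -- cumulative piece lengths).
#' @export
read_gff3_genes <- function(path, genome) {
  gff <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gff)
  df$ID <- as.character(df$ID)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))

  # map feature -> gene through the mRNA level where present
  gene_ids <- df$ID[df$type == "gene"]
  mrna2gene <- setNames(df$Parent[df$type == "mRNA"], df$ID[df$type == "mRNA"])
  to_gene <- function(parent) {
    ifelse(parent %in% gene_ids, parent, unname(mrna2gene[parent]))
  }

  genome_chr <- as_genome_chr(genome)

  build_part <- function(type) {
    part <- df[df$type == type, , drop = FALSE]
    part$gene_id <- to_gene(part$Parent)
    part[order(part$gene_id, part$start), c("gene_id", "seqnames", "strand", "start", "end")]
  }
  exon_df <- build_part("exon")
  cds_df <- build_part("CDS")
  if (nrow(exon_df) == 0 && nrow(cds_df) > 0) exon_df <- cds_df
  if (nrow(cds_df) == 0 && nrow(exon_df) > 0) cds_df <- exon_df

  genes <- unique(cds_df$gene_id)
  rows <- purrr::map(genes, function(g) {
    ex <- exon_df[exon_df$gene_id == g, , drop = FALSE]
    cd <- cds_df[cds_df$gene_id == g, , drop = FALSE]
    scaf <- as.character(cd$seqnames[1])
    strand <- as.character(cd$strand[1])
    if (!scaf %in% names(genome_chr)) {
      abort(sprintf("gene %s: scaffold %s not in genome", g, scaf))
    }
    slen <- nchar(genome_chr[[scaf]])
    if (any(cd$start < 1) || any(cd$end > slen)) {
      abort(sprintf("gene %s: CDS outside scaffold bounds (%s length %d)", g, scaf, slen))
    }
    pieces <- substring(genome_chr[[scaf]], cd$start, cd$end)
    cds_seq <- paste(pieces, collapse = "")
    if (strand == "-") cds_seq <- revcomp(cds_seq)
    plens <- cd$end - cd$start + 1L
    if (strand == "-") plens <- rev(plens)
    tibble(
      gene_id = g, scaffold_id = scaf, strand = strand,
      n_exons = nrow(ex),
      exons = list(tibble(start = ex$start, end = ex$end)),
      cds_intervals = list(tibble(start = cd$start, end = cd$end)),
      cds_sequence = cds_seq,
      cds_length = sum(plens),
      cds_piece_starts = list(c(1L, cumsum(plens)[-length(plens)] + 1L))
    )
  })
  bind_rows(rows)
}

#' Genomic position of each CDS base of a gene
#'
#' Returns, in mRNA-sense order (CDS position 1 first), the genomic
#' coordinate of every CDS base. The mapping is a bijection between CDS
#' coordinates and the genomic CDS bases.
#'
#' @param genes A `read_gff3_genes()` tibble.
#' @param gene_id Gene identifier.
#' @return Integer vector of genomic positions, length `cds_length`.
#' @export
cds_genomic_positions <- function(genes, gene_id) {
  row <- genes[genes$gene_id == gene_id, ]
  if (nrow(row) != 1) abort(paste0("unknown gene_id: ", gene_id))
  iv <- row$cds_intervals[[1]]
  pos <- unlist(Map(seq.int, iv$start, iv$end))
  if (row$strand == "-") pos <- rev(pos)
  as.integer(pos)
}

#' Read aligned reads from a SAM file
#'
#' The SAM file must have `@SQ` header lines and NM tags on mapped reads
#' (reads enter as SAM; BAM/CRAM are not supported). Unmapped records are
#' dropped. `properly_paired` reflects SAM flag bit 0x2, `reverse` bit
#' 0x10, `first_in_pair` bit 0x40. Sequences are as stored (reference
#' orientation). A mapped read lacking an NM tag gets `edit_distance = NA`
#' with a warning (such reads fail the pair filter) or an error, per
#' `missing_nm`.
#'
#' @param path Path to a SAM file.
#' @param missing_nm `"warn"` (default) or `"error"`.
#' @return A tibble with columns `read_id`, `target_id`, `flag`, `start`,
#'   `cigar`, `sequence`, `properly_paired`, `reverse`, `first_in_pair`,
#'   `edit_distance`.
#' @export
read_sam <- function(path, missing_nm = c("warn", "error")) {
  missing_nm <- match.arg(missing_nm)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM"
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  nm <- res$tag$NM %||% rep(NA_integer_, length(res$qname))
  out <- tibble(
    read_id = res$qname,
    target_id = as.character(res$rname),
    flag = as.integer(res$flag),
    start = as.integer(res$pos),
    cigar = res$cigar,
    sequence = as.character(res$seq),
    edit_distance = as.integer(nm)
  )
  out <- out[bitwAnd(out$flag, 4L) == 0L, , drop = FALSE]  # drop unmapped
  out$properly_paired <- bitwAnd(out$flag, 2L) > 0L
  out$reverse <- bitwAnd(out$flag, 16L) > 0L
  out$first_in_pair <- bitwAnd(out$flag, 64L) > 0L
  if (anyNA(out$edit_distance)) {
    msg <- sprintf("%d mapped read(s) lack an NM tag; they will fail pair filtering",
                   sum(is.na(out$edit_distance)))
    if (missing_nm == "error") abort(msg) else warn(msg)
  }
  select(out, "read_id", "target_id", "flag", "start", "cigar", "sequence",
         "properly_paired", "reverse", "first_in_pair", "edit_distance")
}

#' Write aligned reads to a SAM file
#'
#' Inverse of [read_sam()] for the columns that reader exposes; mate
#' coordinates are not tracked (RNEXT `*`). Target lengths are taken from
#' `target_lengths` (named vector) for the `@SQ` header.
#'
#' @param reads A reads tibble (as from [read_sam()]).
#' @param target_lengths Named integer vector of reference lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, target_lengths, path) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths), as.integer(target_lengths))
  )
  nm <- ifelse(is.na(reads$edit_distance), character(nrow(reads)),
               sprintf("\tNM:i:%d", reads$edit_distance))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*%s",
                  reads$read_id, reads$flag, reads$target_id, reads$start,
                  reads$cigar, reads$sequence, nm)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read BLAST outfmt-6 tabular hits
#'
#' Fixed 12-column order: query id, subject id, percent identity, alignment
#' length, mismatches, gap opens, q.start, q.end, s.start, s.end, evalue,
#' bit score. Subject strand is derived from the s.start/s.end order
#' (minus when s.start > s.end).
#'
#' @param path Path to a tab-separated hit table (no header).
#' @return A tibble with columns `query_id`, `subject_id`, `identity_pct`,
#'   `aln_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `bit_score`, `strand`.
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cols <- c("query_id", "subject_id", "identity_pct", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bit_score")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as_tibble(setNames(rep(list(numeric()), 12), cols))
    out$query_id <- character(); out$subject_id <- character()
    out$strand <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    abort(sprintf("row %d has %d columns; expected 12 (BLAST outfmt 6)",
                  which(nf != 12)[1], nf[nf != 12][1]))
  }
  m <- do.call(rbind, fields)
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    identity_pct = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12])
  )
  out$strand <- ifelse(out$s_start <= out$s_end, "+", "-")
  out
}

#' Write hits in BLAST outfmt-6 order
#' @param hits A tibble as returned by [read_blast_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  body <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%.1f",
                  hits$query_id, hits$subject_id, hits$identity_pct,
                  hits$aln_length, hits$mismatches, hits$gap_opens,
                  hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                  hits$evalue, hits$bit_score)
  writeLines(body, path)
  invisible(path)
}

#' Read protein feature annotations
#'
#' Tab-separated with header `gene_id, kind, aa_start, aa_end, label`;
#' coordinates are 1-based inclusive amino-acid positions. `kind` must be
#' one of `domain`, `transmembrane`, `coil`, `targeting_signal`.
#'
#' @param path Path to the feature table.
#' @return A tibble with those columns.
#' @export
read_feature_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), kind = readr::col_character(),
    aa_start = readr::col_integer(), aa_end = readr::col_integer(),
    label = readr::col_character()
  ))
  kinds <- c("domain", "transmembrane", "coil", "targeting_signal")
  bad <- setdiff(unique(out$kind), kinds)
  if (length(bad)) abort(paste0("unknown feature kind(s): ", paste(bad, collapse = ", ")))
  if (any(out$aa_start < 1 | out$aa_start > out$aa_end)) {
    abort("feature coordinates must satisfy 1 <= aa_start <= aa_end")
  }
  as_tibble(out)
}

#' Read per-gene expected counts
#'
#' Tab-separated with header `gene_id, replicate_id, expected_count` (long
#' format, one row per gene and replicate).
#'
#' @param path Path to the counts table.
#' @return A tibble with those columns.
#' @export
read_expected_counts <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    replicate_id = readr::col_character(),
    expected_count = readr::col_double()
  ))
  if (any(out$expected_count < 0)) abort("expected_count must be non-negative")
  as_tibble(out)
}

#' Read validated transcript-to-genome alignments
#'
#' Tab-separated with header `transcript_id, scaffold_id, strand, blocks,
#' avg_identity_pct, percent_aligned`; `blocks` is a `;`-separated list of
#' `start-end` genomic intervals (1-based inclusive, ascending).
#'
#' @param path Path to the alignment table.
#' @return A tibble with a `blocks` list-column of `start`/`end` tibbles.
#' @export
read_transcript_alignments <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    scaffold_id = readr::col_character(),
    strand = readr::col_character(),
    blocks = readr::col_character(),
    avg_identity_pct = readr::col_double(),
    percent_aligned = readr::col_double()
  ))
  out$blocks <- purrr::map(out$blocks, function(b) {
    parts <- strsplit(strsplit(b, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    tibble(
      start = as.integer(vapply(parts, `[`, "", 1)),
      end = as.integer(vapply(parts, `[`, "", 2))
    )
  })
  as_tibble(out)
}

#' Write transcript-to-genome alignments
#' @param alignments Tibble as from [read_transcript_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_alignments <- function(alignments, path) {
  blocks <- vapply(alignments$blocks, function(b) {
    paste(sprintf("%d-%d", b$start, b$end), collapse = ";")
  }, character(1))
  out <- tibble(
    transcript_id = alignments$transcript_id,
    scaffold_id = alignments$scaffold_id,
    strand = alignments$strand,
    blocks = blocks,
    avg_identity_pct = alignments$avg_identity_pct,
    percent_aligned = alignments$percent_aligned
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' Converts 1-based inclusive `start`/`end` columns to BED's 0-based
#' half-open convention.
#'
#' @param x Tibble with columns `chrom`, `start`, `end`, and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  body <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                  x$chrom, as.integer(x$start) - 1L, as.integer(x$end),
                  x$name %||% ".",
                  as.character(x$score %||% 0),
                  x$strand %||% ".")
  writeLines(body, path)
  invisible(path)
}
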