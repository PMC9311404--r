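# Shared fixtures: simulations are cached per seed (several test files and
# the acceptance suite reuse them), and small builders construct gene
# models and aligned reads directly in code.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed) {
  key <- paste0("seed", seed)
  if (!exists(key, envir = .sim_cache)) {
    assign(key, simulate_slts(slts_sim_config(seed = seed)), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

cached_recovery <- function(seed) {
  key <- paste0("rec", seed)
  if (!exists(key, envir = .sim_cache)) {
    assign(key, recovery_report(cached_sim(seed)), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# A gene-model row in read_gff3_genes() layout, built from a CDS sequence
# and CDS piece lengths; exons are laid out on a dummy scaffold with
# 100-bp introns starting at genomic position 1001.
make_gene <- function(gene_id, cds, piece_lens = NULL, strand = "+",
                      scaffold = "chrT") {
  L <- nchar(cds)
  if (is.null(piece_lens)) piece_lens <- L
  stopifnot(sum(piece_lens) == L)
  starts <- integer(length(piece_lens))
  pos <- 1001L
  ex <- list()
  for (i in seq_along(piece_lens)) {
    ex[[i]] <- c(start = pos, end = pos + piece_lens[i] - 1L)
    pos <- pos + piece_lens[i] + 100L
  }
  ex <- tibble::as_tibble(do.call(rbind, ex))
  piece_starts <- c(1L, cumsum(piece_lens)[-length(piece_lens)] + 1L)
  if (strand == "-") piece_starts <- piece_starts  # CDS-space starts unchanged
  tibble::tibble(
    gene_id = gene_id, scaffold_id = scaffold, strand = strand,
    n_exons = length(piece_lens), exons = list(ex), cds_intervals = list(ex),
    cds_sequence = cds, cds_length = L,
    cds_piece_starts = list(as.integer(piece_starts))
  )
}

rand_cds <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# an aligned read row in read_sam() layout; default sequence is a run of
# A (contains no SL motif), sized to the CIGAR's query length
make_read <- function(read_id, target_id, start, cigar, sequence = NULL,
                      flag = 163L, edit_distance = 0L) {
  qlen <- sum(GenomicAlignments::explodeCigarOpLengths(
    cigar, ops = c("M", "I", "S"))[[1]])
  if (is.null(sequence)) sequence <- strrep("A", qlen)
  stopifnot(nchar(sequence) == qlen)
  tibble::tibble(
    read_id = read_id, target_id = target_id, flag = as.integer(flag),
    start = as.integer(start), cigar = cigar, sequence = sequence,
    properly_paired = bitwAnd(as.integer(flag), 2L) > 0L,
    reverse = bitwAnd(as.integer(flag), 16L) > 0L,
    first_in_pair = bitwAnd(as.integer(flag), 64L) > 0L,
    edit_distance = as.integer(edit_distance)
  )
}

# a proper pair: forward mate (flag 163) + reverse mate (flag 83)
make_pair <- function(read_id, target_id, fwd_start, rev_start,
                      fwd_cigar = "150M", rev_cigar = "150M",
                      fwd_seq = NULL, rev_seq = NULL,
                      fwd_nm = 0L, rev_nm = 0L,
                      proper = TRUE) {
  f1 <- if (proper) 163L else 161L
  f2 <- if (proper) 83L else 81L
  dplyr::bind_rows(
    make_read(read_id, target_id, fwd_start, fwd_cigar, fwd_seq, f1, fwd_nm),
    make_read(read_id, target_id, rev_start, rev_cigar, rev_seq, f2, rev_nm)
  )
}

# n identical motif-bearing pairs evidencing a site at CDS position p
sl_support_pairs <- function(n, target_id, p, gene_cds, prefix = "slp",
                             read_len = 150L, sl = sl_definition()) {
  cons <- sl$conserved_region
  k <- nchar(cons)
  mlen <- read_len - k
  fwd_seq <- paste0(cons, substr(gene_cds, p, p + mlen - 1L))
  rev_start <- p + 100L
  rev_seq <- substr(gene_cds, rev_start, rev_start + read_len - 1L)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_pair(sprintf("%s_%03d", prefix, i), target_id,
              fwd_start = p, rev_start = rev_start,
              fwd_cigar = sprintf("%dS%dM", k, mlen),
              fwd_seq = fwd_seq, rev_seq = rev_seq)
  }))
}

# n plain covering pairs starting at s (background depth)
bg_pairs <- function(n, target_id, s, gene_cds, prefix = "bgp",
                     read_len = 150L, frag = 250L) {
  rev_start <- s + frag - read_len
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_pair(sprintf("%s_%03d", prefix, i), target_id,
              fwd_start = s, rev_start = rev_start,
              fwd_seq = substr(gene_cds, s, s + read_len - 1L),
              rev_seq = substr(gene_cds, rev_start, rev_start + read_len - 1L))
  }))
}
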