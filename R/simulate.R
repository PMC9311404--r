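# Synthetic SLTS dataset generator with a machine-readable truth manifest.
# Emulates: multi-exon gene models on a small genome; stranded paired-end
# reads over CDSs with the conserved SL region prepended at planted
# addition sites (5'-terminal, exon-junction, and internal-AG sites) at
# controlled support fractions; artificially 5'-extended gene models
# lacking read support; SL RNA loci and decayed (partial) copies; recycled
# intron-less paralogs with an upstream SL; and a planted expression-group
# difference. Reads are simulated directly as CDS alignments (SAM), so no
# aligner is needed to exercise the pipeline.

#' Configuration for the synthetic SLTS dataset
#'
#' Defaults give 60 genes on a ~0.3 Mb two-scaffold genome at read depth
#' 50, enough for every pipeline stage to run in seconds.
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_genes Number of ordinary gene models (recycled paralogs are
#'   extra).
#' @param exons_per_gene Inclusive range of exon counts.
#' @param cds_length Inclusive range of CDS lengths (rounded to codons).
#' @param read_length Read length in bp.
#' @param fragment_length Insert size (fixed; background pairs tile each
#'   CDS at evenly spaced starts so coverage is uniform).
#' @param depth Target mean read depth per CDS.
#' @param error_rate Per-aligned-base substitution rate (NM reflects the
#'   planted errors exactly).
#' @param sl_gene_fraction Fraction of genes given at least one SL
#'   addition site.
#' @param site_mix Proportions of non-construct SL sites that are
#'   5'-terminal (`position_1`), at an exon junction (`junction`), or
#'   internal immediately after a planted AG acceptor mimic (`internal`);
#'   must sum to 1.
#' @param support_range Range of planted support fractions at a site.
#' @param n_mispredicted Genes given an artificial 5' CDS extension with
#'   zero read coverage.
#' @param n_recycled Recycled intron-less paralogs with a full SL copy
#'   planted upstream.
#' @param n_sl_loci Full SL RNA loci planted in intergenic sequence.
#' @param n_partial_loci Decayed, 3'-anchored partial SL copies planted in
#'   intergenic sequence.
#' @param n_replicates Expression replicates per gene.
#' @param expr_mean_sl,expr_mean_other Mean expression (TPM scale) of
#'   genes with / without SL sites.
#' @param expr_cv Between-gene coefficient of variation of expression.
#' @param intron_length,intergenic Inclusive ranges for intron and
#'   intergenic spacer lengths.
#' @return A list of class `slts_sim_config`.
#' @export
slts_sim_config <- function(seed = 1L, n_genes = 60L,
                            exons_per_gene = c(1L, 5L),
                            cds_length = c(600L, 1500L),
                            read_length = 150L, fragment_length = 250L,
                            depth = 50L, error_rate = 0,
                            sl_gene_fraction = 0.35,
                            site_mix = c(position_1 = 0.5, junction = 0.25,
                                         internal = 0.25),
                            support_range = c(0.3, 0.8),
                            n_mispredicted = 2L, n_recycled = 2L,
                            n_sl_loci = 3L, n_partial_loci = 3L,
                            n_replicates = 3L,
                            expr_mean_sl = 62.95, expr_mean_other = 22.72,
                            expr_cv = 0.25,
                            intron_length = c(60L, 200L),
                            intergenic = c(1500L, 4000L)) {
  stopifnot(n_genes > 10, depth > 0, read_length > 20,
            fragment_length >= read_length, error_rate >= 0, error_rate < 1,
            sl_gene_fraction > 0, sl_gene_fraction <= 1,
            abs(sum(site_mix) - 1) < 1e-9, all(site_mix >= 0),
            support_range[1] > 0, support_range[2] <= 1,
            n_mispredicted >= 0, n_recycled >= 0, n_replicates >= 2)
  structure(as.list(environment()), class = "slts_sim_config")
}

# partition total into k parts each >= m (random composition)
random_partition <- function(total, k, m) {
  extra <- total - k * m
  if (extra < 0) abort("infeasible partition")
  if (k == 1) return(total)
  cuts <- sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
  m + diff(c(0L, cuts, extra))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# replace every in-frame ATG codon at or after `from` (codon-aligned) by ATC
scrub_inframe_atg <- function(cds, from = 4L) {
  L <- nchar(cds)
  p <- from + ((1L - from) %% 3L)
  chars <- strsplit(cds, "")[[1]]
  while (p + 2L <= L) {
    if (chars[p] == "A" && chars[p + 1L] == "T" && chars[p + 2L] == "G") {
      chars[p + 2L] <- "C"
    }
    p <- p + 3L
  }
  paste(chars, collapse = "")
}

set_bases <- function(seq, at, bases) {
  chars <- strsplit(seq, "")[[1]]
  chars[at] <- bases
  paste(chars, collapse = "")
}

# a base different from each of the given bases (deterministic choice)
mismatch_base <- function(base) {
  c(A = "C", C = "A", G = "T", T = "G", N = "A")[[base]]
}

#' Generate a synthetic SLTS dataset with planted ground truth
#'
#' See [slts_sim_config()] for the knobs. Output is deterministic given
#' the config seed. Five construct genes carry truncation events with
#' known consequence categories: a targeting-signal removal (A), a domain
#' removal (B), a start-codon-free tail (C), a dual-site gene (D), and a
#' plain featureless event; construct CDSs have their in-frame ATGs
#' controlled so the retained start is known exactly.
#'
#' @param config An [slts_sim_config()].
#' @param outdir Optional directory; when given, writes `genome.fa`,
#'   `genes.gff3`, `cds.fa`, `transcripts.fa`, `reads.sam`,
#'   `alignments.tsv`, `hits.tsv`, `features.tsv`, `counts.tsv`, and
#'   `truth.json`.
#' @return A list of class `slts_sim`: `genome` (named character),
#'   `genes`, `reads`, `transcripts`, `alignments`, `hits`, `features`,
#'   `counts` tibbles, `truth` (list of tibbles), `sl` and `config`.
#' @export
simulate_slts <- function(config = slts_sim_config(), outdir = NULL) {
  set.seed(config$seed)
  sl <- sl_definition()
  conserved <- sl$conserved_region
  k_cons <- nchar(conserved)
  R <- config$read_length
  FRAG <- config$fragment_length

  n <- config$n_genes
  gene_ids <- sprintf("g%03d", seq_len(n))

  ## ---- role assignment -------------------------------------------------
  n_sl <- max(8L, round(n * config$sl_gene_fraction))
  construct_labels <- c("A", "B", "C", "D", "E")
  perm <- sample(gene_ids)
  construct_genes <- setNames(perm[1:5], construct_labels)
  rest_sl_pool <- perm[6:n_sl]
  n_rest <- length(rest_sl_pool)
  n_pos1 <- round(config$site_mix[["position_1"]] * n_rest)
  n_junc <- round(config$site_mix[["junction"]] * n_rest)
  n_int <- n_rest - n_pos1 - n_junc
  pos1_genes <- rest_sl_pool[seq_len(n_pos1)]
  junc_genes <- rest_sl_pool[n_pos1 + seq_len(n_junc)]
  int_genes <- rest_sl_pool[n_pos1 + n_junc + seq_len(n_int)]
  non_sl <- perm[(n_sl + 1):n]
  mispred_genes <- non_sl[seq_len(config$n_mispredicted)]
  decoy_genes <- non_sl[config$n_mispredicted + 1:2]
  recycle_pool <- setdiff(non_sl, c(mispred_genes, decoy_genes))

  ## ---- gene structures and CDS sequences -------------------------------
  plan <- tibble(gene_id = gene_ids) |>
    mutate(
      strand = sample(c("+", "-"), n, replace = TRUE),
      n_exons = sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                       n, replace = TRUE),
      cds_len = {
        L <- sample(seq(config$cds_length[1], config$cds_length[2]), n, replace = TRUE)
        as.integer(L - L %% 3L)
      }
    )
  # constraints: junction-site genes need >= 2 exons and a roomy first
  # exon; construct genes get a fixed generous length
  plan$n_exons[plan$gene_id %in% junc_genes] <-
    pmax(plan$n_exons[plan$gene_id %in% junc_genes], 2L)
  # internal sites need room for the site window and the downstream mate
  plan$cds_len[plan$gene_id %in% int_genes] <-
    pmax(plan$cds_len[plan$gene_id %in% int_genes], 900L)
  plan$n_exons[plan$gene_id == decoy_genes[2]] <-
    pmax(plan$n_exons[plan$gene_id == decoy_genes[2]], 2L)
  plan$cds_len[plan$gene_id %in% decoy_genes] <-
    pmax(plan$cds_len[plan$gene_id %in% decoy_genes], 900L)
  plan$cds_len[plan$gene_id %in% construct_genes] <- 1200L
  plan$n_exons[plan$gene_id %in% construct_genes[c("A", "B", "C", "D")]] <-
    pmax(plan$n_exons[plan$gene_id %in% construct_genes[c("A", "B", "C", "D")]], 2L)
  plan$n_exons[plan$gene_id == construct_genes[["E"]]] <- 1L

  min_exon <- 60L
  piece_lengths <- vector("list", n)
  for (i in seq_len(n)) {
    L <- plan$cds_len[i]; ne <- plan$n_exons[i]
    if (plan$gene_id[i] %in% c(junc_genes, construct_genes[c("A", "B", "C", "D")])) {
      f1 <- sample(160:220, 1)
      piece_lengths[[i]] <- c(f1, random_partition(L - f1, ne - 1L, min_exon))
    } else {
      piece_lengths[[i]] <- random_partition(L, ne, min_exon)
    }
  }

  cds_seq <- vapply(plan$cds_len, function(L) {
    paste0("ATG", rand_dna(L - 3L))
  }, character(1))
  names(cds_seq) <- plan$gene_id

  ## ---- planted sites ---------------------------------------------------
  piece_starts <- lapply(piece_lengths, function(pl) {
    c(1L, cumsum(pl)[-length(pl)] + 1L)
  })
  names(piece_starts) <- plan$gene_id
  len_of <- setNames(plan$cds_len, plan$gene_id)

  pick_internal <- function(g, lo = 150L, hi = NULL, avoid = integer()) {
    L <- len_of[[g]]
    hi <- hi %||% (L - 2L * FRAG)
    st <- piece_starts[[g]]
    repeat {
      p <- sample(lo:hi, 1)
      if (all(abs(p - st) > 6L) && all(abs(p - avoid) > 260L)) return(p)
    }
  }

  sites <- list()
  add_site <- function(g, p, ctx, f) {
    sites[[length(sites) + 1]] <<- tibble(gene_id = g, position = as.integer(p),
                                          context_class = ctx, planted_support = f)
  }
  rsupp <- function() stats::runif(1, config$support_range[1], config$support_range[2])

  for (g in pos1_genes) add_site(g, 1L, "position_1", rsupp())
  for (g in junc_genes) add_site(g, piece_starts[[g]][2], "precise_junction", rsupp())
  for (g in int_genes) add_site(g, pick_internal(g), "internal", rsupp())
  # constructs: internal sites with controlled support (Type planted)
  pA <- pick_internal(construct_genes[["A"]], hi = 400L)
  pB <- pick_internal(construct_genes[["B"]], hi = 400L)
  pC <- pick_internal(construct_genes[["C"]], hi = 400L)
  pE <- pick_internal(construct_genes[["E"]], hi = 400L)
  pD1 <- pick_internal(construct_genes[["D"]], hi = 300L)
  pD2 <- pick_internal(construct_genes[["D"]], lo = pD1 + 261L, hi = 700L, avoid = pD1)
  add_site(construct_genes[["A"]], pA, "internal", 0.6)   # Type 1
  add_site(construct_genes[["B"]], pB, "internal", 0.35)  # Type 2
  add_site(construct_genes[["C"]], pC, "internal", 0.6)   # Type 1
  add_site(construct_genes[["D"]], pD1, "internal", 0.5)
  add_site(construct_genes[["D"]], pD2, "internal", 0.6)  # event site, Type 1
  add_site(construct_genes[["E"]], pE, "internal", 0.35)  # Type 2
  sites <- bind_rows(sites)

  ## ---- construct CDS edits (controlled ATGs, features) -----------------
  inframe_at_or_after <- function(p) p + ((1L - p) %% 3L)
  retained <- c(A = inframe_at_or_after(max(92L, pA)),
                B = inframe_at_or_after(pB),
                D = inframe_at_or_after(pD2),
                E = inframe_at_or_after(pE))
  for (lbl in c("A", "B", "D", "E")) {
    g <- construct_genes[[lbl]]
    cds_seq[[g]] <- scrub_inframe_atg(cds_seq[[g]])
    q <- retained[[lbl]]
    cds_seq[[g]] <- set_bases(cds_seq[[g]], q:(q + 2L), c("A", "T", "G"))
  }
  gC <- construct_genes[["C"]]
  cds_seq[[gC]] <- scrub_inframe_atg(cds_seq[[gC]], from = pC)

  # internal sites sit immediately after an AG (acceptor mimic)
  for (i in which(sites$context_class == "internal")) {
    g <- sites$gene_id[i]; p <- sites$position[i]
    cds_seq[[g]] <- set_bases(cds_seq[[g]], c(p - 2L, p - 1L), c("A", "G"))
  }

  features <- bind_rows(
    tibble(gene_id = construct_genes[["A"]], kind = "targeting_signal",
           aa_start = 1L, aa_end = 30L, label = "synthetic_signal"),
    tibble(gene_id = construct_genes[["B"]], kind = "domain",
           aa_start = 10L, aa_end = 60L, label = "synthetic_domain")
  )

  ## ---- misprediction offsets -------------------------------------------
  mispred <- tibble(gene_id = mispred_genes,
                    true_cds_start_offset = sample(100:140, length(mispred_genes),
                                                   replace = TRUE))
  offset_of <- setNames(rep(0L, n), plan$gene_id)
  offset_of[mispred$gene_id] <- as.integer(mispred$true_cds_start_offset)

  ## ---- genome assembly --------------------------------------------------
  scaffolds <- list(scaf1 = character(), scaf2 = character())
  scaff_len <- c(scaf1 = 0L, scaf2 = 0L)
  gene_rows <- list()

  spacer <- function() rand_dna(sample(config$intergenic[1]:config$intergenic[2], 1))

  append_seq <- function(scaf, s) {
    scaffolds[[scaf]][[length(scaffolds[[scaf]]) + 1]] <<- s
    start <- scaff_len[[scaf]] + 1L
    scaff_len[[scaf]] <<- scaff_len[[scaf]] + nchar(s)
    start
  }

  for (i in seq_len(n)) {
    g <- plan$gene_id[i]
    scaf <- if (i %% 2L == 0L) "scaf2" else "scaf1"
    append_seq(scaf, spacer())
    pl <- piece_lengths[[i]]
    st <- piece_starts[[g]]
    exon_seqs <- substring(cds_seq[[g]], st, st + pl - 1L)
    n_in <- length(pl) - 1L
    intron_seqs <- if (n_in > 0) {
      vapply(seq_len(n_in), function(j) {
        paste0("GT", rand_dna(sample(config$intron_length[1]:config$intron_length[2], 1) - 4L), "AG")
      }, character(1))
    } else character()
    body_parts <- character(2L * length(pl) - 1L)
    body_parts[seq(1, length(body_parts), by = 2)] <- exon_seqs
    if (n_in > 0) body_parts[seq(2, length(body_parts), by = 2)] <- intron_seqs
    body <- paste(body_parts, collapse = "")
    # exon positions within the sense body
    part_len <- nchar(body_parts)
    part_end <- cumsum(part_len)
    part_start <- part_end - part_len + 1L
    ex_idx <- seq(1, length(body_parts), by = 2)
    if (plan$strand[i] == "+") {
      off <- append_seq(scaf, body) - 1L
      ex <- tibble(start = off + part_start[ex_idx], end = off + part_end[ex_idx])
    } else {
      off <- append_seq(scaf, revcomp(body)) - 1L
      blen <- nchar(body)
      ex <- tibble(start = off + blen - part_end[ex_idx] + 1L,
                   end = off + blen - part_start[ex_idx] + 1L) |>
        arrange(start)
    }
    gene_rows[[g]] <- tibble(
      gene_id = g, scaffold_id = scaf, strand = plan$strand[i],
      n_exons = plan$n_exons[i], exons = list(ex), cds_intervals = list(ex),
      cds_sequence = cds_seq[[g]], cds_length = plan$cds_len[i],
      cds_piece_starts = list(as.integer(st))
    )
  }

  ## ---- SL RNA loci and decayed partial copies --------------------------
  sl_full <- sl$full_sequence
  qlen <- nchar(sl_full)
  sl_loci <- list()
  plant_locus <- function(kind, frag_len) {
    scaf <- sample(names(scaffolds), 1)
    strand <- sample(c("+", "-"), 1)
    frag <- substr(sl_full, qlen - frag_len + 1L, qlen)
    q_start <- qlen - frag_len + 1L
    # two mismatching bases immediately 5' of the fragment (in SL sense) so
    # the maximal match starts exactly at the planted query position
    guard <- if (q_start > 1L) {
      paste0(mismatch_base(substr(sl_full, q_start - 2L, q_start - 2L)),
             mismatch_base(substr(sl_full, q_start - 1L, q_start - 1L)))
    } else ""
    sense <- paste0(guard, frag)
    ins <- if (strand == "+") sense else revcomp(sense)
    append_seq(scaf, spacer())
    s0 <- append_seq(scaf, ins)
    g_len <- nchar(ins)
    if (strand == "+") {
      hs <- s0 + nchar(guard); he <- s0 + g_len - 1L
    } else {
      hs <- s0; he <- s0 + frag_len - 1L
    }
    sl_loci[[length(sl_loci) + 1]] <<- tibble(
      scaffold_id = scaf, start = as.integer(hs), end = as.integer(he),
      strand = strand, kind = kind, q_start = as.integer(q_start))
  }
  for (j in seq_len(config$n_sl_loci)) plant_locus("full", qlen)
  for (j in seq_len(config$n_partial_loci)) plant_locus("partial", sample(8:15, 1))
  sl_loci <- bind_rows(sl_loci)

  ## ---- recycled intron-less paralogs with upstream SL ------------------
  recycled <- list()
  if (config$n_recycled > 0) {
    sources <- sample(recycle_pool, config$n_recycled)
    for (j in seq_len(config$n_recycled)) {
      src <- sources[j]
      rid <- sprintf("r%03d", j)
      scaf <- sample(names(scaffolds), 1)
      strand <- sample(c("+", "-"), 1)
      gap <- sample(20:80, 1)
      sense <- paste0(sl_full, rand_dna(gap), cds_seq[[src]])
      ins <- if (strand == "+") sense else revcomp(sense)
      append_seq(scaf, spacer())
      s0 <- append_seq(scaf, ins)
      total <- nchar(ins)
      if (strand == "+") {
        gstart <- s0 + qlen + gap; gend <- s0 + total - 1L
      } else {
        gstart <- s0; gend <- s0 + nchar(cds_seq[[src]]) - 1L
      }
      ex <- tibble(start = as.integer(gstart), end = as.integer(gend))
      gene_rows[[rid]] <- tibble(
        gene_id = rid, scaffold_id = scaf, strand = strand, n_exons = 1L,
        exons = list(ex), cds_intervals = list(ex),
        cds_sequence = cds_seq[[src]],
        cds_length = nchar(cds_seq[[src]]),
        cds_piece_starts = list(1L))
      recycled[[j]] <- tibble(source_gene = src, gene_id = rid,
                              scaffold_id = scaf, strand = strand,
                              sl_upstream_distance = as.integer(gap))
    }
  }
  recycled <- if (length(recycled)) bind_rows(recycled) else
    tibble(source_gene = character(), gene_id = character(),
           scaffold_id = character(), strand = character(),
           sl_upstream_distance = integer())

  for (scaf in names(scaffolds)) append_seq(scaf, spacer())
  genome <- vapply(scaffolds, paste, character(1), collapse = "")
  genes <- bind_rows(gene_rows)

  ## ---- reads ------------------------------------------------------------
  mutate_seq <- function(seq) {
    if (config$error_rate == 0) return(list(seq = seq, nm = 0L))
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < config$error_rate)
    for (h in hit) chars[h] <- mismatch_base(chars[h])
    list(seq = paste(chars, collapse = ""), nm = length(hit))
  }

  read_rows <- vector("list", 2 * n)
  truth_sites <- sites
  truth_sites$supporting_reads <- NA_integer_
  truth_sites$support_fraction <- NA_real_

  for (i in seq_len(n)) {
    g <- plan$gene_id[i]
    L <- plan$cds_len[i]
    e0 <- offset_of[[g]]
    span <- L - e0
    n_frags <- ceiling(config$depth * span / (2 * R))
    starts <- as.integer(round(seq(e0 + 1L, L - FRAG + 1L, length.out = n_frags)))
    cds <- cds_seq[[g]]

    left_seq <- substring(cds, starts, starts + R - 1L)
    right_start <- starts + FRAG - R
    right_seq <- substring(cds, right_start, right_start + R - 1L)
    nm_l <- integer(n_frags); nm_r <- integer(n_frags)
    if (config$error_rate > 0) {
      for (jj in seq_len(n_frags)) {
        ml <- mutate_seq(left_seq[jj]); mr <- mutate_seq(right_seq[jj])
        left_seq[jj] <- ml$seq; nm_l[jj] <- ml$nm
        right_seq[jj] <- mr$seq; nm_r[jj] <- mr$nm
      }
    }
    fid <- sprintf("%s_f%04d", g, seq_len(n_frags))
    bg <- tibble(
      read_id = rep(fid, 2),
      target_id = g,
      flag = c(rep(163L, n_frags), rep(83L, n_frags)),
      start = c(starts, right_start),
      cigar = sprintf("%dM", R),
      sequence = c(left_seq, right_seq),
      edit_distance = c(nm_l, nm_r)
    )
    read_rows[[2L * i - 1L]] <- bg

    gsites <- which(truth_sites$gene_id == g)
    if (length(gsites)) {
      bg_spans <- IRanges::IRanges(bg$start, width = R)
      sl_list <- list()
      for (si in gsites) {
        p <- truth_sites$position[si]
        f <- truth_sites$planted_support[si]
        bg_depth <- IRanges::countOverlaps(IRanges::IRanges(p, p), bg_spans)
        n_slr <- max(as.integer(round(f / (1 - f) * bg_depth)), 12L)
        mlen <- R - k_cons
        sseq <- paste0(conserved, substr(cds, p, p + mlen - 1L))
        m_start <- p + FRAG - R
        mseq <- substr(cds, m_start, m_start + R - 1L)
        nm_s <- integer(n_slr); nm_m <- integer(n_slr)
        sseqs <- rep(sseq, n_slr); mseqs <- rep(mseq, n_slr)
        if (config$error_rate > 0) {
          for (jj in seq_len(n_slr)) {
            # errors only on aligned bases; the clipped leader is untouched
            al <- mutate_seq(substr(sseqs[jj], k_cons + 1L, R))
            sseqs[jj] <- paste0(substr(sseqs[jj], 1L, k_cons), al$seq)
            nm_s[jj] <- al$nm
            mm <- mutate_seq(mseqs[jj]); mseqs[jj] <- mm$seq; nm_m[jj] <- mm$nm
          }
        }
        sid <- sprintf("%s_s%d_%03d", g, p, seq_len(n_slr))
        sl_list[[length(sl_list) + 1]] <- tibble(
          read_id = rep(sid, 2),
          target_id = g,
          flag = c(rep(163L, n_slr), rep(83L, n_slr)),
          start = c(rep(p, n_slr), rep(m_start, n_slr)),
          cigar = c(rep(sprintf("%dS%dM", k_cons, mlen), n_slr),
                    rep(sprintf("%dM", R), n_slr)),
          sequence = c(sseqs, mseqs),
          edit_distance = c(nm_s, nm_m)
        )
        truth_sites$supporting_reads[si] <- n_slr
        truth_sites$support_fraction[si] <- n_slr / (n_slr + bg_depth)
      }
      read_rows[[2L * i]] <- bind_rows(sl_list)
    }
  }
  reads <- bind_rows(read_rows) |>
    mutate(properly_paired = TRUE,
           reverse = bitwAnd(.data$flag, 16L) > 0L,
           first_in_pair = bitwAnd(.data$flag, 64L) > 0L) |>
    select("read_id", "target_id", "flag", "start", "cigar", "sequence",
           "properly_paired", "reverse", "first_in_pair", "edit_distance")

  ## ---- transcripts, alignments, hits -----------------------------------
  tx_rows <- list(); aln_rows <- list(); hit_rows <- list(); ev_rows <- list()

  trimmed_blocks <- function(g, p) {
    pos <- sort(cds_genomic_positions(genes, g)[p:len_of[[g]]])
    brk <- c(0L, which(diff(pos) != 1L), length(pos))
    tibble(start = pos[brk[-length(brk)] + 1L], end = pos[brk[-1]])
  }

  add_transcript <- function(tid, g, p, identity = 100, shift_intron = FALSE) {
    lead <- sample(0:14, 1)
    raw <- paste0(rand_dna(lead), conserved,
                  substr(cds_seq[[g]], p, len_of[[g]]))
    flipped <- stats::runif(1) < 0.3
    stored <- if (flipped) revcomp(raw) else raw
    tx_rows[[length(tx_rows) + 1]] <<- tibble(
      seq_id = tid, sequence = stored, gene_id = g, site = as.integer(p),
      orientation = if (flipped) "reverse_complement" else "forward",
      lead = as.integer(lead))
    blocks <- trimmed_blocks(g, p)
    if (shift_intron && nrow(blocks) > 1) {
      blocks$end[1] <- blocks$end[1] - 10L
    }
    grow <- genes[genes$gene_id == g, ]
    aln_rows[[length(aln_rows) + 1]] <<- tibble(
      transcript_id = tid, scaffold_id = grow$scaffold_id,
      strand = grow$strand, blocks = list(blocks),
      avg_identity_pct = identity, percent_aligned = 100)
    tlen <- len_of[[g]] - p + 1L
    hit_rows[[length(hit_rows) + 1]] <<- tibble(
      query_id = tid, subject_id = g, identity_pct = identity,
      aln_length = tlen, mismatches = 0L, gap_opens = 0L,
      q_start = 1L, q_end = tlen, s_start = as.integer(p),
      s_end = len_of[[g]], evalue = 1e-180, bit_score = 500,
      strand = "+")
  }

  event_specs <- tibble(
    label = c("A", "B", "C", "D", "E"),
    gene_id = unname(construct_genes),
    point = c(pA, pB, pC, pD2, pE),
    planted_type = c(1L, 2L, 1L, 1L, 2L),
    planted_categories = c("A", "B", "C", "D", "")
  )
  for (j in seq_len(nrow(event_specs))) {
    tid <- sprintf("t_%s", event_specs$gene_id[j])
    add_transcript(tid, event_specs$gene_id[j], event_specs$point[j])
    ev_rows[[j]] <- mutate(event_specs[j, ], transcript_id = tid)
  }
  events_truth <- bind_rows(ev_rows) |>
    select("transcript_id", "gene_id", truncation_point = "point",
           "planted_type", "planted_categories")

  # full-length SL transcripts for a few position-1 genes (no truncation)
  for (g in utils::head(pos1_genes, 3)) {
    add_transcript(sprintf("t_%s", g), g, 1L)
  }
  # decoys: one failing alignment validation, one with a shifted donor
  dec1 <- decoy_genes[1]; dec2 <- decoy_genes[2]
  p_dec1 <- min(300L, len_of[[dec1]] - 2L * FRAG)
  add_transcript("t_decoy_lowid", dec1, p_dec1, identity = 92)
  p_dec2 <- {
    st <- piece_starts[[dec2]]
    if (length(st) > 1) min(150L, st[2] - 10L) else 150L
  }
  add_transcript("t_decoy_shift", dec2, p_dec2, shift_intron = TRUE)

  transcripts <- bind_rows(tx_rows)
  alignments <- bind_rows(aln_rows)
  hits <- bind_rows(hit_rows)

  ## ---- expression counts ------------------------------------------------
  sl_gene_set <- unique(truth_sites$gene_id)
  all_ids <- genes$gene_id
  grp <- ifelse(all_ids %in% sl_gene_set, "sl", "no_sl")
  mu <- ifelse(grp == "sl", config$expr_mean_sl, config$expr_mean_other)
  shape <- 1 / config$expr_cv^2
  lambda <- stats::rgamma(length(all_ids), shape = shape, rate = shape / mu)
  glen <- setNames(genes$cds_length, genes$gene_id)
  counts <- tidyr::expand_grid(gene_id = all_ids,
                               replicate_id = sprintf("rep%d", seq_len(config$n_replicates))) |>
    left_join(tibble(gene_id = all_ids, lambda = lambda), by = "gene_id") |>
    mutate(expected_count = .data$lambda * glen[.data$gene_id] / 1000 *
             exp(stats::rnorm(dplyr::n(), 0, 0.05))) |>
    select("gene_id", "replicate_id", "expected_count")
  expression_groups <- tibble(gene_id = all_ids, group = grp, mean = lambda)

  truth <- list(
    planted_sites = select(truth_sites, "gene_id", "position", "context_class",
                           "planted_support", "supporting_reads",
                           "support_fraction"),
    mispredicted_genes = mispred,
    sl_loci = sl_loci,
    recycled_paralogs = recycled,
    truncation_events = events_truth,
    transcripts = select(transcripts, "seq_id", "gene_id", "site",
                         "orientation", "lead"),
    decoys = tibble(seq_id = c("t_decoy_lowid", "t_decoy_shift"),
                    reason = c("low_identity", "shifted_donor")),
    expression_groups = expression_groups
  )

  sim <- structure(
    list(genome = genome, genes = genes, reads = reads,
         transcripts = select(transcripts, "seq_id", "sequence"),
         alignments = alignments, hits = hits, features = features,
         counts = counts, truth = truth, sl = sl, config = config),
    class = "slts_sim"
  )
  if (!is.null(outdir)) write_slts_dataset(sim, outdir)
  sim
}

#' Write a simulated dataset to disk
#'
#' @param sim An `slts_sim` object.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_slts_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_fasta(setNames(sim$genome, names(sim$genome)), fp("genome.fa"))
  write_gff3_genes(sim$genes, fp("genes.gff3"))
  write_fasta(setNames(sim$genes$cds_sequence, sim$genes$gene_id), fp("cds.fa"))
  write_fasta(sim$transcripts, fp("transcripts.fa"))
  write_sam(sim$reads, setNames(sim$genes$cds_length, sim$genes$gene_id),
            fp("reads.sam"))
  write_transcript_alignments(sim$alignments, fp("alignments.tsv"))
  write_blast_hits(sim$hits, fp("hits.tsv"))
  readr::write_tsv(sim$features, fp("features.tsv"))
  readr::write_tsv(sim$counts, fp("counts.tsv"))
  jsonlite::write_json(lapply(sim$truth, as.data.frame), fp("truth.json"),
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble (as from [read_gff3_genes()] or
#'   [simulate_slts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    ex <- genes$exons[[i]]
    cd <- genes$cds_intervals[[i]]
    scaf <- genes$scaffold_id[i]
    strand <- genes$strand[i]
    span <- c(min(ex$start), max(ex$end))
    lines <- c(lines,
      sprintf("%s\tsltscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s", scaf, span[1], span[2], strand, g),
      sprintf("%s\tsltscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s", scaf, span[1], span[2], strand, g, g),
      sprintf("%s\tsltscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
              scaf, ex$start, ex$end, strand, g, seq_len(nrow(ex)), g))
    # CDS phase in translation order (sense order differs by strand)
    ord <- if (strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
    plen <- (cd$end - cd$start + 1L)[ord]
    cum <- c(0L, cumsum(plen)[-length(plen)])
    phase <- (3L - (cum %% 3L)) %% 3L
    phase_by_row <- integer(nrow(cd)); phase_by_row[ord] <- phase
    lines <- c(lines,
      sprintf("%s\tsltscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.c%d;Parent=%s.t1",
              scaf, cd$start, cd$end, strand, phase_by_row, g, seq_len(nrow(cd)), g))
  }
  writeLines(lines, path)
  invisible(path)
}
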