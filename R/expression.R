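# Expression: per-gene TPM from expected counts and CDS lengths, and the
# unequal-variance comparison of genes with vs without SL addition sites.

#' Compute per-gene TPM from expected counts
#'
#' Within each replicate, `tpm_i = (c_i / L_i) / sum_j(c_j / L_j) * 1e6`,
#' where `c` is the expected read count and `L` the CDS length in nt.
#' TPM sums to one million per replicate. Genes with zero or missing CDS
#' length are excluded with a warning; a replicate with all-zero counts is
#' an error.
#'
#' @param counts Long tibble (`gene_id`, `replicate_id`,
#'   `expected_count`), e.g. from [read_expected_counts()].
#' @param genes Gene models, or a named numeric vector of CDS lengths.
#' @return `counts` with `cds_length` and `tpm` columns added.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), replicate_id = "r1",
#'                          expected_count = c(10, 30))
#' compute_tpm(counts, c(a = 1000, b = 3000))
#' @export
compute_tpm <- function(counts, genes) {
  len <- if (is.data.frame(genes)) setNames(genes$cds_length, genes$gene_id) else genes
  counts$cds_length <- unname(len[counts$gene_id])
  bad <- is.na(counts$cds_length) | counts$cds_length <= 0
  if (any(bad)) {
    warn(sprintf("%d gene/replicate row(s) with missing or zero CDS length excluded",
                 sum(bad)))
    counts <- counts[!bad, , drop = FALSE]
  }
  counts |>
    group_by(.data$replicate_id) |>
    mutate(rate = .data$expected_count / .data$cds_length,
           tpm = {
             tot <- sum(.data$rate)
             if (tot == 0) abort(paste0("all counts are zero in replicate ",
                                        .data$replicate_id[1]))
             .data$rate / tot * 1e6
           }) |>
    ungroup() |>
    select(-"rate")
}

#' Welch's two-sample unequal-variance t-test (closed form)
#'
#' Computes the Welch statistic, the Welch--Satterthwaite degrees of
#' freedom, and the two-tailed p-value from the t distribution.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return A list with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
welch_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    return(list(t = 0, df = n1 + n2 - 2, p_value = 1,
                mean_x = mean(x), mean_y = mean(y)))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df),
       mean_x = mean(x), mean_y = mean(y))
}

#' Compare expression of genes with and without SL addition sites
#'
#' Averages TPM per gene across replicates (arithmetic mean), splits genes
#' into those with at least one SL addition site and the rest, and applies
#' a two-sample t-test assuming unequal variance ([welch_t_test()]).
#'
#' @param tpm Tibble from [compute_tpm()].
#' @param sl_genes Character vector of gene ids with SL addition sites, or
#'   a site tibble with a `gene_id` column.
#' @return An object of class `slts_expression_test` with the statistic,
#'   degrees of freedom, p-value, group means and sizes. Supports
#'   [tidy()] and [glance()].
#' @export
sl_expression_test <- function(tpm, sl_genes) {
  if (is.data.frame(sl_genes)) sl_genes <- unique(sl_genes$gene_id)
  per_gene <- tpm |>
    group_by(.data$gene_id) |>
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop") |>
    mutate(group = if_else(.data$gene_id %in% sl_genes, "sl", "no_sl"))
  a <- per_gene$mean_tpm[per_gene$group == "sl"]
  b <- per_gene$mean_tpm[per_gene$group == "no_sl"]
  w <- welch_t_test(a, b)
  structure(
    list(t = w$t, df = w$df, p_value = w$p_value,
         mean_sl = w$mean_x, mean_no_sl = w$mean_y,
         n_sl = length(a), n_no_sl = length(b), per_gene = per_gene),
    class = "slts_expression_test"
  )
}

#' @export
print.slts_expression_test <- function(x, ...) {
  cat("Welch two-sample t-test: mean TPM, genes with vs without SL sites\n")
  cat(sprintf("  n = %d (SL) vs %d (no SL)\n", x$n_sl, x$n_no_sl))
  cat(sprintf("  mean TPM = %.2f (SL) vs %.2f (no SL)\n", x$mean_sl, x$mean_no_sl))
  cat(sprintf("  t = %.4f, df = %.2f, two-tailed p = %.3g\n", x$t, x$df, x$p_value))
  invisible(x)
}

#' Tidy an SL expression test
#' @param x An `slts_expression_test`.
#' @param ... Unused.
#' @return One-row tibble with `estimate` (difference of group means),
#'   `mean_sl`, `mean_no_sl`, `statistic`, `df`, `p_value`.
#' @export
tidy.slts_expression_test <- function(x, ...) {
  tibble(estimate = x$mean_sl - x$mean_no_sl, mean_sl = x$mean_sl,
         mean_no_sl = x$mean_no_sl, statistic = x$t, df = x$df,
         p_value = x$p_value)
}

#' Glance at an SL expression test
#' @param x An `slts_expression_test`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `n_sl`,
#'   `n_no_sl`.
#' @export
glance.slts_expression_test <- function(x, ...) {
  tibble(statistic = x$t, df = x$df, p_value = x$p_value,
         n_sl = x$n_sl, n_no_sl = x$n_no_sl)
}
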