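#' Paired differential expression by the Wilcoxon signed-rank test
#'
#' A distribution-light stand-in for a negative-binomial DE engine: for each
#' gene, per-patient differences `d_i = log2(tumor_i + 1) - log2(normal_i + 1)`
#' are computed on normalized counts and tested with the two-sided Wilcoxon
#' signed-rank test (exact for up to 25 patients, normal approximation with
#' continuity correction beyond). The reported fold change is the mean of the
#' `d_i`. P-values are BH-adjusted across the tested gene set. Users with
#' results from an external DE tool can substitute them via [read_de_table()].
#'
#' @param x A `paired_counts` object with at least 3 complete patients.
#' @param genes Genes to test; default all genes in the matrix.
#' @return A tibble with columns `gene_id`, `log2_fold_change`, `p_value`,
#'   `p_adjusted`, `source = "internal"`.
#' @export
paired_de <- function(x, genes = NULL) {
  if (n_patients(x) < 3) abort("paired DE needs at least 3 complete patients")
  genes <- genes %||% rownames(x$counts)
  miss <- setdiff(genes, rownames(x$counts))
  if (length(miss) > 0) {
    abort(paste0("gene(s) absent from count matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  m <- normalized_counts(x)
  norm_s <- condition_samples(x, "normal")
  tum_s <- condition_samples(x, "tumor")
  d <- log2(m[genes, tum_s, drop = FALSE] + 1) -
    log2(m[genes, norm_s, drop = FALSE] + 1)
  pvals <- unname(apply(d, 1, signed_rank_p, exact_max = 25))
  res <- tibble(
    gene_id = genes,
    log2_fold_change = unname(rowMeans(d)),
    p_value = pvals,
    p_adjusted = p.adjust(pvals, method = "BH"),
    source = "internal"
  )
  res
}

# Two-sided signed-rank p for a vector of paired differences. Zeros are
# dropped (all-zero -> p = 1); |d| ties get average ranks. Exact for up to
# `exact_max` nonzero differences via the convolution of the sign-flip
# distribution (equivalent to full 2^n enumeration, ties included), normal
# approximation with continuity and tie correction beyond.
signed_rank_p <- function(d, exact_max = 25) {
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of W+ over all 2^n sign assignments, ranks doubled so the
    # support is integer even with average ranks
    r2 <- as.integer(round(2 * r))
    probs <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs)
      probs <- (c(probs, rep(0, ri)) + shifted) / 2
    }
    w2 <- round(2 * w)
    support <- seq_along(probs) - 1L
    pl <- sum(probs[support <= w2])
    pu <- sum(probs[support >= w2])
    min(1, 2 * min(pl, pu))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Import a differential-expression results table
#'
#' Reads a TSV with columns `gene_id`, `log2FoldChange`, `pvalue`, `padj`
#' (the conventional column names of count-based DE tools). Rows with missing
#' `padj` are dropped; their number is stored in the `n_dropped` attribute.
#'
#' @param path Path to the TSV file.
#' @return A tibble in the same shape as [paired_de()] with
#'   `source = "imported"`.
#' @export
read_de_table <- function(path) {
  de <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("gene_id", "log2FoldChange", "pvalue", "padj")
  miss <- setdiff(req, names(de))
  if (length(miss) > 0) {
    abort(paste0("DE table is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(de) == 0L) abort(paste0("DE table is empty: ", path))
  n_dropped <- sum(is.na(de$padj))
  de <- filter(de, !is.na(.data$padj))
  out <- tibble(
    gene_id = as.character(de$gene_id),
    log2_fold_change = de$log2FoldChange,
    p_value = de$pvalue,
    p_adjusted = de$padj,
    source = "imported"
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Select the antisense differential-expression (ncNATDiffExp) list
#'
#' Keeps pairs whose antisense gene is significantly differentially expressed
#' between tumor and normal at adjusted p < alpha (strict inequality). Pairs
#' whose NAT gene has no DE result are excluded with a notice.
#'
#' @param pairs Filtered pairs tibble.
#' @param de DE results ([paired_de()] or [read_de_table()]).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The selected subset of `pairs`, with `nat_padj` attached.
#' @export
select_nat_diffexp <- function(pairs, de, alpha = 0.05) {
  idx <- match(pairs$nat_gene_id, de$gene_id)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    inform(paste0(n_missing, " pair(s) excluded: NAT gene absent from DE ",
                  "results"))
  }
  padj <- de$p_adjusted[idx]
  keep <- !is.na(padj) & padj < alpha
  out <- pairs[keep, , drop = FALSE]
  out$nat_padj <- padj[keep]
  out
}
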