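#' Spearman correlation with a t-approximation p-value
#'
#' Rho is the Pearson correlation of the average-tie rank vectors; the
#' two-sided p-value comes from `t = rho * sqrt((n-2) / (1-rho^2))` on n-2
#' degrees of freedom. `rho = +-1` is reported with the smallest representable
#' positive p. A constant input vector yields a flagged missing result
#' (`rho = NA`), never a silent zero.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param n_perm If > 0, replace the t-approximation with a Monte-Carlo
#'   permutation p-value on that many permutations (useful for very small n).
#' @return A tibble with columns `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y, n_perm = 0) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 4) abort("need at least 4 observations")
  rho <- spearman_rho(x, y)
  if (is.na(rho)) {
    return(tibble(rho = NA_real_, p = NA_real_, n = n))
  }
  if (n_perm > 0) {
    obs <- abs(rho)
    perm <- vapply(seq_len(n_perm), function(i) {
      abs(spearman_rho(x, sample(y)))
    }, numeric(1))
    p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  } else {
    p <- spearman_p_t(rho, n)
  }
  tibble(rho = rho, p = p, n = n)
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

spearman_p_t <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(.Machine$double.xmin)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tt), df = n - 2)
}

# Row-wise Spearman correlation between matching rows of two matrices.
# Returns list(rho, p) vectors; constant rows give NA.
row_spearman <- function(mx, my) {
  stopifnot(dim(mx) == dim(my))
  n <- ncol(mx)
  rx <- t(apply(mx, 1, rank))
  ry <- t(apply(my, 1, rank))
  cx <- rx - rowMeans(rx)
  cy <- ry - rowMeans(ry)
  vx <- rowSums(cx^2)
  vy <- rowSums(cy^2)
  rho <- unname(rowSums(cx * cy) / sqrt(vx * vy))
  rho[vx == 0 | vy == 0] <- NA_real_
  p <- vapply(rho, spearman_p_t, numeric(1), n = n, USE.NAMES = FALSE)
  list(rho = rho, p = p)
}

#' Fisher-z test for a difference of two correlations
#'
#' Transforms each coefficient with atanh and compares them on the normal
#' scale: `z = (atanh(r2) - atanh(r1)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value `2 * (1 - pnorm(|z|))`. In this package condition 1 is
#' the adjacent-normal tissue and condition 2 the tumor, so positive z means
#' the correlation becomes more positive in the tumor. Coefficients at |r| = 1
#' are clamped to 1 - 1e-15 with a warning.
#'
#' @param r1,r2 Correlation coefficients (vectorized).
#' @param n1,n2 Sample sizes (> 3).
#' @return A tibble with columns `z`, `p`.
#' @export
fisher_z_diff <- function(r1, n1, r2, n2) {
  if (any(c(n1, n2) <= 3)) abort("Fisher-z variance requires n > 3")
  clamp <- function(r) {
    hi <- abs(r) >= 1
    if (any(hi, na.rm = TRUE)) {
      warn("correlation(s) at |r| = 1 clamped to 1 - 1e-15")
      r[hi & !is.na(r)] <- sign(r[hi & !is.na(r)]) * (1 - 1e-15)
    }
    r
  }
  z1 <- atanh(clamp(r1))
  z2 <- atanh(clamp(r2))
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (z2 - z1) / se
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Significance-and-sign class of a correlation
#'
#' `"+"` when p < alpha and r > 0, `"-"` when p < alpha and r < 0, `"0"`
#' otherwise; `NA` when the correlation is missing.
#'
#' @param r,p Correlation and p-value (vectorized).
#' @param alpha Per-condition significance level (default 0.05).
#' @return Character vector of class symbols.
#' @export
correlation_class <- function(r, p, alpha = 0.05) {
  out <- rep("0", length(r))
  out[!is.na(p) & p < alpha & r > 0] <- "+"
  out[!is.na(p) & p < alpha & r < 0] <- "-"
  out[is.na(r) | is.na(p)] <- NA_character_
  out
}

#' Differential correlation of antisense/sense pairs between conditions
#'
#' For every pair, computes the Spearman correlation of NAT vs PC expression
#' across patients separately in normal and tumor tissue, the Fisher-z
#' difference score (tumor minus normal), its two-sided p-value with BH
#' adjustment across pairs, and the two-symbol class label such as `"0/+"` —
#' normal-tissue class, then tumor class.
#'
#' @param pairs Pairs tibble, typically after [filter_expressed_pairs()].
#' @param x A `paired_counts` object.
#' @param scale Expression scale used for the correlations: `"normalized"`
#'   (default; size-factor scaled), `"raw"`, or `"log"` (log2 normalized + 1).
#'   Spearman correlation is invariant to the log option; it is offered for
#'   plotting parity.
#' @param alpha Per-condition significance level for the class calls.
#' @return A tibble of class `natpairs_diffcor` with per-pair columns
#'   `r_normal`, `p_normal`, `r_tumor`, `p_tumor`, `n_normal`, `n_tumor`,
#'   `z_diff`, `p_diff`, `p_diff_adj`, `class_normal`, `class_tumor`,
#'   `diffcor_class`.
#' @export
diffcor <- function(pairs, x, scale = c("normalized", "raw", "log"),
                    alpha = 0.05) {
  scale <- match.arg(scale)
  if (nrow(pairs) == 0L) abort("no pairs supplied")
  m <- switch(scale,
    normalized = normalized_counts(x),
    raw = x$counts,
    log = log2(normalized_counts(x) + 1)
  )
  norm_s <- condition_samples(x, "normal")
  tum_s <- condition_samples(x, "tumor")
  pc_i <- match(pairs$pc_gene_id, rownames(m))
  nat_i <- match(pairs$nat_gene_id, rownames(m))
  if (anyNA(pc_i) || anyNA(nat_i)) {
    abort("all pair genes must be present in the count matrix")
  }
  cn <- row_spearman(m[nat_i, norm_s, drop = FALSE],
                     m[pc_i, norm_s, drop = FALSE])
  ct <- row_spearman(m[nat_i, tum_s, drop = FALSE],
                     m[pc_i, tum_s, drop = FALSE])
  fz <- fisher_z_diff(cn$rho, length(norm_s), ct$rho, length(tum_s))
  res <- tibble(
    pc_gene_id = pairs$pc_gene_id,
    nat_gene_id = pairs$nat_gene_id,
    r_normal = cn$rho, p_normal = cn$p,
    r_tumor = ct$rho, p_tumor = ct$p,
    n_normal = length(norm_s), n_tumor = length(tum_s),
    z_diff = fz$z, p_diff = fz$p,
    p_diff_adj = p.adjust(fz$p, method = "BH"),
    class_normal = correlation_class(cn$rho, cn$p, alpha),
    class_tumor = correlation_class(ct$rho, ct$p, alpha)
  ) |>
    mutate(diffcor_class = if_else(
      is.na(.data$class_normal) | is.na(.data$class_tumor),
      NA_character_,
      paste0(.data$class_normal, "/", .data$class_tumor)
    ))
  n_na <- sum(is.na(res$diffcor_class))
  if (n_na > 0) {
    inform(paste0(n_na, " pair(s) with a constant expression vector were ",
                  "left unclassified"))
  }
  class(res) <- c("natpairs_diffcor", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "scale") <- scale
  res
}

#' Select the differential-correlation (DiffCor) list
#'
#' Keeps pairs whose correlation difference is significant (adjusted p by
#' default, raw p with `use_adjusted = FALSE`) and whose class changed between
#' conditions, i.e. the concordant classes `0/0`, `+/+` and `-/-` are removed.
#'
#' @param results A `natpairs_diffcor` tibble from [diffcor()].
#' @param alpha_diff Significance level for the difference test.
#' @param use_adjusted Use BH-adjusted p (default) or raw p.
#' @return The selected subset of `results`.
#' @export
select_diffcor <- function(results, alpha_diff = 0.05, use_adjusted = TRUE) {
  p <- if (use_adjusted) results$p_diff_adj else results$p_diff
  keep <- !is.na(p) & p < alpha_diff &
    !is.na(results$diffcor_class) &
    !(results$diffcor_class %in% c("0/0", "+/+", "-/-"))
  results[keep, , drop = FALSE]
}

#' Count pairs per differential-correlation class
#'
#' @param results A `natpairs_diffcor` tibble.
#' @return A 9-row tibble (`diffcor_class`, `n`) covering every combination of
#'   `-`, `0`, `+`, plus an `n_unclassified` attribute for constant-vector
#'   pairs.
#' @export
summarize_diffcor_classes <- function(results) {
  lv <- as.vector(outer(c("-", "0", "+"), c("-", "0", "+"),
                        function(a, b) paste0(a, "/", b)))
  counts <- table(factor(results$diffcor_class, levels = lv))
  out <- tibble(diffcor_class = lv, n = as.integer(counts))
  attr(out, "n_unclassified") <- sum(is.na(results$diffcor_class))
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a differential-correlation analysis
#'
#' Reports the number of pairs, the mean Spearman coefficient among
#' significantly correlated pairs per condition, the number and fraction of
#' pairs with a significant correlation difference, and the mean z among them.
#'
#' @param x A `natpairs_diffcor` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance natpairs_diffcor
#' @export
glance.natpairs_diffcor <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  sig_n <- !is.na(x$p_normal) & x$p_normal < alpha
  sig_t <- !is.na(x$p_tumor) & x$p_tumor < alpha
  sig_d <- !is.na(x$p_diff) & x$p_diff < alpha
  tibble(
    n_pairs = nrow(x),
    mean_r_normal_sig = mean(x$r_normal[sig_n]),
    mean_r_tumor_sig = mean(x$r_tumor[sig_t]),
    n_diff_sig = sum(sig_d),
    frac_diff_sig = mean(sig_d, na.rm = TRUE),
    mean_z_diff_sig = mean(x$z_diff[sig_d])
  )
}
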