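#' Variation of the antisense-to-sense read-count ratio (varRatio)
#'
#' For each pair, the tumoral read-counts ratio is the sum of tumor antisense
#' counts over the sum of tumor protein-coding counts (summing across all
#' tumor samples); the normal ratio is defined likewise on the normal samples;
#' and `var_ratio` is tumoral ratio / normal ratio. `log_var_ratio` is the
#' natural log. Pairs are expected to have passed the expression filter so
#' all four sums are positive; a zero denominator is a hard error naming the
#' pair.
#'
#' Orientation note: the ratio is antisense over sense, so a pair whose
#' sense/antisense balance tips toward the antisense in the tumor has
#' `var_ratio > 1` (positive log). On the log scale the "left" tail holds
#' pairs whose antisense share decreased in the tumor, the "right" tail pairs
#' whose antisense share increased.
#'
#' @param pairs Filtered pairs tibble.
#' @param x A `paired_counts` object.
#' @param scale `"raw"` (default; the ratios are read-count ratios) or
#'   `"normalized"`.
#' @return A tibble of class `natpairs_varratio` with columns `pc_gene_id`,
#'   `nat_gene_id`, `tumoral_read_counts_ratio`, `normal_read_counts_ratio`,
#'   `var_ratio`, `log_var_ratio`.
#' @export
var_ratio <- function(pairs, x, scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  if (nrow(pairs) == 0L) abort("no pairs supplied")
  calls <- pair_category_calls(pairs, x, min_patients = 1, scale = scale)
  bad <- calls$sum_pc_tumor == 0 | calls$sum_pc_normal == 0 |
    calls$sum_nat_normal == 0
  if (any(bad)) {
    abort(paste0("zero count sum for pair(s): ",
                 paste(head(paste0(calls$pc_gene_id[bad], "/",
                                   calls$nat_gene_id[bad]), 5),
                       collapse = ", "),
                 " — apply the expression filter first"))
  }
  out <- tibble(
    pc_gene_id = calls$pc_gene_id,
    nat_gene_id = calls$nat_gene_id,
    tumoral_read_counts_ratio = calls$sum_nat_tumor / calls$sum_pc_tumor,
    normal_read_counts_ratio = calls$sum_nat_normal / calls$sum_pc_normal
  ) |>
    mutate(
      var_ratio = .data$tumoral_read_counts_ratio /
        .data$normal_read_counts_ratio,
      log_var_ratio = log(.data$var_ratio)
    )
  class(out) <- c("natpairs_varratio", class(out))
  out
}

#' Select extreme-tail pairs of the varRatio distribution
#'
#' Thresholds the log-transformed varRatio distribution at mean +- k_sd
#' standard deviations (computed over the full evaluated set). Pairs below
#' the lower threshold form the left list, pairs above the upper threshold
#' the right list. With the antisense-over-sense orientation of the ratio,
#' the right tail is where the sense/antisense balance tips toward the
#' antisense in the tumor; the mapping is recorded in the `orientation`
#' attribute so reports can print it.
#'
#' @param results A `natpairs_varratio` tibble.
#' @param k_sd Number of standard deviations (default 1).
#' @return `results` with an added `tail` column (`"left"`, `"right"`,
#'   `"none"`) and attributes `threshold_low`, `threshold_high`,
#'   `orientation`.
#' @export
select_var_extremes <- function(results, k_sd = 1) {
  if (nrow(results) < 10) abort("need at least 10 varRatio values")
  lv <- results$log_var_ratio
  mu <- mean(lv)
  sd_ <- stats::sd(lv)
  if (sd_ == 0) {
    warn("varRatio distribution is degenerate (sd = 0); no extremes selected")
    results$tail <- "none"
    attr(results, "threshold_low") <- mu
    attr(results, "threshold_high") <- mu
    return(results)
  }
  lo <- mu - k_sd * sd_
  hi <- mu + k_sd * sd_
  results$tail <- dplyr::case_when(
    lv < lo ~ "left",
    lv > hi ~ "right",
    TRUE ~ "none"
  )
  attr(results, "threshold_low") <- lo
  attr(results, "threshold_high") <- hi
  attr(results, "orientation") <- paste(
    "log_var_ratio = log(tumor NAT/PC ratio over normal NAT/PC ratio);",
    "right tail = antisense share increased in tumor,",
    "left tail = antisense share decreased in tumor"
  )
  results
}

#' One-row summary of a varRatio analysis
#'
#' @param x A `natpairs_varratio` tibble (after [select_var_extremes()] if
#'   tail counts are wanted).
#' @param ... Unused.
#' @return A one-row tibble with the distribution moments and tail sizes.
#' @method glance natpairs_varratio
#' @export
glance.natpairs_varratio <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    mean_log_var_ratio = mean(x$log_var_ratio),
    sd_log_var_ratio = stats::sd(x$log_var_ratio),
    n_left = if ("tail" %in% names(x)) sum(x$tail == "left") else NA_integer_,
    n_right = if ("tail" %in% names(x)) sum(x$tail == "right") else NA_integer_
  )
}
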