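#' Per-category expression calls for each pair
#'
#' Internal helper: for each pair, whether each of the four transcript
#' categories (PC/NAT x normal/tumor) has a raw count > 0 in at least
#' `min_patients` patients of that tissue, plus the per-category count sums.
#' @noRd
pair_category_calls <- function(pairs, x, min_patients = 7,
                                scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  m_raw <- x$counts
  m_sum <- if (scale == "raw") m_raw else normalized_counts(x)
  norm_s <- condition_samples(x, "normal")
  tum_s <- condition_samples(x, "tumor")

  absent <- setdiff(unique(c(pairs$pc_gene_id, pairs$nat_gene_id)),
                    rownames(m_raw))
  if (length(absent) > 0) {
    inform(paste0(length(absent), " pair gene(s) absent from the count ",
                  "matrix are treated as unexpressed"))
  }
  take <- function(m, idx, cols) {
    out <- matrix(0, nrow = length(idx), ncol = length(cols))
    ok <- !is.na(idx)
    out[ok, ] <- m[idx[ok], cols, drop = FALSE]
    out
  }
  pc_idx <- match(pairs$pc_gene_id, rownames(m_raw))
  nat_idx <- match(pairs$nat_gene_id, rownames(m_raw))

  res <- tibble(
    pc_gene_id = pairs$pc_gene_id,
    nat_gene_id = pairs$nat_gene_id,
    pc_normal = rowSums(take(m_raw, pc_idx, norm_s) > 0) >= min_patients,
    pc_tumor = rowSums(take(m_raw, pc_idx, tum_s) > 0) >= min_patients,
    nat_normal = rowSums(take(m_raw, nat_idx, norm_s) > 0) >= min_patients,
    nat_tumor = rowSums(take(m_raw, nat_idx, tum_s) > 0) >= min_patients,
    sum_pc_normal = rowSums(take(m_sum, pc_idx, norm_s)),
    sum_pc_tumor = rowSums(take(m_sum, pc_idx, tum_s)),
    sum_nat_normal = rowSums(take(m_sum, nat_idx, norm_s)),
    sum_nat_tumor = rowSums(take(m_sum, nat_idx, tum_s))
  )
  res
}

#' Tabulate pairs by their 4-way expression pattern
#'
#' Classifies every pair by whether the protein-coding transcript and the
#' antisense are expressed (raw count > 0 in at least `min_patients` patients)
#' in normal and in tumor tissue, and sums read counts per category within
#' each of the 16 patterns.
#'
#' @param pairs Pairs tibble ([build_nat_pairs()]).
#' @param x A `paired_counts` object.
#' @param min_patients Patient threshold per tissue (default 7).
#' @param scale Count scale for the summed-count columns (`"raw"` default).
#' @return A 16-row tibble with logical columns `pc_normal`, `pc_tumor`,
#'   `nat_normal`, `nat_tumor`, `n_pairs`, and the four summed-count columns,
#'   sorted by decreasing `n_pairs`.
#' @export
expression_category_table <- function(pairs, x, min_patients = 7,
                                      scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  calls <- pair_category_calls(pairs, x, min_patients, scale)
  grid <- tidyr::expand_grid(
    pc_normal = c(TRUE, FALSE), pc_tumor = c(TRUE, FALSE),
    nat_normal = c(TRUE, FALSE), nat_tumor = c(TRUE, FALSE)
  )
  tab <- calls |>
    group_by(.data$pc_normal, .data$pc_tumor, .data$nat_normal,
             .data$nat_tumor) |>
    summarise(
      n_pairs = n(),
      sum_pc_normal = sum(.data$sum_pc_normal),
      sum_pc_tumor = sum(.data$sum_pc_tumor),
      sum_nat_normal = sum(.data$sum_nat_normal),
      sum_nat_tumor = sum(.data$sum_nat_tumor),
      .groups = "drop"
    )
  out <- grid |>
    left_join(tab, by = names(grid)) |>
    mutate(across(c("n_pairs"), ~ tidyr::replace_na(.x, 0L)),
           across(dplyr::starts_with("sum_"), ~ tidyr::replace_na(.x, 0))) |>
    arrange(dplyr::desc(.data$n_pairs))
  stopifnot(sum(out$n_pairs) == nrow(pairs))
  out
}

#' Keep pairs expressed in all four categories
#'
#' Retains the pairs whose protein-coding and antisense transcripts are both
#' expressed (raw count > 0 in at least `min_patients` patients) in both the
#' tumor and the normal tissue — the stratum all downstream selection methods
#' operate on.
#'
#' @inheritParams expression_category_table
#' @return The subset of `pairs` with the all-yes pattern.
#' @export
filter_expressed_pairs <- function(pairs, x, min_patients = 7) {
  calls <- pair_category_calls(pairs, x, min_patients)
  keep <- calls$pc_normal & calls$pc_tumor & calls$nat_normal & calls$nat_tumor
  pairs[keep, , drop = FALSE]
}

#' Global antisense-to-sense read-count percentage
#'
#' Total NAT counts over all pairs and samples of one condition divided by
#' total PC counts over the same, as a percentage. This is the summary behind
#' statements like "antisense read counts represent 17% of their coding
#' counterparts in non-malignant tissues".
#'
#' @inheritParams expression_category_table
#' @param condition `"normal"` or `"tumor"`.
#' @param scale `"raw"` (default) or `"normalized"`.
#' @return A single percentage (0 if all NAT counts are zero).
#' @export
global_nat_pc_ratio <- function(pairs, x, condition = c("normal", "tumor"),
                                scale = c("raw", "normalized")) {
  condition <- match.arg(condition)
  scale <- match.arg(scale)
  if (nrow(pairs) == 0L) abort("no pairs supplied")
  calls <- pair_category_calls(pairs, x, min_patients = 1, scale = scale)
  pc_sum <- if (condition == "normal") sum(calls$sum_pc_normal) else
    sum(calls$sum_pc_tumor)
  nat_sum <- if (condition == "normal") sum(calls$sum_nat_normal) else
    sum(calls$sum_nat_tumor)
  if (pc_sum == 0) abort("protein-coding count total is zero; ratio undefined")
  100 * nat_sum / pc_sum
}
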