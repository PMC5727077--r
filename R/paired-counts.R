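#' Construct a paired count matrix
#'
#' Bundles a genes-by-samples count matrix with a sample sheet describing the
#' tumor/normal pairing. Every patient must contribute exactly one tumor and
#' one adjacent-normal sample; incomplete or ambiguous patients are dropped
#' with a warning.
#'
#' @param counts Non-negative integer matrix, rownames are gene IDs, colnames
#'   sample IDs.
#' @param samples Data frame with columns `sample_id`, `patient_id`,
#'   `condition` (values `"tumor"` / `"normal"`).
#' @param size_factors Optional positive per-sample scaling factors, named by
#'   sample ID.
#' @return An object of class `paired_counts`: a list with elements `counts`,
#'   `samples` (tibble) and `size_factors` (or `NULL`).
#' @export
paired_counts <- function(counts, samples, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate gene IDs in counts")
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("counts must be finite and non-negative")
  }
  samples <- as_tibble(samples)
  req <- c("sample_id", "patient_id", "condition")
  if (!all(req %in% names(samples))) {
    abort(paste0("sample sheet must have columns: ",
                 paste(req, collapse = ", ")))
  }
  if (!all(samples$condition %in% c("tumor", "normal"))) {
    abort("condition must be 'tumor' or 'normal'")
  }
  missing_in_sheet <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_in_sheet) > 0) {
    abort(paste0("count column(s) absent from sample sheet: ",
                 paste(missing_in_sheet, collapse = ", ")))
  }
  samples <- filter(samples, .data$sample_id %in% colnames(counts))

  # keep only patients with exactly one tumor and one normal sample
  tab <- samples |>
    count(.data$patient_id, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
  if (!"tumor" %in% names(tab)) tab$tumor <- 0L
  if (!"normal" %in% names(tab)) tab$normal <- 0L
  complete <- tab$patient_id[tab$tumor == 1L & tab$normal == 1L]
  dropped <- setdiff(tab$patient_id, complete)
  if (length(dropped) > 0) {
    warn(paste0("dropping ", length(dropped),
                " patient(s) without exactly one tumor and one normal sample: ",
                paste(dropped, collapse = ", ")))
    samples <- filter(samples, .data$patient_id %in% complete)
  }
  if (nrow(samples) == 0L) abort("no complete patients left")
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (!is.null(size_factors)) {
    size_factors <- size_factors[samples$sample_id]
    if (any(!is.finite(size_factors)) || any(size_factors <= 0)) {
      abort("size_factors must be strictly positive")
    }
  }
  structure(
    list(counts = counts, samples = samples, size_factors = size_factors),
    class = "paired_counts"
  )
}

#' @export
print.paired_counts <- function(x, ...) {
  cat("<paired_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", n_patients(x), " patients)\n", sep = "")
  cat("  size factors: ",
      if (is.null(x$size_factors)) "not computed" else "present", "\n",
      sep = "")
  invisible(x)
}

#' Number of complete patients in a paired count matrix
#' @param x A `paired_counts` object.
#' @return Integer patient count.
#' @export
n_patients <- function(x) {
  length(unique(x$samples$patient_id))
}

#' Sample IDs for one condition, ordered by patient
#' @param x A `paired_counts` object.
#' @param condition `"tumor"` or `"normal"`.
#' @return Character vector of sample IDs ordered by patient ID.
#' @export
condition_samples <- function(x, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  s <- filter(x$samples, .data$condition == !!condition) |>
    arrange(.data$patient_id)
  s$sample_id
}

#' Load a paired count matrix from TSV files
#'
#' @param counts_path TSV whose first column is `gene_id` and whose remaining
#'   columns are per-sample counts.
#' @param sheet_path TSV with columns `sample_id`, `patient_id`, `condition`.
#' @return A [paired_counts()] object.
#' @export
read_paired_counts <- function(counts_path, sheet_path) {
  cts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  if (names(cts)[1] != "gene_id") {
    abort("first column of the counts TSV must be 'gene_id'")
  }
  if (anyDuplicated(cts$gene_id)) abort("duplicate gene IDs in counts")
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene_id
  storage.mode(m) <- "double"
  sheet <- readr::read_tsv(sheet_path, show_col_types = FALSE)
  paired_counts(m, sheet)
}

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j = median_g count(g, j) / geomean_k count(g, k)`
#' over reference genes g with a nonzero count in every sample. The factors
#' are then rescaled to unit geometric mean so normalized totals stay on the
#' raw-count scale.
#'
#' @param x A `paired_counts` object.
#' @param fallback_total_count If `TRUE` and no gene is nonzero in all
#'   samples, fall back to library-size scaling (column total / mean total).
#' @return `x` with `size_factors` filled in.
#' @export
compute_size_factors <- function(x, fallback_total_count = FALSE) {
  m <- x$counts
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    if (!fallback_total_count) {
      abort(paste0("no gene has nonzero counts in every sample; ",
                   "set fallback_total_count = TRUE for library-size scaling"))
    }
    tot <- colSums(m)
    sf <- tot / mean(tot)
  } else {
    logm <- log(m[ref, , drop = FALSE])
    loggeo <- rowMeans(logm)
    sf <- apply(logm, 2, function(col) exp(median(col - loggeo)))
    sf <- sf / exp(mean(log(sf)))
  }
  x$size_factors <- setNames(sf, colnames(m))
  x
}

#' Normalized count matrix
#'
#' @param x A `paired_counts` object with size factors (computed on the fly
#'   with defaults if absent).
#' @return Matrix of counts divided column-wise by the size factors.
#' @export
normalized_counts <- function(x) {
  if (is.null(x$size_factors)) x <- compute_size_factors(x)
  sweep(x$counts, 2, x$size_factors, "/")
}
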