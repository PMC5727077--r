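#' Default antisense biotype whitelist
#'
#' Biotypes accepted for the non-coding member of a sense/antisense pair.
#' The list deliberately goes beyond the `antisense` biotype because curated
#' antisense annotation lags behind: any of these non-coding classes sitting
#' on the strand opposite a protein-coding gene is treated as a putative
#' natural antisense transcript (ncNAT).
#'
#' @return Character vector of biotype tokens.
#' @export
nat_biotype_whitelist <- function() {
  c(
    "3prime_overlapping_ncrna", "antisense", "IG_C_pseudogene",
    "IG_V_pseudogene", "lincRNA", "misc_RNA", "polymorphic_pseudogene",
    "processed_transcript", "pseudogene", "sense_intronic",
    "sense_overlapping", "snoRNA", "snRNA"
  )
}

#' Read gene-level records from a GTF annotation
#'
#' Parses `gene` features from an Ensembl-dialect GTF and returns one row per
#' gene with coordinates (1-based, inclusive), strand and biotype. Either the
#' `gene_biotype` or the `gene_type` attribute key is accepted. Features with
#' missing strand or biotype are skipped with a warning; the number skipped is
#' stored in the `n_skipped` attribute.
#'
#' @param path Path to a GTF file.
#' @param feature_level Feature type to keep; only `"gene"` is supported.
#' @return A tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`, and attribute `n_skipped`.
#' @export
read_gene_annotation <- function(path, feature_level = "gene") {
  feature_level <- match.arg(feature_level, "gene")
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  first <- readLines(path, n = 100L)
  if (!any(nzchar(first) & !startsWith(first, "#"))) {
    abort(paste0("no gene features in annotation file: ", path))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) abort(paste0("cannot read GTF '", path, "': ",
                                     conditionMessage(e)))
  )
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type)) {
    gr <- gr[as.character(mc$type) == feature_level]
    mc <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0L) {
    abort(paste0("no gene features in annotation file: ", path))
  }
  biotype <- as.character(mc$gene_biotype %||% mc$gene_type %||%
                            rep(NA_character_, length(gr)))
  genes <- tibble(
    gene_id = as.character(mc$gene_id),
    gene_name = as.character(mc$gene_name %||% mc$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype
  )
  bad <- is.na(genes$biotype) | !(genes$strand %in% c("+", "-")) |
    is.na(genes$gene_id)
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " gene feature(s) lacking strand or biotype ",
                "were skipped"))
    genes <- genes[!bad, , drop = FALSE]
  }
  if (nrow(genes) == 0L) {
    abort(paste0("no usable gene features in annotation file: ", path))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicate gene_id values in annotation")
  }
  attr(genes, "n_skipped") <- n_skipped
  genes
}

#' Build ncNAT/PCT pairs from gene records
#'
#' A pair is formed when (1) two genes overlap in genomic coordinates on the
#' same chromosome, (2) they lie on opposite strands, and (3) one has the
#' `protein_coding` biotype while the other has a biotype from the whitelist.
#' Overlap is evaluated on gene spans with 1-based inclusive coordinates, so
#' `overlap_bp = min(end) - max(start) + 1`. A protein-coding gene overlapped
#' by k whitelisted genes yields k pairs; `n_opposite_partners_of_pc` records
#' k for each protein-coding gene.
#'
#' @param genes Tibble of gene records as from [read_gene_annotation()].
#' @param biotype_whitelist Accepted non-coding biotypes; defaults to
#'   [nat_biotype_whitelist()].
#' @param strip_chr_prefix If `TRUE`, a leading `"chr"` is removed from
#'   chromosome names before comparison. Default `FALSE` (exact match).
#' @return Tibble with columns `pc_gene_id`, `nat_gene_id`, `chrom`,
#'   `overlap_bp`, `nat_biotype`, `n_opposite_partners_of_pc`, one row per
#'   (pc, nat) pair.
#' @export
build_nat_pairs <- function(genes, biotype_whitelist = nat_biotype_whitelist(),
                            strip_chr_prefix = FALSE) {
  empty <- tibble(
    pc_gene_id = character(), nat_gene_id = character(), chrom = character(),
    overlap_bp = integer(), nat_biotype = character(),
    n_opposite_partners_of_pc = integer()
  )
  if (nrow(genes) == 0L) return(empty)
  chrom <- genes$chrom
  if (strip_chr_prefix) chrom <- sub("^chr", "", chrom)

  pc <- genes$biotype == "protein_coding"
  nc <- genes$biotype %in% biotype_whitelist
  if (!any(pc) || !any(nc)) return(empty)

  gr <- function(idx) {
    GenomicRanges::GRanges(
      seqnames = chrom[idx],
      ranges = IRanges::IRanges(start = genes$start[idx], end = genes$end[idx]),
      strand = genes$strand[idx]
    )
  }
  gr_pc <- gr(which(pc))
  gr_nc <- gr(which(nc))
  # same-chromosome overlap irrespective of strand, then keep opposite
  # strands; disjoint seqlevels between the two sets are fine (no pairs)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_pc, gr_nc, ignore.strand = TRUE)
  )
  i <- which(pc)[S4Vectors::queryHits(hits)]
  j <- which(nc)[S4Vectors::subjectHits(hits)]
  keep <- genes$strand[i] != genes$strand[j] & genes$gene_id[i] != genes$gene_id[j]
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(empty)

  pairs <- tibble(
    pc_gene_id = genes$gene_id[i],
    nat_gene_id = genes$gene_id[j],
    chrom = chrom[i],
    overlap_bp = as.integer(pmin(genes$end[i], genes$end[j]) -
                              pmax(genes$start[i], genes$start[j]) + 1L),
    nat_biotype = genes$biotype[j]
  ) |>
    distinct(.data$pc_gene_id, .data$nat_gene_id, .keep_all = TRUE) |>
    group_by(.data$pc_gene_id) |>
    mutate(n_opposite_partners_of_pc = n()) |>
    ungroup() |>
    arrange(.data$pc_gene_id, .data$nat_gene_id)
  stopifnot(all(pairs$overlap_bp >= 1L))
  pairs
}

#' Write a pairs table to TSV
#'
#' @param pairs Pairs tibble from [build_nat_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}
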