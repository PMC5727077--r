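#' Run the full sense/antisense deregulation analysis
#'
#' Orchestrates the stages end to end: expression filtering of the pairs,
#' differential correlation (DiffCor), paired antisense differential
#' expression (ncNATDiffExp), read-count ratio variation (varRatio left and
#' right), the deduplicated union list, and — when survival data are
#' supplied — the survival screen of the lists' protein-coding genes against
#' random-control distributions. Every threshold in force is echoed into the
#' log, and all reports can be written as TSVs.
#'
#' @param pairs Pairs tibble from [build_nat_pairs()].
#' @param x A `paired_counts` object.
#' @param out_dir Optional directory for TSV reports and `pipeline.log`.
#' @param min_patients Expression-filter threshold per tissue (default 7).
#' @param alpha Per-condition significance level for correlation classes and
#'   the DE selection (default 0.05).
#' @param alpha_diff Significance level for the correlation-difference test.
#' @param use_adjusted Use BH-adjusted p for the DiffCor selection (default
#'   `TRUE`; set `FALSE` for the raw-p variant).
#' @param k_sd varRatio tail threshold in standard deviations (default 1).
#' @param de Optional imported DE results ([read_de_table()]); default is the
#'   internal paired test ([paired_de()]) on the pairs' antisense genes.
#' @param survival Optional list with elements `surv` (tibble `patient_id`,
#'   `time`, `event`) and `expression` (genes x patients matrix). When
#'   absent, the enrichment stage is skipped with a notice.
#' @param n_reps Random-control draws for the enrichment stage.
#' @param seed Integer seed for the control draws.
#' @param external_gene_list Optional character vector (or path to a one-
#'   gene-per-line file) of external cancer gene symbols to intersect with
#'   the selected lists' protein-coding genes.
#' @return A list with elements `filtered_pairs`, `diffcor`, `diffcor_list`,
#'   `de`, `natdiffexp_list`, `varratio`, `varratio_left`, `varratio_right`,
#'   `union_list`, `category_table`, `enrichment` (or `NULL`),
#'   `external_intersection` (or `NULL`) and `log` (character vector).
#' @export
run_nat_pipeline <- function(pairs, x, out_dir = NULL,
                             min_patients = 7, alpha = 0.05,
                             alpha_diff = 0.05, use_adjusted = TRUE,
                             k_sd = 1, de = NULL, survival = NULL,
                             n_reps = 200, seed = 1,
                             external_gene_list = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  say("thresholds: min_patients=", min_patients, " alpha=", alpha,
      " alpha_diff=", alpha_diff, " use_adjusted=", use_adjusted,
      " k_sd=", k_sd, " n_reps=", n_reps, " seed=", seed)

  cat_tab <- stage("categorize",
                   expression_category_table(pairs, x, min_patients))
  filtered <- stage("filter", filter_expressed_pairs(pairs, x, min_patients))
  say("pairs: ", nrow(pairs), " input, ", nrow(filtered),
      " expressed in all four categories (>=", min_patients,
      " patients per tissue)")
  if (nrow(filtered) == 0L) abort("no pairs pass the expression filter")

  dc <- stage("diffcor", diffcor(filtered, x, alpha = alpha))
  dc_list <- select_diffcor(dc, alpha_diff, use_adjusted)
  say("DiffCor list: ", nrow(dc_list), " pairs (",
      if (use_adjusted) "adjusted" else "raw", " p < ", alpha_diff,
      ", class changed)")

  if (is.null(de)) {
    de <- stage("diffexp",
                paired_de(x, genes = unique(filtered$nat_gene_id)))
  }
  de_list <- stage("diffexp", select_nat_diffexp(filtered, de, alpha))
  say("ncNATDiffExp list: ", nrow(de_list), " pairs (NAT adjusted p < ",
      alpha, ")")

  vr <- stage("varratio",
              select_var_extremes(var_ratio(filtered, x), k_sd = k_sd))
  say("varRatio tails at mean +/- ", k_sd, " sd of log varRatio; ",
      attr(vr, "orientation"))
  vr_left <- filter(vr, .data$tail == "left")
  vr_right <- filter(vr, .data$tail == "right")
  say("varRatio lists: ", nrow(vr_left), " left, ", nrow(vr_right), " right")

  pair_key <- function(d) paste(d$pc_gene_id, d$nat_gene_id)
  union_keys <- unique(c(pair_key(dc_list), pair_key(de_list),
                         pair_key(vr_left), pair_key(vr_right)))
  union_list <- filtered[pair_key(filtered) %in% union_keys, , drop = FALSE]
  say("union list: ", nrow(union_list), " unique deregulated pairs")

  enrichment <- NULL
  if (!is.null(survival)) {
    enrichment <- stage("survival", {
      expr_genes <- rownames(survival$expression)
      lists <- list(
        DiffCor = unique(dc_list$pc_gene_id),
        ncNATDiffExp = unique(de_list$pc_gene_id),
        VarRatioLeft = unique(vr_left$pc_gene_id),
        VarRatioRight = unique(vr_right$pc_gene_id),
        Union = unique(union_list$pc_gene_id)
      )
      lists <- lists[vapply(lists, length, integer(1)) > 0]
      selected_pc <- unique(union_list$pc_gene_id)
      universes <- list(
        with_antisense = setdiff(
          intersect(unique(pairs$pc_gene_id), expr_genes), selected_pc),
        without_antisense = setdiff(
          expr_genes, unique(c(pairs$pc_gene_id, pairs$nat_gene_id)))
      )
      universes <- universes[vapply(universes, length, integer(1)) > 0]
      screen_genes <- intersect(
        unique(c(unlist(lists), unlist(universes))), expr_genes)
      screen <- survival_screen(survival$surv, survival$expression,
                                genes = screen_genes, alpha = alpha)
      list(
        screen = screen,
        report = survival_enrichment(
          purrr::map(lists, ~ intersect(.x, expr_genes)),
          screen, universes, n_reps = n_reps, seed = seed)
      )
    })
    say("survival enrichment computed for ",
        nrow(enrichment$report), " list x control combinations")
  } else {
    say("no survival data supplied; enrichment stage skipped")
  }

  external_intersection <- NULL
  if (!is.null(external_gene_list)) {
    external_intersection <- intersect_gene_list(
      list(DiffCor = dc_list$pc_gene_id,
           ncNATDiffExp = de_list$pc_gene_id,
           VarRatioLeft = vr_left$pc_gene_id,
           VarRatioRight = vr_right$pc_gene_id),
      external_gene_list
    )
    say("external gene-list intersection: ",
        nrow(external_intersection), " genes")
  }

  out <- list(
    filtered_pairs = filtered, category_table = cat_tab,
    diffcor = dc, diffcor_list = dc_list,
    de = de, natdiffexp_list = de_list,
    varratio = vr, varratio_left = vr_left, varratio_right = vr_right,
    union_list = union_list,
    enrichment = enrichment,
    external_intersection = external_intersection,
    log = log_lines
  )
  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  out
}

write_pipeline_reports <- function(out, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(d, f) if (!is.null(d)) readr::write_tsv(d, file.path(out_dir, f))
  w(out$filtered_pairs, "filtered_pairs.tsv")
  w(out$category_table, "category_table.tsv")
  w(as_tibble(out$diffcor), "diffcor_results.tsv")
  w(as_tibble(out$diffcor_list), "diffcor_list.tsv")
  w(out$de, "de_results.tsv")
  w(out$natdiffexp_list, "natdiffexp_list.tsv")
  w(as_tibble(out$varratio), "varratio_results.tsv")
  w(out$union_list, "union_list.tsv")
  if (!is.null(out$enrichment)) {
    w(out$enrichment$report, "survival_enrichment.tsv")
    w(as_tibble(out$enrichment$screen), "survival_screen.tsv")
  }
  w(out$external_intersection, "external_intersection.tsv")
  writeLines(out$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' Intersect selected protein-coding genes with an external gene list
#'
#' Case-sensitive symbol match between the union of the selected lists'
#' protein-coding genes and an external list (e.g. a curated cancer gene
#' census), one gene per line if given as a file.
#'
#' @param lists Named list of character vectors of gene symbols, or a single
#'   character vector.
#' @param external Character vector of external gene symbols, or a path to a
#'   plain-text file with one symbol per line.
#' @return A tibble with columns `gene` and `in_lists` (comma-separated names
#'   of the selection lists containing the gene).
#' @export
intersect_gene_list <- function(lists, external) {
  if (!is.list(lists)) lists <- list(selected = lists)
  if (length(external) == 1 && file.exists(external)) {
    external <- readLines(external)
  }
  external <- unique(trimws(external))
  external <- external[external != ""]
  if (length(external) == 0) {
    warn("external gene list is empty; intersection is empty")
    return(tibble(gene = character(), in_lists = character()))
  }
  all_genes <- sort(unique(unlist(lists)))
  hit <- intersect(all_genes, external)
  tibble(
    gene = hit,
    in_lists = vapply(hit, function(g) {
      paste(names(lists)[vapply(lists, function(l) g %in% l, logical(1))],
            collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  )
}
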