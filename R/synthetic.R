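#' Configuration for the synthetic sense/antisense cohort
#'
#' Describes a paired tumor/normal cohort of antisense/sense loci with the
#' statistical structure the analysis assumes: negative-binomial counts, a
#' roughly 1000-fold sense-over-antisense expression ratio, per-condition
#' rank correlation imposed through a Gaussian copula, an optional
#' tumor-specific antisense up-shift, and survival times linked to a planted
#' gene subset.
#'
#' @param n_patients Patients with one tumor and one normal sample each
#'   (default 22).
#' @param n_pairs Number of antisense/sense loci.
#' @param n_unpaired_pc Isolated protein-coding genes with no antisense
#'   partner (they feed the "without antisense" control universe).
#' @param pc_mean Baseline mean count of a protein-coding gene before the
#'   per-gene lognormal factor.
#' @param nat_to_pc_ratio Antisense mean as a fraction of its sense partner
#'   (default 0.001, i.e. sense roughly 1000-fold above antisense).
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param baseline_r Target Spearman correlation of unplanted pairs in both
#'   conditions (default 0).
#' @param planted_diffcor List of specs `list(class=, r_normal=, r_tumor=,
#'   count=)` for pairs with condition-specific correlation.
#' @param planted_nat_shift `c(fold=, count=)`: pairs whose tumor antisense
#'   mean is multiplied by `fold`.
#' @param planted_survival `c(hazard_ratio=, count=)`: genes (taken from the
#'   planted pairs' protein-coding genes) linked to survival, with
#'   `hazard_ratio` the hazard ratio at +1 sd of expression.
#' @param censoring_rate Expected fraction of censored patients in the
#'   survival cohort.
#' @param n_survival_patients Size of the (separate) survival cohort.
#' @param seed Integer seed driving every draw.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 22,
                             n_pairs = 1000,
                             n_unpaired_pc = 600,
                             pc_mean = 5000,
                             nat_to_pc_ratio = 0.001,
                             nb_dispersion = 0.1,
                             baseline_r = 0,
                             planted_diffcor = list(),
                             planted_nat_shift = c(fold = 4, count = 0),
                             planted_survival = c(hazard_ratio = 3, count = 0),
                             censoring_rate = 0.3,
                             n_survival_patients = 200,
                             seed = 1) {
  stopifnot(n_patients >= 2, n_pairs >= 0, n_unpaired_pc >= 0,
            pc_mean > 0, nat_to_pc_ratio > 0, nb_dispersion > 0,
            censoring_rate >= 0, censoring_rate < 1,
            n_survival_patients >= 2)
  n_dc <- sum(vapply(planted_diffcor, function(p) p$count, numeric(1)))
  if (n_dc + planted_nat_shift[["count"]] > n_pairs) {
    abort("planted pair counts exceed n_pairs")
  }
  structure(
    list(
      n_patients = n_patients, n_pairs = n_pairs,
      n_unpaired_pc = n_unpaired_pc, pc_mean = pc_mean,
      nat_to_pc_ratio = nat_to_pc_ratio, nb_dispersion = nb_dispersion,
      baseline_r = baseline_r, planted_diffcor = planted_diffcor,
      planted_nat_shift = planted_nat_shift,
      planted_survival = planted_survival,
      censoring_rate = censoring_rate,
      n_survival_patients = n_survival_patients,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic gene annotation
#'
#' Writes a GTF with one protein-coding gene and one overlapping
#' opposite-strand `antisense`-biotype gene per locus, plus isolated
#' protein-coding genes, spread over three chromosomes. Loci never overlap
#' each other, so pair discovery must recover exactly the intended pairs.
#'
#' @param config A [synthetic_config()].
#' @param path Output GTF path.
#' @return A list: `gtf` (the path) and `truth` (tibble of intended
#'   `pc_gene_id` / `nat_gene_id` pairs).
#' @export
generate_annotation <- function(config, path = tempfile(fileext = ".gtf")) {
  n <- config$n_pairs
  m <- config$n_unpaired_pc
  ids <- function(prefix, k) sprintf("%s%05d", prefix, seq_len(k))
  pc_id <- ids("SYNPC", n)
  nat_id <- ids("SYNNAT", n)
  upc_id <- ids("SYNUPC", m)
  locus <- seq_len(n + m)
  chrom <- as.character((locus - 1L) %% 3L + 1L)
  offset <- ((locus - 1L) %/% 3L) * 10000L + 1L

  gtf_line <- function(chr, start, end, strand, id, biotype) {
    sprintf(paste0("%s\tnatpairs_synth\tgene\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; gene_name \"%s\"; gene_biotype \"%s\";"),
            chr, start, end, strand, id, id, biotype)
  }
  lines <- character(0)
  if (n > 0) {
    s <- offset[seq_len(n)]
    pc_strand <- ifelse(seq_len(n) %% 2L == 0L, "-", "+")
    nat_strand <- ifelse(pc_strand == "+", "-", "+")
    lines <- c(
      gtf_line(chrom[seq_len(n)], s, s + 3000L, pc_strand, pc_id,
               "protein_coding"),
      gtf_line(chrom[seq_len(n)], s + 1000L, s + 1800L, nat_strand, nat_id,
               "antisense")
    )
  }
  if (m > 0) {
    s <- offset[n + seq_len(m)]
    lines <- c(lines, gtf_line(chrom[n + seq_len(m)], s, s + 3000L, "+",
                               upc_id, "protein_coding"))
  }
  writeLines(lines, path)
  list(
    gtf = path,
    truth = tibble(pc_gene_id = pc_id, nat_gene_id = nat_id)
  )
}

# Spearman target -> Gaussian copula correlation (continuous-margin identity)
copula_rho <- function(r_s) 2 * sin(pi * r_s / 6)

#' Generate paired tumor/normal counts for the synthetic cohort
#'
#' Per-gene baseline means are lognormal around `pc_mean`; antisense means
#' are the sense mean times `nat_to_pc_ratio` times a second lognormal
#' factor. Counts are negative-binomial, linked within a pair and condition
#' by a Gaussian copula at the pair's target Spearman correlation, with a
#' per-sample lognormal library factor shared by all genes of a sample.
#' Planted differential-correlation pairs get their class-specific
#' `(r_normal, r_tumor)`; planted antisense-shift pairs get their tumor
#' antisense mean multiplied by the configured fold.
#'
#' @param config A [synthetic_config()].
#' @param truth Pair truth table from [generate_annotation()] (defaults to
#'   the IDs the generator would produce).
#' @return A list: `x` (a [paired_counts()] object with unpaired genes
#'   included), `truth` (pair table with `planted_diffcor`,
#'   `planted_class`, `r_normal`, `r_tumor`, `planted_shift` columns) and
#'   `survival_genes` (protein-coding genes designated for the survival
#'   planting, drawn from planted pairs first).
#' @export
generate_counts <- function(config, truth = NULL) {
  cfg <- config
  if (is.null(truth)) {
    truth <- generate_annotation(cfg, path = tempfile(fileext = ".gtf"))$truth
  }
  n <- nrow(truth)
  np <- cfg$n_patients
  withr::with_seed(cfg$seed, {
    # per-gene structure
    pc_base <- cfg$pc_mean * rlnorm(n, 0, 1)
    nat_base <- pc_base * cfg$nat_to_pc_ratio * rlnorm(n, 0, 1)
    upc_base <- cfg$pc_mean * rlnorm(cfg$n_unpaired_pc, 0, 1)

    r_normal <- rep(cfg$baseline_r, n)
    r_tumor <- rep(cfg$baseline_r, n)
    planted_class <- rep(NA_character_, n)
    k <- 0L
    for (pd in cfg$planted_diffcor) {
      if (pd$count == 0) next
      idx <- k + seq_len(pd$count)
      r_normal[idx] <- pd$r_normal
      r_tumor[idx] <- pd$r_tumor
      planted_class[idx] <- pd$class
      k <- k + pd$count
    }
    shift_n <- cfg$planted_nat_shift[["count"]]
    shift_idx <- if (shift_n > 0) k + seq_len(shift_n) else integer(0)
    nat_fold_tumor <- rep(1, n)
    nat_fold_tumor[shift_idx] <- cfg$planted_nat_shift[["fold"]]

    infeasible <- abs(c(r_normal, r_tumor)) > 0.99
    if (any(infeasible)) {
      warn("target Spearman correlations above 0.99 clamped to 0.99")
      r_normal <- pmin(pmax(r_normal, -0.99), 0.99)
      r_tumor <- pmin(pmax(r_tumor, -0.99), 0.99)
    }

    patients <- sprintf("P%03d", seq_len(np))
    samples <- tibble(
      sample_id = c(paste0(patients, "_N"), paste0(patients, "_T")),
      patient_id = rep(patients, 2),
      condition = rep(c("normal", "tumor"), each = np)
    )
    lib <- setNames(rlnorm(2 * np, 0, 0.2), samples$sample_id)
    size <- 1 / cfg$nb_dispersion

    draw_condition <- function(r_target, nat_mean, cols) {
      rho <- copula_rho(r_target)
      z1 <- matrix(rnorm(n * np), n, np)
      e2 <- matrix(rnorm(n * np), n, np)
      z2 <- rho * z1 + sqrt(1 - rho^2) * e2
      mu_pc <- outer(pc_base, lib[cols])
      mu_nat <- outer(nat_mean, lib[cols])
      list(
        pc = matrix(qnbinom(pnorm(z1), size = size, mu = mu_pc), n, np),
        nat = matrix(qnbinom(pnorm(z2), size = size, mu = mu_nat), n, np)
      )
    }
    cols_n <- samples$sample_id[samples$condition == "normal"]
    cols_t <- samples$sample_id[samples$condition == "tumor"]
    dn <- draw_condition(r_normal, nat_base, cols_n)
    dt <- draw_condition(r_tumor, nat_base * nat_fold_tumor, cols_t)

    upc <- matrix(
      rnbinom(cfg$n_unpaired_pc * 2 * np, size = size,
              mu = outer(upc_base, lib)),
      cfg$n_unpaired_pc, 2 * np
    )
    counts <- rbind(
      cbind(dn$pc, dt$pc),
      cbind(dn$nat, dt$nat),
      upc
    )
    rownames(counts) <- c(truth$pc_gene_id, truth$nat_gene_id,
                          sprintf("SYNUPC%05d", seq_len(cfg$n_unpaired_pc)))
    colnames(counts) <- c(cols_n, cols_t)

    truth_out <- truth |>
      mutate(
        planted_diffcor = !is.na(planted_class),
        planted_class = planted_class,
        r_normal = r_normal, r_tumor = r_tumor,
        planted_shift = dplyr::row_number() %in% shift_idx
      )
    # survival-planted genes sit inside planted-deregulated pairs
    n_surv <- cfg$planted_survival[["count"]]
    planted_pool <- truth_out$pc_gene_id[truth_out$planted_diffcor |
                                           truth_out$planted_shift]
    if (n_surv > length(planted_pool)) {
      planted_pool <- c(planted_pool,
                        setdiff(truth_out$pc_gene_id, planted_pool))
    }
    survival_genes <- head(planted_pool, n_surv)

    list(
      x = paired_counts(counts, samples),
      truth = truth_out,
      survival_genes = survival_genes
    )
  })
}

#' Generate a synthetic survival cohort with planted gene effects
#'
#' Event times are exponential with log-hazard `log(hazard_ratio) * s_i`,
#' where `s_i` is a standard-normal patient risk score; planted genes'
#' (standardized log-) expression tracks `s_i` with independent N(0, 0.5^2)
#' noise, null genes are independent N(0, 1). Censoring times are independent
#' exponentials calibrated to the configured expected censoring rate.
#'
#' @param config A [synthetic_config()].
#' @param gene_ids Genes to simulate expression for.
#' @param planted_genes Subset of `gene_ids` linked to survival.
#' @param baseline_hazard Baseline event rate (default 0.1 per time unit).
#' @return A list: `surv` (tibble `patient_id`, `time`, `event`),
#'   `expression` (genes x patients matrix), `planted_genes`.
#' @export
generate_survival <- function(config, gene_ids, planted_genes = character(0),
                              baseline_hazard = 0.1) {
  stopifnot(all(planted_genes %in% gene_ids))
  np <- config$n_survival_patients
  hr <- config$planted_survival[["hazard_ratio"]]
  withr::with_seed(config$seed + 1L, {
    s <- rnorm(np)
    expr <- matrix(rnorm(length(gene_ids) * np), length(gene_ids), np,
                   dimnames = list(gene_ids, sprintf("S%04d", seq_len(np))))
    pl <- match(planted_genes, gene_ids)
    if (length(pl) > 0) {
      expr[pl, ] <- matrix(rep(s, each = length(pl)), length(pl), np) +
        matrix(rnorm(length(pl) * np, sd = 0.5), length(pl), np)
    }
    hazard <- baseline_hazard * exp(log(hr) * s)
    t_event <- rexp(np, rate = hazard)
    cr <- config$censoring_rate
    if (cr > 0) {
      t_cens <- rexp(np, rate = baseline_hazard * cr / (1 - cr))
    } else {
      t_cens <- rep(Inf, np)
    }
    surv <- tibble(
      patient_id = colnames(expr),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
    list(surv = surv, expression = expr, planted_genes = planted_genes)
  })
}

#' Write the synthetic cohort to disk in the formats the pipeline reads
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths (`gtf`, `counts`,
#'   `samples`, `truth`).
#' @export
write_synthetic_cohort <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- generate_annotation(config, file.path(dir, "annotation.gtf"))
  gen <- generate_counts(config, ann$truth)
  cts <- as_tibble(gen$x$counts, rownames = "gene_id")
  readr::write_tsv(cts, file.path(dir, "counts.tsv"))
  readr::write_tsv(gen$x$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(gen$truth, file.path(dir, "truth_pairs.tsv"))
  invisible(list(
    gtf = ann$gtf,
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth_pairs.tsv")
  ))
}
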