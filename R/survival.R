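#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at each distinct
#' event time the observed minus expected event count in group 1 is
#' accumulated with its hypergeometric variance; the statistic
#' `(sum O - sum E)^2 / sum V` is referred to a chi-square with 1 df.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = death, 0 = censored).
#' @param group Two-level group labels.
#' @return A tibble with columns `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    abort("log-rank test requires exactly two nonempty groups")
  }
  if (sum(event) == 0) abort("log-rank test requires at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble(chi2 = fit$chisq, df = 1L,
         p = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Screen genes for survival association by median-split log-rank test
#'
#' Each gene's patients are dichotomized at the median expression (values
#' equal to the median go to the high group) and the two groups compared with
#' the log-rank test. A gene is flagged associated when its p-value passes
#' `alpha` (`p <= alpha` by default, strict `<` with `strict = TRUE`).
#' Constant-expression genes cannot be split and are excluded from
#' denominators, with a count.
#'
#' @param surv Tibble with columns `patient_id`, `time` (> 0), `event` (0/1).
#' @param expression Numeric matrix, genes x patients; column names must
#'   match `surv$patient_id`.
#' @param genes Genes to screen; default all rows of `expression`.
#' @param alpha Association threshold on the log-rank p (default 0.05).
#' @param strict Use `p < alpha` instead of `p <= alpha`.
#' @return A tibble of class `natpairs_screen` with columns `gene_id`,
#'   `chi2`, `p`, `associated`, `excluded`.
#' @export
survival_screen <- function(surv, expression, genes = NULL, alpha = 0.05,
                            strict = FALSE) {
  if (any(surv$time <= 0)) abort("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) abort("event must be 0/1")
  if (nrow(surv) < 20) {
    warn("fewer than 20 patients: the log-rank screen will be underpowered")
  }
  genes <- genes %||% rownames(expression)
  miss <- setdiff(genes, rownames(expression))
  if (length(miss) > 0) {
    abort(paste0("gene(s) absent from expression matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  idx <- match(surv$patient_id, colnames(expression))
  if (anyNA(idx)) abort("every patient needs an expression column")
  ex <- expression[genes, idx, drop = FALSE]

  res <- purrr::map(genes, function(g) {
    v <- ex[g, ]
    med <- median(v)
    high <- v >= med
    if (all(high) || !any(high)) {
      return(tibble(gene_id = g, chi2 = NA_real_, p = NA_real_,
                    associated = NA, excluded = TRUE))
    }
    lr <- logrank_test(surv$time, surv$event,
                       factor(high, levels = c(FALSE, TRUE)))
    tibble(gene_id = g, chi2 = lr$chi2, p = lr$p,
           associated = if (strict) lr$p < alpha else lr$p <= alpha,
           excluded = FALSE)
  }) |> purrr::list_rbind()
  n_excl <- sum(res$excluded)
  if (n_excl > 0) {
    inform(paste0(n_excl, " constant-expression gene(s) excluded from the ",
                  "survival screen"))
  }
  class(res) <- c("natpairs_screen", class(res))
  res
}

#' Random-control distribution of survival-associated gene counts
#'
#' Draws `n_reps` random gene lists of size `list_size` (without replacement
#' within each draw) from a control universe and records, per draw, how many
#' and what percentage of the drawn genes are survival-associated in the
#' screen. The universe is sorted by gene ID before sampling so results are
#' reproducible given the seed.
#'
#' @param screen A `natpairs_screen` tibble from [survival_screen()].
#' @param universe Gene IDs eligible as controls (must be screened genes;
#'   typically excludes every gene selected by any of the three methods).
#' @param list_size Size of each random list.
#' @param n_reps Number of random draws (default 200).
#' @param seed Optional integer seed applied locally to the draws.
#' @return A one-row tibble: `mean_count`, `sd_count`, `mean_pct`, `sd_pct`,
#'   `ci_low_pct`, `ci_high_pct` (empirical 2.5/97.5 percent quantiles),
#'   `n_reps`, `list_size`, plus the per-draw counts in the `draws` attribute.
#' @export
control_distribution <- function(screen, universe, list_size, n_reps = 200,
                                 seed = NULL) {
  universe <- sort(unique(universe))
  scr <- filter(screen, !.data$excluded)
  universe <- intersect(universe, scr$gene_id)
  if (length(universe) < list_size) {
    abort("control universe is smaller than the requested list size")
  }
  assoc <- setNames(scr$associated, scr$gene_id)
  draw_counts <- withr::with_seed(
    seed %||% sample.int(.Machine$integer.max, 1),
    vapply(seq_len(n_reps), function(i) {
      sum(assoc[sample(universe, list_size)])
    }, numeric(1))
  )
  pct <- 100 * draw_counts / list_size
  out <- tibble(
    mean_count = mean(draw_counts), sd_count = stats::sd(draw_counts),
    mean_pct = mean(pct), sd_pct = stats::sd(pct),
    ci_low_pct = unname(stats::quantile(pct, 0.025, type = 7)),
    ci_high_pct = unname(stats::quantile(pct, 0.975, type = 7)),
    n_reps = n_reps, list_size = list_size
  )
  attr(out, "draws") <- draw_counts
  out
}

#' Chi-squared enrichment of a gene list against a control distribution
#'
#' Pearson chi-squared test (no continuity correction) on the 2x2 table of
#' associated / not-associated genes in the candidate list versus the rounded
#' mean associated count of the random-control distribution.
#'
#' @param n_assoc,n_total Associated and total gene counts of the candidate
#'   list.
#' @param control Control summary from [control_distribution()].
#' @return A tibble with columns `chi2`, `p`.
#' @export
enrichment_test <- function(n_assoc, n_total, control) {
  ctrl_assoc <- round(control$mean_count)
  tab <- rbind(
    c(n_assoc, n_total - n_assoc),
    c(ctrl_assoc, control$list_size - ctrl_assoc)
  )
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warn("chi-squared expected cell below 1; p-value may be unreliable")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Survival-enrichment report for selected gene lists
#'
#' For each named gene list, counts the screened genes associated with
#' survival and compares the fraction with one or more random-control
#' distributions, mirroring a list-by-control enrichment table.
#'
#' @param lists Named list of character vectors of protein-coding gene IDs.
#' @param screen A `natpairs_screen` tibble covering the lists and universes.
#' @param universes Named list of control-universe gene ID vectors (e.g.
#'   `with_antisense`, `without_antisense`).
#' @param n_reps Random draws per control distribution.
#' @param seed Integer seed for the control draws.
#' @return A tibble with one row per (list, universe): list size, number
#'   screened, number and percentage associated, control mean/sd/CI, and the
#'   chi-squared enrichment p-value.
#' @export
survival_enrichment <- function(lists, screen, universes, n_reps = 200,
                                seed = NULL) {
  stopifnot(length(names(lists)) == length(lists),
            length(names(universes)) == length(universes))
  scr <- filter(screen, !.data$excluded)
  rows <- list()
  for (ln in names(lists)) {
    gl <- unique(lists[[ln]])
    hit <- filter(scr, .data$gene_id %in% gl)
    n_assoc <- sum(hit$associated)
    for (un in names(universes)) {
      ctrl <- control_distribution(screen, universes[[un]],
                                   list_size = length(gl),
                                   n_reps = n_reps, seed = seed)
      et <- enrichment_test(n_assoc, nrow(hit), ctrl)
      rows[[paste(ln, un)]] <- tibble(
        list_name = ln, control = un,
        n_genes = length(gl), n_screened = nrow(hit),
        n_associated = n_assoc,
        pct_associated = 100 * n_assoc / nrow(hit),
        control_mean_pct = ctrl$mean_pct, control_sd_pct = ctrl$sd_pct,
        control_ci_low_pct = ctrl$ci_low_pct,
        control_ci_high_pct = ctrl$ci_high_pct,
        chi2 = et$chi2, chi2_p = et$p
      )
    }
  }
  bind_rows(rows)
}
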