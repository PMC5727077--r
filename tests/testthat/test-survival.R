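test_that("the log-rank statistic matches hand-tallied O/E/V sums", {
  # 6-patient toy, all events, two groups
  time <- 1:6; event <- rep(1, 6); grp <- rep(c("A", "B"), each = 3)
  got <- logrank_test(time, event, grp)
  want <- oracle_logrank(time, event, grp)
  expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)

  # identical curves built by duplicating patients across groups
  t2 <- c(1, 2, 3, 4, 1, 2, 3, 4); e2 <- rep(1, 8)
  g2 <- rep(c("A", "B"), each = 4)
  same <- logrank_test(t2, e2, g2)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # label swap leaves the squared statistic unchanged
  swap <- logrank_test(time, event, rev(grp))
  set.seed(30)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    tt <- sample(1:12, n, replace = TRUE)  # ties included
    ee <- rbinom(n, 1, 0.8)
    gg <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(gg)) < 2 || sum(ee) == 0) next
    got <- logrank_test(tt, ee, gg)
    want <- oracle_logrank(tt, ee, gg)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-8, info = paste(i))
    sw <- logrank_test(tt, ee, ifelse(gg == "A", "B", "A"))
    expect_equal(sw$chi2, got$chi2, tolerance = 1e-9)
  }
  expect_error(logrank_test(time, event, rep("A", 6)), "two nonempty")
  expect_error(logrank_test(time, rep(0, 6), grp), "at least one event")
})

test_that("the median-split screen finds planted hazards and excludes constants", {
  cfg <- synthetic_config(n_survival_patients = 200,
                          planted_survival = c(hazard_ratio = 3, count = 5),
                          seed = 31)
  genes <- sprintf("G%03d", 1:60)
  planted <- genes[1:5]
  sv <- generate_survival(cfg, genes, planted)
  expr <- sv$expression
  expr["G060", ] <- 1  # constant gene
  expect_message(scr <- survival_screen(sv$surv, expr), "constant")
  expect_true(all(scr$excluded[scr$gene_id == "G060"]))
  expect_false(any(scr$excluded[scr$gene_id != "G060"]))
  # planted 3x-hazard genes are detected
  expect_true(all(scr$associated[scr$gene_id %in% planted]))
  # null association rate stays near the nominal level
  null_rate <- mean(scr$associated[!scr$gene_id %in% c(planted, "G060")])
  expect_lt(null_rate, 0.2)
  # warning below 20 patients
  expect_warning(
    survival_screen(sv$surv[1:10, ], expr[1:3, 1:10, drop = FALSE]),
    "underpowered")
})

test_that("control distributions have hypergeometric behavior and are seed-stable", {
  # a universe where every gene is associated gives mean = list size, sd = 0
  scr <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:100),
    chi2 = 5, p = 0.01, associated = TRUE, excluded = FALSE
  )
  class(scr) <- c("natpairs_screen", class(scr))
  ctrl <- control_distribution(scr, scr$gene_id, list_size = 10,
                               n_reps = 50, seed = 1)
  expect_equal(ctrl$mean_count, 10)
  expect_equal(ctrl$sd_count, 0)

  # exactly 10% associated: mean and sd near the closed-form hypergeometric
  scr2 <- scr
  scr2$associated <- rep(c(TRUE, rep(FALSE, 9)), 10)
  ctrl2 <- control_distribution(scr2, scr2$gene_id, list_size = 40,
                                n_reps = 400, seed = 2)
  K <- 10; N <- 100; k <- 40
  hyper_mean <- k * K / N
  hyper_sd <- sqrt(k * (K / N) * (1 - K / N) * (N - k) / (N - 1))
  expect_equal(ctrl2$mean_count, hyper_mean, tolerance = 0.15)
  expect_equal(ctrl2$sd_count, hyper_sd, tolerance = 0.2)

  # fixed seed: bit-identical summaries
  again <- control_distribution(scr2, scr2$gene_id, list_size = 40,
                                n_reps = 400, seed = 2)
  expect_identical(ctrl2, again)
  expect_error(control_distribution(scr, scr$gene_id[1:5], list_size = 10),
               "smaller")
})

test_that("the chi-squared enrichment test matches the direct Pearson formula", {
  ctrl <- tibble::tibble(mean_count = 57, list_size = 582)
  got <- enrichment_test(71, 440, ctrl)
  want <- oracle_chisq_2x2(rbind(c(71, 369), c(57, 525)))
  expect_equal(got$chi2, want$chi2, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # equal fractions give a near-zero statistic
  ctrl0 <- tibble::tibble(mean_count = 44, list_size = 440)
  flat <- enrichment_test(44, 440, ctrl0)
  expect_lt(flat$chi2, 1e-10)
  expect_gt(flat$p, 0.999)
  # tiny expected cells warn but still report a p-value
  ctrl_small <- tibble::tibble(mean_count = 0, list_size = 5)
  expect_warning(small <- enrichment_test(1, 5, ctrl_small), "below 1")
  expect_true(is.finite(small$p))
})

test_that("a planted gene list is flagged enriched; random lists are not", {
  cfg <- synthetic_config(n_survival_patients = 200,
                          planted_survival = c(hazard_ratio = 3, count = 15),
                          seed = 33)
  genes <- sprintf("G%03d", 1:300)
  planted <- genes[1:15]
  sv <- generate_survival(cfg, genes, planted)
  scr <- survival_screen(sv$surv, sv$expression)
  rep_tab <- survival_enrichment(
    lists = list(planted = c(planted, genes[16:40]),
                 random = genes[101:150]),
    screen = scr,
    universes = list(null = genes[151:300]),
    n_reps = 100, seed = 3
  )
  p_planted <- rep_tab$chi2_p[rep_tab$list_name == "planted"]
  expect_lt(p_planted, 0.05)
  expect_gt(rep_tab$pct_associated[rep_tab$list_name == "planted"],
            rep_tab$control_ci_high_pct[rep_tab$list_name == "planted"])
  expect_gt(rep_tab$chi2_p[rep_tab$list_name == "random"], 0.01)
})
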