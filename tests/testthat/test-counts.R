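make_counts_tsv <- function(m) {
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(m, rownames = "gene_id"), f)
  f
}

test_that("paired count loading validates pairing and sample-sheet consistency", {
  m <- matrix(1:16, 4, 4,
              dimnames = list(paste0("G", 1:4),
                              c("P1_N", "P1_T", "P2_N", "P2_T")))
  sheet <- tibble::tibble(
    sample_id = colnames(m),
    patient_id = rep(c("P1", "P2"), each = 2),
    condition = rep(c("normal", "tumor"), 2)
  )
  fs <- tempfile(fileext = ".tsv"); readr::write_tsv(sheet, fs)
  x <- read_paired_counts(make_counts_tsv(m), fs)
  expect_s3_class(x, "paired_counts")
  expect_equal(n_patients(x), 2L)
  expect_equal(dim(x$counts), c(4L, 4L))

  # a patient with two tumor samples is dropped with a warning
  sheet2 <- sheet; sheet2$condition[3] <- "tumor"
  fs2 <- tempfile(fileext = ".tsv"); readr::write_tsv(sheet2, fs2)
  expect_warning(x2 <- read_paired_counts(make_counts_tsv(m), fs2),
                 "P2")
  expect_equal(n_patients(x2), 1L)

  # a counts column missing from the sheet is fatal and names the column
  fs3 <- tempfile(fileext = ".tsv"); readr::write_tsv(sheet[-4, ], fs3)
  expect_error(read_paired_counts(make_counts_tsv(m), fs3), "P2_T")

  # duplicate gene IDs are fatal
  mdup <- rbind(m, m[1, , drop = FALSE])
  expect_error(read_paired_counts(make_counts_tsv(mdup), fs), "duplicate")
})

test_that("median-of-ratios size factors match hand computation and DESeq2", {
  m <- matrix(c(10, 20, 40, 5, 100,
                10, 20, 40, 5, 100), 5, 2,
              dimnames = list(paste0("G", 1:5), c("P1_N", "P1_T")))
  x <- toy_counts(m, n_patients = 1)
  expect_equal(unname(compute_size_factors(x)$size_factors), c(1, 1))

  # column 2 = 2 x column 1: factors proportional to (1, 2)
  m2 <- m; m2[, 2] <- 2 * m[, 1]
  x2 <- compute_size_factors(toy_counts(m2, n_patients = 1))
  sf <- unname(x2$size_factors)
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(exp(mean(log(sf))), 1)  # unit geometric mean
  expect_equal(sf, c(1 / sqrt(2), sqrt(2)))  # hand computation

  # an all-zero gene is excluded from the reference set
  m3 <- rbind(m2, GZ = c(0, 0))
  x3 <- compute_size_factors(toy_counts(m3, n_patients = 1))
  expect_equal(unname(x3$size_factors), sf)

  # no common nonzero gene: fatal unless the fallback flag is set
  m4 <- matrix(c(5, 0, 0, 10), 2, 2,
               dimnames = list(c("A", "B"), c("P1_N", "P1_T")))
  expect_error(compute_size_factors(toy_counts(m4, n_patients = 1)),
               "fallback")
  x4 <- compute_size_factors(toy_counts(m4, n_patients = 1),
                             fallback_total_count = TRUE)
  expect_equal(unname(x4$size_factors), c(5, 10) / 7.5)

  # independent cross-check against DESeq2's estimator on a random matrix
  skip_if_not_installed("DESeq2")
  set.seed(11)
  mr <- matrix(rnbinom(300, mu = 50, size = 5) + 1, 30, 10)
  dimnames(mr) <- list(paste0("G", 1:30),
                       paste0("P", rep(1:5, 2), rep(c("_N", "_T"), each = 5)))
  xr <- compute_size_factors(toy_counts(mr, n_patients = 5))
  ref <- DESeq2::estimateSizeFactorsForMatrix(mr)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(xr$size_factors), unname(ref), tolerance = 1e-10)
})

test_that("size-factor ratios are equivariant to rescaling one sample", {
  set.seed(3)
  m <- matrix(rnbinom(200, mu = 100, size = 10) + 1, 20, 10)
  dimnames(m) <- list(paste0("G", 1:20),
                      paste0("P", rep(1:5, 2), rep(c("_N", "_T"), each = 5)))
  sf0 <- compute_size_factors(toy_counts(m, 5))$size_factors
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  sf1 <- compute_size_factors(toy_counts(m2, 5))$size_factors
  expect_equal(unname(sf1[3] / sf1[1]), unname(5 * sf0[3] / sf0[1]),
               tolerance = 1e-10)
})

test_that("category table satisfies its conservation laws and matches a per-pair loop", {
  cfg <- synthetic_config(n_pairs = 100, n_patients = 22, n_unpaired_pc = 0,
                          seed = 5)
  gen <- generate_counts(cfg)
  pairs <- gen$truth[, c("pc_gene_id", "nat_gene_id")]
  tab <- expression_category_table(pairs, gen$x, min_patients = 7)
  expect_equal(nrow(tab), 16L)
  expect_equal(sum(tab$n_pairs), nrow(pairs))
  # column sums are conserved over rows
  expect_equal(sum(tab$sum_pc_normal) + sum(tab$sum_pc_tumor) +
                 sum(tab$sum_nat_normal) + sum(tab$sum_nat_tumor),
               sum(gen$x$counts[c(pairs$pc_gene_id, pairs$nat_gene_id), ]))

  # per-pair loop oracle for the row assignment
  norm_s <- condition_samples(gen$x, "normal")
  tum_s <- condition_samples(gen$x, "tumor")
  loop_pattern <- vapply(seq_len(nrow(pairs)), function(i) {
    pcv <- gen$x$counts[pairs$pc_gene_id[i], ]
    natv <- gen$x$counts[pairs$nat_gene_id[i], ]
    paste(sum(pcv[norm_s] > 0) >= 7, sum(pcv[tum_s] > 0) >= 7,
          sum(natv[norm_s] > 0) >= 7, sum(natv[tum_s] > 0) >= 7)
  }, character(1))
  want <- table(loop_pattern)
  got <- setNames(tab$n_pairs,
                  paste(tab$pc_normal, tab$pc_tumor, tab$nat_normal,
                        tab$nat_tumor))
  expect_equal(got[names(want)], setNames(as.integer(want), names(want)))

  # filter consistency: all-yes row count equals the filtered pair count
  filt <- filter_expressed_pairs(pairs, gen$x, min_patients = 7)
  expect_equal(nrow(filt),
               tab$n_pairs[tab$pc_normal & tab$pc_tumor & tab$nat_normal &
                             tab$nat_tumor])
})

test_that("the at-least-7-patients filter is a sharp boundary", {
  np <- 22
  base <- matrix(5, 2, 2 * np)
  patients <- sprintf("P%02d", seq_len(np))
  colnames(base) <- c(paste0(patients, "_N"), paste0(patients, "_T"))
  rownames(base) <- c("PC1", "NAT1")
  pairs <- tibble::tibble(pc_gene_id = "PC1", nat_gene_id = "NAT1")
  # NAT expressed in only 6 tumor patients: excluded
  m6 <- base; m6["NAT1", paste0(patients, "_T")] <- c(rep(1, 6), rep(0, 16))
  x6 <- toy_counts(m6, np)
  expect_equal(nrow(filter_expressed_pairs(pairs, x6)), 0L)
  # 7 tumor patients: retained
  m7 <- base; m7["NAT1", paste0(patients, "_T")] <- c(rep(1, 7), rep(0, 15))
  x7 <- toy_counts(m7, np)
  expect_equal(nrow(filter_expressed_pairs(pairs, x7)), 1L)
  # empty pair set stays empty
  expect_equal(nrow(filter_expressed_pairs(pairs[0, ], x7)), 0L)
  # a pair gene absent from the matrix counts as unexpressed, with a notice
  pairs2 <- tibble::tibble(pc_gene_id = "PC1", nat_gene_id = "GHOST")
  expect_message(out <- filter_expressed_pairs(pairs2, x7), "absent")
  expect_equal(nrow(out), 0L)
})

test_that("global antisense/sense percentages follow the count sums", {
  np <- 4
  patients <- sprintf("P%02d", seq_len(np))
  m <- matrix(0, 2, 2 * np,
              dimnames = list(c("PC1", "NAT1"),
                              c(paste0(patients, "_N"),
                                paste0(patients, "_T"))))
  m["PC1", ] <- 100
  m["NAT1", paste0(patients, "_N")] <- 17
  m["NAT1", paste0(patients, "_T")] <- 26
  x <- toy_counts(m, np)
  pairs <- tibble::tibble(pc_gene_id = "PC1", nat_gene_id = "NAT1")
  expect_equal(global_nat_pc_ratio(pairs, x, "normal"), 17)
  expect_equal(global_nat_pc_ratio(pairs, x, "tumor"), 26)
  # all-zero NAT: 0 percent
  m0 <- m; m0["NAT1", ] <- 0
  expect_equal(global_nat_pc_ratio(pairs, toy_counts(m0, np), "normal"), 0)
  # zero PC total: undefined
  mz <- m; mz["PC1", ] <- 0
  expect_error(global_nat_pc_ratio(pairs, toy_counts(mz, np), "normal"),
               "zero")
  expect_error(global_nat_pc_ratio(pairs[0, ], x, "normal"), "no pairs")
})
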