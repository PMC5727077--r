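# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and the libraries standing behind them) so that agreement is a
# real cross-check, not a tautology.

# All-pairs O(n^2) check of the three pairing conditions on gene spans.
oracle_pairs <- function(genes, whitelist = nat_biotype_whitelist()) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      a <- genes[i, ]; b <- genes[j, ]
      if (a$biotype != "protein_coding") next
      if (!(b$biotype %in% whitelist)) next
      if (a$gene_id == b$gene_id) next
      if (a$chrom != b$chrom) next
      if (a$strand == b$strand) next
      ov <- min(a$end, b$end) - max(a$start, b$start) + 1
      if (ov < 1) next
      rows[[length(rows) + 1]] <- data.frame(
        pc_gene_id = a$gene_id, nat_gene_id = b$gene_id,
        overlap_bp = as.integer(ov), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pc_gene_id = character(), nat_gene_id = character(),
                      overlap_bp = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$pc_gene_id, out$nat_gene_id), , drop = FALSE]
}

# Random annotation of n genes over a few chromosomes for property tests.
random_annotation <- function(n, n_chrom = 3, max_pos = 5e4) {
  biotypes <- c("protein_coding", "antisense", "lincRNA", "pseudogene",
                "miRNA", "rRNA")
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(3000, n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    gene_name = sprintf("G%04d", seq_len(n)),
    chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(biotypes, n, replace = TRUE,
                     prob = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1))
  )
}

# Spearman via explicit ranks + textbook Pearson formula + t p-value.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# Benjamini-Hochberg by the literal step-up definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided signed-rank p by literal 2^n enumeration (n <= 12).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  pl <- mean(w_all <= w_obs + 1e-9)
  pu <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(pl, pu))
}

# Log-rank by a literal loop over distinct event times (O, E, V tallies).
oracle_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  stopifnot(all(group %in% c(1, 2)))
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d_tot * n1 / n_tot
    if (n_tot > 1) {
      V <- V + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Pearson chi-squared on a 2x2 table by the direct formula.
oracle_chisq_2x2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Hypergeometric enrichment p for planted-truth recovery checks.
oracle_hyper_p <- function(n_hit, list_size, n_planted, n_total) {
  stats::phyper(n_hit - 1, n_planted, n_total - n_planted, list_size,
                lower.tail = FALSE)
}

# Small well-formed paired cohort; the sheet is derived from column names of
# the form <patient>_N / <patient>_T.
toy_counts <- function(counts, ...) {
  cn <- colnames(counts)
  samples <- tibble::tibble(
    sample_id = cn,
    patient_id = sub("_[NT]$", "", cn),
    condition = ifelse(grepl("_T$", cn), "tumor", "normal")
  )
  paired_counts(counts, samples)
}

# Write a minimal Ensembl-dialect GTF from a genes tibble.
write_toy_gtf <- function(genes, path, biotype_key = "gene_biotype") {
  lines <- sprintf(
    "%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; %s \"%s\";",
    genes$chrom, genes$start, genes$end, genes$strand,
    genes$gene_id, genes$gene_name, biotype_key, genes$biotype
  )
  writeLines(lines, path)
  path
}
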