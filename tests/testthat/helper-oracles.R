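# Independent oracles used to check package computations by a second route.

# Two-tailed Fisher p by direct enumeration over all tables with the
# observed margins, point probabilities from log-binomial coefficients
# (independent of dhyper). Same 1e-7 relative tolerance on the
# point-probability comparison as the implementation under test.
oracle_fisher <- function(a, b, cc, d) {
  K <- a + cc; M <- b + d; n_in <- a + b; N <- K + M
  if (N == 0 || n_in == 0 || n_in == N) return(1)
  ks <- max(0, n_in - M):min(n_in, K)
  pr <- exp(lchoose(K, ks) + lchoose(M, n_in - ks) - lchoose(N, n_in))
  sum(pr[pr <= pr[ks == a] * (1 + 1e-7)])
}

# Raw TMM scaling factor of sample y against reference yr by direct
# evaluation of the trimmed, precision-weighted mean of M-values
# (30% log-ratio trim, 5% intensity trim).
oracle_tmm_factor <- function(y, yr, logratioTrim = 0.3, sumTrim = 0.05) {
  N <- sum(y); Nr <- sum(yr)
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  M <- log2((y / N) / (yr / Nr))
  A <- 0.5 * log2((y / N) * (yr / Nr))
  w <- (N - y) / (N * y) + (Nr - yr) / (Nr * yr)
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# Two-sided rank-sum p by exhaustive enumeration of all group labellings.
oracle_ranksum <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  mu <- na * (length(pooled) + 1) / 2
  W_obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  Ws <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Closed-form OLS on a small design matrix (solve of the normal equations).
oracle_ols_beta <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# One full planted-signal replicate: simulate genome + expression, call
# DEGs through the package pipeline, return enrichment profiles and truth.
recovery_replicate <- function(theta, seed, n_genes = 5000, n_samples = 200,
                               n_chrom = 4, chrom_length = 6e7,
                               degs_from = c("fit", "truth")) {
  degs_from <- match.arg(degs_from)
  truth <- synthetic_truth(theta = theta, seed = seed)
  sim <- simulate_genome(n_chrom, chrom_length, n_genes, truth)
  expr <- simulate_expression(sim$genes, sim$chrom_map, n_samples, truth)
  degs <- if (degs_from == "fit") {
    fit <- fit_age_degs(expr$counts, expr$meta)
    fit$table
  } else {
    data.frame(gene_id = expr$labels$gene_id,
               direction = expr$labels$direction)
  }
  bins <- assign_bins(sim$genes, sim$chrom_map)
  list(profile = enrichment_profile(degs, bins, n_bins = 10),
       centromere = centromere_control(degs, sim$genes, sim$chrom_map,
                                       n_bins = 10),
       degs = degs, labels = expr$labels, genes = sim$genes,
       chrom_map = sim$chrom_map)
}

# Tiny GTF / BED / BEDPE writers for parser tests.
write_tmp_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}
gtf_gene_line <- function(chrom, start, end, strand, id,
                          type = "protein_coding") {
  sprintf('%s\tsrc\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
          chrom, start, end, strand, id, type)
}
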