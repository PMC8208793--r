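#' Remove genes with low average read count
#'
#' Genes whose mean raw count across all samples is strictly below
#' `min_mean` are removed; a gene at exactly the threshold is kept.
#'
#' @param counts gene-by-sample matrix of raw counts (rownames = gene ids).
#' @param min_mean minimum mean count (default 1).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_mean = 1) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  keep <- rowMeans(counts) >= min_mean
  if (!any(keep))
    stop("no genes retained at mean count >= ", min_mean)
  counts[keep, , drop = FALSE]
}

#' TMM normalization to counts per million
#'
#' Between-sample scaling by the trimmed mean of M-values (30% trim on
#' log-ratios, 5% trim on absolute log-intensity, precision-weighted,
#' factors rescaled to geometric mean 1), computed by edgeR; the reference
#' sample defaults to the one whose count upper quartile is closest to the
#' mean upper quartile. Normalized values are counts per million on the
#' effective library size `library_size * factor`.
#'
#' @param counts gene-by-sample matrix of raw counts.
#' @param reference column name or index of the reference sample, or `NULL`
#'   for edgeR's upper-quartile default.
#' @return list with elements `cpm` (normalized matrix), `factors` (named
#'   per-sample scaling factors, geometric mean 1) and `lib_size`.
#' @export
tmm_normalize <- function(counts, reference = NULL) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  ref <- if (is.null(reference)) NULL
  else if (is.character(reference)) match(reference, colnames(counts))
  else as.integer(reference)
  d <- edgeR::DGEList(counts = counts)
  d <- edgeR::calcNormFactors(d, method = "TMM", refColumn = ref)
  f <- d$samples$norm.factors
  names(f) <- colnames(counts)
  list(cpm = edgeR::cpm(d, normalized.lib.sizes = TRUE),
       factors = f,
       lib_size = lib)
}

#' Per-gene linear model of expression on age
#'
#' Ordinary least squares of `log2(normalized expression + 1)` on age plus
#' covariate indicators; the reported p-value is the two-tailed t-test on
#' the age coefficient. Genes with constant expression are flagged
#' degenerate and given `beta_age = 0`, `p = 1`.
#'
#' @param y numeric vector of log2 normalized expression, one per sample.
#' @param age numeric vector of ages in years.
#' @param covariates optional `data.frame` of per-sample covariates (e.g.
#'   sex, tissue), entered as factors.
#' @return named numeric vector `c(beta_age, se, p_raw)`.
#' @export
fit_age_model <- function(y, age, covariates = NULL) {
  X <- age_design(age, covariates, n = length(y))
  drop(fit_age_models(matrix(y, nrow = 1,
                             dimnames = list("gene", NULL)), X))
}

# Design matrix for the age model; errors on constant age.
age_design <- function(age, covariates = NULL, n = length(age)) {
  if (length(age) != n) stop("age length does not match sample count")
  if (length(unique(age)) < 2) stop("age is constant across samples")
  dat <- data.frame(age = age)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (!is.numeric(v)) v <- factor(v)
      if (is.factor(v) && nlevels(droplevels(v)) < 2) next  # no contrast
      dat[[nm]] <- v
    }
  }
  stats::model.matrix(~ ., data = dat)
}

#' Fit the age model to every gene of a matrix
#'
#' Vectorized OLS over genes sharing one design matrix: a QR decomposition
#' of the design is reused for all genes, so fitting thousands of genes is
#' a single set of matrix operations.
#'
#' @param logexpr gene-by-sample matrix of log2 normalized expression.
#' @param design design matrix from [age_design] (must contain an `age`
#'   column).
#' @return matrix with one row per gene and columns `beta_age`, `se`,
#'   `p_raw`.
#' @keywords internal
fit_age_models <- function(logexpr, design) {
  stopifnot(is.matrix(logexpr), ncol(logexpr) == nrow(design),
            "age" %in% colnames(design))
  n <- nrow(design)
  p <- ncol(design)
  if (n < p + 2)
    stop("need at least ", p + 2, " samples to fit ", p, " parameters")
  qrX <- qr(design)
  Y <- t(logexpr)                              # samples x genes
  coefs <- qr.coef(qrX, Y)                     # p x genes
  res <- qr.resid(qrX, Y)
  df <- n - p
  sigma2 <- colSums(res^2) / df
  XtXinv_aa <- chol2inv(qr.R(qrX))[match("age", colnames(design)),
                                   match("age", colnames(design))]
  beta <- coefs["age", ]
  se <- sqrt(sigma2 * XtXinv_aa)
  tstat <- beta / se
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- sigma2 < .Machine$double.eps & abs(beta) < 1e-12
  beta[degenerate] <- 0
  p_raw[degenerate] <- 1
  se[degenerate] <- NA_real_
  out <- cbind(beta_age = beta, se = se, p_raw = p_raw)
  rownames(out) <- rownames(logexpr)
  out
}

#' Call differentially expressed genes with Bonferroni correction
#'
#' `p_adj = min(1, p_raw * m)` over the `m` tested genes; a gene is called
#' `up` when `p_adj < alpha` and its age coefficient is positive, `down`
#' when negative, `none` otherwise.
#'
#' @param fits matrix or data.frame with columns `beta_age`, `se`, `p_raw`
#'   and gene ids as rownames (as returned by [fit_age_models]).
#' @param alpha corrected-p threshold (default 0.001).
#' @return `data.frame` with columns `gene_id`, `beta_age`, `se`, `p_raw`,
#'   `p_adj`, `direction`.
#' @export
call_degs <- function(fits, alpha = 0.001) {
  stopifnot(alpha > 0, alpha < 1)
  fits <- as.data.frame(fits)
  if (nrow(fits) < 1) stop("no tested genes")
  p_adj <- stats::p.adjust(fits$p_raw, method = "bonferroni")
  direction <- rep("none", nrow(fits))
  direction[p_adj < alpha & fits$beta_age > 0] <- "up"
  direction[p_adj < alpha & fits$beta_age < 0] <- "down"
  data.frame(
    gene_id = rownames(fits),
    beta_age = fits$beta_age,
    se = fits$se,
    p_raw = fits$p_raw,
    p_adj = p_adj,
    direction = direction,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Identify age-related DEGs from a raw count matrix
#'
#' The full differential-expression stage in one call: low-count filtering
#' (mean raw count below `min_mean` removed), TMM normalization to CPM,
#' `log2(CPM + 1)` transform, per-gene OLS on age with the requested
#' covariates, and Bonferroni-corrected DEG calls at `alpha`.
#'
#' @param counts gene-by-sample raw count matrix.
#' @param meta `data.frame` with one row per sample (matched to columns of
#'   `counts` by `sample_id`) and columns `sample_id`, `age` plus any
#'   covariates.
#' @param covariates character vector of metadata columns to adjust for
#'   (default `"sex"`; use `c("sex", "tissue")` for a pooled multi-tissue
#'   fit, which treats repeated subjects as independent).
#' @param min_mean low-count filter threshold (default 1).
#' @param alpha corrected-p DEG threshold (default 0.001).
#' @return An object of class `"deg_fit"`: a list with `table` (the
#'   [call_degs] data.frame), `n_genes_in`, `n_genes_tested`, `n_samples`,
#'   `covariates`, `alpha`, `tmm_factors` and `logcpm` (the transformed
#'   matrix used for fitting).
#' @examples
#' truth <- synthetic_truth(theta = 4, seed = 7)
#' sim <- simulate_genome(n_chrom = 2, chrom_length = 3e7, n_genes = 300,
#'                        truth = truth)
#' expr <- simulate_expression(sim$genes, sim$chrom_map, n_samples = 60,
#'                             truth = truth)
#' fit <- fit_age_degs(expr$counts, expr$meta)
#' fit
#' @export
fit_age_degs <- function(counts, meta, covariates = "sex",
                         min_mean = 1, alpha = 0.001) {
  stopifnot(is.matrix(counts))
  if (!all(c("sample_id", "age") %in% names(meta)))
    stop("meta must have 'sample_id' and 'age' columns")
  idx <- match(colnames(counts), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  meta <- meta[idx, , drop = FALSE]
  if (any(meta$age < 0 | meta$age > 120)) stop("ages must lie in [0, 120]")
  n_in <- nrow(counts)
  counts <- filter_low_expression(counts, min_mean)
  norm <- tmm_normalize(counts)
  logcpm <- log2(norm$cpm + 1)
  missing_cov <- setdiff(covariates, names(meta))
  if (length(missing_cov))
    stop("covariate(s) not in metadata: ", paste(missing_cov, collapse = ", "))
  X <- age_design(meta$age, meta[, covariates, drop = FALSE])
  fits <- fit_age_models(logcpm, X)
  tab <- call_degs(fits, alpha)
  structure(list(
    table = tab,
    n_genes_in = n_in,
    n_genes_tested = nrow(tab),
    n_samples = ncol(counts),
    covariates = covariates,
    alpha = alpha,
    tmm_factors = norm$factors,
    logcpm = logcpm
  ), class = "deg_fit")
}

#' @export
print.deg_fit <- function(x, ...) {
  nup <- sum(x$table$direction == "up")
  ndn <- sum(x$table$direction == "down")
  cat("Age-related differential expression fit\n")
  cat("  genes: ", x$n_genes_tested, " tested (", x$n_genes_in,
      " before low-count filter), samples: ", x$n_samples, "\n", sep = "")
  cat("  model: log2(CPM + 1) ~ age",
      if (length(x$covariates)) paste(" +", paste(x$covariates, collapse = " + ")),
      "\n", sep = "")
  cat("  DEGs at Bonferroni p < ", x$alpha, ": ", nup + ndn,
      " (", nup, " up, ", ndn, " down)\n", sep = "")
  invisible(x)
}

#' @export
summary.deg_fit <- function(object, ...) {
  tab <- object$table
  deg <- tab[tab$direction != "none", , drop = FALSE]
  out <- list(
    n_tested = nrow(tab),
    n_up = sum(tab$direction == "up"),
    n_down = sum(tab$direction == "down"),
    alpha = object$alpha,
    beta_range = range(deg$beta_age),
    top = utils::head(deg[order(deg$p_adj), ], 10)
  )
  class(out) <- "summary.deg_fit"
  out
}

#' @export
print.summary.deg_fit <- function(x, ...) {
  cat(x$n_up + x$n_down, "DEGs of", x$n_tested, "tested genes at Bonferroni p <",
      x$alpha, "\n")
  cat("  up:", x$n_up, " down:", x$n_down, "\n")
  if (x$n_up + x$n_down > 0) {
    cat("  age-coefficient range among DEGs: [",
        signif(x$beta_range[1], 3), ", ", signif(x$beta_range[2], 3),
        "] log2 units/year\n", sep = "")
    cat("  strongest calls:\n")
    print(x$top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.deg_fit <- function(object, ...) {
  stats::setNames(object$table$beta_age, object$table$gene_id)
}

#' Pearson correlation between gene expression and age
#'
#' @param y numeric vector of (log) expression values, one per sample.
#' @param age numeric vector of ages.
#' @return the Pearson correlation coefficient.
#' @export
age_correlation <- function(y, age) {
  if (length(y) != length(age)) stop("expression and age lengths differ")
  if (length(y) < 3) stop("need at least 3 samples")
  if (stats::sd(y) == 0 || stats::sd(age) == 0)
    stop("correlation undefined: constant vector")
  stats::cor(y, age)
}

#' Two-tailed Wilcoxon rank-sum comparison
#'
#' Exact by full enumeration of all group labellings when the total sample
#' is small (n <= 12; midranks for ties, two-sided by the symmetric
#' deviation of the rank sum from its null mean); for larger samples the
#' normal approximation with midrank tie correction (stats::wilcox.test).
#' Completely tied inputs (zero rank variance) return p = 1.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return two-tailed p-value.
#' @export
ranksum_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  if (stats::var(r) == 0) return(1)
  if (n <= 12) {
    na <- length(a)
    mu <- na * (n + 1) / 2
    dev_obs <- abs(sum(r[seq_len(na)]) - mu)
    sets <- utils::combn(n, na)
    devs <- abs(colSums(matrix(r[sets], nrow = na)) - mu)
    return(mean(devs >= dev_obs - 1e-9))
  }
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                       correct = FALSE))
  unname(res$p.value)
}

#' Read a counts TSV (first column gene_id, one column per sample)
#' @param path path to the TSV.
#' @return gene-by-sample numeric matrix with rownames.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  storage.mode(m) <- "numeric"
  m
}

#' Write a counts matrix as TSV
#' @param counts gene-by-sample matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV (sample_id, subject_id, tissue, sex, age)
#' @param path path to the TSV.
#' @return `data.frame` of sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age")
  if (!all(need %in% names(meta)))
    stop("metadata must have at least columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in ", path)
  meta
}
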