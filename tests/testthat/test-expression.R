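test_that("low-expression filter removes genes with mean count below 1", {
  m <- rbind(a = c(0, 0, 1), b = c(1, 1, 1), c = c(10, 10, 10))
  out <- filter_low_expression(m, 1)
  expect_equal(rownames(out), c("b", "c"))    # mean exactly 1 is retained
  big <- rbind(matrix(0, 100, 3,
                      dimnames = list(paste0("z", 1:100), NULL)),
               matrix(10, 5, 3, dimnames = list(paste0("k", 1:5), NULL)))
  expect_equal(nrow(filter_low_expression(big, 1)), 5)
  expect_error(filter_low_expression(m, 100), "no genes retained")
})

test_that("TMM factors are unity for identical or rescaled samples", {
  set.seed(21)
  y <- matrix(rpois(2000, 50), ncol = 2,
              dimnames = list(paste0("g", 1:1000), c("A", "B")))
  y[, 2] <- y[, 1]
  expect_equal(unname(tmm_normalize(y)$factors), c(1, 1), tolerance = 1e-12)
  y2 <- cbind(A = y[, 1], B = 2L * y[, 1])
  expect_equal(unname(tmm_normalize(y2)$factors), c(1, 1), tolerance = 1e-12)
  y0 <- cbind(A = y[, 1], B = 0L * y[, 1])
  expect_error(tmm_normalize(y0), "zero library")
})

test_that("TMM matches a brute-force trimmed weighted-mean oracle", {
  set.seed(22)
  base <- rpois(1000, 60)
  b <- base
  up <- sample(1000, 50)                      # 5% of genes 4-fold up in B
  b[up] <- b[up] * 4L
  m <- cbind(A = base, B = b)
  rownames(m) <- paste0("g", 1:1000)
  norm <- tmm_normalize(m, reference = "A")
  raw_f <- oracle_tmm_factor(m[, "B"], m[, "A"])
  expected <- c(1, raw_f) / exp(mean(log(c(1, raw_f))))
  expect_equal(unname(norm$factors), expected, tolerance = 0.02)
  # factors always have geometric mean 1
  expect_equal(exp(mean(log(norm$factors))), 1, tolerance = 1e-12)
  # normalized values are CPM on the effective library size
  expect_equal(norm$cpm[1, "A"],
               m[1, "A"] / (sum(m[, "A"]) * norm$factors[["A"]]) * 1e6)
})

test_that("the age model recovers an exact linear trend", {
  age <- seq(20, 65, length.out = 10)
  y <- 0.1 * age + 5
  fit <- fit_age_model(y, age)
  expect_equal(fit[["beta_age"]], 0.1, tolerance = 1e-10)
  expect_lt(fit[["p_raw"]], 1e-12)
  # location invariance
  fit2 <- fit_age_model(y + 100, age)
  expect_equal(fit2[["beta_age"]], fit[["beta_age"]], tolerance = 1e-10)
  expect_error(fit_age_model(y, rep(50, 10)), "constant")
  # constant expression is a flagged degenerate fit
  fit3 <- fit_age_model(rep(2, 10), age)
  expect_equal(fit3[["beta_age"]], 0)
  expect_equal(fit3[["p_raw"]], 1)
})

test_that("age-model p-values are calibrated under the null", {
  set.seed(23)
  n <- 40
  age <- runif(n, 20, 79)
  sex <- rep(c("male", "female"), n / 2)
  Y <- matrix(rnorm(1000 * n), nrow = 1000,
              dimnames = list(paste0("g", 1:1000), NULL))
  X <- subtelomeR:::age_design(age, data.frame(sex = sex))
  fits <- subtelomeR:::fit_age_models(Y, X)
  frac <- mean(fits[, "p_raw"] < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("a sex confound is removed by the covariate", {
  set.seed(24)
  n <- 60
  sex <- rep(c("male", "female"), each = n / 2)
  age <- ifelse(sex == "female", runif(n, 50, 79), runif(n, 20, 49))
  y <- 2 * (sex == "female") + rnorm(n, sd = 0.05)   # no true age effect
  with_cov <- fit_age_model(y, age, data.frame(sex = sex))
  without <- fit_age_model(y, age)
  expect_lt(abs(with_cov[["beta_age"]]), 0.005)
  expect_gt(abs(without[["beta_age"]]), 0.02)
  # closed-form OLS oracle agrees on both designs
  X1 <- cbind(1, age, sex == "male")
  X0 <- cbind(1, age)
  expect_equal(unname(with_cov[["beta_age"]]),
               unname(oracle_ols_beta(X1, y)[2]), tolerance = 1e-8)
  expect_equal(unname(without[["beta_age"]]),
               unname(oracle_ols_beta(X0, y)[2]), tolerance = 1e-8)
})

test_that("Bonferroni DEG calling applies threshold, cap and direction", {
  fits <- data.frame(beta_age = c(0.1, 0.1, -0.2),
                     se = 0.01, p_raw = c(1e-7, 5e-6, 0.9),
                     row.names = c("a", "b", "c"))
  m <- 1000
  fits_m <- fits[rep(1:3, length.out = m), ]
  rownames(fits_m) <- paste0("g", 1:m)
  out <- call_degs(fits_m, alpha = 0.001)
  expect_equal(out$p_adj[1], 1e-4)
  expect_equal(out$direction[1], "up")
  expect_equal(out$p_adj[2], 5e-3)
  expect_equal(out$direction[2], "none")
  expect_equal(out$p_adj[3], 1)               # capped at 1
  expect_true(all(out$p_adj >= out$p_raw))
  # monotone in alpha: fewer DEGs at stricter threshold
  strict <- call_degs(fits_m, alpha = 1e-5)
  expect_lte(sum(strict$direction != "none"), sum(out$direction != "none"))
  # direction consistent with the sign of the age coefficient
  deg <- out[out$direction != "none", ]
  expect_true(all((deg$direction == "up") == (deg$beta_age > 0)))
})

test_that("gene-age correlation matches the Pearson formula", {
  expect_equal(age_correlation(20:40, 20:40), 1)
  expect_equal(age_correlation(-(20:40), 20:40), -1)
  r <- age_correlation(c(1, 2, 4), c(20, 40, 60))
  expect_equal(r, 30 / (20 * sqrt(7 / 3)), tolerance = 1e-12)
  expect_equal(r, 0.98198, tolerance = 1e-4)
  expect_error(age_correlation(c(1, 1, 1), c(20, 40, 60)), "constant")
  expect_error(age_correlation(1:2, c(20, 40)), "at least 3")
})

test_that("rank-sum comparison is exact for small tie-free groups", {
  expect_equal(ranksum_compare(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(ranksum_compare(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_lt(ranksum_compare(1:20, 1:20 + 1000), 1e-6)
  # enumeration oracle on random small tie-free cases
  set.seed(25)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(1000, na + nb)
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(ranksum_compare(a, b), oracle_ranksum(a, b),
                 tolerance = 1e-9)
  }
  expect_error(ranksum_compare(numeric(), 1:3), "non-empty")
})

test_that("count and metadata TSV round-trips preserve the matrix", {
  m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  f <- tempfile(fileext = ".tsv")
  write_counts(m, f)
  expect_equal(read_counts(f), m + 0)
  meta <- data.frame(sample_id = c("s1", "s2"), subject_id = c("p1", "p2"),
                     tissue = "t", sex = c("male", "female"),
                     age = c(30, 60))
  fm <- tempfile(fileext = ".tsv")
  utils::write.table(meta, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_sample_meta(fm), meta)
})
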