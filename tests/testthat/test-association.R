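toy_geno <- function(g, chrom = NULL, pos = NULL) {
  m <- ncol(g)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_data(g, chrom, pos)
}

test_that("markers violating missing-rate or MAF thresholds are dropped", {
  set.seed(1)
  n <- 20
  g <- matrix(rbinom(n * 10, 2, 0.5), n, 10)
  g[1:5, 1] <- NA                      # 25% missing  -> dropped
  g[, 2] <- 0L                         # MAF 0        -> dropped
  g[, 3] <- c(1L, rep(0L, n - 1))      # MAF 0.025    -> dropped
  g[1:4, 4] <- NA                      # 20% missing  -> kept (not > 0.20)
  geno <- toy_geno(g)
  out <- filter_genotypes(geno)
  expect_equal(ncol(out$matrix), 7)
  expect_false(any(c("chr1_1000", "chr1_2000", "chr1_3000") %in% out$map$id))
  expect_true("chr1_4000" %in% out$map$id)
  expect_equal(unname(attr(out, "dropped")["missing"]), 1L)
  expect_equal(unname(attr(out, "dropped")["maf"]), 2L)
  expect_error(filter_genotypes(geno, max_missing = 0, min_maf = 0.6),
               class = "empty_panel_error")
})

test_that("structure covariates behave at the edges", {
  set.seed(2)
  g <- matrix(rbinom(200, 2, 0.5), 10, 20)
  g[2, ] <- g[1, ]                     # duplicate samples
  geno <- toy_geno(g)
  pcs <- structure_covariates(geno, n_pcs = 2)
  expect_equal(pcs[1, ], pcs[2, ], tolerance = 1e-10)
  only_int <- structure_covariates(geno, n_pcs = 0)
  expect_equal(ncol(only_int), 1)
  expect_true(all(only_int == 1))
  expect_error(structure_covariates(geno, n_pcs = 10), class = "dimension_error")
})

test_that("kinship has VanRaden structure: symmetry, twins, vanishing off-diagonals", {
  set.seed(3)
  g <- matrix(rbinom(30 * 500, 2, 0.5), 30, 500)
  g <- rbind(g, g[1, ])                # duplicated individual
  geno <- toy_geno(g)
  K <- kinship(geno)
  expect_identical(K, t(K))
  expect_equal(K[1, 31], K[1, 1], tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # unrelated equal-frequency markers: off-diagonals shrink with marker count
  set.seed(4)
  big <- matrix(rbinom(100 * 20000, 2, 0.5), 100, 20000)
  K2 <- kinship(toy_geno(big))
  off <- K2[upper.tri(K2)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("with identity kinship the scan reduces to per-marker OLS", {
  set.seed(5)
  n <- 30; m <- 15
  g <- matrix(rbinom(n * m, 2, 0.4), n, m)
  geno <- toy_geno(g)
  y <- rnorm(n) + 0.6 * g[, 4]
  res <- mlm_scan(setNames(y, geno$samples), geno, K = diag(n))
  p_ols <- vapply(seq_len(m), function(j) {
    f <- summary(lm(y ~ g[, j]))$fstatistic
    pf(f[1], f[2], f[3], lower.tail = FALSE)
  }, numeric(1))
  expect_equal(res$result$p, unname(p_ols), tolerance = 1e-8)
})

test_that("the scan matches a brute-force GLS grid oracle on a small panel", {
  set.seed(6)
  n <- 6
  g <- matrix(c(0, 1, 2, 0, 1, 2,
                2, 2, 1, 1, 0, 0), n, 2)
  geno <- toy_geno(g)
  Z <- matrix(rnorm(n * 4), n, 4)
  K <- tcrossprod(Z) / 4 + diag(0.5, n)
  K <- K / mean(diag(K))
  y <- c(1.2, 0.3, -0.5, 2.0, 0.7, -1.1)
  res <- mlm_scan(setNames(y, geno$samples), geno, K = K)
  for (j in 1:2) {
    X <- cbind(1, g[, j])
    oracle <- reml_gls_oracle(y, X, K)
    expect_equal(res$result$beta[j], oracle$beta, tolerance = 1e-4)
    expect_equal(res$result$p[j], oracle$p, tolerance = 1e-4)
  }
})

test_that("p-values are invariant to a consistent sample permutation", {
  set.seed(7)
  n <- 40; m <- 25
  cfg <- sim_config(n_samples = n, n_snps = m, n_chromosomes = 2,
                    missing_rate = 0, seed = 3)
  sim <- simulate_genotypes(cfg)
  tr <- simulate_traits(sim$geno, sim$truth, cfg)
  K <- kinship(sim$geno)
  y <- setNames(tr$chalk, tr$sample_id)
  r1 <- mlm_scan(y, sim$geno, K = K)
  perm <- sample.int(n)
  geno2 <- genotype_data(sim$geno$matrix[perm, ], sim$geno$map$chrom,
                         sim$geno$map$pos, sim$geno$map$id,
                         sim$geno$samples[perm])
  r2 <- mlm_scan(y, geno2, K = K[perm, perm])
  expect_equal(r1$result$p, r2$result$p, tolerance = 1e-6)
})

test_that("misaligned sample ids and asymmetric kinship are rejected", {
  set.seed(8)
  g <- matrix(rbinom(40, 2, 0.5), 10, 4)
  geno <- toy_geno(g)
  y <- setNames(rnorm(9), geno$samples[1:9])
  expect_error(mlm_scan(y, geno), class = "alignment_error")
  y10 <- setNames(rnorm(10), geno$samples)
  Kbad <- matrix(runif(100), 10, 10)
  expect_error(mlm_scan(y10, geno, K = Kbad), class = "kinship_error")
})

test_that("bran filtering keeps only non-pigmented samples in the scan", {
  set.seed(9)
  n <- 30
  g <- matrix(rbinom(n * 8, 2, 0.5), n, 8)
  geno <- toy_geno(g)
  y <- setNames(rnorm(n), geno$samples)
  bran <- rep(c("white", "red", "brown"), length.out = n)
  res <- mlm_scan(y, geno, bran = bran)
  expect_equal(res$n, sum(bran != "red"))
})

test_that("q-values reproduce the Benjamini-Hochberg closed form", {
  out <- fdr_threshold(c(0.01, 0.02, 0.03, 0.04), pi0_method = "one")
  expect_equal(out$q, rep(0.04, 4))
  all1 <- fdr_threshold(rep(1, 5), pi0_method = "one")
  expect_equal(all1$q, rep(1, 5))
  expect_equal(fdr_threshold(c(0.01, 0.04), pi0_method = "one")$q,
               p.adjust(c(0.01, 0.04), "BH"))
  expect_error(fdr_threshold(numeric(0)), class = "config_error")
  expect_error(fdr_threshold(c(0.5, 0)), class = "config_error")
})

test_that("q-values are monotone in p and pi0 stays in (0, 1]", {
  set.seed(10)
  p <- runif(10000)
  out <- fdr_threshold(p)
  ord <- order(p)
  expect_false(is.unsorted(out$q[ord]))
  expect_gt(out$pi0, 0)
  expect_lte(out$pi0, 1)
  expect_equal(sum(out$significant), sum(p <= 1e-6))
})

test_that("manhattan coordinates accumulate chromosome offsets", {
  df <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   pos = c(10L, 100L, 40L),
                   p = c(0.5, 0.01, 0.2),
                   id = c("a", "b", "c"))
  mq <- manhattan_qq_data(df)
  expect_equal(mq$manhattan$cum_pos, c(10, 100, 140))
  single <- manhattan_qq_data(data.frame(chrom = "chr1", pos = 5L, p = 0.3,
                                         id = "x"))
  expect_equal(single$qq$expected, -log10(0.5))
})

test_that("uniform p-values give genomic inflation near one", {
  set.seed(11)
  df <- data.frame(chrom = "chr1", pos = seq_len(10000),
                   p = runif(10000), id = as.character(seq_len(10000)))
  mq <- manhattan_qq_data(df)
  expect_equal(mq$lambda_gc, 1, tolerance = 0.05)
})

test_that("a vanishing polygenic component converges to ordinary least squares", {
  set.seed(12)
  n <- 25; m <- 10
  g <- matrix(rbinom(n * m, 2, 0.5), n, m)
  geno <- toy_geno(g)
  y <- rnorm(n)                      # no polygenic signal at all
  res <- mlm_scan(setNames(y, geno$samples), geno, K = diag(n) * 1e-6 + diag(n) * 0)
  # K ~ 0: delta is driven large and the fit matches OLS
  p_ols <- vapply(seq_len(m), function(j) {
    f <- summary(lm(y ~ g[, j]))$fstatistic
    pf(f[1], f[2], f[3], lower.tail = FALSE)
  }, numeric(1))
  expect_equal(res$result$p, unname(p_ols), tolerance = 1e-4)
})
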