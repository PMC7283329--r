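# Genotype QC, population-structure covariates, VanRaden kinship, per-marker
# REML mixed-linear-model scan, and FDR control.

#' Filter markers by missing rate and minor allele frequency
#'
#' Drops markers with missing rate above `max_missing` or MAF (computed on
#' non-missing calls) below `min_maf`.
#'
#' @param geno a [genotype_data()].
#' @param max_missing maximum tolerated missing rate (default 0.20).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return filtered [genotype_data()]; attribute `"dropped"` reports counts
#'   per rule.
#' @export
filter_genotypes <- function(geno, max_missing = 0.20, min_maf = 0.05) {
  g <- geno$matrix
  miss <- colMeans(is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0
  drop_miss <- miss > max_missing
  drop_maf <- !drop_miss & maf < min_maf
  keep <- !(drop_miss | drop_maf)
  if (!any(keep)) gs_stop("all markers filtered out", class = "empty_panel_error")
  out <- genotype_data(g[, keep, drop = FALSE], chrom = geno$map$chrom[keep],
                       pos = geno$map$pos[keep], id = geno$map$id[keep],
                       samples = geno$samples)
  attr(out, "dropped") <- c(missing = sum(drop_miss), maf = sum(drop_maf))
  out
}

impute_scale <- function(g, vanraden = FALSE) {
  p <- colMeans(g, na.rm = TRUE) / 2
  for (j in seq_len(ncol(g))) {
    nas <- is.na(g[, j])
    if (any(nas)) g[nas, j] <- 2 * p[j]
  }
  Z <- sweep(g, 2L, 2 * p)
  list(Z = Z, p = p)
}

#' Principal-component structure covariates
#'
#' Mean-imputes missing calls per marker, centers by twice the allele
#' frequency, scales by sqrt(2 p q), and scores the samples on the top
#' principal axes.
#'
#' @param geno a filtered [genotype_data()].
#' @param n_pcs number of principal components (default 3; 0 gives an
#'   intercept-only covariate matrix).
#' @return samples x (1 + n_pcs) matrix: intercept column then PC scores;
#'   attribute `"pve"` holds each PC's proportion of genotypic variance.
#' @export
structure_covariates <- function(geno, n_pcs = 3) {
  n <- nrow(geno$matrix)
  if (n_pcs >= n) gs_stop("n_pcs must be < number of samples", class = "dimension_error")
  out <- matrix(1, n, 1, dimnames = list(geno$samples, "intercept"))
  if (n_pcs == 0) return(out)
  zs <- impute_scale(geno$matrix)
  sc <- sqrt(2 * zs$p * (1 - zs$p))
  keep <- sc > 1e-8
  Zs <- sweep(zs$Z[, keep, drop = FALSE], 2L, sc[keep], "/")
  sv <- svd(Zs, nu = n_pcs, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  out <- cbind(out, pcs)
  attr(out, "pve") <- sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2)
  out
}

#' VanRaden kinship matrix
#'
#' K = Z Z' / (2 * sum p_j (1 - p_j)) with Z the allele-frequency-centered,
#' mean-imputed genotype matrix; symmetrized against floating-point drift.
#'
#' @param geno a filtered [genotype_data()].
#' @return samples x samples kinship matrix.
#' @export
kinship <- function(geno) {
  zs <- impute_scale(geno$matrix)
  denom <- 2 * sum(zs$p * (1 - zs$p))
  if (denom <= 0) gs_stop("no polymorphic markers for kinship", class = "empty_panel_error")
  K <- tcrossprod(zs$Z) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(geno$samples, geno$samples)
  K
}

#' Per-marker mixed-linear-model association scan
#'
#' Fits, for every marker, y = covariates * gamma + x_m * beta + u + e with
#' u ~ N(0, sigma2_g K) and e ~ N(0, sigma2_e I). Variance components are
#' re-estimated by REML for every marker ("each marker", no compression)
#' over the ratio delta = sigma2_e / sigma2_g, using one eigendecomposition
#' of K shared across markers; beta is tested by a Wald F(1, n - p) test.
#' Missing genotype calls are mean-imputed (the same fill used for the
#' kinship and PC inputs), keeping the rotated design consistent across
#' markers.
#'
#' @param trait named numeric vector (names = sample ids), e.g. a group-PC1
#'   spectral trait.
#' @param geno a filtered [genotype_data()].
#' @param covariates samples x q matrix from [structure_covariates()]
#'   (default: intercept only).
#' @param K kinship matrix from [kinship()] (default: computed from `geno`).
#' @param bran optional per-sample bran-color class; when supplied, only
#'   non-pigmented classes (white, light brown, brown) enter the scan.
#' @return object of class `association_result`: data.frame `result` with
#'   chrom, pos, id, beta, se, p, r2 per marker, plus `n`, `lambda_gc`.
#' @export
mlm_scan <- function(trait, geno, covariates = NULL, K = NULL, bran = NULL) {
  ids <- geno$samples
  if (is.null(names(trait))) {
    if (length(trait) != length(ids))
      gs_stop("unnamed trait must match the genotype sample count",
              class = "alignment_error")
    names(trait) <- ids
  }
  if (!all(ids %in% names(trait)))
    gs_stop("trait is missing samples: ",
            paste(head(setdiff(ids, names(trait)), 3), collapse = ", "),
            class = "alignment_error")
  keep <- seq_along(ids)
  if (!is.null(bran)) {
    nonpig <- c("white", "light_brown", "light brown", "brown")
    keep <- which(tolower(bran) %in% nonpig)
    if (length(keep) < 10) gs_stop("too few non-pigmented samples", class = "config_error")
  }
  ids <- ids[keep]
  y <- as.numeric(trait[ids])
  g <- geno$matrix[keep, , drop = FALSE]
  n <- length(y)
  if (is.null(covariates)) covariates <- matrix(1, n, 1)
  else covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  if (is.null(K)) {
    sub <- genotype_data(g, geno$map$chrom, geno$map$pos, geno$map$id, ids)
    K <- kinship(sub)
  } else K <- as.matrix(K)[keep, keep, drop = FALSE]
  if (max(abs(K - t(K))) > 1e-8) gs_stop("K must be symmetric", class = "kinship_error")
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    gs_stop("K is not positive semi-definite", class = "kinship_error")
  d <- pmax(eg$values, 1e-10)
  U <- eg$vectors
  G <- impute_scale(g)$Z + matrix(2 * colMeans(g, na.rm = TRUE),
                                  n, ncol(g), byrow = TRUE) # imputed 0/1/2
  yr <- crossprod(U, y)[, 1]
  X0r <- crossprod(U, covariates)
  Gr <- crossprod(U, G)
  res <- mlm_scan_cpp(X0r, Gr, yr, d)
  p <- pf(res$fstat, 1, res$df2, lower.tail = FALSE)
  p[!is.finite(p)] <- NA_real_
  p[!is.na(p)] <- pmax(p[!is.na(p)], .Machine$double.xmin)
  out <- data.frame(chrom = geno$map$chrom, pos = geno$map$pos,
                    id = geno$map$id, beta = res$beta, se = res$se,
                    p = p, r2 = res$r2, delta = res$delta,
                    stringsAsFactors = FALSE)
  lambda_gc <- median(qchisq(out$p, 1, lower.tail = FALSE), na.rm = TRUE) /
    qchisq(0.5, 1)
  structure(list(result = out, n = n, lambda_gc = lambda_gc),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: %d markers, n = %d, lambda_GC = %.3f\n",
              nrow(x$result), x$n, x$lambda_gc))
  top <- x$result[order(x$result$p), ][1:min(5, nrow(x$result)), c("chrom", "pos", "id", "beta", "p")]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Storey q-values and a genome-wide significance flag
#'
#' Estimates pi0 by the natural-spline smoother over a lambda grid
#' (0.05-0.95); q-values are pi0 times the Benjamini-Hochberg step-up
#' adjustment, so `pi0 = 1` reduces exactly to BH. Markers with
#' p <= `p_cutoff` (default 1e-6) are flagged genome-wide significant.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param p_cutoff genome-wide significance threshold on p.
#' @param pi0_method "smoother" (Storey) or "one" (BH).
#' @return list: `q` (q-values, same order), `pi0`, `significant` (logical),
#'   `p_cutoff`.
#' @export
fdr_threshold <- function(pvalues, p_cutoff = 1e-6,
                          pi0_method = c("smoother", "one")) {
  pi0_method <- match.arg(pi0_method)
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) gs_stop("no p-values", class = "config_error")
  if (any(p <= 0 | p > 1)) gs_stop("p-values must lie in (0, 1]", class = "config_error")
  pi0 <- 1
  if (pi0_method == "smoother" && length(p) >= 100) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- min(1, max(predict(fit, x = max(lam))$y, 0))
    if (pi0 <= 0) pi0 <- 1   # degenerate smoother: fall back to BH
  }
  q_all <- rep(NA_real_, length(pvalues))
  q_all[!is.na(pvalues)] <- pmin(pi0 * p.adjust(p, method = "BH"), 1)
  list(q = q_all, pi0 = pi0,
       significant = !is.na(pvalues) & pvalues <= p_cutoff,
       p_cutoff = p_cutoff)
}

#' Manhattan and QQ plot data
#'
#' Adds a cumulative genome coordinate (chromosomes laid end to end in sorted
#' label order), -log10(p), and expected-vs-observed quantiles; reports the
#' genomic inflation factor lambda_GC.
#'
#' @param assoc an [mlm_scan()] result, or its `result` data.frame.
#' @return list: `manhattan` (chrom, pos, cum_pos, id, p, neglog10p),
#'   `qq` (expected, observed, both -log10), `lambda_gc`, `chrom_offsets`.
#' @export
manhattan_qq_data <- function(assoc) {
  df <- if (inherits(assoc, "association_result")) assoc$result else assoc
  if (!nrow(df)) gs_stop("empty association result", class = "config_error")
  df <- df[order(df$chrom, df$pos), ]
  offs <- c(0, cumsum(vapply(split(df$pos, df$chrom), max, numeric(1))))
  chroms <- names(split(df$pos, df$chrom))
  names(offs) <- c(chroms, "_end")
  df$cum_pos <- df$pos + offs[match(df$chrom, chroms)]
  df$neglog10p <- -log10(df$p)
  ok <- !is.na(df$p)
  m <- sum(ok)
  expected <- -log10((seq_len(m) - 0.5) / m)
  observed <- sort(df$neglog10p[ok], decreasing = TRUE)
  lambda_gc <- median(qchisq(df$p[ok], 1, lower.tail = FALSE)) / qchisq(0.5, 1)
  list(manhattan = df[, c("chrom", "pos", "cum_pos", "id", "p", "neglog10p")],
       qq = data.frame(expected = expected, observed = observed),
       lambda_gc = lambda_gc,
       chrom_offsets = offs[seq_along(chroms)])
}
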