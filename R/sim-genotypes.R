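# Structured genotype and trait simulation for a rice-like diversity panel.

#' Simulate structured genotypes under a Balding-Nichols model
#'
#' Draws ancestral allele frequencies uniformly, then per-sub-population
#' frequencies from the Balding-Nichols Beta distribution with divergence
#' `fst`, and genotypes as binomial(2) counts of the alternate allele.
#' Markers receive ordered 1-based positions on `cfg$n_chromosomes`
#' chromosomes; missing calls are injected completely at random. Causal
#' chalk loci are drawn from markers with common ancestral frequency
#' (0.3-0.7) so their effects are observable in a panel of modest size.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` (a [genotype_data()]) and `truth` (a `sim_truth`
#'   list carrying causal indices, per-sample sub-population labels, and the
#'   per-sub-population allele frequencies used).
#' @export
simulate_genotypes <- function(cfg) {
  if (!inherits(cfg, "sim_config")) gs_stop("cfg must be a sim_config", class = "config_error")
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_snps; K <- cfg$n_subpops
  subpop <- sort(rep_len(seq_len(K), n))  # near-balanced panel
  p_anc <- runif(m, 0.1, 0.9)
  causal <- integer(0)
  if (cfg$n_causal > 0) {
    common <- which(p_anc >= 0.3 & p_anc <= 0.7)
    causal <- sort(sample(common, cfg$n_causal))
  }
  a <- p_anc * (1 - cfg$fst) / cfg$fst
  b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
  p_sub <- matrix(0, K, m)
  for (k in seq_len(K)) p_sub[k, ] <- qbeta(runif(m), a, b)
  # keep causal loci segregating in every sub-population
  if (length(causal)) p_sub[, causal] <- pmin(pmax(p_sub[, causal], 0.1), 0.9)
  g <- matrix(0L, n, m)
  for (k in seq_len(K)) {
    idx <- which(subpop == k)
    g[idx, ] <- matrix(rbinom(length(idx) * m, 2L, rep(p_sub[k, ], each = length(idx))),
                       length(idx), m)
  }
  if (cfg$missing_rate > 0) {
    nmiss <- rbinom(1L, n * m, cfg$missing_rate)
    if (nmiss > 0) {
      miss <- sample.int(n * m, nmiss)
      # never blank out causal loci entirely; plain MCAR elsewhere
      g[miss] <- NA_integer_
    }
  }
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), m))
  pos <- integer(m)
  for (cc in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(cfg$chrom_length, length(idx)))
  }
  ids <- sprintf("S%d_%d", chrom, pos)
  samples <- sprintf("ACC%03d", seq_len(n))
  geno <- genotype_data(g, chrom = paste0("chr", chrom), pos = pos, id = ids,
                        samples = samples)
  truth <- structure(list(
    causal_snp_indices = causal,
    causal_effects = cfg$causal_effects,
    subpop = cfg$subpop_labels[subpop],
    subpop_index = subpop,
    p_subpop = p_sub
  ), class = "sim_truth")
  list(geno = geno, truth = truth)
}

#' Simulate grain-quality traits on a simulated panel
#'
#' Percent chalk is a clipped additive trait: baseline + sum of causal-locus
#' effects (0/1/2 coding, mean-imputed where missing) + a per-sub-population
#' shift + Gaussian noise, truncated to \[0, 100\]. Amylose is generated with a
#' configurable correlation to chalk; kernel dimensions and alkali spreading
#' value (ASV) are drawn with sub-population means; bran color class is drawn
#' from `cfg$bran_probs`, and each sample is assigned a production
#' environment at random.
#'
#' @param geno a [genotype_data()].
#' @param truth `sim_truth` from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @param amylose_cor target correlation between amylose and chalk.
#' @return data.frame (class `trait_table`) with one row per sample:
#'   sample_id, subpop, environment, bran, chalk, amylose, asv, length_mm,
#'   width_mm, thickness_mm.
#' @export
simulate_traits <- function(geno, truth, cfg, amylose_cor = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(geno$matrix)
  set.seed(cfg$seed + 1L)
  gen <- numeric(n)
  if (length(truth$causal_snp_indices)) {
    X <- geno$matrix[, truth$causal_snp_indices, drop = FALSE]
    for (j in seq_len(ncol(X))) {
      xj <- X[, j]
      xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
      gen <- gen + cfg$causal_effects[j] * xj
    }
  }
  shift <- cfg$subpop_chalk_shift[truth$subpop_index]
  noise <- rnorm(n, 0, cfg$trait_noise_sd)
  chalk <- pmin(pmax(cfg$chalk_baseline + gen + shift + noise, 0), 100)
  z <- if (sd(chalk) > 0) as.numeric(scale(chalk)) else numeric(n)
  amylose <- 22 + 4 * (amylose_cor * z +
                         sqrt(max(0, 1 - amylose_cor^2)) * rnorm(n))
  asv <- pmin(pmax(round(4 + 1.2 * rnorm(n) + 0.3 * truth$subpop_index), 1), 7)
  env <- sample(cfg$env_labels, n, replace = TRUE)
  bran <- character(n)
  for (k in seq_len(cfg$n_subpops)) {
    idx <- which(truth$subpop_index == k)
    pk <- cfg$bran_probs[[min(k, length(cfg$bran_probs))]]
    bran[idx] <- sample(names(pk), length(idx), replace = TRUE, prob = pk)
  }
  out <- data.frame(
    sample_id = geno$samples,
    subpop = truth$subpop,
    environment = env,
    bran = bran,
    chalk = chalk,
    amylose = amylose,
    asv = asv,
    length_mm = 7 + 0.5 * rnorm(n) - 0.4 * (truth$subpop_index - 1),
    width_mm = 2.2 + 0.15 * rnorm(n) + 0.15 * (truth$subpop_index - 1),
    thickness_mm = 1.8 + 0.08 * rnorm(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("trait_table", "data.frame")
  out
}
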