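# Shared fixtures and independent oracles used across the suite.

# small, fast scene configuration for imaging tests
tiny_cfg <- function(seed = 1, ...) {
  sim_config(n_samples = 12, n_snps = 300, n_chromosomes = 2,
             grains_per_sample = 2, seed = seed, ...)
}

# run the imaging front-end on a rendered scene, returning aligned pieces
scene_spectra <- function(cfg) {
  sim <- simulate_genotypes(cfg)
  traits <- simulate_traits(sim$geno, sim$truth, cfg)
  scene <- render_scene(traits, cfg)
  cube <- calibrate(scene$raw, scene$white, scene$dark, scene$wavelengths)
  mask <- segment_grains(cube, min_area = 10, sample_map = scene$sample_map)
  sp <- extract_spectra(cube, mask)
  list(sim = sim, traits = traits[match(sp$sample_ids, traits$sample_id), ],
       scene = scene, cube = cube, mask = mask, spectra = sp)
}

# independent REML oracle: dense-matrix GLS over a fine variance-ratio grid,
# no eigen rotation shared with the implementation
reml_gls_oracle <- function(y, X, K, grid = 10^seq(-5, 5, length.out = 2001)) {
  n <- length(y); p <- ncol(X)
  best <- list(ll = -Inf)
  for (lambda in grid) {
    V <- K + diag(lambda, n)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) + determinant(V)$modulus +
                    determinant(XtVX)$modulus + (n - p))
    if (ll > best$ll) {
      se <- sqrt(s2 * solve(XtVX)[p, p])
      best <- list(ll = ll, lambda = lambda, beta = beta[p], se = se,
                   p = pf((beta[p] / se)^2, 1, n - p, lower.tail = FALSE))
    }
  }
  best
}

# brute-force interval union: expand every marker by flank, merge by scanning
brute_merge <- function(chrom, pos, flank) {
  out <- NULL
  for (cc in unique(chrom)) {
    ps <- sort(pos[chrom == cc])
    lo <- pmax(ps - flank, 1); hi <- ps + flank
    s <- lo[1]; e <- hi[1]
    for (i in seq_along(ps)[-1]) {
      if (lo[i] <= e + 1) e <- max(e, hi[i])
      else { out <- rbind(out, data.frame(chrom = cc, start = s, stop = e)); s <- lo[i]; e <- hi[i] }
    }
    out <- rbind(out, data.frame(chrom = cc, start = s, stop = e))
  }
  out[order(out$chrom, out$start), ]
}

# brute-force O(n^2) overlap of two interval sets
brute_overlap <- function(a, b) {
  hits <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] && a$start[i] <= b$stop[j] && b$start[j] <= a$stop[i])
      hits <- rbind(hits, data.frame(a_index = i, b_index = j))
  }
  hits
}

# random sorted disjoint segment set on a few chromosomes
random_segments <- function(n, seed) {
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", 1:3), n, replace = TRUE))
  out <- do.call(rbind, lapply(unique(chrom), function(cc) {
    k <- sum(chrom == cc)
    s <- sort(sample.int(5e6, k))
    len <- sample.int(40000, k)
    # force disjoint by pushing starts past the previous stop
    for (i in seq_len(k)[-1]) s[i] <- max(s[i], s[i - 1] + len[i - 1] + 2L)
    data.frame(chrom = cc, start = s, stop = s + len, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# mean silhouette of a 1-D embedding against known labels
silhouette1d <- function(x, labels) {
  d <- abs(outer(x, x, "-"))
  sil <- vapply(seq_along(x), function(i) {
    same <- labels == labels[i]; same[i] <- FALSE
    a <- if (any(same)) mean(d[i, same]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
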