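# Wavelength grouping by K-means, per-group PC1 spectral traits, trait
# regression, and data for the clustered heatmap.

#' Group wavelengths into contiguous spectral ranges by K-means
#'
#' Each band is a point in sample space (its standardized across-sample
#' profile); bands are clustered by K-means (20 restarts, best
#' within-cluster sum of squares kept) and the labels are post-processed
#' into exactly `k` contiguous nm ranges by a minimum-mismatch dynamic
#' program whose blocks take the majority K-means label.
#'
#' @param spectra a [spectra_table()].
#' @param k number of wavelength groups (default 5).
#' @param seed seed for the K-means restarts.
#' @param nstart number of K-means restarts.
#' @return object of class `wavelength_groups`: `group` (integer per band,
#'   numbered left to right), `ranges` (data.frame group, lo_nm, hi_nm),
#'   `kmeans_cluster` (raw K-means label per band).
#' @export
group_wavelengths <- function(spectra, k = 5, seed = 1, nstart = 20) {
  X <- spectra$spectra
  nb <- ncol(X)
  if (k >= nb) gs_stop("k must be < number of bands", class = "config_error")
  prof <- scale(X)                  # standardize each band's profile
  prof[, attr(prof, "scaled:scale") == 0] <- 0
  set.seed(seed)
  km <- kmeans(t(prof), centers = k, nstart = nstart, iter.max = 100)
  if (any(km$size == 0)) gs_stop("empty K-means cluster", class = "clustering_error")
  lab <- km$cluster
  # DP: partition bands 1..nb into k contiguous blocks minimizing the number
  # of bands whose K-means label differs from their block's majority label
  counts <- vapply(seq_len(k), function(cl) cumsum(lab == cl), numeric(nb))
  counts <- rbind(0, counts)        # counts[j+1, cl] = #{lab[1..j] == cl}
  block_cost <- function(i, j) (j - i + 1L) - max(counts[j + 1L, ] - counts[i, ])
  INF <- .Machine$integer.max / 2
  dp <- matrix(INF, k + 1L, nb + 1L)
  choice <- matrix(0L, k + 1L, nb + 1L)
  dp[1L, 1L] <- 0
  for (b in seq_len(k)) {
    for (j in seq_len(nb)) {
      for (i in seq_len(j)) {
        prev <- dp[b, i]
        if (prev >= INF) next
        cost <- prev + block_cost(i, j)
        if (cost < dp[b + 1L, j + 1L]) {
          dp[b + 1L, j + 1L] <- cost
          choice[b + 1L, j + 1L] <- i
        }
      }
    }
  }
  bounds <- integer(k + 1L); bounds[k + 1L] <- nb
  for (b in k:1) bounds[b] <- choice[b + 1L, bounds[b + 1L] + 1L] - 1L
  group <- integer(nb)
  for (b in seq_len(k)) group[(bounds[b] + 1L):bounds[b + 1L]] <- b
  wl <- spectra$wavelengths
  ranges <- data.frame(group = seq_len(k),
                       lo_nm = wl[bounds[seq_len(k)] + 1L],
                       hi_nm = wl[bounds[-1L]])
  structure(list(group = group, ranges = ranges, kmeans_cluster = lab,
                 wavelengths = wl),
            class = "wavelength_groups")
}

#' @export
print.wavelength_groups <- function(x, ...) {
  cat("wavelength_groups:\n")
  for (i in seq_len(nrow(x$ranges)))
    cat(sprintf("  group %d: %g-%g nm (%d bands)\n", i, x$ranges$lo_nm[i],
                x$ranges$hi_nm[i], sum(x$group == i)))
  invisible(x)
}

#' Per-group first principal component spectral traits
#'
#' For each wavelength group: center the group's bands, take the first
#' principal axis, and score the samples. The sign is fixed so PC1
#' correlates positively with the group's mean reflectance, making higher
#' scores mean brighter grain.
#'
#' @param spectra a [spectra_table()].
#' @param groups a [group_wavelengths()] result, or a list of numeric
#'   length-2 nm ranges.
#' @return data.frame of class `spectral_trait`: sample_id, one `PC1_g<k>`
#'   column per group; attribute `"varprop"` holds PC1's proportion of
#'   variance per group.
#' @export
spectral_trait_pc1 <- function(spectra, groups) {
  X <- spectra$spectra
  wl <- spectra$wavelengths
  idx_list <- if (inherits(groups, "wavelength_groups")) {
    lapply(seq_len(nrow(groups$ranges)), function(i) which(groups$group == i))
  } else {
    lapply(groups, function(r) which(wl >= r[1] & wl <= r[2]))
  }
  out <- data.frame(sample_id = spectra$sample_ids, stringsAsFactors = FALSE)
  varprop <- numeric(length(idx_list))
  for (i in seq_along(idx_list)) {
    idx <- idx_list[[i]]
    if (length(idx) < 2) gs_stop("group ", i, " has < 2 bands", class = "config_error")
    Xi <- X[, idx, drop = FALSE]
    if (all(apply(Xi, 2L, sd) < 1e-14))
      gs_stop("group ", i, " has zero variance", class = "degenerate_error")
    pc <- prcomp(Xi, center = TRUE, scale. = FALSE)
    sc <- pc$x[, 1]
    if (cor(sc, rowMeans(Xi)) < 0) sc <- -sc
    out[[paste0("PC1_g", i)]] <- sc
    varprop[i] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  attr(out, "varprop") <- varprop
  class(out) <- c("spectral_trait", "data.frame")
  out
}

#' Simple linear regression of a grain trait on a spectral predictor
#'
#' @param trait numeric trait values (NA allowed).
#' @param predictor numeric predictor (e.g. a group PC1 score).
#' @return list: `r_squared`, `p_value` (F test), `n`, `slope`, `intercept`,
#'   and `stars` ("**" for p < 0.01, "*" for p < 0.05, "ns" otherwise).
#' @export
regress_trait <- function(trait, predictor) {
  ok <- is.finite(trait) & is.finite(predictor)
  if (sum(ok) < 3) gs_stop("need >= 3 complete pairs", class = "config_error")
  x <- predictor[ok]; y <- trait[ok]
  if (sd(x) < 1e-14) gs_stop("constant predictor", class = "degenerate_error")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE))
  list(r_squared = sm$r.squared, p_value = p, n = sum(ok),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "ns")
}

#' Hierarchical clustering heatmap data for spectra and a trait
#'
#' Joins the spectra with a trait column, optionally min-max normalizes each
#' column to \[0, 1\], clusters samples by average-linkage agglomeration on
#' 1 - Pearson correlation or Euclidean distance, and returns the ordered
#' matrix plus the dendrogram.
#'
#' @param spectra a [spectra_table()] (possibly restricted to a band range).
#' @param trait optional numeric vector (e.g. percent chalk) appended as a
#'   final column named `trait`.
#' @param metric "pearson" (distance 1 - r) or "euclidean".
#' @param normalize01 logical; min-max normalize each column first.
#' @return list of class `cluster_heatmap`: `matrix` (normalized, original
#'   row order), `ordered` (rows permuted to leaf order), `hclust`, `order`.
#' @export
cluster_heatmap <- function(spectra, trait = NULL,
                            metric = c("pearson", "euclidean"),
                            normalize01 = TRUE) {
  metric <- match.arg(metric)
  M <- spectra$spectra
  if (!is.null(trait)) {
    stopifnot(length(trait) == nrow(M))
    M <- cbind(M, trait = trait)
  }
  if (normalize01) M <- apply(M, 2L, normalize01)
  rownames(M) <- spectra$sample_ids
  if (metric == "pearson") {
    sds <- apply(M, 1L, sd)
    if (any(sds < 1e-14))
      gs_stop("constant row under Pearson distance: ",
              paste(head(rownames(M)[sds < 1e-14], 3), collapse = ", "),
              class = "degenerate_error")
    D <- as.dist(1 - cor(t(M)))
  } else {
    D <- dist(M)
  }
  hc <- hclust(D, method = "average")
  structure(list(matrix = M, ordered = M[hc$order, , drop = FALSE],
                 hclust = hc, order = hc$order),
            class = "cluster_heatmap")
}
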