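# Rendering of synthetic hyperspectral grain scenes.
#
# Each sample contributes a few elliptical "grains" on a dark background.
# The designed per-pixel reflectance is
#   bran baseline(nm) + chalk% * loading(nm) + environment offset(nm)
# where the chalk loading is a smooth bump supported only on
# [chalk_band_lo, chalk_band_hi]. Raw counts are constructed around fixed
# white/dark reference levels so that (raw - D)/(W - D) returns the designed
# reflectance exactly when noise_sd = 0.

bran_baseline <- function(wl, mult) {
  # smooth visible ramp up to a NIR plateau; pericarp pigment absorbs mainly
  # in the visible range, so the bran-class multiplier tapers off in the NIR
  vis <- 0.18 + 0.32 / (1 + exp(-(wl - 620) / 60))
  base <- vis
  base[wl > 700] <- pmax(base[wl > 700], 0.18 + 0.32 / (1 + exp(-(700 - 620) / 60)))
  pigment_weight <- 1 / (1 + exp((wl - 700) / 30))
  eff_mult <- 1 - (1 - mult) * (0.15 + 0.85 * pigment_weight)
  eff_mult * base
}

chalk_loading <- function(wl, lo, hi, gain) {
  # tapered-flat (Tukey) window: flat over most of the support with smooth
  # cosine edges, zero exactly at the boundaries; chalk elevates reflectance
  # across the whole band rather than at a single peak
  out <- numeric(length(wl))
  inside <- wl >= lo & wl <= hi
  u <- (wl[inside] - lo) / (hi - lo)
  alpha <- 0.2
  w <- rep(1, length(u))
  w[u < alpha] <- 0.5 * (1 - cos(pi * u[u < alpha] / alpha))
  w[u > 1 - alpha] <- 0.5 * (1 - cos(pi * (1 - u[u > 1 - alpha]) / alpha))
  out[inside] <- gain / 100 * w
  out
}

band_offset <- function(wl, spec_list, label) {
  out <- numeric(length(wl))
  e <- spec_list[[label]]
  if (is.null(e)) return(out)
  inside <- wl >= e$range[1] & wl <= e$range[2]
  out[inside] <- e$offset
  out
}

#' Render a synthetic hyperspectral grain scene
#'
#' Lays out `cfg$grains_per_sample` non-overlapping ellipses per sample on a
#' low-reflectance background, builds the designed reflectance per pixel, and
#' converts it to raw counts with matching white and dark reference cubes.
#'
#' @param traits a `trait_table` from [simulate_traits()].
#' @param cfg a [sim_config()].
#' @return list with `raw` (counts array), `white`, `dark` (reference arrays
#'   of the same shape), `wavelengths`, `labels` (rows x cols integer matrix,
#'   0 = background, k = sample k), `sample_map` (data.frame grain -> sample
#'   with centroids), and `design` (samples x bands designed mean reflectance,
#'   the renderer's ground truth).
#' @export
render_scene <- function(traits, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  wl <- cfg$wavelengths
  nb <- length(wl)
  n <- nrow(traits)
  missing_bran <- setdiff(unique(traits$bran), names(cfg$bran_palette))
  if (length(missing_bran))
    gs_stop("no palette entry for bran class: ", paste(missing_bran, collapse = ", "),
            class = "config_error")
  a0 <- cfg$grain_axes[1]; b0 <- cfg$grain_axes[2]
  cell_h <- 2L * ceiling(a0 * 1.3) + 3L
  cell_w <- 2L * ceiling(b0 * 1.3) + 3L
  ngrain <- n * cfg$grains_per_sample
  ncell_col <- ceiling(sqrt(ngrain * cell_h / cell_w))
  ncell_row <- ceiling(ngrain / ncell_col)
  nrow_img <- ncell_row * cell_h
  ncol_img <- ncell_col * cell_w
  if (ncell_row * ncell_col < ngrain)
    gs_stop("scene too small for requested grain count", class = "capacity_error")

  bg_reflectance <- 0.04
  Wlev <- 4000; Dlev <- 100  # reference count levels
  npix <- nrow_img * ncol_img
  design_px <- matrix(bg_reflectance, npix, nb)
  labels <- matrix(0L, nrow_img, ncol_img)
  sample_map <- data.frame(grain = integer(ngrain), sample_id = character(ngrain),
                           row = numeric(ngrain), col = numeric(ngrain),
                           stringsAsFactors = FALSE)
  design <- matrix(0, n, nb,
                   dimnames = list(traits$sample_id, format(wl, trim = TRUE)))
  grain <- 0L
  for (i in seq_len(n)) {
    spec <- bran_baseline(wl, cfg$bran_palette[[traits$bran[i]]]) +
      traits$chalk[i] * chalk_loading(wl, cfg$chalk_band_lo, cfg$chalk_band_hi,
                                      cfg$chalk_reflectance_gain) +
      band_offset(wl, cfg$env_offsets, traits$environment[i]) +
      band_offset(wl, cfg$subpop_offsets, traits$subpop[i])
    design[i, ] <- spec
    for (g in seq_len(cfg$grains_per_sample)) {
      grain <- grain + 1L
      cr <- (grain - 1L) %/% ncell_col
      cc <- (grain - 1L) %% ncell_col
      ctr_r <- cr * cell_h + cell_h / 2 + runif(1, -1, 1)
      ctr_c <- cc * cell_w + cell_w / 2 + runif(1, -1, 1)
      ar <- a0 * runif(1, 0.85, 1.15)
      br <- b0 * runif(1, 0.85, 1.15)
      rr <- pmax(1L, floor(ctr_r - ar)):pmin(nrow_img, ceiling(ctr_r + ar))
      cols <- pmax(1L, floor(ctr_c - br)):pmin(ncol_img, ceiling(ctr_c + br))
      gg <- expand.grid(r = rr, c = cols)
      inside <- ((gg$r - ctr_r) / ar)^2 + ((gg$c - ctr_c) / br)^2 <= 1
      gg <- gg[inside, , drop = FALSE]
      if (!nrow(gg)) next
      lin <- gg$r + (gg$c - 1L) * nrow_img
      labels[cbind(gg$r, gg$c)] <- i
      design_px[lin, ] <- matrix(spec, nrow(gg), nb, byrow = TRUE)
      sample_map$grain[grain] <- grain
      sample_map$sample_id[grain] <- traits$sample_id[i]
      sample_map$row[grain] <- ctr_r
      sample_map$col[grain] <- ctr_c
    }
  }
  raw_px <- Dlev + design_px * (Wlev - Dlev)
  if (cfg$noise_sd > 0)
    raw_px <- raw_px + rnorm(length(raw_px), 0, cfg$noise_sd * (Wlev - Dlev))
  raw <- array(raw_px, dim = c(nrow_img, ncol_img, nb))
  white <- array(Wlev, dim = dim(raw))
  dark <- array(Dlev, dim = dim(raw))
  list(raw = raw, white = white, dark = dark, wavelengths = wl,
       labels = labels, sample_map = sample_map, design = design)
}

#' Generate and write a complete synthetic study to disk
#'
#' Runs [simulate_genotypes()], [simulate_traits()] and [render_scene()] and
#' writes the artifacts in the pipeline's exchange formats: ENVI cubes (raw,
#' white, dark), a plain-text sample map (TSV), traits as TSV, genotypes as
#' VCF, a synthetic gene annotation as GFF3, and the simulation ground truth
#' as JSON.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param n_genes number of synthetic gene models in the GFF3 annotation.
#' @return invisibly, a named list of the file paths written plus the
#'   in-memory objects (`geno`, `truth`, `traits`, `scene`).
#' @export
simulate_study <- function(cfg, dir, n_genes = 400) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(cfg)
  traits <- simulate_traits(sim$geno, sim$truth, cfg)
  scene <- render_scene(traits, cfg)
  paths <- list(
    raw = file.path(dir, "raw.img"), white = file.path(dir, "white.img"),
    dark = file.path(dir, "dark.img"), sample_map = file.path(dir, "sample_map.tsv"),
    traits = file.path(dir, "traits.tsv"), vcf = file.path(dir, "genotypes.vcf"),
    gff3 = file.path(dir, "annotation_synthetic.gff3"),
    truth = file.path(dir, "truth.json")
  )
  write_envi(scene$raw, scene$wavelengths, paths$raw)
  write_envi(scene$white, scene$wavelengths, paths$white)
  write_envi(scene$dark, scene$wavelengths, paths$dark)
  write.table(scene$sample_map, paths$sample_map, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(traits, paths$traits, sep = "\t", quote = FALSE, row.names = FALSE)
  write_vcf(sim$geno, paths$vcf)
  genes <- simulate_annotation(cfg, sim$geno, n_genes = n_genes)
  write_gff3(genes, paths$gff3)
  truth <- sim$truth
  truth$chalk <- traits$chalk
  truth$discriminative_band <- cfg$wavelengths >= cfg$chalk_band_lo &
    cfg$wavelengths <= cfg$chalk_band_hi
  jsonlite::write_json(
    list(causal_snp_indices = truth$causal_snp_indices,
         causal_ids = sim$geno$map$id[truth$causal_snp_indices],
         causal_effects = truth$causal_effects,
         subpop = truth$subpop, chalk = truth$chalk,
         environment = traits$environment, bran = traits$bran,
         discriminative_band = truth$discriminative_band),
    paths$truth, auto_unbox = FALSE, digits = NA)
  invisible(c(paths, list(geno = sim$geno, truth = truth, traits = traits,
                          scene = scene, genes = genes)))
}

#' Simulate a gene annotation covering the marker map
#'
#' Places non-overlapping gene models uniformly along each chromosome of a
#' simulated panel; used to exercise the candidate-gene search. The output is
#' synthetic and carries no biological meaning.
#'
#' @param cfg a [sim_config()].
#' @param geno a [genotype_data()] whose chromosomes to cover.
#' @param n_genes total number of gene models.
#' @return data.frame with gene_id, chrom, start, stop, strand, description.
#' @export
simulate_annotation <- function(cfg, geno, n_genes = 400) {
  set.seed(cfg$seed + 3L)
  chroms <- unique(geno$map$chrom)
  per <- ceiling(n_genes / length(chroms))
  out <- do.call(rbind, lapply(chroms, function(cc) {
    starts <- sort(sample.int(cfg$chrom_length - 20000L, per))
    len <- sample(1000:15000, per, replace = TRUE)
    stop <- pmin(starts + len, cfg$chrom_length)
    # enforce non-overlap within chromosome
    keep <- c(TRUE, starts[-1] > head(stop, -1))
    data.frame(gene_id = sprintf("GENE_%s_%06d", cc, starts),
               chrom = cc, start = starts, stop = stop,
               strand = sample(c("+", "-"), per, replace = TRUE),
               description = "synthetic gene model",
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}
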