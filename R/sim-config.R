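#' Configuration for the synthetic grain-imaging study
#'
#' Bundles every knob of the synthetic-data generator: a structured rice
#' diversity panel (sub-populations diverged under a Balding-Nichols model),
#' grain-quality traits with a small number of causal chalk loci, and
#' hyperspectral grain scenes in which chalk elevates reflectance on a fixed
#' near-infrared support (default 690-920 nm), bran color sets the visible
#' baseline, and production environments shift narrow band windows.
#'
#' @param n_samples number of accessions (samples).
#' @param n_subpops number of genetic sub-populations.
#' @param fst divergence parameter in (0, 1) of the Balding-Nichols model.
#' @param n_snps number of biallelic markers.
#' @param n_causal number of causal chalk loci.
#' @param causal_effects additive effect per minor allele of each causal
#'   locus, in percent-chalk units (recycled/truncated to `n_causal`).
#' @param chalk_band_lo,chalk_band_hi nm bounds of the spectral support on
#'   which chalk elevates reflectance.
#' @param chalk_reflectance_gain reflectance increase at the loading peak for
#'   100 percent chalk.
#' @param env_offsets named list, one entry per environment label, each a
#'   `list(range = c(lo_nm, hi_nm), offset = <reflectance>)` band shift.
#' @param subpop_offsets like `env_offsets`, keyed by sub-population label;
#'   visible-range signatures that make sub-populations spectrally separable.
#' @param bran_palette named numeric vector of visible-baseline reflectance
#'   multipliers per bran-color class.
#' @param bran_probs list mapping sub-population label to the probability of
#'   each bran class (rows of a palette-length simplex).
#' @param noise_sd per-pixel reflectance noise standard deviation.
#' @param trait_noise_sd standard deviation of the Gaussian noise on chalk, in
#'   percent-chalk units.
#' @param chalk_baseline baseline percent chalk before genetic and group shifts.
#' @param subpop_chalk_shift per-sub-population additive shift on chalk (%).
#' @param missing_rate probability a genotype call is set missing.
#' @param n_chromosomes,chrom_length marker map layout (bp, 1-based).
#' @param wavelengths band centers in nm (default 400-1004 nm every 4 nm).
#' @param grains_per_sample ellipse count drawn per sample.
#' @param grain_axes mean semi-axes (row, col) of a grain ellipse in pixels.
#' @param seed integer seed controlling all randomness of the generator.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 96,
                       n_subpops = 3,
                       fst = 0.15,
                       n_snps = 5000,
                       n_causal = 3,
                       causal_effects = c(12, 9, 7),
                       chalk_band_lo = 690,
                       chalk_band_hi = 920,
                       chalk_reflectance_gain = 0.35,
                       env_offsets = list(
                         TX08 = list(range = c(400, 460), offset = 0.030),
                         AR09 = list(range = c(740, 790), offset = -0.008),
                         AR10 = list(range = c(840, 900), offset = 0.008)
                       ),
                       subpop_offsets = list(
                         IND = list(range = c(495, 570), offset = -0.030),
                         TEJ = list(range = c(590, 660), offset = 0.030),
                         TRJ = list(range = c(430, 500), offset = 0.030)
                       ),
                       bran_palette = c(white = 1.00, light_brown = 0.88,
                                        brown = 0.75, red = 0.45, purple = 0.30),
                       bran_probs = NULL,
                       noise_sd = 0.01,
                       trait_noise_sd = 6,
                       chalk_baseline = 8,
                       subpop_chalk_shift = c(0, 4, 8),
                       missing_rate = 0.02,
                       n_chromosomes = 12,
                       chrom_length = 30e6,
                       wavelengths = seq(400, 1004, by = 4),
                       grains_per_sample = 3,
                       grain_axes = c(4, 6),
                       seed = 1) {
  check_number(n_samples, "n_samples", lo = 2)
  check_number(n_subpops, "n_subpops", lo = 1)
  check_number(fst, "fst", lo = 1e-12, hi = 1 - 1e-12)
  check_number(n_snps, "n_snps", lo = 1)
  check_number(n_causal, "n_causal", lo = 0, hi = n_snps)
  check_number(chalk_band_lo, "chalk_band_lo")
  check_number(chalk_band_hi, "chalk_band_hi")
  if (chalk_band_lo >= chalk_band_hi)
    gs_stop("chalk_band_lo must be < chalk_band_hi", class = "config_error")
  check_number(noise_sd, "noise_sd", lo = 0)
  check_number(trait_noise_sd, "trait_noise_sd", lo = 0)
  check_number(missing_rate, "missing_rate", lo = 0, hi = 1)
  check_number(n_chromosomes, "n_chromosomes", lo = 2)
  if (!is.numeric(wavelengths) || is.unsorted(wavelengths, strictly = TRUE))
    gs_stop("wavelengths must be strictly increasing", class = "config_error")
  if (n_causal > 0) {
    causal_effects <- rep_len(causal_effects, n_causal)
  } else {
    causal_effects <- numeric(0)
  }
  subpop_chalk_shift <- rep_len(subpop_chalk_shift, n_subpops)
  subpop_labels <- names(subpop_offsets)
  if (length(subpop_labels) < n_subpops)
    subpop_labels <- c(subpop_labels,
                       paste0("POP", seq_len(n_subpops - length(subpop_labels))))
  subpop_labels <- subpop_labels[seq_len(n_subpops)]
  if (is.null(bran_probs)) {
    # non-pigmented classes dominate; class mix differs by sub-population so
    # bran color carries sub-population signal, as in a real diversity panel
    bran_probs <- lapply(seq_len(n_subpops), function(i) {
      p <- setNames(numeric(length(bran_palette)), names(bran_palette))
      mass <- c(0.5, 0.3, 0.2)
      k <- min(3L, length(p))
      # rotate the mass so each sub-population favors a different class
      p[seq_len(k)] <- mass[((seq_len(k) + i - 2L) %% k) + 1L]
      p / sum(p)
    })
    names(bran_probs) <- subpop_labels
  }
  structure(list(
    n_samples = as.integer(n_samples), n_subpops = as.integer(n_subpops),
    fst = fst, n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
    causal_effects = causal_effects,
    chalk_band_lo = chalk_band_lo, chalk_band_hi = chalk_band_hi,
    chalk_reflectance_gain = chalk_reflectance_gain,
    env_offsets = env_offsets, subpop_offsets = subpop_offsets,
    bran_palette = bran_palette, bran_probs = bran_probs,
    noise_sd = noise_sd, trait_noise_sd = trait_noise_sd,
    chalk_baseline = chalk_baseline, subpop_chalk_shift = subpop_chalk_shift,
    missing_rate = missing_rate,
    n_chromosomes = as.integer(n_chromosomes), chrom_length = chrom_length,
    wavelengths = wavelengths,
    grains_per_sample = as.integer(grains_per_sample),
    grain_axes = grain_axes,
    subpop_labels = subpop_labels,
    env_labels = names(env_offsets),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic grain-imaging study configuration\n")
  cat(sprintf("  samples: %d in %d sub-populations (Fst = %.3g)\n",
              x$n_samples, x$n_subpops, x$fst))
  cat(sprintf("  markers: %d on %d chromosomes, %d causal chalk loci\n",
              x$n_snps, x$n_chromosomes, x$n_causal))
  cat(sprintf("  chalk band: %g-%g nm; %d bands %g-%g nm\n",
              x$chalk_band_lo, x$chalk_band_hi, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  environments: %s\n", paste(x$env_labels, collapse = ", ")))
  invisible(x)
}
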