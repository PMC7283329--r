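# End-to-end orchestration: calibrate -> segment -> extract -> (preprocess)
# -> classify / trait-spectra -> gwas -> segments -> genes, from a single
# config, with a manifest of inputs, parameters and output checksums.

#' Build and validate a pipeline configuration
#'
#' Collects every stage's paths and parameters. Defaults follow the analysis
#' conventions used throughout the package: no preprocessing, 750 nm ROI
#' band, five wavelength groups, 702-922 nm chalk trait band, MAF 0.05 /
#' missing 0.20 genotype filters, 3 PCs + kinship MLM, p <= 1e-6 genome-wide
#' cutoff, 100 kb segment flank, 150 kb candidate-gene radius, VIP 0.8,
#' 10% holdback.
#'
#' @param paths named list: raw, white, dark (ENVI), sample_map, traits
#'   (TSV), vcf, gff3. Stages whose inputs are absent can be disabled.
#' @param stages character vector of stages to run, any of "imaging",
#'   "classify", "trait_spectra", "gwas", "segments", "genes".
#' @param preprocess character vector of preprocessing methods ("none"
#'   default).
#' @param classify_target "subpop" or "environment".
#' @param roi_nm,min_area imaging parameters.
#' @param n_groups wavelength-group count.
#' @param trait_band nm range of the chalk spectral trait (default
#'   c(702, 922)).
#' @param vip_threshold,holdback_fraction chemometrics parameters.
#' @param max_missing,min_maf,n_pcs,p_cutoff GWAS parameters.
#' @param flank,radius segment / candidate-gene parameters in bp.
#' @param seed single global seed propagated to every stochastic stage.
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(paths, stages = c("imaging", "classify",
                                              "trait_spectra", "gwas",
                                              "segments", "genes"),
                            preprocess = "none",
                            classify_target = c("subpop", "environment"),
                            roi_nm = 750, min_area = 10, n_groups = 5,
                            trait_band = c(702, 922), vip_threshold = 0.8,
                            holdback_fraction = 0.10,
                            max_missing = 0.20, min_maf = 0.05, n_pcs = 3,
                            p_cutoff = 1e-6, flank = 100e3, radius = 150e3,
                            seed = 1, out_dir = tempfile("grainspec_run")) {
  classify_target <- match.arg(classify_target)
  stages <- match.arg(stages, several.ok = TRUE)
  check_number(p_cutoff, "p_cutoff", lo = 1e-300, hi = 1 - 1e-12)
  check_number(flank, "flank", lo = 1)
  check_number(radius, "radius", lo = 1)
  needed <- c("raw", "white", "dark", "sample_map")
  if ("gwas" %in% stages) needed <- c(needed, "vcf", "traits")
  if ("genes" %in% stages) needed <- c(needed, "gff3")
  if (any(c("classify", "trait_spectra") %in% stages)) needed <- c(needed, "traits")
  missing_paths <- needed[!vapply(needed, function(k)
    !is.null(paths[[k]]) && file.exists(paths[[k]]), logical(1))]
  if (length(missing_paths))
    gs_stop("missing input path(s): ", paste(unique(missing_paths), collapse = ", "),
            class = "validation_error")
  structure(list(paths = paths, stages = stages, preprocess = preprocess,
                 classify_target = classify_target, roi_nm = roi_nm,
                 min_area = min_area, n_groups = n_groups,
                 trait_band = trait_band, vip_threshold = vip_threshold,
                 holdback_fraction = holdback_fraction,
                 max_missing = max_missing, min_maf = min_maf, n_pcs = n_pcs,
                 p_cutoff = p_cutoff, flank = flank, radius = radius,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

read_yaml_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and writes every artifact under
#' `config$out_dir`, finishing with `manifest.json` (stages completed,
#' parameters used, md5 checksum per output). A stage failure writes a
#' `FAILED` marker naming the stage and re-raises the error; completed
#' outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `stages`, `parameters`,
#'   `outputs`, `checksums`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  done <- character(0)
  current_stage <- "setup"
  emit <- function(obj, name, writer = NULL) {
    path <- file.path(config$out_dir, name)
    if (is.null(writer)) write.table(obj, path, sep = "\t", quote = FALSE,
                                     row.names = FALSE)
    else writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  res <- list()
  tryCatch({
    current_stage <- "imaging"
    raw <- read_envi(config$paths$raw)
    white <- read_envi(config$paths$white)
    dark <- read_envi(config$paths$dark)
    cube <- calibrate(raw$values, white$values, dark$values, raw$wavelengths)
    smap <- read.delim(config$paths$sample_map, stringsAsFactors = FALSE)
    mask <- segment_grains(cube, roi_wavelength = config$roi_nm,
                           min_area = config$min_area, sample_map = smap)
    spectra <- extract_spectra(cube, mask)
    spectra <- preprocess_chain(spectra, config$preprocess)
    emit(spectra, "spectra.tsv", write_spectra_tsv)
    res$spectra <- spectra
    done <- c(done, "imaging")

    traits <- NULL
    if (!is.null(config$paths$traits)) {
      traits <- read.delim(config$paths$traits, stringsAsFactors = FALSE)
      traits <- traits[match(spectra$sample_ids, traits$sample_id), ]
    }

    if ("classify" %in% config$stages) {
      current_stage <- "classify"
      labels <- if (config$classify_target == "subpop") traits$subpop
                else traits$environment
      model <- fit_plsda(spectra, class_coding(labels),
                         holdback_fraction = config$holdback_fraction,
                         seed = config$seed)
      v <- vip(model)
      sel <- select_wavelengths(model, config$vip_threshold)
      lda <- fit_lda(spectra$spectra[, spectra$wavelengths %in% sel, drop = FALSE],
                     labels, holdback = model$holdback)
      emit(data.frame(wavelength = model$wavelengths, vip = v, model$beta,
                      check.names = FALSE), "beta_vip.tsv")
      emit(data.frame(wavelength = sel), "selected_wavelengths.tsv")
      emit(list(pve = as.list(model$pve),
                plsda_holdback_accuracy = model$holdback_accuracy,
                lda_train_accuracy = lda$train_accuracy,
                lda_holdback_accuracy = lda$holdback_accuracy,
                n_components = model$n_components),
           "classification.json",
           function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
      res$classification <- list(pls = model, lda = lda, selected = sel)
      done <- c(done, "classify")
    }

    pc1 <- NULL
    if ("trait_spectra" %in% config$stages) {
      current_stage <- "trait_spectra"
      groups <- group_wavelengths(spectra, k = config$n_groups, seed = config$seed)
      st <- spectral_trait_pc1(spectra, groups)
      band_trait <- spectral_trait_pc1(spectra, list(config$trait_band))
      pc1 <- setNames(band_trait$PC1_g1, band_trait$sample_id)
      reg <- regress_trait(traits$chalk, pc1)
      emit(groups$ranges, "wavelength_groups.tsv")
      emit(cbind(st, trait_band_pc1 = pc1), "spectral_traits.tsv")
      emit(list(chalk_r_squared = reg$r_squared, chalk_p = reg$p_value,
                stars = reg$stars,
                pc1_varprop = attr(band_trait, "varprop")[1]),
           "trait_regression.json",
           function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
      res$trait_spectra <- list(groups = groups, pc1 = pc1, regression = reg)
      done <- c(done, "trait_spectra")
    }

    assoc <- NULL
    if ("gwas" %in% config$stages) {
      current_stage <- "gwas"
      geno <- read_vcf_genotypes(config$paths$vcf)
      geno <- filter_genotypes(geno, config$max_missing, config$min_maf)
      if (is.null(pc1)) gs_stop("gwas stage requires trait_spectra",
                                class = "validation_error")
      bran <- traits$bran[match(geno$samples, traits$sample_id)]
      covar <- structure_covariates(geno, config$n_pcs)
      K <- kinship(geno)
      assoc <- mlm_scan(pc1, geno, covariates = covar, K = K, bran = bran)
      fdr <- fdr_threshold(assoc$result$p, p_cutoff = config$p_cutoff)
      assoc$result$q <- fdr$q
      assoc$result$significant <- fdr$significant
      emit(assoc$result, "gwas.tsv")
      mq <- manhattan_qq_data(assoc)
      emit(mq$manhattan, "manhattan.tsv")
      emit(mq$qq, "qq.tsv")
      emit(list(n = assoc$n, lambda_gc = assoc$lambda_gc, pi0 = fdr$pi0,
                n_significant = sum(fdr$significant)),
           "gwas_summary.json",
           function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
      res$gwas <- assoc
      done <- c(done, "gwas")
    }

    segs <- NULL
    if ("segments" %in% config$stages && !is.null(assoc)) {
      current_stage <- "segments"
      sig <- assoc$result[assoc$result$significant %in% TRUE, ]
      if (nrow(sig)) {
        segs <- define_segments(sig[, c("chrom", "pos", "p")],
                                flank = config$flank, p_cutoff = config$p_cutoff,
                                trait = "spectral_pc1")
        emit(segs, "segments.tsv", function(o, p) write_segments(o, p))
      } else {
        segs <- NULL
        writeLines("no significant markers", file.path(config$out_dir, "segments.tsv"))
        outputs <- c(outputs, file.path(config$out_dir, "segments.tsv"))
      }
      res$segments <- segs
      done <- c(done, "segments")
    }

    if ("genes" %in% config$stages && !is.null(segs) && nrow(segs)) {
      current_stage <- "genes"
      ann <- read_gff3_genes(config$paths$gff3)
      hits <- candidate_genes(segs, ann, radius = config$radius)
      emit(hits, "candidate_genes.tsv")
      res$genes <- hits
      done <- c(done, "genes")
    }
  }, error = function(e) {
    writeLines(c(paste("FAILED at stage:", current_stage),
                 conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    gs_stop("pipeline failed at stage '", current_stage, "': ",
            conditionMessage(e), class = "stage_error")
  })
  manifest <- list(
    stages = done,
    parameters = unclass(config)[setdiff(names(config), c("paths", "out_dir"))],
    inputs = lapply(config$paths, function(p) unname(tools::md5sum(p))),
    outputs = basename(outputs),
    checksums = setNames(as.list(unname(tools::md5sum(outputs))), basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(manifest, results = list(res)))
}
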