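#' Genotype matrix with marker map
#'
#' Container for a samples x markers matrix coded 0/1/2 (count of the
#' alternate allele, `NA` = missing) plus marker metadata. Positions must be
#' strictly increasing within each chromosome.
#'
#' @param matrix integer matrix samples x markers, entries in {0,1,2,NA}.
#' @param chrom chromosome label per marker.
#' @param pos 1-based bp position per marker.
#' @param id marker identifier per marker.
#' @param samples sample identifiers (defaults to rownames or G1..Gn).
#' @return object of class `genotype_data`.
#' @export
genotype_data <- function(matrix, chrom, pos, id = NULL, samples = NULL) {
  m <- ncol(matrix)
  if (length(chrom) != m || length(pos) != m)
    gs_stop("marker metadata length must match ncol(matrix)", class = "config_error")
  vals <- matrix[!is.na(matrix)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    gs_stop("genotype codes must be 0/1/2 or NA", class = "config_error")
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (is.unsorted(p, strictly = TRUE))
      gs_stop("positions must be strictly increasing within chromosome ", cc,
              class = "config_error")
  }
  if (is.null(id)) id <- sprintf("%s_%d", chrom, pos)
  if (is.null(samples)) samples <- rownames(matrix) %||% sprintf("G%d", seq_len(nrow(matrix)))
  rownames(matrix) <- samples
  colnames(matrix) <- id
  structure(list(matrix = matrix,
                 map = data.frame(chrom = as.character(chrom),
                                  pos = as.integer(pos), id = id,
                                  stringsAsFactors = FALSE),
                 samples = samples),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  miss <- mean(is.na(x$matrix))
  cat(sprintf("genotype_data: %d samples x %d markers on %d chromosomes (%.1f%% missing)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$map$chrom)), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$matrix)
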