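# Exchange-format I/O: VCF (via vcfR), GFF3 (via rtracklayer), spectra TSV.

#' Write genotypes as a minimal VCF 4.2 file
#'
#' Emits GT-only records (0/0, 0/1, 1/1, ./.) with REF=A, ALT=T placeholders;
#' the alternate-allele count equals the 0/1/2 coding of the matrix.
#'
#' @param geno a [genotype_data()].
#' @param path output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  g <- geno$matrix
  gt <- matrix("./.", ncol(g), nrow(g))  # markers x samples
  codes <- c("0/0", "0/1", "1/1")
  tg <- t(g)
  ok <- !is.na(tg)
  gt[ok] <- codes[tg[ok] + 1L]
  body <- cbind(geno$map$chrom, geno$map$pos, geno$map$id, "A", "T", ".",
                "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=grainspec synthetic panel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$samples), collapse = "\t")), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields into 0/1/2 alternate-allele counts. Multi-allelic sites
#' are skipped with a warning, mirroring standard GWAS practice.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a [genotype_data()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  g <- apply(gt, 2L, count_alt)  # markers x samples -> counts
  g <- t(g)                      # samples x markers
  # order markers by (chrom, pos); vcfR keeps file order
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ord <- order(chrom, pos)
  genotype_data(g[, ord, drop = FALSE], chrom = chrom[ord], pos = pos[ord],
                id = fix[ord, "ID"], samples = colnames(gt))
}

#' Write a gene table as GFF3
#'
#' @param genes data.frame with gene_id, chrom, start, stop, strand,
#'   description (as produced by [simulate_annotation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tgrainspec\tgene\t%d\t%d\t.\t%s\t.\tID=%s;description=%s",
                     genes$chrom, genes$start, genes$stop, genes$strand,
                     genes$gene_id, gsub("[;=\t]", " ", genes$description)), con)
  invisible(path)
}

#' Read gene records from a GFF3 annotation
#'
#' Imports via rtracklayer and keeps gene-type features only.
#'
#' @param path GFF3 path.
#' @return data.frame with gene_id, chrom, start, stop, strand, description.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (!length(gr)) gs_stop("no gene features in ", path, class = "io_error")
  desc <- if ("description" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$description) else NA_character_
  data.frame(gene_id = as.character(gr$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             stop = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             description = desc,
             stringsAsFactors = FALSE)
}

#' Write a spectra table as TSV
#'
#' Layout: `sample_id` column, then one column per wavelength with the nm
#' value as header.
#'
#' @param spectra a [spectra_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_tsv <- function(spectra, path) {
  df <- data.frame(sample_id = spectra$sample_ids, spectra$spectra,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", format(spectra$wavelengths, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectra table from TSV
#'
#' @param path TSV path written by [write_spectra_tsv()].
#' @return a [spectra_table()].
#' @export
read_spectra_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl <- as.numeric(colnames(df)[-1])
  spectra_table(as.matrix(df[, -1, drop = FALSE]), wl, df$sample_id)
}
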