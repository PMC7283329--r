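# Merging significant markers into genomic segments, cross-set segment
# overlap, and the candidate-gene search around peak SNPs. Interval algebra
# is delegated to IRanges/GenomicRanges (reduce, findOverlaps); the merging
# semantics (flank, transitive merge of overlapping or abutting intervals,
# leftmost-minimum-p peak) are defined here. Coordinates are 1-based
# inclusive throughout (VCF/GFF3 convention).

markers_to_granges <- function(chrom, pos, flank, chrom_lengths = NULL) {
  start <- pmax(pos - flank, 1)
  stop <- pos + flank
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[chrom]
    if (any(is.na(len)))
      gs_stop("chrom_lengths missing for: ",
              paste(unique(chrom[is.na(len)]), collapse = ", "),
              class = "coordinate_error")
    if (any(pos > len))
      gs_stop("marker position beyond chromosome length", class = "coordinate_error")
    stop <- pmin(stop, len)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, stop))
}

#' Merge significant markers into genomic segments
#'
#' Each significant marker seeds the interval [pos - flank, pos + flank]
#' (clipped to \[1, chromosome length\]); intervals on the same chromosome that
#' overlap or abut are merged transitively. Each merged segment is summarized
#' by its peak SNP: the minimum-p marker, ties broken by smaller position.
#'
#' @param markers data.frame with columns chrom, pos, p (only significant
#'   markers; all p must be <= `p_cutoff`).
#' @param flank flank in bp on either side of a marker (default 100 kb).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   clipping and coordinate validation.
#' @param p_cutoff significance cutoff the input is checked against.
#' @param trait,environment optional labels stored on every segment.
#' @return data.frame of class `segment_table`: chrom, start, stop, peak_pos,
#'   peak_p, n_snps, trait, environment; sorted, non-overlapping per
#'   chromosome.
#' @export
define_segments <- function(markers, flank = 100e3, chrom_lengths = NULL,
                            p_cutoff = 1e-6, trait = NA_character_,
                            environment = NA_character_) {
  stopifnot(all(c("chrom", "pos", "p") %in% names(markers)))
  if (!nrow(markers)) gs_stop("no significant markers", class = "config_error")
  if (any(markers$p > p_cutoff))
    gs_stop("markers include p > cutoff ", p_cutoff, class = "config_error")
  markers <- markers[order(markers$chrom, markers$pos), , drop = FALSE]
  gr <- markers_to_granges(markers$chrom, markers$pos, flank, chrom_lengths)
  merged <- GenomicRanges::reduce(gr)   # merges overlapping and abutting
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(markers$chrom, IRanges::IRanges(markers$pos, markers$pos)),
    merged)
  seg_of <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  out <- do.call(rbind, lapply(seq_along(merged), function(s) {
    idx <- which(seg_of == s)
    mk <- markers[idx, , drop = FALSE]
    best <- idx[order(mk$p, mk$pos)[1]]
    data.frame(chrom = as.character(GenomicRanges::seqnames(merged)[s]),
               start = GenomicRanges::start(merged)[s],
               stop = GenomicRanges::end(merged)[s],
               peak_pos = markers$pos[best], peak_p = markers$p[best],
               n_snps = length(idx), stringsAsFactors = FALSE)
  }))
  out$trait <- trait
  out$environment <- environment
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("segment_table", "data.frame")
  out
}

check_sorted_disjoint <- function(seg, name) {
  for (cc in unique(seg$chrom)) {
    s <- seg[seg$chrom == cc, , drop = FALSE]
    if (is.unsorted(s$start) || any(s$start[-1] <= head(s$stop, -1)))
      gs_stop(name, " must be sorted and non-overlapping per chromosome",
              class = "contract_error")
  }
  invisible(TRUE)
}

#' Overlap two segment sets
#'
#' Reports every pair of segments (one from each set) on the same chromosome
#' whose intervals intersect in at least 1 bp, with the shared interval.
#' N-way queries ("common between several environments") are obtained by
#' iterating: overlap A with B, then the shared intervals with C.
#'
#' @param a,b segment data.frames (chrom, start, stop), each internally
#'   sorted and non-overlapping per chromosome.
#' @return data.frame: chrom, a_index, b_index, a_start, a_stop, b_start,
#'   b_stop, shared_start, shared_stop. Zero rows when nothing overlaps.
#' @export
overlap_segments <- function(a, b) {
  check_sorted_disjoint(a, "set A")
  check_sorted_disjoint(b, "set B")
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$stop))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$stop))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi))
    return(data.frame(chrom = character(0), a_index = integer(0),
                      b_index = integer(0), a_start = integer(0),
                      a_stop = integer(0), b_start = integer(0),
                      b_stop = integer(0), shared_start = integer(0),
                      shared_stop = integer(0), stringsAsFactors = FALSE))
  out <- data.frame(
    chrom = a$chrom[qi], a_index = qi, b_index = si,
    a_start = a$start[qi], a_stop = a$stop[qi],
    b_start = b$start[si], b_stop = b$stop[si],
    shared_start = pmax(a$start[qi], b$start[si]),
    shared_stop = pmin(a$stop[qi], b$stop[si]),
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$shared_start), , drop = FALSE]
}

#' Segments shared by every set
#'
#' Iterated pairwise intersection: the shared intervals of the first two
#' sets are intersected with the third, and so on.
#'
#' @param ... two or more segment data.frames.
#' @return data.frame chrom, start, stop of the n-way shared intervals.
#' @export
common_segments <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 2)
  cur <- sets[[1]][, c("chrom", "start", "stop")]
  for (i in 2:length(sets)) {
    ov <- overlap_segments(cur, sets[[i]])
    if (!nrow(ov)) return(data.frame(chrom = character(0), start = integer(0),
                                     stop = integer(0)))
    cur <- data.frame(chrom = ov$chrom, start = ov$shared_start,
                      stop = ov$shared_stop, stringsAsFactors = FALSE)
    cur <- cur[order(cur$chrom, cur$start), , drop = FALSE]
    # intersections of disjoint sets stay disjoint; merge exact duplicates
    cur <- unique(cur)
  }
  rownames(cur) <- NULL
  cur
}

#' Candidate genes around segment peak SNPs
#'
#' For each segment, lists the genes whose span intersects
#' [peak_pos - radius, peak_pos + radius] on the same chromosome. Distance is
#' 0 when the gene span contains the peak, otherwise the distance from the
#' peak to the nearer gene edge; hits are sorted by distance within segment.
#'
#' @param segments a `segment_table` from [define_segments()].
#' @param annotation gene data.frame (gene_id, chrom, start, stop, strand,
#'   description), e.g. from [read_gff3_genes()].
#' @param radius search radius around the peak SNP in bp (default 150 kb).
#' @return data.frame: segment index, chrom, peak_pos, gene_id, gene_start,
#'   gene_stop, strand, distance, description.
#' @export
candidate_genes <- function(segments, annotation, radius = 150e3) {
  seg_chr <- unique(segments$chrom)
  ann_chr <- unique(annotation$chrom)
  unmatched <- setdiff(seg_chr, ann_chr)
  if (length(unmatched))
    gs_stop("annotation lacks chromosome(s): ",
            paste(unmatched, collapse = ", "), class = "naming_error")
  win <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(pmax(segments$peak_pos - radius, 1),
                     segments$peak_pos + radius))
  genes <- GenomicRanges::GRanges(annotation$chrom,
                                  IRanges::IRanges(annotation$start, annotation$stop))
  hits <- GenomicRanges::findOverlaps(win, genes)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi))
    return(data.frame(segment = integer(0), chrom = character(0),
                      peak_pos = integer(0), gene_id = character(0),
                      gene_start = integer(0), gene_stop = integer(0),
                      strand = character(0), distance = integer(0),
                      description = character(0), stringsAsFactors = FALSE))
  peak <- segments$peak_pos[qi]
  gstart <- annotation$start[si]; gstop <- annotation$stop[si]
  dist <- ifelse(peak >= gstart & peak <= gstop, 0L,
                 pmin(abs(peak - gstart), abs(peak - gstop)))
  out <- data.frame(segment = qi, chrom = segments$chrom[qi], peak_pos = peak,
                    gene_id = annotation$gene_id[si], gene_start = gstart,
                    gene_stop = gstop, strand = annotation$strand[si],
                    distance = as.integer(dist),
                    description = annotation$description[si],
                    stringsAsFactors = FALSE)
  out <- out[order(out$segment, out$distance, out$gene_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write segments as TSV (report and BED-compatible forms)
#'
#' Emits the 1-based report (chrom, start, stop, peak SNP position, p) and,
#' when `bed` is TRUE, a 0-based half-open BED3 file alongside it.
#'
#' @param segments a `segment_table`.
#' @param path output TSV path.
#' @param bed also write `<path>.bed`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, bed = TRUE) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (bed) {
    beddf <- data.frame(segments$chrom, segments$start - 1L, segments$stop)
    write.table(beddf, paste0(path, ".bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
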