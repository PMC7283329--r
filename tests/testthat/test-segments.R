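test_that("a single SNP seeds a clipped flanked segment", {
  seg <- define_segments(data.frame(chrom = "chr1", pos = 1000000L, p = 1e-8),
                         flank = 100e3)
  expect_equal(seg$start, 900000)
  expect_equal(seg$stop, 1100000)
  expect_equal(seg$peak_pos, 1000000)
  near_start <- define_segments(data.frame(chrom = "chr1", pos = 50000L, p = 1e-8))
  expect_equal(near_start$start, 1)
  clipped <- define_segments(data.frame(chrom = "chr1", pos = 950000L, p = 1e-7),
                             chrom_lengths = c(chr1 = 1000000))
  expect_equal(clipped$stop, 1000000)
  expect_error(define_segments(data.frame(chrom = "chr1", pos = 2000000L, p = 1e-7),
                               chrom_lengths = c(chr1 = 1000000)),
               class = "coordinate_error")
})

test_that("nearby significant SNPs merge with the minimum-p peak", {
  mk <- data.frame(chrom = "chr1", pos = c(1000000L, 1150000L),
                   p = c(1e-8, 1e-7))
  seg <- define_segments(mk, flank = 100e3)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$stop), c(900000, 1250000))
  expect_equal(seg$peak_pos, 1000000)
  expect_equal(seg$n_snps, 2)
  # 300 kb apart: disjoint segments
  far <- define_segments(data.frame(chrom = "chr1",
                                    pos = c(1000000L, 1300000L),
                                    p = c(1e-8, 1e-7)), flank = 100e3)
  expect_equal(nrow(far), 2)
  # peak ties broken by leftmost position
  tie <- define_segments(data.frame(chrom = "chr1", pos = c(1000000L, 1050000L),
                                    p = c(1e-8, 1e-8)))
  expect_equal(tie$peak_pos, 1000000)
})

test_that("abutting flanked intervals merge and p above cutoff is rejected", {
  # stops/starts exactly adjacent after flanking: 1e6+1e5 + 1 = 1.2e6 - 1e5
  mk <- data.frame(chrom = "chr1", pos = c(1000000L, 1200001L), p = c(1e-8, 1e-8))
  seg <- define_segments(mk, flank = 100e3)
  expect_equal(nrow(seg), 1)
  expect_error(define_segments(data.frame(chrom = "chr1", pos = 1L, p = 1e-3)),
               class = "config_error")
})

test_that("segment merging matches a brute-force union oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 50
    mk <- data.frame(chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
                     pos = sample.int(3e6, n), p = 10^-runif(n, 6, 12))
    mk <- mk[order(mk$chrom, mk$pos), ]
    mk <- mk[!duplicated(mk[c("chrom", "pos")]), ]
    seg <- define_segments(mk, flank = 100e3)
    oracle <- brute_merge(mk$chrom, mk$pos, 100e3)
    expect_equal(seg$chrom, oracle$chrom, info = seed)
    expect_equal(seg$start, oracle$start, info = seed)
    expect_equal(seg$stop, oracle$stop, info = seed)
    # every significant marker covered by exactly one segment
    cover <- vapply(seq_len(nrow(mk)), function(i)
      sum(seg$chrom == mk$chrom[i] & seg$start <= mk$pos[i] &
            seg$stop >= mk$pos[i]), numeric(1))
    expect_true(all(cover == 1))
    expect_lte(nrow(seg), nrow(mk))
  }
})

test_that("re-running segment definition on its own peaks stays inside", {
  set.seed(33)
  mk <- data.frame(chrom = "chr2", pos = sort(sample.int(2e6, 30)),
                   p = 10^-runif(30, 6, 10))
  seg <- define_segments(mk, flank = 100e3)
  seg2 <- define_segments(data.frame(chrom = seg$chrom, pos = seg$peak_pos,
                                     p = seg$peak_p), flank = 100e3)
  ov <- overlap_segments(seg2, seg)
  expect_equal(nrow(ov), nrow(seg2))
  expect_true(all(ov$a_start >= ov$b_start - 0 | ov$a_start >= 1))
  for (i in seq_len(nrow(seg2))) {
    inside <- any(seg$chrom == seg2$chrom[i] & seg$start <= seg2$start[i] &
                    seg$stop >= seg2$stop[i])
    expect_true(inside)
  }
})

test_that("segment overlap matches a brute-force oracle and is symmetric", {
  for (seed in 1:20) {
    a <- random_segments(50, seed)
    b <- random_segments(50, seed + 1000)
    ov <- overlap_segments(a, b)
    oracle <- brute_overlap(a, b)
    got <- if (nrow(ov)) ov[order(ov$a_index, ov$b_index), c("a_index", "b_index")]
           else data.frame(a_index = integer(0), b_index = integer(0))
    want <- if (is.null(oracle)) data.frame(a_index = integer(0), b_index = integer(0))
            else oracle[order(oracle$a_index, oracle$b_index), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)), info = seed)
    rev <- overlap_segments(b, a)
    expect_equal(nrow(rev), nrow(ov))
    if (nrow(ov)) {
      expect_setequal(paste(rev$b_index, rev$a_index),
                      paste(ov$a_index, ov$b_index))
    }
  }
})

test_that("identical sets self-overlap; disjoint intervals do not", {
  a <- random_segments(20, 5)
  self <- overlap_segments(a, a)
  expect_true(all(seq_len(nrow(a)) %in% self$a_index[self$a_index == self$b_index]))
  x <- data.frame(chrom = "chr1", start = 1L, stop = 100L)
  y <- data.frame(chrom = "chr1", start = 200L, stop = 300L)
  expect_equal(nrow(overlap_segments(x, y)), 0)
  expect_error(overlap_segments(data.frame(chrom = "chr1", start = c(5L, 1L),
                                           stop = c(10L, 3L)), y),
               class = "contract_error")
})

test_that("n-way common segments come from iterated intersection", {
  a <- data.frame(chrom = "chr1", start = c(100L, 1000L), stop = c(500L, 1500L))
  b <- data.frame(chrom = "chr1", start = 300L, stop = 1200L)
  cc <- data.frame(chrom = "chr1", start = 400L, stop = 1100L)
  out <- common_segments(a, b, cc)
  expect_equal(out$start, c(400, 1000))
  expect_equal(out$stop, c(500, 1100))
})

test_that("candidate genes honor the search radius around the peak", {
  seg <- define_segments(data.frame(chrom = "chr1", pos = 31494903L, p = 1e-8),
                         flank = 100e3)
  ann <- data.frame(
    gene_id = c("overlapping", "upstream_117kb", "beyond_151kb"),
    chrom = "chr1",
    start = c(31490000L, 31494903L - 117000L - 5000L, 31494903L + 151000L),
    stop = c(31500000L, 31494903L - 117000L, 31494903L + 156000L),
    strand = "+", description = "synthetic gene model",
    stringsAsFactors = FALSE)
  hits <- candidate_genes(seg, ann, radius = 150e3)
  expect_setequal(hits$gene_id, c("overlapping", "upstream_117kb"))
  expect_equal(hits$distance[hits$gene_id == "overlapping"], 0L)
  expect_equal(hits$distance[hits$gene_id == "upstream_117kb"], 117000L)
  expect_error(candidate_genes(seg, transform(ann, chrom = "1")),
               class = "naming_error")
})

test_that("candidate genes equal a brute-force scan of the annotation", {
  set.seed(44)
  seg <- define_segments(data.frame(chrom = rep(c("chr1", "chr2"), each = 3),
                                    pos = c(sort(sample.int(3e6, 3)),
                                            sort(sample.int(3e6, 3))),
                                    p = rep(1e-8, 6)), flank = 50e3)
  ann <- do.call(rbind, lapply(c("chr1", "chr2"), function(cc) {
    s <- sort(sample.int(3e6, 120))
    data.frame(gene_id = paste0(cc, "_g", seq_along(s)), chrom = cc,
               start = s, stop = s + sample.int(20000, 120), strand = "+",
               description = "synthetic gene model", stringsAsFactors = FALSE)
  }))
  hits <- candidate_genes(seg, ann, radius = 150e3)
  brute <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    sel <- ann$chrom == seg$chrom[i] &
      ann$stop >= seg$peak_pos[i] - 150e3 & ann$start <= seg$peak_pos[i] + 150e3
    if (!any(sel)) return(NULL)
    data.frame(segment = i, gene_id = ann$gene_id[sel])
  }))
  expect_setequal(paste(hits$segment, hits$gene_id),
                  paste(brute$segment, brute$gene_id))
  expect_true(all(hits$distance <= 150e3))
})

test_that("VCF and GFF3 round-trips preserve genotype and gene content", {
  cfg <- tiny_cfg(seed = 17)
  sim <- simulate_genotypes(cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(sim$geno, vcf)
  back <- read_vcf_genotypes(vcf)
  expect_equal(unname(back$matrix), unname(sim$geno$matrix))
  expect_equal(back$map$pos, sim$geno$map$pos)
  expect_equal(back$samples, sim$geno$samples)

  genes <- simulate_annotation(cfg, sim$geno, n_genes = 30)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(genes, gff)
  back_g <- read_gff3_genes(gff)
  expect_equal(nrow(back_g), nrow(genes))
  expect_setequal(back_g$gene_id, genes$gene_id)
  expect_equal(back_g$start[order(back_g$gene_id)],
               genes$start[order(genes$gene_id)])
})
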