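gr0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

test_that("topic specificity is the in-cluster fraction of carrying cells", {
  mat <- Matrix::sparseMatrix(i = c(1, 2, 3, 1), j = c(1, 1, 2, 3), x = 1,
                              dims = c(3, 4),
                              dimnames = list(c("a", "b", "c"),
                                              paste0("p", 1:4)))
  labels <- c(1L, NA, 2L)
  expect_warning(spec <- topic_specificity(mat, labels, topic = 1),
                 "no carrying cells")
  expect_equal(unname(spec[1]), 0.5)  # one of two carriers in cluster 1
  expect_equal(unname(spec[2]), 0)    # carrier is in cluster 2
  expect_equal(unname(spec[3]), 1)    # only carrier is in cluster 1
  expect_true(is.na(spec[4]))
})

test_that("top peaks rule returns top-n or all above the floor, whichever is larger", {
  s <- setNames(seq(0.999, 0.6, length.out = 300), paste0("pk", 1:300))
  expect_length(top_topic_peaks(s, n = 250, floor = 0.5), 300)
  s2 <- setNames(c(runif(100, 0.51, 1), runif(900, 0, 0.4)),
                 paste0("pk", 1:1000))
  top <- top_topic_peaks(s2, n = 250, floor = 0.5)
  expect_length(top, 250)
  expect_true(all(paste0("pk", 1:100) %in% top))
  s3 <- setNames(runif(30), paste0("pk", 1:30))
  expect_length(top_topic_peaks(s3, n = 250), 30)
})

test_that("nearest downstream gene respects strand and the distance cap", {
  ann <- exon_annotation(chrom = c("chr1", "chr1", "chr1"),
                         start = c(2000, 2400, 500),
                         end = c(2100, 2500, 800),
                         strand = c("+", "+", "-"),
                         gene = c("gA", "gB", "gC"))
  pk <- gr0("chr1", 900, 1100)
  # + strand exon at 2000: stranded gap 900 <= 1200 -> gA (gB at 1300 loses)
  expect_equal(nearest_downstream_gene(pk, ann["gA" == ann$gene]), "gA")
  expect_equal(nearest_downstream_gene(pk, ann), "gC")
  # gC: - strand exon ending at 800, peak upstream in gene frame, gap 100
  expect_equal(nearest_downstream_gene(pk, ann[ann$gene == "gC"]), "gC")
  # beyond the cap: exon at 2400 -> gap 1300 -> none
  expect_true(is.na(nearest_downstream_gene(pk, ann[ann$gene == "gB"])))
  # brute force over all stranded distances: gC (100) < gA (900) < gB (1300)
  gaps <- c(gA = 2000 - 1100, gB = 2400 - 1100, gC = 900 - 800)
  expect_equal(nearest_downstream_gene(pk, ann),
               names(which.min(gaps[gaps <= 1200])))
})

test_that("overlapping peak-exon pairs obey the allow_overlap flag", {
  ann <- exon_annotation("chr1", 1000, 1200, "+", "gO")
  pk <- gr0("chr1", 1100, 1300)
  expect_true(is.na(nearest_downstream_gene(pk, ann, allow_overlap = FALSE)))
  expect_equal(nearest_downstream_gene(pk, ann, allow_overlap = TRUE), "gO")
})

test_that("tissue enrichment recovers planted tissue blocks and covers the null", {
  sim <- simulate_expression(n_markers_per_tissue = 30, n_housekeeping = 300,
                             tissues = paste0("t", 1:6), noise_sd = 0.15,
                             seed = 19)
  expr <- sim$expression
  muscle_genes <- names(sim$truth$marker_tissue)[sim$truth$marker_tissue == "t1"]
  res <- tissue_enrichment(muscle_genes, expr, n_random = 100,
                           sample_size = 100, seed = 20)
  expect_gt(res$log2_ratio["t1"], 1)
  expect_gt(res$ci_lower["t1"], 0)  # CI excludes 0 for the planted tissue
  # a null-drawn gene set straddles zero in >= 90% of tissues
  set.seed(21)
  null_set <- sample(rownames(expr), 100)
  res0 <- tissue_enrichment(null_set, expr, n_random = 100,
                            sample_size = 100, seed = 22)
  covers <- res0$ci_lower <= 0 & res0$ci_upper >= 0
  expect_gte(mean(covers), 0.9)
  expect_error(tissue_enrichment(character(0), expr), "empty")
})

test_that("ChIP overlap enrichment detects planted topic-TF alignment", {
  g <- genome_table("chr1", 2e5)
  set.seed(23)
  mk <- function(n, lo, hi) {
    s <- sort(sample(seq(lo, hi, by = 400), n))
    gr0("chr1", s, s + 150)
  }
  topic_peaks <- list(T1 = mk(40, 1000, 80000),
                      T2 = mk(40, 100000, 180000))
  tf <- GenomicRanges::resize(topic_peaks$T1[1:30], 200, fix = "center")
  counts <- c(T1 = 40, T2 = 40)
  res <- chip_overlap_enrichment(topic_peaks, tf, counts, n_random = 100,
                                 seed = 24)
  expect_gt(res$log2_ratio["T1"], 0.5)
  expect_gt(res$ci_lower["T1"], 0)
  expect_error(chip_overlap_enrichment(topic_peaks,
                                       GenomicRanges::GRanges(), counts),
               "empty")
})

test_that("stage z-score assignment uses the 1.5 threshold", {
  sig <- rbind(c(10, 1, 1, 1), c(2, 2, 2, 2), c(1, 1, 1, 10))
  colnames(sig) <- paste0("L", 1:4)
  sets <- assign_stages_by_zscore(sig)
  expect_equal(sets$L1, 1L)     # z = 1.5 exactly at a 1-high profile
  expect_equal(sets$L4, 3L)
  expect_true(all(lengths(sets[c("L2", "L3")]) == 0))  # flat row nowhere
})

test_that("stage enrichment is positive for a planted stage and null-symmetric", {
  g <- genome_table("chr1", 3e5)
  set.seed(25)
  universe <- gr0("chr1", seq(0, 299000, by = 600),
                  seq(0, 299000, by = 600) + 150)
  idx <- split(seq_along(universe), rep(1:4, length.out = length(universe)))
  stage_sets <- lapply(idx, function(i) universe[i])
  names(stage_sets) <- paste0("L", 1:4)
  query <- stage_sets$L2[1:60]  # planted L2 set
  res <- stage_enrichment(query, stage_sets, universe, n_random = 100,
                          seed = 26)
  expect_gt(res$log2_ratio["L2"], 1)
  # null query drawn from the universe -> CIs cover 0 in >= 90% of stages
  null_q <- universe[sample.int(length(universe), 60)]
  res0 <- stage_enrichment(null_q, stage_sets, universe, n_random = 100,
                           seed = 27)
  expect_gte(mean(res0$ci_lower <= 0 & res0$ci_upper >= 0), 0.75)
})

test_that("overlap_stats matches the hypergeometric oracle exactly", {
  g <- genome_table("chr1", 1000)
  a <- gr0("chr1", 0, 100); b <- gr0("chr1", 50, 150)
  os <- overlap_stats(a, b, g)
  expect_equal(os$a_in_b, 1)
  expect_equal(os$b_in_a, 1)
  expect_equal(unname(os$bp),
               c(50, 50, 50, 850))
  oracle <- phyper(50 - 1, 100, 900, 100, lower.tail = FALSE)
  expect_equal(os$p_value, oracle, tolerance = 1e-12)
  # A = B: full overlap, minimal p
  os2 <- overlap_stats(a, a, g)
  expect_equal(unname(os2$bp["a_only"]), 0)
  expect_lt(os2$p_value, 1e-100)
  # disjoint
  os3 <- overlap_stats(a, gr0("chr1", 500, 600), g)
  expect_equal(os3$a_in_b, 0)
  expect_error(overlap_stats(gr0("chr1", 900, 1100), b, g), "bounds")
})

test_that("signal enrichment separates true peaks from shuffles", {
  g <- genome_table("chr1", 10000)
  peaks <- gr0("chr1", c(1000, 5000), c(1300, 5300))
  base <- rep(1, 10000)
  base[1001:1300] <- 2; base[5001:5300] <- 2
  sig <- methods::as(list(chr1 = S4Vectors::Rle(base)), "SimpleRleList")
  shuf <- shuffle_peaks(peaks, g, seed = 28)
  # shuffles preserve count and widths per chromosome
  expect_length(shuf, 2)
  expect_setequal(GenomicRanges::width(shuf), GenomicRanges::width(peaks))
  expect_true(GenomicRanges::isDisjoint(shuf))
  res <- signal_enrichment_over_peaks(peaks, sig, shuf)
  expect_true(all(res$true > 0.8))
  expect_true(all(abs(res$shuffled) < 0.3, na.rm = TRUE))
  # constant signal -> all ratios 0
  flat <- methods::as(list(chr1 = S4Vectors::Rle(rep(2, 10000))),
                      "SimpleRleList")
  res0 <- signal_enrichment_over_peaks(peaks, flat, shuf)
  expect_equal(res0$true, c(0, 0))
})

test_that("tissue entropy has the closed-form values", {
  expect_equal(tissue_entropy(c(1, 0, 0)), 0)
  expect_equal(tissue_entropy(c(0.5, 0.5)), 1)
  expect_equal(tissue_entropy(rep(1, 27)), log2(27))
  expect_equal(tissue_entropy(rep(1, 27)), 4.7549, tolerance = 1e-4)
  # permutation invariance and uniform maximality
  set.seed(29)
  p <- rgamma(8, 1)
  expect_equal(tissue_entropy(p), tissue_entropy(sample(p)))
  expect_lte(tissue_entropy(p), tissue_entropy(rep(1, 8)))
  expect_error(tissue_entropy(rep(0, 5)), "zero")
})

test_that("the worked peak-diversity example scores exactly two", {
  # one gene; a non-overlapping neuron peak plus overlapping intestine and
  # pharynx peaks
  ann <- exon_annotation("chr1", 5000, 5400, "+", "gene1")
  tissue_sets <- list(
    neuron = gr0("chr1", 4300, 4450),
    intestine = gr0("chr1", 4600, 4800),
    pharynx = gr0("chr1", 4700, 4900))
  expect_equal(peak_diversity_score("gene1", tissue_sets, ann), 2L)
  # single peak from a single tissue
  expect_equal(peak_diversity_score("gene1", tissue_sets["neuron"], ann), 1L)
  # two disjoint components with identical signature count once...
  sets2 <- list(neuron = gr0("chr1", c(4300, 4600), c(4400, 4700)))
  expect_equal(peak_diversity_score("gene1", sets2, ann), 1L)
  # ...unless component counting is requested
  expect_equal(peak_diversity_score("gene1", sets2, ann,
                                    distinct_signatures = FALSE), 2L)
})

test_that("mean peak entropy averages per-peak tissue distributions", {
  ann <- exon_annotation("chr1", 5000, 5400, "+", "gene1")
  tissue_sets <- list(
    neuron = gr0("chr1", 4300, 4450),
    intestine = gr0("chr1", 4600, 4800),
    pharynx = gr0("chr1", 4700, 4900))
  # neuron peak entropy 0; intestine and pharynx peaks each overlap both -> 1
  expect_equal(mean_peak_entropy("gene1", tissue_sets, ann), (0 + 1 + 1) / 3)
  expect_equal(mean_peak_entropy("gene1", tissue_sets["neuron"], ann), 0)
  expect_warning(
    out <- mean_peak_entropy("gene1",
                             list(neuron = gr0("chr1", 100, 200)), ann),
    "no peaks linked")
  expect_true(is.na(out))
  expect_error(mean_peak_entropy("nope", tissue_sets, ann), "unknown gene")
})

test_that("marker gene cells use the stranded promoter window", {
  ann <- exon_annotation(rep("chr1", 2), c(5000, 8000), c(5500, 8500),
                         c("+", "-"), c("gPlus", "gMinus"))
  peaks <- c(gr0("chr1", 5100, 5200),   # inside gPlus body
             gr0("chr1", 3600, 3700),   # 1300 bp upstream of gPlus: excluded
             gr0("chr1", 8600, 8700),   # within 1200 bp above gMinus (- strand upstream)
             gr0("chr1", 4000, 4100))   # within 1200 bp of gPlus start
  mat <- Matrix::sparseMatrix(i = c(1, 2, 3, 4), j = c(1, 2, 3, 4), x = 1,
                              dims = c(4, 4),
                              dimnames = list(paste0("cell", 1:4),
                                              peak_ids(peaks)))
  expect_setequal(marker_gene_cells("gPlus", mat, ann),
                  c("cell1", "cell4"))
  expect_setequal(marker_gene_cells("gMinus", mat, ann), "cell3")
  expect_error(marker_gene_cells("gX", mat, ann), "unknown gene")
})

test_that("synthetic ChIP supports the non-HOT filter contract", {
  sim <- simulate_fragments(n_types = 2, cells_per_type = 10, seed = 30)
  chip <- simulate_chip(sim$truth$planted_peaks, sim$truth$genome,
                        hot_fraction = 1.0, seed = 31)
  expect_length(filter_hot_sites(chip), 0)
  chip2 <- simulate_chip(sim$truth$planted_peaks, sim$truth$genome,
                         hot_fraction = 0, seed = 31)
  expect_length(filter_hot_sites(chip2), length(chip2))
})
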