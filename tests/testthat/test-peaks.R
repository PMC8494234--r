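gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

test_that("merge_peak_sets merges overlapping and abutting intervals", {
  a <- gr("chr1", 0, 100); a$source <- "x"
  b <- gr("chr1", 50, 150); b$source <- "y"
  m <- merge_peak_sets(a, b)
  expect_length(m, 1)
  expect_equal(GenomicRanges::start(m), 1)
  expect_equal(GenomicRanges::end(m), 150)
  expect_equal(m$source, "x,y")
  # disjoint sets concatenate; result sorted and idempotent
  d1 <- gr("chr1", 500, 600); d2 <- gr("chr1", 200, 300)
  md <- merge_peak_sets(d1, d2)
  expect_equal(GenomicRanges::start(md), c(201, 501))
  m2 <- merge_peak_sets(md)
  expect_equal(GenomicRanges::granges(m2), GenomicRanges::granges(md))
})

test_that("toy multi-summit signal splits at the inter-summit minimum", {
  pk <- gr("chr1", 100, 106)
  segs <- split_multisummit(pk, c(1, 5, 1, 1, 6, 1), smooth_window = 1)
  expect_length(segs, 2)
  bed <- granges_to_bed(segs)
  # exact tiling of [100, 106)
  expect_equal(bed$start, c(100, 103))
  expect_equal(bed$end, c(103, 106))
  # boundary agrees with the brute-force valley oracle
  v <- c(1, 5, 1, 1, 6, 1)
  expect_equal(bed$end[1] - 100, valley_oracle(v, 2, 5))
  # one summit per segment, at the planted maxima
  expect_equal(segs$summit, c(101, 104))
})

test_that("single-maximum and all-zero signals leave the peak unchanged", {
  pk <- gr("chr1", 0, 10)
  one <- split_multisummit(pk, c(1, 2, 5, 2, 1, 1, 1, 1, 1, 1),
                           smooth_window = 1)
  expect_length(one, 1)
  expect_equal(GenomicRanges::width(one), 10)
  expect_warning(z <- split_multisummit(pk, rep(0, 10)), "all-zero")
  expect_length(z, 1)
})

test_that("splitting conserves covered base pairs on random signals", {
  set.seed(14)
  for (i in 1:1000) {
    w <- sample(10:60, 1)
    v <- rpois(w, 3) + rep(c(0, sample(0:20, 1), 0),
                           length.out = w)
    pk <- gr("chr1", 1000, 1000 + w)
    segs <- suppressWarnings(
      split_multisummit(pk, v, smooth_window = sample(c(1, 3, 5), 1),
                        min_prominence = runif(1, 0.05, 0.3)))
    expect_equal(sum(GenomicRanges::width(segs)), w)
    expect_true(GenomicRanges::isDisjoint(segs))
    bed <- granges_to_bed(segs)
    expect_equal(min(bed$start), 1000)
    expect_equal(max(bed$end), 1000 + w)
    # contiguous tiling
    if (nrow(bed) > 1)
      expect_equal(bed$start[-1], bed$end[-nrow(bed)])
  }
})

test_that("the built-in caller finds planted enrichment and respects the null", {
  g <- genome_table("chr1", 1e5)
  set.seed(15)
  # uniform background plus one 50x-enriched 300-bp region
  n_bg <- 2000
  bg <- data.table::data.table(chrom = "chr1",
                               start = sample.int(99940, n_bg),
                               cell = "pool")
  bg$end <- bg$start + 60L
  enr <- data.table::data.table(chrom = "chr1",
                                start = sample(50000:50240, 300,
                                               replace = TRUE),
                                cell = "pool")
  enr$end <- enr$start + 60L
  cs <- data.table::rbindlist(list(bg, enr))
  res <- call_peaks_builtin(cs, g)
  expect_length(res$peaks, 1)
  expect_true(IRanges::overlapsAny(gr("chr1", 50000, 50300), res$peaks))
  # two enriched regions separated by a cold gap -> two peaks
  enr2 <- data.table::data.table(chrom = "chr1",
                                 start = sample(20000:20200, 250, TRUE),
                                 cell = "pool")
  enr2$end <- enr2$start + 60L
  res2 <- call_peaks_builtin(data.table::rbindlist(list(bg, enr, enr2)), g)
  expect_length(res2$peaks, 2)
  # treatment = control -> no peaks
  res3 <- call_peaks_builtin(cs, g, control = cs)
  expect_length(res3$peaks, 0)
  # zero cut sites -> empty set
  expect_length(call_peaks_builtin(cs[0], g)$peaks, 0)
})

test_that("the caller's per-window false-positive rate under the null stays below q", {
  g <- genome_table("chr1", 2e4)
  set.seed(16)
  fp <- vapply(1:100, function(i) {
    cs <- data.table::data.table(chrom = "chr1",
                                 start = sample.int(19940, 400),
                                 cell = "pool")
    cs$end <- cs$start + 60L
    res <- call_peaks_builtin(cs, g, control = cs)
    length(res$peaks)
  }, numeric(1))
  n_windows <- length(seq(1, 2e4 - 150 + 1, by = 75))
  expect_lte(mean(fp) / n_windows, 0.05)
})

test_that("narrowPeak and bedGraph round trips are lossless", {
  pk <- gr("chr1", c(100, 400), c(250, 600))
  pk$name <- c("p1", "p2"); pk$score <- c(10, 20)
  pk$signalValue <- c(1.5, 2.5); pk$pValue <- c(3, 4); pk$qValue <- c(2, 3)
  pk$summit <- c(170L, 500L)
  f <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, f)
  back <- read_narrowpeak(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pk))
  expect_equal(back$summit, pk$summit)
  expect_equal(back$qValue, pk$qValue)
  g <- genome_table("chr1", 1000)
  sig <- methods::as(list(chr1 = S4Vectors::Rle(c(rep(0, 100), rep(2.5, 50),
                                                  rep(0, 850)))),
                     "SimpleRleList")
  fb <- tempfile(fileext = ".bdg")
  write_bedgraph(sig, fb)
  sig2 <- read_bedgraph(fb, g)
  expect_equal(as.numeric(sig2$chr1), as.numeric(sig$chr1))
})

test_that("the external caller errors helpfully when MACS2 is missing", {
  if (Sys.which("macs2") != "") skip("MACS2 present; adapter would run")
  expect_error(call_peaks_external("x.bed", macs2 = "macs2"),
               "built-in")
})

test_that("run_iteration recovers planted structure end to end", {
  sim <- simulate_fragments(n_types = 2, cells_per_type = 80,
                            shared_peaks = 10, strong_peaks_per_type = 10,
                            weak_peaks_per_type = 5, seed = 17)
  genome <- sim$truth$genome
  cs <- fragments_to_cutsites(deduplicate_fragments(sim$fragments), genome)
  bulk <- call_peaks_builtin(cs, genome)
  cfg <- lda_config(K = 3, alpha = 3, beta = 0.06 * length(bulk$peaks),
                    iterations = 300, burn_in = 150, sample_stride = 10,
                    seed = 18)
  it <- suppressWarnings(run_iteration(cs, bulk$peaks, genome, cfg,
                                       min_grow = 100, min_keep = 30,
                                       engine = "pca"))
  expect_equal(it$stats$n_clusters, 2)
  lab <- it$clustering$labels
  truth <- sim$truth$cell_type[names(lab)]
  ok <- !is.na(lab)
  expect_gt(mclust::adjustedRandIndex(lab[ok], truth[ok]), 0.95)
  expect_gt(length(it$peaks), 0)
  expect_error(run_iteration(cs[0], bulk$peaks, genome, cfg), "empty")
})
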