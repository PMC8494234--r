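#' Simulate a planted-cell-type binary cells-by-peaks matrix
#'
#' Cells belong to one of `n_types` planted types. A cell detects each of
#' its own type's specific peaks with probability `detect_rate_specific`,
#' every other type's specific peak with `detect_rate_background`, and each
#' shared peak with `detect_rate_specific`; detections are independent
#' Bernoulli draws given the labels. The defaults are the desk-scale
#' preset: recovery by LDA is achievable but not trivial.
#'
#' @param n_cells total cells (default 600).
#' @param n_types planted types (default 5).
#' @param peaks_per_type specific peaks per type (default 80).
#' @param shared_peaks peaks accessible to all types (default 100).
#' @param detect_rate_specific detection rate for a cell's own peaks
#'   (default 0.35).
#' @param detect_rate_background cross-type detection rate (default 0.01).
#' @param seed RNG seed.
#' @return list with `matrix` (binary sparse, cells x peaks) and `truth`
#'   (class `synthetic_truth`: per-cell type labels, per-peak type labels,
#'   parameters, seed).
#' @export
simulate_matrix <- function(n_cells = 600, n_types = 5, peaks_per_type = 80,
                            shared_peaks = 100,
                            detect_rate_specific = 0.35,
                            detect_rate_background = 0.01, seed = 1) {
  stopifnot(detect_rate_specific >= 0, detect_rate_specific <= 1,
            detect_rate_background >= 0, detect_rate_background <= 1)
  if (detect_rate_specific == 0 && detect_rate_background == 0)
    stop("all detection rates are zero; expected density is zero")
  set.seed(seed)
  type <- rep(seq_len(n_types), length.out = n_cells)
  n_peaks <- n_types * peaks_per_type + shared_peaks
  peak_type <- c(rep(seq_len(n_types), each = peaks_per_type),
                 rep(0L, shared_peaks))  # 0 = shared
  rate <- matrix(detect_rate_background, n_cells, n_peaks)
  for (t in seq_len(n_types))
    rate[type == t, peak_type == t] <- detect_rate_specific
  rate[, peak_type == 0L] <- detect_rate_specific
  hits <- matrix(rbinom(n_cells * n_peaks, 1, as.vector(rate)),
                 n_cells, n_peaks)
  cells <- sprintf("cell_%04d", seq_len(n_cells))
  peaks <- sprintf("peak_%04d", seq_len(n_peaks))
  mat <- methods::as(Matrix::Matrix(hits, sparse = TRUE,
                                    dimnames = list(cells, peaks)),
                     "CsparseMatrix")
  truth <- structure(list(cell_type = setNames(type, cells),
                          peak_type = setNames(peak_type, peaks),
                          params = list(n_cells = n_cells, n_types = n_types,
                                        peaks_per_type = peaks_per_type,
                                        shared_peaks = shared_peaks,
                                        detect_rate_specific = detect_rate_specific,
                                        detect_rate_background = detect_rate_background),
                          seed = seed),
                     class = "synthetic_truth")
  list(matrix = mat, truth = truth)
}

# place n non-overlapping equal-width intervals uniformly on a genome,
# keeping at least one width of clear space between them
place_planted_peaks <- function(genome, n, width) {
  chroms <- names(genome)
  per_chrom <- table(factor(sample(chroms, n, replace = TRUE,
                                   prob = genome / sum(genome)),
                            levels = chroms))
  ch_out <- character(0); s_out <- integer(0)
  for (ch in chroms) {
    need <- per_chrom[[ch]]
    if (need == 0) next
    len <- genome[[ch]]
    starts <- integer(0)
    while (length(starts) < need) {
      s <- sample.int(len - width + 1L, 1)
      if (all(abs(starts - s) >= 2L * width)) starts <- c(starts, s)
    }
    ch_out <- c(ch_out, rep(ch, need)); s_out <- c(s_out, starts)
  }
  gr <- GenomicRanges::GRanges(ch_out,
                               IRanges::IRanges(s_out, s_out + width - 1L))
  GenomeInfoDb::seqlevels(gr) <- chroms
  GenomeInfoDb::seqlengths(gr) <- as.numeric(genome)
  GenomicRanges::sort(gr)
}

#' Simulate per-cell fragment streams over a toy genome
#'
#' Each planted type has shared peaks (accessible to all types) plus
#' strong- and weak-specific peaks; a cell draws `frags_per_cell`
#' fragments, each landing inside one of the cell's accessible peaks with
#' probability `p_in` (choosing a peak with probability proportional to its
#' strength) and uniformly on the genome otherwise. Fragment lengths are
#' lognormal. The three strength classes make the
#' iterative pipeline's planted condition hold by construction: weak
#' specific peaks sit below the bulk caller's detection limit but above the
#' pseudobulk (per-cluster) limit. Depth per cell is desk-scale and
#' configurable.
#'
#' @param genome a [genome_table()]; default three 200-kb chromosomes.
#' @param n_types planted cell types (default 3).
#' @param cells_per_type cells per type (default 150).
#' @param frags_per_cell fragments per cell (default 60).
#' @param p_in probability a fragment lands in an accessible peak
#'   (default 0.4).
#' @param shared_peaks,strong_peaks_per_type,weak_peaks_per_type planted
#'   peak counts (defaults 20, 15, 15).
#' @param peak_width planted peak width in bp (default 150).
#' @param strength relative per-fragment weights for the shared, strong,
#'   and weak classes (default c(3, 2, 0.5)).
#' @param meanlog,sdlog fragment-length lognormal parameters (defaults give
#'   ~80 bp sub-nucleosomal fragments).
#' @param seed RNG seed.
#' @return list with `fragments` (data.table chrom, start, end, barcode)
#'   and `truth` (cell types, planted peak GRanges with `class` and `type`
#'   columns, parameters, seed).
#' @export
simulate_fragments <- function(genome = genome_table(c("chrI", "chrII", "chrIII"),
                                                     c(2e5, 2e5, 2e5)),
                               n_types = 3, cells_per_type = 150,
                               frags_per_cell = 60, p_in = 0.4,
                               shared_peaks = 20, strong_peaks_per_type = 15,
                               weak_peaks_per_type = 15, peak_width = 150,
                               strength = c(shared = 3, strong = 2,
                                            weak = 0.5),
                               meanlog = 4.4, sdlog = 0.3, seed = 1) {
  set.seed(seed)
  n_planted <- shared_peaks + n_types * (strong_peaks_per_type +
                                           weak_peaks_per_type)
  planted <- place_planted_peaks(genome, n_planted, peak_width)
  idx <- sample(length(planted))  # random genomic placement per class
  cls <- c(rep("shared", shared_peaks),
           rep(rep(c("strong", "weak"),
                   c(strong_peaks_per_type, weak_peaks_per_type)), n_types))
  typ <- c(rep(0L, shared_peaks),
           rep(seq_len(n_types), each = strong_peaks_per_type +
                 weak_peaks_per_type))
  planted$class <- cls[order(idx)]
  planted$type <- typ[order(idx)]
  n_cells <- n_types * cells_per_type
  cell_type <- rep(seq_len(n_types), each = cells_per_type)
  barcodes <- sprintf("BC%04d", seq_len(n_cells))
  chrom_names <- as.character(GenomicRanges::seqnames(planted))
  peak_start0 <- GenomicRanges::start(planted) - 1L
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    t <- cell_type[i]
    acc <- which(planted$type == 0L | planted$type == t)
    w <- strength[planted$class[acc]]
    n <- frags_per_cell
    in_peak <- runif(n) < p_in
    n_in <- sum(in_peak)
    len <- pmax(20L, as.integer(round(rlnorm(n, meanlog, sdlog))))
    chrom <- character(n); start <- integer(n)
    if (n_in > 0) {
      pk <- acc[sample.int(length(acc), n_in, replace = TRUE, prob = w)]
      centers <- peak_start0[pk] +
        sample.int(peak_width, n_in, replace = TRUE) - 1L
      chrom[in_peak] <- chrom_names[pk]
      start[in_peak] <- centers - len[in_peak] %/% 2L
    }
    n_bg <- n - n_in
    if (n_bg > 0) {
      ch <- sample(names(genome), n_bg, replace = TRUE,
                   prob = genome / sum(genome))
      chrom[!in_peak] <- ch
      start[!in_peak] <- floor(runif(n_bg) * (genome[ch] - len[!in_peak]))
    }
    start <- pmax(start, 0L)
    end <- pmin(start + len, as.integer(genome[chrom]))
    start <- pmin(start, end - 1L)
    rows[[i]] <- data.table::data.table(chrom = chrom, start = start,
                                        end = end, barcode = barcodes[i])
  }
  fragments <- data.table::rbindlist(rows)
  data.table::setorder(fragments, chrom, start, end, barcode)
  truth <- structure(list(cell_type = setNames(cell_type, barcodes),
                          planted_peaks = planted,
                          params = list(n_types = n_types,
                                        cells_per_type = cells_per_type,
                                        frags_per_cell = frags_per_cell,
                                        p_in = p_in,
                                        strength = strength,
                                        peak_width = peak_width),
                          genome = genome, seed = seed),
                     class = "synthetic_truth")
  list(fragments = fragments, truth = truth)
}

#' Simulate a genes x tissues expression table
#'
#' Tissue-exclusive marker genes have expression concentrated in one
#' tissue; housekeeping genes are uniform across tissues; all values get
#' multiplicative lognormal noise.
#'
#' @param n_markers_per_tissue exclusive genes per tissue (default 20).
#' @param n_housekeeping uniform genes (default 200).
#' @param tissues tissue names (default 27 generic tissues).
#' @param base_tpm expression scale (default 100).
#' @param noise_sd sdlog of the multiplicative noise (default 0.2; 0 for
#'   exact block structure).
#' @param seed RNG seed.
#' @return list with `expression` (matrix, gene rownames, tissue colnames)
#'   and `truth` (marker-gene tissue map).
#' @export
simulate_expression <- function(n_markers_per_tissue = 20,
                                n_housekeeping = 200,
                                tissues = paste0("tissue_", seq_len(27)),
                                base_tpm = 100, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  n_t <- length(tissues)
  n_m <- n_markers_per_tissue * n_t
  genes <- c(sprintf("marker_%03d", seq_len(n_m)),
             sprintf("hk_%03d", seq_len(n_housekeeping)))
  marker_tissue <- rep(seq_len(n_t), each = n_markers_per_tissue)
  expr <- matrix(0, length(genes), n_t, dimnames = list(genes, tissues))
  expr[cbind(seq_len(n_m), marker_tissue)] <- base_tpm
  expr[(n_m + 1):length(genes), ] <- base_tpm / n_t
  if (noise_sd > 0)
    expr <- expr * matrix(rlnorm(length(expr), 0, noise_sd), nrow(expr))
  truth <- structure(list(marker_tissue = setNames(tissues[marker_tissue],
                                                   genes[seq_len(n_m)]),
                          seed = seed),
                     class = "synthetic_truth")
  list(expression = expr, truth = truth)
}

#' Simulate TF ChIP-like interval sets with occupancy and stage labels
#'
#' A configurable fraction of the planted tissue peaks is covered by
#' same-tissue TF intervals; decoy intervals are placed uniformly; a
#' fraction of all intervals is marked as high-occupancy-target (HOT,
#' occupancy >= 41), which the non-HOT filter removes.
#'
#' @param planted_peaks GRanges with a `type` column (0 = shared).
#' @param genome a [genome_table()].
#' @param fraction_covered fraction of planted type peaks covered
#'   (default 0.8).
#' @param decoy_count uniformly placed decoys (default 50).
#' @param hot_fraction fraction of intervals marked HOT (default 0.1).
#' @param stages stage labels cycled over intervals (default L1-L4).
#' @param width ChIP interval width (default 200).
#' @param seed RNG seed.
#' @return GRanges with `occupancy`, `stage`, and `tissue` columns (tissue
#'   NA for decoys).
#' @export
simulate_chip <- function(planted_peaks, genome, fraction_covered = 0.8,
                          decoy_count = 50, hot_fraction = 0.1,
                          stages = c("L1", "L2", "L3", "L4"),
                          width = 200, seed = 1) {
  set.seed(seed)
  typed <- planted_peaks[planted_peaks$type != 0L]
  n_cover <- round(fraction_covered * length(typed))
  covered <- if (n_cover > 0) {
    sel <- sort(sample.int(length(typed), n_cover))
    g <- GenomicRanges::resize(GenomicRanges::granges(typed[sel]), width,
                               fix = "center")
    g <- GenomicRanges::trim(g)
    g$tissue <- typed$type[sel]
    g
  } else GenomicRanges::GRanges(tissue = integer(0))
  decoys <- if (decoy_count > 0) {
    ch <- sample(names(genome), decoy_count, replace = TRUE,
                 prob = genome / sum(genome))
    s <- vapply(ch, function(c) sample.int(genome[[c]] - width, 1),
                numeric(1))
    g <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + width - 1L))
    g$tissue <- NA_integer_
    g
  } else GenomicRanges::GRanges(tissue = integer(0))
  chip <- c(covered, decoys)
  n <- length(chip)
  hot <- runif(n) < hot_fraction
  chip$occupancy <- ifelse(hot, 41L + as.integer(rpois(n, 10)),
                           as.integer(rpois(n, 5)))
  chip$stage <- sample(stages, n, replace = TRUE)
  GenomicRanges::sort(chip)
}

#' Remove high-occupancy-target (HOT) ChIP intervals
#' @param chip GRanges with an `occupancy` column.
#' @param max_other_experiments intervals bound in more than this many
#'   other experiments are removed (default 40, i.e. keep occupancy <= 40).
#' @return filtered GRanges.
#' @export
filter_hot_sites <- function(chip, max_other_experiments = 40) {
  chip[chip$occupancy <= max_other_experiments]
}
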