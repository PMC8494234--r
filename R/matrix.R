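#' Peak identifier strings
#' @param peaks GRanges.
#' @return character vector "chrom:start-end" (0-based half-open).
#' @export
peak_ids <- function(peaks) {
  paste0(as.character(GenomicRanges::seqnames(peaks)), ":",
         GenomicRanges::start(peaks) - 1L, "-", GenomicRanges::end(peaks))
}

#' Parse peak identifier strings back to GRanges
#' @param ids character "chrom:start-end".
#' @return GRanges.
#' @export
parse_peak_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(vapply(m, length, integer(1)) != 4)
  if (length(bad) > 0) stop("malformed peak id: ", ids[bad[1]])
  GenomicRanges::GRanges(
    seqnames = vapply(m, `[`, character(1), 2),
    ranges = IRanges::IRanges(
      start = as.integer(vapply(m, `[`, character(1), 3)) + 1L,
      end = as.integer(vapply(m, `[`, character(1), 4))))
}

#' Build the binary cells-by-peaks matrix
#'
#' Entry (cell, peak) is 1 iff at least one cut site of the cell overlaps
#' the peak by >= 1 bp; multiplicity is ignored.
#'
#' @param cutsites data.table of cut sites (chrom, start, end, cell).
#' @param peaks GRanges of non-overlapping (merged) peaks.
#' @return binary sparse `dgCMatrix`, rows = cells (sorted), columns =
#'   peak ids in `peaks` order.
#' @export
build_matrix <- function(cutsites, peaks) {
  if (length(peaks) == 0) stop("peak set is empty")
  if (!GenomicRanges::isDisjoint(peaks))
    stop("peaks overlap; merge them first (see merge_peak_sets)")
  cs <- bed_to_granges(cutsites)
  cells <- sort(unique(cutsites$cell))
  hits <- GenomicRanges::findOverlaps(cs, peaks)
  i <- match(cutsites$cell[S4Vectors::queryHits(hits)], cells)
  j <- S4Vectors::subjectHits(hits)
  mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(cells), length(peaks)),
                              dimnames = list(cells, peak_ids(peaks)))
  mat@x[] <- 1
  methods::as(mat, "CsparseMatrix")
}

sigmoid_kernel <- function(kernel_width) {
  k <- plogis(seq(-6, 6, length.out = kernel_width))
  k - mean(k)
}

#' Change-point filter for sorted per-item fractions
#'
#' Items are sorted ascending, mean-centered, and convolved with a
#' zero-centered sigmoid-shaped kernel (a smoothed slope detector). The
#' removal threshold is `mean(conv) + 4 * IQR(conv)`. On each requested
#' extreme, the change point is the position of the maximal
#' above-threshold response (the slope jump); items beyond it are flagged.
#' Edge-replicated padding gives one centered convolution value per item.
#' A degenerate all-tied response (IQR = 0, e.g. constant input) flags
#' nothing.
#'
#' @param values named numeric vector of per-item fractions.
#' @param kernel_width odd kernel length (default 101).
#' @param side which extreme(s) to examine: "low", "high", or "both".
#' @return list of class `changepoint_result`: `sorted`, `conv`,
#'   `threshold`, `kept_range` (index range kept in sorted order),
#'   `removed` (item names or indices), `side`.
#' @export
changepoint_filter <- function(values, kernel_width = 101,
                               side = c("both", "low", "high")) {
  side <- match.arg(side)
  n <- length(values)
  ids <- if (is.null(names(values))) as.character(seq_len(n)) else names(values)
  if (kernel_width %% 2 == 0) kernel_width <- kernel_width + 1L
  if (n < kernel_width) {
    warning("fewer items (", n, ") than kernel_width (", kernel_width,
            "); no filtering applied")
    return(structure(list(sorted = sort(values), conv = numeric(0),
                          threshold = NA_real_, kept_range = c(1L, n),
                          removed = character(0), side = side),
                     class = "changepoint_result"))
  }
  ord <- order(values)
  sorted <- values[ord]
  centered <- sorted - mean(sorted)
  hw <- (kernel_width - 1L) %/% 2L
  padded <- c(rep(centered[1], hw), centered, rep(centered[n], hw))
  kern <- sigmoid_kernel(kernel_width)
  # exact cross-correlation: conv[i] = sum_j kern[j] * padded[i + j - 1]
  conv <- as.vector(embed_rows(padded, kernel_width) %*% kern)
  iqr <- IQR(conv)
  threshold <- mean(conv) + 4 * iqr
  exceed <- if (iqr > 0) conv > threshold else rep(FALSE, n)
  removed_idx <- integer(0)
  lo_kept <- 1L
  hi_kept <- n
  half <- ceiling(n / 2)
  if (side %in% c("high", "both")) {
    cand <- which(exceed & seq_len(n) > half)
    if (length(cand) > 0) {
      cp <- cand[which.max(conv[cand])]  # ties -> smallest index (which.max)
      if (cp < n) {
        removed_idx <- c(removed_idx, seq(cp + 1L, n))
        hi_kept <- cp
      }
    }
  }
  if (side %in% c("low", "both")) {
    cand <- which(exceed & seq_len(n) <= half)
    if (length(cand) > 0) {
      mx <- max(conv[cand])
      cp <- max(cand[conv[cand] == mx])  # ties -> largest index
      if (cp > 1) {
        removed_idx <- c(removed_idx, seq(1L, cp - 1L))
        lo_kept <- cp
      }
    }
  }
  structure(list(sorted = sorted, conv = conv, threshold = threshold,
                 kept_range = c(lo_kept, hi_kept),
                 removed = ids[ord][removed_idx], side = side),
            class = "changepoint_result")
}

# rows of the sliding-window embedding, in left-to-right order
embed_rows <- function(x, width) {
  n <- length(x) - width + 1L
  idx <- outer(seq_len(n), seq_len(width) - 1L, `+`)
  matrix(x[idx], nrow = n)
}

#' Filter outlier cells and peaks from the binary matrix
#'
#' Applies the change-point filter to per-cell peak fractions (low side:
#' near-empty cells) and per-peak cell fractions (both sides: peaks in very
#' few or very many cells), then drops any all-zero rows and columns.
#'
#' @param mat binary cells-by-peaks sparse matrix.
#' @param kernel_width convolution kernel length (default 101).
#' @return list with `matrix` (filtered) and `report` (removed cells/peaks
#'   with reasons).
#' @export
filter_matrix <- function(mat, kernel_width = 101) {
  cell_frac <- Matrix::rowSums(mat) / ncol(mat)
  names(cell_frac) <- rownames(mat)
  peak_frac <- Matrix::colSums(mat) / nrow(mat)
  names(peak_frac) <- colnames(mat)
  cell_cp <- changepoint_filter(cell_frac, kernel_width, side = "low")
  peak_cp <- changepoint_filter(peak_frac, kernel_width, side = "both")
  keep_cells <- setdiff(rownames(mat), cell_cp$removed)
  keep_peaks <- setdiff(colnames(mat), peak_cp$removed)
  out <- mat[keep_cells, keep_peaks, drop = FALSE]
  zero_rows <- rownames(out)[Matrix::rowSums(out) == 0]
  zero_cols <- colnames(out)[Matrix::colSums(out) == 0]
  if (length(zero_rows) > 0 || length(zero_cols) > 0)
    out <- out[Matrix::rowSums(out) > 0, Matrix::colSums(out) > 0,
               drop = FALSE]
  report <- list(
    removed_cells = data.frame(
      id = c(cell_cp$removed, zero_rows),
      reason = c(rep("low-coverage outlier", length(cell_cp$removed)),
                 rep("all-zero after filtering", length(zero_rows)))),
    removed_peaks = data.frame(
      id = c(peak_cp$removed, zero_cols),
      reason = c(rep("coverage outlier", length(peak_cp$removed)),
                 rep("all-zero after filtering", length(zero_cols)))),
    cell_changepoint = cell_cp,
    peak_changepoint = peak_cp)
  list(matrix = out, report = report)
}

#' Write a cells-by-peaks matrix directory
#'
#' MatrixMarket coordinate file plus sidecar identifier lists
#' (`matrix.mtx`, `cells.txt`, `peaks.txt`).
#'
#' @param mat binary sparse matrix with dimnames.
#' @param dir output directory (created).
#' @export
write_matrix_dir <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat, file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "cells.txt"))
  writeLines(colnames(mat), file.path(dir, "peaks.txt"))
  invisible(dir)
}

#' Read a cells-by-peaks matrix directory
#' @param dir directory written by [write_matrix_dir()].
#' @return binary sparse dgCMatrix.
#' @export
read_matrix_dir <- function(dir) {
  mat <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  mat <- methods::as(methods::as(mat, "dMatrix"), "CsparseMatrix")
  dimnames(mat) <- list(readLines(file.path(dir, "cells.txt")),
                        readLines(file.path(dir, "peaks.txt")))
  mat@x[] <- 1
  mat
}
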