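#' Read a narrowPeak file
#' @param path narrowPeak (BED6+4) path.
#' @return GRanges with mcols name, score, signalValue, pValue, qValue,
#'   summit (absolute bp, 0-based, NA when -1).
#' @export
read_narrowpeak <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) != 10) stop("narrowPeak file must have 10 columns: ", path)
  data.table::setnames(dt, cols)
  gr <- GenomicRanges::GRanges(dt$chrom,
                               IRanges::IRanges(dt$start + 1L, dt$end))
  gr$name <- dt$name; gr$score <- dt$score
  gr$signalValue <- dt$signalValue
  gr$pValue <- dt$pValue; gr$qValue <- dt$qValue
  gr$summit <- ifelse(dt$peak < 0, NA_integer_, dt$start + dt$peak)
  gr
}

#' Write a narrowPeak file
#' @param peaks GRanges; missing mcols are filled with narrowPeak defaults.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- length(peaks)
  gv <- function(col, default) {
    if (!is.null(mcols(peaks)[[col]])) mcols(peaks)[[col]] else rep(default, n)
  }
  summit <- gv("summit", NA_integer_)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = gv("name", "."), score = gv("score", 0), strand = ".",
    signalValue = gv("signalValue", 0), pValue = gv("pValue", -1),
    qValue = gv("qValue", -1),
    peak = ifelse(is.na(summit), -1L,
                  as.integer(summit) - (GenomicRanges::start(peaks) - 1L)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph into a per-base signal track
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @param genome a [genome_table()].
#' @return RleList of per-base values, one element per chromosome.
#' @export
read_bedgraph <- function(path, genome) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  out <- lapply(names(genome), function(ch) {
    v <- numeric(genome[[ch]])
    sub <- dt[dt$chrom == ch, ]
    for (i in seq_len(nrow(sub)))
      v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
    S4Vectors::Rle(v)
  })
  names(out) <- names(genome)
  methods::as(out, "SimpleRleList")
}

#' Write a per-base signal track as bedGraph
#' @param signal RleList keyed by chromosome.
#' @param path output path.
#' @export
write_bedgraph <- function(signal, path) {
  rows <- list()
  for (ch in names(signal)) {
    r <- signal[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, head(ends, -1))
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    rows[[ch]] <- data.table::data.table(chrom = ch, start = starts[keep],
                                         end = ends[keep],
                                         value = vals[keep])
  }
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Call peaks with the external MACS2 adapter
#'
#' Invokes MACS2 on a cut-site BED with the flag set used throughout the
#' pipeline (`--format BED -g <genome size> --nomodel --qvalue 0.05 --SPMR
#' --tsize 60 --bdg --keep-dup all --call-summits`), optionally with a
#' naked-DNA control, and parses the narrowPeak and bedGraph outputs.
#'
#' @param cutsites_bed path to the treatment cut-site BED.
#' @param control_bed optional control cut-site BED; when NULL MACS2 runs
#'   without a control (logged).
#' @param genome_size effective genome size (default 9e7, the worm).
#' @param genome a [genome_table()] used to expand the signal bedGraph.
#' @param name run name (output prefix).
#' @param outdir output directory.
#' @param macs2 MACS2 executable name or path.
#' @return list with `peaks` (GRanges) and `signal` (RleList), as from the
#'   built-in caller.
#' @export
call_peaks_external <- function(cutsites_bed, control_bed = NULL,
                                genome_size = 9e7, genome = NULL,
                                name = "scitopic", outdir = tempdir(),
                                macs2 = "macs2") {
  if (Sys.which(macs2) == "")
    stop("MACS2 executable not found; use call_peaks_builtin() for the ",
         "built-in desk-scale caller")
  args <- c("callpeak", "-t", cutsites_bed, "--format", "BED",
            "-g", format(genome_size, scientific = FALSE),
            "--nomodel", "--qvalue", "0.05", "--SPMR", "--tsize", "60",
            "--bdg", "--keep-dup", "all", "--call-summits",
            "-n", name, "--outdir", outdir)
  if (is.null(control_bed)) {
    message("no control provided; running MACS2 without a control")
  } else {
    args <- c(args, "-c", control_bed)
  }
  status <- system2(macs2, args, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("MACS2 exited with status ", status)
  np <- file.path(outdir, paste0(name, "_peaks.narrowPeak"))
  if (!file.exists(np)) stop("MACS2 produced no narrowPeak output at ", np)
  peaks <- read_narrowpeak(np)
  signal <- NULL
  bdg <- file.path(outdir, paste0(name, "_treat_pileup.bdg"))
  if (file.exists(bdg) && !is.null(genome))
    signal <- read_bedgraph(bdg, genome)
  list(peaks = peaks, signal = signal)
}

#' Built-in desk-scale peak caller
#'
#' A windowed Poisson enrichment caller for pooled cut sites: cut-site
#' counts in sliding windows are tested against the maximum of the global
#' rate, a 10-kb local background, and a (depth-scaled) control rate;
#' Benjamini-Hochberg correction is applied over windows, and adjacent
#' significant windows are merged into peaks. This is a deliberately simple
#' stand-in for a dedicated peak caller at desk scale, not a MACS2
#' reimplementation.
#'
#' @param cutsites data.table of cut sites.
#' @param genome a [genome_table()].
#' @param control optional control cut sites (e.g. from naked DNA).
#' @param window window width in bp (default 150).
#' @param step window step in bp (default 75).
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @param local_bg local background width in bp (default 10000).
#' @param source label recorded on the returned peaks (default "bulk").
#' @return list with `peaks` (GRanges with summit, score = -log10 q,
#'   source) and `signal` (per-base coverage RleList).
#' @export
call_peaks_builtin <- function(cutsites, genome, control = NULL,
                               window = 150, step = 75, q_threshold = 0.05,
                               local_bg = 10000, source = "bulk") {
  empty <- GenomicRanges::GRanges()
  if (nrow(cutsites) == 0)
    return(list(peaks = empty, signal = NULL))
  cs <- bed_to_granges(cutsites, genome)
  signal <- GenomicRanges::coverage(cs)
  wins <- make_windows(genome, window, step)
  counts <- GenomicRanges::countOverlaps(wins, cs)
  lambda_global <- mean(counts)
  big <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::resize(wins, local_bg,
                                              fix = "center")))
  lambda_local <- GenomicRanges::countOverlaps(big, cs) *
    (GenomicRanges::width(wins) / GenomicRanges::width(big))
  lambda <- pmax(lambda_global, lambda_local)
  if (!is.null(control) && nrow(control) > 0) {
    ctrl <- bed_to_granges(control, genome)
    scale <- length(cs) / length(ctrl)
    # control rate at both window and local resolution (scaled to depth)
    ctrl_win <- GenomicRanges::countOverlaps(wins, ctrl) * scale
    ctrl_local <- GenomicRanges::countOverlaps(big, ctrl) * scale *
      (GenomicRanges::width(wins) / GenomicRanges::width(big))
    lambda <- pmax(lambda, ctrl_win, ctrl_local)
  }
  p <- ppois(counts - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- q <= q_threshold & counts > 0
  if (!any(sig))
    return(list(peaks = empty, signal = signal))
  peaks <- GenomicRanges::reduce(wins[sig])
  # summit and score per merged peak
  summit <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    ch <- as.character(GenomicRanges::seqnames(peaks))[i]
    s <- GenomicRanges::start(peaks)[i]; e <- GenomicRanges::end(peaks)[i]
    v <- as.numeric(signal[[ch]][s:e])
    summit[i] <- s + which.max(v) - 2L  # 0-based absolute position
  }
  ov <- GenomicRanges::findOverlaps(wins[sig], peaks)
  minq <- tapply(q[sig][S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), min)
  peaks$summit <- summit
  peaks$score <- -log10(pmax(as.numeric(minq), 1e-300))
  peaks$source <- source
  list(peaks = peaks, signal = signal)
}

make_windows <- function(genome, window, step) {
  per_chrom <- lapply(names(genome), function(ch) {
    starts <- seq(1, max(1, genome[[ch]] - window + 1), by = step)
    list(chrom = rep(ch, length(starts)), start = starts,
         end = pmin(starts + window - 1, genome[[ch]]))
  })
  out <- GenomicRanges::GRanges(
    unlist(lapply(per_chrom, `[[`, "chrom")),
    IRanges::IRanges(unlist(lapply(per_chrom, `[[`, "start")),
                     unlist(lapply(per_chrom, `[[`, "end"))))
  GenomeInfoDb::seqlevels(out) <- names(genome)
  GenomeInfoDb::seqlengths(out) <- as.numeric(genome)
  out
}

#' Merge peak sets into a single non-overlapping set
#'
#' Overlapping or abutting intervals are merged; contributing source labels
#' are concatenated (comma-joined, unique).
#'
#' @param ... GRanges peak sets, or a single list of them.
#' @return sorted, disjoint GRanges with a `source` column.
#' @export
merge_peak_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !methods::is(sets[[1]], "GRanges"))
    sets <- sets[[1]]
  sets <- Filter(function(g) length(g) > 0, sets)
  if (length(sets) == 0) return(GenomicRanges::GRanges())
  all_gr <- do.call(c, lapply(sets, function(g) {
    src <- if (!is.null(g$source)) as.character(g$source)
           else rep(".", length(g))
    gr <- GenomicRanges::granges(g)
    gr$source <- src
    gr
  }))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_gr))
  ov <- GenomicRanges::findOverlaps(all_gr, merged)
  src <- tapply(all_gr$source[S4Vectors::queryHits(ov)],
                S4Vectors::subjectHits(ov),
                function(s) paste(sort(unique(s)), collapse = ","))
  merged$source <- as.character(src[as.character(seq_along(merged))])
  merged
}

# centered moving average with shrinking windows at the edges
smooth_signal <- function(v, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  hw <- (window - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# plateau-collapsed strict local maxima of a numeric vector
local_maxima <- function(s) {
  n <- length(s)
  if (n == 1) return(1L)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1 || r$values[i - 1] < r$values[i]
    right_ok <- i == k || r$values[i + 1] < r$values[i]
    left_ok && right_ok
  }, logical(1))
  as.integer(floor((starts[is_max] + ends[is_max]) / 2))
}

#' Split a multi-summit peak into single-summit segments
#'
#' The per-base signal over the peak is smoothed with a moving average;
#' local maxima with prominence of at least `min_prominence` times the peak
#' maximum are summits, and segment boundaries are placed at the
#' minimum-signal position between adjacent summits (ties broken at the
#' position closest to the midpoint between the summits). The returned
#' segments are contiguous, non-overlapping, and exactly tile the peak.
#'
#' @param peak a single GRanges interval.
#' @param signal per-base RleList covering the peak, or a numeric vector of
#'   length `width(peak)`.
#' @param smooth_window moving-average width in bp (default 50).
#' @param min_prominence minimum summit prominence as a fraction of the
#'   peak's maximum smoothed signal (default 0.1).
#' @return GRanges of segments with a `summit` column (absolute bp,
#'   0-based).
#' @export
split_multisummit <- function(peak, signal, smooth_window = 50,
                              min_prominence = 0.1) {
  stopifnot(length(peak) == 1)
  ch <- as.character(GenomicRanges::seqnames(peak))
  s0 <- GenomicRanges::start(peak); e0 <- GenomicRanges::end(peak)
  v <- if (is.numeric(signal)) signal else as.numeric(signal[[ch]][s0:e0])
  if (length(v) != e0 - s0 + 1) stop("signal does not cover the peak")
  if (all(v == 0)) {
    warning("all-zero signal over peak; returned unchanged")
    out <- GenomicRanges::granges(peak)
    out$summit <- NA_integer_
    return(out)
  }
  s <- smooth_signal(v, smooth_window)
  summits <- local_maxima(s)
  # prominence pruning: drop the lower of an adjacent pair whose valley is
  # too shallow, until all inter-summit valleys are deep enough
  prom <- min_prominence * max(s)
  while (length(summits) > 1) {
    drop <- NA_integer_
    for (i in seq_len(length(summits) - 1)) {
      lo <- summits[i]; hi <- summits[i + 1]
      valley <- min(s[lo:hi])
      if (min(s[lo], s[hi]) - valley < prom) {
        drop <- if (s[lo] <= s[hi]) i else i + 1L
        break
      }
    }
    if (is.na(drop)) break
    summits <- summits[-drop]
  }
  if (length(summits) <= 1) {
    out <- GenomicRanges::granges(peak)
    out$summit <- s0 - 1L +
      (if (length(summits) == 1) summits else which.max(s)) - 1L
    return(out)
  }
  # boundaries at inter-summit minima; ties -> closest to summit midpoint
  bounds <- integer(length(summits) - 1)
  for (i in seq_len(length(summits) - 1)) {
    lo <- summits[i]; hi <- summits[i + 1]
    between <- lo:hi
    cand <- between[s[between] == min(s[between])]
    mid <- (lo + hi) / 2
    bounds[i] <- cand[which.min(abs(cand - mid))]
  }
  seg_start <- c(1L, bounds + 1L)
  seg_end <- c(bounds, length(v))
  out <- GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + seg_start - 1L,
                                                     s0 + seg_end - 1L))
  out$summit <- s0 - 1L + summits - 1L
  out
}

#' Base-pair Jaccard index of two interval sets
#' @param a,b GRanges.
#' @return intersection bp / union bp.
#' @export
jaccard_peaks <- function(a, b) {
  a <- GenomicRanges::reduce(a); b <- GenomicRanges::reduce(b)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(a, b)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

#' One iteration of the cluster-then-call pipeline
#'
#' Builds and filters the binary matrix from the current peak set, fits
#' LDA, clusters the cells by topic, pools the cut sites of each cluster,
#' calls peaks per cluster with the built-in caller, and merges the
#' per-cluster calls into a refined peak set.
#'
#' @param cutsites cut sites for all cells.
#' @param peaks current peak set (GRanges; e.g. bulk calls).
#' @param genome a [genome_table()].
#' @param config an [lda_config()].
#' @param control optional control cut sites for the caller.
#' @param cluster_threshold centroid-score threshold (default 0.2).
#' @param min_grow,min_keep cluster augmentation/floor sizes.
#' @param engine embedding engine for clustering.
#' @param caller_args list of extra arguments for [call_peaks_builtin()].
#' @return list with `model`, `clustering`, `peaks` (merged per-cluster
#'   calls) and `stats` (per-stage counts).
#' @export
run_iteration <- function(cutsites, peaks, genome, config, control = NULL,
                          cluster_threshold = 0.2, min_grow = 150,
                          min_keep = 50, engine = c("umap", "pca"),
                          caller_args = list()) {
  engine <- match.arg(engine)
  if (nrow(cutsites) == 0) stop("no cut sites; empty cell set")
  mat <- build_matrix(cutsites, peaks)
  filt <- filter_matrix(mat)
  model <- fit_lda(filt$matrix, config)
  clustering <- cluster_cells(model$theta, threshold = cluster_threshold,
                              min_grow = min_grow, min_keep = min_keep,
                              seed = config$seed, engine = engine)
  labels <- clustering$labels
  topics <- sort(unique(labels[!is.na(labels)]))
  if (length(topics) == 0) {
    warning("no topic clusters formed; returning the input peak set")
    return(list(model = model, clustering = clustering, peaks = peaks,
                stats = list(n_cells = nrow(filt$matrix), n_clusters = 0,
                             n_peaks_in = length(peaks),
                             n_peaks_out = length(peaks))))
  }
  per_cluster <- lapply(topics, function(t) {
    cells <- names(labels)[!is.na(labels) & labels == t]
    pooled <- cutsites[cutsites$cell %in% cells, ]
    res <- do.call(call_peaks_builtin,
                   c(list(cutsites = pooled, genome = genome,
                          control = control,
                          source = paste0("cluster_", t)), caller_args))
    res$peaks
  })
  merged <- merge_peak_sets(per_cluster)
  list(model = model, clustering = clustering, peaks = merged,
       stats = list(n_cells = nrow(filt$matrix),
                    n_clusters = length(topics),
                    cluster_sizes = table(labels),
                    n_peaks_in = length(peaks),
                    n_peaks_out = length(merged)))
}
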