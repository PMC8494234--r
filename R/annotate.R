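#' Build a stranded exon annotation
#'
#' @param chrom,start,end exon coordinates (0-based half-open).
#' @param strand "+" or "-" per exon.
#' @param gene gene identifier per exon.
#' @return GRanges of exons with strand and a `gene` column.
#' @export
exon_annotation <- function(chrom, start, end, strand, gene) {
  stopifnot(all(strand %in% c("+", "-")))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                               strand = strand)
  gr$gene <- gene
  gr
}

#' Topic specificity of peaks
#'
#' For each peak, the fraction of cells carrying the peak that belong to
#' the given topic's cluster. Peaks carried by no cell are undefined (NA,
#' with a warning).
#'
#' @param mat binary cells-by-peaks matrix.
#' @param labels per-cell topic labels (NA = unassigned), aligned with the
#'   rows of `mat`.
#' @param topic topic id.
#' @return named numeric vector of specificities in [0, 1] per peak.
#' @export
topic_specificity <- function(mat, labels, topic) {
  stopifnot(length(labels) == nrow(mat))
  carriers <- Matrix::colSums(mat)
  members <- !is.na(labels) & labels == topic
  in_cluster <- Matrix::colSums(mat[members, , drop = FALSE])
  spec <- as.numeric(in_cluster) / as.numeric(carriers)
  if (any(carriers == 0)) {
    warning(sum(carriers == 0), " peak(s) with no carrying cells excluded")
    spec[carriers == 0] <- NA_real_
  }
  names(spec) <- colnames(mat)
  spec
}

#' Top topic-specific peaks
#'
#' Returns either the top `n` peaks by specificity or all peaks with
#' specificity strictly above `floor`, whichever set is larger. Ties are
#' resolved by the (coordinate-sorted) peak order.
#'
#' @param specificity named numeric vector from [topic_specificity()].
#' @param n top-peak count (default 250).
#' @param floor specificity floor (default 0.5).
#' @return character vector of peak ids.
#' @export
top_topic_peaks <- function(specificity, n = 250, floor = 0.5) {
  specificity <- specificity[!is.na(specificity)]
  above <- names(specificity)[specificity > floor]
  if (length(above) > n) return(above)
  ord <- order(specificity, decreasing = TRUE)  # stable ties by input order
  names(specificity)[ord[seq_len(min(n, length(specificity)))]]
}

# stranded downstream gap in bp between a peak and an exon, in the gene
# frame; 0 for abutting, negative when the exon lies upstream or overlaps
stranded_gap <- function(peaks, exons, p_idx, e_idx) {
  plus <- as.character(GenomicRanges::strand(exons))[e_idx] == "+"
  ifelse(plus,
         (GenomicRanges::start(exons)[e_idx] - 1L) -
           GenomicRanges::end(peaks)[p_idx],
         (GenomicRanges::start(peaks)[p_idx] - 1L) -
           GenomicRanges::end(exons)[e_idx])
}

#' Assign peaks to the nearest downstream gene
#'
#' A peak is assigned to the gene whose nearest exon lies downstream of the
#' peak in the gene's orientation (the peak is upstream of the exon in the
#' gene frame) within `max_dist` bp. Overlapping peak-exon pairs are
#' included only when `allow_overlap = TRUE` (they count as distance 0).
#' Nearest by stranded distance; ties by exon coordinate, then gene id.
#'
#' @param peaks GRanges of peaks.
#' @param annotations exon GRanges from [exon_annotation()].
#' @param max_dist maximum stranded distance in bp (default 1200).
#' @param allow_overlap include overlapping pairs (default FALSE).
#' @return character vector: assigned gene id per peak (NA if none).
#' @export
nearest_downstream_gene <- function(peaks, annotations, max_dist = 1200,
                                    allow_overlap = FALSE) {
  hits <- GenomicRanges::findOverlaps(peaks, annotations, maxgap = max_dist,
                                      ignore.strand = TRUE)
  p_idx <- S4Vectors::queryHits(hits)
  e_idx <- S4Vectors::subjectHits(hits)
  gap <- stranded_gap(peaks, annotations, p_idx, e_idx)
  pair_overlap <- as.logical(
    GenomicRanges::start(peaks)[p_idx] <= GenomicRanges::end(annotations)[e_idx] &
    GenomicRanges::start(annotations)[e_idx] <= GenomicRanges::end(peaks)[p_idx] &
    as.character(GenomicRanges::seqnames(peaks))[p_idx] ==
      as.character(GenomicRanges::seqnames(annotations))[e_idx])
  eff_gap <- ifelse(pair_overlap, 0L, gap)
  keep <- if (allow_overlap) {
    (pair_overlap | (gap >= 0)) & eff_gap <= max_dist
  } else {
    !pair_overlap & gap >= 0 & gap <= max_dist
  }
  out <- rep(NA_character_, length(peaks))
  if (!any(keep)) return(out)
  cand <- data.frame(p = p_idx[keep], gap = eff_gap[keep],
                     exon_pos = GenomicRanges::start(annotations)[e_idx[keep]],
                     gene = annotations$gene[e_idx[keep]])
  cand <- cand[order(cand$p, cand$gap, cand$exon_pos, cand$gene), ]
  first <- !duplicated(cand$p)
  out[cand$p[first]] <- cand$gene[first]
  out
}

new_enrichment_result <- function(categories, observed, null_mean, ratios,
                                  n_random) {
  structure(list(categories = categories, observed = observed,
                 null_mean = null_mean,
                 log2_ratio = rowMeans(ratios),
                 ci_lower = apply(ratios, 1, quantile, 0.025),
                 ci_upper = apply(ratios, 1, quantile, 0.975),
                 n_random = n_random),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  df <- data.frame(category = x$categories, observed = x$observed,
                   log2_ratio = round(x$log2_ratio, 3),
                   ci_lower = round(x$ci_lower, 3),
                   ci_upper = round(x$ci_upper, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tissue-expression enrichment of a gene set
#'
#' Each gene's expression is normalized to a distribution over tissues; the
#' observed mean distribution over `gene_set` is compared, per tissue, with
#' the mean distribution of `n_random` random samples of `sample_size`
#' genes, as a log2 ratio with a percentile 95% confidence interval.
#'
#' @param gene_set character vector of gene ids.
#' @param expression genes x tissues matrix of non-negative values (TPM),
#'   with gene rownames and tissue colnames.
#' @param n_random random samples (default 100).
#' @param sample_size genes per random sample (default 250).
#' @param seed RNG seed.
#' @return an `enrichment_result` over tissues.
#' @export
tissue_enrichment <- function(gene_set, expression, n_random = 100,
                              sample_size = 250, seed = 1) {
  if (length(gene_set) == 0) stop("empty gene set")
  rs <- rowSums(expression)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " gene(s) with all-zero expression dropped")
    expression <- expression[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  missing <- setdiff(gene_set, rownames(expression))
  if (length(missing) > 0) {
    message(length(missing), " gene(s) not in the expression table dropped")
    gene_set <- setdiff(gene_set, missing)
  }
  if (length(gene_set) == 0) stop("no gene in the set has expression data")
  norm <- expression / rs
  observed <- colMeans(norm[gene_set, , drop = FALSE])
  set.seed(seed)
  ratios <- vapply(seq_len(n_random), function(i) {
    samp <- sample(rownames(norm), min(sample_size, nrow(norm)))
    log2(observed / colMeans(norm[samp, , drop = FALSE]))
  }, numeric(ncol(norm)))
  null_mean <- observed / 2^rowMeans(ratios)
  new_enrichment_result(colnames(expression), observed, null_mean,
                        ratios, n_random)
}

#' Enrichment of per-topic peaks for overlap with TF ChIP sites
#'
#' Observed: per-topic counts of peaks overlapping `tf_peaks`. Null: random
#' draws of equal total size assign each drawn peak to a topic with
#' probability proportional to the topic's total peak count. Per-topic log2
#' ratios of observed to drawn counts with percentile CI; a pseudo-count of
#' 0.5 replaces zero counts (flagged in `zero_flagged`).
#'
#' @param topic_peaks named list of GRanges, one per topic (peaks with
#'   probability greater than zero for that topic).
#' @param tf_peaks GRanges of (non-HOT, merged) TF ChIP peaks.
#' @param topic_peak_counts named numeric, total peaks per topic.
#' @param n_random random draws (default 100).
#' @param seed RNG seed.
#' @return an `enrichment_result` over topics.
#' @export
chip_overlap_enrichment <- function(topic_peaks, tf_peaks, topic_peak_counts,
                                    n_random = 100, seed = 1) {
  if (length(tf_peaks) == 0) stop("empty TF peak set")
  topics <- names(topic_peaks)
  observed <- vapply(topic_peaks, function(g)
    sum(IRanges::overlapsAny(g, tf_peaks)), numeric(1))
  total <- sum(observed)
  prob <- topic_peak_counts[topics] / sum(topic_peak_counts[topics])
  set.seed(seed)
  draws <- stats::rmultinom(n_random, size = total, prob = prob)
  obs_adj <- ifelse(observed == 0, 0.5, observed)
  draws_adj <- ifelse(draws == 0, 0.5, draws)
  ratios <- log2(obs_adj / draws_adj)
  res <- new_enrichment_result(topics, observed, rowMeans(draws),
                               ratios, n_random)
  res$zero_flagged <- topics[observed == 0]
  res
}

#' Assign peaks to developmental stages by signal z-score
#'
#' Signal heights are z-scored per peak across stages; a peak belongs to
#' every stage with z >= `z_threshold`. Peaks with flat signal (zero
#' standard deviation) are assigned nowhere.
#'
#' @param signal peaks x stages numeric matrix.
#' @param z_threshold assignment threshold (default 1.5).
#' @return named list of integer peak-index vectors, one per stage.
#' @export
assign_stages_by_zscore <- function(signal, z_threshold = 1.5) {
  sds <- apply(signal, 1, sd)
  z <- (signal - rowMeans(signal)) / ifelse(sds == 0, Inf, sds)
  lapply(setNames(seq_len(ncol(signal)), colnames(signal)),
         function(j) which(z[, j] >= z_threshold))
}

#' Stage-overlap enrichment of a peak set
#'
#' Observed per-stage overlap counts of the query peaks with pre-assigned
#' stage peak sets, compared to random samples of equal size drawn from a
#' peak universe.
#'
#' @param query_peaks GRanges.
#' @param stage_sets named list of GRanges pre-assigned to stages.
#' @param universe GRanges to draw random samples from.
#' @param n_random random samples (default 100).
#' @param seed RNG seed.
#' @return an `enrichment_result` over stages.
#' @export
stage_enrichment <- function(query_peaks, stage_sets, universe,
                             n_random = 100, seed = 1) {
  stages <- names(stage_sets)
  count_by_stage <- function(peaks)
    vapply(stage_sets, function(s) sum(IRanges::overlapsAny(peaks, s)),
           numeric(1))
  observed <- count_by_stage(query_peaks)
  set.seed(seed)
  n <- length(query_peaks)
  ratios <- vapply(seq_len(n_random), function(i) {
    samp <- universe[sample.int(length(universe), min(n, length(universe)))]
    drawn <- count_by_stage(samp)
    log2(ifelse(observed == 0, 0.5, observed) /
           ifelse(drawn == 0, 0.5, drawn))
  }, numeric(length(stages)))
  new_enrichment_result(stages, observed, observed / 2^rowMeans(ratios),
                        ratios, n_random)
}

#' Overlap statistics and Fisher's exact test for two interval sets
#'
#' Element overlap counts in both directions (>= 1 bp rule), base-pair
#' coverage of the genome by each set, and a right-tailed Fisher exact p
#' from the 2x2 base-pair table (A-and-B, A-only, B-only, neither).
#'
#' @param a,b merged (non-overlapping) GRanges.
#' @param genome a [genome_table()].
#' @return list with `a_in_b`, `b_in_a` (element counts), `bp` (named
#'   vector: intersection, a_only, b_only, neither), `frac_a`, `frac_b`
#'   (genome fractions), `p_value`.
#' @export
overlap_stats <- function(a, b, genome) {
  for (g in list(a, b)) {
    ch <- as.character(GenomicRanges::seqnames(g))
    if (any(!ch %in% names(genome)) ||
        any(GenomicRanges::end(g) > genome[ch]))
      stop("interval exceeds chromosome bounds")
  }
  a <- GenomicRanges::reduce(a); b <- GenomicRanges::reduce(b)
  g_total <- sum(genome)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b,
                                                             ignore.strand = TRUE)))
  a_bp <- sum(GenomicRanges::width(a)); b_bp <- sum(GenomicRanges::width(b))
  tab <- matrix(c(inter, a_bp - inter, b_bp - inter,
                  g_total - a_bp - b_bp + inter), 2, 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(a_in_b = sum(IRanges::overlapsAny(a, b)),
       b_in_a = sum(IRanges::overlapsAny(b, a)),
       bp = c(intersection = inter, a_only = a_bp - inter,
              b_only = b_bp - inter,
              neither = g_total - a_bp - b_bp + inter),
       frac_a = a_bp / g_total, frac_b = b_bp / g_total,
       p_value = p)
}

#' Shuffle peaks within their chromosomes
#'
#' Uniform placement on the same chromosome with rejection of overlaps
#' among the shuffled intervals; counts and widths are preserved per
#' chromosome.
#'
#' @param peaks GRanges.
#' @param genome a [genome_table()].
#' @param seed RNG seed.
#' @param max_tries rejection-sampling attempts per interval (default 1000).
#' @return shuffled GRanges.
#' @export
shuffle_peaks <- function(peaks, genome, seed = 1, max_tries = 1000) {
  set.seed(seed)
  out <- vector("list", length(peaks))
  placed <- GenomicRanges::GRanges()
  ord <- order(-GenomicRanges::width(peaks))  # widest first eases packing
  for (i in ord) {
    ch <- as.character(GenomicRanges::seqnames(peaks))[i]
    w <- GenomicRanges::width(peaks)[i]
    len <- genome[[ch]]
    for (t in seq_len(max_tries)) {
      s <- sample.int(len - w + 1L, 1)
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + w - 1L))
      if (!any(IRanges::overlapsAny(cand, placed))) {
        placed <- c(placed, cand)
        out[[i]] <- cand
        break
      }
    }
    if (is.null(out[[i]]))
      stop("could not place a shuffled interval without overlap on ", ch)
  }
  res <- do.call(c, out)
  res
}

#' Signal enrichment of peaks relative to their chromosome
#'
#' Per-peak log2 of mean signal over the peak divided by mean signal over
#' the peak's whole chromosome, for both the true peaks and a shuffled
#' control set.
#'
#' @param peaks GRanges.
#' @param signal per-base RleList.
#' @param shuffled_peaks GRanges (e.g. from [shuffle_peaks()]).
#' @return list with numeric vectors `true` and `shuffled`.
#' @export
signal_enrichment_over_peaks <- function(peaks, signal, shuffled_peaks) {
  score <- function(gr) {
    vapply(seq_along(gr), function(i) {
      ch <- as.character(GenomicRanges::seqnames(gr))[i]
      chrom_mean <- mean(signal[[ch]])
      if (chrom_mean == 0) {
        warning("zero chromosome mean for ", ch, "; peak skipped")
        return(NA_real_)
      }
      peak_mean <- mean(as.numeric(
        signal[[ch]][GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]]))
      log2(peak_mean / chrom_mean)
    }, numeric(1))
  }
  list(true = score(peaks), shuffled = score(shuffled_peaks))
}

#' Shannon entropy of a tissue distribution
#'
#' @param p non-negative vector with positive sum (normalized internally).
#' @param base logarithm base (default 2: bits).
#' @return entropy.
#' @export
tissue_entropy <- function(p, base = 2) {
  if (any(p < 0)) stop("negative values in the distribution")
  s <- sum(p)
  if (s == 0) stop("zero vector has no entropy")
  p <- p[p > 0] / s
  -sum(p * log(p)) / log(base)
}

# peaks (pooled across tissue sets, tagged with tissue) linked to a gene's
# exons within max_dist, allowing overlaps
linked_peaks <- function(gene, tissue_sets, annotations, max_dist = 1200) {
  pooled <- do.call(c, lapply(names(tissue_sets), function(ts) {
    g <- GenomicRanges::granges(tissue_sets[[ts]])
    g$tissue <- ts
    g
  }))
  exons <- annotations[annotations$gene == gene]
  if (length(exons) == 0) stop("unknown gene: ", gene)
  assigned <- nearest_downstream_gene(pooled, annotations,
                                      max_dist = max_dist,
                                      allow_overlap = TRUE)
  pooled[!is.na(assigned) & assigned == gene]
}

#' Mean tissue entropy of the peaks linked to a gene
#'
#' Peaks from the per-tissue sets are linked to the gene's exons (nearest
#' downstream within `max_dist`, allowing overlaps). Each linked peak's
#' tissue distribution is its count of overlapping peaks from each tissue
#' set; the gene's score is the mean entropy of those distributions.
#'
#' @param gene gene id.
#' @param tissue_sets named list of per-tissue peak GRanges.
#' @param annotations exon GRanges from [exon_annotation()].
#' @param max_dist linkage distance (default 1200).
#' @param base entropy base (default 2).
#' @return mean entropy in bits (NA with a warning when no peak links).
#' @export
mean_peak_entropy <- function(gene, tissue_sets, annotations,
                              max_dist = 1200, base = 2) {
  lp <- linked_peaks(gene, tissue_sets, annotations, max_dist)
  if (length(lp) == 0) {
    warning("no peaks linked to gene ", gene, "; excluded")
    return(NA_real_)
  }
  ent <- vapply(seq_along(lp), function(i) {
    counts <- vapply(tissue_sets, function(ts)
      GenomicRanges::countOverlaps(lp[i], ts), numeric(1))
    tissue_entropy(counts, base = base)
  }, numeric(1))
  mean(ent)
}

#' Peak diversity score of a gene
#'
#' Linked peaks (as in [mean_peak_entropy()]) are grouped into connected
#' components under the >= 1 bp overlap relation; each component's
#' signature is the set of tissues contributing peaks to it. The score is
#' the number of distinct signatures (or the number of components when
#' `distinct_signatures = FALSE`).
#'
#' @param gene gene id.
#' @param tissue_sets named list of per-tissue peak GRanges.
#' @param annotations exon GRanges.
#' @param max_dist linkage distance (default 1200).
#' @param distinct_signatures deduplicate identical tissue signatures
#'   (default TRUE).
#' @return integer score >= 1 (0 when no peak links).
#' @export
peak_diversity_score <- function(gene, tissue_sets, annotations,
                                 max_dist = 1200,
                                 distinct_signatures = TRUE) {
  lp <- linked_peaks(gene, tissue_sets, annotations, max_dist)
  if (length(lp) == 0) return(0L)
  comp <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(lp, GenomicRanges::reduce(lp)))
  sigs <- tapply(lp$tissue, comp,
                 function(ts) paste(sort(unique(ts)), collapse = "+"))
  if (distinct_signatures) length(unique(sigs)) else length(sigs)
}

#' Cells carrying accessibility near a marker gene
#'
#' Returns the cells with at least one peak overlapping the gene body or
#' the stranded window from `upstream` bp 5' of the gene to `downstream`
#' bp 3' of it.
#'
#' @param gene gene id.
#' @param mat binary cells-by-peaks matrix (peak-id column names).
#' @param annotations exon GRanges from [exon_annotation()].
#' @param upstream bp upstream of the gene (default 1200).
#' @param downstream bp downstream (default 100).
#' @return character vector of cell ids.
#' @export
marker_gene_cells <- function(gene, mat, annotations, upstream = 1200,
                              downstream = 100) {
  exons <- annotations[annotations$gene == gene]
  if (length(exons) == 0) stop("unknown gene: ", gene)
  body <- range(GenomicRanges::granges(exons))
  plus <- as.character(GenomicRanges::strand(exons))[1] == "+"
  win <- if (plus) {
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(body),
      IRanges::IRanges(max(1L, GenomicRanges::start(body) - upstream),
                       GenomicRanges::end(body) + downstream))
  } else {
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(body),
      IRanges::IRanges(max(1L, GenomicRanges::start(body) - downstream),
                       GenomicRanges::end(body) + upstream))
  }
  peaks <- parse_peak_ids(colnames(mat))
  hit_cols <- which(IRanges::overlapsAny(peaks, win, ignore.strand = TRUE))
  if (length(hit_cols) == 0) return(character(0))
  carriers <- Matrix::rowSums(mat[, hit_cols, drop = FALSE]) > 0
  rownames(mat)[carriers]
}

#' Row-normalize a matrix for heatmap display
#' @param m numeric matrix.
#' @return matrix with each row divided by its sum (zero rows left as is).
#' @export
row_normalize <- function(m) {
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  m / rs
}
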