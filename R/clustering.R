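#' Centroid-similarity score of a topic
#'
#' Cells are ranked by their probability for the topic; the centroid is the
#' mean theta row of the top `top_n` cells, and the score is the mean dot
#' product of those rows with the centroid. Scores near 1 mean the topic's
#' strongest cells form a tight group in topic space.
#'
#' @param theta cells-by-topics probability matrix.
#' @param topic topic column index.
#' @param top_n number of top cells (default 50); if fewer cells exist all
#'   are used with a warning. Ranking ties keep the original cell order.
#' @return numeric score in [0, 1].
#' @export
topic_centroid_score <- function(theta, topic, top_n = 50) {
  n <- nrow(theta)
  if (n < top_n) {
    warning("fewer cells (", n, ") than top_n (", top_n, "); using all")
    top_n <- n
  }
  ord <- order(theta[, topic], decreasing = TRUE)  # stable: ties by index
  rows <- theta[ord[seq_len(top_n)], , drop = FALSE]
  centroid <- colMeans(rows)
  mean(as.vector(rows %*% centroid))
}

#' Select candidate cell-type topics by centroid score
#'
#' @param theta cells-by-topics matrix.
#' @param threshold minimum centroid score (default 0.2, strict >).
#' @param top_n top cells used per topic score.
#' @return integer vector of topic indices with score > threshold, ordered
#'   by decreasing score; the scores are attached as attribute `"scores"`.
#' @export
select_cluster_topics <- function(theta, threshold = 0.2, top_n = 50) {
  scores <- vapply(seq_len(ncol(theta)), function(t)
    suppressWarnings(topic_centroid_score(theta, t, top_n)), numeric(1))
  sel <- which(scores > threshold)
  if (length(sel) == 0)
    warning("no topic exceeds the centroid-score threshold ", threshold)
  sel <- sel[order(scores[sel], decreasing = TRUE)]
  attr(sel, "scores") <- scores
  sel
}

#' Assign cells to topic clusters by the majority-probability rule
#'
#' A cell is assigned to a selected topic iff its theta entry for that
#' topic is strictly greater than 0.5 (at most one topic can satisfy this);
#' otherwise it is unassigned (`NA`).
#'
#' @param theta cells-by-topics matrix (rows sum to 1).
#' @param selected_topics topic indices eligible for clusters.
#' @return integer vector of topic labels (NA = unassigned), named by cell.
#' @export
assign_cells <- function(theta, selected_topics) {
  labels <- rep(NA_integer_, nrow(theta))
  if (length(selected_topics) > 0) {
    sub <- theta[, selected_topics, drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    hit <- sub[cbind(seq_len(nrow(sub)), best)] > 0.5
    labels[hit] <- selected_topics[best[hit]]
  }
  names(labels) <- rownames(theta)
  labels
}

#' L2-normalize theta rows and embed
#'
#' Rows are L2-normalized, then reduced by the selected manifold embedding:
#' UMAP (via uwot, deterministic given seed and single-threaded layout) or
#' a deterministic PCA reducer. 2 dimensions for display, 10 for cluster
#' augmentation.
#'
#' @param theta cells-by-topics matrix with non-zero rows.
#' @param n_dims output dimensionality (2 or 10 typically).
#' @param seed RNG seed.
#' @param engine "umap" (default when uwot is installed) or "pca".
#' @return cells x n_dims coordinate matrix.
#' @export
embed_theta <- function(theta, n_dims = 2, seed = 1,
                        engine = c("umap", "pca")) {
  engine <- match.arg(engine)
  norms <- sqrt(rowSums(theta^2))
  if (any(norms == 0)) stop("theta has all-zero rows")
  x <- theta / norms
  if (engine == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      warning("uwot not installed; falling back to PCA embedding")
      engine <- "pca"
    }
  }
  if (engine == "umap") {
    set.seed(seed)
    coords <- uwot::umap(x, n_components = n_dims,
                         n_neighbors = min(15, nrow(x) - 1),
                         n_threads = 1, n_sgd_threads = 0)
  } else {
    k <- min(n_dims, ncol(x))
    p <- prcomp(x, center = TRUE, scale. = FALSE)
    coords <- p$x[, seq_len(min(k, ncol(p$x))), drop = FALSE]
    if (ncol(coords) < n_dims)  # pad when theta has fewer dimensions
      coords <- cbind(coords, matrix(0, nrow(coords), n_dims - ncol(coords)))
  }
  rownames(coords) <- rownames(theta)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

# step-function slope detector over a ranked-distance sequence:
# positive response where the distances jump (difference of step means)
step_convolution <- function(d, halfwidth = 10) {
  n <- length(d)
  padded <- c(rep(d[1], halfwidth), d, rep(d[n], halfwidth))
  after <- vapply(seq_len(n), function(i)
    mean(padded[(i + halfwidth + 1):(i + 2 * halfwidth)]), numeric(1))
  before <- vapply(seq_len(n), function(i)
    mean(padded[i:(i + halfwidth - 1)]), numeric(1))
  after - before
}

#' Grow small clusters with nearby unassigned cells
#'
#' For each cluster smaller than `min_size` (processed in ascending size
#' order), the cluster centroid is estimated as the mean of 200 draws from
#' a Gaussian kernel density estimate of the member coordinates (Scott's
#' bandwidth); the nearest `ceiling(1.25 * size)` cells to the centroid are
#' ranked by distance, the ranked distances are convolved with a step
#' kernel to detect distance jumps, and the closest unassigned cell whose
#' convolution value does not exceed 1.5 x IQR of all convolution values is
#' added. The procedure iterates (recomputing the centroid) until the
#' cluster reaches `min_size` or no eligible cell remains. Existing labels
#' are never changed.
#'
#' @param labels integer topic labels (NA = unassigned), named by cell.
#' @param coords embedding coordinates (typically 10-dim), rows aligned
#'   with `labels`.
#' @param min_size grow clusters below this size (default 150).
#' @param seed RNG seed for the KDE draws.
#' @param kde_samples draws used for the centroid (default 200).
#' @param step_halfwidth half-width of the step kernel (default 10).
#' @return updated label vector; added cells are recorded in attribute
#'   `"augmented"`.
#' @export
augment_small_clusters <- function(labels, coords, min_size = 150, seed = 1,
                                   kde_samples = 200, step_halfwidth = 10) {
  stopifnot(nrow(coords) == length(labels))
  set.seed(seed)
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_size]
  small <- small[order(sizes[small])]
  added <- character(0)
  for (cl in small) {
    topic <- as.integer(cl)
    repeat {
      members <- which(!is.na(labels) & labels == topic)
      if (length(members) >= min_size) break
      if (length(members) < 2) {
        warning("cluster ", cl, " has < 2 members; KDE undefined, skipped")
        break
      }
      mx <- coords[members, , drop = FALSE]
      m <- nrow(mx); d <- ncol(mx)
      bw <- apply(mx, 2, sd) * m^(-1 / (d + 4))
      bw[bw == 0] <- 1e-9
      pick <- sample.int(m, kde_samples, replace = TRUE)
      draws <- mx[pick, , drop = FALSE] +
        matrix(rnorm(kde_samples * d), kde_samples, d) %*% diag(bw, d)
      centroid <- colMeans(draws)
      dist_all <- sqrt(colSums((t(coords) - centroid)^2))
      k <- min(ceiling(1.25 * m), nrow(coords))
      nn <- order(dist_all)[seq_len(k)]
      conv <- step_convolution(dist_all[nn], step_halfwidth)
      # median-centered whisker rule: the raw ranked-distance slope has a
      # positive baseline, so the outlier cutoff is taken relative to the
      # typical convolution value
      cutoff <- stats::median(conv) + 1.5 * IQR(conv)
      eligible <- nn[is.na(labels[nn]) & conv <= cutoff]
      if (length(eligible) == 0) break
      add <- eligible[which.min(dist_all[eligible])]
      labels[add] <- topic
      added <- c(added, names(labels)[add])
    }
  }
  attr(labels, "augmented") <- added
  labels
}

#' Dissolve clusters below the minimum size
#'
#' @param labels integer topic labels (NA = unassigned).
#' @param min_cells clusters with fewer members are dissolved (default 50).
#' @return labels with dissolved clusters' cells set to NA; the dissolved
#'   topics are attached as attribute `"dropped_topics"`.
#' @export
drop_small_clusters <- function(labels, min_cells = 50) {
  att <- attributes(labels)
  sizes <- table(labels)
  dropped <- as.integer(names(sizes)[sizes < min_cells])
  labels[labels %in% dropped] <- NA_integer_
  attributes(labels) <- att
  attr(labels, "dropped_topics") <- dropped
  labels
}

#' Full topic-clustering step
#'
#' Scores topics, assigns cells by the >50% rule, grows small clusters in a
#' 10-dimensional embedding, and dissolves clusters that remain below the
#' peak-calling floor.
#'
#' @param theta cells-by-topics matrix.
#' @param threshold centroid-score threshold (default 0.2).
#' @param min_grow clusters below this size are augmented (default 150).
#' @param min_keep clusters below this size are dissolved (default 50).
#' @param seed RNG seed.
#' @param engine embedding engine passed to [embed_theta()].
#' @return list of class `topic_clustering`: `selected_topics`, `scores`,
#'   `labels`, `assigned_by`, `coords2`, `coords10`, `sizes`.
#' @export
cluster_cells <- function(theta, threshold = 0.2, min_grow = 150,
                          min_keep = 50, seed = 1,
                          engine = c("umap", "pca")) {
  engine <- match.arg(engine)
  selected <- select_cluster_topics(theta, threshold)
  labels <- assign_cells(theta, selected)
  by_prob <- !is.na(labels)
  coords10 <- embed_theta(theta, n_dims = 10, seed = seed, engine = engine)
  coords2 <- embed_theta(theta, n_dims = 2, seed = seed, engine = engine)
  labels <- augment_small_clusters(labels, coords10, min_size = min_grow,
                                   seed = seed)
  labels <- drop_small_clusters(labels, min_cells = min_keep)
  assigned_by <- ifelse(is.na(labels), NA_character_,
                        ifelse(by_prob, "probability", "augmentation"))
  structure(list(selected_topics = as.integer(selected),
                 scores = attr(selected, "scores"),
                 labels = labels, assigned_by = assigned_by,
                 coords2 = coords2, coords10 = coords10,
                 sizes = table(labels)),
            class = "topic_clustering")
}

#' @export
print.topic_clustering <- function(x, ...) {
  cat("Topic clustering:", length(x$selected_topics), "selected topics,",
      sum(!is.na(x$labels)), "of", length(x$labels), "cells assigned\n")
  print(x$sizes)
  invisible(x)
}
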