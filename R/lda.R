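#' LDA configuration
#'
#' Symmetric Dirichlet priors are parameterized by their *total* weight by
#' default (`prior_scaling = "total"`): the per-component weights are
#' `alpha / K` for the cell-topic prior and `beta / V` for the topic-peak
#' prior, so `alpha` and `beta` measure how much mass the uniform prior
#' carries relative to the data. `prior_scaling = "per_component"` uses
#' `alpha` and `beta` directly per component.
#'
#' @param K number of topics (>= 1).
#' @param alpha cell-topic prior weight (default 3.0).
#' @param beta topic-peak prior weight (default 2000.0).
#' @param iterations Gibbs sweeps (default 4000).
#' @param burn_in sweeps before sampling starts (default `iterations / 2`).
#' @param sample_stride take a posterior sample every this many post-burn-in
#'   sweeps (default 40).
#' @param seed RNG seed.
#' @param n_workers document partitions for distributed-style training
#'   (1 = exact serial collapsed Gibbs, bit-reproducible given seed).
#' @param estimator aggregate posterior samples by "mean" (default: mean of
#'   sampled count matrices plus prior) or "mode" (most frequent topic per
#'   token).
#' @param prior_scaling "total" (default) or "per_component".
#' @return list of class `lda_config`.
#' @export
lda_config <- function(K, alpha = 3.0, beta = 2000.0, iterations = 4000,
                       burn_in = NULL, sample_stride = 40, seed = 1,
                       n_workers = 1, estimator = c("mean", "mode"),
                       prior_scaling = c("total", "per_component")) {
  estimator <- match.arg(estimator)
  prior_scaling <- match.arg(prior_scaling)
  if (K < 1) stop("K must be >= 1")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (sample_stride < 1) stop("sample_stride must be >= 1")
  if (is.null(burn_in)) burn_in <- iterations %/% 2
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 sample_stride = as.integer(sample_stride),
                 seed = as.integer(seed), n_workers = as.integer(n_workers),
                 estimator = estimator, prior_scaling = prior_scaling),
            class = "lda_config")
}

# per-component prior weights implied by a config and vocabulary size
prior_components <- function(config, V) {
  if (config$prior_scaling == "total")
    list(a = config$alpha / config$K, b = config$beta / V)
  else
    list(a = config$alpha, b = config$beta)
}

matrix_to_docs <- function(mat) {
  mt <- methods::as(Matrix::t(mat), "CsparseMatrix")  # column = cell
  lapply(seq_len(ncol(mt)), function(d) {
    mt@i[(mt@p[d] + 1L):mt@p[d + 1L]] + 1L
  })
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Runs the collapsed Gibbs sampler with conditional
#' `p(z_i = k) prop-to (n_dk + a) (n_wk + b) / (n_k + V b)` where `a`, `b`
#' are the per-component prior weights. theta and phi are prior-smoothed
#' estimates aggregated from post-burn-in samples taken every
#' `sample_stride` sweeps; docTopic and wordTopic are the integer count
#' matrices of the final (estimator "mean") or modal (estimator "mode")
#' assignment state.
#'
#' @param mat filtered binary cells-by-peaks matrix; every cell needs at
#'   least one peak.
#' @param config an [lda_config()].
#' @param track_tokens also return per-token topic sample frequencies
#'   (forced on for estimator "mode").
#' @return object of class `lda_model` with elements `config`, `docTopic`
#'   (D x K), `wordTopic` (V x K), `theta` (D x K), `phi` (K x V), `z`
#'   (final token assignments with token doc/word indices), `cells`,
#'   `vocab`, `n_samples`, and optionally `token_freq`.
#' @export
fit_lda <- function(mat, config, track_tokens = FALSE) {
  stopifnot(inherits(config, "lda_config"))
  D <- nrow(mat); V <- ncol(mat)
  if (V == 0) stop("empty vocabulary")
  ntok <- Matrix::rowSums(mat)
  if (any(ntok == 0))
    stop("cell(s) with zero peaks: ",
         paste(head(rownames(mat)[ntok == 0], 3), collapse = ", "),
         "; filter the matrix first (see filter_matrix)")
  if (config$K > V)
    warning("more topics (", config$K, ") than peaks (", V, ")")
  pr <- prior_components(config, V)
  docs <- matrix_to_docs(mat)
  track <- track_tokens || config$estimator == "mode"
  set.seed(config$seed)
  fit <- lda_fit_cpp(docs, V, config$K, pr$a, pr$b, config$iterations,
                     config$burn_in, config$sample_stride, config$n_workers,
                     track)
  alpha_tot <- pr$a * config$K
  beta_tot <- pr$b * V
  if (config$estimator == "mean") {
    docTopic <- fit$docTopic
    wordTopic <- fit$wordTopic
    theta <- (fit$nd_mean + pr$a) / (ntok + alpha_tot)
    phi <- t(fit$nw_mean + pr$b) / (fit$nk_mean + beta_tot)
  } else {
    zmode <- max.col(fit$token_freq, ties.method = "first")
    docTopic <- counts_from_assignments(fit$token_doc + 1L, zmode, D, config$K)
    wordTopic <- counts_from_assignments(fit$token_word + 1L, zmode, V, config$K)
    nk <- colSums(wordTopic)
    theta <- (docTopic + pr$a) / (ntok + alpha_tot)
    phi <- t(wordTopic + pr$b) / (nk + beta_tot)
  }
  dimnames(docTopic) <- list(rownames(mat), NULL)
  dimnames(wordTopic) <- list(colnames(mat), NULL)
  dimnames(theta) <- list(rownames(mat), NULL)
  dimnames(phi) <- list(NULL, colnames(mat))
  out <- list(config = config, docTopic = docTopic, wordTopic = wordTopic,
              theta = theta, phi = phi,
              z = list(topic = fit$z + 1L, doc = fit$token_doc + 1L,
                       word = fit$token_word + 1L),
              cells = rownames(mat), vocab = colnames(mat),
              n_samples = fit$n_samples)
  if (track) out$token_freq <- fit$token_freq
  structure(out, class = "lda_model")
}

counts_from_assignments <- function(idx, z, n, K) {
  m <- matrix(0L, n, K)
  tab <- table(factor(idx, levels = seq_len(n)), factor(z, levels = seq_len(K)))
  m[] <- as.integer(tab)
  m
}

#' @export
print.lda_model <- function(x, ...) {
  cat("LDA model:", length(x$cells), "cells x", length(x$vocab), "peaks,",
      x$config$K, "topics\n")
  cat("  alpha =", x$config$alpha, " beta =", x$config$beta,
      " (", x$config$prior_scaling, "prior scaling )\n")
  cat("  ", x$n_samples, "posterior samples aggregated by",
      x$config$estimator, "\n")
  invisible(x)
}

#' Infer topic mixtures for new cells with phi fixed
#'
#' Gibbs sampling over the new cells' tokens only, holding the topic-peak
#' distributions at the trained values. Peaks absent from the model
#' vocabulary are dropped (with a logged count); a cell left with no
#' in-vocabulary peaks receives the prior mean row with a warning.
#'
#' @param model a fitted `lda_model`.
#' @param new_mat binary cells-by-peaks matrix for the new cells.
#' @param iterations Gibbs sweeps per cell (default 400).
#' @param seed RNG seed.
#' @return matrix of prior-smoothed theta rows (cells x K).
#' @export
predict_theta <- function(model, new_mat, iterations = 400, seed = 1) {
  keep <- colnames(new_mat) %in% model$vocab
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " peak(s) absent from the model vocabulary dropped")
  sub <- new_mat[, keep, drop = FALSE]
  # re-express columns in model vocabulary indices
  col_map <- match(colnames(sub), model$vocab)
  docs <- lapply(matrix_to_docs_safe(sub), function(d) col_map[d])
  empty <- vapply(docs, length, integer(1)) == 0
  if (any(empty))
    warning(sum(empty), " cell(s) with no in-vocabulary peaks; ",
            "returning prior mean rows")
  pr <- prior_components(model$config, length(model$vocab))
  set.seed(seed)
  theta <- lda_predict_cpp(docs, model$phi, pr$a, iterations,
                           iterations %/% 2, 1L)
  rownames(theta) <- rownames(new_mat)
  theta
}

matrix_to_docs_safe <- function(mat) {
  if (nrow(mat) == 0) return(list())
  mt <- methods::as(Matrix::t(mat), "CsparseMatrix")
  lapply(seq_len(ncol(mt)), function(d) {
    if (mt@p[d + 1L] == mt@p[d]) integer(0)
    else mt@i[(mt@p[d] + 1L):mt@p[d + 1L]] + 1L
  })
}

#' Export the binary corpus in BOW format
#'
#' Header lines `D`, `V`, `NNZ`, then one line per document:
#' `doc_len term_id:1 term_id:1 ...` (term ids 1-based).
#'
#' @param mat binary cells-by-peaks matrix.
#' @param path output file.
#' @export
export_bow <- function(mat, path) {
  if (nrow(mat) == 0 || ncol(mat) == 0 || sum(mat) == 0)
    stop("empty matrix cannot be exported")
  docs <- matrix_to_docs_safe(mat)
  lines <- c(nrow(mat), ncol(mat), as.integer(sum(mat)),
             vapply(docs, function(d) {
               if (length(d) == 0) "0"
               else paste(length(d), paste0(d, ":1", collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Import a BOW corpus file
#' @param path file written by [export_bow()] (or compatible).
#' @return binary sparse cells-by-peaks matrix (default dimnames).
#' @export
import_bow <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated BOW file: header incomplete")
  D <- as.integer(lines[1]); V <- as.integer(lines[2])
  if (is.na(D) || is.na(V)) stop("malformed BOW header")
  if (length(lines) != D + 3)
    stop("expected ", D, " document lines, found ", length(lines) - 3)
  ii <- integer(0); jj <- integer(0)
  dup <- FALSE
  for (d in seq_len(D)) {
    ln <- trimws(lines[d + 3])
    parts <- strsplit(ln, "\\s+")[[1]]
    len <- suppressWarnings(as.integer(parts[1]))
    if (is.na(len)) stop("malformed BOW line ", d + 3)
    if (len == 0) next
    if (length(parts) != len + 1) stop("malformed BOW line ", d + 3,
                                       ": length field mismatch")
    ids <- suppressWarnings(as.integer(sub(":.*$", "", parts[-1])))
    if (anyNA(ids) || any(ids < 1 | ids > V))
      stop("malformed BOW line ", d + 3, ": bad term id")
    if (anyDuplicated(ids)) { dup <- TRUE; ids <- unique(ids) }
    ii <- c(ii, rep(d, length(ids))); jj <- c(jj, ids)
  }
  if (dup) warning("duplicate (doc, term) entries collapsed to binary")
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(D, V),
                              dimnames = list(paste0("cell_", seq_len(D)),
                                              paste0("peak_", seq_len(V))))
  methods::as(mat, "CsparseMatrix")
}
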