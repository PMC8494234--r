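#' Split cells into disjoint cross-validation folds
#'
#' @param cell_ids character vector of cell identifiers.
#' @param folds number of folds (default 5).
#' @param seed RNG seed; the same seed reproduces the same partition.
#' @return list of disjoint cell-id sets whose sizes differ by at most 1
#'   and whose union is `cell_ids`.
#' @export
cv_split <- function(cell_ids, folds = 5, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  n <- length(cell_ids)
  if (n < folds) stop("need at least as many cells as folds")
  set.seed(seed)
  shuffled <- sample(cell_ids)
  split(shuffled, rep(seq_len(folds), length.out = n))
}

#' Held-out log-likelihood of one cell by a Chib-style estimator
#'
#' With the topic-peak distributions `phi` fixed, the cell's topic vector
#' is sampled by Gibbs; the pivot `z*` is the highest-probability
#' assignment visited, and `log p(w) = log p(w, z*) - log p-hat(z* | w)`,
#' where `p-hat` averages the full-sweep Gibbs transition kernel into `z*`
#' over states from the stationary chain. A left-to-right sequential
#' estimator is available as a cross-check (`method = "l2r"`).
#'
#' @param phi K x V matrix; rows must be proper distributions.
#' @param tokens integer vector of the held-out cell's peak indices
#'   (1-based, into the columns of `phi`).
#' @param alpha total cell-topic prior weight (per-component weight is
#'   `alpha / K`).
#' @param iterations Gibbs sweeps; half are used to locate the pivot and
#'   half as stationary samples (default 1000).
#' @param seed RNG seed.
#' @param method "chib" (default) or "l2r".
#' @return list of class `heldout_result`: `loglik` (nats), `n_tokens`,
#'   `perplexity = exp(-loglik / n_tokens)`.
#' @export
heldout_loglik_chib <- function(phi, tokens, alpha = 3.0, iterations = 1000,
                                seed = 1, method = c("chib", "l2r")) {
  method <- match.arg(method)
  if (length(tokens) == 0) stop("held-out cell has no tokens")
  rs <- rowSums(phi)
  if (any(abs(rs - 1) > 1e-6))
    stop("phi rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  if (any(tokens < 1 | tokens > ncol(phi)))
    stop("token index outside the phi vocabulary")
  K <- nrow(phi)
  a <- alpha / K
  set.seed(seed)
  if (K == 1) {
    ll <- sum(log(phi[1, tokens]))
  } else if (method == "chib") {
    half <- max(1L, as.integer(iterations) %/% 2L)
    ll <- chib_loglik_cpp(as.integer(tokens), phi, a, half, half)
  } else {
    ll <- l2r_loglik_cpp(as.integer(tokens), phi, a,
                         max(10L, as.integer(iterations) %/% 10L))
  }
  n <- length(tokens)
  structure(list(loglik = ll, n_tokens = n, perplexity = exp(-ll / n)),
            class = "heldout_result")
}

# deterministic per-(K, fold) seed derived from the master seed
derive_seed <- function(seed, k_index, fold) {
  as.integer((as.numeric(seed) * 2654435761 + k_index * 97911 + fold * 7919) %%
               2147483647) + 1L
}

#' Cross-validated topic-number selection
#'
#' For each candidate K and each of `folds` folds, an LDA model is trained
#' on the remaining folds and the held-out fold is scored by Chib-style
#' perplexity. The recommended K minimizes the mean held-out perplexity
#' (ties toward smaller K); the final K used for the production model is
#' `ceiling(1.5 * recommended)`.
#'
#' @param mat filtered binary cells-by-peaks matrix.
#' @param k_grid integer vector of candidate topic counts.
#' @param folds number of CV folds (default 5).
#' @param seed master seed; per-fold model seeds are derived from it.
#' @param config an [lda_config()] template; its `K` and `seed` are
#'   overridden per fold.
#' @param chib_iterations Gibbs sweeps for each held-out cell (default 400).
#' @return list of class `cv_report`: `k_grid`, `fold_perplexity`
#'   (|grid| x folds), `mean_perplexity`, `sd_perplexity`,
#'   `recommended_k`, `final_k`, `failures`.
#' @export
select_num_topics <- function(mat, k_grid, folds = 5, seed = 1,
                              config = lda_config(K = 2),
                              chib_iterations = 400) {
  if (length(k_grid) == 0) stop("k_grid is empty")
  k_grid <- sort(unique(as.integer(k_grid)))
  fold_sets <- cv_split(rownames(mat), folds = folds, seed = seed)
  perp <- matrix(NA_real_, length(k_grid), folds,
                 dimnames = list(paste0("K", k_grid), NULL))
  failures <- character(0)
  for (ki in seq_along(k_grid)) {
    K <- k_grid[ki]
    for (f in seq_len(folds)) {
      res <- tryCatch({
        test_cells <- fold_sets[[f]]
        train <- mat[!rownames(mat) %in% test_cells, , drop = FALSE]
        train <- train[Matrix::rowSums(train) > 0,
                       Matrix::colSums(train) > 0, drop = FALSE]
        cfg <- config
        cfg$K <- K
        cfg$seed <- derive_seed(seed, ki, f)
        model <- fit_lda(train, cfg)
        test <- mat[test_cells, , drop = FALSE]
        keep <- colnames(test) %in% model$vocab
        test <- test[, keep, drop = FALSE]
        col_map <- match(colnames(test), model$vocab)
        docs <- matrix_to_docs_safe(test)
        pp <- vapply(seq_along(docs), function(i) {
          tk <- col_map[docs[[i]]]
          if (length(tk) == 0) return(NA_real_)
          heldout_loglik_chib(model$phi, tk, alpha = cfg$alpha,
                              iterations = chib_iterations,
                              seed = derive_seed(cfg$seed, ki, i))$perplexity
        }, numeric(1))
        mean(pp, na.rm = TRUE)
      }, error = function(e) {
        failures <<- c(failures,
                       sprintf("K=%d fold=%d: %s", K, f, conditionMessage(e)))
        NA_real_
      })
      perp[ki, f] <- res
    }
  }
  mean_perp <- rowMeans(perp, na.rm = TRUE)
  sd_perp <- apply(perp, 1, sd, na.rm = TRUE)
  rec <- k_grid[which.min(mean_perp)]  # ties -> smaller K (sorted grid)
  structure(list(k_grid = k_grid, fold_perplexity = perp,
                 mean_perplexity = mean_perp, sd_perplexity = sd_perp,
                 recommended_k = rec,
                 final_k = as.integer(ceiling(1.5 * rec)),
                 failures = failures),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validated topic selection\n")
  for (i in seq_along(x$k_grid))
    cat(sprintf("  K = %3d  mean perplexity = %.3f (sd %.3f)\n",
                x$k_grid[i], x$mean_perplexity[i], x$sd_perplexity[i]))
  cat("recommended K =", x$recommended_k, "; final K (1.5x, ceiling) =",
      x$final_k, "\n")
  if (length(x$failures) > 0)
    cat(length(x$failures), "fold failure(s)\n")
  invisible(x)
}
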