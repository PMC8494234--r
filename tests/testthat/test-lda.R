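toy_corpus <- function() {
  mat <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 3, 4), x = 1,
                              dims = c(2, 4),
                              dimnames = list(c("c1", "c2"),
                                              paste0("p", 1:4)))
  methods::as(mat, "CsparseMatrix")
}

test_that("K = 1 degenerates to prior-smoothed peak frequencies", {
  sim <- simulate_matrix(n_cells = 40, n_types = 2, peaks_per_type = 10,
                         shared_peaks = 5, seed = 3)
  cfg <- lda_config(K = 1, alpha = 3, beta = 2, iterations = 20,
                    burn_in = 10, sample_stride = 1, seed = 1)
  m <- fit_lda(sim$matrix, cfg)
  expect_equal(as.numeric(m$theta), rep(1, nrow(sim$matrix)))
  V <- ncol(sim$matrix)
  b <- 2 / V
  expected_phi <- (Matrix::colSums(sim$matrix) + b) /
    (sum(sim$matrix) + 2)
  expect_equal(as.numeric(m$phi), as.numeric(expected_phi), tolerance = 1e-12)
})

test_that("count conservation holds per cell and in total", {
  sim <- simulate_matrix(n_cells = 60, n_types = 3, peaks_per_type = 15,
                         shared_peaks = 10, seed = 4)
  cfg <- lda_config(K = 4, alpha = 3, beta = 0.06 * ncol(sim$matrix),
                    iterations = 100, burn_in = 50, sample_stride = 5,
                    seed = 2)
  m <- fit_lda(sim$matrix, cfg)
  expect_equal(unname(rowSums(m$docTopic)),
               unname(Matrix::rowSums(sim$matrix)))
  expect_equal(sum(m$docTopic), sum(m$wordTopic))
  expect_equal(max(abs(rowSums(m$theta) - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(rowSums(m$phi) - 1)), 0, tolerance = 1e-9)
})

test_that("zero-token cells are rejected with a pointer to filtering", {
  mat <- toy_corpus()
  mat["c2", ] <- 0
  expect_error(fit_lda(mat, lda_config(K = 2)), "filter")
})

test_that("Gibbs marginals match exhaustive enumeration on a tiny corpus", {
  mat <- toy_corpus()
  K <- 2; V <- 4; a <- 0.1; b <- 0.1
  marg <- enumerate_lda_posterior(c(1, 1, 2, 2), c(1, 2, 3, 4), 2, V, K, a, b)
  cfg <- lda_config(K = K, alpha = K * a, beta = V * b, iterations = 12000,
                    burn_in = 2000, sample_stride = 1, seed = 11)
  m <- fit_lda(mat, cfg, track_tokens = TRUE)
  tv <- max(colSums(abs(t(m$token_freq) - marg)) / 2)
  expect_lt(tv, 0.05)
})

test_that("mode estimator yields integer counts that conserve tokens", {
  sim <- simulate_matrix(n_cells = 50, n_types = 2, peaks_per_type = 10,
                         shared_peaks = 5, seed = 5)
  cfg <- lda_config(K = 3, alpha = 3, beta = 0.06 * ncol(sim$matrix),
                    iterations = 80, burn_in = 40, sample_stride = 4,
                    seed = 3, estimator = "mode")
  m <- fit_lda(sim$matrix, cfg)
  expect_true(all(m$docTopic == round(m$docTopic)))
  expect_equal(unname(rowSums(m$docTopic)),
               unname(Matrix::rowSums(sim$matrix)))
})

test_that("cell order does not change the recovered structure", {
  # the chain visits tokens in storage order, so permuting cells permutes
  # the random stream: equality is statistical (same partition of cells up
  # to topic relabeling), not bitwise
  sim <- simulate_matrix(n_cells = 150, n_types = 3, peaks_per_type = 30,
                         shared_peaks = 10, detect_rate_specific = 0.45,
                         detect_rate_background = 0.005, seed = 6)
  cfg <- lda_config(K = 3, alpha = 3, beta = 0.06 * ncol(sim$matrix),
                    iterations = 300, burn_in = 150, sample_stride = 5,
                    seed = 4)
  m1 <- fit_lda(sim$matrix, cfg)
  perm <- rev(seq_len(nrow(sim$matrix)))
  m2 <- fit_lda(sim$matrix[perm, ], cfg)
  ari <- mclust::adjustedRandIndex(
    apply(m1$theta, 1, which.max),
    apply(m2$theta[rownames(m1$theta), ], 1, which.max))
  expect_equal(ari, 1)
})

test_that("single-worker runs are bit-reproducible; workers approximate serial", {
  sim <- simulate_matrix(n_cells = 120, n_types = 3, peaks_per_type = 20,
                         shared_peaks = 10, seed = 7)
  V <- ncol(sim$matrix)
  cfg <- lda_config(K = 3, alpha = 3, beta = 0.06 * V, iterations = 200,
                    burn_in = 100, sample_stride = 5, seed = 5)
  m1 <- fit_lda(sim$matrix, cfg)
  m2 <- fit_lda(sim$matrix, cfg)
  expect_identical(m1$theta, m2$theta)
  # held-out perplexity of partitioned vs serial training within 2%
  test_idx <- 1:20
  train <- sim$matrix[-test_idx, ]
  cfg_tr <- cfg
  score <- function(model) {
    mean(vapply(test_idx, function(i) {
      toks <- match(colnames(sim$matrix)[sim$matrix[i, ] > 0], model$vocab)
      toks <- toks[!is.na(toks)]
      heldout_loglik_chib(model$phi, toks, alpha = 3, iterations = 400,
                          seed = i)$perplexity
    }, numeric(1)))
  }
  p_serial <- score(fit_lda(train, cfg_tr))
  cfg_tr$n_workers <- 4L
  p_par <- score(fit_lda(train, cfg_tr))
  expect_lt(abs(p_serial - p_par) / p_serial, 0.02)
})

test_that("predict_theta concentrates on the right planted topic", {
  sim <- simulate_matrix(n_cells = 200, n_types = 2, peaks_per_type = 40,
                         shared_peaks = 0,
                         detect_rate_specific = 0.5,
                         detect_rate_background = 0.005, seed = 8)
  V <- ncol(sim$matrix)
  cfg <- lda_config(K = 2, alpha = 1, beta = 0.06 * V, iterations = 300,
                    burn_in = 150, sample_stride = 5, seed = 6)
  m <- fit_lda(sim$matrix, cfg)
  new_cells <- sim$matrix[1:10, ]
  th <- predict_theta(m, new_cells, iterations = 400, seed = 7)
  expect_equal(dim(th), c(10, 2))
  expect_true(all(apply(th, 1, max) > 0.9))
  # predicted dominant topic equals the training dominant topic per cell
  expect_equal(unname(apply(th, 1, which.max)),
               unname(apply(m$theta[1:10, ], 1, which.max)))
  # empty new-cell set
  expect_equal(nrow(predict_theta(m, sim$matrix[0, ], seed = 1)), 0)
})

test_that("predict_theta under uniform phi returns the prior mean", {
  sim <- simulate_matrix(n_cells = 30, n_types = 2, peaks_per_type = 10,
                         shared_peaks = 0, seed = 9)
  cfg <- lda_config(K = 2, alpha = 2, beta = 1, iterations = 50,
                    burn_in = 25, sample_stride = 1, seed = 1)
  m <- fit_lda(sim$matrix, cfg)
  m$phi[] <- 1 / ncol(sim$matrix)
  th <- predict_theta(m, sim$matrix[1:5, ], iterations = 2000, seed = 3)
  expect_true(all(abs(th - 0.5) < 0.05))
})

test_that("BOW export/import round trip preserves the corpus", {
  sim <- simulate_matrix(n_cells = 25, n_types = 2, peaks_per_type = 8,
                         shared_peaks = 4, seed = 10)
  f <- tempfile(fileext = ".bow")
  export_bow(sim$matrix, f)
  back <- import_bow(f)
  expect_equal(unname(as.matrix(back)), unname(as.matrix(sim$matrix)))
  expect_error(export_bow(sim$matrix[0, ], f), "empty")
})

test_that("BOW import handles duplicates and malformed lines", {
  f <- tempfile(fileext = ".bow")
  writeLines(c("2", "3", "4", "2 1:1 1:1", "2 2:1 3:1"), f)
  expect_warning(mat <- import_bow(f), "duplicate")
  expect_equal(as.numeric(mat[1, ]), c(1, 0, 0))
  writeLines(c("1", "3", "2", "2 1:1"), f)
  expect_error(import_bow(f), "line 4")
})
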