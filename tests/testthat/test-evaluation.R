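test_that("confusion metrics match hand-computed cases", {
  cm <- matrix(c(8, 3, 2, 7), 2, 2)  # rows = truth: [[8,2],[3,7]]
  m <- confusion_metrics(cm)
  expect_equal(m$acc, 0.75)
  expect_equal(unname(m$pnm[1]), 11 / 21)
  d <- diag(c(5, 9, 3))
  md <- confusion_metrics(d)
  expect_equal(md$acc, 1)
  expect_equal(md$kappa, 1)
  expect_equal(unname(md$pnm), rep(1, 3))
  expect_equal(md$fpr_max, 0)
  off <- matrix(c(0, 10, 10, 0), 2, 2)
  expect_equal(unname(confusion_metrics(off)$pnm), c(-1, -1))
  expect_error(confusion_metrics(matrix(0, 2, 2)), "invalid")
})

test_that("metrics agree with independent textbook formulas on random matrices", {
  set.seed(35)
  for (rep in 1:200) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, lambda = 8), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    m <- confusion_metrics(cm)
    tot <- sum(cm)
    expect_equal(m$acc, sum(diag(cm)) / tot)
    expect_equal(unname(m$pnm), pnm_oracle(cm))
    # Cohen's kappa via the standard expected-agreement formula
    pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
    expect_equal(m$kappa, (m$acc - pe) / (1 - pe), tolerance = 1e-12)
    for (i in seq_len(K)) {
      expect_equal(unname(m$tpr[i]), cm[i, i] / sum(cm[i, ]))
      expect_equal(unname(m$fpr[i]),
                   (sum(cm[, i]) - cm[i, i]) / (tot - sum(cm[i, ])))
    }
  }
})

test_that("the composite index weights the four summaries as printed", {
  perfect <- confusion_metrics(diag(c(10, 10)))
  expect_equal(idx_metric(perfect), 0)
  worthless <- list(kappa = 0, fpr_max = 1, acc = 0.5, pnm_min = 0)
  expect_equal(idx_metric(worthless), 0.925)
  # improving any single component lowers the index
  base <- list(kappa = 0.4, fpr_max = 0.3, acc = 0.7, pnm_min = 0.4)
  for (fld in c("kappa", "acc", "pnm_min")) {
    better <- base; better[[fld]] <- better[[fld]] + 0.1
    expect_lt(idx_metric(better), idx_metric(base))
  }
  better <- base; better$fpr_max <- better$fpr_max - 0.1
  expect_lt(idx_metric(better), idx_metric(base))
})

test_that("box-constraint tuning is deterministic and ties break small", {
  set.seed(36)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, mean = 0), n, 2),
             matrix(rnorm(n * 2, mean = 6), n, 2))
  y <- rep(c("a", "b"), each = n)
  res <- tune_and_classify(x, y, x, k1 = 2, seed = 3)
  expect_equal(mean(res$pred == y), 1)    # separable clouds
  expect_equal(res$chosen_C, 0.01)        # all C tie; smallest wins
  res2 <- tune_and_classify(x, y, x, k1 = 2, seed = 3)
  expect_identical(res2$chosen_C, res$chosen_C)
  expect_identical(res2$pred, res$pred)
  expect_error(tune_and_classify(x, rep("a", 2 * n), x), "single class")
})

test_that("CCA recognition finds the stimulus frequency and its invariances", {
  fs <- 250
  t <- seq_len(2 * fs) / fs
  epoch <- cbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t) + 0.1)
  res <- cca_ssvep_classify(epoch, c(8, 10, 12), fs)
  expect_equal(res$freq, 10)
  # adding a harmonic, rescaling a channel, or a DC offset changes nothing
  epoch2 <- epoch + cbind(0.5 * sin(2 * pi * 20 * t), 0)
  expect_equal(cca_ssvep_classify(epoch2, c(8, 10, 12), fs)$freq, 10)
  epoch3 <- sweep(epoch, 2, c(13, 0.2), `*`)
  epoch3 <- epoch3 + 40
  expect_equal(cca_ssvep_classify(epoch3, c(8, 10, 12), fs)$freq, 10)
  # harmonics above Nyquist are truncated rather than fatal
  expect_equal(cca_ssvep_classify(epoch, c(10, 60), fs, n_harmonics = 6)$freq,
               10)
})

test_that("the persistence rule reproduces hand-computed timing values", {
  fs <- 400
  dt <- 1000 / fs
  # (1) planning throughout 1.5 s: latency -1500 + 35 * 2.5 ms, one run
  s1 <- rep("planning", 600)
  t1 <- recognition_timing(s1, fs)
  expect_false(t1$failed)
  expect_equal(t1$latency_ms, -1500 + 35 * dt)
  expect_equal(t1$cr_max_ms, 1500)
  expect_equal(t1$cr_median_ms, 1500)
  # (2) a single 50 ms burst never qualifies
  s2 <- c(rep("rest", 200), rep("planning", 20), rep("rest", 380))
  t2 <- recognition_timing(s2, fs)
  expect_true(t2$failed)
  expect_true(is.na(t2$latency_ms))
  # (3) alternating 100 ms planning / 100 ms rest
  s3 <- rep(c(rep("planning", 40), rep("rest", 40)), length.out = 600)
  t3 <- recognition_timing(s3, fs)
  expect_false(t3$failed)
  expect_equal(t3$cr_max_ms, 100)
  expect_equal(t3$latency_ms, -1500 + 35 * dt)
  expect_equal(length(t3$runs_ms), 8)
})
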