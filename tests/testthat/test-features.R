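test_that("Higuchi dimension is calibrated on known signal classes", {
  expect_equal(higuchi_fd(seq(0, 1, length.out = 1000), kmax = 8), 1,
               tolerance = 0.05)
  set.seed(16)
  expect_equal(higuchi_fd(rnorm(1000), kmax = 8), 2, tolerance = 0.15)
  x <- sin(2 * pi * 2 * seq(0, 1, length.out = 500))  # far above Nyquist
  expect_lt(higuchi_fd(x, kmax = 8), 1.3)
  expect_error(higuchi_fd(1:10, kmax = 8), "too short")
})

test_that("Sevcik dimension matches its closed form and is scale-invariant", {
  # straight line, N = 100: 1 + ln(sqrt(2)) / ln(2 * 99) exactly
  expect_equal(sevcik_fd(seq_len(100)), 1 + log(sqrt(2)) / log(198),
               tolerance = 1e-12)
  # converges toward 1 on smooth curves as N grows
  expect_equal(sevcik_fd(seq_len(1000)), 1, tolerance = 0.05)
  set.seed(17)
  x <- rnorm(500)
  expect_gt(sevcik_fd(x), 1.5)
  expect_equal(sevcik_fd(x), sevcik_fd(100 * x + 7))
  expect_equal(sevcik_fd(rep(4, 50)), 1)
})

test_that("band power concentrates where the signal lives and obeys Parseval", {
  fs <- 400
  # one full second: the rectangular-window main lobe (~ +-1 Hz) then sits
  # comfortably inside the 8-12 Hz band
  x <- sin(2 * pi * 10 * seq_len(fs) / fs)
  bp <- band_power(x, fs, c(8, 12))
  tot <- mean(x^2)
  expect_gt(bp / tot, 0.9)
  expect_equal(band_power(numeric(100), fs, c(8, 12)), 0)
  set.seed(18)
  y <- rnorm(100)
  bands <- list(c(0.1, 4), c(8, 12), c(13, 17), c(18, 24), c(26, 30),
                c(30, 50), c(50, 70))
  s <- sum(vapply(bands, function(b) band_power(y, fs, b), numeric(1)))
  expect_lte(s, mean(y^2) + 1e-12)
  expect_error(band_power(y, fs, c(150, 250)), "Nyquist")
})

test_that("the feature bank has exactly 12 features per channel", {
  fs <- 400
  set.seed(19)
  win <- matrix(rnorm(300), 100, 3,
                dimnames = list(NULL, c("Cz", "CP1", "CP2")))
  fv <- extract_features(win, fs)
  expect_length(fv, 36L)
  expect_identical(names(fv)[1:12], paste("Cz", feature_names(), sep = "_"))
  z <- extract_features(matrix(0, 100, 1, dimnames = list(NULL, "Cz")), fs)
  expect_equal(unname(z[c("Cz_MAV", "Cz_WL", "Cz_RF", "Cz_BP_8_12")]),
               rep(0, 4))
  one <- extract_features(matrix(c(0, 1, 0, 1, rep(0, 96)), 100, 1,
                                 dimnames = list(NULL, "Cz")), fs)
  expect_equal(unname(one[["Cz_WL"]]), 4)  # three unit steps plus the return
})

test_that("waveform length sums successive absolute differences", {
  x <- c(0, 1, 0, 1)
  expect_equal(sum(abs(diff(x))), 3)
  win <- matrix(c(x, rep(0, 96)), 100, 1, dimnames = list(NULL, "Cz"))
  expect_equal(unname(extract_features(win, 400)[["Cz_WL"]]),
               sum(abs(diff(win[, 1]))))
})

test_that("features scale with the documented homogeneity degrees", {
  fs <- 400
  set.seed(20)
  x <- rnorm(100)
  w1 <- matrix(x, dimnames = list(NULL, "Cz"))
  w2 <- matrix(3 * x, dimnames = list(NULL, "Cz"))
  f1 <- extract_features(w1, fs); f2 <- extract_features(w2, fs)
  expect_equal(f2[["Cz_MAV"]], 3 * f1[["Cz_MAV"]])
  expect_equal(f2[["Cz_WL"]], 3 * f1[["Cz_WL"]])
  expect_equal(f2[["Cz_BP_8_12"]], 9 * f1[["Cz_BP_8_12"]])
  expect_equal(f2[["Cz_FDH"]], f1[["Cz_FDH"]])
  expect_equal(f2[["Cz_FDSH"]], f1[["Cz_FDSH"]])
})

test_that("sliding extraction yields T - window + 1 vectors at stride 1", {
  fs <- 400
  set.seed(23)
  rec <- matrix(rnorm(150 * 2), 150, 2, dimnames = list(NULL, c("Cz", "CP1")))
  sf <- sliding_features(rec, fs, window_ms = 250, stride = 1L)
  n <- round(0.25 * fs)
  expect_equal(nrow(sf$features), 150 - n + 1)
  expect_equal(ncol(sf$features), 24)
  expect_equal(sf$end_sample[1], n)
  # a window extracted directly matches the corresponding sliding row
  direct <- extract_features(rec[21:120, , drop = FALSE], fs)
  expect_equal(sf$features[21, ], direct)
  expect_error(sliding_features(rec[1:50, ], fs), "shorter")
})
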