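test_that("virtual distance is the decreasing exponential of similarity", {
  expect_equal(virtual_distance(0), 1)
  expect_equal(virtual_distance(1, 5), exp(-5))
  expect_equal(virtual_distance(-1, 5), exp(5))
  cc <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(virtual_distance(cc, 3)) < 0))
})

test_that("baseline weights are inverse-distance normalized", {
  m <- electrode_montage(
    c("T", "N1", "N2"),
    positions = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    neighbors_small = list(T = c("N1", "N2")), targets = "T")
  w <- baseline_weights(m, "T", "lar_small")
  expect_equal(unname(w), c(2 / 3, 1 / 3))
  expect_equal(sum(w), 1)
  wu <- baseline_weights(m, "T", "lar_small", unit_distance = TRUE)
  expect_equal(unname(wu), c(0.5, 0.5))
  m2 <- electrode_montage(
    c("T", "N1", "N2"),
    positions = rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
    neighbors_small = list(T = c("N1", "N2")), targets = "T")
  expect_error(baseline_weights(m2, "T", "lar_small"), "oincident")
})

test_that("amplitude correction follows the three printed branches", {
  n <- 40
  set.seed(1)
  # independent channels: every pairwise r below the cutoff
  win <- cbind(t = rnorm(n), a = rnorm(n), b = rnorm(n))
  vals <- c(t = 1, a = 2, b = 9)
  ac <- amplitude_correction(vals, win, vstd_min = 0.1, vstd_max = 1,
                             r_cut = 0.85)
  expect_equal(unname(ac), rep(2, 3))  # median over SS for each member
  # two tightly correlated members, one independent
  base <- rnorm(n)
  win2 <- cbind(t = base + rnorm(n, sd = 0.05),
                a = base + rnorm(n, sd = 0.05), b = rnorm(n))
  vals2 <- c(t = 4, a = 6, b = 100)
  ac2 <- amplitude_correction(vals2, win2, vstd_min = 0.1, vstd_max = 1,
                              r_cut = 0.85)
  expect_equal(unname(ac2[c("t", "a")]), c(5, 5))  # median over Se = {t, a}
  expect_equal(unname(ac2[["b"]]), median(vals2))  # b: min pairwise r < cut
  # quiet sample: dispersion below threshold leaves amplitudes untouched
  ac3 <- amplitude_correction(c(t = 1, a = 1.1), win[, 1:2],
                              vstd_min = 1, vstd_max = 8)
  expect_equal(unname(ac3), c(0, 0))
  # singleton set never nulls the signal
  expect_equal(unname(amplitude_correction(c(t = 5), win[, 1, drop = FALSE],
                                           0.01, 1)), 0)
})

test_that("identical channels cancel exactly in every mode", {
  m <- gait_montage()
  set.seed(4)
  w <- cumsum(rnorm(300))
  rec <- matrix(w, 300, 20, dimnames = list(NULL, m$electrodes))
  for (mode in c("ad_war", "ad_lar_small", "war", "lar_small")) {
    fr <- filter_record(rec, m, targets = "Cz",
                        config = filter_config(mode), fs = 400)
    expect_lt(max(abs(fr$filtered[40:300, "Cz"])), 1e-10)
  }
})

test_that("uniform similarity reduces the adaptive filter to the unit-distance baseline", {
  m <- occ_montage()
  set.seed(5)
  target_sig <- rnorm(400)
  shared <- cumsum(rnorm(400)) * 0.2 + rnorm(400)
  rec <- matrix(shared, 400, length(m$electrodes),
                dimnames = list(NULL, m$electrodes))
  rec[, "Oz"] <- target_sig
  ad <- filter_record(rec, m, targets = "Oz",
                      config = filter_config("ad_war", unit_distance = TRUE),
                      fs = 250)
  bl <- filter_record(rec, m, targets = "Oz",
                      config = filter_config("war", unit_distance = TRUE),
                      fs = 250)
  post <- 25:400
  expect_lt(max(abs(ad$filtered[post, "Oz"] - bl$filtered[post, "Oz"])),
            1e-10)
})

test_that("weights normalize to one and favor the less similar neighbor", {
  mo <- occ_montage()
  rec <- common_mode_record(mo, seed = 12, n = 400)
  cfg <- filter_config("ad_war")
  st <- filter_state(mo, "Oz", cfg, fs = 250)
  for (t in 1:400) {
    r <- filter_step(st, rec$record[t, ])
    st <- r$state
    out <- r$output$Oz
    if (out$warmup) next
    expect_equal(sum(out$weights), 1, tolerance = 1e-12)
    cc <- out$selection$ccc_values[out$selection$selected]
    if (length(cc) >= 2) {
      ord <- order(cc)
      expect_true(all(diff(out$weights[ord]) <= 1e-14))
    }
  }
})

test_that("batch filtering equals streaming sample-for-sample", {
  m <- gait_montage()
  set.seed(2)
  rec <- matrix(rnorm(200 * 20), 200, 20,
                dimnames = list(NULL, m$electrodes))
  for (mode in c("ad_lar_small", "ad_war")) {
    cfg <- filter_config(mode)
    fr <- filter_record(rec, m, targets = c("Cz", "CP1"), config = cfg,
                        fs = 400)
    st <- filter_state(m, c("Cz", "CP1"), cfg, fs = 400)
    outs <- matrix(NA_real_, 200, 2)
    for (t in 1:200) {
      r <- filter_step(st, rec[t, ])
      st <- r$state
      outs[t, ] <- c(r$output$Cz$value, r$output$CP1$value)
    }
    expect_lt(max(abs(outs - fr$filtered)), 1e-10)
  }
})

test_that("the filter is causal and deterministic", {
  mo <- occ_montage()
  rec <- common_mode_record(mo, seed = 8, n = 300)$record
  cfg <- filter_config("ad_war")
  a <- filter_record(rec, mo, targets = "Oz", config = cfg, fs = 250)
  b <- filter_record(rec, mo, targets = "Oz", config = cfg, fs = 250)
  expect_identical(a$filtered, b$filtered)       # no hidden randomness
  rec2 <- rec
  rec2[201, ] <- rec2[201, ] + 500               # future perturbation
  c2 <- filter_record(rec2, mo, targets = "Oz", config = cfg, fs = 250)
  expect_identical(a$filtered[1:200, ], c2$filtered[1:200, ])
  expect_false(isTRUE(all.equal(a$filtered[201, ], c2$filtered[201, ])))
  # zero record stays zero
  z <- matrix(0, 100, length(mo$electrodes),
              dimnames = list(NULL, mo$electrodes))
  fz <- filter_record(z, mo, targets = "Oz", config = cfg, fs = 250)
  expect_equal(max(abs(fz$filtered)), 0)
})

test_that("warm-up honors the configured policy", {
  mo <- occ_montage()
  rec <- common_mode_record(mo, seed = 9, n = 60)$record
  fr_pass <- filter_record(rec, mo, targets = "Oz",
                           config = filter_config("ad_war",
                                                  warmup_policy = "passthrough"),
                           fs = 250)
  expect_equal(fr_pass$filtered[1:24, "Oz"], unname(rec[1:24, "Oz"]))
  gb <- baseline_weights(mo, "Oz", "war")
  fr_base <- filter_record(rec, mo, targets = "Oz",
                           config = filter_config("ad_war"), fs = 250)
  expect_equal(unname(fr_base$filtered[1, "Oz"]),
               unname(rec[1, "Oz"] - sum(gb * rec[1, names(gb)])))
  expect_true(all(fr_base$diagnostics$Oz$warmup[1:24]))
  expect_false(any(fr_base$diagnostics$Oz$warmup[25:60]))
})

test_that("channel mismatches are contract errors", {
  mo <- occ_montage()
  rec <- matrix(0, 50, 3, dimnames = list(NULL, c("Oz", "O1", "O2")))
  expect_error(filter_record(rec, mo, targets = "Oz",
                             config = filter_config("ad_war"), fs = 250),
               "lacks montage channel")
  st <- filter_state(mo, "Oz", filter_config("ad_war"), fs = 250)
  expect_error(filter_step(st, c(1, 2, 3)), "channels")
  full <- common_mode_record(mo, seed = 1, n = 30)$record
  expect_error(filter_record(full, mo, targets = "Qz",
                             config = filter_config("ad_war"), fs = 250),
               "unknown target")
})
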