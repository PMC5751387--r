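test_that("records are bit-identical for the same seed and differ across seeds", {
  a <- gen_ssvep(ssvep_demo_spec(duration = 1, seed = 5))
  b <- gen_ssvep(ssvep_demo_spec(duration = 1, seed = 5))
  expect_identical(a$record, b$record)
  c2 <- gen_ssvep(ssvep_demo_spec(duration = 1, seed = 6))
  expect_false(identical(a$record, c2$record))
})

test_that("a noiseless local component appears only on its channel", {
  mo <- occ_montage()
  sp <- synthetic_spec(mo, fs = 250, duration = 4,
                       local = list(list(channel = "Oz", freq = 12,
                                         amplitude = 2)),
                       noise_sigma = 0, seed = 1)
  rec <- gen_ssvep(sp)
  peak_power <- vapply(mo$electrodes, function(ch) {
    sp <- magnitude_spectrum(rec$record[, ch], 250)
    max(sp$mag)
  }, numeric(1))
  expect_gt(peak_power[["Oz"]], 100)
  expect_lt(max(peak_power[setdiff(mo$electrodes, "Oz")]), 1e-8)
  expect_equal(rec$truth$freq, 12)
  expect_equal(rec$truth$channel, "Oz")
})

test_that("generated power decomposes into the specified components", {
  mo <- occ_montage()
  # deterministic sinusoids at full cycles: power is exactly sum(a^2 / 2)
  sp <- synthetic_spec(mo, fs = 250, duration = 4,
                       common = list(list(type = "sine", freq = 10,
                                          amplitude = 3)),
                       local = list(list(channel = "Oz", freq = 25,
                                         amplitude = 2)),
                       noise_sigma = 0, seed = 2)
  rec <- gen_ssvep(sp)
  expect_equal(mean(rec$record[, "Oz"]^2), 3^2 / 2 + 2^2 / 2,
               tolerance = 0.01)
  expect_equal(mean(rec$record[, "P3"]^2), 3^2 / 2, tolerance = 0.01)
  # with noise: variance adds within a few percent at this length
  sp2 <- synthetic_spec(mo, fs = 250, duration = 40,
                        common = list(list(type = "sine", freq = 10,
                                           amplitude = 3)),
                        noise_sigma = 2, seed = 3)
  rec2 <- gen_ssvep(sp2)
  expect_equal(mean(rec2$record[, "Oz"]^2), 3^2 / 2 + 4, tolerance = 0.05)
})

test_that("adding a component does not perturb the other streams", {
  mo <- occ_montage()
  base <- synthetic_spec(mo, fs = 250, duration = 1,
                         common = list(list(type = "pink_noise",
                                            amplitude = 5)),
                         noise_sigma = 0, seed = 4)
  plus <- synthetic_spec(mo, fs = 250, duration = 1,
                         common = list(list(type = "pink_noise",
                                            amplitude = 5)),
                         local = list(list(channel = "Oz", freq = 12,
                                           amplitude = 1)),
                         noise_sigma = 0, seed = 4)
  a <- gen_ssvep(base); b <- gen_ssvep(plus)
  expect_identical(a$record[, "P3"], b$record[, "P3"])
})

test_that("bursts multiply only the named channel over their window", {
  mo <- occ_montage()
  clean <- common_mode_record(mo, seed = 6)
  burst <- common_mode_record(mo, seed = 6, burst_channel = "PO3")
  delta <- abs(clean$record - burst$record)
  expect_equal(sum(colSums(delta)[setdiff(mo$electrodes, "PO3")]), 0)
  hit <- which(delta[, "PO3"] > 0)
  expect_gte(min(hit), 499)
  expect_lte(max(hit), 627)
  ratio <- burst$record[hit, "PO3"] / clean$record[hit, "PO3"]
  expect_equal(unname(ratio), rep(50, length(hit)), tolerance = 1e-9)
})

test_that("component amplitude drives the measured SSVEP response monotonically", {
  snrs <- vapply(c(0.5, 2, 8), function(a) {
    rec <- gen_ssvep(ssvep_demo_spec(stim_amplitude = a, seed = 11))
    ssvep_snr(magnitude_spectrum(rec$record[, "Oz"], rec$fs), 12)
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("gait epochs carry the documented structure and effects", {
  m <- gait_montage()
  ep <- gen_gait_epochs(m, seed = 12)
  expect_length(ep$epochs, 60L)
  expect_equal(sum(ep$label == "planning"), 24L)
  expect_equal(sum(ep$label == "rest"), 36L)
  expect_equal(as.vector(table(ep$session)), rep(10L, 6))  # 4 + 6 / session
  expect_equal(nrow(ep$epochs[[1]]), 600L)              # 1.5 s at 400 Hz
  expect_equal(nrow(ep$epochs[[which(ep$label == "rest")[1]]]), 800L)
  expect_identical(gen_gait_epochs(m, seed = 12)$epochs, ep$epochs)
  # planted effects: after removing the shared EOG/line interference with
  # the reference filter, low-frequency band power on Cz separates the
  # classes (on the raw channel the common mode masks the ramp by design)
  cz_bp <- function(epochs) {
    cfg <- filter_config("war")
    vapply(seq_along(epochs$epochs), function(e) {
      fr <- filter_record(epochs$epochs[[e]], m, targets = "Cz",
                          config = cfg, fs = epochs$fs)
      band_power(fr$filtered[1:600, "Cz"], epochs$fs, c(0.1, 4))
    }, numeric(1))
  }
  bp <- cz_bp(ep)
  p <- wilcox.test(bp[ep$label == "planning"], bp[ep$label == "rest"])$p.value
  expect_lt(p, 0.01)
  # null configuration removes the separation (generator self-check)
  ep0 <- gen_gait_epochs(m, mrcp_amplitude = 0, mu_attenuation = 0,
                         seed = 12)
  bp0 <- cz_bp(ep0)
  p0 <- wilcox.test(bp0[ep0$label == "planning"],
                    bp0[ep0$label == "rest"])$p.value
  expect_gt(p0, 0.05)
})

test_that("specification invariants are enforced", {
  mo <- occ_montage()
  expect_error(synthetic_spec(mo, fs = 100, duration = 1,
                              local = list(list(channel = "Oz", freq = 49,
                                                amplitude = 1,
                                                harmonics = c(1, 0.5)))),
               "Nyquist")
  expect_error(synthetic_spec(mo, fs = 250, duration = 1,
                              common = list(list(type = "sine", freq = 10,
                                                 amplitude = -2))),
               "nonnegative")
})
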