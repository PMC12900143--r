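test_that("generation is a pure function of spec and seed", {
  sp <- tiny_spec()
  a <- generate_recording(sp, "experimental", 99)
  b <- generate_recording(sp, "experimental", 99)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$recording$quality, b$recording$quality)
  expect_identical(a$truth$amplitudes, b$truth$amplitudes)
  expect_false(identical(
    a$recording$data,
    generate_recording(sp, "experimental", 100)$recording$data))

  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$recording[[1]]$data, c2$recording[[1]]$data)
  expect_identical(c1$group, c2$group)
})

test_that("cohort sizes and group labels follow the spec", {
  co <- generate_cohort(tiny_spec(n_experimental = 9, n_control = 6))
  expect_equal(nrow(co), 15)
  expect_equal(sum(co$group == "experimental"), 9)
  co2 <- generate_cohort(tiny_spec(n_experimental = 1, n_control = 1))
  expect_equal(nrow(co2), 2)
  expect_error(generate_cohort(tiny_spec(n_experimental = 1, n_control = 0)),
               class = "neuroplay_parameter_error")
  expect_error(generate_recording(tiny_spec(), "patients", 1),
               class = "neuroplay_parameter_error")
})

test_that("zero amplitudes and zero noise give an all-zero matrix", {
  sp <- cohort_spec(n_experimental = 1, n_control = 1,
                    event_durations = c(eyes_open = 5, eyes_closed = 5,
                                        lecture = 5, play = 5),
                    base_amplitude = c(theta = 0, alpha = 0, betaL = 0,
                                       betaH = 0, gamma = 0),
                    noise_scale = 0, artifact_rate = 0)
  r <- generate_recording(sp, "control", 3)$recording
  expect_true(all(r$data == 0))
  expect_equal(dim(r$data)[1], 14)
})

test_that("single-band configurations concentrate spectral power in-band", {
  bands <- default_bands()
  for (b in bands$band) {
    r <- generate_recording(pure_band_spec(b), "control", 21)$recording
    # independent periodogram oracle (Hann-tapered to curb edge leakage)
    seg <- r$data["O1", 1:1024] ; seg <- seg - mean(seg)
    taper <- 0.5 - 0.5 * cos(2 * pi * seq_along(seg) / length(seg))
    p <- Mod(fft(seg * taper))^2
    f <- (seq_along(seg) - 1) * r$sampling_rate / length(seg)
    inrange <- f >= 4 & f < 45
    lo <- bands$low[bands$band == b]; hi <- bands$high[bands$band == b]
    inband <- f >= lo & f < hi
    expect_gte(sum(p[inband]) / sum(p[inrange]), 0.95)
  }
})

test_that("eyes-closed boosts occipital alpha for every participant", {
  co <- generate_cohort(tiny_spec(alpha_closed_factor = 2))
  for (i in seq_len(nrow(co))) {
    bp <- epoch_band_powers(co$recording[[i]], events = 1:2,
                            amplitude_limit = Inf)
    occ <- bp[bp$electrode %in% c("O1", "O2") & bp$band == "alpha", ]
    m <- tapply(occ$power, occ$event, mean)
    expect_gt(m[["2"]], m[["1"]])
  }
})

test_that("noise-free generation recovers the configured power ordering", {
  sp <- cohort_spec(n_experimental = 1, n_control = 1,
                    event_durations = c(eyes_open = 8, eyes_closed = 8,
                                        lecture = 16, play = 16),
                    noise_scale = 0, artifact_rate = 0)
  r <- generate_recording(sp, "experimental", 17)
  bp <- epoch_band_powers(r$recording, events = 3, amplitude_limit = Inf)
  mean_bp <- aggregate(power ~ electrode + band, bp, mean)
  truth <- r$truth$amplitudes[r$truth$amplitudes$event == 3, ]
  # within each band, the electrodes the truth boosts must rank highest
  for (b in unique(truth$band)) {
    tb <- truth[truth$band == b, ]
    mb <- mean_bp[mean_bp$band == b, ]
    top_true <- tb$electrode[tb$amplitude == max(tb$amplitude)]
    top_obs <- mb$electrode[order(-mb$power)][seq_along(top_true)]
    expect_setequal(top_obs, top_true)
  }
})

test_that("quality dropouts are local and flagged in CQ/EQ", {
  sp <- tiny_spec()
  r0 <- generate_recording(sp, "control", 31)$recording
  r1 <- inject_quality_dropout(r0, "F3", c(5, 15))
  ch <- which(rownames(r0$data) == "F3")
  expect_identical(r1$data[-ch, ], r0$data[-ch, ])
  expect_identical(r1$quality$cq[-ch, ], r0$quality$cq[-ch, ])
  expect_true(all(r1$quality$cq[ch, 6:15] < 70))
  expect_true(all(abs(r1$data[ch, (5 * 128 + 1):(15 * 128)]) > 100))
  # untouched outside the interval
  expect_identical(r1$data[ch, 1:(5 * 128)], r0$data[ch, 1:(5 * 128)])

  expect_identical(inject_quality_dropout(r0, "F3", c(5, 5)), r0)
  expect_error(inject_quality_dropout(r0, "F3", c(5, 1e6)),
               class = "neuroplay_bounds_error")
  expect_error(inject_quality_dropout(r0, "Cz", c(0, 1)),
               class = "neuroplay_montage_error")
})

test_that("survey generation is seeded, valid and distribution-faithful", {
  point7 <- c(0, 0, 0, 0, 0, 0, 1)
  s <- generate_survey(list(experimental = point7, control = point7),
                       c(experimental = 3, control = 2), seed = 5)
  qcols <- setdiff(names(s), c("participant", "group"))
  expect_true(all(as.matrix(s[qcols]) == 7))
  expect_equal(nrow(s), 5)

  s2 <- generate_survey(list(experimental = point7, control = point7),
                        c(experimental = 3, control = 2), seed = 5)
  expect_identical(s, s2)

  # uniform profile: chi-square goodness of fit on 7000 draws
  unif <- rep(1 / 7, 7)
  big <- generate_survey(list(all = unif), c(all = 7000), seed = 8,
                         questions = "Q1")
  tab <- table(factor(big$Q1, levels = 1:7))
  expect_gt(chisq.test(tab)$p.value, 0.01)

  expect_error(generate_survey(list(a = c(0.5, 0.5, 0, 0, 0, 0, 0.1)),
                               c(a = 2), 1),
               class = "neuroplay_parameter_error")
})
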