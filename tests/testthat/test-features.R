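test_that("default bands tile 4-45 Hz without overlap", {
  b <- default_bands()
  expect_equal(b$low, c(4, 8, 12, 16, 25))
  expect_equal(b$high, c(8, 12, 16, 25, 45))
  expect_equal(b$high[-5], b$low[-1])  # contiguous under [low, high)
  expect_error(default_bands(alpha = c(12, 8)),
               class = "neuroplay_parameter_error")
})

test_that("band power localises sinusoids and closes over the partition", {
  fs <- 128
  t <- seq(0, 2, length.out = 2 * fs + 1)[1:(2 * fs)]
  mk_epoch <- function(f) {
    m <- matrix(rep(sin(2 * pi * f * t), 14), nrow = 14, byrow = TRUE)
    rownames(m) <- emotiv_montage()$label
    m
  }
  bp <- band_power(mk_epoch(10), fs)
  o1 <- bp[bp$electrode == "O1", ]
  expect_gte(o1$power[o1$band == "alpha"] / sum(o1$power), 0.95)

  # all-zero epoch
  z <- mk_epoch(10) * 0
  expect_true(all(band_power(z, fs)$power == 0))

  # closure: five bands partition total 4-45 Hz power
  set.seed(2)
  noise <- matrix(rnorm(14 * 256), nrow = 14,
                  dimnames = list(emotiv_montage()$label, NULL))
  bp <- band_power(noise, fs)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 255) / 256)
  freqs <- (0:255) * fs / 256
  half <- 1:129
  for (ch in 1:14) {
    x <- noise[ch, ] - mean(noise[ch, ])
    spec <- Mod(fft(x * w))^2 / (256 * sum(w^2))
    p <- spec[half]
    p[2:128] <- p[2:128] * 2
    total <- sum(p[freqs[half] >= 4 & freqs[half] < 45])
    expect_equal(sum(bp$power[bp$electrode == rownames(noise)[ch]]), total,
                 tolerance = 1e-9)
  }

  # DC offset and sign flip leave band powers unchanged
  e <- mk_epoch(20)
  expect_equal(band_power(e + 42, fs), band_power(e, fs), tolerance = 1e-9)
  expect_equal(band_power(-e, fs), band_power(e, fs), tolerance = 1e-9)

  expect_error(band_power(mk_epoch(10)[, 1:32], fs),
               class = "neuroplay_resolution_error")
})

test_that("epoch rejection flags exactly the artifact-bearing epochs", {
  sp <- tiny_spec()
  r <- generate_recording(sp, "control", 41)$recording
  eps <- reject_epochs(r, 3, epoch_length = 2, amplitude_limit = 1000)
  expect_true(all(eps$accepted))
  expect_equal(nrow(eps), 10)  # 20 s event, 2 s epochs

  eps0 <- reject_epochs(r, 3, epoch_length = 2, amplitude_limit = 0)
  expect_true(all(!eps0$accepted))

  # inject a 500 uV burst and check only its epochs flip at limit 100
  ev <- r$events[r$events$event == 3, ]
  burst_at <- ev$onset + 5 * r$sampling_rate  # inside epoch 3
  r2 <- r
  r2$data[4, burst_at:(burst_at + 10)] <- 500
  e1 <- reject_epochs(r, 3, 2, 100)
  e2 <- reject_epochs(r2, 3, 2, 100)
  flipped <- which(e1$accepted != e2$accepted)
  expect_equal(flipped, 3L)
  expect_error(reject_epochs(r, 9), class = "neuroplay_event_error")
})

test_that("quality gate keeps clean cohorts and drops engineered dropouts", {
  co <- generate_cohort(tiny_spec())
  qf <- quality_filter(co, threshold = 70)
  expect_equal(nrow(qf$kept), nrow(co))
  expect_true(all(qf$report$kept))

  # boundary: constant quality exactly at the threshold is kept
  r <- co$recording[[1]]
  r$quality$cq[] <- 70; r$quality$eq[] <- 70
  co_b <- co; co_b$recording[[1]] <- r
  expect_true(quality_filter(co_b, threshold = 70)$report$kept[1])

  # a full-recording dropout excludes exactly that participant
  dur <- ncol(co$recording[[2]]$data) / co$recording[[2]]$sampling_rate
  co$recording[[2]] <- inject_quality_dropout(co$recording[[2]], "T8",
                                              c(0, dur))
  qf2 <- quality_filter(co, threshold = 70)
  expect_equal(qf2$excluded$participant, co$participant[2])
  expect_equal(nrow(qf2$kept), nrow(co) - 1)

  bad <- co; bad$recording[[1]]$quality <- NULL
  expect_error(quality_filter(bad), class = "neuroplay_quality_error")
  expect_error(quality_filter(co, threshold = 101),
               class = "neuroplay_parameter_error")
})

test_that("performance metrics are baseline-anchored, bounded and monotone", {
  sp <- tiny_spec()
  ebp <- epoch_band_powers(generate_recording(sp, "control", 51)$recording)
  pm <- performance_metrics(ebp, events = 3:4, cadence = 10)
  expect_true(all(pm$value >= 0 & pm$value <= 1, na.rm = TRUE))
  expect_setequal(unique(pm$metric),
                  c("attention", "engagement", "excitement", "stress",
                    "relaxation", "interest"))

  # scoring the baseline itself centres every metric near 0.5 ...
  pm_base <- performance_metrics(ebp, events = 1:2, cadence = 10)
  expect_true(all(abs(pm_base$value - 0.5) < 0.45, na.rm = TRUE))

  # ... and a window identical to the baseline mean maps exactly to 0.5:
  # build an epoch table whose every epoch carries the same band powers
  labels <- emotiv_montage()$label
  one <- tidyr::expand_grid(electrode = labels,
                            band = default_bands()$band) |>
    dplyr::mutate(power = 1 + seq_along(electrode) / 100)
  flat <- purrr::map_dfr(1:4, function(ev)
    purrr::map_dfr(1:5, function(ep)
      dplyr::mutate(one, event = ev, epoch = ep, accepted = TRUE,
                    .before = 1)))
  pm_flat <- performance_metrics(flat, events = 3:4, epoch_length = 2,
                                 cadence = 10)
  expect_true(all(abs(pm_flat$value - 0.5) < 1e-12))

  # symmetric F3/F4 alpha gives interest exactly 0.5: duplicate left
  # frontal signals onto the right so the asymmetry is identically zero
  r <- generate_recording(sp, "control", 52)$recording
  sym <- r
  lab <- rownames(sym$data)
  for (pr in list(c("F4", "F3"), c("AF4", "AF3"), c("F8", "F7"),
                  c("FC6", "FC5"), c("T8", "T7"), c("P8", "P7"),
                  c("O2", "O1")))
    sym$data[lab == pr[1], ] <- sym$data[lab == pr[2], ]
  pms <- performance_metrics(epoch_band_powers(sym), events = 3:4)
  expect_true(all(abs(pms$value[pms$metric == "interest"] - 0.5) < 1e-9,
                  na.rm = TRUE))
  expect_true(all(abs(pms$value[pms$metric == "stress"] - 0.5) < 1e-9,
                  na.rm = TRUE))

  # monotone response: stronger frontal beta never lowers mean attention
  means <- vapply(c(1, 1.5, 2), function(f) {
    spf <- tiny_spec(group_effects = default_group_effects(factor = f),
                     seed = 77L)
    rec <- generate_recording(spf, "experimental", 60)$recording
    p <- performance_metrics(epoch_band_powers(rec), events = 3:4)
    mean(p$value[p$metric == "attention"], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))

  expect_error(performance_metrics(ebp[ebp$event > 2, ]),
               class = "neuroplay_baseline_error")
})

test_that("gap interpolation fills interior and edge gaps only", {
  expect_equal(interpolate_missing(c(0.4, NA, 0.6)), c(0.4, 0.5, 0.6))
  v <- c(0.2, 0.7, 0.4)
  expect_equal(interpolate_missing(v), v)
  expect_equal(interpolate_missing(c(NA, 0.3, 0.3, NA)), rep(0.3, 4))
  expect_error(interpolate_missing(c(NA_real_, NA_real_)),
               class = "neuroplay_interpolation_error")

  tb <- tibble::tibble(event = 3, metric = "attention", window = 1:3,
                       time_s = c(0, 10, 20), value = c(0.4, NA, 0.6))
  expect_equal(interpolate_missing(tb)$value, c(0.4, 0.5, 0.6))
})

test_that("group time courses aggregate means and dispersions", {
  pm1 <- tibble::tibble(participant = "a", group = "experimental",
                        event = 4, window = 1:3, time_s = c(0, 10, 20),
                        metric = "attention", value = c(0.4, 0.5, 0.6))
  tc <- aggregate_timecourse(pm1, "attention", 4)
  expect_equal(tc$mean, pm1$value)
  expect_true(all(tc$sd == 0))

  pm2 <- dplyr::bind_rows(pm1, dplyr::mutate(pm1, participant = "b"))
  tc2 <- aggregate_timecourse(pm2, "attention", 4)
  expect_true(all(tc2$sd == 0))
  expect_true(all(tc2$n == 2))
  expect_error(aggregate_timecourse(pm1, "attention", 2),
               class = "neuroplay_empty_group_error")
})
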