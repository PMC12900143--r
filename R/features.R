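#' The five analysis frequency bands
#'
#' Theta 4-8, alpha 8-12, low-beta 12-16, high-beta 16-25 and gamma 25-45 Hz.
#' Band membership uses the half-open convention `[low, high)`, so the five
#' bands exactly tile the 4-45 Hz analysis range without double counting.
#'
#' @param theta,alpha,betaL,betaH,gamma Numeric `c(low, high)` edges in Hz.
#' @return A tibble with columns `band`, `low`, `high`.
#' @export
default_bands <- function(theta = c(4, 8), alpha = c(8, 12),
                          betaL = c(12, 16), betaH = c(16, 25),
                          gamma = c(25, 45)) {
  b <- tibble(band = c("theta", "alpha", "betaL", "betaH", "gamma"),
              low = c(theta[1], alpha[1], betaL[1], betaH[1], gamma[1]),
              high = c(theta[2], alpha[2], betaL[2], betaH[2], gamma[2]))
  if (any(b$high <= b$low))
    abort("Band edges must satisfy low < high.", class = "neuroplay_parameter_error")
  b
}

#' Screen recordings on contact and EEG quality
#'
#' A recording is kept only when, over every analysed event window, the
#' fraction of per-second quality samples with both CQ and EQ at or above the
#' threshold reaches the coverage level (default 1, i.e. consistently good
#' contact; the threshold itself is inclusive).
#'
#' @param cohort A cohort tibble from [generate_cohort()] (columns
#'   `participant`, `group`, `recording`), or a list of `eeg_recording`s.
#' @param threshold Quality threshold in percent, in (0, 100].
#' @param coverage Minimum fraction of qualifying samples per event.
#' @param events Integer event ids to screen (default all four).
#' @return A list with `kept` and `excluded` cohort tibbles and a `report`
#'   tibble (`participant`, `kept`, `reason`, worst per-event coverage).
#' @export
quality_filter <- function(cohort, threshold = 70, coverage = 1,
                           events = 1:4) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 100)
    abort("`threshold` must lie in (0, 100].", class = "neuroplay_parameter_error")
  if (!is.data.frame(cohort))
    cohort <- tibble(participant = sprintf("P%02d", seq_along(cohort)),
                     group = NA_character_, recording = cohort)
  check_one <- function(rec) {
    if (is.null(rec$quality) || is.null(rec$quality$cq) || is.null(rec$quality$eq))
      abort("Recording lacks CQ/EQ quality series; cannot apply quality filter.",
            class = "neuroplay_quality_error")
    fs <- rec$sampling_rate
    cov <- vapply(events, function(ev) {
      e <- rec$events[rec$events$event == ev, ]
      if (nrow(e) == 0) return(NA_real_)
      s0 <- floor((e$onset - 1) / fs) + 1
      s1 <- min(ncol(rec$quality$cq), ceiling((e$onset - 1 + e$n_samples) / fs))
      ok <- rec$quality$cq[, s0:s1, drop = FALSE] >= threshold &
        rec$quality$eq[, s0:s1, drop = FALSE] >= threshold
      mean(colSums(!ok) == 0)   # fraction of seconds where all channels qualify
    }, numeric(1))
    min(cov, na.rm = TRUE)
  }
  worst <- vapply(cohort$recording, check_one, numeric(1))
  keep <- worst >= coverage
  report <- tibble(participant = cohort$participant, group = cohort$group,
                   worst_coverage = worst, kept = keep,
                   reason = ifelse(keep, "ok",
                                   sprintf("quality coverage %.2f below %.2f at threshold %g",
                                           worst, coverage, threshold)))
  list(kept = cohort[keep, ], excluded = cohort[!keep, ], report = report)
}

event_samples <- function(recording, event) {
  e <- recording$events[recording$events$event == event, ]
  if (nrow(e) != 1)
    abort(paste0("Event ", event, " not found in recording."),
          class = "neuroplay_event_error")
  seq(e$onset, e$onset + e$n_samples - 1)
}

#' Segment an event into epochs and reject artifact-laden ones
#'
#' The event window is cut into non-overlapping epochs; an epoch is rejected
#' when any channel's peak-to-peak amplitude exceeds the limit.
#'
#' @param recording An `eeg_recording`.
#' @param event Event id (1-4).
#' @param epoch_length Epoch length in seconds.
#' @param amplitude_limit Peak-to-peak rejection limit in microvolts.
#' @return A tibble `epoch`, `start` (sample), `accepted`, `max_ptp`.
#' @export
reject_epochs <- function(recording, event, epoch_length = 2,
                          amplitude_limit = 100) {
  fs <- recording$sampling_rate
  len <- round(epoch_length * fs)
  if (len < 2)
    abort("Epoch length must cover at least 2 samples.",
          class = "neuroplay_parameter_error")
  idx <- event_samples(recording, event)
  n_ep <- floor(length(idx) / len)
  starts <- idx[1] + (seq_len(n_ep) - 1) * len
  ptp <- vapply(starts, function(s) {
    seg <- recording$data[, s:(s + len - 1), drop = FALSE]
    max(apply(seg, 1, function(x) max(x) - min(x)))
  }, numeric(1))
  tibble(epoch = seq_len(n_ep), start = as.integer(starts),
         accepted = ptp <= amplitude_limit, max_ptp = ptp)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

#' Absolute band power of one epoch via windowed periodogram
#'
#' Removes each channel's DC offset, applies a Hann window, and integrates
#' the one-sided periodogram over each band's half-open frequency range
#' `[low, high)`. The periodogram is normalised so that summing all bins
#' recovers the windowed signal's mean square (microvolts squared); the five
#' default bands therefore partition the total 4-45 Hz power exactly.
#'
#' @param epoch A channels x samples matrix (rownames = electrode labels).
#' @param fs Sampling rate in Hz.
#' @param bands A band table from [default_bands()].
#' @return A tibble `electrode`, `band`, `power` (microvolts squared).
#' @export
band_power <- function(epoch, fs, bands = default_bands()) {
  n <- ncol(epoch)
  min_width <- min(bands$high - bands$low)
  if (n / fs < 2 / min_width)
    abort("Epoch too short to resolve the narrowest band.",
          class = "neuroplay_resolution_error")
  w <- hann_window(n)
  wnorm <- sum(w^2)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)
  out <- purrr::map(seq_len(nrow(epoch)), function(ch) {
    x <- epoch[ch, ] - mean(epoch[ch, ])
    spec <- Mod(fft(x * w))^2 / (n * wnorm)
    p <- spec[half]
    # fold negative frequencies into the one-sided spectrum
    dup <- half[-1]
    dup <- dup[freqs[dup] != fs / 2 & freqs[dup] != 0]
    p[match(dup, half)] <- p[match(dup, half)] * 2
    vapply(seq_len(nrow(bands)), function(b) {
      sum(p[freqs[half] >= bands$low[b] & freqs[half] < bands$high[b]])
    }, numeric(1))
  })
  tibble(electrode = rep(rownames(epoch), each = nrow(bands)),
         band = rep(bands$band, times = nrow(epoch)),
         power = unlist(out))
}

#' Per-epoch band powers for one recording
#'
#' Runs artifact rejection then [band_power()] on every accepted epoch of the
#' requested events. Rejected epochs appear with `accepted = FALSE` and `NA`
#' power so downstream epoch counts stay aligned to the event clock.
#'
#' @param recording An `eeg_recording`.
#' @param events Event ids to analyse.
#' @param epoch_length,amplitude_limit Passed to [reject_epochs()].
#' @param bands A band table.
#' @return A tibble `event`, `epoch`, `accepted`, `electrode`, `band`,
#'   `power`.
#' @export
epoch_band_powers <- function(recording, events = 1:4, epoch_length = 2,
                              amplitude_limit = 100, bands = default_bands()) {
  fs <- recording$sampling_rate
  len <- round(epoch_length * fs)
  purrr::map_dfr(events, function(ev) {
    eps <- reject_epochs(recording, ev, epoch_length, amplitude_limit)
    purrr::map_dfr(seq_len(nrow(eps)), function(i) {
      if (eps$accepted[i]) {
        bp <- band_power(recording$data[, eps$start[i]:(eps$start[i] + len - 1),
                                        drop = FALSE], fs, bands)
      } else {
        bp <- tibble(electrode = rep(rownames(recording$data),
                                     each = nrow(bands)),
                     band = rep(bands$band, times = nrow(recording$data)),
                     power = NA_real_)
      }
      mutate(bp, event = ev, epoch = eps$epoch[i], accepted = eps$accepted[i],
             .before = 1)
    })
  })
}

#' Cohort band-power table
#'
#' Mean absolute band power per participant, event, electrode and band over
#' the accepted epochs (the quantity scalp maps and group contrasts are built
#' from).
#'
#' @param cohort A cohort tibble (`participant`, `group`, `recording`).
#' @param events,epoch_length,amplitude_limit,bands See [epoch_band_powers()].
#' @return A tibble `participant`, `group`, `event`, `electrode`, `band`,
#'   `power`, `n_epochs`.
#' @export
band_power_table <- function(cohort, events = 1:4, epoch_length = 2,
                             amplitude_limit = 100, bands = default_bands()) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    epoch_band_powers(cohort$recording[[i]], events, epoch_length,
                      amplitude_limit, bands) |>
      filter(.data$accepted) |>
      group_by(.data$event, .data$electrode, .data$band) |>
      summarise(power = mean(.data$power), n_epochs = n(), .groups = "drop") |>
      mutate(participant = cohort$participant[i], group = cohort$group[i],
             .before = 1)
  })
}

pm_frontal <- c("AF3", "AF4", "F3", "F4")
pm_occipital <- c("O1", "O2")

pm_raw_indices <- function(bp) {
  # bp: electrode x band power tibble for one epoch (NA power allowed)
  wide <- tidyr::pivot_wider(bp, id_cols = "electrode", names_from = "band",
                             values_from = "power")
  tot <- function(rows) {
    r <- wide[wide$electrode %in% rows, ]
    colSums(r[, c("theta", "alpha", "betaL", "betaH", "gamma")])
  }
  fr <- tot(pm_frontal); al <- tot(wide$electrode); oc <- tot(pm_occipital)
  rfr <- tot(c("AF4", "F4")); lfr <- tot(c("AF3", "F3"))
  f4 <- tot("F4"); f3 <- tot("F3")
  c(attention = (fr[["betaL"]] + fr[["betaH"]]) / (fr[["theta"]] + fr[["alpha"]]),
    engagement = (al[["betaL"]] + al[["betaH"]]) / (al[["alpha"]] + al[["theta"]]),
    excitement = (fr[["betaH"]] + fr[["gamma"]]) / sum(fr),
    stress = (rfr[["alpha"]] - lfr[["alpha"]]) / (rfr[["alpha"]] + lfr[["alpha"]]),
    relaxation = oc[["alpha"]] / sum(oc),
    interest = (f4[["alpha"]] - f3[["alpha"]]) / (f4[["alpha"]] + f3[["alpha"]]))
}

pm_metric_names <- c("attention", "engagement", "excitement", "stress",
                     "relaxation", "interest")

#' Transparent performance-metric proxy series
#'
#' Computes six documented band-ratio indices per analysis window and maps
#' each onto \[0, 1\] by standardising against the participant's own baseline
#' (events 1-2) and applying the logistic function, so a window identical to
#' the baseline mean scores exactly 0.5. The indices are declared proxies for
#' the vendor's closed-form metrics, not reconstructions of them:
#' * attention — frontal (AF3, AF4, F3, F4) beta over theta + alpha;
#' * engagement — all-channel beta over alpha + theta;
#' * excitement — frontal (high-beta + gamma) share of total frontal power;
#' * stress — right-minus-left frontal alpha asymmetry;
#' * relaxation — occipital alpha share of total occipital power;
#' * interest — F4 vs F3 alpha asymmetry.
#'
#' Within each metric window (default 10 s) the index is computed from the
#' mean band powers of the accepted analysis epochs it contains; windows with
#' no accepted epoch are missing (`NA`).
#'
#' @param ebp Per-epoch band powers from [epoch_band_powers()] covering the
#'   baseline events (1-2) and the events of interest.
#' @param events Events to score (default 3-4).
#' @param epoch_length Analysis epoch length in seconds used to build `ebp`.
#' @param cadence Metric window length in seconds (one value per window).
#' @return A tibble `event`, `window`, `time_s`, `metric`, `value`.
#' @export
performance_metrics <- function(ebp, events = 3:4, epoch_length = 2,
                                cadence = 10) {
  base <- ebp |> filter(.data$event %in% 1:2, .data$accepted)
  if (nrow(base) == 0)
    abort("No accepted baseline epochs (events 1-2): baseline required.",
          class = "neuroplay_baseline_error")
  base_idx <- base |>
    group_by(.data$event, .data$epoch) |>
    dplyr::group_map(~ pm_raw_indices(.x))
  base_mat <- do.call(rbind, base_idx)
  mu <- colMeans(base_mat, na.rm = TRUE)
  sdv <- apply(base_mat, 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1   # degenerate baseline: unit scale

  per_window <- ceiling(cadence / epoch_length)
  purrr::map_dfr(events, function(ev) {
    d <- ebp |> filter(.data$event == ev)
    if (nrow(d) == 0) return(tibble())
    n_ep <- max(d$epoch)
    n_win <- floor(n_ep / per_window)
    purrr::map_dfr(seq_len(n_win), function(w) {
      eps <- ((w - 1) * per_window + 1):(w * per_window)
      dd <- d |> filter(.data$epoch %in% eps, .data$accepted)
      if (nrow(dd) == 0) {
        vals <- setNames(rep(NA_real_, length(pm_metric_names)),
                         pm_metric_names)
      } else {
        mbp <- dd |> group_by(.data$electrode, .data$band) |>
          summarise(power = mean(.data$power), .groups = "drop")
        raw <- pm_raw_indices(mbp)
        vals <- plogis((raw - mu) / sdv)
      }
      tibble(event = ev, window = w, time_s = (w - 1) * cadence,
             metric = pm_metric_names,
             value = as.numeric(vals[pm_metric_names]))
    })
  })
}

#' Fill missing values in a performance-metric series
#'
#' Interior gaps are linearly interpolated between the flanking observed
#' values; leading and trailing gaps take the nearest observed value.
#' Observed values are never altered.
#'
#' @param x Numeric vector with `NA` gaps, or a metric series tibble from
#'   [performance_metrics()] (interpolated per event and metric).
#' @return Same shape as the input with gaps filled.
#' @export
interpolate_missing <- function(x) {
  fill <- function(v) {
    if (all(is.na(v)))
      abort("All values missing: cannot interpolate.",
            class = "neuroplay_interpolation_error")
    if (!anyNA(v)) return(v)
    as.numeric(zoo::na.approx(v, na.rm = FALSE, rule = 2))
  }
  if (is.numeric(x)) return(fill(x))
  x |> group_by(.data$event, .data$metric) |>
    mutate(value = fill(.data$value)) |> ungroup()
}

#' Group mean +/- SD time course of a performance metric
#'
#' Aligns every participant's metric series to event onset and summarises per
#' time window and group.
#'
#' @param pm_cohort Tibble of stacked [performance_metrics()] outputs with
#'   `participant` and `group` columns.
#' @param metric Metric name.
#' @param event Event id.
#' @return A tibble `group`, `time_s`, `mean`, `sd`, `n`.
#' @export
aggregate_timecourse <- function(pm_cohort, metric, event) {
  d <- pm_cohort |> filter(.data$metric == !!metric, .data$event == !!event)
  if (nrow(d) == 0)
    abort("No data for that metric/event.", class = "neuroplay_empty_group_error")
  d |> group_by(.data$group, .data$time_s) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = if (sum(!is.na(.data$value)) > 1)
                sd(.data$value, na.rm = TRUE) else 0,
              n = sum(!is.na(.data$value)), .groups = "drop")
}
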