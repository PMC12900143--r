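#' Specification of a synthetic two-group EEG cohort
#'
#' Describes the study design a generated cohort emulates: group sizes, the
#' 14-channel montage at a given sampling rate, four recording windows
#' ("time events": eyes-open baseline, eyes-closed baseline, lecture, game
#' play), per-band oscillation amplitudes, 1/f background noise, transient
#' movement artifacts and contact-quality dropouts. Defaults follow the study
#' design this package targets: 9 experimental and 6 control participants,
#' baselines of 60 s, a 180 s lecture and 300 s of play, and an experimental
#' profile with beta amplitudes raised by 50% over the right-frontal
#' electrodes AF4, F4, F8 and FC6 during the lecture and play windows.
#'
#' @param n_experimental,n_control Group sizes.
#' @param sampling_rate Sampling rate in Hz.
#' @param event_durations Named numeric vector of window durations in seconds
#'   (`eyes_open`, `eyes_closed`, `lecture`, `play`).
#' @param base_amplitude Named per-band oscillation RMS amplitude in microvolts
#'   applied to every channel.
#' @param occipital_alpha_gain Multiplier on alpha amplitude at O1/O2 in all
#'   windows (posterior alpha dominance).
#' @param alpha_closed_factor Additional multiplier on occipital alpha during
#'   the eyes-closed window (> 1 reproduces alpha blocking release).
#' @param group_effects Tibble with columns `group`, `event`, `electrode`,
#'   `band`, `factor`: multiplicative amplitude effects defining the ground
#'   truth group differences. `NULL` uses the default right-frontal beta
#'   profile; use a zero-row tibble for no group effect.
#' @param noise_exponent Spectral slope of the 1/f background (power ~
#'   1/f^exponent).
#' @param noise_scale RMS amplitude (microvolts) of the 1/f background; 0
#'   disables it.
#' @param artifact_rate Expected movement artifacts per minute.
#' @param artifact_amplitude Peak amplitude (microvolts) of artifact bursts.
#' @param dropout_rate Fraction of recording time with degraded contact
#'   quality injected per affected channel.
#' @param seed Master seed; the cohort is a pure function of the spec.
#'
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_experimental = 9, n_control = 6,
                        sampling_rate = 128,
                        event_durations = c(eyes_open = 60, eyes_closed = 60,
                                            lecture = 180, play = 300),
                        base_amplitude = c(theta = 3, alpha = 3, betaL = 1.5,
                                           betaH = 1.2, gamma = 0.8),
                        occipital_alpha_gain = 1.5,
                        alpha_closed_factor = 2,
                        group_effects = NULL,
                        noise_exponent = 1, noise_scale = 2,
                        artifact_rate = 2, artifact_amplitude = 150,
                        dropout_rate = 0, seed = 1L) {
  if (n_experimental < 0 || n_control < 0)
    abort("Group sizes must be non-negative.", class = "neuroplay_parameter_error")
  if (any(event_durations <= 0))
    abort("Event durations must be positive.", class = "neuroplay_parameter_error")
  if (any(base_amplitude < 0))
    abort("Amplitudes must be non-negative.", class = "neuroplay_parameter_error")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort("`dropout_rate` must lie in [0, 1).", class = "neuroplay_parameter_error")
  bands <- c("theta", "alpha", "betaL", "betaH", "gamma")
  if (!all(bands %in% names(base_amplitude)))
    abort("`base_amplitude` must name all five bands.", class = "neuroplay_parameter_error")
  group_effects <- group_effects %||% default_group_effects()
  structure(
    list(n_experimental = n_experimental, n_control = n_control,
         sampling_rate = sampling_rate,
         event_durations = event_durations[c("eyes_open", "eyes_closed",
                                             "lecture", "play")],
         base_amplitude = base_amplitude[bands],
         occipital_alpha_gain = occipital_alpha_gain,
         alpha_closed_factor = alpha_closed_factor,
         group_effects = group_effects,
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         artifact_rate = artifact_rate,
         artifact_amplitude = artifact_amplitude,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Default experimental-group amplitude profile
#'
#' A 50% beta (low and high) amplitude increase over the right-frontal
#' electrodes AF4, F4, F8, FC6 during the lecture and play windows (events 3
#' and 4). These factors are generator ground truth that downstream feature
#' extraction should recover; they are not measurements.
#'
#' @param electrodes,bands,events,factor Profile components.
#' @return A tibble with columns `group`, `event`, `electrode`, `band`,
#'   `factor`.
#' @export
default_group_effects <- function(electrodes = c("AF4", "F4", "F8", "FC6"),
                                  bands = c("betaL", "betaH"),
                                  events = 3:4, factor = 1.5) {
  g <- expand.grid(event = events, electrode = electrodes, band = bands,
                   stringsAsFactors = FALSE)
  tibble(group = "experimental", event = g$event, electrode = g$electrode,
         band = g$band, factor = factor)
}

#' Realized amplitude table for one participant
#'
#' Expands a cohort spec into the per (event, electrode, band) oscillation
#' amplitudes for a participant of the given group, applying the occipital
#' alpha gain, the eyes-closed alpha factor and any group effects.
#'
#' @param spec A [cohort_spec()].
#' @param group `"experimental"` or `"control"`.
#' @return A tibble `event`, `electrode`, `band`, `amplitude` (microvolt RMS).
#' @export
amplitude_profile <- function(spec, group) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% c("experimental", "control"))
    abort(paste0("Unknown group label '", group, "'."),
          class = "neuroplay_parameter_error")
  labels <- emotiv_montage()$label
  bands <- names(spec$base_amplitude)
  g <- expand.grid(event = 1:4, electrode = labels, band = bands,
                   stringsAsFactors = FALSE)
  amp <- tibble(event = g$event, electrode = g$electrode, band = g$band,
                amplitude = as.numeric(spec$base_amplitude[g$band]))
  occ <- amp$electrode %in% c("O1", "O2") & amp$band == "alpha"
  amp$amplitude[occ] <- amp$amplitude[occ] * spec$occipital_alpha_gain
  amp$amplitude[occ & amp$event == 2] <-
    amp$amplitude[occ & amp$event == 2] * spec$alpha_closed_factor
  ge <- spec$group_effects
  ge <- ge[ge$group == group, ]
  if (nrow(ge) > 0) {
    for (i in seq_len(nrow(ge))) {
      hit <- amp$event == ge$event[i] & amp$electrode == ge$electrode[i] &
        amp$band == ge$band[i]
      amp$amplitude[hit] <- amp$amplitude[hit] * ge$factor[i]
    }
  }
  amp
}

band_limited_noise <- function(n, low, high, fs) {
  # ideal (brick-wall) band-pass of white noise via FFT masking
  x <- rnorm(n)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  keep <- f >= low & f < high
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

pink_noise <- function(n, exponent) {
  x <- rnorm(n)
  f <- seq(0, n - 1) / n
  f <- pmin(f, 1 - f)            # two-sided frequency axis
  shape <- c(0, (f[-1] * n)^(-exponent / 2))
  y <- Re(fft(fft(x) * shape, inverse = TRUE)) / n
  y / sd(y)
}

#' Generate one synthetic EEG recording with ground truth
#'
#' Each channel is a sum over the five bands of band-limited Gaussian noise
#' scaled to the participant's configured RMS amplitude for the current
#' event, plus 1/f background noise and transient movement-artifact bursts.
#' Contact (CQ) and EEG (EQ) quality are emulated as percent series at 1 Hz.
#' The output is fully determined by the spec, group and seed.
#'
#' @param spec A [cohort_spec()].
#' @param group `"experimental"` or `"control"`.
#' @param participant_seed Integer seed for this participant.
#' @return A list with `recording` (class `eeg_recording`: `data` 14 x N
#'   microvolt matrix, `sampling_rate`, `montage`, `quality` (`cq`, `eq`
#'   14 x seconds percent matrices), `events` tibble) and `truth` (realized
#'   amplitudes plus injected artifact and dropout intervals).
#' @export
generate_recording <- function(spec, group, participant_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  amp <- amplitude_profile(spec, group)
  fs <- spec$sampling_rate
  durs <- spec$event_durations
  n_ev <- round(durs * fs)
  onsets <- cumsum(c(0, head(n_ev, -1))) + 1
  total <- sum(n_ev)
  labels <- emotiv_montage()$label
  bands <- default_bands()

  withr::with_seed(participant_seed, {
    data <- matrix(0, nrow = 14, ncol = total, dimnames = list(labels, NULL))
    for (ch in seq_len(14)) {
      sig <- numeric(total)
      for (b in seq_len(nrow(bands))) {
        sel <- amp[amp$electrode == labels[ch] & amp$band == bands$band[b], ]
        a_ev <- sel$amplitude[order(sel$event)]
        if (all(a_ev == 0)) next
        bn <- band_limited_noise(total, bands$low[b], bands$high[b], fs)
        for (ev in 1:4) {
          idx <- onsets[ev]:(onsets[ev] + n_ev[ev] - 1)
          seg <- bn[idx]
          r <- sqrt(mean(seg^2))
          if (r > 0) sig[idx] <- sig[idx] + seg / r * a_ev[ev]
        }
      }
      if (spec$noise_scale > 0)
        sig <- sig + spec$noise_scale * pink_noise(total, spec$noise_exponent)
      data[ch, ] <- sig
    }

    # transient movement artifacts: short high-amplitude hann bursts
    n_art <- stats::rpois(1, spec$artifact_rate * total / fs / 60)
    artifacts <- tibble(channel = character(), start = integer(), end = integer())
    if (n_art > 0) {
      w <- round(0.3 * fs)
      for (k in seq_len(n_art)) {
        ch <- sample.int(14, 1)
        s0 <- sample.int(total - w, 1)
        burst <- spec$artifact_amplitude * sample(c(-1, 1), 1) *
          (0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1)))
        data[ch, s0:(s0 + w - 1)] <- data[ch, s0:(s0 + w - 1)] + burst
        artifacts <- bind_rows(artifacts,
                               tibble(channel = labels[ch], start = s0,
                                      end = s0 + w - 1L))
      }
    }

    secs <- ceiling(total / fs)
    cq <- matrix(pmin(100, pmax(0, 100 - abs(rnorm(14 * secs, 3, 2)))),
                 nrow = 14, dimnames = list(labels, NULL))
    eq <- matrix(pmin(100, pmax(0, 100 - abs(rnorm(14 * secs, 3, 2)))),
                 nrow = 14, dimnames = list(labels, NULL))

    events <- tibble(event = 1:4,
                     label = c("eyes_open", "eyes_closed", "lecture", "play"),
                     onset = as.integer(onsets),
                     n_samples = as.integer(n_ev))
    rec <- structure(list(data = data, sampling_rate = fs,
                          montage = emotiv_montage(),
                          quality = list(cq = cq, eq = eq),
                          events = events),
                     class = "eeg_recording")
    dropouts <- tibble(channel = character(), start_s = numeric(),
                       end_s = numeric())
    if (spec$dropout_rate > 0) {
      ch <- sample.int(14, 1)
      len <- spec$dropout_rate * total / fs
      s0 <- runif(1, 0, total / fs - len)
      rec <- inject_quality_dropout(rec, labels[ch], c(s0, s0 + len))
      dropouts <- tibble(channel = labels[ch], start_s = s0, end_s = s0 + len)
    }
    list(recording = rec,
         truth = list(amplitudes = amp, artifacts = artifacts,
                      dropouts = dropouts, group = group,
                      seed = participant_seed))
  })
}

#' Generate a full two-group cohort
#'
#' Derives an independent seed per participant from the master seed, then
#' generates each recording with [generate_recording()].
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `participant`, `group`, and list-columns
#'   `recording` and `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_experimental + spec$n_control
  if (n < 2)
    abort("A cohort needs at least two participants.",
          class = "neuroplay_parameter_error")
  groups <- c(rep("experimental", spec$n_experimental),
              rep("control", spec$n_control))
  seeds <- withr::with_seed(spec$seed, sample.int(.Machine$integer.max - 1, n))
  out <- purrr::map2(groups, seeds,
                     function(g, s) generate_recording(spec, g, s))
  tibble(participant = sprintf("P%02d", seq_len(n)), group = groups,
         recording = purrr::map(out, "recording"),
         truth = purrr::map(out, "truth"))
}

#' Inject a contact-quality dropout into a recording
#'
#' Emulates poor electrode contact: within the interval the channel's CQ and
#' EQ fall well below any sensible inclusion threshold and the signal is
#' replaced by a high-amplitude drift. All other samples and channels are
#' untouched.
#'
#' @param recording An `eeg_recording`.
#' @param channel Electrode label.
#' @param interval Numeric `c(start, end)` in seconds from recording start;
#'   an empty interval (start == end) returns the recording unchanged.
#' @return The modified `eeg_recording`.
#' @export
inject_quality_dropout <- function(recording, channel, interval) {
  stopifnot(inherits(recording, "eeg_recording"))
  labels <- rownames(recording$data)
  if (!channel %in% labels)
    abort(paste0("Unknown channel '", channel, "'."),
          class = "neuroplay_montage_error")
  fs <- recording$sampling_rate
  total_s <- ncol(recording$data) / fs
  if (length(interval) != 2 || interval[1] > interval[2] ||
      interval[1] < 0 || interval[2] > total_s)
    abort("Dropout interval out of recording range.",
          class = "neuroplay_bounds_error")
  if (interval[1] == interval[2]) return(recording)
  ch <- match(channel, labels)
  s0 <- max(1, floor(interval[1] * fs) + 1)
  s1 <- min(ncol(recording$data), ceiling(interval[2] * fs))
  drift <- 300 + 100 * seq(0, 1, length.out = s1 - s0 + 1)
  recording$data[ch, s0:s1] <- drift
  q0 <- max(1, floor(interval[1]) + 1)
  q1 <- min(ncol(recording$quality$cq), ceiling(interval[2]))
  recording$quality$cq[ch, q0:q1] <- 10
  recording$quality$eq[ch, q0:q1] <- 10
  recording
}

#' The post-experience survey instrument (7-point Likert items)
#'
#' Fixture table of the closed survey questions: identifier, wording,
#' instrument family (IPQ presence themes, TAM acceptance themes) and theme.
#'
#' @return A tibble with columns `question`, `text`, `instrument`, `theme`.
#' @export
survey_questions <- function() {
  tibble::tribble(
    ~question, ~instrument, ~theme, ~text,
    "Q1a", "-",   "Player performance", "How familiar are you with gaming?",
    "Q2.1", "IPQ", "Spatial presence",  "How immersed did you feel in the virtual environment?",
    "Q2.2", "IPQ", "Realism",           "How realistic do you find the environment?",
    "Q3.1", "IPQ", "Involvement",       "How involved did you feel while playing the virtual reality role play?",
    "Q3.3", "IPQ", "Involvement",       "How well could you concentrate on the assigned tasks of the role play?",
    "Q3.4", "IPQ", "Involvement",       "How easy was it to stay focused?",
    "Q4.1", "IPQ", "Immersion",         "How well did VR assist you in giving a more engaging experience?",
    "Q5.1", "IPQ", "Engagement",        "How emotionally engaged were you while playing the virtual role play?",
    "Q6.1", "TAM", "Ease of use",       "How easy did you find it to learn the controls and interact with the environment?",
    "Q6.2", "TAM", "Ease of use",       "How straightforward do you think VR is for using it for learning purposes?",
    "Q7.1", "TAM", "Usefulness",        "How well did VR assist you in understanding the educational purpose of this experiment?",
    "Q7.2", "TAM", "Usefulness",        "Would you see yourself using this technology for educational learning purposes?")
}

#' Generate a synthetic 7-point Likert survey table
#'
#' Draws seeded categorical responses per participant and question from
#' per-group response distributions.
#'
#' @param group_profiles Named list (one entry per group). Each entry is
#'   either a single probability vector of length 7 applied to every
#'   question, or a named list `question -> probability vector`.
#' @param n_per_group Named integer vector of participants per group.
#' @param seed Integer seed.
#' @param questions Character vector of question identifiers (defaults to the
#'   Likert items of [survey_questions()]).
#' @return A tibble with `participant`, `group` and one integer column (1-7)
#'   per question.
#' @export
generate_survey <- function(group_profiles, n_per_group, seed,
                            questions = survey_questions()$question) {
  get_p <- function(profile, q) {
    p <- if (is.list(profile)) profile[[q]] else profile
    if (is.null(p) || length(p) != 7)
      abort("Each profile must give 7 response probabilities.",
            class = "neuroplay_parameter_error")
    if (abs(sum(p) - 1) > 1e-8)
      abort("Response probabilities must sum to 1.",
            class = "neuroplay_parameter_error")
    p
  }
  withr::with_seed(seed, {
    rows <- purrr::map(names(group_profiles), function(g) {
      ng <- n_per_group[[g]]
      ans <- lapply(questions, function(q) {
        sample.int(7, ng, replace = TRUE, prob = get_p(group_profiles[[g]], q))
      })
      names(ans) <- questions
      tibble(participant = sprintf("%s%02d", toupper(substr(g, 1, 1)),
                                   seq_len(ng)),
             group = g, !!!ans)
    })
    bind_rows(rows)
  })
}
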