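# Small generator configurations shared across test files. Durations are
# shortened so a recording holds a handful of epochs; the scientific
# structure (montage, events, amplitude model) is the package default.

tiny_spec <- function(..., seed = 11L) {
  args <- utils::modifyList(
    list(n_experimental = 2, n_control = 2,
         event_durations = c(eyes_open = 10, eyes_closed = 10,
                             lecture = 20, play = 20),
         artifact_rate = 0, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

# noise-free single-band spec used by spectral-fidelity checks
pure_band_spec <- function(band, amplitude = 1) {
  amps <- c(theta = 0, alpha = 0, betaL = 0, betaH = 0, gamma = 0)
  amps[band] <- amplitude
  cohort_spec(n_experimental = 1, n_control = 1,
              event_durations = c(eyes_open = 8, eyes_closed = 8,
                                  lecture = 8, play = 8),
              base_amplitude = amps, occipital_alpha_gain = 1,
              alpha_closed_factor = 1, noise_scale = 0, artifact_rate = 0,
              group_effects = default_group_effects()[0, ])
}

# brute-force two-sided exact Mann-Whitney p by enumerating all group
# assignments of the pooled ranks (tie-free samples only)
mw_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}
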