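#' Configuration of a full analysis run
#'
#' Collects every knob of the generate -> filter -> features -> topography ->
#' statistics chain so a run is fully replayable from its archived config.
#'
#' @param seed Master seed driving cohort generation and permutation tests.
#' @param cohort A [cohort_spec()]; its own seed is overridden by `seed`.
#' @param quality_threshold CQ/EQ inclusion threshold in percent.
#' @param quality_coverage Minimum fraction of qualifying seconds per event.
#' @param epoch_length Analysis epoch length in seconds.
#' @param amplitude_limit Epoch rejection limit (microvolts peak-to-peak).
#' @param pm_cadence Performance-metric window in seconds.
#' @param analysis_events Events scored and mapped (default lecture + play).
#' @param bands Band table from [default_bands()].
#' @param n_perm Permutations for the permutation tests.
#' @param topo_resolution Scalp-map grid resolution.
#' @param out_dir Output directory.
#' @param game A [game_config()] for the bundled game run.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, cohort = cohort_spec(),
                       quality_threshold = 70, quality_coverage = 1,
                       epoch_length = 2, amplitude_limit = 100,
                       pm_cadence = 10, analysis_events = 3:4,
                       bands = default_bands(), n_perm = 1999,
                       topo_resolution = 67,
                       out_dir = file.path(tempdir(), "neuroplay-run"),
                       game = game_config()) {
  if (quality_threshold <= 0 || quality_threshold > 100)
    abort("`quality_threshold` must lie in (0, 100].",
          class = "neuroplay_config_error")
  cohort$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 quality_threshold = quality_threshold,
                 quality_coverage = quality_coverage,
                 epoch_length = epoch_length,
                 amplitude_limit = amplitude_limit,
                 pm_cadence = pm_cadence, analysis_events = analysis_events,
                 bands = bands, n_perm = n_perm,
                 topo_resolution = topo_resolution, out_dir = out_dir,
                 game = game),
            class = "run_config")
}

#' Desk-scale demonstration configuration
#'
#' A small cohort (3 experimental, 2 control) with shortened windows
#' (20 s baselines, 40 s lecture, 60 s play) that exercises every pipeline
#' stage in seconds rather than minutes.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1L,
                        out_dir = file.path(tempdir(), "neuroplay-demo")) {
  run_config(
    seed = seed,
    cohort = cohort_spec(n_experimental = 3, n_control = 2,
                         event_durations = c(eyes_open = 20, eyes_closed = 20,
                                             lecture = 40, play = 60),
                         seed = seed),
    n_perm = 499, topo_resolution = 31, out_dir = out_dir)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: the bundled supply-chain game scenario (both
#' communication phases), cohort generation, quality filtering, per-epoch
#' band powers, performance-metric scoring, study-style per-metric summaries
#' with Mann-Whitney and permutation tests, 0-1 normalised scalp-map grids
#' per group x event x band, and survey sentiment aggregation. All tables are
#' written as CSV under `config$out_dir`, together with the archived config
#' (`config.yaml`) and a JSON run report. Two runs with the same config
#' produce byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: per-stage row counts, exclusion log, artifact
#'   paths, package version and config hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  art <- character()
  save_csv <- function(x, name) {
    p <- file.path(out, name)
    readr::write_csv(x, p)
    art <<- c(art, p)
    p
  }

  # -- stage 1: supply-chain game (both phases)
  ledgers <- purrr::map_dfr(c("no_communication", "communication"),
                            function(ph) {
    cfg <- config$game
    cfg$phase <- ph
    run_scenario(cfg)$ledger
  })
  save_csv(ledgers, "game_ledger.csv")
  kpis <- kpi_report(ledgers[ledgers$phase == "no_communication", ],
                     config$game)
  save_csv(kpis, "game_kpis.csv")

  # -- stage 2: cohort generation
  cohort <- generate_cohort(config$cohort)

  # -- stage 3: quality gate
  qf <- quality_filter(cohort, threshold = config$quality_threshold,
                       coverage = config$quality_coverage)
  save_csv(qf$report, "quality_report.csv")
  kept <- qf$kept

  # -- stage 4-5: band powers and performance metrics
  ebps <- purrr::map(kept$recording, epoch_band_powers,
                     events = 1:4, epoch_length = config$epoch_length,
                     amplitude_limit = config$amplitude_limit,
                     bands = config$bands)
  bp <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    ebps[[i]] |>
      filter(.data$accepted, .data$event %in% config$analysis_events) |>
      group_by(.data$event, .data$electrode, .data$band) |>
      summarise(power = mean(.data$power), n_epochs = n(), .groups = "drop") |>
      mutate(participant = kept$participant[i], group = kept$group[i],
             .before = 1)
  })
  save_csv(bp, "band_power.csv")
  pm <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    performance_metrics(ebps[[i]], events = config$analysis_events,
                        epoch_length = config$epoch_length,
                        cadence = config$pm_cadence) |>
      mutate(participant = kept$participant[i], group = kept$group[i],
             .before = 1)
  })
  save_csv(pm, "pm_series.csv")

  # -- stage 6: study-style summaries and tests
  summaries <- purrr::map_dfr(config$analysis_events, function(ev) {
    purrr::map_dfr(pm_metric_names, function(m) {
      s <- summarize_pm(pm, m, ev)
      comp <- s$comparison
      perm <- tryCatch(
        permutation_test(pm$value[pm$group == "experimental" &
                                    pm$metric == m & pm$event == ev],
                         pm$value[pm$group == "control" &
                                    pm$metric == m & pm$event == ev],
                         n_perm = config$n_perm, seed = config$seed),
        error = function(e) NULL)
      tidyr::pivot_wider(
        s$summary, names_from = "group",
        values_from = c("n", "n_participants", "missing", "mean", "sd")) |>
        mutate(mw_W = comp$statistic, mw_p = comp$p_value,
               perm_Z = if (is.null(perm)) NA_real_ else perm$statistic,
               perm_p = if (is.null(perm)) NA_real_ else perm$p_value)
    })
  })
  save_csv(summaries, "pm_summary.csv")

  # -- stage 7: scalp maps
  norm <- normalize_bandpower(bp)
  save_csv(norm, "band_power_normalized.csv")
  for (g in unique(norm$group)) for (ev in config$analysis_events)
    for (b in config$bands$band) {
      v <- norm |> filter(.data$group == g, .data$event == ev, .data$band == b)
      if (nrow(v) != 14) next
      tm <- render_topomap(select(v, "electrode", value = "norm_power"),
                           resolution = config$topo_resolution)
      save_csv(tm$grid, sprintf("heatmap_%s_event%d_%s.csv", g, ev, b))
    }

  # -- stage 8: synthetic survey sentiment
  survey <- generate_survey(
    list(experimental = c(.02, .03, .05, .10, .25, .35, .20),
         control = c(.02, .03, .05, .20, .30, .30, .10)),
    n_per_group = c(experimental = config$cohort$n_experimental,
                    control = config$cohort$n_control),
    seed = config$seed)
  save_csv(survey, "survey_responses.csv")
  save_csv(likert_sentiment(survey, by = "group"), "survey_sentiment.csv")

  report <- list(
    package_version = as.character(utils::packageVersion("neuroplay")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_generated = nrow(cohort), n_kept = nrow(kept),
    n_excluded = nrow(qf$excluded),
    exclusions = qf$report[!qf$report$kept,
                           c("participant", "group", "reason")],
    stage_rows = list(game_ledger = nrow(ledgers), band_power = nrow(bp),
                      pm_series = nrow(pm), summaries = nrow(summaries)),
    artifacts = art)
  yaml::write_yaml(serialize_config(config), file.path(out, "config.yaml"))
  jsonlite::write_json(report[c("package_version", "config_hash", "seed",
                                "n_generated", "n_kept", "n_excluded")],
                       file.path(out, "run_report.json"), auto_unbox = TRUE)
  structure(report, class = "run_report")
}

serialize_config <- function(config) {
  c2 <- unclass(config)
  c2$cohort <- unclass(c2$cohort)
  c2$cohort$group_effects <- as.data.frame(c2$cohort$group_effects)
  c2$game <- unclass(c2$game)
  c2$game$npc <- unclass(c2$game$npc)
  c2$bands <- as.data.frame(c2$bands)
  c2
}

#' @export
print.run_report <- function(x, ...) {
  cat("neuroplay run:", x$n_kept, "of", x$n_generated,
      "participants kept (", x$n_excluded, "excluded )\n")
  cat("  artifacts:", length(x$artifacts), "files\n")
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}

#' Plot a group attention time course with error bars
#'
#' @param tc Output of [aggregate_timecourse()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc) {
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from event onset (s)", y = "Metric (0-1)") +
    ggplot2::theme_minimal()
}

#' Diverging Likert sentiment plot
#'
#' @param sentiment Output of [likert_sentiment()] with a `question` column.
#' @return A ggplot object.
#' @export
plot_sentiment <- function(sentiment) {
  long <- tidyr::pivot_longer(sentiment,
                              c("pct_negative", "pct_neutral", "pct_positive"),
                              names_to = "sentiment", values_to = "pct")
  long$sentiment <- factor(sub("pct_", "", long$sentiment),
                           levels = c("negative", "neutral", "positive"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$question, y = .data$pct,
                                     fill = .data$sentiment)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(negative = "#B2182B",
                                          neutral = "#CCCCCC",
                                          positive = "#2166AC")) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "% of responses", x = NULL) +
    ggplot2::theme_minimal()
}
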