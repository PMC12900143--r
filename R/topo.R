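#' Normalise band powers to 0-1 per scalp-map panel
#'
#' Within each normalisation scope (by default one scalp-map panel: group x
#' event x band), the 14 electrode means are rescaled to `(v - min) /
#' (max - min)`, so the weakest electrode maps to 0 and the strongest to 1 —
#' the per-panel colour scale of the study-style heatmaps. A degenerate scope
#' (all electrodes equal) maps to 0.5 everywhere.
#'
#' @param table A band-power table from [band_power_table()], or any tibble
#'   with an `electrode` column, a `power` column and the scope columns.
#' @param scope Character vector of grouping columns.
#' @return The input with electrode means collapsed per scope and a
#'   `norm_power` column in \[0, 1\].
#' @export
normalize_bandpower <- function(table, scope = c("group", "event", "band")) {
  if (nrow(table) == 0)
    abort("Empty band-power table.", class = "neuroplay_empty_scope_error")
  table |>
    group_by(across(all_of(c(scope, "electrode")))) |>
    summarise(power = mean(.data$power, na.rm = TRUE), .groups = "drop") |>
    group_by(across(all_of(scope))) |>
    mutate(norm_power = {
      rng <- range(.data$power)
      if (diff(rng) == 0) rep(0.5, length(.data$power))
      else (.data$power - rng[1]) / diff(rng)
    }) |>
    ungroup()
}

#' Render an interpolated topographic scalp map
#'
#' Inverse-distance-weighted interpolation (power 2) of the 14 electrode
#' values over a grid masked to a disk of radius 1.1 times the outermost
#' electrode. IDW is exact at electrode sites and bounded by the input range,
#' which makes the rendered panel fully reproducible and keeps electrode-site
#' values stable across grid resolutions.
#'
#' @param values A tibble with columns `electrode` (or `label`) and `value`
#'   (typically `norm_power` from [normalize_bandpower()]), exactly one row
#'   per montage electrode.
#' @param montage A montage tibble (default [emotiv_montage()]).
#' @param resolution Grid points per axis.
#' @param idw_power IDW exponent.
#' @return A `topo_map` object: list with `grid` (tibble `x`, `y`, `value`
#'   with `NA` outside the head disk), `electrodes`, `resolution`.
#' @export
render_topomap <- function(values, montage = emotiv_montage(),
                           resolution = 67, idw_power = 2) {
  if ("label" %in% names(values) && !"electrode" %in% names(values))
    values <- rename(values, electrode = "label")
  if ("norm_power" %in% names(values) && !"value" %in% names(values))
    values <- rename(values, value = "norm_power")
  if (nrow(values) != nrow(montage) ||
      !setequal(values$electrode, montage$label) ||
      anyDuplicated(values$electrode) > 0)
    abort("`values` must cover each montage electrode exactly once.",
          class = "neuroplay_montage_error")
  m <- left_join(values, montage, by = c(electrode = "label"))
  rmax <- 1.1 * max(sqrt(m$x^2 + m$y^2))
  ax <- seq(-rmax, rmax, length.out = resolution)
  grid <- expand.grid(x = ax, y = ax)
  d2 <- outer(grid$x, m$x, "-")^2 + outer(grid$y, m$y, "-")^2
  w <- d2^(-idw_power / 2)
  exact <- d2 < 1e-12
  val <- as.numeric((w %*% m$value) / rowSums(w))
  hit <- which(rowSums(exact) > 0)
  if (length(hit) > 0)
    val[hit] <- m$value[apply(exact[hit, , drop = FALSE], 1, which.max)]
  val[sqrt(grid$x^2 + grid$y^2) > rmax] <- NA_real_
  structure(list(grid = tibble(x = grid$x, y = grid$y, value = val),
                 electrodes = select(m, "electrode", "x", "y", "value"),
                 resolution = resolution, radius = rmax),
            class = "topo_map")
}

#' Interpolate a topographic map value at arbitrary scalp positions
#'
#' Same IDW rule as [render_topomap()], evaluated at given points — used to
#' check resolution stability and to read values at electrode sites.
#'
#' @param map A `topo_map`.
#' @param x,y Coordinates on the unit head disk.
#' @return Numeric values.
#' @export
topo_value_at <- function(map, x, y) {
  m <- map$electrodes
  vapply(seq_along(x), function(i) {
    d2 <- (x[i] - m$x)^2 + (y[i] - m$y)^2
    if (any(d2 < 1e-12)) return(m$value[which.min(d2)])
    w <- d2^(-1)
    sum(w * m$value) / sum(w)
  }, numeric(1))
}

#' Plot a topographic scalp map
#'
#' @param object A `topo_map` from [render_topomap()].
#' @param ... Unused.
#' @return A ggplot object (blue-to-red 0-1 fill with electrode overlay).
#' @exportS3Method ggplot2::autoplot
autoplot.topo_map <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradientn(
      colours = c("#2166AC", "#67A9CF", "#F7F7F7", "#EF8A62", "#B2182B"),
      limits = c(0, 1), na.value = "transparent", name = "0-1") +
    ggplot2::geom_point(data = object$electrodes, size = 1) +
    ggplot2::geom_text(data = object$electrodes,
                       ggplot2::aes(label = .data$electrode),
                       vjust = -0.8, size = 2.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @export
print.topo_map <- function(x, ...) {
  cat("Topographic scalp map:", x$resolution, "x", x$resolution,
      "grid, head radius", round(x$radius, 3), "\n")
  invisible(x)
}
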