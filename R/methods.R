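#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an electrode design
#'
#' One row per electrode with its role and position in mm.
#'
#' @param x an `electrode_design`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.electrode_design <- function(x, ...) {
  tibble::as_tibble(x$layout)
}

#' One-row summary of an electrode design
#'
#' @param x an `electrode_design`.
#' @param ... unused.
#' @return a tibble with the objective, per-modality costs, predicted
#'   quality and hull area.
#' @export
glance.electrode_design <- function(x, ...) {
  c <- x$cost
  tibble::tibble(
    n_electrodes = sum(!x$layout$is_reference),
    objective = c$objective,
    O1 = c$O1, O2 = c$O2, O3 = c$O3, O4 = c$O4,
    modality_aggregate = c$modality_aggregate,
    quality = c$quality,
    area_mm2 = c$area_mm2,
    scheme = c$scheme
  )
}

#' Tidy a cost breakdown
#'
#' @param x a `cost_breakdown`.
#' @param ... unused.
#' @return a tibble with one row per cost component (per-muscle EMG terms
#'   included).
#' @export
tidy.cost_breakdown <- function(x, ...) {
  comp <- tibble::tibble(
    component = c("EMG", "EDA", "ECG", "area"),
    cost = c(x$O1, x$O2, x$O3, x$O4),
    weight = unname(x$weights[c("EMG", "EDA", "ECG", "area")]),
    penalty = c(unname(x$penalties[c("EMG", "EDA", "ECG")]), 0)
  )
  if (!is.null(x$per_muscle)) {
    comp <- dplyr::bind_rows(
      comp,
      tibble::tibble(
        component = paste0("EMG:", names(x$per_muscle)),
        cost = unname(x$per_muscle), weight = NA_real_, penalty = NA_real_
      )
    )
  }
  comp
}

#' Tidy a bounding-box sweep
#'
#' @param x a `layout_sweep`.
#' @param ... unused.
#' @return the per-window results tibble (without the design list-column).
#' @export
tidy.layout_sweep <- function(x, ...) {
  x$results[, setdiff(names(x$results), "design")]
}

#' One-row summary of a sweep
#'
#' @param x a `layout_sweep`.
#' @param ... unused.
#' @return a tibble with window counts and the selected designs' headline
#'   numbers (NA when a selection rule has no qualifying design).
#' @export
glance.layout_sweep <- function(x, ...) {
  safe <- function(f) tryCatch(f(x), sensorlayout_not_found = function(e) NULL)
  ao <- safe(select_area_optimized)
  qo <- safe(select_quality_optimized)
  tibble::tibble(
    n_windows = nrow(x$results),
    n_feasible = sum(x$results$feasible),
    increment = x$increment,
    area_optimized_height = if (is.null(ao)) NA_real_ else find_height(x, ao),
    area_optimized_area = if (is.null(ao)) NA_real_ else ao$cost$area_mm2,
    area_optimized_quality = if (is.null(ao)) NA_real_ else ao$cost$quality,
    quality_optimized_area = if (is.null(qo)) NA_real_ else qo$cost$area_mm2,
    quality_optimized_quality = if (is.null(qo)) NA_real_ else qo$cost$quality
  )
}

find_height <- function(sweep, design) {
  for (i in seq_len(nrow(sweep$results))) {
    d <- sweep$results$design[[i]]
    if (!is.null(d) && identical(d$cost$objective, design$cost$objective) &&
        identical(d$cost$area_mm2, design$cost$area_mm2)) {
      return(sweep$results$height[i])
    }
  }
  NA_real_
}

#' Plot an electrode design
#'
#' Draws the forearm outline, muscle lines with innervation zones, ECG
#' candidate keypoints, and the electrode disks coloured by modality, to
#' scale in mm.
#'
#' @param object an `electrode_design`.
#' @param model optional `forearm_model`; rebuilt from the design's
#'   measurements and the default template when omitted.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.electrode_design <- function(object, model = NULL, ...) {
  if (is.null(model)) model <- build_forearm_model(object$measurements)
  outline <- model$outline
  muscles <- model$muscles
  iz_df <- dplyr::bind_rows(lapply(seq_len(nrow(muscles)), function(i) {
    iz <- muscles$iz[[i]]
    polys <- if (is.matrix(iz) || is.data.frame(iz)) list(iz) else iz
    dplyr::bind_rows(lapply(seq_along(polys), function(j) {
      p <- as_point_matrix(polys[[j]])
      tibble::tibble(
        muscle = muscles$muscle[i], piece = paste(muscles$muscle[i], j),
        u = p[, 1], v = p[, 2]
      )
    }))
  }))
  meas <- object$layout[!object$layout$is_reference, ]
  disk <- function(u0, v0, r, id) {
    t <- seq(0, 2 * pi, length.out = 48)
    tibble::tibble(electrode = id, u = u0 + r * cos(t), v = v0 + r * sin(t))
  }
  disks <- dplyr::bind_rows(purrr::pmap(
    list(meas$u, meas$v, meas$radius, meas$electrode), disk
  ))
  disks <- dplyr::left_join(disks, meas[, c("electrode", "modality")], by = "electrode")

  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = outline, ggplot2::aes(u, v),
      fill = "antiquewhite", colour = "grey30"
    ) +
    ggplot2::geom_polygon(
      data = iz_df, ggplot2::aes(u, v, group = .data$piece),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_segment(
      data = muscles,
      ggplot2::aes(x = .data$k1_u, y = .data$k1_v, xend = .data$k2_u, yend = .data$k2_v),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_polygon(
      data = disks, ggplot2::aes(u, v, group = .data$electrode, fill = .data$modality),
      colour = "black", linewidth = 0.2, alpha = 0.8
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "u (mm, radial →)", y = "v (mm, wrist → elbow)",
      fill = NULL,
      title = sprintf(
        "objective %.3f, quality %.3f, hull %.0f mm²",
        object$cost$objective, object$cost$quality, object$cost$area_mm2
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sweep's quality/area trade-off
#'
#' Predicted quality and hull area of the best design found in each
#' bounding-box window, against window height.
#'
#' @param object a `layout_sweep`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.layout_sweep <- function(object, ...) {
  res <- tidy(object)
  res <- res[res$feasible, ]
  long <- tidyr_pivot(res)
  ggplot2::ggplot(long, ggplot2::aes(.data$height, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "window height (mm)", y = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape; avoids a tidyr dependency for one call
tidyr_pivot <- function(res) {
  dplyr::bind_rows(
    tibble::tibble(height = res$height, metric = "predicted quality", value = res$quality),
    tibble::tibble(height = res$height, metric = "hull area (mm²)", value = res$area_mm2)
  )
}

#' @importFrom rlang .data
NULL
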