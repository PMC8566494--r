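#' Integrated predictive cost model
#'
#' Per-modality cost (energy) functions, all normalized so 0 is the best
#' achievable sensing quality and 1 the worst: surface-EMG orientation and
#' inter-electrode distance curves, electrodermal sweat-gland coverage, ECG
#' keypoint SNR scores, a convex-hull area ratio, and exponential penalties
#' for lower-bound (cost-ceiling) violations. [score_layout()] combines them
#' into the global objective.
#'
#' @name cost_model
NULL

#' EMG orientation cost curve
#'
#' Cost of misalignment between a bipolar electrode pair and the muscle
#' line, fitted to published signal-degradation data:
#' 0.0057 theta + 0.000181 theta^2 for theta <= 60 degrees, and 1 beyond
#' (signal drops drastically past 60 degrees). Clamped to \[0, 1\].
#'
#' @param theta axial angle in degrees, in \[0, 90\] (vectorized).
#' @return cost in \[0, 1\].
#' @export
#' @examples
#' emg_orientation_cost(c(0, 30, 75))
emg_orientation_cost <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 90)) {
    rlang::abort("theta must be in [0, 90] degrees", class = "sensorlayout_domain_error")
  }
  pmin(1, pmax(0, ifelse(theta <= 60, 0.0057 * theta + 0.000181 * theta^2, 1)))
}

#' EMG inter-electrode distance cost curve
#'
#' Piecewise cost of the centre-to-centre distance of an EMG pair:
#' max(0, 1.0125 - 0.0586 d + 0.0007 d^2) for 5 < d <= 25 mm, 0 for
#' 25 < d <= 60 mm, 1 above 60 mm (drastic signal drop at large
#' separations), and 1 at d <= 5 mm, where the curve is not defined and
#' electrodes would practically touch.
#'
#' @param d centre-to-centre distance in mm, > 0 (vectorized).
#' @return cost in \[0, 1\].
#' @export
#' @examples
#' emg_distance_cost(c(10, 40, 70))
emg_distance_cost <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    rlang::abort("d must be positive", class = "sensorlayout_domain_error")
  }
  out <- ifelse(
    d <= 5, 1,
    ifelse(d <= 25, pmax(0, 1.0125 - 0.0586 * d + 0.0007 * d^2),
      ifelse(d <= 60, 0, 1)
    )
  )
  pmin(1, out)
}

# disk (center, radius) vs polygon overlap: center inside, or any edge
# within radius
disk_intersects_polygon <- function(center, radius, poly) {
  if (pip_one(center, poly, tol = 1e-9)) return(TRUE)
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  for (k in seq_len(n)) {
    if (seg_dist(center, poly[j[k], ], poly[k, ]) <= radius) return(TRUE)
  }
  FALSE
}

#' EMG cost of one electrode pair on one muscle
#'
#' Pre-checks first: if either electrode centre is more than 10 mm from the
#' muscle line, or either electrode disk overlaps an innervation zone, the
#' pair scores 1 (worst). Otherwise the cost is the weighted average
#' `alpha * orientation_cost + (1 - alpha) * distance_cost`.
#'
#' @param e1,e2 electrode centres `c(u, v)` in mm.
#' @param muscle one row of `model$muscles` (columns k1_u, k1_v, k2_u,
#'   k2_v and list-column `iz`), in mm.
#' @param alpha orientation-vs-distance priority in \[0,1\] (default 0.5).
#' @param radius electrode radius in mm (EMG default).
#' @param line_tolerance maximum centre offset from the muscle line, mm.
#' @return cost in \[0, 1\].
#' @export
emg_muscle_cost <- function(e1, e2, muscle, alpha = 0.5,
                            radius = electrode_radius("EMG"),
                            line_tolerance = 10) {
  k1 <- c(muscle$k1_u, muscle$k1_v)
  k2 <- c(muscle$k2_u, muscle$k2_v)
  e1 <- as.numeric(e1); e2 <- as.numeric(e2)
  if (point_segment_distance(e1, k1, k2) > line_tolerance ||
      point_segment_distance(e2, k1, k2) > line_tolerance) {
    return(1)
  }
  izs <- muscle$iz
  if (!is.null(izs) && length(izs)) {
    if (is.matrix(izs[[1]]) || is.data.frame(izs[[1]])) iz_list <- izs else iz_list <- izs[[1]]
    for (iz in iz_list) {
      iz <- as_point_matrix(iz)
      if (disk_intersects_polygon(e1, radius, iz) ||
          disk_intersects_polygon(e2, radius, iz)) {
        return(1)
      }
    }
  }
  theta <- pair_angle_to_line(e1, e2, k1, k2)
  d <- sqrt(sum((e2 - e1)^2))
  alpha * emg_orientation_cost(theta) + (1 - alpha) * emg_distance_cost(d)
}

#' Overall EMG cost of a layout
#'
#' Unweighted mean of the per-muscle pair costs over the selected muscles
#' (the EMG priority weight is applied once, in the global objective).
#'
#' @param layout a layout tibble (see [build_baseline_layout()]).
#' @param model a `forearm_model`.
#' @param muscles muscles to score; default all muscles present in the layout.
#' @param alpha orientation-vs-distance priority.
#' @return list with `O1` (mean cost) and `per_muscle` (named numeric).
#' @export
emg_cost <- function(layout, model, muscles = NULL, alpha = 0.5) {
  emg <- layout[layout$modality == "EMG" & !layout$is_reference, ]
  if (is.null(muscles)) muscles <- unique(emg$muscle)
  if (length(muscles) == 0) {
    rlang::abort("EMG enabled but no muscle selected", class = "sensorlayout_config_error")
  }
  per <- vapply(muscles, function(ms) {
    pair <- emg[emg$muscle == ms, ]
    if (nrow(pair) != 2) {
      rlang::abort(sprintf("muscle %s must have exactly 2 EMG electrodes", ms),
        class = "sensorlayout_role_error"
      )
    }
    mrow <- model$muscles[model$muscles$muscle == ms, ]
    emg_muscle_cost(
      c(pair$u[1], pair$v[1]), c(pair$u[2], pair$v[2]),
      mrow, alpha = alpha, radius = pair$radius[1]
    )
  }, numeric(1))
  list(O1 = mean(per), per_muscle = per)
}

#' Sweat glands covered by an EDA electrode pair
#'
#' N_s = (pi r^2 + d * 2r) * density: the disk of one electrode plus the
#' band between the electrodes.
#'
#' @param d centre-to-centre distance, mm (>= 0).
#' @param r electrode radius, mm (default 5, the EDA electrode).
#' @param density sweat glands per mm^2.
#' @return expected gland count (real-valued).
#' @export
#' @examples
#' eda_gland_count(60, 5, 1.08) # ~ 733 on the forearm at the recommended 6 cm
eda_gland_count <- function(d, r = 5, density = 1.08) {
  if (any(d < 0) || any(r <= 0) || any(density <= 0)) {
    rlang::abort("d >= 0, r > 0 and density > 0 required", class = "sensorlayout_domain_error")
  }
  (pi * r^2 + d * 2 * r) * density
}

#' EDA cost of an electrode pair
#'
#' Cost 1 when fewer than the functional minimum of 140 glands is covered or
#' the pair exceeds the recommended 60 mm separation (risk of spanning
#' dermatomes); otherwise 1 - N_s / N_max, with N_max the coverage at the
#' recommended distance.
#'
#' @param d_s centre-to-centre distance, mm.
#' @param density sweat glands per mm^2.
#' @param r electrode radius, mm.
#' @param recommended_distance mm (default 60).
#' @param min_glands functional minimum gland count (default 140).
#' @return cost in \[0, 1\].
#' @export
eda_cost <- function(d_s, density, r = 5, recommended_distance = 60, min_glands = 140) {
  n_s <- eda_gland_count(d_s, r, density)
  n_max <- eda_gland_count(recommended_distance, r, density)
  ifelse(n_s <= min_glands | d_s > recommended_distance, 1, 1 - n_s / n_max)
}

#' ECG cost of an electrode pair
#'
#' The discrete keypoint model: the pair is assigned to the nearest
#' candidate ECG pair (minimizing the summed centre-to-keypoint distance
#' over the two possible matchings). Within the capture radius the cost is
#' 1 - SNR/SNR_max of the assigned candidate, so the best pair scores 0 and
#' the wrist pair (relative SNR 0.25) scores 0.75; beyond it the cost is 1.
#'
#' @param e1,e2 electrode centres `c(u, v)`, mm.
#' @param model a `forearm_model` with at least one ECG candidate pair.
#' @param capture_radius per-electrode capture radius, mm (default 20).
#' @return cost in \[0, 1\].
#' @export
ecg_cost <- function(e1, e2, model, capture_radius = 20) {
  cp <- model$ecg_pairs
  if (is.null(cp) || nrow(cp) == 0) {
    rlang::abort("model has no ECG candidate pairs", class = "sensorlayout_config_error")
  }
  e1 <- as.numeric(e1); e2 <- as.numeric(e2)
  d <- function(p, qu, qv) sqrt((p[1] - qu)^2 + (p[2] - qv)^2)
  sum_dist <- pmin(
    d(e1, cp$k1_u, cp$k1_v) + d(e2, cp$k2_u, cp$k2_v),
    d(e1, cp$k2_u, cp$k2_v) + d(e2, cp$k1_u, cp$k1_v)
  )
  i <- which.min(sum_dist)
  if (sum_dist[i] > 2 * capture_radius) return(1)
  1 - cp$rel_snr[i] / max(cp$rel_snr)
}

#' Rule-based baseline layout
#'
#' The non-optimized reference placement following published guides: EMG
#' pairs centred on each selected muscle's two keypoints, the EDA pair
#' straddling the template's mid-forearm anchor at the recommended 60 mm
#' spacing, and the ECG pair on the maximum-SNR candidate keypoints. Under
#' the default template every enabled modality scores cost 0 (predicted
#' quality 1.0), and the baseline's convex hull normalizes the area term.
#'
#' @param model a `forearm_model`.
#' @param config a [design_config()].
#' @return a layout: tibble with columns `electrode`, `modality`, `muscle`,
#'   `member`, `radius`, `u`, `v`, `is_reference`.
#' @export
#' @examples
#' model <- build_forearm_model(forearm_measurements(250, 55, 70, 85))
#' build_baseline_layout(model, design_config("EMG", muscles = c("FCR", "BR", "PL")))
build_baseline_layout <- function(model, config) {
  roster <- layout_roster(config)
  u <- numeric(nrow(roster)); v <- numeric(nrow(roster))
  for (i in seq_len(nrow(roster))) {
    if (roster$modality[i] == "EMG") {
      mrow <- model$muscles[model$muscles$muscle == roster$muscle[i], ]
      if (roster$member[i] == "A") {
        u[i] <- mrow$k1_u; v[i] <- mrow$k1_v
      } else {
        u[i] <- mrow$k2_u; v[i] <- mrow$k2_v
      }
    } else if (roster$modality[i] == "EDA") {
      off <- if (roster$member[i] == "A") -30 else 30
      u[i] <- model$eda_anchor[1]
      v[i] <- model$eda_anchor[2] + off
    } else {
      best <- model$ecg_pairs[which.max(model$ecg_pairs$rel_snr), ]
      if (roster$member[i] == "A") {
        u[i] <- best$k1_u; v[i] <- best$k1_v
      } else {
        u[i] <- best$k2_u; v[i] <- best$k2_v
      }
    }
  }
  layout <- roster
  layout$u <- u
  layout$v <- v
  layout$is_reference <- FALSE
  val <- validate_layout(layout, model)
  if (!val$valid) {
    rlang::abort(
      paste0(
        "baseline layout infeasible under this template: ",
        paste(val$violations$detail, collapse = "; ")
      ),
      class = "sensorlayout_template_error"
    )
  }
  layout
}

#' Convex-hull area cost
#'
#' Hull area of the measurement-electrode centres normalized by the
#' baseline layout's hull area. Layouts with fewer than three electrodes
#' have a degenerate hull and score 0 (with a warning).
#'
#' @param layout a layout tibble.
#' @param baseline_area baseline hull area, mm^2 (> 0).
#' @return area ratio >= 0 (may exceed 1 if the layout outgrows the baseline).
#' @export
area_cost <- function(layout, baseline_area) {
  if (!is.numeric(baseline_area) || baseline_area <= 0) {
    rlang::abort("baseline_area must be positive", class = "sensorlayout_domain_error")
  }
  centers <- as.matrix(layout[!layout$is_reference, c("u", "v")])
  if (nrow(centers) < 3) {
    rlang::warn("fewer than 3 measurement electrodes: degenerate hull, area cost 0")
    return(0)
  }
  area <- tryCatch(convex_hull_area(centers), sensorlayout_degenerate_hull = function(e) {
    rlang::warn("collinear electrode centres: degenerate hull, area cost 0")
    0
  })
  area / baseline_area
}

#' Lower-bound penalty
#'
#' Exponential penalty for violating a modality's cost ceiling l_k:
#' P_k = p * (exp(max(O_k - l_k, 0)) - 1). Zero when the cost is within
#' its ceiling; grows exponentially with the size of the violation, with
#' the softness p scaling how hard the bound is enforced.
#'
#' @param o_k modality cost in \[0, 1\] (vectorized).
#' @param bound cost ceiling l_k in \[0, 1\].
#' @param softness p >= 0.
#' @return penalty >= 0.
#' @export
lower_bound_penalty <- function(o_k, bound, softness) {
  if (any(softness < 0)) rlang::abort("softness must be >= 0", class = "sensorlayout_domain_error")
  softness * (exp(pmax(o_k - bound, 0)) - 1)
}

#' Score a layout: the global objective
#'
#' Evaluates every enabled modality cost, the area term, and (under the
#' bound or hybrid schemes) the lower-bound penalties, combining them into
#' the global objective O = sum_k w_k O_k (+ sum_k P_k). Also reports the
#' predicted quality, 1 minus the weight-normalized modality-cost
#' aggregate; the area term is a size metric, not signal quality, and is
#' excluded from quality.
#'
#' @param layout a layout tibble.
#' @param model a `forearm_model`.
#' @param config a [design_config()].
#' @param baseline_area hull area of the baseline layout in mm^2; computed
#'   from [build_baseline_layout()] when `NULL`.
#' @return an object of class `cost_breakdown`: list with `O1`, `O2`, `O3`,
#'   `O4`, `per_muscle`, `penalties`, `objective`, `modality_aggregate`,
#'   `quality`, `area_mm2`.
#' @export
score_layout <- function(layout, model, config, baseline_area = NULL) {
  if (is.null(baseline_area)) {
    baseline <- build_baseline_layout(model, config)
    baseline_area <- layout_hull_area(baseline)
  }
  fn <- make_objective(model, config, baseline_area)
  centers <- as.matrix(layout[!layout$is_reference, c("u", "v")])
  fn(centers, full = TRUE)
}

layout_hull_area <- function(layout) {
  centers <- as.matrix(layout[!layout$is_reference, c("u", "v")])
  if (nrow(centers) < 3) return(0)
  tryCatch(convex_hull_area(centers), sensorlayout_degenerate_hull = function(e) 0)
}

# Precompiled objective over an electrode-centre matrix ordered as
# layout_roster(config). The hot path of the annealer: avoids tibble
# subsetting per evaluation.
make_objective <- function(model, config, baseline_area) {
  roster <- layout_roster(config)
  has <- function(m) m %in% config$modalities
  w <- config$weights
  alpha <- config$alpha

  emg_idx <- NULL; muscle_geo <- NULL
  if (has("EMG")) {
    emg_idx <- lapply(config$muscles, function(ms) which(roster$muscle %in% ms))
    muscle_geo <- lapply(config$muscles, function(ms) {
      mrow <- model$muscles[model$muscles$muscle == ms, ]
      izs <- mrow$iz
      iz_list <- if (length(izs) && (is.matrix(izs[[1]]) || is.data.frame(izs[[1]]))) izs else izs[[1]]
      list(
        k1 = c(mrow$k1_u, mrow$k1_v), k2 = c(mrow$k2_u, mrow$k2_v),
        iz = lapply(iz_list, as_point_matrix),
        radius = electrode_radius("EMG")
      )
    })
    names(muscle_geo) <- config$muscles
  }
  eda_idx <- which(roster$modality == "EDA")
  ecg_idx <- which(roster$modality == "ECG")
  n_meas <- nrow(roster)
  degenerate_area <- n_meas < 3

  function(centers, full = FALSE) {
    O1 <- NA_real_; O2 <- NA_real_; O3 <- NA_real_
    per_muscle <- NULL
    if (has("EMG")) {
      per_muscle <- vapply(seq_along(emg_idx), function(i) {
        g <- muscle_geo[[i]]
        idx <- emg_idx[[i]]
        e1 <- centers[idx[1], ]; e2 <- centers[idx[2], ]
        if (seg_dist(e1, g$k1, g$k2) > 10 || seg_dist(e2, g$k1, g$k2) > 10) return(1)
        for (iz in g$iz) {
          if (disk_intersects_polygon(e1, g$radius, iz) ||
              disk_intersects_polygon(e2, g$radius, iz)) {
            return(1)
          }
        }
        ev <- e2 - e1
        d <- sqrt(sum(ev^2))
        if (d == 0) return(1)
        kv <- g$k2 - g$k1
        theta <- acos(min(1, abs(sum(ev * kv)) / (d * sqrt(sum(kv^2))))) * 180 / pi
        alpha * emg_orientation_cost(theta) + (1 - alpha) * emg_distance_cost(d)
      }, numeric(1))
      names(per_muscle) <- config$muscles
      O1 <- mean(per_muscle)
    }
    if (has("EDA")) {
      d_s <- sqrt(sum((centers[eda_idx[1], ] - centers[eda_idx[2], ])^2))
      O2 <- eda_cost(d_s, model$gland_density)
    }
    if (has("ECG")) {
      O3 <- ecg_cost(centers[ecg_idx[1], ], centers[ecg_idx[2], ], model)
    }
    area <- if (degenerate_area) 0 else {
      hull <- graham_scan(centers)
      if (nrow(hull) < 3) 0 else polygon_area(hull)
    }
    O4 <- if (baseline_area > 0) area / baseline_area else 0

    costs <- c(EMG = O1, EDA = O2, ECG = O3)
    enabled <- config$modalities
    weighted <- sum(w[enabled] * costs[enabled]) + w["area"] * O4
    penalties <- c(EMG = 0, EDA = 0, ECG = 0)
    if (config$scheme %in% c("bounds", "hybrid") && !is.null(config$bounds)) {
      for (m in names(config$bounds)) {
        penalties[m] <- lower_bound_penalty(costs[m], config$bounds[[m]], config$softness)
      }
    }
    objective <- unname(weighted + sum(penalties))
    if (!full) return(objective)
    w_en <- w[enabled]
    aggregate <- if (sum(w_en) > 0) {
      sum(w_en * costs[enabled]) / sum(w_en)
    } else {
      mean(costs[enabled])
    }
    structure(
      list(
        O1 = O1, O2 = O2, O3 = O3, O4 = unname(O4),
        per_muscle = per_muscle,
        penalties = penalties,
        objective = objective,
        modality_aggregate = unname(aggregate),
        quality = unname(1 - aggregate),
        area_mm2 = unname(area),
        baseline_area_mm2 = baseline_area,
        weights = w,
        scheme = config$scheme
      ),
      class = "cost_breakdown"
    )
  }
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown>\n")
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.4f", v))
  cat(sprintf(
    "  O1 (EMG) %s  O2 (EDA) %s  O3 (ECG) %s  O4 (area) %s\n",
    fmt(x$O1), fmt(x$O2), fmt(x$O3), fmt(x$O4)
  ))
  cat(sprintf(
    "  objective %.4f  quality %.4f  area %.1f mm^2\n",
    x$objective, x$quality, x$area_mm2
  ))
  invisible(x)
}
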