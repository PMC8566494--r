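# Shared fixtures, built in code at test time.

demo_measurements <- function() forearm_measurements(250, 55, 70, 85)

demo_model <- function() build_forearm_model(demo_measurements())

# wrist-anchored rectangular window spanning the forearm's full width
wrist_window <- function(model, height) {
  outline <- as.matrix(model$outline)
  ur <- range(outline[, 1])
  rbind(c(ur[1], 0), c(ur[2], 0), c(ur[2], height), c(ur[1], height))
}

# single-muscle toy: constant width so the PL line is exactly vertical in mm,
# making the continuum optimum (aligned pair, cost 0) grid-attainable
toy_template <- function() {
  forearm_template(
    outline = tibble::tibble(u = c(0.02, 0.98, 0.98, 0.02), v = c(0, 0, 1, 1)),
    muscles = tibble::tibble(
      muscle = "PL",
      k1_u = 0.5, k1_v = 0.30, k2_u = 0.5, k2_v = 0.44,
      iz = list(cbind(u = c(0.45, 0.55, 0.55, 0.45), v = c(0.356, 0.356, 0.384, 0.384)))
    ),
    ecg_pairs = tibble::tibble(
      pair = c("wrist", "upper"),
      k1_u = c(0.3, 0.3), k1_v = c(0.05, 0.9),
      k2_u = c(0.7, 0.7), k2_v = c(0.05, 0.9),
      rel_snr = c(0.25, 1)
    ),
    eda_anchor = c(0.5, 0.5),
    gland_density = 1.08
  )
}

toy_model <- function() {
  build_forearm_model(forearm_measurements(250, 50, 50, 50), toy_template())
}

# exhaustive grid search over valid electrode pairs for one muscle inside a
# rectangular region: the independent oracle for the annealer
grid_pair_optimum <- function(model, muscle_id, region, spacing_mm = 2,
                              min_dist = 12, alpha = 0.5) {
  us <- seq(region[1, 1], region[2, 1], by = spacing_mm)
  vs <- seq(region[1, 2], region[3, 2], by = spacing_mm)
  grid <- as.matrix(expand.grid(u = us, v = vs))
  mrow <- model$muscles[model$muscles$muscle == muscle_id, ]
  k1 <- c(mrow$k1_u, mrow$k1_v); k2 <- c(mrow$k2_u, mrow$k2_v)
  r <- electrode_radius("EMG")
  line_ok <- vapply(
    seq_len(nrow(grid)),
    function(i) point_segment_distance(grid[i, ], k1, k2) <= 10, logical(1)
  )
  iz <- mrow$iz[[1]]
  iz_list <- if (is.matrix(iz) || is.data.frame(iz)) list(iz) else iz
  iz_ok <- vapply(seq_len(nrow(grid)), function(i) {
    for (poly in iz_list) {
      poly <- as.matrix(poly)
      if (point_in_polygon(grid[i, , drop = FALSE], poly)) return(FALSE)
      n <- nrow(poly); j <- c(n, seq_len(n - 1))
      for (k in seq_len(n)) {
        if (point_segment_distance(grid[i, ], poly[j[k], ], poly[k, ]) <= r) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  cand <- grid[line_ok & iz_ok, , drop = FALSE]
  if (nrow(cand) < 2) return(1)
  best <- 1
  kvec <- k2 - k1
  for (i in seq_len(nrow(cand) - 1)) {
    du <- cand[(i + 1):nrow(cand), 1] - cand[i, 1]
    dv <- cand[(i + 1):nrow(cand), 2] - cand[i, 2]
    d <- sqrt(du^2 + dv^2)
    ok <- d >= min_dist
    if (!any(ok)) next
    theta <- acos(pmin(1, abs(du[ok] * kvec[1] + dv[ok] * kvec[2]) /
                         (d[ok] * sqrt(sum(kvec^2))))) * 180 / pi
    cost <- alpha * emg_orientation_cost(theta) + (1 - alpha) * emg_distance_cost(d[ok])
    best <- min(best, cost)
  }
  best
}
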