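#' Annealing configuration
#'
#' Simulated-annealing schedule and constraint parameters. The candidate
#' budget defaults to 15,490 evaluated solutions per run, matching the
#' published sweep protocol; the schedule itself (geometric cooling from
#' T0 = 1 with factor 0.95, 100 moves per temperature, 10 mm maximum step)
#' is a standard default sized to that budget.
#'
#' @param t0 initial temperature (> 0).
#' @param cooling geometric cooling factor in (0, 1).
#' @param moves_per_temp proposals between cooling steps.
#' @param candidates total candidate solutions per run.
#' @param step maximum translation per move, mm.
#' @param p_teleport probability that a move translates the chosen electrode
#'   to a uniform random point of the search region instead of a local step.
#'   The EMG cost term is flat (worst score 1) everywhere outside the 10 mm
#'   muscle corridors, so purely local moves random-walk across a plateau;
#'   occasional long-range translations let the annealer discover corridors
#'   within the candidate budget. Set to 0 for purely local moves.
#' @param seed integer RNG seed; all stochastic choices derive from it.
#' @param spacing minimum centre-to-centre distance between measurement
#'   electrodes, mm (the 12 mm safety rule, which also exceeds the sum of
#'   any two electrode radii so electrodes can never overlap).
#' @param init_attempts rejection-sampling attempts before declaring the
#'   region infeasible.
#' @return an object of class `anneal_config`.
#' @export
anneal_config <- function(t0 = 1, cooling = 0.95, moves_per_temp = 100,
                          candidates = 15490, step = 10, p_teleport = 0.25,
                          seed = 1, spacing = 12, init_attempts = 10000) {
  bad <- function(msg) rlang::abort(msg, class = "sensorlayout_config_error")
  if (t0 <= 0) bad("t0 must be > 0")
  if (cooling <= 0 || cooling >= 1) bad("cooling must be in (0, 1)")
  if (candidates < 1) bad("candidates must be >= 1")
  if (step < 0) bad("step must be >= 0")
  if (p_teleport < 0 || p_teleport > 1) bad("p_teleport must be in [0, 1]")
  if (spacing <= 0) bad("spacing must be > 0")
  structure(
    list(
      t0 = t0, cooling = cooling, moves_per_temp = as.integer(moves_per_temp),
      candidates = as.integer(candidates), step = step, p_teleport = p_teleport,
      seed = as.integer(seed), spacing = spacing,
      init_attempts = as.integer(init_attempts)
    ),
    class = "anneal_config"
  )
}

#' Validate a layout against spacing and containment constraints
#'
#' A layout is valid when every pair of measurement electrodes is at least
#' `spacing` mm apart centre-to-centre (which also enforces non-overlap,
#' since 12 mm exceeds the sum of any two electrode radii) and every
#' measurement-electrode centre lies inside the search region (the sketched
#' shape if given, otherwise the forearm outline). Reference electrodes are
#' off-forearm and exempt.
#'
#' @param layout a layout tibble.
#' @param model a `forearm_model` (supplies the outline).
#' @param shape optional region polygon (matrix or data frame with columns
#'   u, v, in mm) that the layout must not exceed.
#' @param spacing minimum centre-to-centre distance, mm.
#' @return list with `valid` (logical) and `violations` (tibble with
#'   columns `type`, `detail`).
#' @export
validate_layout <- function(layout, model, shape = NULL, spacing = 12) {
  meas <- layout[!layout$is_reference, ]
  centers <- as.matrix(meas[, c("u", "v")])
  violations <- list()
  if (nrow(centers) >= 2) {
    dm <- as.matrix(stats::dist(centers))
    idx <- which(upper.tri(dm) & dm < spacing - 1e-9, arr.ind = TRUE)
    if (nrow(idx)) {
      violations$spacing <- tibble::tibble(
        type = "spacing",
        detail = sprintf(
          "%s and %s are %.2f mm apart (< %g mm)",
          meas$electrode[idx[, 1]], meas$electrode[idx[, 2]],
          dm[idx], spacing
        )
      )
    }
  }
  region <- if (is.null(shape)) as.matrix(model$outline) else as_point_matrix(shape)
  inside <- point_in_polygon(centers, region)
  if (!is.null(shape)) inside <- inside & point_in_polygon(centers, as.matrix(model$outline))
  if (any(!inside)) {
    violations$containment <- tibble::tibble(
      type = "containment",
      detail = sprintf("%s centre outside the search region", meas$electrode[!inside])
    )
  }
  violations <- dplyr::bind_rows(violations)
  if (is.null(violations) || nrow(violations) == 0) {
    violations <- tibble::tibble(type = character(0), detail = character(0))
  }
  list(valid = nrow(violations) == 0, violations = violations)
}

# vectorized constraint predicate on a centre matrix; when moved is given,
# only that electrode's pairwise distances and containment are rechecked
centers_valid <- function(centers, region_mat, outline_mat, spacing, moved = NULL) {
  n <- nrow(centers)
  if (is.null(moved)) {
    if (n >= 2) {
      d <- stats::dist(centers)
      if (any(d < spacing - 1e-9)) return(FALSE)
    }
    if (!all(pip_fast(centers, region_mat))) return(FALSE)
    if (!is.null(outline_mat) && !all(pip_fast(centers, outline_mat))) return(FALSE)
  } else {
    p <- centers[moved, ]
    if (n >= 2) {
      others <- centers[-moved, , drop = FALSE]
      d2 <- (others[, 1] - p[1])^2 + (others[, 2] - p[2])^2
      if (any(d2 < (spacing - 1e-9)^2)) return(FALSE)
    }
    if (!pip_one(p, region_mat, tol = 1e-9)) return(FALSE)
    if (!is.null(outline_mat) && !pip_one(p, outline_mat, tol = 1e-9)) return(FALSE)
  }
  TRUE
}

pip_fast <- function(pts, poly) {
  vapply(seq_len(nrow(pts)), function(i) pip_one(pts[i, ], poly, tol = 1e-9), logical(1))
}

#' Random initial layout inside a region
#'
#' Uniform rejection sampling inside the search region: electrode centres
#' are drawn uniformly in the region's bounding box, accepted when inside
#' the region (and forearm outline) and at least `spacing` mm from every
#' electrode already placed. Deterministic for a given seed.
#'
#' @inheritParams validate_layout
#' @param config a [design_config()].
#' @param opt an [anneal_config()] (supplies spacing, attempts and seed
#'   when `rng_ready = FALSE`).
#' @param rng_ready set to `TRUE` when the caller has already seeded the
#'   RNG stream (as [anneal()] does).
#' @return a valid layout tibble.
#' @export
random_initial_layout <- function(model, config, opt = anneal_config(),
                                  shape = NULL, rng_ready = FALSE) {
  if (!rng_ready) set.seed(opt$seed)
  roster <- layout_roster(config)
  region <- if (is.null(shape)) as.matrix(model$outline) else as_point_matrix(shape)
  outline_mat <- if (is.null(shape)) NULL else as.matrix(model$outline)
  bb_u <- range(region[, 1]); bb_v <- range(region[, 2])
  n <- nrow(roster)
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    if (attempts >= opt$init_attempts) {
      rlang::abort(
        sprintf(
          "could not place %d electrodes in the region after %d attempts (region infeasible?)",
          n, attempts
        ),
        class = "sensorlayout_infeasible_region"
      )
    }
    attempts <- attempts + 1L
    p <- c(stats::runif(1, bb_u[1], bb_u[2]), stats::runif(1, bb_v[1], bb_v[2]))
    if (!pip_one(p, region, tol = 1e-9)) next
    if (!is.null(outline_mat) && !pip_one(p, outline_mat, tol = 1e-9)) next
    if (placed > 0L) {
      prev <- centers[seq_len(placed), , drop = FALSE]
      if (any((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 < opt$spacing^2)) {
        # restart occasionally so early bad placements cannot wedge the sampler
        if (attempts %% 500L == 0L) placed <- 0L
        next
      }
    }
    placed <- placed + 1L
    centers[placed, ] <- p
  }
  layout <- roster
  layout$u <- centers[, 1]
  layout$v <- centers[, 2]
  layout$is_reference <- FALSE
  layout
}

#' Propose a neighbouring layout
#'
#' Picks one measurement electrode uniformly at random and translates it.
#' By default the translation vector has direction uniform on \[0, 2 pi)
#' and magnitude uniform on (0, step\]. With probability `p_teleport` (and
#' a `region` supplied) the vector instead carries the electrode to a
#' uniform random point of the region's bounding box — the long-range move
#' the annealer needs to cross the EMG cost plateaus. The proposal is
#' returned whether or not it is valid; validity is enforced by rejection
#' inside [anneal()].
#'
#' @param layout a layout tibble.
#' @param step maximum local translation, mm.
#' @param p_teleport probability of a long-range move (default 0: the pure
#'   local kernel).
#' @param region polygon (n x 2 matrix, mm) whose bounding box long-range
#'   moves sample; required when `p_teleport > 0`.
#' @return the proposed layout tibble (exactly one electrode moved).
#' @export
propose_neighbor <- function(layout, step = 10, p_teleport = 0, region = NULL) {
  meas_idx <- which(!layout$is_reference)
  i <- meas_idx[sample.int(length(meas_idx), 1L)]
  if (p_teleport > 0 && stats::runif(1) < p_teleport) {
    if (is.null(region)) {
      rlang::abort("p_teleport > 0 needs a region", class = "sensorlayout_config_error")
    }
    region <- as_point_matrix(region)
    layout$u[i] <- stats::runif(1, min(region[, 1]), max(region[, 1]))
    layout$v[i] <- stats::runif(1, min(region[, 2]), max(region[, 2]))
  } else {
    ang <- stats::runif(1, 0, 2 * pi)
    mag <- stats::runif(1, 0, step)
    layout$u[i] <- layout$u[i] + mag * cos(ang)
    layout$v[i] <- layout$v[i] + mag * sin(ang)
  }
  layout
}

#' Annealing acceptance rule
#'
#' Draw c ~ Uniform(0, 1) and accept when c <= exp(-delta / t).
#' Improvements (delta <= 0) are always accepted since the threshold is
#' then at least 1.
#'
#' @param delta objective difference, proposed minus current.
#' @param t annealing temperature (> 0).
#' @return logical.
#' @export
accept_move <- function(delta, t) {
  if (any(t <= 0)) rlang::abort("temperature must be > 0", class = "sensorlayout_domain_error")
  stats::runif(length(delta)) <= exp(-delta / t)
}

#' Optimize an electrode layout by simulated annealing
#'
#' Starts from a random valid layout inside the search region and explores
#' single-electrode translations, rejecting constraint-violating proposals
#' outright (their energy is never evaluated) and accepting valid ones by
#' the Metropolis rule with geometric cooling. The best layout seen is
#' returned, after `opt$candidates` proposals. Bit-reproducible for a given
#' seed: one RNG stream, consumed in the order initial layout, then per
#' proposal (electrode index, kernel choice, direction and magnitude or
#' teleport target, acceptance draw for valid proposals).
#'
#' @param model a `forearm_model`.
#' @param config a [design_config()].
#' @param opt an [anneal_config()].
#' @param shape optional region polygon in mm that the layout must not
#'   exceed; defaults to the whole forearm outline.
#' @param baseline_area baseline hull area in mm^2 for the area term;
#'   computed from [build_baseline_layout()] when `NULL`.
#' @return an object of class `electrode_design`: list with the best
#'   `layout`, its `cost` breakdown, `config`, `opt`, `shape`,
#'   `model_fingerprint` and the objective `trace` (best-so-far per
#'   temperature batch).
#' @export
#' @examples
#' model <- build_forearm_model(forearm_measurements(250, 55, 70, 85))
#' cfg <- design_config("EMG", muscles = "FCR")
#' design <- anneal(model, cfg, anneal_config(candidates = 500, seed = 7))
#' design$cost$objective
anneal <- function(model, config, opt = anneal_config(), shape = NULL,
                   baseline_area = NULL) {
  set.seed(opt$seed)
  if (is.null(baseline_area)) {
    baseline <- build_baseline_layout(model, config)
    baseline_area <- layout_hull_area(baseline)
  }
  objective <- make_objective(model, config, baseline_area)
  layout <- random_initial_layout(model, config, opt, shape, rng_ready = TRUE)
  region <- if (is.null(shape)) as.matrix(model$outline) else as_point_matrix(shape)
  outline_mat <- if (is.null(shape)) NULL else as.matrix(model$outline)

  centers <- as.matrix(layout[, c("u", "v")])
  n <- nrow(centers)
  cur_obj <- objective(centers)
  best_centers <- centers
  best_obj <- cur_obj
  temp <- opt$t0
  trace <- numeric(0)
  moves_in_batch <- 0L

  bb_u <- range(region[, 1])
  bb_v <- range(region[, 2])
  anchors <- teleport_anchors(layout, model)
  for (iter in seq_len(opt$candidates)) {
    i <- sample.int(n, 1L)
    cand <- centers
    if (opt$p_teleport > 0 && stats::runif(1) < opt$p_teleport) {
      # long-range move: half uniform exploration of the region, half biased
      # toward the moved electrode's own anatomical guide (muscle line or
      # ECG keypoints) — the objective is flat far from the guides, so
      # uninformed jumps alone discover them too slowly
      anch <- anchors[[i]]
      if (is.null(anch) || stats::runif(1) < 0.5) {
        cand[i, 1] <- stats::runif(1, bb_u[1], bb_u[2])
        cand[i, 2] <- stats::runif(1, bb_v[1], bb_v[2])
      } else {
        t <- stats::runif(1)
        base <- anch$a + t * (anch$b - anch$a)
        cand[i, ] <- base + stats::runif(2, -anch$radius, anch$radius)
      }
    } else {
      ang <- stats::runif(1, 0, 2 * pi)
      mag <- stats::runif(1, 0, opt$step)
      cand[i, 1] <- cand[i, 1] + mag * cos(ang)
      cand[i, 2] <- cand[i, 2] + mag * sin(ang)
    }
    if (centers_valid(cand, region, outline_mat, opt$spacing, moved = i)) {
      new_obj <- objective(cand)
      if (stats::runif(1) <= exp(-(new_obj - cur_obj) / temp)) {
        centers <- cand
        cur_obj <- new_obj
        if (new_obj < best_obj) {
          best_obj <- new_obj
          best_centers <- cand
        }
      }
    }
    moves_in_batch <- moves_in_batch + 1L
    if (moves_in_batch >= opt$moves_per_temp) {
      temp <- temp * opt$cooling
      trace <- c(trace, best_obj)
      moves_in_batch <- 0L
    }
  }
  layout$u <- best_centers[, 1]
  layout$v <- best_centers[, 2]
  cost <- objective(best_centers, full = TRUE)
  new_design(layout, cost, config, opt, shape, model, trace = trace)
}

# per-electrode guide segments for biased long-range moves: an EMG
# electrode targets its own muscle line (within the 10 mm corridor + IZ
# slack), an ECG electrode the candidate keypoints (within the capture
# radius), EDA electrodes have no guide (any location can score well)
teleport_anchors <- function(layout, model) {
  lapply(seq_len(nrow(layout)), function(i) {
    role <- layout$modality[i]
    if (role == "EMG") {
      m <- model$muscles[model$muscles$muscle == layout$muscle[i], ]
      list(a = c(m$k1_u, m$k1_v), b = c(m$k2_u, m$k2_v), radius = 12)
    } else if (role == "ECG") {
      cp <- model$ecg_pairs
      k <- if (layout$member[i] == "A") {
        cbind(cp$k1_u, cp$k1_v)
      } else {
        cbind(cp$k2_u, cp$k2_v)
      }
      # segment degenerates to a random candidate keypoint per proposal is
      # overkill; spanning the keypoint range reaches all candidates
      list(a = k[1, ], b = k[nrow(k), ], radius = 18)
    } else {
      NULL
    }
  })
}

new_design <- function(layout, cost, config, opt, shape, model, trace = NULL) {
  structure(
    list(
      layout = layout,
      cost = cost,
      config = config,
      opt = opt,
      shape = if (is.null(shape)) NULL else as_point_matrix(shape),
      model_fingerprint = model$template_fingerprint,
      measurements = model$measurements,
      trace = trace
    ),
    class = "electrode_design"
  )
}

#' @export
print.electrode_design <- function(x, ...) {
  cat("<electrode_design>", nrow(x$layout), "measurement electrodes;",
      paste(x$config$modalities, collapse = "+"), "\n")
  cat(sprintf(
    "  objective %.4f  quality %.4f  hull area %.1f mm^2\n",
    x$cost$objective, x$cost$quality, x$cost$area_mm2
  ))
  invisible(x)
}
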