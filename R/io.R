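#' Save a design to a JSON file
#'
#' Writes a versioned, lossless JSON description of an `electrode_design`:
#' measurements, configuration, optimizer settings, electrode records in mm,
#' cost breakdown, optional shape and the template fingerprint. Numbers are
#' serialized at full precision so `load_design(save_design(x))` is exact
#' and identical seeds yield byte-identical files.
#'
#' @param design an `electrode_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_design <- function(design, path) {
  stopifnot(inherits(design, "electrode_design"))
  cfg <- design$config
  obj <- list(
    schema_version = "1.0",
    measurements = design$measurements[c("f1", "f2", "f3", "f4")],
    modalities = cfg$modalities,
    muscles = cfg$muscles,
    weights = as.list(cfg$weights),
    alpha = cfg$alpha,
    bounds = if (is.null(cfg$bounds)) NULL else as.list(cfg$bounds),
    softness = cfg$softness,
    scheme = cfg$scheme,
    optimizer = design$opt[c(
      "t0", "cooling", "moves_per_temp", "candidates", "step", "seed",
      "spacing", "init_attempts"
    )],
    shape = if (is.null(design$shape)) NULL else unname(apply(design$shape, 1, as.list)),
    electrodes = lapply(seq_len(nrow(design$layout)), function(i) {
      r <- design$layout[i, ]
      list(
        electrode = r$electrode, modality = r$modality,
        muscle = if (is.na(r$muscle)) NULL else r$muscle,
        member = r$member, radius = r$radius, u = r$u, v = r$v,
        is_reference = r$is_reference
      )
    }),
    cost = {
      cc <- design$cost[c(
        "O1", "O2", "O3", "O4", "per_muscle", "penalties", "objective",
        "modality_aggregate", "quality", "area_mm2", "baseline_area_mm2"
      )]
      # named vectors must become JSON objects, not bare arrays
      if (!is.null(cc$per_muscle)) cc$per_muscle <- as.list(cc$per_muscle)
      cc$penalties <- as.list(cc$penalties)
      cc
    },
    template_fingerprint = design$model_fingerprint
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a design from a JSON file
#'
#' @param path a file written by [save_design()].
#' @return an `electrode_design`.
#' @export
load_design <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      rlang::abort(paste0("cannot parse design file: ", conditionMessage(e)),
        class = "sensorlayout_parse_error"
      )
    }
  )
  if (is.null(obj$schema_version) || obj$schema_version != "1.0") {
    rlang::abort(
      sprintf("unsupported design schema version '%s'", obj$schema_version %||% "<missing>"),
      class = "sensorlayout_version_error"
    )
  }
  for (key in c("electrodes", "measurements", "modalities", "cost")) {
    if (is.null(obj[[key]])) {
      rlang::abort(sprintf("design file is missing the '%s' key", key),
        class = "sensorlayout_parse_error"
      )
    }
  }
  layout <- dplyr::bind_rows(lapply(obj$electrodes, function(e) {
    tibble::tibble(
      electrode = e$electrode, modality = e$modality,
      muscle = e$muscle %||% NA_character_, member = e$member,
      radius = e$radius, u = e$u, v = e$v, is_reference = isTRUE(e$is_reference)
    )
  }))
  cfg <- design_config(
    modalities = unlist(obj$modalities),
    muscles = if (length(obj$muscles)) unlist(obj$muscles) else MUSCLE_IDS,
    weights = unlist(obj$weights),
    alpha = obj$alpha,
    bounds = if (is.null(obj$bounds)) NULL else unlist(obj$bounds),
    softness = obj$softness,
    scheme = obj$scheme
  )
  opt <- do.call(anneal_config, obj$optimizer)
  cost <- obj$cost
  cost$per_muscle <- if (length(cost$per_muscle)) unlist(cost$per_muscle) else NULL
  cost$penalties <- unlist(cost$penalties)
  cost$weights <- cfg$weights
  cost$scheme <- cfg$scheme
  cost[c("O1", "O2", "O3", "O4")] <-
    lapply(cost[c("O1", "O2", "O3", "O4")], function(x) x %||% NA_real_)
  class(cost) <- "cost_breakdown"
  shape <- if (is.null(obj$shape)) NULL else {
    do.call(rbind, lapply(obj$shape, function(p) c(p$u %||% p[[1]], p$v %||% p[[2]])))
  }
  structure(
    list(
      layout = layout, cost = cost, config = cfg, opt = opt, shape = shape,
      model_fingerprint = obj$template_fingerprint,
      measurements = do.call(forearm_measurements, obj$measurements),
      trace = NULL
    ),
    class = "electrode_design"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a template file
#'
#' Templates persist as versioned JSON with keys `outline`, `muscles`
#' (each `{id, k1, k2, iz}` in normalized coordinates), `ecg_pairs`
#' (`{id, k1, k2, rel_snr}`), `eda_anchor` and `gland_density_per_mm2`.
#'
#' @param template a `forearm_template`.
#' @param path file path.
#' @return `path` (write) or a `forearm_template` (read).
#' @export
write_template <- function(template, path) {
  validate_template(template)
  m <- template$muscles
  obj <- list(
    version = template$version,
    outline = unname(lapply(seq_len(nrow(template$outline)), function(i) {
      c(template$outline$u[i], template$outline$v[i])
    })),
    muscles = lapply(seq_len(nrow(m)), function(i) {
      iz <- m$iz[[i]]
      iz_list <- if (is.matrix(iz) || is.data.frame(iz)) list(iz) else iz
      list(
        id = m$muscle[i],
        k1 = c(m$k1_u[i], m$k1_v[i]),
        k2 = c(m$k2_u[i], m$k2_v[i]),
        iz = lapply(iz_list, function(p) unname(apply(as_point_matrix(p), 1, c, simplify = FALSE)))
      )
    }),
    ecg_pairs = lapply(seq_len(nrow(template$ecg_pairs)), function(i) {
      e <- template$ecg_pairs[i, ]
      list(id = e$pair, k1 = c(e$k1_u, e$k1_v), k2 = c(e$k2_u, e$k2_v), rel_snr = e$rel_snr)
    }),
    eda_anchor = template$eda_anchor,
    gland_density_per_mm2 = template$gland_density
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      rlang::abort(paste0("cannot parse template file: ", conditionMessage(e)),
        class = "sensorlayout_parse_error"
      )
    }
  )
  if (is.null(obj$version)) {
    rlang::abort("template file must carry a version field",
      class = "sensorlayout_version_error"
    )
  }
  outline <- do.call(rbind, lapply(obj$outline, unlist))
  muscles <- dplyr::bind_rows(lapply(obj$muscles, function(m) {
    tibble::tibble(
      muscle = m$id,
      k1_u = m$k1[[1]], k1_v = m$k1[[2]],
      k2_u = m$k2[[1]], k2_v = m$k2[[2]]
    )
  }))
  muscles$iz <- lapply(obj$muscles, function(m) {
    polys <- lapply(m$iz, function(p) do.call(rbind, lapply(p, unlist)))
    if (length(polys) == 1) polys[[1]] else polys
  })
  ecg <- dplyr::bind_rows(lapply(obj$ecg_pairs, function(e) {
    tibble::tibble(
      pair = e$id,
      k1_u = e$k1[[1]], k1_v = e$k1[[2]],
      k2_u = e$k2[[1]], k2_v = e$k2[[2]],
      rel_snr = e$rel_snr
    )
  }))
  forearm_template(
    outline = tibble::tibble(u = outline[, 1], v = outline[, 2]),
    muscles = muscles, ecg_pairs = ecg,
    eda_anchor = unlist(obj$eda_anchor),
    gland_density = obj$gland_density_per_mm2,
    version = obj$version
  )
}

#' Export a design as SVG
#'
#' Plain SVG 1.1 with 1 user unit = 1 mm and no transforms, sized to the
#' forearm bounding box, for direct printing. `"layout"` mode draws the
#' forearm outline, muscle lines and filled electrode disks labelled by
#' role; `"stencil"` mode draws punch-hole circles only, one per
#' measurement electrode.
#'
#' @param design an `electrode_design`.
#' @param path output file.
#' @param mode `"layout"` or `"stencil"`.
#' @param model optional `forearm_model` for outline/muscle context in
#'   layout mode; rebuilt from the design's measurements and the default
#'   template when omitted.
#' @return `path`, invisibly.
#' @export
export_svg <- function(design, path, mode = c("layout", "stencil"), model = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "electrode_design"))
  if (is.null(model)) model <- build_forearm_model(design$measurements)
  outline <- as.matrix(model$outline)
  u0 <- min(outline[, 1]); u1 <- max(outline[, 1])
  v0 <- min(outline[, 2]); v1 <- max(outline[, 2])
  w <- u1 - u0; h <- v1 - v0
  # SVG y grows downward; flip v so the wrist (v = 0) sits at the bottom
  X <- function(u) u - u0
  Y <- function(v) v1 - v
  num <- function(x) formatC(x, format = "fg", digits = 15, width = 1)

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%smm" height="%smm" viewBox="0 0 %s %s">',
      num(w), num(h), num(w), num(h)
    )
  )
  meas <- design$layout[!design$layout$is_reference, ]
  if (mode == "layout") {
    pts <- paste(sprintf("%s,%s", num(X(outline[, 1])), num(Y(outline[, 2]))), collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="none" stroke="black" stroke-width="0.5"/>', pts
    ))
    for (i in seq_len(nrow(model$muscles))) {
      m <- model$muscles[i, ]
      lines <- c(lines, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="grey" stroke-width="0.3" stroke-dasharray="2,2"/>',
        num(X(m$k1_u)), num(Y(m$k1_v)), num(X(m$k2_u)), num(Y(m$k2_v))
      ))
    }
    fill <- c(EMG = "#1b9e77", EDA = "#d95f02", ECG = "#7570b3")
    for (i in seq_len(nrow(meas))) {
      e <- meas[i, ]
      lines <- c(lines, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="0.75" stroke="black" stroke-width="0.2"/>',
        num(X(e$u)), num(Y(e$v)), num(e$radius), fill[[e$modality]]
      ))
      lines <- c(lines, sprintf(
        '<text x="%s" y="%s" font-size="3" text-anchor="middle">%s</text>',
        num(X(e$u)), num(Y(e$v) - e$radius - 1), e$electrode
      ))
    }
  } else {
    for (i in seq_len(nrow(meas))) {
      e <- meas[i, ]
      lines <- c(lines, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="black" stroke-width="0.3"/>',
        num(X(e$u)), num(Y(e$v)), num(e$radius)
      ))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
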