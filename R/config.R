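#' Design configuration
#'
#' Bundles what the sensor must measure and how the objective weighs each
#' modality. Any subset of EMG, EDA and ECG can be enabled; EMG additionally
#' selects individual muscles. Three objective schemes are supported:
#' `"weights"` (relative modality priorities w1..w3 summing to 1 plus an area
#' weight w4), `"bounds"` (per-modality cost ceilings enforced by exponential
#' penalties, modality weights off), and `"hybrid"` (both).
#'
#' @param modalities character subset of `c("EMG", "EDA", "ECG")`.
#' @param muscles muscles for EMG sensing, subset of
#'   `c("FCR", "BR", "PL", "PQ", "FCU")`. Ignored unless EMG is enabled.
#' @param weights named numeric `c(EMG=, EDA=, ECG=, area=)`. Defaults to
#'   equal priority over the enabled modalities and area weight 0 (size is
#'   then controlled by the search region, as in the sweep protocol).
#'   Disabled modalities must have weight 0; under the weight scheme the
#'   enabled modality weights must sum to 1.
#' @param alpha EMG-internal priority between orientation and
#'   inter-electrode distance, in \[0,1\] (default 0.5: equal priorities).
#' @param bounds optional named numeric of per-modality cost ceilings in
#'   \[0,1\] (e.g. `c(EMG = 0.1)`). Supplying bounds selects the bound or
#'   hybrid scheme.
#' @param softness penalty softness p >= 0 for bound violations; higher is
#'   harder enforcement.
#' @param scheme one of `"weights"`, `"bounds"`, `"hybrid"`; default is
#'   `"weights"` without bounds, `"hybrid"` with.
#' @return an object of class `design_config`.
#' @export
#' @examples
#' design_config("EMG", muscles = c("FCR", "BR", "PL"))
design_config <- function(modalities = c("EMG", "EDA", "ECG"),
                          muscles = MUSCLE_IDS,
                          weights = NULL,
                          alpha = 0.5,
                          bounds = NULL,
                          softness = 1,
                          scheme = NULL) {
  bad <- function(msg) rlang::abort(msg, class = "sensorlayout_config_error")
  modalities <- unique(toupper(modalities))
  if (length(modalities) == 0 || !all(modalities %in% c("EMG", "EDA", "ECG"))) {
    bad("modalities must be a non-empty subset of EMG, EDA, ECG")
  }
  if ("EMG" %in% modalities) {
    muscles <- unique(toupper(muscles))
    if (length(muscles) == 0 || !all(muscles %in% MUSCLE_IDS)) {
      bad(paste("with EMG enabled, muscles must be a non-empty subset of",
                paste(MUSCLE_IDS, collapse = ", ")))
    }
  } else {
    muscles <- character(0)
  }
  if (is.null(scheme)) scheme <- if (is.null(bounds)) "weights" else "hybrid"
  scheme <- match.arg(scheme, c("weights", "bounds", "hybrid"))

  if (is.null(weights)) {
    w <- c(EMG = 0, EDA = 0, ECG = 0, area = 0)
    if (scheme != "bounds") w[modalities] <- 1 / length(modalities)
  } else {
    if (is.null(names(weights))) {
      if (length(weights) != 4) bad("unnamed weights must be length 4 (EMG, EDA, ECG, area)")
      names(weights) <- c("EMG", "EDA", "ECG", "area")
    }
    w <- c(EMG = 0, EDA = 0, ECG = 0, area = 0)
    if (!all(names(weights) %in% names(w))) bad("weight names must be EMG, EDA, ECG, area")
    w[names(weights)] <- weights
  }
  if (any(w < 0)) bad("weights must be non-negative")
  if (any(w[setdiff(c("EMG", "EDA", "ECG"), modalities)] != 0)) {
    bad("disabled modalities must have weight 0")
  }
  if (scheme %in% c("weights", "hybrid")) {
    if (abs(sum(w[modalities]) - 1) > 1e-9) {
      bad("enabled modality weights must sum to 1 under the weight scheme")
    }
  } else {
    w[c("EMG", "EDA", "ECG")] <- 0  # bound-only: only area weight and penalties
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) bad("alpha must be in [0, 1]")
  if (!is.null(bounds)) {
    if (is.null(names(bounds)) || !all(names(bounds) %in% c("EMG", "EDA", "ECG"))) {
      bad("bounds must be named by modality")
    }
    if (any(bounds < 0 | bounds > 1)) bad("bounds must be in [0, 1]")
    if (!all(names(bounds) %in% modalities)) bad("bounds refer to disabled modalities")
  }
  if (!is.numeric(softness) || softness < 0) bad("softness must be >= 0")
  structure(
    list(
      modalities = modalities, muscles = muscles, weights = w, alpha = alpha,
      bounds = bounds, softness = softness, scheme = scheme
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>", x$scheme, "scheme;",
      paste(x$modalities, collapse = "+"), "\n")
  if (length(x$muscles)) cat("  muscles:", paste(x$muscles, collapse = ", "), "\n")
  cat("  weights:", paste(sprintf("%s=%g", names(x$weights), x$weights), collapse = " "), "\n")
  if (!is.null(x$bounds)) {
    cat("  bounds:", paste(sprintf("%s<=%g", names(x$bounds), x$bounds), collapse = " "),
        sprintf("(softness %g)\n", x$softness))
  }
  invisible(x)
}

#' Electrode radius for a modality
#'
#' EMG and ECG electrodes have 50 mm^2 sensing area (radius sqrt(50/pi)
#' ~ 3.989 mm); EDA electrodes have 0.785 cm^2 (radius 5.0 mm).
#'
#' @param modality "EMG", "EDA" or "ECG".
#' @return radius in mm.
#' @export
electrode_radius <- function(modality) {
  unname(c(EMG = sqrt(50 / pi), EDA = 5.0, ECG = sqrt(50 / pi))[modality])
}

#' Measurement-electrode roster for a configuration
#'
#' One row per measurement electrode: two per selected muscle (members A/B),
#' two for EDA and two for ECG when enabled. Reference electrodes (one common
#' EMG reference, one for ECG, none for EDA) sit away from the forearm and
#' are not part of the placed layout; see [reference_electrode_count()].
#'
#' @param config a [design_config()].
#' @return tibble with columns `electrode`, `modality`, `muscle`, `member`,
#'   `radius` (mm), in canonical order.
#' @export
layout_roster <- function(config) {
  rows <- list()
  if ("EMG" %in% config$modalities) {
    rows$emg <- tibble::tibble(
      modality = "EMG",
      muscle = rep(config$muscles, each = 2),
      member = rep(c("A", "B"), length(config$muscles))
    )
  }
  if ("EDA" %in% config$modalities) {
    rows$eda <- tibble::tibble(modality = "EDA", muscle = NA_character_, member = c("A", "B"))
  }
  if ("ECG" %in% config$modalities) {
    rows$ecg <- tibble::tibble(modality = "ECG", muscle = NA_character_, member = c("A", "B"))
  }
  roster <- dplyr::bind_rows(rows)
  roster$electrode <- ifelse(
    is.na(roster$muscle),
    paste(roster$modality, roster$member, sep = "_"),
    paste(roster$modality, roster$muscle, roster$member, sep = "_")
  )
  roster$radius <- electrode_radius(roster$modality)
  roster[, c("electrode", "modality", "muscle", "member", "radius")]
}

#' Number of off-forearm reference electrodes required
#'
#' At most two are ever needed: one common reference for EMG and one for
#' ECG, both placed away from the forearm (EDA needs none).
#'
#' @param config a [design_config()].
#' @return integer count (0, 1 or 2).
#' @export
reference_electrode_count <- function(config) {
  sum(c("EMG", "ECG") %in% config$modalities)
}
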