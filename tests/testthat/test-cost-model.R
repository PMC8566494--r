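# Cost model: the printed EMG curves, EDA gland coverage, ECG scores,
# area ratio, penalties, and the global objective.

test_that("EMG orientation cost matches the printed polynomial", {
  # hand-evaluated: 0.0057*t + 0.000181*t^2 below 60 degrees, 1 above
  expect_equal(emg_orientation_cost(0), 0)
  expect_equal(emg_orientation_cost(10), 0.057 + 0.0181, tolerance = 1e-12)
  expect_equal(emg_orientation_cost(20), 0.114 + 0.0724, tolerance = 1e-12)
  expect_equal(emg_orientation_cost(30), 0.3339, tolerance = 1e-12)
  expect_equal(emg_orientation_cost(45), 0.2565 + 0.3665250, tolerance = 1e-12)
  expect_equal(emg_orientation_cost(60), 0.342 + 0.6516, tolerance = 1e-12)
  expect_equal(emg_orientation_cost(60.0001), 1)
  expect_equal(emg_orientation_cost(75), 1)
  expect_equal(emg_orientation_cost(90), 1)
  expect_error(emg_orientation_cost(-1), class = "sensorlayout_domain_error")
  expect_error(emg_orientation_cost(91), class = "sensorlayout_domain_error")
  # nondecreasing on [0, 60]
  th <- seq(0, 60, by = 0.5)
  expect_true(all(diff(emg_orientation_cost(th)) >= 0))
})

test_that("EMG distance cost matches the printed piecewise curve", {
  expect_equal(emg_distance_cost(10), 1.0125 - 0.586 + 0.07, tolerance = 1e-12)
  expect_equal(emg_distance_cost(15), max(0, 1.0125 - 0.879 + 0.1575), tolerance = 1e-12)
  expect_equal(emg_distance_cost(20), max(0, 1.0125 - 1.172 + 0.28), tolerance = 1e-12)
  expect_equal(emg_distance_cost(25), 0)   # max(0, -0.015) at the breakpoint
  expect_equal(emg_distance_cost(30), 0)
  expect_equal(emg_distance_cost(40), 0)
  expect_equal(emg_distance_cost(60), 0)
  expect_equal(emg_distance_cost(60.001), 1)
  expect_equal(emg_distance_cost(70), 1)
  expect_equal(emg_distance_cost(5), 1)    # undefined region scored worst
  expect_equal(emg_distance_cost(2), 1)
  expect_error(emg_distance_cost(0), class = "sensorlayout_domain_error")
  expect_error(emg_distance_cost(-3), class = "sensorlayout_domain_error")
  # nonincreasing on (5, 25], continuous at 25
  d <- seq(5.01, 25, by = 0.1)
  expect_true(all(diff(emg_distance_cost(d)) <= 1e-12))
  expect_lt(abs(emg_distance_cost(25 - 1e-9) - emg_distance_cost(25 + 1e-9)), 1e-6)
})

test_that("EMG pair cost applies pre-checks then the weighted curve average", {
  model <- toy_model()
  pl <- model$muscles[model$muscles$muscle == "PL", ]  # vertical line u=0, v 75..110
  # aligned pair, d = 30, clear of the IZ: both terms zero
  expect_equal(emg_muscle_cost(c(0, 76), c(0, 106), pl), 0)
  # one electrode 15 mm off the muscle line scores worst
  expect_equal(emg_muscle_cost(c(0, 76), c(15, 90), pl), 1)
  # electrode disk overlapping the innervation zone scores worst
  expect_equal(emg_muscle_cost(c(0, 92.5), c(0, 76), pl), 1)
  # theta = 30 degrees, d = 10 mm: 0.5*0.3339 + 0.5*0.4965
  e1 <- c(0, 76); e2 <- c(10 * sin(pi / 6), 76 + 10 * cos(pi / 6))
  expect_equal(emg_muscle_cost(e1, e2, pl), 0.5 * 0.3339 + 0.5 * 0.4965, tolerance = 1e-9)
  # symmetric in the two electrodes
  expect_equal(emg_muscle_cost(e1, e2, pl), emg_muscle_cost(e2, e1, pl))
})

test_that("overall EMG score is the unweighted mean over selected muscles", {
  model <- demo_model()
  cfg <- design_config("EMG", muscles = c("FCR", "BR", "PL"))
  bl <- build_baseline_layout(model, cfg)
  res <- emg_cost(bl, model, cfg$muscles)
  expect_equal(unname(res$O1), mean(res$per_muscle))
  expect_equal(unname(res$O1), 0)
  # degrading one pair moves the mean by exactly 1/m
  bad <- bl
  bad$u[bad$electrode == "EMG_FCR_A"] <- bad$u[bad$electrode == "EMG_FCR_A"] + 20
  res_bad <- emg_cost(bad, model, cfg$muscles)
  expect_equal(unname(res_bad$O1), 1 / 3)
  expect_error(emg_cost(bl, model, character(0)), class = "sensorlayout_config_error")
})

test_that("EDA gland coverage follows N_s = (pi r^2 + 2 r d) D_s", {
  expect_equal(round(eda_gland_count(60, 5, 1.08)), 733)
  expect_equal(eda_gland_count(0, 5, 1.08), pi * 25 * 1.08)
  expect_equal(eda_gland_count(30, 5, 1.08), (pi * 25 + 300) * 1.08)
  expect_error(eda_gland_count(-1, 5, 1.08), class = "sensorlayout_domain_error")
  expect_error(eda_gland_count(10, 0, 1.08), class = "sensorlayout_domain_error")
})

test_that("EDA cost is 0 at the recommended distance and decreasing below it", {
  expect_equal(eda_cost(60, 1.08), 0)
  expect_equal(eda_cost(61, 1.08), 1)         # beyond the recommended distance
  expect_equal(eda_cost(3, 1.08), 1)          # under 140 glands
  n30 <- eda_gland_count(30, 5, 1.08)
  n60 <- eda_gland_count(60, 5, 1.08)
  expect_equal(eda_cost(30, 1.08), 1 - n30 / n60, tolerance = 1e-12)
  expect_equal(eda_cost(30, 1.08), 0.442, tolerance = 5e-4)
  d <- seq(8, 60, by = 1)
  expect_true(all(diff(eda_cost(d, 1.08)) < 0))
})

test_that("ECG cost reproduces the printed keypoint scores", {
  model <- demo_model()
  upper <- model$ecg_pairs[model$ecg_pairs$pair == "upper", ]
  wrist <- model$ecg_pairs[model$ecg_pairs$pair == "wrist", ]
  expect_equal(ecg_cost(c(upper$k1_u, upper$k1_v), c(upper$k2_u, upper$k2_v), model), 0)
  expect_equal(ecg_cost(c(wrist$k1_u, wrist$k1_v), c(wrist$k2_u, wrist$k2_v), model), 0.75)
  # pair far from every candidate keypoint: beyond the capture radius
  expect_equal(ecg_cost(c(0, 125), c(0, 113), model), 1)
  # matching is invariant to electrode order
  expect_equal(
    ecg_cost(c(upper$k2_u, upper$k2_v), c(upper$k1_u, upper$k1_v), model), 0
  )
  no_ecg <- model
  no_ecg$ecg_pairs <- model$ecg_pairs[0, ]
  expect_error(ecg_cost(c(0, 0), c(1, 1), no_ecg), class = "sensorlayout_config_error")
})

test_that("baseline layouts have the stated electrode counts and zero cost", {
  model <- demo_model()
  full <- design_config()
  bl_full <- build_baseline_layout(model, full)
  expect_equal(nrow(bl_full), 14)     # 5 muscles x 2 + EDA 2 + ECG 2
  uni <- design_config("EMG", muscles = c("FCR", "BR", "PL"))
  bl_uni <- build_baseline_layout(model, uni)
  expect_equal(nrow(bl_uni), 6)
  expect_lte(reference_electrode_count(full), 2)
  expect_equal(reference_electrode_count(uni), 1)
  expect_equal(reference_electrode_count(design_config("EDA")), 0)
  cost <- score_layout(bl_full, model, full)
  expect_equal(cost$modality_aggregate, 0)
  expect_equal(cost$quality, 1)       # predicted quality 1.0 for the baseline
  expect_equal(cost$O4, 1)            # its own hull normalizes the area term
  # partition into per-modality subsets is disjoint and exhaustive
  expect_equal(anyDuplicated(bl_full$electrode), 0)
  expect_equal(sum(bl_full$modality == "EMG"), 10)
  expect_equal(sum(bl_full$modality == "EDA"), 2)
  expect_equal(sum(bl_full$modality == "ECG"), 2)
})

test_that("area cost is the hull ratio with a degenerate-hull convention", {
  mk <- function(side) {
    tibble::tibble(
      electrode = paste0("e", 1:4), modality = "EMG", muscle = "FCR",
      member = c("A", "B", "A", "B"), radius = electrode_radius("EMG"),
      u = c(0, side, side, 0), v = c(0, 0, side, side), is_reference = FALSE
    )
  }
  expect_equal(area_cost(mk(20), baseline_area = 400), 1)
  expect_equal(area_cost(mk(20 / sqrt(2)), baseline_area = 400), 0.5)
  two <- mk(20)[1:2, ]
  expect_warning(o4 <- area_cost(two, baseline_area = 400), "degenerate")
  expect_equal(o4, 0)
  expect_error(area_cost(mk(20), baseline_area = 0), class = "sensorlayout_domain_error")
})

test_that("lower-bound penalties are exponential in the violation", {
  expect_equal(lower_bound_penalty(0.2, 0.3, softness = 2), 0)
  expect_equal(lower_bound_penalty(0.5, 0.3, softness = 0), 0)
  expect_equal(lower_bound_penalty(0.4, 0.3, softness = 1), exp(0.1) - 1, tolerance = 1e-12)
  expect_equal(lower_bound_penalty(0.8, 0.3, softness = 2), 2 * (exp(0.5) - 1), tolerance = 1e-12)
})

test_that("global objective is the weighted sum plus penalties, per scheme", {
  model <- demo_model()
  # single modality reduces to its own cost
  uni <- design_config("EMG", muscles = c("FCR", "BR", "PL"))
  bl <- build_baseline_layout(model, uni)
  bad <- bl
  bad$u[1] <- bad$u[1] + 25  # push FCR_A off its line
  cost <- score_layout(bad, model, uni)
  expect_equal(cost$objective, cost$O1)
  expect_equal(cost$O1, 1 / 3)
  # weighted scheme: objective == w . O + penalties on random valid layouts
  full <- design_config(weights = c(EMG = 0.5, EDA = 0.3, ECG = 0.2, area = 0.1))
  for (s in 1:5) {
    lay <- random_initial_layout(model, full, anneal_config(seed = s))
    cb <- score_layout(lay, model, full)
    expect_equal(
      cb$objective,
      0.5 * cb$O1 + 0.3 * cb$O2 + 0.2 * cb$O3 + 0.1 * cb$O4 + sum(cb$penalties)
    )
    expect_true(all(c(cb$O1, cb$O2, cb$O3) >= 0 & c(cb$O1, cb$O2, cb$O3) <= 1))
    expect_equal(
      cb$modality_aggregate, 0.5 * cb$O1 + 0.3 * cb$O2 + 0.2 * cb$O3
    )
    expect_equal(cb$quality, 1 - cb$modality_aggregate)
  }
  # bound-only scheme: modality weights off, objective = w4*O4 once bounds hold
  bounded <- design_config(
    weights = c(EMG = 0, EDA = 0, ECG = 0, area = 1),
    bounds = c(EMG = 1, EDA = 1, ECG = 1), softness = 5, scheme = "bounds"
  )
  blf <- build_baseline_layout(model, bounded)
  cbb <- score_layout(blf, model, bounded)
  expect_equal(sum(cbb$penalties), 0)
  expect_equal(cbb$objective, cbb$O4)
  # hybrid: violated ceiling adds p*(exp(excess)-1)
  tight <- design_config(bounds = c(EMG = 0), softness = 2)
  lay <- random_initial_layout(model, tight, anneal_config(seed = 9))
  cbt <- score_layout(lay, model, tight)
  expect_equal(unname(cbt$penalties["EMG"]), 2 * (exp(max(cbt$O1, 0)) - 1), tolerance = 1e-12)
  # weight-scheme weights must sum to 1 over the enabled modalities
  expect_error(
    design_config(weights = c(EMG = 0.5, EDA = 0.2, ECG = 0.2, area = 0)),
    class = "sensorlayout_config_error"
  )
})

test_that("muscle order does not change the EMG aggregate", {
  model <- demo_model()
  cfg1 <- design_config("EMG", muscles = c("FCR", "BR", "PL"))
  cfg2 <- design_config("EMG", muscles = c("PL", "FCR", "BR"))
  lay <- random_initial_layout(model, cfg1, anneal_config(seed = 4))
  o1 <- emg_cost(lay, model, cfg1$muscles)$O1
  o2 <- emg_cost(lay, model, cfg2$muscles)$O1
  expect_equal(o1, o2)
})
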