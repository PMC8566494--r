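# Optimizer: constraint validation, initialization, proposals, acceptance,
# and the annealer against an exhaustive-grid oracle on a toy instance.

test_that("layout validation flags spacing and containment violations", {
  model <- demo_model()
  cfg <- design_config("EMG", muscles = "FCR")
  bl <- build_baseline_layout(model, cfg)
  expect_true(validate_layout(bl, model)$valid)
  # two electrodes 11 mm apart violate the 12 mm rule
  close <- bl
  close$u <- c(0, 11); close$v <- c(100, 100)
  v <- validate_layout(close, model)
  expect_false(v$valid)
  expect_true("spacing" %in% v$violations$type)
  # centre outside the sketched shape violates containment
  shape <- rbind(c(-20, 0), c(20, 0), c(20, 50), c(-20, 50))
  out <- bl
  out$u <- c(0, 0); out$v <- c(20, 80)  # second centre beyond the shape
  v2 <- validate_layout(out, model, shape = shape)
  expect_false(v2$valid)
  expect_true("containment" %in% v2$violations$type)
  expect_equal(nrow(v2$violations), 1)
})

test_that("random initial layouts are valid, seed-deterministic, and fail on tiny regions", {
  model <- demo_model()
  cfg <- design_config()  # 14 electrodes
  lay1 <- random_initial_layout(model, cfg, anneal_config(seed = 5))
  expect_true(validate_layout(lay1, model)$valid)
  lay2 <- random_initial_layout(model, cfg, anneal_config(seed = 5))
  expect_identical(lay1, lay2)
  lay3 <- random_initial_layout(model, cfg, anneal_config(seed = 6))
  expect_false(identical(lay1$u, lay3$u))
  # a 20 x 20 mm box cannot hold 14 electrodes at >= 12 mm spacing
  tiny <- rbind(c(-10, 0), c(10, 0), c(10, 20), c(-10, 20))
  expect_error(
    random_initial_layout(model, cfg, anneal_config(seed = 1), shape = tiny),
    class = "sensorlayout_infeasible_region"
  )
})

test_that("neighbour proposals move exactly one electrode, uniformly chosen", {
  model <- demo_model()
  cfg <- design_config()
  lay <- random_initial_layout(model, cfg, anneal_config(seed = 2))
  set.seed(11)
  for (i in 1:20) {
    prop <- propose_neighbor(lay, step = 10)
    moved <- which(prop$u != lay$u | prop$v != lay$v)
    expect_length(moved, 1)
    d <- sqrt((prop$u[moved] - lay$u[moved])^2 + (prop$v[moved] - lay$v[moved])^2)
    expect_lte(d, 10)
  }
  # electrode choice is uniform: chi-squared over 10,000 draws
  set.seed(12)
  n <- nrow(lay)
  counts <- integer(n)
  for (i in 1:10000) {
    prop <- propose_neighbor(lay, step = 5)
    moved <- which(prop$u != lay$u | prop$v != lay$v)
    counts[moved] <- counts[moved] + 1L
  }
  chisq <- sum((counts - 10000 / n)^2 / (10000 / n))
  expect_lt(chisq, qchisq(0.999, df = n - 1))
  # zero step leaves the layout unchanged
  expect_equal(propose_neighbor(lay, step = 0)[, c("u", "v")], lay[, c("u", "v")])
})

test_that("acceptance follows the Metropolis rule", {
  set.seed(21)
  expect_true(accept_move(-0.1, t = 0.5))       # improvements always accepted
  expect_true(accept_move(0, t = 0.5))          # threshold exactly 1
  expect_error(accept_move(0.1, t = 0), class = "sensorlayout_domain_error")
  # empirical acceptance frequency matches exp(-delta/T)
  set.seed(22)
  acc <- accept_move(rep(0.2, 1e5), t = 0.1)
  expect_equal(mean(acc), exp(-2), tolerance = 0.005 / exp(-2))
})

test_that("annealing matches the exhaustive-grid optimum on the toy muscle", {
  model <- toy_model()
  cfg <- design_config("EMG", muscles = "PL")
  region <- rbind(c(-20, 55), c(20, 55), c(20, 130), c(-20, 130))
  grid_opt <- grid_pair_optimum(model, "PL", region, spacing_mm = 2)
  expect_equal(grid_opt, 0)  # aligned pair at 25 < d <= 60 is grid-attainable
  d <- anneal(model, cfg, anneal_config(candidates = 4000, seed = 31), shape = region)
  expect_true(validate_layout(d$layout, model, shape = region)$valid)
  expect_gte(d$cost$objective, grid_opt - 1e-9)
  expect_lte(d$cost$objective, grid_opt + 0.05)
})

test_that("annealing is deterministic and returns the best layout seen", {
  model <- demo_model()
  cfg <- design_config("EMG", muscles = c("FCR", "PL"))
  opt <- anneal_config(candidates = 1500, seed = 8)
  d1 <- anneal(model, cfg, opt)
  d2 <- anneal(model, cfg, opt)
  expect_identical(d1$layout, d2$layout)
  expect_identical(d1$cost$objective, d2$cost$objective)
  expect_true(validate_layout(d1$layout, model)$valid)
  # best-so-far trace is monotonically non-increasing
  expect_true(all(diff(d1$trace) <= 1e-12))
  # near-greedy mode (tiny T0) still only improves
  dg <- anneal(model, cfg, anneal_config(candidates = 1500, seed = 8, t0 = 1e-9))
  expect_true(all(diff(dg$trace) <= 1e-12))
})
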