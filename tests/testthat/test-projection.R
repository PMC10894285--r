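# 1 x 12 strip with one 10-cell property flanked by public land
strip_fixture <- function(lr = 0.2, native = NULL) {
  id <- matrix(c(0L, rep(1L, 10L), 0L), 1, 12)
  props <- manual_property_map(id, cell_area = 100, lr_fraction = lr)
  if (is.null(native)) native <- matrix(1L, 1, 12)
  list(props = props, state = landscape_state(native, 2016),
       constraints = constraint_set(properties = props))
}

test_that("convertibility honours protection and the Legal Reserve floor", {
  fx <- strip_fixture()
  # 10-cell property, lr 0.2: floor 2 cells; all 10 native -> convertible
  conv <- convertible_mask(fx$state, fx$constraints)
  expect_true(all(conv[fx$props$id == 1L]))

  # 7 native out of 10 still exceeds the 2-cell floor
  native7 <- matrix(1L, 1, 12)
  native7[1, 2:4] <- 0L
  conv7 <- convertible_mask(landscape_state(native7, 2016), fx$constraints)
  expect_true(all(conv7[fx$props$id == 1L & native7 == 1L]))

  # exactly at the floor: the whole property freezes
  native2 <- matrix(0L, 1, 12)
  native2[1, c(2L, 3L)] <- 1L   # 2 native = 0.2 * 10
  native2[1, c(1L, 12L)] <- 1L  # public cells stay native
  conv2 <- convertible_mask(landscape_state(native2, 2016), fx$constraints)
  expect_false(any(conv2[fx$props$id == 1L]))
  # public native cells remain convertible (no floor)
  expect_true(all(conv2[fx$props$id == 0L & native2 == 1L]))

  # protected cells are never convertible
  prot <- matrix(0L, 1, 12); prot[1, 6] <- 1L
  cons_pa <- constraint_set(properties = fx$props, protected_mask = prot)
  convp <- convertible_mask(fx$state, cons_pa)
  expect_false(convp[1, 6])
  # ... unless the hard mask is switched off
  cons_soft <- constraint_set(properties = fx$props, protected_mask = prot,
                              enforce_pa = FALSE)
  expect_true(convertible_mask(fx$state, cons_soft)[1, 6])
})

test_that("a simulation step saturates, cancels at the floor, and is reproducible", {
  fx <- strip_fixture()
  stack <- flat_stack(1, 12)

  # k = -50: nothing converts
  set.seed(1)
  s_none <- simulate_step(fx$state, stack, coef_vector(-50), fx$constraints)
  expect_identical(s_none$native, fx$state$native)
  expect_identical(s_none$time, 2018L)

  # k = +50: conversion saturates but the exact floor (2 cells) survives
  set.seed(2)
  s_all <- simulate_step(fx$state, stack, coef_vector(50), fx$constraints)
  expect_identical(sum(s_all$native[fx$props$id == 1L]), 2L)
  expect_identical(sum(s_all$native[fx$props$id == 0L]), 0L)  # public gone

  # property with exactly one cell above the floor: that cell converts,
  # then the property freezes
  native3 <- matrix(0L, 1, 12)
  native3[1, 2:4] <- 1L   # 3 native, floor 2
  st3 <- landscape_state(native3, 2016)
  set.seed(3)
  s3 <- simulate_step(st3, stack, coef_vector(50), fx$constraints)
  expect_identical(sum(s3$native), 2L)
  set.seed(4)
  s3b <- simulate_step(s3, stack, coef_vector(50), fx$constraints)
  expect_identical(s3b$native, s3$native)

  # same seed, same successor
  set.seed(99); a <- simulate_step(fx$state, stack, coef_vector(0), fx$constraints)
  set.seed(99); b <- simulate_step(fx$state, stack, coef_vector(0), fx$constraints)
  expect_identical(a, b)
})

test_that("accumulated probabilities are iteration counts on the 1/n lattice", {
  fx <- strip_fixture()
  stack <- flat_stack(1, 12)
  post <- const_posterior(coef_vector(qlogis(0.3)))
  pr <- run_projection(fx$state, stack, post, fx$constraints,
                       horizon_year = 2030, n_iterations = 50L, seed = 5L)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_true(all(abs(pr$prob * 50 - round(pr$prob * 50)) < 1e-9))
  # cellwise monotone in the horizon year
  expect_true(all(apply(pr$prob, 1L, function(x) all(diff(x) >= 0))))

  # single iteration: probabilities are the binary trajectory
  pr1 <- run_projection(fx$state, stack, post, fx$constraints,
                        horizon_year = 2030, n_iterations = 1L, seed = 6L)
  expect_true(all(pr1$prob %in% c(0, 1)))

  expect_error(run_projection(fx$state, stack, post, fx$constraints,
                              horizon_year = 2031),
               "multiple of 2|%% 2")
})

test_that("three-cell projection matches the exhaustive absorbing-chain oracle", {
  # one 3-cell property, lr 1/3 -> floor 1 cell; intercept-only model
  id <- matrix(1L, 1, 3)
  props <- manual_property_map(id, cell_area = 100, lr_fraction = 1 / 3)
  cons <- constraint_set(properties = props)
  state <- landscape_state(matrix(1L, 1, 3), 2016)
  stack <- flat_stack(1, 3)
  p <- 0.22
  horizon <- 2050
  n_steps <- (horizon - 2016) / 2

  # exact chain on native counts {3, 2, 1}: at n native, the n cells are
  # convertible while n > 1; conversions beyond n - 1 are cancelled
  dist <- c(`3` = 1, `2` = 0, `1` = 0)
  for (s in seq_len(n_steps)) {
    d3 <- dist[["3"]]; d2 <- dist[["2"]]
    p3_stay <- dbinom(0, 3, p)
    p3_to2 <- dbinom(1, 3, p)
    p3_to1 <- 1 - p3_stay - p3_to2          # 2 or 3 draws, capped at 2
    p2_stay <- dbinom(0, 2, p)
    p2_to1 <- 1 - p2_stay                   # 1 or 2 draws, capped at 1
    dist <- c(`3` = d3 * p3_stay,
              `2` = d3 * p3_to2 + d2 * p2_stay,
              `1` = d3 * p3_to1 + d2 * p2_to1 + dist[["1"]])
  }
  expected_native <- sum(as.numeric(names(dist)) * dist)
  exact_cell_prob <- (3 - expected_native) / 3

  n_iter <- 10000L
  pr <- run_projection(state, stack, const_posterior(coef_vector(qlogis(p))),
                       cons, horizon, n_iterations = n_iter, seed = 7L)
  mc <- mean(pr$prob[, n_steps])
  se <- sd(pr$iter_total[, n_steps] / (3 * 100)) / sqrt(n_iter)
  expect_lt(abs(mc - exact_cell_prob), 3 * se)
})

test_that("projection with the generating model reproduces the generator's rate", {
  cfg <- synth_config(grid_rows = 64, grid_cols = 64, n_periods = 1L,
                      intercept = -3, seed = 31L)
  ds <- synth_dataset(cfg)
  gen_frac <- 1 - sum(ds$observed_states[[1L]]$native) / (64 * 64)
  post <- const_posterior(ds$truth)
  cons <- constraint_set(properties = ds$properties, enforce_pa = FALSE,
                         enforce_lr = FALSE)
  pr <- run_projection(ds$initial_state, ds$drivers, post, cons,
                       horizon_year = cfg$start_year + 2L,
                       n_iterations = 100L, seed = 8L)
  proj_frac <- mean(pr$iter_total[, 1L]) / (64 * 64 * 100)
  n <- 64 * 64
  expect_lt(abs(proj_frac - gen_frac), 3 * sqrt(gen_frac * (1 - gen_frac) / n))
})

test_that("audits, ensembles and grouped ledgers are mutually consistent", {
  ds <- small_dataset()
  post <- small_posterior()
  cons <- constraint_set(properties = ds$properties)
  final <- ds$observed_states[[length(ds$observed_states)]]
  pr <- run_projection(final, ds$drivers, post, cons, 2030,
                       n_iterations = 30L, seed = 9L)

  expect_identical(lr_audit(pr), 0L)
  expect_identical(pa_audit(pr), 0L)

  # ensemble of identical members is the identity on probabilities
  ens <- ensemble(list(pr, pr, pr, pr))
  expect_equal(ens$prob, pr$prob)
  expect_identical(ens$label, "ensemble")
  # mixture semantics: {0,0,0,1} at a cell averages to 0.25
  fake <- pr
  fake$prob[] <- 0
  fake$prob[1L, ] <- 1
  mix <- ensemble(list(pr, pr, pr, fake))
  expect_equal(mix$prob[1L, ], (3 * pr$prob[1L, ] + 1) / 4)
  expect_equal(mix$prob[-1L, ], 0.75 * pr$prob[-1L, ])
  # ensemble of ensembles with equal weights equals the flat mean
  e1 <- ensemble(list(pr, fake))
  e2 <- ensemble(list(pr, fake))
  expect_equal(ensemble(list(e1, e2))$prob, e1$prob)

  expect_error(ensemble(list(pr, run_projection(final, ds$drivers, post,
                                                cons, 2024,
                                                n_iterations = 2L,
                                                seed = 1L))),
               "share the grid and horizon")

  # grouped ledgers conserve the total under both partitions
  year <- 2030
  tot <- total_loss(pr, year)$mean
  by_class <- loss_summary(pr, "class", year)
  by_region <- loss_summary(pr, "region", year)
  by_prop <- loss_summary(pr, "property", year)
  expect_equal(sum(by_class$loss_ha), tot, tolerance = 1e-9)
  expect_equal(sum(by_region$loss_ha), tot, tolerance = 1e-9)
  expect_equal(sum(by_prop$loss_ha), tot, tolerance = 1e-9)

  # arithmetic contract of the expectation
  fxp <- strip_fixture()
  zero <- run_projection(fxp$state, flat_stack(1, 12),
                         const_posterior(coef_vector(-50)), fxp$constraints,
                         2020, n_iterations = 10L, seed = 2L)
  expect_true(all(loss_summary(zero, "class", 2020)$loss_ha == 0))
})

test_that("expected grouped loss follows probability times area", {
  # 5 cells at probability 1 and 100 ha cells -> 500 ha in the property
  id <- matrix(1L, 1, 5)
  props <- manual_property_map(id, cell_area = 100, lr_fraction = 0.2)
  cons <- constraint_set(properties = props, enforce_lr = FALSE)
  state <- landscape_state(matrix(1L, 1, 5), 2016)
  pr <- run_projection(state, flat_stack(1, 5),
                       const_posterior(coef_vector(50)), cons, 2018,
                       n_iterations = 20L, seed = 3L)
  expect_equal(sum(prob_raster(pr, 2018)), 5)
  expect_equal(loss_summary(pr, "property", 2018)$loss_ha[1L], 500)
})
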