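test_that("property classification matches the bracket definitions exactly", {
  expect_identical(classify_property(150), "C1")
  expect_identical(classify_property(150.01), "C2")
  expect_identical(classify_property(400), "C2")
  expect_identical(classify_property(1000), "C3")
  expect_identical(classify_property(2500), "C4")
  expect_identical(classify_property(2500.01), "C5")
  expect_error(classify_property(0.5), "outside")

  # every area in [1, 10^4] maps to exactly one class
  areas <- seq(1, 1e4, by = 0.01)
  cls <- classify_property(areas)
  expect_false(anyNA(cls))
  expect_setequal(unique(cls), c("C1", "C2", "C3", "C4", "C5"))
  # boundaries are the only places the class changes
  changes <- areas[which(cls[-1] != cls[-length(cls)])]
  expect_equal(changes, c(150, 400, 1000, 2500))
})

test_that("the large-property rule freezes the configured share on top of the Legal Reserve", {
  # one 30-cell (3000 ha) property, lr 0.20, rule 30% additive -> 50% kept
  id <- matrix(1L, 5, 6)
  props <- manual_property_map(id, cell_area = 100, lr_fraction = 0.2)
  cons <- constraint_set(properties = props)
  state <- landscape_state(matrix(1L, 5, 6), 2016)
  scen <- scenario_config("protect30",
                          large_property_rule = list(threshold_ha = 2500,
                                                     protected_fraction = 0.3))
  sc <- apply_scenario(cons, props, scen, state, seed = 1L)
  expect_identical(sum(sc$frozen_mask), 9L)   # 0.3 * 30 cells
  expect_equal(sc$properties$table$extra_protected_fraction, 0.3)

  # saturated conversion: floor 6 + frozen 9 = 15 cells = 50% survive
  stack <- flat_stack(5, 6)
  st <- state
  set.seed(2)
  for (i in 1:6) st <- simulate_step(st, stack, coef_vector(50), sc)
  expect_identical(sum(st$native), 15L)

  # max-mode freezes only up to max(lr, rule)
  scen_max <- scenario_config("protect30max",
                              large_property_rule = list(
                                threshold_ha = 2500,
                                protected_fraction = 0.3, mode = "max"))
  sc_max <- apply_scenario(cons, props, scen_max, state, seed = 1L)
  expect_identical(sum(sc_max$frozen_mask), 3L)  # (0.3 - 0.2) * 30
  st <- state
  set.seed(3)
  for (i in 1:6) st <- simulate_step(st, stack, coef_vector(50), sc_max)
  expect_identical(sum(st$native), 9L)           # 30% of 30 cells

  # a threshold above every property leaves the constraints untouched
  scen_hi <- scenario_config("none",
                             large_property_rule = list(threshold_ha = 5000,
                                                        protected_fraction = 0.3))
  sc_hi <- apply_scenario(cons, props, scen_hi, state, seed = 1L)
  expect_identical(sum(sc_hi$frozen_mask), 0L)
  expect_equal(sc_hi$properties$table$lr_fraction,
               props$table$lr_fraction)
})

test_that("scenarios only ever add protection and prefer intact neighbourhoods", {
  ds <- small_dataset()
  state <- ds$observed_states[[length(ds$observed_states)]]
  cons <- constraint_set(properties = ds$properties)
  scen <- scenario_config("protect30",
                          large_property_rule = list(threshold_ha = 2500,
                                                     protected_fraction = 0.3))
  sc <- apply_scenario(cons, ds$properties, scen, state, seed = 4L)
  expect_true(all(sc$properties$table$lr_fraction >=
                    ds$properties$table$lr_fraction))
  expect_gt(sum(sc$frozen_mask), 0)
  # frozen cells are native and sit in qualifying properties
  frozen_cells <- which(sc$frozen_mask == 1L)
  expect_true(all(state$native[frozen_cells] == 1L))
  qual <- ds$properties$table$property_id[ds$properties$table$area_ha > 2500]
  expect_true(all(ds$properties$id[frozen_cells] %in% qual))

  # Legal Reserve overrides: lr = 1 freezes a whole region
  scen_lr <- scenario_config("full_lr", lr_overrides = c(cerrado = 1.0))
  sc_lr <- apply_scenario(cons, ds$properties, scen_lr, state, seed = 5L)
  reg_props <- sc_lr$properties$table$property_id[
    sc_lr$properties$table$region == "cerrado"]
  conv <- convertible_mask(state, sc_lr)
  in_region <- ds$properties$id %in% reg_props
  expect_false(any(conv[in_region]))
})

test_that("avoided loss is zero against itself and dominated under paired seeds", {
  ds <- small_dataset()
  post <- small_posterior()
  final <- ds$observed_states[[length(ds$observed_states)]]
  cons <- constraint_set(properties = ds$properties)
  bau <- run_projection(final, ds$drivers, post, cons, 2030,
                        n_iterations = 25L, seed = 11L)

  a0 <- avoided_loss(bau, bau, 2030)
  expect_identical(a0$ha, 0)
  expect_identical(a0$percent_of_bau, 0)
  expect_false(a0$inconsistent)

  scen <- scenario_config("protect30",
                          large_property_rule = list(threshold_ha = 2500,
                                                     protected_fraction = 0.3))
  sc <- apply_scenario(cons, ds$properties, scen, final, seed = 6L)
  scr <- run_projection(final, ds$drivers, post, sc, 2030,
                        n_iterations = 25L, seed = 11L)
  av <- avoided_loss(bau, scr, 2030)
  expect_gt(av$ha, 0)
  expect_false(av$inconsistent)
  expect_equal(av$percent_of_bau, round(100 * av$ha / total_loss(bau, 2030)$mean, 1))
  # with paired seeds, the scenario never loses more, property by property
  expect_true(all(scr$prop_loss <= bau$prop_loss + 1e-9))
})

test_that("paired-seed runs are cellwise dominated when constraints only freeze cells", {
  ds <- small_dataset()
  post <- small_posterior()
  final <- ds$observed_states[[length(ds$observed_states)]]
  cons <- constraint_set(properties = ds$properties, enforce_lr = FALSE)
  scen <- scenario_config("protect30",
                          large_property_rule = list(threshold_ha = 2500,
                                                     protected_fraction = 0.3))
  sc <- apply_scenario(cons, ds$properties, scen, final, seed = 7L)
  bau <- run_projection(final, ds$drivers, post, cons, 2026,
                        n_iterations = 15L, seed = 13L)
  scr <- run_projection(final, ds$drivers, post, sc, 2026,
                        n_iterations = 15L, seed = 13L)
  # without the floor's cancellation coupling, the converted set of the
  # scenario is a subset of BAU's in every iteration, hence cellwise on
  # the accumulated probabilities
  expect_true(all(scr$prob <= bau$prob + 1e-9))
})

test_that("area shares reduce to the printed-percentage convention", {
  expect_equal(area_share_percent(4.1, 30.6, 0), 13)
  expect_equal(area_share_percent(4.1, 26.5, 0), 15)
  expect_equal(area_share_percent(26.5, 200), 13.2)
  expect_error(area_share_percent(1, 0), "total_area")
})

test_that("the static-mask shortcut removes exactly the newly frozen probability mass", {
  ds <- small_dataset()
  post <- small_posterior()
  final <- ds$observed_states[[length(ds$observed_states)]]
  cons <- constraint_set(properties = ds$properties)
  bau <- run_projection(final, ds$drivers, post, cons, 2026,
                        n_iterations = 10L, seed = 17L)
  scen <- scenario_config("protect30",
                          large_property_rule = list(threshold_ha = 2500,
                                                     protected_fraction = 0.3))
  sc <- apply_scenario(cons, ds$properties, scen, final, seed = 8L)
  masked <- scenario_mask(bau, sc, cons)
  newly <- which(sc$frozen_mask == 1L)
  expect_true(all(masked$prob[newly, ] == 0))
  others <- setdiff(seq_len(nrow(bau$prob)), newly)
  expect_equal(masked$prob[others, ], bau$prob[others, ])
  av <- avoided_loss(bau, masked, 2026)
  expect_equal(av$ha,
               sum(bau$prob[newly, length(bau$years)]) * bau$grid$cell_area)
})
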