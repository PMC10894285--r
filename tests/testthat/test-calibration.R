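test_that("transition samples count conversions and reject reversions", {
  ds <- small_dataset()
  s0 <- ds$initial_state
  s1 <- ds$observed_states[[1L]]

  tr_same <- build_transitions(s0, landscape_state(s0$native, s0$time + 2L),
                               ds$drivers, 1L)
  expect_identical(sum(tr_same$outcome), 0L)
  expect_length(tr_same$outcome, sum(s0$native))

  tr <- build_transitions(s0, s1, ds$drivers, 1L)
  expect_identical(sum(tr$outcome), sum(s0$native) - sum(s1$native))
  expect_true(all(c(setdiff(cerrado_variables(), "land_cover"), "land_cover")
                  %in% colnames(tr$X)))

  reverted <- s1$native
  reverted[which(s1$native == 0L)[1L]] <- 1L
  expect_error(build_transitions(s1, landscape_state(reverted, s1$time + 2L),
                                 ds$drivers, 2L),
               "reversion")
})

test_that("the Bernoulli log-likelihood matches closed forms", {
  n <- 50L
  smp <- make_bernoulli_sample(n, c(x1 = 0.5), -1, seed = 1L)
  expect_equal(log_likelihood(smp, coef_vector(0)), n * log(0.5))

  # y = {1, 0} with p = {0.8, 0.3} -> log(0.8) + log(0.7)
  hand <- structure(list(
    cells = 1:2, outcome = c(1L, 0L),
    X = matrix(qlogis(c(0.8, 0.3)), 2, 1, dimnames = list(NULL, "x1")),
    period = c(start = 0, end = 2)), class = "transition_sample")
  expect_equal(log_likelihood(hand, coef_vector(0, c(x1 = 1))),
               log(0.8) + log(0.7))

  # perfect separation with huge |k| approaches 0 from below (clipped)
  sep <- structure(list(
    cells = 1:2, outcome = c(1L, 0L),
    X = matrix(c(1, -1), 2, 1, dimnames = list(NULL, "x1")),
    period = c(start = 0, end = 2)), class = "transition_sample")
  ll <- log_likelihood(sep, coef_vector(0, c(x1 = 500)))
  expect_lt(ll, 0)
  expect_gt(ll, -1e-9)

  expect_error(log_likelihood(hand, coef_vector(0, c(x9 = 1))),
               "absent from the sample")
})

test_that("AUC equals the brute-force pair-counting oracle", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(compute_auc(c(0.9, 0.4, 0.6), c(1, 0, 1)), 1.0)
  expect_error(compute_auc(c(0.1, 0.2), c(1, 1)), "at least one")
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    outcomes <- rbinom(n, 1, 0.4)
    if (sum(outcomes) %in% c(0, n)) outcomes[1:2] <- c(0L, 1L)
    expect_equal(compute_auc(scores, outcomes),
                 oracle_auc(scores, outcomes))
  }
})

test_that("MCMC chains are seed-deterministic and sample the prior without data", {
  smp <- make_bernoulli_sample(500L, c(x1 = 1), -1, seed = 2L)
  cfg <- mcmc_config(n_iter = 2000L, burn_in = 1000L, seed = 11L)
  p1 <- mcmc_calibrate(smp, "x1", cfg)
  p2 <- mcmc_calibrate(smp, "x1", cfg)
  expect_identical(p1$draws, p2$draws)
  expect_gte(nrow(p1$draws), 100L)
  expect_gt(p1$acceptance_rate, 0)
  expect_lt(p1$acceptance_rate, 1)

  # no records: the posterior is the prior N(0, prior_sd^2)
  prior_fit <- mcmc_calibrate(empty_sample(), "x1",
                              mcmc_config(n_iter = 20000L, seed = 3L))
  sds <- apply(prior_fit$draws, 2, sd)
  expect_true(all(abs(sds - 10) / 10 < 0.15))
})

test_that("MCMC chains are mean-stationary after burn-in (Geweke-style)", {
  smp <- make_bernoulli_sample(2000L, c(x1 = 0.8, x2 = -0.4), -1.5, seed = 4L)
  fit <- mcmc_calibrate(smp, c("x1", "x2"),
                        mcmc_config(n_iter = 10000L, burn_in = 5000L,
                                    seed = 5L))
  n <- nrow(fit$draws)
  a <- seq_len(floor(0.1 * n))
  b <- seq(ceiling(0.5 * n), n)
  for (j in seq_len(ncol(fit$draws))) {
    za <- fit$draws[a, j]; zb <- fit$draws[b, j]
    z <- (mean(za) - mean(zb)) / sqrt(var(za) / length(za) +
                                      var(zb) / length(zb))
    expect_lt(abs(z), 3)
  }
})

test_that("posterior recovers generating coefficients on direct Bernoulli data", {
  truth <- c(x1 = 0.7, x2 = -0.5)
  smp <- make_bernoulli_sample(20000L, truth, -2, seed = 6L)
  fit <- mcmc_calibrate(smp, c("x1", "x2"),
                        mcmc_config(n_iter = 6000L, burn_in = 3000L,
                                    seed = 7L))
  s <- posterior_summary(fit)
  expect_gt(s["intercept", "hi"], -2); expect_lt(s["intercept", "lo"], -2)
  expect_gt(s["x1", "hi"], 0.7);       expect_lt(s["x1", "lo"], 0.7)
  expect_gt(s["x2", "hi"], -0.5);      expect_lt(s["x2", "lo"], -0.5)
})

test_that("test likelihood falls when any coordinate moves off the truth", {
  # generating coefficients beat 5-SE single-coordinate perturbations
  truth <- c(x1 = 0.6, x2 = -0.4, x3 = 0.3)
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    train <- make_bernoulli_sample(100000L, truth, -2.5, seed = 100L + r)
    test <- make_bernoulli_sample(100000L, truth, -2.5, seed = 900L + r)
    # Fisher standard errors at the truth on the training design
    eta <- -2.5 + drop(train$X %*% truth)
    w <- plogis(eta) * (1 - plogis(eta))
    Xd <- cbind(1, train$X)
    se <- sqrt(diag(solve(crossprod(Xd * sqrt(w)))))[-1L]
    base <- log_likelihood(test, coef_vector(-2.5, truth))
    ok <- TRUE
    for (j in seq_along(truth)) {
      pert <- truth
      pert[j] <- pert[j] + 5 * se[j]
      if (log_likelihood(test, coef_vector(-2.5, pert)) >= base) ok <- FALSE
    }
    wins <- wins + ok
  }
  expect_gte(wins, round(0.9 * n_rep))
})

test_that("held-out likelihood selection prefers the generating subset over it plus noise", {
  # the held-out sample is much larger than the training one so the
  # criterion's overfit penalty (which grows with the test/train
  # information ratio) dominates the chance fluctuation of the spurious
  # coefficient
  truth <- c(x1 = 0.8, x2 = -0.6)
  wins <- 0L
  n_rep <- 20L
  cfg <- mcmc_config(n_iter = 4000L, burn_in = 2000L, seed = 1L)
  for (r in seq_len(n_rep)) {
    train <- make_bernoulli_sample(1000L, c(truth, x3 = 0), -1.5,
                                   seed = 200L + r)
    test <- make_bernoulli_sample(50000L, c(truth, x3 = 0), -1.5,
                                  seed = 700L + r)
    cfg$seed <- 50L + r
    sel <- select_model(train, test,
                        list(c("x1", "x2"), c("x1", "x2", "x3")), cfg)
    if (identical(sort(sel$subset), c("x1", "x2"))) wins <- wins + 1L
  }
  expect_gte(wins, round(0.8 * n_rep))
})

test_that("selection is trivial for one candidate and breaks exact ties deterministically", {
  smp <- make_bernoulli_sample(300L, c(x1 = 0.5, x2 = 0.2), -1, seed = 8L)
  sp <- split_transitions(smp, seed = 9L)
  cfg <- mcmc_config(n_iter = 1000L, burn_in = 500L, seed = 10L)
  single <- select_model(sp$train, sp$test, list("x1"), cfg)
  expect_identical(single$subset, "x1")

  # with no data every candidate scores exactly 0: smaller subset first,
  # then lexicographic
  e <- empty_sample(c("x1", "x2"))
  tie <- select_model(e, e, list(c("x1", "x2"), "x2", "x1"), cfg)
  expect_true(all(tie$scores$test_loglik == 0))
  expect_identical(tie$subset, "x1")
})

test_that("forward selection drops constant covariates and reports audit scores", {
  ds <- small_dataset()
  tr1 <- build_transitions(ds$initial_state, ds$observed_states[[1L]],
                           ds$drivers, 1L)
  expect_identical(constant_covariates(tr1), "land_cover")
  sp <- split_transitions(tr1, seed = 2L)
  sel <- forward_select(sp$train, sp$test,
                        variables = c("distance_to_rivers",
                                      "agricultural_potential"),
                        config = mcmc_config(n_iter = 1200L, burn_in = 600L,
                                             seed = 3L))
  expect_false("land_cover" %in% sel$subset)
  expect_true(nrow(sel$scores) >= 2L)
  expect_true(all(diff(range(sel$scores$size)) <= 2))
})

test_that("contribution tables report medians in order with zeros for excluded variables", {
  post <- small_posterior()
  tab <- summarize_contributions(post)
  expect_identical(tab$variable, cerrado_variables())
  excluded <- setdiff(cerrado_variables(), colnames(post$draws))
  expect_true(all(tab$median_contribution[tab$variable %in% excluded] == 0))
  # sign recovery: the generating protection effect is negative
  expect_lt(tab$median_contribution[tab$variable == "protected_areas"], 0)
  expect_gt(tab$median_contribution[tab$variable == "distance_to_rivers"], 0)

  # intercept-only model: every driver row is zero
  fit0 <- mcmc_calibrate(make_bernoulli_sample(200L, c(x1 = 0), -1, 12L),
                         character(0),
                         mcmc_config(n_iter = 1000L, burn_in = 500L,
                                     seed = 1L))
  tab0 <- summarize_contributions(fit0)
  expect_true(all(tab0$median_contribution == 0))
})
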