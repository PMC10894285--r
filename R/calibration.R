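#' Build the transition sample for one calibration period
#'
#' One record per cell that is native at the period start: outcome 1 if the
#' cell is anthropogenic at the period end (converted within the interval),
#' 0 if it remained native. The covariate matrix holds every stack layer
#' (standardized values, dynamic layers at the given period) plus the
#' `land_cover` fraction computed from the start state. A cell that reverts
#' from anthropogenic to native violates the monotone-loss contract and is
#' rejected as a data error.
#'
#' @param state_start,state_end `landscape_state`s on the same grid with
#'   `state_end$time > state_start$time`.
#' @param stack A standardized `driver_stack`.
#' @param period_index 1-based period index for dynamic layers.
#' @return An object of class `transition_sample`: list with `cells`
#'   (indices), `outcome` (0/1), `X` (covariate matrix, one named column per
#'   variable), `period` (start and end years).
#' @export
build_transitions <- function(state_start, state_end, stack,
                              period_index = 1L) {
  stopifnot(inherits(state_start, "landscape_state"),
            inherits(state_end, "landscape_state"),
            identical(dim(state_start$native), dim(state_end$native)),
            state_end$time > state_start$time)
  reverted <- which(state_start$native == 0L & state_end$native == 1L)
  if (length(reverted) > 0L) {
    stop("anthropogenic-to-native reversion at cell(s) ",
         paste(utils::head(reverted, 5L), collapse = ", "),
         if (length(reverted) > 5L) " ..." else "",
         ": transition maps must be monotone")
  }
  if (is.null(stack$standardization)) {
    stop("standardize() the stack before building transitions")
  }
  cells <- which(state_start$native == 1L)
  outcome <- as.integer(state_end$native[cells] == 0L)

  vars <- c(setdiff(names(stack$layers), stack$excluded), "land_cover")
  X <- matrix(NA_real_, length(cells), length(vars),
              dimnames = list(NULL, vars))
  for (nm in setdiff(vars, "land_cover")) {
    X[, nm] <- get_layer(stack, nm, period_index)[cells]
  }
  X[, "land_cover"] <- neighborhood_landcover(state_start,
                                              stack$nb_radius)[cells]
  structure(list(cells = cells, outcome = outcome, X = X,
                 period = c(start = state_start$time, end = state_end$time)),
            class = "transition_sample")
}

#' @export
print.transition_sample <- function(x, ...) {
  cat("transition_sample ", x$period[["start"]], "-", x$period[["end"]], ": ",
      length(x$outcome), " native cells, ", sum(x$outcome), " converted\n",
      sep = "")
  invisible(x)
}

#' Split a transition sample into training and test sets
#'
#' Seeded random cell split (default 70/30) used for held-out-likelihood
#' model scoring.
#'
#' @param sample A `transition_sample`.
#' @param train_fraction Fraction of records assigned to training.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both `transition_sample`s.
#' @export
split_transitions <- function(sample, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(sample, "transition_sample"),
            train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  n <- length(sample$outcome)
  idx <- sample.int(n, size = round(train_fraction * n))
  subset_ts <- function(i) {
    structure(list(cells = sample$cells[i], outcome = sample$outcome[i],
                   X = sample$X[i, , drop = FALSE], period = sample$period),
              class = "transition_sample")
  }
  list(train = subset_ts(idx), test = subset_ts(setdiff(seq_len(n), idx)))
}

#' Bernoulli log-likelihood of a transition sample
#'
#' `sum(y*log(p) + (1-y)*log(1-p))` with `p = plogis(k)` and probabilities
#' clipped to `[1e-12, 1 - 1e-12]` for numerical safety.
#'
#' @param sample A `transition_sample`.
#' @param coeffs A `coef_vector` whose names appear among the sample's
#'   covariate columns.
#' @return The log-likelihood (a scalar; 0 for an empty sample).
#' @export
log_likelihood <- function(sample, coeffs) {
  stopifnot(inherits(sample, "transition_sample"),
            inherits(coeffs, "coef_vector"))
  p <- conversion_probability(sample, coeffs)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  y <- sample$outcome
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Per-record conversion probabilities under a coefficient vector
#'
#' @inheritParams log_likelihood
#' @return Numeric vector of probabilities, one per record.
#' @export
conversion_probability <- function(sample, coeffs) {
  nm <- names(coeffs$coefficients)
  missing_vars <- setdiff(nm, colnames(sample$X))
  if (length(missing_vars) > 0) {
    stop("coefficients reference covariates absent from the sample: ",
         paste(missing_vars, collapse = ", "))
  }
  k <- coeffs$intercept
  if (length(nm) > 0) {
    k <- k + drop(sample$X[, nm, drop = FALSE] %*% coeffs$coefficients)
  }
  stats::plogis(rep_len(k, length(sample$outcome)))
}

#' MCMC settings
#'
#' Random-walk Metropolis settings: `n_iter` total iterations, the first
#' `burn_in` discarded (during which the proposal scale adapts toward a
#' 20-40% acceptance rate), remaining draws thinned so at least
#' `min_draws` are retained. Priors are independent Gaussians
#' N(0, `prior_sd`^2) on every coefficient including the intercept.
#'
#' @param n_iter Total iterations (default 20000).
#' @param burn_in Iterations discarded (default half of `n_iter`).
#' @param thin Thinning interval; default keeps about `min_draws` draws.
#' @param proposal_sd Initial per-coordinate proposal standard deviation.
#' @param prior_sd Prior standard deviation.
#' @param min_draws Minimum retained draws (>= 100, the Monte Carlo
#'   iteration budget of the projection stage).
#' @param adapt_window Iterations per adaptation update during burn-in.
#' @param seed Integer seed.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 20000L, burn_in = n_iter %/% 2L,
                        thin = NULL, proposal_sd = 0.1, prior_sd = 10,
                        min_draws = 1000L, adapt_window = 100L, seed = 1L) {
  stopifnot(n_iter > burn_in, burn_in >= 0, proposal_sd > 0, prior_sd > 0,
            min_draws >= 100L)
  if (is.null(thin)) thin <- max(1L, (n_iter - burn_in) %/% min_draws)
  stopifnot(thin >= 1L, thin <= n_iter - burn_in)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), proposal_sd = proposal_sd,
                 prior_sd = prior_sd, adapt_window = as.integer(adapt_window),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Calibrate the conversion model by random-walk Metropolis
#'
#' Samples the posterior of the logistic conversion model for one variable
#' subset: Bernoulli likelihood, independent Gaussian priors
#' N(0, prior_sd^2) on the intercept and every coefficient, joint Gaussian
#' random-walk proposals. During burn-in the per-coordinate proposal
#' scales track the chain's running standard deviations and a global
#' factor is tuned toward a 20-40% acceptance rate; the chain starts at
#' the maximum-likelihood estimate when one exists. Fully seeded and
#' reproducible; the compiled kernel draws all randomness from R's
#' stream.
#'
#' @param sample A `transition_sample` (may be empty, in which case the
#'   chain samples the prior).
#' @param subset Character vector of covariate names to include (empty for
#'   an intercept-only model).
#' @param config An `mcmc_config`.
#' @return An object of class `nv_posterior`: list with `subset`, `draws`
#'   (matrix, one row per retained draw; columns `intercept` + subset),
#'   `loglik` (trace at retained draws), `acceptance_rate`, `period`,
#'   `config`.
#' @export
mcmc_calibrate <- function(sample, subset = character(0),
                           config = mcmc_config()) {
  stopifnot(inherits(sample, "transition_sample"),
            inherits(config, "mcmc_config"))
  subset <- as.character(subset)
  missing_vars <- setdiff(subset, colnames(sample$X))
  if (length(missing_vars) > 0) {
    stop("subset names covariates absent from the sample: ",
         paste(missing_vars, collapse = ", "))
  }
  Xd <- cbind(intercept = rep(1, length(sample$outcome)),
              sample$X[, subset, drop = FALSE])
  # start at the maximum-likelihood estimate where one exists: the chain
  # then only has to explore the posterior, not travel to it
  init <- rep(0, ncol(Xd))
  if (length(sample$outcome) > 0) {
    mle <- tryCatch(
      suppressWarnings(stats::glm.fit(Xd, sample$outcome,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(mle) && all(is.finite(mle$coefficients)) &&
        all(abs(mle$coefficients) < 1e3)) {
      init <- unname(mle$coefficients)
    }
  }
  set.seed(config$seed)
  fit <- mh_logistic_cpp(Xd, as.integer(sample$outcome),
                         init,
                         config$n_iter, config$burn_in, config$thin,
                         config$prior_sd, config$proposal_sd,
                         config$adapt_window)
  draws <- fit$draws
  colnames(draws) <- colnames(Xd)
  structure(list(subset = subset, draws = draws, loglik = drop(fit$loglik),
                 acceptance_rate = fit$acceptance_rate,
                 period = sample$period, config = config),
            class = "nv_posterior")
}

#' @export
print.nv_posterior <- function(x, ...) {
  cat("nv_posterior: ", nrow(x$draws), " draws, acceptance ",
      round(x$acceptance_rate, 3), "\n", sep = "")
  print(round(posterior_summary(x), 4))
  invisible(x)
}

#' Posterior summaries
#'
#' @param posterior An `nv_posterior`.
#' @param prob Central credibility mass for the interval columns.
#' @return Matrix with rows per parameter and columns `mean`, `median`,
#'   `lo`, `hi`.
#' @export
posterior_summary <- function(posterior, prob = 0.95) {
  q <- (1 - prob) / 2
  t(apply(posterior$draws, 2L, function(d) {
    c(mean = mean(d), median = stats::median(d),
      lo = unname(stats::quantile(d, q)),
      hi = unname(stats::quantile(d, 1 - q)))
  }))
}

#' Posterior-mean coefficient vector
#'
#' @param posterior An `nv_posterior`.
#' @return A `coef_vector` at the posterior means.
#' @export
posterior_mean <- function(posterior) {
  m <- colMeans(posterior$draws)
  coef_vector(m[["intercept"]], m[setdiff(names(m), "intercept")])
}

# One retained draw as a coef_vector.
.posterior_draw <- function(posterior, i) {
  d <- posterior$draws[i, ]
  coef_vector(d[["intercept"]], d[setdiff(names(d), "intercept")])
}

# Canonical audit key for a subset (order-free), used for tie-breaking.
.subset_key <- function(subset) paste(sort(subset), collapse = "+")

#' Covariates that are constant in a sample
#'
#' A covariate column with zero variance carries no information for the
#' period (the canonical case: `land_cover` in a period starting from an
#' all-native landscape) and must be excluded from that period's model —
#' its coefficient would simply resample the prior and then contaminate
#' projections.
#'
#' @param sample A `transition_sample`.
#' @return Character vector of constant column names (possibly empty).
#' @export
constant_covariates <- function(sample) {
  v <- apply(sample$X, 2L, function(col) length(unique(col)) == 1L)
  colnames(sample$X)[v]
}

#' Pool transition samples across periods
#'
#' Concatenates the records of several periods into one sample (covariate
#' columns must agree), e.g. for parameter-recovery studies that calibrate
#' one model on the full observed record.
#'
#' @param samples List of `transition_sample`s.
#' @return A `transition_sample` spanning the first and last period years.
#' @export
pool_transitions <- function(samples) {
  stopifnot(length(samples) >= 1L)
  cn <- colnames(samples[[1L]]$X)
  for (s in samples) stopifnot(identical(colnames(s$X), cn))
  structure(list(
    cells = unlist(lapply(samples, `[[`, "cells")),
    outcome = unlist(lapply(samples, `[[`, "outcome")),
    X = do.call(rbind, lapply(samples, `[[`, "X")),
    period = c(start = min(vapply(samples, function(s) s$period[["start"]],
                                  numeric(1))),
               end = max(vapply(samples, function(s) s$period[["end"]],
                                numeric(1))))
  ), class = "transition_sample")
}

#' Select the variable subset with the highest test likelihood
#'
#' Calibrates each candidate subset on the training sample and scores it by
#' the test-sample log-likelihood at the posterior-mean coefficients. Ties
#' are broken toward the smaller subset, then lexicographically on the
#' sorted variable names. All scores are returned for audit.
#'
#' @param train,test `transition_sample`s from [split_transitions()].
#' @param candidates List of character vectors (variable subsets).
#' @param config An `mcmc_config`; candidate i is run at seed
#'   `config$seed + i` for reproducibility.
#' @return List with `subset` (the winner), `posterior` (its fit on the
#'   training sample), and `scores` (data.frame: subset key, size, test
#'   log-likelihood).
#' @export
select_model <- function(train, test, candidates, config = mcmc_config()) {
  stopifnot(length(candidates) > 0)
  fits <- vector("list", length(candidates))
  scores <- data.frame(subset = character(length(candidates)),
                       size = integer(length(candidates)),
                       test_loglik = numeric(length(candidates)),
                       stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    fits[[i]] <- mcmc_calibrate(train, candidates[[i]], cfg_i)
    scores$subset[i] <- .subset_key(candidates[[i]])
    scores$size[i] <- length(candidates[[i]])
    scores$test_loglik[i] <- log_likelihood(test, posterior_mean(fits[[i]]))
  }
  ord <- order(-scores$test_loglik, scores$size, scores$subset)
  best <- ord[1L]
  list(subset = candidates[[best]], posterior = fits[[best]],
       scores = scores)
}

#' Greedy forward selection over the driver variables
#'
#' Starting from the always-included covariates, repeatedly adds the
#' variable that most improves the test log-likelihood, stopping when no
#' addition improves it. A thrifty stand-in for exhaustive subset search.
#'
#' @param train,test `transition_sample`s.
#' @param variables Candidate variables (default: all stack covariates).
#' @param always Covariates always included (default `land_cover`).
#' @param config An `mcmc_config`.
#' @return As [select_model()]: list with `subset`, `posterior`, `scores`.
#' @export
forward_select <- function(train, test,
                           variables = setdiff(colnames(train$X), "land_cover"),
                           always = "land_cover",
                           config = mcmc_config()) {
  const <- constant_covariates(train)
  variables <- setdiff(variables, const)
  always <- setdiff(intersect(always, colnames(train$X)), const)
  current <- always
  cfg <- config
  cfg$seed <- config$seed
  fit <- mcmc_calibrate(train, current, cfg)
  best_score <- log_likelihood(test, posterior_mean(fit))
  scores <- data.frame(subset = .subset_key(current), size = length(current),
                       test_loglik = best_score, stringsAsFactors = FALSE)
  remaining <- setdiff(variables, current)
  step <- 0L
  repeat {
    step <- step + 1L
    trial <- lapply(remaining, function(v) c(current, v))
    if (length(trial) == 0L) break
    res <- select_model(train, test, trial, {
      cfg2 <- config; cfg2$seed <- config$seed + 100L * step; cfg2
    })
    scores <- rbind(scores, res$scores)
    best_trial <- max(res$scores$test_loglik)
    if (best_trial > best_score) {
      best_score <- best_trial
      current <- res$subset
      fit <- res$posterior
      remaining <- setdiff(remaining, current)
    } else {
      break
    }
  }
  list(subset = current, posterior = fit, scores = scores)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' converted record scores higher than a randomly chosen unconverted one,
#' counting ties as one half — exact over all pairs, computed via ranks.
#'
#' @param probabilities Numeric scores, one per record.
#' @param outcomes Binary outcomes (1 = converted).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(probabilities, outcomes) {
  stopifnot(length(probabilities) == length(outcomes),
            all(outcomes %in% c(0, 1)))
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires at least one converted and one unconverted record")
  }
  r <- rank(probabilities)   # midranks handle ties as half-wins
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Median posterior contributions in the reporting order
#'
#' Per-variable median posterior coefficient, with 0 for every variable the
#' selection excluded, emitted in the canonical reporting order. Negative
#' entries mean the variable lowers the conversion probability (the
#' protected-area indicator is the canonical example).
#'
#' @param posterior An `nv_posterior`.
#' @param full_variable_list Variables to report (default
#'   [cerrado_variables()]).
#' @return data.frame with columns `variable` and `median_contribution`.
#' @export
summarize_contributions <- function(posterior,
                                    full_variable_list = cerrado_variables()) {
  med <- apply(posterior$draws, 2L, stats::median)
  out <- vapply(full_variable_list, function(v) {
    if (v %in% colnames(posterior$draws)) med[[v]] else 0
  }, numeric(1))
  data.frame(variable = full_variable_list, median_contribution = unname(out),
             stringsAsFactors = FALSE)
}
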