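# Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

# a mid-sized synthetic landscape with a slightly elevated conversion rate
# so per-period event counts are comfortable at 64 x 64
small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- synth_config(grid_rows = 64, grid_cols = 64, seed = 42,
                        intercept = -3.5)
    .fixtures$small <- synth_dataset(cfg)
  }
  .fixtures$small
}

small_transitions <- function() {
  if (is.null(.fixtures$small_tr)) {
    ds <- small_dataset()
    states <- c(list(ds$initial_state), ds$observed_states)
    .fixtures$small_tr <- pool_transitions(lapply(
      seq_along(ds$observed_states),
      function(i) build_transitions(states[[i]], states[[i + 1L]],
                                    ds$drivers, i)))
  }
  .fixtures$small_tr
}

small_posterior <- function() {
  if (is.null(.fixtures$small_post)) {
    ds <- small_dataset()
    tr <- small_transitions()
    .fixtures$small_post <- mcmc_calibrate(
      tr,
      setdiff(names(ds$truth$coefficients), constant_covariates(tr)),
      mcmc_config(n_iter = 4000L, burn_in = 2000L, seed = 7L))
  }
  .fixtures$small_post
}

# transition sample with standard-normal covariates and Bernoulli outcomes
# from a known logistic model (no landscape involved)
make_bernoulli_sample <- function(n, beta, intercept, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * length(beta)), n,
              dimnames = list(NULL, names(beta)))
  p <- stats::plogis(intercept + drop(X %*% beta))
  structure(list(cells = seq_len(n),
                 outcome = stats::rbinom(n, 1L, p),
                 X = X, period = c(start = 0, end = 2)),
            class = "transition_sample")
}

empty_sample <- function(vars = "x1") {
  structure(list(cells = integer(0), outcome = integer(0),
                 X = matrix(numeric(0), 0L, length(vars),
                            dimnames = list(NULL, vars)),
                 period = c(start = 0, end = 2)),
            class = "transition_sample")
}

# a degenerate posterior holding one fixed coefficient vector
const_posterior <- function(coeffs, n_draws = 100L) {
  draws <- matrix(rep(c(coeffs$intercept, coeffs$coefficients),
                      each = n_draws),
                  nrow = n_draws)
  colnames(draws) <- c("intercept", names(coeffs$coefficients))
  structure(list(subset = names(coeffs$coefficients), draws = draws,
                 loglik = rep(0, n_draws), acceptance_rate = 0.3,
                 period = c(start = 2014, end = 2016),
                 config = mcmc_config(seed = 1L)),
            class = "nv_posterior")
}

# single-property landscape on an arbitrary grid, built by hand
manual_property_map <- function(id_matrix, cell_area = 100, lr_fraction) {
  ids <- sort(unique(id_matrix[id_matrix > 0L]))
  n_cells <- vapply(ids, function(g) sum(id_matrix == g), integer(1))
  tab <- data.frame(
    property_id = ids, n_cells = n_cells,
    area_ha = n_cells * cell_area,
    size_class = classify_property(n_cells * cell_area),
    region = "cerrado",
    lr_fraction = rep_len(lr_fraction, length(ids)),
    extra_protected_fraction = 0, stringsAsFactors = FALSE)
  structure(list(id = id_matrix, table = tab), class = "property_map")
}

# intercept-only driver stack (standardized, no layers needed beyond one
# placeholder so the stack is valid)
flat_stack <- function(nr, nc, cell_area = 100) {
  st <- driver_stack(list(elevation = matrix(stats::rnorm(nr * nc), nr, nc)),
                     cell_area = cell_area)
  standardize(st)
}

# brute-force oracles -----------------------------------------------------

oracle_neighborhood <- function(native, radius) {
  nr <- nrow(native); nc <- ncol(native)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      rs <- max(1, r - radius):min(nr, r + radius)
      cs <- max(1, cc - radius):min(nc, cc + radius)
      win <- native[rs, cs]
      out[r, cc] <- (sum(win == 0) - (native[r, cc] == 0)) /
        (length(win) - 1)
    }
  }
  out
}

oracle_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
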