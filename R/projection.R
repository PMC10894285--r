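# ceiling() robust to floating-point noise in lr_fraction * n_cells
.ceil_eps <- function(x) ceiling(x - 1e-9)

# one-shot log messages (e.g. "public land present"), per session
.cerradosim_env <- new.env(parent = emptyenv())
.log_once <- function(key, msg) {
  if (!isTRUE(.cerradosim_env[[key]])) {
    message(msg)
    .cerradosim_env[[key]] <- TRUE
  }
}

#' Construct a constraint set
#'
#' The constraints under which projection (not calibration) operates:
#' strict-protection cells are never convertible, and a property only
#' yields cells while its native area stays above its Legal Reserve floor.
#' Both behaviours are independently switchable. During calibration,
#' protection acts only as a covariate; the hard mask applies to projected
#' futures.
#'
#' @param properties A `property_map` (or `NULL` for a property-free
#'   landscape).
#' @param protected_mask Binary matrix of strict-protection cells; defaults
#'   to the cells the property map marks protected (`id == -1`).
#' @param enforce_pa Freeze protected cells (default `TRUE`).
#' @param enforce_lr Enforce the per-property Legal Reserve floor (default
#'   `TRUE`).
#' @param frozen_mask Optional binary matrix of additional scenario-frozen
#'   cells.
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(properties = NULL, protected_mask = NULL,
                           enforce_pa = TRUE, enforce_lr = TRUE,
                           frozen_mask = NULL) {
  if (is.null(protected_mask) && !is.null(properties)) {
    protected_mask <- matrix(as.integer(properties$id == -1L),
                             nrow(properties$id), ncol(properties$id))
  }
  if (!is.null(properties)) {
    stopifnot(all(properties$table$lr_fraction > 0),
              all(properties$table$lr_fraction <= 1))
    if (!is.null(protected_mask)) {
      stopifnot(identical(dim(protected_mask), dim(properties$id)))
    }
    if (!is.null(frozen_mask)) {
      stopifnot(identical(dim(frozen_mask), dim(properties$id)))
    }
  }
  structure(list(properties = properties, protected_mask = protected_mask,
                 enforce_pa = isTRUE(enforce_pa),
                 enforce_lr = isTRUE(enforce_lr),
                 frozen_mask = frozen_mask),
            class = "constraint_set")
}

# Minimum native cells each property must keep (its Legal Reserve floor,
# in cells), given current lr_fraction values.
.min_native_cells <- function(properties) {
  .ceil_eps(properties$table$lr_fraction * properties$table$n_cells)
}

# Per-property count of native cells that can count toward the Legal
# Reserve: scenario-frozen cells are excluded, so extra protection sits on
# top of (not inside) the reserve.
.lr_native_count <- function(state, constraints) {
  props <- constraints$properties
  ok <- state$native == 1L & props$id > 0L
  if (!is.null(constraints$frozen_mask)) {
    ok <- ok & constraints$frozen_mask == 0L
  }
  tabulate(props$id[ok], nbins = nrow(props$table))
}

#' Cells currently available for conversion
#'
#' A cell is convertible iff it is native, not under strict protection (or
#' scenario freeze), and — when the Legal Reserve floor is enforced — its
#' property's current native area strictly exceeds `lr_fraction` times the
#' property area. Properties exactly at (or below) the floor are frozen.
#' [simulate_step()] additionally cancels conversions that would push a
#' property below the integer-cell floor `ceiling(lr_fraction * n_cells)`,
#' so the floor is exact. Scenario-frozen cells do not count toward a
#' property's Legal Reserve: extra protection sits on top of the reserve,
#' not inside it. Cells belonging to no property and not protected (public
#' untitled land) are convertible with no floor.
#'
#' @param state A `landscape_state`.
#' @param constraints A `constraint_set`.
#' @return Logical matrix.
#' @export
convertible_mask <- function(state, constraints) {
  stopifnot(inherits(state, "landscape_state"),
            inherits(constraints, "constraint_set"))
  conv <- state$native == 1L
  if (constraints$enforce_pa && !is.null(constraints$protected_mask)) {
    conv[constraints$protected_mask == 1L] <- FALSE
  }
  if (!is.null(constraints$frozen_mask)) {
    conv[constraints$frozen_mask == 1L] <- FALSE
  }
  props <- constraints$properties
  if (constraints$enforce_lr && !is.null(props)) {
    native_count <- .lr_native_count(state, constraints)
    # frozen once native area no longer strictly exceeds the LR floor
    frozen_prop <- native_count <=
      props$table$lr_fraction * props$table$n_cells + 1e-9
    pos <- which(props$id > 0L)
    conv[pos] <- conv[pos] & !frozen_prop[props$id[pos]]
    if (any(props$id == 0L & conv)) {
      .log_once("public_land",
                "cells outside any property and outside protection treated as convertible public land")
    }
  }
  conv
}

# Precomputed per-draw predictor pieces: everything except the endogenous
# land-cover term is fixed within an iteration (dynamic drivers are held at
# their final observed layer during projection).
.step_cache <- function(stack, coeffs, period_index) {
  eta <- matrix(coeffs$intercept, stack$grid$rows, stack$grid$cols)
  beta_lc <- 0
  for (nm in names(coeffs$coefficients)) {
    if (nm == "land_cover") {
      beta_lc <- coeffs$coefficients[[nm]]
    } else {
      if (is.null(stack$layers[[nm]])) {
        stop("coefficient '", nm, "' references a layer missing from the stack")
      }
      eta <- eta + coeffs$coefficients[[nm]] * get_layer(stack, nm, period_index)
    }
  }
  list(static_eta = eta, beta_lc = beta_lc)
}

#' Simulate one two-year conversion step
#'
#' Every convertible cell converts independently with probability
#' `plogis(k(x))`; conversions that would push a property below its Legal
#' Reserve floor are cancelled in randomized cell order, so the floor is
#' exact. The neighbourhood land-cover covariate is recomputed from the
#' incoming state. Randomness comes from R's RNG stream (seed it with
#' `set.seed()` for reproducibility).
#'
#' @param state A `landscape_state`.
#' @param stack A standardized `driver_stack`.
#' @param coeff_draw A `coef_vector` (typically one posterior draw).
#' @param constraints A `constraint_set`.
#' @param period_index Layer period for dynamic drivers; defaults to the
#'   last observed layer.
#' @param cache Optional precomputed predictor pieces (internal fast path).
#' @return The successor `landscape_state` (time advanced by 2 years).
#' @export
simulate_step <- function(state, stack, coeff_draw, constraints,
                          period_index = stack$n_periods, cache = NULL) {
  conv <- convertible_mask(state, constraints)
  idx <- which(conv)
  native <- state$native
  if (length(idx) > 0L) {
    if (is.null(cache)) cache <- .step_cache(stack, coeff_draw, period_index)
    nb <- neighborhood_landcover(state, stack$nb_radius)
    eta <- cache$static_eta[idx] + cache$beta_lc * nb[idx]
    p <- stats::plogis(eta)
    # one uniform per grid cell, so paired-seed runs under different
    # constraints share their conversion draws cell for cell
    u <- stats::runif(length(state$native))
    cand <- idx[u[idx] < p]

    props <- constraints$properties
    if (constraints$enforce_lr && !is.null(props) && length(cand) > 0L) {
      allowed <- .lr_native_count(state, constraints) -
        .min_native_cells(props)
      cand <- cand[order(u[cand])]   # randomized cancellation order
      pid <- props$id[cand]
      in_prop <- pid > 0L
      if (any(in_prop)) {
        rk <- stats::ave(rep(1L, sum(in_prop)), pid[in_prop], FUN = seq_along)
        keep <- rep(TRUE, length(cand))
        keep[in_prop] <- rk <= allowed[pid[in_prop]]
        cand <- cand[keep]
      }
    }
    native[cand] <- 0L
  }
  landscape_state(native, state$time + 2L)
}

#' Monte Carlo projection of native-vegetation loss
#'
#' For each of `n_iterations` iterations, draws one coefficient vector from
#' the posterior (an internally consistent world) and simulates every
#' two-year step from the initial state to the horizon under the
#' constraints. The accumulated conversion probability of a cell at year Y
#' is the fraction of iterations in which it had converted by Y. Loss is
#' accounted per property, size class and region at every step, and the
#' across-iteration distribution of total loss yields the central 95%
#' interval.
#'
#' @param initial_state A `landscape_state` (its `time` is the projection
#'   origin).
#' @param stack A standardized `driver_stack`.
#' @param posterior An `nv_posterior`.
#' @param constraints A `constraint_set`.
#' @param horizon_year Final year; `horizon_year - initial` must be a
#'   positive multiple of 2.
#' @param n_iterations Monte Carlo iterations (default 100).
#' @param seed Integer seed.
#' @param label Optional label stored on the result (defaults to the
#'   posterior's period).
#' @return An object of class `projection_result`.
#' @export
run_projection <- function(initial_state, stack, posterior, constraints,
                           horizon_year, n_iterations = 100L, seed = 1L,
                           label = NULL) {
  stopifnot(inherits(initial_state, "landscape_state"),
            inherits(posterior, "nv_posterior"))
  start <- initial_state$time
  if (horizon_year <= start || (horizon_year - start) %% 2L != 0L) {
    stop("horizon_year must exceed the initial year by a positive multiple of 2")
  }
  n_steps <- (horizon_year - start) %/% 2L
  years <- start + 2L * seq_len(n_steps)
  nr <- stack$grid$rows; nc <- stack$grid$cols
  ncell <- nr * nc
  cell_area <- stack$grid$cell_area

  n_draws <- nrow(posterior$draws)
  set.seed(seed)
  if (n_draws < n_iterations) {
    message("posterior has ", n_draws, " retained draws < ", n_iterations,
            " iterations: sampling draws with replacement")
    draw_idx <- sample.int(n_draws, n_iterations, replace = TRUE)
  } else {
    draw_idx <- sample.int(n_draws, n_iterations)
  }

  props <- constraints$properties
  classes <- c("C1", "C2", "C3", "C4", "C5", "public")
  regions <- if (!is.null(props)) {
    c(sort(unique(props$table$region)), "public")
  } else "public"
  np <- if (!is.null(props)) nrow(props$table) else 0L

  inc <- matrix(0, ncell, n_steps)              # conversions at step s
  iter_total <- matrix(0, n_iterations, n_steps)
  iter_class <- array(0, c(n_iterations, length(classes), n_steps),
                      dimnames = list(NULL, classes, years))
  iter_region <- array(0, c(n_iterations, length(regions), n_steps),
                       dimnames = list(NULL, regions, years))
  prop_inc <- matrix(0, np + 1L, n_steps)       # + public row

  class_of <- if (np > 0L) match(props$table$size_class, classes) else integer(0)
  region_of <- if (np > 0L) match(props$table$region, regions) else integer(0)
  pub_class <- match("public", classes)
  pub_region <- match("public", regions)

  init_native <- if (np > 0L) {
    .lr_native_count(initial_state, constraints)
  } else integer(0)
  max_converted <- numeric(np)   # worst case across iterations, per property

  for (it in seq_len(n_iterations)) {
    coeffs <- .posterior_draw(posterior, draw_idx[it])
    cache <- .step_cache(stack, coeffs, stack$n_periods)
    state <- initial_state
    conv_count <- numeric(np)
    for (s in seq_len(n_steps)) {
      nxt <- simulate_step(state, stack, coeffs, constraints, cache = cache)
      converted <- which(state$native == 1L & nxt$native == 0L)
      if (length(converted) > 0L) {
        inc[converted, s] <- inc[converted, s] + 1
        iter_total[it, s] <- iter_total[it, s] + length(converted) * cell_area
        pid <- if (np > 0L) props$id[converted] else rep(0L, length(converted))
        pub_n <- sum(pid <= 0L)
        if (pub_n > 0L) {
          iter_class[it, pub_class, s] <- iter_class[it, pub_class, s] +
            pub_n * cell_area
          iter_region[it, pub_region, s] <- iter_region[it, pub_region, s] +
            pub_n * cell_area
          prop_inc[np + 1L, s] <- prop_inc[np + 1L, s] + pub_n
        }
        own <- pid[pid > 0L]
        if (length(own) > 0L) {
          cnt <- tabulate(own, nbins = np)
          hit <- which(cnt > 0L)
          for (g in hit) {   # few properties hit per step
            iter_class[it, class_of[g], s] <-
              iter_class[it, class_of[g], s] + cnt[g] * cell_area
            iter_region[it, region_of[g], s] <-
              iter_region[it, region_of[g], s] + cnt[g] * cell_area
          }
          prop_inc[hit, s] <- prop_inc[hit, s] + cnt[hit]
          conv_count[hit] <- conv_count[hit] + cnt[hit]
        }
      }
      state <- nxt
    }
    if (np > 0L) max_converted <- pmax(max_converted, conv_count)
  }

  cum <- function(m) {
    if (is.matrix(m)) m %*% upper.tri(diag(n_steps), diag = TRUE) else m
  }
  iter_class_cum <- iter_class
  iter_region_cum <- iter_region
  for (s in 2:max(2L, n_steps)) {
    if (s > n_steps) break
    iter_class_cum[, , s] <- iter_class_cum[, , s - 1L] + iter_class[, , s]
    iter_region_cum[, , s] <- iter_region_cum[, , s - 1L] + iter_region[, , s]
  }

  structure(list(
    years = years,
    grid = stack$grid,
    n_iterations = n_iterations,
    prob = cum(inc) / n_iterations,
    iter_total = cum(iter_total),
    iter_class = iter_class_cum,
    iter_region = iter_region_cum,
    prop_loss = cum(prop_inc) * cell_area / n_iterations,
    properties = props,
    init_native = init_native,
    max_converted = max_converted,
    protected_mask = constraints$protected_mask,
    frozen_mask = constraints$frozen_mask,
    label = if (is.null(label)) {
      if (!is.null(posterior$period)) {
        paste0(posterior$period[["start"]], "-", posterior$period[["end"]])
      } else "model"
    } else label
  ), class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  tl <- total_loss(x, max(x$years))
  cat("projection_result [", x$label, "]: ", min(x$years) - 2L, " -> ",
      max(x$years), ", ", x$n_iterations, " iterations\n", sep = "")
  cat("  expected loss by ", max(x$years), ": ", round(tl$mean), " ha (95% CI ",
      round(tl$lo), "-", round(tl$hi), ")\n", sep = "")
  invisible(x)
}

#' Accumulated conversion-probability raster at a year
#'
#' @param result A `projection_result`.
#' @param year A projection year (must be one of `result$years`).
#' @return Matrix of accumulated conversion probabilities.
#' @export
prob_raster <- function(result, year) {
  s <- match(year, result$years)
  if (is.na(s)) stop("year ", year, " is not a projection step")
  matrix(result$prob[, s], result$grid$rows, result$grid$cols)
}

#' Total projected loss with its across-iteration interval
#'
#' @param result A `projection_result`.
#' @param year A projection year.
#' @param prob Central interval mass (default 0.95).
#' @return List with `mean`, `lo`, `hi`, `halfwidth` (all in ha).
#' @export
total_loss <- function(result, year, prob = 0.95) {
  s <- match(year, result$years)
  if (is.na(s)) stop("year ", year, " is not a projection step")
  tot <- result$iter_total[, s]
  q <- stats::quantile(tot, c((1 - prob) / 2, 1 - (1 - prob) / 2))
  list(mean = mean(tot), lo = unname(q[1L]), hi = unname(q[2L]),
       halfwidth = unname(diff(q)) / 2)
}

#' Ensemble of period-specific projections
#'
#' Cellwise arithmetic mean of the members' accumulated conversion
#' probabilities per year; per-iteration loss distributions are pooled
#' (equal-weight mixture), and per-property ledgers averaged.
#'
#' @param results List of `projection_result`s on one grid and horizon.
#' @return A `projection_result` labelled `"ensemble"`.
#' @export
ensemble <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "projection_result")))
  ref <- results[[1L]]
  for (r in results[-1L]) {
    if (!identical(r$years, ref$years) || !identical(r$grid, ref$grid)) {
      stop("ensemble members must share the grid and horizon")
    }
  }
  k <- length(results)
  prob <- Reduce(`+`, lapply(results, `[[`, "prob")) / k
  abind1 <- function(field) {
    do.call(rbind, lapply(results, `[[`, field))
  }
  stack_arr <- function(field) {
    parts <- lapply(results, `[[`, field)
    d <- dim(parts[[1L]])
    out <- array(0, c(sum(vapply(parts, function(a) dim(a)[1L], numeric(1))),
                      d[2L], d[3L]), dimnames = dimnames(parts[[1L]]))
    at <- 0L
    for (a in parts) {
      out[at + seq_len(dim(a)[1L]), , ] <- a
      at <- at + dim(a)[1L]
    }
    out
  }
  structure(list(
    years = ref$years, grid = ref$grid,
    n_iterations = sum(vapply(results, `[[`, numeric(1), "n_iterations")),
    prob = prob,
    iter_total = abind1("iter_total"),
    iter_class = stack_arr("iter_class"),
    iter_region = stack_arr("iter_region"),
    prop_loss = Reduce(`+`, lapply(results, `[[`, "prop_loss")) / k,
    properties = ref$properties,
    init_native = ref$init_native,
    max_converted = Reduce(pmax, lapply(results, `[[`, "max_converted")),
    protected_mask = ref$protected_mask,
    frozen_mask = ref$frozen_mask,
    label = "ensemble"
  ), class = "projection_result")
}

#' Grouped loss summary
#'
#' Expected cumulative loss in ha by the grouping key at a year, with the
#' across-iteration central 95% interval (per-property summaries report the
#' expectation only).
#'
#' @param result A `projection_result`.
#' @param by `"class"`, `"region"` or `"property"`.
#' @param year A projection year.
#' @param prob Central interval mass.
#' @return data.frame with columns `group`, `loss_ha`, `lo`, `hi`.
#' @export
loss_summary <- function(result, by = c("class", "region", "property"),
                         year, prob = 0.95) {
  by <- match.arg(by)
  s <- match(year, result$years)
  if (is.na(s)) stop("year ", year, " is not a projection step")
  q <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  if (by %in% c("class", "region")) {
    arr <- if (by == "class") result$iter_class else result$iter_region
    sl <- arr[, , s, drop = FALSE]
    data.frame(
      group = dimnames(arr)[[2L]],
      loss_ha = apply(sl, 2L, mean),
      lo = apply(sl, 2L, stats::quantile, probs = q[1L]),
      hi = apply(sl, 2L, stats::quantile, probs = q[2L]),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    np <- nrow(result$prop_loss) - 1L
    ids <- if (np > 0L) c(result$properties$table$property_id, 0L) else 0L
    data.frame(group = as.character(ids),
               loss_ha = result$prop_loss[, s],
               lo = NA_real_, hi = NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

#' Legal Reserve audit of a projection
#'
#' Counts properties that converted beyond their Legal Reserve allowance —
#' i.e. whose native area was pushed below the integer-cell floor
#' `ceiling(lr_fraction * n_cells)` by the projection — in any Monte Carlo
#' iteration. Properties that already start below their floor (a historical
#' LR deficit, possible because observed transitions are taken as-is) are
#' not violations as long as the projection converts nothing in them.
#' A correct projection reports zero.
#'
#' @param result A `projection_result` built with a property map.
#' @return Number of violating properties.
#' @export
lr_audit <- function(result) {
  props <- result$properties
  if (is.null(props) || length(result$init_native) == 0L) return(0L)
  allowance <- pmax(0, result$init_native - .min_native_cells(props))
  sum(result$max_converted > allowance)
}

#' Protected-area audit of a projection
#'
#' Counts protected cells with non-zero accumulated conversion probability
#' at the horizon. With the hard protected-area mask enforced the count is
#' exactly zero.
#'
#' @param result A `projection_result` run with a protected mask.
#' @return Number of protected cells ever converted in any iteration.
#' @export
pa_audit <- function(result) {
  if (is.null(result$protected_mask)) return(0L)
  s <- length(result$years)
  sum(result$prob[result$protected_mask == 1L, s] > 0)
}

#' Long-format loss ledger
#'
#' Expected cumulative loss per property, size class, region and projection
#' year, suitable for CSV export.
#'
#' @param result A `projection_result` built with a property map.
#' @return data.frame with columns `property_id`, `class`, `region`,
#'   `year`, `loss_ha`.
#' @export
loss_ledger <- function(result) {
  props <- result$properties
  np <- if (!is.null(props)) nrow(props$table) else 0L
  ids <- c(if (np > 0L) props$table$property_id, 0L)
  cls <- c(if (np > 0L) props$table$size_class, "public")
  reg <- c(if (np > 0L) props$table$region, "public")
  n_steps <- length(result$years)
  data.frame(
    property_id = rep(ids, times = n_steps),
    class = rep(cls, times = n_steps),
    region = rep(reg, times = n_steps),
    year = rep(result$years, each = np + 1L),
    loss_ha = as.vector(result$prop_loss),
    stringsAsFactors = FALSE
  )
}
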