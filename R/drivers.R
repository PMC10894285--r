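#' Canonical driver variable names
#'
#' The closed vocabulary of covariates entering the conversion model, in the
#' conventional reporting order: the endogenous neighbourhood land-cover
#' fraction first, then the nine landscape drivers, with the protected-area
#' indicator last.
#'
#' @return Character vector of variable names.
#' @export
cerrado_variables <- function() {
  c("land_cover",
    "distance_to_roads", "distance_to_cities", "dry_season_length",
    "elevation", "agricultural_potential", "distance_to_rivers",
    "cattle", "permanent_agriculture", "annual_crop_agriculture",
    "protected_areas")
}

# Layers that enter the linear predictor raw: the binary protected-area
# indicator (so its coefficient is directly interpretable as a log-odds
# shift) and the land-cover fraction, which is already on [0, 1] and is
# recomputed from the evolving state rather than stored.
.raw_variables <- function() c("protected_areas", "land_cover")

#' Construct a driver stack
#'
#' Bundles aligned covariate rasters into the container used throughout the
#' pipeline. Static variables are single matrices; dynamic variables (cattle
#' and the two agriculture fractions, in the default synthetic landscapes)
#' are lists of matrices, one per calibration period.
#'
#' @param layers Named list of matrices, or lists of matrices for dynamic
#'   variables. Names must come from [cerrado_variables()] (excluding
#'   `land_cover`, which is computed from the landscape state).
#' @param cell_area Cell area in hectares (default 100 ha = 1 km^2).
#' @param n_periods Number of calibration periods the dynamic layers span.
#' @param nb_radius Moore-window radius (cells) of the neighbourhood
#'   land-cover covariate.
#' @return An object of class `driver_stack`.
#' @export
driver_stack <- function(layers, cell_area = 100, n_periods = 1L,
                         nb_radius = 3L) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  bad <- setdiff(names(layers), setdiff(cerrado_variables(), "land_cover"))
  if (length(bad) > 0) {
    stop("unknown driver layer(s): ", paste(bad, collapse = ", "))
  }
  first <- layers[[1L]]
  dims <- dim(if (is.list(first)) first[[1L]] else first)
  for (nm in names(layers)) {
    ll <- if (is.list(layers[[nm]])) layers[[nm]] else list(layers[[nm]])
    for (m in ll) {
      if (!identical(dim(m), dims)) {
        stop("layer ", nm, " does not share the grid shape")
      }
    }
    if (is.list(layers[[nm]]) && length(layers[[nm]]) != n_periods) {
      stop("dynamic layer ", nm, " must have one matrix per period")
    }
  }
  structure(list(
    grid = list(rows = dims[1L], cols = dims[2L], cell_area = cell_area),
    layers = layers,
    n_periods = as.integer(n_periods),
    nb_radius = as.integer(nb_radius),
    standardization = NULL,
    excluded = character()
  ), class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat("driver_stack:", x$grid$rows, "x", x$grid$cols, "grid,",
      length(x$layers), "layers,", x$n_periods, "period(s)\n")
  dyn <- names(x$layers)[vapply(x$layers, is.list, logical(1))]
  cat("  dynamic:", if (length(dyn)) paste(dyn, collapse = ", ") else "none", "\n")
  cat("  standardized:", !is.null(x$standardization), "\n")
  invisible(x)
}

#' Extract one layer of a driver stack
#'
#' Dynamic variables return the layer of the requested period; periods past
#' the last observed layer are held at the final layer (drivers are not
#' extrapolated during projection).
#'
#' @param stack A `driver_stack`.
#' @param name Variable name.
#' @param period_index 1-based period index.
#' @return A matrix.
#' @export
get_layer <- function(stack, name, period_index = 1L) {
  layer <- stack$layers[[name]]
  if (is.null(layer)) stop("no layer named '", name, "' in the stack")
  if (is.list(layer)) {
    layer[[min(period_index, length(layer))]]
  } else {
    layer
  }
}

#' Construct a landscape state
#'
#' A binary native-vegetation map at one time step: 1 = native vegetation,
#' 0 = anthropogenic use.
#'
#' @param native Matrix of 0/1 values.
#' @param time Calendar year of the state.
#' @return An object of class `landscape_state`.
#' @export
landscape_state <- function(native, time) {
  stopifnot(is.matrix(native), all(native %in% c(0, 1)))
  structure(list(native = matrix(as.integer(native), nrow(native), ncol(native)),
                 time = as.integer(time)),
            class = "landscape_state")
}

#' @export
print.landscape_state <- function(x, ...) {
  cat("landscape_state @", x$time, ":", sum(x$native), "native /",
      length(x$native), "cells\n")
  invisible(x)
}

#' Neighbourhood land-cover fraction
#'
#' Per-cell fraction of anthropogenic cells among the neighbours in the
#' (2r+1) x (2r+1) Moore window centred on the cell (the focal cell itself
#' is not counted), truncated at grid edges. This is the endogenous
#' covariate that lets conversion pressure track the evolving landscape:
#' it is recomputed from the current state at every simulation step.
#'
#' @param state A `landscape_state`.
#' @param radius Window radius in cells (>= 1).
#' @return Matrix of fractions in \[0, 1\].
#' @export
neighborhood_landcover <- function(state, radius) {
  stopifnot(inherits(state, "landscape_state"), radius >= 1)
  anth <- 1 - state$native
  (.box_sum(anth, radius) - anth) /
    (.box_count(nrow(anth), ncol(anth), radius) - 1)
}

#' Standardize the continuous layers of a driver stack
#'
#' Transforms every continuous layer to zero mean and unit standard
#' deviation over the training cells, freezing the (mean, sd) pairs in the
#' stack so the identical transform is reused verbatim at every projection
#' step. The binary protected-area indicator is left untransformed. For
#' dynamic variables the moments are taken from the first-period layer and
#' applied to all periods, so one frozen pair governs the variable
#' throughout.
#'
#' A layer that is constant over the training cells cannot be standardized;
#' it is left untouched and recorded in `stack$excluded` (with a warning) so
#' model selection can skip it.
#'
#' Calling `standardize()` on an already-standardized stack is a no-op, so
#' the operation is idempotent given the frozen parameters.
#'
#' @param stack A `driver_stack`.
#' @param training_cells Integer cell indices over which moments are
#'   computed; defaults to all cells.
#' @return The standardized `driver_stack`.
#' @export
standardize <- function(stack, training_cells = NULL) {
  stopifnot(inherits(stack, "driver_stack"))
  if (!is.null(stack$standardization)) return(stack)
  if (is.null(training_cells)) {
    training_cells <- seq_len(stack$grid$rows * stack$grid$cols)
  }
  stopifnot(length(training_cells) > 0)
  pars <- list()
  for (nm in names(stack$layers)) {
    if (nm %in% .raw_variables()) next
    ref <- get_layer(stack, nm, 1L)[training_cells]
    mu <- mean(ref)
    sd_ <- stats::sd(ref)
    if (!is.finite(sd_) || sd_ == 0) {
      warning("layer '", nm, "' is constant over the training cells; ",
              "excluded from the candidate set")
      stack$excluded <- union(stack$excluded, nm)
      next
    }
    pars[[nm]] <- c(mean = mu, sd = sd_)
    if (is.list(stack$layers[[nm]])) {
      stack$layers[[nm]] <- lapply(stack$layers[[nm]],
                                   function(m) (m - mu) / sd_)
    } else {
      stack$layers[[nm]] <- (stack$layers[[nm]] - mu) / sd_
    }
  }
  stack$standardization <- pars
  stack
}

#' Construct a coefficient vector
#'
#' @param intercept Intercept of the linear predictor.
#' @param coefficients Named numeric vector of per-variable coefficients
#'   (may be empty for an intercept-only model).
#' @return An object of class `coef_vector`.
#' @export
coef_vector <- function(intercept, coefficients = numeric(0)) {
  coefficients <- unlist(coefficients)
  if (length(coefficients) > 0) stopifnot(!is.null(names(coefficients)))
  stopifnot(is.finite(intercept), all(is.finite(coefficients)))
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients),
            class = "coef_vector")
}

#' Linear predictor of the conversion model
#'
#' Evaluates k(x) = b0 + sum_v b_v z_v(x, t) over the native cells of the
#' current state; the conversion probability is then `plogis(k)`. The
#' `land_cover` covariate, if present among the coefficients, is computed
#' from the state with [neighborhood_landcover()]; all other covariates are
#' read from the (standardized) stack at the given period. Anthropogenic
#' cells carry no defined predictor and are returned as `NA`.
#'
#' @param stack A standardized `driver_stack`.
#' @param coefficients A `coef_vector`.
#' @param state A `landscape_state`.
#' @param period_index 1-based period index for dynamic layers.
#' @return Matrix of predictor values, `NA` on anthropogenic cells.
#' @export
linear_predictor <- function(stack, coefficients, state, period_index = 1L) {
  stopifnot(inherits(stack, "driver_stack"),
            inherits(coefficients, "coef_vector"),
            inherits(state, "landscape_state"))
  k <- matrix(coefficients$intercept, stack$grid$rows, stack$grid$cols)
  for (nm in names(coefficients$coefficients)) {
    b <- coefficients$coefficients[[nm]]
    z <- if (nm == "land_cover") {
      neighborhood_landcover(state, stack$nb_radius)
    } else {
      if (is.null(stack$layers[[nm]])) {
        stop("coefficient '", nm, "' references a layer missing from the stack")
      }
      get_layer(stack, nm, period_index)
    }
    k <- k + b * z
  }
  k[state$native == 0L] <- NA_real_
  k
}
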