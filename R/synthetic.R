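#' Default Legal Reserve regions
#'
#' Band layout of Legal Reserve (LR) regimes for synthetic landscapes: the
#' grid is split into vertical bands, one per regime, with the bulk of the
#' area under the 20% rule (the general savanna regime) and progressively
#' smaller bands under the 35%, 50% and 80% Legal-Amazon regimes.
#'
#' @return data.frame with columns `region`, `lr_fraction`, `weight`.
#' @export
default_lr_regions <- function() {
  data.frame(
    region      = c("cerrado", "cerrado_legal_amazon", "transition",
                    "amazon_forest"),
    lr_fraction = c(0.20, 0.35, 0.50, 0.80),
    weight      = c(0.70, 0.15, 0.10, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic landscape
#'
#' Defines the study conditions a synthetic dataset emulates: grid size and
#' resolution, the number of two-year calibration periods, the generating
#' coefficients of the conversion model, the property-size law, the
#' protected-area share, and the Legal Reserve regimes.
#'
#' Defaults describe a 200 x 200 grid of 1 km^2 cells (4 Mha), four
#' two-year periods starting in 2008, a protected share of 8.3% of cells, a
#' heavy-tailed lognormal property-size law spanning all five size classes,
#' and a sparse generating model: strong positive dependence on the
#' neighbourhood land-cover fraction, a negative protected-area effect,
#' weak positive effects of distance to rivers and agricultural potential,
#' and a baseline intercept giving roughly 1% conversion per two-year step.
#'
#' @param grid_rows,grid_cols Grid dimensions (>= 8).
#' @param cell_area Cell area in ha (default 100 = 1 km^2).
#' @param n_periods Number of two-year calibration intervals.
#' @param true_coefficients Named vector of generating coefficients (on the
#'   standardized covariate scale; `land_cover` and `protected_areas` raw).
#' @param intercept Generating intercept.
#' @param property_size_law Named vector `c(meanlog=, sdlog=)` of the
#'   lognormal property-size law in ha.
#' @param pa_fraction Proportion of cells under strict protection.
#' @param lr_regions data.frame as [default_lr_regions()]; every
#'   `lr_fraction` must be one of 0.20, 0.35, 0.50, 0.80.
#' @param smoothing_sigma Gaussian autocorrelation length (cells) of the
#'   continuous driver fields.
#' @param start_year First calibration year.
#' @param seed Integer seed governing every random component.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid_rows = 200L, grid_cols = 200L,
                         cell_area = 100,
                         n_periods = 4L,
                         true_coefficients = c(land_cover = 2.5,
                                               protected_areas = -1.4,
                                               distance_to_rivers = 0.3,
                                               agricultural_potential = 0.4),
                         intercept = -4.5,
                         property_size_law = c(meanlog = log(200), sdlog = 1.5),
                         pa_fraction = 0.083,
                         lr_regions = default_lr_regions(),
                         smoothing_sigma = 5,
                         start_year = 2008L,
                         seed = 1L) {
  stopifnot(grid_rows >= 8L, grid_cols >= 8L, cell_area > 0,
            n_periods >= 1L,
            pa_fraction >= 0, pa_fraction <= 1,
            all(c("meanlog", "sdlog") %in% names(property_size_law)),
            all(lr_regions$lr_fraction %in% c(0.20, 0.35, 0.50, 0.80)),
            all(lr_regions$weight > 0),
            is.finite(intercept))
  bad <- setdiff(names(true_coefficients), cerrado_variables())
  if (length(bad) > 0) {
    stop("true_coefficients name unknown variable(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_area = cell_area, n_periods = as.integer(n_periods),
    true_coefficients = true_coefficients, intercept = intercept,
    property_size_law = property_size_law, pa_fraction = pa_fraction,
    lr_regions = lr_regions, smoothing_sigma = smoothing_sigma,
    start_year = as.integer(start_year), seed = as.integer(seed)
  ), class = "synth_config")
}

# Protected-area mask drawn on its own sub-seed so generate_properties()
# can reproduce it without regenerating the full stack.
.pa_mask <- function(config) {
  set.seed(.sub_seed(config$seed, 1L))
  s <- .smooth_field(config$grid_rows, config$grid_cols,
                     config$smoothing_sigma)
  if (config$pa_fraction <= 0) {
    return(matrix(0L, config$grid_rows, config$grid_cols))
  }
  thr <- stats::quantile(s, 1 - config$pa_fraction)
  matrix(as.integer(s > thr), config$grid_rows, config$grid_cols)
}

#' Generate synthetic driver rasters
#'
#' Builds one raster per named driver: Euclidean distance transforms from
#' randomly seeded source cells for the three distance variables, smoothed
#' (spatially autocorrelated) Gaussian fields rescaled to plausible units
#' for the continuous variables, and a contiguous binary protected-area
#' mask with mean close to `pa_fraction`. The three census-like variables
#' (cattle, permanent and annual crop agriculture) are dynamic: one layer
#' per period, drifting as an AR(1) process (rho = 0.9) around the initial
#' field. The neighbourhood land-cover channel is not stored; it is
#' computed from the landscape state on demand.
#'
#' @param config A `synth_config`.
#' @return A `driver_stack` (unstandardized).
#' @export
generate_drivers <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  ncell <- nr * nc
  sig <- config$smoothing_sigma
  rho <- 0.9

  n_src <- function(per_cells) max(1L, round(ncell / per_cells))
  if (ncell < 3L) stop("grid too small to place distance-transform sources")

  set.seed(.sub_seed(config$seed, 2L))
  dist_layer <- function(n) .distance_to(nr, nc, sample.int(ncell, n))
  distance_to_roads  <- dist_layer(n_src(800))
  distance_to_cities <- dist_layer(n_src(2000))
  distance_to_rivers <- dist_layer(n_src(400))

  dry_season_length <- 150 + 30 * .smooth_field(nr, nc, sig)
  elevation <- 500 + 200 * .smooth_field(nr, nc, sig)
  agricultural_potential <- stats::plogis(.smooth_field(nr, nc, sig))

  # dynamic variables: latent AR(1) field per period, transformed to units
  dynamic <- function(transform) {
    f <- .smooth_field(nr, nc, sig)
    out <- vector("list", config$n_periods)
    for (t in seq_len(config$n_periods)) {
      if (t > 1L) {
        f <- rho * f + sqrt(1 - rho^2) * .smooth_field(nr, nc, sig)
      }
      out[[t]] <- transform(f)
    }
    out
  }
  cattle <- dynamic(function(f) exp(3 + 0.8 * f))          # head / km^2
  permanent_agriculture   <- dynamic(function(f) stats::plogis(-2 + f))
  annual_crop_agriculture <- dynamic(function(f) stats::plogis(-1.5 + f))

  protected_areas <- .pa_mask(config)

  driver_stack(
    list(distance_to_roads = distance_to_roads,
         distance_to_cities = distance_to_cities,
         distance_to_rivers = distance_to_rivers,
         dry_season_length = dry_season_length,
         elevation = elevation,
         agricultural_potential = agricultural_potential,
         cattle = cattle,
         permanent_agriculture = permanent_agriculture,
         annual_crop_agriculture = annual_crop_agriculture,
         protected_areas = protected_areas + 0),
    cell_area = config$cell_area,
    n_periods = config$n_periods
  )
}

#' Generate a synthetic property mosaic
#'
#' Tessellates the non-protected grid into contiguous properties by seeded
#' region growing: target areas are drawn from the lognormal size law,
#' converted to cell counts (>= 1), and grown from random centroids over
#' 4-neighbour adjacency until the target is met or the patch is enclosed.
#' Every non-protected cell belongs to exactly one property. Each property
#' receives the Legal Reserve fraction of the vertical region band its seed
#' cell falls in, and a size class from [classify_property()].
#'
#' @param config A `synth_config`.
#' @param protected Optional binary protected mask; when omitted it is
#'   reproduced from the config seed (identical to the one
#'   [generate_drivers()] emits).
#' @return An object of class `property_map`: a list with `id` (integer
#'   matrix, -1 on protected cells) and `table` (one row per property:
#'   `property_id`, `n_cells`, `area_ha`, `size_class`, `region`,
#'   `lr_fraction`, `extra_protected_fraction`).
#' @export
generate_properties <- function(config, protected = NULL) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  if (is.null(protected)) protected <- .pa_mask(config)
  stopifnot(identical(dim(protected), c(nr, nc)))

  # vertical region bands by cumulative weight
  w <- config$lr_regions$weight / sum(config$lr_regions$weight)
  band_edges <- c(0, cumsum(w)) * nc
  col_region <- findInterval(seq_len(nc) - 0.5, band_edges,
                             rightmost.closed = TRUE)
  col_region <- pmin(col_region, nrow(config$lr_regions))

  set.seed(.sub_seed(config$seed, 3L))
  ncell <- nr * nc
  id <- integer(ncell)
  id[protected == 1L] <- -1L
  meanlog <- config$property_size_law[["meanlog"]]
  sdlog <- config$property_size_law[["sdlog"]]

  free <- which(id == 0L)
  next_id <- 0L
  seed_cells <- integer(0)
  assigned <- id != 0L
  while (length(free) > 0L) {
    next_id <- next_id + 1L
    target <- max(1L, round(stats::rlnorm(1, meanlog, sdlog) / config$cell_area))
    seed_cell <- free[sample.int(length(free), 1L)]
    seed_cells[next_id] <- seed_cell
    # BFS region growing over unassigned 4-neighbours
    queue <- seed_cell
    assigned[seed_cell] <- TRUE
    id[seed_cell] <- next_id
    grown <- 1L
    head <- 1L
    while (grown < target && head <= length(queue)) {
      cell <- queue[head]
      head <- head + 1L
      r <- ((cell - 1L) %% nr) + 1L
      nb <- c(if (r > 1L) cell - 1L,
              if (r < nr) cell + 1L,
              if (cell > nr) cell - nr,
              if (cell <= ncell - nr) cell + nr)
      nb <- nb[!assigned[nb]]
      if (length(nb) > 0L) {
        take <- nb[seq_len(min(length(nb), target - grown))]
        assigned[take] <- TRUE
        id[take] <- next_id
        queue <- c(queue, take)
        grown <- grown + length(take)
      }
    }
    free <- free[!assigned[free]]
  }

  n_cells <- tabulate(id[id > 0L], nbins = next_id)
  area_ha <- n_cells * config$cell_area
  seed_col <- ((seed_cells - 1L) %/% nr) + 1L
  region_idx <- col_region[seed_col]
  tab <- data.frame(
    property_id = seq_len(next_id),
    n_cells = n_cells,
    area_ha = area_ha,
    size_class = classify_property(area_ha),
    region = config$lr_regions$region[region_idx],
    lr_fraction = config$lr_regions$lr_fraction[region_idx],
    extra_protected_fraction = 0,
    stringsAsFactors = FALSE
  )
  structure(list(id = matrix(id, nr, nc), table = tab),
            class = "property_map")
}

#' @export
print.property_map <- function(x, ...) {
  cat("property_map:", nrow(x$table), "properties;",
      sum(x$id == -1L), "protected cells\n")
  print(table(x$table$size_class))
  invisible(x)
}

#' Generate a conversion history from known coefficients
#'
#' Starting from an all-native landscape, simulates `n_periods` two-year
#' transitions in which every native cell converts independently with
#' probability `plogis(intercept + sum(beta_v * z_v))`, the same logistic
#' rule the calibration module fits. Drivers are standardized (frozen
#' moments over all cells) before the predictor is formed, so the generating
#' coefficients live on the scale calibration estimates. No Legal Reserve or
#' protected-area constraint is imposed on the history: protection acts only
#' through its (negative) coefficient, as in the observed record.
#'
#' @param drivers A `driver_stack` (standardized or not; it will be
#'   standardized over all cells).
#' @param properties A `property_map`.
#' @param config The `synth_config` holding the generating coefficients.
#' @param rng_seed Seed for the conversion draws.
#' @return An object of class `synthetic_dataset`: list with `drivers`
#'   (standardized stack), `initial_state`, `observed_states` (one per
#'   period boundary), `properties`, and `truth` (intercept and
#'   coefficients actually used).
#' @export
generate_history <- function(drivers, properties, config,
                             rng_seed = config$seed) {
  stopifnot(inherits(drivers, "driver_stack"),
            inherits(properties, "property_map"),
            inherits(config, "synth_config"))
  stack <- standardize(drivers)
  truth <- coef_vector(config$intercept, config$true_coefficients)

  state <- landscape_state(matrix(1L, config$grid_rows, config$grid_cols),
                           config$start_year)
  set.seed(rng_seed %% 2147483647)
  states <- vector("list", config$n_periods)
  for (t in seq_len(config$n_periods)) {
    k <- linear_predictor(stack, truth, state, period_index = t)
    p <- stats::plogis(k)
    native_idx <- which(state$native == 1L)
    if (sum(p[native_idx]) < 1) {
      stop("degenerate configuration: expected conversions per period < 1 cell")
    }
    u <- stats::runif(length(native_idx))
    converted <- native_idx[u < p[native_idx]]
    native <- state$native
    native[converted] <- 0L
    state <- landscape_state(native, state$time + 2L)
    states[[t]] <- state
  }

  structure(list(
    drivers = stack,
    initial_state = landscape_state(
      matrix(1L, config$grid_rows, config$grid_cols), config$start_year),
    observed_states = states,
    properties = properties,
    truth = truth,
    config = config
  ), class = "synthetic_dataset")
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_drivers()],
#' [generate_properties()] and [generate_history()] under the config's seed.
#'
#' @param config A `synth_config`.
#' @return A `synthetic_dataset`.
#' @export
synth_dataset <- function(config) {
  drivers <- generate_drivers(config)
  properties <- generate_properties(config,
                                    protected = get_layer(drivers,
                                                          "protected_areas"))
  generate_history(drivers, properties, config)
}
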