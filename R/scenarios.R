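#' Property size classification
#'
#' The five-class property-size scheme used for loss accounting: C1
#' (1-150 ha, small), C2 (150-400 ha) and C3 (400-1000 ha, medium), C4
#' (1000-2500 ha) and C5 (> 2500 ha, large). Bracket upper bounds are
#' inclusive (150 ha is C1, 2500 ha is C4); areas below 1 ha fall outside
#' the scheme and raise an error.
#'
#' @param area Numeric vector of property areas in hectares.
#' @return Character vector of classes `"C1"`..`"C5"`.
#' @export
classify_property <- function(area) {
  if (any(area < 1)) {
    stop("property area below 1 ha is outside the size classification")
  }
  cut(area, breaks = c(1, 150, 400, 1000, 2500, Inf),
      labels = c("C1", "C2", "C3", "C4", "C5"),
      include.lowest = TRUE, right = TRUE) |> as.character()
}

#' Construct a scenario configuration
#'
#' A policy scenario is a transformation of the constraint set: Legal
#' Reserve overrides by region, additional protected areas, and/or a
#' large-property rule that freezes a fixed share of every property above
#' an area threshold (the headline policy: protect 30% of properties
#' larger than 2500 ha).
#'
#' @param name Scenario label.
#' @param lr_overrides Named numeric vector, region -> new Legal Reserve
#'   fraction.
#' @param pa_additions Optional binary matrix of extra protected cells.
#' @param large_property_rule `NULL`, or a list with `threshold_ha`,
#'   `protected_fraction` and optionally `mode` (`"additive"`, the default,
#'   reads the rule as protection on top of the Legal Reserve; `"max"`
#'   freezes only up to `max(lr_fraction, protected_fraction)` in total).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, lr_overrides = NULL, pa_additions = NULL,
                            large_property_rule = NULL) {
  if (!is.null(large_property_rule)) {
    stopifnot(large_property_rule$threshold_ha > 0,
              large_property_rule$protected_fraction >= 0,
              large_property_rule$protected_fraction <= 1)
    if (is.null(large_property_rule$mode)) {
      large_property_rule$mode <- "additive"
    }
    stopifnot(large_property_rule$mode %in% c("additive", "max"))
  }
  if (!is.null(lr_overrides)) {
    stopifnot(!is.null(names(lr_overrides)),
              all(lr_overrides > 0), all(lr_overrides <= 1))
  }
  structure(list(name = name, lr_overrides = lr_overrides,
                 pa_additions = pa_additions,
                 large_property_rule = large_property_rule),
            class = "scenario_config")
}

#' Apply a policy scenario to a constraint set
#'
#' Legal Reserve overrides replace `lr_fraction` by region. The
#' large-property rule freezes specific cells of every qualifying property:
#' in `"additive"` mode (the default reading, protection complementing the
#' Legal Reserve) a fraction `protected_fraction` of the property's cells
#' is frozen on top of the LR floor, so a 3000-ha property in a 20% region
#' ends up with 50% of its area non-convertible; in `"max"` mode only
#' `max(0, protected_fraction - lr_fraction)` of the cells are frozen, for
#' a total frozen share of `max(lr_fraction, protected_fraction)`. Frozen
#' cells are the currently native cells with the highest native
#' neighbourhood fraction (ties broken at random), emulating protection of
#' contiguous remnants. If a property has fewer native cells than the rule
#' requires, all its native cells are frozen and the deficit is reported.
#'
#' Scenarios only add protection: the frozen area of a property never
#' decreases.
#'
#' @param base A `constraint_set` (business as usual).
#' @param properties The `property_map` (defaults to the one in `base`).
#' @param scenario A `scenario_config`.
#' @param state The current `landscape_state` (defines "currently native").
#' @param seed Integer seed for tie-breaking.
#' @return A new `constraint_set`.
#' @export
apply_scenario <- function(base, properties = base$properties, scenario,
                           state, seed = 1L) {
  stopifnot(inherits(base, "constraint_set"),
            inherits(scenario, "scenario_config"),
            inherits(state, "landscape_state"))
  props <- properties
  if (!is.null(scenario$lr_overrides)) {
    for (reg in names(scenario$lr_overrides)) {
      props$table$lr_fraction[props$table$region == reg] <-
        scenario$lr_overrides[[reg]]
    }
  }
  protected <- base$protected_mask
  if (!is.null(scenario$pa_additions)) {
    stopifnot(identical(dim(scenario$pa_additions), dim(state$native)))
    protected <- if (is.null(protected)) scenario$pa_additions else
      pmax(protected, scenario$pa_additions)
  }
  frozen <- if (is.null(base$frozen_mask)) {
    matrix(0L, nrow(state$native), ncol(state$native))
  } else base$frozen_mask

  rule <- scenario$large_property_rule
  if (!is.null(rule) && !is.null(props)) {
    qualifying <- which(props$table$area_ha > rule$threshold_ha)
    if (length(qualifying) > 0L) {
      extra_frac <- if (rule$mode == "additive") {
        rep(rule$protected_fraction, length(qualifying))
      } else {
        pmax(0, rule$protected_fraction -
               props$table$lr_fraction[qualifying])
      }
      set.seed(seed)
      native_frac <- 1 - neighborhood_landcover(state, 3L)
      jitter <- stats::runif(length(state$native))   # random tie-break
      deficit <- 0
      for (qi in seq_along(qualifying)) {
        g <- qualifying[qi]
        n_freeze <- .ceil_eps(extra_frac[qi] * props$table$n_cells[g])
        if (n_freeze == 0L) next
        cells <- which(props$id == g & state$native == 1L & frozen == 0L)
        if (length(cells) < n_freeze) {
          deficit <- deficit + (n_freeze - length(cells))
          n_freeze <- length(cells)
        }
        if (n_freeze > 0L) {
          ord <- order(-native_frac[cells], jitter[cells])
          frozen[cells[ord[seq_len(n_freeze)]]] <- 1L
        }
        props$table$extra_protected_fraction[g] <-
          props$table$extra_protected_fraction[g] + extra_frac[qi]
      }
      if (deficit > 0) {
        message("large-property rule short of native cells: ", deficit,
                " cell(s) could not be frozen")
      }
    }
  }
  constraint_set(properties = props, protected_mask = protected,
                 enforce_pa = base$enforce_pa, enforce_lr = base$enforce_lr,
                 frozen_mask = frozen)
}

#' Avoided loss of a scenario relative to business as usual
#'
#' Difference in expected loss at a year between the BAU and scenario
#' projections, in ha and as a percentage of the BAU loss. For paired-seed
#' runs the estimate is low-variance; a negative avoided loss beyond three
#' Monte Carlo standard errors is flagged as a configuration inconsistency.
#'
#' @param bau,scenario_result `projection_result`s sharing grid and
#'   horizon.
#' @param year A projection year.
#' @return List with `ha`, `percent_of_bau` (one decimal),
#'   `percent_headline` (rounded to the nearest integer), and
#'   `inconsistent` (logical flag).
#' @export
avoided_loss <- function(bau, scenario_result, year) {
  stopifnot(inherits(bau, "projection_result"),
            inherits(scenario_result, "projection_result"),
            identical(bau$years, scenario_result$years),
            identical(bau$grid, scenario_result$grid))
  b <- total_loss(bau, year)
  s <- total_loss(scenario_result, year)
  ha <- b$mean - s$mean
  stp <- match(year, bau$years)
  se <- sqrt(stats::var(bau$iter_total[, stp]) / nrow(bau$iter_total) +
             stats::var(scenario_result$iter_total[, stp]) /
               nrow(scenario_result$iter_total))
  inconsistent <- ha < -3 * se
  if (inconsistent) {
    warning("avoided loss ", round(ha),
            " ha is negative beyond 3 Monte Carlo SE: the scenario loses ",
            "more than BAU, check the configuration")
  }
  pct <- if (b$mean > 0) 100 * ha / b$mean else 0
  list(ha = ha,
       percent_of_bau = round(pct, 1),
       percent_headline = round(pct),
       inconsistent = inconsistent)
}

#' Loss as a share of a reference area
#'
#' Expresses a projected loss as a percentage of a total area (for example
#' a biome's extent), in the same units.
#'
#' @param loss Loss (any area unit).
#' @param total_area Reference area (same unit).
#' @param digits Decimal places of the returned percentage.
#' @return Percentage.
#' @export
area_share_percent <- function(loss, total_area, digits = 1) {
  stopifnot(total_area > 0)
  round(100 * loss / total_area, digits)
}

#' Static-mask approximation of a scenario's avoided loss
#'
#' Instead of re-simulating, zeroes the BAU accumulated conversion
#' probability on every cell the scenario newly freezes or protects: a
#' cheap upper-bound-style estimate that ignores displaced conversion
#' pressure.
#'
#' @param bau A BAU `projection_result`.
#' @param scenario_constraints The scenario `constraint_set` (from
#'   [apply_scenario()]).
#' @param base_constraints The BAU `constraint_set`.
#' @return A `projection_result` with masked probabilities and rescaled
#'   totals, labelled `"<bau label>+mask"`.
#' @export
scenario_mask <- function(bau, scenario_constraints, base_constraints) {
  newly <- matrix(0L, bau$grid$rows, bau$grid$cols)
  add_diff <- function(new_m, old_m) {
    if (is.null(new_m)) return(NULL)
    if (is.null(old_m)) new_m else pmax(new_m - old_m, 0L)
  }
  fz <- add_diff(scenario_constraints$frozen_mask, base_constraints$frozen_mask)
  pa <- add_diff(scenario_constraints$protected_mask,
                 base_constraints$protected_mask)
  if (!is.null(fz)) newly <- pmax(newly, fz)
  if (!is.null(pa)) newly <- pmax(newly, pa)
  out <- bau
  masked <- which(newly == 1L)
  removed <- colSums(out$prob[masked, , drop = FALSE]) * bau$grid$cell_area
  out$prob[masked, ] <- 0
  out$iter_total <- sweep(out$iter_total, 2L, removed)
  out$label <- paste0(bau$label, "+mask")
  out
}
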