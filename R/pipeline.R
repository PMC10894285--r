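#' Configuration of a full pipeline run
#'
#' Single configuration object driving the end-to-end analysis: synthetic
#' landscape, calibration periods, MCMC settings, projection settings and
#' policy scenarios.
#'
#' @param synth A `synth_config`.
#' @param periods List of `c(start, end)` year pairs; defaults to
#'   `n_periods` consecutive two-year intervals from the synth start year
#'   (the canonical four: 2008-2010, 2010-2012, 2012-2014, 2014-2016).
#'   Periods must be non-overlapping and each must span exactly 2 years.
#' @param mcmc An `mcmc_config`.
#' @param selection `"forward"` (greedy forward selection, the default) or
#'   `"truth"` (calibrate the generating subset, for recovery studies).
#' @param horizon_year Projection horizon (>= last period end).
#' @param n_iterations Monte Carlo iterations per projection.
#' @param projection_seed Seed shared by BAU and scenario projections
#'   (paired seeds reduce the Monte Carlo variance of avoided loss).
#' @param scenarios Named list of `scenario_config`s (may be empty).
#' @param train_fraction Train share of the per-period 70/30 split.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       periods = NULL,
                       mcmc = mcmc_config(),
                       selection = c("forward", "truth"),
                       horizon_year = 2070L,
                       n_iterations = 100L,
                       projection_seed = 421L,
                       scenarios = list(),
                       train_fraction = 0.7) {
  selection <- match.arg(selection)
  if (is.null(periods)) {
    periods <- lapply(seq_len(synth$n_periods), function(i) {
      c(synth$start_year + 2L * (i - 1L), synth$start_year + 2L * i)
    })
  }
  for (p in periods) {
    if (length(p) != 2L || p[2L] - p[1L] != 2L) {
      stop("each calibration period must span exactly 2 years")
    }
  }
  starts <- vapply(periods, `[`, numeric(1), 1L)
  ends <- vapply(periods, `[`, numeric(1), 2L)
  ord <- order(starts)
  if (any(starts[ord][-1L] < ends[ord][-length(ends)])) {
    stop("calibration periods overlap")
  }
  if (length(periods) != synth$n_periods) {
    stop("periods must match synth$n_periods")
  }
  stopifnot(horizon_year >= max(ends))
  if ((horizon_year - max(ends)) %% 2L != 0L) {
    stop("horizon_year must be an even number of years past the last period")
  }
  structure(list(synth = synth, periods = periods, mcmc = mcmc,
                 selection = selection, horizon_year = as.integer(horizon_year),
                 n_iterations = as.integer(n_iterations),
                 projection_seed = as.integer(projection_seed),
                 scenarios = scenarios,
                 train_fraction = train_fraction),
            class = "run_config")
}

# rebuild a run_config (e.g. from a manifest) from a plain list
.as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  synth <- x$synth
  synth$lr_regions <- as.data.frame(synth$lr_regions,
                                    stringsAsFactors = FALSE)
  sc <- do.call(synth_config, synth[setdiff(names(synth), character(0))])
  mc <- do.call(mcmc_config, x$mcmc[c("n_iter", "burn_in", "thin",
                                      "proposal_sd", "prior_sd",
                                      "adapt_window", "seed")])
  scen <- lapply(x$scenarios, function(s) {
    if (inherits(s, "scenario_config")) s else
      do.call(scenario_config, s)
  })
  run_config(synth = sc, periods = lapply(x$periods, as.integer), mcmc = mc,
             selection = x$selection, horizon_year = x$horizon_year,
             n_iterations = x$n_iterations,
             projection_seed = x$projection_seed,
             scenarios = scen, train_fraction = x$train_fraction)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) the synthetic dataset, standardizes drivers,
#' builds per-period transition samples, selects and calibrates the
#' conversion model per period, validates with AUC, projects each period's
#' model to the horizon under business-as-usual constraints, ensembles the
#' periods, applies each policy scenario (re-simulated with paired seeds),
#' and writes all outputs plus a replayable manifest to `out_dir`.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output.
#' @param dataset Optional pre-built `synthetic_dataset` (must match
#'   `config$synth`); by default it is generated from the config.
#' @return List with `dataset`, `fits` (per period: posterior, scores,
#'   auc), `projections` (per period), `bau` (ensemble), `scenario_runs`
#'   (per scenario: ensemble, avoided at horizon), `contributions`,
#'   `auc_table`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, dataset = NULL) {
  config <- .as_run_config(config)
  n_periods <- length(config$periods)

  if (is.null(dataset)) dataset <- synth_dataset(config$synth)
  stack <- dataset$drivers
  props <- dataset$properties

  # --- calibration per period -------------------------------------------
  fits <- vector("list", n_periods)
  auc_table <- data.frame(period = character(0), auc = numeric(0),
                          stringsAsFactors = FALSE)
  contributions <- NULL
  states <- c(list(dataset$initial_state), dataset$observed_states)
  for (i in seq_len(n_periods)) {
    sample_i <- build_transitions(states[[i]], states[[i + 1L]], stack,
                                  period_index = i)
    split_i <- split_transitions(sample_i, config$train_fraction,
                                 seed = config$mcmc$seed + 1000L * i)
    cfg_i <- config$mcmc
    cfg_i$seed <- config$mcmc$seed + i
    if (config$selection == "forward") {
      sel <- forward_select(split_i$train, split_i$test, config = cfg_i)
    } else {
      subset_true <- setdiff(names(dataset$truth$coefficients),
                             constant_covariates(split_i$train))
      post <- mcmc_calibrate(split_i$train, subset_true, cfg_i)
      sel <- list(subset = subset_true, posterior = post,
                  scores = data.frame(
                    subset = .subset_key(subset_true),
                    size = length(subset_true),
                    test_loglik = log_likelihood(split_i$test,
                                                 posterior_mean(post)),
                    stringsAsFactors = FALSE))
    }
    auc <- compute_auc(conversion_probability(split_i$test,
                                              posterior_mean(sel$posterior)),
                       split_i$test$outcome)
    period_lab <- paste0(config$periods[[i]][1L], "-",
                         config$periods[[i]][2L])
    auc_table <- rbind(auc_table,
                       data.frame(period = period_lab, auc = auc,
                                  stringsAsFactors = FALSE))
    contrib_i <- summarize_contributions(sel$posterior)
    names(contrib_i)[2L] <- period_lab
    contributions <- if (is.null(contributions)) contrib_i else
      cbind(contributions, contrib_i[2L])
    fits[[i]] <- list(period = period_lab, subset = sel$subset,
                      posterior = sel$posterior, scores = sel$scores,
                      auc = auc)
  }

  # --- BAU projection per period + ensemble -----------------------------
  final_state <- states[[n_periods + 1L]]
  constraints <- constraint_set(properties = props)
  projections <- vector("list", n_periods)
  for (i in seq_len(n_periods)) {
    projections[[i]] <- run_projection(
      final_state, stack, fits[[i]]$posterior, constraints,
      horizon_year = config$horizon_year,
      n_iterations = config$n_iterations,
      seed = config$projection_seed + i,
      label = fits[[i]]$period)
  }
  bau <- ensemble(projections)

  # --- scenarios (paired projection seeds) ------------------------------
  scenario_runs <- list()
  for (nm in names(config$scenarios)) {
    scen_constraints <- apply_scenario(constraints, props,
                                       config$scenarios[[nm]],
                                       state = final_state,
                                       seed = config$projection_seed)
    scen_proj <- vector("list", n_periods)
    for (i in seq_len(n_periods)) {
      scen_proj[[i]] <- run_projection(
        final_state, stack, fits[[i]]$posterior, scen_constraints,
        horizon_year = config$horizon_year,
        n_iterations = config$n_iterations,
        seed = config$projection_seed + i,
        label = paste0(fits[[i]]$period, "+", nm))
    }
    scen_ens <- ensemble(scen_proj)
    scenario_runs[[nm]] <- list(
      constraints = scen_constraints,
      result = scen_ens,
      avoided = avoided_loss(bau, scen_ens, config$horizon_year),
      avoided_mask = {
        masked <- scenario_mask(bau, scen_constraints, constraints)
        avoided_loss(bau, masked, config$horizon_year)
      })
  }

  out <- list(dataset = dataset, fits = fits, projections = projections,
              bau = bau, scenario_runs = scenario_runs,
              contributions = contributions, auc_table = auc_table,
              config = config, out_dir = out_dir)

  # --- outputs ----------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(auc_table, file.path(out_dir, "auc.csv"),
                     row.names = FALSE)
    utils::write.csv(contributions,
                     file.path(out_dir, "contributions.csv"),
                     row.names = FALSE)
    for (i in seq_len(n_periods)) {
      write_posterior(fits[[i]]$posterior,
                      file.path(out_dir, paste0("posterior_",
                                                fits[[i]]$period, ".csv")),
                      file.path(out_dir, paste0("posterior_",
                                                fits[[i]]$period, ".yaml")))
    }
    for (yr in intersect(c(2050L, config$horizon_year), bau$years)) {
      write_ascii_grid(prob_raster(bau, yr),
                       file.path(out_dir, paste0("prob_bau_", yr, ".asc")))
    }
    write_ledger(loss_ledger(bau), file.path(out_dir, "ledger_bau.csv"))
    for (nm in names(scenario_runs)) {
      write_ledger(loss_ledger(scenario_runs[[nm]]$result),
                   file.path(out_dir, paste0("ledger_", nm, ".csv")))
    }
    write_manifest(config, out_dir)
  }
  out
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] with the manifest's exact configuration and
#' verifies the outputs are bit-identical to the recorded checksums.
#'
#' @param manifest_path Path to a `manifest.yaml`.
#' @param out_dir Directory for the replayed outputs.
#' @return The [run_pipeline()] result, with an added element
#'   `checksums_match` (logical).
#' @export
replay_manifest <- function(manifest_path, out_dir) {
  m <- read_manifest(manifest_path)
  res <- run_pipeline(m$config, out_dir)
  new_sums <- tools::md5sum(file.path(out_dir, names(m$checksums)))
  res$checksums_match <- identical(unname(new_sums),
                                   unname(m$checksums))
  res
}
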