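# Headline analyses: decoy effect, competition, sensitivity, kint scan --------

#' Quantify the decoy effect of one receptor on another
#'
#' The decoy effect measures receptor competition for a shared ligand pool:
#' the percent increase in active (ligand-bridged) complexes of the target
#' receptor when the competing receptor is removed,
#' \deqn{100 \times \frac{[\mathrm{act}]_{removed-} - [\mathrm{act}]_{removed+}}
#'       {[\mathrm{act}]_{removed+}}}
#' Both scenarios are pre-simulated independently (the deletion is applied
#' before pre-simulation, so two self-consistent steady states are
#' compared).
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param ligand ligand name.
#' @param dose_ng_ml dose (ng/mL); may be a vector.
#' @param time_s evaluation time after ligand addition (s).
#' @param target receptor whose activation is read out ("R1" or "R2").
#' @param removed receptor deleted in the comparison scenario.
#' @param location "surface", "internal" or "whole_cell".
#' @param init,init_removed optional pre-simulated states to reuse for the
#'   baseline and deletion scenarios.
#' @param control integrator settings.
#' @return tibble (target, removed, ligand, dose_ng_ml, time_s, location,
#'   active_with, active_without, decoy_pct).
#' @export
decoy_effect <- function(network, params, ligand, dose_ng_ml,
                         time_s = 4 * 3600, target = "R2", removed = "R1",
                         location = "whole_cell",
                         init = NULL, init_removed = NULL,
                         control = sim_control()) {
  if (target == removed) stop("target and removed must differ", call. = FALSE)
  times <- sort(unique(c(0, time_s)))
  if (is.null(init)) init <- presimulate(network, params)
  params_rm <- apply_perturbation(params, list(kind = "receptor_deletion",
                                               target = removed))
  if (is.null(init_removed)) init_removed <- presimulate(network, params_rm)
  out <- lapply(dose_ng_ml, function(dd) {
    tr_with <- simulate_ligand_treatment(network, params, ligand, dd,
                                         times = times, init = init,
                                         control = control)
    tr_without <- simulate_ligand_treatment(network, params_rm, ligand, dd,
                                            times = times, init = init_removed,
                                            control = control)
    ti <- match(time_s, times)
    a_with <- active_complexes(tr_with, target, location)$value[ti]
    a_without <- active_complexes(tr_without, target, location)$value[ti]
    if (a_with == 0)
      stop("active ", target, " is zero in the baseline scenario",
           call. = FALSE)
    tibble::tibble(target = target, removed = removed, ligand = ligand,
                   dose_ng_ml = dd, time_s = time_s, location = location,
                   active_with = a_with, active_without = a_without,
                   decoy_pct = 100 * (a_without - a_with) / a_with)
  })
  dplyr::bind_rows(out)
}

#' Normalized local sensitivity of a model output to a parameter
#'
#' Runs a baseline and a perturbed simulation and reports the percentage
#' change in the output divided by the percentage change in the parameter:
#' 0 means no sensitivity, +1 a linear relationship, negative values an
#' inverse relationship. The default perturbation is a one-sided five-fold
#' increase; \code{symmetric = TRUE} averages the up- and down-scaled
#' estimates for robustness checks.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param parameter parameter name as understood by [scale_parameter()]
#'   (e.g. \code{"R2.kint"}, \code{"ligated.R2.kint"}).
#' @param output output descriptor: list(receptor, metric = "total" or
#'   "active", location, time_s).
#' @param fold fold change applied (default 5).
#' @param ligand,dose_ng_ml treatment condition.
#' @param symmetric also evaluate a 1/fold scaling and average.
#' @param init optional pre-simulated baseline state (reused only when the
#'   parameter does not alter the pre-ligand steady state).
#' @param control integrator settings.
#' @return tibble (parameter, output, fold, sensitivity, baseline, perturbed).
#' @export
local_sensitivity <- function(network, params, parameter, output,
                              fold = 5, ligand = "V165", dose_ng_ml = 50,
                              symmetric = FALSE, init = NULL,
                              control = sim_control()) {
  stopifnot(fold > 0, fold != 1)
  out_name <- paste(output$receptor, output$metric, output$location,
                    sep = "_")
  read_out <- function(p_i) {
    tr <- simulate_ligand_treatment(network, p_i, ligand, dose_ng_ml,
                                    times = sort(unique(c(0, output$time_s))),
                                    init = if (is.null(init)) NULL else
                                      presim_for(p_i), control = control)
    ti <- match(output$time_s, tr$times)
    if (output$metric == "total")
      aggregate_receptor(tr, output$receptor, output$location)$value[ti]
    else
      active_complexes(tr, output$receptor, output$location)$value[ti]
  }
  # ligated-complex multipliers do not alter the no-ligand steady state, so
  # the baseline pre-simulation can be reused; unligated trafficking
  # parameters change the steady state and force a fresh pre-simulation
  presim_for <- function(p_i) {
    if (startsWith(parameter, "ligated.")) init else presimulate(network, p_i)
  }
  base <- read_out(params)
  if (base == 0) stop("baseline output is zero; sensitivity undefined",
                      call. = FALSE)
  sens_one <- function(f) {
    p2 <- scale_parameter(params, parameter, f)
    pert <- read_out(p2)
    ((pert - base) / base) / (f - 1)
  }
  s <- sens_one(fold)
  if (symmetric) s <- mean(c(s, sens_one(1 / fold)))
  out_time <- output$time_s
  tibble::tibble(parameter = parameter, output = out_name,
                 time_s = out_time, fold = fold, sensitivity = s,
                 baseline = base)
}

# the trafficking parameters scanned in the one-at-a-time analysis
ligated_parameter_grid <- function(receptors = c("R1", "R2", "N1")) {
  expand.grid(receptor = receptors,
              param = c("kint", "kdeg", "krec4", "k4to11", "krec11"),
              stringsAsFactors = FALSE)
}

#' Predicted western-blot-style localization ratios
#'
#' Simulates a ligand treatment and reduces the trajectory to normalized
#' surface / internal / whole-cell receptor ratios at blot sampling times,
#' each normalized to its time-zero (no ligand) level: the quantity the
#' normalized band intensities estimate.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param ligand,dose_ng_ml treatment.
#' @param receptor receptor blotted.
#' @param times_min sampling times (minutes).
#' @param init optional pre-simulated state.
#' @param control integrator settings.
#' @return tibble (receptor, localization, time_min, ratio).
#' @export
predict_blot_ratios <- function(network, params, ligand = "V165",
                                dose_ng_ml = 50, receptor = "R2",
                                times_min = c(0, 15, 30, 60, 120, 240),
                                init = NULL, control = sim_control()) {
  tr <- simulate_ligand_treatment(network, params, ligand, dose_ng_ml,
                                  times = times_min * 60, init = init,
                                  control = control)
  out <- lapply(c("surface", "internal", "whole_cell"), function(loc) {
    ser <- aggregate_receptor(tr, receptor, loc)
    ser <- normalize_to_control(ser, ser$value[1])
    tibble::tibble(receptor = receptor, localization = loc,
                   time_min = times_min, ratio = ser$value)
  })
  dplyr::bind_rows(out)
}

#' Scan the ligand-bound VEGFR2 internalization multiplier against blot data
#'
#' Simulates the VEGF165a treatment with the ligated-VEGFR2 internalization
#' rate constant set to each candidate multiple of the unligated value,
#' computes the sum of squared residuals against normalized surface,
#' internal and whole-cell VEGFR2 ratios (all localizations weighted
#' equally, measured time points only), and returns the best multiplier with
#' the full SSE profile. Three-fold is the value that the published surface
#' decline selects.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params} (its ligated kint multiplier is
#'   overridden by each candidate).
#' @param data blot dataset tibble with columns (receptor, localization,
#'   time_min, ratio), e.g. from [generate_blot_dataset()]; replicates are
#'   individual rows.
#' @param multipliers candidate fold-increases (must cover 1,2,3,4,8).
#' @param ligand,dose_ng_ml treatment condition.
#' @param init optional pre-simulated state (the multiplier does not affect
#'   the no-ligand steady state, so one pre-simulation serves all).
#' @param control integrator settings.
#' @return object of class \code{kint_scan}: list(best, profile, predictions).
#' @export
internalization_multiplier_scan <- function(network, params, data,
                                            multipliers = c(1, 2, 3, 4, 8),
                                            ligand = "V165", dose_ng_ml = 50,
                                            init = NULL,
                                            control = sim_control()) {
  if (is.null(data) || !nrow(data)) stop("empty blot dataset", call. = FALSE)
  if (is.null(init)) init <- presimulate(network, params)
  receptor <- unique(data$receptor)
  stopifnot(length(receptor) == 1)
  times_min <- sort(unique(data$time_min))
  preds <- lapply(multipliers, function(m) {
    p_m <- params
    i <- p_m$ligated_multipliers$receptor == "R2" &
      p_m$ligated_multipliers$param == "kint"
    p_m$ligated_multipliers$multiplier[i] <- m
    pr <- predict_blot_ratios(network, p_m, ligand, dose_ng_ml, receptor,
                              times_min, init = init, control = control)
    pr$multiplier <- m
    pr
  })
  predictions <- dplyr::bind_rows(preds)
  profile <- scan_sse(predictions, data)
  structure(list(
    best = profile$multiplier[which.min(profile$sse)],
    profile = profile,
    predictions = predictions,
    data = data
  ), class = "kint_scan")
}

#' Sum-of-squared-residuals profile of scan predictions against a dataset
#'
#' Exposed separately so Monte-Carlo recovery studies can resample noisy
#' datasets against one set of simulated prediction curves.
#'
#' @param predictions tibble (localization, time_min, ratio, multiplier).
#' @param data blot dataset tibble (localization, time_min, ratio).
#' @return tibble (multiplier, sse).
#' @export
scan_sse <- function(predictions, data) {
  joined <- dplyr::inner_join(
    data, predictions,
    by = c("receptor", "localization", "time_min"),
    suffix = c("_obs", "_pred"), relationship = "many-to-many")
  if (!nrow(joined)) stop("no overlap between data and predictions",
                          call. = FALSE)
  dplyr::summarise(dplyr::group_by(joined, .data$multiplier),
                   sse = sum((.data$ratio_obs - .data$ratio_pred)^2),
                   .groups = "drop")
}

#' @export
print.kint_scan <- function(x, ...) {
  cat("<kint_scan> best multiplier:", x$best, "\n")
  print(as.data.frame(x$profile), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.kint_scan <- function(x, ...) x$profile

#' @export
glance.kint_scan <- function(x, ...) {
  tibble::tibble(best_multiplier = x$best,
                 min_sse = min(x$profile$sse),
                 n_multipliers = nrow(x$profile))
}

#' Two-ligand competition grid
#'
#' Simulates co-administration of two ligands over a dose grid (zero rows
#' and columns are the single-ligand references) and reports a readout at
#' one time and location. A companion column gives the percent reduction of
#' the readout relative to the corresponding single-ligand reference.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param ligand_a,ligand_b the two ligands.
#' @param doses_a,doses_b dose grids (ng/mL); 0 entries are references.
#' @param time_s evaluation time (s), default two hours.
#' @param location "surface", "internal" or "whole_cell".
#' @param readouts any of "active_R2_by_a", "active_R1_by_a",
#'   "active_R1_by_b", "free_a", "free_b"; all are computed from the same
#'   trajectories.
#' @param init optional pre-simulated state.
#' @param control integrator settings.
#' @return tibble (dose_a, dose_b, readout, location, time_s, value,
#'   reference, reduction_pct). \code{reference} is the single-ligand value
#'   at the same dose of the readout's own ligand; \code{reduction_pct} is
#'   100 (reference - value) / reference.
#' @export
competition_grid <- function(network, params, ligand_a = "V165",
                             ligand_b = "P1",
                             doses_a = c(0, 5, 50, 150),
                             doses_b = c(0, 5, 50, 150),
                             time_s = 2 * 3600,
                             location = "whole_cell",
                             readouts = "active_R1_by_a",
                             init = NULL, control = sim_control()) {
  all_readouts <- c("active_R2_by_a", "active_R1_by_a", "active_R1_by_b",
                    "free_a", "free_b")
  readouts <- match.arg(readouts, all_readouts, several.ok = TRUE)
  if (is.null(init)) init <- presimulate(network, params)
  doses_a <- sort(unique(c(0, doses_a)))
  doses_b <- sort(unique(c(0, doses_b)))
  times <- sort(unique(c(0, time_s)))
  eval_one <- function(da, db) {
    tr <- simulate_ligand_treatment(network, params,
                                    ligand = c(ligand_a, ligand_b),
                                    dose_ng_ml = c(da, db),
                                    times = times, init = init,
                                    control = control)
    ti <- match(time_s, times)
    vapply(readouts, function(ro) switch(ro,
      active_R2_by_a = active_complexes(tr, "R2", location,
                                        ligand = ligand_a)$value[ti],
      active_R1_by_a = active_complexes(tr, "R1", location,
                                        ligand = ligand_a)$value[ti],
      active_R1_by_b = active_complexes(tr, "R1", location,
                                        ligand = ligand_b)$value[ti],
      free_a = free_ligand(tr, ligand_a, location)$value[ti],
      free_b = free_ligand(tr, ligand_b, location)$value[ti]), 1)
  }
  grid <- expand.grid(dose_a = doses_a, dose_b = doses_b)
  vals <- mapply(eval_one, grid$dose_a, grid$dose_b)
  vals <- matrix(vals, nrow = length(readouts),
                 dimnames = list(readouts, NULL))
  out <- lapply(readouts, function(ro) {
    g <- grid
    g$value <- vals[ro, ]
    # percent reduction vs the single-ligand reference of the readout's own
    # ligand
    own_is_a <- ro %in% c("active_R2_by_a", "active_R1_by_a", "free_a")
    ref_for <- function(da, db) {
      if (own_is_a) g$value[g$dose_a == da & g$dose_b == 0]
      else g$value[g$dose_a == 0 & g$dose_b == db]
    }
    g$reference <- mapply(ref_for, g$dose_a, g$dose_b)
    tibble::tibble(ligand_a = ligand_a, ligand_b = ligand_b,
                   dose_a = g$dose_a, dose_b = g$dose_b,
                   readout = ro, location = location, time_s = time_s,
                   value = g$value, reference = g$reference,
                   reduction_pct = ifelse(g$reference > 0,
                                          100 * (g$reference - g$value) /
                                            g$reference, NA_real_))
  })
  dplyr::bind_rows(out)
}

#' Single-ligand dose-response tables
#'
#' Per-dose trajectories reduced to readout tables, optionally under
#' receptor deletions (the NRP1/VEGFR2-deletion comparisons).
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param ligand ligand name.
#' @param doses_ng_ml dose grid (ng/mL).
#' @param times_s evaluation times (s).
#' @param readouts character vector: \code{"<receptor>_total_<location>"},
#'   \code{"<receptor>_active_<location>"} or \code{"free_<ligand>_<location>"}
#'   with location one of surface/internal/whole_cell.
#' @param deletions receptors deleted throughout.
#' @param init optional pre-simulated state.
#' @param control integrator settings.
#' @return tibble (ligand, dose_ng_ml, time_s, readout, value).
#' @export
dose_response <- function(network, params, ligand, doses_ng_ml,
                          times_s = c(900, 3600, 14400),
                          readouts = c("R2_active_whole_cell",
                                       "R1_active_whole_cell"),
                          deletions = character(), init = NULL,
                          control = sim_control()) {
  stopifnot(all(doses_ng_ml >= 0))
  for (d in deletions)
    params <- apply_perturbation(params, list(kind = "receptor_deletion",
                                              target = d))
  if (is.null(init)) init <- presimulate(network, params)
  times <- sort(unique(c(0, times_s)))
  out <- lapply(doses_ng_ml, function(dd) {
    tr <- simulate_ligand_treatment(network, params, ligand, dd,
                                    times = times, deletions = deletions,
                                    init = init, control = control)
    rows <- lapply(readouts, function(ro) {
      ser <- parse_readout(ro)(tr)
      tibble::tibble(ligand = ligand, dose_ng_ml = dd,
                     time_s = times_s, readout = ro,
                     value = ser$value[match(times_s, tr$times)])
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

parse_readout <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  loc <- if (parts[length(parts)] == "cell")
    paste(parts[length(parts) - 1], parts[length(parts)], sep = "_")
  else parts[length(parts)]
  if (parts[1] == "free") {
    lig <- parts[2]
    return(function(tr) free_ligand(tr, lig, loc))
  }
  receptor <- parts[1]; metric <- parts[2]
  if (metric == "total") function(tr) aggregate_receptor(tr, receptor, loc)
  else if (metric == "active") function(tr) active_complexes(tr, receptor, loc)
  else stop("cannot parse readout: ", name, call. = FALSE)
}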