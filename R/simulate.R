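# Pre-simulation, protocols, and event-driven integration ---------------------

#' Integrator control settings
#'
#' Defaults follow the package's numerical policy: absolute tolerance of
#' 1e-3 molecules/cell, relative tolerance 1e-8; negative excursions are
#' clipped only below the absolute tolerance.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (#/cell).
#' @param hmax maximum step (s).
#' @param hmin minimum step (s).
#' @return list of control settings.
#' @export
sim_control <- function(rtol = 1e-8, atol = 1e-3, hmax = Inf, hmin = 1e-10) {
  list(rtol = rtol, atol = atol, hmax = hmax, hmin = hmin)
}

ligand_species_id <- function(network, ligand, compartment = "surface") {
  sp <- network$species
  i <- which(sp$label == ligand & sp$compartment == compartment &
               sp$n_monomers == 1L)
  if (!length(i)) stop("no free species for ligand ", ligand, call. = FALSE)
  sp$id[i]
}

#' Pre-simulate to the no-ligand steady state
#'
#' Integrates the synthesis / trafficking / degradation / coupling system
#' with no ligand present until the receptor distribution is stationary,
#' then polishes the state with damped Newton iteration on the analytic
#' Jacobian (degraded pools and matrix species are excluded from the root
#' solve: the former grow secularly, the latter are structurally zero
#' without ligand). Convergence demands a relative time-derivative below
#' \code{tol_rel_per_h} per hour for every species.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param t_burnin integration time before the Newton polish (s).
#' @param tol_rel_per_h convergence tolerance, relative derivative per hour.
#' @param control integrator settings, see [sim_control()].
#' @return steady-state vector (#/cell), one entry per species row, with the
#'   degraded pools zeroed.
#' @export
presimulate <- function(network, params, t_burnin = 48 * 3600,
                        tol_rel_per_h = 1e-8,
                        control = sim_control(rtol = 1e-6)) {
  sp <- network$species
  m <- model_arrays(network, params)
  y0 <- numeric(nrow(sp))
  # seed surface receptors near their baselines to shorten the transient
  for (r in intersect(network$rules$receptors, names(params$rtot))) {
    i <- which(sp$label == r & sp$compartment == "surface")
    y0[i] <- params$rtot[[r]]
  }
  res <- .rosenbrock_integrate(m, y0, c(0, t_burnin),
                               control$rtol, control$atol,
                               control$hmax, control$hmin)
  y <- res$y[2, ]
  keep <- which(sp$compartment %in% COMPARTMENTS & !sp$has_matrix)
  # structurally absent species (deleted receptors, absent ligands) sit at
  # zero (up to roundoff) with zero derivative; excluding them keeps the
  # Newton Jacobian nonsingular
  f0 <- .mass_action_rhs(m, y)
  absent <- y[keep] < 1e-6 & abs(f0[keep]) < 1e-12
  y[keep[absent]] <- 0
  keep <- keep[!absent]
  ns <- .steady_newton(m, y, keep - 1L, 1e-12, 50L)
  y <- as.vector(ns$y)
  y[sp$compartment == "degraded"] <- 0
  f <- .mass_action_rhs(m, y)
  rel <- abs(f[keep]) * 3600 / pmax(abs(y[keep]), 1)
  if (max(rel) > tol_rel_per_h) {
    worst <- keep[which.max(rel)]
    stop(sprintf(
      "pre-simulation did not converge: worst species %s@%s (relative derivative %.3g/h)",
      sp$label[worst], sp$compartment[worst], max(rel)), call. = FALSE)
  }
  y
}

#' Define a simulation protocol
#'
#' A protocol is a pre-simulation followed by a timeline of events relative
#' to ligand addition at t = 0. Three event kinds are supported:
#' \code{ligand_step} (sudden increase of the extracellular ligand
#' concentration by \code{dose_ng_ml}), \code{knockdown} (sudden scaling of
#' trafficking parameters, e.g. siRNA depletion of Rab4a/Rab11a), and
#' \code{receptor_deletion} (receptor absent: applied before pre-simulation,
#' with zero production and zero initial levels).
#'
#' @param events tibble or data frame with columns \code{time_s},
#'   \code{kind} (one of "ligand_step", "knockdown", "receptor_deletion"),
#'   and the event payload columns \code{ligand}, \code{dose_ng_ml},
#'   \code{target}, \code{scale} (unused entries NA).
#' @param times output grid (s, relative to ligand addition at t = 0).
#' @return object of class \code{vegfr_protocol}.
#' @export
simulation_protocol <- function(events, times = seq(0, 4 * 3600, by = 60)) {
  ev <- tibble::as_tibble(events)
  for (col in c("ligand", "target")) if (is.null(ev[[col]])) ev[[col]] <- NA_character_
  for (col in c("dose_ng_ml", "scale")) if (is.null(ev[[col]])) ev[[col]] <- NA_real_
  if (is.null(ev$time_s)) ev$time_s <- 0
  bad <- setdiff(ev$kind, c("ligand_step", "knockdown", "receptor_deletion"))
  if (length(bad)) stop("unknown event kind: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ev <- ev[order(ev$time_s), ]
  structure(list(events = ev, times = sort(unique(times))),
            class = "vegfr_protocol")
}

#' Convenience protocol: a single ligand step at t = 0
#'
#' @param ligand ligand name.
#' @param dose_ng_ml dose (ng/mL).
#' @param times output grid (s).
#' @param deletions receptors deleted throughout (pre-simulation included).
#' @return a \code{vegfr_protocol}.
#' @export
ligand_step_protocol <- function(ligand, dose_ng_ml,
                                 times = seq(0, 4 * 3600, by = 60),
                                 deletions = character()) {
  nd <- length(deletions); nl <- length(ligand)
  ev <- tibble::tibble(
    time_s = c(rep(-Inf, nd), rep(0, nl)),
    kind = c(rep("receptor_deletion", nd), rep("ligand_step", nl)),
    ligand = c(rep(NA_character_, nd), ligand),
    dose_ng_ml = c(rep(NA_real_, nd), dose_ng_ml),
    target = c(deletions, rep(NA_character_, nl)),
    scale = rep(NA_real_, nd + nl)
  )
  simulation_protocol(ev, times)
}

#' Apply a perturbation event to a parameter set
#'
#' Knockdown of \code{"Rab4a"} scales both exits from the Rab4a compartment
#' toward recycling (\code{krec4} and \code{k4to11}) for every receptor;
#' \code{"Rab11a"} scales \code{krec11}. A named trafficking parameter
#' (\code{"R2.kint"}, \code{"ligated.R2.kint"}, ...) is scaled directly.
#' Receptor deletion zeroes the receptor's production (initial levels are
#' zeroed by the pre-simulation).
#'
#' @param params a \code{vegfr_params}.
#' @param event one-row event (list or tibble row) with \code{kind},
#'   \code{target}, \code{scale}.
#' @return modified \code{vegfr_params}.
#' @export
apply_perturbation <- function(params, event) {
  kind <- event$kind
  if (kind == "knockdown") {
    target <- event$target
    scale <- event$scale
    stopifnot(is.finite(scale), scale >= 0)
    if (identical(target, "Rab4a")) {
      for (r in params$trafficking$receptor) {
        params <- scale_parameter(params, paste0(r, ".krec4"), scale)
        params <- scale_parameter(params, paste0(r, ".k4to11"), scale)
      }
    } else if (identical(target, "Rab11a")) {
      for (r in params$trafficking$receptor)
        params <- scale_parameter(params, paste0(r, ".krec11"), scale)
    } else {
      params <- scale_parameter(params, target, scale)
    }
  } else if (kind == "receptor_deletion") {
    if (!event$target %in% params$trafficking$receptor)
      stop("unknown receptor: ", event$target, call. = FALSE)
    i <- params$trafficking$receptor == event$target
    params$trafficking$kprod[i] <- 0
  } else if (kind != "ligand_step") {
    stop("unknown event kind: ", kind, call. = FALSE)
  }
  params
}

#' Simulate a protocol from the pre-simulated steady state
#'
#' Runs the pre-simulation (with any receptor deletions applied first), then
#' integrates the stiff system across the event timeline. Ligand steps are
#' state discontinuities applied exactly at the event time; knockdowns are
#' parameter discontinuities. Output is sampled on the protocol grid.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param protocol a \code{vegfr_protocol}.
#' @param init optional initial state (defaults to [presimulate()] under the
#'   deletion-adjusted parameters).
#' @param control integrator settings, see [sim_control()].
#' @return object of class \code{vegfr_trajectory}: times (s), state matrix
#'   (#/cell), species table, and provenance (parameters and protocol).
#' @export
simulate_protocol <- function(network, params, protocol, init = NULL,
                              control = sim_control()) {
  stopifnot(inherits(protocol, "vegfr_protocol"))
  ev <- protocol$events
  # deletions shape the pre-simulation
  for (i in which(ev$kind == "receptor_deletion"))
    params <- apply_perturbation(params, ev[i, ])
  if (is.null(init)) init <- presimulate(network, params)
  y <- init
  times <- protocol$times
  t0 <- min(times[1], ev$time_s[is.finite(ev$time_s)], 0)
  out <- matrix(NA_real_, length(times), length(y))
  pending <- ev[is.finite(ev$time_s) & ev$time_s >= t0, , drop = FALSE]
  m <- model_arrays(network, params)
  t_now <- t0
  # event application at t_now
  apply_events_at <- function(tt) {
    hit <- which(pending$time_s == tt)
    for (i in hit) {
      e <- pending[i, ]
      if (e$kind == "ligand_step") {
        idx <- ligand_species_id(network, e$ligand)
        y[idx] <<- y[idx] + ligand_dose_to_count(e$dose_ng_ml, e$ligand,
                                                 params$geometry)
      } else if (e$kind == "knockdown") {
        params <<- apply_perturbation(params, e)
        m <<- model_arrays(network, params)
      }
    }
    if (length(hit)) pending <<- pending[-hit, , drop = FALSE]
  }
  apply_events_at(t_now)
  # the grid point at t0 reports the post-event state (a ligand step at
  # t = 0 is part of the t = 0 condition; receptor levels are unaffected)
  if (times[1] == t_now) out[1, ] <- y
  # integration legs between events
  stops <- sort(unique(c(times, pending$time_s[pending$kind != "receptor_deletion"])))
  stops <- stops[stops > t_now]
  for (tt in stops) {
    res <- .rosenbrock_integrate(m, y, c(t_now, tt), control$rtol,
                                 control$atol, control$hmax, control$hmin)
    y <- res$y[2, ]
    if (min(y) < -100 * control$atol)
      stop(sprintf("negative state beyond tolerance at t = %g (min %.3g)",
                   tt, min(y)), call. = FALSE)
    t_now <- tt
    apply_events_at(t_now)
    ti <- match(tt, times)
    if (!is.na(ti)) out[ti, ] <- y
  }
  structure(list(times = times, y = out, species = network$species,
                 params = params, protocol = protocol),
            class = "vegfr_trajectory")
}

#' Simulate a single-ligand treatment
#'
#' The standard experiment: pre-simulate to steady state, add the ligand as
#' a step at t = 0, follow for several hours.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param ligand ligand name(s).
#' @param dose_ng_ml dose(s), ng/mL, matched to \code{ligand}.
#' @param times output grid (s).
#' @param deletions receptors deleted throughout.
#' @param init optional pre-simulated state to reuse.
#' @param control integrator settings.
#' @return a \code{vegfr_trajectory}.
#' @export
simulate_ligand_treatment <- function(network, params, ligand, dose_ng_ml,
                                      times = seq(0, 4 * 3600, by = 120),
                                      deletions = character(), init = NULL,
                                      control = sim_control()) {
  keep <- dose_ng_ml > 0
  prot <- ligand_step_protocol(ligand[keep], dose_ng_ml[keep], times,
                               deletions)
  simulate_protocol(network, params, prot, init = init, control = control)
}

#' @export
print.vegfr_trajectory <- function(x, ...) {
  cat("<vegfr_trajectory>", length(x$times), "time points x",
      ncol(x$y), "species;",
      sprintf("t = [%g, %g] s\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x a \code{vegfr_trajectory}.
#' @param ... unused.
#' @return tibble (time_s, species_id, label, compartment, count_per_cell).
#' @export
as_tibble.vegfr_trajectory <- function(x, ...) {
  sp <- x$species
  tibble::tibble(
    time_s = rep(x$times, times = nrow(sp)),
    species_id = rep(sp$id, each = length(x$times)),
    label = rep(sp$label, each = length(x$times)),
    compartment = rep(sp$compartment, each = length(x$times)),
    count_per_cell = as.vector(x$y)
  )
}

#' Audit monomer conservation along a trajectory
#'
#' For every monomer kind, the total over all species (including the
#' degraded pools) changes only by synthesis. Returns the worst absolute
#' discrepancy between the observed change and the integrated synthesis
#' input, per monomer kind.
#'
#' @param traj a \code{vegfr_trajectory}.
#' @return tibble (monomer, max_abs_error, scale) where scale is the largest
#'   total observed for that monomer.
#' @export
conservation_audit <- function(traj) {
  sp <- traj$species
  kinds <- c("R1", "R2", "N1", "V165", "V121", "P1", "P2")
  kinds <- kinds[kinds %in% unlist(lapply(sp$template, function(t) t$kinds))]
  kprod <- stats::setNames(traj$params$trafficking$kprod,
                           traj$params$trafficking$receptor)
  # ligand steps add mass; account for them
  ev <- traj$protocol$events
  out <- lapply(kinds, function(k) {
    w <- vapply(sp$template, function(t) sum(t$kinds == k), 1)
    tot <- as.vector(traj$y %*% w)
    t_rel <- traj$times - traj$times[1]
    expected <- tot[1] +
      if (k %in% names(kprod)) kprod[[k]] * t_rel else 0
    if (k %in% ev$ligand) {
      for (i in which(ev$ligand == k & ev$kind == "ligand_step")) {
        if (ev$time_s[i] <= traj$times[1]) next  # already in the t0 snapshot
        add <- ligand_dose_to_count(ev$dose_ng_ml[i], k, traj$params$geometry)
        expected <- expected + add * (traj$times >= ev$time_s[i])
      }
    }
    tibble::tibble(monomer = k,
                   max_abs_error = max(abs(tot - expected)),
                   scale = max(tot))
  })
  dplyr::bind_rows(out)
}

#' Calibrate receptor production to the baseline surface levels
#'
#' Production rates are identified so that the pre-simulated steady state
#' reproduces the configured baseline surface receptor levels; the
#' closed-form single-receptor values are refined by fixed-point iteration
#' against the full coupled model (dimerization and co-trafficking shift
#' the uncoupled solution slightly).
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param iters fixed-point iterations.
#' @return \code{vegfr_params} with calibrated \code{kprod}.
#' @export
calibrate_production <- function(network, params, iters = 4) {
  for (it in seq_len(iters)) {
    y <- presimulate(network, params)
    for (r in params$trafficking$receptor) {
      achieved <- receptor_total(network, y, r, "surface")
      i <- params$trafficking$receptor == r
      params$trafficking$kprod[i] <-
        params$trafficking$kprod[i] * params$rtot[[r]] / achieved
    }
  }
  params
}

#' Stoichiometry-weighted receptor total in one location, from a state vector
#'
#' @param network a \code{vegfr_network}.
#' @param state numeric state vector (#/cell).
#' @param receptor "R1", "R2" or "N1".
#' @param location "surface", "internal" or "whole_cell".
#' @return total receptor count (#/cell).
#' @export
receptor_total <- function(network, state, receptor,
                           location = c("surface", "internal", "whole_cell")) {
  location <- match.arg(location)
  sp <- network$species
  comps <- switch(location, surface = "surface",
                  internal = c("rab4", "rab11"),
                  whole_cell = COMPARTMENTS)
  w <- vapply(sp$template, function(t) sum(t$kinds == receptor), 1)
  sel <- sp$compartment %in% comps
  sum(state[sel] * w[sel])
}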