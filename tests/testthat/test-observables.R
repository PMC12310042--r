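# Observable aggregation, fluxes, Scatchard ------------------------------------

make_state_traj <- function(net, setter) {
  y <- numeric(nrow(net$species))
  y <- setter(y, net$species)
  structure(list(times = 0, y = matrix(y, 1), species = net$species,
                 params = default_params_cached(),
                 protocol = simulation_protocol(
                   tibble::tibble(time_s = numeric(), kind = character()),
                   times = 0)),
            class = "vegfr_trajectory")
}

test_that("receptor aggregation is stoichiometry-weighted and excludes the
          degraded pool", {
  net <- full_network()
  # a single delta-closed VEGFR2 dimer contributes two VEGFR2
  tr <- make_state_traj(net, function(y, sp) {
    y[sp$id[sp$label == "2xR2.V165[delta]" & sp$compartment == "surface"]] <- 1
    y[sp$id[sp$label == "R2" & sp$compartment == "degraded"]] <- 100
    y
  })
  expect_equal(aggregate_receptor(tr, "R2", "surface")$value, 2)
  expect_equal(aggregate_receptor(tr, "R2", "whole_cell")$value, 2)
  expect_equal(aggregate_receptor(tr, "R1", "surface")$value, 0)
  # empty state
  tr0 <- make_state_traj(net, function(y, sp) y)
  expect_equal(aggregate_receptor(tr0, "R2", "whole_cell")$value, 0)
})

test_that("whole-cell levels equal surface plus internal everywhere", {
  tr <- v165_trajectory()
  for (r in c("R1", "R2", "N1")) {
    s <- aggregate_receptor(tr, r, "surface")$value
    i <- aggregate_receptor(tr, r, "internal")$value
    w <- aggregate_receptor(tr, r, "whole_cell")$value
    expect_equal(w, s + i)
  }
})

test_that("active complexes require a doubly-bound ligand and localize as
          reported", {
  bl <- baseline_state()
  net <- full_network()
  # no ligand: no active complexes anywhere, ever
  tr0 <- simulate_ligand_treatment(net, bl$params, "V165", 0,
                                   times = c(0, 3600), init = bl$init)
  expect_true(all(active_complexes(tr0, "R1", "whole_cell")$value == 0))
  expect_true(all(active_complexes(tr0, "R2", "whole_cell")$value == 0))
  # VEGF165a: more signal-capable VEGFR2 complexes inside than on the surface
  tr <- v165_trajectory()
  i1h <- match(3600, tr$times); i4h <- match(14400, tr$times)
  for (ti in c(i1h, i4h)) {
    expect_gt(active_complexes(tr, "R2", "internal")$value[ti],
              active_complexes(tr, "R2", "surface")$value[ti])
  }
  # PLGF1 binds only VEGFR1 yet drives predominantly internal ligation
  trp <- simulate_ligand_treatment(net, bl$params, "P1", 50,
                                   times = c(0, 3600, 14400), init = bl$init)
  expect_gt(active_complexes(trp, "R1", "internal")$value[3],
            2 * active_complexes(trp, "R1", "surface")$value[3])
  # active complexes never exceed half the ligated receptors
  sp <- net$species
  for (r in c("R1", "R2")) {
    w_lig <- vapply(sp$template, function(t)
      if (any(t$bonds[, 3] == 1L)) sum(t$kinds == r) else 0, 1)
    for (loc in c("surface", "internal")) {
      comps <- if (loc == "surface") "surface" else c("rab4", "rab11")
      sel <- sp$compartment %in% comps
      ligated <- as.vector(tr$y[, sp$id[sel]] %*% w_lig[sel])
      act <- active_complexes(tr, r, loc)$value
      expect_true(all(act <= floor(ligated / 2) + 1e-9))
    }
  }
})

test_that("normalization to control is a pointwise ratio with guarded zeros", {
  tr <- v165_trajectory()
  s <- aggregate_receptor(tr, "R2", "surface")
  expect_equal(normalize_to_control(s, s)$value, rep(1, nrow(s)))
  n1 <- normalize_to_control(s, s$value[1])
  expect_equal(n1$value[1], 1)
  expect_true(all(n1$value <= 1 + 1e-9))  # declining under 3x internalization
  # idempotent on an already-normalized series with unit control
  expect_equal(normalize_to_control(n1, 1)$value, n1$value)
  expect_error(normalize_to_control(s, 0), "zero")
})

test_that("transport fluxes balance at the pre-ligand steady state", {
  bl <- baseline_state()
  net <- full_network()
  fl <- compute_fluxes(net, bl$params, bl$init)
  get <- function(r, proc) fl$flux[fl$receptor == r & fl$process == proc]
  for (r in c("R1", "R2", "N1")) {
    # surface: in = production + both recycling routes, out = internalization
    expect_equal(get(r, "production") + get(r, "recycling_rab4") +
                   get(r, "recycling_rab11"),
                 get(r, "internalization"), tolerance = 1e-6)
    # early endosome: in = internalization, out = degradation + recycling +
    # transfer
    expect_equal(get(r, "internalization"),
                 get(r, "degradation") + get(r, "recycling_rab4") +
                   get(r, "transfer_rab11"), tolerance = 1e-6)
    # recycling endosome: transfer in = recycling out
    expect_equal(get(r, "transfer_rab11"), get(r, "recycling_rab11"),
                 tolerance = 1e-6)
    # production flux equals the configured kprod exactly
    expect_equal(get(r, "production"),
                 bl$params$trafficking$kprod[
                   bl$params$trafficking$receptor == r])
  }
  # zero state: all fluxes zero except zeroth-order production
  fl0 <- compute_fluxes(net, bl$params, numeric(nrow(net$species)))
  expect_true(all(fl0$flux[fl0$process != "production"] == 0))
})

test_that("the one-step 1:1 Scatchard is an exact straight line", {
  p <- default_params_cached()
  s <- scatchard(p, "R2", "one_step_121")
  fit <- stats::lm(bound_over_free ~ bound, data = s)
  expect_gt(summary(fit)$r.squared, 1 - 1e-10)
  kon_cell <- volumetric_rate_to_percell(1e7, p$geometry$volume_fl[["surface"]])
  kd_cell <- 1e-3 / kon_cell
  f <- scatchard_fit(s)
  expect_equal(f$slope, -1 / kd_cell, tolerance = 1e-6)
  # x-intercept: half the receptors in ligand units (one ligand per dimer)
  expect_equal(f$x_intercept, p$rtot[["R2"]] / 2, tolerance = 1e-6)
  # dilute limit of bound/free approaches sites / KD
  dil <- scatchard(p, "R2", "one_step_121", doses_ng_ml = 1e-6)
  expect_equal(dil$bound_over_free, p$rtot[["R2"]] / 2 / kd_cell,
               tolerance = 1e-4)
})

test_that("a pure one-site binding subnetwork matches the closed-form 1:1
          equilibrium across a 100-fold dose range", {
  # VEGF165a binding NRP1 engages a single site with the measured constants
  p <- default_params_cached()
  rules <- vegfr_rules(ligands = "V165", receptors = "N1",
                       ligand_receptor = list(V165 = character()),
                       ligand_nrp1 = "V165", ligand_matrix = character(),
                       rr_pairs = list(), r1_n1_coupling = FALSE,
                       include_matrix = FALSE)
  p0 <- p
  p0$trafficking[, c("kint", "kdeg", "krec4", "k4to11", "krec11", "kprod")] <- 0
  net <- build_network(rules, p0)
  sp <- net$species
  m <- vegftraffic:::model_arrays(net, p0)
  b <- p$binding_1to1[p$binding_1to1$ligand == "V165" &
                        p$binding_1to1$partner == "N1", ]
  kon_cell <- volumetric_rate_to_percell(b$kon_M, p$geometry$volume_fl[["surface"]])
  kd_cell <- b$koff / kon_cell
  n1_tot <- p$rtot[["N1"]]
  for (dose in c(0.5, 5, 50)) {
    y0 <- numeric(nrow(sp))
    y0[sp$id[sp$label == "N1" & sp$compartment == "surface"]] <- n1_tot
    l0 <- ligand_dose_to_count(dose, "V165", p$geometry)
    y0[sp$id[sp$label == "V165" & sp$compartment == "surface"]] <- l0
    y <- vegftraffic:::.rosenbrock_integrate(m, y0, c(0, 3 * 3600),
                                             1e-10, 1e-6, Inf, 1e-10)$y[2, ]
    bound <- y[sp$id[sp$label == "N1.V165" & sp$compartment == "surface"]]
    qa <- 1; qb <- -(l0 + n1_tot + kd_cell); qc <- l0 * n1_tot
    expected <- (-qb - sqrt(qb^2 - 4 * qa * qc)) / 2
    expect_equal(bound, expected, tolerance = 0.05)
  }
})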