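# Pre-simulation and event-driven integration ----------------------------------

test_that("pre-simulation matches the closed-form single-receptor solution", {
  # one receptor, no coupling, no ligand: a linear 3-compartment system
  # whose steady state we solve independently with base R linear algebra
  rules <- vegfr_rules(ligands = "P1", receptors = "R1",
                       ligand_receptor = list(P1 = character()),
                       ligand_nrp1 = character(), ligand_matrix = character(),
                       rr_pairs = list(), r1_n1_coupling = FALSE,
                       include_matrix = FALSE)
  p <- default_params_cached()
  net <- build_network(rules, p)
  y <- presimulate(net, p)
  tr <- p$trafficking[p$trafficking$receptor == "R1", ]
  A <- with(tr, rbind(
    c(-kint, krec4, krec11),
    c(kint, -(kdeg + krec4 + k4to11), 0),
    c(0, k4to11, -krec11)))
  expected <- solve(A, c(-tr$kprod, 0, 0))
  sp <- net$species
  got <- vapply(c("surface", "rab4", "rab11"), function(cc)
    y[sp$id[sp$label == "R1" & sp$compartment == cc]], 1)
  expect_equal(unname(got), expected, tolerance = 1e-8)
})

test_that("zero production gives the all-zero steady state", {
  p <- default_params_cached()
  p$trafficking$kprod <- c(0, 0, 0)
  y <- presimulate(full_network(), p)
  expect_lt(max(abs(y)), 1e-3)  # zero to within the absolute tolerance
})

test_that("the full steady state reproduces the baseline receptor asymmetries", {
  bl <- baseline_state()
  net <- full_network()
  y <- bl$init
  # <= 10% of VEGFR1 on the surface; VEGFR2 about half and half; NRP1
  # majority-surface; surface totals at the configured baselines
  fr <- function(r) receptor_total(net, y, r, "surface") /
    receptor_total(net, y, r, "whole_cell")
  expect_lt(fr("R1"), 0.12)
  expect_gt(fr("R2"), 0.4); expect_lt(fr("R2"), 0.6)
  expect_gt(fr("N1"), 0.5)
  for (r in c("R1", "R2", "N1"))
    expect_equal(receptor_total(net, y, r, "surface"),
                 bl$params$rtot[[r]], tolerance = 0.01)
  # VEGFR1 turns over fastest (the least stable receptor)
  turnover <- vapply(c("R1", "R2", "N1"), function(r)
    receptor_total(net, y, r, "whole_cell") /
      bl$params$trafficking$kprod[bl$params$trafficking$receptor == r], 1)
  expect_lt(turnover[["R1"]], turnover[["R2"]])
  expect_lt(turnover[["R1"]], turnover[["N1"]])
})

test_that("non-convergence is reported with the worst species", {
  rules <- vegfr_rules(ligands = "P1", receptors = "R1",
                       ligand_receptor = list(P1 = character()),
                       ligand_nrp1 = character(), ligand_matrix = character(),
                       rr_pairs = list(), r1_n1_coupling = FALSE,
                       include_matrix = FALSE)
  p <- default_params_cached()
  expect_error(
    presimulate(build_network(rules, p), p, t_burnin = 10,
                tol_rel_per_h = 0),
    "did not converge.*R1")
})

test_that("a zero-dose ligand step leaves the steady state untouched", {
  bl <- baseline_state()
  net <- full_network()
  tr <- simulate_ligand_treatment(net, bl$params, "V165", 0,
                                  times = c(0, 3600, 7200), init = bl$init)
  live <- net$species$compartment != "degraded"  # degraded pools accumulate
  for (i in seq_along(tr$times))
    expect_equal(tr$y[i, live], bl$init[live], tolerance = 1e-6)
})

test_that("monomer totals change only by synthesis along a trajectory", {
  audit <- conservation_audit(v165_trajectory())
  expect_true(all(audit$max_abs_error <= 1e-6 * pmax(audit$scale, 1)))
})

test_that("trajectories are invariant to output-grid refinement and to
          splitting a run with a neutral event", {
  bl <- baseline_state()
  net <- full_network()
  coarse <- simulate_ligand_treatment(net, bl$params, "V165", 50,
                                      times = c(0, 7200, 14400),
                                      init = bl$init)
  fine <- simulate_ligand_treatment(net, bl$params, "V165", 50,
                                    times = seq(0, 14400, by = 1800),
                                    init = bl$init)
  i_f <- match(c(0, 7200, 14400), fine$times)
  expect_equal(coarse$y, fine$y[i_f, ], tolerance = 1e-5)
  # a scale-1 knockdown event at 2 h forces an integration split but must
  # not change anything
  ev <- tibble::tibble(time_s = c(0, 7200),
                       kind = c("ligand_step", "knockdown"),
                       ligand = c("V165", NA), dose_ng_ml = c(50, NA),
                       target = c(NA, "Rab4a"), scale = c(NA, 1))
  split <- simulate_protocol(net, bl$params,
                             simulation_protocol(ev, c(0, 7200, 14400)),
                             init = bl$init)
  expect_equal(split$y, coarse$y, tolerance = 1e-6)
})

test_that("receptor deletion zeroes that receptor's species at all times", {
  bl <- baseline_state()
  net <- full_network()
  tr <- simulate_ligand_treatment(net, bl$params, "V165", 50,
                                  times = c(0, 3600, 14400),
                                  deletions = "R1")
  w <- vapply(net$species$template, function(t) sum(t$kinds == "R1"), 1)
  expect_true(all(abs(tr$y %*% w) < 1e-6))
  expect_error(
    apply_perturbation(bl$params, list(kind = "receptor_deletion",
                                       target = "R7")),
    "unknown receptor")
})

test_that("Rab4a/Rab11a knockdown leaves localized receptor levels close to
          control at 1 h and 4 h", {
  bl <- baseline_state()
  net <- full_network()
  ev <- tibble::tibble(
    time_s = c(-18 * 3600, -18 * 3600, 0),
    kind = c("knockdown", "knockdown", "ligand_step"),
    ligand = c(NA, NA, "V165"), dose_ng_ml = c(NA, NA, 50),
    target = c("Rab4a", "Rab11a", NA), scale = c(0.1, 0.1, NA))
  kd <- simulate_protocol(net, bl$params,
                          simulation_protocol(ev, c(0, 3600, 14400)),
                          init = bl$init)
  ctrl <- simulate_ligand_treatment(net, bl$params, "V165", 50,
                                    times = c(0, 3600, 14400),
                                    init = bl$init)
  # the ligand response (levels relative to each arm's own time zero, the
  # experimental normalization) is what the knockdown leaves unchanged
  for (r in c("R1", "R2", "N1")) for (loc in c("surface", "internal")) {
    a <- aggregate_receptor(kd, r, loc)$value
    b <- aggregate_receptor(ctrl, r, loc)$value
    expect_lt(max(abs((a / a[1]) / (b / b[1]) - 1)), 0.15)
  }
})

test_that("as_tibble gives a tidy long trajectory", {
  tr <- v165_trajectory()
  tl <- tibble::as_tibble(tr)
  expect_equal(nrow(tl), length(tr$times) * nrow(tr$species))
  expect_true(all(c("time_s", "species_id", "compartment",
                    "count_per_cell") %in% names(tl)))
})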