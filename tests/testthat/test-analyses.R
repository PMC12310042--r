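# Decoy effect, sensitivity, multiplier scan, competition ----------------------

test_that("decoy effect is zero when the removed receptor is already absent", {
  net <- full_network()
  p <- baseline_state()$params
  p$trafficking$kprod[p$trafficking$receptor == "R1"] <- 0
  d <- decoy_effect(net, p, "V165", 50, time_s = 3600, target = "R2",
                    removed = "R1", location = "whole_cell")
  expect_equal(d$decoy_pct, 0, tolerance = 1e-6)
  expect_error(decoy_effect(net, p, "V165", 50, target = "R2",
                            removed = "R2"), "differ")
})

test_that("decoy scenario labels are antisymmetric up to the denominator", {
  bl <- baseline_state()
  d <- decoy_effect(full_network(), bl$params, "V165", 5, time_s = 3600,
                    location = "whole_cell", init = bl$init)
  d1 <- d$decoy_pct / 100
  d2 <- (d$active_with - d$active_without) / d$active_without
  expect_equal((1 + d1) * (1 + d2), 1, tolerance = 1e-10)
})

test_that("without NRP1, VEGFR1 removal frees ligand for VEGFR2 inside the
          cell but not at the surface", {
  # the reservoir effect in its pure form: NRP1 deleted so that receptor
  # competition for VEGF165a is between VEGFR1 and VEGFR2 alone
  net <- full_network()
  p <- apply_perturbation(baseline_state()$params,
                          list(kind = "receptor_deletion", target = "N1"))
  init <- presimulate(net, p)
  d_int <- decoy_effect(net, p, "V165", c(5, 50), time_s = 4 * 3600,
                        location = "internal", init = init)
  d_surf <- decoy_effect(net, p, "V165", c(5, 50), time_s = 4 * 3600,
                         location = "surface", init = init)
  # intracellular: substantial, and stronger at the sub-saturating dose
  expect_gt(d_int$decoy_pct[1], 20)
  expect_gt(d_int$decoy_pct[1], d_int$decoy_pct[2])
  # surface: essentially no decoy effect (large extracellular reservoir)
  expect_true(all(abs(d_surf$decoy_pct) < 3))
})

test_that("local sensitivity is 1 for a linear input and 0 for a decoupled
          parameter", {
  net <- full_network()
  p <- baseline_state()$params
  out <- list(receptor = "R1", metric = "total", location = "whole_cell",
              time_s = 14400)
  s <- local_sensitivity(net, p, "R1.kprod", out, fold = 5,
                         ligand = "V165", dose_ng_ml = 50)
  expect_equal(s$sensitivity, 1, tolerance = 1e-3)
  # VEGFR1 readout vs a VEGFR2-only parameter with NRP1 deleted and a
  # VEGFR1-only ligand: no coupling path at all
  p_n <- apply_perturbation(p, list(kind = "receptor_deletion", target = "N1"))
  s0 <- local_sensitivity(net, p_n, "R2.kint", out, fold = 5,
                          ligand = "P1", dose_ng_ml = 50)
  expect_equal(s0$sensitivity, 0, tolerance = 1e-6)
  expect_error(local_sensitivity(net, p_n, "R2.kint",
                                 list(receptor = "R2", metric = "active",
                                      location = "surface", time_s = 0),
                                 ligand = "P1", dose_ng_ml = 50),
               "zero")
})

test_that("surface VEGFR2 responds negatively to the ligated internalization
          rate and the sensitivity is fold-stable for a linear output", {
  net <- full_network()
  bl <- baseline_state()
  out <- list(receptor = "R2", metric = "total", location = "surface",
              time_s = 14400)
  s <- local_sensitivity(net, bl$params, "ligated.R2.kint", out, fold = 5,
                         init = bl$init)
  expect_lt(s$sensitivity, 0)
  out_lin <- list(receptor = "R1", metric = "total", location = "whole_cell",
                  time_s = 14400)
  s5 <- local_sensitivity(net, bl$params, "R1.kprod", out_lin, fold = 5)
  s25 <- local_sensitivity(net, bl$params, "R1.kprod", out_lin, fold = 2.5)
  expect_lt(abs(s5$sensitivity - s25$sensitivity) / abs(s5$sensitivity), 0.1)
})

test_that("the internalization-multiplier scan recovers self-consistent data
          and orders the surface decline by multiplier", {
  preds <- scan_predictions_cached()
  # data equal to the multiplier-1 curves: argmin must be 1
  d1 <- preds[preds$multiplier == 1,
              c("receptor", "localization", "time_min", "ratio")]
  prof <- scan_sse(preds, d1)
  expect_equal(prof$multiplier[which.min(prof$sse)], 1)
  expect_equal(min(prof$sse), 0, tolerance = 1e-12)
  # deeper surface decline for larger multipliers: 8x deepest
  surf240 <- preds[preds$localization == "surface" & preds$time_min == 240, ]
  expect_true(all(diff(surf240$ratio[order(surf240$multiplier)]) < 0))
  # full object construction on a small noisy dataset
  truth3 <- preds[preds$multiplier == 3,
                  c("receptor", "localization", "time_min", "ratio")]
  data <- generate_blot_dataset(truth3, noise_cv = 0.05, seed = 7)
  scan <- internalization_multiplier_scan(full_network(),
                                          baseline_state()$params, data,
                                          init = baseline_state()$init)
  expect_equal(scan$best, 3)
  expect_s3_class(tidy(scan), "tbl_df")
  expect_equal(glance(scan)$best_multiplier, 3)
  expect_error(internalization_multiplier_scan(full_network(),
                                               baseline_state()$params,
                                               data[0, ]),
               "empty")
})

test_that("competition grids reduce to single-ligand responses at zero dose", {
  net <- full_network()
  bl <- baseline_state()
  g <- competition_grid(net, bl$params, "V165", "P1",
                        doses_a = c(0, 50), doses_b = c(0, 50),
                        time_s = 7200, readouts = "active_R1_by_a",
                        init = bl$init)
  ref <- dose_response(net, bl$params, "V165", 50, times_s = 7200,
                       readouts = "R1_active_whole_cell", init = bl$init)
  got <- g$value[g$dose_a == 50 & g$dose_b == 0]
  expect_equal(got, ref$value, tolerance = 1e-6)
  # the zero-zero cell has no active complexes, and reduction at the
  # reference column is zero by construction
  expect_equal(g$value[g$dose_a == 0 & g$dose_b == 0], 0)
  expect_equal(g$reduction_pct[g$dose_a == 50 & g$dose_b == 0], 0)
})

test_that("dose-response readouts are nonnegative and support deletions", {
  net <- full_network()
  bl <- baseline_state()
  dr <- dose_response(net, bl$params, "P1", c(0, 5, 50), times_s = 3600,
                      readouts = c("R1_active_whole_cell",
                                   "R1_total_surface", "free_P1_internal"),
                      init = bl$init)
  expect_true(all(dr$value >= 0))
  expect_equal(dr$value[dr$dose_ng_ml == 0 & dr$readout ==
                          "R1_active_whole_cell"], 0)
  # VEGF165a activation of VEGFR1 is strongly enhanced by NRP1 deletion at
  # low doses (heterodimer-blocked VEGFR1 becomes available), and the
  # enhancement fades as the dose saturates the receptors
  a_wt <- dose_response(net, bl$params, "V165", c(2.5, 50), times_s = 14400,
                        readouts = "R1_active_whole_cell", init = bl$init)
  a_n1 <- dose_response(net, bl$params, "V165", c(2.5, 50), times_s = 14400,
                        readouts = "R1_active_whole_cell", deletions = "N1")
  expect_gt(a_n1$value[1], 1.5 * a_wt$value[1])
  expect_lt(a_n1$value[2] / a_wt$value[2], a_n1$value[1] / a_wt$value[1])
})
test_that("plot constructors return ggplot objects", {
  tr <- v165_trajectory()
  expect_s3_class(autoplot(tr), "ggplot")
  preds <- scan_predictions_cached()
  truth3 <- preds[preds$multiplier == 3,
                  c("receptor", "localization", "time_min", "ratio")]
  d <- generate_blot_dataset(truth3, noise_cv = 0.1, seed = 3)
  scan <- list(predictions = preds, data = d,
               profile = scan_sse(preds, d), best = 3)
  class(scan) <- "kint_scan"
  expect_s3_class(autoplot(scan), "ggplot")
  p <- default_params_cached()
  s <- list(`121` = scatchard(p, "R2", "one_step_121"))
  expect_s3_class(plot_scatchard(s), "ggplot")
})
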