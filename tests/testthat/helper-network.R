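# Shared fixtures, built once per test session --------------------------------

.fixtures <- new.env(parent = emptyenv())

full_network <- function() {
  if (is.null(.fixtures$net)) .fixtures$net <- build_network()
  .fixtures$net
}

default_params_cached <- function() {
  if (is.null(.fixtures$params)) .fixtures$params <- default_parameters()
  .fixtures$params
}

# calibrated production + pre-simulated baseline, shared across tests
baseline_state <- function() {
  if (is.null(.fixtures$init)) {
    .fixtures$params_cal <- calibrate_production(full_network(),
                                                 default_params_cached())
    .fixtures$init <- presimulate(full_network(), .fixtures$params_cal)
  }
  list(params = .fixtures$params_cal, init = .fixtures$init)
}

# a fast 4-h VEGF165a 50 ng/mL trajectory on the hour grid, shared
v165_trajectory <- function() {
  if (is.null(.fixtures$tr_v165)) {
    bl <- baseline_state()
    .fixtures$tr_v165 <- simulate_ligand_treatment(
      full_network(), bl$params, "V165", 50,
      times = c(0, 900, 1800, 3600, 7200, 14400), init = bl$init)
  }
  .fixtures$tr_v165
}

# blot-ratio prediction curves for the multiplier scan grid, shared between
# the analysis, synthetic-data and acceptance tests (five simulations)
scan_predictions_cached <- function() {
  if (is.null(.fixtures$scan_preds)) {
    bl <- baseline_state()
    preds <- lapply(c(1, 2, 3, 4, 8), function(m) {
      p_m <- bl$params
      i <- p_m$ligated_multipliers$receptor == "R2" &
        p_m$ligated_multipliers$param == "kint"
      p_m$ligated_multipliers$multiplier[i] <- m
      pr <- predict_blot_ratios(full_network(), p_m, "V165", 50, "R2",
                                c(0, 15, 30, 60, 120, 240), init = bl$init)
      pr$multiplier <- m
      pr
    })
    .fixtures$scan_preds <- dplyr::bind_rows(preds)
  }
  .fixtures$scan_preds
}

# reduced rule set used by several enumeration tests
p1_r1_rules <- function() {
  vegfr_rules(ligands = "P1", receptors = "R1",
              ligand_receptor = list(P1 = "R1"),
              ligand_nrp1 = character(), ligand_matrix = character(),
              rr_pairs = list(c("R1", "R1")), r1_n1_coupling = FALSE,
              include_matrix = FALSE)
}

# single-receptor, single-ligand network with transport switched off
# (equilibrium binding test-bed)
binding_only_network <- function(receptor = "R2", ligand = "V165",
                                 dimerize = TRUE) {
  rules <- vegfr_rules(
    ligands = ligand, receptors = receptor,
    ligand_receptor = stats::setNames(list(receptor), ligand),
    ligand_nrp1 = character(), ligand_matrix = character(),
    rr_pairs = if (dimerize) list(c(receptor, receptor)) else list(),
    r1_n1_coupling = FALSE, include_matrix = FALSE)
  p <- default_params_cached()
  p$trafficking[, c("kint", "kdeg", "krec4", "k4to11", "krec11", "kprod")] <- 0
  list(net = build_network(rules, p), params = p)
}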