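# Reaction generation ----------------------------------------------------------

test_that("a surface VEGFR1 monomer has the full expected reaction menu", {
  net <- full_network()
  sp <- net$species
  r1_id <- sp$id[sp$label == "R1" & sp$compartment == "surface"]
  rx <- net$reactions
  involving <- vapply(rx$reactants, function(r) r1_id %in% r, TRUE)
  kinds <- rx$kind[involving]
  expect_true("transport_kint" %in% kinds)
  # couples with R1 and with N1
  pairs <- stats::na.omit(rx$pair[involving & rx$kind == "couple_rr"])
  expect_true(all(c("R1-R1", "N1-R1") %in% pairs))
  # binds every R1-binding ligand from solution
  ligs <- rx$lig[involving & rx$kind == "bind_solution"]
  expect_true(all(c("V165", "V121", "P1", "P2") %in% ligs))
  # and is produced by zeroth-order synthesis
  made <- vapply(rx$products, function(p) r1_id %in% p, TRUE)
  expect_true(any(made & rx$kind == "synthesis"))
})

test_that("the degraded pool is a strict sink", {
  net <- full_network()
  degr_ids <- net$species$id[net$species$compartment == "degraded"]
  outgoing <- vapply(net$reactions$reactants, function(r)
    any(r %in% degr_ids), TRUE)
  expect_false(any(outgoing))
})

test_that("complexes are trafficked as a unit", {
  net <- full_network()
  sp <- net$species
  delta_surf <- sp$id[sp$label == "2xR2.V165[delta]" &
                        sp$compartment == "surface"]
  delta_rab4 <- sp$id[sp$label == "2xR2.V165[delta]" &
                        sp$compartment == "rab4"]
  rx <- net$reactions
  internalize <- which(rx$kind == "transport_kint" &
                         vapply(rx$reactants, function(r)
                           identical(r, delta_surf), TRUE))
  expect_length(internalize, 1)
  expect_equal(rx$products[[internalize]], delta_rab4)
})

test_that("statistical factors are 2x for monomers and 4x for naked dimers", {
  net <- full_network()
  sp <- net$species
  rx <- net$reactions
  v_id <- sp$id[sp$label == "V165" & sp$compartment == "surface"]
  r2_id <- sp$id[sp$label == "R2" & sp$compartment == "surface"]
  rr_id <- sp$id[sp$label == "2xR2[dimer]" & sp$compartment == "surface"]
  to_monomer <- which(rx$kind == "bind_solution" &
                        vapply(rx$reactants, function(r)
                          setequal(r, c(v_id, r2_id)), TRUE))
  to_dimer <- which(rx$kind == "bind_solution" &
                      vapply(rx$reactants, function(r)
                        setequal(r, c(v_id, rr_id)), TRUE))
  expect_equal(rx$mult[to_monomer], 2)
  expect_equal(rx$mult[to_dimer], 4)
  # identical reactants counted as molecule pairs
  self_couple <- which(rx$kind == "couple_rr" &
                         vapply(rx$reactants, function(r)
                           identical(r, c(r2_id, r2_id)), TRUE))
  expect_equal(rx$mult[self_couple], 0.5)
})

test_that("every binding and coupling reaction is reversible; transport is
          irreversible except the two recycling routes", {
  net <- full_network()
  rx <- net$reactions
  sig <- function(re, pr) paste(paste(sort(re), collapse = ","),
                                paste(sort(pr), collapse = ","))
  fwd_kinds <- c("bind_solution", "bind_membrane", "couple_rr",
                 "closure_lr", "closure_rr")
  rev_kinds <- c("unbind", "uncouple_rr")
  fwd <- rx[rx$kind %in% fwd_kinds, ]
  rev <- rx[rx$kind %in% rev_kinds, ]
  rev_sigs <- mapply(sig, rev$reactants, rev$products)
  fwd_needing_reverse <- mapply(sig, fwd$products, fwd$reactants)
  expect_true(all(fwd_needing_reverse %in% rev_sigs))
  # transport: only krec4 and krec11 return to the surface
  tr <- rx[startsWith(rx$kind, "transport_"), ]
  to_surface <- vapply(tr$products, function(p)
    all(net$species$compartment[p] == "surface"), TRUE)
  expect_setequal(unique(tr$kind[to_surface]),
                  c("transport_krec4", "transport_krec11"))
  expect_false(any(tr$kind[!to_surface] %in%
                     c("transport_krec4", "transport_krec11")))
})

test_that("a missing rate reference raises a configuration error", {
  p <- default_params_cached()
  p$binding_1to1 <- p$binding_1to1[p$binding_1to1$ligand != "P1", ]
  expect_error(compute_rates(full_network(), p), "P1")
})

test_that("matrix-bound species never change compartment", {
  net <- full_network()
  mx_ids <- net$species$id[net$species$has_matrix]
  rx <- net$reactions
  transported <- vapply(rx$reactants, function(r) any(r %in% mx_ids), TRUE) &
    startsWith(rx$kind, "transport_")
  expect_false(any(transported))
})
test_that("compartment rate multipliers scale ligand-bond kinetics locally", {
  net <- full_network()
  p <- default_params_cached()
  base <- compute_rates(net, p)
  p2 <- p
  i <- p2$compartment_rate_multipliers$compartment == "rab4"
  p2$compartment_rate_multipliers$kon_mult[i] <- 2
  p2$compartment_rate_multipliers$koff_mult[i] <- 0.5
  scaled <- compute_rates(net, p2)
  rx <- net$reactions
  on_kinds <- rx$kind %in% c("bind_solution", "bind_membrane", "closure_lr",
                             "closure_rr")
  off_kinds <- rx$kind == "unbind"
  in4 <- rx$compartment == "rab4"
  expect_equal(scaled[on_kinds & in4], 2 * base[on_kinds & in4])
  expect_equal(scaled[off_kinds & in4], 0.5 * base[off_kinds & in4])
  untouched <- !(on_kinds | off_kinds) | !in4
  expect_equal(scaled[untouched & rx$compartment != "rab4"],
               base[untouched & rx$compartment != "rab4"])
})
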