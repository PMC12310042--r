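# Reaction network generation -------------------------------------------------
#
# Reactions are generated mechanically from the species graphs:
#   * bimolecular association: every single new bond joining two species in
#     the same compartment whose product is itself a valid species;
#   * intramolecular ring closure: every addable bond inside one species
#     (a bound bivalent ligand capturing its receptor's dimer partner, or the
#     two receptors bridged by one ligand coupling to each other);
#   * dissociation / ring opening: every removable bond;
#   * first-order transport between compartments, the whole complex moving
#     as a unit at the rate constants of its dominant receptor;
#   * zeroth-order synthesis of receptor monomers into the surface.
# Symmetry-equivalent bond choices that lead to the same product are merged
# into a single reaction with an integer multiplicity, which reproduces the
# statistical factors of the dimerization model (2x base kon for a ligand
# binding a receptor monomer, 4x for binding an unliganded dimer).
# Rate constants are resolved from the parameter set by compute_rates(), so
# perturbations (knockdowns, multiplier scans, pH variants) only touch the
# parameter object, never the network structure.

merge_templates <- function(a, b) {
  na <- length(a$kinds)
  bonds_b <- b$bonds
  if (nrow(bonds_b)) bonds_b[, 1:2] <- bonds_b[, 1:2] + na
  new_template(c(a$kinds, b$kinds), rbind(a$bonds, bonds_b))
}

# dominant trafficking class of a complex: the first receptor of the
# precedence order present in the complex. VEGFR2-containing complexes move
# at VEGFR2's rates (slow); VEGFR1-containing complexes, including the
# VEGFR1-NRP1 heterodimer, at VEGFR1's fast rates -- the only assignment
# that keeps VEGFR1 >= 90% internal while NRP1 coupled to VEGFR1 still
# moves faster than NRP1 bridged to VEGFR2.
trafficking_class <- function(kinds, precedence = c("R2", "R1", "N1")) {
  for (r in precedence) if (any(kinds == r)) return(r)
  NA_character_
}

# does the template contain a ligand bound (receptor-site) to a receptor of
# the given kind (for N1: bound via the heparin domain)?
has_ligated <- function(tpl, kind) {
  b <- tpl$bonds
  if (!nrow(b)) return(FALSE)
  if (kind == "N1") return(any(b[, 3] == 2L))
  any(b[, 3] == 1L & tpl$kinds[b[, 2]] == kind)
}

#' Generate the reaction network
#'
#' Emits every association, dissociation, ring closure/opening, transport,
#' degradation and synthesis reaction for the instantiated species, with a
#' symbolic rate reference for each (resolved to numbers by
#' [compute_rates()]).
#'
#' @param species species tibble from [instantiate_species()].
#' @param rules the [vegfr_rules()] used for enumeration.
#' @param params a [default_parameters()] object (used only to check that a
#'   rate reference exists for every generated reaction).
#' @return object of class \code{vegfr_network}: list with \code{species},
#'   \code{reactions} (tibble), and \code{rules}.
#' @export
generate_reactions <- function(species, rules, params) {
  stopifnot(inherits(rules, "vegfr_rules"), inherits(params, "vegfr_params"))
  sp <- species
  lookup <- stats::setNames(sp$id, paste(sp$key, sp$compartment))
  find_sp <- function(key, comp) {
    id <- lookup[paste(key, comp)]
    if (is.na(id)) NA_integer_ else as.integer(id)
  }
  rx <- list()
  emit <- function(kind, comp, order, reactants, products, mult,
                   lig = NA, partner = NA, pair = NA, traffic = NA) {
    rx[[length(rx) + 1L]] <<- tibble::tibble(
      kind = kind, compartment = comp, order = order,
      reactants = list(reactants), products = list(products),
      mult = mult, lig = lig, partner = partner, pair = pair,
      traffic = traffic)
  }

  is_ligand <- function(k) k %in% rules$ligands
  live <- sp[sp$compartment %in% COMPARTMENTS, ]

  # --- associations and closures, per compartment ---------------------------
  for (comp in COMPARTMENTS) {
    here <- live[live$compartment == comp, ]
    n_here <- nrow(here)
    # intramolecular closures
    for (ii in seq_len(n_here)) {
      tpl <- here$template[[ii]]
      n <- template_size(tpl)
      if (n < 3L) next
      usage <- site_usage(tpl)
      bonded <- matrix(FALSE, n, n)
      bonded[tpl$bonds[, 1:2, drop = FALSE]] <- TRUE
      bonded <- bonded | t(bonded)
      within <- !bonded & !diag(TRUE, n)
      cands <- addable_bonds(tpl$kinds, usage, rules, within = within)
      if (!length(cands)) next
      groups <- list()
      for (bond in cands) {
        nb <- normalize_bond(tpl$kinds, bond[1], bond[2], bond[3])
        cand <- new_template(tpl$kinds, rbind(tpl$bonds, nb))
        if (!template_valid(cand, rules)) next
        pid <- find_sp(canonical_key(cand), comp)
        if (is.na(pid)) next
        ty <- nb[3]
        if (ty %in% c(4L, 5L)) {
          # receptor-receptor coupling inside a ligand-bridged triad
          bridger <- bridging_ligand(tpl, nb[1], nb[2])
          gkey <- paste("closure_rr", pid,
                        paste(sort(c(tpl$kinds[nb[1]], tpl$kinds[nb[2]])),
                              collapse = "-"), bridger)
          groups[[gkey]] <- c(groups[[gkey]],
                              list(list(kind = "closure_rr", pid = pid,
                                        pair = paste(sort(c(tpl$kinds[nb[1]],
                                                            tpl$kinds[nb[2]])),
                                                     collapse = "-"),
                                        lig = bridger,
                                        partner = tpl$kinds[nb[2]])))
        } else {
          lg <- tpl$kinds[nb[1]]; tgt <- tpl$kinds[nb[2]]
          gkey <- paste("closure_lr", pid, lg, tgt, ty)
          groups[[gkey]] <- c(groups[[gkey]],
                              list(list(kind = "closure_lr", pid = pid,
                                        lig = lg, partner = tgt, pair = NA)))
        }
      }
      for (g in groups) {
        g1 <- g[[1]]
        emit(g1$kind, comp, 1L, here$id[ii], g1$pid, length(g),
             lig = g1$lig, partner = g1$partner, pair = g1$pair)
      }
    }
    # bimolecular associations (unordered pairs, including self-pairs)
    for (ii in seq_len(n_here)) {
      for (jj in ii:n_here) {
        a <- here$template[[ii]]; b <- here$template[[jj]]
        merged <- merge_templates(a, b)
        na <- template_size(a); nb_ <- template_size(b)
        usage <- site_usage(merged)
        within <- matrix(FALSE, na + nb_, na + nb_)
        within[seq_len(na), na + seq_len(nb_)] <- TRUE
        within[na + seq_len(nb_), seq_len(na)] <- TRUE
        cands <- addable_bonds(merged$kinds, usage, rules, within = within)
        if (!length(cands)) next
        groups <- list()
        weights <- list()
        for (bond in cands) {
          nb2 <- normalize_bond(merged$kinds, bond[1], bond[2], bond[3])
          cand <- new_template(merged$kinds, rbind(merged$bonds, nb2))
          if (!template_valid(cand, rules)) next
          pid <- find_sp(canonical_key(cand), comp)
          if (is.na(pid)) next
          ty <- nb2[3]
          k1 <- merged$kinds[nb2[1]]; k2 <- merged$kinds[nb2[2]]
          # statistical weight: a bivalent ligand with both receptor sites
          # free offers two equivalent sites for the same bond (this yields
          # the 2x monomer / 4x unliganded-dimer on-rate factors)
          wgt <- if (ty == 1L) 2L - usage$g[nb2[1]] else 1L
          if (ty %in% c(4L, 5L)) {
            ctx <- "couple_rr"
            gkey <- paste(ctx, pid, paste(sort(c(k1, k2)), collapse = "-"))
            info <- list(kind = ctx, pid = pid,
                         pair = paste(sort(c(k1, k2)), collapse = "-"),
                         lig = NA, partner = NA)
          } else {
            # ligand bond: solution-phase if the ligand-side species is a
            # free ligand, else membrane crosslinking
            lig_free <- (nb2[1] <= na && na == 1L && is_ligand(a$kinds[1])) ||
              (nb2[1] > na && nb_ == 1L && is_ligand(b$kinds[1]))
            ctx <- if (lig_free) "bind_solution" else "bind_membrane"
            gkey <- paste(ctx, pid, k1, k2, ty)
            info <- list(kind = ctx, pid = pid, lig = k1, partner = k2,
                         pair = NA)
          }
          groups[[gkey]] <- info
          weights[[gkey]] <- (if (is.null(weights[[gkey]])) 0 else
                                weights[[gkey]]) + wgt
        }
        for (gkey in names(groups)) {
          g1 <- groups[[gkey]]
          w <- weights[[gkey]]
          # identical reactants: rate law k x^2 counts ordered pairs; halve
          # to count molecule pairs once
          if (ii == jj) w <- w / 2
          emit(g1$kind, comp, 2L, c(here$id[ii], here$id[jj]), g1$pid,
               w, lig = g1$lig, partner = g1$partner, pair = g1$pair)
        }
      }
    }
    # dissociations / ring openings
    for (ii in seq_len(n_here)) {
      tpl <- here$template[[ii]]
      b <- tpl$bonds
      if (!nrow(b)) next
      groups <- list()
      for (k in seq_len(nrow(b))) {
        rem <- new_template(tpl$kinds, b[-k, , drop = FALSE])
        parts <- split_components(rem)
        ty <- b[k, 3]
        k1 <- tpl$kinds[b[k, 1]]; k2 <- tpl$kinds[b[k, 2]]
        if (length(parts) == 1L) {
          pids <- find_sp(canonical_key(rem), comp)
        } else {
          pids <- vapply(parts, function(p) find_sp(canonical_key(p), comp), 1L)
        }
        if (anyNA(pids)) next
        if (ty %in% c(4L, 5L)) {
          ctx <- "uncouple_rr"; lig <- NA; partner <- NA
          pair <- paste(sort(c(k1, k2)), collapse = "-")
        } else {
          ctx <- "unbind"; lig <- k1; partner <- k2; pair <- NA
        }
        gkey <- paste(ctx, paste(sort(pids), collapse = "+"), k1, k2, ty)
        groups[[gkey]] <- c(groups[[gkey]],
                            list(list(kind = ctx, pids = pids, lig = lig,
                                      partner = partner, pair = pair,
                                      ty = ty)))
      }
      for (g in groups) {
        g1 <- g[[1]]
        emit(g1$kind, comp, 1L, here$id[ii], g1$pids, length(g),
             lig = g1$lig, partner = g1$partner, pair = g1$pair)
      }
    }
  }

  # --- transport, degradation, synthesis ------------------------------------
  degr_id <- function(kind) {
    i <- which(sp$compartment == "degraded" &
                 vapply(sp$template, function(t)
                   length(t$kinds) == 1L && t$kinds == kind, TRUE))
    if (length(i)) sp$id[i] else NA_integer_
  }
  for (ii in which(live$compartment %in% COMPARTMENTS & !live$has_matrix)) {
    row <- live[ii, ]
    tpl <- row$template[[1]]
    cls <- trafficking_class(tpl$kinds)
    comp <- row$compartment
    if (is.na(cls)) {
      # ligand-only species: degraded from the early endosome, no transport
      if (comp == "rab4") {
        prods <- unlist(lapply(tpl$kinds, degr_id))
        emit("degrade_ligand", comp, 1L, row$id, prods, 1L)
      }
      next
    }
    move <- function(param, to) {
      pid <- find_sp(row$key, to)
      if (is.na(pid)) return()
      emit(paste0("transport_", param), comp, 1L, row$id, pid, 1L,
           traffic = paste(cls, param, sep = "."),
           lig = if (has_ligated(tpl, cls)) "ligated" else NA)
    }
    if (comp == "surface") move("kint", "rab4")
    if (comp == "rab4") {
      move("krec4", "surface")
      move("k4to11", "rab11")
      prods <- unlist(lapply(tpl$kinds[tpl$kinds != "M"], degr_id))
      emit("degrade", comp, 1L, row$id, prods, 1L,
           traffic = paste(cls, "kdeg", sep = "."),
           lig = if (has_ligated(tpl, cls)) "ligated" else NA)
    }
    if (comp == "rab11") move("krec11", "surface")
  }
  for (r in rules$receptors) {
    pid <- find_sp(sp$key[match(r, sp$label)], "surface")
    emit("synthesis", "surface", 0L, integer(), pid, 1L,
         traffic = paste(r, "kprod", sep = "."))
  }

  reactions <- dplyr::bind_rows(rx)
  reactions$rxn_id <- seq_len(nrow(reactions))
  net <- structure(list(species = sp, reactions = reactions, rules = rules,
                        cache = new.env(parent = emptyenv())),
                   class = "vegfr_network")
  # fail fast if any reaction lacks a rate reference
  invisible(compute_rates(net, params))
  net
}

# ligand (if any) whose two receptor-site bonds connect monomers i and j
bridging_ligand <- function(tpl, i, j) {
  b <- tpl$bonds
  for (lg in which(!tpl$kinds %in% c("R1", "R2", "N1", "M"))) {
    tgt <- b[b[, 3] == 1L & b[, 1] == lg, 2]
    if (length(tgt) == 2L && all(sort(tgt) == sort(c(i, j))))
      return(tpl$kinds[lg])
  }
  NA_character_
}

# connected components of a template after a bond removal
split_components <- function(tpl) {
  n <- length(tpl$kinds)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(tpl$bonds)) {
    for (k in seq_len(nrow(tpl$bonds))) {
      a <- find(tpl$bonds[k, 1]); b <- find(tpl$bonds[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  lapply(unique(comp), function(cc) {
    keep <- which(comp == cc)
    remap <- match(seq_len(n), keep)
    bsub <- tpl$bonds[tpl$bonds[, 1] %in% keep, , drop = FALSE]
    if (nrow(bsub)) {
      bsub[, 1] <- remap[bsub[, 1]]; bsub[, 2] <- remap[bsub[, 2]]
    }
    new_template(tpl$kinds[keep], bsub)
  })
}

#' @export
print.vegfr_network <- function(x, ...) {
  cat("<vegfr_network>\n")
  cat("  species:  ", sum(x$species$counted), "counted (",
      nrow(x$species), "state variables )\n")
  cat("  reactions:", nrow(x$reactions), "\n")
  print(table(x$reactions$kind))
  invisible(x)
}

#' Resolve the numeric rate constant of every reaction
#'
#' Maps each reaction's symbolic rate reference to a number using the
#' current parameter set: solution binding uses volume-adjusted base
#' constants (quarter of the measured 1:1 kon for bivalent receptor-site
#' binding, the measured kon for the NRP1/matrix domain), membrane
#' crosslinking uses the derived kon_LR scaled by compartment area,
#' receptor-receptor coupling uses per-area constants over the compartment
#' area, ring closures use kdelta_LR / kdelta_RR, unbinding uses
#' sqrt(koff/2) for receptor-site bonds and measured koff otherwise, and
#' transport/synthesis use the trafficking table with any ligated-complex
#' multipliers. Compartment-specific kon/koff multipliers (endosomal pH
#' hooks) scale every ligand bond formation/breakage in that compartment.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @return numeric vector of rate constants, one per reaction, in
#'   (#/cell)-based units.
#' @export
compute_rates <- function(network, params) {
  rx <- network$reactions
  g <- params$geometry
  b1 <- params$binding_1to1
  bkey <- paste(b1$ligand, b1$partner)
  crr <- params$coupling_rr
  mult_tab <- params$compartment_rate_multipliers
  kon_mult <- stats::setNames(mult_tab$kon_mult, mult_tab$compartment)
  koff_mult <- stats::setNames(mult_tab$koff_mult, mult_tab$compartment)
  traffic <- params$trafficking
  lmult <- params$ligated_multipliers

  get_binding <- function(lig, partner) {
    i <- match(paste(lig, partner), bkey)
    if (is.na(i)) stop("no binding constants for ", lig, "-", partner,
                       call. = FALSE)
    list(kon_M = b1$kon_M[i], koff = b1$koff[i])
  }
  get_rr <- function(pair) {
    i <- match(pair, crr$pair)
    if (is.na(i)) stop("no coupling constants for pair ", pair, call. = FALSE)
    list(kon = crr$kon_rr_um2[i], koff = crr$koff_rr[i])
  }
  # derived LR coupling constants for one ligand-receptor pair at the surface
  lr_coupling <- function(lig, partner, pair = NULL) {
    meas <- get_binding(lig, partner)
    koff_base <- sqrt(meas$koff / 2)
    rtot <- params$rtot[[partner]]
    kon_rr_cell <- if (!is.null(pair))
      surface_rate_to_percell(get_rr(pair)$kon, g$area[["surface"]])
    else 0
    derive_coupling_constants(koff_base, kon_rr_cell, rtot,
                              formula = params$coupling_formula)
  }

  rates <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    kind <- rx$kind[i]; comp <- rx$compartment[i]; m <- rx$mult[i]
    k <- switch(kind,
      bind_solution = {
        meas <- get_binding(rx$lig[i], rx$partner[i])
        base <- if (rx$partner[i] %in% c("R1", "R2"))
          meas$kon_M / 4 else meas$kon_M
        volumetric_rate_to_percell(base, g$volume_fl[[comp]]) *
          kon_mult[[comp]]
      },
      bind_membrane = {
        if (rx$partner[i] %in% c("R1", "R2", "N1")) {
          cc <- lr_coupling(rx$lig[i], rx$partner[i])
          cc$kon_LR * g$area[["surface"]] / g$area[[comp]] * kon_mult[[comp]]
        } else { # matrix capture by a tethered ligand: zero-flux channel
          meas <- get_binding(rx$lig[i], rx$partner[i])
          volumetric_rate_to_percell(meas$kon_M, g$volume_fl[[comp]]) *
            kon_mult[[comp]]
        }
      },
      couple_rr = surface_rate_to_percell(get_rr(rx$pair[i])$kon,
                                          g$area[[comp]]),
      closure_lr = {
        cc <- lr_coupling(rx$lig[i], rx$partner[i])
        cc$kdelta_LR * kon_mult[[comp]]
      },
      closure_rr = {
        cc <- lr_coupling(rx$lig[i], rx$partner[i], pair = rx$pair[i])
        cc$kdelta_RR * kon_mult[[comp]]
      },
      unbind = {
        meas <- get_binding(rx$lig[i], rx$partner[i])
        base <- if (rx$partner[i] %in% c("R1", "R2"))
          sqrt(meas$koff / 2) else meas$koff
        base * koff_mult[[comp]]
      },
      uncouple_rr = get_rr(rx$pair[i])$koff,
      synthesis = ,
      degrade = ,
      transport_kint = ,
      transport_krec4 = ,
      transport_k4to11 = ,
      transport_krec11 = {
        parts <- strsplit(rx$traffic[i], ".", fixed = TRUE)[[1]]
        ti <- match(parts[1], traffic$receptor)
        if (is.na(ti)) stop("no trafficking constants for ", parts[1],
                            call. = FALSE)
        val <- traffic[[parts[2]]][ti]
        if (identical(rx$lig[i], "ligated") && parts[2] != "kprod") {
          li <- lmult$receptor == parts[1] & lmult$param == parts[2]
          if (any(li)) val <- val * lmult$multiplier[li]
        }
        val
      },
      degrade_ligand = params$kdeg_ligand,
      stop("unknown reaction kind: ", kind, call. = FALSE)
    )
    rates[i] <- k * m
  }
  rates
}

#' Export the reaction list as a flat table for audit
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params} (rates are included when supplied).
#' @return tibble with reaction id, kind, compartment, reactant and product
#'   labels, multiplicity and rate constant.
#' @export
reaction_table <- function(network, params = NULL) {
  rx <- network$reactions
  lab <- stats::setNames(paste0(network$species$label, "@",
                                network$species$compartment),
                         network$species$id)
  out <- tibble::tibble(
    rxn_id = rx$rxn_id, kind = rx$kind, compartment = rx$compartment,
    order = rx$order,
    reactants = vapply(rx$reactants, function(r)
      paste(lab[as.character(r)], collapse = " + "), ""),
    products = vapply(rx$products, function(p)
      paste(lab[as.character(p)], collapse = " + "), ""),
    mult = rx$mult
  )
  if (!is.null(params)) out$rate <- compute_rates(network, params)
  out
}

#' Build the complete model network
#'
#' One-stop constructor: enumerate complexes, instantiate species, generate
#' reactions.
#'
#' @param rules a [vegfr_rules()].
#' @param params a [default_parameters()].
#' @return a \code{vegfr_network}.
#' @export
build_network <- function(rules = vegfr_rules(), params = default_parameters()) {
  species <- instantiate_species(enumerate_complexes(rules), rules)
  generate_reactions(species, rules, params)
}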