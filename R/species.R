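# Species instantiation and classification ----------------------------------

COMPARTMENTS <- c("surface", "rab4", "rab11")

#' Place complex templates in compartments to form the model species
#'
#' Non-matrix templates (receptor complexes and free ligands) exist at the
#' cell surface (for free ligand: the extracellular medium), in Rab4a/5a
#' early endosomes and in Rab11a recycling endosomes. Matrix-containing
#' templates exist only at the surface and are never internalized. The
#' cumulative degradation pool is represented by one bookkeeping species per
#' receptor kind (these are what the printed species inventory counts) plus
#' one uncounted accumulator per ligand kind, used for conservation audits.
#'
#' @param templates tibble from [enumerate_complexes()].
#' @param rules the [vegfr_rules()] the templates were enumerated under.
#' @return tibble with one row per species: \code{id} (stable integer),
#'   \code{key}, \code{label}, \code{compartment}, \code{counted} (is this
#'   row part of the species inventory), monomer counts, classification
#'   labels from [classify_species()], and the template as a list-column.
#' @export
instantiate_species <- function(templates, rules) {
  stopifnot(is.data.frame(templates), inherits(rules, "vegfr_rules"))
  cls <- classify_species(templates)
  tpl <- dplyr::bind_cols(templates, cls)
  place <- function(df, comp) dplyr::mutate(df, compartment = comp)
  body <- dplyr::bind_rows(
    lapply(COMPARTMENTS, function(cc) {
      place(if (cc == "surface") tpl else tpl[!tpl$has_matrix, ], cc)
    })
  )
  body$counted <- TRUE
  # degraded pools: receptors counted, ligand accumulators bookkeeping-only
  degr <- function(kind, counted) {
    row <- tpl[tpl$label == kind & tpl$n_monomers == 1L, ]
    if (!nrow(row)) return(NULL)
    row$compartment <- "degraded"
    row$counted <- counted
    row
  }
  degr_rows <- dplyr::bind_rows(
    lapply(rules$receptors, degr, counted = TRUE),
    lapply(rules$ligands, degr, counted = FALSE)
  )
  out <- dplyr::bind_rows(body, degr_rows)
  out$id <- seq_len(nrow(out))
  dplyr::relocate(out, "id", "label", "compartment", "counted")
}

#' Classify complex templates
#'
#' A complex is \emph{active} for a receptor when one bivalent ligand is
#' bound to two receptors of that kind (the receptor-ligand-receptor triad
#' taken as the signal-initiation species); the receptor-receptor bond of
#' the delta-closed conformation is not required. \code{is_dimer} marks any
#' receptor-receptor bond (homodimer or VEGFR1-NRP1 coupling); \code{ligated}
#' marks complexes containing at least one ligand bound to a receptor.
#'
#' @param templates tibble from [enumerate_complexes()] (or any tibble with a
#'   \code{template} list-column).
#' @return tibble of labels aligned with \code{templates}: \code{active_R1},
#'   \code{active_R2}, \code{is_dimer}, \code{ligated}, \code{delta},
#'   \code{n_rr_bonds}.
#' @export
classify_species <- function(templates) {
  lab <- lapply(templates$template, function(t) {
    b <- t$bonds
    kinds <- t$kinds
    active <- c(R1 = FALSE, R2 = FALSE)
    delta <- FALSE
    if (nrow(b)) {
      for (i in which(!kinds %in% c("R1", "R2", "N1", "M"))) {
        tgt <- b[b[, 3] == 1L & b[, 1] == i, 2]
        if (length(tgt) == 2L) {
          k <- unique(kinds[tgt])
          if (length(k) == 1L && k %in% c("R1", "R2"))
            active[[k]] <- TRUE
          if (any(b[, 3] == 4L &
                  ((b[, 1] == tgt[1] & b[, 2] == tgt[2]) |
                   (b[, 1] == tgt[2] & b[, 2] == tgt[1]))))
            delta <- TRUE
        }
      }
    }
    n_rr <- if (nrow(b)) sum(b[, 3] %in% c(4L, 5L)) else 0L
    ligated <- nrow(b) && any(b[, 3] == 1L)
    c(active_R1 = active[["R1"]], active_R2 = active[["R2"]],
      is_dimer = n_rr > 0L, ligated = ligated, delta = delta,
      n_rr_bonds = n_rr)
  })
  m <- do.call(rbind, lab)
  tibble::tibble(
    active_R1 = as.logical(m[, "active_R1"]),
    active_R2 = as.logical(m[, "active_R2"]),
    is_dimer = as.logical(m[, "is_dimer"]),
    ligated = as.logical(m[, "ligated"]),
    delta = as.logical(m[, "delta"]),
    n_rr_bonds = as.integer(m[, "n_rr_bonds"])
  )
}

#' Build the full species inventory for a rule set
#'
#' Convenience wrapper: enumerate templates, place them in compartments, and
#' return the species table. With the default rules the inventory contains
#' 281 counted species.
#'
#' @inheritParams instantiate_species
#' @return species tibble, see [instantiate_species()].
#' @export
species_inventory <- function(rules = vegfr_rules()) {
  instantiate_species(enumerate_complexes(rules), rules)
}

#' Export the species inventory as a flat table
#'
#' Serializes id, composition, bond list and compartment, mirroring the
#' model's published ID tables, suitable for CSV export.
#'
#' @param species species tibble from [instantiate_species()].
#' @return tibble with columns id, label, composition, bonds, compartment,
#'   counted.
#' @export
species_table <- function(species) {
  comp_str <- vapply(species$template, function(t)
    paste(sort(t$kinds), collapse = "+"), "")
  bond_str <- vapply(species$template, function(t) {
    if (!nrow(t$bonds)) return("")
    paste(apply(t$bonds, 1, function(r)
      paste0(t$kinds[r[1]], r[1], "-", t$kinds[r[2]], r[2], ":",
             names(BOND_TYPES)[r[3]])), collapse = ";")
  }, "")
  tibble::tibble(
    id = species$id, label = species$label, composition = comp_str,
    bonds = bond_str, compartment = species$compartment,
    counted = species$counted
  )
}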