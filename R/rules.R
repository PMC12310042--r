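#' Binding rules for the VEGF receptor-ligand network
#'
#' Constructs the rule set from which all molecular complexes and reactions
#' are enumerated. The default encodes the interaction biology of the four
#' ligand isoforms (VEGF165a, VEGF121a, PLGF1, PLGF2) with VEGFR1, VEGFR2,
#' NRP1 and extracellular-matrix binding sites:
#' all four ligands bind VEGFR1; only the VEGF-A isoforms bind VEGFR2;
#' only the heparin-binding isoforms (VEGF165a, PLGF2) bind NRP1 or matrix;
#' VEGFR1 and VEGFR2 homodimerize; VEGFR1 couples directly to NRP1 while
#' VEGFR2 does not (VEGFR2 and NRP1 are bridged only by VEGF165a); the
#' NRP1-binding ligands cannot bind a VEGFR1 that is coupled to NRP1 and
#' cannot bind NRP1 and matrix simultaneously.
#'
#' Each monomer carries typed binding sites with fixed valences: receptors
#' have one ligand site; VEGFR1 has one homodimerization site and one NRP1
#' coupling site; VEGFR2 has one homodimerization site; NRP1 has one ligand
#' site and one VEGFR1 coupling site; ligands are bivalent toward receptors
#' and (heparin-binding isoforms) have one NRP1/matrix site; a matrix site
#' binds one ligand.
#'
#' @param ligands character vector of ligand names to include.
#' @param receptors character vector of receptor names to include
#'   (subset of \code{c("R1","R2","N1")}).
#' @param ligand_receptor named list: for each ligand, the receptors its two
#'   symmetric receptor-binding sites can engage.
#' @param ligand_nrp1 ligands whose heparin-binding domain binds NRP1.
#' @param ligand_matrix ligands whose heparin-binding domain binds matrix.
#' @param rr_pairs receptor homodimerization pairs.
#' @param r1_n1_coupling logical; direct VEGFR1-NRP1 coupling.
#' @param exclude_on_r1n1 ligands that cannot bind a VEGFR1 already coupled
#'   to NRP1 (and whose bound VEGFR1 cannot subsequently couple NRP1).
#' @param include_matrix logical; enumerate matrix-bound complexes (these are
#'   surface-only and held at zero concentration in the standard simulations).
#' @param max_receptors maximum number of receptor tyrosine kinases
#'   (VEGFR1 + VEGFR2) per complex; 2 caps the network at dimers.
#' @param allow_two_ligands logical; may a receptor dimer carry a ligand on
#'   each of its two ligand sites.
#' @param allow_nrp1_ligand_on_r1 logical; may a ligand engaged via its
#'   heparin domain by NRP1 also bind VEGFR1 through a receptor site
#'   (bridging VEGFR1 and NRP1 through one ligand). Default FALSE: ligand
#'   bridging of NRP1 is a VEGFR2-specific interaction.
#' @param allow_matrix_ligand_on_r1 logical; may a matrix-tethered ligand
#'   engage VEGFR1 through a receptor site. Default TRUE.
#' @param matrix_single_ligand logical; matrix-containing complexes are
#'   enumerated to single-ligand depth. Default TRUE.
#' @return an object of class \code{vegfr_rules}.
#' @export
vegfr_rules <- function(ligands = c("V165", "V121", "P1", "P2"),
                        receptors = c("R1", "R2", "N1"),
                        ligand_receptor = list(
                          V165 = c("R1", "R2"),
                          V121 = c("R1", "R2"),
                          P1 = "R1",
                          P2 = "R1"
                        ),
                        ligand_nrp1 = c("V165", "P2"),
                        ligand_matrix = c("V165", "P2"),
                        rr_pairs = list(c("R1", "R1"), c("R2", "R2")),
                        r1_n1_coupling = TRUE,
                        exclude_on_r1n1 = c("V165", "P2"),
                        include_matrix = TRUE,
                        max_receptors = 2L,
                        allow_two_ligands = TRUE,
                        allow_nrp1_ligand_on_r1 = FALSE,
                        allow_matrix_ligand_on_r1 = TRUE,
                        matrix_single_ligand = TRUE) {
  ligands <- match.arg(ligands, c("V165", "V121", "P1", "P2"),
                       several.ok = TRUE)
  if (length(receptors) && !all(receptors %in% c("R1", "R2", "N1")))
    stop("receptors must be a subset of R1, R2, N1", call. = FALSE)
  ligand_receptor <- lapply(ligand_receptor, intersect, receptors)
  ligand_receptor <- ligand_receptor[names(ligand_receptor) %in% ligands]
  ligand_nrp1 <- intersect(intersect(ligand_nrp1, ligands),
                           if ("N1" %in% receptors) ligand_nrp1 else character())
  ligand_matrix <- if (include_matrix) intersect(ligand_matrix, ligands)
                   else character()
  rr_pairs <- Filter(function(p) all(p %in% receptors), rr_pairs)

  # contradictory rules: a ligand both allowed on R1 and excluded from all R1
  for (lg in names(ligand_receptor)) {
    if (!length(ligand_receptor[[lg]]) && !lg %in% c(ligand_nrp1, ligand_matrix) &&
        lg %in% ligands && length(receptors))
      ligand_receptor[[lg]] <- character() # ligand participates only as free species
  }

  structure(
    list(
      ligands = ligands,
      receptors = receptors,
      ligand_receptor = ligand_receptor,
      ligand_nrp1 = ligand_nrp1,
      ligand_matrix = ligand_matrix,
      rr_pairs = rr_pairs,
      r1_n1_coupling = r1_n1_coupling && all(c("R1", "N1") %in% receptors),
      exclude_on_r1n1 = intersect(exclude_on_r1n1, ligands),
      include_matrix = include_matrix,
      max_receptors = as.integer(max_receptors),
      allow_two_ligands = isTRUE(allow_two_ligands),
      allow_nrp1_ligand_on_r1 = isTRUE(allow_nrp1_ligand_on_r1),
      allow_matrix_ligand_on_r1 = isTRUE(allow_matrix_ligand_on_r1),
      matrix_single_ligand = isTRUE(matrix_single_ligand)
    ),
    class = "vegfr_rules"
  )
}

#' @export
print.vegfr_rules <- function(x, ...) {
  cat("<vegfr_rules>\n")
  cat("  ligands:  ", paste(x$ligands, collapse = ", "), "\n")
  cat("  receptors:", paste(x$receptors, collapse = ", "), "\n")
  for (lg in names(x$ligand_receptor))
    cat("  ", lg, "binds:", paste(x$ligand_receptor[[lg]], collapse = ", "),
        if (lg %in% x$ligand_nrp1) "+ NRP1" else "",
        if (lg %in% x$ligand_matrix) "+ matrix" else "", "\n")
  cat("  homodimers:", paste(vapply(x$rr_pairs, paste, "", collapse = "-"),
                             collapse = ", "), "\n")
  cat("  R1-N1 coupling:", x$r1_n1_coupling, "\n")
  invisible(x)
}

monomer_category <- function(kind) {
  ifelse(kind %in% c("R1", "R2", "N1"), "receptor",
         ifelse(kind == "M", "matrix-site", "ligand"))
}
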