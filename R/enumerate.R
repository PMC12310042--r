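# Complex enumeration -------------------------------------------------------
#
# A complex template is a connected, site-typed bond graph over monomers.
# Internally: list(kinds = character(), bonds = matrix(i, j, type-code)).
# Bond type codes: 1 = lr (ligand receptor-site to R1/R2 ligand-site),
#                  2 = ln (ligand heparin-domain to NRP1),
#                  3 = lm (ligand heparin-domain to matrix site),
#                  4 = rr (receptor homodimerization),
#                  5 = rn (VEGFR1-NRP1 coupling).
# Because every pair of monomer kinds admits at most one bond class, a
# kind-labelled simple graph identifies a complex up to isomorphism; the
# delta-closed triad (ligand bound twice plus a receptor-receptor bond) and
# the open triad (ligand bound twice, receptors uncoupled) differ in edge set
# and are therefore distinct species, matching the paper's delta notation.

BOND_TYPES <- c(lr = 1L, ln = 2L, lm = 3L, rr = 4L, rn = 5L)

new_template <- function(kinds, bonds = NULL) {
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 3)
  list(kinds = kinds, bonds = bonds)
}

template_size <- function(tpl) length(tpl$kinds)

# used site counts per monomer, by site class
site_usage <- function(tpl) {
  n <- template_size(tpl)
  g <- integer(n)  # ligand receptor-sites used
  h <- integer(n)  # ligand heparin-domain used (ln or lm)
  l <- integer(n)  # receptor ligand-site used
  d <- integer(n)  # receptor homodimer site used
  r <- integer(n)  # R1 NRP1-site / N1 R1-site used / matrix site used
  b <- tpl$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1]; j <- b[k, 2]; ty <- b[k, 3]
      if (ty == 1L) { g[i] <- g[i] + 1L; l[j] <- l[j] + 1L }
      else if (ty == 2L) { h[i] <- h[i] + 1L; l[j] <- l[j] + 1L }
      else if (ty == 3L) { h[i] <- h[i] + 1L; r[j] <- r[j] + 1L }
      else if (ty == 4L) { d[i] <- d[i] + 1L; d[j] <- d[j] + 1L }
      else { r[i] <- r[i] + 1L; r[j] <- r[j] + 1L }  # rn: R1.n -- N1.r
    }
  }
  list(g = g, h = h, l = l, d = d, r = r)
}

# ordered bond rows: lr/ln/lm rows store (ligand, receptor/matrix);
# rr rows (i, j) unordered; rn rows (R1, N1).
normalize_bond <- function(kinds, i, j, type) {
  swap <- switch(as.character(type),
    `1` = monomer_category(kinds[i]) != "ligand",
    `2` = kinds[i] == "N1",
    `3` = kinds[i] == "M",
    `4` = i > j,
    `5` = kinds[i] == "N1")
  if (swap) c(j, i, type) else c(i, j, type)
}

template_valid <- function(tpl, rules) {
  kinds <- tpl$kinds
  n_rtk <- sum(kinds %in% c("R1", "R2"))
  if (n_rtk > rules$max_receptors) return(FALSE)
  is_lig <- kinds %in% rules$ligands
  if (!rules$allow_two_ligands && sum(is_lig) > 1L) return(FALSE)
  if (rules$matrix_single_ligand && any(kinds == "M") && sum(is_lig) > 1L)
    return(FALSE)
  b <- tpl$bonds
  if (!nrow(b)) return(TRUE)
  # per-monomer bond partners by type
  for (idx in which(is_lig)) {
    tgt <- b[b[, 3] == 1L & b[, 1] == idx, 2]
    if (length(tgt)) {
      # a ligand's two receptor sites engage one receptor kind only
      if (length(unique(kinds[tgt])) > 1L) return(FALSE)
      if (any(kinds[tgt] == "R1")) {
        if (!rules$allow_nrp1_ligand_on_r1 &&
            any(b[, 3] == 2L & b[, 1] == idx)) return(FALSE)
        if (!rules$allow_matrix_ligand_on_r1 &&
            any(b[, 3] == 3L & b[, 1] == idx)) return(FALSE)
      }
    }
  }
  # NRP1 engaged by VEGFR1 admits no ligand, and vice versa
  n1_lig <- b[b[, 3] == 2L, 2]
  n1_r1  <- b[b[, 3] == 5L, 2]
  if (length(intersect(n1_lig, n1_r1))) return(FALSE)
  # excluded ligands cannot engage an NRP1-coupled VEGFR1
  r1_n1 <- b[b[, 3] == 5L, 1]
  if (length(r1_n1)) {
    excl <- which(kinds %in% rules$exclude_on_r1n1)
    if (length(excl)) {
      bad <- b[b[, 3] == 1L & b[, 1] %in% excl & b[, 2] %in% r1_n1, ,
               drop = FALSE]
      if (nrow(bad)) return(FALSE)
    }
  }
  TRUE
}

# isomorphism-invariant key: minimum edge-list encoding over all
# within-kind permutations (complexes are small, <= ~6 monomers)
canonical_key <- function(tpl) {
  kinds <- tpl$kinds
  n <- length(kinds)
  ord <- order(kinds)
  kinds_s <- kinds[ord]
  if (!nrow(tpl$bonds)) return(paste(kinds_s, collapse = "+"))
  # relabel bonds to sorted-kind positions, then minimize over permutations
  pos <- integer(n); pos[ord] <- seq_len(n)
  groups <- split(seq_len(n), kinds_s)
  perms_of <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms_of(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  group_perms <- lapply(groups, perms_of)
  combos <- expand.grid(lapply(group_perms, seq_along))
  b0 <- tpl$bonds
  b0[, 1] <- pos[b0[, 1]]; b0[, 2] <- pos[b0[, 2]]
  best <- NULL
  for (ci in seq_len(nrow(combos))) {
    perm <- integer(n)
    for (gi in seq_along(groups)) {
      perm[groups[[gi]]] <- group_perms[[gi]][[combos[ci, gi]]]
    }
    b <- b0
    b[, 1] <- perm[b0[, 1]]; b[, 2] <- perm[b0[, 2]]
    sw <- b[, 3] == 4L & b[, 1] > b[, 2]
    tmp <- b[sw, 1]; b[sw, 1] <- b[sw, 2]; b[sw, 2] <- tmp
    o <- order(b[, 3], b[, 1], b[, 2])
    key <- paste(b[o, 1], b[o, 2], b[o, 3], sep = ".", collapse = ";")
    if (is.null(best) || key < best) best <- key
  }
  paste0(paste(kinds_s, collapse = "+"), "|", best)
}

# all single-bond additions between free sites of one or two templates
addable_bonds <- function(kinds, usage, rules, within = NULL) {
  out <- list()
  n <- length(kinds)
  idx_pairs <- if (is.null(within)) NULL else within
  add <- function(i, j, type) out[[length(out) + 1L]] <<- c(i, j, type)
  for (i in seq_len(n)) {
    ki <- kinds[i]
    if (ki %in% rules$ligands) {
      # receptor sites
      if (usage$g[i] < 2L) {
        for (j in seq_len(n)) {
          if (!is.null(within) && !within[i, j]) next
          if (kinds[j] %in% rules$ligand_receptor[[ki]] && usage$l[j] < 1L)
            add(i, j, 1L)
        }
      }
      # heparin domain
      if (usage$h[i] < 1L) {
        for (j in seq_len(n)) {
          if (!is.null(within) && !within[i, j]) next
          if (kinds[j] == "N1" && ki %in% rules$ligand_nrp1 &&
              usage$l[j] < 1L && usage$r[j] < 1L)
            add(i, j, 2L)
          if (kinds[j] == "M" && ki %in% rules$ligand_matrix &&
              usage$r[j] < 1L)
            add(i, j, 3L)
        }
      }
    } else if (ki %in% c("R1", "R2")) {
      if (usage$d[i] < 1L) {
        for (j in seq_len(n)) {
          if (j <= i) next
          if (!is.null(within) && !within[i, j]) next
          if (kinds[j] == ki && usage$d[j] < 1L &&
              any(vapply(rules$rr_pairs, function(p)
                all(sort(p) == sort(c(ki, kinds[j]))), TRUE)))
            add(i, j, 4L)
        }
      }
      if (ki == "R1" && rules$r1_n1_coupling && usage$r[i] < 1L) {
        for (j in seq_len(n)) {
          if (!is.null(within) && !within[i, j]) next
          if (kinds[j] == "N1" && usage$r[j] < 1L && usage$l[j] < 1L)
            add(i, j, 5L)
        }
      }
    }
  }
  out
}

#' Enumerate all molecular complexes permitted by a rule set
#'
#' Breadth-first closure over single-bond association and intramolecular
#' ring-closure moves, starting from the monomers, deduplicated by an
#' isomorphism-invariant canonical key. The result is deterministic: templates
#' are ordered by monomer count, then canonical key.
#'
#' @param rules a [vegfr_rules()] object.
#' @return tibble with one row per template: \code{key}, \code{label}
#'   (human-readable composition), \code{n_monomers}, counts of each monomer
#'   kind, \code{n_bonds}, \code{has_matrix}, and a list-column
#'   \code{template} holding the bond graph.
#' @export
enumerate_complexes <- function(rules) {
  stopifnot(inherits(rules, "vegfr_rules"))
  monomers <- c(rules$receptors,
                rules$ligands,
                if (rules$include_matrix && length(rules$ligand_matrix)) "M")
  pool <- list()
  keys <- character()
  push <- function(tpl) {
    if (!template_valid(tpl, rules)) return(FALSE)
    key <- canonical_key(tpl)
    if (key %in% keys) return(FALSE)
    keys[[length(keys) + 1L]] <<- key
    pool[[length(pool) + 1L]] <<- tpl
    TRUE
  }
  for (m in monomers) push(new_template(m))
  frontier <- seq_along(pool)
  while (length(frontier)) {
    added <- integer()
    # intramolecular closures on the frontier
    for (fi in frontier) {
      tpl <- pool[[fi]]
      n <- template_size(tpl)
      if (n >= 2L) {
        usage <- site_usage(tpl)
        bonded <- matrix(FALSE, n, n)
        if (nrow(tpl$bonds)) {
          bonded[tpl$bonds[, 1:2, drop = FALSE]] <- TRUE
          bonded <- bonded | t(bonded)
        }
        within <- !bonded & !diag(TRUE, n)
        for (bond in addable_bonds(tpl$kinds, usage, rules, within = within)) {
          nb <- normalize_bond(tpl$kinds, bond[1], bond[2], bond[3])
          cand <- new_template(tpl$kinds, rbind(tpl$bonds, nb))
          if (push(cand)) added <- c(added, length(pool))
        }
      }
    }
    # bimolecular merges: frontier x pool (both orders covered by symmetry)
    n_pool <- length(pool)
    for (fi in frontier) {
      for (pj in seq_len(n_pool)) {
        a <- pool[[fi]]; b <- pool[[pj]]
        na <- template_size(a); nb_ <- template_size(b)
        kinds <- c(a$kinds, b$kinds)
        bonds <- rbind(a$bonds,
                       if (nrow(b$bonds)) b$bonds +
                         matrix(c(na, na, 0L), nrow(b$bonds), 3, byrow = TRUE)
                       else NULL)
        if (is.null(bonds)) bonds <- matrix(integer(), ncol = 3)
        usage <- site_usage(new_template(kinds, bonds))
        # only cross bonds
        within <- matrix(FALSE, na + nb_, na + nb_)
        within[seq_len(na), na + seq_len(nb_)] <- TRUE
        within[na + seq_len(nb_), seq_len(na)] <- TRUE
        for (bond in addable_bonds(kinds, usage, rules, within = within)) {
          nbd <- normalize_bond(kinds, bond[1], bond[2], bond[3])
          cand <- new_template(kinds, rbind(bonds, nbd))
          if (push(cand)) added <- c(added, length(pool))
        }
      }
    }
    frontier <- unique(added)
  }
  keys_all <- vapply(pool, canonical_key, "")
  ord <- order(vapply(pool, template_size, 1L), keys_all)
  pool <- pool[ord]; keys_all <- keys_all[ord]
  tibble::tibble(
    key = keys_all,
    label = vapply(pool, template_label, ""),
    n_monomers = vapply(pool, template_size, 1L),
    n_R1 = vapply(pool, function(t) sum(t$kinds == "R1"), 1L),
    n_R2 = vapply(pool, function(t) sum(t$kinds == "R2"), 1L),
    n_N1 = vapply(pool, function(t) sum(t$kinds == "N1"), 1L),
    n_V165 = vapply(pool, function(t) sum(t$kinds == "V165"), 1L),
    n_V121 = vapply(pool, function(t) sum(t$kinds == "V121"), 1L),
    n_P1 = vapply(pool, function(t) sum(t$kinds == "P1"), 1L),
    n_P2 = vapply(pool, function(t) sum(t$kinds == "P2"), 1L),
    n_M = vapply(pool, function(t) sum(t$kinds == "M"), 1L),
    n_bonds = vapply(pool, function(t) nrow(t$bonds), 1L),
    has_matrix = vapply(pool, function(t) any(t$kinds == "M"), TRUE),
    template = pool
  )
}

# human-readable label, e.g. "V165d(R2.R2)" for the delta-closed triad
template_label <- function(tpl) {
  kinds <- tpl$kinds
  if (length(kinds) == 1L) return(kinds)
  b <- tpl$bonds
  has_rr <- any(b[, 3] == 4L)
  lig <- which(kinds %in% c("V165", "V121", "P1", "P2"))
  parts <- character()
  # delta marker: some ligand bound twice with its two receptors coupled
  delta <- FALSE
  for (i in lig) {
    tgt <- b[b[, 3] == 1L & b[, 1] == i, 2]
    if (length(tgt) == 2L &&
        any(b[, 3] == 4L &
            ((b[, 1] == tgt[1] & b[, 2] == tgt[2]) |
             (b[, 1] == tgt[2] & b[, 2] == tgt[1])))) delta <- TRUE
  }
  comp <- table(kinds)
  lab <- paste(vapply(names(comp), function(k)
    if (comp[[k]] > 1L) paste0(comp[[k]], "x", k) else k, ""),
    collapse = ".")
  n_xl <- sum(vapply(lig, function(i) sum(b[, 3] == 1L & b[, 1] == i) == 2L, TRUE))
  if (delta) lab <- paste0(lab, "[delta]")
  else if (n_xl > 0L) lab <- paste0(lab, "[bridge]")
  else if (has_rr || any(b[, 3] == 5L)) lab <- paste0(lab, "[dimer]")
  lab
}
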