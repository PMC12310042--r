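# Independent brute-force bond-graph enumeration oracle ----------------------
#
# Deliberately separate from the package implementation: enumerates every
# labelled graph over monomer multisets up to a size cap, filters by valence
# and connectivity, and deduplicates by explicit permutation isomorphism.
# Only practical for reduced rule sets (small multisets).

oracle_enumerate <- function(kinds_avail, allowed_bonds, capacities,
                             max_size = 4, max_per_kind = 2) {
  # all multisets up to max_size
  multisets <- list()
  grid <- expand.grid(rep(list(0:max_per_kind), length(kinds_avail)))
  names(grid) <- kinds_avail
  for (i in seq_len(nrow(grid))) {
    n <- sum(grid[i, ])
    if (n >= 1 && n <= max_size)
      multisets[[length(multisets) + 1L]] <-
        rep(kinds_avail, times = as.integer(grid[i, ]))
  }
  bond_ok <- function(k1, k2) {
    any(vapply(allowed_bonds, function(b)
      all(sort(b) == sort(c(k1, k2))), TRUE))
  }
  canon <- function(kinds, edges) {
    n <- length(kinds)
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (r in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], r)
      out
    }
    best <- NULL
    for (pp in perms(seq_len(n))) {
      if (any(kinds[pp] != kinds[order(kinds)])) next
      # relabel into sorted-kind order
      pos <- integer(n); pos[pp] <- seq_len(n)
      if (nrow(edges)) {
        e <- cbind(pmin(pos[edges[, 1]], pos[edges[, 2]]),
                   pmax(pos[edges[, 1]], pos[edges[, 2]]))
        e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
        key <- paste(apply(e, 1, paste, collapse = "-"), collapse = ";")
      } else key <- ""
      if (is.null(best) || key < best) best <- key
    }
    paste0(paste(sort(kinds), collapse = "+"), "|", best)
  }
  seen <- character()
  for (kinds in multisets) {
    n <- length(kinds)
    pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(), 2, 0)
    cand <- which(apply(pairs, 2, function(pr)
      bond_ok(kinds[pr[1]], kinds[pr[2]])))
    # every subset of candidate bonds
    for (mask in 0:(2^length(cand) - 1)) {
      sel <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0]
      edges <- t(pairs[, sel, drop = FALSE])
      if (n > 1 && length(sel) < n - 1) next  # cannot be connected
      # valence check
      deg_ok <- TRUE
      for (v in seq_len(n)) {
        used <- sum(edges == v)
        if (used > capacities[[kinds[v]]]$total) { deg_ok <- FALSE; break }
        # receptor-receptor vs ligand bonds tracked separately
        if (!is.null(capacities[[kinds[v]]]$per_partner)) {
          for (partner in names(capacities[[kinds[v]]]$per_partner)) {
            cnt <- sum(apply(edges, 1, function(e)
              (e[1] == v && kinds[e[2]] == partner) ||
                (e[2] == v && kinds[e[1]] == partner)))
            if (cnt > capacities[[kinds[v]]]$per_partner[[partner]]) {
              deg_ok <- FALSE; break
            }
          }
        }
        if (!deg_ok) break
      }
      if (!deg_ok) next
      # connectivity
      if (n > 1) {
        reach <- 1L
        repeat {
          new <- unique(c(reach, edges[edges[, 1] %in% reach, 2],
                          edges[edges[, 2] %in% reach, 1]))
          if (length(new) == length(reach)) break
          reach <- new
        }
        if (length(reach) < n) next
      }
      seen <- union(seen, canon(kinds, edges))
    }
  }
  seen
}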