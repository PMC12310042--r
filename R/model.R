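# Compilation of the network into integrator arrays ---------------------------

# memoized on the network object's cache environment
compile_arrays <- function(network) {
  if (is.null(network$cache)) {
    # networks built by older constructors: create a transient cache
    network$cache <- new.env(parent = emptyenv())
  }
  if (!is.null(network$cache$arrays)) return(network$cache$arrays)
  rx <- network$reactions
  n_rx <- nrow(rx)
  order <- rx$order
  i1 <- integer(n_rx); i2 <- integer(n_rx)
  s_rxn <- integer(0); s_sp <- integer(0); s_coef <- numeric(0)
  for (j in seq_len(n_rx)) {
    re <- rx$reactants[[j]]
    pr <- rx$products[[j]]
    if (order[j] >= 1L) i1[j] <- re[1]
    if (order[j] == 2L) i2[j] <- re[2]
    delta <- numeric(0)
    ids <- c(re, pr)
    coefs <- c(rep(-1, length(re)), rep(1, length(pr)))
    agg <- tapply(coefs, ids, sum)
    keep <- agg != 0
    if (any(keep)) {
      s_rxn <- c(s_rxn, rep(j, sum(keep)))
      s_sp <- c(s_sp, as.integer(names(agg))[keep])
      s_coef <- c(s_coef, as.numeric(agg[keep]))
    }
  }
  arrays <- list(
    order = as.integer(order),
    i1 = pmax(i1 - 1L, 0L), i2 = pmax(i2 - 1L, 0L),
    s_rxn = s_rxn - 1L, s_sp = s_sp - 1L, s_coef = s_coef,
    n_sp = nrow(network$species)
  )
  network$cache$arrays <- arrays
  arrays
}

model_arrays <- function(network, params) {
  a <- compile_arrays(network)
  a$rate <- compute_rates(network, params)
  a
}

#' Evaluate the time-derivative of the state
#'
#' Exposed mainly for testing and flux audits.
#'
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param state numeric state vector (#/cell), one entry per species row.
#' @return numeric vector dstate/dt (#/cell/s).
#' @export
state_derivative <- function(network, params, state) {
  .mass_action_rhs(model_arrays(network, params), state)
}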