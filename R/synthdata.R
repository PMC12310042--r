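# Synthetic western-blot datasets ---------------------------------------------
#
# The experimental readout the model is fitted to is a band intensity,
# normalized to a loading control and then to the no-ligand (time-zero)
# condition: a strictly positive, unit-centered ratio with large
# replicate-to-replicate variability. The generator emulates exactly that
# statistical structure: true localization ratios from a simulated
# trajectory times multiplicative lognormal noise, independent across time
# points and replicates, three replicates by default.

#' Generate a synthetic blot dataset from a truth trajectory
#'
#' Replicate ratios are sampled as truth x lognormal noise with unit mean
#' and the requested coefficient of variation; the draw is reproducible
#' given the seed.
#'
#' @param truth tibble of true ratios, from [predict_blot_ratios()]:
#'   columns (receptor, localization, time_min, ratio).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0.2, matching the reported high replicate variability).
#' @param n_reps replicates per condition (default 3).
#' @param seed RNG seed.
#' @param condition free-text condition label (ligand and dose).
#' @return tibble (condition, receptor, localization, time_min, replicate,
#'   ratio) with attributes \code{noise_cv} and \code{seed}.
#' @export
generate_blot_dataset <- function(truth, noise_cv = 0.2, n_reps = 3,
                                  seed = 1, condition = "V165 50 ng/mL") {
  stopifnot(noise_cv >= 0, n_reps >= 1)
  need <- c("receptor", "localization", "time_min", "ratio")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop("truth is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- withr::with_seed(seed, {
    reps <- lapply(seq_len(n_reps), function(r) {
      noise <- if (noise_cv > 0)
        stats::rlnorm(nrow(truth), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, nrow(truth))
      tibble::tibble(condition = condition,
                     receptor = truth$receptor,
                     localization = truth$localization,
                     time_min = truth$time_min,
                     replicate = r,
                     ratio = truth$ratio * noise)
    })
    dplyr::bind_rows(reps)
  })
  attr(out, "noise_cv") <- noise_cv
  attr(out, "seed") <- seed
  out
}

#' Parameter-recovery fixture for the internalization-multiplier fit
#'
#' Draws a ground-truth ligated-VEGFR2 internalization multiplier from the
#' scan grid, simulates the VEGF165a treatment under it, and emits a noisy
#' blot dataset together with the sealed truth, for recovery tests.
#'
#' @param seed RNG seed (controls both the multiplier draw and the noise).
#' @param network a \code{vegfr_network}.
#' @param params a \code{vegfr_params}.
#' @param multipliers candidate truth values (default 1, 2, 3, 4, 8).
#' @param noise_cv noise level.
#' @param n_reps replicates.
#' @param init optional pre-simulated state.
#' @param truth_multiplier optionally force the truth instead of drawing it.
#' @return list with \code{truth_multiplier}, \code{dataset} (tibble),
#'   \code{truth_ratios} (noise-free predictions).
#' @export
recovery_fixture <- function(seed, network, params,
                             multipliers = c(1, 2, 3, 4, 8),
                             noise_cv = 0.2, n_reps = 3, init = NULL,
                             truth_multiplier = NULL) {
  if (is.null(truth_multiplier))
    truth_multiplier <- withr::with_seed(seed, sample(multipliers, 1))
  p_t <- params
  i <- p_t$ligated_multipliers$receptor == "R2" &
    p_t$ligated_multipliers$param == "kint"
  p_t$ligated_multipliers$multiplier[i] <- truth_multiplier
  truth <- predict_blot_ratios(network, p_t, init = init)
  dataset <- generate_blot_dataset(truth, noise_cv = noise_cv,
                                   n_reps = n_reps, seed = seed,
                                   condition = sprintf(
                                     "V165 50 ng/mL (kint x%g)",
                                     truth_multiplier))
  list(truth_multiplier = truth_multiplier, dataset = dataset,
       truth_ratios = truth)
}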