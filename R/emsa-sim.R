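#' Simulate EMSA lane quantifications for a saturation binding series
#'
#' The true bound fraction follows the one-site specific-binding model
#' `Y = Bmax * X / (Kd + X)`.  Observed fractions add Gaussian noise
#' (truncated to `[0, 1]`); lane intensities are emitted on an arbitrary
#' densitometry scale with a positive background offset added to both
#' bands, so that background subtraction followed by the bound/(bound +
#' unbound) ratio recovers the noisy fraction exactly.
#'
#' @param kd dissociation constant in nM (> 0)
#' @param bmax saturating bound fraction (> 0)
#' @param concentrations protein concentrations in nM (all > 0); the
#'   default is the five-point 50-2000 nM design
#' @param noise_sd Gaussian noise on the bound fraction
#' @param n_replicates replicate series (default 3, i.e. triplicates)
#' @param seed integer seed
#' @param total_intensity band intensity scale (arbitrary units)
#' @param background_level mean blank-region intensity
#' @return list with `lanes` (data.table: `lane`, `replicate`,
#'   `concentration_nM`, `bound`, `unbound`, `background`) and `truth`
#'   (`kd`, `bmax`, per-lane true and observed fractions)
#' @export
generate_emsa_data <- function(kd, bmax = 1,
                               concentrations = c(50, 100, 500, 1000, 2000),
                               noise_sd = 0.02, n_replicates = 3, seed = 1,
                               total_intensity = 1000,
                               background_level = 50) {
  if (kd <= 0) stop("kd must be positive")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  withr::with_seed(fan_seed(seed, "emsa"), {
    grid <- data.table(
      replicate = rep(seq_len(n_replicates), each = length(concentrations)),
      concentration_nM = rep(concentrations, n_replicates))
    y_true <- bmax * grid$concentration_nM / (kd + grid$concentration_nM)
    y_obs <- pmin(1, pmax(0, y_true + rnorm(nrow(grid), 0, noise_sd)))
    bg <- abs(rnorm(nrow(grid), background_level, background_level / 10))
    lanes <- data.table(
      lane = sprintf("lane_%02d", seq_len(nrow(grid))),
      replicate = grid$replicate,
      concentration_nM = grid$concentration_nM,
      bound = total_intensity * y_obs + bg,
      unbound = total_intensity * (1 - y_obs) + bg,
      background = bg)
  })
  list(lanes = lanes,
       truth = list(kd = kd, bmax = bmax,
                    fraction_true = y_true, fraction_observed = y_obs))
}

#' Write an EMSA lane CSV
#' @param lanes data.table from [generate_emsa_data()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_emsa_lanes <- function(lanes, path) {
  fwrite(lanes, path)
  invisible(path)
}
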