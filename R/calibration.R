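#' Calibration inputs
#'
#' The constants entering the density / labeling-efficiency chain. These are
#' preparation-specific (species, age, synapse type) and therefore always
#' supplied by the caller, never hard-coded: `n_total_channels` comes from
#' independent functional estimates (e.g. 1,320 channels per mossy-fiber
#' bouton), the AZ and extra-AZ areas from ultrastructural reconstructions
#' (e.g. 3.33 and 75.5 um^2 per bouton), and the particle densities from the
#' replica itself (e.g. 232 and 0.84 particles/um^2), either measured
#' elsewhere or computed here with [densities_from_patterns()].
#'
#' @param n_total_channels total channels per bouton (N_total, > 0 for the
#'   efficiency chain).
#' @param az_total_area_um2 total AZ area per bouton, um^2 (> 0).
#' @param extra_area_um2 extra-AZ membrane area per bouton, um^2 (>= 0).
#' @param rho_az gold-particle density in AZs, particles/um^2.
#' @param rho_extra gold-particle density outside AZs, particles/um^2.
#' @return an object of class `calibration_inputs`.
#' @export
calibration_inputs <- function(n_total_channels, az_total_area_um2,
                               extra_area_um2, rho_az, rho_extra) {
  stopifnot(n_total_channels >= 0, az_total_area_um2 > 0,
            extra_area_um2 >= 0, rho_az >= 0, rho_extra >= 0)
  structure(list(n_total_channels = n_total_channels,
                 az_total_area_um2 = az_total_area_um2,
                 extra_area_um2 = extra_area_um2,
                 rho_az = rho_az, rho_extra = rho_extra),
            class = "calibration_inputs")
}

#' Pooled particle densities from a dataset
#'
#' Pools particle counts and window areas per region class and reports
#' densities in particles/um^2. Only P-face patterns contribute (E-face and
#' cross-fracture particles are background by construction). Extra-AZ
#' regions are optional; their absence yields `rho_extra = 0`.
#'
#' @param dataset a [replica_dataset()].
#' @return list with `rho_az`, `rho_extra` (particles/um^2), plus the pooled
#'   `az_area_um2`, `extra_area_um2`, `n_az_particles`, `n_extra_particles`.
#' @export
densities_from_patterns <- function(dataset) {
  stopifnot(inherits(dataset, "replica_dataset"))
  if (!length(dataset$patterns))
    stop("dataset contains no patterns", call. = FALSE)
  pf <- Filter(function(p) p$face == "P_face", dataset$patterns)
  az <- Filter(function(p) p$window$region_class == "AZ", pf)
  ex <- Filter(function(p) p$window$region_class == "extra_AZ", pf)
  if (!length(az))
    stop("dataset contains no AZ region", call. = FALSE)
  a_az <- sum(vapply(az, function(p) polygon_area(p$window), 0)) / NM2_PER_UM2
  n_az <- sum(vapply(az, npoints, 0L))
  if (a_az <= 0) stop("total AZ area is zero", call. = FALSE)
  if (length(ex)) {
    a_ex <- sum(vapply(ex, function(p) polygon_area(p$window), 0)) / NM2_PER_UM2
    if (a_ex <= 0) stop("total extra-AZ area is zero", call. = FALSE)
    n_ex <- sum(vapply(ex, npoints, 0L))
  } else {
    a_ex <- 0; n_ex <- 0L
  }
  list(rho_az = n_az / a_az,
       rho_extra = if (a_ex > 0) n_ex / a_ex else 0,
       az_area_um2 = a_az, extra_area_um2 = a_ex,
       n_az_particles = n_az, n_extra_particles = n_ex)
}

#' Fraction of channels located in active zones
#'
#' f_AZ = rho_AZ A_AZ / (rho_AZ A_AZ + rho_extra A_extra) — the share of all
#' labelled channels that sit inside AZs, assuming a common labeling
#' efficiency inside and outside. With the reference constants
#' (232, 3.33, 0.84, 75.5) this is 0.924, i.e. 92% of channels in AZs.
#'
#' @param inputs a [calibration_inputs()].
#' @return fraction in \[0, 1\].
#' @export
fraction_in_az <- function(inputs) {
  stopifnot(inherits(inputs, "calibration_inputs"))
  num <- inputs$rho_az * inputs$az_total_area_um2
  den <- num + inputs$rho_extra * inputs$extra_area_um2
  if (den <= 0)
    stop("fraction undefined: no particles in either compartment",
         call. = FALSE)
  num / den
}

#' True AZ channel density and labeling efficiency
#'
#' true density = N_total x f_AZ / A_AZ (channels/um^2), and
#' efficiency = rho_AZ / true density — the probability that one channel
#' yields one detected gold particle. With the reference constants this is
#' (1,320 x 0.92) / 3.33 = 365 channels/um^2 and 232 / 365 = 64%.
#' Efficiency above 1 indicates over-labeling (antibody aggregation or
#' multiple binding) and triggers a warning rather than clamping.
#'
#' @param inputs a [calibration_inputs()].
#' @param f_az fraction of channels in AZs; defaults to
#'   [fraction_in_az()] of `inputs`.
#' @return an object of class `calibration_result`: `f_az`,
#'   `true_density_az` (channels/um^2), `efficiency`, `inputs`.
#' @export
true_density_and_efficiency <- function(inputs,
                                        f_az = fraction_in_az(inputs)) {
  stopifnot(inherits(inputs, "calibration_inputs"))
  if (inputs$n_total_channels <= 0)
    stop("n_total_channels must be positive for the efficiency chain",
         call. = FALSE)
  true_density <- inputs$n_total_channels * f_az / inputs$az_total_area_um2
  if (true_density <= 0)
    stop("true density is zero: efficiency undefined", call. = FALSE)
  efficiency <- inputs$rho_az / true_density
  if (efficiency > 1)
    warning("efficiency > 1: apparent over-labeling ",
            "(antibody aggregation or multiple binding)", call. = FALSE)
  structure(list(f_az = f_az, true_density_az = true_density,
                 efficiency = efficiency, inputs = inputs),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  # report rounding convention: densities to integers, efficiency and f_az
  # to whole percent; machine-readable fields keep full precision
  cat(sprintf(
    "calibration_result: f_AZ = %.0f%%, true AZ density = %.0f channels/um^2, efficiency = %.0f%%\n",
    100 * x$f_az, x$true_density_az, 100 * x$efficiency))
  invisible(x)
}

#' Convert a particle count to an estimated channel count
#'
#' channels = particles / efficiency. With efficiency 0.64, an AZ with 16
#' particles is estimated to hold 25 channels.
#'
#' @param az_particle_count particle count(s), vectorised.
#' @param efficiency labeling efficiency in (0, 1].
#' @return estimated channel count(s).
#' @export
channels_per_az <- function(az_particle_count, efficiency) {
  if (efficiency <= 0)
    stop("efficiency must be positive", call. = FALSE)
  az_particle_count / efficiency
}
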