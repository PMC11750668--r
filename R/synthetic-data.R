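#' Synthetic saturating oxidation-rate ramp
#'
#' Generates an exogenous-oxidation-rate curve with the shape such curves
#' show in tracer studies: zero at the first drink, rising with a single
#' time constant toward a plateau as gut absorption and delivery saturate:
#' \deqn{r(t) = r_{max} (1 - e^{-t/\tau}) + \epsilon(t),}
#' with optional i.i.d. Gaussian noise, clipped at zero.  The noiseless
#' family has the closed-form integral
#' \eqn{r_{max}(T - \tau(1 - e^{-T/\tau}))}, which the test-suite uses as an
#' analytic oracle for the bin-averaging integrator.
#'
#' @param r_max Plateau oxidation rate, g/min (> 0).
#' @param tau Time constant of the ramp, min (> 0).
#' @param noise_sd Standard deviation of additive Gaussian noise, g/min
#'   (>= 0).
#' @param seed Integer seed; the curve is deterministic for a fixed seed.
#' @param duration Curve duration, min (> 0).
#' @param step Sampling step, min (> 0).
#' @return An \code{\link{oxidation_curve}} sampled at
#'   \code{seq(0, duration, by = step)}.
#' @examples
#' make_ramp_curve(r_max = 1.5, tau = 30, duration = 120, step = 5)
#' @export
make_ramp_curve <- function(r_max, tau, noise_sd = 0, seed = 1L,
                            duration = 120, step = 5) {
  stopifnot(r_max > 0, tau > 0, noise_sd >= 0, duration > 0, step > 0)
  times <- seq(0, duration, by = step)
  if (times[length(times)] < duration) times <- c(times, duration)
  rates <- r_max * (1 - exp(-times / tau))
  if (noise_sd > 0) {
    rates <- withr::with_seed(as.integer(seed),
                              rates + stats::rnorm(length(rates), 0, noise_sd))
  }
  oxidation_curve(times, pmax(rates, 0),
                  label = sprintf("ramp(r_max=%g, tau=%g)", r_max, tau))
}

#' Closed-form integral of the noiseless ramp
#'
#' \eqn{\int_0^T r_{max}(1 - e^{-t/\tau}) dt = r_{max}(T - \tau(1 - e^{-T/\tau}))}.
#' Exposed so callers can check integrators against the analytic value.
#'
#' @inheritParams make_ramp_curve
#' @param upper Upper limit of integration, min.
#' @return Grams oxidized over [0, upper].
#' @export
ramp_integral <- function(r_max, tau, upper) {
  r_max * (upper - tau * (1 - exp(-upper / tau)))
}

#' Deterministic grid of athlete fuel profiles
#'
#' Builds a body-mass sweep of valid fuel profiles by scaling a reference
#' profile's extensive quantities (energy expenditure, oxidation rates,
#' glycogen store, liver glucose) linearly with body mass.  Linear mass
#' scaling is the simplest defensible allometry for whole-body fuel fluxes
#' and stores over a narrow elite-runner mass range; the grid exists to
#' exercise downstream code on plausible parameter spreads, not to model
#' individual athletes.
#'
#' @param mass_range Body masses, kg; non-empty, all > 0.
#' @param reference An \code{\link{athlete_profile}} used as the anchor.
#' @param reference_mass Body mass the reference profile corresponds to, kg.
#' @return A list of validated \code{athlete_profile} objects, one per mass.
#' @examples
#' grid <- make_profile_grid(c(54, 58, 62), load_profile("male"), 59)
#' @export
make_profile_grid <- function(mass_range, reference = load_profile("male"),
                              reference_mass = 59) {
  if (!length(mass_range)) stop("`mass_range` must be non-empty", call. = FALSE)
  stopifnot(all(mass_range > 0), reference_mass > 0,
            inherits(reference, "athlete_profile"))
  lapply(as.numeric(mass_range), function(m) {
    s <- m / reference_mass
    athlete_profile(
      label = sprintf("%s_%gkg", reference$label, m),
      total_energy_rate = reference$total_energy_rate * s,
      cho_ox_rate = reference$cho_ox_rate * s,
      fat_ox_rate = reference$fat_ox_rate * s,
      glycogen_capacity = reference$glycogen_capacity * s,
      liver_glucose_total = reference$liver_glucose_total * s,
      duration = reference$duration)
  })
}
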