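#' Total carbohydrate oxidized over the bout
#'
#' The obligatory carbohydrate demand: oxidation rate times duration
#' (5.1 g/min over 120 min is 612 g; 4.4 g/min gives 528 g).
#'
#' @param cho_ox_rate Carbohydrate oxidation rate, g/min (>= 0).
#' @param duration Exercise duration, min (>= 0).
#' @return Grams of carbohydrate required, exact product.
#' @export
total_cho_required <- function(cho_ox_rate, duration) {
  stopifnot(all(cho_ox_rate >= 0), all(duration >= 0))
  cho_ox_rate * duration
}

#' Carbohydrate deficit beyond usable muscle glycogen
#'
#' Demand not covered by muscle glycogen, clamped at zero: a glycogen store
#' larger than the demand leaves no deficit (the surplus is flagged, not
#' reported as a negative requirement).
#'
#' @param total_required Total carbohydrate demand, g.
#' @param glycogen_supplied Usable muscle glycogen, g.
#' @return Grams of deficit, with attribute \code{surplus} (logical): TRUE
#'   when glycogen exceeded demand and the value was clamped at 0.
#' @examples
#' cho_deficit(612, 469)  # 143 g
#' @export
cho_deficit <- function(total_required, glycogen_supplied) {
  stopifnot(all(total_required >= 0), all(glycogen_supplied >= 0))
  raw <- total_required - glycogen_supplied
  structure(pmax(raw, 0), surplus = raw < 0)
}

#' Exogenous carbohydrate required after liver-glucose accounting
#'
#' Two accounting conventions for the liver glucose pool:
#' \describe{
#'   \item{\code{"printed"}}{the deficit plus the liver contribution --- the
#'     convention behind the headline 211 g (male) and 238 g (female)
#'     requirements, which models hepatic glucose output as fully suppressed
#'     by high carbohydrate ingestion so its share must also come from the
#'     drinks.}
#'   \item{\code{"strict"}}{the deficit alone --- the liver pool is simply
#'     reassigned to exogenous supply without adding it on top, avoiding the
#'     double count.}
#' }
#'
#' @param deficit Carbohydrate deficit beyond muscle glycogen, g.
#' @param liver_contribution Liver glucose disappearance, g.
#' @param mode \code{"printed"} (default) or \code{"strict"}.
#' @return Grams of exogenous carbohydrate required.
#' @examples
#' corrected_exogenous(143, 68)            # 211 g
#' corrected_exogenous(143, 68, "strict")  # 143 g
#' @export
corrected_exogenous <- function(deficit, liver_contribution,
                                mode = c("printed", "strict")) {
  stopifnot(all(deficit >= 0), all(liver_contribution >= 0))
  mode <- match.arg(mode)
  if (mode == "printed") as.numeric(deficit) + liver_contribution
  else as.numeric(deficit)
}

#' Convert a bout total to a per-hour rate
#'
#' @param total Grams over the bout.
#' @param duration Bout duration, min (> 0).
#' @return Rate in g/hr.
#' @examples
#' rate_per_hour(211, 120)  # 105.5 g/hr
#' @export
rate_per_hour <- function(total, duration) {
  if (any(duration <= 0)) stop("`duration` must be positive", call. = FALSE)
  total / (duration / 60)
}

#' Shortfall of an oxidation ceiling against a required rate
#'
#' Compares what a model demands (a required exogenous oxidation rate) with
#' what gut/oxidation physiology can deliver over the bout (a ceiling on
#' total exogenous oxidation, e.g. the 137 g observed under the best drink
#' formulation).  Positive values are the shortfall --- the grams by which the
#' requirement overshoots the ceiling; negative values are surplus headroom.
#'
#' @param required_rate Required exogenous oxidation rate, g/hr.
#' @param ceiling_total Achievable total exogenous oxidation over the bout, g.
#' @param duration Bout duration, min.
#' @return Signed grams over the bout.
#' @examples
#' oxidation_shortfall(106, 137, 120)  # 75 g short over 2 h
#' @export
oxidation_shortfall <- function(required_rate, ceiling_total, duration) {
  stopifnot(all(required_rate >= 0), all(ceiling_total >= 0),
            all(duration >= 0))
  required_rate * (duration / 60) - ceiling_total
}

#' Full exogenous-requirement accounting for one threshold
#'
#' Runs demand, glycogen supply, deficit, liver correction and per-hour
#' conversion in one pass.  This is the per-threshold engine behind
#' \code{\link{fuel_budget}}.
#'
#' @param profile An \code{\link{athlete_profile}}.
#' @param threshold Depletion threshold fraction in [0, 1].
#' @param liver_mode \code{"printed"} or \code{"strict"}; see
#'   \code{\link{corrected_exogenous}}.
#' @return An object of class \code{exogenous_requirement}: a list with
#'   \code{total_cho_required}, \code{glycogen_supplied}, \code{deficit},
#'   \code{surplus} (logical clamp flag), \code{liver_contribution},
#'   \code{liver_mode}, \code{exogenous_total} and \code{exogenous_rate}
#'   (g/hr).
#' @export
exogenous_requirement <- function(profile, threshold,
                                  liver_mode = c("printed", "strict")) {
  stopifnot(inherits(profile, "athlete_profile"))
  liver_mode <- match.arg(liver_mode)
  demand <- total_cho_required(profile$cho_ox_rate, profile$duration)
  supplied <- usable_glycogen(profile$glycogen_capacity, threshold)
  deficit <- cho_deficit(demand, supplied)
  exo <- corrected_exogenous(deficit, profile$liver_glucose_total, liver_mode)
  structure(list(total_cho_required = demand,
                 glycogen_supplied = supplied,
                 deficit = as.numeric(deficit),
                 surplus = isTRUE(attr(deficit, "surplus")),
                 liver_contribution = profile$liver_glucose_total,
                 liver_mode = liver_mode,
                 exogenous_total = exo,
                 exogenous_rate = rate_per_hour(exo, profile$duration)),
            class = "exogenous_requirement")
}

#' @export
print.exogenous_requirement <- function(x, ...) {
  cat(sprintf("Exogenous CHO requirement (liver mode: %s)\n", x$liver_mode))
  cat(sprintf("  demand %g g | glycogen %g g | deficit %g g%s\n",
              x$total_cho_required, x$glycogen_supplied, x$deficit,
              if (x$surplus) " (glycogen surplus, clamped)" else ""))
  cat(sprintf("  exogenous %g g (%.1f g/hr)\n",
              x$exogenous_total, x$exogenous_rate))
  invisible(x)
}
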