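#' Athlete fuel profile
#'
#' Bundles the per-athlete model parameters that drive the whole fuel budget:
#' total energy expenditure, carbohydrate and fat oxidation rates at race
#' intensity, the muscle glycogen store at the start line, and the liver
#' glucose made available over the race.  All rates are per minute and all
#' amounts in grams; per-hour values are produced only at reporting
#' boundaries.
#'
#' Two fixtures are packaged, \code{"male"} and \code{"female"}, carrying the
#' published model parameters for a sub-2-hour-marathon attempt
#' (male: 88.3 kJ/min, CHO 5.1 g/min, fat 0.07 g/min, glycogen 690 g,
#' liver glucose 68 g; female: 75.7 kJ/min, 4.4 g/min, 0.06 g/min, 499 g,
#' 49 g).  Load them with \code{\link{load_profile}}.
#'
#' @param label Free-text label for the profile (e.g. \code{"male"}).
#' @param total_energy_rate Total energy expenditure, kJ/min.
#' @param cho_ox_rate Carbohydrate oxidation rate, g/min.
#' @param fat_ox_rate Fat oxidation rate, g/min.
#' @param glycogen_capacity Muscle glycogen at the start of exercise, g.
#' @param liver_glucose_total Liver glucose disappearance over the bout, g.
#' @param duration Exercise duration, min. Defaults to 120 (a 2-hour race).
#'
#' @return An object of class \code{athlete_profile}.
#' @seealso \code{\link{load_profile}}, \code{\link{fuel_budget}}
#' @export
athlete_profile <- function(label, total_energy_rate, cho_ox_rate,
                            fat_ox_rate, glycogen_capacity,
                            liver_glucose_total, duration = 120) {
  num <- c(total_energy_rate = total_energy_rate, cho_ox_rate = cho_ox_rate,
           fat_ox_rate = fat_ox_rate, glycogen_capacity = glycogen_capacity,
           liver_glucose_total = liver_glucose_total, duration = duration)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("field `%s` must be a single finite number", nm),
           call. = FALSE)
    }
    if (v < 0) {
      stop(sprintf("field `%s` must be non-negative (got %g)", nm, v),
           call. = FALSE)
    }
  }
  if (duration <= 0) {
    stop("field `duration` must be positive", call. = FALSE)
  }
  structure(list(label = as.character(label)[1L],
                 total_energy_rate = as.numeric(total_energy_rate),
                 cho_ox_rate = as.numeric(cho_ox_rate),
                 fat_ox_rate = as.numeric(fat_ox_rate),
                 glycogen_capacity = as.numeric(glycogen_capacity),
                 liver_glucose_total = as.numeric(liver_glucose_total),
                 duration = as.numeric(duration)),
            class = "athlete_profile")
}

profile_fields <- c("label", "total_energy_rate", "cho_ox_rate",
                    "fat_ox_rate", "glycogen_capacity",
                    "liver_glucose_total", "duration")

#' Load an athlete fuel profile from a fixture or config file
#'
#' @param source Either the name of a packaged fixture (\code{"male"} or
#'   \code{"female"}) or the path to a flat JSON document whose keys are
#'   exactly the \code{\link{athlete_profile}} field names (\code{duration}
#'   optional, default 120 min).
#'
#' @return A validated \code{athlete_profile}.
#' @examples
#' load_profile("male")$cho_ox_rate   # 5.1 g/min
#' load_profile("female")$glycogen_capacity  # 499 g
#' @export
load_profile <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- if (source %in% c("male", "female")) {
    system.file("extdata", paste0("profile_", source, ".json"),
                package = "fuelbudget", mustWork = TRUE)
  } else {
    if (!file.exists(source)) {
      stop(sprintf("profile source '%s' is neither a packaged fixture ",
                   source), "(\"male\"/\"female\") nor an existing file",
           call. = FALSE)
    }
    source
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("could not parse profile config '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  required <- setdiff(profile_fields, c("duration"))
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop(sprintf("profile config is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  athlete_profile(label = doc$label,
                  total_energy_rate = doc$total_energy_rate,
                  cho_ox_rate = doc$cho_ox_rate,
                  fat_ox_rate = doc$fat_ox_rate,
                  glycogen_capacity = doc$glycogen_capacity,
                  liver_glucose_total = doc$liver_glucose_total,
                  duration = if (is.null(doc$duration)) 120 else doc$duration)
}

#' Write an athlete fuel profile to a flat JSON config
#'
#' The inverse of \code{\link{load_profile}}: re-loading the written file
#' reproduces every field exactly.
#'
#' @param profile An \code{athlete_profile}.
#' @param path File to write.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "athlete_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf("Athlete fuel profile: %s (%g min)\n", x$label, x$duration))
  cat(sprintf("  energy expenditure %.1f kJ/min | CHO %.2f g/min | fat %.2f g/min\n",
              x$total_energy_rate, x$cho_ox_rate, x$fat_ox_rate))
  cat(sprintf("  muscle glycogen %g g | liver glucose %g g\n",
              x$glycogen_capacity, x$liver_glucose_total))
  invisible(x)
}

#' Audit the energy closure of a fuel profile
#'
#' Checks whether the substrate oxidation rates, converted through the energy
#' densities, reproduce the stated total energy expenditure.  Returns the
#' relative discrepancy
#' \deqn{|r_{CHO} e_{CHO} + r_{fat} e_{fat} - E| / E,}
#' a dimensionless number that should be small (a few percent) when rates and
#' total were measured or modelled consistently.
#'
#' @param profile An \code{\link{athlete_profile}}.
#' @param constants An \code{\link{energy_constants}} object.
#' @return Relative discrepancy (dimensionless, >= 0).
#' @examples
#' audit_energy_closure(load_profile("male"))  # about 0.03
#' @export
audit_energy_closure <- function(profile, constants = energy_constants()) {
  stopifnot(inherits(profile, "athlete_profile"),
            inherits(constants, "energy_constants"))
  if (profile$total_energy_rate == 0) {
    stop("energy closure is undefined when `total_energy_rate` is zero",
         call. = FALSE)
  }
  reconstructed <- profile$cho_ox_rate * constants$e_cho +
    profile$fat_ox_rate * constants$e_fat
  abs(reconstructed - profile$total_energy_rate) / profile$total_energy_rate
}
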