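#' Fuel budget for a marathon at sub-2-hour intensity
#'
#' The central accounting object of the package.  For one athlete profile it
#' runs the complete substrate budget at each requested glycogen-depletion
#' threshold: total carbohydrate demand over the bout, glycogen remnant and
#' usable store at the threshold, the deficit beyond muscle glycogen, the
#' liver-glucose correction, and the resulting exogenous carbohydrate
#' requirement in grams and g/hr.  With two thresholds it also reports the
#' windfall --- the extra glycogen freed by relaxing the stricter threshold.
#'
#' Every value is recomputed from the profile at call time; nothing is
#' cached.  All rounding happens at the glycogen remnant (half away from
#' zero to whole grams); downstream rows consume the rounded remnant, which
#' keeps the budget in integer grams for integer inputs.
#'
#' @param profile An \code{\link{athlete_profile}}, or a fixture name /
#'   config path accepted by \code{\link{load_profile}}.
#' @param thresholds Glycogen depletion thresholds as fractions in [0, 1].
#'   Default \code{c(0.32, 0.20)}: the critiqued model's 32\% and the 20\%
#'   alternative supported by the classic depletion studies.
#' @param liver_mode Liver-glucose accounting, \code{"printed"} (default) or
#'   \code{"strict"}; see \code{\link{corrected_exogenous}}.
#' @param constants An \code{\link{energy_constants}} object.
#'
#' @return An object of class \code{fuel_budget}: a list with the echoed
#'   inputs (\code{profile}, \code{thresholds}, \code{liver_mode},
#'   \code{constants}), the energy-closure audit (\code{closure}), the total
#'   demand (\code{total_cho_required}), one \code{\link{glycogen_budget}}
#'   and one \code{\link{exogenous_requirement}} per threshold
#'   (\code{glycogen}, \code{requirement}, named by threshold), and
#'   \code{windfall} (g; \code{NA} with fewer than two thresholds).
#'
#' @examples
#' fb <- fuel_budget("male")
#' fb
#' coef(fb)
#' predict(fb, fat_rate = c(0.07, 0.5, 0.75))
#' @seealso \code{\link{fat_scenario_sweep}}, \code{\link{cumulative_oxidation}}
#' @export
fuel_budget <- function(profile, thresholds = c(0.32, 0.20),
                        liver_mode = c("printed", "strict"),
                        constants = energy_constants()) {
  if (is.character(profile)) profile <- load_profile(profile)
  stopifnot(inherits(profile, "athlete_profile"),
            inherits(constants, "energy_constants"))
  liver_mode <- match.arg(liver_mode)
  if (!length(thresholds) || any(thresholds < 0) || any(thresholds > 1)) {
    stop("`thresholds` must be a non-empty vector of fractions in [0, 1]",
         call. = FALSE)
  }
  thresholds <- sort(unique(as.numeric(thresholds)), decreasing = TRUE)
  tnames <- threshold_name(thresholds)
  glyc <- lapply(thresholds, function(f)
    glycogen_budget(profile$glycogen_capacity, f))
  reqs <- lapply(thresholds, function(f)
    exogenous_requirement(profile, f, liver_mode))
  names(glyc) <- names(reqs) <- tnames
  windfall <- if (length(thresholds) >= 2L) {
    threshold_windfall(profile$glycogen_capacity,
                       max(thresholds), min(thresholds))
  } else NA_real_
  structure(list(profile = profile,
                 thresholds = thresholds,
                 liver_mode = liver_mode,
                 constants = constants,
                 closure = audit_energy_closure(profile, constants),
                 total_cho_required = total_cho_required(profile$cho_ox_rate,
                                                         profile$duration),
                 glycogen = glyc,
                 requirement = reqs,
                 windfall = windfall),
            class = "fuel_budget")
}

# "32" for 0.32, "2.5" for 0.025 -- percent label without trailing zeros
threshold_name <- function(f) {
  vapply(f, function(x) sub("\\.?0+$", "", sprintf("%.4f", 100 * x)),
         character(1))
}

#' @export
print.fuel_budget <- function(x, ...) {
  p <- x$profile
  cat(sprintf("Marathon fuel budget: %s profile, %g min, liver mode '%s'\n",
              p$label, p$duration, x$liver_mode))
  cat(sprintf("  CHO %g g/min, fat %g g/min, glycogen %g g, liver glucose %g g\n",
              p$cho_ox_rate, p$fat_ox_rate, p$glycogen_capacity,
              p$liver_glucose_total))
  cat(sprintf("  Total CHO demand over bout: %g g\n\n", x$total_cho_required))
  tn <- names(x$requirement)
  wide <- max(nchar(tn)) + 2L
  hdr <- paste0(sprintf("  %-42s", "threshold (% of starting glycogen)"),
                paste(formatC(paste0(tn, "%"), width = wide), collapse = ""))
  cat(hdr, "\n")
  row <- function(lab, vals, fmt = "%g") {
    cat(sprintf("  %-42s", lab),
        paste(formatC(sprintf(fmt, vals), width = wide), collapse = ""), "\n",
        sep = "")
  }
  row("glycogen remnant (g)", vapply(x$glycogen, `[[`, 0, "remnant"))
  row("usable glycogen (g)", vapply(x$glycogen, `[[`, 0, "usable"))
  row("CHO deficit beyond glycogen (g)",
      vapply(x$requirement, `[[`, 0, "deficit"))
  row("required exogenous CHO (g)",
      vapply(x$requirement, `[[`, 0, "exogenous_total"))
  row("required exogenous CHO (g/hr)",
      vapply(x$requirement, `[[`, 0, "exogenous_rate"), fmt = "%.1f")
  if (!is.na(x$windfall)) {
    cat(sprintf("\n  Windfall from relaxing %s%% to %s%%: %g g\n",
                tn[1L], tn[length(tn)], x$windfall))
  }
  invisible(x)
}

#' @export
summary.fuel_budget <- function(object, ...) {
  print(object)
  cat(sprintf("\n  Energy closure discrepancy: %.1f%% (CHO %.1f + fat %.1f vs %.1f kJ/min)\n",
              100 * object$closure,
              object$profile$cho_ox_rate * object$constants$e_cho,
              object$profile$fat_ox_rate * object$constants$e_fat,
              object$profile$total_energy_rate))
  zc <- vapply(object$requirement, function(r)
    zero_exogenous_fat_rate(r$exogenous_rate, object$profile$fat_ox_rate,
                            object$constants), numeric(1))
  cat("  Fat oxidation rate closing the requirement (g/min):",
      paste(sprintf("%s%%: %.2f", names(zc), zc), collapse = ", "), "\n")
  cat(sprintf("  Energy constants: CHO %.1f, fat %.1f kJ/g\n",
              object$constants$e_cho, object$constants$e_fat))
  invisible(object)
}

#' Flatten a fuel budget to a one-row record
#'
#' One field per budget row, suffixed by threshold percent (e.g.
#' \code{remnant_32}, \code{exogenous_rate_20}), plus the echoed inputs.
#' This is the serialization surface used by \code{\link{write_report}}.
#'
#' @param x A \code{fuel_budget}.
#' @param ... Unused.
#' @return A one-row data.frame.
#' @export
as.data.frame.fuel_budget <- function(x, ...) {
  p <- x$profile
  rec <- data.frame(label = p$label,
                    duration = p$duration,
                    total_energy_rate = p$total_energy_rate,
                    cho_ox_rate = p$cho_ox_rate,
                    fat_ox_rate = p$fat_ox_rate,
                    glycogen_capacity = p$glycogen_capacity,
                    liver_glucose_total = p$liver_glucose_total,
                    liver_mode = x$liver_mode,
                    e_cho = x$constants$e_cho,
                    e_fat = x$constants$e_fat,
                    total_cho_required = x$total_cho_required,
                    stringsAsFactors = FALSE)
  for (tn in names(x$requirement)) {
    g <- x$glycogen[[tn]]; r <- x$requirement[[tn]]
    rec[[paste0("remnant_", tn)]] <- g$remnant
    rec[[paste0("usable_", tn)]] <- g$usable
    rec[[paste0("deficit_", tn)]] <- r$deficit
    rec[[paste0("exogenous_total_", tn)]] <- r$exogenous_total
    rec[[paste0("exogenous_rate_", tn)]] <- r$exogenous_rate
  }
  rec$windfall <- x$windfall
  rec
}

#' @export
coef.fuel_budget <- function(object, ...) {
  rec <- as.data.frame(object)
  num <- rec[vapply(rec, is.numeric, logical(1))]
  stats::setNames(as.numeric(num[1L, ]), names(num))
}

#' Predict exogenous requirements under raised fat oxidation
#'
#' Evaluates the fat-oxidation counterfactual for a fitted budget: for each
#' scenario fat rate, the spared carbohydrate is credited against the
#' budget's per-hour exogenous requirement.
#'
#' @param object A \code{\link{fuel_budget}}.
#' @param fat_rate Scenario fat oxidation rates, g/min; all >= the
#'   profile's baseline rate.
#' @param threshold Which threshold's requirement to use (percent label or
#'   fraction); defaults to the budget's first (stricter) threshold.
#' @param base_rate Override the per-hour base requirement, g/hr (e.g. the
#'   upstream model's externally stated 90 or 106 g/hr), bypassing
#'   \code{threshold}.
#' @param ... Unused.
#' @return A data.frame with columns \code{scenario_fat_rate},
#'   \code{spared_cho_rate}, \code{required_exogenous_rate}; attribute
#'   \code{zero_crossing_fat_rate}.
#' @export
predict.fuel_budget <- function(object, fat_rate = NULL, threshold = NULL,
                                base_rate = NULL, ...) {
  if (is.null(base_rate)) {
    tn <- if (is.null(threshold)) {
      names(object$requirement)[1L]
    } else if (is.numeric(threshold)) {
      threshold_name(threshold)
    } else as.character(threshold)
    if (!tn %in% names(object$requirement)) {
      stop(sprintf("threshold '%s' not in this budget (have: %s)", tn,
                   paste(names(object$requirement), collapse = ", ")),
           call. = FALSE)
    }
    base_rate <- object$requirement[[tn]]$exogenous_rate
  }
  baseline <- object$profile$fat_ox_rate
  if (is.null(fat_rate)) {
    fat_rate <- seq(baseline,
                    zero_exogenous_fat_rate(base_rate, baseline,
                                            object$constants) + 0.1,
                    by = 0.01)
  }
  fat_scenario_sweep(base_rate, baseline, fat_rate, object$constants)
}

#' Plot the fat-oxidation counterfactual for a fuel budget
#'
#' Required exogenous carbohydrate (g/hr) against the scenario fat oxidation
#' rate, with the zero-crossing marked.
#'
#' @param x A \code{\link{fuel_budget}}.
#' @param threshold,base_rate Passed to \code{\link{predict.fuel_budget}}.
#' @param ... Further arguments to \code{\link[graphics]{plot}}.
#' @export
plot.fuel_budget <- function(x, threshold = NULL, base_rate = NULL, ...) {
  sw <- predict(x, threshold = threshold, base_rate = base_rate)
  zc <- attr(sw, "zero_crossing_fat_rate")
  graphics::plot(sw$scenario_fat_rate, sw$required_exogenous_rate,
                 type = "l", lwd = 2,
                 xlab = "fat oxidation rate (g/min)",
                 ylab = "required exogenous CHO (g/hr)",
                 main = sprintf("Fat-oxidation counterfactual (%s)",
                                x$profile$label), ...)
  graphics::abline(v = zc, lty = 2)
  graphics::mtext(sprintf("zero crossing at %.2f g/min", zc),
                  side = 3, line = 0, cex = 0.8)
  invisible(sw)
}

#' Write / read a fuel-budget report
#'
#' Serializes the flat record of \code{\link{as.data.frame.fuel_budget}} as
#' CSV (header row) or JSON (one object); re-reading reproduces the record
#' field for field.
#'
#' @param x A \code{fuel_budget} or a one-row record data.frame.
#' @param path Output file.
#' @param format \code{"csv"} or \code{"json"}; default from the file
#'   extension.
#' @return \code{write_report}: \code{path}, invisibly.
#'   \code{read_report}: a one-row data.frame.
#' @export
write_report <- function(x, path, format = NULL) {
  rec <- if (inherits(x, "fuel_budget")) as.data.frame(x) else x
  stopifnot(is.data.frame(rec))
  format <- report_format(path, format)
  if (format == "csv") {
    utils::write.csv(rec, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(as.list(rec[1L, , drop = FALSE]), path,
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = NULL) {
  format <- report_format(path, format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}

report_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("csv", "json")) ext else "csv"
}
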