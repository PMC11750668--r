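#' Instantaneous exogenous carbohydrate oxidation curve
#'
#' A tabulated curve of instantaneous exogenous-CHO oxidation rates over a
#' bout.  Exogenous oxidation starts at (or near) zero when the first drink
#' is taken and ramps toward a plateau as gut delivery saturates; the curve
#' records that time course.  Between tabulated points the curve is treated
#' as piecewise linear.
#'
#' @param times Sample times, min; strictly increasing, starting at 0.
#' @param rates Oxidation rates at \code{times}, g/min; all >= 0.
#' @param label Free-text label (e.g. the drink formulation).
#' @return A data.frame of class \code{oxidation_curve} with columns
#'   \code{time} and \code{rate} and a \code{label} attribute.
#' @export
oxidation_curve <- function(times, rates, label = "curve") {
  times <- as.numeric(times); rates <- as.numeric(rates)
  if (length(times) < 2L || length(times) != length(rates)) {
    stop("`times` and `rates` must be equal-length vectors (>= 2 points)",
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(rates))) {
    stop("curve contains non-finite values", call. = FALSE)
  }
  if (times[1L] != 0) stop("curve must start at time 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(rates < 0)) stop("`rates` must be non-negative", call. = FALSE)
  structure(data.frame(time = times, rate = rates),
            label = as.character(label)[1L],
            class = c("oxidation_curve", "data.frame"))
}

#' Read / write an oxidation curve as CSV
#'
#' The on-disk dialect is a two-column CSV with header
#' \code{time_min,rate_g_per_min}; one curve per file.
#'
#' @param path CSV file.
#' @param label Curve label; defaults to the file name without extension.
#' @return \code{read_oxidation_curve}: an \code{\link{oxidation_curve}}.
#' @export
read_oxidation_curve <- function(path, label = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_min", "rate_g_per_min")
  if (!all(need %in% names(d))) {
    stop(sprintf("curve CSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  oxidation_curve(d$time_min, d$rate_g_per_min, label = label)
}

#' @rdname read_oxidation_curve
#' @param curve An \code{oxidation_curve} to write.
#' @export
write_oxidation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "oxidation_curve"))
  utils::write.csv(
    data.frame(time_min = curve$time, rate_g_per_min = curve$rate),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Carbohydrate ingestion rate of a sports drink
#'
#' Concentration is \% weight/volume (grams of carbohydrate per 100 ml), so
#' a 22.5\% drink at 400 ml/hr delivers 90 g/hr and a 15\% drink at
#' 800 ml/hr delivers 120 g/hr.
#'
#' @param concentration Carbohydrate concentration, \% w/v, in [0, 100].
#' @param fluid_rate Fluid ingestion rate, ml/hr (>= 0).
#' @return Ingestion rate, g/hr.
#' @export
ingestion_rate <- function(concentration, fluid_rate) {
  if (any(concentration < 0) || any(concentration > 100)) {
    stop("`concentration` must be a %% w/v value in [0, 100]", call. = FALSE)
  }
  if (any(fluid_rate < 0)) {
    stop("`fluid_rate` must be non-negative", call. = FALSE)
  }
  concentration / 100 * fluid_rate
}

# exact integral of the piecewise-linear interpolant of (times, rates)
# over [a, b]; [a, b] must lie within the curve's span
interp_integral <- function(times, rates, a, b) {
  knots <- sort(unique(c(a, b, times[times > a & times < b])))
  vals <- stats::approx(times, rates, xout = knots, rule = 1)$y
  sum(diff(knots) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

#' Cumulative exogenous carbohydrate oxidation by bin averaging
#'
#' Converts an instantaneous oxidation-rate curve into the amounts oxidized
#' per bin and cumulatively, the way cumulative-oxidation panels are built
#' from rate data: the bout is cut into fixed-width bins (30 min by
#' default), the average rate within each bin is multiplied by the bin
#' width, and the per-bin amounts are summed.  The bin average is the exact
#' time-average of the piecewise-linear interpolant, so per-bin amounts
#' equal the trapezoidal integral of the curve over the bin.
#'
#' If an ingestion rate is supplied the cumulative ingested amount,
#' unoxidized residual and running oxidation efficiency are tracked at every
#' bin edge as well.
#'
#' @param curve An \code{\link{oxidation_curve}} covering [0, duration].
#' @param duration Bout duration, min.
#' @param bin_width Bin width, min; must divide \code{duration} evenly.
#' @param ingestion_rate_g_hr Optional constant ingestion rate, g/hr,
#'   assumed to start at t = 0.
#' @return A data.frame of class \code{cumulative_oxidation}, one row per
#'   bin, with columns \code{bin_start}, \code{bin_end},
#'   \code{oxidized_per_bin}, \code{cumulative_oxidized} and --- when
#'   ingestion is given --- \code{cumulative_ingested}, \code{unoxidized},
#'   \code{efficiency}.  Attributes \code{total_oxidized},
#'   \code{total_ingested}, \code{label}.
#' @examples
#' rc <- make_ramp_curve(r_max = 1.5, tau = 30, duration = 120, step = 5)
#' cumulative_oxidation(rc, duration = 120, bin_width = 30)
#' @export
cumulative_oxidation <- function(curve, duration, bin_width = 30,
                                 ingestion_rate_g_hr = NULL) {
  stopifnot(inherits(curve, "oxidation_curve"), duration > 0, bin_width > 0)
  if (max(curve$time) < duration) {
    stop(sprintf("curve ends at %g min but duration is %g min",
                 max(curve$time), duration), call. = FALSE)
  }
  nbin <- duration / bin_width
  if (abs(nbin - round(nbin)) > 1e-9) {
    stop("`bin_width` must divide `duration` evenly", call. = FALSE)
  }
  nbin <- round(nbin)
  edges <- seq(0, duration, by = bin_width)
  per_bin <- vapply(seq_len(nbin), function(i) {
    interp_integral(curve$time, curve$rate, edges[i], edges[i + 1L])
  }, numeric(1))
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_end = edges[-1L],
                    oxidized_per_bin = per_bin,
                    cumulative_oxidized = cumsum(per_bin))
  total_ing <- NA_real_
  if (!is.null(ingestion_rate_g_hr)) {
    stopifnot(ingestion_rate_g_hr >= 0)
    out$cumulative_ingested <- ingestion_rate_g_hr / 60 * out$bin_end
    out$unoxidized <- out$cumulative_ingested - out$cumulative_oxidized
    out$efficiency <- ifelse(out$cumulative_ingested > 0,
                             out$cumulative_oxidized / out$cumulative_ingested,
                             0)
    total_ing <- ingestion_rate_g_hr / 60 * duration
  }
  structure(out,
            total_oxidized = sum(per_bin),
            total_ingested = total_ing,
            label = attr(curve, "label"),
            class = c("cumulative_oxidation", "data.frame"))
}

#' @export
print.cumulative_oxidation <- function(x, ...) {
  cat(sprintf("Cumulative exogenous CHO oxidation (%s)\n", attr(x, "label")))
  cat(sprintf("  total oxidized: %.1f g", attr(x, "total_oxidized")))
  ti <- attr(x, "total_ingested")
  if (!is.na(ti)) {
    cat(sprintf(" of %.1f g ingested (%.0f%% efficiency)",
                ti, 100 * attr(x, "total_oxidized") / ti))
  }
  cat("\n\n")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Unoxidized exogenous carbohydrate residual
#'
#' Grams ingested but not oxidized over the full bout.  Oxidized exceeding
#' ingested over the whole bout would mean the "exogenous" oxidation drew on
#' something other than the drinks, so it is rejected as inconsistent.
#'
#' @param ingested_total Total carbohydrate ingested, g.
#' @param oxidized_total Total exogenous carbohydrate oxidized, g.
#' @return Residual grams.
#' @examples
#' unoxidized_residual(288, 137)  # 151 g left unoxidized
#' @export
unoxidized_residual <- function(ingested_total, oxidized_total) {
  stopifnot(all(ingested_total >= 0), all(oxidized_total >= 0))
  if (any(oxidized_total > ingested_total)) {
    stop("oxidized total exceeds ingested total over the full bout",
         call. = FALSE)
  }
  ingested_total - oxidized_total
}

#' Oxidation efficiency of ingested carbohydrate
#'
#' Fraction of the ingested carbohydrate actually oxidized during the bout
#' (reported as a whole percent at reporting boundaries).
#'
#' @inheritParams unoxidized_residual
#' @return Fraction in [0, 1].
#' @examples
#' oxidation_efficiency(137, 288)  # 0.476, reported as 48%
#' @export
oxidation_efficiency <- function(oxidized_total, ingested_total) {
  if (any(ingested_total <= 0)) {
    stop("`ingested_total` must be positive", call. = FALSE)
  }
  stopifnot(all(oxidized_total >= 0), all(oxidized_total <= ingested_total))
  oxidized_total / ingested_total
}

#' Average rate over the bout
#'
#' @param total Grams over the bout.
#' @param duration Bout duration, min (> 0).
#' @return Average rate, g/hr.
#' @examples
#' average_rate(137, 120)  # 68.5 g/hr
#' @export
average_rate <- function(total, duration) {
  rate_per_hour(total, duration)
}
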