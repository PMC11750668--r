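#' Energy densities used for substrate/energy conversions
#'
#' Creates the pair of combustion energy densities (kJ per gram) that every
#' substrate-to-energy conversion in the package uses.  The defaults are
#' back-computed from the modelled sub-2-hour-marathon intensity itself:
#' 17.3 kJ/g carbohydrate reproduces a total energy expenditure of
#' 88.3 kJ/min at a carbohydrate oxidation rate of 5.1 g/min, and 38.0 kJ/g
#' fat reproduces 57 kJ/min at a fat oxidation rate of 1.5 g/min.  They sit
#' within the usual physiological ranges (CHO 16-18, fat 37-40 kJ/g) but are
#' deliberately the internally consistent pair, not textbook constants, and
#' both can be overridden.
#'
#' @param e_cho Energy density of carbohydrate, kJ per gram. Must be > 0.
#' @param e_fat Energy density of fat, kJ per gram. Must exceed \code{e_cho}
#'   (fat is always the denser fuel).
#'
#' @return An object of class \code{energy_constants}: a list with elements
#'   \code{e_cho} and \code{e_fat}.
#' @examples
#' k <- energy_constants()
#' k$e_fat / k$e_cho  # grams of CHO spared per gram of fat oxidized
#' @export
energy_constants <- function(e_cho = 17.3, e_fat = 38.0) {
  stopifnot(is.numeric(e_cho), length(e_cho) == 1L, is.finite(e_cho),
            is.numeric(e_fat), length(e_fat) == 1L, is.finite(e_fat))
  if (e_cho <= 0) {
    stop("`e_cho` must be positive (kJ per gram carbohydrate)", call. = FALSE)
  }
  if (e_fat <= e_cho) {
    stop("`e_fat` must exceed `e_cho`: fat is the denser fuel", call. = FALSE)
  }
  structure(list(e_cho = e_cho, e_fat = e_fat), class = "energy_constants")
}

#' @export
print.energy_constants <- function(x, ...) {
  cat(sprintf("Energy constants: CHO %.1f kJ/g, fat %.1f kJ/g (ratio %.3f)\n",
              x$e_cho, x$e_fat, x$e_fat / x$e_cho))
  invisible(x)
}

# round half away from zero, the single rounding rule used for reported grams
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
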