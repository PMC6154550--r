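#' Transition-state free-energy shift from an unbinding rate change
#'
#' Transition-state (Eyring) theory gives `k = C exp(-dG_TS / (R T))` with
#' a prefactor that cancels in rate ratios, so a change in the unbinding
#' rate constant maps directly to a change in the barrier between the
#' bound state and the unbinding transition state:
#' `ddG_TS = R T log(k_ref / k_mod)`. A modulator that slows unbinding
#' (`k_mod < k_ref`) yields a positive ddG (a higher barrier), whether by
#' destabilising the transition state or stabilising the bound state.
#'
#' @param k_ref Reference unbinding rate constant (min^-1), > 0.
#' @param k_mod Modulated unbinding rate constant (min^-1), > 0. Units
#'   cancel in the ratio; any common unit works.
#' @param temperature Temperature (K), > 0. Default 310.
#' @return Barrier free-energy change (kcal/mol).
#' @export
#' @examples
#' ddg_from_rates(0.015, 0.0095)       # ~0.28 kcal/mol, below 1 kcal/mol
#' ddg_from_rates(1, 0.82, 310)        # an 18% rate decrease
ddg_from_rates <- function(k_ref, k_mod, temperature = 310) {
  if (any(!is.finite(k_ref)) || any(k_ref <= 0) ||
      any(!is.finite(k_mod)) || any(k_mod <= 0))
    stop("rate constants must be positive and finite")
  if (any(temperature <= 0)) stop("temperature must be > 0")
  .kB * temperature * log(k_ref / k_mod)
}

#' @rdname ddg_from_rates
#' @param percent_decrease Reported percentage decrease of the rate
#'   (e.g. 18 for an 18% slower koff).
#' @export
ddg_from_percent <- function(percent_decrease, temperature = 310) {
  if (any(percent_decrease >= 100)) stop("percent decrease must be < 100")
  ddg_from_rates(1, 1 - percent_decrease / 100, temperature)
}

#' Rate ratio implied by a barrier shift
#'
#' Exact inverse of [ddg_from_rates()]: `k_ref / k_mod = exp(ddg / (R T))`.
#'
#' @param ddg Barrier free-energy change (kcal/mol).
#' @param temperature Temperature (K), > 0.
#' @return Dimensionless ratio `k_ref / k_mod`.
#' @export
rate_ratio_from_ddg <- function(ddg, temperature = 310) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  exp(ddg / (.kB * temperature))
}

#' Summarise an unbinding rate pair
#'
#' Bundles a reference/modulated koff pair with the implied
#' transition-state free-energy change and the percentage rate decrease.
#'
#' @inheritParams ddg_from_rates
#' @return An object of class `"rate_shift"` with fields `k_ref`,
#'   `k_mod`, `temperature`, `ddg` (kcal/mol) and `percent_decrease`.
#' @export
#' @examples
#' rate_shift(0.015, 0.0095)
rate_shift <- function(k_ref, k_mod, temperature = 310) {
  structure(list(k_ref = k_ref, k_mod = k_mod, temperature = temperature,
                 ddg = ddg_from_rates(k_ref, k_mod, temperature),
                 percent_decrease = 100 * (1 - k_mod / k_ref)),
            class = "rate_shift")
}

#' @export
print.rate_shift <- function(x, digits = 4, ...) {
  cat("Unbinding rate shift at ", x$temperature, " K\n", sep = "")
  cat("  koff: ", format(x$k_ref), " -> ", format(x$k_mod), " min^-1 (",
      format(round(x$percent_decrease, 1)), "% decrease)\n", sep = "")
  cat("  ddG(TS) = ", format(round(x$ddg, digits)), " kcal/mol\n", sep = "")
  invisible(x)
}
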