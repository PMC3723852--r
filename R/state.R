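#' System state of the Ca2+ model
#'
#' The model tracks seven state variables: the free cytosolic and SR Ca2+
#' concentrations `c` and `c_s` (uM), the fraction `phi` of inhibited IP3
#' receptors, the fraction `s` of activated store-operated channels, and
#' three drug-effect states — the effective agonist/IP3 concentration
#' `p_eff` (uM), the Rya-Caf-evoked RyR leak conductance `ryr_leak` (1/s),
#' and the operating SERCA fraction `serca_eff`.
#'
#' Tiny negative concentration excursions (integrator overshoot) are clipped
#' to zero; excursions below -1e-6 are treated as genuine errors.
#'
#' @param c cytosolic Ca2+ (uM, >= 0).
#' @param c_s SR Ca2+ (uM, >= 0).
#' @param phi inhibited IPR fraction, in [0,1].
#' @param s activated SOCC fraction, in [0,1].
#' @param p_eff effective agonist concentration (uM, >= 0).
#' @param ryr_leak Rya-Caf RyR leak conductance (1/s, >= 0).
#' @param serca_eff operating SERCA fraction, in [0,1].
#' @return A named numeric vector of class `asm_state`.
#' @examples
#' asm_state(c = 0.05, c_s = 100, phi = 0.1, s = 0.07)
#' @export
asm_state <- function(c, c_s, phi, s, p_eff = 0, ryr_leak = 0,
                      serca_eff = 1) {
  y <- c(c = c, c_s = c_s, phi = phi, s = s, p_eff = p_eff,
         ryr_leak = ryr_leak, serca_eff = serca_eff)
  y <- validate_state(y)
  class(y) <- "asm_state"
  y
}

state_names <- c("c", "c_s", "phi", "s", "p_eff", "ryr_leak", "serca_eff")

# Overshoot guard: clip transient negatives, reject gross violations.
validate_state <- function(y) {
  y <- unclass(y)
  if (length(y) != 7L) stop("state must have 7 components")
  names(y) <- state_names
  if (any(!is.finite(y))) stop("non-finite state component")
  lowest <- min(y[c("c", "c_s", "p_eff", "ryr_leak")])
  if (lowest < -1e-6)
    stop("negative state component beyond tolerance: ", lowest)
  for (nm in c("c", "c_s", "p_eff", "ryr_leak"))
    if (y[[nm]] < 1e-12) y[[nm]] <- max(y[[nm]], 0)
  for (nm in c("phi", "s", "serca_eff")) {
    if (y[[nm]] < -1e-6 || y[[nm]] > 1 + 1e-6)
      stop("state component ", nm, " outside [0,1]: ", y[[nm]])
    y[[nm]] <- min(max(y[[nm]], 0), 1)
  }
  y
}

#' @export
print.asm_state <- function(x, ...) {
  cat("asm_state:\n")
  print(round(unclass(x), 6))
  invisible(x)
}
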