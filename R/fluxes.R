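#' Steady-state SOCC activation (STIM dissociation curve)
#'
#' Fraction of STIM proteins dissociated from SR Ca2+, and hence the
#' steady-state fraction of activated store-operated channels, as a reverse
#' Hill function of the SR Ca2+ concentration:
#' \deqn{s_\infty(c_s) = \frac{K_s^{n_s}}{K_s^{n_s} + c_s^{n_s}}.}
#' It equals 1 for an empty store and decreases strictly with store load.
#'
#' @param c_s SR Ca2+ concentration (uM, >= 0); vectorized.
#' @param params an [asm_parameters()] object.
#' @return Activation fraction(s) in [0, 1].
#' @examples
#' p <- asm_parameters()
#' soce_steady_state(p$K_s, p) # 0.5 at half-activation
#' @export
soce_steady_state <- function(c_s, params) {
  if (any(c_s < 0)) stop("c_s must be non-negative")
  kn <- params$K_s^params$n_s
  kn / (kn + c_s^params$n_s)
}

#' Plasma-membrane Ca2+ influx
#'
#' Total Ca2+ influx through the plasma membrane: a constant leak, a
#' receptor-operated component proportional to the effective agonist
#' concentration, and the store-operated component `V_s * s`. Removing
#' external Ca2+ suppresses all three (the channels may still gate, but
#' carry no current); the PMCA is unaffected by that flag.
#'
#' @param state an [asm_state()] or named state vector.
#' @param params an [asm_parameters()] object.
#' @param external_ca is external Ca2+ present? (default `TRUE`).
#' @return Named list with components `J_leak_in`, `J_ROCE`, `J_SOCE` and
#'   their sum `total` (uM/s).
#' @export
pm_influx <- function(state, params, external_ca = TRUE) {
  y <- validate_state(state)
  ext <- as.numeric(isTRUE(external_ca))
  out <- list(
    J_leak_in = ext * params$alpha_0,
    J_ROCE    = ext * params$alpha_1 * y[["p_eff"]],
    J_SOCE    = ext * params$V_s * y[["s"]]
  )
  out$total <- out$J_leak_in + out$J_ROCE + out$J_SOCE
  out
}

#' Plasma-membrane Ca2+-ATPase (PMCA) efflux
#'
#' Saturating pump flux \eqn{V_p c / (K_p + c)}: zero at `c = 0`, half its
#' plateau at `c = K_p`, strictly increasing.
#'
#' @param c cytosolic Ca2+ (uM, >= 0); vectorized.
#' @param params an [asm_parameters()] object.
#' @return Efflux (uM/s).
#' @export
pmca_flux <- function(c, params) {
  if (any(c < 0)) stop("c must be non-negative")
  params$V_p * c / (params$K_p + c)
}

#' SERCA uptake flux
#'
#' Saturating uptake \eqn{\epsilon V_e c / (K_e + c)} scaled by the current
#' fraction `serca_eff` of operating pumps (CPA reduces this fraction).
#'
#' @param c cytosolic Ca2+ (uM, >= 0); vectorized.
#' @param serca_eff operating SERCA fraction in [0,1].
#' @param params an [asm_parameters()] object.
#' @return Uptake flux (uM/s).
#' @export
serca_flux <- function(c, serca_eff, params) {
  if (any(c < 0)) stop("c must be non-negative")
  if (any(serca_eff < 0 | serca_eff > 1))
    stop("serca_eff must lie in [0,1]")
  serca_eff * params$V_e * c / (params$K_e + c)
}

#' IP3-receptor open probability
#'
#' Li-Rinzel/Tang reduction of the De Young-Keizer model: the receptor opens
#' when its three identical subunits each bind IP3 and activating Ca2+ while
#' escaping Ca2+ inhibition,
#' \deqn{P_{IPR} = \left[\frac{p}{p+K_1}\cdot\frac{c}{c+K_5}\cdot(1-\phi)\right]^3,}
#' where `phi` is the per-subunit inhibited fraction (see
#' [phi_relaxation()]).
#'
#' @param c cytosolic Ca2+ (uM, >= 0).
#' @param p_eff effective agonist/IP3 concentration (uM, >= 0).
#' @param phi inhibited fraction in [0,1].
#' @param params an [asm_parameters()] object.
#' @return Open probability in [0, 1]; vectorized over the inputs.
#' @export
ipr_open_probability <- function(c, p_eff, phi, params) {
  if (any(c < 0) || any(p_eff < 0)) stop("c and p_eff must be non-negative")
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0,1]")
  (p_eff * c * (1 - phi) / ((p_eff + params$K_1) * (c + params$K_5)))^3
}

#' IPR Ca2+-inhibition kinetics
#'
#' First-order relaxation of the inhibited subunit fraction `phi`. Ca2+
#' binds the inhibitory site at rate
#' \eqn{\beta(c,p) = c\,(a_2 p + a_4 K_1)/(p + K_1)} (the site affinity
#' depends on whether IP3 is bound; \eqn{a_2 = k_{-2}/K_2},
#' \eqn{a_4 = k_{-4}/K_4}) and unbinds at rate
#' \eqn{\alpha(p) = (k_{-2} p + k_{-4} K_3)/(p + K_3)}. Then
#' \eqn{d\phi/dt = \mathrm{rate}\,(\phi_\infty - \phi)} with
#' \eqn{\phi_\infty = \beta/(\alpha+\beta)} and rate \eqn{\alpha+\beta}.
#' By the detailed-balance relation of the De Young-Keizer constants this
#' reduces to the familiar Li-Rinzel form with
#' \eqn{Q_2 = K_2 (p+K_1)/(p+K_3)}.
#'
#' @param c cytosolic Ca2+ (uM, >= 0).
#' @param p_eff effective agonist concentration (uM, >= 0).
#' @param params an [asm_parameters()] object.
#' @return List with `phi_inf` (steady-state inhibited fraction, in [0,1])
#'   and `rate` (relaxation rate, 1/s, > 0).
#' @export
phi_relaxation <- function(c, p_eff, params) {
  if (any(c < 0) || any(p_eff < 0)) stop("c and p_eff must be non-negative")
  km2 <- params$k_minus_2
  km4 <- k_minus_4(params)
  a2 <- km2 / params$K_2
  a4 <- km4 / params$K_4
  beta  <- c * (a2 * p_eff + a4 * params$K_1) / (p_eff + params$K_1)
  alpha <- (km2 * p_eff + km4 * params$K_3) / (p_eff + params$K_3)
  list(phi_inf = beta / (alpha + beta), rate = alpha + beta)
}

#' SR-to-cytosol Ca2+ release
#'
#' Total release flux \eqn{(k_{IPR} P_{IPR} + \lambda_{RyR} + J_{SR})(c_s - c)}
#' through IP3 receptors, Rya-Caf-locked ryanodine receptors, and an
#' unspecified passive leak, each proportional to the SR-cytosol gradient.
#'
#' @param state an [asm_state()] or named state vector.
#' @param params an [asm_parameters()] object.
#' @return Named list with `J_IPR`, `J_RyR`, `J_SR_leak` and `total` (uM/s).
#' @export
sr_release_flux <- function(state, params) {
  y <- validate_state(state)
  grad <- y[["c_s"]] - y[["c"]]
  p_open <- ipr_open_probability(y[["c"]], y[["p_eff"]], y[["phi"]], params)
  out <- list(
    J_IPR     = params$k_IPR * p_open * grad,
    J_RyR     = y[["ryr_leak"]] * grad,
    J_SR_leak = params$J_SR * grad
  )
  out$total <- out$J_IPR + out$J_RyR + out$J_SR_leak
  out
}

#' Full flux breakdown at a state
#'
#' Evaluates every model flux (cytosolic reference frame, uM/s). The totals
#' are the exact sums of their components and are the quantities used by
#' [asm_rhs()].
#'
#' @inheritParams pm_influx
#' @return Named numeric vector with elements `J_leak_in`, `J_ROCE`,
#'   `J_SOCE`, `J_pm_in_total`, `J_PMCA`, `J_IPR`, `J_RyR`, `J_SR_leak`,
#'   `J_rel_total`, `J_SERCA`.
#' @export
flux_breakdown <- function(state, params, external_ca = TRUE) {
  y <- validate_state(state)
  inn <- pm_influx(y, params, external_ca)
  rel <- sr_release_flux(y, params)
  c(J_leak_in = inn$J_leak_in, J_ROCE = inn$J_ROCE, J_SOCE = inn$J_SOCE,
    J_pm_in_total = inn$total,
    J_PMCA = pmca_flux(y[["c"]], params),
    J_IPR = rel$J_IPR, J_RyR = rel$J_RyR, J_SR_leak = rel$J_SR_leak,
    J_rel_total = rel$total,
    J_SERCA = serca_flux(y[["c"]], y[["serca_eff"]], params))
}

#' Fluorescence-indicator emulation
#'
#' Maps a cytosolic Ca2+ series through the saturating binding curve
#' \eqn{F = c/(c + K_d)} of a high-affinity dye, for qualitative comparison
#' with fluorescence recordings. Never feeds back into the dynamics.
#'
#' @param c cytosolic Ca2+ (uM, >= 0); vectorized.
#' @param dye_Kd indicator affinity (uM, > 0).
#' @return Normalized fluorescence in [0, 1).
#' @export
fluorescence_transform <- function(c, dye_Kd) {
  if (length(dye_Kd) != 1L || !is.finite(dye_Kd) || dye_Kd <= 0)
    stop("dye_Kd must be a positive number")
  if (any(c < 0)) stop("c must be non-negative")
  c / (c + dye_Kd)
}
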