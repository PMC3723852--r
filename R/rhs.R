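#' Drug-target set
#'
#' The piecewise-constant targets toward which the drug-effect states relax:
#' agonist concentration, Rya-Caf exposure, CPA exposure, and presence of
#' external Ca2+. The resting targets (no drug, external Ca2+ on) are the
#' defaults.
#'
#' @param agonist agonist target concentration (uM, >= 0).
#' @param ryacaf is the ryanodine-caffeine treatment being applied?
#' @param cpa is CPA present?
#' @param external_ca is external Ca2+ present?
#' @return A named list of class `asm_targets`.
#' @export
drug_targets <- function(agonist = 0, ryacaf = FALSE, cpa = FALSE,
                         external_ca = TRUE) {
  if (!is.finite(agonist) || agonist < 0)
    stop("agonist target must be non-negative")
  out <- list(agonist = as.numeric(agonist), ryacaf = isTRUE(ryacaf),
              cpa = isTRUE(cpa), external_ca = isTRUE(external_ca))
  class(out) <- "asm_targets"
  out
}

#' Drug-effect dynamics
#'
#' First-order relaxation of the three drug-effect states toward the current
#' targets: `p_eff` relaxes toward the agonist target with timescale `tau_p`;
#' `serca_eff` toward 1 (no CPA) or `1 - cpa_block_fraction` (CPA on) with
#' timescale `tau_e`; the Rya-Caf RyR leak rises with a saturating
#' first-order law of timescale `tau_SR` toward its ceiling
#' `K_RYR * tau_SR^2` while the treatment is applied, and is frozen — never
#' decays — once exposure ends, because ryanodine locks the channels open
#' irreversibly.
#'
#' @param state an [asm_state()] or named state vector.
#' @param targets a [drug_targets()] list.
#' @param params an [asm_parameters()] object.
#' @return Named numeric vector of derivatives of `p_eff`, `ryr_leak`,
#'   `serca_eff`.
#' @export
drug_state_derivatives <- function(state, targets, params) {
  y <- validate_state(state)
  ryr_max <- params$K_RYR * params$tau_SR^2
  serca_target <- if (targets$cpa) 1 - params$cpa_block_fraction else 1
  c(p_eff = (targets$agonist - y[["p_eff"]]) / params$tau_p,
    ryr_leak = if (targets$ryacaf)
      (ryr_max - y[["ryr_leak"]]) / params$tau_SR else 0,
    serca_eff = (serca_target - y[["serca_eff"]]) / params$tau_e)
}

#' Right-hand side of the Ca2+ model
#'
#' Assembles the time derivatives of the seven state variables:
#' \deqn{dc/dt = J_{rel} - J_{SERCA} + J_{in} - J_{PMCA},}
#' \deqn{dc_s/dt = \gamma\,(J_{SERCA} - J_{rel}),}
#' with `phi` and `s` relaxing to their Ca2+-dependent steady states and the
#' drug states following [drug_state_derivatives()]. The factor `gamma`
#' converts cytosolic flux to SR concentration change (the SR is the smaller
#' compartment). With plasma-membrane fluxes disabled the combination
#' `c + c_s / gamma` is conserved exactly.
#'
#' @param state an [asm_state()] or named state vector.
#' @param params an [asm_parameters()] object.
#' @param targets a [drug_targets()] list (controls agonist, Rya-Caf, CPA
#'   and the external-Ca2+ flag).
#' @return Named numeric vector of the seven time derivatives.
#' @export
asm_rhs <- function(state, params, targets = drug_targets()) {
  y <- validate_state(state)
  fx <- flux_breakdown(y, params, targets$external_ca)
  pr <- phi_relaxation(y[["c"]], y[["p_eff"]], params)
  s_inf <- soce_steady_state(y[["c_s"]], params)
  dd <- drug_state_derivatives(y, targets, params)
  net_sr <- fx[["J_SERCA"]] - fx[["J_rel_total"]]
  c(c = fx[["J_rel_total"]] - fx[["J_SERCA"]] +
      fx[["J_pm_in_total"]] - fx[["J_PMCA"]],
    c_s = params$gamma * net_sr,
    phi = pr$rate * (pr$phi_inf - y[["phi"]]),
    s = (s_inf - y[["s"]]) / params$tau_s,
    dd)
}

#' Analytic Jacobian of the model right-hand side
#'
#' Exact partial derivatives of [asm_rhs()] with respect to the state. Used
#' for equilibrium refinement and linear stability analysis. With
#' `frozen = TRUE` (the default, used for all bifurcation work) the drug
#' states are held at their targets and the 4x4 Jacobian of the dynamical
#' core (`c`, `c_s`, `phi`, `s`) is returned; otherwise the full 7x7 matrix.
#'
#' @param state an [asm_state()] or named state vector.
#' @param params an [asm_parameters()] object.
#' @param targets a [drug_targets()] list.
#' @param frozen freeze drug states at their targets (4x4) or include their
#'   rows and columns (7x7)?
#' @return A square numeric matrix with dimnames.
#' @export
asm_jacobian <- function(state, params, targets = drug_targets(),
                         frozen = TRUE) {
  y <- validate_state(state)
  P <- params
  ext <- as.numeric(targets$external_ca)
  c0 <- y[["c"]]; cs <- y[["c_s"]]; phi <- y[["phi"]]
  p <- y[["p_eff"]]; lam <- y[["ryr_leak"]]; eps <- y[["serca_eff"]]

  grad <- cs - c0
  m <- p / (p + P$K_1)            # IP3 binding
  a <- c0 / (c0 + P$K_5)          # Ca activation
  A <- m * a * (1 - phi)          # per-subunit open fraction
  P_open <- A^3
  da_dc <- P$K_5 / (c0 + P$K_5)^2
  dm_dp <- P$K_1 / (p + P$K_1)^2
  dP_dc   <- 3 * A^2 * m * (1 - phi) * da_dc
  dP_dphi <- -3 * A^2 * m * a
  dP_dp   <- 3 * A^2 * a * (1 - phi) * dm_dp

  rel_rate <- P$k_IPR * P_open + lam + P$J_SR      # 1/s
  dpm_dc <- P$V_p * P$K_p / (P$K_p + c0)^2
  dse_dc <- eps * P$V_e * P$K_e / (P$K_e + c0)^2
  se_unit <- P$V_e * c0 / (P$K_e + c0)             # SERCA at eps = 1

  km2 <- P$k_minus_2; km4 <- k_minus_4(P)
  a2 <- km2 / P$K_2; a4 <- km4 / P$K_4
  b_p <- (a2 * p + a4 * P$K_1) / (p + P$K_1)       # beta = c * b(p)
  alpha <- (km2 * p + km4 * P$K_3) / (p + P$K_3)
  db_dp <- P$K_1 * (a2 - a4) / (p + P$K_1)^2
  dalpha_dp <- P$K_3 * (km2 - km4) / (p + P$K_3)^2

  kn <- P$K_s^P$n_s
  dsinf_dcs <- -P$n_s * kn * cs^(P$n_s - 1) / (kn + cs^P$n_s)^2

  J <- matrix(0, 7, 7, dimnames = list(state_names, state_names))
  # dc/dt row
  J["c", "c"] <- P$k_IPR * dP_dc * grad - rel_rate - dse_dc - dpm_dc
  J["c", "c_s"] <- rel_rate
  J["c", "phi"] <- P$k_IPR * dP_dphi * grad
  J["c", "s"] <- ext * P$V_s
  J["c", "p_eff"] <- P$k_IPR * dP_dp * grad + ext * P$alpha_1
  J["c", "ryr_leak"] <- grad
  J["c", "serca_eff"] <- -se_unit
  # dc_s/dt row = -gamma * (release - serca) pieces
  J["c_s", "c"] <- P$gamma * (dse_dc - P$k_IPR * dP_dc * grad + rel_rate)
  J["c_s", "c_s"] <- -P$gamma * rel_rate
  J["c_s", "phi"] <- -P$gamma * P$k_IPR * dP_dphi * grad
  J["c_s", "p_eff"] <- -P$gamma * P$k_IPR * dP_dp * grad
  J["c_s", "ryr_leak"] <- -P$gamma * grad
  J["c_s", "serca_eff"] <- P$gamma * se_unit
  # dphi/dt = c * b(p) * (1 - phi) - alpha * phi
  J["phi", "c"] <- b_p * (1 - phi)
  J["phi", "phi"] <- -(c0 * b_p + alpha)
  J["phi", "p_eff"] <- c0 * db_dp * (1 - phi) - dalpha_dp * phi
  # ds/dt
  J["s", "c_s"] <- dsinf_dcs / P$tau_s
  J["s", "s"] <- -1 / P$tau_s
  # drug rows
  J["p_eff", "p_eff"] <- -1 / P$tau_p
  J["ryr_leak", "ryr_leak"] <- if (targets$ryacaf) -1 / P$tau_SR else 0
  J["serca_eff", "serca_eff"] <- -1 / P$tau_e

  if (frozen) J[1:4, 1:4] else J
}
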