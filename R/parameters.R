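#' Model parameters for the airway smooth muscle cell Ca2+ model
#'
#' Constructs the full parameter set of the whole-cell Ca2+ model with
#' store-operated Ca2+ entry (SOCE). Defaults are the published reference
#' values; any subset can be overridden by name. Units are micromolar (uM)
#' for concentrations and affinities, seconds (s) for times, uM/s for fluxes.
#'
#' The parameters are:
#' \describe{
#'   \item{V_p, K_p}{plasma-membrane Ca2+-ATPase (PMCA) maximum flux (uM/s)
#'     and affinity (uM).}
#'   \item{V_s, K_s, n_s, tau_s}{SOCE maximum flux (uM/s), STIM affinity for
#'     SR Ca2+ (uM), Hill exponent of the STIM dissociation curve, and the
#'     slow SOCC activation timescale (s).}
#'   \item{alpha_0, alpha_1}{constant plasma-membrane leak influx (uM/s) and
#'     receptor-operated Ca2+ entry (ROCE) rate (1/s).}
#'   \item{gamma}{cytosol/SR volume ratio, folding in the relative effect of
#'     fast linear buffers in each compartment (dimensionless, > 1).}
#'   \item{V_e, K_e}{SERCA maximum flux (uM/s) and affinity (uM).}
#'   \item{k_IPR, J_SR}{maximum IP3-receptor release rate and passive SR leak
#'     rate (both 1/s, multiplying the SR-to-cytosol gradient).}
#'   \item{K_1 .. K_5, k_minus_2}{equilibrium constants (uM) and the
#'     inhibitory-site Ca2+ dissociation rate (1/s) of the De Young-Keizer
#'     IP3-receptor scheme. The second inhibitory-site rate k_minus_4 is tied
#'     to k_minus_2 by the fixed ratio 0.138 and is not a free parameter.}
#'   \item{tau_p, tau_e, tau_SR, K_RYR}{drug-effect kinetics: first-order
#'     timescales (s) for agonist, CPA and ryanodine-caffeine effects, and the
#'     Rya-Caf RyR leak ramp constant (1/s^2).}
#'   \item{cpa_block_fraction}{fraction of SERCA capacity removed at full CPA
#'     effect (scenario knob, in [0,1]). The default reproduces the
#'     partial-block phenotype: Ca2+ returns close to its resting level when
#'     agonist is washed out in the continued presence of CPA.}
#'   \item{dye_Kd}{affinity (uM) of the fluorescent indicator emulation used
#'     by [fluorescence_transform()]; never feeds back into the dynamics.}
#' }
#'
#' @param ... named parameter overrides, e.g. `V_s = 0` for a SOCE knockout.
#' @return An object of class `asm_parameters` (a named list).
#' @examples
#' p <- asm_parameters()
#' p$gamma
#' asm_parameters(V_s = 0)$V_s
#' @export
asm_parameters <- function(...) {
  p <- list(
    V_p     = 7.5,
    K_p     = 1.5,
    V_s     = 1.57,
    K_s     = 50,
    n_s     = 4,
    tau_s   = 30,
    alpha_0 = 0,
    gamma   = 5.405,
    alpha_1 = 0.00105,
    V_e     = 5,
    K_e     = 0.1,
    tau_e   = 30,
    k_IPR   = 0.667,
    tau_p   = 30,
    J_SR    = 0.01,
    K_RYR   = 0.19,
    tau_SR  = 10,
    K_1     = 0.138,
    K_2     = 1.05,
    K_3     = 0.943,
    K_4     = 0.144,
    K_5     = 0.082,
    k_minus_2 = 0.167,
    cpa_block_fraction = 0.15,
    dye_Kd  = 0.17
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  p <- lapply(p, as.numeric)
  class(p) <- "asm_parameters"
  validate_parameters(p)
  p
}

#' Second inhibitory-site dissociation rate
#'
#' k_minus_4 is tied to k_minus_2 by the fixed ratio 0.138 of the original
#' De Young-Keizer constants and is derived, never stored.
#'
#' @param params an `asm_parameters` object.
#' @return k_minus_4 in 1/s.
#' @export
k_minus_4 <- function(params) 0.138 * params$k_minus_2

validate_parameters <- function(p) {
  stopifnot(inherits(p, "asm_parameters"))
  pos <- c("V_p", "K_p", "K_s", "tau_s", "gamma", "V_e", "K_e",
           "tau_e", "k_IPR", "tau_p", "J_SR", "K_RYR", "tau_SR",
           "K_1", "K_2", "K_3", "K_4", "K_5", "k_minus_2", "dye_Kd")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter ", nm, " must be a positive number, got ", p[[nm]])
  # V_s = 0 is allowed: the SOCE-knockout experiment
  for (nm in c("V_s", "alpha_0", "alpha_1"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("parameter ", nm, " must be non-negative, got ", p[[nm]])
  if (!is.finite(p$n_s) || p$n_s < 1 || p$n_s != round(p$n_s))
    stop("parameter n_s must be an integer >= 1, got ", p$n_s)
  if (!is.finite(p$cpa_block_fraction) ||
      p$cpa_block_fraction < 0 || p$cpa_block_fraction > 1)
    stop("parameter cpa_block_fraction must lie in [0,1], got ",
         p$cpa_block_fraction)
  if (p$gamma <= 1)
    stop("parameter gamma must exceed 1 (cytosol larger than SR), got ",
         p$gamma)
  invisible(p)
}

#' @export
print.asm_parameters <- function(x, ...) {
  cat("Airway smooth muscle Ca2+ model parameters\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 20), format(v)), sep = "\n")
  cat("  (k_minus_4 = 0.138 * k_minus_2 =", format(k_minus_4(x)), ")\n")
  invisible(x)
}

#' Read a model configuration file
#'
#' Parses a flat plain-text `key = value` configuration (one pair per line,
#' `#` comments allowed) into an `asm_parameters` object. Keys use the
#' published parameter symbols (`V_p`, `K_s`, `k_minus_2`, ...). An empty
#' file yields the full default parameter set. Unknown keys and values that
#' violate a parameter invariant are errors naming the offending key.
#'
#' @param path path to the configuration file.
#' @return An `asm_parameters` object.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ov <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse config line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- suppressWarnings(as.numeric(trimws(sub("^[^=]*=", "", ln))))
    if (is.na(val))
      stop("non-numeric value for key '", key, "'")
    ov[[key]] <- val
  }
  do.call(asm_parameters, ov)
}

#' Write a model configuration file
#'
#' Serializes parameters as flat `key = value` text readable by
#' [load_config()]. Full precision is kept so that a round trip reproduces
#' the parameters exactly.
#'
#' @param params an `asm_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_parameters(params)
  lines <- c("# asm Ca2+ model configuration",
             paste(names(params), "=",
                   vapply(params, format, "", digits = 17)))
  writeLines(lines, path)
  invisible(path)
}
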