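#' Locate an equilibrium of the Ca2+ model
#'
#' Finds a root of the dynamical core (`c`, `c_s`, `phi`, `s`) with the drug
#' states held at their asymptotic targets, by damped Newton iteration using
#' the analytic Jacobian. Unless an explicit start is given, a deterministic
#' multi-start grid (`c` in {0.05, 0.2, 1} uM x `c_s` in {10, 100, 300} uM,
#' with `phi` and `s` at their conditional steady states) is tried in order
#' and the first converged non-negative root is returned; when `start` is
#' supplied (e.g. the previous point of a branch continuation) only that
#' start is used, preserving branch continuity.
#'
#' @param params an [asm_parameters()] object.
#' @param targets a [drug_targets()] list; the drug states are frozen at
#'   `agonist`, the Rya-Caf ceiling (if `ryacaf`) and the CPA-scaled SERCA
#'   fraction.
#' @param start optional numeric vector `c(c, c_s, phi, s)` used as the sole
#'   Newton start.
#' @param tol residual infinity-norm tolerance (default 1e-11).
#' @return An object of class `asm_equilibrium`: the full 7-component state,
#'   the residual norm, the (4x4, drug-frozen) Jacobian eigenvalues, a
#'   stability label and the leading eigenstructure.
#' @export
find_equilibrium <- function(params, targets = drug_targets(),
                             start = NULL, tol = 1e-11) {
  frozen <- frozen_drug_states(params, targets)
  fn <- function(x) {
    y <- c(x, frozen)
    names(y) <- state_names
    unname(asm_rhs(y, params, targets)[1:4])
  }
  jn <- function(x) {
    y <- c(x, frozen)
    names(y) <- state_names
    asm_jacobian(y, params, targets, frozen = TRUE)
  }
  starts <- if (!is.null(start)) list(as.numeric(start)) else {
    grid <- expand.grid(c = c(0.05, 0.2, 1), c_s = c(10, 100, 300))
    lapply(seq_len(nrow(grid)), function(i) {
      c0 <- grid$c[i]; cs0 <- grid$c_s[i]
      c(c0, cs0, phi_relaxation(c0, targets$agonist, params)$phi_inf,
        soce_steady_state(cs0, params))
    })
  }
  best <- NULL
  for (x0 in starts) {
    sol <- newton_root(fn, jn, x0, tol = tol)
    if (!is.null(sol) && all(sol$x[1:2] >= 0) &&
        all(sol$x[3:4] >= -1e-9 & sol$x[3:4] <= 1 + 1e-9)) {
      best <- sol
      break
    }
  }
  if (is.null(best))
    stop("no equilibrium found within bounds for the given targets")
  y <- c(best$x, frozen)
  names(y) <- state_names
  y <- validate_state(y)
  J <- asm_jacobian(y, params, targets, frozen = TRUE)
  ev <- eigen(J, only.values = TRUE)$values
  lead <- ev[which.max(Re(ev))]
  structure(list(
    state = y,
    residual = best$resid,
    eigenvalues = ev,
    stable = max(Re(ev)) < 0,
    leading = if (abs(Im(lead)) > 1e-9) "complex pair" else "real",
    targets = targets,
    params = params
  ), class = "asm_equilibrium")
}

# asymptotic drug-state values for fixed targets
frozen_drug_states <- function(params, targets) {
  c(p_eff = targets$agonist,
    ryr_leak = if (targets$ryacaf) params$K_RYR * params$tau_SR^2 else 0,
    serca_eff = if (targets$cpa) 1 - params$cpa_block_fraction else 1)
}

# damped Newton with step halving; returns NULL on failure
newton_root <- function(fn, jn, x0, tol = 1e-11, maxit = 200) {
  x <- x0
  f <- tryCatch(fn(x), error = function(e) NULL)
  if (is.null(f)) return(NULL)
  for (it in seq_len(maxit)) {
    r <- max(abs(f))
    if (r < tol) return(list(x = x, resid = r))
    J <- tryCatch(jn(x), error = function(e) NULL)
    if (is.null(J)) return(NULL)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      xn[1:2] <- pmax(xn[1:2], 0)
      xn[3:4] <- pmin(pmax(xn[3:4], 0), 1)
      fn_new <- tryCatch(fn(xn), error = function(e) NULL)
      if (!is.null(fn_new) && all(is.finite(fn_new)) &&
          (max(abs(fn_new)) < r || lambda < 1e-8)) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-8 && max(abs(fn_new)) >= r) return(NULL)
    x <- xn; f <- fn_new
  }
  r <- max(abs(f))
  if (r < tol) list(x = x, resid = r) else NULL
}

#' @export
print.asm_equilibrium <- function(x, ...) {
  cat("asm_equilibrium (residual", format(x$residual, digits = 3), ")\n")
  print(round(unclass(x$state), 6))
  cat("stability:", if (x$stable) "stable" else "unstable",
      "| leading eigenstructure:", x$leading, "\n")
  cat("eigenvalues:",
      paste(sprintf("%.5f%+.5fi", Re(x$eigenvalues), Im(x$eigenvalues)),
            collapse = "  "), "\n")
  invisible(x)
}
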