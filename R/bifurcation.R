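#' Oscillation metrics of a Ca2+ trace
#'
#' Peak-based summary of a cytosolic Ca2+ time series: local maxima with
#' prominence of at least a fraction of the analysed range are taken as
#' spikes; the trace is called oscillating when at least `min_peaks` spikes
#' occur and the peak-to-trough range exceeds the amplitude floor.
#' Frequency is 60 over the mean inter-peak interval (per minute);
#' amplitude is mean peak minus mean trough (uM).
#'
#' @param time sample times (s), strictly increasing.
#' @param c cytosolic Ca2+ samples (uM).
#' @param transient initial transient (s) discarded before analysis.
#' @param min_peaks minimum number of spikes required (>= 3).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   window's Ca2+ range.
#' @param amp_floor minimum peak-to-trough range (uM) to call oscillation.
#' @return A list of class `asm_oscillation`: `oscillating`, `frequency`
#'   (per min, `NA` when not oscillating), `amplitude`, `baseline` (mean
#'   trough), `mean_peak`, `n_periods`.
#' @examples
#' t <- seq(0, 200, 0.05)
#' oscillation_metrics(t, 0.3 + 0.2 * sin(2 * pi * t / 10), transient = 0)
#' @export
oscillation_metrics <- function(time, c, transient = 200, min_peaks = 3,
                                prominence_frac = 0.05, amp_floor = 0.01) {
  keep <- time >= transient
  if (sum(keep) < 10) stop("analysis window too short")
  t <- time[keep]; x <- c[keep]
  rng <- diff(range(x))
  pk <- which(diff(sign(diff(x))) == -2) + 1
  tr <- which(diff(sign(diff(x))) == 2) + 1
  if (rng > 0) pk <- pk[x[pk] >= min(x) + prominence_frac * rng]
  oscillating <- length(pk) >= min_peaks && rng > amp_floor
  if (oscillating) {
    mean_peak <- mean(x[pk])
    troughs <- if (length(tr)) x[tr] else min(x)
    baseline <- mean(troughs)
    out <- list(oscillating = TRUE,
                frequency = 60 / mean(diff(t[pk])),
                amplitude = mean_peak - baseline,
                baseline = baseline,
                mean_peak = mean_peak,
                n_periods = length(pk) - 1L)
  } else {
    out <- list(oscillating = FALSE, frequency = NA_real_,
                amplitude = NA_real_, baseline = mean(x),
                mean_peak = NA_real_, n_periods = 0L)
  }
  class(out) <- "asm_oscillation"
  out
}

#' @export
print.asm_oscillation <- function(x, ...) {
  if (x$oscillating)
    cat(sprintf(
      "oscillating: %.3f /min, amplitude %.4f uM (baseline %.4f, mean peak %.4f, %d periods)\n",
      x$frequency, x$amplitude, x$baseline, x$mean_peak, x$n_periods))
  else cat("not oscillating (baseline", format(x$baseline, digits = 5),
           "uM)\n")
  invisible(x)
}

sweepable_params <- c("agonist", "V_s", "K_s")

apply_sweep_value <- function(params, targets, param, value) {
  if (param == "agonist") targets$agonist <- value
  else params[[param]] <- value
  list(params = params, targets = targets)
}

#' Equilibrium branch and Hopf points along a parameter sweep
#'
#' Continues the equilibrium across a grid of the swept parameter
#' (`"agonist"`, `"V_s"` or `"K_s"`), starting each solve from the previous
#' grid point's root (branch continuity). At every point the drug-frozen
#' 4x4 Jacobian eigenvalues classify stability; Hopf bifurcations are
#' detected as sign changes of the largest real part over the complex
#' eigenvalue pairs and refined by bisection to a parameter tolerance of
#' 1e-4.
#'
#' @param param name of the swept parameter.
#' @param range numeric length-2 sweep range (should bracket the default
#'   value).
#' @param params an [asm_parameters()] object.
#' @param n number of grid points.
#' @param targets baseline [drug_targets()] (for `V_s`/`K_s` sweeps this
#'   carries the fixed agonist level).
#' @return An object of class `asm_branch` with elements `equilibria` (one
#'   row per grid point: parameter value, state, max real part, leading
#'   imaginary part, stability) and `hopf` (refined Hopf parameter values).
#' @export
sweep_equilibrium_branch <- function(param = c("agonist", "V_s", "K_s"),
                                     range, params = asm_parameters(),
                                     n = 101, targets = drug_targets()) {
  param <- match.arg(param)
  grid <- seq(range[1], range[2], length.out = n)
  grid <- grid[if (param == "agonist") grid >= 0 else grid > 0]
  rows <- vector("list", length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    pt <- apply_sweep_value(params, targets, param, grid[i])
    eq <- tryCatch(
      find_equilibrium(pt$params, pt$targets, start = prev),
      error = function(e) NULL)
    if (is.null(eq) && !is.null(prev))
      eq <- tryCatch(find_equilibrium(pt$params, pt$targets),
                     error = function(e) NULL)
    if (is.null(eq))
      stop("equilibrium lost inside sweep range at ", param, " = ",
           grid[i])
    prev <- unname(eq$state[1:4])
    ev <- eq$eigenvalues
    cplx <- ev[abs(Im(ev)) > 1e-9]
    rows[[i]] <- data.frame(
      value = grid[i], c = eq$state[["c"]], c_s = eq$state[["c_s"]],
      phi = eq$state[["phi"]], s = eq$state[["s"]],
      max_re = max(Re(ev)),
      max_re_complex = if (length(cplx)) max(Re(cplx)) else NA_real_,
      lead_im = abs(Im(ev[which.max(Re(ev))])),
      stable = max(Re(ev)) < 0)
  }
  eqd <- do.call(rbind, rows)
  cr <- refine_hopf(eqd, param, params, targets)
  structure(list(param = param, equilibria = eqd, hopf = cr$hopf,
                 eq_fold = cr$fold, params = params, targets = targets),
            class = "asm_branch")
}

# Stability-boundary crossings, refined by bisection on the largest
# eigenvalue real part; a crossing whose leading eigenvalue is a complex
# pair is a Hopf point (a real crossing would be a fold and is reported
# separately).
refine_hopf <- function(eqd, param, params, targets, tol = 1e-4) {
  f <- eqd$max_re
  idx <- which(sign(f[-1]) != sign(f[-nrow(eqd)]))
  hopf <- numeric(0); fold <- numeric(0)
  for (i in idx) {
    lo <- eqd$value[i]; hi <- eqd$value[i + 1]
    x_lo <- unname(unlist(eqd[i, c("c", "c_s", "phi", "s")]))
    g <- function(v, start) {
      pt <- apply_sweep_value(params, targets, param, v)
      eq <- find_equilibrium(pt$params, pt$targets, start = start)
      ev <- eq$eigenvalues
      lead <- ev[which.max(Re(ev))]
      list(val = Re(lead), im = abs(Im(lead)),
           state = unname(eq$state[1:4]))
    }
    s_lo <- g(lo, x_lo)
    s_mid <- s_lo
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      s_mid <- g(mid, s_lo$state)
      if (sign(s_mid$val) == sign(s_lo$val)) {
        lo <- mid; s_lo <- s_mid
      } else hi <- mid
    }
    at <- (lo + hi) / 2
    if (s_mid$im > 1e-9 || s_lo$im > 1e-9) hopf <- c(hopf, at)
    else fold <- c(fold, at)
  }
  list(hopf = hopf, fold = fold)
}

#' Periodic branch: oscillation annotations along a parameter sweep
#'
#' Simulates the drug-frozen model past its transient at every grid value,
#' sweeping both upward and downward with the final state inherited from
#' the previous grid value, so that each sweep direction follows its own
#' attractor through bistable windows. Reports [oscillation_metrics()] per
#' grid point and direction, the bistability window (grid values where the
#' two directions settle on different attractors), and an estimate of the
#' saddle-node (fold) of limit cycles where the cycle-carrying sweep loses
#' its oscillation beyond the rightmost Hopf point.
#'
#' @inheritParams sweep_equilibrium_branch
#' @param t_sim simulated time per grid point (s).
#' @param transient transient discarded before metrics (s).
#' @param dt sampling interval (s).
#' @param rtol,atol solver tolerances.
#' @return An object of class `asm_branch` with element `metrics` (per grid
#'   value and sweep direction: oscillating, frequency, amplitude, max c,
#'   max s), `bistability` (grid values where the directions disagree) and
#'   `fold` (estimated cycle-fold parameter value, or `NA`).
#' @export
sweep_periodic_branch <- function(param = c("agonist", "V_s", "K_s"),
                                  range, params = asm_parameters(),
                                  n = 41, targets = drug_targets(),
                                  t_sim = 1000, transient = 200,
                                  dt = 0.05, rtol = 1e-8, atol = 1e-10) {
  param <- match.arg(param)
  grid <- seq(range[1], range[2], length.out = n)
  grid <- grid[if (param == "agonist") grid >= 0 else grid > 0]

  run_dir <- function(values) {
    y <- NULL
    res <- vector("list", length(values))
    for (i in seq_along(values)) {
      pt <- apply_sweep_value(params, targets, param, values[i])
      if (is.null(y)) {
        y <- unname(find_equilibrium(pt$params, pt$targets)$state[1:4])
        # nudge off the root so an unstable equilibrium is escaped
        y[1] <- y[1] * 1.02 + 1e-4
      }
      sol <- integrate_frozen(y, pt$params, pt$targets, t_sim, dt,
                              rtol, atol)
      y <- sol$y_end
      m <- oscillation_metrics(sol$time, sol$c, transient = transient)
      res[[i]] <- data.frame(value = values[i],
                             oscillating = m$oscillating,
                             frequency = m$frequency,
                             amplitude = m$amplitude,
                             max_c = max(sol$c[sol$time >= transient]),
                             max_s = max(sol$s[sol$time >= transient]))
    }
    do.call(rbind, res)
  }
  up <- run_dir(grid)
  down <- run_dir(rev(grid))
  down <- down[order(down$value), ]
  up$direction <- "up"; down$direction <- "down"
  metrics <- rbind(up, down)

  bist <- grid[up$oscillating != down$oscillating]
  # fold: extinction of the cycle-carrying direction at the high end
  fold <- NA_real_
  osc_any <- up$oscillating | down$oscillating
  if (any(osc_any)) {
    i_last <- max(which(osc_any))
    if (i_last < length(grid))
      fold <- (grid[i_last] + grid[i_last + 1]) / 2
  }
  structure(list(param = param, metrics = metrics, bistability = bist,
                 fold = fold, params = params, targets = targets),
            class = "asm_branch")
}

# fast fixed-target integration of the 4-variable dynamical core
integrate_frozen <- function(y4, params, targets, t_sim, dt = 0.05,
                             rtol = 1e-8, atol = 1e-10) {
  frozen <- frozen_drug_states(params, targets)
  # drug states start at their targets, so they stay constant: the
  # 7-state compiled RHS integrates the frozen 4-variable core.
  tg <- targets
  tg$ryacaf <- FALSE   # keeps ryr_leak constant at its frozen value
  y0 <- c(y4, unname(frozen))
  times <- seq(0, t_sim, by = dt)
  sol <- deSolve::lsoda(y0, times, func = "asmca_derivs",
                        parms = pack_parms(params, tg),
                        dllname = "asmca", initfunc = "asmca_initmod",
                        rtol = rtol, atol = atol, hmax = 1)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed at t = ", sol[nrow(sol), 1])
  list(time = sol[, 1], c = pmax(sol[, 2], 0), c_s = pmax(sol[, 3], 0),
       phi = sol[, 4], s = sol[, 5],
       y_end = pmax(sol[nrow(sol), 2:5], 0))
}

#' @export
print.asm_branch <- function(x, ...) {
  cat("asm_branch over", x$param, "\n")
  if (!is.null(x$equilibria)) {
    cat(" equilibria:", nrow(x$equilibria), "grid points;",
        sum(x$equilibria$stable), "stable\n")
    cat(" Hopf points:",
        if (length(x$hopf)) paste(signif(x$hopf, 6), collapse = ", ")
        else "none", "\n")
  }
  if (!is.null(x$metrics)) {
    up <- x$metrics[x$metrics$direction == "up", ]
    cat(" periodic annotations:", nrow(up), "grid points;",
        sum(up$oscillating), "oscillating (up-sweep)\n")
    if (length(x$bistability))
      cat(" bistability window:",
          paste(signif(range(x$bistability), 6), collapse = " .. "), "\n")
    if (!is.na(x$fold)) cat(" cycle fold estimate:",
                            signif(x$fold, 6), "\n")
  }
  invisible(x)
}

#' Write a bifurcation branch as delimited text
#'
#' Emits the per-grid tables plus a structured key=value summary block
#' (Hopf locations, bistability window, fold estimate) with the resolved
#' parameters.
#'
#' @param branch an `asm_branch`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_branch <- function(branch, path) {
  stopifnot(inherits(branch, "asm_branch"))
  p <- branch$params
  hdr <- c("# asm_branch schema_version=1",
           paste0("# swept_param=", branch$param),
           paste0("# param ", names(p), "=",
                  vapply(p, format, "", digits = 17)))
  if (!is.null(branch$hopf))
    hdr <- c(hdr, paste0("# hopf=", paste(format(branch$hopf, digits = 10),
                                          collapse = ",")))
  if (!is.null(branch$bistability) && length(branch$bistability))
    hdr <- c(hdr, paste0("# bistability=",
                         paste(format(range(branch$bistability),
                                      digits = 10), collapse = "..")))
  if (!is.null(branch$fold) && !is.na(branch$fold))
    hdr <- c(hdr, paste0("# fold=", format(branch$fold, digits = 10)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- if (!is.null(branch$equilibria)) branch$equilibria
         else branch$metrics
  utils::write.table(format(tab, digits = 15), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
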