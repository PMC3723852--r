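p0 <- default_params

test_that("oscillation metrics recover a known sinusoid and reject noise", {
  t <- seq(0, 200, by = 0.05)
  m <- oscillation_metrics(t, 0.3 + 0.2 * sin(2 * pi * t / 10),
                           transient = 0)
  expect_true(m$oscillating)
  expect_equal(m$frequency, 6.0, tolerance = 1e-3)
  expect_equal(m$amplitude, 0.4, tolerance = 1e-3)
  expect_equal(m$baseline, 0.1, tolerance = 1e-3)
  expect_gte(m$n_periods, 3)

  m2 <- oscillation_metrics(t, rep(0.25, length(t)), transient = 0)
  expect_false(m2$oscillating)
  expect_true(is.na(m2$frequency))

  expect_error(oscillation_metrics(t, t, transient = 300), "too short")
})

test_that("sustained agonist evokes oscillations in the observed band", {
  pr <- asm_protocol(data.frame(time = 0, agonist = 1), duration = 700)
  tr <- simulate_protocol(pr, p0, dt = 0.1, fluxes = FALSE)
  m <- oscillation_metrics(tr$time, tr$c, transient = 250)
  expect_true(m$oscillating)
  # the band reported for human lung slices is 0.5-11 per minute
  expect_gt(m$frequency, 0.5)
  expect_lt(m$frequency, 11)
  expect_gt(m$amplitude, 0.1)
})

test_that("without agonist the trajectory settles on the resting root", {
  pr <- asm_protocol(data.frame(time = numeric(0)), duration = 800,
                     initial = asm_state(c = 0.2, c_s = 60, phi = 0.3,
                                         s = 0.4))
  tr <- simulate_protocol(pr, p0, dt = 1, fluxes = FALSE)
  expect_lt(abs(tr$c[nrow(tr)] - resting_eq$state[["c"]]), 1e-4)
})

test_that("closed-cell trajectories conserve c + c_s/gamma", {
  # no external Ca2+ and a practically absent PMCA: a closed cell
  pc <- asm_parameters(V_p = 1e-9)
  pr <- asm_protocol(data.frame(time = 0, agonist = 0.8, ryacaf = NA,
                                cpa = NA, external_ca = FALSE),
                     duration = 400,
                     initial = asm_state(c = 0.1, c_s = 90, phi = 0.1,
                                         s = 0.2))
  tr <- simulate_protocol(pr, pc, dt = 0.5, fluxes = FALSE)
  tot <- tr$c + tr$c_s / pc$gamma
  expect_lt(diff(range(tot)), 1e-6)
})

test_that("trajectories keep every state inside its physical box", {
  set.seed(21)
  for (i in 1:4) {
    ev <- data.frame(time = c(0, 150, 300),
                     agonist = c(runif(1, 0, 2), 0, runif(1, 0, 2)),
                     ryacaf = c(NA, runif(1) > 0.5, NA),
                     cpa = c(runif(1) > 0.5, NA, NA),
                     external_ca = c(NA, NA, runif(1) > 0.5))
    pr <- asm_protocol(ev, duration = 450)
    tr <- simulate_protocol(pr, p0, dt = 0.5, fluxes = FALSE)
    expect_true(all(tr$c >= 0 & tr$c_s >= 0))
    expect_true(all(tr$phi >= 0 & tr$phi <= 1))
    expect_true(all(tr$s >= 0 & tr$s <= 1))
    expect_true(all(tr$serca_eff >= 0 & tr$serca_eff <= 1))
  }
})

test_that("up- and down-sweeps agree where a single attractor exists", {
  pb <- sweep_periodic_branch("agonist", c(0.6, 1.2), p0, n = 4,
                              t_sim = 700, transient = 300, dt = 0.1)
  up <- pb$metrics[pb$metrics$direction == "up", ]
  dn <- pb$metrics[pb$metrics$direction == "down", ]
  expect_true(all(up$oscillating) && all(dn$oscillating))
  expect_lt(max(abs(up$frequency - dn$frequency) / up$frequency), 0.02)
})

test_that("trajectory flux columns are consistent with the state", {
  pr <- asm_protocol(data.frame(time = 0, agonist = 1), duration = 60)
  tr <- simulate_protocol(pr, p0, dt = 1, fluxes = TRUE)
  i <- nrow(tr)
  st <- asm_state(tr$c[i], tr$c_s[i], tr$phi[i], tr$s[i], tr$p_eff[i],
                  tr$ryr_leak[i], tr$serca_eff[i])
  fx <- flux_breakdown(st, p0)
  expect_equal(tr$J_SERCA[i], fx[["J_SERCA"]], tolerance = 1e-12)
  expect_equal(tr$J_pm_in_total[i], fx[["J_pm_in_total"]],
               tolerance = 1e-12)
  expect_equal(tr$J_rel_total[i], fx[["J_rel_total"]], tolerance = 1e-12)
})
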