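test_that("targets resolve piecewise-constantly with documented tie-break", {
  ev <- data.frame(time = c(100, 300, 300),
                   agonist = c(1, 0.5, 2),
                   ryacaf = c(NA, TRUE, NA),
                   cpa = NA, external_ca = NA)
  pr <- asm_protocol(ev, duration = 500)
  t0 <- drug_targets_at(50, pr)  # before the first event: resting targets
  expect_equal(t0$agonist, 0)
  expect_true(t0$external_ca)
  expect_false(t0$ryacaf)
  expect_equal(drug_targets_at(150, pr)$agonist, 1)
  tied <- drug_targets_at(350, pr)
  expect_equal(tied$agonist, 2)      # later-listed event wins the tie
  expect_true(tied$ryacaf)           # earlier event's other target kept
  expect_error(drug_targets_at(600, pr), "duration")
  expect_error(drug_targets_at(-1, pr), "duration")
})

test_that("protocol construction validates its event table", {
  expect_error(asm_protocol(data.frame(time = c(10, 5), agonist = 1), 100),
               "non-decreasing")
  expect_error(asm_protocol(data.frame(time = 10, agonist = -1), 100),
               "agonist")
  expect_error(asm_protocol(data.frame(time = 10, agonist = 1), 5),
               "duration")
})

test_that("named protocols encode the experimental designs", {
  fig3 <- build_protocol("fig3_threestep")
  ev <- fig3$events
  ag_on <- ev$time[!is.na(ev$agonist) & ev$agonist > 0]
  rya_on <- ev$time[!is.na(ev$ryacaf) & ev$ryacaf]
  expect_length(ag_on, 2)                # two agonist phases
  expect_length(rya_on, 1)
  expect_true(ag_on[1] < rya_on & rya_on < ag_on[2])  # Rya-Caf in between

  zc <- build_protocol("cpa_zero_ca")
  off <- zc$events$time[!is.na(zc$events$external_ca) &
                          !zc$events$external_ca]
  final_ag <- max(zc$events$time[!is.na(zc$events$agonist) &
                                   zc$events$agonist > 0])
  expect_true(off < final_ag)  # Ca2+ removed strictly before last agonist

  ff <- build_protocol("cpa_fast_full")
  expect_equal(ff$param_overrides[["cpa_block_fraction"]], 1)
  expect_false("tau_e" %in% names(ff$param_overrides))  # fast: default 30 s
  sf <- build_protocol("cpa_slow_full")
  expect_gt(sf$param_overrides[["tau_e"]], 100)

  expect_error(build_protocol("no_such"), "unknown protocol")

  # building is pure data: no side effects, protocol fields only
  expect_s3_class(fig3, "asm_protocol")
  expect_named(fig3, c("events", "duration", "initial", "param_overrides"))
})

test_that("protocols round-trip through their text serialization", {
  f <- withr::local_tempfile(fileext = ".protocol")
  for (nm in c("fig3_threestep", "cpa_partial", "cpa_zero_ca")) {
    pr <- build_protocol(nm)
    write_protocol(pr, f)
    back <- read_protocol(f)
    expect_equal(back$events, pr$events)
    expect_identical(back$duration, pr$duration)
    expect_equal(back$param_overrides, pr$param_overrides)
  }
})

test_that("agonist onset follows the first-order lag identity", {
  p0 <- default_params
  pr <- asm_protocol(data.frame(time = 0, agonist = 1), duration = p0$tau_p,
                     initial = resting_eq$state)
  tr <- simulate_protocol(pr, p0, dt = 0.5, fluxes = FALSE)
  # continuity at the step: p_eff starts from its prior value
  expect_equal(tr$p_eff[1], 0)
  # p_eff(tau_p) = 1 - exp(-1)
  expect_equal(tr$p_eff[nrow(tr)], 1 - exp(-1), tolerance = 1e-5)
})

test_that("the Rya-Caf leak never decreases once evoked", {
  tr <- simulate_protocol(build_protocol("fig3_threestep"), default_params,
                          dt = 0.5, fluxes = FALSE)
  onset <- min(tr$time[tr$ryr_leak > 0])
  lam <- tr$ryr_leak[tr$time >= onset]
  expect_true(all(diff(lam) >= -1e-9))
  # and it persists after exposure ends (irreversibility)
  expect_gt(tr$ryr_leak[nrow(tr)], 0.9 * max(lam))
})
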