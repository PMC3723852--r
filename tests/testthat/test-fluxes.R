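p0 <- default_params

test_that("STIM dissociation curve has the reverse-Hill signature", {
  expect_equal(soce_steady_state(p0$K_s, p0), 0.5)
  expect_equal(soce_steady_state(0, p0), 1)
  expect_equal(soce_steady_state(100, p0), 50^4 / (50^4 + 100^4))
  cs <- seq(0, 400, by = 2)
  expect_true(all(diff(soce_steady_state(cs, p0)) < 0))
  expect_error(soce_steady_state(-1, p0), "non-negative")
})

test_that("plasma-membrane influx components follow the reference rates", {
  st <- asm_state(c = 0.1, c_s = 100, phi = 0.1, s = 0)
  expect_equal(pm_influx(st, p0)$total, 0)  # alpha_0 = 0, no agonist/SOCE
  st <- asm_state(c = 0.1, c_s = 100, phi = 0.1, s = 0, p_eff = 1)
  expect_equal(pm_influx(st, p0)$total, 0.00105)  # pure ROCE
  st <- asm_state(c = 0.1, c_s = 100, phi = 0.1, s = 1)
  expect_equal(pm_influx(st, p0)$total, 1.57)     # pure SOCE
  # removing external Ca2+ silences every influx component
  off <- pm_influx(asm_state(0.1, 100, 0.1, 1, p_eff = 2), p0,
                   external_ca = FALSE)
  expect_identical(unlist(off), c(J_leak_in = 0, J_ROCE = 0, J_SOCE = 0,
                                  total = 0))
})

test_that("pump fluxes saturate with the half-saturation identities", {
  expect_equal(pmca_flux(p0$K_p, p0), p0$V_p / 2)
  expect_equal(pmca_flux(0, p0), 0)
  expect_equal(pmca_flux(1e9, p0), p0$V_p, tolerance = 1e-8)
  expect_true(all(diff(pmca_flux(seq(0, 5, 0.05), p0)) > 0))

  expect_equal(serca_flux(p0$K_e, 1, p0), p0$V_e / 2)
  expect_equal(serca_flux(3, 0, p0), 0)
  expect_equal(serca_flux(1e9, 0.5, p0), 2.5, tolerance = 1e-8)
  expect_true(all(diff(serca_flux(seq(0, 5, 0.05), 1, p0)) > 0))
  expect_error(serca_flux(1, 1.5, p0), "serca_eff")
  expect_error(pmca_flux(-0.1, p0), "non-negative")
})

test_that("IPR open probability gates on IP3, Ca2+ and inhibition", {
  expect_equal(ipr_open_probability(0.2, 0, 0.1, p0), 0)
  expect_equal(ipr_open_probability(0.2, 1, 1, p0), 0)
  # strictly increasing in agonist at fixed c, phi
  ps <- seq(0.1, 5, by = 0.1)
  po <- ipr_open_probability(0.2, ps, 0, p0)
  expect_true(all(diff(po) > 0))
  expect_gt(ipr_open_probability(0.2, 1, 0, p0),
            ipr_open_probability(0.2, 0.1, 0, p0))
  expect_true(all(po >= 0 & po <= 1))
})

test_that("inhibition kinetics stay in bounds and increase with Ca2+", {
  grid <- expand.grid(c = c(0, 0.05, 0.3, 1, 10), p = c(0, 0.5, 1, 5))
  for (i in seq_len(nrow(grid))) {
    pr <- phi_relaxation(grid$c[i], grid$p[i], p0)
    expect_gte(pr$phi_inf, 0); expect_lte(pr$phi_inf, 1)
    expect_gt(pr$rate, 0)
  }
  # no Ca2+ bound at c = 0: the inhibited steady state vanishes
  expect_equal(phi_relaxation(0, 1, p0)$phi_inf, 0)
  cs <- seq(0, 10, by = 0.05)
  pi1 <- vapply(cs, function(cc) phi_relaxation(cc, 1, p0)$phi_inf, 0)
  expect_true(all(diff(pi1) >= 0))
})

test_that("SR release components scale with the published rates", {
  st <- asm_state(c = 0.2, c_s = 0.2, phi = 0.3, s = 0.1, p_eff = 1)
  rel <- sr_release_flux(st, p0)
  expect_equal(unlist(rel), c(J_IPR = 0, J_RyR = 0, J_SR_leak = 0,
                              total = 0))  # no gradient, no flux
  st <- asm_state(c = 0.2, c_s = 100.2, phi = 0.3, s = 0.1)  # p_eff = 0
  rel <- sr_release_flux(st, p0)
  expect_equal(rel$J_SR_leak, 0.01 * 100)
  expect_equal(rel$J_IPR, 0)
  st <- asm_state(c = 0.2, c_s = 100.2, phi = 0.3, s = 0.1, p_eff = 1,
                  ryr_leak = 0.5)
  rel <- sr_release_flux(st, p0)
  expect_equal(rel$J_RyR, 0.5 * 100)
  # IPR component is exactly k_IPR * P_open * gradient
  expect_equal(rel$J_IPR,
               p0$k_IPR * ipr_open_probability(0.2, 1, 0.3, p0) * 100)
})

test_that("flux breakdown components sum to the totals bit-for-bit", {
  set.seed(42)
  for (i in 1:25) {
    st <- random_state()
    ext <- runif(1) > 0.5
    fx <- flux_breakdown(st, p0, external_ca = ext)
    expect_identical(fx[["J_pm_in_total"]],
                     fx[["J_leak_in"]] + fx[["J_ROCE"]] + fx[["J_SOCE"]])
    expect_identical(fx[["J_rel_total"]],
                     fx[["J_IPR"]] + fx[["J_RyR"]] + fx[["J_SR_leak"]])
    if (st[["c_s"]] >= st[["c"]])
      expect_true(all(fx >= 0))
  }
})

test_that("fluorescence emulation is a saturating monotone map", {
  expect_equal(fluorescence_transform(0.17, 0.17), 0.5)
  expect_equal(fluorescence_transform(0, 0.17), 0)
  f <- fluorescence_transform(seq(0, 3, 0.01), 0.17)
  expect_true(all(diff(f) > 0) && all(f >= 0 & f < 1))
  expect_error(fluorescence_transform(1, -2), "dye_Kd")
  expect_error(fluorescence_transform(-1, 0.17), "non-negative")
})
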