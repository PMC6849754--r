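test_that("chi limits: saturating at D = 0, compensation point at huge D", {
  r0 <- calc_chi(std_ks, 0)
  expect_equal(r0$chi, 1)
  expect_equal(r0$ci, std_ks$ca)
  rbig <- calc_chi(std_ks, 1e12)
  expect_equal(rbig$chi, std_ks$gammastar / std_ks$ca, tolerance = 1e-3)
  expect_error(calc_chi(std_ks, -5), class = "vcx_domain_error")
})

test_that("analytic chi is the argmin of the least-cost function", {
  # standard conditions, against dense grid search
  chi <- calc_chi(std_ks, 1000)$chi
  chi_num <- oracle_chi_grid(std_ks, 1000, std_params$beta)
  expect_equal(chi, chi_num, tolerance = 1e-4)

  # seeded random environments
  envs <- draw_envs(25, seed = 101)
  for (i in seq_len(nrow(envs))) {
    ks <- calc_kinetics(envs$tg[i], calc_patm(envs$z[i]), envs$ca_ppm[i])
    chi <- calc_chi(ks, envs$dg[i])$chi
    expect_equal(chi, oracle_chi_grid(ks, envs$dg[i], std_params$beta),
                 tolerance = 1e-3)
  }
})

test_that("chi errors when Ca does not exceed Gamma*", {
  ks <- calc_kinetics(25, 101325, ca_ppm = 20)   # Ca ~ 2 Pa < Gamma*
  expect_error(calc_chi(ks, 1000), class = "vcx_domain_error")
})

test_that("m and mc follow the hand-checked arithmetic and limits", {
  ks <- std_ks
  # stated-input hand arithmetic: ci 30, Gamma* 4.332, K 71.9
  ks2 <- structure(list(gammastar = 4.332, K = 71.9), class = "kinetic_state")
  mm <- calc_m_terms(30, ks2)
  expect_equal(mm$m, 25.668 / 38.664)
  expect_equal(mm$mc, 25.668 / 101.9)
  # numerator vanishes near the compensation point
  tiny <- calc_m_terms(ks$gammastar + 1e-9, ks)
  expect_lt(tiny$m, 1e-8)
  expect_lt(tiny$mc, 1e-9)
  # both approach 1 at very high ci
  big <- calc_m_terms(1e9, ks)
  expect_equal(big$m, 1, tolerance = 1e-6)
  expect_equal(big$mc, 1, tolerance = 1e-6)
  # ordering tied to K vs 2 Gamma*
  mm3 <- calc_m_terms(30, ks)
  expect_gt(mm3$m, mm3$mc)
  expect_error(calc_m_terms(ks$gammastar, ks), class = "vcx_domain_error")
})

test_that("omega satisfies the marginal-cost condition dAj/dJmax = c", {
  for (I in c(100, 800, 2000)) {
    for (m in c(0.3, 0.5, 0.65, 0.8)) {
      om <- calc_omega(std_params, m)
      jmax <- std_params$phi * I * om
      deriv <- oracle_dAj_dJmax(jmax, I, m, std_params$phi,
                                std_params$theta)
      expect_equal(deriv, std_params$c_cost, tolerance = 1e-6)
    }
  }
})

test_that("closed-form omega equals bisection of the marginal condition", {
  set.seed(202)
  for (i in 1:25) {
    theta <- runif(1, 0.7, 0.99)
    cc <- runif(1, 0.02, 0.12)
    m <- runif(1, 4 * cc * 1.15, 0.95)
    p <- model_params(theta = theta, c_cost = cc)
    expect_equal(calc_omega(p, m),
                 oracle_omega_bisect(theta, cc, m),
                 tolerance = 1e-6)
  }
})

test_that("omega modes agree and structural properties hold", {
  m <- c(0.35, 0.6, 0.8)
  p_num <- model_params(omega_mode = "numeric")
  expect_equal(calc_omega(std_params, m), calc_omega(p_num, m),
               tolerance = 1e-6)
  # infeasible below m = 4c
  expect_error(calc_omega(std_params, 4 * std_params$c_cost * 0.99),
               class = "vcx_domain_error")
  expect_error(calc_omega(std_params, 0.05), class = "vcx_domain_error")
})

test_that("omega* identities: algebraic corners and Aj equivalence", {
  expect_equal(calc_omega_star(1, 1), 2)
  expect_equal(calc_omega_star(0, 0.85), 0)
  # Aj via phi I m omega*/(8 theta) == hyperbola at Jmax = phi I omega
  for (m in c(0.3, 0.55, 0.8)) {
    om <- calc_omega(std_params, m)
    oms <- calc_omega_star(om, std_params$theta)
    for (I in c(150, 800, 1800)) {
      aj_closed <- std_params$phi * I * m * oms / (8 * std_params$theta)
      aj_direct <- oracle_aj(std_params$phi * I * om, I, m,
                             std_params$phi, std_params$theta)
      expect_equal(aj_closed, aj_direct, tolerance = 1e-10)
    }
    expect_gt(oms, 0)
    expect_lt(oms, 2)
  }
})

test_that("Vcmax*: proportional to I, coordination Ac = Aj", {
  mm <- calc_m_terms(calc_chi(std_ks, 1000)$ci, std_ks)
  om <- calc_omega(std_params, mm$m)
  oms <- calc_omega_star(om, std_params$theta)
  v800 <- calc_vcmax_star(800, mm$m, mm$mc, oms, std_params)
  v1600 <- calc_vcmax_star(1600, mm$m, mm$mc, oms, std_params)
  expect_identical(v1600, 2 * v800)
  # scalar arithmetic oracle: phi I (m/mc) omega*/(8 theta)
  expect_equal(v800, 0.257 * 800 * (mm$m / mm$mc) * oms / (8 * 0.85),
               tolerance = 1e-12)
  # coordination: Ac = Vcmax* mc equals Aj
  ac <- v800 * mm$mc
  aj <- oracle_aj(std_params$phi * 800 * om, 800, mm$m, std_params$phi,
                  std_params$theta)
  expect_equal(ac, aj, tolerance = 1e-10)
  expect_error(calc_vcmax_star(800, 0.6, 0, 1.2), class = "vcx_domain_error")
})

test_that("peaked-Arrhenius scaling: identity, oracle value, single peak", {
  expect_identical(kattge_knorr_scale(100, 300, 300, 640), 100)
  # frozen scalar evaluation: 100 scaled To 309.07 K -> 298.15 K, dS(25)
  expect_equal(kattge_knorr_scale(100, 309.07, 298.15,
                                  entropy_vcmax(25)),
               53.1960401824802, tolerance = 1e-10)
  # single-peaked and smooth in target temperature
  tg <- seq(273.15, 318.15, by = 0.5)
  v <- kattge_knorr_scale(100, 309.07, tg, entropy_vcmax(25))
  peak <- which.max(v)
  expect_true(peak > 1 && peak < length(v))
  expect_true(all(diff(v[seq_len(peak)]) > 0))
  expect_true(all(diff(v[peak:length(v)]) < 0))
  expect_error(kattge_knorr_scale(100, 25, 298, 640),
               class = "vcx_domain_error")
})

test_that("optimum temperature regression is Kelvin-consistent", {
  # 25 degC growth -> To ~ 309.07 K ~ 35.9 degC (24.92 + 0.44 * 25)
  expect_equal(calc_t_opt(298.15), 177.884 + 0.44 * 298.15)
  expect_equal(calc_t_opt(298.15) - 273.15, 24.92 + 0.44 * 25,
               tolerance = 1e-3)
  expect_error(calc_t_opt(25), class = "vcx_domain_error")
})

test_that("full prediction equals the chained per-stage oracle", {
  pred <- predict_optimal(800, 25, 1000, 0)
  # chain the independent pieces
  ks <- calc_kinetics(25, calc_patm(0))
  chi <- oracle_chi_grid(ks, 1000, std_params$beta)
  ci <- chi * ks$ca
  m <- (ci - ks$gammastar) / (ci + 2 * ks$gammastar)
  mc <- (ci - ks$gammastar) / (ci + ks$K)
  om <- oracle_omega_bisect(std_params$theta, std_params$c_cost, m)
  oms <- 1 + om - sqrt((1 + om)^2 - 4 * std_params$theta * om)
  vstar <- 0.257 * 800 * (m / mc) * oms / (8 * 0.85)
  to <- 177.884 + 0.44 * 298.15
  vc <- oracle_kk(vstar, to, 298.15, 668.39 - 1.07 * 25)
  expect_equal(pred$vcmax_opt, vc, tolerance = 1e-4)
  jm <- oracle_kk(0.257 * 800 * om, to, 298.15, 659.70 - 0.75 * 25,
                  Ha = 49884)
  expect_equal(pred$jmax_opt, jm, tolerance = 1e-4)
  expect_equal(pred$jv_ratio, jm / vc, tolerance = 1e-4)
})

test_that("coordination holds at the optimum for random environments", {
  envs <- draw_envs(100, seed = 303)
  pred <- predict_optimal(envs$ig, envs$tg, envs$dg, envs$z, envs$ca_ppm)
  ac <- pred$vcmax_star * pred$mc
  aj <- std_params$phi * pred$ig_umol_m2_s * pred$m * pred$omega_star /
    (8 * std_params$theta)
  expect_equal(ac, aj, tolerance = 1e-8)
  expect_true(all(pred$m > pred$mc))
  expect_true(all(pred$omega > 0))
  expect_true(all(pred$omega_star > 0 & pred$omega_star < 2))
  expect_true(all(pred$vcmax_opt > 0 & pred$jmax_opt > 0))
})

test_that("sensitivity signs at standard conditions match the model", {
  base <- list(ig = 800, tg = 25, dg = 1000, z = 0)
  # linear and increasing in irradiance; chi invariant
  ig <- seq(100, 2000, by = 100)
  p_ig <- predict_optimal(ig, base$tg, base$dg, base$z)
  expect_true(all(diff(p_ig$vcmax_opt) > 0))
  expect_equal(p_ig$vcmax_opt / ig, rep(p_ig$vcmax_opt[1] / ig[1],
                                        length(ig)), tolerance = 1e-12)
  expect_equal(diff(range(p_ig$chi)), 0)
  # increasing in temperature over 0-30, chi increasing in Tg
  tg <- seq(0, 30, by = 1)
  p_tg <- predict_optimal(base$ig, tg, base$dg, base$z)
  expect_true(all(diff(p_tg$vcmax_opt) > 0))
  expect_true(all(diff(p_tg$chi) > 0))
  # increasing in vapour pressure deficit; chi decreasing
  dg <- seq(100, 4000, by = 100)
  p_dg <- predict_optimal(base$ig, base$tg, dg, base$z)
  expect_true(all(diff(p_dg$vcmax_opt) > 0))
  expect_true(all(diff(p_dg$chi) < 0))
  # increasing in elevation
  z <- seq(0, 4500, by = 250)
  p_z <- predict_optimal(base$ig, base$tg, base$dg, z)
  expect_true(all(diff(p_z$vcmax_opt) > 0))
  # Jmax:Vcmax ratio declines with temperature
  tg2 <- seq(10, 35, by = 1)
  p_jv <- predict_optimal(base$ig, tg2, base$dg, base$z)
  expect_true(all(diff(p_jv$jv_ratio) < 0))
})

test_that("jv_ratio_mode at_to reports the unscaled ratio", {
  p <- model_params(jv_ratio_mode = "at_to")
  pred <- predict_optimal(800, 25, 1000, 0, params = p)
  expect_equal(pred$jv_ratio,
               (p$phi * 800 * pred$omega) / pred$vcmax_star)
})

test_that("predict_vcmax carries identifiers and validates schema", {
  sites <- data.frame(site_id = c("a", "b"), lat = c(10, 20),
                      lon = c(30, 40), z_m = c(0, 1000),
                      tg_c = c(25, 15), dg_pa = c(1000, 800),
                      ig_umol_m2_s = c(800, 600))
  out <- predict_vcmax(sites)
  expect_equal(out$site_id, c("a", "b"))
  expect_equal(out$ca_ppm, c(400, 400))
  expect_error(predict_vcmax(sites[-4]), class = "vcx_parse_error")
})
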