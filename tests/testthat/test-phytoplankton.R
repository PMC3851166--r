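p0 <- default_params()
sP <- make_initial_state("P", "oligotrophic-summer")
qP <- compute_quotas(sP, p0)

test_that("quotas are computed from the state", {
  expect_equal(qP$QN, sP[["Nb"]] / sP[["Cb"]])
  expect_equal(qP$QP, sP[["Pb"]] / sP[["Cb"]])
  expect_equal(qP$theta, sP[["Chla"]] / sP[["Cb"]])
  expect_equal(qP$QC_ba, sP[["Cba"]] / sP[["Nba"]])
  sn <- make_initial_state("noP", "oligotrophic-summer")
  qn <- compute_quotas(sn, p0)
  expect_true(is.na(qn$QP))
})

test_that("quotas error when a biomass pool is below the floor", {
  s <- sP
  s[["Cb"]] <- 0
  expect_error(compute_quotas(s, p0), "Cb")
})

test_that("nutrient limitation follows Liebig's minimum over N and P", {
  lim <- nutrient_limitation(qP, p0, "P")
  expect_equal(lim$Qstar, min(lim$limN, lim$limP))
  expect_gte(lim$Qstar, 0)
  expect_lte(lim$Qstar, 1)
  expect_identical(lim$limiting_element,
                   if (lim$limP < lim$limN) "P" else "N")
  # hand-computed normalized quota
  expect_equal(lim$limN,
               min(1, max(0, (qP$QN - p0$phyto$QN_min) /
                               (p0$phyto$QN_max - p0$phyto$QN_min))))
})

test_that("limitation clamps at the quota bounds", {
  q <- qP
  q$QN <- p0$phyto$QN_min / 2
  expect_equal(nutrient_limitation(q, p0, "P")$limN, 0)
  q$QN <- p0$phyto$QN_max * 2
  expect_equal(nutrient_limitation(q, p0, "P")$limN, 1)
})

test_that("noP version ignores phosphorus in the limitation", {
  sn <- make_initial_state("noP", "oligotrophic-summer")
  qn <- compute_quotas(sn, p0)
  lim <- nutrient_limitation(qn, p0, "noP")
  expect_true(is.na(lim$limP))
  expect_equal(lim$Qstar, lim$limN)
})

test_that("gross primary production saturates with irradiance", {
  E <- c(0, 5, 20, 80, 320, 1280)
  gpp <- vapply(E, function(e) {
    gross_primary_production(sP, qP, e, p0, "P")
  }, 0)
  expect_equal(gpp[1], 0)
  expect_true(all(diff(gpp) > 0))           # monotone in E
  lim <- nutrient_limitation(qP, p0, "P")
  pmax_flux <- sP[["Cb"]] * p0$phyto$PCm * lim$Qstar
  expect_true(all(gpp <= pmax_flux + 1e-12))
  expect_equal(gpp[6], pmax_flux, tolerance = 1e-2)  # near saturation
})

test_that("gross primary production is linear in light at low irradiance", {
  g1 <- gross_primary_production(sP, qP, 0.01, p0, "P")
  g2 <- gross_primary_production(sP, qP, 0.02, p0, "P")
  expect_equal(g2 / g1, 2, tolerance = 1e-3)
  # slope equals alpha * theta * E * Cb in the limit
  expect_equal(g1,
               sP[["Cb"]] * p0$phyto$alpha_chl * qP$theta * 0.01,
               tolerance = 1e-3)
})

test_that("production falls to zero as the limiting quota empties", {
  q <- qP
  q$QN <- p0$phyto$QN_min       # empty N quota
  expect_equal(gross_primary_production(sP, q, 80, p0, "P"), 0)
})

test_that("nutrient uptake is Michaelis-Menten scaled by quota head-room", {
  up <- nutrient_uptake(sP, qP, p0, "P")
  expect_named(up, c("NO3", "NH4", "PO4"))
  expect_true(all(up >= 0))
  hungerN <- (p0$phyto$QN_max - qP$QN) / (p0$phyto$QN_max - p0$phyto$QN_min)
  expect_equal(unname(up[["NO3"]]),
               sP[["Cb"]] * p0$phyto$V_NO3 * sP[["NO3"]] /
                 (sP[["NO3"]] + p0$phyto$K_NO3) * hungerN)
  # at satiated quota, uptake stops
  q <- qP
  q$QN <- p0$phyto$QN_max
  q$QP <- p0$phyto$QP_max
  up0 <- nutrient_uptake(sP, q, p0, "P")
  expect_equal(unname(up0[["NO3"]]), 0)
  expect_equal(unname(up0[["PO4"]]), 0)
})

test_that("ammonium inhibition suppresses nitrate uptake when enabled", {
  p_inh <- default_params(phyto.nh4_inhib = 0.05)
  up <- nutrient_uptake(sP, qP, p_inh, "P")
  up_ref <- nutrient_uptake(sP, qP, p0, "P")
  expect_lt(up[["NO3"]], up_ref[["NO3"]])
  expect_equal(up[["NH4"]], up_ref[["NH4"]])
})

test_that("photoacclimation keeps theta inside its bounds", {
  # theta_dot = (Chla_dot - theta * Cb_dot) / Cb with the matching
  # physiological carbon losses; it must be restoring at both bounds.
  theta_dot <- function(theta, E) {
    s <- sP
    s[["Chla"]] <- s[["Cb"]] * theta
    q <- compute_quotas(s, p0)
    loss <- p0$phyto$resp + p0$phyto$exud + p0$phyto$mort
    cb_dot <- gross_primary_production(s, q, E, p0, "P") - loss * s[["Cb"]]
    chla_dot <- chlorophyll_tendency(s, q, E, p0, "P")
    (chla_dot - theta * cb_dot) / s[["Cb"]]
  }
  for (E in c(5, 80, 300)) {
    expect_gte(theta_dot(p0$phyto$theta_min, E), -1e-12)
    expect_lte(theta_dot(p0$phyto$theta_max, E), 1e-12)
  }
})

test_that("the chlorophyll synthesis ratio declines with irradiance", {
  # rho implied from the tendency: rho = (Chla_dot + loss * Chla) / GPP
  s <- sP
  q <- compute_quotas(s, p0)
  loss <- p0$phyto$resp + p0$phyto$exud + p0$phyto$mort
  rho_at <- function(E) {
    (chlorophyll_tendency(s, q, E, p0, "P") + loss * s[["Chla"]]) /
      gross_primary_production(s, q, E, p0, "P")
  }
  expect_gt(rho_at(2), rho_at(400))   # pigment dilution under high light
  expect_lte(rho_at(2), p0$phyto$theta_max + 1e-12)
  expect_gte(rho_at(400), p0$phyto$theta_min - 1e-12)
})

test_that("phyto_sms conserves phytoplankton element flow directions", {
  f <- sample_forcing()
  d <- phyto_sms(sP, f, p0, "P")
  expect_named(d, c("Cb", "Nb", "Chla", "Pb"), ignore.order = TRUE)
  # nutrient-replete, lit water: biomass grows
  s <- sP
  s[["NO3"]] <- 5; s[["PO4"]] <- 0.5
  expect_gt(phyto_sms(s, f, p0, "P")[["Cb"]], 0)
  # darkness: carbon declines
  expect_lt(phyto_sms(sP, list(temp = 20, E = 0), p0, "P")[["Cb"]], 0)
})
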