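test_that("lability rules carry the documented default fractions", {
  r <- lability_rules()
  expect_equal(r$doc, 0.20)
  expect_equal(r$don, 0.20)
  expect_equal(r$dop, 0.88)
  expect_equal(r$poc, 0.18)
  expect_equal(r$pon, 0.20)
  expect_equal(r$pop, 0.88)
  expect_error(lability_rules(doc = 1.2), "\\[0, 1\\]")
})

test_that("apply_lability maps raw to model pools with worked values", {
  raw <- c(NO3 = 100, NH4 = 5, PO4 = 1.5, DOC = 100, DON = 10, DOP = 10,
           POC = 50, PON = 6, POP = 0.5)
  out <- apply_lability(raw)
  expect_equal(unname(out[["LDOC"]]), 20)    # 20% of 100
  expect_equal(unname(out[["DPOC"]]), 9)     # 18% of 50
  expect_equal(unname(out[["LDOP"]]), 8.8)   # 88% of 10
  expect_equal(unname(out[["DPON"]]), 1.2)   # 20% of 6
  expect_equal(unname(out[["DPOP"]]), 0.44)  # 88% of 0.5
  expect_equal(unname(out[["NO3"]]), 100)    # nutrients pass through
  # alternative particulate-nitrogen reading: fraction of POC
  alt <- apply_lability(raw, lability_rules(pon_from_poc = TRUE))
  expect_equal(unname(alt[["DPON"]]), 0.2 * 50)
})

test_that("apply_lability refuses already-labile inputs and missing columns", {
  expect_error(apply_lability(c(NO3 = 1, LDOC = 5)), "re-applied")
  expect_error(apply_lability(c(NO3 = 1)), "missing")
})

test_that("the Rhone loader applies lability and the 90% discharge factor", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  make_river_fixture(404, 30, "rhone", file = f)
  raw <- utils::read.csv(f)
  rs <- load_river_series(f, "rhone")
  expect_s3_class(rs, "river_series")
  expect_equal(rs$discharge, 0.90 * raw$discharge)
  expect_equal(rs$LDOC, 0.20 * raw$DOC)
  expect_equal(rs$DPOC, 0.18 * raw$POC)
  expect_equal(rs$DPOP, 0.88 * raw$POP)
  expect_equal(rs$NO3, raw$NO3)
})

test_that("the Caronte source is constant with a 20 m3/s discharge", {
  cs <- load_river_series(river = "caronte")
  expect_equal(cs$discharge, 20)
  expect_equal(cs$NO3, 0.75)
  expect_equal(cs$NH4, 2.72)
  expect_equal(cs$PO4, 0.4)
  expect_equal(cs$LDOC, 45)
  expect_equal(cs$LDON, 3.73)
  expect_equal(cs$LDOP, 0.11)
  expect_equal(cs$DPOC, 1.8)
  expect_equal(cs$DPON, 1.36)
  expect_equal(cs$DPOP, 0.078)
})

test_that("the WWTP loader fixes PO4 at 13.4 and keeps daily N", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  make_river_fixture(405, 20, "wwtp", file = f)
  raw <- utils::read.csv(f)
  ws <- load_river_series(f, "wwtp")
  expect_equal(ws$PO4, rep(13.4, nrow(ws)))
  expect_equal(ws$NO3, raw$NO3)
  expect_equal(ws$NH4, raw$NH4)
  expect_equal(ws$LDOC, rep(135, nrow(ws)))
})

test_that("urban rivers take nutrients from the Rhone series", {
  fr <- tempfile(fileext = ".csv"); fu <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fr, fu)))
  make_river_fixture(406, 40, "rhone", file = fr)
  make_river_fixture(407, 40, "urban", file = fu)
  rs <- load_river_series(fr, "rhone")
  us <- load_river_series(fu, "huveaune",
                          rhone_nutrients = rs[c("date", "NO3", "NH4", "PO4")])
  expect_equal(us$NO3, rs$NO3[match(us$date, rs$date)])
  expect_equal(us$LDOC, rep(38.5, nrow(us)))
  expect_error(load_river_series(fu, "huveaune"), "rhone_nutrients")
})

test_that("gaps in daily series are forward-filled with a warning", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  df <- make_river_fixture(408, 10, "wwtp")
  df <- df[-c(4, 5), ]
  utils::write.csv(df, f, row.names = FALSE)
  expect_warning(ws <- load_river_series(f, "wwtp"), "forward-filled")
  expect_equal(nrow(ws), 10L)
  expect_equal(ws$NO3[4], ws$NO3[3])  # carried forward
})

test_that("river fluxes convert concentration x discharge to tendencies", {
  cs <- load_river_series(river = "caronte")
  fx <- river_boundary_flux(cs, volume_m3 = 86400 * 20)  # 1 volume/d
  expect_equal(fx$NO3, cs$NO3)  # conc * Q * 86400 / V = conc
})

test_that("dry deposition delivers the accumulated mass as a mean flux", {
  dry <- data.frame(date = as.Date("2008-01-01") + c(0, 10, 24),
                    NO3 = c(0, 50, 140))
  out <- atmospheric_deposition_flux(dry, mld_m = 10)
  expect_equal(out$NO3_flux[1], 5)            # 50 umol/m2 over 10 d
  expect_equal(out$NO3_flux[15], 10)          # 140 over 14 d
  expect_equal(sum(out$NO3_flux), 190)        # total mass preserved
  expect_equal(out$NO3_tend, out$NO3_flux / 1e4)
})

test_that("wet deposition is concentration times rainfall", {
  dry <- data.frame(date = as.Date("2008-01-01") + c(0, 4), NO3 = c(0, 0))
  wet <- data.frame(date = as.Date("2008-01-01"), NO3 = 2)
  rain <- data.frame(date = as.Date("2008-01-01") + 0:3,
                     rain_mm = c(0, 10, 0, 5))
  out <- atmospheric_deposition_flux(dry, wet, rain, mld_m = 10)
  # 2 umol/L x 10 mm = 20 umol/m2/d -> 0.002 umol/L/d over 10 m
  expect_equal(out$NO3_flux, c(0, 20, 0, 10))
  expect_equal(out$NO3_tend[2], 0.002)
})

test_that("light extinction reproduces the k = k_w + k_chl * Chla law", {
  p <- default_params()
  out <- light_extinction(2, p, dz = 10, E0 = 1, at = "bottom")
  expect_equal(out$k, 0.04 + 0.03 * 2)
  expect_equal(out$E, exp(-1))
  # profile: energy decreases monotonically with depth
  prof <- light_extinction(rep(0.5, 10), p, dz = 2, E0 = 100)
  expect_true(all(diff(prof$E) < 0))
  expect_error(light_extinction(-1, p, dz = 1), "Chla")
})

test_that("physical_forcing validates its inputs", {
  expect_error(physical_forcing(time = c(1, 1), temp = c(10, 10),
                                E0 = c(1, 1)))
  expect_error(physical_forcing(time = c(0, 1), temp = c(10, 10),
                                E0 = c(-1, 1)))
  f <- physical_forcing(time = 0:2, temp = rep(15, 3), E0 = rep(50, 3),
                        dilution = rep(0.1, 3))
  expect_s3_class(f, "physical_forcing")
})

test_that("river registry lists all known sources", {
  expect_setequal(river_registry(),
                  c("rhone", "caronte", "wwtp", "bonneveine", "huveaune",
                    "aygalade", "belvedere"))
})
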