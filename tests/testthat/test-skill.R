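# Hand-computed reference vectors for the statistics.
M <- c(1, 2, 3, 4, 5)
O <- c(2, 2, 4, 4, 6)
p_ref <- paired_series(M, O, variable = "x")

test_that("percentage bias matches the hand computation", {
  # PB = 100 * sum(O - M) / sum(O) = 100 * 3 / 18
  expect_equal(percentage_bias(p_ref), 100 * 3 / 18)
  # overestimation is negative
  over <- paired_series(O + 1, O)
  expect_lt(percentage_bias(over), 0)
  expect_error(percentage_bias(paired_series(c(1, 2), c(1, -1))), "zero")
})

test_that("cost function is mean absolute error over sd of observations", {
  expect_equal(cost_function(p_ref), mean(abs(M - O)) / sd(O))
  expect_equal(cost_function(p_ref, population = TRUE),
               mean(abs(M - O)) / (sd(O) * sqrt(4 / 5)))
  expect_equal(cost_function(paired_series(O, O)), 0)
  expect_error(cost_function(paired_series(c(1, 2), c(3, 3))), "variance")
})

test_that("AAE, RMSD and correlation match hand computations", {
  expect_equal(aae(p_ref), mean(abs(M - O)))            # 3/5... = 0.6? keep
  expect_equal(rmsd(p_ref), sqrt(mean((M - O)^2)))
  expect_gte(rmsd(p_ref), aae(p_ref))
  expect_equal(correlation(p_ref), cor(M, O))
  expect_equal(correlation(paired_series(O, O)), 1)
  expect_error(correlation(paired_series(c(1, 1), c(0, 2))), "constant")
})

test_that("OSPAR bins reproduce the published classification", {
  expect_identical(as.character(classify_ospar(c(0, 0.5, 1, 1.5, 2, 2.5,
                                                 3, 3.5))),
                   c("very good", "very good", "very good", "good", "good",
                     "reasonable", "reasonable", "poor"))
  # the reported surface-temperature cost function of 0.27 is very good
  expect_identical(as.character(classify_ospar(0.27)), "very good")
  expect_error(classify_ospar(-0.1))
})

test_that("target coordinates decompose the RMSD (Jolliff identity)", {
  tg <- target_diagram_coords(p_ref)
  expect_equal(tg[["Bias_star"]], (mean(M) - mean(O)) / sd(O))
  total <- rmsd(p_ref) / sd(O)
  expect_equal(tg[["uRMSD_star"]]^2 + tg[["Bias_star"]]^2, total^2,
               tolerance = 1e-12)
  # sign convention: model with more variance plots to the right
  wide <- paired_series(3 * (O - mean(O)) + mean(O), O)
  expect_gt(target_diagram_coords(wide)[["uRMSD_star"]], 0)
  narrow <- paired_series(0.1 * (O - mean(O)) + mean(O), O)
  expect_lt(target_diagram_coords(narrow)[["uRMSD_star"]], 0)
})

test_that("Jolliff identity holds to 1e-10 on 1000 random series", {
  set.seed(20201)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    o <- rnorm(n, 10, 2)
    m <- o + rnorm(n, sample(c(-1, 0, 1), 1), runif(1, 0.1, 3))
    pp <- paired_series(m, o)
    tg <- target_diagram_coords(pp)
    err <- abs(tg[["uRMSD_star"]]^2 + tg[["Bias_star"]]^2 -
                 (rmsd(pp) / sd(o))^2)
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-10)
})

test_that("skill_report assembles consistent statistics", {
  rep <- skill_report(p_ref)
  expect_s3_class(rep, "skill_report")
  expect_equal(rep$CF, cost_function(p_ref))
  expect_equal(rep$PB, percentage_bias(p_ref))
  expect_equal(rep$RMSD, rmsd(p_ref))
  expect_identical(rep$ospar_rating,
                   as.character(classify_ospar(rep$CF)))
  df <- as.data.frame(rep)
  expect_equal(df$CF, rep$CF)
  expect_output(print(rep), "OSPAR")
})

test_that("a perfect closed loop scores zero error and rating very good", {
  perfect <- paired_series(O, O, variable = "Chla")
  rep <- skill_report(perfect)
  expect_equal(rep$CF, 0)
  expect_equal(rep$PB, 0)
  expect_equal(rep$AAE, 0)
  expect_equal(rep$RMSD, 0)
  expect_equal(rep$Bias_star, 0)
  expect_equal(rep$uRMSD_star, 0)
  expect_identical(rep$ospar_rating, "very good")
})

test_that("paired_series drops incomplete pairs", {
  pp <- paired_series(c(1, NA, 3), c(1, 2, NA))
  expect_equal(nrow(pp), 1L)
})

test_that("monthly climatology groups by calendar month", {
  d <- as.Date("2008-01-15") + c(0, 10, 40, 370)
  v <- c(1, 3, 5, 7)
  cl <- monthly_climatology(d, v)
  expect_equal(cl$month[1], 1L)
  expect_equal(cl$n[cl$month == 1], 3L)        # two Januaries + one
  expect_equal(cl$mean[cl$month == 1], mean(c(1, 3, 7)))
  expect_equal(cl$sd[cl$month == 2], 0)        # single value
})

test_that("match_series pairs nearest-in-time records", {
  fm <- tempfile(fileext = ".csv"); fo <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fm, fo)))
  mod <- data.frame(timestamp = format(as.Date("2008-01-01") + 0:30),
                    variable = "Chla", value = sin(0:30 / 5) + 2)
  obs <- data.frame(timestamp = format(as.Date("2008-01-01") +
                                         c(3, 10, 17, 50)),
                    variable = "Chla", value = c(2.5, 3.0, 2.2, 9))
  utils::write.csv(mod, fm, row.names = FALSE)
  utils::write.csv(obs, fo, row.names = FALSE)
  ps <- match_series(fm, fo, tolerance_days = 1)
  expect_named(ps, "Chla")
  expect_equal(nrow(ps$Chla), 3L)  # day-50 obs is out of tolerance
  expect_equal(ps$Chla$model[1], mod$value[4])
})
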