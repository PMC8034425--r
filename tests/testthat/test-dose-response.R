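test_that("percent growth follows the piecewise formula and is continuous", {
  expect_equal(percent_growth(150, 100, 200), 50)
  expect_equal(percent_growth(100, 100, 200), 0)
  expect_equal(percent_growth(50, 100, 200), -50)
  expect_equal(percent_growth(200, 100, 200), 100)  # Ti = C
  # continuity at Ti = Tz: both branches give 0
  expect_equal(percent_growth(100 - 1e-9, 100, 200),
               percent_growth(100 + 1e-9, 100, 200), tolerance = 1e-7)
  expect_error(percent_growth(50, 100, 100), "undefined")
})

test_that("growth inhibition converts single-dose growth values", {
  expect_equal(as.numeric(growth_inhibition(60)), 40)
  expect_equal(as.numeric(growth_inhibition(100)), 0)
  expect_equal(as.numeric(growth_inhibition(0)), 100)
  gi <- growth_inhibition(-25)
  expect_equal(as.numeric(gi), -25)  # lethality passes through
  expect_true(attr(gi, "lethal"))
})

test_that("endpoint concentration interpolates in log dose and censors", {
  conc <- 10^seq(-8, -4)
  # exact grid hit
  e <- endpoint_concentration(conc, c(100, 75, 50, 25, 0), 50)
  expect_equal(e$value, 1e-6)
  expect_equal(e$censor, "exact")
  # log-linear interpolation midway between bracketing doses
  e <- endpoint_concentration(conc, c(100, 80, 60, 40, 20), 50)
  expect_equal(log10(e$value), -5.5)
  # never reaches the level
  e <- endpoint_concentration(conc, c(100, 90, 80, 70, 60), 50)
  expect_equal(e$censor, "above_max")
  expect_equal(e$value, 1e-4)
  # already below at the lowest dose
  e <- endpoint_concentration(conc, c(30, 20, 10, 0, -10), 50)
  expect_equal(e$censor, "below_min")
  expect_error(endpoint_concentration(conc, c(100, NA, 50, 25, 0), 50),
               "non-finite")
})

test_that("endpoint concentration is monotone under uniform PG shifts", {
  conc <- 10^seq(-8, -4)
  set.seed(5)
  for (i in 1:20) {
    pg <- sort(runif(5, -60, 110), decreasing = TRUE)
    e1 <- endpoint_concentration(conc, pg, 50)
    e2 <- endpoint_concentration(conc, pg - runif(1, 0, 30), 50)
    # shifting PG down can only move the crossing earlier
    expect_lte(e2$value, e1$value + 1e-12)
  }
})

test_that("plate analysis recovers a noiseless Hill curve and censors edge cases", {
  # true GI50 2 uM, floor -80, hill 1: signals built from the growth model
  conc <- 10^seq(-8, -4)
  floor <- -80; h <- 1
  m <- 2e-6 / ((100 - 50) / (50 - floor))^(1 / h)
  pg <- floor + (100 - floor) / (1 + (conc / m)^h)
  tz <- 0.25; c0 <- 1
  ti <- ifelse(pg >= 0, tz + pg / 100 * (c0 - tz), tz * (1 + pg / 100))
  plate <- dose_plate("L1", "NSCLC", tz, c0, conc, ti)
  r <- analyze_plate(plate)
  truth <- oracle_hill_crossing(50, m, h, floor)
  # within one interpolation cell (10-fold dose spacing)
  expect_lt(abs(log10(r$gi50$value) - log10(truth)), 1)
  expect_lt(abs(log10(r$gi50$value) - log10(2e-6)), 1)
  expect_equal(r$gi50$censor, "exact")
  # ordering when all exact and monotone
  expect_lte(r$gi50$value, r$tgi$value)
  expect_lte(r$tgi$value, r$lc50$value)

  # all Ti = C: no inhibition anywhere
  r2 <- analyze_plate(dose_plate("L2", "P", tz, c0, conc, rep(c0, 5)))
  expect_true(all(c(r2$gi50$censor, r2$tgi$censor, r2$lc50$censor) ==
                    "above_max"))
  # all Ti = 0: total kill from the lowest dose
  r3 <- analyze_plate(dose_plate("L3", "P", tz, c0, conc, rep(0, 5)))
  expect_equal(r3$gi50$censor, "below_min")
  expect_equal(r3$tgi$censor, "below_min")
})

test_that("screen summary reports panel ranges excluding censored values", {
  conc <- 10^seq(-8, -4)
  mk <- function(id, gi50_uM) {
    floor <- -80; h <- 1.5
    m <- gi50_uM * 1e-6 / ((100 - 50) / (50 - floor))^(1 / h)
    pg <- floor + (100 - floor) / (1 + (conc / m)^h)
    ti <- ifelse(pg >= 0, 0.25 + pg / 100 * 0.75, 0.25 * (1 + pg / 100))
    dose_plate(id, "NSCLC", 0.25, 1, conc, ti)
  }
  s <- summarize_screen(list(mk("A", 1), mk("B", 2), mk("C", 4)))
  rg <- s$panel_ranges[s$panel_ranges$endpoint == "GI50", ]
  expect_equal(rg$n_censored, 0)
  expect_lt(abs(log10(rg$min_uM) - log10(1)), 0.5)
  expect_lt(abs(log10(rg$max_uM) - log10(4)), 0.5)

  # single plate: degenerate range
  s1 <- summarize_screen(list(mk("A", 2)))
  rg1 <- s1$panel_ranges[s1$panel_ranges$endpoint == "GI50", ]
  expect_equal(rg1$min_uM, rg1$max_uM)

  # fully censored panel
  s2 <- summarize_screen(list(
    dose_plate("X", "Colon", 0.25, 1, conc, rep(1, 5)),
    dose_plate("Y", "Colon", 0.25, 1, conc, rep(1, 5))))
  rgc <- s2$panel_ranges[s2$panel_ranges$endpoint == "GI50", ]
  expect_equal(rgc$n_censored, 2)
  expect_true(is.na(rgc$min_uM))
})

test_that("censored endpoints serialize as range inequalities in uM", {
  conc <- 10^seq(-8, -4)
  r <- analyze_plate(dose_plate("X", "P", 0.25, 1, conc, rep(1, 5)))
  expect_equal(format_endpoint_uM(r$gi50, conc), "> 100")
  r2 <- analyze_plate(dose_plate("Y", "P", 0.25, 1, conc, rep(0, 5)))
  expect_equal(format_endpoint_uM(r2$gi50, conc), "< 0.01")
})

test_that("plate TSV round-trips through the readers", {
  gp <- gen_dose_plates(n_lines = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plates_tsv(gp$plates, path)
  back <- read_plates_tsv(path)
  expect_setequal(names(back), vapply(gp$plates, `[[`, "", "cell_line"))
  orig <- gp$plates[[1]]
  got <- back[[orig$cell_line]]
  expect_equal(got$ti, orig$ti, tolerance = 1e-8)
})
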