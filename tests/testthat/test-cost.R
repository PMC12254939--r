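test_that("diurnal profiling averages each clock hour over days", {
  ts <- seq(as.POSIXct("2020-03-01 00:00:00", tz = "UTC"),
            by = 3600, length.out = 48)
  s <- data.frame(timestamp = ts, price_eur_kwh = 0.05)
  prof <- diurnalProfile(s, 2020)
  expect_equal(unname(meanPrice(prof)), rep(0.05, 24))

  s2 <- s
  s2$price_eur_kwh[c(9, 33)] <- c(0.10, 0.30)  # hour 8 on both days
  expect_equal(unname(meanPrice(diurnalProfile(s2, 2020))[["8"]]), 0.20)

  expect_error(diurnalProfile(s[-10, ], 2020), "gap error")
  expect_error(diurnalProfile(s, 2019), "full day")
})

test_that("hour ranking is by descending price with earlier-hour ties", {
  p <- makeProfile(0.1)
  expect_equal(rankHours(p), 0:23)
  p2 <- makeProfile(c(rep(0.1, 8), 0.5, rep(0.1, 15)))
  expect_equal(rankHours(p2)[1], 8L)
  dp <- patternProfile()
  rk <- rankHours(dp)
  peaks <- c(8:10, 17:19); trough <- c(23, 0:4)
  expect_true(max(match(peaks, rk)) < min(match(trough, rk)))
})

test_that("hourly energy follows the power model", {
  one <- lightRegime("1h", data.frame(start_h = c(0, 1), duration_h = c(1, 23),
                                      ppfd = c(100, 0)), 0)
  e <- hourlyEnergy(one, linearPowerModel(2.5))
  expect_equal(unname(e[1]), 0.040)
  expect_equal(unname(e[2:24]), rep(0, 23))
  two <- lightRegime("1h", data.frame(start_h = c(0, 1), duration_h = c(1, 23),
                                      ppfd = c(200, 0)), 0)
  expect_equal(hourlyEnergy(two), 2 * e)

  dt <- data.frame(ppfd = c(0, 100, 300), watts_m2 = c(0, 45, 150))
  pm <- tablePowerModel(dt)
  expect_equal(power(pm, 200), 97.5)  # interpolated midpoint
  expect_error(power(pm, 400), "extrapolate")
  expect_error(tablePowerModel(data.frame(ppfd = c(0, 100),
                                          watts_m2 = c(5, 45))),
               "start at")
})

test_that("daily cost factorises under a constant price", {
  p <- makeProfile(0.10)
  for (reg in builtinRegimes()[c("Sunlike", "Price-Based")]) {
    expect_equal(dailyCost(reg, p),
                 0.10 * sum(hourlyEnergy(reg)))
  }
  one <- lightRegime("1h", data.frame(start_h = c(0, 1), duration_h = c(1, 23),
                                      ppfd = c(100, 0)), 0)
  expect_equal(dailyCost(one, p), 0.004)
  # equal-DLI regimes cost the same under a flat price and linear power
  r <- builtinRegimes()
  expect_equal(dailyCost(r[["Constant-196"]], p),
               dailyCost(r[["Split-Night"]], p))
})

test_that("savings are relative, zero against self, and scale-invariant", {
  prof <- patternProfile()
  base <- constant18(196, 5)
  expect_equal(savingsVsBaseline(base, base, prof), 0)
  # a regime drawing half the energy under a flat price saves 50%
  expect_equal(savingsVsBaseline(constant18(98, 5), base, makeProfile(0.1),
                                 checkDLI = FALSE), 50)
  r11 <- constant18(196, 11)
  s <- savingsVsBaseline(r11, base, prof)
  expect_equal(s, 100 * (dailyCost(base, prof) - dailyCost(r11, prof)) /
                 dailyCost(base, prof))
  # invariant to a uniform price rescale
  prof3 <- makeProfile(3 * meanPrice(prof))
  expect_equal(savingsVsBaseline(r11, base, prof3), s)
  # and to a uniform efficacy change
  expect_equal(savingsVsBaseline(r11, base, prof, linearPowerModel(5)), s)
  expect_error(savingsVsBaseline(constant18(100, 5), base, prof),
               "unequal DLI")
})

test_that("shift scan enumerates all 24 anchors and flags the argmin", {
  flat <- makeProfile(0.07)
  sc <- shiftScan(constant18(), flat)
  expect_equal(nrow(sc), 24L)
  expect_equal(sc$start_hour, 0:23)
  expect_true(all(abs(sc$cost_eur_m2 - sc$cost_eur_m2[1]) < 1e-12))
  expect_true(all(abs(sc$savings_pct) < 1e-9))
  expect_equal(which(sc$is_best), 1L)  # earliest tie wins

  dp <- patternProfile()
  sc2 <- shiftScan(constant18(196, 5), dp)
  best <- sc2$start_hour[sc2$is_best]
  # the 6-h dark block must cover the most expensive contiguous 6-h window
  prices <- meanPrice(dp)
  roll6 <- vapply(0:23, function(h) sum(prices[((h + 0:5) %% 24) + 1]),
                  numeric(1))
  darkStart <- (best + 18) %% 24
  expect_equal(roll6[darkStart + 1], max(roll6))
  expect_true(all(sc2$cost_eur_m2[sc2$is_best] <= sc2$cost_eur_m2))
})

test_that("optimal anchoring matches an independent brute force", {
  regs <- builtinRegimes()[c("Split-Night", "Price-Based", "Sunlike")]
  for (seed in 1:25) {
    prof <- withr::with_seed(seed, makeProfile(stats::runif(24, 0.02, 0.3)))
    for (reg in regs) {
      fit <- targetCheapHours(reg, prof)
      bf <- bruteForceBestAnchor(reg, prof)
      expect_equal(fit$start_hour, bf$start_hour)
      expect_equal(fit$cost_eur_m2, bf$cost, tolerance = 1e-12)
    }
  }
})

test_that("Split-Night anchored on the double-peak pattern darkens 08-11 and 17-20", {
  fit <- targetCheapHours(builtinRegimes()[["Split-Night"]], patternProfile())
  expect_equal(fit$start_hour, 11L)
  hp <- hourlyPPFD(fit$regime)
  expect_equal(unname(hp[as.character(c(8:10, 17:19))]), rep(0, 6))
})

test_that("dark-block coverage of expensive hours drives Split-Night shift costs", {
  prof <- patternProfile()
  prices <- meanPrice(prof)
  sn <- builtinRegimes()[["Split-Night"]]
  sc <- shiftScan(sn, prof)
  darkPriceMass <- vapply(0:23, function(h) {
    hp <- hourlyPPFD(lightRegime("x", regimeIntervals(sn), h))
    sum(prices[hp == 0])
  }, numeric(1))
  peakCover <- vapply(0:23, function(h) {
    hp <- hourlyPPFD(lightRegime("x", regimeIntervals(sn), h))
    sum(hp == 0 & prices == max(prices))
  }, numeric(1))
  # cost falls exactly as the price mass under darkness grows (the lit
  # intensity is constant, so cost is affine in the covered price mass)
  expect_equal(order(sc$cost_eur_m2), order(-darkPriceMass))
  # and the cheapest shift darkens all six ranked-expensive hours
  expect_equal(peakCover[sc$is_best], 6)
  expect_lt(mean(sc$cost_eur_m2[peakCover == 6]),
            mean(sc$cost_eur_m2[peakCover == 0]))
})

test_that("cost report has Table-style shape and a zero baseline row", {
  s <- genPriceSeries(years = 2020:2023, seed = 3)
  base <- list("Constant 05-23" = constant18(196, 5, "Constant 05-23"))
  solo <- costReport(base, s, baseline = "Constant 05-23")
  expect_s4_class(solo, "CostReport")
  expect_true(all(abs(reportTable(solo)$savings_pct) < 1e-12))
  expect_true(is.na(dynamicMeanSavings(solo)))

  regs <- lapply(builtinRegimes(), scaleToDLI, targetDLI = 12.7)
  rep4 <- costReport(regs, s, baseline = "Constant 05-23",
                     dynamic = c("Price-Based", "Split-Night"))
  tab <- reportTable(rep4)
  expect_equal(nrow(tab), length(regs) * 4L)
  expect_equal(sort(unique(tab$year)), as.character(2020:2023))
  expect_equal(dynamicMeanSavings(rep4),
               mean(tab$savings_pct[tab$is_dynamic]))
  expect_error(costReport(regs, s, baseline = "nope"), "unknown baseline")
  # unequal DLIs refused unless rescaled
  expect_error(costReport(builtinRegimes(), s), "common DLI")
})

test_that("spot-price CSV reader handles both dialects and comma decimals", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  ts <- seq(as.POSIXct("2021-01-01 00:00:00", tz = "UTC"), by = 3600,
            length.out = 48)
  writeLines(c("timestamp,price_eur_kwh",
               paste(format(ts, "%Y-%m-%dT%H:%M:%S"),
                     sprintf("%.3f", seq_along(ts) / 100), sep = ",")), f1)
  long <- readSpotPrices(f1)
  expect_equal(nrow(long), 48L)
  expect_equal(long$price_eur_kwh[3], 0.03)

  f2 <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("date", sprintf("%02d - %02d", 0:23, 1:24)), collapse = ",")
  row1 <- paste(c("2021-01-01", gsub(".", ",", sprintf("%.2f", (1:24) / 10),
                                     fixed = TRUE)), collapse = ",")
  # quote comma-decimal cells so the CSV stays 25 columns wide
  row1 <- paste(c("2021-01-01",
                  sprintf('"%s"', gsub(".", ",", sprintf("%.2f", (1:24) / 10),
                                       fixed = TRUE))), collapse = ",")
  writeLines(c(hdr, row1), f2)
  wide <- readSpotPrices(f2)
  expect_equal(nrow(wide), 24L)
  expect_equal(wide$price_eur_kwh, (1:24) / 10)
  prof <- diurnalProfile(wide, 2021)
  expect_equal(unname(meanPrice(prof)[["5"]]), 0.6)
})
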