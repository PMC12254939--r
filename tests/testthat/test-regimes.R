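test_that("built-in regimes encode the published schedules", {
  r <- builtinRegimes()
  expect_length(r, 11L)

  c155 <- r[["Constant-155"]]
  expect_equal(startClock(c155), 6)
  iv <- regimeIntervals(c155)
  expect_equal(iv$ppfd, c(155, 0))
  expect_equal(iv$duration_h, c(18, 6))

  hl <- regimeIntervals(r[["High-Low"]])
  expect_equal(hl$ppfd, c(275, 95, 0))
  expect_equal(hl$start_h, c(0, 6, 18))

  sn <- regimeIntervals(r[["Split-Night"]])
  expect_equal(sn$ppfd, c(196, 0, 196, 0))
  expect_equal(sn$duration_h, c(6, 3, 12, 3))
  expect_equal(startClock(r[["Split-Night"]]), 11)

  pb <- regimeIntervals(r[["Price-Based"]])
  expect_equal(pb$ppfd, c(100, 0, 150, 340, 150, 0))
  expect_equal(pb$duration_h, c(6, 3, 3, 6, 3, 3))
})

test_that("DLI integration reproduces the published daily light integrals", {
  r <- builtinRegimes()
  expect_equal(computeDLI(r[["Constant-155"]]), 10.044)
  expect_equal(computeDLI(r[["Price-Based"]]), 12.744)
  small <- c("Constant-155", "High-Low", "Sunlike", "Low-High")
  dliSmall <- vapply(r[small], computeDLI, numeric(1))
  expect_true(all(abs(dliSmall - dliSmall[1]) < 1e-9))
  expect_true(all(signif(dliSmall, 3) == 10.0))
  large <- c("Constant-196", "Split-Night", "Price-Based")
  expect_true(all(signif(vapply(r[large], computeDLI, numeric(1)), 3) == 12.7))

  dark <- lightRegime("off", data.frame(start_h = 0, duration_h = 24, ppfd = 0))
  expect_equal(computeDLI(dark), 0)
})

test_that("cumulative DLI integrates from photoperiod onset", {
  r <- builtinRegimes()
  expect_equal(cumulativeDLI(r[["Constant-155"]], 0), 0)
  expect_equal(cumulativeDLI(r[["Constant-155"]], 6), 3.348)
  expect_equal(cumulativeDLI(r[["High-Low"]], 6), 5.94)
  for (reg in r) {
    grid <- cumulativeDLI(reg, seq(0, 24, by = 0.5))
    expect_true(all(diff(grid) >= -1e-12))
    expect_equal(grid[length(grid)], computeDLI(reg))
  }
  expect_error(cumulativeDLI(r[[1]], 25), "\\[0, 24\\]")
  expect_error(cumulativeDLI(r[[1]], -1), "\\[0, 24\\]")
})

test_that("equal-DLI scaling is shape-preserving and exact", {
  r <- builtinRegimes()
  # rescaling the 155 umol constant to 12.7 mol reproduces a ~196 constant
  s <- scaleToDLI(r[["Constant-155"]], 12.70)
  expect_equal(regimeIntervals(s)$ppfd[1], 12.70 / (155 * 64800e-6) * 155,
               tolerance = 1e-12)
  expect_equal(regimeIntervals(s)$ppfd[1], 196, tolerance = 1e-3 * 196)
  expect_equal(regimeIntervals(s)$start_h, regimeIntervals(r[[1]])$start_h)

  # identity and round-trip accuracy over all built-ins and targets
  for (reg in r) {
    expect_equal(regimeIntervals(scaleToDLI(reg, computeDLI(reg)))$ppfd,
                 regimeIntervals(reg)$ppfd)
    for (d in c(0.5, 10, 12.7, 40)) {
      expect_equal(computeDLI(scaleToDLI(reg, d)), d, tolerance = 1e-9)
    }
  }
  dark <- lightRegime("off", data.frame(start_h = 0, duration_h = 24, ppfd = 0))
  expect_error(scaleToDLI(dark, 10), "zero DLI")
})

test_that("photoperiod shifting is cyclic and DLI-conserving", {
  r <- builtinRegimes()
  shifted <- shiftStart(r[["Constant 05-23"]], 6)
  expect_equal(startClock(shifted), 11)
  expect_equal(hourlyPPFD(shifted), hourlyPPFD(r[["Constant 11-05"]]))
  expect_equal(hourlyPPFD(shiftStart(r[["Sunlike"]], 24)),
               hourlyPPFD(r[["Sunlike"]]))
  expect_equal(startClock(shiftStart(r[["Sunlike"]], -6)),
               startClock(shiftStart(r[["Sunlike"]], 18)))
  for (h in c(-7, 0, 3, 11.5, 23, 48)) {
    expect_identical(computeDLI(shiftStart(r[["Price-Based"]], h)),
                     computeDLI(r[["Price-Based"]]))
  }
})

test_that("hourly PPFD discretisation is lossless for whole-hour regimes", {
  for (reg in builtinRegimes()) {
    hp <- hourlyPPFD(reg)
    expect_equal(sum(hp) * 3600 / 1e6, computeDLI(reg))
  }
  # sub-hour intervals average within the hour
  half <- lightRegime("half", data.frame(start_h = c(0, 0.5),
                                         duration_h = c(0.5, 23.5),
                                         ppfd = c(200, 0)), 0)
  expect_equal(unname(hourlyPPFD(half)[1]), 100)
})

test_that("regime validity rejects malformed interval coverage", {
  expect_error(lightRegime("gap", data.frame(start_h = c(0, 10),
                                             duration_h = c(8, 14),
                                             ppfd = c(100, 0))),
               "coverage")
  expect_error(lightRegime("overlap", data.frame(start_h = c(0, 10),
                                                 duration_h = c(12, 14),
                                                 ppfd = c(100, 0))),
               "coverage")
  expect_error(lightRegime("short", data.frame(start_h = 0, duration_h = 20,
                                               ppfd = 100)),
               "coverage")
  expect_error(lightRegime("neg", data.frame(start_h = c(0, 12),
                                             duration_h = c(12, 12),
                                             ppfd = c(-5, 0))),
               "ppfd")
})

test_that("regime JSON round-trips numerically exactly", {
  f <- withr::local_tempfile(fileext = ".json")
  regs <- builtinRegimes()[c("Price-Based", "Constant-155")]
  writeRegimes(regs, f)
  back <- readRegimes(f)
  expect_equal(names(back), names(regs))
  for (nm in names(regs)) {
    expect_identical(regimeIntervals(back[[nm]]), regimeIntervals(regs[[nm]]))
    expect_identical(startClock(back[[nm]]), startClock(regs[[nm]]))
  }
  # the bundled file matches the in-code constructors
  bundled <- readRegimes(system.file("extdata", "builtin_regimes.json",
                                     package = "cealux"))
  expect_equal(vapply(bundled, computeDLI, numeric(1)),
               vapply(builtinRegimes(), computeDLI, numeric(1)))
})
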