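# Electricity-cost engine: diurnal price profiling, hour ranking, regime
# costing, cyclic-anchor optimisation, and the regime x year cost report.

#' Linear and table power models
#'
#' `linearPowerModel()` assumes power draw proportional to PPFD with a
#' constant photon efficacy (W m-2 = ppfd / efficacy); `tablePowerModel()`
#' interpolates a measured dimming curve.
#'
#' @param efficacy Photon efficacy in umol J-1 (default 2.5, typical of
#'   current horticultural LED luminaires).
#' @param dimmingTable `data.frame` with strictly increasing `ppfd` and
#'   nondecreasing `watts_m2`, starting at `(0, 0)`.
#' @return A [PowerModel-class].
#' @examples
#' power(linearPowerModel(2.5), 100)  # 40 W m-2
#' @export
linearPowerModel <- function(efficacy = 2.5) {
  new("PowerModel", mode = "linear", efficacy = as.numeric(efficacy),
      dimmingTable = data.frame())
}

#' @rdname linearPowerModel
#' @export
tablePowerModel <- function(dimmingTable) {
  new("PowerModel", mode = "table", efficacy = NA_real_,
      dimmingTable = as.data.frame(dimmingTable))
}

#' @rdname power
#' @export
setGeneric("power", function(pm, ppfd) standardGeneric("power"))

#' Luminaire power draw for a PPFD target
#'
#' @param pm A [PowerModel-class].
#' @param ppfd PPFD values, umol m-2 s-1 (vectorised).
#' @return Power draw, W m-2.  Table mode refuses PPFD above the table
#'   range (no extrapolation).
#' @aliases power
#' @export
setMethod("power", "PowerModel", function(pm, ppfd) {
  stopifnot(all(is.finite(ppfd)), all(ppfd >= 0))
  if (pm@mode == "linear") return(ppfd / pm@efficacy)
  dt <- pm@dimmingTable
  if (any(ppfd > max(dt$ppfd))) {
    stop("ppfd above dimming-table range; refusing to extrapolate")
  }
  stats::approx(dt$ppfd, dt$watts_m2, xout = ppfd, rule = 1)$y
})

setMethod("show", "PowerModel", function(object) {
  if (object@mode == "linear") {
    cat(sprintf("PowerModel: linear, efficacy %.3g umol J-1\n", object@efficacy))
  } else {
    cat(sprintf("PowerModel: dimming table, %d points up to %g umol m-2 s-1\n",
                nrow(object@dimmingTable), max(object@dimmingTable$ppfd)))
  }
})

#' Read an hourly spot-price CSV
#'
#' Accepts two dialects: (1) long format with columns `timestamp`
#' (ISO-8601 hour) and `price_eur_kwh`; (2) a day x hour matrix as exported
#' by Nord Pool, with a date first column and 24 hour columns.  Comma
#' decimals are tolerated in either.  Negative prices are kept as printed
#' (they occur in day-ahead markets).
#'
#' @param path CSV path.
#' @param tz Timezone used to parse timestamps (default `"UTC"`; prices are
#'   taken at face value in local market time, no DST correction beyond
#'   what the input encodes).
#' @return `data.frame` with `timestamp` (POSIXct) and `price_eur_kwh`,
#'   sorted, strictly increasing.
#' @export
readSpotPrices <- function(path, tz = "UTC") {
  hdr <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  toNum <- function(x) as.numeric(gsub(",", ".", as.character(x), fixed = TRUE))
  if (all(c("timestamp", "price_eur_kwh") %in% names(hdr))) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    ts <- as.POSIXct(d$timestamp, tz = tz,
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    out <- data.frame(timestamp = ts, price_eur_kwh = toNum(d$price_eur_kwh))
  } else if (ncol(hdr) == 25L) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    dates <- as.Date(d[[1]])
    prices <- t(apply(d[, -1, drop = FALSE], 1, toNum))
    ts <- rep(as.POSIXct(paste(dates, "00:00:00"), tz = tz),
              each = 24L) + rep(0:23, times = length(dates)) * 3600
    out <- data.frame(timestamp = ts, price_eur_kwh = as.vector(t(prices)))
  } else {
    stop("unrecognised price CSV layout: expected timestamp/price_eur_kwh ",
         "columns or a date + 24 hour-column matrix")
  }
  out <- out[order(out$timestamp), , drop = FALSE]
  if (anyNA(out$price_eur_kwh)) stop("non-numeric prices in ", path)
  if (any(diff(as.numeric(out$timestamp)) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  rownames(out) <- NULL
  out
}

#' Diurnal price profile of one calendar year
#'
#' Per-clock-hour arithmetic mean of the hourly spot price over all days of
#' `year`.  The year's coverage must be gap-free at hourly spacing; missing
#' hours are an error that lists the absent timestamps.
#'
#' @param series `data.frame` with `timestamp` (POSIXct, hourly) and
#'   `price_eur_kwh`, e.g. from [readSpotPrices()] or [genPriceSeries()].
#' @param year Calendar year (integer or character).
#' @return A [DiurnalPriceProfile-class].
#' @export
diurnalProfile <- function(series, year) {
  stopifnot(all(c("timestamp", "price_eur_kwh") %in% names(series)))
  yr <- as.character(year)
  yrs <- format(series$timestamp, "%Y")
  sel <- series[yrs == yr, , drop = FALSE]
  if (nrow(sel) < 24L) stop("series does not cover a full day of year ", yr)
  tnum <- as.numeric(sel$timestamp)
  full <- seq(min(tnum), max(tnum), by = 3600)
  if (length(full) != nrow(sel) || !all(tnum == full)) {
    missing <- setdiff(full, tnum)
    stop("gap error: missing hourly timestamps: ",
         paste(utils::head(format(as.POSIXct(missing, tz = "UTC",
                                             origin = "1970-01-01")), 5L),
               collapse = ", "),
         if (length(missing) > 5L) sprintf(" (+%d more)", length(missing) - 5L))
  }
  hour <- as.integer(format(sel$timestamp, "%H"))
  mp <- vapply(0:23, function(h) mean(sel$price_eur_kwh[hour == h]), numeric(1))
  names(mp) <- as.character(0:23)
  new("DiurnalPriceProfile", year = yr, meanPrice = mp,
      nDays = as.integer(round(nrow(sel) / 24)))
}

#' @rdname meanPrice
#' @export
setGeneric("meanPrice", function(x) standardGeneric("meanPrice"))

#' Accessors for DiurnalPriceProfile
#'
#' @param x A [DiurnalPriceProfile-class].
#' @return `meanPrice()` the named 24-vector of mean prices (eur/kWh);
#'   `profileYear()` the year label.
#' @aliases meanPrice
#' @export
setMethod("meanPrice", "DiurnalPriceProfile", function(x) x@meanPrice)

#' @rdname meanPrice
#' @export
profileYear <- function(x) x@year

setMethod("show", "DiurnalPriceProfile", function(object) {
  cat(sprintf("DiurnalPriceProfile %s (%d days)\n", object@year, object@nDays))
  cat(sprintf("  mean %.4f, min %.4f (hour %s), max %.4f (hour %s) eur/kWh\n",
              mean(object@meanPrice), min(object@meanPrice),
              names(which.min(object@meanPrice)), max(object@meanPrice),
              names(which.max(object@meanPrice))))
})

#' Rank clock hours by mean price
#'
#' @param profile A [DiurnalPriceProfile-class].
#' @return Integer permutation of `0:23`, most expensive hour first; ties
#'   broken by the earlier clock hour.
#' @export
rankHours <- function(profile) {
  stopifnot(is(profile, "DiurnalPriceProfile"))
  p <- profile@meanPrice
  as.integer(names(p)[order(-p, as.integer(names(p)))])
}

#' Hourly electrical energy of a regime
#'
#' Converts the clock-hour PPFD profile of a regime into energy drawn per
#' clock hour: `kWh m-2 = power(ppfd) * 1 h / 1000`.
#'
#' @param regime A clock-anchored [LightRegime-class].
#' @param pm A [PowerModel-class].
#' @return Named numeric length 24, kWh m-2 per clock hour.
#' @examples
#' sum(hourlyEnergy(builtinRegimes()[["Constant-196"]], linearPowerModel(2.5)))
#' @export
hourlyEnergy <- function(regime, pm = linearPowerModel()) {
  power(pm, hourlyPPFD(regime)) / 1000
}

#' Daily electricity cost of a regime
#'
#' `sum_h energy[h] * meanPrice[h]`, with regime hours joined to profile
#' hours on clock time via the regime's `startClock`.
#'
#' @param regime A [LightRegime-class].
#' @param profile A [DiurnalPriceProfile-class].
#' @param pm A [PowerModel-class].
#' @return Cost in eur m-2 day-1.
#' @export
dailyCost <- function(regime, profile, pm = linearPowerModel()) {
  stopifnot(is(profile, "DiurnalPriceProfile"))
  sum(hourlyEnergy(regime, pm) * profile@meanPrice)
}

#' Percentage savings of a regime against a baseline
#'
#' `100 * (cost_baseline - cost_regime) / cost_baseline`.  Cost comparison
#' is only meaningful between regimes delivering the same DLI, so unequal
#' DLIs are refused unless `checkDLI = FALSE`.
#'
#' @param regime,baseline [LightRegime-class] objects at equal DLI.
#' @param profile A [DiurnalPriceProfile-class].
#' @param pm A [PowerModel-class].
#' @param checkDLI Refuse regimes whose DLIs differ by more than 1e-6
#'   relative (default `TRUE`).
#' @return Savings in percent (positive = cheaper than baseline).
#' @export
savingsVsBaseline <- function(regime, baseline, profile,
                              pm = linearPowerModel(), checkDLI = TRUE) {
  if (checkDLI) {
    d1 <- computeDLI(regime); d0 <- computeDLI(baseline)
    if (abs(d1 - d0) > 1e-6 * max(d0, 1e-12)) {
      stop("regimes have unequal DLI (", signif(d1, 6), " vs ", signif(d0, 6),
           "); scale them first or pass checkDLI = FALSE")
    }
  }
  cb <- dailyCost(baseline, profile, pm)
  cr <- dailyCost(regime, profile, pm)
  100 * (cb - cr) / cb
}

#' Cost of every cyclic photoperiod start
#'
#' Evaluates [dailyCost()] with the regime's `startClock` set to each of the
#' 24 clock hours, keeping the ZT-relative shape fixed.  Savings are quoted
#' against the regime's cost at its current anchor.
#'
#' @param regime A [LightRegime-class].
#' @param profile A [DiurnalPriceProfile-class].
#' @param pm A [PowerModel-class].
#' @return `data.frame` with `start_hour` (0-23), `cost_eur_m2`,
#'   `savings_pct` and logical `is_best` flagging the argmin (earliest hour
#'   on ties).
#' @export
shiftScan <- function(regime, profile, pm = linearPowerModel()) {
  stopifnot(is(regime, "LightRegime"))
  ref <- dailyCost(regime, profile, pm)
  cost <- vapply(0:23, function(h) {
    dailyCost(lightRegime(regime@name, regime@intervals, h), profile, pm)
  }, numeric(1))
  out <- data.frame(start_hour = 0:23, cost_eur_m2 = cost,
                    savings_pct = 100 * (ref - cost) / ref)
  out$is_best <- seq_len(24L) == which.min(cost)  # which.min: earliest tie
  out
}

#' Cheapest cyclic anchor of a fixed regime shape
#'
#' Exhaustive search over the 24 cyclic clock anchors of the (fixed-shape,
#' fixed-DLI) regime; returns the anchor minimising daily cost.  With a
#' double-peaked diurnal price profile this places the regime's dark blocks
#' over the most expensive hours.
#'
#' @inheritParams shiftScan
#' @return List with `regime` (the re-anchored [LightRegime-class]),
#'   `start_hour` and `cost_eur_m2`.
#' @export
targetCheapHours <- function(regime, profile, pm = linearPowerModel()) {
  sc <- shiftScan(regime, profile, pm)
  best <- sc[sc$is_best, ]
  list(regime = lightRegime(regime@name, regime@intervals, best$start_hour),
       start_hour = best$start_hour, cost_eur_m2 = best$cost_eur_m2)
}

#' Regime x year cost report
#'
#' For each calendar year present in `series`, builds the diurnal price
#' profile and costs every regime, reporting euro cost per m2 per day and
#' percentage savings against `baseline`.  Regimes named in `dynamic` are
#' costed at their cheapest cyclic anchor (see [targetCheapHours()]),
#' mirroring a scheduling practice where dynamic schedules are free to be
#' positioned against the price pattern while constant photoperiod scenarios
#' keep their stated clocks.  The baseline is always costed at its stated
#' clock.
#'
#' All regimes must arrive at a common DLI; alternatively pass `targetDLI`
#' to have them rescaled (shape-preserving) before costing.
#'
#' @param regimes Named list of [LightRegime-class] objects.
#' @param series Hourly price `data.frame` (see [diurnalProfile()]).
#' @param pm A [PowerModel-class].
#' @param baseline Name of the baseline regime (must be in `regimes`).
#' @param dynamic Character vector of regime names to anchor optimally
#'   (default none).  Their mean savings across years is reported as the
#'   dynamic-set summary.
#' @param targetDLI Optional common DLI to rescale all regimes to.
#' @return A [CostReport-class].
#' @export
costReport <- function(regimes, series, pm = linearPowerModel(),
                       baseline = "Constant 05-23", dynamic = character(),
                       targetDLI = NULL) {
  if (!baseline %in% names(regimes)) stop("unknown baseline name: ", baseline)
  if (!all(dynamic %in% names(regimes))) {
    stop("dynamic names absent from regimes: ",
         paste(setdiff(dynamic, names(regimes)), collapse = ", "))
  }
  if (!is.null(targetDLI)) {
    regimes <- lapply(regimes, scaleToDLI, targetDLI = targetDLI)
  } else {
    dlis <- vapply(regimes, computeDLI, numeric(1))
    if (diff(range(dlis)) > 1e-6 * max(dlis)) {
      stop("regimes are not at a common DLI; pre-scale them or pass targetDLI")
    }
  }
  years <- sort(unique(format(series$timestamp, "%Y")))
  rows <- list()
  for (yr in years) {
    prof <- diurnalProfile(series, yr)
    cb <- dailyCost(regimes[[baseline]], prof, pm)
    for (nm in names(regimes)) {
      if (nm %in% dynamic) {
        fit <- targetCheapHours(regimes[[nm]], prof, pm)
        cost <- fit$cost_eur_m2; anchor <- fit$start_hour
      } else {
        cost <- dailyCost(regimes[[nm]], prof, pm)
        anchor <- regimes[[nm]]@startClock
      }
      rows[[length(rows) + 1L]] <- data.frame(
        regime = nm, year = yr, cost_eur_m2 = cost,
        savings_pct = 100 * (cb - cost) / cb, anchor_clock = anchor,
        is_baseline = nm == baseline, is_dynamic = nm %in% dynamic)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  dms <- if (length(dynamic)) {
    mean(tab$savings_pct[tab$is_dynamic])
  } else NA_real_
  new("CostReport", table = tab, baseline = baseline,
      dynamicMeanSavings = dms)
}

#' Accessors for CostReport
#'
#' @param x A [CostReport-class].
#' @return `reportTable()` the tidy regime x year `data.frame`;
#'   `dynamicMeanSavings()` the mean savings (%) of the dynamic set across
#'   years (`NA` when no dynamic set was declared).
#' @export
reportTable <- function(x) x@table

#' @rdname reportTable
#' @export
dynamicMeanSavings <- function(x) x@dynamicMeanSavings

setMethod("show", "CostReport", function(object) {
  tab <- object@table
  cat(sprintf("CostReport: %d regimes x %d years (baseline %s)\n",
              length(unique(tab$regime)), length(unique(tab$year)),
              object@baseline))
  wide <- stats::reshape(
    tab[, c("regime", "year", "savings_pct")], direction = "wide",
    idvar = "regime", timevar = "year")
  names(wide) <- sub("savings_pct.", "savings% ", names(wide), fixed = TRUE)
  print(wide, row.names = FALSE, digits = 3)
  if (!is.na(object@dynamicMeanSavings)) {
    cat(sprintf("Dynamic-set mean savings: %.1f%%\n", object@dynamicMeanSavings))
  }
})

#' Write a cost report to CSV
#'
#' Mirrors the report table layout: one row per regime with cost and
#' savings columns per year.
#'
#' @param report A [CostReport-class].
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
writeCostReport <- function(report, path) {
  tab <- reportTable(report)
  wide <- stats::reshape(
    tab[, c("regime", "year", "cost_eur_m2", "savings_pct")],
    direction = "wide", idvar = "regime", timevar = "year")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
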