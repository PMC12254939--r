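# Lighting regimes: construction, DLI arithmetic, scaling, shifting.

#' Construct a LightRegime
#'
#' @param name Regime label.
#' @param intervals `data.frame` with columns `start_h`, `duration_h`,
#'   `ppfd` (umol m-2 s-1), contiguous and jointly covering `[0, 24)` in
#'   zeitgeber time.  Dark periods are explicit `ppfd = 0` rows.
#' @param startClock Clock time of ZT 0 in hours (e.g. `6` for 06:00).
#' @return A [LightRegime-class] object.
#' @examples
#' r <- lightRegime("Constant-155",
#'                  data.frame(start_h = c(0, 18), duration_h = c(18, 6),
#'                             ppfd = c(155, 0)), startClock = 6)
#' computeDLI(r)
#' @export
lightRegime <- function(name, intervals, startClock = 0) {
  intervals <- as.data.frame(intervals)[, c("start_h", "duration_h", "ppfd")]
  intervals[] <- lapply(intervals, as.numeric)
  new("LightRegime", name = as.character(name), intervals = intervals,
      startClock = as.numeric(startClock))
}

# Compact interval spec: ppfd/duration pairs laid end to end from ZT 0.
.blocks <- function(ppfd, duration_h) {
  data.frame(start_h = cumsum(c(0, duration_h[-length(duration_h)])),
             duration_h = duration_h, ppfd = ppfd)
}

#' Accessors for LightRegime
#'
#' @param x A [LightRegime-class].
#' @return `regimeName()` the label; `regimeIntervals()` the interval
#'   `data.frame`; `startClock()` the clock hour of ZT 0.
#' @export
regimeName <- function(x) x@name

#' @rdname regimeName
#' @export
regimeIntervals <- function(x) x@intervals

#' @rdname regimeName
#' @export
startClock <- function(x) x@startClock

setMethod("show", "LightRegime", function(object) {
  iv <- object@intervals
  cat(sprintf("LightRegime \"%s\" (ZT 0 at %05.2f clock h)\n",
              object@name, object@startClock))
  for (i in seq_len(nrow(iv))) {
    cat(sprintf("  ZT %5.2f-%5.2f h : %7.1f umol m-2 s-1\n",
                iv$start_h[i], iv$start_h[i] + iv$duration_h[i], iv$ppfd[i]))
  }
  cat(sprintf("  DLI %.3g mol m-2 d-1\n", computeDLI(object)))
})

#' Built-in lighting regimes
#'
#' The eleven regimes analysed in the package's reference scenario set:
#'
#' * Small-scale set (photoperiod 06:00, L18:D6, DLI 10.0 mol m-2):
#'   `Constant-155` (18 h at 155), and `High-Low`, `Sunlike`, `Low-High`,
#'   which split the photoperiod into three 6-h blocks with high light
#'   (275 umol m-2 s-1) at ZT 0-6, 6-12 or 12-18 respectively and low light
#'   (95) in the other two blocks.
#' * Larger-scale set (photoperiod 11:00, DLI 12.7 mol m-2):
#'   `Constant-196` (L18:D6 at 196), `Split-Night` (L6:D3:L12:D3 at 196)
#'   and `Price-Based` (6 h at 100, 3 h dark, 3 h at 150, 6 h at 340,
#'   3 h at 150, 3 h dark).  With the 11:00 anchor the two dark blocks of
#'   Split-Night and Price-Based fall on the expensive clock hours
#'   08:00-11:00 and 17:00-20:00.
#' * Four photoperiod-shift scenarios of an 18-h constant regime at 196:
#'   `Constant 05-23` (the costing baseline), `Constant 11-05`,
#'   `Constant 17-11`, `Constant 23-17`.
#'
#' @return Named list of [LightRegime-class] objects.
#' @examples
#' sapply(builtinRegimes(), computeDLI)
#' @export
builtinRegimes <- function() {
  r <- list(
    lightRegime("Constant-155", .blocks(c(155, 0), c(18, 6)), 6),
    lightRegime("High-Low", .blocks(c(275, 95, 0), c(6, 12, 6)), 6),
    lightRegime("Sunlike", .blocks(c(95, 275, 95, 0), c(6, 6, 6, 6)), 6),
    lightRegime("Low-High", .blocks(c(95, 275, 0), c(12, 6, 6)), 6),
    lightRegime("Constant-196", .blocks(c(196, 0), c(18, 6)), 11),
    lightRegime("Split-Night", .blocks(c(196, 0, 196, 0), c(6, 3, 12, 3)), 11),
    lightRegime("Price-Based",
                .blocks(c(100, 0, 150, 340, 150, 0), c(6, 3, 3, 6, 3, 3)), 11),
    lightRegime("Constant 05-23", .blocks(c(196, 0), c(18, 6)), 5),
    lightRegime("Constant 11-05", .blocks(c(196, 0), c(18, 6)), 11),
    lightRegime("Constant 17-11", .blocks(c(196, 0), c(18, 6)), 17),
    lightRegime("Constant 23-17", .blocks(c(196, 0), c(18, 6)), 23)
  )
  names(r) <- vapply(r, regimeName, character(1))
  r
}

#' @rdname computeDLI
#' @export
setGeneric("computeDLI", function(regime) standardGeneric("computeDLI"))

#' Daily light integral of a regime
#'
#' Integrates the PPFD schedule over 24 h:
#' `DLI = sum(ppfd * duration_seconds) / 1e6` mol m-2 day-1.
#'
#' @param regime A [LightRegime-class].
#' @return DLI in mol m-2 day-1.
#' @examples
#' signif(computeDLI(builtinRegimes()[["Constant-155"]]), 3)  # 10.0
#' @aliases computeDLI
#' @export
setMethod("computeDLI", "LightRegime", function(regime) {
  iv <- regime@intervals
  sum(iv$ppfd * iv$duration_h * 3600) / 1e6
})

#' @rdname cumulativeDLI
#' @export
setGeneric("cumulativeDLI", function(regime, zt_h) standardGeneric("cumulativeDLI"))

#' Cumulative DLI from photoperiod onset
#'
#' Integral of PPFD from ZT 0 up to `zt_h`, in mol m-2.  Nondecreasing in
#' `zt_h`; equals [computeDLI()] at `zt_h = 24`.  Vectorised over `zt_h`.
#'
#' @param regime A [LightRegime-class].
#' @param zt_h Hours since photoperiod onset, in `[0, 24]`.
#' @return Cumulative DLI, mol m-2.
#' @examples
#' cumulativeDLI(builtinRegimes()[["High-Low"]], 6)  # 5.94
#' @aliases cumulativeDLI
#' @export
setMethod("cumulativeDLI", "LightRegime", function(regime, zt_h) {
  if (any(!is.finite(zt_h)) || any(zt_h < 0) || any(zt_h > 24)) {
    stop("zt_h must lie in [0, 24]")
  }
  iv <- regime@intervals
  vapply(zt_h, function(z) {
    covered <- pmin(pmax(z - iv$start_h, 0), iv$duration_h)
    sum(iv$ppfd * covered * 3600) / 1e6
  }, numeric(1))
})

#' @rdname scaleToDLI
#' @export
setGeneric("scaleToDLI", function(regime, targetDLI) standardGeneric("scaleToDLI"))

#' Scale a regime to a target DLI
#'
#' Multiplies every PPFD value by one scalar so that the regime's DLI equals
#' `targetDLI`.  Interval boundaries (the regime's shape in time) are
#' preserved; intensity scaling is the unique shape-preserving way to
#' equalise DLI across regimes before cost comparison.
#'
#' @param regime A [LightRegime-class] with positive DLI.
#' @param targetDLI Target daily light integral, mol m-2.
#' @return A rescaled [LightRegime-class].
#' @examples
#' # Constant-155 rescaled to 12.7 mol m-2 reproduces a ~196 umol constant:
#' scaleToDLI(builtinRegimes()[["Constant-155"]], 12.7)
#' @aliases scaleToDLI
#' @export
setMethod("scaleToDLI", "LightRegime", function(regime, targetDLI) {
  stopifnot(is.finite(targetDLI), targetDLI > 0)
  d <- computeDLI(regime)
  if (d <= 0) stop("cannot scale a regime with zero DLI")
  iv <- regime@intervals
  iv$ppfd <- iv$ppfd * (targetDLI / d)
  lightRegime(regime@name, iv, regime@startClock)
})

#' @rdname shiftStart
#' @export
setGeneric("shiftStart", function(regime, offset_h) standardGeneric("shiftStart"))

#' Shift a regime's photoperiod start on the clock
#'
#' Advances `startClock` by `offset_h` modulo 24.  The ZT-relative interval
#' pattern, and hence the DLI, are untouched; only the alignment to
#' clock-indexed prices changes.
#'
#' @param regime A [LightRegime-class].
#' @param offset_h Hours to advance the photoperiod start (may be negative).
#' @return A shifted [LightRegime-class].
#' @examples
#' startClock(shiftStart(builtinRegimes()[["Constant 05-23"]], 6))  # 11
#' @aliases shiftStart
#' @export
setMethod("shiftStart", "LightRegime", function(regime, offset_h) {
  stopifnot(is.finite(offset_h))
  lightRegime(regime@name, regime@intervals,
              (regime@startClock + offset_h) %% 24)
})

#' Mean PPFD per clock hour
#'
#' Discretises the regime onto the 24 clock-hour bins used for price joins:
#' entry `h` is the within-hour average PPFD over clock `[h, h + 1)`.  For
#' whole-hour schedules (all built-ins) the binning is lossless.
#'
#' @param regime A [LightRegime-class].
#' @return Named numeric length 24 (clock hours "0".."23"), umol m-2 s-1.
#' @export
hourlyPPFD <- function(regime) {
  stopifnot(is(regime, "LightRegime"))
  # raw integral in umol m-2 s-1 * h units over ZT [0, z]
  iv <- regime@intervals
  raw <- function(z) {
    covered <- pmin(pmax(z - iv$start_h, 0), iv$duration_h)
    sum(iv$ppfd * covered)
  }
  out <- vapply(0:23, function(h) {
    z0 <- (h - regime@startClock) %% 24
    z1 <- z0 + 1
    if (z1 <= 24) raw(z1) - raw(z0) else (raw(24) - raw(z0)) + raw(z1 - 24)
  }, numeric(1))
  names(out) <- as.character(0:23)
  out
}

#' Read and write lighting-regime JSON
#'
#' The JSON schema is a list of
#' `{name, start_clock: "HH:MM", intervals: [{start_h, duration_h, ppfd}]}`
#' objects.  The reader validates interval coverage via the class validity;
#' the writer round-trips numerically exactly (digits are not truncated).
#'
#' @param path File path.
#' @return `readRegimes()` a named list of [LightRegime-class];
#'   `writeRegimes()` invisibly `path`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeRegimes(builtinRegimes()[1:2], f)
#' readRegimes(f)
#' @export
readRegimes <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  regs <- lapply(raw, function(x) {
    sc <- x$start_clock
    if (is.list(sc)) sc <- sc[[1]]
    hm <- as.numeric(strsplit(as.character(sc), ":", fixed = TRUE)[[1]])
    iv <- x$intervals
    if (is.list(iv) && !is.data.frame(iv)) iv <- iv[[1]]
    nm <- x$name
    if (is.list(nm)) nm <- nm[[1]]
    lightRegime(nm, as.data.frame(iv), hm[1] + hm[2] / 60)
  })
  names(regs) <- vapply(regs, regimeName, character(1))
  regs
}

#' @rdname readRegimes
#' @param regimes Named list of [LightRegime-class] objects.
#' @export
writeRegimes <- function(regimes, path) {
  if (is(regimes, "LightRegime")) regimes <- list(regimes)
  out <- lapply(unname(regimes), function(r) {
    sc <- r@startClock
    list(name = r@name,
         start_clock = sprintf("%02d:%02d", floor(sc),
                               round((sc - floor(sc)) * 60)),
         intervals = r@intervals)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
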