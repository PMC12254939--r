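NULL

# Internal helper: validity messages accumulate into a character vector;
# TRUE means valid.
.collect <- function(msgs) if (length(msgs) == 0L) TRUE else msgs

#' LightRegime: a piecewise-constant 24-h PPFD schedule
#'
#' A lighting regime is an ordered set of contiguous intervals that jointly
#' cover one 24-h cycle in zeitgeber time (ZT; hours since photoperiod
#' onset), each with a constant photosynthetic photon flux density (PPFD,
#' umol m-2 s-1).  Dark periods are explicit intervals with `ppfd = 0`.
#' `startClock` anchors ZT 0 on the wall clock (hours, e.g. `6` for 06:00)
#' and is only consulted where the schedule is joined to clock-indexed
#' electricity prices.
#'
#' Intervals use the half-open convention `[start_h, start_h + duration_h)`.
#'
#' @slot name Character label.
#' @slot intervals A `data.frame` with columns `start_h`, `duration_h`,
#'   `ppfd`, ordered by `start_h`, covering `[0, 24)` without gaps or
#'   overlaps.
#' @slot startClock Clock time of ZT 0 in hours, in `[0, 24)`.
#'
#' @seealso [lightRegime()], [builtinRegimes()], [computeDLI()]
#' @aliases LightRegime
#' @exportClass LightRegime
setClass("LightRegime",
  representation(name = "character", intervals = "data.frame",
                 startClock = "numeric"),
  validity = function(object) {
    msg <- character()
    iv <- object@intervals
    need <- c("start_h", "duration_h", "ppfd")
    if (!all(need %in% names(iv))) {
      return(paste("intervals must have columns", paste(need, collapse = ", ")))
    }
    if (nrow(iv) == 0L) msg <- c(msg, "regime has no intervals")
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (length(object@startClock) != 1L || !is.finite(object@startClock) ||
        object@startClock < 0 || object@startClock >= 24) {
      msg <- c(msg, "startClock must be a single value in [0, 24)")
    }
    if (nrow(iv) > 0L) {
      if (any(!is.finite(iv$ppfd)) || any(iv$ppfd < 0)) {
        msg <- c(msg, "ppfd values must be finite and >= 0")
      }
      if (any(!is.finite(iv$duration_h)) || any(iv$duration_h <= 0)) {
        msg <- c(msg, "interval durations must be finite and > 0")
      }
      if (is.unsorted(iv$start_h, strictly = TRUE)) {
        msg <- c(msg, "interval start_h must be strictly increasing")
      }
      tol <- 1e-9
      if (abs(iv$start_h[1L]) > tol) {
        msg <- c(msg, "coverage error: first interval must start at ZT 0")
      }
      ends <- iv$start_h + iv$duration_h
      if (nrow(iv) > 1L &&
          any(abs(iv$start_h[-1L] - ends[-nrow(iv)]) > tol)) {
        msg <- c(msg, "coverage error: intervals must be contiguous (no gaps/overlaps)")
      }
      if (abs(ends[nrow(iv)] - 24) > tol) {
        msg <- c(msg, "coverage error: intervals must jointly cover [0, 24)")
      }
    }
    .collect(msg)
  })

#' DiurnalPriceProfile: mean spot price per clock hour
#'
#' Per-clock-hour arithmetic means of an hourly electricity spot-price
#' series over all days of one calendar year (eur/kWh).  This 24-point
#' profile is what drives hour ranking, regime costing and anchoring.
#'
#' @slot year Character year label.
#' @slot meanPrice Numeric length 24, named "0".."23" (clock hour).
#' @slot nDays Integer number of days averaged.
#'
#' @seealso [diurnalProfile()], [rankHours()], [dailyCost()]
#' @aliases DiurnalPriceProfile
#' @exportClass DiurnalPriceProfile
setClass("DiurnalPriceProfile",
  representation(year = "character", meanPrice = "numeric", nDays = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@meanPrice) != 24L) msg <- c(msg, "meanPrice must have 24 entries")
    if (any(!is.finite(object@meanPrice))) msg <- c(msg, "meanPrice must be finite")
    if (length(object@year) != 1L) msg <- c(msg, "year must be a single label")
    if (length(object@nDays) != 1L || object@nDays < 1L) {
      msg <- c(msg, "nDays must be a positive integer")
    }
    .collect(msg)
  })

#' PowerModel: electrical power drawn per unit PPFD
#'
#' Converts a PPFD target into luminaire power draw (W m-2).  Linear mode
#' divides PPFD by a constant photon efficacy (umol J-1; modern horticultural
#' LEDs are ~2.5-3 umol J-1 and output is close to proportional to drive
#' current).  Table mode linearly interpolates a measured dimming curve
#' (`ppfd` -> `watts_m2`), for luminaires whose draw departs from
#' proportionality; PPFD requests above the table range are an error, never
#' extrapolated.
#'
#' @slot mode `"linear"` or `"table"`.
#' @slot efficacy Photon efficacy, umol J-1 (linear mode).
#' @slot dimmingTable `data.frame` with columns `ppfd`, `watts_m2`
#'   (table mode), power nondecreasing in ppfd, power(0) = 0.
#'
#' @seealso [linearPowerModel()], [tablePowerModel()], [hourlyEnergy()]
#' @aliases PowerModel
#' @exportClass PowerModel
setClass("PowerModel",
  representation(mode = "character", efficacy = "numeric",
                 dimmingTable = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("linear", "table")) {
      msg <- c(msg, "mode must be 'linear' or 'table'")
    }
    if (object@mode == "linear" &&
        (length(object@efficacy) != 1L || !is.finite(object@efficacy) ||
         object@efficacy <= 0)) {
      msg <- c(msg, "efficacy must be a single positive number")
    }
    if (object@mode == "table") {
      dt <- object@dimmingTable
      if (!all(c("ppfd", "watts_m2") %in% names(dt)) || nrow(dt) < 2L) {
        msg <- c(msg, "dimmingTable needs >= 2 rows of (ppfd, watts_m2)")
      } else {
        if (is.unsorted(dt$ppfd, strictly = TRUE)) {
          msg <- c(msg, "dimmingTable ppfd must be strictly increasing")
        }
        if (is.unsorted(dt$watts_m2)) {
          msg <- c(msg, "dimmingTable power must be nondecreasing in ppfd")
        }
        if (dt$ppfd[1L] > 0 || abs(dt$watts_m2[1L]) > 1e-12) {
          msg <- c(msg, "dimmingTable must start at (0, 0)")
        }
      }
    }
    .collect(msg)
  })

#' PulseProtocol: a PAM quenching protocol
#'
#' Ordered actinic phases plus the schedule of saturating pulses used to read
#' fluorescence landmarks off a quenching trace.  Pulse windows are
#' `[time, time + pulseDuration]`; the first pulse (label `"Fm"`) must fall
#' in a dark phase, and `foWindow` is the pre-pulse dark span averaged for Fo.
#'
#' @slot name Protocol label.
#' @slot phases `data.frame` with columns `label`, `duration_s`,
#'   `actinic_ppfd`, in order from trace start.
#' @slot pulseTimes Numeric, strictly increasing seconds from trace start.
#' @slot pulseLabels Character labels, one per pulse; first is `"Fm"`.
#' @slot pulseDuration Saturating-pulse duration, seconds (0.8 s).
#' @slot pulsePPFD Saturating-pulse intensity, umol m-2 s-1.
#' @slot foWindow Numeric length 2: `[from, to]` seconds averaged for Fo.
#'
#' @seealso [smallQuenchingProtocol()], [largeQuenchingProtocol()],
#'   [landmarkValues()]
#' @aliases PulseProtocol
#' @exportClass PulseProtocol
setClass("PulseProtocol",
  representation(name = "character", phases = "data.frame",
                 pulseTimes = "numeric", pulseLabels = "character",
                 pulseDuration = "numeric", pulsePPFD = "numeric",
                 foWindow = "numeric"),
  validity = function(object) {
    msg <- character()
    ph <- object@phases
    if (!all(c("label", "duration_s", "actinic_ppfd") %in% names(ph)) ||
        nrow(ph) == 0L) {
      return("phases must have columns label, duration_s, actinic_ppfd")
    }
    if (any(ph$duration_s <= 0)) msg <- c(msg, "phase durations must be > 0")
    if (length(object@pulseTimes) != length(object@pulseLabels)) {
      msg <- c(msg, "pulseTimes and pulseLabels lengths differ")
    }
    if (length(object@pulseTimes) > 0L) {
      if (is.unsorted(object@pulseTimes, strictly = TRUE)) {
        msg <- c(msg, "pulse times must be strictly increasing")
      }
      span <- sum(ph$duration_s)
      if (any(object@pulseTimes < 0 | object@pulseTimes > span)) {
        msg <- c(msg, "pulse times must lie within the phase span")
      }
      if (anyDuplicated(object@pulseLabels)) {
        msg <- c(msg, "pulse labels must be unique")
      }
    }
    if (object@pulseDuration <= 0) msg <- c(msg, "pulseDuration must be > 0")
    if (length(object@foWindow) != 2L || object@foWindow[1L] < 0 ||
        diff(object@foWindow) <= 0) {
      msg <- c(msg, "foWindow must be an increasing [from, to] pair")
    }
    .collect(msg)
  })

#' QuenchingResult: fluorescence landmarks and derived parameters
#'
#' Container for the landmarks extracted from one quenching trace: the
#' dark-acclimated minimum (Fo) and maximum (Fm) fluorescence, the
#' light/dark-acclimated maxima Fm' at each labelled saturating pulse, the
#' maximum quantum efficiency of PSII photochemistry Fv/Fm = (Fm - Fo)/Fm,
#' and non-photochemical quenching NPQ = (Fm - Fm')/Fm' at each landmark.
#'
#' @slot fo,fm Numeric scalars, arbitrary fluorescence units.
#' @slot fmPrime Named numeric: Fm' per landmark label.
#' @slot fvFm Numeric scalar in `[0, 1)`.
#' @slot npq Named numeric: NPQ per landmark label.
#' @slot protocolName Protocol the landmarks came from.
#'
#' @seealso [runQuenchingProtocol()], [npqAt()]
#' @aliases QuenchingResult
#' @exportClass QuenchingResult
setClass("QuenchingResult",
  representation(fo = "numeric", fm = "numeric", fmPrime = "numeric",
                 fvFm = "numeric", npq = "numeric", protocolName = "character"),
  validity = function(object) {
    msg <- character()
    if (object@fm < object@fo) msg <- c(msg, "fm must be >= fo")
    if (!identical(names(object@fmPrime), names(object@npq))) {
      msg <- c(msg, "fmPrime and npq must share landmark names")
    }
    .collect(msg)
  })

#' RGBImage: a top-view RGB plant image with physical scale
#'
#' @slot pixels Numeric `H x W x 3` array, channels R, G, B on the 0-255
#'   scale.
#' @slot mmPerPx Physical size of one pixel edge, mm.
#'
#' @seealso [rgbImage()], [readRGBImage()], [segmentCanopy()]
#' @aliases RGBImage
#' @exportClass RGBImage
setClass("RGBImage",
  representation(pixels = "array", mmPerPx = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3L] != 3L || d[1L] < 1L || d[2L] < 1L) {
      msg <- c(msg, "pixels must be a nonempty H x W x 3 array")
    }
    if (any(object@pixels < 0 | object@pixels > 255, na.rm = TRUE)) {
      msg <- c(msg, "pixel values must lie in [0, 255]")
    }
    if (length(object@mmPerPx) != 1L || !is.finite(object@mmPerPx) ||
        object@mmPerPx <= 0) {
      msg <- c(msg, "mmPerPx must be a single positive number")
    }
    .collect(msg)
  })

#' CanopyMask: a boolean segmentation mask with provenance
#'
#' @slot mask Logical `H x W` matrix, `TRUE` on canopy pixels.
#' @slot provenance List recording the thresholding parameters used.
#'
#' @seealso [segmentCanopy()], [canopyArea()], [roundness()], [compactness()]
#' @aliases CanopyMask
#' @exportClass CanopyMask
setClass("CanopyMask",
  representation(mask = "matrix", provenance = "list"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be a logical matrix")
    TRUE
  })

#' CostReport: regime x year electricity costs and savings
#'
#' @slot table `data.frame` with columns `regime`, `year`, `cost_eur_m2`,
#'   `savings_pct`, `anchor_clock`, `is_baseline`, `is_dynamic`.
#' @slot baseline Baseline regime name.
#' @slot dynamicMeanSavings Mean savings (%) of the dynamic regime set
#'   across all years, or `NA` if no dynamic set was declared.
#'
#' @seealso [costReport()]
#' @aliases CostReport
#' @exportClass CostReport
setClass("CostReport",
  representation(table = "data.frame", baseline = "character",
                 dynamicMeanSavings = "numeric"))

#' FeatureTable: LC-MS features x samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `"intensity"` assay (features x samples, `NA` = missing), feature
#' metadata in `rowData` (`mz`, `rt_min`, `mode`) and sample metadata in
#' `colData` (`class`, `is_qc`).  Pooled QC injections carry
#' `is_qc = TRUE`; biological samples carry a `class` label
#' (regime x timepoint).
#'
#' @seealso [featureTable()], [readFeatureTable()], [filterFeatures()]
#' @aliases FeatureTable
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object)) {
      msg <- c(msg, "assay 'intensity' is required")
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("mz", "rt_min", "mode") %in% names(rd))) {
      msg <- c(msg, "rowData must have mz, rt_min, mode")
    } else if (any(!is.finite(rd$rt_min))) {
      msg <- c(msg, "rt_min must be finite")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("class", "is_qc") %in% names(cd))) {
      msg <- c(msg, "colData must have class, is_qc")
    }
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "intensities must be >= 0")
    .collect(msg)
  })
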