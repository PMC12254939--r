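# PAM chlorophyll-fluorescence quenching analysis: protocol encodings,
# landmark extraction, Fv/Fm, NPQ and partially relaxed NPQ.

#' Maximum quantum efficiency of PSII photochemistry
#'
#' `Fv/Fm = (Fm - Fo) / Fm`, from the dark-acclimated minimum (Fo) and
#' maximum (Fm) fluorescence.  Healthy leaves sit around 0.83-0.89.
#'
#' @param fo Minimum fluorescence, arbitrary units, `>= 0`.
#' @param fm Maximum fluorescence, arbitrary units, `> 0`.
#' @return Dimensionless value in `[0, 1)`.
#' @examples
#' fvFm(0.2, 1.0)  # 0.8
#' @export
fvFm <- function(fo, fm) {
  stopifnot(all(is.finite(fo)), all(is.finite(fm)))
  if (any(fm <= 0)) stop("fm must be > 0")
  if (any(fo < 0)) stop("fo must be >= 0")
  (fm - fo) / fm
}

#' Non-photochemical quenching
#'
#' `NPQ = (Fm - Fm') / Fm'`, from the dark-acclimated maximum fluorescence
#' Fm and the light-acclimated maximum Fm' at a saturating pulse.
#'
#' @param fm Dark-acclimated maximum fluorescence, `> 0`.
#' @param fm_prime Light-acclimated maximum fluorescence, `> 0`.
#' @return Dimensionless NPQ (vectorised over `fm_prime`).
#' @examples
#' npq(2, 1)  # 1
#' @export
npq <- function(fm, fm_prime) {
  stopifnot(all(is.finite(fm)), all(is.finite(fm_prime)))
  if (any(fm_prime <= 0)) stop("fm_prime must be > 0")
  (fm - fm_prime) / fm_prime
}

#' Construct a PulseProtocol
#'
#' @param name Protocol label.
#' @param phases `data.frame` with `label`, `duration_s`, `actinic_ppfd`.
#' @param pulseTimes Seconds from trace start, strictly increasing.
#' @param pulseLabels One label per pulse; the first must be `"Fm"`.
#' @param pulseDuration Saturating-pulse duration, s.
#' @param pulsePPFD Saturating-pulse intensity, umol m-2 s-1.
#' @param foWindow `[from, to]` seconds of dark trace averaged for Fo.
#' @return A [PulseProtocol-class].
#' @export
pulseProtocol <- function(name, phases, pulseTimes, pulseLabels,
                          pulseDuration = 0.8, pulsePPFD = 3000,
                          foWindow = c(0, pulseTimes[1] - pulseDuration)) {
  new("PulseProtocol", name = name, phases = as.data.frame(phases),
      pulseTimes = as.numeric(pulseTimes),
      pulseLabels = as.character(pulseLabels),
      pulseDuration = as.numeric(pulseDuration),
      pulsePPFD = as.numeric(pulsePPFD), foWindow = as.numeric(foWindow))
}

#' The two bundled quenching protocols
#'
#' `smallQuenchingProtocol()` is a classic three-phase quenching routine:
#' 21.7 s initial dark (Fm pulse at 5.06 s, Fo averaged over the pre-pulse
#' window 0-4.5 s), 70 s actinic light at 155 umol m-2 s-1 with saturating
#' pulses at 31.7, 41.7, 51.7, 71.7 and 91.7 s reading landmarks L1-L4 and
#' Lss, then 100 s dark relaxation with pulses at 121.7, 181.7 and 191.7 s
#' (D1-D3).  Saturating pulses are 800 ms at 1085 umol m-2 s-1.
#'
#' `largeQuenchingProtocol()` models a whole-plant imaging routine run
#' after dark acclimation: a 9-min high-light period at 800 umol m-2 s-1,
#' a 27-min dark relaxation, then a light ramp of 3-min steps at 100, 200,
#' 300, 600, 800, 1000 and 1200 umol m-2 s-1, with 800 ms saturating pulses
#' at ~3000 umol m-2 s-1 every 3 min throughout.  The instrument's exact
#' Fo/Fm acquisition timing is not published, so this encoding opens with a
#' 6-min dark phase whose Fm pulse fires at 180 s (Fo window 0-150 s); the
#' 3-min pulse grid then puts one pulse exactly 9 min into the dark
#' relaxation, the landmark used for partially relaxed NPQ.  Dark-phase
#' pulses are labelled `D1..D9`, high-light pulses `HL1..HL3`, ramp pulses
#' `R1..R7`.
#'
#' @return A [PulseProtocol-class].
#' @examples
#' smallQuenchingProtocol()
#' @export
smallQuenchingProtocol <- function() {
  pulseProtocol(
    name = "small-quenching",
    phases = data.frame(
      label = c("dark", "actinic", "relax"),
      duration_s = c(21.7, 70, 100),
      actinic_ppfd = c(0, 155, 0)),
    pulseTimes = c(5.06, 31.7, 41.7, 51.7, 71.7, 91.7, 121.7, 181.7, 191.7),
    pulseLabels = c("Fm", "L1", "L2", "L3", "L4", "Lss", "D1", "D2", "D3"),
    pulseDuration = 0.8, pulsePPFD = 1085, foWindow = c(0, 4.5))
}

#' @rdname smallQuenchingProtocol
#' @export
largeQuenchingProtocol <- function() {
  ramp <- c(100, 200, 300, 600, 800, 1000, 1200)
  pulseProtocol(
    name = "large-quenching",
    phases = data.frame(
      label = c("dark", "highlight", "relax", paste0("ramp", ramp)),
      duration_s = c(360, 540, 1620, rep(180, 7)),
      actinic_ppfd = c(0, 800, 0, ramp)),
    pulseTimes = 180 * (1:20),
    pulseLabels = c("Fm", paste0("HL", 1:3), paste0("D", 1:9),
                    paste0("R", 1:7)),
    pulseDuration = 0.8, pulsePPFD = 3000, foWindow = c(0, 150))
}

setMethod("show", "PulseProtocol", function(object) {
  cat(sprintf("PulseProtocol \"%s\": %d phases spanning %.1f s, %d pulses (%g ms at %g umol m-2 s-1)\n",
              object@name, nrow(object@phases), sum(object@phases$duration_s),
              length(object@pulseTimes), 1000 * object@pulseDuration,
              object@pulsePPFD))
  ph <- object@phases
  t0 <- cumsum(c(0, ph$duration_s[-nrow(ph)]))
  for (i in seq_len(nrow(ph))) {
    cat(sprintf("  %-10s %7.1f-%7.1f s  actinic %g\n", ph$label[i], t0[i],
                t0[i] + ph$duration_s[i], ph$actinic_ppfd[i]))
  }
})

#' Actinic PPFD at protocol time
#'
#' Step function over phases (half-open `[start, end)` convention).
#'
#' @param protocol A [PulseProtocol-class].
#' @param t Seconds from trace start (vectorised).
#' @return Actinic PPFD at `t` (0 beyond the span).
#' @export
actinicAt <- function(protocol, t) {
  ph <- protocol@phases
  starts <- cumsum(c(0, ph$duration_s[-nrow(ph)]))
  idx <- findInterval(t, c(starts, sum(ph$duration_s)),
                      rightmost.closed = FALSE)
  out <- rep(0, length(t))
  ok <- idx >= 1L & idx <= nrow(ph)
  out[ok] <- ph$actinic_ppfd[idx[ok]]
  out
}

#' Read and write quenching protocols as JSON
#'
#' Schema: `{name, phases: [{label, duration_s, actinic_ppfd}],
#' pulse_times_s, pulse_labels, pulse_duration_s, pulse_ppfd, fo_window_s}`.
#' Copies of the two bundled protocols live in
#' `system.file("extdata", package = "cealux")`.
#'
#' @param path JSON path.
#' @return `readPulseProtocol()` a [PulseProtocol-class]; the writer
#'   invisibly `path`.
#' @export
readPulseProtocol <- function(path) {
  x <- jsonlite::fromJSON(path)
  pulseProtocol(x$name, as.data.frame(x$phases), x$pulse_times_s,
                x$pulse_labels, x$pulse_duration_s, x$pulse_ppfd,
                x$fo_window_s)
}

#' @rdname readPulseProtocol
#' @param protocol A [PulseProtocol-class].
#' @export
writePulseProtocol <- function(protocol, path) {
  jsonlite::write_json(
    list(name = protocol@name, phases = protocol@phases,
         pulse_times_s = protocol@pulseTimes,
         pulse_labels = protocol@pulseLabels,
         pulse_duration_s = protocol@pulseDuration,
         pulse_ppfd = protocol@pulsePPFD,
         fo_window_s = protocol@foWindow),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fluorescence trace CSV
#'
#' Columns `time_s` and `f` (arbitrary units), optional `actinic_ppfd`.
#'
#' @param path CSV path.
#' @return `data.frame` sorted by `time_s`.
#' @export
readTrace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "f") %in% names(d)))
  d[order(d$time_s), , drop = FALSE]
}

.checkTrace <- function(trace) {
  stopifnot(all(c("time_s", "f") %in% names(trace)))
  if (nrow(trace) < 2L) stop("trace needs >= 2 samples")
  if (is.unsorted(trace$time_s)) stop("trace time_s must be nondecreasing")
  if (any(trace$f < 0)) stop("trace contains negative fluorescence")
  invisible(trace)
}

#' Extract fluorescence landmarks from a trace
#'
#' For every labelled saturating pulse, Fm' is estimated within the pulse
#' window `[time, time + pulseDuration]`: by default the window maximum
#' (robust to sampling phase); `estimator = "median3"` takes the median of
#' the three largest samples, trading a little plateau fidelity for noise
#' robustness.  Fm is the value at the first (dark-phase) pulse; Fo is the
#' mean of the pre-pulse dark window.
#'
#' @param trace `data.frame` with `time_s`, `f`.
#' @param protocol A [PulseProtocol-class] the trace must span.
#' @param estimator `"max"` (default) or `"median3"`.
#' @return Named numeric: `Fo`, then one value per pulse label.
#' @export
landmarkValues <- function(trace, protocol, estimator = c("max", "median3")) {
  estimator <- match.arg(estimator)
  .checkTrace(trace)
  stopifnot(is(protocol, "PulseProtocol"))
  tmax <- max(trace$time_s)
  need <- max(protocol@pulseTimes) + protocol@pulseDuration
  if (tmax < need - 1e-9) {
    stop("resolution error: trace ends at ", signif(tmax, 6),
         " s but protocol needs ", signif(need, 6), " s")
  }
  inFo <- trace$time_s >= protocol@foWindow[1] &
    trace$time_s <= protocol@foWindow[2]
  if (!any(inFo)) stop("resolution error: no samples in the Fo window")
  fo <- mean(trace$f[inFo])
  vals <- vapply(protocol@pulseTimes, function(tp) {
    w <- trace$f[trace$time_s >= tp &
                   trace$time_s <= tp + protocol@pulseDuration]
    if (length(w) == 0L) {
      stop("resolution error: no samples in pulse window at ", tp, " s")
    }
    if (estimator == "max") max(w)
    else stats::median(sort(w, decreasing = TRUE)[seq_len(min(3L, length(w)))])
  }, numeric(1))
  names(vals) <- protocol@pulseLabels
  c(Fo = fo, vals)
}

#' Run a full quenching analysis on one trace
#'
#' Assembles Fo, Fm and every Fm' landmark via [landmarkValues()], then
#' derives `Fv/Fm` and the NPQ series `(Fm - Fm')/Fm'` at every landmark.
#'
#' @inheritParams landmarkValues
#' @return A [QuenchingResult-class].
#' @examples
#' pro <- smallQuenchingProtocol()
#' tr <- genQuenchingTrace(pro, npqSS = 1.5, seed = 1)$trace
#' runQuenchingProtocol(tr, pro)
#' @export
runQuenchingProtocol <- function(trace, protocol,
                                 estimator = c("max", "median3")) {
  lm <- landmarkValues(trace, protocol, match.arg(estimator))
  fo <- lm[["Fo"]]
  fm <- lm[["Fm"]]
  fmp <- lm[setdiff(names(lm), c("Fo", "Fm"))]
  new("QuenchingResult", fo = fo, fm = fm, fmPrime = fmp,
      fvFm = fvFm(fo, fm), npq = npq(fm, fmp),
      protocolName = protocol@name)
}

#' Accessors for QuenchingResult
#'
#' @param x A [QuenchingResult-class].
#' @param label Landmark label(s); default all.
#' @return `npqAt()` NPQ at the requested landmark(s); `fmPrimeAt()` the
#'   Fm' values; `fvFmOf()` the scalar Fv/Fm.
#' @export
npqAt <- function(x, label = NULL) {
  if (is.null(label)) x@npq else x@npq[label]
}

#' @rdname npqAt
#' @export
fmPrimeAt <- function(x, label = NULL) {
  if (is.null(label)) x@fmPrime else x@fmPrime[label]
}

#' @rdname npqAt
#' @export
fvFmOf <- function(x) x@fvFm

setMethod("show", "QuenchingResult", function(object) {
  cat(sprintf("QuenchingResult (%s): Fo %.3f, Fm %.3f, Fv/Fm %.3f\n",
              object@protocolName, object@fo, object@fm, object@fvFm))
  cat("  NPQ:", paste(sprintf("%s %.3f", names(object@npq), object@npq),
                      collapse = ", "), "\n")
})

# Start time of the dark-relaxation phase: the first actinic-off phase that
# follows an actinic-on phase.
.relaxOnset <- function(protocol) {
  ph <- protocol@phases
  starts <- cumsum(c(0, ph$duration_s[-nrow(ph)]))
  lit <- ph$actinic_ppfd > 0
  for (i in seq_len(nrow(ph))[-1]) {
    if (!lit[i] && lit[i - 1L]) return(starts[i])
  }
  stop("protocol mismatch error: no dark relaxation phase after light")
}

#' Partially relaxed NPQ
#'
#' NPQ evaluated at the saturating pulse nearest to 9 min after the onset of
#' dark relaxation following a high-light period — a fixed waypoint on the
#' relaxation curve that separates fast (energy-dependent) from slowly
#' reversible quenching.  With pulses on a 3-min grid a conforming trace
#' has a pulse exactly at the 9-min mark; traces with no pulse within
#' 90 s of it are refused.
#'
#' @inheritParams landmarkValues
#' @return NPQ (dimensionless) at the matched pulse.
#' @export
partiallyRelaxedNPQ <- function(trace, protocol,
                                estimator = c("max", "median3")) {
  target <- .relaxOnset(protocol) + 9 * 60
  d <- abs(protocol@pulseTimes - target)
  if (min(d) > 90) {
    stop("protocol mismatch error: no saturating pulse within 90 s of ",
         "9 min into dark relaxation (t = ", target, " s)")
  }
  label <- protocol@pulseLabels[which.min(d)]
  res <- runQuenchingProtocol(trace, protocol, match.arg(estimator))
  unname(npqAt(res, label))
}
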