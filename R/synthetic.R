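# Seeded synthetic-data generators.  Each is a pure function of its
# parameters and seed (RNG state is scoped with withr::with_seed, so adding
# one generator call never perturbs another), and each emits machine-readable
# ground truth enabling closed-loop recovery tests in its consuming module.

#' Closed-form diurnal price pattern
#'
#' The noise-free expected profile of [genPriceSeries()]: `base` everywhere,
#' `base + amplitude` over the peak hours and `base - amplitude` over the
#' trough hours.
#'
#' @param base Baseline price, eur/kWh.
#' @param peakAmplitude Symmetric peak/trough amplitude, eur/kWh.
#' @param peakHours Clock hours of the two demand peaks (default 08-11 and
#'   17-20).
#' @param troughHours Clock hours of the night trough (default 23-05).
#' @return Named numeric length 24.
#' @export
diurnalPattern <- function(base = 0.08, peakAmplitude = 0.04,
                           peakHours = c(8:10, 17:19),
                           troughHours = c(23, 0:4)) {
  p <- rep(base, 24)
  p[peakHours + 1] <- base + peakAmplitude
  p[troughHours + 1] <- base - peakAmplitude
  names(p) <- as.character(0:23)
  p
}

#' Generate a synthetic hourly spot-price series
#'
#' Emulates the repeating diurnal structure of a day-ahead electricity
#' market: a double-peaked daytime pattern (morning and early-evening
#' peaks) with a cheap night trough, i.i.d. Gaussian hour-to-hour noise and
#' a per-year scale factor capturing annual price-level shifts.  Prices may
#' go negative under noise; they are kept as generated (day-ahead markets
#' print negative prices).
#'
#' @inheritParams diurnalPattern
#' @param years Calendar years to generate (hourly, full years).
#' @param noiseSD I.i.d. Gaussian noise sd per hour, eur/kWh.
#' @param yearScale Named multipliers per year; years not named get 1.
#'   The default spread mimics the 2020-2023 European price-level swing.
#' @param seed Integer seed; same seed, same series.
#' @return `data.frame` with `timestamp` (POSIXct UTC) and
#'   `price_eur_kwh`.
#' @examples
#' s <- genPriceSeries(years = 2020, seed = 1)
#' diurnalProfile(s, 2020)
#' @export
genPriceSeries <- function(years = 2020:2023, base = 0.08,
                           peakAmplitude = 0.04,
                           peakHours = c(8:10, 17:19),
                           troughHours = c(23, 0:4), noiseSD = 0.02,
                           yearScale = c("2020" = 0.45, "2021" = 1,
                                         "2022" = 2.2, "2023" = 0.8),
                           seed = 1) {
  pattern <- diurnalPattern(base, peakAmplitude, peakHours, troughHours)
  withr::with_seed(seed, {
    out <- lapply(years, function(yr) {
      t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", yr), tz = "UTC")
      t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00", yr), tz = "UTC")
      ts <- seq(t0, t1, by = 3600)
      hour <- as.integer(format(ts, "%H"))
      sc <- if (as.character(yr) %in% names(yearScale)) {
        yearScale[[as.character(yr)]]
      } else 1
      data.frame(timestamp = ts,
                 price_eur_kwh = sc * (pattern[hour + 1] +
                                         stats::rnorm(length(ts), 0, noiseSD)))
    })
    do.call(rbind, out)
  })
}

# NPQ(t) under two-state kinetics: relaxes toward npqSS at rate kInd while
# actinic light is on, decays at rate kRel in darkness.  Vectorised over t;
# phases are walked once to get the boundary values.
.npqKinetics <- function(protocol, t, npqSS, kInd, kRel) {
  ph <- protocol@phases
  starts <- cumsum(c(0, ph$duration_s[-nrow(ph)]))
  n0 <- numeric(nrow(ph))
  cur <- 0
  for (i in seq_len(nrow(ph))) {
    n0[i] <- cur
    d <- ph$duration_s[i]
    cur <- if (ph$actinic_ppfd[i] > 0) {
      npqSS + (cur - npqSS) * exp(-kInd * d)
    } else cur * exp(-kRel * d)
  }
  idx <- pmin(findInterval(t, starts), nrow(ph))
  dt <- t - starts[idx]
  lit <- ph$actinic_ppfd[idx] > 0
  out <- numeric(length(t))
  out[lit] <- npqSS + (n0[idx[lit]] - npqSS) * exp(-kInd * dt[lit])
  out[!lit] <- n0[idx[!lit]] * exp(-kRel * dt[!lit])
  out
}

#' Generate a synthetic quenching trace
#'
#' Simulates a PAM fluorescence trace under a [PulseProtocol-class] using
#' deliberately simple single-pool NPQ kinetics: NPQ relaxes toward the
#' steady state `npqSS` at rate `kInd` under actinic light and decays at
#' rate `kRel` in darkness; the light-acclimated maximum is
#' `Fm'(t) = fm / (1 + NPQ(t))`.  Between pulses the fluorescence sits at a
#' steady-state level below Fm' (at `fo` in darkness); during each 800-ms
#' saturating pulse it rises to Fm'(t).  Gaussian noise is added on top.
#' The generator's purpose is closed-loop recoverability of the derived
#' parameters, not photophysical realism.
#'
#' @param protocol A [PulseProtocol-class].
#' @param fo,fm Dark-acclimated minimum/maximum fluorescence, a.u.
#'   (`fm > fo > 0`); defaults give Fv/Fm = 0.86.
#' @param npqSS Steady-state NPQ under actinic light.
#' @param kInd Induction rate under light, s-1.
#' @param kRel Dark relaxation rate, s-1 (default half-time 5 min).
#' @param noiseSD Gaussian noise sd, a.u.  The default reflects per-plant
#'   aggregate traces (ROI means over thousands of pixels), which are very
#'   smooth; single-pixel traces would be far noisier.
#' @param samplingHz Sampling rate, Hz.
#' @param seed Integer seed.
#' @return List with `trace` (`data.frame`: `time_s`, `f`, `actinic_ppfd`)
#'   and `truth`: the generating parameters plus `fvFm`, the true NPQ at
#'   every pulse label (`npqAtPulse`), and `partiallyRelaxed` (true NPQ at
#'   the pulse 9 min into dark relaxation, `NA` if the protocol has none).
#' @export
genQuenchingTrace <- function(protocol, fo = 0.42, fm = 3, npqSS = 1.5,
                              kInd = 0.08, kRel = log(2) / 300,
                              noiseSD = 0.005, samplingHz = 10, seed = 1) {
  stopifnot(is(protocol, "PulseProtocol"), fm > fo, fo > 0,
            kInd > 0, kRel > 0, npqSS >= 0)
  span <- max(sum(protocol@phases$duration_s),
              max(protocol@pulseTimes) + protocol@pulseDuration)
  t <- seq(0, span, by = 1 / samplingHz)
  npqT <- .npqKinetics(protocol, t, npqSS, kInd, kRel)
  fmPrime <- fm / (1 + npqT)
  actinic <- actinicAt(protocol, t)
  f <- ifelse(actinic > 0, fo + 0.4 * (fmPrime - fo), fo)
  inPulse <- rep(FALSE, length(t))
  for (tp in protocol@pulseTimes) {
    inPulse <- inPulse | (t >= tp & t <= tp + protocol@pulseDuration)
  }
  f[inPulse] <- fmPrime[inPulse]
  f <- withr::with_seed(seed, pmax(f + stats::rnorm(length(t), 0, noiseSD), 0))
  npqPulse <- .npqKinetics(protocol, protocol@pulseTimes, npqSS, kInd, kRel)
  names(npqPulse) <- protocol@pulseLabels
  pr <- tryCatch({
    target <- .relaxOnset(protocol) + 540
    d <- abs(protocol@pulseTimes - target)
    if (min(d) > 90) NA_real_ else unname(npqPulse[which.min(d)])
  }, error = function(e) NA_real_)
  list(trace = data.frame(time_s = t, f = f, actinic_ppfd = actinic),
       truth = list(fo = fo, fm = fm, fvFm = (fm - fo) / fm, npqSS = npqSS,
                    kInd = kInd, kRel = kRel, npqAtPulse = npqPulse,
                    partiallyRelaxed = pr))
}

# Rasterise one rosette: union of leafCount ellipses radiating from the
# image centre.  Returns the logical mask.
.drawRosette <- function(targetAreaPx, angles, widths, H, W) {
  L <- sqrt(targetAreaPx / 2.2)
  if (1.05 * L > min(H, W) / 2 - 2) {
    stop("frame-overflow error: rosette (extent ", round(2.1 * L),
         " px) exceeds the ", H, " x ", W, " frame")
  }
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  x <- matrix(rep(seq_len(W), each = H), H, W) - cx
  y <- matrix(rep(seq_len(H), times = W), H, W) - cy
  mask <- matrix(FALSE, H, W)
  a <- 0.55 * L
  for (i in seq_along(angles)) {
    th <- angles[i]
    b <- 0.30 * L * widths[i]
    ox <- 0.5 * L * cos(th); oy <- 0.5 * L * sin(th)
    u <- (x - ox) * cos(th) + (y - oy) * sin(th)
    v <- -(x - ox) * sin(th) + (y - oy) * cos(th)
    mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
  }
  mask
}

#' Generate a growing-rosette image series
#'
#' Renders top-view images of exponentially expanding green rosettes on a
#' brown background.  Plant `p` at day `t` targets a canopy area
#' `A0 * exp(growthRate * t) * u_p * e_pt`, with a per-plant lognormal size
#' factor `u_p` (the plant's leaf geometry is fixed across days, so each
#' plant's own expansion is exactly exponential) and optional per-
#' observation jitter `e_pt`.  The emitted ground truth is the actual
#' rasterised pixel count of each mask, so segmentation recovery can be
#' checked exactly.
#'
#' @param days Numeric vector of imaging days (relative, day 0 first).
#' @param nPlants Number of plants.
#' @param initialAreaPx Target canopy area at day 0, pixels.
#' @param growthRate Relative expansion rate, day-1.
#' @param leafCount Leaves per rosette.
#' @param plantSdlog Lognormal sd of the per-plant size factor.
#' @param obsSdlog Lognormal sd of per-observation area jitter.
#' @param noiseSD Pixel colour noise sd (0-255 scale); 0 gives flat
#'   colours and exact segmentation.
#' @param imageSize Square frame edge, px.
#' @param mmPerPx Physical pixel size, mm.
#' @param seed Integer seed; same seed, byte-identical images.
#' @return List with `images` (named list of [RGBImage-class],
#'   `"p<plant>_d<day>"`) and `truth` (`data.frame`: `plant_id`, `day`,
#'   `target_area_px`, `true_area_px`).
#' @export
genRosetteSeries <- function(days = c(0, 4, 8, 12, 16), nPlants = 1,
                             initialAreaPx = 1500, growthRate = 0.12,
                             leafCount = 8, plantSdlog = 0.1, obsSdlog = 0,
                             noiseSD = 0, imageSize = 200, mmPerPx = 0.5,
                             seed = 1) {
  H <- W <- imageSize
  leafGreen <- c(60, 140, 50); bg <- c(120, 90, 60)
  withr::with_seed(seed, {
    images <- list(); rows <- list()
    for (p in seq_len(nPlants)) {
      u <- exp(stats::rnorm(1, 0, plantSdlog))
      angles <- 2 * pi * (seq_len(leafCount) - 1) / leafCount +
        stats::runif(leafCount, -0.15, 0.15)
      widths <- stats::runif(leafCount, 0.85, 1.15)
      for (d in days) {
        target <- initialAreaPx * exp(growthRate * d) * u *
          exp(stats::rnorm(1, 0, obsSdlog))
        mask <- .drawRosette(target, angles, widths, H, W)
        px <- array(0, c(H, W, 3))
        for (ch in 1:3) {
          layer <- matrix(bg[ch], H, W)
          layer[mask] <- leafGreen[ch]
          if (noiseSD > 0) layer <- layer + stats::rnorm(H * W, 0, noiseSD)
          px[, , ch] <- pmin(pmax(layer, 0), 255)
        }
        nm <- sprintf("p%d_d%g", p, d)
        images[[nm]] <- rgbImage(px, mmPerPx)
        rows[[nm]] <- data.frame(plant_id = sprintf("p%d", p), day = d,
                                 target_area_px = target,
                                 true_area_px = sum(mask))
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(images = images, truth = truth)
  })
}

# Deterministic mean concentration trajectory: the excess over baseline
# grows with cumulative DLI in light and decays exponentially in darkness;
# the trajectory starts at its 24-h periodic fixed point so consecutive
# days repeat.
.carbMean <- function(regime, zt, coeff, decay, baseline) {
  iv <- regime@intervals
  run <- function(e0, z) {
    e <- e0
    for (i in seq_len(nrow(iv))) {
      s <- iv$start_h[i]; d <- iv$duration_h[i]
      if (z <= s) break
      dt <- min(z - s, d)
      if (iv$ppfd[i] > 0) {
        e <- e + coeff * iv$ppfd[i] * dt * 3600 / 1e6
      } else {
        e <- e * exp(-decay * dt)
      }
    }
    e
  }
  beta <- run(0, 24)
  alpha <- run(1, 24) - beta
  e0 <- if (alpha < 1) beta / (1 - alpha) else 0
  baseline + vapply(zt, function(z) run(e0, z), numeric(1))
}

#' Generate a diel carbohydrate series
#'
#' Concentrations accumulate in proportion to the regime's cumulative DLI
#' while the lights are on and decay exponentially through dark hours
#' (starting each day at the 24-h periodic steady state), with lognormal
#' replicate scatter of a stated CV.  Defaults approximate diel
#' sucrose/starch dynamics in lettuce leaves at DLI ~10 mol m-2.
#'
#' @param regime A [LightRegime-class].
#' @param zt ZT sampling times, hours.
#' @param analytes Analyte names; must index `baseline` and
#'   `accumulationCoeff`.
#' @param baseline Named baseline concentrations, umol g-1 FW.
#' @param accumulationCoeff Named accumulation per unit cumulative DLI,
#'   umol g-1 FW per mol m-2.
#' @param darkDecayRate Dark decay rate of the accumulated excess, h-1.
#' @param replicateCV Replicate coefficient of variation (lognormal).
#' @param nRep Replicates per timepoint.
#' @param seed Integer seed.
#' @return List with `series` (`data.frame`: `regime`, `zt_h`, `analyte`,
#'   `conc_umol_gFW`, `rep`) and `truth` (`data.frame` of the deterministic
#'   mean curve per analyte and timepoint, plus the generator parameters as
#'   attributes).
#' @export
genCarbSeries <- function(regime, zt = c(0, 6, 12, 18),
                          analytes = c("sucrose", "starch"),
                          baseline = c(sucrose = 2, starch = 1),
                          accumulationCoeff = c(sucrose = 0.7, starch = 0.8),
                          darkDecayRate = 0.15, replicateCV = 0.15,
                          nRep = 3, seed = 1) {
  stopifnot(is(regime, "LightRegime"),
            all(analytes %in% names(baseline)),
            all(analytes %in% names(accumulationCoeff)))
  sdlog <- sqrt(log(1 + replicateCV^2))
  truth <- do.call(rbind, lapply(analytes, function(an) {
    data.frame(regime = regime@name, zt_h = zt, analyte = an,
               mean_conc = .carbMean(regime, zt, accumulationCoeff[[an]],
                                     darkDecayRate, baseline[[an]]))
  }))
  series <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      data.frame(regime = truth$regime[i], zt_h = truth$zt_h[i],
                 analyte = truth$analyte[i],
                 conc_umol_gFW = truth$mean_conc[i] *
                   exp(stats::rnorm(nRep, 0, sdlog)),
                 rep = seq_len(nRep))
    }))
  })
  attr(truth, "replicateCV") <- replicateCV
  attr(truth, "sdlog") <- sdlog
  list(series = series, truth = truth)
}

#' Generate a synthetic LC-MS feature table with known rule violators
#'
#' Builds a log-normal-intensity feature table in which a controlled number
#' of features are constructed to violate exactly one filtering rule each
#' (and to pass every rule applied before it), so [filterFeatures()] can be
#' checked against exact ground truth.  By default there is no class
#' effect: biological classes share one intensity distribution, the null
#' model under which a PCA projection shows no class separation.
#'
#' @param nFeatures Total feature count.
#' @param classes Biological class labels.
#' @param nSamplesPerClass Samples per class.
#' @param qcN Pooled-QC injection count.
#' @param missingRate Background missingness rate in biological samples of
#'   clean features (capped so clean features keep >= 2/3 presence in at
#'   least one class).
#' @param fracRT,fracIntensity,fracRSD,fracPresence Fractions of features
#'   constructed to violate the retention-time, intensity-floor, QC-RSD and
#'   class-presence rules respectively.
#' @param classEffect Lognormal sd of a per-class intensity shift; 0
#'   (default) is the null model.
#' @param seed Integer seed.
#' @return List with `table` (a [FeatureTable-class]) and `truth`
#'   (`data.frame`: `feature_id`, `violates` in `none`/`retention_time`/
#'   `min_intensity`/`qc_rsd`/`class_presence`).
#' @export
genFeatureTable <- function(nFeatures = 200, classes = c("A", "B", "C"),
                            nSamplesPerClass = 6, qcN = 5,
                            missingRate = 0.1, fracRT = 0.1,
                            fracIntensity = 0.05, fracRSD = 0.05,
                            fracPresence = 0.1, classEffect = 0, seed = 1) {
  nv <- c(retention_time = floor(fracRT * nFeatures),
          min_intensity = floor(fracIntensity * nFeatures),
          qc_rsd = floor(fracRSD * nFeatures),
          class_presence = floor(fracPresence * nFeatures))
  stopifnot(sum(nv) <= nFeatures)
  nBio <- length(classes) * nSamplesPerClass
  sampleId <- c(unlist(lapply(classes, function(cl) {
    paste0(cl, "_", seq_len(nSamplesPerClass))
  })), paste0("QC_", seq_len(qcN)))
  cls <- c(rep(classes, each = nSamplesPerClass), rep("QC", qcN))
  isQC <- c(rep(FALSE, nBio), rep(TRUE, qcN))
  withr::with_seed(seed, {
    violates <- sample(c(rep(names(nv), nv),
                         rep("none", nFeatures - sum(nv))))
    fid <- sprintf("F%04d", seq_len(nFeatures))
    rt <- stats::runif(nFeatures, 0.5, 3.9)
    isRT <- violates == "retention_time"
    rt[isRT] <- ifelse(stats::runif(sum(isRT)) < 0.5,
                       stats::runif(sum(isRT), 0.05, 0.35),
                       stats::runif(sum(isRT), 4.05, 5.5))
    base <- stats::rlnorm(nFeatures, log(1000), 0.8)
    m <- matrix(NA_real_, nFeatures, nBio + qcN,
                dimnames = list(fid, sampleId))
    classShift <- matrix(exp(stats::rnorm(nFeatures * length(classes), 0,
                                          classEffect)),
                         nFeatures, length(classes))
    for (j in seq_len(nBio)) {
      k <- match(cls[j], classes)
      m[, j] <- base * classShift[, k] * stats::rlnorm(nFeatures, 0, 0.3)
    }
    for (j in nBio + seq_len(qcN)) m[, j] <- base * stats::rlnorm(nFeatures, 0, 0.15)
    # QC-RSD violators: fixed dispersed QC pattern with guaranteed RSD > 150%
    isRSD <- violates == "qc_rsd"
    if (any(isRSD) && qcN >= 2) {
      mult <- c(rep(0.1, qcN - 1), 4)
      m[isRSD, nBio + seq_len(qcN)] <- outer(base[isRSD], mult)
    }
    # intensity violators: every sample below the floor
    isInt <- violates == "min_intensity"
    if (any(isInt)) {
      rowMax <- apply(m[isInt, , drop = FALSE], 1, max)
      m[isInt, ] <- m[isInt, , drop = FALSE] / rowMax *
        stats::runif(sum(isInt), 1, 8)
    }
    # background missingness on clean biological cells, capped per class
    maxMissOK <- floor(nSamplesPerClass / 3)
    for (i in which(violates %in% c("none", "retention_time"))) {
      for (k in seq_along(classes)) {
        ix <- which(cls == classes[k])
        miss <- ix[stats::runif(nSamplesPerClass) < missingRate]
        if (length(miss) > maxMissOK) miss <- miss[seq_len(maxMissOK)]
        m[i, miss] <- NA_real_
      }
    }
    # presence violators: strictly fewer than 2/3 present in every class
    isPres <- violates == "class_presence"
    nPresent <- ceiling(2 * nSamplesPerClass / 3) - 1L
    for (i in which(isPres)) {
      for (k in seq_along(classes)) {
        ix <- which(cls == classes[k])
        m[i, sample(ix, nSamplesPerClass - nPresent)] <- NA_real_
      }
    }
    rd <- data.frame(mz = stats::runif(nFeatures, 100, 900), rt_min = rt,
                     mode = sample(c("pos", "neg"), nFeatures, TRUE),
                     row.names = fid)
    cd <- data.frame(class = cls, is_qc = isQC, row.names = sampleId)
    list(table = featureTable(m, rd, cd),
         truth = data.frame(feature_id = fid, violates = violates))
  })
}
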