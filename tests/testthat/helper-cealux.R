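# Shared builders for the test suite.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Profile with explicit per-hour means (recycled), bypassing a price series.
makeProfile <- function(prices, year = "2020") {
  mp <- rep_len(prices, 24)
  names(mp) <- as.character(0:23)
  new("DiurnalPriceProfile", year = year, meanPrice = mp, nDays = 1L)
}

# The noise-free double-peaked day pattern as a profile object.
patternProfile <- function(...) makeProfile(diurnalPattern(...))

# An 18-h constant regime at a given clock anchor.
constant18 <- function(ppfd = 196, startClock = 5, name = "const18") {
  lightRegime(name, data.frame(start_h = c(0, 18), duration_h = c(18, 6),
                               ppfd = c(ppfd, 0)), startClock)
}

# Independent brute-force cost: rotate the 24-h ppfd pattern over all 24
# anchors using plain vector arithmetic (no shiftScan machinery).
bruteForceBestAnchor <- function(regime, profile, efficacy = 2.5) {
  base <- hourlyPPFD(lightRegime("x", regimeIntervals(regime), 0))
  prices <- meanPrice(profile)
  costs <- vapply(0:23, function(h) {
    ppfd <- base[((0:23 - h) %% 24) + 1]
    sum(ppfd / efficacy / 1000 * prices)
  }, numeric(1))
  list(start_hour = which.min(costs) - 1L, cost = min(costs), costs = costs)
}

# Tiny flat-colour image builder.
flatImage <- function(rgb, h = 4, w = 4, mmPerPx = 1) {
  px <- array(0, c(h, w, 3))
  for (i in 1:3) px[, , i] <- rgb[i]
  rgbImage(px, mmPerPx)
}

# Rasterised disk mask of radius r in a (2r + 2m) square frame.
diskMask <- function(r, margin = 5) {
  n <- 2 * (r + margin)
  c0 <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n, n) - c0
  y <- matrix(rep(seq_len(n), times = n), n, n) - c0
  x^2 + y^2 <= r^2
}

# Independent per-feature re-check of the filter rules: returns the first
# failing rule (in application order) for every feature, or "none".
oracleFirstFail <- function(ft) {
  m <- SummarizedExperiment::assay(ft, "intensity")
  rd <- as.data.frame(SummarizedExperiment::rowData(ft))
  cd <- as.data.frame(SummarizedExperiment::colData(ft))
  vapply(rownames(m), function(fid) {
    x <- m[fid, ]
    if (rd[fid, "rt_min"] < 0.4 || rd[fid, "rt_min"] > 4) return("retention_time")
    if (!any(x >= 10, na.rm = TRUE)) return("min_intensity")
    qcv <- x[cd$is_qc]; qcv <- qcv[!is.na(qcv)]
    if (length(qcv) < 2 || 100 * sd(qcv) / mean(qcv) >= 150) return("qc_rsd")
    ok <- FALSE
    for (cl in unique(cd$class[!cd$is_qc])) {
      ix <- !cd$is_qc & cd$class == cl
      if (mean(!is.na(x[ix])) >= 2 / 3) ok <- TRUE
    }
    if (!ok) return("class_presence")
    "none"
  }, character(1))
}

ruleOrder <- c("retention_time", "min_intensity", "qc_rsd", "class_presence")

# Hand-constructed 10-feature table tripping each filter rule once
# (in application order), with 6 clean features.  3 QCs, 2 classes x 3.
toyFeatureTable <- function() {
  sampleId <- c(paste0("A_", 1:3), paste0("B_", 1:3), paste0("QC_", 1:3))
  cd <- data.frame(class = c(rep("A", 3), rep("B", 3), rep("QC", 3)),
                   is_qc = c(rep(FALSE, 6), rep(TRUE, 3)),
                   row.names = sampleId)
  m <- matrix(1000, 10, 9, dimnames = list(sprintf("F%02d", 1:10), sampleId))
  rt <- rep(2, 10)
  rt[1] <- 0.3                      # F01: RT violator
  m[2, ] <- 5                       # F02: never reaches intensity 10
  m[3, 7:9] <- c(100, 100, 4000)    # F03: QC RSD 184% > 150
  m[4, 1:6] <- c(1000, NA, NA, NA, NA, 1000)  # F04: 1/3 presence everywhere
  rd <- data.frame(mz = seq(100, 1000, length.out = 10), rt_min = rt,
                   mode = rep(c("pos", "neg"), 5),
                   row.names = rownames(m))
  featureTable(m, rd, cd)
}
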