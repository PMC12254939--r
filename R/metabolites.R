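# LC-MS feature-table preprocessing (filters, imputation, normalisation,
# PCA projection) and diel carbohydrate-to-DLI association.

#' Construct a FeatureTable
#'
#' @param intensity Numeric features x samples matrix, `NA` for missing,
#'   values `>= 0`.
#' @param rowData `data.frame`/`DataFrame` with `mz`, `rt_min`, `mode`
#'   (`"pos"`/`"neg"`), one row per feature.  Row names become feature ids.
#' @param colData `data.frame`/`DataFrame` with `class` and logical
#'   `is_qc`, one row per sample.
#' @return A [FeatureTable-class].
#' @export
featureTable <- function(intensity, rowData, colData) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = as.matrix(intensity)),
    rowData = rowData, colData = colData)
  new("FeatureTable", se)
}

#' Read a feature table and sample metadata from CSV
#'
#' Feature CSV: `feature_id, mz, rt_min, mode, <one column per sample>`;
#' sample CSV: `sample_id, class, is_qc`.  Empty cells are missing values.
#'
#' @param featurePath,samplePath CSV paths.
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(featurePath, samplePath) {
  f <- utils::read.csv(featurePath, stringsAsFactors = FALSE,
                       check.names = FALSE)
  s <- utils::read.csv(samplePath, stringsAsFactors = FALSE)
  stopifnot(all(c("feature_id", "mz", "rt_min", "mode") %in% names(f)),
            all(c("sample_id", "class", "is_qc") %in% names(s)))
  if (!all(s$sample_id %in% names(f))) {
    stop("sample columns missing from feature CSV: ",
         paste(setdiff(s$sample_id, names(f)), collapse = ", "))
  }
  m <- as.matrix(f[, s$sample_id, drop = FALSE])
  rownames(m) <- f$feature_id
  rd <- f[, c("mz", "rt_min", "mode")]
  rownames(rd) <- f$feature_id
  cd <- data.frame(class = s$class, is_qc = as.logical(s$is_qc),
                   row.names = s$sample_id)
  featureTable(m, rd, cd)
}

#' @rdname writeFeatureTable
#' @export
writeFeatureTable <- function(table, featurePath, samplePath) {
  m <- SummarizedExperiment::assay(table, "intensity")
  rd <- as.data.frame(SummarizedExperiment::rowData(table))
  out <- cbind(data.frame(feature_id = rownames(m)), rd, as.data.frame(m))
  utils::write.csv(out, featurePath, row.names = FALSE, na = "")
  cd <- as.data.frame(SummarizedExperiment::colData(table))
  utils::write.csv(cbind(data.frame(sample_id = rownames(cd)), cd),
                   samplePath, row.names = FALSE)
  invisible(featurePath)
}

#' Write a feature table to CSV
#'
#' Inverse of [readFeatureTable()].
#'
#' @param table A [FeatureTable-class].
#' @param featurePath,samplePath Output CSV paths.
#' @return Invisibly `featurePath`.
#' @aliases writeFeatureTable
#' @name writeFeatureTable
NULL

#' Relative standard deviation over QC samples
#'
#' `sd/mean * 100` per feature over the non-missing QC intensities
#' (missing values are absent, not zero).  Features with fewer than two
#' observed QC values have no defined repeatability and return `Inf`.
#'
#' @param table A [FeatureTable-class].
#' @return Numeric RSD (%) per feature.
#' @export
qcRSD <- function(table) {
  qc <- SummarizedExperiment::colData(table)$is_qc
  m <- SummarizedExperiment::assay(table, "intensity")[, qc, drop = FALSE]
  apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(Inf)
    100 * stats::sd(x) / mean(x)
  })
}

#' Filter an LC-MS feature table
#'
#' Applies, in order, the four feature-quality rules:
#' 1. retention time within `rtRange` (inclusive);
#' 2. maximum intensity over all samples at least `minIntensity` (a feature
#'    must reach the floor somewhere; requiring it in every sample would
#'    make the presence rule vacuous);
#' 3. RSD across QC samples strictly below `maxRSD` % (see [qcRSD()]);
#' 4. present (non-missing) in at least `presenceFraction` of the samples
#'    of at least one biological class (`anyClass = TRUE`, default) or of
#'    every class (`anyClass = FALSE`).  QC samples do not form a class.
#'
#' @param table A [FeatureTable-class].
#' @param rtRange Inclusive retention-time window, minutes.
#' @param minIntensity Intensity floor.
#' @param maxRSD QC-RSD ceiling, percent; `NULL`/`Inf` disables the rule.
#' @param presenceFraction Required within-class presence fraction.
#' @param anyClass Presence rule satisfied in any one class (default) or in
#'   all classes.
#' @return List with `table` (the retained [FeatureTable-class]) and
#'   `report`, a `data.frame` of per-rule removal counts (in application
#'   order) whose counts telescope: input = retained + sum(removed).
#' @export
filterFeatures <- function(table, rtRange = c(0.4, 4), minIntensity = 10,
                           maxRSD = 150, presenceFraction = 2 / 3,
                           anyClass = TRUE) {
  stopifnot(is(table, "FeatureTable"))
  rsdEnabled <- !is.null(maxRSD) && is.finite(maxRSD)
  cd <- SummarizedExperiment::colData(table)
  if (rsdEnabled && !any(cd$is_qc)) {
    stop("config error: QC-RSD rule enabled but the table has no QC samples")
  }
  nInput <- nrow(table)
  keepLog <- list()
  cur <- table

  rd <- SummarizedExperiment::rowData(cur)
  keep <- rd$rt_min >= rtRange[1] & rd$rt_min <= rtRange[2]
  keepLog[["retention_time"]] <- sum(!keep)
  cur <- cur[keep, ]

  m <- SummarizedExperiment::assay(cur, "intensity")
  keep <- apply(m, 1, function(x) any(!is.na(x) & x >= minIntensity))
  keepLog[["min_intensity"]] <- sum(!keep)
  cur <- cur[keep, ]

  if (rsdEnabled) {
    keep <- qcRSD(cur) < maxRSD
    keepLog[["qc_rsd"]] <- sum(!keep)
    cur <- cur[keep, ]
  }

  cdc <- SummarizedExperiment::colData(cur)
  bio <- !cdc$is_qc
  cls <- split(which(bio), cdc$class[bio])
  m <- SummarizedExperiment::assay(cur, "intensity")
  presence <- vapply(rownames(m), function(fid) {
    fr <- vapply(cls, function(ix) mean(!is.na(m[fid, ix])), numeric(1))
    if (anyClass) any(fr >= presenceFraction) else all(fr >= presenceFraction)
  }, logical(1))
  keepLog[["class_presence"]] <- sum(!presence)
  cur <- cur[presence, ]

  report <- data.frame(rule = names(keepLog),
                       removed = unlist(keepLog, use.names = FALSE))
  report$retained_after <- nInput - cumsum(report$removed)
  attr(report, "input") <- nInput
  attr(report, "retained") <- nrow(cur)
  list(table = cur, report = report)
}

#' Drop QC samples
#'
#' @param table A [FeatureTable-class].
#' @return The table restricted to biological samples.
#' @export
dropQCSamples <- function(table) {
  table[, !SummarizedExperiment::colData(table)$is_qc]
}

#' Impute missing intensities from the lowest decile
#'
#' Per feature, missing entries are replaced by the mean of that feature's
#' lowest decile of observed intensities (the `ceiling(n/10)` smallest
#' values).  Observed values are never altered; a second call is a no-op.
#' QC samples must have been dropped first (see [dropQCSamples()]), since
#' imputation feeds the biological-sample projection only.
#'
#' @param table A [FeatureTable-class] without QC samples.
#' @return The imputed [FeatureTable-class].
#' @export
imputeLow10 <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  if (any(SummarizedExperiment::colData(table)$is_qc)) {
    stop("drop QC samples before imputation (dropQCSamples())")
  }
  m <- SummarizedExperiment::assay(table, "intensity")
  for (i in seq_len(nrow(m))) {
    miss <- is.na(m[i, ])
    if (!any(miss)) next
    obs <- sort(m[i, !miss])
    if (length(obs) == 0L) {
      stop("imputation error: feature ", rownames(m)[i],
           " has no observed values")
    }
    m[i, miss] <- mean(obs[seq_len(ceiling(length(obs) / 10))])
  }
  SummarizedExperiment::assay(table, "intensity") <- m
  table
}

#' Log-transform and Z-score normalise
#'
#' Natural log of every intensity, then per-feature centring to mean 0 and
#' scaling to sd 1.  Features with zero variance cannot be scaled and are
#' dropped with a warning.
#'
#' @param table A [FeatureTable-class] (post-imputation: all entries `> 0`)
#'   or a bare positive matrix.
#' @return Numeric features x samples matrix of Z scores.
#' @export
normalizeLogZ <- function(table) {
  m <- if (is(table, "FeatureTable")) {
    SummarizedExperiment::assay(table, "intensity")
  } else as.matrix(table)
  if (anyNA(m)) stop("missing values present; impute first (imputeLow10())")
  if (any(m <= 0)) stop("domain error: nonpositive intensities cannot be logged")
  lm <- log(m)
  sds <- apply(lm, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped (sd = 0)")
    lm <- lm[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (lm - rowMeans(lm)) / sds
}

#' Principal-component scores of the samples
#'
#' Projects samples onto the top `k` variance axes of the normalised
#' feature matrix.  Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so scores are
#' reproducible across platforms.
#'
#' @param mat Features x samples matrix (e.g. from [normalizeLogZ()]).
#' @param k Number of components (default 2).
#' @return Samples x k score matrix with columns `PC1..PCk` and attribute
#'   `"variance_explained"` (proportion per component).
#' @export
pcaScores <- function(mat, k = 2) {
  x <- t(as.matrix(mat))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (k > ncol(pc$rotation)) {
    stop("rank error: k = ", k, " exceeds data rank ", ncol(pc$rotation))
  }
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(scores, "variance_explained") <- ve[seq_len(k)]
  scores
}

#' Read a diel carbohydrate series CSV
#'
#' Columns: `regime, zt_h, analyte, conc_umol_gFW, rep`.
#'
#' @param path CSV path.
#' @return `data.frame` of the series.
#' @export
readCarbSeries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("regime", "zt_h", "analyte", "conc_umol_gFW", "rep") %in%
                  names(d)))
  d
}

# A ZT timepoint counts as a photoperiod timepoint if it lies in the closure
# of a lit interval (so the instant the lights switch off still belongs to
# the photoperiod it terminates).
.inPhotoperiod <- function(regime, zt) {
  iv <- regime@intervals
  vapply(zt, function(z) {
    any(iv$ppfd > 0 & z >= iv$start_h - 1e-9 &
          z <= iv$start_h + iv$duration_h + 1e-9)
  }, logical(1))
}

#' Correlation of carbohydrate content with cumulative DLI
#'
#' Pearson correlation between the cumulative daily light integral of the
#' regime at each sampled ZT and the replicate-mean concentration of one
#' analyte, over photoperiod timepoints.  Dark-period timepoints are
#' excluded by default: cumulative DLI is flat in darkness while sugars are
#' catabolised, so the association under study concerns accumulation in
#' light.
#'
#' @param series Carbohydrate `data.frame` (see [readCarbSeries()] or
#'   [genCarbSeries()]).
#' @param regime The [LightRegime-class] the plants grew under.
#' @param analyte One of the analytes present (e.g. `"sucrose"`,
#'   `"starch"`).
#' @param lightOnly Exclude dark-period timepoints (default `TRUE`).
#' @return Pearson correlation coefficient.
#' @export
carbDliCorrelation <- function(series, regime, analyte, lightOnly = TRUE) {
  stopifnot(is(regime, "LightRegime"))
  s <- series[series$analyte == analyte, , drop = FALSE]
  if (nrow(s) == 0L) stop("analyte not present in series: ", analyte)
  agg <- stats::aggregate(conc_umol_gFW ~ zt_h, data = s, FUN = mean)
  if (lightOnly) {
    agg <- agg[.inPhotoperiod(regime, agg$zt_h), , drop = FALSE]
  }
  if (nrow(agg) < 3L) {
    stop("sample-size error: need >= 3 timepoints, have ", nrow(agg))
  }
  stats::cor(cumulativeDLI(regime, agg$zt_h), agg$conc_umol_gFW)
}
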