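test_that("each filter rule trips exactly once on the hand-built toy table", {
  res <- filterFeatures(toyFeatureTable())
  rep <- res$report
  expect_equal(rep$rule,
               c("retention_time", "min_intensity", "qc_rsd", "class_presence"))
  expect_equal(rep$removed, c(1L, 1L, 1L, 1L))
  expect_equal(attr(rep, "retained"), 6L)
  expect_equal(sort(rownames(res$table)), sprintf("F%02d", 5:10))
  # telescoping identity
  expect_equal(attr(rep, "input"), attr(rep, "retained") + sum(rep$removed))
  expect_equal(rep$retained_after[4], attr(rep, "retained"))
})

test_that("filtering matches a brute-force per-feature oracle", {
  for (seed in 1:6) {
    g <- genFeatureTable(nFeatures = 40, seed = seed, missingRate = 0.15)
    res <- filterFeatures(g$table)
    # oracle: re-derive each feature's first failing rule independently
    firstFail <- oracleFirstFail(g$table)
    expect_equal(res$report$removed,
                 as.integer(table(factor(firstFail,
                                         c(ruleOrder, "none")))[1:4]),
                 ignore_attr = TRUE)
    expect_setequal(rownames(res$table), names(firstFail)[firstFail == "none"])
    expect_equal(attr(res$report, "input"),
                 attr(res$report, "retained") + sum(res$report$removed))
  }
})

test_that("QC-RSD uses sd/mean over observed QC values only", {
  ft <- toyFeatureTable()
  m <- assay(ft, "intensity")
  m["F05", 7:9] <- c(100, 200, NA)  # missing treated as absent
  assay(ft, "intensity") <- m
  r <- qcRSD(ft)
  expect_equal(unname(r["F05"]), 100 * sd(c(100, 200)) / 150)
  m["F06", 7:9] <- c(500, NA, NA)   # single QC value: undefined -> Inf
  assay(ft, "intensity") <- m
  expect_equal(unname(qcRSD(ft)["F06"]), Inf)
  # the rule needs QC samples at all
  noQC <- ft[, !colData(ft)$is_qc]
  expect_error(filterFeatures(noQC), "config error")
  expect_silent(filterFeatures(noQC, maxRSD = NULL))
})

test_that("low-decile imputation fills missing cells and is idempotent", {
  vals <- c(seq(10, 100, by = 10), NA)
  m <- matrix(vals, 1, 11, dimnames = list("F1", paste0("s", 1:11)))
  ft <- featureTable(m, data.frame(mz = 500, rt_min = 2, mode = "pos",
                                   row.names = "F1"),
                     data.frame(class = rep("A", 11), is_qc = FALSE,
                                row.names = colnames(m)))
  imp <- imputeLow10(ft)
  expect_equal(unname(assay(imp, "intensity")["F1", "s11"]), 10)
  expect_equal(assay(imp, "intensity")[1, 1:10], m[1, 1:10])  # untouched
  expect_identical(assay(imputeLow10(imp), "intensity"),
                   assay(imp, "intensity"))
  # 15 observed values -> lowest ceiling(15/10) = 2 averaged
  m2 <- matrix(c(2, 4, seq(10, 140, by = 10), NA), 1, 17,
               dimnames = list("F1", paste0("s", 1:17)))
  ft2 <- featureTable(m2, data.frame(mz = 1, rt_min = 1, mode = "neg",
                                     row.names = "F1"),
                      data.frame(class = rep("A", 17), is_qc = FALSE,
                                 row.names = colnames(m2)))
  expect_equal(unname(assay(imputeLow10(ft2), "intensity")[1, 17]), 3)
  # QC columns must be dropped first
  expect_error(imputeLow10(toyFeatureTable()), "drop QC")
})

test_that("log/Z normalisation standardises features and drops constants", {
  g <- genFeatureTable(nFeatures = 30, missingRate = 0, fracRT = 0,
                       fracIntensity = 0, fracRSD = 0, fracPresence = 0,
                       seed = 3)
  z <- normalizeLogZ(dropQCSamples(g$table))
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-10))
  # monotone order preserved per feature
  m <- assay(dropQCSamples(g$table), "intensity")
  expect_equal(order(m[1, ]), order(z[1, ]))
  # constant feature dropped with a warning
  m2 <- m[1:3, ]
  m2[2, ] <- 42
  expect_warning(z2 <- normalizeLogZ(m2), "constant")
  expect_equal(nrow(z2), 2L)
  # zero/missing entries are domain errors
  m3 <- m[1:2, ]; m3[1, 1] <- 0
  expect_error(normalizeLogZ(m3), "domain error")
})

test_that("PCA scores are reproducible, sign-fixed and rank-aware", {
  g <- genFeatureTable(nFeatures = 30, missingRate = 0, fracRT = 0,
                       fracIntensity = 0, fracRSD = 0, fracPresence = 0,
                       seed = 8)
  z <- normalizeLogZ(dropQCSamples(g$table))
  sc <- pcaScores(z, k = 2)
  expect_equal(dim(sc), c(ncol(z), 2L))
  # identical samples get identical scores
  z2 <- cbind(z, dup = z[, 1])
  sc2 <- pcaScores(z2, k = 2)
  expect_equal(unname(sc2[1, ]), unname(sc2[ncol(z2), ]), tolerance = 1e-9)
  # rank-1 data: PC1 captures essentially all variance
  u <- rnorm(20); v <- rnorm(8)
  sc1 <- pcaScores(outer(u, v), k = 2)
  ve <- attr(sc1, "variance_explained")
  expect_gt(ve[1], 0.999)
  expect_error(pcaScores(outer(u, v), k = 9), "rank error")
})

test_that("carbohydrate-DLI correlation is exact in the linear case", {
  reg <- builtinRegimes()[["Constant-155"]]
  zt <- c(0, 6, 12, 18)
  lin <- data.frame(regime = "Constant-155", zt_h = rep(zt, each = 2),
                    analyte = "sucrose",
                    conc_umol_gFW = 2 + 0.7 * cumulativeDLI(reg, rep(zt, each = 2)),
                    rep = rep(1:2, 4))
  expect_equal(carbDliCorrelation(lin, reg, "sucrose"), 1)
  # permuting concentrations destroys the association
  shuf <- lin
  shuf$conc_umol_gFW <- shuf$conc_umol_gFW[c(5:8, 1:4)]
  expect_lt(abs(carbDliCorrelation(shuf, reg, "sucrose")), 0.9)
  expect_error(carbDliCorrelation(lin[lin$zt_h < 7, ], reg, "sucrose"),
               "sample-size error")
  expect_error(carbDliCorrelation(lin, reg, "maltose"), "not present")
})

test_that("dark timepoints are excluded from the DLI association", {
  reg <- builtinRegimes()[["Constant-155"]]
  zt <- c(0, 6, 12, 18, 21, 23)  # last two in darkness
  g <- genCarbSeries(reg, zt = zt, replicateCV = 0, seed = 1)
  s <- g$series[g$series$analyte == "starch", ]
  kept <- cealux:::.inPhotoperiod(reg, zt)
  expect_equal(kept, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # with decaying dark values included the correlation would be weaker
  rLight <- carbDliCorrelation(s, reg, "starch", lightOnly = TRUE)
  rAll <- carbDliCorrelation(s, reg, "starch", lightOnly = FALSE)
  expect_gt(rLight, rAll)
  expect_gt(rLight, 0.99)
})

test_that("feature-table CSV round-trips including missing cells", {
  g <- genFeatureTable(nFeatures = 12, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(g$table, f1, f2)
  back <- readFeatureTable(f1, f2)
  expect_equal(assay(back, "intensity"), assay(g$table, "intensity"))
  expect_equal(as.data.frame(colData(back)), as.data.frame(colData(g$table)))
  expect_equal(rowData(back)$rt_min, rowData(g$table)$rt_min)
})
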