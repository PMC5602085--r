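# Per-eye multimodal abnormality classification and the cross-tabulated
# modality agreement report.

# small normative + helper objects built once per file
classifyFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    layout <- fixtureLayout()
    d <- cohortDesign(groupSizes = c(control = 300L, PPG = 0L, POAG = 0L))
    eyes <- simulateCohort(d, layout, seed = 51)
    nrm <- buildNormativeDB(eyes, layout, seed = 51L)
    tab <- sapPointTable()
    cache <<- list(layout = layout, normative = nrm, tab = tab,
                   s10 = selectSapPoints(tab, "central10"),
                   s15 = selectSapPoints(tab, "central15"))
    cache
  }
})

# an EpochRMS / FieldSummary / OctSummary triple with every feature at a
# chosen normative quantile
featuresAtQuantile <- function(fx, qEpoch = 0.5) {
  f <- fx$normative@features
  qcol <- function(feat) {
    v <- f[f$feature == feat, ]
    # interpolate between the stored quantiles for the median-ish case
    if (qEpoch <= 0.01) v$q01 else if (qEpoch <= 0.05) v$q05
    else (v$q05 + v$q95) / 2
  }
  vals <- vapply(c("dc10", "ic1_10", "ic2_10", "dc15", "ic1_15", "ic2_15"),
                 qcol, numeric(1))
  rms <- new("EpochRMS", eyeId = "fx", values = vals,
             windows = epochWindows())
  normDb <- fx$normative@sapNormalDb
  field <- data.frame(point_id = as.integer(names(normDb)),
                      x_deg = fx$tab$x_deg, y_deg = fx$tab$y_deg,
                      sensitivity_db = unname(normDb))
  fs <- regionalFieldSummary(field, fx$normative, fx$s10, fx$s15,
                             age = fx$normative@ageRef, eyeId = "fx")
  mid <- function(feat) {
    v <- f[f$feature == feat, ]
    (v$q05 + v$q95) / 2
  }
  octMT <- vapply(paste0("mT_", c("center",
                                  paste0("inner_", c("sup", "nas", "inf",
                                                     "tem")),
                                  paste0("outer_", c("sup", "nas", "inf",
                                                     "tem")))),
                  mid, numeric(1))
  names(octMT) <- sub("^mT_", "", names(octMT))
  gcipl <- vapply(paste0("gcipl_s", 1:6), mid, numeric(1))
  eye <- new("EyeRecord", eyeId = "fx", subjectId = "fx", group = "control",
             age = fx$normative@ageRef, gender = "F", laterality = "OD",
             kernels = matrix(0, 1, 2), kernelTimes = c(0, 105),
             traceSegments = list(), sampleRate = 1200,
             sapField = field, octMT = octMT, octGCIPL = gcipl,
             latent = list())
  list(rms = rms, fs = fs, oct = octSummary(eye, fx$normative))
}

test_that("an eye at control medians carries no abnormality flags", {
  fx <- classifyFixture()
  at <- featuresAtQuantile(fx)
  fl <- classifyEye(at$fs, at$rms, at$oct, fx$normative, fx$s15)
  expect_false(fl@sapAbnormal)
  expect_false(fl@mfergAbnormal)
  expect_false(fl@mtAbnormal)
  expect_false(fl@gciplAbnormal)
})

test_that("a depressed DC15 alone triggers only the mfERG flag", {
  fx <- classifyFixture()
  at <- featuresAtQuantile(fx)
  f <- fx$normative@features
  v <- rmsValues(at$rms)
  v["dc15"] <- f$q01[f$feature == "dc15"] * 0.999  # below 1st percentile
  rms <- new("EpochRMS", eyeId = "fx", values = v,
             windows = epochWindows())
  fl <- classifyEye(at$fs, rms, at$oct, fx$normative, fx$s15)
  expect_true(fl@mfergAbnormal)
  expect_equal(fl@details$mferg_epochs, "dc15")
  expect_false(fl@sapAbnormal || fl@mtAbnormal || fl@gciplAbnormal)

  # two-sided option also flags abnormally large responses
  v2 <- rmsValues(at$rms)
  v2["ic2_15"] <- f$q95[f$feature == "ic2_15"] * 1.5
  rms2 <- new("EpochRMS", eyeId = "fx", values = v2,
              windows = epochWindows())
  expect_false(classifyEye(at$fs, rms2, at$oct, fx$normative,
                           fx$s15)@mfergAbnormal)
  expect_true(classifyEye(at$fs, rms2, at$oct, fx$normative, fx$s15,
                          twoSided = TRUE)@mfergAbnormal)
})

test_that("classification is monotone: lower values never clear a flag", {
  fx <- classifyFixture()
  at <- featuresAtQuantile(fx)
  f <- fx$normative@features
  set.seed(61)
  for (i in 1:10) {
    shrink <- runif(6, 0.3, 1)
    v <- rmsValues(at$rms) * shrink
    rms <- new("EpochRMS", eyeId = "fx", values = v,
               windows = epochWindows())
    fl1 <- classifyEye(at$fs, rms, at$oct, fx$normative, fx$s15)
    v2 <- v * runif(6, 0.3, 1)
    rms2 <- new("EpochRMS", eyeId = "fx", values = v2,
                windows = epochWindows())
    fl2 <- classifyEye(at$fs, rms2, at$oct, fx$normative, fx$s15)
    if (fl1@mfergAbnormal) expect_true(fl2@mfergAbnormal)
  }
})

test_that("the 26-eye example table reproduces its headline percentages", {
  tab <- fixtureFlagTable()
  expect_equal(nrow(tab), 26L)
  ct <- crosstabReport(tab)
  p <- crosstabPercentages(ct)
  expect_equal(p$percent[p$category == "mferg_gcipl_no_sap"], 100 * 8 / 26)
  expect_equal(p$percent[p$category == "thin_mferg_no_sap"], 100 * 8 / 23)
  expect_equal(ct@nGciplThin, 23L)
  expect_equal(p$count[p$category == "mt_and_gcipl"], 17L)
  expect_equal(p$count[p$category == "gcipl_only"], 6L)
  expect_equal(p$count[p$category == "mt_only"], 1L)
  expect_equal(p$count[p$category == "thin_sap_no_mferg"], 4L)
  expect_equal(p$count[p$category == "thin_both"], 3L)
})

test_that("an all-normal cohort cross-tabulates to zero percentages", {
  tab <- data.frame(eye_id = paste0("e", 1:5), sap = FALSE, mferg = FALSE,
                    mT = FALSE, gcipl = FALSE)
  ct <- crosstabReport(tab)
  p <- crosstabPercentages(ct)
  expect_equal(p$count[p$category == "none"], 5L)
  expect_true(all(p$percent[p$category != "none"] == 0))
  expect_error(crosstabReport(tab[0, ]), "at least one")
})
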