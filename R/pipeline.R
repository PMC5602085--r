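# Feature extraction into a SummarizedExperiment and the end-to-end
# pipeline: simulate -> signal -> perimetry -> OCT -> statistics ->
# classification -> report.

#' Extract the per-eye feature table
#'
#' Runs the analysis modules over a cohort and assembles the tidy feature
#' container: a \linkS4class{SummarizedExperiment} with one column per eye
#' (colData: subject, group, age, gender, laterality) and one row per
#' feature: the six regional mfERG epoch RMS averages (\code{dc10, ic1_10,
#' ic2_10, dc15, ic1_15, ic2_15}), the perimetry summaries
#' (\code{ms10_linear, ms15_linear, md10_db, md15_db}) and the OCT
#' summaries (\code{mt_central, gcipl_mean}).
#'
#' mfERG features are computed from each eye's kernel waveforms; for eyes
#' carrying raw trace segments the full signal chain is run instead
#' (artifact rejection, 1-200 Hz zero-phase band-pass, kernel extraction).
#'
#' @param eyes list of \linkS4class{EyeRecord}s
#' @param layout the \linkS4class{HexLayout}
#' @param normative a \linkS4class{NormativeDB}; if NULL, built from the
#'   cohort's own control eyes (self-referential normative)
#' @param mseq,schedule stimulus objects, required for eyes with traces
#' @param windows epoch windows
#' @param pointTable perimetry point table for the SAP masks
#' @return a \code{SummarizedExperiment}; the normative database used is
#'   attached as metadata element \code{"normative"}
#' @export
cohortFeatures <- function(eyes, layout, normative = NULL, mseq = NULL,
                           schedule = NULL, windows = epochWindows(),
                           pointTable = sapPointTable()) {
  if (is.null(normative))
    normative <- buildNormativeDB(eyes, layout, windows)
  m10 <- centralHexagons(layout, 1L)
  m15 <- centralHexagons(layout, 2L)
  s10 <- selectSapPoints(pointTable, "central10")
  s15 <- selectSapPoints(pointTable, "central15")

  rows <- lapply(eyes, function(e) {
    ks <- eyeKernelSet(e, mseq, schedule)
    rms <- rmsValues(regionalRMS(ks, m10, m15, windows, e@eyeId))
    fs <- regionalFieldSummary(e@sapField, normative, s10, s15,
                               age = e@age, eyeId = e@eyeId)
    c(rms,
      ms10_linear = fs@ms10Linear, ms15_linear = fs@ms15Linear,
      md10_db = fs@md10Db, md15_db = fs@md15Db,
      mt_central = unname(etdrsCentralMT(e@octMT)),
      gcipl_mean = unname(gciplAnnulusMean(e@octGCIPL)))
  })
  assay <- t(do.call(rbind, rows))
  colnames(assay) <- vapply(eyes, function(e) e@eyeId, character(1))
  cd <- S4Vectors::DataFrame(cohortManifest(eyes), row.names = colnames(assay))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), colData = cd)
  S4Vectors::metadata(se)$normative <- normative
  se
}

# kernel set of one eye: from stored waveforms, or through the signal chain
# when raw traces are present
eyeKernelSet <- function(eye, mseq = NULL, schedule = NULL) {
  if (length(eye@traceSegments)) {
    if (is.null(mseq) || is.null(schedule))
      stop("eye ", eye@eyeId, " carries raw traces; mseq and schedule ",
           "are required to process them")
    cl <- rejectArtifacts(eye@traceSegments)
    trace <- bandpass(unlist(cl$segments), eye@sampleRate)
    extractFirstOrderKernels(trace, mseq, schedule, eye@sampleRate)
  } else {
    new("KernelSet", waveforms = eye@kernels, times = eye@kernelTimes,
        sampleRate = eye@sampleRate)
  }
}

#' Feature table as a long data.frame
#'
#' @param se SummarizedExperiment from \code{\link{cohortFeatures}}
#' @return data.frame (eye_id, feature, value)
#' @export
featureLong <- function(se) {
  a <- SummarizedExperiment::assay(se)
  data.frame(eye_id = rep(colnames(a), each = nrow(a)),
             feature = rep(rownames(a), ncol(a)),
             value = as.numeric(a))
}

#' Feature table in wide per-eye form with demographics
#'
#' @param se SummarizedExperiment from \code{\link{cohortFeatures}}
#' @return data.frame, one row per eye
#' @export
featureWide <- function(se) {
  a <- t(SummarizedExperiment::assay(se))
  cbind(as.data.frame(SummarizedExperiment::colData(se)),
        as.data.frame(a))
}

#' Run the whole analysis pipeline
#'
#' Simulates the cohort and a separate large control sample for the
#' normative database, extracts features, runs the group statistics
#' (one-way ANOVA per feature), the structure-function regressions
#' (mfERG/SAP responses against OCT predictors, age/gender-adjusted, one
#' FDR family), the covariate-adjusted ROC per marker, and the per-eye
#' multimodal classification with its cross-tabulation. Re-running with the
#' same seed is bit-identical.
#'
#' @param design a \linkS4class{CohortDesign}
#' @param seed integer seed driving every random draw
#' @param outDir optional directory; when given, CSV/JSON outputs are
#'   written (feature table, regression and ROC tables, cross-tab, run log)
#' @param layout stimulus layout
#' @param nNormative size of the simulated normative control sample
#' @param mfergRegion region for the mfERG abnormality criterion
#' @return (invisibly) list with \code{eyes}, \code{features} (SE),
#'   \code{normative}, \code{anova}, \code{structureFunction}, \code{roc},
#'   \code{delong}, \code{flags}, \code{crosstab}, \code{seed}
#' @export
runPipeline <- function(design = cohortDesign(), seed = 1L, outDir = NULL,
                        layout = buildHexLayout(), nNormative = 200L,
                        mfergRegion = "15") {
  eyes <- simulateCohort(design, layout, seed = seed)
  normDesign <- cohortDesign(groupSizes = c(control = as.integer(nNormative),
                                            PPG = 0L, POAG = 0L))
  normEyes <- simulateCohort(normDesign, layout, seed = seed + 1000L)
  normative <- buildNormativeDB(normEyes, layout, seed = seed + 1000L)
  se <- cohortFeatures(eyes, layout, normative = normative)
  wide <- featureWide(se)
  manifest <- cohortManifest(eyes)

  hasCases <- any(manifest$group != "control")
  hasControls <- any(manifest$group == "control")
  markers <- c("dc10", "ic1_10", "ic2_10", "ms10_linear", "md10_db",
               "mt_central", "dc15", "ic1_15", "ic2_15", "ms15_linear",
               "md15_db", "gcipl_mean")

  anovaTab <- sfTab <- rocTab <- NULL
  rocs <- list()
  delong <- NULL
  if (hasCases && hasControls) {
    anovaTab <- do.call(rbind, lapply(markers, function(m) {
      a <- anovaOneway(wide[[m]], wide$group)
      data.frame(feature = m, F = a$F, p = a$p)
    }))
    responses <- c("dc10", "ic1_10", "ic2_10", "ms10_linear", "md10_db",
                   "dc15", "ic1_15", "ic2_15", "ms15_linear", "md15_db")
    sfTab <- structureFunctionTable(wide, responses,
                                    c("mt_central", "gcipl_mean"))
    disease <- as.integer(wide$group != "control")
    rocs <- lapply(markers, function(m)
      adjustedROC(wide[[m]], disease, age = wide$age, gender = wide$gender,
                  markerName = m))
    names(rocs) <- markers
    rocTab <- do.call(rbind, lapply(rocs, function(r)
      data.frame(marker = r@marker, auc = r@auc, se = r@seAuc)))
    rownames(rocTab) <- NULL
    delong <- delongCompare(rocs$gcipl_mean, rocs$mt_central)
  } else {
    message("single-class cohort: group statistics and ROC stages skipped")
  }

  m15 <- centralHexagons(layout, 2L)
  m10 <- centralHexagons(layout, 1L)
  pointTable <- sapPointTable()
  s10 <- selectSapPoints(pointTable, "central10")
  s15 <- selectSapPoints(pointTable, "central15")
  flags <- lapply(eyes, function(e) {
    ks <- eyeKernelSet(e)
    rms <- regionalRMS(ks, m10, m15, eyeId = e@eyeId)
    fs <- regionalFieldSummary(e@sapField, normative, s10, s15,
                               age = e@age, eyeId = e@eyeId)
    classifyEye(fs, rms, octSummary(e, normative), normative, s15,
                mfergRegion = mfergRegion)
  })
  ft <- flagTable(flags, groups = manifest$group)
  ct <- crosstabReport(ft)

  out <- list(eyes = eyes, features = se, normative = normative,
              anova = anovaTab, structureFunction = sfTab, roc = rocTab,
              delong = delong, flags = ft, crosstab = ct,
              seed = as.integer(seed))
  if (!is.null(outDir)) writeReportBundle(out, outDir)
  invisible(out)
}

# write the report bundle as plain CSV/JSON
writeReportBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.csv(featureWide(bundle$features),
            file.path(outDir, "features.csv"), row.names = FALSE)
  if (!is.null(bundle$anova))
    write.csv(bundle$anova, file.path(outDir, "anova.csv"),
              row.names = FALSE)
  if (!is.null(bundle$structureFunction))
    write.csv(bundle$structureFunction,
              file.path(outDir, "structure_function.csv"), row.names = FALSE)
  if (!is.null(bundle$roc))
    write.csv(bundle$roc, file.path(outDir, "roc.csv"), row.names = FALSE)
  write.csv(bundle$flags, file.path(outDir, "flags.csv"), row.names = FALSE)
  write.csv(crosstabPercentages(bundle$crosstab),
            file.path(outDir, "crosstab.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = bundle$seed,
         n_eyes = ncol(bundle$features),
         package_version = as.character(utils::packageVersion("glaucoSF")),
         r_version = R.version.string),
    file.path(outDir, "run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
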