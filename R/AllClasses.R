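#' @import methods
#' @importFrom stats quantile rnorm rbinom runif sd aov anova lm glm coef
#'   confint fitted p.adjust pairwise.t.test pnorm qnorm binomial vcov
#'   setNames complete.cases
#' @importFrom utils head read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Spatial classes
# ---------------------------------------------------------------------------

#' Hexagonal stimulus layout
#'
#' Positions of the stimulus hexagons in visual-field coordinates (degrees,
#' fovea at the origin, right-eye orientation), their relative areas and the
#' hexagonal ring each belongs to (ring 0 is the central hexagon).
#'
#' @slot centers numeric matrix (n x 2), columns \code{x_deg}, \code{y_deg}.
#' @slot areas numeric vector of per-hexagon area scale factors.
#' @slot ring integer vector of ring indices (0 = central hexagon).
#' @slot preset character, name of the generating preset.
#' @exportClass HexLayout
setClass("HexLayout",
  representation(centers = "matrix", areas = "numeric", ring = "integer",
                 preset = "character"))

setValidity("HexLayout", function(object) {
  n <- nrow(object@centers)
  msg <- character()
  if (ncol(object@centers) != 2L) msg <- c(msg, "centers must be n x 2")
  if (length(object@areas) != n) msg <- c(msg, "areas length mismatch")
  if (length(object@ring) != n) msg <- c(msg, "ring length mismatch")
  if (n && sum(object@ring == 0L) != 1L)
    msg <- c(msg, "ring 0 must contain exactly one hexagon")
  if (n && any(object@areas <= 0)) msg <- c(msg, "areas must be positive")
  if (length(msg)) msg else TRUE
})

#' Named spatial subset of a layout
#'
#' A set of element ids within one modality's spatial layout: stimulus
#' hexagons (mfERG), perimetry test points (SAP) or OCT sectors.
#'
#' @slot modality character, one of \code{"mfERG"}, \code{"SAP"}, \code{"OCT"}.
#' @slot memberIds integer vector of element ids (unique, non-empty).
#' @slot label character label, e.g. \code{"central10"}.
#' @exportClass RegionMask
setClass("RegionMask",
  representation(modality = "character", memberIds = "integer",
                 label = "character"))

setValidity("RegionMask", function(object) {
  msg <- character()
  if (!object@modality %in% c("mfERG", "SAP", "OCT"))
    msg <- c(msg, "modality must be one of mfERG, SAP, OCT")
  if (anyDuplicated(object@memberIds)) msg <- c(msg, "memberIds not unique")
  if (anyNA(object@memberIds)) msg <- c(msg, "memberIds must not be NA")
  if (length(msg)) msg else TRUE
})

#' Elliptical annulus specification (mm on the retina)
#'
#' Geometry of the macular ganglion cell-inner plexiform layer (GCIPL)
#' measurement region: an elliptical annulus with a circular foveolar
#' exclusion zone.
#'
#' @slot verticalDiameter numeric, outer vertical diameter in mm.
#' @slot horizontalDiameter numeric, outer horizontal diameter in mm.
#' @slot innerExclusionDiameter numeric, diameter of the central exclusion, mm.
#' @exportClass AnnulusSpec
setClass("AnnulusSpec",
  representation(verticalDiameter = "numeric", horizontalDiameter = "numeric",
                 innerExclusionDiameter = "numeric"))

setValidity("AnnulusSpec", function(object) {
  msg <- character()
  d <- c(object@verticalDiameter, object@horizontalDiameter,
         object@innerExclusionDiameter)
  if (any(d <= 0)) msg <- c(msg, "all diameters must be positive")
  if (object@innerExclusionDiameter >=
      min(object@verticalDiameter, object@horizontalDiameter))
    msg <- c(msg, "inner exclusion must be smaller than the outer ellipse")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Stimulus classes
# ---------------------------------------------------------------------------

#' Maximal-length binary sequence
#'
#' An m-sequence of period 2^order - 1 generated by a Fibonacci linear
#' feedback shift register with primitive feedback taps, together with the
#' per-hexagon circular shifts used to decorrelate stimulus locations.
#'
#' @slot order integer, shift-register length n.
#' @slot taps integer vector of feedback tap positions.
#' @slot bits integer vector of 0/1 of length 2^order - 1.
#' @slot shifts integer vector, circular shift (in m-steps) per hexagon.
#' @exportClass MSequence
setClass("MSequence",
  representation(order = "integer", taps = "integer", bits = "integer",
                 shifts = "integer"))

setValidity("MSequence", function(object) {
  msg <- character()
  N <- 2L^object@order - 1L
  if (length(object@bits) != N)
    msg <- c(msg, sprintf("bits must have length 2^%d - 1 = %d",
                          object@order, N))
  if (sum(object@bits) != 2L^(object@order - 1L))
    msg <- c(msg, "sequence not balanced (ones must equal 2^(order-1))")
  if (anyDuplicated(object@shifts)) msg <- c(msg, "shifts must be distinct")
  if (length(msg)) msg else TRUE
})

#' Two-global-flash frame schedule
#'
#' The per-m-step frame pattern of the two-global-flash multifocal ERG
#' protocol: one m-frame (hexagons flicker according to the m-sequence),
#' followed by two full-field global flashes separated by dark frames.
#'
#' @slot frameRate numeric, display frame rate in Hz.
#' @slot framesPerStep integer, frames per m-sequence step.
#' @slot pattern character vector of frame roles, e.g.
#'   \code{c("M","B","GF","B","GF","B")}.
#' @slot luminances named numeric, cd/m2 for \code{M_on}, \code{M_off},
#'   \code{GF}, \code{B}.
#' @slot nSegments integer, number of recording segments.
#' @slot nSteps integer, number of m-steps (sequence length).
#' @exportClass FrameSchedule
setClass("FrameSchedule",
  representation(frameRate = "numeric", framesPerStep = "integer",
                 pattern = "character", luminances = "numeric",
                 nSegments = "integer", nSteps = "integer"))

setValidity("FrameSchedule", function(object) {
  msg <- character()
  if (length(object@pattern) != object@framesPerStep)
    msg <- c(msg, "pattern length must equal framesPerStep")
  if (sum(object@pattern == "M") != 1L)
    msg <- c(msg, "pattern must contain exactly one M frame")
  if (sum(object@pattern == "GF") != 2L)
    msg <- c(msg, "pattern must contain exactly two global-flash frames")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Cohort classes
# ---------------------------------------------------------------------------

#' Synthetic cohort design
#'
#' Group sizes, demographics, per-group structural targets and coupling/noise
#' parameters of the synthetic three-group cohort (healthy controls,
#' preperimetric glaucoma PPG, primary open-angle glaucoma POAG). The default
#' design reproduces the demographic and thickness structure of an early
#' glaucoma case-control study: 16 control, 6 PPG and 20 POAG eyes.
#'
#' All per-group numeric slots are named vectors with names
#' \code{c("control","PPG","POAG")}.
#'
#' @slot groupSizes integer, eyes per group.
#' @slot ageMean,ageSD numeric, age distribution (years).
#' @slot maleProp numeric, proportion of male subjects.
#' @slot gciplMean,gciplSD numeric, GCIPL annulus mean thickness (um).
#' @slot mtMean,mtSD numeric, central macular thickness (um).
#' @slot mdMean,mdSD numeric, SAP mean defect (dB, positive = loss).
#' @slot gciplLossScale numeric, um of GCIPL lost per unit latent loss.
#' @slot mtLossScale numeric, um of central mT lost per unit latent loss.
#' @slot sapCoupling numeric per group, dB of extra field loss per unit of
#'   within-group excess structural loss.
#' @slot noise named numeric: measurement noise levels (see vignette).
#' @slot spatialSD numeric, SD of the smooth per-hexagon integrity field.
#' @slot eyesPerSubject integer, 1 or 2.
#' @exportClass CohortDesign
setClass("CohortDesign",
  representation(groupSizes = "integer", ageMean = "numeric", ageSD = "numeric",
                 maleProp = "numeric", gciplMean = "numeric",
                 gciplSD = "numeric", mtMean = "numeric", mtSD = "numeric",
                 mdMean = "numeric", mdSD = "numeric",
                 gciplLossScale = "numeric", mtLossScale = "numeric",
                 sapCoupling = "numeric", noise = "numeric",
                 spatialSD = "numeric", eyesPerSubject = "integer"))

setValidity("CohortDesign", function(object) {
  grp <- c("control", "PPG", "POAG")
  msg <- character()
  for (sl in c("groupSizes", "ageMean", "ageSD", "maleProp", "gciplMean",
               "gciplSD", "mtMean", "mtSD", "mdMean", "mdSD", "sapCoupling")) {
    v <- slot(object, sl)
    if (!all(grp %in% names(v)))
      msg <- c(msg, sprintf("slot %s must be named by group", sl))
  }
  if (any(object@groupSizes < 0L)) msg <- c(msg, "group sizes must be >= 0")
  if (any(object@ageSD < 0) || any(object@gciplSD < 0) || any(object@mtSD < 0))
    msg <- c(msg, "SDs must be >= 0")
  if (!object@eyesPerSubject %in% c(1L, 2L))
    msg <- c(msg, "eyesPerSubject must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' One synthetic eye
#'
#' A single eye's multimodal record: per-hexagon first-order response
#' waveforms (and optionally the raw segment traces they were embedded in),
#' the SAP sensitivity field, OCT sector thicknesses and demographics.
#'
#' @slot eyeId,subjectId character.
#' @slot group character, one of control/PPG/POAG.
#' @slot age numeric years; @slot gender character "M"/"F".
#' @slot laterality character "OD"/"OS".
#' @slot kernels numeric matrix (hexagons x time samples), uV, the per-hexagon
#'   response waveforms on the 0-105 ms epoch grid.
#' @slot kernelTimes numeric vector, ms, time axis of \code{kernels}.
#' @slot traceSegments list of numeric vectors (uV), empty unless the eye was
#'   simulated with full traces.
#' @slot sampleRate numeric, Hz.
#' @slot sapField data.frame (point_id, x_deg, y_deg, sensitivity_db).
#' @slot octMT numeric length 9, ETDRS sector thicknesses (um), names
#'   \code{center, inner_*, outer_*}.
#' @slot octGCIPL numeric length 6, GCIPL sector thicknesses (um).
#' @slot latent list, generator internals (latent loss, integrity field).
#' @exportClass EyeRecord
setClass("EyeRecord",
  representation(eyeId = "character", subjectId = "character",
                 group = "character", age = "numeric", gender = "character",
                 laterality = "character", kernels = "matrix",
                 kernelTimes = "numeric", traceSegments = "list",
                 sampleRate = "numeric", sapField = "data.frame",
                 octMT = "numeric", octGCIPL = "numeric", latent = "list"))

setValidity("EyeRecord", function(object) {
  msg <- character()
  if (!object@group %in% c("control", "PPG", "POAG"))
    msg <- c(msg, "unknown group label")
  if (length(object@octMT) != 9L) msg <- c(msg, "octMT must have 9 sectors")
  if (length(object@octGCIPL) != 6L)
    msg <- c(msg, "octGCIPL must have 6 sectors")
  if (any(object@octMT <= 0) || any(object@octGCIPL <= 0))
    msg <- c(msg, "thicknesses must be positive")
  db <- object@sapField$sensitivity_db
  if (length(db) && (any(db < 0) || any(db > 40)))
    msg <- c(msg, "SAP sensitivities must lie in [0, 40] dB")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Feature / summary classes
# ---------------------------------------------------------------------------

#' Per-eye epoch RMS amplitudes
#'
#' Root-mean-square amplitudes of the direct component (DC, 15-45 ms) and the
#' two induced components (IC1 45-75 ms, IC2 75-105 ms), averaged over the
#' central 7 hexagons (10 degrees) and the central 19 hexagons (15 degrees).
#'
#' @slot eyeId character.
#' @slot values named numeric: \code{dc10, ic1_10, ic2_10, dc15, ic1_15,
#'   ic2_15} in uV.
#' @slot windows list of the three epoch windows (ms).
#' @exportClass EpochRMS
setClass("EpochRMS",
  representation(eyeId = "character", values = "numeric", windows = "list"))

setValidity("EpochRMS", function(object) {
  need <- c("dc10", "ic1_10", "ic2_10", "dc15", "ic1_15", "ic2_15")
  msg <- character()
  if (!all(need %in% names(object@values)))
    msg <- c(msg, "values must contain the six regional epoch RMS entries")
  if (any(object@values < 0)) msg <- c(msg, "RMS values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-eye perimetry summary
#'
#' @slot eyeId character.
#' @slot ms10Linear,ms15Linear numeric, mean linear sensitivity.
#' @slot md10Db,md15Db numeric, mean defect in dB (positive = loss).
#' @slot globalMdDb numeric, mean defect over all points.
#' @slot pointProb character vector per point, probability class in
#'   \code{">=5%", "<5%", "<2%", "<1%", "<0.5%"} (NA without a normative DB).
#' @slot pointIds integer, point ids aligned with \code{pointProb}.
#' @exportClass FieldSummary
setClass("FieldSummary",
  representation(eyeId = "character", ms10Linear = "numeric",
                 ms15Linear = "numeric", md10Db = "numeric",
                 md15Db = "numeric", globalMdDb = "numeric",
                 pointProb = "character", pointIds = "integer"))

setValidity("FieldSummary", function(object) {
  msg <- character()
  if (object@ms10Linear <= 0 || object@ms15Linear <= 0)
    msg <- c(msg, "linear mean sensitivities must be positive")
  ok <- c(">=5%", "<5%", "<2%", "<1%", "<0.5%", NA_character_)
  if (!all(object@pointProb %in% ok))
    msg <- c(msg, "invalid probability class")
  if (length(msg)) msg else TRUE
})

#' Per-eye OCT summary
#'
#' @slot eyeId character.
#' @slot mtCentral numeric, area-weighted ETDRS 1+3 mm macular thickness (um).
#' @slot gciplMean numeric, GCIPL elliptical-annulus mean (um).
#' @slot sectorValues list with elements \code{mT} (9) and \code{GCIPL} (6).
#' @slot sectorFlags list with per-sector flags in
#'   \code{"normal","yellow","red"} (NA flags without a normative DB).
#' @exportClass OctSummary
setClass("OctSummary",
  representation(eyeId = "character", mtCentral = "numeric",
                 gciplMean = "numeric", sectorValues = "list",
                 sectorFlags = "list"))

#' Control-derived normative database
#'
#' Empirical quantiles of every analysed feature in a control sample, used by
#' the abnormality criteria: per-feature 1st/5th/95th percentiles, and
#' per-SAP-point deviation quantiles for the probability classes.
#'
#' @slot features data.frame: feature, q01, q05, q95.
#' @slot sapPointDeviation data.frame: point_id, q95, q98, q99, q995 of the
#'   (normal - measured) dB deviation.
#' @slot sapNormalDb numeric, age-reference normal sensitivity per point (dB).
#' @slot ageRef numeric, reference age (years) of \code{sapNormalDb}.
#' @slot ageSlopeDbPerDecade numeric, normative age-correction slope.
#' @slot nControls integer; @slot seed integer, provenance.
#' @exportClass NormativeDB
setClass("NormativeDB",
  representation(features = "data.frame", sapPointDeviation = "data.frame",
                 sapNormalDb = "numeric", ageRef = "numeric",
                 ageSlopeDbPerDecade = "numeric", nControls = "integer",
                 seed = "integer"))

setValidity("NormativeDB", function(object) {
  f <- object@features
  msg <- character()
  if (!all(c("feature", "q01", "q05", "q95") %in% names(f)))
    msg <- c(msg, "features must have columns feature, q01, q05, q95")
  if (nrow(f) && any(f$q01 > f$q05 | f$q05 > f$q95))
    msg <- c(msg, "feature quantiles must be ordered q01 <= q05 <= q95")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Statistics result classes
# ---------------------------------------------------------------------------

#' Structure-function regression fit
#'
#' @slot response,predictor character feature names.
#' @slot slope numeric, rate of change of the response per unit predictor.
#' @slot ci95 numeric length 2.
#' @slot pValue,pFdr numeric.
#' @slot covariates character, adjustment covariates.
#' @slot mixed logical, TRUE if a subject random intercept was used.
#' @slot nObs integer.
#' @exportClass ModelFit
setClass("ModelFit",
  representation(response = "character", predictor = "character",
                 slope = "numeric", ci95 = "numeric", pValue = "numeric",
                 pFdr = "numeric", covariates = "character",
                 mixed = "logical", nObs = "integer"))

setValidity("ModelFit", function(object) {
  msg <- character()
  if (length(object@ci95) != 2L) msg <- c(msg, "ci95 must have length 2")
  else if (!is.na(object@slope) && !anyNA(object@ci95) &&
           (object@slope < object@ci95[1] || object@slope > object@ci95[2]))
    msg <- c(msg, "ci95 must contain the slope")
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Covariate-adjusted ROC result
#'
#' @slot marker character feature name.
#' @slot auc,seAuc numeric, Mann-Whitney AUC and DeLong standard error.
#' @slot scores numeric, the logistic-regression scores the ROC is built on.
#' @slot labels integer 0/1 disease labels aligned with \code{scores}.
#' @slot covariates character, covariates in the logistic score model.
#' @slot nCases,nControls integer.
#' @exportClass ROCResult
setClass("ROCResult",
  representation(marker = "character", auc = "numeric", seAuc = "numeric",
                 scores = "numeric", labels = "integer",
                 covariates = "character", nCases = "integer",
                 nControls = "integer"))

setValidity("ROCResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
  if (object@seAuc < 0) msg <- c(msg, "seAuc must be >= 0")
  if (length(object@scores) != length(object@labels))
    msg <- c(msg, "scores and labels must be aligned")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Classification classes
# ---------------------------------------------------------------------------

#' Per-eye multimodal abnormality flags
#'
#' @slot eyeId character.
#' @slot sapAbnormal,mfergAbnormal,mtAbnormal,gciplAbnormal logical.
#' @slot details list naming the triggering epoch/point/sector per modality.
#' @exportClass AbnormalityFlags
setClass("AbnormalityFlags",
  representation(eyeId = "character", sapAbnormal = "logical",
                 mfergAbnormal = "logical", mtAbnormal = "logical",
                 gciplAbnormal = "logical", details = "list"))

#' Cross-tabulated modality agreement
#'
#' Counts and percentages of the flag combinations used in the per-eye
#' multimodal analysis, with explicit denominators (all eyes; eyes with
#' GCIPL thinning).
#'
#' @slot counts named integer.
#' @slot percentages data.frame: category, count, denominator, percent.
#' @slot nEyes,nGciplThin integer.
#' @exportClass CrossTab
setClass("CrossTab",
  representation(counts = "integer", percentages = "data.frame",
                 nEyes = "integer", nGciplThin = "integer"))

setValidity("CrossTab", function(object) {
  p <- object@percentages
  msg <- character()
  if (nrow(p) && any(abs(p$percent - 100 * p$count / p$denominator) > 1e-8))
    msg <- c(msg, "percentages inconsistent with counts")
  if (length(msg)) msg else TRUE
})
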