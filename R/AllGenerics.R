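# Accessors and show methods. Slots are never reached into by user code;
# these are the supported surface.

#' Number of hexagons in a layout
#' @param x a \linkS4class{HexLayout}
#' @return integer
#' @export
nHexagons <- function(x) nrow(x@centers)

#' Hexagon centers (degrees)
#' @param x a \linkS4class{HexLayout}
#' @return numeric matrix with columns x_deg, y_deg
#' @export
hexCenters <- function(x) x@centers

#' Hexagon ring indices
#' @param x a \linkS4class{HexLayout}
#' @return integer vector (0 = central hexagon)
#' @export
hexRings <- function(x) x@ring

#' Hexagon area scale factors
#' @param x a \linkS4class{HexLayout}
#' @return numeric vector
#' @export
hexAreas <- function(x) x@areas

#' Member ids of a region mask
#' @param x a \linkS4class{RegionMask}
#' @return integer vector
#' @export
memberIds <- function(x) x@memberIds

#' Label of a region mask
#' @param x a \linkS4class{RegionMask}
#' @return character
#' @export
maskLabel <- function(x) x@label

#' Bits of an m-sequence
#' @param x an \linkS4class{MSequence}
#' @return integer vector of 0/1
#' @export
mseqBits <- function(x) x@bits

#' Per-hexagon circular shifts of an m-sequence
#' @param x an \linkS4class{MSequence}
#' @return integer vector (shifts in m-steps)
#' @export
mseqShifts <- function(x) x@shifts

#' Order of an m-sequence
#' @param x an \linkS4class{MSequence}
#' @return integer
#' @export
mseqOrder <- function(x) x@order

#' Total stimulation duration of a frame schedule
#' @param x a \linkS4class{FrameSchedule}
#' @return numeric, seconds
#' @export
scheduleDuration <- function(x) x@nSteps * x@framesPerStep / x@frameRate

#' Interval between the two global flashes of a schedule
#' @param x a \linkS4class{FrameSchedule}
#' @return numeric, ms
#' @export
globalFlashInterval <- function(x) {
  gf <- which(x@pattern == "GF")
  diff(gf) * 1000 / x@frameRate
}

#' Epoch RMS values of an eye
#' @param x an \linkS4class{EpochRMS}
#' @return named numeric (dc10, ic1_10, ic2_10, dc15, ic1_15, ic2_15), uV
#' @export
rmsValues <- function(x) x@values

#' AUC of a ROC result
#' @param x a \linkS4class{ROCResult}
#' @return numeric in [0, 1]
#' @export
aucValue <- function(x) x@auc

#' Standard error of an AUC (DeLong estimator)
#' @param x a \linkS4class{ROCResult}
#' @return numeric
#' @export
aucSE <- function(x) x@seAuc

#' Scores underlying a ROC result
#' @param x a \linkS4class{ROCResult}
#' @return numeric vector of logistic scores
#' @export
rocScores <- function(x) x@scores

#' Slope of a structure-function fit
#' @param x a \linkS4class{ModelFit}
#' @return numeric regression coefficient
#' @export
fitSlope <- function(x) x@slope

#' 95 percent confidence interval of a fit
#' @param x a \linkS4class{ModelFit}
#' @return numeric length 2
#' @export
fitCI <- function(x) x@ci95

#' p-value of a structure-function fit
#' @param x a \linkS4class{ModelFit}
#' @return numeric
#' @export
fitP <- function(x) x@pValue

#' Flags of an abnormality classification as a logical vector
#' @param x an \linkS4class{AbnormalityFlags}
#' @return named logical (sap, mferg, mT, gcipl)
#' @export
flagVector <- function(x) {
  c(sap = x@sapAbnormal, mferg = x@mfergAbnormal,
    mT = x@mtAbnormal, gcipl = x@gciplAbnormal)
}

#' Percentage table of a cross-tabulation
#' @param x a \linkS4class{CrossTab}
#' @return data.frame with category, count, denominator, percent
#' @export
crosstabPercentages <- function(x) x@percentages

setMethod("show", "HexLayout", function(object) {
  cat("HexLayout '", object@preset, "': ", nHexagons(object),
      " hexagons, rings 0-", max(object@ring), ", extent ",
      sprintf("%.1f", 2 * max(sqrt(rowSums(object@centers^2)))),
      " deg diameter\n", sep = "")
})

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask '", object@label, "' (", object@modality, "): ",
      length(object@memberIds), " members\n", sep = "")
})

setMethod("show", "MSequence", function(object) {
  cat("MSequence: order ", object@order, ", length ", length(object@bits),
      ", taps {", paste(object@taps, collapse = ","), "}, ",
      length(object@shifts), " hexagon shifts\n", sep = "")
})

setMethod("show", "FrameSchedule", function(object) {
  cat("FrameSchedule: ", object@frameRate, " Hz, ", object@framesPerStep,
      " frames/step [", paste(object@pattern, collapse = ","), "], ",
      object@nSteps, " steps, ", object@nSegments, " segments, total ",
      sprintf("%.2f", scheduleDuration(object)), " s\n", sep = "")
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:",
      paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
            collapse = ", "),
      sprintf("(total %d eyes)\n", sum(object@groupSizes)))
})

setMethod("show", "EyeRecord", function(object) {
  cat("EyeRecord ", object@eyeId, ": ", object@group, ", age ",
      round(object@age, 1), ", ", object@gender, ", ", object@laterality,
      "; ", nrow(object@kernels), " hexagon waveforms",
      if (length(object@traceSegments))
        sprintf(", %d trace segments", length(object@traceSegments)) else "",
      "\n", sep = "")
})

setMethod("show", "EpochRMS", function(object) {
  cat("EpochRMS ", object@eyeId, " (uV):\n", sep = "")
  print(round(object@values, 4))
})

setMethod("show", "NormativeDB", function(object) {
  cat("NormativeDB from", object@nControls, "control eyes,",
      nrow(object@features), "features,", nrow(object@sapPointDeviation),
      "SAP points (seed", object@seed, ")\n")
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: %s ~ %s %s| slope %.4g [%.4g, %.4g], p = %.3g%s\n",
              object@response, object@predictor,
              if (object@mixed) "(mixed) " else "",
              object@slope, object@ci95[1], object@ci95[2], object@pValue,
              if (!is.na(object@pFdr))
                sprintf(", p_fdr = %.3g", object@pFdr) else ""))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult %s: AUC %.3f (SE %.3f), %d cases / %d controls\n",
              object@marker, object@auc, object@seAuc,
              object@nCases, object@nControls))
})

setMethod("show", "AbnormalityFlags", function(object) {
  v <- flagVector(object)
  cat("AbnormalityFlags ", object@eyeId, ": ",
      paste(sprintf("%s=%s", names(v), ifelse(v, "abnormal", "normal")),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "CrossTab", function(object) {
  cat("CrossTab over", object@nEyes, "eyes (", object@nGciplThin,
      "with GCIPL thinning):\n")
  print(object@percentages, row.names = FALSE)
})
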