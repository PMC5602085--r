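# Perimetry summaries: point-wise dB -> linear conversion, regional mean
# linear sensitivity (MS) and mean defect (MD, in dB), per-point
# probability classes from the control normative database.

#' Convert decibel sensitivity to linear units
#'
#' Point sensitivities are converted individually (10^(dB/10)) before any
#' averaging: the mean of linear sensitivities is not the linear value of
#' the mean dB.
#'
#' @param db sensitivity in dB (vectorized)
#' @return linear sensitivity (relative 1/Lambert units)
#' @examples
#' dbToLinear(c(0, 10))          # 1, 10
#' mean(dbToLinear(c(20, 30)))   # 550, not 10^2.5
#' @export
dbToLinear <- function(db) {
  if (any(!is.finite(db))) stop("dB sensitivities must be finite")
  10^(db / 10)
}

#' Convert linear sensitivity to dB
#' @param x linear sensitivity (> 0)
#' @return dB
#' @export
linearToDb <- function(x) 10 * log10(x)

#' Regional perimetry summary
#'
#' Computes, over the central-10 and central-15 point masks: MS (mean of the
#' point-wise linear sensitivities) and MD (mean of age-corrected normal dB
#' minus measured dB, positive = loss, kept in dB). Each point also receives
#' a probability class from the normative point-wise deviation quantiles
#' (\code{">=5%"} down to \code{"<0.5%"}), mimicking a device probability
#' plot.
#'
#' @param field data.frame (point_id, x_deg, y_deg, sensitivity_db)
#' @param normative a \linkS4class{NormativeDB} covering all points
#' @param mask10,mask15 \linkS4class{RegionMask}s from
#'   \code{\link{selectSapPoints}}
#' @param age subject age, years (for the normative age correction)
#' @param eyeId id recorded in the result
#' @return a \linkS4class{FieldSummary}
#' @export
regionalFieldSummary <- function(field, normative, mask10, mask15, age = 50,
                                 eyeId = "eye") {
  stopifnot(is(normative, "NormativeDB"))
  if (!all(field$point_id %in% names(normative@sapNormalDb)))
    stop("normative database does not cover all field points")
  normDb <- normative@sapNormalDb[as.character(field$point_id)] -
    normative@ageSlopeDbPerDecade * (age - normative@ageRef) / 10
  dev <- normDb - field$sensitivity_db
  lin <- dbToLinear(field$sensitivity_db)

  i10 <- match(mask10@memberIds, field$point_id)
  i15 <- match(mask15@memberIds, field$point_id)
  if (anyNA(i10) || anyNA(i15))
    stop("mask references points missing from the field")

  q <- normative@sapPointDeviation
  qi <- match(field$point_id, q$point_id)
  prob <- rep(">=5%", nrow(field))
  prob[dev > q$q95[qi]] <- "<5%"
  prob[dev > q$q98[qi]] <- "<2%"
  prob[dev > q$q99[qi]] <- "<1%"
  prob[dev > q$q995[qi]] <- "<0.5%"

  new("FieldSummary", eyeId = eyeId,
      ms10Linear = mean(lin[i10]), ms15Linear = mean(lin[i15]),
      md10Db = mean(dev[i10]), md15Db = mean(dev[i15]),
      globalMdDb = mean(dev), pointProb = prob,
      pointIds = as.integer(field$point_id))
}
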