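# Per-eye multimodal abnormality classification in the central 15 degrees
# and cross-tabulated modality agreement.

#' Classify one eye against the control normative database
#'
#' Applies the central-area abnormality criteria:
#' \itemize{
#'   \item SAP: at least one central-15-degree point with a probability
#'     class below 0.5 percent.
#'   \item 2F-mfERG: a regional RMS average (DC, IC1 and/or IC2) outside
#'     the 95 percent quantile of controls. Read one-sided by default
#'     (below the control 5th percentile), because glaucomatous damage
#'     reduces response amplitude; \code{twoSided = TRUE} also flags values
#'     above the 95th percentile.
#'   \item OCT (mT and GCIPL separately): at least one sector flagged
#'     yellow or red (at or below the control 5th / 1st percentile).
#' }
#'
#' @param fieldSummary a \linkS4class{FieldSummary}
#' @param epochRms an \linkS4class{EpochRMS}
#' @param octSum an \linkS4class{OctSummary} with sector flags
#' @param normative the \linkS4class{NormativeDB} used throughout
#' @param sapMask15 \linkS4class{RegionMask} of the central-15 SAP points
#' @param mfergRegion \code{"15"} (default) or \code{"10"}: which regional
#'   averages the mfERG criterion is evaluated on
#' @param twoSided logical, see above
#' @return an \linkS4class{AbnormalityFlags}
#' @export
classifyEye <- function(fieldSummary, epochRms, octSum, normative, sapMask15,
                        mfergRegion = c("15", "10"), twoSided = FALSE) {
  mfergRegion <- match.arg(mfergRegion)
  sel <- fieldSummary@pointIds %in% sapMask15@memberIds
  sapBad <- fieldSummary@pointProb[sel] == "<0.5%"
  sapAb <- any(sapBad)

  feats <- paste0(c("dc", "ic1_", "ic2_"), mfergRegion)
  idx <- match(feats, normative@features$feature)
  if (anyNA(idx)) stop("normative database lacks regional mfERG features")
  vals <- rmsValues(epochRms)[feats]
  low <- vals < normative@features$q05[idx]
  high <- vals > normative@features$q95[idx]
  mfergAb <- any(low) || (twoSided && any(high))

  mtAb <- any(octSum@sectorFlags$mT %in% c("yellow", "red"))
  gciplAb <- any(octSum@sectorFlags$GCIPL %in% c("yellow", "red"))

  new("AbnormalityFlags", eyeId = fieldSummary@eyeId,
      sapAbnormal = sapAb, mfergAbnormal = mfergAb, mtAbnormal = mtAb,
      gciplAbnormal = gciplAb,
      details = list(
        sap_points = fieldSummary@pointIds[sel][sapBad],
        mferg_epochs = feats[low | (twoSided & high)],
        mT_sectors = names(octSum@sectorFlags$mT)[
          octSum@sectorFlags$mT %in% c("yellow", "red")],
        gcipl_sectors = names(octSum@sectorFlags$GCIPL)[
          octSum@sectorFlags$GCIPL %in% c("yellow", "red")]))
}

#' Flags of many eyes as a data.frame
#'
#' @param flags list of \linkS4class{AbnormalityFlags}
#' @param groups optional character vector of group labels per eye
#' @return data.frame (eye_id, group, sap, mferg, mT, gcipl)
#' @export
flagTable <- function(flags, groups = NULL) {
  out <- do.call(rbind, lapply(flags, function(f)
    data.frame(eye_id = f@eyeId, sap = f@sapAbnormal,
               mferg = f@mfergAbnormal, mT = f@mtAbnormal,
               gcipl = f@gciplAbnormal)))
  if (!is.null(groups)) out <- cbind(out[1], group = groups, out[-1])
  out
}

#' Cross-tabulate modality agreement
#'
#' Counts and percentages of the flag combinations of the multimodal
#' analysis, with explicit denominators: over all eyes - no alterations,
#' mfERG-only, abnormal mT and GCIPL, GCIPL thinning with normal mT,
#' abnormal mT with normal GCIPL, and mfERG + GCIPL alterations without a
#' SAP defect; and, among eyes with GCIPL thinning - abnormal mfERG with
#' normal SAP, SAP defect with normal mfERG, and both.
#'
#' @param flags data.frame as from \code{\link{flagTable}}, or a list of
#'   \linkS4class{AbnormalityFlags}
#' @return a \linkS4class{CrossTab}
#' @export
crosstabReport <- function(flags) {
  if (is.list(flags) && !is.data.frame(flags)) flags <- flagTable(flags)
  if (nrow(flags) < 1L) stop("need at least one eye")
  n <- nrow(flags)
  thin <- flags$gcipl
  nThin <- sum(thin)
  counts <- c(
    none = sum(!flags$sap & !flags$mferg & !flags$mT & !flags$gcipl),
    mferg_only = sum(flags$mferg & !flags$sap & !flags$mT & !flags$gcipl),
    mt_and_gcipl = sum(flags$mT & flags$gcipl),
    gcipl_only = sum(flags$gcipl & !flags$mT),
    mt_only = sum(flags$mT & !flags$gcipl),
    mferg_gcipl_no_sap = sum(flags$mferg & flags$gcipl & !flags$sap),
    thin_mferg_no_sap = sum(thin & flags$mferg & !flags$sap),
    thin_sap_no_mferg = sum(thin & flags$sap & !flags$mferg),
    thin_both = sum(thin & flags$sap & flags$mferg))
  denom <- c(rep(n, 6L), rep(max(nThin, 1L), 3L))
  pct <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    denominator = as.integer(denom),
                    percent = 100 * as.integer(counts) / denom)
  new("CrossTab", counts = setNames(as.integer(counts), names(counts)),
      percentages = pct, nEyes = as.integer(n), nGciplThin = as.integer(nThin))
}

#' Fixed 26-eye example flag table
#'
#' A fixed cross-tabulation example: 26 early-glaucoma eyes (6
#' preperimetric, 20 with field defects) with per-modality abnormality
#' flags, in which 8 of 26 eyes (30.8 percent) show mfERG and GCIPL
#' alterations without a central SAP defect, and 8 of the 23 GCIPL-thin
#' eyes (34.8 percent) show an abnormal mfERG with a normal field. Used in
#' tests and documentation of \code{\link{crosstabReport}}.
#'
#' @return data.frame (eye_id, group, sap, mferg, mT, gcipl)
#' @export
referenceFlagTable <- function() {
  f <- function(sap, mferg, mT, gcipl, k)
    data.frame(sap = rep(sap, k), mferg = mferg, mT = mT, gcipl = gcipl)
  tab <- rbind(
    cbind(group = "PPG", rbind(
      f(FALSE, FALSE, FALSE, FALSE, 1),   # fully normal
      f(FALSE, TRUE, FALSE, FALSE, 1),    # mfERG only
      f(FALSE, TRUE, TRUE, TRUE, 2),      # mfERG+, no field defect
      f(FALSE, FALSE, TRUE, TRUE, 1),
      f(FALSE, TRUE, FALSE, TRUE, 1))),   # GCIPL thin, mT normal
    cbind(group = "POAG", rbind(
      f(FALSE, TRUE, FALSE, TRUE, 3),
      f(FALSE, FALSE, FALSE, TRUE, 2),
      f(TRUE, FALSE, TRUE, FALSE, 1),     # mT abnormal, GCIPL normal
      f(FALSE, TRUE, TRUE, TRUE, 2),
      f(TRUE, FALSE, TRUE, TRUE, 4),      # field defect, mfERG normal
      f(TRUE, TRUE, TRUE, TRUE, 3),
      f(FALSE, FALSE, TRUE, TRUE, 5))))
  cbind(eye_id = sprintf("ex%02d", seq_len(nrow(tab))), tab)
}
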