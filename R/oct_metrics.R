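# OCT summaries: ETDRS 1+3 mm central macular thickness, GCIPL elliptical
# annulus mean, control normative database and sector abnormality flags.

#' Default GCIPL annulus geometry
#'
#' Elliptical annulus of 4.0 mm vertical and 4.8 mm horizontal outer
#' diameter with a 1 mm foveolar exclusion, i.e. the central 13.2 x 15.8
#' degrees at 3.3 deg/mm.
#'
#' @return an \linkS4class{AnnulusSpec}
#' @export
defaultAnnulus <- function() {
  new("AnnulusSpec", verticalDiameter = 4.0, horizontalDiameter = 4.8,
      innerExclusionDiameter = 1.0)
}

#' Central macular thickness (ETDRS 1 + 3 mm)
#'
#' Area-weighted mean of the ETDRS center sector (1 mm disk) and the four
#' inner-ring sectors (1-3 mm annulus quadrants); the outer ring is ignored.
#' Weights are the sector areas: pi * 0.5^2 for the center and
#' pi * (1.5^2 - 0.5^2) / 4 per inner quadrant.
#'
#' @param sectorValues named numeric of 9 ETDRS sector thicknesses (um):
#'   \code{center}, \code{inner_sup/nas/inf/tem}, \code{outer_sup/nas/inf/tem}
#' @return central thickness, um
#' @examples
#' s <- c(center = 250, inner_sup = 310, inner_nas = 310, inner_inf = 310,
#'        inner_tem = 310, outer_sup = 999, outer_nas = 999,
#'        outer_inf = 999, outer_tem = 999)
#' etdrsCentralMT(s)  # 303.33: outer ring ignored
#' @export
etdrsCentralMT <- function(sectorValues) {
  need <- c("center", paste0("inner_", c("sup", "nas", "inf", "tem")))
  if (!all(need %in% names(sectorValues)))
    stop("missing ETDRS sectors: ",
         paste(setdiff(need, names(sectorValues)), collapse = ", "))
  aC <- pi * 0.5^2
  aI <- pi * (1.5^2 - 0.5^2)
  (sectorValues["center"] * aC +
      mean(sectorValues[need[-1]]) * aI) / (aC + aI)
}

#' GCIPL elliptical-annulus mean thickness
#'
#' For sector input (the 6 device sectors), the unweighted sector mean: the
#' device's sectors are near-equal-area by construction of its annulus. For
#' a thickness map given as a function \code{f(x_mm, y_mm)}, the mean is
#' computed by numeric integration over the elliptical annulus; the central
#' exclusion zone never contributes.
#'
#' @param x either a numeric vector of 6 sector thicknesses (um) or a
#'   vectorized function \code{f(x_mm, y_mm)} returning thickness
#' @param spec an \linkS4class{AnnulusSpec} (default \code{defaultAnnulus()})
#' @param gridStep integration grid step, mm (map input only)
#' @return mean thickness, um
#' @export
gciplAnnulusMean <- function(x, spec = defaultAnnulus(), gridStep = 0.01) {
  stopifnot(is(spec, "AnnulusSpec"))
  if (is.numeric(x)) {
    if (length(x) != 6L) stop("sector input must have 6 sectors")
    return(mean(x))
  }
  if (!is.function(x)) stop("x must be 6 sector values or a map function")
  a <- spec@horizontalDiameter / 2
  b <- spec@verticalDiameter / 2
  r0 <- spec@innerExclusionDiameter / 2
  gx <- seq(-a, a, by = gridStep)
  gy <- seq(-b, b, by = gridStep)
  pts <- expand.grid(x = gx, y = gy)
  inside <- (pts$x / a)^2 + (pts$y / b)^2 <= 1 &
    pts$x^2 + pts$y^2 > r0^2
  mean(x(pts$x[inside], pts$y[inside]))
}

#' Build the control normative database
#'
#' Computes, from the control eyes of a cohort, the empirical quantiles
#' (linear interpolation) that the abnormality criteria use: per-feature
#' 1st/5th/95th percentiles for the regional mfERG epoch RMS averages, the
#' OCT summaries and every OCT sector; and per-SAP-point deviation quantiles
#' (95/98/99/99.5) for the probability classes. Only control-group records
#' contribute.
#'
#' @param eyes list of \linkS4class{EyeRecord}s (non-control eyes are
#'   dropped)
#' @param layout the \linkS4class{HexLayout} the eyes were simulated on
#' @param windows epoch windows (default \code{\link{epochWindows}})
#' @param ageSlopeDbPerDecade normative perimetry age-correction slope
#' @param seed provenance tag stored in the database
#' @return a \linkS4class{NormativeDB}
#' @export
buildNormativeDB <- function(eyes, layout, windows = epochWindows(),
                             ageSlopeDbPerDecade = 0.1, seed = NA_integer_) {
  eyes <- Filter(function(e) e@group == "control", eyes)
  if (length(eyes) < 5L)
    stop("need at least 5 control eyes to build a normative database")
  m10 <- centralHexagons(layout, 1L)
  m15 <- centralHexagons(layout, 2L)

  featRows <- lapply(eyes, function(e) {
    ks <- new("KernelSet", waveforms = e@kernels, times = e@kernelTimes,
              sampleRate = e@sampleRate)
    rms <- rmsValues(regionalRMS(ks, m10, m15, windows, e@eyeId))
    c(rms, mt_central = unname(etdrsCentralMT(e@octMT)),
      gcipl_mean = unname(gciplAnnulusMean(e@octGCIPL)),
      setNames(as.numeric(e@octMT), paste0("mT_", names(e@octMT))),
      setNames(as.numeric(e@octGCIPL), names(e@octGCIPL)))
  })
  fm <- do.call(rbind, featRows)
  features <- data.frame(feature = colnames(fm),
                         q01 = apply(fm, 2, quantile, 0.01, names = FALSE),
                         q05 = apply(fm, 2, quantile, 0.05, names = FALSE),
                         q95 = apply(fm, 2, quantile, 0.95, names = FALSE),
                         row.names = NULL)

  ageRef <- mean(vapply(eyes, function(e) e@age, numeric(1)))
  pts <- eyes[[1]]@sapField[, c("point_id", "x_deg", "y_deg")]
  adjDb <- vapply(eyes, function(e) {
    e@sapField$sensitivity_db +
      ageSlopeDbPerDecade * (e@age - ageRef) / 10
  }, numeric(nrow(pts)))
  sapNormalDb <- setNames(rowMeans(adjDb), as.character(pts$point_id))
  devs <- sapNormalDb - adjDb            # deviation per point x eye
  sapPointDeviation <- data.frame(
    point_id = pts$point_id,
    q95 = apply(devs, 1, quantile, 0.95, names = FALSE),
    q98 = apply(devs, 1, quantile, 0.98, names = FALSE),
    q99 = apply(devs, 1, quantile, 0.99, names = FALSE),
    q995 = apply(devs, 1, quantile, 0.995, names = FALSE))

  new("NormativeDB", features = features,
      sapPointDeviation = sapPointDeviation, sapNormalDb = sapNormalDb,
      ageRef = ageRef, ageSlopeDbPerDecade = ageSlopeDbPerDecade,
      nControls = length(eyes), seed = as.integer(seed))
}

#' Flag OCT sectors against normative percentiles
#'
#' \code{"red"} if the sector value is at or below the control 1st
#' percentile, \code{"yellow"} if at or below the 5th percentile (but above
#' the 1st), \code{"normal"} otherwise. Boundaries are inclusive.
#'
#' @param sectorValues named numeric sector thicknesses (um); names must
#'   match normative feature names (e.g. \code{gcipl_s1}, \code{mT_center})
#' @param normative a \linkS4class{NormativeDB}
#' @return named character flags
#' @export
flagSectors <- function(sectorValues, normative) {
  idx <- match(names(sectorValues), normative@features$feature)
  if (anyNA(idx))
    stop("sectors absent from normative database: ",
         paste(names(sectorValues)[is.na(idx)], collapse = ", "))
  q01 <- normative@features$q01[idx]
  q05 <- normative@features$q05[idx]
  flags <- rep("normal", length(sectorValues))
  flags[sectorValues <= q05] <- "yellow"
  flags[sectorValues <= q01] <- "red"
  setNames(flags, names(sectorValues))
}

#' Per-eye OCT summary
#'
#' @param eye an \linkS4class{EyeRecord}
#' @param normative optional \linkS4class{NormativeDB} for sector flags
#' @return an \linkS4class{OctSummary}
#' @export
octSummary <- function(eye, normative = NULL) {
  mt <- unname(etdrsCentralMT(eye@octMT))
  gc <- unname(gciplAnnulusMean(eye@octGCIPL))
  flags <- list(mT = rep(NA_character_, 9), GCIPL = rep(NA_character_, 6))
  if (!is.null(normative)) {
    flags$mT <- flagSectors(setNames(as.numeric(eye@octMT),
                                     paste0("mT_", names(eye@octMT))),
                            normative)
    flags$GCIPL <- flagSectors(setNames(as.numeric(eye@octGCIPL),
                                        names(eye@octGCIPL)), normative)
  }
  new("OctSummary", eyeId = eye@eyeId, mtCentral = mt, gciplMean = gc,
      sectorValues = list(mT = eye@octMT, GCIPL = eye@octGCIPL),
      sectorFlags = flags)
}
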