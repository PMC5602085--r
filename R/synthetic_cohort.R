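# Synthetic three-group cohort generator. A latent per-eye structural-loss
# variable (scaled so that one unit equals `gciplLossScale` um of GCIPL)
# jointly drives the inner-retinal component of the focal response (hence
# DC/IC1/IC2 amplitudes), GCIPL and macular thinning, and - through a
# group-specific coupling - SAP sensitivity loss, with age and gender
# confounding. Group-level defaults reproduce the demographic and thickness
# structure of an early-glaucoma case-control cohort (16 control, 6 PPG,
# 20 POAG eyes).

#' Construct a synthetic cohort design
#'
#' Returns the default \linkS4class{CohortDesign}: per-group sizes, ages,
#' gender mix, GCIPL / central macular thickness distributions (um) and SAP
#' mean-defect distributions (dB), plus the coupling and noise parameters of
#' the generator (see the methods vignette). All arguments override the
#' defaults; per-group vectors are named \code{control, PPG, POAG}.
#'
#' @param groupSizes integer, eyes per group.
#' @param ageMean,ageSD years.
#' @param maleProp proportion of male subjects per group.
#' @param gciplMean,gciplSD GCIPL annulus mean, um.
#' @param mtMean,mtSD ETDRS 1+3 mm macular thickness, um.
#' @param mdMean,mdSD SAP mean defect, dB (positive = loss).
#' @param gciplLossScale um of GCIPL per unit latent loss.
#' @param mtLossScale um of central mT per unit latent loss.
#' @param sapCoupling dB of extra field loss per unit within-group excess
#'   structural loss.
#' @param noise named numeric: \code{gcipl} (um), \code{sector} (um),
#'   \code{sapDb} (dB per point), \code{gain} (log-SD of the per-eye mfERG
#'   amplitude factor), \code{waveUv} (white noise SD on kernel waveforms,
#'   uV), \code{traceUv} (white noise SD on raw traces, uV).
#' @param spatialSD SD of the smooth per-hexagon integrity modulation.
#' @param eyesPerSubject 1 (default) or 2; with 2, consecutive eyes share a
#'   subject (same age/gender, correlated loss), exercising the mixed-model
#'   random intercept.
#' @return a \linkS4class{CohortDesign}
#' @export
cohortDesign <- function(groupSizes = c(control = 16L, PPG = 6L, POAG = 20L),
                         ageMean = c(control = 49.2, PPG = 63, POAG = 60.6),
                         ageSD = c(control = 7.02, PPG = 15.9, POAG = 12.4),
                         maleProp = c(control = 2 / 16, PPG = 5 / 6,
                                      POAG = 17 / 21),
                         gciplMean = c(control = 80.7, PPG = 68.2,
                                       POAG = 65.4),
                         gciplSD = c(control = 4.7, PPG = 10.2, POAG = 9.3),
                         mtMean = c(control = 308.4, PPG = 302.6,
                                    POAG = 296.5),
                         mtSD = c(control = 12.7, PPG = 15.8, POAG = 18.7),
                         mdMean = c(control = 0.12, PPG = -0.08, POAG = 4.7),
                         mdSD = c(control = 1.84, PPG = 0.62, POAG = 4.56),
                         gciplLossScale = 30, mtLossScale = 23,
                         sapCoupling = c(control = 0, PPG = 0, POAG = 8),
                         noise = c(gcipl = 1.5, sector = 2.5, sapDb = 1.2,
                                   gain = 0.045, waveUv = 0.05,
                                   traceUv = 0.15),
                         spatialSD = 0.08, eyesPerSubject = 1L) {
  new("CohortDesign",
      groupSizes = setNames(as.integer(groupSizes), names(groupSizes)),
      ageMean = ageMean,
      ageSD = ageSD, maleProp = maleProp, gciplMean = gciplMean,
      gciplSD = gciplSD, mtMean = mtMean, mtSD = mtSD, mdMean = mdMean,
      mdSD = mdSD, gciplLossScale = gciplLossScale, mtLossScale = mtLossScale,
      sapCoupling = sapCoupling, noise = noise, spatialSD = spatialSD,
      eyesPerSubject = as.integer(eyesPerSubject))
}

#' Focal response waveform template
#'
#' The per-hexagon first-order response model: a biphasic outer-retina
#' component (negative lobe near 20 ms, positive lobe near 32 ms) plus
#' inner-retina terms scaled by the local ganglion integrity \code{g} in
#' [0, 1]: an adaptive enhancement of the direct component and the two
#' induced responses to the global flashes (peaks near 57 and 85 ms). With
#' \code{g = 1} (healthy) the template's epoch RMS values are about 0.87
#' (DC), 0.55 (IC1) and 0.51 (IC2) uV.
#'
#' @param g ganglion integrity scalar (1 = healthy, 0 = complete loss)
#' @param times numeric, ms (default 0-105 ms at 1200 Hz)
#' @return numeric waveform, uV
#' @export
responseTemplate <- function(g, times = kernelTimeGrid()) {
  gpk <- function(mu, s) exp(-(times - mu)^2 / (2 * s^2))
  -0.5 * gpk(20, 3) + (1.2 + 0.4 * g) * gpk(32, 5) +
    g * (0.9 * gpk(57, 6) + 0.8 * gpk(85, 7))
}

#' Default kernel epoch time grid
#' @param sampleRate Hz (default 1200)
#' @param epochMs epoch length, ms (default 105)
#' @return numeric, ms
#' @export
kernelTimeGrid <- function(sampleRate = 1200, epochMs = 105) {
  n <- as.integer(ceiling(epochMs / 1000 * sampleRate)) + 1L
  (0:(n - 1L)) / sampleRate * 1000
}

#' Age-referenced normal SAP sensitivity
#'
#' Normative hill-of-vision model used by the generator and (through the
#' control sample) by the perimetry normative database: a linear decline
#' with eccentricity and a small age-correction slope.
#'
#' @param x,y point coordinates, degrees
#' @param age years
#' @param ageRef reference age (default 50)
#' @param ageSlopeDbPerDecade sensitivity decline per decade (default 0.1)
#' @return sensitivity, dB
#' @export
normalSensitivityDb <- function(x, y, age = 50, ageRef = 50,
                                ageSlopeDbPerDecade = 0.1) {
  ecc <- sqrt(x^2 + y^2)
  32 - 0.25 * ecc - ageSlopeDbPerDecade * (age - ageRef) / 10
}

# group-level latent loss mean on the unit scale of gciplLossScale
groupLossMean <- function(design, group) {
  (design@gciplMean["control"] - design@gciplMean[group]) /
    design@gciplLossScale
}

# smooth per-hexagon modulation field: iid noise averaged over neighbours
smoothHexField <- function(layout, sdTarget, radiusDeg = 6) {
  ctr <- hexCenters(layout)
  d <- as.matrix(stats::dist(ctr))
  w <- d <= radiusDeg
  z <- rnorm(nrow(ctr))
  sm <- as.numeric(w %*% z) / rowSums(w)
  if (sd(sm) > 0) sm <- sm / sd(sm) * sdTarget
  sm
}

#' Simulate one eye
#'
#' Draws a latent structural loss for the eye from its group's distribution,
#' expands it into a spatially smooth per-hexagon integrity field, and
#' generates all modalities from it: per-hexagon response waveforms (and,
#' optionally, the full raw trace segments they are embedded in), the SAP
#' sensitivity field, and OCT sector thicknesses. Uses the caller's RNG
#' state; seed via \code{\link{simulateCohort}} or \code{set.seed} for
#' reproducibility.
#'
#' @param design a \linkS4class{CohortDesign}
#' @param group \code{"control"}, \code{"PPG"} or \code{"POAG"}
#' @param layout a \linkS4class{HexLayout}
#' @param traces logical; if TRUE, synthesize the continuous segment traces
#'   (requires \code{mseq} and \code{schedule})
#' @param mseq,schedule stimulus objects, required when \code{traces = TRUE}
#' @param sampleRate Hz (default 1200)
#' @param pointTable perimetry point table (default \code{\link{sapPointTable}})
#' @param eyeId,subjectId,laterality identifiers
#' @param age,gender,lossLatent optional overrides; drawn from the design
#'   when NULL
#' @return an \linkS4class{EyeRecord}
#' @export
simulateEye <- function(design, group, layout, traces = FALSE, mseq = NULL,
                        schedule = NULL, sampleRate = 1200,
                        pointTable = sapPointTable(), eyeId = "eye1",
                        subjectId = "subj1", laterality = "OD",
                        age = NULL, gender = NULL, lossLatent = NULL) {
  if (!group %in% c("control", "PPG", "POAG"))
    stop("unknown group label: ", group)
  nz <- design@noise
  L <- design@gciplLossScale
  S <- groupLossMean(design, group)
  sdLoss <- sqrt(max(design@gciplSD[group]^2 - nz["gcipl"]^2, 0.25)) / L

  if (is.null(age)) age <- max(35, min(85,
    rnorm(1, design@ageMean[group], design@ageSD[group])))
  if (is.null(gender))
    gender <- if (runif(1) < design@maleProp[group]) "M" else "F"
  if (is.null(lossLatent)) lossLatent <- rnorm(1, S, sdLoss)
  loss <- unname(lossLatent)

  # OCT: GCIPL carries the latent; mT couples to it within group
  gcipl <- design@gciplMean[group] - L * (loss - S) + rnorm(1, 0, nz["gcipl"]) -
    0.1 * (age - design@ageMean[group])
  mtResid <- sqrt(max(design@mtSD[group]^2 - (design@mtLossScale * sdLoss)^2,
                      4))
  mt <- design@mtMean[group] - design@mtLossScale * (loss - S) +
    rnorm(1, 0, mtResid)
  gcipl <- max(gcipl, 30)
  mt <- max(mt, 150)

  gciplSectors <- gcipl + rnorm(6, 0, nz["sector"])
  gciplSectors <- pmax(gciplSectors - mean(gciplSectors) + gcipl, 30)
  names(gciplSectors) <- paste0("gcipl_s", 1:6)
  ctrVal <- max(mt - 24 + rnorm(1, 0, 2), 120)
  innerTarget <- (9 * mt - ctrVal) / 8
  inner <- innerTarget + rnorm(4, 0, nz["sector"])
  inner <- inner - mean(inner) + innerTarget
  outer <- mt - 15 + rnorm(4, 0, nz["sector"])
  octMT <- pmax(c(ctrVal, inner, outer), 100)
  names(octMT) <- c("center", paste0("inner_", c("sup", "nas", "inf", "tem")),
                    paste0("outer_", c("sup", "nas", "inf", "tem")))

  # mfERG: integrity field scales the inner-retinal response terms
  gEye <- min(max(1 - loss, 0.02), 1.25)
  gHex <- pmin(pmax(gEye * (1 + smoothHexField(layout, design@spatialSD)),
                    0.02), 1.3)
  gain <- exp(rnorm(1, 0, nz["gain"])) *
    (1 - 0.003 * (age - design@ageMean[group]))
  times <- kernelTimeGrid(sampleRate)
  cleanKernels <- gain * t(vapply(gHex, responseTemplate, numeric(length(times)),
                                  times = times))
  kernels <- cleanKernels +
    matrix(rnorm(length(cleanKernels), 0, nz["waveUv"]),
           nrow(cleanKernels))

  # SAP: group-level field loss, deeper where local integrity is lower
  sapLossDb <- design@mdMean[group] +
    design@sapCoupling[group] * (loss - S) +
    rnorm(1, 0, sqrt(max(design@mdSD[group]^2 -
                           (design@sapCoupling[group] * sdLoss)^2, 0.09)))
  ptHex <- nearestHexagon(pointTable, layout)
  rel <- (1 - gHex[ptHex]) + 0.2
  w <- rel / mean(rel)
  normDb <- normalSensitivityDb(pointTable$x_deg, pointTable$y_deg, age)
  measured <- pmin(pmax(normDb - sapLossDb * w -
                          rnorm(nrow(pointTable), 0, nz["sapDb"]), 0), 40)
  sapField <- data.frame(point_id = pointTable$point_id,
                         x_deg = pointTable$x_deg, y_deg = pointTable$y_deg,
                         sensitivity_db = measured)

  segs <- list()
  if (traces) {
    if (is.null(mseq) || is.null(schedule))
      stop("traces = TRUE requires mseq and schedule")
    segs <- synthesizeSegments(cleanKernels, mseq, schedule, sampleRate,
                               noiseUv = nz["traceUv"])
  }

  new("EyeRecord", eyeId = eyeId, subjectId = subjectId, group = group,
      age = age, gender = gender, laterality = laterality,
      kernels = unname(kernels), kernelTimes = times,
      traceSegments = segs, sampleRate = sampleRate, sapField = sapField,
      octMT = octMT, octGCIPL = gciplSectors,
      latent = list(loss = loss, gHex = gHex, gain = gain,
                    sapLossDb = unname(sapLossDb)))
}

# id of the hexagon nearest each perimetry point
nearestHexagon <- function(pointTable, layout) {
  ctr <- hexCenters(layout)
  vapply(seq_len(nrow(pointTable)), function(i) {
    which.min((ctr[, 1] - pointTable$x_deg[i])^2 +
                (ctr[, 2] - pointTable$y_deg[i])^2)
  }, integer(1))
}

#' Synthesize raw trace segments from per-hexagon waveforms
#'
#' Builds the continuous recording implied by the stimulus: at every m-step
#' in which a hexagon is "on" (after its circular shift), its response
#' waveform is added at the m-frame onset; responses overlap into the next
#' step, and the recording wraps circularly. 1/f-like plus white noise is
#' superimposed, and the trace is cut into the schedule's segments.
#'
#' @param kernels numeric matrix (hexagons x epoch samples), uV
#' @param mseq an \linkS4class{MSequence} with one shift per kernel row
#' @param schedule a \linkS4class{FrameSchedule}
#' @param sampleRate Hz
#' @param noiseUv white-noise SD, uV (a slow 1/f-like component of equal
#'   power is added as well); 0 disables noise
#' @return list of numeric segment traces
#' @export
synthesizeSegments <- function(kernels, mseq, schedule, sampleRate,
                               noiseUv = 0.15) {
  N <- length(mseq@bits)
  if (nrow(kernels) != length(mseq@shifts))
    stop("one m-sequence shift per kernel row required")
  sps <- sampleRate * schedule@framesPerStep / schedule@frameRate
  if (abs(sps - round(sps)) > 1e-9)
    stop("sampleRate must give an integer number of samples per m-step")
  sps <- as.integer(round(sps))
  L <- N * sps
  B <- t(vapply(mseq@shifts,
                function(s) as.numeric(shiftBits(mseq@bits, s)),
                numeric(N)))
  S <- crossprod(B, kernels)            # per-step summed injected waveform
  trace <- numeric(L)
  starts <- (seq_len(N) - 1L) * sps
  for (j in seq_len(ncol(S))) {
    idx <- (starts + j - 1L) %% L + 1L
    trace[idx] <- trace[idx] + S[, j]
  }
  if (noiseUv > 0) {
    white <- rnorm(L, 0, noiseUv)
    slow <- as.numeric(stats::filter(rnorm(L, 0, noiseUv * 0.05), 0.999,
                                     method = "recursive"))
    trace <- trace + white + slow
  }
  bd <- segmentBoundaries(schedule)
  lapply(seq_len(nrow(bd)), function(i) {
    trace[((bd$first_step[i] - 1L) * sps + 1L):(bd$last_step[i] * sps)]
  })
}

#' Simulate a complete cohort
#'
#' Generates all eyes of the design with a fixed seed (bit-identical on
#' re-run). With \code{eyesPerSubject = 2}, consecutive eyes within a group
#' share a subject: same age and gender, latent loss correlated between
#' fellow eyes.
#'
#' @param design a \linkS4class{CohortDesign}
#' @param layout a \linkS4class{HexLayout}
#' @param seed integer RNG seed
#' @param traces,mseq,schedule,sampleRate,pointTable passed to
#'   \code{\link{simulateEye}}
#' @return list of \linkS4class{EyeRecord}s, with the cohort manifest
#'   data.frame in attribute \code{"manifest"}
#' @examples
#' eyes <- simulateCohort(cohortDesign(), buildHexLayout(), seed = 1)
#' length(eyes)  # 42
#' @export
simulateCohort <- function(design, layout, seed = 1L, traces = FALSE,
                           mseq = NULL, schedule = NULL, sampleRate = 1200,
                           pointTable = sapPointTable()) {
  stopifnot(is(design, "CohortDesign"))
  set.seed(seed)
  eyes <- list()
  k <- 0L
  subj <- 0L
  for (group in c("control", "PPG", "POAG")) {
    n <- design@groupSizes[group]
    if (n == 0L) next
    # fixed gender composition per group (as a demographics table would
    # report), shuffled across subjects
    nSubjMax <- ceiling(n / design@eyesPerSubject)
    nM <- round(design@maleProp[group] * nSubjMax)
    genders <- sample(c(rep("M", nM), rep("F", nSubjMax - nM)))
    i <- 0L
    sj <- 0L
    while (i < n) {
      subj <- subj + 1L
      sj <- sj + 1L
      nEyesSubj <- min(design@eyesPerSubject, n - i)
      age <- max(35, min(85, rnorm(1, design@ageMean[group],
                                   design@ageSD[group])))
      gender <- genders[sj]
      S <- groupLossMean(design, group)
      sdLoss <- sqrt(max(design@gciplSD[group]^2 -
                           design@noise["gcipl"]^2, 0.25)) /
        design@gciplLossScale
      lossSubj <- rnorm(1, S, sdLoss)
      for (e in seq_len(nEyesSubj)) {
        i <- i + 1L; k <- k + 1L
        loss <- if (design@eyesPerSubject == 2L)
          lossSubj + rnorm(1, 0, sdLoss * 0.3) else lossSubj
        eyes[[k]] <- simulateEye(design, group, layout, traces = traces,
                                 mseq = mseq, schedule = schedule,
                                 sampleRate = sampleRate,
                                 pointTable = pointTable,
                                 eyeId = sprintf("eye%03d", k),
                                 subjectId = sprintf("subj%03d", subj),
                                 laterality = if (e == 1L) "OD" else "OS",
                                 age = age, gender = gender,
                                 lossLatent = loss)
      }
    }
  }
  attr(eyes, "manifest") <- cohortManifest(eyes)
  attr(eyes, "seed") <- as.integer(seed)
  eyes
}

#' Cohort manifest
#'
#' @param eyes list of \linkS4class{EyeRecord}s
#' @return data.frame (eye_id, subject_id, group, age, gender, laterality)
#' @export
cohortManifest <- function(eyes) {
  do.call(rbind, lapply(eyes, function(e)
    data.frame(eye_id = e@eyeId, subject_id = e@subjectId, group = e@group,
               age = e@age, gender = e@gender, laterality = e@laterality)))
}
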