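# Signal chain: artifact rejection, band-pass filtering, first-order kernel
# extraction by m-sequence cross-correlation, epoch RMS and regional
# averaging.

#' Per-hexagon first-order response waveforms
#'
#' @slot waveforms numeric matrix (hexagons x samples), uV.
#' @slot times numeric, ms post m-frame onset (covers at least 0-105 ms).
#' @slot sampleRate numeric, Hz.
#' @exportClass KernelSet
setClass("KernelSet",
  representation(waveforms = "matrix", times = "numeric",
                 sampleRate = "numeric"))

setValidity("KernelSet", function(object) {
  msg <- character()
  if (ncol(object@waveforms) != length(object@times))
    msg <- c(msg, "times must align with waveform columns")
  if (length(object@times) && max(object@times) < 105)
    msg <- c(msg, "waveforms must cover at least 105 ms")
  if (any(!is.finite(object@waveforms)))
    msg <- c(msg, "waveforms must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KernelSet", function(object) {
  cat("KernelSet:", nrow(object@waveforms), "hexagons,",
      length(object@times), "samples at", object@sampleRate, "Hz (0-",
      sprintf("%.1f", max(object@times)), "ms)\n")
})

#' Waveform matrix of a kernel set
#' @param x a \linkS4class{KernelSet}
#' @return numeric matrix (hexagons x samples), uV
#' @export
kernelWaveforms <- function(x) x@waveforms

#' Time axis of a kernel set
#' @param x a \linkS4class{KernelSet}
#' @return numeric vector, ms
#' @export
kernelTimes <- function(x) x@times

#' Two-pass artifact rejection
#'
#' Flags recording segments whose peak amplitude is an outlier relative to
#' the remaining segments and replaces them by the mean of their nearest
#' unflagged neighbours in recording order. The procedure is run
#' \code{passes} times (default 2), so a moderate artifact masked by a gross
#' one in the first pass is caught in the second once the statistics have
#' settled.
#'
#' @param segments list of numeric trace vectors (>= 2)
#' @param zThreshold leave-one-out z-score above which a segment's peak
#'   amplitude is flagged (default 3)
#' @param passes number of passes (default 2)
#' @return list with \code{segments} (cleaned) and \code{log} (per-pass
#'   integer vectors of flagged segment indices)
#' @export
rejectArtifacts <- function(segments, zThreshold = 3, passes = 2L) {
  if (!is.list(segments) || length(segments) < 2L)
    stop("need at least 2 segments")
  n <- length(segments)
  cleaned <- segments
  replaced <- logical(n)
  log <- vector("list", passes)
  for (p in seq_len(passes)) {
    amp <- vapply(cleaned, function(s) max(abs(s)), numeric(1))
    z <- vapply(seq_len(n), function(i) {
      oth <- amp[-i]
      s <- sd(oth)
      if (length(oth) < 2L || is.na(s)) return(0)
      if (s == 0) {
        if (amp[i] == mean(oth)) 0 else Inf
      } else (amp[i] - mean(oth)) / s
    }, numeric(1))
    flag <- which(z > zThreshold)
    log[[p]] <- flag
    if (length(flag) == 0L) next
    replaced[flag] <- TRUE
    if (all(replaced))
      stop("unrecoverable recording: every segment was flagged")
    good <- which(!replaced)
    for (i in flag) {
      prv <- good[good < i]
      nxt <- good[good > i]
      nb <- c(if (length(prv)) max(prv), if (length(nxt)) min(nxt))
      cleaned[[i]] <- Reduce(`+`, cleaned[nb]) / length(nb)
    }
  }
  names(log) <- paste0("pass", seq_len(passes))
  list(segments = cleaned, log = log)
}

#' Zero-phase band-pass filter
#'
#' 2nd-order Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), so epochs are not shifted in time. The default
#' 1-200 Hz band removes offset and drift (high-pass) and high-frequency
#' noise (low-pass).
#'
#' @param x numeric trace (uV)
#' @param sampleRate sampling rate, Hz; must exceed twice the upper edge
#' @param low,high band edges in Hz
#' @return filtered trace
#' @export
bandpass <- function(x, sampleRate, low = 1, high = 200) {
  if (sampleRate <= 2 * high)
    stop("sample rate must exceed twice the upper band edge (",
         2 * high, " Hz)")
  bf <- signal::butter(2, c(low, high) / (sampleRate / 2), type = "pass")
  # remove the mean first: DC lies outside the passband anyway, and exact
  # demeaning keeps the forward-backward pass free of offset transients
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Extract first-order kernels by m-sequence cross-correlation
#'
#' Recovers each hexagon's first-order response from the continuous trace:
#' the trace is segmented into one epoch per m-step (0 to ~105 ms after the
#' m-frame onset, wrapping circularly at the recording end) and
#' cross-correlated with the +/-1-recoded m-sequence at the hexagon's
#' circular shift, normalized by the number of "on" steps. Because distinct
#' circular shifts of an m-sequence are exactly orthogonal under this
#' correlation, responses of different hexagons separate without cross-talk
#' as long as shifts are spaced by more than the epoch length.
#'
#' @param trace numeric vector, the (cleaned, filtered) recording; its length
#'   must equal steps x samples-per-step
#' @param mseq the \linkS4class{MSequence} that drove the stimulus
#' @param schedule the \linkS4class{FrameSchedule}
#' @param sampleRate sampling rate of the trace, Hz
#' @param epochMs epoch duration, ms (default 105)
#' @return a \linkS4class{KernelSet} (one row per hexagon shift)
#' @export
extractFirstOrderKernels <- function(trace, mseq, schedule, sampleRate,
                                     epochMs = 105) {
  N <- length(mseq@bits)
  sps <- sampleRate * schedule@framesPerStep / schedule@frameRate
  if (abs(sps - round(sps)) > 1e-9)
    stop("sampleRate must give an integer number of samples per m-step")
  sps <- as.integer(round(sps))
  L <- N * sps
  if (length(trace) != L)
    stop("trace length ", length(trace), " does not match schedule (",
         L, " samples expected)")
  nEpoch <- as.integer(ceiling(epochMs / 1000 * sampleRate)) + 1L
  # shift spacing must exceed the epoch length for separability
  sh <- sort(unique(mseq@shifts))
  if (length(sh) > 1L) {
    gaps <- diff(c(sh, sh[1] + N))
    epochSteps <- ceiling(nEpoch / sps)
    if (min(gaps) < epochSteps)
      stop("shift spacing (", min(gaps), " steps) is below the epoch ",
           "length (", epochSteps, " steps): kernels are not separable")
  }
  starts <- (seq_len(N) - 1L) * sps
  idx <- outer(starts, 0:(nEpoch - 1L), "+") %% L + 1L
  X <- matrix(trace[idx], N, nEpoch)
  cbase <- 2 * mseq@bits - 1
  C <- t(vapply(mseq@shifts, function(s) as.numeric(shiftBits(cbase, s)),
                numeric(N)))
  K <- (C %*% X) / sum(mseq@bits)
  new("KernelSet", waveforms = unname(K),
      times = (0:(nEpoch - 1L)) / sampleRate * 1000,
      sampleRate = sampleRate)
}

#' Epoch root-mean-square amplitude
#'
#' RMS of the waveform samples within a half-open time window [t0, t1) ms.
#' No baseline is subtracted: the analysis windows abut and the 1 Hz
#' high-pass already removes offset.
#'
#' @param x numeric waveform (uV)
#' @param times numeric, ms, aligned with \code{x}
#' @param window numeric length 2, c(t0, t1) with t0 < t1
#' @return RMS amplitude, uV
#' @examples
#' t <- seq(0, 105, by = 0.5)
#' rmsEpoch(sin(2 * pi * t / 10), t, c(15, 45))  # ~0.7071
#' @export
rmsEpoch <- function(x, times, window) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(t0, t1) with t0 < t1")
  sel <- times >= window[1] & times < window[2]
  if (!any(sel)) stop("empty window: no samples in [", window[1], ", ",
                      window[2], ") ms")
  sqrt(mean(x[sel]^2))
}

#' Default epoch windows (ms)
#'
#' Direct component DC 15-45 ms, first induced component IC1 45-75 ms,
#' second induced component IC2 75-105 ms.
#'
#' @return named list of c(t0, t1) windows
#' @export
epochWindows <- function() {
  list(dc = c(15, 45), ic1 = c(45, 75), ic2 = c(75, 105))
}

#' Regional epoch RMS averages
#'
#' Computes the per-hexagon epoch RMS for the three analysis windows and
#' averages them arithmetically over the central-7 (10 degrees) and
#' central-19 (15 degrees) hexagon masks.
#'
#' @param kernels a \linkS4class{KernelSet}
#' @param mask10,mask15 \linkS4class{RegionMask}s over hexagon ids (from
#'   \code{\link{centralHexagons}})
#' @param windows epoch windows, as \code{\link{epochWindows}}
#' @param eyeId id recorded in the result
#' @return an \linkS4class{EpochRMS}
#' @export
regionalRMS <- function(kernels, mask10, mask15, windows = epochWindows(),
                        eyeId = "eye") {
  stopifnot(is(kernels, "KernelSet"))
  nh <- nrow(kernels@waveforms)
  ids <- unique(c(mask10@memberIds, mask15@memberIds))
  if (any(ids < 1L | ids > nh))
    stop("mask references hexagons missing from the kernel set")
  perHex <- vapply(windows, function(w)
    apply(kernels@waveforms, 1, rmsEpoch, times = kernels@times, window = w),
    numeric(nh))
  vals <- c(dc10 = mean(perHex[mask10@memberIds, "dc"]),
            ic1_10 = mean(perHex[mask10@memberIds, "ic1"]),
            ic2_10 = mean(perHex[mask10@memberIds, "ic2"]),
            dc15 = mean(perHex[mask15@memberIds, "dc"]),
            ic1_15 = mean(perHex[mask15@memberIds, "ic1"]),
            ic2_15 = mean(perHex[mask15@memberIds, "ic2"]))
  new("EpochRMS", eyeId = eyeId, values = vals, windows = windows)
}
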