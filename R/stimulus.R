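# Maximal-length sequence generation and the two-global-flash frame schedule.

# Primitive feedback taps (Fibonacci LFSR) for register lengths 2-16.
# Each entry lists the tap positions of a primitive polynomial over GF(2).
PRIMITIVE_TAPS <- list(
  `2` = c(2L, 1L), `3` = c(3L, 2L), `4` = c(4L, 3L), `5` = c(5L, 3L),
  `6` = c(6L, 5L), `7` = c(7L, 6L), `8` = c(8L, 6L, 5L, 4L), `9` = c(9L, 5L),
  `10` = c(10L, 7L), `11` = c(11L, 9L), `12` = c(12L, 6L, 4L, 1L),
  `13` = c(13L, 4L, 3L, 1L), `14` = c(14L, 5L, 3L, 1L), `15` = c(15L, 14L),
  `16` = c(16L, 15L, 13L, 4L))

#' Generate a maximal-length binary sequence
#'
#' Runs a Fibonacci linear feedback shift register (LFSR) with the given
#' feedback taps for one full period of 2^order - 1 steps. With primitive
#' taps the output is an m-sequence: balanced (2^(order-1) ones) and closed
#' under shift-and-add (the XOR of the sequence with any circular shift of
#' itself is another circular shift). The full period is verified at
#' generation time; taps that are not primitive fail with a diagnostic.
#'
#' Per-hexagon stimulation uses one m-sequence with a distinct circular
#' shift per hexagon (the standard multifocal construction); shifts are
#' spread evenly over the period, about \code{(2^order - 1) / nShifts}
#' steps apart.
#'
#' @param order register length n (2 to 16 with shipped taps)
#' @param taps feedback tap positions; defaults to a shipped primitive set
#' @param seedState initial register contents as a 0/1 vector of length
#'   \code{order}; must not be all zero
#' @param nShifts number of per-hexagon shifts to assign (default 103)
#' @return an \linkS4class{MSequence}
#' @examples
#' m <- generateMSequence(13)
#' length(mseqBits(m))  # 8191
#' sum(mseqBits(m))     # 4096
#' @export
generateMSequence <- function(order, taps = NULL, seedState = NULL,
                              nShifts = 103L) {
  order <- as.integer(order)
  if (is.null(taps)) {
    taps <- PRIMITIVE_TAPS[[as.character(order)]]
    if (is.null(taps))
      stop("no shipped primitive taps for order ", order,
           "; supply taps explicitly")
  }
  taps <- as.integer(taps)
  if (any(taps < 1L) || any(taps > order))
    stop("tap positions must lie in 1..order")
  if (is.null(seedState)) seedState <- c(1L, rep(0L, order - 1L))
  seedState <- as.integer(seedState)
  if (length(seedState) != order) stop("seedState must have length ", order)
  if (all(seedState == 0L))
    stop("degenerate all-zero register state: the LFSR would never leave it")

  N <- 2L^order - 1L
  bits <- integer(N)
  s <- seedState
  seedKey <- sum(seedState * 2^(seq_len(order) - 1))
  for (i in seq_len(N)) {
    bits[i] <- s[order]
    fb <- sum(s[taps]) %% 2L
    s <- c(fb, s[-order])
    key <- sum(s * 2^(seq_len(order) - 1))
    if (key == seedKey && i < N)
      stop("taps are not primitive: LFSR period ", i,
           " < 2^", order, " - 1 = ", N)
  }
  if (nShifts > N) stop("cannot assign ", nShifts, " distinct shifts; ",
                        "sequence has only ", N, " steps")
  shifts <- as.integer(floor((seq_len(nShifts) - 1L) * (N / nShifts)))
  new("MSequence", order = order, taps = taps, bits = bits, shifts = shifts)
}

#' Circularly shift an m-sequence's bits
#'
#' @param bits 0/1 vector
#' @param k shift in steps (bit i of the result is bit i + k of the input,
#'   modulo the period)
#' @return shifted 0/1 vector
#' @export
shiftBits <- function(bits, k) {
  N <- length(bits)
  k <- ((k %% N) + N) %% N
  if (k == 0) bits else c(bits[(k + 1):N], bits[1:k])
}

#' Build the two-global-flash frame schedule
#'
#' Lays out the display frames of one m-sequence step: one m-frame in which
#' the hexagons flicker according to the m-sequence, followed by two
#' full-field global flashes separated by dark frames. At the default 75 Hz
#' and 6 frames per step the two global flashes are 2 frames = 26.7 ms
#' apart and an order-13 sequence runs 8191 x 6 / 75 = 655.3 s, i.e. 10 min
#' 55 s, recorded in 16 segments.
#'
#' @param mseq an \linkS4class{MSequence}
#' @param frameRate display frame rate, Hz (default 75)
#' @param framesPerStep frames per m-step (>= 3; default 6)
#' @param nSegments number of recording segments (default 16)
#' @param luminances named numeric, cd/m2 for \code{M_on}, \code{M_off},
#'   \code{GF}, \code{B}
#' @return a \linkS4class{FrameSchedule}
#' @examples
#' sched <- buildFrameSchedule(generateMSequence(13))
#' scheduleDuration(sched)     # 655.28 s
#' globalFlashInterval(sched)  # 26.67 ms
#' @export
buildFrameSchedule <- function(mseq, frameRate = 75, framesPerStep = 6L,
                               nSegments = 16L,
                               luminances = c(M_on = 100, M_off = 0.5,
                                              GF = 200, B = 0)) {
  stopifnot(is(mseq, "MSequence"))
  framesPerStep <- as.integer(framesPerStep)
  if (frameRate <= 0) stop("frameRate must be positive")
  if (framesPerStep < 3L)
    stop("framesPerStep must be >= 3 to host one m-frame and two ",
         "global flashes")
  pattern <- if (framesPerStep >= 5L)
    c("M", "B", "GF", "B", "GF", rep("B", framesPerStep - 5L))
  else if (framesPerStep == 4L) c("M", "GF", "B", "GF")
  else c("M", "GF", "GF")
  new("FrameSchedule", frameRate = frameRate, framesPerStep = framesPerStep,
      pattern = pattern, luminances = luminances,
      nSegments = as.integer(nSegments), nSteps = length(mseq@bits))
}

#' Frame-by-frame schedule table
#'
#' Expands a schedule into one row per display frame with its time, role and
#' nominal luminance (m-frame luminance is the "on" level; per-hexagon on/off
#' follows the m-sequence and its shifts).
#'
#' @param schedule a \linkS4class{FrameSchedule}
#' @param steps which m-steps to expand (default first 10)
#' @return data.frame (frame_index, time_s, step, role, luminance_cd_m2)
#' @export
scheduleTable <- function(schedule, steps = seq_len(min(10L,
                                                        schedule@nSteps))) {
  fps <- schedule@framesPerStep
  lum <- c(M = unname(schedule@luminances["M_on"]),
           GF = unname(schedule@luminances["GF"]),
           B = unname(schedule@luminances["B"]))
  rows <- lapply(steps, function(k) {
    idx <- (k - 1L) * fps + seq_len(fps)
    data.frame(frame_index = idx, time_s = (idx - 1) / schedule@frameRate,
               step = k, role = schedule@pattern,
               luminance_cd_m2 = lum[schedule@pattern])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Segment boundaries of a recording
#'
#' Partitions the m-steps into \code{nSegments} near-equal contiguous runs.
#'
#' @param schedule a \linkS4class{FrameSchedule}
#' @return data.frame (segment, first_step, last_step)
#' @export
segmentBoundaries <- function(schedule) {
  n <- schedule@nSteps
  k <- schedule@nSegments
  cuts <- floor(seq(0, n, length.out = k + 1))
  data.frame(segment = seq_len(k), first_step = cuts[-(k + 1)] + 1,
             last_step = cuts[-1])
}
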