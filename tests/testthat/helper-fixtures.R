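# Shared fixtures, built in code at test time.

fixtureLayout <- function() buildHexLayout()

# small stimulus for fast signal tests: order 8 (255 steps), 103 shifts
fixtureStimulus <- function(order = 8L) {
  m <- generateMSequence(order)
  list(mseq = m, schedule = buildFrameSchedule(m))
}

# brute-force Mann-Whitney AUC by counting concordant pairs (ties = 1/2)
bruteForceAUC <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# on-minus-off epoch averaging: independent oracle for kernel extraction
averagingOracle <- function(trace, mseq, schedule, sampleRate, hex,
                            epochMs = 105) {
  N <- length(mseqBits(mseq))
  sps <- as.integer(round(sampleRate * schedule@framesPerStep /
                            schedule@frameRate))
  L <- N * sps
  nEpoch <- as.integer(ceiling(epochMs / 1000 * sampleRate)) + 1L
  bits <- shiftBits(mseqBits(mseq), mseqShifts(mseq)[hex])
  epochs <- t(vapply(seq_len(N), function(k) {
    idx <- ((k - 1L) * sps + 0:(nEpoch - 1L)) %% L + 1L
    trace[idx]
  }, numeric(nEpoch)))
  colMeans(epochs[bits == 1, , drop = FALSE]) -
    colMeans(epochs[bits == 0, , drop = FALSE])
}

# deterministic 26-eye flag fixture
fixtureFlagTable <- function() referenceFlagTable()
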