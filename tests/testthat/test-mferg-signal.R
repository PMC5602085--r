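# Signal chain: artifact rejection, band-pass, kernel extraction by
# m-sequence cross-correlation, epoch RMS, regional averaging.

test_that("epoch RMS matches closed forms and is scale-equivariant", {
  t <- seq(0, 105, by = 0.25)
  zero <- rep(0, length(t))
  expect_equal(rmsEpoch(zero, t, c(15, 45)), 0)
  expect_equal(rmsEpoch(rep(5, length(t)), t, c(75, 105)), 5)
  # unit sine over whole periods: RMS = 1/sqrt(2)
  x <- sin(2 * pi * t / 10)
  expect_equal(rmsEpoch(x, t, c(15, 45)), 1 / sqrt(2), tolerance = 1e-3)
  # scale equivariance: rms(c x) = |c| rms(x)
  y <- rnorm(length(t))
  for (c0 in c(-3, 0.5, 7))
    expect_equal(rmsEpoch(c0 * y, t, c(15, 45)),
                 abs(c0) * rmsEpoch(y, t, c(15, 45)))
  expect_error(rmsEpoch(x, t, c(45, 45)), "t0 < t1")
  expect_error(rmsEpoch(x, t, c(200, 300)), "empty window")
})

test_that("band-pass removes offset and keeps the passband", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  # constant offset lies outside the passband
  out <- bandpass(rep(3, length(t)), fs)
  expect_lt(abs(mean(out)), 3e-6)
  gain <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- bandpass(x, fs)
    mid <- t > 0.5 & t < 1.5
    sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2))
  }
  expect_gt(gain(50), 0.95)          # mid-band preserved within 5%
  expect_lt(gain(400), 0.20)         # stop-band attenuated > 80%
  expect_error(bandpass(t, sampleRate = 300), "twice the upper")
})

test_that("artifact rejection flags outliers over two passes", {
  base <- lapply(1:8, function(i) sin(seq(0, 10, length.out = 200)))
  clean <- rejectArtifacts(base)
  expect_identical(clean$segments, base)
  expect_length(clean$log$pass1, 0L)

  # one segment at 10x amplitude: leave-one-out z >> 3 in pass 1
  seg <- base
  seg[[4]] <- 10 * seg[[4]]
  r <- rejectArtifacts(seg)
  expect_equal(r$log$pass1, 4L)
  expect_equal(r$segments[[4]], (seg[[3]] + seg[[5]]) / 2)

  # borderline outlier masked by a gross one: caught only in pass 2
  seg2 <- base
  seg2[[2]] <- 25 * seg2[[2]]
  seg2[[6]] <- 2.1 * seg2[[6]]
  r2 <- rejectArtifacts(seg2)
  expect_equal(r2$log$pass1, 2L)
  expect_equal(r2$log$pass2, 6L)

  expect_error(rejectArtifacts(base, zThreshold = -10), "unrecoverable")
  expect_error(rejectArtifacts(base[[1]]), "at least 2")
})

test_that("kernel extraction recovers injected responses without cross-talk", {
  st <- fixtureStimulus(order = 8L)
  fs <- 1200
  times <- kernelTimeGrid(fs)
  tmpl <- responseTemplate(1, times)
  nHex <- length(mseqShifts(st$mseq))

  # zero trace -> all-zero kernels
  sps <- fs * st$schedule@framesPerStep / st$schedule@frameRate
  L <- length(mseqBits(st$mseq)) * sps
  k0 <- extractFirstOrderKernels(rep(0, L), st$mseq, st$schedule, fs)
  expect_equal(max(abs(kernelWaveforms(k0))), 0)

  # single active hexagon, noise-free
  kernels <- matrix(0, nHex, length(times))
  kernels[17, ] <- tmpl
  trace <- unlist(synthesizeSegments(kernels, st$mseq, st$schedule, fs,
                                     noiseUv = 0))
  ks <- extractFirstOrderKernels(trace, st$mseq, st$schedule, fs)
  rec <- kernelWaveforms(ks)[17, ]
  expect_gt(cor(rec, tmpl), 0.999)
  # independent oracle: on-minus-off epoch averaging
  oracle <- averagingOracle(trace, st$mseq, st$schedule, fs, 17)
  expect_gt(cor(rec, oracle), 0.999)
  # cross-talk in silent hexagons < 1% of the own-response RMS
  ownRms <- sqrt(mean(rec^2))
  crossRms <- sqrt(rowMeans(kernelWaveforms(ks)[-17, ]^2))
  expect_lt(max(crossRms), 0.01 * ownRms)

  # two active hexagons with distinct shifts separate cleanly
  kernels2 <- matrix(0, nHex, length(times))
  kernels2[5, ] <- tmpl
  kernels2[60, ] <- 0.5 * tmpl
  tr2 <- unlist(synthesizeSegments(kernels2, st$mseq, st$schedule, fs,
                                   noiseUv = 0))
  ks2 <- extractFirstOrderKernels(tr2, st$mseq, st$schedule, fs)
  expect_gt(cor(kernelWaveforms(ks2)[5, ], tmpl), 0.999)
  expect_gt(cor(kernelWaveforms(ks2)[60, ], tmpl), 0.999)
  expect_equal(sqrt(mean(kernelWaveforms(ks2)[60, ]^2)) /
                 sqrt(mean(kernelWaveforms(ks2)[5, ]^2)),
               0.5, tolerance = 0.01)

  expect_error(extractFirstOrderKernels(trace[-1], st$mseq, st$schedule, fs),
               "does not match")
})

test_that("insufficient shift spacing triggers the separability error", {
  m <- generateMSequence(6, nShifts = 60L)   # 63 steps, spacing 2 < epoch
  sched <- buildFrameSchedule(m)
  fs <- 1200
  L <- 63 * fs * 6 / 75
  expect_error(extractFirstOrderKernels(rep(0, L), m, sched, fs),
               "not separable")
})

test_that("regional averages combine per-hexagon RMS arithmetically", {
  layout <- fixtureLayout()
  times <- kernelTimeGrid()
  tmpl <- responseTemplate(1, times)
  m10 <- centralHexagons(layout, 1)
  m15 <- centralHexagons(layout, 2)

  # identical kernels in every hexagon: regional equals single-hexagon RMS
  ks <- new("KernelSet", waveforms = matrix(tmpl, 103, length(times),
                                            byrow = TRUE),
            times = times, sampleRate = 1200)
  r <- rmsValues(regionalRMS(ks, m10, m15))
  single <- rmsEpoch(tmpl, times, c(15, 45))
  expect_equal(unname(r["dc10"]), single)
  expect_equal(unname(r["dc15"]), single)

  # central 7 active, ring 2 silent: central-19 mean is 7/19 of it
  w <- matrix(0, 103, length(times))
  for (h in memberIds(m10)) w[h, ] <- tmpl
  ks2 <- new("KernelSet", waveforms = w, times = times, sampleRate = 1200)
  r2 <- rmsValues(regionalRMS(ks2, m10, m15))
  expect_equal(unname(r2["dc15"]), single * 7 / 19)
  expect_equal(unname(r2["dc10"]), single)

  bad <- new("RegionMask", modality = "mfERG", memberIds = 999L,
             label = "bad")
  expect_error(regionalRMS(ks, bad, m15), "missing")
})

test_that("noise-free end-to-end RMS equals the injected template RMS", {
  st <- fixtureStimulus(order = 8L)
  fs <- 1200
  times <- kernelTimeGrid(fs)
  tmpl <- responseTemplate(0.7, times)
  nHex <- length(mseqShifts(st$mseq))
  kernels <- matrix(0, nHex, length(times))
  kernels[3, ] <- tmpl
  trace <- unlist(synthesizeSegments(kernels, st$mseq, st$schedule, fs,
                                     noiseUv = 0))
  ks <- extractFirstOrderKernels(trace, st$mseq, st$schedule, fs)
  for (w in epochWindows()) {
    want <- rmsEpoch(tmpl, times, w)
    got <- rmsEpoch(kernelWaveforms(ks)[3, ], kernelTimes(ks), w)
    expect_equal(got, want, tolerance = 1e-6)
  }
})
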