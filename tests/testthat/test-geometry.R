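# Spatial geometry: hexagon rings, central masks, mm/degree conversion,
# ganglion-cell displacement, perimetry point selection.

test_that("hexagonal ring cardinalities match brute-force neighbour expansion", {
  # independent oracle: BFS over axial-coordinate neighbours from the origin
  neighbours <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1),
                      c(-1, 1))
  frontier <- matrix(c(0L, 0L), 1)
  seen <- "0,0"
  counts <- integer()
  for (k in 1:5) {
    nxt <- unique(do.call(rbind, lapply(seq_len(nrow(frontier)), function(i)
      t(t(neighbours) + frontier[i, ]))))
    keys <- paste(nxt[, 1], nxt[, 2], sep = ",")
    new <- !(keys %in% seen)
    frontier <- nxt[new, , drop = FALSE]
    seen <- c(seen, keys[new])
    counts[k] <- nrow(frontier)
  }
  expect_equal(counts, 6L * 1:5)
  expect_equal(cumsum(c(1L, counts)), c(1L, 7L, 19L, 37L, 61L, 91L))

  layout <- fixtureLayout()
  expect_equal(sum(hexRings(layout) == 0L), 1L)
  expect_equal(sum(hexRings(layout) == 1L), 6L)
  expect_equal(sum(hexRings(layout) == 2L), 12L)
})

test_that("the shipped 103-hexagon layout satisfies its invariants", {
  layout <- fixtureLayout()
  expect_equal(nHexagons(layout), 103L)
  expect_lte(2 * max(sqrt(rowSums(hexCenters(layout)^2))), 50)
  # eccentricity scaling: area increases monotonically with ring
  ringArea <- tapply(hexAreas(layout), hexRings(layout), unique)
  expect_true(all(diff(unlist(ringArea)) > 0))
  # identity scaling: all areas equal
  flat <- buildHexLayout(eccentricityScaling = 1)
  expect_equal(length(unique(hexAreas(flat))), 1L)
  expect_error(buildHexLayout("veris61"), "unknown")
  # custom grid path
  grid <- data.frame(x_deg = c(0, 2), y_deg = c(0, 0), ring = c(0, 1))
  expect_equal(nHexagons(buildHexLayout(grid)), 2L)
})

test_that("central hexagon masks have 1/7/19 members, nested and monotone", {
  layout <- fixtureLayout()
  sizes <- vapply(0:4, function(k)
    length(memberIds(centralHexagons(layout, k))), integer(1))
  expect_equal(sizes, c(1L, 7L, 19L, 37L, 61L))
  for (k in 1:4)
    expect_true(all(memberIds(centralHexagons(layout, k - 1)) %in%
                      memberIds(centralHexagons(layout, k))))
  expect_error(centralHexagons(layout, -1), "out of range")
  expect_error(centralHexagons(layout, 9), "out of range")
})

test_that("mm-to-degree conversion is linear with the 3.3 deg/mm default", {
  expect_equal(mmToDegrees(4.0), 13.2)
  expect_equal(mmToDegrees(4.8), 15.84)
  expect_equal(mmToDegrees(0), 0)
  # linear and strictly monotone in both arguments
  x <- c(0.5, 1, 2, 3)
  expect_equal(mmToDegrees(2 * x), 2 * mmToDegrees(x))
  expect_true(all(diff(mmToDegrees(x)) > 0))
  expect_true(mmToDegrees(2, 4) > mmToDegrees(2, 3.3))
  expect_error(mmToDegrees(1, factor = 0), "positive")
  expect_error(mmToDegrees(-1), ">= 0")
})

test_that("ganglion-cell displacement reproduces both anchors and is monotone", {
  expect_equal(drasdoDisplacement(1), 0.62)
  expect_equal(drasdoDisplacement(4), 0.12)
  expect_equal(drasdoDisplacement(2.5), 0.37)
  # constant extension outside the anchors
  expect_equal(drasdoDisplacement(0.2), 0.62)
  expect_equal(drasdoDisplacement(7), 0.12)
  ecc <- seq(1, 4, by = 0.05)
  expect_true(all(diff(drasdoDisplacement(ecc)) <= 0))
  expect_true(all(drasdoDisplacement(seq(0, 8, by = 0.25)) >= 0))
  expect_error(drasdoDisplacement(-0.1), ">= 0")
})

test_that("SAP point selection nests central10 in central15 with 4 added points", {
  tab <- sapPointTable()
  m10 <- selectSapPoints(tab, "central10")
  m15 <- selectSapPoints(tab, "central15")
  expect_equal(length(memberIds(m15)) - length(memberIds(m10)), 4L)
  expect_true(all(memberIds(m10) %in% memberIds(m15)))

  # brute-force point-in-disk check with and without displacement
  for (disp in c(TRUE, FALSE)) {
    ecc <- sqrt(tab$x_deg^2 + tab$y_deg^2)
    if (disp) ecc <- ecc + 3.3 * drasdoDisplacement(ecc / 3.3)
    manual <- tab$point_id[ecc <= 10]
    m <- selectSapPoints(tab, "central10", displacement = disp)
    expect_setequal(memberIds(m), manual)
  }

  far <- data.frame(point_id = 1:4, x_deg = c(30, -30, 30, -30),
                    y_deg = c(30, 30, -30, -30))
  expect_warning(m0 <- selectSapPoints(far, "central10"), "no points")
  expect_length(memberIds(m0), 0L)
  expect_error(selectSapPoints(tab, "central15", additionalIds = c(1, 2)),
               "exactly 4")
  expect_error(selectSapPoints(tab, "central15",
                               additionalIds = c(999, 998, 997, 996)),
               "not present")
  # an additional point inside 10 degrees breaks the superset contract
  expect_error(selectSapPoints(tab, "central15",
                               additionalIds = c(1, 37, 38, 39)),
               "extend central10")
})
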