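# Group statistics: ANOVA, BH-FDR, covariate-adjusted ROC with DeLong
# variance, paired DeLong comparison, structure-function regressions.

test_that("one-way ANOVA matches the brute-force mean-square ratio", {
  # identical distributions in each group: F = 0, p = 1
  a <- anovaOneway(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)

  set.seed(5)
  g <- rep(c("a", "b", "c"), each = 4)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2) + rnorm(12, 0, 1e-4)
  expect_lt(anovaOneway(y, g)$p, 1e-6)

  # independent summation oracle on a random fixture
  y2 <- rnorm(30)
  g2 <- rep(c("a", "b", "c"), each = 10)
  means <- tapply(y2, g2, mean)
  ssb <- sum(10 * (means - mean(y2))^2)
  ssw <- sum((y2 - means[g2])^2)
  Foracle <- (ssb / 2) / (ssw / 27)
  expect_equal(anovaOneway(y2, g2)$F, Foracle)

  pw <- anovaOneway(y2, g2)$pairwise
  expect_true(all(pw <= 1, na.rm = TRUE))
  expect_error(anovaOneway(1:5, c("a", "a", "a", "a", "b")), "degenerate")
  expect_error(anovaOneway(1:3, rep("a", 3)), "2 groups")
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(fdrAdjust(0.04), 0.04)
  # step-up by hand: (0.01*3/1, 0.02*3/2, 0.03*3/3) then cumulative min
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(20)
  q <- fdrAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # order-preserving
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("AUC equals the brute-force concordant-pair count", {
  # worked 5 vs 5 fixture
  cases <- c(0.9, 0.8, 0.7, 0.6, 0.55)
  ctrls <- c(0.5, 0.4, 0.3, 0.2, 0.1)
  r <- suppressWarnings(adjustedROC(c(cases, ctrls),
                                    c(rep(1, 5), rep(0, 5))))
  expect_equal(aucValue(r), 1.0)
  # swap the boundary pair (0.55 case <-> 0.5 control): one discordant pair
  swapped <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.55, 0.4, 0.3, 0.2, 0.1)
  r2 <- adjustedROC(swapped, c(rep(1, 5), rep(0, 5)))
  expect_equal(aucValue(r2), 0.96)

  # random small fixtures, with ties
  set.seed(11)
  for (i in 1:8) {
    n <- sample(8:20, 1)
    lab <- c(rep(1, ceiling(n / 2)), rep(0, floor(n / 2)))
    sc <- round(rnorm(n), 1)            # rounding forces ties
    r <- adjustedROC(sc, lab)
    expect_equal(aucValue(r), bruteForceAUC(rocScores(r), lab))
  }
  expect_error(adjustedROC(1:5, rep(1, 5)), "both classes")
})

test_that("adjusted AUC equals the marker AUC when covariates are constant", {
  set.seed(3)
  x <- rnorm(60)
  lab <- rbinom(60, 1, plogis(2 * x))
  if (length(unique(lab)) == 2) {
    r0 <- adjustedROC(x, lab)
    r1 <- adjustedROC(x, lab, age = rep(55, 60), gender = rep("F", 60))
    expect_equal(aucValue(r1), aucValue(r0))
  }
})

test_that("a pure-noise marker gives AUC near one half", {
  set.seed(7)
  n <- 2000
  lab <- rep(c(0, 1), n / 2)
  r <- adjustedROC(rnorm(n), lab)
  expect_lt(abs(aucValue(r) - 0.5), 0.03)
})

test_that("DeLong standard error agrees with the independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  lab <- c(rep(1, 30), rep(0, 40))
  sc <- c(rnorm(30, 1), rnorm(40, 0))
  r <- adjustedROC(sc, lab)
  pr <- pROC::roc(lab, rocScores(r), quiet = TRUE, direction = "<")
  expect_equal(aucValue(r), as.numeric(pROC::auc(pr)))
  expect_equal(aucSE(r), sqrt(pROC::var(pr)), tolerance = 1e-9)
})

test_that("DeLong comparison is symmetric and null on identical scores", {
  set.seed(17)
  lab <- c(rep(1, 20), rep(0, 20))
  a <- adjustedROC(c(rnorm(20, 1), rnorm(20)), lab)
  d0 <- delongCompare(a, a)
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  b <- adjustedROC(rnorm(40), lab)
  ab <- delongCompare(a, b)
  ba <- delongCompare(b, a)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  cShort <- adjustedROC(rnorm(10), c(rep(1, 5), rep(0, 5)))
  expect_error(delongCompare(a, cShort), "not paired")
})

test_that("DeLong test separates markers with very different AUCs", {
  set.seed(23)
  hits <- 0
  nSeeds <- 30
  for (i in seq_len(nSeeds)) {
    lab <- c(rep(1, 100), rep(0, 100))
    good <- c(rnorm(100, 1.81), rnorm(100))   # true AUC ~0.9
    noise <- rnorm(200)                       # true AUC 0.5
    p <- delongCompare(adjustedROC(good, lab),
                       adjustedROC(noise, lab))$p
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / nSeeds, 0.95)
})

test_that("structure-function regression recovers slopes and handles subjects", {
  set.seed(32)
  n <- 200
  df <- data.frame(subject_id = paste0("s", 1:n),
                   age = rnorm(n, 55, 10),
                   gender = sample(c("M", "F"), n, replace = TRUE),
                   mt = rnorm(n, 300, 15))
  df$resp <- 0.05 * df$mt - 0.02 * df$age +
    0.3 * (df$gender == "M") + rnorm(n, 0, 1)
  fit <- fitStructureFunction(df, "resp", "mt")
  expect_false(fit@mixed)
  expect_equal(fitSlope(fit), 0.05, tolerance = 0.2)
  expect_true(fitCI(fit)[1] <= 0.05 && 0.05 <= fitCI(fit)[2])

  # null predictor: slope CI covers zero (single fixed seed)
  df$null <- rnorm(n)
  fit0 <- fitStructureFunction(df, "resp", "null")
  expect_gt(fitP(fit0), 0.01)

  dfc <- df; dfc$mt <- 300
  expect_error(fitStructureFunction(dfc, "resp", "mt"), "singular")
  expect_error(fitStructureFunction(df[1:5, ], "resp", "mt"), "at least 10")

  # duplicated subjects, subject-constant predictor, strong subject
  # effects: the mixed model must not claim the precision of 2m
  # independent eyes, so its CI is wider than the naive OLS CI
  set.seed(33)
  m <- 40
  sub <- rep(paste0("s", 1:m), each = 2)
  subEff <- rep(rnorm(m, 0, 3), each = 2)
  d2 <- data.frame(subject_id = sub, age = rep(rnorm(m, 55, 8), each = 2),
                   gender = rep(sample(c("M", "F"), m, TRUE), each = 2),
                   x = rep(rnorm(m), each = 2))
  d2$y <- 0.5 * d2$x + subEff + rnorm(2 * m, 0, 0.5)
  fitM <- fitStructureFunction(d2, "y", "x")
  expect_true(fitM@mixed)
  d2ols <- d2; d2ols$subject_id <- paste0("u", seq_len(nrow(d2)))
  fitO <- fitStructureFunction(d2ols, "y", "x")
  expect_gt(diff(fitCI(fitM)), diff(fitCI(fitO)) * 0.99)
})

test_that("the regression table shares one FDR family", {
  set.seed(41)
  n <- 60
  df <- data.frame(subject_id = paste0("s", 1:n), age = rnorm(n, 55, 8),
                   gender = sample(c("M", "F"), n, TRUE),
                   mt = rnorm(n, 300, 15), gc = rnorm(n, 75, 8))
  df$r1 <- 0.04 * df$mt + rnorm(n)
  df$r2 <- rnorm(n)
  tab <- structureFunctionTable(df, c("r1", "r2"), c("mt", "gc"))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$p_fdr, unname(fdrAdjust(tab$p)))
  expect_true(all(tab$p_fdr >= tab$p))
})
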