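# Group statistics: one-way ANOVA with Bonferroni post hoc, linear
# mixed-effects structure-function regressions adjusted for age and gender,
# Benjamini-Hochberg FDR, covariate-adjusted ROC (logistic scores,
# Mann-Whitney AUC, DeLong variance) and DeLong comparison of paired AUCs.

#' One-way ANOVA with Bonferroni post hoc
#'
#' Classical one-way analysis of variance across groups, followed by
#' pairwise two-sample t comparisons whose p-values are Bonferroni-adjusted
#' (multiplied by the number of pairs, capped at 1).
#'
#' @param values numeric
#' @param group factor or character of the same length (>= 2 groups, each
#'   with >= 2 observations)
#' @return list with \code{F}, \code{p} and \code{pairwise} (matrix of
#'   adjusted p-values)
#' @export
anovaOneway <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  n <- table(group)
  if (any(n < 2L)) stop("degenerate input: every group needs >= 2 values")
  fit <- aov(values ~ group)
  tab <- anova(fit)
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.nan(Fv)) {                     # zero within- and between-variance
    Fv <- 0; p <- 1
  }
  pw <- suppressWarnings(
    pairwise.t.test(values, group, p.adjust.method = "bonferroni"))$p.value
  list(F = unname(Fv), p = unname(p), pairwise = pw)
}

#' Structure-function regression adjusted for age and gender
#'
#' Fits the functional response (SAP or mfERG feature) against a structural
#' predictor (OCT feature) with age and gender as fixed-effect covariates.
#' When some subjects contribute more than one eye, a subject random
#' intercept is included (\code{lme4}/\code{lmerTest}); with one eye per
#' subject the model collapses to ordinary least squares.
#'
#' @param data data.frame with the response, predictor, \code{age},
#'   \code{gender} and \code{subject_id} columns
#' @param response,predictor column names
#' @param subject column holding subject ids (default \code{"subject_id"})
#' @return a \linkS4class{ModelFit}
#' @export
fitStructureFunction <- function(data, response, predictor,
                                 subject = "subject_id") {
  need <- c(response, predictor, "age", "gender", subject)
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)),
                                    collapse = ", "))
  cc <- complete.cases(data[, need])
  data <- data[cc, ]
  if (nrow(data) < 10L) stop("need at least 10 complete cases")
  if (sd(data[[predictor]]) == 0)
    stop("singular fit: predictor '", predictor, "' is constant")
  mixed <- anyDuplicated(data[[subject]]) > 0L
  if (mixed) {
    f <- stats::as.formula(paste0("`", response, "` ~ `", predictor,
                                  "` + age + gender + (1|", subject, ")"))
    fit <- lmerTest::lmer(f, data = data)
    co <- summary(fit)$coefficients
    row <- grep(predictor, rownames(co), fixed = TRUE)[1]
    slope <- co[row, "Estimate"]
    se <- co[row, "Std. Error"]
    p <- co[row, "Pr(>|t|)"]
    ci <- slope + c(-1, 1) * qnorm(0.975) * se
  } else {
    f <- stats::as.formula(paste0("`", response, "` ~ `", predictor,
                                  "` + age + gender"))
    fit <- lm(f, data = data)
    co <- summary(fit)$coefficients
    row <- grep(predictor, rownames(co), fixed = TRUE)[1]
    slope <- co[row, "Estimate"]
    p <- co[row, "Pr(>|t|)"]
    ci <- unname(confint(fit)[row, ])
  }
  new("ModelFit", response = response, predictor = predictor,
      slope = unname(slope), ci95 = ci, pValue = unname(p),
      pFdr = NA_real_, covariates = c("age", "gender"), mixed = mixed,
      nObs = nrow(data))
}

#' Structure-function regression table with FDR adjustment
#'
#' Fits every response-predictor pair and adjusts the p-values jointly
#' (one Benjamini-Hochberg family per call).
#'
#' @param data as in \code{\link{fitStructureFunction}}
#' @param responses,predictors character vectors of column names
#' @param subject subject-id column
#' @return data.frame (response, predictor, slope, ci_lo, ci_hi, p, p_fdr,
#'   mixed, n)
#' @export
structureFunctionTable <- function(data, responses, predictors,
                                   subject = "subject_id") {
  fits <- list()
  for (r in responses) for (x in predictors)
    fits[[paste(r, x, sep = "~")]] <-
      fitStructureFunction(data, r, x, subject)
  p <- vapply(fits, fitP, numeric(1))
  pf <- fdrAdjust(p)
  out <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(response = f@response, predictor = f@predictor,
               slope = f@slope, ci_lo = f@ci95[1], ci_hi = f@ci95[2],
               p = f@pValue, p_fdr = pf[i], mixed = f@mixed, n = f@nObs)
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: order-preserving, bounded by 1, never smaller
#' than the raw values.
#'
#' @param p numeric p-values in [0, 1]
#' @return adjusted p-values
#' @export
fdrAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Mann-Whitney placements: for each case, the fraction of controls it
# outscores (ties count 1/2), and vice versa.
placements <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Covariate-adjusted ROC analysis
#'
#' Fits a logistic regression of disease on \code{age + gender + marker},
#' takes the predicted probabilities as the diagnostic score, and computes
#' the nonparametric (Mann-Whitney / Wilcoxon) AUC of the scores with ties
#' counted one half. The AUC standard error is the DeLong variance
#' estimator. With constant covariates, the logistic transform is monotone
#' in the marker and the adjusted AUC equals the unadjusted marker AUC.
#'
#' @param marker numeric marker values
#' @param disease 0/1 (or logical / two-level factor) disease labels
#' @param age,gender optional covariates; omitted from the score model
#'   when NULL
#' @param markerName label stored in the result
#' @return a \linkS4class{ROCResult}
#' @export
adjustedROC <- function(marker, disease, age = NULL, gender = NULL,
                        markerName = "marker") {
  labels <- as.integer(as.factor(disease)) - 1L
  if (length(unique(labels)) != 2L)
    stop("both classes must be present")
  df <- data.frame(y = labels, marker = marker)
  if (!is.null(age)) df$age <- age
  if (!is.null(gender)) df$gender <- factor(gender)
  if (!is.null(df$gender) && nlevels(df$gender) < 2L) df$gender <- NULL
  if (anyNA(df)) stop("missing marker or covariate values")
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (any(fitted(fit) > 1 - 1e-10) && any(fitted(fit) < 1e-10))
    warning("perfect or near-perfect separation; AUC computed from scores")
  scores <- unname(fitted(fit))
  pl <- placements(scores, labels)
  n1 <- length(pl$v10); n0 <- length(pl$v01)
  auc <- mean(pl$v10)
  v <- if (n1 > 1 && n0 > 1)
    stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0 else 0
  new("ROCResult", marker = markerName, auc = auc, seAuc = sqrt(v),
      scores = scores, labels = labels,
      covariates = setdiff(names(df), c("y", "marker")),
      nCases = as.integer(n1), nControls = as.integer(n0))
}

#' DeLong test for two correlated AUCs
#'
#' Paired z-test comparing the AUCs of two markers evaluated on the same
#' eyes, using the DeLong covariance of the Mann-Whitney placement values.
#' Symmetric in its arguments (the z statistic changes sign, the p-value is
#' identical).
#'
#' @param rocA,rocB \linkS4class{ROCResult}s computed on the same eyes (the
#'   label vectors must match)
#' @return list with \code{z}, \code{p} and \code{aucDiff}
#' @export
delongCompare <- function(rocA, rocB) {
  if (length(rocA@labels) != length(rocB@labels) ||
      any(rocA@labels != rocB@labels))
    stop("ROC results are not paired: label vectors differ")
  pa <- placements(rocA@scores, rocA@labels)
  pb <- placements(rocB@scores, rocB@labels)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  d <- mean(pa$v10) - mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  z <- if (v <= 0) {
    if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else d / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)), aucDiff = d)
}
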