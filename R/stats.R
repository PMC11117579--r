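# Reliability and method-comparison statistics over ratio tables:
# Pearson correlation with interpretation bands, paired t test, relative
# absolute error, ICC, split-plot factorial ANOVA (between-subject gender
# x within-subject spinal level) and Tukey HSD post hoc tests.

#' Interpretation band for a Pearson correlation
#'
#' Bands: Excellent (PCC > 0.810), Good ([0.61, 0.809]), Moderate
#' ([0.410, 0.609]), Fair ([0.210, 0.409]), Poor (< 0.209). The printed
#' band edges leave small gaps (e.g. between 0.809 and 0.810); a value
#' falling in a gap is assigned to the nearer lower band so the rule is
#' total and deterministic.
#'
#' @param pcc correlation value in [-1, 1].
#' @return One of "Excellent", "Good", "Moderate", "Fair", "Poor".
#' @examples
#' pccBand(0.645)  # "Good"
#' pccBand(0.837)  # "Excellent"
#' @export
pccBand <- function(pcc) {
  stopifnot(is.finite(pcc), abs(pcc) <= 1)
  if (pcc > 0.810) "Excellent"
  else if (pcc >= 0.61) "Good"
  else if (pcc >= 0.410) "Moderate"
  else if (pcc >= 0.210) "Fair"
  else "Poor"
}

#' Pearson correlation with interpretation band
#'
#' @param x,y paired numeric vectors (equal length >= 3, both with
#'   nonzero variance).
#' @return List with \code{pcc} and \code{band}.
#' @export
pearsonWithBand <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: correlation undefined")
  r <- stats::cor(x, y)
  list(pcc = r, band = pccBand(r))
}

#' Paired sample t test
#'
#' \eqn{t = \bar d / (s_d / \sqrt n)} on the differences d = x - y, with
#' df = n - 1 and a two-sided p value. Zero-variance differences with a
#' nonzero mean cannot be tested and are flagged degenerate (t and p NA).
#'
#' @param x,y paired numeric vectors (length >= 3).
#' @return List with \code{t}, \code{df}, \code{p}, \code{meanDiff},
#'   \code{degenerate}.
#' @export
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, meanDiff = 0, degenerate = FALSE))
    return(list(t = NA_real_, df = n - 1, p = NA_real_, meanDiff = mean(d),
                degenerate = TRUE))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       meanDiff = mean(d), degenerate = FALSE)
}

#' Relative absolute error between paired measurements
#'
#' Per pair, the absolute difference divided by the first measurement,
#' in percent: \eqn{e_i = 100 |x_i - y_i| / x_i}. Deliberately asymmetric
#' in (x, y): the first measurement is the reference.
#'
#' @param x,y paired numeric vectors; all x nonzero.
#' @return List with \code{errors} (per pair, percent) and \code{summary}
#'   (mean, sd, min, max).
#' @export
absoluteError <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x == 0)) stop("reference measurements (x) must be nonzero")
  e <- 100 * abs(x - y) / x
  list(errors = e,
       summary = c(mean = mean(e), sd = stats::sd(e),
                   min = min(e), max = max(e)))
}

#' Intraclass correlation coefficient
#'
#' Single-rater ICC from the two-way mean-squares decomposition of an
#' n subjects x k raters table with no missing cells. The default
#' \code{"ICC2"} is the two-way random-effects absolute-agreement form
#' ICC(2,1), the standard repeatability coefficient; \code{"ICC3"} is the
#' two-way mixed consistency form ICC(3,1) and \code{"ICC1"} the one-way
#' form ICC(1,1).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (n >= 3, k >= 2, no NA).
#' @param type one of "ICC2", "ICC3", "ICC1".
#' @return Scalar ICC.
#' @export
iccAgreement <- function(ratings, type = c("ICC2", "ICC3", "ICC1")) {
  type <- match.arg(type)
  stopifnot(is.matrix(ratings))
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters")
  if (anyNA(ratings)) stop("missing cells are not allowed")
  grand <- mean(ratings)
  rowM <- rowMeans(ratings); colM <- colMeans(ratings)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  switch(type,
    ICC2 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3 = (msr - mse) / (msr + (k - 1) * mse),
    ICC1 = {
      msw <- (ssc + sse) / (n * (k - 1))   # one-way: within-subject MS
      (msr - msw) / (msr + (k - 1) * msw)
    })
}

#' Split-plot factorial ANOVA
#'
#' Two-factor ANOVA with a between-subject factor (gender) and a
#' within-subject factor (spinal level), subject nested in the
#' between-subject factor as the error stratum. When every subject is
#' observed at every within level, the classical split-plot F tests are
#' used (\code{stats::aov} with an \code{Error(subject)} stratum; group
#' sizes may differ — the design stays orthogonal). With incomplete
#' within-subject data the model is refitted as a linear mixed model with
#' a random subject intercept and type-III F tests with Satterthwaite
#' degrees of freedom.
#'
#' @param data data.frame of observations.
#' @param response,between,within,subject column names.
#' @return data.frame with one row per effect (between, within,
#'   interaction): effect, df1, df2, F, p.
#' @export
splitPlotAnova <- function(data, response = "ratio_percent",
                           between = "gender", within = "level",
                           subject = "subject_id") {
  stopifnot(all(c(response, between, within, subject) %in% names(data)))
  d <- data.frame(
    y = data[[response]],
    b = factor(data[[between]]),
    w = factor(data[[within]]),
    s = factor(data[[subject]])
  )
  cells <- table(d$b, d$w)
  if (any(cells < 2)) {
    empty <- which(cells < 2, arr.ind = TRUE)
    stop("cells with fewer than 2 observations: ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  complete <- all(table(d$s, d$w) == 1)
  effects <- c(between, within, paste(between, within, sep = ":"))
  if (complete) {
    fit <- stats::aov(y ~ b * w + Error(s), data = d)
    sm <- summary(fit)
    betweenTab <- sm[["Error: s"]][[1]]
    withinTab <- sm[["Error: Within"]][[1]]
    out <- data.frame(
      effect = effects,
      df1 = c(betweenTab["b", "Df"], withinTab["w", "Df"],
              withinTab["b:w", "Df"]),
      df2 = c(betweenTab["Residuals", "Df"],
              rep(withinTab["Residuals", "Df"], 2)),
      F = c(betweenTab["b", "F value"], withinTab["w", "F value"],
            withinTab["b:w", "F value"]),
      p = c(betweenTab["b", "Pr(>F)"], withinTab["w", "Pr(>F)"],
            withinTab["b:w", "Pr(>F)"])
    )
  } else {
    fit <- lmerTest::lmer(y ~ b * w + (1 | s), data = d,
                          control = lme4::lmerControl(calc.derivs = FALSE))
    a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    out <- data.frame(
      effect = effects,
      df1 = a$NumDF, df2 = a$DenDF, F = a$`F value`, p = a$`Pr(>F)`
    )
  }
  rownames(out) <- NULL
  out
}

#' Tukey HSD post hoc comparisons
#'
#' All-pairs comparisons of group means by the studentized range with
#' pooled within-group variance (family-wise adjusted p values).
#'
#' @param values numeric vector of observations.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @return data.frame with columns pair, diff, lwr, upr, p_adj.
#' @export
tukeyHsd <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL)
}
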