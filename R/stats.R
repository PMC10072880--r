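#' Welch's unequal-variance t-test
#'
#' Two-sample t statistic with the Welch-Satterthwaite degrees of freedom;
#' used for young-versus-old comparisons within a tissue. When both groups
#' are constant, the p-value is 1 for equal means and 0 otherwise, by
#' convention.
#'
#' @param a,b Numeric samples of size >= 2.
#' @return List with `statistic`, `df`, `p_value`, `estimate` (mean
#'   difference `a - b`).
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stopf("welch_test needs >= 2 observations per group")
  }
  if (var(a) == 0 && var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf,
                df = length(a) + length(b) - 2,
                p_value = if (eq) 1 else 0,
                estimate = mean(a) - mean(b)))
  }
  fit <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, estimate = unname(diff(rev(fit$estimate))))
}

#' One-way ANOVA with Tukey HSD pairwise contrasts
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor), >= 3 levels, each with
#'   >= 2 observations.
#' @return data.frame with one row per pairwise contrast: `contrast`,
#'   `estimate`, `p_adj`.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3L) stopf("Tukey HSD needs >= 3 groups")
  if (any(table(groups) < 2L)) stopf("every group needs >= 2 observations")
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  data.frame(contrast = rownames(tk), estimate = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' Dunnett's many-to-one contrasts against a control group
#'
#' One-way ANOVA followed by Dunnett's multiple comparison of each
#' treatment against the named control (as used for treated-versus-control
#' spectra comparisons).
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param control Name of the control level.
#' @return data.frame with one row per treatment: `contrast`, `estimate`,
#'   `p_adj`.
#' @export
dunnett_test <- function(values, groups, control) {
  groups <- factor(groups)
  if (!control %in% levels(groups)) {
    stopf("control group '%s' not present", control)
  }
  if (any(table(groups) < 2L)) stopf("every group needs >= 2 observations")
  groups <- stats::relevel(groups, ref = control)
  dat <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = dat)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  data.frame(contrast = names(sm$test$coefficients),
             estimate = unname(sm$test$coefficients),
             p_adj = unname(as.numeric(sm$test$pvalues)),
             row.names = NULL)
}

#' Fieller confidence interval for a ratio of means
#'
#' Confidence interval for `mean(a) / mean(b)` from Fieller's theorem for
#' two independent Gaussian samples. With a pooled variance estimate
#' (`var_equal = TRUE`, the default) the interval is exact under equal
#' variances; `var_equal = FALSE` uses per-group variances with
#' Welch-Satterthwaite degrees of freedom. When the denominator mean is not
#' significantly nonzero at the chosen level, the bounded interval does not
#' exist and the result is flagged `bounded = FALSE` with infinite limits
#' rather than raising an error.
#'
#' @param a Numerator sample.
#' @param b Denominator sample.
#' @param level Confidence level (default 0.95).
#' @param var_equal Pool the variance estimate across groups.
#' @return List with `ratio`, `lower`, `upper`, `bounded`, `level`.
#' @export
fieller_ratio_ci <- function(a, b, level = 0.95, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    stopf("fieller_ratio_ci needs >= 2 observations per group")
  }
  ma <- mean(a); mb <- mean(b)
  na <- length(a); nb <- length(b)
  if (mb == 0) {
    return(list(ratio = NA_real_, lower = -Inf, upper = Inf,
                bounded = FALSE, level = level))
  }
  if (var_equal) {
    s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    va <- s2 / na; vb <- s2 / nb
    df <- na + nb - 2
  } else {
    va <- var(a) / na; vb <- var(b) / nb
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  ratio <- ma / mb
  if (va == 0 && vb == 0) {
    return(list(ratio = ratio, lower = ratio, upper = ratio,
                bounded = TRUE, level = level))
  }
  tq <- qt(1 - (1 - level) / 2, df)
  # Roots of (ma - rho mb)^2 = t^2 (va + rho^2 vb)
  A <- mb^2 - tq^2 * vb
  if (A <= 0) {
    return(list(ratio = ratio, lower = -Inf, upper = Inf,
                bounded = FALSE, level = level))
  }
  disc <- va * mb^2 + vb * ma^2 - tq^2 * va * vb
  root <- tq * sqrt(disc)
  list(ratio = ratio,
       lower = (ma * mb - root) / A,
       upper = (ma * mb + root) / A,
       bounded = TRUE, level = level)
}

#' Linear regression of mutation frequency on age
#'
#' Ordinary least squares of frequency against age with a pointwise
#' confidence band, as used to display clock-like accumulation of SNVs over
#' the lifespan.
#'
#' @param age Numeric ages (months); >= 3 points with >= 2 distinct ages.
#' @param frequency Mutation frequencies.
#' @param level Confidence level of the band.
#' @param at Ages at which to evaluate the band (default: the data ages).
#' @return List with `slope`, `intercept`, `r_squared`, and `band`
#'   (data.frame `age`, `fit`, `lower`, `upper`).
#' @export
age_regression <- function(age, frequency, level = 0.95, at = NULL) {
  if (length(age) != length(frequency)) {
    stopf("age and frequency must have equal length")
  }
  if (length(age) < 3L) stopf("age_regression needs >= 3 points")
  if (length(unique(age)) < 2L) stopf("all ages identical: slope undefined")
  fit <- lm(frequency ~ age)
  if (is.null(at)) at <- sort(unique(age))
  pred <- predict(fit, newdata = data.frame(age = at),
                  interval = "confidence", level = level)
  list(
    slope = unname(coef(fit)[["age"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r_squared = summary(fit)$r.squared,
    band = data.frame(age = at, fit = pred[, "fit"],
                      lower = pred[, "lwr"], upper = pred[, "upr"])
  )
}
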