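#' One-way ANOVA with Bonferroni correction over mean/max/ROM
#'
#' For every angle and outcome (`mean`, `max`, `rom`), performs a
#' single-factor analysis of variance across groups with the foot as the
#' statistical unit. The Bonferroni factor is 3 — the three outcomes tested
#' per angle — and is never applied across angles. Pairwise group
#' differences are assessed post hoc with two-sample t-tests on the pooled
#' within-group SD, Bonferroni-adjusted with the same factor.
#'
#' @param outcomes Long-format `data.frame` with columns `angle`, `outcome`
#'   (`"mean"`, `"max"`, `"rom"`), `group`, `value` (one row per foot).
#' @param alpha Significance level (default 0.05).
#' @param posthoc Also compute pairwise group comparisons (default `TRUE`).
#' @return List with `omnibus` (data.frame: angle, outcome, df1, df2, F,
#'   p, p_adj, significant) and `posthoc` (data.frame: angle, outcome,
#'   group1, group2, t, p, p_adj, significant), or `NULL` posthoc.
#' @export
anova_bonferroni <- function(outcomes, alpha = 0.05, posthoc = TRUE) {
  stopifnot(all(c("angle", "outcome", "group", "value") %in% names(outcomes)))
  omni <- list(); ph <- list()
  for (a in unique(outcomes$angle)) {
    for (oc in unique(outcomes$outcome)) {
      d <- outcomes[outcomes$angle == a & outcomes$outcome == oc, ]
      if (!nrow(d)) next
      g <- factor(d$group)
      if (nlevels(g) < 2L)
        stop("need at least two groups", call. = FALSE)
      if (any(table(g) < 2L))
        stop("each group needs at least two feet", call. = FALSE)
      if (all(tapply(d$value, g, stats::var) < 1e-20))
        stop("degenerate test: zero variance within every group", call. = FALSE)
      fit <- stats::aov(value ~ g, data = data.frame(value = d$value, g = g))
      s <- summary(fit)[[1L]]
      Fv <- s$`F value`[1L]; p <- s$`Pr(>F)`[1L]
      omni[[length(omni) + 1L]] <- data.frame(
        angle = a, outcome = oc, df1 = s$Df[1L], df2 = s$Df[2L],
        F = Fv, p = p, p_adj = min(1, 3 * p),
        significant = min(1, 3 * p) < alpha)
      if (posthoc) {
        mse <- s$`Mean Sq`[2L]; df2 <- s$Df[2L]
        lev <- levels(g)
        for (i in seq_len(nlevels(g) - 1L)) for (jj in (i + 1L):nlevels(g)) {
          vi <- d$value[g == lev[i]]; vj <- d$value[g == lev[jj]]
          se <- sqrt(mse * (1 / length(vi) + 1 / length(vj)))
          tv <- (mean(vi) - mean(vj)) / se
          pp <- 2 * stats::pt(-abs(tv), df2)
          ph[[length(ph) + 1L]] <- data.frame(
            angle = a, outcome = oc, group1 = lev[i], group2 = lev[jj],
            t = tv, p = pp, p_adj = min(1, 3 * pp),
            significant = min(1, 3 * pp) < alpha)
        }
      }
    }
  }
  list(omnibus = do.call(rbind, omni),
       posthoc = if (posthoc) do.call(rbind, ph) else NULL)
}

#' Shapiro-Wilk normality check
#'
#' Advisory normality screen for summary outcomes; the group comparison
#' proceeds regardless of its result, mirroring common practice for gait
#' parameters.
#'
#' @param values Numeric vector, 3 to 5000 observations.
#' @return List with `statistic` (W) and `p`.
#' @export
shapiro_wilk_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires between 3 and 5000 observations", call. = FALSE)
  if (stats::var(values) < 1e-20)
    stop("degenerate input: zero variance", call. = FALSE)
  s <- stats::shapiro.test(values)
  list(statistic = unname(s$statistic), p = s$p.value)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Numeric vectors of equal length (>= 3), e.g. a kinematic angle
#'   and a radiographic measure per foot.
#' @return List with `r`, `p`, and `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) < 1e-20 || stats::var(y) < 1e-20)
    stop("degenerate input: zero variance", call. = FALSE)
  if (abs(stats::cor(x, y)) >= 1 - 1e-12) {
    r <- stats::cor(x, y)
    return(list(r = r, p = 0, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
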