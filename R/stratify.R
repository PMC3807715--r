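#' Assign subjects to low/middle/high alpha3/alpha2 groups
#'
#' Fixed mode uses the published cutoffs with boundaries belonging to the
#' upper group: low for `r < 1`, middle for `1 <= r < 1.17`, high for
#' `r >= 1.17`.  Tertile mode derives cutoffs from the empirical 33.3 and
#' 66.7 percentiles of the sample, with the same boundary convention.
#'
#' @param ratios positive numeric vector of alpha3/alpha2 ratios.
#' @param mode `"fixed"` (default) or `"tertile"`.
#' @param cutoffs length-2 numeric cutoffs for fixed mode
#'   (default `c(1, 1.17)`).
#' @return factor with levels `low`, `middle`, `high`.
#' @export
assign_groups <- function(ratios, mode = c("fixed", "tertile"),
                          cutoffs = c(1, 1.17)) {
  mode <- match.arg(mode)
  if (length(ratios) == 0L) stop("`ratios` must be non-empty")
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("all ratios must be finite and positive")
  }
  if (mode == "tertile") {
    cutoffs <- unname(stats::quantile(ratios, c(1, 2) / 3, type = 7))
  }
  lab <- ifelse(ratios < cutoffs[1L], "low",
                ifelse(ratios < cutoffs[2L], "middle", "high"))
  factor(lab, levels = c("low", "middle", "high"))
}

#' Levene's test for homogeneity of variance (mean-centered)
#'
#' One-way ANOVA on absolute deviations from the group means, the SPSS
#' default used to choose between pooled-variance and Welch-type post hocs.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
levene_test <- function(x, g) {
  g <- droplevels(factor(g))
  ctr <- stats::ave(x, g, FUN = mean)
  z <- abs(x - ctr)
  if (stats::var(z) == 0) return(list(statistic = 0, df = c(NA, NA), p_value = 1))
  fit <- stats::anova(stats::lm(z ~ g))
  list(statistic = fit$`F value`[1L],
       df = c(fit$Df[1L], fit$Df[2L]),
       p_value = fit$`Pr(>F)`[1L])
}

#' Games-Howell pairwise comparisons
#'
#' Welch-type pairwise tests with studentized-range reference distribution;
#' appropriate under heteroscedasticity.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `p_value`.
#' @export
games_howell <- function(x, g) {
  g <- droplevels(factor(g))
  lev <- levels(g)
  k <- length(lev)
  m <- tapply(x, g, mean)
  v <- tapply(x, g, stats::var)
  n <- tapply(x, g, length)
  out <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    t <- abs(m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(t * sqrt(2), k, df, lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = lev[i], group2 = lev[j],
                                 diff = unname(m[i] - m[j]),
                                 p_value = unname(p)))
  }
  out
}

bonferroni_pairwise <- function(x, g) {
  g <- droplevels(factor(g))
  lev <- levels(g)
  k <- length(lev)
  m <- tapply(x, g, mean)
  n <- tapply(x, g, length)
  fit <- stats::anova(stats::lm(x ~ g))
  mse <- fit$`Mean Sq`[2L]
  dfe <- fit$Df[2L]
  npair <- k * (k - 1L) / 2L
  out <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    t <- abs(m[i] - m[j]) / se
    p <- min(1, 2 * stats::pt(t, dfe, lower.tail = FALSE) * npair)
    out <- rbind(out, data.frame(group1 = lev[i], group2 = lev[j],
                                 diff = unname(m[i] - m[j]),
                                 p_value = unname(p)))
  }
  out
}

#' Compare demographics and scores across ratio groups
#'
#' One-way ANOVA for continuous variables and a chi-squared test for
#' dichotomous ones; for continuous variables, Levene's test selects the
#' post hoc family (Games-Howell under heteroscedasticity, Bonferroni
#' otherwise).  Constant variables are flagged and reported with p = 1.
#'
#' @param cohort data.frame with a `group` column (factor) plus the
#'   variables to compare.
#' @param continuous character vector of continuous variable names; by
#'   default all numeric columns except `group`.
#' @param dichotomous character vector of dichotomous variable names
#'   (e.g. `"sex"`).
#' @param levene_alpha significance level for the variance-homogeneity
#'   gate (default 0.05).
#' @return list keyed by variable: each entry has `test`, `p_value`, and for
#'   continuous variables `posthoc` (data.frame) and `posthoc_method`.
#' @export
demographics_compare <- function(cohort, continuous = NULL,
                                 dichotomous = intersect("sex", names(cohort)),
                                 levene_alpha = 0.05) {
  if (!"group" %in% names(cohort)) stop("cohort must contain a `group` column")
  g <- droplevels(factor(cohort$group))
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("need >= 2 groups with >= 2 subjects each")
  }
  if (is.null(continuous)) {
    continuous <- setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)],
                          c("id", dichotomous))
  }
  res <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    ok <- is.finite(x)
    if (stats::var(x[ok]) == 0) {
      res[[v]] <- list(test = "anova", p_value = 1, flag = "constant_variable")
      next
    }
    fit <- stats::anova(stats::lm(x[ok] ~ g[ok]))
    lev <- levene_test(x[ok], g[ok])
    hetero <- lev$p_value < levene_alpha
    ph <- if (hetero) games_howell(x[ok], g[ok]) else bonferroni_pairwise(x[ok], g[ok])
    res[[v]] <- list(test = "anova", p_value = fit$`Pr(>F)`[1L],
                     levene_p = lev$p_value,
                     posthoc_method = if (hetero) "games_howell" else "bonferroni",
                     posthoc = ph)
  }
  for (v in dichotomous) {
    x <- cohort[[v]]
    tab <- table(x, g)
    if (nrow(tab) < 2L) {
      res[[v]] <- list(test = "chisq", p_value = 1, flag = "constant_variable")
    } else {
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      res[[v]] <- list(test = "chisq", p_value = p)
    }
  }
  res
}
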