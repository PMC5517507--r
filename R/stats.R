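#' Two-way mixed-model intraclass correlation (consistency)
#'
#' Computes the consistency-type two-way mixed-model ICC (Shrout-Fleiss
#' ICC(3,1) and ICC(3,k)) from the two-way ANOVA decomposition of a
#' subjects x raters rating matrix:
#' \deqn{ICC_{single} = (MS_R - MS_E) / (MS_R + (k-1) MS_E)}
#' \deqn{ICC_{average} = (MS_R - MS_E) / MS_R}
#' with the standard F-based 95% confidence intervals. A matrix with zero
#' between-subject and zero error variance is perfect agreement by
#' convention (ICC = 1).
#'
#' @param ratings n_subjects x k numeric matrix, no missing cells, n >= 3,
#'   k >= 2
#' @param conf confidence level for the intervals
#' @return object of class `icc_result`: `icc_single`, `icc_average`,
#'   `ci_single`, `ci_average`, `n_subjects`, `k_raters`, mean squares
#' @export
icc_two_way_mixed <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3L) stop_pp("ICC needs at least 3 subjects")
  if (k < 2L) stop_pp("ICC needs at least 2 raters")
  if (anyNA(ratings)) stop_pp("ICC ratings must have no missing cells")
  g <- mean(ratings)
  ss_rows <- k * sum((rowMeans(ratings) - g)^2)
  ss_cols <- n * sum((colMeans(ratings) - g)^2)
  ss_tot <- sum((ratings - g)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (mse <= 1e-30) {
    ## perfect within-subject agreement (including the all-constant case)
    res <- list(icc_single = 1, icc_average = 1,
                ci_single = c(1, 1), ci_average = c(1, 1))
  } else {
    single <- (msr - mse) / (msr + (k - 1) * mse)
    average <- (msr - mse) / msr
    f <- msr / mse
    alpha <- 1 - conf
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    res <- list(
      icc_single = single, icc_average = average,
      ci_single = c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1)),
      ci_average = c(1 - 1 / fl, 1 - 1 / fu))
  }
  structure(c(res, list(n_subjects = n, k_raters = k,
                        ms_rows = msr, ms_err = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (two-way mixed, consistency), n=%d, k=%d\n  single  %.3f (%.3f-%.3f)\n  average %.3f (%.3f-%.3f)\n",
              x$n_subjects, x$k_raters, x$icc_single, x$ci_single[1],
              x$ci_single[2], x$icc_average, x$ci_average[1], x$ci_average[2]))
  invisible(x)
}

mean_sd <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
}

#' Compare variables between groups
#'
#' Continuous variables: independent two-sample t-test for two groups;
#' one-way ANOVA and Kruskal-Wallis for more than two (both are reported,
#' as group-comparison tables in this field mix them). Categorical
#' variables: Pearson chi-squared without continuity correction. Group
#' summaries are formatted mean ± SD.
#'
#' @param table data.frame of per-eye rows
#' @param grouping name of the grouping column
#' @param variables columns to compare (default: all others)
#' @return data.frame: variable, per-group summary columns, statistic, p
#'   (and `p_kruskal` for > 2 groups), test name
#' @export
compare_groups <- function(table, grouping, variables = NULL) {
  if (!grouping %in% names(table)) stop_pp(sprintf("no column `%s`", grouping))
  g <- as.factor(table[[grouping]])   # declared empty levels are kept
  counts <- table(g)
  if (nlevels(g) < 2L) stop_pp("need at least 2 groups")
  if (any(counts == 0L)) {
    stop_pp(sprintf("empty group: %s", names(counts)[counts == 0][1]))
  }
  variables <- variables %||% setdiff(names(table), grouping)
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    base <- data.frame(variable = v, stringsAsFactors = FALSE)
    if (is.numeric(x)) {
      if (any(tapply(x, g, function(z) sum(is.finite(z))) < 2L)) {
        stop_pp(sprintf("variable `%s`: a group has fewer than 2 observations", v))
      }
      summ <- tapply(x, g, mean_sd)
      for (lev in levels(g)) base[[lev]] <- unname(summ[lev])
      if (nlevels(g) == 2L) {
        tt <- t.test(x ~ g, var.equal = TRUE)
        base$statistic <- unname(tt$statistic)
        base$p <- tt$p.value
        base$p_kruskal <- NA_real_
        base$test <- "t"
      } else {
        av <- anova(aov(x ~ g))
        kw <- kruskal.test(x ~ g)
        base$statistic <- av[1, "F value"]
        base$p <- av[1, "Pr(>F)"]
        base$p_kruskal <- kw$p.value
        base$test <- "anova+kruskal"
      }
    } else {
      tab <- table(factor(x), g)
      for (lev in levels(g)) {
        base[[lev]] <- paste(tab[, lev], collapse = ":")
      }
      if (nrow(tab) >= 2L) {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        base$statistic <- unname(ct$statistic)
        base$p <- ct$p.value
      } else {
        base$statistic <- NA_real_   # a single observed level: no test
        base$p <- NA_real_
      }
      base$p_kruskal <- NA_real_
      base$test <- "chisq"
    }
    base
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlation matrix
#'
#' @param table data.frame
#' @param variables numeric columns to correlate (>= 2)
#' @return data.frame: var1, var2, r, p, n, flag (`"zero_variance"` where R
#'   is undefined)
#' @export
correlation_matrix <- function(table, variables) {
  if (length(variables) < 2L) stop_pp("need at least 2 variables")
  pairs <- utils::combn(variables, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pr <- pairs[, j]
    x <- table[[pr[1]]]
    y <- table[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) stop_pp(sprintf("fewer than 3 complete pairs for %s ~ %s", pr[1], pr[2]))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(data.frame(var1 = pr[1], var2 = pr[2], r = NA_real_,
                        p = NA_real_, n = sum(ok), flag = "zero_variance",
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pr[1], var2 = pr[2], r = unname(ct$estimate),
               p = ct$p.value, n = sum(ok), flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Univariate screen followed by multivariate linear regression
#'
#' Each candidate is regressed on the dependent variable alone; candidates
#' whose univariate P falls below `screen_p` enter a joint multivariate
#' ordinary-least-squares model, reported with 95% confidence intervals.
#' Collinear survivors are kept (no dropping); a large condition number of
#' the multivariate design is reported as a warning flag.
#'
#' @param table data.frame
#' @param dependent name of the dependent variable
#' @param candidates names of candidate predictors
#' @param screen_p univariate inclusion threshold (default 0.2)
#' @return object of class `regression_report`: `univariate` (variable,
#'   beta, p), `multivariate` (variable, beta, ci_low, ci_high, p),
#'   `selected`, `screen_p`, `condition_number`, `collinearity_warning`
#' @export
regression_tables <- function(table, dependent, candidates, screen_p = 0.2) {
  num_ok <- vapply(c(dependent, candidates), function(v) is.numeric(table[[v]]),
                   logical(1))
  if (!all(num_ok)) stop_pp("dependent and candidates must be numeric columns")
  if (nrow(table) <= length(candidates) + 2L) {
    stop_pp("need n > number of candidates + 2")
  }
  uni <- do.call(rbind, lapply(candidates, function(v) {
    fit <- lm(stats::reformulate(v, dependent), data = table)
    cf <- summary(fit)$coefficients
    data.frame(variable = v, beta = cf[2, 1], p = cf[2, 4],
               stringsAsFactors = FALSE)
  }))
  selected <- uni$variable[uni$p < screen_p]
  multi <- NULL
  cond <- NA_real_
  if (length(selected) > 0L) {
    fit <- lm(stats::reformulate(selected, dependent), data = table)
    cf <- summary(fit)$coefficients
    ci <- confint(fit)
    keep <- rownames(cf) != "(Intercept)"
    multi <- data.frame(variable = rownames(cf)[keep], beta = cf[keep, 1],
                        ci_low = ci[keep, 1], ci_high = ci[keep, 2],
                        p = cf[keep, 4], row.names = NULL,
                        stringsAsFactors = FALSE)
    cond <- kappa(stats::model.matrix(fit), exact = TRUE)
  }
  structure(list(univariate = uni, multivariate = multi, selected = selected,
                 screen_p = screen_p, condition_number = cond,
                 collinearity_warning = is.finite(cond) && cond > 1e4),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("regression_report: screen P < %.2g kept %d of %d candidates\n",
              x$screen_p, length(x$selected), nrow(x$univariate)))
  print(x$univariate)
  if (!is.null(x$multivariate)) {
    cat("multivariate:\n")
    print(x$multivariate)
  }
  invisible(x)
}
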