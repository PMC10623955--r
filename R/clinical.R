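#' Baseline characteristics comparison table
#'
#' Compares every covariate between cases and controls. Continuous
#' variables use the pooled-variance Student t-test when both groups pass a
#' Shapiro-Wilk normality check (p > 0.05), otherwise the Mann-Whitney U
#' test; binary/categorical variables use the Yates-corrected chi-square
#' test, switching to Fisher's exact test when any expected cell count
#' falls below 5. Summaries are mean +/- SD, median (quartiles) or n (%).
#'
#' @param data Tibble with a `group` column ("AF"/"control") and one column
#'   per covariate; an id column may be excluded via `id_col`.
#' @param id_col Name of a subject identifier column to ignore (default
#'   "subject_id" when present).
#' @return Tibble: `variable`, `type`, `summary_af`, `summary_control`,
#'   `test`, `statistic`, `p_value`.
#' @export
baseline_table <- function(data, id_col = "subject_id") {
  stopifnot("group" %in% names(data))
  vars <- setdiff(names(data), c("group", intersect(id_col, names(data))))
  af <- data$group == "AF"
  if (sum(af) < 2 || sum(!af) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    if (all(is.na(x))) {
      warning("variable '", v, "' is all-missing; skipped", call. = FALSE)
      return(NULL)
    }
    categorical <- is.character(x) || is.factor(x) || is.logical(x) ||
      dplyr::n_distinct(x[!is.na(x)]) <= 2
    if (categorical) {
      baseline_categorical(v, x, af)
    } else {
      baseline_continuous(v, x, af)
    }
  })
}

baseline_continuous <- function(v, x, af) {
  xa <- x[af & !is.na(x)]; xc <- x[!af & !is.na(x)]
  normal <- function(z) {
    if (length(z) < 3 || stats::sd(z) == 0) return(FALSE)
    stats::shapiro.test(z)$p.value > 0.05
  }
  if (normal(xa) && normal(xc)) {
    tt <- stats::t.test(xa, xc, var.equal = TRUE)
    tibble::tibble(
      variable = v, type = "continuous",
      summary_af = sprintf("%.2f ± %.2f", mean(xa), stats::sd(xa)),
      summary_control = sprintf("%.2f ± %.2f", mean(xc), stats::sd(xc)),
      test = "student-t", statistic = unname(tt$statistic),
      p_value = tt$p.value
    )
  } else {
    p <- wilcox_rank_sum(xa, xc)
    qs <- function(z) sprintf("%.2f (%.2f-%.2f)", stats::median(z),
                              stats::quantile(z, 0.25), stats::quantile(z, 0.75))
    tibble::tibble(
      variable = v, type = "continuous",
      summary_af = qs(xa), summary_control = qs(xc),
      test = "mann-whitney", statistic = NA_real_, p_value = p
    )
  }
}

baseline_categorical <- function(v, x, af) {
  tab <- table(factor(af, c(TRUE, FALSE), c("AF", "control")), x)
  expected <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$expected)
  pct <- function(g) {
    n <- sum(af == g & !is.na(x))
    lv <- sort(unique(x[!is.na(x)]), decreasing = TRUE)[1]
    k <- sum(x[af == g] == lv, na.rm = TRUE)
    sprintf("%d (%.1f%%)", k, 100 * k / n)
  }
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    tibble::tibble(variable = v, type = "categorical",
                   summary_af = pct(TRUE), summary_control = pct(FALSE),
                   test = "fisher", statistic = NA_real_, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    tibble::tibble(variable = v, type = "categorical",
                   summary_af = pct(TRUE), summary_control = pct(FALSE),
                   test = "chi-square", statistic = unname(ct$statistic),
                   p_value = ct$p.value)
  }
}

#' Pooled-variance Student t-test from summary statistics
#'
#' Two-sided t-test computed from group means, SDs and sizes alone, for
#' checking published baseline-table rows.
#'
#' @param mean1,sd1,n1 First group summary (n >= 2, sd > 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' t_test_from_summary(62.48, 10.66, 23, 59.65, 12.45, 23)
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pearson correlation with complete-case handling
#'
#' @param x,y Numeric vectors (pairs with any NA are dropped; >= 3 complete
#'   pairs required).
#' @return Tibble: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# crude but standard separation heuristic for logistic fits
glm_separated <- function(fit) {
  !fit$converged || any(abs(stats::coef(fit)[-1]) > 15) ||
    any(summary(fit)$coefficients[-1, "Std. Error"] > 100)
}

#' Univariate logistic screen of clinical covariates
#'
#' Fits one single-predictor logistic regression of case status per
#' covariate and marks the candidates passing `p < alpha`, always keeping
#' the forced variables. Perfectly separated predictors are flagged and
#' retained with a warning.
#'
#' @param data Clinical tibble with a `group` column.
#' @param alpha Screening threshold on the Wald p-value (default 0.100).
#' @param forced Variables always carried forward (default "DM").
#' @param variables Covariates to screen (default: every column except
#'   `group` and `id_col`).
#' @param id_col Identifier column to ignore.
#' @return Tibble: `variable`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `separation`, `selected` (p < alpha), `forced`, `candidate`
#'   (selected or forced).
#' @export
univariate_screen <- function(data, alpha = 0.100, forced = "DM",
                              variables = NULL, id_col = "subject_id") {
  stopifnot("group" %in% names(data))
  vars <- variables %||%
    setdiff(names(data), c("group", intersect(id_col, names(data))))
  y <- as.numeric(data$group == "AF")
  out <- purrr::map_dfr(vars, function(v) {
    d <- tibble::tibble(y = y, x = data[[v]])
    d <- d[stats::complete.cases(d), ]
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(), data = d))
    sep <- glm_separated(fit)
    if (sep) {
      warning("possible separation for variable '", v,
              "'; retained with unreliable Wald statistics", call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
    tibble::tibble(
      variable = v, or = exp(b),
      ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
      p_value = sm["x", "Pr(>|z|)"], separation = sep
    )
  })
  out |>
    dplyr::mutate(
      selected = .data$p_value < alpha,
      forced = .data$variable %in% forced,
      candidate = .data$selected | .data$forced
    )
}

#' Multivariable logistic regression for case status
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of case status
#' on the selected covariates, complete cases only, with Wald standard
#' errors, odds ratios and 95% CIs. Non-convergence or separation is
#' flagged, never silent.
#'
#' @param data Clinical tibble with a `group` column.
#' @param variables Covariates to include (character).
#' @return Object of class `af_logistic` wrapping the glm fit, with
#'   `converged` flag and the input variable list.
#' @export
fit_logistic <- function(data, variables) {
  stopifnot("group" %in% names(data), length(variables) >= 0)
  miss <- setdiff(variables, names(data))
  if (length(miss) > 0) {
    stop("variable(s) not in table: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data[, c("group", variables), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$.y <- as.numeric(d$group == "AF")
  rhs <- if (length(variables) == 0) "1" else
    paste(sprintf("`%s`", variables), collapse = " + ")
  fit <- suppressWarnings(stats::glm(
    stats::as.formula(paste(".y ~", rhs)),
    family = stats::binomial(), data = d,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  sep <- if (length(variables) > 0) glm_separated(fit) else !fit$converged
  if (sep) {
    warning("logistic fit flagged: non-convergence or separation; ",
            "Wald statistics unreliable", call. = FALSE)
  }
  structure(list(fit = fit, variables = variables,
                 converged = fit$converged && !sep,
                 n = nrow(d), n_case = sum(d$.y)),
            class = "af_logistic")
}

#' @export
print.af_logistic <- function(x, ...) {
  cat(sprintf("<af_logistic> %d subjects (%d cases), %d covariate(s)%s\n",
              x$n, x$n_case, length(x$variables),
              ifelse(x$converged, "", " [FLAGGED: separation/non-convergence]")))
  print(tidy.af_logistic(x))
  invisible(x)
}
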