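#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an OPLS-DA model: one row per variable
#'
#' @param x A `ba_oplsda` model.
#' @param ... Unused.
#' @return Tibble: `ba`, `weight`, `loading`, `vip`.
#' @export
tidy.ba_oplsda <- function(x, ...) {
  tibble::tibble(ba = names(x$vip), weight = unname(x$w),
                 loading = unname(x$p), vip = unname(x$vip))
}

#' One-row OPLS-DA model summary
#'
#' @param x A `ba_oplsda` model.
#' @param ... Unused.
#' @return Tibble: `n`, `n_variables`, `n_orthogonal`, `r2x`, `r2y`, `q2`.
#' @export
glance.ba_oplsda <- function(x, ...) {
  tibble::tibble(n = length(x$t), n_variables = length(x$w),
                 n_orthogonal = x$n_orthogonal,
                 r2x = x$r2x, r2y = x$r2y, q2 = x$q2)
}

#' Tidy a ROC curve: one row per threshold
#'
#' @param x A `ba_roc` object.
#' @param ... Unused.
#' @return The threshold/sensitivity/specificity tibble.
#' @export
tidy.ba_roc <- function(x, ...) x$curve

#' One-row ROC summary
#'
#' @param x A `ba_roc` object.
#' @param ... Unused.
#' @return Tibble: `auc`, `ci_low`, `ci_high`, `cutpoint`, `sens_at_cut`,
#'   `spec_at_cut`, `direction`, `n_case`, `n_control`.
#' @export
glance.ba_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci[1], ci_high = x$ci[2],
                 cutpoint = x$cutpoint, sens_at_cut = x$sens_at_cut,
                 spec_at_cut = x$spec_at_cut, direction = x$direction,
                 n_case = x$n_case, n_control = x$n_control)
}

#' Tidy a logistic model: odds ratios with Wald CIs
#'
#' @param x An `af_logistic` fit.
#' @param ... Unused.
#' @return Tibble: `variable`, `estimate`, `std_error`, `or`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
tidy.af_logistic <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  est <- unname(sm[, "Estimate"]); se <- unname(sm[, "Std. Error"])
  tibble::tibble(
    variable = rownames(sm),
    estimate = est,
    std_error = se,
    or = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se),
    p_value = unname(sm[, "Pr(>|z|)"])
  )
}

#' One-row logistic fit summary
#'
#' @param x An `af_logistic` fit.
#' @param ... Unused.
#' @return Tibble: `n`, `n_case`, `converged`, `deviance`, `aic`.
#' @export
glance.af_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, n_case = x$n_case, converged = x$converged,
                 deviance = x$fit$deviance, aic = x$fit$aic)
}

#' Tidy a PCA: explained variance per component
#'
#' @param x A `ba_pca` object.
#' @param ... Unused.
#' @return The `explained_variance` tibble.
#' @export
tidy.ba_pca <- function(x, ...) x$explained_variance
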