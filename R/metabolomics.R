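#' Summarise bile-acid panel composition
#'
#' Computes per-sample total bile-acid load, the secondary-BA proportion
#' (sum of secondary analytes over total), and a Wilcoxon rank-sum group
#' test of that proportion. Samples with zero total are flagged and
#' excluded from the test (their proportion is undefined).
#'
#' @param panel Tibble: `sample_id` + one numeric column per bile acid
#'   (nmol/g).
#' @param groups Tibble: `sample_id`, `group`.
#' @param class_map Classification tibble from [ba_class_map()]; must cover
#'   every panel analyte.
#' @return List with `per_sample` (tibble: `sample_id`, `group`, `total`,
#'   `secondary_total`, `secondary_prop`, `excluded`) and `test` (tibble:
#'   `p_value`, `median_af`, `median_control`, `n_excluded`).
#' @export
summarize_composition <- function(panel, groups, class_map = ba_class_map()) {
  stopifnot("sample_id" %in% names(panel))
  bas <- setdiff(names(panel), "sample_id")
  uncovered <- setdiff(bas, class_map$ba)
  if (length(uncovered) > 0) {
    stop("class map does not cover panel analyte(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  secondary <- class_map$ba[class_map$class == "secondary"]
  sec_cols <- intersect(bas, secondary)
  per_sample <- panel |>
    dplyr::mutate(
      total = rowSums(dplyr::pick(dplyr::all_of(bas))),
      secondary_total = rowSums(dplyr::pick(dplyr::all_of(sec_cols)))
    ) |>
    dplyr::mutate(
      excluded = .data$total == 0,
      secondary_prop = ifelse(.data$excluded, NA_real_,
                              .data$secondary_total / .data$total)
    ) |>
    dplyr::left_join(groups, by = "sample_id") |>
    dplyr::select("sample_id", "group", "total", "secondary_total",
                  "secondary_prop", "excluded")
  ok <- per_sample |> dplyr::filter(!.data$excluded)
  x <- ok$secondary_prop[ok$group == "AF"]
  y <- ok$secondary_prop[ok$group == "control"]
  test <- tibble::tibble(
    p_value = wilcox_rank_sum(x, y),
    median_af = stats::median(x),
    median_control = stats::median(y),
    n_excluded = sum(per_sample$excluded)
  )
  list(per_sample = per_sample, test = test)
}

#' Differential bile acids with volcano coordinates
#'
#' Per-analyte Wilcoxon rank-sum tests and median fold changes (same rules
#' as [differential_features()]), plus volcano-plot coordinates.
#'
#' @inheritParams summarize_composition
#' @param adjust Add a Benjamini-Hochberg `q_value` column (default FALSE).
#' @return Tibble: `ba`, `median_af`, `median_control`, `log2_fc`,
#'   `p_value`, `direction`, `neglog10_p`.
#' @export
differential_bas <- function(panel, groups, adjust = FALSE) {
  stopifnot("sample_id" %in% names(panel))
  long <- panel |>
    tidyr::pivot_longer(-"sample_id", names_to = "ba", values_to = "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  differential_features(long, groups, adjust = adjust) |>
    dplyr::mutate(neglog10_p = -log10(.data$p_value))
}

# log10(x + eps_j) with per-variable pseudo-count eps_j = half the minimum
# nonzero value, then centering / unit-variance scaling. Constant or
# all-zero variables are dropped with a warning.
scale_panel_matrix <- function(panel, scaling = c("log10-uv", "uv", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(panel[, setdiff(names(panel), "sample_id"), drop = FALSE])
  rownames(X) <- panel$sample_id
  if (scaling == "log10-uv") {
    eps <- apply(X, 2, function(v) {
      nz <- v[v > 0]
      if (length(nz) == 0) NA_real_ else min(nz) / 2
    })
    drop_zero <- is.na(eps)
    if (any(drop_zero)) {
      warning("dropping all-zero variable(s): ",
              paste(colnames(X)[drop_zero], collapse = ", "), call. = FALSE)
      X <- X[, !drop_zero, drop = FALSE]; eps <- eps[!drop_zero]
    }
    X <- log10(sweep(X, 2, eps, "+"))
  } else {
    eps <- rep(0, ncol(X))
  }
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (scaling %in% c("log10-uv", "uv")) {
    const <- sds == 0
    if (any(const)) {
      warning("dropping constant variable(s) under unit-variance scaling: ",
              paste(colnames(X)[const], collapse = ", "), call. = FALSE)
      X <- X[, !const, drop = FALSE]
      ctr <- ctr[!const]; sds <- sds[!const]; eps <- eps[!const]
    }
    X <- scale(X, center = ctr, scale = sds)
  } else {
    X <- scale(X, center = ctr, scale = FALSE)
    sds <- rep(1, ncol(X))
  }
  list(X = X, center = ctr, sd = sds, eps = eps, scaling = scaling)
}

#' Principal component analysis of a bile-acid panel
#'
#' PCA on log10-transformed, unit-variance-scaled concentrations (the same
#' preprocessing as the discriminant model; configurable).
#'
#' @inheritParams summarize_composition
#' @param groups Optional sample-group tibble carried into the scores.
#' @param scaling "log10-uv" (default), "uv" or "none" (centering only).
#' @return Object of class `ba_pca`: list with `scores` (tibble),
#'   `loadings` (tibble), `explained_variance` (tibble: `component`,
#'   `variance`, `proportion`), and the scaling parameters.
#' @export
pca_scores <- function(panel, groups = NULL, scaling = "log10-uv") {
  stopifnot("sample_id" %in% names(panel), nrow(panel) >= 2,
            ncol(panel) >= 3)
  sc <- scale_panel_matrix(panel, scaling)
  pc <- stats::prcomp(sc$X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  scores <- tibble::as_tibble(pc$x) |>
    dplyr::mutate(sample_id = panel$sample_id, .before = 1)
  if (!is.null(groups)) scores <- dplyr::left_join(scores, groups, by = "sample_id")
  structure(list(
    scores = scores,
    loadings = tibble::as_tibble(pc$rotation) |>
      dplyr::mutate(ba = rownames(pc$rotation), .before = 1),
    explained_variance = tibble::tibble(
      component = paste0("PC", seq_along(ev)),
      variance = ev, proportion = ev / sum(ev)
    ),
    center = sc$center, sd = sc$sd, eps = sc$eps, scaling = sc$scaling
  ), class = "ba_pca")
}

#' @export
print.ba_pca <- function(x, ...) {
  p1 <- 100 * x$explained_variance$proportion[1]
  p2 <- if (nrow(x$explained_variance) > 1) 100 * x$explained_variance$proportion[2] else 0
  cat(sprintf("<ba_pca> %d samples x %d variables; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), nrow(x$loadings), p1, p2))
  invisible(x)
}

# ---- OPLS-DA ---------------------------------------------------------------

opls_core <- function(X, y, n_ortho) {
  w <- drop(crossprod(X, y)) / drop(crossprod(y))
  w <- w / sqrt(sum(w^2))
  W_o <- P_o <- NULL
  T_o <- NULL
  Xd <- X
  if (n_ortho > 0) {
    W_o <- matrix(0, ncol(X), n_ortho)
    P_o <- matrix(0, ncol(X), n_ortho)
    T_o <- matrix(0, nrow(X), n_ortho)
    for (k in seq_len(n_ortho)) {
      t_p <- drop(Xd %*% w)
      p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
      w_o <- p - sum(w * p) * w
      nw <- sqrt(sum(w_o^2))
      if (nw < 1e-12) {
        stop("no orthogonal variation left to extract (n_orthogonal too ",
             "large for the data rank)", call. = FALSE)
      }
      w_o <- w_o / nw
      t_o <- drop(Xd %*% w_o)
      p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
      Xd <- Xd - tcrossprod(t_o, p_o)
      W_o[, k] <- w_o; P_o[, k] <- p_o; T_o[, k] <- t_o
    }
  }
  t_pred <- drop(Xd %*% w)
  p_pred <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  c_coef <- sum(y * t_pred) / sum(t_pred^2)
  list(w = w, t = t_pred, p = p_pred, c = c_coef,
       W_o = W_o, P_o = P_o, T_o = T_o, X_deflated = Xd)
}

opls_predict_y <- function(fit, Xnew) {
  Xd <- Xnew
  if (!is.null(fit$W_o)) {
    for (k in seq_len(ncol(fit$W_o))) {
      t_o <- drop(Xd %*% fit$W_o[, k])
      Xd <- Xd - tcrossprod(t_o, fit$P_o[, k])
    }
  }
  drop(Xd %*% fit$w) * fit$c
}

#' Fit an OPLS-DA model to a bile-acid panel
#'
#' Orthogonal projections to latent structures discriminant analysis by the
#' NIPALS construction: the class response (case = 1, control = 0, then
#' centred) defines a single predictive component; `n_orthogonal`
#' class-orthogonal components are removed from the predictors first.
#' Predictors are log10-transformed and unit-variance scaled by default.
#' Q2 is estimated by 7-fold venetian-blind cross-validation (interleaved
#' folds; scaling refit on each training split). Variable importance in
#' projection (VIP) is computed on the predictive component, so the mean of
#' squared VIPs is exactly 1.
#'
#' @inheritParams summarize_composition
#' @param n_orthogonal Number of orthogonal components (default 1; 0 gives
#'   a plain one-component PLS-DA).
#' @param scaling "log10-uv" (default), "uv" or "none".
#' @param cv Compute the cross-validated Q2 (default TRUE).
#' @param cv_folds Number of venetian-blind folds (default 7).
#' @return Object of class `ba_oplsda`: weights `w` (unit norm), predictive
#'   scores `t`, orthogonal scores `t_o`, loadings, `vip` (named), `r2x`,
#'   `r2y`, `q2`, scaling parameters and sample metadata.
#' @export
fit_oplsda <- function(panel, groups, n_orthogonal = 1,
                       scaling = "log10-uv", cv = TRUE, cv_folds = 7) {
  stopifnot("sample_id" %in% names(panel))
  grp <- groups$group[match(panel$sample_id, groups$sample_id)]
  if (any(is.na(grp))) stop("sample(s) missing from groups table", call. = FALSE)
  if (sum(grp == "AF") < 3 || sum(grp == "control") < 3) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  sc <- scale_panel_matrix(panel, scaling)
  X <- sc$X
  if (n_orthogonal < 0 || n_orthogonal >= min(dim(X))) {
    stop("n_orthogonal must be in [0, rank)", call. = FALSE)
  }
  y_raw <- as.numeric(grp == "AF")
  y <- y_raw - mean(y_raw)
  fit <- opls_core(X, y, n_orthogonal)

  K <- ncol(X)
  vip <- sqrt(K) * abs(fit$w)
  names(vip) <- colnames(X)

  ss_x <- sum(X^2)
  expl_x <- sum(fit$t^2) * sum(fit$p^2)
  if (n_orthogonal > 0) {
    expl_x <- expl_x + sum(purrr::map_dbl(seq_len(n_orthogonal), function(k) {
      sum(fit$T_o[, k]^2) * sum(fit$P_o[, k]^2)
    }))
  }
  y_hat <- fit$t * fit$c
  r2y <- 1 - sum((y - y_hat)^2) / sum(y^2)

  q2 <- NA_real_
  if (cv) {
    q2 <- opls_q2(panel, y_raw, n_orthogonal, scaling, cv_folds)
  }

  structure(list(
    w = fit$w, t = fit$t, p = fit$p, c = fit$c,
    t_o = fit$T_o, w_o = fit$W_o, p_o = fit$P_o,
    vip = vip, r2x = expl_x / ss_x, r2y = r2y, q2 = q2,
    n_orthogonal = n_orthogonal,
    center = sc$center, sd = sc$sd, eps = sc$eps, scaling = sc$scaling,
    sample_id = panel$sample_id, group = grp, y = y
  ), class = "ba_oplsda")
}

# 7-fold venetian-blind (interleaved) cross-validated Q2 on the 0/1 response.
opls_q2 <- function(panel, y_raw, n_orthogonal, scaling, cv_folds) {
  n <- nrow(panel)
  folds <- (seq_len(n) - 1) %% cv_folds + 1
  press <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    sc_tr <- scale_panel_matrix(panel[tr, , drop = FALSE], scaling)
    y_tr <- y_raw[tr] - mean(y_raw[tr])
    fit <- opls_core(sc_tr$X, y_tr, n_orthogonal)
    X_te <- as.matrix(panel[te, names(sc_tr$eps), drop = FALSE])
    if (scaling == "log10-uv") X_te <- log10(sweep(X_te, 2, sc_tr$eps, "+"))
    X_te <- scale(X_te, center = sc_tr$center,
                  scale = if (scaling == "none") FALSE else sc_tr$sd)
    y_hat <- opls_predict_y(fit, X_te) + mean(y_raw[tr])
    press <- press + sum((y_raw[te] - y_hat)^2)
  }
  1 - press / sum((y_raw - mean(y_raw))^2)
}

#' @export
print.ba_oplsda <- function(x, ...) {
  cat(sprintf(
    "<ba_oplsda> 1 predictive + %d orthogonal component(s), %d variables\n",
    x$n_orthogonal, length(x$w)))
  cat(sprintf("  R2X %.3f  R2Y %.3f  Q2 %s\n", x$r2x, x$r2y,
              ifelse(is.na(x$q2), "not computed", sprintf("%.3f", x$q2))))
  invisible(x)
}

#' Select biomarker candidates by VIP
#'
#' Returns the variables whose VIP on the predictive component exceeds the
#' threshold (strict inequality), annotated with their differential-test
#' p-values when a table is supplied.
#'
#' @param model A fitted [fit_oplsda()] model.
#' @param threshold VIP cut (default 1, strict `>`).
#' @param p_table Optional tibble from [differential_bas()] with `ba` and
#'   `p_value` columns.
#' @return Tibble: `ba`, `vip`, and `p_value`/`direction` when available,
#'   sorted by decreasing VIP.
#' @export
vip_select <- function(model, threshold = 1, p_table = NULL) {
  stopifnot(inherits(model, "ba_oplsda"))
  out <- tibble::tibble(ba = names(model$vip), vip = unname(model$vip)) |>
    dplyr::filter(.data$vip > threshold) |>
    dplyr::arrange(dplyr::desc(.data$vip))
  if (!is.null(p_table)) {
    keep <- intersect(c("ba", "p_value", "direction"), names(p_table))
    out <- dplyr::left_join(out, p_table[keep], by = "ba")
  }
  out
}

#' Permutation test of OPLS-DA validity
#'
#' Refits the model under random permutations of the class labels and
#' reports the permuted Q2 values; a sound model's permuted Q2 should fall
#' at or below zero almost always.
#'
#' @inheritParams fit_oplsda
#' @param n_perm Number of permutations (default 100).
#' @return Tibble: `perm`, `q2`.
#' @export
oplsda_permutation <- function(panel, groups, n_orthogonal = 1,
                               scaling = "log10-uv", n_perm = 100) {
  purrr::map_dfr(seq_len(n_perm), function(i) {
    g2 <- groups
    g2$group <- sample(g2$group)
    m <- fit_oplsda(panel, g2, n_orthogonal = n_orthogonal,
                    scaling = scaling, cv = TRUE)
    tibble::tibble(perm = i, q2 = m$q2)
  })
}

# ---- ROC -------------------------------------------------------------------

#' ROC biomarker analysis with Youden cutpoint
#'
#' Empirical ROC curve for a single marker: AUC (ties counted one half,
#' equal to the normalised Mann-Whitney U), DeLong 95% confidence interval,
#' and the optimal cutpoint maximising Youden's J (sensitivity +
#' specificity - 1), reported as the midpoint between adjacent observed
#' values; among equal-J candidates the smallest cutpoint is reported. With
#' `direction = "auto"` the marker is oriented so AUC >= 0.5 and the
#' orientation recorded.
#'
#' @param values Numeric marker values.
#' @param labels Class labels; "AF"/1 = case, "control"/0 = control.
#' @param direction "auto" (default), "up" (cases higher) or "down".
#' @return Object of class `ba_roc`: `auc`, `ci` (length-2), `cutpoint`,
#'   `sens_at_cut`, `spec_at_cut`, `direction`, `curve` (tibble of
#'   thresholds with sensitivity/specificity), `n_case`, `n_control`.
#' @export
#' @examples
#' r <- roc_analysis(c(3, 4, 1, 2), c("AF", "AF", "control", "control"))
#' r$auc; r$cutpoint
roc_analysis <- function(values, labels, direction = c("auto", "up", "down")) {
  direction <- match.arg(direction)
  lab <- if (is.numeric(labels)) labels else as.numeric(labels == "AF")
  ok <- !is.na(values) & !is.na(lab)
  values <- values[ok]; lab <- lab[ok]
  if (sum(lab == 1) == 0 || sum(lab == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  # orient so that AUC >= 0.5 when direction = "auto"
  auc_up <- auc_mann_whitney(values[lab == 1], values[lab == 0])
  dir_use <- switch(direction,
                    up = "up", down = "down",
                    auto = if (auc_up >= 0.5) "up" else "down")
  proc_dir <- if (dir_use == "up") "<" else ">"
  r <- pROC::roc(response = lab, predictor = values, direction = proc_dir,
                 levels = c(0, 1), quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  curve <- tibble::tibble(
    threshold = as.numeric(r$thresholds),
    sensitivity = as.numeric(r$sensitivities),
    specificity = as.numeric(r$specificities)
  )
  j <- curve$sensitivity + curve$specificity - 1
  best <- curve[j >= max(j) - 1e-12, , drop = FALSE]
  best <- best[which.min(best$threshold), ]
  structure(list(
    auc = auc, ci = ci,
    cutpoint = best$threshold,
    sens_at_cut = best$sensitivity, spec_at_cut = best$specificity,
    direction = dir_use, curve = curve,
    n_case = sum(lab == 1), n_control = sum(lab == 0)
  ), class = "ba_roc")
}

# AUC as the normalised Mann-Whitney U with ties counted one half.
auc_mann_whitney <- function(cases, controls) {
  rk <- rank(c(cases, controls))
  n1 <- length(cases); n0 <- length(controls)
  (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.ba_roc <- function(x, ...) {
  cat(sprintf("<ba_roc> AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci[1], x$ci[2], x$n_case, x$n_control))
  cat(sprintf("  Youden cutpoint %.4g (%s marker): sens %.3f, spec %.3f\n",
              x$cutpoint, ifelse(x$direction == "up", "higher-in-cases",
                                 "lower-in-cases"),
              x$sens_at_cut, x$spec_at_cut))
  invisible(x)
}

#' ROC summary for every panel analyte
#'
#' Runs [roc_analysis()] per bile acid and returns one summary row each.
#'
#' @inheritParams summarize_composition
#' @param markers Subset of analytes (default: all panel columns).
#' @return Tibble: `ba`, `auc`, `ci_low`, `ci_high`, `cutpoint`,
#'   `sens_at_cut`, `spec_at_cut`, `direction`.
#' @export
roc_table <- function(panel, groups, markers = NULL) {
  bas <- markers %||% setdiff(names(panel), "sample_id")
  grp <- groups$group[match(panel$sample_id, groups$sample_id)]
  purrr::map_dfr(bas, function(ba) {
    r <- roc_analysis(panel[[ba]], grp)
    tibble::tibble(ba = ba, auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2],
                   cutpoint = r$cutpoint, sens_at_cut = r$sens_at_cut,
                   spec_at_cut = r$spec_at_cut, direction = r$direction)
  })
}
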