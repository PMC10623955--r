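six_groups <- function() {
  tibble::tibble(sample_id = paste0("s", 1:6),
                 group = rep(c("AF", "control"), each = 3))
}

test_that("composition summary computes totals and secondary proportions", {
  panel <- tibble::tibble(sample_id = paste0("s", 1:6),
                          CA = c(50, 10, 0, 20, 30, 40),
                          DCA = c(50, 30, 10, 20, 10, 5))
  out <- summarize_composition(panel, six_groups())
  expect_equal(out$per_sample$secondary_prop[1], 0.5)   # CA 50 / DCA 50
  expect_equal(out$per_sample$secondary_prop[3], 1.0)   # all-secondary
  expect_equal(out$per_sample$total[2], 40)
  bad <- panel; bad$ba_extra <- 1
  expect_error(summarize_composition(bad, six_groups()), "does not cover")
})

test_that("zero-total samples are flagged and excluded from the group test", {
  panel <- tibble::tibble(sample_id = paste0("s", 1:6),
                          CA = c(0, 1, 2, 3, 4, 5),
                          DCA = c(0, 1, 1, 1, 2, 2))
  out <- summarize_composition(panel, six_groups())
  expect_true(out$per_sample$excluded[1])
  expect_true(is.na(out$per_sample$secondary_prop[1]))
  expect_equal(out$test$n_excluded, 1)
  expect_false(is.na(out$test$p_value))
})

test_that("planted secondary depletion in AF is detected with high power", {
  sec <- ba_class_map()
  dn <- stats::setNames(rep(-1.5, sum(sec$class == "secondary")),
                        sec$ba[sec$class == "secondary"])
  hits <- vapply(1:60, function(s) {
    sim <- simulate_ba_panel(simulation_config(ba_effect_map = dn, seed = s))
    comp <- summarize_composition(sim$panel, sim$groups)
    comp$test$p_value < 0.05 &&
      comp$test$median_af < comp$test$median_control
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("differential BAs on identical groups are all null", {
  sim <- simulate_ba_panel(simulation_config(seed = 6))
  half <- sim$panel[1:23, ]
  mirrored <- dplyr::bind_rows(
    half, dplyr::mutate(half, sample_id = paste0(sample_id, "_m")))
  grp <- tibble::tibble(sample_id = mirrored$sample_id,
                        group = rep(c("AF", "control"), each = 23))
  res <- differential_bas(mirrored, grp)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$log2_fc == 0))
})

test_that("PCA: correlated pair loads on one component; full rank reconstructs", {
  set.seed(8)
  x <- stats::rlnorm(12)
  panel2 <- tibble::tibble(sample_id = paste0("s", 1:12), A = x, B = 3 * x)
  pc <- pca_scores(panel2)
  expect_equal(pc$explained_variance$proportion[1], 1, tolerance = 1e-9)

  sim <- simulate_ba_panel(tiny_config(seed = 8))
  pc2 <- pca_scores(sim$panel)
  S <- as.matrix(pc2$scores[, grep("^PC", names(pc2$scores))])
  L <- as.matrix(pc2$loadings[, grep("^PC", names(pc2$loadings))])
  X <- bileaxis:::scale_panel_matrix(sim$panel, "log10-uv")$X
  expect_lt(max(abs(S %*% t(L) - X)), 1e-8)
  # trace identity: eigenvalue sum equals total variance of the scaled data
  expect_equal(sum(pc2$explained_variance$variance),
               sum(apply(X, 2, stats::var)), tolerance = 1e-10)
})

test_that("constant variables are dropped with a warning before scaling", {
  panel <- tibble::tibble(sample_id = paste0("s", 1:8),
                          A = stats::rlnorm(8), B = 1)
  expect_warning(pc <- pca_scores(panel), "constant")
  expect_equal(nrow(pc$loadings), 1)
})

test_that("OPLS-DA: informative variable dominates VIP and invariants hold", {
  set.seed(15)
  n <- 20
  grp <- tibble::tibble(sample_id = paste0("s", 1:n),
                        group = rep(c("AF", "control"), each = n / 2))
  y <- as.numeric(grp$group == "AF")
  panel <- tibble::tibble(
    sample_id = grp$sample_id,
    informative = exp(2 * y + stats::rnorm(n, 0, 0.1)),
    noise1 = stats::rlnorm(n), noise2 = stats::rlnorm(n),
    noise3 = stats::rlnorm(n), noise4 = stats::rlnorm(n)
  )
  m <- fit_oplsda(panel, grp)
  expect_equal(names(which.max(m$vip)), "informative")
  expect_gt(m$vip[["informative"]], 1)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-10)
  expect_lt(abs(sum(m$t * m$t_o[, 1])), 1e-8)
  expect_gt(m$q2, 0.5)
  expect_error(fit_oplsda(panel, grp, n_orthogonal = -1), "n_orthogonal")
  expect_error(fit_oplsda(panel, grp, n_orthogonal = 50), "n_orthogonal")
})

test_that("equal-magnitude weights give VIP exactly 1 for every variable", {
  n <- 8
  grp <- tibble::tibble(sample_id = paste0("s", 1:n),
                        group = rep(c("AF", "control"), each = n / 2))
  y <- as.numeric(grp$group == "AF")
  panel <- tibble::tibble(sample_id = grp$sample_id,
                          A = y + c(0.1, -0.1, 0.2, -0.2, 0.1, -0.1, 0.2, -0.2),
                          B = -(y + c(0.1, -0.1, 0.2, -0.2, 0.1, -0.1, 0.2, -0.2)))
  m <- fit_oplsda(panel, grp, n_orthogonal = 0, scaling = "uv", cv = FALSE)
  expect_equal(unname(m$vip), c(1, 1), tolerance = 1e-12)
  expect_equal(nrow(vip_select(m)), 0)  # strict > 1
})

test_that("zero orthogonal components reduce to one-component PLS-DA", {
  sim <- simulate_ba_panel(tiny_config(seed = 23))
  m0 <- fit_oplsda(sim$panel, sim$groups, n_orthogonal = 0, cv = FALSE)
  sc <- bileaxis:::scale_panel_matrix(sim$panel, "log10-uv")
  grp <- sim$groups$group[match(sim$panel$sample_id, sim$groups$sample_id)]
  y <- as.numeric(grp == "AF"); y <- y - mean(y)
  w <- drop(crossprod(sc$X, y)); w <- w / sqrt(sum(w^2))
  expect_lt(max(abs(m0$t - drop(sc$X %*% w))), 1e-8)
})

test_that("planted effects are recovered by the VIP selection", {
  up <- c("UDCA", "bUDCA", "HCA", "7-KetoLCA")
  dn <- c("LCA", "GDCA", "dehydroLCA", "12-ketoLCA")
  eff <- stats::setNames(c(rep(2, 4), rep(-2, 4)), c(up, dn))
  ok <- vapply(1:40, function(s) {
    sim <- simulate_ba_panel(simulation_config(ba_effect_map = eff, seed = s))
    m <- fit_oplsda(sim$panel, sim$groups, cv = FALSE)
    sel <- vip_select(m)$ba
    all(c(up, dn) %in% sel)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("ROC handles perfect separation and matches the pair-counting AUC", {
  r <- roc_analysis(c(3, 4, 1, 2), c("AF", "AF", "control", "control"))
  expect_equal(r$auc, 1)
  expect_equal(r$cutpoint, 2.5)
  expect_equal(r$sens_at_cut, 1)
  expect_equal(r$spec_at_cut, 1)
  r2 <- roc_analysis(c(2, 3, 1, 4), c("AF", "AF", "control", "control"))
  expect_equal(r2$auc, 0.5)  # 2 concordant / 2 discordant pairs
  expect_error(roc_analysis(1:4, rep("AF", 4)), "both classes")
})

test_that("reported cutpoint sensitivity/specificity recompute from the data", {
  set.seed(41)
  for (i in 1:20) {
    v <- round(stats::rnorm(30), 1)  # ties likely
    lab <- rep(c("AF", "control"), c(14, 16))
    r <- roc_analysis(v, lab)
    cases <- v[lab == "AF"]; controls <- v[lab == "control"]
    if (r$direction == "up") {
      expect_equal(r$sens_at_cut, mean(cases > r$cutpoint))
      expect_equal(r$spec_at_cut, mean(controls < r$cutpoint))
    } else {
      expect_equal(r$sens_at_cut, mean(cases < r$cutpoint))
      expect_equal(r$spec_at_cut, mean(controls > r$cutpoint))
    }
  }
})

test_that("AUC is invariant under strictly monotone marker transforms", {
  set.seed(43)
  v <- stats::rlnorm(40)
  lab <- rep(c("AF", "control"), each = 20)
  a0 <- roc_analysis(v, lab)$auc
  expect_equal(roc_analysis(log(v), lab)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_analysis(v^3, lab)$auc, a0, tolerance = 1e-12)
  # auto-orientation keeps AUC at or above one half
  expect_gte(roc_analysis(-v, lab)$auc, 0.5)
})
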