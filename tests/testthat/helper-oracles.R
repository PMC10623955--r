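# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles, without touching the
# package's own code paths.

# hit filter: compare every e-value to factor * min, zeros mapped to 1e-308
brute_filter_idx <- function(evalues, factor = 10) {
  e <- pmax(evalues, 1e-308)
  which(e <= factor * min(e))
}

# longest common rank-prefix of a set of lineages (rows = hits)
brute_lca <- function(lineage_mat) {
  ranks <- ncol(lineage_mat)
  lin <- rep(NA_character_, ranks)
  for (j in seq_len(ranks)) {
    vals <- unique(lineage_mat[, j])
    if (length(vals) == 1 && !is.na(vals)) lin[j] <- vals else break
  }
  lin
}

# exact two-sided Wilcoxon rank-sum p by exhaustive label enumeration:
# p = min(1, 2 * min(P(W <= w_obs), P(W >= w_obs)))
enum_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ws <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# AUC by all-pairs concordance counting, ties worth one half
brute_auc <- function(cases, controls) {
  s <- 0
  for (a in cases) for (b in controls) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(cases) * length(controls))
}

# random lineage generator over a synthetic taxonomy for LCA stress tests
random_lineage_pool <- function(n_genera = 12) {
  i <- seq_len(n_genera)
  fam <- ceiling(i / 3); ord <- ceiling(fam / 2)
  data.frame(
    superkingdom = "Bacteria",
    phylum = sprintf("P%02d", ceiling(ord / 2)),
    class = sprintf("C%02d", ord),
    order = sprintf("O%02d", ord),
    family = sprintf("F%02d", fam),
    genus = sprintf("G%02d", i),
    species = sprintf("G%02d_sp", i),
    stringsAsFactors = FALSE
  )
}

# small fast simulation configs for module tests
tiny_config <- function(seed = 1, ...) {
  simulation_config(n_af = 10, n_control = 10, n_genes = 80, n_genera = 12,
                    seed = seed, ...)
}

no_ba_effects <- function() stats::setNames(numeric(0), character(0))
no_enzyme_effects <- function() stats::setNames(numeric(0), character(0))
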