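test_that("hit filter keeps exactly the hits within 10x of the top e-value", {
  h <- tibble::tibble(gene_id = "g1",
                      enzyme = c("BaiH", "BaiB", "BSH"),
                      evalue = c(1e-20, 5e-20, 2e-19))
  kept <- filter_significant_hits(h)
  expect_setequal(kept$evalue, c(1e-20, 5e-20))
  # single hit is retained; empty input returns empty output
  one <- tibble::tibble(gene_id = "g", enzyme = "BSH", evalue = 1e-5)
  expect_equal(nrow(filter_significant_hits(one)), 1)
  expect_equal(nrow(filter_significant_hits(one[0, ])), 0)
  # boundary is inclusive
  hb <- tibble::tibble(gene_id = "g", enzyme = c("A", "B"),
                       evalue = c(1e-20, 1e-19))
  expect_equal(nrow(filter_significant_hits(hb)), 2)
  expect_error(filter_significant_hits(h, factor = 0), "positive")
})

test_that("filtering is idempotent and zero e-values stay meaningful", {
  set.seed(5)
  h <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:40), each = 5),
    enzyme = sample(ba_enzymes(), 200, replace = TRUE),
    evalue = 10^stats::runif(200, -180, -5)
  )
  h$evalue[sample(200, 8)] <- 0
  once <- filter_significant_hits(h)
  twice <- filter_significant_hits(once)
  expect_identical(once, twice)
  # a zero e-value gene still retains its top hit
  expect_true(all(unique(h$gene_id) %in% once$gene_id))
})

test_that("enzyme assignment follows best-hit with bitscore and name tie-breaks", {
  h <- tibble::tibble(gene_id = "g1", enzyme = c("BaiH", "BaiCD"),
                      evalue = c(1e-50, 1e-10), bitscore = c(100, 900))
  expect_equal(assign_enzyme(h)$enzyme, "BaiH")
  tie <- tibble::tibble(gene_id = "g1", enzyme = c("BaiB", "BaiF"),
                        evalue = c(1e-30, 1e-30), bitscore = c(150, 200))
  expect_equal(assign_enzyme(tie)$enzyme, "BaiF")
  lex <- tibble::tibble(gene_id = "g1", enzyme = c("BaiF", "BaiB"),
                        evalue = 1e-30, bitscore = 200)
  expect_equal(assign_enzyme(lex)$enzyme, "BaiB")
  expect_equal(nrow(assign_enzyme(h[0, ])), 0)
})

test_that("enzyme profile sums assigned gene abundances, zero rows included", {
  ab <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       s1 = c(0.01, 0.02, 0.5), s2 = c(0.1, 0.2, 0.3))
  asg <- tibble::tibble(gene_id = c("g1", "g2"),
                        enzyme = c("7a-HSDH", "7a-HSDH"))
  prof <- compute_enzyme_profile(asg, ab)
  expect_equal(prof$s1[prof$enzyme == "7a-HSDH"], 0.03)
  expect_equal(prof$s1[prof$enzyme == "BaiI"], 0)
  expect_equal(nrow(prof), 13)
  bad <- tibble::tibble(gene_id = "missing_gene", enzyme = "BSH")
  expect_error(compute_enzyme_profile(bad, ab), "missing_gene")
})

test_that("random assignments match brute-force per-enzyme summation and conserve mass", {
  set.seed(11)
  sim <- simulate_metagenome(tiny_config(seed = 11))
  asg <- assign_enzyme(filter_significant_hits(sim$hits))
  prof <- compute_enzyme_profile(asg, sim$abundance)
  samples <- setdiff(names(sim$abundance), "gene_id")
  for (e in unique(asg$enzyme)) {
    genes <- asg$gene_id[asg$enzyme == e]
    manual <- colSums(sim$abundance[sim$abundance$gene_id %in% genes, samples])
    expect_equal(as.numeric(prof[prof$enzyme == e, samples]),
                 unname(manual), tolerance = 1e-12)
  }
  expect_true(all(colSums(prof[, samples]) <= 1 + 1e-9))
})

test_that("taxonomic LCA backs off one rank when retained genera disagree", {
  pool <- random_lineage_pool()
  # two genera in the same family, both within threshold
  th <- dplyr::bind_cols(
    tibble::tibble(gene_id = "g1", evalue = c(1e-40, 5e-40)),
    dplyr::bind_rows(pool[1, ], pool[2, ])
  )
  out <- lca_assign(th)
  expect_equal(out$rank, "family")
  expect_equal(out$family, pool$family[1])
  expect_true(is.na(out$genus))
  # a single retained genus resolves to species depth
  th2 <- dplyr::bind_cols(tibble::tibble(gene_id = "g2", evalue = 1e-40),
                          pool[3, ])
  expect_equal(lca_assign(th2)$rank, "species")
  # disagreement at superkingdom gives root
  far <- pool[4, ]; far$superkingdom <- "Archaea"
  th3 <- dplyr::bind_cols(tibble::tibble(gene_id = "g3", evalue = c(1e-40, 2e-40)),
                          dplyr::bind_rows(pool[4, ], far))
  expect_equal(lca_assign(th3)$rank, "root")
})

test_that("malformed lineages (gap in the rank ladder) are rejected", {
  pool <- random_lineage_pool()
  bad <- pool[1, ]
  bad$family <- NA_character_  # genus present below a missing family
  th <- dplyr::bind_cols(tibble::tibble(gene_id = "gX", evalue = 1e-30), bad)
  expect_error(lca_assign(th), "malformed lineage")
})

test_that("adding a hit never deepens the LCA assignment", {
  pool <- random_lineage_pool()
  rank_depth <- function(r) match(r, c("root", tax_ranks()))
  set.seed(21)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    rows <- pool[sample(nrow(pool), k, replace = TRUE), , drop = FALSE]
    th <- dplyr::bind_cols(
      tibble::tibble(gene_id = "g", evalue = 10^stats::runif(k, -50, -49)),
      rows)
    extra_row <- pool[sample(nrow(pool), 1), , drop = FALSE]
    th2 <- dplyr::bind_rows(
      th, dplyr::bind_cols(tibble::tibble(gene_id = "g", evalue = 1e-49),
                           extra_row))
    d1 <- rank_depth(lca_assign(th)$rank)
    d2 <- rank_depth(lca_assign(th2)$rank)
    expect_lte(d2, d1)
  }
})

test_that("Wilcoxon p for {1,2,3} vs {4,5,6} equals the exhaustive 0.1", {
  prof <- tibble::tibble(feature = "f", s1 = 1, s2 = 2, s3 = 3,
                         s4 = 4, s5 = 5, s6 = 6)
  grp <- tibble::tibble(sample_id = paste0("s", 1:6),
                        group = rep(c("AF", "control"), each = 3))
  res <- differential_features(prof, grp)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, enum_wilcox_p(1:3, 4:6))
  expect_equal(res$direction, "down-in-AF")
})

test_that("identical groups give p = 1 and zero fold change", {
  prof <- tibble::tibble(feature = "f", s1 = 2, s2 = 5, s3 = 9,
                         s4 = 2, s5 = 5, s6 = 9)
  grp <- tibble::tibble(sample_id = paste0("s", 1:6),
                        group = rep(c("AF", "control"), each = 3))
  res <- differential_features(prof, grp)
  expect_equal(res$p_value, 1)
  expect_equal(res$log2_fc, 0)
  expect_equal(res$direction, "none")
})

test_that("groups with fewer than two samples are rejected", {
  prof <- tibble::tibble(feature = "f", s1 = 1, s2 = 2, s3 = 3)
  grp <- tibble::tibble(sample_id = paste0("s", 1:3),
                        group = c("AF", "control", "control"))
  expect_error(differential_features(prof, grp), "at least 2")
})

test_that("BH adjustment column appears only on request", {
  sim <- simulate_ba_panel(tiny_config(seed = 2))
  d0 <- differential_bas(sim$panel, sim$groups)
  d1 <- differential_bas(sim$panel, sim$groups, adjust = TRUE)
  expect_false("q_value" %in% names(d0))
  expect_true("q_value" %in% names(d1))
  expect_equal(d1$q_value, stats::p.adjust(d1$p_value, method = "BH"))
})
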