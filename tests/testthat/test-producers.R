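make_small_matrix <- function() {
  # Blautia: 2x BaiH + 4 more bai genes (5 distinct) + both HSDHs
  # Prevotella: only 7a-HSDH; Dialister: BSH only
  asg <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    enzyme = c("BaiH", "BaiH", "BaiB", "BaiF", "BaiA", "BaiCD",
               "7a-HSDH", "7b-HSDH", "7a-HSDH", "BSH")
  )
  pool <- genus_lineages_fixture()
  genus <- c(rep("Blautia", 8), "Prevotella", "Dialister")
  lca <- dplyr::bind_cols(
    tibble::tibble(gene_id = asg$gene_id, rank = "genus"),
    pool[match(genus, pool$genus), ]
  )
  lca$species <- NA_character_
  ab <- tibble::tibble(gene_id = asg$gene_id,
                       s1 = seq(0.01, 0.1, length.out = 10),
                       s2 = rep(0.02, 10))
  list(asg = asg, lca = lca, ab = ab)
}

genus_lineages_fixture <- function() {
  tibble::tibble(
    superkingdom = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = "Clostridiales", family = c("Lachnospiraceae", "Prevotellaceae",
                                        "Veillonellaceae"),
    genus = c("Blautia", "Prevotella", "Dialister"),
    species = NA_character_
  )
}

test_that("genus-enzyme matrix counts genes and sums abundance per genus", {
  fx <- make_small_matrix()
  gem <- build_genus_enzyme_matrix(fx$asg, fx$lca, fx$ab)
  baih <- gem$counts[gem$counts$genus == "Blautia" & gem$counts$enzyme == "BaiH", ]
  expect_equal(baih$n_genes, 2)
  expect_true(baih$present)
  bh_ab <- gem$abundance[gem$abundance$genus == "Blautia" &
                           gem$abundance$enzyme == "BaiH", ]
  expect_equal(bh_ab$s1, 0.01 + 0.02, tolerance = 1e-12)
})

test_that("genes resolved above genus are excluded from the genus matrix", {
  fx <- make_small_matrix()
  fx$lca$rank[1] <- "family"
  fx$lca$genus[1] <- NA_character_
  gem <- build_genus_enzyme_matrix(fx$asg, fx$lca, fx$ab)
  baih <- gem$counts[gem$counts$genus == "Blautia" & gem$counts$enzyme == "BaiH", ]
  expect_equal(baih$n_genes, 1)
})

test_that("producer classification applies the pathway, HSDH-pair and bai rules", {
  fx <- make_small_matrix()
  gem <- build_genus_enzyme_matrix(fx$asg, fx$lca, fx$ab)
  rep <- classify_producers(gem)
  expect_true("Blautia" %in% rep$bai_complete_set)        # 5 distinct bai genes
  expect_false("Prevotella" %in% rep$bai_complete_set)
  expect_setequal(rep$pathway_sets[["UDCA-synthesis"]], c("Blautia", "Prevotella"))
  expect_equal(rep$hsdh_pair_set, "Blautia")              # needs both HSDHs
  expect_false("Dialister" %in% unlist(rep$pathway_sets)) # BSH is in no pathway
  bad_map <- ba_pathway_map()
  bad_map$pathways[["UDCA-synthesis"]] <- c("NotAnEnzyme")
  expect_error(classify_producers(gem, bad_map), "unknown enzyme")
})

test_that("Venn regions sum to the union and bai set respects pathway membership", {
  sim <- simulate_metagenome(tiny_config(seed = 13))
  asg <- assign_enzyme(filter_significant_hits(sim$hits))
  lca <- lca_assign(sim$tax_hits)
  gem <- build_genus_enzyme_matrix(asg, lca, sim$abundance)
  rep <- classify_producers(gem)
  union_size <- length(unique(unlist(rep$pathway_sets)))
  expect_equal(sum(rep$venn$n_genera), union_size)
  expect_true(all(rep$bai_complete_set %in%
                    union(rep$pathway_sets[["LCA-synthesis"]],
                          rep$pathway_sets[["DCA-synthesis"]])))
})

test_that("simulated matrix equals a brute-force group-by on the planted truth", {
  sim <- simulate_metagenome(tiny_config(seed = 29))
  asg <- assign_enzyme(filter_significant_hits(sim$hits))
  lca <- lca_assign(sim$tax_hits)
  gem <- build_genus_enzyme_matrix(asg, lca, sim$abundance)
  truth <- merge(sim$truth$gene_enzyme, sim$truth$gene_genus, by = "gene_id")
  manual <- as.data.frame(table(truth$genus, truth$enzyme))
  manual <- manual[manual$Freq > 0, ]
  got <- gem$counts[order(gem$counts$genus, gem$counts$enzyme), ]
  manual <- manual[order(manual$Var1, manual$Var2), ]
  expect_equal(nrow(got), nrow(manual))
  expect_equal(got$n_genes, manual$Freq)
})

test_that("correlation network recovers perfect monotone relationships", {
  ga <- tibble::tibble(genus = "Blautia",
                       !!!stats::setNames(as.list(as.numeric(1:10)),
                                          paste0("s", 1:10)))
  ep_up <- tibble::tibble(enzyme = "BaiH",
                          !!!stats::setNames(as.list(c(2, 3, 5, 8, 9, 11, 14, 18, 20, 30)),
                                             paste0("s", 1:10)))
  edges <- correlation_network(ga, ep_up)
  expect_equal(edges$rho, 1)
  expect_equal(edges$sign, "+")
  ep_dn <- ep_up
  ep_dn[1, -1] <- as.list(rev(as.numeric(ep_up[1, -1])))
  edges2 <- correlation_network(ga, ep_dn)
  expect_equal(edges2$rho, -1)
  expect_equal(edges2$sign, "-")
})

test_that("Spearman edges are invariant under strictly monotone transforms", {
  set.seed(31)
  samples <- paste0("s", 1:12)
  ga <- tibble::tibble(genus = "g",
                       !!!stats::setNames(as.list(stats::runif(12)), samples))
  ep <- tibble::tibble(enzyme = "e",
                       !!!stats::setNames(as.list(stats::runif(12)), samples))
  e1 <- correlation_network(ga, ep, p_threshold = 1.1)
  ga2 <- ga; ga2[1, samples] <- as.list(exp(as.numeric(ga[1, samples]) * 3))
  ep2 <- ep; ep2[1, samples] <- as.list(log(as.numeric(ep[1, samples]) + 1))
  e2 <- correlation_network(ga2, ep2, p_threshold = 1.1)
  expect_equal(e1$rho, e2$rho, tolerance = 1e-12)
  expect_equal(e1$p_value, e2$p_value, tolerance = 1e-12)
})

test_that("independent pairs pass the 0.05 threshold at roughly the nominal rate", {
  set.seed(77)
  n_pairs <- 600
  hits <- vapply(seq_len(n_pairs), function(i) {
    g <- tibble::tibble(genus = "g",
                        !!!stats::setNames(as.list(stats::rnorm(20)), paste0("s", 1:20)))
    e <- tibble::tibble(enzyme = "e",
                        !!!stats::setNames(as.list(stats::rnorm(20)), paste0("s", 1:20)))
    nrow(correlation_network(g, e)) == 1
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("zero-variance vectors are skipped with a warning", {
  samples <- paste0("s", 1:8)
  ga <- tibble::tibble(genus = "g",
                       !!!stats::setNames(as.list(rep(1, 8)), samples))
  ep <- tibble::tibble(enzyme = "e",
                       !!!stats::setNames(as.list(as.numeric(1:8)), samples))
  expect_warning(out <- correlation_network(ga, ep), "zero variance")
  expect_equal(nrow(out), 0)
})
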