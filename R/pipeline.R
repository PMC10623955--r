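#' Run the full bile-acid axis pipeline
#'
#' Orchestrates simulate -> profile -> producers -> metabolome -> clinical
#' over a simulated cohort (or files on disk), writes every stage output
#' under `outdir` as TSV/CSV/JSON/GraphML, and returns a consolidated
#' report. Any stage failure aborts with a stage-named error; outputs
#' written before the failure are preserved. With a fixed configuration and
#' seed, two runs produce byte-identical files (no timestamps are written).
#'
#' @param config A [simulation_config()]; its `seed` drives every stream.
#' @param outdir Output directory (created if needed).
#' @param inputs Optional named list of file paths to run from existing
#'   data instead of simulating: `abundance`, `hits`, `ref_map`,
#'   `tax_hits`, `groups_mg`, `panel`, `groups_ba`, `clinical`. All eight
#'   are required when supplied.
#' @param hit_factor E-value filter multiple (default 10).
#' @param vip_threshold VIP selection cut (default 1).
#' @param network_p Correlation-network p threshold (default 0.05).
#' @param screen_alpha Univariate screening threshold (default 0.100).
#' @param forced Variables forced into the multivariable model (default "DM").
#' @param pathway_map Producer pathway map (default [ba_pathway_map()]).
#' @param class_map Bile-acid class map (default [ba_class_map()]).
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config = simulation_config(), outdir,
                         inputs = NULL,
                         hit_factor = 10, vip_threshold = 1,
                         network_p = 0.05, screen_alpha = 0.100,
                         forced = "DM",
                         pathway_map = ba_pathway_map(),
                         class_map = ba_class_map()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(inputs)) {
    mg <- stage("simulate", simulate_metagenome(config))
    ba <- stage("simulate", simulate_ba_panel(config))
    cl <- stage("simulate", simulate_clinical(config))
    stage("simulate", {
      write_gene_abundance(mg$abundance, file.path(outdir, "gene_abundance.tsv"))
      write_enzyme_hits(mg$hits, file.path(outdir, "enzyme_hits.tsv"),
                        file.path(outdir, "enzyme_ref_map.tsv"))
      write_taxon_hits(mg$tax_hits, file.path(outdir, "taxon_hits.tsv"))
      write_groups(mg$groups, file.path(outdir, "groups_metagenome.tsv"))
      write_ba_panel(ba$panel, file.path(outdir, "ba_panel.csv"))
      write_groups(ba$groups, file.path(outdir, "groups_panel.tsv"))
      write_clinical(cl$clinical, file.path(outdir, "clinical.csv"))
      write_truth(list(metagenome = mg$truth[c("gene_enzyme", "gene_genus",
                                               "affected_enzymes")],
                       ba_panel = ba$truth["affected_bas"],
                       clinical = cl$truth),
                  file.path(outdir, "truth.json"))
    })
    abundance <- mg$abundance; hits <- mg$hits; tax_hits <- mg$tax_hits
    groups_mg <- mg$groups
    panel <- ba$panel; groups_ba <- ba$groups
    clinical <- cl$clinical
  } else {
    need <- c("abundance", "hits", "ref_map", "tax_hits", "groups_mg",
              "panel", "groups_ba", "clinical")
    stage("load", {
      missing_keys <- setdiff(need, names(inputs))
      if (length(missing_keys) > 0) {
        stop("missing input path(s): ", paste(missing_keys, collapse = ", "))
      }
      gone <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
      if (length(gone) > 0) {
        stop("input file(s) not found: ", paste(gone, collapse = ", "))
      }
    })
    abundance <- stage("load", read_gene_abundance(inputs$abundance))
    hits <- stage("load", read_enzyme_hits(inputs$hits, inputs$ref_map))
    tax_hits <- stage("load", read_taxon_hits(inputs$tax_hits))
    groups_mg <- stage("load", read_groups(inputs$groups_mg))
    panel <- stage("load", read_ba_panel(inputs$panel))
    groups_ba <- stage("load", read_groups(inputs$groups_ba))
    clinical <- stage("load", read_clinical(inputs$clinical))
  }

  # --- functional profiling -------------------------------------------------
  prof <- stage("profile", {
    filtered <- filter_significant_hits(hits, factor = hit_factor)
    assignments <- assign_enzyme(filtered)
    profile <- compute_enzyme_profile(assignments, abundance)
    diff_enzymes <- differential_features(profile, groups_mg)
    readr::write_tsv(profile, file.path(outdir, "enzyme_profile.tsv"))
    readr::write_tsv(diff_enzymes, file.path(outdir, "differential_enzymes.tsv"))
    list(assignments = assignments, profile = profile,
         diff_enzymes = diff_enzymes)
  })

  # --- producer analysis ----------------------------------------------------
  prod <- stage("producers", {
    lca <- lca_assign(tax_hits, factor = hit_factor)
    gem <- build_genus_enzyme_matrix(prof$assignments, lca, abundance)
    report <- classify_producers(gem, pathway_map)
    gabund <- genus_abundance(gem)
    diff_genera <- differential_features(gabund, groups_mg)
    edges <- suppressWarnings(
      correlation_network(gabund, prof$profile, p_threshold = network_p)
    )
    readr::write_tsv(lca, file.path(outdir, "lca_assignments.tsv"), na = "")
    readr::write_tsv(gem$counts, file.path(outdir, "genus_enzyme_counts.tsv"))
    readr::write_tsv(diff_genera, file.path(outdir, "differential_genera.tsv"))
    readr::write_tsv(edges, file.path(outdir, "network_edges.tsv"))
    if (nrow(edges) > 0) {
      write_network_graphml(edges, file.path(outdir, "network.graphml"))
    }
    jsonlite::write_json(
      list(set_sizes = as.list(report$set_sizes),
           hsdh_pair_set = report$hsdh_pair_set,
           bai_complete_set = report$bai_complete_set,
           venn = report$venn),
      file.path(outdir, "producer_report.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE
    )
    list(report = report, diff_genera = diff_genera, edges = edges)
  })

  # --- bile-acid metabolomics -----------------------------------------------
  met <- stage("metabolome", {
    comp <- summarize_composition(panel, groups_ba, class_map)
    diff_ba <- differential_bas(panel, groups_ba)
    pca <- pca_scores(panel, groups_ba)
    opls <- fit_oplsda(panel, groups_ba)
    vip <- vip_select(opls, threshold = vip_threshold, p_table = diff_ba)
    sig_ba <- diff_ba$ba[diff_ba$p_value < 0.05]
    rocs <- roc_table(panel, groups_ba,
                      markers = if (length(sig_ba) > 0) sig_ba else NULL)
    readr::write_tsv(comp$per_sample, file.path(outdir, "ba_composition.tsv"))
    readr::write_tsv(diff_ba, file.path(outdir, "differential_bas.tsv"))
    readr::write_tsv(pca$scores, file.path(outdir, "pca_scores.tsv"))
    readr::write_tsv(tidy.ba_oplsda(opls), file.path(outdir, "oplsda_vip.tsv"))
    readr::write_tsv(vip, file.path(outdir, "vip_selected.tsv"))
    readr::write_tsv(rocs, file.path(outdir, "roc_summary.tsv"))
    list(comp = comp, diff_ba = diff_ba, pca = pca, opls = opls,
         vip = vip, rocs = rocs)
  })

  # --- clinical association -------------------------------------------------
  clin <- stage("clinical", {
    base <- baseline_table(clinical)
    corr <- pearson_correlation(clinical$FGF19, clinical$LAD)
    screen <- univariate_screen(clinical, alpha = screen_alpha,
                                forced = forced,
                                variables = setdiff(names(clinical),
                                                    c("subject_id", "group")))
    cand <- screen$variable[screen$candidate]
    multi <- fit_logistic(clinical, cand)
    readr::write_tsv(base, file.path(outdir, "baseline_table.tsv"))
    readr::write_tsv(screen, file.path(outdir, "univariate_screen.tsv"))
    readr::write_tsv(tidy.af_logistic(multi),
                     file.path(outdir, "multivariable_model.tsv"))
    list(base = base, corr = corr, screen = screen, multi = multi)
  })

  report <- list(
    seed = config$seed,
    thresholds = list(hit_factor = hit_factor, vip_threshold = vip_threshold,
                      network_p = network_p, screen_alpha = screen_alpha,
                      bai_min_count = pathway_map$bai_min_count),
    profiling = list(
      n_genes_assigned = nrow(prof$assignments),
      n_differential_enzymes = sum(prof$diff_enzymes$p_value < 0.05),
      differential_enzymes = prof$diff_enzymes$enzyme[
        prof$diff_enzymes$p_value < 0.05]
    ),
    producers = list(
      set_sizes = as.list(prod$report$set_sizes),
      n_hsdh_pair = length(prod$report$hsdh_pair_set),
      n_bai_complete = length(prod$report$bai_complete_set),
      n_differential_genera = sum(prod$diff_genera$p_value < 0.05),
      n_network_edges = nrow(prod$edges)
    ),
    metabolome = list(
      secondary_prop_p = met$comp$test$p_value,
      n_differential_bas = sum(met$diff_ba$p_value < 0.05),
      n_up_in_af = sum(met$diff_ba$p_value < 0.05 &
                         met$diff_ba$direction == "up-in-AF"),
      n_down_in_af = sum(met$diff_ba$p_value < 0.05 &
                           met$diff_ba$direction == "down-in-AF"),
      vip_selected = met$vip$ba,
      oplsda = list(r2x = met$opls$r2x, r2y = met$opls$r2y, q2 = met$opls$q2),
      best_marker = if (nrow(met$rocs) > 0) {
        as.list(met$rocs[which.max(met$rocs$auc),
                         c("ba", "auc", "ci_low", "ci_high", "cutpoint",
                           "sens_at_cut", "spec_at_cut")])
      } else NULL
    ),
    clinical = list(
      fgf19_p = clin$base$p_value[clin$base$variable == "FGF19"],
      fgf19_lad_r = clin$corr$r, fgf19_lad_p = clin$corr$p_value,
      candidates = clin$screen$variable[clin$screen$candidate],
      multivariable = tidy.af_logistic(clin$multi)
    ),
    versions = list(
      bileaxis = as.character(utils::packageVersion("bileaxis")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  stage("report", jsonlite::write_json(
    report, file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null"
  ))
  invisible(report)
}
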