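#' Build a synthetic-cohort simulation configuration
#'
#' Defines the generating model for all pipeline inputs: a log-normal gene
#' catalogue with planted enzyme effects and taxon origins, a 24-bile-acid
#' faecal panel with planted group effects, and a clinical table with a
#' group-shifted FGF19 and a correlated left atrial diameter. Defaults mirror
#' the case-control design the pipeline targets: 50/50 metagenomics samples,
#' 23/23 metabolomics samples, 36/24 clinical subjects; seven biotransformation
#' enzymes depleted four-fold in cases; twelve bile acids enriched and four
#' depleted in cases; FGF19 lower in cases and negatively correlated with LAD.
#'
#' @param n_af,n_control Metagenomics cohort sizes (cases / controls).
#' @param n_genes Number of catalogue genes to simulate.
#' @param n_genera Size of the genus pool genes are planted in.
#' @param gene_sdlog Within-gene log-normal standard deviation (log scale).
#' @param enzyme_gene_frac Fraction of genes carrying a bile-acid enzyme.
#' @param enzyme_effect_map Named numeric vector: enzyme name -> log2 group
#'   effect applied multiplicatively to case samples. Names must belong to
#'   [ba_enzymes()].
#' @param ba_effect_map Named numeric vector: bile-acid name -> log2 group
#'   effect on the faecal panel. Names must belong to `panel`.
#' @param ba_cv Coefficient of variation of panel concentrations (> 0).
#' @param panel Bile-acid panel (character); defaults to [ba_panel()].
#' @param ba_log_mean Named log-scale mean concentration (nmol/g) per bile
#'   acid; defaults to log(50) for every analyte.
#' @param fgf19_effect Log-scale case shift of plasma FGF19 (negative =
#'   lower in cases).
#' @param fgf19_log_mean,fgf19_sdlog Log-scale location and spread of FGF19
#'   (pg/mL) in controls.
#' @param fgf19_lad_rho Target raw-scale Pearson correlation between FGF19
#'   and LAD across the whole cohort, in (-1, 1).
#' @param lad_mean,lad_af_shift,lad_sd LAD (mm) generating parameters.
#' @param lvef_mean,lvef_af_shift,lvef_sd LVEF (%) generating parameters.
#' @param dm_prob_af,dm_prob_control Diabetes prevalence per group.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,sex_prob Demographic parameters.
#' @param decoy_max Maximum number of off-target taxonomy decoys per gene,
#'   planted beyond the 10x e-value rule so the hit filter excludes them.
#' @param decoy_within Number of within-threshold confounder lineages per
#'   gene (0 by default; used to stress the lowest-common-ancestor backoff).
#' @param n_af_panel,n_control_panel Metabolomics cohort sizes.
#' @param n_af_clinical,n_control_clinical Clinical cohort sizes.
#' @param seed Master seed; per-table child streams are derived from it.
#'
#' @return A validated `simulation_config` object (a list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7)
#' names(cfg$enzyme_effect_map)
simulation_config <- function(n_af = 50, n_control = 50,
                              n_genes = 400, n_genera = 40,
                              gene_sdlog = 1, enzyme_gene_frac = 0.3,
                              enzyme_effect_map = default_enzyme_effects(),
                              ba_effect_map = default_ba_effects(),
                              ba_cv = 1,
                              panel = ba_panel(),
                              ba_log_mean = NULL,
                              fgf19_effect = -0.51,
                              fgf19_log_mean = log(232.779), fgf19_sdlog = 0.87,
                              fgf19_lad_rho = -0.277,
                              lad_mean = 36, lad_af_shift = 5, lad_sd = 5,
                              lvef_mean = 62, lvef_af_shift = -4, lvef_sd = 5,
                              dm_prob_af = 0.2, dm_prob_control = 0.2,
                              age_mean = 60, age_sd = 11,
                              bmi_mean = 26, bmi_sd = 3.4, sex_prob = 0.5,
                              decoy_max = 3, decoy_within = 0,
                              n_af_panel = 23, n_control_panel = 23,
                              n_af_clinical = 36, n_control_clinical = 24,
                              seed = 1) {
  if (is.null(ba_log_mean)) {
    ba_log_mean <- stats::setNames(rep(log(50), length(panel)), panel)
  }
  cfg <- structure(
    list(
      n_af = n_af, n_control = n_control,
      n_genes = n_genes, n_genera = n_genera,
      gene_sdlog = gene_sdlog, enzyme_gene_frac = enzyme_gene_frac,
      enzyme_effect_map = enzyme_effect_map,
      ba_effect_map = ba_effect_map,
      ba_cv = ba_cv, panel = panel, ba_log_mean = ba_log_mean,
      fgf19_effect = fgf19_effect,
      fgf19_log_mean = fgf19_log_mean, fgf19_sdlog = fgf19_sdlog,
      fgf19_lad_rho = fgf19_lad_rho,
      lad_mean = lad_mean, lad_af_shift = lad_af_shift, lad_sd = lad_sd,
      lvef_mean = lvef_mean, lvef_af_shift = lvef_af_shift, lvef_sd = lvef_sd,
      dm_prob_af = dm_prob_af, dm_prob_control = dm_prob_control,
      age_mean = age_mean, age_sd = age_sd,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd, sex_prob = sex_prob,
      decoy_max = decoy_max, decoy_within = decoy_within,
      n_af_panel = n_af_panel, n_control_panel = n_control_panel,
      n_af_clinical = n_af_clinical, n_control_clinical = n_control_clinical,
      seed = seed
    ),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
}

#' Default planted enzyme effects
#'
#' Four-fold depletion (log2 effect -2) in cases of the seven enzymes the
#' differential stage is expected to flag: both 7-HSDHs and five bai genes.
#' @return Named numeric vector of log2 effects.
#' @export
default_enzyme_effects <- function() {
  stats::setNames(rep(-2, 7),
                  c("7a-HSDH", "7b-HSDH", "BaiA", "BaiA2", "BaiH", "BaiCD", "BaiN"))
}

#' Default planted bile-acid effects
#'
#' Twelve analytes enriched (log2 effect +2) and four depleted (log2 effect
#' -2) in cases, following the canonical AF faecal-panel direction map.
#' @return Named numeric vector of log2 effects.
#' @export
default_ba_effects <- function() {
  up <- c("UDCA", "bUDCA", "HCA", "7-KetoLCA", "3-DHCA", "6-KetoLCA",
          "CDCA", "TCA", "CA", "GUDCA", "TCDCA", "TUDCA")
  down <- c("dehydroLCA", "12-ketoLCA", "LCA", "GDCA")
  stats::setNames(c(rep(2, length(up)), rep(-2, length(down))), c(up, down))
}

validate_simulation_config <- function(cfg) {
  counts <- c(cfg$n_af, cfg$n_control, cfg$n_genes, cfg$n_genera,
              cfg$n_af_panel, cfg$n_control_panel,
              cfg$n_af_clinical, cfg$n_control_clinical)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all cohort/catalogue counts must be positive integers", call. = FALSE)
  }
  if (!is.numeric(cfg$ba_cv) || cfg$ba_cv <= 0) {
    stop("ba_cv must be a positive coefficient of variation", call. = FALSE)
  }
  if (abs(cfg$fgf19_lad_rho) >= 1) {
    stop("fgf19_lad_rho must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (cfg$gene_sdlog <= 0) stop("gene_sdlog must be > 0", call. = FALSE)
  unknown_enz <- setdiff(names(cfg$enzyme_effect_map), ba_enzymes())
  if (length(unknown_enz) > 0) {
    stop("enzyme effect(s) for unknown enzyme name(s): ",
         paste(unknown_enz, collapse = ", "), call. = FALSE)
  }
  unknown_ba <- setdiff(names(cfg$ba_effect_map), cfg$panel)
  if (length(unknown_ba) > 0) {
    stop("bile-acid effect(s) outside the configured panel: ",
         paste(unknown_ba, collapse = ", "), call. = FALSE)
  }
  missing_mu <- setdiff(cfg$panel, names(cfg$ba_log_mean))
  if (length(missing_mu) > 0) {
    stop("ba_log_mean missing for: ", paste(missing_mu, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  metagenome: %d AF / %d control, %d genes, %d genera\n",
              x$n_af, x$n_control, x$n_genes, x$n_genera))
  cat(sprintf("  BA panel:   %d AF / %d control, %d analytes, %d planted effects\n",
              x$n_af_panel, x$n_control_panel, length(x$panel),
              length(x$ba_effect_map)))
  cat(sprintf("  clinical:   %d AF / %d control, FGF19 log-shift %.3f, target r %.3f\n",
              x$n_af_clinical, x$n_control_clinical, x$fgf19_effect,
              x$fgf19_lad_rho))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic child stream per table, derived from the master seed.
child_seed <- function(seed, k) {
  as.integer((abs(seed) %% 100000L) * 20011L + k * 104729L) %% 2147483629L
}

genus_pool <- function(n_genera) {
  named <- c("Blautia", "Faecalibacterium", "Roseburia", "Dialister",
             "Butyricicoccus", "Prevotella", "Eubacterium", "Clostridium",
             "Ruminococcus", "Bacteroides")
  if (n_genera <= length(named)) return(named[seq_len(n_genera)])
  c(named, sprintf("Genus_%03d", seq_len(n_genera - length(named))))
}

# Synthetic rank ladder: genera nested 3-per-family, families 3-per-order, ...
genus_lineages <- function(genera) {
  i <- seq_along(genera)
  fam <- ceiling(i / 3); ord <- ceiling(fam / 3)
  cls <- ceiling(ord / 3); phy <- ceiling(cls / 3)
  tibble::tibble(
    superkingdom = "Bacteria",
    phylum = sprintf("Phylum_%02d", phy),
    class = sprintf("Class_%02d", cls),
    order = sprintf("Order_%02d", ord),
    family = sprintf("Family_%02d", fam),
    genus = genera,
    species = paste0(genera, "_sp")
  )
}

sample_names <- function(n_af, n_control, prefix = "S") {
  c(sprintf("%s_AF_%03d", prefix, seq_len(n_af)),
    sprintf("%s_CT_%03d", prefix, seq_len(n_control)))
}

groups_table <- function(n_af, n_control, prefix = "S") {
  tibble::tibble(
    sample_id = sample_names(n_af, n_control, prefix),
    group = rep(c("AF", "control"), c(n_af, n_control))
  )
}

log_uniform <- function(n, lo_exp, hi_exp) 10^stats::runif(n, lo_exp, hi_exp)

#' Simulate a gene-catalogue metagenome with planted enzyme content
#'
#' Draws per-sample gene relative abundances from a log-normal model and
#' renormalises each sample to sum to one (closed composition). A configured
#' fraction of genes carries alignment hits to the 13 bile-acid enzyme
#' references, with the true enzyme always the best hit; each enzyme gene
#' also carries taxonomy hits whose retained set resolves to the planted
#' genus, plus decoy lineages beyond the 10x e-value rule. Planted group
#' effects multiply case-sample abundances of affected enzyme genes before
#' renormalisation.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `abundance` (tibble: `gene_id` + one column
#'   per sample, columns summing to 1), `hits` (tibble: `gene_id`, `enzyme`,
#'   `pident`, `evalue`, `bitscore`), `tax_hits` (tibble: `gene_id`,
#'   `evalue`, the seven rank columns), `groups` (tibble: `sample_id`,
#'   `group`) and `truth` (planted maps and effects).
#' @export
#' @examples
#' sim <- simulate_metagenome(simulation_config(n_genes = 50, seed = 1))
#' colSums(sim$abundance[, -1])[1:3]
simulate_metagenome <- function(config) {
  validate_simulation_config(config)
  set.seed(child_seed(config$seed, 1L))

  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  genera <- genus_pool(config$n_genera)
  lineages <- genus_lineages(genera)
  groups <- groups_table(config$n_af, config$n_control, "MG")
  n_s <- nrow(groups)

  n_enz <- max(1L, round(config$enzyme_gene_frac * config$n_genes))
  enz_gene_idx <- sort(sample.int(config$n_genes, n_enz))
  enzyme_of <- sample(rep(ba_enzymes(), length.out = n_enz))
  genus_of <- sample(genera, n_enz, replace = TRUE)

  gene_enzyme <- tibble::tibble(gene_id = genes[enz_gene_idx], enzyme = enzyme_of)
  gene_genus <- tibble::tibble(gene_id = genes[enz_gene_idx], genus = genus_of)

  # log-normal abundances with gene-specific baselines
  base <- stats::rnorm(config$n_genes, 0, 1)
  mat <- exp(base + matrix(stats::rnorm(config$n_genes * n_s, 0, config$gene_sdlog),
                           config$n_genes, n_s))
  # planted multiplicative effects on case samples
  if (length(config$enzyme_effect_map) > 0) {
    af_cols <- which(groups$group == "AF")
    for (enz in names(config$enzyme_effect_map)) {
      rows <- enz_gene_idx[enzyme_of == enz]
      if (length(rows) > 0) {
        mat[rows, af_cols] <- mat[rows, af_cols] * 2^config$enzyme_effect_map[[enz]]
      }
    }
  }
  mat <- sweep(mat, 2, colSums(mat), "/")
  abundance <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes),
    tibble::as_tibble(stats::setNames(as.data.frame(mat), groups$sample_id))
  )

  # enzyme alignment hits: true enzyme strictly best; off-target decoys fail
  # the 10x rule; occasional same-enzyme secondary hits stay within it
  hits <- purrr::map2_dfr(seq_len(n_enz), enzyme_of, function(i, enz) {
    gid <- genes[enz_gene_idx[i]]
    top_e <- log_uniform(1, -180, -30)
    top <- tibble::tibble(gene_id = gid, enzyme = enz,
                          pident = stats::runif(1, 70, 100),
                          evalue = top_e,
                          bitscore = round(stats::runif(1, 500, 1500)))
    extra <- NULL
    n_off <- sample(0:2, 1)
    if (n_off > 0) {
      extra <- tibble::tibble(
        gene_id = gid,
        enzyme = sample(setdiff(ba_enzymes(), enz), n_off),
        pident = stats::runif(n_off, 30, 70),
        evalue = top_e * 10^stats::runif(n_off, 2, 6),
        bitscore = round(stats::runif(n_off, 50, 300))
      )
    }
    second <- NULL
    if (stats::runif(1) < 0.3) {
      second <- tibble::tibble(gene_id = gid, enzyme = enz,
                               pident = stats::runif(1, 60, 90),
                               evalue = top_e * 10^stats::runif(1, 0.05, 0.95),
                               bitscore = round(stats::runif(1, 300, 490)))
    }
    dplyr::bind_rows(top, second, extra)
  })

  # taxonomy hits: top hit is the planted genus; decoys exceed the 10x rule;
  # optional within-threshold confounders for LCA stress testing
  tax_hits <- purrr::map2_dfr(seq_len(n_enz), genus_of, function(i, gen) {
    gid <- genes[enz_gene_idx[i]]
    top_e <- log_uniform(1, -150, -30)
    top <- dplyr::bind_cols(
      tibble::tibble(gene_id = gid, evalue = top_e),
      lineages[match(gen, genera), ]
    )
    out <- top
    n_dec <- sample(0:config$decoy_max, 1)
    if (n_dec > 0) {
      dg <- sample(setdiff(genera, gen), n_dec, replace = FALSE)
      out <- dplyr::bind_rows(out, dplyr::bind_cols(
        tibble::tibble(gene_id = gid,
                       evalue = top_e * 10^stats::runif(n_dec, 1.1, 5)),
        lineages[match(dg, genera), ]
      ))
    }
    if (config$decoy_within > 0) {
      cg <- sample(setdiff(genera, gen), config$decoy_within, replace = FALSE)
      out <- dplyr::bind_rows(out, dplyr::bind_cols(
        tibble::tibble(gene_id = gid,
                       evalue = top_e * 10^stats::runif(config$decoy_within, 0.05, 0.95)),
        lineages[match(cg, genera), ]
      ))
    }
    out
  })

  eff <- config$enzyme_effect_map
  truth <- list(
    gene_enzyme = gene_enzyme,
    gene_genus = gene_genus,
    affected_enzymes = tibble::tibble(
      enzyme = names(eff),
      log2_effect = unname(eff),
      direction = ifelse(unname(eff) > 0, "up-in-AF",
                         ifelse(unname(eff) < 0, "down-in-AF", "none"))
    )[unname(eff) != 0, ],
    genera = genera
  )

  list(abundance = abundance, hits = hits, tax_hits = tax_hits,
       groups = groups, truth = truth)
}

#' Simulate a targeted faecal bile-acid panel
#'
#' Concentrations (nmol/g) are log-normal with a configured coefficient of
#' variation; planted log2 group effects act multiplicatively on case
#' samples. The returned truth records each planted analyte with its
#' direction, the recovery oracle for the differential stage.
#'
#' @param config A [simulation_config()].
#' @return A list with `panel` (tibble: `sample_id` + one column per bile
#'   acid), `groups` and `truth`.
#' @export
#' @examples
#' sim <- simulate_ba_panel(simulation_config(seed = 3))
#' dim(sim$panel)
simulate_ba_panel <- function(config) {
  validate_simulation_config(config)
  set.seed(child_seed(config$seed, 2L))
  groups <- groups_table(config$n_af_panel, config$n_control_panel, "BA")
  n_s <- nrow(groups)
  sdlog <- sqrt(log(1 + config$ba_cv^2))
  af <- as.numeric(groups$group == "AF")

  conc <- purrr::map_dfc(config$panel, function(ba) {
    eff <- if (ba %in% names(config$ba_effect_map)) config$ba_effect_map[[ba]] else 0
    x <- exp(config$ba_log_mean[[ba]] + af * eff * log(2) +
               stats::rnorm(n_s, 0, sdlog))
    stats::setNames(tibble::tibble(x), ba)
  })
  panel <- dplyr::bind_cols(tibble::tibble(sample_id = groups$sample_id), conc)

  eff <- config$ba_effect_map
  truth <- list(
    affected_bas = tibble::tibble(
      ba = names(eff),
      log2_effect = unname(eff),
      direction = ifelse(unname(eff) > 0, "up-in-AF",
                         ifelse(unname(eff) < 0, "down-in-AF", "none"))
    )[unname(eff) != 0, ],
    ba_log_mean = config$ba_log_mean, sdlog = sdlog
  )
  list(panel = panel, groups = groups, truth = truth)
}

#' Simulate a clinical covariate table
#'
#' FGF19 (pg/mL) is log-normal with a negative case shift; LAD (mm) is
#' generated so the raw-scale Pearson correlation with FGF19 across the
#' whole cohort converges to `fgf19_lad_rho`. Because FGF19 is log-normal
#' and both variables carry group shifts, the latent normal correlation is
#' solved for analytically from the configured moments (log-normal
#' attenuation plus the group-difference covariance channel). LVEF is
#' normal with a negative case shift; DM is Bernoulli; age, sex and BMI are
#' group-independent.
#'
#' @param config A [simulation_config()].
#' @return A list with `clinical` (tibble: `subject_id`, `group`, `FGF19`,
#'   `LAD`, `LVEF`, `DM`, `age`, `sex`, `BMI`) and `truth` (generating
#'   parameters, including the solved latent correlation).
#' @export
#' @examples
#' sim <- simulate_clinical(simulation_config(seed = 5))
#' head(sim$clinical)
simulate_clinical <- function(config) {
  validate_simulation_config(config)
  set.seed(child_seed(config$seed, 3L))
  n_af <- config$n_af_clinical; n_ct <- config$n_control_clinical
  n <- n_af + n_ct
  af <- rep(c(1, 0), c(n_af, n_ct))
  p <- n_af / n
  s <- config$fgf19_sdlog

  # closed-form moments of the FGF19 mixture, used to solve for the latent
  # normal correlation that delivers the requested raw-scale Pearson r
  m1 <- exp(config$fgf19_log_mean + config$fgf19_effect + s^2 / 2)
  m0 <- exp(config$fgf19_log_mean + s^2 / 2)
  v1 <- m1^2 * (exp(s^2) - 1); v0 <- m0^2 * (exp(s^2) - 1)
  var_f <- p * v1 + (1 - p) * v0 + p * (1 - p) * (m1 - m0)^2
  cov_af_f <- p * (1 - p) * (m1 - m0)
  var_lad <- config$lad_sd^2 + config$lad_af_shift^2 * p * (1 - p)
  m_mix <- p * m1 + (1 - p) * m0
  rho_latent <- (config$fgf19_lad_rho * sqrt(var_f * var_lad) -
                   config$lad_af_shift * cov_af_f) /
    (config$lad_sd * s * m_mix)
  if (abs(rho_latent) >= 1) {
    stop("requested fgf19_lad_rho is unattainable under the configured ",
         "FGF19/LAD moments (solved latent correlation |",
         round(rho_latent, 3), "| >= 1)", call. = FALSE)
  }

  z1 <- stats::rnorm(n)
  z2 <- rho_latent * z1 + sqrt(1 - rho_latent^2) * stats::rnorm(n)
  fgf19 <- exp(config$fgf19_log_mean + config$fgf19_effect * af + s * z1)
  lad <- config$lad_mean + config$lad_af_shift * af + config$lad_sd * z2
  lvef <- config$lvef_mean + config$lvef_af_shift * af +
    stats::rnorm(n, 0, config$lvef_sd)
  dm <- stats::rbinom(n, 1, ifelse(af == 1, config$dm_prob_af, config$dm_prob_control))
  clinical <- tibble::tibble(
    subject_id = sprintf("SUBJ_%03d", seq_len(n)),
    group = ifelse(af == 1, "AF", "control"),
    FGF19 = fgf19, LAD = lad, LVEF = lvef, DM = dm,
    age = stats::rnorm(n, config$age_mean, config$age_sd),
    sex = stats::rbinom(n, 1, config$sex_prob),
    BMI = stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  )
  truth <- list(
    fgf19_effect = config$fgf19_effect,
    fgf19_lad_rho = config$fgf19_lad_rho,
    rho_latent = rho_latent,
    lad_af_shift = config$lad_af_shift,
    lvef_af_shift = config$lvef_af_shift
  )
  list(clinical = clinical, truth = truth)
}
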