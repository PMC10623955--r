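#' Filter alignment hits by the 10x top-hit e-value rule
#'
#' For each gene, retains exactly the hits whose e-value is at most
#' `factor` times the gene's minimum e-value (inclusive), so the top hit is
#' always retained. An e-value of exactly zero is treated as 1e-308 before
#' multiplication so the rule stays meaningful. Filtering is idempotent.
#'
#' @param hits A data frame with at least `gene_id` and `evalue` columns
#'   (e.g. an enzyme hit table or a taxonomy hit table).
#' @param factor Positive multiple of the per-gene minimum e-value (default 10).
#' @return The retained rows as a tibble, original column set preserved.
#' @export
#' @examples
#' h <- tibble::tibble(gene_id = "g", enzyme = c("BaiH", "BaiB", "BSH"),
#'                     evalue = c(1e-20, 5e-20, 2e-19))
#' filter_significant_hits(h)
filter_significant_hits <- function(hits, factor = 10) {
  stopifnot(is.data.frame(hits), all(c("gene_id", "evalue") %in% names(hits)))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("factor must be a single positive number", call. = FALSE)
  }
  if (nrow(hits) == 0) return(tibble::as_tibble(hits))
  if (any(hits$evalue < 0)) stop("e-values must be >= 0", call. = FALSE)
  hits |>
    dplyr::mutate(.e = pmax(.data$evalue, 1e-308)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(.data$.e <= factor * min(.data$.e)) |>
    dplyr::ungroup() |>
    dplyr::select(-".e")
}

#' Assign each gene the enzyme of its best retained hit
#'
#' Best hit = lowest e-value, ties broken by higher bitscore, then by
#' lexicographic enzyme name (deterministic). Genes without hits are absent
#' from the result.
#'
#' @param hits A (typically already filtered) hit table with `gene_id`,
#'   `enzyme`, `evalue` and optionally `bitscore` columns.
#' @return A tibble with columns `gene_id`, `enzyme`.
#' @export
assign_enzyme <- function(hits) {
  stopifnot(all(c("gene_id", "enzyme", "evalue") %in% names(hits)))
  if (nrow(hits) == 0) return(tibble::tibble(gene_id = character(), enzyme = character()))
  if (!"bitscore" %in% names(hits)) hits$bitscore <- 0
  hits |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$enzyme,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "enzyme") |>
    dplyr::arrange(.data$gene_id)
}

#' Sum gene abundances into an enzyme-by-sample profile
#'
#' The profile entry for enzyme e and sample s is the sum of the relative
#' abundances of the genes assigned to e in s. Enzymes from `enzymes` with
#' no assigned genes appear as all-zero rows.
#'
#' @param assignments A tibble with `gene_id`, `enzyme` (from
#'   [assign_enzyme()]).
#' @param abundance A gene abundance table: `gene_id` column plus one
#'   numeric column per sample.
#' @param enzymes Enzyme vocabulary defining the output rows
#'   (default [ba_enzymes()]).
#' @return A tibble with an `enzyme` column and one column per sample.
#' @export
compute_enzyme_profile <- function(assignments, abundance, enzymes = ba_enzymes()) {
  stopifnot(all(c("gene_id", "enzyme") %in% names(assignments)),
            "gene_id" %in% names(abundance))
  missing <- setdiff(assignments$gene_id, abundance$gene_id)
  if (length(missing) > 0) {
    stop("assigned gene(s) missing from abundance table: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  }
  samples <- setdiff(names(abundance), "gene_id")
  prof <- assignments |>
    dplyr::inner_join(abundance, by = "gene_id") |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum), .groups = "drop")
  out <- tibble::tibble(enzyme = enzymes) |>
    dplyr::left_join(prof, by = "enzyme") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(samples), ~ tidyr::replace_na(.x, 0)))
  out
}

#' Taxonomic assignment by lowest common ancestor of retained hits
#'
#' Hits are first filtered by the 10x top-hit e-value rule per gene
#' ([filter_significant_hits()]); the assigned lineage is then the deepest
#' rank prefix shared by all retained lineages, walking the fixed ladder
#' superkingdom > phylum > class > order > family > genus > species. Genes
#' whose retained hits disagree already at superkingdom are unassigned
#' (root). Lineages must satisfy the prefix property: no rank may be present
#' below a missing rank.
#'
#' @param tax_hits A tibble with `gene_id`, `evalue` and the seven rank
#'   columns; empty string or NA marks a missing rank.
#' @param factor E-value filter multiple (default 10).
#' @return A tibble with `gene_id`, `rank` (the deepest assigned rank or
#'   "root"), and the seven rank columns, NA below the assignment depth.
#' @export
lca_assign <- function(tax_hits, factor = 10) {
  ranks <- tax_ranks()
  stopifnot(all(c("gene_id", "evalue", ranks) %in% names(tax_hits)))
  th <- tax_hits |>
    dplyr::mutate(dplyr::across(dplyr::all_of(ranks), ~ dplyr::na_if(as.character(.x), "")))
  # prefix property: a present rank below a missing one is malformed
  rank_mat <- !is.na(as.matrix(th[ranks]))
  bad <- apply(rank_mat, 1, function(r) any(diff(r) > 0))
  if (any(bad)) {
    stop("malformed lineage (rank present below a missing rank) for gene(s): ",
         paste(unique(th$gene_id[bad]), collapse = ", "), call. = FALSE)
  }
  retained <- filter_significant_hits(th, factor = factor)
  retained |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(~ lca_one(.x, ranks)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id)
}

lca_one <- function(hits, ranks) {
  lin <- rep(NA_character_, length(ranks))
  depth <- 0L
  for (j in seq_along(ranks)) {
    vals <- unique(hits[[ranks[j]]])
    if (length(vals) == 1 && !is.na(vals)) {
      lin[j] <- vals
      depth <- j
    } else {
      break
    }
  }
  out <- tibble::as_tibble(stats::setNames(as.list(lin), ranks))
  dplyr::bind_cols(tibble::tibble(rank = if (depth == 0L) "root" else ranks[depth]), out)
}

# Wilcoxon rank-sum with the exact/approximate gate used throughout the
# pipeline: exact when both groups have <= `exact_max` observations and the
# pooled data carry no ties; otherwise normal approximation with tie and
# continuity correction.
wilcox_rank_sum <- function(x, y, exact_max = 12) {
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !has_ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Two-group differential testing of a feature-by-sample profile
#'
#' Applies the two-sided Wilcoxon rank-sum test per feature (exact when
#' both groups have at most 12 samples and there are no ties, otherwise the
#' tie- and continuity-corrected normal approximation), and computes a
#' median-based log2 fold change with pseudo-count epsilon equal to half
#' the smallest nonzero value of the feature.
#'
#' @param profile A tibble whose first column names the feature (any column
#'   name) and whose remaining columns are samples.
#' @param groups A tibble with `sample_id` and `group` ("AF"/"control").
#' @param adjust If TRUE, adds a Benjamini-Hochberg `q_value` column
#'   (off by default; raw p-values are the primary output).
#' @return A tibble: feature column, `median_af`, `median_control`,
#'   `log2_fc`, `p_value`, `direction` ("up-in-AF"/"down-in-AF"/"none"),
#'   and `q_value` when `adjust = TRUE`.
#' @export
#' @examples
#' prof <- tibble::tibble(enzyme = "BaiH", s1 = 1, s2 = 2, s3 = 3,
#'                        s4 = 4, s5 = 5, s6 = 6)
#' grp <- tibble::tibble(sample_id = paste0("s", 1:6),
#'                       group = rep(c("AF", "control"), each = 3))
#' differential_features(prof, grp)
differential_features <- function(profile, groups, adjust = FALSE) {
  stopifnot(is.data.frame(profile), ncol(profile) >= 3,
            all(c("sample_id", "group") %in% names(groups)))
  feature_col <- names(profile)[1]
  samples <- setdiff(names(profile), feature_col)
  grp <- groups$group[match(samples, groups$sample_id)]
  if (any(is.na(grp))) {
    stop("sample(s) missing from the groups table: ",
         paste(samples[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  if (sum(grp == "AF") < 2 || sum(grp == "control") < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  af_cols <- samples[grp == "AF"]; ct_cols <- samples[grp == "control"]

  res <- purrr::map_dfr(seq_len(nrow(profile)), function(i) {
    x <- as.numeric(profile[i, af_cols])
    y <- as.numeric(profile[i, ct_cols])
    v <- c(x, y)
    nz <- v[v > 0]
    eps <- if (length(nz) > 0) min(nz) / 2 else 0
    m_af <- stats::median(x); m_ct <- stats::median(y)
    # median fold change is defined for nonnegative abundance data only
    l2fc <- if (m_af + eps == 0 && m_ct + eps == 0) 0 else
      if (m_af + eps <= 0 || m_ct + eps <= 0) NA_real_ else
        log2((m_af + eps) / (m_ct + eps))
    tibble::tibble(
      feature = profile[[feature_col]][i],
      median_af = m_af, median_control = m_ct,
      log2_fc = l2fc,
      p_value = wilcox_rank_sum(x, y),
      direction = if (m_af > m_ct) "up-in-AF" else if (m_af < m_ct) "down-in-AF" else "none"
    )
  })
  names(res)[1] <- feature_col
  if (adjust) res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}
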