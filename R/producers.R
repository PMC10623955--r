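#' Aggregate enzyme genes into a genus-by-enzyme harbouring matrix
#'
#' Combines per-gene enzyme assignments with genus-level taxonomic
#' assignments and gene abundances. Genes whose lowest-common-ancestor
#' assignment resolves above genus are excluded (they stay in the enzyme
#' profile, but cannot be attributed to a genus).
#'
#' @param assignments Tibble `gene_id`, `enzyme` from [assign_enzyme()].
#' @param lca Tibble from [lca_assign()]; only rows assigned at genus or
#'   species depth contribute.
#' @param abundance Gene abundance table (`gene_id` + one column per sample).
#' @return An object of class `genus_enzyme_matrix`: a list with
#'   `counts` (tibble: `genus`, `enzyme`, `n_genes`, `present`) and
#'   `abundance` (tibble: `genus`, `enzyme`, one column per sample with the
#'   summed relative abundance).
#' @export
build_genus_enzyme_matrix <- function(assignments, lca, abundance) {
  stopifnot(all(c("gene_id", "enzyme") %in% names(assignments)),
            all(c("gene_id", "genus", "rank") %in% names(lca)),
            "gene_id" %in% names(abundance))
  samples <- setdiff(names(abundance), "gene_id")
  genus_level <- lca |>
    dplyr::filter(.data$rank %in% c("genus", "species"), !is.na(.data$genus)) |>
    dplyr::select("gene_id", "genus")
  joined <- assignments |>
    dplyr::inner_join(genus_level, by = "gene_id")
  counts <- joined |>
    dplyr::count(.data$genus, .data$enzyme, name = "n_genes") |>
    dplyr::mutate(present = .data$n_genes >= 1) |>
    dplyr::arrange(.data$genus, .data$enzyme)
  abund <- joined |>
    dplyr::inner_join(abundance, by = "gene_id") |>
    dplyr::group_by(.data$genus, .data$enzyme) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum), .groups = "drop") |>
    dplyr::arrange(.data$genus, .data$enzyme)
  structure(list(counts = counts, abundance = abund),
            class = "genus_enzyme_matrix")
}

#' @export
print.genus_enzyme_matrix <- function(x, ...) {
  cat("<genus_enzyme_matrix> ",
      dplyr::n_distinct(x$counts$genus), " genera x ",
      dplyr::n_distinct(x$counts$enzyme), " enzymes (",
      nrow(x$counts), " occupied cells)\n", sep = "")
  invisible(x)
}

#' Per-genus total abundance of enzyme genes
#'
#' Convenience summary used by the differential-genus and network stages:
#' sums the genus-by-enzyme abundance over enzymes.
#'
#' @param matrix A `genus_enzyme_matrix`.
#' @return Tibble: `genus` plus one column per sample.
#' @export
genus_abundance <- function(matrix) {
  stopifnot(inherits(matrix, "genus_enzyme_matrix"))
  samples <- setdiff(names(matrix$abundance), c("genus", "enzyme"))
  matrix$abundance |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum), .groups = "drop")
}

#' Classify bile-acid producer genera
#'
#' A genus is a potential producer for a pathway if it harbours at least one
#' gene for any enzyme of that pathway. Also reports the genera carrying
#' both 7-alpha and 7-beta HSDH (the epimerisation pair) and the genera
#' carrying a near-complete bai operon (at least `bai_min_count` distinct
#' bai genes), plus the disjoint Venn regions of the three pathway sets.
#'
#' @param matrix A `genus_enzyme_matrix` from [build_genus_enzyme_matrix()].
#' @param map A pathway map from [ba_pathway_map()].
#' @return An object of class `producer_report`: list with `pathway_sets`
#'   (named list of genus character vectors), `venn` (tibble of disjoint
#'   region counts), `hsdh_pair_set`, `bai_complete_set`, and `set_sizes`.
#' @export
classify_producers <- function(matrix, map = ba_pathway_map()) {
  stopifnot(inherits(matrix, "genus_enzyme_matrix"))
  validate_pathway_map(map)
  counts <- matrix$counts
  genera_of <- function(enzymes) {
    sort(unique(counts$genus[counts$enzyme %in% enzymes & counts$present]))
  }
  pathway_sets <- purrr::map(map$pathways, genera_of)

  hsdh_pair_set <- sort(intersect(genera_of("7a-HSDH"), genera_of("7b-HSDH")))
  bai_complete_set <- counts |>
    dplyr::filter(.data$enzyme %in% map$bai_set, .data$present) |>
    dplyr::distinct(.data$genus, .data$enzyme) |>
    dplyr::count(.data$genus, name = "n_bai") |>
    dplyr::filter(.data$n_bai >= map$bai_min_count) |>
    dplyr::pull("genus") |>
    sort()

  # disjoint Venn regions over the three pathway sets
  all_genera <- sort(unique(unlist(pathway_sets)))
  pnames <- names(pathway_sets)
  membership <- purrr::map_dfc(pathway_sets, ~ all_genera %in% .x)
  venn <- dplyr::bind_cols(tibble::tibble(genus = all_genera), membership) |>
    dplyr::count(dplyr::across(dplyr::all_of(pnames)), name = "n_genera")

  structure(list(
    pathway_sets = pathway_sets,
    set_sizes = purrr::map_int(pathway_sets, length),
    venn = venn,
    hsdh_pair_set = hsdh_pair_set,
    bai_complete_set = bai_complete_set,
    bai_min_count = map$bai_min_count
  ), class = "producer_report")
}

#' @export
print.producer_report <- function(x, ...) {
  cat("<producer_report>\n")
  for (p in names(x$pathway_sets)) {
    cat(sprintf("  %-14s %d genera\n", p, length(x$pathway_sets[[p]])))
  }
  cat(sprintf("  7a+7b HSDH pair: %d genera\n", length(x$hsdh_pair_set)))
  cat(sprintf("  >=%d bai genes:   %d genera\n",
              x$bai_min_count, length(x$bai_complete_set)))
  invisible(x)
}

#' Genus-enzyme correlation network
#'
#' Correlates each genus abundance vector with each enzyme abundance vector
#' across samples (Spearman rank correlation by default) and keeps the
#' signed edges whose p-value falls below the threshold. Zero-variance
#' vectors are skipped with a warning.
#'
#' @param genus_abund Tibble `genus` + one column per sample (e.g. from
#'   [genus_abundance()]).
#' @param enzyme_profile Tibble `enzyme` + one column per sample.
#' @param method "spearman" (default) or "pearson".
#' @param p_threshold Retain edges with p below this value (default 0.05).
#' @return Tibble: `genus`, `enzyme`, `rho`, `p_value`, `sign` ("+"/"-").
#' @export
correlation_network <- function(genus_abund, enzyme_profile,
                                method = c("spearman", "pearson"),
                                p_threshold = 0.05) {
  method <- match.arg(method)
  stopifnot("genus" %in% names(genus_abund), "enzyme" %in% names(enzyme_profile))
  samples <- intersect(setdiff(names(genus_abund), "genus"),
                       setdiff(names(enzyme_profile), "enzyme"))
  if (length(samples) < 4) stop("need at least 4 shared samples", call. = FALSE)
  if (!setequal(setdiff(names(genus_abund), "genus"), samples) ||
      !setequal(setdiff(names(enzyme_profile), "enzyme"), samples)) {
    stop("genus and enzyme tables must cover the same samples", call. = FALSE)
  }
  skipped <- 0L
  edges <- purrr::map_dfr(seq_len(nrow(genus_abund)), function(i) {
    g <- as.numeric(genus_abund[i, samples])
    purrr::map_dfr(seq_len(nrow(enzyme_profile)), function(j) {
      e <- as.numeric(enzyme_profile[j, samples])
      if (stats::sd(g) == 0 || stats::sd(e) == 0) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      ct <- suppressWarnings(stats::cor.test(g, e, method = method, exact = FALSE))
      tibble::tibble(genus = genus_abund$genus[i],
                     enzyme = enzyme_profile$enzyme[j],
                     rho = unname(ct$estimate), p_value = ct$p.value)
    })
  })
  if (skipped > 0) {
    warning(skipped, " genus-enzyme pair(s) skipped (zero variance)", call. = FALSE)
  }
  if (nrow(edges) == 0) {
    return(tibble::tibble(genus = character(), enzyme = character(),
                          rho = numeric(), p_value = numeric(),
                          sign = character()))
  }
  edges |>
    dplyr::filter(.data$p_value < p_threshold) |>
    dplyr::mutate(sign = ifelse(.data$rho >= 0, "+", "-"))
}

#' Write a correlation network as GraphML
#'
#' Exports the edge list as a bipartite genus/enzyme graph readable by
#' standard network viewers.
#'
#' @param edges Edge tibble from [correlation_network()].
#' @param path Output file path (.graphml).
#' @return Invisibly, the path.
#' @export
write_network_graphml <- function(edges, path) {
  stopifnot(all(c("genus", "enzyme", "rho") %in% names(edges)))
  g <- igraph::graph_from_data_frame(
    edges |> dplyr::transmute(from = .data$genus, to = .data$enzyme,
                              weight = .data$rho, sign = .data$sign),
    directed = FALSE,
    vertices = tibble::tibble(
      name = c(unique(edges$genus), unique(edges$enzyme)),
      kind = rep(c("genus", "enzyme"),
                 c(length(unique(edges$genus)), length(unique(edges$enzyme))))
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
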