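# Readers and writers for the pipeline's plain-text dialects: gene
# abundance TSV (gene_id x samples), BLAST-tabular enzyme hits plus a
# reference map, taxonomy-hit TSV with the seven rank columns, sample-group
# TSV, bile-acid panel CSV and clinical CSV. Simulation truth travels as JSON.

blast6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a gene abundance table (TSV, genes x samples)
#' @param path TSV with a `gene_id` column then one numeric column per sample.
#' @return Tibble.
#' @export
read_gene_abundance <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a gene abundance table
#' @param abundance Tibble from [simulate_metagenome()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_gene_abundance <- function(abundance, path) {
  readr::write_tsv(abundance, path)
  invisible(path)
}

#' Read enzyme alignment hits from BLAST tabular format
#'
#' Reads a headerless outfmt-6-style TSV (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) and maps
#' subject ids to enzyme names through a two-column reference map.
#'
#' @param path BLAST tabular TSV.
#' @param ref_map_path TSV with header columns `sseqid`, `enzyme`.
#' @return Tibble: `gene_id`, `enzyme`, `pident`, `evalue`, `bitscore`.
#' @export
read_enzyme_hits <- function(path, ref_map_path) {
  raw <- readr::read_tsv(path, col_names = blast6_cols, show_col_types = FALSE)
  ref <- readr::read_tsv(ref_map_path, show_col_types = FALSE)
  stopifnot(all(c("sseqid", "enzyme") %in% names(ref)))
  unknown <- setdiff(unique(raw$sseqid), ref$sseqid)
  if (length(unknown) > 0) {
    stop("hit(s) to subject id(s) absent from the reference map: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  raw |>
    dplyr::inner_join(ref, by = "sseqid") |>
    dplyr::transmute(gene_id = .data$qseqid, enzyme = .data$enzyme,
                     pident = .data$pident, evalue = .data$evalue,
                     bitscore = .data$bitscore)
}

#' Write enzyme hits as BLAST tabular format plus reference map
#'
#' @param hits Tibble from [simulate_metagenome()] (`gene_id`, `enzyme`,
#'   `pident`, `evalue`, `bitscore`).
#' @param path Output TSV (headerless, outfmt-6 column order).
#' @param ref_map_path Output path for the subject-to-enzyme map.
#' @return Invisibly, `path`.
#' @export
write_enzyme_hits <- function(hits, path, ref_map_path) {
  ref <- tibble::tibble(sseqid = paste0("ref|", ba_enzymes(), "|1"),
                        enzyme = ba_enzymes())
  out <- hits |>
    dplyr::transmute(
      qseqid = .data$gene_id,
      sseqid = paste0("ref|", .data$enzyme, "|1"),
      pident = round(.data$pident, 2),
      length = 300L, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
      evalue = .data$evalue, bitscore = .data$bitscore
    )
  readr::write_tsv(out, path, col_names = FALSE)
  readr::write_tsv(ref, ref_map_path)
  invisible(path)
}

#' Read taxonomy hits (gene_id, evalue, seven rank columns)
#' @param path TSV with header; empty strings mark missing ranks.
#' @return Tibble.
#' @export
read_taxon_hits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = "c", evalue = "d", .default = "c"
                  ))
}

#' Write taxonomy hits
#' @param tax_hits Tibble from [simulate_metagenome()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_taxon_hits <- function(tax_hits, path) {
  readr::write_tsv(tax_hits, path, na = "")
  invisible(path)
}

#' Read a sample-group table (TSV: sample_id, group)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_groups <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(g)))
  g
}

#' Write a sample-group table
#' @param groups Tibble `sample_id`, `group`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_groups <- function(groups, path) {
  readr::write_tsv(groups, path)
  invisible(path)
}

#' Read a bile-acid panel (CSV: sample_id then one column per analyte)
#' @param path CSV path.
#' @return Tibble.
#' @export
read_ba_panel <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("sample_id" %in% names(p))
  p
}

#' Write a bile-acid panel CSV
#' @param panel Tibble from [simulate_ba_panel()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_ba_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' Read a clinical covariate table (CSV with header-declared schema)
#' @param path CSV path.
#' @return Tibble.
#' @export
read_clinical <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("group" %in% names(d))
  d
}

#' Write a clinical covariate table
#' @param clinical Tibble from [simulate_clinical()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(clinical, path)
  invisible(path)
}

#' Write simulation truth as JSON
#' @param truth Truth list from a `simulate_*` call.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
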