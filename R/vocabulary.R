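#' Bile-acid biotransformation enzyme vocabulary
#'
#' The thirteen microbial enzymes profiled by the pipeline: bile-salt
#' hydrolase (BSH), the two 7-hydroxysteroid dehydrogenases that epimerise
#' CDCA and UDCA, and the ten genes of the bai operon that carry out
#' 7-dehydroxylation of primary to secondary bile acids.
#'
#' @return Character vector of the 13 enzyme names.
#' @export
#' @examples
#' ba_enzymes()
ba_enzymes <- function() {
  c("BSH", "7a-HSDH", "7b-HSDH",
    "BaiB", "BaiF", "BaiA", "BaiH", "BaiI", "BaiN",
    "BaiCD", "BaiE", "BaiA2", "BaiG")
}

#' The ten bai operon enzymes
#' @return Character vector of bai gene names.
#' @export
bai_enzymes <- function() {
  c("BaiB", "BaiF", "BaiA", "BaiH", "BaiI", "BaiN",
    "BaiCD", "BaiE", "BaiA2", "BaiG")
}

#' Default 24-bile-acid panel
#'
#' Seventeen bile acids commonly quantified in targeted faecal assays plus
#' seven further conjugates/derivatives to fill a 24-analyte panel. All
#' concentrations are in nmol/g wet faeces.
#'
#' @return Character vector of 24 bile-acid names.
#' @export
ba_panel <- function() {
  c("UDCA", "bUDCA", "HCA", "7-KetoLCA", "3-DHCA", "6-KetoLCA",
    "CDCA", "TCA", "CA", "GUDCA", "TCDCA", "TUDCA",
    "dehydroLCA", "12-ketoLCA", "LCA", "GDCA", "DCA",
    "GCA", "GCDCA", "TDCA", "GLCA", "TLCA", "isoLCA", "7-KetoDCA")
}

#' Default bile-acid classification map
#'
#' Classifies each panel bile acid as primary (host-synthesised CA/CDCA and
#' their glycine/taurine conjugates) or secondary (bacterial transformation
#' products: DCA, LCA, UDCA, HCA, their keto/dehydro derivatives and
#' conjugates), with conjugation state and core parent. The grouping is
#' configurable; this default follows the classical BA biotransformation
#' chemistry.
#'
#' @return A tibble with columns `ba`, `class` ("primary"/"secondary"),
#'   `conjugation` ("free"/"glycine"/"taurine"), `parent`.
#' @export
ba_class_map <- function() {
  tibble::tribble(
    ~ba,          ~class,      ~conjugation, ~parent,
    "CA",         "primary",   "free",       "CA",
    "TCA",        "primary",   "taurine",    "CA",
    "GCA",        "primary",   "glycine",    "CA",
    "CDCA",       "primary",   "free",       "CDCA",
    "TCDCA",      "primary",   "taurine",    "CDCA",
    "GCDCA",      "primary",   "glycine",    "CDCA",
    "UDCA",       "secondary", "free",       "UDCA",
    "bUDCA",      "secondary", "free",       "UDCA",
    "TUDCA",      "secondary", "taurine",    "UDCA",
    "GUDCA",      "secondary", "glycine",    "UDCA",
    "HCA",        "secondary", "free",       "HCA",
    "DCA",        "secondary", "free",       "DCA",
    "TDCA",       "secondary", "taurine",    "DCA",
    "GDCA",       "secondary", "glycine",    "DCA",
    "3-DHCA",     "secondary", "free",       "DCA",
    "12-ketoLCA", "secondary", "free",       "DCA",
    "7-KetoDCA",  "secondary", "free",       "DCA",
    "LCA",        "secondary", "free",       "LCA",
    "TLCA",       "secondary", "taurine",    "LCA",
    "GLCA",       "secondary", "glycine",    "LCA",
    "isoLCA",     "secondary", "free",       "LCA",
    "dehydroLCA", "secondary", "free",       "LCA",
    "7-KetoLCA",  "secondary", "free",       "LCA",
    "6-KetoLCA",  "secondary", "free",       "LCA"
  )
}

#' Default enzyme-to-pathway map for producer classification
#'
#' Maps enzymes to the three secondary-bile-acid synthesis routes: UDCA
#' synthesis through the 7-alpha/7-beta HSDH epimerisation pair, and LCA /
#' DCA synthesis through the bai 7-dehydroxylation operon (the same operon
#' dehydroxylates CDCA to LCA and CA to DCA, so both routes share the bai
#' set by default). BSH deconjugates but is assigned to no synthesis route.
#'
#' @param bai_min_count Minimum number of distinct bai genes for a genus to
#'   count as carrying a near-complete operon (default 5).
#' @return A list with elements `pathways` (named list of enzyme-name
#'   character vectors), `bai_set` and `bai_min_count`.
#' @export
ba_pathway_map <- function(bai_min_count = 5) {
  map <- list(
    pathways = list(
      "UDCA-synthesis" = c("7a-HSDH", "7b-HSDH"),
      "LCA-synthesis"  = bai_enzymes(),
      "DCA-synthesis"  = bai_enzymes()
    ),
    bai_set = bai_enzymes(),
    bai_min_count = bai_min_count
  )
  validate_pathway_map(map)
  map
}

validate_pathway_map <- function(map) {
  stopifnot(is.list(map), all(c("pathways", "bai_set", "bai_min_count") %in% names(map)))
  unknown <- setdiff(unlist(map$pathways), ba_enzymes())
  if (length(unknown) > 0) {
    stop("pathway map references unknown enzyme(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (map$bai_min_count < 1 || map$bai_min_count > length(map$bai_set)) {
    stop("bai_min_count must be between 1 and |bai_set|", call. = FALSE)
  }
  invisible(map)
}

# Fixed taxonomic rank ladder used by the LCA assignment.
tax_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}
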