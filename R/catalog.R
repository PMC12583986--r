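#' Load the hpn gene-family catalog
#'
#' The catalog enumerates the gene families of the hopanoid/BHPD biosynthesis
#' pathway: the MEP isoprenoid backbone (\code{dxs}..\code{ispH},
#' \code{ispA}), squalene synthesis (\code{hpnC/D/E}), the core BHPD steps
#' (\code{shc}, \code{hpnH}, \code{hpnG}), the cyclitol-ether branch
#' (\code{hpnI/K/J}), the amino branch (\code{hpnO}), ring-A methylases
#' (\code{hpnP}, \code{hpnR}), transport and accessory genes, tetrahymanol
#' synthase (\code{ths}) and the sterol-desaturase-like candidate
#' (\code{desat}). Each family carries its pathway stage, whether it is a
#' member of the canonical hpn gene cluster (and its position in the canonical
#' A-R gene order), the percent-similarity acceptance threshold for homology
#' calls, and the label of its shipped surrogate query protein.
#'
#' @return A data frame of class \code{gene_catalog}, one row per family,
#'   with attributes \code{shc_decoy_floor} (percent similarity below which a
#'   squalene-hopene cyclase candidate is treated as the distantly related
#'   secondary Shc clade) and \code{catalog_version}.
#' @export
#' @examples
#' cat <- load_gene_catalog()
#' subset(cat, family_id == "shc")$pathway_stage
load_gene_catalog <- function() {
  if (!is.null(.catalog_cache$catalog)) return(.catalog_cache$catalog)
  path <- system.file("extdata", "gene_catalog.json", package = "hopanotype",
                      mustWork = TRUE)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  fam <- doc$families
  fam$canonical_order <- as.integer(fam$canonical_order)
  stopifnot(!anyDuplicated(fam$family_id),
            all(fam$similarity_threshold > 0 & fam$similarity_threshold <= 100),
            all(fam$pathway_stage %in% c(
              "MEP", "squalene", "core_BHPD", "CE_branch", "amino_branch",
              "methylation", "transport", "accessory", "tetrahymanol",
              "desaturase")))
  .catalog_cache$catalog <- structure(
    fam,
    class = c("gene_catalog", "data.frame"),
    shc_decoy_floor = doc$shc_decoy_floor,
    catalog_version = doc$catalog_version)
  .catalog_cache$catalog
}

.catalog_cache <- new.env(parent = emptyenv())

#' @export
print.gene_catalog <- function(x, ...) {
  cat("hpn gene-family catalog (version ",
      attr(x, "catalog_version"), "): ", nrow(x), " families\n", sep = "")
  cat("  canonical BGC members:",
      paste(x$family_id[x$canonical_bgc_member][order(
        x$canonical_order[x$canonical_bgc_member])], collapse = " "), "\n")
  cat("  shc decoy floor:", attr(x, "shc_decoy_floor"), "% similarity\n")
  invisible(x)
}

#' Similarity threshold for one gene family
#'
#' @param catalog a \code{gene_catalog}
#' @param family_id family name, e.g. \code{"hpnP"}
#' @return percent-similarity threshold (scalar)
#' @export
family_threshold <- function(catalog, family_id) {
  i <- match(family_id, catalog$family_id)
  if (is.na(i)) stop("unknown gene family: ", family_id)
  catalog$similarity_threshold[i]
}

#' Load the shipped surrogate query proteins
#'
#' Surrogate reference sequences stand in for the pathway query proteins; they
#' were generated once with a background amino-acid composition and are frozen
#' in the package. Detection tests plant (mutated) copies of these sequences,
#' so their particular residues carry no biological meaning.
#'
#' @return an \code{AAStringSet} named by query label (e.g. \code{REF_SHC})
#' @export
load_reference_proteins <- function() {
  path <- system.file("extdata", "reference_proteins.fasta",
                      package = "hopanotype", mustWork = TRUE)
  Biostrings::readAAStringSet(path)
}
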