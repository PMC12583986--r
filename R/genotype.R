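#' Assemble a per-genome genotype from accepted gene hits
#'
#' Builds the presence/absence map over the full gene-family catalog and
#' evaluates completeness of the MEP isoprenoid pathway. MEP completeness
#' requires \code{dxs} (or the pyruvate-dehydrogenase-derived bypass
#' \code{aceE}), \code{dxr}, \code{ispD} plus \code{ispF} (or the fused
#' \code{ispDF}), \code{ispE}, \code{ispG}, \code{ispH} and \code{ispA}.
#'
#' @param hits a \code{gene_hits} data frame from one genome
#' @param architecture optional \code{\link{classify_architecture}} report
#' @param catalog a \code{\link{load_gene_catalog}} catalog
#' @return a \code{genome_genotype}: \code{genome_id}, \code{presence}
#'   (named character vector over the catalog, values \code{present} /
#'   \code{absent}), \code{mep_complete}, \code{mep_notes},
#'   \code{architecture}
#' @export
assemble_genotype <- function(hits, architecture = NULL,
                              catalog = load_gene_catalog()) {
  gids <- unique(hits$genome_id)
  if (length(gids) > 1)
    stop("hits from mixed genomes: ", paste(gids, collapse = ", "))
  acc <- accepted_hits(hits)
  presence <- stats::setNames(
    ifelse(catalog$family_id %in% acc$family_id, "present", "absent"),
    catalog$family_id)
  genotype(genome_id = if (length(gids)) gids else "genome",
           presence = presence, architecture = architecture,
           catalog = catalog)
}

#' Construct a genotype from a presence map
#'
#' Fixture-derived genotypes may carry three-valued presence
#' (\code{present} / \code{absent} / \code{unknown}); pipeline-derived
#' genotypes are two-valued.
#'
#' @param genome_id genome label
#' @param presence named character vector over catalog families
#' @param architecture optional \code{architecture_report}
#' @param catalog a \code{gene_catalog}
#' @return a \code{genome_genotype}
#' @export
genotype <- function(genome_id, presence, architecture = NULL,
                     catalog = load_gene_catalog()) {
  if (!all(names(presence) %in% catalog$family_id))
    stop("presence map names outside the catalog: ",
         paste(setdiff(names(presence), catalog$family_id), collapse = ", "))
  full <- stats::setNames(rep("unknown", nrow(catalog)), catalog$family_id)
  full[names(presence)] <- presence
  if (!all(full %in% c("present", "absent", "unknown")))
    stop("presence values must be present/absent/unknown")

  p <- function(x) full[x] == "present"
  mep_notes <- character(0)
  dxs_ok <- p("dxs") || p("aceE")
  if (!p("dxs") && p("aceE"))
    mep_notes <- c(mep_notes, "dxs absent; aceE-type bypass present")
  ispdf_ok <- (p("ispD") && p("ispF")) || p("ispDF")
  if (!(p("ispD") && p("ispF")) && p("ispDF"))
    mep_notes <- c(mep_notes, "ispD and ispF fused as ispDF")
  mep <- dxs_ok && p("dxr") && ispdf_ok && p("ispE") && p("ispG") &&
    p("ispH") && p("ispA")
  structure(list(genome_id = genome_id, presence = full,
                 mep_complete = mep, mep_notes = mep_notes,
                 architecture = architecture),
            class = "genome_genotype")
}

#' @export
print.genome_genotype <- function(x, ...) {
  pres <- names(x$presence)[x$presence == "present"]
  unk <- sum(x$presence == "unknown")
  cat("genotype of ", x$genome_id, ": ", length(pres), " families present",
      if (unk) paste0(" (", unk, " unknown)"), "\n", sep = "")
  cat("  present:", paste(pres, collapse = " "), "\n")
  cat("  MEP pathway complete:", x$mep_complete,
      if (length(x$mep_notes)) paste0(" [", paste(x$mep_notes, collapse = "; "), "]"),
      "\n")
  invisible(x)
}

#' Predict the producible hopanoid/BHPD classes from a genotype
#'
#' Applies the biosynthesis logic of the hpn pathway. The predictions are
#' genetic capacities, not guarantees of product: ring-A methylation genes in
#' particular are known to occur without detectable methylated product, so
#' \code{methyl_2}/\code{methyl_3} read as "capacity to methylate".
#' Rules (all conjunctions follow the pathway order):
#' \itemize{
#'   \item \code{shc} => C30 hopanoids
#'   \item \code{shc & hpnH} => any BHPD; adenosylhopane
#'   \item \code{... & hpnG} => BHT (tetrol)
#'   \item \code{... & hpnG & hpnO} => aminotriol
#'   \item BHT & \code{hpnI} alone => terminal BHT N-acetylglucosamine
#'   \item BHT & \code{hpnI & hpnK & !hpnJ} => terminal BHT glucosamine
#'   \item BHT & \code{hpnI & hpnK & hpnJ} => BHT cyclitol ether
#'   \item \code{hpnP} => 2-methylation capacity; \code{hpnR} =>
#'     3-methylation capacity; both => 2,3-dimethyl conceivable
#'   \item \code{ths} => tetrahymanol
#'   \item sterol-desaturase-like gene => unsaturation suggested (advisory
#'     only; the responsible gene is not established)
#' }
#' BHpentol/BHhexol have no known biosynthesis genes and are never asserted.
#' \code{unknown} gene states never switch a flag to \code{TRUE}; they are
#' surfaced in \code{confidence_notes}.
#'
#' @param genotype a \code{genome_genotype}
#' @return a \code{chemotype_prediction} list of logical flags plus
#'   \code{confidence_notes}
#' @export
predict_chemotype <- function(genotype) {
  pres <- genotype$presence
  p <- function(x) !is.na(pres[x]) && pres[x] == "present"
  u <- function(x) !is.na(pres[x]) && pres[x] == "unknown"
  notes <- character(0)
  note_unknown <- function(flag, fams) {
    unk <- fams[vapply(fams, u, logical(1))]
    if (length(unk))
      notes <<- c(notes, paste0(flag, ": state of ",
                                paste(unk, collapse = "/"), " unknown"))
  }

  c30 <- p("shc"); note_unknown("c30_hopanoids", "shc")
  bhpd <- c30 && p("hpnH"); if (c30) note_unknown("bhpd_any", "hpnH")
  adeno <- bhpd
  bht <- bhpd && p("hpnG"); if (bhpd) note_unknown("bht", "hpnG")
  amino <- bht && p("hpnO"); if (bht) note_unknown("aminotriol", "hpnO")
  ce_acgluc <- bht && p("hpnI") && !p("hpnK")
  ce_gluc <- bht && p("hpnI") && p("hpnK") && !p("hpnJ")
  ce_full <- bht && p("hpnI") && p("hpnK") && p("hpnJ")
  if (bht) note_unknown("cyclitol ether branch", c("hpnI", "hpnK", "hpnJ"))
  me2 <- p("hpnP"); note_unknown("methyl_2", "hpnP")
  me3 <- p("hpnR"); note_unknown("methyl_3", "hpnR")
  th <- p("ths"); note_unknown("tetrahymanol", "ths")
  uns <- p("desat") || p("hpnX")
  note_unknown("unsaturation_suggested", c("desat", "hpnX"))

  structure(list(
    c30_hopanoids = c30, bhpd_any = bhpd, adenosylhopane = adeno,
    bht = bht, aminotriol = amino,
    ce_acetylglucosamine_terminal = ce_acgluc,
    ce_glucosamine_terminal = ce_gluc, ce_terminal = ce_full,
    methyl_2 = me2, methyl_3 = me3,
    dimethyl_2_3_possible = me2 && me3, tetrahymanol = th,
    unsaturation_suggested = uns,
    confidence_notes = notes), class = "chemotype_prediction")
}

#' @export
print.chemotype_prediction <- function(x, ...) {
  flags <- unlist(x[vapply(x, is.logical, logical(1))])
  cat("predicted chemotype capacities:\n")
  on <- names(flags)[flags]
  cat("  ", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  if (length(x$confidence_notes)) {
    cat("  notes:\n")
    for (n in x$confidence_notes) cat("   -", n, "\n")
  }
  invisible(x)
}
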