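#' Acceptance policy for homology calls
#'
#' A hit is accepted when its percent similarity reaches the family threshold
#' from the catalog and it covers at least \code{coverage_floor} of the query
#' length (the coverage floor guards against domain-fragment false
#' positives). \code{report_candidates} controls how many top-scoring
#' proteins per family are evaluated in detail and reported (rejections
#' included).
#'
#' @param coverage_floor minimum query coverage in (0,1]
#' @param report_candidates candidates retained per family
#' @param threshold_overrides named numeric vector of per-family
#'   percent-similarity thresholds overriding the catalog
#' @return a \code{threshold_policy} list
#' @export
threshold_policy <- function(coverage_floor = 0.7, report_candidates = 5L,
                             threshold_overrides = NULL) {
  stopifnot(coverage_floor > 0, coverage_floor <= 1, report_candidates >= 1)
  structure(list(coverage_floor = coverage_floor,
                 report_candidates = as.integer(report_candidates),
                 threshold_overrides = threshold_overrides),
            class = "threshold_policy")
}

#' Scan a proteome for hpn pathway genes
#'
#' Aligns every catalog query protein against every protein of the proteome
#' (Smith-Waterman, see \code{\link{align_local}}), then calls presence per
#' family: the best-scoring protein is accepted if its percent similarity
#' reaches the family threshold and its query coverage the coverage floor.
#' The top candidates per family are reported with their rejection reasons so
#' that near-misses remain auditable. Squalene-hopene cyclase candidates
#' below the secondary-Shc similarity floor are subsequently flagged by
#' \code{\link{exclude_secondary_shc}}, which \code{scan_proteome} applies by
#' default.
#'
#' @param proteome an \code{AAStringSet} (names are protein/locus ids) or a
#'   list of \code{\link{protein_record}}s
#' @param catalog a \code{\link{load_gene_catalog}} catalog
#' @param policy a \code{\link{threshold_policy}}
#' @param scoring a \code{\link{scoring_scheme}}
#' @param genome_id genome label recorded on the hits
#' @param references query proteins (defaults to the shipped surrogates)
#' @param apply_shc_floor apply the secondary-Shc decoy rule
#' @return a \code{gene_hits} data frame: \code{genome_id},
#'   \code{family_id}, \code{protein_id}, \code{score},
#'   \code{percent_similarity}, \code{query_coverage}, \code{call}
#'   (\code{accepted}, \code{rejected_low_similarity},
#'   \code{rejected_low_coverage}, \code{rejected_decoy},
#'   \code{rejected_outcompeted}), ordered by (family_id, protein_id)
#' @export
scan_proteome <- function(proteome, catalog = load_gene_catalog(),
                          policy = threshold_policy(),
                          scoring = scoring_scheme(),
                          genome_id = "genome",
                          references = load_reference_proteins(),
                          apply_shc_floor = TRUE) {
  prot <- .as_aastringset(proteome)
  empty <- data.frame(genome_id = character(), family_id = character(),
                      protein_id = character(), score = numeric(),
                      percent_similarity = numeric(),
                      query_coverage = numeric(), call = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("gene_hits", "data.frame")
  if (length(prot) == 0L) return(empty)
  if (anyDuplicated(names(prot))) stop("duplicate protein ids in proteome")

  rows <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    fam <- catalog$family_id[i]
    qlab <- catalog$query_label[i]
    if (!qlab %in% names(references))
      stop("no reference protein for family ", fam, " (", qlab, ")")
    query <- references[[qlab]]
    thr <- catalog$similarity_threshold[i]
    ov <- policy$threshold_overrides
    if (!is.null(ov) && fam %in% names(ov)) thr <- ov[[fam]]

    scores <- Biostrings::pairwiseAlignment(
      pattern = prot, subject = query, type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      scoreOnly = TRUE)
    ord <- order(-scores, names(prot))
    keep <- utils::head(ord, policy$report_candidates)

    aln <- Biostrings::pairwiseAlignment(
      pattern = prot[keep], subject = query, type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    # pattern/subject are swapped relative to align_local(query, target);
    # the statistics are symmetric except coverage, computed on the query
    pa <- as.character(Biostrings::alignedSubject(aln))
    sa <- as.character(Biostrings::alignedPattern(aln))
    fam_rows <- lapply(seq_along(keep), function(m) {
      st <- .alignment_stats(pa[m], sa[m], scoring$matrix, length(query))
      data.frame(genome_id = genome_id, family_id = fam,
                 protein_id = names(prot)[keep[m]],
                 score = Biostrings::score(aln)[m],
                 percent_similarity = st$percent_similarity,
                 query_coverage = st$query_coverage,
                 call = NA_character_, stringsAsFactors = FALSE)
    })
    fam_df <- do.call(rbind, fam_rows)
    # best candidate: highest score, ties by lexicographically lowest id
    best <- order(-fam_df$score, fam_df$protein_id)[1]
    call <- rep("rejected_outcompeted", nrow(fam_df))
    for (k in seq_len(nrow(fam_df))) {
      passes_sim <- fam_df$percent_similarity[k] >= thr
      passes_cov <- fam_df$query_coverage[k] >= policy$coverage_floor
      if (k == best) {
        call[k] <- if (passes_sim && passes_cov) "accepted"
                   else if (!passes_sim) "rejected_low_similarity"
                   else "rejected_low_coverage"
      } else if (!passes_sim) call[k] <- "rejected_low_similarity"
    }
    fam_df$call <- call
    rows[[i]] <- fam_df
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$family_id, hits$protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("gene_hits", "data.frame")
  if (apply_shc_floor)
    hits <- exclude_secondary_shc(hits,
                                  floor = attr(catalog, "shc_decoy_floor"))
  hits
}

#' Flag distantly related secondary squalene-hopene cyclases
#'
#' Some genomes encode a second protein annotated as Shc that is only
#' distantly related to the pathway Shc and whose gene is not part of the
#' BHPD gene cluster; such candidates form a separate clade and are excluded
#' from genotype calls. Any \code{shc} candidate below the similarity floor
#' is marked \code{rejected_decoy}; hits of other families are untouched.
#'
#' @param hits a \code{gene_hits} data frame
#' @param floor percent-similarity floor (default 40)
#' @return the hits with updated \code{call}
#' @export
exclude_secondary_shc <- function(hits, floor = 40) {
  if (is.null(floor)) floor <- 40
  sel <- hits$family_id == "shc" & hits$percent_similarity < floor
  hits$call[sel] <- "rejected_decoy"
  hits
}

#' Accepted hits only
#'
#' @param hits a \code{gene_hits} data frame
#' @return the accepted subset
#' @export
accepted_hits <- function(hits) {
  hits[hits$call == "accepted", , drop = FALSE]
}

.as_aastringset <- function(x) {
  if (inherits(x, "AAStringSet")) return(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "protein_record"))) {
    if (length(x) == 0L) return(Biostrings::AAStringSet())
    out <- Biostrings::AAStringSet(vapply(x, `[[`, character(1), "sequence"))
    names(out) <- vapply(x, `[[`, character(1), "id")
    return(out)
  }
  if (is.character(x)) {
    out <- Biostrings::AAStringSet(x)
    if (is.null(names(out))) names(out) <- paste0("protein_", seq_along(out))
    return(out)
  }
  stop("cannot interpret proteome input")
}
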