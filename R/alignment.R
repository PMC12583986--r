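.matrix_cache <- new.env(parent = emptyenv())

#' Protein record constructor
#'
#' @param id record identifier
#' @param sequence amino-acid string over the 20-letter alphabet plus X
#' @return a \code{protein_record} (list with \code{id}, \code{sequence})
#' @export
protein_record <- function(id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (is.na(sequence) || !nzchar(sequence))
    stop("protein sequence must be non-empty (id: ", id, ")")
  bad <- setdiff(strsplit(sequence, "")[[1]], c(strsplit(
    "ARNDCQEGHILKMFPSTWYV", "")[[1]], "X"))
  if (length(bad))
    stop("invalid amino-acid letters in ", id, ": ",
         paste(unique(bad), collapse = ""))
  structure(list(id = as.character(id), sequence = sequence),
            class = "protein_record")
}

#' Scoring scheme for local protein alignment
#'
#' BLOSUM62 with affine gap penalties (open 11, extend 1) is the default,
#' matching the scoring conventions of standard protein database searches.
#'
#' @param matrix substitution matrix name available in \pkg{Biostrings}
#'   (e.g. \code{"BLOSUM62"}, \code{"BLOSUM45"}, \code{"PAM250"})
#' @param gap_open gap opening penalty (positive)
#' @param gap_extend gap extension penalty per residue (positive)
#' @return a \code{scoring_scheme} list
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.null(.matrix_cache[[matrix]])) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    .matrix_cache[[matrix]] <- get(matrix, envir = e)
  }
  sub <- .matrix_cache[[matrix]]
  stopifnot(gap_open >= 0, gap_extend > 0)
  structure(list(matrix_name = matrix, matrix = sub,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

.as_aa <- function(x) {
  if (inherits(x, "protein_record")) x$sequence else as.character(x)
}

# column-wise identity / positives / coverage statistics for one alignment
.alignment_stats <- function(p, s, sub, query_len) {
  pa <- strsplit(p, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  ncol_aln <- length(pa)
  gap <- pa == "-" | sa == "-"
  ident <- sum(!gap & pa == sa)
  pos <- if (any(!gap)) sum(sub[cbind(pa[!gap], sa[!gap])] > 0) else 0L
  list(aligned_length = ncol_aln,
       percent_identity = 100 * ident / ncol_aln,
       percent_similarity = 100 * pos / ncol_aln,
       query_coverage = sum(pa != "-") / query_len)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under an affine-gap scoring scheme (via
#' \code{Biostrings::pairwiseAlignment}). Percent similarity is the fraction
#' of alignment columns with a positive substitution score (the "positives"
#' convention of protein database searches); gap columns count as
#' non-positive for both identity and similarity.
#'
#' @param query,target \code{protein_record}s (or plain sequence strings)
#' @param scoring a \code{\link{scoring_scheme}}
#' @return an \code{alignment_result} list: \code{score},
#'   \code{aligned_length}, \code{percent_identity},
#'   \code{percent_similarity}, \code{query_coverage}
#' @export
#' @examples
#' a <- align_local("MKTAYIAKQR", "MKTAYIAKQR")
#' a$percent_identity  # 100
align_local <- function(query, target, scoring = scoring_scheme()) {
  q <- .as_aa(query); t <- .as_aa(target)
  if (!nzchar(q) || !nzchar(t)) stop("cannot align empty sequences")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q), subject = Biostrings::AAString(t),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  st <- .alignment_stats(p, s, scoring$matrix, nchar(q))
  structure(c(list(score = Biostrings::score(aln)), st,
              list(query_id = if (inherits(query, "protein_record")) query$id else NA_character_,
                   target_id = if (inherits(target, "protein_record")) target$id else NA_character_)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "local alignment: score %.1f over %d columns; id %.1f%%, sim %.1f%%, query coverage %.2f\n",
    x$score, x$aligned_length, x$percent_identity, x$percent_similarity,
    x$query_coverage))
  invisible(x)
}
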