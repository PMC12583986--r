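#' Gap policy for cluster building
#'
#' Two pathway genes join the same candidate cluster when they lie on the
#' same contig and either at most \code{G} non-pathway genes lie between them
#' or their locus-tag numeric suffixes differ by at most \code{L} (locus tags
#' typically step by 5 per gene, so the default \code{L = 50} spans about ten
#' genes). Small non-pathway insertions inside clusters are thereby
#' tolerated.
#'
#' @param G maximum intervening non-pathway gene count (default 5)
#' @param L maximum locus-tag numeric gap (default 50)
#' @return a \code{gap_policy} list
#' @export
gap_policy <- function(G = 5, L = 50) {
  stopifnot(G >= 0, L >= 0)
  structure(list(G = G, L = L), class = "gap_policy")
}

.locus_suffix <- function(tags) {
  m <- regmatches(tags, regexpr("[0-9]+$", tags))
  out <- rep(NA_real_, length(tags))
  has <- grepl("[0-9]+$", tags)
  out[has] <- as.numeric(m)
  out
}

#' Group accepted gene hits into candidate biosynthetic gene clusters
#'
#' Maps each accepted hit to its genome feature by locus tag, sorts pathway
#' genes along each contig, and chains neighbouring pathway genes under the
#' \code{\link{gap_policy}} adjacency rule; clusters are maximal under this
#' relation. The result is independent of the input hit order and idempotent.
#'
#' @param hits a \code{gene_hits} data frame (only accepted hits are used)
#' @param features data frame with columns \code{contig}, \code{start},
#'   \code{end}, \code{strand}, \code{locus_tag} (1-based inclusive
#'   coordinates), one row per annotated gene
#' @param policy a \code{\link{gap_policy}}
#' @return list of \code{gene_cluster} objects, each with \code{genome_id},
#'   \code{members} (hit/feature table ordered by start), \code{span_bp},
#'   \code{intervening} (non-pathway gene counts per internal gap) and
#'   \code{fragment_index}
#' @export
cluster_hits <- function(hits, features, policy = gap_policy()) {
  acc <- accepted_hits(hits)
  if (nrow(acc) == 0L) return(list())
  acc <- acc[order(acc$family_id, acc$protein_id), , drop = FALSE]
  idx <- match(acc$protein_id, features$locus_tag)
  if (anyNA(idx))
    stop("no genome feature for accepted hit(s): ",
         paste(acc$protein_id[is.na(idx)], collapse = ", "))
  mem <- cbind(acc, features[idx, c("contig", "start", "end", "strand"),
                             drop = FALSE])
  mem$locus_num <- .locus_suffix(acc$protein_id)
  features <- features[order(features$contig, features$start), , drop = FALSE]

  clusters <- list()
  for (ctg in unique(mem$contig)) {
    cm <- mem[mem$contig == ctg, , drop = FALSE]
    cm <- cm[order(cm$start, cm$protein_id), , drop = FALSE]
    cf <- features[features$contig == ctg, , drop = FALSE]
    is_path <- cf$locus_tag %in% cm$protein_id
    grp <- 1L
    gid <- integer(nrow(cm))
    gaps <- numeric(0)
    gid[1] <- grp
    if (nrow(cm) > 1) for (k in 2:nrow(cm)) {
      i1 <- which(cf$locus_tag == cm$protein_id[k - 1])[1]
      i2 <- which(cf$locus_tag == cm$protein_id[k])[1]
      between <- cf[seq(min(i1, i2) + 1, length.out = max(abs(i2 - i1) - 1, 0)), ,
                    drop = FALSE]
      n_interv <- sum(!between$locus_tag %in% cm$protein_id)
      locus_ok <- !is.na(cm$locus_num[k]) && !is.na(cm$locus_num[k - 1]) &&
        abs(cm$locus_num[k] - cm$locus_num[k - 1]) <= policy$L
      joined <- n_interv <= policy$G || locus_ok
      if (!joined) grp <- grp + 1L
      gid[k] <- grp
      gaps[k - 1] <- n_interv
    }
    for (g in unique(gid)) {
      m <- cm[gid == g, , drop = FALSE]
      internal <- if (nrow(m) > 1) gaps[which(gid == g)[-nrow(m)]] else numeric(0)
      clusters[[length(clusters) + 1L]] <- structure(
        list(genome_id = m$genome_id[1], members = m,
             span_bp = max(m$end) - min(m$start) + 1L,
             intervening = internal, fragment_index = NA_integer_),
        class = "gene_cluster")
    }
  }
  # deterministic genome order: by contig then start of first member
  ord <- order(vapply(clusters, function(cl) cl$members$contig[1], character(1)),
               vapply(clusters, function(cl) min(cl$members$start), numeric(1)))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$fragment_index <- i
  clusters
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat("gene cluster (fragment ", x$fragment_index, ") on ",
      x$members$contig[1], ": ",
      paste(x$members$family_id, collapse = "-"),
      " [", x$span_bp, " bp]\n", sep = "")
  invisible(x)
}

#' Classify cluster architecture against the canonical gene order
#'
#' Assigns an architecture class and scores how well the observed genomic
#' order of canonical cluster genes agrees with the canonical A-R order
#' (Kendall rank correlation over the genes present). Each cluster fragment
#' is orientation-normalized by its majority strand before scoring, so a
#' whole-cluster strand flip (a minus-strand operon) scores the same as the
#' forward layout. Genes outside the canonical cluster roster (e.g.
#' \code{hpnO}, \code{hpnP}, \code{hpnR}) are never scored.
#'
#' @param clusters output of \code{\link{cluster_hits}}
#' @param catalog a \code{\link{load_gene_catalog}} catalog
#' @return an \code{architecture_report} list: \code{n_fragments},
#'   \code{class} (\code{contiguous}, \code{fragmented}, \code{dispersed},
#'   \code{absent}), \code{order_concordance}, \code{genes_outside_cluster}
#' @export
classify_architecture <- function(clusters, catalog = load_gene_catalog()) {
  canon <- catalog$family_id[catalog$canonical_bgc_member]
  canon_rank <- stats::setNames(catalog$canonical_order[catalog$canonical_bgc_member],
                                canon)
  core <- lapply(clusters, function(cl)
    cl$members[cl$members$family_id %in% canon, , drop = FALSE])
  n_core <- vapply(core, nrow, integer(1))
  if (length(clusters) == 0L || sum(n_core) == 0L)
    return(structure(list(n_fragments = 0L, class = "absent",
                          order_concordance = NA_real_,
                          genes_outside_cluster = character(0)),
                     class = "architecture_report"))
  frags <- which(n_core > 0)
  n_fragments <- length(frags)

  observed <- unlist(lapply(frags, function(i) {
    m <- core[[i]][order(core[[i]]$start), , drop = FALSE]
    fams <- m$family_id
    if (mean(m$strand == "-") > 0.5) fams <- rev(fams)
    fams
  }))
  conc <- if (length(observed) >= 2)
    suppressWarnings(stats::cor(seq_along(observed),
                                as.numeric(canon_rank[observed]),
                                method = "kendall"))
  else NA_real_

  outside <- if (any(n_core >= 2))
    unlist(lapply(frags[n_core[frags] == 1], function(i) core[[i]]$family_id))
  else character(0)
  cls <- if (n_fragments == 1L) "contiguous"
         else if (any(n_core >= 2)) "fragmented"
         else "dispersed"
  structure(list(n_fragments = n_fragments, class = cls,
                 order_concordance = conc,
                 genes_outside_cluster = as.character(outside %||% character(0))),
            class = "architecture_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.architecture_report <- function(x, ...) {
  cat("hpn cluster architecture: ", x$class, " (", x$n_fragments,
      " fragment(s)); order concordance ",
      ifelse(is.na(x$order_concordance), "NA",
             sprintf("%.2f", x$order_concordance)), "\n", sep = "")
  invisible(x)
}
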