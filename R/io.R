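#' Read a protein FASTA file
#'
#' Light structural validation (with line numbers) happens before parsing so
#' that malformed files fail with a useful message; duplicate record ids are
#' rejected.
#'
#' @param path FASTA path
#' @return an \code{AAStringSet} named by record id (first word of header)
#' @export
read_proteome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stop("empty FASTA file: ", path)
  first <- nonempty[1]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA at line ", first, ": expected a '>' header")
  prev_header <- FALSE
  for (i in nonempty) {
    if (startsWith(lines[i], ">")) {
      if (prev_header)
        stop("malformed FASTA at line ", i, ": header without sequence")
      prev_header <- TRUE
    } else prev_header <- FALSE
  }
  if (prev_header)
    stop("malformed FASTA at line ", nonempty[length(nonempty)],
         ": header without sequence")
  set <- Biostrings::readAAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(set)[duplicated(names(set))]), collapse = ", "))
  set
}

#' Write a proteome FASTA file
#'
#' @param proteome an \code{AAStringSet}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_proteome <- function(proteome, path) {
  Biostrings::writeXStringSet(.as_aastringset(proteome), path)
  invisible(path)
}

#' Read a gene feature table (GFF3 or TSV)
#'
#' GFF3 files are read with \pkg{rtracklayer}; gene and CDS rows with a
#' \code{locus_tag} attribute become features (other attributes are
#' ignored). The TSV dialect expects a header with columns \code{contig},
#' \code{start}, \code{end}, \code{strand}, \code{locus_tag}. Coordinates
#' are 1-based inclusive in both dialects.
#'
#' @param path input path; dialect chosen by extension (\code{.gff},
#'   \code{.gff3} vs anything else) unless \code{format} is given
#' @param format \code{"auto"}, \code{"gff3"} or \code{"tsv"}
#' @return data frame with columns \code{contig}, \code{start}, \code{end},
#'   \code{strand}, \code{locus_tag}
#' @export
read_features <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") {
    g <- rtracklayer::readGFF(path)
    g <- as.data.frame(g)
    g <- g[g$type %in% c("gene", "CDS"), , drop = FALSE]
    if (!"locus_tag" %in% names(g))
      warning("no locus_tag attribute in ", path,
              "; clustering will fall back to coordinates only")
    out <- data.frame(contig = as.character(g$seqid),
                      start = as.integer(g$start),
                      end = as.integer(g$end),
                      strand = as.character(g$strand),
                      locus_tag = if ("locus_tag" %in% names(g))
                        as.character(g$locus_tag) else NA_character_,
                      stringsAsFactors = FALSE)
    # one feature per locus tag (gene + CDS rows collapse)
    out <- out[!duplicated(out[c("contig", "start", "end", "locus_tag")]), ,
               drop = FALSE]
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "start", "end", "strand", "locus_tag")
    if (!all(need %in% names(tab)))
      stop("feature TSV must have columns: ", paste(need, collapse = ", "))
    out <- tab[need]
    out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  }
  bad <- which(out$start > out$end)
  if (length(bad))
    stop("start > end in feature row(s) ",
         paste(bad, collapse = ", "), " (locus ",
         paste(out$locus_tag[bad], collapse = ", "), ")")
  if (!all(out$strand %in% c("+", "-", "*")))
    stop("strand must be '+' or '-'")
  rownames(out) <- NULL
  out
}

#' Write a feature table in the TSV dialect
#'
#' @param features feature data frame
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Plain-text (YAML) serializable settings bundle for a pipeline run.
#' Unknown keys are rejected on read so that typos fail loudly.
#'
#' @param proteome,features input paths (optional)
#' @param threshold_overrides named list/vector of per-family similarity
#'   thresholds
#' @param gap_G,gap_L cluster gap policy settings
#' @param coverage_floor query-coverage floor for hit acceptance
#' @param tolerance cross-platform consistency tolerance (percentage points)
#' @param output_dir output directory
#' @param seed integer seed
#' @param verbosity 0..2
#' @return a \code{run_config} list
#' @export
run_config <- function(proteome = NULL, features = NULL,
                       threshold_overrides = NULL,
                       gap_G = 5, gap_L = 50, coverage_floor = 0.7,
                       tolerance = 15, output_dir = ".", seed = 1L,
                       verbosity = 1L) {
  structure(list(proteome = proteome, features = features,
                 threshold_overrides = threshold_overrides,
                 gap_G = gap_G, gap_L = gap_L,
                 coverage_floor = coverage_floor, tolerance = tolerance,
                 output_dir = output_dir, seed = as.integer(seed),
                 verbosity = as.integer(verbosity)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a \code{run_config}
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown run_config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Re-run the fixture-derived reference computations
#'
#' Recomputes, from the packaged fixture tables, the survey percentages,
#' panel counts, methylation statistics and concordance counts, and compares
#' each with its packaged reference value. All values are computed at call
#' time; nothing is looked up.
#'
#' @return data frame with columns \code{check}, \code{expected},
#'   \code{observed}, \code{pass}
#' @export
#' @examples
#' rep <- reproduce()
#' all(rep$pass)
reproduce <- function() {
  checks <- reference_checks()
  df <- data.frame(check = names(checks),
                   expected = vapply(checks, `[[`, numeric(1), "expected"),
                   observed = vapply(checks, `[[`, numeric(1), "observed"),
                   stringsAsFactors = FALSE)
  df$pass <- abs(df$expected - df$observed) <=
    vapply(checks, `[[`, numeric(1), "tol")
  rownames(df) <- NULL
  df
}

# named list of check -> expected (printed reference value), observed
# (recomputed), tol (half printed precision)
reference_checks <- function() {
  t2 <- load_fixture("survey_T2")
  genus <- survey_fractions(
    data.frame(taxon = t2$order, n_total = t2$genera_total,
               n_with_gene = t2$genera_with_shc), "genus")
  genome <- survey_fractions(
    data.frame(taxon = t2$order, n_total = t2$genomes_total,
               n_with_gene = t2$genomes_with_shc), "genome")
  pick <- function(tab, ord) tab$fraction[tab$taxon == ord]
  pc <- panel_counts()
  panel <- build_concordance_panel()
  conc <- concordance_table(panel$gene, panel$product)
  shc_row <- conc[conc$feature == "shc", ]
  g2 <- load_fixture("genotype_F2")

  chk <- function(expected, observed, tol = 0.5)
    list(expected = expected, observed = observed, tol = tol)
  list(
    hyphomicrobiales_genera_shc_pct = chk(27, pick(genus, "Hyphomicrobiales")),
    rhodospirillales_genera_shc_pct = chk(69, pick(genus, "Rhodospirillales")),
    sphingomonadales_genera_shc_pct = chk(18, pick(genus, "Sphingomonadales")),
    hyphomicrobiales_genomes_shc_pct = chk(30, pick(genome, "Hyphomicrobiales")),
    species_without_rohmer_products = chk(9, pc$n_no_rohmer_products, 0),
    species_without_c30_hopanoids = chk(22, pc$n_no_c30_hopanoids, 0),
    species_without_intact_bhpds = chk(6, pc$n_no_intact_bhpds, 0),
    tetrahymanol_producers = chk(3, pc$n_tetrahymanol_producers, 0),
    max_s22_fraction = chk(0.79, pc$max_s22_fraction, 0.005),
    me2_c32_mean = chk(1.0, pc$me2_c32$mean, 0.05),
    me2_c32_max = chk(5.1, pc$me2_c32$max, 0.05),
    me2_hop17_21_mean = chk(62, pc$me2_hop17_21_mean, 0.5),
    me2_tetrahymanol_mean = chk(55, pc$me2_tetrahymanol_mean, 0.5),
    species_with_shc = chk(49, sum(g2$shc == "present"), 0),
    shc_positive_without_bhpds = chk(1, shc_row$gene_pos_prod_neg, 0))
}
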