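# Independent brute-force oracles used to cross-check the implementation.

# Smith-Waterman local alignment score by straightforward Gotoh dynamic
# programming (affine gaps: a gap of length L costs open + extend * L).
# Written independently of the package's alignment path.
sw_score_oracle <- function(q, t, sub, gap_open = 11, gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  ta <- strsplit(t, "")[[1]]
  n <- length(qa); m <- length(ta)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (move along target)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in target
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + sub[qa[i - 1], ta[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Kendall rank concordance by explicit pair enumeration.
kendall_oracle <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  conc <- 0; disc <- 0
  for (i in seq_len(length(x) - 1)) for (j in (i + 1):length(x)) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(length(x), 2)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# all sequences of the given length over an alphabet
enumerate_peptides <- function(len, alphabet) {
  if (len == 0) return(character(0))
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), len), stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

random_peptide <- function(len, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# fabricate an accepted gene_hits row set for clustering tests (no alignment)
fake_hits <- function(family_ids, locus_tags, genome_id = "g") {
  data.frame(genome_id = rep_len(genome_id, length(family_ids)),
             family_id = family_ids,
             protein_id = locus_tags,
             score = rep_len(100, length(family_ids)),
             percent_similarity = rep_len(90, length(family_ids)),
             query_coverage = rep_len(1, length(family_ids)),
             call = rep_len("accepted", length(family_ids)),
             stringsAsFactors = FALSE)
}

# feature table builder: genes laid out left to right on one contig
fake_features <- function(locus_tags, contig = "c1", strand = "+",
                          start0 = 1, len = 900, gap = 100) {
  n <- length(locus_tags)
  starts <- start0 + (seq_len(n) - 1) * (len + gap)
  data.frame(contig = contig, start = starts, end = starts + len - 1,
             strand = rep_len(strand, n), locus_tag = locus_tags,
             stringsAsFactors = FALSE)
}

# the full MEP backbone used by several genotype tests
mep_families <- c("dxs", "dxr", "ispDF", "ispE", "ispG", "ispH", "ispA")

presence_from <- function(present, catalog = load_gene_catalog()) {
  stats::setNames(ifelse(catalog$family_id %in% present, "present", "absent"),
                  catalog$family_id)
}
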