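#' Survey fractions over gene-hit count tables
#'
#' Computes, per taxon row, the percentage of units (genera or genomes)
#' carrying a gene. Rendering follows report style (whole numbers at >= 10,
#' one decimal below); the numeric column keeps full precision.
#'
#' @param counts data frame with columns \code{taxon}, \code{n_total},
#'   \code{n_with_gene}
#' @param level \code{"genus"} or \code{"genome"}
#' @return a \code{survey_stats} data frame with added \code{fraction}
#'   (percent), \code{fraction_rendered} and \code{level}
#' @export
#' @examples
#' survey_fractions(data.frame(taxon = "Hyphomicrobiales",
#'                             n_total = 171, n_with_gene = 46), "genus")
survey_fractions <- function(counts, level = c("genus", "genome")) {
  level <- match.arg(level)
  stopifnot(all(c("taxon", "n_total", "n_with_gene") %in% names(counts)))
  if (any(counts$n_total <= 0))
    stop("n_total must be positive for every row")
  if (any(counts$n_with_gene < 0 | counts$n_with_gene > counts$n_total))
    stop("n_with_gene must lie in [0, n_total]")
  out <- counts
  out$fraction <- 100 * counts$n_with_gene / counts$n_total
  out$fraction_rendered <- render_percent(out$fraction)
  out$level <- level
  structure(out, class = c("survey_stats", "data.frame"))
}

#' Genotype-versus-phenotype concordance table
#'
#' Crosses, per feature, a gene-side call (from genotypes or predictions)
#' with a product-side call (from lipid measurements) over a matched species
#' panel, and reports the 2x2 outcome counts with positive and negative
#' predictive values. Species with an unknown state on either side fall into
#' the \code{unknown} cell: a gene present without detectable product is a
#' recorded outcome, not an error, because predictions are capacities.
#'
#' @param gene data frame of logical/NA gene-side calls, one row per
#'   species (rownames or a \code{species} column), one column per feature
#' @param product data frame of logical/NA product-side calls with the same
#'   species and features
#' @return a \code{concordance_report} data frame with one row per feature:
#'   counts \code{gene_pos_prod_pos}, \code{gene_pos_prod_neg},
#'   \code{gene_neg_prod_pos}, \code{gene_neg_prod_neg}, \code{unknown},
#'   \code{ppv}, \code{npv}
#' @export
concordance_table <- function(gene, product) {
  if ("species" %in% names(gene)) {
    rownames(gene) <- gene$species; gene$species <- NULL
  }
  if ("species" %in% names(product)) {
    rownames(product) <- product$species; product$species <- NULL
  }
  miss <- c(setdiff(rownames(gene), rownames(product)),
            setdiff(rownames(product), rownames(gene)))
  if (length(miss))
    stop("unmatched species between gene and product panels: ",
         paste(unique(miss), collapse = ", "))
  product <- product[rownames(gene), , drop = FALSE]
  feats <- intersect(names(gene), names(product))
  if (!length(feats)) stop("no shared features between panels")
  rows <- lapply(feats, function(f) {
    g <- gene[[f]]; p <- product[[f]]
    unknown <- is.na(g) | is.na(p)
    data.frame(feature = f,
               gene_pos_prod_pos = sum(!unknown & g & p),
               gene_pos_prod_neg = sum(!unknown & g & !p),
               gene_neg_prod_pos = sum(!unknown & !g & p),
               gene_neg_prod_neg = sum(!unknown & !g & !p),
               unknown = sum(unknown), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ppv <- with(out, ifelse(gene_pos_prod_pos + gene_pos_prod_neg > 0,
                              gene_pos_prod_pos /
                                (gene_pos_prod_pos + gene_pos_prod_neg), NA))
  out$npv <- with(out, ifelse(gene_neg_prod_neg + gene_neg_prod_pos > 0,
                              gene_neg_prod_neg /
                                (gene_neg_prod_neg + gene_neg_prod_pos), NA))
  structure(out, class = c("concordance_report", "data.frame"),
            n_species = nrow(gene))
}

#' Build the gene/product concordance panel from the packaged fixtures
#'
#' Gene side: narrated per-species gene presence (three-valued; unknown
#' propagates to the unknown cell). Product side, per species: BHPDs counted
#' as produced when intact BHPDs were detected or Rohmer degradation products
#' were obtained; C30 hopanoids and tetrahymanol from their concentration
#' columns; ring-A methylation products from the MRM degree-of-methylation
#' table, complemented by the narrated LC-only observations for the two
#' species not analysed by the Rohmer method.
#'
#' @param detection_floor minimum degree of methylation counted as product
#'   (default 0.01 percent, the MRM detection threshold)
#' @return list with data frames \code{gene} and \code{product} (features:
#'   \code{shc}, \code{bhpd_any}, \code{c30_hopanoids}, \code{tetrahymanol},
#'   \code{methyl_2}, \code{methyl_3}) ready for
#'   \code{\link{concordance_table}}
#' @export
build_concordance_panel <- function(detection_floor = 0.01) {
  g2 <- load_fixture("genotype_F2")
  t3 <- load_fixture("rohmer_T3")
  t4 <- load_fixture("methylation_T4")
  notes <- utils::read.csv(system.file("extdata", "phenotype_notes.csv",
                                       package = "hopanotype", mustWork = TRUE))
  stopifnot(identical(sort(g2$species), sort(t3$species)))
  sp <- g2$species
  tri <- function(x) ifelse(x == "present", TRUE,
                            ifelse(x == "absent", FALSE, NA))
  gene <- data.frame(
    species = sp,
    shc = tri(g2$shc),
    bhpd_any = tri(g2$shc) & tri(g2$hpnH),
    c30_hopanoids = tri(g2$shc),
    tetrahymanol = tri(g2$ths),
    methyl_2 = tri(g2$hpnP),
    methyl_3 = tri(g2$hpnR), stringsAsFactors = FALSE)

  i3 <- match(sp, t3$species)
  num_or_zero <- function(col) {
    v <- t3[[col]][i3]
    bd <- fixture_is_bd(t3, col)[i3]
    ifelse(bd, 0, v)  # below-detection counts as product-negative; n.d. stays NA
  }
  sum_bhpds <- num_or_zero("sum_bhpds")
  n_bhpds <- t3$n_bhpds[i3]
  bhpd_prod <- (n_bhpds > 0) |
    (!is.na(sum_bhpds) & sum_bhpds > 0)
  c30 <- num_or_zero("hop22_29_ene") + num_or_zero("hop17_21_ene") +
    num_or_zero("diplopterol")
  th <- num_or_zero("tetrahymanol")

  i4 <- match(sp, t4$species)
  me_any <- function(cols) {
    vals <- sapply(cols, function(cn) {
      v <- rep(0, length(sp))           # species absent from the MRM table: no
      in4 <- !is.na(i4)                 # methylated product was identified
      raw <- t4[[cn]][i4[in4]]
      bd <- fixture_is_bd(t4, cn)[i4[in4]]
      v[in4] <- ifelse(bd, 0, raw)
      v
    })
    rowSums(vals, na.rm = TRUE)
  }
  me2 <- me_any(c("me2_hop22_29_ene", "me2_hop17_21_ene", "me2_diplopterol",
                  "me2_tetrahymanol", "me2_c31_hopanol", "me2_c32_hopanol"))
  me3 <- me_any(c("me3_c31_hopanol", "me3_c32_hopanol"))
  product <- data.frame(
    species = sp,
    shc = bhpd_prod,                    # product side of the shc feature: BHPDs
    bhpd_any = bhpd_prod,
    c30_hopanoids = !is.na(c30) & c30 > 0,
    tetrahymanol = !is.na(th) & th > 0,
    methyl_2 = me2 >= detection_floor,
    methyl_3 = me3 >= detection_floor, stringsAsFactors = FALSE)
  # species not analysed by the Rohmer/MRM route: narrated LC observations
  for (k in seq_len(nrow(notes))) {
    i <- match(notes$species[k], product$species)
    f <- sub("_product$", "", notes$feature[k])
    product[[f]][i] <- switch(notes$value[k], present = TRUE, absent = FALSE, NA)
  }
  nd_c30 <- is.na(c30)
  product$c30_hopanoids[nd_c30] <- NA
  product$tetrahymanol[is.na(th)] <- NA
  list(gene = gene, product = product)
}

#' Derived counts over the packaged panel tables
#'
#' Every count is computed from the fixture tables at call time. Species with
#' not-determined measurements are excluded from the counts whose denominator
#' covers only measured species (Rohmer-derived counts); counts based on the
#' intact-BHPD columns cover all panel species.
#'
#' @param t3 the \code{rohmer_T3} fixture (default: packaged)
#' @param t4 the \code{methylation_T4} fixture (default: packaged)
#' @return a \code{panel_summary} list of named counts and statistics
#' @export
panel_counts <- function(t3 = load_fixture("rohmer_T3"),
                         t4 = load_fixture("methylation_T4")) {
  if (nrow(t3) == 0)
    return(structure(list(
      n_species = 0L, n_measured = 0L, n_no_rohmer_products = 0L,
      n_no_c30_hopanoids = 0L, n_no_intact_bhpds = 0L,
      n_tetrahymanol_producers = 0L, max_s22_fraction = NA_real_,
      me2_c32 = list(n = 0L, mean = NA_real_, max = NA_real_),
      me2_hop17_21_mean = NA_real_, me2_tetrahymanol_mean = NA_real_),
      class = "panel_summary"))
  measured <- !fixture_is_nd(t3, "sum_bhpds")
  no_rohmer <- measured & fixture_is_bd(t3, "sum_bhpds")
  c30_cols <- c("hop22_29_ene", "hop17_21_ene", "diplopterol")
  c30_measured <- !Reduce(`|`, lapply(c30_cols, fixture_is_nd, tab = t3))
  no_c30 <- c30_measured &
    Reduce(`&`, lapply(c30_cols, fixture_is_bd, tab = t3))
  no_intact <- t3$n_bhpds == 0
  th <- ifelse(fixture_is_bd(t3, "tetrahymanol"), 0, t3$tetrahymanol)
  s22 <- t3$s22_pct
  me2c32 <- t4$me2_c32_hopanol[!fixture_is_bd(t4, "me2_c32_hopanol")]
  me2h17 <- t4$me2_hop17_21_ene[!fixture_is_bd(t4, "me2_hop17_21_ene")]
  me2th <- t4$me2_tetrahymanol[!fixture_is_bd(t4, "me2_tetrahymanol")]
  structure(list(
    n_species = nrow(t3),
    n_measured = sum(measured),
    n_no_rohmer_products = sum(no_rohmer),
    n_no_c30_hopanoids = sum(no_c30),
    n_no_intact_bhpds = sum(no_intact),
    n_tetrahymanol_producers = sum(!is.na(th) & th > 0),
    max_s22_fraction = if (all(is.na(s22))) NA_real_
                       else max(s22, na.rm = TRUE) / 100,
    me2_c32 = list(n = length(me2c32), mean = mean(me2c32), max = max(me2c32)),
    me2_hop17_21_mean = mean(me2h17),
    me2_tetrahymanol_mean = mean(me2th)),
    class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("panel summary over", x$n_species, "species (",
      x$n_measured, "measured by Rohmer degradation)\n")
  cat("  without Rohmer products:      ", x$n_no_rohmer_products, "\n")
  cat("  without C30 hopanoids:        ", x$n_no_c30_hopanoids, "\n")
  cat("  without intact BHPDs:         ", x$n_no_intact_bhpds, "\n")
  cat("  tetrahymanol producers:       ", x$n_tetrahymanol_producers, "\n")
  cat("  max 22S/(22S+22R):            ", x$max_s22_fraction, "\n")
  cat(sprintf("  2-Me C32 hopanol: n=%d mean=%.2f max=%.2f\n",
              x$me2_c32$n, x$me2_c32$mean, x$me2_c32$max))
  invisible(x)
}
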