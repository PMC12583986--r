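#' In-silico Rohmer degradation of one BHPD structure
#'
#' Periodate/borohydride (Rohmer) treatment cleaves the BHPD side chain at
#' vicinal diols, yielding a GC-amenable hopanol whose carbon number
#' fingerprints the parent polyol class. The mapping applied here (the rule
#' table mirrors the structural groups of the panel):
#' \itemize{
#'   \item nucleoside side chains carry no free vicinal diol pair -> no
#'     product;
#'   \item anhydro pentols: the internal ether consumes the free diol -> no
#'     product (documented assumption);
#'   \item tetrol-based side chains -> bishomohopan-32-ol (C32). This
#'     includes all CE stages and carbamoyl derivatives on a tetrol base
#'     (their C-35 substitution leaves the 32,33,34-hydroxyls vicinal),
#'     Me-ether/ethenolamine C-35 derivatives, the acyl esters (ester
#'     positions still leave a free vicinal pair), the 35-aminotriol and its
#'     N-acyl amides;
#'   \item pentol-based side chains (incl. CE/carbamoyl on pentol, and
#'     aminotetrol) -> homohopan-31-ol (C31);
#'   \item hexol-based side chains (incl. CE/carbamoyl on hexol) ->
#'     hopan-30-ol (C30).
#' }
#' Ring-A methylation, ring unsaturation and the C-22 configuration pass
#' through the degradation unchanged.
#'
#' @param s a \code{\link{bhpd_structure}}
#' @return a \code{hopanol_product} (\code{carbon_number},
#'   \code{ring_a_methyl}, \code{n_double_bonds}, \code{c22_config}) or
#'   \code{NULL} when the structure yields no product
#' @export
#' @examples
#' degradation_product(bhpd_structure("tetrol", c22_config = "R"))  # C32
#' degradation_product(bhpd_structure("nucleoside", subtype = "adenosyl")) # NULL
degradation_product <- function(s) {
  cn <- switch(s$side_chain_class,
    nucleoside = NA_integer_,
    anhydro_pentol = NA_integer_,
    tetrol = 32L,
    tetrol_derivative = 32L,
    pentol = 31L,
    hexol = 30L,
    ce_series = switch(s$base, tetrol = 32L, pentol = 31L, hexol = 30L),
    carbamoyl = switch(s$base, tetrol = 32L, pentol = 31L, hexol = 30L),
    amino = switch(s$subtype, aminotriol = 32L, aminotetrol = 31L,
                   `N-acyl-amino-acid` = 32L))
  if (is.na(cn)) return(NULL)
  structure(list(carbon_number = cn, ring_a_methyl = s$ring_a_methyl,
                 n_double_bonds = length(s$unsaturation),
                 c22_config = s$c22_config),
            class = "hopanol_product")
}

#' @export
print.hopanol_product <- function(x, ...) {
  nm <- c(`30` = "hopan-30-ol", `31` = "homohopan-31-ol",
          `32` = "bishomohopan-32-ol")[as.character(x$carbon_number)]
  cat(if (x$ring_a_methyl != "none") paste0(x$ring_a_methyl, " "), nm,
      if (x$n_double_bonds > 0) sprintf(" (%d double bond%s)", x$n_double_bonds,
                                        if (x$n_double_bonds > 1) "s" else ""),
      ", 22", x$c22_config, "\n", sep = "")
  invisible(x)
}

#' Predict the GC hopanol profile implied by an LC inventory
#'
#' Maps every structure of a normalized inventory through
#' \code{\link{degradation_product}} and sums abundances by product
#' (carbon number, ring-A methylation, double bonds, C-22 configuration).
#' The profile is renormalized over the structures that yield a product; the
#' abundance mapping to no product is recorded as the invisible fraction
#' (e.g. a pure adenosylhopane producer is 100\% invisible to the Rohmer
#' method).
#'
#' @param inv a \code{\link{normalize_inventory}} inventory
#' @return a \code{gc_profile} data frame (\code{carbon_number},
#'   \code{ring_a_methyl}, \code{n_double_bonds}, \code{c22_config},
#'   \code{share} in percent of visible products) with attribute
#'   \code{invisible_fraction} (percent of inventory abundance)
#' @export
predict_gc_profile <- function(inv) {
  prods <- lapply(inv$structure, degradation_product)
  vis <- !vapply(prods, is.null, logical(1))
  invisible_fraction <- sum(inv$rel_abundance[!vis])
  if (!any(vis)) {
    out <- data.frame(carbon_number = integer(), ring_a_methyl = character(),
                      n_double_bonds = integer(), c22_config = character(),
                      share = numeric(), stringsAsFactors = FALSE)
    return(structure(out, class = c("gc_profile", "data.frame"),
                     invisible_fraction = invisible_fraction))
  }
  tab <- data.frame(
    carbon_number = vapply(prods[vis], `[[`, integer(1), "carbon_number"),
    ring_a_methyl = vapply(prods[vis], `[[`, character(1), "ring_a_methyl"),
    n_double_bonds = vapply(prods[vis], function(p) as.integer(p$n_double_bonds),
                            integer(1)),
    c22_config = vapply(prods[vis], `[[`, character(1), "c22_config"),
    abundance = inv$rel_abundance[vis], stringsAsFactors = FALSE)
  agg <- stats::aggregate(abundance ~ carbon_number + ring_a_methyl +
                            n_double_bonds + c22_config, data = tab, FUN = sum)
  agg$share <- 100 * agg$abundance / sum(agg$abundance)
  agg$abundance <- NULL
  agg <- agg[order(agg$carbon_number, agg$ring_a_methyl,
                   agg$n_double_bonds, agg$c22_config), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("gc_profile", "data.frame"),
            invisible_fraction = invisible_fraction)
}

#' Cross-platform consistency of LC inventory and GC hopanol profile
#'
#' The Rohmer degradation on intact cells provides an independent check on
#' the LC-derived BHPD inventory. This compares (i) the pentol-plus-hexol
#' share, (ii) the unsaturated share and (iii) the 22S fraction between the
#' LC inventory summary and the (predicted or measured) GC hopanol profile;
#' each absolute delta gets a pass flag at the tolerance.
#'
#' @param lc an \code{\link{summarize_inventory}} summary
#' @param gc a \code{\link{predict_gc_profile}} profile
#' @param tolerance pass tolerance in percentage points (default 15)
#' @return a \code{consistency_report} data frame with columns
#'   \code{quantity}, \code{lc}, \code{gc}, \code{delta}, \code{pass}
#' @export
cross_platform_check <- function(lc, gc, tolerance = 15) {
  gc_ph <- if (nrow(gc)) sum(gc$share[gc$carbon_number %in% c(30L, 31L)]) else NA_real_
  gc_uns <- if (nrow(gc)) sum(gc$share[gc$n_double_bonds > 0]) else NA_real_
  known <- gc$c22_config %in% c("R", "S")
  gc_s22 <- if (any(known))
    100 * sum(gc$share[gc$c22_config == "S"]) / sum(gc$share[known])
  else NA_real_
  rows <- data.frame(
    quantity = c("pct_pentol_plus_hexol", "pct_unsaturated", "s22_fraction"),
    lc = c(lc$pct_pentol_plus_hexol, lc$pct_unsaturated, lc$s22_fraction),
    gc = c(gc_ph, gc_uns, gc_s22), stringsAsFactors = FALSE)
  rows$delta <- abs(rows$lc - rows$gc)
  rows$pass <- !is.na(rows$delta) & rows$delta <= tolerance
  structure(rows, class = c("consistency_report", "data.frame"),
            tolerance = tolerance)
}
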