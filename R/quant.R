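#' Internal-standard quantification of a GC peak
#'
#' Semi-quantitative single-point quantification against a co-injected
#' internal standard (n-tricosan-1-ol in the reference protocol: 150 uL of a
#' 0.205 mg/mL solution, i.e. 0.03075 mg per sample), assuming a response
#' factor of 1:
#' \deqn{c = (A_{analyte}/A_{IS}) \times m_{IS} / m_{biomass}}
#'
#' @param analyte_area integrated analyte peak area (>= 0)
#' @param is_area internal-standard peak area (> 0)
#' @param is_mass_mg internal-standard mass added, mg (default 0.03075)
#' @param biomass_g dry cell mass extracted, g (> 0)
#' @return concentration in mg per g dry cells
#' @export
#' @examples
#' quantify_by_internal_standard(1e6, 1e6, biomass_g = 0.030)  # 1.025 mg/g
quantify_by_internal_standard <- function(analyte_area, is_area,
                                          is_mass_mg = 0.03075, biomass_g) {
  stopifnot(analyte_area >= 0)
  if (!is.finite(is_area) || is_area <= 0)
    stop("internal standard area must be > 0")
  if (!is.finite(biomass_g) || biomass_g <= 0)
    stop("biomass must be > 0")
  (analyte_area / is_area) * is_mass_mg / biomass_g
}

#' Degree of ring-A methylation from MRM peak areas
#'
#' \code{100 * methylated / (methylated + unmethylated)}. The two species are
#' read from separate MRM channels (transition to m/z 205 for the ring-A
#' methylated skeleton, to m/z 191 for the unmethylated one), so coelution of
#' the methylated compound with its unmethylated counterpart does not bias
#' the ratio; that is why this function takes areas, not retention windows.
#'
#' @param area_methylated peak area in the methylated (-> m/z 205) channel
#' @param area_unmethylated peak area in the unmethylated (-> m/z 191) channel
#' @return percent methylation in [0, 100]
#' @export
#' @examples
#' methylation_degree(5.1, 94.9)  # 5.1
methylation_degree <- function(area_methylated, area_unmethylated) {
  stopifnot(area_methylated >= 0, area_unmethylated >= 0)
  tot <- area_methylated + area_unmethylated
  if (tot == 0) stop("degree of methylation undefined: both areas are zero")
  100 * area_methylated / tot
}

#' C-22 epimer fraction from peak areas
#'
#' \code{100 * S / (S + R)} for the 22S and 22R epimers of an extended
#' hopanol (e.g. bishomohopan-32-ol after Rohmer degradation).
#'
#' @param area_22S,area_22R epimer peak areas (>= 0, not both zero)
#' @return percent 22S/(22S+22R)
#' @export
epimer_fraction <- function(area_22S, area_22R) {
  stopifnot(area_22S >= 0, area_22R >= 0)
  tot <- area_22S + area_22R
  if (tot == 0) stop("epimer fraction undefined: both areas are zero")
  100 * area_22S / tot
}

#' Normalize raw responses into a relative-abundance inventory
#'
#' @param structures list of \code{\link{bhpd_structure}}
#' @param responses non-negative responses, one per structure, at least one
#'   positive
#' @return a \code{lipid_inventory}: data frame with list-column
#'   \code{structure} and \code{rel_abundance} (percent, summing to 100);
#'   zero-response structures are dropped
#' @export
normalize_inventory <- function(structures, responses) {
  stopifnot(length(structures) == length(responses), all(responses >= 0))
  if (length(responses) == 0 || sum(responses) == 0)
    stop("inventory normalization needs at least one positive response")
  keep <- responses > 0
  structures <- structures[keep]
  responses <- responses[keep]
  inv <- data.frame(
    structure_id = vapply(structures, function(s)
      if (is.na(s$structure_id)) s$side_chain_class else s$structure_id,
      character(1)),
    rel_abundance = 100 * responses / sum(responses),
    stringsAsFactors = FALSE)
  inv$structure <- structures
  structure(inv, class = c("lipid_inventory", "data.frame"))
}

#' @export
print.lipid_inventory <- function(x, ...) {
  cat("lipid inventory:", nrow(x), "BHPDs\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s %s\n", x$structure_id[i],
                render_percent(x$rel_abundance[i])))
  invisible(x)
}

#' Summary statistics of a normalized inventory
#'
#' @param inv a \code{\link{normalize_inventory}} inventory (may be empty)
#' @return an \code{inventory_summary}: \code{n_bhpds},
#'   \code{pct_unsaturated}, \code{pct_pentol_plus_hexol},
#'   \code{pct_by_group} (over the five side-chain groups),
#'   \code{s22_fraction} (percent 22S among structures with known C-22
#'   configuration, \code{NA} if none)
#' @export
summarize_inventory <- function(inv) {
  groups <- c("nucleoside", "polyol", "ce", "carbamoyl", "amino")
  if (is.null(inv) || nrow(inv) == 0)
    return(structure(list(n_bhpds = 0L, pct_unsaturated = 0,
                          pct_pentol_plus_hexol = 0,
                          pct_by_group = stats::setNames(rep(0, 5), groups),
                          s22_fraction = NA_real_),
                     class = "inventory_summary"))
  ab <- inv$rel_abundance
  uns <- vapply(inv$structure, function(s) length(s$unsaturation) > 0, logical(1))
  ph <- vapply(inv$structure, is_pentol_or_hexol_based, logical(1))
  grp <- vapply(inv$structure, structure_group, character(1))
  byg <- vapply(groups, function(g) sum(ab[grp == g]), numeric(1))
  conf <- vapply(inv$structure, function(s) s$c22_config, character(1))
  known <- conf %in% c("R", "S")
  s22 <- if (any(known)) 100 * sum(ab[conf == "S"]) / sum(ab[known]) else NA_real_
  structure(list(n_bhpds = nrow(inv),
                 pct_unsaturated = sum(ab[uns]),
                 pct_pentol_plus_hexol = sum(ab[ph]),
                 pct_by_group = byg,
                 s22_fraction = s22),
            class = "inventory_summary")
}

#' @export
print.inventory_summary <- function(x, ...) {
  cat("inventory summary: ", x$n_bhpds, " BHPDs; unsaturated ",
      render_percent(x$pct_unsaturated), "; pentol+hexol ",
      render_percent(x$pct_pentol_plus_hexol), "\n", sep = "")
  invisible(x)
}

#' Render a percentage in report style
#'
#' Values of 10 or more print as whole numbers, smaller values with one
#' decimal; values below the detection floor render as below-detection.
#' Internal computations always keep full precision -- this helper only
#' formats.
#'
#' @param x percent value
#' @param detection_floor below-detection rendering floor (default 0.01)
#' @return character
#' @export
render_percent <- function(x, detection_floor = 0.01) {
  vapply(x, function(v) {
    if (is.na(v)) "n.d."
    else if (v < detection_floor && v > 0) "<d.l."
    else if (v >= 10) sprintf("%.0f%%", v)
    else sprintf("%.1f%%", v)
  }, character(1))
}
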