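#' BHPD structure constructor
#'
#' Represents one bacteriohopanepolyol derivative as a core (ring-A
#' methylation state) combined with a side-chain class, optional ring
#' unsaturation and the C-22 configuration. The side-chain classes follow the
#' five structural groups used for the culture panel: nucleoside BHPDs;
#' BHT/BHpentol/BHhexol and derivatives; cyclitol ethers (CE) and precursors;
#' carbamoyl BHPDs; and amino BHPDs.
#'
#' @param side_chain_class one of \code{nucleoside}, \code{tetrol},
#'   \code{tetrol_derivative}, \code{pentol}, \code{hexol},
#'   \code{anhydro_pentol}, \code{ce_series}, \code{carbamoyl}, \code{amino}
#' @param subtype required for \code{nucleoside}
#'   (\code{adenosyl}, \code{Me-adenosyl}, \code{diMe-adenosyl},
#'   \code{inosyl}, \code{N-Me-inosyl}), \code{tetrol_derivative}
#'   (\code{Me-ether}, \code{ethenolamine}, \code{monoacyl}, \code{diacyl})
#'   and \code{amino} (\code{aminotriol}, \code{aminotetrol},
#'   \code{N-acyl-amino-acid})
#' @param base polyol base for \code{ce_series} and \code{carbamoyl}
#'   (\code{tetrol}, \code{pentol}, \code{hexol})
#' @param stage CE maturation stage (\code{acetylglucosamine},
#'   \code{glucosamine}, \code{cyclitol}, \code{Me-cyclitol})
#' @param ring_a_methyl \code{none}, \code{2Me} or \code{3Me}
#' @param unsaturation character subset of \code{c("d6", "d11")}
#' @param c22_config \code{R}, \code{S} or \code{unknown}
#' @param structure_id,label,isomer_note optional annotations
#' @return a \code{bhpd_structure}
#' @export
#' @examples
#' bht <- bhpd_structure("tetrol", c22_config = "R")
#' ce  <- bhpd_structure("ce_series", base = "tetrol", stage = "cyclitol")
bhpd_structure <- function(side_chain_class,
                           subtype = NA_character_,
                           base = NA_character_,
                           stage = NA_character_,
                           ring_a_methyl = "none",
                           unsaturation = character(0),
                           c22_config = "unknown",
                           structure_id = NA_character_,
                           label = NA_character_,
                           isomer_note = NA_character_) {
  classes <- c("nucleoside", "tetrol", "tetrol_derivative", "pentol",
               "hexol", "anhydro_pentol", "ce_series", "carbamoyl", "amino")
  if (!side_chain_class %in% classes)
    stop("unknown side_chain_class: ", side_chain_class)
  subtypes <- list(
    nucleoside = c("adenosyl", "Me-adenosyl", "diMe-adenosyl", "inosyl",
                   "N-Me-inosyl"),
    tetrol_derivative = c("Me-ether", "ethenolamine", "monoacyl", "diacyl"),
    amino = c("aminotriol", "aminotetrol", "N-acyl-amino-acid"))
  if (side_chain_class %in% names(subtypes)) {
    if (is.na(subtype) || !subtype %in% subtypes[[side_chain_class]])
      stop(side_chain_class, " requires subtype in: ",
           paste(subtypes[[side_chain_class]], collapse = ", "))
  } else if (!is.na(subtype))
    stop("subtype is not applicable to ", side_chain_class)
  if (side_chain_class %in% c("ce_series", "carbamoyl")) {
    if (is.na(base) || !base %in% c("tetrol", "pentol", "hexol"))
      stop(side_chain_class, " requires base tetrol/pentol/hexol")
  } else if (!is.na(base))
    stop("base is not applicable to ", side_chain_class)
  if (side_chain_class == "ce_series") {
    if (is.na(stage) || !stage %in% c("acetylglucosamine", "glucosamine",
                                      "cyclitol", "Me-cyclitol"))
      stop("ce_series requires stage acetylglucosamine/glucosamine/cyclitol/Me-cyclitol")
  } else if (!is.na(stage))
    stop("stage is not applicable to ", side_chain_class)
  if (!ring_a_methyl %in% c("none", "2Me", "3Me"))
    stop("ring_a_methyl must be none/2Me/3Me")
  unsaturation <- as.character(unsaturation)
  if (!all(unsaturation %in% c("d6", "d11")) || anyDuplicated(unsaturation))
    stop("unsaturation must be a subset of {d6, d11}")
  if (!c22_config %in% c("R", "S", "unknown"))
    stop("c22_config must be R/S/unknown")
  structure(list(structure_id = structure_id, label = label,
                 side_chain_class = side_chain_class, subtype = subtype,
                 base = base, stage = stage, ring_a_methyl = ring_a_methyl,
                 unsaturation = sort(unsaturation), c22_config = c22_config,
                 isomer_note = isomer_note),
            class = "bhpd_structure")
}

#' @export
print.bhpd_structure <- function(x, ...) {
  cat("BHPD",
      if (!is.na(x$structure_id)) paste0("[", x$structure_id, "]"),
      if (!is.na(x$label)) x$label else x$side_chain_class,
      "| core:", x$ring_a_methyl,
      "| unsaturation:",
      if (length(x$unsaturation)) paste(x$unsaturation, collapse = ",") else "none",
      "| C-22:", x$c22_config, "\n")
  invisible(x)
}

#' Side-chain group of a BHPD structure
#'
#' Maps a structure to one of the five structural groups used in inventory
#' summaries.
#'
#' @param s a \code{bhpd_structure}
#' @return one of \code{"nucleoside"}, \code{"polyol"}, \code{"ce"},
#'   \code{"carbamoyl"}, \code{"amino"}
#' @export
structure_group <- function(s) {
  switch(s$side_chain_class,
         nucleoside = "nucleoside",
         tetrol = , tetrol_derivative = , pentol = , hexol = ,
         anhydro_pentol = "polyol",
         ce_series = "ce",
         carbamoyl = "carbamoyl",
         amino = "amino")
}

#' Is the side chain pentol- or hexol-based?
#'
#' Pentol/hexol-based means the free polyols, the anhydro pentol, and the CE
#' and carbamoyl derivatives built on a pentol or hexol base.
#'
#' @param s a \code{bhpd_structure}
#' @return logical
#' @export
is_pentol_or_hexol_based <- function(s) {
  s$side_chain_class %in% c("pentol", "hexol", "anhydro_pentol") ||
    (s$side_chain_class %in% c("ce_series", "carbamoyl") &&
       s$base %in% c("pentol", "hexol"))
}

#' Load the packaged 63-structure BHPD roster
#'
#' The roster reconstructs the identified BHPD structures of the culture
#' panel from the narrative survey; every row constructs a valid
#' \code{\link{bhpd_structure}}. Rows with \code{source == "inferred"} fill
#' gaps where the narrative names a group but not each individual compound.
#'
#' @return named list of \code{bhpd_structure} (names are structure ids)
#' @export
load_structure_roster <- function() {
  path <- system.file("extdata", "bhpd_structures.csv",
                      package = "hopanotype", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    uns <- if (is.na(r$unsaturation) || !nzchar(r$unsaturation)) character(0)
           else strsplit(r$unsaturation, ";")[[1]]
    bhpd_structure(side_chain_class = r$side_chain_class,
                   subtype = if (is.na(r$subtype)) NA_character_ else r$subtype,
                   base = if (is.na(r$base)) NA_character_ else r$base,
                   stage = if (is.na(r$stage)) NA_character_ else r$stage,
                   ring_a_methyl = r$ring_a_methyl,
                   unsaturation = uns,
                   c22_config = r$c22_config,
                   structure_id = r$structure_id, label = r$label,
                   isomer_note = if (is.na(r$isomer_note)) NA_character_
                                 else r$isomer_note)
  })
  stats::setNames(out, tab$structure_id)
}
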