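#' Packaged reference tables for the 54-species culture panel
#'
#' The package ships transcriptions of the printed reference tables for a
#' panel of 54 cultivated Alphaproteobacteria species: the strain roster
#' (\code{strains_T1}), the genome-survey gene counts by order
#' (\code{survey_T2}), Rohmer-degradation concentrations and inventory
#' summaries (\code{rohmer_T3}), GC-MRM degrees of ring-A methylation
#' (\code{methylation_T4}), the narrated per-species gene presence/absence
#' calls (\code{genotype_F2}), and the narrated single-compound lipid
#' inventories (\code{inventory_F3}).
#'
#' Measured-but-below-detection cells and not-determined cells are distinct
#' states: in the CSV files the former are \code{"BD"} and the latter
#' \code{"NA"}. Numeric columns parse both to \code{NA} while the distinction
#' is kept in a parallel character matrix attached as attribute
#' \code{"status"} (values \code{"ok"}, \code{"bd"}, \code{"nd"}); neither
#' marker is ever coerced to zero.
#'
#' @param table_id one of \code{"strains_T1"}, \code{"survey_T2"},
#'   \code{"rohmer_T3"}, \code{"methylation_T4"}, \code{"genotype_F2"},
#'   \code{"inventory_F3"}.
#' @return a data frame of class \code{fixture_table}; measurement columns
#'   carry the \code{"status"} attribute described above.
#' @export
#' @examples
#' t3 <- load_fixture("rohmer_T3")
#' t3[t3$species == "Gluconacetobacter diazotrophicus", "sum_bhpds"]
load_fixture <- function(table_id) {
  files <- c(strains_T1     = "table1_strains.csv",
             survey_T2      = "survey_t2.csv",
             rohmer_T3      = "table3_rohmer.csv",
             methylation_T4 = "table4_methylation.csv",
             genotype_F2    = "genotype_f2.csv",
             inventory_F3   = "inventory_f3.csv")
  if (length(table_id) != 1L || !table_id %in% names(files))
    stop("unknown table_id ", deparse(table_id), "; valid ids: ",
         paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[table_id]], package = "hopanotype",
                      mustWork = TRUE)
  read_fixture_file(path, table_id)
}

# character columns that must never be parsed as numbers
.fixture_id_cols <- c("species", "strain", "dsm_culture", "order", "family",
                      "genome_assembly", "structure_id")

#' Read a fixture-format CSV from an arbitrary path
#'
#' Same parsing as \code{\link{load_fixture}}; exposed so that fixture tables
#' written with \code{\link{write_fixture}} can be read back.
#'
#' @param path CSV path
#' @param table_id label recorded on the result
#' @return a \code{fixture_table}
#' @export
read_fixture_file <- function(path, table_id = basename(path)) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), check.names = FALSE)
  is_meas <- vapply(names(raw), function(cn) {
    x <- raw[[cn]]
    !cn %in% .fixture_id_cols &&
      all(x %in% c("BD", "NA") | !is.na(suppressWarnings(as.numeric(x))))
  }, logical(1))
  meas_cols <- names(raw)[is_meas]
  status <- NULL
  if (length(meas_cols)) {
    status <- vapply(raw[meas_cols], function(x)
      ifelse(x == "BD", "bd", ifelse(x == "NA", "nd", "ok")),
      character(nrow(raw)))
    status <- matrix(status, nrow = nrow(raw),
                     dimnames = list(NULL, meas_cols))
  }
  out <- raw
  for (cn in meas_cols) {
    x <- raw[[cn]]
    x[x %in% c("BD", "NA")] <- NA
    out[[cn]] <- as.numeric(x)
  }
  structure(out, class = c("fixture_table", "data.frame"),
            table_id = table_id, status = status)
}

#' @export
print.fixture_table <- function(x, ...) {
  cat("fixture table '", attr(x, "table_id"), "': ", nrow(x), " rows, ",
      ncol(x), " columns\n", sep = "")
  NextMethod()
}

#' Cell status helpers for fixture tables
#'
#' @param tab a \code{fixture_table} with measurement columns
#' @param column column name
#' @return logical vector along rows: the cell was below the detection limit
#'   (\code{fixture_is_bd}) or not determined (\code{fixture_is_nd})
#' @export
fixture_is_bd <- function(tab, column) {
  st <- attr(tab, "status")
  if (is.null(st) || !column %in% colnames(st))
    stop("no status tracked for column ", column)
  st[, column] == "bd"
}

#' @rdname fixture_is_bd
#' @export
fixture_is_nd <- function(tab, column) {
  st <- attr(tab, "status")
  if (is.null(st) || !column %in% colnames(st))
    stop("no status tracked for column ", column)
  st[, column] == "nd"
}

#' Write a fixture table to CSV
#'
#' Reverses the parsing of \code{\link{load_fixture}}: below-detection cells
#' are written back as \code{"BD"} and not-determined cells as \code{"NA"},
#' so a write-then-read cycle reproduces every cell value and marker.
#'
#' @param tab a \code{fixture_table}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_fixture <- function(tab, path) {
  out <- as.data.frame(tab)
  st <- attr(tab, "status")
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) {
      x <- vapply(out[[cn]], function(v)
        if (is.na(v)) NA_character_
        else format(v, trim = TRUE, scientific = FALSE), character(1))
      if (!is.null(st) && cn %in% colnames(st)) {
        x[st[, cn] == "bd"] <- "BD"
        x[st[, cn] == "nd"] <- "NA"
      }
      x[is.na(x)] <- "NA"
      out[[cn]] <- x
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
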