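#' Bundled parameter tables
#'
#' `vdw_table()` returns the bundled Bondi-style van der Waals radii,
#' `mhp_table()` the atomic hydrophobicity constants (logP-derived units,
#' implicit hydrogens), and `asp_table()` the five-class Eisenberg--McLachlan
#' atomic solvation parameters in cal/(mol A^2).  Each accepts a `file`
#' argument so a user-supplied plain-text table (same columns, tab-separated,
#' `#` comments) can replace the bundled one.
#'
#' @param file Optional path to a replacement table.
#' @return A data frame: `element`/`radius` for radii, `class`/`f` for
#'   hydrophobicity constants, `class`/`asp` for solvation parameters.
#' @name param_tables
NULL

read_param_table <- function(file, required) {
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("parameter table ", file, " lacks column(s): ",
         paste(missing, collapse = ", "))
  tab
}

#' @rdname param_tables
#' @export
vdw_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "vdw_radii.tsv", package = "porescape")
  read_param_table(file, c("element", "radius"))
}

#' @rdname param_tables
#' @export
mhp_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "mhp_classes.tsv", package = "porescape")
  read_param_table(file, c("class", "f"))
}

#' @rdname param_tables
#' @export
asp_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "asp_eisenberg.tsv", package = "porescape")
  read_param_table(file, c("class", "asp"))
}

vdw_lookup <- function(elements, table = vdw_table(), default = 1.7) {
  r <- table$radius[match(toupper(elements), toupper(table$element))]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(elements[unknown]), collapse = ", "),
            "; using default vdW radius ", default, " A")
    r[unknown] <- default
  }
  r
}
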