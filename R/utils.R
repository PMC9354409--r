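# Internal helpers shared across the package.

# Cell values treated as "not detected" when reading tables. Both the ASCII
# hyphen and the en/em dashes occur in published tables.
.missing_markers <- c("-", "\u2013", "\u2014", "", "NA")

#' Chemical classes recognized in compound tables
#'
#' The closed set of compound classes used throughout: esters, alcohols,
#' aldehydes, and a catch-all `other` (aromatic hydrocarbons, alkanes, ...).
#' @export
chem_classes <- c("ester", "alcohol", "aldehyde", "other")

# Canonical compound-name key: case-insensitive, internal whitespace collapsed.
# Deliberately no fuzzy matching - a silent mis-join is worse than a loud miss.
norm_name <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

# Canonicalize threshold units. Accepts the micro sign (U+00B5), Greek mu
# (U+03BC), or a plain "u"; only ug/L and ug/kg are valid.
canon_unit <- function(x) {
  raw <- x
  x <- gsub("\u00b5|\u03bc", "u", trimws(x))
  x <- tolower(x)
  out <- c("ug/l" = "ug/L", "ug/kg" = "ug/kg")[x]
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    abort(paste0(
      "Unknown threshold unit(s): ", paste(bad, collapse = ", "),
      ". Expected ug/L or ug/kg."
    ))
  }
  unname(out)
}

fmt2 <- function(x) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = 2))
}

# Parse a numeric table cell: missing markers -> NA, anything else must be a
# valid non-negative number.
parse_value_cells <- function(x, what = "value") {
  x <- trimws(as.character(x))
  miss <- x %in% .missing_markers | is.na(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    abort(paste0(
      "Non-numeric ", what, " cell(s): ",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  out[miss] <- NA_real_
  out
}

# Read a delimited text file as all-character columns, sniffing comma vs tab.
read_delim_chr <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE, na = character()
  )
}

check_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(paste0("`", what, "` must be a single non-empty string."))
  }
  invisible(x)
}
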