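# Odor detection thresholds: point values, intervals ("a-b"), and approximate
# values ("~x"), with curated carbon-chain homolog brackets for inferring
# unknown ester thresholds.

#' Construct a threshold database
#'
#' A threshold database pairs a table of per-compound detection thresholds
#' with an optional curated bracket map used to infer thresholds of esters
#' that lack a literature value (see [infer_threshold()]).
#'
#' Threshold entries are one of three kinds:
#' * `point` \u2014 a single literature value (`low == high`);
#' * `interval` \u2014 a bracketed range (`low < high`);
#' * `approx` \u2014 a single approximate value (`low == high`), rendered `\u2248x`.
#'
#' Units `ug/L` and `ug/kg` are both accepted and treated as numerically
#' equivalent when scoring (aqueous matrices, density ~ 1 kg/L); this is
#' required to combine aqueous-solution thresholds reported per litre with
#' matrix thresholds reported per kilogram in one ROAV computation.
#'
#' @param entries A data frame with columns `compound`, `kind`, `low`, `high`,
#'   `unit`, and optionally `source`.
#' @param brackets Optional data frame with columns `formula`, `ref_low`,
#'   `ref_high`; `ref_high` may be `NA` for an exact-homolog rule. Reference
#'   compounds must resolve to `point` entries.
#' @return A `threshold_db` object.
#' @export
threshold_db <- function(entries, brackets = NULL) {
  entries <- as_tibble(entries)
  needed <- c("compound", "kind", "low", "high", "unit")
  miss <- setdiff(needed, names(entries))
  if (length(miss)) {
    abort(paste0("Threshold entries lack column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"source" %in% names(entries)) entries$source <- NA_character_
  entries$source[!is.na(entries$source) &
    !nzchar(trimws(entries$source))] <- NA_character_
  entries <- entries[, c(needed, "source")]

  keys <- norm_name(entries$compound)
  if (anyDuplicated(keys)) {
    abort(paste0(
      "Duplicate threshold compound(s): ",
      paste(unique(entries$compound[duplicated(keys)]), collapse = ", ")
    ))
  }
  if (!all(entries$kind %in% c("point", "interval", "approx"))) {
    abort("Threshold `kind` must be point, interval, or approx.")
  }
  if (any(!is.finite(entries$low) | !is.finite(entries$high) |
    entries$low <= 0 | entries$high <= 0)) {
    abort("Thresholds must be positive finite numbers.")
  }
  if (any(entries$low > entries$high)) {
    bad <- entries$compound[entries$low > entries$high]
    abort(paste0(
      "Inverted threshold interval for: ", paste(bad, collapse = ", ")
    ))
  }
  pt <- entries$kind %in% c("point", "approx")
  if (any(entries$low[pt] != entries$high[pt])) {
    abort("point/approx entries must have low == high.")
  }
  entries$unit <- canon_unit(entries$unit)

  if (!is.null(brackets)) {
    brackets <- as_tibble(brackets)
    if (!all(c("formula", "ref_low") %in% names(brackets))) {
      abort("Bracket map needs columns `formula` and `ref_low`.")
    }
    if (!"ref_high" %in% names(brackets)) brackets$ref_high <- NA_character_
    brackets$ref_high[!is.na(brackets$ref_high) &
      !nzchar(trimws(brackets$ref_high))] <- NA_character_
    if (anyDuplicated(brackets$formula)) {
      abort("Duplicate formula(s) in bracket map.")
    }
    refs <- stats::na.omit(c(brackets$ref_low, brackets$ref_high))
    hit <- match(norm_name(refs), keys)
    if (anyNA(hit)) {
      abort(paste0(
        "Bracket reference(s) not in threshold entries: ",
        paste(unique(refs[is.na(hit)]), collapse = ", ")
      ))
    }
    if (!all(entries$kind[hit] == "point")) {
      abort("Bracket references must resolve to point-threshold entries.")
    }
  } else {
    brackets <- tibble(
      formula = character(), ref_low = character(), ref_high = character()
    )
  }

  structure(
    list(entries = entries, brackets = brackets),
    class = "threshold_db"
  )
}

#' @export
print.threshold_db <- function(x, ...) {
  cat(
    "# Threshold database: ", nrow(x$entries), " entries, ",
    nrow(x$brackets), " curated bracket(s)\n",
    sep = ""
  )
  print(x$entries, ...)
  invisible(x)
}

#' Parse threshold strings
#'
#' Accepts point values (`"3"`), intervals (`"3-5"`, with ASCII hyphen or en
#' dash), and approximate values (`"~2.2"` or `"\u22482.2"`).
#'
#' @param x Character vector of threshold strings.
#' @return A tibble with columns `kind`, `low`, `high`.
#' @export
parse_threshold <- function(x) {
  one <- function(s) {
    s0 <- trimws(s)
    if (grepl("^[~\u2248]", s0)) {
      v <- suppressWarnings(as.numeric(sub("^[~\u2248]\\s*", "", s0)))
      if (is.na(v)) abort(paste0("Cannot parse threshold: ", s))
      return(tibble(kind = "approx", low = v, high = v))
    }
    parts <- strsplit(s0, "\\s*[-\u2013\u2014]\\s*")[[1]]
    if (length(parts) == 2L) {
      lo <- suppressWarnings(as.numeric(parts[1]))
      hi <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(lo) || is.na(hi)) abort(paste0("Cannot parse threshold: ", s))
      if (lo > hi) abort(paste0("Inverted threshold interval: ", s))
      return(tibble(kind = "interval", low = lo, high = hi))
    }
    v <- suppressWarnings(as.numeric(s0))
    if (is.na(v)) abort(paste0("Cannot parse threshold: ", s))
    tibble(kind = "point", low = v, high = v)
  }
  dplyr::bind_rows(lapply(x, one))
}

#' Read a threshold database from CSV
#'
#' The threshold file has columns `compound,threshold,unit,source` with the
#' syntaxes understood by [parse_threshold()]. An optional bracket file has
#' columns `formula,ref_low,ref_high` (empty `ref_high` means the unknown
#' ester's threshold is taken as approximately equal to `ref_low`'s).
#'
#' @param path Threshold CSV path.
#' @param bracket_path Optional curated bracket CSV path.
#' @return A `threshold_db`.
#' @export
read_threshold_db <- function(path, bracket_path = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read_delim_chr(path)
  need <- c("compound", "threshold", "unit")
  if (!all(need %in% names(raw))) {
    abort("Threshold CSV needs columns compound, threshold, unit.")
  }
  parsed <- parse_threshold(raw$threshold)
  entries <- tibble(
    compound = raw$compound,
    kind = parsed$kind, low = parsed$low, high = parsed$high,
    unit = raw$unit,
    source = if ("source" %in% names(raw)) raw$source else NA_character_
  )
  brackets <- NULL
  if (!is.null(bracket_path)) {
    if (!file.exists(bracket_path)) {
      abort(paste0("File not found: ", bracket_path))
    }
    brackets <- read_delim_chr(bracket_path)
  }
  threshold_db(entries, brackets)
}

#' Write a threshold database back to CSV
#'
#' Round-trips all three threshold syntaxes (point, `a\u2013b` interval, `\u2248x`).
#'
#' @param db A `threshold_db`.
#' @param path Output CSV path for the entries.
#' @param bracket_path Optional output CSV path for the bracket map.
#' @return `path`, invisibly.
#' @export
write_threshold_db <- function(db, path, bracket_path = NULL) {
  stopifnot(inherits(db, "threshold_db"))
  e <- db$entries
  num <- function(v) format(v, trim = TRUE, scientific = FALSE, digits = 15)
  thr <- dplyr::case_when(
    e$kind == "interval" ~ paste0(num(e$low), "\u2013", num(e$high)),
    e$kind == "approx" ~ paste0("\u2248", num(e$low)),
    TRUE ~ num(e$low)
  )
  readr::write_csv(
    tibble(
      compound = e$compound, threshold = thr, unit = e$unit, source = e$source
    ),
    path,
    progress = FALSE, na = ""
  )
  if (!is.null(bracket_path)) {
    readr::write_csv(db$brackets, bracket_path, progress = FALSE, na = "")
  }
  invisible(path)
}

#' Look up a compound's detection threshold
#'
#' Matching is exact after case folding and whitespace collapsing; there is no
#' fuzzy matching. `NULL` means "no detection threshold known".
#'
#' @param db A `threshold_db`.
#' @param compound Compound name.
#' @return A one-row tibble (`compound`, `kind`, `low`, `high`, `unit`,
#'   `source`) or `NULL`.
#' @export
lookup_threshold <- function(db, compound) {
  stopifnot(inherits(db, "threshold_db"))
  check_scalar_string(compound, "compound")
  i <- match(norm_name(compound), norm_name(db$entries$compound))
  if (is.na(i)) {
    return(NULL)
  }
  db$entries[i, ]
}

#' Dimensionless threshold magnitude(s)
#'
#' `ug/kg` and `ug/L` are treated as numerically equivalent (aqueous matrix,
#' density ~ 1), so the magnitudes pass through unchanged. Kept as an explicit
#' step so the unit convention is auditable.
#'
#' @param entry A one-row threshold entry (from [lookup_threshold()] or
#'   [infer_threshold()]).
#' @return Named numeric vector `c(low = , high = )`.
#' @export
normalize_threshold <- function(entry) {
  stopifnot(is.data.frame(entry), nrow(entry) == 1L)
  canon_unit(entry$unit) # validates
  c(low = entry$low, high = entry$high)
}

#' Infer an unknown ester threshold from curated homolog brackets
#'
#' Short-chain ester detection thresholds vary systematically with carbon
#' chain length, so the threshold of an ester without a literature value can
#' be bracketed between those of structurally adjacent esters. Because the
#' choice of reference homologs is a judgement call (structural analogy, not
#' just carbon count), the bracket map is curated, not computed: formulas
#' absent from the map are refused with a `roav_no_bracket` error rather than
#' guessed.
#'
#' An exact-homolog rule (`ref_high` empty) yields an `approx` entry equal to
#' the reference threshold; a two-reference rule yields an `interval` entry
#' spanning the two reference thresholds.
#'
#' @param db A `threshold_db` whose bracket map contains `formula`.
#' @param formula Molecular formula text, e.g. `"C6H10O2"`.
#' @return A one-row tibble like a threshold entry (`source = "inferred"`).
#' @export
infer_threshold <- function(db, formula) {
  stopifnot(inherits(db, "threshold_db"))
  check_scalar_string(formula, "formula")
  i <- match(formula, db$brackets$formula)
  if (is.na(i)) {
    abort(
      paste0("No curated threshold bracket for formula ", formula, "."),
      class = "roav_no_bracket"
    )
  }
  b <- db$brackets[i, ]
  lo_ref <- lookup_threshold(db, b$ref_low)
  if (is.na(b$ref_high)) {
    return(tibble(
      compound = NA_character_, kind = "approx",
      low = lo_ref$low, high = lo_ref$low,
      unit = lo_ref$unit, source = "inferred"
    ))
  }
  hi_ref <- lookup_threshold(db, b$ref_high)
  if (lo_ref$unit != hi_ref$unit) {
    abort("Bracket references use different units.")
  }
  vals <- range(lo_ref$low, hi_ref$low)
  tibble(
    compound = NA_character_, kind = "interval",
    low = vals[1], high = vals[2],
    unit = lo_ref$unit, source = "inferred"
  )
}
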