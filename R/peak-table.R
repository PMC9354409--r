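# Compound peak tables: validated tibbles of per-compound, per-group GC-MS
# peak areas or relative contents.

.meta_cols <- c("compound", "formula", "class", "odor")

#' Construct a validated peak table
#'
#' A peak table is a tibble with metadata columns `compound` (required,
#' unique), `formula`, `class` (one of [chem_classes]), and `odor`, followed
#' by one numeric column per sample group. `NA` means the compound was not
#' detected in that group. Tables carry a `mode` attribute: `"area"` for raw
#' peak areas or `"relative_content"` for percentages of the per-group total.
#'
#' In `relative_content` mode the detected values of each group are expected
#' to sum to 100; deviations beyond `sum_tol` raise a warning (condition class
#' `roav_sum_warning`), since published tables rounded to two decimals can
#' drift from 100 by more than rounding alone.
#'
#' @param x A data frame with the columns described above.
#' @param mode `"area"` or `"relative_content"`.
#' @param sum_tol Allowed absolute deviation of per-group sums from 100 in
#'   `relative_content` mode before a warning is raised.
#' @return A `peak_tbl` tibble.
#' @export
#' @examples
#' peak_table(
#'   tibble::tibble(
#'     compound = c("ethyl acetate", "hexyl alcohol"),
#'     class = c("ester", "alcohol"),
#'     broth = c(80, 20)
#'   ),
#'   mode = "relative_content"
#' )
peak_table <- function(x, mode = c("area", "relative_content"), sum_tol = 0.5) {
  mode <- match.arg(mode)
  x <- as_tibble(x)
  if (!"compound" %in% names(x)) abort("Peak table needs a `compound` column.")
  if (!"class" %in% names(x)) abort("Peak table needs a `class` column.")
  if (!"formula" %in% names(x)) x$formula <- NA_character_
  if (!"odor" %in% names(x)) x$odor <- NA_character_
  x <- dplyr::relocate(x, dplyr::all_of(.meta_cols))

  if (any(is.na(x$compound) | !nzchar(trimws(x$compound)))) {
    abort(paste0(
      "Empty compound name(s) in rows: ",
      paste(which(is.na(x$compound) | !nzchar(trimws(x$compound))),
        collapse = ", "
      )
    ))
  }
  keys <- norm_name(x$compound)
  if (anyDuplicated(keys)) {
    dup <- unique(x$compound[duplicated(keys)])
    abort(paste0(
      "Duplicate compound name(s): ", paste(dup, collapse = ", "),
      " (rows ", paste(which(keys %in% norm_name(dup)), collapse = ", "), ")."
    ))
  }
  bad_class <- setdiff(unique(x$class), chem_classes)
  if (length(bad_class)) {
    abort(paste0(
      "Unknown chem class(es): ", paste(bad_class, collapse = ", "),
      ". Expected one of: ", paste(chem_classes, collapse = ", "), "."
    ))
  }

  groups <- setdiff(names(x), .meta_cols)
  if (!length(groups)) abort("Peak table needs at least one group column.")
  for (g in groups) {
    v <- x[[g]]
    if (!is.numeric(v)) abort(paste0("Group column `", g, "` is not numeric."))
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0(
        "Negative value(s) in group `", g, "` (rows ",
        paste(which(!is.na(v) & v < 0), collapse = ", "), ")."
      ))
    }
    if (any(!is.finite(v) & !is.na(v))) {
      abort(paste0("Non-finite value(s) in group `", g, "`."))
    }
  }

  if (mode == "relative_content") {
    sums <- vapply(groups, function(g) sum(x[[g]], na.rm = TRUE), numeric(1))
    off <- abs(sums - 100) > sum_tol & sums > 0
    if (any(off)) {
      warn(
        paste0(
          "Relative contents do not sum to 100 within +/-", sum_tol, ": ",
          paste0(groups[off], " = ", round(sums[off], 2), collapse = ", ")
        ),
        class = "roav_sum_warning"
      )
    }
  }

  structure(x, class = c("peak_tbl", class(tibble())), mode = mode)
}

#' Read a compound table from CSV or TSV
#'
#' Expects a header `compound,formula,class,odor,<group1>,<group2>,...`
#' (`formula` and `odor` may be absent). Cells containing `-`, an en/em dash,
#' or nothing are read as not detected.
#'
#' @param path Path to a CSV or TSV file (delimiter is sniffed).
#' @inheritParams peak_table
#' @return A `peak_tbl` tibble.
#' @export
read_peak_table <- function(path, mode = c("area", "relative_content"),
                            sum_tol = 0.5) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read_delim_chr(path)
  for (mc in intersect(c("formula", "odor"), names(raw))) {
    raw[[mc]][!is.na(raw[[mc]]) & !nzchar(trimws(raw[[mc]]))] <- NA_character_
  }
  groups <- setdiff(names(raw), .meta_cols)
  for (g in groups) raw[[g]] <- parse_value_cells(raw[[g]], paste0("`", g, "`"))
  peak_table(raw, mode = mode, sum_tol = sum_tol)
}

#' Write a compound table to CSV
#'
#' Numbers are rendered with two decimal places and non-detections as `-`,
#' mirroring the conventions of published volatile-profile tables.
#'
#' @param x A `peak_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "peak_tbl"))
  out <- as_tibble(x)
  for (g in peak_groups(x)) out[[g]] <- fmt2(out[[g]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.peak_tbl <- function(x, ...) {
  cat(
    "# Peak table (", attr(x, "mode"), " mode): ", nrow(x), " compounds, ",
    length(peak_groups(x)), " group(s)\n",
    sep = ""
  )
  NextMethod()
}

#' Group labels of a peak table
#' @param x A `peak_tbl`.
#' @return Character vector of group column names, in table order.
#' @export
peak_groups <- function(x) {
  setdiff(names(x), .meta_cols)
}

#' Table mode (`"area"` or `"relative_content"`)
#' @param x A `peak_tbl`.
#' @export
peak_mode <- function(x) attr(x, "mode")

check_group <- function(x, group) {
  check_scalar_string(group, "group")
  if (!group %in% peak_groups(x)) {
    abort(paste0(
      "Unknown group `", group, "`. Available: ",
      paste(peak_groups(x), collapse = ", "), "."
    ))
  }
  invisible(group)
}

#' Normalize peak areas to relative contents
#'
#' Converts each group column to percentages: `100 * A_i / sum(A_i)` over the
#' detected (non-`NA`) compounds of that group. Non-detections stay `NA`.
#' Already-normalized tables are renormalized, which is the identity up to
#' scaling, so the operation is idempotent.
#'
#' @param x A `peak_tbl`.
#' @return A `peak_tbl` in `relative_content` mode whose detected values sum
#'   to exactly 100 per group.
#' @export
#' @examples
#' pt <- peak_table(
#'   tibble::tibble(
#'     compound = c("a", "b", "c"), class = "ester",
#'     broth = c(2, 3, 5)
#'   ),
#'   mode = "area"
#' )
#' relative_content(pt)
relative_content <- function(x) {
  stopifnot(inherits(x, "peak_tbl"))
  out <- as_tibble(x)
  for (g in peak_groups(x)) {
    v <- out[[g]]
    s <- sum(v, na.rm = TRUE)
    if (all(is.na(v)) || s <= 0) {
      abort(paste0(
        "Group `", g, "` has no positive detected value; cannot normalize."
      ))
    }
    out[[g]] <- 100 * v / s
  }
  peak_table(out, mode = "relative_content", sum_tol = Inf)
}

#' Count detected compounds
#'
#' A compound is detected in a group when its cell is not `NA`.
#'
#' @param x A `peak_tbl`.
#' @param group A group label, or `NULL` for all groups.
#' @return An integer for a single group, otherwise a tibble with one row per
#'   group (`group`, `n_detected`).
#' @export
detected_count <- function(x, group = NULL) {
  stopifnot(inherits(x, "peak_tbl"))
  if (is.null(group)) {
    return(tibble(
      group = peak_groups(x),
      n_detected = vapply(
        peak_groups(x), function(g) sum(!is.na(x[[g]])), integer(1),
        USE.NAMES = FALSE
      )
    ))
  }
  check_group(x, group)
  sum(!is.na(x[[group]]))
}

#' Per-class compound counts and relative-content totals
#'
#' For one group, counts the detected compounds in each chemical class and
#' sums their values. Every class in [chem_classes] appears in the output,
#' with zeros where no member was detected.
#'
#' @param x A `peak_tbl` (meaningful totals require `relative_content` mode).
#' @param group A group label.
#' @return A tibble with columns `chem_class`, `n`, `total`.
#' @export
class_totals <- function(x, group) {
  stopifnot(inherits(x, "peak_tbl"))
  check_group(x, group)
  det <- tibble(chem_class = x$class, value = x[[group]]) |>
    dplyr::filter(!is.na(.data$value))
  tibble(chem_class = chem_classes) |>
    dplyr::left_join(
      det |>
        dplyr::group_by(.data$chem_class) |>
        dplyr::summarise(
          n = dplyr::n(), total = sum(.data$value),
          .groups = "drop"
        ),
      by = "chem_class"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      total = dplyr::coalesce(.data$total, 0)
    )
}

#' Most abundant detected compounds of a group
#'
#' Detected compounds sorted by value descending; ties are broken by compound
#' name (ascending, lexicographic) so the ordering is deterministic.
#'
#' @param x A `peak_tbl`.
#' @param group A group label.
#' @param n Number of compounds to return (truncated to the detected count).
#' @return A tibble with columns `compound`, `value`.
#' @export
top_compounds <- function(x, group, n = 5) {
  stopifnot(inherits(x, "peak_tbl"))
  check_group(x, group)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a single integer >= 1.")
  }
  tibble(compound = x$compound, value = x[[group]]) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(dplyr::desc(.data$value), .data$compound) |>
    head(n = floor(n))
}
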