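# Relative odor activity value (ROAV) scoring.
#
# ROAV_A = (C_A / C_stan) * (T_stan / T_A) * 100, where C is relative content,
# T the odor detection threshold, and "stan" the compound contributing most to
# the overall aroma (max C/T), which scores 100 by construction.

#' Default ROAV classification boundaries
#'
#' Compounds with ROAV (at the lower bound of an interval threshold) above
#' `key_min` are key odor compounds; below `potential_max` (or with no usable
#' threshold) they are potential odor compounds; in between they are modified
#' odor compounds. The conventional potential/modified boundary for OAV-style
#' scores is 0.1, but published ROAV tables in this domain place scores down
#' to 0.01 among the modified compounds, so 0.01 is the shipped default; pass
#' `roav_bins(potential_max = 0.1)` for the conventional bins.
#'
#' @param key_min Lower ROAV bound (exclusive) for key odor compounds.
#' @param potential_max Upper ROAV bound (exclusive) for potential compounds.
#' @return Named numeric vector of boundaries.
#' @export
roav_bins <- function(key_min = 1, potential_max = 0.01) {
  if (!is.numeric(key_min) || !is.numeric(potential_max) ||
    potential_max >= key_min) {
    abort("Need numeric boundaries with potential_max < key_min.")
  }
  c(key_min = unname(key_min), potential_max = unname(potential_max))
}

#' Raw ROAV score
#'
#' Vectorized computation of `(content / ref_content) * (ref_threshold /
#' threshold) * 100`. For interval thresholds pass both bounds: because ROAV
#' is anti-monotone in the threshold, the score at the interval's *lower*
#' bound is the *upper* ROAV endpoint and vice versa.
#'
#' @param content Relative content(s) of the scored compound(s), percent.
#' @param t_low,t_high Threshold bounds (equal for point/approx thresholds).
#' @param ref_content Relative content of the reference compound.
#' @param ref_threshold Point threshold of the reference compound.
#' @return A tibble with columns `roav_low`, `roav_high`.
#' @export
#' @examples
#' roav_score(15.44, 1, 1, ref_content = 8.03, ref_threshold = 0.1)
roav_score <- function(content, t_low, t_high = t_low, ref_content,
                       ref_threshold) {
  if (any(t_low <= 0 | t_high <= 0, na.rm = TRUE) || ref_threshold <= 0) {
    abort("Detection thresholds must be positive.")
  }
  if (ref_content <= 0) abort("Reference relative content must be positive.")
  if (any(content < 0, na.rm = TRUE)) abort("Relative contents must be >= 0.")
  tibble(
    roav_low = (content / ref_content) * (ref_threshold / t_high) * 100,
    roav_high = (content / ref_content) * (ref_threshold / t_low) * 100
  )
}

#' Classify ROAV scores into odor roles
#'
#' Classification uses the upper ROAV endpoint (the score at the lower bound
#' of an interval threshold) and unrounded values; `NA` (no usable threshold)
#' is always `potential`.
#'
#' @param roav_high Numeric vector of upper ROAV endpoints (`NA` allowed).
#' @param bins Boundaries from [roav_bins()].
#' @return Character vector in `c("key", "modified", "potential")`.
#' @export
classify_roav <- function(roav_high, bins = roav_bins()) {
  dplyr::case_when(
    is.na(roav_high) ~ "potential",
    roav_high > bins[["key_min"]] ~ "key",
    roav_high < bins[["potential_max"]] ~ "potential",
    TRUE ~ "modified"
  )
}

# Resolve a threshold for every compound: direct lookup first, then curated
# formula bracketing, else no threshold (NA row).
resolve_thresholds <- function(compound, formula, db) {
  rows <- purrr::map2(compound, formula, function(cmp, frm) {
    hit <- lookup_threshold(db, cmp)
    if (!is.null(hit)) {
      return(tibble(
        t_kind = hit$kind, t_low = hit$low, t_high = hit$high,
        t_unit = hit$unit, t_source = "db"
      ))
    }
    if (!is.na(frm) && nzchar(frm)) {
      inf <- tryCatch(infer_threshold(db, frm), roav_no_bracket = function(e) NULL)
      if (!is.null(inf)) {
        return(tibble(
          t_kind = inf$kind, t_low = inf$low, t_high = inf$high,
          t_unit = inf$unit, t_source = "inferred"
        ))
      }
    }
    tibble(
      t_kind = NA_character_, t_low = NA_real_, t_high = NA_real_,
      t_unit = NA_character_, t_source = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

#' Select the reference (maximum-contribution) compound of a group
#'
#' The reference is the detected compound maximizing content/threshold among
#' compounds with a point-like (point or approx) threshold; its ROAV is 100
#' by construction. Interval-threshold compounds are not eligible since the
#' reference must pin the scale to a single value. Ties are broken in favor
#' of `point` over `approx` entries, then by compound name.
#'
#' @param x A `peak_tbl` in `relative_content` mode.
#' @param db A `threshold_db`.
#' @param group Group label to score.
#' @param score_classes Chemical classes eligible for scoring. Compound
#'   classes dominated by high-threshold species (alkanes and other
#'   hydrocarbons, pooled in `"other"`) are excluded by default.
#' @return The reference compound's name.
#' @export
select_reference <- function(x, db, group,
                             score_classes = c("ester", "alcohol", "aldehyde")) {
  cand <- scored_compounds(x, db, group, score_classes)
  cand <- cand |>
    dplyr::filter(.data$t_kind %in% c("point", "approx")) |>
    dplyr::mutate(ct = .data$content / .data$t_low) |>
    dplyr::arrange(
      dplyr::desc(.data$ct), .data$t_kind != "point", .data$compound
    )
  if (!nrow(cand)) {
    abort(paste0(
      "No detected compound with a point threshold in group `", group, "`."
    ))
  }
  cand$compound[[1]]
}

# Detected, scorable compounds of a group with resolved thresholds.
scored_compounds <- function(x, db, group, score_classes) {
  stopifnot(inherits(x, "peak_tbl"))
  if (peak_mode(x) != "relative_content") {
    abort("Peak table must be in relative_content mode (see relative_content()).")
  }
  check_group(x, group)
  bad <- setdiff(score_classes, chem_classes)
  if (length(bad)) {
    abort(paste0("Unknown score class(es): ", paste(bad, collapse = ", ")))
  }
  det <- tibble(
    compound = x$compound, chem_class = x$class,
    formula = x$formula, odor = x$odor, content = x[[group]]
  ) |>
    dplyr::filter(!is.na(.data$content), .data$chem_class %in% score_classes)
  dplyr::bind_cols(
    det,
    resolve_thresholds(det$compound, det$formula, db)
  )
}

#' Build the full ROAV table for one group
#'
#' Scores every detected compound of the group (within `score_classes`)
#' against the automatically selected reference, classifies each score, and
#' ranks the key compounds by descending upper ROAV (ties by name). Compounds
#' without a known or inferable threshold stay in the table with an undefined
#' (`NA`) ROAV and class `potential`; they are never dropped.
#'
#' @inheritParams select_reference
#' @param bins Classification boundaries from [roav_bins()].
#' @return A `roav_tbl` tibble with columns `compound`, `chem_class`, `odor`,
#'   `threshold_kind`, `threshold_low`, `threshold_high`, `unit`,
#'   `threshold_source`, `relative_content`, `roav_low`, `roav_high`, `roav`
#'   (formatted as in published tables: `hi\u2013lo` for intervals, `\u2248x` for
#'   approximate thresholds), `odor_class`, and `rank`. The group, reference
#'   compound, and bins are carried as attributes (see [glance.roav_tbl()]).
#' @export
build_roav_table <- function(x, db, group, bins = roav_bins(),
                             score_classes = c("ester", "alcohol", "aldehyde")) {
  if (peak_mode(x) == "area") x <- relative_content(x)
  scored <- scored_compounds(x, db, group, score_classes)
  ref <- select_reference(x, db, group, score_classes)
  ref_row <- scored[match(norm_name(ref), norm_name(scored$compound)), ]

  sc <- roav_score(
    scored$content, scored$t_low, scored$t_high,
    ref_content = ref_row$content, ref_threshold = ref_row$t_low
  )
  out <- scored |>
    dplyr::mutate(
      roav_low = sc$roav_low,
      roav_high = sc$roav_high,
      odor_class = classify_roav(sc$roav_high, bins)
    ) |>
    dplyr::arrange(
      dplyr::desc(!is.na(.data$roav_high)),
      dplyr::desc(.data$roav_high), .data$compound
    )
  is_key <- out$odor_class == "key"
  out$rank <- NA_integer_
  out$rank[is_key] <- seq_len(sum(is_key))

  out <- out |>
    dplyr::transmute(
      compound = .data$compound,
      chem_class = .data$chem_class,
      odor = .data$odor,
      threshold_kind = .data$t_kind,
      threshold_low = .data$t_low,
      threshold_high = .data$t_high,
      unit = .data$t_unit,
      threshold_source = .data$t_source,
      relative_content = .data$content,
      roav_low = .data$roav_low,
      roav_high = .data$roav_high,
      roav = format_roav(.data$roav_low, .data$roav_high, .data$t_kind),
      odor_class = .data$odor_class,
      rank = .data$rank
    )

  structure(
    out,
    class = c("roav_tbl", class(tibble())),
    group = group,
    reference = ref_row$compound,
    reference_content = ref_row$content,
    reference_threshold = ref_row$t_low,
    bins = bins,
    score_classes = score_classes
  )
}

# Render ROAV values the way flavor tables print them: interval scores as
# "high-low" (the endpoint order is swapped relative to the threshold
# endpoints), approximate scores with a leading tilde-equals.
format_roav <- function(roav_low, roav_high, kind) {
  dplyr::case_when(
    is.na(roav_high) ~ "-",
    kind == "interval" ~ paste0(fmt2(roav_high), "\u2013", fmt2(roav_low)),
    kind == "approx" ~ paste0("\u2248", fmt2(roav_high)),
    TRUE ~ fmt2(roav_high)
  )
}

#' @export
print.roav_tbl <- function(x, ...) {
  cat(
    "# ROAV table for group `", attr(x, "group"), "` (reference: ",
    attr(x, "reference"), ", scores 100)\n",
    sep = ""
  )
  NextMethod()
}

#' @rdname build_roav_table
#' @param x A `roav_tbl`.
#' @param ... Unused.
#' @export
tidy.roav_tbl <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a ROAV table
#'
#' @param x A `roav_tbl`.
#' @param ... Unused.
#' @return A tibble with the group, reference compound, and class counts.
#' @export
glance.roav_tbl <- function(x, ...) {
  tibble(
    group = attr(x, "group"),
    reference = attr(x, "reference"),
    n_scored = nrow(x),
    n_key = sum(x$odor_class == "key"),
    n_modified = sum(x$odor_class == "modified"),
    n_potential = sum(x$odor_class == "potential"),
    key_min = attr(x, "bins")[["key_min"]],
    potential_max = attr(x, "bins")[["potential_max"]]
  )
}

#' Write a ROAV table to CSV
#'
#' @param x A `roav_tbl`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roav_table <- function(x, path) {
  stopifnot(inherits(x, "roav_tbl"))
  out <- as_tibble(x) |>
    dplyr::transmute(
      compound = .data$compound,
      class = .data$chem_class,
      threshold = dplyr::case_when(
        is.na(.data$threshold_kind) ~ "-",
        .data$threshold_kind == "interval" ~
          paste0(.data$threshold_low, "\u2013", .data$threshold_high),
        .data$threshold_kind == "approx" ~ paste0("\u2248", .data$threshold_low),
        TRUE ~ as.character(.data$threshold_low)
      ),
      unit = dplyr::coalesce(.data$unit, "-"),
      relative_content = fmt2(.data$relative_content),
      roav = .data$roav,
      odor_class = .data$odor_class,
      rank = .data$rank
    )
  readr::write_csv(out, path, progress = FALSE, na = "-")
  invisible(path)
}
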