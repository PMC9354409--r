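# Comparison of key odor compounds between two strains.

#' Compare the key odor compounds of two groups
#'
#' Set operations over the key-class compounds of two ROAV tables built with
#' the same classification bins. Detection differences and classification
#' differences are reported separately:
#' * `shared_key` — key in both groups, with both ROAVs;
#' * `unique_key_a` / `unique_key_b` — key in one group and *not detected* in
#'   the other: these are the compounds that can explain a different aroma;
#' * `downshifted_a` / `downshifted_b` — key in one group but detected at
#'   sub-key ROAV in the other (a difference of degree, not of presence).
#'
#' For every group, `|shared| + |unique| + |downshifted|` equals its key
#' count, and swapping the inputs swaps the per-group fields exactly.
#'
#' @param a,b `roav_tbl` objects from [build_roav_table()].
#' @return A `strain_comparison` object (see fields above); `shared_key` is
#'   ordered by descending mean ROAV, unique sets by descending ROAV.
#' @export
compare_key_compounds <- function(a, b) {
  stopifnot(inherits(a, "roav_tbl"), inherits(b, "roav_tbl"))
  bins_a <- attr(a, "bins")
  bins_b <- attr(b, "bins")
  if (!isTRUE(all.equal(bins_a, bins_b))) {
    abort(
      "ROAV tables were classified with different bins; comparison refused.",
      class = "roav_bin_mismatch"
    )
  }

  key_a <- dplyr::filter(as_tibble(a), .data$odor_class == "key")
  key_b <- dplyr::filter(as_tibble(b), .data$odor_class == "key")
  ka <- norm_name(key_a$compound)
  kb <- norm_name(key_b$compound)
  det_a <- norm_name(a$compound)
  det_b <- norm_name(b$compound)

  shared <- key_a |>
    dplyr::filter(ka %in% kb) |>
    dplyr::transmute(
      compound = .data$compound,
      roav_a = .data$roav_high,
      roav_b = key_b$roav_high[match(norm_name(.data$compound), kb)]
    ) |>
    dplyr::arrange(
      dplyr::desc((.data$roav_a + .data$roav_b) / 2), .data$compound
    )

  uniq <- function(keys, key_tbl, other_detected) {
    key_tbl |>
      dplyr::filter(!(keys %in% other_detected)) |>
      dplyr::arrange(dplyr::desc(.data$roav_high), .data$compound) |>
      dplyr::pull("compound")
  }
  down <- function(keys, key_tbl, other_tbl, other_detected) {
    key_tbl |>
      dplyr::filter(keys %in% other_detected, !(keys %in% norm_name(
        dplyr::filter(other_tbl, .data$odor_class == "key")$compound
      ))) |>
      dplyr::transmute(
        compound = .data$compound,
        roav = .data$roav_high,
        class_other = other_tbl$odor_class[
          match(norm_name(.data$compound), norm_name(other_tbl$compound))
        ]
      )
  }

  structure(
    list(
      group_a = attr(a, "group"),
      group_b = attr(b, "group"),
      bins = bins_a,
      key_count_a = nrow(key_a),
      key_count_b = nrow(key_b),
      shared_key = shared,
      unique_key_a = uniq(ka, key_a, det_b),
      unique_key_b = uniq(kb, key_b, det_a),
      downshifted_a = down(ka, key_a, as_tibble(b), det_b),
      downshifted_b = down(kb, key_b, as_tibble(a), det_a)
    ),
    class = "strain_comparison"
  )
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(
    "# Key-compound comparison: ", x$group_a, " (", x$key_count_a,
    " key) vs ", x$group_b, " (", x$key_count_b, " key)\n",
    sep = ""
  )
  cat("  shared key compounds: ", nrow(x$shared_key), "\n", sep = "")
  cat(
    "  unique to ", x$group_a, ": ",
    if (length(x$unique_key_a)) paste(x$unique_key_a, collapse = ", ") else "(none)",
    "\n",
    sep = ""
  )
  cat(
    "  unique to ", x$group_b, ": ",
    if (length(x$unique_key_b)) paste(x$unique_key_b, collapse = ", ") else "(none)",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a strain comparison into one long tibble
#'
#' @param x A `strain_comparison`.
#' @param ... Unused.
#' @return A tibble with columns `compound`, `status`, `roav_a`, `roav_b`.
#' @export
tidy.strain_comparison <- function(x, ...) {
  dplyr::bind_rows(
    x$shared_key |> dplyr::mutate(status = "shared"),
    tibble(
      compound = x$unique_key_a, status = "unique_a",
      roav_a = NA_real_, roav_b = NA_real_
    ),
    tibble(
      compound = x$unique_key_b, status = "unique_b",
      roav_a = NA_real_, roav_b = NA_real_
    ),
    x$downshifted_a |>
      dplyr::transmute(
        compound = .data$compound, status = "downshifted_a",
        roav_a = .data$roav, roav_b = NA_real_
      ),
    x$downshifted_b |>
      dplyr::transmute(
        compound = .data$compound, status = "downshifted_b",
        roav_a = NA_real_, roav_b = .data$roav
      )
  ) |>
    dplyr::relocate("compound", "status")
}

#' Aggregate odor notes over each group's key compounds
#'
#' Tokenizes the free-text odor descriptors of the key compounds (split on
#' commas/semicolons, lowercased) and reports the per-group token frequencies,
#' the dominant note, and the descriptors of the strain-unique key compounds.
#' Purely descriptive; compounds without a descriptor count as `"unlabeled"`.
#'
#' @param comparison A `strain_comparison`.
#' @param x The `peak_tbl` holding the `odor` descriptor column.
#' @return A list with `summary` (group, dominant_note, n_key), `tokens`
#'   (group, note, n), and `unique_notes` (group, compound, odor).
#' @export
aroma_note_summary <- function(comparison, x) {
  stopifnot(inherits(comparison, "strain_comparison"), inherits(x, "peak_tbl"))
  odor_of <- function(compounds) {
    x$odor[match(norm_name(compounds), norm_name(x$compound))]
  }
  tokens_of <- function(odors) {
    toks <- unlist(lapply(odors, function(o) {
      if (is.na(o) || !nzchar(trimws(o))) {
        return("unlabeled")
      }
      tolower(trimws(strsplit(o, "[,;]")[[1]]))
    }))
    toks[nzchar(toks)]
  }

  key_sets <- list(
    c(comparison$shared_key$compound, comparison$unique_key_a,
      comparison$downshifted_a$compound),
    c(comparison$shared_key$compound, comparison$unique_key_b,
      comparison$downshifted_b$compound)
  )
  groups <- c(comparison$group_a, comparison$group_b)

  tok_tbl <- purrr::map2(groups, key_sets, function(g, comps) {
    toks <- tokens_of(odor_of(comps))
    if (!length(toks)) toks <- "unlabeled"
    tibble(group = g, note = toks) |>
      dplyr::count(.data$group, .data$note, name = "n")
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$group, dplyr::desc(.data$n), .data$note)

  summary <- tok_tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      group = .data$group, dominant_note = .data$note
    ) |>
    dplyr::mutate(
      n_key = c(comparison$key_count_a, comparison$key_count_b)[
        match(.data$group, groups)
      ]
    )

  unique_notes <- dplyr::bind_rows(
    tibble(
      group = comparison$group_a, compound = comparison$unique_key_a,
      odor = odor_of(comparison$unique_key_a)
    ),
    tibble(
      group = comparison$group_b, compound = comparison$unique_key_b,
      odor = odor_of(comparison$unique_key_b)
    )
  ) |>
    dplyr::mutate(odor = dplyr::coalesce(.data$odor, "unlabeled"))

  list(summary = summary, tokens = tok_tbl, unique_notes = unique_notes)
}
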