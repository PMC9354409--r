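# End-to-end orchestration: compound table -> relative content -> ROAV ->
# classification -> strain comparison -> e-nose summaries.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      paste0("Pipeline stage `", stage, "` failed: ", conditionMessage(e)),
      class = "roav_pipeline_error"
    )
  })
}

resolve_input <- function(x, reader, what) {
  if (is.character(x)) {
    if (!file.exists(x)) abort(paste0(what, " file not found: ", x))
    return(reader(x))
  }
  x
}

#' Run the full aroma-profiling analysis
#'
#' Orchestrates the whole pipeline: read/validate inputs, normalize peak
#' areas to relative contents if needed, score each strain's compounds by
#' ROAV, classify and rank them, compare the strains' key-compound sets and
#' aroma notes, and (if sensor data are given) summarize the e-nose responses
#' by PCA, LDA, radar profiles, and ratios to the blank control.
#'
#' The blank (medium-only) group is used for detection-feasibility context
#' and e-nose ratios but never enters ROAV scoring or reference selection:
#' ROAV compares contributors within a fermentation aroma, which the
#' uninoculated medium does not have.
#'
#' All input files are checked before any output is written, so a bad config
#' fails cleanly without partial results. Re-running with identical inputs
#' gives byte-identical numeric outputs.
#'
#' @param compounds A `peak_tbl` or path to a compound CSV/TSV.
#' @param thresholds A `threshold_db` or path to a threshold CSV.
#' @param brackets Optional bracket CSV path (ignored when `thresholds` is
#'   already a `threshold_db`).
#' @param sensors Optional sensor tibble or CSV path.
#' @param mode Mode of the compound table when read from file.
#' @param blank Label of the blank-control group, or `NULL` if none.
#' @param strains Strain group labels to score; defaults to all non-blank
#'   groups.
#' @param bins Classification boundaries from [roav_bins()].
#' @param sum_tol Sum tolerance passed to [read_peak_table()].
#' @param out_dir Optional output directory; when given, writes the
#'   relative-content table, per-strain ROAV tables, comparison report
#'   (CSV + JSON), e-nose summaries, and a run log.
#' @return An `aroma_report` list: `peaks`, `detected`, `class_totals`,
#'   `roav` (named list of `roav_tbl`), `comparison`, `notes`, `enose`.
#' @export
run_aroma_pipeline <- function(compounds, thresholds, brackets = NULL,
                               sensors = NULL,
                               mode = c("relative_content", "area"),
                               blank = NULL, strains = NULL,
                               bins = roav_bins(), sum_tol = 0.5,
                               out_dir = NULL) {
  mode <- match.arg(mode)

  # fail fast on any missing input before computing or writing anything
  for (p in list(compounds, thresholds, brackets, sensors)) {
    if (is.character(p) && !file.exists(p)) {
      abort(paste0("Input file not found: ", p), class = "roav_pipeline_error")
    }
  }

  peaks <- with_stage(
    "read_compounds",
    resolve_input(compounds, function(p) read_peak_table(p, mode, sum_tol),
      "Compound"
    )
  )
  db <- with_stage(
    "read_thresholds",
    resolve_input(thresholds, function(p) read_threshold_db(p, brackets),
      "Threshold"
    )
  )
  sens <- if (!is.null(sensors)) {
    with_stage(
      "read_sensors",
      resolve_input(sensors, read_sensor_matrix, "Sensor")
    )
  }

  peaks <- with_stage("relative_content", {
    if (peak_mode(peaks) == "area") relative_content(peaks) else peaks
  })

  groups <- peak_groups(peaks)
  if (!is.null(blank) && !blank %in% groups) {
    abort(paste0("Blank group `", blank, "` not in compound table."),
      class = "roav_pipeline_error"
    )
  }
  strains <- strains %||% setdiff(groups, blank)
  if (!length(strains)) abort("No strain groups to score.")

  detected <- detected_count(peaks)
  totals <- purrr::map(
    setNames(groups, groups),
    function(g) class_totals(peaks, g)
  ) |>
    dplyr::bind_rows(.id = "group")

  roav_tbls <- with_stage("roav", {
    purrr::map(
      setNames(strains, strains),
      function(g) build_roav_table(peaks, db, g, bins = bins)
    )
  })

  comparison <- NULL
  notes <- NULL
  if (length(strains) >= 2L) {
    comparison <- with_stage(
      "compare",
      compare_key_compounds(roav_tbls[[strains[1]]], roav_tbls[[strains[2]]])
    )
    notes <- with_stage("notes", aroma_note_summary(comparison, peaks))
  }

  enose <- NULL
  if (!is.null(sens)) {
    enose <- with_stage("enose", {
      sgroups <- unique(sens$group)
      res <- list(
        pca = enose_pca(sens, k = min(2L, nrow(sens) - 1L)),
        lda = if (length(sgroups) >= 2L) enose_lda(sens),
        radar = purrr::map(
          setNames(sgroups, sgroups),
          function(g) radar_profile(sens, g)
        )
      )
      if (!is.null(blank) && blank %in% sgroups) {
        res$ratio_to_blank <- purrr::map(
          setNames(setdiff(sgroups, blank), setdiff(sgroups, blank)),
          function(g) response_ratio(sens, g, blank)
        )
      }
      res
    })
  }

  report <- structure(
    list(
      peaks = peaks, detected = detected, class_totals = totals,
      roav = roav_tbls, comparison = comparison, notes = notes,
      enose = enose, bins = bins, blank = blank, strains = strains
    ),
    class = "aroma_report"
  )

  if (!is.null(out_dir)) {
    with_stage("write_outputs", write_report(report, out_dir))
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_peak_table(report$peaks, file.path(out_dir, "relative_content.csv"))
  readr::write_csv(report$class_totals, file.path(out_dir, "class_totals.csv"),
    progress = FALSE
  )
  for (g in names(report$roav)) {
    write_roav_table(report$roav[[g]], file.path(out_dir, paste0("roav_", g, ".csv")))
  }
  if (!is.null(report$comparison)) {
    cmp <- report$comparison
    readr::write_csv(tidy(cmp), file.path(out_dir, "comparison.csv"),
      progress = FALSE
    )
    jsonlite::write_json(
      list(
        group_a = cmp$group_a, group_b = cmp$group_b,
        key_count_a = cmp$key_count_a, key_count_b = cmp$key_count_b,
        shared_key = cmp$shared_key,
        unique_key_a = cmp$unique_key_a, unique_key_b = cmp$unique_key_b,
        dominant_notes = report$notes$summary
      ),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  if (!is.null(report$enose)) {
    readr::write_csv(
      report$enose$pca$scores,
      file.path(out_dir, "enose_pca_scores.csv"),
      progress = FALSE
    )
    if (!is.null(report$enose$ratio_to_blank)) {
      readr::write_csv(
        dplyr::bind_rows(report$enose$ratio_to_blank, .id = "group"),
        file.path(out_dir, "enose_ratio_to_blank.csv"),
        progress = FALSE
      )
    }
  }
  log_lines <- c(
    paste0("roavtools ", as.character(utils::packageVersion("roavtools"))),
    paste0("strains: ", paste(report$strains, collapse = ", ")),
    paste0("blank: ", report$blank %||% "(none)"),
    paste0(
      "bins: key_min=", report$bins[["key_min"]],
      " potential_max=", report$bins[["potential_max"]]
    ),
    vapply(names(report$roav), function(g) {
      paste0("reference[", g, "]: ", attr(report$roav[[g]], "reference"))
    }, character(1))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.aroma_report <- function(x, ...) {
  cat("# Aroma profiling report\n")
  cat(
    "  groups: ",
    paste0(x$detected$group, " (", x$detected$n_detected, " detected)",
      collapse = ", "
    ), "\n",
    sep = ""
  )
  for (g in names(x$roav)) {
    gl <- glance(x$roav[[g]])
    cat(
      "  ", g, ": reference ", gl$reference, "; ", gl$n_key, " key, ",
      gl$n_modified, " modified, ", gl$n_potential, " potential\n",
      sep = ""
    )
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
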