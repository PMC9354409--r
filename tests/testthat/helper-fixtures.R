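# Small in-code builders shared across tests.

make_peaks <- function(values, classes = NULL, formulas = NULL, odors = NULL,
                       mode = "area", sum_tol = 0.5) {
  n <- nrow(values)
  peak_table(
    dplyr::bind_cols(
      tibble::tibble(
        compound = rownames(values) %||% sprintf("cmp%02d", seq_len(n)),
        formula = formulas %||% NA_character_,
        class = classes %||% "ester",
        odor = odors %||% NA_character_
      ),
      tibble::as_tibble(values)
    ),
    mode = mode, sum_tol = sum_tol
  )
}

make_db <- function(compound, value, unit = "ug/L", kind = "point",
                    high = value, brackets = NULL) {
  threshold_db(
    tibble::tibble(
      compound = compound, kind = kind, low = value, high = high, unit = unit
    ),
    brackets = brackets
  )
}

# random relative-content table with point thresholds for property tests
random_scored_setup <- function(n = 10, seed = 1) {
  withr::with_seed(seed, {
    areas <- matrix(rlnorm(n, log(100), 1), ncol = 1)
    colnames(areas) <- "g1"
    pt <- relative_content(make_peaks(areas))
    db <- make_db(pt$compound, 10^runif(n, -1, 2))
    list(peaks = pt, db = db)
  })
}

`%||%` <- rlang::`%||%`
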