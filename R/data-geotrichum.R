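# Bundled example data: volatile profiles of two Geotrichum candidum strains
# (a wild type and a space-mutagenized derivative) fermented in potato
# dextrose broth, with the uninoculated medium as blank control, transcribed
# from the published relative-content and detection-threshold tables.

#' Example volatile profile of two *Geotrichum candidum* strains
#'
#' Relative contents (percent of total volatiles, HS-SPME-GC-MS) of 38
#' compounds across three groups: uninoculated medium (`blank`), the wild
#' strain (`wild`), and a mutagenized strain (`mutagenic`). Molecular
#' formulas are supplied for the five esters whose detection thresholds must
#' be inferred by homolog bracketing (see [geotrichum_thresholds()]).
#'
#' The printed source columns sum to 100 +/- ~3 (two-decimal rounding and
#' internal inconsistencies of the source tables), so the loader uses a sum
#' tolerance of 3.5 instead of the default 0.5.
#'
#' @return A `peak_tbl` in `relative_content` mode.
#' @export
#' @examples
#' detected_count(geotrichum_peaks())
geotrichum_peaks <- function() {
  read_peak_table(
    system.file("extdata", "geotrichum_volatiles.csv", package = "roavtools"),
    mode = "relative_content", sum_tol = 3.5
  )
}

#' Example odor detection thresholds with curated ester brackets
#'
#' Literature detection thresholds (ug/L or ug/kg) for the compounds of
#' [geotrichum_peaks()], plus the curated carbon-chain bracket map used to
#' infer the five ester thresholds without literature values:
#' C6H10O2 bracketed 3-5 ug/L, C7H12O2 1-3 ug/L, C9H16O2 2-2.2 ug/L,
#' C7H14O2 approximately 3 ug/L, and C9H18O2 approximately 2.2 ug/L.
#'
#' @return A `threshold_db`.
#' @export
#' @examples
#' lookup_threshold(geotrichum_thresholds(), "Phenylethyl alcohol")
geotrichum_thresholds <- function() {
  read_threshold_db(
    system.file("extdata", "odor_thresholds.csv", package = "roavtools"),
    system.file("extdata", "ester_brackets.csv", package = "roavtools")
  )
}
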