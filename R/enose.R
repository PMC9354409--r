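# Electronic-nose sensor-array analysis: PCA, LDA, radar profiles, and
# ratio-to-blank summaries for replicate x sensor response matrices.

#' PEN3 sensor names
#'
#' The ten metal-oxide sensors of the PEN3 electronic nose, in array order,
#' with their nominal chemical sensitivities.
#' @export
pen3_sensors <- c(
  W1C = "aromatic compounds",
  W5S = "nitrogen oxides (broad range)",
  W3C = "ammonia, aromatic compounds",
  W6S = "hydrides",
  W5C = "short-chain alkanes, aromatics",
  W1S = "methyl groups",
  W1W = "sulfides",
  W2S = "alcohols, aldehydes, ketones",
  W2W = "aromatics, organic sulfur compounds",
  W3S = "long-chain alkanes"
)

# Validate a sensor response data frame: a `group` label column plus numeric,
# finite, non-negative sensor columns; >= 2 rows.
check_sensor_tbl <- function(x, group_col = "group") {
  x <- as_tibble(x)
  if (!group_col %in% names(x)) {
    abort(paste0("Sensor table needs a `", group_col, "` column."))
  }
  sensors <- setdiff(names(x), group_col)
  if (!length(sensors)) abort("Sensor table has no sensor columns.")
  for (s in sensors) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(paste0("Sensor column `", s, "` is not numeric."))
    if (any(!is.finite(v))) abort(paste0("Non-finite response in `", s, "`."))
    if (any(v < 0)) abort(paste0("Negative response in `", s, "`."))
  }
  if (nrow(x) < 2L) abort("Sensor table needs at least two rows.")
  x
}

sensor_names <- function(x, group_col = "group") setdiff(names(x), group_col)

sensor_matrix <- function(x, group_col = "group") {
  as.matrix(x[, sensor_names(x, group_col)])
}

check_sensor_group <- function(x, group, group_col = "group") {
  check_scalar_string(group, "group")
  if (!group %in% x[[group_col]]) {
    abort(paste0(
      "Unknown group `", group, "`. Available: ",
      paste(unique(x[[group_col]]), collapse = ", "), "."
    ))
  }
  invisible(group)
}

#' Read an e-nose response matrix from CSV
#'
#' Expects a `group` column followed by one numeric column per sensor (for
#' the PEN3 array: `W1C,W5S,W3C,W6S,W5C,W1S,W1W,W2S,W2W,W3S`).
#'
#' @param path CSV path.
#' @param group_col Name of the group-label column.
#' @return A validated tibble.
#' @export
read_sensor_matrix <- function(path, group_col = "group") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read_delim_chr(path)
  for (s in setdiff(names(raw), group_col)) {
    raw[[s]] <- parse_value_cells(raw[[s]], paste0("`", s, "`"))
  }
  check_sensor_tbl(raw, group_col)
}

# Common container for ordination results.
new_enose_ord <- function(scores, loadings, explained_ratio, explained_full,
                          method) {
  structure(
    list(
      scores = scores, loadings = loadings,
      explained_ratio = explained_ratio, explained_full = explained_full,
      method = method
    ),
    class = "enose_ord"
  )
}

#' @export
print.enose_ord <- function(x, ...) {
  cat(
    "# ", toupper(x$method), " of e-nose responses: ",
    paste0(
      names(x$explained_ratio), " ",
      sprintf("%.2f%%", 100 * x$explained_ratio),
      collapse = ", "
    ), "\n",
    sep = ""
  )
  print(x$scores, ...)
  invisible(x)
}

#' @export
tidy.enose_ord <- function(x, ...) x$scores

#' @export
glance.enose_ord <- function(x, ...) {
  tibble(
    method = x$method,
    k = length(x$explained_ratio),
    explained_total = sum(x$explained_ratio)
  )
}

# Fix component signs so the largest-magnitude loading of each axis is
# positive (eigenvectors are otherwise defined only up to sign).
fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis of sensor responses
#'
#' Mean-centered PCA of the covariance matrix (all PEN3 sensors share a
#' response scale, so no per-sensor standardization by default; set
#' `use_correlation = TRUE` to standardize). Explained ratios are computed
#' against the total variance over all components, so they sum to 1 when
#' `k` equals the matrix rank.
#'
#' @param x Sensor tibble (see [read_sensor_matrix()]).
#' @param k Number of components to retain.
#' @param use_correlation Standardize sensors to unit variance first.
#' @param group_col Name of the group-label column.
#' @return An `enose_ord` with `scores` (tibble: group + `PC1..PCk`),
#'   `loadings` (tibble: sensor + `PC1..PCk`), `explained_ratio`, and
#'   `explained_full` (ratios over all components).
#' @export
enose_pca <- function(x, k = 2, use_correlation = FALSE, group_col = "group") {
  x <- check_sensor_tbl(x, group_col)
  m <- sensor_matrix(x, group_col)
  if (all(abs(sweep(m, 2, colMeans(m))) < 1e-12)) {
    abort("Sensor matrix is constant; PCA undefined.")
  }
  k_max <- min(nrow(m) - 1L, ncol(m))
  if (k < 1 || k > k_max) {
    abort(paste0("`k` must be between 1 and ", k_max, "."))
  }
  p <- prcomp(m, center = TRUE, scale. = use_correlation)
  expl_full <- p$sdev^2 / sum(p$sdev^2)
  fixed <- fix_signs(p$rotation[, seq_len(k), drop = FALSE],
    p$x[, seq_len(k), drop = FALSE])
  axes <- paste0("PC", seq_len(k))
  scores <- dplyr::bind_cols(
    tibble(group = x[[group_col]]),
    as_tibble(`colnames<-`(fixed$scores, axes))
  )
  loadings <- dplyr::bind_cols(
    tibble(sensor = colnames(m)),
    as_tibble(`colnames<-`(fixed$loadings, axes))
  )
  new_enose_ord(
    scores, loadings,
    explained_ratio = setNames(expl_full[seq_len(k)], axes),
    explained_full = expl_full,
    method = "pca"
  )
}

#' Linear discriminant analysis of sensor responses
#'
#' Discriminant axes of the between-group versus within-group scatter
#' matrices, from the generalized eigenproblem `Sw^-1 Sb`. The within scatter
#' is stabilized with a small ridge (`ridge * trace(Sw)` on the diagonal) so
#' small replicate counts, or perfectly separated groups with zero
#' within-group noise, remain solvable. At most `groups - 1` axes exist;
#' explained ratios are eigenvalue proportions and sum to 1 over the full
#' axis set. Axis vectors are scaled to unit norm.
#'
#' @param x Sensor tibble.
#' @param ridge Relative ridge added to the within-scatter diagonal.
#' @param group_col Name of the group-label column.
#' @return An `enose_ord` with axes `LD1..LDm`.
#' @export
enose_lda <- function(x, ridge = 1e-8, group_col = "group") {
  x <- check_sensor_tbl(x, group_col)
  g <- as.character(x[[group_col]])
  if (length(unique(g)) < 2L) {
    abort("LDA needs at least two groups.")
  }
  m <- sensor_matrix(x, group_col)
  p <- ncol(m)
  mu <- colMeans(m)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (lev in unique(g)) {
    rows <- m[g == lev, , drop = FALSE]
    mug <- colMeans(rows)
    cen <- sweep(rows, 2, mug)
    sw <- sw + crossprod(cen)
    sb <- sb + nrow(rows) * tcrossprod(mug - mu)
  }
  tr_sw <- sum(diag(sw))
  lambda <- ridge * (if (tr_sw > 0) tr_sw else sum(diag(sb)))
  if (lambda == 0) abort("Sensor matrix is constant; LDA undefined.")
  sw_r <- sw + diag(lambda, p)

  e <- eigen(solve(sw_r, sb))
  vals <- Re(e$values)
  vecs <- Re(e$vectors)
  m_axes <- min(length(unique(g)) - 1L, p)
  ord <- order(vals, decreasing = TRUE)[seq_len(m_axes)]
  vals <- pmax(vals[ord], 0)
  vecs <- vecs[, ord, drop = FALSE]
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")

  scores_m <- sweep(m, 2, mu) %*% vecs
  fixed <- fix_signs(vecs, scores_m)
  axes <- paste0("LD", seq_len(m_axes))
  scores <- dplyr::bind_cols(
    tibble(group = x[[group_col]]),
    as_tibble(`colnames<-`(fixed$scores, axes))
  )
  loadings <- dplyr::bind_cols(
    tibble(sensor = colnames(m)),
    as_tibble(`colnames<-`(fixed$loadings, axes))
  )
  expl <- if (sum(vals) > 0) vals / sum(vals) else rep(NA_real_, m_axes)
  new_enose_ord(
    scores, loadings,
    explained_ratio = setNames(expl, axes),
    explained_full = expl,
    method = "lda"
  )
}

#' Mean sensor response of a group (radar profile)
#'
#' @param x Sensor tibble.
#' @param group Group label.
#' @param group_col Name of the group-label column.
#' @return A tibble `sensor`, `mean_response` in sensor column order.
#' @export
radar_profile <- function(x, group, group_col = "group") {
  x <- check_sensor_tbl(x, group_col)
  check_sensor_group(x, group, group_col)
  m <- sensor_matrix(x, group_col)[x[[group_col]] == group, , drop = FALSE]
  tibble(sensor = colnames(m), mean_response = unname(colMeans(m)))
}

#' Per-sensor response ratio of a group relative to a blank control
#'
#' The ratio of group mean to blank mean, sensor by sensor; the standard way
#' to express how much a fermentation headspace exceeds the uninoculated
#' medium on each sensor chemistry.
#'
#' @param x Sensor tibble.
#' @param group Group label of interest.
#' @param blank Group label of the blank control.
#' @param group_col Name of the group-label column.
#' @return A tibble `sensor`, `group_mean`, `blank_mean`, `ratio`.
#' @export
response_ratio <- function(x, group, blank, group_col = "group") {
  x <- check_sensor_tbl(x, group_col)
  check_sensor_group(x, group, group_col)
  check_sensor_group(x, blank, group_col)
  gm <- radar_profile(x, group, group_col)
  bm <- radar_profile(x, blank, group_col)
  if (any(bm$mean_response == 0)) {
    abort(paste0(
      "Blank mean is zero on sensor(s): ",
      paste(bm$sensor[bm$mean_response == 0], collapse = ", ")
    ))
  }
  tibble(
    sensor = gm$sensor,
    group_mean = gm$mean_response,
    blank_mean = bm$mean_response,
    ratio = gm$mean_response / bm$mean_response
  )
}

#' Sensors responding strongly relative to the blank
#'
#' A pragmatic call-out rule for radar summaries: sensors whose mean
#' ratio-to-blank exceeds `cutoff` (default 2).
#'
#' @inheritParams response_ratio
#' @param cutoff Ratio above which a sensor counts as a strong responder.
#' @return Character vector of sensor names, strongest first.
#' @export
strong_responders <- function(x, group, blank, cutoff = 2,
                              group_col = "group") {
  rr <- response_ratio(x, group, blank, group_col)
  rr |>
    dplyr::filter(.data$ratio > cutoff) |>
    dplyr::arrange(dplyr::desc(.data$ratio)) |>
    dplyr::pull("sensor")
}
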