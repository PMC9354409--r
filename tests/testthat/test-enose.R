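sim_sensors <- function(seed = 1, noise = 0.15, replicates = 6) {
  simulate_sensor_matrix(
    sim_config(seed = seed, sensor_noise_sd = noise, replicates = replicates)
  )$sensors
}

test_that("sensor matrices are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c("group,W1C,W5S", "a,1,2", "a,1.5,2.5", "b,3,4"),
    path
  )
  x <- read_sensor_matrix(path)
  expect_equal(nrow(x), 3)
  expect_identical(sensor_names <- setdiff(names(x), "group"), c("W1C", "W5S"))

  writeLines(c("group,W1C", "a,-1", "b,1"), path)
  expect_error(read_sensor_matrix(path), "Negative")
})

test_that("collinear data put all PCA variance on PC1", {
  base <- matrix(seq(0.5, 3, length.out = 6), ncol = 1) %*%
    matrix(runif(10, 0.5, 2), nrow = 1)
  x <- dplyr::bind_cols(
    tibble::tibble(group = rep(c("a", "b"), each = 3)),
    tibble::as_tibble(`colnames<-`(base, names(pen3_sensors)))
  )
  p <- enose_pca(x, k = 2)
  expect_equal(unname(p$explained_ratio[["PC1"]]), 1, tolerance = 1e-10)
})

test_that("PCA matches a direct covariance eigendecomposition oracle", {
  x <- sim_sensors(seed = 3)
  p <- enose_pca(x, k = 3)

  m <- as.matrix(x[, -1])
  e <- eigen(stats::cov(m), symmetric = TRUE)
  total <- sum(e$values)
  expect_equal(
    unname(p$explained_ratio),
    (e$values / total)[1:3],
    tolerance = 1e-8
  )
  # loadings and scores agree up to sign
  cen <- sweep(m, 2, colMeans(m))
  for (j in 1:3) {
    expect_equal(
      abs(as.matrix(p$loadings[, -1])[, j]),
      abs(e$vectors[, j]),
      tolerance = 1e-8, ignore_attr = TRUE
    )
    expect_equal(
      abs(as.matrix(p$scores[, -1])[, j]),
      abs(cen %*% e$vectors[, j])[, 1],
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }
  # explained ratios over all components sum to 1; scores are centered
  expect_equal(sum(p$explained_full), 1, tolerance = 1e-10)
  expect_equal(colMeans(as.matrix(p$scores[, -1])), rep(0, 3),
    tolerance = 1e-10, ignore_attr = TRUE
  )
})

test_that("PCA is invariant to row order and to duplicating every row", {
  x <- sim_sensors(seed = 4)
  p1 <- enose_pca(x, k = 2)
  p2 <- enose_pca(x[rev(seq_len(nrow(x))), ], k = 2)
  expect_equal(p1$explained_ratio, p2$explained_ratio, tolerance = 1e-12)
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-10)

  dup <- dplyr::bind_rows(x, x)
  p3 <- enose_pca(dup, k = 2)
  expect_equal(p1$explained_ratio, p3$explained_ratio, tolerance = 1e-10)

  constant <- x
  for (s in setdiff(names(x), "group")) constant[[s]] <- 1
  expect_error(enose_pca(constant), "constant")
})

test_that("LDA explained ratios cover the full axis set and need >= 2 groups", {
  x <- sim_sensors(seed = 5)
  l <- enose_lda(x)
  expect_length(l$explained_ratio, 2) # 3 groups -> 2 axes
  expect_equal(sum(l$explained_ratio), 1, tolerance = 1e-10)

  single <- dplyr::filter(x, .data$group == "blank")
  expect_error(enose_lda(single), "two groups")
})

test_that("LDA matches a whitening-based generalized-eigenproblem oracle", {
  x <- sim_sensors(seed = 6)
  l <- enose_lda(x)

  m <- as.matrix(x[, -1])
  g <- x$group
  p <- ncol(m)
  mu <- colMeans(m)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (lev in unique(g)) {
    rows <- m[g == lev, , drop = FALSE]
    cen <- sweep(rows, 2, colMeans(rows))
    sw <- sw + crossprod(cen)
    sb <- sb + nrow(rows) * tcrossprod(colMeans(rows) - mu)
  }
  sw_r <- sw + diag(1e-8 * sum(diag(sw)), p)
  es <- eigen(sw_r, symmetric = TRUE)
  wh <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  ev <- eigen(wh %*% sb %*% wh, symmetric = TRUE)$values
  expect_equal(
    unname(l$explained_ratio),
    (ev / sum(ev[1:2]))[1:2],
    tolerance = 1e-8
  )
})

test_that("LDA eigenvalue proportions agree with MASS::lda on balanced groups", {
  skip_if_not_installed("MASS")
  x <- sim_sensors(seed = 7)
  l <- enose_lda(x)
  fit <- MASS::lda(as.matrix(x[, -1]), grouping = x$group)
  expect_equal(
    unname(l$explained_ratio),
    unname(fit$svd^2 / sum(fit$svd^2)),
    tolerance = 1e-6
  )
})

test_that("well-separated groups are fully split along LD1", {
  sim <- simulate_sensor_matrix(
    sim_config(seed = 8, sensor_noise_sd = 0.05, replicates = 8)
  )
  two <- dplyr::filter(sim$sensors, .data$group != "mutant")
  l <- enose_lda(two)
  s <- split(l$scores$LD1, l$scores$group)
  expect_true(max(s[[1]]) < min(s[[2]]) || max(s[[2]]) < min(s[[1]]))

  # when one contrast (fermented vs blank) dwarfs the strain difference,
  # LD1 dominates the discriminant variance
  dominant <- default_sensor_means()
  dominant["mutant", ] <- dominant["wild", ] * 1.08
  sim3 <- simulate_sensor_matrix(
    sim_config(seed = 8, sensor_means = dominant, sensor_noise_sd = 0.05)
  )
  expect_gt(unname(enose_lda(sim3$sensors)$explained_ratio[["LD1"]]), 0.9)
})

test_that("radar profiles are per-sensor group means in array order", {
  x <- sim_sensors(seed = 9)
  r <- radar_profile(x, "wild")
  expect_identical(r$sensor, names(pen3_sensors))
  m <- as.matrix(x[x$group == "wild", -1])
  expect_equal(r$mean_response, unname(colMeans(m)))

  onerow <- x[c(1, which(x$group == "wild")[1]), ]
  r1 <- radar_profile(onerow, "wild")
  expect_equal(r1$mean_response, unname(as.matrix(onerow[2, -1])[1, ]),
    ignore_attr = TRUE
  )
  expect_error(radar_profile(x, "nope"), "Unknown group")
})

test_that("response ratios divide group means by blank means", {
  x <- sim_sensors(seed = 10)
  rr <- response_ratio(x, "wild", "blank")
  expect_equal(
    rr$ratio,
    radar_profile(x, "wild")$mean_response /
      radar_profile(x, "blank")$mean_response
  )
  # identity: a group against itself is all ones
  expect_equal(response_ratio(x, "blank", "blank")$ratio, rep(1, 10))

  zero <- x
  zero$W1C[zero$group == "blank"] <- 0
  expect_error(response_ratio(zero, "wild", "blank"), "W1C")
})

test_that("noise-free default sensor means reproduce the configured sulfide ratios", {
  sim <- simulate_sensor_matrix(sim_config(seed = 1, sensor_noise_sd = 0))
  rw <- response_ratio(sim$sensors, "wild", "blank")
  rm_ <- response_ratio(sim$sensors, "mutant", "blank")
  expect_equal(rw$ratio[rw$sensor == "W1W"], 5.15)
  expect_equal(rm_$ratio[rm_$sensor == "W1W"], 4.27)
  expect_setequal(
    strong_responders(sim$sensors, "wild", "blank"),
    c("W1W", "W5S", "W1S", "W2S", "W2W")
  )
})
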