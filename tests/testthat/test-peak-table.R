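test_that("CSV parsing maps dash/empty cells to non-detections and keeps group order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c(
      "compound,formula,class,odor,g1,g2",
      "a,,ester,Fruity,1,2",
      "b,,alcohol,,-,3",
      "c,,aldehyde,,4,–"
    ),
    path
  )
  pt <- read_peak_table(path, mode = "area")
  expect_s3_class(pt, "peak_tbl")
  expect_identical(peak_groups(pt), c("g1", "g2"))
  expect_identical(pt$g1, c(1, NA, 4))
  expect_identical(pt$g2, c(2, 3, NA))
  expect_true(is.na(pt$odor[2]))
})

test_that("validation rejects duplicates, negatives, and unknown classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c("compound,class,g1", "a,ester,1", "A ,ester,2"),
    path
  )
  expect_error(read_peak_table(path, "area"), "Duplicate compound.*a|A")

  expect_error(
    make_peaks(matrix(-1, 1, 1, dimnames = list("a", "g1"))),
    "Negative"
  )
  expect_error(
    peak_table(
      tibble::tibble(compound = "a", class = "ketone", g1 = 1),
      "area"
    ),
    "Unknown chem class"
  )
})

test_that("the bundled strain fixture loads with the published shape", {
  pt <- geotrichum_peaks()
  expect_equal(nrow(pt), 38)
  expect_identical(peak_groups(pt), c("blank", "wild", "mutagenic"))
  expect_equal(detected_count(pt, "wild"), 30)
  expect_equal(detected_count(pt, "mutagenic"), 31)
  expect_equal(detected_count(pt, "blank"), 8)
})

test_that("relative contents are forced proportions summing to 100 per group", {
  pt <- make_peaks(matrix(c(2, 3, 5), ncol = 1, dimnames = list(NULL, "g1")))
  rc <- relative_content(pt)
  expect_equal(rc$g1, c(20, 30, 50))

  one <- relative_content(
    make_peaks(matrix(5, 1, 1, dimnames = list("a", "g1")))
  )
  expect_equal(one$g1, 100)

  # property: sums to 100, scale-invariant, idempotent (random tables)
  for (seed in 1:5) {
    areas <- withr::with_seed(
      seed,
      matrix(rlnorm(20, 10, 1), ncol = 2, dimnames = list(NULL, c("a", "b")))
    )
    rc <- relative_content(make_peaks(areas))
    expect_equal(sum(rc$a), 100)
    expect_equal(sum(rc$b), 100)
    scaled <- relative_content(make_peaks(areas * 7.3))
    expect_equal(rc$a, scaled$a)
    expect_equal(tibble::as_tibble(relative_content(rc)), tibble::as_tibble(rc))
  }
})

test_that("normalization refuses groups without any positive value", {
  pt <- make_peaks(
    matrix(c(1, 2, NA, NA), ncol = 2, dimnames = list(NULL, c("ok", "empty")))
  )
  expect_error(relative_content(pt), "empty")
})

test_that("out-of-tolerance relative-content sums raise a classed warning", {
  vals <- matrix(c(60, 30), ncol = 1, dimnames = list(NULL, "g1"))
  expect_warning(
    make_peaks(vals, mode = "relative_content"),
    class = "roav_sum_warning"
  )
  expect_silent(make_peaks(vals, mode = "relative_content", sum_tol = 15))
})

test_that("detection counts split by class and add up across classes", {
  pt <- geotrichum_peaks()
  for (g in peak_groups(pt)) {
    ct <- class_totals(pt, g)
    expect_setequal(ct$chem_class, chem_classes)
    expect_equal(sum(ct$n), detected_count(pt, g))
  }
  ct <- class_totals(pt, "wild")
  expect_equal(ct$n[ct$chem_class == "ester"], 27)
  expect_equal(ct$total[ct$chem_class == "ester"], 91.96)
  expect_equal(ct$n[ct$chem_class == "other"], 0)
  expect_equal(ct$total[ct$chem_class == "other"], 0)
})

test_that("top compounds agree with a full-sort oracle and truncate cleanly", {
  pt <- geotrichum_peaks()
  top5 <- top_compounds(pt, "wild", 5)
  expect_identical(
    sort(top5$compound),
    sort(c(
      "Ethyl 3-methyl butyrate", "Ethyl hexanoate", "Phenylacetaldehyde",
      "Ethyl isobutyrate", "Ethyl 2-methyl butyrate"
    ))
  )
  expect_equal(sum(top5$value), 60.55, tolerance = 1e-8)

  for (seed in 1:3) {
    areas <- withr::with_seed(
      seed,
      matrix(rlnorm(15, 5, 2), ncol = 1, dimnames = list(NULL, "g1"))
    )
    pt2 <- make_peaks(areas)
    got <- top_compounds(pt2, "g1", 7)
    oracle <- tibble::tibble(compound = pt2$compound, value = pt2$g1)
    oracle <- oracle[order(-oracle$value, oracle$compound), ][1:7, ]
    expect_equal(got, tibble::as_tibble(oracle), ignore_attr = TRUE)
  }

  all_of_them <- top_compounds(pt, "blank", 99)
  expect_equal(nrow(all_of_them), 8)
  expect_error(top_compounds(pt, "nope", 5), "Unknown group")
})

test_that("peak tables round-trip through CSV with dash markers", {
  pt <- geotrichum_peaks()
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(pt, path)
  back <- read_peak_table(path, "relative_content", sum_tol = 3.5)
  expect_equal(detected_count(back), detected_count(pt))
  expect_equal(back$wild, pt$wild, tolerance = 1e-9)
})
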