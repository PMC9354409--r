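# Expected ROAVs below are hand-recomputable from the fixture inputs:
# ROAV = (C / C_ref) * (T_ref / T) * 100 with reference ethyl isobutyrate
# (C_ref 8.03 wild / 8.48 mutagenic, T_ref 0.1 ug/L).

test_that("the reference compound maximizes content/threshold", {
  pt <- geotrichum_peaks()
  db <- geotrichum_thresholds()
  expect_identical(select_reference(pt, db, "wild"), "Ethyl isobutyrate")
  expect_identical(select_reference(pt, db, "mutagenic"), "Ethyl isobutyrate")

  # single thresholded compound is its own reference
  one <- relative_content(
    make_peaks(matrix(3, 1, 1, dimnames = list("solo", "g1")))
  )
  expect_identical(select_reference(one, make_db("solo", 2), "g1"), "solo")

  # random tables agree with a brute-force argmax of C/T
  for (seed in 1:5) {
    setup <- random_scored_setup(n = 12, seed = seed)
    got <- select_reference(setup$peaks, setup$db, "g1")
    ct <- setup$peaks$g1 / setup$db$entries$low[
      match(tolower(setup$peaks$compound), tolower(setup$db$entries$compound))
    ]
    expect_identical(got, setup$peaks$compound[which.max(ct)])
  }
})

test_that("ROAV scores reproduce the published wild-type column", {
  sc <- roav_score(15.44, 1, ref_content = 8.03, ref_threshold = 0.1)
  expect_equal(round(sc$roav_high, 2), 19.23)

  # the reference scores exactly 100 against itself
  self <- roav_score(8.03, 0.1, ref_content = 8.03, ref_threshold = 0.1)
  expect_equal(self$roav_low, 100)
  expect_equal(self$roav_high, 100)

  # interval threshold: endpoints swap order (anti-monotone in T)
  iv <- roav_score(5.82, 3, 5, ref_content = 8.03, ref_threshold = 0.1)
  expect_equal(round(iv$roav_low, 2), 1.45)
  expect_equal(round(iv$roav_high, 2), 2.42)

  # mixed units: ug/kg magnitude used as-is
  pea <- roav_score(7.63, 4, ref_content = 8.48, ref_threshold = 0.1)
  expect_equal(round(pea$roav_high, 2), 2.25)

  expect_error(roav_score(1, 0, ref_content = 1, ref_threshold = 1), "positive")
})

test_that("ROAV is scale-invariant and monotone in content and threshold", {
  for (seed in 1:5) {
    vals <- withr::with_seed(seed, list(
      c = runif(1, 0.1, 30), t = runif(1, 0.1, 10),
      cr = runif(1, 1, 30), tr = runif(1, 0.05, 5)
    ))
    base <- roav_score(vals$c, vals$t,
      ref_content = vals$cr, ref_threshold = vals$tr
    )$roav_high
    # rescaling all contents by the same factor changes nothing (ratio form)
    scaled <- roav_score(vals$c * 3.7, vals$t,
      ref_content = vals$cr * 3.7, ref_threshold = vals$tr
    )$roav_high
    expect_equal(base, scaled)
    # strictly increasing in content, strictly decreasing in threshold
    expect_gt(
      roav_score(vals$c * 1.1, vals$t,
        ref_content = vals$cr, ref_threshold = vals$tr
      )$roav_high,
      base
    )
    expect_lt(
      roav_score(vals$c, vals$t * 1.1,
        ref_content = vals$cr, ref_threshold = vals$tr
      )$roav_high,
      base
    )
  }
})

test_that("classification bins assign key/modified/potential as documented", {
  expect_identical(classify_roav(19.23), "key")
  expect_identical(classify_roav(0.94), "modified")
  expect_identical(classify_roav(NA_real_), "potential")
  expect_identical(classify_roav(0.005), "potential")
  # configurable boundaries
  expect_identical(
    classify_roav(0.05, roav_bins(potential_max = 0.1)),
    "potential"
  )
  expect_error(roav_bins(key_min = 0.01, potential_max = 1), "potential_max")
})

test_that("the assembled wild-type ROAV table matches the published analysis", {
  w <- build_roav_table(geotrichum_peaks(), geotrichum_thresholds(), "wild")
  expect_identical(attr(w, "reference"), "Ethyl isobutyrate")
  expect_equal(max(w$roav_high, na.rm = TRUE), 100)
  expect_equal(sum(w$roav_high == 100, na.rm = TRUE), 1)

  expect_equal(glance(w)$n_key, 11)
  # published contribution ranking, head and tail
  key <- w$compound[w$odor_class == "key"][order(w$rank[w$odor_class == "key"])]
  expect_identical(
    key[1:3],
    c("Ethyl isobutyrate", "Ethyl hexanoate", "Ethyl 2-methyl butyrate")
  )
  expect_identical(key[10:11], c("Ethyl heptanoate", "Isobutyl isovalerate"))

  val <- function(cmp) w$roav_high[match(cmp, w$compound)]
  expect_equal(val("Ethyl 3-methyl butyrate"), 8.62, tolerance = 0.01)
  expect_equal(val("Ethyl caprylate"), 2.85, tolerance = 0.01)
  expect_equal(val("Butyric acid ethyl ester"), 2.34, tolerance = 0.01)
  expect_equal(val("Ethyl caprate"), 0.02, tolerance = 0.5)
  expect_identical(
    w$roav[w$compound == "Methyl 3-methyl-2-butenoate"],
    "2.42–1.45"
  )

  # no-threshold compounds stay in the table as potential, ROAV undefined
  miv <- w[w$compound == "Methyl isovalerate", ]
  expect_true(is.na(miv$roav_high))
  expect_identical(miv$odor_class, "potential")
  expect_equal(nrow(w), 30)
})

test_that("the mutagenic-type table yields nine key compounds ending in phenylethyl alcohol", {
  m <- build_roav_table(geotrichum_peaks(), geotrichum_thresholds(), "mutagenic")
  expect_equal(glance(m)$n_key, 9)
  key <- m$compound[m$odor_class == "key"][order(m$rank[m$odor_class == "key"])]
  expect_identical(key[1:2], c("Ethyl isobutyrate", "Ethyl hexanoate"))
  expect_identical(key[8:9], c("Butyric acid ethyl ester", "Phenylethyl alcohol"))
  val <- function(cmp) m$roav_high[match(cmp, m$compound)]
  expect_equal(val("Ethyl 3-methyl butyrate"), 9.25, tolerance = 0.01)
  expect_equal(val("Ethyl caprylate"), 3.13, tolerance = 0.01)
  expect_equal(val("Phenylethyl alcohol"), 2.25, tolerance = 0.01)
})

test_that("a single-compound table scores its compound as the 100-point key reference", {
  one <- relative_content(
    make_peaks(matrix(4, 1, 1, dimnames = list("solo", "g1")))
  )
  tbl <- build_roav_table(one, make_db("solo", 2), "g1")
  expect_equal(tbl$roav_high, 100)
  expect_identical(tbl$odor_class, "key")
  expect_equal(tbl$rank, 1L)
})

test_that("key ranks are 1..k and consistent with descending upper ROAV", {
  for (seed in 1:5) {
    setup <- random_scored_setup(n = 15, seed = seed)
    tbl <- build_roav_table(setup$peaks, setup$db, "g1")
    key <- tbl[tbl$odor_class == "key", ]
    expect_identical(sort(key$rank), seq_len(nrow(key)))
    expect_true(all(diff(key$roav_high[order(key$rank)]) <= 0))
    expect_true(all(is.na(tbl$rank[tbl$odor_class != "key"])))
  }
})
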