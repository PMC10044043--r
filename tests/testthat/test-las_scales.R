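test_that("the built-in catalogue matches the published scale system", {
  does <- builtin_scales("doe")
  bucks <- builtin_scales("buck")
  expect_length(does, 17)
  expect_length(bucks, 10)
  # bucks carry no mammary-system traits
  expect_false(any(vapply(bucks, `[[`, "", "major_area") ==
                     "mammary_system"))
  # traits scored with the same criteria in both sexes
  shared <- names(does)[vapply(does, `[[`, TRUE, "shared_with_bucks")]
  expect_setequal(shared, c("body_depth", "angularity", "bone_quality",
                            "rear_legs_rear_view", "rear_legs_side_view",
                            "mobility"))
  st <- does$stature
  expect_equal(c(st$zoometric_min, st$midpoint, st$zoometric_max),
               c(62, 70, 78))
  ra <- does$rump_angle
  expect_equal(ra$direction, "decreasing")
  expect_equal(c(ra$zoometric_min, ra$midpoint, ra$zoometric_max),
               c(55, 43, 31))
})

test_that("zoometric translation hits the printed anchors and optima", {
  does <- builtin_scales("doe")
  expect_equal(zoometric_to_las(70, does$stature), 5L)
  expect_equal(zoometric_to_las(62, does$stature), 1L)
  expect_equal(zoometric_to_las(78, does$stature), 9L)
  # inverted-direction trait: optimum 3 cm scores 9
  expect_equal(zoometric_to_las(3, does$rear_insertion_height), 9L)
  expect_equal(zoometric_to_las(11, does$rear_insertion_height), 1L)
  # knotted scale: anterior insertion 45 -> 1, 90 -> 5, 120 -> 9
  expect_equal(zoometric_to_las(c(45, 90, 120), does$anterior_insertion),
               c(1L, 5L, 9L))
  # exhaustive: every published optimum measurement maps to its optimum
  # score, for does and bucks
  for (sex in c("doe", "buck")) {
    for (sc in builtin_scales(sex)) {
      if (sc$type != "measured") next
      expect_equal(zoometric_to_las(sc$optimum_zoometric, sc),
                   sc$optimum_score,
                   info = paste(sex, sc$trait))
    }
  }
  # clipping and categorical errors
  expect_equal(zoometric_to_las(200, does$stature), 9L)
  expect_error(zoometric_to_las(5, does$mobility), "categorical")
  expect_error(zoometric_to_las("x", does$stature))
})

test_that("translation is monotone in the measurement", {
  does <- builtin_scales("doe")
  for (nm in names(does)) {
    sc <- does[[nm]]
    if (sc$type != "measured") next
    lo <- min(sc$zoometric_min, sc$zoometric_max)
    hi <- max(sc$zoometric_min, sc$zoometric_max)
    grid <- seq(lo, hi, length.out = 41)
    scores <- zoometric_to_las(grid, sc)
    d <- diff(scores)
    if (sc$direction == "increasing") {
      expect_true(all(d >= 0), info = nm)
    } else {
      expect_true(all(d <= 0), info = nm)
    }
  }
})

test_that("scale inversion is the involution K + 1 - s", {
  sc9 <- builtin_scales("doe")$rear_insertion_height
  expect_equal(invert_scale(9L, sc9), 1L)
  expect_equal(invert_scale(5L, sc9), 5L)
  expect_equal(invert_scale(invert_scale(1:9, sc9), sc9), 1:9)
  sc5 <- builtin_scales("doe", "proposal")$rear_insertion_height
  expect_equal(sc5$las_max, 5L)
  expect_equal(invert_scale(2L, sc5), 4L)
  expect_error(invert_scale(10L, sc9), "outside")
})

test_that("final score weights, thresholds and qualifications", {
  expect_equal(sum(area_weights("doe")), 100)
  expect_equal(sum(area_weights("buck")), 100)
  all100 <- stats::setNames(rep(100, 4), names(area_weights("doe")))
  fs <- final_score(all100, "doe")
  expect_equal(fs$score, 100)
  expect_equal(fs$qualification, "E")
  all84 <- stats::setNames(rep(84, 4), names(area_weights("doe")))
  expect_equal(final_score(all84, "doe")$qualification, "BB")
  b69 <- stats::setNames(rep(69, 3), names(area_weights("buck")))
  fb <- final_score(b69, "buck")
  expect_equal(fb$score, 69)
  expect_equal(fb$qualification, "IN")
  # 69.5 rounds half away from zero before classification -> 70 -> R
  b695 <- stats::setNames(rep(69.5, 3), names(area_weights("buck")))
  expect_equal(final_score(b695, "buck")$qualification, "R")
  expect_error(final_score(all100[-1], "doe"), "missing area")
})

test_that("score cards aggregate trait scores through areas to a final score", {
  does <- builtin_scales("doe")
  optimal <- vapply(does, function(s) as.numeric(s$optimum_score_agg), 0)
  rec <- as.data.frame(as.list(optimal))
  rec$animal <- "doe1"
  card <- score_records(rec, "doe")
  expect_equal(card$final_score, 100)
  expect_equal(card$qualification, "E")
  # inversion policy flips the two insertion traits
  card_inv <- score_records(rec, "doe", invert_policy = TRUE)
  expect_equal(card_inv$rear_insertion_height,
               10L - rec$rear_insertion_height)
  expect_lt(card_inv$final_score, 100)
})

test_that("the catalogue round-trips through a YAML config", {
  tmp <- withr::local_tempfile(fileext = ".yml")
  scales <- builtin_scales("doe")
  write_scales(scales, tmp)
  back <- read_scales(tmp)
  expect_equal(names(back), names(scales))
  expect_equal(back$stature$midpoint, 70)
  expect_equal(back$anterior_insertion$knots[, "score"], c(1, 5, 9),
               ignore_attr = TRUE)
  # translation behaves identically after the round trip
  expect_equal(zoometric_to_las(64.2, back$stature),
               zoometric_to_las(64.2, scales$stature))
})
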