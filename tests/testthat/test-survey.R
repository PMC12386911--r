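# Ground-survey validation: filtering, point-in-box matching, accuracy rate.

test_that("confidence filtering is strictly greater-than", {
  d <- data.frame(cx = 1:3, cy = 1, w = 1, h = 1, class_id = 0L,
                  confidence = c(0.59, 0.60, 0.61))
  kept <- filterByConfidence(d, 0.60)
  expect_equal(kept$confidence, 0.61)
  expect_equal(nrow(filterByConfidence(d[0, ], 0.6)), 0)
  expect_equal(nrow(filterByConfidence(d, 0)), 3)
  expect_equal(filterByConfidence(d, 0)$cx, 1:3)  # order preserved
})

test_that("points match Weak boxes only, boundary inclusive", {
  dets <- data.frame(image_id = "a",
                     cx = c(50, 150), cy = c(50, 50), w = 20, h = 20,
                     class_id = c(0L, 1L), confidence = 0.9)
  pts <- data.frame(image_id = "a",
                    x = c(50, 150, 40, 300), y = c(50, 50, 40, 300),
                    category = "previously_damaged")
  m <- matchSurveyPoints(pts, dets)
  expect_equal(m, c(TRUE, FALSE, TRUE, FALSE))  # dead box never matches;
  # (40,40) sits exactly on the weak box corner -> inclusive match
  expect_error(matchSurveyPoints(pts, dets, image_ids = "b"), "unknown image")
})

test_that("point matching equals exhaustive point-in-rectangle enumeration", {
  set.seed(44)
  dets <- data.frame(image_id = sample(c("a", "b"), 8, TRUE),
                     cx = runif(8, 20, 180), cy = runif(8, 20, 180),
                     w = runif(8, 10, 40), h = runif(8, 10, 40),
                     class_id = rep(0L, 8), confidence = 0.9)
  pts <- data.frame(image_id = sample(c("a", "b"), 10, TRUE),
                    x = runif(10, 0, 200), y = runif(10, 0, 200),
                    category = "newly_damaged")
  got <- matchSurveyPoints(pts, dets)
  want <- vapply(seq_len(10), function(i) {
    hit <- FALSE
    for (j in seq_len(8)) {
      if (dets$image_id[j] != pts$image_id[i]) next
      if (pts$x[i] >= dets$cx[j] - dets$w[j] / 2 &&
          pts$x[i] <= dets$cx[j] + dets$w[j] / 2 &&
          pts$y[i] >= dets$cy[j] - dets$h[j] / 2 &&
          pts$y[i] <= dets$cy[j] + dets$h[j] / 2) hit <- TRUE
    }
    hit
  }, logical(1))
  expect_equal(got, want)
})

test_that("matching is monotone in added detections", {
  set.seed(45)
  pts <- data.frame(image_id = "a", x = runif(12, 0, 100),
                    y = runif(12, 0, 100), category = "newly_damaged")
  dets <- data.frame(image_id = "a", cx = runif(5, 0, 100),
                     cy = runif(5, 0, 100), w = 25, h = 25, class_id = 0L,
                     confidence = 0.9)
  before <- matchSurveyPoints(pts, dets)
  more <- rbind(dets, data.frame(image_id = "a", cx = 50, cy = 50, w = 40,
                                 h = 40, class_id = 0L, confidence = 0.9))
  after <- matchSurveyPoints(pts, more)
  expect_true(all(after >= before))
})

test_that("accuracy rate reproduces the published field-survey arithmetic", {
  expect_equal(accuracyRate(70, 68), 97.14)
  expect_equal(accuracyRate(11, 10), 90.91)
  expect_equal(accuracyRate(81, 78), 96.30)
  expect_error(accuracyRate(0, 0), "undefined")
  expect_error(accuracyRate(5, 6))
  # scale invariance in the counts
  expect_equal(accuracyRate(7, 5), accuracyRate(70, 50))
  # half-up rounding at the boundary
  expect_equal(accuracyRate(2000, 1259), 62.95)
})

test_that("the survey report reproduces the worked example end to end", {
  ex <- surveyWorkedExample()
  rep <- buildSurveyReport(ex$points, ex$detections)
  rates <- surveyRates(rep)
  expect_equal(rates$AR[rates$category == "previously_damaged"], 97.14)
  expect_equal(rates$AR[rates$category == "newly_damaged"], 90.91)
  ov <- surveyOverall(rep)
  expect_equal(ov$AR, 96.30)
  expect_equal(ov$DT, 81); expect_equal(ov$SD, 78)
  expect_equal(rep@detections$weak, 92)
  expect_equal(rep@detections$dead, 20)
  # overall is computed from summed counts, not the mean of category rates
  expect_false(isTRUE(all.equal(ov$AR, mean(rates$AR))))
})

test_that("survey report hits degenerate all/none matched cases", {
  pts <- data.frame(image_id = "a", x = c(10, 20), y = c(10, 20),
                    category = c("previously_damaged", "newly_damaged"))
  none <- buildSurveyReport(pts, data.frame(image_id = character(),
                                            cx = numeric(), cy = numeric(),
                                            w = numeric(), h = numeric(),
                                            class_id = integer(),
                                            confidence = numeric()))
  expect_true(all(surveyRates(none)$AR == 0))
  all_ <- buildSurveyReport(pts, data.frame(image_id = "a", cx = 15, cy = 15,
                                            w = 30, h = 30, class_id = 0L,
                                            confidence = 0.95))
  expect_true(all(surveyRates(all_)$AR == 100))
  # a confidence filter of 1.0 drops every detection
  conf1 <- buildSurveyReport(pts, data.frame(image_id = "a", cx = 15, cy = 15,
                                             w = 30, h = 30, class_id = 0L,
                                             confidence = 0.95),
                             conf_threshold = 1.0)
  expect_true(all(surveyRates(conf1)$AR == 0))
})

test_that("survey CSV and report files round trip", {
  ex <- surveyWorkedExample()
  f <- tempfile(fileext = ".csv")
  utils::write.csv(ex$points, f, row.names = FALSE)
  back <- readSurveyPoints(f)
  expect_equal(nrow(back), nrow(ex$points))
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(image_id = "a", x = 1, y = 1,
                              category = "mystery"), bad, row.names = FALSE)
  expect_error(readSurveyPoints(bad), "unknown survey categories")
  rep <- buildSurveyReport(ex$points, ex$detections)
  txt <- tempfile(fileext = ".txt"); js <- tempfile(fileext = ".json")
  writeSurveyReport(rep, txt, js)
  expect_match(paste(readLines(txt), collapse = "\n"), "97.14")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$overall$AR, 96.30)
  expect_equal(parsed$detections$weak, 92)
})
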