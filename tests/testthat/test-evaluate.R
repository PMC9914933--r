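# A fixed small level space for assignment tests: centers on the unit
# diagonal at 0, 0.3 and 1 (already level-ordered by distance to origin).
fixed_space <- function() {
  ctr <- rbind(Low = c(0, 0, 0), Medium = c(0.3, 0.3, 0.3), High = c(1, 1, 1))
  colnames(ctr) <- c("nipi", "thq", "tcr")
  nrm <- list(min = c(nipi = 0, thq = 0, tcr = 0),
              max = c(nipi = 2, thq = 4, tcr = 0.01))
  ctrO <- sweep(sweep(ctr, 2, nrm$max - nrm$min, "*"), 2, nrm$min, "+")
  new("RiskLevelSpace", k = 3L, centers = ctr, centersOriginal = ctrO,
      levels = c("Low", "Medium", "High"),
      silhouetteByK = c("3" = 0.9), normalization = nrm,
      assignment = factor(character(0), c("Low", "Medium", "High")),
      medoids = integer(0), cost = 0)
}

test_that("points at a center take that center's level at distance zero", {
  sp <- fixed_space()
  orig <- sp@centersOriginal
  out <- assignLevel(orig, sp)
  expect_equal(as.character(out$level), c("Low", "Medium", "High"))
  expect_equal(out$Low[1], 0)
  expect_equal(out$Medium[2], 0)
  expect_equal(out$High[3], 0)
})

test_that("equidistant points break ties toward the lower level", {
  sp <- fixed_space()
  mid <- (sp@centersOriginal[1, ] + sp@centersOriginal[2, ]) / 2
  out <- assignLevel(matrix(mid, 1, dimnames = list(NULL, c("nipi", "thq", "tcr"))), sp)
  expect_equal(as.character(out$level), "Low")
  expect_equal(out$Low, out$Medium, tolerance = 1e-12)
})

test_that("assignment agrees with a brute-force nearest-center scan", {
  sp <- fixed_space()
  set.seed(3)
  pts <- cbind(nipi = runif(100, 0, 2.5), thq = runif(100, 0, 5),
               tcr = runif(100, 0, 0.012))
  got <- assignLevel(pts, sp)
  nrm <- sp@normalization
  for (i in 1:100) {
    z <- (pts[i, ] - nrm$min) / (nrm$max - nrm$min)
    d <- apply(sp@centers, 1, function(ctr) sqrt(sum((z - ctr)^2)))
    expect_equal(as.character(got$level[i]), names(which.min(d)))
  }
})

test_that("regression metrics match hand evaluation and satisfy RMSE >= MAE", {
  expect_equal(regressionMetrics(c(1, 2), c(1, 2)), c(rmse = 0, mae = 0))
  expect_equal(regressionMetrics(c(0, 0), c(1, 1)), c(rmse = 1, mae = 1))
  got <- regressionMetrics(c(0, 0), c(1, 3))
  expect_equal(got[["rmse"]], sqrt(5), tolerance = 1e-12)
  expect_equal(got[["mae"]], 2)
  expect_error(regressionMetrics(1:3, 1:2), "equal")
  set.seed(7)
  for (r in 1:20) {
    y <- rnorm(10); yh <- rnorm(10)
    m <- regressionMetrics(y, yh)
    expect_gte(m[["rmse"]], m[["mae"]])
  }
})

test_that("classification metrics match the hand-worked counts", {
  # a two-class label stream engineered to give TP=9, FP=1, FN=3 for "A"
  truth <- c(rep("A", 12), rep("B", 8))
  pred <- c(rep("A", 9), rep("B", 3), "A", rep("B", 7))
  got <- classificationMetrics(truth, pred, levels = c("A", "B"))
  a <- got[got$level == "A", ]
  expect_equal(a$tp, 9); expect_equal(a$fp, 1); expect_equal(a$fn, 3)
  expect_equal(a$precision, 90)
  expect_equal(a$recall, 75)
  expect_equal(a$f1, 81.818, tolerance = 1e-3)
  # F1 is the harmonic mean of P and R
  expect_equal(a$f1, 2 * a$precision * a$recall / (a$precision + a$recall))
})

test_that("perfect predictions score 100 everywhere; swapping swaps P and R", {
  lv <- c("Low", "Medium", "High")
  truth <- sample(rep(lv, times = c(10, 6, 4)))
  perfect <- classificationMetrics(truth, truth, levels = lv)
  expect_equal(perfect$precision, rep(100, 3))
  expect_equal(perfect$recall, rep(100, 3))
  expect_equal(perfect$f1, rep(100, 3))
  set.seed(11)
  pred <- sample(lv, length(truth), replace = TRUE)
  ab <- classificationMetrics(truth, pred, levels = lv)
  ba <- classificationMetrics(pred, truth, levels = lv)
  expect_equal(ab$precision, ba$recall)
  expect_equal(ab$recall, ba$precision)
  expect_error(classificationMetrics(truth, c(pred[-1], "Severe"), levels = lv),
               "outside")
})

test_that("zero-denominator metrics warn and report zero", {
  truth <- c("Low", "Low", "Medium")
  pred <- c("Low", "Low", "Low")
  w <- capture_warnings(
    got <- classificationMetrics(truth, pred,
                                 levels = c("Low", "Medium", "High")))
  expect_true(all(grepl("zero denominator", w)))
  expect_length(w, 3)                    # Medium recall, High precision+recall
  m <- got[got$level == "Medium", ]
  expect_equal(m$recall, 0)
  h <- got[got$level == "High", ]
  expect_equal(h$precision, 0)
  expect_equal(h$f1, 0)
})

test_that("micro-averaged recall equals overall accuracy", {
  lv <- c("Low", "Medium", "High")
  set.seed(13)
  truth <- sample(lv, 60, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  pred <- ifelse(runif(60) < 0.8, truth, sample(lv, 60, replace = TRUE))
  suppressWarnings(got <- classificationMetrics(truth, pred, levels = lv))
  micro <- sum(got$tp) / (sum(got$tp) + sum(got$fn))
  expect_equal(micro, mean(truth == pred), tolerance = 1e-12)
})

test_that("a forecast equal to the truth evaluates to zero error and 100%", {
  set.seed(17)
  tb <- random_tables(nProv = 3, nWeeks = 30, nPerWeek = 4)
  ie <- buildIndicatorSeries(tb$samples, tb$consumption, lod = tb$lod)
  sp <- gradeRiskSpace(ie, kCandidates = 2:3, seed = 1, nRestarts = 5)
  truthDf <- indicatorTable(ie)
  sub <- truthDf[truthDf$week > 24, ]
  pred <- do.call(rbind, lapply(c("nipi", "thq", "tcr"), function(ind)
    data.frame(province = sub$province, week = sub$week, indicator = ind,
               value = sub[[ind]])))
  fr <- new("ForecastResult", predictions = pred, splitWeek = 24L,
            horizon = 6L, method = "oracle")
  rep_ <- evaluatePipeline(ie, fr, sp)
  expect_equal(regressionReport(rep_)$rmse, rep(0, 3))
  expect_equal(regressionReport(rep_)$mae, rep(0, 3))
  cls <- classificationReport(rep_)
  present <- cls[cls$tp + cls$fn > 0, ]
  expect_equal(present$f1, rep(100, nrow(present)))
})

test_that("a small constant offset leaves levels intact and shows up as the error", {
  sp <- fixed_space()
  set.seed(19)
  lv <- c(1, 2, 3)[sample(1:3, 40, replace = TRUE)]
  ctrO <- sp@centersOriginal
  truthPts <- ctrO[lv, , drop = FALSE]
  weeks <- rep(31:34, 10)
  prov <- rep(sprintf("P%02d", 1:10), each = 4)
  mkfr <- function(pts, method) {
    new("ForecastResult", predictions = do.call(rbind,
      lapply(1:3, function(j) data.frame(province = prov, week = weeks,
        indicator = c("nipi", "thq", "tcr")[j], value = pts[, j]))),
      splitWeek = 30L, horizon = 4L, method = method)
  }
  # offset well below half the minimum center gap in every coordinate
  off <- c(0.05, 0.1, 0.00025)            # original units
  predPts <- sweep(truthPts, 2, off, "+")
  # truth matrices laid out to match the forecast's (province, week) order
  iet <- IndicatorExperiment(
    nipi = matrix(truthPts[, 1], 10, 4, byrow = TRUE),
    thq = matrix(truthPts[, 2], 10, 4, byrow = TRUE),
    tcr = matrix(truthPts[, 3], 10, 4, byrow = TRUE),
    provinces = sprintf("P%02d", 1:10), weeks = 31:34)
  fr <- mkfr(predPts, "offset")
  rep_ <- evaluatePipeline(iet, fr, sp)
  reg <- regressionReport(rep_)
  expect_equal(reg$rmse, off, tolerance = 1e-9)
  expect_equal(reg$mae, off, tolerance = 1e-9)
  cls <- classificationReport(rep_)
  present <- cls[cls$tp + cls$fn > 0, ]
  expect_equal(present$f1, rep(100, nrow(present)))
})
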