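test_that("half-LOD substitution replaces exactly the censored entries", {
  s <- data.frame(province = "P01", week = 1,
                  cd = c(0.01, 0.30), cr = c(0.05, 0.4), as = c(0.01, 0.02),
                  cd_censored = c(TRUE, FALSE), cr_censored = c(TRUE, FALSE),
                  as_censored = c(TRUE, FALSE))
  out <- substituteLOD(s, c(cd = 0.01, cr = 0.05, as = 0.01))
  expect_equal(out$cd, c(0.005, 0.30))
  expect_equal(out$cr, c(0.025, 0.4))
  expect_equal(out$as, c(0.005, 0.02))
  expect_error(substituteLOD(s, c(cd = 0.01, cr = 0.05, as = 0.01, hg = 1)),
               "unknown metal")
  expect_error(substituteLOD(s, c(cd = 0.01, cr = 0.05)), "covering metals")
})

test_that("single-factor index is the concentration/limit ratio", {
  expect_equal(singleFactorIndex(0.2, 0.2), 1)
  expect_equal(singleFactorIndex(0, 1), 0)
  expect_equal(singleFactorIndex(0.1, 0.2), 0.5)
  expect_error(singleFactorIndex(0.1, 0), "positive")
  expect_error(singleFactorIndex(-0.1, 1), ">= 0")
})

test_that("Nemerow index combines max and mean as published", {
  expect_equal(nemerowIndex(c(1, 1, 1)), 1)
  expect_equal(nemerowIndex(c(0, 0, 0)), 0)
  expect_equal(nemerowIndex(c(0.5, 1.0, 0.2)), 0.81274, tolerance = 1e-5)
  expect_error(nemerowIndex(numeric(0)), "non-empty")
  # matrix form agrees with rowwise evaluation
  m <- matrix(runif(30), 10, 3)
  expect_equal(nemerowIndex(m), apply(m, 1, nemerowIndex))
  # algebraic envelope: Pmax/sqrt(2) <= NIPI <= Pmax
  pm <- apply(m, 1, max)
  expect_true(all(nemerowIndex(m) >= pm / sqrt(2) - 1e-12))
  expect_true(all(nemerowIndex(m) <= pm + 1e-12))
})

test_that("hazard quotient, THQ and EDI evaluate as published", {
  expect_equal(hazardQuotient(0.24, 0.05, 0.001, 60), 0.2)
  expect_equal(hazardQuotient(0.24, 0.05, 0.003, 60), 0.06667, tolerance = 1e-4)
  expect_equal(hazardQuotient(0.24, 0, 0.001, 60), 0)
  expect_error(hazardQuotient(0, 0.05, 0.001, 60), "positive")
  expect_equal(targetHazardQuotient(c(0.2, 0.1, 0.3)), 0.6)
  expect_equal(targetHazardQuotient(c(0, 0, 0)), 0)
  hq <- runif(3)
  expect_gte(targetHazardQuotient(hq), max(hq))
  expect_equal(estimatedDailyIntake(0.24, 0.05, 60), 2e-4)
  expect_equal(estimatedDailyIntake(0.24, 0.1, 60),
               2 * estimatedDailyIntake(0.24, 0.05, 60))
})

test_that("TCR reduces to sum(CSF * EDI) under the default exposure constants", {
  cst <- hmConstants()
  expect_equal(totalCarcinogenicRisk(c(cd = 2e-4, cr = 0, as = 0), cst),
               1.26e-3)
  expect_equal(totalCarcinogenicRisk(c(cd = 0, cr = 0, as = 0), cst), 0)
  set.seed(4)
  for (i in 1:25) {
    edi <- c(cd = runif(1, 0, 1e-3), cr = runif(1, 0, 1e-3),
             as = runif(1, 0, 1e-3))
    expect_equal(totalCarcinogenicRisk(edi, cst),
                 sum(cst$csf[c("cd", "cr", "as")] * edi), tolerance = 1e-15)
  }
  # non-default exposure constants break the cancellation as expected
  cst2 <- hmConstants(ef = 300)
  edi <- c(cd = 1e-4, cr = 1e-4, as = 1e-4)
  expect_equal(totalCarcinogenicRisk(edi, cst2),
               (300 / 365) * sum(cst2$csf[c("cd", "cr", "as")] * edi))
})

test_that("indicator series matches the straight-line oracle on a toy table", {
  set.seed(21)
  tb <- random_tables(nProv = 2, nWeeks = 3, nPerWeek = 1)
  ie <- buildIndicatorSeries(tb$samples, tb$consumption, lod = tb$lod)
  orc <- oracle_indicators(tb$samples, tb$consumption, tb$lod)
  got <- indicatorTable(ie)
  got <- got[order(got$province, got$week), ]
  expect_equal(got$nipi, orc$nipi, tolerance = 1e-12)
  expect_equal(got$thq, orc$thq, tolerance = 1e-12)
  expect_equal(got$tcr, orc$tcr, tolerance = 1e-12)
})

test_that("a sample exactly at the limits gives NIPI 1; all-censored weeks give the half-LOD index", {
  s <- data.frame(province = "P01", week = 1, cd = 0.2, cr = 1.0, as = 0.2,
                  cd_censored = FALSE, cr_censored = FALSE, as_censored = FALSE)
  cons <- data.frame(province = "P01", f50_kg_per_day = 0.3)
  ie <- buildIndicatorSeries(s, cons)
  expect_equal(as.vector(nipi(ie)), 1)
  sc <- data.frame(province = "P01", week = 1, cd = 0.01, cr = 0.05, as = 0.01,
                   cd_censored = TRUE, cr_censored = TRUE, as_censored = TRUE)
  iec <- buildIndicatorSeries(sc, cons, lod = c(cd = 0.01, cr = 0.05, as = 0.01))
  # P = (0.005/0.2, 0.025/1, 0.005/0.2) = (0.025, 0.025, 0.025)
  expect_equal(as.vector(nipi(iec)), 0.025)
})

test_that("indicators are invariant to sample order and monotone in concentration", {
  set.seed(31)
  tb <- random_tables(nProv = 2, nWeeks = 2, nPerWeek = 6)
  ie1 <- buildIndicatorSeries(tb$samples, tb$consumption, lod = tb$lod)
  perm <- sample(nrow(tb$samples))
  ie2 <- buildIndicatorSeries(tb$samples[perm, ], tb$consumption, lod = tb$lod)
  expect_equal(nipi(ie1), nipi(ie2))
  expect_equal(thq(ie1), thq(ie2))
  expect_equal(tcr(ie1), tcr(ie2))
  up <- tb$samples
  up$cd <- up$cd * 1.5
  up$cd_censored <- FALSE
  ie3 <- buildIndicatorSeries(up, tb$consumption, lod = tb$lod)
  expect_true(all(thq(ie3) >= thq(ie1) - 1e-12))
  expect_true(all(tcr(ie3) >= tcr(ie1) - 1e-12))
})

test_that("empty weeks are gap-filled by carrying indicators forward", {
  set.seed(41)
  tb <- random_tables(nProv = 1, nWeeks = 1, nPerWeek = 3)
  s <- tb$samples
  s2 <- s; s2$week <- 3                  # weeks 2 and 4,5 have no samples
  samples <- rbind(s, s2)
  ie <- buildIndicatorSeries(samples, tb$consumption, lod = tb$lod, nWeeks = 5)
  expect_equal(as.vector(gapFilled(ie)), c(FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(nipi(ie)[1, 2], nipi(ie)[1, 1])
  expect_equal(nipi(ie)[1, 4], nipi(ie)[1, 3])
  expect_equal(nipi(ie)[1, 5], nipi(ie)[1, 3])
})

test_that("missing consumption records are rejected", {
  set.seed(51)
  tb <- random_tables(nProv = 2, nWeeks = 2, nPerWeek = 2)
  expect_error(buildIndicatorSeries(tb$samples, tb$consumption[1, , drop = FALSE],
                                    lod = tb$lod),
               "missing consumption")
})

test_that("indicator tables round-trip through CSV", {
  set.seed(61)
  tb <- random_tables(nProv = 2, nWeeks = 3, nPerWeek = 2)
  ie <- buildIndicatorSeries(tb$samples, tb$consumption, lod = tb$lod)
  path <- tempfile(fileext = ".csv")
  writeIndicatorTable(ie, path)
  back <- readIndicatorTable(path)
  expect_equal(nipi(back), nipi(ie), tolerance = 1e-12)
  expect_equal(gapFilled(back), gapFilled(ie))
})
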