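# Structural contracts of the network building blocks and the trained
# forecaster, all at toy scale.

ns <- asNamespace("RiceRiskCast")

tiny_config <- function(...) {
  args <- list(inputLength = 12L, labelLength = 4L, horizon = 4L, d = 8L,
               nHeads = 2L, ffnDim = 16L, epochs = 2L, batchSize = 8L,
               windowStride = 1L, dropout = 0, seed = 5L)
  over <- list(...)
  args[names(over)] <- over
  do.call(forecastConfig, args)
}

tiny_series <- function(nProv = 3, nWeeks = 40, seed = 2) {
  set.seed(seed)
  wk <- seq_len(nWeeks)
  vals <- t(sapply(seq_len(nProv), function(p)
    1 + 0.3 * sin(2 * pi * wk / 13) + 0.05 * rnorm(nWeeks) + 0.2 * p))
  rownames(vals) <- sprintf("P%02d", seq_len(nProv))
  IndicatorExperiment(nipi = vals, thq = vals / 2, tcr = vals / 1e3)
}

test_that("ELU has the published two-branch form", {
  x <- ns$ad_const(matrix(c(-1, 0, 2, -3), 2, 2))
  y <- ns$op_elu(x)
  expect_equal(y$val[1, 1], exp(-1) - 1, tolerance = 1e-12)  # -0.63212
  expect_equal(y$val[2, 1], 0)
  expect_equal(y$val[1, 2], 2)
  expect_equal(y$val[2, 2], exp(-3) - 1, tolerance = 1e-12)
})

test_that("the distilling pipeline halves the sequence length", {
  set.seed(3)
  B <- 2
  for (L in c(7, 8, 12)) {
    x <- ns$ad_const(matrix(rnorm(B * L * 4), B * L, 4))
    pooled <- ns$op_maxpool(x, B, L)
    expect_equal(nrow(pooled$val), B * ceiling(L / 2))
  }
  # conv1d with same padding keeps the length
  x <- ns$ad_const(matrix(rnorm(2 * 8 * 4), 16, 4))
  W <- ns$ad_const(matrix(rnorm(12 * 4), 12, 4))
  b <- ns$ad_const(numeric(4))
  expect_equal(nrow(ns$op_conv1d(x, W, b, 2, 8, 3)$val), 16)
})

test_that("zero inputs with zero embedding tables embed to zero", {
  cfg <- tiny_config()
  p <- list(emb.val = ns$ad_const(matrix(0, 1, cfg$d)),
            emb.woy = ns$ad_const(matrix(0, 53, cfg$d)),
            emb.prov = ns$ad_const(matrix(0, 2, cfg$d)))
  emb <- ns$.embed_segment(p, cfg, numeric(12), rep(1L, 12), 1L, 12L, 1L,
                           training = FALSE)
  pe <- ns$.sinusoidal_pe(12, cfg$d)
  expect_equal(emb$val, pe)             # only the fixed positional term remains
})

test_that("decoder output is causal in the label inputs", {
  ie <- tiny_series()
  cfg <- tiny_config(epochs = 1L)
  m <- informerTrain(ie, "nipi", splitWeek = 30, config = cfg)
  set.seed(9)
  enc <- rnorm(cfg$inputLength)
  lab <- rnorm(cfg$labelLength)
  base <- informerForward(m, enc, lab, startWeek = 5, province = 2)
  for (t in 2:cfg$labelLength) {
    lab2 <- lab
    lab2[t] <- lab2[t] + 1
    pert <- informerForward(m, enc, lab2, startWeek = 5, province = 2)
    expect_lt(max(abs(pert[seq_len(t - 1)] - base[seq_len(t - 1)])), 1e-6)
    # and later positions do react in general
    expect_gt(max(abs(pert - base)), 1e-8)
  }
})

test_that("perturbing the encoder input moves every decoder position", {
  ie <- tiny_series()
  cfg <- tiny_config(epochs = 1L)
  m <- informerTrain(ie, "nipi", splitWeek = 30, config = cfg)
  set.seed(13)
  enc <- rnorm(cfg$inputLength)
  lab <- rnorm(cfg$labelLength)
  base <- informerForward(m, enc, lab, startWeek = 5, province = 1)
  enc2 <- enc + 0.5
  pert <- informerForward(m, enc2, lab, startWeek = 5, province = 1)
  expect_true(all(abs(pert - base) > 0))  # cross-attention is unmasked
})

test_that("every parameter receives gradient on a random batch", {
  cfg <- tiny_config()
  set.seed(21)
  params <- ns$.init_params(cfg, nProv = 2)
  z <- matrix(rnorm(2 * 30), 2, 30)
  batch <- ns$.make_batch(z, c(1L, 2L), c(1L, 3L), cfg)
  out <- ns$.informer_forward(params, cfg, batch, training = FALSE)
  Ldec <- cfg$labelLength + cfg$horizon
  hIdx <- as.vector(vapply(1:2, function(b)
    (b - 1L) * Ldec + (cfg$labelLength + 1L):Ldec, integer(cfg$horizon)))
  loss <- ns$op_mse(ns$op_slice(out, hIdx), batch$target)
  ns$ad_backward(loss)
  for (nm in names(params)) {
    g <- params[[nm]]$grad
    expect_false(is.null(g), info = nm)
    expect_gt(max(abs(g)), 0, label = sprintf("gradient norm of %s", nm))
  }
})

test_that("training is deterministic and reduces the loss on seasonal data", {
  ie <- tiny_series()
  cfg <- tiny_config(epochs = 3L)
  m1 <- informerTrain(ie, "nipi", splitWeek = 30, config = cfg)
  m2 <- informerTrain(ie, "nipi", splitWeek = 30, config = cfg)
  expect_identical(m1@trainingLog$loss, m2@trainingLog$loss)
  expect_identical(m1@params, m2@params)
  expect_lt(m1@trainingLog$loss[3], m1@trainingLog$loss[1])
})

test_that("a constant series is forecast to its constant", {
  vals <- matrix(2.5, 2, 40, dimnames = list(c("P01", "P02"), NULL))
  ie <- IndicatorExperiment(nipi = vals, thq = vals, tcr = vals)
  cfg <- tiny_config(epochs = 30L)
  m <- informerTrain(ie, "nipi", splitWeek = 30, config = cfg)
  pred <- informerPredict(m, ie, splitWeek = 30)
  # constant series has sd 0 -> scale 1; the net must learn the constant
  expect_lt(max(abs(pred$value - 2.5) / 2.5), 0.05)
})

test_that("prediction output covers exactly the horizon in original units", {
  ie <- tiny_series()
  cfg <- tiny_config(epochs = 1L)
  m <- informerTrain(ie, "nipi", splitWeek = 30, config = cfg)
  pred <- informerPredict(m, ie, splitWeek = 30)
  expect_equal(nrow(pred), 3 * cfg$horizon)
  expect_setequal(unique(pred$week), 30 + seq_len(cfg$horizon))
  expect_true(all(pred$value >= 0))
  # the log-standardization round trip inverts exactly on training data
  sc <- m@scaling
  lv <- log(pmax(nipi(ie), m@config$logFloor))
  z <- (lv - sc$center) / sc$scale
  back <- exp(z * sc$scale + sc$center)
  expect_equal(back, pmax(nipi(ie), m@config$logFloor), tolerance = 1e-12)
})

test_that("series too short for one window are rejected", {
  ie <- tiny_series(nWeeks = 20)
  cfg <- tiny_config()
  expect_error(informerTrain(ie, "nipi", splitWeek = 15, config = cfg),
               "shorter")
})

test_that("models round-trip through the JSON checkpoint", {
  ie <- tiny_series()
  cfg <- tiny_config(epochs = 1L)
  m <- informerTrain(ie, "thq", splitWeek = 30, config = cfg)
  path <- tempfile(fileext = ".json")
  writeInformerModel(m, path)
  back <- readInformerModel(path)
  p1 <- informerPredict(m, ie, 30)
  p2 <- informerPredict(back, ie, 30)
  expect_equal(p2$value, p1$value, tolerance = 1e-10)
})
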