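#' Forecaster configuration
#'
#' Hyperparameters of the Informer-style indicator forecaster.  The
#' encoder reads \code{inputLength} weeks; the decoder is primed with the
#' last \code{labelLength} known weeks followed by \code{horizon} zero
#' placeholders and emits the whole horizon in one pass (generative
#' decoding).  \code{samplingFactor} c controls how many queries receive
#' full softmax attention rows: \code{u = ceiling(c * log(L_Q))}, the
#' remaining rows fall back to the (causally cumulative) mean of the
#' values.  The encoder has a main stack of \code{encLayers} attention
#' layers with a distilling convolution + ELU + max-pool (halving the
#' length) between consecutive layers — one distillation fewer than
#' encoding layers — and a half-length replica stack reading the last
#' half of the input; stack outputs are concatenated into the feature
#' map.
#'
#' @param inputLength encoder window length (weeks).
#' @param labelLength known decoder context (weeks), < inputLength.
#' @param horizon forecast length (weeks).
#' @param d embedding width; must be divisible by \code{nHeads}.
#' @param nHeads attention heads.
#' @param encLayers attention layers in the main encoder stack.
#' @param ffnDim width of the position-wise feed-forward sublayer.
#' @param samplingFactor c in \code{u = ceiling(c * log(L_Q))}.
#' @param convKernel distilling convolution kernel size (same padding).
#' @param dropout dropout probability during training.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batchSize windows per gradient step.
#' @param windowStride stride between consecutive training windows.
#' @param seed integer RNG seed for init, shuffling and dropout.
#' @return validated list of class \code{"ForecastConfig"}.
#' @export
forecastConfig <- function(inputLength = 36L, labelLength = 12L, horizon = 21L,
                           d = 32L, nHeads = 4L, encLayers = 2L,
                           ffnDim = 64L, samplingFactor = 1,
                           convKernel = 3L, dropout = 0.05, lr = 2e-3,
                           epochs = 8L, batchSize = 32L, windowStride = 1L,
                           seed = 1L) {
  if (labelLength >= inputLength) stop("labelLength must be < inputLength")
  if (horizon < 1) stop("horizon must be >= 1")
  if (d %% nHeads != 0) stop("d must be divisible by nHeads")
  if (samplingFactor <= 0) stop("samplingFactor must be > 0")
  structure(list(inputLength = as.integer(inputLength),
                 labelLength = as.integer(labelLength),
                 horizon = as.integer(horizon), d = as.integer(d),
                 nHeads = as.integer(nHeads), encLayers = as.integer(encLayers),
                 ffnDim = as.integer(ffnDim), samplingFactor = samplingFactor,
                 convKernel = as.integer(convKernel), dropout = dropout,
                 lr = lr, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 windowStride = as.integer(windowStride),
                 seed = as.integer(seed)),
            class = "ForecastConfig")
}

#' Sparsity measure of a query
#'
#' \eqn{M(q, K) = \ln \sum_j e^{q k_j^T / \sqrt d} - \frac{1}{L_K}
#' \sum_j q k_j^T / \sqrt d}, computed with a max-shifted log-sum-exp.
#' It is the gap between the log-sum-exp and the mean of the attention
#' scores: 0 for a single key, \eqn{\ln L_K} for constant scores, and
#' large for queries whose attention would be concentrated; queries with
#' the largest measure get full softmax rows in ProbSparse attention.
#'
#' @param q numeric query vector (length d).
#' @param K key matrix (L_K x d).
#' @return the non-negative sparsity measure.
#' @export
#' @examples
#' sparsityMeasure(c(1, 0), matrix(rnorm(10), 5, 2))
sparsityMeasure <- function(q, K) {
  K <- as.matrix(K)
  s <- as.vector(K %*% q) / sqrt(length(q))
  .logsumexp(s) - mean(s)
}

#' ProbSparse attention (single head)
#'
#' The \code{u} queries with the largest \code{\link{sparsityMeasure}}
#' receive full rows \code{softmax(q K^T / sqrt(d)) V}; every other
#' query falls back to the mean of the values (under a causal mask, the
#' cumulative mean of values up to its own position).  With
#' \code{u >= nrow(Q)} this reduces exactly to dense softmax attention.
#' Under \code{causal = TRUE}, key j > query i is excluded before the
#' softmax and query selection uses a streaming rule (query i is
#' selected iff its measure ranks in the top u among queries 1..i), so
#' no output row depends on later inputs.
#'
#' @param Q,K,V numeric matrices (L_Q x d, L_K x d, L_K x d).
#' @param u number of queries given full attention rows.
#' @param causal logical, mask future keys (requires L_Q == L_K).
#' @return L_Q x d output matrix.
#' @export
probSparseAttention <- function(Q, K, V, u, causal = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    stop("shape mismatch between Q, K and V")
  if (u < 1) stop("u must be >= 1")
  .attn_forward_one(Q, K, V, u, causal)$out
}

# ---- parameter initialisation ----

.init_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

.init_attn <- function(d, prefix, params) {
  for (w in c("Wq", "Wk", "Wv", "Wo"))
    params[[paste0(prefix, ".", w)]] <- ad_param(.init_mat(d, d))
  for (b in c("bq", "bk", "bv", "bo"))
    params[[paste0(prefix, ".", b)]] <- ad_param(numeric(d))
  params
}

.init_block <- function(d, ffn, prefix, params) {
  params <- .init_attn(d, paste0(prefix, ".attn"), params)
  params[[paste0(prefix, ".ln1.g")]] <- ad_param(rep(1, d))
  params[[paste0(prefix, ".ln1.b")]] <- ad_param(numeric(d))
  params[[paste0(prefix, ".ffn.W1")]] <- ad_param(.init_mat(d, ffn))
  params[[paste0(prefix, ".ffn.b1")]] <- ad_param(numeric(ffn))
  params[[paste0(prefix, ".ffn.W2")]] <- ad_param(.init_mat(ffn, d))
  params[[paste0(prefix, ".ffn.b2")]] <- ad_param(numeric(d))
  params[[paste0(prefix, ".ln2.g")]] <- ad_param(rep(1, d))
  params[[paste0(prefix, ".ln2.b")]] <- ad_param(numeric(d))
  params
}

.init_params <- function(cfg, nProv) {
  d <- cfg$d
  p <- list()
  p[["emb.val"]] <- ad_param(.init_mat(1, d))
  p[["emb.woy"]] <- ad_param(matrix(stats::rnorm(53 * d, 0, 0.02), 53, d))
  p[["emb.prov"]] <- ad_param(matrix(stats::rnorm(nProv * d, 0, 0.02), nProv, d))
  for (j in seq_len(cfg$encLayers)) {
    p <- .init_block(d, cfg$ffnDim, sprintf("enc1.l%d", j), p)
    if (j < cfg$encLayers) {
      p[[sprintf("enc1.d%d.W", j)]] <- ad_param(.init_mat(cfg$convKernel * d, d))
      p[[sprintf("enc1.d%d.b", j)]] <- ad_param(numeric(d))
    }
  }
  for (j in seq_len(max(1L, cfg$encLayers - 1L)))
    p <- .init_block(d, cfg$ffnDim, sprintf("enc2.l%d", j), p)
  p <- .init_block(d, cfg$ffnDim, "dec.self", p)
  p <- .init_block(d, cfg$ffnDim, "dec.cross", p)
  p[["head.W"]] <- ad_param(.init_mat(d, 1))
  p[["head.b"]] <- ad_param(numeric(1))
  p
}

# ---- forward pass ----

.sinusoidal_pe <- function(L, d) {
  pos <- seq_len(L) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 10000^(-(i %/% 2 * 2) / d))
  pe <- angle
  even <- (i %% 2) == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

# Value + positional + calendar + province embedding of one segment.
.embed_segment <- function(p, cfg, vals, woy, provIdx, L, B, training) {
  x <- op_linear(ad_const(matrix(vals, ncol = 1)), p[["emb.val"]])
  x <- op_add(x, op_embed(p[["emb.woy"]], woy))
  x <- op_add(x, op_embed(p[["emb.prov"]], rep(provIdx, each = L)))
  pe <- .sinusoidal_pe(L, cfg$d)[rep(seq_len(L), B), , drop = FALSE]
  x <- op_add(x, ad_const(pe))
  op_dropout(x, cfg$dropout, training)
}

.u_of <- function(cfg, L) max(1L, min(L, ceiling(cfg$samplingFactor * log(L))))

.attn_block <- function(x, p, prefix, cfg, B, Lq, kv = NULL, Lk = Lq,
                        causal = FALSE, u = .u_of(cfg, Lq), training = FALSE) {
  ap <- list(Wq = p[[paste0(prefix, ".attn.Wq")]], Wk = p[[paste0(prefix, ".attn.Wk")]],
             Wv = p[[paste0(prefix, ".attn.Wv")]], Wo = p[[paste0(prefix, ".attn.Wo")]],
             bq = p[[paste0(prefix, ".attn.bq")]], bk = p[[paste0(prefix, ".attn.bk")]],
             bv = p[[paste0(prefix, ".attn.bv")]], bo = p[[paste0(prefix, ".attn.bo")]])
  a <- op_mha(x, if (is.null(kv)) x else kv, ap, cfg$nHeads, u, causal, B, Lq, Lk)
  x <- op_layernorm(op_add(x, op_dropout(a, cfg$dropout, training)),
                    p[[paste0(prefix, ".ln1.g")]], p[[paste0(prefix, ".ln1.b")]])
  f <- op_linear(op_elu(op_linear(x, p[[paste0(prefix, ".ffn.W1")]],
                                  p[[paste0(prefix, ".ffn.b1")]])),
                 p[[paste0(prefix, ".ffn.W2")]], p[[paste0(prefix, ".ffn.b2")]])
  op_layernorm(op_add(x, op_dropout(f, cfg$dropout, training)),
               p[[paste0(prefix, ".ln2.g")]], p[[paste0(prefix, ".ln2.b")]])
}

# Full network forward.  batch: list with encVals, encWoy, decVals,
# decWoy (vectors, batch-major), provIdx (one per sequence), B.
.informer_forward <- function(p, cfg, batch, training = FALSE) {
  B <- batch$B
  Lenc <- cfg$inputLength
  Ldec <- cfg$labelLength + cfg$horizon
  xe <- .embed_segment(p, cfg, batch$encVals, batch$encWoy, batch$provIdx,
                       Lenc, B, training)
  # main stack: attention layers with distilling between consecutive ones
  x1 <- xe
  L1 <- Lenc
  for (j in seq_len(cfg$encLayers)) {
    x1 <- .attn_block(x1, p, sprintf("enc1.l%d", j), cfg, B, L1,
                      training = training)
    if (j < cfg$encLayers) {
      x1 <- op_conv1d(x1, p[[sprintf("enc1.d%d.W", j)]],
                      p[[sprintf("enc1.d%d.b", j)]], B, L1, cfg$convKernel)
      x1 <- op_elu(x1)
      x1 <- op_maxpool(x1, B, L1)
      L1 <- (L1 + 2L - 3L) %/% 2L + 1L
    }
  }
  # replica stack on the last half of the input
  Lh <- Lenc %/% 2L
  halfIdx <- as.vector(vapply(seq_len(B), function(b)
    (b - 1L) * Lenc + (Lenc - Lh + 1L):Lenc, integer(Lh)))
  x2 <- op_slice(xe, halfIdx)
  for (j in seq_len(max(1L, cfg$encLayers - 1L)))
    x2 <- .attn_block(x2, p, sprintf("enc2.l%d", j), cfg, B, Lh,
                      training = training)
  # concatenate stack outputs along time, sequence-contiguous
  Lf <- L1 + Lh
  cat2 <- op_rbind2(x1, x2)
  perm <- as.vector(vapply(seq_len(B), function(b)
    c((b - 1L) * L1 + seq_len(L1), B * L1 + (b - 1L) * Lh + seq_len(Lh)),
    integer(Lf)))
  featmap <- op_slice(cat2, perm)

  xd <- .embed_segment(p, cfg, batch$decVals, batch$decWoy, batch$provIdx,
                       Ldec, B, training)
  xd <- .attn_block(xd, p, "dec.self", cfg, B, Ldec, causal = TRUE,
                    training = training)
  xd <- .attn_block(xd, p, "dec.cross", cfg, B, Ldec, kv = featmap, Lk = Lf,
                    u = Ldec, training = training)
  out <- op_linear(xd, p[["head.W"]], p[["head.b"]])
  # anchored decoding: the head predicts deviations from the value at
  # the forecast origin (the encoder's last position), so the untrained
  # network starts from level persistence and learning refines it
  anchor <- matrix(rep(batch$lastVals, each = Ldec), ncol = 1)
  op_add_const(out, anchor)
}

# ---- window construction ----

.week_of_year <- function(w) ((w - 1L) %% 53L) + 1L  # 53-week study years (159 = 3 x 53)

# One window per (province, encoder start).  series: province x week
# matrix of standardized values.
.make_batch <- function(series, provIdx, starts, cfg, withTarget = TRUE) {
  Lenc <- cfg$inputLength
  lab <- cfg$labelLength
  h <- cfg$horizon
  encVals <- decVals <- numeric(0)
  encWoy <- decWoy <- integer(0)
  target <- numeric(0)
  for (i in seq_along(starts)) {
    t0 <- starts[i]
    pr <- provIdx[i]
    encW <- t0:(t0 + Lenc - 1L)
    decW <- (t0 + Lenc - lab):(t0 + Lenc + h - 1L)
    encVals <- c(encVals, series[pr, encW])
    decVals <- c(decVals, series[pr, encW[(Lenc - lab + 1L):Lenc]], numeric(h))
    encWoy <- c(encWoy, .week_of_year(encW))
    decWoy <- c(decWoy, .week_of_year(decW))
    if (withTarget)
      target <- c(target, series[pr, (t0 + Lenc):(t0 + Lenc + h - 1L)])
  }
  lastVals <- series[cbind(provIdx, starts + Lenc - 1L)]
  list(encVals = encVals, encWoy = encWoy, decVals = decVals, decWoy = decWoy,
       provIdx = provIdx, B = length(starts), lastVals = lastVals,
       target = if (withTarget) matrix(target, ncol = 1))
}

#' Train the indicator forecaster
#'
#' Fits one Informer-style network to the weekly series of a single
#' indicator, pooled across provinces with a learned province embedding.
#' Indicators are positive and span orders of magnitude across
#' contamination regimes, so each series is modelled on the log scale
#' (values floored at half the smallest positive training value) and
#' standardized per province using only the training weeks; sliding
#' windows over weeks \code{1..splitWeek} provide the training pairs;
#' the loss is the mean squared error on the horizon slice of the
#' decoder output; optimisation is Adam with global-norm gradient
#' clipping.  Training is deterministic for a fixed \code{config$seed}.
#'
#' @param ie an \code{\link{IndicatorExperiment}}.
#' @param indicator one of \code{"nipi"}, \code{"thq"}, \code{"tcr"}.
#' @param splitWeek last training week; forecasts start at
#'   \code{splitWeek + 1}.
#' @param config a \code{\link{forecastConfig}}.
#' @return an \code{\link{InformerModel}}.
#' @export
informerTrain <- function(ie, indicator = c("nipi", "thq", "tcr"),
                          splitWeek = 138L, config = forecastConfig()) {
  indicator <- match.arg(indicator)
  stopifnot(inherits(config, "ForecastConfig"))
  vals <- SummarizedExperiment::assay(ie, indicator)
  weeks <- weekIndex(ie)
  if (splitWeek > max(weeks)) stop("splitWeek beyond the observed week axis")
  trainCols <- which(weeks <= splitWeek)
  if (length(trainCols) < config$inputLength + config$horizon)
    stop("series shorter than inputLength + horizon")
  # indicators are positive and span orders of magnitude across
  # contamination regimes; modelling log values makes regime shifts
  # additive and keeps the standardized range compact
  tr <- vals[, trainCols, drop = FALSE]
  pos <- tr[tr > 0]
  logFloor <- if (length(pos)) min(pos) / 2 else 1e-12
  lv <- log(pmax(vals, logFloor))
  # per-province centering removes baseline differences; one global
  # scale per indicator keeps the z -> log gain uniform, so a given
  # z-space precision means the same relative error in every province
  ctr <- rowMeans(lv[, trainCols, drop = FALSE])
  sclG <- stats::sd(lv[, trainCols, drop = FALSE] - ctr)
  if (!is.finite(sclG) || sclG == 0) sclG <- 1
  scl <- rep(sclG, nrow(lv))
  z <- (lv - ctr) / scl

  nProv <- nrow(z)
  lastStart <- length(trainCols) - config$inputLength - config$horizon + 1L
  starts0 <- seq(1L, lastStart, by = config$windowStride)
  wins <- expand.grid(prov = seq_len(nProv), start = starts0)

  log_ <- data.frame(epoch = integer(0), loss = numeric(0))
  params <- NULL
  .with_seed(config$seed, {
    params <- .init_params(config, nProv)
    state <- adam_init(params)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nrow(wins))
      tot <- 0
      nb <- 0L
      for (i0 in seq(1L, nrow(wins), by = config$batchSize)) {
        sel <- ord[i0:min(i0 + config$batchSize - 1L, nrow(wins))]
        batch <- .make_batch(z, wins$prov[sel], wins$start[sel], config)
        out <- .informer_forward(params, config, batch, training = TRUE)
        Ldec <- config$labelLength + config$horizon
        hIdx <- as.vector(vapply(seq_along(sel), function(b)
          (b - 1L) * Ldec + (config$labelLength + 1L):Ldec,
          integer(config$horizon)))
        loss <- op_mse(op_slice(out, hIdx), batch$target)
        ad_backward(loss)
        state <- adam_step(params, state, lr = config$lr)
        tot <- tot + loss$val
        nb <- nb + 1L
      }
      log_ <- rbind(log_, data.frame(epoch = ep, loss = tot / nb))
    }
  })
  cfgOut <- unclass(config)
  cfgOut$logFloor <- logFloor
  new("InformerModel", indicator = indicator,
      params = lapply(params, function(p) p$val), config = cfgOut,
      scaling = data.frame(province = rownames(vals), center = ctr,
                           scale = scl),
      trainingLog = log_)
}

#' Forecast the indicator over the horizon
#'
#' Runs the trained network once per province (generative decoding: the
#' whole horizon in a single forward pass, no autoregressive loop) on
#' the window ending at \code{splitWeek} and maps the output back to
#' indicator units (inverting the per-province standardization and the
#' log transform, so predictions are positive by construction).
#'
#' @param model an \code{\link{InformerModel}}.
#' @param ie the \code{\link{IndicatorExperiment}} holding the observed
#'   series (provinces must match training).
#' @param splitWeek forecast origin; defaults to the training split.
#' @return data.frame: province, week, indicator, value.
#' @export
informerPredict <- function(model, ie, splitWeek = 138L) {
  cfg <- model@config
  vals <- SummarizedExperiment::assay(ie, model@indicator)
  if (!identical(rownames(vals), model@scaling$province))
    stop("provinces differ from the training data")
  weeks <- weekIndex(ie)
  if (splitWeek < cfg$inputLength) stop("not enough history before splitWeek")
  z <- (log(pmax(vals, cfg$logFloor)) - model@scaling$center) /
    model@scaling$scale
  nProv <- nrow(z)
  t0 <- splitWeek - cfg$inputLength + 1L
  batch <- .make_batch(z, seq_len(nProv), rep(t0, nProv),
                       structure(cfg, class = "ForecastConfig"),
                       withTarget = FALSE)
  p <- lapply(model@params, ad_const)
  out <- .informer_forward(p, cfg, batch, training = FALSE)
  Ldec <- cfg$labelLength + cfg$horizon
  pred <- matrix(out$val[, 1], nrow = nProv, byrow = TRUE)
  pred <- pred[, (cfg$labelLength + 1L):Ldec, drop = FALSE]
  pred <- exp(pred * model@scaling$scale + model@scaling$center)
  data.frame(province = rep(rownames(vals), each = cfg$horizon),
             week = rep(splitWeek + seq_len(cfg$horizon), nProv),
             indicator = model@indicator,
             value = as.vector(t(pred)))
}

#' Low-level single-window forward pass
#'
#' Exposes the raw (standardized-scale) decoder output for one window,
#' mainly to let users and tests probe structural contracts such as
#' decoder causality.  No dropout is applied.
#'
#' @param model an \code{\link{InformerModel}}.
#' @param encVals encoder input values (length inputLength, on the
#'   model's standardized log scale).
#' @param decKnown decoder label values (length labelLength); the
#'   horizon slots are zero placeholders appended internally.
#' @param startWeek study week of the first encoder value (drives the
#'   calendar embedding).
#' @param province province index for the province embedding.
#' @return numeric vector of length labelLength + horizon.
#' @export
informerForward <- function(model, encVals, decKnown, startWeek = 1L,
                            province = 1L) {
  cfg <- model@config
  stopifnot(length(encVals) == cfg$inputLength,
            length(decKnown) == cfg$labelLength)
  Lenc <- cfg$inputLength
  h <- cfg$horizon
  encW <- startWeek:(startWeek + Lenc - 1L)
  decW <- (startWeek + Lenc - cfg$labelLength):(startWeek + Lenc + h - 1L)
  batch <- list(encVals = encVals, encWoy = .week_of_year(encW),
                decVals = c(decKnown, numeric(h)),
                decWoy = .week_of_year(decW), provIdx = province, B = 1L,
                lastVals = encVals[length(encVals)])
  p <- lapply(model@params, ad_const)
  out <- .informer_forward(p, cfg, batch, training = FALSE)
  as.vector(out$val)
}

#' Forecast all three indicators
#'
#' Trains one forecaster per indicator (independently, as the three
#' series are modelled separately) and predicts the horizon weeks for
#' every province.
#'
#' @inheritParams informerTrain
#' @param horizon forecast length; overrides \code{config$horizon}.
#' @param returnModels also return the trained models.
#' @return a \code{\link{ForecastResult}}; with \code{returnModels=TRUE},
#'   a list with elements \code{forecast} and \code{models}.
#' @export
forecastIndicators <- function(ie, splitWeek = 138L, horizon = 21L,
                               config = forecastConfig(),
                               returnModels = FALSE) {
  config$horizon <- as.integer(horizon)
  models <- list()
  preds <- list()
  for (ind in c("nipi", "thq", "tcr")) {
    cfgI <- config
    cfgI$seed <- config$seed + match(ind, c("nipi", "thq", "tcr")) * 1000L
    m <- informerTrain(ie, ind, splitWeek, structure(cfgI, class = "ForecastConfig"))
    models[[ind]] <- m
    preds[[ind]] <- informerPredict(m, ie, splitWeek)
  }
  fr <- new("ForecastResult", predictions = do.call(rbind, preds),
            splitWeek = as.integer(splitWeek), horizon = as.integer(horizon),
            method = "informer")
  if (returnModels) list(forecast = fr, models = models) else fr
}

#' Persistence baseline forecast
#'
#' Repeats each province's last observed indicator value at the split
#' week across the whole horizon — the naive reference any learned
#' forecaster must beat.
#'
#' @inheritParams forecastIndicators
#' @return a \code{\link{ForecastResult}} with method "persistence".
#' @export
persistenceForecast <- function(ie, splitWeek = 138L, horizon = 21L) {
  weeks <- weekIndex(ie)
  col <- match(splitWeek, weeks)
  if (is.na(col)) stop("splitWeek not on the observed week axis")
  preds <- lapply(c("nipi", "thq", "tcr"), function(ind) {
    last <- SummarizedExperiment::assay(ie, ind)[, col]
    data.frame(province = rep(provinces(ie), each = horizon),
               week = rep(splitWeek + seq_len(horizon), nrow(ie)),
               indicator = ind, value = rep(last, each = horizon))
  })
  new("ForecastResult", predictions = do.call(rbind, preds),
      splitWeek = as.integer(splitWeek), horizon = as.integer(horizon),
      method = "persistence")
}

#' Serialize a trained model to JSON (and back)
#'
#' Weights, configuration, scaling and training log as a single
#' plain-text artifact.
#'
#' @param model an \code{\link{InformerModel}}.
#' @param path JSON file path.
#' @export
writeInformerModel <- function(model, path) {
  obj <- list(indicator = model@indicator, params = model@params,
              config = model@config,
              scaling = as.list(model@scaling),
              trainingLog = as.list(model@trainingLog))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeInformerModel
#' @export
readInformerModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(x) {
    if (is.matrix(x)) x else if (is.list(x)) do.call(rbind, x) else as.numeric(x)
  })
  cfg <- obj$config
  intFields <- c("inputLength", "labelLength", "horizon", "d", "nHeads",
                 "encLayers", "ffnDim", "convKernel", "epochs", "batchSize",
                 "windowStride", "seed")
  cfg[intFields] <- lapply(cfg[intFields], as.integer)
  new("InformerModel", indicator = obj$indicator, params = params,
      config = cfg, scaling = as.data.frame(obj$scaling),
      trainingLog = as.data.frame(obj$trainingLog))
}
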