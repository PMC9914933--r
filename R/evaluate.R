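#' Assign indicator points to risk levels
#'
#' Projects points (original indicator units) into the normalized space
#' of a fitted \code{\link{RiskLevelSpace}} and assigns each to the level
#' of its nearest cluster center (Euclidean distance); ties break toward
#' the lower level.
#'
#' @param points n x 3 matrix (columns nipi, thq, tcr) in original
#'   units, or a data.frame with those columns.
#' @param space a \code{\link{RiskLevelSpace}}.
#' @return data.frame with a factor column \code{level} and one distance
#'   column per level (normalized space).
#' @export
assignLevel <- function(points, space) {
  if (is.data.frame(points))
    points <- as.matrix(points[, c("nipi", "thq", "tcr")])
  pts <- minMaxNormalize(points, space@normalization)$points
  D <- sapply(seq_len(space@k), function(i) .dist_to(pts, space@centers[i, ]))
  if (!is.matrix(D)) D <- matrix(D, nrow = 1)
  colnames(D) <- space@levels
  # centers are stored lowest-risk first, so "first" ties to the lower level
  lev <- space@levels[max.col(-D, ties.method = "first")]
  cbind(data.frame(level = factor(lev, levels = space@levels)),
        as.data.frame(D))
}

#' Forecast error metrics
#'
#' Root mean square error and mean absolute error of a prediction
#' against truth.
#'
#' @param y,yhat equal-length numeric vectors.
#' @return named numeric: \code{rmse}, \code{mae} (always rmse >= mae).
#' @export
regressionMetrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0)
    stop("y and yhat must have equal nonzero length")
  c(rmse = sqrt(mean((y - yhat)^2)), mae = mean(abs(y - yhat)))
}

#' Per-level precision, recall and F1
#'
#' One-vs-rest counts per risk level: TP = correct predictions of the
#' level, FP = predicted the level but the truth differs, FN = truth is
#' the level but predicted otherwise.  Precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = harmonic mean, all in percent.  A zero denominator
#' yields 0 with a warning (small high-risk classes can be absent from a
#' split).
#'
#' @param truth,pred equal-length vectors of level labels.
#' @param levels the level set; defaults to the union of observed labels.
#' @return data.frame: level, tp, fp, fn, precision, recall, f1.
#' @export
classificationMetrics <- function(truth, pred,
                                  levels = union(unique(truth), unique(pred))) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  if (!all(c(as.character(truth), as.character(pred)) %in% levels))
    stop("label outside the level set")
  res <- lapply(levels, function(lv) {
    tp <- sum(truth == lv & pred == lv)
    fp <- sum(truth != lv & pred == lv)
    fn <- sum(truth == lv & pred != lv)
    safe <- function(num, den, what) {
      if (den == 0) {
        warning(sprintf("%s undefined for level '%s' (zero denominator); reported as 0",
                        what, lv), call. = FALSE)
        0
      } else 100 * num / den
    }
    p <- safe(tp, tp + fp, "precision")
    r <- safe(tp, tp + fn, "recall")
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(level = lv, tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f1 = f1)
  })
  do.call(rbind, res)
}

#' Evaluate a forecast against the observed series
#'
#' Pools forecast weeks across provinces and computes (i) RMSE/MAE per
#' indicator and (ii) per-level precision/recall/F1 of the risk levels
#' obtained by nearest-center assignment of the forecast triplets,
#' against truth levels.  Truth levels default to nearest-center
#' assignment of the observed indicator triplets (truth and prediction
#' share the graded space); a ground-truth label vector can be supplied
#' instead, e.g. the generator's latent regimes in recovery studies.
#'
#' @param ie observed \code{\link{IndicatorExperiment}} (must cover the
#'   forecast weeks).
#' @param forecast a \code{\link{ForecastResult}}.
#' @param space a \code{\link{RiskLevelSpace}}.
#' @param truthLevels optional vector of true levels, ordered like the
#'   forecast's (province, week) pairs.
#' @return an \code{\link{EvaluationReport}}.
#' @export
evaluatePipeline <- function(ie, forecast, space, truthLevels = NULL) {
  pred <- predictions(forecast)
  weeks <- weekIndex(ie)
  if (!all(unique(pred$week) %in% weeks))
    stop("no (or incomplete) overlap between forecast weeks and observed weeks")
  inds <- c("nipi", "thq", "tcr")
  truthOf <- function(ind) {
    m <- SummarizedExperiment::assay(ie, ind)
    sub <- pred[pred$indicator == ind, ]
    m[cbind(match(sub$province, rownames(m)), match(sub$week, weeks))]
  }
  reg <- do.call(rbind, lapply(inds, function(ind) {
    sub <- pred[pred$indicator == ind, ]
    rm_ <- regressionMetrics(truthOf(ind), sub$value)
    data.frame(indicator = ind, rmse = rm_[["rmse"]], mae = rm_[["mae"]])
  }))
  wide <- function(src) {
    out <- lapply(inds, function(ind) src[[ind]])
    stats::setNames(as.data.frame(out), inds)
  }
  predWide <- wide(split(pred$value, pred$indicator)[inds])
  truthWide <- wide(stats::setNames(lapply(inds, truthOf), inds))
  predLev <- assignLevel(as.matrix(predWide), space)$level
  if (is.null(truthLevels))
    truthLevels <- assignLevel(as.matrix(truthWide), space)$level
  cls <- classificationMetrics(as.character(truthLevels),
                               as.character(predLev), levels = space@levels)
  new("EvaluationReport", regression = reg, classification = cls)
}

#' Write an evaluation report
#'
#' JSON plus a small human-readable text table (levels by
#' precision/recall/F1).
#'
#' @param report an \code{\link{EvaluationReport}}.
#' @param jsonPath,txtPath output paths (\code{NULL} skips one of them).
#' @export
writeEvaluationReport <- function(report, jsonPath = NULL, txtPath = NULL) {
  if (!is.null(jsonPath))
    jsonlite::write_json(list(regression = regressionReport(report),
                              classification = classificationReport(report)),
                         jsonPath, digits = NA, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(txtPath)) {
    con <- file(txtPath, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(show(report)), con)
  }
  invisible(NULL)
}
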