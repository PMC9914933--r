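#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

# The three heavy metals tracked throughout the package; all per-metal
# vectors (limits, RfD, CSF, LODs, concentrations) use these names.
.metals <- c("cd", "cr", "as")

#' IndicatorExperiment: province-by-week risk indicator container
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: rows are
#' provinces, columns are study weeks, and the assays \code{nipi},
#' \code{thq}, \code{tcr} hold the three weekly risk-assessment indicators
#' (Nemerow integrated pollution index, target hazard quotient, total
#' carcinogenic risk).  A logical assay \code{gapFilled} marks
#' province-weeks whose values were carried over from a neighbouring week
#' because no sample was available.
#'
#' @param nipi,thq,tcr numeric matrices (provinces x weeks), all
#'   non-negative and of identical dimension.
#' @param gapFilled logical matrix of the same dimension; \code{NULL}
#'   means nothing was gap-filled.
#' @param provinces character vector of province identifiers (row names).
#' @param weeks integer vector of 1-based study week indices (column
#'   order), strictly increasing.
#' @return An \code{IndicatorExperiment}.
#' @export
#' @examples
#' m <- matrix(runif(6), 2, 3, dimnames = list(c("P01", "P02"), NULL))
#' ie <- IndicatorExperiment(nipi = m, thq = m / 2, tcr = m / 1e4)
#' nipi(ie)[1, ]
setClass("IndicatorExperiment", contains = "SummarizedExperiment")

setValidity("IndicatorExperiment", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  need <- c("nipi", "thq", "tcr")
  if (!all(need %in% an))
    return(sprintf("assays must include %s", paste(need, collapse = ", ")))
  for (a in need) {
    v <- SummarizedExperiment::assay(object, a)
    if (!is.numeric(v)) return(sprintf("assay '%s' must be numeric", a))
    if (any(!is.na(v) & v < 0)) return(sprintf("assay '%s' has negative values", a))
  }
  wk <- object$week
  if (is.null(wk)) return("colData must carry a 'week' column")
  if (any(diff(wk) <= 0)) return("week indices must be strictly increasing")
  TRUE
})

#' @rdname IndicatorExperiment-class
#' @export
IndicatorExperiment <- function(nipi, thq, tcr, gapFilled = NULL,
                                provinces = rownames(nipi),
                                weeks = seq_len(ncol(nipi))) {
  if (is.null(provinces))
    provinces <- sprintf("P%02d", seq_len(nrow(nipi)))
  if (is.null(gapFilled))
    gapFilled <- matrix(FALSE, nrow(nipi), ncol(nipi))
  dimnames(nipi) <- dimnames(thq) <- dimnames(tcr) <- dimnames(gapFilled) <-
    list(provinces, paste0("W", weeks))
  se <- SummarizedExperiment(
    assays = list(nipi = nipi, thq = thq, tcr = tcr, gapFilled = gapFilled),
    colData = DataFrame(week = as.integer(weeks)),
    rowData = DataFrame(province = provinces))
  new("IndicatorExperiment", se)
}

#' @rdname RiceRiskCast-generics
#' @export
setMethod("nipi", "IndicatorExperiment", function(x, ...) SummarizedExperiment::assay(x, "nipi"))

#' @rdname RiceRiskCast-generics
#' @export
setMethod("thq", "IndicatorExperiment", function(x, ...) SummarizedExperiment::assay(x, "thq"))

#' @rdname RiceRiskCast-generics
#' @export
setMethod("tcr", "IndicatorExperiment", function(x, ...) SummarizedExperiment::assay(x, "tcr"))

#' @rdname RiceRiskCast-generics
#' @export
setMethod("gapFilled", "IndicatorExperiment", function(x, ...) SummarizedExperiment::assay(x, "gapFilled"))

#' @rdname RiceRiskCast-generics
#' @export
setMethod("provinces", "IndicatorExperiment", function(x, ...) rownames(x))

#' @rdname RiceRiskCast-generics
#' @export
setMethod("weekIndex", "IndicatorExperiment", function(x, ...) x$week)

#' @describeIn IndicatorExperiment-class all province-week points as an
#'   n x 3 matrix (columns nipi, thq, tcr), stacked province-major.
#' @export
setMethod("indicatorMatrix", "IndicatorExperiment", function(x, ...) {
  cbind(nipi = as.vector(t(nipi(x))),
        thq  = as.vector(t(thq(x))),
        tcr  = as.vector(t(tcr(x))))
})

#' RiskLevelSpace: graded three-dimensional risk space
#'
#' Result of K-medoids grading of the normalized (NIPI, THQ, TCR) space:
#' the selected number of levels, the cluster centers (dataset medoids) in
#' normalized and original units, the level labels ordered by Euclidean
#' distance of the center from the origin (Low < ... < High), the mean
#' silhouette per candidate cluster count, and the min-max normalization
#' parameters needed to project new points into the space.
#'
#' @slot k integer, number of risk levels.
#' @slot centers k x 3 matrix of medoid coordinates in normalized space,
#'   rows ordered Low to High.
#' @slot centersOriginal the same centers in original indicator units.
#' @slot levels character vector of level labels, lowest risk first.
#' @slot silhouetteByK named numeric, mean silhouette per candidate k.
#' @slot normalization list with numeric vectors \code{min} and \code{max}.
#' @slot assignment factor of level labels for the points used in grading.
#' @slot medoids integer indices (into the graded point set) of the
#'   centers, in level order.
#' @slot cost numeric, total within-cluster distance of the kept solution.
#' @export
setClass("RiskLevelSpace",
  representation(k = "integer", centers = "matrix",
                 centersOriginal = "matrix", levels = "character",
                 silhouetteByK = "numeric", normalization = "list",
                 assignment = "factor", medoids = "integer",
                 cost = "numeric"))

setValidity("RiskLevelSpace", function(object) {
  if (nrow(object@centers) != object@k) return("centers must have k rows")
  if (length(object@levels) != object@k) return("levels must have length k")
  d <- sqrt(rowSums(object@centers^2))
  if (is.unsorted(d)) return("levels must be ordered by center distance from the origin")
  if (!all(c("min", "max") %in% names(object@normalization)))
    return("normalization must hold 'min' and 'max'")
  TRUE
})

#' @rdname RiceRiskCast-generics
#' @export
setMethod("riskLevels", "RiskLevelSpace", function(x, ...) x@levels)

#' @rdname RiceRiskCast-generics
#' @param normalized return centers in normalized (TRUE) or original units.
#' @export
setMethod("centers", "RiskLevelSpace", function(x, normalized = TRUE, ...)
  if (normalized) x@centers else x@centersOriginal)

#' @rdname RiceRiskCast-generics
#' @export
setMethod("silhouetteByK", "RiskLevelSpace", function(x, ...) x@silhouetteByK)

#' @rdname RiceRiskCast-generics
#' @export
setMethod("normalizationParams", "RiskLevelSpace", function(x, ...) x@normalization)

setMethod("show", "RiskLevelSpace", function(object) {
  cat(sprintf("RiskLevelSpace with %d levels (silhouette-selected from k = %s)\n",
              object@k, paste(names(object@silhouetteByK), collapse = ",")))
  tab <- data.frame(level = object@levels,
                    round(object@centers, 6),
                    n = as.integer(table(object@assignment)[object@levels]))
  print(tab, row.names = FALSE)
  cat(sprintf("mean silhouette at k = %d: %.4f\n", object@k,
              object@silhouetteByK[[as.character(object@k)]]))
})

#' ForecastResult: predicted indicator triplets over the horizon
#'
#' Long-format predictions for every province, forecast week and
#' indicator, together with the train/test split week, the horizon length
#' and the forecasting method that produced them.
#'
#' @slot predictions data.frame with columns \code{province},
#'   \code{week}, \code{indicator}, \code{value}.
#' @slot splitWeek integer, last week used for training/conditioning.
#' @slot horizon integer, number of forecast weeks.
#' @slot method character, e.g. \code{"informer"} or \code{"persistence"}.
#' @export
setClass("ForecastResult",
  representation(predictions = "data.frame", splitWeek = "integer",
                 horizon = "integer", method = "character"))

setValidity("ForecastResult", function(object) {
  need <- c("province", "week", "indicator", "value")
  if (!all(need %in% names(object@predictions)))
    return(sprintf("predictions must have columns %s", paste(need, collapse = ", ")))
  if (any(object@predictions$week <= object@splitWeek))
    return("all forecast weeks must lie after the split week")
  TRUE
})

#' @rdname RiceRiskCast-generics
#' @export
setMethod("predictions", "ForecastResult", function(x, ...) x@predictions)

setMethod("show", "ForecastResult", function(object) {
  cat(sprintf("ForecastResult (%s): %d provinces x %d weeks (%d..%d) x %d indicators\n",
              object@method,
              length(unique(object@predictions$province)), object@horizon,
              object@splitWeek + 1L, object@splitWeek + object@horizon,
              length(unique(object@predictions$indicator))))
})

#' EvaluationReport: forecast and risk-level performance summary
#'
#' Per-indicator RMSE and MAE over the forecast weeks, and one-vs-rest
#' precision/recall/F1 (percent) per risk level with the underlying
#' TP/FP/FN counts.
#'
#' @slot regression data.frame: indicator, rmse, mae.
#' @slot classification data.frame: level, tp, fp, fn, precision, recall,
#'   f1 (percent).
#' @export
setClass("EvaluationReport",
  representation(regression = "data.frame", classification = "data.frame"))

#' @rdname RiceRiskCast-generics
#' @export
setMethod("regressionReport", "EvaluationReport", function(x, ...) x@regression)

#' @rdname RiceRiskCast-generics
#' @export
setMethod("classificationReport", "EvaluationReport", function(x, ...) x@classification)

setMethod("show", "EvaluationReport", function(object) {
  cat("Indicator forecast error:\n")
  print(transform(object@regression, rmse = signif(rmse, 5), mae = signif(mae, 5)),
        row.names = FALSE)
  cat("\nRisk level prediction (one-vs-rest, %):\n")
  cl <- object@classification
  cl$precision <- round(cl$precision, 2)
  cl$recall <- round(cl$recall, 2)
  cl$f1 <- round(cl$f1, 2)
  print(cl, row.names = FALSE)
})

#' InformerModel: trained indicator forecasting network
#'
#' Weights and configuration of an Informer-style encoder-decoder trained
#' on one indicator series (pooled across provinces, with a learned
#' province embedding), plus the per-province standardization fitted on
#' the training weeks and the training loss log.
#'
#' @slot indicator which indicator the model forecasts ("nipi", "thq" or "tcr").
#' @slot params named list of weight matrices/vectors.
#' @slot config forecast configuration list (see \code{\link{forecastConfig}}).
#' @slot scaling data.frame: province, center, scale.
#' @slot trainingLog data.frame: epoch, loss.
#' @export
setClass("InformerModel",
  representation(indicator = "character", params = "list", config = "list",
                 scaling = "data.frame", trainingLog = "data.frame"))

setMethod("show", "InformerModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("InformerModel for '%s': %d parameters, d=%d, %d heads, %d epochs trained\n",
              object@indicator, np, object@config$d, object@config$nHeads,
              nrow(object@trainingLog)))
  if (nrow(object@trainingLog) > 0)
    cat(sprintf("final training loss: %.6f\n",
                object@trainingLog$loss[nrow(object@trainingLog)]))
})
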