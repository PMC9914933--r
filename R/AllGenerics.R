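#' @title Generics for RiceRiskCast containers
#' @description Accessor generics for the S4 containers used across the
#'   package: indicator matrices, risk-level spaces, forecasts and reports.
#' @param x an object
#' @param ... passed to methods
#' @name RiceRiskCast-generics
NULL

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("nipi", function(x, ...) standardGeneric("nipi"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("thq", function(x, ...) standardGeneric("thq"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("tcr", function(x, ...) standardGeneric("tcr"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("gapFilled", function(x, ...) standardGeneric("gapFilled"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("provinces", function(x, ...) standardGeneric("provinces"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("weekIndex", function(x, ...) standardGeneric("weekIndex"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("indicatorMatrix", function(x, ...) standardGeneric("indicatorMatrix"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("riskLevels", function(x, ...) standardGeneric("riskLevels"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("centers", function(x, ...) standardGeneric("centers"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("silhouetteByK", function(x, ...) standardGeneric("silhouetteByK"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("normalizationParams", function(x, ...) standardGeneric("normalizationParams"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("predictions", function(x, ...) standardGeneric("predictions"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("regressionReport", function(x, ...) standardGeneric("regressionReport"))

#' @rdname RiceRiskCast-generics
#' @export
setGeneric("classificationReport", function(x, ...) standardGeneric("classificationReport"))
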