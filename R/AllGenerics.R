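#' @rdname ExpressionMatrix-class
#' @param x an object.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname PCADecomposition-class
#' @param x an object.
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname PCADecomposition-class
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname PCADecomposition-class
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname PCADecomposition-class
#' @export
setGeneric("scoreSd", function(x) standardGeneric("scoreSd"))

#' @rdname PCSelection-class
#' @param x an object.
#' @export
setGeneric("omega", function(x) standardGeneric("omega"))

#' @rdname FeatureOutlierResult-class
#' @param x an object.
#' @export
setGeneric("rawP", function(x) standardGeneric("rawP"))

#' @rdname FeatureOutlierResult-class
#' @export
setGeneric("adjustedP", function(x) standardGeneric("adjustedP"))

#' @rdname FeatureOutlierResult-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname DiscriminationResult-class
#' @param x an object.
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname DiscriminationResult-class
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname QValueResult-class
#' @param x an object.
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname QValueResult-class
#' @export
setGeneric("pi0", function(x) standardGeneric("pi0"))
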