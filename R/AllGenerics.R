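#' @rdname ExpressionMatrix-class
#' @param x an `ExpressionMatrix`.
#' @export
setGeneric("exprLayer", function(x) standardGeneric("exprLayer"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname SignatureScores-class
#' @param x a `SignatureScores`.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname CentroidModel-class
#' @param x a `CentroidModel`.
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname CentroidModel-class
#' @export
setGeneric("cvTrace", function(x) standardGeneric("cvTrace"))

#' @rdname SimTruth-class
#' @param x a `SimTruth`.
#' @export
setGeneric("responderLabels", function(x) standardGeneric("responderLabels"))

#' @rdname SimTruth-class
#' @export
setGeneric("programGenes", function(x) standardGeneric("programGenes"))

#' @rdname SimTruth-class
#' @export
setGeneric("immuneHigh", function(x) standardGeneric("immuneHigh"))
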