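#' @include sisTF-package.R
NULL

#' Gene identifiers of an object
#'
#' @param x an object holding genes (e.g. an [AnnotatedGeneSet]).
#' @return Character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Feature universe of an object
#'
#' The ordered feature space defines the coordinates of binary gene vectors:
#' position `i` of every encoded vector corresponds to `featureSpace(x)[i]`.
#' Features are kept in ascending byte order ("alphabetical" sorting of the
#' Pfam/GO identifier strings).
#'
#' @param x an [AnnotatedGeneSet], [WeightTable] or [SisModel].
#' @return Character vector of feature identifiers, sorted ascending.
#' @export
setGeneric("featureSpace", function(x) standardGeneric("featureSpace"))

#' Per-gene feature sets
#'
#' @param x an [AnnotatedGeneSet].
#' @return Named list of character vectors, one per gene.
#' @export
setGeneric("featureSets", function(x) standardGeneric("featureSets"))

#' Encode genes as binary feature vectors
#'
#' @param x an [AnnotatedGeneSet].
#' @param features optional character vector restricting (and ordering) the
#'   columns; defaults to the full feature space.
#' @return Integer 0/1 matrix, genes in rows, features in columns.
#' @export
setGeneric("encodeGenes", function(x, features = NULL) standardGeneric("encodeGenes"))

#' Per-feature, per-category weights
#'
#' @param x a [WeightTable] or [SisModel].
#' @param what one of `"w"` (weights), `"P"` (joint probabilities),
#'   `"IC"` (information content) or `"C"` (per-category counts).
#' @return Numeric matrix, features in rows, the four categories in columns.
#' @export
setGeneric("featureWeights", function(x, what = "w") standardGeneric("featureWeights"))
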