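#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## AnnotatedGeneSet
## ---------------------------------------------------------------------------

#' A set of genes annotated with binary Pfam/GO features
#'
#' Holds, for every gene, the set of feature identifiers (Pfam accessions and
#' GO term IDs) it carries, together with the ordered feature space that
#' defines vector coordinates for [encodeGenes()].
#'
#' @slot featureSets named list of character vectors; names are gene ids,
#'   values the feature ids of each gene (each gene has at least one).
#' @slot featureSpace character vector of feature ids, sorted ascending by
#'   byte order, duplicate-free, covering every feature used by any gene.
#'
#' @seealso [buildFeatureTable()] to construct one from raw annotation
#'   evidence, [simulateGeneSet()] for synthetic instances.
#' @export
setClass("AnnotatedGeneSet",
  slots = c(featureSets = "list", featureSpace = "character"))

setValidity("AnnotatedGeneSet", function(object) {
  fs <- object@featureSets
  sp <- object@featureSpace
  msg <- character()
  ## an empty gene set is a valid degenerate object
  if (length(fs) > 0L &&
      (is.null(names(fs)) || anyDuplicated(names(fs)) || any(!nzchar(names(fs)))))
    msg <- c(msg, "featureSets must be uniquely named by non-empty gene ids")
  if (any(lengths(fs) == 0L))
    msg <- c(msg, "every gene must carry at least one feature")
  if (anyDuplicated(sp))
    msg <- c(msg, "featureSpace contains duplicates")
  if (is.unsorted(sp, strictly = TRUE) && length(sp) > 1L)
    msg <- c(msg, "featureSpace must be sorted ascending")
  used <- unique(unlist(fs, use.names = FALSE))
  if (!all(used %in% sp))
    msg <- c(msg, "some gene features are absent from featureSpace")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedGeneSet
#'
#' @param featureSets named list of character vectors (gene id -> feature ids).
#'   Duplicate features within a gene are collapsed.
#' @param featureSpace optional character vector of feature ids; defaults to
#'   the sorted union of all features in `featureSets`. Always re-sorted.
#' @return An [AnnotatedGeneSet-class] object.
#' @examples
#' gs <- AnnotatedGeneSet(list(g1 = c("PF00046", "GO:0003700"),
#'                             g2 = "PF00046"))
#' featureSpace(gs)
#' encodeGenes(gs)
#' @export
AnnotatedGeneSet <- function(featureSets, featureSpace = NULL) {
  ## enforce locale-independent byte order for feature coordinates
  featureSets <- lapply(featureSets, function(f) {
    sort(unique(as.character(f)), method = "radix")
  })
  if (length(featureSets) == 0L) names(featureSets) <- character(0)
  if (is.null(featureSpace))
    featureSpace <- unique(unlist(featureSets, use.names = FALSE))
  featureSpace <- sort(unique(as.character(featureSpace)), method = "radix")
  new("AnnotatedGeneSet", featureSets = featureSets, featureSpace = featureSpace)
}

#' @rdname geneIds
#' @export
setMethod("geneIds", "AnnotatedGeneSet", function(x) names(x@featureSets))

#' @rdname featureSpace
#' @export
setMethod("featureSpace", "AnnotatedGeneSet", function(x) x@featureSpace)

#' @rdname featureSets
#' @export
setMethod("featureSets", "AnnotatedGeneSet", function(x) x@featureSets)

#' @export
setMethod("length", "AnnotatedGeneSet", function(x) length(x@featureSets))

setMethod("show", "AnnotatedGeneSet", function(object) {
  cat("AnnotatedGeneSet with", length(object@featureSets), "genes and",
      length(object@featureSpace), "features\n")
  n <- min(3L, length(object@featureSets))
  for (i in seq_len(n)) {
    f <- object@featureSets[[i]]
    cat("  ", names(object@featureSets)[i], ": ",
        paste(utils::head(f, 4L), collapse = ","),
        if (length(f) > 4L) ",..." else "", "\n", sep = "")
  }
  if (length(object@featureSets) > n) cat("  ...\n")
})

#' @rdname encodeGenes
#' @export
setMethod("encodeGenes", "AnnotatedGeneSet", function(x, features = NULL) {
  if (is.null(features)) features <- x@featureSpace
  bad <- setdiff(unique(unlist(x@featureSets, use.names = FALSE)), x@featureSpace)
  if (length(bad))
    stop("features outside the feature space: ", paste(bad, collapse = ", "))
  m <- matrix(0L, nrow = length(x@featureSets), ncol = length(features),
              dimnames = list(names(x@featureSets), features))
  for (i in seq_along(x@featureSets)) {
    hit <- features %in% x@featureSets[[i]]
    if (any(hit)) m[i, hit] <- 1L
  }
  m
})

## ---------------------------------------------------------------------------
## WeightTable
## ---------------------------------------------------------------------------

#' Per-feature, per-category statistical-information weights
#'
#' For feature i and category j, with C_ij the number of category-j training
#' genes carrying i, N_j the number of category-j genes, and
#' C_i = sum_j C_ij, the joint probability is
#' P_ij = C_ij^2 / (N_j * C_i), the information content IC_ij = -log2(P_ij),
#' and the weight w_ij = 1 / IC_ij (0 when C_ij = 0; capped at `wMax` when
#' IC_ij = 0, i.e. P_ij = 1). Multi-label genes contribute to every category
#' they belong to.
#'
#' @slot counts integer matrix C_ij, features x 4 categories.
#' @slot nSamples named numeric, N_j for the four categories.
#' @slot prob numeric matrix P_ij.
#' @slot infoContent numeric matrix IC_ij (Inf where P_ij = 0).
#' @slot weights numeric matrix w_ij.
#' @slot wMax cap applied where IC = 0.
#' @seealso [estimateWeights()]
#' @export
setClass("WeightTable",
  slots = c(counts = "matrix", nSamples = "numeric", prob = "matrix",
            infoContent = "matrix", weights = "matrix", wMax = "numeric"))

setValidity("WeightTable", function(object) {
  msg <- character()
  mats <- list(object@counts, object@prob, object@infoContent, object@weights)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    msg <- c(msg, "count/prob/IC/weight matrices must share dimensions")
  if (!identical(colnames(object@counts), SIS_CATEGORIES))
    msg <- c(msg, "columns must be TFS, MEM, ENZ, OTS in that order")
  if (!identical(names(object@nSamples), SIS_CATEGORIES))
    msg <- c(msg, "nSamples must be named by the four categories")
  if (any(object@prob < 0 | object@prob > 1))
    msg <- c(msg, "joint probabilities must lie in [0, 1]")
  if (any(object@weights < 0))
    msg <- c(msg, "weights must be non-negative")
  if (any((object@weights == 0) != (object@counts == 0)))
    msg <- c(msg, "w_ij must be zero exactly where C_ij is zero")
  if (length(msg)) msg else TRUE
})

#' @rdname featureSpace
#' @export
setMethod("featureSpace", "WeightTable", function(x) rownames(x@weights))

#' @rdname featureWeights
#' @export
setMethod("featureWeights", "WeightTable", function(x, what = "w") {
  switch(match.arg(what, c("w", "P", "IC", "C")),
         w = x@weights, P = x@prob, IC = x@infoContent, C = x@counts)
})

setMethod("show", "WeightTable", function(object) {
  cat("WeightTable:", nrow(object@weights), "features x 4 categories",
      sprintf("(N_j: %s)\n", paste(sprintf("%s=%d", SIS_CATEGORIES,
                                           as.integer(object@nSamples)),
                                   collapse = " ")))
})

## ---------------------------------------------------------------------------
## MWDRanking
## ---------------------------------------------------------------------------

#' Mutual-weight-difference feature ranking
#'
#' Per feature, the four category weights are sorted descending into
#' w_(1) >= w_(2) >= w_(3) >= w_(4) and
#' MWD = w_(1) - (w_(2) + w_(3) + w_(4)) / 3. Features whose top weight is
#' less than the sum of the other three are pruned; the remainder is sorted
#' by MWD descending (ties by feature id ascending).
#'
#' @slot ranking data.frame with columns `feature_id`, `mwd`, `w1`..`w4`
#'   (sorted weights) and `top_category`, ordered by decreasing `mwd`.
#' @slot pruned character vector of pruned feature ids.
#' @seealso [rankFeaturesMWD()]
#' @export
setClass("MWDRanking", slots = c(ranking = "data.frame", pruned = "character"))

setValidity("MWDRanking", function(object) {
  r <- object@ranking
  msg <- character()
  need <- c("feature_id", "mwd", "w1", "w2", "w3", "w4", "top_category")
  if (!all(need %in% names(r)))
    msg <- c(msg, "ranking lacks required columns")
  else {
    if (is.unsorted(rev(r$mwd)))
      msg <- c(msg, "ranking must be sorted by decreasing MWD")
    if (any(r$feature_id %in% object@pruned))
      msg <- c(msg, "pruned features must be absent from the ranking")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("length", "MWDRanking", function(x) nrow(x@ranking))

#' Ranked features of an MWDRanking
#' @param x an [MWDRanking-class].
#' @param k optional head size.
#' @return Character vector of feature ids in rank order.
#' @export
rankedFeatures <- function(x, k = NULL) {
  stopifnot(is(x, "MWDRanking"))
  ids <- x@ranking$feature_id
  if (!is.null(k)) ids <- utils::head(ids, k)
  ids
}

setMethod("show", "MWDRanking", function(object) {
  cat("MWDRanking:", nrow(object@ranking), "features kept,",
      length(object@pruned), "pruned\n")
  print(utils::head(object@ranking[, c("feature_id", "mwd", "top_category")], 5L),
        row.names = FALSE)
})

## ---------------------------------------------------------------------------
## SisModel
## ---------------------------------------------------------------------------

#' A trained statistical-information-similarity classifier
#'
#' @slot featureSpace full feature space the model was trained on.
#' @slot selectedFeatures the top-k ranked features in use for scoring.
#' @slot weightTable [WeightTable-class] over the full feature space.
#' @slot trainingMatrix binary matrix of training genes over
#'   `selectedFeatures`.
#' @slot trainingLabels named list: gene id -> category subset.
#' @slot ranking the [MWDRanking-class] the selection came from.
#' @slot curve LOOCV performance per candidate k (see [sisLoocv()]).
#' @slot bestK the selected feature count.
#' @seealso [sisFit()], [sisPredict()]
#' @export
setClass("SisModel",
  slots = c(featureSpace = "character", selectedFeatures = "character",
            weightTable = "WeightTable", trainingMatrix = "matrix",
            trainingLabels = "list", ranking = "MWDRanking",
            curve = "data.frame", bestK = "integer"))

setValidity("SisModel", function(object) {
  msg <- character()
  if (!all(object@selectedFeatures %in% object@ranking@ranking$feature_id))
    msg <- c(msg, "selected features must come from the ranking")
  if (!identical(colnames(object@trainingMatrix), object@selectedFeatures))
    msg <- c(msg, "training matrix columns must equal selectedFeatures")
  if (!identical(rownames(object@trainingMatrix), names(object@trainingLabels)))
    msg <- c(msg, "training matrix rows must align with trainingLabels")
  if (length(msg)) msg else TRUE
})

#' @rdname featureSpace
#' @export
setMethod("featureSpace", "SisModel", function(x) x@featureSpace)

#' @rdname featureWeights
#' @export
setMethod("featureWeights", "SisModel", function(x, what = "w")
  featureWeights(x@weightTable, what))

#' Selected features of a trained model
#' @param x a [SisModel-class].
#' @return Character vector of the top-k feature ids in rank order.
#' @export
selectedFeatures <- function(x) {
  stopifnot(is(x, "SisModel"))
  x@selectedFeatures
}

#' LOOCV performance curve of a trained model
#' @param x a [SisModel-class].
#' @return data.frame, one row per candidate k.
#' @export
loocvCurve <- function(x) {
  stopifnot(is(x, "SisModel"))
  x@curve
}

setMethod("show", "SisModel", function(object) {
  cat("SisModel: ", nrow(object@trainingMatrix), " training genes, k = ",
      object@bestK, " of ", length(object@ranking),
      " ranked features (space: ", length(object@featureSpace), ")\n", sep = "")
  if (nrow(object@curve)) {
    b <- object@curve[object@curve$k == object@bestK, , drop = FALSE]
    cat(sprintf("  LOOCV at best k: accuracy %.4f, precision %.4f, MCC %.4f\n",
                b$accuracy[1], b$precision[1], b$mcc[1]))
  }
})

## ---------------------------------------------------------------------------
## SampleGroups (maternal-factor caller)
## ---------------------------------------------------------------------------

#' Sample-class grouping for the maternal-factor caller
#'
#' Egg classes supply the maternal expression level; excluded classes (early
#' embryos through blastocyst, testis, ovary, embryonic stem cells) take part
#' in neither side of the comparison; every remaining class is late-stage
#' somatic and must individually be exceeded by the fold rule.
#'
#' @slot eggClasses character, sample-class names counted as egg/MII oocyte.
#' @slot excludedClasses character, classes dropped from the comparison.
#' @export
setClass("SampleGroups",
  slots = c(eggClasses = "character", excludedClasses = "character"))

setValidity("SampleGroups", function(object) {
  msg <- character()
  if (length(object@eggClasses) == 0L)
    msg <- c(msg, "at least one egg class is required")
  if (length(intersect(object@eggClasses, object@excludedClasses)))
    msg <- c(msg, "egg and excluded classes must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleGroups
#'
#' @param eggClasses character vector of egg/MII-oocyte class names.
#' @param excludedClasses character vector of class names excluded from the
#'   somatic comparison set. Defaults to the conventional exclusion list
#'   (early embryos, gonads, ES cells).
#' @return A [SampleGroups-class] object.
#' @export
SampleGroups <- function(eggClasses,
                         excludedClasses = c("1cell", "2cell", "4cell", "8cell",
                                             "morula", "blastocyst", "testis",
                                             "ovary", "ES_cell")) {
  new("SampleGroups", eggClasses = as.character(eggClasses),
      excludedClasses = as.character(excludedClasses))
}

setMethod("show", "SampleGroups", function(object) {
  cat("SampleGroups: egg = {", paste(object@eggClasses, collapse = ", "),
      "}; excluded = {", paste(object@excludedClasses, collapse = ", "), "}\n")
})
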