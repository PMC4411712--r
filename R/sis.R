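## Statistical-information-similarity classifier: weight estimation, MWD
## feature ranking, weighted-cosine scoring, nearest-neighbour prediction and
## the LOOCV feature-count sweep.

#' Normalize category labels
#'
#' Accepts either a named list (gene id -> character vector of categories) or
#' a data.frame with columns `gene_id` and `categories` (comma-joined), and
#' returns a named list aligned to `ids`. Multi-membership is allowed; every
#' gene must carry at least one of TFS, MEM, ENZ, OTS.
#'
#' @param labels named list or data.frame of category labels.
#' @param ids gene ids the labels must cover (order of the result).
#' @return Named list of character category vectors.
#' @export
normalizeLabels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    if (!all(c("gene_id", "categories") %in% names(labels)))
      stop("label data.frame needs 'gene_id' and 'categories' columns")
    if (anyDuplicated(labels$gene_id))
      stop("duplicate gene_id in labels")
    lst <- strsplit(as.character(labels$categories), ",", fixed = TRUE)
    names(lst) <- labels$gene_id
    labels <- lst
  }
  if (is.null(names(labels)))
    stop("labels must be named by gene id")
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop("labels missing for genes: ", paste(utils::head(missing, 5L), collapse = ", "))
  labels <- labels[ids]
  bad <- !vapply(labels, function(x) length(x) >= 1L && all(x %in% SIS_CATEGORIES),
                 logical(1))
  if (any(bad))
    stop("every gene needs >= 1 category from {TFS, MEM, ENZ, OTS}; offending: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  labels
}

## M x 4 logical membership matrix in SIS_CATEGORIES column order
.membershipMatrix <- function(labelsList) {
  m <- vapply(SIS_CATEGORIES,
              function(j) vapply(labelsList, function(l) j %in% l, logical(1)),
              logical(length(labelsList)))
  m <- matrix(m, nrow = length(labelsList),
              dimnames = list(names(labelsList), SIS_CATEGORIES))
  m
}

.asBinaryMatrix <- function(x, features = NULL) {
  if (is(x, "AnnotatedGeneSet")) return(encodeGenes(x, features))
  if (!is.matrix(x)) stop("expected an AnnotatedGeneSet or a binary matrix")
  storage.mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L))) stop("binary matrix may contain only 0 and 1")
  x
}

#' Estimate per-feature, per-category weights
#'
#' Counts feature occurrences per category and converts them to weights via
#' joint probability and information content:
#' P_ij = C_ij^2 / (N_j * C_i), IC_ij = -log2(P_ij), w_ij = 1/IC_ij
#' (0 where C_ij = 0; capped at `wMax` where P_ij = 1 so that IC = 0).
#' A gene labeled with several categories contributes its features to C_ij
#' and itself to N_j for each of them, and C_i = sum_j C_ij under that same
#' convention.
#'
#' @param x an [AnnotatedGeneSet-class] or a binary gene-by-feature matrix
#'   with dimnames.
#' @param labels category labels (see [normalizeLabels()]); all four
#'   categories must be populated.
#' @param wMax cap for the weight of a feature with zero information content
#'   (exclusive to a category and universal within it).
#' @return A [WeightTable-class].
#' @examples
#' gs <- simulateGeneSet(signatureSpec(n_genes_per_category = 5, seed = 1))
#' wt <- estimateWeights(gs$geneset, gs$labels)
#' head(featureWeights(wt))
#' @export
estimateWeights <- function(x, labels, wMax = 1e6) {
  mat <- .asBinaryMatrix(x)
  labels <- normalizeLabels(labels, rownames(mat))
  member <- .membershipMatrix(labels)
  nj <- colSums(member)
  if (any(nj == 0))
    stop("configuration error: no training samples in category ",
         paste(SIS_CATEGORIES[nj == 0], collapse = ", "))
  ## sums of 0/1 products: exact integers in double arithmetic
  cij <- crossprod(mat, member * 1)
  dimnames(cij) <- list(colnames(mat), SIS_CATEGORIES)
  ci <- rowSums(cij)
  if (any(ci == 0))
    stop("consistency error: feature(s) in the space but absent from all genes: ",
         paste(utils::head(colnames(mat)[ci == 0], 5L), collapse = ", "))
  denom <- matrix(ci, nrow = nrow(cij), ncol = 4L) *
    matrix(nj, nrow = nrow(cij), ncol = 4L, byrow = TRUE)
  p <- (cij * cij) / denom
  ## 0 - log2(p) rather than -log2(p): at P = 1 the latter is IEEE negative
  ## zero and 1/IC would flip to -Inf instead of hitting the cap
  ic <- ifelse(p > 0, 0 - log2(p), Inf)
  w <- ifelse(cij == 0, 0, pmin(1 / ic, wMax))
  dimnames(p) <- dimnames(ic) <- dimnames(w) <- dimnames(cij)
  new("WeightTable", counts = cij, nSamples = setNames(as.numeric(nj), SIS_CATEGORIES),
      prob = p, infoContent = ic, weights = w, wMax = wMax)
}

#' Rank features by mutual weight difference
#'
#' For each feature the four category weights are sorted descending and the
#' mutual weight difference MWD = w_(1) - (w_(2)+w_(3)+w_(4))/3 computed.
#' Features whose top weight is smaller than the sum of the other three are
#' pruned; the rest are sorted by MWD descending, ties broken by feature id
#' ascending.
#'
#' @param weights a [WeightTable-class].
#' @return An [MWDRanking-class].
#' @export
rankFeaturesMWD <- function(weights) {
  stopifnot(is(weights, "WeightTable"))
  w <- featureWeights(weights, "w")
  sorted <- t(apply(w, 1L, sort.int, decreasing = TRUE, method = "shell"))
  top <- SIS_CATEGORIES[max.col(w, ties.method = "first")]
  mwd <- sorted[, 1L] - (sorted[, 2L] + sorted[, 3L] + sorted[, 4L]) / 3
  keep <- sorted[, 1L] >= sorted[, 2L] + sorted[, 3L] + sorted[, 4L]
  df <- data.frame(feature_id = rownames(w), mwd = mwd,
                   w1 = sorted[, 1L], w2 = sorted[, 2L],
                   w3 = sorted[, 3L], w4 = sorted[, 4L],
                   top_category = top, row.names = NULL,
                   stringsAsFactors = FALSE)
  pruned <- df$feature_id[!keep]
  df <- df[keep, , drop = FALSE]
  df <- df[order(-df$mwd, df$feature_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  new("MWDRanking", ranking = df, pruned = pruned)
}

#' Cosine similarity of two binary feature vectors
#'
#' @param a,b numeric 0/1 vectors of equal length.
#' @return `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`, in `[0, 1]` for binary
#'   vectors.
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 0, 1))  # 0.5
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  sa <- sum(a * a); sb <- sum(b * b)
  if (sa == 0 || sb == 0)
    stop("similarity is undefined for a zero vector")
  ## a single square root of the integer product keeps sim(a, a) exactly 1
  ## for binary vectors
  sum(a * b) / sqrt(sa * sb)
}

#' Weighted similarity score between two genes for one category
#'
#' `SCORE(a, b, j) = sim(a, b) * sum_k w_kj`, where k runs over the features
#' present in both a and b and w_kj is the weight of feature k in category j
#' (b is the training gene belonging to j).
#'
#' @param a,b 0/1 vectors aligned to the rows of the weight matrix.
#' @param weights a [WeightTable-class], or a numeric weight matrix with the
#'   four category columns.
#' @param category one of `"TFS"`, `"MEM"`, `"ENZ"`, `"OTS"`.
#' @return Non-negative numeric score.
#' @export
sisScore <- function(a, b, weights, category) {
  category <- match.arg(category, SIS_CATEGORIES)
  w <- if (is(weights, "WeightTable")) featureWeights(weights, "w") else weights
  if (length(a) != nrow(w) || length(b) != nrow(w))
    stop("vectors must be aligned to the weight matrix rows")
  shared <- which(a == 1 & b == 1)
  cosineSimilarity(a, b) * sum(w[shared, category])
}

## Core nearest-neighbour scorer. For one query (0/1 vector over the selected
## features) scores every (training gene, category-it-belongs-to) pair and
## returns the maximum. All accumulations run left-to-right over ascending
## feature index so results are reproducible to the last bit.
.nnaClassify <- function(q, trainMat, member, w, trainNormSq, excludeId = NULL) {
  res <- list(category = NA_character_, score = NA_real_,
              neighbor = NA_character_, unclassifiable = TRUE)
  on <- which(q == 1)
  if (length(on) == 0L) return(res)
  ## training genes with no feature in the active space cannot share a
  ## feature with any query; they are excluded as neighbours
  keep <- trainNormSq > 0
  if (!is.null(excludeId)) keep[rownames(trainMat) == excludeId] <- FALSE
  if (!any(keep)) return(res)
  sub <- trainMat[keep, on, drop = FALSE]
  dots <- rowSums(sub)
  sims <- dots / sqrt(length(on) * trainNormSq[keep])
  scores <- matrix(0, nrow = nrow(sub), ncol = 4L,
                   dimnames = list(rownames(sub), SIS_CATEGORIES))
  for (j in seq_len(4L)) {
    wj <- matrix(w[on, j], nrow = nrow(sub), ncol = length(on), byrow = TRUE)
    scores[, j] <- sims * rowSums(sub * wj)
  }
  allowed <- member[keep, , drop = FALSE]
  if (!any(allowed & scores > 0)) return(res)
  best <- max(scores[allowed])
  hit <- which(allowed & scores == best, arr.ind = TRUE)
  ## ties: fixed category priority, then neighbour id ascending
  ord <- order(match(SIS_CATEGORIES[hit[, 2L]], SIS_TIE_ORDER),
               rownames(sub)[hit[, 1L]], method = "radix")
  pick <- hit[ord[1L], ]
  list(category = SIS_CATEGORIES[pick[[2L]]], score = best,
       neighbor = rownames(sub)[pick[[1L]]], unclassifiable = FALSE)
}

#' Classify one query gene with the nearest-neighbour rule
#'
#' Scores the query against every training gene b under every category b
#' belongs to and returns the pair with the maximum weighted-cosine score.
#' Score ties are broken by category priority TFS > ENZ > MEM > OTS, then by
#' neighbour id ascending. A query with no selected feature, or sharing no
#' positively weighted feature with any training gene, is unclassifiable.
#'
#' @param query either a 0/1 vector over `selectedFeatures(model)`, or a
#'   character vector of feature ids.
#' @param model a [SisModel-class].
#' @param excludeId optional training gene id to leave out (LOOCV).
#' @return List with `category`, `score`, `neighbor`, `unclassifiable`.
#' @export
classifyNNA <- function(query, model, excludeId = NULL) {
  stopifnot(is(model, "SisModel"))
  sel <- model@selectedFeatures
  if (is.character(query)) {
    q <- as.integer(sel %in% query)
  } else {
    if (!is.null(names(query))) query <- query[match(sel, names(query))]
    q <- as.integer(query)
    q[is.na(q)] <- 0L
    if (length(q) != length(sel))
      stop("query vector must align with the model's selected features")
  }
  member <- .membershipMatrix(model@trainingLabels)
  w <- featureWeights(model@weightTable, "w")[sel, , drop = FALSE]
  .nnaClassify(q, model@trainingMatrix, member, w,
               rowSums(model@trainingMatrix), excludeId)
}

#' Default feature-count grid for the LOOCV sweep
#'
#' A powers-of-two ladder up to (and including) `n`, keeping the sweep cost
#' linear in `log(n)` rather than `n`.
#'
#' @param n length of the pruned ranking.
#' @return Increasing integer vector.
#' @export
defaultKGrid <- function(n) {
  if (n < 1L) stop("ranking is empty")
  sort(unique(c(2L^(0:floor(log2(n))), as.integer(n))))
}

#' Leave-one-out cross-validation over a feature-count grid
#'
#' For each candidate k, the top-k ranked features define the working space;
#' every training gene is classified by [classifyNNA()] against all others,
#' and TF-versus-rest performance (TFS = positive; unclassifiable counts as a
#' negative prediction) plus four-way accuracy (a prediction is correct when
#' the predicted category is among the gene's labels) are recorded. Weights
#' are estimated once on the full data and restricted to the top-k features
#' (set `reweightPerK = TRUE` to re-estimate within each restricted space,
#' where genes losing all features drop out of the counts).
#'
#' @param x an [AnnotatedGeneSet-class] or binary matrix of training genes.
#' @param labels category labels (see [normalizeLabels()]).
#' @param ranking an [MWDRanking-class]; defaults to ranking freshly
#'   estimated weights.
#' @param kGrid increasing integer vector of candidate feature counts, each
#'   `<=` the ranking length; default [defaultKGrid()].
#' @param weightTable optional precomputed [WeightTable-class].
#' @param wMax weight cap, see [estimateWeights()].
#' @param reweightPerK logical, re-estimate weights inside each top-k space.
#' @return List with `curve` (data.frame: k, confusion counts, the five
#'   TF-versus-rest measures, four-way accuracy, number unclassifiable) and
#'   `bestK` (the k with maximal TF-versus-rest accuracy; ties -> smaller k).
#' @export
sisLoocv <- function(x, labels, ranking = NULL, kGrid = NULL,
                     weightTable = NULL, wMax = 1e6, reweightPerK = FALSE) {
  mat <- .asBinaryMatrix(x)
  labels <- normalizeLabels(labels, rownames(mat))
  if (is.null(weightTable)) weightTable <- estimateWeights(mat, labels, wMax)
  if (is.null(ranking)) ranking <- rankFeaturesMWD(weightTable)
  if (is.null(kGrid)) kGrid <- defaultKGrid(length(ranking))
  kGrid <- as.integer(kGrid)
  if (length(kGrid) == 0L) stop("configuration error: empty k grid")
  if (any(kGrid < 0L) || any(kGrid > length(ranking)))
    stop("configuration error: k grid values must lie in [0, ranking length]")
  member <- .membershipMatrix(labels)
  truthTF <- member[, "TFS"]
  wFull <- featureWeights(weightTable, "w")
  rows <- vector("list", length(kGrid))
  for (gi in seq_along(kGrid)) {
    k <- kGrid[gi]
    sel <- rankedFeatures(ranking, k)
    sub <- mat[, sel, drop = FALSE]
    if (reweightPerK && k > 0L) {
      inPlay <- rowSums(sub) > 0
      w <- featureWeights(estimateWeights(sub[inPlay, , drop = FALSE],
                                          labels[inPlay], wMax), "w")
    } else {
      w <- wFull[sel, , drop = FALSE]
    }
    normSq <- rowSums(sub)
    predTF <- logical(nrow(sub))
    correct4 <- logical(nrow(sub))
    nUncl <- 0L
    for (m in seq_len(nrow(sub))) {
      r <- if (k == 0L) list(unclassifiable = TRUE, category = NA_character_)
           else .nnaClassify(sub[m, ], sub, member, w, normSq,
                             excludeId = rownames(sub)[m])
      if (r$unclassifiable) {
        nUncl <- nUncl + 1L
      } else {
        predTF[m] <- r$category == "TFS"
        correct4[m] <- r$category %in% labels[[m]]
      }
    }
    cc <- confusionCounts(predTF, truthTF)
    met <- classifierMetrics(cc)
    rows[[gi]] <- data.frame(k = k, TP = cc[["TP"]], FP = cc[["FP"]],
                             TN = cc[["TN"]], FN = cc[["FN"]],
                             sensitivity = met$sensitivity,
                             specificity = met$specificity,
                             accuracy = met$accuracy,
                             precision = met$precision,
                             mcc = met$mcc,
                             accuracy4 = mean(correct4),
                             n_unclassifiable = nUncl,
                             stringsAsFactors = FALSE)
  }
  curve <- do.call(rbind, rows)
  ## sensitivity with k = 0: everything unclassifiable, so 0 predicted
  ## positives and sensitivity = 0/(TP+FN) = 0 whenever positives exist
  best <- curve$k[order(-curve$accuracy, curve$k)][1L]
  list(curve = curve, bestK = as.integer(best))
}

#' Fit the statistical-information-similarity classifier
#'
#' Runs the full training path: binary encoding, weight estimation, MWD
#' ranking with pruning, LOOCV sweep over the feature-count grid, and freezes
#' the top-k features at the accuracy-maximizing k.
#'
#' @inheritParams sisLoocv
#' @param kGrid candidate feature counts; default [defaultKGrid()].
#' @return A [SisModel-class].
#' @examples
#' sim <- simulateGeneSet(signatureSpec(n_genes_per_category = 15, seed = 2))
#' model <- sisFit(sim$geneset, sim$labels)
#' model
#' @export
sisFit <- function(x, labels, kGrid = NULL, wMax = 1e6, reweightPerK = FALSE) {
  mat <- .asBinaryMatrix(x)
  labels <- normalizeLabels(labels, rownames(mat))
  wt <- estimateWeights(mat, labels, wMax)
  ranking <- rankFeaturesMWD(wt)
  cv <- sisLoocv(mat, labels, ranking = ranking, kGrid = kGrid,
                 weightTable = wt, wMax = wMax, reweightPerK = reweightPerK)
  sel <- rankedFeatures(ranking, cv$bestK)
  new("SisModel", featureSpace = colnames(mat), selectedFeatures = sel,
      weightTable = wt, trainingMatrix = mat[, sel, drop = FALSE],
      trainingLabels = labels, ranking = ranking, curve = cv$curve,
      bestK = cv$bestK)
}

#' Predict categories for query genes
#'
#' Classifies each query gene against the full training set of a fitted
#' model. Query features outside the model's selected features are ignored;
#' a query with none of the selected features is reported unclassifiable
#' with `tf_flag = FALSE`.
#'
#' @param x an [AnnotatedGeneSet-class] of query genes (or a binary matrix
#'   whose columns cover the model's selected features).
#' @param model a [SisModel-class].
#' @return data.frame with columns `gene_id`, `category` (NA when
#'   unclassifiable), `score`, `neighbor`, `tf_flag`.
#' @export
sisPredict <- function(x, model) {
  stopifnot(is(model, "SisModel"))
  sel <- model@selectedFeatures
  if (is(x, "AnnotatedGeneSet")) {
    sets <- featureSets(x)
    ids <- geneIds(x)
    bits <- lapply(sets, function(f) as.integer(sel %in% f))
  } else {
    mat <- .asBinaryMatrix(x)
    ids <- rownames(mat)
    bits <- lapply(seq_len(nrow(mat)), function(i) {
      v <- integer(length(sel))
      hit <- match(sel, colnames(mat))
      v[!is.na(hit)] <- mat[i, hit[!is.na(hit)]]
      v
    })
  }
  if (length(ids) == 0L)
    return(data.frame(gene_id = character(), category = character(),
                      score = numeric(), neighbor = character(),
                      tf_flag = logical(), stringsAsFactors = FALSE))
  member <- .membershipMatrix(model@trainingLabels)
  w <- featureWeights(model@weightTable, "w")[sel, , drop = FALSE]
  res <- lapply(bits, .nnaClassify, trainMat = model@trainingMatrix,
                member = member, w = w,
                trainNormSq = rowSums(model@trainingMatrix))
  data.frame(gene_id = ids,
             category = vapply(res, `[[`, "", "category"),
             score = vapply(res, `[[`, 0, "score"),
             neighbor = vapply(res, `[[`, "", "neighbor"),
             tf_flag = vapply(res, function(r)
               !r$unclassifiable && r$category == "TFS", logical(1)),
             stringsAsFactors = FALSE)
}
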