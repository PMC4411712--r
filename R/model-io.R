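## Flat-file model serialization. Counts are integers, so weights, ranking
## and the selected feature set are reconstructed bit-identically on read;
## only the LOOCV curve is stored as formatted floating point.

SIS_MODEL_VERSION <- "sisTF-model/1"

#' Serialize a fitted model to a directory of plain-text files
#'
#' Layout: `model.yaml` (version, best k, weight cap, per-category sample
#' counts, k grid), `counts.tsv` (per-feature category counts over the full
#' feature space — weights and the MWD ranking are recomputed from these on
#' read), `training.tsv` (gene id, categories, comma-joined selected
#' features present) and `curve.tsv` (the LOOCV sweep).
#'
#' @param model a [SisModel-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [readSisModel()]
#' @export
writeSisModel <- function(model, dir) {
  stopifnot(is(model, "SisModel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(version = SIS_MODEL_VERSION,
              best_k = model@bestK,
              w_max = model@weightTable@wMax,
              n_samples = as.list(model@weightTable@nSamples))
  yaml::write_yaml(hdr, file.path(dir, "model.yaml"))
  cts <- featureWeights(model@weightTable, "C")
  write.table(data.frame(feature_id = rownames(cts), cts, check.names = FALSE,
                         stringsAsFactors = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tm <- model@trainingMatrix
  feats <- apply(tm, 1L, function(b)
    paste(colnames(tm)[b == 1L], collapse = ","))
  write.table(data.frame(gene_id = rownames(tm),
                         categories = vapply(model@trainingLabels, paste,
                                             collapse = ",", ""),
                         features = feats, stringsAsFactors = FALSE),
              file.path(dir, "training.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeMetricsTsv(model@curve, file.path(dir, "curve.tsv"))
  invisible(dir)
}

#' Read a serialized model
#'
#' @param dir directory written by [writeSisModel()].
#' @return A [SisModel-class].
#' @export
readSisModel <- function(dir) {
  hdr <- yaml::read_yaml(file.path(dir, "model.yaml"))
  if (!identical(hdr$version, SIS_MODEL_VERSION))
    stop("unsupported model version: ", hdr$version)
  cts <- read.table(file.path(dir, "counts.tsv"), sep = "\t", header = TRUE,
                    quote = "", stringsAsFactors = FALSE, check.names = FALSE)
  cij <- as.matrix(cts[, SIS_CATEGORIES])
  rownames(cij) <- cts$feature_id
  nj <- unlist(hdr$n_samples)[SIS_CATEGORIES]
  wMax <- hdr$w_max
  ci <- rowSums(cij)
  denom <- matrix(ci, nrow = nrow(cij), ncol = 4L) *
    matrix(nj, nrow = nrow(cij), ncol = 4L, byrow = TRUE)
  p <- (cij * cij) / denom
  ic <- ifelse(p > 0, 0 - log2(p), Inf)  # avoid IEEE -0 at P = 1
  w <- ifelse(cij == 0, 0, pmin(1 / ic, wMax))
  dimnames(p) <- dimnames(ic) <- dimnames(w) <- dimnames(cij)
  wt <- new("WeightTable", counts = cij,
            nSamples = setNames(as.numeric(nj), SIS_CATEGORIES),
            prob = p, infoContent = ic, weights = w, wMax = wMax)
  ranking <- rankFeaturesMWD(wt)
  tr <- read.table(file.path(dir, "training.tsv"), sep = "\t", header = TRUE,
                   quote = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  sel <- rankedFeatures(ranking, hdr$best_k)
  tm <- matrix(0L, nrow = nrow(tr), ncol = length(sel),
               dimnames = list(tr$gene_id, sel))
  featLists <- strsplit(tr$features, ",", fixed = TRUE)
  for (i in seq_len(nrow(tr)))
    tm[i, featLists[[i]][nzchar(featLists[[i]])]] <- 1L
  labels <- strsplit(tr$categories, ",", fixed = TRUE)
  names(labels) <- tr$gene_id
  curve <- read.table(file.path(dir, "curve.tsv"), sep = "\t", header = TRUE,
                      quote = "", stringsAsFactors = FALSE)
  new("SisModel", featureSpace = rownames(cij), selectedFeatures = sel,
      weightTable = wt, trainingMatrix = tm, trainingLabels = labels,
      ranking = ranking, curve = curve, bestK = as.integer(hdr$best_k))
}
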