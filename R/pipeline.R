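## Staged pipeline: feature table -> labels -> fitted model -> predictions,
## every stage materialized as a plain-text artifact another invocation can
## resume from.

#' Resolved pipeline configuration
#'
#' Collects every tunable threshold with its conventional default: Pfam
#' E-value 1e-3, GO-transfer E-value 1e-10 with top 10 hits and a 50%
#' majority, feature occupancy minimum 20 genes, homology propagation at
#' identity >= 25%, E-value <= 1e-20, >= 2 hits and a 50% majority, maternal
#' fold 4, weight cap 1e6.
#'
#' @param domtblout,blast_go,go_map,metadata,blast_homology input file paths
#'   (any may be NA when the corresponding stage is not run).
#' @param out_dir artifact directory.
#' @param pfam_evalue,go_evalue,go_top_hits,go_frac,min_gene_count GO/Pfam
#'   annotation thresholds.
#' @param hom_identity,hom_evalue,hom_min_hits,hom_frac,hom_top_hits
#'   homology-propagation thresholds.
#' @param mf_fold maternal-factor fold threshold.
#' @param w_max weight cap.
#' @param k_grid LOOCV feature-count grid (NULL = powers-of-two ladder).
#' @param reweight_per_k re-estimate weights inside each top-k space.
#' @param threads accepted for interface compatibility; the LOOCV loop is
#'   sequential and results never depend on this value.
#' @param seed integer seed recorded with the run.
#' @return A list of class `"sisConfig"`.
#' @export
runConfig <- function(domtblout = NA_character_, blast_go = NA_character_,
                      go_map = NA_character_, metadata = NA_character_,
                      blast_homology = NA_character_, out_dir = "sistf_out",
                      pfam_evalue = 1e-3, go_evalue = 1e-10, go_top_hits = 10L,
                      go_frac = 0.5, min_gene_count = 20L,
                      hom_identity = 25, hom_evalue = 1e-20,
                      hom_min_hits = 2L, hom_frac = 0.5, hom_top_hits = 10L,
                      mf_fold = 4, w_max = 1e6, k_grid = NULL,
                      reweight_per_k = FALSE, threads = 1L, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "sisConfig")
}

.stageMsg <- function(stage, what) message("[", stage, "] ", what)

#' Run the staged prediction pipeline
#'
#' Stages, in order: (1) `features.tsv` — parse the domtblout and BLAST/GO
#' inputs and build the filtered feature table; (2) `labels.tsv` — rule-based
#' labeling with homology propagation; (3) `model/` plus `curve.tsv` — fit
#' the classifier with the LOOCV sweep; (4) `predictions.tsv` — classify the
#' training genes with the frozen model. A stage whose artifact already
#' exists is skipped, so deleting a downstream artifact and rerunning
#' regenerates only the downstream stages. The resolved configuration is
#' echoed to `config.yaml` next to the artifacts. Reruns with identical
#' inputs and configuration produce byte-identical artifacts.
#'
#' @param config a `"sisConfig"` from [runConfig()].
#' @return Named list of artifact paths, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "sisConfig"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list(features = file.path(out, "features.tsv"),
                labels = file.path(out, "labels.tsv"),
                model = file.path(out, "model"),
                curve = file.path(out, "curve.tsv"),
                predictions = file.path(out, "predictions.tsv"),
                config = file.path(out, "config.yaml"))
  cfgOut <- config
  cfgOut$k_grid <- if (is.null(config$k_grid)) "auto" else config$k_grid
  yaml::write_yaml(unclass(cfgOut), paths$config)

  for (f in c("domtblout", "blast_go", "go_map", "metadata")) {
    if (is.na(config[[f]]) || !file.exists(config[[f]]))
      stop("pipeline stage 'inputs': missing input file for '", f, "'")
  }

  if (!file.exists(paths$features)) {
    .stageMsg("features", "building feature table")
    hits <- readDomtblout(config$domtblout)
    pfam <- assignPfamFeatures(hits, config$pfam_evalue)
    blast <- readBlastTab(config$blast_go)
    goMap <- readGoMap(config$go_map)
    go <- assignGoFeatures(blast, goMap, config$go_evalue,
                           config$go_top_hits, config$go_frac)
    gs <- buildFeatureTable(pfam, go, config$min_gene_count)
    writeFeatureTable(gs, paths$features)
  } else .stageMsg("features", "artifact exists, skipping")
  gs <- readFeatureTable(paths$features)

  if (!file.exists(paths$labels)) {
    .stageMsg("labels", "rule-based labeling + homology propagation")
    meta <- readMetadataTsv(config$metadata)
    meta <- meta[meta$gene_id %in% geneIds(gs), , drop = FALSE]
    hom <- if (!is.na(config$blast_homology) &&
               file.exists(config$blast_homology))
      readBlastTab(config$blast_homology) else NULL
    labels <- assignCategoryLabels(meta, hom,
                                   minHits = config$hom_min_hits,
                                   topN = config$hom_top_hits,
                                   minFrac = config$hom_frac,
                                   minIdentity = config$hom_identity,
                                   evalueMax = config$hom_evalue)
    writeLabelsTsv(labels, paths$labels)
  } else .stageMsg("labels", "artifact exists, skipping")
  labels <- readLabelsTsv(paths$labels)

  if (!dir.exists(paths$model)) {
    .stageMsg("model", "fitting classifier (LOOCV sweep)")
    model <- sisFit(gs, labels, kGrid = config$k_grid, wMax = config$w_max,
                    reweightPerK = config$reweight_per_k)
    writeSisModel(model, paths$model)
    writeMetricsTsv(loocvCurve(model), paths$curve)
  } else .stageMsg("model", "artifact exists, skipping")
  model <- readSisModel(paths$model)

  if (!file.exists(paths$predictions)) {
    .stageMsg("predict", "classifying genes")
    pred <- sisPredict(gs, model)
    writePredictionsTsv(pred, paths$predictions)
  } else .stageMsg("predict", "artifact exists, skipping")

  invisible(paths)
}

#' Write a predictions TSV
#'
#' Columns: `gene_id`, `category`, `score`, `neighbor`, `tf_flag`.
#'
#' @param pred data.frame from [sisPredict()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writePredictionsTsv <- function(pred, path) {
  out <- pred
  out$score <- sprintf("%.17g", out$score)
  out$tf_flag <- as.integer(out$tf_flag)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
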