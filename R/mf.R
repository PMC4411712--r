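## Strictly-maternal-factor caller: a gene is maternal when its egg
## expression is at least `fold` times the value in every late-stage somatic
## sample, with early embryos, gonads and ES cells excluded from the
## comparison, and genes collapsed over probes by an any-probe rule.

.mfAssay <- function(se) {
  stopifnot(is(se, "SummarizedExperiment"))
  a <- SummarizedExperiment::assays(se)
  nm <- if ("exprs" %in% names(a)) "exprs" else 1L
  m <- as.matrix(a[[nm]])
  if (any(!is.finite(m)) || any(m <= 0))
    stop("expression values must be positive finite reals (linear scale)")
  m
}

.resolveGroups <- function(se, groups) {
  stopifnot(is(groups, "SampleGroups"))
  cls <- SummarizedExperiment::colData(se)$sample_class
  if (is.null(cls))
    stop("colData(se)$sample_class is required")
  cls <- as.character(cls)
  egg <- which(cls %in% groups@eggClasses)
  excluded <- which(cls %in% groups@excludedClasses)
  somatic <- setdiff(seq_along(cls), c(egg, excluded))
  if (length(egg) == 0L)
    stop("configuration error: no egg samples resolved")
  if (length(somatic) == 0L)
    stop("configuration error: no somatic samples remain after exclusion")
  list(egg = egg, somatic = somatic, excluded = excluded)
}

#' Call strictly maternal probes
#'
#' A probe is called maternal iff its egg statistic (mean over egg
#' replicates by default, or the minimum) is at least `fold` times the value
#' of *every* late-stage somatic sample individually — "no less than
#' four-fold" is read inclusively, so a probe sitting exactly at the fold
#' boundary is called. Samples of excluded classes take part in neither side
#' of the comparison.
#'
#' Values must be positive and on linear scale (post-normalization). If the
#' matrix looks log-transformed (all values below 30) the caller refuses
#' unless `inputScale = "linear"` is stated explicitly.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment-class] with assay
#'   `"exprs"` (probes x samples), `rowData()$gene_id` and
#'   `colData()$sample_class`.
#' @param groups a [SampleGroups-class].
#' @param fold linear-scale fold threshold, default 4.
#' @param eggStat `"mean"` (default) or `"min"` aggregation over egg
#'   replicates.
#' @param inputScale `"auto"` (reject suspected log-scale input) or
#'   `"linear"`.
#' @return Named logical vector, one element per probe.
#' @export
callMaternalProbes <- function(se, groups, fold = 4,
                               eggStat = c("mean", "min"),
                               inputScale = c("auto", "linear")) {
  eggStat <- match.arg(eggStat)
  inputScale <- match.arg(inputScale)
  if (fold <= 1) stop("configuration error: fold must exceed 1")
  m <- .mfAssay(se)
  if (inputScale == "auto" && max(m) < 30)
    stop("all values are < 30: input looks log-scale; the fold rule needs ",
         "linear-scale values. Pass inputScale = \"linear\" to override.")
  g <- .resolveGroups(se, groups)
  eggVal <- if (eggStat == "mean") rowMeans(m[, g$egg, drop = FALSE])
            else apply(m[, g$egg, drop = FALSE], 1L, min)
  somMax <- apply(m[, g$somatic, drop = FALSE], 1L, max)
  ## egg >= fold * v_s for every somatic s  <=>  egg >= fold * max_s v_s
  calls <- eggVal >= fold * somMax
  names(calls) <- rownames(m)
  calls
}

#' Collapse probe-level maternal calls to genes
#'
#' A gene is maternal iff *any* of its probes is called maternal (probe
#' disagreement is attributed to alternative isoforms, so one passing probe
#' retains the gene).
#'
#' @param calls named logical vector from [callMaternalProbes()].
#' @param geneMap named character vector or data.frame mapping probe id to
#'   gene id; probes without a mapping are dropped with a warning.
#' @return Named logical vector, one element per gene.
#' @export
collapseToGenes <- function(calls, geneMap) {
  if (is.data.frame(geneMap)) {
    gm <- setNames(as.character(geneMap$gene_id), geneMap$probe_id)
  } else gm <- geneMap
  genes <- gm[names(calls)]
  if (anyNA(genes)) {
    warning(sum(is.na(genes)), " probe(s) without gene mapping dropped")
    calls <- calls[!is.na(genes)]
    genes <- genes[!is.na(genes)]
  }
  res <- tapply(calls, genes, any)
  setNames(as.logical(res), names(res))
}

#' Call strictly maternal genes
#'
#' Runs [callMaternalProbes()] and [collapseToGenes()] and summarizes per
#' gene.
#'
#' @inheritParams callMaternalProbes
#' @return data.frame: `gene_id`, `n_probes`, `n_mf_probes`, `mf_flag`.
#' @examples
#' sim <- simulateExpression(expressionSpec(n_genes = 30, seed = 3))
#' head(callMaternalFactors(sim$se, sim$groups))
#' @export
callMaternalFactors <- function(se, groups, fold = 4,
                                eggStat = c("mean", "min"),
                                inputScale = c("auto", "linear")) {
  calls <- callMaternalProbes(se, groups, fold, eggStat, inputScale)
  genes <- as.character(SummarizedExperiment::rowData(se)$gene_id)
  if (is.null(genes) || length(genes) != length(calls))
    stop("rowData(se)$gene_id is required for gene collapse")
  nProbes <- tapply(calls, genes, length)
  nMf <- tapply(calls, genes, sum)
  ids <- sort(unique(genes), method = "radix")
  data.frame(gene_id = ids,
             n_probes = as.integer(nProbes[ids]),
             n_mf_probes = as.integer(nMf[ids]),
             mf_flag = as.integer(nMf[ids]) > 0L,
             stringsAsFactors = FALSE)
}

#' Write / read an expression TSV with probe-to-gene mapping
#'
#' Columns: `probe_id`, `gene_id`, then one column per sample. The companion
#' sample-class TSV has columns `sample_id`, `class`.
#'
#' @param se a SummarizedExperiment as in [callMaternalProbes()].
#' @param path expression TSV path.
#' @param classPath optional sample-class TSV path.
#' @return `path` invisibly (writer); a SummarizedExperiment (reader).
#' @export
writeExpressionTsv <- function(se, path, classPath = NULL) {
  m <- .mfAssay(se)
  df <- data.frame(probe_id = rownames(m),
                   gene_id = as.character(SummarizedExperiment::rowData(se)$gene_id),
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(m)
  ## full precision so that round-trips preserve boundary ratios exactly
  for (j in names(vals)) vals[[j]] <- sprintf("%.17g", vals[[j]])
  write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(classPath)) {
    cls <- data.frame(sample_id = colnames(m),
                      class = as.character(
                        SummarizedExperiment::colData(se)$sample_class),
                      stringsAsFactors = FALSE)
    write.table(cls, classPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(path, classPath = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe_id
  cls <- if (!is.null(classPath)) {
    cdf <- read.table(classPath, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE)
    setNames(cdf$class, cdf$sample_id)[colnames(m)]
  } else rep(NA_character_, ncol(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    rowData = S4Vectors::DataFrame(gene_id = df$gene_id,
                                   row.names = df$probe_id),
    colData = S4Vectors::DataFrame(sample_class = unname(cls),
                                   row.names = colnames(m)))
}
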