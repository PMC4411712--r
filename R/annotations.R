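## Building the binary feature table from raw annotation evidence: HMMER
## domtblout and tabular BLAST readers, the Pfam e-value cutoff, the
## five-criteria GO transfer, redundancy/sequence pre-filters, and the
## feature/gene occupancy filters.

#' Filter protein sequences by length and alphabet
#'
#' Retains sequences whose length lies in `[minLen, maxLen]` (inclusive) and
#' whose characters are all in the allowed alphabet (the 20 standard amino
#' acids plus X/B/Z/U by default); everything else — e.g. sequences carrying
#' `'*'` — is rejected with a reason.
#'
#' @param x a [Biostrings::AAStringSet] or path to a protein FASTA file.
#' @param minLen,maxLen inclusive length bounds.
#' @param alphabet allowed single-letter residue codes.
#' @return List with `retained` (AAStringSet) and `rejected` (data.frame:
#'   `id`, `reason`).
#' @export
filterSequences <- function(x, minLen = 50L, maxLen = 5000L,
                            alphabet = c("A","C","D","E","F","G","H","I","K",
                                         "L","M","N","P","Q","R","S","T","V",
                                         "W","Y","X","B","Z","U")) {
  if (is.character(x) && length(x) == 1L)
    x <- Biostrings::readAAStringSet(x)
  stopifnot(is(x, "AAStringSet"))
  if (any(!nzchar(names(x))))
    stop("sequence records must have non-empty ids")
  lens <- Biostrings::width(x)
  seqs <- as.character(x)
  okAlpha <- vapply(seqs, function(s) {
    all(strsplit(s, "")[[1L]] %in% alphabet)
  }, logical(1), USE.NAMES = FALSE)
  reason <- rep(NA_character_, length(x))
  reason[lens < minLen] <- "too short"
  reason[lens > maxLen] <- "too long"
  reason[is.na(reason) & !okAlpha] <- "irregular characters"
  keep <- is.na(reason)
  list(retained = x[keep],
       rejected = data.frame(id = names(x)[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Read HMMER3 hmmscan --domtblout output
#'
#' Whitespace-delimited rows, `#` comments skipped. Per data row the query
#' name (column 4), the Pfam model accession (column 2, version suffix such
#' as `.28` stripped) and the full-sequence E-value (column 7) are extracted.
#' Rows with fewer than 23 columns raise a parse error naming the row.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `pfam_id`, `evalue`.
#' @export
readDomtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  n <- 0L
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(f) < 23L)
      stop("domtblout parse error at line ", i, ": expected >= 23 columns, got ",
           length(f))
    acc <- sub("\\.\\d+$", "", f[2L])
    ev <- suppressWarnings(as.numeric(f[7L]))
    if (is.na(ev) || ev <= 0)
      stop("domtblout parse error at line ", i, ": bad E-value '", f[7L], "'")
    if (!grepl("^PF\\d{5}$", acc))
      stop("domtblout parse error at line ", i, ": bad Pfam accession '",
           f[2L], "'")
    n <- n + 1L
    out[[n]] <- data.frame(gene_id = f[4L], pfam_id = acc, evalue = ev,
                           stringsAsFactors = FALSE)
  }
  if (n == 0L)
    return(data.frame(gene_id = character(), pfam_id = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(n)])
}

#' Read 12-column tabular BLAST output
#'
#' Standard `-outfmt 6` columns (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore). Hits are ranked 1..n within each
#' query by ascending E-value (stable for ties).
#'
#' @param path file path.
#' @return data.frame of the 12 columns plus `rank`.
#' @export
readBlastTab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, quote = "",
               comment.char = "", stringsAsFactors = FALSE,
               col.names = cols),
    error = function(e) stop("BLAST table parse error: ", conditionMessage(e)))
  if (nrow(df) == 0L) { df$rank <- integer(); return(df) }
  rankBlastHits(df)
}

#' Assign within-query ranks to BLAST hits
#'
#' @param df data.frame with at least `qseqid` and `evalue`.
#' @return `df` reordered by query then ascending E-value, with a 1-based
#'   `rank` column, consecutive within each query.
#' @export
rankBlastHits <- function(df) {
  ord <- order(df$qseqid, df$evalue, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$qseqid, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Read a subject-to-GO mapping table
#'
#' Two-column TSV (`subject_id`, `go_id`), no header.
#'
#' @param path file path.
#' @return Named list: subject id -> character vector of GO ids.
#' @export
readGoMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   stringsAsFactors = FALSE,
                   col.names = c("subject_id", "go_id"))
  split(df$go_id, df$subject_id)
}

#' Keep the longest member of each redundancy cluster
#'
#' Consumes a precomputed cluster table (e.g. from CD-HIT at 90% identity)
#' and returns the ids to retain: the longest member per cluster, ties
#' broken by member id ascending.
#'
#' @param clusters data.frame with columns `cluster_id`, `member_id`,
#'   `length`, or a path to a headerless TSV of those three columns.
#' @return Character vector of retained member ids.
#' @export
applyClusterFilter <- function(clusters) {
  if (is.character(clusters) && length(clusters) == 1L)
    clusters <- read.table(clusters, sep = "\t", header = FALSE, quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("cluster_id", "member_id", "length"))
  keep <- vapply(split(seq_len(nrow(clusters)), clusters$cluster_id),
                 function(idx) {
                   sub <- clusters[idx, , drop = FALSE]
                   sub <- sub[order(-sub$length, sub$member_id, method = "radix"), ]
                   sub$member_id[1L]
                 }, "")
  unname(sort(keep, method = "radix"))
}

#' Assign Pfam features from domain hits
#'
#' A hit is retained iff its full-sequence E-value is `<= evalueMax`
#' (inclusive threshold); duplicate hits of the same family on one gene
#' collapse to a single feature.
#'
#' @param hits data.frame from [readDomtblout()].
#' @param evalueMax E-value cutoff, default `1e-3`.
#' @return Named list: gene id -> character vector of Pfam feature ids.
#' @export
assignPfamFeatures <- function(hits, evalueMax = 1e-3) {
  hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  lapply(split(hits$pfam_id, hits$gene_id), function(x)
    sort(unique(x), method = "radix"))
}

#' Transfer GO terms from BLAST hits
#'
#' Per query: hits with E-value `<= evalueMax` are kept, truncated to the
#' `topN` best ranks, and a GO term is transferred iff it occurs in at least
#' `minFrac` of those kept hits. Subjects absent from the mapping contribute
#' empty GO sets (they still count in the denominator).
#'
#' @param blast data.frame from [readBlastTab()] (must carry `rank`).
#' @param goMap named list from [readGoMap()].
#' @param evalueMax E-value cutoff, default `1e-10`.
#' @param topN number of top hits retained, default 10.
#' @param minFrac minimum fraction of kept hits carrying the term, in
#'   `(0, 1]`, default 0.5.
#' @return Named list: query id -> character vector of GO feature ids
#'   (queries with no kept hits map to empty vectors).
#' @export
assignGoFeatures <- function(blast, goMap, evalueMax = 1e-10, topN = 10L,
                             minFrac = 0.5) {
  if (!(minFrac > 0 && minFrac <= 1))
    stop("configuration error: minFrac must lie in (0, 1]")
  if (is.null(blast$rank)) blast <- rankBlastHits(blast)
  res <- lapply(split(blast, blast$qseqid), function(sub) {
    sub <- sub[sub$evalue <= evalueMax, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    sub <- utils::head(sub, topN)
    if (nrow(sub) == 0L) return(character())
    goLists <- lapply(sub$sseqid, function(s) unique(goMap[[s]]))
    counts <- table(unlist(goLists, use.names = FALSE))
    sort(names(counts)[counts >= minFrac * nrow(sub)], method = "radix")
  })
  res
}

#' Build the annotated gene set from Pfam and GO feature assignments
#'
#' Per gene, Pfam and GO features are unioned; features occurring in fewer
#' than `minGeneCount` genes are removed; genes left featureless are then
#' excluded. Both filters are applied once, in that order. The feature space
#' of the result is the sorted set of surviving features.
#'
#' @param pfamFeatures named list, gene id -> Pfam feature ids.
#' @param goFeatures named list, gene id -> GO feature ids.
#' @param minGeneCount minimum number of genes a feature must occur in,
#'   default 20.
#' @return An [AnnotatedGeneSet-class].
#' @examples
#' buildFeatureTable(list(g1 = "PF00001", g2 = "PF00001", g3 = "PF00001"),
#'                   list(g3 = "GO:0000001"), minGeneCount = 2)
#' @export
buildFeatureTable <- function(pfamFeatures, goFeatures = list(),
                              minGeneCount = 20L) {
  ids <- sort(unique(c(names(pfamFeatures), names(goFeatures))), method = "radix")
  sets <- setNames(lapply(ids, function(g)
    sort(unique(c(pfamFeatures[[g]], goFeatures[[g]])), method = "radix")), ids)
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L)
    stop("no informative features: all genes are featureless")
  counts <- table(unlist(sets, use.names = FALSE))
  keepFeat <- names(counts)[counts >= minGeneCount]
  sets <- lapply(sets, function(f) f[f %in% keepFeat])
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L)
    stop("no informative features survive the occupancy filter")
  AnnotatedGeneSet(sets, featureSpace = keepFeat)
}

#' Write / read a feature table TSV
#'
#' Two columns, tab-separated with header: `gene_id` and comma-joined
#' `features`.
#'
#' @param x an [AnnotatedGeneSet-class].
#' @param path file path.
#' @return `path` invisibly (writer); an [AnnotatedGeneSet-class] (reader).
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "AnnotatedGeneSet"))
  df <- data.frame(gene_id = geneIds(x),
                   features = vapply(featureSets(x), paste,
                                     collapse = ",", ""),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  sets <- strsplit(df$features, ",", fixed = TRUE)
  names(sets) <- df$gene_id
  AnnotatedGeneSet(sets)
}
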