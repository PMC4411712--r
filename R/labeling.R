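## Rule-based construction of the four training categories from protein
## metadata, homology propagation of labels, and the OTS fallback.

#' Default transcription-factor-activity phrase list
#'
#' Reads the phrase file shipped with the package (or a user-supplied one):
#' one phrase per line, `#` comments ignored, matched case-insensitively as
#' substrings against Pfam/GO descriptions.
#'
#' @param path optional path to an alternative phrase file.
#' @return Character vector of lower-case phrases.
#' @export
tfActivityPhrases <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tf_activity_phrases.txt", package = "sisTF",
                        mustWork = TRUE)
  lines <- trimws(readLines(path))
  tolower(lines[nzchar(lines) & !grepl("^#", lines)])
}

.containsAny <- function(text, phrases) {
  text <- tolower(text)
  any(vapply(phrases, function(p) grepl(p, text, fixed = TRUE), logical(1)))
}

#' Label genes by metadata rules
#'
#' Case-insensitive substring rules over a protein metadata table:
#' \describe{
#'   \item{TFS}{any Pfam/GO description matches the transcription-factor
#'     activity phrase list, or name/description contains "transcription
#'     factor" or "transcription initiation factor" — unless a cofactor
#'     keyword fires.}
#'   \item{cofactor veto}{"cofactor", "coregulator", "coactivator" or
#'     "corepressor" anywhere in name/description/keywords forces OTS and
#'     vetoes TFS (MEM/ENZ are unaffected).}
#'   \item{MEM}{description contains "membrane", or GO descriptions include
#'     "integral to membrane", or keywords contain "transmembrane", or the
#'     `tmhmm_flag` column is TRUE.}
#'   \item{ENZ}{the `ec_flag` column is TRUE, or the description carries an
#'     EC-number pattern (`EC x.x.x.x`), or a word with a configured enzyme
#'     suffix ("-ase" by default).}
#' }
#' Genes matching no rule get an empty category set here; homology
#' propagation and the OTS fallback complete the labeling.
#'
#' @param meta data.frame with columns `gene_id`, `name`, `description`,
#'   `keywords` and `go_descriptions` (`;`-joined), optionally
#'   `pfam_descriptions`, `ec_flag`, `tmhmm_flag`.
#' @param tfPhrases phrase list, see [tfActivityPhrases()].
#' @param enzymeSuffixes word suffixes flagging enzymes in free text.
#' @return data.frame: `gene_id`, `categories` (comma-joined, possibly
#'   empty), `provenance` (rule names that fired).
#' @examples
#' labelByRules(data.frame(gene_id = "g1", name = "g1",
#'   description = "homeobox transcription factor", keywords = "",
#'   go_descriptions = ""))
#' @export
labelByRules <- function(meta, tfPhrases = tfActivityPhrases(),
                         enzymeSuffixes = "ase") {
  stopifnot(all(c("gene_id", "name", "description") %in% names(meta)))
  getCol <- function(nm, default) {
    if (nm %in% names(meta)) meta[[nm]] else rep(default, nrow(meta))
  }
  keywords <- getCol("keywords", "")
  goDesc <- getCol("go_descriptions", "")
  pfamDesc <- getCol("pfam_descriptions", "")
  ecFlag <- as.logical(getCol("ec_flag", FALSE))
  tmhmm <- as.logical(getCol("tmhmm_flag", FALSE))
  cofactorWords <- c("cofactor", "coregulator", "coactivator", "corepressor")
  enzPattern <- paste0("\\b[[:alnum:]-]+(", paste(enzymeSuffixes, collapse = "|"),
                       ")\\b")
  ecPattern <- "\\bEC[ :]?\\d+\\.\\d+\\.\\d+\\.\\d+"
  out <- data.frame(gene_id = meta$gene_id, categories = "", provenance = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(meta))) {
    nameDesc <- paste(meta$name[i], meta$description[i])
    annDesc <- paste(goDesc[i], pfamDesc[i])
    fired <- character()
    cats <- character()
    tf <- .containsAny(annDesc, tfPhrases) ||
      .containsAny(nameDesc, c("transcription factor",
                               "transcription initiation factor"))
    veto <- .containsAny(paste(nameDesc, keywords[i]), cofactorWords)
    if (tf && !veto) { cats <- c(cats, "TFS"); fired <- c(fired, "tf_keyword") }
    if (veto) { cats <- c(cats, "OTS"); fired <- c(fired, "cofactor_veto") }
    mem <- .containsAny(meta$description[i], "membrane") ||
      .containsAny(goDesc[i], "integral to membrane") ||
      .containsAny(keywords[i], "transmembrane") ||
      isTRUE(tmhmm[i])
    if (mem) { cats <- c(cats, "MEM"); fired <- c(fired, "membrane_rule") }
    enz <- isTRUE(ecFlag[i]) ||
      grepl(ecPattern, meta$description[i], ignore.case = TRUE) ||
      grepl(enzPattern, meta$description[i], ignore.case = TRUE)
    if (enz) { cats <- c(cats, "ENZ"); fired <- c(fired, "enzyme_rule") }
    cats <- unique(cats)
    out$categories[i] <- paste(cats[order(match(cats, SIS_CATEGORIES))],
                               collapse = ",")
    out$provenance[i] <- paste(fired, collapse = ",")
  }
  out
}

#' Propagate category labels by homology
#'
#' For one still-unlabeled gene: its BLAST hits are truncated to the `topN`
#' best ranks, then filtered to identity `>= minIdentity` and E-value
#' `<= evalueMax`. If at least `minHits` hits qualify and at least `minFrac`
#' of the qualifying hits carry a category c in {TFS, MEM, ENZ}, every such
#' c is assigned; otherwise the gene is assigned OTS.
#'
#' @param geneId the query gene id.
#' @param blast data.frame of BLAST hits (all queries or just this one; a
#'   `rank` column is added if absent).
#' @param labelsSoFar named list, subject gene id -> character categories
#'   (typically the rule-stage labels).
#' @param minHits minimum number of qualifying hits, default 2.
#' @param topN hit-list truncation, default 10.
#' @param minFrac minimum fraction of qualifying hits sharing a category,
#'   default 0.5.
#' @param minIdentity minimum percent identity, default 25.
#' @param evalueMax maximum E-value, default 1e-20.
#' @return List with `categories` (character) and `provenance`.
#' @export
propagateByHomology <- function(geneId, blast, labelsSoFar, minHits = 2L,
                                topN = 10L, minFrac = 0.5, minIdentity = 25,
                                evalueMax = 1e-20) {
  if (is.null(blast$rank)) blast <- rankBlastHits(blast)
  sub <- blast[blast$qseqid == geneId, , drop = FALSE]
  sub <- sub[order(sub$rank), , drop = FALSE]
  sub <- utils::head(sub, topN)
  sub <- sub[sub$pident >= minIdentity & sub$evalue <= evalueMax, , drop = FALSE]
  ots <- list(categories = "OTS", provenance = "homology_residual")
  if (nrow(sub) < minHits) return(ots)
  cats <- character()
  for (j in c("TFS", "MEM", "ENZ")) {
    n <- sum(vapply(sub$sseqid, function(s) j %in% labelsSoFar[[s]], logical(1)))
    if (n >= minFrac * nrow(sub)) cats <- c(cats, j)
  }
  if (length(cats) == 0L) return(ots)
  list(categories = cats, provenance = "homology_propagation")
}

#' Finalize category labels with the OTS fallback
#'
#' Genes with no category after the rule and homology passes receive OTS.
#' Errors on duplicated gene ids. Attaches per-category totals as the
#' `"totals"` attribute.
#'
#' @param labels data.frame with `gene_id`, `categories` (comma-joined,
#'   possibly empty) and optionally `provenance`.
#' @return The completed data.frame (every gene has >= 1 category).
#' @export
finalizeLabels <- function(labels) {
  if (anyDuplicated(labels$gene_id))
    stop("duplicate gene_id in labels: ",
         labels$gene_id[duplicated(labels$gene_id)][1L])
  if (is.null(labels$provenance)) labels$provenance <- ""
  empty <- !nzchar(labels$categories)
  labels$categories[empty] <- "OTS"
  labels$provenance[empty] <- ifelse(nzchar(labels$provenance[empty]),
                                     paste0(labels$provenance[empty],
                                            ",ots_fallback"),
                                     "ots_fallback")
  lst <- strsplit(labels$categories, ",", fixed = TRUE)
  totals <- vapply(SIS_CATEGORIES, function(j)
    sum(vapply(lst, function(x) j %in% x, logical(1))), integer(1))
  attr(labels, "totals") <- totals
  labels
}

#' Run the full labeling pipeline
#'
#' Rule-based labeling, homology propagation for the genes the rules left
#' unlabeled, then the OTS fallback. Output is independent of input row
#' order: propagation consults only the rule-stage labels.
#'
#' @inheritParams labelByRules
#' @param blast optional BLAST table for homology propagation.
#' @param ... further arguments passed to [propagateByHomology()].
#' @return data.frame as from [finalizeLabels()].
#' @export
assignCategoryLabels <- function(meta, blast = NULL,
                                 tfPhrases = tfActivityPhrases(), ...) {
  ruleLabels <- labelByRules(meta, tfPhrases = tfPhrases)
  labelsSoFar <- strsplit(ruleLabels$categories, ",", fixed = TRUE)
  names(labelsSoFar) <- ruleLabels$gene_id
  unl <- which(!nzchar(ruleLabels$categories))
  if (length(unl) && !is.null(blast) && nrow(blast)) {
    if (is.null(blast$rank)) blast <- rankBlastHits(blast)
    for (i in unl) {
      r <- propagateByHomology(ruleLabels$gene_id[i], blast, labelsSoFar, ...)
      ruleLabels$categories[i] <- paste(r$categories, collapse = ",")
      ruleLabels$provenance[i] <- r$provenance
    }
  }
  finalizeLabels(ruleLabels)
}

#' Write / read a labels TSV
#'
#' Three tab-separated columns with header: `gene_id`, `categories`
#' (comma-joined), `provenance`.
#'
#' @param labels data.frame of labels.
#' @param path file path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
writeLabelsTsv <- function(labels, path) {
  write.table(labels[, c("gene_id", "categories", "provenance")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelsTsv
#' @export
readLabelsTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE, colClasses = "character")
}
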