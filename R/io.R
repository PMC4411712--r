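## Writers for the raw-annotation dialects the readers consume. Fixture
## generators call these so every reader can be tested on files produced
## entirely in code.

#' Write Pfam feature assignments as an hmmscan domtblout file
#'
#' Emits the 23-column whitespace-aligned HMMER3 `--domtblout` dialect: one
#' row per (gene, Pfam family), the family as target with a versioned
#' accession, the gene as query, and the given full-sequence E-value.
#'
#' @param pfamSets named list: gene id -> character vector of `PF#####` ids.
#' @param path output path.
#' @param evalue full-sequence E-value written for every hit.
#' @return `path`, invisibly.
#' @export
writeDomtbloutFixture <- function(pfamSets, path, evalue = 1e-10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
               "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
             con)
  for (g in names(pfamSets)) {
    for (pf in pfamSets[[g]]) {
      writeLines(sprintf(
        "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f synthetic domain",
        tolower(pf), paste0(pf, ".1"), 120L, g, "-", 300L, evalue, 150.0, 0.1,
        1L, 1L, evalue, evalue, 148.0, 0.1, 1L, 120L, 10L, 130L, 8L, 132L,
        0.95), con)
    }
  }
  invisible(path)
}

#' Write a 12-column tabular BLAST file
#'
#' @param df data.frame with the standard `-outfmt 6` columns (a `rank`
#'   column, if present, is dropped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlastTabTsv <- function(df, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a subject-to-GO mapping TSV
#'
#' @param goMap named list (subject id -> GO ids) or a two-column data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGoMapTsv <- function(goMap, path) {
  if (!is.data.frame(goMap)) {
    goMap <- data.frame(
      subject_id = rep(names(goMap), lengths(goMap)),
      go_id = unlist(goMap, use.names = FALSE), stringsAsFactors = FALSE)
  }
  write.table(goMap, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a protein metadata TSV
#'
#' Tab-separated with header; list-like fields (`keywords`,
#' `go_descriptions`, `pfam_descriptions`) are `;`-joined, flags are 0/1.
#'
#' @param meta metadata data.frame (see [labelByRules()]).
#' @param path file path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
writeMetadataTsv <- function(meta, path) {
  out <- meta
  out$ec_flag <- as.integer(out$ec_flag)
  out$tmhmm_flag <- as.integer(out$tmhmm_flag)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetadataTsv
#' @export
readMetadataTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE,
                   colClasses = c(ec_flag = "integer", tmhmm_flag = "integer"))
  for (col in c("name", "description", "keywords", "go_descriptions",
                "pfam_descriptions"))
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  df$ec_flag <- df$ec_flag == 1L
  df$tmhmm_flag <- df$tmhmm_flag == 1L
  df
}

#' Emit the full raw-annotation fixture file set for a gene set
#'
#' Splits each gene's features by namespace (Pfam `PF...` versus GO
#' `GO:...`), writes the Pfam part as a domtblout file and the GO part as a
#' BLAST table plus GO map: each gene gets one synthetic BLAST subject
#' (`SUB_<gene>`) carrying exactly the gene's GO features, so the GO-transfer
#' rule (one kept hit, every term in 100% of hits) reconstructs them.
#'
#' @param geneset an [AnnotatedGeneSet-class].
#' @param dir output directory (created if needed).
#' @return Named list of the written paths (`domtblout`, `blast`, `go_map`).
#' @export
writeAnnotationFixtures <- function(geneset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- featureSets(geneset)
  pfam <- lapply(sets, function(f) f[startsWith(f, "PF")])
  go <- lapply(sets, function(f) f[startsWith(f, "GO:")])
  paths <- list(domtblout = file.path(dir, "hits.domtblout"),
                blast = file.path(dir, "go_blast.tsv"),
                go_map = file.path(dir, "go_map.tsv"))
  writeDomtbloutFixture(pfam[lengths(pfam) > 0L], paths$domtblout)
  withGo <- names(go)[lengths(go) > 0L]
  blast <- do.call(rbind, lapply(withGo, function(g)
    .blastRow(g, paste0("SUB_", g), 95, 1e-50)))
  if (is.null(blast)) blast <- .emptyBlast()
  writeBlastTabTsv(blast, paths$blast)
  goMap <- setNames(go[withGo], paste0("SUB_", withGo))
  writeGoMapTsv(goMap, paths$go_map)
  paths
}
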