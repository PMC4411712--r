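## Deterministic synthetic-data generators. Every downstream stage can be
## exercised from these with no external downloads: gene sets with planted
## category signatures, metadata/BLAST tables tuned to the labeling rules,
## and expression matrices with planted strictly-maternal genes.

#' Specification for a synthetic annotated gene set
#'
#' Describes a four-category training set with planted category-specific
#' signature features plus category-agnostic noise features. A signature
#' feature of category c appears in c's genes with probability
#' `signature_presence_prob` and leaks into the genes of the other three
#' categories with probability `leak_prob`; noise features appear in any gene
#' with probability `noise_presence_prob`.
#'
#' @param n_genes_per_category genes per category (>= 1).
#' @param n_signature_features_per_category signature features per category
#'   (>= 1, <= 999).
#' @param n_noise_features number of noise features (>= 1).
#' @param signature_presence_prob in `[0, 1]`, must exceed `leak_prob`.
#' @param leak_prob in `[0, 1]`.
#' @param noise_presence_prob in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A list of class `"SignatureSpec"`.
#' @seealso [simulateGeneSet()]
#' @export
signatureSpec <- function(n_genes_per_category = 100L,
                          n_signature_features_per_category = 10L,
                          n_noise_features = 60L,
                          signature_presence_prob = 0.9,
                          leak_prob = 0.05,
                          noise_presence_prob = 0.3,
                          seed = 1L) {
  spec <- list(n_genes_per_category = as.integer(n_genes_per_category),
               n_signature_features_per_category =
                 as.integer(n_signature_features_per_category),
               n_noise_features = as.integer(n_noise_features),
               signature_presence_prob = signature_presence_prob,
               leak_prob = leak_prob,
               noise_presence_prob = noise_presence_prob,
               seed = as.integer(seed))
  .validateSignatureSpec(spec)
  structure(spec, class = "SignatureSpec")
}

.validateSignatureSpec <- function(spec) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid SignatureSpec: field '", field, "' ", why)
  chk(spec$n_genes_per_category >= 1L, "n_genes_per_category", "must be >= 1")
  chk(spec$n_signature_features_per_category >= 1L &&
        spec$n_signature_features_per_category <= 999L,
      "n_signature_features_per_category", "must be in [1, 999]")
  chk(spec$n_noise_features >= 1L, "n_noise_features", "must be >= 1")
  for (f in c("signature_presence_prob", "leak_prob", "noise_presence_prob"))
    chk(spec[[f]] >= 0 && spec[[f]] <= 1, f, "must be a probability in [0, 1]")
  chk(spec$signature_presence_prob > spec$leak_prob,
      "signature_presence_prob", "must exceed leak_prob")
  chk(is.finite(spec$seed), "seed", "must be a finite integer")
  invisible(spec)
}

#' Synthetic feature identifiers
#'
#' Signature features live in a Pfam-like namespace (`PF9<c><sss>`, category
#' c in 1..4) and noise features in a GO-like namespace (`GO:80000<tt>`), so
#' Pfam-versus-GO provenance stays testable downstream.
#'
#' @param spec a `"SignatureSpec"`.
#' @return List with `signature` (per-category list of feature ids, in
#'   TFS/MEM/ENZ/OTS order) and `noise` (character vector).
#' @export
signatureFeatureIds <- function(spec) {
  nSig <- spec$n_signature_features_per_category
  sig <- lapply(seq_len(4L), function(c)
    sprintf("PF9%d%03d", c, seq_len(nSig)))
  names(sig) <- SIS_CATEGORIES
  list(signature = sig,
       noise = sprintf("GO:%07d", 8000000L + seq_len(spec$n_noise_features)))
}

#' Generate a synthetic annotated gene set with planted signatures
#'
#' Sampling procedure (replayable): categories are processed in the order
#' TFS, MEM, ENZ, OTS (index c = 1..4). For category c the RNG is seeded with
#' `seed + c`; then for each gene g = 1..n in turn the following uniform
#' draws are consumed: `n_sig` for the category's own signature features
#' (present where u < signature_presence_prob), `3 * n_sig` for the other
#' categories' signature features in ascending category order (present where
#' u < leak_prob), and `n_noise` for the noise features (present where
#' u < noise_presence_prob). A gene that ends up featureless receives its
#' category's first signature feature.
#'
#' @param spec a `"SignatureSpec"` from [signatureSpec()].
#' @return List with `geneset` ([AnnotatedGeneSet-class]), `labels` (named
#'   list, gene id -> planted category), and `signatureFeatures` (per-category
#'   list of planted signature feature ids).
#' @examples
#' sim <- simulateGeneSet(signatureSpec(n_genes_per_category = 10, seed = 42))
#' sim$geneset
#' @export
simulateGeneSet <- function(spec) {
  .validateSignatureSpec(spec)
  ids <- signatureFeatureIds(spec)
  nSig <- spec$n_signature_features_per_category
  sets <- list()
  labels <- list()
  for (c in seq_len(4L)) {
    cat <- SIS_CATEGORIES[c]
    set.seed(spec$seed + c)
    others <- setdiff(seq_len(4L), c)
    for (g in seq_len(spec$n_genes_per_category)) {
      gid <- sprintf("%s_g%03d", cat, g)
      own <- ids$signature[[c]][runif(nSig) < spec$signature_presence_prob]
      uLeak <- runif(3L * nSig)
      leaked <- character()
      for (oi in seq_along(others)) {
        u <- uLeak[((oi - 1L) * nSig + 1L):(oi * nSig)]
        leaked <- c(leaked, ids$signature[[others[oi]]][u < spec$leak_prob])
      }
      noise <- ids$noise[runif(spec$n_noise_features) < spec$noise_presence_prob]
      feats <- c(own, leaked, noise)
      if (length(feats) == 0L) feats <- ids$signature[[c]][1L]
      sets[[gid]] <- feats
      labels[[gid]] <- cat
    }
  }
  list(geneset = AnnotatedGeneSet(sets), labels = labels,
       signatureFeatures = ids$signature)
}

#' Generate metadata and homology-BLAST fixtures matched to the labeling rules
#'
#' Produces a protein metadata table and a 12-column BLAST table constructed
#' so that the rule-based labeler plus homology propagation recover the
#' planted categories exactly. A seeded fraction of genes is left with
#' uninformative descriptions and instead given qualifying BLAST hits to
#' rule-labeled genes of the same category (the first two genes of each
#' category are always rule-labeled so propagation has anchors); a seeded
#' fraction of the rule-labeled OTS genes receives a description that
#' triggers the transcription-factor keyword *and* a cofactor keyword,
#' exercising the cofactor veto.
#'
#' @param geneset an [AnnotatedGeneSet-class] (may be empty).
#' @param labels named list, gene id -> single planted category.
#' @param seed integer RNG seed.
#' @param homolog_fraction fraction of genes labeled only via homology.
#' @param cofactor_fraction fraction of rule-labeled OTS genes given
#'   cofactor-veto descriptions.
#' @return List with `metadata` (data.frame: gene_id, name, description,
#'   keywords, go_descriptions, pfam_descriptions, ec_flag, tmhmm_flag) and
#'   `blast` (12-column data.frame for [propagateByHomology()]).
#' @export
simulateMetadata <- function(geneset, labels, seed = 1L,
                             homolog_fraction = 0.2,
                             cofactor_fraction = 0.25) {
  ids <- geneIds(geneset)
  if (length(ids) == 0L)
    return(list(metadata = .emptyMetadata(), blast = .emptyBlast()))
  if (!all(ids %in% names(labels)))
    stop("labels must cover every gene in the gene set")
  set.seed(seed)
  cat <- vapply(labels[ids], `[[`, "", 1L)
  homology <- runif(length(ids)) < homolog_fraction
  ## anchors: first two genes of each category always carry rule metadata
  for (j in SIS_CATEGORIES) {
    anchor <- which(cat == j)
    homology[utils::head(anchor, 2L)] <- FALSE
  }
  cofactor <- runif(length(ids)) < cofactor_fraction
  meta <- data.frame(gene_id = ids, name = ids,
                     description = "", keywords = "", go_descriptions = "",
                     pfam_descriptions = "", ec_flag = FALSE,
                     tmhmm_flag = FALSE, stringsAsFactors = FALSE)
  blastRows <- list()
  for (i in seq_along(ids)) {
    gid <- ids[i]
    if (homology[i]) {
      meta$description[i] <- "uncharacterized protein"
      anchors <- setdiff(ids[cat == cat[i] & !homology], gid)
      if (cat[i] %in% c("TFS", "MEM", "ENZ")) {
        subj <- utils::head(anchors, 3L)
        ev <- c(1e-50, 1e-45, 1e-40)[seq_along(subj)]
        pid <- c(90, 85, 80)[seq_along(subj)]
        blastRows[[length(blastRows) + 1L]] <-
          .blastRow(gid, subj, pid, ev)
        ## decoy below the identity cutoff, must not count
        decoyPool <- setdiff(ids[cat != cat[i] & !homology], gid)
        if (length(decoyPool))
          blastRows[[length(blastRows) + 1L]] <-
            .blastRow(gid, decoyPool[1L], 20, 1e-30)
      } else {
        ## a single hit: below the minimum-hit count, so OTS by residue rule
        if (length(anchors))
          blastRows[[length(blastRows) + 1L]] <-
            .blastRow(gid, anchors[1L], 90, 1e-50)
      }
    } else if (cat[i] == "TFS") {
      meta$description[i] <- "homeobox transcription factor"
    } else if (cat[i] == "MEM") {
      meta$description[i] <- "predicted protein"
      meta$go_descriptions[i] <- "integral to membrane"
    } else if (cat[i] == "ENZ") {
      meta$description[i] <- "alcohol dehydrogenase"
      meta$ec_flag[i] <- TRUE
    } else if (cofactor[i]) {
      ## fires the TF keyword and the cofactor veto at once
      meta$description[i] <- "transcription factor cofactor subunit"
    } else {
      meta$description[i] <- "hypothetical protein"
    }
  }
  blast <- if (length(blastRows)) do.call(rbind, blastRows) else .emptyBlast()
  list(metadata = meta, blast = blast)
}

.blastRow <- function(q, subjects, pident, evalue) {
  n <- length(subjects)
  data.frame(qseqid = q, sseqid = subjects, pident = pident,
             length = 200L, mismatch = 10L, gapopen = 0L,
             qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
             evalue = evalue, bitscore = 300, stringsAsFactors = FALSE)
}

.emptyMetadata <- function() {
  data.frame(gene_id = character(), name = character(),
             description = character(), keywords = character(),
             go_descriptions = character(), pfam_descriptions = character(),
             ec_flag = logical(), tmhmm_flag = logical(),
             stringsAsFactors = FALSE)
}

.emptyBlast <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Specification for a synthetic expression matrix with planted maternal genes
#'
#' @param n_genes number of genes (>= 1).
#' @param n_probes_per_gene probes per gene (>= 1; for planted genes only the
#'   first probe is maternal, exercising the any-probe collapse rule).
#' @param egg_samples number of egg/MII-oocyte replicates (>= 1).
#' @param somatic_sample_classes class names, one late-stage somatic sample
#'   each (>= 1).
#' @param excluded_sample_classes class names for samples excluded from the
#'   comparison (early embryos, gonads, ES cells); one sample each.
#' @param planted_mf_fraction fraction of genes planted as strictly maternal,
#'   in (0, 1).
#' @param mf_fold linear-scale egg-over-somatic fold for planted genes
#'   (>= 4 by default).
#' @param noise_sd standard deviation of log2-scale noise.
#' @param seed integer RNG seed.
#' @return List of class `"ExpressionSpec"`.
#' @export
expressionSpec <- function(n_genes = 500L, n_probes_per_gene = 2L,
                           egg_samples = 3L,
                           somatic_sample_classes = c("liver", "brain", "heart",
                                                      "kidney", "muscle", "lung"),
                           excluded_sample_classes = c("8cell", "morula",
                                                       "blastocyst", "testis",
                                                       "ovary", "ES_cell"),
                           planted_mf_fraction = 0.1, mf_fold = 4,
                           noise_sd = 0.25, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_probes_per_gene = as.integer(n_probes_per_gene),
               egg_samples = as.integer(egg_samples),
               somatic_sample_classes = as.character(somatic_sample_classes),
               excluded_sample_classes = as.character(excluded_sample_classes),
               planted_mf_fraction = planted_mf_fraction,
               mf_fold = mf_fold, noise_sd = noise_sd, seed = as.integer(seed))
  .validateExpressionSpec(spec)
  structure(spec, class = "ExpressionSpec")
}

.validateExpressionSpec <- function(spec) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid ExpressionSpec: field '", field, "' ", why)
  chk(spec$n_genes >= 1L, "n_genes", "must be >= 1")
  chk(spec$n_probes_per_gene >= 1L, "n_probes_per_gene", "must be >= 1")
  chk(spec$egg_samples >= 1L, "egg_samples", "must be >= 1")
  chk(length(spec$somatic_sample_classes) >= 1L, "somatic_sample_classes",
      "must name at least one somatic class")
  chk(spec$planted_mf_fraction > 0 && spec$planted_mf_fraction < 1,
      "planted_mf_fraction", "must lie in (0, 1)")
  chk(spec$mf_fold > 1, "mf_fold", "must exceed 1")
  chk(spec$noise_sd >= 0, "noise_sd", "must be >= 0")
  invisible(spec)
}

#' Generate a synthetic expression matrix with planted maternal factors
#'
#' Values are drawn on log2 scale and exponentiated (microarray practice;
#' the caller's fold rule is linear-scale). Planted genes satisfy the fold
#' rule in every somatic comparison by a construction margin: every egg
#' replicate is at least `mf_fold` times the maximum somatic value of the
#' maternal probe. The first planted gene sits exactly on the boundary
#' (egg = `mf_fold` x max somatic, no margin, identical egg replicates).
#' Non-planted genes have their first somatic sample equal to the egg level,
#' so the rule fails there by construction. Samples of excluded classes get
#' half the egg level on planted genes: they would break the fold rule were
#' they not excluded from the comparison.
#'
#' @param spec an `"ExpressionSpec"` from [expressionSpec()].
#' @return List with `se` (a
#'   [SummarizedExperiment::SummarizedExperiment-class]; assay `"exprs"`,
#'   `rowData()$gene_id`, `colData()$sample_class`), `planted` (character
#'   vector of planted gene ids) and `groups` (a [SampleGroups-class] with
#'   egg class `"egg"`).
#' @examples
#' sim <- simulateExpression(expressionSpec(n_genes = 20, seed = 3))
#' length(sim$planted)
#' @export
simulateExpression <- function(spec) {
  .validateExpressionSpec(spec)
  set.seed(spec$seed)
  genes <- sprintf("gene%04d", seq_len(spec$n_genes))
  nPlanted <- round(spec$n_genes * spec$planted_mf_fraction)
  planted <- sort(sample(genes, nPlanted))
  samples <- c(sprintf("egg_%d", seq_len(spec$egg_samples)),
               spec$somatic_sample_classes, spec$excluded_sample_classes)
  classes <- c(rep("egg", spec$egg_samples), spec$somatic_sample_classes,
               spec$excluded_sample_classes)
  eggCols <- seq_len(spec$egg_samples)
  somCols <- spec$egg_samples + seq_along(spec$somatic_sample_classes)
  excCols <- spec$egg_samples + length(spec$somatic_sample_classes) +
    seq_along(spec$excluded_sample_classes)
  nProbes <- spec$n_genes * spec$n_probes_per_gene
  vals <- matrix(NA_real_, nrow = nProbes, ncol = length(samples))
  probeIds <- character(nProbes)
  probeGenes <- character(nProbes)
  boundaryGene <- planted[1L]
  row <- 0L
  for (g in seq_along(genes)) {
    gid <- genes[g]
    isPlanted <- gid %in% planted
    for (p in seq_len(spec$n_probes_per_gene)) {
      row <- row + 1L
      probeIds[row] <- sprintf("%s_p%d", gid, p)
      probeGenes[row] <- gid
      mu <- runif(1, 4, 10)
      if (isPlanted && p == 1L) {
        som <- 2^(mu + rnorm(length(somCols), 0, spec$noise_sd))
        maxSom <- max(som)
        if (gid == boundaryGene) {
          egg <- rep(spec$mf_fold * maxSom, spec$egg_samples)
        } else {
          margin <- runif(1, 0.25, 1)
          egg <- spec$mf_fold * maxSom *
            2^(margin + abs(rnorm(spec$egg_samples, 0, spec$noise_sd)))
        }
        vals[row, somCols] <- som
        vals[row, eggCols] <- egg
        vals[row, excCols] <- egg[1L] / 2
      } else {
        base <- 2^(mu + rnorm(length(samples), 0, spec$noise_sd))
        vals[row, ] <- base
        ## force a violation: first somatic sample tracks the egg statistic
        vals[row, somCols[1L]] <- mean(vals[row, eggCols])
      }
    }
  }
  dimnames(vals) <- list(probeIds, samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals),
    rowData = S4Vectors::DataFrame(gene_id = probeGenes, row.names = probeIds),
    colData = S4Vectors::DataFrame(sample_class = classes, row.names = samples))
  groups <- SampleGroups(eggClasses = "egg",
                         excludedClasses = spec$excluded_sample_classes)
  list(se = se, planted = planted, groups = groups)
}

#' Simulate protein sequences for a set of gene ids
#'
#' Plain random amino-acid strings (no realistic domain content) for
#' exercising FASTA round-trips and the sequence pre-filters.
#'
#' @param ids character gene ids.
#' @param seed integer RNG seed.
#' @param minLen,maxLen sequence length range.
#' @return A [Biostrings::AAStringSet].
#' @export
simulateProteinSequences <- function(ids, seed = 1L, minLen = 80L, maxLen = 400L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  seqs <- vapply(ids, function(id) {
    len <- sample(minLen:maxLen, 1L)
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, "")
  Biostrings::AAStringSet(setNames(seqs, ids))
}
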