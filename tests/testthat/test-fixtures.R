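test_that("gene-set simulation is deterministic and validates its spec", {
  spec <- signatureSpec(n_genes_per_category = 20, seed = 11)
  a <- simulateGeneSet(spec)
  b <- simulateGeneSet(spec)
  expect_identical(featureSets(a$geneset), featureSets(b$geneset))
  expect_identical(a$labels, b$labels)
  expect_true(all(lengths(featureSets(a$geneset)) >= 1))
  expect_error(signatureSpec(signature_presence_prob = 0.1, leak_prob = 0.5),
               "signature_presence_prob")
  expect_error(signatureSpec(n_genes_per_category = 0),
               "n_genes_per_category")
})

test_that("with zero leak, signature features stay inside their own category", {
  sim <- simulateGeneSet(signatureSpec(n_genes_per_category = 30,
                                       leak_prob = 0, seed = 5))
  truth <- unlist(sim$labels)
  for (j in names(sim$signatureFeatures)) {
    carriers <- names(Filter(function(f)
      any(f %in% sim$signatureFeatures[[j]]), featureSets(sim$geneset)))
    expect_true(all(truth[carriers] == j))
  }
})

test_that("sampling replays exactly from the documented RNG stream layout", {
  spec <- signatureSpec(n_genes_per_category = 100,
                        n_signature_features_per_category = 10,
                        n_noise_features = 60,
                        signature_presence_prob = 0.9, leak_prob = 0.05,
                        seed = 7)
  sim <- simulateGeneSet(spec)
  ids <- signatureFeatureIds(spec)
  ## independent re-simulation of the documented draw order
  expected <- list()
  for (c in 1:4) {
    set.seed(spec$seed + c)
    others <- setdiff(1:4, c)
    for (g in seq_len(spec$n_genes_per_category)) {
      gid <- sprintf("%s_g%03d", CATS[c], g)
      feats <- ids$signature[[c]][runif(10) < 0.9]
      u <- runif(30)
      for (oi in seq_along(others)) {
        feats <- c(feats,
                   ids$signature[[others[oi]]][u[(oi - 1) * 10 + 1:10] < 0.05])
      }
      feats <- c(feats, ids$noise[runif(60) < spec$noise_presence_prob])
      if (!length(feats)) feats <- ids$signature[[c]][1]
      expected[[gid]] <- sort(unique(feats), method = "radix")
    }
  }
  expect_identical(featureSets(sim$geneset), expected[names(featureSets(sim$geneset))])
  ## per-category count of each planted signature feature agrees
  truth <- unlist(sim$labels)
  for (j in CATS) {
    inJ <- featureSets(sim$geneset)[truth == j]
    for (f in ids$signature[[j]]) {
      expect_identical(sum(vapply(inJ, function(x) f %in% x, logical(1))),
                       sum(vapply(expected[names(inJ)],
                                  function(x) f %in% x, logical(1))))
    }
  }
})

test_that("metadata fixtures encode the labeling rules and empty sets work", {
  sim <- simulateGeneSet(signatureSpec(n_genes_per_category = 15, seed = 3))
  md <- simulateMetadata(sim$geneset, sim$labels, seed = 3)
  truth <- unlist(sim$labels)
  tfs <- md$metadata[truth[md$metadata$gene_id] == "TFS" &
                       md$metadata$description != "uncharacterized protein", ]
  expect_true(all(grepl("transcription factor", tfs$description)))
  mem <- md$metadata[truth[md$metadata$gene_id] == "MEM" &
                       md$metadata$description != "uncharacterized protein", ]
  expect_true(all(grepl("integral to membrane", mem$go_descriptions)))
  empty <- simulateMetadata(AnnotatedGeneSet(list(), character()),
                            list(), seed = 1)
  expect_identical(nrow(empty$metadata), 0L)
  expect_identical(nrow(empty$blast), 0L)
})

test_that("expression simulation plants the documented maternal structure", {
  spec <- expressionSpec(n_genes = 500, planted_mf_fraction = 0.1, seed = 3)
  sim <- simulateExpression(spec)
  expect_length(sim$planted, 50L)
  expect_identical(simulateExpression(spec)$planted, sim$planted)
  m <- SummarizedExperiment::assay(sim$se, "exprs")
  cls <- SummarizedExperiment::colData(sim$se)$sample_class
  somCols <- !(cls %in% c("egg", spec$excluded_sample_classes))
  eggCols <- cls == "egg"
  genes <- SummarizedExperiment::rowData(sim$se)$gene_id
  ## planted genes: the maternal probe beats fold x every somatic sample
  for (g in head(sim$planted, 10)) {
    p1 <- which(genes == g)[1]
    expect_true(mean(m[p1, eggCols]) >= spec$mf_fold * max(m[p1, somCols]))
  }
  ## non-planted genes fail on the first somatic sample by construction
  nonPlanted <- setdiff(unique(genes), sim$planted)
  for (g in head(nonPlanted, 10)) {
    rows <- which(genes == g)
    ok <- vapply(rows, function(p)
      mean(m[p, eggCols]) >= spec$mf_fold * max(m[p, somCols]), logical(1))
    expect_false(any(ok))
  }
  expect_error(expressionSpec(planted_mf_fraction = 0), "planted_mf_fraction")
})

test_that("noiseless expression places the first planted gene exactly on the fold boundary", {
  spec <- expressionSpec(n_genes = 40, noise_sd = 0, seed = 9)
  sim <- simulateExpression(spec)
  m <- SummarizedExperiment::assay(sim$se, "exprs")
  cls <- SummarizedExperiment::colData(sim$se)$sample_class
  genes <- SummarizedExperiment::rowData(sim$se)$gene_id
  somCols <- !(cls %in% c("egg", spec$excluded_sample_classes))
  p1 <- which(genes == sim$planted[1])[1]
  expect_identical(mean(m[p1, cls == "egg"]),
                   spec$mf_fold * max(m[p1, somCols]))
})

test_that("generated annotation files round-trip through the readers", {
  sim <- simulateGeneSet(signatureSpec(n_genes_per_category = 10, seed = 21))
  dir <- withr::local_tempdir()
  paths <- writeAnnotationFixtures(sim$geneset, dir)
  pfam <- assignPfamFeatures(readDomtblout(paths$domtblout))
  go <- assignGoFeatures(readBlastTab(paths$blast), readGoMap(paths$go_map))
  rebuilt <- buildFeatureTable(pfam, go, minGeneCount = 1)
  expect_identical(featureSets(rebuilt),
                   featureSets(sim$geneset)[geneIds(rebuilt)])
  expect_setequal(geneIds(rebuilt), geneIds(sim$geneset))
  expect_identical(featureSpace(rebuilt), featureSpace(sim$geneset))
})
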