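test_that("binary encoding follows the sorted feature space", {
  gs <- AnnotatedGeneSet(list(g1 = c("PF00046", "GO:0003700"),
                              g2 = c("GO:0003700", "PF00046", "PF00104")),
                         featureSpace = c("GO:0003700", "PF00046", "PF00104"))
  m <- encodeGenes(gs)
  expect_identical(m["g1", ], c("GO:0003700" = 1L, PF00046 = 1L, PF00104 = 0L))
  expect_identical(m["g2", ], c("GO:0003700" = 1L, PF00046 = 1L, PF00104 = 1L))
  ## column sums recount the raw feature table
  sim <- simulateGeneSet(signatureSpec(n_genes_per_category = 10, seed = 4))
  enc <- encodeGenes(sim$geneset)
  counts <- table(unlist(featureSets(sim$geneset)))
  expect_identical(colSums(enc)[names(counts)],
                   setNames(as.numeric(counts), names(counts)))
})

test_that("weight estimation reproduces the closed-form hand example", {
  ## feature F in 2 of 4 TFS genes and nowhere else: C = 2, N = 4, C_i = 2,
  ## so P = 2^2/(4*2) = 0.5, IC = 1, w = 1
  mat <- matrix(0L, 16, 2, dimnames = list(sprintf("g%02d", 1:16), c("F", "G")))
  mat[1:2, "F"] <- 1L
  mat[, "G"] <- 1L                       # keeps every gene featured
  labels <- setNames(as.list(rep(CATS, each = 4)), rownames(mat))
  wt <- estimateWeights(mat, labels)
  expect_identical(featureWeights(wt, "P")["F", "TFS"], 0.5)
  expect_identical(featureWeights(wt, "IC")["F", "TFS"], 1)
  expect_identical(featureWeights(wt)["F", "TFS"], 1)
  expect_identical(featureWeights(wt)["F", "MEM"], 0)   # C = 0 -> w = 0
  ## exclusive and universal feature: P = 1, IC = 0, w capped
  mat2 <- cbind(mat, H = 0L)
  mat2[9:12, "H"] <- 1L                  # exactly the ENZ genes
  wt2 <- estimateWeights(mat2, labels, wMax = 1e6)
  expect_identical(featureWeights(wt2, "P")["H", "ENZ"], 1)
  expect_identical(featureWeights(wt2)["H", "ENZ"], 1e6)
  expect_error(estimateWeights(mat, labels[1:6]), "missing")
})

test_that("multi-label genes count in every category they belong to", {
  mat <- matrix(1L, 4, 1, dimnames = list(sprintf("g%d", 1:4), "F"))
  labels <- list(g1 = c("TFS", "MEM"), g2 = "MEM", g3 = "ENZ", g4 = "OTS")
  wt <- estimateWeights(mat, labels)
  cc <- featureWeights(wt, "C")
  expect_identical(cc["F", ], c(TFS = 1, MEM = 2, ENZ = 1, OTS = 1))
  expect_identical(sum(cc["F", ]), 5)    # C_i under multi-label counting
  expect_identical(wt@nSamples, c(TFS = 1, MEM = 2, ENZ = 1, OTS = 1))
})

test_that("weight estimation matches the brute-force oracle on random instances", {
  for (s in 1:25) {
    inst <- randomInstance(nGenes = 20, nFeat = 8, seed = s)
    wt <- estimateWeights(inst$mat, inst$labels)
    ref <- oracleWeights(inst$mat, inst$labels)
    expect_equal(featureWeights(wt, "C"), ref$C, tolerance = 0)
    expect_equal(featureWeights(wt, "P"), ref$P, tolerance = 1e-12)
    expect_equal(featureWeights(wt), ref$W, tolerance = 1e-12)
  }
})

test_that("MWD ranking computes the difference, prunes, and breaks ties by id", {
  w <- rbind(A = c(1.0, 0.1, 0.1, 0.1),    # MWD 0.9, kept
             B = c(0.4, 0.2, 0.2, 0.2),    # 0.4 < 0.6 -> pruned
             C = c(0.2, 0.2, 0.2, 0.2),    # symmetric -> pruned
             D = c(0.9, 0.0, 0.0, 0.0))
  colnames(w) <- CATS
  cnt <- (w > 0) * 1; dimnames(cnt) <- dimnames(w)
  wt <- new("WeightTable", counts = cnt,
            nSamples = setNames(rep(2, 4), CATS), prob = w * 0.5,
            infoContent = ifelse(w > 0, 1 / pmax(w, 1e-9), Inf), weights = w,
            wMax = 1e6)
  r <- rankFeaturesMWD(wt)
  expect_identical(r@pruned, c("B", "C"))
  ## A and D tie at MWD 0.9; the tie breaks by feature id ascending
  expect_identical(rankedFeatures(r), c("A", "D"))
  expect_identical(r@ranking$mwd, c(0.9, 0.9))
  ## tied MWD -> feature id ascending
  w2 <- rbind(Z = c(1, 0, 0, 0), A = c(1, 0, 0, 0)); colnames(w2) <- CATS
  cnt2 <- (w2 > 0) * 1; dimnames(cnt2) <- dimnames(w2)
  wt2 <- new("WeightTable", counts = cnt2,
             nSamples = setNames(rep(2, 4), CATS), prob = w2 * 0.5,
             infoContent = ifelse(w2 > 0, 1, Inf), weights = w2, wMax = 1e6)
  expect_identical(rankedFeatures(rankFeaturesMWD(wt2)), c("A", "Z"))
})

test_that("cosine similarity and the weighted score follow the closed forms", {
  expect_identical(cosineSimilarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_identical(cosineSimilarity(c(1, 1, 0), c(0, 0, 1)), 0)
  expect_identical(cosineSimilarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosineSimilarity(c(0, 0, 0), c(1, 0, 1)), "zero vector")
  w <- matrix(0, 3, 4, dimnames = list(c("f1", "f2", "f3"), CATS))
  w["f1", "TFS"] <- 0.8
  expect_identical(sisScore(c(1, 1, 0), c(1, 0, 1), w, "TFS"), 0.5 * 0.8)
  expect_identical(sisScore(c(1, 0, 0), c(0, 1, 1), w, "TFS"), 0)
  expect_identical(sisScore(c(1, 0, 0), c(1, 0, 0), w, "TFS"), 0.8)
})

test_that("similarity and score obey their invariants on random vectors", {
  set.seed(99)
  w <- matrix(runif(40), 10, 4, dimnames = list(sprintf("f%02d", 1:10), CATS))
  for (i in 1:200) {
    a <- rbinom(10, 1, 0.5); b <- rbinom(10, 1, 0.5)
    if (sum(a) == 0 || sum(b) == 0) next
    s <- cosineSimilarity(a, b)
    expect_identical(s, cosineSimilarity(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_identical(s == 1, identical(which(a == 1), which(b == 1)))
    for (j in CATS) {
      sc <- sisScore(a, b, w, j)
      expect_gte(sc, 0)
      expect_lte(sc, sum(w[a == 1 & b == 1, j]) + 1e-15)
      expect_equal(sc, oracleScore(a, b, w, j), tolerance = 1e-12)
    }
  }
})

test_that("nearest-neighbour classification applies the documented tie-breaks", {
  mat <- rbind(t1 = c(1L, 1L, 0L), m1 = c(1L, 1L, 0L), o1 = c(0L, 0L, 1L))
  colnames(mat) <- c("f1", "f2", "f3")
  labels <- list(t1 = "TFS", m1 = "MEM", o1 = "OTS")
  w <- matrix(0.5, 3, 4, dimnames = list(colnames(mat), CATS))
  wt <- new("WeightTable", counts = (w > 0) * 1 + 0,
            nSamples = setNames(rep(1, 4), CATS), prob = w,
            infoContent = w * 0 + 2, weights = w, wMax = 1e6)
  rk <- rankFeaturesMWD(wt)  # all equal weights -> everything pruned
  expect_identical(length(rk), 0L)
  model <- new("SisModel", featureSpace = colnames(mat),
               selectedFeatures = colnames(mat),
               weightTable = wt,
               trainingMatrix = mat, trainingLabels = labels,
               ranking = new("MWDRanking",
                             ranking = data.frame(feature_id = colnames(mat),
                                                  mwd = c(3, 2, 1),
                                                  w1 = 1, w2 = 0, w3 = 0, w4 = 0,
                                                  top_category = "TFS",
                                                  stringsAsFactors = FALSE),
                             pruned = character()),
               curve = data.frame(), bestK = 3L)
  ## equal scores against a TFS and a MEM neighbour: TFS wins the tie
  r <- classifyNNA(c(1, 1, 0), model)
  expect_identical(r$category, "TFS")
  expect_identical(r$neighbor, "t1")
  ## no shared feature with anyone -> unclassifiable
  r2 <- classifyNNA(c(0, 0, 0), model)
  expect_true(r2$unclassifiable)
  r3 <- classifyNNA("f4", model)
  expect_true(r3$unclassifiable)
})

test_that("LOOCV matches the naive double-loop oracle exactly, tie-breaks included", {
  for (s in c(1, 2)) {
    sim <- simulateGeneSet(signatureSpec(
      n_genes_per_category = 25, n_signature_features_per_category = 5,
      n_noise_features = 20, signature_presence_prob = 0.8, leak_prob = 0.15,
      seed = s))
    mat <- encodeGenes(sim$geneset)
    labels <- normalizeLabels(sim$labels, rownames(mat))
    wt <- estimateWeights(mat, labels)
    rk <- rankFeaturesMWD(wt)
    grid <- unique(c(1L, 2L, 5L, length(rk)))
    cv <- sisLoocv(mat, labels, ranking = rk, kGrid = grid, weightTable = wt)
    ref <- oracleLoocv(mat, labels, rankedFeatures(rk), grid,
                       featureWeights(wt))
    for (col in c("TP", "FP", "TN", "FN"))
      expect_identical(as.integer(cv$curve[[col]]), as.integer(ref[[col]]))
    for (col in c("sensitivity", "specificity", "accuracy", "precision", "mcc"))
      expect_identical(cv$curve[[col]], ref[[col]])
    expect_identical(cv$bestK,
                     ref$k[order(-ref$accuracy, ref$k)][1])
    ## per-sample category decisions agree at the largest k
    model <- sisFit(mat, labels, kGrid = grid)
    sel <- selectedFeatures(model)
    for (m in sample(rownames(mat), 10)) {
      got <- classifyNNA(mat[m, sel], model, excludeId = m)
      want <- oracleNNA(mat[m, sel],
                        mat[, sel, drop = FALSE], labels,
                        featureWeights(wt)[sel, , drop = FALSE],
                        excludeId = m)
      expect_identical(got$unclassifiable, want$unclassifiable)
      if (!got$unclassifiable) {
        expect_identical(got$category, want$category)
        expect_identical(got$neighbor, want$neighbor)
        expect_identical(got$score, want$score)
      }
    }
  }
})

test_that("LOOCV edge cases: separable data scores perfectly; k = 0 kills sensitivity", {
  sim <- simulateGeneSet(signatureSpec(
    n_genes_per_category = 15, leak_prob = 0, signature_presence_prob = 1,
    noise_presence_prob = 0, seed = 6))
  mat <- encodeGenes(sim$geneset)
  cv <- sisLoocv(mat, sim$labels, kGrid = c(0L, 40L))
  expect_identical(cv$curve$sensitivity[cv$curve$k == 0], 0)
  expect_identical(cv$curve$accuracy[cv$curve$k == 40], 1)
  expect_identical(cv$bestK, 40L)
  expect_error(sisLoocv(mat, sim$labels, kGrid = integer(0)), "empty k grid")
})

test_that("raising the leak rate never improves expected LOOCV accuracy", {
  accAt <- function(leak) {
    accs <- vapply(1:3, function(s) {
      sim <- simulateGeneSet(signatureSpec(
        n_genes_per_category = 20, n_signature_features_per_category = 4,
        n_noise_features = 10, signature_presence_prob = 0.9,
        leak_prob = leak, seed = 100 + s))
      cv <- sisLoocv(encodeGenes(sim$geneset), sim$labels)
      max(cv$curve$accuracy)
    }, numeric(1))
    mean(accs)
  }
  acc <- vapply(c(0.02, 0.15, 0.4), accAt, numeric(1))
  expect_true(all(diff(acc) <= 0))
})

test_that("fit + predict flags training TFs on separable data; degenerate queries handled", {
  sim <- simulateGeneSet(signatureSpec(
    n_genes_per_category = 15, leak_prob = 0, signature_presence_prob = 1,
    noise_presence_prob = 0, seed = 10))
  model <- sisFit(sim$geneset, sim$labels)
  pred <- sisPredict(sim$geneset, model)
  truth <- unlist(sim$labels)[pred$gene_id]
  expect_identical(pred$tf_flag, unname(truth == "TFS"))
  ## the accuracy-driven sweep may freeze a k too small to cover the
  ## non-TF categories; with the full ranking all four are recovered
  full <- sisFit(sim$geneset, sim$labels, kGrid = 40L)
  predFull <- sisPredict(sim$geneset, full)
  expect_identical(predFull$category, unname(truth))
  ## empty query set -> empty output
  empty <- sisPredict(AnnotatedGeneSet(list(), character()), model)
  expect_identical(nrow(empty), 0L)
  ## query with only unselected features -> unclassifiable, not a TF
  alien <- AnnotatedGeneSet(list(q1 = "GO:9999999"))
  p <- sisPredict(alien, model)
  expect_true(is.na(p$category))
  expect_false(p$tf_flag)
})

test_that("models round-trip bit-identically through the flat-file format", {
  sim <- simulateGeneSet(signatureSpec(n_genes_per_category = 12, seed = 14))
  model <- sisFit(sim$geneset, sim$labels)
  dir <- withr::local_tempdir()
  writeSisModel(model, dir)
  back <- readSisModel(dir)
  expect_identical(featureWeights(back), featureWeights(model))
  expect_identical(back@trainingMatrix, model@trainingMatrix)
  expect_identical(back@trainingLabels, model@trainingLabels)
  expect_identical(back@bestK, model@bestK)
  expect_identical(selectedFeatures(back), selectedFeatures(model))
  pred1 <- sisPredict(sim$geneset, model)
  pred2 <- sisPredict(sim$geneset, back)
  expect_identical(pred1, pred2)
})
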