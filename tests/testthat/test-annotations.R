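test_that("sequence filter enforces inclusive length bounds and the alphabet", {
  aa <- function(n) paste(rep("A", n), collapse = "")
  seqs <- Biostrings::AAStringSet(c(short = aa(49), lo = aa(50), hi = aa(5000),
                                    long = aa(5001),
                                    star = paste0(aa(60), "*"),
                                    odd = paste0(aa(60), "J"),
                                    ext = paste0(aa(60), "XBZU")))
  res <- filterSequences(seqs)
  expect_setequal(names(res$retained), c("lo", "hi", "ext"))
  expect_identical(res$rejected$reason[res$rejected$id == "short"], "too short")
  expect_identical(res$rejected$reason[res$rejected$id == "long"], "too long")
  expect_identical(res$rejected$reason[res$rejected$id == "star"],
                   "irregular characters")
  expect_identical(res$rejected$reason[res$rejected$id == "odd"],
                   "irregular characters")
})

test_that("domtblout reader strips version suffixes, skips comments, flags bad rows", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "hits.domtblout")
  writeDomtbloutFixture(list(geneA = c("PF00046", "PF00104"),
                             geneB = "PF00046"), f, evalue = 1e-6)
  hits <- readDomtblout(f)
  expect_identical(nrow(hits), 3L)
  expect_setequal(hits$pfam_id, c("PF00046", "PF00104"))
  expect_true(all(hits$evalue == 1e-6))
  ## comments only -> empty
  writeLines(c("# full-width comment", "# another"), f)
  expect_identical(nrow(readDomtblout(f)), 0L)
  ## truncated row -> parse error naming the line
  writeLines("pf00046 PF00046.28 120 geneA - 300 1e-06", f)
  expect_error(readDomtblout(f), "line 1")
})

test_that("Pfam feature assignment applies an inclusive e-value cutoff with set semantics", {
  hits <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                     pfam_id = c("PF00001", "PF00001", "PF00002", "PF00003"),
                     evalue = c(1e-3, 1e-5, 2e-3, 1e-4),
                     stringsAsFactors = FALSE)
  f <- assignPfamFeatures(hits, evalueMax = 1e-3)
  expect_identical(f$g1, "PF00001")  # boundary kept, duplicate collapsed, 2e-3 dropped
  expect_identical(f$g2, "PF00003")
})

test_that("GO transfer keeps top hits after the e-value filter and applies the majority rule", {
  subjects <- sprintf("S%02d", 1:11)
  goMap <- setNames(vector("list", 11), subjects)
  for (s in subjects) goMap[[s]] <- character()
  for (s in subjects[1:5]) goMap[[s]] <- "GO:0000003"     # 5 of 10 kept
  for (s in subjects[1:4]) goMap[[s]] <- c(goMap[[s]], "GO:0000009")  # 4 of 10
  goMap[["S11"]] <- "GO:0000004"                          # only in rank 11
  blast <- data.frame(qseqid = "q1", sseqid = subjects, pident = 90,
                      length = 100L, mismatch = 0L, gapopen = 0L,
                      qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                      evalue = 10^-(40 - seq_along(subjects)), bitscore = 200,
                      stringsAsFactors = FALSE)
  res <- assignGoFeatures(blast, goMap)
  expect_identical(res$q1, "GO:0000003")   # exactly 50% passes, 40% does not,
                                           # rank-11 term truncated away
  ## no hit passes the e-value filter -> empty GO set
  weak <- transform(blast, evalue = 1e-5)
  expect_identical(assignGoFeatures(weak, goMap)$q1, character(0))
  expect_error(assignGoFeatures(blast, goMap, minFrac = 0), "minFrac")
})

test_that("feature table filters features below the gene-count floor, then featureless genes", {
  ## toy: 3 genes share A; one gene has only the unique feature B
  pfam <- list(g1 = "PF00010", g2 = "PF00010", g3 = "PF00010", g4 = "PF00099")
  gs <- buildFeatureTable(pfam, minGeneCount = 2)
  expect_identical(featureSpace(gs), "PF00010")
  expect_identical(geneIds(gs), c("g1", "g2", "g3"))
  ## a feature in 19 genes is removed at the default floor of 20
  many <- setNames(rep(list("PF00777"), 19), sprintf("h%02d", 1:19))
  expect_error(buildFeatureTable(many), "no informative features")
})

test_that("feature table construction is idempotent and monotone in the floor", {
  sim <- simulateGeneSet(signatureSpec(n_genes_per_category = 15, seed = 13))
  sets <- featureSets(sim$geneset)
  for (floor in c(2, 8)) {
    gs <- buildFeatureTable(sets, minGeneCount = floor)
    again <- buildFeatureTable(featureSets(gs), minGeneCount = floor)
    expect_identical(featureSets(again), featureSets(gs))
    expect_identical(featureSpace(again), featureSpace(gs))
  }
  sizes <- vapply(c(1, 2, 5, 8, 12),
                  function(floor) {
                    gs <- buildFeatureTable(sets, minGeneCount = floor)
                    c(length(featureSpace(gs)), length(gs))
                  }, numeric(2))
  expect_true(all(diff(sizes[1, ]) <= 0))
  expect_true(all(diff(sizes[2, ]) <= 0))
})

test_that("cluster filter keeps the longest member per cluster", {
  cl <- data.frame(cluster_id = c("c1", "c1", "c1", "c2", "c2"),
                   member_id = c("a", "b", "c", "d", "e"),
                   length = c(100, 300, 300, 50, 40),
                   stringsAsFactors = FALSE)
  expect_identical(applyClusterFilter(cl), c("b", "d"))  # tie -> id ascending
})

test_that("BLAST reader ranks hits within query by ascending e-value", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "b.tsv")
  df <- data.frame(qseqid = c("q1", "q1", "q2"), sseqid = c("s1", "s2", "s3"),
                   pident = 90, length = 100L, mismatch = 0L, gapopen = 0L,
                   qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                   evalue = c(1e-10, 1e-30, 1e-5), bitscore = 200,
                   stringsAsFactors = FALSE)
  writeBlastTabTsv(df, f)
  got <- readBlastTab(f)
  expect_identical(got$rank[got$qseqid == "q1"], c(1L, 2L))
  expect_identical(got$sseqid[got$qseqid == "q1" & got$rank == 1L], "s2")
  expect_identical(got$rank[got$qseqid == "q2"], 1L)
})
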