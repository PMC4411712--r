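## Naive reference implementations, written as plain double loops straight
## from the defining formulas. They share no code with the package internals
## and serve as independent oracles.

CATS <- c("TFS", "MEM", "ENZ", "OTS")
TIE <- c("TFS", "ENZ", "MEM", "OTS")

## counts -> P -> IC -> w, one feature and category at a time
oracleWeights <- function(mat, labelsList, wMax = 1e6) {
  nFeat <- ncol(mat)
  C <- matrix(0, nFeat, 4, dimnames = list(colnames(mat), CATS))
  N <- setNames(numeric(4), CATS)
  for (j in CATS) {
    inJ <- vapply(labelsList[rownames(mat)], function(l) j %in% l, logical(1))
    N[j] <- sum(inJ)
    for (i in seq_len(nFeat)) C[i, j] <- sum(mat[inJ, i])
  }
  P <- IC <- W <- C * 0
  for (i in seq_len(nFeat)) {
    ci <- sum(C[i, ])
    for (j in CATS) {
      P[i, j] <- (C[i, j] / N[j]) * (C[i, j] / ci)
      if (P[i, j] > 0) {
        IC[i, j] <- -log2(P[i, j])
        W[i, j] <- if (IC[i, j] == 0) wMax else min(1 / IC[i, j], wMax)
      } else {
        IC[i, j] <- Inf
        W[i, j] <- 0
      }
    }
  }
  list(C = C, N = N, P = P, IC = IC, W = W)
}

## MWD ranking: per-feature descending sort, prune, order by MWD then id
oracleMWD <- function(W) {
  rows <- list()
  pruned <- character()
  for (i in seq_len(nrow(W))) {
    s <- sort(W[i, ], decreasing = TRUE)
    if (s[1] < s[2] + s[3] + s[4]) {
      pruned <- c(pruned, rownames(W)[i])
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        feature_id = rownames(W)[i], mwd = s[1] - (s[2] + s[3] + s[4]) / 3,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(ranking = data.frame(feature_id = character(), mwd = numeric()),
                pruned = pruned))
  df <- do.call(rbind, rows)
  df <- df[order(-df$mwd, df$feature_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  list(ranking = df, pruned = pruned)
}

oracleSim <- function(a, b) sum(a * b) / sqrt(sum(a) * sum(b))

oracleScore <- function(a, b, W, j) {
  shared <- which(a == 1 & b == 1)
  oracleSim(a, b) * sum(W[shared, j])
}

## nearest neighbour over all (training gene, its categories) pairs
oracleNNA <- function(q, mat, labelsList, W, excludeId = NULL) {
  if (sum(q) == 0) return(list(unclassifiable = TRUE))
  cand <- data.frame(neighbor = character(), category = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  for (b in rownames(mat)) {
    if (!is.null(excludeId) && b == excludeId) next
    bb <- mat[b, ]
    if (sum(bb) == 0) next
    for (j in labelsList[[b]]) {
      cand <- rbind(cand, data.frame(neighbor = b, category = j,
                                     score = oracleScore(q, bb, W, j),
                                     stringsAsFactors = FALSE))
    }
  }
  cand <- cand[cand$score > 0, , drop = FALSE]
  if (nrow(cand) == 0) return(list(unclassifiable = TRUE))
  best <- max(cand$score)
  cand <- cand[cand$score == best, , drop = FALSE]
  cand <- cand[order(match(cand$category, TIE), cand$neighbor,
                     method = "radix"), , drop = FALSE]
  list(unclassifiable = FALSE, category = cand$category[1],
       neighbor = cand$neighbor[1], score = best)
}

oracleMetrics <- function(tp, fp, tn, fn) {
  den <- function(x) if (x == 0) NA_real_ else x
  mden <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(sensitivity = tp / den(tp + fn),
       specificity = tn / den(tn + fp),
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = tp / den(tp + fp),
       mcc = if (mden > 0) (tp * tn - fp * fn) / sqrt(mden) else 0)
}

## the full LOOCV sweep, O(M^2 N) double loop per k
oracleLoocv <- function(mat, labelsList, rankedIds, kGrid, W) {
  rows <- list()
  for (k in kGrid) {
    sel <- head(rankedIds, k)
    sub <- mat[, sel, drop = FALSE]
    wk <- W[sel, , drop = FALSE]
    predTF <- logical(nrow(sub))
    truthTF <- vapply(labelsList[rownames(sub)], function(l) "TFS" %in% l,
                      logical(1))
    categories <- rep(NA_character_, nrow(sub))
    for (m in seq_len(nrow(sub))) {
      r <- oracleNNA(sub[m, ], sub, labelsList, wk,
                     excludeId = rownames(sub)[m])
      if (!r$unclassifiable) {
        predTF[m] <- r$category == "TFS"
        categories[m] <- r$category
      }
    }
    tp <- sum(predTF & truthTF); fp <- sum(predTF & !truthTF)
    tn <- sum(!predTF & !truthTF); fn <- sum(!predTF & truthTF)
    met <- oracleMetrics(tp, fp, tn, fn)
    rows[[length(rows) + 1]] <- data.frame(
      k = k, TP = tp, FP = fp, TN = tn, FN = fn,
      sensitivity = met$sensitivity, specificity = met$specificity,
      accuracy = met$accuracy, precision = met$precision, mcc = met$mcc,
      categories = I(list(categories)), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## random small multi-label instance for property tests
randomInstance <- function(nGenes = 24, nFeat = 10, seed = 1) {
  set.seed(seed)
  repeat {
    mat <- matrix(rbinom(nGenes * nFeat, 1, 0.35), nGenes, nFeat,
                  dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                  sprintf("F%03d", seq_len(nFeat))))
    ## every gene and feature must be populated
    if (all(rowSums(mat) > 0) && all(colSums(mat) > 0)) break
  }
  labels <- lapply(seq_len(nGenes), function(i) {
    l <- CATS[c(sample(4, 1), if (runif(1) < 0.25) sample(4, 1))]
    unique(l)
  })
  ## guarantee all four categories populated
  for (j in seq_len(4)) labels[[j]] <- unique(c(labels[[j]], CATS[j]))
  names(labels) <- rownames(mat)
  list(mat = mat, labels = labels)
}
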