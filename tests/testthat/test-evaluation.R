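# hand-built annotated repertoire from an explicit similarity matrix
toy_repertoire <- function(sim_vals, ids, peptides, peptide_seqs = NULL) {
  m <- matrix(sim_vals, length(ids), length(ids),
              dimnames = list(ids, ids))
  annotated_repertoire(m, stats::setNames(peptides, ids), peptide_seqs)
}

test_that("duplicate pairs are mutual nearest neighbors with 100% accuracy", {
  # 4 TCRs, two perfect-duplicate pairs with distinct peptides
  m <- diag(4) * 0 + 0.2
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 1
  diag(m) <- 1
  dimnames(m) <- list(letters[1:4], letters[1:4])
  rep <- annotated_repertoire(m, c(a = "P1", b = "P1", c = "P2", d = "P2"))
  row <- peptide_identity(rep, rank = 1)
  expect_equal(row$accuracy, 100)
  expect_equal(row$n_clustered, 4L)
  # 2 TCRs with different peptides -> rank-1 accuracy 0
  rep2 <- toy_repertoire(c(1, 0.5, 0.5, 1), c("x", "y"), c("P1", "P2"))
  expect_equal(peptide_identity(rep2, rank = 1)$accuracy, 0)
})

test_that("peptide identity equals a brute-force neighbor enumeration", {
  set.seed(101)
  n <- 12
  ids <- sprintf("t%02d", 1:n)
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  peps <- sample(c("P1", "P2", "P3"), n, replace = TRUE)
  rep <- annotated_repertoire(m, stats::setNames(peps, ids))
  for (k in c(1, 2, 5)) {
    for (t in list(NULL, 0.5, 0.9)) {
      got <- peptide_identity(rep, rank = k, threshold = t)
      clustered <- 0
      correct <- 0
      for (i in 1:n) {
        sims <- m[i, -i]
        cand <- ids[-i]
        if (!is.null(t)) {
          cand <- cand[sims > t]
          sims <- sims[sims > t]
        }
        if (length(cand) == 0) next
        clustered <- clustered + 1
        top <- cand[order(-sims, cand)][seq_len(min(k, length(cand)))]
        if (any(peps[match(top, ids)] == peps[i])) correct <- correct + 1
      }
      expect_equal(got$n_clustered, clustered)
      expect_equal(got$n_correct, correct)
      if (clustered > 0) {
        expect_equal(got$accuracy, 100 * correct / clustered)
      }
    }
  }
})

test_that("accuracy is non-decreasing in rank and coverage in threshold", {
  sr <- small_repertoire(n_families = 3, per_family = 4, seed = 61L)
  rep <- sr$annotated
  tab <- rank_threshold_report(rep, ranks = c(1, 2, 5),
                               thresholds = c(NA, 0.7, 0.8, 0.9))
  for (t in unique(tab$threshold)) {
    sel <- if (is.na(t)) is.na(tab$threshold) else
      !is.na(tab$threshold) & tab$threshold == t
    acc <- tab$accuracy[sel]
    acc <- acc[!is.na(acc)]
    expect_false(is.unsorted(acc))
  }
  # clustered fraction weakly decreases as the threshold rises
  cov <- tab$coverage[tab$rank == 1]
  cov[is.na(cov)] <- 0
  expect_false(is.unsorted(rev(cov)))
})

test_that("sequence recapitulation counts positional peptide identities", {
  # all TCRs bind the same 9-mer -> 100%
  m <- matrix(0.5, 3, 3)
  diag(m) <- 1
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  rep <- annotated_repertoire(m, stats::setNames(rep("KLGGALQAK", 3),
                                                 c("a", "b", "c")))
  expect_equal(sequence_recapitulation(rep), 100)
  # nearest-neighbor peptides differing at 1 of 9 positions
  rep2 <- toy_repertoire(c(1, 0.9, 0.9, 1), c("a", "b"),
                         c("KLGGALQAK", "KLGGALQAV"))
  expect_equal(sequence_recapitulation(rep2), 100 * 8 / 9)
  # unequal lengths: identities relative to the longer peptide
  expect_equal(tcrfp:::peptide_identity_fraction("KLGGALQAK", "KLGGALQ"),
               7 / 9)
})

test_that("all-pairs AUC equals the Mann-Whitney oracle", {
  # positives all above negatives -> AUC 1; identical scores -> 0.5
  set.seed(71)
  for (trial in 1:5) {
    n <- 8
    ids <- sprintf("s%d", 1:n)
    m <- matrix(round(stats::runif(n * n), 2), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    peps <- sample(c("P1", "P2"), n, replace = TRUE)
    if (length(unique(peps)) < 2) peps[1] <- setdiff(c("P1", "P2"), peps)[1]
    rep <- annotated_repertoire(m, stats::setNames(peps, ids))
    got <- same_specificity_roc(rep)
    idx <- which(upper.tri(m), arr.ind = TRUE)
    scores <- m[idx]
    labels <- peps[idx[, 1]] == peps[idx[, 2]]
    expect_equal(got$auc, mw_auc_oracle(scores, labels), tolerance = 1e-12)
    # ROC endpoints
    expect_equal(got$points$fpr[1], 0)
    expect_equal(got$points$tpr[nrow(got$points)], 1)
  }
  # degenerate separable and tied cases
  sep <- toy_repertoire(c(1, 0.9, 0.2, 0.9, 1, 0.2, 0.2, 0.2, 1),
                        c("a", "b", "c"), c("P", "P", "Q"))
  expect_equal(same_specificity_roc(sep)$auc, 1)
  tied <- toy_repertoire(c(1, 0.5, 0.5, 0.5, 1, 0.5, 0.5, 0.5, 1),
                         c("a", "b", "c"), c("P", "P", "Q"))
  expect_equal(same_specificity_roc(tied)$auc, 0.5)
  # single-class input is fatal
  mono <- toy_repertoire(c(1, 0.5, 0.5, 1), c("a", "b"), c("P", "P"))
  expect_error(same_specificity_roc(mono), "positive and negative")
})

test_that("rank-1 ROC mode scores each TCR's closest neighbor", {
  # well-separated families make every rank-1 pair positive, which is a
  # degenerate single-class ROC -> fatal; use a noisy repertoire instead
  sep <- small_repertoire(n_families = 2, per_family = 3, jitter = 0,
                          spread = 8, seed = 67L)
  expect_error(same_specificity_roc(sep$annotated, mode = "rank1"),
               "positive and negative")
  noisy <- small_repertoire(n_families = 3, per_family = 3, jitter = 2,
                            spread = 1.5, seed = 73L)
  got <- same_specificity_roc(noisy$annotated, mode = "rank1")
  expect_equal(got$n_pos + got$n_neg, length(noisy$annotated$ids))
  # oracle: recompute the rank-1 scores/labels by hand and count pairs
  ids <- noisy$annotated$ids
  peps <- noisy$peptides[ids]
  scores <- labels <- numeric(0)
  for (i in seq_along(ids)) {
    others <- ids[-i]
    s <- noisy$sim[i, others]
    nn <- others[order(-s, others)][1]
    scores <- c(scores, noisy$sim[ids[i], nn])
    labels <- c(labels, peps[nn] == peps[ids[i]])
  }
  expect_equal(got$auc, mw_auc_oracle(scores, as.logical(labels)),
               tolerance = 1e-12)
  # all-pairs mode agrees with an established ROC implementation
  skip_if_not_installed("pROC")
  idx <- which(upper.tri(noisy$sim), arr.ind = TRUE)
  ap_scores <- noisy$sim[idx]
  ap_labels <- peps[idx[, 1]] == peps[idx[, 2]]
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = as.integer(ap_labels), predictor = ap_scores,
    direction = "<", quiet = TRUE)))
  expect_equal(same_specificity_roc(noisy$annotated)$auc, as.numeric(ref),
               tolerance = 1e-10)
})

test_that("cross-validated AUC is deterministic and exact when separable", {
  sr <- small_repertoire(n_families = 2, per_family = 5, jitter = 0,
                         seed = 79L)
  cv1 <- cross_validated_auc(sr$annotated, folds = 5, seed = 11)
  cv2 <- cross_validated_auc(sr$annotated, folds = 5, seed = 11)
  expect_identical(cv1, cv2)
  # zero jitter separates families perfectly
  expect_equal(cv1$mean, 1)
  expect_equal(cv1$sd, 0)
  # label shuffles sit near chance
  shuf <- sr$annotated
  set.seed(5)
  null_means <- replicate(20, {
    perm <- sample(shuf$peptides)
    names(perm) <- shuf$ids
    r <- annotated_repertoire(shuf$similarity, perm)
    suppressMessages(cross_validated_auc(r, folds = 3, seed = 13)$mean)
  })
  expect_lt(abs(mean(null_means) - 0.5), 0.15)
})

test_that("similarity-probability curve tallies rank-1 bins directly", {
  # duplicates-only repertoire: all mass in the top bin with probability 1
  m <- diag(4) * 0 + 0.1
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 1
  diag(m) <- 1
  dimnames(m) <- list(letters[1:4], letters[1:4])
  rep <- annotated_repertoire(m, c(a = "P1", b = "P1", c = "P2", d = "P2"))
  curve <- suppressMessages(similarity_probability_curve(rep))
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$probability, 1)
  expect_equal(curve$bin_high, 1)
  expect_equal(curve$n_pairs, 4L)
  # two-family synthetic repertoire: recount matches a direct tally
  sr <- small_repertoire(n_families = 2, per_family = 4, seed = 83L)
  bins <- seq(0, 1, 0.25)
  got <- suppressMessages(similarity_probability_curve(sr$annotated, bins))
  sims <- pos <- numeric(0)
  for (i in seq_along(sr$annotated$ids)) {
    others <- sr$annotated$ids[-i]
    s <- sr$sim[i, others]
    nn <- others[order(-s, others)][1]
    sims <- c(sims, sr$sim[sr$annotated$ids[i], nn])
    pos <- c(pos, sr$peptides[nn] == sr$peptides[sr$annotated$ids[i]])
  }
  for (r in seq_len(nrow(got))) {
    # bins are left-closed, the last one closed on both ends
    sel <- sims >= got$bin_low[r] &
      (sims < got$bin_high[r] | got$bin_high[r] == 1)
    expect_equal(got$n_pairs[r], sum(sel))
    expect_equal(got$probability[r], mean(pos[sel]))
  }
  expect_error(similarity_probability_curve(sr$annotated, c(-0.1, 1)),
               "within")
})

test_that("UPGMA merges follow hand-executed agglomeration", {
  # 3 items, two identical: the duplicate pair merges first at height 0
  m <- matrix(c(1, 1, 0.5, 1, 1, 0.5, 0.5, 0.5, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cl <- upgma_cluster(m)
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(sort(cl$hclust$labels[-cl$hclust$merge[1, ]]), c("a", "b"))
  expect_match(cl$newick, "^\\(")
  # 4-item matrix: heights equal hand-computed UPGMA averages
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.2
  d["a", "c"] <- d["c", "a"] <- 0.6
  d["b", "c"] <- d["c", "b"] <- 0.8
  d["a", "d"] <- d["d", "a"] <- 0.9
  d["b", "d"] <- d["d", "b"] <- 0.7
  d["c", "d"] <- d["d", "c"] <- 0.4
  cl2 <- upgma_cluster(1 - d)
  # merges: {a,b}@0.2, {c,d}@0.4, then average of (0.6,0.9,0.8,0.7)=0.75
  expect_equal(cl2$hclust$height, c(0.2, 0.4, 0.75), tolerance = 1e-12)
  # permuting input gives an isomorphic tree (same heights)
  perm <- c(3, 1, 4, 2)
  cl3 <- upgma_cluster((1 - d)[perm, perm])
  expect_equal(sort(cl3$hclust$height), sort(cl2$hclust$height),
               tolerance = 1e-12)
  expect_error(upgma_cluster(matrix(c(1, NaN, NaN, 1), 2, 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b")))),
               "non-finite")
})
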