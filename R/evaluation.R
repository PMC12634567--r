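## evaluation: specificity-pairing statistics, ROC/AUC, clustering.

#' Construct an annotated repertoire
#'
#' Bundles a TCR similarity matrix with the cognate-peptide label of every
#' TCR (and, optionally, the peptide sequences) for specificity-pairing
#' evaluation.
#'
#' @param similarity symmetric similarity matrix with unit diagonal, row and
#'   column names the TCR ids.
#' @param peptides character vector of peptide labels, named by TCR id (or
#'   in matrix order).
#' @param peptide_sequences optional peptide amino-acid sequences, named by
#'   TCR id; defaults to `peptides` when those are themselves sequences.
#' @return object of class `annotated_repertoire`.
#' @export
annotated_repertoire <- function(similarity, peptides,
                                 peptide_sequences = NULL) {
  similarity <- as.matrix(similarity)
  ids <- rownames(similarity)
  if (is.null(ids) || !identical(ids, colnames(similarity))) {
    stop("similarity matrix must have matching row/column names")
  }
  if (anyDuplicated(ids)) stop("duplicate tcr_id(s)")
  if (any(is.na(similarity))) stop("NA entries in similarity matrix")
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    stop("similarity matrix is not symmetric")
  }
  if (max(abs(diag(similarity) - 1)) > 1e-8) {
    stop("similarity matrix must have unit diagonal")
  }
  if (is.null(names(peptides))) names(peptides) <- ids
  if (!all(ids %in% names(peptides))) {
    stop("peptide labels missing for some TCRs")
  }
  peptides <- peptides[ids]
  if (!is.null(peptide_sequences)) {
    if (is.null(names(peptide_sequences))) names(peptide_sequences) <- ids
    peptide_sequences <- peptide_sequences[ids]
  }
  structure(list(similarity = similarity, ids = ids,
                 peptides = as.character(peptides),
                 peptide_sequences = peptide_sequences),
            class = "annotated_repertoire")
}

## Neighbor ids of TCR i (self excluded), sorted by decreasing similarity,
## ties broken by lexicographic tcr_id.
neighbor_ids <- function(rep, i, threshold = NULL) {
  ids <- rep$ids
  cand <- ids[-i]
  s <- rep$similarity[i, cand]
  if (!is.null(threshold) && !is.na(threshold)) {
    keep <- s > threshold
    cand <- cand[keep]
    s <- s[keep]
  }
  cand[order(-s, cand)]
}

#' Peptide-identity (rank/threshold) pairing statistic
#'
#' For every TCR, its neighbors with similarity strictly above the threshold
#' are ranked by decreasing similarity (ties by lexicographic id). A TCR is
#' "clustered" if it has at least one such neighbor; it is correctly paired
#' if any of its top-`rank` clustered neighbors binds the same peptide.
#' Accuracy is correct/clustered; coverage is clustered/total.
#'
#' @param rep an [annotated_repertoire()].
#' @param rank number of top neighbors considered (1, 2, 5 ...).
#' @param threshold similarity threshold (strict `>`), or `NULL`/`NA` for
#'   none.
#' @return one-row data frame: `rank`, `threshold`, `accuracy` (%; `NA` if no
#'   TCR is clustered), `n_correct`, `n_clustered`, `coverage` (%),
#'   `n_total`.
#' @export
peptide_identity <- function(rep, rank = 1L, threshold = NULL) {
  stopifnot(inherits(rep, "annotated_repertoire"), is_count(rank))
  n <- length(rep$ids)
  if (n < 2L) stop("need at least 2 TCRs")
  pep <- rep$peptides
  names(pep) <- rep$ids
  clustered <- 0L
  correct <- 0L
  for (i in seq_len(n)) {
    nb <- neighbor_ids(rep, i, threshold)
    if (length(nb) == 0L) next
    clustered <- clustered + 1L
    top <- nb[seq_len(min(rank, length(nb)))]
    if (any(pep[top] == pep[i])) correct <- correct + 1L
  }
  data.frame(
    rank = as.integer(rank),
    threshold = if (is.null(threshold)) NA_real_ else as.numeric(threshold),
    accuracy = if (clustered > 0L) 100 * correct / clustered else NA_real_,
    n_correct = correct, n_clustered = clustered,
    coverage = 100 * clustered / n, n_total = n
  )
}

#' Rank/threshold accuracy table
#'
#' [peptide_identity()] evaluated over a grid of ranks and similarity
#' thresholds (`NA` = no threshold).
#'
#' @param rep an [annotated_repertoire()].
#' @param ranks ranks to evaluate (default 1, 2, 5).
#' @param thresholds thresholds to evaluate (default none, 0.7, 0.8, 0.9).
#' @return data frame with one row per (threshold, rank) combination.
#' @export
rank_threshold_report <- function(rep, ranks = c(1L, 2L, 5L),
                                  thresholds = c(NA, 0.7, 0.8, 0.9)) {
  do.call(rbind, lapply(thresholds, function(t) {
    do.call(rbind, lapply(ranks, function(k) {
      peptide_identity(rep, rank = k, threshold = if (is.na(t)) NULL else t)
    }))
  }))
}

## residue identity fraction between two peptide sequences
peptide_identity_fraction <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    return(mean(av == bv))
  }
  ## unequal lengths: identities from an unpenalized global alignment,
  ## relative to the longer peptide
  sub <- diag(1, 26)
  dimnames(sub) <- list(LETTERS, LETTERS)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 0,
    scoreOnly = TRUE
  )
  aln / max(nchar(a), nchar(b))
}

#' Sequence recapitulation of nearest-neighbor peptides
#'
#' For each TCR, the residue identity fraction between its cognate peptide
#' and the peptide of its nearest (rank-1) neighbor; averaged over TCRs, in
#' percent. Same-length peptides are compared positionally, others through
#' an unpenalized global alignment with identities counted against the
#' longer peptide.
#'
#' @param rep an [annotated_repertoire()] with `peptide_sequences` (falls
#'   back to the peptide labels when they are sequences).
#' @return average identity in percent.
#' @export
sequence_recapitulation <- function(rep) {
  stopifnot(inherits(rep, "annotated_repertoire"))
  seqs <- rep$peptide_sequences
  if (is.null(seqs)) seqs <- rep$peptides
  names(seqs) <- rep$ids
  vals <- vapply(seq_along(rep$ids), function(i) {
    nn <- neighbor_ids(rep, i)[1L]
    peptide_identity_fraction(seqs[[rep$ids[i]]], seqs[[nn]])
  }, numeric(1))
  100 * mean(vals)
}

## AUC by the rank (Mann-Whitney) statistic, ties averaged
rank_auc <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative pairs")
  r <- rank(scores)  # average ranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC for same-specificity prediction
#'
#' Pairs are labeled positive when both TCRs bind the same peptide. Scores
#' are either all unordered pair similarities (`mode = "all_pairs"`) or, per
#' TCR, the similarity to its rank-1 neighbor (`mode = "rank1"`). The AUC is
#' the rank (Mann-Whitney) statistic with ties averaged.
#'
#' @param rep an [annotated_repertoire()].
#' @param mode `"all_pairs"` (default) or `"rank1"`.
#' @return list with `auc`, `points` (data frame `fpr`, `tpr` over score
#'   cutoffs), `n_pos`, `n_neg`.
#' @export
same_specificity_roc <- function(rep, mode = c("all_pairs", "rank1")) {
  stopifnot(inherits(rep, "annotated_repertoire"))
  mode <- match.arg(mode)
  pep <- rep$peptides
  names(pep) <- rep$ids
  if (mode == "all_pairs") {
    n <- length(rep$ids)
    idx <- which(upper.tri(rep$similarity), arr.ind = TRUE)
    scores <- rep$similarity[idx]
    labels <- pep[rep$ids[idx[, 1]]] == pep[rep$ids[idx[, 2]]]
  } else {
    scores <- numeric(length(rep$ids))
    labels <- logical(length(rep$ids))
    for (i in seq_along(rep$ids)) {
      nn <- neighbor_ids(rep, i)[1L]
      scores[i] <- rep$similarity[rep$ids[i], nn]
      labels[i] <- pep[nn] == pep[rep$ids[i]]
    }
  }
  auc <- rank_auc(scores, labels)
  ## ROC points over decreasing score cutoffs (tied scores grouped)
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  grp <- !duplicated(s)
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last <- c(which(grp[-1]), length(s))
  pts <- data.frame(fpr = c(0, fp[last] / sum(!labels)),
                    tpr = c(0, tp[last] / sum(labels)))
  list(auc = auc, points = pts, n_pos = sum(labels), n_neg = sum(!labels))
}

#' Cross-validated AUC over random 70/30 splits
#'
#' Draws `folds` independent random splits keeping `1 - train_frac` of the
#' TCRs as a held-out subset, computes the same-specificity AUC on each
#' held-out subset, and reports mean and standard deviation. Held-out
#' subsets with a single class are redrawn (with a message).
#'
#' @param rep an [annotated_repertoire()].
#' @param folds number of random splits (default 5).
#' @param train_frac fraction held *in* (default 0.7; the AUC is computed on
#'   the remaining 30%).
#' @param seed RNG seed; same seed gives identical output.
#' @param mode passed to [same_specificity_roc()].
#' @return list with `mean`, `sd`, `aucs` (per fold).
#' @export
cross_validated_auc <- function(rep, folds = 5L, train_frac = 0.7,
                                seed = 1L, mode = "all_pairs") {
  stopifnot(inherits(rep, "annotated_repertoire"), is_count(folds))
  n <- length(rep$ids)
  n_test <- max(2L, round((1 - train_frac) * n))
  aucs <- with_seed(seed, {
    vapply(seq_len(folds), function(f) {
      for (attempt in seq_len(100L)) {
        test <- sort(sample.int(n, n_test))
        sub <- annotated_repertoire(
          rep$similarity[test, test, drop = FALSE],
          rep$peptides[test],
          if (!is.null(rep$peptide_sequences)) rep$peptide_sequences[test]
        )
        r <- tryCatch(same_specificity_roc(sub, mode = mode),
                      error = function(e) NULL)
        if (!is.null(r)) return(r$auc)
        message("fold ", f, ": single-class held-out set, resampling")
      }
      stop("could not draw a two-class held-out set in 100 attempts")
    }, numeric(1))
  })
  list(mean = mean(aucs), sd = stats::sd(aucs), aucs = aucs)
}

#' Similarity vs same-peptide probability curve
#'
#' Bins every TCR's rank-1 neighbor pair by its similarity and reports the
#' fraction of pairs binding the same peptide per bin. Empty bins are
#' omitted with a note.
#'
#' @param rep an [annotated_repertoire()].
#' @param bins ascending bin edges inside [0, 1] (default 0, 0.1, ..., 1).
#' @return data frame `bin_low`, `bin_high`, `n_pairs`, `probability`.
#' @export
similarity_probability_curve <- function(rep, bins = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(rep, "annotated_repertoire"))
  if (any(bins < 0 | bins > 1) || is.unsorted(bins, strictly = TRUE) ||
      length(bins) < 2L) {
    stop("bin edges must be strictly ascending within [0, 1]")
  }
  pep <- rep$peptides
  names(pep) <- rep$ids
  sims <- pos <- numeric(length(rep$ids))
  for (i in seq_along(rep$ids)) {
    nn <- neighbor_ids(rep, i)[1L]
    sims[i] <- rep$similarity[rep$ids[i], nn]
    pos[i] <- pep[nn] == pep[rep$ids[i]]
  }
  cut_idx <- findInterval(sims, bins, rightmost.closed = TRUE,
                          all.inside = TRUE)
  out <- do.call(rbind, lapply(seq_len(length(bins) - 1L), function(b) {
    sel <- cut_idx == b
    if (!any(sel)) return(NULL)
    data.frame(bin_low = bins[b], bin_high = bins[b + 1L],
               n_pairs = sum(sel), probability = mean(pos[sel]))
  }))
  if (nrow(out) < length(bins) - 1L) {
    message(length(bins) - 1L - nrow(out), " empty bin(s) omitted")
  }
  out
}

#' Label-permutation null distribution of the rank-1 pairing accuracy
#'
#' Shuffles the peptide labels and recomputes the rank-1, no-threshold
#' peptide-identity accuracy for each permutation. Used as the random
#' baseline when judging whether an observed accuracy is better than chance.
#'
#' @param rep an [annotated_repertoire()].
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return numeric vector of permuted accuracies in percent.
#' @export
permutation_baseline <- function(rep, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(rep, "annotated_repertoire"))
  n <- length(rep$ids)
  nn <- vapply(seq_len(n), function(i) {
    match(neighbor_ids(rep, i)[1L], rep$ids)
  }, integer(1))
  with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      lab <- sample(rep$peptides)
      100 * mean(lab[nn] == lab)
    }, numeric(1))
  })
}

#' UPGMA clustering of a similarity matrix
#'
#' Converts similarities to distances (1 - similarity) and builds an
#' average-linkage (UPGMA) dendrogram.
#'
#' @param similarity symmetric similarity matrix with unit diagonal and no
#'   missing entries.
#' @return list with `hclust` (the merge tree), `phylo` (ape tree with
#'   branch lengths) and `newick` (serialized tree string).
#' @export
upgma_cluster <- function(similarity) {
  similarity <- as.matrix(similarity)
  if (any(!is.finite(similarity))) stop("non-finite similarity entries")
  if (max(abs(similarity - t(similarity))) > 1e-8 ||
      max(abs(diag(similarity) - 1)) > 1e-8) {
    stop("similarity matrix must be symmetric with unit diagonal")
  }
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy, newick = ape::write.tree(phy))
}
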