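## fingerprint: centroid placement, 18-value ES5D fingerprint, similarity.

FP_STATS <- c("mean", "sd", "m3")

#' Tip-of-loop residue position
#'
#' The centroid anchor of a CDR loop is its middle residue; for loops of even
#' length the lower of the two middle positions is taken.
#'
#' @param n_residues loop length (>= 1).
#' @return 1-based residue position of the loop tip: `(n+1)/2` for odd `n`,
#'   `n/2` for even `n`.
#' @export
tip_of_loop_index <- function(n_residues) {
  if (!is_count(n_residues)) stop("loop must have at least one residue")
  n <- as.integer(n_residues)
  if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L
}

## centroid-set constructor (6 x 5 matrix, loop rownames)
as_centroid_set <- function(coords, mode, C, P) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(6L, 5L))) stop("centroids must form a 6 x 5 matrix")
  if (!all(is.finite(coords))) stop("non-finite centroid coordinates")
  rownames(coords) <- LOOP_ORDER
  colnames(coords) <- c("x", "y", "z", "q_w", "l_w")
  structure(list(coords = coords, mode = mode, C = C, P = P),
            class = "centroid_set")
}

#' Place tip-of-loop (TOL) centroids
#'
#' Places one centroid per CDR loop on the CA atom of the loop's tip residue.
#' The centroid's fourth and fifth coordinates are that CA's weighted charge
#' and weighted lipophilicity.
#'
#' @param cdrs a CDR set with assigned properties ([assign_properties()]).
#' @return a `centroid_set` in TOL mode.
#' @export
place_centroids_tol <- function(cdrs) {
  stopifnot(inherits(cdrs, "cdr_set"))
  if (is.null(cdrs$C)) {
    stop("CDR set has no assigned properties; call assign_properties() first")
  }
  coords <- matrix(NA_real_, 6L, 5L)
  for (i in seq_along(LOOP_ORDER)) {
    loop <- LOOP_ORDER[i]
    at <- cdrs$loops[[loop]]
    res_key <- paste(at$residue_number, at$insert)
    res_levels <- unique(res_key)
    tip_key <- res_levels[tip_of_loop_index(length(res_levels))]
    ca <- which(res_key == tip_key & at$atom_name == "CA")
    if (length(ca) == 0L) {
      stop("loop ", loop, ": tip residue has no CA atom")
    }
    ca <- ca[1L]
    coords[i, ] <- c(at$x[ca], at$y[ca], at$z[ca], at$q_w[ca], at$l_w[ca])
  }
  as_centroid_set(coords, "TOL", cdrs$C, cdrs$P)
}

#' Universal centroids from a genome vector
#'
#' Interprets an optimizer genome (30 centroid coordinates followed by the C
#' and P weights, 32 values in total) as a universal centroid set. Universal
#' centroids assume structures superposed into the canonical frame
#' ([principal_axis_superpose()]) before fingerprinting.
#'
#' @param genome numeric vector of length 32: six centroids x 5 coordinates
#'   (row-wise), then C, then P.
#' @return a `centroid_set` in universal mode.
#' @export
place_centroids_universal <- function(genome) {
  if (length(genome) != 32L || !all(is.finite(genome))) {
    stop("genome must be 32 finite values")
  }
  C <- genome[31L]
  P <- genome[32L]
  if (C <= 0 || P <= 0) stop("C and P must be positive")
  as_centroid_set(matrix(genome[1:30], 6L, 5L, byrow = TRUE), "universal",
                  C, P)
}

## distance-moment triples (mean, population SD, third-moment statistic) of
## all pooled atoms against each centroid row; the 18-value core shared by
## the fingerprint and the GA fitness paths
es5d_values <- function(atoms, centroid_mat, third_moment = "cbrt") {
  values <- numeric(18L)
  nms <- character(18L)
  for (i in seq_len(6L)) {
    d <- sqrt(rowSums(sweep(atoms, 2L, centroid_mat[i, ])^2))
    m <- mean(d)
    s <- sqrt(mean((d - m)^2))
    m3 <- mean((d - m)^3)
    if (third_moment == "cbrt") m3 <- sign(m3) * abs(m3)^(1 / 3)
    values[(3L * i - 2L):(3L * i)] <- c(m, s, m3)
    nms[(3L * i - 2L):(3L * i)] <- paste(LOOP_ORDER[i], FP_STATS, sep = ".")
  }
  names(values) <- nms
  values
}

#' Compute the 18-value ES5D fingerprint of a TCR
#'
#' Pools all atoms of the six CDR loops and, for each of the six centroids,
#' computes the mean, population standard deviation and third-moment
#' statistic of the 5D Euclidean atom-centroid distances. The third moment is
#' reported, by default, as the signed cube root of the third central moment
#' so that all 18 values carry distance units; the raw central moment is
#' available via `third_moment = "raw"`.
#'
#' @param cdrs a CDR set with assigned properties.
#' @param centroids a `centroid_set`; default: TOL centroids of `cdrs`.
#' @param third_moment `"cbrt"` (default) or `"raw"`.
#' @return an object of class `tcr_fingerprint`: 18 named values (triples in
#'   loop order CDR1a..CDR3b) plus provenance metadata.
#' @export
compute_fingerprint <- function(cdrs, centroids = NULL,
                                third_moment = c("cbrt", "raw")) {
  stopifnot(inherits(cdrs, "cdr_set"))
  third_moment <- match.arg(third_moment)
  if (is.null(centroids)) centroids <- place_centroids_tol(cdrs)
  stopifnot(inherits(centroids, "centroid_set"))
  atoms <- pooled_atoms_5d(cdrs)
  if (centroids$mode == "universal" &&
      (!isTRUE(all.equal(centroids$C, cdrs$C)) ||
       !isTRUE(all.equal(centroids$P, cdrs$P)))) {
    stop("centroid weights (C, P) disagree with the CDR set's weights")
  }
  if (nrow(atoms) < 2L) stop("need at least 2 CDR atoms")
  values <- es5d_values(atoms, centroids$coords, third_moment)
  structure(
    list(tcr_id = cdrs$tcr_id, values = values, mode = centroids$mode,
         C = cdrs$C, P = cdrs$P, hydrogen_policy = cdrs$hydrogen_policy,
         table_tag = cdrs$table_tag, third_moment = third_moment),
    class = "tcr_fingerprint"
  )
}

#' Fingerprint a TCR structure in one call
#'
#' Convenience wrapper: extract CDRs, assign properties and compute the
#' TOL-mode fingerprint.
#'
#' @param structure a [as_tcr_structure()] object.
#' @param annotation optional CDR annotation (default IMGT ranges).
#' @param table optional property table.
#' @param C,P property weights.
#' @param ... passed to [compute_fingerprint()].
#' @return a `tcr_fingerprint`.
#' @export
fingerprint_structure <- function(structure, annotation = NULL, table = NULL,
                                  C = 25, P = 4, ...) {
  cdrs <- assign_properties(extract_cdrs(structure, annotation), table = table,
                            C = C, P = P)
  compute_fingerprint(cdrs, ...)
}

#' @export
print.tcr_fingerprint <- function(x, digits = 4, ...) {
  cat("ES5D fingerprint '", x$tcr_id, "' (", x$mode, " centroids, C=", x$C,
      ", P=", x$P, ", ", x$hydrogen_policy, ")\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

fp_metadata <- function(fp) {
  list(mode = fp$mode, C = fp$C, P = fp$P,
       hydrogen_policy = fp$hydrogen_policy, table_tag = fp$table_tag,
       third_moment = fp$third_moment)
}

check_fp_compatible <- function(fpA, fpB) {
  if (length(fpA$values) != length(fpB$values)) {
    stop("fingerprint lengths differ")
  }
  a <- fp_metadata(fpA)
  b <- fp_metadata(fpB)
  bad <- names(a)[!mapply(identical, a, b)]
  if (length(bad)) {
    stop("incompatible fingerprints (differing ", paste(bad, collapse = ", "),
         "); refusing comparison")
  }
  invisible(TRUE)
}

#' Manhattan-based fingerprint similarity
#'
#' Similarity between two fingerprints x^A, x^B of length n:
#' \deqn{S = (1 + \frac{1}{n}\sum_{i=1}^{n} |x_i^A - x_i^B|)^{-1}}
#' It equals 1 for identical fingerprints and decreases towards 0 with
#' increasing mean absolute difference. Fingerprints with differing
#' provenance (centroid mode, weights, hydrogen policy, property table,
#' third-moment convention) refuse comparison.
#'
#' @param fpA,fpB `tcr_fingerprint` objects.
#' @return similarity score in (0, 1].
#' @export
fp_similarity <- function(fpA, fpB) {
  stopifnot(inherits(fpA, "tcr_fingerprint"), inherits(fpB, "tcr_fingerprint"))
  check_fp_compatible(fpA, fpB)
  1 / (1 + mean(abs(fpA$values - fpB$values)))
}

#' All-against-all fingerprint similarity matrix
#'
#' @param fps list of mutually compatible `tcr_fingerprint` objects with
#'   unique `tcr_id`s (>= 2).
#' @return symmetric similarity matrix with unit diagonal, labeled by
#'   `tcr_id`.
#' @export
pairwise_similarity <- function(fps) {
  if (length(fps) < 2L) stop("need at least 2 fingerprints")
  ids <- vapply(fps, function(f) f$tcr_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate tcr_id(s): ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  for (f in fps[-1L]) check_fp_compatible(fps[[1L]], f)
  vals <- t(vapply(fps, function(f) f$values, fps[[1L]]$values))
  n <- length(fps)
  sim <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- 1 / (1 + mean(abs(vals[i, ] - vals[j, ])))
      sim[i, j] <- s
      sim[j, i] <- s
    }
  }
  sim
}

#' Write fingerprints to a delimited table
#'
#' One row per TCR: `tcr_id`, the 18 values, then the provenance metadata
#' columns. A `#` header records the package version.
#'
#' @param fps list of `tcr_fingerprint` objects.
#' @param path output file.
#' @export
write_fingerprints <- function(fps, path) {
  if (inherits(fps, "tcr_fingerprint")) fps <- list(fps)
  for (f in fps[-1L]) check_fp_compatible(fps[[1L]], f)
  vals <- t(vapply(fps, function(f) f$values, fps[[1L]]$values))
  meta <- fp_metadata(fps[[1L]])
  tab <- data.frame(tcr_id = vapply(fps, function(f) f$tcr_id, character(1)),
                    vals, mode = meta$mode, C = meta$C, P = meta$P,
                    hydrogen_policy = meta$hydrogen_policy,
                    table_tag = meta$table_tag,
                    third_moment = meta$third_moment,
                    stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tcrfp fingerprints v",
                    as.character(utils::packageVersion("tcrfp"))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fingerprints written by [write_fingerprints()]
#'
#' @param path fingerprint table file.
#' @return list of `tcr_fingerprint` objects.
#' @export
read_fingerprints <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  vcols <- as.vector(outer(FP_STATS, LOOP_ORDER,
                           function(s, l) paste(l, s, sep = ".")))
  if (!all(vcols %in% names(tab))) stop("missing fingerprint value columns")
  lapply(seq_len(nrow(tab)), function(i) {
    values <- as.numeric(tab[i, vcols])
    names(values) <- vcols
    structure(
      list(tcr_id = tab$tcr_id[i], values = values, mode = tab$mode[i],
           C = tab$C[i], P = tab$P[i],
           hydrogen_policy = tab$hydrogen_policy[i],
           table_tag = tab$table_tag[i], third_moment = tab$third_moment[i]),
      class = "tcr_fingerprint"
    )
  })
}
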