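## seqsim: normalized BLOSUM62 sequence comparator over the six CDR loops.

#' Construct a CDR sequence set
#'
#' @param tcr_id identifier.
#' @param sequences named (or canonically ordered) character vector of the
#'   six CDR amino-acid strings, uppercase one-letter codes.
#' @param peptide optional cognate-peptide sequence label.
#' @return object of class `cdr_sequence_set`.
#' @export
as_cdr_sequence_set <- function(tcr_id, sequences, peptide = NULL) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences))) names(sequences) <- LOOP_ORDER
  if (!setequal(names(sequences), LOOP_ORDER) || length(sequences) != 6L) {
    stop("need exactly the six loops ", paste(LOOP_ORDER, collapse = ", "))
  }
  sequences <- sequences[LOOP_ORDER]
  if (any(!nzchar(sequences))) stop("empty CDR sequence")
  bad <- grepl(paste0("[^", paste(STANDARD_AA1, collapse = ""), "]"),
               sequences)
  if (any(bad)) {
    stop("illegal residue letters in loop(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  structure(list(tcr_id = as.character(tcr_id), sequences = sequences,
                 peptide = peptide),
            class = "cdr_sequence_set")
}

## the CDR sequences of an extracted structure as a sequence set
#' @rdname as_cdr_sequence_set
#' @param cdrs a [extract_cdrs()] result.
#' @export
cdr_sequences <- function(cdrs, peptide = NULL) {
  stopifnot(inherits(cdrs, "cdr_set"))
  as_cdr_sequence_set(cdrs$tcr_id, cdrs$sequences, peptide)
}

#' Global BLOSUM62 alignment score
#'
#' Optimal global (end gaps penalized) pairwise alignment score under the
#' BLOSUM62 matrix with affine gaps: the first residue of a gap costs
#' `|gap_open|`, each further residue `|gap_extend|` (defaults 3 and 1).
#' Raw scores can be negative.
#'
#' @param seqA,seqB non-empty amino-acid strings (uppercase one-letter).
#' @param gap_open,gap_extend gap penalties (sign is ignored).
#' @return raw alignment score.
#' @export
blosum62_score <- function(seqA, seqB, gap_open = -3, gap_extend = -1) {
  ok <- paste0("^[", paste(STANDARD_AA1, collapse = ""), "]+$")
  if (!grepl(ok, seqA) || !grepl(ok, seqB)) {
    stop("illegal residue letter (need non-empty standard one-letter codes)")
  }
  open <- abs(gap_open)
  ext <- abs(gap_extend)
  ## Biostrings charges open + L*ext for a gap of length L; the convention
  ## here is open + (L-1)*ext, hence the shifted opening penalty.
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = open - ext, gapExtension = ext, scoreOnly = TRUE
  )
}

## summed per-loop raw score between two sequence sets
cdr_blosum_sum <- function(a, b, gap_open = -3, gap_extend = -1) {
  sum(vapply(LOOP_ORDER, function(loop) {
    blosum62_score(a$sequences[[loop]], b$sequences[[loop]],
                   gap_open, gap_extend)
  }, numeric(1)))
}

#' Normalized CDR sequence similarity
#'
#' Aligns each of the six CDR loops separately (global BLOSUM62, affine
#' gaps), sums the raw scores, and normalizes to [0, 1] by the geometric mean
#' of the two self-scores with clamping at 0:
#' `max(0, S(A,B)) / sqrt(S(A,A) * S(B,B))`. Identical sequence sets score
#' exactly 1.
#'
#' @param tcrA,tcrB [as_cdr_sequence_set()] objects.
#' @param gap_open,gap_extend gap penalties (defaults -3 / -1).
#' @return similarity in [0, 1].
#' @export
tcr_sequence_similarity <- function(tcrA, tcrB, gap_open = -3,
                                    gap_extend = -1) {
  stopifnot(inherits(tcrA, "cdr_sequence_set"),
            inherits(tcrB, "cdr_sequence_set"))
  s_ab <- cdr_blosum_sum(tcrA, tcrB, gap_open, gap_extend)
  s_aa <- cdr_blosum_sum(tcrA, tcrA, gap_open, gap_extend)
  s_bb <- cdr_blosum_sum(tcrB, tcrB, gap_open, gap_extend)
  max(0, s_ab) / sqrt(s_aa * s_bb)
}

#' All-against-all CDR sequence similarity matrix
#'
#' @param seqsets list of >= 2 [as_cdr_sequence_set()] objects with unique
#'   ids.
#' @param ... passed to [tcr_sequence_similarity()].
#' @return symmetric similarity matrix with unit diagonal.
#' @export
pairwise_sequence_similarity <- function(seqsets, ...) {
  if (length(seqsets) < 2L) stop("need at least 2 sequence sets")
  ids <- vapply(seqsets, function(s) s$tcr_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate tcr_id(s)")
  n <- length(seqsets)
  sim <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- tcr_sequence_similarity(seqsets[[i]], seqsets[[j]], ...)
      sim[i, j] <- s
      sim[j, i] <- s
    }
  }
  sim
}

#' Read / write CDR sequence tables
#'
#' Delimited table with columns `tcr_id`, `cdr1a`, `cdr2a`, `cdr3a`, `cdr1b`,
#' `cdr2b`, `cdr3b` and optional `peptide`.
#'
#' @param path file path.
#' @return list of `cdr_sequence_set` objects.
#' @export
read_cdr_sequences <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  cols <- tolower(LOOP_ORDER)
  if (!all(c("tcr_id", cols) %in% names(tab))) {
    stop("sequence table must have columns tcr_id, ",
         paste(cols, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    seqs <- as.character(tab[i, cols])
    names(seqs) <- LOOP_ORDER
    as_cdr_sequence_set(tab$tcr_id[i], seqs,
                        if ("peptide" %in% names(tab)) tab$peptide[i])
  })
}

#' @rdname read_cdr_sequences
#' @param seqsets list of `cdr_sequence_set` objects.
#' @export
write_cdr_sequences <- function(seqsets, path) {
  tab <- do.call(rbind, lapply(seqsets, function(s) {
    row <- as.data.frame(as.list(s$sequences), stringsAsFactors = FALSE)
    names(row) <- tolower(LOOP_ORDER)
    cbind(data.frame(tcr_id = s$tcr_id, stringsAsFactors = FALSE), row,
          data.frame(peptide = if (is.null(s$peptide)) NA else s$peptide,
                     stringsAsFactors = FALSE))
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
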