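# Shared fixtures and independent oracles used across the suite.

# small labeled repertoire with fingerprints and similarity matrix
small_repertoire <- function(n_families = 2L, per_family = 3L, jitter = 0.3,
                             spread = 6, seed = 7L) {
  spec <- fixture_spec(n_families = n_families, tcrs_per_family = per_family,
                       jitter = jitter, family_spread = spread, seed = seed)
  rep <- make_repertoire(spec)
  fps <- lapply(rep$structures, fingerprint_structure,
                annotation = rep$annotation)
  sim <- pairwise_similarity(unname(fps))
  peptides <- stats::setNames(rep$labels$peptide, rep$labels$tcr_id)
  list(rep = rep, fps = fps, sim = sim, peptides = peptides,
       annotated = annotated_repertoire(sim, peptides))
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(structure, R, t = c(0, 0, 0)) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + t[1]
  at$y <- xyz[, 2] + t[2]
  at$z <- xyz[, 3] + t[3]
  as_tcr_structure(structure$tcr_id, at, structure$alpha_chain_id,
                   structure$beta_chain_id, structure$numbering_scheme)
}

# hand-rolled PDB ATOM/HETATM record (fixed columns)
pdb_record <- function(record = "ATOM", serial, name, alt = "", resname,
                       chain, resno, x, y, z, occ = 1, elem) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno, x, y, z, occ, 0,
          elem)
}

# minimal two-chain PDB text: 4 residues per chain (N, CA, C, O each)
toy_pdb_lines <- function() {
  lines <- character(0)
  serial <- 0L
  for (chain in c("A", "B")) {
    for (r in 1:4) {
      base <- c(r * 3, if (chain == "B") 8 else 0, r)
      for (a in c("N", "CA", "C", "O")) {
        serial <- serial + 1L
        off <- switch(a, N = c(-1, 0, 0), CA = c(0, 0, 0), C = c(1, 0, 0),
                      O = c(1, 1, 0))
        lines <- c(lines, pdb_record("ATOM", serial, a, "", "ALA", chain, r,
                                     base[1] + off[1], base[2] + off[2],
                                     base[3] + off[3],
                                     elem = substr(a, 1, 1)))
      }
    }
  }
  c(lines, "END")
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# independent affine-gap global alignment score by exhaustive recursion:
# a gap of length L costs |open| + (L - 1) * |ext|
enumerate_alignment_score <- function(a, b, sub, open = 3, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + sub[av[i], bv[j]], "m")
    }
    if (i <= length(av)) {
      rec(i + 1, j, score - if (prev == "a") ext else open, "a")
    }
    if (j <= length(bv)) {
      rec(i, j + 1, score - if (prev == "b") ext else open, "b")
    }
  }
  rec(1, 1, 0, "m")
  best
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Mann-Whitney AUC by direct concordant/discordant pair counting
mw_auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
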