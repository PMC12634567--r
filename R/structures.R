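## structures: PDB input, CDR extraction, canonical-frame superposition, RMSD.

#' Construct a TCR structure object
#'
#' Low-level constructor used by the PDB reader and the synthetic-structure
#' generator. A TCR structure holds the atom records of exactly one alpha and
#' one beta chain, IMGT-numbered.
#'
#' @param tcr_id identifier string.
#' @param atoms data frame with columns `chain_id`, `residue_number`,
#'   `insert` (optional, "" for none), `residue_name` (3-letter standard
#'   amino-acid code), `atom_name`, `element`, `x`, `y`, `z`.
#' @param alpha_chain_id,beta_chain_id chain identifiers of the alpha and
#'   beta chain.
#' @param numbering_scheme numbering tag; "imgt" is required for the
#'   conserved-residue QC filters.
#' @return an object of class `tcr_structure`.
#' @export
as_tcr_structure <- function(tcr_id, atoms, alpha_chain_id, beta_chain_id,
                             numbering_scheme = "imgt") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain_id", "residue_number", "residue_name", "atom_name",
            "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  for (ch in c(alpha_chain_id, beta_chain_id)) {
    if (!any(atoms$chain_id == ch)) stop("chain '", ch, "' not found")
  }
  if (!identical(sort(unique(atoms$chain_id)),
                 sort(c(alpha_chain_id, beta_chain_id)))) {
    stop("atoms must contain exactly the alpha and beta chains")
  }
  bad <- setdiff(unique(atoms$residue_name), STANDARD_AA3)
  if (length(bad)) stop("non-standard residue name(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(toupper(atoms$element)), KNOWN_ELEMENTS)
  if (length(bad)) stop("unknown element symbol(s): ",
                        paste(bad, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  atoms$residue_number <- as.integer(atoms$residue_number)
  ## canonical atom order: chain, residue number, insertion code, file order
  atoms$role <- ifelse(atoms$chain_id == alpha_chain_id, "alpha", "beta")
  ord <- order(match(atoms$role, CHAIN_ROLES), atoms$residue_number,
               atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(
    list(tcr_id = as.character(tcr_id), atoms = atoms,
         alpha_chain_id = alpha_chain_id, beta_chain_id = beta_chain_id,
         numbering_scheme = numbering_scheme,
         has_hydrogens = any(toupper(atoms$element) == "H")),
    class = "tcr_structure"
  )
}

#' @export
print.tcr_structure <- function(x, ...) {
  cat("TCR structure '", x$tcr_id, "': ", nrow(x$atoms), " atoms, chains ",
      x$alpha_chain_id, " (alpha) / ", x$beta_chain_id, " (beta), ",
      if (x$has_hydrogens) "with" else "without", " hydrogens\n", sep = "")
  invisible(x)
}

#' Read a paired-chain TCR structure from a PDB file
#'
#' Parses coordinate records with bio3d, keeps the two requested chains,
#' drops waters, hetero residues and non-standard amino acids, and resolves
#' alternate locations to the highest-occupancy conformer.
#'
#' @param pdb_source path to a PDB file.
#' @param alpha_chain_id,beta_chain_id chain identifiers of the alpha and
#'   beta chain; both must be present.
#' @param tcr_id identifier to attach; defaults to the file base name.
#' @param numbering_scheme numbering tag carried on the object ("imgt"
#'   assumed; the QC filters require it).
#' @return a [as_tcr_structure()] object.
#' @export
read_tcr_structure <- function(pdb_source, alpha_chain_id, beta_chain_id,
                               tcr_id = NULL, numbering_scheme = "imgt") {
  if (!file.exists(pdb_source)) stop("PDB file not found: ", pdb_source)
  if (is.null(tcr_id)) {
    tcr_id <- tools::file_path_sans_ext(basename(pdb_source))
  }
  pdb <- bio3d::read.pdb(pdb_source, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain %in% c(alpha_chain_id, beta_chain_id) &
             at$resid %in% STANDARD_AA3, , drop = FALSE]
  for (ch in c(alpha_chain_id, beta_chain_id)) {
    if (!any(at$chain == ch)) {
      stop("chain '", ch, "' not found in ", pdb_source)
    }
  }
  ## alternate locations: keep the highest-occupancy record per atom
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)
  atoms <- data.frame(
    chain_id = at$chain, residue_number = at$resno, insert = ins,
    residue_name = at$resid, atom_name = at$elety, element = elem,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  as_tcr_structure(tcr_id, atoms, alpha_chain_id, beta_chain_id,
                   numbering_scheme)
}

#' Extract the six CDR loops from a TCR structure
#'
#' Slices the annotated inclusive IMGT residue-number ranges out of the
#' structure. Residues missing inside a range are skipped silently (partial
#' models are common); a range that resolves to zero residues is an error.
#'
#' @param structure a [as_tcr_structure()] object.
#' @param annotation a [as_cdr_annotation()] table; defaults to the standard
#'   IMGT ranges on the structure's two chains.
#' @return an object of class `cdr_set`: per-loop atom tables and one-letter
#'   loop sequences in the fixed order CDR1a, CDR2a, CDR3a, CDR1b, CDR2b,
#'   CDR3b.
#' @export
extract_cdrs <- function(structure, annotation = NULL) {
  stopifnot(inherits(structure, "tcr_structure"))
  if (is.null(annotation)) {
    annotation <- default_cdr_annotation(structure$alpha_chain_id,
                                         structure$beta_chain_id)
  }
  annotation <- as_cdr_annotation(annotation)
  at <- structure$atoms
  loops <- list()
  seqs <- character(0)
  for (i in seq_len(nrow(annotation))) {
    loop <- annotation$loop[i]
    ch <- annotation$chain_id[i]
    if (!any(at$chain_id == ch)) {
      stop("loop ", loop, ": chain '", ch, "' not present in structure '",
           structure$tcr_id, "'")
    }
    sel <- at$chain_id == ch & at$residue_number >= annotation$start[i] &
      at$residue_number <= annotation$end[i]
    sub <- at[sel, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("loop ", loop, " is empty after resolving range ",
           annotation$start[i], "-", annotation$end[i], " on chain ", ch,
           " of '", structure$tcr_id, "'")
    }
    rownames(sub) <- NULL
    res_key <- paste(sub$residue_number, sub$insert)
    res_first <- !duplicated(res_key)
    loops[[loop]] <- sub
    seqs[loop] <- paste(aa3_to_1(sub$residue_name[res_first]), collapse = "")
  }
  structure(
    list(tcr_id = structure$tcr_id, loops = loops, sequences = seqs,
         has_hydrogens = structure$has_hydrogens, annotation = annotation),
    class = "cdr_set"
  )
}

#' @export
print.cdr_set <- function(x, ...) {
  cat("CDR set for '", x$tcr_id, "':\n", sep = "")
  for (loop in names(x$loops)) {
    cat(sprintf("  %-6s %-18s %d atoms\n", loop, x$sequences[loop],
                nrow(x$loops[[loop]])))
  }
  invisible(x)
}

## xyz coordinate matrix (n x 3) of an atom table / structure.
atoms_xyz <- function(x) {
  if (inherits(x, "tcr_structure")) x <- x$atoms
  as.matrix(x[, c("x", "y", "z")])
}

#' Superpose a TCR structure into its canonical principal-axis frame
#'
#' Centers all atoms (unit masses) at the origin and rotates the structure so
#' its principal axes of the coordinate covariance, ordered by descending
#' eigenvalue, lie along x, y, z. The residual axis-sign ambiguity is fixed
#' deterministically: the first two axes are flipped, if needed, so the CA
#' atom of the lowest-numbered alpha-chain CDR1 residue has non-negative
#' first and second coordinates, and the third axis keeps the rotation
#' proper (determinant +1). The transform is rigid, so the result is
#' invariant to any rigid motion of the input.
#'
#' @param structure a [as_tcr_structure()] object with at least 3
#'   non-collinear atoms.
#' @param cdr1a_range inclusive IMGT range used to locate the sign-reference
#'   CA on the alpha chain (default `c(27, 38)`).
#' @return the structure with transformed coordinates.
#' @export
principal_axis_superpose <- function(structure, cdr1a_range = c(27L, 38L)) {
  stopifnot(inherits(structure, "tcr_structure"))
  xyz <- atoms_xyz(structure)
  if (nrow(xyz) < 3L) stop("need at least 3 atoms")
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2L, ctr)
  cv <- crossprod(xc) / nrow(xc)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= max(eg$values[1], 1) * 1e-10) {
    stop("degenerate inertia tensor: atoms are (near-)collinear")
  }
  v <- eg$vectors  # columns ordered by decreasing eigenvalue
  rot <- xc %*% v
  at <- structure$atoms
  ref <- which(at$role == "alpha" & at$atom_name == "CA" &
                 at$residue_number >= cdr1a_range[1] &
                 at$residue_number <= cdr1a_range[2])
  if (length(ref) == 0L) ref <- which(at$role == "alpha" & at$atom_name == "CA")
  if (length(ref) == 0L) ref <- 1L
  ref <- ref[1L]
  sgn <- c(if (rot[ref, 1] < 0) -1 else 1,
           if (rot[ref, 2] < 0) -1 else 1, 1)
  ## keep the rotation proper
  sgn[3] <- sgn[1] * sgn[2] * sign(det(v))
  rot <- sweep(rot, 2L, sgn, `*`)
  at$x <- rot[, 1]
  at$y <- rot[, 2]
  at$z <- rot[, 3]
  structure$atoms <- at
  structure
}

#' Minimum RMSD between two matched atom sets
#'
#' Root-mean-square deviation in Angstrom after optimal rigid (Kabsch)
#' superposition, as used to compare structural models. Atom sets must have
#' equal counts and matched order.
#'
#' @param setA,setB n x 3 coordinate matrices (or atom tables / structures,
#'   from which xyz coordinates are taken in canonical order).
#' @return RMSD in Angstrom.
#' @export
tcr_rmsd <- function(setA, setB) {
  a <- if (is.matrix(setA)) setA else atoms_xyz(setA)
  b <- if (is.matrix(setB)) setB else atoms_xyz(setB)
  if (nrow(a) != nrow(b)) {
    stop("atom count mismatch: ", nrow(a), " vs ", nrow(b))
  }
  bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
}
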