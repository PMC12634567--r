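## synthetic_fixtures: TCR-like structures with controllable families.

## CA template positions of the framework residues (per chain); conserved
## QC residues CYS23 / LEU89 / CYS104 / TRP118 are always present.
FRAMEWORK_TEMPLATE <- data.frame(
  residue_number = c(23L, 40L, 75L, 89L, 104L, 118L),
  residue_name = c("CYS", "VAL", "SER", "LEU", "CYS", "TRP"),
  x = c(0, 4, 8, 9, 5.5, 10),
  y = c(0, -3, -1, 2, 0.5, 6),
  z = c(0, 2, -2, 1, 0.5, 2),
  stringsAsFactors = FALSE
)

## loop anchor centers (alpha chain); beta chain is the same shifted by
## BETA_OFFSET
LOOP_CENTERS <- matrix(c(-4, 9, 3,
                         2, 10, -2,
                         0, 13, 1), 3L, 3L, byrow = TRUE,
                       dimnames = list(c("CDR1", "CDR2", "CDR3"),
                                       c("x", "y", "z")))
BETA_OFFSET <- c(1.5, -4, 10)

## per-residue heavy-atom offsets from the CA position
RESIDUE_ATOM_OFFSETS <- list(
  N = c(-1.2, 0.6, 0.2), CA = c(0, 0, 0), C = c(1.2, 0.6, -0.1),
  O = c(1.5, 1.7, 0.3), CB = c(-0.2, -1.0, 1.0)
)

#' Specification of a synthetic TCR repertoire
#'
#' Defines the study conditions the generator emulates: structural
#' "families" of TCRs sharing a specificity label, with identical loop
#' conformations and sequences up to a per-member coordinate jitter, and
#' family-specific loop placements separated by `family_spread`.
#'
#' @param n_families number of specificity families (>= 1).
#' @param tcrs_per_family members per family (>= 1).
#' @param loop_lengths residue counts of the six loops in canonical order
#'   (default 6, 6, 13, 6, 6, 13; capped by the IMGT annotation ranges
#'   12/10/13).
#' @param jitter within-family per-atom Gaussian coordinate noise, Angstrom
#'   (default 0.3).
#' @param family_spread between-family displacement of each loop's
#'   placement, Angstrom (default 6).
#' @param peptides optional cognate 9-mer per family (default: generated
#'   from the seed).
#' @param seed RNG seed; fixtures are bit-reproducible from it.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_families = 2L, tcrs_per_family = 5L,
                         loop_lengths = c(6L, 6L, 13L, 6L, 6L, 13L),
                         jitter = 0.3, family_spread = 6, peptides = NULL,
                         seed = 42L) {
  stopifnot(is_count(n_families), is_count(tcrs_per_family),
            length(loop_lengths) == 6L, all(loop_lengths >= 1),
            jitter >= 0, family_spread >= 0)
  caps <- c(12L, 10L, 13L, 12L, 10L, 13L)
  if (any(loop_lengths > caps)) {
    stop("loop lengths exceed the default IMGT ranges (max ",
         paste(caps, collapse = "/"), ")")
  }
  if (!is.null(peptides) && length(peptides) != n_families) {
    stop("need one peptide per family")
  }
  structure(list(n_families = as.integer(n_families),
                 tcrs_per_family = as.integer(tcrs_per_family),
                 loop_lengths = stats::setNames(as.integer(loop_lengths),
                                                LOOP_ORDER),
                 jitter = jitter, family_spread = family_spread,
                 peptides = peptides, seed = as.integer(seed)),
            class = "fixture_spec")
}

## family-level attributes (loop directions, sequences, peptide), all drawn
## from the family seed so any member can be rebuilt standalone
family_attributes <- function(spec, family) {
  with_seed(derive_seed(spec$seed, family), {
    dirs <- lapply(LOOP_ORDER, function(l) {
      v <- stats::rnorm(3L)
      v / sqrt(sum(v^2))
    })
    names(dirs) <- LOOP_ORDER
    seqs <- vapply(LOOP_ORDER, function(l) {
      paste(sample(STANDARD_AA1, spec$loop_lengths[[l]], replace = TRUE),
            collapse = "")
    }, character(1))
    peptide <- if (!is.null(spec$peptides)) {
      spec$peptides[family]
    } else {
      paste(sample(STANDARD_AA1, 9L, replace = TRUE), collapse = "")
    }
    list(dirs = dirs, sequences = seqs, peptide = peptide)
  })
}

## heavy atoms of one residue around a CA position
residue_atoms <- function(resno, resname, ca) {
  atoms <- c("N", "CA", "C", "O", if (resname != "GLY") "CB")
  do.call(rbind, lapply(atoms, function(a) {
    p <- ca + RESIDUE_ATOM_OFFSETS[[a]]
    data.frame(residue_number = resno, residue_name = resname, atom_name = a,
               element = substr(a, 1, 1), x = p[1], y = p[2], z = p[3],
               stringsAsFactors = FALSE)
  }))
}

## CA path of a loop: a semicircular arc at its (family-shifted) center
loop_ca_path <- function(center, n) {
  radius <- max(2, 3.8 * n / pi)
  theta <- seq(0, pi, length.out = max(n, 2L))[seq_len(n)]
  cbind(center[1] + radius * cos(theta),
        center[2] + radius * sin(theta) * 0.6,
        center[3] + 1.5 * sin(2 * theta))
}

#' Generate one synthetic TCR structure
#'
#' Builds a two-chain TCR-like structure on a fixed idealized framework
#' template (conserved residues CYS23, LEU89, CYS104, TRP118 at template
#' positions on both chains) with six CDR loops whose placement and
#' sequences are family-specific and whose coordinates get per-member
#' Gaussian jitter. The template is hand-built, not derived from any
#' deposited structure.
#'
#' @param spec a [fixture_spec()].
#' @param family family index (1-based).
#' @param index member index within the family.
#' @return list with `structure` ([as_tcr_structure()]), `annotation`
#'   (default IMGT ranges), `sequences` ([as_cdr_sequence_set()] including
#'   the cognate peptide) and `peptide`.
#' @export
make_toy_tcr <- function(spec, family, index) {
  stopifnot(inherits(spec, "fixture_spec"),
            family >= 1, family <= spec$n_families, index >= 1)
  fam <- family_attributes(spec, family)
  ann <- default_cdr_annotation("A", "B")
  tcr_id <- sprintf("F%02d_T%02d", family, index)
  chains <- list(alpha = list(id = "A", offset = c(0, 0, 0)),
                 beta = list(id = "B", offset = BETA_OFFSET))
  atoms <- list()
  for (role in names(chains)) {
    off <- chains[[role]]$offset
    fw <- FRAMEWORK_TEMPLATE
    for (i in seq_len(nrow(fw))) {
      atoms[[length(atoms) + 1L]] <- cbind(
        residue_atoms(fw$residue_number[i], fw$residue_name[i],
                      c(fw$x[i], fw$y[i], fw$z[i]) + off),
        chain_id = chains[[role]]$id
      )
    }
    for (k in 1:3) {
      loop <- LOOP_ORDER[k + if (role == "beta") 3L else 0L]
      n <- spec$loop_lengths[[loop]]
      center <- LOOP_CENTERS[k, ] + off +
        spec$family_spread * fam$dirs[[loop]]
      path <- loop_ca_path(center, n)
      seq1 <- strsplit(fam$sequences[[loop]], "")[[1]]
      start <- ann[loop, "start"]
      for (j in seq_len(n)) {
        res3 <- STANDARD_AA3[match(seq1[j], STANDARD_AA1)]
        atoms[[length(atoms) + 1L]] <- cbind(
          residue_atoms(start + j - 1L, res3, path[j, ]),
          chain_id = chains[[role]]$id
        )
      }
    }
  }
  at <- do.call(rbind, atoms)
  if (spec$jitter > 0) {
    noise <- with_seed(derive_seed(spec$seed, family, index), {
      matrix(stats::rnorm(3L * nrow(at), sd = spec$jitter), nrow(at), 3L)
    })
    at$x <- at$x + noise[, 1]
    at$y <- at$y + noise[, 2]
    at$z <- at$z + noise[, 3]
  }
  struct <- as_tcr_structure(tcr_id, at, "A", "B")
  seqs <- as_cdr_sequence_set(tcr_id, fam$sequences, fam$peptide)
  list(structure = struct, annotation = ann, sequences = seqs,
       peptide = fam$peptide)
}

#' Generate a labeled synthetic repertoire
#'
#' @param spec a [fixture_spec()].
#' @return list of class `synthetic_repertoire`: `structures` (named list),
#'   `annotation`, `sequence_sets`, `labels` (data frame `tcr_id`,
#'   `peptide`) and the `spec`.
#' @export
make_repertoire <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  structures <- list()
  seqsets <- list()
  labels <- list()
  for (f in seq_len(spec$n_families)) {
    for (i in seq_len(spec$tcrs_per_family)) {
      tcr <- make_toy_tcr(spec, f, i)
      id <- tcr$structure$tcr_id
      structures[[id]] <- tcr$structure
      seqsets[[id]] <- tcr$sequences
      labels[[id]] <- data.frame(tcr_id = id, peptide = tcr$peptide,
                                 stringsAsFactors = FALSE)
    }
  }
  structure(list(structures = structures,
                 annotation = default_cdr_annotation("A", "B"),
                 sequence_sets = seqsets,
                 labels = do.call(rbind, c(labels, make.row.names = FALSE)),
                 spec = spec),
            class = "synthetic_repertoire")
}

#' Corrupt a structural model for QC testing
#'
#' Mode `"displace_segment"` rigidly moves the beta-chain segment from
#' `segment_start` onwards (it contains the conserved TRP118) by
#' `displacement`, emulating a badly modelled beta-chain fragment: with the
#' default 15 Angstrom shift at least one conserved-residue distance leaves
#' its calibrated mean +/- 4 SD band. The corruption is exactly reversible
#' by the inverse vector.
#'
#' @param structure a [as_tcr_structure()] object containing the conserved
#'   residues.
#' @param mode corruption mode; only `"displace_segment"` is defined.
#' @param displacement 3-vector in Angstrom (default `c(15, 0, 0)`).
#' @param segment_start first beta-chain residue number moved (default 118).
#' @return the corrupted structure.
#' @export
corrupt_model <- function(structure, mode = "displace_segment",
                          displacement = c(15, 0, 0),
                          segment_start = 118L) {
  stopifnot(inherits(structure, "tcr_structure"))
  if (!identical(mode, "displace_segment")) {
    stop("unknown corruption mode: ", mode)
  }
  if (length(displacement) != 3L || !all(is.finite(displacement))) {
    stop("displacement must be a finite 3-vector")
  }
  at <- structure$atoms
  sel <- at$role == "beta" & at$residue_number >= segment_start
  if (!any(sel)) stop("no beta-chain residues at or after ", segment_start)
  at$x[sel] <- at$x[sel] + displacement[1]
  at$y[sel] <- at$y[sel] + displacement[2]
  at$z[sel] <- at$z[sel] + displacement[3]
  structure$atoms <- at
  structure
}

#' Write a synthetic repertoire to disk
#'
#' Emits one PDB file per TCR plus the annotation, label and CDR-sequence
#' tables, in the formats the command-line interface consumes.
#'
#' @param rep a [make_repertoire()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_repertoire <- function(rep, dir) {
  stopifnot(inherits(rep, "synthetic_repertoire"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(rep$structures)) {
    write_structure_pdb(rep$structures[[id]],
                        file.path(dir, paste0(id, ".pdb")))
  }
  ann <- rep$annotation
  ann$tcr_id <- "*"
  utils::write.table(ann[, c("tcr_id", "loop", "chain_id", "start", "end")],
                     file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rep$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_cdr_sequences(rep$sequence_sets, file.path(dir, "sequences.tsv"))
  invisible(dir)
}

#' Write a TCR structure as a PDB file
#'
#' @param structure a [as_tcr_structure()] object.
#' @param path output PDB path.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "tcr_structure"))
  at <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$residue_number, resid = at$residue_name,
    eleno = seq_len(nrow(at)), elety = at$atom_name, chain = at$chain_id,
    insert = ifelse(at$insert == "", NA, at$insert),
    o = rep(1, nrow(at)), b = rep(0, nrow(at)), elesy = at$element
  )
  invisible(path)
}
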