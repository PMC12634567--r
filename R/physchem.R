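## physchem: per-atom partial charges and Wildman-Crippen logP contributions.

#' Read a per-atom property table
#'
#' The table maps (residue, atom name) to a partial charge (e) and an atomic
#' Wildman-Crippen logP contribution. The bundled default was computed once
#' on Gly-X-Gly tripeptide templates (physiological protonation for Asp, Glu,
#' Lys, Arg) and renormalized so every residue sums exactly to its formal
#' charge; its provenance tag is `gasteiger-gxg-v1`. The tag is recorded in
#' every fingerprint so that fingerprints computed under different tables are
#' never compared.
#'
#' @param path tab-delimited file with columns `residue`, `atom`, `element`,
#'   `charge`, `logp`; `#` lines are comments. Default: the bundled table.
#' @param tag provenance tag; parsed from a `tag:` comment if present.
#' @return a `property_table` data frame with attribute `tag`.
#' @export
read_property_table <- function(path = NULL, tag = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "property_table_gasteiger.tsv",
                        package = "tcrfp", mustWork = TRUE)
  }
  hdr <- readLines(path, n = 10L)
  if (is.null(tag)) {
    m <- regmatches(hdr, regexpr("tag: *[A-Za-z0-9._-]+", hdr))
    tag <- if (length(m)) sub("tag: *", "", m[[1]]) else "untagged"
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("residue", "atom", "charge", "logp")
  if (!all(need %in% names(tab))) {
    stop("property table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(paste(tab$residue, tab$atom))) {
    stop("duplicated (residue, atom) entries in property table")
  }
  attr(tab, "tag") <- tag
  class(tab) <- c("property_table", "data.frame")
  tab
}

## default table, cached per session
property_table_cache <- new.env(parent = emptyenv())
default_property_table <- function() {
  if (is.null(property_table_cache$tab)) {
    property_table_cache$tab <- read_property_table()
  }
  property_table_cache$tab
}

#' Assign weighted charge and lipophilicity to CDR atoms
#'
#' Adds the fourth and fifth fingerprint dimensions to every atom of a CDR
#' set: the weighted partial charge `q_w = C * charge` and the weighted
#' lipophilicity `l_w = P * logp`, with charge and logP looked up in the
#' property table by (residue, atom name). Default weights are C = 25 and
#' P = 4.
#'
#' Structures without hydrogens are processed heavy-atom-only and flagged
#' (`hydrogen_policy = "heavy-only"`); fingerprints with different hydrogen
#' policies refuse comparison.
#'
#' @param cdrs a [extract_cdrs()] result.
#' @param table a [read_property_table()] table; default bundled.
#' @param C,P positive weights for charge and lipophilicity.
#' @param unmapped policy for atoms absent from the table: `"zero"` (default;
#'   zero contributions, one summary warning) or `"strict"` (error).
#' @return the CDR set with per-atom `charge`, `logp`, `q_w`, `l_w` columns
#'   and metadata fields `C`, `P`, `table_tag`, `hydrogen_policy`.
#' @export
assign_properties <- function(cdrs, table = NULL, C = 25, P = 4,
                              unmapped = c("zero", "strict")) {
  stopifnot(inherits(cdrs, "cdr_set"))
  unmapped <- match.arg(unmapped)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop("charge weight C must be a single positive number")
  }
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P <= 0) {
    stop("lipophilicity weight P must be a single positive number")
  }
  if (is.null(table)) table <- default_property_table()
  key <- paste(table$residue, table$atom)
  missed <- character(0)
  for (loop in names(cdrs$loops)) {
    at <- cdrs$loops[[loop]]
    idx <- match(paste(at$residue_name, at$atom_name), key)
    if (anyNA(idx)) {
      bad <- unique(paste(at$residue_name, at$atom_name)[is.na(idx)])
      if (unmapped == "strict") {
        stop("atoms missing from property table: ",
             paste(bad, collapse = ", "))
      }
      missed <- c(missed, bad)
    }
    at$charge <- ifelse(is.na(idx), 0, table$charge[idx])
    at$logp <- ifelse(is.na(idx), 0, table$logp[idx])
    at$q_w <- C * at$charge
    at$l_w <- P * at$logp
    cdrs$loops[[loop]] <- at
  }
  if (length(missed)) {
    warning(length(unique(missed)),
            " atom type(s) not in property table, contributions set to 0: ",
            paste(unique(missed), collapse = ", "))
  }
  cdrs$C <- C
  cdrs$P <- P
  cdrs$table_tag <- attr(table, "tag")
  cdrs$hydrogen_policy <- if (cdrs$has_hydrogens) "all-atom" else "heavy-only"
  cdrs
}

## 5D coordinate matrix (x, y, z, q_w, l_w) of all atoms pooled across loops.
pooled_atoms_5d <- function(cdrs) {
  stopifnot(inherits(cdrs, "cdr_set"))
  if (is.null(cdrs$C)) {
    stop("CDR set has no assigned properties; call assign_properties() first")
  }
  do.call(rbind, lapply(cdrs$loops, function(at) {
    as.matrix(at[, c("x", "y", "z", "q_w", "l_w")])
  }))
}
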