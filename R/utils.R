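#' @keywords internal
"_PACKAGE"

## Fixed loop order used everywhere a fingerprint or annotation is laid out.
LOOP_ORDER <- c("CDR1a", "CDR2a", "CDR3a", "CDR1b", "CDR2b", "CDR3b")

## Chain role tags.
CHAIN_ROLES <- c("alpha", "beta")

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
STANDARD_AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V")
names(STANDARD_AA1) <- STANDARD_AA3

KNOWN_ELEMENTS <- c("H", "C", "N", "O", "S", "SE", "P")

aa3_to_1 <- function(res3) {
  out <- STANDARD_AA1[res3]
  if (anyNA(out)) {
    stop("non-standard residue name(s): ",
         paste(unique(res3[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Default IMGT CDR residue ranges
#'
#' Inclusive IMGT residue-number ranges used to annotate the six CDR loops
#' when no explicit annotation table is supplied: 27-38 (CDR1), 56-65 (CDR2)
#' and 105-117 (CDR3) on each chain.
#'
#' @param alpha_chain_id,beta_chain_id chain identifiers to write into the
#'   annotation (defaults "A" and "B").
#' @return a `cdr_annotation` data frame with columns `loop`, `chain_id`,
#'   `start`, `end`.
#' @export
default_cdr_annotation <- function(alpha_chain_id = "A", beta_chain_id = "B") {
  ann <- data.frame(
    loop = LOOP_ORDER,
    chain_id = rep(c(alpha_chain_id, beta_chain_id), each = 3L),
    start = rep(c(27L, 56L, 105L), 2L),
    end = rep(c(38L, 65L, 117L), 2L),
    stringsAsFactors = FALSE
  )
  as_cdr_annotation(ann)
}

#' Validate a CDR annotation table
#'
#' @param x data frame with columns `loop`, `chain_id`, `start`, `end`; one
#'   row per loop, all six of CDR1a..CDR3b present.
#' @return the validated annotation, rows ordered canonically, with class
#'   `cdr_annotation`.
#' @export
as_cdr_annotation <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("loop", "chain_id", "start", "end")
  if (!all(need %in% names(x))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(x$loop, LOOP_ORDER) || nrow(x) != 6L) {
    stop("annotation must contain exactly the six loops ",
         paste(LOOP_ORDER, collapse = ", "))
  }
  x <- x[match(LOOP_ORDER, x$loop), need]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(x$end < x$start)) stop("annotation ranges must satisfy start <= end")
  for (ch in unique(x$chain_id)) {
    r <- x[x$chain_id == ch, ]
    if (nrow(r) > 1L) {
      r <- r[order(r$start), ]
      if (any(r$start[-1L] <= r$end[-nrow(r)])) {
        stop("overlapping CDR ranges on chain ", ch)
      }
    }
  }
  rownames(x) <- x$loop
  class(x) <- c("cdr_annotation", "data.frame")
  x
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Mix integers into a derived sub-seed (stays within 32-bit range).
derive_seed <- function(...) {
  v <- as.numeric(c(...))
  s <- 0
  for (x in v) s <- (s * 69069 + x + 1) %% 2147483629
  as.integer(s)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 1
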