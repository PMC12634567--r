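## model_qc: conserved-residue distance filters for TCR structural models.

CONSERVED_RESIDUES <- c(CYS = 23L, LEU = 89L, CYS2 = 104L, TRP = 118L)

#' Default conserved-residue distance definitions
#'
#' Distance filters are defined between CA atoms of the four conserved
#' framework residues CYS23, LEU89, CYS104 and TRP118 (IMGT numbering). The
#' default definition list evaluates all six unordered pairs of the four
#' residues on each chain (12 distances); the exact published pair list is
#' configurable, so users may supply their own subset.
#'
#' @return data frame with columns `name`, `chain` ("alpha"/"beta"), `res_i`,
#'   `res_j`.
#' @export
default_filter_definitions <- function() {
  res <- unname(CONSERVED_RESIDUES)
  pairs <- t(utils::combn(res, 2L))
  defs <- do.call(rbind, lapply(CHAIN_ROLES, function(ch) {
    data.frame(name = sprintf("%s_Ca%d_Ca%d", ch, pairs[, 1], pairs[, 2]),
               chain = ch, res_i = pairs[, 1], res_j = pairs[, 2],
               stringsAsFactors = FALSE)
  }))
  rownames(defs) <- NULL
  defs
}

## CA coordinate of one residue, or NULL if absent
ca_coord <- function(structure, role, resno) {
  at <- structure$atoms
  i <- which(at$role == role & at$residue_number == resno &
               at$atom_name == "CA")
  if (length(i) == 0L) return(NULL)
  c(at$x[i[1L]], at$y[i[1L]], at$z[i[1L]])
}

#' Measure conserved-residue CA-CA distances
#'
#' @param structure an IMGT-numbered [as_tcr_structure()] object.
#' @param definitions distance definition table
#'   ([default_filter_definitions()] by default, or the `definitions` of a
#'   calibrated `filter_spec`).
#' @return named numeric vector of Euclidean distances in Angstrom.
#'   A referenced residue missing its CA raises an error with reason
#'   "unmeasurable".
#' @export
measure_filter_distances <- function(structure, definitions = NULL) {
  stopifnot(inherits(structure, "tcr_structure"))
  if (!identical(structure$numbering_scheme, "imgt")) {
    stop("filter distances require IMGT numbering")
  }
  if (is.null(definitions)) definitions <- default_filter_definitions()
  if (inherits(definitions, "filter_spec")) {
    definitions <- definitions$definitions
  }
  d <- numeric(nrow(definitions))
  names(d) <- definitions$name
  for (k in seq_len(nrow(definitions))) {
    a <- ca_coord(structure, definitions$chain[k], definitions$res_i[k])
    b <- ca_coord(structure, definitions$chain[k], definitions$res_j[k])
    if (is.null(a) || is.null(b)) {
      stop("unmeasurable: conserved residue ",
           if (is.null(a)) definitions$res_i[k] else definitions$res_j[k],
           " (", definitions$chain[k], " chain) has no CA in '",
           structure$tcr_id, "'")
    }
    d[k] <- sqrt(sum((a - b)^2))
  }
  d
}

#' Calibrate distance filters on reference structures
#'
#' For every distance definition, computes the mean and (population) standard
#' deviation over the reference structures and sets the accepted range to
#' mean +/- 4 SD. References on which a distance cannot be measured are
#' excluded with a warning.
#'
#' @param references list of >= 2 measurable [as_tcr_structure()] objects.
#' @param definitions distance definition table (default
#'   [default_filter_definitions()]).
#' @return an object of class `filter_spec`: the definitions augmented with
#'   `mean`, `sd`, `low`, `high` columns and the number of references used.
#' @export
calibrate_filters <- function(references, definitions = NULL) {
  if (is.null(definitions)) definitions <- default_filter_definitions()
  meas <- list()
  for (s in references) {
    d <- tryCatch(measure_filter_distances(s, definitions),
                  error = function(e) e)
    if (inherits(d, "error")) {
      warning("reference '", s$tcr_id, "' excluded from calibration: ",
              conditionMessage(d))
    } else {
      meas[[length(meas) + 1L]] <- d
    }
  }
  if (length(meas) < 2L) {
    stop("need at least 2 measurable reference structures (",
         length(meas), " usable)")
  }
  m <- do.call(rbind, meas)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  spec <- definitions
  spec$mean <- unname(mu)
  spec$sd <- unname(sd_pop)
  spec$low <- spec$mean - 4 * spec$sd
  spec$high <- spec$mean + 4 * spec$sd
  structure(list(definitions = definitions, table = spec,
                 n_references = length(meas)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("Distance filter spec calibrated on", x$n_references, "references:\n")
  print(cbind(x$table["name"], round(x$table[c("mean", "sd", "low", "high")],
                                     2)))
  invisible(x)
}

#' Apply calibrated distance filters to a model
#'
#' A model passes only if every measured distance lies inside its accepted
#' `[low, high]` band (inclusive). A model on which a distance cannot be
#' measured is rejected with reason "unmeasurable".
#'
#' @param structure model to check.
#' @param spec a [calibrate_filters()] result (or an equivalent table read
#'   with [read_filter_spec()]).
#' @return list with elements `pass` (logical), `reason` ("ok", "violations"
#'   or "unmeasurable") and `report` (per-filter table: distance, bounds,
#'   `ok`).
#' @export
apply_filters <- function(structure, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  d <- tryCatch(measure_filter_distances(structure, spec$definitions),
                error = function(e) e)
  if (inherits(d, "error")) {
    return(list(pass = FALSE, reason = "unmeasurable",
                message = conditionMessage(d), report = NULL))
  }
  rep <- spec$table
  rep$distance <- unname(d[rep$name])
  rep$ok <- rep$distance >= rep$low & rep$distance <= rep$high
  list(pass = all(rep$ok),
       reason = if (all(rep$ok)) "ok" else "violations",
       report = rep[, c("name", "chain", "res_i", "res_j", "distance",
                        "low", "high", "ok")])
}

#' Write / read a filter spec as delimited text
#'
#' @param spec a `filter_spec`.
#' @param path file path.
#' @export
write_filter_spec <- function(spec, path) {
  stopifnot(inherits(spec, "filter_spec"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tcrfp filter spec, calibrated on ", spec$n_references,
                    " references"), con)
  utils::write.table(spec$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_filter_spec
#' @export
read_filter_spec <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "chain", "res_i", "res_j", "mean", "sd", "low", "high")
  if (!all(need %in% names(tab))) {
    stop("filter spec must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$low > tab$high)) stop("invalid filter bounds (low > high)")
  hdr <- readLines(path, n = 1L)
  n_ref <- suppressWarnings(
    as.integer(sub(".*calibrated on ([0-9]+) references.*", "\\1", hdr))
  )
  structure(list(definitions = tab[, c("name", "chain", "res_i", "res_j")],
                 table = tab,
                 n_references = if (is.na(n_ref)) NA_integer_ else n_ref),
            class = "filter_spec")
}
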