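#' Sample-by-metabolite intensity matrix
#'
#' The central data container of the package: a samples x metabolites matrix
#' of peak intensities together with an explicit missingness mask (missing =
#' below the limit of detection) and a processing-state flag. The state moves
#' through \code{"raw"} (positive intensities, possibly with missing entries),
#' \code{"imputed_scaled"} (missing entries imputed with the per-metabolite
#' minimum, each metabolite divided by its median) and \code{"log"} (natural
#' log of the scaled values). The mask is carried along unchanged so that the
#' provenance of imputed cells is never lost.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns,
#'   with row and column names. Under state \code{"raw"} all non-missing
#'   entries must be strictly positive.
#' @param missing logical matrix of the same dimension marking entries below
#'   the limit of detection; \code{NULL} means "derive from \code{NA}s in
#'   \code{values}".
#' @param state one of \code{"raw"}, \code{"imputed_scaled"}, \code{"log"}.
#'
#' @return An object of class \code{metab_matrix}: a list with elements
#'   \code{values}, \code{missing} and \code{state}.
#' @export
metab_matrix <- function(values, missing = NULL, state = c("raw", "imputed_scaled", "log")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values) > 0)
    colnames(values) <- paste0("M", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate metabolite ids")
  if (is.null(missing)) {
    missing <- is.na(values)
  }
  if (!identical(dim(missing), dim(values)))
    stop("'missing' mask must have the same dimension as 'values'")
  dimnames(missing) <- dimnames(values)
  if (state == "raw") {
    obs <- values[!missing]
    if (any(!is.na(obs) & obs <= 0))
      stop("raw intensities must be strictly positive where observed")
  } else {
    if (any(missing & is.na(values)))
      stop(sprintf("state '%s' requires imputed (finite) values everywhere", state))
    if (any(!is.finite(values)))
      stop("non-finite values in a processed matrix")
  }
  structure(list(values = values, missing = missing, state = state),
            class = "metab_matrix")
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("metab_matrix: %d samples x %d metabolites [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  missing (below LOD): %d cells (%.1f%%)\n",
              sum(x$missing), 100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.metab_matrix <- function(x) dim(x$values)

#' Sample and metabolite identifiers
#' @param x a \code{metab_matrix}
#' @return character vector of ids
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
metabolite_ids <- function(x) colnames(x$values)

# internal: subset metabolites (columns), preserving mask and state
subset_metabolites <- function(x, keep) {
  metab_matrix(x$values[, keep, drop = FALSE],
               x$missing[, keep, drop = FALSE], state = x$state)
}

# internal: subset samples (rows)
subset_samples <- function(x, keep) {
  metab_matrix(x$values[keep, , drop = FALSE],
               x$missing[keep, , drop = FALSE], state = x$state)
}

#' Validate a metabolite annotation table
#'
#' Annotation maps each metabolite to its biochemical subclass ("subpathway",
#' e.g. creatine metabolism) and major class ("superpathway", e.g. amino
#' acid). Used by the subclass composite analysis and for reporting.
#'
#' @param annotation data.frame with columns \code{metabolite},
#'   \code{subclass}, \code{major_class}.
#' @return the validated data.frame (character columns, no duplicates)
#' @export
annotation_table <- function(annotation) {
  need <- c("metabolite", "subclass", "major_class")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  annotation <- as.data.frame(annotation)[need]
  annotation[] <- lapply(annotation, as.character)
  if (anyDuplicated(annotation$metabolite))
    stop("duplicate metabolite ids in annotation")
  annotation
}
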