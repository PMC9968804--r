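# Core containers shared across the pipeline stages.

#' Construct an expression matrix with sample labels
#'
#' The central data container of the pipeline: a nonnegative miRNA-by-sample
#' signal matrix together with a 0/1 disease label per sample (1 = case,
#' 0 = control).
#'
#' @param signal numeric matrix, miRNAs in rows (unique rownames), samples in
#'   columns (unique colnames); all entries must be nonnegative and finite.
#' @param labels integer vector of 0/1 labels, one per sample, in column order
#'   (or named by sample id).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `signal` and `labels`.
#' @export
expression_matrix <- function(signal, labels) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(signal) > 0 &&
      (is.null(rownames(signal)) || anyDuplicated(rownames(signal)))) {
    stop("`signal` needs unique rownames (miRNA ids)", call. = FALSE)
  }
  # subsetting to zero rows drops rownames to NULL; keep a typed empty vector
  if (nrow(signal) == 0 && is.null(rownames(signal))) {
    rownames(signal) <- character(0)
  }
  if (is.null(colnames(signal)) || anyDuplicated(colnames(signal))) {
    stop("`signal` needs unique colnames (sample ids)", call. = FALSE)
  }
  if (any(!is.finite(signal)) || any(signal < 0)) {
    stop("`signal` must be finite and nonnegative", call. = FALSE)
  }
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), colnames(signal))) {
      stop("label names do not match sample ids", call. = FALSE)
    }
    labels <- labels[colnames(signal)]
  }
  labels <- as.integer(labels)
  if (length(labels) != ncol(signal) || !all(labels %in% c(0L, 1L))) {
    stop("`labels` must be 0/1, one per sample", call. = FALSE)
  }
  structure(
    list(signal = signal, labels = setNames(labels, colnames(signal))),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d miRNAs x %d samples (%d case / %d control)\n",
    nrow(x$signal), ncol(x$signal), sum(x$labels == 1L), sum(x$labels == 0L)
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$signal)

#' miRNA and sample identifiers of an expression matrix
#' @param m an `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
mirna_ids <- function(m) rownames(m$signal)

#' @rdname mirna_ids
#' @export
sample_ids <- function(m) colnames(m$signal)

# internal: row-subset preserving class
subset_mirnas <- function(m, ids) {
  expression_matrix(m$signal[ids, , drop = FALSE], m$labels)
}

#' Construct a feature panel
#'
#' An ordered set of selected miRNA ids plus the selection method that
#' produced it.
#'
#' @param ids character vector of unique miRNA ids, in selection order.
#' @param method one of `"all"`, `"top_scc"`, `"overlap_3d"`, `"cluster_3d"`,
#'   `"random"`.
#' @param params list of parameters the builder used (recorded verbatim).
#' @return An object of class `FeaturePanel`.
#' @export
feature_panel <- function(ids,
                          method = c("all", "top_scc", "overlap_3d",
                                     "cluster_3d", "random"),
                          params = list()) {
  method <- match.arg(method)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("panel ids must be unique", call. = FALSE)
  structure(list(mirna_ids = ids, method = method, params = params),
            class = "FeaturePanel")
}

#' @export
print.FeaturePanel <- function(x, ...) {
  cat(sprintf("FeaturePanel [%s]: %d miRNAs\n", x$method, length(x$mirna_ids)))
  invisible(x)
}

#' @export
length.FeaturePanel <- function(x) length(x$mirna_ids)

#' Construct a contact matrix bound to its bin table
#'
#' @param counts symmetric nonnegative numeric matrix of contact counts with a
#'   zero diagonal, one row/column per genomic bin.
#' @param bins the bin table (as from [make_toy_genome()]) the matrix is
#'   indexed by.
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(counts, bins) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stop("`counts` must be a square matrix", call. = FALSE)
  }
  if (nrow(counts) != nrow(bins)) {
    stop("contact matrix dimension does not match the bin table", call. = FALSE)
  }
  if (any(counts < 0)) stop("contact counts must be nonnegative", call. = FALSE)
  if (!isTRUE(all.equal(counts, t(counts)))) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(counts) != 0)) stop("contact matrix diagonal must be zero", call. = FALSE)
  structure(list(counts = counts, bins = bins), class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins, %.0f total counts\n",
              nrow(x$counts), sum(x$counts) / 2))
  invisible(x)
}
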