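# profiling module: internal-control standardization and the two record
# filters (low expression, ambiguous annotation).

#' Standardize signals by internal-control miRNAs
#'
#' Divides every entry of a sample column by that sample's mean signal over
#' the three designated internal-control miRNAs, then removes the control rows
#' from the output. This removes per-sample technical scale: multiplying a
#' whole raw column by any c > 0 leaves its normalized values unchanged.
#'
#' @param raw an `ExpressionMatrix` containing the control rows.
#' @param control_ids exactly 3 miRNA ids with strictly positive signal in
#'   every sample.
#' @return A control-normalized `ExpressionMatrix` without the control rows.
#' @export
normalize_by_controls <- function(raw, control_ids) {
  stopifnot(inherits(raw, "ExpressionMatrix"))
  if (length(control_ids) != 3) {
    stop_config("exactly 3 internal-control ids are required")
  }
  missing <- setdiff(control_ids, mirna_ids(raw))
  if (length(missing) > 0) {
    stop("control miRNA(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ctl <- raw$signal[control_ids, , drop = FALSE]
  bad <- colnames(ctl)[apply(ctl <= 0, 2, any)]
  if (length(bad) > 0) {
    stop("non-positive control signal in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  denom <- colMeans(ctl)
  keep <- setdiff(mirna_ids(raw), control_ids)
  expression_matrix(sweep(raw$signal[keep, , drop = FALSE], 2, denom, "/"),
                    raw$labels)
}

#' Remove low-expression miRNAs
#'
#' Keeps a miRNA if its signal reaches `min_score` in at least `min_samples`
#' samples. Row order is preserved and the filter is idempotent.
#'
#' @param m an `ExpressionMatrix`.
#' @param min_score expression score threshold (default 5).
#' @param min_samples minimum number of samples at or above `min_score`;
#'   defaults to 76% of the cohort (the published analysis used 1,000 of
#'   1,309 samples).
#' @return The filtered `ExpressionMatrix` (a warning is emitted when empty).
#' @export
filter_low_expression <- function(m, min_score = 5, min_samples = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  n <- ncol(m$signal)
  if (is.null(min_samples)) min_samples <- ceiling(0.76 * n)
  if (min_samples > n) {
    stop_config("min_samples cannot exceed the number of samples")
  }
  keep <- rowSums(m$signal >= min_score) >= min_samples
  if (!any(keep)) warning("low-expression filter removed every miRNA", call. = FALSE)
  expression_matrix(m$signal[keep, , drop = FALSE], m$labels)
}

#' Remove ambiguously annotated miRNAs
#'
#' Keeps only miRNAs that appear in the annotation with a single, uniquely
#' mapped record; rows absent from the annotation are dropped with a logged
#' count.
#'
#' @param m an `ExpressionMatrix`.
#' @param ann annotation table (`mirna_id, ..., unique`).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_ambiguous <- function(m, ann) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  uniq_ids <- unique(ann$mirna_id[ann$unique])
  uniq_ids <- uniq_ids[!(uniq_ids %in% ann$mirna_id[!ann$unique])]
  keep <- mirna_ids(m) %in% uniq_ids
  n_absent <- sum(!(mirna_ids(m) %in% ann$mirna_id))
  if (n_absent > 0) {
    mir3d_log("filter_ambiguous",
              sprintf("dropped %d miRNA(s) absent from the annotation", n_absent),
              level = "WARN")
  }
  if (!any(keep)) warning("ambiguity filter removed every miRNA", call. = FALSE)
  expression_matrix(m$signal[keep, , drop = FALSE], m$labels)
}
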