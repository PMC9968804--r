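# cli_io module: bit-exact readers/writers for every on-disk format the
# pipeline touches, plus configuration handling.

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

read_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write / read an expression matrix
#'
#' The expression TSV has a header row of sample ids with `mirna_id` as the
#' first column; values are serialized at full precision (`%.17g`) so a
#' write/read round trip is bit-identical. Labels live in a companion TSV
#' (`sample_id`, `label`).
#'
#' @param m an `ExpressionMatrix`.
#' @param path expression TSV path.
#' @param labels_path labels TSV path.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns an `ExpressionMatrix`.
#' @export
write_expression <- function(m, path, labels_path = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  vals <- matrix(fmt_num(m$signal), nrow = nrow(m$signal))
  df <- data.frame(mirna_id = mirna_ids(m), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("mirna_id", sample_ids(m))
  write_tsv(df, path)
  if (!is.null(labels_path)) write_labels(m$labels, labels_path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, labels_path) {
  df <- read_tsv(path)
  if (colnames(df)[1] != "mirna_id") {
    stop("parse error in ", path, " line 1: first column must be 'mirna_id'",
         call. = FALSE)
  }
  dup <- which(duplicated(df$mirna_id))
  if (length(dup) > 0) {
    stop("parse error in ", path, " line ", dup[1] + 1L,
         ": duplicate miRNA id '", df$mirna_id[dup[1]], "'", call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (any(!is.finite(vals))) {
    bad <- which(apply(!is.finite(vals), 1, any))[1]
    stop("parse error in ", path, " line ", bad + 1L, ": non-numeric cell",
         call. = FALSE)
  }
  rownames(vals) <- df$mirna_id
  labels <- read_labels(labels_path)
  if (!setequal(names(labels), colnames(vals))) {
    stop("label/sample mismatch between ", path, " and ", labels_path,
         call. = FALSE)
  }
  expression_matrix(vals, labels)
}

#' Write / read sample labels
#'
#' @param labels named integer vector of 0/1 labels.
#' @param path labels TSV path (`sample_id`, `label`).
#' @return `read_labels` returns the named label vector.
#' @export
write_labels <- function(labels, path) {
  write_tsv(data.frame(sample_id = names(labels), label = as.integer(labels)),
            path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read_tsv(path)
  if (!all(df$label %in% c(0L, 1L))) {
    stop("parse error in ", path, ": labels must be 0/1", call. = FALSE)
  }
  setNames(as.integer(df$label), df$sample_id)
}

#' Write / read a miRNA annotation as BED6
#'
#' One line per mapping: `chrom, tss, tss + 1, mirna_id, 0, strand` (0-based,
#' half-open). A miRNA with several lines is non-unique; the reader
#' reconstructs the `unique` flag from id multiplicity.
#'
#' @param ann annotation table.
#' @param path BED path.
#' @return `read_annotation_bed` returns the annotation `data.frame`.
#' @export
write_annotation_bed <- function(ann, path) {
  bed <- data.frame(ann$chrom, ann$tss, ann$tss + 1L, ann$mirna_id, 0L,
                    ann$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("parse error in ", path, ": BED6 required", call. = FALSE)
  ann <- data.frame(mirna_id = bed[[4]], chrom = bed[[1]], tss = bed[[2]],
                    strand = bed[[6]], stringsAsFactors = FALSE)
  multi <- unique(ann$mirna_id[duplicated(ann$mirna_id)])
  ann$unique <- !(ann$mirna_id %in% multi)
  ann[order(ann$mirna_id, ann$chrom, ann$tss), , drop = FALSE]
}

#' Write / read a bin table as BED
#'
#' `chrom, start, end, bin_id` (0-based, half-open).
#'
#' @param bins bin table.
#' @param path BED path.
#' @return `read_bins` returns the bin `data.frame`.
#' @export
write_bins <- function(bins, path) {
  write.table(bins[, c("chrom", "start", "end", "bin_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(bin_id = as.integer(bed[[4]]), chrom = bed[[1]],
             start = bed[[2]], end = bed[[3]], stringsAsFactors = FALSE)
}

#' Write / read a contact matrix as an upper-triangle triplet TSV
#'
#' Columns `bin_i, bin_j, count` with `bin_i < bin_j`; zero pairs are omitted.
#' The reader materializes the full symmetric matrix, validates bin ids
#' against the bin table and rejects lower-triangle entries that conflict with
#' their upper-triangle mirror.
#'
#' @param contacts a `ContactMatrix`.
#' @param path triplet TSV path.
#' @param bins bin table the triplets are indexed by.
#' @return `read_contacts` returns a `ContactMatrix`.
#' @export
write_contacts <- function(contacts, path) {
  C <- contacts$counts
  idx <- which(upper.tri(C) & C != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   count = fmt_num(C[idx]))
  df <- df[order(df$bin_i, df$bin_j), ]
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path, bins) {
  df <- read_tsv(path)
  n <- nrow(bins)
  if (any(df$bin_i < 0 | df$bin_i >= n | df$bin_j < 0 | df$bin_j >= n)) {
    stop("parse error in ", path, ": bin id out of range", call. = FALSE)
  }
  C <- matrix(0, n, n)
  i <- pmin(df$bin_i, df$bin_j) + 1L
  j <- pmax(df$bin_i, df$bin_j) + 1L
  key <- paste(i, j)
  dupes <- duplicated(key)
  if (any(dupes)) {
    for (d in which(dupes)) {
      first <- match(key[d], key)
      if (df$count[d] != df$count[first]) {
        stop("parse error in ", path, ": conflicting duplicate for bin pair (",
             i[d] - 1L, ", ", j[d] - 1L, ")", call. = FALSE)
      }
    }
  }
  C[cbind(i, j)] <- df$count
  C[cbind(j, i)] <- df$count
  diag(C) <- 0
  contact_matrix(C, bins)
}

#' Write / read 3D bin coordinates
#'
#' TSV with columns `bin_id, x, y, z`, full precision, insertion order
#' preserved.
#'
#' @param model a `Genome3DModel`.
#' @param bins bin table matching the coordinates.
#' @param path coordinates TSV path.
#' @return `read_coords` returns a `Genome3DModel` (stress `NA`-free: 0 when
#'   unknown).
#' @export
write_coords <- function(model, bins, path) {
  df <- data.frame(bin_id = bins$bin_id,
                   x = fmt_num(model$coords[, 1]),
                   y = fmt_num(model$coords[, 2]),
                   z = fmt_num(model$coords[, 3]))
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_coords
#' @export
read_coords <- function(path) {
  df <- read_tsv(path)
  coords <- as.matrix(df[, c("x", "y", "z")])
  rownames(coords) <- df$bin_id
  genome3d_model(coords, stress = 0, n_restarts_used = 0L)
}

#' Write / read a feature panel (one miRNA id per line)
#'
#' @param panel a `FeaturePanel`.
#' @param path panel file path.
#' @param method method tag to attach on read.
#' @return `read_panel` returns a `FeaturePanel`.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel$mirna_ids, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, method = "all") {
  ids <- readLines(path)
  feature_panel(ids[nzchar(ids)], method)
}

#' Write a spatial clustering and its scatter export
#'
#' `write_clustering` emits `mirna_id, cluster_id, is_singleton`;
#' `write_cluster_scatter` emits `mirna_id, x, y, z, cluster_id` for 3D
#' scatter plots of the cluster structure.
#'
#' @param clustering a `SpatialClustering`.
#' @param table the miRNA 3D table the clustering was computed on.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_clustering <- function(clustering, path) {
  write_tsv(as.data.frame(clustering), path)
  invisible(path)
}

#' @rdname write_clustering
#' @export
write_cluster_scatter <- function(clustering, table, path) {
  df <- merge(table, as.data.frame(clustering), by = "mirna_id")
  write_tsv(df[, c("mirna_id", "x", "y", "z", "cluster_id")], path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' A nested list holding every tunable constant of the pipeline, mirroring the
#' published protocol where stated (score cutoff 5, top-k selection with
#' p < 0.05, DBSCAN with min_pts = 2, 0.5 decision cutoff, 300 embedding
#' restarts) and this package's calibrated defaults elsewhere. `eps` defaults
#' to 0.25 because the synthetic pipeline's contact-to-distance convention
#' (`d = 1/c`) puts single-contact pairs at unit distance, an order of
#' magnitude below the published model's scale.
#'
#' @param seed master seed; every stage derives its substream from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(),  # overrides for sim_config()
    control_ids = sprintf("ctl-miR-%d", 1:3),
    embedding = list(alpha = 1, cap_factor = 1.5, n_restarts = 300L,
                     max_iter = 500L, tol = 1e-9),
    filter = list(min_score = 5, min_samples = NULL),
    selection = list(eps = 0.25, min_pts = 2L, k_top = 60L,
                     m_representatives = 20L, p_max = 0.05,
                     selection_mode = "fixed_panel"),
    models = list(families = c("svc", "svr_linear", "svr_rbf",
                               "knn_regression"),
                  C = 1, gamma = "scale", k = 5L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [default_config()]; numeric
#' ranges are validated before any stage runs.
#'
#' @param path YAML file path.
#' @param seed optional seed override.
#' @return Validated configuration list.
#' @export
read_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (embedding$alpha <= 0) stop_config("embedding alpha must be > 0")
    if (embedding$n_restarts < 1) stop_config("n_restarts must be >= 1")
    if (selection$eps <= 0) stop_config("eps must be > 0")
    if (selection$min_pts < 2) stop_config("min_pts must be >= 2")
    if (selection$k_top < 1 || selection$m_representatives < 1) {
      stop_config("panel sizes must be >= 1")
    }
    fam <- c("svc", "svr_linear", "svr_rbf", "knn_regression")
    if (!all(models$families %in% fam)) stop_config("unknown model family")
  })
  # sim block is validated by sim_config() itself
  sim <- cfg$sim
  sim$seed <- NULL
  do.call(sim_config, c(sim, list(seed = cfg$seed)))
  cfg
}
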