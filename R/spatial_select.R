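# spatial_select module: Spearman scoring, DBSCAN over the 3D-mapped miRNAs,
# and the four feature-panel builders.

#' Score miRNAs by Spearman correlation with the disease label
#'
#' Per miRNA, the Spearman rank correlation (mid-rank ties) between its signal
#' vector and the 0/1 label vector, with a two-sided p-value from the usual
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`. Constant signal
#' vectors get `rho = 0`, `p = 1` and are flagged.
#'
#' @param m an `ExpressionMatrix` with both classes present and >= 3 samples.
#' @return `data.frame(mirna_id, rho, abs_rho, p, constant)`, one row per
#'   miRNA in matrix order.
#' @export
spearman_scores <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  y <- m$labels
  n <- length(y)
  if (n < 3) stop("at least 3 samples required", call. = FALSE)
  if (length(unique(y)) < 2) stop("both labels must be present", call. = FALSE)
  constant <- apply(m$signal, 1, function(v) length(unique(v)) == 1L)
  rho <- rep(0, nrow(m$signal))
  if (any(!constant)) {
    rho[!constant] <- suppressWarnings(
      as.vector(cor(t(m$signal[!constant, , drop = FALSE]), y,
                    method = "spearman"))
    )
  }
  p <- rep(1, length(rho))
  ok <- !constant & abs(rho) < 1
  tstat <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * pt(-abs(tstat), df = n - 2)
  p[!constant & abs(rho) >= 1] <- 0
  data.frame(mirna_id = mirna_ids(m), rho = rho, abs_rho = abs(rho), p = p,
             constant = constant, stringsAsFactors = FALSE)
}

#' Select the top-k miRNAs by absolute Spearman correlation
#'
#' Filters to `p < p_max`, sorts by `|rho|` descending (ties broken by
#' lexicographic id) and takes the first `min(k, available)` miRNAs.
#'
#' @param scores a score table from [spearman_scores()].
#' @param k panel size cap (>= 1).
#' @param p_max p-value cutoff (default 0.05).
#' @return A `FeaturePanel` with method `"top_scc"` (warning when empty).
#' @export
top_k_by_score <- function(scores, k, p_max = 0.05) {
  if (k < 1) stop_config("k must be >= 1")
  s <- scores[scores$p < p_max, , drop = FALSE]
  if (nrow(s) == 0) {
    warning("no miRNA passes the p-value cutoff; returning an empty panel",
            call. = FALSE)
  }
  s <- s[order(-s$abs_rho, s$mirna_id, method = "radix"), , drop = FALSE]
  feature_panel(head(s$mirna_id, k), "top_scc",
                params = list(k = k, p_max = p_max))
}

#' Density-based clustering of 3D-mapped miRNAs (DBSCAN)
#'
#' Standard DBSCAN with Euclidean distance on the `<x, y, z>` coordinates. A
#' point is a core point when its closed eps-neighborhood (itself included)
#' holds at least `min_pts` points; clusters are the connected components of
#' core points, border points join the cluster of their nearest core point
#' (ties: smaller distance, then smaller miRNA id), and every noise point is
#' promoted to its own singleton cluster. Cluster ids are assigned in order of
#' each cluster's smallest miRNA id, so the partition is invariant to input
#' row order.
#'
#' @param table a miRNA 3D table from [map_tss_to_coords()] (nonempty).
#' @param eps neighborhood radius in model units (> 0). The published analysis
#'   used 3 in the units of its (undeposited) model; the right value depends
#'   on the embedding's arbitrary length scale.
#' @param min_pts minimum closed-neighborhood size of a core point (>= 2).
#' @return A `SpatialClustering`: `data.frame(mirna_id, cluster_id,
#'   is_singleton)` with the `eps`/`min_pts` used stored as attributes.
#' @export
dbscan_cluster <- function(table, eps = 3, min_pts = 2) {
  if (nrow(table) == 0) stop("table must be nonempty", call. = FALSE)
  if (eps <= 0) stop_config("eps must be > 0")
  if (min_pts < 2) stop_config("min_pts must be >= 2")
  tab <- table[order(table$mirna_id), , drop = FALSE]
  X <- as.matrix(tab[, c("x", "y", "z")])
  n <- nrow(X)
  D <- as.matrix(dist(X))
  nbr <- D <= eps
  core <- rowSums(nbr) >= min_pts
  lab <- rep(NA_integer_, n)
  if (any(core)) {
    g <- igraph::graph_from_adjacency_matrix(
      nbr[core, core, drop = FALSE], mode = "undirected", diag = FALSE
    )
    lab[core] <- igraph::components(g)$membership
  }
  for (i in which(!core)) {
    cand <- which(core & nbr[, i])
    if (length(cand) > 0) {
      # nearest core point; ties resolved by smaller (id-sorted) index
      lab[i] <- lab[cand[which.min(D[cand, i])]]
    }
  }
  noise <- which(is.na(lab))
  if (length(noise) > 0) {
    lab[noise] <- max(c(0L, lab), na.rm = TRUE) + seq_along(noise)
  }
  # canonical ids: order of each cluster's smallest member (rows are id-sorted)
  lab <- match(lab, unique(lab))
  sizes <- tabulate(lab)
  out <- data.frame(mirna_id = tab$mirna_id, cluster_id = lab,
                    is_singleton = sizes[lab] == 1L, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "eps") <- eps
  attr(out, "min_pts") <- min_pts
  class(out) <- c("SpatialClustering", "data.frame")
  out
}

# largest-remainder apportionment of m seats to clusters with given sizes;
# ties: larger remainder, then larger cluster, then lexicographic cluster id
largest_remainder <- function(sizes, m) {
  quota <- m * sizes / sum(sizes)
  alloc <- floor(quota)
  left <- m - sum(alloc)
  if (left > 0) {
    ord <- order(-(quota - alloc), -sizes, names(sizes), method = "radix")
    alloc[ord[seq_len(left)]] <- alloc[ord[seq_len(left)]] + 1
  }
  alloc
}

#' Per-cluster proportional representatives
#'
#' Allocates `m` panel seats across spatial clusters proportionally to
#' cluster size by largest-remainder apportionment (ties: larger remainder,
#' then larger cluster, then lexicographic cluster id) and fills each
#' cluster's seats with its members of highest `|rho|` (ties by id). The
#' selected total is exactly `min(m, number of clustered miRNAs)`.
#'
#' @param clustering a `SpatialClustering`.
#' @param scores score table covering every clustered miRNA.
#' @param m target panel size (>= 1).
#' @param p_max optional p-value cutoff applied to the candidate pool before
#'   apportionment (default `NULL`: no filter, the plain reading of the
#'   published protocol).
#' @param at_least_one if `TRUE` and `m` >= number of clusters, every cluster
#'   receives at least one seat before the remainder is apportioned.
#' @return A `FeaturePanel` with method `"cluster_3d"`, ordered by cluster id
#'   then descending `|rho|`.
#' @export
proportional_representatives <- function(clustering, scores, m, p_max = NULL,
                                         at_least_one = FALSE) {
  if (m < 1) stop_config("m must be >= 1")
  pool <- merge(as.data.frame(clustering), scores, by = "mirna_id")
  if (nrow(pool) < nrow(clustering)) {
    stop("clustered miRNA(s) without a score: ",
         paste(setdiff(clustering$mirna_id, scores$mirna_id), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(p_max)) pool <- pool[pool$p < p_max, , drop = FALSE]
  n_total <- nrow(pool)
  if (m >= n_total) {
    if (m > n_total) {
      warning("m exceeds the number of available miRNAs; returning all",
              call. = FALSE)
    }
    pool <- pool[order(pool$cluster_id, -pool$abs_rho, pool$mirna_id,
                       method = "radix"), ]
    return(feature_panel(pool$mirna_id, "cluster_3d",
                         params = list(m = m, p_max = p_max)))
  }
  sizes <- table(pool$cluster_id)
  sizes_v <- setNames(as.numeric(sizes), names(sizes))
  if (at_least_one && m >= length(sizes_v)) {
    base <- rep(1, length(sizes_v))
    alloc <- base + largest_remainder(pmax(sizes_v - 1, 0), m - length(sizes_v))
  } else {
    alloc <- largest_remainder(sizes_v, m)
  }
  alloc <- pmin(alloc, sizes_v)
  picked <- unlist(lapply(names(sizes_v), function(cl) {
    mem <- pool[pool$cluster_id == as.integer(cl), , drop = FALSE]
    mem <- mem[order(-mem$abs_rho, mem$mirna_id, method = "radix"), ]
    head(mem$mirna_id, alloc[[cl]])
  }), use.names = FALSE)
  feature_panel(picked, "cluster_3d",
                params = list(m = m, p_max = p_max, at_least_one = at_least_one,
                              allocation = setNames(as.integer(alloc), names(sizes_v))))
}

#' Panel of miRNAs present in both expression and 3D space
#'
#' @param m an `ExpressionMatrix` (typically the filtered one).
#' @param table a miRNA 3D table from [map_tss_to_coords()].
#' @return A `FeaturePanel` with method `"overlap_3d"`, in matrix row order
#'   (warning when the overlap is empty).
#' @export
overlap_3d_panel <- function(m, table) {
  ids <- mirna_ids(m)[mirna_ids(m) %in% table$mirna_id]
  if (length(ids) == 0) {
    warning("no miRNA is present in both the expression matrix and the 3D table",
            call. = FALSE)
  }
  feature_panel(ids, "overlap_3d")
}

#' The whole-expression panel
#'
#' @param m an `ExpressionMatrix`.
#' @return A `FeaturePanel` with method `"all"` containing every miRNA of `m`.
#' @export
all_panel <- function(m) feature_panel(mirna_ids(m), "all")

#' A size-matched random panel (baseline)
#'
#' @param m an `ExpressionMatrix` providing the id universe.
#' @param size panel size.
#' @param seed integer seed.
#' @return A `FeaturePanel` with method `"random"`.
#' @export
random_panel <- function(m, size, seed = 1L) {
  ids <- mirna_ids(m)
  if (size > length(ids)) stop_config("size exceeds the id universe")
  set.seed(seed)
  feature_panel(sample(ids, size), "random", params = list(seed = seed))
}
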