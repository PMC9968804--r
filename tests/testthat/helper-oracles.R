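# Independent reference implementations (oracles) used by the tests. These are
# deliberately written as plain, brute-force procedures so they share no code
# path with the package functions they check.

options(mir3d.quiet = TRUE)

# --- brute-force DBSCAN by literal density reachability ---------------------
# Core point: closed eps-neighborhood holds >= min_pts points. A cluster is
# grown by BFS from a seed core through core neighborhoods; border points join
# the cluster of their nearest core point (ties: smaller distance, then the
# smaller id in sorted order). Noise points become singleton clusters.
oracle_dbscan <- function(table, eps, min_pts) {
  tab <- table[order(table$mirna_id), , drop = FALSE]
  X <- as.matrix(tab[, c("x", "y", "z")])
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_pts, TRUE)
  lab <- rep(NA_integer_, n)
  cl <- 0L
  for (seed in seq_len(n)) {
    if (!core[seed] || !is.na(lab[seed])) next
    cl <- cl + 1L
    queue <- seed
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      if (!is.na(lab[p])) next
      lab[p] <- cl
      nbrs <- which(D[p, ] <= eps & core & is.na(lab))
      queue <- c(queue, nbrs)
    }
  }
  for (i in which(!core)) {
    cand <- which(core & D[, i] <= eps)
    if (length(cand) > 0) lab[i] <- lab[cand[which.min(D[cand, i])]]
  }
  for (i in which(is.na(lab))) {
    cl <- cl + 1L
    lab[i] <- cl
  }
  split(tab$mirna_id, lab)
}

# canonical partition signature: sorted list of sorted member sets
partition_signature <- function(members_by_cluster) {
  sig <- unname(lapply(members_by_cluster, function(ids) sort(as.character(ids))))
  sig[order(vapply(sig, `[`, "", 1))]
}

clustering_signature <- function(clustering) {
  partition_signature(split(clustering$mirna_id, clustering$cluster_id))
}

# --- Spearman by explicit rank-then-Pearson ---------------------------------
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# --- exhaustive largest-remainder check -------------------------------------
# Enumerates every feasible integer allocation (0 <= a_c <= size_c, sum = m)
# and returns the minimal total absolute deviation from the exact quotas.
oracle_min_deviation <- function(sizes, m) {
  grids <- lapply(sizes, function(s) 0:s)
  combos <- as.matrix(do.call(expand.grid, grids))
  combos <- combos[rowSums(combos) == m, , drop = FALSE]
  quota <- m * sizes / sum(sizes)
  min(rowSums(abs(sweep(combos, 2, quota))))
}

# --- AUC as the fraction of correctly ordered (pos, neg) pairs --------------
oracle_auc_pairs <- function(score, truth) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# --- small random fixtures ---------------------------------------------------
rand_expr <- function(n_mirna = 12, n_sample = 10, seed = 1) {
  set.seed(seed)
  sig <- matrix(rlnorm(n_mirna * n_sample, meanlog = 2, sdlog = 1),
                nrow = n_mirna,
                dimnames = list(sprintf("m%03d", seq_len(n_mirna)),
                                sprintf("s%03d", seq_len(n_sample))))
  labels <- rep_len(c(0L, 1L), n_sample)
  expression_matrix(sig, labels)
}

rand_points_table <- function(n, seed, spread = 5) {
  set.seed(seed)
  data.frame(mirna_id = sprintf("m%03d", seq_len(n)),
             x = runif(n, 0, spread), y = runif(n, 0, spread),
             z = runif(n, 0, spread), stringsAsFactors = FALSE)
}
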