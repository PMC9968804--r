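# spatial_select: Spearman scores, DBSCAN, apportionment, panel builders

test_that("spearman_scores gets signed extremes and ties right", {
  sig <- rbind(up = c(1, 2, 3, 4, 5, 6),
               down = c(6, 5, 4, 3, 2, 1),
               flat = rep(7, 6))
  colnames(sig) <- paste0("s", 1:6)
  m <- expression_matrix(sig, c(0L, 0L, 0L, 1L, 1L, 1L))
  sc <- spearman_scores(m)
  # with a 0/1 label, a monotone-increasing vector attains the maximum
  # achievable |rho| for ties in y; both extremes are symmetric
  expect_equal(sc$rho[1], -sc$rho[2])
  expect_equal(sc$abs_rho[1], oracle_spearman(sig["up", ], m$labels))
  expect_true(sc$constant[3])
  expect_equal(sc$rho[3], 0)
  expect_equal(sc$p[3], 1)
  expect_true(all(sc$p >= 0 & sc$p <= 1))

  expect_error(spearman_scores(expression_matrix(sig[, 1:2], c(0L, 1L))),
               "3 samples")
  expect_error(spearman_scores(expression_matrix(sig, rep(1L, 6))),
               "both labels")
})

test_that("spearman_scores matches the rank-then-Pearson oracle with ties", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(6:30, 1)
    # heavy ties: small integer support
    sig <- matrix(sample(1:4, 5 * n, replace = TRUE), 5, n,
                  dimnames = list(paste0("m", 1:5), paste0("s", 1:n)))
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 1L - y[1]
    m <- expression_matrix(sig, y)
    sc <- spearman_scores(m)
    for (i in 1:5) {
      if (sc$constant[i]) next
      expect_equal(sc$rho[i], oracle_spearman(sig[i, ], y), tolerance = 1e-12)
    }
  }
})

test_that("top_k_by_score sorts, filters, and saturates", {
  sc <- data.frame(
    mirna_id = c("a", "b", "c", "d", "e"),
    rho = c(0.9, -0.95, 0.5, 0.5, 0.2),
    abs_rho = c(0.9, 0.95, 0.5, 0.5, 0.2),
    p = c(0.001, 0.001, 0.01, 0.01, 0.5),
    constant = FALSE, stringsAsFactors = FALSE
  )
  p <- top_k_by_score(sc, k = 3)
  expect_equal(p$mirna_ids, c("b", "a", "c"))  # |rho| desc, tie c-before-d by id
  expect_equal(top_k_by_score(sc, k = 100)$mirna_ids, c("b", "a", "c", "d"))  # e: p>=0.05
  expect_equal(top_k_by_score(sc, k = 100, p_max = 1)$mirna_ids,
               c("b", "a", "c", "d", "e"))
  expect_warning(top_k_by_score(sc, 2, p_max = 1e-9), "empty panel")
  expect_error(top_k_by_score(sc, 0), "k must be")

  # brute-sort oracle on random tables
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    tab <- data.frame(mirna_id = sample(sprintf("m%02d", 1:n)),
                      rho = round(runif(n, -1, 1), 2),
                      p = c(0.01, runif(n - 1)),  # keep the pool nonempty
                      stringsAsFactors = FALSE)
    tab$abs_rho <- abs(tab$rho)
    tab$constant <- FALSE
    keep <- tab[tab$p < 0.05, ]
    oracle <- keep$mirna_id[order(-keep$abs_rho, keep$mirna_id)]
    expect_equal(top_k_by_score(tab, 10)$mirna_ids, head(oracle, 10))
  }
})

test_that("dbscan_cluster reproduces hand-worked configurations", {
  tab <- data.frame(mirna_id = c("a", "b", "c"),
                    x = c(0, 1, 10), y = 0, z = 0, stringsAsFactors = FALSE)
  cl <- dbscan_cluster(tab, eps = 3, min_pts = 2)
  expect_equal(cl$cluster_id, c(1L, 1L, 2L))  # pair + promoted singleton
  expect_equal(cl$is_singleton, c(FALSE, FALSE, TRUE))

  # identical points are always co-clustered core points
  same <- data.frame(mirna_id = c("p", "q"), x = 1, y = 1, z = 1)
  expect_equal(dbscan_cluster(same, eps = 0.001, min_pts = 2)$cluster_id,
               c(1L, 1L))

  # chain a-b-c with 2-unit gaps and eps 2: one connected component
  chain <- data.frame(mirna_id = c("a", "b", "c"),
                      x = c(0, 2, 4), y = 0, z = 0)
  expect_equal(dbscan_cluster(chain, eps = 2, min_pts = 2)$cluster_id,
               rep(1L, 3))
  # but with min_pts 3 only b is core; a and c become its border points
  expect_equal(dbscan_cluster(chain, eps = 2, min_pts = 3)$cluster_id,
               rep(1L, 3))

  expect_error(dbscan_cluster(tab, eps = 0), "eps")
  expect_error(dbscan_cluster(tab, eps = 1, min_pts = 1), "min_pts")
  expect_error(dbscan_cluster(tab[0, ], eps = 1), "nonempty")
})

test_that("dbscan_cluster equals the brute-force density-reachability oracle", {
  for (s in 1:20) {
    n <- sample(10:60, 1)
    tab <- rand_points_table(n, seed = s)
    for (eps in c(0.4, 0.8, 1.5)) {
      got <- clustering_signature(dbscan_cluster(tab, eps = eps, min_pts = 3))
      want <- partition_signature(oracle_dbscan(tab, eps = eps, min_pts = 3))
      expect_identical(got, want)
    }
  }
})

test_that("dbscan_cluster is invariant to row order and rigid motion", {
  tab <- rand_points_table(40, seed = 77)
  base <- dbscan_cluster(tab, eps = 1, min_pts = 2)
  set.seed(1)
  shuf <- dbscan_cluster(tab[sample(nrow(tab)), ], eps = 1, min_pts = 2)
  expect_identical(clustering_signature(base), clustering_signature(shuf))

  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  moved <- tab
  moved[, c("x", "y", "z")] <-
    as.matrix(tab[, c("x", "y", "z")]) %*% R + 100
  rot <- dbscan_cluster(moved, eps = 1, min_pts = 2)
  expect_identical(clustering_signature(base), clustering_signature(rot))

  # scaling points and eps together changes nothing
  scaled <- tab
  scaled[, c("x", "y", "z")] <- tab[, c("x", "y", "z")] * 7
  expect_identical(clustering_signature(base),
                   clustering_signature(dbscan_cluster(scaled, eps = 7,
                                                       min_pts = 2)))
})

test_that("largest-remainder apportionment matches worked examples", {
  lr <- mir3d:::largest_remainder
  expect_equal(unname(lr(setNames(c(50, 30, 20), c("1", "2", "3")), 10)),
               c(5, 3, 2))
  expect_equal(unname(lr(setNames(c(7, 5, 3), c("1", "2", "3")), 5)),
               c(2, 2, 1))  # quotas 2.33, 1.67, 1.00 -> floor 2,1,1 + 1 seat
  expect_equal(sum(lr(setNames(c(3, 3, 3), c("1", "2", "3")), 7)), 7)
})

test_that("proportional_representatives honors quotas and fills by |rho|", {
  clustering <- structure(
    data.frame(mirna_id = sprintf("m%02d", 1:10),
               cluster_id = rep(c(1L, 2L), c(7, 3)),
               is_singleton = FALSE, stringsAsFactors = FALSE),
    eps = 1, min_pts = 2, class = c("SpatialClustering", "data.frame")
  )
  scores <- data.frame(mirna_id = sprintf("m%02d", 1:10),
                       rho = seq(0.95, 0.05, by = -0.1),
                       abs_rho = seq(0.95, 0.05, by = -0.1),
                       p = 0.001, constant = FALSE, stringsAsFactors = FALSE)
  p <- proportional_representatives(clustering, scores, m = 5)
  # quotas 3.5 / 1.5 -> floors 3/1, last seat to either remainder 0.5 tie ->
  # larger cluster wins: 4 from cluster 1, 1 from cluster 2, by |rho| within
  expect_equal(p$mirna_ids, c("m01", "m02", "m03", "m04", "m08"))
  expect_equal(length(p$mirna_ids), 5)

  # a single cluster simply returns its top-m members
  one <- clustering; one$cluster_id <- 1L
  expect_equal(proportional_representatives(one, scores, 3)$mirna_ids,
               c("m01", "m02", "m03"))

  # m >= pool returns everything (with a warning when strictly greater)
  expect_equal(length(proportional_representatives(clustering, scores, 10)$mirna_ids),
               10)
  expect_warning(proportional_representatives(clustering, scores, 11),
                 "returning all")
  expect_error(proportional_representatives(clustering, scores, 0), "m must")
  expect_error(
    proportional_representatives(clustering, scores[-1, ], 3), "m01")
})

test_that("apportionment is exact-sum, size-capped, and deviation-minimal", {
  lr <- mir3d:::largest_remainder
  for (s in 1:50) {
    set.seed(s)
    k <- sample(2:4, 1)
    sizes <- setNames(sample(1:7, k, replace = TRUE), as.character(seq_len(k)))
    m <- sample(seq_len(sum(sizes)), 1)
    al <- pmin(lr(sizes, m), sizes)
    expect_equal(sum(al), m)            # all seats assigned
    expect_true(all(al >= 0))
    # largest remainder minimizes total |alloc - quota| among exact-sum
    # integer allocations (classical property; checked exhaustively)
    quota <- m * sizes / sum(sizes)
    expect_equal(sum(abs(al - quota)), oracle_min_deviation(sizes, m),
                 tolerance = 1e-9)
  }
})

test_that("panel builders are consistent set operations", {
  m <- rand_expr(10, 8, seed = 5)
  tab <- data.frame(mirna_id = c("m003", "m007", "zzz"), x = 0, y = 0, z = 0,
                    stringsAsFactors = FALSE)
  ov <- overlap_3d_panel(m, tab)
  expect_equal(ov$mirna_ids, c("m003", "m007"))  # matrix row order, intersection
  expect_warning(overlap_3d_panel(m, tab[3, , drop = FALSE]), "no miRNA")

  expect_equal(all_panel(m)$mirna_ids, mirna_ids(m))

  r1 <- random_panel(m, 4, seed = 9)
  r2 <- random_panel(m, 4, seed = 9)
  expect_identical(r1$mirna_ids, r2$mirna_ids)
  expect_true(all(r1$mirna_ids %in% mirna_ids(m)))
  expect_error(random_panel(m, 11), "exceeds")
})
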