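# eval_loocv: LOOCV predictions, metric arithmetic, curve data

# a small, well-separated two-class dataset: class means differ by several SDs
separable_expr <- function(n_mirna = 6, n_per_class = 8, seed = 3, gap = 6) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  sig <- matrix(rnorm(n_mirna * n), n_mirna,
                dimnames = list(sprintf("m%02d", seq_len(n_mirna)),
                                sprintf("s%02d", seq_len(n))))
  sig <- sig + gap * matrix(labels, n_mirna, n, byrow = TRUE)
  expression_matrix(sig - min(sig) + 1, labels)
}

test_that("loocv_predict returns one oriented score per sample", {
  m <- separable_expr()
  panel <- all_panel(m)
  for (fam in c("svc", "svr_linear", "svr_rbf", "knn_regression")) {
    pred <- loocv_predict(m, panel, model_spec(fam, k = 3))
    expect_s3_class(pred, "PredictionVector")
    expect_equal(nrow(pred), ncol(m$signal))
    expect_equal(pred$sample_id, sample_ids(m))
    expect_identical(pred$truth, unname(m$labels))
    expect_identical(pred$call, as.integer(pred$score >= 0.5))
    # the classes are far apart: every family should separate them perfectly
    expect_identical(pred$call, pred$truth)
    expect_true(attr(pred, "selection_leakage"))
  }
})

test_that("loocv scores are invariant to sample order", {
  m <- separable_expr(seed = 8, gap = 2)
  panel <- all_panel(m)
  pred <- loocv_predict(m, panel, model_spec("svc"))
  set.seed(2)
  perm <- sample(ncol(m$signal))
  m2 <- expression_matrix(m$signal[, perm], m$labels[perm])
  pred2 <- loocv_predict(m2, panel, model_spec("svc"))
  # libsvm's solver is order-sensitive at its optimizer tolerance
  expect_equal(pred2$score[match(pred$sample_id, pred2$sample_id)],
               pred$score, tolerance = 1e-3)
})

test_that("KNN with k = 1 copies a duplicated twin's label", {
  # two identical copies of each sample: the held-out sample's nearest
  # neighbor is always its twin, so 1-NN LOOCV is perfect by construction
  base <- matrix(rnorm(4 * 6), 4,
                 dimnames = list(paste0("m", 1:4), paste0("a", 1:6)))
  sig <- cbind(base, base)
  colnames(sig) <- paste0("s", 1:12)
  y <- rep(c(0L, 1L, 0L, 1L, 0L, 1L), 2)
  m <- expression_matrix(sig - min(sig) + 1, y)
  pred <- loocv_predict(m, all_panel(m), model_spec("knn_regression", k = 1))
  expect_identical(pred$call, pred$truth)
  expect_equal(pred$score, as.numeric(pred$truth))
})

test_that("loocv_predict validates its inputs", {
  m <- separable_expr()
  ghost <- feature_panel(c("m01", "nope"), "all")
  expect_error(loocv_predict(m, ghost, model_spec("svc")), "nope")
  expect_error(loocv_predict(m, all_panel(m), model_spec("svc"),
                             selection_mode = "nested"),
               "panel_builder")
  # removing one sample must still leave both classes in every fold
  one_pos <- expression_matrix(m$signal[, 1:9], c(rep(0L, 8), 1L))
  expect_error(loocv_predict(one_pos, all_panel(one_pos), model_spec("svc")),
               "single class")
})

test_that("nested mode records per-fold panels built without the held-out sample", {
  m <- separable_expr(n_per_class = 6)
  builder <- function(m_tr) top_k_by_score(spearman_scores(m_tr), k = 3)
  pred <- loocv_predict(m, panel = NULL, model_spec("svc"),
                        selection_mode = "nested", panel_builder = builder)
  fp <- attr(pred, "fold_panels")
  expect_length(fp, ncol(m$signal))
  expect_true(all(vapply(fp, length, 0L) == 3))
  expect_false(attr(pred, "selection_leakage"))
})

test_that("compute_metrics matches hand-worked confusion tables", {
  perfect <- structure(
    data.frame(sample_id = paste0("s", 1:4), score = c(0.9, 0.8, 0.1, 0.2),
               call = c(1L, 1L, 0L, 0L), truth = c(1L, 1L, 0L, 0L)),
    class = c("PredictionVector", "data.frame")
  )
  met <- compute_metrics(perfect)
  expect_equal(unlist(unclass(met)),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1,
                 aupr = 1, auc = 1))

  # calls (1,0,1,0) against truth (1,0,0,1): tp=1 fp=1 fn=1 tn=1
  half <- structure(
    data.frame(sample_id = paste0("s", 1:4), score = c(0.9, 0.1, 0.8, 0.2),
               call = c(1L, 0L, 1L, 0L), truth = c(1L, 0L, 0L, 1L)),
    class = c("PredictionVector", "data.frame")
  )
  m2 <- compute_metrics(half)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$f1, 0.5)
  # pairs (pos vs neg): 0.9>0.1, 0.9>0.8, 0.2>0.1 ordered; 0.2<0.8 not
  expect_equal(m2$auc, 0.75)

  # nothing called positive: precision defined as 0 and flagged, f1 = 0
  none <- half
  none$call <- 0L
  m3 <- compute_metrics(none)
  expect_equal(m3$precision, 0)
  expect_equal(m3$f1, 0)
  expect_true(attr(m3, "no_positive_call"))

  expect_error(compute_metrics(data.frame(score = 1, call = 1L, truth = 1L)),
               "both classes")
})

test_that("AUC agrees with the pairwise oracle and is antisymmetric", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(8:40, 1)
    truth <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0L, 1L)
    score <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    a <- mir3d:::auc_mann_whitney(score, truth)
    expect_equal(a, oracle_auc_pairs(score, truth), tolerance = 1e-12)
    expect_equal(a + mir3d:::auc_mann_whitney(-score, truth), 1,
                 tolerance = 1e-12)
    expect_true(a >= 0 && a <= 1)
  }
})

test_that("curve data is consistent with the scalar metrics", {
  set.seed(12)
  n <- 30
  truth <- rep(c(0L, 1L), 15)
  score <- runif(n) + 0.3 * truth
  pred <- structure(
    data.frame(sample_id = paste0("s", 1:n), score = score,
               call = as.integer(score >= 0.5), truth = truth),
    class = c("PredictionVector", "data.frame")
  )
  cv <- curves(pred)
  expect_equal(cv$roc$fpr[1], 0)
  expect_equal(cv$roc$tpr[1], 0)
  expect_equal(tail(cv$roc$fpr, 1), 1)
  expect_equal(tail(cv$roc$tpr, 1), 1)
  expect_true(all(diff(cv$roc$fpr) >= 0))
  expect_true(all(diff(cv$roc$tpr) >= 0))
  expect_equal(tail(cv$pr$recall, 1), 1)

  # trapezoidal area under the ROC points equals the Mann-Whitney AUC
  trap <- sum(diff(cv$roc$fpr) *
                (head(cv$roc$tpr, -1) + tail(cv$roc$tpr, -1)) / 2)
  expect_equal(trap, mir3d:::auc_mann_whitney(score, truth), tolerance = 1e-12)

  # a perfect ranking passes through (fpr 0, tpr 1)
  ps <- pred
  ps$score <- truth + runif(n, 0, 0.4)
  cvp <- curves(ps)
  expect_true(any(cvp$roc$fpr == 0 & cvp$roc$tpr == 1))

  # reversing the scores mirrors the ROC through the diagonal
  pr <- pred
  pr$score <- -pred$score
  cvr <- curves(pr)
  expect_equal(sum(diff(cvr$roc$fpr) *
                     (head(cvr$roc$tpr, -1) + tail(cvr$roc$tpr, -1)) / 2),
               1 - trap, tolerance = 1e-12)
})

test_that("random scores give AUC near one half", {
  aucs <- vapply(1:40, function(s) {
    set.seed(s)
    truth <- rep(c(0L, 1L), each = 25)
    mir3d:::auc_mann_whitney(runif(50), truth)
  }, 0)
  # null mean 0.5, per-draw SD ~ sqrt((n1+n2+1)/(12 n1 n2)) ~ 0.082
  expect_lt(abs(mean(aucs) - 0.5), 4 * 0.082 / sqrt(length(aucs)))
})

test_that("compare_panels crosses panels and specs; duplicates agree", {
  m <- separable_expr(n_per_class = 6, gap = 3)
  panels <- list(all = all_panel(m), also_all = all_panel(m))
  specs <- list(svc = model_spec("svc"), knn = model_spec("knn_regression", k = 3))
  grid <- compare_panels(m, panels, specs)
  expect_equal(nrow(grid), 4)
  expect_setequal(grid$panel, c("all", "also_all"))
  expect_equal(grid$n_features, rep(nrow(m$signal), 4))
  # identical panels give identical rows per family
  for (fam in unique(grid$family)) {
    sub <- grid[grid$family == fam, ]
    expect_equal(sub[sub$panel == "all", -1], sub[sub$panel == "also_all", -1],
                 ignore_attr = TRUE)
  }
  preds <- attr(grid, "predictions")
  expect_length(preds, 4)
  expect_s3_class(preds[["all.svc"]], "PredictionVector")
})
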