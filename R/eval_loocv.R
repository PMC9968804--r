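# eval_loocv module: leave-one-out evaluation of feature panels across the
# four model families, the six summary metrics and PR/ROC curve data.

#' Specify a prediction model
#'
#' @param family one of `"svc"` (support vector classification, RBF kernel),
#'   `"svr_linear"`, `"svr_rbf"` (support vector regression) or
#'   `"knn_regression"`.
#' @param C cost parameter for the SVM families.
#' @param gamma RBF kernel width: `"scale"` (1 / (n_features * overall
#'   feature variance), computed on each training fold) or a positive number.
#' @param k neighbor count for KNN regression (>= 1).
#' @param scale_features z-score features on the training fold and apply the
#'   fold's transform to the held-out sample. Defaults to `TRUE` for the
#'   scale-sensitive SVM families and `FALSE` for KNN.
#' @return An object of class `ModelSpec`.
#' @export
model_spec <- function(family = c("svc", "svr_linear", "svr_rbf",
                                  "knn_regression"),
                       C = 1, gamma = "scale", k = 5L, scale_features = NULL) {
  family <- match.arg(family)
  if (k < 1) stop_config("k must be >= 1")
  if (is.null(scale_features)) scale_features <- family != "knn_regression"
  structure(list(family = family, C = C, gamma = gamma, k = as.integer(k),
                 scale_features = scale_features),
            class = "ModelSpec")
}

# z-scoring transform fit on the training fold; constant features get sd 1
fold_scaler <- function(xtr) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[sdv == 0] <- 1
  function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
}

resolve_gamma <- function(spec, xtr) {
  if (identical(spec$gamma, "scale")) {
    v <- var(as.vector(xtr))
    if (!is.finite(v) || v == 0) v <- 1
    1 / (ncol(xtr) * v)
  } else {
    spec$gamma
  }
}

# fit on (xtr, ytr), return continuous scores for xte. SVC margins are mapped
# through a logistic so that margin 0 corresponds to score 0.5; regressors
# return raw predictions.
fit_predict_score <- function(spec, xtr, ytr, xte) {
  if (spec$scale_features) {
    sc <- fold_scaler(xtr)
    xtr <- sc(xtr)
    xte <- sc(xte)
  }
  switch(spec$family,
    svc = {
      fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)),
                        type = "C-classification", kernel = "radial",
                        cost = spec$C, gamma = resolve_gamma(spec, xtr),
                        scale = FALSE)
      pr <- predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient the margin so that positive favors class "1"
      sgn <- if (grepl("^1/", colnames(dv)[1])) 1 else -1
      plogis(sgn * dv[, 1])
    },
    svr_linear = ,
    svr_rbf = {
      kern <- if (spec$family == "svr_linear") "linear" else "radial"
      fit <- e1071::svm(xtr, as.numeric(ytr), type = "eps-regression",
                        kernel = kern, cost = spec$C,
                        gamma = resolve_gamma(spec, xtr), scale = FALSE)
      unname(predict(fit, xte))
    },
    knn_regression = {
      fit <- caret::knnreg(xtr, as.numeric(ytr), k = spec$k)
      unname(predict(fit, xte))
    }
  )
}

#' Leave-one-out cross-validated predictions for a feature panel
#'
#' For each sample the model is fit on all other samples and the held-out
#' sample is scored. In `fixed_panel` mode the features are restricted to the
#' given panel (which was typically selected on the full data set - the
#' protocol of the original analysis; the potential selection leakage is
#' logged and flagged on the result). In `nested` mode the panel is re-derived
#' on each training fold via `panel_builder`, so selection never sees the
#' held-out label.
#'
#' @param m an `ExpressionMatrix`.
#' @param panel a nonempty `FeaturePanel`; every id must be present in `m`
#'   (ignored in `nested` mode).
#' @param spec a [model_spec()].
#' @param selection_mode `"fixed_panel"` or `"nested"`.
#' @param panel_builder for `nested` mode: `function(m_train) -> FeaturePanel`.
#' @return A `PredictionVector`: `data.frame(sample_id, score, call, truth)`
#'   with one row per sample; `call = score >= 0.5`. The attribute
#'   `selection_leakage` is `TRUE` in `fixed_panel` mode; in `nested` mode the
#'   per-fold selected ids are attached as the `fold_panels` attribute.
#' @export
loocv_predict <- function(m, panel, spec,
                          selection_mode = c("fixed_panel", "nested"),
                          panel_builder = NULL) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(spec, "ModelSpec"))
  y <- unname(m$labels)
  n <- length(y)
  if (selection_mode == "fixed_panel") {
    if (length(panel) == 0) stop("panel must be nonempty", call. = FALSE)
    missing <- setdiff(panel$mirna_ids, mirna_ids(m))
    if (length(missing) > 0) {
      stop("panel miRNA(s) absent from the matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    mir3d_log("loocv_predict",
              "fixed_panel mode: the panel was selected outside the CV loop; ",
              "feature-selection leakage is possible", level = "WARN")
  } else if (is.null(panel_builder)) {
    stop("nested mode requires a panel_builder", call. = FALSE)
  }
  score <- numeric(n)
  fold_panels <- if (selection_mode == "nested") vector("list", n) else NULL
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      stop(sprintf("training fold %d contains a single class", i), call. = FALSE)
    }
    if (selection_mode == "nested") {
      m_tr <- expression_matrix(m$signal[, -i, drop = FALSE], m$labels[-i])
      p_i <- panel_builder(m_tr)
      ids <- p_i$mirna_ids
      if (length(ids) == 0) stop("nested selection returned an empty panel",
                                 call. = FALSE)
      fold_panels[[i]] <- ids
    } else {
      ids <- panel$mirna_ids
    }
    xtr <- t(m$signal[ids, -i, drop = FALSE])
    xte <- t(m$signal[ids, i, drop = FALSE])
    score[i] <- fit_predict_score(spec, xtr, ytr, xte)
  }
  out <- data.frame(sample_id = sample_ids(m), score = score,
                    call = as.integer(score >= 0.5), truth = y,
                    stringsAsFactors = FALSE)
  attr(out, "family") <- spec$family
  attr(out, "selection_mode") <- selection_mode
  attr(out, "selection_leakage") <- selection_mode == "fixed_panel"
  attr(out, "fold_panels") <- fold_panels
  class(out) <- c("PredictionVector", "data.frame")
  out
}

# Mann-Whitney AUC on continuous scores; ties counted half
auc_mann_whitney <- function(score, truth) {
  np <- sum(truth == 1)
  nn <- sum(truth == 0)
  r <- rank(score)
  (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
}

# average precision by step-wise summation over unique-score thresholds
average_precision <- function(score, truth) {
  np <- sum(truth == 1)
  o <- order(-score)
  s <- score[o]
  t <- truth[o]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(t)[grp_end]
  pp <- grp_end
  rec <- tp / np
  prec <- tp / pp
  sum(diff(c(0, rec)) * prec)
}

#' Six-metric summary of a prediction vector
#'
#' Positive class is 1. Accuracy, precision, recall and F1 are computed from
#' the binary calls; AUC is the Mann-Whitney rank statistic on the continuous
#' scores (ties counted half) and AUPR is the average precision by step-wise
#' summation. Precision is defined as 0 (and flagged) when nothing is called
#' positive.
#'
#' @param pred a `PredictionVector` with both classes in `truth`.
#' @return A `MetricSet`: named list with `accuracy`, `precision`, `recall`,
#'   `f1`, `aupr`, `auc`, all in `[0, 1]`.
#' @export
compute_metrics <- function(pred) {
  truth <- pred$truth
  if (length(unique(truth)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  call <- pred$call
  tp <- sum(call == 1 & truth == 1)
  tn <- sum(call == 0 & truth == 0)
  fp <- sum(call == 1 & truth == 0)
  fn <- sum(call == 0 & truth == 1)
  accuracy <- (tp + tn) / length(truth)
  no_positive_call <- (tp + fp) == 0
  precision <- if (no_positive_call) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  out <- list(
    accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
    aupr = average_precision(pred$score, truth),
    auc = auc_mann_whitney(pred$score, truth)
  )
  attr(out, "no_positive_call") <- no_positive_call
  class(out) <- "MetricSet"
  out
}

#' @export
print.MetricSet <- function(x, ...) {
  cat(paste(sprintf("%s=%.4f", names(x), unlist(x)), collapse = "  "), "\n")
  invisible(x)
}

#' PR and ROC curve points
#'
#' Sweeps the decision threshold over the unique continuous scores. ROC points
#' are monotone in FPR and include the (0, 0) and (1, 1) endpoints; PR points
#' are anchored at recall 0 (precision of the strictest threshold) and reach
#' recall 1 at the loosest. The trapezoidal area under the returned ROC points
#' equals the Mann-Whitney AUC.
#'
#' @param pred a `PredictionVector` with both classes present.
#' @return List with `roc` (`data.frame(threshold, fpr, tpr)`) and `pr`
#'   (`data.frame(threshold, recall, precision)`).
#' @export
curves <- function(pred) {
  truth <- pred$truth
  if (length(unique(truth)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  np <- sum(truth == 1)
  nn <- sum(truth == 0)
  o <- order(-pred$score)
  s <- pred$score[o]
  t <- truth[o]
  grp_end <- cumsum(rle(s)$lengths)
  thr <- s[grp_end]
  tp <- cumsum(t)[grp_end]
  fp <- grp_end - tp
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fp / nn),
                    tpr = c(0, tp / np))
  prec <- tp / grp_end
  pr <- data.frame(threshold = c(Inf, thr), recall = c(0, tp / np),
                   precision = c(prec[1], prec))
  list(roc = roc, pr = pr)
}

#' Evaluate every panel under every model
#'
#' Full cross of panels and model specifications: each combination is run
#' through [loocv_predict()] and [compute_metrics()].
#'
#' @param m an `ExpressionMatrix`.
#' @param panels named list of `FeaturePanel`s (>= 1).
#' @param specs named list of [model_spec()]s (>= 1).
#' @param selection_mode passed to [loocv_predict()] (`fixed_panel` default).
#' @return `data.frame(panel, family, n_features, accuracy, precision,
#'   recall, f1, aupr, auc)` with the per-sample `PredictionVector`s attached
#'   as the `predictions` attribute (a named list, for violin/curve plots).
#' @export
compare_panels <- function(m, panels, specs, selection_mode = "fixed_panel") {
  stopifnot(length(panels) >= 1, length(specs) >= 1)
  if (is.null(names(panels))) {
    names(panels) <- vapply(panels, function(p) p$method, "")
  }
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$family, "")
  }
  rows <- list()
  preds <- list()
  for (pn in names(panels)) {
    for (sn in names(specs)) {
      pred <- loocv_predict(m, panels[[pn]], specs[[sn]],
                            selection_mode = selection_mode)
      met <- compute_metrics(pred)
      key <- paste(pn, sn, sep = ".")
      preds[[key]] <- pred
      rows[[key]] <- data.frame(panel = pn, family = specs[[sn]]$family,
                                n_features = length(panels[[pn]]),
                                as.data.frame(unclass(met)),
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "predictions") <- preds
  out
}
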