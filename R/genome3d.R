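# genome3d module: contact -> distance conversion, multi-restart stress
# minimization embedding, structure comparison and TSS -> coordinate mapping.

#' Construct a 3D genome model
#'
#' @param coords numeric matrix with one row per bin and columns x, y, z; all
#'   entries finite.
#' @param stress final normalized Kruskal stress of the embedding (>= 0).
#' @param n_restarts_used number of restarts actually run.
#' @param restart_stress optional numeric vector of the final stress of each
#'   restart.
#' @param converged logical; `FALSE` flags that no restart reached the
#'   convergence tolerance within `max_iter`.
#' @return An object of class `Genome3DModel`.
#' @export
genome3d_model <- function(coords, stress, n_restarts_used,
                           restart_stress = NULL, converged = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns", call. = FALSE)
  if (any(!is.finite(coords))) stop("coords must be finite", call. = FALSE)
  if (stress < 0) stop("stress must be >= 0", call. = FALSE)
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, stress = stress,
                 n_restarts_used = as.integer(n_restarts_used),
                 restart_stress = restart_stress, converged = converged),
            class = "Genome3DModel")
}

#' @export
print.Genome3DModel <- function(x, ...) {
  cat(sprintf("Genome3DModel: %d bins, stress %.4g (%d restarts%s)\n",
              nrow(x$coords), x$stress, x$n_restarts_used,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Convert a contact matrix into wish distances
#'
#' Applies the standard inverse power-law conversion `d_ij = c_ij^-alpha` to
#' positive contacts; pairs with zero contacts receive a capped distance of
#' `cap_factor` times the largest finite converted distance.
#'
#' @param contacts a `ContactMatrix` or a plain symmetric count matrix.
#' @param alpha conversion exponent, > 0.
#' @param cap_factor multiplier (> 1 recommended) for the zero-contact cap.
#' @return An object of class `DistanceTargets`: list with `wish` (symmetric
#'   positive matrix, zero diagonal), `alpha` and `cap`.
#' @export
contacts_to_distances <- function(contacts, alpha = 1, cap_factor = 1.5) {
  if (alpha <= 0) stop_config("alpha must be > 0")
  C <- if (inherits(contacts, "ContactMatrix")) contacts$counts else contacts
  off <- C[upper.tri(C)]
  if (all(off == 0)) {
    stop("all-zero contact matrix carries no distance information", call. = FALSE)
  }
  W <- ifelse(C > 0, C^(-alpha), NA_real_)
  diag(W) <- 0
  cap <- cap_factor * max(W[upper.tri(W)], na.rm = TRUE)
  W[is.na(W)] <- cap
  diag(W) <- 0
  distance_targets(W, alpha = alpha, cap = cap)
}

#' Construct distance targets directly
#'
#' @param wish symmetric matrix of positive target distances (zero diagonal).
#' @param alpha exponent used to derive the targets (`NA` when built directly
#'   from known distances).
#' @param cap distance assigned to zero-contact pairs.
#' @return A `DistanceTargets` object.
#' @export
distance_targets <- function(wish, alpha = NA_real_, cap = max(wish)) {
  wish <- as.matrix(wish)
  if (!isTRUE(all.equal(wish, t(wish)))) {
    stop("wish distances must be symmetric", call. = FALSE)
  }
  off <- wish[upper.tri(wish)]
  if (any(off <= 0) || any(off > cap + 1e-12)) {
    stop("wish distances must lie in (0, cap]", call. = FALSE)
  }
  structure(list(wish = wish, alpha = alpha, cap = cap),
            class = "DistanceTargets")
}

#' Normalized Kruskal stress
#'
#' `sqrt(sum_(i<j) (dhat_ij - d_ij)^2 / sum_(i<j) d_ij^2)` where `dhat` are
#' the realized pairwise distances of `coords` and `d` the wish distances.
#' Zero exactly when the configuration realizes the targets.
#'
#' @param coords numeric n x 3 coordinate matrix.
#' @param targets a `DistanceTargets` (or plain wish-distance matrix).
#' @return Nonnegative scalar.
#' @export
kruskal_stress <- function(coords, targets) {
  W <- if (inherits(targets, "DistanceTargets")) targets$wish else as.matrix(targets)
  if (nrow(coords) != nrow(W)) stop("shapes do not agree", call. = FALSE)
  D <- as.matrix(dist(coords))
  up <- upper.tri(W)
  sqrt(sum((D[up] - W[up])^2) / sum(W[up]^2))
}

# one SMACOF (majorization) run from a given start; monotone in raw stress
smacof_run <- function(W, X, max_iter, tol) {
  n <- nrow(W)
  s_prev <- kruskal_stress(X, W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- as.matrix(dist(X))
    R <- W / D
    R[!is.finite(R)] <- 0
    B <- -R
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    s <- kruskal_stress(X, W)
    if (s_prev - s < tol * max(s_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    s_prev <- s
  }
  list(X = X, stress = s, converged = converged)
}

raw_stress_value <- function(x, W) {
  X <- matrix(x, ncol = 3)
  D <- as.matrix(dist(X))
  sum(((D - W)[upper.tri(W)])^2)
}

raw_stress_grad <- function(x, W) {
  X <- matrix(x, ncol = 3)
  D <- as.matrix(dist(X))
  diag(D) <- 1
  F <- (D - W) / D
  diag(F) <- 0
  as.vector(2 * (diag(rowSums(F)) %*% X - F %*% X))
}

#' Embed wish distances into 3D by multi-restart stress minimization
#'
#' Runs `n_restarts` independent majorization (SMACOF-type) minimizations of
#' the Kruskal stress from random initial coordinates and returns the
#' conformation with the lowest final stress, optionally polished by a
#' quasi-Newton refinement. This mirrors the generate-many-conformations,
#' keep-the-best-matched protocol of physical 3D genome reconstruction, with
#' "best-matched" operationalized as minimum normalized stress.
#'
#' @param targets a `DistanceTargets`.
#' @param n_restarts number of random restarts (>= 1). The package default
#'   mirrors the 300-conformation protocol; small values (e.g. 5) are adequate
#'   for desk-scale problems.
#' @param max_iter majorization iteration cap per restart.
#' @param tol relative stress-decrease threshold for convergence.
#' @param seed integer seed; the result is deterministic given it.
#' @param polish if `TRUE`, refine the best restart with BFGS on the raw
#'   stress (kept only when it improves).
#' @return A `Genome3DModel` with per-restart final stresses in
#'   `restart_stress`. If no restart converged within `max_iter` the best
#'   conformation so far is returned with `converged = FALSE` and a warning.
#' @export
embed_structure <- function(targets, n_restarts = 300L, max_iter = 500L,
                            tol = 1e-9, seed = 1L, polish = TRUE) {
  stopifnot(inherits(targets, "DistanceTargets"))
  if (n_restarts < 1) stop_config("n_restarts must be >= 1")
  W <- targets$wish
  n <- nrow(W)
  best <- NULL
  restart_stress <- numeric(n_restarts)
  any_converged <- FALSE
  for (r in seq_len(n_restarts)) {
    set.seed(substream_seed(seed, r))
    X0 <- matrix(runif(n * 3, -1, 1) * max(W) / 2, ncol = 3)
    fit <- smacof_run(W, X0, max_iter, tol)
    restart_stress[r] <- fit$stress
    any_converged <- any_converged || fit$converged
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (polish) {
    o <- tryCatch(
      optim(as.vector(best$X), raw_stress_value, raw_stress_grad, W = W,
            method = "BFGS", control = list(maxit = 300, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(o)) {
      Xp <- matrix(o$par, ncol = 3)
      sp <- kruskal_stress(Xp, W)
      if (sp < best$stress) best <- list(X = Xp, stress = sp)
    }
  }
  if (!any_converged) {
    warning("no restart converged within max_iter; returning best-so-far",
            call. = FALSE)
  }
  rownames(best$X) <- rownames(W)
  genome3d_model(best$X, stress = best$stress, n_restarts_used = n_restarts,
                 restart_stress = restart_stress, converged = any_converged)
}

#' Procrustes RMSD between two point configurations
#'
#' Root-mean-square deviation after optimal translation, rotation, uniform
#' scaling and (optionally) reflection of `b` onto `a`. Invariant under rigid
#' motions and global rescaling, so it compares shapes regardless of the
#' arbitrary frame of an embedding.
#'
#' @param a,b numeric matrices of identical dimensions (>= 3 rows).
#' @param allow_reflection if `TRUE` (default) mirror images count as a
#'   perfect match.
#' @return Nonnegative scalar RMSD.
#' @export
procrustes_rmsd <- function(a, b, allow_reflection = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) || nrow(a) < 3) {
    stop("inputs must have identical dimensions with >= 3 rows", call. = FALSE)
  }
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  if (sum(ac^2) == 0 || sum(bc^2) == 0) {
    stop("degenerate (all-coincident) configuration", call. = FALSE)
  }
  s <- svd(t(bc) %*% ac)
  d_sign <- rep(1, length(s$d))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    d_sign[length(d_sign)] <- -1
    R <- s$u %*% diag(d_sign) %*% t(s$v)
  }
  sc <- sum(s$d * d_sign) / sum(bc^2)
  sqrt(mean(rowSums((ac - sc * bc %*% R)^2)))
}

#' Map miRNA TSSs onto 3D bin coordinates
#'
#' Each uniquely mapped miRNA is assigned the bin whose 0-based half-open
#' interval `[start, end)` contains its TSS and inherits that bin's
#' coordinates. Non-unique miRNAs, records on chromosomes absent from the bin
#' table, and TSSs outside every bin are dropped; the counts are logged.
#'
#' @param annotation annotation table (`mirna_id, chrom, tss, strand, unique`).
#' @param bins bin table matching `model`.
#' @param model a `Genome3DModel` with one coordinate row per bin.
#' @return `data.frame(mirna_id, bin_id, x, y, z)` sorted by `mirna_id`
#'   (hence invariant to annotation row order).
#' @export
map_tss_to_coords <- function(annotation, bins, model) {
  if (nrow(model$coords) != nrow(bins)) {
    stop("model does not match the bin table", call. = FALSE)
  }
  n_nonuniq <- length(unique(annotation$mirna_id[!annotation$unique]))
  ann <- annotation[annotation$unique, , drop = FALSE]
  bin_id <- rep(NA_integer_, nrow(ann))
  for (ch in unique(ann$chrom)) {
    rows <- which(ann$chrom == ch)
    sub <- bins[bins$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    j <- findInterval(ann$tss[rows], sub$start)
    ok <- j >= 1 & j <= nrow(sub)
    ok[ok] <- ann$tss[rows][ok] < sub$end[j[ok]]
    bin_id[rows[ok]] <- sub$bin_id[j[ok]]
  }
  dropped <- sum(is.na(bin_id))
  if (n_nonuniq > 0 || dropped > 0) {
    mir3d_log("map_tss_to_coords",
              sprintf("dropped %d non-unique miRNA(s) and %d record(s) outside the binned genome",
                      n_nonuniq, dropped),
              level = "WARN")
  }
  ann <- ann[!is.na(bin_id), , drop = FALSE]
  bin_id <- bin_id[!is.na(bin_id)]
  idx <- match(bin_id, bins$bin_id)
  out <- data.frame(mirna_id = ann$mirna_id, bin_id = bin_id,
                    x = model$coords[idx, 1], y = model$coords[idx, 2],
                    z = model$coords[idx, 3], stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
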