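# Pipeline orchestration: runs the stages in canonical order against an
# output directory and emits a reproducibility manifest.

STAGES <- c("simulate", "reconstruct", "profile", "select", "evaluate")

pipe_path <- function(outdir, name) file.path(outdir, name)

require_inputs <- function(stage, outdir, files) {
  missing <- files[!file.exists(pipe_path(outdir, files))]
  if (length(missing) > 0) {
    stop(sprintf("stage '%s': missing input(s): %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

stage_simulate <- function(cfg, outdir) {
  sim <- cfg$sim
  sim$seed <- NULL
  ds <- simulate_dataset(do.call(sim_config, c(sim, list(seed = cfg$seed))))
  write_expression(ds$expr, pipe_path(outdir, "expression.tsv"),
                   pipe_path(outdir, "labels.tsv"))
  write_annotation_bed(ds$annotation, pipe_path(outdir, "annotation.bed"))
  write_bins(ds$bins, pipe_path(outdir, "bins_full.bed"))
  write_bins(ds$bins_3d, pipe_path(outdir, "bins_3d.bed"))
  write_contacts(ds$contacts, pipe_path(outdir, "contacts.tsv"))
  write_coords(ds$structure, ds$bins_3d, pipe_path(outdir, "true_coords.tsv"))
  jsonlite::write_json(
    list(informative_mirnas = ds$truth$informative_mirnas,
         informative_clusters = ds$truth$informative_clusters,
         effect_size = ds$truth$effect_size,
         control_ids = ds$truth$control_ids),
    pipe_path(outdir, "truth.json"), auto_unbox = FALSE, digits = NA
  )
  c("expression.tsv", "labels.tsv", "annotation.bed", "bins_full.bed",
    "bins_3d.bed", "contacts.tsv", "true_coords.tsv", "truth.json")
}

stage_reconstruct <- function(cfg, outdir) {
  require_inputs("reconstruct", outdir, c("contacts.tsv", "bins_3d.bed"))
  bins <- read_bins(pipe_path(outdir, "bins_3d.bed"))
  contacts <- read_contacts(pipe_path(outdir, "contacts.tsv"), bins)
  emb <- cfg$embedding
  targets <- contacts_to_distances(contacts, alpha = emb$alpha,
                                   cap_factor = emb$cap_factor)
  model <- embed_structure(targets, n_restarts = emb$n_restarts,
                           max_iter = emb$max_iter, tol = emb$tol,
                           seed = substream_seed(cfg$seed, 11L))
  write_coords(model, bins, pipe_path(outdir, "coords.tsv"))
  jsonlite::write_json(
    list(stress = model$stress, restart_stress = model$restart_stress,
         chosen_restart = which.min(model$restart_stress),
         converged = model$converged,
         seed = substream_seed(cfg$seed, 11L)),
    pipe_path(outdir, "embed_report.json"), auto_unbox = TRUE, digits = NA
  )
  c("coords.tsv", "embed_report.json")
}

stage_profile <- function(cfg, outdir) {
  require_inputs("profile", outdir,
                 c("expression.tsv", "labels.tsv", "annotation.bed"))
  raw <- read_expression(pipe_path(outdir, "expression.tsv"),
                         pipe_path(outdir, "labels.tsv"))
  ann <- read_annotation_bed(pipe_path(outdir, "annotation.bed"))
  m <- normalize_by_controls(raw, cfg$control_ids)
  m <- filter_ambiguous(m, ann)
  m <- filter_low_expression(m, min_score = cfg$filter$min_score,
                             min_samples = cfg$filter$min_samples)
  write_expression(m, pipe_path(outdir, "expression_filtered.tsv"))
  "expression_filtered.tsv"
}

stage_select <- function(cfg, outdir) {
  require_inputs("select", outdir,
                 c("expression_filtered.tsv", "labels.tsv", "annotation.bed",
                   "bins_3d.bed", "coords.tsv"))
  m <- read_expression(pipe_path(outdir, "expression_filtered.tsv"),
                       pipe_path(outdir, "labels.tsv"))
  ann <- read_annotation_bed(pipe_path(outdir, "annotation.bed"))
  bins <- read_bins(pipe_path(outdir, "bins_3d.bed"))
  model <- read_coords(pipe_path(outdir, "coords.tsv"))
  tab <- map_tss_to_coords(ann, bins, model)
  tab <- tab[tab$mirna_id %in% mirna_ids(m), , drop = FALSE]

  scores <- spearman_scores(m)
  write_tsv(scores, pipe_path(outdir, "scores.tsv"))

  sel <- cfg$selection
  clustering <- dbscan_cluster(tab, eps = sel$eps, min_pts = sel$min_pts)
  write_clustering(clustering, pipe_path(outdir, "clustering.tsv"))
  write_cluster_scatter(clustering, tab, pipe_path(outdir, "cluster_scatter.tsv"))

  panels <- list(
    all = all_panel(m),
    top_scc = top_k_by_score(scores, k = sel$k_top, p_max = sel$p_max),
    overlap_3d = overlap_3d_panel(m, tab),
    cluster_3d = proportional_representatives(clustering, scores,
                                              m = sel$m_representatives)
  )
  for (nm in names(panels)) {
    write_panel(panels[[nm]], pipe_path(outdir, paste0("panel_", nm, ".txt")))
  }
  c("scores.tsv", "clustering.tsv", "cluster_scatter.tsv",
    paste0("panel_", names(panels), ".txt"))
}

stage_evaluate <- function(cfg, outdir) {
  panel_files <- paste0("panel_", c("all", "top_scc", "overlap_3d",
                                    "cluster_3d"), ".txt")
  require_inputs("evaluate", outdir,
                 c("expression_filtered.tsv", "labels.tsv", panel_files))
  m <- read_expression(pipe_path(outdir, "expression_filtered.tsv"),
                       pipe_path(outdir, "labels.tsv"))
  panels <- list(
    all = read_panel(pipe_path(outdir, "panel_all.txt"), "all"),
    top_scc = read_panel(pipe_path(outdir, "panel_top_scc.txt"), "top_scc"),
    overlap_3d = read_panel(pipe_path(outdir, "panel_overlap_3d.txt"),
                            "overlap_3d"),
    cluster_3d = read_panel(pipe_path(outdir, "panel_cluster_3d.txt"),
                            "cluster_3d")
  )
  mod <- cfg$models
  specs <- lapply(mod$families, function(f) {
    model_spec(f, C = mod$C, gamma = mod$gamma, k = mod$k)
  })
  names(specs) <- mod$families
  grid <- compare_panels(m, panels, specs,
                         selection_mode = cfg$selection$selection_mode)
  utils::write.csv(grid, pipe_path(outdir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(grid, pipe_path(outdir, "metrics.json"), digits = NA)

  preds <- attr(grid, "predictions")
  long <- do.call(rbind, lapply(names(preds), function(key) {
    cbind(combo = key, as.data.frame(preds[[key]]))
  }))
  write_tsv(long, pipe_path(outdir, "predictions.tsv"))
  curves_long <- do.call(rbind, lapply(names(preds), function(key) {
    cv <- curves(preds[[key]])
    rbind(
      data.frame(combo = key, type = "roc", threshold = cv$roc$threshold,
                 x = cv$roc$fpr, y = cv$roc$tpr),
      data.frame(combo = key, type = "pr", threshold = cv$pr$threshold,
                 x = cv$pr$recall, y = cv$pr$precision)
    )
  }))
  write_tsv(curves_long, pipe_path(outdir, "curves.tsv"))
  c("metrics.csv", "metrics.json", "predictions.tsv", "curves.tsv")
}

#' Run the pipeline
#'
#' Executes the requested stages in canonical order (`simulate`,
#' `reconstruct`, `profile`, `select`, `evaluate`) against `outdir`, writing
#' every intermediate artifact to disk so stages can also be run one at a time
#' across sessions. A manifest (config snapshot, package version, per-file
#' checksums, accumulated warnings) is written to `manifest.json`; identical
#' config and seed reproduce identical outputs.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @param stages subset of the five stage names.
#' @param outdir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = STAGES,
                         outdir = tempfile("mir3d_run_")) {
  stages <- match.arg(stages, STAGES, several.ok = TRUE)
  stages <- STAGES[STAGES %in% stages]
  config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  files <- character(0)
  runner <- list(simulate = stage_simulate, reconstruct = stage_reconstruct,
                 profile = stage_profile, select = stage_select,
                 evaluate = stage_evaluate)
  for (st in stages) {
    mir3d_log(st, "stage started")
    out <- withCallingHandlers(
      runner[[st]](config, outdir),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(st, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    files <- c(files, out)
    mir3d_log(st, "stage finished")
  }
  checks <- tools::md5sum(pipe_path(outdir, files))
  names(checks) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("mir3d")),
    seed = config$seed,
    stages = stages,
    config = config,
    checksums = as.list(checks),
    warnings = warnings_seen,
    n_failures = 0L
  )
  jsonlite::write_json(manifest, pipe_path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest$outdir <- outdir
  invisible(manifest)
}
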