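# Synthetic-data module: toy genomes, ground-truth structures, Hi-C-like
# contact matrices, miRNA annotations and case/control expression with a
# planted, spatially clustered differential signal.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. The defaults define the package's reference study conditions: a
#' 100 case / 100 control cohort with 300 miRNAs of which 20 informative ones
#' are planted inside two compact spatial domains of a toy genome whose 3D
#' model covers only the first `n_chrom_3d` chromosomes (so, as in real
#' studies, only a minority of expressed miRNAs carry 3D information).
#'
#' @param seed integer; fully determines all generator output.
#' @param n_chrom,bins_per_chrom,bin_size toy genome shape (all >= 1);
#'   `bin_size` in base pairs.
#' @param n_chrom_3d number of leading chromosomes covered by the 3D model.
#' @param domain_bins bins per informative spatial domain on each 3D
#'   chromosome; the remaining bins of that chromosome form a filler domain.
#' @param n_mirna total number of simulated miRNAs (informative + background).
#' @param n_informative number of miRNAs planted inside the informative
#'   domains; these carry the differential signal.
#' @param frac_multimapped fraction in [0, 1) of background miRNAs annotated
#'   at two genomic locations (hence not uniquely mappable).
#' @param frac_low fraction of background miRNAs simulated at a low expression
#'   level (`low_meanlog`), to exercise the low-expression filter.
#' @param n_case,n_control cohort sizes.
#' @param effect_size standardized shift (in units of `sdlog`) of the log-mean
#'   of informative miRNAs in cases; must be >= 0.
#' @param meanlog,sdlog_mu per-miRNA baseline log-means are drawn once per
#'   dataset from Normal(`meanlog`, `sdlog_mu`).
#' @param sdlog within-miRNA log-scale noise SD.
#' @param low_meanlog log-mean assigned to the `frac_low` low-expression
#'   miRNAs.
#' @param sample_scale_sd log-scale SD of the per-sample technical scale
#'   factor multiplying every raw signal in a sample (what internal-control
#'   normalization is meant to remove).
#' @param compaction in [0, 1); how strongly bins are pulled toward their
#'   spatial domain centroid.
#' @param step random-walk step length of the chromosome backbone, in model
#'   units.
#' @param territory_radius radius of the ball in which chromosome territories
#'   are placed, in model units.
#' @param contact_scale,contact_decay parameters k and beta of the contact
#'   model `E[c_ij] = k * d_ij^-beta`; both must be > 0.
#' @param contact_noise `"poisson"` (counts drawn from the expectation) or
#'   `"none"` (expectation returned as-is).
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 24L, bins_per_chrom = 22L, bin_size = 1e5,
                       n_chrom_3d = 2L, domain_bins = 20L,
                       n_mirna = 300L, n_informative = 20L,
                       frac_multimapped = 0.1, frac_low = 0.05,
                       n_case = 100L, n_control = 100L,
                       effect_size = 1.0,
                       meanlog = 3.9, sdlog_mu = 0.7, sdlog = 0.5,
                       low_meanlog = 0, sample_scale_sd = 0.3,
                       compaction = 0.85, step = 1, territory_radius = 8,
                       contact_scale = 10, contact_decay = 1,
                       contact_noise = c("poisson", "none")) {
  contact_noise <- match.arg(contact_noise)
  cfg <- as.list(environment())
  counts <- c("n_chrom", "bins_per_chrom", "bin_size", "n_chrom_3d",
              "domain_bins", "n_mirna", "n_informative", "n_case", "n_control")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop_config(nm, " must be a positive count")
    }
  }
  if (frac_multimapped < 0 || frac_multimapped >= 1) {
    stop_config("frac_multimapped must be in [0, 1)")
  }
  if (frac_low < 0 || frac_low >= 1) stop_config("frac_low must be in [0, 1)")
  if (effect_size < 0) stop_config("effect_size must be >= 0")
  if (compaction < 0 || compaction >= 1) stop_config("compaction must be in [0, 1)")
  if (contact_scale <= 0 || contact_decay <= 0) {
    stop_config("contact_scale and contact_decay must be > 0")
  }
  if (n_chrom_3d > n_chrom) stop_config("n_chrom_3d cannot exceed n_chrom")
  if (domain_bins > bins_per_chrom) {
    stop_config("domain_bins cannot exceed bins_per_chrom")
  }
  if (n_informative > n_mirna) stop_config("n_informative cannot exceed n_mirna")
  structure(cfg, class = "SimConfig")
}

#' Build a toy binned genome
#'
#' @param n_chrom,bins_per_chrom,bin_size all >= 1; `bin_size` in base pairs.
#' @return A bin table: `data.frame(bin_id, chrom, start, end)` with dense
#'   0-based `bin_id` in genome order and 0-based half-open bin intervals that
#'   restart at 0 on every chromosome.
#' @examples
#' make_toy_genome(2, 3, 100)
#' @export
make_toy_genome <- function(n_chrom, bins_per_chrom, bin_size) {
  for (v in c(n_chrom, bins_per_chrom, bin_size)) {
    if (length(v) != 1 || is.na(v) || v < 1) {
      stop_config("make_toy_genome arguments must all be >= 1")
    }
  }
  n_chrom <- as.integer(n_chrom); bins_per_chrom <- as.integer(bins_per_chrom)
  starts <- (seq_len(bins_per_chrom) - 1L) * bin_size
  data.frame(
    bin_id = seq_len(n_chrom * bins_per_chrom) - 1L,
    chrom = rep(paste0("chr", seq_len(n_chrom)), each = bins_per_chrom),
    start = rep(starts, n_chrom),
    end = rep(starts + bin_size, n_chrom),
    stringsAsFactors = FALSE
  )
}

#' Simulate a ground-truth 3D genome structure
#'
#' Each chromosome is laid down as a fixed-step 3D random walk starting at a
#' random point inside a territory ball; bins are then pulled toward the
#' centroid of their spatial domain by `compaction`, producing compact,
#' TAD-like blobs.
#'
#' @param bins bin table from [make_toy_genome()].
#' @param n_domains either a single integer >= 1 (bins are split into that
#'   many contiguous, near-equal blocks in genome order) or an integer vector
#'   giving the domain id of every bin.
#' @param compaction in [0, 1); 0 leaves the pure random walk.
#' @param seed integer seed; the output is deterministic given it.
#' @param step,territory_radius backbone step length and territory ball
#'   radius, in model units.
#' @return A `Genome3DModel` (see [genome3d_model()]) whose `domains`
#'   element records the per-bin domain id.
#' @export
simulate_structure <- function(bins, n_domains, compaction, seed = 1L,
                               step = 1, territory_radius = 8) {
  if (compaction < 0 || compaction >= 1) {
    stop_config("compaction must be in [0, 1)")
  }
  n <- nrow(bins)
  if (length(n_domains) == 1L) {
    if (n_domains < 1) stop_config("n_domains must be >= 1")
    domains <- as.integer(cut(seq_len(n), breaks = n_domains, labels = FALSE))
  } else {
    if (length(n_domains) != n) {
      stop_config("per-bin domain vector must have one entry per bin")
    }
    domains <- as.integer(n_domains)
  }
  set.seed(seed)
  coords <- matrix(NA_real_, n, 3, dimnames = list(bins$bin_id, c("x", "y", "z")))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    origin <- runif_ball(1, territory_radius)
    dirs <- matrix(rnorm(length(idx) * 3), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2)) * step
    coords[idx, ] <- apply(dirs, 2, cumsum) +
      matrix(origin, length(idx), 3, byrow = TRUE)
  }
  for (d in unique(domains)) {
    idx <- domains == d
    cen <- colMeans(coords[idx, , drop = FALSE])
    coords[idx, ] <- sweep(
      sweep(coords[idx, , drop = FALSE], 2, cen) * (1 - compaction), 2, cen, "+"
    )
  }
  model <- genome3d_model(coords, stress = 0, n_restarts_used = 0L)
  model$domains <- domains
  model
}

#' Generate a Hi-C-like contact matrix from a 3D structure
#'
#' Expected counts follow the inverse power law `E[c_ij] = k * d_ij^-beta`
#' for distinct bins i, j; the diagonal is zero and the matrix symmetric.
#'
#' @param model a `Genome3DModel` with at least 2 bins.
#' @param bins bin table matching the model.
#' @param beta,k decay exponent and scale, both > 0.
#' @param seed seed for the noise draw (ignored for `noise = "none"`).
#' @param noise `"none"` returns the expectation; `"poisson"` draws counts.
#' @return A `ContactMatrix`.
#' @export
structure_to_contacts <- function(model, bins, beta = 1, k = 10, seed = 1L,
                                  noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (beta <= 0 || k <= 0) stop_config("beta and k must be > 0")
  X <- model$coords
  if (nrow(X) < 2) stop_config("model must have at least 2 bins")
  D <- as.matrix(dist(X))
  zero <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    stop(sprintf("coincident bins (distance 0): bin pair (%d, %d)",
                 zero[1, 1] - 1L, zero[1, 2] - 1L), call. = FALSE)
  }
  E <- k * D^(-beta)
  diag(E) <- 0
  if (noise == "poisson") {
    set.seed(seed)
    up <- upper.tri(E)
    C <- matrix(0, nrow(E), ncol(E))
    C[up] <- rpois(sum(up), E[up])
    C <- C + t(C)
  } else {
    C <- E
  }
  dimnames(C) <- dimnames(D)
  contact_matrix(C, bins)
}

#' Simulate a miRNA TSS annotation
#'
#' TSS positions are uniform over the genome. Exactly
#' `round(frac_multimapped * n_mirna)` miRNAs are multi-mapped: they receive a
#' second record at an independent location, and all their records carry
#' `unique = FALSE`.
#'
#' @param bins bin table defining the genome.
#' @param n_mirna number of miRNAs (>= 1).
#' @param frac_multimapped fraction in [0, 1) of non-uniquely mapped miRNAs.
#' @param seed integer seed.
#' @param ids optional character vector of miRNA ids (default
#'   `"miR-001"...`).
#' @return `data.frame(mirna_id, chrom, tss, strand, unique)`, one row per
#'   mapping.
#' @export
make_annotation <- function(bins, n_mirna, frac_multimapped = 0, seed = 1L,
                            ids = NULL) {
  if (n_mirna < 1) stop_config("n_mirna must be >= 1")
  if (frac_multimapped < 0 || frac_multimapped >= 1) {
    stop_config("frac_multimapped must be in [0, 1)")
  }
  set.seed(seed)
  if (is.null(ids)) ids <- sprintf("miR-%03d", seq_len(n_mirna))
  stopifnot(length(ids) == n_mirna)
  n_mm <- round(frac_multimapped * n_mirna)
  mm_ids <- if (n_mm > 0) sample(ids, n_mm) else character(0)
  draw_tss <- function(n) {
    b <- sample(nrow(bins), n, replace = TRUE)
    data.frame(
      chrom = bins$chrom[b],
      tss = floor(bins$start[b] + runif(n) * (bins$end[b] - bins$start[b])),
      stringsAsFactors = FALSE
    )
  }
  primary <- draw_tss(n_mirna)
  ann <- data.frame(
    mirna_id = ids, primary,
    strand = sample(c("+", "-"), n_mirna, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (n_mm > 0) {
    extra <- draw_tss(n_mm)
    ann <- rbind(ann, data.frame(
      mirna_id = mm_ids, extra,
      strand = sample(c("+", "-"), n_mm, replace = TRUE),
      stringsAsFactors = FALSE
    ))
  }
  ann$unique <- !(ann$mirna_id %in% mm_ids)
  ann <- ann[order(ann$mirna_id, ann$chrom, ann$tss), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Simulate case/control miRNA expression with a planted signal
#'
#' Background expression is log-normal with a per-miRNA log-mean drawn once
#' per dataset. miRNAs located in the designated informative spatial clusters
#' have their log-mean shifted by `effect_size * sdlog` in cases only. Three
#' internal-control miRNAs with case-independent expectation are appended, and
#' every sample's raw column is multiplied by a technical scale factor so that
#' internal-control normalization is meaningful.
#'
#' @param annotation annotation table from [make_annotation()].
#' @param clustering_truth list with `assignment` (named vector mapping
#'   miRNA id to its ground-truth spatial cluster, `NA` when unmapped) and
#'   `informative_clusters` (cluster ids carrying the signal).
#' @param cfg a [sim_config()].
#' @return List with `expr` (raw `ExpressionMatrix`, controls included) and
#'   `truth` (a `GroundTruth` list: `informative_mirnas`, `effect_size`,
#'   `informative_clusters`, `control_ids`).
#' @export
simulate_expression <- function(annotation, clustering_truth, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  assignment <- clustering_truth$assignment
  informative_clusters <- clustering_truth$informative_clusters
  ids <- unique(annotation$mirna_id)
  if (length(ids) < 3) stop_config("fewer than 3 miRNAs available for controls")
  informative <- ids[!is.na(assignment[ids]) &
                       assignment[ids] %in% informative_clusters]
  if (cfg$effect_size > 0 && length(informative) == 0) {
    stop_config("effect_size > 0 but no miRNA maps into an informative cluster")
  }
  set.seed(substream_seed(cfg$seed, 4L))
  n <- cfg$n_case + cfg$n_control
  samples <- c(sprintf("AD_%03d", seq_len(cfg$n_case)),
               sprintf("NC_%03d", seq_len(cfg$n_control)))
  labels <- setNames(rep(c(1L, 0L), c(cfg$n_case, cfg$n_control)), samples)

  mu <- rnorm(length(ids), cfg$meanlog, cfg$sdlog_mu)
  names(mu) <- ids
  background <- setdiff(ids, informative)
  n_low <- round(cfg$frac_low * length(background))
  if (n_low > 0) mu[sample(background, n_low)] <- cfg$low_meanlog

  shift <- cfg$effect_size * cfg$sdlog
  meanlog <- outer(mu, rep(0, n), "+")
  meanlog[informative, labels == 1L] <- meanlog[informative, labels == 1L] + shift
  sig <- matrix(rlnorm(length(ids) * n, as.vector(meanlog), cfg$sdlog),
                nrow = length(ids), dimnames = list(ids, samples))

  control_ids <- sprintf("ctl-miR-%d", 1:3)
  ctl <- matrix(rlnorm(3 * n, 0, 0.1), nrow = 3,
                dimnames = list(control_ids, samples))
  sig <- rbind(sig, ctl)
  scale_fac <- exp(rnorm(n, 0, cfg$sample_scale_sd))
  sig <- sweep(sig, 2, scale_fac, "*")

  truth <- list(
    informative_mirnas = informative,
    effect_size = cfg$effect_size,
    informative_clusters = informative_clusters,
    control_ids = control_ids
  )
  list(expr = expression_matrix(sig, labels), truth = truth)
}

#' Generate a complete synthetic study
#'
#' Orchestrates the full generator: toy genome, ground-truth structure over
#' the 3D-covered chromosomes (per chromosome one compact informative domain
#' of `domain_bins` bins plus a small filler domain), Hi-C-like contacts,
#' annotation (informative miRNAs planted inside the informative domains,
#' background miRNAs uniform over the rest of the genome) and the raw
#' expression matrix. All randomness fans out from `cfg$seed` via per-stage
#' substreams.
#'
#' @param cfg a [sim_config()].
#' @return List with elements `config`, `bins` (full genome), `bins_3d`,
#'   `structure` (ground-truth `Genome3DModel`), `contacts`, `annotation`,
#'   `expr`, `truth` and `clustering_truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  bins <- make_toy_genome(cfg$n_chrom, cfg$bins_per_chrom, cfg$bin_size)
  bins_3d <- bins[bins$chrom %in% paste0("chr", seq_len(cfg$n_chrom_3d)), ]
  bins_3d$bin_id <- seq_len(nrow(bins_3d)) - 1L
  rownames(bins_3d) <- NULL

  # two domains per 3D chromosome: informative block + filler tail
  per_chrom <- rep(c(1L, 2L), c(cfg$domain_bins, cfg$bins_per_chrom - cfg$domain_bins))
  domains <- as.integer(per_chrom +
    rep((seq_len(cfg$n_chrom_3d) - 1L) * 2L, each = cfg$bins_per_chrom))
  informative_clusters <- seq(1L, by = 2L, length.out = cfg$n_chrom_3d)

  structure3d <- simulate_structure(
    bins_3d, domains, cfg$compaction, seed = substream_seed(cfg$seed, 1L),
    step = cfg$step, territory_radius = cfg$territory_radius
  )
  contacts <- structure_to_contacts(
    structure3d, bins_3d, beta = cfg$contact_decay, k = cfg$contact_scale,
    seed = substream_seed(cfg$seed, 2L), noise = cfg$contact_noise
  )

  # annotation: planted informative TSSs inside informative-domain bins;
  # background uniform over the remaining genome (multi-mapping there only)
  set.seed(substream_seed(cfg$seed, 3L))
  all_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
  planted_ids <- sort(sample(all_ids, cfg$n_informative))
  inf_bins <- bins_3d[structure3d$domains %in% informative_clusters, ]
  b <- sample(nrow(inf_bins), cfg$n_informative, replace = TRUE)
  planted <- data.frame(
    mirna_id = planted_ids,
    chrom = inf_bins$chrom[b],
    tss = floor(inf_bins$start[b] +
                  runif(cfg$n_informative) * (inf_bins$end[b] - inf_bins$start[b])),
    strand = sample(c("+", "-"), cfg$n_informative, replace = TRUE),
    unique = TRUE,
    stringsAsFactors = FALSE
  )
  bg_bins <- background_bins(bins, bins_3d, structure3d$domains, informative_clusters)
  background <- make_annotation(
    bg_bins, cfg$n_mirna - cfg$n_informative,
    frac_multimapped = cfg$frac_multimapped,
    seed = substream_seed(cfg$seed, 5L),
    ids = setdiff(all_ids, planted_ids)
  )
  annotation <- rbind(planted, background)
  annotation <- annotation[order(annotation$mirna_id, annotation$chrom,
                                 annotation$tss), ]
  rownames(annotation) <- NULL

  # ground-truth spatial assignment by TSS bin of uniquely mapped miRNAs
  map <- map_tss_to_coords(annotation, bins_3d, structure3d)
  assignment <- setNames(rep(NA_integer_, cfg$n_mirna), all_ids)
  assignment[map$mirna_id] <- structure3d$domains[map$bin_id + 1L]
  clustering_truth <- list(assignment = assignment,
                           informative_clusters = informative_clusters)

  sim <- simulate_expression(annotation, clustering_truth, cfg)
  sim$truth$true_coords <- structure3d$coords

  list(config = cfg, bins = bins, bins_3d = bins_3d, structure = structure3d,
       contacts = contacts, annotation = annotation, expr = sim$expr,
       truth = sim$truth, clustering_truth = clustering_truth)
}

# bins outside the informative domains (other chromosomes + filler bins)
background_bins <- function(bins, bins_3d, domains, informative_clusters) {
  inf <- bins_3d[domains %in% informative_clusters, c("chrom", "start")]
  key <- paste(bins$chrom, bins$start)
  bins[!(key %in% paste(inf$chrom, inf$start)), , drop = FALSE]
}
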