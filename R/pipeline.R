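# End-to-end orchestration: ingest/simulate -> QC -> clonotype -> diversity
# -> network -> clone dynamics -> IGHV usage.

#' Run the full repertoire analysis pipeline
#'
#' Executes all stages in order on either a simulated cohort or AIRR input
#' files, with one global seed fanned out to per-stage seeds so every
#' stochastic stage is independently reproducible.  Re-running with the
#' same configuration and seed reproduces all tables exactly.
#'
#' @param config A list:
#'   \describe{
#'     \item{simulation}{a [simulation_config()] (mutually exclusive with
#'       `airr_path`/`meta_path`)}
#'     \item{airr_path, meta_path}{input files for real data}
#'     \item{identity_threshold}{CDR3 identity threshold (default 0.90)}
#'     \item{min_clones}{sample retention threshold (default 100)}
#'     \item{downsample}{`NULL` to skip, or a list with `depth`,
#'       `n_replicates`, `min_reads`}
#'     \item{covariates}{covariate names for model adjustment}
#'     \item{fdr}{FDR level for usage flagging (default 0.05)}
#'     \item{usage_filter}{list with `min_usage`, `min_prevalence`}
#'     \item{enrich_gene}{gene tested for enrichment among shared
#'       persistent clones (default `"IGHV3-23"`)}
#'     \item{outdir}{optional directory; all result tables are written as
#'       TSV}
#'   }
#' @param seed Global integer seed.
#' @return A `bcrdyn_run` object: per-stage results (`qc`, `diversity`,
#'   `network`, `models`, `clone_dynamics`, `usage`, ...) plus a manifest
#'   of stage row counts and seeds.
#' @export
run_pipeline <- function(config = list(), seed = 1L) {
  cfg <- config
  identity_threshold <- cfg$identity_threshold %||% 0.90
  min_clones <- cfg$min_clones %||% 100
  covariates <- cfg$covariates
  fdr <- cfg$fdr %||% 0.05
  usage_filter <- cfg$usage_filter %||% list(min_usage = 0.05,
                                             min_prevalence = 0.10)
  enrich_gene <- cfg$enrich_gene %||% "IGHV3-23"
  manifest <- list(seed = seed, stages = list())
  note_stage <- function(name, n) {
    manifest$stages[[name]] <<- n
  }

  # stage 1: input
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- generate_cohort(cfg$simulation, seed = derive_seed(seed, 1))
    reads <- sim$reads
    meta <- sim$meta
    truth <- sim$truth
  } else {
    if (is.null(cfg$airr_path) || is.null(cfg$meta_path)) {
      stop("config needs either `simulation` or `airr_path` + `meta_path`")
    }
    meta <- read_table(cfg$meta_path)
    reads <- read_rearrangements(cfg$airr_path, meta)
  }
  note_stage("input_reads", nrow(reads))

  # stage 2: read QC
  flt <- filter_reads(reads)
  note_stage("qc_retained", nrow(flt$reads))

  # stage 3: clonotyping (pooled) + sample QC
  asg <- assign_clones(flt$reads, identity_threshold, scope = "pooled")
  fs <- filter_samples(asg, min_clones)
  reads_ok <- fs$reads
  meta_ok <- meta[meta$sample_id %in% fs$retained, , drop = FALSE]
  note_stage("samples_retained", length(fs$retained))
  if (!length(fs$retained)) {
    stop("no samples retained after the ", min_clones, "-clone filter")
  }

  # stage 4: diversity + models
  div <- sample_diversity(reads_ok)
  down <- NULL
  if (!is.null(cfg$downsample)) {
    ds <- cfg$downsample
    down <- downsample_diversity(reads_ok, depth = ds$depth,
                                 n_replicates = ds$n_replicates %||% 10,
                                 seed = derive_seed(seed, 4),
                                 min_reads = ds$min_reads %||% 1000,
                                 identity_threshold = identity_threshold)
  }
  times <- sort(unique(meta_ok$time_months))
  cross <- list()
  for (t in times) {
    cross[[paste0("t", t)]] <- list(
      richness = fit_cross_sectional(div, meta_ok, "richness", t,
                                     covariates),
      entropy = fit_cross_sectional(div, meta_ok, "entropy", t, covariates)
    )
  }
  lmm <- list(
    richness = fit_growth_lmm(div, meta_ok, "richness", covariates),
    entropy = fit_growth_lmm(div, meta_ok, "entropy", covariates)
  )
  note_stage("diversity_samples", nrow(div))

  # stage 5: network
  nw <- network_summary(reads_ok)
  gini_models <- list()
  for (t in times) {
    gini_models[[paste0("t", t)]] <- list(
      gini_v = fit_cross_sectional(nw, meta_ok, "gini_v", t, covariates),
      gini_c = fit_cross_sectional(nw, meta_ok, "gini_c", t, covariates)
    )
  }
  note_stage("network_samples", nrow(nw))

  # stage 6: clone dynamics
  mat <- build_clone_matrix(reads_ok, restrict_multi_sample = TRUE)
  assoc <- list()
  for (t in times) {
    assoc[[paste0("t", t)]] <- tryCatch(
      clone_outcome_association(mat, meta_ok, t),
      error = function(e) NULL
    )
  }
  track <- find_persistent_clones(reads_ok)
  pers_models <- model_persistence_and_expansion(track, meta_ok)
  note_stage("multi_sample_clones", nrow(mat))

  # stage 7: IGHV usage
  usage <- compute_usage(reads_ok)
  usage_f <- filter_low_usage(usage, usage_filter$min_usage %||% 0.05,
                              usage_filter$min_prevalence %||% 0.10)
  diff_usage <- list()
  for (t in times) {
    diff_usage[[paste0("t", t)]] <- tryCatch(
      differential_usage(usage_f, meta_ok, t, covariates, fdr = fdr),
      error = function(e) NULL
    )
  }
  # enrichment of the focal gene among persistent shared clones
  clone_genes <- tapply(reads_ok$v_gene, reads_ok$clone_id,
                        function(x) x[1])
  shared_pers <- unique(track$clone_id[track$persistent & track$shared])
  enrichment <- NULL
  if (length(shared_pers)) {
    enrichment <- gene_set_enrichment(enrich_gene, shared_pers,
                                      unique(track$clone_id), clone_genes)
  }
  note_stage("genes_retained", ncol(usage_f))

  run <- structure(list(
    meta = meta_ok, qc = flt$qc, sample_filter = fs["excluded"],
    reads = reads_ok, diversity = div, downsampled = down,
    models = list(cross_sectional = cross, lmm = lmm,
                  gini = gini_models),
    network = nw,
    clone_dynamics = list(matrix = mat, association = assoc,
                          track = track, models = pers_models,
                          enrichment = enrichment),
    usage = list(matrix = usage, filtered = usage_f,
                 differential = diff_usage),
    truth = truth,
    manifest = manifest
  ), class = "bcrdyn_run")

  if (!is.null(cfg$outdir)) write_run(run, cfg$outdir)
  run
}

# write the standard result tables of a pipeline run
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_table(run$qc, file.path(outdir, "qc_report.tsv"))
  write_table(run$diversity, file.path(outdir, "diversity.tsv"))
  if (!is.null(run$downsampled)) {
    write_table(run$downsampled, file.path(outdir, "downsampled.tsv"))
  }
  write_table(run$network, file.path(outdir, "network_summary.tsv"))
  write_table(clone_table(run$reads), file.path(outdir, "clones.tsv"))
  write_table(run$clone_dynamics$track,
              file.path(outdir, "clone_tracking.tsv"))
  for (t in names(run$clone_dynamics$association)) {
    a <- run$clone_dynamics$association[[t]]
    if (!is.null(a)) {
      write_table(a, file.path(outdir,
                               paste0("clone_association_", t, ".tsv")))
    }
  }
  um <- data.frame(sample_id = rownames(run$usage$matrix),
                   run$usage$matrix, check.names = FALSE)
  write_table(um, file.path(outdir, "usage_matrix.tsv"))
  for (t in names(run$usage$differential)) {
    d <- run$usage$differential[[t]]
    if (!is.null(d)) {
      write_table(d, file.path(outdir,
                               paste0("differential_usage_", t, ".tsv")))
    }
  }
  invisible(outdir)
}

#' @export
print.bcrdyn_run <- function(x, ...) {
  cat("BCR repertoire pipeline run\n")
  cat("  samples retained:", nrow(x$diversity), "\n")
  cat("  pooled clones:   ",
      length(unique(x$reads$clone_id)), "\n")
  cat("  multi-sample clones:", nrow(x$clone_dynamics$matrix), "\n")
  tr <- x$clone_dynamics$track
  cat("  persistent clones:",
      length(unique(tr$clone_id[tr$persistent])),
      " shared:", length(unique(tr$clone_id[tr$shared])), "\n")
  cat("  IGHV genes after low-usage filter:",
      ncol(x$usage$filtered), "\n")
  invisible(x)
}

#' @export
summary.bcrdyn_run <- function(object, ...) {
  x <- object
  cat("Diversity by group (means):\n")
  dat <- merge(x$diversity, x$meta, by = "sample_id")
  agg <- stats::aggregate(cbind(richness, entropy) ~ outcome + time_months,
                          dat, mean)
  print(format(agg[order(agg$time_months, agg$outcome), ], digits = 4),
        row.names = FALSE)
  cat("\nEntropy growth model interaction:\n")
  it <- x$models$lmm$entropy$interaction
  if (!is.null(it)) print(format(it, digits = 4), row.names = FALSE)
  invisible(x)
}
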