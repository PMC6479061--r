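#' Shannon entropy of a clone-size distribution, in bits
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} with \eqn{p_i} the frequency of clone
#' *i*.  Zero for a single clone; \eqn{\log_2 N} for `N` equally sized
#' clones.
#'
#' @param clone_counts Positive read counts, one per clone.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(clone_counts) {
  if (length(clone_counts) == 0) stop("empty clone-count vector")
  if (any(clone_counts <= 0)) stop("clone counts must be positive")
  p <- clone_counts / sum(clone_counts)
  -sum(p * log2(p))
}

#' Somatic hypermutation frequency
#'
#' Per-read mutation frequency is `1 - v_identity` (fraction of mutated
#' positions in the V segment relative to germline); the aggregate is the
#' read-weighted mean at sample or clone level.
#'
#' @param reads Clone-assigned reads with a `v_identity` column.
#' @param per Aggregation level, `"sample"` or `"clone"`.
#' @return `data.frame` with the grouping id and `shm_rate` (NA when all
#'   `v_identity` are missing in a group, never silently zero).
#' @export
shm_frequency <- function(reads, per = c("sample", "clone")) {
  per <- match.arg(per)
  key <- if (per == "sample") reads$sample_id else reads$clone_id
  mut <- 1 - reads$v_identity
  rates <- vapply(split(seq_along(mut), key), function(i) {
    weighted_mean_na(mut[i], reads$duplicate_count[i])
  }, numeric(1))
  out <- data.frame(id = names(rates), shm_rate = as.numeric(rates),
                    stringsAsFactors = FALSE)
  names(out)[1] <- if (per == "sample") "sample_id" else "clone_id"
  out
}

#' Per-sample diversity summary
#'
#' Richness (number of unique clones), Shannon entropy in bits, the uniform
#' upper bound `h_max = log2(richness)` and the sample SHM frequency.
#'
#' @param reads Clone-assigned reads.
#' @return One row per sample.
#' @export
sample_diversity <- function(reads) {
  samples <- split(seq_len(nrow(reads)), reads$sample_id)
  rows <- lapply(names(samples), function(s) {
    i <- samples[[s]]
    counts <- tapply(reads$duplicate_count[i], reads$clone_id[i], sum)
    data.frame(
      sample_id = s,
      n_reads = sum(reads$duplicate_count[i]),
      richness = length(counts),
      entropy = shannon_entropy(as.numeric(counts)),
      h_max = log2(length(counts)),
      shm_rate = weighted_mean_na(1 - reads$v_identity[i],
                                  reads$duplicate_count[i]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Downsampled diversity estimates
#'
#' Controls for unequal sequencing depth: each sample is subsampled without
#' replacement to a common depth, clones are re-inferred on the subsample,
#' and richness/entropy are recomputed; means over replicates are reported.
#' Samples below `min_reads` (default 1000, the floor used for genomic-DNA
#' libraries) are excluded from this analysis only — they remain in the
#' full-data analyses.
#'
#' @param reads QC'd reads (clone assignment is re-run per replicate).
#' @param depth Common depth; default the smallest read count among samples
#'   passing the floor.  An explicit depth larger than some retained
#'   sample's read count is an error naming that sample.
#' @param n_replicates Number of random subsamples; default 10.
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param min_reads Per-sample read floor applied before depth selection.
#' @param identity_threshold Passed to [assign_clones()].
#' @return `data.frame` per retained sample: depth, replicate count, mean
#'   (and SD) of downsampled richness and entropy; excluded samples are in
#'   the `"excluded"` attribute.
#' @export
downsample_diversity <- function(reads, depth = NULL, n_replicates = 10,
                                 seed = 1L, min_reads = 1000,
                                 identity_threshold = 0.90) {
  sizes <- tapply(as.numeric(reads$duplicate_count), reads$sample_id, sum)
  excluded <- names(sizes)[sizes < min_reads]
  keep <- setdiff(names(sizes), excluded)
  if (!length(keep)) stop("no samples at or above the read floor")
  if (is.null(depth)) {
    depth <- min(sizes[keep])
  } else {
    too_small <- keep[sizes[keep] < depth]
    if (length(too_small)) {
      stop("depth ", depth, " exceeds the read count of sample(s): ",
           paste(too_small, collapse = ", "))
    }
  }
  reads <- reads[reads$sample_id %in% keep, , drop = FALSE]
  by_sample <- split(seq_len(nrow(reads)), as.character(reads$sample_id))
  set.seed(seed)
  acc <- lapply(by_sample, function(i) {
    matrix(NA_real_, nrow = n_replicates, ncol = 2,
           dimnames = list(NULL, c("richness", "entropy")))
  })
  for (r in seq_len(n_replicates)) {
    for (s in names(by_sample)) {
      i <- by_sample[[s]]
      # expand duplicate_count so each physical read is one sampling unit
      units <- rep(i, times = reads$duplicate_count[i])
      take <- sample(units, depth, replace = FALSE)
      sub <- reads[sort(unique(take)), , drop = FALSE]
      sub$duplicate_count <- as.integer(table(take)[as.character(sort(unique(take)))])
      asg <- assign_clones(sub, identity_threshold, scope = "per_sample")
      counts <- tapply(asg$duplicate_count, asg$clone_id, sum)
      acc[[s]][r, ] <- c(length(counts), shannon_entropy(as.numeric(counts)))
    }
  }
  out <- do.call(rbind, lapply(names(acc), function(s) {
    data.frame(
      sample_id = s,
      depth = depth,
      n_replicates = n_replicates,
      downsampled_richness_mean = mean(acc[[s]][, "richness"]),
      downsampled_richness_sd = stats::sd(acc[[s]][, "richness"]),
      downsampled_entropy_mean = mean(acc[[s]][, "entropy"]),
      downsampled_entropy_sd = stats::sd(acc[[s]][, "entropy"]),
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "excluded") <- data.frame(sample_id = excluded,
                                      n_reads = as.numeric(sizes[excluded]),
                                      stringsAsFactors = FALSE)
  out
}
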