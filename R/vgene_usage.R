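# Clone-normalized IGHV gene usage and differential-usage analysis.

#' Clone-normalized IGHV gene usage matrix
#'
#' `usage[sample, gene]` = number of clones in the sample using that IGHV
#' gene divided by the sample's total clone count.  Counting is per clone,
#' never per read, so expanded clones do not inflate their gene's usage.
#'
#' @param reads Clone-assigned reads.
#' @return Numeric matrix, rows = samples, columns = IGHV genes; every row
#'   sums to 1.
#' @export
compute_usage <- function(reads) {
  key <- paste(reads$sample_id, reads$clone_id, sep = "\r")
  first <- !duplicated(key)
  clones <- data.frame(sample_id = as.character(reads$sample_id[first]),
                       v_gene = reads$v_gene[first],
                       stringsAsFactors = FALSE)
  tab <- table(clones$sample_id, clones$v_gene)
  mat <- matrix(as.numeric(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  mat / rowSums(mat)
}

#' Filter low-usage IGHV genes
#'
#' A gene is retained iff its usage is at least `min_usage` in at least
#' `min_prevalence` of the samples (both boundaries inclusive), the
#' standard prevalence filter for compositional gene-usage data.
#'
#' @param mat Usage matrix from [compute_usage()].
#' @param min_usage Usage threshold; default 0.05.
#' @param min_prevalence Fraction of samples required at or above the
#'   threshold; default 0.10.
#' @return The usage matrix restricted to retained genes, with the logical
#'   retention mask over all genes in the `"retained"` attribute.
#' @export
filter_low_usage <- function(mat, min_usage = 0.05, min_prevalence = 0.10) {
  prev <- colMeans(mat >= min_usage - 1e-12)
  keep <- prev >= min_prevalence - 1e-12
  if (!any(keep)) {
    stop("all genes filtered out; review min_usage/min_prevalence")
  }
  out <- mat[, keep, drop = FALSE]
  attr(out, "retained") <- keep
  out
}

#' Differential IGHV gene usage at one time point
#'
#' Per gene, an ordinary least-squares model of usage on clinical outcome
#' group (plus optional covariates) among the samples at one time point,
#' with Benjamini–Hochberg FDR adjustment across genes on the primary
#' contrast's p-value.
#'
#' @param mat Filtered usage matrix.
#' @param meta Sample metadata.
#' @param time Time point in months.
#' @param covariates Covariate column names in `meta`.
#' @param contrast Outcome group whose coefficient (vs the NP reference) is
#'   the primary per-gene test; default `"PR"`.
#' @param fdr Flagging level for `q_value`; default 0.05.
#' @return `data.frame` per gene: estimate, SE, nominal p for the primary
#'   contrast, overall group F-test p, BH `q_value` and `significant` flag.
#' @export
differential_usage <- function(mat, meta, time, covariates = NULL,
                               contrast = "PR", fdr = 0.05) {
  meta_t <- meta[meta$time_months == time &
                   meta$sample_id %in% rownames(mat), , drop = FALSE]
  if (length(unique(meta_t$outcome)) < 2) {
    stop("need at least two outcome groups at time ", time)
  }
  rows <- lapply(colnames(mat), function(g) {
    rec <- data.frame(sample_id = rownames(mat), usage = mat[, g],
                      stringsAsFactors = FALSE)
    m <- fit_cross_sectional(rec, meta_t, "usage", time = time,
                             covariates = covariates)
    term <- paste0("outcome", contrast)
    tr <- m$terms[m$terms$term == term, , drop = FALSE]
    fs <- summary(m$fit)$fstatistic
    data.frame(
      gene = g,
      estimate = if (nrow(tr)) tr$estimate else NA_real_,
      std_error = if (nrow(tr)) tr$std_error else NA_real_,
      p_value = if (nrow(tr)) tr$p_value else NA_real_,
      p_overall = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < fdr
  out$time_months <- time
  rownames(out) <- NULL
  out[order(out$p_value), , drop = FALSE]
}

#' IGHV gene enrichment in a clone subset
#'
#' Tests whether clones using a given IGHV gene are over-represented in a
#' clone subset (e.g. persistent shared clones, or outcome-associated
#' clones) relative to a background clone set, by Fisher's exact test on
#' the 2 x 2 table (in subset vs not) x (uses gene vs not).
#'
#' @param gene IGHV gene name (gene level, e.g. `"IGHV3-23"`).
#' @param clone_subset Character vector of clone ids; must be a subset of
#'   `background` and non-empty.
#' @param background Character vector of background clone ids.
#' @param clone_genes Named character vector mapping clone id to its IGHV
#'   gene.
#' @return List: the 2 x 2 `table`, `p_one_sided` (over-representation,
#'   the default reading) and `p_two_sided`.
#' @export
gene_set_enrichment <- function(gene, clone_subset, background,
                                clone_genes) {
  if (!length(clone_subset)) stop("empty clone subset")
  if (!all(clone_subset %in% background)) {
    stop("clone_subset must be contained in background")
  }
  background <- unique(background)
  clone_subset <- unique(clone_subset)
  uses <- clone_genes[background] == gene
  in_sub <- background %in% clone_subset
  tab <- table(factor(in_sub, c(TRUE, FALSE), c("subset", "rest")),
               factor(uses, c(TRUE, FALSE), c("gene", "other")))
  list(
    table = tab,
    p_one_sided = stats::fisher.test(tab, alternative = "greater")$p.value,
    p_two_sided = stats::fisher.test(tab)$p.value
  )
}
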