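# Clone-level dynamics: outcome association, persistence, sharing, expansion.

#' Clone presence/absence association with clinical outcome
#'
#' For each clone (rows of a presence-restricted clone matrix), builds the
#' 2 x 3 contingency table of presence/absence by outcome group over the
#' subjects observed at one time point and applies the exact conditional
#' test with fixed margins (Fisher; Freeman–Halton extension for 2 x 3).
#' Only presence enters — read counts are ignored.  A group with no subjects
#' at the time point is dropped with a warning and the test reduces to
#' 2 x 2.
#'
#' @param mat Clone-by-sample count matrix from [build_clone_matrix()]
#'   (restricted to clones present in more than one sample).
#' @param meta Sample metadata; one sample per subject at the time point.
#' @param time Time point in months.
#' @return `data.frame` per clone: per-group presence counts, group sizes,
#'   exact p-value and Benjamini–Hochberg adjusted q-value.
#' @export
clone_outcome_association <- function(mat, meta, time) {
  meta_t <- meta[meta$time_months == time, , drop = FALSE]
  meta_t <- meta_t[meta_t$sample_id %in% colnames(mat), , drop = FALSE]
  if (anyDuplicated(meta_t$subject_id)) {
    stop("more than one sample per subject at time ", time,
         "; subset to one (e.g. a single source/isotype) first")
  }
  groups <- intersect(OUTCOME_LEVELS, unique(as.character(meta_t$outcome)))
  empty <- setdiff(OUTCOME_LEVELS, groups)
  if (length(empty)) {
    warning("no subjects at time ", time, " for group(s): ",
            paste(empty, collapse = ", "), "; test reduced accordingly")
  }
  if (length(groups) < 2) stop("need at least two outcome groups")
  n_per_group <- vapply(groups, function(g)
    sum(meta_t$outcome == g), integer(1))
  pres <- mat[, meta_t$sample_id, drop = FALSE] > 0
  # presence counts per clone per group
  cnt <- vapply(groups, function(g) {
    cols <- meta_t$sample_id[meta_t$outcome == g]
    rowSums(pres[, cols, drop = FALSE])
  }, numeric(nrow(pres)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1,
                                       dimnames = list(rownames(pres), groups))
  # clones sharing a presence pattern share a p-value: test each pattern once
  pattern <- apply(cnt, 1, paste, collapse = ",")
  upat <- !duplicated(pattern)
  pvals_u <- vapply(which(upat), function(i) {
    tab <- rbind(present = cnt[i, ], absent = n_per_group - cnt[i, ])
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  p <- pvals_u[match(pattern, pattern[upat])]
  out <- data.frame(clone_id = rownames(mat), stringsAsFactors = FALSE)
  for (g in groups) out[[paste0("present_", g)]] <- cnt[, g]
  for (g in groups) out[[paste0("n_", g)]] <- n_per_group[[g]]
  out$p_value <- p
  out$q_value <- stats::p.adjust(p, method = "BH")
  out$time_months <- time
  out[order(out$p_value), , drop = FALSE]
}

#' Track clones across time points and subjects
#'
#' A clone is *persistent* in a subject when it is present at more than one
#' of that subject's time points, and *shared* when the same (pooled-scope)
#' clone id occurs in at least two subjects.  Sharing is annotated as
#' within-group when all carrying subjects have the same clinical outcome.
#'
#' @param reads Pooled-scope clone-assigned reads.
#' @return `data.frame`, one row per clone x subject: time points present,
#'   total reads, `persistent`, `shared`, `n_carriers`, carrier groups and
#'   `within_group` flag.
#' @export
find_persistent_clones <- function(reads) {
  key <- paste(reads$clone_id, reads$subject_id, sep = "\r")
  kid <- match(key, unique(key))  # 1..K in first-occurrence order
  first <- !duplicated(key)
  n_keys <- sum(first)
  n_reads <- rowsum(as.numeric(reads$duplicate_count), kid)  # sorted 1..K
  # collapse to unique (clone, subject, time) triples before aggregating
  dd <- !duplicated(paste(kid, reads$time_months))
  tkid <- kid[dd]
  tt <- reads$time_months[dd]
  ord <- order(tkid, tt)
  tkid <- tkid[ord]; tt <- tt[ord]
  n_times <- tabulate(tkid, n_keys)
  # string form of the time-point set: cheap for the single-time majority,
  # grouped paste only for the multi-time (persistent) minority
  times <- character(n_keys)
  firsts <- !duplicated(tkid)   # first triple of group k is row k, in order
  single <- n_times == 1L
  times[single] <- as.character(tt[firsts][single])
  multi <- which(!single)
  if (length(multi)) {
    sel <- tkid %in% multi
    sp <- split(tt[sel], factor(tkid[sel], levels = multi))
    times[multi] <- vapply(sp, paste, character(1), collapse = ",")
  }
  out <- data.frame(
    clone_id = reads$clone_id[first],
    subject_id = as.character(reads$subject_id[first]),
    outcome = as.character(reads$outcome[first]),
    time_points = as.character(times),
    n_time_points = as.integer(n_times),
    total_reads = as.numeric(n_reads[, 1]),
    stringsAsFactors = FALSE
  )
  out$persistent <- out$n_time_points >= 2
  # rows are unique (clone, subject) pairs, so carriers = rows per clone
  cid <- match(out$clone_id, unique(out$clone_id))
  out$n_carriers <- tabulate(cid)[cid]
  out$shared <- out$n_carriers >= 2
  out$carrier_groups <- out$outcome
  multi <- which(out$shared)
  if (length(multi)) {
    grp <- vapply(split(out$outcome[multi], cid[multi]),
                  function(g) paste(sort(unique(g)), collapse = ","),
                  character(1))
    out$carrier_groups[multi] <- grp[as.character(cid[multi])]
  }
  out$within_group <- out$shared & !grepl(",", out$carrier_groups)
  rownames(out) <- NULL
  out
}

#' Group differences in clone persistence and clonal expansion
#'
#' Two linear models: (1) the per-subject number of persistent clones on
#' outcome group (subjects with none contribute zero), and (2) the total
#' read count of each persistent clone (summed over that subject's time
#' points) on outcome group.  A group with no persistent clones is absent
#' from model 2's contrasts (reported missing, never imputed as zero).
#'
#' @param track Output of [find_persistent_clones()].
#' @param meta Sample metadata (used to enumerate all subjects and their
#'   groups for model 1).
#' @param log_counts Model expansion on `log(count + 1)` scale instead of
#'   raw counts; default `FALSE`.
#' @return List with `persistence` and `expansion`, both `bcrdyn_model`.
#' @export
model_persistence_and_expansion <- function(track, meta,
                                            log_counts = FALSE) {
  subjects <- unique(meta[, c("subject_id", "outcome")])
  n_pers <- tapply(track$persistent, track$subject_id, sum)
  subjects$n_persistent <- as.numeric(n_pers[as.character(subjects$subject_id)])
  subjects$n_persistent[is.na(subjects$n_persistent)] <- 0
  subjects$sample_id <- subjects$subject_id  # fit_cross_sectional joins on it
  m1 <- fit_cross_sectional(
    subjects[, c("sample_id", "n_persistent")],
    subjects[, c("sample_id", "subject_id", "outcome")],
    response = "n_persistent"
  )
  m1$type <- "persistence (clones per subject)"

  pers <- track[track$persistent, , drop = FALSE]
  type2 <- if (log_counts) "expansion (log reads per persistent clone)"
    else "expansion (reads per persistent clone)"
  if (!nrow(pers)) {
    m2 <- NULL
  } else {
    pers$response <- if (log_counts) log(pers$total_reads + 1) else
      pers$total_reads
    pers$sample_id <- paste(pers$clone_id, pers$subject_id)
    missing_groups <- setdiff(unique(as.character(subjects$outcome)),
                              unique(pers$outcome))
    if (length(unique(pers$outcome)) < 2) {
      # one group only: no contrast estimable, report its mean alone
      fit <- stats::lm(response ~ 1, data = pers)
      sm <- summary(fit)$coefficients
      m2 <- new_model_result(
        data.frame(term = rownames(sm), estimate = sm[, 1],
                   std_error = sm[, 2], statistic = sm[, 3],
                   p_value = sm[, 4], stringsAsFactors = FALSE),
        NULL, "response ~ 1", nrow(pers), TRUE, type2, fit = fit)
    } else {
      m2 <- fit_cross_sectional(
        pers[, c("sample_id", "response")],
        data.frame(sample_id = pers$sample_id,
                   subject_id = pers$subject_id,
                   outcome = pers$outcome, stringsAsFactors = FALSE),
        response = "response"
      )
      m2$type <- type2
    }
    if (length(missing_groups)) {
      m2$note <- paste("no persistent clones in group(s):",
                       paste(missing_groups, collapse = ", "),
                       "- contrasts involving them are missing")
    }
  }
  list(persistence = m1, expansion = m2)
}
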