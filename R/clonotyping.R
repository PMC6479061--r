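#' CDR3 nucleotide identity between two equal-length sequences
#'
#' Fraction of positions with matching nucleotides.  A position carrying `N`
#' on either side counts as a mismatch (including `N` vs `N`): ambiguous
#' bases never support clonal relatedness.
#'
#' @param a,b Nucleotide strings of equal, positive length.
#' @return Identity fraction in \[0, 1\].
#' @export
cdr3_identity <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0) {
    stop("cdr3_identity requires equal, positive lengths; ",
         "partition by CDR3 length first")
  }
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  n_code <- utf8ToInt("N")
  mean(av == bv & av != n_code & bv != n_code)
}

# Single-linkage clustering of a set of equal-length CDR3 strings at an
# identity threshold.  Returns an integer cluster label per sequence.
# Union-find with merging during the pairwise scan; partitions produced by
# the (V, J, length) split are small, so the O(m^2 L) scan is cheap.
cluster_cdr3 <- function(cdr3s, threshold) {
  m <- length(cdr3s)
  if (m == 1L) return(1L)
  L <- nchar(cdr3s[1])
  M <- vapply(cdr3s, utf8ToInt, integer(L))
  if (is.null(dim(M))) M <- matrix(M, nrow = L)
  # make every N unique so N never matches anything (including another N)
  is_n <- M == utf8ToInt("N")
  if (any(is_n)) M[is_n] <- -seq_len(sum(is_n))
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  min_match <- threshold * L - 1e-9
  for (i in seq_len(m - 1L)) {
    js <- (i + 1L):m
    matches <- .colSums(M[, js, drop = FALSE] == M[, i], L, length(js))
    hits <- js[matches >= min_match]
    for (j in hits) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

#' Assign reads to clones
#'
#' A clone is a set of reads with the same IGHV gene, same IGHJ gene, same
#' CDR3 nucleotide length and CDR3 nucleotide identity at or above
#' `identity_threshold`, closed under single linkage (transitive closure).
#' Gene calls are collapsed to gene level (alleles stripped; the first call
#' of a multi-assignment is used).
#'
#' Clone identifiers are deterministic: the (v_gene, j_gene, cdr3_length)
#' partition key plus the lexicographically smallest member CDR3, so reruns
#' on the same reads (in any order) give identical ids, and the same clone
#' observed in several samples shares one id under pooled scope.
#'
#' @param reads QC'd annotated reads (see [filter_reads()]).
#' @param identity_threshold Minimum CDR3 identity, inclusive; default 0.90.
#' @param scope `"pooled"` clusters all samples together (required for
#'   persistence/sharing analyses); `"per_sample"` clusters each sample
#'   independently and prefixes clone ids with the sample id.
#' @return The input reads with added columns `v_gene`, `j_gene`,
#'   `cdr3_length` and `clone_id`.  Reads with unparseable V/J calls or an
#'   invalid CDR3 are excluded and reported in the `"excluded"` attribute.
#' @export
assign_clones <- function(reads, identity_threshold = 0.90,
                          scope = c("pooled", "per_sample")) {
  scope <- match.arg(scope)
  ok <- reads$valid %||% (!is.na(reads$junction) & nzchar(reads$junction))
  excluded <- reads[!ok, , drop = FALSE]
  reads <- reads[ok, , drop = FALSE]
  if (!nrow(reads)) stop("no valid reads to clonotype")
  reads$v_gene <- collapse_gene(reads$v_call)
  reads$j_gene <- collapse_gene(reads$j_call)
  reads$cdr3_length <- nchar(reads$junction)
  part_key <- paste(reads$v_gene, reads$j_gene, reads$cdr3_length, sep = "|")
  if (scope == "per_sample") {
    part_key <- paste(reads$sample_id, part_key, sep = "|")
  }
  junc <- reads$junction
  clone_id <- character(nrow(reads))
  for (idx in split(seq_len(nrow(reads)), part_key)) {
    cdr3 <- junc[idx]
    uniq <- unique(cdr3)
    if (length(uniq) == 1L) {  # fast path: single clonotype sequence
      clone_id[idx] <- paste(part_key[idx[1]], uniq, sep = "|")
      next
    }
    labels <- cluster_cdr3(uniq, identity_threshold)
    lab_per_read <- labels[match(cdr3, uniq)]
    # stable id: partition key + smallest member CDR3 of the cluster
    anchor <- vapply(split(uniq, labels), min, character(1))
    clone_id[idx] <- paste(part_key[idx[1]], anchor[lab_per_read],
                           sep = "|")
  }
  reads$clone_id <- clone_id
  attr(reads, "excluded") <- excluded
  attr(reads, "identity_threshold") <- identity_threshold
  attr(reads, "scope") <- scope
  reads
}

#' Summarise clones as one row per clone x sample
#'
#' @param reads Clone-assigned reads from [assign_clones()].
#' @return `data.frame` with clone_id, v_gene, j_gene, cdr3_length,
#'   representative (smallest) CDR3, sample_id, subject_id, time_months,
#'   outcome and the read count (weighted by `duplicate_count`).
#' @export
clone_table <- function(reads) {
  key <- paste(reads$clone_id, reads$sample_id, sep = "\r")
  first <- !duplicated(key)
  counts <- tapply(reads$duplicate_count, key, sum)
  out <- reads[first, intersect(c("clone_id", "v_gene", "j_gene",
                                  "cdr3_length", "sample_id", "subject_id",
                                  "time_months", "outcome"), names(reads)),
               drop = FALSE]
  out$n_reads <- as.numeric(counts[key[first]])
  rep_cdr3 <- tapply(reads$junction, reads$clone_id, min)
  out$representative_cdr3 <- as.character(rep_cdr3[out$clone_id])
  rownames(out) <- NULL
  out[order(out$sample_id, out$clone_id), , drop = FALSE]
}

#' Exclude low-quality samples by clone count
#'
#' Samples with fewer than `min_clones` inferred clones are removed from all
#' downstream analyses.
#'
#' @param reads Clone-assigned reads.
#' @param min_clones Minimum clone count for retention (a sample with
#'   exactly `min_clones` clones is retained); default 100.
#' @return List with `reads` (retained rows), `retained` (sample ids) and
#'   `excluded`, a `data.frame` of excluded samples and their clone counts.
#' @export
filter_samples <- function(reads, min_clones = 100) {
  n_clones <- tapply(reads$clone_id, reads$sample_id,
                     function(x) length(unique(x)))
  bad <- names(n_clones)[n_clones < min_clones]
  list(
    reads = reads[!(reads$sample_id %in% bad), , drop = FALSE],
    retained = setdiff(names(n_clones), bad),
    excluded = data.frame(sample_id = bad,
                          n_clones = as.integer(n_clones[bad]),
                          stringsAsFactors = FALSE)
  )
}

#' Clone-by-sample count matrix
#'
#' @param reads Pooled-scope clone-assigned reads.
#' @param restrict_multi_sample If `TRUE`, keep only clones present in at
#'   least two samples (the clone set used for outcome association and
#'   sharing analyses).
#' @return Integer matrix, rows = clones, columns = samples, entries =
#'   read counts (weighted by `duplicate_count`).
#' @export
build_clone_matrix <- function(reads, restrict_multi_sample = TRUE) {
  if (restrict_multi_sample) {
    # restrict before building the dense matrix: presence pairs first
    pair <- paste(reads$clone_id, reads$sample_id, sep = "\r")
    dd <- !duplicated(pair)
    n_samp <- table(reads$clone_id[dd])
    keep <- names(n_samp)[n_samp >= 2]
    reads <- reads[reads$clone_id %in% keep, , drop = FALSE]
  }
  clones <- sort(unique(reads$clone_id))
  samples <- sort(unique(as.character(reads$sample_id)))
  mat <- matrix(0, length(clones), length(samples),
                dimnames = list(clones, samples))
  ci <- match(reads$clone_id, clones)
  si <- match(as.character(reads$sample_id), samples)
  key <- (ci - 1) * length(samples) + si
  agg <- rowsum(as.numeric(reads$duplicate_count), key)
  k <- as.numeric(rownames(agg))
  mat[cbind((k - 1) %/% length(samples) + 1, (k - 1) %% length(samples) + 1)] <-
    agg[, 1]
  mat
}
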