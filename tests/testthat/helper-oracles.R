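# Independent oracles used to validate the package's implementations.
# These deliberately use naive algorithms (brute force, enumeration,
# closed forms) and share no code with the package internals.

# --- clonotyping oracle: all-pairs identity + BFS connected components ----

oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv & av != "N" & bv != "N")
}

# reads: data.frame with v_gene, j_gene, junction; returns integer partition
oracle_clones <- function(v, j, cdr3, threshold = 0.90) {
  n <- length(cdr3)
  chars <- strsplit(cdr3, "")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) { adj[i, k] <- TRUE; next }
      same <- v[i] == v[k] && j[i] == j[k] &&
        nchar(cdr3[i]) == nchar(cdr3[k])
      if (same) {
        a <- chars[[i]]; b <- chars[[k]]
        ident <- mean(a == b & a != "N" & b != "N")
        if (ident >= threshold - 1e-12) adj[i, k] <- TRUE
      }
    }
  }
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    next_id <- next_id + 1L
    queue <- i
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- next_id
      queue <- c(queue, which(adj[cur, ] & is.na(comp)))
    }
  }
  comp
}

# --- Gini oracle: pairwise mean absolute difference ----------------------

oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# --- downsampling oracle: hypergeometric expected richness ---------------
# E[richness at depth d] = sum_c (1 - choose(n - k_c, d) / choose(n, d))
oracle_downsampled_richness <- function(clone_counts, depth) {
  n <- sum(clone_counts)
  sum(1 - exp(lchoose(n - clone_counts, depth) - lchoose(n, depth)))
}

# --- BH oracle: textbook step-up -----------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# --- exact-test oracle: full enumeration over fixed-margin tables --------
# two-sided by probability ordering (null probabilities <= observed count)

oracle_fisher_2xc <- function(tab) {
  row1 <- sum(tab[1, ])
  cols <- colSums(tab)
  prob_of <- function(x) {
    # x: first-row counts; hypergeometric-multivariate probability
    exp(sum(lchoose(cols, x)) - lchoose(sum(cols), row1))
  }
  # enumerate all first rows with the fixed margins
  ranges <- lapply(seq_along(cols), function(j)
    0:min(cols[j], row1))
  grid <- expand.grid(ranges)
  grid <- grid[rowSums(grid) == row1, , drop = FALSE]
  probs <- apply(grid, 1, prob_of)
  p_obs <- prob_of(tab[1, ])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- adjusted Rand index (partition agreement) ---------------------------

oracle_ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# --- small random read-set generator for clonotyping tests ---------------
# built to create colliding and near-identical CDR3s across few V/J cells

random_read_set <- function(n, n_v = 3, n_j = 2, lens = c(9, 12),
                            mutate_prob = 0.6) {
  v <- paste0("IGHV", sample.int(n_v, n, replace = TRUE))
  j <- paste0("IGHJ", sample.int(n_j, n, replace = TRUE))
  len <- sample(lens, n, replace = TRUE)
  base <- vapply(len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
    character(1))
  # with some probability, derive a read from an earlier one by 0-2 edits
  for (i in seq_len(n)) {
    if (i > 1 && stats::runif(1) < mutate_prob) {
      src <- sample.int(i - 1, 1)
      v[i] <- v[src]; j[i] <- j[src]; len[i] <- len[src]
      s <- base[src]
      for (e in seq_len(sample(0:2, 1))) {
        p <- sample.int(nchar(s), 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      base[i] <- s
    }
  }
  data.frame(
    sequence_id = sprintf("r%04d", seq_len(n)), sample_id = "s1",
    sequence = base, productive = TRUE, locus = "IGH",
    v_call = v, j_call = j, junction = base,
    v_identity = 1, isotype = "unknown", has_v_indel = FALSE,
    duplicate_count = 1L, valid = TRUE, stringsAsFactors = FALSE
  )
}

# Read set whose clones are cliques at the 90% identity threshold:
# founder CDR3s of length 20 plus copies at most one edit away, so every
# within-clone pair matches at >= 18/20 = 0.90 and the clone partition is
# closed under subsampling (needed for the hypergeometric oracle).
clique_read_set <- function(n_clones, mean_size = 3) {
  sizes <- 1 + stats::rpois(n_clones, mean_size - 1)
  rows <- lapply(seq_len(n_clones), function(ci) {
    L <- 20
    founder <- paste(sample(c("A", "C", "G", "T"), L, TRUE),
                     collapse = "")
    cdr3 <- vapply(seq_len(sizes[ci]), function(k) {
      s <- founder
      if (stats::runif(1) < 0.5) {
        p <- sample.int(L, 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }, character(1))
    data.frame(v_call = paste0("IGHV", 1 + ci %% 4),
               j_call = paste0("IGHJ", 1 + ci %% 2),
               junction = cdr3, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  data.frame(
    sequence_id = sprintf("c%04d", seq_len(n)), sample_id = "s1",
    sequence = df$junction, productive = TRUE, locus = "IGH",
    v_call = df$v_call, j_call = df$j_call, junction = df$junction,
    v_identity = 1, isotype = "unknown", has_v_indel = FALSE,
    duplicate_count = 1L, valid = TRUE, stringsAsFactors = FALSE
  )
}

# minimal metadata for synthetic read frames
meta_for <- function(sample_ids, outcome = "NP", subject = NULL,
                     time = 0) {
  data.frame(
    sample_id = sample_ids,
    subject_id = subject %||% paste0("subj_", sample_ids),
    time_months = time, outcome = outcome, source = "gDNA",
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
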