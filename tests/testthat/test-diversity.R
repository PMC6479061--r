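# Shannon entropy, SHM frequency, downsampling, diversity models.

test_that("shannon_entropy matches direct evaluation and bounds", {
  expect_equal(shannon_entropy(5), 0)
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2.0)
  expect_equal(shannon_entropy(c(2, 1, 1)), 1.5)
  expect_equal(shannon_entropy(c(1, 1)), 1.0)
  expect_error(shannon_entropy(numeric(0)), "empty")
  expect_error(shannon_entropy(c(1, 0)), "positive")
})

test_that("entropy is bounded by log2 N with equality iff uniform", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    counts <- sample(1:50, n, replace = TRUE)
    h <- shannon_entropy(counts)
    expect_true(h >= 0 && h <= log2(n) + 1e-12)
    if (length(unique(counts)) == 1) {
      expect_equal(h, log2(n))
    }
    # relabeling invariance
    expect_equal(shannon_entropy(sample(counts)), h)
  }
  # merging two equal-size clones strictly decreases entropy
  counts <- c(4, 4, 2, 1)
  expect_lt(shannon_entropy(c(8, 2, 1)), shannon_entropy(counts))
})

test_that("shm_frequency is the read-weighted mean of 1 - v_identity", {
  r <- make_reads(c("ACGTACGTAC", "ACGTACGTAT"), v_identity = c(1, 1))
  expect_equal(shm_frequency(r)$shm_rate, 0)
  r2 <- make_reads("ACGTACGTAC", v_identity = 0.98)
  expect_equal(shm_frequency(r2)$shm_rate, 0.02)
  r3 <- make_reads(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAT"),
                   v_identity = c(0.98, 0.98, 0.95))
  expect_equal(shm_frequency(r3)$shm_rate, 0.03)
  # duplicate_count weighting
  r4 <- make_reads(c("ACGTACGTAC", "ACGTACGTAT"),
                   v_identity = c(0.98, 0.95),
                   duplicate_count = c(2L, 1L))
  expect_equal(shm_frequency(r4)$shm_rate, 0.03)
  # all-missing v_identity is NA, not zero
  r5 <- make_reads("ACGTACGTAC", v_identity = NA_real_)
  expect_true(is.na(shm_frequency(r5)$shm_rate))
})

test_that("downsampling at full depth reproduces full-sample values", {
  set.seed(21)
  reads <- random_read_set(120)
  asg <- assign_clones(reads)
  full <- sample_diversity(asg)
  ds <- downsample_diversity(reads, depth = 120, n_replicates = 3,
                             seed = 9, min_reads = 1)
  expect_equal(ds$downsampled_richness_mean, full$richness)
  expect_equal(ds$downsampled_entropy_mean, full$entropy, tolerance = 1e-12)
  expect_equal(ds$downsampled_richness_sd, 0)
})

test_that("downsampling is seed-reproducible and errors on bad depth", {
  set.seed(22)
  reads <- random_read_set(80)
  a <- downsample_diversity(reads, depth = 40, n_replicates = 5, seed = 4,
                            min_reads = 1)
  b <- downsample_diversity(reads, depth = 40, n_replicates = 5, seed = 4,
                            min_reads = 1)
  expect_equal(a, b)
  expect_error(
    downsample_diversity(reads, depth = 500, seed = 1, min_reads = 1),
    "s1")
})

test_that("mean downsampled richness matches the hypergeometric form", {
  # 10 singleton clones, depth 5: E[richness] is exactly 5
  cdr3 <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = ""),
    character(1))
  set.seed(33)
  reads <- make_reads(cdr3)
  reads$v_call <- paste0("IGHV", 1:10)
  ds <- downsample_diversity(reads, depth = 5, n_replicates = 200,
                             seed = 13, min_reads = 1)
  expect_equal(oracle_downsampled_richness(rep(1, 10), 5), 5)
  se <- stats::sd(rep(c(5), 1))  # each replicate draws exactly 5 singletons
  expect_equal(ds$downsampled_richness_mean, 5)
})

test_that("samples below the read floor are excluded from downsampling only", {
  set.seed(44)
  big <- random_read_set(60)
  small <- random_read_set(20)
  small$sample_id <- "s2"
  small$sequence_id <- paste0("t", seq_len(nrow(small)))
  reads <- rbind(big, small)
  ds <- downsample_diversity(reads, n_replicates = 2, seed = 5,
                             min_reads = 30)
  expect_equal(ds$sample_id, "s1")
  expect_equal(attr(ds, "excluded")$sample_id, "s2")
  # the small sample still participates in full-data diversity
  div <- sample_diversity(assign_clones(reads))
  expect_setequal(div$sample_id, c("s1", "s2"))
})

test_that("cross-sectional OLS recovers group mean differences", {
  rec <- data.frame(sample_id = paste0("s", 1:4),
                    richness = c(3, 5, 7, 9))
  meta <- meta_for(paste0("s", 1:4), outcome = c("NP", "NP", "PR", "PR"))
  m <- fit_cross_sectional(rec, meta, "richness", time = 0)
  expect_equal(m$terms$estimate[m$terms$term == "outcomePR"], 4.0)
  # all-equal responses give zero group coefficients
  rec$richness <- 5
  m0 <- fit_cross_sectional(rec, meta, "richness", time = 0)
  expect_equal(m0$terms$estimate[m0$terms$term == "outcomePR"], 0)
})

test_that("two-group OLS p-value equals the pooled-variance t-test", {
  set.seed(8)
  for (rep in 1:5) {
    y <- rnorm(12)
    g <- rep(c("NP", "PR"), each = 6)
    rec <- data.frame(sample_id = paste0("s", 1:12), entropy = y)
    meta <- meta_for(paste0("s", 1:12), outcome = g)
    m <- fit_cross_sectional(rec, meta, "entropy", time = 0)
    tt <- t.test(y[g == "PR"], y[g == "NP"], var.equal = TRUE)
    expect_equal(m$terms$p_value[m$terms$term == "outcomePR"],
                 tt$p.value, tolerance = 1e-12)
  }
})

test_that("cross-sectional fit reports aliased covariates as an error", {
  rec <- data.frame(sample_id = paste0("s", 1:6), entropy = rnorm(6))
  meta <- meta_for(paste0("s", 1:6),
                   outcome = rep(c("NP", "PR"), each = 3))
  meta$dupe <- as.numeric(meta$outcome == "PR")  # collinear with group
  expect_error(fit_cross_sectional(rec, meta, "entropy", 0,
                                   covariates = "dupe"),
               "aliased|singular")
})

test_that("growth LMM recovers zero slopes for constant response", {
  meta <- do.call(rbind, lapply(c(0, 6, 24), function(t)
    meta_for(paste0("s", 1:9, "_t", t), subject = paste0("P", 1:9),
             outcome = rep(c("NP", "PNR", "PR"), each = 3), time = t)))
  rec <- data.frame(sample_id = meta$sample_id, entropy = 1.0)
  m <- fit_growth_lmm(rec, meta, "entropy")
  slopes <- m$terms$estimate[grepl("time_months", m$terms$term)]
  expect_true(all(abs(slopes) < 1e-8))
})

test_that("growth LMM detects a configured group-by-time divergence", {
  set.seed(99)
  meta <- do.call(rbind, lapply(c(0, 6, 24), function(t)
    meta_for(paste0("s", 1:18, "_t", t), subject = paste0("P", 1:18),
             outcome = rep(c("NP", "PR"), each = 9), time = t)))
  slope <- ifelse(meta$outcome == "PR", -0.05, 0.05)
  subj_int <- rnorm(18, 0, 0.3)[as.integer(factor(meta$subject_id))]
  rec <- data.frame(
    sample_id = meta$sample_id,
    entropy = 8 + subj_int + slope * meta$time_months + rnorm(nrow(meta), 0, 0.2))
  m <- fit_growth_lmm(rec, meta, "entropy")
  expect_lt(m$interaction$p_value, 0.01)
  est <- m$terms$estimate[m$terms$term == "outcomePR:time_months"]
  expect_lt(abs(est - (-0.1)), 0.05)
})
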