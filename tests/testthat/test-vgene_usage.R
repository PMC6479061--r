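# Clone-normalized IGHV usage, low-usage filter, differential usage, BH,
# gene-set enrichment.

test_that("usage is clone-normalized and rows sum to one", {
  # sample with 10 clones, 3 using IGHV3-23 (one of them heavily expanded)
  cdr3 <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = ""),
    character(1))
  set.seed(61)
  reads <- make_reads(c(cdr3, rep(cdr3[1], 20)))  # expansion of clone 1
  reads$v_call <- c(rep("IGHV3-23*01", 3), paste0("IGHV1-", 1:7, "*01"),
                    rep("IGHV3-23*01", 20))
  reads$sequence_id <- paste0("u", seq_len(nrow(reads)))
  asg <- assign_clones(reads)
  usage <- compute_usage(asg)
  expect_equal(unname(usage["s1", "IGHV3-23"]), 0.3)  # per clone, not read
  expect_equal(unname(rowSums(usage)), 1, tolerance = 1e-12)
})

test_that("unused genes get zero usage and rows still sum to one", {
  set.seed(62)
  reads <- rbind(make_reads("ACGTACGTAC", v = "IGHV1-2*01", sample = "a"),
                 make_reads("TTTTCCCCGG", v = "IGHV3-23*01", sample = "b"))
  reads$sequence_id <- c("z1", "z2")
  usage <- compute_usage(assign_clones(reads))
  expect_equal(unname(usage["a", "IGHV3-23"]), 0)
  expect_equal(unname(rowSums(usage)), c(1, 1), tolerance = 1e-12)
})

test_that("the low-usage filter applies inclusive boundaries", {
  mat <- matrix(c(
    rep(0.04, 10),               # below threshold everywhere -> removed
    c(0.10, 0.10, rep(0.01, 8)), # 0.10 in 20% of samples -> retained
    c(0.05, rep(0.01, 9)),       # exactly 0.05 in exactly 10% -> retained
    rep(0.85, 10)                # abundant -> retained
  ), nrow = 10,
  dimnames = list(paste0("s", 1:10), c("gA", "gB", "gC", "gD")))
  out <- filter_low_usage(mat, min_usage = 0.05, min_prevalence = 0.10)
  expect_setequal(colnames(out), c("gB", "gC", "gD"))
  expect_error(filter_low_usage(mat[, "gA", drop = FALSE]), "filtered")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
  set.seed(63)
  for (rep in 1:50) {
    p <- runif(sample(3:40, 1))
    adj <- stats::p.adjust(p, "BH")
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("differential usage flags a shifted gene and not a flat one", {
  set.seed(64)
  n <- 18
  meta <- meta_for(paste0("s", 1:n), subject = paste0("P", 1:n),
                   outcome = rep(c("NP", "PR"), each = n / 2))
  genes <- paste0("g", 1:6)
  mat <- matrix(abs(rnorm(n * 6, 0.1, 0.01)), n, 6,
                dimnames = list(meta$sample_id, genes))
  mat[meta$outcome == "PR", "g3"] <- mat[meta$outcome == "PR", "g3"] + 0.05
  res <- differential_usage(mat, meta, time = 0)
  expect_true(res$significant[res$gene == "g3"])
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"),
               tolerance = 1e-12)
  flat <- res[res$gene == "g1", ]
  expect_gt(flat$p_value, 0.05)
  # identical usage across groups -> zero coefficient
  mat2 <- mat; mat2[, "g1"] <- 0.2
  res2 <- differential_usage(mat2, meta, time = 0)
  expect_equal(res2$estimate[res2$gene == "g1"], 0)
})

test_that("gene relabeling permutes results without changing values", {
  set.seed(65)
  n <- 12
  meta <- meta_for(paste0("s", 1:n), subject = paste0("P", 1:n),
                   outcome = rep(c("NP", "PR"), each = 6))
  mat <- matrix(abs(rnorm(n * 4, 0.2, 0.05)), n, 4,
                dimnames = list(meta$sample_id, paste0("g", 1:4)))
  res <- differential_usage(mat, meta, 0)
  perm <- c(3, 1, 4, 2)
  mat2 <- mat[, perm]
  res2 <- differential_usage(mat2, meta, 0)
  m1 <- res[order(res$gene), c("estimate", "p_value", "q_value")]
  m2 <- res2[order(res2$gene), c("estimate", "p_value", "q_value")]
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("enrichment p-values match the hypergeometric closed form", {
  clone_genes <- stats::setNames(
    c(rep("IGHV3-23", 5), rep("IGHV1-2", 95)), paste0("c", 1:100))
  subset5 <- paste0("c", 1:5)  # exactly the five users
  res <- gene_set_enrichment("IGHV3-23", subset5, names(clone_genes),
                             clone_genes)
  expect_equal(res$p_one_sided, 1 / choose(100, 5), tolerance = 1e-9)
  expect_equal(res$p_one_sided,
               stats::phyper(4, 5, 95, 5, lower.tail = FALSE),
               tolerance = 1e-12)
  # subset disjoint from gene users: one-sided enrichment p = 1
  res2 <- gene_set_enrichment("IGHV3-23", paste0("c", 96:100),
                              names(clone_genes), clone_genes)
  expect_equal(res2$p_one_sided, 1)
  # matched fractions on balanced margins: two-sided p = 1
  cg <- stats::setNames(rep(c("IGHV3-23", "IGHV1-2"), 10), paste0("k", 1:20))
  res3 <- gene_set_enrichment("IGHV3-23", paste0("k", 1:10),
                              names(cg), cg)
  expect_equal(res3$p_two_sided, 1)
  expect_error(gene_set_enrichment("IGHV3-23", character(0),
                                   names(cg), cg), "empty")
  expect_error(gene_set_enrichment("IGHV3-23", "nope", names(cg), cg),
               "contained")
})
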