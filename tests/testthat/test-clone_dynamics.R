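# Clone-outcome association, persistence/sharing, expansion models.

test_that("clone present everywhere gives p = 1", {
  meta <- meta_for(paste0("s", 1:6), subject = paste0("P", 1:6),
                   outcome = rep(c("NP", "PNR", "PR"), each = 2))
  mat <- matrix(1, 2, 6,
                dimnames = list(c("cl1", "cl2"), paste0("s", 1:6)))
  res <- clone_outcome_association(mat, meta, time = 0)
  expect_equal(res$p_value, c(1, 1))
})

test_that("a perfectly separating 2x2 table gives the enumerated p-value", {
  meta <- meta_for(paste0("s", 1:10), subject = paste0("P", 1:10),
                   outcome = rep(c("NP", "PR"), each = 5))
  mat <- matrix(0, 1, 10, dimnames = list("cl", paste0("s", 1:10)))
  mat[1, 1:5] <- 1  # present in all NP, absent in all PR
  res <- suppressWarnings(clone_outcome_association(mat, meta, time = 0))
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
})

test_that("association ignores read counts (presence only)", {
  meta <- meta_for(paste0("s", 1:6), subject = paste0("P", 1:6),
                   outcome = rep(c("NP", "PR"), each = 3))
  mat1 <- matrix(c(1, 1, 0, 0, 1, 0), 1,
                 dimnames = list("cl", paste0("s", 1:6)))
  mat2 <- mat1 * 50
  r1 <- suppressWarnings(clone_outcome_association(mat1, meta, 0))
  r2 <- suppressWarnings(clone_outcome_association(mat2, meta, 0))
  expect_equal(r1$p_value, r2$p_value)
})

test_that("2x3 p-values match exhaustive enumeration on random tables", {
  set.seed(31)
  for (rep in 1:40) {
    n_per <- sample(2:5, 3, replace = TRUE)
    meta <- meta_for(paste0("s", seq_len(sum(n_per))),
                     subject = paste0("P", seq_len(sum(n_per))),
                     outcome = rep(c("NP", "PNR", "PR"), n_per))
    pres <- rbinom(sum(n_per), 1, runif(1, 0.2, 0.8))
    mat <- matrix(pres, 1, dimnames = list("cl", meta$sample_id))
    res <- clone_outcome_association(mat, meta, 0)
    tab <- rbind(tapply(pres, meta$outcome, sum)[c("NP", "PNR", "PR")],
                 n_per - tapply(pres, meta$outcome, sum)[c("NP", "PNR", "PR")])
    expect_equal(res$p_value, oracle_fisher_2xc(tab), tolerance = 1e-9)
  }
})

test_that("persistence and sharing flags follow their definitions", {
  reads <- rbind(
    make_reads("ACGTACGTAC", sample = "A0", subject = "A", time = 0,
               outcome = "PR"),
    make_reads("ACGTACGTAC", sample = "A24", subject = "A", time = 24,
               outcome = "PR"),
    make_reads("TTTTCCCCGG", sample = "A0b", subject = "A", time = 0,
               outcome = "PR"),
    make_reads("ACGTACGTAC", sample = "B0", subject = "B", time = 0,
               outcome = "PR"),
    make_reads("GGGGAAAATT", sample = "C0", subject = "C", time = 0,
               outcome = "NP")
  )
  reads$sequence_id <- paste0("p", seq_len(nrow(reads)))
  # fix sample ids so subject A has one sample per time
  reads$sample_id <- c("A_t0", "A_t24", "A_t0", "B_t0", "C_t0")
  asg <- assign_clones(reads)
  trk <- find_persistent_clones(asg)
  cloneA <- trk[trk$subject_id == "A" &
                  grepl("ACGTACGTAC", trk$clone_id), ]
  expect_true(cloneA$persistent)
  expect_equal(cloneA$time_points, "0,24")
  # the same clone is shared with subject B, within the PR group
  expect_true(all(trk$shared[grepl("ACGTACGTAC", trk$clone_id)]))
  expect_equal(unique(trk$carrier_groups[grepl("ACGTACGTAC",
                                               trk$clone_id)]), "PR")
  expect_true(all(trk$within_group[grepl("ACGTACGTAC", trk$clone_id)]))
  # single-time, single-subject clones are neither
  soloC <- trk[trk$subject_id == "C", ]
  expect_false(soloC$persistent)
  expect_false(soloC$shared)
})

test_that("persistence model counts zero for subjects without persistent clones", {
  meta <- meta_for(paste0("s", 1:6), subject = paste0("P", 1:6),
                   outcome = rep(c("NP", "PR"), each = 3))
  track <- data.frame(
    clone_id = c("c1", "c2", "c3"),
    subject_id = c("P4", "P5", "P5"),
    outcome = "PR",
    time_points = "0,6", n_time_points = 2L, total_reads = c(10, 6, 4),
    persistent = TRUE, n_carriers = 1L, shared = FALSE,
    carrier_groups = "PR", within_group = FALSE,
    stringsAsFactors = FALSE
  )
  m <- model_persistence_and_expansion(track, meta)
  # NP subjects contribute zeros: NP mean 0, PR mean (1+2+0)/3 = 1
  cf <- coef(m$persistence)
  expect_equal(unname(cf["(Intercept)"]), 0)
  expect_equal(unname(cf["outcomePR"]), 1)
  # expansion model has no NP persistent clones -> note, PR-only fit
  expect_match(m$expansion$note %||% "", "NP")
})

test_that("identical persistence counts give zero group coefficients", {
  meta <- meta_for(paste0("s", 1:4), subject = paste0("P", 1:4),
                   outcome = rep(c("NP", "PR"), each = 2))
  track <- data.frame(
    clone_id = paste0("c", 1:4), subject_id = paste0("P", 1:4),
    outcome = rep(c("NP", "PR"), each = 2),
    time_points = "0,6", n_time_points = 2L, total_reads = 5,
    persistent = TRUE, n_carriers = 1L, shared = FALSE,
    carrier_groups = rep(c("NP", "PR"), each = 2), within_group = FALSE,
    stringsAsFactors = FALSE
  )
  m <- model_persistence_and_expansion(track, meta)
  expect_equal(unname(coef(m$persistence)["outcomePR"]), 0)
  expect_equal(unname(coef(m$expansion)["outcomePR"]), 0)
})

test_that("a configured expansion difference is detected in simulation", {
  # persistent PR clones 3x larger than NP: positive PR coefficient
  set.seed(55)
  pos <- vapply(1:20, function(s) {
    n <- 8
    meta <- meta_for(paste0("s", 1:n), subject = paste0("P", 1:n),
                     outcome = rep(c("NP", "PR"), each = n / 2))
    counts <- c(rpois(12, 5), rpois(12, 15))
    track <- data.frame(
      clone_id = paste0("c", 1:24),
      subject_id = rep(paste0("P", 1:n), each = 3),
      outcome = rep(c("NP", "PR"), each = 12),
      time_points = "0,6", n_time_points = 2L,
      total_reads = counts + 1,
      persistent = TRUE, n_carriers = 1L, shared = FALSE,
      carrier_groups = rep(c("NP", "PR"), each = 12),
      within_group = FALSE, stringsAsFactors = FALSE
    )
    m <- model_persistence_and_expansion(track, meta)
    unname(coef(m$expansion)["outcomePR"]) > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})
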