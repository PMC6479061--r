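# Build a minimal annotated-read frame from explicit fields.
make_reads <- function(cdr3, v = "IGHV3-23*01", j = "IGHJ4*02",
                       sample = "s1", subject = NULL, time = 0,
                       outcome = "NP", sequence = NULL, v_identity = 1,
                       productive = TRUE, locus = "IGH",
                       has_v_indel = FALSE, isotype = "unknown",
                       duplicate_count = 1L) {
  n <- length(cdr3)
  data.frame(
    sequence_id = sprintf("q%04d", seq_len(n)),
    sample_id = rep_len(sample, n),
    subject_id = rep_len(subject %||% paste0("subj_", sample), n),
    time_months = rep_len(time, n),
    outcome = rep_len(outcome, n),
    sequence = rep_len(sequence %||% cdr3, n),
    productive = rep_len(productive, n),
    locus = rep_len(locus, n),
    v_call = rep_len(v, n), j_call = rep_len(j, n),
    junction = cdr3,
    v_identity = rep_len(v_identity, n),
    isotype = rep_len(isotype, n),
    has_v_indel = rep_len(has_v_indel, n),
    duplicate_count = rep_len(duplicate_count, n),
    valid = !is.na(cdr3) & nzchar(cdr3),
    stringsAsFactors = FALSE
  )
}

# tiny simulation config for fast cohort-level tests
small_config <- function(...) {
  simulation_config(
    n_subjects = c(NP = 3, PNR = 3, PR = 3),
    baseline_entropy_bits = c(NP = 5.2, PNR = 5.4, PR = 5.7),
    clone_size_law = list(type = "powerlaw", exponent = 2.5,
                          max_size = 50),
    shared_clone_count = c(NP = 0, PNR = 2, PR = 2),
    ...
  )
}
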