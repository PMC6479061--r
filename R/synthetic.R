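# Synthetic longitudinal BCR cohort generator with known ground truth.

BASES <- c("A", "C", "G", "T")

# Default IGHV gene pool: common human heavy-chain V genes with frequencies
# loosely shaped like peripheral-blood repertoires (IGHV3 family dominant,
# IGHV3-23 the single most used gene).
default_vgene_frequencies <- function() {
  genes <- c(
    "IGHV1-2" = 3.0, "IGHV1-8" = 1.5, "IGHV1-18" = 2.5, "IGHV1-46" = 2.0,
    "IGHV1-69" = 3.0, "IGHV2-5" = 1.5, "IGHV2-70" = 0.8, "IGHV3-7" = 3.5,
    "IGHV3-9" = 2.5, "IGHV3-11" = 2.0, "IGHV3-15" = 2.5, "IGHV3-21" = 2.5,
    "IGHV3-23" = 7.0, "IGHV3-30" = 5.0, "IGHV3-33" = 3.0, "IGHV3-48" = 2.5,
    "IGHV3-53" = 2.0, "IGHV3-74" = 2.0, "IGHV4-4" = 2.0, "IGHV4-31" = 2.0,
    "IGHV4-34" = 4.0, "IGHV4-39" = 3.5, "IGHV4-59" = 3.5, "IGHV4-61" = 1.5,
    "IGHV5-51" = 3.0, "IGHV6-1" = 1.5, "IGHV7-4-1" = 1.0
  )
  genes / sum(genes)
}

default_jgene_frequencies <- function() {
  j <- c("IGHJ1" = 0.02, "IGHJ2" = 0.04, "IGHJ3" = 0.08, "IGHJ4" = 0.50,
         "IGHJ5" = 0.12, "IGHJ6" = 0.24)
  j / sum(j)
}

# CDR3 nucleotide length distribution: 30..66 nt, peaked around 45.
default_cdr3_lengths <- function() {
  lens <- seq(30, 66, by = 3)
  w <- stats::dnorm(lens, mean = 45, sd = 7.5)
  stats::setNames(w / sum(w), lens)
}

# Discrete clone-size laws ------------------------------------------------

size_law_pmf <- function(law) {
  s <- seq_len(law$max_size %||% 1000)
  p <- switch(law$type,
    powerlaw = s^(-(law$exponent %||% 2.5)),
    lognormal = stats::dlnorm(s, law$meanlog %||% 0.3, law$sdlog %||% 0.8),
    stop("unknown clone_size_law type: ", law$type)
  )
  p / sum(p)
}

# Entropy offset of a size law: for N iid clone sizes,
# H ~ log2(N * mu) - E[s log2 s] / mu, so H - log2 N -> offset below.
# `expansion` transforms a fraction of clones to round(mult * s).
size_law_entropy_offset <- function(pmf, persistent_fraction = 0,
                                    expansion = 1) {
  s <- seq_along(pmf)
  if (persistent_fraction > 0 && expansion != 1) {
    s_exp <- pmax(1, round(expansion * s))
    mu <- (1 - persistent_fraction) * sum(pmf * s) +
      persistent_fraction * sum(pmf * s_exp)
    el <- (1 - persistent_fraction) * sum(pmf * s * log2(s)) +
      persistent_fraction * sum(pmf * s_exp * log2(s_exp))
  } else {
    mu <- sum(pmf * s)
    el <- sum(pmf * s * log2(s))
  }
  log2(mu) - el / mu
}

#' Simulation configuration for a synthetic longitudinal BCR cohort
#'
#' Encodes the cohort structure the generator emulates: three clinical
#' outcome groups (NP, PNR, PR) sampled longitudinally, heavy-tailed clone
#' sizes, group-specific baseline diversity and time trends (PR highest
#' baseline entropy and declining, NP lowest and rising, PNR flat),
#' persistent clones with group-specific expansion, clones shared between
#' subjects within a group, configurable per-group IGHV usage tilts, and
#' somatic hypermutation.
#'
#' Diversity targets are stated in entropy units (bits); the generator's
#' primitive parameters are per-group log richness, derived internally from
#' the entropy targets through the clone-size-law entropy offset
#' (see the methods vignette).  Supply `baseline_log_richness` /
#' `richness_slope_per_month` directly to bypass the derivation.
#'
#' @param n_subjects Named integer vector, subjects per group.
#' @param time_points Sampling times in months, ascending.
#' @param baseline_entropy_bits Per-group expected entropy at month 0.
#' @param entropy_slope_bits_per_month Per-group entropy trend.
#' @param baseline_log_richness,richness_slope_per_month Optional direct
#'   parameterisation (natural-log clone counts); overrides the entropy
#'   derivation when supplied.
#' @param sigma_subject SD of the per-subject random effect on log
#'   richness.
#' @param clone_size_law List: `type` (`"powerlaw"` or `"lognormal"`) plus
#'   parameters (`exponent`, `max_size`; `meanlog`, `sdlog`).
#' @param vgene_frequencies,jgene_frequencies Named probability vectors.
#' @param vgene_group_multipliers Named list per group of named multipliers
#'   applied to `vgene_frequencies` (renormalised), e.g.
#'   `list(PR = c("IGHV3-23" = 2.5))`.
#' @param cdr3_length_distribution Named probability vector over CDR3
#'   nucleotide lengths.
#' @param shm_rate Per-group per-base V-segment mutation probability.
#' @param variant_fraction Fraction of a clone's reads carrying additional
#'   (read-level) mutations; the remainder are exact copies of the clone
#'   founder, which is what creates multi-read network vertices.
#' @param persistent_clone_fraction Per-group fraction of a subject's
#'   baseline clones designated persistent (re-emitted at every time
#'   point).
#' @param expansion_multiplier Per-group size multiplier for persistent
#'   clones.
#' @param shared_clone_count Per-group number of founders re-used across
#'   (at least two) subjects of the group.
#' @param isotype_mix Named probability vector over isotype labels.
#' @param v_segment_length,j_segment_length Lengths of the simulated V and
#'   J segments flanking the CDR3 in the emitted full sequence.
#' @param seed Default seed for [generate_cohort()].
#' @return A validated list of class `bcrdyn_simconfig`.
#' @export
simulation_config <- function(
    n_subjects = c(NP = 10, PNR = 10, PR = 7),
    time_points = c(0, 6, 24),
    baseline_entropy_bits = c(NP = 7.7, PNR = 7.95, PR = 8.2),
    entropy_slope_bits_per_month = c(NP = 0.05, PNR = 0, PR = -0.05),
    baseline_log_richness = NULL,
    richness_slope_per_month = NULL,
    sigma_subject = 0.2,
    clone_size_law = list(type = "powerlaw", exponent = 2.5,
                          max_size = 100),
    vgene_frequencies = default_vgene_frequencies(),
    jgene_frequencies = default_jgene_frequencies(),
    vgene_group_multipliers = list(PR = c("IGHV3-23" = 2.5)),
    cdr3_length_distribution = default_cdr3_lengths(),
    shm_rate = c(NP = 0.010, PNR = 0.012, PR = 0.015),
    variant_fraction = 0.25,
    persistent_clone_fraction = c(NP = 0.03, PNR = 0.03, PR = 0.03),
    expansion_multiplier = c(NP = 1, PNR = 1.5, PR = 3),
    shared_clone_count = c(NP = 0, PNR = 5, PR = 6),
    isotype_mix = c(IgM = 0.40, IgD = 0.25, IgG = 0.18, IgA = 0.15,
                    IgE = 0.02),
    v_segment_length = 270,
    j_segment_length = 30,
    seed = 1L) {
  groups <- names(n_subjects)
  stopifnot(all(groups %in% OUTCOME_LEVELS), all(n_subjects >= 0),
            !is.unsorted(time_points), all(time_points >= 0))
  for (p in list(vgene_frequencies, jgene_frequencies,
                 cdr3_length_distribution, isotype_mix)) {
    if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
    if (any(p < 0)) stop("probabilities must be non-negative")
  }
  pmf <- size_law_pmf(clone_size_law)
  if (is.null(baseline_log_richness) || is.null(richness_slope_per_month)) {
    offset <- vapply(groups, function(g) {
      size_law_entropy_offset(pmf, persistent_clone_fraction[[g]],
                              expansion_multiplier[[g]])
    }, numeric(1))
    baseline_log_richness <- baseline_log_richness %||%
      ((baseline_entropy_bits[groups] - offset) * log(2))
    richness_slope_per_month <- richness_slope_per_month %||%
      (entropy_slope_bits_per_month[groups] * log(2))
  }
  structure(list(
    n_subjects = n_subjects, time_points = time_points,
    baseline_entropy_bits = baseline_entropy_bits,
    entropy_slope_bits_per_month = entropy_slope_bits_per_month,
    baseline_log_richness = baseline_log_richness,
    richness_slope_per_month = richness_slope_per_month,
    sigma_subject = sigma_subject, clone_size_law = clone_size_law,
    size_pmf = pmf, size_cdf = cumsum(pmf)[-length(pmf)],
    vgene_frequencies = vgene_frequencies,
    jgene_frequencies = jgene_frequencies,
    vgene_group_multipliers = vgene_group_multipliers,
    cdr3_length_distribution = cdr3_length_distribution,
    shm_rate = shm_rate, variant_fraction = variant_fraction,
    persistent_clone_fraction = persistent_clone_fraction,
    expansion_multiplier = expansion_multiplier,
    shared_clone_count = shared_clone_count,
    isotype_mix = isotype_mix,
    v_segment_length = v_segment_length,
    j_segment_length = j_segment_length,
    seed = seed
  ), class = "bcrdyn_simconfig")
}

# n random nucleotide strings with the given lengths, drawn in one pass
BASE_CODES <- utf8ToInt("ACGT")
rand_strings <- function(lens) {
  if (!length(lens)) return(character(0))
  codes <- sample(BASE_CODES, sum(lens), replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  all <- intToUtf8(codes)
  substring(all, starts, ends)
}

# substitute n_mut positions of s with a different random base
ALT_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
mutate_string <- function(s, n_mut) {
  if (n_mut == 0) return(s)
  L <- nchar(s)
  pos <- sample.int(L, min(n_mut, L))
  for (p in pos) {
    alt <- ALT_BASES[[substr(s, p, p)]]
    substr(s, p, p) <- alt[sample.int(length(alt), 1L)]
  }
  s
}

# draw founders (one row each) for a group
draw_founders <- function(n, group, cfg) {
  vp <- cfg$vgene_frequencies
  mult <- cfg$vgene_group_multipliers[[group]]
  if (!is.null(mult)) {
    vp[names(mult)] <- vp[names(mult)] * mult
    vp <- vp / sum(vp)
  }
  lens <- as.integer(sample(names(cfg$cdr3_length_distribution), n,
                            replace = TRUE,
                            prob = cfg$cdr3_length_distribution))
  data.frame(
    v_gene = sample(names(vp), n, replace = TRUE, prob = vp),
    j_gene = sample(names(cfg$jgene_frequencies), n, replace = TRUE,
                    prob = cfg$jgene_frequencies),
    cdr3_length = lens,
    cdr3 = rand_strings(lens),
    v_seg = rand_strings(rep(cfg$v_segment_length, n)),
    j_seg = rand_strings(rep(cfg$j_segment_length, n)),
    v_mut = stats::rbinom(n, cfg$v_segment_length, cfg$shm_rate[[group]]),
    isotype = sample(names(cfg$isotype_mix), n, replace = TRUE,
                     prob = cfg$isotype_mix),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws, for every subject-by-time sample, a target clone count from
#' `exp(baseline_log_richness[group] + slope[group] * month + subject
#' effect)`, clone sizes from the configured heavy-tailed law (persistent
#' clones scaled by the group expansion multiplier), founder V/J/CDR3
#' identities (with per-group IGHV tilts), and emits reads as
#' hypermutation-perturbed copies of the founders.  Read-level CDR3
#' mutations are capped at 5% of positions, so all within-clone CDR3 pairs
#' stay at or above 90% identity and the true clone partition is
#' recoverable.  Persistent founders recur at every time point of their
#' subject; shared founders recur across subjects within a group.  Fully
#' deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List with `reads` (annotated AIRR-style reads, all productive
#'   IGH), `meta` (sample metadata with subject covariates) and `truth`
#'   (ground truth: read-to-clone map, founder table with
#'   persistent/shared flags, per-sample true diversity inputs, and the
#'   generative coefficients).
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "bcrdyn_simconfig"))
  cfg <- config
  set.seed(seed %||% cfg$seed)
  groups <- names(cfg$n_subjects)

  subjects <- do.call(rbind, lapply(groups, function(g) {
    n <- cfg$n_subjects[[g]]
    if (n == 0) return(NULL)
    data.frame(group = g, idx = seq_len(n), stringsAsFactors = FALSE)
  }))
  subjects$subject_id <- sprintf("S%02d", seq_len(nrow(subjects)))
  subjects$u <- stats::rnorm(nrow(subjects), 0, cfg$sigma_subject)
  subjects$age <- sample(1:19, nrow(subjects), replace = TRUE)
  subjects$sex <- sample(c("M", "F"), nrow(subjects), replace = TRUE)
  subjects$immunosuppression <- sample(c("steroid_based", "steroid_free"),
                                       nrow(subjects), replace = TRUE)
  subjects$hla_mismatch <- sample(1:6, nrow(subjects), replace = TRUE)

  # shared founders per group, each handed to >= 2 subjects of the group
  shared_assign <- list()  # subject_id -> founder ids
  shared_tab <- list()     # group -> founder data.frame
  founder_seq <- 0L
  founder_rows <- list()
  for (g in groups) {
    n_sh <- cfg$shared_clone_count[[g]]
    if (n_sh == 0) next
    subj_g <- subjects$subject_id[subjects$group == g]
    if (length(subj_g) < 2) {
      stop("shared_clone_count for group ", g,
           " requires at least two subjects (config error)")
    }
    f <- draw_founders(n_sh, g, cfg)
    f$founder_id <- sprintf("F%06d", founder_seq + seq_len(n_sh))
    founder_seq <- founder_seq + n_sh
    f$shared <- TRUE
    founder_rows[[length(founder_rows) + 1L]] <- f
    shared_tab[[g]] <- f
    for (k in seq_len(n_sh)) {
      carriers <- sample(subj_g, sample(2:min(3, length(subj_g)), 1))
      for (s in carriers) {
        shared_assign[[s]] <- c(shared_assign[[s]], f$founder_id[k])
      }
    }
  }

  reads_acc <- list()
  truth_acc <- list()
  meta_rows <- list()
  samp_truth <- list()
  persistent_ids <- list()
  read_seq <- 0L

  for (si in seq_len(nrow(subjects))) {
    g <- subjects$group[si]
    sid <- subjects$subject_id[si]
    b <- cfg$baseline_log_richness[[g]]
    m <- cfg$richness_slope_per_month[[g]]
    u <- subjects$u[si]
    n0 <- max(1L, as.integer(round(exp(b + u))))
    sh_ids <- shared_assign[[sid]] %||% character(0)
    n_pers <- max(length(sh_ids),
                  as.integer(round(cfg$persistent_clone_fraction[[g]] * n0)))
    n_new_pers <- n_pers - length(sh_ids)
    pers_df <- NULL
    if (length(sh_ids)) {
      st <- shared_tab[[g]]
      pers_df <- st[match(sh_ids, st$founder_id), , drop = FALSE]
    }
    if (n_new_pers > 0) {
      pers <- draw_founders(n_new_pers, g, cfg)
      pers$founder_id <- sprintf("F%06d", founder_seq + seq_len(n_new_pers))
      founder_seq <- founder_seq + n_new_pers
      pers$shared <- FALSE
      founder_rows[[length(founder_rows) + 1L]] <- pers
      pers_df <- rbind(pers_df, pers)
    }
    persistent_ids[[sid]] <- pers_df$founder_id %||% character(0)

    for (t in cfg$time_points) {
      n_t <- max(n_pers + 1L, as.integer(round(exp(b + m * t + u))))
      n_fresh <- n_t - n_pers
      fresh <- draw_founders(n_fresh, g, cfg)
      fresh$founder_id <- sprintf("F%06d", founder_seq + seq_len(n_fresh))
      founder_seq <- founder_seq + n_fresh
      fresh$shared <- FALSE
      founder_rows[[length(founder_rows) + 1L]] <- fresh

      samp <- sprintf("%s_t%02d", sid, t)
      meta_rows[[samp]] <- data.frame(
        sample_id = samp, subject_id = sid, time_months = t, outcome = g,
        source = "gDNA", age = subjects$age[si], sex = subjects$sex[si],
        immunosuppression = subjects$immunosuppression[si],
        hla_mismatch = subjects$hla_mismatch[si], stringsAsFactors = FALSE
      )

      frow <- rbind(pers_df, fresh)
      # clone sizes; persistent clones carry the group expansion multiplier
      sizes <- findInterval(stats::runif(n_t), cfg$size_cdf) + 1L
      mult <- cfg$expansion_multiplier[[g]]
      if (n_pers > 0 && mult != 1) {
        sizes[seq_len(n_pers)] <-
          pmax(1L, as.integer(round(mult * sizes[seq_len(n_pers)])))
      }
      total <- sum(sizes)
      n_var <- stats::rbinom(n_t, sizes, cfg$variant_fraction)
      n_copy <- sizes - n_var

      f_vseg <- frow$v_seg; f_cdr3 <- frow$cdr3; f_jseg <- frow$j_seg
      f_vmut <- frow$v_mut; f_len <- frow$cdr3_length
      f_id <- frow$founder_id
      fulls <- paste0(f_vseg, f_cdr3, f_jseg)
      clone_rep <- rep(seq_len(n_t), sizes)
      # default every read to an exact founder copy, then perturb variants
      seqs <- fulls[clone_rep]
      juncs <- f_cdr3[clone_rep]
      vids <- 1 - f_vmut[clone_rep] / cfg$v_segment_length
      n_var_total <- sum(n_var)
      if (n_var_total > 0) {
        block_start <- cumsum(sizes) - sizes + 1L
        var_idx <- rep(block_start + n_copy - 1L, n_var) + sequence(n_var)
        var_clone <- rep(seq_len(n_t), n_var)
        ev <- stats::rpois(n_var_total, 1)
        ec <- pmin(stats::rpois(n_var_total, 0.3),
                   floor(0.05 * f_len[var_clone]))
        vids[var_idx] <- 1 - (f_vmut[var_clone] + ev) / cfg$v_segment_length
        for (w in which(ev > 0 | ec > 0)) {
          j <- var_idx[w]; ci <- var_clone[w]
          v2 <- mutate_string(f_vseg[ci], ev[w])
          c2 <- mutate_string(f_cdr3[ci], ec[w])
          seqs[j] <- paste0(v2, c2, f_jseg[ci])
          juncs[j] <- c2
        }
      }
      ids <- sprintf("R%08d", read_seq + seq_len(total))
      read_seq <- read_seq + total
      reads_acc[[samp]] <- data.frame(
        sequence_id = ids, sample_id = samp, sequence = seqs,
        productive = TRUE, locus = "IGH",
        v_call = paste0(frow$v_gene[clone_rep], "*01"),
        j_call = frow$j_gene[clone_rep],
        junction = juncs, v_identity = vids,
        isotype = frow$isotype[clone_rep],
        has_v_indel = FALSE, duplicate_count = 1L,
        stringsAsFactors = FALSE
      )
      truth_acc[[samp]] <- data.frame(
        sequence_id = ids, sample_id = samp, true_clone = f_id[clone_rep],
        stringsAsFactors = FALSE
      )
      samp_truth[[samp]] <- data.frame(
        sample_id = samp, true_richness = n_t,
        true_entropy = shannon_entropy(sizes), stringsAsFactors = FALSE
      )
    }
  }

  ftab <- do.call(rbind, founder_rows)
  ftab$persistent <- ftab$founder_id %in% unlist(persistent_ids)
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  reads <- do.call(rbind, reads_acc)
  rownames(reads) <- NULL
  reads <- annotate_reads(reads, meta)

  truth <- list(
    read_clone = do.call(rbind, truth_acc),
    founders = ftab,
    persistent_by_subject = persistent_ids,
    sample_truth = do.call(rbind, samp_truth),
    coefficients = list(
      baseline_log_richness = cfg$baseline_log_richness,
      richness_slope_per_month = cfg$richness_slope_per_month,
      subject_effects = stats::setNames(subjects$u, subjects$subject_id)
    )
  )
  rownames(truth$read_clone) <- rownames(truth$sample_truth) <- NULL
  list(reads = reads, meta = meta, truth = truth)
}

#' True per-sample diversity from generator ground truth
#'
#' Richness is the number of true clones per sample; entropy is the Shannon
#' entropy (bits) of the true clone read counts.
#'
#' @param truth The `truth` element returned by [generate_cohort()].
#' @return `data.frame`: sample_id, richness, entropy.
#' @export
truth_diversity <- function(truth) {
  rc <- truth$read_clone
  rows <- lapply(split(rc$true_clone, rc$sample_id), function(cl) {
    counts <- as.numeric(table(cl))
    data.frame(richness = length(counts),
               entropy = shannon_entropy(counts))
  })
  out <- do.call(rbind, rows)
  out <- data.frame(sample_id = names(rows), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
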