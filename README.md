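# bcrdyn — longitudinal B-cell receptor repertoire dynamics

`bcrdyn` is an R package for analysing longitudinal B-cell receptor (BCR)
heavy-chain repertoires across clinical outcome groups — for example,
kidney-transplant recipients sampled before transplant and at 6 and 24
months, classified as non-progressors (NP), progressors without rejection
(PNR) and progressors with rejection (PR). It is aimed at immunologists
and biostatisticians who have AIRR-annotated rearrangement data (e.g.
IgBLAST output) and want a tested, reproducible path from reads to
group-level inference.

## What it computes

* **Clonotypes.** A clone is a set of reads with the same IGHV gene, the
  same IGHJ gene, the same CDR3 nucleotide length and CDR3 nucleotide
  identity ≥ 90%, closed under single linkage. Samples with fewer than
  100 clones are excluded.
* **Diversity.** Species richness *N* (number of clones) and Shannon
  entropy in bits,

  *H* = −Σᵢ pᵢ log₂ pᵢ,  0 ≤ *H* ≤ *H*max = log₂ *N*,

  plus somatic hypermutation frequency (read-weighted mean of
  1 − v_identity), with a depth-matched downsampling mode (default 10
  replicates) to control sequencing-depth bias.
* **Models.** Cross-sectional OLS of a per-sample summary on outcome
  group at each time point (NP reference, all pairwise contrasts), and a
  conditional-growth linear mixed model
  `response ~ group * time + (1 + time | subject)` whose group-by-time
  interaction is the headline longitudinal test.
* **Networks.** Per-sample repertoire networks (vertices = identical
  sequences, clusters = clones) summarised by Gini indices of vertex and
  cluster size, Gini(V) and Gini(C).
* **Clone dynamics.** Exact conditional (Fisher / Freeman–Halton) tests
  of clone presence against outcome, persistence across time points,
  sharing across subjects, and linear models of persistence and clonal
  expansion.
* **IGHV usage.** Clone-normalised gene usage, a prevalence filter
  (usage ≥ 0.05 in ≥ 10% of samples), per-time-point differential usage
  with Benjamini–Hochberg FDR, and gene-set enrichment (e.g. IGHV3-23
  among shared persistent clones).
* **Synthetic cohorts.** `simulation_config()` / `generate_cohort()`
  produce seeded three-group longitudinal cohorts with known ground
  truth (clone partition, diversity trajectories, persistent/shared
  clones, gene-usage tilts), so the whole pipeline is testable without
  any external data.

## A worked example

```r
library(bcrdyn)

cfg <- list(simulation = simulation_config(),
            downsample = list(n_replicates = 10, min_reads = 1000))
run <- run_pipeline(cfg, seed = 1)
print(run)
```

```
BCR repertoire pipeline run
  samples retained: 81
  pooled clones:    36554
  multi-sample clones: 333
  persistent clones: 333  shared: 11
  IGHV genes after low-usage filter: 10
```

All 81 simulated samples clear the 100-clone threshold; 36,554 clones are
inferred across the pooled cohort, of which 333 occur in more than one
sample, 333 persist across time points within a subject and 11 are shared
between subjects (the configured 5 PNR + 6 PR shared founders). The
headline longitudinal test:

```r
run$models$lmm$entropy$interaction
#                  term  f_value df1 df2      p_value
#   outcome:time_months 138.2286   2  51 2.550324e-21
```

The entropy trajectories of the groups diverge (NP rising, PR falling),
exactly as configured in the generator. Differential IGHV usage at
baseline recovers the configured PR tilt of IGHV3-23:

```r
head(run$usage$differential$t0, 3)
#       gene     estimate   std_error      p_value      q_value significant
#   IGHV3-23  0.113996290 0.007381000 5.738044e-14 5.738044e-13        TRUE
#    IGHV3-7 -0.009393008 0.004332572 4.029844e-02 2.014922e-01       FALSE
#   IGHV5-51 -0.010017222 0.005127201 6.248278e-02 2.082759e-01       FALSE
```

For real data, replace `simulation` with `airr_path`/`meta_path` (an AIRR
Rearrangement TSV and a sample metadata table), or call the stage
functions (`read_rearrangements()`, `filter_reads()`, `assign_clones()`,
`sample_diversity()`, `network_summary()`, …) directly.

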