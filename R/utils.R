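# Internal helpers shared across modules.

OUTCOME_LEVELS <- c("NP", "PNR", "PR")
ISOTYPE_LEVELS <- c("IgM", "IgD", "IgG", "IgA", "IgE", "unknown")

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Collapse an IGHV/IGHJ allele call to gene level: first listed call wins for
# multi-assignments ("IGHV3-23,IGHV3-23D"), allele suffixes stripped
# ("IGHV3-23*01" -> "IGHV3-23").
collapse_gene <- function(call) {
  g <- sub(",.*$", "", as.character(call))
  sub("\\*.*$", "", g)
}

# Derive a per-stage seed from the global seed; keeps results < 2^31 so the
# value is a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.double(seed) * 48271 + stage * 16807) %% 2147483647L) + 1L
}

# Outcome factor with NP as the reference level; tolerates a subset of levels.
outcome_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), OUTCOME_LEVELS)
  if (length(bad)) {
    stop("unknown outcome group(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = intersect(OUTCOME_LEVELS, unique(x)))
}

# Weighted mean that propagates an all-NA input as NA rather than NaN.
weighted_mean_na <- function(x, w) {
  keep <- !is.na(x)
  if (!any(keep)) return(NA_real_)
  sum(x[keep] * w[keep]) / sum(w[keep])
}

stop_missing_column <- function(cols, required) {
  miss <- setdiff(required, cols)
  if (length(miss)) {
    stop("required column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
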