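#' Read an AIRR rearrangement table and join sample metadata
#'
#' Reads a tab-separated AIRR Rearrangement file (one row per sequencing read)
#' and joins it to a sample metadata table carrying subject, time point and
#' clinical outcome.  Rows with a missing V call, J call or CDR3 are returned
#' flagged invalid (`valid = FALSE`) rather than silently dropped, so that
#' read-level QC accounting stays exact.
#'
#' The junction column may be named `junction` or `cdr3`; the first present is
#' used (override with `column_map`).  Unknown columns are preserved.
#'
#' @param path Path to a tab-separated rearrangement file with a header. The
#'   required columns are `sequence_id`, `sample_id`, `v_call`, `j_call`,
#'   `productive` and a junction column.
#' @param meta Sample metadata `data.frame` with columns `sample_id`,
#'   `subject_id`, `time_months`, `outcome`, and optionally `source` plus any
#'   clinical covariates.
#' @param column_map Optional named character vector mapping canonical names
#'   (e.g. `junction`) to the column names used in the file.
#' @return A `data.frame` of annotated reads: the file columns (junction
#'   normalised to `junction`), the joined metadata columns, derived
#'   `has_v_indel` and `locus` when absent, `duplicate_count` (default 1),
#'   and a logical `valid` column.
#' @seealso [filter_reads()], [write_table()]
#' @export
read_rearrangements <- function(path, meta, column_map = NULL) {
  stopifnot(is.data.frame(meta))
  stop_missing_column(names(meta),
                      c("sample_id", "subject_id", "time_months", "outcome"))
  reads <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = c("", "NA"))
  for (canon in names(column_map)) {
    if (column_map[[canon]] %in% names(reads)) {
      names(reads)[names(reads) == column_map[[canon]]] <- canon
    }
  }
  if (!"junction" %in% names(reads) && "cdr3" %in% names(reads)) {
    names(reads)[names(reads) == "cdr3"] <- "junction"
  }
  stop_missing_column(names(reads), c("sequence_id", "sample_id", "v_call",
                                      "j_call", "productive", "junction"))
  annotate_reads(reads, meta)
}

# Shared between file ingestion and the in-memory path used for simulated
# cohorts: metadata join, type coercion, validity flagging.
annotate_reads <- function(reads, meta) {
  unknown <- setdiff(unique(reads$sample_id), meta$sample_id)
  if (length(unknown)) {
    stop("sample_id absent from metadata (provenance error): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(reads$sample_id, meta$sample_id)
  for (col in c("subject_id", "time_months", "outcome", "source")) {
    if (col %in% names(meta)) reads[[col]] <- meta[[col]][idx]
  }
  if (is.character(reads$productive) || is.factor(reads$productive)) {
    reads$productive <- toupper(as.character(reads$productive)) %in%
      c("T", "TRUE", "YES", "1")
  }
  if (!"locus" %in% names(reads)) {
    reads$locus <- ifelse(startsWith(as.character(reads$v_call), "IGH"),
                          "IGH", "other")
  }
  if (!"has_v_indel" %in% names(reads)) {
    if ("v_cigar" %in% names(reads)) {
      reads$has_v_indel <- grepl("[ID]", reads$v_cigar)
    } else {
      warning("no V-indel information (has_v_indel / v_cigar); ",
              "treating all reads as indel-free")
      reads$has_v_indel <- FALSE
    }
  }
  if (is.character(reads$has_v_indel)) {
    reads$has_v_indel <- toupper(reads$has_v_indel) %in% c("T", "TRUE", "1")
  }
  if (!"duplicate_count" %in% names(reads)) reads$duplicate_count <- 1L
  reads$duplicate_count[is.na(reads$duplicate_count)] <- 1L
  if (!"v_identity" %in% names(reads)) reads$v_identity <- NA_real_
  if (!"isotype" %in% names(reads)) reads$isotype <- "unknown"
  reads$valid <- !is.na(reads$v_call) & !is.na(reads$j_call) &
    !is.na(reads$junction) & nzchar(reads$junction) &
    grepl("^[ACGTN]+$", reads$junction)
  rownames(reads) <- NULL
  reads
}

#' Apply read-level quality-control filters
#'
#' Retains productive heavy-chain (IGH) reads without V-segment indels and
#' with a valid CDR3.  Reads flagged chimeric by the upstream annotator (a
#' logical `chimera` column, when present) are removed; chimera detection is
#' not re-derived here.  Each removed read is counted under exactly one
#' reason (priority: non-IGH, nonfunctional, V indel, chimera, invalid CDR3),
#' so per-sample reason counts sum to the number of removed reads.
#'
#' @param reads Annotated reads from [read_rearrangements()].
#' @return A list with `reads` (the retained rows) and `qc`, a `data.frame`
#'   of per-sample counts: input, retained, and one column per removal
#'   reason.
#' @export
filter_reads <- function(reads) {
  reason <- rep(NA_character_, nrow(reads))
  mark <- function(cond, label) {
    ifelse(is.na(reason) & cond, label, reason)
  }
  reason <- mark(reads$locus != "IGH", "non_igh")
  reason <- mark(!reads$productive, "nonfunctional")
  reason <- mark(reads$has_v_indel, "v_indel")
  if ("chimera" %in% names(reads)) {
    reason <- mark(reads$chimera %in% c(TRUE, "T", "TRUE"), "chimeric")
  }
  reason <- mark(!reads$valid, "invalid_cdr3")

  keep <- is.na(reason)
  reasons <- c("non_igh", "nonfunctional", "v_indel", "chimeric",
               "invalid_cdr3")
  samples <- unique(as.character(reads$sample_id))
  qc <- data.frame(sample_id = samples, input = 0L, retained = 0L,
                   stringsAsFactors = FALSE)
  for (r in reasons) qc[[r]] <- 0L
  tab_in <- table(reads$sample_id)
  qc$input <- as.integer(tab_in[qc$sample_id])
  tab_keep <- table(reads$sample_id[keep])
  qc$retained <- as.integer(ifelse(is.na(tab_keep[qc$sample_id]), 0L,
                                   tab_keep[qc$sample_id]))
  for (r in reasons) {
    t <- table(reads$sample_id[!keep & reason == r])
    if (length(t)) {
      hit <- qc$sample_id %in% names(t)
      qc[[r]][hit] <- as.integer(t[qc$sample_id[hit]])
    }
  }
  list(reads = reads[keep, , drop = FALSE], qc = qc)
}

#' Write a result table as deterministic TSV
#'
#' Tab-separated, UTF-8, no quoting, missing values as empty strings, reals
#' written with enough digits that re-reading reproduces them to at least 12
#' significant digits.
#'
#' @param records A `data.frame` with atomic columns.
#' @param path Output file path.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.15g", out[[j]])
      v[is.na(out[[j]]) | is.nan(out[[j]])] <- ""
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path File path.
#' @return A `data.frame` with inferred column types.
#' @export
read_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "")
}
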