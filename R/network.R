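#' Gini index of a size distribution
#'
#' With sizes sorted ascending, \eqn{G = \sum_i (2i - n - 1) x_i / (n \sum x)}.
#' Zero for equal sizes, approaching 1 for maximal inequality;
#' scale-invariant.  The conventional unadjusted estimator (no small-sample
#' correction).
#'
#' @param sizes Positive numbers.
#' @return Gini index in \[0, 1).
#' @export
gini_index <- function(sizes) {
  if (length(sizes) == 0) stop("empty size vector")
  if (any(sizes <= 0)) stop("sizes must be positive")
  x <- sort(sizes)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Build the per-sample B-cell network summary
#'
#' Vertices are unique full rearrangement nucleotide sequences, sized by the
#' number of identical reads; edges connect vertices of the same clone, so
#' clusters coincide with clones (a singleton clone is a cluster of one
#' vertex).  Clonality is quantified by the Gini index of the vertex-size
#' distribution (Gini(V), overall expansion) and of the cluster-size
#' distribution (Gini(C), clonal dominance).
#'
#' @param reads One sample's clone-assigned reads.
#' @param collapse Vertex key: `"sequence"` (full rearrangement, default) or
#'   `"cdr3"`.
#' @param cluster_size Cluster size metric: `"vertices"` (unique sequences
#'   per clone, default) or `"reads"`.
#' @return A list of class `bcrdyn_network`: sample_id, n_vertices,
#'   n_clusters, total_bcr, gini_v, gini_c, and the vertex/cluster size
#'   multisets.
#' @export
build_network <- function(reads, collapse = c("sequence", "cdr3"),
                          cluster_size = c("vertices", "reads")) {
  collapse <- match.arg(collapse)
  cluster_size <- match.arg(cluster_size)
  if (length(unique(reads$sample_id)) != 1) {
    stop("build_network takes reads from a single sample")
  }
  key_col <- if (collapse == "sequence" && "sequence" %in% names(reads))
    "sequence" else "junction"
  vkey <- paste(reads[[key_col]], reads$clone_id, sep = "\r")
  vid <- match(vkey, unique(vkey))
  vertex_sizes <- rowsum(as.numeric(reads$duplicate_count), vid)[, 1]
  vertex_clone <- reads$clone_id[!duplicated(vkey)]
  cluster_sizes <- if (cluster_size == "vertices") {
    as.numeric(table(vertex_clone))
  } else {
    as.numeric(rowsum(vertex_sizes, vertex_clone)[, 1])
  }
  structure(list(
    sample_id = as.character(reads$sample_id[1]),
    n_vertices = length(vertex_sizes),
    n_clusters = length(unique(vertex_clone)),
    total_bcr = sum(as.numeric(reads$duplicate_count)),
    gini_v = gini_index(as.numeric(vertex_sizes)),
    gini_c = gini_index(cluster_sizes),
    vertex_sizes = as.numeric(vertex_sizes),
    cluster_sizes = cluster_sizes
  ), class = "bcrdyn_network")
}

#' @export
print.bcrdyn_network <- function(x, ...) {
  cat(sprintf(
    "B-cell network %s: %d BCR reads, %d vertices, %d clones\n",
    x$sample_id, x$total_bcr, x$n_vertices, x$n_clusters))
  cat(sprintf("  Gini(V) = %.3f  Gini(C) = %.3f\n", x$gini_v, x$gini_c))
  invisible(x)
}

#' Network summaries for every sample
#'
#' @inheritParams build_network
#' @param reads Clone-assigned reads (any number of samples).
#' @return `data.frame` with one row per sample: n_vertices, n_clusters,
#'   total_bcr, gini_v, gini_c.
#' @export
network_summary <- function(reads, collapse = "sequence",
                            cluster_size = "vertices") {
  rows <- lapply(split(seq_len(nrow(reads)), as.character(reads$sample_id)),
                 function(i) {
    nw <- build_network(reads[i, , drop = FALSE], collapse, cluster_size)
    data.frame(sample_id = nw$sample_id, n_vertices = nw$n_vertices,
               n_clusters = nw$n_clusters, total_bcr = nw$total_bcr,
               gini_v = nw$gini_v, gini_c = nw$gini_c,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' igraph representation of one sample's repertoire network
#'
#' For visual inspection (force-directed layouts); edges connect all vertex
#' pairs of the same clone.  Requires the igraph package.
#'
#' @param reads One sample's clone-assigned reads.
#' @param collapse Vertex key, as in [build_network()].
#' @return An igraph graph with vertex attributes `size` (identical-read
#'   count) and `clone_id`.
#' @export
repertoire_graph <- function(reads, collapse = "sequence") {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("repertoire_graph requires the igraph package")
  }
  key_col <- if (collapse == "sequence" && "sequence" %in% names(reads))
    "sequence" else "junction"
  vkey <- paste(reads[[key_col]], reads$clone_id, sep = "\r")
  sizes <- tapply(as.numeric(reads$duplicate_count), vkey, sum)
  clone <- reads$clone_id[match(names(sizes), vkey)]
  ids <- paste0("v", seq_along(sizes))
  edges <- do.call(rbind, lapply(split(seq_along(ids), clone), function(m) {
    if (length(m) < 2) return(NULL)
    t(utils::combn(ids[m], 2))
  }))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "size", value = as.numeric(sizes))
  g <- igraph::set_vertex_attr(g, "clone_id", value = clone)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  g
}
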