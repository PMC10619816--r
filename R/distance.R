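# Biophysical sequence distances ----------------------------------------------
#
# Raw Euclidean distances between sequences in the flattened, filtered
# high-dimensional biophysical property space. Projections (UMAP/PCA) do
# not preserve distances, so distance work happens here, before projection.

#' Pairwise Euclidean distances in the parsed biophysical space
#'
#' @param parsed A \code{parsed_matrix}. Two datasets to be compared must be
#'   co-parsed (identical retained columns), e.g. by parsing their
#'   concatenated tensors.
#' @param feature_subset Optional character vector of feature names: only
#'   retained columns whose source alignment column belongs to these
#'   features enter the metric (e.g. CDR3-only vs all-CDR distances).
#' @return Object of class \code{"distance_matrix"}: symmetric matrix
#'   \code{D} with zero diagonal, \code{chain_scope}, and the column index
#'   of the space the distances were computed in.
#' @export
pairwise_distance <- function(parsed, feature_subset = NULL) {
  stopifnot(inherits(parsed, "parsed_matrix"))
  cols <- seq_len(ncol(parsed$data))
  if (!is.null(feature_subset)) {
    known <- unique(parsed$column_index$feature)
    bad <- setdiff(feature_subset, known)
    if (length(bad) > 0)
      stop("feature(s) not present in the parsed matrix: ",
           paste(bad, collapse = ", "))
    cols <- which(parsed$column_index$feature %in% feature_subset)
  }
  D <- as.matrix(stats::dist(parsed$data[, cols, drop = FALSE]))
  dimnames(D) <- list(rownames(parsed$data), rownames(parsed$data))
  structure(list(D = D,
                 chain_scope = feature_subset %||% "all",
                 column_index = parsed$column_index[cols, ]),
            class = "distance_matrix")
}

#' @export
#' @method print distance_matrix
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix: %d x %d (scope: %s)\n", nrow(x$D), ncol(x$D),
              paste(x$chain_scope, collapse = ", ")))
  invisible(x)
}

#' Flat clusters from a distance matrix at a distance cutoff
#'
#' Hierarchical clustering (default average linkage) cut at height
#' \code{cutoff}.
#'
#' @param D A \code{distance_matrix} or square symmetric matrix.
#' @param cutoff Positive dendrogram height at which to cut.
#' @param linkage \code{"average"} (default), \code{"complete"}, or
#'   \code{"single"}.
#' @return A \code{cluster_assignment} (no noise labels).
#' @export
hierarchical_clusters <- function(D, cutoff,
                                  linkage = c("average", "complete",
                                              "single")) {
  linkage <- match.arg(linkage)
  if (cutoff <= 0) stop("cutoff must be positive")
  M <- if (inherits(D, "distance_matrix")) D$D else as.matrix(D)
  hc <- stats::hclust(stats::as.dist(M), method = linkage)
  labels <- stats::cutree(hc, h = cutoff) - 1L
  structure(list(labels = relabel_contiguous(labels),
                 algorithm = "hierarchical",
                 params = list(cutoff = cutoff, linkage = linkage)),
            class = "cluster_assignment")
}

#' Correlate an internal distance matrix with an external one
#'
#' Pearson correlation over all upper-triangle pairs, and again restricted
#' to "near" pairs whose external distance is at or below a cutoff
#' (optionally also bounding the internal distance), the regime where
#' sequence metrics are expected to agree best.
#'
#' @param D_internal A \code{distance_matrix} (or square matrix).
#' @param D_external Square matrix of the same dimension and sequence order
#'   (e.g. distances imported from another metric).
#' @param near_external Optional external-distance cutoff for the near
#'   subset.
#' @param near_internal Optional additional internal-distance cutoff.
#' @return A list: \code{r_all}, \code{n_all}, \code{r_near}, \code{n_near}.
#' @export
distance_correlation_report <- function(D_internal, D_external,
                                        near_external = NULL,
                                        near_internal = NULL) {
  A <- if (inherits(D_internal, "distance_matrix")) D_internal$D
       else as.matrix(D_internal)
  B <- as.matrix(D_external)
  if (!all(dim(A) == dim(B)))
    stop("distance matrices differ in dimension")
  ut <- upper.tri(A)
  a <- A[ut]; b <- B[ut]
  out <- list(r_all = stats::cor(a, b), n_all = length(a),
              r_near = NA_real_, n_near = 0L)
  near <- rep(TRUE, length(a))
  if (!is.null(near_external)) near <- near & b <= near_external
  if (!is.null(near_internal)) near <- near & a <= near_internal
  if (!is.null(near_external) || !is.null(near_internal)) {
    if (sum(near) >= 3) {
      out$r_near <- stats::cor(a[near], b[near])
      out$n_near <- sum(near)
    }
  }
  out
}

#' Write / read a distance matrix as headered CSV
#'
#' @param D A \code{distance_matrix} or square matrix.
#' @param path File path.
#' @export
write_distance_csv <- function(D, path) {
  M <- if (inherits(D, "distance_matrix")) D$D else as.matrix(D)
  utils::write.csv(M, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
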