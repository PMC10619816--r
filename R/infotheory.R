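# Information-theoretic repertoire statistics ---------------------------------
#
# Position-sensitive residue frequencies, Shannon entropy, mutual
# information (plug-in estimators), and order-sensitive N-gram
# distributions. Frequencies condition on occupancy: pad cells never enter
# p(x), and coverage is reported alongside so low-coverage artifacts stay
# visible.

#' Position-sensitive residue frequencies
#'
#' @param enc An \code{encoded_matrix}.
#' @return An object of class \code{"frequency_profile"}: \code{probs}
#'   (width x 20; each positive row sums to 1, zero-coverage columns are
#'   all-zero) and \code{coverage} (per-column occupancy).
#' @export
position_frequencies <- function(enc) {
  stopifnot(inherits(enc, "encoded_matrix"))
  W <- ncol(enc$codes)
  probs <- matrix(0, W, 20, dimnames = list(NULL, AA_ALPHABET))
  for (w in seq_len(W)) {
    v <- enc$codes[, w]
    v <- v[v > 0L]
    if (length(v) > 0)
      probs[w, ] <- tabulate(v, nbins = 20) / length(v)
  }
  structure(list(probs = probs, coverage = coverage_profile(enc)),
            class = "frequency_profile")
}

# -sum p log2 p with 0 log 0 = 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

#' Per-column Shannon entropy (bits)
#'
#' Base-2 plug-in entropy of the occupancy-conditional residue distribution
#' at each alignment column; the theoretical ceiling is log2(20) = 4.3219
#' bits (all 20 residues equiprobable). Zero-coverage columns score 0.
#'
#' @param x A \code{frequency_profile} or an \code{encoded_matrix}.
#' @return An object of class \code{"entropy_profile"}: \code{H} (bits per
#'   column) and \code{coverage}.
#' @export
shannon_entropy <- function(x) {
  if (inherits(x, "encoded_matrix")) x <- position_frequencies(x)
  stopifnot(inherits(x, "frequency_profile"))
  H <- apply(x$probs, 1, entropy_bits)
  structure(list(H = H, coverage = x$coverage), class = "entropy_profile")
}

#' Pairwise mutual information between alignment columns
#'
#' Plug-in estimator I(X;Y) = H(X) - H(X|Y) in bits, computed from joint
#' residue counts restricted to sequences occupying both columns
#' (pairwise-complete; no small-sample bias correction). The matrix is
#' symmetric, non-negative, and its diagonal equals the per-column entropy.
#'
#' @param enc An \code{encoded_matrix} with at least 2 sequences.
#' @return An object of class \code{"mi_matrix"} wrapping the width x width
#'   matrix \code{I}.
#' @export
mutual_information <- function(enc) {
  stopifnot(inherits(enc, "encoded_matrix"), nrow(enc$codes) >= 2)
  W <- ncol(enc$codes)
  I <- matrix(0, W, W)
  for (i in seq_len(W)) {
    for (j in i:W) {
      x <- enc$codes[, i]; y <- enc$codes[, j]
      m <- x > 0L & y > 0L
      if (!any(m)) next
      joint <- table(factor(x[m], levels = 1:20),
                     factor(y[m], levels = 1:20)) / sum(m)
      val <- entropy_bits(rowSums(joint)) + entropy_bits(colSums(joint)) -
        entropy_bits(as.vector(joint))
      I[i, j] <- I[j, i] <- max(val, 0)
    }
  }
  structure(list(I = I), class = "mi_matrix")
}

#' Order-sensitive N-gram frequencies
#'
#' Slides a window of width \code{n} over each raw feature string
#' independently, never across feature boundaries or alignment pads, and
#' accumulates occurrence probabilities of ordered residue tuples.
#'
#' @param rep A \code{repertoire}.
#' @param n Gram order (>= 1); di-grams by default.
#' @param features Feature names to include (default all).
#' @return An object of class \code{"ngram_distribution"}: \code{n},
#'   \code{probs} (named probability vector over observed grams, summing to
#'   1), \code{counts}, \code{total_windows}. Empty when no sequence is long
#'   enough.
#' @export
ngram_frequencies <- function(rep, n = 2, features = NULL) {
  stopifnot(inherits(rep, "repertoire"), n >= 1)
  if (is.null(features)) features <- rep$feature_names
  counts <- integer(0)
  tally <- new.env(parent = emptyenv())
  total <- 0L
  for (f in features) {
    for (s in rep$features[, f]) {
      s <- gsub("-", "", s)
      L <- nchar(s)
      if (L < n) next
      for (k in seq_len(L - n + 1L)) {
        g <- substr(s, k, k + n - 1L)
        tally[[g]] <- (if (is.null(tally[[g]])) 0L else tally[[g]]) + 1L
        total <- total + 1L
      }
    }
  }
  grams <- sort(ls(tally))
  counts <- vapply(grams, function(g) tally[[g]], integer(1))
  probs <- if (total > 0) counts / total else numeric(0)
  structure(list(n = as.integer(n), probs = probs, counts = counts,
                 total_windows = total),
            class = "ngram_distribution")
}

#' Signed difference of a statistic between two datasets (A - B)
#'
#' Positional statistics (frequency, entropy, mutual information) require
#' the two repertoires to be co-encoded on identical column grids (pin
#' \code{feature_widths} in the alignment spec); N-gram differences align
#' on the union of observed grams.
#'
#' @param A,B \code{encoded_matrix} objects (positional statistics) or
#'   \code{repertoire} objects (\code{statistic = "ngram"}).
#' @param statistic One of \code{"frequency"}, \code{"entropy"},
#'   \code{"mi"}, \code{"ngram"}.
#' @param n Gram order when \code{statistic = "ngram"}.
#' @return The elementwise difference in the natural shape of the statistic
#'   (matrix, vector, or named vector over grams).
#' @export
dataset_difference <- function(A, B,
                               statistic = c("frequency", "entropy", "mi",
                                             "ngram"),
                               n = 2) {
  statistic <- match.arg(statistic)
  if (statistic == "ngram") {
    da <- ngram_frequencies(A, n = n)
    db <- ngram_frequencies(B, n = n)
    grams <- sort(union(names(da$probs), names(db$probs)))
    pa <- ifelse(grams %in% names(da$probs), da$probs[grams], 0)
    pb <- ifelse(grams %in% names(db$probs), db$probs[grams], 0)
    out <- pa - pb
    names(out) <- grams
    return(out)
  }
  stopifnot(inherits(A, "encoded_matrix"), inherits(B, "encoded_matrix"))
  if (ncol(A$codes) != ncol(B$codes) ||
      !identical(A$column_map$feature, B$column_map$feature) ||
      !identical(A$column_map$offset, B$column_map$offset))
    stop("datasets are not co-encoded on the same column grid")
  switch(statistic,
         frequency = position_frequencies(A)$probs -
           position_frequencies(B)$probs,
         entropy = shannon_entropy(A)$H - shannon_entropy(B)$H,
         mi = mutual_information(A)$I - mutual_information(B)$I)
}
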