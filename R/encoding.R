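# Positional integer encoding of repertoires ----------------------------------
#
# Each structural feature is placed independently into a fixed-width window
# under one of four pseudo-structural alignment schemes; windows are
# concatenated (optionally separated by forced pad columns) into one integer
# matrix per repertoire. Codes: 0 = pad, 1..20 = residues in alphabetical
# one-letter order, 21 reserved.

#' Alignment specification for repertoire encoding
#'
#' @param scheme One of \code{"central"}, \code{"left"}, \code{"right"},
#'   \code{"bulge"}. \code{central} anchors each sequence's central residue
#'   at the window center (so variable-length loops overlap at their apex);
#'   \code{left}/\code{right} anchor the N-/C-terminus; \code{bulge} pins
#'   \code{pad_len/2} residues to each window edge (mimicking MHC-buried
#'   peptide anchors) and centrally aligns the remainder.
#' @param pad_len Bulge only: total number of edge-pinned terminal residues,
#'   split evenly between N- and C-termini. Must be even and >= 0.
#' @param feature_widths Optional named (or positional) integer vector of
#'   window widths per feature; defaults to each feature's maximum observed
#'   length. Pinning widths makes two datasets co-encodable on one grid.
#' @param inter_feature_gap Number of forced pad columns between feature
#'   windows (default 0).
#' @return An object of class \code{"alignment_spec"}.
#' @export
alignment_spec <- function(scheme = c("central", "left", "right", "bulge"),
                           pad_len = 0L, feature_widths = NULL,
                           inter_feature_gap = 0L) {
  scheme <- match.arg(scheme)
  pad_len <- as.integer(pad_len)
  if (pad_len < 0L || pad_len %% 2L != 0L)
    stop("pad_len must be a non-negative even integer")
  if (inter_feature_gap < 0L) stop("inter_feature_gap must be >= 0")
  structure(list(scheme = scheme, pad_len = pad_len,
                 feature_widths = feature_widths,
                 inter_feature_gap = as.integer(inter_feature_gap)),
            class = "alignment_spec")
}

#' Central residue of a sequence (0-based index)
#'
#' The center of an even-length sequence is the residue preceding the
#' midway point: odd length L gives (L-1)/2, even length L gives L/2 - 1.
#'
#' @param x An amino-acid string, or an integer length.
#' @return 0-based integer index of the central residue.
#' @export
center_index <- function(x) {
  L <- if (is.character(x)) nchar(x) else as.integer(x)
  if (any(L < 1)) stop("cannot take the center of an empty sequence")
  as.integer((L - 1L) %/% 2L)
}

# 0-based start offset of a length-L sequence inside a width-W window
window_start <- function(L, W, scheme, pad_len) {
  switch(scheme,
         left = 0L,
         right = W - L,
         central = center_index(W) - center_index(L),
         stop("window_start undefined for scheme ", scheme))
}

#' Encode a repertoire as an integer positional matrix
#'
#' @param rep A validated \code{repertoire}.
#' @param spec An \code{\link{alignment_spec}}; default central alignment at
#'   per-feature maximum widths.
#' @return An object of class \code{"encoded_matrix"}: integer matrix
#'   \code{codes} (sequences x total width, entries 0..20), a
#'   \code{column_map} data.frame (column, feature, offset, role), the spec,
#'   and the residue alphabet. Gap characters (\code{-}) in pre-aligned
#'   repertoires encode as pad (0) at their aligned positions.
#' @export
encode_repertoire <- function(rep, spec = alignment_spec("central")) {
  stopifnot(inherits(rep, "repertoire"), inherits(spec, "alignment_spec"))
  n <- nrow(rep$features)
  if (n < 1) stop("cannot encode an empty repertoire")
  nf <- length(rep$feature_names)
  lens <- nchar(rep$features)
  if (!is.matrix(lens)) lens <- matrix(lens, ncol = nf)
  widths <- spec$feature_widths
  if (is.null(widths)) widths <- apply(lens, 2, max)
  widths <- as.integer(rep(widths, length.out = nf))
  for (f in seq_len(nf)) {
    if (any(lens[, f] > widths[f]))
      stop(sprintf("feature '%s' has sequences longer than its window (%d > %d)",
                   rep$feature_names[f], max(lens[, f]), widths[f]))
  }
  gap <- spec$inter_feature_gap
  total <- sum(widths) + gap * (nf - 1L)
  codes <- matrix(0L, n, total)
  col_feature <- character(total)
  col_offset <- integer(total)
  col_role <- character(total)
  col0 <- 0L
  for (f in seq_len(nf)) {
    W <- widths[f]
    block <- matrix(0L, n, W)
    for (i in seq_len(n)) {
      block[i, ] <- place_sequence(rep$features[i, f], W, spec)
    }
    codes[, (col0 + 1L):(col0 + W)] <- block
    col_feature[(col0 + 1L):(col0 + W)] <- rep$feature_names[f]
    col_offset[(col0 + 1L):(col0 + W)] <- seq_len(W) - 1L
    col_role[(col0 + 1L):(col0 + W)] <- "window"
    col0 <- col0 + W
    if (f < nf && gap > 0L) {
      col_feature[(col0 + 1L):(col0 + gap)] <- NA_character_
      col_offset[(col0 + 1L):(col0 + gap)] <- NA_integer_
      col_role[(col0 + 1L):(col0 + gap)] <- "gap"
      col0 <- col0 + gap
    }
  }
  rownames(codes) <- rep$ids
  structure(list(codes = codes,
                 column_map = data.frame(column = seq_len(total),
                                         feature = col_feature,
                                         offset = col_offset,
                                         role = col_role,
                                         stringsAsFactors = FALSE),
                 spec = spec, alphabet = AA_ALPHABET,
                 feature_names = rep$feature_names, ids = rep$ids),
            class = "encoded_matrix")
}

# one feature string -> integer window of width W
place_sequence <- function(s, W, spec) {
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  codes <- match(chars, AA_ALPHABET)
  codes[chars == "-"] <- 0L           # MSA gaps occupy their column as pad
  if (anyNA(codes))
    stop("unencodable character in sequence '", s,
         "': run validate_repertoire() first")
  out <- integer(W)
  if (spec$scheme != "bulge") {
    st <- window_start(L, W, spec$scheme, spec$pad_len)
    out[(st + 1L):(st + L)] <- codes
    return(out)
  }
  nb <- spec$pad_len %/% 2L
  if (L <= spec$pad_len) {
    # degenerate: too short to fill both terminal blocks; fill the N-block
    # first, then the C-block from the right, interior empty
    n_left <- min(L, nb)
    if (n_left > 0L) out[seq_len(n_left)] <- codes[seq_len(n_left)]
    n_right <- L - n_left
    if (n_right > 0L)
      out[(W - n_right + 1L):W] <- codes[(n_left + 1L):L]
    return(out)
  }
  if (nb > 0L) {
    out[seq_len(nb)] <- codes[seq_len(nb)]
    out[(W - nb + 1L):W] <- codes[(L - nb + 1L):L]
  }
  mid <- codes[(nb + 1L):(L - nb)]
  Wi <- W - 2L * nb
  if (length(mid) > Wi)
    stop("sequence longer than its window under bulge alignment")
  if (length(mid) > 0L) {
    st <- center_index(Wi) - center_index(length(mid))
    out[nb + (st + 1L):(st + length(mid))] <- mid
  }
  out
}

#' @export
#' @method print encoded_matrix
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("Encoded matrix: %d sequences x %d columns (%s alignment)\n",
              nrow(x$codes), ncol(x$codes), x$spec$scheme))
  invisible(x)
}

#' Decode one encoded row back to its feature strings
#'
#' Reads the non-zero codes of a row left-to-right within each feature
#' window; lossless for validated, gap-free input.
#'
#' @param enc An \code{encoded_matrix}.
#' @param i Row index.
#' @return Named character vector, one string per feature.
#' @export
decode_row <- function(enc, i) {
  out <- character(length(enc$feature_names))
  names(out) <- enc$feature_names
  for (f in enc$feature_names) {
    cols <- enc$column_map$column[!is.na(enc$column_map$feature) &
                                    enc$column_map$feature == f]
    v <- enc$codes[i, cols]
    out[f] <- paste(enc$alphabet[v[v > 0L]], collapse = "")
  }
  out
}

#' Per-column occupancy of an encoded matrix
#'
#' @param enc An \code{encoded_matrix}.
#' @return Numeric vector: fraction of sequences with a residue (non-pad)
#'   at each column. Forced gap columns are exactly 0.
#' @export
coverage_profile <- function(enc) {
  colMeans(enc$codes > 0L)
}
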