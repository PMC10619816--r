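# Biophysical property tensors ------------------------------------------------
#
# Every residue carries 62 values: 1 positional-visualization value plus 61
# biophysical properties. Each property is Z-score normalized across the 20
# residues of the dictionary (never across the dataset), so pad cells (0)
# sit at the dictionary mean of every property.

#' Load a residue property dictionary
#'
#' Reads a 20-row CSV (residues in alphabetical one-letter order, first
#' column \code{residue}) of per-residue property values and Z-score
#' normalizes each property across the 20 residues using the population
#' standard deviation (divisor 20). The bundled default couples canonical
#' published scales (hydropathy, charge, volume, flexibility, secondary
#' structure propensities, ...) with class indicators and derived
#' hotspot-style descriptors; it is a synthetic stand-in for any in-house
#' dictionary and fully user-replaceable.
#'
#' @param path Path to a property CSV; \code{NULL} loads the bundled table.
#' @return An object of class \code{"property_table"}: \code{property_names},
#'   \code{raw} and \code{normalized} 20 x P matrices (rownames = residues),
#'   and \code{dropped} (names of zero-variance properties removed with a
#'   warning).
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_properties_synthetic.csv",
                        package = "repbiophys")
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "residue"))
    stop("property table must have a leading 'residue' column")
  if (nrow(df) != 20 || anyDuplicated(df$residue))
    stop("property table must have exactly 20 unique residue rows")
  if (!setequal(df$residue, AA_ALPHABET))
    stop("property table residues must be the 20 standard one-letter codes")
  df <- df[match(AA_ALPHABET, df$residue), ]
  raw <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(raw)) stop("non-numeric value in property table")
  rownames(raw) <- AA_ALPHABET
  if (anyDuplicated(colnames(raw))) stop("duplicate property names")
  mu <- colMeans(raw)
  sdev <- sqrt(colMeans(sweep(raw, 2, mu)^2))  # population sd, divisor 20
  constant <- sdev < .Machine$double.eps^0.5
  if (any(constant)) {
    warning("dropping zero-variance propert",
            if (sum(constant) > 1) "ies: " else "y: ",
            paste(colnames(raw)[constant], collapse = ", "))
  }
  raw <- raw[, !constant, drop = FALSE]
  normalized <- sweep(sweep(raw, 2, mu[!constant]), 2, sdev[!constant], "/")
  structure(list(property_names = colnames(raw), raw = raw,
                 normalized = normalized,
                 dropped = colnames(df)[-1][constant]),
            class = "property_table")
}

#' @export
#' @method print property_table
print.property_table <- function(x, ...) {
  cat(sprintf("Property table: %d residues x %d properties\n",
              nrow(x$raw), ncol(x$raw)))
  invisible(x)
}

#' Expand an encoded matrix into a sequences x positions x properties tensor
#'
#' @param enc An \code{encoded_matrix} (codes 0..20).
#' @param table A \code{property_table}; default the bundled dictionary.
#' @return An object of class \code{"property_tensor"}: numeric array
#'   \code{values} (n x width x P) with pad cells exactly 0, plus references
#'   to the encoding and table.
#' @export
build_tensor <- function(enc, table = load_property_table()) {
  stopifnot(inherits(enc, "encoded_matrix"), inherits(table, "property_table"))
  if (any(enc$codes > 20L))
    stop("reserved residue code 21 has no property values")
  lut <- rbind(0, table$normalized)      # row 1 = pad
  vals <- lut[enc$codes + 1L, , drop = FALSE]
  dim(vals) <- c(nrow(enc$codes), ncol(enc$codes), ncol(table$normalized))
  dimnames(vals) <- list(enc$ids, NULL, table$property_names)
  structure(list(values = vals, source = enc, table = table),
            class = "property_tensor")
}

#' @export
#' @method print property_tensor
print.property_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Property tensor: %d sequences x %d positions x %d properties\n",
              d[1], d[2], d[3]))
  invisible(x)
}

check_property <- function(tensor, property_name) {
  p <- match(property_name, dimnames(tensor$values)[[3]])
  if (is.na(p)) stop("unknown property: ", property_name)
  p
}

#' Position-sensitive average of one biophysical property
#'
#' Averages a property over a group of sequences at every alignment column.
#' By default pad cells contribute 0 to the sum and are counted in the
#' denominator, so sparsely occupied stem columns are diluted toward 0;
#' \code{coverage_norm = TRUE} divides by the occupied count instead.
#'
#' @param tensor A \code{property_tensor}.
#' @param property_name Property to average.
#' @param group Optional row subset (indices or logical); default all.
#' @param coverage_norm Normalize by per-column occupancy instead of group
#'   size.
#' @param n_boot If > 0, additionally bootstrap the per-column mean this
#'   many times and report the bootstrap SD.
#' @param seed Seed for the bootstrap.
#' @return A data.frame with columns \code{column}, \code{mean} and (when
#'   bootstrapped) \code{boot_mean}, \code{boot_sd}.
#' @export
position_average <- function(tensor, property_name, group = NULL,
                             coverage_norm = FALSE, n_boot = 0, seed = NULL) {
  p <- check_property(tensor, property_name)
  M <- tensor$values[, , p, drop = FALSE]
  dim(M) <- dim(tensor$values)[1:2]
  if (!is.null(group)) M <- M[group, , drop = FALSE]
  if (nrow(M) == 0) stop("empty group")
  if (coverage_norm) {
    occ <- tensor$source$codes > 0L
    if (!is.null(group)) occ <- occ[group, , drop = FALSE]
    denom <- colSums(occ)
    mu <- ifelse(denom > 0, colSums(M) / denom, 0)
  } else {
    mu <- colMeans(M)
  }
  out <- data.frame(column = seq_along(mu), mean = mu)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    bm <- replicate(n_boot, colMeans(M[sample.int(nrow(M), replace = TRUE), ,
                                       drop = FALSE]))
    if (is.null(dim(bm))) bm <- matrix(bm, nrow = 1)
    out$boot_mean <- rowMeans(bm)
    out$boot_sd <- apply(bm, 1, stats::sd)
  }
  out
}

#' Net (per-sequence) average of one biophysical property
#'
#' Each sequence's net value is the property summed over its occupied
#' (non-pad) cells divided by its occupied cell count; the group value is
#' the mean of these per-sequence nets, with an optional bootstrap SD.
#'
#' @inheritParams position_average
#' @return A list: \code{per_sequence} nets, \code{mean}, and (when
#'   bootstrapped) \code{boot_mean}, \code{boot_sd}.
#' @export
net_average <- function(tensor, property_name, group = NULL,
                        n_boot = 0, seed = NULL) {
  p <- check_property(tensor, property_name)
  M <- tensor$values[, , p, drop = FALSE]
  dim(M) <- dim(tensor$values)[1:2]
  occ <- tensor$source$codes > 0L
  if (!is.null(group)) {
    M <- M[group, , drop = FALSE]
    occ <- occ[group, , drop = FALSE]
  }
  if (nrow(M) == 0) stop("empty group")
  nets <- rowSums(M) / pmax(rowSums(occ), 1L)
  out <- list(per_sequence = nets, mean = mean(nets))
  if (n_boot > 0) {
    br <- bootstrap_mean_sd(nets, n_boot = n_boot, seed = seed)
    out$boot_mean <- br$estimate
    out$boot_sd <- br$sd
  }
  out
}

#' Single-property mask of a tensor
#'
#' @param tensor A \code{property_tensor}.
#' @param property_name Property to slice out.
#' @return Numeric matrix (sequences x positions); pad cells are 0.
#' @export
property_mask <- function(tensor, property_name) {
  p <- check_property(tensor, property_name)
  M <- tensor$values[, , p, drop = FALSE]
  dim(M) <- dim(tensor$values)[1:2]
  rownames(M) <- dimnames(tensor$values)[[1]]
  M
}

#' Flatten, filter, and optionally entropy-reweight a property tensor
#'
#' The tensor is flattened to sequences x (positions * properties), columns
#' ordered position-major. All-zero (empty) columns are dropped; remaining
#' columns are scanned in index order and any column whose absolute Pearson
#' correlation with an earlier retained column exceeds
#' \code{corr_threshold} is dropped (first-kept rule, deterministic).
#' With \code{reweight = TRUE} each retained column is multiplied by the
#' positional Shannon entropy of its source alignment column divided by the
#' maximum entropy log2(20) = 4.3219 bits, down-weighting invariant
#' positions to zero.
#'
#' @param tensor A \code{property_tensor}.
#' @param corr_threshold Correlation filter threshold (default 0.75); with a
#'   threshold >= 1 only empty columns are dropped.
#' @param reweight Apply positional entropy re-weighting.
#' @return An object of class \code{"parsed_matrix"}: \code{data} (n x M),
#'   \code{column_index} (flat column, position, property, feature),
#'   \code{dropped} (flat column, reason), \code{reweighted}, and the
#'   per-retained-column \code{weights}.
#' @export
parse_matrix <- function(tensor, corr_threshold = 0.75, reweight = FALSE) {
  stopifnot(inherits(tensor, "property_tensor"))
  d <- dim(tensor$values)
  if (d[1] < 2) stop("parse_matrix needs at least 2 sequences")
  n <- d[1]; W <- d[2]; P <- d[3]
  flat <- aperm(tensor$values, c(1, 3, 2))
  dim(flat) <- c(n, P * W)
  # flat column (w-1)*P + p  <->  (position w, property p)
  pos_of <- rep(seq_len(W), each = P)
  prop_of <- rep(dimnames(tensor$values)[[3]], times = W)
  feat_of <- tensor$source$column_map$feature[pos_of]

  nonzero <- colSums(flat != 0) > 0
  dropped <- data.frame(column = which(!nonzero),
                        reason = rep("empty", sum(!nonzero)),
                        stringsAsFactors = FALSE)
  keep_idx <- which(nonzero)
  if (corr_threshold < 1 && length(keep_idx) > 1) {
    X <- flat[, keep_idx, drop = FALSE]
    C <- suppressWarnings(abs(stats::cor(X)))
    C[is.na(C)] <- 0                     # zero-variance columns: uncorrelated
    kept <- logical(length(keep_idx))
    kept[1] <- TRUE
    for (j in 2:length(keep_idx)) {
      if (!any(C[j, kept] > corr_threshold)) kept[j] <- TRUE
    }
    if (any(!kept)) {
      partner <- vapply(which(!kept), function(j)
        keep_idx[which(kept & C[j, seq_along(kept)] > corr_threshold)][1],
        integer(1))
      dropped <- rbind(dropped,
                       data.frame(column = keep_idx[!kept],
                                  reason = paste0("correlated-with:", partner),
                                  stringsAsFactors = FALSE))
    }
    keep_idx <- keep_idx[kept]
  }
  if (length(keep_idx) < 2) stop("fewer than 2 columns survive parsing")
  data <- flat[, keep_idx, drop = FALSE]
  weights <- rep(1, length(keep_idx))
  if (reweight) {
    H <- shannon_entropy(position_frequencies(tensor$source))$H
    weights <- H[pos_of[keep_idx]] / log2(20)
    data <- sweep(data, 2, weights, "*")
  }
  rownames(data) <- dimnames(tensor$values)[[1]]
  structure(list(data = data,
                 column_index = data.frame(column = keep_idx,
                                           position = pos_of[keep_idx],
                                           property = prop_of[keep_idx],
                                           feature = feat_of[keep_idx],
                                           stringsAsFactors = FALSE),
                 dropped = dropped[order(dropped$column), ],
                 reweighted = reweight, weights = weights,
                 corr_threshold = corr_threshold),
            class = "parsed_matrix")
}

#' @export
#' @method print parsed_matrix
print.parsed_matrix <- function(x, ...) {
  cat(sprintf(
    "Parsed feature matrix: %d sequences x %d retained columns (%d dropped%s)\n",
    nrow(x$data), ncol(x$data), nrow(x$dropped),
    if (x$reweighted) ", entropy-reweighted" else ""))
  invisible(x)
}

#' Load a 20 x 20 pairwise residue interaction table
#'
#' @param path CSV path (leading \code{residue} column, residues in
#'   alphabetical order); \code{NULL} loads the bundled synthetic chart of
#'   textbook-level interaction propensities (salt bridges, hydrophobic
#'   packing, aromatic stacking, hydrogen bonds).
#' @return A symmetric numeric 20 x 20 matrix.
#' @export
load_pair_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_pair_interactions_synthetic.csv",
                        package = "repbiophys")
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1])
  rownames(M) <- df$residue
  if (!all(dim(M) == c(20, 20))) stop("pair table must be 20 x 20")
  M[AA_ALPHABET, AA_ALPHABET]
}

#' Position-pair interaction scores between two encoded repertoires
#'
#' For each column pair (one column from each encoding) the mean pairwise
#' interaction score over paired rows is computed; any pair with a pad
#' member contributes 0.
#'
#' @param encA,encB \code{encoded_matrix} objects with equal row counts
#'   (rows are paired, e.g. receptor vs ligand of the same complex).
#' @param pair_table 20 x 20 score matrix from \code{\link{load_pair_table}}.
#' @return Numeric matrix (width A x width B) of mean scores.
#' @export
interaction_score <- function(encA, encB, pair_table = load_pair_table()) {
  if (nrow(encA$codes) != nrow(encB$codes))
    stop("interaction_score requires paired datasets with equal row counts")
  lut <- rbind(0, cbind(0, pair_table))   # index 1 = pad
  n <- nrow(encA$codes)
  out <- matrix(0, ncol(encA$codes), ncol(encB$codes))
  for (j in seq_len(ncol(encB$codes))) {
    bj <- encB$codes[, j] + 1L
    S <- matrix(lut[cbind(as.vector(encA$codes + 1L),
                          rep(bj, times = ncol(encA$codes)))],
                n, ncol(encA$codes))
    out[, j] <- colMeans(S)
  }
  out
}
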