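# Repertoire container and I/O ------------------------------------------------

#' The 20 standard amino acids in alphabetical one-letter order
#'
#' Residue codes used throughout the package: code 1 = A ... code 20 = Y,
#' code 0 = pad (empty matrix cell), code 21 = reserved non-standard
#' placeholder (never produced from validated input).
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a repertoire of immune-molecule sequences
#'
#' A repertoire is an ordered set of molecules, each described by one or
#' more structural-feature amino-acid strings (e.g. the six CDR loops of a
#' TCR, or a single peptide) plus free-form per-sequence metadata.
#'
#' @param features Character matrix (sequences x features) or data.frame of
#'   amino-acid strings. Column names become the feature names.
#' @param metadata Optional data.frame of per-sequence metadata (character).
#' @param ids Optional character vector of sequence identifiers; defaults to
#'   \code{"seq_<row-index>"} (0-based).
#' @param feature_names Optional explicit feature names.
#' @param provenance Free-text source descriptor.
#' @param aligned Logical; \code{TRUE} for pre-aligned (MSA-derived)
#'   repertoires in which the gap character \code{"-"} is a legal placeholder
#'   encoded as pad.
#' @return An object of class \code{"repertoire"}.
#' @export
repertoire <- function(features, metadata = NULL, ids = NULL,
                       feature_names = NULL, provenance = "",
                       aligned = FALSE) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, ncol = 1)
  storage.mode(features) <- "character"
  n <- nrow(features)
  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names)) feature_names <- paste0("feature", seq_len(ncol(features)))
  colnames(features) <- feature_names
  if (is.null(ids)) ids <- paste0("seq_", seq_len(n) - 1L)
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal the number of sequences")
  if (is.null(metadata)) metadata <- data.frame(row.names = seq_len(n))
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (nrow(metadata) != n) stop("metadata must have one row per sequence")
  rownames(features) <- NULL
  rownames(metadata) <- NULL
  structure(list(feature_names = feature_names, ids = ids,
                 features = features, metadata = metadata,
                 provenance = provenance, aligned = aligned),
            class = "repertoire")
}

#' @export
#' @method print repertoire
print.repertoire <- function(x, ...) {
  cat(sprintf("Repertoire: %d sequences, %d feature(s) [%s]\n",
              nrow(x$features), length(x$feature_names),
              paste(x$feature_names, collapse = ", ")))
  if (ncol(x$metadata) > 0)
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  if (nzchar(x$provenance)) cat("  source:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.repertoire <- function(x) nrow(x$features)

#' Row-subset a repertoire (order preserving)
#'
#' @param x A repertoire.
#' @param i Row index vector (integer or logical).
#' @param ... Unused.
#' @export
`[.repertoire` <- function(x, i, ...) {
  repertoire(x$features[i, , drop = FALSE],
             metadata = x$metadata[i, , drop = FALSE],
             ids = x$ids[i], feature_names = x$feature_names,
             provenance = x$provenance, aligned = x$aligned)
}

#' Read a repertoire from a CSV file
#'
#' The expected dialect is a plain UTF-8 comma-separated file with a header
#' row. Feature columns (one amino-acid string per structural feature) are
#' named explicitly; all remaining columns are treated as metadata unless
#' \code{metadata_columns} restricts them. An \code{id} column, when present
#' and not itself a feature column, supplies sequence identifiers.
#'
#' @param path Path to the CSV file.
#' @param feature_columns Character vector of feature column names.
#' @param metadata_columns Optional character vector restricting which
#'   non-feature columns are kept as metadata (default: all of them).
#' @return A \code{repertoire} with one record per row, in file order.
#'   No validation is applied; see \code{\link{validate_repertoire}}.
#' @export
read_repertoire_csv <- function(path, feature_columns,
                                metadata_columns = NULL) {
  if (!file.exists(path)) stop("cannot read repertoire file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(feature_columns, names(df))
  if (length(missing_cols) > 0)
    stop("feature column(s) not present in header: ",
         paste(missing_cols, collapse = ", "))
  ids <- NULL
  if ("id" %in% names(df) && !("id" %in% feature_columns)) ids <- df[["id"]]
  if (is.null(metadata_columns)) {
    metadata_columns <- setdiff(names(df), c(feature_columns, "id"))
  } else {
    missing_md <- setdiff(metadata_columns, names(df))
    if (length(missing_md) > 0)
      stop("metadata column(s) not present in header: ",
           paste(missing_md, collapse = ", "))
  }
  repertoire(as.matrix(df[, feature_columns, drop = FALSE]),
             metadata = df[, metadata_columns, drop = FALSE],
             ids = ids, feature_names = feature_columns,
             provenance = path)
}

#' Write a repertoire to CSV
#'
#' Inverse of \code{\link{read_repertoire_csv}}: writes an \code{id} column,
#' the feature columns, and the metadata columns.
#'
#' @param rep A repertoire.
#' @param path Output path.
#' @export
write_repertoire_csv <- function(rep, path) {
  df <- data.frame(id = rep$ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (f in rep$feature_names) df[[f]] <- rep$features[, f]
  for (m in names(rep$metadata)) df[[m]] <- rep$metadata[[m]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a repertoire and filter out malformed records
#'
#' Feature strings are uppercased, then every record is checked: each
#' feature must be non-empty and composed solely of the 20 standard
#' one-letter residue codes. Ambiguity codes (\code{X}, \code{B}, \code{Z}),
#' stops (\code{*}) and gaps (\code{-}) count as improper characters, except
#' that \code{-} is permitted in pre-aligned repertoires (where it encodes
#' to pad). Rejections are reported, never raised.
#'
#' @param rep A repertoire.
#' @return A list with elements \code{repertoire} (surviving records, in
#'   original order) and \code{rejections} (data.frame of id, feature,
#'   reason).
#' @export
validate_repertoire <- function(rep) {
  feats <- toupper(rep$features)
  allowed <- AA_ALPHABET
  if (isTRUE(rep$aligned)) allowed <- c(allowed, "-")
  ok <- rep(TRUE, nrow(feats))
  rej_id <- character(0); rej_feat <- character(0); rej_reason <- character(0)
  for (i in seq_len(nrow(feats))) {
    for (f in rep$feature_names) {
      s <- feats[i, f]
      if (is.na(s) || !nzchar(s)) {
        ok[i] <- FALSE
        rej_id <- c(rej_id, rep$ids[i]); rej_feat <- c(rej_feat, f)
        rej_reason <- c(rej_reason, "missing feature")
      } else if (!all(strsplit(s, "")[[1]] %in% allowed)) {
        ok[i] <- FALSE
        rej_id <- c(rej_id, rep$ids[i]); rej_feat <- c(rej_feat, f)
        rej_reason <- c(rej_reason, "improper character")
      }
    }
  }
  out <- rep
  out$features <- feats
  out <- out[ok]
  list(repertoire = out,
       rejections = data.frame(id = rej_id, feature = rej_feat,
                               reason = rej_reason,
                               stringsAsFactors = FALSE))
}

#' Read a FASTA file as a single-feature repertoire
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param feature_name Name given to the single feature column.
#' @return A \code{repertoire} with feature arity 1; FASTA headers become ids.
#' @export
read_fasta <- function(path, feature_name = "seq") {
  recs <- parse_fasta(path)
  repertoire(matrix(recs$seq, ncol = 1,
                    dimnames = list(NULL, feature_name)),
             ids = recs$id, provenance = path)
}

# FASTA reading goes through seqinr; returned as plain character vectors
parse_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  list(id = names(recs), seq = toupper(unlist(recs, use.names = FALSE)))
}

#' Read a pre-aligned multi-sequence alignment as a repertoire
#'
#' Each region of alignment columns becomes one structural feature. In
#' \code{"as-aligned"} mode (the default) gap characters are retained and
#' encode to pad, so the alignment's column structure is preserved; in
#' \code{"strip"} mode gaps are removed per record for downstream
#' re-alignment by the encoder.
#'
#' @param path Path to an aligned FASTA file (all rows the same width).
#' @param region_spec List of two-element integer vectors
#'   \code{c(start, end)} (1-based, inclusive) of alignment columns; each
#'   becomes one feature. Default: one region spanning the full width.
#' @param mode \code{"as-aligned"} or \code{"strip"}.
#' @param feature_names Optional names for the regions.
#' @return A \code{repertoire}; \code{aligned = TRUE} in as-aligned mode.
#' @export
read_msa <- function(path, region_spec = NULL,
                     mode = c("as-aligned", "strip"),
                     feature_names = NULL) {
  mode <- match.arg(mode)
  recs <- parse_fasta(path)
  widths <- nchar(recs$seq)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: rows differ in width")
  W <- widths[1]
  if (is.null(region_spec)) region_spec <- list(c(1L, W))
  for (rg in region_spec) {
    if (length(rg) != 2 || rg[1] < 1 || rg[2] > W || rg[1] > rg[2])
      stop("region spec exceeds alignment width (", W, " columns)")
  }
  if (is.null(feature_names))
    feature_names <- vapply(region_spec, function(rg)
      paste0("region_", rg[1], "_", rg[2]), "")
  feats <- vapply(region_spec, function(rg)
    substr(recs$seq, rg[1], rg[2]), character(length(recs$seq)))
  if (!is.matrix(feats)) feats <- matrix(feats, nrow = length(recs$seq))
  colnames(feats) <- feature_names
  if (mode == "strip") feats[] <- gsub("-", "", feats)
  repertoire(feats, ids = recs$id, provenance = path,
             aligned = (mode == "as-aligned"))
}

#' Subset a repertoire by metadata or feature content
#'
#' @param rep A repertoire.
#' @param key A metadata column name or a feature name.
#' @param predicate Either a value (records kept where the key equals it) or
#'   a function of the per-record character vector returning a logical
#'   vector. Missing values never match.
#' @return An order-preserving subset repertoire.
#' @export
subset_by_metadata <- function(rep, key, predicate) {
  if (key %in% names(rep$metadata)) {
    vals <- rep$metadata[[key]]
  } else if (key %in% rep$feature_names) {
    vals <- rep$features[, key]
  } else {
    stop("key not found in metadata or features: ", key)
  }
  keep <- if (is.function(predicate)) predicate(vals) else vals %in% predicate
  keep[is.na(keep)] <- FALSE
  rep[keep]
}
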