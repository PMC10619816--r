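# Synthetic CDR3 benchmark generator ------------------------------------------
#
# Single-chain CDR3 sequences are built V(D)J-style: a V-segment prefix
# (after 0-2 terminal deletions), a run of inserted residues drawn i.i.d.
# from a biased insertion distribution, and a J-segment suffix (after 0-2
# leading deletions). Segment identities and selection weights are
# deliberately pseudo-random, not biological frequencies; the point is a
# labeled benchmark with known, tunable biophysical signal.

# bundled pseudo segment pool: V prefixes begin with the canonical C,
# J suffixes end with the canonical F
DEFAULT_V_SEGMENTS <- c("CASS", "CAVRG", "CASSL", "CSARD", "CAWSVG",
                        "CASR", "CAISE", "CAVG")
DEFAULT_J_SEGMENTS <- c("EQYF", "YTEAF", "NYGYTF", "EKLFF", "TEAFF",
                        "QGQHF")

#' Build a V/J segment pool with seeded pseudo-random selection weights
#'
#' @param v_segments Character vector of V-gene amino-acid prefixes.
#' @param j_segments Character vector of J-gene amino-acid suffixes.
#' @param seed Seed for the weight draw (weights are drawn once, uniformly,
#'   then normalized to sum to 1 per pool).
#' @return Object of class \code{"segment_pool"}.
#' @export
segment_pool <- function(v_segments = DEFAULT_V_SEGMENTS,
                         j_segments = DEFAULT_J_SEGMENTS,
                         seed = 1L) {
  if (length(v_segments) == 0 || length(j_segments) == 0)
    stop("segment pools must be non-empty")
  set.seed(seed)
  vw <- stats::runif(length(v_segments), 0.5, 1.5)
  jw <- stats::runif(length(j_segments), 0.5, 1.5)
  structure(list(v_segments = v_segments, j_segments = j_segments,
                 v_weights = vw / sum(vw), j_weights = jw / sum(jw),
                 seed = seed),
            class = "segment_pool")
}

#' Insertion distributions of the three benchmark presets
#'
#' Cysteine and proline are excluded from all presets. \code{"Random"}
#' inserts each of the remaining 18 residues with probability 1/18;
#' \code{"KRQN"} up-weights the positively charged K and R 20-fold and the
#' hydrophilic Q and N 10-fold; \code{"DEHY"} up-weights the negatively
#' charged D and E 20-fold and the amphipathic H and Y 10-fold (weights
#' normalized over the 18 allowed residues).
#'
#' @param preset \code{"Random"}, \code{"KRQN"}, or \code{"DEHY"}.
#' @return Named probability vector over the 20 residues (C and P at 0).
#' @export
insertion_distribution <- function(preset = c("Random", "KRQN", "DEHY")) {
  preset <- match.arg(preset)
  w <- stats::setNames(rep(1, 20), AA_ALPHABET)
  w[c("C", "P")] <- 0
  if (preset == "KRQN") {
    w[c("K", "R")] <- 20
    w[c("Q", "N")] <- 10
  } else if (preset == "DEHY") {
    w[c("D", "E")] <- 20
    w[c("H", "Y")] <- 10
  }
  w / sum(w)
}

#' Generative specification for one synthetic CDR3 subset
#'
#' @param pool A \code{\link{segment_pool}}.
#' @param insertion_weights Named per-residue probability vector (e.g. from
#'   \code{\link{insertion_distribution}}); excluded residues at weight 0.
#' @param label Subset name stored as metadata on generated sequences.
#' @param deletion_range Integer vector of allowed per-segment junctional
#'   deletions (default 0:2, uniform).
#' @param target_lengths Total sequence lengths aimed for (default 11:14);
#'   the insertion count is chosen per sequence to hit a uniformly drawn
#'   target, floored at 0 when the trimmed segments already exceed it.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(pool, insertion_weights, label,
                       deletion_range = 0:2, target_lengths = 11:14) {
  if (any(insertion_weights < 0)) stop("insertion weights must be >= 0")
  if (abs(sum(insertion_weights) - 1) > 1e-9)
    stop("insertion weights must sum to 1")
  structure(list(pool = pool, insertion_weights = insertion_weights,
                 label = label, deletion_range = as.integer(deletion_range),
                 target_lengths = as.integer(target_lengths)),
            class = "sim_config")
}

#' Generate a synthetic CDR3 repertoire
#'
#' Each sequence is (V prefix after uniform junctional deletion) +
#' (inserted residues i.i.d. from the insertion distribution) + (J suffix
#' after uniform leading deletion). Reproducible under a fixed seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n Number of sequences (>= 1).
#' @param seed RNG seed.
#' @return A \code{repertoire} with single feature \code{"cdr3"} and
#'   metadata column \code{subset} = the config label.
#' @export
generate_dataset <- function(config, n, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  set.seed(seed)
  pool <- config$pool
  pick <- function(v, size, prob = NULL)   # length-1 vectors stay literal
    v[sample.int(length(v), size, replace = TRUE, prob = prob)]
  vi <- sample.int(length(pool$v_segments), n, replace = TRUE,
                   prob = pool$v_weights)
  ji <- sample.int(length(pool$j_segments), n, replace = TRUE,
                   prob = pool$j_weights)
  dv <- pick(config$deletion_range, n)
  dj <- pick(config$deletion_range, n)
  tgt <- pick(config$target_lengths, n)
  v <- pool$v_segments[vi]
  j <- pool$j_segments[ji]
  v <- substr(v, 1L, nchar(v) - dv)          # deletions at the V junction
  j <- substr(j, dj + 1L, nchar(j))          # deletions at the J junction
  n_ins <- pmax(0L, tgt - nchar(v) - nchar(j))
  allowed <- names(config$insertion_weights)[config$insertion_weights > 0]
  prob <- config$insertion_weights[config$insertion_weights > 0]
  total_ins <- sum(n_ins)
  ins_chars <- if (total_ins > 0)
    sample(allowed, total_ins, replace = TRUE, prob = prob) else character(0)
  stops <- cumsum(n_ins)
  starts <- stops - n_ins + 1L
  mids <- vapply(seq_len(n), function(i) {
    if (n_ins[i] == 0L) "" else
      paste(ins_chars[starts[i]:stops[i]], collapse = "")
  }, "")
  seqs <- paste0(v, mids, j)
  repertoire(matrix(seqs, ncol = 1, dimnames = list(NULL, "cdr3")),
             metadata = data.frame(subset = rep(config$label, n),
                                   stringsAsFactors = FALSE),
             provenance = sprintf("simulated:%s", config$label))
}

#' The three-subset simulated benchmark
#'
#' Generates the Random, KRQN, and DEHY subsets (5,000 sequences each by
#' default, 15,000 total) from one shared segment pool, with total lengths
#' in 11-14 residues and the generating subset stored in the \code{subset}
#' metadata column.
#'
#' @param n_per_subset Sequences per subset (default 5000).
#' @param seed Base RNG seed (pool weights and the three subset draws are
#'   derived from it).
#' @return A labeled \code{repertoire} of the three concatenated subsets.
#' @export
preset_benchmark <- function(n_per_subset = 5000, seed = 1L) {
  pool <- segment_pool(seed = seed)
  subsets <- c("Random", "KRQN", "DEHY")
  reps <- lapply(seq_along(subsets), function(k) {
    cfg <- sim_config(pool, insertion_distribution(subsets[k]), subsets[k])
    generate_dataset(cfg, n_per_subset, seed = seed + k)
  })
  feats <- do.call(rbind, lapply(reps, function(r) r$features))
  md <- do.call(rbind, lapply(reps, function(r) r$metadata))
  repertoire(feats, metadata = md,
             provenance = sprintf("simulated benchmark (3 x %d, seed %d)",
                                  n_per_subset, seed))
}

#' Run the standard pipeline and score clustering against known labels
#'
#' The standard pipeline: central encoding, property-dictionary Z-score
#' normalization, entropy re-weighting of the parsed matrix, 3-component
#' UMAP projection, DBSCAN clustering; purity is scored against a metadata
#' label with noise excluded, and the fraction of sequences assigned to any
#' cluster is reported alongside.
#'
#' @param rep A labeled \code{repertoire} (e.g. from
#'   \code{\link{preset_benchmark}}).
#' @param label_key Metadata column with the reference label (default
#'   \code{"subset"}).
#' @param proj_seed Projection seed (default 617).
#' @param eps,min_pts DBSCAN parameters (defaults 0.15 and 5).
#' @param n_neighbors UMAP neighborhood size (default 25).
#' @param table Property dictionary (default bundled).
#' @return A list: \code{purity} (\code{purity_report}),
#'   \code{fraction_clustered}, \code{assignment}, \code{projection},
#'   \code{parsed}, \code{encoded}.
#' @export
evaluate_benchmark <- function(rep, label_key = "subset", proj_seed = 617,
                               eps = 0.15, min_pts = 5, n_neighbors = 25,
                               table = load_property_table()) {
  val <- validate_repertoire(rep)
  enc <- encode_repertoire(val$repertoire, alignment_spec("central"))
  tens <- build_tensor(enc, table)
  parsed <- parse_matrix(tens, corr_threshold = 0.75, reweight = TRUE)
  proj <- project(parsed, "umap", n_components = 3, seed = proj_seed,
                  params = list(n_neighbors = n_neighbors))
  assign <- cluster_points(proj, "dbscan", eps = eps, min_pts = min_pts)
  pur <- purity(assign, val$repertoire, label_key)
  list(purity = pur, fraction_clustered = pur$fraction_clustered,
       assignment = assign, projection = proj, parsed = parsed,
       encoded = enc)
}
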