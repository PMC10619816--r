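# Projection, density clustering, purity, motifs ------------------------------

#' Project a parsed feature matrix to low dimension
#'
#' @param parsed A \code{parsed_matrix} (or plain numeric matrix).
#' @param method \code{"umap"} (via uwot), \code{"pca"} (full-rank SVD via
#'   \code{prcomp}), or \code{"tsne"} (via Rtsne).
#' @param n_components Target dimension (default 3).
#' @param seed RNG seed; fixed seed + input gives identical coordinates
#'   (UMAP/t-SNE run single-threaded for that reason). Default 617.
#' @param params Named list of method parameters. UMAP default
#'   \code{n_neighbors = 25}; remaining parameters are library defaults.
#' @return Object of class \code{"projection"}: \code{coords}
#'   (n x n_components), \code{method}, \code{params}, \code{seed}.
#' @export
project <- function(parsed, method = c("umap", "pca", "tsne"),
                    n_components = 3, seed = 617, params = list()) {
  method <- match.arg(method)
  X <- if (inherits(parsed, "parsed_matrix")) parsed$data else as.matrix(parsed)
  if (nrow(X) < 2) stop("projection needs at least 2 rows")
  if (n_components > ncol(X))
    stop("n_components exceeds the number of retained columns")
  set.seed(seed)
  coords <- switch(
    method,
    pca = {
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      pc$x[, seq_len(n_components), drop = FALSE]
    },
    umap = {
      args <- c(list(X = X, n_components = n_components,
                     n_threads = 1, n_sgd_threads = 0),
                modifyList(list(n_neighbors = 25), params))
      args$n_neighbors <- min(args$n_neighbors, nrow(X) - 1)
      do.call(uwot::umap, args)
    },
    tsne = {
      args <- modifyList(
        list(X = X, dims = n_components, check_duplicates = FALSE,
             perplexity = min(30, floor((nrow(X) - 1) / 3))),
        params)
      Rtsne::Rtsne(args$X, dims = args$dims,
                   perplexity = args$perplexity,
                   check_duplicates = args$check_duplicates)$Y
    })
  coords <- unname(as.matrix(coords))
  rownames(coords) <- rownames(X)
  structure(list(coords = coords, method = method, params = params,
                 seed = seed),
            class = "projection")
}

#' @export
#' @method print projection
print.projection <- function(x, ...) {
  cat(sprintf("Projection: %d points in %d dimensions (%s, seed %d)\n",
              nrow(x$coords), ncol(x$coords), x$method, x$seed))
  invisible(x)
}

#' Cluster projected coordinates
#'
#' @param proj A \code{projection} (or numeric coordinate matrix).
#' @param algorithm \code{"dbscan"} (default \code{eps = 0.15},
#'   \code{min_pts = 5}), \code{"optics"} (default \code{min_pts = 10},
#'   extraction at \code{eps_cl}), \code{"kmeans"} (requires \code{k}), or
#'   \code{"hierarchical"} (requires \code{k} or \code{h}).
#' @param ... Algorithm parameters (\code{eps}, \code{min_pts}, \code{k},
#'   \code{h}, \code{linkage}, \code{eps_cl}, \code{seed}).
#' @return Object of class \code{"cluster_assignment"}: integer
#'   \code{labels} per point with -1 = noise and non-noise labels relabeled
#'   to a contiguous 0..k-1 set (order of first appearance), plus
#'   \code{algorithm} and \code{params}.
#' @export
cluster_points <- function(proj, algorithm = c("dbscan", "optics", "kmeans",
                                               "hierarchical"), ...) {
  algorithm <- match.arg(algorithm)
  X <- if (inherits(proj, "projection")) proj$coords else as.matrix(proj)
  if (any(!is.finite(X))) stop("coordinates must be finite")
  prm <- list(...)
  labels <- switch(
    algorithm,
    dbscan = {
      eps <- prm$eps %||% 0.15
      min_pts <- prm$min_pts %||% 5
      dbscan_impl(X, eps, min_pts)
    },
    optics = {
      min_pts <- prm$min_pts %||% 10
      eps_cl <- prm$eps_cl %||% 0.15
      ord <- optics_impl(X, min_pts, max_eps = prm$max_eps %||% Inf)
      optics_extract(ord, eps_cl)
    },
    kmeans = {
      if (is.null(prm$k)) stop("kmeans requires a cluster count 'k'")
      if (prm$k >= nrow(X)) seq_len(nrow(X)) - 1L  # one point per cluster
      else {
        set.seed(prm$seed %||% 617)
        stats::kmeans(X, centers = prm$k, nstart = prm$nstart %||% 10,
                      iter.max = 100)$cluster - 1L
      }
    },
    hierarchical = {
      hc <- stats::hclust(stats::dist(X),
                          method = prm$linkage %||% "average")
      if (!is.null(prm$k)) stats::cutree(hc, k = prm$k) - 1L
      else if (!is.null(prm$h)) stats::cutree(hc, h = prm$h) - 1L
      else stop("hierarchical clustering requires 'k' or 'h'")
    })
  structure(list(labels = relabel_contiguous(labels),
                 algorithm = algorithm, params = prm),
            class = "cluster_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# renumber non-noise labels to 0..k-1 in order of first appearance
relabel_contiguous <- function(labels) {
  labels <- as.integer(labels)
  pos <- labels >= 0L
  if (any(pos)) {
    u <- unique(labels[pos])
    labels[pos] <- match(labels[pos], u) - 1L
  }
  labels
}

#' @export
#' @method print cluster_assignment
print.cluster_assignment <- function(x, ...) {
  k <- length(unique(x$labels[x$labels >= 0]))
  cat(sprintf("Cluster assignment (%s): %d clusters, %d/%d points noise\n",
              x$algorithm, k, sum(x$labels < 0), length(x$labels)))
  invisible(x)
}

# -- density clustering internals ---------------------------------------------

# fixed-radius neighbor lists via grid binning (cells of side eps; only the
# 3^d adjacent cells can contain neighbors). Returns a list of integer
# vectors including the point itself.
radius_neighbors <- function(X, eps) {
  n <- nrow(X); d <- ncol(X)
  g <- floor(sweep(X, 2, apply(X, 2, min)) / eps)
  storage.mode(g) <- "integer"
  key <- do.call(paste, c(as.data.frame(g), list(sep = ",")))
  cell_id <- match(key, unique(key))
  members <- split(seq_len(n), cell_id)
  cell_coord <- g[!duplicated(key), , drop = FALSE]
  lookup <- new.env(parent = emptyenv(), size = length(members))
  ukeys <- unique(key)
  for (c_i in seq_along(ukeys)) assign(ukeys[c_i], c_i, envir = lookup)
  offsets <- as.matrix(expand.grid(rep(list(-1L:1L), d)))
  nb <- vector("list", n)
  eps2 <- eps^2
  for (c_i in seq_along(members)) {
    cand_cells <- integer(0)
    for (o in seq_len(nrow(offsets))) {
      k2 <- paste(cell_coord[c_i, ] + offsets[o, ], collapse = ",")
      hit <- lookup[[k2]]
      if (!is.null(hit)) cand_cells <- c(cand_cells, hit)
    }
    cand <- unlist(members[cand_cells], use.names = FALSE)
    Xc <- X[cand, , drop = FALSE]
    pts <- members[[c_i]]
    for (start in seq(1, length(pts), by = 256)) {
      chunk <- pts[start:min(start + 255, length(pts))]
      D2 <- outer(rowSums(X[chunk, , drop = FALSE]^2), rowSums(Xc^2), "+") -
        2 * X[chunk, , drop = FALSE] %*% t(Xc)
      for (r in seq_along(chunk))
        nb[[chunk[r]]] <- cand[D2[r, ] <= eps2 + 1e-12]
    }
  }
  nb
}

# classic DBSCAN: core points have >= min_pts neighbors (self included);
# clusters are density-connected components, border points join the first
# cluster that reaches them, the rest is noise (-1)
dbscan_impl <- function(X, eps, min_pts) {
  n <- nrow(X)
  nb <- radius_neighbors(X, eps)
  core <- lengths(nb) >= min_pts
  labels <- rep(-2L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier) > 0) {
      nbrs <- unique(unlist(nb[frontier], use.names = FALSE))
      newpts <- nbrs[labels[nbrs] == -2L]
      labels[newpts] <- cl
      frontier <- newpts[core[newpts]]
    }
  }
  labels[labels == -2L] <- -1L
  labels
}

# OPTICS ordering (Ankerst et al. style): processes points in order of
# smallest current reachability; O(n^2) distance work, adequate for the
# projected 2-3 dimensional spaces this package clusters
optics_impl <- function(X, min_pts, max_eps = Inf) {
  n <- nrow(X)
  reach <- rep(Inf, n)
  core_dist <- rep(Inf, n)
  processed <- rep(FALSE, n)
  order_out <- integer(n)
  seeds_reach <- rep(Inf, n)
  for (step in seq_len(n)) {
    cand <- which(!processed)
    i <- cand[which.min(seeds_reach[cand])]
    if (is.infinite(seeds_reach[i])) i <- cand[1]
    processed[i] <- TRUE
    order_out[step] <- i
    reach[i] <- seeds_reach[i]
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    within <- d <= max_eps
    if (sum(within) >= min_pts) {
      cd <- sort(d[within], partial = min_pts)[min_pts]
      core_dist[i] <- cd
      newreach <- pmax(cd, d)
      upd <- !processed & within & newreach < seeds_reach
      seeds_reach[upd] <- newreach[upd]
    }
  }
  list(order = order_out, reachability = reach[order_out],
       core_dist = core_dist[order_out], min_pts = min_pts)
}

# DBSCAN-equivalent cluster extraction from an OPTICS ordering at eps_cl
optics_extract <- function(ord, eps_cl) {
  n <- length(ord$order)
  labels <- rep(-1L, n)
  cl <- -1L
  for (k in seq_len(n)) {
    i <- ord$order[k]
    if (ord$reachability[k] > eps_cl) {
      if (ord$core_dist[k] <= eps_cl) {
        cl <- cl + 1L
        labels[i] <- cl
      }
    } else {
      labels[i] <- max(cl, 0L)
    }
  }
  labels
}

# -- purity -------------------------------------------------------------------

#' Cluster purity against a metadata label
#'
#' Per-cluster purity is the fraction of members sharing the cluster's most
#' common label; the summary is the unweighted mean and SD over clusters.
#' Noise points (label -1) are excluded unless \code{include_noise}.
#'
#' @param assign A \code{cluster_assignment}.
#' @param rep A \code{repertoire}, or directly a character vector of labels.
#' @param metadata_key Metadata column holding the reference label (ignored
#'   when \code{rep} is already a label vector).
#' @param include_noise Treat noise points as one extra cluster.
#' @return Object of class \code{"purity_report"}: \code{per_cluster}
#'   data.frame (cluster, size, majority, purity), \code{mean_purity},
#'   \code{sd_purity}, \code{metadata_key}, \code{fraction_clustered}.
#' @export
purity <- function(assign, rep, metadata_key = NULL, include_noise = FALSE) {
  labels <- if (inherits(rep, "repertoire")) {
    if (is.null(metadata_key) || !metadata_key %in% names(rep$metadata))
      stop("metadata_key not found: ", metadata_key)
    rep$metadata[[metadata_key]]
  } else as.character(rep)
  cl <- assign$labels
  if (length(cl) != length(labels))
    stop("assignment and labels differ in length")
  keep <- if (include_noise) rep(TRUE, length(cl)) else cl >= 0L
  frac_clustered <- mean(cl >= 0L)
  ids <- sort(unique(cl[keep]))
  if (length(ids) == 0) {
    return(structure(list(per_cluster = data.frame(cluster = integer(0),
                                                   size = integer(0),
                                                   majority = character(0),
                                                   purity = numeric(0)),
                          mean_purity = NA_real_, sd_purity = NA_real_,
                          metadata_key = metadata_key,
                          fraction_clustered = frac_clustered),
                     class = "purity_report"))
  }
  per <- lapply(ids, function(k) {
    tab <- table(labels[cl == k])
    data.frame(cluster = k, size = sum(tab),
               majority = names(tab)[which.max(tab)],
               purity = max(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_cluster = per,
                 mean_purity = mean(per$purity),
                 sd_purity = if (nrow(per) > 1) stats::sd(per$purity) else 0,
                 metadata_key = metadata_key,
                 fraction_clustered = frac_clustered),
            class = "purity_report")
}

#' @export
#' @method print purity_report
print.purity_report <- function(x, ...) {
  cat(sprintf("Cluster purity vs '%s': %.3f +/- %.3f over %d clusters (%.0f%% clustered)\n",
              x$metadata_key %||% "labels", x$mean_purity, x$sd_purity,
              nrow(x$per_cluster), 100 * x$fraction_clustered))
  invisible(x)
}

#' Regroup encoded rows by cluster
#'
#' @param enc An \code{encoded_matrix}.
#' @param assign Matching \code{cluster_assignment}.
#' @param cluster_ids Clusters to keep, in display order.
#' @return A list: \code{enc} (rows reordered cluster by cluster, original
#'   order within each), \code{boundaries} (row indices after which a new
#'   cluster starts), \code{clusters}.
#' @export
isolate_clusters <- function(enc, assign, cluster_ids) {
  unknown <- setdiff(cluster_ids, assign$labels)
  if (length(unknown) > 0)
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
  rows <- unlist(lapply(cluster_ids, function(k) which(assign$labels == k)))
  sizes <- vapply(cluster_ids, function(k) sum(assign$labels == k), integer(1))
  out <- enc
  out$codes <- enc$codes[rows, , drop = FALSE]
  out$ids <- enc$ids[rows]
  list(enc = out, boundaries = cumsum(sizes)[-length(sizes)],
       clusters = cluster_ids, rows = rows)
}

# property classes for motif wildcards; the small set is tested before the
# broader polar/nonpolar sets that contain its members
MOTIF_CLASSES <- list(
  positive = c("K", "R", "H"),
  negative = c("D", "E"),
  small = c("S", "T", "G", "A"),
  hydrophilic = c("S", "T", "N", "Q", "C", "Y", "W"),
  nonpolar = c("A", "V", "L", "I", "M", "F", "G", "P")
)

#' Property-class motif of a sequence cluster
#'
#' Summarizes the rows of an encoded matrix column by column: a residue
#' letter where one residue dominates, a class wildcard \code{X(class)}
#' where one biophysical class dominates (positive, negative, small,
#' hydrophilic, nonpolar; small is evaluated before the broader sets), and
#' \code{.} otherwise. Frequencies are conditional on occupancy; all-pad
#' columns emit \code{.}.
#'
#' @param enc An \code{encoded_matrix} (typically one isolated cluster).
#' @param rows Optional row subset.
#' @param letter_threshold Minimum single-residue frequency for a letter
#'   (default 0.7).
#' @param class_threshold Minimum class frequency for a wildcard (default
#'   0.7).
#' @return Character vector of per-column tokens with class
#'   \code{"cluster_motif"}; \code{format()} collapses it to one string.
#' @export
cluster_motif <- function(enc, rows = NULL, letter_threshold = 0.7,
                          class_threshold = 0.7) {
  codes <- enc$codes
  if (!is.null(rows)) codes <- codes[rows, , drop = FALSE]
  if (nrow(codes) < 1) stop("cluster_motif needs at least one row")
  tokens <- character(ncol(codes))
  for (w in seq_len(ncol(codes))) {
    v <- codes[, w]
    v <- v[v > 0L]
    if (length(v) == 0) { tokens[w] <- "."; next }
    freq <- tabulate(v, nbins = 20) / length(v)
    if (max(freq) >= letter_threshold) {
      tokens[w] <- AA_ALPHABET[which.max(freq)]
      next
    }
    tok <- "."
    for (cls in names(MOTIF_CLASSES)) {
      if (sum(freq[match(MOTIF_CLASSES[[cls]], AA_ALPHABET)]) >=
          class_threshold) {
        tok <- paste0("X(", cls, ")")
        break
      }
    }
    tokens[w] <- tok
  }
  structure(tokens, class = "cluster_motif")
}

#' @export
#' @method format cluster_motif
format.cluster_motif <- function(x, ...) paste(unclass(x), collapse = " ")

#' @export
#' @method print cluster_motif
print.cluster_motif <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
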