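make_blobs <- function(n_per = 30, centers = list(c(0, 0, 0), c(10, 10, 10)),
                       sd = 0.02, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(centers, function(cc)
    matrix(rnorm(n_per * 3, sd = sd), ncol = 3) +
      matrix(cc, n_per, 3, byrow = TRUE)))
  list(X = X, truth = rep(seq_along(centers) - 1L, each = n_per))
}

test_that("projections are reproducible and respect their contracts", {
  pt <- load_property_table()
  set.seed(21)
  seqs <- vapply(1:60, function(i)
    paste(sample(AA_ALPHABET, 7, replace = TRUE), collapse = ""), "")
  parsed <- parse_matrix(build_tensor(encode_strings(seqs, "central"), pt))
  # fixed seed twice: identical UMAP coordinates
  p1 <- project(parsed, "umap", seed = 617)
  p2 <- project(parsed, "umap", seed = 617)
  expect_identical(p1$coords, p2$coords)
  expect_equal(ncol(p1$coords), 3L)
  # duplicated input rows land on identical PCA points
  dup <- rbind(parsed$data[1, , drop = FALSE], parsed$data)
  pp <- project(dup, "pca", seed = 617)
  expect_equal(pp$coords[1, ], pp$coords[2, ], tolerance = 1e-8)
  # PCA on rank-2 data: third component variance ~ 0
  base <- matrix(rnorm(80), 40, 2)
  rank2 <- cbind(base, base %*% matrix(c(1, 2, -1, 0.5), 2, 2))
  pr <- project(rank2, "pca", n_components = 3, seed = 1)
  expect_lt(var(pr$coords[, 3]), 1e-20)
  expect_error(project(parsed$data[, 1:2], "pca", n_components = 3),
               "n_components")
})

test_that("density clustering recovers well-separated blobs", {
  bl <- make_blobs()
  asg <- cluster_points(bl$X, "dbscan", eps = 0.15, min_pts = 5)
  expect_equal(length(unique(asg$labels[asg$labels >= 0])), 2L)
  expect_equal(purity(asg, as.character(bl$truth))$mean_purity, 1)
  # OPTICS agrees on the same geometry
  asg_o <- cluster_points(bl$X, "optics", min_pts = 10, eps_cl = 0.15)
  expect_equal(length(unique(asg_o$labels[asg_o$labels >= 0])), 2L)
  expect_equal(purity(asg_o, as.character(bl$truth))$mean_purity, 1)
  # far-away singleton is noise under DBSCAN
  X2 <- rbind(bl$X, c(50, 50, 50))
  asg2 <- cluster_points(X2, "dbscan", eps = 0.15, min_pts = 5)
  expect_equal(asg2$labels[nrow(X2)], -1L)
  # all points identical collapse into one cluster
  same <- matrix(1, 20, 3)
  expect_equal(unique(cluster_points(same, "dbscan")$labels), 0L)
  # kmeans with k = n puts every point in its own cluster
  small <- make_blobs(n_per = 3)$X
  asg_k <- cluster_points(small, "kmeans", k = nrow(small), seed = 1)
  expect_equal(sort(unique(asg_k$labels)), 0:(nrow(small) - 1L))
  expect_error(cluster_points(small, "kmeans"), "requires")
})

test_that("in-package DBSCAN matches a brute-force reference", {
  brute_dbscan <- function(X, eps, min_pts) {
    D <- as.matrix(dist(X))
    nb <- apply(D <= eps, 1, which, simplify = FALSE)
    core <- lengths(nb) >= min_pts
    labels <- rep(-2L, nrow(X)); cl <- -1L
    for (i in seq_len(nrow(X))) {
      if (labels[i] != -2L || !core[i]) next
      cl <- cl + 1L; labels[i] <- cl; frontier <- i
      while (length(frontier)) {
        nbrs <- unique(unlist(nb[frontier]))
        newp <- nbrs[labels[nbrs] == -2L]
        labels[newp] <- cl
        frontier <- newp[core[newp]]
      }
    }
    labels[labels == -2L] <- -1L
    labels
  }
  set.seed(13)
  for (rep_i in 1:5) {
    X <- matrix(rnorm(3 * 120, sd = 0.5), ncol = 3)
    eps <- runif(1, 0.2, 0.6)
    got <- cluster_points(X, "dbscan", eps = eps, min_pts = 4)$labels
    want <- brute_dbscan(X, eps, 4)
    # same partition up to label names: compare co-membership
    expect_equal(got == -1L, want == -1L)
    m <- got >= 0
    expect_equal(outer(got[m], got[m], "=="), outer(want[m], want[m], "=="))
  }
})

test_that("purity summarizes clusters the way it is reported", {
  asg <- structure(list(labels = c(0L, 0L, 0L, 1L, 1L, -1L),
                        algorithm = "manual", params = list()),
                   class = "cluster_assignment")
  labels <- c("A", "A", "B", "C", "C", "Z")
  rp <- purity(asg, labels)
  expect_equal(rp$per_cluster$purity, c(2 / 3, 1))
  expect_equal(rp$mean_purity, mean(c(2 / 3, 1)))
  # noise excluded: the Z point changes nothing
  expect_equal(rp$fraction_clustered, 5 / 6)
  # single-label clusters: mean 1, sd 0
  pure <- purity(structure(list(labels = c(0L, 0L, 1L, 1L)),
                           class = "cluster_assignment"),
                 c("A", "A", "B", "B"))
  expect_equal(pure$mean_purity, 1)
  expect_equal(pure$sd_purity, 0)
  # relabeling permutes but does not change the statistics
  relab <- structure(list(labels = c(1L, 1L, 1L, 0L, 0L, -1L)),
                     class = "cluster_assignment")
  rp2 <- purity(relab, labels)
  expect_equal(sort(rp2$per_cluster$purity), sort(rp$per_cluster$purity))
  expect_equal(rp2$mean_purity, rp$mean_purity)
  # one big uniform cluster approaches 1/3 purity over three classes
  set.seed(2)
  big <- structure(list(labels = rep(0L, 3000)),
                   class = "cluster_assignment")
  rp3 <- purity(big, sample(c("a", "b", "c"), 3000, replace = TRUE))
  expect_equal(rp3$mean_purity, 1 / 3, tolerance = 0.05)
  # no non-noise clusters: empty report
  empty <- purity(structure(list(labels = rep(-1L, 4)),
                            class = "cluster_assignment"),
                  c("a", "b", "a", "b"))
  expect_equal(nrow(empty$per_cluster), 0L)
  expect_true(is.na(empty$mean_purity))
})

test_that("cluster isolation regroups rows with recorded boundaries", {
  enc <- encode_strings(c("CAAF", "CADF", "CAEF", "CKKF", "CKRF"), "left")
  asg <- structure(list(labels = c(0L, 0L, 0L, 1L, 1L)),
                   class = "cluster_assignment")
  iso <- isolate_clusters(enc, asg, c(0L, 1L))
  expect_equal(nrow(iso$enc$codes), 5L)
  expect_equal(iso$boundaries, 3L)
  solo <- isolate_clusters(enc, asg, 1L)
  expect_equal(nrow(solo$enc$codes), 2L)
  expect_equal(solo$enc$ids, c("seq_3", "seq_4"))
  expect_error(isolate_clusters(enc, asg, 7L), "unknown cluster")
})

test_that("motifs emit letters, class wildcards, then wildcards", {
  # conserved column, small-class column, uniform column
  enc <- encode_strings(c("RSA", "RTC", "RGD", "RAE", "RSF", "RTG",
                          "RGH", "RAI", "RSK", "RTL"), "left")
  m <- cluster_motif(enc)
  expect_equal(m[1], "R")
  expect_equal(m[2], "X(small)")
  expect_equal(m[3], ".")
  # positive class beats the broader sets for K/R/H columns
  encp <- encode_strings(c("KA", "RA", "HA", "KA"), "left")
  expect_equal(cluster_motif(encp)[1], "X(positive)")
  # all-pad columns print as wildcards
  encw <- encode_strings("AA", "left", width = 3)
  expect_equal(cluster_motif(encw)[3], ".")
  expect_match(format(m), "R X\\(small\\) \\.")
})
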