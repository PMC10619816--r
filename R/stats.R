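# Nonparametric statistics ----------------------------------------------------
#
# Position-sensitive repertoire averages are not normally distributed (20
# discrete residues), so summaries are bootstrapped and significance comes
# from a two-sided nonparametric permutation test on the difference of
# means: p = (1 + #(z^2 >= z0^2)) / (R + 1).

#' Bootstrap mean and standard deviation of per-sequence values
#'
#' Resamples the sequences with replacement \code{n_boot} times, takes the
#' mean of each resample, and reports the mean and SD of the bootstrap
#' distribution.
#'
#' @param values Numeric vector, one scalar per sequence.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional RNG seed.
#' @return Object of class \code{"bootstrap_result"}: \code{estimate},
#'   \code{sd}, \code{n_boot}, \code{seed}.
#' @export
bootstrap_mean_sd <- function(values, n_boot = 1000, seed = NULL) {
  if (length(values) == 0) stop("cannot bootstrap an empty vector")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- colMeans(matrix(values[sample.int(n, n * n_boot, replace = TRUE)],
                           nrow = n))
  structure(list(estimate = mean(means), sd = stats::sd(means),
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' Two-sided nonparametric permutation test on a difference of means
#'
#' The empirical statistic is z0 = mean(A) - mean(B). Group labels are
#' randomly permuted (preserving group sizes) R times, or exhaustively
#' enumerated when the total number of distinct relabelings is small, and
#' the two-sided p-value is (1 + #(z^2 >= z0^2)) / (R + 1), bounded below
#' by 1/(R + 1).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param R Number of random permutations (default 1000).
#' @param seed Optional RNG seed.
#' @param exhaustive \code{"auto"} (enumerate when choose(nA+nB, nA) <=
#'   10000), \code{"always"}, or \code{"never"}.
#' @return Object of class \code{"permutation_result"}: \code{p},
#'   \code{z0}, \code{R} (permutations actually used), \code{exceed_count},
#'   \code{exhaustive}, \code{seed}.
#' @export
permutation_test <- function(a, b, R = 1000, seed = NULL,
                             exhaustive = c("auto", "always", "never")) {
  exhaustive <- match.arg(exhaustive)
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty")
  z0 <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  n_arr <- choose(n, na)
  do_exhaustive <- exhaustive == "always" ||
    (exhaustive == "auto" && n_arr <= 10000)
  tol <- 1e-12
  if (do_exhaustive) {
    idx <- utils::combn(n, na)
    z <- apply(idx, 2, function(ii) mean(pool[ii]) - mean(pool[-ii]))
    exceed <- sum(z^2 >= z0^2 - tol)
    R_used <- ncol(idx)
  } else {
    if (!is.null(seed)) set.seed(seed)
    z <- replicate(R, {
      ii <- sample.int(n, na)
      mean(pool[ii]) - mean(pool[-ii])
    })
    exceed <- sum(z^2 >= z0^2 - tol)
    R_used <- R
  }
  structure(list(p = (1 + exceed) / (R_used + 1), z0 = z0, R = R_used,
                 exceed_count = exceed, exhaustive = do_exhaustive,
                 seed = seed),
            class = "permutation_result")
}

#' @export
#' @method print permutation_result
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: z0 = %.4g, p = %.4g (%s, R = %d)\n",
              x$z0, x$p, if (x$exhaustive) "exhaustive" else "random",
              x$R))
  invisible(x)
}

#' Column-wise permutation significance between two property tensors
#'
#' At every alignment column the per-sequence values of one property (pad
#' cells contribute 0, consistent with \code{\link{position_average}}) are
#' compared between the two repertoires with a permutation test. Raw
#' per-column p-values are reported without multiple-testing correction
#' (optional Benjamini-Hochberg), flagged at \code{alpha}, and maximal runs
#' of >= 2 flagged columns are annotated as contiguous regions.
#'
#' @param tensorA,tensorB \code{property_tensor} objects co-encoded on the
#'   same column grid.
#' @param property_name Property to test.
#' @param alpha Significance level (default 0.05).
#' @param R Permutations per column (default 1000).
#' @param seed Optional base seed (per-column seeds are offset from it).
#' @param adjust \code{"none"} (default, matching per-position asterisks) or
#'   \code{"BH"}.
#' @return A list: \code{table} (data.frame column, p, flag, region) and
#'   \code{regions} (list of integer column ranges of length >= 2).
#' @export
positionwise_significance <- function(tensorA, tensorB, property_name,
                                      alpha = 0.05, R = 1000, seed = NULL,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  dA <- dim(tensorA$values); dB <- dim(tensorB$values)
  if (dA[2] != dB[2])
    stop("tensors are not co-encoded on the same column grid")
  mA <- property_mask(tensorA, property_name)
  mB <- property_mask(tensorB, property_name)
  W <- ncol(mA)
  p <- numeric(W)
  for (w in seq_len(W)) {
    p[w] <- permutation_test(mA[, w], mB[, w], R = R,
                             seed = if (is.null(seed)) NULL else seed + w,
                             exhaustive = "never")$p
  }
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  flag <- p_adj < alpha
  # maximal runs of >= 2 flagged columns
  region <- integer(W)
  regions <- list()
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rid <- 0L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= 2) {
      rid <- rid + 1L
      region[starts[k]:ends[k]] <- rid
      regions[[rid]] <- c(starts[k], ends[k])
    }
  }
  list(table = data.frame(column = seq_len(W), p = p_adj, flag = flag,
                          region = region),
       regions = regions)
}

#' Two-sided nonparametric Studentized bootstrap test
#'
#' Tests equality of means via the studentized difference
#' t = (mean(A) - mean(B)) / sqrt(var(A)/nA + var(B)/nB). Both groups are
#' shifted to a common (pooled) mean to enforce the null, resampled within
#' group \code{n_boot} times, and the two-sided p-value is
#' (1 + #(|t*| >= |t0|)) / (n_boot + 1).
#'
#' @param a,b Numeric vectors of length >= 2 (the variance must exist).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional RNG seed.
#' @return Object of class \code{"permutation_result"} (same fields; here
#'   \code{z0} is the studentized statistic and \code{R} = \code{n_boot}).
#' @export
studentized_bootstrap_test <- function(a, b, n_boot = 1000, seed = NULL) {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need >= 2 values (variance undefined otherwise)")
  if (!is.null(seed)) set.seed(seed)
  se <- function(x, y) sqrt(stats::var(x) / length(x) +
                              stats::var(y) / length(y))
  s0 <- se(a, b)
  t0 <- if (s0 > 0) (mean(a) - mean(b)) / s0 else
    if (mean(a) == mean(b)) 0 else Inf
  mu <- mean(c(a, b))
  a0 <- a - mean(a) + mu
  b0 <- b - mean(b) + mu
  tstar <- replicate(n_boot, {
    ra <- sample(a0, replace = TRUE)
    rb <- sample(b0, replace = TRUE)
    s <- se(ra, rb)
    if (s > 0) (mean(ra) - mean(rb)) / s else
      if (mean(ra) == mean(rb)) 0 else Inf
  })
  exceed <- sum(tstar^2 >= t0^2 - 1e-12)
  structure(list(p = (1 + exceed) / (n_boot + 1), z0 = t0, R = n_boot,
                 exceed_count = exceed, exhaustive = FALSE, seed = seed),
            class = "permutation_result")
}
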