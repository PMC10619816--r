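test_that("position frequencies condition on occupancy", {
  enc <- encode_strings(c("LL", "LQ", "L"), "left", width = 2)
  fp <- position_frequencies(enc)
  expect_equal(unname(fp$probs[1, "L"]), 1)
  expect_equal(fp$probs[2, c("L", "Q")], c(L = 0.5, Q = 0.5))
  expect_equal(sum(fp$probs[2, ]), 1)
  expect_equal(fp$coverage, c(1, 2 / 3))
  # zero-coverage column gives an all-zero row
  pad <- encode_strings("A", "left", width = 2)
  expect_equal(sum(position_frequencies(pad)$probs[2, ]), 0)
})

test_that("entropy matches brute-force computation and its known limits", {
  # uniform over all 20 residues: the 4.32-bit ceiling
  enc20 <- encode_strings(AA_ALPHABET, "left", width = 1)
  expect_equal(shannon_entropy(enc20)$H, log2(20), tolerance = 1e-12)
  # single residue: 0 bits; 50/50: 1 bit
  expect_equal(shannon_entropy(encode_strings(c("A", "A"), "left"))$H, 0)
  expect_equal(shannon_entropy(encode_strings(c("A", "C"), "left"))$H, 1)
  # brute-force agreement on arbitrary counts
  col <- c("A", "A", "C", "D", "D", "D", "W")
  enc <- encode_strings(col, "left", width = 1)
  expect_equal(shannon_entropy(enc)$H, brute_entropy(col))
})

test_that("merging residue symbols never increases entropy", {
  set.seed(7)
  for (rep_i in 1:20) {
    col <- sample(AA_ALPHABET[1:6], 30, replace = TRUE)
    merged <- ifelse(col %in% c("A", "C"), "A", col)
    expect_lte(brute_entropy(merged),
               brute_entropy(col) + 1e-12)
  }
  # and via the package path: recode C as A in the sequences
  col <- sample(AA_ALPHABET[1:6], 40, replace = TRUE)
  H1 <- shannon_entropy(encode_strings(col, "left", width = 1))$H
  H2 <- shannon_entropy(encode_strings(gsub("C", "A", col), "left",
                                       width = 1))$H
  expect_lte(H2, H1 + 1e-12)
})

test_that("mutual information matches the joint-count oracle on small sets", {
  # perfectly coupled pair at 1 bit each
  enc <- encode_strings(c("AA", "AA", "GG", "GG"), "left")
  mi <- mutual_information(enc)$I
  expect_equal(mi[1, 2], 1)
  # invariant column: zero information with everything
  enc2 <- encode_strings(c("AC", "AD", "AW", "AY"), "left")
  expect_equal(mutual_information(enc2)$I[1, 2], 0)
  # random <= 10-sequence instances against the brute-force oracle
  set.seed(11)
  for (rep_i in 1:10) {
    n <- sample(4:10, 1)
    s <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "G", "K"), 3, replace = TRUE), collapse = ""), "")
    enc <- encode_strings(s, "left")
    mi <- mutual_information(enc)$I
    chars <- do.call(rbind, strsplit(s, ""))
    for (i in 1:3) for (j in 1:3) {
      expect_equal(mi[i, j], brute_mi(chars[, i], chars[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("MI matrices are symmetric, non-negative, entropy on the diagonal", {
  set.seed(23)
  s <- vapply(1:40, function(i)
    paste(sample(AA_ALPHABET[1:8], 5, replace = TRUE), collapse = ""), "")
  enc <- encode_strings(s, "left")
  mi <- mutual_information(enc)$I
  expect_equal(mi, t(mi))
  expect_true(all(mi >= 0))
  expect_equal(diag(mi), shannon_entropy(enc)$H, tolerance = 1e-12)
})

test_that("N-grams slide within features and never across boundaries", {
  r1 <- repertoire(matrix("AAA", ncol = 1, dimnames = list(NULL, "s")))
  d <- ngram_frequencies(r1, 2)
  expect_equal(d$probs, c(AA = 1))
  r2 <- repertoire(matrix("ACD", ncol = 1, dimnames = list(NULL, "s")))
  expect_equal(ngram_frequencies(r2, 2)$probs, c(AC = 0.5, CD = 0.5))
  # two features never produce a cross-boundary gram
  r3 <- repertoire(matrix(c("AC", "DF"), ncol = 2,
                          dimnames = list(NULL, c("f1", "f2"))))
  d3 <- ngram_frequencies(r3, 2)
  expect_setequal(names(d3$probs), c("AC", "DF"))
  # n longer than every sequence: empty distribution
  expect_equal(ngram_frequencies(r3, 5)$total_windows, 0L)
  # probabilities always sum to one when grams exist
  expect_equal(sum(d3$probs), 1)
})

test_that("dataset differences are antisymmetric and zero on identity", {
  encA <- encode_strings(c("ACDK", "AWDK", "ACYK"), "left")
  encB <- encode_strings(c("ACDK", "AWYK", "GCDK"), "left")
  for (stat in c("frequency", "entropy", "mi")) {
    dAB <- dataset_difference(encA, encB, stat)
    dBA <- dataset_difference(encB, encA, stat)
    expect_equal(dAB, -dBA)
    expect_true(all(dataset_difference(encA, encA, stat) == 0))
  }
  # mismatched grids refuse to difference
  encC <- encode_strings(c("ACD", "AWD"), "left")
  expect_error(dataset_difference(encA, encC, "entropy"), "co-encoded")
  # a digram present only in A appears at +q
  rA <- repertoire(matrix("AC", ncol = 1, dimnames = list(NULL, "s")))
  rB <- repertoire(matrix("DF", ncol = 1, dimnames = list(NULL, "s")))
  dd <- dataset_difference(rA, rB, "ngram")
  expect_equal(dd[["AC"]], 1)
  expect_equal(dd[["DF"]], -1)
})
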