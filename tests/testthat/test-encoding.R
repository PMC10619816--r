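test_that("the central residue precedes the midway point for even lengths", {
  expect_equal(center_index("CAF"), 1L)
  expect_equal(center_index("CASF"), 1L)
  expect_equal(center_index("AB"), 0L)
  expect_equal(center_index(9L), 4L)
  expect_error(center_index(""), "empty")
})

test_that("alignment schemes place sequences as specified", {
  # central: odd sequence in odd window and even sequence in even window
  e1 <- encode_strings("CAF", "central", width = 5)
  expect_equal(unname(e1$codes[1, ]), c(0L, 2L, 1L, 5L, 0L))
  e2 <- encode_strings("CASF", "central", width = 6)
  expect_equal(unname(e2$codes[1, ]),
               c(0L, 2L, 1L, 16L, 5L, 0L))
  # left anchors residue 0; right anchors the final residue
  expect_equal(unname(encode_strings("CAF", "left", width = 5)$codes[1, ]),
               c(2L, 1L, 5L, 0L, 0L))
  expect_equal(unname(encode_strings("CAF", "right", width = 5)$codes[1, ]),
               c(0L, 0L, 2L, 1L, 5L))
  # bulge pins pad_len/2 residues to each edge, centers the rest
  eb <- encode_strings("NLVPMVATV", "bulge", width = 14, pad_len = 6)
  expect_equal(AA_ALPHABET[eb$codes[1, eb$codes[1, ] > 0]],
               strsplit("NLVPMVATV", "")[[1]])
  expect_equal(which(eb$codes[1, ] > 0), c(1:3, 6:8, 12:14))
  # width == length: dense row, no interior pad
  eb9 <- encode_strings("NLVPMVATV", "bulge", width = 9, pad_len = 6)
  expect_equal(unname(eb9$codes[1, ]),
               match(strsplit("NLVPMVATV", "")[[1]], AA_ALPHABET))
  # degenerate: sequence no longer than pad_len fills N then C blocks
  eshort <- encode_strings("CASF", "bulge", width = 10, pad_len = 6)
  expect_equal(which(eshort$codes[1, ] > 0), c(1:3, 10))
  expect_error(encode_strings("NLVPMVATV", "central", width = 5),
               "longer than its window")
})

test_that("non-zero codes decode back to the input feature string", {
  seqs <- c("CAVSNF", "CILRDEYF", "CAF", "WYQGGKLI")
  for (scheme in c("central", "left", "right")) {
    enc <- encode_strings(seqs, scheme)
    for (i in seq_along(seqs))
      expect_equal(unname(decode_row(enc, i)), seqs[i])
  }
  enc <- encode_strings(seqs, "bulge", width = 10, pad_len = 4)
  for (i in seq_along(seqs))
    expect_equal(unname(decode_row(enc, i)), seqs[i])
})

test_that("same-length datasets relate left/right/central encodings", {
  seqs <- c("CAVSNF", "CILRDE", "WYQGGK")
  el <- encode_strings(seqs, "left", width = 8)
  er <- encode_strings(seqs, "right", width = 8)
  ec <- encode_strings(seqs, "central", width = 8)
  # right-encoding equals the column-reversed left-encoding of the
  # residue-reversed sequences (same pad structure, mirrored anchor)
  rev_seqs <- vapply(seqs, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)
  el_rev <- encode_strings(rev_seqs, "left", width = 8)
  expect_equal(er$codes, el_rev$codes[, ncol(el_rev$codes):1, drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(er$codes > 0, (el$codes > 0)[, ncol(el$codes):1, drop = FALSE],
               ignore_attr = TRUE)
  # central is left shifted by a constant
  shift <- which(ec$codes[1, ] > 0)[1] - which(el$codes[1, ] > 0)[1]
  expect_equal(ec$codes[, (1 + shift):(6 + shift)], el$codes[, 1:6],
               ignore_attr = TRUE)
})

test_that("coverage counts occupied rows per column", {
  enc <- encode_strings(c("NLVPMVATV", "NLVPMVATV"), "bulge",
                        width = 9, pad_len = 6)
  expect_equal(coverage_profile(enc), rep(1, 9))
  mix <- encode_strings(c("NLVPMVATV", "NLVPMVATTV"), "bulge",
                        width = 10, pad_len = 6)
  cov <- coverage_profile(mix)
  expect_true(all(cov[c(1:3, 8:10)] == 1))
  expect_true(any(cov < 1))
  # forced inter-feature gap columns have zero coverage
  r2 <- repertoire(matrix(c("CAF", "CASF"), ncol = 2,
                          dimnames = list(NULL, c("a", "b"))))
  g <- encode_repertoire(r2, alignment_spec("left", inter_feature_gap = 2))
  gap_cols <- g$column_map$column[g$column_map$role == "gap"]
  expect_length(gap_cols, 2L)
  expect_equal(unname(coverage_profile(g)[gap_cols]), c(0, 0))
})

test_that("multi-feature windows concatenate in feature order", {
  rep <- toy_repertoire()
  enc <- encode_repertoire(rep, alignment_spec("central"))
  expect_equal(ncol(enc$codes), 5L + 5L)
  expect_equal(unique(enc$column_map$feature), c("cdr3a", "cdr3b"))
  for (i in seq_len(4))
    expect_equal(decode_row(enc, i), rep$features[i, ],
                 ignore_attr = TRUE)
})
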