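test_that("the bundled dictionary carries 62 Z-normalized values per residue", {
  pt <- load_property_table()
  expect_equal(ncol(pt$raw), 62L)
  expect_equal(rownames(pt$normalized), AA_ALPHABET)
  # population Z-score identities: mean 0, sd 1 (divisor 20) per property
  expect_lt(max(abs(colMeans(pt$normalized))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(pt$normalized^2)) - 1)), 1e-10)
  # net charge over the 20 residues sums to zero after normalization
  expect_lt(abs(sum(pt$normalized[, "charge"])), 1e-10)
})

test_that("degenerate property tables are reported", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(residue = AA_ALPHABET, good = seq_len(20), flat = 1)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_warning(pt <- load_property_table(path), "flat")
  expect_equal(pt$property_names, "good")

  dup <- data.frame(residue = c(AA_ALPHABET[-1], "A"), v = seq_len(20))
  dup$residue[2] <- "A"
  write.csv(dup, path, row.names = FALSE, quote = FALSE)
  expect_error(load_property_table(path))
})

test_that("tensors look up normalized values with pads at exactly zero", {
  pt <- load_property_table()
  enc <- encode_strings(c("K", "D"), "left", width = 2)
  tens <- build_tensor(enc, pt)
  expect_equal(tens$values[1, 1, ], pt$normalized["K", ])
  expect_equal(tens$values[2, 1, ], pt$normalized["D", ])
  # all-pad column is zero across sequences and properties
  expect_true(all(tens$values[, 2, ] == 0))
  # identical sequences give identical slabs
  two <- build_tensor(encode_strings(c("CASF", "CASF"), "left"), pt)
  expect_equal(two$values[1, , ], two$values[2, , ])
})

test_that("position and net averages follow the stated denominators", {
  pt <- load_property_table()
  kv <- pt$normalized["K", "charge"]
  dv <- pt$normalized["D", "charge"]
  # +K and -D at the same column average toward their midpoint
  tens <- build_tensor(encode_strings(c("K", "D"), "left", width = 1), pt)
  pa <- position_average(tens, "charge")
  expect_equal(pa$mean, (kv + dv) / 2)
  # position occupied in half the rows: pad counts in the denominator...
  half <- build_tensor(encode_strings(c("KK", "K"), "left", width = 2), pt)
  expect_equal(position_average(half, "charge")$mean[2], kv / 2)
  # ...unless coverage normalization is requested
  expect_equal(position_average(half, "charge",
                                coverage_norm = TRUE)$mean[2], kv)
  # net average: homopolymer gives the residue's own value; a mix the midpoint
  hom <- build_tensor(encode_strings("KKKK", "central"), pt)
  expect_equal(net_average(hom, "charge")$mean, kv)
  mix <- build_tensor(encode_strings("KKDD", "central"), pt)
  expect_equal(net_average(mix, "charge")$mean, (kv + dv) / 2)
  # bootstrap of identical sequences collapses to sd 0
  same <- build_tensor(encode_strings(c("KKK", "KKK", "KKK"), "central"), pt)
  nb <- net_average(same, "charge", n_boot = 50, seed = 1)
  expect_equal(nb$boot_sd, 0)
  expect_error(position_average(tens, "not_a_property"), "unknown property")
})

test_that("property masks slice the tensor consistently", {
  pt <- load_property_table()
  tens <- build_tensor(encode_strings(c("KAD", "KKD"), "central"), pt)
  m <- property_mask(tens, "hydropathy")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(colMeans(m)),
               position_average(tens, "hydropathy")$mean)
  # pad cells are zero in any mask
  t2 <- build_tensor(encode_strings(c("KA", "K"), "left", width = 2), pt)
  expect_equal(unname(property_mask(t2, "volume")[2, 2]), 0)
})

test_that("parsing drops empty and correlated columns deterministically", {
  pt <- load_property_table()
  set.seed(42)
  seqs <- vapply(1:30, function(i)
    paste(sample(AA_ALPHABET, 8, replace = TRUE), collapse = ""), "")
  tens <- build_tensor(encode_strings(seqs, "left", width = 10), pt)
  parsed <- parse_matrix(tens)
  # empty flat columns (pad-only positions 9-10) are gone
  expect_true(all(colSums(parsed$data != 0) > 0))
  expect_true(any(parsed$dropped$reason == "empty"))
  # no surviving pair exceeds the threshold
  C <- abs(cor(parsed$data))
  diag(C) <- 0
  C[is.na(C)] <- 0
  expect_lte(max(C), 0.75 + 1e-12)
  # idempotence: re-filtering the retained columns drops nothing
  C2 <- suppressWarnings(abs(cor(parsed$data)))
  # threshold >= 1 keeps everything non-empty
  loose <- parse_matrix(tens, corr_threshold = 1)
  expect_true(all(loose$dropped$reason == "empty"))
  # duplicated property columns: the later twin is dropped as correlated
  expect_true(any(grepl("correlated-with", parsed$dropped$reason)))
})

test_that("entropy re-weighting zeroes invariant positions", {
  pt <- load_property_table()
  # position 1 invariant (all C), position 2 variable
  seqs <- c("CK", "CD", "CE", "CR", "CA", "CG")
  tens <- build_tensor(encode_strings(seqs, "left"), pt)
  pw <- parse_matrix(tens, corr_threshold = 1, reweight = TRUE)
  pos1 <- pw$column_index$position == 1
  expect_true(all(pw$data[, pos1] == 0))
  expect_true(any(pw$data[, !pos1] != 0))
  # weights are H/log2(20), bounded by 1
  expect_true(all(pw$weights >= 0 & pw$weights <= 1))
})

test_that("pairwise interaction scores read straight off the pair chart", {
  pair <- load_pair_table()
  expect_true(isSymmetric(pair))
  encK <- encode_strings("K", "left")
  encD <- encode_strings("D", "left")
  s <- interaction_score(encK, encD, pair)
  expect_equal(s[1, 1], pair["K", "D"])
  # a pad member contributes zero
  encKpad <- encode_strings("K", "left", width = 2)
  s2 <- interaction_score(encKpad, encD, pair)
  expect_equal(s2[2, 1], 0)
  # mismatched row counts are an error
  enc2 <- encode_strings(c("K", "R"), "left")
  expect_error(interaction_score(enc2, encD, pair), "paired")
})
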