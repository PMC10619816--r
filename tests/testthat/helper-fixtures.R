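# Shared fixtures, built in code at test time

# a tiny paired-chain repertoire with metadata
toy_repertoire <- function() {
  repertoire(
    matrix(c("CAVS", "CASSF",
             "CAVSN", "CASSL",
             "CILRD", "CASSF",
             "CAVS", "CASRF"),
           ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("cdr3a", "cdr3b"))),
    metadata = data.frame(antigen = c("NLVPMVATV", "NLVPMVATV",
                                      "LLWNGPMAV", "LLWNGPMAV"),
                          stringsAsFactors = FALSE))
}

# write a temporary CSV repertoire file, returning its path
toy_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# an encoded single-feature repertoire from raw strings
encode_strings <- function(seqs, scheme = "central", width = NULL,
                           pad_len = 0) {
  r <- repertoire(matrix(seqs, ncol = 1, dimnames = list(NULL, "seq")))
  encode_repertoire(r, alignment_spec(scheme, pad_len = pad_len,
                                      feature_widths = width))
}

# brute-force Shannon entropy in bits from raw symbol counts
brute_entropy <- function(symbols) {
  p <- table(symbols) / length(symbols)
  -sum(p * log2(p))
}

# brute-force mutual information in bits from two aligned symbol vectors
brute_mi <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (joint[i, j] > 0)
      s <- s + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  }
  unname(s)
}
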