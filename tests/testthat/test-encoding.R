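test_that("OHB follows the A/G/T/C bit convention", {
  expect_equal(encode_ohb("A")[1:4], c(1, 0, 0, 0))
  expect_equal(encode_ohb("G"), c(0, 1, 0, 0))
  expect_equal(encode_ohb("T"), c(0, 0, 1, 0))
  expect_equal(encode_ohb("CG"), c(0, 0, 0, 1, 0, 1, 0, 0))
  v <- encode_ohb(fixture_window())
  expect_length(v, 164L)
  # exactly one bit set per position
  expect_equal(colSums(matrix(v, nrow = 4L)), rep(1, 41))
})

test_that("SNF is the running density of the current nucleotide", {
  v <- encode_snf("AACGTACT")
  expect_equal(v[3:8], c(1/3, 1/4, 1/5, 3/6, 2/7, 2/8))
  expect_equal(v[1], 1)
  expect_equal(encode_snf("AAAA"), rep(1, 4))
  # d_i in [1/i, 1] for random sequences
  set.seed(201)
  for (rep in 1:25) {
    s <- random_dna(sample(5:50, 1))
    d <- encode_snf(s)
    i <- seq_along(d)
    expect_true(all(d >= 1 / i - 1e-12 & d <= 1 + 1e-12))
  }
})

test_that("KNF matches hand examples and has unit block sums", {
  expect_equal(unname(encode_knf("AAAA", k = 1)), c(1, 0, 0, 0))
  v <- encode_knf("AACCA", k = 2)
  expect_equal(v[c("AA", "AC", "CA", "CC")],
               c(AA = 1/4, AC = 1/4, CA = 1/4, CC = 1/4))
  expect_equal(sum(v), 1)
  expect_length(encode_knf(fixture_window(), k = c(1, 2)), 20L)
  expect_error(encode_knf("ACG", k = 5), "k must")
})

test_that("KSNPF matches hand examples and has unit block sums", {
  v <- encode_ksnpf("ACGT", k = 1)  # pairs A_G and C_T, denominator 2
  expect_equal(unname(v[c("AxG", "CxT")]), c(0.5, 0.5))
  expect_equal(sum(v != 0), 2L)
  expect_equal(unname(encode_ksnpf("AAAA", k = 1)["AxA"]), 1)
  expect_length(encode_ksnpf(fixture_window(), k = 1:3), 48L)
  expect_error(encode_ksnpf("ACGT", k = 3), "k must")
})

test_that("KNF and KSNPF agree with the brute-force counting oracle", {
  set.seed(202)
  for (rep in 1:250) {
    s <- random_dna(sample(10:60, 1))
    expect_equal(unname(encode_knf(s, k = c(1, 2))),
                 unname(knf_oracle(s, c(1, 2))), tolerance = 1e-12)
    expect_equal(unname(encode_ksnpf(s, k = 1:3)),
                 unname(ksnpf_oracle(s, 1:3)), tolerance = 1e-12)
  }
})

test_that("PseDNC collapses to dinucleotide frequencies for a flat table", {
  flat <- psednc_params(property_table = matrix(0, 38, 16))
  s <- fixture_window()
  v <- encode_psednc(s, flat)
  expect_length(v, 19L)
  expect_equal(unname(v[17:19]), c(0, 0, 0))
  f <- tabulate(match(substring(s, 1:40, 2:41),
                      sort(as.vector(outer(c("A","C","G","T"),
                                           c("A","C","G","T"), paste0)))),
                nbins = 16) / 40
  expect_equal(unname(v[1:16]), f)
})

test_that("PseDNC sums to 1 for random sequences and property tables", {
  set.seed(203)
  for (rep in 1:100) {
    m <- matrix(rnorm(38 * 16), 38, 16)
    m <- (m - rowMeans(m)) / sqrt(rowMeans((m - rowMeans(m))^2))
    p <- psednc_params(lambda = sample(1:5, 1), w = runif(1, 0.01, 0.5),
                       property_table = m)
    v <- encode_psednc(random_dna(sample(10:60, 1)), p)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
  }
  expect_error(encode_psednc("ACGT", psednc_params(lambda = 4)), "lambda")
})

test_that("the shipped property table is standardized per row", {
  P <- dinucleotide_properties()
  expect_equal(dim(P), c(38L, 16L))
  expect_equal(unname(rowMeans(P)), rep(0, 38), tolerance = 1e-10)
  expect_equal(unname(rowMeans(P^2)), rep(1, 38), tolerance = 1e-10)
})

test_that("encode_all assembles the published 292-dimension layout", {
  s <- sample_set("w", fixture_window())
  m <- encode_all(s)
  expect_equal(dim(m), c(1L, 292L))
  lay <- attr(m, "layout")
  expect_equal(lay$family, c("OHB", "SNF", "KNF", "KSNPF", "PseDNC"))
  expect_equal(lay$start, c(1L, 165L, 206L, 226L, 274L))
  expect_equal(lay$end, c(164L, 205L, 225L, 273L, 292L))
  # determinism, bit for bit
  expect_identical(m, encode_all(s))
})

test_that("shuffling preserves composition blocks but not positional blocks", {
  set.seed(204)
  diff_ohb <- 0L
  for (rep in 1:10) {
    s <- random_dna(41)
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(encode_knf(sh, k = 1), encode_knf(s, k = 1))
    if (!identical(encode_ohb(sh), encode_ohb(s))) diff_ohb <- diff_ohb + 1L
  }
  expect_gt(diff_ohb, 7L)  # shuffles generally change the positional code
})

test_that("feature tables round-trip through TSV with layout sidecar", {
  s <- generate(3, 3, seed = 31)
  m <- encode_all(s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(m, path)
  expect_true(file.exists(paste0(path, ".layout.tsv")))
  m2 <- read_feature_table(path)
  expect_equal(unclass(m2)[, ], m[, ], tolerance = 1e-9)
  expect_equal(attr(m2, "label"), attr(m, "label"))
})
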