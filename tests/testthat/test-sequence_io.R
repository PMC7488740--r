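test_that("read_fasta reads, labels and validates fixed-length windows", {
  set.seed(101)
  seqs <- replicate(3, random_dna(41, centre_c = TRUE))
  path <- write_tmp_fasta(c("r1", "r2", "r3"), seqs, wrap = TRUE)
  s <- read_fasta(path, label = 1L)
  expect_s3_class(s, "sample_set")
  expect_equal(nrow(s), 3L)
  expect_equal(s$label, rep(1L, 3))
  expect_equal(s$sequence, unname(seqs))

  # wrong length, named offender
  bad <- write_tmp_fasta(c("ok", "short40"),
                         c(seqs[1], substr(seqs[2], 1, 40)))
  expect_error(read_fasta(bad), "short40")

  # ambiguity code, named offender
  nseq <- seqs[1]; substr(nseq, 5, 5) <- "N"
  badn <- write_tmp_fasta(c("ok", "hasN"), c(seqs[1], nseq))
  expect_error(read_fasta(badn), "hasN")
  # opt-in skip mode keeps the valid record
  expect_warning(sk <- read_fasta(badn, label = 0L, on_invalid = "skip"),
                 "skipped")
  expect_equal(sk$id, "ok")

  # non-C centre rejected for candidate windows, accepted when disabled
  noc <- seqs[1]; substr(noc, 21, 21) <- "A"
  badc <- write_tmp_fasta("offcentre", noc)
  expect_error(read_fasta(badc), "centre")
  expect_equal(nrow(read_fasta(badc, centre_c = FALSE)), 1L)

  # lowercase input is up-cased silently
  lower <- write_tmp_fasta("lc", tolower(seqs[1]))
  expect_equal(read_fasta(lower)$sequence, seqs[[1]])
})

test_that("FASTA round-trip preserves ids, sequences and order", {
  set.seed(102)
  s <- generate(4, 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(s, path)
  s2 <- read_fasta(path)
  expect_equal(s2$id, s$id)
  expect_equal(s2$sequence, s$sequence)
})

test_that("extract_windows emits one window per eligible cytosine", {
  # exactly one window: the whole 41-nt sequence, C only at the centre
  one <- paste0(strrep("A", 20), "C", strrep("T", 20))
  w <- extract_windows(one)
  expect_equal(nrow(w), 1L)
  expect_equal(w$sequence, one)
  expect_equal(w$id, "query_pos21")

  # cytosines too close to either end yield nothing
  margins <- strrep("A", 41)
  substr(margins, 5, 5) <- "C"; substr(margins, 40, 40) <- "C"
  expect_equal(nrow(extract_windows(margins)), 0L)

  # 45-nt, Cs at 21..23: hand enumeration gives 3 windows, centres at 21,22,23
  s45 <- paste0(strrep("A", 20), "CCC", strrep("G", 22))
  w3 <- extract_windows(s45)
  expect_equal(nrow(w3), 3L)
  expect_equal(w3$id, paste0("query_pos", 21:23))
  expect_true(all(substr(w3$sequence, 21, 21) == "C"))

  expect_error(extract_windows(strrep("C", 50), window_length = 40L), "odd")
})

test_that("every extracted window is centre-C with the requested length", {
  set.seed(103)
  for (rep in 1:20) {
    len <- sample(41:120, 1)
    wl <- sample(c(21L, 41L), 1)
    w <- extract_windows(random_dna(len), window_length = wl)
    if (nrow(w) == 0L) next
    expect_true(all(nchar(w$sequence) == wl))
    expect_true(all(substr(w$sequence, (wl + 1) %/% 2, (wl + 1) %/% 2) == "C"))
    # id encodes the true source position
    pos <- as.integer(sub("query_pos", "", w$id))
    expect_true(all(pos > (wl - 1) %/% 2 & pos <= len - (wl - 1) %/% 2))
  }
})

test_that("sample_set enforces unique ids and valid alphabets", {
  w <- fixture_window()
  expect_error(sample_set(c("a", "a"), c(w, w)), "duplicate")
  expect_error(sample_set("a", sub("A", "N", w)), "non-ACGT")
})
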