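# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive nested loops / pairwise enumeration so they share
# no code path with the implementation they check.

random_dna <- function(n, centre_c = FALSE) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (centre_c) s[(n + 1L) %/% 2L] <- "C"
  paste(s, collapse = "")
}

# all 4^k k-mers in lexicographic order over A,C,G,T
all_kmers <- function(k) {
  g <- rev(rep(list(c("A", "C", "G", "T")), k))
  apply(rev(expand.grid(g, stringsAsFactors = FALSE)), 1L, paste, collapse = "")
}

knf_oracle <- function(sequence, k) {
  chars <- strsplit(sequence, "")[[1L]]
  S <- length(chars)
  unlist(lapply(sort(k), function(kk) {
    kmers <- all_kmers(kk)
    counts <- setNames(numeric(length(kmers)), kmers)
    for (i in 1:(S - kk + 1L)) {
      w <- paste(chars[i:(i + kk - 1L)], collapse = "")
      counts[w] <- counts[w] + 1
    }
    counts / (S - kk + 1L)
  }))
}

ksnpf_oracle <- function(sequence, k) {
  chars <- strsplit(sequence, "")[[1L]]
  S <- length(chars)
  nuc <- c("A", "C", "G", "T")
  unlist(lapply(sort(k), function(kk) {
    pairs <- paste0(rep(nuc, each = 4L), rep(nuc, 4L))
    counts <- setNames(numeric(16L), pairs)
    for (i in 1:(S - kk - 1L)) {
      pr <- paste0(chars[i], chars[i + kk + 1L])
      counts[pr] <- counts[pr] + 1
    }
    counts / (S - kk - 1L)
  }))
}

# AUC as the fraction of (positive, negative) pairs ranked correctly,
# half credit for ties
auc_pairwise_oracle <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

write_tmp_fasta <- function(ids, seqs, wrap = FALSE) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  lines <- unlist(Map(function(i, s) {
    body <- if (wrap) {
      starts <- seq(1L, nchar(s), by = 10L)
      substring(s, starts, pmin(starts + 9L, nchar(s)))
    } else s
    c(paste0(">", i), body)
  }, ids, seqs))
  writeLines(lines, path)
  path
}

# a valid 41-nt cytosine-centred window used across tests
fixture_window <- function() paste0(strrep("ACGT", 5L), "C", strrep("TGCA", 5L))
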