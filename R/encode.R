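# Encoders work on integer codes 1..4 in lexicographic order A,C,G,T.
# The one-hot bit order is the separate A,G,T,C convention (see encode_ohb).
.NUC <- c("A", "C", "G", "T")

seq_to_codes <- function(sequence) {
  x <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]], .NUC)
  if (anyNA(x)) stop("sequence contains a non-ACGT character")
  x
}

#' One-hot binary (OHB) encoding
#'
#' Each position becomes a 4-bit indicator with bit order
#' `A = (1,0,0,0)`, `G = (0,1,0,0)`, `T = (0,0,1,0)`, `C = (0,0,0,1)`,
#' giving `4 L` dimensions for an `L`-nt window (164 for L = 41). OHB is the
#' fully positional encoding: it carries the complete sequence and is the
#' block where per-position motif signal shows up.
#'
#' @param sequence a single DNA string over `{A,C,G,T}`.
#' @return Numeric 0/1 vector of length `4 * nchar(sequence)`.
#' @export
#' @examples
#' encode_ohb("CG")  # 0 0 0 1 0 1 0 0
encode_ohb <- function(sequence) {
  codes <- seq_to_codes(sequence)
  bit <- c(1L, 4L, 2L, 3L)[codes]  # lexicographic code -> slot in (A,G,T,C)
  out <- numeric(4L * length(codes))
  out[4L * (seq_along(codes) - 1L) + bit] <- 1
  out
}

#' Sequential nucleotide frequency (SNF / nucleotide density)
#'
#' Entry `i` is the frequency of the nucleotide observed at position `i`
#' among positions `1..i` (current position included), so the first entry is
#' always 1 and entry `i` lies in `[1/i, 1]`.
#'
#' @inheritParams encode_ohb
#' @return Numeric vector of length `nchar(sequence)`.
#' @export
#' @examples
#' round(encode_snf("AACGTACT"), 2)
encode_snf <- function(sequence) {
  codes <- seq_to_codes(sequence)
  n <- length(codes)
  counts <- integer(4L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    counts[codes[i]] <- counts[codes[i]] + 1L
    out[i] <- counts[codes[i]] / i
  }
  out
}

#' k-nucleotide frequency (KNF)
#'
#' Frequencies of contiguous k-mers over the window, denominator `S - k + 1`
#' (the number of k-mer windows), one block of `4^k` values per `k` in
#' ascending order, k-mers ordered lexicographically over (A,C,G,T). Each
#' block sums to 1.
#'
#' @inheritParams encode_ohb
#' @param k integer vector of k-mer sizes, default `c(1, 2)`.
#' @return Named numeric vector of length `sum(4^k)`.
#' @export
encode_knf <- function(sequence, k = c(1L, 2L)) {
  codes <- seq_to_codes(sequence)
  S <- length(codes)
  k <- sort(as.integer(k))
  if (any(k < 1L) || any(k > S))
    stop("k must satisfy 1 <= k <= sequence length (", S, ")")
  blocks <- lapply(k, function(kk) {
    idx <- codes[seq_len(S - kk + 1L)] - 1L
    if (kk > 1L) for (j in seq_len(kk - 1L))
      idx <- idx * 4L + (codes[(1L + j):(S - kk + 1L + j)] - 1L)
    counts <- tabulate(idx + 1L, nbins = 4L^kk)
    out <- counts / (S - kk + 1L)
    names(out) <- kmer_names(kk)
    out
  })
  unlist(blocks)
}

kmer_names <- function(k) {
  grids <- rev(rep(list(.NUC), k))
  apply(rev(expand.grid(grids, stringsAsFactors = FALSE)), 1L, paste, collapse = "")
}

#' k-spaced nucleotide pair frequency (KSNPF)
#'
#' Frequencies of ordered nucleotide pairs separated by exactly `k`
#' intervening positions (e.g. `AXXT` for k = 2), denominator `S - k - 1`
#' (the number of such pair positions), 16 values per `k` in ascending order,
#' pairs ordered lexicographically. Each 16-entry block sums to 1.
#'
#' @inheritParams encode_ohb
#' @param k integer vector of spacer sizes, default `1:3`.
#' @return Named numeric vector of length `16 * length(k)`.
#' @export
encode_ksnpf <- function(sequence, k = 1:3) {
  codes <- seq_to_codes(sequence)
  S <- length(codes)
  k <- sort(as.integer(k))
  if (any(k < 1L) || any(k > S - 2L))
    stop("k must satisfy 1 <= k <= sequence length - 2 (", S - 2L, ")")
  blocks <- lapply(k, function(kk) {
    n_pairs <- S - kk - 1L
    first <- codes[seq_len(n_pairs)]
    second <- codes[seq_len(n_pairs) + kk + 1L]
    counts <- tabulate((first - 1L) * 4L + second, nbins = 16L)
    out <- counts / n_pairs
    names(out) <- paste0(rep(.NUC, each = 4L), strrep("x", kk), rep(.NUC, 4L))
    out
  })
  unlist(blocks)
}
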