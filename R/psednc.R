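#' Dinucleotide physico-chemical property table
#'
#' Loads a 38-property x 16-dinucleotide table and standardizes each
#' property row to zero mean / unit variance across the 16 dinucleotides,
#' as the pseudo dinucleotide composition definition requires.
#'
#' The table shipped with the package
#' (`dinucleotide_properties_synthetic.tsv`) carries the canonical 38 DNA
#' local-property names but SYNTHETIC values (seeded random draws): the
#' published supplementary table of measured values is not redistributable
#' here, and every structural property of the encoding (dimension, ordering,
#' normalization) is independent of the actual values. Substitute a real
#' table via `path` for production use; the format is TSV with a `property`
#' column followed by the 16 dinucleotide columns AA..TT in lexicographic
#' order.
#'
#' @param path optional path to a user-supplied property TSV.
#' @return Numeric matrix, properties x 16 dinucleotides, rows standardized.
#' @export
dinucleotide_properties <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dinucleotide_properties_synthetic.tsv",
                        package = "meth4c", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  dinucs <- as.vector(outer(.NUC, .NUC, paste0))
  dinucs <- sort(dinucs)
  if (!all(dinucs %in% names(df)))
    stop("property table must have columns ", paste(dinucs, collapse = ", "))
  m <- as.matrix(df[, dinucs])
  rownames(m) <- df$property
  # per-property standardization across the 16 dinucleotides (population sd)
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  if (any(sdev == 0)) stop("constant property row: ",
                           rownames(m)[which(sdev == 0)[1L]])
  (m - mu) / sdev
}

#' Parameters for pseudo dinucleotide composition
#'
#' @param lambda number of correlation tiers (default 3); must be smaller
#'   than the window length.
#' @param w weight factor for the tier-correlation terms (default 0.05).
#' @param property_table standardized property matrix as returned by
#'   [dinucleotide_properties()].
#' @return A `psednc_params` list.
#' @export
psednc_params <- function(lambda = 3L, w = 0.05,
                          property_table = dinucleotide_properties()) {
  stopifnot(lambda >= 1L, w > 0, is.matrix(property_table),
            ncol(property_table) == 16L)
  structure(list(lambda = as.integer(lambda), w = w,
                 property_table = property_table),
            class = "psednc_params")
}

#' Pseudo dinucleotide composition (PseDNC)
#'
#' The first 16 entries are normalized dinucleotide frequencies and the last
#' `lambda` entries are tier-correlation terms: `theta_j` is the mean, over
#' positions `i`, of the correlation function `Theta(i, i+j)`, itself the
#' mean squared difference of the standardized property values of the
#' dinucleotides starting at `i` and at `i+j`. The whole vector is divided by
#' `sum(f) + w * sum(theta)`, so it sums to 1.
#'
#' @inheritParams encode_ohb
#' @param params a [psednc_params] object.
#' @return Numeric vector of length `16 + lambda`.
#' @export
encode_psednc <- function(sequence, params = psednc_params()) {
  codes <- seq_to_codes(sequence)
  L <- length(codes)
  lambda <- params$lambda
  if (lambda >= L) stop("lambda (", lambda, ") must be < sequence length (", L, ")")
  # dinucleotide index at each start position, lexicographic AA..TT
  di <- (codes[-L] - 1L) * 4L + codes[-1L]        # length L-1
  f <- tabulate(di, nbins = 16L) / (L - 1L)
  P <- params$property_table                       # properties x 16, standardized
  theta <- vapply(seq_len(lambda), function(j) {
    n <- L - j - 1L
    a <- di[seq_len(n)]
    b <- di[seq_len(n) + j]
    # Theta(i, i+j) = mean over properties of squared value difference
    d2 <- colMeans((P[, a, drop = FALSE] - P[, b, drop = FALSE])^2)
    mean(d2)
  }, numeric(1L))
  denom <- sum(f) + params$w * sum(theta)
  out <- c(f, params$w * theta) / denom
  names(out) <- c(sort(as.vector(outer(.NUC, .NUC, paste0))),
                  paste0("theta", seq_len(lambda)))
  out
}
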