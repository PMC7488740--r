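#' Encoder configuration
#'
#' Bundles the parameters of the five encoder families. The defaults
#' reproduce the published 292-dimensional space for 41-nt windows:
#' OHB (4L = 164), SNF (L = 41), KNF with k in {1,2} (20), KSNPF with
#' k in {1,2,3} (48) and PseDNC with lambda = 3 (19).
#'
#' @param window_length window length L, default 41.
#' @param knf_k k-mer sizes for KNF, default `c(1, 2)`.
#' @param ksnpf_k spacer sizes for KSNPF, default `1:3`.
#' @param psednc a [psednc_params] object.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(window_length = 41L, knf_k = c(1L, 2L),
                           ksnpf_k = 1:3, psednc = psednc_params()) {
  structure(list(window_length = as.integer(window_length),
                 knf_k = sort(as.integer(knf_k)),
                 ksnpf_k = sort(as.integer(ksnpf_k)),
                 psednc = psednc),
            class = "encoder_config")
}

#' Feature-space layout
#'
#' Describes which dimensions belong to which encoder family. Blocks are
#' contiguous, non-overlapping, and cover `1..total_dim`; with the default
#' configuration the blocks are D1-D164 (OHB), D165-D205 (SNF), D206-D225
#' (KNF), D226-D273 (KSNPF) and D274-D292 (PseDNC).
#'
#' @param config an [encoder_config].
#' @return A `feature_layout`: data frame with columns `family`, `start`,
#'   `end`, plus attributes `total_dim` and `descriptors` (per-dimension
#'   names).
#' @export
feature_layout <- function(config = encoder_config()) {
  L <- config$window_length
  widths <- c(
    OHB    = 4L * L,
    SNF    = L,
    KNF    = sum(4L^config$knf_k),
    KSNPF  = 16L * length(config$ksnpf_k),
    PseDNC = 16L + config$psednc$lambda
  )
  end <- cumsum(widths)
  start <- end - widths + 1L
  desc <- c(
    paste0("OHB_pos", rep(seq_len(L), each = 4L), "_", rep(c("A","G","T","C"), L)),
    paste0("SNF_pos", seq_len(L)),
    paste0("KNF_", unlist(lapply(config$knf_k, kmer_names))),
    paste0("KSNPF_", unlist(lapply(config$ksnpf_k, function(kk)
      paste0(rep(.NUC, each = 4L), strrep("x", kk), rep(.NUC, 4L))))),
    paste0("PseDNC_", c(sort(as.vector(outer(.NUC, .NUC, paste0))),
                        paste0("theta", seq_len(config$psednc$lambda))))
  )
  out <- data.frame(family = names(widths), start = start, end = end,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total_dim") <- unname(end[length(end)])
  attr(out, "descriptors") <- desc
  class(out) <- c("feature_layout", "data.frame")
  out
}

#' Encode DNA windows into the full feature space
#'
#' Concatenates the five encoder families in the fixed order OHB, SNF, KNF,
#' KSNPF, PseDNC; with defaults this yields 292 dimensions per 41-nt window.
#'
#' @param x a [sample_set], or a character vector of equal-length DNA strings.
#' @param config an [encoder_config].
#' @return Numeric matrix, samples x dimensions, with column names
#'   `D1..D<total>`, row names the sample ids, and attributes `layout`
#'   (a [feature_layout]) and `label` (integer vector, `NA` if unlabeled).
#' @export
encode_all <- function(x, config = encoder_config()) {
  if (inherits(x, "sample_set")) {
    sequences <- x$sequence; ids <- x$id; labels <- x$label
    stopifnot(attr(x, "window_length") == config$window_length)
  } else {
    sequences <- toupper(as.character(x))
    ids <- if (!is.null(names(x))) names(x) else paste0("s", seq_along(sequences))
    labels <- rep(NA_integer_, length(sequences))
  }
  layout <- feature_layout(config)
  p <- attr(layout, "total_dim")
  m <- matrix(NA_real_, length(sequences), p,
              dimnames = list(ids, paste0("D", seq_len(p))))
  for (i in seq_along(sequences)) {
    m[i, ] <- c(encode_ohb(sequences[i]),
                encode_snf(sequences[i]),
                encode_knf(sequences[i], config$knf_k),
                encode_ksnpf(sequences[i], config$ksnpf_k),
                encode_psednc(sequences[i], config$psednc))
  }
  attr(m, "layout") <- layout
  attr(m, "label") <- as.integer(labels)
  m
}

#' Write / read an encoded feature table
#'
#' The on-disk format is TSV with columns `id`, `label`, `D1..Dp`; the
#' layout is written alongside as `<path>.layout.tsv` (dimension, family,
#' descriptor).
#'
#' @param m matrix produced by [encode_all()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(m, path) {
  df <- data.frame(id = rownames(m), label = attr(m, "label"),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  layout <- attr(m, "layout")
  if (!is.null(layout)) {
    fam <- rep(layout$family, layout$end - layout$start + 1L)
    ldf <- data.frame(dimension = paste0("D", seq_along(fam)), family = fam,
                      descriptor = attr(layout, "descriptors"))
    utils::write.table(ldf, paste0(path, ".layout.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$id
  attr(m, "label") <- as.integer(df$label)
  m
}
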