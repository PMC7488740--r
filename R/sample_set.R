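#' Construct a set of fixed-length DNA windows
#'
#' A `sample_set` is the package's basic container: a data frame with one row
#' per DNA window and columns `id`, `sequence` and `label`, plus a
#' `window_length` attribute shared by all rows. Candidate 4mC windows are
#' cytosine-centred: position `(L + 1) / 2` (1-based) must hold `C`.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of DNA strings over `{A,C,G,T}`
#'   (lowercase is up-cased silently), all of length `window_length`.
#' @param label optional binary label per record (`1` = 4mC, `0` = non-4mC);
#'   `NA` for unlabeled windows.
#' @param window_length expected window length, default 41.
#' @param centre_c if `TRUE` (default), require `C` at the centre position.
#'
#' @return An object of class `sample_set`.
#' @export
#' @examples
#' s <- sample_set("w1", paste0(strrep("A", 20), "C", strrep("T", 20)))
sample_set <- function(id, sequence, label = NA_integer_, window_length = 41L,
                       centre_c = TRUE) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  label <- as.integer(label)
  if (length(label) == 1L) label <- rep(label, length(sequence))
  stopifnot(length(id) == length(sequence), length(label) == length(sequence))
  if (anyDuplicated(id))
    stop("duplicate sample ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  validate_sequences(sequence, id, window_length, centre_c = centre_c)
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "window_length") <- as.integer(window_length)
  class(out) <- c("sample_set", "data.frame")
  out
}

# Hard validation used by every constructor/reader. Names the first offending
# record so users can locate it in their FASTA.
validate_sequences <- function(sequence, id, window_length, centre_c = TRUE) {
  bad_len <- nchar(sequence) != window_length
  if (any(bad_len))
    stop("record '", id[which(bad_len)[1L]], "' has length ",
         nchar(sequence[which(bad_len)[1L]]), ", expected ", window_length)
  bad_chr <- grepl("[^ACGT]", sequence)
  if (any(bad_chr))
    stop("record '", id[which(bad_chr)[1L]],
         "' contains a non-ACGT character; ambiguity codes are not supported")
  if (centre_c && window_length %% 2L == 1L) {
    centre <- (window_length + 1L) %/% 2L
    bad_c <- substr(sequence, centre, centre) != "C"
    if (any(bad_c))
      stop("record '", id[which(bad_c)[1L]], "' does not have C at centre position ",
           centre)
  }
  invisible(TRUE)
}

#' Combine sample sets
#'
#' Row-binds sample sets sharing a window length; ids must stay unique.
#'
#' @param ... `sample_set` objects.
#' @param deparse.level unused (base signature).
#' @return A [sample_set].
#' @method rbind sample_set
#' @export
rbind.sample_set <- function(..., deparse.level = 1) {
  sets <- list(...)
  wl <- unique(vapply(sets, function(s) attr(s, "window_length"), integer(1L)))
  if (length(wl) != 1L) stop("window lengths differ: ", paste(wl, collapse = ", "))
  sample_set(unlist(lapply(sets, `[[`, "id")),
             unlist(lapply(sets, `[[`, "sequence")),
             unlist(lapply(sets, `[[`, "label")),
             window_length = wl, centre_c = FALSE)
}

#' @export
print.sample_set <- function(x, ...) {
  n_lab <- sum(!is.na(x$label))
  cat("<sample_set> ", nrow(x), " windows of length ",
      attr(x, "window_length"), "; ", sum(x$label == 1L, na.rm = TRUE),
      " positive / ", sum(x$label == 0L, na.rm = TRUE), " negative / ",
      nrow(x) - n_lab, " unlabeled\n", sep = "")
  invisible(x)
}

#' Read fixed-length DNA windows from a FASTA file
#'
#' Positive and negative benchmark windows are distributed as two separate
#' FASTA files, so the label is supplied by the caller rather than parsed from
#' headers. Sequences are up-cased and validated: wrong length, non-ACGT
#' characters or (for candidate 4mC windows) a non-C centre base raise an
#' error naming the offending record.
#'
#' @param path path to a FASTA file (wrapped or single-line records).
#' @param label optional binary label attached to every record (1 = 4mC).
#' @param window_length expected window length, default 41.
#' @param centre_c require a C at the centre position (default `TRUE`).
#' @param on_invalid `"error"` (default) stops at the first invalid record;
#'   `"skip"` drops invalid records with a warning.
#'
#' @return A [sample_set].
#' @export
read_fasta <- function(path, label = NA_integer_, window_length = 41L,
                       centre_c = TRUE, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  id <- sub("\\s.*$", "", names(recs))
  sequence <- toupper(as.character(recs))
  if (on_invalid == "skip") {
    centre <- (window_length + 1L) %/% 2L
    keep <- nchar(sequence) == window_length & !grepl("[^ACGT]", sequence)
    if (centre_c && window_length %% 2L == 1L)
      keep <- keep & substr(sequence, centre, centre) == "C"
    if (!all(keep))
      warning(sum(!keep), " invalid record(s) skipped: ",
              paste(utils::head(id[!keep], 5L), collapse = ", "))
    id <- id[keep]; sequence <- sequence[keep]
  }
  sample_set(id, sequence, label = label, window_length = window_length,
             centre_c = centre_c)
}

#' Write a sample set to FASTA
#'
#' @param x a [sample_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "sample_set"))
  writeLines(paste0(">", x$id, "\n", x$sequence), path)
  invisible(path)
}

#' Extract cytosine-centred windows from a long DNA sequence
#'
#' Scans the forward strand of `sequence` and emits one unlabeled window per
#' cytosine that has enough flanking context on both sides; cytosines closer
#' than `(window_length - 1) / 2` to either end are skipped (no padding).
#' Window ids are `<id_prefix>_pos<p>` with `p` the 1-based position of the
#' centre cytosine in the source sequence.
#'
#' @param sequence a single DNA string over `{A,C,G,T}`.
#' @param window_length odd window size, default 41.
#' @param id_prefix prefix for generated window ids.
#' @return A [sample_set] of unlabeled candidate windows (possibly empty).
#' @export
extract_windows <- function(sequence, window_length = 41L, id_prefix = "query") {
  if (window_length %% 2L != 1L)
    stop("window_length must be odd, got ", window_length)
  sequence <- toupper(sequence)
  stopifnot(length(sequence) == 1L)
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains a non-ACGT character")
  len <- nchar(sequence)
  flank <- (window_length - 1L) %/% 2L
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  centres <- which(chars == "C")
  centres <- centres[centres > flank & centres <= len - flank]
  if (length(centres) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      label = integer(), stringsAsFactors = FALSE)
    attr(out, "window_length") <- as.integer(window_length)
    class(out) <- c("sample_set", "data.frame")
    return(out)
  }
  windows <- substring(sequence, centres - flank, centres + flank)
  sample_set(paste0(id_prefix, "_pos", centres), windows,
             label = NA_integer_, window_length = window_length)
}
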