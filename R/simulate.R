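#' Position-specific motif model for synthetic 4mC windows
#'
#' Positives are drawn from per-position nucleotide distributions that
#' interpolate between a background composition and a motif target:
#' `weights = (1 - effect) * background + effect * target`. By default five
#' positions flanking the centre carry a consensus base at full target
#' weight, loosely imitating the position-specific enrichment seen around
#' genuine 4mC sites; all other positions are background. The centre
#' position is forced to `C` for both classes.
#'
#' @param window_length odd window length, default 41.
#' @param background length-4 probability vector over (A,C,G,T), default
#'   uniform.
#' @param motif_offsets positions of the motif relative to the centre
#'   (default `c(-3, -2, -1, 1, 2)`).
#' @param consensus consensus bases at the motif offsets (recycled),
#'   default `c("G", "A", "G", "G", "T")`.
#' @param effect_strength interpolation weight in `[0, 1]`; 0 makes
#'   positives indistinguishable from background, 1 makes the motif
#'   positions deterministic. Default 0.8 (a strong motif).
#' @return A `motif_model`: list with `position_weights` (L x 4 matrix of
#'   per-position probabilities for the positive class), `background`, and
#'   `effect_strength`.
#' @export
motif_model <- function(window_length = 41L, background = rep(0.25, 4),
                        motif_offsets = c(-3L, -2L, -1L, 1L, 2L),
                        consensus = c("G", "A", "G", "G", "T"),
                        effect_strength = 0.8) {
  stopifnot(window_length %% 2L == 1L, length(background) == 4L,
            effect_strength >= 0, effect_strength <= 1)
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (any(background < 0)) stop("background probabilities must be >= 0")
  centre <- (window_length + 1L) %/% 2L
  pos <- centre + as.integer(motif_offsets)
  if (any(pos < 1L | pos > window_length | pos == centre))
    stop("motif offsets must stay inside the window and avoid the centre")
  consensus <- rep_len(match(toupper(consensus), .NUC), length(pos))
  if (anyNA(consensus)) stop("consensus must be A/C/G/T")
  W <- matrix(background, window_length, 4L, byrow = TRUE,
              dimnames = list(NULL, .NUC))
  for (i in seq_along(pos)) {
    target <- numeric(4L); target[consensus[i]] <- 1
    W[pos[i], ] <- (1 - effect_strength) * background + effect_strength * target
  }
  W[centre, ] <- c(0, 1, 0, 0)  # centre cytosine, both classes
  structure(list(position_weights = W, background = background,
                 effect_strength = effect_strength,
                 window_length = as.integer(window_length)),
            class = "motif_model")
}

#' Generate a labeled synthetic window set
#'
#' Positives are sampled column-wise from the motif model's per-position
#' distributions; negatives from the background composition at every
#' position. Both classes have `C` forced at the centre, so every generated
#' window is a valid candidate 4mC site.
#'
#' @param n_pos,n_neg numbers of positive and negative windows.
#' @param motif a [motif_model].
#' @param seed RNG seed.
#' @param id_prefix prefix for the generated ids (use distinct prefixes for
#'   train and test sets so [independent_test()] sees disjoint ids).
#' @return A labeled [sample_set] (positives first, ids
#'   `<prefix>pos_1..`/`<prefix>neg_1..`).
#' @export
generate <- function(n_pos, n_neg, motif = motif_model(), seed = 42L,
                     id_prefix = "") {
  stopifnot(n_pos >= 0L, n_neg >= 0L, n_pos + n_neg > 0L)
  L <- motif$window_length
  centre <- (L + 1L) %/% 2L
  with_seed(seed, {
    draw <- function(n, weights_fun) {
      m <- matrix("", n, L)
      for (j in seq_len(L))
        m[, j] <- sample(.NUC, n, replace = TRUE, prob = weights_fun(j))
      m[, centre] <- "C"
      apply(m, 1L, paste, collapse = "")
    }
    pos <- if (n_pos > 0L) draw(n_pos, function(j) motif$position_weights[j, ]) else character()
    neg <- if (n_neg > 0L) draw(n_neg, function(j) motif$background) else character()
  })
  sample_set(c(if (n_pos > 0L) paste0(id_prefix, "pos_", seq_len(n_pos)),
               if (n_neg > 0L) paste0(id_prefix, "neg_", seq_len(n_neg))),
             c(pos, neg),
             label = c(rep(1L, n_pos), rep(0L, n_neg)),
             window_length = L)
}

#' Generate a labeled synthetic feature table
#'
#' A direct fixture for selection and classifier tests that bypasses the
#' sequence encoders: informative dimensions are Gaussian with a
#' class-conditional mean shift of `effect` (in within-class standard
#' deviations, sd = 1); noise dimensions are standard normal in both
#' classes. Classes are balanced, positives first.
#'
#' @param n total number of samples (even, split 50/50).
#' @param n_informative number of informative dimensions (placed first).
#' @param n_noise number of pure-noise dimensions.
#' @param effect class-conditional mean shift of the informative dimensions.
#' @param seed RNG seed.
#' @return Numeric matrix `n x (n_informative + n_noise)` with columns
#'   `D1..Dp`, a `label` attribute, and an `informative` attribute holding
#'   the informative column indices.
#' @export
generate_feature_table <- function(n, n_informative, n_noise, effect,
                                   seed = 42L) {
  stopifnot(n >= 4L, n %% 2L == 0L, n_informative >= 0L, n_noise >= 0L,
            n_informative + n_noise >= 1L)
  p <- n_informative + n_noise
  y <- rep(c(1L, 0L), each = n %/% 2L)
  x <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * p), n, p)
    if (n_informative > 0L) {
      shift <- ifelse(y == 1L, effect / 2, -effect / 2)
      m[, seq_len(n_informative)] <- m[, seq_len(n_informative)] + shift
    }
    m
  })
  dimnames(x) <- list(c(paste0("pos_", seq_len(n %/% 2L)),
                        paste0("neg_", seq_len(n %/% 2L))),
                      paste0("D", seq_len(p)))
  attr(x, "label") <- y
  attr(x, "informative") <- seq_len(n_informative)
  x
}
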