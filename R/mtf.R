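## ---- Markov Transition Field imaging of EEG windows ------------------------

#' MTF imaging parameters
#'
#' @param n_bins Number of amplitude quantile bins (default 32).
#' @param image_mode Field construction; only `"full_pairwise"` (the standard
#'   Markov Transition Field, pixel (i, j) = transition probability between
#'   the quantile bins of samples i and j) is implemented.
#' @param output_size Side length of the resized classifier input
#'   (default 224).
#' @param grayscale Single-channel output flag (default `TRUE`).
#' @return An object of class `mtf_params`.
#' @export
mtf_params <- function(n_bins = 32L, image_mode = "full_pairwise",
                       output_size = 224L, grayscale = TRUE) {
  if (n_bins < 2) sl_stop("n_bins must be >= 2", "spikeloop_invalid_configuration")
  if (output_size < n_bins) {
    sl_stop("output_size must be >= n_bins", "spikeloop_invalid_configuration")
  }
  image_mode <- match.arg(image_mode, "full_pairwise")
  structure(list(n_bins = as.integer(n_bins), image_mode = image_mode,
                 output_size = as.integer(output_size), grayscale = grayscale),
            class = "mtf_params")
}

#' Quantile-discretize a window's amplitudes
#'
#' Maps each value to one of `n_bins` equal-occupancy amplitude bins defined
#' by the empirical quantiles of this window (right-closed bins, ties share
#' the bin of their largest rank). With `n` distinct values the occupancies
#' differ by at most one; a constant window collapses to a single occupied
#' bin.
#'
#' @param values Numeric window values (non-empty).
#' @param n_bins Number of bins (>= 2).
#' @return Integer bin indices in `1..n_bins`, monotone in the values.
#' @export
quantile_bins <- function(values, n_bins = 32L) {
  if (length(values) == 0) {
    sl_stop("values must be non-empty", "spikeloop_invalid_configuration")
  }
  if (n_bins < 2) sl_stop("n_bins must be >= 2", "spikeloop_invalid_configuration")
  r <- rank(values, ties.method = "max")
  pmin(as.integer(ceiling(r * n_bins / length(values))), as.integer(n_bins))
}

#' First-order transition matrix of a bin sequence
#'
#' `W[a, b]` is the count of consecutive pairs `a -> b` divided by the total
#' number of transitions leaving `a`; rows with at least one outgoing
#' transition sum to 1, rows with none are all zero.
#'
#' @param bins Integer bin indices in `1..n_bins`, length >= 2.
#' @param n_bins Number of bins.
#' @return `n_bins` x `n_bins` row-stochastic (or zero-row) matrix.
#' @export
transition_matrix <- function(bins, n_bins) {
  stopifnot(length(bins) >= 2)
  from <- bins[-length(bins)]
  to <- bins[-1]
  W <- matrix(0, n_bins, n_bins)
  counts <- tabulate(from + (to - 1L) * n_bins, nbins = n_bins * n_bins)
  W[] <- counts
  rs <- rowSums(W)
  nz <- rs > 0
  W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  W
}

#' Markov Transition Field image of one window
#'
#' Encodes a window as the full pairwise field `M[i, j] = W[q_i, q_j]` where
#' `q_i` is the amplitude-quantile bin of sample `i` and `W` the window's
#' bin-transition matrix. Every entry is a transition probability in
#' `[0, 1]`; the image side equals the window length.
#'
#' @param window A window frame (list with `values`, optionally
#'   `start_index`) or a bare numeric vector.
#' @param params An [mtf_params()].
#' @return Object of class `mtf_image`: list with `matrix` (window_len x
#'   window_len) and `source_window` (the start index, if known).
#' @export
mtf_image <- function(window, params = mtf_params()) {
  values <- if (is.list(window)) window$values else window
  bins <- quantile_bins(values, params$n_bins)
  W <- transition_matrix(bins, params$n_bins)
  structure(list(matrix = W[bins, bins],
                 source_window = if (is.list(window)) window$start_index else NA),
            class = "mtf_image")
}

## bilinear interpolation matrix (n_out x n_in), pixel-center convention;
## rows are convex weights so probability bounds survive resizing
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pos <- pmin(pmax(pos, 1), n_in)
  lo <- floor(pos)
  hi <- pmin(lo + 1, n_in)
  w <- pos - lo
  for (i in seq_len(n_out)) {
    A[i, lo[i]] <- A[i, lo[i]] + (1 - w[i])
    A[i, hi[i]] <- A[i, hi[i]] + w[i]
  }
  A
}

#' Resize an MTF image to the classifier input geometry
#'
#' Bilinear separable resize to `output_size` x `output_size`, single
#' (grayscale) channel. The entries are transition probabilities and bilinear
#' weights are convex, so values remain in `[0, 1]`.
#'
#' @param image An `mtf_image` (or bare square matrix).
#' @param params An [mtf_params()].
#' @return `output_size` x `output_size` numeric matrix in `[0, 1]`.
#' @export
to_classifier_input <- function(image, params = mtf_params()) {
  M <- if (inherits(image, "mtf_image")) image$matrix else image
  if (nrow(M) != ncol(M)) sl_stop("MTF image must be square", "spikeloop_input")
  s <- params$output_size
  if (s == nrow(M)) return(pmin(pmax(M, 0), 1))
  A <- bilinear_matrix(s, nrow(M))
  out <- A %*% M %*% t(A)
  pmin(pmax(out, 0), 1)
}

#' Batch MTF featurization of a window set
#'
#' Computes, for each selected window, the resized grayscale MTF image that
#' [to_classifier_input()] would produce, without materializing the
#' intermediate window_len x window_len field: with `E` the one-hot bin
#' indicator the resized field `A (E W t(E)) t(A)` equals `(A E) W t(A E)`,
#' which is assembled per window in `O(n_bins^2)`.
#'
#' @param windows A `window_set`.
#' @param params An [mtf_params()].
#' @param which Indices of windows to featurize (default all).
#' @return Matrix of `length(which)` rows, each a flattened (column-major)
#'   `output_size^2` image.
#' @export
mtf_features <- function(windows, params = mtf_params(), which = NULL) {
  which <- which %||% seq_along(windows$starts)
  L <- nrow(windows$values)
  s <- params$output_size
  A <- bilinear_matrix(s, L)
  out <- matrix(0, length(which), s * s)
  for (k in seq_along(which)) {
    v <- windows$values[, which[k]]
    bins <- quantile_bins(v, params$n_bins)
    W <- transition_matrix(bins, params$n_bins)
    B <- t(rowsum(t(A), group = bins))            # s x n_occupied
    occ <- sort(unique(bins))
    img <- B %*% W[occ, occ, drop = FALSE] %*% t(B)
    out[k, ] <- as.numeric(img)
  }
  pmin(pmax(out, 0), 1)
}

#' Export an MTF image as an 8-bit grayscale PNG
#'
#' @param image An `mtf_image` or numeric matrix in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mtf_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    sl_stop("the png package is required for PNG export", "spikeloop_io")
  }
  M <- if (inherits(image, "mtf_image")) image$matrix else image
  png::writePNG(pmin(pmax(M, 0), 1), path)
  invisible(path)
}
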