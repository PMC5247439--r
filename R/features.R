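SWF_STATS <- c("Er", "m", "std", "k", "sk", "e")
BANDS4 <- c("A4", "D4", "D3", "D2", "D1")

## Statistical moments on a coefficient vector. Conventions: std uses the
## n-1 denominator; skewness and kurtosis are the population-standardised
## third and fourth moments (normal -> kurtosis 3), without bias
## correction; a zero-variance band yields k = sk = 0.
swf_stat <- function(coeffs, stat, er) {
  switch(stat,
    Er = er,
    m = mean(coeffs),
    std = if (length(coeffs) > 1) sd(coeffs) else 0,
    k = {
      m2 <- mean((coeffs - mean(coeffs))^2)
      if (m2 == 0) 0 else mean((coeffs - mean(coeffs))^4) / m2^2
    },
    sk = {
      m2 <- mean((coeffs - mean(coeffs))^2)
      if (m2 == 0) 0 else mean((coeffs - mean(coeffs))^3) / m2^1.5
    },
    e = {
      p <- coeffs^2
      if (sum(p) == 0) 0 else {
        p <- p / sum(p)
        p <- p[p > 0]
        -sum(p * log2(p))
      }
    },
    stop("unknown statistic: ", stat, call. = FALSE))
}

#' Statistical wavelet features of one epoch
#'
#' For every requested (channel, band) pair, computes the requested
#' statistics of that band's coefficients: relative energy `Er`
#' (normalised over all five bands of the channel's decomposition, so it
#' is invariant to which bands are selected), mean `m`, standard
#' deviation `std` (n-1), kurtosis `k`, skewness `sk`, and wavelet
#' energy entropy `e` (Shannon entropy, base 2, of the band's normalised
#' squared coefficients, with 0 log 0 = 0). The full configuration (3
#' channels x 5 bands x 6 statistics) yields 90 values.
#'
#' @param decomp an `epoch_decomposition` (see [decompose_epochs()]).
#' @param bands bands to use, subset of `A4, D4, D3, D2, D1`.
#' @param channels channels to use, subset of `Fz, Pz, Cz`.
#' @param statistics statistics to compute, subset of
#'   `Er, m, std, k, sk, e`.
#' @return named numeric vector, names `channel.band.statistic`
#'   (e.g. `Fz.A4.Er`), in deterministic (channel, band, statistic)
#'   order.
#' @export
extract_swf <- function(decomp, bands = BANDS4, channels = CHANNELS,
                        statistics = SWF_STATS) {
  stopifnot(inherits(decomp, "epoch_decomposition"))
  channels <- match_channels(channels)
  bad <- setdiff(bands, names(decomp[[1]]))
  if (length(bad)) stop("unknown band(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(statistics, SWF_STATS)
  if (length(bad)) stop("unknown statistic(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- numeric(0)
  for (ch in channels) {
    er <- band_energies(decomp[[ch]])$relative
    for (b in bands) {
      coeffs <- decomp[[ch]][[b]]
      for (s in statistics) {
        v <- swf_stat(coeffs, s, er[[b]])
        names(v) <- paste(ch, b, s, sep = ".")
        out <- c(out, v)
      }
    }
  }
  out
}

#' Threshold wavelet coefficients by relative magnitude
#'
#' Zeroes every coefficient whose magnitude, normalised by the block's
#' maximum absolute value, falls strictly below `epsilon` (the wavelet
#' compression rule); `epsilon = 0` is the identity and `epsilon = 1`
#' keeps only the maximal-magnitude coefficient(s). Thresholding zeroes
#' in place, never shortens, so downstream feature dimensions are
#' unaffected. `normalize = FALSE` compares raw magnitudes to `epsilon`
#' instead.
#'
#' @param coeffs numeric vector (one channel-band block).
#' @param epsilon threshold, >= 0.
#' @param normalize divide magnitudes by `max(abs(coeffs))` before
#'   comparing (default).
#' @return vector of the same length with sub-threshold entries zeroed;
#'   attribute `zeroed_count` gives how many were zeroed.
#' @examples
#' threshold_coefficients(c(1, 0.4, 0.05, 0.005), 0.1)  # zeroes the last two
#' @export
threshold_coefficients <- function(coeffs, epsilon, normalize = TRUE) {
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  if (epsilon == 0 || length(coeffs) == 0)
    return(structure(coeffs, zeroed_count = 0L))
  mags <- abs(coeffs)
  ref <- if (normalize && max(mags) > 0) mags / max(mags) else mags
  zero <- ref < epsilon
  coeffs[zero] <- 0
  structure(coeffs, zeroed_count = sum(zero))
}

#' Wavelet-coefficient features of one epoch
#'
#' Concatenates the selected bands' raw coefficients per channel in
#' fixed (channel, band, index) order, optionally thresholding each
#' channel-band block with [threshold_coefficients()] first. With a
#' single band (A4 or D4), 3 channels and 144-sample epochs this yields
#' 27 coefficients (nine per channel); the length does not depend on
#' `epsilon`.
#'
#' @inheritParams extract_swf
#' @param epsilon magnitude threshold (0 = no thresholding, the
#'   without-thresholding variant).
#' @param normalize passed to [threshold_coefficients()].
#' @return named numeric vector (`channel.band.c<index>`); attribute
#'   `zeroed_count` totals the zeroed coefficients.
#' @export
extract_wcf <- function(decomp, bands = c("A4", "D4"), channels = CHANNELS,
                        epsilon = 0, normalize = TRUE) {
  stopifnot(inherits(decomp, "epoch_decomposition"))
  channels <- match_channels(channels)
  bad <- setdiff(bands, names(decomp[[1]]))
  if (length(bad)) stop("unknown band(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- numeric(0)
  zeroed <- 0L
  for (ch in channels) {
    for (b in bands) {
      coeffs <- threshold_coefficients(decomp[[ch]][[b]], epsilon, normalize)
      zeroed <- zeroed + attr(coeffs, "zeroed_count")
      v <- as.numeric(coeffs)
      names(v) <- paste0(ch, ".", b, ".c", seq_along(v))
      out <- c(out, v)
    }
  }
  structure(out, zeroed_count = zeroed)
}

#' Build a labelled trial-by-feature matrix
#'
#' Decomposes every epoch ([decompose_epochs()]) and extracts one
#' feature vector per trial with either descriptor, assembling a data
#' frame whose feature columns come first (stable, order-deterministic
#' names) followed by the label columns `subject_id`, `group`,
#' `content`, `trial_id`.
#'
#' @param epochs an [epoch_set()]; all epochs share geometry by
#'   construction.
#' @param descriptor `"swf"` (statistical wavelet features) or `"wcf"`
#'   (raw coefficients).
#' @param bands,channels,statistics configuration passed to
#'   [extract_swf()] / [extract_wcf()] (statistics apply to SWF only).
#' @param epsilon,normalize WCF thresholding (ignored for SWF).
#' @param J,n_keep decomposition depth and per-epoch samples kept.
#' @return data frame of class `feature_matrix` with attribute
#'   `feature_names`.
#' @examples
#' ep <- simulate_epochs(sim_params(n_subjects_per_group = 2,
#'                                  trials_per_subject = 10, seed = 3))
#' fm <- build_feature_matrix(ep, "swf", bands = c("A4", "D4"),
#'                            statistics = c("Er", "std"))
#' dim(fm)  # trials x (12 features + 4 label columns)
#' @export
build_feature_matrix <- function(epochs, descriptor = c("swf", "wcf"),
                                 bands = c("A4", "D4"), channels = CHANNELS,
                                 statistics = c("Er", "std"),
                                 epsilon = 0, normalize = TRUE,
                                 J = 4, n_keep = 144) {
  descriptor <- match.arg(descriptor)
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_epochs(epochs) == 0L) {
    fm <- data.frame(subject_id = character(), group = character(),
                     content = character(), trial_id = integer())
    attr(fm, "feature_names") <- character()
    class(fm) <- c("feature_matrix", "data.frame")
    return(fm)
  }
  decomps <- decompose_epochs(epochs, J = J, n_keep = n_keep)
  feature_matrix_from_decomps(decomps, epochs$info, descriptor, bands,
                              channels, statistics, epsilon, normalize)
}

## Shared by build_feature_matrix and combination_search (which reuses
## precomputed decompositions across configurations).
feature_matrix_from_decomps <- function(decomps, info, descriptor, bands,
                                        channels, statistics, epsilon = 0,
                                        normalize = TRUE) {
  rows <- lapply(decomps, function(d) {
    if (descriptor == "swf")
      extract_swf(d, bands, channels, statistics)
    else
      extract_wcf(d, bands, channels, epsilon, normalize)
  })
  feats <- do.call(rbind, rows)
  fm <- as.data.frame(feats)
  fm$subject_id <- info$subject_id
  fm$group <- info$group
  fm$content <- info$content
  fm$trial_id <- info$trial_id
  attr(fm, "feature_names") <- colnames(feats)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Feature column names of a feature matrix
#' @param fm a `feature_matrix`.
#' @return character vector of feature column names.
#' @export
feature_names <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  attr(fm, "feature_names")
}

feature_values <- function(fm) {
  as.matrix(fm[, feature_names(fm), drop = FALSE])
}
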