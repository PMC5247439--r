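## Level-J Haar discrete wavelet transform.
##
## Analysis convention: at each level the k-th approximation/detail
## output is formed from the non-overlapping input pair (x[2k-1], x[2k]):
##   a_k = (x[2k-1] + x[2k]) / sqrt(2)   (low-pass h  = (1, 1)/sqrt(2))
##   d_k = (x[2k-1] - x[2k]) / sqrt(2)   (high-pass g = (1,-1)/sqrt(2))
## For Haar this equals periodized convolution with stride 2; it is
## padding-free and exactly orthonormal, so Parseval holds to machine
## precision and the transform is matrix-verifiable.

#' The orthonormal Haar analysis filter pair
#'
#' @return list with low-pass taps `h = (1, 1)/sqrt(2)` and high-pass
#'   taps `g = (1, -1)/sqrt(2)`.
#' @export
haar_filters <- function() {
  list(h = c(1, 1) / sqrt(2), g = c(1, -1) / sqrt(2))
}

#' Level-J Haar discrete wavelet transform
#'
#' Iterated filter-and-decimate pyramid with the orthonormal Haar pair.
#' The signal length must be divisible by `2^J` (epochs are truncated to
#' 144 samples upstream for `J = 4`; see [decompose_epochs()]). Total
#' coefficient energy equals input energy (Parseval) and
#' [haar_idwt()] reconstructs the input exactly.
#'
#' @param signal numeric vector (uV), length a positive multiple of `2^J`.
#' @param J decomposition depth (default 4, so the approximation band A4
#'   covers the lowest 1/16 of the represented frequency range).
#' @return object of class `haar_dwt`: a named list of coefficient
#'   vectors `A{J}, D{J}, ..., D1` with attributes `J` and `n_input`.
#' @examples
#' d <- haar_dwt(sin(2 * pi * (0:143) / 48), J = 4)
#' lengths(unclass(d))  # A4 9, D4 9, D3 18, D2 36, D1 72
#' @export
haar_dwt <- function(signal, J = 4) {
  J <- stopifnot_scalar_count(J, "J", 1L)
  n <- length(signal)
  if (n < 2^J)
    stop(sprintf("signal length %d is shorter than 2^J = %d", n, 2^J),
         call. = FALSE)
  if (n %% 2^J != 0)
    stop(sprintf("signal length %d is not divisible by 2^J = %d", n, 2^J),
         call. = FALSE)
  a <- as.numeric(signal)
  details <- vector("list", J)
  for (j in seq_len(J)) {
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  out <- c(list(a), rev(details))
  names(out) <- c(paste0("A", J), paste0("D", J:1))
  structure(out, J = J, n_input = n, class = "haar_dwt")
}

#' Inverse level-J Haar transform
#'
#' Exact inverse of [haar_dwt()]: `haar_idwt(haar_dwt(x))` returns `x`
#' up to machine precision.
#'
#' @param decomp a `haar_dwt` object (band lengths must be consistent).
#' @return numeric vector of length `n_input`.
#' @export
haar_idwt <- function(decomp) {
  stopifnot(inherits(decomp, "haar_dwt"))
  J <- attr(decomp, "J")
  a <- decomp[[paste0("A", J)]]
  for (j in J:1) {
    d <- decomp[[paste0("D", j)]]
    if (length(d) != length(a))
      stop(sprintf("inconsistent band lengths: |D%d| = %d but expected %d",
                   j, length(d), length(a)), call. = FALSE)
    x <- numeric(2 * length(a))
    x[seq(1, length(x), by = 2)] <- (a + d) / sqrt(2)
    x[seq(2, length(x), by = 2)] <- (a - d) / sqrt(2)
    a <- x
  }
  a
}

#' Dyadic band-frequency labels for a level-J decomposition
#'
#' Maps each band to its nominal frequency range under repeated halving
#' of a top frequency: `D1 = (f_top/2, f_top)`, `Dj = (f_top/2^j,
#' f_top/2^(j-1))`, `A_J = (0, f_top/2^J)`. With the conventional
#' `f_top = 30` Hz (the band-pass upper limit) and `J = 4` this yields
#' the delta-low band A4 = 0--1.875 Hz and delta-high D4 =
#' 1.875--3.75 Hz. The map is a labelling layer: it reflects the
#' filtered band's extent, not the Nyquist frequency of the raw sampling
#' rate, and `f_top` is configurable.
#'
#' @param f_top top frequency in Hz (> 0).
#' @param J decomposition depth (>= 1).
#' @return data frame with columns `band`, `low`, `high` (Hz); the bands
#'   tile `(0, f_top)` without overlap.
#' @examples
#' band_frequency_map(30, 4)
#' @export
band_frequency_map <- function(f_top = 30, J = 4) {
  J <- stopifnot_scalar_count(J, "J", 1L)
  if (f_top <= 0) stop("`f_top` must be positive", call. = FALSE)
  band <- c(paste0("A", J), paste0("D", J:1))
  low <- c(0, f_top / 2^(J:1))
  high <- c(f_top / 2^J, f_top / 2^((J:1) - 1))
  data.frame(band = band, low = low, high = high)
}

#' Band energies and relative energies of a decomposition
#'
#' Energy of a band is the sum of its squared coefficients; the relative
#' energy Er of a band is its energy divided by the total over all
#' `J + 1` bands (so the Er values sum to 1). By Parseval the total
#' equals the input signal energy.
#'
#' @param decomp a `haar_dwt` object with non-zero total energy.
#' @return list of class `band_energies`: `energy` (named vector, uV^2),
#'   `total`, `relative` (named vector summing to 1).
#' @export
band_energies <- function(decomp) {
  stopifnot(inherits(decomp, "haar_dwt"))
  e <- vapply(unclass(decomp), function(c) sum(c^2), numeric(1))
  total <- sum(e)
  if (total == 0)
    stop("all-zero decomposition: relative energy undefined", call. = FALSE)
  structure(list(energy = e, total = total, relative = e / total),
            class = "band_energies")
}

#' Decompose every epoch channel with the Haar DWT
#'
#' Truncates each epoch to its first `n_keep` samples (144 by default:
#' the largest multiple of `2^4` within a 150-sample 600 ms epoch, so A4
#' and D4 each carry 9 coefficients per channel) and decomposes each
#' channel to level `J`.
#'
#' @param epochs an [epoch_set()].
#' @param J decomposition depth.
#' @param n_keep samples kept per epoch before the transform; must be a
#'   multiple of `2^J` and no longer than the epoch.
#' @return list of per-epoch decompositions; each element is a named list
#'   of `haar_dwt` objects for channels Fz, Pz, Cz (class
#'   `epoch_decomposition`).
#' @export
decompose_epochs <- function(epochs, J = 4, n_keep = 144) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_s <- dim(epochs$data)[2]
  if (n_keep > n_s)
    stop(sprintf("n_keep = %d exceeds epoch length %d", n_keep, n_s),
         call. = FALSE)
  lapply(seq_len(n_epochs(epochs)), function(i) {
    d <- lapply(1:3, function(ch) haar_dwt(epochs$data[ch, 1:n_keep, i], J))
    names(d) <- CHANNELS
    class(d) <- "epoch_decomposition"
    d
  })
}
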