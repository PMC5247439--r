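## Shared fixtures and independent oracles, all built in code.

## Explicit orthonormal Haar analysis matrix (independent of the
## pyramid implementation): rows are the scaling functions at level J
## followed by the wavelets at levels J..1, in the same coefficient
## order the transform emits (A_J, D_J, ..., D_1).
haar_matrix <- function(n, J = 4) {
  stopifnot(n %% 2^J == 0)
  rows <- list()
  blk <- 2^J
  for (k in seq_len(n / blk)) {
    r <- numeric(n)
    r[((k - 1) * blk + 1):(k * blk)] <- 1 / sqrt(blk)
    rows[[length(rows) + 1L]] <- r
  }
  for (j in J:1) {
    blk <- 2^j
    for (k in seq_len(n / blk)) {
      r <- numeric(n)
      idx <- ((k - 1) * blk + 1):(k * blk)
      r[idx[1:(blk / 2)]] <- 1 / sqrt(blk)
      r[idx[(blk / 2 + 1):blk]] <- -1 / sqrt(blk)
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

## Brute-force AUC: concordant-pair counting with half credit for ties,
## LA as the positive class.
auc_pair_oracle <- function(x, y) {
  la <- x[y == "LA"]
  ha <- x[y == "HA"]
  s <- 0
  for (a in la) for (b in ha) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(la) * length(ha))
}

## Kruskal-Wallis H by manual midranks with tie correction.
kw_manual_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) -
    3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

## Analytic gain of the order-2 Butterworth band-pass as designed by the
## bilinear transform with prewarped edges (single forward pass).
butter_bp_gain <- function(f, low, high, fs, order = 2) {
  W <- function(fr) 2 * fs * tan(pi * fr / fs)
  w <- W(f)
  w0sq <- W(low) * W(high)
  B <- W(high) - W(low)
  x <- (w^2 - w0sq) / (B * w)
  1 / sqrt(1 + x^(2 * order))
}

## Small synthetic cohorts shared across tests.
tiny_params <- function(n_subj = 3, trials = 20, seed = 11, ...) {
  sim_params(n_subjects_per_group = n_subj, trials_per_subject = trials,
             artifact_rate = 0, seed = seed, ...)
}

tiny_feature_matrix <- function(n_subj = 3, trials = 20, seed = 11,
                                bands = c("A4", "D4"),
                                statistics = c("Er", "std"), ...) {
  ep <- simulate_epochs(tiny_params(n_subj, trials, seed, ...))
  ep <- ep[ep$info$stimulus == "target"]
  build_feature_matrix(ep, "swf", bands = bands, statistics = statistics)
}

## Trimmed hyperparameter grid so unit tests stay fast; acceptance runs
## use the full default grid.
fast_svm <- function(seed = 1) {
  svm_config(C_grid = 2^(0:4), gamma_grid = 2^seq(-8, -2, by = 2),
             seed = seed)
}

## Feature matrix straight from numeric data, for oracle tests.
fm_from_matrix <- function(X, groups, subject_id = NULL) {
  X <- as.matrix(X)
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  fm <- as.data.frame(X)
  fm$subject_id <- subject_id %||% paste0("S", seq_len(nrow(X)))
  fm$group <- groups
  fm$content <- "2D"
  fm$trial_id <- seq_len(nrow(X))
  attr(fm, "feature_names") <- colnames(X)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
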