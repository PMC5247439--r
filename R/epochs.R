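#' Construct a set of single-trial EEG epochs
#'
#' The container used throughout the pipeline: a 3 x samples x trials
#' array of microvolt values (channel order Fz, Pz, Cz) plus per-trial
#' metadata.
#'
#' @param data numeric array, `3 x n_samples x n_epochs` (channels Fz, Pz,
#'   Cz in that order), in microvolts.
#' @param info data frame with one row per epoch and columns `subject_id`,
#'   `group` (`"LA"`, `"HA"` or `"unknown"`), `content` (`"2D"`/`"3D"`),
#'   `trial_id` and optionally `stimulus` (`"target"`/`"standard"`).
#' @param fs sampling rate in Hz.
#' @param pre_ms,post_ms pre- and post-stimulus window bounds in ms; the
#'   stimulus-onset sample is the first post-stimulus sample.
#' @return an object of class `epoch_set`.
#' @examples
#' e <- epoch_set(array(0, c(3, 150, 2)),
#'                data.frame(subject_id = c("S1", "S1"),
#'                           group = "unknown", content = "2D",
#'                           trial_id = 1:2))
#' n_epochs(e)
#' @export
epoch_set <- function(data, info, fs = 250, pre_ms = 100, post_ms = 500) {
  if (length(dim(data)) != 3L || dim(data)[1] != 3L)
    stop("`data` must be a 3 x n_samples x n_epochs array (Fz, Pz, Cz rows)",
         call. = FALSE)
  n_expected <- round(fs * (pre_ms + post_ms) / 1000)
  if (dim(data)[2] != n_expected)
    stop(sprintf("epoch length %d does not match round(fs*(pre+post)/1000) = %d",
                 dim(data)[2], n_expected), call. = FALSE)
  info <- as.data.frame(info)
  req <- c("subject_id", "group", "content", "trial_id")
  miss <- setdiff(req, names(info))
  if (length(miss))
    stop("`info` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(info) != dim(data)[3])
    stop("`info` must have one row per epoch", call. = FALSE)
  if (is.null(info$stimulus)) info$stimulus <- "target"
  dimnames(data) <- list(CHANNELS, NULL, NULL)
  structure(list(data = data, info = info, fs = fs,
                 pre_ms = pre_ms, post_ms = post_ms),
            class = "epoch_set")
}

#' Number of epochs in an epoch set
#' @param x an `epoch_set`.
#' @return integer count of trials.
#' @export
n_epochs <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  dim(x$data)[3]
}

#' Subset an epoch set by trial
#' @param x an `epoch_set`.
#' @param i trial index vector (integer or logical).
#' @return an `epoch_set` containing the selected trials.
#' @export
`[.epoch_set` <- function(x, i) {
  epoch_set(x$data[, , i, drop = FALSE], x$info[i, , drop = FALSE],
            fs = x$fs, pre_ms = x$pre_ms, post_ms = x$post_ms)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x 3 channels x %d samples (fs = %g Hz, -%g..+%g ms)\n",
              n_epochs(x), dim(x$data)[2], x$fs, x$pre_ms, x$post_ms))
  cat(sprintf("  subjects: %d  groups: %s\n",
              length(unique(x$info$subject_id)),
              paste(names(table(x$info$group)), table(x$info$group),
                    sep = "=", collapse = " ")))
  invisible(x)
}

combine_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  fs <- sets[[1]]$fs
  data <- array(unlist(lapply(sets, function(s) s$data)),
                dim = c(3, dim(sets[[1]]$data)[2],
                        sum(vapply(sets, n_epochs, 1L))))
  info <- do.call(rbind, lapply(sets, function(s) s$info))
  rownames(info) <- NULL
  epoch_set(data, info, fs = fs,
            pre_ms = sets[[1]]$pre_ms, post_ms = sets[[1]]$post_ms)
}

#' Write epochs to the long-format CSV interchange file
#'
#' One row per sample: `subject_id, group, content, trial_id, channel,
#' sample_index, value`, ordered by (subject, trial, channel, index) with
#' 0-based contiguous sample indices. Values round-trip losslessly (to
#' 1e-9 uV) through [read_epochs()].
#'
#' @param epochs an `epoch_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_s <- dim(epochs$data)[2]
  n_e <- n_epochs(epochs)
  info <- epochs$info
  ord <- order(info$subject_id, info$trial_id)
  rows <- lapply(ord, function(i) {
    data.frame(subject_id = info$subject_id[i], group = info$group[i],
               content = info$content[i], trial_id = info$trial_id[i],
               channel = rep(CHANNELS, each = n_s),
               sample_index = rep(0:(n_s - 1L), 3),
               value = as.vector(t(epochs$data[, , i])))
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read epochs from the long-format CSV interchange file
#'
#' Parses and validates the format written by [write_epochs()]: known
#' channel names (Fz, Pz, Cz), contiguous 0-based sample indices, and a
#' common epoch length across trials. Violations raise an error naming
#' the offending rows.
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz the samples were recorded at.
#' @param pre_ms,post_ms epoch window bounds in ms (metadata not stored in
#'   the CSV itself).
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path, fs = 250, pre_ms = 100, post_ms = 500) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "content", "trial_id", "channel",
           "sample_index", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("epoch CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!df$channel %in% CHANNELS)
  if (length(bad))
    stop(sprintf("unknown channel '%s' at CSV row %d (expected Fz, Pz, Cz)",
                 df$channel[bad[1]], bad[1]), call. = FALSE)
  key <- interaction(df$subject_id, df$trial_id, df$channel, drop = TRUE)
  lens <- tapply(df$sample_index, key, function(ix) {
    if (!identical(sort(ix), as.integer(seq_along(ix)) - 1L) &&
        !identical(sort(ix), as.numeric(seq_along(ix) - 1L)))
      return(NA_integer_)
    length(ix)
  })
  if (anyNA(lens))
    stop("non-contiguous sample indices for trial block ",
         names(lens)[which(is.na(lens))[1]], call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("ragged trials: epoch lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  n_s <- unname(lens[1])
  df <- df[order(df$subject_id, df$trial_id, match(df$channel, CHANNELS),
                 df$sample_index), ]
  tkey <- unique(df[, c("subject_id", "trial_id", "group", "content")])
  n_e <- nrow(tkey)
  data <- array(NA_real_, c(3, n_s, n_e))
  idx <- split(seq_len(nrow(df)),
               factor(paste(df$subject_id, df$trial_id),
                      levels = unique(paste(df$subject_id, df$trial_id))))
  for (i in seq_len(n_e)) {
    block <- df[idx[[i]], ]
    data[, , i] <- matrix(block$value, nrow = 3, byrow = TRUE)
  }
  epoch_set(data, data.frame(subject_id = tkey$subject_id, group = tkey$group,
                             content = tkey$content, trial_id = tkey$trial_id),
            fs = fs, pre_ms = pre_ms, post_ms = post_ms)
}
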