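## Internal helpers shared across modules.

CHANNELS <- c("Fz", "Pz", "Cz")
GROUPS <- c("LA", "HA")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)`, restoring the caller's RNG state
#' afterwards so seeded package functions do not disturb the session RNG.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Fan one top-level seed out to per-stage streams, staying below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 2039 + offset) %% 2147483587L + 1L
}

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

stopifnot_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

match_channels <- function(channels) {
  bad <- setdiff(channels, CHANNELS)
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "),
         " (expected Fz, Pz, Cz)", call. = FALSE)
  CHANNELS[CHANNELS %in% channels]
}
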