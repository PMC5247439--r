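#' Within-, between- and mixture-class scatter matrices with J1/J2
#'
#' Mixture-weighted scatter matrices of the feature matrix:
#' `S_w = sum_c sum_{i in c} (x_i - mu_c)(x_i - mu_c)' / n`,
#' `S_b = sum_c (n_c/n) (mu_c - mu)(mu_c - mu)'`, and their sum
#' `S_m = S_w + S_b` (the population covariance about the global mean).
#' The separability criteria are `J1 = trace(S_m)/trace(S_w)` and
#' `J2 = det(S_m)/det(S_w)`; both take large values when classes are
#' tight around their own means and the class means are far apart, and
#' J1 >= 1 always.
#'
#' @param fm a `feature_matrix` with >= 2 classes, each with >= 2 rows.
#' @return list of class `scatter_criteria`: matrices `S_w`, `S_b`,
#'   `S_m`, and scalars `J1`, `J2` (`J2` is `NA` with a `singular`
#'   attribute when `S_w` is singular).
#' @export
scatter_criteria <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- feature_values(fm)
  y <- fm$group
  classes <- unique(y)
  if (length(classes) < 2L || any(table(y) < 2L))
    stop("need >= 2 classes with >= 2 rows each", call. = FALSE)
  n <- nrow(X)
  d <- ncol(X)
  mu <- colMeans(X)
  S_w <- matrix(0, d, d, dimnames = list(colnames(X), colnames(X)))
  S_b <- matrix(0, d, d, dimnames = list(colnames(X), colnames(X)))
  for (cls in classes) {
    Xc <- X[y == cls, , drop = FALSE]
    mu_c <- colMeans(Xc)
    cen <- sweep(Xc, 2, mu_c)
    S_w <- S_w + crossprod(cen) / n
    S_b <- S_b + (nrow(Xc) / n) * tcrossprod(mu_c - mu)
  }
  S_m <- S_w + S_b
  J1 <- sum(diag(S_m)) / sum(diag(S_w))
  det_w <- det(S_w)
  J2 <- if (abs(det_w) < .Machine$double.eps * max(1, abs(det(S_m))))
    NA_real_ else det(S_m) / det_w
  out <- list(S_w = S_w, S_b = S_b, S_m = S_m, J1 = J1, J2 = J2)
  attr(out, "singular") <- is.na(J2)
  class(out) <- "scatter_criteria"
  out
}

#' @export
print.scatter_criteria <- function(x, ...) {
  cat(sprintf("J1 (trace ratio) = %.4f   J2 (determinant ratio) = %s\n",
              x$J1, if (is.na(x$J2)) "NA (S_w singular)" else
                format(x$J2, digits = 6)))
  invisible(x)
}

#' Kruskal-Wallis test across sample groups
#'
#' Rank-based (midrank ties) H statistic with a chi-square p-value on
#' `g - 1` degrees of freedom, for comparing two or more independent
#' groups of feature values without a normality assumption.
#'
#' @param samples list of >= 2 non-empty numeric vectors.
#' @return list of class `group_test`: `statistic`, `p_value`,
#'   `group_sizes`, `test`.
#' @export
kruskal_wallis_check <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("`samples` must be a list of >= 2 groups", call. = FALSE)
  if (any(lengths(samples) == 0L))
    stop("every group must be non-empty", call. = FALSE)
  kt <- kruskal.test(samples)
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 group_sizes = lengths(samples),
                 test = "Kruskal-Wallis"),
            class = "group_test")
}

#' Draw per-class feature subsamples for the Kruskal-Wallis check
#'
#' Reproduces the logic of testing several independent within-class
#' samples against each other: the rows of each class are shuffled
#' (seeded) and dealt into `n_samples` disjoint subsamples, and the
#' chosen feature's values in each subsample form one group; the
#' 2 x `n_samples` groups are then compared with
#' [kruskal_wallis_check()].
#'
#' @param fm a `feature_matrix`.
#' @param feature feature column to test (default: first feature).
#' @param n_samples subsamples per class (default 3, giving 6 groups).
#' @param seed integer seed.
#' @return a `group_test` result.
#' @export
kw_feature_samples <- function(fm, feature = feature_names(fm)[1],
                               n_samples = 3, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  n_samples <- stopifnot_scalar_count(n_samples, "n_samples", 1L)
  groups <- list()
  for (cls in GROUPS) {
    idx <- which(fm$group == cls)
    if (length(idx) < n_samples)
      stop("class ", cls, " has fewer rows than n_samples", call. = FALSE)
    idx <- with_seed(derive_seed(seed, match(cls, GROUPS)),
                     idx[sample.int(length(idx))])
    part <- rep_len(seq_len(n_samples), length(idx))
    for (s in seq_len(n_samples))
      groups[[length(groups) + 1L]] <- fm[[feature]][idx[part == s]]
  }
  kruskal_wallis_check(groups)
}

#' Two-sample t-test comparing system accuracies
#'
#' Independent two-sample t-test (pooled variance by default; Welch with
#' `var_equal = FALSE`) on two vectors of repeated cross-validation
#' accuracies, e.g. from the 2D and 3D systems. When both samples are
#' constant and equal -- as when both systems sit at the accuracy
#' ceiling -- p = 1 by convention, flagged in the `degenerate`
#' attribute.
#'
#' @param acc_2d,acc_3d numeric accuracy vectors (each length >= 2).
#' @param var_equal pooled-variance form if `TRUE` (default).
#' @return list of class `group_test`: `statistic`, `p_value`,
#'   `group_sizes`, `test`.
#' @export
content_effect_ttest <- function(acc_2d, acc_3d, var_equal = TRUE) {
  if (length(acc_2d) < 2L || length(acc_3d) < 2L)
    stop("both samples must have length >= 2", call. = FALSE)
  if (var(acc_2d) == 0 && var(acc_3d) == 0) {
    if (mean(acc_2d) == mean(acc_3d)) {
      return(structure(list(statistic = 0, p_value = 1,
                            group_sizes = c(length(acc_2d), length(acc_3d)),
                            test = "two-sample t (degenerate: both samples constant)"),
                       degenerate = TRUE, class = "group_test"))
    }
    return(structure(list(statistic = Inf, p_value = 0,
                          group_sizes = c(length(acc_2d), length(acc_3d)),
                          test = "two-sample t (degenerate: constant, unequal)"),
                     degenerate = TRUE, class = "group_test"))
  }
  tt <- t.test(acc_2d, acc_3d, var.equal = var_equal)
  structure(list(statistic = unname(tt$statistic),
                 p_value = unname(tt$p.value),
                 group_sizes = c(length(acc_2d), length(acc_3d)),
                 test = if (var_equal) "two-sample t (pooled)" else "Welch t"),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (groups: %s)\n",
              x$test, x$statistic, x$p_value,
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Repeated cross-validation accuracy harness
#'
#' Runs `repeats` rounds of k-fold CV, re-randomising the fold
#' assignment each round, and returns the `repeats * k` per-fold
#' accuracies (e.g. 3 x 10 = 30 values per system) for use with
#' [content_effect_ttest()].
#'
#' @param fm a `feature_matrix`.
#' @param repeats CV repetitions (default 3).
#' @param k folds per repetition (default 10).
#' @param config an [svm_config()].
#' @param seed integer seed.
#' @return numeric vector of length `repeats * k` (fractions in [0, 1]
#'   are returned as percentages, consistent with `eval_metrics`).
#' @export
repeated_cv_accuracies <- function(fm, repeats = 3, k = 10,
                                   config = svm_config(), seed = 1) {
  repeats <- stopifnot_scalar_count(repeats, "repeats", 1L)
  unlist(lapply(seq_len(repeats), function(r) {
    cv <- crossvalidate(fm, k = k, config = config,
                        seed = derive_seed(seed, 3000L + r))
    cv$per_fold$accuracy
  }))
}
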