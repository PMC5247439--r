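#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  fn <- attr(x, "feature_names")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "feature_names") <- intersect(fn, names(out))
    class(out) <- c("feature_matrix", "data.frame")
  }
  out
}

#' Rank features by area under the ROC curve
#'
#' Per-feature AUC via the rank-sum (Mann-Whitney) formulation with
#' midrank tie handling, oriented with LA as the positive class
#' (AUC = P(x_LA > x_HA) + 0.5 P(x_LA = x_HA)). Features are ranked by
#' discriminability `|AUC - 0.5|` descending, ties broken by feature
#' name order.
#'
#' @param fm a `feature_matrix` containing both classes.
#' @return data frame (class `auc_ranking`) with columns `feature`,
#'   `auc`, `discriminability`, `rank`, ordered by rank.
#' @export
auc_rank_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$group
  if (length(unique(y)) < 2L)
    stop("both classes (LA, HA) must be present", call. = FALSE)
  X <- feature_values(fm)
  n_pos <- sum(y == "LA")
  n_neg <- sum(y == "HA")
  auc <- apply(X, 2, function(x) {
    r <- rank(x)                       # midranks handle ties
    (sum(r[y == "LA"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  })
  disc <- abs(auc - 0.5)
  ord <- order(-disc, names(auc))
  out <- data.frame(feature = names(auc)[ord], auc = unname(auc[ord]),
                    discriminability = unname(disc[ord]),
                    rank = seq_along(auc))
  class(out) <- c("auc_ranking", "data.frame")
  out
}

#' SVM tuning configuration
#'
#' Grid and protocol for the nested hyperparameter search: grid search
#' over `C_grid x gamma_grid` scored by `inner_folds`-fold
#' cross-validation accuracy on a seeded stratified `tuning_fraction`
#' subset of the training data. The default grids `C = 2^0..2^13`,
#' `gamma = 2^-11..2^-4` bracket the hyperparameter magnitudes typical
#' for RBF-SVMs on features of this scale.
#'
#' @param C_grid positive soft-margin costs.
#' @param gamma_grid positive RBF kernel widths.
#' @param inner_folds inner CV folds (>= 2, default 5).
#' @param tuning_fraction fraction of training data used for tuning
#'   (default 0.25).
#' @param scale z-score features with training-fold statistics before
#'   fitting (applied to the test fold with the same statistics).
#' @param seed integer seed for the tuning subset and folds.
#' @return list of class `svm_config`.
#' @export
svm_config <- function(C_grid = 2^(0:13), gamma_grid = 2^(-11:-4),
                       inner_folds = 5, tuning_fraction = 0.25,
                       scale = TRUE, seed = 1) {
  if (!length(C_grid) || !length(gamma_grid) ||
      any(C_grid <= 0) || any(gamma_grid <= 0))
    stop("grids must be non-empty and positive", call. = FALSE)
  inner_folds <- stopifnot_scalar_count(inner_folds, "inner_folds", 2L)
  tuning_fraction <- stopifnot_fraction(tuning_fraction, "tuning_fraction")
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 inner_folds = inner_folds, tuning_fraction = tuning_fraction,
                 scale = scale, seed = seed),
            class = "svm_config")
}

## Stratified fold ids: within each class, shuffle then deal out
## cyclically, so per-fold class proportions are within one trial of the
## global proportions. Seeded by the caller's RNG state.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, s = s)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$s, "/")

fit_svm <- function(X, y, C, gamma) {
  e1071::svm(X, factor(y, levels = GROUPS), kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

#' Tune SVM hyperparameters by nested grid search
#'
#' Draws a seeded stratified `tuning_fraction` subset of the training
#' rows, then scores every `(C, gamma)` pair of the grid by stratified
#' `inner_folds`-fold CV accuracy on that subset. Ties are broken toward
#' smaller `C`, then smaller `gamma`. If a refold produces a single-class
#' inner fold, the folds are redrawn with a shifted seed (logged via a
#' message).
#'
#' @param fm training `feature_matrix` containing both classes (features
#'   are used as provided; standardise beforehand if desired).
#' @param config an [svm_config()].
#' @return list with `C`, `gamma`, `inner_accuracy` (mean inner-CV
#'   accuracy of the chosen pair) and `grid` (full results table).
#' @export
tune_svm <- function(fm, config = svm_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "svm_config"))
  y <- fm$group
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  X <- feature_values(fm)
  ## seeded stratified tuning subset
  sub <- with_seed(derive_seed(config$seed, 1L), {
    unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      n_take <- max(2L, round(config$tuning_fraction * length(idx)))
      idx[sample.int(length(idx), min(n_take, length(idx)))]
    }))
  })
  Xt <- X[sub, , drop = FALSE]
  yt <- y[sub]
  k <- min(config$inner_folds, min(table(yt)))
  fold <- NULL
  for (attempt in 0:5) {
    fold <- with_seed(derive_seed(config$seed, 2L + attempt),
                      stratified_folds(yt, k))
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(yt[fold != f])) == 2L, logical(1)))
    if (ok) break
    message("degenerate inner fold; refolding with shifted seed")
  }
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(yt[tr])) < 2L) next
      m <- fit_svm(Xt[tr, , drop = FALSE], yt[tr], grid$C[g], grid$gamma[g])
      pred <- predict(m, Xt[!tr, , drop = FALSE])
      correct <- correct + sum(pred == yt[!tr])
    }
    correct / length(yt)
  }, numeric(1))
  best <- grid[order(-grid$accuracy, grid$C, grid$gamma), ][1, ]
  list(C = best$C, gamma = best$gamma, inner_accuracy = best$accuracy,
       grid = grid)
}

auc_from_scores <- function(score, y) {
  r <- rank(score)
  n_pos <- sum(y == "LA")
  n_neg <- sum(y == "HA")
  (sum(r[y == "LA"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

## Decision scores oriented so that larger means LA.
svm_scores <- function(model, X) {
  pred <- predict(model, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  s <- dv[, 1]
  if (!grepl("^LA/", colnames(dv)[1])) s <- -s
  list(pred = pred, score = s)
}

#' Confusion-matrix performance metrics
#'
#' The four standard percentages with LA as the positive class:
#' accuracy = (TP+TN)/n x 100, precision = TP/(TP+FP) x 100,
#' sensitivity = TP/(TP+FN) x 100, specificity = TN/(TN+FP) x 100.
#' A zero denominator yields `NA` with the affected metric listed in the
#' `undefined` attribute (never a silent 0).
#'
#' @param confusion named numeric vector with elements `TP`, `FP`, `TN`,
#'   `FN` (counts >= 0, total > 0).
#' @return list of class `eval_metrics` with the four percentages and
#'   the confusion counts.
#' @examples
#' compute_metrics(c(TP = 40, FP = 20, TN = 30, FN = 10))
#' @export
compute_metrics <- function(confusion) {
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(confusion)))
    stop("`confusion` must have elements TP, FP, TN, FN", call. = FALSE)
  cf <- confusion[need]
  if (any(cf < 0) || sum(cf) <= 0)
    stop("confusion counts must be >= 0 with a positive total", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- list(accuracy = 100 * (cf[["TP"]] + cf[["TN"]]) / sum(cf),
              sensitivity = ratio(cf[["TP"]], cf[["TP"]] + cf[["FN"]]),
              specificity = ratio(cf[["TN"]], cf[["TN"]] + cf[["FP"]]),
              precision = ratio(cf[["TP"]], cf[["TP"]] + cf[["FP"]]),
              confusion = cf)
  undefined <- c("sensitivity", "specificity", "precision")[
    is.na(c(out$sensitivity, out$specificity, out$precision))]
  attr(out, "undefined") <- undefined
  class(out) <- "eval_metrics"
  out
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %s  specificity %s  precision %s\n",
              x$accuracy,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.2f%%", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.2f%%", x$specificity)),
              ifelse(is.na(x$precision), "NA", sprintf("%.2f%%", x$precision))))
  if (!is.null(x$auc)) cat(sprintf("AUC %.4f\n", x$auc))
  if (!is.null(x$chosen_C))
    cat(sprintf("chosen C = %g, gamma = %g\n", x$chosen_C, x$chosen_gamma))
  invisible(x)
}

confusion_from_pred <- function(pred, truth) {
  c(TP = sum(pred == "LA" & truth == "LA"),
    FP = sum(pred == "LA" & truth == "HA"),
    TN = sum(pred == "HA" & truth == "HA"),
    FN = sum(pred == "HA" & truth == "LA"))
}

## One train/test evaluation round: scale on train, tune, fit, score.
evaluate_split <- function(fm, train_idx, test_idx, config, seed) {
  Xall <- feature_values(fm)
  y <- fm$group
  Xtr <- Xall[train_idx, , drop = FALSE]
  Xte <- Xall[test_idx, , drop = FALSE]
  if (config$scale) {
    sc <- scale_fit(Xtr)
    Xtr <- scale_apply(Xtr, sc)
    Xte <- scale_apply(Xte, sc)
  }
  fm_tr <- fm[train_idx, , drop = FALSE]
  fm_tr[, feature_names(fm)] <- Xtr
  tuned <- tune_svm(fm_tr, svm_config(config$C_grid, config$gamma_grid,
                                      config$inner_folds,
                                      config$tuning_fraction,
                                      scale = FALSE, seed = seed))
  model <- fit_svm(Xtr, y[train_idx], tuned$C, tuned$gamma)
  sc_out <- svm_scores(model, Xte)
  list(pred = as.character(sc_out$pred), score = sc_out$score,
       truth = y[test_idx], C = tuned$C, gamma = tuned$gamma)
}

#' Stratified k-fold cross-validation of the RBF-SVM classifier
#'
#' Seeded stratified folds; per fold the hyperparameters are tuned on
#' the training side only ([tune_svm()]), the model is refit on the full
#' training side and scored on the held-out fold. The four percentage
#' metrics are averaged over folds; the AUC is computed from the pooled
#' decision values. Identical seeds reproduce identical folds, tuning
#' subsets and metrics.
#'
#' @param fm a `feature_matrix`.
#' @param k number of folds (default 10; requires `n >= k`).
#' @param config an [svm_config()].
#' @param seed integer seed controlling folding and tuning.
#' @return an `eval_metrics` object with fields `accuracy`,
#'   `sensitivity`, `specificity`, `precision` (fold-averaged
#'   percentages), `auc` (pooled), `confusion` (pooled counts),
#'   `chosen_C`/`chosen_gamma` (most frequent per-fold choice) and
#'   `per_fold` (data frame of per-fold results).
#' @export
crossvalidate <- function(fm, k = 10, config = svm_config(), seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  k <- stopifnot_scalar_count(k, "k", 2L)
  n <- nrow(fm)
  if (n < k)
    stop(sprintf("n = %d < k = %d folds; use a smaller k", n, k),
         call. = FALSE)
  y <- fm$group
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  fold <- with_seed(derive_seed(seed, 11L), stratified_folds(y, k))
  per_fold <- vector("list", k)
  pooled_score <- numeric(0)
  pooled_truth <- character(0)
  pooled_cf <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (f in seq_len(k)) {
    res <- evaluate_split(fm, which(fold != f), which(fold == f), config,
                          derive_seed(seed, 100L + f))
    cf <- confusion_from_pred(res$pred, res$truth)
    m <- compute_metrics(cf)
    per_fold[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                                sensitivity = m$sensitivity,
                                specificity = m$specificity,
                                precision = m$precision,
                                C = res$C, gamma = res$gamma)
    pooled_cf <- pooled_cf + cf
    pooled_score <- c(pooled_score, res$score)
    pooled_truth <- c(pooled_truth, res$truth)
  }
  per_fold <- do.call(rbind, per_fold)
  pick_mode <- function(v) as.numeric(names(sort(table(v), decreasing = TRUE))[1])
  out <- list(accuracy = mean(per_fold$accuracy),
              sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
              specificity = mean(per_fold$specificity, na.rm = TRUE),
              precision = mean(per_fold$precision, na.rm = TRUE),
              auc = auc_from_scores(pooled_score, pooled_truth),
              confusion = pooled_cf,
              chosen_C = pick_mode(per_fold$C),
              chosen_gamma = pick_mode(per_fold$gamma),
              per_fold = per_fold)
  class(out) <- "eval_metrics"
  out
}

#' Subject-holdout evaluation
#'
#' Splits by subject, stratified by group (no subject contributes trials
#' to both sides): per group, `train_fraction` of the subjects (seeded)
#' form the training side; the classifier is tuned and fit on their
#' trials and evaluated on the held-out subjects' trials. This is the
#' stricter protocol: trial-level folding lets within-subject
#' correlation leak between training and test.
#'
#' @param fm a `feature_matrix` whose `subject_id` column identifies
#'   subjects (>= 2 subjects per group).
#' @param train_fraction fraction of each group's subjects used for
#'   training (default 0.7).
#' @param config an [svm_config()].
#' @param seed integer seed.
#' @return an `eval_metrics` object; also carries `train_subjects` and
#'   `test_subjects`.
#' @export
subject_holdout_evaluate <- function(fm, train_fraction = 0.7,
                                     config = svm_config(), seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  train_fraction <- stopifnot_fraction(train_fraction, "train_fraction")
  subj <- unique(fm[, c("subject_id", "group")])
  counts <- table(subj$group)
  if (any(counts < 2L) || length(counts) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  train_subj <- with_seed(derive_seed(seed, 21L), {
    unlist(lapply(GROUPS, function(g) {
      ids <- subj$subject_id[subj$group == g]
      n_tr <- min(length(ids) - 1L, max(1L, floor(train_fraction * length(ids))))
      sample(ids, n_tr)
    }))
  })
  train_idx <- which(fm$subject_id %in% train_subj)
  test_idx <- which(!fm$subject_id %in% train_subj)
  res <- evaluate_split(fm, train_idx, test_idx, config,
                        derive_seed(seed, 22L))
  out <- compute_metrics(confusion_from_pred(res$pred, res$truth))
  out$auc <- auc_from_scores(res$score, res$truth)
  out$chosen_C <- res$C
  out$chosen_gamma <- res$gamma
  out$train_subjects <- sort(train_subj)
  out$test_subjects <- sort(setdiff(subj$subject_id, train_subj))
  out
}

#' Exhaustive band/channel/statistic combination search
#'
#' Evaluates every configuration in the cross product of the supplied
#' band, channel and statistic subsets by k-fold CV accuracy
#' ([crossvalidate()] with a shared seed, so configurations are
#' comparable) and returns the results sorted by accuracy. Epoch
#' decompositions are computed once and reused across configurations.
#'
#' @param epochs an [epoch_set()].
#' @param band_subsets list of band subsets (default: each of the five
#'   bands individually).
#' @param channel_subsets list of channel subsets (default: all three).
#' @param statistic_subsets list of SWF statistic subsets (default:
#'   `Er` and `std`).
#' @param k,config,seed evaluation protocol, as in [crossvalidate()].
#' @param J,n_keep decomposition settings.
#' @param max_configs error if the cross product exceeds this many
#'   configurations.
#' @return data frame (class `combination_search`) with columns `bands`,
#'   `channels`, `statistics`, `n_features`, `accuracy`, `auc`, sorted
#'   by accuracy descending (ties: fewer features first, then
#'   configuration label).
#' @export
combination_search <- function(epochs,
                               band_subsets = as.list(BANDS4),
                               channel_subsets = list(CHANNELS),
                               statistic_subsets = list(c("Er", "std")),
                               k = 10, config = svm_config(), seed = 1,
                               J = 4, n_keep = 144, max_configs = 200) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!length(band_subsets) || !length(channel_subsets) ||
      !length(statistic_subsets))
    stop("candidate subset lists must be non-empty", call. = FALSE)
  n_cfg <- length(band_subsets) * length(channel_subsets) *
    length(statistic_subsets)
  if (n_cfg > max_configs)
    stop(sprintf("%d configurations exceed max_configs = %d",
                 n_cfg, max_configs), call. = FALSE)
  decomps <- decompose_epochs(epochs, J = J, n_keep = n_keep)
  rows <- list()
  i <- 0L
  for (bs in band_subsets) for (cs in channel_subsets)
    for (ss in statistic_subsets) {
      i <- i + 1L
      fm <- feature_matrix_from_decomps(decomps, epochs$info, "swf",
                                        bs, cs, ss)
      cv <- crossvalidate(fm, k = k, config = config, seed = seed)
      rows[[i]] <- data.frame(bands = paste(bs, collapse = "+"),
                              channels = paste(cs, collapse = "+"),
                              statistics = paste(ss, collapse = "+"),
                              n_features = length(feature_names(fm)),
                              accuracy = cv$accuracy, auc = cv$auc)
    }
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, out$n_features, out$bands), ]
  rownames(out) <- NULL
  class(out) <- c("combination_search", "data.frame")
  out
}
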