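#' Monte Carlo cross-validation configuration
#'
#' @param n_outer Outer train/test iterations (default 100).
#' @param n_inner Inner train/validation iterations for feature ranking
#'   (default 100).
#' @param train_frac Training fraction of both split levels (default 0.7).
#' @param rebalance_factor Bootstrap the smallest phenotype up to this
#'   fraction of the largest one in every training set (default 0.6).
#' @param num_trees Random-forest trees (default 500).
#' @param shap_nsim Permutations per explained sample in the Monte-Carlo
#'   Shapley estimator (default 8).
#' @param shap_max_explain Cap on explained validation samples per iteration
#'   (default 40); keeps the attribution cost bounded.
#' @param max_redraw How often a degenerate split (a class missing from a
#'   partition) may be re-drawn before erroring (default 50).
#' @param seed Master seed for all splits, resampling and forests.
#' @return List of class `mccv_config`.
#' @export
mccv_config <- function(n_outer = 100, n_inner = 100, train_frac = 0.7,
                        rebalance_factor = 0.6, num_trees = 500,
                        shap_nsim = 8, shap_max_explain = 40,
                        max_redraw = 50, seed = 1) {
  stopifnot(n_outer >= 1, n_inner >= 1,
            train_frac > 0, train_frac < 1,
            rebalance_factor > 0, rebalance_factor <= 1)
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 train_frac = train_frac,
                 rebalance_factor = rebalance_factor,
                 num_trees = as.integer(num_trees),
                 shap_nsim = as.integer(shap_nsim),
                 shap_max_explain = as.integer(shap_max_explain),
                 max_redraw = as.integer(max_redraw),
                 seed = as.integer(seed)),
            class = "mccv_config")
}

#' Remove highly correlated features
#'
#' Greedy pruning: while any pair has absolute Pearson correlation above
#' `r_max`, the member of the worst pair with the larger mean absolute
#' correlation to all remaining features is dropped (ties go to the
#' alphabetically later name). Constant features are dropped first with a
#' warning since their correlation is undefined.
#'
#' @param features Numeric matrix or data frame (imputed).
#' @param r_max Correlation threshold (default 0.7).
#' @return Character vector of kept feature names; every pairwise `|r|` of
#'   the kept set is at most `r_max`.
#' @export
correlation_prune <- function(features, r_max = 0.7) {
  x <- as.matrix(features)
  const <- colnames(x)[apply(x, 2, stats::sd) == 0]
  if (length(const)) {
    warning("dropping constant feature(s): ", paste(const, collapse = ", "))
    x <- x[, setdiff(colnames(x), const), drop = FALSE]
  }
  repeat {
    if (ncol(x) < 2) break
    r <- abs(stats::cor(x))
    diag(r) <- 0
    if (max(r) <= r_max) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    cand <- colnames(x)[worst]
    mean_abs <- colMeans(r[, cand, drop = FALSE])
    drop <- if (abs(diff(mean_abs)) > 1e-12) {
      cand[which.max(mean_abs)]
    } else {
      sort(cand)[2]  # alphabetically later
    }
    x <- x[, setdiff(colnames(x), drop), drop = FALSE]
  }
  colnames(x)
}

#' Bootstrap the minority phenotype up in a training set
#'
#' Appends rows of the minority class, resampled with replacement, until its
#' count reaches `round(factor * n_reference)`. All original rows are kept;
#' nothing is ever down-sampled.
#'
#' @param train_labels Phenotype per training row.
#' @param factor Target size as a fraction of the reference class.
#' @param seed Integer seed.
#' @param minority,reference Class labels; defaults pick the smallest and
#'   largest class.
#' @return Integer index vector into the training rows (original order plus
#'   appended bootstrap indices).
#' @export
bootstrap_rebalance <- function(train_labels, factor = 0.6, seed = 1,
                                minority = NULL, reference = NULL) {
  lab <- as.character(train_labels)
  tb <- table(lab)
  minority <- minority %||% names(tb)[which.min(tb)]
  reference <- reference %||% names(tb)[which.max(tb)]
  if (!minority %in% lab) {
    stop("minority class '", minority, "' absent from training labels",
         call. = FALSE)
  }
  target <- round(factor * sum(lab == reference))
  idx_min <- which(lab == minority)
  extra <- target - length(idx_min)
  if (extra <= 0) return(seq_along(lab))
  boot <- with_seed(seed, sample(idx_min, extra, replace = TRUE))
  c(seq_along(lab), boot)
}

# medians from training rows only; fills both partitions (no leakage)
impute_train_median <- function(x_train, x_other = NULL) {
  med <- apply(x_train, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      if (anyNA(m[, j])) m[is.na(m[, j]), j] <- med[j]
    }
    m
  }
  list(train = fill(x_train),
       other = if (is.null(x_other)) NULL else fill(x_other),
       medians = med)
}

fit_rf <- function(x, y, num_trees, seed) {
  df <- as.data.frame(x)
  df$.class <- factor(y)
  ranger::ranger(dependent.variable.name = ".class", data = df,
                 num.trees = num_trees, probability = TRUE, seed = seed,
                 num.threads = 1)
}

predict_rf_prob <- function(fit, x) {
  stats::predict(fit, data = as.data.frame(x), num.threads = 1)$predictions
}

predict_rf_class <- function(fit, x) {
  pr <- predict_rf_prob(fit, x)
  colnames(pr)[max.col(pr, ties.method = "first")]
}

#' Monte-Carlo Shapley feature attribution for a fitted classifier
#'
#' Permutation-sampling estimate of Shapley values (Strumbelj-Kononenko):
#' for each explained sample and each of `nsim` random feature orderings, a
#' background training row is drawn and features are switched one by one
#' from the background to the explained values; the prediction increments
#' along the chain are unbiased estimates of the per-feature Shapley
#' contributions. Importance is the mean over explained samples and classes
#' of the absolute Shapley value.
#'
#' @param fit Fitted probability forest (from `ranger`).
#' @param background Training feature matrix (sampling pool).
#' @param x_explain Matrix of samples to explain.
#' @param nsim Permutations per sample.
#' @param seed Integer seed.
#' @return Named numeric vector of per-feature importances.
#' @export
shapley_importance <- function(fit, background, x_explain, nsim = 8,
                               seed = 1) {
  p <- ncol(x_explain)
  n <- nrow(x_explain)
  with_seed(seed, {
    perms <- replicate(n * nsim, sample.int(p), simplify = FALSE)
    bg_idx <- sample.int(nrow(background), n * nsim, replace = TRUE)
    ## chain rows: for each (sample, perm): p + 1 hybrid rows
    rows <- matrix(NA_real_, n * nsim * (p + 1), p)
    colnames(rows) <- colnames(x_explain)
    r <- 0L
    for (i in seq_len(n)) {
      for (s in seq_len(nsim)) {
        ps <- (i - 1L) * nsim + s
        perm <- perms[[ps]]
        cur <- background[bg_idx[ps], ]
        rows[r + 1L, ] <- cur
        for (j in seq_len(p)) {
          cur[perm[j]] <- x_explain[i, perm[j]]
          rows[r + 1L + j, ] <- cur
        }
        r <- r + p + 1L
      }
    }
    pr <- predict_rf_prob(fit, rows)
    n_class <- ncol(pr)
    phi <- matrix(0, p, n_class)
    r <- 0L
    for (i in seq_len(n)) {
      phi_i <- matrix(0, p, n_class)
      for (s in seq_len(nsim)) {
        perm <- perms[[(i - 1L) * nsim + s]]
        inc <- pr[(r + 2L):(r + p + 1L), , drop = FALSE] -
          pr[(r + 1L):(r + p), , drop = FALSE]
        phi_i[perm, ] <- phi_i[perm, ] + inc
        r <- r + p + 1L
      }
      phi <- phi + abs(phi_i / nsim)
    }
    stats::setNames(rowMeans(phi / n), colnames(x_explain))
  })
}

#' Rank features by median Shapley rank over inner MCCV iterations
#'
#' Runs `n_inner` stratified train/validation splits of the (outer) training
#' data; each iteration median-imputes from its training part, rebalances
#' the minority phenotype, fits a random forest and ranks features by
#' Shapley importance (rank 1 = most important). The final order is by
#' ascending median rank, ties broken by mean rank, then by name.
#'
#' @param x Feature matrix (may contain `NA`).
#' @param y Phenotype labels.
#' @param cfg An [mccv_config()].
#' @return Data frame `feature`, `median_rank`, `mean_rank`, ordered; the
#'   ordered feature names are in `$feature`.
#' @export
shap_rank_features <- function(x, y, cfg = mccv_config()) {
  x <- as.matrix(x)
  y <- as.character(y)
  p <- ncol(x)
  ranks <- matrix(NA_real_, cfg$n_inner, p, dimnames = list(NULL, colnames(x)))
  for (it in seq_len(cfg$n_inner)) {
    sp <- draw_split(y, cfg$train_frac, child_seed(cfg$seed, 7000 + it),
                     cfg$max_redraw)
    imp <- impute_train_median(x[sp$train, , drop = FALSE],
                               x[sp$test, , drop = FALSE])
    idx <- bootstrap_rebalance(y[sp$train], cfg$rebalance_factor,
                               seed = child_seed(cfg$seed, 8000 + it))
    fit <- fit_rf(imp$train[idx, , drop = FALSE], y[sp$train][idx],
                  cfg$num_trees, seed = child_seed(cfg$seed, 9000 + it))
    xe <- imp$other
    if (nrow(xe) > cfg$shap_max_explain) {
      keep <- with_seed(child_seed(cfg$seed, 10000 + it),
                        sample.int(nrow(xe), cfg$shap_max_explain))
      xe <- xe[keep, , drop = FALSE]
    }
    importance <- shapley_importance(fit, imp$train[idx, , drop = FALSE], xe,
                                     nsim = cfg$shap_nsim,
                                     seed = child_seed(cfg$seed, 11000 + it))
    ranks[it, ] <- rank(-importance, ties.method = "average")
  }
  med <- apply(ranks, 2, stats::median)
  mea <- colMeans(ranks)
  ord <- order(med, mea, colnames(x))
  data.frame(feature = colnames(x)[ord], median_rank = med[ord],
             mean_rank = mea[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

# stratified split; re-drawn (with a message) if any class is missing from a
# partition, which can only happen for singleton classes
draw_split <- function(y, frac, seed, max_redraw = 50) {
  for (attempt in seq_len(max_redraw)) {
    sp <- with_seed(seed + attempt - 1L, stratified_split(y, frac))
    if (all(unique(y) %in% y[sp$train]) && all(unique(y) %in% y[sp$test])) {
      if (attempt > 1) message("split re-drawn (", attempt - 1,
                               " degenerate attempt(s))")
      return(sp)
    }
  }
  stop("could not draw a split containing every class", call. = FALSE)
}

macro_recall <- function(truth, pred) {
  classes <- sort(unique(truth))
  mean(vapply(classes, function(cl)
    mean(pred[truth == cl] == cl), numeric(1)))
}

per_class_metrics <- function(truth, pred, prob) {
  classes <- sort(unique(truth))
  out <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    recall <- tp / sum(truth == cl)
    precision <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else NA_real_
    auc <- as.numeric(pROC::auc(
      response = factor(as.integer(truth == cl), levels = c(0, 1)),
      predictor = prob[, cl], quiet = TRUE, direction = "<"))
    c(auroc = auc, precision = precision, recall = recall)
  })
  names(out) <- classes
  out
}

#' Recall as a function of the number of selected features
#'
#' For every feature count `f = 1..F` (features added in ranked order) runs
#' `n_outer` stratified 70/30 splits: training-median imputation, minority
#' bootstrap rebalancing, random-forest fit, macro (unweighted) recall on
#' the untouched test split. The same splits are reused across feature
#' counts so the curve varies only through the feature set.
#'
#' @param x Feature matrix (may contain `NA`).
#' @param y Phenotype labels.
#' @param order Ranked feature names (from [shap_rank_features()]).
#' @param cfg An [mccv_config()].
#' @return Data frame of class `recall_curve`: `f`, `mean_recall`,
#'   `sd_recall`, `mean_recall_train`; the feature order is kept in the
#'   `"features"` attribute.
#' @export
mccv_recall_curve <- function(x, y, order, cfg = mccv_config()) {
  stopifnot(length(order) >= 1)
  x <- as.matrix(x)[, order, drop = FALSE]
  y <- as.character(y)
  splits <- lapply(seq_len(cfg$n_outer), function(it)
    draw_split(y, cfg$train_frac, child_seed(cfg$seed, 100 + it),
               cfg$max_redraw))
  res <- matrix(NA_real_, cfg$n_outer, length(order))
  res_tr <- res
  for (f in seq_along(order)) {
    for (it in seq_len(cfg$n_outer)) {
      sp <- splits[[it]]
      xt <- x[sp$train, seq_len(f), drop = FALSE]
      xs <- x[sp$test, seq_len(f), drop = FALSE]
      imp <- impute_train_median(xt, xs)
      idx <- bootstrap_rebalance(y[sp$train], cfg$rebalance_factor,
                                 seed = child_seed(cfg$seed, 200 + it))
      fit <- fit_rf(imp$train[idx, , drop = FALSE], y[sp$train][idx],
                    cfg$num_trees,
                    seed = child_seed(cfg$seed, 300 + it * 1000 + f))
      res[it, f] <- macro_recall(y[sp$test], predict_rf_class(fit, imp$other))
      res_tr[it, f] <- macro_recall(y[sp$train],
                                    predict_rf_class(fit, imp$train))
    }
  }
  out <- data.frame(f = seq_along(order),
                    mean_recall = colMeans(res),
                    sd_recall = apply(res, 2, stats::sd),
                    mean_recall_train = colMeans(res_tr))
  attr(out, "features") <- order
  class(out) <- c("recall_curve", "data.frame")
  out
}

#' Knee-point detection on a recall-vs-feature-count curve
#'
#' Kneedle algorithm for a concave, increasing curve: normalize both axes to
#' `[0, 1]`, form the difference curve `d = y_n - x_n`, and confirm the first
#' local maximum of `d` whose height is not re-attained before `d` drops
#' below the sensitivity threshold
#' `d_max - sensitivity * mean(diff(x_n))`. When no knee is confirmed (e.g.
#' a straight line), the full feature count is returned with a warning.
#'
#' @param curve A [mccv_recall_curve()] result, or any data frame with
#'   columns `f` and `mean_recall`.
#' @param sensitivity Kneedle sensitivity (default 1).
#' @return The knee feature count (integer).
#' @export
knee_select <- function(curve, sensitivity = 1.0) {
  x <- curve$f
  y <- curve$mean_recall
  n <- length(x)
  if (n < 3) stop("need at least 3 curve points", call. = FALSE)
  if (diff(range(y)) == 0) {
    warning("flat curve: no knee found; returning the full feature count")
    return(as.integer(x[n]))
  }
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  d <- yn - xn
  step <- mean(diff(xn))
  is_lmax <- vapply(seq_len(n), function(i) {
    i > 1 && i < n && d[i] > d[i - 1] && d[i] >= d[i + 1]
  }, logical(1))
  knee <- NA_integer_
  i_lmx <- NA_integer_
  thresh <- -Inf
  for (i in seq_len(n)) {
    if (is_lmax[i]) {
      i_lmx <- i
      thresh <- d[i] - sensitivity * step
    } else if (!is.na(i_lmx) && d[i] < thresh) {
      knee <- i_lmx
      break
    }
  }
  if (is.na(knee)) {
    warning("no knee found; returning the full feature count")
    return(as.integer(x[n]))
  }
  as.integer(x[knee])
}

#' Final classifier evaluation over fresh MCCV splits
#'
#' Over `n_outer` fresh stratified splits: per-class one-vs-rest AUROC,
#' precision and recall on the test and training partitions (mean and SD
#' across iterations), the train-test gap per metric, and — when
#' `feature_frequency = TRUE` — the frequency with which each feature lands
#' among the top `knee_f` Shapley ranks of the iteration's model. A gap
#' above 0.1 in any metric adds an overfitting note to the report.
#'
#' @param x Feature matrix (may contain `NA`).
#' @param y Phenotype labels.
#' @param features Chosen feature names (nonempty).
#' @param cfg An [mccv_config()].
#' @param knee_f Feature-combination size for the frequency analysis
#'   (default: all chosen features).
#' @param feature_frequency Whether to compute per-feature top-`knee_f`
#'   selection frequencies (one Shapley ranking per outer iteration).
#' @return List of class `classifier_report`: `metrics` (per class and
#'   metric: train/test mean and SD, gap), `macro` (macro-averaged),
#'   `overfitting` (logical), `notes`, `feature_frequency`, `features`.
#' @export
evaluate_final <- function(x, y, features, cfg = mccv_config(),
                           knee_f = length(features),
                           feature_frequency = FALSE) {
  stopifnot(length(features) >= 1)
  x <- as.matrix(x)[, features, drop = FALSE]
  y <- as.character(y)
  classes <- sort(unique(y))
  metric_names <- c("auroc", "precision", "recall")
  acc_test <- array(NA_real_, c(cfg$n_outer, length(classes), 3),
                    dimnames = list(NULL, classes, metric_names))
  acc_train <- acc_test
  freq <- stats::setNames(numeric(length(features)), features)
  for (it in seq_len(cfg$n_outer)) {
    # identical seed streams to mccv_recall_curve, so evaluating the full
    # ranked set reproduces the curve's endpoint exactly
    sp <- draw_split(y, cfg$train_frac, child_seed(cfg$seed, 100 + it),
                     cfg$max_redraw)
    imp <- impute_train_median(x[sp$train, , drop = FALSE],
                               x[sp$test, , drop = FALSE])
    idx <- bootstrap_rebalance(y[sp$train], cfg$rebalance_factor,
                               seed = child_seed(cfg$seed, 200 + it))
    fit <- fit_rf(imp$train[idx, , drop = FALSE], y[sp$train][idx],
                  cfg$num_trees,
                  seed = child_seed(cfg$seed, 300 + it * 1000 +
                                      length(features)))
    for (part in c("test", "train")) {
      xm <- if (part == "test") imp$other else imp$train
      ym <- if (part == "test") y[sp$test] else y[sp$train]
      pr <- predict_rf_prob(fit, xm)
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
      met <- per_class_metrics(ym, pred, pr)
      for (cl in classes) {
        if (part == "test") acc_test[it, cl, ] <- met[[cl]]
        else acc_train[it, cl, ] <- met[[cl]]
      }
    }
    if (feature_frequency && length(features) > 1) {
      xe <- imp$other
      if (nrow(xe) > cfg$shap_max_explain) {
        keep <- with_seed(child_seed(cfg$seed, 700 + it),
                          sample.int(nrow(xe), cfg$shap_max_explain))
        xe <- xe[keep, , drop = FALSE]
      }
      importance <- shapley_importance(fit, imp$train[idx, , drop = FALSE],
                                       xe, nsim = cfg$shap_nsim,
                                       seed = child_seed(cfg$seed, 800 + it))
      top <- names(sort(importance, decreasing = TRUE))[seq_len(
        min(knee_f, length(features)))]
      freq[top] <- freq[top] + 1
    }
  }
  summarize <- function(a) {
    list(mean = apply(a, c(2, 3), mean, na.rm = TRUE),
         sd = apply(a, c(2, 3), stats::sd, na.rm = TRUE))
  }
  s_test <- summarize(acc_test)
  s_train <- summarize(acc_train)
  gap <- s_train$mean - s_test$mean
  macro <- data.frame(
    metric = metric_names,
    test_mean = colMeans(s_test$mean), test_sd = colMeans(s_test$sd),
    train_mean = colMeans(s_train$mean),
    gap = colMeans(gap), row.names = NULL)
  overfit <- any(gap > 0.1, na.rm = TRUE)
  notes <- character(0)
  if (overfit) {
    notes <- paste0("overfitting: train-test gap exceeds 0.1 for ",
                    paste(unique(colnames(gap)[which(gap > 0.1,
                                                     arr.ind = TRUE)[, 2]]),
                          collapse = ", "))
  }
  structure(list(metrics = list(test = s_test, train = s_train, gap = gap),
                 macro = macro, overfitting = overfit, notes = notes,
                 feature_frequency = if (feature_frequency)
                   freq / cfg$n_outer else NULL,
                 features = features, knee_f = knee_f, cfg = cfg),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Phenotype classifier report (", x$cfg$n_outer,
      " MCCV iterations, ", length(x$features), " features)\n", sep = "")
  cat("features:", paste(x$features, collapse = ", "), "\n")
  cat("\nper-class test metrics (mean +/- sd):\n")
  m <- x$metrics$test
  for (cl in rownames(m$mean)) {
    cat(sprintf("  %s: AUROC %.3f +/- %.3f, precision %.3f +/- %.3f, recall %.3f +/- %.3f\n",
                cl, m$mean[cl, "auroc"], m$sd[cl, "auroc"],
                m$mean[cl, "precision"], m$sd[cl, "precision"],
                m$mean[cl, "recall"], m$sd[cl, "recall"]))
  }
  cat("\nmacro averages:\n")
  print(x$macro, row.names = FALSE, digits = 3)
  if (x$overfitting) cat("\nNOTE:", x$notes, "\n")
  invisible(x)
}

#' Plot a recall curve with its knee point
#'
#' @param x A [mccv_recall_curve()] result.
#' @param knee Optional knee feature count to mark.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.recall_curve <- function(x, knee = NULL, ...) {
  graphics::plot(x$f, x$mean_recall, type = "b",
                 ylim = range(c(x$mean_recall - x$sd_recall,
                                x$mean_recall + x$sd_recall)),
                 xlab = "number of features", ylab = "macro recall", ...)
  graphics::arrows(x$f, x$mean_recall - x$sd_recall,
                   x$f, x$mean_recall + x$sd_recall,
                   angle = 90, code = 3, length = 0.03)
  if (!is.null(knee)) graphics::abline(v = knee, lty = 2, col = 2)
  invisible(x)
}
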