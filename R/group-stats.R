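#' Median-center protein intensities per batch
#'
#' For every protein, subtracts each batch's median and adds back the grand
#' median over all observed values, so batch location offsets cancel while
#' the overall intensity scale is preserved. Missing cells are untouched;
#' a protein unobserved in some batch keeps its `NA`s there.
#'
#' @param m Samples x proteins matrix of log2 intensities (`NA` = missing).
#' @param batch Batch label per sample (row).
#' @return Normalized matrix of the same shape.
#' @export
normalize_batches <- function(m, batch) {
  stopifnot(nrow(m) == length(batch))
  if (!length(batch) || anyNA(batch)) {
    stop("every sample needs a batch label", call. = FALSE)
  }
  tb <- table(batch)
  if (any(tb < 3)) {
    stop("each batch needs at least 3 samples", call. = FALSE)
  }
  out <- m
  for (b in unique(batch)) {
    rows <- which(batch == b)
    bmed <- apply(m[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    out[rows, ] <- sweep(m[rows, , drop = FALSE], 2, bmed, `-`)
  }
  grand <- apply(m, 2, stats::median, na.rm = TRUE)
  sweep(out, 2, grand, `+`)
}

#' Differential-abundance screen across phenotypes
#'
#' Per protein: one-way ANOVA across the phenotype groups on observed log2
#' intensities, Benjamini-Hochberg correction over the tested proteins only,
#' and Tukey HSD (Tukey-Kramer for unbalanced groups) pairwise post-hoc
#' p-values. A pair is flagged significant when both the BH-adjusted ANOVA
#' p-value and the pairwise p-value are at most 0.05 (the dual criterion).
#' Proteins with fewer than `min_n` observations in any group are excluded
#' before testing — and therefore before the BH correction.
#'
#' @param m Samples x proteins matrix (log2, `NA` = missing).
#' @param labels Phenotype per sample.
#' @param min_n Minimum observations per group (default 5).
#' @return Data frame of class `da_result`, one row per tested protein:
#'   per-group n and mean, `p_anova`, `p_fdr`, and for each group pair the
#'   Tukey p-value, the direction of the mean difference and the
#'   significance flag. Attribute `n_excluded` counts filtered proteins.
#' @export
differential_abundance <- function(m, labels, min_n = 5) {
  labels <- as.character(labels)
  stopifnot(nrow(m) == length(labels))
  groups <- sort(unique(labels))
  k <- length(groups)
  if (k < 2) stop("need at least 2 phenotype groups", call. = FALSE)

  obs <- !is.na(m)
  ncell <- vapply(groups, function(g)
    colSums(obs[labels == g, , drop = FALSE]), numeric(ncol(m)))
  if (ncol(m) == 1) ncell <- matrix(ncell, nrow = 1)
  tested <- rowSums(ncell >= min_n) == k
  n_excluded <- sum(!tested)
  if (!any(tested)) {
    res <- data.frame(protein = character(0))
    attr(res, "n_excluded") <- n_excluded
    return(res)
  }

  mt <- m[, tested, drop = FALSE]
  p <- ncol(mt)
  gi <- lapply(groups, function(g) which(labels == g))
  n_g <- vapply(gi, function(i) colSums(!is.na(mt[i, , drop = FALSE])),
                numeric(p))
  sum_g <- vapply(gi, function(i)
    colSums(mt[i, , drop = FALSE], na.rm = TRUE), numeric(p))
  if (p == 1) { n_g <- matrix(n_g, nrow = 1); sum_g <- matrix(sum_g, nrow = 1) }
  mean_g <- sum_g / n_g
  N <- rowSums(n_g)
  grand <- rowSums(sum_g) / N
  ssb <- rowSums(n_g * (mean_g - grand)^2)
  sst <- colSums(sweep(mt, 2, grand, `-`)^2, na.rm = TRUE)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- N - k
  mse <- ssw / df2
  f <- (ssb / df1) / mse
  p_anova <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # degenerate cases: no within-group variance
  p_anova[ssw == 0 & ssb <= 1e-12 * pmax(sst, 1)] <- 1
  p_anova[!is.finite(p_anova)] <- 1
  p_fdr <- stats::p.adjust(p_anova, method = "BH")

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  res <- data.frame(protein = colnames(mt), stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    res[[paste0("n_", groups[g])]] <- n_g[, g]
    res[[paste0("mean_", groups[g])]] <- mean_g[, g]
  }
  res$p_anova <- p_anova
  res$p_fdr <- p_fdr
  for (pr in pairs) {
    i <- match(pr[1], groups); j <- match(pr[2], groups)
    diff <- mean_g[, j] - mean_g[, i]
    se <- sqrt(mse / 2 * (1 / n_g[, i] + 1 / n_g[, j]))
    q <- abs(diff) / se
    p_pair <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    p_pair[!is.finite(p_pair)] <- 1
    tag <- paste0(pr[1], pr[2])
    res[[paste0("p_", tag)]] <- p_pair
    res[[paste0("dir_", tag)]] <- ifelse(diff > 0, "up",
                                         ifelse(diff < 0, "down", "none"))
    res[[paste0("sig_", tag)]] <- p_fdr <= 0.05 & p_pair <= 0.05
  }
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  class(res) <- c("da_result", "data.frame")
  res
}

#' Integer-rounded percentages from counts
#'
#' @param counts Named count vector.
#' @param digits Rounding digits (default 0, matching baseline tables).
#' @return Percentages of the total.
#' @export
count_percent <- function(counts, digits = 0) {
  round(100 * counts / sum(counts), digits)
}

#' Baseline-characteristics table across phenotypes
#'
#' Continuous variables: median (IQR) per cluster, Kruskal-Wallis omnibus
#' test and pairwise Mann-Whitney tests with Bonferroni correction (x3 for
#' three clusters). Categorical variables: count (%) per cluster, chi-square
#' omnibus test and pairwise chi-square tests with Bonferroni correction.
#' Denominators are the available (non-missing) data points per variable.
#'
#' @param data Data frame or matrix of variables (rows = patients).
#' @param labels Phenotype per row.
#' @param categorical_vars Names of columns to treat as categorical.
#' @return Data frame, one row per variable (categorical variables with more
#'   than two levels get one row per level for the summaries): per-cluster
#'   summary strings, `p_omnibus` and pairwise Bonferroni-adjusted p-values.
#' @export
baseline_table <- function(data, labels, categorical_vars = character()) {
  data <- as.data.frame(data)
  labels <- as.character(labels)
  stopifnot(nrow(data) == length(labels))
  groups <- sort(unique(labels))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  rows <- list()
  for (v in colnames(data)) {
    x <- data[[v]]
    ok <- !is.na(x)
    xs <- x[ok]; ls <- labels[ok]
    if (length(unique(xs)) < 2) {
      warning("variable '", v, "' has a single distinct value; p set to 1")
      p_omni <- 1
      p_pair <- rep(NA_real_, n_pairs)
    } else if (v %in% categorical_vars) {
      p_omni <- suppressWarnings(
        stats::chisq.test(table(xs, ls))$p.value)
      p_pair <- vapply(pairs, function(pr) {
        sel <- ls %in% pr
        min(1, n_pairs * suppressWarnings(
          stats::chisq.test(table(xs[sel], ls[sel]))$p.value))
      }, numeric(1))
    } else {
      p_omni <- stats::kruskal.test(xs, factor(ls))$p.value
      p_pair <- vapply(pairs, function(pr) {
        min(1, n_pairs * suppressWarnings(
          stats::wilcox.test(xs[ls == pr[1]], xs[ls == pr[2]])$p.value))
      }, numeric(1))
    }
    summ <- vapply(groups, function(g) {
      xg <- xs[ls == g]
      if (v %in% categorical_vars) {
        # most frequent level shown; full tables belong in a dedicated export
        tb <- sort(table(xg), decreasing = TRUE)
        sprintf("%s: %d (%d%%)", names(tb)[1], tb[1],
                round(100 * tb[1] / length(xg)))
      } else {
        q <- stats::quantile(xg, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
      }
    }, character(1))
    row <- data.frame(variable = v, n = length(xs),
                      stringsAsFactors = FALSE)
    for (g in seq_along(groups)) row[[groups[g]]] <- summ[g]
    row$p_omnibus <- p_omni
    for (i in seq_along(pairs)) {
      row[[paste0("p_", pairs[[i]][1], pairs[[i]][2])]] <- p_pair[i]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear regression of a protein against a laboratory measurement
#'
#' Ordinary least squares on pairwise-complete observations, with the
#' Pearson correlation, its p-value and a 95% confidence band for the mean
#' regression line.
#'
#' @param protein Protein intensity vector.
#' @param lab Laboratory measurement vector (same length).
#' @return List: `slope`, `intercept`, `r`, `p`, `n`, and `band` (data frame
#'   `lab`, `fit`, `lwr`, `upr`).
#' @export
lab_regression <- function(protein, lab) {
  stopifnot(length(protein) == length(lab))
  ok <- !is.na(protein) & !is.na(lab)
  if (sum(ok) < 3) stop("need at least 3 paired observations", call. = FALSE)
  x <- lab[ok]; y <- protein[ok]
  if (stats::sd(x) == 0) stop("laboratory values have zero variance",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  ct <- if (stats::sd(y) == 0) list(estimate = NA_real_, p.value = NA_real_)
        else stats::cor.test(x, y)
  grid <- data.frame(x = seq(min(x), max(x), length.out = 100))
  band <- stats::predict(fit, grid, interval = "confidence", level = 0.95)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       band = data.frame(lab = grid$x, fit = band[, "fit"],
                         lwr = band[, "lwr"], upr = band[, "upr"]))
}
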