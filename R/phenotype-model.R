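#' Principal component reduction to an explained-variance target
#'
#' Runs PCA on the standardized matrix and keeps the smallest number of
#' leading components whose cumulative explained-variance ratio strictly
#' exceeds `variance_target`.
#'
#' @param z Numeric matrix without missing cells (z-scored variables, plus
#'   any appended indicator columns).
#' @param variance_target Fraction in (0, 1); default 0.70.
#' @return List with `pca` (list: `rotation`, `center`, `ratios`, `m`) and
#'   `scores` (rows projected on the first `m` components).
#' @export
fit_reduce <- function(z, variance_target = 0.70) {
  if (variance_target <= 0 || variance_target >= 1) {
    stop("variance_target must lie in (0, 1)", call. = FALSE)
  }
  if (anyNA(z)) stop("matrix must be fully imputed before PCA", call. = FALSE)
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  ratios <- p$sdev^2 / sum(p$sdev^2)
  m <- which(cumsum(ratios) > variance_target)[1]
  if (is.na(m)) m <- length(ratios)
  pca <- list(rotation = p$rotation, center = p$center, ratios = ratios,
              m = as.integer(m))
  list(pca = pca, scores = p$x[, seq_len(m), drop = FALSE])
}

# project new rows into the frozen component space
pca_project <- function(pca, z) {
  sweep(z, 2, pca$center, `-`) %*%
    pca$rotation[, seq_len(pca$m), drop = FALSE]
}

#' Fit k-means with multiple restarts under a fixed seed
#'
#' @param scores Score matrix (rows = patients).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_restarts Random restarts; the best solution by total
#'   within-cluster sum of squares is kept.
#' @return List with `labels` (1..k), `centers`, `inertia`, `sizes`.
#' @export
fit_kmeans <- function(scores, k, seed = 1, n_restarts = 10) {
  scores <- as.matrix(scores)
  if (k > nrow(scores)) {
    stop("k must not exceed the number of rows", call. = FALSE)
  }
  fit <- with_seed(seed,
    stats::kmeans(scores, centers = k, nstart = n_restarts, iter.max = 200))
  list(labels = stats::setNames(fit$cluster, rownames(scores)),
       centers = fit$centers, inertia = fit$tot.withinss,
       sizes = fit$size)
}

#' Select the cluster number by mean silhouette width
#'
#' Fits k-means for every candidate `k` and computes the mean silhouette
#' width on Euclidean distances; the `k` maximising the mean silhouette is
#' selected. Candidates producing an empty cluster are marked invalid and
#' excluded from the argmax.
#'
#' @param scores Score matrix.
#' @param k_range Candidate cluster numbers (default 2..8).
#' @param seed Integer seed.
#' @param n_restarts Restarts per candidate.
#' @return List with `k` (selected) and `curve` (data frame `k`,
#'   `silhouette`, `valid`).
#' @export
silhouette_select_k <- function(scores, k_range = 2:8, seed = 1,
                                n_restarts = 10) {
  scores <- as.matrix(scores)
  if (nrow(scores) <= max(k_range)) {
    stop("need more rows than max(k_range)", call. = FALSE)
  }
  d <- stats::dist(scores)
  sil <- rep(NA_real_, length(k_range))
  valid <- rep(FALSE, length(k_range))
  for (i in seq_along(k_range)) {
    km <- fit_kmeans(scores, k_range[i], seed = child_seed(seed, k_range[i]),
                     n_restarts = n_restarts)
    if (any(km$sizes == 0)) next
    s <- cluster::silhouette(unname(km$labels), d)
    sil[i] <- mean(s[, "sil_width"])
    valid[i] <- TRUE
  }
  if (!any(valid)) stop("no valid clustering in k_range", call. = FALSE)
  curve <- data.frame(k = k_range, silhouette = sil, valid = valid)
  list(k = k_range[valid][which.max(sil[valid])], curve = curve)
}

#' Derive sepsis phenotypes from the day-1 matrix
#'
#' The single fitting entry point: chains the frozen standardizer, PCA to the
#' explained-variance target, silhouette-based selection of the cluster
#' number and k-means, then names clusters by descending size (the largest
#' cluster is phenotype "A"). The returned object freezes every parameter
#' (day-1 means/SDs, loadings, centroids) so later days can be projected
#' reproducibly with [predict.phenotype_model()].
#'
#' @param day1 Fully imputed day-1 matrix (patients x numeric variables).
#' @param variance_target Explained-variance target for PCA (default 0.70,
#'   strict inequality).
#' @param k_range Candidate cluster numbers for silhouette selection; a
#'   single value skips selection and fixes `k`.
#' @param seed Integer seed driving k-means restarts.
#' @param focus Optional named character vector (or single-column data frame)
#'   of infection-focus categories per patient; encoded as one-hot indicator
#'   columns appended after z-scoring (the indicators themselves are not
#'   z-scored).
#' @param n_restarts k-means restarts (default 10).
#' @return Object of class `phenotype_model`.
#' @export
derive_phenotypes <- function(day1, variance_target = 0.70, k_range = 2:8,
                              seed = 1, focus = NULL, n_restarts = 10) {
  if (anyNA(day1)) stop("day-1 matrix must be fully imputed", call. = FALSE)
  std <- fit_standardizer(day1)
  z <- apply_standardizer(std, day1)
  focus_levels <- NULL
  if (!is.null(focus)) {
    if (is.data.frame(focus)) {
      focus <- stats::setNames(as.character(focus$focus), focus$patient_id)
    }
    focus <- focus[rownames(day1)]
    focus_levels <- sort(unique(as.character(focus)))
    z <- cbind(z, one_hot(focus, levels = focus_levels))
  }
  red <- fit_reduce(z, variance_target)
  if (length(k_range) > 1) {
    sel <- silhouette_select_k(red$scores, k_range,
                               seed = child_seed(seed, "silhouette"),
                               n_restarts = n_restarts)
  } else {
    sel <- list(k = k_range, curve = NULL)
  }
  km <- fit_kmeans(red$scores, sel$k, seed = child_seed(seed, "kmeans"),
                   n_restarts = n_restarts)
  ## letters by descending cluster size; ties broken by lower cluster index
  ord <- order(-km$sizes, seq_along(km$sizes))
  label_order <- stats::setNames(LETTERS[order(ord)], seq_along(km$sizes))
  labels <- stats::setNames(unname(label_order[as.character(km$labels)]),
                            names(km$labels))
  structure(
    list(standardizer = std, pca = red$pca,
         centroids = km$centers, k = sel$k,
         label_order = label_order, sizes = km$sizes,
         silhouette = sel$curve, inertia = km$inertia,
         labels = labels, focus_levels = focus_levels,
         variance_target = variance_target, seed = seed),
    class = "phenotype_model"
  )
}

# standardize + append indicators + project, shared by fit and predict
model_scores <- function(object, newdata, focus = NULL) {
  z <- apply_standardizer(object$standardizer, newdata)
  if (!is.null(object$focus_levels)) {
    if (is.null(focus)) {
      stop("model was fitted with infection-focus indicators; supply `focus`",
           call. = FALSE)
    }
    if (is.data.frame(focus)) {
      focus <- stats::setNames(as.character(focus$focus), focus$patient_id)
    }
    z <- cbind(z, one_hot(focus[rownames(newdata)],
                          levels = object$focus_levels))
  }
  pca_project(object$pca, z)
}

#' Assign score rows to the nearest phenotype centroid
#'
#' Euclidean distance in the frozen component space; ties go to the lower
#' cluster index (hence the earlier letter in size order).
#'
#' @param scores Score matrix with `m` columns.
#' @param model A `phenotype_model`.
#' @return Named character vector of phenotype letters.
#' @export
assign_nearest_centroid <- function(scores, model) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) {
    stop("scores contain non-finite values", call. = FALSE)
  }
  if (ncol(scores) != ncol(model$centroids)) {
    stop("score dimensionality (", ncol(scores), ") does not match the ",
         "model's component count (", ncol(model$centroids), ")",
         call. = FALSE)
  }
  # direct differences (not the expanded quadratic form) so exact ties
  # survive floating point and resolve toward the lower cluster index
  d2 <- vapply(seq_len(nrow(model$centroids)), function(j)
    rowSums(sweep(scores, 2, model$centroids[j, ], `-`)^2),
    numeric(nrow(scores)))
  if (nrow(scores) == 1) d2 <- matrix(d2, nrow = 1)
  idx <- apply(d2, 1, which.min)
  stats::setNames(unname(model$label_order[as.character(idx)]),
                  rownames(scores))
}

#' Project new data with the frozen day-1 parameters
#'
#' @param object A `phenotype_model`.
#' @param newdata Imputed matrix with the fitted columns (any assessment
#'   day).
#' @param focus Infection-focus vector if the model used indicators.
#' @param type `"class"` for phenotype letters (frozen standardization, PCA
#'   projection, nearest-centroid assignment) or `"scores"` for the projected
#'   component scores.
#' @param ... Unused.
#' @return Named character vector of letters, or a score matrix.
#' @export
predict.phenotype_model <- function(object, newdata, focus = NULL,
                                    type = c("class", "scores"), ...) {
  type <- match.arg(type)
  sc <- model_scores(object, newdata, focus)
  if (type == "scores") return(sc)
  assign_nearest_centroid(sc, object)
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("Sepsis phenotype model (frozen day-1 standardizer + PCA + k-means)\n")
  cat("  patients fitted :", length(x$labels), "\n")
  cat("  components kept :", x$pca$m, sprintf("(> %.0f%% of variance)\n",
                                              100 * x$variance_target))
  cat("  clusters        :", x$k, "\n")
  sz <- table(x$labels)
  cat("  phenotypes      :",
      paste(sprintf("%s=%d (%d%%)", names(sz), sz,
                    round(100 * sz / sum(sz))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.phenotype_model <- function(object, ...) {
  out <- list(
    k = object$k, m = object$pca$m,
    explained = sum(object$pca$ratios[seq_len(object$pca$m)]),
    sizes = table(object$labels),
    silhouette = object$silhouette, inertia = object$inertia
  )
  class(out) <- "summary.phenotype_model"
  out
}

#' @export
print.summary.phenotype_model <- function(x, ...) {
  cat("Phenotype model summary\n")
  cat(sprintf("  %d clusters on %d components (%.1f%% variance explained)\n",
              x$k, x$m, 100 * x$explained))
  print(x$sizes)
  if (!is.null(x$silhouette)) {
    cat("  silhouette curve:\n")
    print(x$silhouette, row.names = FALSE)
  }
  invisible(x)
}

#' @export
fitted.phenotype_model <- function(object, ...) object$labels

#' @export
coef.phenotype_model <- function(object, ...) object$centroids

#' Plot the silhouette curve used for cluster-number selection
#'
#' @param x A `phenotype_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phenotype_model <- function(x, ...) {
  if (is.null(x$silhouette)) {
    stop("model was fitted with a fixed k; no silhouette curve to plot",
         call. = FALSE)
  }
  graphics::plot(x$silhouette$k, x$silhouette$silhouette, type = "b",
                 xlab = "number of clusters k",
                 ylab = "mean silhouette width", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Serialize a phenotype model to JSON
#'
#' All frozen parameters (day-1 means/SDs, loadings, centroids, label order)
#' are written with full floating-point precision so the reloaded model
#' reproduces projections bit-exactly.
#'
#' @param model A `phenotype_model`.
#' @param path Output file path.
#' @export
write_phenotype_model <- function(model, path) {
  x <- list(
    mean = as.list(model$standardizer$mean),
    sd = as.list(model$standardizer$sd),
    variables = model$standardizer$variables,
    rotation = model$pca$rotation, rotation_rows = rownames(model$pca$rotation),
    center = as.list(model$pca$center),
    ratios = model$pca$ratios, m = model$pca$m,
    centroids = model$centroids, k = model$k,
    label_order = as.list(model$label_order),
    sizes = model$sizes, focus_levels = model$focus_levels,
    variance_target = model$variance_target, seed = model$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Reload a serialized phenotype model
#'
#' @param path Path written by [write_phenotype_model()].
#' @return A `phenotype_model` (without the fitted labels/silhouette curve,
#'   which are fit-time artefacts).
#' @export
read_phenotype_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- x$rotation
  rownames(rot) <- x$rotation_rows
  colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  cen <- x$centroids
  rownames(cen) <- seq_len(nrow(cen))
  colnames(cen) <- paste0("PC", seq_len(ncol(cen)))
  std <- structure(list(mean = unlist(x$mean)[x$variables],
                        sd = unlist(x$sd)[x$variables],
                        variables = x$variables),
                   class = "standardizer")
  structure(
    list(standardizer = std,
         pca = list(rotation = rot,
                    center = unlist(x$center)[rownames(rot)],
                    ratios = x$ratios, m = as.integer(x$m)),
         centroids = cen, k = as.integer(x$k),
         label_order = stats::setNames(unlist(x$label_order),
                                       names(x$label_order)),
         sizes = x$sizes, silhouette = NULL, inertia = NULL,
         labels = NULL,
         focus_levels = if (length(x$focus_levels)) x$focus_levels else NULL,
         variance_target = x$variance_target, seed = x$seed),
    class = "phenotype_model"
  )
}
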