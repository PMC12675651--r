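#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never disturbs the
#' caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic child seed from a master seed
#'
#' One master seed drives a whole pipeline run; each stochastic stage gets its
#' own stream via `child_seed(master, stage_index)`. The scheme is recorded in
#' the run manifest so any single stage can be replayed bit-identically.
#'
#' @param seed Master seed (integer).
#' @param k Stage index (non-negative integer) or stage name (hashed).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  if (is.character(k)) {
    k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 30269 + 1013) %%
               (.Machine$integer.max - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as CSV with round-trip-stable floats
#'
#' Numeric columns are serialized with 17 significant digits so that reading
#' the file back reproduces the doubles bit-identically; missing values are
#' empty fields.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_csv17 <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) {
      v <- sprintf("%.17g", x[[j]])
      v[is.na(x[[j]])] <- NA_character_
      x[[j]] <- v
    }
  }
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Stratified train/test split indices
#'
#' Samples `frac` of each class (rounded, at least one row per class) into the
#' training set. Guarantees every class present in both partitions when each
#' class has at least two rows.
#'
#' @param y Class labels (factor or character).
#' @param frac Training fraction in (0, 1).
#' @return List with integer vectors `train` and `test`.
#' @keywords internal
stratified_split <- function(y, frac = 0.7) {
  y <- as.character(y)
  train <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# one-hot encoding of a categorical patient covariate; level set can be frozen
# so later days use the day-1 column layout
one_hot <- function(x, levels = NULL, prefix = "focus") {
  x <- as.character(x)
  levels <- levels %||% sort(unique(x))
  m <- vapply(levels, function(l) as.numeric(x == l), numeric(length(x)))
  m <- matrix(m, nrow = length(x),
              dimnames = list(names(x), paste0(prefix, "_", levels)))
  m
}
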