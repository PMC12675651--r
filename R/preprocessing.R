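#' Select clustering variables by day-1 missingness
#'
#' A variable is retained when its day-1 patient-level missing fraction is
#' strictly below `threshold` and it is not on the exclusion list (treatment
#' surrogates such as vasopressor doses). The denominator is the number of
#' patients with at least one observation of any variable on the given day.
#'
#' @param table Long observation table (`patient_id`, `day`, `variable`,
#'   `value`).
#' @param day Assessment day used for the filter (default 1).
#' @param threshold Missing-fraction cutoff (default 0.30, strict).
#' @param exclusions Character vector of variable names to drop regardless.
#' @param aggregation Named character vector mapping variable name to one of
#'   `"median"`, `"min"`, `"max"`; defaults to the packaged catalogue.
#' @return Data frame of variable specs: `variable`, `aggregation`,
#'   `missing_fraction`, `retained`.
#' @export
select_variables <- function(table, day = 1, threshold = 0.30,
                             exclusions = character(), aggregation = NULL) {
  if (!nrow(table)) stop("empty observation table", call. = FALSE)
  if (is.null(aggregation)) {
    cv <- clinical_variables()
    aggregation <- stats::setNames(cv$aggregation, cv$variable)
    exclusions <- union(exclusions, cv$variable[cv$exclude])
  }
  d <- table[table$day == day & !is.na(table$value), ]
  denom <- length(unique(d$patient_id))
  if (denom == 0) stop("no observations on day ", day, call. = FALSE)
  vars <- sort(unique(table$variable))
  nobs <- vapply(vars, function(v)
    length(unique(d$patient_id[d$variable == v])), integer(1))
  miss <- 1 - nobs / denom
  agg <- unname(aggregation[vars])
  agg[is.na(agg)] <- "median"
  data.frame(variable = vars, aggregation = agg, missing_fraction = miss,
             retained = miss < threshold & !(vars %in% exclusions),
             row.names = NULL, stringsAsFactors = FALSE)
}

agg_fun <- function(rule) {
  switch(rule,
         median = function(x) stats::median(x),
         min = function(x) min(x),
         max = function(x) max(x),
         stop("unknown aggregation rule: ", rule, call. = FALSE))
}

#' Aggregate repeated daily observations into per-day patient matrices
#'
#' For every patient, day and retained variable with at least one
#' observation, applies the variable's aggregation rule (median, min or max)
#' to that day's observations; cells without observations are `NA`. The
#' column set is identical across days.
#'
#' @param table Long observation table.
#' @param specs Variable specs from [select_variables()]; only retained
#'   variables become columns.
#' @return Named list (one element per day, names `"1"`, `"4"`, ...) of
#'   numeric matrices with patient-id rownames and a `"day"` attribute.
#' @export
aggregate_daily <- function(table, specs) {
  keep <- specs[specs$retained, , drop = FALSE]
  if (any(is.na(keep$aggregation))) {
    stop("every retained variable needs an aggregation rule", call. = FALSE)
  }
  tab <- table[table$variable %in% keep$variable & !is.na(table$value), ]
  days <- sort(unique(table$day))
  out <- vector("list", length(days))
  names(out) <- as.character(days)
  for (i in seq_along(days)) {
    d <- tab[tab$day == days[i], ]
    pats <- sort(unique(table$patient_id[table$day == days[i] &
                                           !is.na(table$value)]))
    m <- matrix(NA_real_, length(pats), nrow(keep),
                dimnames = list(pats, keep$variable))
    for (v in seq_len(nrow(keep))) {
      dv <- d[d$variable == keep$variable[v], ]
      if (!nrow(dv)) next
      val <- tapply(dv$value, dv$patient_id, agg_fun(keep$aggregation[v]))
      m[names(val), v] <- as.numeric(val)
    }
    attr(m, "day") <- days[i]
    out[[i]] <- m
  }
  out
}

#' Impute a day matrix by two-day lookahead, then cohort median
#'
#' An absent cell is filled with the same patient's value from the nearer of
#' the two subsequent assessment days; if neither is available, the cohort
#' median of the variable is used. Observed cells are never altered.
#'
#' @param day1 Matrix to impute (patients x variables).
#' @param day2,day3 The two subsequent day matrices (may omit patients);
#'   either may be `NULL`.
#' @param fallback Optional named vector of frozen per-variable medians. When
#'   `NULL` (the day-1 use case) medians are computed from the observed cells
#'   of `day1` itself. Later-day imputation passes the frozen day-1 medians
#'   so that no information leaks backwards across days.
#' @return The imputed matrix; no `NA` cells remain.
#' @export
impute_lookahead <- function(day1, day2 = NULL, day3 = NULL, fallback = NULL) {
  out <- day1
  for (nxt in list(day2, day3)) {
    if (is.null(nxt)) next
    common <- intersect(rownames(out), rownames(nxt))
    for (v in colnames(out)) {
      need <- common[is.na(out[common, v]) & !is.na(nxt[common, v])]
      if (length(need)) out[need, v] <- nxt[need, v]
    }
  }
  med <- fallback
  if (is.null(med)) {
    med <- apply(day1, 2, stats::median, na.rm = TRUE)
  }
  for (v in colnames(out)) {
    if (anyNA(out[, v])) {
      if (!is.finite(med[v])) {
        stop("variable '", v, "' has no observed values to impute from",
             call. = FALSE)
      }
      out[is.na(out[, v]), v] <- med[v]
    }
  }
  attr(out, "day") <- attr(day1, "day")
  out
}

#' Clamp a concentration at the quantification limits
#'
#' Values below the lower limit of quantification are recorded as 0; values
#' above the upper limit are replaced by the upper limit; the limits
#' themselves pass through unchanged.
#'
#' @param value Numeric vector of raw concentrations.
#' @param lloq,uloq Lower / upper limit of quantification, `lloq < uloq`.
#' @return Clamped numeric vector, every element in `{0} U [lloq, uloq]`.
#' @export
clamp_limits <- function(value, lloq, uloq) {
  if (any(lloq >= uloq)) stop("lloq must be smaller than uloq", call. = FALSE)
  ifelse(value < lloq, 0, pmin(value, uloq))
}

#' Fit a frozen z-score standardizer on the day-1 matrix
#'
#' Stores per-variable mean and sample standard deviation (n - 1 denominator)
#' so that any later day can be transformed with the day-1 parameters.
#'
#' @param day1 Fully imputed numeric matrix (patients x variables).
#' @return Object of class `standardizer` with elements `mean`, `sd`,
#'   `variables`.
#' @export
fit_standardizer <- function(day1) {
  if (anyNA(day1)) stop("standardizer requires a fully imputed matrix",
                        call. = FALSE)
  mu <- colMeans(day1)
  sd <- apply(day1, 2, stats::sd)
  bad <- colnames(day1)[sd == 0 | !is.finite(sd)]
  if (length(bad)) {
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(mean = mu, sd = sd, variables = colnames(day1)),
            class = "standardizer")
}

#' Apply (or invert) a frozen standardizer
#'
#' @param s A [fit_standardizer()] object.
#' @param m Matrix whose columns match the fitted variables.
#' @param inverse If `TRUE`, map z-scores back to the original scale.
#' @return Transformed matrix.
#' @export
apply_standardizer <- function(s, m, inverse = FALSE) {
  stopifnot(inherits(s, "standardizer"))
  if (!identical(colnames(m), s$variables)) {
    missing_v <- setdiff(s$variables, colnames(m))
    extra_v <- setdiff(colnames(m), s$variables)
    stop("column mismatch with fitted standardizer; missing: [",
         paste(missing_v, collapse = ", "), "], unexpected: [",
         paste(extra_v, collapse = ", "), "]", call. = FALSE)
  }
  if (inverse) {
    sweep(sweep(m, 2, s$sd, `*`), 2, s$mean, `+`)
  } else {
    sweep(sweep(m, 2, s$mean, `-`), 2, s$sd, `/`)
  }
}
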