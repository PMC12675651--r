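# shared fixtures, all generated in code

# a tiny variable catalogue so large-n generator checks stay fast
tiny_variables <- function() {
  data.frame(
    variable = c("lactate", "map", "creatinine"),
    dist = c("lognormal", "normal", "lognormal"),
    location = c(0.6931, 85, 0),
    scale = c(0.4, 10, 0.4),
    aggregation = c("max", "min", "max"),
    exclude = FALSE,
    stringsAsFactors = FALSE
  )
}

# default-sized cohort clustered end to end; memoised per session because
# several tests inspect the same fitted model
fitted_default_cohort <- local({
  cache <- NULL
  function(seed = 42) {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_patients = 384, seed = seed)
    co <- generate_cohort(cfg)
    specs <- select_variables(co$observations)
    daily <- aggregate_daily(co$observations, specs)
    d1 <- impute_lookahead(daily[[1]], daily[[2]], daily[[3]])
    model <- derive_phenotypes(d1, seed = seed, focus = co$focus)
    cache <<- list(cohort = co, specs = specs, daily = daily, day1 = d1,
                   model = model)
    cache
  }
})

# long observation table built by hand for preprocessing unit tests
toy_long_table <- function() {
  data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p2", "p3", "p1", "p2", "p2"),
    day = c(1, 1, 1, 1, 1, 1, 4, 4, 4),
    variable = c("creatinine", "creatinine", "creatinine", "map", "map",
                 "creatinine", "creatinine", "creatinine", "map"),
    value = c(1.0, 1.6, 1.2, 80, 90, 7.31, 2.0, 1.1, 70),
    stringsAsFactors = FALSE
  )
}

# three well-separated Gaussian blobs in the plane
three_blobs <- function(n_per = 50, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  x <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(n_per, centers[i, 1]), rnorm(n_per, centers[i, 2]))))
  rownames(x) <- sprintf("r%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(1:3, each = n_per))
}

# separable three-class data with a given class imbalance
separable_classes <- function(n = c(60, 45, 15), sep = 6, seed = 1) {
  set.seed(seed)
  lab <- rep(c("A", "B", "C"), n)
  mu <- c(A = 0, B = sep, C = 2 * sep)
  x <- cbind(f1 = rnorm(sum(n), mu[lab]),
             f2 = rnorm(sum(n), mu[lab] / 2))
  rownames(x) <- sprintf("s%03d", seq_len(sum(n)))
  list(x = x, y = stats::setNames(lab, rownames(x)))
}
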