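test_that("batch median normalization removes constructed offsets", {
  set.seed(3)
  base <- matrix(rnorm(60, 20), 20, 3, dimnames = list(NULL, c("P1", "P2", "P3")))
  batch <- rep(c("b1", "b2"), each = 10)
  shifted <- base
  shifted[batch == "b1", ] <- shifted[batch == "b1", ] + 1
  shifted[batch == "b2", ] <- shifted[batch == "b2", ] - 1
  norm <- normalize_batches(shifted, batch)
  for (p in colnames(norm)) {
    expect_lt(abs(stats::median(norm[batch == "b1", p]) -
                    stats::median(norm[batch == "b2", p])), 1e-9)
  }
  # single batch is a no-op
  expect_equal(normalize_batches(base, rep("b1", 20)), base,
               tolerance = 1e-12)
  # missing cells stay missing
  withna <- shifted
  withna[1, 1] <- NA
  expect_true(is.na(normalize_batches(withna, batch)[1, 1]))
  expect_error(normalize_batches(base, rep(c("b1", "b2"), c(18, 2))),
               "at least 3")
})

test_that("batch normalization reduces inter-batch spread on generator output", {
  cfg <- sim_config(n_patients = 200, days = 1, seed = 14, n_proteins = 100,
                    batch_effect_sd = 1, variables = tiny_variables())
  co <- generate_cohort(cfg)
  pm <- generate_proteome(co$truth, cfg)
  spread <- function(m) {
    meds <- sapply(sort(unique(pm$batch)), function(b)
      apply(m[pm$batch == b, , drop = FALSE], 2, stats::median, na.rm = TRUE))
    mean(apply(meds, 1, function(r) max(r) - min(r)))
  }
  norm <- normalize_batches(pm$intensity, pm$batch)
  expect_lt(spread(norm), spread(pm$intensity))
})

test_that("Benjamini-Hochberg step-up matches hand arithmetic and is monotone", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(4)
  m <- matrix(rnorm(45 * 30, 20), 45, 30,
              dimnames = list(NULL, sprintf("P%02d", 1:30)))
  labels <- rep(c("A", "B", "C"), each = 15)
  da <- differential_abundance(m, labels)
  expect_equal(da$p_fdr, stats::p.adjust(da$p_anova, "BH"))
  ord <- order(da$p_anova)
  expect_true(all(diff(da$p_fdr[ord]) >= -1e-12))
  expect_true(all(da$p_fdr >= da$p_anova - 1e-12))
  expect_true(all(da$p_fdr <= 1))
})

test_that("vectorised ANOVA and Tukey p-values match aov/TukeyHSD", {
  set.seed(5)
  n <- c(A = 12, B = 9, C = 7)  # unbalanced on purpose
  labels <- rep(names(n), n)
  m <- matrix(rnorm(sum(n) * 20, 20), sum(n), 20,
              dimnames = list(NULL, sprintf("P%02d", 1:20)))
  m[, 1:5] <- m[, 1:5] + outer(as.numeric(factor(labels)), rep(1, 5))
  da <- differential_abundance(m, labels, min_n = 5)
  for (j in c(1, 3, 11, 20)) {
    fit <- stats::aov(m[, j] ~ factor(labels))
    p_ref <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)[[1]]
    expect_equal(da$p_anova[j], p_ref, tolerance = 1e-8)
    expect_equal(da$p_AB[j], tk["B-A", "p adj"], tolerance = 1e-6)
    expect_equal(da$p_AC[j], tk["C-A", "p adj"], tolerance = 1e-6)
    expect_equal(da$p_BC[j], tk["C-B", "p adj"], tolerance = 1e-6)
  }
  # dual criterion: flag iff p_fdr <= 0.05 AND pairwise p <= 0.05
  expect_identical(da$sig_AC, da$p_fdr <= 0.05 & da$p_AC <= 0.05)
})

test_that("Tukey p-value agrees with a max-statistic permutation oracle", {
  # one constructed 3 x 5 instance; the oracle permutes labels and compares
  # the family-wise maximum studentised range statistic
  x <- c(4.1, 5.0, 4.4, 4.8, 4.3,
         5.6, 5.1, 6.0, 5.4, 5.9,
         6.4, 7.0, 6.1, 6.8, 6.7)
  labels <- rep(c("A", "B", "C"), each = 5)
  da <- differential_abundance(matrix(x, ncol = 1,
                                      dimnames = list(NULL, "P1")),
                               labels, min_n = 5)
  obs <- abs(mean(x[1:5]) - mean(x[6:10])) /
    sqrt((sum((x[1:5] - mean(x[1:5]))^2) +
            sum((x[6:10] - mean(x[6:10]))^2) +
            sum((x[11:15] - mean(x[11:15]))^2)) / 12 / 5)
  set.seed(99)
  nperm <- 100000
  idx <- replicate(nperm, sample.int(15))
  gsum <- function(rows) colSums(matrix(x[idx[rows, ]], length(rows)))
  gsq <- function(rows) colSums(matrix(x[idx[rows, ]]^2, length(rows)))
  s1 <- gsum(1:5); s2 <- gsum(6:10); s3 <- gsum(11:15)
  ssw <- (gsq(1:5) - s1^2 / 5) + (gsq(6:10) - s2^2 / 5) +
    (gsq(11:15) - s3^2 / 5)
  se <- sqrt(ssw / 12 / 5)  # sqrt(mse / 2 * (1/5 + 1/5))
  qmax <- pmax(abs(s1 - s2), abs(s1 - s3), abs(s2 - s3)) / 5 / se
  p_oracle <- mean(qmax >= obs)
  expect_lt(abs(da$p_AB[1] - p_oracle), 0.06)
})

test_that("the minimum-observation filter runs before testing and BH", {
  set.seed(6)
  m <- matrix(rnorm(30 * 10, 20), 30, 10,
              dimnames = list(NULL, sprintf("P%02d", 1:10)))
  labels <- rep(c("A", "B", "C"), each = 10)
  m[labels == "C", 1:4] <- NA  # first four proteins fail min_n in C
  da <- differential_abundance(m, labels, min_n = 5)
  expect_equal(nrow(da), 6)
  expect_equal(attr(da, "n_excluded"), 4)
  expect_false(any(sprintf("P%02d", 1:4) %in% da$protein))
  # BH universe is the tested set only
  expect_equal(da$p_fdr, stats::p.adjust(da$p_anova, "BH"))
  # all identical values: p = 1 by convention, never flagged
  flat <- matrix(5, 30, 1, dimnames = list(NULL, "F1"))
  daf <- differential_abundance(flat, labels, min_n = 5)
  expect_equal(daf$p_anova, 1)
  expect_false(daf$sig_AB)
})

test_that("null proteomes keep the dual-criterion flag rate controlled", {
  # type-I check: 50 null replicates, 3 x 20 samples, 500 proteins
  rates <- vapply(1:50, function(rep) {
    set.seed(1000 + rep)
    m <- matrix(rnorm(60 * 500, 20), 60, 500,
                dimnames = list(NULL, sprintf("P%03d", 1:500)))
    labels <- rep(c("A", "B", "C"), each = 20)
    da <- differential_abundance(m, labels)
    mean(da$sig_AB | da$sig_AC | da$sig_BC)
  }, numeric(1))
  bound <- 0.05 + 3 * stats::sd(rates) / sqrt(length(rates))
  expect_lte(mean(rates), bound)
})

test_that("gradient proteins are reliably flagged at default effect sizes", {
  hits <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_patients = 250, days = 1, seed = seed,
                      n_proteins = 110, variables = tiny_variables())
    co <- generate_cohort(cfg)
    pm <- generate_proteome(co$truth, cfg)
    norm <- normalize_batches(pm$intensity, pm$batch)
    da <- differential_abundance(norm, pm$phenotype)
    grad <- da[da$protein %in% pm$sets$gradient, ]
    mean(grad$sig_AC)
  }, numeric(1))
  expect_gte(mean(hits >= 0.8), 0.8)
})

test_that("baseline table reproduces contingency arithmetic and test choices", {
  expect_equal(unname(count_percent(c(202, 156, 26))), c(53, 41, 7))
  set.seed(7)
  n <- c(A = 60, B = 50, C = 20)
  labels <- rep(names(n), n)
  d <- data.frame(
    sofa = c(rnorm(60, 7, 2), rnorm(50, 10, 2), rnorm(20, 15, 2)),
    sex = sample(c("f", "m"), sum(n), replace = TRUE)
  )
  bt <- baseline_table(d, labels, categorical_vars = "sex")
  expect_equal(nrow(bt), 2)
  sofa <- bt[bt$variable == "sofa", ]
  expect_equal(sofa$p_omnibus,
               stats::kruskal.test(d$sofa, factor(labels))$p.value)
  raw_ab <- stats::wilcox.test(d$sofa[labels == "A"],
                               d$sofa[labels == "B"])$p.value
  expect_equal(sofa$p_AB, min(1, 3 * raw_ab))
  sex <- bt[bt$variable == "sex", ]
  expect_equal(sex$p_omnibus,
               suppressWarnings(stats::chisq.test(table(d$sex,
                                                        labels))$p.value))
  # single-valued variable: omnibus p forced to 1 with a warning
  d2 <- data.frame(flat = rep(1, sum(n)))
  expect_warning(bt2 <- baseline_table(d2, labels), "single distinct")
  expect_equal(bt2$p_omnibus, 1)
})

test_that("omnibus p-values are calibrated under the null", {
  set.seed(8)
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    x <- rnorm(60)
    stats::kruskal.test(x, factor(rep(c("A", "B", "C"), each = 20)))$p.value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("protein-lab regression recovers exact and null relations", {
  x <- 1:20
  y <- 2 * x + 1
  r <- lab_regression(y, x)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_true(all(r$band$upr >= r$band$fit & r$band$fit >= r$band$lwr))
  set.seed(9)
  xs <- rnorm(200)
  ys <- sample(xs)  # shuffled: no association
  rs <- lab_regression(ys, xs)
  expect_lt(abs(rs$r), 0.2)
  expect_gt(rs$p, 0.001)
  expect_error(lab_regression(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(lab_regression(c(1, 2), c(1, 2)), "at least 3")
})
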