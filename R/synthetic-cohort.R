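#' Simulation configuration for the synthetic sepsis cohort
#'
#' @param n_patients Number of patients.
#' @param days Assessment-day grid (study days, day 1 = sepsis diagnosis).
#' @param n_proteins Number of plasma proteins in the simulated proteome.
#' @param n_batches Number of proteomics processing batches.
#' @param batch_effect_sd Standard deviation (log2-intensity units) of the
#'   additive per-batch, per-protein offset.
#' @param missing_rate Per patient-day-variable probability that a clinical
#'   variable goes unrecorded (MCAR); must stay below 0.30 so that retained
#'   variables survive the selection filter.
#' @param protein_missing_rate Per-cell missingness of the protein matrix.
#' @param obs_rate Poisson mean of extra same-day repeat measurements; the
#'   number of observations per variable-day is `1 + Poisson(obs_rate)`.
#' @param seed Integer seed; fully determines all generator output.
#' @param variables Variable catalogue, defaults to [clinical_variables()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 384, days = c(1, 4, 7, 10),
                       n_proteins = 609, n_batches = 4, batch_effect_sd = 0.5,
                       missing_rate = 0.10, protein_missing_rate = 0.05,
                       obs_rate = 2, seed = 1, variables = clinical_variables()) {
  if (missing_rate < 0 || missing_rate >= 0.30) {
    stop("missing_rate must lie in [0, 0.30) for retained variables",
         call. = FALSE)
  }
  if (n_patients < 1 || n_batches < 1 || obs_rate < 0) {
    stop("invalid sim_config sizing", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), days = sort(days),
                 n_proteins = as.integer(n_proteins),
                 n_batches = as.integer(n_batches),
                 batch_effect_sd = batch_effect_sd,
                 missing_rate = missing_rate,
                 protein_missing_rate = protein_missing_rate,
                 obs_rate = obs_rate, seed = as.integer(seed),
                 variables = variables),
            class = "sim_config")
}

# draw observation values for one (day, variable) chunk; parameters are
# per-patient because the location shift depends on the latent state
draw_values <- function(n_obs, dist, location, scale, shift, smult) {
  mloc <- location + shift * scale
  msc <- scale * smult
  loc_rep <- rep(mloc, n_obs)
  sc_rep <- rep(msc, n_obs)
  if (dist == "lognormal") {
    stats::rlnorm(length(loc_rep), meanlog = loc_rep, sdlog = sc_rep)
  } else {
    stats::rnorm(length(loc_rep), mean = loc_rep, sd = sc_rep)
  }
}

#' Generate a synthetic sepsis cohort with ground truth
#'
#' Simulates day-1 latent phenotypes from the profile prevalences, evolves
#' each patient along the assessment-day grid with the profile transition
#' probabilities (death and discharge are absorbing: no observations exist
#' afterwards), and emits repeated daily measurements of each clinical
#' variable from the phenotype-shifted distributions, with MCAR missingness.
#' Patients alive after the last grid day die within 30 days with the
#' probability attached to their last latent state.
#'
#' @param config A [sim_config()].
#' @param profiles List of [phenotype_profile()]s; prevalences must sum to 1.
#' @return A list of class `synthetic_cohort` with elements
#'   `observations` (long data frame: `patient_id`, `day`, `variable`,
#'   `value`), `truth` (list with `states` — latent phenotype per alive
#'   patient-day — and `outcomes` — day-1 phenotype, death/discharge day,
#'   proteomics batch), `focus` (infection focus per patient), and the
#'   `config` and `profiles` used.
#' @export
generate_cohort <- function(config, profiles = default_profiles()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
  prev <- vapply(profiles, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev) - 1) > 1e-9) {
    stop("profile prevalences must sum to 1", call. = FALSE)
  }
  if (config$n_patients < 3 * length(profiles)) {
    stop("n_patients must be at least 3 x number of profiles", call. = FALSE)
  }
  labels <- vapply(profiles, `[[`, character(1), "label")
  names(profiles) <- labels
  vars <- config$variables
  days <- config$days

  with_seed(config$seed, {
    n <- config$n_patients
    pid <- sprintf("P%05d", seq_len(n))

    ## latent state trajectory over the grid
    state <- matrix(NA_character_, n, length(days),
                    dimnames = list(pid, paste0("day", days)))
    state[, 1] <- sample(labels, n, replace = TRUE, prob = prev)
    death_day <- rep(NA_real_, n)
    discharge_day <- rep(NA_real_, n)
    if (length(days) > 1) {
      for (t in 2:length(days)) {
        for (l in labels) {
          idx <- which(state[, t - 1] == l)
          if (!length(idx)) next
          tr <- profiles[[l]]$transition
          state[idx, t] <- sample(names(tr), length(idx), replace = TRUE,
                                  prob = tr)
        }
        died <- which(state[, t] == "deceased" & is.na(death_day))
        death_day[died] <- days[t]
        disc <- which(state[, t] == "discharged" & is.na(discharge_day))
        discharge_day[disc] <- days[t]
        # absorbing: keep the outcome label for all later grid days
        gone <- which(state[, t - 1] %in% c("deceased", "discharged"))
        state[gone, t] <- state[gone, t - 1]
      }
    }
    ## 30-day outcome for grid survivors, conditional on last latent state
    last <- state[, length(days)]
    alive <- which(last %in% labels)
    late_p <- vapply(profiles, `[[`, numeric(1), "mortality_30d")[last[alive]]
    late_die <- alive[stats::runif(length(alive)) < late_p]
    death_day[late_die] <- days[length(days)] +
      sample.int(30 - days[length(days)], length(late_die), replace = TRUE)

    batch <- sample.int(config$n_batches, n, replace = TRUE)
    focus <- character(n)
    for (l in labels) {
      idx <- which(state[, 1] == l)
      fpr <- profiles[[l]]$focus_probs
      if (is.null(fpr)) fpr <- stats::setNames(1, "unknown")
      focus[idx] <- sample(names(fpr), length(idx), replace = TRUE, prob = fpr)
    }

    ## per-profile shift / scale-multiplier lookup tables
    shift_mat <- matrix(0, length(labels), nrow(vars),
                        dimnames = list(labels, vars$variable))
    smult_mat <- matrix(1, length(labels), nrow(vars),
                        dimnames = list(labels, vars$variable))
    for (l in labels) {
      s <- profiles[[l]]$shifts
      s <- s[names(s) %in% vars$variable]
      if (length(s)) shift_mat[l, names(s)] <- s
      sm <- profiles[[l]]$scale_mult
      sm <- sm[names(sm) %in% vars$variable]
      if (length(sm)) smult_mat[l, names(sm)] <- sm
    }

    ## per-patient age (constant across days, shifted by day-1 state)
    vage <- vars[vars$variable == "age", ]
    age <- NULL
    if (nrow(vage) == 1) {
      shift <- shift_mat[state[, 1], "age"]
      age <- round(pmax(18, stats::rnorm(n, vage$location + shift * vage$scale,
                                         vage$scale)))
    }

    ## observations: one chunk per (day, variable)
    chunks <- vector("list", length(days) * nrow(vars))
    ci <- 0L
    for (t in seq_along(days)) {
      alive_t <- which(state[, t] %in% labels)
      if (!length(alive_t)) next
      st_t <- state[alive_t, t]
      for (v in seq_len(nrow(vars))) {
        vn <- vars$variable[v]
        if (vn == "age") {
          ci <- ci + 1L
          chunks[[ci]] <- data.frame(patient_id = pid[alive_t],
                                     day = days[t], variable = "age",
                                     value = age[alive_t],
                                     stringsAsFactors = FALSE)
          next
        }
        present <- alive_t[stats::runif(length(alive_t)) >= config$missing_rate]
        if (!length(present)) next
        st_p <- state[present, t]
        shift <- shift_mat[st_p, vn]
        smult <- smult_mat[st_p, vn]
        n_obs <- 1L + stats::rpois(length(present), config$obs_rate)
        val <- draw_values(n_obs, vars$dist[v], vars$location[v],
                           vars$scale[v], shift, smult)
        if (vars$dist[v] == "normal" && vn != "base_excess") {
          val <- pmax(val, 0)
        }
        ci <- ci + 1L
        chunks[[ci]] <- data.frame(patient_id = rep(pid[present], n_obs),
                                   day = days[t], variable = vn, value = val,
                                   stringsAsFactors = FALSE)
      }
    }
    obs <- do.call(rbind, chunks[seq_len(ci)])
    obs <- obs[order(obs$patient_id, obs$day, obs$variable), ]
    rownames(obs) <- NULL

    states_long <- do.call(rbind, lapply(seq_along(days), function(t) {
      idx <- which(state[, t] %in% labels)
      data.frame(patient_id = pid[idx], day = days[t],
                 state = unname(state[idx, t]), stringsAsFactors = FALSE)
    }))

    out <- list(
      observations = obs,
      truth = list(
        states = states_long,
        outcomes = data.frame(patient_id = pid,
                              phenotype_day1 = unname(state[, 1]),
                              death_day = death_day,
                              discharge_day = discharge_day,
                              batch = batch, stringsAsFactors = FALSE)
      ),
      focus = data.frame(patient_id = pid, focus = focus,
                         stringsAsFactors = FALSE),
      config = config, profiles = profiles
    )
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic sepsis cohort:", x$config$n_patients, "patients,",
      length(x$config$days), "assessment days,",
      nrow(x$observations), "observations\n")
  cat("Day-1 phenotypes:",
      paste(names(table(x$truth$outcomes$phenotype_day1)),
            table(x$truth$outcomes$phenotype_day1), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic plasma proteome for a cohort
#'
#' One plasma sample per patient (day 1), log2 intensities. Three designated
#' regulated protein sets mirror the biology the screen is meant to detect:
#' a `gradient` set (complement/coagulation) decreasing in expectation
#' A -> B -> C, a `liver` set strongly elevated in phenotype C (hepatocyte
#' leakage), and a `renal` set of low-molecular-weight proteins elevated in
#' phenotype B. Each batch adds an additive per-protein offset with standard
#' deviation `batch_effect_sd`.
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param config The [sim_config()] used for the cohort.
#' @return A list of class `synthetic_proteome` with elements `intensity`
#'   (samples x proteins matrix, log2 scale, `NA` for missing), `batch`,
#'   `phenotype` (named by sample), and `sets` (the regulated protein names).
#' @export
generate_proteome <- function(truth, config) {
  stopifnot(is.list(truth), nrow(truth$outcomes) > 0)
  n_reg <- 60L + 25L + 15L
  if (config$n_proteins < n_reg) {
    stop("n_proteins must be at least ", n_reg,
         " (the designated regulated proteins)", call. = FALSE)
  }
  with_seed(child_seed(config$seed, "proteome"), {
    out <- truth$outcomes
    n <- nrow(out)
    prot <- sprintf("PROT%04d", seq_len(config$n_proteins))
    sets <- list(gradient = prot[1:60], liver = prot[61:85],
                 renal = prot[86:100])
    base <- stats::rnorm(config$n_proteins, mean = 20, sd = 2)

    eff <- matrix(0, 3, config$n_proteins,
                  dimnames = list(c("A", "B", "C"), prot))
    eff["B", sets$gradient] <- -0.8
    eff["C", sets$gradient] <- -1.6
    eff["B", sets$liver] <- 0.3
    eff["C", sets$liver] <- 3.0
    eff["B", sets$renal] <- 1.2
    eff["C", sets$renal] <- 1.5

    batch_off <- matrix(stats::rnorm(config$n_batches * config$n_proteins,
                                     sd = config$batch_effect_sd),
                        config$n_batches, config$n_proteins)

    ph <- out$phenotype_day1
    ph_row <- match(ph, rownames(eff))
    ph_eff <- eff[ph_row, , drop = FALSE]
    ph_eff[is.na(ph_row), ] <- 0  # phenotypes beyond A/B/C: unregulated
    m <- matrix(rep(base, each = n), n, config$n_proteins) + ph_eff +
      batch_off[out$batch, , drop = FALSE] +
      matrix(stats::rnorm(n * config$n_proteins, sd = 0.7), n)
    dimnames(m) <- list(out$patient_id, prot)
    if (config$protein_missing_rate > 0) {
      m[stats::runif(length(m)) < config$protein_missing_rate] <- NA_real_
    }
    structure(list(intensity = m,
                   batch = stats::setNames(out$batch, out$patient_id),
                   phenotype = stats::setNames(ph, out$patient_id),
                   sets = sets),
              class = "synthetic_proteome")
  })
}

#' Generate a clamped cytokine panel for a cohort
#'
#' Log-normal draws per analyte and patient, shifted by the day-1 phenotype,
#' then clamped at the quantification limits with [clamp_limits()]: values
#' below the LLOQ are recorded as 0, values above the ULOQ as the ULOQ.
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param limits Data frame as in [default_cytokine_limits()].
#' @param seed Integer seed.
#' @return Long data frame `patient_id`, `analyte`, `value` with every value
#'   in `{0} U [lloq, uloq]`.
#' @export
generate_cytokines <- function(truth, limits = default_cytokine_limits(),
                               seed = 1) {
  if (any(limits$lloq <= 0) || any(limits$uloq <= 0)) {
    stop("quantification limits must be positive", call. = FALSE)
  }
  if (any(limits$lloq >= limits$uloq)) {
    stop("lloq must be below uloq for every analyte", call. = FALSE)
  }
  with_seed(child_seed(seed, "cytokines"), {
    out <- truth$outcomes
    n <- nrow(out)
    res <- vector("list", nrow(limits))
    for (a in seq_len(nrow(limits))) {
      sh <- ifelse(out$phenotype_day1 == "B", limits$shift_B[a],
                   ifelse(out$phenotype_day1 == "C", limits$shift_C[a], 0))
      raw <- stats::rlnorm(n, meanlog = limits$meanlog[a] + sh,
                           sdlog = limits$sdlog[a])
      res[[a]] <- data.frame(patient_id = out$patient_id,
                             analyte = limits$analyte[a],
                             value = clamp_limits(raw, limits$lloq[a],
                                                  limits$uloq[a]),
                             stringsAsFactors = FALSE)
    }
    x <- do.call(rbind, res)
    x[order(x$patient_id, x$analyte), ]
  })
}
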