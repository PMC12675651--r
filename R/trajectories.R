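TRAJ_STATES <- c("A", "B", "C", "deceased", "discharged", "absent")

#' Project a later-day matrix into the frozen day-1 component space
#'
#' Applies the day-1 standardization parameters and the day-1 PCA loadings
#' to any assessment day's matrix. Equivalent to
#' `predict(model, day_matrix, type = "scores")`.
#'
#' @param day_matrix Imputed matrix whose columns match the fitted columns.
#' @param model A `phenotype_model`.
#' @param focus Infection-focus vector when the model used indicators.
#' @return Score matrix (rows x m components).
#' @export
project_day <- function(day_matrix, model, focus = NULL) {
  model_scores(model, day_matrix, focus)
}

#' Build per-patient phenotype trajectories across assessment days
#'
#' Combines per-day phenotype assignments (from
#' [predict.phenotype_model()]) with recorded outcomes into one ordered
#' state per patient and day. Outcomes are absorbing: from the first
#' assessment day on or after a patient's death (or discharge) day, the
#' state is `deceased` (`discharged`) on every later day. Patients without
#' data on a day and without a recorded outcome are `absent`.
#'
#' @param assignments Named list, one element per assessment day (names are
#'   the day labels), each a named character vector of phenotype letters.
#' @param outcomes Optional data frame `patient_id`, `death_day`,
#'   `discharge_day` (NA when not applicable).
#' @param days Numeric day grid; defaults to the assignment names.
#' @return Data frame `patient_id`, `day`, `state` of class
#'   `trajectory_table`.
#' @export
build_trajectories <- function(assignments, outcomes = NULL, days = NULL) {
  days <- days %||% as.numeric(names(assignments))
  stopifnot(length(days) == length(assignments))
  patients <- sort(unique(unlist(lapply(assignments, names))))
  if (!is.null(outcomes)) patients <- sort(union(patients, outcomes$patient_id))
  dd <- stats::setNames(rep(NA_real_, length(patients)), patients)
  cd <- dd
  if (!is.null(outcomes)) {
    dd[outcomes$patient_id] <- outcomes$death_day
    cd[outcomes$patient_id] <- outcomes$discharge_day
  }
  res <- vector("list", length(days))
  for (i in seq_along(days)) {
    a <- assignments[[i]]
    state <- rep("absent", length(patients))
    names(state) <- patients
    got <- intersect(patients, names(a))
    state[got] <- unname(a[got])
    state[!is.na(dd) & dd <= days[i]] <- "deceased"
    state[!is.na(cd) & cd <= days[i] & is.na(dd)] <- "discharged"
    res[[i]] <- data.frame(patient_id = patients, day = days[i],
                           state = unname(state), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$patient_id, out$day), ]
  rownames(out) <- NULL
  bad <- setdiff(unique(out$state), TRAJ_STATES)
  if (length(bad)) stop("unknown state label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  class(out) <- c("trajectory_table", "data.frame")
  out
}

#' Tabulate state-to-state transitions between assessment days
#'
#' @param traj A [build_trajectories()] table.
#' @param day_pairs List of length-2 numeric vectors (source day, target
#'   day); defaults to consecutive days of the grid.
#' @return List of transition tables; each has `source_day`, `target_day`
#'   and a `counts` matrix (states x states) whose row sums equal the number
#'   of patients in the source state on the source day.
#' @export
build_transitions <- function(traj, day_pairs = NULL) {
  days <- sort(unique(traj$day))
  if (is.null(day_pairs)) {
    day_pairs <- Map(c, days[-length(days)], days[-1])
  }
  bad <- setdiff(unique(traj$state), TRAJ_STATES)
  if (length(bad)) stop("unknown state label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  lapply(day_pairs, function(dp) {
    src <- traj[traj$day == dp[1], ]
    tgt <- traj[traj$day == dp[2], ]
    tgt_state <- stats::setNames(tgt$state, tgt$patient_id)[src$patient_id]
    tgt_state[is.na(tgt_state)] <- "absent"
    counts <- table(factor(src$state, levels = TRAJ_STATES),
                    factor(tgt_state, levels = TRAJ_STATES))
    counts <- unclass(as.matrix(counts))
    names(dimnames(counts)) <- c("source", "target")
    structure(list(source_day = dp[1], target_day = dp[2], counts = counts),
              class = "transition_table")
  })
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Transitions day %g -> day %g\n", x$source_day, x$target_day))
  print(x$counts)
  invisible(x)
}

#' Summarize transition fractions and cluster-C mortality
#'
#' From the first day pair (typically day 1 -> day 4) reports, per source
#' phenotype, the fraction of patients remaining and the fraction moving to
#' each other state; empty source states yield `NA` fractions rather than 0.
#' When the trajectory table and outcomes are supplied, also reports the
#' fraction of patients who ever visited phenotype C and died within 30
#' days.
#'
#' @param tables A [build_transitions()] list.
#' @param traj Optional trajectory table (for the ever-visited-C fraction).
#' @param outcomes Optional outcomes data frame with `death_day`.
#' @return List with `fractions` (data frame: `source_state`,
#'   `target_state`, `fraction`, `n_source`) and `c_visitor_mortality`.
#' @export
transition_summary <- function(tables, traj = NULL, outcomes = NULL) {
  first <- tables[[1]]
  cl <- intersect(rownames(first$counts), c("A", "B", "C"))
  rows <- list()
  for (s in cl) {
    n_src <- sum(first$counts[s, ])
    for (t in colnames(first$counts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        source_state = s, target_state = t,
        fraction = if (n_src > 0) first$counts[s, t] / n_src else NA_real_,
        n_source = n_src, stringsAsFactors = FALSE)
    }
  }
  frac <- do.call(rbind, rows)
  cvm <- NA_real_
  if (!is.null(traj) && !is.null(outcomes)) {
    visitors <- unique(traj$patient_id[traj$state == "C"])
    if (length(visitors)) {
      died <- outcomes$patient_id[!is.na(outcomes$death_day) &
                                    outcomes$death_day <= 30]
      cvm <- mean(visitors %in% died)
    }
  }
  list(fractions = frac, c_visitor_mortality = cvm)
}
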