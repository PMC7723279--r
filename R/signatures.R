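# Model-free behavioral statistics. Eligibility windows never cross block
# boundaries (each block is its own symbol pair).

#' Correct choice rate
#'
#' Fraction of private choices equal to the reward-maximizing symbol of
#' their context. Under random-walk contingencies the instantaneous walk
#' values define the correct symbol.
#'
#' @param dataset Completed trial records (with `p_a`/`p_b`).
#' @return Probability in `[0, 1]`.
#' @export
correct_choice_rate <- function(dataset) {
  priv <- dataset$trial_type == "private" & !is.na(dataset$choice)
  if (!any(priv)) stop("dataset has no private trials with choices")
  d <- dataset[priv, ]
  correct <- ifelse(d$p_a >= d$p_b, d$option_a, d$option_b)
  mean(d$choice == correct)
}

# Per-block helper: for each private trial, the row indices of the lag-1..k
# most recent observational trials in the same block.
block_windows <- function(dataset) {
  split(seq_len(nrow(dataset)),
        list(dataset$subject_id, dataset$session, dataset$block), drop = TRUE)
}

#' Behavioral imitation rate
#'
#' Fraction of private choices matching the demonstration observed `lag`
#' demonstrations earlier in the same block (lag 1 = the most recent
#' demonstration preceding the choice).
#'
#' @param dataset Completed trial records.
#' @param lag 1 or 2.
#' @param condition Optional filter on the `condition` column (e.g. `"SD"`).
#' @return Probability in `[0, 1]`.
#' @export
imitation_rate <- function(dataset, lag = 1L, condition = NULL) {
  stopifnot(lag %in% c(1L, 2L))
  if (!is.null(condition)) dataset <- dataset[dataset$condition %in% condition, ]
  matches <- 0L
  eligible <- 0L
  for (idx in block_windows(dataset)) {
    blk <- dataset[idx, ]
    obs_pos <- which(blk$trial_type == "observational")
    for (t in which(blk$trial_type == "private" & !is.na(blk$choice))) {
      prior <- obs_pos[obs_pos < t]
      if (length(prior) >= lag) {
        d <- blk$demonstration[prior[length(prior) - lag + 1L]]
        eligible <- eligible + 1L
        matches <- matches + as.integer(blk$choice[t] == d)
      }
    }
  }
  if (eligible == 0L) stop("no private choices preceded by >= ", lag,
                           " demonstrations in the same block")
  matches / eligible
}

# Windows of two consecutive observational trials immediately followed by a
# private choice; longer observational runs contribute their final two
# demonstrations only.
accumulation_windows <- function(dataset) {
  out <- list()
  for (idx in block_windows(dataset)) {
    blk <- dataset[idx, ]
    n <- nrow(blk)
    for (t in seq_len(n)) {
      if (t >= 3L && blk$trial_type[t] == "private" && !is.na(blk$choice[t]) &&
          blk$trial_type[t - 1L] == "observational" &&
          blk$trial_type[t - 2L] == "observational") {
        out[[length(out) + 1L]] <- list(choice = blk$choice[t],
                                        d1 = blk$demonstration[t - 1L],
                                        d2 = blk$demonstration[t - 2L])
      }
    }
  }
  out
}

#' Accumulation of social signals
#'
#' Difference in behavioral imitation rates between the two demonstrations
#' preceding a private choice (`d_{t-1}` minus `d_{t-2}`), over windows
#' where trials `t-2` and `t-1` are observational and `t` is private. A
#' learner influenced only by the last demonstration shows a positive
#' differential; accumulation over demonstrations drives it toward zero.
#'
#' @param dataset Completed trial records.
#' @return Differential in `[-1, 1]`.
#' @export
accumulation <- function(dataset) {
  w <- accumulation_windows(dataset)
  if (length(w) == 0L) {
    stop("no runs of >= 2 demonstrations followed by a private choice")
  }
  r1 <- mean(vapply(w, function(x) x$choice == x$d1, logical(1)))
  r2 <- mean(vapply(w, function(x) x$choice == x$d2, logical(1)))
  r1 - r2
}

#' Propagation of social signals
#'
#' Difference in behavioral imitation rates between the two private choices
#' following a demonstration (`c_{t+1}` minus `c_{t+2}` matched against
#' `d_t`), over windows where trial `t` is observational and trials `t+1`,
#' `t+2` are private. A learner whose social bias decays after one choice
#' shows a positive differential; persistent (value-stored) imitation drives
#' it toward zero.
#'
#' @param dataset Completed trial records.
#' @return Differential in `[-1, 1]`.
#' @export
propagation <- function(dataset) {
  m1 <- logical(0)
  m2 <- logical(0)
  for (idx in block_windows(dataset)) {
    blk <- dataset[idx, ]
    n <- nrow(blk)
    for (t in seq_len(n)) {
      if (t + 2L <= n && blk$trial_type[t] == "observational" &&
          blk$trial_type[t + 1L] == "private" &&
          blk$trial_type[t + 2L] == "private" &&
          !is.na(blk$choice[t + 1L]) && !is.na(blk$choice[t + 2L])) {
        m1 <- c(m1, blk$choice[t + 1L] == blk$demonstration[t])
        m2 <- c(m2, blk$choice[t + 2L] == blk$demonstration[t])
      }
    }
  }
  if (length(m1) == 0L) {
    stop("no demonstrations followed by >= 2 private choices")
  }
  mean(m1) - mean(m2)
}

#' Signature table for a dataset
#'
#' Convenience wrapper computing all model-free signatures at once.
#'
#' @param dataset Completed trial records.
#' @param source Label for the `source` column (e.g. `"observed"` or a
#'   model id).
#' @param condition Optional condition filter applied to the imitation
#'   metrics (accumulation/propagation windows only exist in observational
#'   blocks regardless).
#' @return One-row `data.frame` with `correct_choice_rate`,
#'   `imitation_lag1`, `imitation_lag2`, `accumulation`, `propagation`,
#'   `source`.
#' @export
signature_table <- function(dataset, source = "observed", condition = NULL) {
  sub <- if (is.null(condition)) dataset else
    dataset[dataset$condition %in% c(condition, "P"), ]
  obs_sub <- if (is.null(condition)) dataset else
    dataset[dataset$condition %in% condition, ]
  data.frame(
    source = source,
    correct_choice_rate = correct_choice_rate(sub),
    imitation_lag1 = imitation_rate(obs_sub, 1L),
    imitation_lag2 = imitation_rate(obs_sub, 2L),
    accumulation = accumulation(obs_sub),
    propagation = propagation(obs_sub),
    stringsAsFactors = FALSE
  )
}

#' Observed vs model-simulated choice correlations
#'
#' Posterior-predictive style check: each subject's fitted model is
#' simulated `n_sims` times on the subject's own schedule; observed choices
#' are then correlated with the mean simulated choice frequencies, across
#' trials (within subject, averaged over subjects) and across subjects
#' (per-subject mean rates), with a least-squares slope/intercept on the
#' across-subject scatter. Subjects with constant observed choices have an
#' undefined across-trial correlation and are flagged.
#'
#' @param datasets Named list of per-subject completed trial records.
#' @param spec A [model_spec()].
#' @param params_by_subject Named list (or single vector) of fitted
#'   parameter sets.
#' @param n_sims Simulation replicates per subject.
#' @param seed Integer seed.
#' @return A list with `across_trial_rho`, `across_subject_rho`, `slope`,
#'   `intercept`, `degenerate_subjects`.
#' @export
observed_vs_simulated <- function(datasets, spec, params_by_subject,
                                  n_sims = 20L, seed = 1L) {
  if (!is.list(params_by_subject)) {
    params_by_subject <- stats::setNames(
      rep(list(params_by_subject), length(datasets)), names(datasets))
  }
  rho_trial <- numeric(0)
  degenerate <- character(0)
  obs_rate <- sim_rate <- numeric(0)
  for (nm in names(datasets)) {
    if (is.null(params_by_subject[[nm]])) {
      stop("no fitted parameters for subject ", nm)
    }
    d <- datasets[[nm]]
    priv <- d$trial_type == "private"
    obs_choice <- as.numeric(d$choice[priv] == d$option_a[priv])
    freqs <- matrix(0, sum(priv), n_sims)
    for (s in seq_len(n_sims)) {
      sim <- simulate_agent(spec, params_by_subject[[nm]], d,
                            seed = seed + 1000L * match(nm, names(datasets)) + s)
      freqs[, s] <- as.numeric(sim$choice[priv] == sim$option_a[priv])
    }
    sim_freq <- rowMeans(freqs)
    if (stats::sd(obs_choice) == 0) {
      degenerate <- c(degenerate, nm)
    } else {
      rho_trial <- c(rho_trial,
                     stats::cor(obs_choice, sim_freq, method = "spearman"))
    }
    obs_rate <- c(obs_rate, mean(obs_choice))
    sim_rate <- c(sim_rate, mean(sim_freq))
  }
  across_subject <- if (length(obs_rate) >= 3L && stats::sd(obs_rate) > 0) {
    stats::cor(obs_rate, sim_rate, method = "spearman")
  } else NA_real_
  coefs <- if (length(obs_rate) >= 2L && stats::sd(sim_rate) > 0) {
    stats::coef(stats::lm(obs_rate ~ sim_rate))
  } else c(NA_real_, NA_real_)
  list(
    across_trial_rho = if (length(rho_trial) > 0L) mean(rho_trial) else NA_real_,
    across_subject_rho = across_subject,
    slope = unname(coefs[2]), intercept = unname(coefs[1]),
    degenerate_subjects = degenerate
  )
}
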