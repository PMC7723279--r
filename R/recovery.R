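#' Parameter recovery
#'
#' Simulate-and-refit assessment of the fitting procedure: draw `n_subjects`
#' parameter vectors from the priors, simulate each subject on a fresh
#' schedule, refit the generating model, and report the Spearman rank
#' correlation between generating and recovered values per free parameter.
#'
#' @param spec A [model_spec()] (or id string).
#' @param config A [task_config()] describing the schedules.
#' @param n_subjects Cohort size (at least 10).
#' @param seed Master seed.
#' @param fit_opts A [fit_options()] list; MAP (`"lpp"`) fitting is the
#'   default as it stabilizes per-subject estimates.
#' @return A list of class `"parameter_recovery"`: `correlations`
#'   (`data.frame` with `parameter`, `rho`, `p_value`, `n`), `true` and
#'   `recovered` matrices.
#' @export
parameter_recovery <- function(spec, config, n_subjects = 40L, seed = 1L,
                               fit_opts = fit_options(objective = "lpp")) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  if (n_subjects < 10L) stop("parameter recovery needs at least 10 subjects")
  true_params <- withr::with_seed(seed, sample_prior_params(spec, n_subjects))
  if (any(apply(true_params, 2L, function(x) length(unique(x)) == 1L))) {
    stop("degenerate parameter draws: a parameter is constant across subjects")
  }
  recovered <- matrix(NA_real_, n_subjects, spec$n_free,
                      dimnames = list(NULL, spec$free))
  for (si in seq_len(n_subjects)) {
    sched <- make_schedule(config, seed = seed + 2L * si,
                           subject_id = sprintf("pr.%02d", si))
    params <- param_set()
    params[spec$free] <- true_params[si, ]
    sim <- simulate_agent(spec, params, sched, seed = seed + 2L * si + 1L)
    opts <- fit_opts
    opts$seed <- seed + 100000L + si
    recovered[si, ] <- fit_subject(spec, sim, opts)$estimates
  }
  correlations <- do.call(rbind, lapply(spec$free, function(nm) {
    ct <- suppressWarnings(
      stats::cor.test(true_params[, nm], recovered[, nm], method = "spearman")
    )
    data.frame(parameter = nm, rho = unname(ct$estimate),
               p_value = ct$p.value, n = n_subjects,
               stringsAsFactors = FALSE)
  }))
  structure(list(correlations = correlations, true = true_params,
                 recovered = recovered, model_id = spec$id),
            class = "parameter_recovery")
}

#' @export
print.parameter_recovery <- function(x, ...) {
  cat("<parameter_recovery>", x$model_id, "\n")
  print(transform(x$correlations, rho = round(rho, 3),
                  p_value = signif(p_value, 3)))
  invisible(x)
}

#' Nonparametric comparison of parameter samples
#'
#' Wilcoxon signed-rank test for paired samples (e.g. private vs imitation
#' learning rates within subjects) or Wilcoxon rank-sum test for unpaired
#' samples (e.g. between-subject demonstrator groups); two-sided.
#'
#' @param values_a,values_b Numeric samples (equal length when paired).
#' @param paired Use the signed-rank test.
#' @return A list with `statistic`, `p_value`, `method`, `n`.
#' @export
compare_parameters <- function(values_a, values_b, paired = TRUE) {
  stopifnot(length(values_a) > 0L, length(values_b) > 0L)
  if (paired) {
    if (length(values_a) != length(values_b)) {
      stop("paired comparison needs equal-length samples")
    }
    if (all(values_a == values_b)) {
      stop("all paired differences are zero; the signed-rank test is undefined")
    }
  }
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = paired, exact = FALSE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method, n = c(length(values_a), length(values_b)))
}
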