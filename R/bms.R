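#' Random-effects Bayesian model selection
#'
#' Variational treatment of model identity as a random effect across
#' subjects: with a uniform Dirichlet prior (`alpha_0 = 1` per model), the
#' per-subject model responsibilities and the Dirichlet pseudo-counts are
#' iterated to convergence,
#' `u_nk = softmax_k(l_nk + psi(alpha_k) - psi(sum(alpha)))`,
#' `alpha_k = alpha_0 + sum_n u_nk`. Expected model frequencies are
#' `alpha / sum(alpha)`; exceedance probabilities (the posterior probability
#' that a model is more frequent than every alternative) are computed
#' exactly via the Beta distribution when two models are compared and by
#' seeded Monte-Carlo Dirichlet sampling otherwise.
#'
#' @param evidence Numeric subjects x models matrix of log-evidence
#'   approximations (e.g. the [aic()] values); column names identify models.
#' @param n_xp_samples Monte-Carlo sample count for the exceedance
#'   probabilities (ignored when `ncol(evidence) == 2`).
#' @param seed Integer seed for the Monte-Carlo step.
#' @param max_iter,tol Convergence controls for the variational iteration
#'   (`tol` on the largest change in `alpha`).
#' @return A list of class `"bms_result"`: `dirichlet_alpha`,
#'   `expected_frequency`, `exceedance_probability`, `chance_level`,
#'   `responsibilities`, `n_iter`.
#' @export
#' @examples
#' ev <- matrix(c(0, 0, 0, -3, -4, -2), nrow = 3,
#'              dimnames = list(NULL, c("M1", "M2")))
#' rfx_bms(ev, seed = 1)$exceedance_probability
rfx_bms <- function(evidence, n_xp_samples = 1e6, seed = 1L,
                    max_iter = 500L, tol = 1e-4) {
  evidence <- as.matrix(evidence)
  if (anyNA(evidence) || any(!is.finite(evidence))) {
    stop("evidence matrix must be finite")
  }
  n <- nrow(evidence)
  k <- ncol(evidence)
  if (n < 1L || k < 2L) stop("need at least 1 subject and 2 models")
  models <- colnames(evidence) %||% paste0("M", seq_len(k))

  alpha0 <- rep(1, k)
  alpha <- alpha0 + n / k
  u <- matrix(1 / k, n, k)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- sweep(evidence, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1L, max)
    u <- exp(w)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
    if (iter >= max_iter) {
      stop("rfx_bms did not converge in ", max_iter,
           " iterations (last delta = ", signif(delta, 3), ")")
    }
  }

  ef <- alpha / sum(alpha)
  if (k == 2L) {
    xp1 <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    xp <- c(xp1, 1 - xp1)
  } else {
    xp <- withr::with_seed(seed, {
      g <- matrix(stats::rgamma(n_xp_samples * k, shape = rep(alpha, each = n_xp_samples)),
                  ncol = k)
      tabulate(max.col(g), nbins = k) / n_xp_samples
    })
  }
  structure(list(
    models = models,
    dirichlet_alpha = stats::setNames(alpha, models),
    expected_frequency = stats::setNames(ef, models),
    exceedance_probability = stats::setNames(xp, models),
    chance_level = 1 / k,
    responsibilities = u, n_iter = iter
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>", length(x$models), "models, chance level",
      round(x$chance_level, 3), "\n")
  print(round(rbind(expected_frequency = x$expected_frequency,
                    exceedance_probability = x$exceedance_probability), 3))
  invisible(x)
}

#' Model recovery
#'
#' Confusion analysis of the model space under the fitting pipeline: for
#' each generating model, simulate a cohort with prior-drawn parameters on
#' schedules from `config`, fit every model in the space by the chosen
#' objective, convert NLLs to log-evidence approximations ([aic()]), and run
#' [rfx_bms()]. The space is identifiable when the frequency/exceedance
#' matrices are diagonally dominant.
#'
#' @param model_space List of [model_spec()]s (or id strings), at least 2.
#' @param config A [task_config()] describing the schedules.
#' @param n_subjects Simulated subjects per generating model.
#' @param seed Master seed; all schedules, parameter draws, simulations and
#'   fits derive from it.
#' @param fit_opts A [fit_options()] list used for every fit.
#' @param n_xp_samples Monte-Carlo samples for exceedance probabilities.
#' @return A list of class `"recovery_report"`: `frequency` and `xp`
#'   (generating x fitted matrices), `evidence` (per-cohort AIC matrices),
#'   `seeds`, `n_subjects`.
#' @export
model_recovery <- function(model_space, config, n_subjects = 20L, seed = 1L,
                           fit_opts = fit_options(), n_xp_samples = 1e6) {
  specs <- lapply(model_space, function(s) if (inherits(s, "model_spec")) s else model_spec(s))
  if (length(specs) < 2L) stop("model space must contain at least 2 models")
  ids <- vapply(specs, `[[`, character(1), "id")
  k <- length(specs)
  freq <- xp <- matrix(NA_real_, k, k, dimnames = list(generating = ids, fitted = ids))
  evidence <- list()
  seeds <- list()
  for (gi in seq_len(k)) {
    gen <- specs[[gi]]
    cohort_seed <- seed + 10000L * gi
    true_params <- withr::with_seed(cohort_seed,
                                    sample_prior_params(gen, n_subjects))
    datasets <- lapply(seq_len(n_subjects), function(si) {
      sched <- make_schedule(config, seed = cohort_seed + 2L * si,
                             subject_id = sprintf("%s.%02d", gen$id, si))
      params <- param_set()
      params[gen$free] <- true_params[si, ]
      simulate_agent(gen, params, sched, seed = cohort_seed + 2L * si + 1L)
    })
    opts <- fit_opts
    opts$seed <- cohort_seed
    fits <- fit_cohort(specs, datasets, opts)
    ev <- matrix(fits$aic, nrow = n_subjects, ncol = k, byrow = TRUE,
                 dimnames = list(unique(fits$subject_id), ids))
    bms <- rfx_bms(ev, n_xp_samples = n_xp_samples, seed = cohort_seed)
    freq[gi, ] <- bms$expected_frequency
    xp[gi, ] <- bms$exceedance_probability
    evidence[[gen$id]] <- ev
    seeds[[gen$id]] <- cohort_seed
  }
  structure(list(frequency = freq, xp = xp, evidence = evidence,
                 seeds = seeds, n_subjects = n_subjects),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$n_subjects, "subjects per generating model\n")
  cat("exceedance probabilities (rows generate, columns fit):\n")
  print(round(x$xp, 3))
  invisible(x)
}
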