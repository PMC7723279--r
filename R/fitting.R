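#' Parameter bounds
#'
#' Box constraints used by the optimizer: learning rates in (0, 1) (the
#' imitation rate extends to (-1, 1) when negative imitation is allowed),
#' inverse temperature in (0, 100\], and the choice-autocorrelation weight
#' in \[-10, 10\].
#'
#' @param spec A [model_spec()].
#' @return List with numeric vectors `lower` and `upper` named by the spec's
#'   free parameters.
#' @export
param_bounds <- function(spec) {
  eps <- 1e-6
  lower <- c(alpha_p = eps, alpha_i = eps, alpha_d = eps, alpha_m = eps,
             beta = 1e-3, kappa = -10)
  upper <- c(alpha_p = 1 - eps, alpha_i = 1 - eps, alpha_d = 1 - eps,
             alpha_m = 1 - eps, beta = 100, kappa = 10)
  if (spec$allow_negative_imitation) lower[["alpha_i"]] <- -1 + eps
  list(lower = lower[spec$free], upper = upper[spec$free])
}

#' Negative log-likelihood of a dataset under a model
#'
#' Sum of `-log pi(c_t)` over private trials, with the learner state evolved
#' chronologically through all trials (demonstration updates included).
#' Observational matching responses contribute no likelihood terms. Choice
#' probabilities are floored at 1e-12 inside the log.
#'
#' @param spec A [model_spec()].
#' @param params A named parameter vector (see [param_set()]).
#' @param dataset Trial records for one subject, chronologically ordered,
#'   with choices and outcomes filled on private trials.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' cfg <- task_config("exp2")
#' sim <- simulate_agent(model_spec("RW2"), param_set(beta = 2),
#'                       make_schedule(cfg, seed = 1), seed = 2)
#' dataset_nll(model_spec("RW2"), param_set(beta = 2), sim)
dataset_nll <- function(spec, params, dataset) {
  run_engine(spec, params, dataset, simulate = FALSE)$nll
}

#' Log-prior over model parameters
#'
#' The fitting priors: `gamma(shape = 1.2, scale = 5)` on the inverse
#' temperature, `beta(1.1, 1.1)` on every learning rate in (0, 1), and a
#' flat (zero-contribution) prior on `kappa`. When negative imitation is
#' allowed, `alpha_i` also gets a flat prior over (-1, 1).
#'
#' @inheritParams dataset_nll
#' @return Scalar log-density (sum over the spec's free parameters).
#' @export
log_prior <- function(params, spec) {
  params <- as_param_set(params)
  b <- param_bounds(spec)
  v <- params[spec$free]
  if (any(v < b$lower - 1e-12) || any(v > b$upper + 1e-12)) {
    stop("parameter(s) out of bounds: ",
         paste(spec$free[v < b$lower | v > b$upper], collapse = ", "))
  }
  lp <- 0
  for (nm in spec$free) {
    lp <- lp + switch(nm,
      beta = stats::dgamma(params[[nm]], shape = 1.2, scale = 5, log = TRUE),
      kappa = 0,
      alpha_i = if (spec$allow_negative_imitation) 0 else
        stats::dbeta(params[[nm]], 1.1, 1.1, log = TRUE),
      stats::dbeta(params[[nm]], 1.1, 1.1, log = TRUE)
    )
  }
  lp
}

#' Draw parameters from the fitting priors
#'
#' Learning rates from `beta(1.1, 1.1)`, inverse temperature from
#' `gamma(1.2, scale = 5)`, and the autocorrelation weight uniform on
#' (-1, 1) (its prior is flat; draws are confined to the plausible
#' perseveration range). Values are clipped to the fitting bounds. Used for
#' optimizer restarts and for generating recovery cohorts.
#'
#' @param spec A [model_spec()].
#' @param n Number of draws.
#' @return An `n` x `n_free` matrix with one parameter vector per row.
#' @export
sample_prior_params <- function(spec, n = 1L) {
  b <- param_bounds(spec)
  draws <- vapply(spec$free, function(nm) {
    x <- switch(nm,
      beta = stats::rgamma(n, shape = 1.2, scale = 5),
      kappa = stats::runif(n, -1, 1),
      alpha_i = if (spec$allow_negative_imitation) stats::runif(n, -1, 1) else
        stats::rbeta(n, 1.1, 1.1),
      stats::rbeta(n, 1.1, 1.1)
    )
    pmin(pmax(x, b$lower[[nm]]), b$upper[[nm]])
  }, numeric(n))
  matrix(draws, nrow = n, dimnames = list(NULL, spec$free))
}

#' Akaike information criterion, log-evidence convention
#'
#' `AIC = -NLL - p`: the log-likelihood at the optimum minus the number of
#' free parameters. Note this is on the log-evidence scale (larger is
#' better), differing from the conventional `2p + 2 NLL` by a factor of -2;
#' it is used directly as a model log-evidence approximation in
#' [rfx_bms()].
#'
#' @param nll Minimized negative log-likelihood.
#' @param p Number of free parameters.
#' @return Scalar.
#' @export
aic <- function(nll, p) {
  stopifnot(p >= 0)
  -nll - p
}

#' Fitting options
#'
#' @param objective `"nll"` (maximum likelihood) or `"lpp"` (maximum a
#'   posteriori, adding the [log_prior()]).
#' @param n_restarts Number of optimizer restarts; starting points are drawn
#'   from the priors.
#' @param tolerance Convergence tolerance on the objective.
#' @param seed Integer seed for the restart draws.
#' @return A list of options for [fit_subject()].
#' @export
fit_options <- function(objective = c("nll", "lpp"), n_restarts = 10L,
                        tolerance = 1e-6, seed = 1L) {
  list(objective = match.arg(objective), n_restarts = as.integer(n_restarts),
       tolerance = tolerance, seed = as.integer(seed))
}

#' Fit a model to one subject's choices
#'
#' Bounded quasi-Newton (`L-BFGS-B`) minimization of the negative
#' log-likelihood (or negative log posterior), restarted from
#' prior-drawn starting points; the best restart wins (ties by first).
#'
#' @param spec A [model_spec()].
#' @param dataset One subject's chronologically ordered trial records.
#' @param options A [fit_options()] list.
#' @return A list of class `"fit_result"`: fitted `params` (full
#'   [param_set()]), `estimates` (free parameters only), `nll`, `lpp`,
#'   `aic` (= `-nll - p`), `p`, `n_trials_used` (private trials),
#'   `converged`, `n_restarts`, `objective`.
#' @export
fit_subject <- function(spec, dataset, options = fit_options()) {
  stopifnot(nrow(dataset) > 0L)
  b <- param_bounds(spec)
  use_lpp <- options$objective == "lpp"
  obj <- function(theta) {
    params <- param_set()
    params[spec$free] <- theta
    val <- dataset_nll(spec, params, dataset)
    if (use_lpp) val <- val - log_prior(params, spec)
    if (!is.finite(val)) val <- 1e10
    val
  }
  starts <- withr::with_seed(options$seed,
                             sample_prior_params(spec, options$n_restarts))
  best <- NULL
  failures <- character(0)
  for (i in seq_len(options$n_restarts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(factr = options$tolerance / .Machine$double.eps,
                                  maxit = 500L)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) {
    stop("all ", options$n_restarts, " restarts failed; last error: ",
         utils::tail(failures, 1L))
  }
  params <- param_set()
  params[spec$free] <- best$par
  nll <- dataset_nll(spec, params, dataset)
  lpp <- -nll + log_prior(params, spec)
  structure(list(
    model_id = spec$id, spec = spec, params = params,
    estimates = stats::setNames(as.numeric(best$par), spec$free),
    nll = nll, lpp = lpp, aic = aic(nll, spec$n_free), p = spec$n_free,
    n_trials_used = sum(dataset$trial_type == "private"),
    converged = best$convergence == 0L, n_restarts = options$n_restarts,
    objective = options$objective
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model_id,
      sprintf("NLL %.2f | LPP %.2f | AIC %.2f | %d private trials\n",
              x$nll, x$lpp, x$aic, x$n_trials_used))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Fit several models to several subjects
#'
#' @param specs List of [model_spec()]s (or model id strings).
#' @param datasets Named list of per-subject trial records.
#' @param options A [fit_options()] list; each subject x model fit uses a
#'   seed derived from `options$seed`.
#' @return A `data.frame` with one row per subject x model (columns
#'   `subject_id`, `model_id`, `nll`, `lpp`, `aic`, `p`, `converged` and one
#'   column per parameter), plus the raw fits in `attr(, "fits")`.
#' @export
fit_cohort <- function(specs, datasets, options = fit_options()) {
  specs <- lapply(specs, function(s) if (inherits(s, "model_spec")) s else model_spec(s))
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, function(d) d$subject_id[1], character(1))
  }
  rows <- list()
  fits <- list()
  for (si in seq_along(datasets)) {
    for (mi in seq_along(specs)) {
      opts <- options
      opts$seed <- options$seed + 1000L * si + mi
      f <- fit_subject(specs[[mi]], datasets[[si]], opts)
      fits[[paste(names(datasets)[si], f$model_id, sep = ".")]] <- f
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = names(datasets)[si], model_id = f$model_id,
        nll = f$nll, lpp = f$lpp, aic = f$aic, p = f$p,
        converged = f$converged, t(f$params), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
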