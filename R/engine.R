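# Encode a trial-record data.frame for the compiled engine.
# Contexts are indexed in order of first appearance; options are coded
# 1 = option_a, 2 = option_b.
encode_trials <- function(trials, require_choices = FALSE) {
  needed <- c("context_id", "trial_type", "option_a", "option_b",
              "demonstration", "choice", "outcome")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial data lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  ctx_levels <- unique(trials$context_id)
  context <- match(trials$context_id, ctx_levels)
  obs <- trials$trial_type == "observational"
  if (any(!trials$trial_type %in% c("observational", "private"))) {
    stop("trial_type must be 'observational' or 'private'")
  }
  code_option <- function(x) {
    out <- rep(0L, length(x))
    out[!is.na(x) & x == trials$option_a] <- 1L
    out[!is.na(x) & x == trials$option_b] <- 2L
    bad <- !is.na(x) & out == 0L
    if (any(bad)) {
      stop("symbol not in context at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    out
  }
  demo <- code_option(trials$demonstration)
  if (any(obs & demo == 0L)) {
    stop("observational trial(s) without demonstration at row(s) ",
         paste(utils::head(which(obs & demo == 0L), 5L), collapse = ", "))
  }
  choice <- code_option(trials$choice)
  outcome <- ifelse(is.na(trials$outcome), 0, trials$outcome)
  if (require_choices && any(!obs & choice == 0L)) {
    stop("private trial(s) without recorded choice at row(s) ",
         paste(utils::head(which(!obs & choice == 0L), 5L), collapse = ", "))
  }
  pa <- if ("p_a" %in% names(trials)) trials$p_a else rep(NA_real_, nrow(trials))
  pb <- if ("p_b" %in% names(trials)) trials$p_b else rep(NA_real_, nrow(trials))
  list(context = as.integer(context), type = as.integer(obs),
       demo = demo, choice = choice, outcome = as.numeric(outcome),
       pa = as.numeric(pa), pb = as.numeric(pb),
       n_contexts = length(ctx_levels), ctx_levels = ctx_levels)
}

run_engine <- function(spec, params, trials, simulate = FALSE, urand = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  params <- as_param_set(params)
  if (!spec$use_kappa) params[["kappa"]] <- 0
  enc <- encode_trials(trials, require_choices = !simulate)
  if (simulate) {
    if (is.null(urand)) stop("simulation requires uniform draws")
    if (anyNA(enc$pa[enc$type == 0L]) || anyNA(enc$pb[enc$type == 0L])) {
      stop("simulation requires per-trial win probabilities p_a and p_b")
    }
  } else {
    urand <- matrix(0, 0L, 2L)
  }
  rl_engine_cpp(enc$context, enc$type, enc$demo, enc$choice, enc$outcome,
                enc$pa, enc$pb, enc$n_contexts,
                spec$family_code, spec$variant, unname(params),
                spec$symmetric_private, spec$obs_match_last_action,
                simulate, urand)
}

#' Simulate an agent on a schedule
#'
#' Plays a learner model through a schedule: observational trials apply the
#' model's demonstration update, private trials sample a choice from the
#' model's policy and an outcome from the context's contingencies, then apply
#' the private value update.
#'
#' @param spec A [model_spec()].
#' @param params A [param_set()] (or named subset).
#' @param schedule A schedule from [make_schedule()] (demonstrations filled,
#'   choices/outcomes empty); must carry `p_a`/`p_b`.
#' @param seed Integer seed; the completed record is reproducible given
#'   `(spec, params, schedule, seed)`.
#' @return The schedule with `choice` and `outcome` filled on private trials,
#'   plus columns `p_choice_a` (model probability of choosing `option_a` on
#'   private trials) and `alpha_i_state` (running per-state imitation rate,
#'   metaVS only).
#' @export
#' @examples
#' cfg <- task_config("exp2")
#' sched <- make_schedule(cfg, seed = 3)
#' sim <- simulate_agent(model_spec("VS2"),
#'                       param_set(alpha_p = 0.3, alpha_i = 0.25, beta = 5),
#'                       sched, seed = 4)
#' mean(sim$choice[sim$trial_type == "private"] == "A")
simulate_agent <- function(spec, params, schedule, seed) {
  urand <- withr::with_seed(seed, matrix(stats::runif(2L * nrow(schedule)),
                                         ncol = 2L))
  res <- run_engine(spec, params, schedule, simulate = TRUE, urand = urand)
  out <- schedule
  priv <- schedule$trial_type == "private"
  out$choice[priv] <- ifelse(res$choice[priv] == 1L,
                             schedule$option_a[priv], schedule$option_b[priv])
  out$outcome[priv] <- res$outcome[priv]
  out$p_choice_a <- res$p_a
  out$alpha_i_state <- res$alpha_i_state
  out
}
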