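FAMILY_CODES <- c(RW = 0L, DB = 1L, MB = 2L, VS = 3L, metaVS = 4L)

#' Model identifiers
#'
#' All implemented learner models: two Rescorla-Wagner baselines (`RW1`
#' asymmetric, `RW2` with symmetric value update of the unchosen option), six
#' decision-biasing variants (`DB1`-`DB6`: policy / value / symmetric-value
#' bias, without or with accumulation over consecutive demonstrations), nine
#' model-based imitation variants (`MB1`-`MB9`: demonstrator model learned by
#' policy / value / symmetric-value update crossed with the same three bias
#' steps), two value-shaping variants (`VS1`, `VS2`), and the meta-learning
#' model `metaVS` whose per-state imitation rate tracks learner-demonstrator
#' agreement.
#'
#' @return Character vector of model ids usable in [model_spec()].
#' @export
model_registry <- function() {
  c("RW1", "RW2", paste0("DB", 1:6), paste0("MB", 1:9), "VS1", "VS2", "metaVS")
}

#' Specify a learner model
#'
#' @param id A model id from [model_registry()].
#' @param use_kappa Include the choice-autocorrelation parameter `kappa` in
#'   the softmax (robustness variant: `FALSE` removes it).
#' @param symmetric_private Use the symmetric private value update (the
#'   unchosen option moves toward `-r`). Defaults to `TRUE` for every model
#'   except `RW1`, matching the final model space.
#' @param allow_negative_imitation Let `alpha_i` range over (-1, 1) instead
#'   of (0, 1) (robustness variant).
#' @param alpha_d_fixed Fix the demonstrator-model learning rate `alpha_d`
#'   at 0.1 (model-based variants); set `FALSE` to fit it.
#' @param obs_match_last_action Treat the matching key press on
#'   observational trials as a performed action for the
#'   choice-autocorrelation term. Off by default: the match is forced, not a
#'   free choice, and keeping perseveration tied to free choices preserves
#'   the exact `alpha_i = 0` collapse of every social model onto its RW
#'   baseline.
#' @return A list of class `"model_spec"` with the family/variant coding and
#'   the names of the free parameters.
#' @export
#' @examples
#' model_spec("VS2")$free
model_spec <- function(id, use_kappa = TRUE, symmetric_private = NULL,
                       allow_negative_imitation = FALSE, alpha_d_fixed = TRUE,
                       obs_match_last_action = FALSE) {
  id <- as.character(id)
  if (!id %in% model_registry()) {
    stop("unknown model id '", id, "'; see model_registry()")
  }
  if (id == "metaVS") {
    family <- "metaVS"; variant <- 1L
  } else {
    family <- sub("[0-9]+$", "", id)
    variant <- as.integer(sub("^[A-Z]+", "", id))
  }
  if (is.null(symmetric_private)) symmetric_private <- !identical(id, "RW1")
  free <- c("alpha_p",
            if (family %in% c("DB", "MB", "VS")) "alpha_i",
            if (family == "MB" && !alpha_d_fixed) "alpha_d",
            if (family == "metaVS") "alpha_m",
            "beta",
            if (use_kappa) "kappa")
  structure(list(
    id = id, family = family, variant = variant,
    family_code = FAMILY_CODES[[family]],
    use_kappa = use_kappa,
    symmetric_private = isTRUE(symmetric_private),
    allow_negative_imitation = isTRUE(allow_negative_imitation),
    alpha_d_fixed = isTRUE(alpha_d_fixed),
    obs_match_last_action = isTRUE(obs_match_last_action),
    free = free, n_free = length(free)
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$id, "- free parameters:",
      paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Full parameter set
#'
#' Assembles the six-parameter vector used by every model; parameters a
#' model does not use are held at neutral values (`alpha_i = 0`,
#' `alpha_d = 0.1`, `alpha_m = 0`, `kappa = 0`).
#'
#' @param alpha_p Private reward learning rate in (0, 1).
#' @param alpha_i Imitation learning rate / decision bias in (0, 1) (or
#'   (-1, 1) when negative imitation is allowed).
#' @param alpha_d Demonstrator-model learning rate (model-based variants).
#' @param alpha_m Meta learning rate (metaVS).
#' @param beta Softmax inverse temperature, positive.
#' @param kappa Choice-autocorrelation weight.
#' @return Named numeric vector of length 6.
#' @export
param_set <- function(alpha_p = 0.3, alpha_i = 0, alpha_d = 0.1,
                      alpha_m = 0, beta = 3, kappa = 0) {
  c(alpha_p = alpha_p, alpha_i = alpha_i, alpha_d = alpha_d,
    alpha_m = alpha_m, beta = beta, kappa = kappa)
}

as_param_set <- function(params) {
  full <- param_set()
  if (is.null(names(params))) {
    stop("parameters must be a named vector")
  }
  unknown <- setdiff(names(params), names(full))
  if (length(unknown) > 0L) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  full[names(params)] <- params
  full
}

#' Initialize learner state
#'
#' Fresh state for a model over `n_contexts` symbol pairs: value function
#' `Q = 0`, decision trace equal to `Q`, demonstrator policy uniform,
#' demonstrator values 0, per-state imitation rate 0, and no last action.
#'
#' @param spec A [model_spec()].
#' @param n_contexts Number of choice contexts (symbol pairs).
#' @return A list of class `"learner_state"`.
#' @export
init_state <- function(spec, n_contexts) {
  stopifnot(inherits(spec, "model_spec"), n_contexts >= 1L)
  structure(list(
    spec = spec, n_contexts = as.integer(n_contexts),
    Q = matrix(0, n_contexts, 2),
    Q_prime = matrix(0, n_contexts, 2),
    pi_trace = rep(0.5, n_contexts),
    trace_on = rep(FALSE, n_contexts),
    pi_D = rep(0.5, n_contexts),       # P(demonstrator chooses option 1)
    Q_D = matrix(0, n_contexts, 2),
    alpha_i_state = rep(0, n_contexts),
    last_action = rep(0L, n_contexts)  # 0 = none
  ), class = "learner_state")
}

softmax_pair <- function(v, last_action, beta, kappa) {
  lam1 <- if (last_action == 0L) 0 else if (last_action == 1L) 1 else -1
  p1 <- 1 / (1 + exp(pmin(pmax(beta * (v[2] - v[1] - lam1 * kappa), -700), 700)))
  c(p1, 1 - p1)
}

#' Softmax action policy
#'
#' Probability of each symbol under the softmax with choice autocorrelation:
#' `pi(c) = 1 / (1 + exp(beta * (V(cbar) - V(c) - lambda(c) * kappa)))`, with
#' `lambda(c) = +1` if `c` is the last performed action and `-1` otherwise
#' (0 before any action).
#'
#' @param state A [init_state()] learner state.
#' @param context Context index.
#' @param params A [param_set()].
#' @param decision_source `"Q"` (the value function), `"Q_prime"` (the
#'   decision-biasing trace, falling back to `Q` when no trace is active) or
#'   `"biased"` (the policy actually used for the next private choice, see
#'   [decision_values()]).
#' @return Numeric pair of probabilities summing to 1.
#' @export
policy <- function(state, context, params,
                   decision_source = c("Q", "Q_prime", "biased")) {
  decision_source <- match.arg(decision_source)
  params <- as_param_set(params)
  if (decision_source == "biased") {
    return(decision_values(state, context, params, state$spec))
  }
  v <- switch(decision_source,
    Q = state$Q[context, ],
    Q_prime = if (state$trace_on[context]) state$Q_prime[context, ] else state$Q[context, ]
  )
  kap <- if (state$spec$use_kappa) params[["kappa"]] else 0
  p <- softmax_pair(v, state$last_action[context], params[["beta"]], kap)
  if (any(!is.finite(p))) stop("non-finite policy")
  p
}

#' Private value update
#'
#' Rescorla-Wagner update after a private choice `c` with outcome `r`:
#' `Q(c) <- Q(c) + alpha_p * (r - Q(c))`, and under the symmetric variant
#' also `Q(cbar) <- Q(cbar) + alpha_p * (-r - Q(cbar))`. The choice becomes
#' the last performed action and any decision-biasing trace is cleared.
#'
#' @inheritParams policy
#' @param choice Chosen option (1 or 2).
#' @param outcome Outcome in `{+1, -1}`.
#' @param symmetric Apply the symmetric update; defaults to the spec's flag.
#' @return The updated state.
#' @export
private_update <- function(state, context, choice, outcome, params,
                           symmetric = state$spec$symmetric_private) {
  stopifnot(choice %in% c(1L, 2L))
  if (!outcome %in% c(-1, 1)) stop("outcome must be +1 or -1")
  params <- as_param_set(params)
  ap <- params[["alpha_p"]]
  other <- 3L - choice
  state$Q[context, choice] <- state$Q[context, choice] +
    ap * (outcome - state$Q[context, choice])
  if (symmetric) {
    state$Q[context, other] <- state$Q[context, other] +
      ap * (-outcome - state$Q[context, other])
  }
  state$last_action[context] <- as.integer(choice)
  state$trace_on[context] <- FALSE
  state
}

#' Integrate a demonstration
#'
#' Applies the model family's observational update for a demonstration `d`:
#'
#' * `DB1`-`DB3`: re-derive the decision trace from `Q` (policy for DB1,
#'   value copy for DB2/DB3), then bias it toward `d` (policy update, value
#'   update, or symmetric value update).
#' * `DB4`-`DB6`: the same bias rules on a persistent trace, so consecutive
#'   demonstrations accumulate.
#' * `MB1`-`MB9`: update the demonstrator model (policy `pi_D` for MB1-3,
#'   values `Q_D` for MB4-6, symmetric for MB7-9) at rate `alpha_d`; `Q` is
#'   untouched.
#' * `VS1`/`VS2`: treat `d` as a surrogate reward,
#'   `Q(d) <- Q(d) + alpha_i * (1 - Q(d))`, and for VS2 also
#'   `Q(dbar) <- Q(dbar) + alpha_i * (-1 - Q(dbar))`.
#' * `metaVS`: first update the per-state imitation rate,
#'   `alpha_i(s) <- alpha_i(s) + alpha_m * (tau - alpha_i(s))` with `tau = 1`
#'   iff `Q(d) = max(Q(d), Q(dbar))`, then apply the symmetric value-shaping
#'   update at rate `alpha_i(s)`.
#'
#' When the spec's `obs_match_last_action` flag is set (off by default), the
#' demonstrated symbol becomes the last performed action.
#'
#' @inheritParams policy
#' @param demonstration Demonstrated option (1 or 2).
#' @param spec The model spec (defaults to the state's).
#' @return The updated state.
#' @export
observe_demonstration <- function(state, context, demonstration, params,
                                  spec = state$spec) {
  stopifnot(demonstration %in% c(1L, 2L))
  params <- as_param_set(params)
  d <- as.integer(demonstration)
  db <- 3L - d
  ai <- params[["alpha_i"]]
  kap <- if (spec$use_kappa) params[["kappa"]] else 0

  if (spec$family == "DB") {
    kind <- (spec$variant - 1L) %% 3L
    accumulate <- spec$variant > 3L
    if (!accumulate || !state$trace_on[context]) {
      if (kind == 0L) {
        state$pi_trace[context] <- softmax_pair(
          state$Q[context, ], state$last_action[context],
          params[["beta"]], kap
        )[1]
      } else {
        state$Q_prime[context, ] <- state$Q[context, ]
      }
    }
    if (kind == 0L) {
      pd <- if (d == 1L) state$pi_trace[context] else 1 - state$pi_trace[context]
      pd <- pd + ai * (1 - pd)
      state$pi_trace[context] <- if (d == 1L) pd else 1 - pd
    } else {
      state$Q_prime[context, d] <- state$Q_prime[context, d] +
        ai * (1 - state$Q_prime[context, d])
      if (kind == 2L) {
        state$Q_prime[context, db] <- state$Q_prime[context, db] +
          ai * (-1 - state$Q_prime[context, db])
      }
    }
    state$trace_on[context] <- TRUE
  } else if (spec$family == "MB") {
    ad <- params[["alpha_d"]]
    model_kind <- (spec$variant - 1L) %/% 3L
    if (model_kind == 0L) {
      pd <- if (d == 1L) state$pi_D[context] else 1 - state$pi_D[context]
      pd <- pd + ad * (1 - pd)
      state$pi_D[context] <- if (d == 1L) pd else 1 - pd
    } else {
      state$Q_D[context, d] <- state$Q_D[context, d] +
        ad * (1 - state$Q_D[context, d])
      if (model_kind == 2L) {
        state$Q_D[context, db] <- state$Q_D[context, db] +
          ad * (-1 - state$Q_D[context, db])
      }
    }
  } else if (spec$family == "VS") {
    state$Q[context, d] <- state$Q[context, d] + ai * (1 - state$Q[context, d])
    if (spec$variant == 2L) {
      state$Q[context, db] <- state$Q[context, db] +
        ai * (-1 - state$Q[context, db])
    }
  } else if (spec$family == "metaVS") {
    tau <- as.numeric(state$Q[context, d] >= state$Q[context, db])
    state$alpha_i_state[context] <- state$alpha_i_state[context] +
      params[["alpha_m"]] * (tau - state$alpha_i_state[context])
    a <- state$alpha_i_state[context]
    state$Q[context, d] <- state$Q[context, d] + a * (1 - state$Q[context, d])
    state$Q[context, db] <- state$Q[context, db] + a * (-1 - state$Q[context, db])
  } else if (spec$family != "RW") {
    stop("unknown model family: ", spec$family)
  }
  if (spec$obs_match_last_action) state$last_action[context] <- d
  state
}

#' Policy used for the next private choice
#'
#' The action probabilities a model actually uses on a private trial: the
#' softmax on `Q` for RW/VS/metaVS; the biased policy or `Q_prime` trace for
#' DB (falling back to `Q` when no trace is active); and for MB the softmax
#' on `Q` biased toward the demonstrator model's preferred symbol (argmax of
#' `pi_D` or `Q_D`; ties leave the policy unbiased) with magnitude `alpha_i`
#' using the variant's bias step.
#'
#' @inheritParams policy
#' @param spec The model spec (defaults to the state's).
#' @return Numeric pair of probabilities summing to 1.
#' @export
decision_values <- function(state, context, params, spec = state$spec) {
  params <- as_param_set(params)
  kap <- if (spec$use_kappa) params[["kappa"]] else 0
  beta <- params[["beta"]]
  ai <- params[["alpha_i"]]
  last <- state$last_action[context]
  base <- function(v) softmax_pair(v, last, beta, kap)

  if (spec$family %in% c("RW", "VS", "metaVS")) {
    return(base(state$Q[context, ]))
  }
  if (spec$family == "DB") {
    if (!state$trace_on[context]) return(base(state$Q[context, ]))
    kind <- (spec$variant - 1L) %% 3L
    if (kind == 0L) {
      p1 <- state$pi_trace[context]
      return(c(p1, 1 - p1))
    }
    return(base(state$Q_prime[context, ]))
  }
  if (spec$family == "MB") {
    model_kind <- (spec$variant - 1L) %/% 3L
    pref1 <- if (model_kind == 0L) state$pi_D[context] - 0.5 else
      state$Q_D[context, 1] - state$Q_D[context, 2]
    if (pref1 == 0) return(base(state$Q[context, ]))
    dstar <- if (pref1 > 0) 1L else 2L
    bias_kind <- (spec$variant - 1L) %% 3L
    if (bias_kind == 0L) {
      p <- base(state$Q[context, ])
      pd <- p[dstar] + ai * (1 - p[dstar])
      p[dstar] <- pd
      p[3L - dstar] <- 1 - pd
      return(p)
    }
    v <- state$Q[context, ]
    v[dstar] <- v[dstar] + ai * (1 - v[dstar])
    if (bias_kind == 2L) {
      v[3L - dstar] <- v[3L - dstar] + ai * (-1 - v[3L - dstar])
    }
    return(base(v))
  }
  stop("unknown model family: ", spec$family)
}
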