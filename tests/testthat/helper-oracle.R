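# Independent reference implementations used as oracles.

# From-scratch NLL for the RW / VS / metaVS families (softmax with
# autocorrelation, symmetric or asymmetric private update), written directly
# from the update equations without using package state objects.
oracle_nll_valuefam <- function(family = c("RW", "VS", "metaVS"), variant = 1L,
                                params, trials, symmetric_private = TRUE,
                                obs_match = FALSE) {
  family <- match.arg(family)
  ap <- params[["alpha_p"]]; ai <- params[["alpha_i"]]
  am <- params[["alpha_m"]]; beta <- params[["beta"]]; kap <- params[["kappa"]]
  ctxs <- unique(trials$context_id)
  Q <- matrix(0, length(ctxs), 2)
  ais <- rep(0, length(ctxs))
  last <- rep(0L, length(ctxs))
  nll <- 0
  for (t in seq_len(nrow(trials))) {
    cx <- match(trials$context_id[t], ctxs)
    if (trials$trial_type[t] == "observational") {
      d <- if (trials$demonstration[t] == trials$option_a[t]) 1L else 2L
      u <- 3L - d
      if (family == "VS") {
        Q[cx, d] <- Q[cx, d] + ai * (1 - Q[cx, d])
        if (variant == 2L) Q[cx, u] <- Q[cx, u] + ai * (-1 - Q[cx, u])
      } else if (family == "metaVS") {
        tau <- as.numeric(Q[cx, d] >= Q[cx, u])
        ais[cx] <- ais[cx] + am * (tau - ais[cx])
        Q[cx, d] <- Q[cx, d] + ais[cx] * (1 - Q[cx, d])
        Q[cx, u] <- Q[cx, u] + ais[cx] * (-1 - Q[cx, u])
      }
      if (obs_match) last[cx] <- d
    } else {
      c_ <- if (trials$choice[t] == trials$option_a[t]) 1L else 2L
      u <- 3L - c_
      lam <- if (last[cx] == 0L) 0 else if (last[cx] == c_) 1 else -1
      p <- 1 / (1 + exp(beta * (Q[cx, u] - Q[cx, c_] - lam * kap)))
      nll <- nll - log(max(p, 1e-12))
      r <- trials$outcome[t]
      Q[cx, c_] <- Q[cx, c_] + ap * (r - Q[cx, c_])
      if (symmetric_private) Q[cx, u] <- Q[cx, u] + ap * (-r - Q[cx, u])
      last[cx] <- c_
    }
  }
  nll
}

# NLL composed from the package's exported stepwise state operations
# (init_state / observe_demonstration / decision_values / private_update):
# an R code path fully separate from the compiled engine.
stepwise_nll <- function(spec, params, trials) {
  ctxs <- unique(trials$context_id)
  state <- init_state(spec, length(ctxs))
  nll <- 0
  for (t in seq_len(nrow(trials))) {
    cx <- match(trials$context_id[t], ctxs)
    if (trials$trial_type[t] == "observational") {
      d <- if (trials$demonstration[t] == trials$option_a[t]) 1L else 2L
      state <- observe_demonstration(state, cx, d, params)
    } else {
      p <- decision_values(state, cx, params)
      c_ <- if (trials$choice[t] == trials$option_a[t]) 1L else 2L
      nll <- nll - log(max(p[c_], 1e-12))
      state <- private_update(state, cx, c_, trials$outcome[t], params)
    }
  }
  nll
}

# Small deterministic trial table for hand-checks: one context, explicit
# trial types / demonstrations / choices / outcomes.
tiny_trials <- function(types, demos = NULL, choices = NULL, outcomes = NULL) {
  n <- length(types)
  data.frame(
    subject_id = "t", session = 1L, block = 1L, trial_index = seq_len(n) - 1L,
    condition = "SD", context_id = "c1",
    trial_type = types, option_a = "A", option_b = "B",
    demonstration = demos %||% rep(NA_character_, n),
    choice = choices %||% rep(NA_character_, n),
    outcome = outcomes %||% rep(NA_real_, n),
    p_a = 0.7, p_b = 0.3, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
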