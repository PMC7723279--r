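#' Task configuration for an observational bandit experiment
#'
#' Builds the design object consumed by [make_schedule()]. Three built-in
#' styles emulate the published designs:
#'
#' * `"exp1"`: 4 sessions of five 20-trial blocks (one private `P` block and
#'   two blocks each with a skilled (`SD`) and unskilled (`UD`) demonstrator,
#'   within-subject), stable 0.7/0.3 contingencies, observational:private
#'   ratio 1:1 in observational blocks (400 trials total).
#' * `"exp2"`: 3 sessions of five 20-trial blocks (one `P`, four with the
#'   subject's demonstrator condition, between-subject), 0.6/0.4
#'   contingencies, ratio 1:1 (300 trials).
#' * `"exp3"`: one 300-trial block per subject, reward probabilities of both
#'   symbols following independent reflected Gaussian random walks,
#'   observational:private ratio 1:2, demonstrator correct-choice rates
#'   0.84 (`SD`) or 0.60 (`UD`), between-subject.
#'
#' Demonstrations occur in runs of 1 to `max_obs_run` consecutive
#' observational trials, with at most `max_same_option_run` consecutive
#' demonstrations of the same symbol.
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param condition For between-subject styles (`exp2`, `exp3`), the
#'   observational condition of this subject: `"SD"` or `"UD"`.
#' @param n_sessions,trials_per_block,conditions_per_session Overrides for
#'   the per-style defaults. `conditions_per_session` is a character vector
#'   of block conditions laid out in one session (shuffled at generation).
#' @param obs_to_private_ratio Integer pair, observational:private trials in
#'   observational blocks.
#' @param p_correct Win probability of the better symbol (stable designs).
#' @param walk A list with `start`, `step_sd`, `lower`, `upper` for the
#'   random-walk design (both symbols walk independently).
#' @param demonstrators Named numeric vector of demonstrator skills
#'   (probability of demonstrating the currently reward-maximizing symbol),
#'   e.g. `c(SD = 0.8, UD = 0.2)`.
#' @param max_obs_run,max_same_option_run Run-length constraints
#'   (`max_same_option_run` defaults to `Inf` for `exp3`, whose replayed
#'   demonstrator behavior is unconstrained).
#'
#' @return A list of class `"task_config"`.
#' @export
#' @examples
#' cfg <- task_config("exp1")
#' sched <- make_schedule(cfg, seed = 1)
#' table(sched$trial_type)
task_config <- function(experiment = c("exp1", "exp2", "exp3"),
                        condition = "SD",
                        n_sessions = NULL,
                        trials_per_block = NULL,
                        conditions_per_session = NULL,
                        obs_to_private_ratio = NULL,
                        p_correct = NULL,
                        walk = NULL,
                        demonstrators = NULL,
                        max_obs_run = 7L,
                        max_same_option_run = 3L) {
  experiment <- match.arg(experiment)
  condition <- match.arg(condition, c("SD", "UD"))
  defaults <- switch(experiment,
    exp1 = list(
      n_sessions = 4L, trials_per_block = 20L,
      conditions_per_session = c("P", "SD", "SD", "UD", "UD"),
      obs_to_private_ratio = c(1L, 1L), p_correct = 0.7, walk = NULL,
      demonstrators = c(SD = 0.8, UD = 0.2)
    ),
    exp2 = list(
      n_sessions = 3L, trials_per_block = 20L,
      conditions_per_session = c("P", rep(condition, 4L)),
      obs_to_private_ratio = c(1L, 1L), p_correct = 0.6, walk = NULL,
      demonstrators = c(SD = 0.8, UD = 0.2)
    ),
    exp3 = list(
      n_sessions = 1L, trials_per_block = 300L,
      conditions_per_session = condition,
      obs_to_private_ratio = c(1L, 2L), p_correct = NULL,
      walk = list(start = 0.5, step_sd = 0.03, lower = 0.2, upper = 0.8),
      demonstrators = c(SD = 0.84, UD = 0.60)
    )
  )
  # the same-option run limit belongs to the computer-demonstrator designs;
  # the random-walk design replays free demonstrator behavior, where long
  # same-option runs are expected
  if (experiment == "exp3" && missing(max_same_option_run)) {
    max_same_option_run <- Inf
  }
  cfg <- list(
    experiment = experiment,
    condition = condition,
    n_sessions = as.integer(n_sessions %||% defaults$n_sessions),
    trials_per_block = as.integer(trials_per_block %||% defaults$trials_per_block),
    conditions_per_session = conditions_per_session %||% defaults$conditions_per_session,
    obs_to_private_ratio = as.integer(obs_to_private_ratio %||% defaults$obs_to_private_ratio),
    p_correct = p_correct %||% defaults$p_correct,
    walk = walk %||% defaults$walk,
    demonstrators = demonstrators %||% defaults$demonstrators,
    max_obs_run = as.integer(max_obs_run),
    max_same_option_run = as.numeric(max_same_option_run)
  )
  validate_task_config(cfg)
  class(cfg) <- "task_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_task_config <- function(cfg) {
  stopifnot(
    cfg$n_sessions >= 1L, cfg$trials_per_block >= 1L,
    length(cfg$obs_to_private_ratio) == 2L, all(cfg$obs_to_private_ratio >= 1L),
    cfg$max_obs_run >= 1L, cfg$max_same_option_run >= 1L,
    all(cfg$conditions_per_session %in% c("P", "SD", "UD"))
  )
  if (cfg$experiment %in% c("exp1", "exp2")) {
    if (cfg$trials_per_block != 20L) {
      stop("exp1/exp2 designs use 20-trial blocks; got ", cfg$trials_per_block)
    }
    if (!identical(cfg$obs_to_private_ratio, c(1L, 1L))) {
      stop("exp1/exp2 designs use a 1:1 observational:private ratio")
    }
    if (is.null(cfg$p_correct) || cfg$p_correct < 0 || cfg$p_correct > 1) {
      stop("stable designs need p_correct in [0, 1]")
    }
  } else {
    if (!identical(cfg$obs_to_private_ratio, c(1L, 2L))) {
      stop("exp3 designs use a 1:2 observational:private ratio")
    }
    w <- cfg$walk
    if (is.null(w) || w$step_sd < 0 || w$lower >= w$upper ||
        w$start < w$lower || w$start > w$upper) {
      stop("invalid walk configuration: need lower < upper, start within bounds, step_sd >= 0")
    }
  }
  obs_cond <- setdiff(cfg$conditions_per_session, "P")
  if (!all(obs_cond %in% names(cfg$demonstrators))) {
    stop("demonstrator skill missing for condition(s): ",
         paste(setdiff(obs_cond, names(cfg$demonstrators)), collapse = ", "))
  }
  if (any(cfg$demonstrators < 0 | cfg$demonstrators > 1)) {
    stop("demonstrator skills must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Reflected Gaussian random walk over probabilities
#'
#' Random-walk reward contingencies for the restless-bandit design: Gaussian
#' increments with standard deviation `step_sd`, reflected at the `lower` and
#' `upper` bounds.
#'
#' @param walk List with `start`, `step_sd`, `lower`, `upper`.
#' @param n_trials Length of the returned sequence.
#' @param seed Integer seed (the global RNG state is left untouched).
#' @return Numeric vector of length `n_trials`, all values within bounds.
#' @export
make_random_walk <- function(walk, n_trials, seed) {
  stopifnot(n_trials >= 1L)
  if (walk$step_sd < 0) stop("step_sd must be nonnegative")
  if (walk$lower >= walk$upper) stop("walk bounds must satisfy lower < upper")
  if (walk$start < walk$lower || walk$start > walk$upper) {
    stop("walk start must lie within bounds")
  }
  withr::with_seed(seed, {
    steps <- stats::rnorm(n_trials, 0, walk$step_sd)
    x <- numeric(n_trials)
    cur <- walk$start
    for (i in seq_len(n_trials)) {
      cur <- reflect_into(cur + steps[i], walk$lower, walk$upper)
      x[i] <- cur
    }
    x
  })
}

reflect_into <- function(x, lower, upper) {
  width <- upper - lower
  # fold into [0, 2*width), then reflect the upper half
  y <- (x - lower) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  lower + y
}

#' Sample a bandit outcome
#'
#' Draws a +1/-1 outcome for choosing `choice` in a choice context where the
#' reward-maximizing symbol wins with probability `p_correct`: the correct
#' symbol pays +1 with probability `p_correct`, the other symbol with
#' probability `1 - p_correct`.
#'
#' @param p_correct Win probability of the correct symbol.
#' @param choice Label of the chosen symbol; must be one of `symbols`.
#' @param symbols The context's two symbol labels.
#' @param correct Label of the reward-maximizing symbol.
#' @param n Number of draws.
#' @return Integer vector of `n` outcomes in `{+1, -1}`.
#' @export
#' @examples
#' withr::with_seed(1, mean(sample_outcome(0.7, "A", n = 1e4) == 1))
sample_outcome <- function(p_correct, choice, symbols = c("A", "B"),
                           correct = symbols[1], n = 1L) {
  stopifnot(p_correct >= 0, p_correct <= 1, length(symbols) == 2L)
  if (!choice %in% symbols) stop("unknown symbol: ", choice)
  if (!correct %in% symbols) stop("unknown symbol: ", correct)
  p <- if (identical(choice, correct)) p_correct else 1 - p_correct
  ifelse(stats::runif(n) < p, 1L, -1L)
}

# Partition n_obs observational trials into runs of length 1..max_run and
# interleave them with n_priv private trials so that distinct runs are
# separated by at least one private trial. Returns a logical vector
# (TRUE = observational).
interleave_block <- function(n_obs, n_priv, max_run, max_tries = 1000L) {
  if (n_obs == 0L) return(rep(FALSE, n_priv))
  for (try in seq_len(max_tries)) {
    runs <- integer(0)
    rem <- n_obs
    while (rem > 0L) {
      r <- sample.int(min(max_run, rem), 1L)
      runs <- c(runs, r)
      rem <- rem - r
    }
    k <- length(runs)
    if (k - 1L <= n_priv) {
      # distribute private trials over k+1 gaps; interior gaps get >= 1
      gaps <- rep(0L, k + 1L)
      if (k > 1L) gaps[2:k] <- 1L
      extra <- n_priv - sum(gaps)
      if (extra > 0L) {
        idx <- sample.int(k + 1L, extra, replace = TRUE)
        gaps <- gaps + tabulate(idx, nbins = k + 1L)
      }
      out <- logical(0)
      for (i in seq_len(k)) {
        out <- c(out, rep(FALSE, gaps[i]), rep(TRUE, runs[i]))
      }
      out <- c(out, rep(FALSE, gaps[k + 1L]))
      return(out)
    }
  }
  stop("could not interleave ", n_obs, " observational with ", n_priv,
       " private trials under max_obs_run = ", max_run)
}

# Demonstration sequence for one block.
#
# Stable blocks (constant correct symbol) with a finite same-option limit
# use a controlled quota: round(skill * n) correct demonstrations, arranged
# uniformly among orders satisfying the run limit. Plain per-trial
# Bernoulli(skill) draws conditioned on the limit would depress the realized
# correct-choice rate far below the nominal skill (long correct runs are the
# ones rejected), whereas the quota keeps it at skill exactly, the way a
# computer-controlled demonstrator delivers "80% correct".
#
# Walk-driven blocks (correct symbol varies by trial) or unconstrained
# configurations use independent per-trial Bernoulli(skill) draws.
draw_demonstrations <- function(correct_symbols, skill, max_same,
                                max_tries = 1000L) {
  n <- length(correct_symbols)
  if (n == 0L) return(character(0))
  other <- ifelse(correct_symbols == "A", "B", "A")
  stable <- length(unique(correct_symbols)) == 1L
  if (stable && is.finite(max_same)) {
    k <- round(skill * n)
    # k same-symbol demonstrations need ceiling(k / max_same) - 1 separators
    if (ceiling(k / max_same) - 1L > n - k ||
        ceiling((n - k) / max_same) - 1L > k) {
      stop("infeasible same-option constraint: ", k, "/", n,
           " correct demonstrations cannot satisfy max_same_option_run = ",
           max_same)
    }
    base <- c(rep(TRUE, k), rep(FALSE, n - k))
    for (try in seq_len(max_tries)) {
      pick_correct <- sample(base)
      d <- ifelse(pick_correct, correct_symbols, other)
      if (max(rle(d)$lengths) <= max_same) return(d)
    }
  } else {
    for (try in seq_len(max_tries)) {
      pick_correct <- stats::runif(n) < skill
      d <- ifelse(pick_correct, correct_symbols, other)
      if (!is.finite(max_same) || max(rle(d)$lengths) <= max_same) return(d)
    }
  }
  stop("could not draw a demonstration sequence with at most ", max_same,
       " consecutive same-option demonstrations")
}

#' Generate a trial schedule for one subject
#'
#' Lays out sessions and blocks per the configuration, interleaves
#' observational and private trials at the configured ratio (runs of 1-7
#' demonstrations, separated by private trials), draws demonstration symbols
#' at the demonstrator's skill honoring the `max_same_option_run` limit (a
#' controlled per-block quota of correct demonstrations for stable
#' contingencies, per-trial Bernoulli draws under random walks), and attaches
#' the per-trial win probabilities of both symbols. Choices and outcomes are
#' left unfilled; see [simulate_agent()].
#'
#' Symbols are labelled `"A"`/`"B"` within each context; which one is
#' reward-maximizing is randomized per block (stable designs) or follows the
#' walks (exp3).
#'
#' @param config A [task_config()].
#' @param seed Integer seed; schedules are bitwise reproducible given
#'   `(config, seed)`.
#' @param subject_id Subject identifier written into the records.
#' @return A `data.frame` of trial records with columns `subject_id`,
#'   `session`, `block`, `trial_index` (0-based within block), `condition`,
#'   `context_id`, `trial_type`, `option_a`, `option_b`, `demonstration`,
#'   `choice`, `outcome`, `p_a`, `p_b`.
#' @export
make_schedule <- function(config, seed, subject_id = "s01") {
  validate_task_config(config)
  ratio <- config$obs_to_private_ratio
  tpb <- config$trials_per_block
  per_unit <- sum(ratio)
  withr::with_seed(seed, {
    records <- list()
    for (ses in seq_len(config$n_sessions)) {
      conds <- sample(config$conditions_per_session)
      for (b in seq_along(conds)) {
        cond <- conds[b]
        ctx <- sprintf("%s.s%d.b%d", subject_id, ses, b)
        if (cond == "P") {
          is_obs <- rep(FALSE, tpb)
        } else {
          if (tpb %% per_unit != 0L) {
            stop("block length ", tpb, " is not divisible by the ",
                 "observational:private ratio ", ratio[1], ":", ratio[2])
          }
          n_obs <- tpb %/% per_unit * ratio[1]
          is_obs <- interleave_block(n_obs, tpb - n_obs, config$max_obs_run)
        }
        if (is.null(config$walk)) {
          a_correct <- stats::runif(1) < 0.5
          p_a <- rep(if (a_correct) config$p_correct else 1 - config$p_correct, tpb)
          p_b <- 1 - p_a
        } else {
          p_a <- make_random_walk(config$walk, tpb, seed = sample.int(2^30, 1L))
          p_b <- make_random_walk(config$walk, tpb, seed = sample.int(2^30, 1L))
        }
        demonstration <- rep(NA_character_, tpb)
        if (any(is_obs)) {
          correct <- ifelse(p_a[is_obs] >= p_b[is_obs], "A", "B")
          demonstration[is_obs] <- draw_demonstrations(
            correct, config$demonstrators[[cond]], config$max_same_option_run
          )
        }
        records[[length(records) + 1L]] <- data.frame(
          subject_id = subject_id, session = ses, block = b,
          trial_index = seq_len(tpb) - 1L, condition = cond,
          context_id = ctx,
          trial_type = ifelse(is_obs, "observational", "private"),
          option_a = "A", option_b = "B",
          demonstration = demonstration,
          choice = NA_character_, outcome = NA_real_,
          p_a = p_a, p_b = p_b,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, records)
  })
}

#' Check a schedule against the design constraints
#'
#' Pure validation of a (possibly hand-built) schedule: per-constraint
#' pass/fail for the trial-record schema, the observational:private ratio,
#' the maximum run of consecutive observational trials, the maximum run of
#' same-option demonstrations, and block lengths. Malformed records are
#' reported, not raised.
#'
#' @param schedule A trial-record `data.frame` (see [make_schedule()]).
#' @param config Optional [task_config()] supplying the expected ratio,
#'   block length and run limits; defaults check only the schema and the
#'   published run limits (7 and 3).
#' @return A `data.frame` with columns `constraint`, `pass`, `detail`.
#' @export
validate_schedule <- function(schedule, config = NULL) {
  stopifnot(nrow(schedule) > 0L)
  max_obs_run <- if (is.null(config)) 7L else config$max_obs_run
  max_same <- if (is.null(config)) 3L else config$max_same_option_run
  res <- list()
  add <- function(constraint, pass, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(
      constraint = constraint, pass = pass, detail = detail,
      stringsAsFactors = FALSE
    )
  }

  needed <- c("subject_id", "session", "block", "trial_index", "condition",
              "context_id", "trial_type", "option_a", "option_b",
              "demonstration", "choice", "outcome")
  missing_cols <- setdiff(needed, names(schedule))
  add("schema_columns", length(missing_cols) == 0L,
      paste(missing_cols, collapse = ","))
  if (length(missing_cols) > 0L) {
    return(do.call(rbind, res))
  }

  obs <- schedule$trial_type == "observational"
  bad_demo <- obs & (is.na(schedule$demonstration) |
                       !(schedule$demonstration == schedule$option_a |
                           schedule$demonstration == schedule$option_b))
  add("observational_trials_carry_demonstration", !any(bad_demo),
      if (any(bad_demo)) paste("rows", paste(which(bad_demo), collapse = ",")) else "")

  by_block <- split(seq_len(nrow(schedule)),
                    list(schedule$subject_id, schedule$session, schedule$block),
                    drop = TRUE)
  runs_obs <- 0L
  runs_same <- 0L
  ratio_ok <- TRUE
  for (idx in by_block) {
    o <- schedule$trial_type[idx] == "observational"
    if (any(o)) {
      r <- rle(o)
      runs_obs <- max(runs_obs, max(r$lengths[r$values]))
      d <- schedule$demonstration[idx][o]
      runs_same <- max(runs_same, max(rle(d)$lengths))
      if (!is.null(config)) {
        ratio <- config$obs_to_private_ratio
        ratio_ok <- ratio_ok && sum(o) * ratio[2] == sum(!o) * ratio[1]
      }
    }
  }
  add("max_observational_run", runs_obs <= max_obs_run,
      sprintf("observed %d, limit %s", runs_obs, format(max_obs_run)))
  add("max_same_option_demonstration_run", runs_same <= max_same,
      sprintf("observed %d, limit %s", runs_same, format(max_same)))
  if (!is.null(config)) {
    add("obs_to_private_ratio", ratio_ok, "")
    lens <- vapply(by_block, length, integer(1))
    add("block_length", all(lens == config$trials_per_block),
        sprintf("lengths %s", paste(sort(unique(lens)), collapse = ",")))
  }
  do.call(rbind, res)
}
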