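# A deterministic copier: always repeats the most recent demonstration in
# the block (chance before the first demonstration).
simulate_copier <- function(sched, seed, blind = FALSE) {
  out <- sched
  withr::with_seed(seed, {
    for (idx in socialrl:::block_windows(sched)) {
      last_demo <- NA_character_
      for (t in idx) {
        if (out$trial_type[t] == "observational") {
          last_demo <- out$demonstration[t]
        } else {
          out$choice[t] <- if (blind || is.na(last_demo)) {
            sample(c("A", "B"), 1L)
          } else last_demo
          p <- if (out$choice[t] == "A") out$p_a[t] else out$p_b[t]
          out$outcome[t] <- if (runif(1) < p) 1 else -1
        }
      }
    }
  })
  out
}

test_that("correct choice rate reflects ground truth", {
  cfg <- task_config("exp1")
  sched <- make_schedule(cfg, seed = 1)
  always <- sched
  always$choice[always$trial_type == "private"] <-
    with(always[always$trial_type == "private", ],
         ifelse(p_a >= p_b, option_a, option_b))
  always$outcome[always$trial_type == "private"] <- 1
  expect_equal(correct_choice_rate(always), 1.0)

  rand <- simulate_copier(sched, seed = 2, blind = TRUE)
  expect_lt(abs(correct_choice_rate(rand) - 0.5), 0.15)

  sharp <- simulate_agent(model_spec("RW2"),
                          param_set(alpha_p = 0.5, beta = 20),
                          sched, seed = 3)
  expect_gt(correct_choice_rate(sharp), 0.6)
  expect_error(correct_choice_rate(sched), "private trials")
})

test_that("imitation rate separates copiers from demonstration-blind agents", {
  cfg <- task_config("exp1")
  sched <- make_schedule(cfg, seed = 4)
  cop <- simulate_copier(sched, seed = 5)
  expect_equal(imitation_rate(cop, 1L), 1.0)
  blind_rates <- vapply(1:10, function(i) {
    imitation_rate(simulate_copier(make_schedule(cfg, seed = 40 + i),
                                   seed = 50 + i, blind = TRUE), 1L)
  }, numeric(1))
  expect_lt(abs(mean(blind_rates) - 0.5), 0.05)
})

test_that("accumulation and propagation have the expected signs for copiers", {
  cfg <- task_config("exp1")
  accs <- props <- numeric(0)
  for (i in 1:10) {
    sched <- make_schedule(cfg, seed = 60 + i)
    cop <- simulate_copier(sched, seed = 70 + i)
    accs <- c(accs, accumulation(cop))
    blind <- simulate_copier(sched, seed = 80 + i, blind = TRUE)
    props <- c(props, propagation(blind))
  }
  # last-demonstration copier: lag-1 match is 1, lag-2 only when the two
  # demonstrations agree -> positive differential
  expect_gt(mean(accs), 0.1)
  # demonstration-blind agent: both differentials ~ 0
  expect_lt(abs(mean(props)), 0.05)
})

test_that("eligibility windows ignore non-qualifying trials", {
  # a block with an isolated demonstration cannot contribute to accumulation
  trials <- tiny_trials(c("observational", "private", "private"),
                        demos = c("A", NA, NA),
                        choices = c(NA, "A", "B"),
                        outcomes = c(NA, 1, -1))
  expect_error(accumulation(trials), "runs")
  expect_equal(propagation(trials), 1) # c_{t+1} matches, c_{t+2} does not
  expect_equal(imitation_rate(trials, 1L), 0.5)
  expect_error(imitation_rate(trials, 2L), "demonstrations")
})

test_that("signature ordering separates the model families", {
  # simulated cohorts at matched, fitted-scale parameters
  cfg <- task_config("exp2")
  prm <- param_set(alpha_p = 0.2, alpha_i = 0.2, beta = 3)
  sims <- list()
  for (id in c("DB1", "DB6", "VS2", "MB9")) {
    sims[[id]] <- do.call(rbind, lapply(1:30, function(i) {
      sched <- make_schedule(cfg, seed = 90 + i,
                             subject_id = sprintf("%s.%02d", id, i))
      simulate_agent(model_spec(id), prm, sched, seed = 190 + i)
    }))
  }
  acc <- vapply(sims, accumulation, numeric(1))
  prop <- vapply(sims, propagation, numeric(1))
  # DB1 lacks accumulation: its lag-1/lag-2 differential is the largest;
  # the accumulating variants keep both lags comparable
  expect_gt(acc[["DB1"]], acc[["DB6"]])
  expect_gt(acc[["DB1"]], acc[["MB9"]])
  # decision-biasing traces die after one private choice: both DB variants
  # show larger propagation differentials than the value-storing models
  expect_gt(prop[["DB6"]], prop[["VS2"]])
  expect_gt(prop[["DB6"]], prop[["MB9"]])
  expect_gt(prop[["DB1"]], prop[["MB9"]])
  expect_lt(abs(prop[["VS2"]]), 0.1)
  expect_lt(abs(prop[["MB9"]]), 0.1)
})

test_that("observed-vs-simulated self-consistency gives slope ~ 1", {
  cfg <- task_config("exp2")
  spec <- model_spec("VS2")
  prms <- list()
  datasets <- list()
  for (i in 1:8) {
    prm <- param_set(alpha_p = 0.3, alpha_i = 0.1 + 0.05 * i, beta = 4)
    sched <- make_schedule(cfg, seed = 200 + i,
                           subject_id = sprintf("s%02d", i))
    datasets[[sprintf("s%02d", i)]] <- simulate_agent(spec, prm, sched,
                                                      seed = 300 + i)
    prms[[sprintf("s%02d", i)]] <- prm
  }
  res <- observed_vs_simulated(datasets, spec, prms, n_sims = 10L, seed = 9L)
  expect_gt(res$across_trial_rho, 0.2)
  expect_lt(abs(res$slope - 1), 0.6)
  expect_lt(abs(res$intercept), 0.4)

  # constant-choice subjects are flagged, not correlated
  const <- datasets[[1]]
  const$choice[const$trial_type == "private"] <- "A"
  res2 <- observed_vs_simulated(list(s01 = const), spec, prms[1], n_sims = 3L,
                                seed = 10L)
  expect_equal(res2$degenerate_subjects, "s01")
})
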