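test_that("generated schedules respect block structure and trial ratios", {
  for (exp in c("exp1", "exp2")) {
    cfg <- task_config(exp)
    sched <- make_schedule(cfg, seed = 7)
    blocks <- split(sched, list(sched$session, sched$block), drop = TRUE)
    expect_true(all(vapply(blocks, nrow, integer(1)) == 20L))
    for (blk in blocks) {
      n_obs <- sum(blk$trial_type == "observational")
      if (blk$condition[1] == "P") expect_equal(n_obs, 0L)
      else expect_equal(n_obs, 10L) # 1:1 ratio in 20-trial blocks
    }
  }
  cfg3 <- task_config("exp3")
  s3 <- make_schedule(cfg3, seed = 7)
  expect_equal(nrow(s3), 300L)
  expect_equal(sum(s3$trial_type == "private"),
               2L * sum(s3$trial_type == "observational"))
})

test_that("run-length constraints hold across many seeds", {
  cfg <- task_config("exp1")
  max_obs <- 0L
  max_same <- 0L
  for (seed in 0:19) {
    sched <- make_schedule(cfg, seed = seed)
    rep_ <- validate_schedule(sched, cfg)
    expect_true(all(rep_$pass), info = paste("seed", seed))
    blocks <- split(sched, list(sched$session, sched$block), drop = TRUE)
    for (blk in blocks) {
      o <- blk$trial_type == "observational"
      if (any(o)) {
        r <- rle(o)
        max_obs <- max(max_obs, max(r$lengths[r$values]))
        max_same <- max(max_same, max(rle(blk$demonstration[o])$lengths))
      }
    }
  }
  expect_lte(max_obs, 7L)
  expect_lte(max_same, 3L)
})

test_that("demonstrator skill governs the demonstration correct-choice rate", {
  # degenerate Bernoulli policies produce constant runs, so the same-option
  # limit is lifted for this check
  cfg_perfect <- task_config("exp1", demonstrators = c(SD = 1, UD = 0),
                             max_same_option_run = Inf)
  sched <- make_schedule(cfg_perfect, seed = 3)
  obs <- sched[sched$trial_type == "observational" & sched$condition == "SD", ]
  correct <- ifelse(obs$p_a >= obs$p_b, obs$option_a, obs$option_b)
  expect_true(all(obs$demonstration == correct))

  # binomial check at n >= 1000 demonstrations, skill 0.8
  cfg <- task_config("exp1")
  hits <- 0L; n <- 0L; seed <- 0L
  while (n < 1000L) {
    sched <- make_schedule(cfg, seed = 100L + seed)
    obs <- sched[sched$trial_type == "observational" & sched$condition == "SD", ]
    correct <- ifelse(obs$p_a >= obs$p_b, obs$option_a, obs$option_b)
    hits <- hits + sum(obs$demonstration == correct)
    n <- n + nrow(obs)
    seed <- seed + 1L
  }
  ci <- binom.test(hits, n, p = 0.8)$conf.int
  expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
})

test_that("schedules are bitwise reproducible given (config, seed)", {
  cfg <- task_config("exp2", condition = "UD")
  expect_identical(make_schedule(cfg, seed = 11), make_schedule(cfg, seed = 11))
  expect_false(identical(make_schedule(cfg, seed = 11),
                         make_schedule(cfg, seed = 12)))
})

test_that("sample_outcome follows the contingency and rejects unknown symbols", {
  expect_equal(sample_outcome(1, "A", n = 5L), rep(1L, 5L))
  expect_error(sample_outcome(0.7, "Z"), "unknown symbol")
  wins <- withr::with_seed(1, mean(sample_outcome(0.7, "A", n = 10000L) == 1L))
  expect_lt(abs(wins - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
  wins_bad <- withr::with_seed(2, mean(sample_outcome(0.7, "B", n = 10000L) == 1L))
  expect_lt(abs(wins_bad - 0.3), 3 * sqrt(0.7 * 0.3 / 10000))
  wins_even <- withr::with_seed(3, mean(sample_outcome(0.5, "A", n = 10000L) == 1L))
  expect_lt(abs(wins_even - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("random walks stay within bounds, reflect, and match the step scale", {
  w <- list(start = 0.5, step_sd = 0.03, lower = 0.2, upper = 0.8)
  x <- make_random_walk(w, 10000L, seed = 5)
  expect_length(x, 10000L)
  expect_true(all(x >= 0.2 & x <= 0.8))
  expect_identical(x, make_random_walk(w, 10000L, seed = 5))

  expect_equal(make_random_walk(list(start = 0.4, step_sd = 0, lower = 0.2,
                                     upper = 0.8), 50L, seed = 1),
               rep(0.4, 50L))
  # reflection at the lower bound under large shocks
  xlow <- make_random_walk(list(start = 0.2, step_sd = 0.5, lower = 0.2,
                                upper = 0.8), 200L, seed = 2)
  expect_true(all(xlow >= 0.2))
  # increment sd away from bounds ~ step_sd
  wide <- list(start = 0.5, step_sd = 0.01, lower = 0.01, upper = 0.99)
  y <- make_random_walk(wide, 10000L, seed = 6)
  expect_lt(abs(sd(diff(y)) - 0.01) / 0.01, 0.1)
  expect_error(make_random_walk(list(start = 0.5, step_sd = -1, lower = 0,
                                     upper = 1), 10L, seed = 1), "nonnegative")
})

test_that("validate_schedule flags hand-built violations", {
  cfg <- task_config("exp2")
  sched <- make_schedule(cfg, seed = 1)
  # 8 consecutive observational trials in one block
  bad <- sched
  idx <- which(bad$session == 1 & bad$block == 2)[1:8]
  bad$trial_type[idx] <- "observational"
  bad$demonstration[idx] <- rep(c("A", "B"), 4L)
  rep_ <- validate_schedule(bad)
  expect_false(rep_$pass[rep_$constraint == "max_observational_run"])

  # observational trial with missing demonstration
  bad2 <- sched
  i <- which(bad2$trial_type == "observational")[1]
  bad2$demonstration[i] <- NA_character_
  rep2 <- validate_schedule(bad2)
  expect_false(rep2$pass[rep2$constraint == "observational_trials_carry_demonstration"])

  # generator output passes everything
  expect_true(all(validate_schedule(sched, cfg)$pass))
})

test_that("infeasible configurations raise named errors", {
  expect_error(task_config("exp1", trials_per_block = 21),
               "20-trial blocks")
  expect_error(task_config("exp1", obs_to_private_ratio = c(1L, 3L)), "1:1")
  expect_error(task_config("exp3", walk = list(start = 0.9, step_sd = 0.03,
                                               lower = 0.2, upper = 0.8)),
               "walk")
  cfg <- task_config("exp2")
  cfg$max_obs_run <- 1L   # 10 obs runs need 9 separators; only 10 available, ok
  expect_silent(make_schedule(cfg, seed = 1))
  expect_error(socialrl:::interleave_block(10L, 3L, 1L), "interleave")
})
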