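test_that("state initialization is neutral everywhere", {
  st <- init_state(model_spec("metaVS"), 3L)
  expect_equal(st$Q, matrix(0, 3, 2))
  expect_equal(st$alpha_i_state, rep(0, 3))
  expect_equal(st$pi_D, rep(0.5, 3))
  expect_equal(st$Q_D, matrix(0, 3, 2))
  expect_equal(st$last_action, rep(0L, 3))
})

test_that("softmax policy matches its closed form", {
  st <- init_state(model_spec("RW1"), 1L)
  # beta = 0: flat policy
  expect_equal(policy(st, 1L, param_set(beta = 0)), c(0.5, 0.5))
  # equal values, kappa = 0: symmetric
  expect_equal(policy(st, 1L, param_set(beta = 5)), c(0.5, 0.5))
  # V = (1, 0), beta = 1, kappa = 0, no last action
  st$Q[1, ] <- c(1, 0)
  p <- policy(st, 1L, param_set(beta = 1, kappa = 0))
  expect_equal(p[1], 1 / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(sum(p), 1)
  # autocorrelation: repeating the last action is favored
  st$Q[1, ] <- c(0, 0)
  st$last_action[1] <- 1L
  p_pers <- policy(st, 1L, param_set(beta = 1, kappa = 0.5))
  expect_equal(p_pers[1], 1 / (1 + exp(1 * (0 - 0 - 0.5))), tolerance = 1e-12)
})

test_that("private updates follow the delta rule", {
  st <- init_state(model_spec("RW1"), 1L)
  st <- private_update(st, 1L, 1L, 1, param_set(alpha_p = 0.5), symmetric = FALSE)
  expect_equal(st$Q[1, ], c(0.5, 0))
  expect_equal(st$last_action[1], 1L)
  # symmetric variant moves the unchosen value toward -r
  st2 <- init_state(model_spec("RW2"), 1L)
  st2 <- private_update(st2, 1L, 1L, 1, param_set(alpha_p = 0.5))
  expect_equal(st2$Q[1, ], c(0.5, -0.5))
  # alpha_p = 0 leaves values unchanged
  st3 <- private_update(init_state(model_spec("RW1"), 1L), 1L, 2L, -1,
                        param_set(alpha_p = 0))
  expect_equal(st3$Q[1, ], c(0, 0))
  expect_error(private_update(st, 1L, 1L, 0.5, param_set()), "\\+1 or -1")
})

test_that("repeated updates converge to the outcome mean", {
  # stochastic approximation: Q(c) tracks the running mean of r
  params <- param_set(alpha_p = 0.05)
  st <- init_state(model_spec("RW1"), 1L)
  rs <- withr::with_seed(9, ifelse(runif(2000) < 0.7, 1, -1))
  for (r in rs) st <- private_update(st, 1L, 1L, r, params, symmetric = FALSE)
  expect_lt(abs(st$Q[1, 1] - 0.4), 0.15)
})

test_that("demonstration updates match hand-evaluated arithmetic", {
  # DB1: pi(d) = 0.5 -> 0.6 under alpha_i = 0.2
  st <- init_state(model_spec("DB1"), 1L)
  st <- observe_demonstration(st, 1L, 1L, param_set(alpha_i = 0.2, beta = 1))
  expect_equal(st$pi_trace[1], 0.6)
  p <- decision_values(st, 1L, param_set(alpha_i = 0.2, beta = 1))
  expect_equal(p, c(0.6, 0.4))

  # VS2: Q = (0,0) -> (0.3, -0.3) under alpha_i = 0.3
  st <- init_state(model_spec("VS2"), 1L)
  st <- observe_demonstration(st, 1L, 1L, param_set(alpha_i = 0.3))
  expect_equal(st$Q[1, ], c(0.3, -0.3))

  # metaVS from Q = (0.4, 0.1), demonstration of the higher-valued option:
  # tau = 1, alpha_i(s) 0 -> 0.5, then Q(d) = 0.4 + 0.5*(1-0.4) = 0.7
  st <- init_state(model_spec("metaVS"), 1L)
  st$Q[1, ] <- c(0.4, 0.1)
  st <- observe_demonstration(st, 1L, 1L, param_set(alpha_m = 0.5))
  expect_equal(st$alpha_i_state[1], 0.5)
  expect_equal(st$Q[1, 1], 0.7)
  expect_equal(st$Q[1, 2], 0.1 + 0.5 * (-1 - 0.1))

  # metaVS tie rule: equal values count as agreement (tau = 1)
  st <- init_state(model_spec("metaVS"), 1L)
  st <- observe_demonstration(st, 1L, 2L, param_set(alpha_m = 0.25))
  expect_equal(st$alpha_i_state[1], 0.25)

  # DB6 accumulates: two same-option demonstrations from Q'(d) = 0 at
  # alpha_i = 0.2 give 0.2 then 0.2 + 0.2*0.8 = 0.36
  st <- init_state(model_spec("DB6"), 1L)
  prm <- param_set(alpha_i = 0.2)
  st <- observe_demonstration(st, 1L, 1L, prm)
  st <- observe_demonstration(st, 1L, 1L, prm)
  expect_equal(st$Q_prime[1, 1], 0.36)

  # DB3 re-derives from Q each time: no accumulation
  st <- init_state(model_spec("DB3"), 1L)
  st <- observe_demonstration(st, 1L, 1L, prm)
  one <- st$Q_prime[1, 1]
  st <- observe_demonstration(st, 1L, 1L, prm)
  expect_equal(st$Q_prime[1, 1], one)

  # MB9 with Q_D = (0.8, -0.8): symmetric bias of magnitude 0.4 on fresh Q
  st <- init_state(model_spec("MB9"), 1L)
  st$Q_D[1, ] <- c(0.8, -0.8)
  p <- decision_values(st, 1L, param_set(alpha_i = 0.4, beta = 1))
  # biased values (0.4, -0.4) feed the softmax
  expect_equal(p[1], 1 / (1 + exp(1 * (-0.4 - 0.4))), tolerance = 1e-12)

  # MB demonstrator-model tie: no bias
  st <- init_state(model_spec("MB9"), 1L)
  expect_equal(decision_values(st, 1L, param_set(alpha_i = 0.4, beta = 1)),
               c(0.5, 0.5))
})

test_that("zero imitation collapses every social model onto its RW baseline", {
  cfg <- task_config("exp2")
  sched <- make_schedule(cfg, seed = 21)
  data <- simulate_agent(model_spec("RW2"), param_set(alpha_p = 0.4, beta = 3,
                                                      kappa = 0.3),
                         sched, seed = 22)
  prm <- param_set(alpha_p = 0.4, alpha_i = 0, alpha_m = 0, beta = 3,
                   kappa = 0.3)
  ref <- dataset_nll(model_spec("RW2"), prm, data)
  for (id in c(paste0("DB", 1:6), paste0("MB", 1:9), "VS1", "VS2", "metaVS")) {
    expect_equal(dataset_nll(model_spec(id), prm, data), ref,
                 tolerance = 1e-12, info = id)
  }
})

test_that("compiled engine agrees with the stepwise R operations for all models", {
  cfg <- task_config("exp1")
  sched <- make_schedule(cfg, seed = 31)
  data <- simulate_agent(model_spec("VS2"),
                         param_set(alpha_p = 0.35, alpha_i = 0.2, beta = 4,
                                   kappa = 0.4), sched, seed = 32)
  prm <- param_set(alpha_p = 0.3, alpha_i = 0.25, alpha_d = 0.15,
                   alpha_m = 0.35, beta = 2.5, kappa = -0.3)
  for (id in model_registry()) {
    spec <- model_spec(id)
    expect_equal(dataset_nll(spec, prm, data), stepwise_nll(spec, prm, data),
                 tolerance = 1e-10, info = id)
  }
})

test_that("engine agrees with a from-scratch oracle for the value families", {
  cfg <- task_config("exp2")
  sched <- make_schedule(cfg, seed = 41)
  data <- simulate_agent(model_spec("VS2"),
                         param_set(alpha_p = 0.3, alpha_i = 0.3, beta = 3),
                         sched, seed = 42)
  cases <- list(
    list(id = "RW1", fam = "RW", var = 1L, sym = FALSE),
    list(id = "RW2", fam = "RW", var = 2L, sym = TRUE),
    list(id = "VS1", fam = "VS", var = 1L, sym = TRUE),
    list(id = "VS2", fam = "VS", var = 2L, sym = TRUE),
    list(id = "metaVS", fam = "metaVS", var = 1L, sym = TRUE)
  )
  prm <- param_set(alpha_p = 0.25, alpha_i = 0.2, alpha_m = 0.3, beta = 3,
                   kappa = 0.2)
  for (cs in cases) {
    expect_equal(
      dataset_nll(model_spec(cs$id, symmetric_private = cs$sym), prm, data),
      oracle_nll_valuefam(cs$fam, cs$var, prm, data,
                          symmetric_private = cs$sym),
      tolerance = 1e-10, info = cs$id
    )
  }
})

test_that("values and traces stay bounded in [-1, 1]", {
  types <- withr::with_seed(51, sample(c("observational", "private"), 300,
                                       replace = TRUE))
  demos <- ifelse(types == "observational",
                  withr::with_seed(52, sample(c("A", "B"), 300, replace = TRUE)),
                  NA_character_)
  choices <- ifelse(types == "private",
                    withr::with_seed(53, sample(c("A", "B"), 300, replace = TRUE)),
                    NA_character_)
  outs <- ifelse(types == "private",
                 withr::with_seed(54, sample(c(-1, 1), 300, replace = TRUE)),
                 NA_real_)
  trials <- tiny_trials(types, demos, choices, outs)
  prm <- param_set(alpha_p = 0.9, alpha_i = 0.95, alpha_d = 0.9,
                   alpha_m = 0.9, beta = 5, kappa = 1)
  for (id in c("RW2", "DB6", "MB9", "VS2", "metaVS")) {
    spec <- model_spec(id)
    st <- init_state(spec, 1L)
    for (t in seq_len(nrow(trials))) {
      if (types[t] == "observational") {
        d <- if (demos[t] == "A") 1L else 2L
        st <- observe_demonstration(st, 1L, d, prm)
      } else {
        c_ <- if (choices[t] == "A") 1L else 2L
        st <- private_update(st, 1L, c_, outs[t], prm)
      }
      expect_true(all(abs(st$Q) <= 1 + 1e-12), info = id)
      expect_true(all(abs(st$Q_prime) <= 1 + 1e-12), info = id)
      expect_true(all(abs(st$Q_D) <= 1 + 1e-12), info = id)
      expect_true(st$alpha_i_state[1] >= 0 && st$alpha_i_state[1] <= 1,
                  info = id)
    }
  }
})

test_that("simulation is seed-reproducible and respects model reductions", {
  cfg <- task_config("exp2")
  sched <- make_schedule(cfg, seed = 61)
  a <- simulate_agent(model_spec("VS2"), param_set(alpha_i = 0.3, beta = 3),
                      sched, seed = 62)
  b <- simulate_agent(model_spec("VS2"), param_set(alpha_i = 0.3, beta = 3),
                      sched, seed = 62)
  expect_identical(a, b)
  # VS with alpha_i = 0 and RW produce identical choices under the same seed
  rw <- simulate_agent(model_spec("RW2"), param_set(beta = 3), sched, seed = 63)
  vs0 <- simulate_agent(model_spec("VS2"), param_set(alpha_i = 0, beta = 3),
                        sched, seed = 63)
  expect_identical(rw$choice, vs0$choice)
  # near-greedy agent on deterministic rewards locks onto the winner
  det <- make_schedule(task_config("exp1", p_correct = 1), seed = 64)
  gre <- simulate_agent(model_spec("RW2"), param_set(alpha_p = 0.9, beta = 50),
                        det, seed = 65)
  expect_gt(correct_choice_rate(gre), 0.9)
})

test_that("imitative agents imitate above chance", {
  cfg <- task_config("exp2")
  rates <- vapply(1:20, function(i) {
    sched <- make_schedule(cfg, seed = 70 + i)
    sim <- simulate_agent(model_spec("VS2"),
                          param_set(alpha_p = 0.3, alpha_i = 0.3, beta = 5),
                          sched, seed = 170 + i)
    imitation_rate(sim, 1L, condition = "SD")
  }, numeric(1))
  expect_gt(mean(rates), 0.6)
})
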