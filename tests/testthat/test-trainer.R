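test_that("baseline initialization is the model's own greedy cost", {
  m0 <- policy_model(seed = 1)
  b1 <- initialize_baselines(m0, list(cost_matrix(matrix(3, 1, 1))))
  expect_equal(b1, 3)

  gen <- mwm_instance_generator(6)
  samples <- gen(20, 99)
  b <- initialize_baselines(m0, samples)
  # every baseline is the cost of some valid permutation of its matrix
  for (i in seq_along(samples)) {
    bf <- solve_brute_force(samples[[i]])
    worst <- solve_brute_force(
      cost_matrix(unclass(samples[[i]]), "minimize"))$total_cost
    expect_gte(b[i], worst - 1e-9)
    expect_lte(b[i], bf$total_cost + 1e-9)
  }
  expect_identical(initialize_baselines(m0, samples), b)
  expect_error(initialize_baselines(m0, list()), "empty")
})

test_that("baseline EMA update follows b' = b + alpha (AC - b)", {
  expect_equal(update_baseline(10, 1L, 6, 0.5), 8)
  expect_equal(update_baseline(10, 1L, 6, 1), 6)
  expect_error(update_baseline(c(1, 2), 3L, 5, 0.1), "unknown")
  # geometric convergence at rate (1 - alpha)
  b <- 10
  for (k in 1:12) {
    b_next <- update_baseline(b, 1L, 2, 0.3)
    expect_equal(b_next - 2, (1 - 0.3) * (b - 2), tolerance = 1e-12)
    b <- b_next
  }
})

test_that("zero advantage gives exactly zero gradient", {
  m0 <- policy_model(seed = 2)
  mats <- mwm_instance_generator(5)(8, 7)
  # force baselines equal to whatever the sampled cost will be: run once to
  # capture rewards, then replay the same seed with those as baselines
  probe <- reinforce_gradient(m0, mats, rep(0, 8), "maximize", seed = 55)
  est <- reinforce_gradient(m0, mats, probe$rewards, "maximize", seed = 55)
  expect_identical(est$rewards, probe$rewards)
  expect_equal(max(abs(unlist(est$grads))), 0)
})

test_that("analytic REINFORCE gradient matches finite differences", {
  set.seed(64)
  worst <- 0
  for (rep in 1:6) {
    n <- sample(3:5, 1)
    Cn <- normalize_cost(rand_cost(n, sense = "maximize"))
    perm <- sample(n)
    mp <- perturbed_model(seed = rep + 40, scale = 0.05)
    g <- analytic_logp_grads(mp, Cn, perm)
    checks <- list(
      list(get = function(m) m$params$W1,
           set = function(m, v) { m$params$W1[] <- v; m }, g = g$W1),
      list(get = function(m) m$params$Wmid[[2]],
           set = function(m, v) { m$params$Wmid[[2]][] <- v; m },
           g = g$Wmid[[2]]),
      list(get = function(m) m$params$Wlast,
           set = function(m, v) { m$params$Wlast[] <- v; m }, g = g$Wlast))
    for (ch in checks) {
      for (idx in sample(length(ch$get(mp)), 3)) {
        fd <- fd_logp_grad(mp, Cn, perm, ch$get, ch$set, idx)
        ga <- as.numeric(ch$g)[idx]
        rel <- abs(fd - ga) / max(abs(fd), abs(ga), 1e-6)
        worst <- max(worst, rel)
      }
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("training is reproducible and T = 0 is a no-op", {
  gen <- mwm_instance_generator(5)
  cfg0 <- training_config(n_samples = 16, batch_size = 8, n_steps = 0,
                          seed = 3)
  fit0 <- train_policy(cfg0, gen)
  fresh <- policy_model(seed = derive_seed(3L, "init"))
  expect_equal(fit0$model$params, fresh$params)
  expect_equal(nrow(fit0$log), 0L)

  cfg <- training_config(n_samples = 64, batch_size = 16, n_steps = 25,
                         temperature = 0.2, seed = 3)
  fitA <- train_policy(cfg, gen)
  fitB <- train_policy(cfg, gen)
  expect_identical(fitA$log$mean_reward, fitB$log$mean_reward)
  expect_equal(fitA$model$params, fitB$model$params, tolerance = 1e-15)
  # stochastic policy: two different sampling seeds give different draws
  mats <- gen(8, 12)
  b <- initialize_baselines(fitA$model, mats)
  e1 <- reinforce_gradient(fitA$model, mats, b, "maximize", seed = 1)
  e2 <- reinforce_gradient(fitA$model, mats, b, "maximize", seed = 2)
  expect_false(identical(e1$permutations, e2$permutations))
})

test_that("learning rate decays by the configured factor every period", {
  cfg <- training_config(n_samples = 64, batch_size = 16, seed = 1)
  expect_equal(learning_rate_at(cfg, 1), 1e-3)
  expect_equal(learning_rate_at(cfg, 4999), 1e-3)
  expect_equal(learning_rate_at(cfg, 5000), 1e-3 * 0.96)
  expect_equal(learning_rate_at(cfg, 10000), 1e-3 * 0.96^2)
})

test_that("baselines stay within achievable cost bounds during training", {
  gen <- mwm_instance_generator(4)
  cfg <- training_config(n_samples = 40, batch_size = 8, n_steps = 60,
                         temperature = 0.3, seed = 5)
  fit <- train_policy(cfg, gen)
  samples <- gen(40, derive_seed(5L, "instances"))
  for (i in seq_along(samples)) {
    best <- solve_brute_force(samples[[i]])$total_cost
    worst <- solve_brute_force(
      cost_matrix(unclass(samples[[i]]), "minimize"))$total_cost
    expect_lte(fit$baselines[i], best + 1e-9)
    expect_gte(fit$baselines[i], worst - 1e-9)
  }
})

test_that("REINFORCE improves the policy on fixed small MWM instances", {
  cfg <- training_config(n_samples = 500, batch_size = 32, n_steps = 900,
                         temperature = 0.1, seed = 17,
                         objective_sense = "maximize")
  gen <- mwm_instance_generator(5)
  test_set <- gen(200, 4321)
  before <- evaluate_solver(policy_model(seed = derive_seed(17L, "init")),
                            test_set)
  fit <- train_policy(cfg, gen)
  after <- evaluate_solver(fit$model, test_set)
  expect_gt(after$mean_ratio, before$mean_ratio)
  # reward trend: mean sampled reward over the last 10% of steps beats the
  # first 10% (maximization)
  T_ <- nrow(fit$log)
  k <- max(1, floor(T_ / 10))
  expect_gt(mean(fit$log$mean_reward[(T_ - k + 1):T_]),
            mean(fit$log$mean_reward[1:k]))
})
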