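test_that("forward pass: identity start, bounded range, size-agnostic", {
  m0 <- policy_model(seed = 1)   # zero-initialized residual head
  C <- matrix(runif(81), 9, 9)
  expect_equal(policy_forward(m0, C), tanh(C), tolerance = 1e-12)
  expect_equal(policy_forward(m0, matrix(0, 4, 4)), matrix(0, 4, 4))

  mp <- perturbed_model(seed = 9)
  for (N in c(1, 15, 25)) {
    Y <- policy_forward(mp, matrix(runif(N * N), N, N))
    expect_equal(dim(Y), c(N, N))
    expect_true(all(abs(Y) <= 1))
  }
  expect_error(policy_forward(mp, matrix(1, 2, 3)), "square")
})

test_that("compiled forward matches the pure-R reference network", {
  mp <- perturbed_model(seed = 11)
  set.seed(5)
  for (N in c(3, 7, 12)) {
    C <- matrix(runif(N * N), N, N)
    expect_equal(policy_forward(mp, C, training = FALSE),
                 ref_forward(mp, C, training = FALSE), tolerance = 1e-12)
    expect_equal(policy_forward(mp, C, training = TRUE),
                 ref_forward(mp, C, training = TRUE), tolerance = 1e-12)
  }
})

test_that("batch_normalize implements the centering/scaling transform", {
  expect_equal(batch_normalize(c(1, 3), list(mean = 2, var = 1), eps = 0),
               c(-1, 1))
  # constant input with running stats centered on it -> ~0
  expect_equal(batch_normalize(rep(2, 5), list(mean = 2, var = 1e-12)),
               rep(0, 5))
  # training mode: output has mean ~0 and population variance ~1
  set.seed(8)
  t <- rnorm(500, mean = 3, sd = 2)
  out <- batch_normalize(t)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(mean((out - mean(out))^2), 1, tolerance = 1e-4)
})

test_that("greedy decode follows the mask and forced choices", {
  d <- decode_assignment(matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2), "greedy")
  expect_equal(d$permutation, c(1L, 2L))   # row 2's best column is claimed
  expect_lte(d$log_probability, 0)

  d1 <- decode_assignment(matrix(0.3, 1, 1), "greedy")
  expect_equal(d1$permutation, 1L)
  expect_equal(d1$log_probability, 0)

  # diagonal-dominant attractiveness scores -> identity permutation
  set.seed(2)
  S <- matrix(runif(36, 0, 0.3), 6, 6)
  diag(S) <- 0.9
  expect_equal(decode_assignment(S, "greedy")$permutation, 1:6)
})

test_that("decode always returns a bijection (R and compiled paths)", {
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(1:30, 1)
    S <- matrix(rnorm(n * n), n, n)
    mode <- sample(c("greedy", "sample"), 1)
    d <- decode_assignment(S, mode, temperature = runif(1, 0.05, 2))
    expect_identical(sort(d$permutation), seq_len(n))
  }
  for (rep in 1:50) {
    n <- sample(1:20, 1)
    S <- matrix(rnorm(n * n), n * n, 1)
    dec <- lapnet:::.decode_batch_cpp(S, n, 1L, 1.0, FALSE)
    expect_identical(sort(dec$permutations[, 1]), seq_len(n))
  }
})

test_that("sampled permutation frequencies match the analytic distribution", {
  set.seed(31)
  S <- matrix(rnorm(9), 3, 3)
  P <- lapnet:::all_permutations(3)
  probs <- apply(P, 1, function(p) exp(log_prob_of(S, p)))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  ndraw <- 4000
  keys <- apply(P, 1, paste, collapse = "")
  counts <- setNames(numeric(6), keys)
  for (i in seq_len(ndraw)) {
    d <- decode_assignment(S, "sample")
    k <- paste(d$permutation, collapse = "")
    counts[k] <- counts[k] + 1
  }
  freq <- counts / ndraw
  se <- sqrt(probs * (1 - probs) / ndraw)
  expect_true(all(abs(freq - probs) <= 3.5 * se + 1e-9))
})

test_that("log_prob_of matches the decoder and normalizes over permutations", {
  # uniform scores: log(1/3) + log(1/2) + log(1) for any permutation
  U <- matrix(0.5, 3, 3)
  expect_equal(log_prob_of(U, c(2L, 3L, 1L)), log(1 / 3) + log(1 / 2))

  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    S <- matrix(rnorm(n * n), n, n)
    d <- decode_assignment(S, "sample", temperature = 0.7)
    expect_equal(log_prob_of(S, d$permutation, temperature = 0.7),
                 d$log_probability, tolerance = 1e-12)
  }

  # sequential masked softmax is a proper distribution over permutations
  for (n in 3:5) {
    S <- matrix(rnorm(n * n), n, n)
    P <- lapnet:::all_permutations(n)
    tot <- sum(apply(P, 1, function(p) exp(log_prob_of(S, p))))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  expect_error(log_prob_of(matrix(1, 2, 2), c(1L, 1L)), "permutation")
})

test_that("sense-oriented normalization bounds inputs and orients greedy", {
  cmax <- rand_cost(5, seed = 3, sense = "maximize")
  nx <- normalize_cost(cmax)
  expect_true(all(nx >= 0 & nx <= 1))
  expect_equal(max(nx), 1)
  cmin <- rand_cost(5, seed = 3, sense = "minimize")
  expect_equal(normalize_cost(cmin), 1 - nx, tolerance = 1e-12)
  # untrained greedy decode of a minimize matrix picks the row minimum first
  m0 <- policy_model(seed = 1)
  a <- unclass(cmin)
  Y <- policy_forward(m0, normalize_cost(cmin))
  expect_equal(decode_assignment(Y, "greedy")$permutation[1],
               which.min(a[1, ]))
})

test_that("checkpoints round-trip through JSON", {
  mp <- perturbed_model(seed = 77)
  mp$training_steps <- 123L
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(mp, path)
  back <- load_checkpoint(path)
  C <- matrix(runif(64), 8, 8)
  expect_equal(policy_forward(back, C), policy_forward(mp, C),
               tolerance = 1e-12)
  expect_identical(back$training_steps, 123L)
  expect_identical(back$n_blocks, mp$n_blocks)
})
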