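test_that("augmented matrix has the documented block layout", {
  # degenerate: no predictions, one measurement -> pure Gamma diagonal
  D0 <- build_augmented_matrix(NULL, rbind(c(0, 0)), threshold = 1)
  expect_equal(unclass(D0)[1, 1], 1.0)
  expect_equal(dim(D0), c(1L, 1L))

  P <- rbind(c(0, 0), c(1, 0))
  Z <- rbind(c(0, 0.1), c(1, 0.1), c(5, 5))
  tau <- 1
  D <- build_augmented_matrix(P, Z, tau)
  expect_equal(dim(D), c(5L, 5L))
  big <- attr(D, "big_value")
  # Lambda distances, hand-computed
  expect_equal(D[1, 1:3], c(0.1, sqrt(1 + 0.01), sqrt(50)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # Upsilon: tau on the diagonal, big elsewhere (rows 1..M, cols N+1..N+M)
  expect_equal(D[1, 4], tau, ignore_attr = TRUE)
  expect_equal(D[2, 5], tau, ignore_attr = TRUE)
  expect_equal(D[1, 5], big, ignore_attr = TRUE)
  expect_equal(D[2, 4], big, ignore_attr = TRUE)
  # Gamma: tau on the diagonal of rows M+1..M+N x cols 1..N
  expect_equal(diag(unclass(D)[3:5, 1:3]), rep(tau, 3))
  expect_equal(D[4, 1], big, ignore_attr = TRUE)
  # bottom-right block is Lambda transpose
  expect_equal(unclass(D)[3:5, 4:5], t(unclass(D)[1:2, 1:3]))
  expect_true(big > max(unclass(D)[1:2, 1:3]) && big > tau)

  expect_error(build_augmented_matrix(NULL, NULL, 1), "empty")
  expect_error(build_augmented_matrix(rbind(c(NA, 0)), Z, 1), "finite")
  expect_error(build_augmented_matrix(P, Z, -1), "positive")
  expect_error(augment_blocks(matrix(1, 1, 1), 1, big_value = 0.5), "exceed")
})

test_that("solve_exact matches hand-checked examples with lexicographic ties", {
  a <- solve_exact(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(a$permutation, c(1L, 2L))
  expect_equal(a$total_cost, 0)

  b <- solve_exact(matrix(c(4, 2, 3, 1, 0, 2, 3, 5, 2), 3, 3))
  expect_equal(b$total_cost, 5)
  expect_equal(b$permutation, c(2L, 1L, 3L))

  expect_equal(solve_exact(matrix(7, 1, 1))$total_cost, 7)
  expect_equal(solve_exact(matrix(7, 1, 1))$permutation, 1L)

  # all-tie matrix: lexicographically smallest permutation
  expect_equal(solve_exact(matrix(1, 4, 4))$permutation, 1:4)

  expect_error(solve_exact(matrix(1, 2, 3)), "square")
  expect_error(solve_brute_force(rand_cost(10, 1)), "n > 9")
})

test_that("exact solver agrees with brute force (both senses)", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:7, 1)
    m <- matrix(runif(n * n), n, n)
    for (sense in c("minimize", "maximize")) {
      cm <- cost_matrix(m, sense)
      e <- solve_exact(cm)
      b <- solve_brute_force(cm)
      expect_equal(e$total_cost, b$total_cost, tolerance = 1e-10)
      expect_equal(e$permutation, b$permutation)
    }
  }
})

test_that("assignment_cost computes the selected-entry sum and validates", {
  m <- matrix(c(4, 2, 1, 0), 2, 2)
  expect_equal(assignment_cost(m, c(1L, 2L)), 4)
  expect_equal(assignment_cost(m, c(2L, 1L)), 3)
  expect_error(assignment_cost(m, c(1L, 1L)), "permutation")
  expect_error(assignment_cost(m, 1L), "permutation")
  # zero diagonal -> identity cost zero
  z <- matrix(runif(16), 4, 4)
  diag(z) <- 0
  expect_equal(assignment_cost(z, 1:4), 0)
  # optimal cost dominates random permutations
  set.seed(7)
  cm <- rand_cost(6)
  opt <- solve_exact(cm)$total_cost
  for (i in 1:50) {
    expect_gte(assignment_cost(cm, sample(6)), opt - 1e-12)
  }
})

test_that("classify_outcome labels matched / lost / new and partitions", {
  near <- build_augmented_matrix(rbind(c(0, 0)), rbind(c(0, 0.1)), 1)
  out <- classify_outcome(near, solve_exact(near))
  expect_equal(nrow(out$matched_pairs), 1L)
  expect_equal(out$matched_pairs[1, ], c(prediction = 1L, measurement = 1L))
  expect_length(out$lost_predictions, 0)
  expect_length(out$new_measurements, 0)
  expect_false(out$infeasible)

  # distance 5 > 2 * tau: cheaper to declare lost + new (brute-force checked)
  far <- build_augmented_matrix(rbind(c(0, 0)), rbind(c(5, 0)), 1)
  bf <- solve_brute_force(far)
  expect_equal(bf$total_cost, 2)
  out2 <- classify_outcome(far, bf)
  expect_equal(out2$lost_predictions, 1L)
  expect_equal(out2$new_measurements, 1L)
  expect_equal(nrow(out2$matched_pairs), 0L)

  # no predictions: every measurement is new
  none <- build_augmented_matrix(NULL, rbind(c(0, 0), c(1, 1)), 1)
  out3 <- classify_outcome(none, solve_exact(none))
  expect_equal(out3$new_measurements, c(1L, 2L))
})

test_that("optimal augmented assignments partition and avoid big cells", {
  set.seed(33)
  for (rep in 1:40) {
    m <- sample(0:4, 1)
    n <- sample(0:4, 1)
    if (m + n == 0) n <- 1
    D <- generate_association_instance(m, n, threshold = 0.4,
                                       seed = sample.int(1e6, 1))
    asg <- solve_exact(D)
    out <- classify_outcome(D, asg)
    expect_false(out$infeasible)
    # three groups partition predictions and measurements
    preds <- sort(unname(c(out$matched_pairs[, "prediction"],
                           out$lost_predictions)))
    meas <- sort(unname(c(out$matched_pairs[, "measurement"],
                          out$new_measurements)))
    expect_equal(preds, seq_len(m))
    expect_equal(meas, seq_len(n))
    expect_lte(anyDuplicated(out$matched_pairs[, "measurement"]), 0)
  }
})

test_that("cost matrices round-trip through delimited text", {
  cm <- rand_cost(8, seed = 4, sense = "maximize")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cost_matrix(cm, path)
  back <- read_cost_matrix(path, sense = "maximize")
  expect_equal(unclass(back), unclass(cm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(back, "sense"), "maximize")
})
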