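test_that("kalman_predict applies the linear dynamics", {
  km <- kalman_model(diag(4), matrix(0, 4, 4),
                     cbind(diag(2), matrix(0, 2, 2)), diag(2) * 0.1)
  st <- track_state(c(1, 2, 3, 4), diag(4))
  pred <- kalman_predict(km, st)
  expect_equal(pred$mean, c(1, 2, 3, 4))
  expect_equal(pred$cov, diag(4))

  cv <- kalman_cv_model(dt = 1, sigma_a = 0, R = 0.01)
  pred2 <- kalman_predict(cv, track_state(c(0, 0, 1, 0), diag(4) * 0.1))
  expect_equal(pred2$mean, c(1, 0, 1, 0))

  # prediction adds exactly Q, and (det A = 1, Q PSD) never shrinks the
  # covariance volume
  set.seed(9)
  cv2 <- kalman_cv_model(sigma_a = 0.3)
  for (i in 1:20) {
    M <- matrix(rnorm(16), 4, 4)
    P <- M %*% t(M) + diag(4) * 1e-6
    st <- track_state(rnorm(4), P)
    pc <- kalman_predict(cv2, st)$cov
    expect_equal(pc - cv2$A %*% P %*% t(cv2$A), cv2$Q, tolerance = 1e-9)
    expect_gte(det(pc), det(P) * (1 - 1e-9))
  }
  expect_error(kalman_predict(cv, track_state(c(1, 2), diag(2))), "dimension")
})

test_that("kalman_update limits: exact measurement and uninformative one", {
  st <- track_state(c(0, 0, 0.5, 0), diag(c(1, 1, 1, 1)))
  sharp <- kalman_cv_model(R = 1e-14)
  post <- kalman_update(sharp, st, c(2, 3))
  expect_equal(post$mean[1:2], c(2, 3), tolerance = 1e-5)

  vague <- kalman_cv_model(R = 1e12)
  post2 <- kalman_update(vague, st, c(2, 3))
  expect_equal(post2$mean, st$mean, tolerance = 1e-6)
  expect_equal(post2$cov, st$cov, tolerance = 1e-6)
})

test_that("filter converges on a noiseless constant-velocity target", {
  km <- kalman_cv_model(sigma_a = 0.01, R = 1e-10)
  st <- track_state(c(0, 0, 0, 0), diag(c(1, 1, 1, 1)))
  truth_pos <- function(t) c(0.5 * t, -0.2 * t)
  for (t in 1:50) {
    st <- kalman_predict(km, st)
    st <- kalman_update(km, st, truth_pos(t))
  }
  expect_lt(sqrt(sum((st$mean[1:2] - truth_pos(50))^2)), 1e-6)
  expect_lt(sqrt(sum((st$mean[3:4] - c(0.5, -0.2))^2)), 1e-5)
})

test_that("associate_frame resolves sub-threshold matches and far events", {
  km <- kalman_cv_model(R = 0.01)
  st <- track_state(c(0, 0, 0, 0), diag(c(0.01, 0.01, 0.1, 0.1)))
  near <- associate_frame(list(st), data.frame(x = 0, y = 0.1), km,
                          threshold = 1, distance = "euclidean")
  expect_equal(nrow(near$outcome$matched_pairs), 1L)

  far <- associate_frame(list(st), data.frame(x = 9, y = 9), km,
                         threshold = 1, distance = "euclidean")
  expect_equal(far$outcome$lost_predictions, 1L)
  expect_equal(far$outcome$new_measurements, 1L)

  none <- associate_frame(list(), data.frame(x = numeric(0), y = numeric(0)),
                          km, threshold = 1)
  expect_equal(none$cost, 0)
  expect_equal(nrow(none$outcome$matched_pairs), 0L)
})

test_that("exact association cost never exceeds the policy's on a frame", {
  km <- kalman_cv_model(R = 0.01)
  pol <- policy_model(seed = 4)
  set.seed(18)
  for (rep in 1:10) {
    states <- lapply(1:4, function(i) {
      track_state(c(runif(2, 0, 5), rnorm(2, 0, 0.2)),
                  diag(c(0.01, 0.01, 0.1, 0.1)))
    })
    dets <- data.frame(x = runif(4, 0, 5), y = runif(4, 0, 5))
    exa <- associate_frame(states, dets, km, 3, solver = "exact",
                           distance = "mahalanobis")
    pola <- associate_frame(states, dets, km, 3, solver = "policy",
                            distance = "mahalanobis", policy = pol)
    expect_lte(exa$cost, pola$cost + 1e-9)
  }
})

test_that("track_sequence follows clean targets without switches", {
  # single target, straight line, no noise
  det1 <- data.frame(frame = 1:10, x = 0.5 * (0:9), y = rep(2, 10))
  km <- kalman_cv_model(sigma_a = 0.05, R = 1e-6)
  tracks <- track_sequence(det1, km, threshold = 1)
  expect_length(tracks, 1L)
  expect_equal(nrow(tracks[[1]]$history), 10L)
  expect_true(all(tracks[[1]]$history$status[-1] == "tracked"))

  # two parallel well-separated targets: each track follows its own truth
  frames <- 1:12
  det2 <- rbind(
    data.frame(frame = frames, x = 0.4 * (frames - 1), y = 0),
    data.frame(frame = frames, x = 0.4 * (frames - 1), y = 10))
  det2 <- det2[order(det2$frame), ]
  tracks2 <- track_sequence(det2, km, threshold = 1)
  expect_length(tracks2, 2L)
  for (tr in tracks2) {
    ys <- tr$history$y
    expect_lt(diff(range(ys)), 1e-3)   # stays on one lane
  }
  df <- tracks_to_df(tracks2)
  expect_equal(count_id_switches(
    data.frame(id = rep(1:2, each = 12), frame = rep(frames, 2),
               x = rep(0.4 * (frames - 1), 2),
               y = rep(c(0, 10), each = 12)), df, match_radius = 1), 0L)

  expect_length(track_sequence(det1[0, ], km, threshold = 1), 0L)
})

test_that("one-to-one association and unique ids on random scenarios", {
  seen_ids <- integer(0)
  for (rep in 1:40) {
    sc <- generate_crossing_scenario(n_targets = 3, n_frames = 10,
                                     R = 0.02, seed = 9000 + rep,
                                     radius = 5)
    km <- kalman_cv_model(R = 0.02)
    violations <- 0L
    hook <- function(frame, preds, dets) {
      out <- associate_frame(preds, dets, km, 3,
                             distance = "mahalanobis")$outcome
      mp <- out$matched_pairs
      if (anyDuplicated(mp[, "prediction"]) ||
          anyDuplicated(mp[, "measurement"])) {
        violations <<- violations + 1L
      }
    }
    tracks <- track_sequence(sc$measurements, km, 3,
                             distance = "mahalanobis", frame_hook = hook)
    expect_identical(violations, 0L)
    ids <- vapply(tracks, `[[`, integer(1), "id")
    expect_false(anyDuplicated(ids) > 0)
    # a detection never lands in two tracks within one frame
    df <- tracks_to_df(tracks)
    tracked <- df[df$status %in% c("tracked", "new"), ]
    key <- paste(tracked$frame, round(tracked$x, 9), round(tracked$y, 9))
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("crossing scenario keeps identities with the exact solver", {
  # qualitative stress test at low noise: most runs have no identity switch
  zero_sw <- 0L
  n_runs <- 15L
  for (run in seq_len(n_runs)) {
    sc <- generate_crossing_scenario(R = 0.01, seed = 6100 + run)
    km <- kalman_cv_model(R = 0.01)
    tracks <- track_sequence(sc$measurements, km, 3,
                             distance = "mahalanobis")
    sw <- count_id_switches(sc$truth, tracks_to_df(tracks))
    if (sw == 0L) zero_sw <- zero_sw + 1L
  }
  expect_gt(zero_sw, n_runs / 2)
})
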