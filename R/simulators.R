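#' Generate a maximum-weight-matching instance
#'
#' Samples `2n` points uniformly on the unit square — `n` left vertices and
#' `n` right vertices of a complete bipartite graph — and sets the weight of
#' edge `(i, j)` to the Euclidean distance between left point `i` and right
#' point `j`.  The weight matrix therefore lies in `[0, sqrt(2)]`.
#'
#' @param n number of vertices per side (>= 1).
#' @param seed integer seed; the instance is a pure function of `(n, seed)`.
#' @return list of class `mwm_instance`: `left`, `right` (n x 2 point
#'   matrices), `weights` (a maximize-sense [cost_matrix()]), `n`, `seed`.
#' @export
generate_mwm <- function(n, seed) {
  if (!is.numeric(n) || n < 1L) {
    stop("generate_mwm: n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  restore_rng_on_exit()
  set.seed(seed)
  left <- base::matrix(stats::runif(2L * n), n, 2L)
  right <- base::matrix(stats::runif(2L * n), n, 2L)
  structure(list(left = left, right = right,
                 weights = cost_matrix(euclidean_cross_distances(left, right),
                                       sense = "maximize"),
                 n = n, seed = as.integer(seed)),
            class = "mwm_instance")
}

#' Generate a synthetic two-frame association instance
#'
#' Samples `m` "prediction" points and `n` "measurement" points uniformly on
#' the unit square (emulating detections in consecutive frames) and builds
#' the event-aware augmented cost matrix via [build_augmented_matrix()].
#'
#' @param m number of predictions; @param n number of measurements
#'   (`m + n >= 1`).
#' @param threshold gating threshold `tau` for the dummy diagonals.
#' @param seed integer seed.
#' @param big_value optional surrogate for infinity (see
#'   [build_augmented_matrix()]).
#' @return an `augmented_cost_matrix` with the sampled points attached as
#'   attributes `pred_points` and `meas_points`.
#' @export
generate_association_instance <- function(m, n, threshold, seed,
                                          big_value = NULL) {
  m <- as.integer(m); n <- as.integer(n)
  if (m + n < 1L) stop("generate_association_instance: m + n must be >= 1",
                       call. = FALSE)
  restore_rng_on_exit()
  set.seed(seed)
  P <- base::matrix(stats::runif(2L * m), m, 2L)
  Z <- base::matrix(stats::runif(2L * n), n, 2L)
  D <- build_augmented_matrix(P, Z, threshold, big_value)
  attr(D, "pred_points") <- P
  attr(D, "meas_points") <- Z
  attr(D, "seed") <- as.integer(seed)
  D
}

#' Generate the multi-target crossing scenario
#'
#' Places `n_targets` targets at equal angles on a circle of radius `radius`,
#' each moving with constant velocity toward (and past) a target-specific
#' crossing point drawn inside a small disc of radius
#' `crossing_jitter * radius` around the origin, reached at the mid-frame.
#' All trajectories therefore converge near the center around the middle of
#' the sequence — the classic identity-ambiguity stress test — without the
#' degenerate single point where every target coincides exactly.
#' Measurements are the true positions plus zero-mean Gaussian noise with
#' covariance `R`, one measurement per target per frame (no clutter, no
#' missed detections), shuffled within each frame so measurement order
#' carries no identity information.
#'
#' @param n_targets number of targets (>= 2, default 5).
#' @param n_frames number of frames (>= 4, default 40).
#' @param R 2x2 measurement noise covariance, or a scalar `r` meaning
#'   `r * I`.  `R = 0` gives noiseless measurements.
#' @param seed integer seed.
#' @param radius circle radius (scene units, default 10; chosen so that
#'   per-frame motion exceeds the measurement noise at every noise level the
#'   experiments use, the regime the published metric magnitudes imply).
#' @param crossing_jitter dispersion of the per-target crossing points as a
#'   fraction of `radius` (default 0.3): targets cross pairwise in a common
#'   central region rather than through one degenerate coincident point.
#' @return list of class `tracking_scenario`: `truth` (data frame
#'   `target_id, frame, x, y`), `measurements` (data frame `frame, x, y`,
#'   unlabeled), `velocities` (n_targets x 2), `R`, `n_targets`, `n_frames`,
#'   `seed`.
#' @export
generate_crossing_scenario <- function(n_targets = 5L, n_frames = 40L,
                                       R = 0.01, seed = 1L, radius = 10,
                                       crossing_jitter = 0.3) {
  stopifnot(n_targets >= 2L, n_frames >= 4L)
  R <- as_noise_cov(R)
  restore_rng_on_exit()
  set.seed(seed)
  K <- as.integer(n_targets)
  T_ <- as.integer(n_frames)
  ang <- 2 * pi * (seq_len(K) - 1L) / K
  start <- radius * cbind(cos(ang), sin(ang))
  # per-target crossing point in a small disc around the origin
  rho <- crossing_jitter * radius * sqrt(stats::runif(K))
  phi <- 2 * pi * stats::runif(K)
  cross_pt <- cbind(rho * cos(phi), rho * sin(phi))
  t_mid <- (T_ - 1) / 2
  vel <- (cross_pt - start) / t_mid

  frames <- seq_len(T_)
  truth <- do.call(rbind, lapply(seq_len(K), function(k) {
    t0 <- frames - 1L
    data.frame(target_id = k, frame = frames,
               x = start[k, 1] + vel[k, 1] * t0,
               y = start[k, 2] + vel[k, 2] * t0)
  }))

  L <- if (all(R == 0)) base::matrix(0, 2, 2) else chol(R)
  meas <- do.call(rbind, lapply(frames, function(f) {
    tf <- truth[truth$frame == f, ]
    noise <- base::matrix(stats::rnorm(2L * K), K, 2L) %*% L
    ord <- sample.int(K)
    data.frame(frame = f,
               x = (tf$x + noise[, 1])[ord],
               y = (tf$y + noise[, 2])[ord])
  }))
  rownames(truth) <- rownames(meas) <- NULL
  structure(list(truth = truth, measurements = meas, velocities = vel,
                 start = start, R = R, n_targets = K, n_frames = T_,
                 seed = as.integer(seed)),
            class = "tracking_scenario")
}

as_noise_cov <- function(R) {
  if (is.numeric(R) && length(R) == 1L) R <- diag(2) * R
  R <- as.matrix(R)
  if (!identical(dim(R), c(2L, 2L)) || !all(is.finite(R)) ||
      !isTRUE(all.equal(R, t(R))) || any(eigen(R, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-12)) {
    stop("invalid measurement noise covariance R", call. = FALSE)
  }
  R
}

#' Instance generators for [train_policy()]
#'
#' Closures with the `function(n, seed)` signature expected by
#' [train_policy()].  `mwm_instance_generator(size)` yields maximize-sense
#' unit-square MWM weight matrices; `association_instance_generator(m, n,
#' threshold)` yields minimize-sense augmented association matrices.
#'
#' @param size matrix size for MWM instances.
#' @return a `function(n, seed)` returning a list of [cost_matrix()] objects.
#' @export
mwm_instance_generator <- function(size) {
  force(size)
  function(n, seed) {
    lapply(seq_len(n), function(i) {
      generate_mwm(size, derive_seed(seed, paste0("mwm", i)))$weights
    })
  }
}

#' @param m,n predictions / measurements per association instance.
#' @param threshold gating threshold `tau`.
#' @rdname mwm_instance_generator
#' @export
association_instance_generator <- function(m, n, threshold) {
  force(m); force(n); force(threshold)
  function(k, seed) {
    lapply(seq_len(k), function(i) {
      generate_association_instance(m, n, threshold,
                                    derive_seed(seed, paste0("assoc", i)))
    })
  }
}

#' @details `paired_association_generator` emulates what frame-to-frame
#' association matrices actually look like during tracking: `n_targets`
#' predicted positions scattered over a `scene_size`-wide scene, and one
#' measurement per prediction displaced by Gaussian jitter of standard
#' deviation `jitter_sd` (so with the conventional gate
#' `threshold = 3 * jitter_sd`, almost every target is matchable).  Distances
#' are in the same units as `jitter_sd`; using sigma units
#' (`jitter_sd = 1, threshold = 3`) reproduces the Mahalanobis-cost matrices
#' the Kalman tracker feeds the policy.
#'
#' @param n_targets targets per paired instance.
#' @param scene_size side length of the square scene.
#' @param jitter_sd prediction-to-measurement displacement sd.
#' @rdname mwm_instance_generator
#' @export
paired_association_generator <- function(n_targets = 5L, threshold = 3,
                                         scene_size = 100, jitter_sd = 1) {
  force(n_targets); force(threshold); force(scene_size); force(jitter_sd)
  function(k, seed) {
    lapply(seq_len(k), function(i) {
      s <- derive_seed(seed, paste0("paired", i))
      restore_rng_on_exit()
      set.seed(s)
      P <- base::matrix(stats::runif(2L * n_targets, 0, scene_size),
                        n_targets, 2L)
      Z <- P + base::matrix(stats::rnorm(2L * n_targets, sd = jitter_sd),
                            n_targets, 2L)
      lambda <- euclidean_cross_distances(
        P, Z[sample.int(n_targets), , drop = FALSE])
      D <- augment_blocks(lambda, threshold, cap = TRUE)
      attr(D, "seed") <- s
      D
    })
  }
}

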