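#' Linear-Gaussian motion model
#'
#' Container for the discrete-time Markov model `x_t = A x_{t-1} + w`,
#' `w ~ N(0, Q)` with linear measurements `z_t = H x_t + v`, `v ~ N(0, R)`.
#'
#' @param A state transition matrix.
#' @param Q process noise covariance (symmetric PSD).
#' @param H observation matrix.
#' @param R measurement noise covariance (symmetric PSD).
#' @return list of class `kalman_model`.
#' @seealso [kalman_cv_model()] for the standard constant-velocity model.
#' @export
kalman_model <- function(A, Q, H, R) {
  A <- as.matrix(A); Q <- as.matrix(Q); H <- as.matrix(H); R <- as.matrix(R)
  d <- nrow(A)
  stopifnot(ncol(A) == d, identical(dim(Q), dim(A)), ncol(H) == d,
            nrow(R) == nrow(H), ncol(R) == nrow(H))
  check_psd(Q, "Q"); check_psd(R, "R")
  structure(list(A = A, Q = Q, H = H, R = R, state_dim = d,
                 meas_dim = nrow(H)),
            class = "kalman_model")
}

check_psd <- function(M, what) {
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)) ||
      any(eigen((M + t(M)) / 2, symmetric = TRUE,
                only.values = TRUE)$values < -1e-10)) {
    stop(sprintf("kalman_model: %s must be symmetric PSD", what),
         call. = FALSE)
  }
}

#' Constant-velocity Kalman model in the plane
#'
#' State `[x, y, xdot, ydot]` with transition
#' `A = [[1,0,dt,0],[0,1,0,dt],[0,0,1,0],[0,0,0,1]]`, white-acceleration
#' process noise of intensity `sigma_a` (scene units / frame^2), observation
#' `H = [I2 | 0]`, and measurement noise covariance `R`.
#'
#' @param dt frame interval (default 1).
#' @param sigma_a white-acceleration standard deviation (default 0.1).
#' @param R 2x2 measurement covariance or scalar `r` for `r * I`.
#' @return a [kalman_model()].
#' @export
kalman_cv_model <- function(dt = 1, sigma_a = 0.1, R = 0.01) {
  A <- rbind(c(1, 0, dt, 0),
             c(0, 1, 0, dt),
             c(0, 0, 1, 0),
             c(0, 0, 0, 1))
  q2 <- dt^2 / 2
  G <- rbind(c(q2, 0), c(0, q2), c(dt, 0), c(0, dt))  # acceleration loading
  Q <- sigma_a^2 * G %*% t(G)
  H <- cbind(diag(2), base::matrix(0, 2, 2))
  kalman_model(A, Q, H, as_noise_cov(R))
}

#' Track state (mean and covariance)
#'
#' @param mean numeric state mean vector.
#' @param cov covariance matrix (symmetric PSD).
#' @return list of class `track_state`.
#' @export
track_state <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(length(mean) == nrow(cov), nrow(cov) == ncol(cov))
  check_psd(cov, "cov")
  structure(list(mean = mean, cov = cov), class = "track_state")
}

#' Kalman prediction step
#'
#' `mean <- A mean`, `cov <- A cov A' + Q`.
#'
#' @param model a [kalman_model()].
#' @param state a [track_state()].
#' @return the predicted [track_state()].
#' @export
kalman_predict <- function(model, state) {
  if (length(state$mean) != model$state_dim) {
    stop("kalman_predict: state dimension mismatch", call. = FALSE)
  }
  track_state(model$A %*% state$mean,
              model$A %*% state$cov %*% t(model$A) + model$Q)
}

#' Kalman measurement update
#'
#' Standard innovation update with the Joseph-form covariance for numerical
#' symmetry: `K = P H' S^-1`, `S = H P H' + R`.
#'
#' @param model a [kalman_model()].
#' @param state the predicted [track_state()].
#' @param measurement numeric measurement vector (length `nrow(H)`), or a
#'   single detection row with `x`, `y` components.
#' @return the posterior [track_state()].
#' @export
kalman_update <- function(model, state, measurement) {
  z <- as_measurement(measurement, model$meas_dim)
  P <- state$cov
  H <- model$H
  S <- H %*% P %*% t(H) + model$R
  Sc <- tryCatch(chol(S), error = function(e) {
    stop(sprintf("kalman_update: singular innovation covariance (det = %g)",
                 det(S)), call. = FALSE)
  })
  K <- P %*% t(H) %*% chol2inv(Sc)
  y <- z - as.numeric(H %*% state$mean)
  mean_post <- state$mean + as.numeric(K %*% y)
  IKH <- diag(model$state_dim) - K %*% H
  P_post <- IKH %*% P %*% t(IKH) + K %*% model$R %*% t(K)
  track_state(mean_post, (P_post + t(P_post)) / 2)
}

as_measurement <- function(measurement, d) {
  z <- if (is.list(measurement) || is.data.frame(measurement)) {
    c(measurement$x, measurement$y)
  } else {
    as.numeric(measurement)
  }
  if (length(z) != d || !all(is.finite(z))) {
    stop("invalid measurement", call. = FALSE)
  }
  z
}

# Mahalanobis distance of measurement z from the predicted measurement,
# under the innovation covariance S = H P H' + R.
mahalanobis_to_measurement <- function(model, state, z) {
  H <- model$H
  S <- H %*% state$cov %*% t(H) + model$R
  y <- as_measurement(z, model$meas_dim) - as.numeric(H %*% state$mean)
  sqrt(as.numeric(t(y) %*% chol2inv(chol(S)) %*% y))
}

#' Associate predicted tracks with detections in one frame
#'
#' Builds the event-aware augmented cost matrix from the predicted track
#' positions and the frame's detections (Euclidean distances, or Mahalanobis
#' distances under each track's innovation covariance), solves it with the
#' exact solver or the greedy-decoded policy network, and classifies the
#' result into matched / lost / new.
#'
#' @param predicted_states list of predicted [track_state()] objects (may be
#'   empty).
#' @param detections data frame with `x`, `y` columns (may have zero rows).
#' @param model the [kalman_model()] (needed for `H` and, for Mahalanobis
#'   distances, `R`).
#' @param threshold gating threshold `tau` (scene units for Euclidean,
#'   sigma units for Mahalanobis).
#' @param solver `"exact"` or `"policy"`.
#' @param distance `"euclidean"` or `"mahalanobis"`.
#' @param policy a trained [policy_model()] (required for
#'   `solver = "policy"`).
#' @return list: `outcome` (an `association_outcome`), `assignment`,
#'   `matrix` (the augmented matrix), `cost` (association cost of the chosen
#'   assignment).  With no tracks and no detections, an empty outcome.
#' @export
associate_frame <- function(predicted_states, detections, model, threshold,
                            solver = c("exact", "policy"),
                            distance = c("euclidean", "mahalanobis"),
                            policy = NULL) {
  solver <- match.arg(solver)
  distance <- match.arg(distance)
  m <- length(predicted_states)
  n <- nrow(detections)
  if (m == 0L && n == 0L) {
    return(list(outcome = structure(list(
      matched_pairs = cbind(prediction = integer(0),
                            measurement = integer(0)),
      lost_predictions = integer(0), new_measurements = integer(0),
      infeasible = FALSE), class = "association_outcome"),
      assignment = NULL, matrix = NULL, cost = 0))
  }
  lambda <- if (distance == "euclidean") {
    P <- do.call(rbind, lapply(predicted_states, function(s) {
      as.numeric(model$H %*% s$mean)
    }))
    euclidean_cross_distances(
      if (is.null(P)) base::matrix(numeric(0), 0, 2) else P,
      base::matrix(c(detections$x, detections$y), n, 2L))
  } else {
    lam <- base::matrix(0, m, n)
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        lam[i, j] <- mahalanobis_to_measurement(model, predicted_states[[i]],
                                                detections[j, ])
      }
    }
    lam
  }
  D <- augment_blocks(lambda, threshold)
  asg <- if (solver == "exact") {
    solve_exact(D)
  } else {
    if (is.null(policy)) {
      stop("associate_frame: solver = 'policy' requires `policy`",
           call. = FALSE)
    }
    # the policy sees the capped construction (bounded dynamic range, same
    # optimum); costs are accounted on the exact matrix D
    Dp <- augment_blocks(lambda, threshold, cap = TRUE)
    Y <- policy_forward(policy, normalize_cost(Dp))
    dec <- decode_assignment(Y, "greedy")
    new_assignment(dec$permutation, assignment_cost(D, dec$permutation),
                   "minimize")
  }
  list(outcome = classify_outcome(D, asg), assignment = asg, matrix = D,
       cost = asg$total_cost)
}

#' Track a detection sequence frame by frame
#'
#' Single-hypothesis tracking: per frame, every live track is predicted with
#' the Kalman model, predictions are associated to the frame's detections
#' through the augmented cost matrix ([associate_frame()]), matched tracks
#' are measurement-updated, unmatched ("lost") tracks coast on their
#' prediction and are terminated after more than `patience` consecutive lost
#' frames, and unmatched ("new") detections spawn tracks with zero initial
#' velocity and inflated covariance.
#'
#' @param detections data frame with columns `frame`, `x`, `y` (frames need
#'   not start at 1; missing frames are treated as empty).
#' @param model a [kalman_model()] (see [kalman_cv_model()]).
#' @param threshold gating threshold `tau` passed to [associate_frame()].
#' @param solver `"exact"` or `"policy"`; @param policy the policy model for
#'   `solver = "policy"`.
#' @param distance `"euclidean"` or `"mahalanobis"`.
#' @param patience consecutive lost frames tolerated before termination
#'   (default 2).
#' @param init_pos_var,init_vel_var diagonal covariance inflation for new
#'   tracks (defaults: measurement variance; 1).
#' @param frame_hook optional `function(frame, predicted_states, detections)`
#'   observer called before each frame's association (used by the
#'   solver-comparison harness).
#' @return list of tracks; each track is a list with `id`, `history` (data
#'   frame `frame, x, y, status`), `state` (final [track_state()]), `status`
#'   and `consecutive_lost`.  Also records per-frame association cost in
#'   `attr(result, "frame_costs")`.
#' @export
track_sequence <- function(detections, model, threshold,
                           solver = c("exact", "policy"),
                           distance = c("euclidean", "mahalanobis"),
                           policy = NULL, patience = 2L,
                           init_pos_var = NULL, init_vel_var = 1,
                           frame_hook = NULL) {
  solver <- match.arg(solver)
  distance <- match.arg(distance)
  if (nrow(detections) == 0L) {
    return(structure(list(), frame_costs = numeric(0)))
  }
  if (is.null(init_pos_var)) init_pos_var <- max(mean(diag(model$R)), 1e-6)
  frames <- seq(min(detections$frame), max(detections$frame))
  live <- list()     # tracks still alive
  done <- list()     # terminated tracks
  next_id <- 1L
  frame_costs <- numeric(0)

  spawn <- function(det, frame) {
    st <- track_state(c(det$x, det$y, 0, 0),
                      diag(c(init_pos_var, init_pos_var,
                             init_vel_var, init_vel_var)))
    tr <- list(id = next_id, state = st, status = "new",
               consecutive_lost = 0L,
               history = data.frame(frame = frame, x = det$x, y = det$y,
                                    status = "new"))
    next_id <<- next_id + 1L
    tr
  }

  for (f in frames) {
    dets <- detections[detections$frame == f, , drop = FALSE]
    if (f == frames[1L]) {
      for (j in seq_len(nrow(dets))) live[[length(live) + 1L]] <-
          spawn(dets[j, ], f)
      next
    }
    preds <- lapply(live, function(tr) kalman_predict(model, tr$state))
    if (!is.null(frame_hook)) frame_hook(f, preds, dets)
    assoc <- associate_frame(preds, dets, model, threshold,
                             solver = solver, distance = distance,
                             policy = policy)
    frame_costs <- c(frame_costs, assoc$cost)
    out <- assoc$outcome

    matched_of <- integer(length(live))
    if (nrow(out$matched_pairs)) {
      matched_of[out$matched_pairs[, "prediction"]] <-
        out$matched_pairs[, "measurement"]
    }
    keep <- logical(length(live))
    for (i in seq_along(live)) {
      tr <- live[[i]]
      if (matched_of[i] > 0L) {
        det <- dets[matched_of[i], ]
        tr$state <- kalman_update(model, preds[[i]], det)
        tr$status <- "tracked"
        tr$consecutive_lost <- 0L
        pos <- as.numeric(model$H %*% tr$state$mean)
        tr$history <- rbind(tr$history,
                            data.frame(frame = f, x = pos[1], y = pos[2],
                                       status = "tracked"))
        keep[i] <- TRUE
      } else {
        tr$state <- preds[[i]]                 # coast while lost
        tr$status <- "lost"
        tr$consecutive_lost <- tr$consecutive_lost + 1L
        pos <- as.numeric(model$H %*% tr$state$mean)
        tr$history <- rbind(tr$history,
                            data.frame(frame = f, x = pos[1], y = pos[2],
                                       status = "lost"))
        keep[i] <- tr$consecutive_lost <= patience
      }
      live[[i]] <- tr
    }
    done <- c(done, live[!keep])
    live <- live[keep]
    for (j in out$new_measurements) {
      live[[length(live) + 1L]] <- spawn(dets[j, ], f)
    }
  }
  structure(c(done, live), frame_costs = frame_costs)
}

#' Flatten a track list to a data frame
#'
#' @param tracks result of [track_sequence()].
#' @return data frame `track_id, frame, x, y, status`.
#' @export
tracks_to_df <- function(tracks) {
  if (!length(tracks)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0),
                      status = character(0)))
  }
  out <- do.call(rbind, lapply(tracks, function(tr) {
    cbind(track_id = tr$id, tr$history)
  }))
  rownames(out) <- NULL
  out[order(out$track_id, out$frame), ]
}
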