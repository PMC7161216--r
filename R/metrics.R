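#' Optimality ratio
#'
#' `predicted_weight / optimal_weight` for a maximization task; by
#' optimality of the reference solver the ratio lies in `[0, 1]`, and a
#' predicted weight exceeding the optimum (beyond round-off) is an internal
#' error.
#'
#' @param predicted_weight achieved matching weight.
#' @param optimal_weight Hungarian-optimal matching weight (> 0).
#' @return scalar ratio in `[0, 1]`.
#' @export
optimality_ratio <- function(predicted_weight, optimal_weight) {
  stopifnot(optimal_weight > 0)
  if (predicted_weight > optimal_weight * (1 + 1e-9) + 1e-12) {
    stop("optimality_ratio: predicted weight exceeds the optimum", call. = FALSE)
  }
  min(predicted_weight / optimal_weight, 1)
}

#' OSPA-T parameters
#'
#' @param c cutoff / cardinality penalty (> 0); distances are truncated at
#'   `c` and each unmatched object costs `c`.
#' @param p outlier sensitivity order (>= 1).
#' @return list of class `ospa_params`.
#' @export
ospa_params <- function(c = 1, p = 1) {
  stopifnot(c > 0, p >= 1)
  list(c = c, p = p)
}

#' Per-frame OSPA-T distance
#'
#' For truth positions `X` (m points) and estimated positions `Xhat`
#' (n points) with `m <= n`, computes
#' `( (1/n) * ( min over injections sum_i min(c, d_i)^p + c^p (n - m) ) )^(1/p)`,
#' swapping the arguments when `m > n` — i.e. the penalty counts the
#' cardinality gap and the normalization uses the larger cardinality.  The
#' inner matching is solved exactly by the Hungarian solver on the truncated
#' distance matrix.  Both sets empty returns 0 by convention.
#'
#' @param truth_positions numeric matrix (m x 2), possibly 0 rows.
#' @param estimate_positions numeric matrix (n x 2), possibly 0 rows.
#' @param params an [ospa_params()].
#' @return scalar in `[0, c]`.
#' @export
ospa_t_frame <- function(truth_positions, estimate_positions,
                         params = ospa_params()) {
  X <- as_points(truth_positions, "truth_positions")
  Z <- as_points(estimate_positions, "estimate_positions")
  m <- nrow(X); n <- nrow(Z)
  if (m == 0L && n == 0L) return(0)
  if (m > n) { tmp <- X; X <- Z; Z <- tmp; tmp <- m; m <- n; n <- tmp }
  if (m == 0L) return(params$c)
  Dc <- pmin(euclidean_cross_distances(X, Z), params$c)^params$p
  # pad with zero-cost dummy rows so unmatched estimates are free here;
  # their cardinality penalty is added explicitly
  A <- rbind(Dc, base::matrix(0, n - m, n))
  best <- solve_exact(A)$total_cost
  ((best + params$c^params$p * (n - m)) / n)^(1 / params$p)
}

#' Average OSPA-T distance between two track sets
#'
#' Mean of [ospa_t_frame()] over every frame spanned by either track set.
#' Track sets are data frames with columns `id` (or `track_id` /
#' `target_id`), `frame`, `x`, `y`.
#'
#' @param truth,estimate track-set data frames.
#' @param params an [ospa_params()].
#' @return scalar average OSPA-T distance.
#' @export
ospa_t_average <- function(truth, estimate, params = ospa_params()) {
  truth <- as_trackset(truth)
  estimate <- as_trackset(estimate)
  if (max(truth$frame) < min(estimate$frame) ||
      max(estimate$frame) < min(truth$frame)) {
    stop("ospa_t_average: disjoint frame ranges", call. = FALSE)
  }
  frames <- seq(min(truth$frame, estimate$frame),
                max(truth$frame, estimate$frame))
  vals <- vapply(frames, function(f) {
    ospa_t_frame(positions_at(truth, f), positions_at(estimate, f), params)
  }, numeric(1))
  mean(vals)
}

as_trackset <- function(df) {
  df <- as.data.frame(df)
  idcol <- intersect(c("id", "track_id", "target_id"), names(df))
  if (!length(idcol)) stop("track set needs an id column", call. = FALSE)
  data.frame(id = df[[idcol[1L]]], frame = df$frame, x = df$x, y = df$y)
}

positions_at <- function(ts, f) {
  sub <- ts[ts$frame == f, , drop = FALSE]
  base::matrix(c(sub$x, sub$y), nrow(sub), 2L)
}

#' Count identity switches
#'
#' CLEAR-MOT-style identity switches: per frame, ground-truth targets are
#' matched one-to-one to estimated tracks through the augmented cost matrix
#' with gate `match_radius` (so distant pairs stay unmatched), and a switch
#' is counted whenever a truth target's matched estimate id differs from the
#' id it was matched to at its previous matched frame.  The count is
#' invariant to a global relabeling of estimate ids.
#'
#' @param truth,estimate track-set data frames (see [ospa_t_average()]).
#' @param match_radius gating radius (> 0); defaults to the OSPA cutoff 1.
#' @return integer number of identity switches.
#' @export
count_id_switches <- function(truth, estimate, match_radius = 1) {
  stopifnot(match_radius > 0)
  truth <- as_trackset(truth)
  estimate <- as_trackset(estimate)
  frames <- sort(unique(truth$frame))
  last_match <- list()   # truth id -> estimate id at last matched frame
  switches <- 0L
  for (f in frames) {
    tf <- truth[truth$frame == f, , drop = FALSE]
    ef <- estimate[estimate$frame == f, , drop = FALSE]
    if (!nrow(tf) || !nrow(ef)) next
    lambda <- euclidean_cross_distances(
      base::matrix(c(tf$x, tf$y), nrow(tf), 2L),
      base::matrix(c(ef$x, ef$y), nrow(ef), 2L))
    D <- augment_blocks(lambda, match_radius)
    out <- classify_outcome(D, solve_exact(D))
    if (nrow(out$matched_pairs)) {
      for (r in seq_len(nrow(out$matched_pairs))) {
        tid <- as.character(tf$id[out$matched_pairs[r, "prediction"]])
        eid <- ef$id[out$matched_pairs[r, "measurement"]]
        if (!is.null(last_match[[tid]]) && last_match[[tid]] != eid) {
          switches <- switches + 1L
        }
        last_match[[tid]] <- eid
      }
    }
  }
  switches
}

#' Evaluate a solver on a set of LAP instances
#'
#' Greedy-decodes every instance with the policy (or solves it exactly for
#' the reference), scores each solution against the Hungarian optimum and
#' returns the median and full distribution of optimality ratios.
#'
#' @param solver `"exact"` or a trained [policy_model()].
#' @param instances list of [cost_matrix()] instances (same size for policy
#'   evaluation).
#' @param temperature decoder temperature (greedy decoding is unaffected).
#' @param chunk_size policy forward batch size.
#' @return list: `median_ratio`, `mean_ratio`, `ratios` (per instance),
#'   `n_instances`.
#' @export
evaluate_solver <- function(solver, instances, temperature = 1,
                            chunk_size = 256L) {
  stopifnot(length(instances) >= 1L)
  opt <- vapply(instances, function(m) solve_exact(m)$total_cost, numeric(1))
  pred <- if (identical(solver, "exact")) {
    opt
  } else {
    stopifnot(inherits(solver, "policy_model"))
    out <- numeric(length(instances))
    for (idx in split_chunks(seq_along(instances), chunk_size)) {
      Ys <- policy_forward(solver, lapply(instances[idx], normalize_cost),
                           training = FALSE)
      out[idx] <- vapply(seq_along(idx), function(i) {
        perm <- decode_assignment(Ys[[i]], "greedy",
                                  temperature = temperature)$permutation
        assignment_cost(instances[[idx[i]]], perm)
      }, numeric(1))
    }
    out
  }
  sense <- cm_sense(instances[[1L]])
  ratios <- if (sense == "maximize") {
    vapply(seq_along(opt), function(i) optimality_ratio(pred[i], opt[i]),
           numeric(1))
  } else {
    # for minimization report optimum/achieved, also in [0, 1]
    ifelse(pred > 0, opt / pred, 1)
  }
  list(median_ratio = stats::median(ratios), mean_ratio = mean(ratios),
       ratios = ratios, n_instances = length(instances))
}
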