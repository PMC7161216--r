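#' Maximum-weight-matching experiment
#'
#' For each requested size: generate a training set of unit-square MWM
#' instances, train the policy with REINFORCE, evaluate the median
#' optimality ratio against the Hungarian optimum on a fresh seeded test
#' set, and write everything (resolved config, training log, checkpoint,
#' per-instance ratios, report) into `out_dir`.
#'
#' @param sizes integer vector of instance sizes (default `c(15, 20, 25)`).
#' @param n_train training instances per size.
#' @param n_test held-out test instances per size (default 1000).
#' @param epochs passes over the training set.
#' @param batch_size mini-batch size.
#' @param temperature sampling temperature during training.
#' @param seed root seed; training and test streams are derived sub-streams.
#' @param out_dir output directory (created); `NULL` for no file output.
#' @param verbose print progress.
#' @return list with one entry per size: `median_ratio`, `mean_ratio`,
#'   `ratios`, `model`, `log`.
#' @export
run_mwm_experiment <- function(sizes = c(15L, 20L, 25L), n_train = 12800L,
                               n_test = 1000L, epochs = 15L,
                               batch_size = 64L, temperature = 0.1,
                               seed = 1L, out_dir = NULL, verbose = FALSE) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  results <- list()
  for (size in sizes) {
    cfg <- training_config(n_samples = n_train, batch_size = batch_size,
                           epochs = epochs, temperature = temperature,
                           seed = derive_seed(seed, paste0("size", size)),
                           objective_sense = "maximize")
    fit <- train_policy(cfg, mwm_instance_generator(size), verbose = verbose)
    test <- mwm_instance_generator(size)(
      n_test, derive_seed(seed, paste0("test", size)))
    ev <- evaluate_solver(fit$model, test)
    results[[as.character(size)]] <-
      list(size = size, median_ratio = ev$median_ratio,
           mean_ratio = ev$mean_ratio, ratios = ev$ratios,
           model = fit$model, log = fit$log)
    if (!is.null(out_dir)) {
      tag <- sprintf("mwm_n%d", size)
      save_checkpoint(fit$model, file.path(out_dir, paste0(tag, ".json")))
      utils::write.csv(fit$log, file.path(out_dir, paste0(tag, "_log.csv")),
                       row.names = FALSE)
      utils::write.csv(data.frame(ratio = ev$ratios),
                       file.path(out_dir, paste0(tag, "_ratios.csv")),
                       row.names = FALSE)
      write_run_config(list(command = "experiment mwm", size = size,
                            n_train = n_train, n_test = n_test,
                            epochs = epochs, batch_size = batch_size,
                            temperature = temperature, seed = seed),
                       file.path(out_dir, paste0(tag, "_config.txt")))
    }
    if (verbose) {
      message(sprintf("N = %d: median optimality ratio %.4f", size,
                      ev$median_ratio))
    }
  }
  if (!is.null(out_dir)) {
    report <- data.frame(
      size = vapply(results, `[[`, numeric(1), "size"),
      median_ratio = vapply(results, `[[`, numeric(1), "median_ratio"),
      mean_ratio = vapply(results, `[[`, numeric(1), "mean_ratio"))
    utils::write.csv(report, file.path(out_dir, "mwm_report.csv"),
                     row.names = FALSE)
  }
  results
}

#' Compare association solvers frame by frame on one scenario
#'
#' Runs the scenario with the exact-solver tracker and, at every frame,
#' also decodes the policy on the same augmented cost matrix the exact
#' solver saw, so the two association costs are directly comparable (same
#' predictions, same detections).
#'
#' @param scenario a [generate_crossing_scenario()] result.
#' @param model a [kalman_model()].
#' @param threshold gating threshold `tau`.
#' @param policy a trained [policy_model()].
#' @param distance `"euclidean"` or `"mahalanobis"`.
#' @param patience lost-frame tolerance.
#' @return data frame with one row per associated frame: `frame`,
#'   `exact_cost`, `policy_cost`.
#' @export
compare_solvers_on_scenario <- function(scenario, model, threshold, policy,
                                        distance = "mahalanobis",
                                        patience = 2L) {
  rows <- list()
  hook <- function(frame, predicted_states, detections) {
    pol <- associate_frame(predicted_states, detections, model, threshold,
                           solver = "policy", distance = distance,
                           policy = policy)
    exa <- associate_frame(predicted_states, detections, model, threshold,
                           solver = "exact", distance = distance)
    rows[[length(rows) + 1L]] <<- data.frame(frame = frame,
                                             exact_cost = exa$cost,
                                             policy_cost = pol$cost)
  }
  track_sequence(scenario$measurements, model, threshold, solver = "exact",
                 distance = distance, patience = patience,
                 frame_hook = hook)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulated multi-target tracking experiment
#'
#' Runs the crossing scenario `n_runs` times per measurement noise level,
#' tracks the measurements with the chosen solver (Mahalanobis distances, as
#' appropriate for a Kalman innovation gate), and reports the mean and
#' standard deviation of the average OSPA-T distance and of the identity
#' switch count.
#'
#' @param noise_levels numeric vector of isotropic measurement variances
#'   (default `c(0.01, 0.05, 0.1)`).
#' @param n_runs seeded scenario repetitions per level (default 100).
#' @param solver `"exact"` or `"policy"`; @param policy the policy model for
#'   `solver = "policy"`.
#' @param n_targets,n_frames scenario shape (defaults 5 targets, 40 frames).
#' @param threshold Mahalanobis gate in sigma units (default 3).
#' @param patience lost-frame tolerance before track termination.
#' @param ospa an [ospa_params()] (the cutoff `c = 1`, order `p = 1`
#'   defaults).
#' @param seed root seed.
#' @param out_dir optional output directory for per-run dumps and report.
#' @return data frame with one row per noise level: mean/sd OSPA-T, mean/sd
#'   IDSW; per-run values in `attr(result, "runs")`.
#' @export
run_tracking_experiment <- function(noise_levels = c(0.01, 0.05, 0.1),
                                    n_runs = 100L,
                                    solver = c("exact", "policy"),
                                    policy = NULL, n_targets = 5L,
                                    n_frames = 40L, threshold = 3,
                                    patience = 2L, ospa = ospa_params(),
                                    seed = 1L, out_dir = NULL) {
  solver <- match.arg(solver)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  runs <- list()
  rows <- list()
  for (r2 in noise_levels) {
    per_run <- data.frame(run = seq_len(n_runs), ospa_t = NA_real_,
                          idsw = NA_integer_)
    for (run in seq_len(n_runs)) {
      sc <- generate_crossing_scenario(
        n_targets = n_targets, n_frames = n_frames, R = r2,
        seed = derive_seed(seed, sprintf("track_%g_%d", r2, run)))
      model <- kalman_cv_model(R = r2)
      tracks <- track_sequence(sc$measurements, model, threshold,
                               solver = solver, distance = "mahalanobis",
                               policy = policy, patience = patience)
      est <- tracks_to_df(tracks)
      per_run$ospa_t[run] <- ospa_t_average(sc$truth, est, ospa)
      per_run$idsw[run] <- count_id_switches(sc$truth, est,
                                             match_radius = ospa$c)
    }
    runs[[as.character(r2)]] <- per_run
    rows[[as.character(r2)]] <- data.frame(
      R = r2,
      ospa_t_mean = mean(per_run$ospa_t), ospa_t_sd = stats::sd(per_run$ospa_t),
      idsw_mean = mean(per_run$idsw), idsw_sd = stats::sd(per_run$idsw))
    if (!is.null(out_dir)) {
      utils::write.csv(per_run,
                       file.path(out_dir, sprintf("tracking_R%g_runs.csv", r2)),
                       row.names = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "tracking_report.csv"),
                     row.names = FALSE)
    write_run_config(list(command = "experiment tracking",
                          noise_levels = paste(noise_levels, collapse = " "),
                          n_runs = n_runs, solver = solver,
                          n_targets = n_targets, n_frames = n_frames,
                          threshold = threshold, patience = patience,
                          seed = seed),
                     file.path(out_dir, "tracking_config.txt"))
  }
  structure(report, runs = runs)
}
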