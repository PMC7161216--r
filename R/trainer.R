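#' REINFORCE training configuration
#'
#' Bundles every knob of the policy-gradient training loop.  Training visits
#' a fixed set of `n_samples` generated instances (so each instance keeps a
#' persistent baseline), in shuffled mini-batches of `batch_size`, for
#' `n_steps` Adam updates.  The learning rate starts at `learning_rate` and
#' is multiplied by `lr_decay_factor` every `lr_decay_every` steps.
#'
#' @param n_samples number of training instances (fixed set, revisited).
#' @param batch_size mini-batch size `B`.
#' @param n_steps number of gradient steps `T`; default
#'   `ceiling(n_samples / batch_size) * epochs`.
#' @param epochs used only to derive the default `n_steps`.
#' @param learning_rate initial Adam learning rate (default `1e-3`).
#' @param lr_decay_factor multiplicative decay (default `0.96`).
#' @param lr_decay_every decay period in steps (default `5000`).
#' @param baseline_rate exponential-moving-average rate `alpha` of the
#'   per-instance baseline update `b' = b + alpha * (AC - b)` (default 0.1).
#' @param temperature softmax temperature used when sampling assignments
#'   during training (default 1; see [decode_assignment()]).
#' @param seed root seed; instance generation, weight initialization and the
#'   sampling stream are derived from it.
#' @param objective_sense `"maximize"` (e.g. maximum weight matching) or
#'   `"minimize"` (e.g. association cost matrices).
#' @return list of class `training_config`.
#' @export
training_config <- function(n_samples = 12800L, batch_size = 64L,
                            n_steps = NULL, epochs = 3L,
                            learning_rate = 1e-3, lr_decay_factor = 0.96,
                            lr_decay_every = 5000L, baseline_rate = 0.1,
                            temperature = 1, seed = 1L,
                            objective_sense = c("maximize", "minimize")) {
  objective_sense <- match.arg(objective_sense)
  if (is.null(n_steps)) {
    n_steps <- as.integer(ceiling(n_samples / batch_size) * epochs)
  }
  stopifnot(n_samples >= 1L, batch_size >= 1L, n_steps >= 0L,
            learning_rate > 0, lr_decay_factor > 0, lr_decay_factor <= 1,
            lr_decay_every >= 1L, baseline_rate > 0, baseline_rate <= 1,
            temperature > 0)
  structure(list(
    n_samples = as.integer(n_samples), batch_size = as.integer(batch_size),
    n_steps = as.integer(n_steps),
    learning_rate = learning_rate, lr_decay_factor = lr_decay_factor,
    lr_decay_every = as.integer(lr_decay_every),
    baseline_rate = baseline_rate, temperature = temperature,
    seed = as.integer(seed), objective_sense = objective_sense
  ), class = "training_config")
}

#' Learning-rate schedule
#'
#' `lr(t) = learning_rate * lr_decay_factor ^ floor(t / lr_decay_every)`, so
#' with the default schedule the rate at step 5,000 is `1e-3 * 0.96`.
#'
#' @param config a [training_config()].
#' @param step training step (1-based).
#' @return scalar learning rate.
#' @export
learning_rate_at <- function(config, step) {
  config$learning_rate *
    config$lr_decay_factor^(step %/% config$lr_decay_every)
}

#' Initialize per-instance baselines
#'
#' The baseline of each training instance is the assignment cost of the
#' greedy decode of the (possibly untrained) model on that instance, i.e. the
#' cost of the solution the network itself currently produces.
#'
#' @param model a [policy_model()].
#' @param samples list of same-sized [cost_matrix()] objects.
#' @param temperature decoder temperature (greedy decode is
#'   temperature-invariant; kept for signature symmetry).
#' @param chunk_size forward-pass batch size.
#' @return numeric vector of baselines, one per sample.
#' @export
initialize_baselines <- function(model, samples, temperature = 1,
                                 chunk_size = 256L) {
  if (!length(samples)) {
    stop("initialize_baselines: empty sample list", call. = FALSE)
  }
  out <- numeric(length(samples))
  for (idx in split_chunks(seq_along(samples), chunk_size)) {
    Ys <- policy_forward(model, lapply(samples[idx], normalize_cost),
                         training = FALSE)
    out[idx] <- vapply(seq_along(idx), function(i) {
      perm <- decode_assignment(Ys[[i]], "greedy",
                                temperature = temperature)$permutation
      assignment_cost(samples[[idx[i]]], perm)
    }, numeric(1))
  }
  out
}

split_chunks <- function(idx, size) {
  split(idx, ceiling(seq_along(idx) / size))
}

#' Exponential-moving-average baseline update
#'
#' `b'(C_i) = b(C_i) + alpha * (AC(pi_i | C_i) - b(C_i))`.
#'
#' @param store numeric baseline vector (one entry per training sample).
#' @param sample_id index (or indices) of the updated sample(s).
#' @param observed_cost observed assignment cost(s) `AC`.
#' @param alpha EMA rate in `(0, 1]`.
#' @return the updated store.
#' @export
update_baseline <- function(store, sample_id, observed_cost, alpha) {
  if (any(sample_id < 1L) || any(sample_id > length(store))) {
    stop("update_baseline: unknown sample_id", call. = FALSE)
  }
  store[sample_id] <- store[sample_id] +
    alpha * (observed_cost - store[sample_id])
  store
}

#' One REINFORCE gradient estimate
#'
#' Samples an assignment for every matrix in the batch from the stochastic
#' policy, and returns the policy-gradient estimator
#' `(1/B) * sum_i [s * (AC(pi_i | C_i) - b(C_i)) * grad log p(pi_i | C_i)]`
#' as a *descent* direction: the sign `s` is `+1` for a minimization
#' objective and `-1` for maximization, so stepping against the returned
#' gradient improves the objective in both cases.
#'
#' @param model a [policy_model()].
#' @param matrices list of same-sized [cost_matrix()] instances.
#' @param baselines numeric vector of per-instance baselines `b(C_i)`.
#' @param objective_sense `"maximize"` or `"minimize"`.
#' @param temperature sampling temperature.
#' @param seed optional seed for the sampling draw.
#' @return list with `grads` (same structure as `model$params`), `rewards`
#'   (per-sample `AC`), `permutations`, `log_probabilities`, and the
#'   mini-batch BN statistics (`batch_mean`, `batch_var`).
#' @export
reinforce_gradient <- function(model, matrices, baselines,
                               objective_sense = c("maximize", "minimize"),
                               temperature = 1, seed = NULL) {
  objective_sense <- match.arg(objective_sense)
  stopifnot(length(matrices) >= 1L, length(baselines) == length(matrices))
  if (!is.null(seed)) set.seed(seed)
  B <- length(matrices)
  N <- nrow(matrices[[1L]])
  X <- vapply(matrices, function(m) as.vector(normalize_cost(m)),
              numeric(N * N))
  X <- base::matrix(X, N * N, B)
  fwd <- net_forward(model, X, N, B, training = TRUE)
  s <- if (objective_sense == "maximize") -1 else 1

  dec <- .decode_batch_cpp(fwd$Y, N, B, temperature, FALSE)
  P <- dec$permutations                 # N x B, 1-based
  rewards <- vapply(seq_len(B), function(i) {
    sum(unclass_matrix(matrices[[i]])[cbind(seq_len(N), P[, i])])
  }, numeric(1))
  coef <- s * (rewards - baselines) / B
  dY <- .dlogp_batch_cpp(fwd$Y, P, coef, N, B, temperature)
  grads <- net_backward(model, fwd$cache, dY)
  list(grads = grads, rewards = rewards,
       permutations = lapply(seq_len(B), function(i) P[, i]),
       log_probabilities = as.numeric(dec$log_probabilities),
       batch_mean = fwd$batch_mean, batch_var = fwd$batch_var)
}

#' Train the assignment policy with REINFORCE
#'
#' Runs the full policy-gradient loop: draw the fixed training set from the
#' instance generator, initialize per-instance baselines from the untrained
#' model's own greedy solutions, then for `n_steps` steps sample a shuffled
#' mini-batch, sample assignments, form the baseline-subtracted REINFORCE
#' gradient, take an Adam step, and update the visited baselines.  Fully
#' reproducible from `config$seed`.
#'
#' @param config a [training_config()].
#' @param instance_generator `function(n, seed)` returning a list of `n`
#'   same-sized [cost_matrix()] instances (see [mwm_instance_generator()] and
#'   [association_instance_generator()]).
#' @param model optional starting [policy_model()]; default a fresh model
#'   seeded from the config.
#' @param eval_hook optional `function(model, step)` called at step 0 and
#'   every `eval_every` steps; its value is recorded in the returned log.
#' @param eval_every period of `eval_hook` calls (default: never except step
#'   0 and the final step).
#' @param verbose print progress every 500 steps.
#' @return list with `model` (trained), `log` (data frame: step, lr,
#'   mean_reward, mean_baseline, grad_norm), `baselines`, and `evals` (list
#'   of eval_hook results, if any).
#' @export
train_policy <- function(config, instance_generator, model = NULL,
                         eval_hook = NULL, eval_every = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  samples <- instance_generator(config$n_samples,
                                derive_seed(config$seed, "instances"))
  if (is.null(model)) {
    model <- policy_model(seed = derive_seed(config$seed, "init"))
  }
  baselines <- initialize_baselines(model, samples,
                                    temperature = config$temperature)

  adam <- adam_init(model$params)
  evals <- list()
  run_eval <- function(step) {
    if (!is.null(eval_hook)) {
      evals[[length(evals) + 1L]] <<- list(step = step,
                                           value = eval_hook(model, step))
    }
  }

  restore_rng_on_exit()
  set.seed(derive_seed(config$seed, "loop"))
  run_eval(0L)

  T_ <- config$n_steps
  B <- config$batch_size
  n <- config$n_samples
  order_pool <- integer(0)
  log_rows <- vector("list", T_)
  for (step in seq_len(T_)) {
    if (length(order_pool) < B) {
      order_pool <- c(order_pool, sample.int(n))
    }
    idx <- order_pool[seq_len(B)]
    order_pool <- order_pool[-seq_len(B)]

    est <- reinforce_gradient(model, samples[idx], baselines[idx],
                              objective_sense = config$objective_sense,
                              temperature = config$temperature)
    if (!all(vapply(est$rewards, is.finite, logical(1))) ||
        !all(is.finite(unlist(est$grads)))) {
      stop(sprintf(paste0(
        "train_policy: non-finite loss/gradient at step %d; ",
        "offending batch indices: %s"), step,
        paste(idx, collapse = " ")), call. = FALSE)
    }
    lr <- learning_rate_at(config, step)
    upd <- adam_step(adam, model$params, est$grads, lr)
    model$params <- upd$params
    adam <- upd$state

    mom <- model$bn_momentum
    for (l in seq_len(model$n_blocks)) {
      model$bn_mean[[l]] <- (1 - mom) * model$bn_mean[[l]] +
        mom * as.numeric(est$batch_mean[[l]])
      model$bn_var[[l]] <- (1 - mom) * model$bn_var[[l]] +
        mom * as.numeric(est$batch_var[[l]])
    }
    baselines <- update_baseline(baselines, idx, est$rewards,
                                 config$baseline_rate)
    model$training_steps <- model$training_steps + 1L

    log_rows[[step]] <- c(step = step, lr = lr,
                          mean_reward = mean(est$rewards),
                          mean_baseline = mean(baselines[idx]),
                          grad_norm = sqrt(sum(unlist(est$grads)^2)))
    if (!is.null(eval_every) && step %% eval_every == 0L && step < T_) {
      run_eval(step)
    }
    if (verbose && step %% 500L == 0L) {
      message(sprintf("step %d/%d mean reward %.4f", step, T_,
                      mean(est$rewards)))
    }
  }
  if (T_ > 0L) run_eval(T_)
  log <- if (T_ > 0L) {
    as.data.frame(do.call(rbind, log_rows))
  } else {
    data.frame(step = numeric(0), lr = numeric(0), mean_reward = numeric(0),
               mean_baseline = numeric(0), grad_norm = numeric(0))
  }
  list(model = model, log = log, baselines = baselines, evals = evals)
}

# ---- Adam optimizer over the nested parameter list ----------------------

adam_init <- function(params) {
  zeros_like <- function(p) {
    if (is.list(p)) lapply(p, zeros_like) else p * 0
  }
  list(m = zeros_like(params), v = zeros_like(params), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      g <- as.numeric(g)
      dim(g) <- dim(p)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- Map(walk, params, grads[names(params)], state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = modifyList(state, list(m = lapply(out, `[[`, "m"),
                                      v = lapply(out, `[[`, "v"))))
}

#' Derive a named sub-stream seed from a root seed
#'
#' Deterministic mix of the root seed and a stream label, kept inside the
#' 32-bit signed integer range so the result is always a valid `set.seed()`
#' argument.
#'
#' @param seed integer root seed.
#' @param stream character stream label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 10007) %% 2147483647)
}
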