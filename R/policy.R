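#' Residual convolutional assignment policy
#'
#' Constructs the fully convolutional policy network that maps a normalized
#' square cost matrix `C` (treated as a one-channel image) to a score matrix
#' `Y = tanh(C - R(C))`, where `R(C)` is the learned residual ("noise")
#' estimate.  The architecture is: one Conv+ReLU entry block (`n_channels`
#' filters of `kernel_size^2 x 1`), `n_blocks` Conv+BN+ReLU middle blocks,
#' and a final convolution back to one channel; every convolution uses zero
#' padding so the output has the spatial size of the input, making the model
#' size-agnostic.  Batch normalization is the plain centering/scaling
#' transform `t' = (t - E[t]) / sqrt(Var[t])` with mini-batch statistics in
#' training mode and accumulated running statistics in evaluation mode.
#'
#' The final convolution is zero-initialized so an untrained model computes
#' `Y = tanh(C)`: the policy starts from the row-greedy heuristic on the raw
#' (normalized) matrix and learns a residual correction on top of it.
#'
#' @param n_blocks number of middle Conv+BN+ReLU blocks (default 3).
#' @param n_channels number of feature maps per convolution (default 8).
#' @param kernel_size odd convolution kernel width (default 3).
#' @param seed integer seed for the weight initialization.
#' @return An object of class `policy_model`.
#' @export
policy_model <- function(n_blocks = 3L, n_channels = 8L, kernel_size = 3L,
                         seed = 1L) {
  stopifnot(n_blocks >= 1L, n_channels >= 1L, kernel_size %% 2L == 1L)
  k2 <- kernel_size^2
  restore_rng_on_exit()
  set.seed(seed)
  he <- function(fan_in, nr, nc) {
    matrix(stats::rnorm(nr * nc) * sqrt(2 / fan_in), nr, nc)
  }
  params <- list(
    W1 = he(k2, k2, n_channels),
    b1 = numeric(n_channels),
    Wmid = lapply(seq_len(n_blocks), function(i) {
      he(k2 * n_channels, k2 * n_channels, n_channels)
    }),
    Wlast = matrix(0, k2 * n_channels, 1L),  # zero init: identity residual
    blast = 0
  )
  structure(list(
    params = params,
    bn_mean = replicate(n_blocks, numeric(n_channels), simplify = FALSE),
    bn_var = replicate(n_blocks, rep(1, n_channels), simplify = FALSE),
    n_blocks = as.integer(n_blocks),
    n_channels = as.integer(n_channels),
    kernel_size = as.integer(kernel_size),
    bn_eps = 1e-5,
    bn_momentum = 0.1,
    normalization = "per-matrix max",
    training_steps = 0L,
    seed = as.integer(seed)
  ), class = "policy_model")
}

#' @export
print.policy_model <- function(x, ...) {
  cat(sprintf(
    "<policy_model> %d middle blocks, %d channels, %dx%d kernels, %d training steps\n",
    x$n_blocks, x$n_channels, x$kernel_size, x$kernel_size, x$training_steps))
  invisible(x)
}

#' Normalize a cost matrix for the policy network
#'
#' Divides by the maximum entry so values lie in `[0, 1]` (the bounded range
#' the tanh-clipped network expects), and orients the encoding by the
#' optimization sense: a maximize-sense matrix enters as `C / max(C)` and a
#' minimize-sense matrix as `1 - C / max(C)`, so that in both cases a larger
#' input marks a more attractive cell and the untrained (zero-residual)
#' policy's greedy decode is the corresponding row-greedy heuristic.  An
#' all-zero matrix is returned unchanged.
#'
#' @param matrix square numeric matrix or [cost_matrix()]; a plain matrix
#'   defaults to the minimize sense unless `sense` is given.
#' @param sense optional override, `"minimize"` or `"maximize"`.
#' @return plain numeric matrix in `[0, 1]`.
#' @export
normalize_cost <- function(matrix, sense = NULL) {
  a <- check_square(matrix, "normalize_cost")
  if (is.null(sense)) sense <- cm_sense(matrix)
  mx <- max(a)
  if (mx > 0) a <- a / mx
  if (sense == "minimize") 1 - a else a
}

#' Run the policy network forward
#'
#' @param model a [policy_model()].
#' @param matrix a square numeric matrix normalized to `[0, 1]` (see
#'   [normalize_cost()]), or a list of same-sized matrices evaluated as one
#'   batch.
#' @param training logical: mini-batch statistics (`TRUE`) or running
#'   statistics (`FALSE`, default) in batch normalization.
#' @return For a single matrix, the score matrix `Y` in `[-1, 1]` with the
#'   input's shape; for a list input, a list of score matrices.
#' @export
policy_forward <- function(model, matrix, training = FALSE) {
  single <- !is.list(matrix)
  mats <- if (single) list(matrix) else matrix
  N <- nrow(mats[[1L]])
  for (m in mats) {
    if (!is.numeric(m) || nrow(m) != ncol(m)) {
      stop("policy_forward: inputs must be square numeric matrices",
           call. = FALSE)
    }
    if (nrow(m) != N) {
      stop("policy_forward: all matrices in a batch must share one size",
           call. = FALSE)
    }
  }
  X <- vapply(mats, function(m) as.vector(unclass_matrix(m)),
              numeric(N * N))
  X <- base::matrix(X, N * N, length(mats))
  out <- net_forward(model, X, N, length(mats), training = training)
  Ys <- lapply(seq_len(ncol(out$Y)), function(i) {
    base::matrix(out$Y[, i], N, N)
  })
  if (single) Ys[[1L]] else Ys
}

# low-level forward on an (N*N x B) column-per-sample matrix; the backward
# cache stays on the C++ side (with_cache) and is consumed by net_backward
net_forward <- function(model, X, N, B, training, with_cache = training) {
  p <- model$params
  .net_forward_cpp(X, as.integer(N), as.integer(B),
                   p$W1, p$b1, p$Wmid, p$Wlast, p$blast,
                   model$bn_mean, model$bn_var,
                   isTRUE(training), model$bn_eps, model$kernel_size,
                   isTRUE(with_cache))
}

net_backward <- function(model, cache, dY) {
  p <- model$params
  .net_backward_cpp(cache, dY, p$W1, p$Wmid, p$Wlast)
}

#' Batch normalization transform
#'
#' The plain normalization `t' = (t - E[t]) / sqrt(Var[t] + eps)` used inside
#' the policy network's middle blocks (no learned scale/shift).  Exposed for
#' inspection and testing; `statistics = NULL` computes mini-batch statistics
#' from `t` itself (training mode), otherwise the supplied running statistics
#' are applied (evaluation mode).
#'
#' @param t numeric vector/matrix of activations for one channel.
#' @param statistics optional `list(mean =, var =)` of running statistics.
#' @param eps variance stabilizer (default `1e-5`).
#' @return normalized activations with the shape of `t`.
#' @export
batch_normalize <- function(t, statistics = NULL, eps = 1e-5) {
  if (is.null(statistics)) {
    m <- mean(t)
    v <- mean((t - m)^2)
  } else {
    m <- statistics$mean
    v <- statistics$var
  }
  (t - m) / sqrt(v + eps)
}

#' Decode a score matrix into a one-to-one assignment
#'
#' Sequential pointing decoder: rows are processed in ascending order; for
#' row `i` the scores of already-claimed columns are masked to `-Inf`, the
#' remaining scores (divided by `temperature`) are softmax-normalized, and a
#' column is chosen greedily (argmax) or by sampling.  The result is always a
#' valid permutation, and the accumulated log-probability of the chosen
#' columns is returned.  Sampling uses the current R random number generator
#' state, or a caller-supplied seed.
#'
#' @param scores square numeric score matrix (any finite values; typically
#'   the `[-1, 1]` output of [policy_forward()]).
#' @param mode `"greedy"` or `"sample"`.
#' @param temperature softmax temperature (> 0, default 1); lower values
#'   sharpen the distribution, which matters because tanh-bounded scores are
#'   confined to `[-1, 1]`.
#' @param seed optional integer seed applied before sampling.
#' @return A list of class `decoded_assignment`: `permutation` (1-based),
#'   `log_probability` (<= 0) and `mode`.
#' @export
decode_assignment <- function(scores, mode = c("greedy", "sample"),
                              temperature = 1, seed = NULL) {
  mode <- match.arg(mode)
  a <- check_square(scores, "decode_assignment")
  stopifnot(temperature > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(a)
  avail <- rep(TRUE, n)
  perm <- integer(n)
  logp <- 0
  for (i in seq_len(n)) {
    idx <- which(avail)
    u <- a[i, idx] / temperature
    u <- u - max(u)
    w <- exp(u)
    p <- w / sum(w)
    pick <- if (mode == "greedy") which.max(p)
            else sample.int(length(idx), 1L, prob = p)
    perm[i] <- idx[pick]
    avail[idx[pick]] <- FALSE
    logp <- logp + log(p[pick])
  }
  structure(list(permutation = perm, log_probability = logp, mode = mode),
            class = "decoded_assignment")
}

#' @export
print.decoded_assignment <- function(x, ...) {
  cat(sprintf("<decoded_assignment> mode = %s, log p = %.4f\n",
              x$mode, x$log_probability))
  cat("pi:", paste(x$permutation, collapse = " "), "\n")
  invisible(x)
}

#' Log-probability of a permutation under the pointing decoder
#'
#' Returns `sum_i log softmax(masked scores of row i)[pi_i]`, the exact
#' quantity [decode_assignment()] accumulates, so
#' `log_prob_of(Y, decode_assignment(Y, "sample")$permutation)` reproduces
#' the decoder's reported log-probability.
#'
#' @inheritParams decode_assignment
#' @param permutation 1-based permutation vector (or a `decoded_assignment`).
#' @return scalar log-probability (<= 0).
#' @export
log_prob_of <- function(scores, permutation, temperature = 1) {
  a <- check_square(scores, "log_prob_of")
  n <- nrow(a)
  perm <- if (inherits(permutation, "decoded_assignment"))
            permutation$permutation else as.integer(permutation)
  perm <- as_permutation(perm, n)
  avail <- rep(TRUE, n)
  logp <- 0
  for (i in seq_len(n)) {
    idx <- which(avail)
    u <- a[i, idx] / temperature
    u <- u - max(u)
    logZ <- log(sum(exp(u)))
    logp <- logp + u[match(perm[i], idx)] - logZ
    avail[perm[i]] <- FALSE
  }
  logp
}

# Gradient of log_prob_of with respect to the score matrix: for row i over
# the unclaimed columns A_i, d/dY[i,j] = (1[j = pi_i] - softmax_j) / temp.
dlogp_dscores <- function(scores, perm, temperature = 1) {
  n <- nrow(scores)
  g <- base::matrix(0, n, n)
  avail <- rep(TRUE, n)
  for (i in seq_len(n)) {
    idx <- which(avail)
    u <- scores[i, idx] / temperature
    u <- u - max(u)
    p <- exp(u) / sum(exp(u))
    gi <- -p
    gi[match(perm[i], idx)] <- gi[match(perm[i], idx)] + 1
    g[i, idx] <- gi / temperature
    avail[perm[i]] <- FALSE
  }
  g
}

# restore the caller's RNG state when the calling function exits, so seeded
# constructors do not perturb the global random stream
restore_rng_on_exit <- function(envir = parent.frame()) {
  state <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  expr <- if (is.null(state)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(state), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
}
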