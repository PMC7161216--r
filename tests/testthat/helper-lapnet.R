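# shared test utilities: independent reference implementations (oracles)
# and small fixture factories.  Everything is generated in code.

rand_cost <- function(n, seed = NULL, sense = "minimize") {
  if (!is.null(seed)) set.seed(seed)
  cost_matrix(matrix(runif(n * n), n, n), sense = sense)
}

# Pure-R reference forward pass of the residual policy network, written
# against the layer definitions directly (shifted-window convolutions, plain
# batch normalization, tanh residual head).  Independent of the compiled
# path; used to cross-check it.
ref_forward <- function(model, C, training = FALSE) {
  k <- model$kernel_size
  half <- (k - 1) / 2
  N <- nrow(C)
  conv <- function(maps, W) {
    Cin <- length(maps)
    Cout <- ncol(W)
    lapply(seq_len(Cout), function(co) {
      acc <- matrix(0, N, N)
      for (kk in 0:(k * k - 1)) {
        dr <- kk %/% k - half
        dc <- kk %% k - half
        if (max(1, 1 - dr) > min(N, N - dr) ||
            max(1, 1 - dc) > min(N, N - dc)) next
        rs <- max(1, 1 - dr):min(N, N - dr)
        cs <- max(1, 1 - dc):min(N, N - dc)
        for (ci in seq_len(Cin)) {
          w <- W[kk * Cin + ci, co]
          if (w == 0) next
          shifted <- matrix(0, N, N)
          shifted[rs, cs] <- maps[[ci]][rs + dr, cs + dc]
          acc <- acc + w * shifted
        }
      }
      acc
    })
  }
  A <- conv(list(C), model$params$W1)
  A <- lapply(seq_along(A), function(i) pmax(A[[i]] + model$params$b1[i], 0))
  for (l in seq_len(model$n_blocks)) {
    Z <- conv(A, model$params$Wmid[[l]])
    A <- lapply(seq_along(Z), function(i) {
      st <- if (training) NULL else
        list(mean = model$bn_mean[[l]][i], var = model$bn_var[[l]][i])
      pmax(batch_normalize(Z[[i]], st, eps = model$bn_eps), 0)
    })
  }
  r <- conv(A, model$params$Wlast)[[1]] + model$params$blast
  tanh(C - r)
}

# a policy model with a non-trivial residual path (random last layer and
# batch-norm statistics) so reference comparisons exercise every layer
perturbed_model <- function(seed = 2, scale = 0.1) {
  set.seed(seed)
  m <- policy_model(seed = seed)
  k2f <- m$kernel_size^2 * m$n_channels
  m$params$Wlast <- matrix(rnorm(k2f) * scale, k2f, 1)
  m$params$blast <- rnorm(1) * scale
  m$bn_mean <- lapply(m$bn_mean, function(x) rnorm(length(x)) * scale)
  m$bn_var <- lapply(m$bn_var, function(x) 1 + runif(length(x)))
  m
}

# Brute-force OSPA-T for m <= n <= 7: enumerate every injection of the
# truth points into the estimate points.
ref_ospa_frame <- function(X, Z, params = ospa_params()) {
  m <- nrow(X)
  n <- nrow(Z)
  if (m == 0 && n == 0) return(0)
  if (m > n) return(ref_ospa_frame(Z, X, params))
  if (m == 0) return(params$c)
  P <- lapnet:::all_permutations(n)
  best <- Inf
  for (r in seq_len(nrow(P))) {
    tot <- 0
    for (i in seq_len(m)) {
      d <- sqrt(sum((X[i, ] - Z[P[r, i], ])^2))
      tot <- tot + min(params$c, d)^params$p
    }
    best <- min(best, tot)
  }
  ((best + params$c^params$p * (n - m)) / n)^(1 / params$p)
}

# central finite-difference gradient of log p(pi | C) for one parameter
# coordinate, through the training-mode forward pass
fd_logp_grad <- function(model, Cn, perm, get, set, idx, h = 1e-5,
                         temperature = 1) {
  lp <- function(mod) {
    N <- nrow(Cn)
    f <- lapnet:::net_forward(mod, matrix(as.vector(Cn), N * N, 1), N, 1,
                              training = TRUE, with_cache = FALSE)
    log_prob_of(matrix(f$Y, N, N), perm, temperature)
  }
  vp <- get(model)
  vp[idx] <- vp[idx] + h
  vm <- get(model)
  vm[idx] <- vm[idx] - h
  (lp(set(model, vp)) - lp(set(model, vm))) / (2 * h)
}

# analytic gradient of log p(pi | C) for every parameter (batch of one)
analytic_logp_grads <- function(model, Cn, perm, temperature = 1) {
  N <- nrow(Cn)
  fwd <- lapnet:::net_forward(model, matrix(as.vector(Cn), N * N, 1), N, 1,
                              training = TRUE)
  Y <- matrix(fwd$Y, N, N)
  dY <- matrix(as.vector(lapnet:::dlogp_dscores(Y, perm, temperature)),
               N * N, 1)
  lapnet:::net_backward(model, fwd$cache, dY)
}
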