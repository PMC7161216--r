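#' Cost (or weight) matrix for the linear assignment problem
#'
#' Wraps a square numeric matrix together with its optimization sense.  The
#' linear assignment problem (LAP) asks for a one-to-one assignment of rows to
#' columns minimizing (sense `"minimize"`) or maximizing (sense `"maximize"`)
#' the total of the selected entries.
#'
#' @param values square numeric matrix with finite entries.
#' @param sense `"minimize"` or `"maximize"`.
#' @return An object of class `cost_matrix`: the matrix with attributes
#'   `sense` and `n`.
#' @examples
#' cm <- cost_matrix(matrix(c(4, 2, 3, 1, 0, 2, 3, 5, 2), 3, 3))
#' solve_exact(cm)
#' @export
cost_matrix <- function(values, sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("cost_matrix: `values` must be numeric", call. = FALSE)
  }
  if (nrow(values) != ncol(values) || nrow(values) < 1L) {
    stop("cost_matrix: `values` must be a non-empty square matrix",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("cost_matrix: all entries must be finite", call. = FALSE)
  }
  structure(values, class = "cost_matrix", sense = sense, n = nrow(values))
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat(sprintf("<cost_matrix> %dx%d, sense = %s\n", nrow(x), ncol(x),
              attr(x, "sense")))
  print(unclass_matrix(x))
  invisible(x)
}

# strip lapnet attributes for printing / numeric work
unclass_matrix <- function(x) {
  y <- as.matrix(unclass(x))
  attr(y, "sense") <- NULL
  attr(y, "n") <- NULL
  attr(y, "m_predictions") <- NULL
  attr(y, "n_measurements") <- NULL
  attr(y, "threshold") <- NULL
  attr(y, "big_value") <- NULL
  y
}

cm_sense <- function(x) {
  s <- attr(x, "sense")
  if (is.null(s)) "minimize" else s
}

#' Event-aware augmented cost matrix
#'
#' Builds the `(M+N) x (M+N)` association matrix `D` used for frame-to-frame
#' data association with explicit track lifecycle events.  With `M` predicted
#' positions and `N` measured positions, `D` has the block layout
#' \preformatted{
#'   D = [ Lambda (MxN) | Upsilon (MxM) ]
#'       [ Gamma  (NxN) | Lambda' (NxM) ]
#' }
#' where `Lambda[i, j]` is the distance between prediction `i` and measurement
#' `j`, and the dummy blocks `Upsilon` and `Gamma` carry the gating threshold
#' `tau` on their diagonals and a large surrogate for infinity elsewhere.  A
#' prediction assigned to its `Upsilon` diagonal is declared *lost*; a
#' measurement claimed by its `Gamma` diagonal row is declared *new*.  Because
#' a matched pair (i, j) also pairs dummy row `M+j` with dummy column `N+i` at
#' cost `Lambda[i, j]` (the transpose block), the match-versus-event decision
#' compares `Lambda[i, j]` against `tau` entry-wise.
#'
#' @param predicted_positions numeric matrix (M x 2) or list of 2-D points for
#'   the Kalman-predicted target positions; may have zero rows.
#' @param measured_positions numeric matrix (N x 2) or list of 2-D points for
#'   the current-frame detections; may have zero rows.
#' @param threshold gating distance `tau` (> 0), in the same units as the
#'   coordinates.
#' @param big_value finite surrogate for infinity; must exceed `tau` and every
#'   entry of `Lambda`.  Default `10 * max(tau, max(Lambda), 1)`.
#' @return An `augmented_cost_matrix` (also a `cost_matrix` with sense
#'   `"minimize"`) with attributes `m_predictions`, `n_measurements`,
#'   `threshold` and `big_value`.
#' @seealso [classify_outcome()] to translate a solved assignment back into
#'   matched / lost / new labels.
#' @examples
#' D <- build_augmented_matrix(rbind(c(0, 0)), rbind(c(0, 0.1), c(5, 5)),
#'                             threshold = 1)
#' classify_outcome(D, solve_exact(D))
#' @export
build_augmented_matrix <- function(predicted_positions, measured_positions,
                                   threshold, big_value = NULL) {
  P <- as_points(predicted_positions, "predicted_positions")
  Z <- as_points(measured_positions, "measured_positions")
  m <- nrow(P)
  n <- nrow(Z)
  if (m + n < 1L) {
    stop("build_augmented_matrix: both position lists are empty",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("build_augmented_matrix: `threshold` must be a positive scalar",
         call. = FALSE)
  }
  lambda <- euclidean_cross_distances(P, Z)
  augment_blocks(lambda, threshold, big_value)
}

#' Assemble the augmented matrix from a precomputed distance block
#'
#' Lower-level companion of [build_augmented_matrix()] taking the `M x N`
#' prediction-measurement distance block `Lambda` directly, so callers can use
#' any distance (e.g. Mahalanobis under the Kalman innovation covariance).
#'
#' @param lambda numeric `M x N` matrix of nonnegative distances (either
#'   dimension may be 0).
#' @param threshold gating distance `tau` (> 0).
#' @param cap if `TRUE`, distances are truncated at `big_value`
#'   (`Lambda' = pmin(Lambda, big_value)`).  Because a pair with distance
#'   above `tau` is always dominated by the lost-plus-new alternative (cost
#'   `2 tau` versus `2 lambda`), truncation at any value above `tau` leaves
#'   the optimal assignment unchanged while keeping the matrix's dynamic
#'   range bounded — which matters when the matrix is normalized and fed to
#'   the policy network.
#' @inheritParams build_augmented_matrix
#' @return An `augmented_cost_matrix`.
#' @export
augment_blocks <- function(lambda, threshold, big_value = NULL, cap = FALSE) {
  lambda <- as.matrix(lambda)
  m <- nrow(lambda)
  n <- ncol(lambda)
  if (m + n < 1L) {
    stop("augment_blocks: lambda must have at least one row or column",
         call. = FALSE)
  }
  if (length(lambda) && !all(is.finite(lambda))) {
    stop("augment_blocks: non-finite distances", call. = FALSE)
  }
  max_lambda <- if (length(lambda)) max(lambda) else 0
  if (is.null(big_value)) {
    big_value <- 10 * max(threshold, if (cap) 1 else max_lambda, 1)
  }
  if (cap && length(lambda)) {
    lambda <- pmin(lambda, big_value)
    max_lambda <- max(lambda)
  }
  if (big_value <= threshold ||
      (length(lambda) && !cap && big_value <= max_lambda)) {
    stop("augment_blocks: `big_value` must exceed the threshold and max(lambda)",
         call. = FALSE)
  }
  k <- m + n
  D <- matrix(big_value, k, k)
  if (m > 0 && n > 0) {
    D[seq_len(m), seq_len(n)] <- lambda              # Lambda
    D[m + seq_len(n), n + seq_len(m)] <- t(lambda)   # Lambda'
  }
  if (m > 0) {
    ups <- n + seq_len(m)
    D[cbind(seq_len(m), ups)] <- threshold           # Upsilon diagonal
  }
  if (n > 0) {
    gam <- m + seq_len(n)
    D[cbind(gam, seq_len(n))] <- threshold           # Gamma diagonal
  }
  structure(D,
            class = c("augmented_cost_matrix", "cost_matrix"),
            sense = "minimize", n = k,
            m_predictions = m, n_measurements = n,
            threshold = threshold, big_value = big_value)
}

#' @export
print.augmented_cost_matrix <- function(x, ...) {
  cat(sprintf(
    "<augmented_cost_matrix> M = %d predictions, N = %d measurements, tau = %g, big = %g\n",
    attr(x, "m_predictions"), attr(x, "n_measurements"),
    attr(x, "threshold"), attr(x, "big_value")))
  print(unclass_matrix(x))
  invisible(x)
}

as_points <- function(x, what) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) ||
      (is.list(x) && length(x) == 0L)) {
    return(matrix(numeric(0), 0L, 2L))
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(p) as.numeric(p)))
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) {
    stop(sprintf("%s: points must be 2-D", what), call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    stop(sprintf("%s: non-finite coordinates", what), call. = FALSE)
  }
  x
}

# M x N matrix of Euclidean distances between rows of P and rows of Z
euclidean_cross_distances <- function(P, Z) {
  m <- nrow(P)
  n <- nrow(Z)
  if (m == 0L || n == 0L) return(matrix(numeric(0), m, n))
  dx <- outer(P[, 1], Z[, 1], "-")
  dy <- outer(P[, 2], Z[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Read / write a cost matrix as delimited text
#'
#' Plain comma-separated values, one matrix row per line, no header — the
#' round-trip format used by the command-line interface.
#'
#' @param path file path.
#' @param sense optimization sense attached on read.
#' @return `read_cost_matrix` returns a [cost_matrix()];
#'   `write_cost_matrix` returns `path` invisibly.
#' @export
read_cost_matrix <- function(path, sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  rows <- utils::read.table(path, sep = ",", header = FALSE,
                            colClasses = "numeric")
  cost_matrix(as.matrix(rows), sense = sense)
}

#' @param x a matrix or `cost_matrix`.
#' @rdname read_cost_matrix
#' @export
write_cost_matrix <- function(x, path) {
  utils::write.table(unclass_matrix(x), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
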