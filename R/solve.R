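#' Exact solution of the linear assignment problem
#'
#' Hungarian-type solver (Jonker–Volgonant shortest augmenting path with dual
#' potentials, O(n^3)) returning the provably optimal one-to-one assignment
#' for the matrix's sense.  Among cost-equal optima the lexicographically
#' smallest permutation is preferred, implemented through an infinitesimal
#' column-ranked perturbation; the tie-break is exact for the small integer
#' matrices where ties actually arise and has no effect on generic
#' continuous data (see the methods vignette).
#'
#' @param matrix a [cost_matrix()], [build_augmented_matrix()] result, or a
#'   plain square numeric matrix (treated as sense `"minimize"`).
#' @return An object of class `assignment`: list with `permutation`
#'   (1-based: row `i` is assigned column `permutation[i]`), `total_cost`,
#'   and `sense`.
#' @examples
#' solve_exact(matrix(c(4, 2, 3, 1, 0, 2, 3, 5, 2), 3, 3))
#' @export
solve_exact <- function(matrix) {
  a <- check_square(matrix, "solve_exact")
  sense <- cm_sense(matrix)
  n <- nrow(a)
  work <- if (sense == "maximize") -a else a
  # lexicographic tie-break: prefer small columns in early rows.  The row
  # weights decay geometrically faster than the largest column index so the
  # perturbation orders equal-cost optima lexicographically.
  eps <- 1e-9 * (max(abs(a)) + 1)
  pert <- eps * outer((n + 1)^(-seq_len(n)), seq_len(n))
  perm <- lapjv_min(work + pert)
  new_assignment(perm, sum(a[cbind(seq_len(n), perm)]), sense)
}

#' Brute-force solution of the linear assignment problem
#'
#' Exhaustive enumeration of all `n!` permutations in lexicographic order;
#' the independent oracle for [solve_exact()].  Refuses matrices larger than
#' 9 x 9.
#'
#' @inheritParams solve_exact
#' @return An `assignment` (see [solve_exact()]); ties are broken toward the
#'   lexicographically smallest permutation because permutations are visited
#'   in lexicographic order with strict improvement.
#' @export
solve_brute_force <- function(matrix) {
  a <- check_square(matrix, "solve_brute_force")
  sense <- cm_sense(matrix)
  n <- nrow(a)
  if (n > 9L) {
    stop("solve_brute_force: refusing n > 9 (factorial growth)",
         call. = FALSE)
  }
  P <- all_permutations(n)                     # lexicographic order, n! x n
  lin <- as.vector((P - 1L) * n + rep(seq_len(n), each = nrow(P)))
  costs <- rowSums(matrix(a[lin], nrow(P), n))
  best <- if (sense == "maximize") which.max(costs) else which.min(costs)
  new_assignment(P[best, ], costs[best], sense)
}

#' Total cost of an assignment
#'
#' The LAP reward `sum_i C[i, pi_i]` of a permutation on a cost matrix.
#'
#' @inheritParams solve_exact
#' @param assignment an `assignment` object or a bare 1-based permutation
#'   vector.
#' @return scalar total cost.
#' @export
assignment_cost <- function(matrix, assignment) {
  a <- check_square(matrix, "assignment_cost")
  perm <- as_permutation(assignment, nrow(a))
  sum(a[cbind(seq_len(nrow(a)), perm)])
}

#' Interpret a solved augmented matrix as association events
#'
#' Translates the optimal permutation of an [build_augmented_matrix()] result
#' into the three lifecycle groups: prediction `i` assigned to a real
#' measurement column is *matched*; a prediction assigned to its dummy
#' (Upsilon) diagonal is *lost*; a measurement claimed by its dummy (Gamma)
#' diagonal row is *new*.  An assignment that selects an off-diagonal
#' `big_value` cell is structurally infeasible and is flagged.
#'
#' @param matrix an `augmented_cost_matrix`.
#' @param assignment the solved `assignment` (or bare permutation) for it.
#' @return A list of class `association_outcome` with 1-based index fields
#'   `matched_pairs` (two-column matrix `prediction`, `measurement`),
#'   `lost_predictions`, `new_measurements` and logical `infeasible`.
#' @export
classify_outcome <- function(matrix, assignment) {
  if (!inherits(matrix, "augmented_cost_matrix")) {
    stop("classify_outcome: `matrix` must be an augmented_cost_matrix",
         call. = FALSE)
  }
  m <- attr(matrix, "m_predictions")
  n <- attr(matrix, "n_measurements")
  big <- attr(matrix, "big_value")
  perm <- as_permutation(assignment, m + n)
  a <- unclass_matrix(matrix)

  infeasible <- FALSE
  matched_p <- integer(0)
  matched_z <- integer(0)
  lost <- integer(0)
  for (i in seq_len(m)) {
    j <- perm[i]
    if (j <= n) {
      matched_p <- c(matched_p, i)
      matched_z <- c(matched_z, j)
    } else if (j == n + i) {
      lost <- c(lost, i)
    } else {
      # off-diagonal Upsilon cell: big_value, structurally meaningless
      infeasible <- TRUE
      lost <- c(lost, i)
    }
  }
  new_z <- integer(0)
  for (j in seq_len(n)) {
    owner <- which(perm == j)           # row claiming measurement column j
    if (length(owner) == 1L && owner > m) {
      if (owner == m + j) {
        new_z <- c(new_z, j)
      } else {
        infeasible <- TRUE
        new_z <- c(new_z, j)
      }
    }
  }
  if (any(a[cbind(seq_len(m + n), perm)] >= big)) infeasible <- TRUE
  structure(list(
    matched_pairs = cbind(prediction = matched_p, measurement = matched_z),
    lost_predictions = lost,
    new_measurements = new_z,
    infeasible = infeasible
  ), class = "association_outcome")
}

#' @export
print.association_outcome <- function(x, ...) {
  cat(sprintf("<association_outcome> %d matched, %d lost, %d new%s\n",
              nrow(x$matched_pairs), length(x$lost_predictions),
              length(x$new_measurements),
              if (x$infeasible) " [infeasible cells selected]" else ""))
  invisible(x)
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("<assignment> n = %d, sense = %s, total_cost = %g\n",
              length(x$permutation), x$sense, x$total_cost))
  cat("pi:", paste(x$permutation, collapse = " "), "\n")
  invisible(x)
}

new_assignment <- function(perm, total_cost, sense) {
  structure(list(permutation = as.integer(perm),
                 total_cost = as.numeric(total_cost),
                 sense = sense),
            class = "assignment")
}

check_square <- function(matrix, fn) {
  a <- unclass_matrix(matrix)
  if (!is.numeric(a) || nrow(a) != ncol(a) || nrow(a) < 1L) {
    stop(sprintf("%s: input must be a non-empty square numeric matrix", fn),
         call. = FALSE)
  }
  if (!all(is.finite(a))) {
    stop(sprintf("%s: non-finite entries", fn), call. = FALSE)
  }
  a
}

as_permutation <- function(assignment, n) {
  perm <- if (inherits(assignment, "assignment")) assignment$permutation
          else as.integer(assignment)
  if (length(perm) != n || !identical(sort(perm), seq_len(n))) {
    stop("invalid permutation for this matrix size", call. = FALSE)
  }
  perm
}

# Shortest-augmenting-path LAP (dual potentials), minimization.
# Index convention: columns 1..n live at positions 2..(n+1); position 1 is
# the virtual source column of the augmenting path.
lapjv_min <- function(a) {
  n <- nrow(a)
  if (n == 1L) return(1L)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials (v[1] virtual)
  p <- integer(n + 1L)     # p[j]: row assigned to column position j (0 free)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used)                      # column positions
      cur <- a[i0, free - 1L] - u[i0] - v[free]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      k <- which.min(minv[free])
      delta <- minv[free][k]
      j1 <- free[k]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  perm[p[2L:(n + 1L)]] <- seq_len(n)
  perm
}

# All permutations of 1..n in lexicographic order (cached), n! x n matrix.
perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  P <- if (n == 1L) matrix(1L, 1L, 1L) else {
    sub <- all_permutations(n - 1L)
    blocks <- lapply(seq_len(n), function(first) {
      rest <- setdiff(seq_len(n), first)
      cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
    })
    do.call(rbind, blocks)
  }
  dimnames(P) <- NULL
  storage.mode(P) <- "integer"
  perm_cache[[key]] <- P
  P
}
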