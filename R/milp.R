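# Exact solver for the ideal-point preference-elicitation program.
#
# Given group scores Y (plans x groups) and a strict-preference pair set
# Omega, find nonnegative weights w and an ideal point x minimizing the
# number of violated pairs, where pair (j, k) -- j preferred to k -- is
# satisfied when the weighted squared distance of j to x does not exceed
# that of k:
#
#   sum_p (y_kp^2 - y_jp^2) w_p - 2 sum_p (y_kp - y_jp) v_p >= 0,
#   v_p = w_p x_p.
#
# Binary indicators delta_jk relax individual constraints; the objective
# minimizes sum(delta). Rather than a finite big-M, the solver drops the
# constraints of pairs marked violated (the M -> infinity limit, always a
# valid relaxation) and searches violation sets in order of increasing
# cardinality, certifying each candidate set by an LP feasibility check.
# Feasibility subproblems are solved as minimum-norm quadratic programs
# (quadprog), which detect infeasibility reliably at this scale.
#
# The model is positively homogeneous in (w, v), so a normalization is
# needed to exclude w = 0. The weights are constrained to the unit simplex
# and the ideal point to a box [L, U] per dimension, encoded exactly by
# L w_p <= v_p <= U w_p (valid since w_p >= 0). Where w_p = 0, x_p is
# undefined and reported as 1 by convention: a zero-weight group only has
# to sit at its planning goal for the decision-maker to be satisfied.

# Pair coefficient matrices: alpha[i, p] = y_kp^2 - y_jp^2,
# beta[i, p] = y_kp - y_jp for the i-th pair (j preferred to k).
.pair_coeffs <- function(Y, idx) {
  j <- idx[, "j"]; k <- idx[, "k"]
  list(alpha = Y[k, , drop = FALSE]^2 - Y[j, , drop = FALSE]^2,
       beta  = Y[k, , drop = FALSE] - Y[j, , drop = FALSE])
}

# Feasibility / min-norm solve for a satisfied-pair set.
# Variables z = (w, u) with v = u + L*w, 0 <= u <= (U - L) w, sum(w) = 1.
# Returns list(feasible, w, v) .
.elicit_qp <- function(alpha, beta, sat, t, L, U, eps) {
  nv <- 2L * t
  cons <- list(); rhs <- numeric(0)
  # equality first: sum(w) = 1
  cons[[1]] <- c(rep(1, t), rep(0, t)); rhs[1] <- 1
  for (p in seq_len(t)) {  # w_p >= 0
    e <- numeric(nv); e[p] <- 1
    cons[[length(cons) + 1L]] <- e; rhs[length(rhs) + 1L] <- 0
  }
  for (p in seq_len(t)) {  # u_p >= 0
    e <- numeric(nv); e[t + p] <- 1
    cons[[length(cons) + 1L]] <- e; rhs[length(rhs) + 1L] <- 0
  }
  for (p in seq_len(t)) {  # (U - L) w_p - u_p >= 0
    e <- numeric(nv); e[p] <- U - L; e[t + p] <- -1
    cons[[length(cons) + 1L]] <- e; rhs[length(rhs) + 1L] <- 0
  }
  for (i in sat) {  # pair constraints at margin eps
    e <- c(alpha[i, ] - 2 * L * beta[i, ], -2 * beta[i, ])
    cons[[length(cons) + 1L]] <- e; rhs[length(rhs) + 1L] <- eps
  }
  Amat <- do.call(cbind, cons)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(nv), dvec = rep(0, nv),
                       Amat = Amat, bvec = rhs, meq = 1L),
    error = function(e) NULL)
  if (is.null(sol)) return(list(feasible = FALSE))
  w <- sol$solution[seq_len(t)]
  u <- sol$solution[t + seq_len(t)]
  w[w < 0 & w > -1e-10] <- 0  # clip solver dust
  list(feasible = TRUE, w = w, v = u + L * w)
}

#' Recover the ideal point from weights and auxiliaries
#'
#' The elicitation program works in the linearized variables
#' \eqn{v_p = w_p x_p}; the ideal-point coordinate is \eqn{x_p = v_p / w_p}
#' where the weight is meaningfully positive. Where \eqn{w_p} falls below
#' `w_tol` the coordinate is undefined (the group plays no role in the
#' preference distance) and is reported as 1 by convention: such a group
#' merely has to sit at its planning goal.
#'
#' @param weights Nonnegative weight vector.
#' @param auxiliaries The corresponding `v` vector.
#' @param w_tol Weight threshold below which the coordinate is flagged
#'   undefined (default `1e-6`).
#' @return List with `x` (numeric) and `undefined` (logical), both per
#'   dimension.
#' @export
recover_ideal_point <- function(weights, auxiliaries, w_tol = 1e-6) {
  if (length(weights) != length(auxiliaries)) {
    abort_validation("weights and auxiliaries must share one length")
  }
  undef <- weights < w_tol
  x <- ifelse(undef, 1, auxiliaries / ifelse(undef, 1, weights))
  list(x = as.numeric(x), undefined = undef)
}

.check_omega <- function(omega) {
  if (!all(c("preferred", "other") %in% names(omega))) {
    abort_validation("preference set needs columns 'preferred' and 'other'")
  }
  if (any(omega$preferred == omega$other)) {
    abort_validation("a plan cannot be preferred to itself")
  }
  key <- paste(omega$preferred, omega$other, sep = "\r")
  rev_key <- paste(omega$other, omega$preferred, sep = "\r")
  if (any(rev_key %in% key)) {
    abort_validation("preference set contains a pair and its reverse")
  }
  omega[!duplicated(key), , drop = FALSE]
}

.default_x_bounds <- function(Y) {
  span <- max(Y) - min(Y)
  if (span <= 0) span <- 1
  c(min(Y) - span, max(Y) + span)
}

#' Elicit group weights and an ideal point from pairwise preferences
#'
#' Solves the mixed-integer ideal-point program exactly: among all
#' nonnegative weight vectors on the unit simplex and ideal points within
#' `x_bounds`, find a model violating as few preference pairs as possible.
#' The returned objective (the minimum number of violated pairs) is unique
#' even though the optimizing `(w, x)` generally is not; among optimal
#' models the solver reports one maximizing the smallest constraint slack,
#' so that satisfied preferences are reproduced strictly wherever possible.
#'
#' @param Y Score matrix (plans in rows, named by plan id; one column per
#'   structure group). See [as_score_matrix()].
#' @param omega Preference set from [build_preference_set()], or any data
#'   frame with columns `preferred` and `other` holding plan ids.
#' @param epsilon Strictness margin required of satisfied pairs (default 0,
#'   so exact distance ties satisfy a preference).
#' @param x_bounds Length-2 numeric, box for each ideal-point coordinate.
#'   Default: the score range of `Y` widened by one full range on each
#'   side.
#' @param w_tol Weight threshold for flagging undefined ideal-point
#'   coordinates; see [recover_ideal_point()].
#' @param max_subsets Search-effort guard: abort (solver error) after this
#'   many candidate violation sets (default `2e5`).
#' @return An `elicitation_result`: list with `weights` (simplex), `
#'   auxiliaries` (`v = w * x`), `ideal_point`, `undefined` (flags),
#'   `violations` (the pair table with a logical `violated` column),
#'   `objective` (integer), `margin` (smallest slack across satisfied
#'   pairs at the reported model), `x_bounds`, `epsilon`.
#' @export
solve_elicitation <- function(Y, omega, epsilon = 0, x_bounds = NULL,
                              w_tol = 1e-6, max_subsets = 2e5) {
  Y <- as_score_matrix(Y)
  omega <- .check_omega(omega)
  if (nrow(omega) == 0L) abort_validation("preference set is empty")
  idx <- .omega_idx(Y, omega)
  t <- ncol(Y)
  m <- nrow(omega)
  if (is.null(x_bounds)) x_bounds <- .default_x_bounds(Y)
  if (length(x_bounds) != 2L || x_bounds[1] >= x_bounds[2]) {
    abort_validation("x_bounds must be c(lower, upper) with lower < upper")
  }
  L <- x_bounds[1]; U <- x_bounds[2]
  cf <- .pair_coeffs(Y, idx)

  # Search violation sets by increasing cardinality; the first feasible
  # satisfied set certifies the optimum.
  tried <- 0L
  best <- NULL
  for (k in 0:m) {
    subsets <- if (k == 0L) {
      matrix(integer(0), nrow = 0)
    } else {
      combn(m, k)
    }
    ns <- if (k == 0L) 1L else ncol(subsets)
    for (s in seq_len(ns)) {
      tried <- tried + 1L
      if (tried > max_subsets) {
        abort_solver(paste0(
          "elicitation search exceeded ", max_subsets,
          " candidate violation sets; the instance is too large or too",
          " inconsistent for exact search"))
      }
      viol <- if (k == 0L) integer(0) else subsets[, s]
      sat <- setdiff(seq_len(m), viol)
      r <- .elicit_qp(cf$alpha, cf$beta, sat, t, L, U, epsilon)
      if (r$feasible) {
        best <- list(k = k, viol = viol, sat = sat, w = r$w, v = r$v)
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    abort_solver("no feasible model found (cannot occur with valid bounds)")
  }

  # Among optimal models, push the smallest satisfied-pair slack up by
  # bisection for a robust interior report.
  s_hi <- max(abs(cf$alpha)) + 2 * max(abs(c(L, U))) * max(abs(cf$beta)) + 1
  lo <- epsilon; hi <- s_hi
  w <- best$w; v <- best$v
  if (length(best$sat) > 0L) {
    for (iter in 1:25) {
      mid <- (lo + hi) / 2
      r <- .elicit_qp(cf$alpha, cf$beta, best$sat, t, L, U, mid)
      if (r$feasible) {
        lo <- mid; w <- r$w; v <- r$v
      } else {
        hi <- mid
      }
    }
  }

  ip <- recover_ideal_point(w, v, w_tol)
  violated <- rep(FALSE, m)
  violated[best$viol] <- TRUE
  violations <- as.data.frame(omega)
  violations$violated <- violated
  res <- list(weights = setNames(w, colnames(Y)),
              auxiliaries = setNames(v, colnames(Y)),
              ideal_point = setNames(ip$x, colnames(Y)),
              undefined = setNames(ip$undefined, colnames(Y)),
              violations = violations,
              objective = best$k,
              margin = lo,
              x_bounds = x_bounds,
              epsilon = epsilon)
  class(res) <- "elicitation_result"
  res
}

#' @export
print.elicitation_result <- function(x, ...) {
  cat("Ideal-point elicitation:", x$objective, "of",
      nrow(x$violations), "preference pairs violated\n")
  tab <- data.frame(weight = round(x$weights, 4),
                    weight_pct = round(100 * x$weights, 1),
                    ideal_point = round(x$ideal_point, 4),
                    undefined = x$undefined)
  print(tab, ...)
  invisible(x)
}

#' Brute-force minimum violation count over weights and ideal points
#'
#' Independent check for [solve_elicitation()], exhaustive for t <= 2.
#' The violation count is piecewise constant over the search space: in
#' the linearized coordinates (simplex weights, v = w * x) each
#' preference pair contributes one hyperplane, and the count only changes
#' across these planes and the box faces. A dense lattice of simplex
#' weights and ideal points is scanned, and for t <= 2 every vertex of
#' the bounded hyperplane arrangement is enumerated as well; since each
#' cell's minimum is attained at an arrangement vertex (ties count as
#' satisfied, matching the weak constraints of the elicitation program),
#' the candidate minimum is the exact optimum. For t = 3 only the lattice
#' is scanned, so the result upper-bounds the optimum to grid coarseness.
#' Guarded to t <= 3 dimensions and n <= 8 plans.
#'
#' @param Y Score matrix (plans in rows, groups in columns).
#' @param omega Preference pair set (columns `preferred`, `other`).
#' @param grid_resolution Lattice points per axis (default 41).
#' @param x_bounds Ideal-point box; defaults as in [solve_elicitation()].
#' @return Integer: the minimal violation count found.
#' @export
brute_force_elicit <- function(Y, omega, grid_resolution = 41,
                               x_bounds = NULL) {
  Y <- as_score_matrix(Y)
  omega <- .check_omega(omega)
  if (nrow(omega) == 0L) return(0L)
  t <- ncol(Y)
  if (t > 3L || nrow(Y) > 8L) {
    abort_validation("brute_force_elicit is limited to t <= 3, n <= 8")
  }
  idx <- .omega_idx(Y, omega)
  if (is.null(x_bounds)) x_bounds <- .default_x_bounds(Y)
  cf <- .pair_coeffs(Y, idx)
  R <- as.integer(grid_resolution)
  if (R < 2L) abort_validation("grid_resolution must be >= 2")

  best <- .bf_lattice_min(cf, t, x_bounds, R)
  if (best > 0L && t <= 2L) {
    best <- min(best, .bf_vertex_min(cf, t, x_bounds))
  }
  best
}

# Lattice scan: simplex weights x ideal-point lattice.
.bf_lattice_min <- function(cf, t, x_bounds, R) {
  m <- nrow(cf$alpha)
  Wg <- if (t == 1L) {
    matrix(1, 1, 1)
  } else if (t == 2L) {
    w1 <- seq(0, 1, length.out = R)
    cbind(w1, 1 - w1)
  } else {
    g <- expand.grid(w1 = seq(0, 1, length.out = R),
                     w2 = seq(0, 1, length.out = R))
    g <- g[g$w1 + g$w2 <= 1 + 1e-12, ]
    cbind(g$w1, g$w2, pmax(0, 1 - g$w1 - g$w2))
  }
  xs <- seq(x_bounds[1], x_bounds[2], length.out = R)
  Xg <- as.matrix(expand.grid(rep(list(xs), t)))

  # Pair (j,k) is violated iff d_j^2 - d_k^2 > 0, i.e.
  # -alpha.w + 2 beta.(w*x) > 0.
  best <- m + 1L
  tb <- t(cf$beta)
  for (r in seq_len(nrow(Wg))) {
    w <- Wg[r, ]
    aw <- as.numeric(cf$alpha %*% w)           # m
    Mx <- Xg %*% (tb * w)                      # nx x m
    counts <- rowSums(sweep(2 * Mx, 2, aw) > 0)
    mn <- min(counts)
    if (mn < best) best <- as.integer(mn)
    if (best == 0L) break
  }
  best
}

# Exhaustive arrangement-vertex enumeration in linearized coordinates.
# t = 1: z = x; t = 2: z = (w1, v1, v2) with w2 = 1 - w1, v_p = w_p x_p.
# Each pair i is satisfied iff lhs_i(z) >= 0 with
#   lhs_i = alpha_i . w - 2 beta_i . v   (linear in z).
.bf_vertex_min <- function(cf, t, x_bounds) {
  L <- x_bounds[1]; U <- x_bounds[2]
  m <- nrow(cf$alpha)
  tol <- 1e-9

  if (t == 1L) {
    # lhs_i = alpha_i - 2 beta_i x: tie points plus the box ends.
    ties <- ifelse(abs(cf$beta[, 1]) > tol,
                   cf$alpha[, 1] / (2 * cf$beta[, 1]), NA_real_)
    cand <- c(ties[!is.na(ties)], L, U)
    cand <- cand[cand >= L - tol & cand <= U + tol]
    counts <- vapply(cand, function(x) {
      sum(cf$alpha[, 1] - 2 * cf$beta[, 1] * x < -tol)
    }, numeric(1))
    return(as.integer(min(counts)))
  }

  # t == 2: planes a . z = b over z = (w1, v1, v2).
  # Pair i: (alpha_i1 - alpha_i2) w1 - 2 beta_i1 v1 - 2 beta_i2 v2
  #         = -alpha_i2.
  A <- rbind(
    cbind(cf$alpha[, 1] - cf$alpha[, 2], -2 * cf$beta[, 1],
          -2 * cf$beta[, 2]),
    c(1, 0, 0),    # w1 = 0
    c(1, 0, 0),    # w1 = 1
    c(-L, 1, 0),   # v1 = L w1
    c(-U, 1, 0),   # v1 = U w1
    c(L, 0, 1),    # v2 = L (1 - w1)
    c(U, 0, 1))    # v2 = U (1 - w1)
  b <- c(-cf$alpha[, 2], 0, 1, 0, 0, L, U)
  np <- nrow(A)

  lhs_counts <- function(z) {
    lhs <- A[seq_len(m), , drop = FALSE] %*% z - b[seq_len(m)]
    sum(lhs < -tol)
  }
  in_box <- function(z) {
    w1 <- z[1]
    w1 >= -tol && w1 <= 1 + tol &&
      z[2] >= L * w1 - tol && z[2] <= U * w1 + tol &&
      z[3] >= L * (1 - w1) - tol && z[3] <= U * (1 - w1) + tol
  }

  best <- m + 1L
  trips <- combn(np, 3)
  for (s in seq_len(ncol(trips))) {
    ii <- trips[, s]
    M3 <- A[ii, , drop = FALSE]
    z <- tryCatch(solve(M3, b[ii]), error = function(e) NULL)
    if (is.null(z) || !all(is.finite(z)) || !in_box(z)) next
    cnt <- lhs_counts(z)
    if (cnt < best) best <- as.integer(cnt)
    if (best == 0L) break
  }
  best
}
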