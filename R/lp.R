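#' @name lp_solve_eq
#' @title Dense bounded-variable simplex for small linear programs
#'
#' @description Solves `max/min c'x` subject to `A x = b` and
#' `lb <= x <= ub` with a two-phase primal simplex on bounded variables.
#' This is the LP kernel behind [fba()], [fva()] and [room()]; it is
#' written for the dense, modestly sized stoichiometric systems this
#' package produces (tens to a few hundred reactions), with Bland's rule
#' throughout so degenerate networks cannot cycle.
#'
#' @param A constraint matrix (m x n), rows are equalities.
#' @param b right-hand side, length m.
#' @param obj objective coefficients, length n.
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximise (default) or minimise.
#' @param tol pivoting/feasibility tolerance.
#' @param max_iter iteration cap per phase.
#'
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `x` (solution, length n) and `objective` (value of `obj' x`).
#' @keywords internal
NULL

# One simplex phase on the augmented system. `state` is an environment
# holding x, basis, nb_status (-1 at lb, +1 at ub, 2 free, 0 basic).
.simplex_phase <- function(A, cvec, lb, ub, state, tol, max_iter) {
  m <- nrow(A)
  n <- ncol(A)
  for (iter in seq_len(max_iter)) {
    B <- A[, state$basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cvec[state$basis]),
                  error = function(e) qr.solve(t(B), cvec[state$basis]))
    d <- cvec - as.numeric(crossprod(A, y))
    elig <- which((state$nb_status == -1L & d > tol) |
                  (state$nb_status == +1L & d < -tol) |
                  (state$nb_status == 2L & abs(d) > tol))
    if (length(elig) == 0L) return("optimal")
    j <- min(elig)                                    # Bland's rule
    t_dir <- if (state$nb_status[j] == 2L) sign(d[j]) else -state$nb_status[j]
    w <- tryCatch(solve(B, A[, j]), error = function(e) qr.solve(B, A[, j]))
    dB <- -t_dir * w
    # ratio test: how far can the entering variable move off its bound?
    step <- Inf
    leave <- 0L                                       # 0 = bound flip
    for (i in seq_len(m)) {
      bi <- state$basis[i]
      if (dB[i] > tol) {
        s <- (ub[bi] - state$x[bi]) / dB[i]
      } else if (dB[i] < -tol) {
        s <- (lb[bi] - state$x[bi]) / dB[i]
      } else next
      if (s < step - tol || (s < step + tol && (leave == 0L || bi < state$basis[leave]))) {
        step <- max(s, 0)
        leave <- i
      }
    }
    if (state$nb_status[j] != 2L) {
      flip <- ub[j] - lb[j]
      if (flip < step - tol) {
        step <- flip
        leave <- -1L                                  # entering flips bound
      }
    }
    if (!is.finite(step)) return("unbounded")
    state$x[state$basis] <- state$x[state$basis] + step * dB
    state$x[j] <- state$x[j] + t_dir * step
    if (leave == -1L) {
      state$nb_status[j] <- -state$nb_status[j]
      state$x[j] <- if (state$nb_status[j] == -1L) lb[j] else ub[j]
    } else {
      bi <- state$basis[leave]
      hit_upper <- dB[leave] > 0
      state$nb_status[bi] <- if (hit_upper) +1L else -1L
      state$x[bi] <- if (hit_upper) ub[bi] else lb[bi]
      state$basis[leave] <- j
      state$nb_status[j] <- 0L
    }
  }
  stop("simplex iteration limit reached (", max_iter, "); the problem may be numerically degenerate")
}

#' @rdname lp_solve_eq
#' @keywords internal
lp_solve_eq <- function(A, b, obj, lb, ub, maximize = TRUE,
                        tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("infeasible bounds: lb > ub")
  cvec <- if (maximize) obj else -obj
  if (m == 0L) {
    x <- ifelse(cvec > 0, ub, ifelse(cvec < 0, lb, ifelse(is.finite(lb), lb, 0)))
    if (any(!is.finite(x[cvec != 0]))) {
      return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
    }
    return(list(status = "optimal", x = x, objective = sum(obj * x)))
  }
  # start each structural variable at its smallest-magnitude finite bound
  x0 <- numeric(n)
  st0 <- integer(n)
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      if (abs(lb[j]) <= abs(ub[j])) { x0[j] <- lb[j]; st0[j] <- -1L }
      else                          { x0[j] <- ub[j]; st0[j] <- +1L }
    } else if (is.finite(lb[j])) { x0[j] <- lb[j]; st0[j] <- -1L }
    else if (is.finite(ub[j]))   { x0[j] <- ub[j]; st0[j] <- +1L }
    else                         { x0[j] <- 0;     st0[j] <- 2L }
  }
  r <- b - as.numeric(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Aaug <- cbind(A, diag(sgn, nrow = m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  state <- new.env(parent = emptyenv())
  state$x <- c(x0, abs(r))
  state$basis <- n + seq_len(m)
  state$nb_status <- c(st0, rep(0L, m))
  scale <- max(1, abs(b))
  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  s1 <- .simplex_phase(Aaug, c1, lba, uba, state, tol, max_iter)
  art_sum <- sum(state$x[n + seq_len(m)])
  if (s1 != "optimal" || art_sum > 1e-7 * scale) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  uba[n + seq_len(m)] <- 0                 # pin artificials
  state$x[n + seq_len(m)][state$nb_status[n + seq_len(m)] != 0L] <- 0
  c2 <- c(cvec, rep(0, m))
  s2 <- .simplex_phase(Aaug, c2, lba, uba, state, tol, max_iter)
  if (s2 == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }
  x <- state$x[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(obj * x))
}

# Convenience wrapper adding inequality rows `A_ub x <= b_ub` via slack
# variables on top of the equality kernel.
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  A_eq <- if (is.null(A_eq)) matrix(0, 0, n) else as.matrix(A_eq)
  b_eq <- if (is.null(b_eq)) numeric(0) else b_eq
  if (is.null(A_ub)) {
    res <- lp_solve_eq(A_eq, b_eq, obj, lb, ub, maximize = maximize, tol = tol)
    return(res)
  }
  A_ub <- as.matrix(A_ub)
  k <- nrow(A_ub)
  A <- rbind(cbind(A_eq, matrix(0, nrow(A_eq), k)),
             cbind(A_ub, diag(k)))
  res <- lp_solve_eq(A, c(b_eq, b_ub), c(obj, rep(0, k)),
                     c(lb, rep(0, k)), c(ub, rep(Inf, k)),
                     maximize = maximize, tol = tol)
  res$x <- res$x[seq_len(n)]
  res
}
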