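# Analytic solution of the per-well Euler-Lagrange boundary problem
#   d^2X/dt^2 = H^2 (X - X_ref),  X(0) = X_ref, X(t_s) = X_ts
# whose solution is X(t) = X_ref + f(H, t) (X_ts - X_ref) with the
# sinh-ratio spectral function f, plus the transition-state search joining the
# two wells with continuous position, velocity and energy.

#' Sinh-ratio propagator, scalar form
#'
#' `f(x, t) = sinh(x t) / sinh(x t_s)`, evaluated overflow-safely as
#' `exp(x (t - t_s)) * expm1(-2 x t) / expm1(-2 x t_s)` with the rigid-body
#' limit `t / t_s` as `x -> 0`. Monotone nondecreasing in t, f(x,0)=0,
#' f(x,t_s)=1.
#'
#' @param x Eigenvalue(s), >= 0 (vectorized).
#' @param t Time in `[0, t_s]`.
#' @param t_s Half-path duration (> 0).
#' @return Propagator value(s).
#' @export
f_scalar <- function(x, t, t_s) {
  if (t_s <= 0) stop("t_s must be positive")
  if (t < -1e-12 || t > t_s * (1 + 1e-12))
    stop("t = ", t, " outside [0, ", t_s, "]")
  t <- min(max(t, 0), t_s)
  x <- pmax(x, 0)
  small <- x * t_s < 1e-12
  out <- numeric(length(x))
  out[small] <- t / t_s
  xs <- x[!small]
  out[!small] <- exp(xs * (t - t_s)) * expm1(-2 * xs * t) / expm1(-2 * xs * t_s)
  out
}

#' Boundary velocity factor, scalar form
#'
#' `x * coth(x t_s)`: the time derivative of the sinh-ratio propagator at
#' `t = t_s`. Limit `1 / t_s` as `x -> 0`; asymptotically `x` for large
#' `x t_s`. Defines the positive-definite matrix function
#' `M = H coth(H t_s)` of the velocity-continuity system.
#'
#' @inheritParams f_scalar
#' @return Value(s) >= `1 / t_s`.
#' @export
vel_scalar <- function(x, t_s) {
  if (t_s <= 0) stop("t_s must be positive")
  x <- pmax(x, 0)
  y <- x * t_s
  small <- y < 1e-6
  out <- numeric(length(x))
  # coth(y) ~ 1/y + y/3 for small y
  out[small] <- 1 / t_s + x[small] * y[small] / 3
  xs <- x[!small]; ys <- y[!small]
  out[!small] <- xs * (1 + exp(-2 * ys)) / (-expm1(-2 * ys))
  out
}

# ---- spectral backends -------------------------------------------------------

dense_eigen <- function(H) {
  if (is.null(H$cache$eig)) {
    if (is.null(H$dense))
      stop("dense backend requested but Hessian has no dense materialization")
    e <- eigen(H$dense, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1))
      stop("Hessian has a significantly negative eigenvalue (",
           format(min(e$values)), "): not a PSD reference-state Hessian")
    e$values <- pmax(e$values, 0)
    H$cache$eig <- e
  }
  H$cache$eig
}

# Lanczos tridiagonalization with full reorthogonalization.
lanczos_basis <- function(matvec, v, m) {
  n <- length(v)
  beta0 <- sqrt(sum(v^2))
  V <- matrix(0, n, m)
  alpha <- numeric(m); beta <- numeric(m)
  V[, 1] <- v / beta0
  breakdown <- m
  for (k in seq_len(m)) {
    w <- matvec(V[, k])
    alpha[k] <- sum(w * V[, k])
    w <- w - alpha[k] * V[, k]
    if (k > 1) w <- w - beta[k - 1] * V[, k - 1]
    # full reorthogonalization (twice is enough)
    w <- w - V[, 1:k, drop = FALSE] %*% crossprod(V[, 1:k, drop = FALSE], w)
    w <- as.numeric(w)
    beta[k] <- sqrt(sum(w^2))
    if (beta[k] < 1e-13 * max(abs(alpha[1]), 1)) { breakdown <- k; break }
    if (k < m) V[, k + 1] <- w / beta[k]
  }
  m_eff <- min(breakdown, m)
  list(V = V[, seq_len(m_eff), drop = FALSE],
       alpha = alpha[seq_len(m_eff)],
       beta = beta[seq_len(m_eff)], beta0 = beta0, m = m_eff,
       exhausted = breakdown < m)
}

# f(A) v from a Lanczos factorization: ||v|| V_m f(T_m) e_1, with T_m
# diagonalized (tiny symmetric tridiagonal).
lanczos_apply <- function(lz, fn) {
  m <- lz$m
  Tm <- diag(lz$alpha, m, m)
  if (m > 1) {
    idx <- seq_len(m - 1)
    Tm[cbind(idx, idx + 1)] <- lz$beta[idx]
    Tm[cbind(idx + 1, idx)] <- lz$beta[idx]
  }
  e <- eigen(Tm, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  w <- e$vectors %*% (fn(vals) * e$vectors[1, ])
  as.numeric(lz$beta0 * (lz$V %*% w))
}

#' Apply a spectral matrix function to a vector
#'
#' Computes `f(H) v` for a symmetric PSD Hessian operator. The dense backend
#' uses a cached eigendecomposition (`P f(D) P^T v`); the Krylov backend builds
#' a Lanczos basis of span{v, Hv, ...} with full reorthogonalization and
#' evaluates `||v|| V_m f(T_m) e_1`, growing the order m adaptively until two
#' successive iterates agree.
#'
#' @param H A `hessian_operator`.
#' @param fn Scalar function, vectorized over eigenvalues (>= 0).
#' @param v Vector of length `H$n`.
#' @param backend `"auto"`, `"dense"` or `"krylov"`. `"auto"` picks dense when
#'   a dense materialization exists.
#' @param m_max Maximum Krylov order (default 100).
#' @param tol Convergence tolerance on the iterate difference (relative).
#' @return The vector `f(H) v`.
#' @export
apply_matrix_function <- function(H, fn, v, backend = "auto",
                                  m_max = 100, tol = 1e-8) {
  backend <- match.arg(backend, c("auto", "dense", "krylov"))
  if (backend == "auto") backend <- if (!is.null(H$dense)) "dense" else "krylov"
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(numeric(length(v)))
  if (backend == "dense") {
    e <- dense_eigen(H)
    return(as.numeric(e$vectors %*% (fn(e$values) * crossprod(e$vectors, v))))
  }
  prev <- NULL
  m <- min(10, length(v))
  repeat {
    lz <- lanczos_basis(H$matvec, v, m)
    out <- lanczos_apply(lz, fn)
    if (lz$exhausted || lz$m >= length(v)) return(out)
    if (!is.null(prev)) {
      if (sqrt(sum((out - prev)^2)) <= tol * max(sqrt(sum(out^2)), 1e-300))
        return(out)
    }
    if (m >= m_max) {
      warning("Krylov evaluation did not converge at m = ", m_max,
              " (last change ",
              format(sqrt(sum((out - prev)^2))), ")")
      return(out)
    }
    prev <- out
    m <- min(m + 10, m_max, length(v))
  }
}

#' Analytic half-path trajectory
#'
#' Frames of one well's boundary-value solution:
#' `X(t) = X_ref + f(H, t)(X_ts - X_ref)` with the sinh-ratio propagator.
#' `X(0) = X_ref` exactly; `X(t_s) = X_ts` to backend tolerance.
#'
#' @param X_ref Well reference coordinates (3N vector).
#' @param H The well's `hessian_operator`.
#' @param X_ts Boundary (transition-state) coordinates (3N vector).
#' @param t_s Half duration (> 0).
#' @param times Evaluation times within `[0, t_s]`.
#' @param backend,m_max,tol Passed to [apply_matrix_function()].
#' @return Matrix with one row per time, columns the 3N coordinates.
#' @export
half_trajectory <- function(X_ref, H, X_ts, t_s, times, backend = "auto",
                            m_max = 100, tol = 1e-8) {
  v <- X_ts - X_ref
  out <- matrix(0, length(times), length(X_ref))
  backend <- match.arg(backend, c("auto", "dense", "krylov"))
  if (backend == "auto") backend <- if (!is.null(H$dense)) "dense" else "krylov"
  if (backend == "dense" || sqrt(sum(v^2)) == 0) {
    for (q in seq_along(times)) {
      out[q, ] <- if (times[q] == 0) X_ref else
        X_ref + apply_matrix_function(H, function(x) f_scalar(x, times[q], t_s),
                                      v, backend = backend,
                                      m_max = m_max, tol = tol)
    }
    return(out)
  }
  # Krylov: one basis of v serves every time; grow m until all frames settle.
  m <- min(10, length(v))
  prev <- NULL
  repeat {
    lz <- lanczos_basis(H$matvec, v, m)
    frames <- vapply(times, function(tt) {
      if (tt == 0) numeric(length(v)) else
        lanczos_apply(lz, function(x) f_scalar(x, tt, t_s))
    }, numeric(length(v)))
    frames <- t(frames)
    done <- lz$exhausted || lz$m >= length(v) ||
      (!is.null(prev) &&
         max(sqrt(rowSums((frames - prev)^2))) <=
           tol * max(sqrt(sum(v^2)), 1e-300))
    if (done || m >= m_max) {
      if (!done && m >= m_max)
        warning("half_trajectory: Krylov order capped at m = ", m_max)
      for (q in seq_along(times)) out[q, ] <- X_ref + frames[q, ]
      return(out)
    }
    prev <- frames
    m <- min(m + 10, m_max, length(v))
  }
}

# Quadratic well energy U(X) = 1/2 (X - X_ref)^T H (X - X_ref).
quad_energy <- function(H, X_ref, x) {
  d <- x - X_ref
  0.5 * sum(d * H$matvec(d))
}

# Matrix-free conjugate gradients for the SPD velocity-continuity system.
# Stops on the relative residual, or when rounding stalls further progress;
# errors only if the iteration stalls far from the solution.
cg_solve <- function(matvec, b, x0 = NULL, tol = 1e-13, maxit = 2000) {
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - matvec(x)
  p <- r
  rs <- sum(r * r)
  nb <- max(sqrt(sum(b * b)), 1e-300)
  it <- 0; stall <- 0; best_rs <- rs
  while (sqrt(rs) > tol * nb && it < maxit) {
    Ap <- matvec(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) break  # numerically exhausted search direction
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1
    if (rs < 0.99 * best_rs) { best_rs <- rs; stall <- 0 } else stall <- stall + 1
    if (stall >= 50) break  # rounding floor reached
  }
  rel <- sqrt(rs) / nb
  if (rel > 1e-6)
    stop("conjugate gradients did not converge: relative residual ",
         format(rel), " after ", it, " iterations")
  list(x = x, iterations = it, residual = rel)
}

#' Solve for the transition state between two quadratic wells
#'
#' For a trial time split `(t_A, t_B = F - t_A)` the transition point is the
#' solution of the velocity-continuity linear system
#' `(M_A + M_B) X_ts = M_A X_A + M_B X_B` with `M = H coth(H t)`, solved by
#' matrix-free conjugate gradients (position continuity is automatic: both
#' half-paths end at X_ts). An outer bisection on `t_A` drives the
#' energy-continuity residual `U_B(X_ts) - U_A(X_ts) - dE` to zero.
#'
#' @param X_A,X_B Endpoint coordinates (3N vectors, common atoms, superposed).
#' @param H_A,H_B The wells' `hessian_operator`s.
#' @param total_time Total path duration F (> 0).
#' @param dE Free-energy offset of well A relative to well B (kcal/mol): the
#'   surface is `min(U_A + dE, U_B)`.
#' @param backend Matrix-function backend for both wells.
#' @param tol_E Energy-gap tolerance; default `1e-4 * max(U_A(X_B), U_B(X_A))`.
#' @param tol_v Relative velocity-gap tolerance (default 1e-4, checked and
#'   reported).
#' @param max_outer Maximum bisection iterations (default 60).
#' @param m_max,krylov_tol Krylov controls, see [apply_matrix_function()].
#' @return A `transition_result`: `X_ts`, `t_A`, `t_B`, residuals
#'   (`energy_gap`, `velocity_gap`), energies of the transition state in each
#'   well, iteration counts and the outer-iteration trace.
#' @export
solve_transition <- function(X_A, H_A, X_B, H_B, total_time = 1, dE = 0,
                             backend = "auto", tol_E = NULL, tol_v = 1e-4,
                             max_outer = 60, m_max = 100, krylov_tol = 1e-8) {
  stopifnot(length(X_A) == length(X_B), total_time > 0)
  UA_at_B <- quad_energy(H_A, X_A, X_B)
  UB_at_A <- quad_energy(H_B, X_B, X_A)
  scale_E <- max(UA_at_B, UB_at_A)
  if (is.null(tol_E)) tol_E <- 1e-4 * max(scale_E, 1e-12)
  mfun <- function(H, t, v) apply_matrix_function(
    H, function(x) vel_scalar(x, t), v, backend = backend,
    m_max = m_max, tol = krylov_tol)

  trace <- list()
  x_warm <- (X_A + X_B) / 2
  solve_at <- function(t_A) {
    t_B <- total_time - t_A
    rhs <- mfun(H_A, t_A, X_A) + mfun(H_B, t_B, X_B)
    cg <- cg_solve(function(v) mfun(H_A, t_A, v) + mfun(H_B, t_B, v),
                   rhs, x0 = x_warm)
    x_warm <<- cg$x
    X_ts <- cg$x
    g <- quad_energy(H_B, X_B, X_ts) - quad_energy(H_A, X_A, X_ts) - dE
    vA <- mfun(H_A, t_A, X_ts - X_A)
    vB <- -mfun(H_B, t_B, X_ts - X_B)
    vgap <- sqrt(sum((vA - vB)^2)) /
      max(sqrt(sum(vA^2)), sqrt(sum(vB^2)), 1e-300)
    list(X_ts = X_ts, g = g, vgap = vgap, cg_iter = cg$iterations)
  }

  lo <- 0.02 * total_time
  hi <- total_time - lo  # symmetric bracket: lo + hi == total_time exactly
  s_lo <- solve_at(lo); s_hi <- solve_at(hi)
  if (sign(s_lo$g) == sign(s_hi$g) && abs(s_lo$g) > tol_E && abs(s_hi$g) > tol_E)
    stop("energy-continuity residual has no sign change on the time bracket: ",
         "g(", format(lo), ") = ", format(s_lo$g), ", g(", format(hi), ") = ",
         format(s_hi$g), "; the free-energy offset dE = ", dE,
         " admits no well crossing at total time ", total_time)
  best <- NULL; t_best <- NA
  n_outer <- 0
  for (it in seq_len(max_outer)) {
    mid <- (lo + hi) / 2
    s <- solve_at(mid)
    n_outer <- it
    trace[[it]] <- data.frame(iter = it, t_A = mid, energy_gap = s$g,
                              cg_iterations = s$cg_iter,
                              velocity_gap = s$vgap)
    best <- s; t_best <- mid
    if (abs(s$g) <= tol_E) break
    if (sign(s$g) == sign(s_lo$g)) { lo <- mid; s_lo <- s } else { hi <- mid; s_hi <- s }
  }
  res <- list(X_ts = best$X_ts, t_A = t_best, t_B = total_time - t_best,
              total_time = total_time, dE = dE,
              energy_gap = best$g, velocity_gap = best$vgap,
              U_A = quad_energy(H_A, X_A, best$X_ts) + dE,
              U_B = quad_energy(H_B, X_B, best$X_ts),
              cg_iterations = best$cg_iter, outer_iterations = n_outer,
              tol_E = tol_E, tol_v = tol_v,
              trace = do.call(rbind, trace))
  class(res) <- "transition_result"
  if (abs(res$energy_gap) > tol_E)
    warning("energy continuity residual ", format(res$energy_gap),
            " above tolerance ", format(tol_E))
  if (res$velocity_gap > tol_v)
    warning("velocity continuity residual ", format(res$velocity_gap),
            " above tolerance ", format(tol_v))
  res
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("transition_result: t_A = %.6g of F = %g, outer iterations %d\n",
              x$t_A, x$total_time, x$outer_iterations))
  cat(sprintf("  U_A(X_ts)+dE = %.6g, U_B(X_ts) = %.6g kcal/mol\n", x$U_A, x$U_B))
  cat(sprintf("  residuals: energy %.3g, velocity %.3g\n",
              x$energy_gap, x$velocity_gap))
  invisible(x)
}

#' Generate a full minimum-action path
#'
#' Solves the transition state, then evaluates both analytic half-paths on a
#' uniform time grid over `[0, F]`. The grid always contains t = 0 and t = F;
#' for three or more frames the interior grid point nearest the transition
#' time is replaced by it, so the transition state is always a frame. The first
#' and last frames are the endpoints exactly. Per-frame energy is the two-well
#' surface `min(U_A + dE, U_B)`.
#'
#' @inheritParams solve_transition
#' @param n_frames Number of frames (>= 2, default 50).
#' @return A `map_trajectory`: `times`, `frames` (n_frames x 3N), per-frame
#'   `energy`, the `transition` result and the frame index of the transition
#'   state.
#' @export
generate_path <- function(X_A, H_A, X_B, H_B, total_time = 1, dE = 0,
                          n_frames = 50, backend = "auto", tol_E = NULL,
                          tol_v = 1e-4, m_max = 100, krylov_tol = 1e-8) {
  if (n_frames < 2) stop("n_frames must be at least 2")
  # endpoints identical to superposition rounding: constant path
  if (sqrt(sum((X_A - X_B)^2) / (length(X_A) / 3)) < 1e-9) {
    tr <- list(X_ts = X_A, t_A = total_time / 2, t_B = total_time / 2,
               total_time = total_time, dE = dE, energy_gap = 0,
               velocity_gap = 0, U_A = dE, U_B = 0, cg_iterations = 0,
               outer_iterations = 0, trace = NULL)
    class(tr) <- "transition_result"
    X_B <- X_A  # frames replicate the start endpoint exactly
  } else {
    tr <- solve_transition(X_A, H_A, X_B, H_B, total_time = total_time,
                           dE = dE, backend = backend, tol_E = tol_E,
                           tol_v = tol_v, m_max = m_max,
                           krylov_tol = krylov_tol)
  }
  times <- seq(0, total_time, length.out = n_frames)
  ts_idx <- NA_integer_
  if (n_frames >= 3) {
    interior <- 2:(n_frames - 1)
    ts_idx <- interior[which.min(abs(times[interior] - tr$t_A))]
    times[ts_idx] <- tr$t_A
  }
  frames <- matrix(0, n_frames, length(X_A))
  selA <- times <= tr$t_A
  if (any(selA))
    frames[selA, ] <- half_trajectory(X_A, H_A, tr$X_ts, tr$t_A,
                                      times[selA], backend = backend,
                                      m_max = m_max, tol = krylov_tol)
  if (any(!selA))
    frames[!selA, ] <- half_trajectory(X_B, H_B, tr$X_ts, tr$t_B,
                                       tr$total_time - times[!selA],
                                       backend = backend,
                                       m_max = m_max, tol = krylov_tol)
  frames[1, ] <- X_A
  frames[n_frames, ] <- X_B
  energy <- vapply(seq_len(n_frames), function(q)
    min(quad_energy(H_A, X_A, frames[q, ]) + dE,
        quad_energy(H_B, X_B, frames[q, ])), numeric(1))
  structure(list(times = times, frames = frames, energy = energy,
                 transition = tr, transition_index = ts_idx,
                 X_A = X_A, X_B = X_B),
            class = "map_trajectory")
}

#' @export
print.map_trajectory <- function(x, ...) {
  cat(sprintf("map_trajectory: %d frames over [0, %g], transition at t_A = %.6g (frame %s)\n",
              nrow(x$frames), max(x$times), x$transition$t_A,
              ifelse(is.na(x$transition_index), "-", x$transition_index)))
  invisible(x)
}
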