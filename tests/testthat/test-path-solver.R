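# Scalar propagators, matrix functions, half-trajectories and the
# transition-state search.

f_scalar_vec <- function(x, t, t_s) f_scalar(x, t, t_s)
quad_energy_pub <- function(H, ref, x) 0.5 * sum((x - ref) * H$matvec(x - ref))

test_that("sinh-ratio propagator has exact boundaries, zero-mode limit and large-x safety", {
  for (x in c(0, 0.5, 3, 50, 700, 5000)) {
    expect_equal(f_scalar(x, 0, 1), 0)
    expect_equal(f_scalar(x, 1, 1), 1)
  }
  expect_equal(f_scalar(0, 0.3, 1.5), 0.2)
  # direct sinh ratio within double range as oracle
  expect_equal(f_scalar(700, 0.5, 1.0), sinh(700 * 0.5) / sinh(700),
               tolerance = 1e-12)
  expect_equal(f_scalar(12, 0.7, 1.3), sinh(12 * 0.7) / sinh(12 * 1.3),
               tolerance = 1e-12)
  # finite where naive sinh overflows; monotone in t
  expect_true(is.finite(f_scalar(5000, 0.5, 1)))
  ts <- seq(0, 1, by = 0.05)
  vals <- vapply(ts, function(t) f_scalar(8, t, 1), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(f_scalar(1, 2, 1), "outside")
})

test_that("boundary velocity factor matches its limits and the propagator derivative", {
  expect_equal(vel_scalar(0, 2), 0.5)
  expect_equal(vel_scalar(1e-9, 2), 0.5, tolerance = 1e-9)
  # x coth(x t) -> x for large x t
  expect_equal(vel_scalar(500, 1), 500, tolerance = 1e-10)
  set.seed(51)
  for (x in runif(5, 0.1, 10)) {
    h <- 1e-6
    dfd <- (f_scalar(x, 1, 1) - f_scalar(x, 1 - h, 1)) / h
    expect_equal(vel_scalar(x, 1), dfd, tolerance = 1e-4)
  }
  expect_gte(min(vel_scalar(seq(0, 20, 0.5), 0.7)), 1 / 0.7)
  expect_error(vel_scalar(1, 0), "positive")
})

test_that("matrix functions: eigenvector exactness, full-space exactness, dense oracle", {
  tn <- toy_net(10, seed = 52)
  e <- eigen(tn$H$dense, symmetric = TRUE)
  # exact eigenvector: one Krylov step suffices
  v <- e$vectors[, 3]
  lam <- e$values[3]
  fn <- function(x) f_scalar_vec(x, 0.4, 1)
  out <- apply_matrix_function(tn$H, fn, v, backend = "krylov")
  expect_equal(out, fn(lam) * v, tolerance = 1e-9)
  # full space: krylov equals dense to near machine precision
  set.seed(53)
  w <- rnorm(30)
  d1 <- apply_matrix_function(tn$H, fn, w, backend = "dense")
  d2 <- apply_matrix_function(tn$H, fn, w, backend = "krylov", m_max = 30)
  expect_lt(sqrt(sum((d1 - d2)^2)) / sqrt(sum(d1^2)), 1e-10)
  expect_equal(apply_matrix_function(tn$H, fn, rep(0, 30)), rep(0, 30))
})

test_that("Krylov matches the dense backend on a 100-atom network at truncated order", {
  tn <- toy_net(100, seed = 54, k = 0.5, cutoff = 12, box = 25)
  set.seed(55)
  v <- rnorm(300)
  fn <- function(x) f_scalar_vec(x, 0.3, 1)
  d1 <- apply_matrix_function(tn$H, fn, v, backend = "dense")
  d2 <- apply_matrix_function(tn$H, fn, v, backend = "krylov", m_max = 60,
                              tol = 1e-10)
  expect_lt(sqrt(sum((d1 - d2)^2)) / sqrt(sum(d1^2)), 1e-8)
})

test_that("Lanczos factorization satisfies the three-term recurrence", {
  tn <- toy_net(20, seed = 56)
  set.seed(57)
  v <- rnorm(60)
  lz <- actionpath:::lanczos_basis(tn$H$matvec, v, 15)
  m <- lz$m
  Tm <- diag(lz$alpha, m, m)
  if (m > 1) {
    idx <- seq_len(m - 1)
    Tm[cbind(idx, idx + 1)] <- lz$beta[idx]
    Tm[cbind(idx + 1, idx)] <- lz$beta[idx]
  }
  AV <- apply(lz$V, 2, tn$H$matvec)
  resid <- AV - lz$V %*% Tm
  # A V_m = V_m T_m + beta_m v_{m+1} e_m^T: all but the last column vanish
  expect_lt(max(abs(resid[, -m])), 1e-8)
  expect_equal(sqrt(sum(resid[, m]^2)), lz$beta[m], tolerance = 1e-8)
  expect_equal(crossprod(lz$V), diag(m), tolerance = 1e-10)
})

test_that("half-trajectory: constant, free-particle and boundary-exactness cases", {
  tn <- toy_net(8, seed = 58)
  x0 <- vec3(tn$xyz)
  # X_ts = X_ref: constant trajectory
  fr <- half_trajectory(x0, tn$H, x0, 1, c(0, 0.4, 1))
  expect_equal(fr, matrix(rep(x0, 3), 3, byrow = TRUE))
  # free particle (H = 0): straight-line interpolation
  H0 <- actionpath:::make_hessian_operator(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(24, 24)))
  set.seed(59)
  xts <- x0 + rnorm(24)
  fr0 <- half_trajectory(x0, H0, xts, 2, c(0, 0.5, 1, 2))
  expect_equal(fr0[2, ], x0 + 0.25 * (xts - x0), tolerance = 1e-12)
  expect_equal(fr0[3, ], x0 + 0.5 * (xts - x0), tolerance = 1e-12)
  expect_equal(fr0[4, ], xts, tolerance = 1e-12)
  # boundary exactness on a real well
  frb <- half_trajectory(x0, tn$H, xts, 1, c(0, 1))
  expect_equal(frb[1, ], x0)
  expect_equal(frb[2, ], xts, tolerance = 1e-9)
})

test_that("analytic half-trajectory matches direct numerical integration of the equations of motion", {
  tn <- toy_net(5, seed = 60, k = 1, cutoff = 20)
  x0 <- vec3(tn$xyz)
  set.seed(61)
  xts <- x0 + rnorm(15, sd = 0.8)
  times <- seq(0, 1, length.out = 6)  # nodes of the oracle grid
  analytic <- half_trajectory(x0, tn$H, xts, 1, times)
  oracle <- bvp_half_trajectory(x0, tn$H$dense, xts, 1, times, m = 400)
  rms <- sqrt(mean((analytic - oracle)^2))
  expect_lt(rms, 1e-6)
})

test_that("identical wells with zero offset give the exact midpoint transition", {
  tn <- toy_net(10, seed = 62)
  x0 <- vec3(tn$xyz)
  set.seed(63)
  shift <- rnorm(15, sd = 2)
  xB <- x0
  xB[1:15] <- xB[1:15] + shift  # deform part of the system
  tr <- solve_transition(x0, tn$H, xB, tn$H, total_time = 1, dE = 0)
  expect_equal(tr$t_A, 0.5, tolerance = 1e-10)
  expect_equal(tr$X_ts, (x0 + xB) / 2, tolerance = 1e-10)
  expect_lt(abs(tr$energy_gap), 1e-10)
})

test_that("asymmetric wells: continuity residuals small, transition shifts toward the stiff well", {
  tp <- toy_asym_pair(5, seed = 64, kA = 5, kB = 1, scale = 1.12, cutoff = 25)
  tr <- solve_transition(tp$xA, tp$HA, tp$xB, tp$HB, total_time = 1, dE = 0)
  expect_lt(abs(tr$energy_gap) /
              max(quad_energy_pub(tp$HA, tp$xA, tp$xB),
                  quad_energy_pub(tp$HB, tp$xB, tp$xA)),
            1e-4)
  expect_lt(tr$velocity_gap, 1e-4)
  # stiff start well (k1 = 5 k2): the crossing point lies closer to X_A
  expect_lt(rmsd(tp$xA, tr$X_ts), rmsd(tp$xB, tr$X_ts))
})

test_that("transition state agrees with direct minimization of the continuity violations", {
  tp <- toy_asym_pair(5, seed = 65, kA = 5, kB = 1, scale = 1.1, cutoff = 25)
  xA <- tp$xA; xB <- tp$xB; HA <- tp$HA; HB <- tp$HB
  tr <- solve_transition(xA, HA, xB, HB, total_time = 1, dE = 0)
  # oracle: minimize squared velocity + energy continuity violations over
  # (X_ts, t_A) with generic numerical optimization
  obj <- function(p) {
    tA <- p[1]
    if (tA <= 0.01 || tA >= 0.99) return(1e10)
    xts <- p[-1]
    vA <- apply_matrix_function(HA, function(x) vel_scalar(x, tA),
                                xts - xA, backend = "dense")
    vB <- -apply_matrix_function(HB, function(x) vel_scalar(x, 1 - tA),
                                 xts - xB, backend = "dense")
    dU <- quad_energy_pub(HB, xB, xts) - quad_energy_pub(HA, xA, xts)
    sum((vA - vB)^2) + dU^2
  }
  opt <- optim(c(0.5, (xA + xB) / 2), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(sqrt(mean((opt$par[-1] - tr$X_ts)^2)), 1e-3)
  expect_lt(abs(opt$par[1] - tr$t_A), 1e-3)
})

test_that("impossible energy offset raises a no-crossing error", {
  tp <- toy_asym_pair(6, seed = 66, scale = 1.05)
  expect_error(solve_transition(tp$xA, tp$HA, tp$xB, tp$HB, dE = 1e6),
               "no well crossing|sign change")
})

test_that("generated paths hit the endpoints exactly and peak at the transition frame", {
  hp <- make_dumbbell_pair(seed = 67)
  pp <- prepare_pair(hp)
  traj <- generate_path(pp$vA, pp$HA, pp$vB, pp$HB, n_frames = 21)
  expect_identical(traj$frames[1, ], pp$vA)
  expect_identical(traj$frames[21, ], pp$vB)
  expect_equal(traj$times[traj$transition_index], traj$transition$t_A)
  expect_equal(which.max(traj$energy), traj$transition_index)
  # n_frames = 2: exactly the endpoints
  t2 <- generate_path(pp$vA, pp$HA, pp$vB, pp$HB, n_frames = 2)
  expect_equal(nrow(t2$frames), 2)
  expect_identical(t2$frames[1, ], pp$vA)
  expect_identical(t2$frames[2, ], pp$vB)
  # identical endpoints: constant path at zero energy
  tid <- generate_path(pp$vA, pp$HA, pp$vA, pp$HA, n_frames = 5)
  expect_true(all(tid$energy == 0))
  expect_equal(max(abs(sweep(tid$frames, 2, pp$vA))), 0)
})

test_that("time reversal: swapping wells and negating the offset reverses the path", {
  tp <- toy_asym_pair(8, seed = 68, kA = 2, kB = 1, scale = 1.08)
  xA <- tp$xA; xB <- tp$xB
  fw <- generate_path(xA, tp$HA, xB, tp$HB, dE = 0.3, n_frames = 15)
  bw <- generate_path(xB, tp$HB, xA, tp$HA, dE = -0.3, n_frames = 15)
  expect_equal(fw$transition$t_A, 1 - bw$transition$t_A, tolerance = 1e-6)
  expect_equal(fw$transition$X_ts, bw$transition$X_ts, tolerance = 1e-6)
})



test_that("full dense and Krylov paths agree on a medium system", {
  hp <- make_dumbbell_pair(n_per_lobe = 40, seed = 69)
  pp <- prepare_pair(hp)
  times <- seq(0, 0.45, length.out = 5)
  trd <- solve_transition(pp$vA, pp$HA, pp$vB, pp$HB, backend = "dense")
  fd <- half_trajectory(pp$vA, pp$HA, trd$X_ts, trd$t_A, times,
                        backend = "dense")
  fk <- half_trajectory(pp$vA, pp$HA, trd$X_ts, trd$t_A, times,
                        backend = "krylov", tol = 1e-12)
  expect_lt(sqrt(mean((fd - fk)^2)), 1e-6)
})
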