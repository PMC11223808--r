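# Per-frame quantitative analysis of a generated path: energy, RMSD to both
# endpoints, native-contact fractions Q1/Q2, and the Onsager-Machlup action of
# the discretized trajectory.

#' Root-mean-square deviation between paired coordinate sets
#'
#' @param X,Y Paired coordinates (N x 3 matrices or 3N vectors).
#' @param fit Superpose `Y` onto `X` by least squares first (default `FALSE`:
#'   endpoints are already in a common frame, and per-frame refitting would
#'   hide rigid drift).
#' @return RMSD in angstrom.
#' @export
rmsd <- function(X, Y, fit = FALSE) {
  Xm <- if (is.null(dim(X))) as_mat3(X) else as.matrix(X)
  Ym <- if (is.null(dim(Y))) as_mat3(Y) else as.matrix(Y)
  if (!all(dim(Xm) == dim(Ym))) stop("rmsd: dimension mismatch")
  if (nrow(Xm) < 1) stop("rmsd: empty coordinates")
  if (fit) {
    f <- superpose(Xm, Ym)
    Ym <- sweep(Ym %*% t(f$rotation), 2, f$translation, "+")
  }
  sqrt(sum((Xm - Ym)^2) / nrow(Xm))
}

#' Fraction of native contacts present in a frame
#'
#' A reference contact (i, j) with native distance r0 counts as present when
#' the frame distance satisfies `r <= lambda * r0`. Q1 uses the start
#' structure's contact set, Q2 the target's; both equal 1 at their own
#' reference.
#'
#' @param x Frame coordinates (3N vector or N x 3 matrix).
#' @param contacts List or `elastic_network` carrying `i`, `j`, `r0`.
#' @param lambda Tolerance factor (default 1.2).
#' @return Fraction in `[0, 1]`.
#' @export
q_fraction <- function(x, contacts, lambda = 1.2) {
  if (length(contacts$i) == 0)
    stop("q_fraction: empty contact list, Q is undefined")
  r <- edge_lengths(as_vec3(x), contacts$i, contacts$j)
  mean(r <= lambda * contacts$r0)
}

#' Onsager-Machlup action of a discretized trajectory
#'
#' `S = 1/2 integral (dX/dt + grad U(X))^2 dt` by trapezoidal quadrature, with
#' dX/dt from central differences (one-sided at the ends) and the gradient
#' taken from the active well of the two-well surface `min(U_A + dE, U_B)`.
#' Diagnostic only: reported, never optimized.
#'
#' @param traj A `map_trajectory` (or list with `times` and `frames`).
#' @param H_A,H_B Well `hessian_operator`s.
#' @param X_A,X_B Well reference coordinates; default from `traj`.
#' @param dE Free-energy offset (kcal/mol).
#' @return The action value.
#' @export
action_value <- function(traj, H_A, H_B, X_A = traj$X_A, X_B = traj$X_B,
                         dE = 0) {
  tt <- traj$times; fr <- traj$frames
  n <- length(tt)
  if (n < 3) stop("action_value: need at least 3 frames")
  integrand <- numeric(n)
  for (q in seq_len(n)) {
    x <- fr[q, ]
    v <- if (q == 1) (fr[2, ] - fr[1, ]) / (tt[2] - tt[1])
    else if (q == n) (fr[n, ] - fr[n - 1, ]) / (tt[n] - tt[n - 1])
    else (fr[q + 1, ] - fr[q - 1, ]) / (tt[q + 1] - tt[q - 1])
    uA <- quad_energy(H_A, X_A, x) + dE
    uB <- quad_energy(H_B, X_B, x)
    g <- if (uA <= uB) H_A$matvec(x - X_A) else H_B$matvec(x - X_B)
    integrand[q] <- sum((v + g)^2)
  }
  0.5 * sum(diff(tt) * (integrand[-n] + integrand[-1]) / 2)
}

#' Per-frame statistics of a trajectory
#'
#' @param traj A `map_trajectory`.
#' @param net_A,net_B Endpoint elastic networks (contact sets for Q1/Q2).
#' @param lambda Contact tolerance factor for Q (default 1.2).
#' @return Data frame with columns frame, time, energy, rmsd_A, rmsd_B, Q1,
#'   Q2.
#' @export
analyze_trajectory <- function(traj, net_A, net_B, lambda = 1.2) {
  n <- nrow(traj$frames)
  out <- data.frame(frame = seq_len(n), time = traj$times,
                    energy = traj$energy,
                    rmsd_A = NA_real_, rmsd_B = NA_real_,
                    Q1 = NA_real_, Q2 = NA_real_)
  for (q in seq_len(n)) {
    x <- traj$frames[q, ]
    out$rmsd_A[q] <- rmsd(traj$X_A, x)
    out$rmsd_B[q] <- rmsd(traj$X_B, x)
    out$Q1[q] <- q_fraction(x, net_A, lambda)
    out$Q2[q] <- q_fraction(x, net_B, lambda)
  }
  out
}

#' Write the per-frame report
#'
#' Tab-separated table (frame, time, energy, rmsd_A, rmsd_B, Q1, Q2), suitable
#' for Q1-versus-Q2 plots.
#'
#' @param stats Data frame from [analyze_trajectory()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_b <- function(b) if (is.na(b)) "unavailable" else sprintf("%.2f", b)
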