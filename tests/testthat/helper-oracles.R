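# Independent oracles and small builders shared across the suite. Every
# oracle here is written against the mathematical definition, not against the
# package's implementation path.

# Random compact point cloud (angstrom scale), fixed by seed.
random_cloud <- function(n, box = 30, seed = 1) {
  set.seed(seed)
  matrix(runif(3 * n, 0, box), n, 3)
}

# Small elastic network + Hessian on a random cloud.
toy_net <- function(n = 10, seed = 1, k = 1, cutoff = 14, box = 15) {
  xyz <- random_cloud(n, box = box, seed = seed)
  net <- build_cutoff_network(xyz, cutoff = cutoff, k = k)
  list(xyz = xyz, net = net, H = assemble_hessian(net))
}

# Asymmetric two-well toy: well B is a breathing (uniformly scaled)
# deformation of well A, so the A-to-B displacement is genuinely non-rigid and
# both quadratic wells see it.
toy_asym_pair <- function(n = 8, seed = 1, kA = 1, kB = 1, scale = 1.08,
                          cutoff = 20, box = 15) {
  xyzA <- random_cloud(n, box = box, seed = seed)
  ctr <- colMeans(xyzA)
  xyzB <- sweep(sweep(xyzA, 2, ctr) * scale, 2, ctr, "+")
  netA <- build_cutoff_network(xyzA, cutoff = cutoff, k = kA)
  netB <- build_cutoff_network(xyzB, cutoff = cutoff * scale, k = kB)
  list(xA = vec3(xyzA), xB = vec3(xyzB),
       netA = netA, netB = netB,
       HA = assemble_hessian(netA), HB = assemble_hessian(netB))
}

# --- quaternion (Horn) closed-form superposition oracle ----------------------
horn_superpose_rmsd <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  A <- sweep(X, 2, cx); B <- sweep(Y, 2, cy)
  M <- crossprod(B, A)  # sum over points of b a^T
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  sq <- sum(A^2) + sum(B^2) - 2 * lam
  sqrt(max(sq, 0) / nrow(X))
}

# --- brute-force 3-D Delaunay by empty-circumsphere enumeration --------------
circumsphere <- function(P) {
  # P: 4 x 3; returns centre and radius, or NULL when degenerate
  A <- 2 * (P[1:3, , drop = FALSE] - matrix(P[4, ], 3, 3, byrow = TRUE))
  b <- rowSums(P[1:3, , drop = FALSE]^2) - sum(P[4, ]^2)
  if (abs(det(A)) < 1e-10) return(NULL)
  ctr <- solve(A, b)
  list(centre = ctr, r = sqrt(sum((P[1, ] - ctr)^2)))
}

brute_delaunay_edges <- function(xyz, tol = 1e-9) {
  n <- nrow(xyz)
  stopifnot(n <= 14)
  quads <- utils::combn(n, 4)
  edges <- matrix(integer(0), 0, 2)
  for (q in seq_len(ncol(quads))) {
    idx <- quads[, q]
    cs <- circumsphere(xyz[idx, , drop = FALSE])
    if (is.null(cs)) next
    others <- setdiff(seq_len(n), idx)
    d <- sqrt(colSums((t(xyz[others, , drop = FALSE]) - cs$centre)^2))
    if (all(d > cs$r - tol)) {
      pr <- utils::combn(idx, 2)
      edges <- rbind(edges, t(pr))
    }
  }
  unique(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))

# --- finite differences ------------------------------------------------------
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

fd_hessian_from_grad <- function(grad, x, h = 1e-5) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    H[, i] <- (grad(xp) - grad(xm)) / (2 * h)
  }
  (H + t(H)) / 2
}

# Rigid-body basis (3 translations + 3 rotations) at a reference, orthonormal.
rigid_body_modes <- function(xyz) {
  n <- nrow(xyz)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  modes <- matrix(0, 3 * n, 6)
  for (c in 1:3) modes[seq(c, 3 * n, by = 3), c] <- 1
  for (a in 1:3) {
    ax <- c(0, 0, 0); ax[a] <- 1
    rot <- t(vapply(seq_len(n), function(i)
      c(ax[2] * ctr[i, 3] - ax[3] * ctr[i, 2],
        ax[3] * ctr[i, 1] - ax[1] * ctr[i, 3],
        ax[1] * ctr[i, 2] - ax[2] * ctr[i, 1]), numeric(3)))
    modes[, 3 + a] <- as.numeric(t(rot))
  }
  qr.Q(qr(modes))
}

# --- direct numerical BVP integration of d2X/dt2 = H^2 (X - Xref) ------------
# Second-order central finite differences on a uniform grid with the two
# boundary values clamped; Richardson extrapolation over grid halving gives
# O(h^4) accuracy. Independent of the analytic sinh propagator.
bvp_half_trajectory <- function(X_ref, Hdense, X_ts, t_s, times, m = 400) {
  solve_grid <- function(m) {
    h <- t_s / m
    n <- length(X_ref)
    H2 <- Hdense %*% Hdense
    nin <- m - 1
    In <- Matrix::Diagonal(n)
    L <- Matrix::bandSparse(nin, nin, k = c(-1, 0, 1),
                            diagonals = list(rep(1, nin - 1), rep(-2, nin),
                                             rep(1, nin - 1)))
    Amat <- Matrix::kronecker(L, In) / h^2 -
      Matrix::kronecker(Matrix::Diagonal(nin), Matrix::Matrix(H2))
    rhs <- rep(-as.numeric(H2 %*% X_ref), nin)
    rhs[seq_len(n)] <- rhs[seq_len(n)] - X_ref / h^2
    iend <- (nin - 1) * n + seq_len(n)
    rhs[iend] <- rhs[iend] - X_ts / h^2
    sol <- as.numeric(Matrix::solve(Amat, rhs))
    grid <- rbind(matrix(X_ref, 1), matrix(sol, nin, n, byrow = TRUE),
                  matrix(X_ts, 1))
    list(t = seq(0, t_s, length.out = m + 1), x = grid)
  }
  g1 <- solve_grid(m)
  g2 <- solve_grid(2 * m)
  # Richardson at the coarse-grid nodes; requested times must be nodes (exact
  # lookup) or are linearly interpolated
  xr <- (4 * g2$x[seq(1, 2 * m + 1, by = 2), , drop = FALSE] - g1$x) / 3
  out <- matrix(0, length(times), length(X_ref))
  for (q in seq_along(times)) {
    hit <- which(abs(g1$t - times[q]) < 1e-9)
    if (length(hit) == 1) {
      out[q, ] <- xr[hit, ]
    } else {
      for (c in seq_len(ncol(xr)))
        out[q, c] <- stats::approx(g1$t, xr[, c], xout = times[q])$y
    }
  }
  out
}

# 3N vector from an N x 3 matrix (matches the package's internal layout).
vec3 <- function(m) as.numeric(t(m))

# Prepared matched+superposed endpoint pair with networks, from fixture files.
prepare_pair <- function(fx, cutoff = 13, k1 = 0.1, k2 = 0.1) {
  A <- read_structure(fx$A$cif)
  B <- read_structure(fx$B$cif)
  corr <- match_structures(A, B)
  XA <- coords(A)[corr$pairs[, "a"], , drop = FALSE]
  XB <- coords(B)[corr$pairs[, "b"], , drop = FALSE]
  fit <- superpose(XA, XB)
  XB <- sweep(XB %*% t(fit$rotation), 2, fit$translation, "+")
  netA <- build_cutoff_network(XA, cutoff = cutoff, k = k1)
  netB <- build_cutoff_network(XB, cutoff = cutoff, k = k2)
  list(XA = XA, XB = XB, netA = netA, netB = netB,
       HA = assemble_hessian(netA), HB = assemble_hessian(netB),
       vA = vec3(XA), vB = vec3(XB), corr = corr)
}
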