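# CA-only Go-like potential (Clementi-style structure-based model): bonded
# terms along the chain plus a 12-10 attraction between native contacts, all
# minimized at the reference structure. Proteins only. Its Hessian satisfies
# the same operator contract as the Tirion one, so either can drive the path
# solver.

#' Build a Go-model topology from a CA trace
#'
#' Bonds (i,i+1), angles (i..i+2) and dihedrals (i..i+3) follow chain
#' connectivity (consecutive residue numbering within one chain, no term spans
#' a chain break). Native contacts are CA pairs within `contact_cutoff` with
#' sequence separation |i-j| >= 4 within a chain (any separation across
#' chains).
#'
#' @param s A protein-only, one-bead-per-residue `structure3d`.
#' @param contact_cutoff Native-contact cutoff in angstrom (default 8).
#' @param eps Contact well depth epsilon in kcal/mol; the bonded stiffnesses
#'   scale with it (K_bond = 100 eps/A^2, K_angle = 20 eps/rad^2,
#'   K_dih1 = eps, K_dih3 = eps/2).
#' @return A `go_topology`.
#' @export
build_go_topology <- function(s, contact_cutoff = 8, eps = 1) {
  a <- s$atoms
  if (any(residue_kind(a$resid) != "protein"))
    stop("the Go model only considers CA atoms and currently works only for proteins")
  if (any(toupper(a$elety) != "CA"))
    stop("the Go model needs a CA-only (one bead per residue) structure")
  xyz <- coords(s)
  n <- nrow(xyz)
  # consecutive-in-chain runs
  same_chain <- function(i, j) a$chain[i] == a$chain[j]
  consec <- function(i, j) same_chain(i, j) & (a$resno[j] - a$resno[i] == 1)
  idx <- seq_len(n)
  b_ok <- idx[-n][consec(idx[-n], idx[-1])]
  bonds <- cbind(b_ok, b_ok + 1L)
  ang <- bonds[bonds[, 2] %in% b_ok, 1, drop = TRUE]
  angles <- cbind(ang, ang + 1L, ang + 2L)
  dih <- angles[angles[, 3] %in% b_ok, 1, drop = TRUE]
  dihedrals <- cbind(dih, dih + 1L, dih + 2L, dih + 3L)
  d <- as.matrix(stats::dist(xyz))
  pr <- which(upper.tri(d) & d <= contact_cutoff, arr.ind = TRUE)
  seqsep <- abs(a$resno[pr[, 2]] - a$resno[pr[, 1]])
  local <- same_chain(pr[, 1], pr[, 2]) & seqsep < 4
  contacts <- pr[!local, , drop = FALSE]
  geom <- internal_coords(xyz, bonds, angles, dihedrals, contacts)
  structure(list(n_atoms = n, ref = as_vec3(xyz),
                 bonds = bonds, r0 = geom$r0,
                 angles = angles, theta0 = geom$theta0,
                 dihedrals = dihedrals, phi0 = geom$phi0,
                 contacts = contacts, sigma = geom$sigma,
                 K_bond = 100 * eps, K_angle = 20 * eps,
                 K_dih1 = eps, K_dih3 = 0.5 * eps, eps = eps,
                 contact_cutoff = contact_cutoff),
            class = "go_topology")
}

#' @export
print.go_topology <- function(x, ...) {
  cat(sprintf("go_topology: %d CA, %d bonds, %d angles, %d dihedrals, %d contacts (cutoff %g A)\n",
              x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$contacts), x$contact_cutoff))
  invisible(x)
}

internal_coords <- function(xyz, bonds, angles, dihedrals, contacts) {
  list(r0 = pair_dist(xyz, bonds),
       theta0 = apply_rows(angles, function(v) angle_value(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ])),
       phi0 = apply_rows(dihedrals, function(v) dihedral_value(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ], xyz[v[4], ])),
       sigma = pair_dist(xyz, contacts))
}

apply_rows <- function(m, f) {
  if (nrow(m) == 0) return(numeric(0))
  vapply(seq_len(nrow(m)), function(r) f(m[r, ]), numeric(1))
}

pair_dist <- function(xyz, ij) {
  if (nrow(ij) == 0) return(numeric(0))
  sqrt(rowSums((xyz[ij[, 1], , drop = FALSE] - xyz[ij[, 2], , drop = FALSE])^2))
}

angle_value <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, ct)))
}

dihedral_value <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Gradients of the internal coordinates w.r.t. the cartesian positions of the
# atoms involved (validated against finite differences in the test suite).
angle_grad <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  uh <- u / nu; vh <- v / nv
  ct <- sum(uh * vh)
  st <- sqrt(max(1 - ct^2, 1e-14))
  g1 <- (ct * uh - vh) / (nu * st)
  g3 <- (ct * vh - uh) / (nv * st)
  rbind(g1, -(g1 + g3), g3)
}

dihedral_grad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  g1 <- -nb2 / sum(n1^2) * n1
  g4 <- nb2 / sum(n2^2) * n2
  c12 <- sum(b1 * b2) / sum(b2^2)
  c32 <- sum(b3 * b2) / sum(b2^2)
  g2 <- -(1 + c12) * g1 + c32 * g4
  g3 <- -(1 + c32) * g4 + c12 * g1
  rbind(g1, g2, g3, g4)
}

#' Go-model potential energy
#'
#' `E = sum K_b (r-r0)^2 + sum K_a (theta-theta0)^2 +
#'  sum [K_d1 (1-cos(phi-phi0)) + K_d3 (1-cos 3(phi-phi0))] +
#'  sum eps [5 (sigma/r)^12 - 6 (sigma/r)^10]`.
#' Zero gradient at the reference; each contact contributes -eps there.
#'
#' @param top A `go_topology`.
#' @param x Coordinates (3N vector or N x 3 matrix).
#' @return Energy in kcal/mol.
#' @export
go_energy <- function(top, x) {
  xyz <- if (is.null(dim(x))) as_mat3(x) else as.matrix(x)
  rb <- pair_dist(xyz, top$bonds)
  th <- apply_rows(top$angles, function(v) angle_value(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ]))
  ph <- apply_rows(top$dihedrals, function(v) dihedral_value(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ], xyz[v[4], ]))
  rc <- pair_dist(xyz, top$contacts)
  if (any(c(rb, rc) < 1e-9)) stop("coincident atoms: Go energy is singular")
  dphi <- ph - top$phi0
  sum(top$K_bond * (rb - top$r0)^2) +
    sum(top$K_angle * (th - top$theta0)^2) +
    sum(top$K_dih1 * (1 - cos(dphi)) + top$K_dih3 * (1 - cos(3 * dphi))) +
    sum(top$eps * (5 * (top$sigma / rc)^12 - 6 * (top$sigma / rc)^10))
}

#' Go-model gradient
#' @inheritParams go_energy
#' @return 3N gradient vector (kcal/mol/A).
#' @export
go_gradient <- function(top, x) {
  xyz <- if (is.null(dim(x))) as_mat3(x) else as.matrix(x)
  g <- matrix(0, top$n_atoms, 3)
  add <- function(idx, gr) g[idx, ] <<- g[idx, ] + gr
  if (nrow(top$bonds) > 0) {
    dv <- xyz[top$bonds[, 1], , drop = FALSE] - xyz[top$bonds[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    co <- 2 * top$K_bond * (r - top$r0) / r
    add(top$bonds[, 1], dv * co); add(top$bonds[, 2], -dv * co)
  }
  for (t in seq_len(nrow(top$angles))) {
    v <- top$angles[t, ]
    th <- angle_value(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ])
    gr <- angle_grad(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ])
    add(v, 2 * top$K_angle * (th - top$theta0[t]) * gr)
  }
  for (t in seq_len(nrow(top$dihedrals))) {
    v <- top$dihedrals[t, ]
    ph <- dihedral_value(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ], xyz[v[4], ])
    gr <- dihedral_grad(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ], xyz[v[4], ])
    dphi <- ph - top$phi0[t]
    add(v, (top$K_dih1 * sin(dphi) + 3 * top$K_dih3 * sin(3 * dphi)) * gr)
  }
  if (nrow(top$contacts) > 0) {
    dv <- xyz[top$contacts[, 1], , drop = FALSE] - xyz[top$contacts[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    s_r <- top$sigma / r
    dV <- top$eps * 60 * (s_r^10 - s_r^12) / r
    co <- dV / r
    add(top$contacts[, 1], dv * co); add(top$contacts[, 2], -dv * co)
  }
  as_vec3(g)
}

#' Go-model Hessian operator
#'
#' Exact second derivative at the reference. Because every term is at its
#' minimum there, the Hessian is a sum of positive rank-1 blocks
#' `c_term * grad(q) grad(q)^T` over the internal coordinates q: curvatures
#' 2 K_bond, 2 K_angle, K_dih1 + 9 K_dih3, and 120 eps / sigma^2 per contact.
#' Symmetric PSD with the six rigid-body motions in its kernel.
#'
#' @param top A `go_topology`.
#' @param dense_limit Materialize densely when 3N <= this.
#' @return A `hessian_operator`.
#' @export
go_hessian <- function(top, dense_limit = 3000) {
  xyz <- as_mat3(top$ref)
  n3 <- 3L * top$n_atoms
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add_block <- function(atoms, grad, curv) {
    # grad: length(atoms) x 3 gradient of the internal coordinate
    gflat <- as_vec3(grad)
    dof <- as.integer(outer(3L * (atoms - 1L), 1:3, "+"))
    dof <- as.integer(t(matrix(dof, length(atoms), 3)))
    blk <- curv * outer(gflat, gflat)
    idx <- expand.grid(a = seq_along(dof), b = seq_along(dof))
    ii <<- c(ii, dof[idx$a]); jj <<- c(jj, dof[idx$b])
    vv <<- c(vv, blk[cbind(idx$a, idx$b)])
  }
  for (t in seq_len(nrow(top$bonds))) {
    v <- top$bonds[t, ]
    u <- (xyz[v[1], ] - xyz[v[2], ]); u <- u / sqrt(sum(u^2))
    add_block(v, rbind(u, -u), 2 * top$K_bond)
  }
  for (t in seq_len(nrow(top$angles))) {
    v <- top$angles[t, ]
    add_block(v, angle_grad(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ]),
              2 * top$K_angle)
  }
  for (t in seq_len(nrow(top$dihedrals))) {
    v <- top$dihedrals[t, ]
    add_block(v, dihedral_grad(xyz[v[1], ], xyz[v[2], ], xyz[v[3], ], xyz[v[4], ]),
              top$K_dih1 + 9 * top$K_dih3)
  }
  for (t in seq_len(nrow(top$contacts))) {
    v <- top$contacts[t, ]
    u <- (xyz[v[1], ] - xyz[v[2], ]); u <- u / sqrt(sum(u^2))
    add_block(v, rbind(u, -u), 120 * top$eps / top$sigma[t]^2)
  }
  H <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n3, n3))
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  make_hessian_operator(H, dense_limit)
}

# Topology dump for inspection (TSV sections).
write_go_topology <- function(top, path) {
  con <- file(path, "w"); on.exit(close(con))
  dump1 <- function(name, m, val) {
    writeLines(paste0("# ", name), con)
    if (nrow(m) > 0)
      utils::write.table(cbind(as.data.frame(m), value = val), con, sep = "\t",
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  dump1("bonds i j r0", top$bonds, top$r0)
  dump1("angles i j k theta0", top$angles, top$theta0)
  dump1("dihedrals i j k l phi0", top$dihedrals, top$phi0)
  dump1("contacts i j sigma", top$contacts, top$sigma)
  invisible(path)
}
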