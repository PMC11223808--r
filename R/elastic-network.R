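# Elastic network construction and the Tirion potential. A network is built on
# one reference conformation; its quadratic expansion there supplies the
# Hessian operator the path solver consumes.

new_elastic_network <- function(ref_coords, edges, k, geometry, cutoff = NA) {
  ref <- as_vec3(ref_coords)
  n <- length(ref) / 3
  stopifnot(n == floor(n))
  if (nrow(edges) == 0) stop("elastic network has no edges")
  i <- pmin(edges[, 1], edges[, 2]); j <- pmax(edges[, 1], edges[, 2])
  if (any(i == j)) stop("self-edge in elastic network")
  key <- paste(i, j)
  keep <- !duplicated(key)
  i <- i[keep]; j <- j[keep]
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  r0 <- edge_lengths(ref, i, j)
  deg <- tabulate(c(i, j), nbins = n)
  if (any(deg == 0))
    stop("isolated atom(s) in network: ",
         paste(utils::head(which(deg == 0), 5), collapse = ", "),
         " - increase the cutoff or use the Delaunay geometry")
  net <- structure(list(ref = ref, n_atoms = as.integer(n),
                        i = as.integer(i), j = as.integer(j), r0 = r0,
                        k = k, geometry = geometry, cutoff = cutoff),
                   class = "elastic_network")
  comps <- igraph::components(
    igraph::graph_from_edgelist(cbind(i, j), directed = FALSE))
  if (comps$no > 1)
    warning("elastic network has ", comps$no, " connected components ",
            "(sizes ", paste(comps$csize, collapse = ", "), ")")
  net
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("elastic_network: %d atoms, %d edges, geometry=%s%s, k=%g kcal/mol/A^2\n",
              x$n_atoms, length(x$i), x$geometry,
              if (!is.na(x$cutoff)) sprintf(" (Rc=%g A)", x$cutoff) else "",
              x$k))
  invisible(x)
}

# Cell-list neighbour search; falls back to an all-pairs scan for small N.
cutoff_pairs <- function(xyz, rc) {
  n <- nrow(xyz)
  if (n <= 2000) {
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d) & d <= rc, arr.ind = TRUE)
    return(idx)
  }
  cell <- pmax(rc, 1e-6)
  keyv <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  keys <- paste(keyv[, 1], keyv[, 2], keyv[, 3])
  buckets <- split(seq_len(n), keys)
  coords_of <- function(k) as.integer(strsplit(k, " ")[[1]])
  out_i <- integer(0); out_j <- integer(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (k in names(buckets)) {
    ck <- coords_of(k)
    mine <- buckets[[k]]
    neigh <- integer(0)
    for (r in seq_len(nrow(offs))) {
      nk <- paste(ck[1] + offs[r, 1], ck[2] + offs[r, 2], ck[3] + offs[r, 3])
      nb <- buckets[[nk]]
      if (!is.null(nb)) neigh <- c(neigh, nb)
    }
    for (a in mine) {
      cand <- neigh[neigh > a]
      if (length(cand) == 0) next
      dd <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[a, ])^2))
      hit <- cand[dd <= rc]
      out_i <- c(out_i, rep.int(a, length(hit)))
      out_j <- c(out_j, hit)
    }
  }
  cbind(out_i, out_j)
}

#' Build a cutoff elastic network
#'
#' Connects every atom pair closer than `cutoff` in the reference conformation.
#' Typical cutoffs are 13-15 angstrom for one-bead-per-residue networks and 7-9
#' angstrom for all-atom networks.
#'
#' @param ref_coords Reference coordinates (N x 3 matrix or 3N vector).
#' @param cutoff Cutoff radius R_c in angstrom (> 0).
#' @param k Spring constant, kcal/mol/A^2.
#' @return An `elastic_network`.
#' @export
build_cutoff_network <- function(ref_coords, cutoff, k = 0.1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- if (is.null(dim(ref_coords))) as_mat3(ref_coords) else as.matrix(ref_coords)
  pr <- cutoff_pairs(xyz, cutoff)
  if (nrow(pr) == 0) stop("no atom pair within the cutoff")
  new_elastic_network(xyz, pr, k, "cutoff", cutoff = cutoff)
}

# Edges of the 3-D Delaunay tetrahedralization, computed with the
# scipy.spatial.Delaunay (Qhull) bindings of the bundled Python interpreter.
delaunay_edges_qhull <- function(xyz) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    stop("Delaunay geometry needs a python interpreter with scipy on PATH; ",
         "use the cutoff geometry otherwise")
  fin <- tempfile(fileext = ".txt"); fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(xyz, fin, row.names = FALSE, col.names = FALSE)
  code <- paste(
    "import sys, numpy as np",
    "from scipy.spatial import Delaunay",
    "pts = np.loadtxt(sys.argv[1], ndmin=2)",
    "tri = Delaunay(pts)",
    "s = tri.simplices",
    "e = set()",
    "for t in s:",
    "    t = sorted(int(v) for v in t)",
    "    for a in range(4):",
    "        for b in range(a + 1, 4):",
    "            e.add((t[a], t[b]))",
    "np.savetxt(sys.argv[2], np.array(sorted(e), dtype=int) + 1, fmt='%d')",
    sep = "\n")
  st <- suppressWarnings(system2(py, c("-c", shQuote(code), fin, fout),
                                 stdout = TRUE, stderr = TRUE))
  if (!file.exists(fout) || file.info(fout)$size == 0)
    stop("Delaunay tetrahedralization failed",
         if (length(st) > 0) paste0(": ", paste(st, collapse = " ")) else "")
  as.matrix(utils::read.table(fout))
}

#' Build a Delaunay elastic network
#'
#' Edges are the 1-skeleton of the 3-D Delaunay tetrahedralization of the
#' reference conformation: a parameter-free geometry that keeps loosely
#' connected ("dangling") parts attached to the rest of the network. Degenerate
#' (coplanar) inputs are retried once with a 1e-6 angstrom jitter under a fixed
#' seed before failing.
#'
#' @inheritParams build_cutoff_network
#' @param max_edge Optional maximum edge length in angstrom; edges longer than
#'   this are removed (off by default, the geometry is parameter-free).
#' @return An `elastic_network`.
#' @export
build_delaunay_network <- function(ref_coords, k = 0.1, max_edge = NULL) {
  xyz <- if (is.null(dim(ref_coords))) as_mat3(ref_coords) else as.matrix(ref_coords)
  if (nrow(xyz) < 5) stop("Delaunay network needs at least 5 atoms")
  edges <- tryCatch(delaunay_edges_qhull(xyz), error = function(e) e)
  if (inherits(edges, "error")) {
    jit <- with_seed(20260101, matrix(stats::runif(length(xyz), -1e-6, 1e-6),
                                      nrow(xyz), 3))
    edges <- delaunay_edges_qhull(xyz + jit)
  }
  if (!is.null(max_edge)) {
    len <- edge_lengths(as_vec3(xyz), edges[, 1], edges[, 2])
    edges <- edges[len <= max_edge, , drop = FALSE]
  }
  new_elastic_network(xyz, edges, k, "delaunay")
}

#' Tirion elastic energy
#'
#' `V(X) = k/2 * sum over edges (r_ij - r0_ij)^2`: a single isotropic force
#' constant over all network springs, each at rest in the reference
#' conformation.
#'
#' @param net An `elastic_network`.
#' @param x Coordinates (3N vector or N x 3 matrix).
#' @return Energy in kcal/mol (non-negative; zero at the reference).
#' @export
tirion_energy <- function(net, x) {
  x <- as_vec3(x)
  r <- edge_lengths(x, net$i, net$j)
  0.5 * net$k * sum((r - net$r0)^2)
}

#' Tirion energy gradient
#'
#' @inheritParams tirion_energy
#' @return 3N gradient vector (kcal/mol/A); zero at the reference.
#' @export
tirion_gradient <- function(net, x) {
  x <- as_vec3(x)
  xm <- as_mat3(x)
  dv <- xm[net$i, , drop = FALSE] - xm[net$j, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  if (any(r < 1e-12))
    stop("coincident atoms on network edge(s): gradient is singular")
  coef <- net$k * (r - net$r0) / r
  f <- dv * coef
  # scatter-add: force +f on atom i, -f on atom j
  g <- matrix(0, nrow(xm), 3)
  for (c in 1:3) {
    gi <- rowsum(f[, c], net$i)
    gj <- rowsum(f[, c], net$j)
    g[as.integer(rownames(gi)), c] <- g[as.integer(rownames(gi)), c] + gi
    g[as.integer(rownames(gj)), c] <- g[as.integer(rownames(gj)), c] - gj
  }
  as_vec3(g)
}

# ---- Hessian operator --------------------------------------------------------

# At the reference every spring is at rest, so each edge contributes the rank-1
# block k * u u^T (u the unit edge vector) with the usual +/- sign pattern;
# the (r - r0) curvature-of-distance terms vanish.
tirion_hessian_sparse <- function(net) {
  xm <- as_mat3(net$ref)
  dv <- xm[net$i, , drop = FALSE] - xm[net$j, , drop = FALSE]
  u <- dv / sqrt(rowSums(dv^2))
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (a in 1:3) for (b in 1:3) {
    blk <- net$k * u[, a] * u[, b]
    ia <- 3L * (net$i - 1L) + a; ja <- 3L * (net$j - 1L) + a
    ib <- 3L * (net$i - 1L) + b; jb <- 3L * (net$j - 1L) + b
    ii <- c(ii, ia, ja, ia, ja)
    jj <- c(jj, ib, jb, jb, ib)
    vv <- c(vv, blk, blk, -blk, -blk)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(3L * net$n_atoms, 3L * net$n_atoms))
}

#' Hessian operator of an elastic network
#'
#' The exact second derivative of the Tirion energy evaluated at the network's
#' own reference conformation, where it is symmetric positive semidefinite
#' with the six rigid-body motions in its kernel. Stored sparse; a dense
#' materialization is kept for systems up to `dense_limit` coordinates so the
#' spectral (eigendecomposition) backend can use it.
#'
#' @param net An `elastic_network`.
#' @param dense_limit Materialize densely when 3N <= this (default 3000).
#' @return A `hessian_operator`: list with `n` (= 3N), `matvec(v)`, the sparse
#'   matrix, optional dense matrix, and a cache environment for spectral data.
#' @export
assemble_hessian <- function(net, dense_limit = 3000) {
  H <- tirion_hessian_sparse(net)
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  make_hessian_operator(H, dense_limit)
}

make_hessian_operator <- function(Hsparse, dense_limit = 3000) {
  n <- nrow(Hsparse)
  dense <- if (n <= dense_limit) as.matrix(Hsparse) else NULL
  op <- list(n = n, sparse = Hsparse, dense = dense,
             matvec = function(v) as.numeric(Hsparse %*% v),
             cache = new.env(parent = emptyenv()))
  class(op) <- "hessian_operator"
  op
}

#' @export
print.hessian_operator <- function(x, ...) {
  cat(sprintf("hessian_operator: dimension %d (%s)\n", x$n,
              if (is.null(x$dense)) "sparse only" else "sparse + dense"))
  invisible(x)
}

#' Spring constant from the mean B-factor
#'
#' `k = A / <B>`: the smaller the mean crystallographic B-factor, the stiffer
#' the network. Values outside 0.16 +/- 0.09 kcal/mol/A^2 trigger a warning.
#'
#' @param A_factor Proportionality factor A (kcal/mol, carries the temperature
#'   dependence).
#' @param mean_B Mean B-factor in squared angstrom (> 0).
#' @return Spring constant k in kcal/mol/A^2.
#' @export
spring_constant_from_bfactor <- function(A_factor, mean_B) {
  if (!is.finite(mean_B) || mean_B <= 0)
    stop("mean B-factor must be positive and finite")
  k <- A_factor / mean_B
  if (k < 0.16 - 0.09 || k > 0.16 + 0.09)
    warning(sprintf("k = %.3f kcal/mol/A^2 is outside the expected range 0.16 +/- 0.09", k))
  k
}

# Edge-list dump for debugging/visualization.
write_network_edges <- function(net, path) {
  utils::write.table(data.frame(i = net$i, j = net$j, r0 = net$r0, k = net$k),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
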