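# Internal numeric helpers shared across modules.

# Flatten an N x 3 coordinate matrix into the 3N vector (x1,y1,z1,x2,...)
# used by the solver, and back.
as_vec3 <- function(coords) {
  if (is.null(dim(coords))) return(as.numeric(coords))
  as.numeric(t(coords))
}

as_mat3 <- function(v) {
  stopifnot(length(v) %% 3 == 0)
  matrix(v, ncol = 3L, byrow = TRUE)
}

# Pairwise distances for an edge list on flattened coordinates.
edge_lengths <- function(x, i, j) {
  xm <- as_mat3(x)
  sqrt(rowSums((xm[i, , drop = FALSE] - xm[j, , drop = FALSE])^2))
}

# Rotation matrix about a unit axis (Rodrigues), angle in radians.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Evaluate `expr` with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(log, ...) {
  msg <- paste0(...)
  if (!is.null(log)) log$lines <- c(log$lines, msg)
  invisible(msg)
}

new_run_log <- function() {
  e <- new.env(parent = emptyenv())
  e$lines <- character(0)
  e
}
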