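# Deterministic generators of small synthetic endpoint pairs. Fixtures are
# written to disk (both PDB and mmCIF dialects) so the I/O layer participates
# in every integration test; a fixed seed reproduces the files byte for byte.

.FIXTURE_SEQ <- "ADKLGEFRHSWTVQNCYIMP"  # repeating 20-letter residue palette

aa_three <- function(one) {
  m <- names(.AA3)[match(one, .AA3)]
  if (any(is.na(m))) stop("invalid residue code: ",
                          paste(one[is.na(m)], collapse = ","))
  m
}

# Build a CA-only structure3d from coordinates and residue codes.
ca_structure <- function(xyz, one_letter, chain = "A", resno = NULL,
                         bfac = NULL) {
  n <- nrow(xyz)
  if (length(chain) == 1) chain <- rep(chain, n)
  if (is.null(resno)) {
    resno <- integer(n)
    for (ch in unique(chain)) resno[chain == ch] <- seq_len(sum(chain == ch))
  }
  if (is.null(bfac)) bfac <- 20 + 5 * sin(seq_len(n))
  new_structure(data.frame(
    chain = chain, resno = resno, insert = NA_character_,
    resid = aa_three(one_letter), elety = "CA", elesy = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = round(bfac, 2), model = 1L, stringsAsFactors = FALSE))
}

# CA-only nucleic-acid trace (C3' beads for DNA, C4' for RNA).
na_structure <- function(xyz, bases, kind = "dna", chain = "X") {
  n <- nrow(xyz)
  resid <- if (kind == "dna") paste0("D", bases) else bases
  elety <- if (kind == "dna") "C3'" else "C4'"
  new_structure(data.frame(
    chain = rep(chain, n), resno = seq_len(n), insert = NA_character_,
    resid = resid, elety = elety, elesy = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 25, model = 1L, stringsAsFactors = FALSE))
}

# Write one structure in both dialects; returns named paths.
write_fixture <- function(s, dir, name) {
  cif <- file.path(dir, paste0(name, ".cif"))
  pdb <- file.path(dir, paste0(name, ".pdb"))
  write_structure(s, cif)
  a <- s$atoms
  bio3d::write.pdb(file = pdb, xyz = as_vec3(coords(s)), resno = a$resno,
                   resid = a$resid, elety = a$elety,
                   chain = ifelse(nchar(a$chain) > 1,
                                  substr(a$chain, 1, 1), a$chain),
                   o = a$o, b = a$b)
  list(cif = cif, pdb = pdb, structure = s)
}

ideal_helix <- function(n, radius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  th <- (seq_len(n) - 1) * turn
  cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
}

helix_sequence <- function(n) {
  strsplit(paste(rep(.FIXTURE_SEQ, ceiling(n / 20)), collapse = ""), "")[[1]][seq_len(n)]
}

#' Generate a hinge-bent helix endpoint pair
#'
#' Endpoint A is an ideal CA alpha-helix of `n` residues; endpoint B is the
#' same helix rigidly bent at its midpoint by `bend_angle` degrees about an
#' axis through the hinge residue. Residue numbering is shared, so the pair is
#' bypass-compatible.
#'
#' @param n Number of residues (>= 8).
#' @param bend_angle Hinge angle in degrees.
#' @param seed RNG seed (used only for reproducible B-factor noise).
#' @param dir Output directory.
#' @return List with `A` and `B` (each: `cif`, `pdb`, `structure`) and the
#'   hinge residue index.
#' @export
make_helix_pair <- function(n = 20, bend_angle = 30, seed = 1,
                            dir = tempfile("helixpair")) {
  if (n < 8) stop("make_helix_pair: need at least 8 residues")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    xyzA <- ideal_helix(n)
    bf <- 20 + round(stats::runif(n, -3, 3), 2)
    hinge <- floor(n / 2)
    xyzB <- xyzA
    if (bend_angle != 0) {
      R <- rotation_about_axis(c(1, 0, 0), bend_angle * pi / 180)
      tail_idx <- (hinge + 1):n
      pivot <- xyzA[hinge, ]
      xyzB[tail_idx, ] <- sweep(sweep(xyzA[tail_idx, , drop = FALSE], 2, pivot) %*% t(R),
                                2, pivot, "+")
    }
    sq <- helix_sequence(n)
    list(A = write_fixture(ca_structure(xyzA, sq, bfac = bf), dir, "helix_A"),
         B = write_fixture(ca_structure(xyzB, sq, bfac = bf), dir, "helix_B"),
         hinge = hinge)
  })
}

compact_lobe <- function(n, spacing = 3.8, jitter = 0.3) {
  # grid points inside a ball, jittered: compact and tessellation-friendly
  g <- floor(n^(1 / 3)) + 2
  pts <- as.matrix(expand.grid(seq_len(g), seq_len(g), seq_len(g))) * spacing
  ctr <- colMeans(pts)
  pts <- pts[order(rowSums(sweep(pts, 2, ctr)^2)), , drop = FALSE][seq_len(n), ]
  pts + matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
}

#' Generate an open/closed two-domain ("dumbbell") endpoint pair
#'
#' Two rigid compact lobes joined by a 3-residue linker, at two inter-lobe
#' separations: a toy open-to-closed domain motion. Internal lobe geometry is
#' identical in both endpoints, so all path motion is inter-domain.
#'
#' @param n_per_lobe Residues per lobe (default 30).
#' @param separation_open,separation_closed Inter-lobe centre offsets in
#'   angstrom (defaults 20 and 12).
#' @param twist Rigid rotation of the second lobe in the closed form, degrees
#'   (default 50): real domain closures combine approach with rotation, and
#'   the rotation is what breaks start-state contacts along the path.
#' @param seed RNG seed.
#' @param dir Output directory.
#' @param two_chains Assign the two lobes to chains "A" and "B" (linker to
#'   "A"); default is a single chain.
#' @return List with `A` (open) and `B` (closed) fixtures.
#' @export
make_dumbbell_pair <- function(n_per_lobe = 30, separation_open = 20,
                               separation_closed = 12, twist = 50, seed = 1,
                               dir = tempfile("dumbbell"), two_chains = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    lobe1 <- compact_lobe(n_per_lobe)
    lobe2 <- compact_lobe(n_per_lobe)
    lobe1 <- sweep(lobe1, 2, colMeans(lobe1))
    lobe2 <- sweep(lobe2, 2, colMeans(lobe2))
    build <- function(sep, ang = 0) {
      l1 <- lobe1
      l2 <- if (ang != 0)
        lobe2 %*% t(rotation_about_axis(c(0, 0, 1), ang * pi / 180))
      else lobe2
      l2 <- sweep(l2, 2, c(sep, 0, 0), "+")
      # 3-residue linker between the lobes' facing extremes
      p1 <- l1[which.max(l1[, 1]), ]
      p2 <- l2[which.min(l2[, 1]), ]
      lk <- t(vapply(1:3, function(q) p1 + (p2 - p1) * q / 4, numeric(3)))
      rbind(l1, lk, l2)
    }
    n_tot <- 2 * n_per_lobe + 3
    sq <- helix_sequence(n_tot)
    chain <- if (two_chains)
      c(rep("A", n_per_lobe + 3), rep("B", n_per_lobe)) else rep("A", n_tot)
    same <- separation_open == separation_closed
    list(A = write_fixture(ca_structure(build(separation_open), sq,
                                        chain = chain), dir, "dumbbell_A"),
         B = write_fixture(ca_structure(build(separation_closed,
                                              if (same) 0 else twist), sq,
                                        chain = chain), dir, "dumbbell_B"))
  })
}

#' Generate a mutation endpoint pair
#'
#' Same helix backbone in both endpoints; residue identities of endpoint B are
#' changed according to `mutations`, exercising the physico-chemical-class
#' matching rule with a correspondence computable in closed form.
#'
#' @param sequence Character string of one-letter residue codes for endpoint A.
#' @param mutations Named character vector: positions (as names, 1-based) to
#'   new one-letter codes for endpoint B.
#' @param seed RNG seed.
#' @param dir Output directory.
#' @return List with `A`, `B` fixtures and the mutated positions.
#' @export
make_mutation_pair <- function(sequence, mutations = c(), seed = 1,
                               dir = tempfile("mutpair")) {
  sq <- strsplit(sequence, "")[[1]]
  if (!all(sq %in% .AA3)) stop("invalid residue code in sequence")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sqB <- sq
  if (length(mutations) > 0) {
    pos <- as.integer(names(mutations))
    if (any(is.na(pos)) || any(pos < 1 | pos > length(sq)))
      stop("invalid mutation positions")
    if (!all(mutations %in% .AA3)) stop("invalid residue code in mutations")
    sqB[pos] <- unname(mutations)
  }
  with_seed(seed, {
    xyz <- ideal_helix(length(sq))
    list(A = write_fixture(ca_structure(xyz, sq), dir, "mut_A"),
         B = write_fixture(ca_structure(xyz, sqB), dir, "mut_B"),
         positions = if (length(mutations) > 0) as.integer(names(mutations))
         else integer(0))
  })
}
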