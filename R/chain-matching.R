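# Sequence-based matching of the two endpoint structures. The server-side
# structural aligner is replaced by pure global sequence alignment, which is
# the regime all worked examples operate in; rigid superposition of the matched
# atoms is done separately by least squares.

# Physico-chemical residue classes: aligned amino acids are paired when both
# fall in the same class; nucleotides must be identical.
.RES_CLASSES <- list(c("P", "A", "G", "S", "T"),
                     c("D", "N", "E", "Q"),
                     c("H", "K", "R"),
                     c("F", "Y", "W"),
                     c("V", "L", "I", "C", "M"))

res_class <- function(aa) {
  for (k in seq_along(.RES_CLASSES)) if (aa %in% .RES_CLASSES[[k]]) return(k)
  NA_integer_
}

seq_alphabet <- function(s) {
  letters1 <- unique(strsplit(s, "")[[1]])
  if (all(letters1 %in% c("A", "C", "G", "T", "U"))) "nucleotide" else "protein"
}

# Residue table of one chain: one row per residue in atom order, with the
# one-letter code ("X" for residues outside the standard alphabets).
chain_residues <- function(s, chain) {
  a <- s$atoms
  sel <- which(a$chain == chain)
  key <- paste(a$resno[sel], ifelse(is.na(a$insert[sel]), "", a$insert[sel]),
               sep = "|")
  first <- sel[!duplicated(key)]
  kind <- residue_kind(a$resid[first])
  one <- character(length(first))
  for (i in seq_along(first)) {
    r <- toupper(a$resid[first[i]])
    one[i] <- switch(kind[i],
                     protein = unname(.AA3[r]),
                     dna = unname(.DNA[r]),
                     rna = unname(.RNA[r]),
                     "X")
  }
  data.frame(resno = a$resno[first],
             insert = ifelse(is.na(a$insert[first]), "", a$insert[first]),
             resid = toupper(a$resid[first]), kind = kind, one = one,
             stringsAsFactors = FALSE)
}

chain_kind <- function(restab) {
  k <- restab$kind[restab$kind != "other"]
  if (length(k) == 0) return("other")
  names(sort(table(k), decreasing = TRUE))[1]
}

chain_seq <- function(restab) paste(restab$one, collapse = "")

#' Globally align two residue sequences
#'
#' Needleman-Wunsch global alignment through [Biostrings::pairwiseAlignment()]
#' with match +1, mismatch 0, gap opening -10, gap extension -0.5. This scoring
#' strongly prefers ungapped matches of near-identical chains, the situation
#' chain matching of two conformations of the same molecule presents.
#'
#' @param seq1,seq2 Residue strings (one-letter codes), both amino-acid or both
#'   nucleotide.
#' @return A list with gapped strings `aln1`, `aln2` and the alignment `score`.
#' @export
align_sequences <- function(seq1, seq2) {
  if (nchar(seq1) == 0 || nchar(seq2) == 0)
    stop("align_sequences: empty sequence")
  if (seq_alphabet(seq1) != seq_alphabet(seq2))
    stop("align_sequences: sequences are over different alphabets (",
         seq_alphabet(seq1), " vs ", seq_alphabet(seq2), ")")
  letters_all <- sort(unique(strsplit(paste0(seq1, seq2), "")[[1]]))
  sm <- matrix(0, length(letters_all), length(letters_all),
               dimnames = list(letters_all, letters_all))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::BString(seq1), subject = Biostrings::BString(seq2),
    type = "global", substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 0.5)
  list(aln1 = as.character(Biostrings::alignedPattern(aln)),
       aln2 = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Match chains between two structures by sequence
#'
#' Scores every same-alphabet chain pair by global alignment and assigns
#' one-to-one greedily on descending score (minimum score 10). Assignment is
#' score-driven, never name-driven: chains that swap identifiers between the
#' two files are still paired correctly. Unmatched chains are reported.
#'
#' @param A,B `structure3d` endpoints.
#' @param min_score Minimum alignment score for a pair to be eligible.
#' @return List with `map` (data frame chain_a, chain_b, score), `alignments`
#'   (per matched pair), residue tables and unmatched chain names.
#' @export
match_chains <- function(A, B, min_score = 10) {
  ch_a <- unique(A$atoms$chain)
  ch_b <- unique(B$atoms$chain)
  tab_a <- lapply(ch_a, function(c) chain_residues(A, c))
  tab_b <- lapply(ch_b, function(c) chain_residues(B, c))
  names(tab_a) <- ch_a; names(tab_b) <- ch_b
  cand <- list()
  for (i in seq_along(ch_a)) for (j in seq_along(ch_b)) {
    ka <- chain_kind(tab_a[[i]]); kb <- chain_kind(tab_b[[j]])
    if (ka == "other" || kb == "other") next
    if ((ka == "protein") != (kb == "protein")) next
    aln <- align_sequences(chain_seq(tab_a[[i]]), chain_seq(tab_b[[j]]))
    cand[[length(cand) + 1L]] <- list(a = ch_a[i], b = ch_b[j], aln = aln,
                                      score = aln$score)
  }
  if (length(cand) == 0)
    stop("match_chains: no chain pair could be aligned")
  scores <- vapply(cand, `[[`, numeric(1), "score")
  ord <- order(-scores)
  used_a <- character(0); used_b <- character(0)
  map <- list(); alns <- list()
  for (k in ord) {
    cnd <- cand[[k]]
    if (cnd$score < min_score) next
    if (cnd$a %in% used_a || cnd$b %in% used_b) next
    used_a <- c(used_a, cnd$a); used_b <- c(used_b, cnd$b)
    map[[length(map) + 1L]] <- data.frame(chain_a = cnd$a, chain_b = cnd$b,
                                          score = cnd$score,
                                          stringsAsFactors = FALSE)
    alns[[length(alns) + 1L]] <- cnd$aln
  }
  if (length(map) == 0)
    stop("match_chains: no chain pair reached the minimum alignment score")
  map <- do.call(rbind, map)
  list(map = map, alignments = alns,
       residues_a = tab_a, residues_b = tab_b,
       unmatched_a = setdiff(ch_a, map$chain_a),
       unmatched_b = setdiff(ch_b, map$chain_b))
}

#' Extract the common-atom correspondence from matched chains
#'
#' For every aligned (gap-free) residue pair whose amino acids share a
#' physico-chemical class — (P,A,G,S,T), (D,N,E,Q), (H,K,R), (F,Y,W),
#' (V,L,I,C,M) — or whose nucleotides are identical, all atoms present with the
#' same name on both sides are paired. Ordering follows the chain map, then
#' A-side residue order, then A-side atom order.
#'
#' @param A,B `structure3d` endpoints.
#' @param matching Result of [match_chains()].
#' @return An `atom_correspondence`: `pairs` (two-column index matrix into the
#'   atom tables of A and B), `chain_map`, `n_common`.
#' @export
extract_common_atoms <- function(A, B, matching) {
  a <- A$atoms; b <- B$atoms
  key_a <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
                 sep = "|")
  key_b <- paste(b$chain, b$resno, ifelse(is.na(b$insert), "", b$insert),
                 sep = "|")
  ia_all <- integer(0); ib_all <- integer(0)
  for (k in seq_len(nrow(matching$map))) {
    ca <- matching$map$chain_a[k]; cb <- matching$map$chain_b[k]
    aln <- matching$alignments[[k]]
    ta <- matching$residues_a[[ca]]; tb <- matching$residues_b[[cb]]
    g1 <- strsplit(aln$aln1, "")[[1]]; g2 <- strsplit(aln$aln2, "")[[1]]
    p1 <- cumsum(g1 != "-"); p2 <- cumsum(g2 != "-")
    for (col in seq_along(g1)) {
      if (g1[col] == "-" || g2[col] == "-") next
      ra <- ta[p1[col], ]; rb <- tb[p2[col], ]
      if (ra$one == "X" || rb$one == "X") next
      if (ra$kind == "protein") {
        if (rb$kind != "protein") next
        c1 <- res_class(ra$one); c2 <- res_class(rb$one)
        if (is.na(c1) || is.na(c2) || c1 != c2) next
      } else {
        if (rb$kind == "protein" || ra$one != rb$one) next
      }
      sel_a <- which(key_a == paste(ca, ra$resno, ra$insert, sep = "|"))
      sel_b <- which(key_b == paste(cb, rb$resno, rb$insert, sep = "|"))
      mm <- match(toupper(a$elety[sel_a]), toupper(b$elety[sel_b]))
      ok <- !is.na(mm)
      ia_all <- c(ia_all, sel_a[ok])
      ib_all <- c(ib_all, sel_b[mm[ok]])
    }
  }
  if (length(ia_all) < 7)
    stop("too few common atoms (", length(ia_all),
         "): at least 7 are required, rigid-body motion would exhaust fewer")
  structure(list(pairs = cbind(a = ia_all, b = ib_all),
                 chain_map = matching$map,
                 n_common = length(ia_all)),
            class = "atom_correspondence")
}

#' Identity correspondence, bypassing sequence matching
#'
#' Pairs atoms in file order; requires both inputs to have the same atom count.
#'
#' @param A,B `structure3d` endpoints with identical atom counts.
#' @return An `atom_correspondence`.
#' @export
bypass_matching <- function(A, B) {
  if (n_atoms(A) != n_atoms(B))
    stop("bypass requires equal atom counts (", n_atoms(A), " vs ", n_atoms(B),
         "); disable bypass to let sequence matching find the common atoms")
  n <- n_atoms(A)
  structure(list(pairs = cbind(a = seq_len(n), b = seq_len(n)),
                 chain_map = NULL, n_common = n),
            class = "atom_correspondence")
}

#' Match two endpoint structures
#'
#' Convenience wrapper running [match_chains()] then [extract_common_atoms()],
#' or [bypass_matching()] when `bypass = TRUE`.
#' @param A,B `structure3d` endpoints.
#' @param bypass Skip sequence matching and pair atoms by file order.
#' @return An `atom_correspondence`.
#' @export
match_structures <- function(A, B, bypass = FALSE) {
  if (bypass) return(bypass_matching(A, B))
  extract_common_atoms(A, B, match_chains(A, B))
}

#' Least-squares rigid superposition
#'
#' Kabsch algorithm (SVD with proper-rotation correction): finds the rotation
#' and translation minimizing the RMSD of `Y` onto `X`.
#'
#' @param X,Y N x 3 coordinate matrices of paired atoms (N >= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3) such that
#'   `Y %*% t(rotation) + translation` superposes onto `X`, and the residual
#'   `rmsd` in angstrom.
#' @export
superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == 3, all(dim(X) == dim(Y)))
  if (nrow(X) < 3) stop("superpose: need at least 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Y0, X0))  # 3x3 covariance Y^T X
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-30))
    stop("superpose: degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)      # x ~ R y
  Yfit <- Y0 %*% t(R)
  rmsd <- sqrt(sum((Yfit - X0)^2) / nrow(X))
  list(rotation = R, translation = as.numeric(cx - R %*% cy), rmsd = rmsd)
}

# Apply a superposition to all coordinates of a structure.
transform_structure <- function(s, fit) {
  xyz <- coords(s) %*% t(fit$rotation)
  xyz <- sweep(xyz, 2, fit$translation, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# Human-readable match report mirroring the per-chain alignment listing.
format_match_report <- function(matching, corr, fit = NULL) {
  out <- c("# chain matching report", "")
  if (is.null(matching)) {
    out <- c(out, "matching bypassed: atoms paired by file order",
             sprintf("n_common: %d", corr$n_common))
    return(paste(out, collapse = "\n"))
  }
  for (k in seq_len(nrow(matching$map))) {
    m <- matching$map[k, ]
    aln <- matching$alignments[[k]]
    out <- c(out,
             sprintf("chain %s <-> chain %s  (score %.1f)",
                     m$chain_a, m$chain_b, m$score),
             paste0("  A: ", aln$aln1), paste0("  B: ", aln$aln2), "")
  }
  if (length(matching$unmatched_a) > 0)
    out <- c(out, paste("unmatched in A:",
                        paste(matching$unmatched_a, collapse = " ")))
  if (length(matching$unmatched_b) > 0)
    out <- c(out, paste("unmatched in B:",
                        paste(matching$unmatched_b, collapse = " ")))
  out <- c(out, sprintf("n_common: %d", corr$n_common))
  if (!is.null(fit))
    out <- c(out, sprintf("superposition rmsd: %.4f A", fit$rmsd))
  paste(out, collapse = "\n")
}
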