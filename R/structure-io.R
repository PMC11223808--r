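#' @importFrom utils read.table write.table head tail
#' @importFrom stats setNames
NULL

# Residue dictionaries: three-letter amino-acid codes (plus selenomethionine,
# kept because it sits on a protein backbone), and mono/deoxy-nucleotides.
.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M")
.DNA <- c(DA = "A", DC = "C", DG = "G", DT = "T", DI = "I")
.RNA <- c(A = "A", C = "C", G = "G", U = "U", I = "I")

residue_kind <- function(resid) {
  resid <- toupper(resid)
  ifelse(resid %in% names(.AA3), "protein",
         ifelse(resid %in% names(.DNA), "dna",
                ifelse(resid %in% names(.RNA), "rna", "other")))
}

# Representative atom per residue kind for one-bead-per-residue coarse graining.
rep_atom_name <- function(kind) {
  c(protein = "CA", dna = "C3'", rna = "C4'")[kind]
}

new_structure <- function(atoms, source_format = "pdb") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "b", "model")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atoms table lacks columns: ",
                             paste(miss, collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_format = source_format),
            class = "structure3d")
}

#' Number of atoms in a structure
#' @param s A `structure3d` object.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Atom coordinates as a matrix
#' @param s A `structure3d` object.
#' @return N x 3 numeric matrix of coordinates (angstrom).
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure3d: %d atoms, %d chain(s) [%s], %d model(s), source=%s\n",
              nrow(a), length(unique(a$chain)),
              paste(utils::head(unique(a$chain), 8), collapse = ","),
              length(unique(a$model)), x$source_format))
  invisible(x)
}

# Guess the chemical element from a PDB-style atom name when the element
# column is absent (old PDB files).
infer_element <- function(elety) {
  nm <- gsub("[0-9'*\"]", "", toupper(elety))
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  # "CA" inside a polymer residue is a carbon, not calcium, so the first
  # letter is used except for the unambiguous selenium of MSE side chains.
  ifelse(el == "H" | el == "D", "H", ifelse(two == "SE", "SE", el))
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  txt <- readLines(path, n = 200L, warn = FALSE)
  if (any(grepl("^_atom_site\\.", txt)) || any(grepl("^data_", txt)))
    return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|MODEL)", txt))) return("pdb")
  stop("cannot determine file format of '", path,
       "': neither mmCIF atom_site records nor PDB ATOM records found")
}

# ---- mmCIF parsing -----------------------------------------------------------

# Tokenize one mmCIF data line, honouring single/double quoting.
cif_tokens <- function(line) {
  toks <- regmatches(line,
                     gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  decl <- grep("^_atom_site\\.", lines)
  if (length(decl) == 0)
    stop("mmCIF format error in '", path, "': no _atom_site category found")
  fields <- sub("^_atom_site\\.", "", trimws(lines[decl]))
  first_row <- max(decl) + 1L
  rows <- character(0)
  for (k in first_row:length(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" ) next
    if (grepl("^(#|_|loop_|data_)", ln)) break
    rows <- c(rows, ln)
  }
  if (length(rows) == 0)
    stop("mmCIF format error in '", path, "': empty _atom_site loop")
  tok <- lapply(rows, cif_tokens)
  nf <- length(fields)
  # rows may wrap across lines; merge until each record has nf tokens
  recs <- list(); buf <- character(0)
  for (t in tok) {
    buf <- c(buf, t)
    if (length(buf) >= nf) { recs[[length(recs) + 1L]] <- buf[seq_len(nf)]; buf <- character(0) }
  }
  m <- do.call(rbind, recs)
  colnames(m) <- fields
  getcol <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  na_fix <- function(v) { v[v %in% c("?", ".")] <- NA_character_; v }
  num <- function(v, default = NA_real_) {
    out <- suppressWarnings(as.numeric(na_fix(v)))
    out[is.na(out)] <- default
    out
  }
  data.frame(
    type   = m[, "group_PDB"],
    elety  = na_fix(getcol("auth_atom_id", "label_atom_id")),
    alt    = na_fix(getcol("label_alt_id", "auth_alt_id")),
    resid  = toupper(na_fix(getcol("auth_comp_id", "label_comp_id"))),
    chain  = na_fix(getcol("auth_asym_id", "label_asym_id")),
    resno  = as.integer(num(getcol("auth_seq_id", "label_seq_id"))),
    insert = na_fix(getcol("pdbx_PDB_ins_code")),
    x = num(m[, "Cartn_x"]), y = num(m[, "Cartn_y"]), z = num(m[, "Cartn_z"]),
    o = num(getcol("occupancy"), default = 1),
    b = num(getcol("B_iso_or_equiv"), default = 0),
    elesy = toupper(na_fix(getcol("type_symbol"))),
    model = as.integer(num(getcol("pdbx_PDB_model_num"), default = 1)),
    stringsAsFactors = FALSE
  )
}

read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  base <- data.frame(
    type = a$type, elety = a$elety, alt = a$alt,
    resid = toupper(a$resid), chain = a$chain,
    resno = as.integer(a$resno), insert = a$insert,
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    elesy = toupper(a$elesy), model = 1L, stringsAsFactors = FALSE
  )
  if (nmod <= 1L) return(base)
  out <- vector("list", nmod)
  for (k in seq_len(nmod)) {
    ak <- base
    xyz <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    ak$x <- xyz[, 1]; ak$y <- xyz[, 2]; ak$z <- xyz[, 3]
    ak$model <- k
    out[[k]] <- ak
  }
  do.call(rbind, out)
}

# ---- filtering ---------------------------------------------------------------

# Remove HETATM records and hydrogens; resolve alternate locations by keeping
# the highest-occupancy conformer (first wins on ties). Order-preserving.
filter_atoms <- function(df) {
  df <- df[df$type == "ATOM", , drop = FALSE]
  el <- ifelse(is.na(df$elesy) | df$elesy == "", infer_element(df$elety), df$elesy)
  df <- df[!(el %in% c("H", "D")), , drop = FALSE]
  df$elesy <- el[!(el %in% c("H", "D"))]
  if (nrow(df) == 0) return(df)
  if (any(!is.na(df$alt) & !(df$alt %in% c("", ".")))) {
    # one conformer per (model, residue, atom name): highest occupancy wins,
    # the first record wins ties
    key <- paste(df$model, df$chain, df$resno,
                 ifelse(is.na(df$insert), "", df$insert), df$elety, sep = "|")
    ord <- order(key, -df$o, seq_len(nrow(df)))
    keep <- sort(ord[!duplicated(key[ord])])
    df <- df[keep, , drop = FALSE]
  }
  df$alt <- NULL
  rownames(df) <- NULL
  df
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses a structure file, removing hydrogen atoms and all HETATM (ligand,
#' water, ion) records. Alternate locations are resolved to the
#' highest-occupancy conformer. mmCIF chain identifiers of any length are
#' preserved verbatim.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param first_model_only Keep only the first model of a multi-model file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. `"auto"` detects by file
#'   extension, then by content.
#' @return A `structure3d` object: a list with an `atoms` data frame
#'   (chain, resno, insert, resid, elety, elesy, x, y, z, o, b, model) and the
#'   source format.
#' @export
read_structure <- function(path, first_model_only = TRUE, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- if (format == "auto") detect_format(path) else match.arg(format, c("pdb", "mmcif"))
  df <- if (fmt == "mmcif") read_mmcif_atoms(path) else read_pdb_atoms(path)
  df <- filter_atoms(df)
  if (first_model_only && nrow(df) > 0) {
    df <- df[df$model == min(df$model), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (nrow(df) == 0)
    stop("empty structure: no atoms remain in '", path,
         "' after removing hydrogens and HETATM records")
  new_structure(df, source_format = fmt)
}

#' Coarse-grain a structure to one bead per residue
#'
#' In `one_per_residue` mode keeps the CA atom of each amino-acid residue, the
#' C3' atom of each DNA nucleotide and the C4' atom of each RNA nucleotide
#' (C3*/C4* spellings accepted). Residues that lack their representative atom,
#' and residues that are not recognized as protein or nucleic acid, are dropped
#' with a warning. `all_atom` returns the input unchanged.
#'
#' @param s A `structure3d`.
#' @param mode `"one_per_residue"` or `"all_atom"`.
#' @return A `structure3d`.
#' @export
coarse_grain <- function(s, mode = c("one_per_residue", "all_atom")) {
  mode <- match.arg(mode)
  if (mode == "all_atom") return(s)
  a <- s$atoms
  kind <- residue_kind(a$resid)
  nm <- toupper(gsub("\\*", "'", a$elety))
  want <- rep_atom_name(kind)
  keep <- !is.na(want) & nm == want
  res_key <- paste(a$model, a$chain, a$resno,
                   ifelse(is.na(a$insert), "", a$insert), sep = "|")
  dropped_unknown <- unique(res_key[kind == "other"])
  if (length(dropped_unknown) > 0)
    warning(length(dropped_unknown),
            " residue(s) not recognized as protein/DNA/RNA were dropped")
  missing_rep <- setdiff(unique(res_key[kind != "other"]), unique(res_key[keep]))
  if (length(missing_rep) > 0)
    warning(length(missing_rep),
            " polymer residue(s) lack their representative atom and were dropped")
  out <- a[keep, , drop = FALSE]
  # one bead per residue even if the representative atom is duplicated
  out <- out[!duplicated(paste(out$model, out$chain, out$resno,
                               ifelse(is.na(out$insert), "", out$insert))), ,
             drop = FALSE]
  rownames(out) <- NULL
  new_structure(out, source_format = s$source_format)
}

#' Mean crystallographic B-factor
#'
#' @param s A `structure3d` with at least one atom.
#' @return The arithmetic mean B-factor in squared angstrom, or `NA_real_` when
#'   no atom carries a usable (positive) B-factor; reported as "unavailable" in
#'   run logs.
#' @export
mean_bfactor <- function(s) {
  if (n_atoms(s) == 0) stop("mean_bfactor: structure has no atoms")
  b <- s$atoms$b
  if (all(is.na(b)) || all(b[!is.na(b)] == 0)) return(NA_real_)
  mean(b, na.rm = TRUE)
}

# ---- mmCIF writing -----------------------------------------------------------

cif_quote <- function(v) {
  v <- as.character(v)
  v[is.na(v) | v == ""] <- "?"
  needs <- grepl("[ '\"]", v)
  v[needs] <- paste0('"', v[needs], '"')
  v
}

write_mmcif_atoms <- function(df, path, data_name = "actionpath") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", data_name), "#", "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                        "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                        "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                        "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"))),
             con)
  n <- nrow(df)
  rows <- paste("ATOM", seq_len(n), cif_quote(df$elesy), cif_quote(df$elety),
                ".", cif_quote(df$resid), cif_quote(df$chain), "1",
                df$resno, ifelse(is.na(df$insert), "?", df$insert),
                sprintf("%.3f", df$x), sprintf("%.3f", df$y),
                sprintf("%.3f", df$z), sprintf("%.2f", df$o),
                sprintf("%.2f", df$b), df$resno, cif_quote(df$resid),
                cif_quote(df$chain), cif_quote(df$elety), df$model)
  writeLines(rows, con)
  writeLines("#", con)
  invisible(path)
}

#' Write a structure to mmCIF
#'
#' @param s A `structure3d`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  write_mmcif_atoms(s$atoms, path)
  invisible(path)
}

#' Write a multi-model mmCIF trajectory
#'
#' Each frame becomes one model (numbered sequentially from 1) whose atom
#' identities are copied from the template structure. Coordinates are written
#' with three decimals, the PDB convention.
#'
#' @param frames List of coordinate sets (N x 3 matrices or 3N vectors), or a
#'   frames-by-3N matrix.
#' @param template A `structure3d` whose atoms give identities for every frame.
#' @param path Output mmCIF path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, template, path) {
  if (is.matrix(frames) && ncol(frames) == 3 * n_atoms(template))
    frames <- lapply(seq_len(nrow(frames)), function(k) frames[k, ])
  if (length(frames) == 0) stop("write_trajectory: no frames supplied")
  n <- n_atoms(template)
  blocks <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    xyz <- frames[[k]]
    xyz <- if (is.null(dim(xyz))) as_mat3(xyz) else as.matrix(xyz)
    if (nrow(xyz) != n)
      stop("frame ", k, " has ", nrow(xyz), " atoms but template has ", n)
    a <- template$atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a$model <- k
    blocks[[k]] <- a
  }
  write_mmcif_atoms(do.call(rbind, blocks), path, data_name = "trajectory")
  invisible(path)
}
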