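# Reading, filtering, coarse graining and trajectory round trips.

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

pdb_line <- function(serial, name, resn, chain, resno, x, y, z, b = 20,
                     rec = "ATOM", el = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, resn, chain, resno, x, y, z, 1.0, b, el)
}

test_that("hydrogens and HETATM records are removed on read", {
  f <- write_lines_tmp(c(
    pdb_line(1, "N",   "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA",  "ALA", "A", 1, 1.5, 0, 0, el = "C"),
    pdb_line(3, "C",   "ALA", "A", 1, 2.0, 1.0, 0),
    pdb_line(4, "O",   "ALA", "A", 1, 3.0, 1.5, 0),
    pdb_line(5, "CB",  "ALA", "A", 1, 1.8, -1.2, 0, el = "C"),
    pdb_line(6, "HB1", "ALA", "A", 1, 1.9, -2.0, 0, el = "H"),
    pdb_line(7, "O",   "HOH", "A", 2, 9, 9, 9, rec = "HETATM"),
    "END"), ".pdb")
  s <- read_structure(f)
  expect_equal(n_atoms(s), 5)
  expect_false(any(s$atoms$elety == "HB1"))
  expect_false(any(s$atoms$resid == "HOH"))
  # order preserved
  expect_equal(s$atoms$elety, c("N", "CA", "C", "O", "CB"))
})

test_that("empty or atom-free files give an empty-structure error", {
  f <- write_lines_tmp(c(pdb_line(1, "O", "HOH", "A", 1, 0, 0, 0,
                                  rec = "HETATM"), "END"), ".pdb")
  expect_error(read_structure(f), "empty structure")
  f2 <- write_lines_tmp("", ".pdb")
  expect_error(read_structure(f2))
})

test_that("mmCIF multi-character chain identifiers are preserved", {
  f <- write_lines_tmp(c(
    "data_x", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                            "label_alt_id", "label_comp_id", "label_asym_id",
                            "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
                            "occupancy", "B_iso_or_equiv", "auth_seq_id",
                            "auth_comp_id", "auth_asym_id", "auth_atom_id",
                            "pdbx_PDB_model_num")),
    "ATOM 1 C CA . ALA A 1 0.0 0.0 0.0 1.00 20.0 1 ALA A CA 1",
    "ATOM 2 C CA . GLY AB 2 3.8 0.0 0.0 1.00 25.0 2 GLY AB CA 1"), ".cif")
  s <- read_structure(f)
  expect_setequal(unique(s$atoms$chain), c("A", "AB"))
})

test_that("first_model_only keeps one model; multi-model read keeps all", {
  hp <- make_helix_pair(10, 20, seed = 3)
  A <- read_structure(hp$A$cif)
  frames <- list(vec3(coords(A)), vec3(coords(A)) + 1, vec3(coords(A)) + 2)
  out <- tempfile(fileext = ".cif")
  write_trajectory(frames, A, out)
  all_models <- read_structure(out, first_model_only = FALSE)
  expect_equal(sort(unique(all_models$atoms$model)), 1:3)
  expect_equal(n_atoms(all_models), 3 * n_atoms(A))
  one <- read_structure(out, first_model_only = TRUE)
  expect_equal(n_atoms(one), n_atoms(A))
  expect_equal(unique(one$atoms$model), 1)
})

test_that("alternate locations resolve to highest occupancy, first on tie", {
  f <- write_lines_tmp(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 20.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 20.00           C",
    "ATOM      3  CA AGLY A   2       3.800   0.000   0.000  0.50 20.00           C",
    "ATOM      4  CA BGLY A   2       4.800   0.000   0.000  0.50 20.00           C",
    "END"), ".pdb")
  s <- read_structure(f)
  expect_equal(n_atoms(s), 2)
  expect_equal(s$atoms$x, c(1.0, 3.8))  # B wins on occupancy; A wins the tie
})

test_that("coarse graining keeps CA / C3' / C4' and is idempotent", {
  # mixed protein + DNA + RNA chains
  prot <- data.frame(chain = "P", resno = 1:2, insert = NA, resid = "ALA",
                     elety = c("N", "CA"), elesy = c("N", "C"),
                     x = c(0, 1), y = 0, z = c(0, 1), o = 1, b = 10, model = 1L)
  prot <- rbind(prot, within(prot, { elety <- c("CB", "CA") }))
  prot$resno <- c(1, 1, 2, 2)
  dna <- data.frame(chain = "D", resno = 1:2, insert = NA, resid = "DA",
                    elety = c("C3'", "P"), elesy = c("C", "P"),
                    x = 5, y = c(0, 2), z = 0, o = 1, b = 10, model = 1L)
  rna <- data.frame(chain = "R", resno = 1:2, insert = NA, resid = "U",
                    elety = c("C4'", "C3'"), elesy = "C",
                    x = 8, y = c(0, 2), z = 0, o = 1, b = 10, model = 1L)
  s <- actionpath:::new_structure(rbind(prot, dna, rna))
  cg <- suppressWarnings(coarse_grain(s, "one_per_residue"))
  expect_equal(n_atoms(cg), 4)  # 2 CA + 1 C3' + 1 C4' (one DNA/RNA residue lacks its bead)
  expect_setequal(unique(cg$atoms$elety), c("CA", "C3'", "C4'"))
  cg2 <- suppressWarnings(coarse_grain(cg, "one_per_residue"))
  expect_identical(cg$atoms, cg2$atoms)
  expect_identical(coarse_grain(s, "all_atom")$atoms, s$atoms)
})

test_that("mean B-factor averages retained atoms, with unavailable sentinel", {
  hp <- make_helix_pair(10, 0, seed = 4)
  A <- read_structure(hp$A$cif)
  expect_equal(mean_bfactor(A), mean(A$atoms$b))
  z <- A; z$atoms$b <- 0
  expect_true(is.na(mean_bfactor(z)))
  one <- A; one$atoms <- one$atoms[1, , drop = FALSE]; one$atoms$b <- 15
  expect_equal(mean_bfactor(one), 15)
})

test_that("trajectory write/read round-trips coordinates to printed precision", {
  hp <- make_helix_pair(12, 25, seed = 5)
  A <- read_structure(hp$A$cif)
  out <- tempfile(fileext = ".cif")
  write_trajectory(list(coords(A)), A, out)
  back <- read_structure(out)
  expect_lt(max(abs(coords(back) - coords(A))), 1e-3)
  # second round trip is exact (idempotent at printed precision)
  out2 <- tempfile(fileext = ".cif")
  write_trajectory(list(coords(back)), back, out2)
  expect_identical(readLines(out), readLines(out2))
  expect_error(write_trajectory(list(), A, tempfile()), "no frames")
  expect_error(write_trajectory(list(coords(A)[1:5, ]), A, tempfile()),
               "atoms")
})
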