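test_that("multi-model PDB files become trajectories, single models stay structures", {
  s <- make_structure(matrix(rnorm(15), 5, 3), atom_name = c("N", "CA", "C",
                                                             "O", "CB"),
                      residue_index = 1)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  tr <- make_trajectory(s, list(s$xyz, s$xyz + 1, s$xyz + 2))
  write_pdb(tr, tmp)
  back <- read_pdb(tmp)
  expect_s3_class(back, "md_trajectory")
  expect_equal(n_frames(back), 3)
  expect_equal(nrow(back$topology$atoms), 5)

  write_pdb(s, tmp)
  expect_s3_class(read_pdb(tmp), "md_structure")
})

test_that("PDB round-trip preserves atoms and coordinates at PDB precision", {
  h <- build_ideal_helix(8)
  tr <- make_trajectory(h, list(h$xyz, h$xyz + 0.123))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, tmp)
  back <- read_pdb(tmp)
  expect_equal(back$topology$atoms$atom_name, h$atoms$atom_name)
  expect_equal(back$topology$atoms$residue_index, h$atoms$residue_index)
  expect_lt(max(abs(back$frames - tr$frames)), 1e-3)

  # large residue numbers serialize without column overflow
  h2 <- build_peptide_chain(4, start_resid = 9996)
  write_pdb(h2, tmp)
  expect_equal(read_pdb(tmp)$atoms$residue_index, h2$atoms$residue_index)

  expect_error(write_pdb(md_structure(h$atoms[0, ], h$xyz[0, , drop = FALSE]),
                         tmp), "empty")
})

test_that("inconsistent models and unparsable coordinates are hard errors", {
  h <- build_ideal_helix(4)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(make_trajectory(h, list(h$xyz, h$xyz)), tmp)
  lines <- readLines(tmp)
  atom2 <- which(startsWith(lines, "ATOM"))[nrow(h$atoms) + 1]
  writeLines(lines[-atom2], tmp)               # drop one atom from model 2
  expect_error(read_pdb(tmp), "model 2")

  write_pdb(h, tmp)
  lines <- readLines(tmp)
  substr(lines[3], 31, 38) <- " BADCOOR"
  writeLines(lines, tmp)
  expect_error(read_pdb(tmp), "line 3")
})

test_that("altloc reduction keeps the highest-occupancy conformer and solvent filtering preserves atom order", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    5  O   HOH A 101       9.000   0.000   0.000  1.00  0.00           O",
    "ATOM      6  O   ALA A   1       4.000   0.000   0.000  1.00  0.00           O",
    "END"), tmp)
  s <- read_pdb(tmp)
  expect_equal(nrow(s$atoms), 4)
  expect_equal(unname(s$xyz[s$atoms$atom_name == "CA", 1]), 2,
               tolerance = 1e-9)  # occupancy 0.60 wins
  expect_equal(s$atoms$atom_name, c("N", "CA", "C", "O"))
})

test_that("mass and radius assignment uses the standard tables with a defaulted fallback", {
  s <- build_ideal_helix(5)
  expect_equal(unique(s$atoms$mass[s$atoms$element == "C"]), 12.011)
  expect_equal(unique(s$atoms$vdw_radius[s$atoms$element == "O"]), 1.52)
  expect_true(all(s$atoms$mass > 0) && all(s$atoms$vdw_radius > 0))

  odd <- md_structure(data.frame(serial = 1, atom_name = "XX", element = "X",
                                 residue_name = "UNK", residue_index = 1,
                                 chain_id = "A"), matrix(0, 1, 3))
  expect_warning(odd <- assign_masses_radii(odd), "unknown element")
  expect_equal(odd$atoms$vdw_radius, 1.70)

  empty <- md_structure(s$atoms[0, ], s$xyz[0, , drop = FALSE])
  expect_error(assign_masses_radii(empty), "empty")
})

test_that("written PDB files agree with an independent reader", {
  skip_if_not_installed("bio3d")
  h <- build_ideal_helix(6)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, tmp)
  ref <- bio3d::read.pdb(tmp)
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE), unname(h$xyz),
               tolerance = 1e-3)
  expect_equal(ref$atom$resno, h$atoms$residue_index)
  expect_equal(trimws(ref$atom$elety), h$atoms$atom_name)
})

test_that("selection grammar resolves chains, ranges, names and backbone deterministically", {
  sub <- synthetic_substrate_conformers()$common   # chain U, resid 40-76
  sel <- resolve_selection(sub, "chain U and resid 46-76 and name CA")
  expect_length(sel$indices, 31)

  h <- build_ideal_helix(10)
  expect_length(resolve_selection(h, "backbone")$indices, 40)

  two <- build_two_chain_complex(5, 5, gap = 5, seed = 1)
  expect_error(resolve_selection(two, "chain Z"), "empty selection")
  expect_error(resolve_selection(two, "resid one"), "syntax")
  expect_error(resolve_selection(two, "frobnicate A"), "unknown keyword")

  # idempotent, order-stable, strictly increasing
  s1 <- resolve_selection(two, "chain U or chain A")
  expect_equal(s1$indices, seq_len(nrow(two$atoms)))
  expect_true(all(diff(resolve_selection(two, "name CA or backbone")$indices)
                  > 0))
  # AND binds tighter than OR
  s2 <- resolve_selection(two, "chain A and name CA or chain U and name N")
  at <- two$atoms[s2$indices, ]
  expect_true(all((at$chain_id == "A" & at$atom_name == "CA") |
                    (at$chain_id == "U" & at$atom_name == "N")))
})
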