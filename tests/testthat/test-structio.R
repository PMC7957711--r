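# PDB parsing/writing, the molecular data model, selections and RMSD.

test_that("read_pdb parses minimal files and flags glycans", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  22.000  33.000  1.00  0.00           C",
    "HETATM    2  C1  NAG A1601      15.000  22.000  33.000  1.00  0.00           C",
    "END"
  ), tf)
  s <- read_pdb(tf)
  expect_s3_class(s, "Structure")
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[1], 11.0)
  expect_true(s$atoms$is_glycan[2])
  expect_false(s$atoms$is_glycan[1])
  rt <- residue_table(s)
  expect_equal(rt$resno, c(1L, 1601L))

  expect_error(read_pdb(tf, model_index = 3), "out of range")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_pdb(empty), "no ATOM")
})

test_that("multi-model ensembles round-trip with identical topology", {
  base <- make_peptide("AKA", "extended", chain = "B")
  ens <- make_ensemble(base, n_models = 3, jitter = 0.4, seed = 11)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, tf)
  back <- read_pdb(tf)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$atoms$name, base$atoms$name)
    expect_lt(max(abs(coords(back[[i]]) - coords(ens[[i]]))), 1e-3)
  }
  one <- read_pdb(tf, model_index = 2)
  expect_s3_class(one, "Structure")
  expect_lt(max(abs(coords(one) - coords(ens[[2]]))), 1e-3)
})

test_that("write/read round-trip preserves identifiers and coordinates", {
  cx <- plant_complex(synthetic_complex_spec(seed = 3))
  s <- cx$receptor
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tf)
  back <- read_pdb(tf)
  expect_identical(back$atoms$name, s$atoms$name)
  expect_identical(back$atoms$resname, s$atoms$resname)
  expect_identical(back$atoms$chain, s$atoms$chain)
  expect_identical(back$atoms$resno, s$atoms$resno)
  expect_identical(back$atoms$is_het, s$atoms$is_het)
  expect_identical(back$atoms$is_glycan, s$atoms$is_glycan)
  expect_lt(max(abs(coords(back) - coords(s))), 1e-3)
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "END"
  ), tf)
  s <- read_pdb(tf)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 1.0) # higher occupancy wins
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 2.0) # tie: first in file
})

test_that("strip_residues removes selections and errors on empty ones", {
  cx <- plant_complex(synthetic_complex_spec(seed = 1))
  merged <- merge_structures(cx$receptor, cx$ligand)
  n_rec <- nrow(cx$receptor$atoms)
  stripped <- strip_residues(merged, "B")
  expect_equal(nrow(stripped$atoms), n_rec)
  expect_false(any(stripped$atoms$chain == "B"))

  r <- region_spec("two", members = list(c("A", 1), c("A", 2)))
  s2 <- strip_residues(cx$receptor, r)
  expect_equal(nrow(residue_table(s2)), nrow(residue_table(cx$receptor)) - 2)

  nothing <- region_spec("none", members = list(c("Z", 999)))
  expect_error(strip_residues(cx$receptor, nothing), "matched no residues")
})

test_that("atom typing follows the documented tables and is idempotent", {
  p <- assign_atom_types(make_peptide("AKDE", "extended"))
  a <- p$atoms
  # Ala CB: carbon bonded only to carbon
  expect_true(a$is_hydrophobic[a$resname == "ALA" & a$name == "CB"])
  # Lys NZ: donor and cationic
  expect_true(a$is_donor[a$name == "NZ"])
  expect_equal(a$formal_charge_class[a$name == "NZ"], "cationic")
  # backbone carbonyl O: acceptor, not donor
  o <- a[a$name == "O", ]
  expect_true(all(o$is_acceptor) && !any(o$is_donor))
  # Asp/Glu carboxylate oxygens anionic
  expect_true(all(a$formal_charge_class[a$name %in% c("OD1", "OD2", "OE1", "OE2")] == "anionic"))
  # radii from the documented tables
  expect_equal(unique(a$xs_radius[a$element == "C"]), 1.9)
  expect_equal(unique(a$sasa_radius[a$element == "N"]), 1.55)
  # idempotence
  p2 <- assign_atom_types(p)
  expect_identical(p$atoms, p2$atoms)
  # unknown element errors
  bad <- toy_structure(carbon_at(0, 0, 0), typed = FALSE)
  bad$atoms$element <- "Xx"
  expect_error(assign_atom_types(bad), "unknown element")
})

test_that("select_region resolves members, resnames and absent chains", {
  cx <- plant_complex(synthetic_complex_spec(seed = 1))
  one <- select_region(cx$receptor, region_spec("one", members = list(c("A", 2))))
  expect_equal(nrow(one), 1)
  glyc <- select_region(cx$receptor, region_spec("g", resnames = "NAG"))
  expect_equal(nrow(glyc), 1)
  expect_true(all(glyc$is_glycan))
  none <- select_region(cx$receptor, region_spec("z", members = list(c("Z", 1))))
  expect_equal(nrow(none), 0)
})

test_that("ligand_rmsd obeys identity, translation and hand-built rotation", {
  p <- make_peptide("AKA", "helix")
  expect_equal(ligand_rmsd(p, p), 0)
  q <- set_coords(p, sweep(coords(p), 2, c(3, 0, 0), "+"))
  expect_equal(ligand_rmsd(p, q), 3, tolerance = 1e-12)
  # two atoms at +-1 A from a rotation axis through the centroid: 180 deg
  # rotation moves each by the diameter => RMSD 2
  s1 <- toy_structure(rbind(carbon_at(1, 0, 0, resno = 1),
                            carbon_at(-1, 0, 0, resno = 2, name = "C2")))
  s2 <- toy_structure(rbind(carbon_at(-1, 0, 0, resno = 1),
                            carbon_at(1, 0, 0, resno = 2, name = "C2")))
  expect_equal(ligand_rmsd(s1, s2), 2)
  # symmetry and topology mismatch
  expect_equal(ligand_rmsd(q, p), ligand_rmsd(p, q))
  expect_error(ligand_rmsd(p, make_peptide("AK", "helix")), "topology")
})
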