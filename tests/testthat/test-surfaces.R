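# Shrake-Rupley accessibility against closed forms, BSA bookkeeping and the
# interface percentage metrics.

test_that("single-sphere area matches the closed form and converges", {
  s <- toy_structure(carbon_at(0, 0, 0))
  exact <- 4 * pi * (1.70 + 1.4)^2
  res <- sasa(s, n_points = 960)
  expect_equal(res$total, exact, tolerance = 0.02)
  # quadrature is exact for a lone sphere, so strict convergence is checked
  # on the two-sphere cap geometry where points can straddle the boundary
  two <- toy_structure(rbind(carbon_at(0, 0, 0, resno = 1),
                             carbon_at(3, 0, 0, resno = 2, name = "C2")))
  exact2 <- 2 * two_sphere_area_each(1.70 + 1.4, 3)
  err <- vapply(c(96, 960), function(np) abs(sasa(two, n_points = np)$total - exact2),
                numeric(1))
  expect_lt(err[2], err[1])
  expect_error(sasa(s, n_points = 8), "n_points")
})

test_that("two-sphere case matches the spherical-cap closed form", {
  R <- 1.70 + 1.4
  for (d in c(2.0, 3.0, 4.0)) {
    s <- toy_structure(rbind(carbon_at(0, 0, 0, resno = 1),
                             carbon_at(d, 0, 0, resno = 2, name = "C2")))
    res <- sasa(s, n_points = 960)
    exact_each <- two_sphere_area_each(R, d)
    expect_equal(unname(res$per_atom["1"]), exact_each, tolerance = 0.02)
    expect_equal(unname(res$per_atom["2"]), exact_each, tolerance = 0.02)
  }
  # disjoint spheres: additivity; overlapping identical spheres: symmetry
  far <- toy_structure(rbind(carbon_at(0, 0, 0, resno = 1),
                             carbon_at(100, 0, 0, resno = 2, name = "C2")))
  rf <- sasa(far, n_points = 960)
  expect_equal(rf$total, 2 * 4 * pi * R^2, tolerance = 0.02)
  expect_equal(unname(rf$per_atom["1"]), unname(rf$per_atom["2"]))
})

test_that("per-residue areas sum to totals and respect rigid motion", {
  cx <- plant_complex(synthetic_complex_spec(seed = 5))
  res <- sasa(cx$ligand, n_points = 240)
  expect_equal(sum(res$per_residue), res$total, tolerance = 1e-9)
  expect_equal(sum(res$per_atom), res$total, tolerance = 1e-9)
  expect_true(all(res$per_atom >= 0))
  set.seed(3)
  moved <- random_rigid(cx$ligand)
  res2 <- sasa(moved, n_points = 240)
  expect_equal(res2$total, res$total, tolerance = 1e-6)
  expect_equal(unname(res2$per_atom), unname(res$per_atom), tolerance = 1e-6)
})

test_that("residue_bsa books buried area consistently", {
  cx <- plant_complex(synthetic_complex_spec(seed = 1))
  rep <- residue_bsa(cx$ligand, cx$receptor, n_points = 240)
  r <- rep$residues
  expect_true(all(r$BSA >= 0))
  expect_true(all(r$percent_BSA >= 0 & r$percent_BSA <= 100))
  # sum of buried areas equals the total area lost upon complexation
  expect_equal(sum(r$BSA),
               rep$total_ligand_alone + rep$total_receptor_alone -
                 rep$total_complex,
               tolerance = 1e-6)
  # planted residues are interfacial
  lig_int <- r$key[r$molecule == "ligand" & r$interface]
  expect_true(all(paste0("B:", cx$truth$interface_lig) %in% lig_int))
  rec_int <- r$key[r$molecule == "receptor" & r$interface]
  expect_true(all(paste0("A:", cx$truth$interface_rec) %in% rec_int))
})

test_that("separated chains give all-zero interface metrics", {
  a <- assign_atom_types(make_peptide("AKA", "helix", chain = "A"))
  b <- assign_atom_types(make_peptide("ASA", "helix", chain = "B"))
  b <- set_coords(b, sweep(coords(b), 2, c(100, 0, 0), "+"))
  rep <- interface_metrics(b, a, residue_bsa(b, a, n_points = 240))
  expect_true(all(rep$residues$BSA == 0))
  expect_false(any(rep$residues$interface))
  s <- rep$summary
  expect_equal(s$ASA_TI_percent, 0)
  expect_equal(s$ASA_NavI_percent, 0)
  expect_equal(s$toxin_AA_in_interface_percent, 0)
  expect_equal(s$NAG_atoms_in_interface_percent, 0)
})

test_that("2-of-4 equal-ASA interface yields ASA_TI of 50", {
  # four identical, mutually distant single-atom ligand residues; a receptor
  # slab buries two of them partially
  lig <- toy_structure(rbind(
    carbon_at(0, 0, 0, chain = "B", resno = 1),
    carbon_at(20, 0, 0, chain = "B", resno = 2),
    carbon_at(40, 0, 0, chain = "B", resno = 3),
    carbon_at(60, 0, 0, chain = "B", resno = 4)))
  wall <- do.call(rbind, lapply(seq(-2, 2), function(k) {
    rbind(carbon_at(0 + k, 0, 4.5, resno = 100 + k, name = "C1"),
          carbon_at(20 + k, 0, 4.5, resno = 200 + k, name = "C1"))
  }))
  rec <- toy_structure(wall)
  rep <- interface_metrics(lig, rec, residue_bsa(lig, rec, n_points = 960))
  expect_equal(rep$summary$ASA_TI_percent, 50, tolerance = 0.02)
  expect_equal(rep$summary$toxin_AA_in_interface_percent, 50)
})

test_that("a fully enclosed residue reaches 100 percent buried area", {
  shell_pts <- toxdock:::golden_spiral(220) * 5.5
  shell <- do.call(rbind, lapply(seq_len(nrow(shell_pts)), function(i) {
    carbon_at(shell_pts[i, 1], shell_pts[i, 2], shell_pts[i, 3],
              chain = "A", resno = i, name = "C1")
  }))
  rec <- toy_structure(shell)
  lig <- toy_structure(carbon_at(0, 0, 0, chain = "B", resno = 1))
  rep <- residue_bsa(lig, rec, n_points = 960)
  pb <- rep$residues$percent_BSA[rep$residues$molecule == "ligand"]
  expect_equal(pb, 100, tolerance = 0.02)
})

test_that("every-ligand-residue interface gives 100 percent toxin coverage", {
  cx <- plant_complex(synthetic_complex_spec(seed = 2))
  # shrink the case: ligand vs itself shifted slightly -> everything buried
  lig <- assign_atom_types(make_peptide("AK", "extended", chain = "B"))
  rec <- assign_atom_types(make_peptide("AK", "extended", chain = "A"))
  rec <- set_coords(rec, sweep(coords(rec), 2, c(4, 0, 0), "+"))
  rep <- interface_metrics(lig, rec, residue_bsa(lig, rec, n_points = 240))
  expect_equal(rep$summary$toxin_AA_in_interface_percent, 100)
})
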