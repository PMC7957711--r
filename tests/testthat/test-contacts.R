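# RRCS ramp/matrix/aggregates and the geometric interaction detectors.

test_that("rrcs_pair follows the ramp and its sequence-adjacency rule", {
  pair_at <- function(d) {
    a <- toy_structure(carbon_at(0, 0, 0, chain = "A", resno = 1))
    b <- toy_structure(carbon_at(d, 0, 0, chain = "B", resno = 1))
    rrcs_pair(a$atoms, b$atoms)
  }
  expect_equal(pair_at(3.00), 1.0)
  expect_equal(pair_at(3.93), 0.5, tolerance = 1e-12)
  expect_equal(pair_at(4.63), 0.0)
  expect_equal(pair_at(5.5), 0.0)
  # continuity at the ramp ends
  expect_equal(pair_at(3.23 + 1e-9), 1.0, tolerance = 1e-6)
  expect_equal(pair_at(4.63 - 1e-9), 0.0, tolerance = 1e-6)
  # non-increasing in distance
  ds <- seq(2.5, 5.0, by = 0.1)
  vals <- vapply(ds, pair_at, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))

  # same-chain neighbours: backbone N/CA/C/O excluded
  p <- assign_atom_types(make_peptide("AA", "extended"))
  r1 <- p$atoms[p$atoms$resno == 1, ]
  r2 <- p$atoms[p$atoms$resno == 2, ]
  with_rule <- rrcs_pair(r1, r2, seq_adjacent_rule = TRUE)
  without <- rrcs_pair(r1, r2, seq_adjacent_rule = FALSE)
  expect_lt(with_rule, without)
})

test_that("rrcs_matrix matches brute force and partitions cleanly", {
  for (sd in c(1, 7, 23)) {
    cx <- plant_complex(synthetic_complex_spec(seed = sd))
    m <- rrcs_matrix(cx$ligand, cx$receptor)
    expect_true(all(m$entries$score >= 0))
    expect_equal(sum(m$entries$score), naive_rrcs_total(cx$ligand, cx$receptor),
                 tolerance = 1e-9)
    all_total <- rrcs_aggregate(m, partition = "all")
    expect_equal(rrcs_aggregate(m, partition = "AA") +
                   rrcs_aggregate(m, partition = "glycan"),
                 all_total, tolerance = 1e-12)
    # one-residue region equals that residue's column sum
    rec_no <- m$entries$rec_key[1]
    resno <- as.integer(sub("A:", "", rec_no))
    reg <- region_spec("one", members = list(c("A", resno)))
    expect_equal(rrcs_aggregate(m, receptor_region = reg),
                 sum(m$entries$score[m$entries$rec_key == rec_no]))
  }
  # separated chains: empty matrix
  a <- toy_structure(carbon_at(0, 0, 0))
  b <- toy_structure(carbon_at(100, 0, 0, chain = "B"))
  m0 <- rrcs_matrix(b, a)
  expect_equal(nrow(m0$entries), 0)
  expect_equal(rrcs_aggregate(m0), 0)
  expect_error(rrcs_aggregate(m0, receptor_region = region_spec("z", members = list(c("Z", 1)))),
               "no residues")
})

test_that("hydrogen-bond detector applies the heavy-atom criterion", {
  ser_at <- function(d) {
    # Ser OG donor vs a lone backbone-style carbonyl O acceptor
    lig <- toy_structure(data.frame(name = "OG", resname = "SER", chain = "B",
                                    resno = 5, x = d, y = 0, z = 0))
    rec <- toy_structure(data.frame(name = "O", resname = "GLY", chain = "A",
                                    resno = 1, x = 0, y = 0, z = 0))
    detect_hbonds(lig, rec)
  }
  hit <- ser_at(2.9)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 2.9)
  expect_equal(hit$class, "sb") # donor side chain, acceptor backbone
  expect_equal(nrow(ser_at(3.8)), 0)
  # two hydrophobic carbons: no donors/acceptors, no record
  c2 <- toy_structure(carbon_at(3, 0, 0, chain = "B"))
  c1 <- toy_structure(carbon_at(0, 0, 0))
  expect_equal(nrow(detect_hbonds(c2, c1)), 0)
})

test_that("salt-bridge detector pairs opposite charges only, minimal distance", {
  lys <- function(x, chain = "B", resno = 1) {
    toy_structure(data.frame(name = "NZ", resname = "LYS", chain = chain,
                             resno = resno, x = x, y = 0, z = 0))
  }
  glu <- toy_structure(data.frame(
    name = c("OE1", "OE2"), resname = "GLU", chain = "A", resno = 9,
    x = c(0, -1.1), y = c(0, 0.6), z = 0))
  hit <- detect_salt_bridges(lys(3.5), glu)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 3.5) # minimal of the two oxygens
  expect_equal(nrow(detect_salt_bridges(lys(4.5), glu)), 0)
  expect_equal(nrow(detect_salt_bridges(lys(3.0), lys(0, chain = "A", resno = 2))), 0)
})

test_that("pi-cation detector respects distance and ring-normal angle", {
  # ideal phenyl ring in the xy-plane, centroid at origin
  th <- seq(0, 300, by = 60) * pi / 180
  ring <- data.frame(
    name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    resname = "PHE", chain = "A", resno = 3,
    x = 1.39 * cos(th), y = 1.39 * sin(th), z = 0)
  rec <- toy_structure(ring)
  nz_at <- function(x, y, z) {
    toy_structure(data.frame(name = "NZ", resname = "LYS", chain = "B",
                             resno = 1, x = x, y = y, z = z))
  }
  on_axis <- detect_pi_cation(nz_at(0, 0, 4), rec)
  expect_equal(nrow(on_axis), 1)
  expect_equal(on_axis$distance, 4)
  expect_lt(on_axis$angle, 1)
  expect_equal(nrow(detect_pi_cation(nz_at(4, 0, 0), rec)), 0) # in-plane
  expect_equal(nrow(detect_pi_cation(nz_at(0, 0, 7), rec)), 0) # too far
  at60 <- detect_pi_cation(nz_at(4 * sin(59 * pi / 180), 0,
                                 4 * cos(59 * pi / 180)), rec)
  expect_equal(nrow(at60), 1) # just inside the angular cutoff
})

test_that("hydrophobic detector counts qualifying carbon pairs per residue pair", {
  lig <- assign_atom_types(make_peptide("L", "extended", chain = "B"))
  # place a two-carbon hydrophobic probe near the leucine side chain
  cd1 <- lig$atoms[lig$atoms$name == "CD1", c("x", "y", "z")]
  rec <- toy_structure(rbind(
    carbon_at(cd1$x + 4.0, cd1$y, cd1$z, resno = 1, name = "C1"),
    carbon_at(cd1$x + 4.0, cd1$y, cd1$z + 1.5, resno = 1, name = "C2")))
  hit <- detect_hydrophobic(lig, rec)
  expect_equal(nrow(hit), 1)
  expect_gte(hit$n_atom_pairs, 2)
  expect_equal(hit$distance, 4.0, tolerance = 1e-6)
  # carbonyl carbon is not hydrophobic: no record
  co <- toy_structure(data.frame(
    name = c("C", "O"), resname = "GLY", chain = "A", resno = 1,
    x = c(cd1$x + 4.0, cd1$x + 5.2), y = cd1$y, z = cd1$z))
  expect_false(co$atoms$is_hydrophobic[1])
  expect_equal(nrow(detect_hydrophobic(lig, co)), 0)
})

test_that("close contacts use the strict distance cutoff", {
  a <- toy_structure(carbon_at(0, 0, 0))
  near <- toy_structure(carbon_at(2.4, 0, 0, chain = "B"))
  fareno <- toy_structure(carbon_at(2.6, 0, 0, chain = "B"))
  expect_equal(nrow(close_contact_residues(near, a)), 1)
  expect_equal(nrow(close_contact_residues(fareno, a)), 0)
  expect_equal(nrow(close_contact_residues(toy_structure(carbon_at(50, 0, 0, chain = "B")), a)), 0)
  expect_error(close_contact_residues(near, a, cutoff = 0), "positive")
})

test_that("detectors equal exhaustive pair-scan oracles on planted fixtures", {
  for (sd in c(2, 9, 31)) {
    cx <- plant_complex(synthetic_complex_spec(seed = sd))
    det <- detect_all_contacts(cx$ligand, cx$receptor)
    expect_identical(
      sort(unique(paste(det$hbond$lig_key, det$hbond$rec_key))),
      sort(unique(paste(paste0("B:", sub(" .*", "", naive_hbond_pairs(cx$ligand, cx$receptor))),
                        paste0("A:", sub(".* ", "", naive_hbond_pairs(cx$ligand, cx$receptor))))))
    )
    expect_identical(
      sort(unique(paste(det$hydrophobic$lig_key, det$hydrophobic$rec_key))),
      sort(unique(paste(paste0("B:", sub(" .*", "", naive_hydrophobic_pairs(cx$ligand, cx$receptor))),
                        paste0("A:", sub(".* ", "", naive_hydrophobic_pairs(cx$ligand, cx$receptor))))))
    )
    expect_identical(
      sort(unique(paste(det$salt_bridge$lig_key, det$salt_bridge$rec_key))),
      sort(unique(paste(paste0("B:", sub(" .*", "", naive_salt_bridge_pairs(cx$ligand, cx$receptor))),
                        paste0("A:", sub(".* ", "", naive_salt_bridge_pairs(cx$ligand, cx$receptor))))))
    )
  }
})

test_that("detector output is invariant under global rigid motion", {
  cx <- plant_complex(synthetic_complex_spec(seed = 6))
  det0 <- detect_all_contacts(cx$ligand, cx$receptor)
  set.seed(77)
  axis <- stats::rnorm(3); ang <- stats::runif(1, 0, 2 * pi)
  shift <- stats::runif(3, -40, 40)
  lig2 <- random_rigid(cx$ligand, angle = ang, axis = axis, shift = shift)
  rec2 <- random_rigid(cx$receptor, angle = ang, axis = axis, shift = shift)
  det1 <- detect_all_contacts(lig2, rec2)
  expect_identical(contact_pair_set(det0), contact_pair_set(det1))
  expect_equal(det1$hbond$distance, det0$hbond$distance, tolerance = 1e-9)
  m0 <- rrcs_matrix(cx$ligand, cx$receptor)
  m1 <- rrcs_matrix(lig2, rec2)
  expect_equal(m1$entries$score, m0$entries$score, tolerance = 1e-9)
})

test_that("records never pair a residue with itself and are inter-chain", {
  cx <- plant_complex(synthetic_complex_spec(seed = 12))
  det <- detect_all_contacts(cx$ligand, cx$receptor)
  for (k in c("hbond", "salt_bridge", "pi_cation", "hydrophobic")) {
    df <- det[[k]]
    if (!nrow(df)) next
    expect_true(all(grepl("^B:", df$lig_key)))
    expect_true(all(grepl("^A:", df$rec_key)))
  }
})
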