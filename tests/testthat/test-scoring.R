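# Empirical pair terms, complex scoring vs the naive oracle, decomposition,
# clustering and the rigid search contracts.

test_that("surface distance and pair terms match hand values", {
  s1 <- toy_structure(carbon_at(0, 0, 0))
  s2 <- toy_structure(carbon_at(3.8, 0, 0, chain = "B"))
  expect_equal(surface_distance(s1$atoms[1, ], s2$atoms[1, ]), 0)
  s3 <- toy_structure(data.frame(name = "O1", resname = "LIG", chain = "B",
                                 resno = 1, x = 5, y = 0, z = 0))
  expect_equal(surface_distance(s1$atoms[1, ], s3$atoms[1, ]), 5 - 3.6)

  tm <- pair_terms(0)
  expect_equal(unname(tm[, "gauss1"]), 1)
  expect_equal(unname(tm[, "repulsion"]), 0)
  expect_equal(unname(pair_terms(1.0, both_hydrophobic = TRUE)[, "hydrophobic"]), 0.5)
  expect_equal(unname(pair_terms(-0.35, donor_acceptor = TRUE)[, "hbond"]), 0.5)
  expect_equal(unname(pair_terms(2, both_hydrophobic = FALSE)[, "hydrophobic"]), 0)
  # continuity of ramps at their ends
  expect_equal(unname(pair_terms(0.5 + 1e-12, both_hydrophobic = TRUE)[, "hydrophobic"]), 1,
               tolerance = 1e-9)
  expect_equal(unname(pair_terms(1.5, both_hydrophobic = TRUE)[, "hydrophobic"]), 0)
})

test_that("single C..C contact reproduces the hand-evaluated total", {
  rec <- toy_structure(carbon_at(0, 0, 0))
  lig <- toy_structure(carbon_at(3.8, 0, 0, chain = "B"))
  b <- score_complex(rec, lig)
  hand <- -0.035579 * 1 - 0.005156 * exp(-2.25) - 0.035069 * 1
  expect_equal(b$total, hand, tolerance = 1e-12)
  expect_equal(b$total, -0.0712, tolerance = 1e-3)
})

test_that("score_complex equals the naive oracle and conserves per-residue sums", {
  set.seed(42)
  seqs <- c("AK", "DE", "SL", "QN", "FW", "KGE", "ASV")
  for (rep in 1:12) {
    rseq <- sample(seqs, 1)
    lseq <- sample(seqs, 1)
    rec <- assign_atom_types(make_peptide(rseq, "extended", chain = "A"))
    lig <- assign_atom_types(make_peptide(lseq, "helix", chain = "B"))
    lig <- random_rigid(lig, shift = stats::runif(3, -6, 6))
    b <- score_complex(rec, lig)
    o <- naive_score(rec, lig)
    expect_equal(b$total, o$total, tolerance = 1e-9)
    expect_equal(sum(b$per_receptor_residue), b$total, tolerance = 1e-9)
    expect_equal(sum(b$per_ligand_residue), b$total, tolerance = 1e-9)
    if (length(o$per_rec)) {
      expect_equal(unname(b$per_receptor_residue[sort(names(o$per_rec))]),
                   unname(o$per_rec[sort(names(o$per_rec))]), tolerance = 1e-9)
    }
  }
})

test_that("separated molecules score zero and empty molecules error", {
  rec <- toy_structure(carbon_at(0, 0, 0))
  lig <- toy_structure(carbon_at(100, 0, 0, chain = "B"))
  b <- score_complex(rec, lig)
  expect_equal(b$total, 0)
  expect_length(b$per_receptor_residue, 0)
  water <- toy_structure(data.frame(name = "O", resname = "HOH", chain = "B",
                                    resno = 1, x = 0, y = 0, z = 0))
  expect_error(score_complex(rec, water), "empty molecule")
})

test_that("two-atom total decays monotonically and vanishes past the cutoff", {
  rec <- toy_structure(carbon_at(0, 0, 0))
  dists <- seq(6.8, 8.6, by = 0.15)
  totals <- vapply(dists, function(d) {
    score_complex(rec, toy_structure(carbon_at(d, 0, 0, chain = "B")))$total
  }, numeric(1))
  mags <- abs(totals)
  expect_true(all(diff(mags[dists <= 8]) <= 1e-12))
  expect_true(all(totals[dists > 8] == 0))
})

test_that("scoring is invariant under a global rigid motion", {
  cx <- plant_complex(synthetic_complex_spec(seed = 2))
  b0 <- score_complex(cx$receptor, cx$ligand)
  set.seed(9)
  axis <- stats::rnorm(3); ang <- stats::runif(1, 0, 2 * pi)
  shift <- stats::runif(3, -30, 30)
  rec2 <- random_rigid(cx$receptor, angle = ang, axis = axis, shift = shift)
  lig2 <- random_rigid(cx$ligand, angle = ang, axis = axis, shift = shift)
  b1 <- score_complex(rec2, lig2)
  expect_lt(abs(b1$total - b0$total), 1e-6)
})

test_that("decompose_by_residue sorts, restricts to regions and matches brute force", {
  cx <- plant_complex(synthetic_complex_spec(seed = 4))
  b <- score_complex(cx$receptor, cx$ligand)
  d <- decompose_by_residue(b)
  expect_true(all(diff(d$contribution) >= 0)) # most negative first
  o <- naive_score(cx$receptor, cx$ligand)
  top_oracle <- names(o$per_rec)[which.min(o$per_rec)]
  expect_equal(d$key[1], top_oracle)
  reg <- region_spec("r2", members = list(c("A", 2)))
  d2 <- decompose_by_residue(b, region = reg)
  expect_true(all(d2$key == "A:2"))
})

test_that("cluster_poses keeps a survivor set pairwise beyond the threshold", {
  lig <- make_peptide("AKA", "helix", chain = "B")
  hxyz <- coords(lig, heavy = TRUE)
  c0 <- colMeans(hxyz)
  mk <- function(dx) {
    p <- identity_pose()
    p$translation <- c(dx, 0, 0)
    p$coords <- sweep(hxyz, 2, c(dx, 0, 0), "+")
    p
  }
  dups <- lapply(c(0, 0.1, 0.05), mk)
  expect_length(cluster_poses(dups, 2), 1)
  two <- lapply(c(0, 10), mk)
  expect_length(cluster_poses(two, 2), 2)
  chain <- lapply(seq(0, 9, by = 1), mk)
  kept <- cluster_poses(chain, 2)
  xs <- vapply(kept, function(p) p$translation[1], numeric(1))
  expect_true(all(dist(xs) > 2))
})

test_that("dock_rigid validates its configuration", {
  cx <- plant_complex(synthetic_complex_spec(seed = 1))
  cen <- colMeans(coords(cx$ligand, heavy = TRUE))
  expect_error(search_config(cen, c(10, 10, 10), n_restarts = 0), "n_restarts")
  expect_error(search_config(cen, c(10, 10, 10), keep_top = 0), "keep_top")
  expect_error(search_config(cen, c(-1, 10, 10)), "half-widths")
  tiny <- search_config(cen, c(0.5, 0.5, 0.5), n_restarts = 1)
  expect_error(dock_rigid(cx$receptor, cx$ligand, tiny), "too small")
  far <- search_config(cen + c(50, 0, 0), c(12, 12, 12), n_restarts = 1)
  expect_error(dock_rigid(cx$receptor, cx$ligand, far), "enclose")
})

test_that("dock_rigid is deterministic and ranks poses by score", {
  cx <- plant_complex(synthetic_complex_spec(seed = 1))
  cfg <- recovery_config(cx, seed = 5, n_restarts = 4)
  cfg$steps <- 120L
  r1 <- dock_rigid(cx$receptor, cx$ligand, cfg)
  r2 <- dock_rigid(cx$receptor, cx$ligand, cfg)
  expect_identical(
    lapply(r1, function(r) list(r$pose$rotation, r$pose$translation,
                                r$breakdown$total)),
    lapply(r2, function(r) list(r$pose$rotation, r$pose$translation,
                                r$breakdown$total))
  )
  totals <- vapply(r1, function(r) r$breakdown$total, numeric(1))
  expect_true(all(diff(totals) >= 0))
  # RNG state of the session is untouched
  set.seed(123); before <- .Random.seed
  invisible(dock_rigid(cx$receptor, cx$ligand, cfg))
  expect_identical(.Random.seed, before)
})
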