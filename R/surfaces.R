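# Shrake-Rupley solvent-accessible surface area, buried surface area upon
# complexation, and interface percentage metrics.
#
# The point sphere is a deterministic golden-section spiral (no RNG), so all
# areas are exactly reproducible and rigid-motion invariance holds to the
# quadrature resolution when spheres are generated in the molecule frame.

# Intrinsic orthonormal frame of a coordinate set: inertia eigenvectors with
# signs fixed by the third moment along each axis. Rotating the molecule
# rotates the frame with it, so quadrature spheres generated in this frame
# make all areas rigid-motion invariant (degenerate symmetric cases fall back
# to an arbitrary but harmless orientation).
molecule_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  cen <- colMeans(xyz)
  xc <- sweep(xyz, 2, cen)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:3) {
    sk <- sum((xc %*% V[, k])^3)
    if (sk < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each heavy atom is covered with \code{n_points} quasi-uniform points at
#' radius \code{sasa_radius + probe}; a point is accessible iff it lies
#' outside every neighbour's inflated sphere. Hydrogens are excluded.
#'
#' @param s typed Structure
#' @param probe probe radius, Angstrom (water: 1.4)
#' @param n_points points per atom sphere (quadrature resolution)
#' @param frame optional 3x3 rotation applied to the point sphere; defaults
#'   to the molecule's intrinsic inertia frame. \code{\link{residue_bsa}}
#'   passes the complex frame to all of its evaluations so that isolated and
#'   in-complex areas share one quadrature.
#' @return SASAResult: list with \code{per_atom} (Angstrom^2, one value per
#'   heavy atom, named by atom row), \code{per_residue} (named by residue
#'   key), \code{total}, \code{probe}, \code{n_points}, and the heavy-atom
#'   index \code{atom_rows}
#' @export
sasa <- function(s, probe = 1.4, n_points = 960L, frame = NULL) {
  if (n_points < 16) stop("sasa: n_points must be >= 16")
  require_typed(s, "sasa")
  a <- s$atoms
  heavy <- which(!a$is_hydrogen)
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  rad <- a$sasa_radius[heavy] + probe
  n <- length(heavy)
  if (is.null(frame)) frame <- molecule_frame(xyz)
  sphere <- golden_spiral(n_points) %*% t(frame)
  per_atom <- numeric(n)

  # neighbour lists from one pairwise pass
  d2 <- cross_dist2(xyz, xyz)
  rsum <- outer(rad, rad, "+")
  nb <- d2 < rsum^2 & d2 > 1e-12
  for (i in seq_len(n)) {
    pts <- sweep(sphere * rad[i], 2, xyz[i, ], "+")
    js <- which(nb[i, ])
    if (length(js)) {
      pd2 <- cross_dist2(pts, xyz[js, , drop = FALSE])
      buried <- rowSums(pd2 < matrix(rad[js]^2, n_points, length(js),
                                     byrow = TRUE) - 1e-12) > 0
      acc <- sum(!buried)
    } else {
      acc <- n_points
    }
    per_atom[i] <- acc / n_points * 4 * pi * rad[i]^2
  }

  keys <- paste0(a$chain[heavy], ":", a$resno[heavy], a$ins[heavy])
  pr <- rowsum(per_atom, factor(keys, levels = unique(keys)))
  structure(list(
    per_atom = stats::setNames(per_atom, as.character(heavy)),
    per_residue = stats::setNames(as.vector(pr), rownames(pr)),
    total = sum(per_atom),
    probe = probe, n_points = as.integer(n_points),
    atom_rows = heavy
  ), class = "SASAResult")
}

#' @export
print.SASAResult <- function(x, ...) {
  cat(sprintf("SASAResult: total %.1f A^2 over %d atoms (probe %.2f, %d points)\n",
              x$total, length(x$per_atom), x$probe, x$n_points))
  invisible(x)
}

#' Per-residue buried surface area upon complexation
#'
#' Computes, for every residue of both molecules, the accessible area in the
#' isolated molecule and in the assembled complex; BSA is the difference
#' (clamped at zero beyond quadrature noise) and percent_BSA is BSA relative
#' to the residue's isolated area. A residue is interfacial iff its BSA
#' exceeds \code{interface_bsa_min}.
#'
#' @param ligand,receptor typed Structures with disjoint chain ids
#' @param probe probe radius, Angstrom
#' @param n_points sphere points per atom
#' @param interface_bsa_min per-residue interface threshold, Angstrom^2
#' @param interface_atom_bsa_min per-atom interface threshold, Angstrom^2
#' @return InterfaceReport (per-residue part): list with \code{residues}
#'   data.frame(molecule, key, resname, is_glycan, ASA_isolated, ASA_complex,
#'   BSA, percent_BSA, interface), \code{atoms} data.frame for glycan
#'   accounting, totals of the three SASA runs, and the parameters
#' @export
residue_bsa <- function(ligand, receptor, probe = 1.4, n_points = 960L,
                        interface_bsa_min = 0.1,
                        interface_atom_bsa_min = 0.01) {
  require_typed(ligand, "residue_bsa")
  require_typed(receptor, "residue_bsa")
  cx <- merge_structures(receptor, ligand)
  frame <- molecule_frame(coords(cx, heavy = TRUE))
  s_lig <- sasa(ligand, probe, n_points, frame = frame)
  s_rec <- sasa(receptor, probe, n_points, frame = frame)
  s_cx <- sasa(cx, probe, n_points, frame = frame)

  build <- function(s, iso, molecule) {
    rt <- residue_table(s)
    iso_area <- iso$per_residue[rt$key]
    cx_area <- s_cx$per_residue[rt$key]
    cx_area[is.na(cx_area)] <- 0
    bsa <- pmax(iso_area - cx_area, 0)
    data.frame(
      molecule = molecule, key = rt$key, resname = rt$resname,
      is_glycan = rt$is_glycan,
      ASA_isolated = as.vector(iso_area), ASA_complex = as.vector(cx_area),
      BSA = as.vector(bsa),
      percent_BSA = ifelse(iso_area > 0, 100 * bsa / iso_area, 0),
      interface = as.vector(bsa) > interface_bsa_min,
      stringsAsFactors = FALSE
    )
  }
  residues <- rbind(build(ligand, s_lig, "ligand"),
                    build(receptor, s_rec, "receptor"))
  rownames(residues) <- NULL

  # per-atom BSA (complex atoms are receptor rows then ligand rows)
  atom_bsa <- function(s, iso, offset, molecule) {
    rows <- iso$atom_rows
    iso_a <- as.vector(iso$per_atom)
    cx_rows_all <- s_cx$atom_rows
    cx_map <- match(rows + offset, cx_rows_all)
    cx_a <- as.vector(s_cx$per_atom)[cx_map]
    data.frame(
      molecule = molecule, row = rows, name = s$atoms$name[rows],
      key = paste0(s$atoms$chain[rows], ":", s$atoms$resno[rows],
                   s$atoms$ins[rows]),
      is_glycan = s$atoms$is_glycan[rows],
      BSA = pmax(iso_a - cx_a, 0),
      interface = pmax(iso_a - cx_a, 0) > interface_atom_bsa_min,
      stringsAsFactors = FALSE
    )
  }
  atoms <- rbind(atom_bsa(receptor, s_rec, 0L, "receptor"),
                 atom_bsa(ligand, s_lig, nrow(receptor$atoms), "ligand"))
  rownames(atoms) <- NULL

  structure(list(
    residues = residues, atoms = atoms,
    total_ligand_alone = s_lig$total, total_receptor_alone = s_rec$total,
    total_complex = s_cx$total,
    probe = probe, n_points = as.integer(n_points),
    interface_bsa_min = interface_bsa_min,
    interface_atom_bsa_min = interface_atom_bsa_min
  ), class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  ni <- sum(x$residues$interface)
  cat(sprintf("InterfaceReport: %d interface residues; complex ASA %.1f A^2\n",
              ni, x$total_complex))
  if (!is.null(x$summary)) {
    cat(sprintf("  ASA_TI %.1f%%  ASA_NavI %.1f%%  toxin AA in interface %.1f%%  glycan atoms in interface %.1f%%\n",
                x$summary$ASA_TI_percent, x$summary$ASA_NavI_percent,
                x$summary$toxin_AA_in_interface_percent,
                x$summary$NAG_atoms_in_interface_percent))
  }
  invisible(x)
}

#' Interface percentage metrics
#'
#' Completes an InterfaceReport with the four headline percentages:
#' \itemize{
#'   \item \code{ASA_TI_percent}: share of the ligand's isolated ASA carried
#'     by its interface residues;
#'   \item \code{ASA_NavI_percent}: the receptor analogue;
#'   \item \code{toxin_AA_in_interface_percent}: share of ligand amino-acid
#'     residues that are interfacial;
#'   \item \code{NAG_atoms_in_interface_percent}: share of glycan heavy atoms
#'     with per-atom BSA above the atom threshold.
#' }
#'
#' @param ligand,receptor typed Structures (as passed to
#'   \code{\link{residue_bsa}})
#' @param report InterfaceReport from \code{\link{residue_bsa}}
#' @return InterfaceReport with a \code{summary} list added
#' @export
interface_metrics <- function(ligand, receptor, report) {
  stopifnot(inherits(report, "InterfaceReport"))
  res <- report$residues
  lig <- res[res$molecule == "ligand", , drop = FALSE]
  rec <- res[res$molecule == "receptor", , drop = FALSE]
  if (sum(lig$ASA_isolated) <= 0) stop("interface_metrics: ligand has zero ASA")

  asa_pct <- function(df) {
    tot <- sum(df$ASA_isolated)
    if (tot <= 0) return(0)
    100 * sum(df$ASA_isolated[df$interface]) / tot
  }
  lig_aa <- lig[!lig$is_glycan, , drop = FALSE]
  glyc_atoms <- report$atoms[report$atoms$is_glycan, , drop = FALSE]

  report$summary <- list(
    ASA_TI_percent = asa_pct(lig),
    ASA_NavI_percent = asa_pct(rec),
    toxin_AA_in_interface_percent =
      if (nrow(lig_aa)) 100 * sum(lig_aa$interface) / nrow(lig_aa) else 0,
    NAG_atoms_in_interface_percent =
      if (nrow(glyc_atoms)) 100 * sum(glyc_atoms$interface) / nrow(glyc_atoms)
      else 0
  )
  report
}

#' Write an interface report as TSV
#'
#' Emits the per-residue table followed by a commented summary block when the
#' four percentage metrics have been computed.
#' @param report InterfaceReport
#' @param path output path
#' @return invisibly, the per-residue data.frame
#' @export
write_interface_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report$residues, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(report$summary)) {
    for (nm in names(report$summary)) {
      writeLines(sprintf("# %s\t%.4f", nm, report$summary[[nm]]), con)
    }
  }
  invisible(report$residues)
}
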