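# Physical atom typing: scoring radii, surface radii, hydrophobicity,
# hydrogen-bond donor/acceptor capability and formal charge class.
#
# All typing is heavy-atom based. Hydrogens, if present in the file, are
# parsed but carry no type and are excluded from scoring, contact and surface
# computations.

# Scoring radii (Angstrom) used by the empirical pair terms.
XS_RADII <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
              F = 1.5, Cl = 1.8, Br = 2.0, I = 2.2)

# Surface radii (Angstrom) for Shrake-Rupley accessibility; elements outside
# the table fall back to 1.80.
SASA_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
SASA_RADIUS_DEFAULT <- 1.80

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

# Side-chain heavy-atom donor/acceptor table for the standard amino acids.
# Backbone N (donor, except proline) and backbone O/OXT (acceptor) are handled
# separately. His defaults to neutral: ND1/NE2 are acceptors; a configurable
# protonated-His list turns them into cationic donors.
DONOR_TABLE <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), TRP = "NE1"
)
ACCEPTOR_TABLE <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD"
)
CATIONIC_TABLE <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
ANIONIC_TABLE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Infer covalent bonds between heavy atoms by distance
#'
#' A heavy-atom pair is bonded if closer than 1.9 Angstrom (2.2 when either
#' atom is S or P). Robust for standard residues without a connectivity
#' dictionary; used only for hydrophobic-carbon typing.
#'
#' @param s Structure
#' @return two-column integer matrix of atom row indices (i < j)
#' @export
infer_bonds <- function(s) {
  a <- s$atoms
  heavy <- which(!a$is_hydrogen)
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  el <- a$element[heavy]
  n <- length(heavy)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  # grid-free: block over pairs within 2.2 A using cell lists via cut on x
  d2 <- cross_dist2(xyz, xyz)
  lim <- matrix(1.9, n, n)
  sp <- el %in% c("S", "P")
  lim[sp, ] <- 2.2
  lim[, sp] <- 2.2
  hit <- which(d2 > 1e-6 & d2 < lim^2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  cbind(heavy[hit[, 1]], heavy[hit[, 2]])
}

#' Assign physical atom types to a Structure
#'
#' Fills in, for every heavy atom: scoring radius \code{xs_radius}, surface
#' radius \code{sasa_radius}, \code{is_hydrophobic} (a carbon bonded only to
#' carbon/hydrogen), \code{is_donor} / \code{is_acceptor} (per-residue table;
#' backbone N is a donor except in proline, backbone O and OXT are acceptors;
#' glycan oxygens are both donor and acceptor), \code{formal_charge_class}
#' (\code{"cationic"} for Lys NZ, Arg NE/NH1/NH2 and protonated-His ring
#' nitrogens; \code{"anionic"} for Asp OD1/OD2, Glu OE1/OE2 and C-terminal
#' OXT; otherwise \code{"neutral"}), and \code{is_backbone}. Idempotent.
#'
#' @param s Structure
#' @param protonated_his data.frame(chain, resno) of His residues to treat as
#'   protonated (cationic donors at ND1/NE2); default none
#' @return typed Structure
#' @export
assign_atom_types <- function(s, protonated_his = NULL) {
  a <- s$atoms
  heavy <- !a$is_hydrogen
  unknown <- heavy & !(a$element %in% names(XS_RADII)) &
    !(a$element %in% c("Na", "Mg", "Zn", "Fe", "Ca", "K", "Se"))
  if (any(unknown)) {
    bad <- a[which(unknown)[1], ]
    stop(sprintf("assign_atom_types: unknown element '%s' (atom %s %s %s%d)",
                 bad$element, bad$name, bad$resname, bad$chain, bad$resno))
  }

  a$xs_radius <- unname(XS_RADII[a$element])
  a$xs_radius[is.na(a$xs_radius) & heavy] <- 1.9 # metals etc.: excluded later
  a$sasa_radius <- unname(SASA_RADII[a$element])
  a$sasa_radius[is.na(a$sasa_radius) & heavy] <- SASA_RADIUS_DEFAULT
  a$xs_radius[!heavy] <- NA_real_
  a$sasa_radius[!heavy] <- NA_real_

  a$is_backbone <- heavy & !a$is_het & a$name %in% BACKBONE_NAMES

  # hydrophobic: carbon whose bonded heavy neighbours are all carbon
  s$atoms <- a
  bonds <- infer_bonds(s)
  non_c_neighbour <- rep(FALSE, nrow(a))
  if (nrow(bonds)) {
    el_i <- a$element[bonds[, 1]]
    el_j <- a$element[bonds[, 2]]
    non_c_neighbour[bonds[, 1][el_j != "C"]] <- TRUE
    non_c_neighbour[bonds[, 2][el_i != "C"]] <- TRUE
  }
  a$is_hydrophobic <- heavy & a$element == "C" & !non_c_neighbour

  match_table <- function(tbl) {
    out <- rep(FALSE, nrow(a))
    for (rn in names(tbl)) {
      out <- out | (a$resname == rn & a$name %in% tbl[[rn]])
    }
    out & heavy
  }

  a$is_donor <- match_table(DONOR_TABLE) |
    (heavy & !a$is_het & a$name == "N" & a$resname != "PRO")
  a$is_acceptor <- match_table(ACCEPTOR_TABLE) |
    (heavy & !a$is_het & a$name %in% c("O", "OXT"))
  # glycan oxygens are both donor and acceptor; glycan amide N is a donor
  glyc_o <- heavy & a$is_glycan & a$element == "O"
  a$is_donor <- a$is_donor | glyc_o | (heavy & a$is_glycan & a$element == "N")
  a$is_acceptor <- a$is_acceptor | glyc_o

  a$formal_charge_class <- "neutral"
  a$formal_charge_class[match_table(CATIONIC_TABLE)] <- "cationic"
  a$formal_charge_class[match_table(ANIONIC_TABLE) |
                          (heavy & !a$is_het & a$name == "OXT")] <- "anionic"
  if (!is.null(protonated_his) && nrow(protonated_his)) {
    for (i in seq_len(nrow(protonated_his))) {
      hit <- a$resname == "HIS" & a$chain == protonated_his$chain[i] &
        a$resno == protonated_his$resno[i] & a$name %in% c("ND1", "NE2")
      a$formal_charge_class[hit] <- "cationic"
      a$is_donor[hit] <- TRUE
      a$is_acceptor[hit] <- FALSE
    }
  }
  a$formal_charge_class[!heavy] <- "neutral"

  s$atoms <- a
  s$typed <- TRUE
  s
}

# Heavy atoms that take part in scoring/contacts: typed, not hydrogen, not
# water, not an isolated metal ion.
scoring_atom_mask <- function(s) {
  a <- s$atoms
  !a$is_hydrogen & !(a$resname %in% c("HOH", "WAT")) &
    (a$element %in% names(XS_RADII))
}

require_typed <- function(s, fn) {
  if (!isTRUE(s$typed)) stop(fn, ": structure must pass assign_atom_types() first")
  invisible(TRUE)
}
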